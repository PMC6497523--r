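test_that("ground truth uses closed forms for the simple shapes", {
  ci <- fx_circle()
  expect_equal(ci$truth$area, 25 * pi)
  expect_equal(ci$truth$perimeter, 10 * pi)
  sq <- fx_square()
  expect_equal(sq$truth$area, 16)
  expect_equal(sq$truth$perimeter, 16)
  el <- make_outline(shape_spec("ellipse", a = 8, b = 4), n_vertices = 720)
  # polygonal measurement converges to the elliptic-integral perimeter
  expect_equal(outline_perimeter(el$outline), el$truth$perimeter,
               tolerance = 1e-3)
  expect_error(shape_spec("circle", radius = -1), "positive")
  expect_error(shape_spec("falciform", noise = 0.7), "noise")
})

test_that("falciform ground truth comes from the dense polygonization", {
  mo <- fx_falciform()
  expect_equal(outline_area(mo$outline), mo$truth$area, tolerance = 0.01)
  expect_equal(outline_perimeter(mo$outline), mo$truth$perimeter,
               tolerance = 0.01)
  # named features, ordered along the perimeter from the construction
  expect_named(mo$truth$features,
               c("tip", "under_hook", "ventral", "caudal_base"))
  expect_true(all(mo$truth$features >= 0 & mo$truth$features < 1))
})

test_that("identical (spec, seed) pairs reproduce identical outlines", {
  sp <- shape_spec("falciform", noise = 0.05)
  a <- make_outline(sp, seed = 42)
  b <- make_outline(sp, seed = 42)
  expect_identical(a$outline$x, b$outline$x)
  expect_identical(a$outline$y, b$outline$y)
  p1 <- make_population(5, sp, seed = 9)
  p2 <- make_population(5, sp, seed = 9)
  expect_identical(lapply(p1, function(e) e$outline$x),
                   lapply(p2, function(e) e$outline$x))
})

test_that("rotation is rigid: pairwise distances preserved", {
  sp0 <- shape_spec("falciform")
  sp63 <- shape_spec("falciform", rotation = 63)
  a <- make_outline(sp0, n_vertices = 100, seed = 1)$outline
  b <- make_outline(sp63, n_vertices = 100, seed = 1)$outline
  da <- dist(cbind(a$x, a$y))
  db <- dist(cbind(b$x, b$y))
  expect_lt(max(abs(da - db)), 1e-9)
})

test_that("zero-noise populations are exact copies of the base shape", {
  pop <- make_population(5, shape_spec("falciform"), noise = 0, seed = 3)
  xs <- vapply(pop, function(e) e$outline$x[1], numeric(1))
  expect_true(all(xs == xs[1]))
  areas <- vapply(pop, function(e) outline_area(e$outline), numeric(1))
  expect_equal(diff(range(areas)), 0)
})

test_that("rendering produces the documented degenerate outputs", {
  # no outlines: pure noise background
  img <- render_image(list(), canvas = c(64, 64), blur_sigma = 0,
                      noise_sd = 0.02, seed = 1)
  expect_equal(dim(img), c(64, 64))
  expect_gt(sd(img), 0)
  # blur 0, noise 0: binary image
  o <- shift_outline(fx_circle(2, 60)$outline)
  img2 <- render_image(list(o), canvas = c(96, 96), blur_sigma = 0,
                       noise_sd = 0, fg = 0.8, bg = 0.1)
  expect_setequal(unique(as.numeric(img2)), c(0.1, 0.8))
})

test_that("overlapping or out-of-canvas outlines are rejected", {
  o <- shift_outline(fx_circle(2, 60)$outline)
  expect_error(render_image(list(o, o), canvas = c(96, 96)), "overlap")
  expect_error(render_image(list(o), canvas = c(40, 40)), "margin|fit")
})

test_that("written TIFFs round-trip through the reader", {
  o <- shift_outline(fx_circle(2, 60)$outline)
  img <- render_image(list(o), canvas = c(96, 96), seed = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, path)
  back <- read_grayscale_tiff(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 65535)
})
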