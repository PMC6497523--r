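test_that("caliper measures match closed forms", {
  sq <- fx_square()$outline
  expect_equal(max_feret(sq), 4 * sqrt(2), tolerance = 1e-6)
  expect_equal(min_diameter_com(sq), 4, tolerance = 1e-3)
  ci <- fx_circle()$outline
  expect_equal(max_feret(ci), 10, tolerance = 1e-3)
  expect_equal(min_diameter_com(ci), 10, tolerance = 1e-3)
  el <- make_outline(shape_spec("ellipse", a = 8, b = 4),
                     n_vertices = 720)$outline
  expect_equal(max_feret(el), 16, tolerance = 1e-3)
  expect_equal(min_diameter_com(el), 8, tolerance = 1e-3)
})

test_that("circularity follows 4*pi*A/P^2 with its bounds", {
  ci <- fx_circle()$outline
  expect_equal(circularity(ci), 1, tolerance = 1e-3)
  expect_equal(circularity(16, 16), pi / 4)
  # isoperimetric inequality on assorted outlines (1e-3 discretization slack)
  for (o in list(fx_square()$outline, fx_falciform()$outline,
                 make_outline(shape_spec("ellipse", a = 4, b = 2))$outline)) {
    expect_lte(circularity(o), 1 + 1e-3)
  }
  expect_error(circularity(-1, 5))
})

test_that("orientation recovers applied rotations on falciform populations", {
  fitdat <- fx_falc_fit()
  rec0 <- fitdat$records
  # rotating every generated nucleus changes the recovered rotation by the
  # same amount (mod 360); RMS over the population under 2 degrees
  pop_r <- make_population(25, shape_spec("falciform", rotation = 63),
                           noise = 0.03, seed = 11)
  fit_r <- fit_profiles(lapply(pop_r, `[[`, "outline"), L = 500)
  rec_r <- measure_nuclei(fit_r)
  d <- (rec_r$rotation - rec0$rotation + 63) %% 360
  d <- pmin(d, 360 - d)
  expect_lt(sqrt(mean(d^2)), 2)
})

test_that("an already-oriented nucleus re-orients to the identity", {
  fitdat <- fx_falc_fit()
  orn <- attr(fitdat$records, "oriented")[[1]]
  o2 <- nucleus_outline(orn$x / 0.065, orn$y / 0.065, scale = 0.065)
  fit2 <- fit_profiles(list(o2, o2, o2), L = 500)
  rec2 <- measure_nuclei(fit2)
  r <- abs(rec2$rotation[1]) %% 360
  expect_lt(min(r, 360 - r), 1)
})

test_that("bounding box, ellipticity, hook and body behave as defined", {
  fitdat <- fx_falc_fit()
  rec <- fitdat$records
  orn <- attr(rec, "oriented")
  expect_equal(rec$ellipticity, rec$bounding_height / rec$bounding_width)
  # hook + body sum exactly to the bounding width
  expect_equal(rec$hook_length + rec$body_width, rec$bounding_width,
               tolerance = 1e-9)
  expect_true(all(rec$hook_length > 0 & rec$body_width > 0))
  # orientation determinism: re-orienting gives the identical box
  o1 <- orient_vertical(fitdat$outlines[[1]], fitdat$fit, 1)
  o1b <- orient_vertical(fitdat$outlines[[1]], fitdat$fit, 1)
  expect_identical(bounding_box(o1), bounding_box(o1b))
  # centre of mass at the origin
  cen <- nucmorph:::polygon_centroid(o1$x, o1$y)
  expect_lt(max(abs(cen)), 1e-6)
})

test_that("reference angle is the planar tip-CoM-caudal angle", {
  # synthetic oriented nucleus with known landmark geometry
  fake <- structure(list(
    x = c(0, 1, 0, -1), y = c(1, 0, -1, 0),
    landmark_frac = c(tip = 0, lm_2 = 0.25),
    landmark_angles = c(tip = 90, lm_2 = 120),
    tip_frac = 0, flat_x = 0, hook_side = "left",
    rotation = 0, perimeter = 4 * sqrt(2)
  ), class = "oriented_nucleus")
  expect_equal(reference_angle(fake), 90, tolerance = 1e-6)
  fake$landmark_frac["lm_2"] <- 0.5  # diametrically opposite: collinear
  expect_equal(reference_angle(fake), 180, tolerance = 1e-6)
  fake$landmark_frac["lm_2"] <- 0.1  # not in the posterior half
  expect_true(is.na(suppressMessages(reference_angle(fake))))
})

test_that("segment lengths tile the perimeter", {
  fitdat <- fx_falc_fit()
  rec <- fitdat$records
  segs <- rec[, grep("^seg_", names(rec)), drop = FALSE]
  expect_gt(ncol(segs), 1)
  expect_equal(rowSums(segs), rec$perimeter, tolerance = 0.005)
  # square with 4 corner landmarks: four equal segments
  sq <- fx_square()$outline
  sl <- segment_lengths(sq, c(0, 0.25, 0.5, 0.75))
  expect_equal(unname(sl), rep(4, 4), tolerance = 1e-9)
  # fewer than 2 landmarks: one full-perimeter segment
  expect_equal(unname(segment_lengths(sq, 0.3)), 16, tolerance = 1e-9)
})

test_that("measured hook length increases with the generator hook parameter", {
  hooks <- c(2.2, 3, 3.8)
  measured <- vapply(hooks, function(hl) {
    pop <- make_population(8, shape_spec("falciform", hook_length = hl),
                           noise = 0.02, seed = 31)
    fit <- fit_profiles(lapply(pop, `[[`, "outline"), L = 400)
    mean(measure_nuclei(fit)$hook_length)
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("measurements scale correctly under uniform scaling", {
  fitdat <- fx_falc_fit()
  o <- fitdat$outlines[[1]]
  o2 <- o
  o2$scale <- o$scale * 2  # same pixels, twice the physical size
  expect_equal(outline_area(o2), 4 * outline_area(o))
  expect_equal(outline_perimeter(o2), 2 * outline_perimeter(o))
  expect_equal(max_feret(o2), 2 * max_feret(o))
  expect_equal(min_diameter_com(o2), 2 * min_diameter_com(o), tolerance = 1e-9)
  expect_equal(circularity(o2), circularity(o))
})
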