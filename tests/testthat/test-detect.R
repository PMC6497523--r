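test_that("boundary tracing visits the square's boundary pixels in order", {
  m <- matrix(FALSE, 14, 14)
  m[3:12, 3:12] <- TRUE
  tr <- trace_outline(m)
  # brute-force enumeration of boundary pixels: foreground with a
  # 4-neighbour outside the object
  is_boundary <- function(r, c) {
    any(!c(m[r - 1, c], m[r + 1, c], m[r, c - 1], m[r, c + 1]))
  }
  truth <- which(m, arr.ind = TRUE)
  truth <- truth[apply(truth, 1, function(p) is_boundary(p[1], p[2])), ]
  expect_equal(nrow(tr), nrow(truth))  # 36 for a 10x10 square
  expect_setequal(paste(tr[, 1], tr[, 2]), paste(truth[, 1], truth[, 2]))
  # consecutive pixels are 8-neighbours (ordered traversal)
  d <- pmax(abs(diff(tr[, 1])), abs(diff(tr[, 2])))
  expect_true(all(d == 1))
})

test_that("tracing is translation-equivariant and rejects bad masks", {
  m <- matrix(FALSE, 30, 30)
  m[5:14, 8:19] <- TRUE
  m[10:20, 10:15] <- TRUE
  t1 <- trace_outline(m)
  m2 <- matrix(FALSE, 30, 30)
  m2[cbind(which(m, arr.ind = TRUE)[, 1] + 6,
           which(m, arr.ind = TRUE)[, 2] + 4)] <- TRUE
  t2 <- trace_outline(m2)
  expect_equal(t2, t1 + matrix(rep(c(6L, 4L), each = nrow(t1)), ncol = 2))
  expect_error(trace_outline(matrix(FALSE, 5, 5)), "empty")
  mm <- matrix(FALSE, 10, 10); mm[2, 2] <- TRUE; mm[8, 8] <- TRUE
  expect_error(trace_outline(mm), "one connected component")
})

test_that("detection recovers rendered ellipses within tolerance", {
  specs <- list(shape_spec("ellipse", a = 3.5, b = 2),
                shape_spec("ellipse", a = 3, b = 2.5),
                shape_spec("ellipse", a = 4, b = 1.8))
  outs <- list(); truths <- list()
  for (i in seq_along(specs)) {
    mo <- make_outline(specs[[i]], seed = i)
    o <- mo$outline
    o$x <- o$x - min(o$x) + 15 + (i - 1) * 140
    o$y <- o$y - min(o$y) + 15
    outs[[i]] <- o
    truths[[i]] <- mo$truth
  }
  img <- render_image(outs, canvas = c(440, 150), blur_sigma = 1,
                      noise_sd = 0.02, seed = 3)
  dets <- detect_nuclei(img, detection_params())
  expect_length(dets, 3)
  # match by x position
  ord <- order(vapply(dets, function(o) o$com[1], numeric(1)))
  dets <- dets[ord]
  for (i in 1:3) {
    expect_equal(outline_area(dets[[i]]), truths[[i]]$area,
                 tolerance = 0.03)
    expect_equal(outline_perimeter(dets[[i]]), truths[[i]]$perimeter,
                 tolerance = 0.01)
  }
})

test_that("blank images yield no detections and bad input errors", {
  img <- render_image(list(), canvas = c(128, 128), noise_sd = 0.02,
                      seed = 1)
  expect_length(detect_nuclei(img, detection_params()), 0)
  expect_error(detect_nuclei(array(0, c(4, 4, 2)), detection_params()),
               "2-D")
  expect_error(detection_params(min_area = 50, max_area = 10), "min_area")
  expect_error(detection_params(low = 0.5, high = 0.2), "low")
})

test_that("border-straddling objects are excluded when the flag is set", {
  mo <- make_outline(shape_spec("ellipse", a = 3.5, b = 2), seed = 1)
  o <- mo$outline
  # push one ellipse so it clips the left edge (the ellipse is ~108 px wide)
  o$x <- o$x - min(o$x) - 30
  o$y <- o$y - min(o$y) + 20
  o2 <- mo$outline
  o2$x <- o2$x - min(o2$x) + 160
  o2$y <- o2$y - min(o2$y) + 20
  # render only the in-bounds object with render_image; paint the clipped
  # one directly
  img <- render_image(list(o2), canvas = c(320, 140), blur_sigma = 1,
                      noise_sd = 0.01, seed = 2)
  px <- nucmorph:::fill_polygon(o$x, 141 - o$y, 320, 140)
  img[px] <- 0.85
  dets_excl <- detect_nuclei(img, detection_params(exclude_border = TRUE))
  dets_incl <- detect_nuclei(img, detection_params(exclude_border = FALSE))
  expect_length(dets_excl, 1)
  expect_gt(length(dets_incl), length(dets_excl))
})

test_that("detection is invariant to a global exposure change", {
  mo <- make_outline(shape_spec("falciform"), seed = 2)
  o <- shift_outline(mo$outline)
  side <- ceiling(max(o$x, o$y) + 15)
  img <- render_image(list(o), canvas = c(side, side), blur_sigma = 1,
                      noise_sd = 0, fg = 0.4, bg = 0.02, seed = 1)
  d1 <- detect_nuclei(img, detection_params())
  d2 <- detect_nuclei(pmin(img * 2, 1), detection_params())
  expect_length(d1, 1)
  expect_length(d2, 1)
  expect_lt(max(abs(d1[[1]]$x - d2[[1]]$x)), 1)
  expect_lt(max(abs(d1[[1]]$y - d2[[1]]$y)), 1)
})
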