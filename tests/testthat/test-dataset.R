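test_that("interpolation preserves constants, identity and round-trips", {
  expect_equal(interpolate_profile(rep(171, 250), 500), rep(171, 500))
  x <- 180 + 20 * sin(2 * pi * (0:499) / 500)
  expect_equal(interpolate_profile(x, 500), x)
  saw <- rep(c(160, 170, 180, 190), each = 25)[1:100] +
    seq(0, 5, length.out = 100)
  round_trip <- interpolate_profile(interpolate_profile(saw, 200), 100)
  expect_lt(max(abs(round_trip - saw)), 0.5)
  expect_error(interpolate_profile(saw, 50), "at least 100")
})

test_that("alignment recovers exact shifts and breaks ties low", {
  ref <- 180 + 30 * sin(2 * pi * (0:499) / 500) +
    10 * cos(6 * pi * (0:499) / 500)
  for (k in c(0, 1, 37, 250, 499)) {
    x <- nucmorph:::circ_shift(ref, -k)
    al <- align_to_reference(x, ref)
    expect_equal(al$offset, k)
    expect_equal(al$aligned, ref)
    expect_lt(al$rms, 1e-9)
  }
  # constant vs constant: all offsets tie; smallest nonnegative wins
  expect_equal(align_to_reference(rep(171, 300), rep(171, 300))$offset, 0)
  expect_error(align_to_reference(1:10, 1:12), "lengths")
})

test_that("alignment under noise recovers the shift in >= 99/100 trials", {
  ref <- 180 + 30 * sin(2 * pi * (0:499) / 500) +
    10 * cos(6 * pi * (0:499) / 500)
  hits <- 0L
  for (i in 1:100) {
    set.seed(i)
    x <- nucmorph:::circ_shift(ref, -37) + rnorm(500, 0, 2)
    if (abs(align_to_reference(x, ref)$offset - 37) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 99)
})

test_that("the median profile is the pointwise median with IQR envelope", {
  base <- 180 + 20 * sin(2 * pi * (0:299) / 300)
  m <- rbind(base, base, base)
  mp <- build_median(m, align = FALSE)
  # identical profiles: the median is the profile itself, rotated to the
  # global-minimum start convention
  expect_equal(unname(mp$median),
               nucmorph:::circ_shift(base, which.min(base) - 1L))
  expect_equal(mp$q1, mp$q3)  # zero IQR for identical profiles
  # three profiles differing at a single position
  m2 <- rbind(base, base, base)
  m2[1, 100] <- 160; m2[2, 100] <- 170; m2[3, 100] <- 175
  mp2 <- build_median(m2, align = FALSE)
  # the median of {160, 170, 175} at the modified position is 170; the
  # whole median profile equals the base with that one substitution,
  # rotated to the global-minimum start convention
  want <- base
  want[100] <- 170
  expect_equal(unname(mp2$median),
               nucmorph:::circ_shift(want, which.min(want) - 1L))
  expect_true(all(mp2$q1 <= mp2$median + 1e-12) &&
              all(mp2$median <= mp2$q3 + 1e-12))
})

test_that("median construction is invariant to input order", {
  fitdat <- fx_falc_fit()
  mat <- fitdat$fit$profiles
  mp1 <- build_median(mat)
  set.seed(1)
  mp2 <- build_median(mat[sample(nrow(mat)), ])
  expect_equal(mp1$median, mp2$median, tolerance = 1e-9)
})

test_that("segmentation finds constructed extrema and ignores flat profiles", {
  expect_equal(nrow(segment_median(rep(171, 400))), 0)
  x <- rep(180, 400)
  x[100 + (-5:5)] <- 180 - 90 * cos(seq(-pi / 2, pi / 2, length.out = 11))
  x[300 + (-5:5)] <- 180 + 30 * cos(seq(-pi / 2, pi / 2, length.out = 11))
  lm <- segment_median(x, prominence = 5)
  expect_equal(nrow(lm), 2)
  expect_setequal(lm$polarity, c("convex", "concave"))
  expect_equal(lm$index[lm$polarity == "convex"], 100, tolerance = 2)
  expect_equal(lm$index[lm$polarity == "concave"], 300, tolerance = 2)
  # segments tile the profile exactly once
  segs <- attr(lm, "segments")
  expect_equal(sum(segs$length_frac), 1)
})

test_that("landmarks on the falciform median match generator features", {
  fitdat <- fx_falc_fit()
  fit <- fitdat$fit
  lm <- fit$landmarks
  expect_gt(sum(lm$polarity == "convex"), 0)
  expect_gt(sum(lm$polarity == "concave"), 0)
  # start convention: the tip (global minimum) is at position 1
  expect_equal(lm$index[lm$name == "tip"], 1)
  # under-hook concavity: a concave landmark within 2% of the perimeter of
  # the generator's true feature position, measured relative to the tip
  truth <- fitdat$pop[[1]]$truth$features
  rel_truth <- (truth["under_hook"] - truth["tip"]) %% 1
  conc_frac <- (lm$index[lm$polarity == "concave"] - 1) / fit$L
  expect_lt(min(abs(conc_frac - rel_truth)), 0.02)
})

test_that("landmark mapping is exact on the median and shift-equivariant", {
  fitdat <- fx_falc_fit()
  fit <- fitdat$fit
  mp <- fit$median
  lm <- fit$landmarks
  expect_equal(map_landmarks(mp$median, mp, lm), lm$index)
  k <- 7
  shifted <- nucmorph:::circ_shift(mp$median, -k)
  mapped <- map_landmarks(shifted, mp, lm, halfwidth = 15)
  expect_equal((mapped - lm$index) %% fit$L, rep(k, nrow(lm)))
})

test_that("hook tips map within 2% of perimeter for >= 95% of nuclei", {
  fitdat <- fx_falc_fit()
  fit <- fitdat$fit
  n <- nrow(fit$profiles)
  hits <- 0L
  for (i in seq_len(n)) {
    tip_j <- fit$nucleus_landmarks[i, "tip"]
    frac <- nucmorph:::aligned_index_to_arc_frac(fit, i, tip_j)
    truth <- fitdat$pop[[i]]$truth$features["tip"]
    d <- abs(frac - truth)
    if (min(d, 1 - d) <= 0.02) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("variability matches its formula, brute force and invariances", {
  med <- 180 + 20 * sin(2 * pi * (0:399) / 400)
  expect_equal(variability(med, med), 0)
  expect_equal(variability(med + 3, med), 3)
  set.seed(8)
  x <- med + rnorm(400, 0, 5)
  brute <- sqrt(sum((x - med)^2) / 400)
  expect_equal(variability(x, med), brute, tolerance = 1e-12)
  expect_gte(variability(x, med), 0)
  # common circular shift of both leaves the score unchanged
  expect_equal(variability(nucmorph:::circ_shift(x, 13),
                           nucmorph:::circ_shift(med, 13)),
               variability(x, med))
  expect_error(variability(x[1:100], med), "lengths")
})

test_that("variability grows stochastically with generator noise", {
  means <- vapply(c(0, 0.02, 0.05, 0.1), function(ns) {
    pop <- make_population(15, shape_spec("falciform"), noise = ns,
                           seed = 21)
    fit <- fit_profiles(lapply(pop, `[[`, "outline"), L = 300)
    mean(fit$variability)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
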