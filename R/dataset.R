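#' Interpolate a profile to a fixed length
#'
#' Circular linear interpolation of an angle profile onto `L` equally spaced
#' arc-length positions. Profiles whose vertices carry explicit arc-length
#' fractions (class `angle_profile`) are resampled in arc length; plain
#' numeric vectors are assumed equally spaced.
#'
#' @param profile An `angle_profile` or numeric vector of angles (degrees).
#' @param L Target length (at least 100).
#' @return Numeric vector of length `L`.
#' @export
interpolate_profile <- function(profile, L = 1000L) {
  if (L < 100L) stop("'L' must be at least 100")
  if (inherits(profile, "angle_profile")) {
    pos <- profile$arc_frac
    ang <- profile$angles
  } else {
    ang <- as.numeric(profile)
    pos <- (seq_along(ang) - 1) / length(ang)
  }
  n <- length(ang)
  if (n == L && all(pos == (seq_len(L) - 1) / L)) return(ang)
  # wrap one point on each side for circular interpolation
  xs <- c(pos[n] - 1, pos, pos[1] + 1)
  ys <- c(ang[n], ang, ang[1])
  xout <- (seq_len(L) - 1) / L
  stats::approx(xs, ys, xout = xout, ties = "ordered")$y
}

# aligned[i] = x[((i - 1 + k) %% L) + 1]
circ_shift <- function(x, k) {
  L <- length(x)
  k <- ((k %% L) + L) %% L
  if (k == 0) return(x)
  c(x[(k + 1):L], x[1:k])
}

#' Best circular alignment of a profile to a reference
#'
#' Exhaustive search over all `L` circular offsets for the shift minimizing
#' the root-mean-square difference to the reference; ties are broken by the
#' smallest nonnegative offset. The search is exact by construction (every
#' offset is evaluated).
#'
#' @param x Numeric profile, length `L`.
#' @param reference Numeric reference profile, same length.
#' @return List with `offset` (integer in `0:(L-1)`), `aligned` (the shifted
#'   profile) and `rms` (the achieved root-mean-square difference).
#' @export
align_to_reference <- function(x, reference) {
  L <- length(x)
  if (length(reference) != L) stop("profile and reference lengths differ")
  # rms_k^2 * L = sum(x^2) + sum(ref^2) - 2 * sum(x_shift_k * ref);
  # the cross term for all k at once via an index-shift matrix
  idx <- outer(seq_len(L), 0:(L - 1), function(i, k) ((i - 1 + k) %% L) + 1)
  cc <- as.numeric(crossprod(matrix(x[idx], nrow = L), reference))
  sq <- sum(x^2) + sum(reference^2)
  ss <- sq - 2 * cc
  ss[ss < 0] <- 0
  # floating-point-safe tie handling: scores within rounding noise of the
  # minimum count as ties, resolved to the smallest nonnegative offset
  k <- which(ss <= min(ss) + 1e-9 * sq)[1L] - 1L
  aligned <- circ_shift(x, k)
  list(offset = k, aligned = aligned,
       rms = sqrt(mean((aligned - reference)^2)))
}

#' Pointwise median profile with interquartile range
#'
#' Builds the population median profile by iterative re-alignment: profiles
#' are aligned to a running median (initially the first profile), the
#' pointwise median is recomputed, and the cycle repeats until no offset
#' changes or `max_iter` rounds have run.
#'
#' @param mat Numeric matrix, one length-`L` profile per row (already
#'   interpolated), or a list of profiles passed through
#'   [interpolate_profile()].
#' @param L Interpolated length used when `mat` is a list.
#' @param align Align profiles before taking the median.
#' @param max_iter Maximum re-alignment rounds.
#' @return An object of class `median_profile`: list with `median`, `q1`,
#'   `q3` (length-`L` vectors, degrees), `offsets` (per profile) and the
#'   aligned matrix `mat`.
#' @export
build_median <- function(mat, L = 1000L, align = TRUE, max_iter = 10L) {
  if (is.list(mat) && !is.matrix(mat)) {
    mat <- t(vapply(mat, interpolate_profile, numeric(L), L = L))
  }
  if (!is.matrix(mat) || nrow(mat) < 1L) stop("need at least one profile")
  n <- nrow(mat); L <- ncol(mat)
  offsets <- integer(n)
  if (align && n > 1L) {
    # order-invariant starting reference: rotate every profile to its own
    # canonical start (global minimum first) and take the pointwise median
    canon <- t(apply(mat, 1, function(p) circ_shift(p, which.min(p) - 1L)))
    ref <- apply(canon, 2, stats::median)
    for (iter in seq_len(max_iter)) {
      new_off <- integer(n)
      aligned <- mat
      for (i in seq_len(n)) {
        al <- align_to_reference(mat[i, ], ref)
        new_off[i] <- al$offset
        aligned[i, ] <- al$aligned
      }
      ref <- apply(aligned, 2, stats::median)
      if (identical(new_off, offsets) && iter > 1L) break
      offsets <- new_off
    }
    work <- aligned
  } else {
    work <- mat
  }
  med <- apply(work, 2, stats::median)
  # common start convention: global minimum of the median at position 1
  # (the hook tip, in sperm)
  shift <- which.min(med) - 1L
  if (shift > 0L) {
    med <- circ_shift(med, shift)
    work <- t(apply(work, 1, circ_shift, k = shift))
    offsets <- (offsets + shift) %% L
  }
  structure(
    list(median = med,
         q1 = apply(work, 2, stats::quantile, probs = 0.25, names = FALSE),
         q3 = apply(work, 2, stats::quantile, probs = 0.75, names = FALSE),
         offsets = offsets, mat = work),
    class = "median_profile"
  )
}

#' @export
print.median_profile <- function(x, ...) {
  cat(sprintf("<median_profile> L = %d from %d profiles, median range [%.1f, %.1f] deg\n",
              length(x$median), nrow(x$mat), min(x$median), max(x$median)))
  invisible(x)
}

#' Segment a median profile into landmarks
#'
#' Local minima of the (lightly smoothed) median profile lying below 180
#' degrees become convex landmarks; local maxima above 180 degrees become
#' concave landmarks. Extrema whose prominence against the neighbouring
#' opposite extremum falls below `prominence` are suppressed, removing
#' pixel-noise wiggles. The segments between consecutive landmarks tile the
#' profile exactly once.
#'
#' @param median A `median_profile` or numeric median vector (degrees).
#' @param prominence Minimum amplitude (degrees) an extremum must stand out
#'   from its neighbours to count as a landmark.
#' @param smooth Circular moving-average window applied before extremum
#'   detection (odd integer; `1` disables smoothing).
#' @return An object of class `landmark_set`: data frame with columns
#'   `index` (position on the profile), `polarity` (`"convex"` /
#'   `"concave"`), `angle` (median angle there) and `name`; the segment
#'   table is attached as attribute `"segments"`.
#' @export
segment_median <- function(median, prominence = 5, smooth = 3L) {
  med <- if (inherits(median, "median_profile")) median$median else as.numeric(median)
  L <- length(med)
  sm <- if (smooth >= 3L) circular_ma(med, as.integer(smooth)) else med
  nxt <- c(seq_len(L)[-1L], 1L)
  prv <- c(L, seq_len(L)[-L])
  is_max <- sm > sm[prv] & sm >= sm[nxt]
  is_min <- sm < sm[prv] & sm <= sm[nxt]
  ext <- which(is_max | is_min)
  if (length(ext) >= 2L) {
    # prune alternating extrema pairs of low amplitude
    repeat {
      vals <- sm[ext]
      if (length(ext) < 2L) break
      amp <- abs(diff(c(vals, vals[1L])))
      worst <- which.min(amp)
      if (amp[worst] >= prominence) break
      drop <- c(worst, worst %% length(ext) + 1L)
      ext <- ext[-drop]
    }
  }
  conv <- ext[is_min[ext] & sm[ext] < 180]
  conc <- ext[is_max[ext] & sm[ext] > 180]
  idx <- sort(c(conv, conc))
  lm <- data.frame(
    index = idx,
    polarity = if (length(idx)) ifelse(idx %in% conv, "convex", "concave")
               else character(0),
    angle = med[idx],
    name = if (length(idx)) paste0("lm_", seq_along(idx)) else character(0)
  )
  if (nrow(lm) > 0 && any(lm$polarity == "convex")) {
    tip <- lm$index[lm$polarity == "convex"][
      which.min(lm$angle[lm$polarity == "convex"])]
    lm$name[lm$index == tip] <- "tip"
  }
  class(lm) <- c("landmark_set", "data.frame")
  if (nrow(lm) >= 2L) {
    segs <- data.frame(
      from = lm$index,
      to = c(lm$index[-1L], lm$index[1L])
    )
    segs$length_frac <- ((segs$to - segs$from) %% L) / L
    segs$length_frac[segs$length_frac == 0] <- 1
  } else {
    segs <- data.frame(from = 1L, to = 1L, length_frac = 1)
  }
  attr(lm, "segments") <- segs
  lm
}

#' Map median landmarks onto one nucleus profile
#'
#' For each landmark, searches within `halfwidth` positions of the median
#' landmark index for the position minimizing the local root-mean-square
#' difference between the nucleus profile and the median profile over a
#' window centred on the landmark; score ties take the index closest to the
#' median position. The nucleus profile must already be aligned to the
#' median.
#'
#' @param x Aligned nucleus profile, length `L`.
#' @param median A `median_profile` or numeric vector.
#' @param landmarks A `landmark_set` from [segment_median()].
#' @param halfwidth Search half-width in profile positions (default 5% of
#'   `L`).
#' @param window Half-width of the local comparison window.
#' @return Integer vector of per-nucleus landmark indices (same order as
#'   `landmarks`).
#' @export
map_landmarks <- function(x, median, landmarks,
                          halfwidth = round(0.05 * length(x)),
                          window = max(3L, round(0.02 * length(x)))) {
  med <- if (inherits(median, "median_profile")) median$median else as.numeric(median)
  L <- length(x)
  if (length(med) != L) stop("profile and median lengths differ")
  vapply(landmarks$index, function(i0) {
    cand <- (i0 - halfwidth):(i0 + halfwidth)
    score <- vapply(cand, function(i) {
      wi <- ((i - window):(i + window) - 1L) %% L + 1L
      w0 <- ((i0 - window):(i0 + window) - 1L) %% L + 1L
      sqrt(mean((x[wi] - med[w0])^2))
    }, numeric(1))
    best <- which(round(score, 9) == round(min(score), 9))
    pick <- best[which.min(abs(cand[best] - i0))]
    ((cand[pick] - 1L) %% L) + 1L
  }, integer(1))
}

#' Per-nucleus shape-variability score
#'
#' Root-mean-square deviation between a nucleus angle profile and the
#' population median profile, both at the same interpolated length `L`:
#' `sqrt(sum(d_i^2) / L)` with `d_i` the pointwise angle difference in
#' degrees. Zero if and only if the profile equals the median.
#'
#' @param x Nucleus profile (length `L`, degrees), aligned to the median.
#' @param median A `median_profile` or numeric vector of the same length.
#' @return Nonnegative scalar, degrees RMS.
#' @export
variability <- function(x, median) {
  med <- if (inherits(median, "median_profile")) median$median else as.numeric(median)
  if (length(x) != length(med)) stop("profile and median lengths differ")
  sqrt(sum((x - med)^2) / length(x))
}
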