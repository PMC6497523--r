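#' Fit a population shape-profile model
#'
#' The central fitting function of the package. Given a set of nucleus
#' outlines it computes each windowed interior-angle profile, interpolates
#' all profiles to a common length, aligns them by exhaustive circular
#' search with iterative re-alignment to the running median, builds the
#' median profile with its interquartile envelope, discovers landmarks as
#' sub-/super-180-degree extrema of the median, maps each landmark back onto
#' every nucleus by local best fit, and scores each nucleus's deviation from
#' the median (the shape-variability statistic). Profiles are rotated to a
#' common start convention with the global minimum of the median — the hook
#' tip in falciform sperm — at position 1.
#'
#' @param outlines List of [nucleus_outline()] objects, or a numeric matrix
#'   of pre-computed profiles (one row per nucleus).
#' @param window Angle window as a fraction of the perimeter (default 0.05,
#'   i.e. the 20-semilandmark equivalent).
#' @param L Interpolated profile length.
#' @param max_iter Maximum re-alignment rounds.
#' @param prominence Landmark prominence threshold, degrees.
#' @param smooth Moving-average window for extremum detection.
#' @param halfwidth Landmark search half-width, profile positions.
#' @return An object of class `profile_fit`: list with elements
#'   \describe{
#'     \item{profiles}{aligned n x L angle matrix (degrees)}
#'     \item{median}{the `median_profile` (median, q1, q3)}
#'     \item{landmarks}{the `landmark_set` found on the median}
#'     \item{nucleus_landmarks}{n x k matrix of per-nucleus landmark
#'       positions (profile indices)}
#'     \item{variability}{per-nucleus RMS deviation from the median, degrees}
#'     \item{offsets}{per-nucleus circular offsets (profile positions)}
#'     \item{outlines}{the input outlines (if outlines were supplied)}
#'     \item{window, L}{the parameters used}
#'   }
#' @examples
#' pop <- make_population(10, shape_spec("falciform"), noise = 0.03, seed = 1)
#' fit <- fit_profiles(lapply(pop, `[[`, "outline"), L = 200)
#' fit
#' summary(fit)
#' @export
fit_profiles <- function(outlines, window = 0.05, L = 1000L, max_iter = 10L,
                         prominence = 5, smooth = 3L,
                         halfwidth = round(0.05 * L)) {
  cl <- match.call()
  if (is.matrix(outlines)) {
    mat <- t(apply(outlines, 1, interpolate_profile, L = L))
    outs <- NULL
  } else {
    if (!length(outlines)) stop("need at least one outline")
    profs <- lapply(outlines, compute_profile, w = window)
    mat <- t(vapply(profs, interpolate_profile, numeric(L), L = L))
    outs <- outlines
  }
  mp <- build_median(mat, align = TRUE, max_iter = max_iter)
  lm <- segment_median(mp, prominence = prominence, smooth = smooth)
  n <- nrow(mp$mat)
  if (nrow(lm) > 0) {
    nl <- t(vapply(seq_len(n), function(i) {
      map_landmarks(mp$mat[i, ], mp, lm, halfwidth = halfwidth)
    }, integer(nrow(lm))))
    if (nrow(lm) == 1L) nl <- matrix(nl, ncol = 1L)
    colnames(nl) <- lm$name
  } else {
    nl <- matrix(integer(0), nrow = n, ncol = 0L)
  }
  vb <- apply(mp$mat, 1, variability, median = mp)
  structure(
    list(profiles = mp$mat, median = mp, landmarks = lm,
         nucleus_landmarks = nl, variability = vb, offsets = mp$offsets,
         outlines = outs, window = window, L = ncol(mp$mat), call = cl),
    class = "profile_fit"
  )
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf(
    "Shape-profile fit: %d nuclei, L = %d, window = %.3g\n",
    nrow(x$profiles), x$L, x$window))
  cat(sprintf("Landmarks: %d (%d convex, %d concave)\n",
              nrow(x$landmarks),
              sum(x$landmarks$polarity == "convex"),
              sum(x$landmarks$polarity == "concave")))
  cat(sprintf("Variability (deg RMS): median %.2f, range [%.2f, %.2f]\n",
              stats::median(x$variability), min(x$variability),
              max(x$variability)))
  invisible(x)
}

#' @export
summary.profile_fit <- function(object, ...) {
  structure(
    list(n = nrow(object$profiles), L = object$L, window = object$window,
         landmarks = as.data.frame(object$landmarks),
         segments = attr(object$landmarks, "segments"),
         variability = summary(object$variability)),
    class = "summary.profile_fit"
  )
}

#' @export
print.summary.profile_fit <- function(x, ...) {
  cat(sprintf("Shape-profile fit of %d nuclei (L = %d, window = %.3g)\n\n",
              x$n, x$L, x$window))
  cat("Landmarks on the median profile:\n")
  print(x$landmarks)
  cat("\nPer-nucleus variability (deg RMS):\n")
  print(x$variability)
  invisible(x)
}

#' @export
coef.profile_fit <- function(object, ...) object$median$median

#' @export
residuals.profile_fit <- function(object, ...) {
  sweep(object$profiles, 2, object$median$median)
}

#' @rdname fit_profiles
#' @param object A `profile_fit`.
#' @param newdata List of outlines (or profile matrix) to project onto the
#'   fitted median: each is interpolated, aligned to the median, landmark
#'   positions are mapped and the variability score computed.
#' @param ... Unused.
#' @export
predict.profile_fit <- function(object, newdata, ...) {
  if (missing(newdata)) {
    return(list(profiles = object$profiles,
                landmarks = object$nucleus_landmarks,
                variability = object$variability))
  }
  if (is.matrix(newdata)) {
    mat <- t(apply(newdata, 1, interpolate_profile, L = object$L))
  } else {
    if (inherits(newdata, "nucleus_outline")) newdata <- list(newdata)
    profs <- lapply(newdata, compute_profile, w = object$window)
    mat <- t(vapply(profs, interpolate_profile, numeric(object$L),
                    L = object$L))
  }
  aligned <- t(apply(mat, 1, function(p) {
    align_to_reference(p, object$median$median)$aligned
  }))
  lmk <- if (nrow(object$landmarks) > 0) {
    t(apply(aligned, 1, map_landmarks, median = object$median,
            landmarks = object$landmarks))
  } else matrix(integer(0), nrow(aligned), 0L)
  list(profiles = aligned, landmarks = lmk,
       variability = apply(aligned, 1, variability, median = object$median))
}

#' Plot a profile fit
#'
#' Draws the median angle profile with its interquartile envelope and marks
#' the discovered landmarks (convex below 180 degrees, concave above).
#'
#' @param x A `profile_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.profile_fit <- function(x, ...) {
  pos <- (seq_len(x$L) - 1) / x$L * 100
  mp <- x$median
  graphics::plot(pos, mp$median, type = "n",
                 ylim = range(mp$q1, mp$q3),
                 xlab = "perimeter position (%)",
                 ylab = "interior angle (deg)", ...)
  graphics::polygon(c(pos, rev(pos)), c(mp$q1, rev(mp$q3)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(pos, mp$median, lwd = 2, col = "steelblue4")
  graphics::abline(h = 180, lty = 2, col = "grey50")
  if (nrow(x$landmarks) > 0) {
    graphics::points(pos[x$landmarks$index], x$landmarks$angle,
                     pch = ifelse(x$landmarks$polarity == "convex", 25, 24),
                     bg = "orange")
    graphics::text(pos[x$landmarks$index], x$landmarks$angle,
                   x$landmarks$name, pos = 3, cex = 0.7)
  }
  invisible(x)
}

# arc fraction (from outline vertex 1) of aligned profile position j for
# nucleus i of a profile_fit
aligned_index_to_arc_frac <- function(fit, i, j) {
  (((j - 1 + fit$offsets[i]) %% fit$L)) / fit$L
}
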