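#' Orient a nucleus vertically
#'
#' Rotates a nucleus into the standard vertical frame used for bounding-box
#' measurements: the flat region below the hook (the longest run of
#' near-180-degree profile positions between the hook tip and the next
#' ventral convex landmark) is placed vertical, the hook tip points into the
#' +y half-plane, and the centre of mass is translated to the origin. If no
#' flat region can be found the principal axis is used instead, with a
#' warning.
#'
#' The hook side is recorded rather than forced: a rigid rotation cannot
#' mirror a shape, so whether the hook falls on -x (`"left"`, the
#' documented standard chirality) or +x (`"right"`) is determined by the
#' outline itself.
#'
#' @param outline A [nucleus_outline()].
#' @param fit A [fit_profiles()] result containing this outline.
#' @param i Index of `outline` within the fit.
#' @param flat_tol Half-width of the near-180-degree band, degrees.
#' @return An object of class `oriented_nucleus`: list with `x`, `y`
#'   (vertex coordinates in um, centre of mass at the origin), `rotation`
#'   (degrees applied, counterclockwise), `hook_side`, `flat_x` (x-position
#'   of the vertical alignment region), `landmark_frac` (named arc-length
#'   fractions of the per-nucleus landmarks, measured from outline vertex
#'   1), `landmark_angles` (profile angles at those landmarks) and
#'   `tip_frac`.
#' @export
orient_vertical <- function(outline, fit, i = 1L, flat_tol = 10) {
  stopifnot(inherits(outline, "nucleus_outline"), inherits(fit, "profile_fit"))
  L <- fit$L
  prof <- fit$profiles[i, ]
  lm <- fit$landmarks
  nl <- fit$nucleus_landmarks[i, ]
  fracs <- vapply(nl, function(j) aligned_index_to_arc_frac(fit, i, j),
                  numeric(1))
  angs <- prof[nl]
  names(fracs) <- names(angs) <- colnames(fit$nucleus_landmarks)
  x <- outline$x * outline$scale
  y <- outline$y * outline$scale
  flat_idx <- NULL
  tip_j <- if ("tip" %in% names(nl)) nl[["tip"]] else NA_integer_
  if (!is.na(tip_j) && nrow(lm) >= 2L) {
    # the flat region sits directly below the hook: the first sustained
    # near-180-degree stretch after the under-hook concavity (the first
    # concave landmark following the tip); if there is no concavity, fall
    # back to the longest flat run before the next convex landmark
    conc <- nl[lm$polarity == "concave"]
    conv <- nl[lm$polarity == "convex" & lm$name != "tip"]
    if (length(conc)) {
      uh <- conc[which.min((conc - tip_j) %% L)]
      span <- ((uh + seq_len(L %/% 3)) - 1L) %% L + 1L
      inband <- abs(prof[span] - 180) < flat_tol
      first_in <- which(inband)[1]
      if (!is.na(first_in)) {
        # fixed-arc-length alignment window (5% of the perimeter) so the
        # reference direction is comparable across shape families; stop
        # early if the contour leaves the near-180 band
        run_end <- first_in
        limit <- min(length(span), first_in + round(0.05 * L))
        while (run_end < limit && inband[run_end + 1L]) {
          run_end <- run_end + 1L
        }
        flat_idx <- span[first_in:run_end]
      }
    } else if (length(conv)) {
      ventral_j <- conv[which.min((conv - tip_j) %% L)]
      span <- ((tip_j:(tip_j + ((ventral_j - tip_j) %% L))) - 1L) %% L + 1L
      flat_idx <- span[longest_true_run(abs(prof[span] - 180) < flat_tol)]
    }
  }
  used_fallback <- is.null(flat_idx) || length(flat_idx) < 3L
  arcs <- arc_lengths(outline)
  if (!used_fallback) {
    fr <- vapply(flat_idx, function(j) aligned_index_to_arc_frac(fit, i, j),
                 numeric(1))
    pts <- point_at_arc(outline, fr * arcs$total, arcs) * outline$scale
    dir <- stats::prcomp(pts)$rotation[, 1]
  } else {
    warning("no flat alignment region found; using principal axis")
    dir <- stats::prcomp(cbind(x, y))$rotation[, 1]
  }
  theta <- 90 - atan2(dir[2], dir[1]) * 180 / pi
  com <- polygon_centroid(x, y)
  rot <- rotate_xy(x, y, theta, com[1], com[2])
  xr <- rot[, 1] - com[1]
  yr <- rot[, 2] - com[2]
  # hook tip into the +y half-plane
  tip_frac <- if (!is.na(tip_j)) aligned_index_to_arc_frac(fit, i, tip_j)
              else NA_real_
  if (!is.na(tip_frac)) {
    tp <- point_at_arc(outline, tip_frac * arcs$total, arcs) * outline$scale
    tp <- rotate_xy(tp[1], tp[2], theta, com[1], com[2]) - com
    if (tp[2] < 0) {
      theta <- theta + 180
      xr <- -xr; yr <- -yr
      tp <- -tp
    }
  }
  theta <- ((theta + 180) %% 360) - 180
  flat_x <- if (!used_fallback) {
    fr <- vapply(flat_idx, function(j) aligned_index_to_arc_frac(fit, i, j),
                 numeric(1))
    pts <- point_at_arc(outline, fr * arcs$total, arcs) * outline$scale
    pr <- rotate_xy(pts[, 1], pts[, 2], theta, com[1], com[2])
    mean(pr[, 1] - com[1])
  } else 0
  hook_side <- if (is.na(tip_frac)) NA_character_
               else if (tp[1] < flat_x) "left" else "right"
  structure(
    list(x = xr, y = yr, rotation = theta, hook_side = hook_side,
         flat_x = flat_x, landmark_frac = fracs, landmark_angles = angs,
         tip_frac = tip_frac, perimeter = arcs$total * outline$scale),
    class = "oriented_nucleus"
  )
}

longest_true_run <- function(flag) {
  if (!any(flag)) return(integer(0))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  (ends[best] - r$lengths[best] + 1L):ends[best]
}

#' @export
print.oriented_nucleus <- function(x, ...) {
  cat(sprintf(
    "<oriented_nucleus> %d vertices, rotation %.1f deg, hook side %s\n",
    length(x$x), x$rotation, x$hook_side))
  invisible(x)
}

#' Maximum Feret (caliper) diameter
#'
#' The largest pairwise distance between outline points, in micrometres.
#' Computed on the convex hull.
#'
#' @param outline A [nucleus_outline()] or `oriented_nucleus`.
#' @return Length in um.
#' @export
max_feret <- function(outline) {
  xy <- outline_um(outline)
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  max(stats::dist(cbind(hx, hy)))
}

outline_um <- function(o) {
  if (inherits(o, "oriented_nucleus")) cbind(o$x, o$y)
  else cbind(o$x, o$y) * o$scale
}

#' Minimum diameter through the centre of mass
#'
#' The shortest chord through the centre of mass, found by sampling chord
#' directions at `step`-degree resolution and intersecting each line with
#' the polygon. If the centre of mass lies outside the polygon (possible for
#' extreme crescents) the chord is taken between the two boundary
#' intersections nearest the centre on each side, and a message is logged.
#'
#' @inheritParams max_feret
#' @param step Direction sampling step, degrees (at most 0.5).
#' @return Length in um.
#' @export
min_diameter_com <- function(outline, step = 0.5) {
  stopifnot(step <= 0.5)
  xy <- outline_um(outline)
  com <- polygon_centroid(xy[, 1], xy[, 2])
  thetas <- seq(0, 180 - step, by = step) * pi / 180
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1L], 1L)
  ex <- xy[, 1]; ey <- xy[, 2]
  dx <- xy[nxt, 1] - ex; dy <- xy[nxt, 2] - ey
  outside_logged <- FALSE
  best <- Inf
  for (th in thetas) {
    ux <- cos(th); uy <- sin(th)
    # intersect line com + t*u with each edge: com + t*u = e + s*d
    den <- ux * dy - uy * dx
    ok <- abs(den) > 1e-12
    s <- (uy * (ex - com[1]) - ux * (ey - com[2])) / den
    t <- (dy * (ex - com[1]) - dx * (ey - com[2])) / den
    hit <- ok & s >= 0 & s < 1
    tv <- t[hit]
    if (length(tv) < 2L) next
    pos <- tv[tv > 0]; neg <- tv[tv <= 0]
    if (length(pos) && length(neg)) {
      chord <- min(pos) + min(-neg)
    } else {
      if (!outside_logged) {
        message("centre of mass outside polygon; using nearest chord")
        outside_logged <- TRUE
      }
      st <- sort(abs(tv))[1:2]
      chord <- abs(st[2] - st[1])
    }
    if (chord < best) best <- chord
  }
  best
}

#' Circularity
#'
#' `4 * pi * A / P^2`: 1 for a perfect circle, smaller for elongated or
#' rough outlines (isoperimetric inequality).
#'
#' @param area Area, um^2 (or a [nucleus_outline()], from which both values
#'   are measured).
#' @param perimeter Perimeter, um.
#' @return Dimensionless value in `(0, 1]`.
#' @export
circularity <- function(area, perimeter) {
  if (inherits(area, "nucleus_outline")) {
    perimeter <- outline_perimeter(area)
    area <- outline_area(area)
  }
  stopifnot(area > 0, perimeter > 0)
  4 * pi * area / perimeter^2
}

#' Bounding box of a vertically oriented nucleus
#'
#' @param oriented An `oriented_nucleus` from [orient_vertical()].
#' @return Named vector: `width`, `height` (um) and `ellipticity`
#'   (height/width).
#' @export
bounding_box <- function(oriented) {
  w <- diff(range(oriented$x))
  h <- diff(range(oriented$y))
  c(width = w, height = h, ellipticity = h / w)
}

#' Hook length and body width
#'
#' Horizontal distances from the vertical alignment region (the flat region
#' below the hook) to the bounding-box edge on the hook side (hook length)
#' and on the body side (body width). The two sum exactly to the bounding
#' width.
#'
#' @inheritParams bounding_box
#' @return Named vector: `hook_length`, `body_width` (um).
#' @export
hook_and_body <- function(oriented) {
  xr <- range(oriented$x)
  fx <- oriented$flat_x
  if (identical(oriented$hook_side, "right")) {
    c(hook_length = xr[2] - fx, body_width = fx - xr[1])
  } else {
    c(hook_length = fx - xr[1], body_width = xr[2] - fx)
  }
}

#' Angle between the tip, centre of mass and caudal reference point
#'
#' The caudal reference point is the convex landmark with the greatest
#' angular deviation (smallest interior angle) in the posterior half of the
#' perimeter, i.e. arc fraction 0.25-0.75 away from the tip. Returns `NA`
#' with a message if either landmark is missing.
#'
#' @inheritParams bounding_box
#' @return Angle in degrees.
#' @export
reference_angle <- function(oriented) {
  lf <- oriented$landmark_frac
  if (is.na(oriented$tip_frac) || !length(lf)) {
    message("tip or caudal landmark missing; reference angle undefined")
    return(NA_real_)
  }
  rel <- (lf - oriented$tip_frac) %% 1
  post <- which(rel >= 0.25 & rel <= 0.75 & names(lf) != "tip")
  if (!length(post)) {
    message("no posterior landmark; reference angle undefined")
    return(NA_real_)
  }
  caudal <- post[which.min(oriented$landmark_angles[post])]
  pts <- oriented_point_at_frac(oriented, c(oriented$tip_frac, lf[caudal]))
  v1 <- pts[1, ]; v2 <- pts[2, ]
  acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) *
    180 / pi
}

# interpolated point(s) on an oriented nucleus at arc fraction(s) from
# outline vertex 1
oriented_point_at_frac <- function(oriented, frac) {
  o <- list(x = oriented$x, y = oriented$y)
  n <- length(o$x)
  nxt <- c(seq_len(n)[-1L], 1L)
  seg <- sqrt((o$x[nxt] - o$x)^2 + (o$y[nxt] - o$y)^2)
  arcs <- list(s = cumsum(c(0, seg[-n])), total = sum(seg), seg = seg)
  point_at_arc(o, frac * arcs$total, arcs)
}

#' Perimeter segment lengths between landmarks
#'
#' Arc length of each perimeter segment between consecutive per-nucleus
#' landmarks, in landmark order starting from the first landmark. The
#' segments sum to the perimeter. With fewer than two landmarks a single
#' segment of the full perimeter is returned.
#'
#' @param outline A [nucleus_outline()].
#' @param landmark_frac Arc-length fractions of the landmarks (from vertex
#'   1), e.g. from [orient_vertical()].
#' @return Numeric vector of lengths, um.
#' @export
segment_lengths <- function(outline, landmark_frac) {
  P <- outline_perimeter(outline)
  if (length(landmark_frac) < 2L) return(stats::setNames(P, "seg_1"))
  fr <- sort(landmark_frac %% 1)
  d <- diff(c(fr, fr[1] + 1))
  stats::setNames(d * P, paste0("seg_", seq_along(d)))
}

#' Measure the full morphometric parameter set
#'
#' Computes, for every nucleus in a [fit_profiles()] result, the standard
#' parameter set: area, perimeter, maximum Feret diameter, minimum diameter
#' through the centre of mass, circularity, bounding width and height and
#' ellipticity in the vertically oriented frame, hook length and body
#' width, the tip/centre-of-mass/caudal reference angle, per-segment
#' perimeter lengths, and the shape-variability score.
#'
#' @param fit A `profile_fit` whose `outlines` element is populated.
#' @param step Direction sampling step for the minimum diameter, degrees.
#' @return A data frame with one row per nucleus; the list of
#'   `oriented_nucleus` objects is attached as attribute `"oriented"`.
#' @export
measure_nuclei <- function(fit, step = 0.5) {
  stopifnot(inherits(fit, "profile_fit"))
  if (is.null(fit$outlines)) {
    stop("fit was built from a profile matrix; outlines are required")
  }
  n <- length(fit$outlines)
  oriented <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    o <- fit$outlines[[i]]
    orn <- orient_vertical(o, fit, i)
    oriented[[i]] <- orn
    a <- outline_area(o)
    p <- outline_perimeter(o)
    bb <- bounding_box(orn)
    hb <- hook_and_body(orn)
    segs <- segment_lengths(o, orn$landmark_frac)
    rows[[i]] <- c(
      area = a, perimeter = p,
      max_feret = max_feret(o),
      min_diameter = min_diameter_com(o, step = step),
      circularity = circularity(a, p),
      bounding_width = unname(bb["width"]),
      bounding_height = unname(bb["height"]),
      ellipticity = unname(bb["ellipticity"]),
      hook_length = unname(hb["hook_length"]),
      body_width = unname(hb["body_width"]),
      reference_angle = suppressMessages(reference_angle(orn)),
      variability = fit$variability[i],
      rotation = orn$rotation,
      segs
    )
  }
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(
    id = vapply(fit$outlines, function(o) {
      if (is.na(o$id)) "" else o$id
    }, character(1)),
    df
  )
  attr(df, "oriented") <- oriented
  df
}
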