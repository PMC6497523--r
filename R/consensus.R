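#' Resample an oriented nucleus at 1%-of-perimeter semilandmarks
#'
#' Places points at arc lengths `0, 0.01 P, ..., 0.99 P` from the hook-tip
#' landmark (the correspondence anchor) around the oriented outline, by
#' linear interpolation along the polygon edges.
#'
#' @param oriented An `oriented_nucleus` from [orient_vertical()].
#' @param n Number of semilandmarks (default 100, i.e. every 1% of the
#'   perimeter).
#' @return An `n` x 2 matrix of (x, y) coordinates, um.
#' @export
resample_semilandmarks <- function(oriented, n = 100L) {
  anchor <- if (!is.na(oriented$tip_frac)) oriented$tip_frac else 0
  fr <- (anchor + (seq_len(n) - 1) / n) %% 1
  oriented_point_at_frac(oriented, fr)
}

#' Build the consensus nucleus of a population
#'
#' Averages the x and y coordinates of corresponding semilandmarks (spaced
#' every 1% of the perimeter from the hook-tip anchor) across vertically
#' oriented, centred nuclei, yielding the mean outline of the population.
#'
#' @param oriented List of `oriented_nucleus` objects (e.g. the
#'   `"oriented"` attribute of [measure_nuclei()]).
#' @param n Number of semilandmarks.
#' @return An object of class `consensus_shape`: list with `x`, `y` (um,
#'   centred), and `n_nuclei`.
#' @export
build_consensus <- function(oriented, n = 100L) {
  if (!length(oriented)) stop("need at least one oriented nucleus")
  pts <- lapply(oriented, resample_semilandmarks, n = n)
  xs <- rowMeans(vapply(pts, function(p) p[, 1], numeric(n)))
  ys <- rowMeans(vapply(pts, function(p) p[, 2], numeric(n)))
  # centring: contributing nuclei have CoM at the origin, but the mean of
  # semilandmark vertices need not; re-centre the consensus polygon
  cen <- polygon_centroid(xs, ys)
  structure(
    list(x = xs - cen[1], y = ys - cen[2], n_nuclei = length(oriented)),
    class = "consensus_shape"
  )
}

#' @export
print.consensus_shape <- function(x, ...) {
  cat(sprintf("<consensus_shape> %d semilandmarks from %d nuclei\n",
              length(x$x), x$n_nuclei))
  invisible(x)
}

#' @export
plot.consensus_shape <- function(x, ...) {
  graphics::plot(c(x$x, x$x[1]), c(x$y, x$y[1]), type = "l", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::points(0, 0, pch = 19, col = "blue")
  invisible(x)
}

#' Write consensus outlines as an SVG overlay
#'
#' @param shapes A `consensus_shape` or named list of them, overlaid with
#'   distinct colours.
#' @param path Output SVG path.
#' @param width,height SVG canvas size in pixels.
#' @return `path`, invisibly.
#' @export
write_consensus_svg <- function(shapes, path, width = 400, height = 400) {
  if (inherits(shapes, "consensus_shape")) shapes <- list(shapes)
  allx <- unlist(lapply(shapes, `[[`, "x"))
  ally <- unlist(lapply(shapes, `[[`, "y"))
  pad <- 0.05 * max(diff(range(allx)), diff(range(ally)))
  sc <- min((width) / (diff(range(allx)) + 2 * pad),
            (height) / (diff(range(ally)) + 2 * pad))
  cols <- grDevices::hcl.colors(max(3L, length(shapes)), "Dark 3")
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    round(width), round(height)))
  for (k in seq_along(shapes)) {
    s <- shapes[[k]]
    px <- (s$x - min(allx) + pad) * sc
    py <- height - (s$y - min(ally) + pad) * sc  # SVG y runs down
    pts <- paste(sprintf("%.2f,%.2f", px, py), collapse = " ")
    nm <- names(shapes)[k]
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="none" stroke="%s" stroke-width="1.5"><title>%s</title></polygon>',
      pts, cols[k], if (is.null(nm) || !nzchar(nm)) paste0("shape", k) else nm))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Export a consensus shape as CSV coordinates
#'
#' @param shape A `consensus_shape`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
consensus_to_csv <- function(shape, path) {
  utils::write.csv(data.frame(x = shape$x, y = shape$y), path,
                   row.names = FALSE)
  invisible(path)
}
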