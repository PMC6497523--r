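#' Nucleus outline
#'
#' An ordered, closed, simple polygon tracing the perimeter of one nucleus.
#' Coordinates are stored in pixels in a mathematical y-up frame (image row 0
#' at the top is converted on creation); `scale` converts pixels to
#' micrometres. The outline is always stored counterclockwise: clockwise
#' input is silently reversed so that downstream interior-angle measurements
#' are unambiguous.
#'
#' @param x,y Numeric vectors of vertex coordinates (pixels, y-up). The
#'   polygon is implicitly closed; do not repeat the first vertex.
#' @param scale Pixel size in micrometres per pixel.
#' @param id Optional identifier (e.g. source image and object number).
#' @param min_vertices Minimum accepted vertex count. Outlines shorter than
#'   this cannot support a windowed angle profile and are rejected.
#' @return An object of class `nucleus_outline`: a list with elements `x`,
#'   `y`, `scale`, `id` and `com` (the area-weighted centroid, in pixels).
#' @seealso [outline_area()], [outline_perimeter()], [compute_profile()]
#' @export
nucleus_outline <- function(x, y, scale = 1, id = NA_character_,
                            min_vertices = 20L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < min_vertices) {
    stop("outline has ", length(x), " vertices; need at least ", min_vertices)
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("'scale' must be a single positive number (um/pixel)")
  }
  # drop a duplicated closing vertex if the caller supplied one
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  a2 <- signed_area2(x, y)
  if (abs(a2) < .Machine$double.eps) stop("degenerate outline: zero area")
  if (a2 < 0) { # clockwise: store counterclockwise
    x <- rev(x); y <- rev(y)
  }
  out <- structure(
    list(x = x, y = y, scale = scale, id = id, com = c(NA_real_, NA_real_)),
    class = "nucleus_outline"
  )
  out$com <- polygon_centroid(x, y)
  out
}

#' @export
print.nucleus_outline <- function(x, ...) {
  cat(sprintf(
    "<nucleus_outline> %d vertices, scale %.4g um/px, area %.3g um^2%s\n",
    length(x$x), x$scale, outline_area(x),
    if (is.na(x$id)) "" else paste0(", id ", x$id)
  ))
  invisible(x)
}

# twice the signed area (shoelace); > 0 for counterclockwise traversal
signed_area2 <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j])
}

polygon_centroid <- function(x, y) {
  n <- length(x)
  nxt <- c(seq_len(n)[-1L], 1L)
  cr <- x * y[nxt] - x[nxt] * y
  a2 <- sum(cr)
  c(sum((x + x[nxt]) * cr), sum((y + y[nxt]) * cr)) / (3 * a2)
}

polygon_is_simple <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1L], 1L)
  x2 <- x[nxt]; y2 <- y[nxt]
  # brute-force segment intersection over non-adjacent edge pairs
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_cross(x[i], y[i], x2[i], y2[i], x[js], y[js], x2[js], y2[js])))
      return(FALSE)
  }
  TRUE
}

# vectorized proper-crossing test of segment (ax,ay)-(bx,by) vs (cx,cy)-(dx,dy)
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Polygon area of an outline
#'
#' Shoelace area of the outline polygon, converted to square micrometres.
#'
#' @param outline A [nucleus_outline()].
#' @return Area in um^2.
#' @export
outline_area <- function(outline) {
  abs(signed_area2(outline$x, outline$y)) / 2 * outline$scale^2
}

#' Perimeter length of an outline
#'
#' Summed vertex-to-vertex Euclidean length of the closed polygon, in
#' micrometres.
#'
#' @inheritParams outline_area
#' @return Perimeter in um.
#' @export
outline_perimeter <- function(outline) {
  x <- outline$x; y <- outline$y
  nxt <- c(seq_along(x)[-1L], 1L)
  sum(sqrt((x[nxt] - x)^2 + (y[nxt] - y)^2)) * outline$scale
}

# cumulative arc length at each vertex (starting at 0 for vertex 1) plus the
# total perimeter, in pixel units
arc_lengths <- function(outline) {
  x <- outline$x; y <- outline$y
  nxt <- c(seq_along(x)[-1L], 1L)
  seg <- sqrt((x[nxt] - x)^2 + (y[nxt] - y)^2)
  list(s = cumsum(c(0, seg[-length(seg)])), total = sum(seg), seg = seg)
}

# point at arc length t (pixel units, wrapped) along the outline
point_at_arc <- function(outline, t, arcs = arc_lengths(outline)) {
  t <- t %% arcs$total
  i <- findInterval(t, arcs$s)       # edge index the point falls on
  f <- (t - arcs$s[i]) / arcs$seg[i] # fraction along that edge
  f[arcs$seg[i] == 0] <- 0
  n <- length(outline$x)
  j <- i %% n + 1L
  cbind(outline$x[i] + f * (outline$x[j] - outline$x[i]),
        outline$y[i] + f * (outline$y[j] - outline$y[i]))
}

# rigid rotation (degrees, counterclockwise) about a point
rotate_xy <- function(x, y, theta_deg, cx = 0, cy = 0) {
  th <- theta_deg * pi / 180
  dx <- x - cx; dy <- y - cy
  cbind(cx + dx * cos(th) - dy * sin(th),
        cy + dx * sin(th) + dy * cos(th))
}
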