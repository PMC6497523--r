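#' Nucleus detection parameters
#'
#' Parameters controlling edge-based nucleus detection. Edge thresholds are
#' expressed as fractions of the maximum gradient magnitude in the image, so
#' detection is invariant to overall exposure (multiplying the image by a
#' constant changes nothing).
#'
#' @param scale Pixel size, um/pixel.
#' @param min_area,max_area Accepted object area range, um^2. The defaults
#'   (10-60 um^2) bracket the mouse sperm nucleus (~19 um^2) generously.
#' @param low,high Hysteresis edge thresholds as fractions of the maximum
#'   gradient magnitude; `0 < low < high <= 1`.
#' @param closing_radius Radius (pixels) of the disc used for morphological
#'   closing of the edge map before hole filling.
#' @param exclude_border Drop objects touching the image border.
#' @param blur_sigma Gaussian pre-smoothing applied before the gradient,
#'   pixels.
#' @param refine Refine each object's boundary to the half-intensity contour
#'   between local foreground and background (the true edge position for a
#'   symmetrically blurred step edge); recommended.
#' @param smooth_window Circular moving-average window (pixels) applied to
#'   the traced pixel chain, suppressing the staircase bias of digitized
#'   boundaries. Use `0` to keep the raw chain.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(scale = 0.065, min_area = 10, max_area = 60,
                             low = 0.1, high = 0.3, closing_radius = 2L,
                             exclude_border = TRUE, blur_sigma = 1,
                             refine = TRUE, smooth_window = 5L) {
  if (!(min_area > 0 && min_area < max_area)) {
    stop("need 0 < min_area < max_area")
  }
  if (!(low > 0 && low < high && high <= 1)) {
    stop("need 0 < low < high <= 1")
  }
  structure(
    list(scale = scale, min_area = min_area, max_area = max_area,
         low = low, high = high, closing_radius = as.integer(closing_radius),
         exclude_border = isTRUE(exclude_border), blur_sigma = blur_sigma,
         refine = isTRUE(refine), smooth_window = as.integer(smooth_window)),
    class = "detection_params"
  )
}

#' Read a grayscale TIFF image
#'
#' Reads an 8- or 16-bit TIFF as a numeric matrix in `[0, 1]`. Multi-channel
#' files are reduced to their first channel with a warning.
#'
#' @param path TIFF file path.
#' @return Numeric matrix (rows = image rows, top row first).
#' @export
read_grayscale_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    warning("multi-channel image '", basename(path),
            "': using the first channel")
    img <- img[, , 1L]
  }
  img
}

#' Detect nuclei in a grayscale image
#'
#' Edge-based object detection: Gaussian smoothing, Sobel gradient
#' magnitude, hysteresis thresholding of the normalized gradient (weak-edge
#' components are kept only if they contain a strong edge), morphological
#' closing, hole filling and connected-component labelling. Components are
#' filtered by area and optionally by border contact, and each surviving
#' component's boundary is traced into a [nucleus_outline()].
#'
#' @param img Numeric matrix (2-D grayscale image, rows top-down) or a path
#'   accepted by [read_grayscale_tiff()].
#' @param params A [detection_params()].
#' @return List of [nucleus_outline()] objects (possibly empty).
#' @export
detect_nuclei <- function(img, params = detection_params()) {
  if (is.character(img)) img <- read_grayscale_tiff(img)
  if (length(dim(img)) != 2L) stop("'img' must be a 2-D grayscale image")
  stopifnot(inherits(params, "detection_params"))
  mask <- edge_mask(img, params)
  lab <- EBImage::bwlabel(mask)
  nobj <- max(lab)
  out <- list()
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_len(nobj)) {
    m <- lab == k
    if (params$refine) {
      m <- refine_mask(img, m)
      if (is.null(m)) next
    }
    px_area <- sum(m)
    area_um <- px_area * params$scale^2
    if (area_um < params$min_area || area_um > params$max_area) next
    rows <- row(m)[m]; cols <- col(m)[m]
    if (params$exclude_border &&
        (min(rows) == 1L || max(rows) == nr ||
         min(cols) == 1L || max(cols) == nc)) next
    verts <- trace_outline(m)
    if (nrow(verts) < 20L) next
    x <- verts[, 2]; y <- nr + 1 - verts[, 1]
    if (params$smooth_window >= 3L && length(x) >= 3L * params$smooth_window) {
      x <- circular_ma(x, params$smooth_window)
      y <- circular_ma(y, params$smooth_window)
    }
    if (!polygon_is_simple(x, y)) { # fall back to the raw chain
      x <- verts[, 2]; y <- nr + 1 - verts[, 1]
    }
    # pixel centers sit half a pixel inside the half-intensity contour:
    # push the outline out along the local normal to remove the bias
    off <- offset_outward(x, y, 0.5)
    if (polygon_is_simple(off[, 1], off[, 2])) {
      x <- off[, 1]; y <- off[, 2]
    }
    o <- nucleus_outline(x, y, scale = params$scale,
                         id = sprintf("obj%03d", k))
    out[[length(out) + 1L]] <- o
  }
  out
}

# displace each vertex of a simple polygon by d along the outward normal
offset_outward <- function(x, y, d) {
  if (signed_area2(x, y) < 0) d <- -d  # clockwise: outward is left of travel
  n <- length(x)
  nxt <- c(seq_len(n)[-1L], 1L)
  prv <- c(n, seq_len(n - 1L))
  tx <- x[nxt] - x[prv]; ty <- y[nxt] - y[prv]
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  # for counterclockwise traversal the outward normal is right of travel
  cbind(x + d * ty / len, y - d * tx / len)
}

# re-segment one object at the half-intensity level between its local
# foreground and background; returns the refined single-component mask or
# NULL if the refinement degenerates
refine_mask <- function(img, m) {
  brush <- EBImage::makeBrush(9L, "disc")
  dil <- EBImage::dilate(m * 1, brush) > 0
  ring <- dil & !m
  if (!any(ring) || !any(m)) return(NULL)
  fg <- stats::median(img[m])
  bg <- stats::median(img[ring & !(EBImage::dilate(m * 1, EBImage::makeBrush(5L, "disc")) > 0)])
  if (is.na(bg)) bg <- stats::median(img[ring])
  thr <- (fg + bg) / 2
  cand <- dil & (img >= thr)
  lab <- EBImage::bwlabel(cand)
  if (max(lab) == 0) return(NULL)
  # keep the component with the largest overlap with the seed object
  ov <- tabulate(lab[m & cand], nbins = max(lab))
  if (!length(ov) || max(ov) == 0) return(NULL)
  keep <- which.max(ov)
  ref <- lab == keep
  ref <- as.matrix(EBImage::fillHull(EBImage::Image(ref * 1))) > 0
  ref
}

# binary mask of filled objects from hysteresis-thresholded gradient edges
edge_mask <- function(img, params) {
  sm <- if (params$blur_sigma > 0) {
    as.matrix(EBImage::gblur(img, sigma = params$blur_sigma))
  } else img
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(sm, sx))
  gy <- as.matrix(EBImage::filter2(sm, t(sx)))
  g <- sqrt(gx^2 + gy^2)
  gmax <- max(g)
  if (gmax == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  g <- g / gmax
  weak <- g >= params$low
  strong <- g >= params$high
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  wl <- EBImage::bwlabel(weak)
  keep <- unique(wl[strong])
  keep <- keep[keep > 0]
  edges <- matrix(wl %in% keep, nrow(img), ncol(img))
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, "disc")
    edges <- EBImage::closing(edges, brush) > 0
  }
  filled <- EBImage::fillHull(EBImage::Image(edges * 1))
  as.matrix(filled) > 0
}

#' Trace the boundary of a single-object mask
#'
#' Moore-neighbour boundary tracing with Jacob's stopping criterion. The
#' mask must contain exactly one 8-connected foreground component; the
#' returned pixel chain is closed and visits the object's boundary pixels
#' in order (counterclockwise in the image frame with y pointing down, i.e.
#' counterclockwise after conversion to the y-up frame used by
#' [nucleus_outline()]).
#'
#' @param mask Logical (or 0/1) matrix with one foreground component.
#' @return Two-column matrix of (row, col) boundary pixel coordinates.
#' @export
trace_outline <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  lab <- EBImage::bwlabel(mask)
  if (max(lab) != 1L) stop("mask must contain exactly one connected component")
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  # start: first foreground pixel in column-major scan (uppermost of the
  # leftmost column), entered from the left
  start_i <- which(mask)[1L]
  sr <- (start_i - 1L) %% nr + 1L
  sc <- (start_i - 1L) %/% nr + 1L
  # Moore neighbourhood in clockwise order (image frame, row down):
  drs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dcs <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  # backtrack direction index: we came from the left (direction W = 7)
  path <- matrix(0L, nrow = 4L * sum(mask) + 8L, ncol = 2L)
  npath <- 0L
  r <- sr; c <- sc
  prev_dir <- 3L  # by convention we entered the start pixel moving East
  repeat {
    npath <- npath + 1L
    path[npath, ] <- c(r, c)
    found <- FALSE
    for (step in 0:7) {
      # scan clockwise starting just after the backtrack neighbour
      d <- (prev_dir + 4L + step) %% 8L + 1L
      nr2 <- r + drs[d]; nc2 <- c + dcs[d]
      if (inside(nr2, nc2)) {
        if (nr2 == sr && nc2 == sc) {
          return(path[seq_len(npath), , drop = FALSE])
        }
        r <- nr2; c <- nc2
        prev_dir <- d
        found <- TRUE
        break
      }
    }
    if (!found) { # isolated pixel
      return(path[seq_len(npath), , drop = FALSE])
    }
    if (npath >= nrow(path) - 1L) stop("boundary tracing did not terminate")
  }
}
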