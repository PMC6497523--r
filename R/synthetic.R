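#' Parametric nucleus shape specification
#'
#' Describes a synthetic nucleus to be generated by [make_outline()]. Four
#' families are available: `circle`, `ellipse` and `square` (simple controls
#' with closed-form area and perimeter) and `falciform`, a hook-shaped
#' outline emulating the rodent sperm head: an elongated body capped by an
#' apical hook, with a sharp convex tip, a concave under-hook region and a
#' flat ventral region below the hook.
#'
#' The falciform outline is built from a thickened spine: a straight body
#' axis of length `body_length` continued by a circular hook arc of length
#' `hook_length` turning through `hook_curvature` radians, with a half-width
#' profile that is widest (`body_width/2`) mid-body and tapers to sharp
#' points at the tip and the caudal base. Twelve control points sampled from
#' this construction are joined by a periodic cubic spline, so
#' population noise (which perturbs the control points radially) yields
#' smooth, realistic shape variation.
#'
#' @param kind One of `"circle"`, `"ellipse"`, `"square"`, `"falciform"`.
#' @param radius Circle radius (um).
#' @param a,b Ellipse semi-axes (um).
#' @param side Square side (um).
#' @param body_length,body_width Falciform body dimensions (um).
#' @param hook_length Arc length of the apical hook (um).
#' @param hook_curvature Total turning angle of the hook arc (radians).
#' @param rotation Rigid rotation applied to the generated outline (degrees,
#'   counterclockwise).
#' @param noise Population-noise scale in `[0, 0.5]`: the standard deviation
#'   of the relative radial perturbation applied to spline control points
#'   (falciform) or boundary radii (other kinds) when the spec is used by
#'   [make_population()].
#' @param label Population label carried into the ground truth.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("circle", "ellipse", "square", "falciform"),
                       radius = 2.5, a = 4, b = 2, side = 4,
                       body_length = 6, body_width = 3,
                       hook_length = 3, hook_curvature = 2.2,
                       rotation = 0, noise = 0, label = kind) {
  kind <- match.arg(kind)
  lens <- switch(kind,
    circle = c(radius = radius),
    ellipse = c(a = a, b = b),
    square = c(side = side),
    falciform = c(body_length = body_length, body_width = body_width,
                  hook_length = hook_length, hook_curvature = hook_curvature)
  )
  if (any(lens <= 0)) stop("all shape dimensions must be positive")
  if (noise < 0 || noise > 0.5) stop("'noise' must be in [0, 0.5]")
  structure(
    list(kind = kind, params = as.list(lens), rotation = rotation,
         noise = noise, label = label[1]),
    class = "shape_spec"
  )
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s [%s], rotation %g deg, noise %g\n", x$kind,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "),
              x$rotation, x$noise))
  invisible(x)
}

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate one synthetic nucleus outline with analytic ground truth
#'
#' Renders a [shape_spec()] as a polygonal [nucleus_outline()] together with
#' its ground truth: analytic area and perimeter (closed forms for circle,
#' ellipse and square; a 1e4-vertex polygonization for the splined
#' falciform), the applied rotation, the population label, and — for
#' falciform shapes — the true arc-length fractions of the named features
#' (tip, under-hook concavity, ventral flat region, caudal base), which
#' downstream landmark tests are scored against.
#'
#' @param spec A [shape_spec()].
#' @param n_vertices Number of outline vertices to generate.
#' @param scale Pixel size (um/pixel) recorded on the outline; synthetic
#'   coordinates are generated in um and stored as `um / scale` pixels.
#' @param seed Integer seed making the (spec, seed) pair fully reproducible.
#' @param centre Centre of the shape, um.
#' @return A list with elements `outline` ([nucleus_outline()]) and `truth`
#'   (list: `area`, `perimeter`, `rotation`, `label`, `features`).
#' @export
make_outline <- function(spec, n_vertices = 400, scale = 0.065, seed = 1,
                         centre = c(0, 0)) {
  stopifnot(inherits(spec, "shape_spec"))
  p <- spec$params
  feat <- NULL
  if (spec$kind == "falciform") {
    ctrl <- with_seed(seed, falciform_control_points(p, spec$noise))
    dense <- periodic_spline(ctrl, 10000L)        # ground-truth resolution
    xy <- periodic_spline(ctrl, n_vertices)
    truth_area <- abs(signed_area2(dense[, 1], dense[, 2])) / 2
    truth_perim <- poly_perim(dense)
    feat <- falciform_feature_fractions(ctrl, dense)
  } else {
    tt <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    base <- switch(spec$kind,
      circle = cbind(p$radius * cos(tt), p$radius * sin(tt)),
      ellipse = cbind(p$a * cos(tt), p$b * sin(tt)),
      square = square_points(p$side, n_vertices)
    )
    if (spec$noise > 0) {
      r <- with_seed(seed, 1 + spec$noise * stats::rnorm(n_vertices))
      # smooth the radial perturbation so the polygon stays simple
      r <- circular_ma(r, max(3L, n_vertices %/% 20L))
      base <- base * r
    }
    xy <- base
    truth_area <- switch(spec$kind,
      circle = pi * p$radius^2,
      ellipse = pi * p$a * p$b,
      square = p$side^2
    )
    truth_perim <- switch(spec$kind,
      circle = 2 * pi * p$radius,
      ellipse = ellipse_perimeter(p$a, p$b),
      square = 4 * p$side
    )
    if (spec$noise > 0) { # closed forms no longer hold: measure densely
      td <- seq(0, 2 * pi, length.out = 10001L)[-10001L]
      rd <- stats::approx(c(tt, 2 * pi), c(r, r[1]), xout = td)$y
      based <- switch(spec$kind,
        circle = cbind(p$radius * cos(td), p$radius * sin(td)),
        ellipse = cbind(p$a * cos(td), p$b * sin(td)),
        square = NULL
      )
      if (!is.null(based)) {
        dd <- based * rd
        truth_area <- abs(signed_area2(dd[, 1], dd[, 2])) / 2
        truth_perim <- poly_perim(dd)
      }
    }
  }
  rot <- rotate_xy(xy[, 1], xy[, 2], spec$rotation)
  x <- rot[, 1] + centre[1]
  y <- rot[, 2] + centre[2]
  if (!polygon_is_simple(x, y)) {
    stop("shape parameters produce a self-intersecting outline")
  }
  outline <- nucleus_outline(x / scale, y / scale, scale = scale,
                             id = spec$label)
  truth <- list(area = truth_area, perimeter = truth_perim,
                rotation = spec$rotation, label = spec$label,
                features = feat)
  list(outline = outline, truth = truth)
}

poly_perim <- function(xy) {
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1L], 1L)
  sum(sqrt(rowSums((xy[nxt, , drop = FALSE] - xy)^2)))
}

ellipse_perimeter <- function(a, b) {
  # 4 a E(e^2) with a the major semi-axis
  if (b > a) { tmp <- a; a <- b; b <- tmp }
  m <- 1 - (b / a)^2
  4 * a * pracma::ellipke(m)$e
}

square_points <- function(side, n) {
  # n points around a square of given side centred at the origin, CCW
  h <- side / 2
  t <- seq(0, 4, length.out = n + 1L)[-(n + 1L)]
  e <- pmin(floor(t), 3)
  f <- t - e
  x <- numeric(n); y <- numeric(n)
  x[e == 0] <- h;               y[e == 0] <- -h + side * f[e == 0]
  x[e == 1] <- h - side * f[e == 1]; y[e == 1] <- h
  x[e == 2] <- -h;              y[e == 2] <- h - side * f[e == 2]
  x[e == 3] <- -h + side * f[e == 3]; y[e == 3] <- -h
  cbind(x, y)
}

circular_ma <- function(v, k) {
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(v)
  ext <- c(v[(n - (k %/% 2) + 1L):n], v, v[1:(k %/% 2)])
  as.numeric(stats::filter(ext, rep(1 / k, k), sides = 2))[(k %/% 2 + 1L):(k %/% 2 + n)]
}

# Spine-and-width construction of the falciform control polygon.
# Returns a matrix of control points (um, CCW) with attributes marking which
# control point is the tip, under-hook, ventral flat and caudal base.
falciform_control_points <- function(p, noise = 0) {
  Lb <- p$body_length; Wb <- p$body_width
  Lh <- p$hook_length; phi <- p$hook_curvature
  r <- Lh / phi                       # hook arc radius
  # spine: base (0,0) -> (0, Lb), then arc curving toward -x
  spine <- function(s) {             # s in [0, Lb + Lh]
    s <- pmin(pmax(s, 0), Lb + Lh)
    inb <- s <= Lb
    out <- matrix(0, length(s), 2)
    out[inb, ] <- cbind(0, s[inb])
    a <- (s[!inb] - Lb) / r          # turned angle along the arc
    out[!inb, ] <- cbind(r * cos(a) - r, Lb + r * sin(a))
    out
  }
  spine_dir <- function(s) {
    inb <- s <= Lb
    out <- matrix(0, length(s), 2)
    out[inb, 1] <- 0
    out[inb, 2] <- 1
    a <- (s[!inb] - Lb) / r
    out[!inb, ] <- cbind(-sin(a), cos(a))
    out
  }
  S <- Lb + Lh
  halfwidth <- function(s) (Wb / 2) * sin(pi * (s / S))^0.7
  # stations along the spine for the two sides of the outline
  s_stations <- S * c(0.12, 0.38, 0.62, 0.82, 0.95)
  pt <- spine(s_stations); dr <- spine_dir(s_stations)
  nrm <- cbind(-dr[, 2], dr[, 1])    # left normal
  h <- halfwidth(s_stations)
  left <- pt + nrm * h
  right <- pt - nrm * h
  tip <- spine(S)
  base <- spine(0) - c(0, 0.1 * Wb)  # slight caudal point
  # CCW order: up the right (ventral/under-hook) side, around the tip,
  # down the left (dorsal) side, around the base
  ctrl <- rbind(base + c(0.35 * Wb, 0.05 * Lb), right, tip, left[5:1, ],
                base)
  if (noise > 0) {
    cen <- colMeans(ctrl)
    rad <- sweep(ctrl, 2, cen)
    ctrl <- sweep(rad * (1 + noise * stats::rnorm(nrow(ctrl))), 2, cen, "+")
  }
  attr(ctrl, "ix") <- list(tip = 7L, under_hook = 9L, ventral = 11L,
                           caudal_base = 13L)
  ctrl
}

# closed periodic cubic spline through control points, n output vertices
periodic_spline <- function(ctrl, n) {
  m <- nrow(ctrl)
  cx <- c(ctrl[, 1], ctrl[1, 1])
  cy <- c(ctrl[, 2], ctrl[1, 2])
  d <- cumsum(c(0, sqrt(diff(cx)^2 + diff(cy)^2)))  # chord-length parameter
  tt <- seq(0, d[m + 1L], length.out = n + 1L)[-(n + 1L)]
  x <- stats::spline(d, cx, method = "periodic", xout = tt)$y
  y <- stats::spline(d, cy, method = "periodic", xout = tt)$y
  xy <- cbind(x, y)
  attr(xy, "ctrl_param") <- d[seq_len(m)] / d[m + 1L]
  xy
}

# arc-length fractions (from dense vertex 1) of the named falciform features
falciform_feature_fractions <- function(ctrl, dense) {
  ix <- attr(ctrl, "ix")
  cp <- attr(dense, "ctrl_param")
  # convert chord parameter to true arc-length fraction on the dense polygon
  n <- nrow(dense)
  nxt <- c(seq_len(n)[-1L], 1L)
  seg <- sqrt(rowSums((dense[nxt, , drop = FALSE] - dense)^2))
  s <- cumsum(c(0, seg[-n]))
  tot <- sum(seg)
  frac_of <- function(k) {
    # dense vertex nearest the control point
    d2 <- (dense[, 1] - ctrl[k, 1])^2 + (dense[, 2] - ctrl[k, 2])^2
    s[which.min(d2)] / tot
  }
  vapply(ix, frac_of, numeric(1))
}

#' Generate a synthetic population of nuclei
#'
#' Draws `n` seeded perturbations of a base [shape_spec()]: each nucleus is
#' the base shape with its control points (falciform) or boundary radii
#' (other kinds) perturbed radially by the population noise scale, emulating
#' the within-sample shape variation of a real strain.
#'
#' @param n Number of nuclei.
#' @param spec Base [shape_spec()].
#' @param noise Population-noise scale; defaults to the spec's own.
#' @param seed Integer seed; nucleus `i` uses sub-seed `seed + i`. Draws
#'   whose perturbed control polygon self-intersects are deterministically
#'   re-drawn from follow-up sub-seeds (rejection sampling over valid
#'   shapes), so `(spec, seed)` always reproduces the same population.
#' @inheritParams make_outline
#' @return List of `n` elements, each as returned by [make_outline()].
#' @export
make_population <- function(n, spec, noise = spec$noise, seed = 1,
                            n_vertices = 400, scale = 0.065) {
  stopifnot(n >= 1)
  spec$noise <- noise
  lapply(seq_len(n), function(i) {
    for (try in 0:19) {
      res <- tryCatch(
        make_outline(spec, n_vertices = n_vertices, scale = scale,
                     seed = seed + i + try * 100003L),
        error = function(e) NULL
      )
      if (!is.null(res)) return(res)
    }
    stop("could not generate a simple outline for nucleus ", i)
  })
}

#' Canonical example populations
#'
#' Three base shapes used throughout the package's examples and validation
#' suites, emulating the kind of between-strain contrast seen in inbred
#' mice: `strain_a`, the default falciform (long curled hook, 6 x 3 um
#' body, ~19.5 um^2); `strain_b`, a slimmer falciform with a short, nearly
#' straight hook (the kind of difference a trained assessor can see at a
#' glance); and `round_control`, a plain ellipse standing in for
#' non-falciform nuclei.
#'
#' @return Named list of [shape_spec()] objects.
#' @export
example_population_specs <- function() {
  list(
    strain_a = shape_spec("falciform", label = "strain_a"),
    strain_b = shape_spec("falciform", body_length = 6.5, body_width = 2.6,
                          hook_length = 2, hook_curvature = 1.2,
                          label = "strain_b"),
    round_control = shape_spec("ellipse", a = 3.5, b = 1.8,
                               label = "round_control")
  )
}

#' Render outlines into a grayscale microscope-like image
#'
#' Rasterizes filled outlines at high intensity on a dark background, then
#' applies Gaussian blur and additive Gaussian noise, approximating a
#' DAPI-stained fluorescence capture. Outlines must not overlap and must fit
#' inside the canvas with a two-pixel margin.
#'
#' @param outlines List of [nucleus_outline()] objects (may be empty).
#' @param canvas Integer `c(width, height)` in pixels.
#' @param blur_sigma Gaussian blur standard deviation, pixels.
#' @param noise_sd Additive noise standard deviation, on the `[0, 1]`
#'   intensity scale.
#' @param fg,bg Foreground / background intensities in `[0, 1]`.
#' @param seed Seed for the noise field.
#' @return Numeric matrix (rows = image rows, top row first) with values
#'   clipped to `[0, 1]`, writable as 8- or 16-bit TIFF via
#'   [write_image_tiff()].
#' @export
render_image <- function(outlines, canvas = c(256, 256), blur_sigma = 1,
                         noise_sd = 0.02, fg = 0.85, bg = 0.05, seed = 1) {
  w <- as.integer(canvas[1]); h <- as.integer(canvas[2])
  img <- matrix(0, nrow = h, ncol = w)
  masks <- vector("list", length(outlines))
  for (k in seq_along(outlines)) {
    o <- outlines[[k]]
    # convert y-up outline coords to row/col
    col <- o$x
    row <- h + 1 - o$y
    if (min(col) < 3 || max(col) > w - 2 || min(row) < 3 || max(row) > h - 2) {
      stop("outline ", k, " does not fit in the canvas with a 2-pixel margin")
    }
    m <- fill_polygon(col, row, w, h)
    masks[[k]] <- m
    img[m] <- img[m] + 1
  }
  if (any(img > 1)) stop("outlines overlap; nuclei must not touch")
  img <- bg + (fg - bg) * img
  if (blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma))
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(w * h, 0, noise_sd), h, w))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# even-odd scanline fill; returns logical matrix [row, col]
fill_polygon <- function(px, py, w, h) {
  m <- matrix(FALSE, nrow = h, ncol = w)
  n <- length(px)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (r in max(1L, floor(min(py))):min(h, ceiling(max(py)))) {
    yr <- r
    crosses <- ((py <= yr) & (py[nxt] > yr)) | ((py[nxt] <= yr) & (py > yr))
    if (!any(crosses)) next
    i <- which(crosses)
    xx <- px[i] + (yr - py[i]) / (py[nxt][i] - py[i]) * (px[nxt][i] - px[i])
    xx <- sort(xx)
    for (k in seq(1L, length(xx) - 1L, by = 2L)) {
      c0 <- ceiling(xx[k]); c1 <- floor(xx[k + 1L])
      if (c1 >= c0) m[r, max(1L, c0):min(w, c1)] <- TRUE
    }
  }
  m
}

#' Write a rendered image as a single-channel TIFF
#'
#' @param img Matrix from [render_image()] (values in `[0, 1]`).
#' @param path Output file path.
#' @param bits 8 or 16 (default; matches cooled-CCD capture depth).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Simulate an image dataset on disk
#'
#' Renders populations of synthetic nuclei into TIFF images (a fixed number
#' of non-overlapping nuclei per image, placed on a grid) with one JSON
#' sidecar per image recording the ground truth of every rendered nucleus.
#'
#' @param dir Output directory (created if needed).
#' @param specs Named list of base [shape_spec()]s, one per population.
#' @param n_per_pop Nuclei per population.
#' @param per_image Nuclei per image.
#' @param seed Integer seed.
#' @param canvas,scale,blur_sigma,noise_sd Passed to [render_image()].
#' @param n_vertices Vertices per generated outline.
#' @return Data frame listing image files and nucleus ground truths.
#' @export
simulate_dataset <- function(dir, specs, n_per_pop = 50, per_image = 4,
                             seed = 1, canvas = c(512, 512), scale = 0.065,
                             blur_sigma = 1, noise_sd = 0.02,
                             n_vertices = 400) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    sp$label <- nm
    pop <- make_population(n_per_pop, sp, seed = seed + utf8ToInt(substr(nm, 1, 1)),
                           n_vertices = n_vertices, scale = scale)
    all <- c(all, pop)
  }
  # grid placement: per_image cells per canvas
  ncell <- ceiling(sqrt(per_image))
  cw <- canvas[1] %/% ncell; ch <- canvas[2] %/% ncell
  rows <- list()
  img_i <- 0L
  for (start in seq(1, length(all), by = per_image)) {
    img_i <- img_i + 1L
    batch <- all[start:min(start + per_image - 1L, length(all))]
    outs <- vector("list", length(batch))
    gts <- vector("list", length(batch))
    for (j in seq_along(batch)) {
      o <- batch[[j]]$outline
      cell_c <- ((j - 1L) %% ncell)
      cell_r <- ((j - 1L) %/% ncell)
      tx <- cell_c * cw + cw / 2 - o$com[1]
      ty <- cell_r * ch + ch / 2 - o$com[2]
      o$x <- o$x + tx; o$y <- o$y + ty
      o$com <- o$com + c(tx, ty)
      outs[[j]] <- o
      gts[[j]] <- batch[[j]]$truth
    }
    file <- file.path(dir, sprintf("image_%03d.tif", img_i))
    img <- render_image(outs, canvas = canvas, blur_sigma = blur_sigma,
                        noise_sd = noise_sd, seed = seed + img_i)
    write_image_tiff(img, file)
    jsonlite::write_json(
      lapply(gts, function(g) g[c("area", "perimeter", "rotation", "label")]),
      sub("\\.tif$", ".json", file), auto_unbox = TRUE, digits = NA
    )
    for (j in seq_along(batch)) {
      rows[[length(rows) + 1L]] <- data.frame(
        image = basename(file), label = gts[[j]]$label,
        area = gts[[j]]$area, perimeter = gts[[j]]$perimeter,
        rotation = gts[[j]]$rotation
      )
    }
  }
  do.call(rbind, rows)
}
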