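# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_circle <- function(r = 5, n = 720) {
  fx(sprintf("circle_%g_%d", r, n),
     function() make_outline(shape_spec("circle", radius = r),
                             n_vertices = n))
}

fx_square <- function(side = 4, n = 400) {
  fx(sprintf("square_%g_%d", side, n),
     function() make_outline(shape_spec("square", side = side),
                             n_vertices = n))
}

fx_falciform <- function(seed = 1) {
  fx(sprintf("falciform_%d", seed),
     function() make_outline(shape_spec("falciform"), seed = seed))
}

# a fitted falciform population shared by landmark/morphometry/consensus
# tests: n nuclei at noise 0.03, L = 500
fx_falc_fit <- function() {
  fx("falc_fit", function() {
    pop <- make_population(25, shape_spec("falciform"), noise = 0.03,
                           seed = 11)
    outs <- lapply(pop, `[[`, "outline")
    fit <- fit_profiles(outs, L = 500)
    list(pop = pop, outlines = outs, fit = fit,
         records = measure_nuclei(fit))
  })
}

# place an outline at a positive-coordinate position for rendering
shift_outline <- function(o, margin = 15) {
  tx <- margin - min(o$x); ty <- margin - min(o$y)
  o$x <- o$x + tx; o$y <- o$y + ty; o$com <- o$com + c(tx, ty)
  o
}

unwrap_angles <- function(th) {
  cumsum(c(th[1], ((diff(th) + pi) %% (2 * pi)) - pi))
}

# independent brute-force oracle for the windowed interior angle: walks a
# 10x-densified polygon to locate the window endpoints by explicit
# arc-length accumulation, measures the unsigned angle by the law of
# cosines, and resolves interior vs exterior with a point-in-polygon probe
# along the angle bisector (no signed-cross-product shortcut).
brute_force_profile <- function(outline, w) {
  x <- outline$x; y <- outline$y
  n <- length(x)
  # densify 10x by splitting each edge
  dx <- numeric(0); dy <- numeric(0)
  orig_at <- integer(n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    orig_at[i] <- length(dx) + 1L
    f <- (0:9) / 10
    dx <- c(dx, x[i] + f * (x[j] - x[i]))
    dy <- c(dy, y[i] + f * (y[j] - y[i]))
  }
  m <- length(dx)
  seg <- sqrt(diff(c(dx, dx[1]))^2 + diff(c(dy, dy[1]))^2)
  P <- sum(seg)
  cum <- cumsum(c(0, seg[-m]))
  walk_to <- function(target) {
    target <- target %% P
    k <- findInterval(target, cum)
    f <- (target - cum[k]) / seg[k]
    k2 <- k %% m + 1L
    c(dx[k] + f * (dx[k2] - dx[k]), dy[k] + f * (dy[k2] - dy[k]))
  }
  inside <- function(px, py) {
    # even-odd ray crossing
    j <- n
    odd <- FALSE
    for (i in seq_len(n)) {
      if ((y[i] > py) != (y[j] > py) &&
          px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]) {
        odd <- !odd
      }
      j <- i
    }
    odd
  }
  h <- w * P / 2
  vapply(seq_len(n), function(i) {
    s0 <- cum[orig_at[i]]
    V <- c(x[i], y[i])
    A <- walk_to(s0 - h)
    B <- walk_to(s0 + h)
    u <- A - V; v <- B - V
    ca <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    theta <- acos(pmin(1, pmax(-1, ca))) * 180 / pi
    bis <- u / sqrt(sum(u^2)) + v / sqrt(sum(v^2))
    if (sqrt(sum(bis^2)) < 1e-9) return(180)
    bis <- bis / sqrt(sum(bis^2))
    probe <- V + 1e-3 * bis
    if (inside(probe[1], probe[2])) theta else 360 - theta
  }, numeric(1))
}
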