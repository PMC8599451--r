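#' Fiber field simulation specification
#'
#' Synthetic collagen-fiber field: each fiber is a sinusoidally perturbed
#' straight path whose amplitude is solved so its arc-length-to-chord ratio
#' (waviness) matches the target exactly; fiber axes are drawn from an
#' axial von Mises distribution with concentration `orientation_kappa`
#' (0 = isotropic on `[0, pi)`).
#'
#' @param n_fibers number of fibers.
#' @param target_waviness dimensionless, >= 1 (1 = straight).
#' @param orientation_kappa concentration of the axial angle distribution.
#' @param mean_orientation_deg mean fiber axis in degrees, `[0, 180)`.
#' @param fiber_width stroke width in pixels when rendered.
#' @param fiber_length_px chord length of each fiber, px.
#' @param image_size raster side, px.
#' @param n_vertices vertices per polyline.
#' @param seed integer RNG seed.
#' @return Object of class `fiber_field_spec`.
#' @export
fiber_field_spec <- function(n_fibers = 60, target_waviness = 1.3,
                             orientation_kappa = 0, mean_orientation_deg = 90,
                             fiber_width = 3, fiber_length_px = 120,
                             image_size = 512, n_vertices = 200, seed = 1L) {
  if (target_waviness < 1) stop("'target_waviness' must be >= 1")
  if (orientation_kappa < 0) stop("'orientation_kappa' must be >= 0")
  structure(list(n_fibers = as.integer(n_fibers),
                 target_waviness = target_waviness,
                 orientation_kappa = orientation_kappa,
                 mean_orientation_deg = mean_orientation_deg,
                 fiber_width = fiber_width,
                 fiber_length_px = fiber_length_px,
                 image_size = as.integer(image_size),
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "fiber_field_spec")
}

# arc-length / chord ratio of y = A * sin(2*pi*x/L * cycles) sampled at the
# generator's vertex density, as a function of the relative amplitude a=A/L
.sine_waviness <- function(a, n_vertices, cycles = 2) {
  x <- seq(0, 1, length.out = n_vertices)
  y <- a * sin(2 * pi * cycles * x)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# von Mises sampler (rejection method of Best & Fisher)
.rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

#' Generate a synthetic fiber field with ground-truth traces
#'
#' @param spec a [fiber_field_spec()].
#' @return List with `image` (grayscale matrix 0-255, fibers bright),
#'   `traces` (a [fiber_traces()] table of ground-truth polylines) and
#'   `angles_deg` (true fiber axes in `[0, 180)`).
#' @export
gen_fiber_field <- function(spec) {
  stopifnot(inherits(spec, "fiber_field_spec"))
  set.seed(spec$seed)
  s <- spec$image_size
  L <- spec$fiber_length_px
  nv <- spec$n_vertices
  # solve the sine amplitude for the exact target waviness at this sampling
  if (spec$target_waviness == 1) {
    a_rel <- 0
  } else {
    a_rel <- stats::uniroot(function(a) .sine_waviness(a, nv) - spec$target_waviness,
                            c(0, 2), tol = 1e-12)$root
  }
  mu2 <- 2 * spec$mean_orientation_deg * pi / 180
  phi <- .rvonmises(spec$n_fibers, mu2, spec$orientation_kappa)
  angles <- (phi / 2) %% pi  # axial angles in [0, pi)
  img <- matrix(0, s, s)
  rows <- list()
  margin <- L / 2 + a_rel * L + spec$fiber_width + 2
  for (f in seq_len(spec$n_fibers)) {
    th <- angles[f]
    cx <- stats::runif(1, margin, s - margin)
    cy <- stats::runif(1, margin, s - margin)
    tt <- seq(-0.5, 0.5, length.out = nv)
    u <- tt * L
    w <- a_rel * L * sin(2 * pi * 2 * tt)
    x <- cx + u * cos(th) - w * sin(th)
    y <- cy + u * sin(th) + w * cos(th)
    rows[[f]] <- data.frame(fiber_id = f, frame_id = 1L,
                            vertex_index = seq_len(nv), x = x, y = y)
    # stamp the path into the raster
    px <- round(x); py <- round(y)
    rad <- max(0L, floor((spec$fiber_width - 1) / 2))
    for (d in seq_len(length(px))) {
      rr <- (py[d] - rad):(py[d] + rad)
      cc <- (px[d] - rad):(px[d] + rad)
      rr <- rr[rr >= 1 & rr <= s]; cc <- cc[cc >= 1 & cc <= s]
      img[rr, cc] <- 200
    }
  }
  tr <- do.call(rbind, rows)
  class(tr) <- c("fiber_traces", "data.frame")
  list(image = img, traces = tr, angles_deg = angles * 180 / pi)
}

#' Fiber trace table constructor
#'
#' Polyline vertices of manually traced fibers: columns `fiber_id`,
#' `frame_id`, `vertex_index`, `x`, `y`.
#'
#' @param df data.frame with those columns.
#' @return `fiber_traces` data.frame.
#' @export
fiber_traces <- function(df) {
  need <- c("fiber_id", "frame_id", "vertex_index", "x", "y")
  if (!all(need %in% names(df))) stop("fiber traces need columns: ",
                                      paste(need, collapse = ", "))
  class(df) <- c("fiber_traces", "data.frame")
  df
}

#' Read fiber traces from CSV
#' @param path CSV with columns fiber_id, frame_id, vertex_index, x, y.
#' @return A `fiber_traces` table.
#' @export
read_fiber_csv <- function(path) fiber_traces(utils::read.csv(path))

#' Generate a binary test pattern with known fractal dimension
#'
#' @param kind `"line"` (1-px straight line, D = 1), `"filled_square"`
#'   (D = 2), `"sierpinski_triangle"` (bitwise construction on a
#'   `2^depth` grid containing exactly `3^depth` filled cells,
#'   D = log 3 / log 2), or `"random_clusters"` (Gaussian point clusters,
#'   no theoretical D).
#' @param depth recursion depth for the Sierpinski pattern (>= 1).
#' @param size raster side for the non-Sierpinski kinds.
#' @param n_clusters,points_per_cluster,cluster_sd random-cluster
#'   parameters.
#' @param seed RNG seed (random_clusters only).
#' @return List with `mask` (a [binary_mask()]) and
#'   `theoretical_dimension` (NA for random clusters).
#' @export
gen_fractal_pattern <- function(kind = c("line", "filled_square",
                                         "sierpinski_triangle", "random_clusters"),
                                depth = 7, size = 512, n_clusters = 30,
                                points_per_cluster = 200, cluster_sd = 6,
                                seed = 1L) {
  kind <- match.arg(kind)
  if (depth < 1) stop("'depth' must be >= 1")
  if (kind == "line") {
    m <- matrix(FALSE, size, size)
    m[round(size / 2), ] <- TRUE
    dim_theo <- 1.0
  } else if (kind == "filled_square") {
    m <- matrix(TRUE, size, size)
    dim_theo <- 2.0
  } else if (kind == "sierpinski_triangle") {
    n <- 2L^depth
    i <- matrix(rep(0:(n - 1L), times = n), n, n)
    j <- matrix(rep(0:(n - 1L), each = n), n, n)
    m <- matrix(bitwAnd(as.vector(i), as.vector(j)) == 0L, n, n)
    dim_theo <- log(3) / log(2)
  } else {
    set.seed(seed)
    m <- matrix(FALSE, size, size)
    cx <- stats::runif(n_clusters, 1, size)
    cy <- stats::runif(n_clusters, 1, size)
    for (k in seq_len(n_clusters)) {
      px <- round(stats::rnorm(points_per_cluster, cx[k], cluster_sd))
      py <- round(stats::rnorm(points_per_cluster, cy[k], cluster_sd))
      ok <- px >= 1 & px <= size & py >= 1 & py <= size
      m[cbind(py[ok], px[ok])] <- TRUE
    }
    dim_theo <- NA_real_
  }
  list(mask = binary_mask(m, 1, provenance = list(op = "gen_fractal_pattern",
                                                  kind = kind)),
       theoretical_dimension = dim_theo)
}
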