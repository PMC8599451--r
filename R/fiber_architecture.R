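#' Waviness index of a traced fiber
#'
#' `W = Length[curved] / Length[linear]`: polyline arc length divided by
#' the Euclidean distance between the first and last vertex (the tangential
#' chord). `W >= 1`, with equality iff the path is a straight monotone
#' segment. Invariant under rigid motions and uniform scaling.
#'
#' @param x,y vertex coordinates (>= 2 vertices, distinct endpoints), or a
#'   two-column matrix in `x`.
#' @return Waviness index (dimensionless).
#' @export
waviness <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  if (length(x) < 2L) stop("a fiber trace needs at least 2 vertices")
  dx <- diff(x); dy <- diff(y)
  if (any(dx == 0 & dy == 0)) stop("consecutive vertices must be distinct")
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  if (chord == 0) stop("coincident endpoints: linear length is zero")
  sum(sqrt(dx^2 + dy^2)) / chord
}

#' Waviness over frames of traced fibers
#'
#' Per-frame fiber means followed by a grand mean over frames. The study
#' convention is at least ten fibers per frame and at least six frames;
#' shortfalls are warned about but the data are retained.
#'
#' @param traces a [fiber_traces()] table.
#' @param min_fibers,min_frames convention thresholds for the warnings.
#' @return List with `grand_mean`, `grand_sd` (over per-frame means),
#'   `per_frame` data.frame and `n_fibers_total`.
#' @export
waviness_batch <- function(traces, min_fibers = 10, min_frames = 6) {
  stopifnot(inherits(traces, "fiber_traces"))
  if (!nrow(traces)) stop("no traces")
  key <- interaction(traces$frame_id, traces$fiber_id, drop = TRUE)
  w_per_fiber <- vapply(split(traces, key), function(d) {
    d <- d[order(d$vertex_index), ]
    waviness(d$x, d$y)
  }, numeric(1))
  frame_of <- vapply(split(traces$frame_id, key), `[`, traces$frame_id[1], 1)
  per_frame <- tapply(w_per_fiber, frame_of, mean)
  n_per_frame <- tapply(w_per_fiber, frame_of, length)
  if (any(n_per_frame < min_fibers))
    warning(sprintf("%d frame(s) have fewer than %d fibers (retained)",
                    sum(n_per_frame < min_fibers), min_fibers))
  if (length(per_frame) < min_frames)
    warning(sprintf("only %d frame(s); %d are the convention",
                    length(per_frame), min_frames))
  list(grand_mean = mean(per_frame),
       grand_sd = if (length(per_frame) > 1L) stats::sd(per_frame) else 0,
       per_frame = data.frame(frame_id = names(per_frame),
                              mean_waviness = as.numeric(per_frame),
                              n_fibers = as.integer(n_per_frame)),
       n_fibers_total = length(w_per_fiber))
}

#' Structure-tensor anisotropy of a fiber image
#'
#' Accumulates per-pixel intensity gradients inside the ROI into the
#' normalized 2x2 structure (nematic) tensor and scores anisotropy as
#' `(lambda1 - lambda2) / (lambda1 + lambda2)` of its eigenvalues
#' (0 = isotropic, 1 = perfectly aligned). The reported orientation is the
#' dominant fiber axis (perpendicular to the dominant gradient), in degrees
#' on `[0, 180)`. Invariant to intensity gain and offset.
#'
#' @param image grayscale matrix.
#' @param roi optional [binary_mask()] or logical matrix; default whole
#'   frame (a 1-px border is always excluded where gradients are
#'   undefined).
#' @return List with `anisotropy` and `mean_orientation_deg`.
#' @export
anisotropy <- function(image, roi = NULL) {
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3L || nc < 3L) stop("image too small for gradients")
  m <- if (is.null(roi)) matrix(TRUE, nr, nc) else if (inherits(roi, "binary_mask")) roi$mask else roi
  # Scharr derivative kernels: a central difference cross-smoothed with
  # (3, 10, 3)/16, which minimizes the angular bias of the gradient
  # direction at the spatial frequencies of fine fibrillar texture
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  cd_x <- (image[ri, ci + 1] - image[ri, ci - 1]) / 2
  cd_x_up <- (image[ri - 1, ci + 1] - image[ri - 1, ci - 1]) / 2
  cd_x_dn <- (image[ri + 1, ci + 1] - image[ri + 1, ci - 1]) / 2
  cd_y <- (image[ri + 1, ci] - image[ri - 1, ci]) / 2
  cd_y_lf <- (image[ri + 1, ci - 1] - image[ri - 1, ci - 1]) / 2
  cd_y_rt <- (image[ri + 1, ci + 1] - image[ri - 1, ci + 1]) / 2
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[ri, ci] <- (3 * cd_x_up + 10 * cd_x + 3 * cd_x_dn) / 16
  gy[ri, ci] <- (3 * cd_y_lf + 10 * cd_y + 3 * cd_y_rt) / 16
  valid <- m
  valid[c(1, nr), ] <- FALSE; valid[, c(1, nc)] <- FALSE
  if (!any(valid)) stop("empty ROI")
  xx <- mean(gx[valid]^2); yy <- mean(gy[valid]^2); xy <- mean((gx * gy)[valid])
  tr <- xx + yy
  if (tr == 0) stop("constant ROI: no gradient signal")
  disc <- sqrt((xx - yy)^2 + 4 * xy^2)
  score <- disc / tr
  grad_axis <- 0.5 * atan2(2 * xy, xx - yy)   # dominant gradient direction
  fiber_axis <- grad_axis + pi / 2            # fibers run perpendicular to it
  deg <- (fiber_axis * 180 / pi) %% 180
  list(anisotropy = score, mean_orientation_deg = deg)
}

#' Box-counting fractal dimension and lacunarity
#'
#' For each box size and each grid origin offset ("slipping" grids:
#' translated origins in addition to the tight origin-anchored grid),
#' counts occupied boxes `N(eps)` and records per-box foreground mass.
#' `D` is the least-squares slope of `log N(eps)` versus `log(1/eps)`;
#' by default `N(eps)` is the minimal count over grid positions — the
#' tightest cover, which is the definition of the box-counting dimension
#' — with `aggregate = "mean_scan"` available to average the per-scan
#' slopes instead. Lacunarity per scan is `(sigma/mu)^2 + 1` over
#' occupied-box masses, and the reported `Lambda` is its mean over sizes
#' and scans. Grid scans whose sampled foreground density falls below
#' `min_density` of the mean scan density are flagged (and excluded when
#' `apply_density_filter` is TRUE).
#'
#' @param mask a [binary_mask()].
#' @param box_sizes box edge lengths in px; default powers of 2 from 2 up
#'   to 45% of the shorter image side.
#' @param grid_offsets number of translated grid origins in addition to the
#'   tight origin-anchored grid.
#' @param min_density per-scan density filter threshold (0.40 is the
#'   published default).
#' @param apply_density_filter whether flagged scans are excluded from the
#'   averages.
#' @param aggregate `"min_cover"` (default) or `"mean_scan"`.
#' @return List with `D`, `Lambda`, `per_size` table (size, minimal and
#'   mean count, mean lacunarity), `per_scan` (offset, D, density,
#'   flagged).
#' @export
fractal_lacunarity <- function(mask, box_sizes = NULL, grid_offsets = 4,
                               min_density = 0.40, apply_density_filter = FALSE,
                               aggregate = c("min_cover", "mean_scan")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$mask
  if (!any(m)) stop("empty mask")
  side <- min(dim(m))
  if (is.null(box_sizes)) {
    box_sizes <- 2^(1:30)
    box_sizes <- box_sizes[box_sizes <= 0.45 * side]
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 3L) stop("need at least 3 usable box sizes")
  fg <- which(m, arr.ind = TRUE)
  n_fg <- nrow(fg)
  offs <- cbind(0, 0)
  if (grid_offsets > 0) {
    px <- seq_len(grid_offsets)   # small incremental pixel shifts
    offs <- rbind(offs, cbind(px, px))
  }
  n_scan <- nrow(offs)
  counts <- matrix(NA_real_, n_scan, length(box_sizes))
  lac <- matrix(NA_real_, n_scan, length(box_sizes))
  for (sc in seq_len(n_scan)) {
    for (bi in seq_along(box_sizes)) {
      eps <- box_sizes[bi]
      # periodic (toroidal) grid shift: avoids spurious partial boxes at
      # the raster boundary that would bias the slope at large box sizes
      br <- ((fg[, 1] - 1 + offs[sc, 1]) %% nrow(m)) %/% eps
      bc <- ((fg[, 2] - 1 + offs[sc, 2]) %% ncol(m)) %/% eps
      key <- br * (max(bc) + 1) + bc
      mass <- as.numeric(table(key))
      counts[sc, bi] <- length(mass)
      mu <- mean(mass)
      # population CV^2 + 1 over occupied-box masses
      lac[sc, bi] <- if (length(mass) > 1L)
        (stats::sd(mass) * sqrt((length(mass) - 1) / length(mass)) / mu)^2 + 1
      else 1
    }
  }
  lx <- log(1 / box_sizes)
  d_per_scan <- apply(counts, 1, function(ct) {
    stats::coef(stats::lm(log(ct) ~ lx))[2]
  })
  # per-scan sampled foreground density (mean per-box mass / box area),
  # compared across scans per the density filter
  dens <- vapply(seq_len(n_scan), function(sc) {
    mean(n_fg / counts[sc, ] / box_sizes^2)
  }, numeric(1))
  flagged <- dens < min_density * mean(dens)
  use <- if (apply_density_filter) !flagged else rep(TRUE, n_scan)
  if (!any(use)) use <- rep(TRUE, n_scan)
  n_min <- apply(counts[use, , drop = FALSE], 2, min)
  D <- if (aggregate == "min_cover")
    unname(stats::coef(stats::lm(log(n_min) ~ lx))[2])
  else mean(d_per_scan[use])
  list(D = D,
       Lambda = mean(lac[use, , drop = FALSE]),
       per_size = data.frame(box_size = box_sizes,
                             min_count = n_min,
                             mean_count = colMeans(counts[use, , drop = FALSE]),
                             mean_lacunarity = colMeans(lac[use, , drop = FALSE])),
       per_scan = data.frame(offset_px = offs[, 1], D = as.numeric(d_per_scan),
                             density = dens, flagged = flagged))
}

#' Preprocess a fiber image for fractal analysis
#'
#' Exact published chain: rolling-ball background subtraction (radius 75)
#' -> unsharp mask (radius 2, weight 0.60) -> median filter (radius 1) ->
#' automatic threshold (iterative intermeans, bright foreground) ->
#' despeckle.
#'
#' @param image grayscale matrix (0-255).
#' @param rolling_radius,unsharp_radius,unsharp_weight,median_radius chain
#'   parameters (published defaults).
#' @return A [binary_mask()] of the fiber foreground.
#' @export
preprocess_for_fractal <- function(image, rolling_radius = 75,
                                   unsharp_radius = 2, unsharp_weight = 0.60,
                                   median_radius = 1) {
  stopifnot(is.matrix(image))
  x <- rolling_ball_subtract(image, rolling_radius)
  x <- unsharp_mask(x, unsharp_radius, unsharp_weight)
  x <- pmin(pmax(x, 0), 255)
  x <- median_filter(x, median_radius)
  m <- auto_threshold(x, "default_isodata", foreground = "bright")
  despeckle(m)
}
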