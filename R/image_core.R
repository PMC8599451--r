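#' Colour-threshold an RGB section by an HSB gate
#'
#' Reproduces ImageJ-style colour thresholding on the 0-255 HSB scale: a
#' pixel belongs to the mask iff its (hue, saturation, brightness) triple
#' lies inclusively inside the gate. Hue wraps around only when
#' `hue_min > hue_max`.
#'
#' @param image a [section_image()].
#' @param range an [hsb_range()].
#' @return A [binary_mask()] with the gate recorded in its provenance.
#' @export
hsb_threshold <- function(image, range) {
  if (!inherits(image, "section_image")) stop("'image' must be a section_image (RGB)")
  stopifnot(inherits(range, "hsb_range"))
  hsb <- .rgb_to_hsb255(image$rgb)
  if (range$hue_min <= range$hue_max) {
    hue_ok <- hsb$h >= range$hue_min & hsb$h <= range$hue_max
  } else {
    hue_ok <- hsb$h >= range$hue_min | hsb$h <= range$hue_max
  }
  m <- hue_ok &
    hsb$s >= range$sat_min & hsb$s <= range$sat_max &
    hsb$b >= range$bright_min & hsb$b <= range$bright_max
  binary_mask(m, image$pixel_size,
              provenance = list(op = "hsb_threshold", range = unclass(range)))
}

#' Rolling-ball style background subtraction
#'
#' Estimates a smooth background as the grayscale morphological opening of
#' the image with a disc structuring element of the given radius and
#' subtracts it, clamping at zero. Constant images map to (approximately)
#' zero; features smaller than the disc are preserved.
#'
#' @param image numeric matrix (0-255).
#' @param radius ball radius in pixels (> 0).
#' @return Background-subtracted matrix, same shape, values >= 0.
#' @export
rolling_ball_subtract <- function(image, radius) {
  stopifnot(is.matrix(image))
  if (radius <= 0) stop("'radius' must be > 0")
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- EBImage::opening(.as_ebi(image), brush)
  out <- image - .from_ebi(bg)
  out[out < 0] <- 0
  out
}

## ---- automatic histogram thresholds -----------------------------------

# 256-bin histogram of an 8-bit image (values clamped/rounded to 0..255)
.hist256 <- function(image) {
  v <- pmin(pmax(round(as.vector(image)), 0), 255)
  tabulate(v + 1L, nbins = 256L)
}

# Intermeans / isodata (the variant historically labelled "Default").
# The Ridler-Calvard condition t = (mu_below + mu_above)/2 is solved as the
# first crossing t >= (mu0(t) + mu1(t))/2, which is unique; computed here
# with cumulative sums.
.threshold_isodata <- function(h) {
  g <- 0:255
  n0 <- cumsum(h)
  s0 <- cumsum(g * h)
  n1 <- sum(h) - n0
  s1 <- sum(g * h) - s0
  valid <- n0 > 0 & n1 > 0
  mid <- (s0 / n0 + s1 / n1) / 2
  cross <- which(valid & g >= mid)
  if (!length(cross)) stop("degenerate histogram")
  as.integer(cross[1] - 1L)
}

# Yen's maximum-correlation criterion.
.threshold_yen <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  crit <- rep(-Inf, 256)
  for (t in 1:255) {               # threshold index t means gate at gray t-1
    a <- P1sq[t] * P2sq[t]
    b <- P1[t] * (1 - P1[t])
    if (a > 0 && b > 0) crit[t] <- -log(a) + 2 * log(b)
  }
  which.max(crit) - 1L
}

# Triangle (geometric) method: a line is drawn from the histogram peak to
# the foot of the longer tail, and the threshold is the bin whose signed
# deviation below that line (line height minus bin count, the perpendicular
# distance up to a constant factor) is maximal.
.threshold_triangle <- function(h) {
  nz <- which(h > 0L)
  if (length(nz) < 2L) stop("degenerate histogram")
  bmin <- nz[1] - 1L
  bmax <- nz[length(nz)] - 1L
  peak <- which.max(h) - 1L
  # work on the longer tail; mirror the histogram if the tail is on the left
  flipped <- (peak - bmin) > (bmax - peak)
  hh <- if (flipped) rev(h) else h
  peak2 <- if (flipped) 255L - peak else peak
  end2 <- if (flipped) 255L - bmin else bmax
  hp <- hh[peak2 + 1L]
  if (end2 <= peak2) stop("degenerate histogram")
  b <- (peak2 + 1L):end2
  line_height <- hp * (1 - (b - peak2) / (end2 - peak2))
  dev <- line_height - hh[b + 1L]
  t2 <- b[which.max(dev)]
  if (flipped) 255L - t2 else t2
}

# Tsai's moment-preserving method.
.threshold_moments <- function(h) {
  p <- h / sum(h)
  g <- 0:255
  m1 <- sum(g * p); m2 <- sum(g^2 * p); m3 <- sum(g^3 * p)
  cd <- m2 - m1^2
  if (cd <= 0) stop("degenerate histogram")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) stop("moment-preserving solution does not exist")
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)   # fraction of pixels below the threshold
  cum <- cumsum(p)
  t <- which(cum >= p0 - 1e-12)[1] - 1L
  if (is.na(t)) t <- 255L
  as.integer(t)
}

#' Automatic histogram threshold
#'
#' Computes a global threshold on the 256-bin histogram of an 8-bit image by
#' one of four published criteria: iterative intermeans (the classic isodata
#' variant, the historical meaning of the "Default" method identifier),
#' Yen's maximum-correlation criterion, the geometric triangle method, or
#' Tsai's moment-preserving method.
#'
#' @param image numeric matrix with values in `[0, 255]`.
#' @param method one of `"default_isodata"`, `"yen"`, `"triangle"`,
#'   `"moments"`.
#' @param foreground `"bright"` (mask = image > threshold) or `"dark"`
#'   (mask = image < threshold).
#' @param pixel_size micrometres per pixel recorded on the mask.
#' @return A [binary_mask()]; the chosen threshold value is stored in the
#'   provenance and as attribute `threshold`.
#' @export
auto_threshold <- function(image,
                           method = c("default_isodata", "yen", "triangle", "moments"),
                           foreground = c("bright", "dark"),
                           pixel_size = 1) {
  method <- match.arg(method)
  foreground <- match.arg(foreground)
  stopifnot(is.matrix(image))
  h <- .hist256(image)
  if (sum(h > 0L) < 2L)
    stop("degenerate histogram: image is constant, no threshold exists")
  t <- switch(method,
              default_isodata = .threshold_isodata(h),
              yen = .threshold_yen(h),
              triangle = .threshold_triangle(h),
              moments = .threshold_moments(h))
  m <- if (foreground == "bright") image > t else image < t
  out <- binary_mask(m, pixel_size,
                     provenance = list(op = "auto_threshold", method = method,
                                       threshold = t, foreground = foreground))
  attr(out, "threshold") <- t
  out
}

## ---- linear / rank filters --------------------------------------------

#' Median filter
#'
#' Square-window median filter of the given radius (window side
#' `2 * radius + 1`). Idempotent on constant images; removes isolated
#' impulses at radius 1.
#'
#' @param image numeric matrix (0-255).
#' @param radius window radius in pixels (>= 1).
#' @return Filtered matrix.
#' @export
median_filter <- function(image, radius) {
  stopifnot(is.matrix(image))
  if (radius < 1) stop("'radius' must be >= 1")
  .from_ebi(EBImage::medianFilter(.as_ebi(image), as.integer(radius)))
}

#' Gaussian blur
#'
#' @param image numeric matrix (0-255).
#' @param sigma standard deviation of the Gaussian kernel in pixels (> 0).
#' @return Blurred matrix; mean intensity preserved away from borders.
#' @export
gaussian_blur <- function(image, sigma) {
  stopifnot(is.matrix(image))
  if (sigma <= 0) stop("'sigma' must be > 0")
  .from_ebi(EBImage::gblur(.as_ebi(image), sigma = sigma))
}

#' Unsharp mask
#'
#' Sharpens by subtracting a weighted Gaussian blur:
#' `out = (image - weight * blur) / (1 - weight)`.
#'
#' @param image numeric matrix (0-255).
#' @param radius Gaussian sigma of the blur, in pixels.
#' @param weight mask weight in `[0, 1)`.
#' @return Sharpened matrix (not clamped).
#' @export
unsharp_mask <- function(image, radius, weight) {
  stopifnot(is.matrix(image))
  if (radius <= 0) stop("'radius' must be > 0")
  if (weight < 0 || weight >= 1) stop("'weight' must be in [0, 1)")
  (image - weight * gaussian_blur(image, radius)) / (1 - weight)
}

#' Despeckle a binary mask
#'
#' 3x3 median on the binary raster, removing isolated foreground or
#' background pixels.
#'
#' @param mask a [binary_mask()].
#' @return A despeckled [binary_mask()].
#' @export
despeckle <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- median_filter(mask$mask * 255, 1) > 127
  binary_mask(m, mask$pixel_size,
              provenance = list(op = "despeckle", parent = mask$provenance))
}

## ---- skeleton analysis ------------------------------------------------

# Zhang-Suen thinning of a logical matrix, vectorised over the raster.
.thin_zhang_suen <- function(m) {
  pad <- function(x) {
    out <- matrix(FALSE, nrow(x) + 2L, ncol(x) + 2L)
    out[2:(nrow(x) + 1L), 2:(ncol(x) + 1L)] <- x
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      nr <- nrow(m); nc <- ncol(m)
      ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
      P2 <- p[ri - 1L, ci];     P3 <- p[ri - 1L, ci + 1L]
      P4 <- p[ri, ci + 1L];     P5 <- p[ri + 1L, ci + 1L]
      P6 <- p[ri + 1L, ci];     P7 <- p[ri + 1L, ci - 1L]
      P8 <- p[ri, ci - 1L];     P9 <- p[ri - 1L, ci - 1L]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (step == 1L) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Skeletonize a mask and count branches and junctions
#'
#' Thins the mask to a 1-px skeleton (Zhang-Suen), then analyses its
#' topology under 8-connectivity: a junction is a skeleton pixel with at
#' least three skeleton neighbours (adjacent junction pixels are merged into
#' one junction), and a branch is a maximal skeleton path free of junctions
#' (a connected component of the skeleton after junction pixels are
#' removed).
#'
#' @param mask a [binary_mask()].
#' @return List with `skeleton` ([binary_mask()]), `n_branches`,
#'   `n_junctions`.
#' @export
skeleton_stats <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$mask
  if (!any(m)) {
    return(list(skeleton = binary_mask(m, mask$pixel_size,
                                       provenance = list(op = "skeleton")),
                n_branches = 0L, n_junctions = 0L))
  }
  sk <- .thin_zhang_suen(m)
  p <- matrix(FALSE, nrow(sk) + 2L, ncol(sk) + 2L)
  p[2:(nrow(sk) + 1L), 2:(ncol(sk) + 1L)] <- sk
  ri <- 2:(nrow(sk) + 1L); ci <- 2:(ncol(sk) + 1L)
  nb <- p[ri - 1L, ci] + p[ri + 1L, ci] + p[ri, ci - 1L] + p[ri, ci + 1L] +
    p[ri - 1L, ci - 1L] + p[ri - 1L, ci + 1L] +
    p[ri + 1L, ci - 1L] + p[ri + 1L, ci + 1L]
  junction_px <- sk & nb >= 3
  n_junctions <- if (any(junction_px)) max(.label8(junction_px)) else 0L
  rest <- sk & !junction_px
  n_branches <- if (any(rest)) max(.label8(rest)) else 0L
  list(skeleton = binary_mask(sk, mask$pixel_size,
                              provenance = list(op = "skeleton")),
       n_branches = as.integer(n_branches),
       n_junctions = as.integer(n_junctions))
}

#' Label connected components, ImageJ particle-analysis style
#'
#' 8-connected labelling with optional exclusion of components touching the
#' image border ("Exclude on edges") and optional hole filling per
#' component ("Include holes").
#'
#' @param mask a [binary_mask()].
#' @param exclude_edges drop components touching any image border.
#' @param include_holes fill internal holes before measuring.
#' @return List with `labels` (integer matrix), `n`, and `areas_px`
#'   (per-component pixel counts, named by label).
#' @export
analyze_particles <- function(mask, exclude_edges = TRUE, include_holes = TRUE) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$mask
  if (include_holes && any(m)) {
    m <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(m * 1)))) ) > 0.5
  }
  lab <- .label8(m)
  if (exclude_edges && max(lab) > 0L) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border_labels <- border_labels[border_labels > 0L]
    if (length(border_labels)) {
      lab[lab %in% border_labels] <- 0L
      # renumber
      keep <- sort(unique(lab[lab > 0L]))
      lab[] <- match(lab, keep, nomatch = 0L)
    }
  }
  n <- max(lab)
  areas <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  list(labels = lab, n = as.integer(n), areas_px = areas)
}
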