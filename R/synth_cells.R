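#' Multichannel cell-field simulation specification
#'
#' Synthetic registered fluorescence channels with exact ground truth:
#' nuclei are non-overlapping bright disks, marker-positive subsets have
#' exact counts (`round(fraction * n)`), the WGA scar region is rendered as
#' a dense speckle band (membrane-like texture that survives rolling-ball
#' background subtraction), capillaries are disks around their nuclei in
#' the isolectin channel, the MLC-2v cardiomyocyte channel is a filled
#' region covering the cell field, and alpha-SMA vessels are rings of
#' prescribed outer diameter.
#'
#' @param n_nuclei nuclei rendered in the hoechst channel.
#' @param marker_fractions named numeric vector/list in `[0,1]`, e.g.
#'   `c(edu = 0.04)`; each marker channel lights up exactly
#'   `round(fraction * n_nuclei)` nuclei.
#' @param n_capillary_nuclei extra nuclei wrapped in isolectin-positive
#'   disks (rendered in hoechst too).
#' @param capillary_marker_fraction fraction of capillary nuclei positive
#'   for each marker.
#' @param wga_band_fraction fraction of the frame covered by the WGA band
#'   (0 disables the channel).
#' @param vessel_diameters_um outer diameters of alpha-SMA rings (empty =
#'   no asma channel); all are placed inside the WGA band.
#' @param vessel_outside_um diameters of rings placed outside the band.
#' @param pdgfrb_fraction area fraction of the frame covered by the PDGFRb
#'   speckle region (0 disables).
#' @param image_size,pixel_size raster geometry.
#' @param nucleus_radius nucleus disk radius, px.
#' @param noise_sd additive Gaussian noise SD (0 = noiseless, exact truth).
#' @param seed RNG seed.
#' @return Object of class `cell_field_spec`.
#' @export
cell_field_spec <- function(n_nuclei = 100, marker_fractions = c(edu = 0.04),
                            n_capillary_nuclei = 0,
                            capillary_marker_fraction = 0,
                            wga_band_fraction = 0,
                            vessel_diameters_um = numeric(0),
                            vessel_outside_um = numeric(0),
                            pdgfrb_fraction = 0,
                            image_size = 512, pixel_size = 1,
                            nucleus_radius = 4, noise_sd = 0, seed = 1L) {
  mf <- unlist(marker_fractions)
  if (length(mf) && (any(mf < 0) || any(mf > 1)))
    stop("marker fractions must lie in [0, 1]")
  structure(list(n_nuclei = as.integer(n_nuclei), marker_fractions = mf,
                 n_capillary_nuclei = as.integer(n_capillary_nuclei),
                 capillary_marker_fraction = capillary_marker_fraction,
                 wga_band_fraction = wga_band_fraction,
                 vessel_diameters_um = vessel_diameters_um,
                 vessel_outside_um = vessel_outside_um,
                 pdgfrb_fraction = pdgfrb_fraction,
                 image_size = as.integer(image_size), pixel_size = pixel_size,
                 nucleus_radius = nucleus_radius, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cell_field_spec")
}

# stamp a filled disk into a matrix
.stamp_disk <- function(img, cy, cx, r, value) {
  s <- nrow(img)
  rr <- max(1, floor(cy - r)):min(s, ceiling(cy + r))
  cc <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  sub <- outer(rr, cc, function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
  img[rr, cc][sub] <- value
  img
}

# stamp a ring (annulus) with given outer radius and thickness
.stamp_ring <- function(img, cy, cx, r_out, thickness, value) {
  rr <- max(1, floor(cy - r_out)):min(nrow(img), ceiling(cy + r_out))
  cc <- max(1, floor(cx - r_out)):min(ncol(img), ceiling(cx + r_out))
  d2 <- outer(rr, cc, function(i, j) (i - cy)^2 + (j - cx)^2)
  sel <- d2 <= r_out^2 & d2 >= (r_out - thickness)^2
  img[rr, cc][sel] <- value
  img
}

#' Generate a registered multichannel cell field with ground truth
#'
#' Nuclei (and capillary nuclei) are placed by rejection sampling with a
#' minimum centre distance; an explicit error is raised if the requested
#' count cannot fit without overlap. In noiseless mode the ground-truth
#' counts are exact by construction.
#'
#' @param spec a [cell_field_spec()].
#' @return List with `stack` (a [channel_stack()]) and `truth`: nucleus
#'   centres and types, exact per-marker positive counts (split by
#'   cardiomyocyte vs capillary nuclei), WGA band row range and area
#'   fraction, and vessel centres/diameters with their in-band flag.
#' @export
gen_multichannel <- function(spec) {
  stopifnot(inherits(spec, "cell_field_spec"))
  set.seed(spec$seed)
  s <- spec$image_size
  r <- spec$nucleus_radius
  margin <- 3 * r + 4
  n_total <- spec$n_nuclei + spec$n_capillary_nuclei
  min_d <- 2 * r + 5
  # capillary nuclei live in a contiguous band at the bottom of the frame
  # (capillary beds are spatially coherent); cardiomyocyte nuclei occupy
  # the rest, so the isolectin band recipe (median radius 20) can recover
  # the capillary region as a solid mask
  cap_band <- NULL
  if (spec$n_capillary_nuclei > 0) {
    h_cap <- max(round(0.3 * s), 6L * r)
    cap_band <- (s - margin - h_cap + 1L):(s - margin)
  }
  place <- function(n, row_lo, row_hi, cx0, cy0) {
    cx <- cx0; cy <- cy0
    tries <- 0L
    while (length(cx) < length(cx0) + n) {
      tries <- tries + 1L
      if (tries > 500L * max(n, 1L))
        stop(sprintf("cannot place %d nuclei without overlap at this density", n))
      x <- stats::runif(1, margin, s - margin)
      y <- stats::runif(1, row_lo, row_hi)
      if (!length(cx) || min((cx - x)^2 + (cy - y)^2) >= min_d^2) {
        cx <- c(cx, x); cy <- c(cy, y)
      }
    }
    list(cx = cx, cy = cy)
  }
  cm_hi <- if (is.null(cap_band)) s - margin else min(cap_band) - 3 * r
  pos <- place(spec$n_nuclei, margin, cm_hi, numeric(0), numeric(0))
  if (spec$n_capillary_nuclei > 0)
    pos <- place(spec$n_capillary_nuclei, min(cap_band) + 2 * r,
                 max(cap_band) - 2 * r, pos$cx, pos$cy)
  cx <- pos$cx; cy <- pos$cy
  type <- rep(c("cm", "capillary"),
              c(spec$n_nuclei, spec$n_capillary_nuclei))
  hoechst <- matrix(0, s, s)
  for (i in seq_len(n_total)) hoechst <- .stamp_disk(hoechst, cy[i], cx[i], r, 200)
  channels <- list(hoechst = hoechst)

  truth_markers <- list()
  for (mk in names(spec$marker_fractions)) {
    n_pos_cm <- round(spec$marker_fractions[[mk]] * spec$n_nuclei)
    pos_cm <- sample(which(type == "cm"), n_pos_cm)
    n_pos_cap <- round(spec$capillary_marker_fraction * spec$n_capillary_nuclei)
    pos_cap <- if (n_pos_cap > 0) sample(which(type == "capillary"), n_pos_cap) else integer(0)
    ch <- matrix(0, s, s)
    for (i in c(pos_cm, pos_cap)) ch <- .stamp_disk(ch, cy[i], cx[i], r, 200)
    channels[[mk]] <- ch
    truth_markers[[mk]] <- list(positive_cm = n_pos_cm,
                                positive_capillary = n_pos_cap,
                                positive_idx = c(pos_cm, pos_cap))
  }

  # textured (speckled) region renderer: staining texture survives
  # rolling-ball background subtraction, unlike a large flat region
  speckle_region <- function(sel_rows, sel_cols, density) {
    ch <- matrix(0, s, s)
    block <- matrix(60, length(sel_rows), length(sel_cols))
    high <- matrix(stats::runif(length(block)) < density,
                   length(sel_rows), length(sel_cols))
    block[high] <- 200
    ch[sel_rows, sel_cols] <- block
    ch
  }
  if (spec$n_capillary_nuclei > 0) {
    # full-width rendering so the band recipe's large median window does
    # not erode the mask at the left/right frame edges
    channels$isolectin <- speckle_region(cap_band, seq_len(s), 0.95)
    # cardiomyocyte channel: textured region covering the whole frame
    channels$mlc2v <- speckle_region(seq_len(s), seq_len(s), 0.95)
  }
  wga_rows <- NULL
  if (spec$wga_band_fraction > 0) {
    h <- round(spec$wga_band_fraction * s)
    top <- round((s - h) / 2) + 1L
    wga_rows <- top:(top + h - 1L)
    channels$wga <- speckle_region(wga_rows, seq_len(s), 0.9)
  }
  pdgfrb_true_fraction <- NULL
  if (spec$pdgfrb_fraction > 0) {
    h <- round(spec$pdgfrb_fraction * s)
    channels$pdgfrb <- speckle_region(seq_len(s), seq_len(h), 0.95)
    pdgfrb_true_fraction <- sum(channels$pdgfrb == 200) / (s * s)
  }

  vessels <- NULL
  all_d <- c(spec$vessel_diameters_um, spec$vessel_outside_um)
  if (length(all_d)) {
    asma <- matrix(0, s, s)
    in_band <- rep(c(TRUE, FALSE),
                   c(length(spec$vessel_diameters_um), length(spec$vessel_outside_um)))
    vx <- vy <- numeric(length(all_d))
    for (k in seq_along(all_d)) {
      r_out <- all_d[k] / spec$pixel_size / 2
      repeat {
        x <- stats::runif(1, r_out + 4, s - r_out - 4)
        if (in_band[k] && !is.null(wga_rows)) {
          rows_ok <- range(wga_rows)
        } else if (!in_band[k] && !is.null(wga_rows)) {
          # place in the larger clear region above or below the band
          above <- c(1, min(wga_rows) - 1)
          below <- c(max(wga_rows) + 1, s)
          rows_ok <- if (diff(above) >= diff(below)) above else below
        } else {
          rows_ok <- c(1, s)
        }
        y <- stats::runif(1, rows_ok[1] + r_out + 1, rows_ok[2] - r_out - 1)
        if (k == 1 || all((vx[seq_len(k - 1)] - x)^2 + (vy[seq_len(k - 1)] - y)^2 >
                          (2 * max(all_d) / spec$pixel_size)^2)) break
      }
      vx[k] <- x; vy[k] <- y
      asma <- .stamp_ring(asma, y, x, r_out, max(2, r_out / 3), 200)
    }
    channels$asma <- asma
    vessels <- data.frame(x = vx, y = vy, diameter_um = all_d, in_scar = in_band)
  }

  if (spec$noise_sd > 0)
    channels <- lapply(channels, function(ch)
      pmin(pmax(ch + matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s), 0), 255))

  list(stack = channel_stack(channels, spec$pixel_size),
       truth = list(centers = data.frame(x = cx, y = cy, type = type),
                    n_nuclei = spec$n_nuclei,
                    n_capillary = spec$n_capillary_nuclei,
                    markers = truth_markers,
                    wga_rows = wga_rows,
                    wga_fraction = if (is.null(wga_rows)) 0 else length(wga_rows) / s,
                    capillary_band_rows = cap_band,
                    pdgfrb_true_fraction = pdgfrb_true_fraction,
                    vessels = vessels))
}
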