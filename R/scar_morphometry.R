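## HSB gates used throughout the section-level morphometry; the values are
## the published colour-thresholding settings (0-255 HSB convention) and can
## be overridden per call.

#' Default HSB gates for section morphometry
#'
#' `scar`: collagen hue gate (140-200, 10-255, 0-255); `tissue`: expanded
#' hue gate covering the whole stained section (60-255, 10-255, 0-255);
#' `dye`: Evans-blue perfused gate (same hue band as scar, used to detect
#' dye-positive tissue); the four birefringence bins red (1-13), orange
#' (14-25), yellow (26-52) and green (53-110), each with S 10-255 and
#' B 20-255.
#'
#' @return Named list of [hsb_range()] objects.
#' @export
morphometry_gates <- function() {
  list(
    scar = hsb_range(140, 200, 10, 255, 0, 255),
    tissue = hsb_range(60, 255, 10, 255, 0, 255),
    dye = hsb_range(140, 200, 10, 255, 0, 255),
    any_stain = hsb_range(0, 255, 10, 255, 0, 255),
    red = hsb_range(1, 13, 10, 255, 20, 255),
    orange = hsb_range(14, 25, 10, 255, 20, 255),
    yellow = hsb_range(26, 52, 10, 255, 20, 255),
    green = hsb_range(53, 110, 10, 255, 20, 255)
  )
}

#' Scar area fraction of a trichrome section
#'
#' Scar mask = HSB gate (140-200, 10-255, 0-255); tissue mask = expanded
#' gate (60-255, 10-255, 0-255). The fraction is scar area over tissue
#' area, invariant to pixel size.
#'
#' @param section a [section_image()].
#' @param scar_gate,tissue_gate [hsb_range()] gates (published defaults).
#' @return List with `scar_area` (um^2), `tissue_area` (um^2), `fraction`.
#' @export
scar_area_fraction <- function(section,
                               scar_gate = morphometry_gates()$scar,
                               tissue_gate = morphometry_gates()$tissue) {
  scar <- hsb_threshold(section, scar_gate)
  tissue <- hsb_threshold(section, tissue_gate)
  ta <- mask_area(tissue)
  if (ta == 0) stop("tissue area is zero: no pixels inside the tissue gate")
  list(scar_area = mask_area(scar), tissue_area = ta,
       fraction = mask_area(scar) / ta)
}

#' Mean scar fraction over a serial-section stack
#'
#' Unweighted mean of per-level scar fractions; six equally spaced levels
#' from the ligation point down to the apex are the convention.
#'
#' @param stack a [section_stack()] (deviation from 6 levels warned).
#' @param ... passed to [scar_area_fraction()].
#' @return List with `mean_fraction_percent` and `per_level` data.frame.
#' @export
stack_scar_fraction <- function(stack, ...) {
  stopifnot(inherits(stack, "section_stack"))
  if (length(stack$sections) != 6L)
    warning(sprintf("expected 6 levels, got %d", length(stack$sections)))
  per <- lapply(stack$sections, scar_area_fraction, ...)
  fr <- vapply(per, `[[`, numeric(1), "fraction")
  list(mean_fraction_percent = mean(fr) * 100,
       per_level = data.frame(level = stack$level_index,
                              fraction = fr,
                              scar_area = vapply(per, `[[`, numeric(1), "scar_area"),
                              tissue_area = vapply(per, `[[`, numeric(1), "tissue_area")))
}

#' Heart size from the green channel
#'
#' Green channel -> Gaussian blur -> triangle threshold (tissue dark on a
#' bright background) -> largest connected component not touching the image
#' border, holes filled -> area. The blur sigma should be small relative to
#' the section diameter; 50 px (the recipe default) corresponds to
#' high-resolution slide scans.
#'
#' @param section a [section_image()].
#' @param sigma Gaussian blur sigma in pixels.
#' @return List with `area_um2`, `area_px`, and the particle `mask`.
#' @export
heart_size <- function(section, sigma = 50) {
  stopifnot(inherits(section, "section_image"))
  g <- section$rgb[, , 2]
  gb <- gaussian_blur(g, sigma)
  m <- auto_threshold(gb, "triangle", foreground = "dark",
                      pixel_size = section$pixel_size)
  parts <- analyze_particles(m, exclude_edges = TRUE, include_holes = TRUE)
  if (parts$n == 0L)
    stop("no connected component off the image border: section touches the edge or is empty")
  big <- which.max(parts$areas_px)
  area_px <- parts$areas_px[big]
  mask <- binary_mask(parts$labels == big, section$pixel_size,
                      provenance = list(op = "heart_size", sigma = sigma,
                                        threshold = attr(m, "threshold")))
  list(area_um2 = area_px * section$pixel_size^2, area_px = area_px, mask = mask)
}

#' Wall thickness at five points along the scar arc
#'
#' Casts rays from the tissue centroid at `n_points` equally spaced angles
#' across the angular extent of the scar mask and measures the chord length
#' of the tissue mask along each ray.
#'
#' @param tissue_mask,scar_mask aligned [binary_mask()] objects.
#' @param n_points number of measurement rays (5 is the convention).
#' @return Numeric vector of thickness values in micrometres, one per ray.
#' @export
wall_thickness <- function(tissue_mask, scar_mask, n_points = 5) {
  stopifnot(inherits(tissue_mask, "binary_mask"), inherits(scar_mask, "binary_mask"))
  if (!any(scar_mask$mask)) stop("empty scar mask")
  tm <- tissue_mask$mask
  idx_t <- which(tm, arr.ind = TRUE)
  ctr <- colMeans(idx_t)  # (row, col)
  idx_s <- which(scar_mask$mask, arr.ind = TRUE)
  ang <- atan2(idx_s[, 1] - ctr[1], idx_s[, 2] - ctr[2])  # (-pi, pi]
  # angular extent, handling wrap-around: rotate so the largest angular gap
  # between scar pixels sits at the cut point
  sa <- sort(unique(round(ang, 4)))
  if (length(sa) > 1L) {
    gaps <- diff(c(sa, sa[1] + 2 * pi))
    cut <- which.max(gaps)
    lo <- sa[(cut %% length(sa)) + 1L]
    span <- 2 * pi - max(gaps)
  } else {
    lo <- sa[1]; span <- 0
  }
  if (span >= 2 * pi - 1e-6) {
    rays <- seq(0, 2 * pi, length.out = n_points + 1L)[seq_len(n_points)]
  } else {
    rays <- lo + seq(0, span, length.out = n_points)
  }
  rmax <- sqrt(nrow(tm)^2 + ncol(tm)^2)
  step <- 0.25
  vapply(rays, function(a) {
    rr <- seq(0, rmax, by = step)
    pr <- round(ctr[1] + rr * sin(a))
    pc <- round(ctr[2] + rr * cos(a))
    ok <- pr >= 1 & pr <= nrow(tm) & pc >= 1 & pc <= ncol(tm)
    hit <- logical(length(rr))
    hit[ok] <- tm[cbind(pr[ok], pc[ok])]
    sum(hit) * step * tissue_mask$pixel_size
  }, numeric(1))
}

#' Evans-blue infarct (dye-excluded) fraction over a stack
#'
#' Per level, tissue = any stained pixel (saturation gate), perfused = the
#' dye-blue hue gate; the ischemic fraction is `1 - perfused/tissue`. The
#' per-level fractions are averaged (four levels are the convention).
#'
#' @param stack a [section_stack()] of Evans-blue sections.
#' @param dye_gate,tissue_gate [hsb_range()] gates, defaults from
#'   [morphometry_gates()].
#' @return List with `mean_unstained_percent` and `per_level` data.frame.
#' @export
evans_blue_infarct <- function(stack,
                               dye_gate = morphometry_gates()$dye,
                               tissue_gate = morphometry_gates()$any_stain) {
  stopifnot(inherits(stack, "section_stack"))
  if (length(stack$sections) != 4L)
    warning(sprintf("expected 4 levels, got %d", length(stack$sections)))
  fr <- vapply(stack$sections, function(sec) {
    dye <- hsb_threshold(sec, dye_gate)
    tis <- hsb_threshold(sec, tissue_gate)
    nt <- sum(tis$mask)
    if (nt == 0) stop("tissue area is zero on one level")
    1 - sum(dye$mask & tis$mask) / nt
  }, numeric(1))
  list(mean_unstained_percent = mean(fr) * 100,
       per_level = data.frame(level = stack$level_index, unstained_fraction = fr))
}

#' Birefringence hue profile of a polarized-light image
#'
#' Subtracts the mean background value from all channels (math-subtract),
#' then bins ROI pixels into the four published hue gates (red, orange,
#' yellow, green). Total birefringence is the sum of the four bins, set to
#' 100%.
#'
#' @param image a [section_image()] (polarized-light RGB).
#' @param scar_roi a [binary_mask()] restricting the analysis; NULL = whole
#'   frame.
#' @param background_value mean background pixel value to subtract (0-255).
#' @param gates list of the four [hsb_range()] bins.
#' @return List of class `hue_birefringence_profile` with
#'   `fractions_percent` (named, sums to 100) and `pixel_counts`.
#' @export
birefringence_hue_fractions <- function(image, scar_roi = NULL,
                                        background_value = 0,
                                        gates = morphometry_gates()[c("red", "orange", "yellow", "green")]) {
  stopifnot(inherits(image, "section_image"))
  rgb <- pmax(image$rgb - background_value, 0)
  img <- section_image(rgb, image$pixel_size)
  roi <- if (is.null(scar_roi)) matrix(TRUE, dim(rgb)[1], dim(rgb)[2]) else scar_roi$mask
  if (!any(roi)) stop("empty ROI")
  counts <- vapply(gates, function(g) sum(hsb_threshold(img, g)$mask & roi), numeric(1))
  total <- sum(counts)
  if (total == 0)
    stop("zero total birefringent signal inside the ROI: fractions undefined")
  structure(list(fractions_percent = counts / total * 100,
                 pixel_counts = counts),
            class = "hue_birefringence_profile")
}
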