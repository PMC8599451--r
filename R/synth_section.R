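#' Section simulation specification
#'
#' Parameters of a synthetic stained transversal section: a tissue disk on
#' a white background in which a wedge-shaped region of a prescribed area
#' fraction carries the "scar" hue (trichrome mode: collagen blue against
#' muscle red/brown) or the dye-excluded hue (Evans-blue mode: pale
#' ischemic region against perfused blue tissue). Hues follow the 0-255
#' ImageJ HSB convention.
#'
#' @param image_size side of the square raster, px.
#' @param pixel_size micrometres per pixel.
#' @param scar_fraction_target fraction of tissue area carrying the scar
#'   (or ischemic) hue, in `[0, 1]`.
#' @param scar_hue hue centre for the scar pixels (within the 140-200 scar
#'   gate for trichrome mode).
#' @param tissue_hue hue centre for the remaining tissue (within 60-139).
#' @param hue_jitter half-width of uniform hue jitter; jittered hues are
#'   clipped so scar pixels stay within 140-200 and tissue pixels within
#'   60-139.
#' @param disk_radius_px tissue disk radius; default 42% of the image side.
#' @param seed integer RNG seed.
#' @return Object of class `section_sim_spec`.
#' @export
section_sim_spec <- function(image_size = 512, pixel_size = 5,
                             scar_fraction_target = 0.3,
                             scar_hue = 170, tissue_hue = 100,
                             hue_jitter = 0, disk_radius_px = NULL,
                             seed = 1L) {
  if (scar_fraction_target < 0 || scar_fraction_target > 1)
    stop("'scar_fraction_target' must lie in [0, 1]")
  if (scar_hue < 140 || scar_hue > 200) stop("'scar_hue' must lie in 140-200")
  if (tissue_hue < 60 || tissue_hue > 139) stop("'tissue_hue' must lie in 60-139")
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 scar_fraction_target = scar_fraction_target,
                 scar_hue = scar_hue, tissue_hue = tissue_hue,
                 hue_jitter = hue_jitter,
                 disk_radius_px = disk_radius_px %||% round(0.42 * image_size),
                 seed = as.integer(seed)),
            class = "section_sim_spec")
}

#' Generate a synthetic stained section with known scar fraction
#'
#' The tissue is a centred disk; the scar is the angular wedge whose area
#' fraction equals the target (exact up to rasterization). In
#' `"trichrome"` mode scar pixels carry `scar_hue` (blue-range) and tissue
#' pixels `tissue_hue`; in `"evans"` mode the wedge is the dye-excluded
#' (ischemic) region rendered at a pale red-orange hue (25) while the
#' perfused remainder carries the dye-blue `scar_hue`. The background is
#' white (saturation 0), outside every gate.
#'
#' @param spec a [section_sim_spec()].
#' @param mode `"trichrome"` or `"evans"`.
#' @return List with `image` (a [section_image()]), `true_scar_fraction`
#'   (rendered wedge pixels / tissue pixels), `true_tissue_area` (um^2)
#'   and `true_tissue_px`.
#' @export
gen_section <- function(spec, mode = c("trichrome", "evans")) {
  stopifnot(inherits(spec, "section_sim_spec"))
  mode <- match.arg(mode)
  s <- spec$image_size
  r <- spec$disk_radius_px
  ctr <- (s + 1) / 2
  set.seed(spec$seed)
  x <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  y <- matrix(rep(seq_len(s), times = s), s, s)  # row index
  inside <- (x - ctr)^2 + (y - ctr)^2 <= r^2
  theta <- atan2(y - ctr, x - ctr)               # (-pi, pi]
  wedge <- inside & (theta + pi) <= spec$scar_fraction_target * 2 * pi
  if (spec$scar_fraction_target == 0) wedge[] <- FALSE
  n_t <- sum(inside)
  # clip one hue unit inside the gate so 8-bit RGB round-trip quantization
  # cannot push a pixel across a gate boundary
  jit <- function(center, n, lo, hi) {
    h <- center + stats::runif(n, -spec$hue_jitter, spec$hue_jitter)
    pmin(pmax(h, lo + 1), hi - 1)
  }
  rgb <- array(255, dim = c(s, s, 3))
  paint <- function(rgb, sel, hue_lo, hue_hi, center, sat = 180, bright = 200) {
    n <- sum(sel)
    if (!n) return(rgb)
    cols <- .hsb255_to_rgb(jit(center, n, hue_lo, hue_hi), rep(sat, n), rep(bright, n))
    for (k in 1:3) { ch <- rgb[, , k]; ch[sel] <- cols[, k]; rgb[, , k] <- ch }
    rgb
  }
  if (mode == "trichrome") {
    rgb <- paint(rgb, inside & !wedge, 60, 139, spec$tissue_hue)
    rgb <- paint(rgb, wedge, 140, 200, spec$scar_hue)
  } else {
    rgb <- paint(rgb, inside & !wedge, 140, 200, spec$scar_hue)  # perfused, dye blue
    rgb <- paint(rgb, wedge, 15, 35, 25)                         # ischemic, pale red
  }
  list(image = section_image(rgb, spec$pixel_size),
       true_scar_fraction = sum(wedge) / n_t,
       true_tissue_area = n_t * spec$pixel_size^2,
       true_tissue_px = n_t)
}

#' Stack of serial sections
#'
#' Ordered list of [section_image()] levels with uniform pixel size;
#' six levels are the convention for trichrome scar/heart-size analysis
#' and four for Evans-blue infarct analysis.
#'
#' @param sections list of [section_image()].
#' @param level_index optional ordering index (default 1..n).
#' @return Object of class `section_stack`.
#' @export
section_stack <- function(sections, level_index = NULL) {
  if (!length(sections)) stop("empty section stack")
  if (!all(vapply(sections, inherits, logical(1), "section_image")))
    stop("all elements must be section_image objects")
  ps <- vapply(sections, function(x) x$pixel_size, numeric(1))
  if (length(unique(ps)) != 1L) stop("pixel_size must be uniform within a stack")
  li <- level_index %||% seq_along(sections)
  if (is.unsorted(li, strictly = TRUE)) stop("levels must be strictly ordered")
  structure(list(sections = sections, level_index = li),
            class = "section_stack")
}
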