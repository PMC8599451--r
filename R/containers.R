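#' Section image container
#'
#' A colour raster of a histological section together with its physical pixel
#' size. Pixel data are stored as an `nrow x ncol x 3` array of 8-bit channel
#' values (0-255), row index = image y, column index = image x.
#'
#' @param rgb numeric array `h x w x 3` with values in `[0, 255]`, or an
#'   `h x w` matrix which is replicated across the three channels.
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#' @return An object of class `section_image` with elements `rgb` and
#'   `pixel_size`.
#' @export
section_image <- function(rgb, pixel_size) {
  if (is.matrix(rgb)) rgb <- array(rep(rgb, 3L), dim = c(dim(rgb), 3L))
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/px)")
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("channel values must lie in [0, 255]")
  structure(list(rgb = rgb, pixel_size = pixel_size), class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, %.4g um/px\n",
              dim(x$rgb)[1], dim(x$rgb)[2], x$pixel_size))
  invisible(x)
}

#' Binary mask container
#'
#' A boolean raster with physical pixel size and a provenance record of the
#' operation (and parameters) that produced it, so every derived measurement
#' can be replayed.
#'
#' @param mask logical matrix.
#' @param pixel_size micrometres per pixel.
#' @param provenance named list describing the producing operation.
#' @return Object of class `binary_mask` with elements `mask`, `pixel_size`,
#'   `provenance`.
#' @export
binary_mask <- function(mask, pixel_size = 1, provenance = list()) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, pixel_size = pixel_size, provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px (%.1f%%), op: %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask),
              if (length(x$provenance)) x$provenance$op %||% "?" else "?"))
  invisible(x)
}

#' Mask area in square micrometres
#' @param x a `binary_mask`.
#' @return Foreground area, `pixel count * pixel_size^2` (um^2).
#' @export
mask_area <- function(x) {
  stopifnot(inherits(x, "binary_mask"))
  sum(x$mask) * x$pixel_size^2
}

#' HSB range gate (0-255 convention)
#'
#' Hue, saturation and brightness bounds on the 8-bit 0-255 scale used by
#' ImageJ-style colour thresholding. Bounds are inclusive. Hue is treated as
#' circular only when `hue_min > hue_max` (wrap-around gate).
#'
#' @param hue_min,hue_max,sat_min,sat_max,bright_min,bright_max integers in
#'   `[0, 255]`.
#' @return Object of class `hsb_range`.
#' @export
hsb_range <- function(hue_min, hue_max, sat_min = 0, sat_max = 255,
                      bright_min = 0, bright_max = 255) {
  v <- c(hue_min, hue_max, sat_min, sat_max, bright_min, bright_max)
  if (any(v < 0 | v > 255)) stop("all HSB bounds must lie in [0, 255]")
  if (sat_min > sat_max) stop("sat_min > sat_max")
  if (bright_min > bright_max) stop("bright_min > bright_max")
  structure(list(hue_min = hue_min, hue_max = hue_max,
                 sat_min = sat_min, sat_max = sat_max,
                 bright_min = bright_min, bright_max = bright_max),
            class = "hsb_range")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- internal raster helpers -------------------------------------------

# matrix [row, col] 0-255  ->  EBImage Image (x = col-major transposed, 0-1)
.as_ebi <- function(m) EBImage::Image(t(m) / 255)

.from_ebi <- function(img) t(EBImage::imageData(img)) * 255

# RGB array (h x w x 3, 0-255) -> list of H, S, B matrices on the continuous
# 0-255 scale (rounded to nearest integer, matching 8-bit HSB conversion).
.rgb_to_hsb255 <- function(rgb) {
  d <- dim(rgb)
  m <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(h = matrix(round(hsv[1, ] * 255), d[1], d[2]),
       s = matrix(round(hsv[2, ] * 255), d[1], d[2]),
       b = matrix(round(hsv[3, ] * 255), d[1], d[2]))
}

# H, S, B vectors on 0-255 scale -> n x 3 matrix of 8-bit RGB values
.hsb255_to_rgb <- function(h, s, b) {
  cols <- grDevices::hsv(pmin(pmax(h, 0), 255) / 255,
                         pmin(pmax(s, 0), 255) / 255,
                         pmin(pmax(b, 0), 255) / 255)
  t(grDevices::col2rgb(cols))
}

# 8-connected labelling of a logical matrix (ImageJ particle semantics).
# Returns an integer matrix, 0 = background, components numbered 1..n.
.label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  nc <- ncol(mask)
  lookup <- integer(nr * nc)
  lookup[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  neigh <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))  # S, E, SE, NE
  for (k in seq_along(neigh)) {
    dr <- neigh[[k]][1]; dc <- neigh[[k]][2]
    ok <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    nb <- idx[ok] + dr + dc * nr
    hit <- lookup[nb] > 0L
    if (any(hit))
      edges[[k]] <- rbind(lookup[idx[ok]][hit], lookup[nb[hit]])
  }
  ev <- as.integer(unlist(edges))
  g <- igraph::make_graph(ev, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Per-component pixel index list for a label matrix
.component_pixels <- function(lab) {
  idx <- which(lab > 0L)
  split(idx, lab[idx])
}
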