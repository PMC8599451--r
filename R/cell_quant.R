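#' Registered multichannel fluorescence stack
#'
#' Named channels (e.g. hoechst, edu, phh3, wga, isolectin, mlc2v, asma,
#' pdgfrb, erg) as aligned rasters with a common pixel size.
#'
#' @param channels named list of numeric matrices (0-255), identical
#'   shapes, unique names.
#' @param pixel_size micrometres per pixel.
#' @return Object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size = 1) {
  if (!length(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a non-empty named list")
  if (anyDuplicated(names(channels))) stop("channel names must be unique")
  dims <- vapply(channels, function(ch) paste(dim(ch), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) stop("all channels must have the same shape")
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %s px, %.3g um/px, channels: %s\n",
              paste(dim(x$channels[[1]]), collapse = " x "), x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

.get_channel <- function(stack, name) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!name %in% names(stack$channels))
    stop(sprintf("channel '%s' is missing from the stack", name))
  stack$channels[[name]]
}

# threshold a channel, mapping a degenerate (blank/constant) histogram to
# an empty mask rather than an error, for marker channels that may
# legitimately carry no signal
.threshold_or_empty <- function(image, method, pixel_size = 1) {
  tryCatch(auto_threshold(image, method, pixel_size = pixel_size),
           error = function(e) {
             if (grepl("degenerate histogram", conditionMessage(e)))
               binary_mask(matrix(FALSE, nrow(image), ncol(image)), pixel_size,
                           provenance = list(op = "auto_threshold",
                                             method = method, degenerate = TRUE))
             else stop(e)
           })
}

#' Count nuclei in a fluorescence channel
#'
#' Published recipe: rolling-ball background subtraction (radius 50) ->
#' median filter (radius 1) -> automatic threshold ("default_isodata" for
#' Hoechst, "yen" for EdU) -> particle analysis excluding border-touching
#' components, holes included.
#'
#' @param channel numeric matrix (0-255).
#' @param method threshold method identifier.
#' @param pixel_size micrometres per pixel.
#' @return List with `count`, `labels` (integer component matrix) and
#'   `provenance`.
#' @export
count_nuclei <- function(channel, method = "default_isodata", pixel_size = 1) {
  stopifnot(is.matrix(channel))
  prov <- list(op = "count_nuclei", rolling_ball = 50, median_radius = 1,
               method = method)
  if (max(channel) == min(channel))
    return(list(count = 0L, labels = matrix(0L, nrow(channel), ncol(channel)),
                provenance = prov))
  x <- rolling_ball_subtract(channel, 50)
  x <- median_filter(x, 1)
  m <- .threshold_or_empty(x, method, pixel_size)
  parts <- analyze_particles(m, exclude_edges = TRUE, include_holes = TRUE)
  list(count = parts$n, labels = parts$labels, provenance = prov)
}

#' Scar region of interest from the WGA channel
#'
#' Published recipe: rolling-ball (radius 50) -> median filter with the
#' larger radius 20 -> Yen threshold.
#'
#' @param wga_channel numeric matrix.
#' @param pixel_size micrometres per pixel.
#' @return A [binary_mask()] of the scar ROI.
#' @export
scar_roi <- function(wga_channel, pixel_size = 1) {
  stopifnot(is.matrix(wga_channel))
  x <- rolling_ball_subtract(wga_channel, 50)
  x <- median_filter(x, 20)
  m <- auto_threshold(x, "yen", pixel_size = pixel_size)
  m$provenance <- list(op = "scar_roi", rolling_ball = 50, median_radius = 20,
                       method = "yen", threshold = m$provenance$threshold)
  m
}

# centroids (row, col) of labelled components
.centroids <- function(labels) {
  idx <- which(labels > 0L, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(numeric(0), 0, 2))
  cbind(tapply(idx[, 1], labels[labels > 0L], mean),
        tapply(idx[, 2], labels[labels > 0L], mean))
}

#' Marker-positive nucleus fraction inside an ROI
#'
#' Counts nuclei whose component centroid lies in the ROI; a nucleus is
#' marker-positive iff its component overlaps the thresholded marker mask
#' by at least one pixel.
#'
#' @param nuclei_channel,marker_channel aligned matrices.
#' @param roi a [binary_mask()].
#' @param nuclei_method,marker_method threshold identifiers (Hoechst:
#'   default_isodata; EdU: yen).
#' @param exclude optional [binary_mask()]; nuclei whose centroid falls in
#'   it, or positives overlapping it, are excluded (capillary exclusion).
#' @param pixel_size micrometres per pixel.
#' @return List of class `count_result`: `total_nuclei`,
#'   `positive_nuclei`, `fraction_percent`, `roi_area_um2`, `provenance`.
#' @export
positive_fraction_in_roi <- function(nuclei_channel, marker_channel, roi,
                                     nuclei_method = "default_isodata",
                                     marker_method = "yen",
                                     exclude = NULL, pixel_size = 1) {
  stopifnot(inherits(roi, "binary_mask"))
  if (!any(roi$mask)) stop("empty ROI")
  nuc <- count_nuclei(nuclei_channel, nuclei_method, pixel_size)
  marker_mask <- if (max(marker_channel) == min(marker_channel)) {
    matrix(FALSE, nrow(marker_channel), ncol(marker_channel))
  } else {
    x <- rolling_ball_subtract(marker_channel, 50)
    x <- median_filter(x, 1)
    .threshold_or_empty(x, marker_method, pixel_size)$mask
  }
  lab <- nuc$labels
  n <- max(lab)
  total <- 0L; positive <- 0L
  if (n > 0L) {
    cent <- .centroids(lab)
    in_roi <- roi$mask[cbind(pmin(pmax(round(cent[, 1]), 1), nrow(roi$mask)),
                             pmin(pmax(round(cent[, 2]), 1), ncol(roi$mask)))]
    in_excl <- if (!is.null(exclude))
      exclude$mask[cbind(pmin(pmax(round(cent[, 1]), 1), nrow(lab)),
                         pmin(pmax(round(cent[, 2]), 1), ncol(lab)))]
    else rep(FALSE, n)
    keep <- in_roi & !in_excl
    total <- sum(keep)
    pos_overlap <- vapply(seq_len(n), function(k) {
      px <- lab == k
      any(marker_mask[px]) && (is.null(exclude) || !any(exclude$mask[px]))
    }, logical(1))
    positive <- sum(keep & pos_overlap)
  }
  structure(list(total_nuclei = as.integer(total),
                 positive_nuclei = as.integer(positive),
                 fraction_percent = if (total > 0) positive / total * 100 else 0,
                 roi_area_um2 = mask_area(roi),
                 provenance = list(op = "positive_fraction_in_roi",
                                   nuclei_method = nuclei_method,
                                   marker_method = marker_method,
                                   excluded = !is.null(exclude))),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d / %d positive (%.2f%%), ROI %.3g um^2\n",
              x$positive_nuclei, x$total_nuclei, x$fraction_percent,
              x$roi_area_um2))
  invisible(x)
}

#' Dividing-cardiomyocyte fraction
#'
#' The MLC-2v segment (rolling-ball 50, median 1, iterative-intermeans
#' threshold) minus the capillary mask (isolectin: rolling-ball 5, median
#' 20, iterative-intermeans) defines the cardiomyocyte region; nuclei
#' inside it are counted, and a nucleus is scored positive iff it overlaps
#' the EdU or pHH3 mask but not the isolectin mask.
#'
#' @param stack a [channel_stack()] with `mlc2v`, `isolectin`, `hoechst`
#'   and the marker channel.
#' @param marker `"edu"` or `"phh3"`.
#' @return A `count_result` (see [positive_fraction_in_roi()]).
#' @export
cm_proliferation <- function(stack, marker = c("edu", "phh3")) {
  marker <- match.arg(marker)
  mlc <- .get_channel(stack, "mlc2v")
  iso <- .get_channel(stack, "isolectin")
  hoe <- .get_channel(stack, "hoechst")
  mk <- .get_channel(stack, marker)
  ps <- stack$pixel_size
  x <- median_filter(rolling_ball_subtract(mlc, 50), 1)
  mlc_mask <- .threshold_or_empty(x, "default_isodata", ps)
  x <- median_filter(rolling_ball_subtract(iso, 5), 20)
  iso_mask <- .threshold_or_empty(x, "default_isodata", ps)
  cm_region <- binary_mask(mlc_mask$mask & !iso_mask$mask, ps,
                           provenance = list(op = "cm_region",
                                             mlc2v = mlc_mask$provenance,
                                             isolectin = iso_mask$provenance))
  if (!any(cm_region$mask)) stop("cardiomyocyte region is empty")
  positive_fraction_in_roi(hoe, mk, cm_region,
                           nuclei_method = "default_isodata",
                           marker_method = "yen",
                           exclude = iso_mask, pixel_size = ps)
}

# maximum Feret diameter of a pixel set, in pixels (pixel extent included)
.max_feret_px <- function(idx) {
  if (nrow(idx) == 1L) return(1)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  pts <- idx[hull, , drop = FALSE]
  d2 <- 0
  for (i in seq_len(nrow(pts))) {
    dd <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    d2 <- max(d2, max(dd))
  }
  sqrt(d2) + 1
}

#' Count arteries with a minimum-diameter gate
#'
#' Alpha-SMA-positive components are measured by their maximum Feret
#' diameter; vessels below `min_diameter_um` are excluded (to avoid
#' alpha-SMA-positive mesenchyme), as are vessels whose centroid lies
#' outside the WGA-defined scar ROI.
#'
#' @param stack a [channel_stack()] with `asma` and `wga` channels.
#' @param min_diameter_um diameter gate in micrometres (10 is the
#'   convention).
#' @param min_area_px discard specks below this component area.
#' @return List with `count`, `vessels` data.frame (centroid, diameter,
#'   in_scar, retained), and `count_per_scar_mm2`.
#' @export
count_arteries <- function(stack, min_diameter_um = 10, min_area_px = 9) {
  asma <- .get_channel(stack, "asma")
  wga <- .get_channel(stack, "wga")
  ps <- stack$pixel_size
  if (is.null(ps) || !is.finite(ps)) stop("pixel size is required")
  roi <- scar_roi(wga, ps)
  m <- .threshold_or_empty(asma, "default_isodata", ps)
  lab <- .label8(m$mask)
  n <- max(lab)
  if (n == 0L)
    return(list(count = 0L, vessels = NULL,
                count_per_scar_mm2 = 0))
  rows <- lapply(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) return(NULL)
    feret <- .max_feret_px(idx) * ps
    ctr <- colMeans(idx)
    inside <- roi$mask[round(ctr[1]), round(ctr[2])]
    data.frame(y = ctr[1], x = ctr[2], max_diameter_um = feret,
               inside_scar = inside,
               retained = inside && feret >= min_diameter_um)
  })
  vessels <- do.call(rbind, rows)
  scar_mm2 <- mask_area(roi) / 1e6
  cnt <- if (is.null(vessels)) 0L else sum(vessels$retained)
  list(count = as.integer(cnt), vessels = vessels,
       count_per_scar_mm2 = if (scar_mm2 > 0) cnt / scar_mm2 else NA_real_)
}

#' Channel coverage fraction inside an ROI
#'
#' Published recipe for fibroblast (PDGFRb) and capillary (isolectin)
#' coverage: rolling-ball (radius 50) -> automatic threshold (Moments) ->
#' positive area / ROI area x 100.
#'
#' @param channel numeric matrix.
#' @param roi a [binary_mask()].
#' @param method threshold identifier (moments is the published choice).
#' @return Coverage in percent.
#' @export
coverage_fraction <- function(channel, roi, method = "moments") {
  stopifnot(is.matrix(channel), inherits(roi, "binary_mask"))
  if (!any(roi$mask)) stop("empty ROI")
  if (max(channel) == min(channel)) return(0)
  x <- rolling_ball_subtract(channel, 50)
  m <- .threshold_or_empty(x, method)
  sum(m$mask & roi$mask) / sum(roi$mask) * 100
}

#' Cardiomyocyte surface area
#'
#' Width times length of an isolated cell, both in micrometres.
#'
#' @param width,length cell dimensions, um (> 0).
#' @return Surface area in um^2.
#' @export
cm_surface_area <- function(width, length) {
  if (any(width <= 0) || any(length <= 0))
    stop("'width' and 'length' must be > 0")
  width * length
}
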