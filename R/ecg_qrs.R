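#' ECG trace container
#'
#' Uniformly sampled voltage series in millivolts.
#'
#' @param voltage numeric vector, mV; finite values.
#' @param sampling_rate Hz.
#' @param start_time seconds (offset of the first sample).
#' @return Object of class `ecg_trace`.
#' @export
ecg_trace <- function(voltage, sampling_rate, start_time = 0) {
  if (!length(voltage)) stop("'voltage' must be non-empty")
  if (any(!is.finite(voltage))) stop("'voltage' must be finite")
  if (sampling_rate <= 0) stop("'sampling_rate' must be > 0")
  structure(list(voltage = as.numeric(voltage),
                 sampling_rate = sampling_rate,
                 start_time = start_time),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$voltage), x$sampling_rate,
              length(x$voltage) / x$sampling_rate))
  invisible(x)
}

#' Read an ECG trace from CSV
#'
#' Expects a header with columns `time_s` and `voltage_mV`; the sampling
#' rate is inferred from the median time step.
#'
#' @param path CSV file path.
#' @return An [ecg_trace()].
#' @export
read_ecg_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "voltage_mV") %in% names(d)))
    stop("ECG CSV must have columns 'time_s' and 'voltage_mV'")
  dt <- stats::median(diff(d$time_s))
  ecg_trace(d$voltage_mV, sampling_rate = 1 / dt, start_time = d$time_s[1])
}

#' Write an ECG trace to CSV
#' @param trace an [ecg_trace()].
#' @param path output file.
#' @export
write_ecg_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ecg_trace"))
  t <- trace$start_time + (seq_along(trace$voltage) - 1) / trace$sampling_rate
  utils::write.csv(data.frame(time_s = t, voltage_mV = trace$voltage),
                   path, row.names = FALSE)
  invisible(path)
}

#' Estimate the isoelectric baseline of an ECG trace
#'
#' Estimates the electrically neutral reference level between cardiac
#' cycles robustly: when R peaks are supplied, the median of per-beat
#' inter-QRS segment medians (middle half of each RR interval); otherwise
#' the global median of the trace.
#'
#' @param trace an [ecg_trace()].
#' @param r_peaks optional integer vector of R-peak sample indices.
#' @return Baseline level in mV.
#' @export
estimate_baseline <- function(trace, r_peaks = NULL) {
  stopifnot(inherits(trace, "ecg_trace"))
  v <- trace$voltage
  if (is.null(r_peaks) || length(r_peaks) < 2L) return(stats::median(v))
  meds <- vapply(seq_len(length(r_peaks) - 1L), function(i) {
    a <- r_peaks[i]; b <- r_peaks[i + 1L]
    lo <- a + round(0.3 * (b - a)); hi <- a + round(0.7 * (b - a))
    stats::median(v[lo:hi])
  }, numeric(1))
  stats::median(meds)
}

#' Detect R peaks
#'
#' Energy-based detection with an adaptive threshold (Pan-Tompkins style
#' architecture with a matched-filter feature suited to narrow murine QRS
#' complexes): the trace is detrended with a running median, smoothed with
#' a short moving average on the QRS time scale, and squared; peaks of this
#' energy signal above an adaptive threshold, separated by a refractory
#' period, are refined to the local maximum of the detrended voltage.
#'
#' @param trace an [ecg_trace()]; sampling rate must be >= 250 Hz.
#' @param refractory_ms minimum separation between detections, ms.
#' @param detrend_ms running-median window for baseline removal, ms.
#' @param integrate_ms moving-average window before squaring, ms.
#' @param threshold_frac feature threshold as a fraction of the median of
#'   the strongest candidate peaks.
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (possibly empty).
#' @export
detect_r_peaks <- function(trace, refractory_ms = 40, detrend_ms = 200,
                           integrate_ms = 4, threshold_frac = 0.3) {
  stopifnot(inherits(trace, "ecg_trace"))
  fs <- trace$sampling_rate
  if (fs < 250) stop("sampling_rate must be >= 250 Hz for QRS detection")
  v <- trace$voltage
  k <- max(3L, round(detrend_ms / 1000 * fs))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(v) %% 2L == 0L) length(v) - 1L else length(v))
  det <- v - stats::runmed(v, k)
  if (max(abs(det)) == 0) return(integer(0))
  wi <- max(1L, round(integrate_ms / 1000 * fs))
  sm <- as.numeric(stats::filter(det, rep(1 / wi, wi), sides = 2))
  sm[is.na(sm)] <- 0
  f <- sm^2
  refr <- max(1L, round(refractory_ms / 1000 * fs))
  # candidate local maxima of the integrated feature
  cand <- which(f > c(-Inf, f[-length(f)]) & f >= c(f[-1], -Inf))
  if (!length(cand)) return(integer(0))
  # adaptive threshold: a fraction of the median of the strongest candidates
  top <- sort(f[cand], decreasing = TRUE)
  n_top <- max(3L, min(length(top), round(length(v) / fs)))  # ~1 beat/s floor
  thr <- threshold_frac * stats::median(top[seq_len(n_top)])
  cand <- cand[f[cand] >= thr]
  if (!length(cand)) return(integer(0))
  # enforce refractory period, keeping the stronger feature peak
  cand <- cand[order(f[cand], decreasing = TRUE)]
  keep <- logical(0)
  sel <- integer(0)
  for (i in cand) {
    if (!length(sel) || all(abs(sel - i) > refr)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  # refine each detection to the local voltage maximum nearby
  half <- refr
  peaks <- vapply(sel, function(i) {
    lo <- max(1L, i - half); hi <- min(length(v), i + half)
    as.integer(lo + which.max(det[lo:hi]) - 1L)
  }, integer(1))
  sort(unique(peaks))
}

# walk outward from a wave peak until |v - baseline| drops below
# frac * |peak - baseline|; returns the last sample still above the
# criterion (tie-break toward the peak).
.wave_edges <- function(v, peak, baseline, frac, lo_limit, hi_limit) {
  amp <- v[peak] - baseline
  thr <- abs(amp) * frac
  i <- peak
  while (i - 1L >= lo_limit && abs(v[i - 1L] - baseline) >= thr) i <- i - 1L
  j <- peak
  while (j + 1L <= hi_limit && abs(v[j + 1L] - baseline) >= thr) j <- j + 1L
  c(onset = i, offset = j)
}

#' Segment QRS complexes around detected R peaks
#'
#' For each R peak, Q is the most negative extremum in a window before R
#' and S the most negative extremum in a window after R. Amplitudes are
#' signed and relative to the isoelectric baseline; onset/offset of each
#' wave are located where the waveform re-crosses baseline +/- 5% of that
#' wave's peak amplitude, and duration is `(offset - onset) / fs * 1000` ms.
#' Beats whose windows cross the trace boundary are skipped with a warning.
#'
#' @param trace an [ecg_trace()].
#' @param r_peaks integer vector from [detect_r_peaks()].
#' @param window_ms Q/S search window before/after R, ms.
#' @param edge_frac baseline re-crossing fraction of peak amplitude.
#' @param baseline optional precomputed baseline (mV); default
#'   [estimate_baseline()] with the given peaks.
#' @return data.frame of class `qrs_complexes`, one row per retained beat:
#'   per-wave peak index, amplitude (mV), onset/offset indices and duration
#'   (ms), plus `baseline_level`.
#' @export
segment_qrs <- function(trace, r_peaks, window_ms = 50, edge_frac = .qrs_edge_frac,
                        baseline = NULL) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (!length(r_peaks)) stop("no R peaks supplied")
  fs <- trace$sampling_rate
  v <- trace$voltage
  w <- max(1L, round(window_ms / 1000 * fs))
  if (is.null(baseline)) baseline <- estimate_baseline(trace, r_peaks)
  rows <- list()
  skipped <- 0L
  for (r in r_peaks) {
    if (r - w < 1L || r + w > length(v)) { skipped <- skipped + 1L; next }
    qi <- (r - w) + which.min(v[(r - w):(r - 1L)]) - 1L
    si <- r + which.min(v[(r + 1L):(r + w)])
    lo <- max(1L, r - 2L * w); hi <- min(length(v), r + 2L * w)
    qe <- .wave_edges(v, qi, baseline, edge_frac, lo, r)
    re <- .wave_edges(v, r, baseline, edge_frac, lo, hi)
    se <- .wave_edges(v, si, baseline, edge_frac, r, hi)
    rows[[length(rows) + 1L]] <- data.frame(
      r_index = r, r_amp = v[r] - baseline,
      r_onset = re[["onset"]], r_offset = re[["offset"]],
      r_duration_ms = (re[["offset"]] - re[["onset"]]) / fs * 1000,
      q_index = qi, q_amp = v[qi] - baseline,
      q_onset = qe[["onset"]], q_offset = qe[["offset"]],
      q_duration_ms = (qe[["offset"]] - qe[["onset"]]) / fs * 1000,
      s_index = si, s_amp = v[si] - baseline,
      s_onset = se[["onset"]], s_offset = se[["offset"]],
      s_duration_ms = (se[["offset"]] - se[["onset"]]) / fs * 1000,
      baseline_level = baseline
    )
  }
  if (skipped > 0L)
    warning(sprintf("%d beat(s) too close to the trace boundary were skipped", skipped))
  if (!length(rows)) stop("no beats could be segmented")
  out <- do.call(rbind, rows)
  class(out) <- c("qrs_complexes", "data.frame")
  attr(out, "sampling_rate") <- fs
  out
}

#' Summarize QRS complexes over beats
#'
#' @param complexes a `qrs_complexes` data.frame from [segment_qrs()].
#' @return List of class `qrs_summary`: per-wave mean/SD of amplitude (mV)
#'   and duration (ms), `n_beats`, and `heart_rate_bpm` derived from the
#'   mean RR interval (NA with fewer than 2 beats).
#' @export
summarize_qrs <- function(complexes) {
  if (!inherits(complexes, "qrs_complexes") || !nrow(complexes))
    stop("'complexes' must be a non-empty qrs_complexes table")
  fs <- attr(complexes, "sampling_rate")
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  waves <- c("q", "r", "s")
  amp_mean <- vapply(waves, function(w) mean(complexes[[paste0(w, "_amp")]]), numeric(1))
  amp_sd <- vapply(waves, function(w) sd0(complexes[[paste0(w, "_amp")]]), numeric(1))
  dur_mean <- vapply(waves, function(w) mean(complexes[[paste0(w, "_duration_ms")]]), numeric(1))
  dur_sd <- vapply(waves, function(w) sd0(complexes[[paste0(w, "_duration_ms")]]), numeric(1))
  hr <- NA_real_
  if (nrow(complexes) >= 2L) {
    rr <- mean(diff(complexes$r_index)) / fs
    hr <- 60 / rr
  }
  structure(list(amplitude_mean_mV = amp_mean, amplitude_sd_mV = amp_sd,
                 duration_mean_ms = dur_mean, duration_sd_ms = dur_sd,
                 n_beats = nrow(complexes), heart_rate_bpm = hr),
            class = "qrs_summary")
}

#' @export
print.qrs_summary <- function(x, ...) {
  cat(sprintf("<qrs_summary> %d beats, heart rate %.1f bpm\n", x$n_beats,
              x$heart_rate_bpm))
  for (w in c("q", "r", "s"))
    cat(sprintf("  %s: amplitude %+.3f +/- %.3f mV, duration %.2f +/- %.2f ms\n",
                toupper(w), x$amplitude_mean_mV[[w]], x$amplitude_sd_mV[[w]],
                x$duration_mean_ms[[w]], x$duration_sd_ms[[w]]))
  invisible(x)
}
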