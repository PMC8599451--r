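#' ECG simulation specification
#'
#' Parameters of a synthetic murine ECG with known per-beat ground truth.
#' Beats are placed at a regular RR interval; each QRS complex is a triplet
#' of Gaussian deflections (Q negative, R positive, S negative) whose
#' closed-form geometry yields exact truth for amplitudes, peak positions
#' and the baseline-crossing onsets/offsets used by the analysis stage.
#'
#' @param sampling_rate Hz (>= 250).
#' @param duration trace length in seconds (> 0).
#' @param heart_rate beats per minute.
#' @param q_amp,r_amp,s_amp signed wave amplitudes in mV (`r_amp > 0`).
#' @param qrs_width total QRS width in ms (Q and S centres sit half a width
#'   before/after the R centre).
#' @param baseline_wander_amp amplitude of a 0.5 Hz sinusoidal baseline
#'   wander, mV.
#' @param noise_sd additive white Gaussian noise SD, mV (>= 0).
#' @param snr_db optional; if given, overrides `noise_sd` so that the
#'   ratio of mean signal power (mean square of the noiseless waveform) to
#'   noise power equals `10^(snr_db/10)` — the standard power-ratio SNR
#'   definition.
#' @param seed integer RNG seed.
#' @return Object of class `ecg_sim_spec`.
#' @export
ecg_sim_spec <- function(sampling_rate = 1000, duration = 10, heart_rate = 480,
                         q_amp = -0.2, r_amp = 1.0, s_amp = -0.3,
                         qrs_width = 10, baseline_wander_amp = 0,
                         noise_sd = 0, snr_db = NULL, seed = 1L) {
  if (sampling_rate < 250) stop("'sampling_rate' must be >= 250 Hz")
  if (duration <= 0) stop("'duration' must be > 0")
  if (r_amp <= 0) stop("'r_amp' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (heart_rate <= 0) stop("'heart_rate' must be > 0")
  if (qrs_width <= 0) stop("'qrs_width' must be > 0")
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 heart_rate = heart_rate, q_amp = q_amp, r_amp = r_amp,
                 s_amp = s_amp, qrs_width = qrs_width,
                 baseline_wander_amp = baseline_wander_amp,
                 noise_sd = noise_sd, snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "ecg_sim_spec")
}

# fraction of peak amplitude at which onsets/offsets are defined; shared
# with the analysis stage so generator truth and measurement agree.
.qrs_edge_frac <- 0.05

#' Generate a synthetic ECG trace with ground truth
#'
#' @param spec an [ecg_sim_spec()].
#' @return List with `trace` (an [ecg_trace()]) and `truth`, a data.frame
#'   with one row per beat: sample indices (1-based), amplitudes (mV) and
#'   onset/offset indices for Q, R and S, under the same baseline
#'   convention (isoelectric level 0, edges at 5% of peak amplitude) as the
#'   analysis stage.
#' @export
gen_ecg <- function(spec) {
  stopifnot(inherits(spec, "ecg_sim_spec"))
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  rr <- 60 / spec$heart_rate
  n_beats <- round(spec$heart_rate / 60 * spec$duration)
  centers <- (seq_len(n_beats) - 0.5) * rr
  centers <- centers[centers < spec$duration]
  # snap beat centres to the sample grid so the narrow Q/R/S deflections
  # are rendered at their nominal peak amplitudes
  centers <- round(centers * fs) / fs
  w <- spec$qrs_width / 1000                 # s
  sig_r <- w / 8
  sig_qs <- w / 10
  v0 <- numeric(n)
  gauss <- function(center, amp, sig) amp * exp(-(t - center)^2 / (2 * sig^2))
  for (ct in centers) {
    v0 <- v0 + gauss(ct - w / 2, spec$q_amp, sig_qs)
    v0 <- v0 + gauss(ct, spec$r_amp, sig_r)
    v0 <- v0 + gauss(ct + w / 2, spec$s_amp, sig_qs)
  }
  v <- v0
  set.seed(spec$seed)
  noise_sd <- spec$noise_sd
  if (!is.null(spec$snr_db))
    noise_sd <- sqrt(mean(v0^2)) * 10^(-spec$snr_db / 20)
  if (spec$baseline_wander_amp > 0)
    v <- v + spec$baseline_wander_amp * sin(2 * pi * 0.5 * t + stats::runif(1, 0, 2 * pi))
  if (noise_sd > 0)
    v <- v + stats::rnorm(n, 0, noise_sd)

  # ground truth from the noiseless waveform, under the same baseline (0)
  # and edge convention (5% of peak amplitude) as the analysis stage
  to_idx <- function(x) pmin(pmax(round(x * fs) + 1L, 1L), n)
  win <- max(2L, round(w / 2 * fs))
  wave_truth <- function(center_times, sign) {
    ctr <- to_idx(center_times)
    peak <- vapply(ctr, function(i) {
      lo <- max(1, i - win); hi <- min(n, i + win)
      as.integer(if (sign > 0) lo + which.max(v0[lo:hi]) - 1 else lo + which.min(v0[lo:hi]) - 1)
    }, integer(1))
    edges <- vapply(peak, function(p) {
      lo <- max(1, p - 4 * win); hi <- min(n, p + 4 * win)
      as.integer(.wave_edges(v0, p, 0, .qrs_edge_frac, lo, hi))
    }, c(onset = 0L, offset = 0L))
    rownames(edges) <- c("onset", "offset")
    list(index = peak, amp = v0[peak],
         onset = as.integer(edges["onset", ]), offset = as.integer(edges["offset", ]))
  }
  qt <- wave_truth(centers - w / 2, -1)
  rt <- wave_truth(centers, +1)
  st <- wave_truth(centers + w / 2, -1)
  truth <- data.frame(
    beat = seq_along(centers),
    q_index = qt$index, q_amp = qt$amp, q_onset = qt$onset, q_offset = qt$offset,
    r_index = rt$index, r_amp = rt$amp, r_onset = rt$onset, r_offset = rt$offset,
    s_index = st$index, s_amp = st$amp, s_onset = st$onset, s_offset = st$offset
  )
  list(trace = ecg_trace(v, fs), truth = truth)
}
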