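#' Fractional shortening (%)
#'
#' `FS = ((LVID;d - LVID;s) / LVID;d) * 100`, from the left-ventricular
#' internal diameters at end-diastole and end-systole (mm).
#'
#' @param lvid_d,lvid_s diameters in mm; `lvid_d > 0`.
#' @return FS in percent. Negative when `lvid_s > lvid_d` (dyskinesia);
#'   that case is flagged by [summarize_echo()], not treated as an error.
#' @export
fractional_shortening <- function(lvid_d, lvid_s) {
  if (any(lvid_d <= 0)) stop("'lvid_d' must be > 0")
  (lvid_d - lvid_s) / lvid_d * 100
}

#' Ejection fraction (%)
#'
#' Cubic diameter formula: `EF = ((LVID;d^3 - LVID;s^3) / LVID;d^3) * 100`.
#'
#' @inheritParams fractional_shortening
#' @return EF in percent; `EF >= FS` for `0 <= lvid_s <= lvid_d`.
#' @export
ejection_fraction <- function(lvid_d, lvid_s) {
  if (any(lvid_d <= 0)) stop("'lvid_d' must be > 0")
  (lvid_d^3 - lvid_s^3) / lvid_d^3 * 100
}

#' M-mode replicate table constructor
#'
#' One row per replicate measurement of the six M-mode morphometric
#' parameters (mm): LVID;d, LVID;s, LVFW;d, LVFW;s, IVS;d, IVS;s.
#'
#' @param LVID_d,LVID_s,LVFW_d,LVFW_s,IVS_d,IVS_s numeric vectors, mm.
#' @param replicate_id optional identifiers.
#' @return data.frame of class `mmode_measurements`.
#' @export
mmode_measurements <- function(LVID_d, LVID_s, LVFW_d = NA_real_,
                               LVFW_s = NA_real_, IVS_d = NA_real_,
                               IVS_s = NA_real_, replicate_id = NULL) {
  d <- data.frame(LVID_d = LVID_d, LVID_s = LVID_s, LVFW_d = LVFW_d,
                  LVFW_s = LVFW_s, IVS_d = IVS_d, IVS_s = IVS_s)
  num <- unlist(d)
  if (any(num[!is.na(num)] < 0)) stop("M-mode parameters must be >= 0")
  d$replicate_id <- replicate_id %||% seq_len(nrow(d))
  class(d) <- c("mmode_measurements", "data.frame")
  d
}

#' Read M-mode replicates from CSV
#' @param path CSV with one row per replicate and the M-mode columns.
#' @return An `mmode_measurements` table.
#' @export
read_mmode_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("LVID_d", "LVID_s")
  if (!all(need %in% names(d))) stop("M-mode CSV needs columns LVID_d, LVID_s")
  get0c <- function(nm) if (nm %in% names(d)) d[[nm]] else NA_real_
  mmode_measurements(d$LVID_d, d$LVID_s, get0c("LVFW_d"), get0c("LVFW_s"),
                     get0c("IVS_d"), get0c("IVS_s"),
                     replicate_id = if ("replicate_id" %in% names(d)) d$replicate_id else NULL)
}

#' Summarize echocardiographic replicates
#'
#' Averages the morphometric parameters over replicates first (five
#' expected), then computes EF and FS from the averaged diameters. The
#' averaging order matters: computing per-replicate EF/FS and averaging
#' those gives different results for heterogeneous replicates; the
#' parameter-average-first convention is used here.
#'
#' @param measurements an [mmode_measurements()] table (>= 1 row; a warning
#'   is emitted when not exactly 5).
#' @return List of class `echo_summary` with `EF_percent`, `FS_percent`,
#'   averaged parameters (mm), `n_replicates`, and `quality_flag`
#'   (`"lvid_s_exceeds_lvid_d"` when the averaged systolic diameter exceeds
#'   the diastolic one, else `"ok"`).
#' @export
summarize_echo <- function(measurements) {
  if (!inherits(measurements, "mmode_measurements") || !nrow(measurements))
    stop("'measurements' must be a non-empty mmode_measurements table")
  if (nrow(measurements) != 5L)
    warning(sprintf("expected 5 replicates, got %d", nrow(measurements)))
  pars <- c("LVID_d", "LVID_s", "LVFW_d", "LVFW_s", "IVS_d", "IVS_s")
  avg <- vapply(pars, function(p) mean(measurements[[p]]), numeric(1))
  flag <- if (!is.na(avg["LVID_s"]) && avg["LVID_s"] > avg["LVID_d"])
    "lvid_s_exceeds_lvid_d" else "ok"
  structure(list(
    EF_percent = ejection_fraction(avg[["LVID_d"]], avg[["LVID_s"]]),
    FS_percent = fractional_shortening(avg[["LVID_d"]], avg[["LVID_s"]]),
    averaged_mm = avg,
    n_replicates = nrow(measurements),
    quality_flag = flag
  ), class = "echo_summary")
}

#' @export
print.echo_summary <- function(x, ...) {
  cat(sprintf("<echo_summary> EF %.2f%%, FS %.2f%% (n = %d replicates%s)\n",
              x$EF_percent, x$FS_percent, x$n_replicates,
              if (x$quality_flag != "ok") paste0(", flag: ", x$quality_flag) else ""))
  invisible(x)
}
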