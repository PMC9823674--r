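#' Peak muscle contraction of a gait-cycle envelope
#'
#' Locates the global maximum of a 101-point envelope. Ties are broken by the
#' earliest index; a constant envelope has no meaningful peak and is returned
#' flagged degenerate (at 0% with its constant amplitude).
#'
#' @param envelope Numeric vector of 101 values (one gait cycle, index i =
#'   i% of the cycle).
#' @return List of class `peak_contraction` with `time_pct` (integer 0..100),
#'   `amplitude`, and `degenerate` flag.
#' @export
find_peak <- function(envelope) {
  envelope <- as.numeric(envelope)
  if (length(envelope) != 101L) stop("find_peak: envelope must have exactly 101 points")
  i <- which.max(envelope)  # first maximum = earliest-index tie rule
  structure(list(time_pct = i - 1L,
                 amplitude = envelope[i],
                 degenerate = max(envelope) == min(envelope)),
            class = "peak_contraction")
}

#' Normalized root-mean-square error (percent)
#'
#' RMSE between actual and predicted cycles divided by the range of the
#' actual cycle, times 100. The normalizer is always the *actual* signal's
#' per-cycle range. Undefined for a constant actual cycle; returns `NA`.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return nRMSE in percent, or `NA_real_` when the actual cycle is constant.
#' @export
nrmse <- function(actual, predicted) {
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  if (length(actual) != length(predicted)) stop("nrmse: length mismatch")
  rng <- max(actual) - min(actual)
  if (rng == 0) return(NA_real_)
  100 * sqrt(mean((actual - predicted)^2)) / rng
}

#' Pearson correlation coefficient (percent)
#'
#' Product-moment correlation between actual and predicted cycles, times
#' 100. Undefined (returns `NA`) when either signal has zero variance.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return r in percent, in `[-100, 100]`, or `NA_real_`.
#' @export
pearson_r <- function(actual, predicted) {
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  if (length(actual) != length(predicted)) stop("pearson_r: length mismatch")
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) return(NA_real_)
  100 * stats::cor(actual, predicted)
}

#' Peak-timing error (signed, percent of gait cycle)
#'
#' Difference between the actual and predicted peak times, `T_actual -
#' T_predicted`, in percent of the gait cycle. No circular wrapping is
#' applied (peaks at 10% and 90% give -80%); this plain difference is a
#' known limitation for peaks near the cycle boundary.
#'
#' @param actual_peak,predicted_peak [find_peak()] results (or envelopes,
#'   which are reduced with [find_peak()] first).
#' @return Signed timing difference in percent of the gait cycle.
#' @export
delta_tp <- function(actual_peak, predicted_peak) {
  actual_peak <- as_peak(actual_peak); predicted_peak <- as_peak(predicted_peak)
  as.numeric(actual_peak$time_pct - predicted_peak$time_pct)
}

#' Peak-amplitude error (percent)
#'
#' Absolute difference of peak amplitudes relative to the actual peak,
#' `|X_p - Y_p| / X_p * 100`. Undefined (`NA`) when the actual peak
#' amplitude is zero.
#'
#' @inheritParams delta_tp
#' @return Relative amplitude error in percent (>= 0), or `NA_real_`.
#' @export
delta_ep <- function(actual_peak, predicted_peak) {
  actual_peak <- as_peak(actual_peak); predicted_peak <- as_peak(predicted_peak)
  if (actual_peak$amplitude == 0) return(NA_real_)
  100 * abs(actual_peak$amplitude - predicted_peak$amplitude) / actual_peak$amplitude
}

as_peak <- function(x) {
  if (inherits(x, "peak_contraction")) return(x)
  find_peak(x)
}

#' All waveform metrics for one gait cycle
#'
#' @param actual,predicted 101-point envelopes.
#' @return List with `nrmse_pct`, `r_pct`, `delta_tp_pct` (signed),
#'   `delta_ep_pct`; metrics that are undefined for this cycle are `NA`.
#' @export
cycle_metrics <- function(actual, predicted) {
  pa <- find_peak(actual); pp <- find_peak(predicted)
  list(nrmse_pct = nrmse(actual, predicted),
       r_pct = pearson_r(actual, predicted),
       delta_tp_pct = if (pa$degenerate) NA_real_ else delta_tp(pa, pp),
       delta_ep_pct = if (pa$degenerate) NA_real_ else delta_ep(pa, pp))
}

#' Aggregate per-cycle metrics into a report row
#'
#' Computes nRMSE, r, peak-timing and peak-amplitude errors for every cycle
#' and reports mean and sample SD per metric. Peak-timing error is signed per
#' cycle; the headline mean +- SD is taken over absolute values (matching the
#' positive values such tables conventionally print), with the signed
#' aggregate also reported. Cycles for which a metric is undefined (constant
#' actual cycle, zero actual peak) are excluded from that metric's aggregate,
#' never zero-filled; exclusion counts are surfaced.
#'
#' @param actual,predicted Matrices with one 101-point cycle per row.
#' @param muscle Muscle name for the report row.
#' @param group Group label, e.g. `"test"` or `"unseen"`.
#' @return One-row `data.frame` with mean/SD columns per metric, `n_cycles`,
#'   and `n_excluded` (cycles with at least one undefined metric).
#' @export
evaluate_group <- function(actual, predicted, muscle = "muscle", group = "test") {
  actual <- as.matrix(actual); predicted <- as.matrix(predicted)
  if (!all(dim(actual) == dim(predicted))) stop("evaluate_group: dimension mismatch")
  ms <- lapply(seq_len(nrow(actual)), function(i) cycle_metrics(actual[i, ], predicted[i, ]))
  col <- function(f) vapply(ms, `[[`, numeric(1), f)
  nr <- col("nrmse_pct"); rr <- col("r_pct")
  dtp <- col("delta_tp_pct"); dep <- col("delta_ep_pct")
  agg <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x[!is.na(x)]))
  a_nr <- agg(nr); a_r <- agg(rr); a_dtp <- agg(abs(dtp))
  a_dtp_s <- agg(dtp); a_dep <- agg(dep)
  excluded <- sum(is.na(nr) | is.na(rr) | is.na(dtp) | is.na(dep))
  data.frame(
    muscle = muscle, group = group,
    n_cycles = nrow(actual), n_excluded = excluded,
    nrmse_mean = a_nr[["mean"]], nrmse_sd = a_nr[["sd"]],
    r_mean = a_r[["mean"]], r_sd = a_r[["sd"]],
    delta_tp_abs_mean = a_dtp[["mean"]], delta_tp_abs_sd = a_dtp[["sd"]],
    delta_tp_signed_mean = a_dtp_s[["mean"]], delta_tp_signed_sd = a_dtp_s[["sd"]],
    delta_ep_mean = a_dep[["mean"]], delta_ep_sd = a_dep[["sd"]],
    stringsAsFactors = FALSE
  )
}

#' Write an evaluation report to disk
#'
#' Writes the per-muscle table both as a delimited file (one row per muscle
#' and architecture, mean +- SD columns) and as machine-readable JSON.
#'
#' @param report A `data.frame` of [evaluate_group()] rows (typically with an
#'   extra `architecture` column).
#' @param dir Output directory.
#' @return Invisibly, the two file paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "report.csv")
  p2 <- file.path(dir, "report.json")
  data.table::fwrite(report, p1)
  jsonlite::write_json(report, p2, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(c(p1, p2))
}
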