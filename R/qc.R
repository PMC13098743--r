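# Rejection criteria and artifact masking: per-record pass/fail flags with
# reasons, and removal of samples inside marked artifact intervals.

#' TRS signal-to-noise ratio of a DTOF
#'
#' Ratio between the histogram maximum and the standard deviation of a
#' background portion of the same histogram preceding the curve. The
#' background window is the first `bg_frac` of the bins before the
#' rising-edge half-maximum crossing, with a minimum of `bg_min_bins` bins.
#'
#' @param dtof a [dtof_record()].
#' @param bg_frac fraction of pre-curve bins used as background (default 0.1).
#' @param bg_min_bins minimum number of background bins (default 20).
#' @return the SNR (dimensionless). A zero-variance background yields `Inf`
#'   with a warning.
#' @export
trs_snr <- function(dtof, bg_frac = 0.1, bg_min_bins = 20L) {
  counts <- dtof$counts
  i_half <- which(counts >= 0.5 * max(counts))[1]
  n_bg <- max(bg_min_bins, floor(bg_frac * (i_half - 1)))
  if (n_bg >= i_half)
    stop("background window (", n_bg, " bins) reaches the rising edge")
  bg <- counts[seq_len(n_bg)]
  s <- stats::sd(bg)
  if (s == 0) {
    warning("zero background variance; SNR is infinite")
    return(Inf)
  }
  max(counts) / s
}

.qc_result <- function(record_id, passed, reason, snr = NA_real_,
                       count_rate = NA_real_, beta = NA_real_) {
  stopifnot(passed == (reason == "ok"))
  structure(list(record_id = record_id, snr = snr, count_rate = count_rate,
                 beta = beta, passed = passed, reason = reason),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC [%s]: %s (%s)\n", x$record_id,
              if (x$passed) "pass" else "reject", x$reason))
  invisible(x)
}

#' TRS quality control
#'
#' A DTOF passes when its SNR is strictly greater than `threshold`
#' (default 10).
#'
#' @param snr SNR from [trs_snr()].
#' @param threshold rejection threshold (strict inequality).
#' @param record_id identifier carried into the result.
#' @return a `qc_result` with `passed` and `reason` (`"ok"`/`"low_snr"`).
#' @export
qc_trs <- function(snr, threshold = 10, record_id = NA_character_) {
  passed <- is.finite(snr) && snr > threshold || is.infinite(snr)
  .qc_result(record_id, passed, if (passed) "ok" else "low_snr", snr = snr)
}

#' DCS quality control
#'
#' A g2 record is rejected when the averaged detector count rate is below
#' `min_count_rate_khz` or the fitted coherence factor is below `min_beta`.
#' The study protocol phrases the two criteria in one sentence joined by
#' "and"; since either condition alone indicates an unusable curve the
#' default here is rejection on either (`mode = "or"`), with the literal
#' conjunction available as `mode = "and"`.
#'
#' @param rec a [g2_record()] (supplies the count rate).
#' @param fitted_beta coherence factor from [fit_g2()].
#' @param min_count_rate_khz count-rate threshold, kHz (default 10).
#' @param min_beta beta threshold (default 0.4).
#' @param mode `"or"` (default) or `"and"`.
#' @param record_id identifier carried into the result.
#' @return a `qc_result`; `reason` records the first failing criterion.
#' @export
qc_dcs <- function(rec, fitted_beta, min_count_rate_khz = 10, min_beta = 0.4,
                   mode = c("or", "and"), record_id = NA_character_) {
  mode <- match.arg(mode)
  low_cr <- rec$count_rate_khz < min_count_rate_khz
  low_b <- !is.finite(fitted_beta) || fitted_beta < min_beta
  rejected <- if (mode == "or") low_cr || low_b else low_cr && low_b
  reason <- if (!rejected) "ok" else if (low_cr) "low_count_rate" else "low_beta"
  .qc_result(record_id, !rejected, reason, count_rate = rec$count_rate_khz,
             beta = fitted_beta)
}

#' Artifact mask
#'
#' A set of half-open time intervals `[t_start, t_end)` during which samples
#' are removed from all physiological traces (patient manipulation, motion,
#' or manual marking). Intervals are normalized: sorted and merged when
#' overlapping.
#'
#' @param t_start,t_end interval bounds in seconds (vectors, `t_start <
#'   t_end` elementwise).
#' @param source one of `"event_mark"`, `"accelerometer"`, `"manual"`
#'   (recycled).
#' @return a data.frame of class `artifact_mask` with columns `t_start`,
#'   `t_end`, `source`.
#' @export
artifact_mask <- function(t_start, t_end,
                          source = c("event_mark", "accelerometer", "manual")) {
  if (length(t_start) == 0)
    return(structure(data.frame(t_start = numeric(), t_end = numeric(),
                                source = character()),
                     class = c("artifact_mask", "data.frame")))
  source <- match.arg(source, several.ok = TRUE)
  stopifnot(length(t_start) == length(t_end), all(t_start < t_end))
  m <- data.frame(t_start = t_start, t_end = t_end,
                  source = rep_len(source, length(t_start)))
  m <- m[order(m$t_start), , drop = FALSE]
  # merge overlapping/adjacent intervals
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    j <- nrow(out)
    if (m$t_start[i] <= out$t_end[j]) {
      out$t_end[j] <- max(out$t_end[j], m$t_end[i])
    } else out <- rbind(out, m[i, ])
  }
  rownames(out) <- NULL
  structure(out, class = c("artifact_mask", "data.frame"))
}

#' Remove masked samples from a trace
#'
#' Drops every sample whose timestamp falls inside any masked interval
#' (half-open convention: a sample at `t_end` survives). Surviving values
#' are never altered, only membership changes.
#'
#' @param trace a [hemo_trace()] or any data.frame with a `time` column.
#' @param masks an [artifact_mask()] (or a list of them, which are combined).
#' @return the trace with masked rows removed; the number of removed samples
#'   is attached as attribute `"n_masked"`. An empty result triggers a
#'   warning (the subject is then excluded from that variable's statistics).
#' @export
apply_masks <- function(trace, masks) {
  if (is.list(masks) && !is.data.frame(masks))
    masks <- do.call(rbind, masks)
  if (is.null(masks) || nrow(masks) == 0) {
    attr(trace, "n_masked") <- 0L
    return(trace)
  }
  inside <- rep(FALSE, nrow(trace))
  for (i in seq_len(nrow(masks)))
    inside <- inside | (trace$time >= masks$t_start[i] &
                          trace$time < masks$t_end[i])
  out <- trace[!inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_masked") <- sum(inside)
  for (a in c("variable", "location", "baseline_stat"))
    attr(out, a) <- attr(trace, a)
  class(out) <- class(trace)
  if (nrow(out) == 0)
    warning("all samples masked; trace is empty")
  out
}
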