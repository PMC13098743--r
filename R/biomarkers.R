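# Derived physiological variables: arterial oxygen content and the
# hematocrit-corrected metabolic rate of oxygen, the oxygen extraction
# fraction estimate, baseline-relative and difference traces, 10-s binning
# and stream synchronization.

#' Physiological constants used by the biomarker equations
#'
#' @param k oxygen-carrying capacity of hemoglobin, mL O2 per g Hgb
#'   (default 1.36, the mammalian value).
#' @param mchc mean corpuscular hemoglobin concentration, g/L (default 340).
#' @param gamma_venous assumed venous fraction of the microvascular
#'   compartment used by the OEF estimate (default 0.75).
#' @return a list of class `physio_constants`.
#' @export
physio_constants <- function(k = 1.36, mchc = 340, gamma_venous = 0.75) {
  stopifnot(k > 0, mchc > 0, gamma_venous > 0, gamma_venous <= 1)
  structure(list(k = k, mchc = mchc, gamma_venous = gamma_venous),
            class = "physio_constants")
}

#' Arterial hemoglobin concentration from hematocrit
#'
#' `Hgb (g/dL) = HCT(%) / 100 * MCHC(g/L) / 10`.
#'
#' @param hct hematocrit in percent, strictly inside (0, 100).
#' @param constants [physio_constants()].
#' @return hemoglobin concentration in g/dL.
#' @export
hgb_from_hct <- function(hct, constants = physio_constants()) {
  if (any(!is.finite(hct)) || any(hct <= 0) || any(hct >= 100))
    stop("'hct' must lie strictly between 0 and 100 percent")
  (hct / 100) * (constants$mchc / 10)
}

#' Arterial oxygen content
#'
#' `CaO2 = k * Hgb * SaO2`, in mL O2 per dL of blood.
#'
#' @param hgb arterial total hemoglobin concentration, g/dL.
#' @param sao2 arterial oxygen saturation as a fraction in `[0, 1]`.
#' @param constants [physio_constants()].
#' @return arterial oxygen content, mL O2/dL.
#' @export
cao2 <- function(hgb, sao2, constants = physio_constants()) {
  # tolerate float round-off from bin averaging at the saturation ceiling
  if (any(sao2 < -1e-9 | sao2 > 1 + 1e-9, na.rm = TRUE))
    stop("'sao2' must be a fraction in [0, 1]")
  constants$k * hgb * pmin(pmax(sao2, 0), 1)
}

#' Oxygen extraction fraction from tissue and arterial saturation
#'
#' Venous-compartment estimate: the microvascular saturation StO2 is modeled
#' as a mixture `gamma * SvO2 + (1 - gamma) * SaO2`, so
#' `SvO2 = (StO2 - (1 - gamma) * SaO2) / gamma` and
#' `OEF = (SaO2 - SvO2) / SaO2`. At `gamma = 1` this reduces to
#' `(SaO2 - StO2)/SaO2`. Values outside `[0, 1]` are returned as computed;
#' downstream QC flags them.
#'
#' @param sto2 tissue oxygen saturation, fraction.
#' @param sao2 arterial oxygen saturation, fraction, must be positive.
#' @param gamma venous fraction (default 0.75).
#' @return OEF as a fraction (vectorized); `NA` where `sao2 <= 0`.
#' @export
oef_from_sto2 <- function(sto2, sao2, gamma = 0.75) {
  stopifnot(gamma > 0, gamma <= 1)
  bad <- !is.finite(sao2) | sao2 <= 0
  if (any(bad)) warning("sao2 <= 0: OEF undefined, returning NA")
  svo2 <- (sto2 - (1 - gamma) * sao2) / gamma
  out <- (sao2 - svo2) / sao2
  out[bad] <- NA_real_
  out
}

#' Physiological time series container
#'
#' A tidy (time, value) series for one variable at one probe location.
#'
#' @param time timestamps in seconds from session start (sorted).
#' @param value sample values.
#' @param variable one of `"hbo2"`, `"hhb"`, `"hbt"`, `"sto2"`, `"bfi"`,
#'   `"oef"`, `"mro2"` (or a derived name).
#' @param location `"cerebral"` or `"peripheral"`.
#' @return a data.frame of class `hemo_trace` with attributes `variable` and
#'   `location`.
#' @export
hemo_trace <- function(time, value, variable, location) {
  stopifnot(length(time) == length(value), !is.unsorted(time))
  structure(data.frame(time = as.numeric(time), value = as.numeric(value)),
            variable = variable, location = location,
            class = c("hemo_trace", "data.frame"))
}

#' @export
print.hemo_trace <- function(x, ...) {
  cat(sprintf("<hemo_trace> %s @ %s: %d samples, t = [%g, %g] s\n",
              attr(x, "variable"), attr(x, "location"), nrow(x),
              if (nrow(x)) min(x$time) else NA, if (nrow(x)) max(x$time) else NA))
  if (!is.null(attr(x, "baseline_stat")))
    cat(sprintf("  baseline mean: %g\n", attr(x, "baseline_stat")))
  invisible(x)
}

.trace_like <- function(template, time, value, variable = NULL) {
  hemo_trace(time, value,
             variable %||% attr(template, "variable"),
             attr(template, "location"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Timed arterial blood-gas samples
#'
#' @param time draw times in seconds from session start.
#' @param period protocol period label of each draw: `"pre"`, `"mid"`,
#'   `"post"`.
#' @param hgb arterial total hemoglobin, g/dL.
#' @param hct hematocrit, percent in (0, 100).
#' @param paco2 arterial CO2 tension, mmHg.
#' @param hgbo2,hgbr optional arterial oxy-/reduced-hemoglobin, g/dL.
#' @return a data.frame of class `blood_gas`.
#' @export
blood_gas <- function(time, period, hgb, hct, paco2 = NA_real_,
                      hgbo2 = NA_real_, hgbr = NA_real_) {
  stopifnot(all(period %in% c("pre", "mid", "post")))
  if (anyDuplicated(period))
    stop("at most one blood-gas sample per protocol period")
  if (any(hct <= 0 | hct >= 100, na.rm = TRUE)) stop("hct out of range")
  if (any(hgb <= 0, na.rm = TRUE)) stop("hgb must be positive")
  structure(data.frame(time = unname(as.numeric(time)), period = period,
                       hgb = unname(as.numeric(hgb)),
                       hct = unname(as.numeric(hct)),
                       paco2 = unname(as.numeric(paco2)),
                       hgbo2 = unname(as.numeric(hgbo2)),
                       hgbr = unname(as.numeric(hgbr)), row.names = NULL),
            class = c("blood_gas", "data.frame"))
}

#' Impute a missing post-transfusion hematocrit from the cohort
#'
#' When a subject lacks a post-transfusion blood draw, the post hematocrit
#' is imputed as the mean over all other subjects' post values whose
#' pre-transfusion hematocrit matched this subject's (within `tol` percent
#' absolute). With no matching donor the cohort mean post value is used,
#' with a warning.
#'
#' @param pre_hct the subject's own pre-transfusion hematocrit, percent.
#' @param donor_pre,donor_post pre/post hematocrit vectors of the other
#'   subjects (pairs with `NA` post are ignored).
#' @param tol donor-matching tolerance on the pre value, percent (default 0.5).
#' @return imputed post-transfusion hematocrit, percent.
#' @export
impute_post_hct <- function(pre_hct, donor_pre, donor_post, tol = 0.5) {
  stopifnot(length(donor_pre) == length(donor_post))
  ok <- is.finite(donor_pre) & is.finite(donor_post)
  match_ <- ok & abs(donor_pre - pre_hct) <= tol
  if (any(match_)) return(mean(donor_post[match_]))
  warning("no donor with matching pre-transfusion HCT; using cohort mean")
  mean(donor_post[ok])
}

#' Down-sample a trace to 10-s bins
#'
#' Samples are grouped into non-overlapping half-open bins
#' `[k*bin_s, (k+1)*bin_s)`; the bin value is the mean of its members and
#' its timestamp the bin start. Bins with no surviving samples are absent
#' from the output (never NaN-filled or interpolated).
#'
#' @param trace a [hemo_trace()] (or data.frame with `time` and `value`).
#' @param bin_s bin width in seconds (default 10).
#' @return a trace on the binned time base.
#' @export
downsample_10s <- function(trace, bin_s = 10) {
  if (is.unsorted(trace$time)) stop("timestamps must be sorted")
  if (nrow(trace) == 0) return(trace)
  bin <- floor(trace$time / bin_s)
  # grouped means via run lengths: bins are sorted because time is sorted
  r <- rle(bin)
  idx <- cumsum(r$lengths)
  cs <- cumsum(trace$value)
  sums <- cs[idx] - c(0, cs[idx[-length(idx)]])
  .trace_like(trace, r$values * bin_s, sums / r$lengths)
}

#' Baseline-relative trace
#'
#' Divides the entire time course by its mean over the pre-transfusion
#' baseline window, yielding an "r"-variable whose baseline mean is exactly
#' 1 (e.g. relative blood flow rBF).
#'
#' @param trace a [hemo_trace()] on the 10-s base.
#' @param baseline_window length-2 half-open window `[t0, t1)` in seconds.
#' @param min_bins minimum number of unmasked baseline bins (default 3).
#' @return the relative trace; the baseline mean of the input is attached as
#'   attribute `"baseline_stat"`.
#' @export
relative_trace <- function(trace, baseline_window, min_bins = 3L) {
  b <- .baseline_mean(trace, baseline_window, min_bins)
  if (abs(b) < 1e-12 * max(abs(trace$value), 1))
    stop("baseline mean is (near) zero; relative trace undefined")
  out <- .trace_like(trace, trace$time, trace$value / b,
                     paste0("r", attr(trace, "variable")))
  attr(out, "baseline_stat") <- b
  attr(out, "transform") <- "relative"
  out
}

#' Baseline-difference trace
#'
#' Subtracts the mean over the pre-transfusion baseline window from the
#' entire time course, yielding a difference variable whose baseline mean is
#' exactly 0 (e.g. change in oxy-hemoglobin concentration).
#'
#' @inheritParams relative_trace
#' @return the difference trace with attribute `"baseline_stat"`.
#' @export
delta_trace <- function(trace, baseline_window, min_bins = 3L) {
  b <- .baseline_mean(trace, baseline_window, min_bins)
  out <- .trace_like(trace, trace$time, trace$value - b,
                     paste0("d", attr(trace, "variable")))
  attr(out, "baseline_stat") <- b
  attr(out, "transform") <- "delta"
  out
}

.baseline_mean <- function(trace, baseline_window, min_bins) {
  stopifnot(length(baseline_window) == 2L,
            baseline_window[1] < baseline_window[2])
  sel <- trace$time >= baseline_window[1] & trace$time < baseline_window[2]
  if (sum(sel) < min_bins)
    stop("fewer than ", min_bins, " baseline bins survive masking")
  mean(trace$value[sel])
}

#' Protocol period of each timestamp
#'
#' `pre` before transfusion start, `mid` during, `post` at or after the end
#' mark (half-open convention).
#'
#' @param time timestamps in seconds.
#' @param events a data.frame with `time` and `label` columns containing the
#'   `transfusion_start` and `transfusion_end` marks.
#' @return character vector of period labels.
#' @export
protocol_period <- function(time, events) {
  t0 <- .event_time(events, "transfusion_start")
  t1 <- .event_time(events, "transfusion_end")
  ifelse(time < t0, "pre", ifelse(time < t1, "mid", "post"))
}

.event_time <- function(events, label) {
  t <- events$time[events$label == label]
  if (length(t) != 1L)
    stop("session needs exactly one '", label, "' mark; found ", length(t))
  t
}

#' Metabolic rate of oxygen trace
#'
#' `MRO2(t) = BFI(t) * OEF(t) * CaO2(t)` with
#' `CaO2(t) = k * Hgb(t) * SaO2(t)` and `Hgb` derived from the hematocrit of
#' the protocol period containing `t` (pre / mid / post), kept constant
#' within each period. A missing post hematocrit must be imputed with
#' [impute_post_hct()] before calling; otherwise the subject is excluded
#' from MRO2 statistics.
#'
#' @param bfi_trace,oef_trace,sao2_trace [hemo_trace()]s on a common 10-s
#'   time base (timestamps are intersected).
#' @param bloodgas a [blood_gas()] table with an `hct` value per period.
#' @param events event marks with `transfusion_start` / `transfusion_end`.
#' @param constants [physio_constants()].
#' @return a [hemo_trace()] of variable `"mro2"` (units: cm^2/s * mL O2/dL,
#'   an index quantity used in relative form).
#' @export
mro2_trace <- function(bfi_trace, oef_trace, sao2_trace, bloodgas, events,
                       constants = physio_constants()) {
  tt <- Reduce(intersect, list(bfi_trace$time, oef_trace$time,
                               sao2_trace$time))
  if (length(tt) == 0) stop("traces share no common timestamps")
  tt <- sort(tt)
  period <- protocol_period(tt, events)
  hct_by_period <- stats::setNames(bloodgas$hct[match(c("pre", "mid", "post"),
                                                      bloodgas$period)],
                                   c("pre", "mid", "post"))
  if (any(is.na(hct_by_period[unique(period)])))
    stop("missing hematocrit for period(s): ",
         paste(unique(period)[is.na(hct_by_period[unique(period)])],
               collapse = ", "),
         " (impute before deriving MRO2)")
  hgb <- hgb_from_hct(unname(hct_by_period[period]), constants)
  bfi <- bfi_trace$value[match(tt, bfi_trace$time)]
  oef <- oef_trace$value[match(tt, oef_trace$time)]
  sao2 <- sao2_trace$value[match(tt, sao2_trace$time)]
  val <- bfi * oef * cao2(hgb, sao2, constants)
  hemo_trace(tt, val, "mro2", attr(bfi_trace, "location"))
}

#' Synchronize all streams of a monitoring session
#'
#' Applies per-stream clock offsets, down-samples every trace and the vitals
#' to the common 10-s master time base, converts percent-scale SaO2 to a
#' fraction (auto-detected when values exceed 1.5), and assembles a
#' `subject_session`. Sessions without both transfusion marks are
#' unprocessable (hard error).
#'
#' @param traces named list of [hemo_trace()]s (fitted optical time series).
#' @param vitals data.frame with `time`, `sao2`, `map`, `hr`.
#' @param events data.frame with `time`, `label`; must contain
#'   `transfusion_start` and `transfusion_end`.
#' @param bloodgas a [blood_gas()] table.
#' @param masks an [artifact_mask()] (possibly empty).
#' @param offsets named list of additive clock offsets in seconds, applied
#'   to `traces` entries by name and/or to `"vitals"`.
#' @param subject_id identifier.
#' @param bin_s master bin width, seconds (default 10).
#' @return an object of class `subject_session`.
#' @export
synchronize <- function(traces, vitals, events, bloodgas,
                        masks = artifact_mask(numeric(), numeric()),
                        offsets = list(), subject_id = NA_character_,
                        bin_s = 10) {
  .event_time(events, "transfusion_start")  # hard errors when missing
  .event_time(events, "transfusion_end")
  for (nm in names(offsets)) {
    if (nm == "vitals") vitals$time <- vitals$time + offsets[[nm]]
    else if (nm %in% names(traces))
      traces[[nm]]$time <- traces[[nm]]$time + offsets[[nm]]
  }
  if (any(vitals$sao2 > 1.5, na.rm = TRUE)) {
    message("SaO2 appears percent-scaled; converting to fraction")
    vitals$sao2 <- vitals$sao2 / 100
  }
  traces <- lapply(traces, downsample_10s, bin_s = bin_s)
  vit <- lapply(c("sao2", "map", "hr"), function(v) {
    ok <- is.finite(vitals[[v]])
    downsample_10s(hemo_trace(vitals$time[ok], vitals[[v]][ok], v, "systemic"),
                   bin_s = bin_s)
  })
  names(vit) <- c("sao2", "map", "hr")
  structure(list(subject_id = subject_id, traces = traces, vitals = vit,
                 events = events, bloodgas = bloodgas, masks = masks,
                 bin_s = bin_s),
            class = "subject_session")
}

#' @export
print.subject_session <- function(x, ...) {
  cat(sprintf("<subject_session> %s: %d traces, %d blood draws, %d events\n",
              x$subject_id, length(x$traces), nrow(x$bloodgas),
              nrow(x$events)))
  invisible(x)
}
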