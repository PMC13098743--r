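# Inverse problems: fitting measured DTOFs (with IRF) for per-wavelength
# optical properties, converting absorption pairs to hemoglobin
# concentrations and StO2, and fitting g2 curves for the blood-flow index.

#' Raw record constructors
#'
#' Validated containers for the raw optical units: a photon time-of-flight
#' histogram (`dtof_record`), its paired instrument response function
#' (`irf_record`), and an intensity autocorrelation curve (`g2_record`).
#'
#' @param timestamp seconds from session start.
#' @param wavelength nm; TRS wavelengths are restricted to 690 or 830.
#' @param bin_width_ps histogram bin width, ps.
#' @param counts non-negative counts per bin (at least 100 bins for a DTOF).
#' @param location `"cerebral"` or `"peripheral"`.
#' @param tau increasing lag grid, seconds.
#' @param g2 measured intensity autocorrelation values.
#' @param count_rate_khz detector count rate averaged over channels, kHz.
#' @return an object of class `dtof_record`, `irf_record` or `g2_record`.
#' @name raw-records
NULL

#' @rdname raw-records
#' @export
dtof_record <- function(timestamp, wavelength, bin_width_ps, counts,
                        location = c("cerebral", "peripheral")) {
  location <- match.arg(location)
  if (!wavelength %in% c(690, 830))
    stop("TRS wavelength must be 690 or 830 nm")
  if (length(counts) < 100L) stop("a DTOF needs at least 100 bins")
  if (any(counts < 0)) stop("counts must be non-negative")
  stopifnot(bin_width_ps > 0, timestamp >= 0)
  structure(list(timestamp = timestamp, wavelength = wavelength,
                 bin_width_ps = bin_width_ps, counts = as.numeric(counts),
                 location = location),
            class = "dtof_record")
}

#' @rdname raw-records
#' @export
irf_record <- function(bin_width_ps, counts, wavelength) {
  if (any(counts < 0)) stop("IRF counts must be non-negative")
  if (max(counts) <= 0) stop("IRF has no peak")
  stopifnot(bin_width_ps > 0)
  structure(list(bin_width_ps = bin_width_ps, counts = as.numeric(counts),
                 wavelength = wavelength),
            class = "irf_record")
}

#' @rdname raw-records
#' @export
g2_record <- function(timestamp, tau, g2, count_rate_khz,
                      location = c("cerebral", "peripheral")) {
  location <- match.arg(location)
  if (any(diff(tau) <= 0)) stop("'tau' must be increasing")
  if (length(tau) != length(g2)) stop("'tau' and 'g2' lengths differ")
  if (count_rate_khz < 0) stop("count rate must be non-negative")
  structure(list(timestamp = timestamp, tau = as.numeric(tau),
                 g2 = as.numeric(g2), count_rate_khz = count_rate_khz,
                 location = location),
            class = "g2_record")
}

#' Bundled extinction-coefficient table
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin at the
#' wavelengths used by the instrument (690, 785, 830 nm), in 1/(mM*mm).
#' The literature provenance is recorded in the bundled file header and
#' attached as the `"provenance"` attribute. The table is returned as a
#' fresh immutable copy on every call.
#'
#' @param path optional path to an alternative table with the same columns.
#' @return a data.frame of class `extinction_table` with columns
#'   `wavelength_nm`, `eps_hbo2`, `eps_hhb`.
#' @export
extinction_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_coefficients.csv",
                        package = "rbctdo", mustWork = TRUE)
  hdr <- grep("^#", readLines(path, n = 20L), value = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("wavelength_nm", "eps_hbo2", "eps_hhb") %in% names(tab)))
  if (!all(c(690, 830) %in% tab$wavelength_nm))
    stop("extinction table must cover 690 and 830 nm")
  if (any(tab$eps_hbo2 <= 0) || any(tab$eps_hhb <= 0))
    stop("extinction coefficients must be positive")
  structure(tab, provenance = paste(sub("^# ?", "", hdr), collapse = "\n"),
            class = c("extinction_table", "data.frame"))
}

.eps_at <- function(table, wavelength) {
  i <- match(wavelength, table$wavelength_nm)
  if (is.na(i)) stop("no extinction entry at ", wavelength, " nm")
  c(hbo2 = table$eps_hbo2[i], hhb = table$eps_hhb[i])
}

#' Absorption from hemoglobin concentrations (forward map)
#'
#' `mua(lambda) = ln(10) * (eps_HbO2 * hbo2 + eps_Hhb * hhb)`, the linear
#' Beer-Lambert forward map inverted by [chromophores_from_mua()].
#'
#' @param hbo2,hhb concentrations in mM.
#' @param wavelength nm, must be present in `table`.
#' @param table an [extinction_table()].
#' @return absorption coefficient in 1/mm.
#' @export
mua_from_chromophores <- function(hbo2, hhb, wavelength,
                                  table = extinction_table()) {
  eps <- .eps_at(table, wavelength)
  log(10) * (eps[["hbo2"]] * hbo2 + eps[["hhb"]] * hhb)
}

#' Hemoglobin concentrations and StO2 from a two-wavelength absorption pair
#'
#' Solves the 2x2 linear system of the Beer-Lambert forward map at 690 and
#' 830 nm for oxy- and deoxy-hemoglobin concentration, and derives total
#' hemoglobin and tissue oxygen saturation. Solutions with a negative
#' concentration are returned flagged (`physical = FALSE`) rather than
#' clipped, so downstream code can exclude them without biasing difference
#' traces.
#'
#' @param mua_690,mua_830 absorption coefficients, 1/mm, both positive.
#' @param table an [extinction_table()].
#' @return an object of class `chromophore_state`: a list with `hbo2`,
#'   `hhb`, `hbt` (mM), `sto2` (fraction) and `physical` (logical).
#' @export
chromophores_from_mua <- function(mua_690, mua_830,
                                  table = extinction_table()) {
  if (!is.finite(mua_690) || !is.finite(mua_830) || mua_690 <= 0 || mua_830 <= 0)
    stop("both absorption coefficients must be positive")
  E <- rbind(.eps_at(table, 690), .eps_at(table, 830)) * log(10)
  if (abs(det(E)) < 1e-12) stop("singular extinction matrix")
  conc <- solve(E, c(mua_690, mua_830))
  hbo2 <- conc[[1]]; hhb <- conc[[2]]
  hbt <- hbo2 + hhb
  structure(list(hbo2 = hbo2, hhb = hhb, hbt = hbt,
                 sto2 = if (hbt != 0) hbo2 / hbt else NA_real_,
                 physical = hbo2 >= 0 && hhb >= 0),
            class = "chromophore_state")
}

#' @export
print.chromophore_state <- function(x, ...) {
  cat(sprintf("[HbO2] %.4f mM, [Hhb] %.4f mM, [HbT] %.4f mM, StO2 %.1f%%%s\n",
              x$hbo2, x$hhb, x$hbt, 100 * x$sto2,
              if (x$physical) "" else " [non-physical, flagged]"))
  invisible(x)
}

#' Average the reduced scattering coefficient across TRS wavelengths
#'
#' The DCS model consumes a single scattering coefficient; the convention is
#' the arithmetic mean over the fitted TRS wavelengths. If one wavelength is
#' missing the available one is returned with a warning.
#'
#' @param props_690,props_830 [optical_properties()] or NULL when missing.
#' @return mean reduced scattering coefficient, 1/mm.
#' @export
average_musp <- function(props_690, props_830) {
  m1 <- if (!is.null(props_690)) props_690$musp else NA_real_
  m2 <- if (!is.null(props_830)) props_830$musp else NA_real_
  if (is.na(m1) && is.na(m2)) stop("no valid scattering fit at either wavelength")
  if (is.na(m1) || is.na(m2)) {
    warning("musp available at one wavelength only; falling back to it")
    return(ifelse(is.na(m1), m2, m1))
  }
  (m1 + m2) / 2
}

#' Absorption at the DCS wavelength from the fitted TRS pair
#'
#' @param mua_690,mua_830 fitted absorptions, 1/mm.
#' @param method `"mean"` (arithmetic mean, default, parallel to the musp
#'   averaging convention) or `"interp"` (linear interpolation in wavelength).
#' @param target_nm DCS wavelength (default 785).
#' @return absorption coefficient at the DCS wavelength, 1/mm.
#' @export
mua_for_dcs <- function(mua_690, mua_830, method = c("mean", "interp"),
                        target_nm = 785) {
  method <- match.arg(method)
  if (method == "mean") return((mua_690 + mua_830) / 2)
  mua_690 + (mua_830 - mua_690) * (target_nm - 690) / (830 - 690)
}

# Fit window on a measured DTOF: from rise_frac of peak height on the rising
# edge to tail_frac of peak height on the falling tail. Returns 1-based
# inclusive indices.
.dtof_fit_window <- function(counts, rise_frac = 0.8, tail_frac = 0.01) {
  pk <- which.max(counts)
  mx <- counts[pk]
  lo <- which(counts[seq_len(pk)] >= rise_frac * mx)[1]
  after <- which(counts >= tail_frac * mx)
  hi <- max(after[after >= pk])
  c(lo = lo, hi = hi)
}

#' Fit a measured DTOF for absolute optical properties
#'
#' Poisson-weighted least-squares fit of the semi-infinite time-domain
#' diffusion model, convolved with the measured instrument response
#' function, to a photon time-of-flight histogram. The amplitude is profiled
#' analytically and a temporal shift between IRF and DTOF is fitted as an
#' additional nuisance parameter. The fit window runs from `window[1]` of
#' the peak height on the rising edge to `window[2]` on the falling tail,
#' so that early non-diffusive photons are excluded.
#'
#' Non-convergence or a fit at the parameter bounds does not raise an error:
#' the returned object carries `converged`/`flagged` fields so that bad
#' records can be excluded downstream.
#'
#' @param dtof a [dtof_record()].
#' @param irf an [irf_record()] with the same bin width and wavelength.
#' @param geom a [medium_geometry()] (TRS separation, refractive indices).
#' @param window length-2 fractions of peak height delimiting the fit window.
#' @param subtract_background estimate the dark-count level from the
#'   pre-pulse bins (same window rule as [trs_snr()]) and subtract it before
#'   fitting (default TRUE).
#' @param fit_shift fit a fractional-bin temporal shift (default TRUE).
#' @param start named list of starting values, `mua` and `musp` (1/mm).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return an object of class `dtof_fit` with components `props`
#'   ([optical_properties()]), `amplitude`, `shift_ps`, `converged`,
#'   `flagged`, and `diagnostics`.
#' @seealso [fit_g2()] for the DCS counterpart.
#' @export
fit_dtof <- function(dtof, irf, geom, window = c(0.8, 0.01),
                     subtract_background = TRUE, fit_shift = TRUE,
                     start = list(mua = 0.01, musp = 1.0),
                     max_iter = 100L) {
  stopifnot(inherits(dtof, "dtof_record"), inherits(irf, "irf_record"),
            inherits(geom, "medium_geometry"))
  if (!isTRUE(all.equal(dtof$bin_width_ps, irf$bin_width_ps)))
    stop("DTOF and IRF bin widths differ")
  if (dtof$wavelength != irf$wavelength)
    stop("DTOF and IRF wavelengths differ")

  n <- length(dtof$counts)
  t_ps <- (seq_len(n) - 0.5) * dtof$bin_width_ps
  counts <- dtof$counts
  bg_level <- 0
  if (subtract_background) {
    i_half <- which(counts >= 0.5 * max(counts))[1]
    n_bg <- max(20L, floor(0.1 * (i_half - 1)))
    if (n_bg < i_half) {
      bg_level <- mean(counts[seq_len(n_bg)])
      counts <- pmax(counts - bg_level, 0)
    }
  }
  win <- .dtof_fit_window(counts, window[1], window[2])
  failed <- function(reason) {
    structure(list(props = NULL, amplitude = NA_real_, shift_ps = NA_real_,
                   converged = FALSE, flagged = TRUE,
                   diagnostics = list(reason = reason, window = win),
                   record = dtof),
              class = "dtof_fit")
  }
  if (!is.finite(win["lo"]) || win["hi"] - win["lo"] < 10L)
    return(failed("fit window too short"))
  if (sum(counts) < 1000)
    return(failed("too few counts"))

  reff <- effective_reflection(geom$n_tissue, geom$n_outside)
  v <- .C_MM_PER_PS / geom$n_tissue
  zbf <- (2 / 3) * (1 + reff) / (1 - reff)
  irf_n <- irf$counts / sum(irf$counts)
  # initialize the shift by aligning the model and measured peaks
  shift0 <- 0
  if (fit_shift) {
    m0 <- .cpp_td_reflectance(t_ps, start$mua, start$musp, geom$rho, v,
                              1 / start$musp, zbf / start$musp)
    c0 <- .cpp_conv_causal(m0, irf_n)
    shift0 <- (which.max(counts) - which.max(c0)) * dtof$bin_width_ps
    if (abs(shift0) > 45 * dtof$bin_width_ps)
      return(failed("model and measured peaks misaligned beyond shift range"))
  }
  res <- .cpp_fit_dtof(counts, irf_n, t_ps, dtof$bin_width_ps,
                       geom$rho, v, 1.0, zbf,
                       win[["lo"]] - 1L, win[["hi"]] - 1L,
                       start$mua, start$musp, shift0, fit_shift,
                       as.integer(max_iter))
  at_bounds <- res$mua < 2e-6 || res$mua > 0.5 ||
    res$musp < 0.01 || res$musp > 25
  flagged <- !isTRUE(res$converged) || at_bounds
  props <- if (!flagged)
    optical_properties(dtof$wavelength, res$mua, res$musp) else NULL
  structure(list(props = props, amplitude = res$amplitude,
                 shift_ps = res$shift_ps, converged = isTRUE(res$converged),
                 flagged = flagged,
                 diagnostics = list(cost = res$cost,
                                    iterations = res$iterations,
                                    n_fit = res$n_fit, window = win,
                                    background = bg_level,
                                    mua = res$mua, musp = res$musp),
                 record = dtof, irf = irf, geom = geom),
            class = "dtof_fit")
}

#' @export
coef.dtof_fit <- function(object, ...) {
  c(mua = if (is.null(object$props)) NA_real_ else object$props$mua,
    musp = if (is.null(object$props)) NA_real_ else object$props$musp,
    amplitude = object$amplitude, shift_ps = object$shift_ps)
}

#' @export
print.dtof_fit <- function(x, ...) {
  if (x$flagged) {
    cat("DTOF fit: flagged (",
        if (!is.null(x$diagnostics$reason)) x$diagnostics$reason
        else "non-convergence or bounds", ")\n", sep = "")
  } else {
    cat(sprintf("DTOF fit @ %g nm: mua = %.5f /mm, musp = %.3f /mm (shift %.1f ps, %d bins)\n",
                x$record$wavelength, x$props$mua, x$props$musp, x$shift_ps,
                x$diagnostics$n_fit))
  }
  invisible(x)
}

#' @export
fitted.dtof_fit <- function(object, ...) {
  if (object$flagged) return(rep(NA_real_, length(object$record$counts)))
  n <- length(object$record$counts)
  t_ps <- (seq_len(n) - 0.5) * object$record$bin_width_ps
  m <- td_reflectance(object$props, object$geom, t_ps)
  cv <- convolve_with_irf(m, object$irf$counts / sum(object$irf$counts),
                          object$record$bin_width_ps)
  s <- object$shift_ps / object$record$bin_width_ps
  x <- seq_len(n) - 1 - s
  shifted <- stats::approx(seq_len(n) - 1, cv, xout = x, yleft = 0,
                           yright = 0)$y
  object$amplitude * shifted
}

#' @export
residuals.dtof_fit <- function(object, ...) {
  object$record$counts - object$diagnostics$background - fitted(object)
}

#' @export
plot.dtof_fit <- function(x, ...) {
  n <- length(x$record$counts)
  t_ns <- (seq_len(n) - 0.5) * x$record$bin_width_ps / 1000
  graphics::plot(t_ns, pmax(x$record$counts, 0.5), log = "y", type = "s",
                 xlab = "time (ns)", ylab = "counts",
                 main = "DTOF fit", ...)
  if (!x$flagged)
    graphics::lines(t_ns, pmax(fitted(x), 0.5), col = 2, lwd = 2)
  invisible(x)
}

#' Fit an intensity autocorrelation curve for the blood-flow index
#'
#' Joint least squares over the blood-flow index and the coherence factor
#' beta (the amplitude nuisance of the Siegert relation), using the
#' semi-infinite correlation diffusion model with TRS-derived optical
#' properties. The fit range runs from the smallest measured lag to the lag
#' where the plateau-normalized `g2 - 1` falls below `range_floor`.
#'
#' @param rec a [g2_record()].
#' @param props_dcs [optical_properties()] at the DCS wavelength, typically
#'   built from the TRS fits via [average_musp()] and [mua_for_dcs()].
#' @param geom [medium_geometry()] for the DCS separation.
#' @param range_floor fraction of the plateau below which lags are dropped
#'   from the fit (default 0.03).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return an object of class `g2_fit` with `bfi` (cm^2/s), `beta`,
#'   `converged`, `flagged` and `diagnostics`.
#' @export
fit_g2 <- function(rec, props_dcs, geom, range_floor = 0.03,
                   max_iter = 100L) {
  stopifnot(inherits(rec, "g2_record"),
            inherits(props_dcs, "optical_properties"),
            inherits(geom, "medium_geometry"))
  failed <- function(reason) {
    structure(list(bfi = NA_real_, beta = NA_real_, converged = FALSE,
                   flagged = TRUE, diagnostics = list(reason = reason),
                   record = rec),
              class = "g2_fit")
  }
  beta0 <- mean(utils::head(rec$g2, 3)) - 1
  if (!is.finite(beta0) || beta0 < 0.02)
    return(failed("no measurable correlation (flat g2)"))
  beta0 <- min(max(beta0, 0.05), 0.99)
  norm <- (rec$g2 - 1) / beta0
  below <- which(norm < range_floor)
  hi <- if (length(below)) max(min(below), 5L) else length(rec$tau)
  sel <- seq_len(min(hi, length(rec$tau)))
  if (length(sel) < 5L) return(failed("fewer than 5 usable lags"))

  k0 <- 2 * pi * geom$n_tissue / (785e-6)
  b <- .boundary_lengths(props_dcs$musp, geom)
  r1 <- sqrt(geom$rho^2 + b$z0^2)
  # crude single-exponential guess for the starting BFI from the half-decay lag
  K0 <- sqrt(3 * props_dcs$mua * props_dcs$musp)
  i_half <- which(norm[sel] < 0.25)
  tau_half <- if (length(i_half)) rec$tau[sel][i_half[1]] else
    rec$tau[length(sel)]
  bfi0 <- ((K0 + log(2) / r1)^2 - K0^2) /
    (6 * props_dcs$musp^2 * k0^2 * max(tau_half, 1e-8))
  bfi0 <- min(max(bfi0, 1e-9), 1e-2)  # mm^2/s

  res <- .cpp_fit_g2(rec$tau[sel], rec$g2[sel], props_dcs$mua,
                     props_dcs$musp, k0, geom$rho, b$z0, b$zb, bfi0, beta0,
                     as.integer(max_iter))
  flagged <- !isTRUE(res$converged) || res$beta <= 0.01 || res$beta > 1.05 ||
    res$bfi_mm2s <= 2e-12 || res$bfi_mm2s >= 1e2
  structure(list(bfi = res$bfi_mm2s / 100, beta = res$beta,
                 converged = isTRUE(res$converged), flagged = flagged,
                 diagnostics = list(cost = res$cost,
                                    iterations = res$iterations,
                                    n_fit = res$n_fit, bfi0 = bfi0 / 100,
                                    beta0 = beta0),
                 record = rec, props = props_dcs, geom = geom),
            class = "g2_fit")
}

#' @export
coef.g2_fit <- function(object, ...) {
  c(bfi = object$bfi, beta = object$beta)
}

#' @export
print.g2_fit <- function(x, ...) {
  if (x$flagged) {
    cat("g2 fit: flagged (",
        if (!is.null(x$diagnostics$reason)) x$diagnostics$reason
        else "non-convergence or bounds", ")\n", sep = "")
  } else {
    cat(sprintf("g2 fit: BFI = %.3e cm^2/s, beta = %.3f (%d lags)\n",
                x$bfi, x$beta, x$diagnostics$n_fit))
  }
  invisible(x)
}

#' @export
fitted.g2_fit <- function(object, ...) {
  if (object$flagged) return(rep(NA_real_, length(object$record$tau)))
  cfg <- dcs_config(bfi = object$bfi, beta = min(object$beta, 1))
  g1 <- dcs_g1(object$props, object$geom, cfg, object$record$tau)
  1 + object$beta * g1^2
}

#' @export
plot.g2_fit <- function(x, ...) {
  graphics::plot(x$record$tau, x$record$g2, log = "x", xlab = "lag (s)",
                 ylab = "g2", main = "g2 fit", ...)
  if (!x$flagged) graphics::lines(x$record$tau, fitted(x), col = 2, lwd = 2)
  invisible(x)
}
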