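# Closed-form photon-transport forward models for a semi-infinite
# homogeneous medium: time-domain diffuse reflectance (TRS), the normalized
# field autocorrelation (DCS), the Siegert relation, and IRF convolution.

#' Speed of light in vacuum, mm per picosecond
#' @keywords internal
.C_MM_PER_PS <- 0.299792458

#' Optical properties of a homogeneous tissue volume
#'
#' Absorption and reduced scattering coefficients at one wavelength. The
#' diffusion approximation underlying all forward models in this package
#' requires scattering to dominate absorption; when `musp <= mua` the object
#' is still created but carries `diffusion_valid = FALSE` and a warning is
#' raised.
#'
#' @param wavelength wavelength in nm.
#' @param mua absorption coefficient, 1/mm. Must be positive.
#' @param musp reduced scattering coefficient, 1/mm. Must be positive.
#' @return an object of class `optical_properties`.
#' @examples
#' optical_properties(830, mua = 0.01, musp = 1.0)
#' @export
optical_properties <- function(wavelength, mua, musp) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0)
  if (!is.numeric(mua) || length(mua) != 1L || !is.finite(mua) || mua <= 0)
    stop("'mua' must be a single positive number (1/mm)")
  if (!is.numeric(musp) || length(musp) != 1L || !is.finite(musp) || musp <= 0)
    stop("'musp' must be a single positive number (1/mm)")
  valid <- musp > mua
  if (!valid)
    warning("musp <= mua: outside the diffusion regime, forward models are unreliable")
  structure(list(wavelength = wavelength, mua = mua, musp = musp,
                 diffusion_valid = valid),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("Optical properties @ %g nm: mua = %.5g /mm, musp = %.5g /mm%s\n",
              x$wavelength, x$mua, x$musp,
              if (x$diffusion_valid) "" else " [diffusion regime violated]"))
  invisible(x)
}

#' Probe and medium geometry for a semi-infinite reflectance measurement
#'
#' @param rho source-detector separation on the surface, mm.
#' @param n_tissue tissue refractive index (default 1.4, the conventional
#'   value for soft tissue).
#' @param n_outside refractive index of the outside medium (default 1.0, air).
#' @return an object of class `medium_geometry`.
#' @export
medium_geometry <- function(rho, n_tissue = 1.4, n_outside = 1.0) {
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0,
            is.numeric(n_tissue), n_tissue >= 1,
            is.numeric(n_outside), n_outside >= 1)
  structure(list(rho = rho, n_tissue = n_tissue, n_outside = n_outside),
            class = "medium_geometry")
}

#' DCS acquisition configuration
#'
#' @param bfi blood-flow index (effective Brownian diffusion coefficient of
#'   the moving scatterers), cm^2/s. Must be non-negative.
#' @param beta coherence factor (the `g2 - 1` plateau at zero lag), in (0, 1].
#' @param wavelength DCS laser wavelength in nm (default 785).
#' @return an object of class `dcs_config`.
#' @export
dcs_config <- function(bfi, beta, wavelength = 785) {
  if (!is.numeric(bfi) || length(bfi) != 1L || !is.finite(bfi) || bfi < 0)
    stop("'bfi' must be a single non-negative number (cm^2/s)")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("'beta' must lie in (0, 1]")
  stopifnot(wavelength > 0)
  structure(list(wavelength = wavelength, bfi = bfi, beta = beta),
            class = "dcs_config")
}

#' Effective reflection coefficient at a refractive-index mismatch
#'
#' Polynomial approximation (Groenhuis et al.) used to place the
#' extrapolated boundary of the semi-infinite diffusion solution.
#'
#' @param n_tissue,n_outside refractive indices of tissue and outside medium.
#' @return effective reflection coefficient, dimensionless.
#' @export
effective_reflection <- function(n_tissue, n_outside = 1.0) {
  n <- n_tissue / n_outside
  -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
}

# Image-source positions for the extrapolated-boundary solution:
# z0 = 1/musp, zb = 2 D (1 + Reff) / (1 - Reff) with D = 1/(3 musp).
.boundary_lengths <- function(musp, geom) {
  reff <- effective_reflection(geom$n_tissue, geom$n_outside)
  z0 <- 1 / musp
  zb <- (2 / (3 * musp)) * (1 + reff) / (1 - reff)
  list(z0 = z0, zb = zb, reff = reff)
}

#' Time-domain diffuse reflectance of a semi-infinite medium
#'
#' Photon time-of-flight density at the surface, from the extrapolated
#' boundary solution of the diffusion equation with two image sources.
#' The amplitude is arbitrary: all downstream fits estimate scale as a
#' nuisance parameter, and only the curve shape carries information about
#' `mua` and `musp`.
#'
#' @param props [optical_properties()].
#' @param geom [medium_geometry()].
#' @param t_ps strictly increasing vector of photon arrival times, ps (> 0).
#' @return numeric vector of the same length as `t_ps`, non-negative.
#' @examples
#' p <- optical_properties(830, 0.01, 1.0)
#' g <- medium_geometry(30)
#' R <- td_reflectance(p, g, seq(100, 8000, by = 25))
#' @export
td_reflectance <- function(props, geom, t_ps) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "medium_geometry"))
  if (length(t_ps) == 0 || any(!is.finite(t_ps)) || any(t_ps <= 0) ||
      any(diff(t_ps) <= 0))
    stop("'t_ps' must be strictly increasing and positive")
  v <- .C_MM_PER_PS / geom$n_tissue
  b <- .boundary_lengths(props$musp, geom)
  .cpp_td_reflectance(as.numeric(t_ps), props$mua, props$musp, geom$rho, v,
                      b$z0, b$zb)
}

#' Normalized field autocorrelation for semi-infinite DCS
#'
#' Solution of the correlation diffusion equation for Brownian scatterer
#' dynamics (mean-square displacement `6 * BFI * tau`), normalized to
#' `g1(0) = 1`. A static medium (`bfi = 0`) yields `g1 == 1`.
#'
#' @param props [optical_properties()] at the DCS wavelength.
#' @param geom [medium_geometry()] for the DCS separation.
#' @param cfg [dcs_config()] carrying the blood-flow index.
#' @param tau non-negative, increasing lag grid in seconds.
#' @return numeric vector of `g1` values in `[0, 1]`.
#' @export
dcs_g1 <- function(props, geom, cfg, tau) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "medium_geometry"), inherits(cfg, "dcs_config"))
  if (length(tau) == 0 || any(tau < 0) || any(diff(tau) <= 0))
    stop("'tau' must be non-negative and increasing")
  k0 <- 2 * pi * geom$n_tissue / (cfg$wavelength * 1e-6)  # 1/mm
  b <- .boundary_lengths(props$musp, geom)
  .cpp_dcs_g1(as.numeric(tau), props$mua, props$musp, k0,
              cfg$bfi * 100, geom$rho, b$z0, b$zb)  # cm^2/s -> mm^2/s
}

#' Siegert relation
#'
#' Maps the field autocorrelation to the measured intensity autocorrelation,
#' `g2 = 1 + beta * g1^2`.
#'
#' @param g1 field autocorrelation values in `[0, 1]`.
#' @param beta coherence factor in (0, 1].
#' @return `g2` values in `[1, 1 + beta]`.
#' @export
siegert_g2 <- function(g1, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("'beta' must lie in (0, 1]")
  if (any(g1 < -1e-9 | g1 > 1 + 1e-9))
    stop("'g1' values must lie in [0, 1]")
  1 + beta * g1^2
}

#' Convolve a model DTOF with a measured instrument response function
#'
#' Discrete causal convolution truncated to the model length, used to map a
#' tissue forward model into the measured-histogram domain before fitting.
#' Convolving with a unit impulse at the first bin returns the input.
#'
#' @param model_curve model photon time-of-flight density, one value per bin.
#' @param irf instrument response function on the same bin width.
#' @param bin_width_ps histogram bin width of `model_curve`, ps.
#' @param irf_bin_width_ps bin width of `irf`; must equal `bin_width_ps`.
#' @return numeric vector with `length(model_curve)` elements.
#' @export
convolve_with_irf <- function(model_curve, irf, bin_width_ps,
                              irf_bin_width_ps = bin_width_ps) {
  if (!isTRUE(all.equal(bin_width_ps, irf_bin_width_ps)))
    stop("model and IRF bin widths differ; rebin before convolving")
  stopifnot(length(model_curve) > 0, length(irf) > 0)
  .cpp_conv_causal(as.numeric(model_curve), as.numeric(irf))
}

#' Late-tail log-slope of a DTOF
#'
#' Estimates the asymptotic decay rate of a time-of-flight curve by linear
#' regression of `log(R(t) * t^(5/2))` against `t` over a late-time window.
#' The `t^(5/2)` factor removes the known diffusive dispersion of the
#' semi-infinite solution so that the slope converges to `-mua * v`
#' (`v = c / n_tissue`), the classic absorption read-out from the tail.
#'
#' @param curve DTOF values.
#' @param t_ps time grid in ps.
#' @param window_ps length-2 vector, time window over which to regress.
#' @param dispersion_correction multiply by `t^(5/2)` before taking the log
#'   (default TRUE). Without it the raw `d log R / dt` is returned, which
#'   approaches `-mua * v` only at much later times.
#' @return slope in 1/ns (negative for a decaying tail).
#' @export
dtof_tail_slope <- function(curve, t_ps, window_ps,
                            dispersion_correction = TRUE) {
  stopifnot(length(curve) == length(t_ps), length(window_ps) == 2L)
  sel <- t_ps >= window_ps[1] & t_ps <= window_ps[2] & curve > 0
  if (sum(sel) < 3L) stop("fewer than 3 positive samples in the tail window")
  y <- log(curve[sel])
  if (dispersion_correction) y <- y + 2.5 * log(t_ps[sel])
  unname(stats::coef(stats::lm(y ~ t_ps[sel]))[2] * 1000)  # per ns
}
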