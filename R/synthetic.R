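# Seeded generator of synthetic transfusion sessions: ground-truth
# physiology with the study's protocol structure and effect sizes, plus
# simulated raw instrument data (photon time-of-flight histograms with
# Poisson noise, intensity autocorrelation curves, vitals, blood gases).

#' Transfusion session protocol
#'
#' Timing of the monitoring protocol: a baseline epoch, the transfusion
#' itself, and a post-transfusion observation epoch, with one arterial blood
#' draw per epoch (the mid draw when half the bag has been transfused).
#'
#' @param baseline_min baseline duration, minutes (default 30).
#' @param transfusion_min transfusion duration, minutes (default 150; the
#'   clinical range is 120-180).
#' @param post_min post-transfusion observation, minutes (default 30).
#' @param draw_offset_min pre/post blood draws are taken this many minutes
#'   into their epoch (default 10).
#' @return a list of class `protocol_spec`.
#' @export
protocol_spec <- function(baseline_min = 30, transfusion_min = 150,
                          post_min = 30, draw_offset_min = 10) {
  stopifnot(baseline_min > 0, transfusion_min > 0, post_min > 0,
            draw_offset_min > 0, draw_offset_min < baseline_min,
            draw_offset_min < post_min)
  t0 <- baseline_min * 60
  t1 <- t0 + transfusion_min * 60
  structure(list(baseline_min = baseline_min,
                 transfusion_min = transfusion_min, post_min = post_min,
                 draw_offset_min = draw_offset_min,
                 transfusion_start = t0, transfusion_end = t1,
                 total_s = t1 + post_min * 60),
            class = "protocol_spec")
}

#' Programmed physiological effects of the transfusion
#'
#' Per-variable, per-location changes applied smoothly (sigmoidal ramp)
#' across the transfusion epoch, with between-subject variation. Defaults
#' are the cohort effect sizes this generator is meant to emulate:
#' peripheral blood flow +68 percent, no cerebral blood-flow change, oxygen
#' extraction fraction down 7 percent (cerebral) and 8 percent (peripheral),
#' a null deoxy-hemoglobin change, and hematocrit up 2.9 percent absolute
#' (24.5 to 27.4 on average). Between-subject SDs are back-solved from the
#' cohort's printed SDs where available, otherwise 30 percent of the mean
#' effect.
#'
#' The primary programmed courses are the extraction fraction (which fixes
#' StO2 given the arterial saturation) and the deoxy-hemoglobin
#' concentration; total and oxy-hemoglobin are derived via
#' `HbT = Hhb / (1 - StO2)`. With the default baselines this implies mean
#' total/oxy-hemoglobin increases of about +0.0042/+0.0042 mM (cerebral)
#' and +0.0034/+0.0034 mM (peripheral); see the methods vignette.
#'
#' @param null_effects when TRUE, every programmed change is zero (noise
#'   only) - used for type-I error calibration.
#' @return a list of class `effect_spec`.
#' @export
effect_spec <- function(null_effects = FALSE) {
  e <- list(
    bf = list(cerebral = c(mean = 0.00, sd = 0.05),
              peripheral = c(mean = 0.68, sd = 0.204)),
    oef = list(cerebral = c(mean = -0.07, sd = 0.021),
               peripheral = c(mean = -0.08, sd = 0.024)),
    dhhb = list(cerebral = c(mean = 0, sd = 0.0023),
                peripheral = c(mean = 0, sd = 0.00035)),
    hct = c(pre_mean = 24.5, pre_sd = 1.6, delta_mean = 2.9, delta_sd = 1.1),
    paco2 = c(pre_mean = 39.4, pre_sd = 4.3, delta_mean = 0.6,
              delta_sd = 1.5),
    sao2 = c(mean = 0.98, sd = 0.005),
    baselines = list(
      sto2 = c(cerebral = 0.65, peripheral = 0.70),
      hbt = c(cerebral = 0.058, peripheral = 0.042),
      bfi = c(cerebral = 1.2e-8, peripheral = 3.0e-9),
      musp830 = c(cerebral = 0.9, peripheral = 0.7)),
    noise = c(ar1_phi = 0.8, sto2_sd = 0.004, hhb_sd = 0.0003,
              bfi_rel_sd = 0.03, sao2_sd = 0.002),
    assay = c(hgb_sd = 0.1, hct_sd = 0.5, paco2_sd = 0.5))
  if (null_effects) {
    for (v in c("bf", "oef", "dhhb"))
      for (loc in c("cerebral", "peripheral"))
        e[[v]][[loc]]["mean"] <- 0
    e$hct["delta_mean"] <- 0
    e$paco2["delta_mean"] <- 0
  }
  structure(e, class = "effect_spec")
}

#' Instrument configuration for raw-data simulation
#'
#' @param trs_rho,dcs_rho source-detector separations, mm (30 and 25).
#' @param bin_ps,n_bins TRS histogram binning (default 25 ps x 400 bins).
#' @param irf_t0_ps,irf_sigma_ps Gaussian IRF position and width, ps.
#' @param total_counts expected photon counts per DTOF (default 5e5).
#' @param background_per_bin expected dark counts per bin (default 2).
#' @param tau DCS lag grid, seconds (default 60 log-spaced lags over
#'   1e-7..1e-2 s, five decades).
#' @param dcs_beta true coherence factor (default 0.5).
#' @param count_rate_khz DCS detector count rate (default 50, well above the
#'   10 kHz rejection threshold).
#' @param g2_noise_scale scale of the lag-dependent Gaussian noise added to
#'   g2 (default 0.005 at the reference 50 kHz count rate).
#' @param acquisition_s acquisition period of both instruments, seconds
#'   (default 10, i.e. 0.1 Hz).
#' @param n_tissue,n_outside refractive indices.
#' @return a list of class `instrument_spec`.
#' @export
instrument_spec <- function(trs_rho = 30, dcs_rho = 25, bin_ps = 25,
                            n_bins = 400, irf_t0_ps = 1250,
                            irf_sigma_ps = 100, total_counts = 5e5,
                            background_per_bin = 2,
                            tau = 10^seq(-7, -2, length.out = 60),
                            dcs_beta = 0.5, count_rate_khz = 50,
                            g2_noise_scale = 0.005, acquisition_s = 10,
                            n_tissue = 1.4, n_outside = 1.0) {
  stopifnot(total_counts > 0, all(diff(tau) > 0),
            log10(max(tau) / min(tau)) >= 4, dcs_beta > 0, dcs_beta <= 1)
  structure(list(trs_rho = trs_rho, dcs_rho = dcs_rho, bin_ps = bin_ps,
                 n_bins = n_bins, irf_t0_ps = irf_t0_ps,
                 irf_sigma_ps = irf_sigma_ps, total_counts = total_counts,
                 background_per_bin = background_per_bin, tau = tau,
                 dcs_beta = dcs_beta, count_rate_khz = count_rate_khz,
                 g2_noise_scale = g2_noise_scale,
                 acquisition_s = acquisition_s, n_tissue = n_tissue,
                 n_outside = n_outside),
            class = "instrument_spec")
}

# Sigmoidal ramp over the transfusion epoch: exactly 0 before the start
# mark, exactly 1 from the end mark on.
.effect_ramp <- function(time, t0, t1, steepness = 8) {
  x <- (time - t0) / (t1 - t0)
  r <- 1 / (1 + exp(-steepness * (x - 0.5)))
  r <- (r - 1 / (1 + exp(steepness / 2))) /
    (1 / (1 + exp(-steepness / 2)) - 1 / (1 + exp(steepness / 2)))
  r[time < t0] <- 0
  r[time >= t1] <- 1
  pmin(pmax(r, 0), 1)
}

.ar1 <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(numeric(n))
  e <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive",
                           init = stats::rnorm(1, sd = sd)))
}

#' Generate ground-truth physiology for one synthetic session
#'
#' Draws subject-level effects around the programmed defaults, then builds
#' smooth time courses (sigmoidal ramp across the transfusion epoch plus
#' AR(1) physiological noise) for StO2, hemoglobin concentrations,
#' blood-flow index, arterial saturation and the per-period blood-gas
#' values. Internally consistent by construction: `[HbT] = [HbO2] + [Hhb]`,
#' StO2 is derived from the programmed extraction-fraction course, and Hgb
#' follows the hematocrit via the MCHC relation.
#'
#' @param protocol [protocol_spec()].
#' @param effects [effect_spec()].
#' @param gamma_venous venous fraction used to map OEF to StO2 (default
#'   0.75, matching the analysis default).
#' @param seed RNG seed; NULL continues the current RNG stream.
#' @param locations probe placements to generate.
#' @return a list of class `synthetic_truth`.
#' @export
make_ground_truth <- function(protocol = protocol_spec(),
                              effects = effect_spec(), gamma_venous = 0.75,
                              seed = NULL,
                              locations = c("cerebral", "peripheral")) {
  if (!is.null(seed)) set.seed(seed)
  acq <- 10
  tt <- seq(acq / 2, protocol$total_s, by = acq)
  t0 <- protocol$transfusion_start
  t1 <- protocol$transfusion_end
  ramp <- .effect_ramp(tt, t0, t1)
  nz <- effects$noise
  draw1 <- function(spec) stats::rnorm(1, spec[["mean"]], spec[["sd"]])

  sao2_base <- min(max(draw1(effects$sao2), 0.85), 1.0)
  sao2 <- pmin(sao2_base + .ar1(length(tt), nz[["sao2_sd"]],
                                nz[["ar1_phi"]]), 1)
  hct_pre <- draw1(c(mean = effects$hct[["pre_mean"]],
                     sd = effects$hct[["pre_sd"]]))
  hct_delta <- draw1(c(mean = effects$hct[["delta_mean"]],
                       sd = effects$hct[["delta_sd"]]))
  hct <- c(pre = hct_pre, mid = hct_pre + hct_delta / 2,
           post = hct_pre + hct_delta)
  paco2_pre <- draw1(c(mean = effects$paco2[["pre_mean"]],
                       sd = effects$paco2[["pre_sd"]]))
  paco2_delta <- draw1(c(mean = effects$paco2[["delta_mean"]],
                         sd = effects$paco2[["delta_sd"]]))

  draws <- list(sao2 = sao2_base, hct_pre = hct_pre, hct_delta = hct_delta,
                paco2_pre = paco2_pre, paco2_delta = paco2_delta)
  locs <- list()
  clipped <- FALSE
  for (loc in locations) {
    bf_ch <- draw1(effects$bf[[loc]])
    oef_ch <- draw1(effects$oef[[loc]])
    dhhb <- draw1(effects$dhhb[[loc]])
    sto2_0 <- effects$baselines$sto2[[loc]]
    hbt_0 <- effects$baselines$hbt[[loc]]
    bfi_0 <- effects$baselines$bfi[[loc]]
    oef_0 <- (1 - sto2_0 / sao2_base) / gamma_venous
    oef_t <- oef_0 * (1 + oef_ch * ramp)
    sto2 <- sao2_base * (1 - gamma_venous * oef_t) +
      .ar1(length(tt), nz[["sto2_sd"]], nz[["ar1_phi"]])
    if (any(sto2 <= 0.02) || any(sto2 >= 0.95)) {
      clipped <- TRUE
      sto2 <- pmin(pmax(sto2, 0.02), 0.95)
    }
    # deoxy-hemoglobin is programmed (null change by default); total and
    # oxy-hemoglobin follow from the saturation
    hhb_0 <- (1 - sto2_0) * hbt_0
    hhb <- hhb_0 + dhhb * ramp +
      .ar1(length(tt), nz[["hhb_sd"]], nz[["ar1_phi"]])
    hhb <- pmax(hhb, 1e-4)
    hbt <- hhb / (1 - sto2)
    bfi <- bfi_0 * (1 + bf_ch * ramp) *
      pmax(1 + .ar1(length(tt), nz[["bfi_rel_sd"]], nz[["ar1_phi"]]), 0.05)
    locs[[loc]] <- list(sto2 = sto2, hbt = hbt, hbo2 = hbt - hhb,
                        hhb = hhb, bfi = bfi, oef = oef_t,
                        draws = list(bf_change = bf_ch, oef_change = oef_ch,
                                     dhhb = dhhb))
  }
  if (clipped)
    warning("StO2 course hit physiological bounds and was clipped")
  events <- data.frame(
    time = c(t0, t1,
             protocol$draw_offset_min * 60, (t0 + t1) / 2,
             t1 + protocol$draw_offset_min * 60),
    label = c("transfusion_start", "transfusion_end",
              "blood_draw", "blood_draw", "blood_draw"))
  structure(list(time = tt, locations = locs, sao2 = sao2, hct = hct,
                 hgb = hgb_from_hct(hct), paco2 = c(pre = paco2_pre,
                                                    mid = paco2_pre + paco2_delta / 2,
                                                    post = paco2_pre + paco2_delta),
                 events = events, protocol = protocol, draws = draws,
                 gamma_venous = gamma_venous),
            class = "synthetic_truth")
}

# Expected (noise-free) DTOF shape for given chromophores, scaled to the
# configured total counts plus background.
.expected_dtof <- function(hbo2, hhb, wavelength, musp, geom, irf_n, t_ps,
                           total_counts, bg, table) {
  mua <- mua_from_chromophores(hbo2, hhb, wavelength, table)
  props <- optical_properties(wavelength, mua, musp)
  m <- td_reflectance(props, geom, t_ps)
  cv <- .cpp_conv_causal(m, irf_n)
  total_counts * cv / sum(cv) + bg
}

#' Simulate raw instrument data from a ground truth
#'
#' For every acquisition: hemoglobin concentrations are mapped to absorption
#' via the extinction table, the time-domain forward model is convolved with
#' the instrument response function and Poisson photon noise is applied; the
#' blood-flow index is mapped to g2 through the correlation diffusion model
#' and the Siegert relation, with lag-dependent Gaussian noise scaled
#' inversely with the square root of the detector count rate. Blood gases
#' are read from the truth at the draw times with assay noise; event marks
#' are emitted for the transfusion start/end and the draws.
#'
#' @param truth a [make_ground_truth()] result.
#' @param instrument an [instrument_spec()].
#' @param effects the [effect_spec()] that produced `truth` (supplies
#'   baselines and assay noise).
#' @param seed RNG seed; NULL continues the current stream.
#' @param subject_id identifier stamped into the bundle.
#' @param locations placements to simulate (subset of the truth's).
#' @param include_post_draw emit the post-transfusion blood draw (FALSE
#'   mimics a subject whose final draw was skipped).
#' @return a list of class `session_bundle`.
#' @export
simulate_raw <- function(truth, instrument = instrument_spec(),
                         effects = effect_spec(), seed = NULL,
                         subject_id = "S01",
                         locations = names(truth$locations),
                         include_post_draw = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ins <- instrument
  tab <- extinction_table()
  t_ps <- (seq_len(ins$n_bins) - 0.5) * ins$bin_ps
  irf_shape <- stats::dnorm(t_ps, ins$irf_t0_ps, ins$irf_sigma_ps)
  geom_trs <- medium_geometry(ins$trs_rho, ins$n_tissue, ins$n_outside)
  geom_dcs <- medium_geometry(ins$dcs_rho, ins$n_tissue, ins$n_outside)
  idx <- seq(1, length(truth$time),
             by = max(1L, round(ins$acquisition_s / 10)))
  tt <- truth$time[idx]

  trs <- list(); dcs <- list()
  for (loc in locations) {
    L <- truth$locations[[loc]]
    musp830 <- effects$baselines$musp830[[loc]]
    musp <- c("690" = musp830 * 830 / 690, "785" = musp830 * 830 / 785,
              "830" = musp830)
    irf <- list()
    counts <- list()
    for (wl in c(690, 830)) {
      irf[[as.character(wl)]] <-
        as.numeric(stats::rpois(ins$n_bins, 1e6 * irf_shape / sum(irf_shape)))
      cm <- matrix(0L, nrow = length(idx), ncol = ins$n_bins)
      irf_n <- irf_shape / sum(irf_shape)
      for (i in seq_along(idx)) {
        j <- idx[i]
        ex <- .expected_dtof(L$hbo2[j], L$hhb[j], wl,
                             musp[[as.character(wl)]], geom_trs, irf_n,
                             t_ps, ins$total_counts, ins$background_per_bin,
                             tab)
        cm[i, ] <- stats::rpois(ins$n_bins, ex)
      }
      counts[[as.character(wl)]] <- cm
    }
    trs[[loc]] <- list(time = tt, bin_ps = ins$bin_ps,
                       wavelengths = c(690, 830), irf = irf, counts = counts)

    g2m <- matrix(0, nrow = length(idx), ncol = length(ins$tau))
    cr <- rep(ins$count_rate_khz, length(idx))
    k0 <- 2 * pi * ins$n_tissue / 785e-6
    b <- .boundary_lengths(musp[["785"]], geom_dcs)
    for (i in seq_along(idx)) {
      j <- idx[i]
      mua785 <- mua_from_chromophores(L$hbo2[j], L$hhb[j], 785, tab)
      g1 <- .cpp_dcs_g1(ins$tau, mua785, musp[["785"]], k0, L$bfi[j] * 100,
                        ins$dcs_rho, b$z0, b$zb)
      g2 <- 1 + ins$dcs_beta * g1^2
      sdv <- ins$g2_noise_scale * sqrt(50 / cr[i]) * (0.3 + g1)
      g2m[i, ] <- g2 + stats::rnorm(length(g2), sd = sdv)
    }
    dcs[[loc]] <- list(time = tt, tau = ins$tau, count_rate_khz = cr,
                       g2 = g2m)
  }

  # vitals at 1 Hz, linearly interpolated from the truth grid
  vt <- seq(0, truth$protocol$total_s - 1, by = 1)
  sao2_v <- stats::approx(truth$time, truth$sao2, xout = vt, rule = 2)$y
  vitals <- data.frame(
    time = vt, sao2 = sao2_v,
    map = 85 + .ar1(length(vt), 3, 0.995),
    hr = 75 + .ar1(length(vt), 4, 0.995))

  draws <- truth$events[truth$events$label == "blood_draw", "time"]
  periods <- c("pre", "mid", "post")
  keep <- if (include_post_draw) 1:3 else 1:2
  asn <- effects$assay
  bg <- blood_gas(
    time = draws[keep], period = periods[keep],
    hgb = truth$hgb[keep] + stats::rnorm(length(keep), sd = asn[["hgb_sd"]]),
    hct = truth$hct[keep] + stats::rnorm(length(keep), sd = asn[["hct_sd"]]),
    paco2 = truth$paco2[keep] +
      stats::rnorm(length(keep), sd = asn[["paco2_sd"]]))

  structure(list(subject_id = subject_id,
                 geometry = list(trs_rho = ins$trs_rho,
                                 dcs_rho = ins$dcs_rho,
                                 n_tissue = ins$n_tissue,
                                 n_outside = ins$n_outside),
                 trs = trs, dcs = dcs, vitals = vitals, bloodgas = bg,
                 events = truth$events,
                 masks = artifact_mask(numeric(), numeric()),
                 meta = list(seed = seed, acquisition_s = ins$acquisition_s,
                             dcs_beta = ins$dcs_beta)),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %s: locations %s, %d TRS acquisitions\n",
              x$subject_id, paste(names(x$trs), collapse = "/"),
              if (length(x$trs)) length(x$trs[[1]]$time) else 0L))
  invisible(x)
}

#' Simulate one complete synthetic session (truth + raw bundle)
#'
#' @inheritParams simulate_raw
#' @inheritParams make_ground_truth
#' @param include_cerebral simulate the cerebral placement (FALSE mimics a
#'   discarded cerebral probe).
#' @return list with elements `bundle` and `truth`.
#' @export
simulate_session <- function(protocol = protocol_spec(),
                             effects = effect_spec(),
                             instrument = instrument_spec(), seed = 1L,
                             subject_id = "S01", include_cerebral = TRUE,
                             include_post_draw = TRUE) {
  set.seed(seed)
  truth <- make_ground_truth(protocol, effects, seed = NULL)
  locs <- if (include_cerebral) c("cerebral", "peripheral") else "peripheral"
  bundle <- simulate_raw(truth, instrument, effects, seed = NULL,
                         subject_id = subject_id, locations = locs,
                         include_post_draw = include_post_draw)
  list(bundle = bundle, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Independent per-subject seeds are derived from the master seed, so the
#' cohort is reproducible as a whole. With `missingness = TRUE` the first
#' two subjects lack the cerebral placement and the third lacks the
#' post-transfusion blood draw, mimicking a realistic pilot cohort.
#'
#' @param n_subjects cohort size (default 14).
#' @inheritParams simulate_session
#' @param missingness apply the missing-placement pattern (default FALSE).
#' @return a list of class `synthetic_cohort` with `bundles`, `truths`,
#'   `seed`.
#' @export
generate_cohort <- function(n_subjects = 14, protocol = protocol_spec(),
                            effects = effect_spec(),
                            instrument = instrument_spec(), seed = 1L,
                            missingness = FALSE) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  bundles <- vector("list", n_subjects)
  truths <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    ses <- simulate_session(protocol, effects, instrument,
                            seed = sub_seeds[i], subject_id = sid,
                            include_cerebral = !(missingness && i <= 2),
                            include_post_draw = !(missingness && i == 3))
    bundles[[i]] <- ses$bundle
    truths[[i]] <- ses$truth
  }
  names(bundles) <- names(truths) <- vapply(bundles, `[[`, "", "subject_id")
  structure(list(bundles = bundles, truths = truths, seed = seed,
                 missingness = missingness),
            class = "synthetic_cohort")
}

#' Truth-level subject session (optics bypassed)
#'
#' Converts a [make_ground_truth()] result directly into a processed
#' `subject_session` on the 10-s base, skipping raw-data simulation and
#' inverse fitting. Used for fast statistical calibration (e.g. type-I
#' error of the battery under a null cohort) where the optical chain is not
#' under study.
#'
#' @param truth a [make_ground_truth()] result.
#' @param subject_id identifier.
#' @return a `subject_session` with the same derived traces the full
#'   pipeline would produce.
#' @export
truth_session <- function(truth, subject_id = "S01") {
  traces <- list()
  sao2_tr <- hemo_trace(truth$time, truth$sao2, "sao2", "systemic")
  for (loc in names(truth$locations)) {
    L <- truth$locations[[loc]]
    for (v in c("hbo2", "hhb", "hbt", "sto2", "bfi"))
      traces[[paste(loc, v, sep = ".")]] <-
        hemo_trace(truth$time, L[[v]], v, loc)
  }
  vitals <- data.frame(time = truth$time, sao2 = truth$sao2,
                       map = NA_real_, hr = NA_real_)
  draws <- truth$events[truth$events$label == "blood_draw", "time"]
  bg <- blood_gas(time = draws, period = c("pre", "mid", "post"),
                  hgb = unname(truth$hgb), hct = unname(truth$hct),
                  paco2 = unname(truth$paco2))
  ses <- synchronize(traces, vitals, truth$events, bg,
                     subject_id = subject_id)
  derive_session_biomarkers(ses, gamma_venous = truth$gamma_venous)
}
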