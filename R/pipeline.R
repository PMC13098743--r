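# Orchestration: per-session inverse fitting with QC, biomarker derivation,
# and the cohort-level statistical battery.

#' Run configuration
#'
#' Every threshold and constant of the analysis in one place; defaults are
#' the study values. The full configuration is echoed into analysis outputs.
#'
#' @param snr_threshold TRS rejection threshold (records kept when SNR is
#'   strictly greater, default 10).
#' @param dcs_min_count_rate_khz,dcs_min_beta DCS rejection thresholds.
#' @param dcs_qc_mode `"or"` (default) or `"and"`, see [qc_dcs()].
#' @param gamma_venous venous fraction of the OEF estimate.
#' @param k,mchc physiological constants, see [physio_constants()].
#' @param post_window_s post-transfusion analysis window length (360 s).
#' @param bin_s master time base (10 s).
#' @param alpha significance level.
#' @param directions expected test direction per variable.
#' @param exact_n_max largest n using the exact signed-rank null.
#' @param fit_window DTOF fit window as fractions of peak height.
#' @param fit_shift fit the IRF-DTOF shift nuisance.
#' @param mua_dcs_method `"mean"` or `"interp"`, see [mua_for_dcs()].
#' @param impute_hct_tol donor-matching tolerance for [impute_post_hct()].
#' @return a list of class `rbct_config`.
#' @export
rbct_config <- function(snr_threshold = 10, dcs_min_count_rate_khz = 10,
                        dcs_min_beta = 0.4, dcs_qc_mode = "or",
                        gamma_venous = 0.75, k = 1.36, mchc = 340,
                        post_window_s = 360, bin_s = 10, alpha = 0.05,
                        directions = rbct_directions(), exact_n_max = 25L,
                        fit_window = c(0.8, 0.01), fit_shift = TRUE,
                        mua_dcs_method = "mean", impute_hct_tol = 0.5) {
  structure(list(snr_threshold = snr_threshold,
                 dcs_min_count_rate_khz = dcs_min_count_rate_khz,
                 dcs_min_beta = dcs_min_beta, dcs_qc_mode = dcs_qc_mode,
                 gamma_venous = gamma_venous, k = k, mchc = mchc,
                 post_window_s = post_window_s, bin_s = bin_s, alpha = alpha,
                 directions = directions, exact_n_max = exact_n_max,
                 fit_window = fit_window, fit_shift = fit_shift,
                 mua_dcs_method = mua_dcs_method,
                 impute_hct_tol = impute_hct_tol),
            class = "rbct_config")
}

#' Fit and derive all time series of one session bundle
#'
#' For every TRS acquisition the two DTOFs are QC-checked ([trs_snr()],
#' [qc_trs()]) and fitted ([fit_dtof()]); absorption pairs are converted to
#' hemoglobin concentrations and StO2. Each g2 curve is fitted
#' ([fit_g2()]) with the TRS-derived properties of the same acquisition and
#' QC-checked ([qc_dcs()]). Surviving samples are synchronized onto the
#' 10-s base and all derived biomarkers (OEF, MRO2, relative and difference
#' traces) are computed.
#'
#' @param bundle a `session_bundle` (from [simulate_raw()] or
#'   [read_bundle()]).
#' @param config an [rbct_config()].
#' @return a `subject_session` with derived traces and a `qc` summary table.
#' @export
process_session <- function(bundle, config = rbct_config()) {
  geom_trs <- medium_geometry(bundle$geometry$trs_rho,
                              bundle$geometry$n_tissue,
                              bundle$geometry$n_outside)
  geom_dcs <- medium_geometry(bundle$geometry$dcs_rho,
                              bundle$geometry$n_tissue,
                              bundle$geometry$n_outside)
  tab <- extinction_table()
  traces <- list()
  qc_rows <- list()

  for (loc in names(bundle$trs)) {
    trs <- bundle$trs[[loc]]
    nt <- length(trs$time)
    mua <- matrix(NA_real_, nt, 2, dimnames = list(NULL, c("690", "830")))
    musp <- mua
    snr_m <- mua
    pass_m <- matrix(FALSE, nt, 2, dimnames = list(NULL, c("690", "830")))
    reason_m <- matrix("ok", nt, 2, dimnames = list(NULL, c("690", "830")))
    for (wl in c("690", "830")) {
      irf <- irf_record(trs$bin_ps, trs$irf[[wl]], as.numeric(wl))
      cm <- trs$counts[[wl]]
      start <- list(mua = 0.01, musp = 1.0)
      for (i in seq_len(nt)) {
        rec <- dtof_record(trs$time[i], as.numeric(wl), trs$bin_ps, cm[i, ],
                           loc)
        s <- trs_snr(rec)
        snr_m[i, wl] <- s
        q <- qc_trs(s, config$snr_threshold)
        if (!q$passed) {
          pass_m[i, wl] <- FALSE; reason_m[i, wl] <- q$reason
          next
        }
        ft <- fit_dtof(rec, irf, geom_trs, window = config$fit_window,
                       fit_shift = config$fit_shift, start = start)
        if (ft$flagged) {
          pass_m[i, wl] <- FALSE; reason_m[i, wl] <- "fit_failure"
          start <- list(mua = 0.01, musp = 1.0)
        } else {
          pass_m[i, wl] <- TRUE
          mua[i, wl] <- ft$props$mua
          musp[i, wl] <- ft$props$musp
          start <- list(mua = ft$props$mua, musp = ft$props$musp)
        }
      }
      qc_rows[[paste(loc, wl)]] <- data.frame(
        subject = bundle$subject_id, location = loc,
        modality = paste0("trs", wl), timestamp = trs$time,
        snr = snr_m[, wl], count_rate = NA_real_, beta = NA_real_,
        passed = pass_m[, wl], reason = reason_m[, wl])
    }

    both <- pass_m[, 1] & pass_m[, 2]
    chrom <- matrix(NA_real_, nt, 4,
                    dimnames = list(NULL, c("hbo2", "hhb", "hbt", "sto2")))
    for (i in which(both)) {
      cs <- chromophores_from_mua(mua[i, 1], mua[i, 2], tab)
      if (cs$physical)
        chrom[i, ] <- c(cs$hbo2, cs$hhb, cs$hbt, cs$sto2)
    }

    dcs <- bundle$dcs[[loc]]
    nd <- length(dcs$time)
    bfi <- rep(NA_real_, nd)
    beta <- rep(NA_real_, nd)
    dpass <- rep(FALSE, nd)
    dreason <- rep("ok", nd)
    for (i in seq_len(nd)) {
      j <- which.min(abs(trs$time - dcs$time[i]))
      if (!both[j]) { dreason[i] <- "fit_failure"; next }
      props785 <- optical_properties(
        785, mua_for_dcs(mua[j, 1], mua[j, 2], config$mua_dcs_method),
        (musp[j, 1] + musp[j, 2]) / 2)
      rec <- g2_record(dcs$time[i], dcs$tau, dcs$g2[i, ],
                       dcs$count_rate_khz[i], loc)
      ft <- fit_g2(rec, props785, geom_dcs)
      if (ft$flagged) { dreason[i] <- "fit_failure"; next }
      q <- qc_dcs(rec, ft$beta, config$dcs_min_count_rate_khz,
                  config$dcs_min_beta, config$dcs_qc_mode)
      if (!q$passed) { dreason[i] <- q$reason; next }
      dpass[i] <- TRUE
      bfi[i] <- ft$bfi
      beta[i] <- ft$beta
    }
    qc_rows[[paste(loc, "dcs")]] <- data.frame(
      subject = bundle$subject_id, location = loc, modality = "dcs",
      timestamp = dcs$time, snr = NA_real_,
      count_rate = dcs$count_rate_khz, beta = beta, passed = dpass,
      reason = dreason)

    for (v in colnames(chrom)) {
      ok <- is.finite(chrom[, v])
      traces[[paste(loc, v, sep = ".")]] <-
        hemo_trace(trs$time[ok], chrom[ok, v], v, loc)
    }
    traces[[paste(loc, "bfi", sep = ".")]] <-
      hemo_trace(dcs$time[dpass], bfi[dpass], "bfi", loc)
  }

  ses <- synchronize(traces, bundle$vitals, bundle$events, bundle$bloodgas,
                     masks = bundle$masks, subject_id = bundle$subject_id,
                     bin_s = config$bin_s)
  ses$qc <- do.call(rbind, c(qc_rows, list(make.row.names = FALSE)))
  derive_session_biomarkers(ses, gamma_venous = config$gamma_venous,
                            constants = physio_constants(
                              config$k, config$mchc, config$gamma_venous))
}

#' Derive OEF, MRO2 and the baseline-referred traces of a session
#'
#' Operates on a synchronized `subject_session` whose traces are on the
#' 10-s base. Adds, per location: the OEF trace, the hematocrit-corrected
#' MRO2 trace (when the blood-gas table covers all periods present), the
#' relative traces (rbfi, roef, rmro2) and the difference traces (dhbo2,
#' dhhb, dhbt).
#'
#' @param session a `subject_session`.
#' @param gamma_venous venous fraction for the OEF estimate.
#' @param constants [physio_constants()].
#' @return the session with derived traces added; sessions lacking a period
#'   hematocrit get `needs_hct_imputation = TRUE` and no MRO2 trace.
#' @export
derive_session_biomarkers <- function(session, gamma_venous = 0.75,
                                      constants = physio_constants()) {
  t0 <- .event_time(session$events, "transfusion_start")
  bwin <- c(0, t0)
  sao2 <- session$vitals$sao2
  locs <- unique(vapply(session$traces, function(tr)
    attr(tr, "location") %||% "", ""))
  locs <- intersect(locs, c("cerebral", "peripheral"))
  for (loc in locs) {
    g <- function(v) session$traces[[paste(loc, v, sep = ".")]]
    sto2 <- g("sto2")
    if (!is.null(sto2) && nrow(sto2)) {
      tt <- intersect(sto2$time, sao2$time)
      oef <- oef_from_sto2(sto2$value[match(tt, sto2$time)],
                           sao2$value[match(tt, sao2$time)], gamma_venous)
      ok <- is.finite(oef) & oef >= 0 & oef <= 1
      session$traces[[paste(loc, "oef", sep = ".")]] <-
        hemo_trace(tt[ok], oef[ok], "oef", loc)
    }
    oef_tr <- g("oef")
    bfi_tr <- g("bfi")
    if (!is.null(oef_tr) && !is.null(bfi_tr) && nrow(oef_tr) && nrow(bfi_tr)) {
      have_periods <- unique(protocol_period(
        Reduce(intersect, list(bfi_tr$time, oef_tr$time, sao2$time)),
        session$events))
      hct_ok <- all(have_periods %in%
                      session$bloodgas$period[is.finite(session$bloodgas$hct)])
      if (hct_ok) {
        session$traces[[paste(loc, "mro2", sep = ".")]] <-
          mro2_trace(bfi_tr, oef_tr, sao2, session$bloodgas,
                     session$events, constants)
      } else {
        session$needs_hct_imputation <- TRUE
      }
    }
    for (v in c("bfi", "oef", "mro2")) {
      tr <- g(v)
      if (!is.null(tr) && nrow(tr))
        session$traces[[paste0(loc, ".r", v)]] <-
          tryCatch(relative_trace(tr, bwin), error = function(e) NULL)
    }
    for (v in c("hbo2", "hhb", "hbt")) {
      tr <- g(v)
      if (!is.null(tr) && nrow(tr))
        session$traces[[paste0(loc, ".d", v)]] <-
          tryCatch(delta_trace(tr, bwin), error = function(e) NULL)
    }
    session$traces <- Filter(Negate(is.null), session$traces)
  }
  session
}

#' Process every bundle of a cohort
#'
#' Runs [process_session()] per subject; processing continues past
#' per-subject failures (recorded in the `errors` element). Subjects whose
#' post-transfusion hematocrit is missing get it imputed from the cohort
#' ([impute_post_hct()]) and their MRO2 traces are then derived.
#'
#' @param bundles list of `session_bundle`s (or a `synthetic_cohort`).
#' @param config [rbct_config()].
#' @return list of class `rbct_cohort`: `sessions`, `errors`.
#' @export
process_cohort <- function(bundles, config = rbct_config()) {
  if (inherits(bundles, "synthetic_cohort")) bundles <- bundles$bundles
  sessions <- list()
  errors <- list()
  for (b in bundles) {
    res <- tryCatch(process_session(b, config), error = function(e) e)
    if (inherits(res, "error")) errors[[b$subject_id]] <- conditionMessage(res)
    else sessions[[b$subject_id]] <- res
  }
  sessions <- .impute_cohort_hct(sessions, config)
  structure(list(sessions = sessions, errors = errors, config = config),
            class = "rbct_cohort")
}

# Cohort-level post-HCT imputation for subjects missing the post draw.
.impute_cohort_hct <- function(sessions, config) {
  hct_of <- function(s, p) {
    v <- s$bloodgas$hct[s$bloodgas$period == p]
    if (length(v) == 1 && is.finite(v)) v else NA_real_
  }
  pre <- vapply(sessions, hct_of, 0, "pre")
  post <- vapply(sessions, hct_of, 0, "post")
  for (i in seq_along(sessions)) {
    if (!isTRUE(sessions[[i]]$needs_hct_imputation)) next
    if (!is.finite(pre[i])) next
    imputed <- impute_post_hct(pre[i], pre[-i], post[-i],
                               tol = config$impute_hct_tol)
    bg <- sessions[[i]]$bloodgas
    t1 <- .event_time(sessions[[i]]$events, "transfusion_end")
    bg <- rbind(bg, data.frame(time = t1 + 600, period = "post",
                               hgb = hgb_from_hct(imputed), hct = imputed,
                               paco2 = NA_real_, hgbo2 = NA_real_,
                               hgbr = NA_real_))
    class(bg) <- c("blood_gas", "data.frame")
    sessions[[i]]$bloodgas <- bg
    sessions[[i]]$hct_imputed <- imputed
    sessions[[i]]$needs_hct_imputation <- FALSE
    sessions[[i]] <- derive_session_biomarkers(
      sessions[[i]], gamma_venous = config$gamma_venous,
      constants = physio_constants(config$k, config$mchc,
                                   config$gamma_venous))
  }
  sessions
}

#' Cohort statistical battery
#'
#' Per-subject pre/post window means for every derived variable and
#' location, one-sided relative-change tests in the expected directions,
#' two-sided cerebral-versus-peripheral contrasts of the post-transfusion
#' means, paired pre/post tests of the blood-gas variables, and the report
#' tables.
#'
#' @param cohort an `rbct_cohort` (or plain list of `subject_session`s).
#' @param config [rbct_config()].
#' @return an object of class `rbct_analysis` with `window_means`, `tests`,
#'   `optical_table`, `bloodgas_table`, `summaries`.
#' @export
analyze_cohort <- function(cohort, config = rbct_config()) {
  sessions <- if (inherits(cohort, "rbct_cohort")) cohort$sessions else cohort
  if (length(sessions) < 5L)
    stop("analysis refused: fewer than 5 processed subjects (n = ",
         length(sessions), ")")
  wm <- do.call(rbind, lapply(sessions, function(s)
    window_means(s, window_spec(s$events, post_len_s = config$post_window_s))))

  tests <- list()
  summaries <- list()
  subjects <- unique(wm$subject)
  for (v in names(config$directions)) {
    for (loc in c("cerebral", "peripheral")) {
      sel <- wm[wm$variable == v & wm$location == loc, ]
      sel <- sel[match(subjects, sel$subject), ]
      ok <- is.finite(sel$pre_mean) & is.finite(sel$post_mean)
      if (sum(ok, na.rm = TRUE) >= 5) {
        tests[[paste(v, loc, sep = ".")]] <- relative_change_test(
          sel$post_mean[ok], sel$pre_mean[ok],
          alternative = config$directions[[v]], variable = v,
          location = loc, alpha = config$alpha,
          exact_n_max = config$exact_n_max)
        summaries[[paste(v, loc, "post", sep = ".")]] <-
          cohort_summary(sel$post_mean[ok])
      }
    }
    cer <- wm[wm$variable == v & wm$location == "cerebral", ]
    per <- wm[wm$variable == v & wm$location == "peripheral", ]
    pc <- cer$post_mean[match(subjects, cer$subject)]
    pp <- per$post_mean[match(subjects, per$subject)]
    ok <- is.finite(pc) & is.finite(pp)
    if (sum(ok, na.rm = TRUE) >= 5)
      tests[[paste(v, "cvp", sep = ".")]] <- cerebral_vs_peripheral_test(
        pc[ok], pp[ok], variable = v,
        alpha = config$alpha, exact_n_max = config$exact_n_max)
  }

  bg_tests <- list()
  bg_rows <- list()
  for (v in c("hgb", "hct", "paco2")) {
    pre <- vapply(sessions, function(s) {
      x <- s$bloodgas[[v]][s$bloodgas$period == "pre"]
      if (length(x) == 1) x else NA_real_
    }, 0)
    post <- vapply(sessions, function(s) {
      if (!is.null(s$hct_imputed)) return(NA_real_)  # imputed, not measured
      x <- s$bloodgas[[v]][s$bloodgas$period == "post"]
      if (length(x) == 1) x else NA_real_
    }, 0)
    ok <- is.finite(pre) & is.finite(post)
    if (sum(ok) >= 5) {
      tst <- paired_prepost_test(pre[ok], post[ok], variable = v,
                                 alpha = config$alpha,
                                 exact_n_max = config$exact_n_max)
      bg_tests[[v]] <- tst
      s_pre <- cohort_summary(pre[ok])
      s_post <- cohort_summary(post[ok])
      bg_rows[[v]] <- data.frame(
        variable = v,
        pre = sprintf("%.4g(%.2g)", s_pre[["mean"]], s_pre[["sd"]]),
        post = sprintf("%.4g(%.2g)", s_post[["mean"]], s_post[["sd"]]),
        dir = c(up = "↑", down = "↓", none = "-")[tst$direction],
        p = tst$p_label)
      summaries[[paste(v, "pre", sep = ".")]] <- s_pre
      summaries[[paste(v, "post", sep = ".")]] <- s_post
    }
  }

  structure(list(window_means = wm, tests = tests, bg_tests = bg_tests,
                 optical_table = build_results_tables(tests),
                 bloodgas_table = do.call(rbind, c(bg_rows,
                                                   list(make.row.names = FALSE))),
                 summaries = summaries, n_subjects = length(sessions),
                 config = config),
            class = "rbct_analysis")
}

#' @export
print.rbct_analysis <- function(x, ...) {
  cat(sprintf("Transfusion cohort analysis (n = %d subjects)\n\n",
              x$n_subjects))
  if (!is.null(x$bloodgas_table)) {
    cat("Blood-gas variables, pre vs post (paired Wilcoxon):\n")
    print.data.frame(x$bloodgas_table, row.names = FALSE)
    cat("\n")
  }
  print(x$optical_table)
  invisible(x)
}

#' @export
summary.rbct_analysis <- function(object, ...) {
  cat("Per-variable cohort summaries (post window):\n")
  for (nm in names(object$summaries)) {
    s <- object$summaries[[nm]]
    cat(sprintf("  %-22s mean %.4g (SD %.3g), median %.4g [%.4g, %.4g], n=%d\n",
                nm, s[["mean"]], s[["sd"]], s[["median"]], s[["q1"]],
                s[["q3"]], as.integer(s[["n"]])))
  }
  invisible(object)
}

#' Render the analysis as a plain-text/markdown report
#'
#' @param analysis an `rbct_analysis`.
#' @param path optional file to write; when NULL the lines are returned.
#' @return character vector of report lines, invisibly when written.
#' @export
report_markdown <- function(analysis, path = NULL) {
  tb <- analysis$optical_table
  lines <- c("# Transfusion cohort report", "",
             sprintf("Subjects analyzed: %d", analysis$n_subjects), "",
             "## Blood-gas variables (pre vs post)", "",
             "| variable | pre | post | dir | p |", "|---|---|---|---|---|")
  if (!is.null(analysis$bloodgas_table))
    lines <- c(lines, apply(analysis$bloodgas_table, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |")))
  lines <- c(lines, "", "## Optically derived variables", "",
             "| variable | cerebral p | dir | peripheral p | dir | cer vs per p | dir |",
             "|---|---|---|---|---|---|---|",
             apply(tb, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |")))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Run a complete synthetic transfusion study
#'
#' Generates a seeded synthetic cohort, processes every session through the
#' full optical pipeline (QC, DTOF and g2 fitting, biomarker derivation) and
#' runs the cohort statistical battery.
#'
#' @param seed master seed.
#' @param n_subjects cohort size (default 14).
#' @param protocol,effects,instrument generator specifications.
#' @param config [rbct_config()].
#' @param missingness apply the missing-placement pattern (default TRUE: two
#'   subjects without cerebral traces, one without a post blood draw).
#' @return an `rbct_analysis`.
#' @export
run_synthetic_study <- function(seed, n_subjects = 14,
                                protocol = protocol_spec(),
                                effects = effect_spec(),
                                instrument = instrument_spec(),
                                config = rbct_config(), missingness = TRUE) {
  cohort <- generate_cohort(n_subjects, protocol, effects, instrument,
                            seed = seed, missingness = missingness)
  proc <- process_cohort(cohort, config)
  analyze_cohort(proc, config)
}

#' Type-I error of the one-sided battery under a null cohort
#'
#' Repeatedly generates truth-level cohorts with no programmed effects
#' (physiological noise only, optics bypassed), runs the one-sided
#' relative-change tests for every variable and location, and returns the
#' empirical rejection rate at the given level.
#'
#' @param n_seeds number of null cohorts (default 200).
#' @param n_subjects subjects per cohort (default 14).
#' @param seed master seed.
#' @param protocol [protocol_spec()].
#' @param alpha significance level (default 0.05).
#' @return a list with `rate`, `n_tests`, `n_rejected`.
#' @export
null_rejection_rate <- function(n_seeds = 200, n_subjects = 14, seed = 1L,
                                protocol = protocol_spec(), alpha = 0.05) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
  effects <- effect_spec(null_effects = TRUE)
  config <- rbct_config(alpha = alpha)
  rejected <- 0L; total <- 0L
  for (s in seeds) {
    set.seed(s)
    sess <- lapply(seq_len(n_subjects), function(i)
      truth_session(make_ground_truth(protocol, effects, seed = NULL),
                    sprintf("S%02d", i)))
    names(sess) <- vapply(sess, `[[`, "", "subject_id")
    an <- analyze_cohort(sess, config)
    for (t in an$tests) {
      if (t$comparison != "post_vs_baseline") next
      total <- total + 1L
      rejected <- rejected + as.integer(t$significant)
    }
  }
  list(rate = rejected / total, n_tests = total, n_rejected = rejected)
}
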