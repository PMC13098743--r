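# Cohort statistics: exact Wilcoxon signed-rank inference, pre/post window
# means, directional one-sided tests of relative change, paired pre/post and
# cerebral-vs-peripheral tests, and the report tables.

# Exact null distribution of the signed-rank statistic over doubled midranks
# (doubling keeps tied midranks on an integer grid). Returns counts of the
# 2^n equally likely sign assignments by doubled rank sum 0..S.
.signed_rank_counts <- function(ranks2) {
  S <- sum(ranks2)
  f <- numeric(S + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    idx <- seq_len(S + 1 - r)
    g[idx + r] <- g[idx + r] + f[idx]  # sign +: adds r; sign -: adds 0
    f <- g
  }
  f
}

#' Wilcoxon signed-rank test with an exact tied-rank null
#'
#' One-sample (or paired) signed-rank test. Zero differences are removed;
#' absolute differences are midranked, so ties are handled exactly rather
#' than by switching to a normal approximation. For `n <= exact_n_max` the
#' p-value is computed from the exact null distribution of the statistic
#' over all 2^n sign assignments (evaluated by dynamic programming); above
#' that, a normal approximation with continuity correction and tie-corrected
#' variance is used.
#'
#' @param x sample values (or differences when `y` is NULL).
#' @param y optional paired sample; the test is then on `x - y`.
#' @param mu null location (default 0).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_n_max largest n for which the exact null is enumerated
#'   (default 25).
#' @return a list of class `signed_rank_test` with `statistic` (V, the sum
#'   of ranks of positive differences), `p_value`, `n` (non-zero
#'   differences), `exact`, and `alternative`.
#' @export
signed_rank_test <- function(x, y = NULL,
                             alternative = c("two.sided", "greater", "less"),
                             mu = 0, exact_n_max = 25L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x - mu else x - y - mu
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = 0, p_value = 1, n = 0L, exact = TRUE,
                          alternative = alternative, degenerate = TRUE),
                     class = "signed_rank_test"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  exact <- n <= exact_n_max
  if (exact) {
    r2 <- as.integer(round(2 * r))
    cnt <- .signed_rank_counts(r2)
    tot <- 2^n
    v2 <- as.integer(round(2 * v))
    p_ge <- sum(cnt[(v2 + 1):length(cnt)]) / tot
    p_le <- sum(cnt[1:(v2 + 1)]) / tot
  } else {
    mu_v <- n * (n + 1) / 4
    sd_v <- sqrt(sum(r^2) / 4)
    p_ge <- stats::pnorm((v - mu_v - 0.5) / sd_v, lower.tail = FALSE)
    p_le <- stats::pnorm((v - mu_v + 0.5) / sd_v)
  }
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  structure(list(statistic = v, p_value = p, n = n, exact = exact,
                 alternative = alternative, degenerate = FALSE),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s%s): V = %g, n = %d, p = %s\n",
              x$alternative, if (x$exact) ", exact" else ", normal approx.",
              x$statistic, x$n, format_p(x$p_value)))
  invisible(x)
}

#' Report-style p-value formatting
#'
#' Values below 0.001 are reported only as `"<0.001"`.
#' @param p p-value(s).
#' @return character vector.
#' @export
format_p <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.001) "<0.001" else format(signif(x, 2), trim = TRUE,
                                        scientific = FALSE)
  }, "")
}

#' Round half away from zero to a fixed number of decimals
#'
#' The rounding convention used when regenerating printed report tables
#' (R's `round` rounds half to even).
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Analysis windows around the transfusion
#'
#' The pre-transfusion window spans the entire baseline (from session start
#' to the transfusion start mark); the post-transfusion window spans the
#' `post_len_s` seconds (default 6 min) after the transfusion end mark.
#' Both windows are half-open `[t0, t1)`.
#'
#' @param events event table with `transfusion_start` / `transfusion_end`.
#' @param session_start start of the recording on the session clock
#'   (default 0).
#' @param post_len_s post-window length in seconds (default 360).
#' @return a list of class `window_spec` with `pre` and `post`.
#' @export
window_spec <- function(events, session_start = 0, post_len_s = 360) {
  t0 <- .event_time(events, "transfusion_start")
  t1 <- .event_time(events, "transfusion_end")
  stopifnot(session_start < t0, t0 < t1)
  structure(list(pre = c(session_start, t0), post = c(t1, t1 + post_len_s)),
            class = "window_spec")
}

#' Per-subject window means
#'
#' Means of the surviving 10-s bins inside the pre- and post-transfusion
#' windows, per variable and location. Variables lacking bins in either
#' window are excluded (NA means).
#'
#' @param session a `subject_session` whose `traces` are on the 10-s base.
#' @param spec a [window_spec()].
#' @param apply_masks_first drop masked bins before averaging (default TRUE).
#' @return data.frame with `subject`, `location`, `variable`, `pre_mean`,
#'   `post_mean`, `n_pre`, `n_post`.
#' @export
window_means <- function(session, spec, apply_masks_first = TRUE) {
  rows <- lapply(names(session$traces), function(nm) {
    tr <- session$traces[[nm]]
    if (apply_masks_first) tr <- suppressWarnings(apply_masks(tr, session$masks))
    pre <- tr$value[tr$time >= spec$pre[1] & tr$time < spec$pre[2]]
    post <- tr$value[tr$time >= spec$post[1] & tr$time < spec$post[2]]
    data.frame(subject = session$subject_id,
               location = attr(tr, "location") %||% NA_character_,
               variable = attr(tr, "variable") %||% nm,
               pre_mean = if (length(pre)) mean(pre) else NA_real_,
               post_mean = if (length(post)) mean(post) else NA_real_,
               n_pre = length(pre), n_post = length(post))
  })
  do.call(rbind, rows)
}

.test_result <- function(variable, comparison, location, alternative, ht,
                         median_shift, alpha = 0.05) {
  significant <- ht$p_value < alpha
  direction <- if (!significant || median_shift == 0) "none"
  else if (median_shift > 0) "up" else "down"
  structure(list(variable = variable, comparison = comparison,
                 location = location, alternative = alternative, n = ht$n,
                 statistic = ht$statistic, p_value = ht$p_value,
                 p_label = format_p(ht$p_value), direction = direction,
                 significant = significant, exact = ht$exact),
            class = "rbct_test_result")
}

#' @export
print.rbct_test_result <- function(x, ...) {
  arrow <- c(up = "↑", down = "↓", none = "-")[x$direction]
  cat(sprintf("%s [%s, %s]: n = %d, V = %g, p = %s %s\n", x$variable,
              x$location, x$comparison, x$n, x$statistic, x$p_label, arrow))
  invisible(x)
}

#' Test a relative change against zero
#'
#' Per-subject post-window means, each referred to the subject's own
#' pre-window mean (the difference `post - pre` of window means), tested
#' against zero by a one-sided Wilcoxon signed-rank test in the direction
#' expected for the variable ("greater" for quantities expected to rise
#' after transfusion, "less" for those expected to fall).
#'
#' @param post_means per-subject post-window means.
#' @param baseline_ref per-subject pre-window means (same order).
#' @param alternative expected direction, `"greater"` or `"less"` (or
#'   `"two.sided"`).
#' @param variable,location labels carried into the result.
#' @param alpha significance level (default 0.05).
#' @param exact_n_max passed to [signed_rank_test()].
#' @return an `rbct_test_result`.
#' @export
relative_change_test <- function(post_means, baseline_ref,
                                 alternative = c("greater", "less", "two.sided"),
                                 variable = NA_character_,
                                 location = NA_character_, alpha = 0.05,
                                 exact_n_max = 25L) {
  alternative <- match.arg(alternative)
  d <- post_means - baseline_ref
  d <- d[is.finite(d)]
  if (length(d) < 5L)
    stop("relative-change test refused: fewer than 5 paired subject values")
  ht <- signed_rank_test(d, alternative = alternative,
                         exact_n_max = exact_n_max)
  .test_result(variable, "post_vs_baseline", location, alternative, ht,
               stats::median(d), alpha)
}

#' Paired pre/post comparison
#'
#' Wilcoxon signed-rank test on paired pre- and post-transfusion values
#' (blood-gas variables, window means). NA pairs are dropped; fewer than 5
#' complete pairs refuses the test with a message.
#'
#' @param pre,post paired vectors.
#' @param alternative test direction (default two-sided).
#' @param variable label carried into the result.
#' @param alpha significance level.
#' @param exact_n_max passed to [signed_rank_test()].
#' @return an `rbct_test_result`.
#' @export
paired_prepost_test <- function(pre, post,
                                alternative = c("two.sided", "greater", "less"),
                                variable = NA_character_, alpha = 0.05,
                                exact_n_max = 25L) {
  alternative <- match.arg(alternative)
  ok <- is.finite(pre) & is.finite(post)
  if (sum(ok) < 5L)
    stop("paired test refused: fewer than 5 complete pairs")
  ht <- signed_rank_test(post[ok], pre[ok], alternative = alternative,
                         exact_n_max = exact_n_max)
  .test_result(variable, "paired_prepost", NA_character_, alternative, ht,
               stats::median(post[ok] - pre[ok]), alpha)
}

#' Cerebral-versus-peripheral comparison of post-transfusion values
#'
#' Paired two-sided Wilcoxon signed-rank test on subject-matched
#' post-transfusion means; subjects with one placement missing are dropped.
#' An upward arrow in the result means the peripheral values are higher.
#'
#' @param post_means_cerebral,post_means_peripheral subject-matched vectors.
#' @param variable label carried into the result.
#' @param alpha significance level.
#' @param exact_n_max passed to [signed_rank_test()].
#' @return an `rbct_test_result`.
#' @export
cerebral_vs_peripheral_test <- function(post_means_cerebral,
                                        post_means_peripheral,
                                        variable = NA_character_,
                                        alpha = 0.05, exact_n_max = 25L) {
  ok <- is.finite(post_means_cerebral) & is.finite(post_means_peripheral)
  if (sum(ok) < 5L)
    stop("cerebral-vs-peripheral test refused: fewer than 5 complete pairs")
  d <- post_means_peripheral[ok] - post_means_cerebral[ok]
  ht <- signed_rank_test(d, alternative = "two.sided",
                         exact_n_max = exact_n_max)
  .test_result(variable, "cerebral_vs_peripheral", "both", "two.sided", ht,
               stats::median(d), alpha)
}

#' Cohort summary statistics
#'
#' Mean, sample SD (n-1 denominator), median and quartiles (linear
#' interpolation between order statistics, R quantile type 7).
#'
#' @param values numeric vector (NAs dropped), n >= 2.
#' @return named numeric vector `mean`, `sd`, `median`, `q1`, `q3`, `n`.
#' @export
cohort_summary <- function(values) {
  v <- values[is.finite(values)]
  stopifnot(length(v) >= 2L)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(mean = mean(v), sd = stats::sd(v), median = q[2], q1 = q[1], q3 = q[3],
    n = length(v))
}

#' Expected direction of each optically derived variable after transfusion
#'
#' The one-sided alternatives used by [relative_change_test()]: blood flow,
#' metabolic rate of oxygen and the oxy-/total-hemoglobin changes are
#' expected to rise; the oxygen extraction fraction and the deoxy-hemoglobin
#' change are expected to fall.
#'
#' @return named character vector of alternatives by variable.
#' @export
rbct_directions <- function() {
  c(rbfi = "greater", rmro2 = "greater", dhbo2 = "greater", dhbt = "greater",
    roef = "less", dhhb = "less")
}

#' Assemble the report tables from a battery of test results
#'
#' One row per optically derived variable with the cerebral, peripheral and
#' cerebral-versus-peripheral p-values and direction arrows, `p < 0.001`
#' formatting applied. Variables missing a test are emitted with a
#' `"not tested"` status.
#'
#' @param results list of `rbct_test_result` objects.
#' @param variables row order (default: the six optically derived variables).
#' @return data.frame of class `rbct_results_table`.
#' @export
build_results_tables <- function(results,
                                 variables = c("rbfi", "roef", "rmro2",
                                               "dhbo2", "dhhb", "dhbt")) {
  pick <- function(var, comparison, location = NULL) {
    for (r in results) {
      if (identical(r$variable, var) && identical(r$comparison, comparison) &&
          (is.null(location) || identical(r$location, location)))
        return(r)
    }
    NULL
  }
  cell <- function(r) {
    if (is.null(r)) c("not tested", "")
    else c(r$p_label, c(up = "↑", down = "↓", none = "-")[r$direction])
  }
  rows <- lapply(variables, function(v) {
    cer <- cell(pick(v, "post_vs_baseline", "cerebral"))
    per <- cell(pick(v, "post_vs_baseline", "peripheral"))
    cvp <- cell(pick(v, "cerebral_vs_peripheral"))
    data.frame(variable = v, cerebral_p = cer[1], cerebral_dir = cer[2],
               peripheral_p = per[1], peripheral_dir = per[2],
               cer_vs_per_p = cvp[1], cer_vs_per_dir = cvp[2])
  })
  structure(do.call(rbind, rows),
            class = c("rbct_results_table", "data.frame"))
}

#' @export
print.rbct_results_table <- function(x, ...) {
  cat("Post-transfusion tests (one-sided vs baseline; two-sided site contrast)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
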