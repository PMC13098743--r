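test_that("the exact signed-rank engine agrees with wilcox.test when no ties exist", {
  set.seed(17)
  checked <- 0
  while (checked < 40) {
    n <- sample(5:20, 1)
    x <- round(rnorm(n), 3)
    x <- x[x != 0]
    if (length(x) < 5 || anyDuplicated(abs(x))) next
    for (alt in c("two.sided", "greater", "less")) {
      mine <- signed_rank_test(x, alternative = alt)$p_value
      ref <- suppressWarnings(wilcox.test(x, alternative = alt,
                                          exact = TRUE)$p.value)
      expect_equal(mine, ref, tolerance = 1e-12)
    }
    checked <- checked + 1
  }
})

test_that("tied magnitudes are handled exactly (brute-force enumeration)", {
  set.seed(23)
  for (i in 1:25) {
    d <- sample(c(-3, -2, -2, -1, 1, 2, 2, 3), sample(4:10, 1),
                replace = TRUE)
    for (alt in c("two.sided", "greater", "less"))
      expect_equal(signed_rank_test(d, alternative = alt)$p_value,
                   brute_signed_rank(d, alt), tolerance = 1e-12)
  }
})

test_that("degenerate and boundary behavior of the signed-rank test", {
  z <- signed_rank_test(rep(0, 8))
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)
  # all-positive differences reach the enumeration minimum 2^-n
  for (n in c(8, 13)) {
    p <- signed_rank_test(seq_len(n), alternative = "greater")$p_value
    expect_equal(p, 2^-n)
  }
  # a symmetric +/- pattern is null-consistent
  expect_gte(signed_rank_test(c(-3, 3, -1, 1, -2, 2),
                              alternative = "greater")$p_value, 0.5)
  # one-sided p can never undercut 2^-n
  set.seed(4)
  for (i in 1:50) {
    d <- rnorm(10)
    expect_gte(signed_rank_test(d, alternative = "greater")$p_value, 2^-10)
  }
})

test_that("above the exact cutoff the normal approximation with correction is used", {
  set.seed(5)
  x <- rnorm(40)
  t1 <- signed_rank_test(x, alternative = "greater")
  expect_false(t1$exact)
  ref <- suppressWarnings(wilcox.test(x, alternative = "greater",
                                      exact = FALSE, correct = TRUE)$p.value)
  expect_equal(t1$p_value, ref, tolerance = 1e-10)
})

test_that("analysis windows: entire baseline pre, 6 minutes post", {
  ev <- data.frame(time = c(1800, 10800),
                   label = c("transfusion_start", "transfusion_end"))
  ws <- window_spec(ev)
  expect_equal(ws$pre, c(0, 1800))
  expect_equal(ws$post, c(10800, 11160))
  expect_equal(diff(ws$post), 360)
})

test_that("window means: constants, relative-trace baselines, bin counting", {
  ev <- data.frame(time = c(600, 1200), label = c("transfusion_start",
                                                  "transfusion_end"))
  tt <- seq(0, 1790, by = 10)
  bg <- blood_gas(c(100, 800, 1300), c("pre", "mid", "post"),
                  hgb = c(8, 8.5, 9), hct = c(24, 26, 27))
  step <- ifelse(tt < 1199, 2, 5)  # step just before the end mark
  ses <- list(subject_id = "S1",
              traces = list(x = hemo_trace(tt, step, "x", "cerebral"),
                            r = relative_trace(
                              hemo_trace(tt, rep(3, length(tt)) +
                                           c(rnorm(length(tt), 0, 0.1)),
                                         "bfi", "cerebral"), c(0, 600))),
              events = ev, bloodgas = bg,
              masks = artifact_mask(numeric(), numeric()))
  class(ses) <- "subject_session"
  wm <- window_means(ses, window_spec(ev))
  expect_equal(wm$pre_mean[wm$variable == "x"], 2)
  expect_equal(wm$post_mean[wm$variable == "x"], 5)
  expect_equal(wm$n_post[wm$variable == "x"], 36)  # exactly 36 10-s bins
  expect_equal(wm$pre_mean[wm$variable == "rbfi"], 1, tolerance = 1e-12)
})

test_that("relative-change and paired tests enforce their preconditions", {
  expect_error(relative_change_test(1:4, rep(0, 4)), "fewer than 5")
  expect_error(paired_prepost_test(1:3, 2:4), "fewer than 5")
  expect_error(cerebral_vs_peripheral_test(c(1, 2, NA, NA, NA, NA),
                                           c(2, 3, 4, NA, NA, NA)),
               "fewer than 5")
  t1 <- paired_prepost_test(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(t1$p_value, 1)
  expect_identical(t1$direction, "none")
})

test_that("direction arrows follow the median and the significance gate", {
  up <- relative_change_test(seq(1.2, 1.9, length.out = 10), rep(1, 10),
                             alternative = "greater", variable = "rbfi")
  expect_identical(up$direction, "up")
  expect_true(up$significant)
  dn <- relative_change_test(seq(0.7, 0.9, length.out = 10), rep(1, 10),
                             alternative = "less", variable = "roef")
  expect_identical(dn$direction, "down")
  null <- relative_change_test(c(-2, -1, -0.5, 0.5, 1, 2) / 100, rep(0, 6),
                               alternative = "greater", variable = "dhhb")
  expect_identical(null$direction, "none")
  expect_false(null$significant)
})

test_that("cerebral-vs-peripheral drops incomplete pairs and points the arrow at the higher site", {
  cvp <- cerebral_vs_peripheral_test(c(1, 1, 1, 1, 1, 1, NA),
                                     c(2, 2.2, 1.8, 2.1, 1.9, 2, 5),
                                     variable = "rmro2")
  expect_equal(cvp$n, 6)              # the NA pair is excluded
  expect_identical(cvp$direction, "up")
})

test_that("cohort summary: sample SD and interpolated quartiles", {
  s <- cohort_summary(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(s[["mean"]], 5)
  expect_equal(s[["sd"]], sd(c(2, 4, 4, 4, 5, 5, 7, 9)))
  expect_equal(s[["median"]], 4.5)
  same <- cohort_summary(rep(3, 6))
  expect_equal(same[["sd"]], 0)
  expect_equal(same[["q3"]] - same[["q1"]], 0)
})

test_that("p-value formatting and half-up rounding conventions", {
  expect_identical(format_p(c(0.0005, 0.03, 0.22)), c("<0.001", "0.03", "0.22"))
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.5584, 2), 0.56)
})

test_that("the results table carries arrows and flags untested variables", {
  r1 <- relative_change_test(seq(1.2, 1.9, length.out = 10), rep(1, 10),
                             alternative = "greater", variable = "rbfi",
                             location = "peripheral")
  tb <- build_results_tables(list(r1))
  expect_equal(nrow(tb), 6)
  expect_identical(tb$peripheral_p[tb$variable == "rbfi"], "<0.001")
  expect_identical(tb$peripheral_dir[tb$variable == "rbfi"], "↑")
  expect_identical(tb$cerebral_p[tb$variable == "rbfi"], "not tested")
  expect_identical(tb$cerebral_p[tb$variable == "dhhb"], "not tested")
})
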