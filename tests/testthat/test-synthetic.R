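test_that("ground truth is deterministic per seed and internally consistent", {
  t1 <- make_ground_truth(tiny_protocol(), seed = 7)
  t2 <- make_ground_truth(tiny_protocol(), seed = 7)
  expect_identical(t1, t2)
  for (loc in c("cerebral", "peripheral")) {
    L <- t1$locations[[loc]]
    expect_equal(L$hbt, L$hbo2 + L$hhb)                       # exact sum
    expect_true(all(L$sto2 > 0 & L$sto2 < 1))
    expect_true(all(L$bfi > 0))
  }
  expect_equal(unname(t1$hgb), unname(hgb_from_hct(t1$hct)))  # MCHC relation
  expect_equal(sum(t1$events$label == "blood_draw"), 3)
})

test_that("the effect ramp is flat outside the transfusion epoch", {
  e <- effect_spec()
  e$noise[] <- 0
  tr <- make_ground_truth(tiny_protocol(), e, seed = 1)
  t0 <- tiny_protocol()$transfusion_start
  t1 <- tiny_protocol()$transfusion_end
  per <- tr$locations$peripheral
  pre <- tr$time < t0
  post <- tr$time >= t1
  expect_equal(diff(range(per$bfi[pre])), 0)          # constant baseline
  expect_equal(diff(range(per$bfi[post])), 0)         # constant plateau
  expect_equal(diff(range(per$sto2[pre])), 0)
})

test_that("a null spec with zero noise produces constant courses", {
  e <- effect_spec(null_effects = TRUE)
  e$noise[] <- 0
  e$sao2["sd"] <- 0
  e$bf$peripheral["sd"] <- 0; e$bf$cerebral["sd"] <- 0
  e$oef$peripheral["sd"] <- 0; e$oef$cerebral["sd"] <- 0
  e$dhhb$peripheral["sd"] <- 0; e$dhhb$cerebral["sd"] <- 0
  tr <- make_ground_truth(tiny_protocol(), e, seed = 3)
  for (loc in c("cerebral", "peripheral"))
    for (v in c("sto2", "hbt", "bfi"))
      expect_equal(diff(range(tr$locations[[loc]][[v]])), 0)
})

test_that("programmed peripheral flow effect averages to +68 percent across subjects", {
  e <- effect_spec()
  e$noise[] <- 0
  ratios <- vapply(1:24, function(i) {
    tr <- make_ground_truth(tiny_protocol(), e, seed = 100 + i)
    per <- tr$locations$peripheral
    mean(per$bfi[tr$time >= tiny_protocol()$transfusion_end]) /
      mean(per$bfi[tr$time < tiny_protocol()$transfusion_start])
  }, 0)
  # drawn per subject around 1.68 with SD 0.204
  expect_equal(mean(ratios), 1.68, tolerance = 0.08)
  expect_gt(sd(ratios), 0.05)
})

test_that("extreme programmed effects clip StO2 with a warning", {
  e <- effect_spec()
  e$oef$cerebral["mean"] <- -3   # drives StO2 above its physical cap
  e$oef$cerebral["sd"] <- 0
  expect_warning(make_ground_truth(tiny_protocol(), e, seed = 2), "clipped")
})

test_that("simulated raw bundles are deterministic and carry the protocol structure", {
  s1 <- simulate_session(tiny_protocol(), seed = 11)
  s2 <- simulate_session(tiny_protocol(), seed = 11)
  expect_identical(s1$bundle$trs$cerebral$counts, s2$bundle$trs$cerebral$counts)
  expect_identical(s1$bundle$dcs$peripheral$g2, s2$bundle$dcs$peripheral$g2)
  b <- s1$bundle
  expect_equal(nrow(b$bloodgas), 3)
  expect_identical(b$bloodgas$period, c("pre", "mid", "post"))
  expect_true(all(c("transfusion_start", "transfusion_end") %in%
                    b$events$label))
  expect_true(all(b$trs$cerebral$counts[["690"]] >= 0))
  # blood draws sit inside their periods
  p <- protocol_period(b$bloodgas$time, b$events)
  expect_identical(p, b$bloodgas$period)
})

test_that("cohorts honor size, seeds and the missing-data pattern", {
  co <- generate_cohort(6, tiny_protocol(), seed = 5, missingness = TRUE)
  expect_length(co$bundles, 6)
  has_cer <- vapply(co$bundles, function(b) "cerebral" %in% names(b$trs),
                    TRUE)
  expect_equal(sum(!has_cer), 2)              # two cerebral-missing subjects
  draws <- vapply(co$bundles, function(b) nrow(b$bloodgas), 0L)
  expect_equal(sum(draws == 2), 1)            # one missing post draw
  co2 <- generate_cohort(6, tiny_protocol(), seed = 5, missingness = TRUE)
  expect_identical(co$bundles$S04$trs$cerebral$counts,
                   co2$bundles$S04$trs$cerebral$counts)
  one <- generate_cohort(1, tiny_protocol(), seed = 5)
  expect_length(one$bundles, 1)
})

test_that("noise-free raw simulation recovers the true StO2 within 0.5 percent", {
  e <- effect_spec()
  e$noise[] <- 0
  ins <- instrument_spec(total_counts = 5e7, g2_noise_scale = 0)
  set.seed(9)
  truth <- make_ground_truth(tiny_protocol(), e, seed = NULL)
  bundle <- simulate_raw(truth, ins, e, seed = NULL, subject_id = "NF",
                         locations = "cerebral")
  proc <- process_session(bundle)
  tr <- proc$traces[["cerebral.sto2"]]
  m <- match(tr$time + 5, truth$time)
  err <- abs(tr$value - truth$locations$cerebral$sto2[m])
  expect_lt(max(err, na.rm = TRUE), 0.005)
})

test_that("truth-level sessions mirror the processed-trace layout", {
  tr <- make_ground_truth(tiny_protocol(), seed = 13)
  ses <- truth_session(tr, "TL")
  expect_s3_class(ses, "subject_session")
  for (v in c("cerebral.rbfi", "peripheral.roef", "cerebral.dhhb",
              "peripheral.rmro2"))
    expect_true(v %in% names(ses$traces))
  wm <- window_means(ses, window_spec(ses$events))
  expect_true(all(is.finite(wm$pre_mean)))
})
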