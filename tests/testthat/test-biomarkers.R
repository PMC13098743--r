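test_that("hemoglobin from hematocrit via the MCHC relation", {
  expect_equal(hgb_from_hct(26), 8.84)
  expect_equal(hgb_from_hct(24.5), 8.33)
  expect_error(hgb_from_hct(0), "between 0 and 100")
  expect_error(hgb_from_hct(100), "between 0 and 100")
  # mchc override propagates linearly
  expect_equal(hgb_from_hct(30, physio_constants(mchc = 320)), 9.6)
})

test_that("arterial oxygen content", {
  expect_equal(cao2(8.84, 1.0), 12.0224)
  expect_equal(cao2(10, 0.97), 13.192)
  expect_equal(cao2(9, 0), 0)
  expect_error(cao2(9, 1.2), "fraction")
})

test_that("oxygen extraction fraction from the venous-compartment estimate", {
  expect_equal(oef_from_sto2(0.65, 0.98, 0.75), (0.98 - 0.54) / 0.98,
               tolerance = 1e-12)
  expect_equal(oef_from_sto2(0.9, 0.9, 0.75), 0)          # no extraction
  expect_equal(oef_from_sto2(0.6, 0.95, 1), (0.95 - 0.6) / 0.95)
  expect_warning(na <- oef_from_sto2(0.6, 0, 0.75), "undefined")
  expect_true(is.na(na))
})

test_that("relative and difference traces are exact self-normalizations", {
  tt <- seq(0, 2395, by = 5)
  set.seed(31)
  for (i in 1:200) {
    tr <- hemo_trace(tt, rnorm(length(tt), 10, 2), "bfi", "cerebral")
    r <- relative_trace(tr, c(0, 600))
    expect_equal(mean(r$value[r$time < 600]), 1, tolerance = 1e-12)
    d <- delta_trace(tr, c(0, 600))
    expect_equal(mean(d$value[d$time < 600]), 0, tolerance = 1e-12)
    # delta + baseline reconstructs the original
    expect_equal(d$value + attr(d, "baseline_stat"), tr$value)
  }
  cst <- hemo_trace(tt, rep(4, length(tt)), "oef", "cerebral")
  expect_equal(relative_trace(cst, c(0, 600))$value, rep(1, length(tt)))
  expect_equal(delta_trace(cst, c(0, 600))$value, rep(0, length(tt)))
})

test_that("a post-transfusion step appears as the programmed relative / delta change", {
  tt <- seq(0, 2395, by = 5)
  step <- ifelse(tt < 1200, 1, 1.68)
  r <- relative_trace(hemo_trace(tt, step, "bfi", "peripheral"), c(0, 1200))
  expect_equal(mean(r$value[r$time >= 1200]), 1.68)
  dstep <- ifelse(tt < 1200, 0.05, 0.054)
  d <- delta_trace(hemo_trace(tt, dstep, "hbo2", "cerebral"), c(0, 1200))
  expect_equal(mean(d$value[d$time >= 1200]), 0.0040)
  expect_error(relative_trace(hemo_trace(tt, rep(0, length(tt)), "x", "cerebral"),
                              c(0, 1200)), "zero")
})

test_that("10-s binning: half-open bins, means, and absent empty bins", {
  tt <- seq(0, 599.9, by = 1 / 400) # 400 Hz
  cst <- downsample_10s(hemo_trace(tt, rep(3.3, length(tt)), "sto2", "cerebral"))
  expect_equal(cst$value, rep(3.3, nrow(cst)))
  expect_lte(nrow(cst), 60)
  ramp <- downsample_10s(hemo_trace(tt, tt, "sto2", "cerebral"))
  expect_equal(ramp$value, ramp$time + 5, tolerance = 0.01)  # bin midpoint
  # a gap leaves its bins absent rather than NaN
  t2 <- c(seq(0, 99, 1), seq(300, 399, 1))
  g <- downsample_10s(hemo_trace(t2, rep(1, 200), "bfi", "cerebral"))
  expect_equal(nrow(g), 20)
  expect_false(any(g$time %in% seq(100, 290, 10)))
  # brute-force check of one bin
  tr <- hemo_trace(sort(runif(500, 0, 100)), rnorm(500), "bfi", "cerebral")
  ds <- downsample_10s(tr)
  expect_equal(ds$value[ds$time == 40],
               mean(tr$value[tr$time >= 40 & tr$time < 50]))
})

test_that("period assignment is half-open and covers every bin exactly once", {
  ev <- data.frame(time = c(1800, 10800), label = c("transfusion_start",
                                                    "transfusion_end"))
  tt <- seq(0, 12590, by = 10)
  p <- protocol_period(tt, ev)
  expect_true(all(p %in% c("pre", "mid", "post")))
  expect_identical(p[tt == 1800], "mid")    # boundary goes to the later epoch
  expect_identical(p[tt == 10800], "post")
  expect_identical(p[tt == 1790], "pre")
  expect_equal(sum(p == "pre"), 180)
})

test_that("MRO2 composes flow, extraction and oxygen content with per-period HCT", {
  ev <- data.frame(time = c(600, 1800), label = c("transfusion_start",
                                                  "transfusion_end"))
  tt <- seq(0, 2390, by = 10)
  one <- function(v) hemo_trace(tt, rep(v, length(tt)), "bfi", "cerebral")
  bg <- blood_gas(c(100, 1200, 1900), c("pre", "mid", "post"),
                  hgb = c(8.33, 8.82, 9.316), hct = c(24.5, 25.95, 27.4))
  cst <- physio_constants()
  m <- mro2_trace(one(1), one(1), one(1), bg, ev, cst)
  # within the pre window the trace is bfi*oef*cao2(hgb(24.5), 1)
  expect_equal(m$value[m$time < 600],
               rep(1.36 * hgb_from_hct(24.5), 60))
  # doubling the flow doubles mro2 pointwise
  m2 <- mro2_trace(one(2), one(1), one(1), bg, ev, cst)
  expect_equal(m2$value, 2 * m$value)
  # linear in each factor
  m3 <- mro2_trace(one(1), one(0.5), one(1), bg, ev, cst)
  expect_equal(m3$value, 0.5 * m$value)
  # hct switches exactly at the marks
  expect_equal(unique(m$value[m$time >= 1800] / (1.36 * hgb_from_hct(27.4))), 1)
  # missing post hct refuses
  bg2 <- blood_gas(c(100, 1200), c("pre", "mid"), hgb = c(8.33, 8.82),
                   hct = c(24.5, 25.95))
  expect_error(mro2_trace(one(1), one(1), one(1), bg2, ev, cst),
               "missing hematocrit")
})

test_that("an HCT-only change forces the MRO2 ratio 27.4/24.5", {
  ev <- data.frame(time = c(600, 1800), label = c("transfusion_start",
                                                  "transfusion_end"))
  tt <- seq(0, 2390, by = 10)
  one <- function(v) hemo_trace(tt, rep(v, length(tt)), "bfi", "cerebral")
  bg <- blood_gas(c(100, 1200, 1900), c("pre", "mid", "post"),
                  hgb = hgb_from_hct(c(24.5, 25.95, 27.4)),
                  hct = c(24.5, 25.95, 27.4))
  m <- mro2_trace(one(1), one(1), one(1), bg, ev, physio_constants())
  pre <- mean(m$value[m$time < 600])
  post <- mean(m$value[m$time >= 1800])
  expect_equal(post / pre, 27.4 / 24.5, tolerance = 1e-12)
})

test_that("post-transfusion HCT imputation follows the matched-donor rule", {
  expect_equal(impute_post_hct(24, c(24, 24), c(27, 27)), 27)
  expect_equal(impute_post_hct(24, c(24, 24.2), c(26, 28)), 27)
  # matched donors from the bundled clinical table: pre = 24
  # a subject whose own post draw is missing, matched against the table
  tab <- clinical_cohort()
  imp <- impute_post_hct(24, tab$hct_pre, tab$hct_post)
  expect_equal(imp, 27)
  expect_true(imp >= 25 && imp <= 32)  # within the observed post range
  expect_warning(fb <- impute_post_hct(40, c(24, 26), c(27, 29)), "cohort mean")
  expect_equal(fb, 28)
})

test_that("synchronization: offsets, percent SaO2, and hard mark errors", {
  tt <- seq(0, 2399, by = 1)
  traces <- list(cerebral.bfi = hemo_trace(tt, rep(2, 2400), "bfi", "cerebral"))
  vit <- data.frame(time = tt, sao2 = rep(97, 2400), map = 80, hr = 70)
  ev <- data.frame(time = c(600, 1800), label = c("transfusion_start",
                                                  "transfusion_end"))
  bg <- blood_gas(c(100, 1200, 1900), c("pre", "mid", "post"),
                  hgb = c(8, 8.5, 9), hct = c(24, 26, 27))
  expect_message(ses <- synchronize(traces, vit, ev, bg, subject_id = "T1"),
                 "percent")
  expect_true(all(ses$vitals$sao2$value <= 1))
  expect_equal(nrow(ses$traces[["cerebral.bfi"]]), 240)
  # vitals offset shifts only the vitals bins
  ses2 <- synchronize(traces, vit, ev, bg, offsets = list(vitals = 5),
                      subject_id = "T1")
  expect_equal(min(ses2$vitals$sao2$time), 0)
  expect_equal(max(ses2$vitals$sao2$time), 2400)  # shifted into a later bin
  expect_equal(ses2$traces[["cerebral.bfi"]]$time,
               ses$traces[["cerebral.bfi"]]$time)
  expect_error(synchronize(traces, vit, ev[1, , drop = FALSE], bg),
               "transfusion_end")
})
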