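test_that("chromophore conversion inverts the forward map to 1e-10", {
  tab <- extinction_table()
  set.seed(42)
  for (i in 1:50) {
    hbo2 <- runif(1, 0.005, 0.08)
    hhb <- runif(1, 0.002, 0.05)
    cs <- chromophores_from_mua(mua_from_chromophores(hbo2, hhb, 690, tab),
                                mua_from_chromophores(hbo2, hhb, 830, tab),
                                tab)
    expect_equal(cs$hbo2, hbo2, tolerance = 1e-10)
    expect_equal(cs$hhb, hhb, tolerance = 1e-10)
    expect_equal(cs$hbt, cs$hbo2 + cs$hhb)  # exact by construction
    expect_true(cs$physical)
  }
})

test_that("chromophore edge cases: saturation limits, homogeneity, flags", {
  tab <- extinction_table()
  # fully oxygenated
  cs <- chromophores_from_mua(mua_from_chromophores(0.04, 0, 690, tab),
                              mua_from_chromophores(0.04, 0, 830, tab), tab)
  expect_equal(cs$sto2, 1, tolerance = 1e-10)
  # the worked example: 0.040 / 0.020 mM gives StO2 = 2/3
  cs2 <- chromophores_from_mua(mua_from_chromophores(0.04, 0.02, 690, tab),
                               mua_from_chromophores(0.04, 0.02, 830, tab),
                               tab)
  expect_equal(cs2$sto2, 2 / 3, tolerance = 1e-10)
  # doubling both absorptions doubles concentrations, StO2 unchanged
  m1 <- mua_from_chromophores(0.03, 0.015, 690, tab)
  m2 <- mua_from_chromophores(0.03, 0.015, 830, tab)
  a <- chromophores_from_mua(m1, m2, tab)
  b <- chromophores_from_mua(2 * m1, 2 * m2, tab)
  expect_equal(b$hbo2, 2 * a$hbo2)
  expect_equal(b$sto2, a$sto2)
  # impossible pair flags a negative solution instead of clipping
  neg <- chromophores_from_mua(1e-4, 0.05, tab)
  expect_false(neg$physical)
  expect_error(chromophores_from_mua(-0.01, 0.02, tab), "positive")
  # singular table rejected
  bad <- extinction_table()
  bad$eps_hhb <- bad$eps_hbo2
  expect_error(chromophores_from_mua(0.01, 0.01, bad), "singular")
})

test_that("scattering averaging and the DCS absorption rule", {
  p690 <- optical_properties(690, 0.01, 1.0)
  p830 <- optical_properties(830, 0.01, 0.8)
  expect_equal(average_musp(p690, p830), 0.9)
  expect_equal(average_musp(p690, p690), 1.0)
  expect_warning(m <- average_musp(NULL, p830), "one wavelength")
  expect_equal(m, 0.8)
  expect_error(average_musp(NULL, NULL), "no valid")
  expect_equal(mua_for_dcs(0.01, 0.02), 0.015)
  expect_equal(mua_for_dcs(0.01, 0.02, "interp"),
               0.01 + 0.01 * (785 - 690) / 140)
})

test_that("noiseless DTOF round trips recover the generating properties within 1 percent", {
  irf_n <- make_irf_shape()
  irf <- irf_record(25, irf_n, 830)
  geom <- medium_geometry(30)
  for (mua in c(0.005, 0.015, 0.03)) for (musp in c(0.5, 1, 2)) {
    f <- fit_dtof(make_dtof(mua, musp, noise = FALSE, irf_n = irf_n), irf,
                  geom)
    expect_true(f$converged)
    expect_equal(f$props$mua, mua, tolerance = 0.01)
    expect_equal(f$props$musp, musp, tolerance = 0.01)
  }
})

test_that("a delta IRF round trip is exact to numerical precision", {
  delta <- c(1, rep(0, 399))
  p <- optical_properties(830, 0.015, 1)
  m <- td_reflectance(p, medium_geometry(30), TBINS)
  d <- dtof_record(0, 830, 25, 5e5 * m / sum(m))
  f <- fit_dtof(d, irf_record(25, delta, 830), medium_geometry(30),
                subtract_background = FALSE)
  expect_equal(f$props$mua, 0.015, tolerance = 1e-6)
  expect_equal(f$props$musp, 1, tolerance = 1e-6)
})

test_that("the compiled fitter agrees with an independent nls.lm fit", {
  skip_if_not_installed("minpack.lm")
  irf_n <- make_irf_shape()
  geom <- medium_geometry(30)
  set.seed(5)
  d <- make_dtof(0.012, 1.1, irf_n = irf_n)
  f <- fit_dtof(d, irf_record(25, irf_n, 830), geom, fit_shift = FALSE)
  counts <- d$counts - mean(d$counts[1:20])
  pk <- which.max(counts)
  lo <- which(counts[1:pk] >= 0.8 * max(counts))[1]
  hi <- max(which(counts >= 0.01 * max(counts)))
  w <- 1 / sqrt(pmax(counts[lo:hi], 1))
  res_fun <- function(par) {
    p <- optical_properties(830, exp(par[1]), exp(par[2]))
    mm <- convolve_with_irf(td_reflectance(p, geom, TBINS), irf_n, 25)
    a <- sum(w^2 * counts[lo:hi] * mm[lo:hi]) / sum(w^2 * mm[lo:hi]^2)
    w * (counts[lo:hi] - a * mm[lo:hi])
  }
  nf <- minpack.lm::nls.lm(c(log(0.01), log(1)), fn = res_fun)
  expect_equal(f$props$mua, exp(nf$par[1]), tolerance = 1e-3)
  expect_equal(f$props$musp, exp(nf$par[2]), tolerance = 1e-3)
})

test_that("Poisson-noise DTOF fits stay within the accuracy budget and are deterministic", {
  irf_n <- make_irf_shape()
  irf <- irf_record(25, irf_n, 830)
  geom <- medium_geometry(30)
  set.seed(99)
  errs <- replicate(30, {
    f <- fit_dtof(make_dtof(0.015, 1.0, irf_n = irf_n), irf, geom)
    c(abs(f$props$mua / 0.015 - 1), abs(f$props$musp - 1))
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.10)
  set.seed(1)
  d <- make_dtof(0.015, 1.0, irf_n = irf_n)
  f1 <- fit_dtof(d, irf, geom)
  f2 <- fit_dtof(d, irf, geom)
  expect_identical(coef(f1), coef(f2))
})

test_that("fitted absorption is monotone in the true absorption", {
  irf_n <- make_irf_shape()
  irf <- irf_record(25, irf_n, 830)
  geom <- medium_geometry(30)
  truth <- seq(0.006, 0.03, length.out = 6)
  fits <- vapply(truth, function(mua)
    fit_dtof(make_dtof(mua, 1, noise = FALSE, irf_n = irf_n), irf,
             geom)$props$mua, 0)
  expect_equal(cor(truth, fits, method = "spearman"), 1)
})

test_that("pure background noise is flagged, not fatal", {
  set.seed(3)
  d <- dtof_record(0, 830, 25, rpois(400, 3))
  f <- fit_dtof(d, irf_record(25, make_irf_shape(), 830),
                medium_geometry(30))
  expect_false(f$converged)
  expect_true(f$flagged)
  expect_true(all(is.na(coef(f)[c("mua", "musp")])))
})

test_that("noiseless g2 round trips recover BFI and beta within 1 percent", {
  p <- optical_properties(785, 0.012, 0.95)
  geom <- medium_geometry(25)
  for (bfi in c(1e-9, 1e-8, 5e-8)) for (beta in c(0.4, 0.55)) {
    f <- fit_g2(make_g2rec(bfi, beta, p), p, geom)
    expect_true(f$converged)
    expect_equal(f$bfi, bfi, tolerance = 0.01)
    expect_equal(f$beta, beta, tolerance = 0.01)
  }
})

test_that("the g2 fitter agrees with an independent nls.lm fit on noisy data", {
  skip_if_not_installed("minpack.lm")
  p <- optical_properties(785, 0.012, 0.95)
  geom <- medium_geometry(25)
  set.seed(8)
  rec <- make_g2rec(1e-8, 0.5, p, noise_sd = 0.005)
  f <- fit_g2(rec, p, geom)
  res_fun <- function(par) {
    g1 <- dcs_g1(p, geom, dcs_config(exp(par[1]), 0.5), rec$tau)
    rec$g2 - (1 + par[2] * g1^2)
  }
  nf <- minpack.lm::nls.lm(c(log(1e-8), 0.5), fn = res_fun)
  expect_equal(f$bfi, exp(nf$par[1]), tolerance = 0.02)
  expect_equal(f$beta, nf$par[2], tolerance = 0.02)
})

test_that("noisy g2 fits are accurate and degenerate curves are flagged", {
  p <- optical_properties(785, 0.012, 0.95)
  geom <- medium_geometry(25)
  set.seed(12)
  errs <- replicate(30, {
    f <- fit_g2(make_g2rec(1e-8, 0.5, p, noise_sd = 0.005), p, geom)
    abs(f$bfi / 1e-8 - 1)
  })
  expect_lt(median(errs), 0.05)
  flat <- g2_record(0, TAU60, rep(1, 60), 50)
  f <- fit_g2(flat, p, geom)
  expect_true(f$flagged)
  expect_true(is.na(f$bfi))
})

test_that("record constructors enforce their invariants", {
  expect_error(dtof_record(0, 700, 25, rep(1, 400)), "690 or 830")
  expect_error(dtof_record(0, 830, 25, rep(1, 50)), "100 bins")
  expect_error(dtof_record(0, 830, 25, c(rep(1, 399), -1)), "non-negative")
  expect_error(g2_record(0, c(1e-6, 1e-6), c(1.5, 1.4), 50), "increasing")
  expect_error(g2_record(0, c(1e-6, 1e-5), c(1.5, 1.4), -3), "count rate")
  expect_error(irf_record(25, rep(0, 100), 830), "peak")
})

test_that("the extinction table records provenance and covers the instrument wavelengths", {
  tab <- extinction_table()
  expect_true(all(c(690, 785, 830) %in% tab$wavelength_nm))
  expect_match(attr(tab, "provenance"), "extinction")
  expect_true(all(tab$eps_hbo2 > 0 & tab$eps_hhb > 0))
})
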