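test_that("constructors validate physical ranges", {
  expect_error(optical_properties(830, -0.01, 1), "positive")
  expect_error(optical_properties(830, 0.01, 0), "positive")
  expect_warning(optical_properties(830, 1.2, 1.0), "diffusion")
  expect_error(medium_geometry(0), "rho")
  expect_error(dcs_config(-1e-8, 0.5), "non-negative")
  expect_error(dcs_config(1e-8, 0), "beta")
  expect_error(dcs_config(1e-8, 1.2), "beta")
})

test_that("time-domain reflectance matches an independent evaluation of the solution", {
  t_ps <- seq(100, 9000, by = 50)
  for (mua in c(0.005, 0.02)) for (musp in c(0.6, 1.5)) {
    got <- td_reflectance(optical_properties(830, mua, musp),
                          medium_geometry(30), t_ps)
    want <- ref_td(t_ps, mua, musp, 30)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= 0) && all(is.finite(got)))
  }
})

test_that("reflectance vanishes at early times and rejects bad grids", {
  p <- optical_properties(830, 0.01, 1)
  g <- medium_geometry(30)
  expect_equal(td_reflectance(p, g, c(0.1, 1))[1], 0)
  expect_error(td_reflectance(p, g, c(-5, 10)), "increasing")
  expect_error(td_reflectance(p, g, c(10, 10)), "increasing")
})

test_that("an absorption increase multiplies the curve by exp(-delta mua v t) exactly", {
  t_ps <- seq(200, 8000, by = 100)
  g <- medium_geometry(30)
  r1 <- td_reflectance(optical_properties(830, 0.010, 1), g, t_ps)
  r2 <- td_reflectance(optical_properties(830, 0.018, 1), g, t_ps)
  v <- C_MMPS / 1.4
  expect_equal(r2 / r1, exp(-0.008 * v * t_ps), tolerance = 1e-10)
})

test_that("late-tail log-slope reads out -mua*v within 1 percent", {
  g <- medium_geometry(30)
  for (mua in c(0.008, 0.01, 0.03)) {
    t_ps <- seq(25, 60000, by = 25)
    r <- td_reflectance(optical_properties(830, mua, 1.0), g, t_ps)
    v_ns <- 1000 * C_MMPS / 1.4
    expect_equal(dtof_tail_slope(r, t_ps, c(20000, 40000)), -mua * v_ns,
                 tolerance = 0.01)
  }
  # small separation: the slope converges already at 8 ns
  t_ps <- seq(25, 12000, by = 25)
  r <- td_reflectance(optical_properties(830, 0.01, 1.0),
                      medium_geometry(1), t_ps)
  expect_equal(dtof_tail_slope(r, t_ps, c(6000, 10000)),
               -0.01 * 1000 * C_MMPS / 1.4, tolerance = 0.01)
})

test_that("g1 matches an independent evaluation and has the decay properties", {
  p <- optical_properties(785, 0.012, 0.95)
  g <- medium_geometry(25)
  tau <- TAU60
  got <- dcs_g1(p, g, dcs_config(1e-8, 0.5), tau)
  expect_equal(got, ref_g1(tau, 0.012, 0.95, 1e-8, 25), tolerance = 1e-12)
  expect_true(all(diff(got) < 0))
  expect_true(all(got >= 0 & got <= 1))
  expect_equal(dcs_g1(p, g, dcs_config(1e-8, 0.5), c(0, 1e-6))[1], 1)
  # static medium
  expect_equal(dcs_g1(p, g, dcs_config(0, 0.5), tau), rep(1, 60))
})

test_that("the half-decay lag shrinks when the flow index doubles", {
  p <- optical_properties(785, 0.012, 0.95)
  g <- medium_geometry(25)
  tau <- 10^seq(-8, -1, length.out = 400)
  thalf <- function(bfi) {
    g1 <- dcs_g1(p, g, dcs_config(bfi, 0.5), tau)
    stats::approx(g1, tau, xout = 0.5)$y
  }
  expect_lt(thalf(2e-8), thalf(1e-8))
  expect_lt(thalf(4e-8), thalf(2e-8))
})

test_that("Siegert relation and its bounds", {
  expect_equal(siegert_g2(1, 0.5), 1.5)
  expect_equal(siegert_g2(0, 0.77), 1)
  expect_equal(siegert_g2(0.6, 0.4), 1.144)
  g1 <- seq(0, 1, by = 0.01)
  g2 <- siegert_g2(g1, 0.8)
  expect_true(all(g2 >= 1 & g2 <= 1.8))
  expect_error(siegert_g2(g1, 0), "beta")
  expect_error(siegert_g2(c(0.2, 1.4), 0.5), "g1")
})

test_that("IRF convolution: identity kernel, mass conservation, peak delay", {
  m <- c(dnorm(1:300, 100, 30), rep(0, 100))  # zero tail, nothing truncated
  delta <- c(1, rep(0, 399))
  expect_equal(convolve_with_irf(m, delta, 25), m)
  irf <- dnorm(1:80, 30, 8)
  out <- convolve_with_irf(m, irf, 25)
  expect_equal(sum(out), sum(m) * sum(irf), tolerance = 1e-9)
  expect_gt(which.max(out), which.max(m))
  expect_error(convolve_with_irf(m, irf, 25, 50), "bin widths")
})

test_that("forward curves stay finite and nonnegative across the property range", {
  t_ps <- seq(25, 10000, by = 25)
  g <- medium_geometry(30)
  for (mua in c(0.001, 0.01, 0.05)) for (musp in c(0.3, 1, 3)) {
    r <- td_reflectance(optical_properties(830, mua, musp), g, t_ps)
    expect_true(all(is.finite(r)) && all(r >= 0))
    g1 <- dcs_g1(optical_properties(785, mua, musp), medium_geometry(25),
                 dcs_config(1e-8, 0.5), TAU60)
    expect_true(all(is.finite(g1)) && all(g1 >= 0))
  }
})
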