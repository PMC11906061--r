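test_that("baseline distribution functions match their closed forms", {
  d <- sine_dist("exponential", scale = 1)
  expect_equal(baseline_cdf(d, 0), 0)
  expect_equal(baseline_cdf(d, log(2)), 0.5)
  expect_equal(baseline_pdf(d, 0), 1)

  dw <- sine_dist("weibull", scale = 1, shape = 2)
  expect_equal(baseline_cdf(dw, 1), 1 - exp(-1), tolerance = 1e-12)

  dl <- sine_dist("lomax", scale = 1, shape = 1)
  expect_equal(baseline_pdf(dl, 0), 1)
  expect_equal(baseline_quantile(dl, 0.5), 1)

  dg <- sine_dist("gompertz", scale = 0.5, shape = 1)
  expect_equal(baseline_pdf(dg, 0), 0.5)

  # negative time convention: zero mass below the origin
  for (p in oracle_param_grid()) {
    dd <- grid_dist(p)
    expect_identical(baseline_cdf(dd, -1), 0)
    expect_identical(baseline_pdf(dd, -1), 0)
    expect_identical(sine_cdf(dd, -1), 0)
    expect_identical(sine_pdf(dd, -1), 0)
  }
})

test_that("baseline functions agree with reference implementations", {
  skip_if_not_installed("flexsurv")
  t <- c(0.1, 0.7, 2, 5)
  dw <- sine_dist("weibull", scale = 0.6, shape = 1.4)
  expect_equal(baseline_cdf(dw, t),
               stats::pweibull(t, shape = 1.4, scale = 1 / 0.6),
               tolerance = 1e-12)
  expect_equal(baseline_pdf(dw, t),
               stats::dweibull(t, shape = 1.4, scale = 1 / 0.6),
               tolerance = 1e-12)
  dg <- sine_dist("gompertz", scale = 0.3, shape = 0.8)
  expect_equal(baseline_cdf(dg, t),
               flexsurv::pgompertz(t, shape = 0.3, rate = 0.3 * 0.8),
               tolerance = 1e-10)
  expect_equal(baseline_pdf(dg, t),
               flexsurv::dgompertz(t, shape = 0.3, rate = 0.3 * 0.8),
               tolerance = 1e-10)
})

test_that("sine transform matches the trigonometric closed forms", {
  d <- sine_dist("se", scale = 1)
  expect_equal(sine_cdf(d, 1), 0.8376315, tolerance = 1e-6)
  expect_equal(sine_pdf(d, 0), pi / 2, tolerance = 1e-12)
  expect_equal(sine_pdf(d, 1), 0.3156498, tolerance = 1e-6)
  expect_equal(sine_sf(d, 0), 1)
  expect_equal(sine_sf(d, 1), 0.1623685, tolerance = 1e-6)
  expect_equal(sine_hrf(d, 0), pi / 2, tolerance = 1e-12)
  expect_equal(sine_hrf(d, 1), 1.944033, tolerance = 1e-5)
  expect_equal(sine_chrf(d, 0), 0)
  expect_equal(sine_chrf(d, 1), 1.817887, tolerance = 1e-5)
  expect_equal(sine_odds(d, 0), 0)

  # the sine CDF at the baseline median is forced for every family
  for (p in oracle_param_grid()) {
    dd <- grid_dist(p)
    med <- baseline_quantile(dd, 0.5)
    expect_equal(sine_cdf(dd, med), sin(pi / 4), tolerance = 1e-10)
    expect_equal(sine_sf(dd, med), 1 - sin(pi / 4), tolerance = 1e-10)
    expect_equal(sine_odds(dd, med), 1 + sqrt(2), tolerance = 1e-9)
    expect_equal(sine_chrf(dd, med), -log(1 - sin(pi / 4)), tolerance = 1e-9)
  }
})

test_that("sine functions satisfy the definitional identities on a grid", {
  for (p in oracle_param_grid()) {
    d <- grid_dist(p)
    t <- sine_quantile(d, c(0.05, 0.2, 0.5, 0.8, 0.95, 0.999))
    f <- sine_pdf(d, t); s <- sine_sf(d, t); F <- sine_cdf(d, t)
    expect_equal(s, 1 - F, tolerance = 1e-10)
    expect_equal(sine_hrf(d, t), f / s, tolerance = 1e-10)
    expect_equal(sine_chrf(d, t), -log(s), tolerance = 1e-10)
    expect_equal(sine_odds(d, t), F / s, tolerance = 1e-10)
    # stochastic ordering: sin(pi x / 2) >= x on [0, 1]
    expect_true(all(F >= baseline_cdf(d, t) - 1e-12))
    # monotonicity
    expect_true(all(diff(F) >= 0))
    expect_true(all(diff(sine_chrf(d, t)) >= 0))
  }
})

test_that("sine functions agree with the naive oracle transcription", {
  for (p in oracle_param_grid()) {
    d <- grid_dist(p)
    t <- sine_quantile(d, c(0.1, 0.3, 0.6, 0.9))
    expect_equal(sine_cdf(d, t), oracle_F(p$family, t, p$l, p$a),
                 tolerance = 1e-10)
    expect_equal(sine_pdf(d, t), oracle_f(p$family, t, p$l, p$a),
                 tolerance = 1e-10)
    expect_equal(sine_hrf(d, t), oracle_h(p$family, t, p$l, p$a),
                 tolerance = 1e-9)
  }
})

test_that("sine PDF integrates to one and differentiates the CDF", {
  for (p in oracle_param_grid()) {
    d <- grid_dist(p)
    expect_gt(quad_pdf(d), 0.999)
    expect_lt(quad_pdf(d), 1.001)
    # central differences of the CDF recover the PDF
    t <- sine_quantile(d, c(0.1, 0.25, 0.5, 0.75, 0.9))
    h <- 1e-6 * pmax(t, 1)
    num <- (sine_cdf(d, t + h) - sine_cdf(d, t - h)) / (2 * h)
    expect_equal(num, sine_pdf(d, t), tolerance = 1e-6)
  }
})

test_that("quantile and inverse-CHRF round trips are exact", {
  d <- sine_dist("se", scale = 1)
  expect_equal(sine_quantile(d, sin(pi / 4)), log(2), tolerance = 1e-12)
  expect_equal(sine_quantile(d, 0), 0)
  expect_equal(sine_chrf_inverse(d, 0), 0)
  expect_equal(sine_chrf_inverse(d, log(2)), log(3 / 2), tolerance = 1e-12)
  expect_equal(baseline_quantile(sine_dist("exponential", 2), 1 - exp(-2)), 1,
               tolerance = 1e-12)

  u <- c(0.001, 0.1, 0.37, 0.5, 0.83, 0.99, 0.9999)
  v <- c(0.001, 0.05, 0.4, 1, 3, 8)
  for (p in oracle_param_grid()) {
    dd <- grid_dist(p)
    expect_equal(sine_cdf(dd, sine_quantile(dd, u)), u, tolerance = 1e-10)
    expect_equal(sine_chrf(dd, sine_chrf_inverse(dd, v)), v,
                 tolerance = 1e-10)
    expect_equal(baseline_cdf(dd, baseline_quantile(dd, u)), u,
                 tolerance = 1e-10)
  }
})

test_that("survival function keeps precision deep in the right tail", {
  d <- sine_dist("se", scale = 1)
  t <- 30 # G(t) is within 1e-13 of 1; naive 1 - sin(.) would be garbage
  expect_equal(sine_sf(d, t, log = TRUE),
               log(2) + 2 * log(sin(pi * exp(-t) / 4)),
               tolerance = 1e-12)
  expect_true(is.finite(sine_hrf(d, t, log = TRUE)))
  # hazard of the sine-exponential tends to 2x the baseline rate: the
  # half-angle form must reproduce that limit, not overflow
  expect_equal(sine_hrf(d, 40), 2, tolerance = 1e-6)
})

test_that("parameter-domain violations raise errors", {
  expect_error(sine_dist("weibull", scale = -1, shape = 1),
               class = "sinegph_domain_error")
  expect_error(sine_dist("weibull", scale = 1, shape = 0),
               class = "sinegph_domain_error")
  expect_error(sine_dist("weibull", scale = 1),
               class = "sinegph_domain_error")
  expect_error(sine_dist("exponential", scale = 1, shape = 2),
               class = "sinegph_domain_error")
  expect_error(sine_dist("cauchy", scale = 1),
               class = "sinegph_domain_error")
  d <- sine_dist("se", 1)
  expect_error(sine_quantile(d, 1), class = "sinegph_domain_error")
  expect_error(sine_quantile(d, -0.1), class = "sinegph_domain_error")
  expect_error(sine_chrf_inverse(d, -1), class = "sinegph_domain_error")
  expect_error(baseline_quantile(d, 1.2), class = "sinegph_domain_error")
})
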