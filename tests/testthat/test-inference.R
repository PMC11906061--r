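test_that("log prior follows the gamma/normal factorisation", {
  pr <- prior_config()
  # gamma(10,10) log-density at 1: 10 log 10 - log Gamma(10) - 10
  expect_equal(log_prior(c(lambda = 1), pr),
               10 * log(10) - lgamma(10) - 10, tolerance = 1e-12)
  expect_equal(log_prior(c(lambda = 1), pr), 0.2240234, tolerance = 1e-6)
  expect_equal(log_prior(c(treat = 0), pr), -log(10 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(log_prior(c(treat = 0), pr), -3.2215236, tolerance = 1e-6)
  expect_equal(log_prior(c(lambda = 1, alpha = 2, b = 0.5), pr),
               dgamma(1, 10, 10, log = TRUE) + dgamma(2, 10, 10, log = TRUE) +
                 dnorm(0.5, 0, 10, log = TRUE), tolerance = 1e-12)
  expect_identical(log_prior(c(lambda = -1), pr), -Inf)
  expect_identical(log_prior(c(lambda = 1, alpha = 0), pr), -Inf)
  expect_error(log_prior(c(1, 2), pr), class = "sinegph_domain_error")
})

test_that("log posterior decomposes into likelihood plus prior", {
  set.seed(8)
  df <- random_toy_data(12, "weibull", 0.5, 1.2, c(x = 0.3))
  pars <- c(lambda = 0.6, alpha = 1.1, x = 0.2)
  pr <- prior_config()
  lp <- log_posterior(pars, df, "sw", pr)
  m <- sine_ph(sine_dist("sw", 0.6, 1.1), c(x = 0.2))
  expect_equal(lp, ph_loglik(m, df) + log_prior(pars, pr), tolerance = 1e-12)
  # empty data: the prior is the posterior
  expect_equal(log_posterior(pars, NULL, "sw", pr), log_prior(pars, pr))
  # likelihood additivity: duplicating rows doubles the data part
  df2 <- dplyr::bind_rows(df, df)
  expect_equal(log_posterior(pars, df2, "sw", pr) - log_prior(pars, pr),
               2 * (lp - log_prior(pars, pr)), tolerance = 1e-10)
  expect_identical(log_posterior(c(lambda = -1, alpha = 1, x = 0), df, "sw",
                                 pr), -Inf)
})

test_that("the MLE solves the score equation (1-D grid oracle)", {
  set.seed(14)
  d0 <- sine_dist("se", 0.7)
  tt <- simulate_lifetimes(sine_ph(d0), n = 200)
  df <- tibble::tibble(time = tt, event = 1L)
  fit <- fit_sine_ph_mle(df, "se")
  # brute-force grid over lambda
  grid <- seq(0.3, 1.5, by = 1e-4)
  ll <- vapply(grid, function(l) {
    sum(sine_pdf(sine_dist("se", l), tt, log = TRUE))
  }, numeric(1))
  expect_equal(unname(fit$estimate["lambda"]), grid[which.max(ll)],
               tolerance = 1e-4)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-5)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-8)
})

test_that("restarting the optimiser at the optimum is stationary", {
  d <- synthetic_trial("gastric", seed = 23)
  fit <- fit_sine_ph_mle(d, "sw")
  fit2 <- fit_sine_ph_mle(d, "sw", init = fit$estimate)
  expect_true(fit2$converged)
  expect_equal(fit2$estimate, fit$estimate, tolerance = 1e-6)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-10)
})

test_that("maximum likelihood recovers simulated truth within 3 SE", {
  m <- sine_ph(sine_dist("se", 0.4), beta = c(treat = -0.5))
  d <- simulate_ph(m, n = 600, covariates = list(treat = cov_bernoulli(0.5)),
                   censoring = "uniform", target_censoring = 0.15, seed = 61)
  fit <- fit_sine_ph_mle(d, "se")
  truth <- c(lambda = 0.4, treat = -0.5)
  z <- abs(fit$estimate[names(truth)] - truth) / fit$std_error[names(truth)]
  expect_true(all(z < 3))
})

test_that("split R-hat behaves at its landmark cases", {
  set.seed(19)
  one <- rnorm(1000)
  expect_equal(rhat(cbind(one, one, one, one)), 1, tolerance = 0.01)
  expect_gt(rhat(cbind(rep(0, 100), rep(10, 100))), 1.1)
  expect_equal(rhat(matrix(2, 50, 4)), 1)
  x <- matrix(rnorm(4000), 1000, 4)
  expect_gte(rhat(x), 1 - 1e-8)
  expect_lt(rhat(x), 1.01)
  # trending chains must be flagged
  bad <- matrix(rnorm(400), 100, 4) + seq(0, 5, length.out = 100)
  expect_gt(rhat(bad), 1.1)
  expect_warning(rhat(matrix(rnorm(100), ncol = 1)), "Single chain")
})

test_that("effective sample size tracks the autocorrelation structure", {
  set.seed(20)
  x <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(ess(x) / 4000 - 1), 0.2)
  # AR(1) with coefficient 0.9: ess/total -> (1-0.9)/(1+0.9)
  ar <- replicate(4, as.vector(stats::arima.sim(list(ar = 0.9), 1000)))
  ratio <- ess(ar) / 4000
  expect_gt(ratio, (1 - 0.9) / (1 + 0.9) / 2)
  expect_lt(ratio, (1 - 0.9) / (1 + 0.9) * 2)
  expect_identical(ess(matrix(3, 100, 4)), 0)
  # independent reference: coda's estimator on the same i.i.d. draws
  skip_if_not_installed("coda")
  ours <- ess(x)
  theirs <- sum(vapply(1:4, function(j) {
    unname(coda::effectiveSize(coda::mcmc(x[, j])))
  }, numeric(1)))
  expect_lt(abs(ours / theirs - 1), 0.35)
})

test_that("the HMC kernel samples a standard normal correctly", {
  set.seed(33)
  res <- sinegph:::hmc_chain(
    lp = function(u) -0.5 * sum(u^2), d = 1, iter = 3000, warmup = 500,
    step_size = NULL, leapfrog = 10, target_accept = 0.8, init_u = 0.3
  )
  x <- res$draws[, 1]
  e <- ess(matrix(x, ncol = 1)) |> suppressWarnings()
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(e))
  expect_lt(abs(sd(x) - 1), 0.05)
  expect_equal(res$divergences, 0L)
})

test_that("the adaptive Metropolis fallback meets the same contract", {
  d <- synthetic_trial("gastric", seed = 41)
  fit <- fit_sine_ph_bayes(
    d, "se", seed = 42,
    mcmc = mcmc_config(chains = 4, iter = 2500, warmup = 1000,
                       sampler = "adaptive_metropolis")
  )
  s <- summarize_posterior(fit)
  expect_true(all(s$rhat < 1.05))
  expect_true(all(s$ess > 100))
})

test_that("prior-only sampling recovers the gamma(10,10) prior", {
  fit <- fit_sine_ph_bayes(NULL, "se", seed = 71,
                           mcmc = mcmc_config(chains = 4, iter = 1500,
                                              warmup = 500))
  s <- summarize_posterior(fit)
  lam <- s[s$term == "lambda", ]
  expect_lt(abs(lam$estimate - 1), 3 * lam$mcse)
  expect_lt(abs(lam$sd - sqrt(10) / 10), 0.03)
  expect_true(all(fit$draws > 0))
})

test_that("posterior credible intervals cover the generating truth", {
  # reduced-scale calibration: 20 sine-exponential trial replicates
  truth <- c(lambda = 0.3, treat = -0.4)
  model <- sine_ph(sine_dist("se", truth["lambda"]),
                   beta = c(treat = truth[["treat"]]))
  covered <- 0L
  total <- 0L
  for (rep in 1:20) {
    d <- synthetic_trial("gastric", seed = 100 + rep, model = model)
    fit <- fit_sine_ph_bayes(d, "se", seed = 200 + rep,
                             mcmc = mcmc_config(chains = 2, iter = 700,
                                                warmup = 300))
    s <- summarize_posterior(fit)
    for (p in names(truth)) {
      row <- s[s$term == p, ]
      total <- total + 1L
      if (truth[[p]] >= row$q2.5 && truth[[p]] <= row$q97.5) {
        covered <- covered + 1L
      }
    }
  }
  expect_gte(covered / total, 0.85)
})

test_that("posterior summaries have the documented shape and ordering", {
  fake <- structure(
    list(family = "exponential",
         draws = array(rep(2, 400), c(100, 2, 2),
                       dimnames = list(NULL, NULL, c("lambda", "b"))),
         params = c("lambda", "b"), beta_names = "b",
         divergences = c(0L, 0L), accept_rate = c(1, 1),
         priors = prior_config(), mcmc = mcmc_config(), seed = 1,
         data = NULL, n = 0),
    class = "sine_ph_bayes"
  )
  s <- summarize_posterior(fake)
  expect_equal(names(s), c("term", "estimate", "mcse", "sd", "q2.5",
                           "median", "q97.5", "ess", "rhat"))
  expect_equal(s$estimate, c(2, 2))
  expect_equal(s$median, c(2, 2))
  expect_equal(s$sd, c(0, 0))
  expect_identical(s$ess, c(0, 0))

  fit <- fit_sine_ph_bayes(NULL, "sw", seed = 9,
                           mcmc = mcmc_config(chains = 2, iter = 400,
                                              warmup = 200))
  s2 <- summarize_posterior(fit)
  expect_true(all(s2$q2.5 <= s2$median & s2$median <= s2$q97.5))
  expect_equal(generics::tidy(fit), s2)
  g <- generics::glance(fit)
  expect_equal(g$chains, 2)
  expect_equal(g$draws, 400)
})

test_that("Bayesian fit requires a seed and a valid config", {
  d <- synthetic_trial("gastric", seed = 1)
  expect_error(fit_sine_ph_bayes(d, "sw"), class = "sinegph_domain_error")
  expect_error(mcmc_config(iter = 100, warmup = 100),
               class = "sinegph_domain_error")
  expect_error(mcmc_config(target_accept = 1.2),
               class = "sinegph_domain_error")
})
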