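test_that("standard RR sampler recovers prevalence through a dice design", {
  # data constructed at the expected counts for a known pi
  pi <- c(0.1, 0.2, 0.05, 0.15, 0.1, 0.1, 0.05, 0.25)
  P <- dice_profile(3)
  counts <- round(5000 * drop(unclass(P) %*% pi))
  draws <- fit_standard_rr(counts, P, alpha = 1, n_iter = 4000,
                           burn_in = 500, seed = 3)
  expect_lt(max(abs(colMeans(draws) - pi)), 0.03)
  expect_equal(rowSums(draws), rep(1, nrow(draws)), tolerance = 1e-12)
})

test_that("with no all-no observations the cheating posterior collapses", {
  # every indicator is structurally 0 (cheating implies category K), so
  # the logistic likelihood pushes tau towards zero
  m <- dual_model(rr_matrix(diag(8)))
  counts <- c(40, 30, 30, 50, 40, 30, 30, 0)
  b <- fit_bayes(m, freq_pair(counts, counts), burn_in = 1500,
                 n_iter = 1500, seed = 2)
  s <- posterior_summary(b)
  expect_lt(s$mean[s$parameter == "tau_1"], 0.05)
  expect_lt(s$mean[s$parameter == "tau_2"], 0.05)
  # and the latent posterior tracks the pooled empirical distribution
  pooled <- counts / sum(counts)
  pim <- s$mean[grepl("^pi_", s$parameter)]
  expect_lt(max(abs(pim - pooled)), 0.025)
})

test_that("posterior summaries behave on degenerate and uniform chains", {
  m <- dual_model(rr_matrix(diag(8)))
  b <- fit_bayes(m, freq_pair(rep(5, 8), rep(5, 8)), burn_in = 300,
                 n_iter = 300, seed = 1)
  # constant chain: interval collapses to the point
  b2 <- b
  b2$draws <- matrix(rep(b$draws[1, ], each = 200), nrow = 200,
                     dimnames = list(NULL, colnames(b$draws)))
  b2$tau_bar <- matrix(0.3, 200, 2,
                       dimnames = list(NULL, colnames(b$tau_bar)))
  s <- posterior_summary(b2)
  expect_equal(s$lower, s$upper, tolerance = 1e-12)
  expect_equal(s$lower, s$mean, tolerance = 1e-12)
  # iid uniform chain: mean 0.5, equal-tailed interval (0.025, 0.975)
  set.seed(99)
  b3 <- b2
  b3$tau_bar[, 1] <- stats::runif(200)
  b3$tau_bar <- rbind(b3$tau_bar,
                      matrix(stats::runif(2 * 9800), ncol = 2))
  b3$draws <- b3$draws[rep(1, 10000), ]
  s3 <- posterior_summary(b3)
  r <- s3[s3$parameter == "tau_1", ]
  expect_lt(abs(r$mean - 0.5), 0.02)
  expect_lt(abs(r$lower - 0.025), 0.01)
  expect_lt(abs(r$upper - 0.975), 0.01)
})

test_that("Geweke diagnostic calibrates and flags", {
  set.seed(42)
  z_null <- replicate(20, geweke_diagnostic(stats::rnorm(10000))$z)
  expect_true(all(abs(z_null) < 3.5))
  expect_gt(mean(abs(z_null) < 2), 0.8)
  shifted <- c(stats::rnorm(5000), stats::rnorm(5000, 5))
  expect_true(geweke_diagnostic(shifted)$flagged)
  const <- geweke_diagnostic(rep(1, 1000))
  expect_true(is.na(const$z))
  expect_false(const$flagged)
  expect_error(geweke_diagnostic(stats::rnorm(50)), "200")
})

test_that("posterior of the prevalence is symmetric in sample labels", {
  # identical designs in both samples: swapping the two samples' data
  # leaves the latent-prevalence posterior unchanged up to Monte-Carlo
  # error
  P <- dice_profile(3)
  m <- dual_model(P, P)
  a <- c(30, 20, 25, 40, 15, 25, 30, 200)
  b <- c(10, 15, 10, 20, 10, 15, 10, 150)
  f1 <- fit_bayes(m, freq_pair(a, b), burn_in = 2500, n_iter = 2500,
                  seed = 5)
  f2 <- fit_bayes(m, freq_pair(b, a), burn_in = 2500, n_iter = 2500,
                  seed = 6)
  p1 <- colMeans(pi_draws(f1))
  p2 <- colMeans(pi_draws(f2))
  expect_lt(max(abs(p1 - p2)), 0.04)
})

test_that("reproducibility and validation of the sampler interface", {
  m <- model_preset("model-I")
  fx <- benefit_survey()
  b1 <- fit_bayes(m, fx, burn_in = 400, n_iter = 400, seed = 7)
  b2 <- fit_bayes(m, fx, burn_in = 400, n_iter = 400, seed = 7)
  expect_identical(b1$draws, b2$draws)
  expect_true(all(abs(b1$draws) < 10))    # draws respect the prior bounds
  expect_error(fit_bayes(model_preset("model-II"), fx),
               "individual records")
  expect_error(fit_bayes(m, fx, init = rep(20, 9), burn_in = 10,
                         n_iter = 10), "bounds")
  expect_error(prior_spec(lambda_bound = -1), "positive")
})

test_that("prior width does not move the cheating inference on the survey", {
  m <- model_preset("model-I")
  tab <- prior_sensitivity(m, benefit_survey(), widths = c(5, 10),
                           seed = 3, burn_in = 2500, n_iter = 2500)
  t1 <- tab[tab$parameter == "tau_bar_1", ]
  t2 <- tab[tab$parameter == "tau_bar_2", ]
  expect_lt(abs(diff(t1$mean)), 0.05)
  expect_lt(abs(diff(t2$mean)), 0.05)
  expect_type(tab$flagged, "logical")
})
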