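test_that("marginalizing the survey tables sums the dropped question", {
  fx <- benefit_survey()
  m12 <- marginalize_freq(fx[["1"]], J = 3, keep = c(1, 2))
  expect_equal(m12$counts, c(60 + 48, 116 + 269, 41 + 144, 174 + 908))
  d12 <- marginalize_freq(fx[["2"]], J = 3, keep = c(1, 2))
  expect_equal(d12$counts, c(2, 37, 4, 424))
  expect_equal(m12$n, fx[["1"]]$n)
  expect_error(marginalize_freq(fx[["1"]], 3, keep = 4), "1..J")
})

test_that("marginalized Kronecker design equals the retained Kronecker", {
  set.seed(15)
  mats <- lapply(1:3, function(i) {
    w <- stats::runif(3); w <- w / sum(w)
    forced_response_matrix(rr_device(w[1], w[2], w[3]))
  })
  P123 <- profile_design(mats)
  pi <- stats::runif(8); pi <- pi / sum(pi)
  full <- drop(unclass(P123) %*% pi)
  for (keep in list(c(1, 2), c(1, 3), c(2, 3))) {
    ans <- profile_answers(1:8, 3)
    newk <- profile_index(ans[, keep, drop = FALSE])
    lhs <- drop(rowsum(full, newk))
    pi_m <- drop(rowsum(pi, newk))
    rhs <- drop(unclass(profile_design(mats[keep])) %*% pi_m)
    expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("posterior predictive check is calibrated on self-generated data", {
  m <- model_preset("model-I")
  th <- theta_modelI(m, published_modelI_pi(), 0.157, 0.536)
  recs <- simulate_survey(m, th, 1760, 467, seed = 31)
  recs$true_profile <- NULL; recs$cheater <- NULL
  b <- fit_bayes(m, recs, burn_in = 4000, n_iter = 4000, seed = 1)
  # near-empty cells may trip the guarded Pearson denominator here
  p <- suppressWarnings(posterior_predictive_check(b, n_draws = 2000,
                                                   seed = 1))
  expect_gte(p$p_value, 0.05)
  expect_lte(p$p_value, 0.95)
})

test_that("PPC is invariant to the order of the posterior draws", {
  m <- model_preset("model-I")
  b <- fit_bayes(m, benefit_survey(), burn_in = 4000, n_iter = 6000,
                 seed = 2)
  p1 <- posterior_predictive_check(b, n_draws = 4000, seed = 5)
  set.seed(77)
  perm <- sample.int(nrow(b$draws))
  b2 <- b
  b2$draws <- b$draws[perm, ]
  b2$tau_bar <- b$tau_bar[perm, ]
  p2 <- posterior_predictive_check(b2, n_draws = 4000, seed = 5)
  expect_lt(abs(p1$p_value - p2$p_value), 0.025)
})

test_that("PPC refuses covariate models and tiny draw counts", {
  m2 <- model_preset("model-II")
  truth <- published_modelII_truth(m2)
  recs <- simulate_survey(m2, truth, 300, 150, seed = 3)
  recs$true_profile <- NULL; recs$cheater <- NULL
  b <- fit_bayes(m2, recs, burn_in = 300, n_iter = 300, seed = 1)
  expect_error(posterior_predictive_check(b), "covariate-free")
  m <- model_preset("model-I")
  bI <- fit_bayes(m, benefit_survey(), burn_in = 300, n_iter = 1200,
                  seed = 1)
  expect_error(posterior_predictive_check(bI, n_draws = 100), "1000")
})

test_that("pairwise question models agree when cheating is profile-free", {
  # cheating that does not depend on the question subset: the marginal
  # two-question fits should estimate the same cheating levels
  m <- model_preset("model-I")
  th <- theta_modelI(m, published_modelI_pi(), 0.157, 0.536)
  recs <- simulate_survey(m, th, 20000, 8000, seed = 13)
  recs$true_profile <- NULL; recs$cheater <- NULL
  designs <- rep(list(dice_matrix()), 3)
  tab <- pairwise_sensitivity(designs, recs, method = "ml", n_starts = 3,
                              seed = 1)
  expect_equal(tab$model, c("full", "q1q2", "q1q3", "q2q3"))
  expect_lt(max(abs(tab$tau_1 - 0.157)), 0.05)
  expect_lt(max(abs(tab$tau_2 - 0.536)), 0.05)
  expect_error(pairwise_sensitivity(rep(list(dice_matrix()), 2),
                                    benefit_survey()),
               "at least three")
})

test_that("pairwise MCMC intervals separate RR from DQ cheating", {
  tab <- pairwise_sensitivity(rep(list(dice_matrix()), 3), benefit_survey(),
                              method = "mcmc", burn_in = 2500,
                              n_iter = 2500, seed = 4)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$tau_1 < tab$tau_2))
  expect_true(tab$ci_disjoint[tab$model == "full"])
})
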