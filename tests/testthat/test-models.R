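test_that("logistic cheating probability", {
  expect_equal(cheating_prob(c(0, 0, 0), c(1, 2, -1)), 0.5)
  expect_equal(cheating_prob(stats::qlogis(0.157), 1), 0.157)
  expect_equal(cheating_prob(c(-1.899, -0.968, -0.845), c(1, 0, 0)),
               stats::plogis(-1.899))
  expect_error(cheating_prob(c(0, 1), c(1, NA)), "finite")
  expect_error(cheating_prob(c(0, 1), 1), "conformable")
})

test_that("mixture cell probabilities: degenerate and matrix forms agree", {
  m_id <- dual_model(rr_matrix(diag(8)))
  pi <- published_modelI_pi()
  # tau -> 0 with identity design returns pi itself
  th0 <- c(lambda_from_pi(pi, m_id$Z), -40, -40)
  expect_equal(cell_probabilities(m_id, th0, sample = 1), pi,
               tolerance = 1e-10)
  # tau -> 1 collapses onto the all-no category
  th1 <- c(lambda_from_pi(pi, m_id$Z), 40, 40)
  expect_equal(cell_probabilities(m_id, th1, sample = 1),
               c(rep(0, 7), 1), tolerance = 1e-12)
  # mixture form equals the misclassification-matrix form
  m <- dual_model(dice_profile(3))
  thm <- theta_modelI(m, rep(1 / 8, 8), 0.2, 0.2)
  expect_equal(cell_probabilities(m, thm, sample = 1),
               drop(sp_no_matrix(m$P1, 0.2) %*% rep(1 / 8, 8)),
               tolerance = 1e-12)
  # probabilities over random specs
  set.seed(21)
  for (i in 1:10) {
    pi_r <- stats::runif(8); pi_r <- pi_r / sum(pi_r)
    th <- theta_modelI(m, pi_r, stats::runif(1), stats::runif(1))
    for (s in 1:2) {
      p <- cell_probabilities(m, th, sample = s)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("stacked two-sample form equals a block misclassification operator", {
  m <- dual_model(dice_profile(3))
  K <- 8
  E <- matrix(0, K, K); E[K, ] <- 1
  set.seed(33)
  for (i in 1:10) {
    pi <- stats::runif(K); pi <- pi / sum(pi)
    tau <- stats::runif(2)
    th <- theta_modelI(m, pi, tau[1], tau[2])
    # block operator on the stacked (pi, pi) vector
    B <- rbind(cbind((1 - tau[1]) * unclass(m$P1) + tau[1] * E,
                     matrix(0, K, K)),
               cbind(matrix(0, K, K),
                     (1 - tau[2]) * unclass(m$P2) + tau[2] * E))
    stacked <- drop(B %*% c(pi, pi))
    expect_equal(c(cell_probabilities(m, th, 1),
                   cell_probabilities(m, th, 2)),
                 stacked, tolerance = 1e-12)
  }
})

test_that("log-likelihood: record/frequency equivalence and RR oracle", {
  m <- dual_model(dice_profile(3))
  fx <- benefit_survey()
  recs <- do.call(rbind, lapply(fx, function(f)
    data.frame(sample = f$sample, category = rep(seq_along(f$counts),
                                                 f$counts))))
  set.seed(17)
  for (i in 1:5) {
    pi <- stats::runif(8, 0.02, 1); pi <- pi / sum(pi)
    th <- theta_modelI(m, pi, stats::runif(1, 0.05, 0.9),
                       stats::runif(1, 0.05, 0.9))
    expect_equal(dual_loglik(m, th, recs), dual_loglik(m, th, fx),
                 tolerance = 1e-10)
  }
  # single direct-questioning respondent, all-no, no cheating, uniform pi
  one <- data.frame(sample = 2, category = 8)
  th_u <- c(rep(0, 7), -40, -40)
  expect_equal(dual_loglik(m, th_u, one), log(1 / 8), tolerance = 1e-10)
  # standard RR special case: tau = 0 gives the multinomial likelihood
  # with p* = P pi (explicit oracle)
  pi <- published_modelI_pi()
  th_rr <- c(lambda_from_pi(pi, m$Z), -40, -40)
  oracle <- sum(fx[["1"]]$counts * log(drop(unclass(m$P1) %*% pi))) +
    sum(fx[["2"]]$counts * log(pi))
  expect_equal(dual_loglik(m, th_rr, fx), oracle, tolerance = 1e-8)
  # zero predicted probability for an observed cell -> -Inf with warning
  m_id <- dual_model(rr_matrix(diag(8)))
  # lambda_q1 = -400 underflows the yes-to-question-1 cells to exactly 0
  th_zero <- c(-400, rep(0, 6), -40, -40)
  expect_warning(ll <- dual_loglik(m_id, th_zero,
                                   freq_pair(c(5, rep(1, 7)), rep(1, 8))),
                 "zero predicted")
  expect_identical(ll, -Inf)
})

test_that("Clark-Desharnais mapping and likelihood equivalence", {
  sp <- cd_to_spno(cd_parameters(0.3, 0.5, 0.2))
  expect_equal(sp$pi_yes, 0.375)
  expect_equal(sp$tau, 0.2)
  g0 <- cd_to_spno(cd_parameters(0.4, 0.6, 0))
  expect_equal(g0$tau, 0)
  expect_equal(g0$pi_yes, 0.4)
  expect_error(cd_to_spno(cd_parameters(0, 0, 1)), "undefined")
  set.seed(29)
  for (i in 1:20) {
    w <- stats::runif(3, 0.05, 1); w <- w / sum(w)
    cd <- cd_parameters(w[1], w[2], w[3], theta1 = 0.5, theta2 = 0.25)
    sp <- cd_to_spno(cd)
    back <- spno_to_cd(sp$pi_yes, sp$tau, 0.5, 0.25)
    expect_equal(unlist(back[1:3]), unlist(cd[1:3]), tolerance = 1e-12)
    # CD likelihood equals the dual-model likelihood at the mapped
    # parameters with shared cheating across the two forced-yes designs
    counts <- list(c(37, 63), c(21, 79))
    m <- dual_model(cd_design_matrix(0.5), cd_design_matrix(0.25))
    th <- c(lambda_from_pi(c(sp$pi_yes, 1 - sp$pi_yes), m$Z),
            stats::qlogis(sp$tau), stats::qlogis(sp$tau))
    expect_equal(cd_loglik(cd, counts),
                 dual_loglik(m, th, freq_pair(counts[[1]], counts[[2]])),
                 tolerance = 1e-10)
  }
})

test_that("identifiability counting", {
  c3 <- identifiability_count(3)
  expect_identical(c(c3$frequencies, c3$parameters), c(14, 9))
  expect_true(c3$identified)
  c2 <- identifiability_count(2)
  expect_identical(c(c2$frequencies, c2$parameters), c(6, 5))
  expect_true(c2$identified)
  c1 <- identifiability_count(1, dual = FALSE)
  expect_identical(c(c1$frequencies, c1$parameters), c(1, 2))
  expect_false(c1$identified)
})

test_that("model presets carry the published covariate structure", {
  expect_equal(model_preset("model-I")$n_par, 9)
  m2 <- model_preset("model-II")
  expect_equal(m2$n_par, 12)
  expect_equal(m2$covariates1, c("Sex", "Advantage"))
  expect_equal(m2$covariates2, "Advantage")
  expect_equal(model_preset("model-III")$n_par, 17)
})
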