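#' Default covariate generators for the survey simulator
#'
#' Covariates are drawn independently across respondents and across
#' covariates (only marginal distributions are available for the
#' motivating survey): Age is a uniform integer on -20..20 (years centred
#' at 50), Sex is Bernoulli(0.5) (0 woman / 1 man), and the attitude
#' scores Reason and Advantage are drawn from the design-specific
#' marginal distributions of [attitude_marginals()].
#'
#' @return named list of functions `f(n, sample)` returning n draws.
#' @export
default_covariate_generators <- function() {
  marg <- attitude_marginals()
  att <- function(statement) {
    force(statement)
    function(n, sample) {
      d <- marg[marg$design == c("RR", "DQ")[sample] &
                  marg$statement == statement, ]
      sample(d$score, n, replace = TRUE, prob = d$proportion / sum(d$proportion))
    }
  }
  list(
    Age = function(n, sample) sample(-20:20, n, replace = TRUE),
    Sex = function(n, sample) stats::rbinom(n, 1, 0.5),
    Reason = att("Reason"),
    Advantage = att("Advantage"))
}

#' Simulate a dual-sample randomized-response survey
#'
#' Generates individual records with the exact generative structure of the
#' dual mixture model: per respondent, covariates are drawn from the
#' generators, the cheating indicator is Bernoulli with the logistic
#' cheating probability, the true latent profile is drawn from pi (drawn
#' for cheaters too, then ignored -- cheaters are treated as a random
#' sample from the population), and the observed category is the all-no
#' profile K for cheaters or a draw from column `true` of P_s otherwise.
#' Respondents are generated in a fixed order (sample 1 then sample 2)
#' from a single seed, so the output is fully reproducible.
#'
#' @param model a [dual_model()].
#' @param theta true packed parameter vector (lambda, beta1, beta2).
#' @param n1,n2 sample sizes for the randomized-response and
#'   direct-questioning samples.
#' @param seed integer seed.
#' @param covariate_generators named list of generator functions (see
#'   [default_covariate_generators()]); only the covariates the model
#'   uses are generated unless `keep_all_covariates`.
#' @param keep_all_covariates generate all four standard covariates even
#'   if the model uses none.
#' @return data.frame of records with columns `sample`, `category`, any
#'   covariates, and the simulation truth `true_profile` and `cheater`.
#' @examples
#' m <- model_preset("model-I")
#' truth <- c(lambda_from_pi(rep(1/8, 8), m$Z), stats::qlogis(0.15),
#'            stats::qlogis(0.5))
#' head(simulate_survey(m, truth, n1 = 100, n2 = 50, seed = 1))
#' @export
simulate_survey <- function(model, theta, n1, n2, seed = 1,
                            covariate_generators = default_covariate_generators(),
                            keep_all_covariates = FALSE) {
  if (n1 < 0 || n2 < 0) stop("sample sizes must be non-negative")
  pars <- split_theta(model, theta)
  pi <- pi_from_lambda(pars$lambda, model$Z)
  K <- model$K
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- list()
  for (s in 1:2) {
    n <- c(n1, n2)[s]
    if (n == 0) next
    want <- if (keep_all_covariates) names(covariate_generators)
            else union(model$covariates1, model$covariates2)
    df <- data.frame(sample = rep(s, n))
    for (v in want) {
      if (is.null(covariate_generators[[v]])) {
        stop("no generator for covariate ", v)
      }
      df[[v]] <- covariate_generators[[v]](n, s)
    }
    beta <- if (s == 1) pars$beta1 else pars$beta2
    X <- cheat_design(model, df, s)
    tau <- cheating_prob(beta, X)
    cheat <- stats::rbinom(n, 1, tau)
    true_prof <- sample.int(K, n, replace = TRUE, prob = pi)
    P <- unclass(if (s == 1) model$P1 else model$P2)
    obs <- integer(n)
    for (l in unique(true_prof)) {
      ii <- which(true_prof == l)
      obs[ii] <- sample.int(K, length(ii), replace = TRUE, prob = P[, l])
    }
    obs[cheat == 1] <- K
    df$category <- obs
    df$true_profile <- true_prof
    df$cheater <- cheat
    out[[s]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parameter-recovery study
#'
#' Repeatedly simulates surveys from known truth and refits, reporting
#' per-parameter bias, RMSE and Monte-Carlo standard error of the mean
#' estimate (and credible-interval coverage for MCMC fits).
#'
#' @param model a [dual_model()].
#' @param theta true parameter vector.
#' @param n1,n2 sample sizes per replicate.
#' @param n_replicates number of simulate-fit replicates (0 gives an
#'   empty report).
#' @param method `"ml"` or `"mcmc"`.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param fit_args list of further arguments to the fitter.
#' @param transform optional function mapping a packed theta vector to a
#'   named vector of derived quantities (e.g. latent profile
#'   probabilities); recovery is then reported on that scale. Useful
#'   because individual log-linear parameters are boundary-prone when
#'   latent cells are sparse, while the probabilities they imply are not.
#' @return data.frame with one row per parameter: truth, mean_estimate,
#'   bias, rmse, mc_se, and for MCMC, `coverage` of the 95% interval.
#' @export
recovery_study <- function(model, theta, n1, n2, n_replicates,
                           method = c("ml", "mcmc"), seed = 1,
                           fit_args = list(), transform = NULL) {
  method <- match.arg(method)
  tf <- if (is.null(transform)) {
    function(th) stats::setNames(th, model$par_names)
  } else transform
  true_q <- tf(theta)
  npar <- length(true_q)
  if (n_replicates == 0) {
    return(data.frame(parameter = character(), truth = numeric(),
                      mean_estimate = numeric(), bias = numeric(),
                      rmse = numeric(), mc_se = numeric(),
                      coverage = numeric()))
  }
  est <- matrix(NA_real_, n_replicates, npar)
  cover <- matrix(NA, n_replicates, npar)
  for (r in seq_len(n_replicates)) {
    recs <- simulate_survey(model, theta, n1, n2, seed = seed + r)
    recs$true_profile <- NULL
    recs$cheater <- NULL
    if (method == "ml") {
      f <- do.call(fit_ml, c(list(model = model, data = recs,
                                  seed = seed + r), fit_args))
      est[r, ] <- tf(f$theta)
    } else {
      f <- do.call(fit_bayes, c(list(model = model, data = recs,
                                     seed = seed + r), fit_args))
      q_draws <- t(apply(f$draws, 1, tf))
      est[r, ] <- colMeans(q_draws)
      qs <- apply(q_draws, 2, stats::quantile, probs = c(0.025, 0.975))
      cover[r, ] <- true_q >= qs[1, ] & true_q <= qs[2, ]
    }
  }
  data.frame(
    parameter = names(true_q),
    truth = unname(true_q),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(true_q),
    rmse = sqrt(colMeans(sweep(est, 2, true_q)^2)),
    mc_se = apply(est, 2, stats::sd) / sqrt(n_replicates),
    coverage = if (method == "mcmc") colMeans(cover) else NA_real_,
    row.names = NULL)
}
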