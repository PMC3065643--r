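#' Posterior predictive goodness-of-fit check
#'
#' Frequency-level check for covariate-free fits. For each retained
#' posterior draw theta, the expected counts over the 2K cells (both
#' samples pooled into one statistic) are mu_s(theta) = n_s pi*_s(theta);
#' the realized discrepancy is the Pearson chi-square
#' T_obs(theta) = sum (n - mu)^2 / mu, and a replicate table is drawn
#' multinomially per sample from pi*_s(theta) and scored the same way.
#' The posterior predictive p-value is the fraction of draws with
#' T_rep >= T_obs; values near 0 or 1 indicate misfit.
#'
#' @param fit a `dual_mcmc_fit` from a covariate-free model.
#' @param data the observed data (defaults to the data stored in the
#'   fit); frequency tables or records.
#' @param n_draws number of posterior draws to use (evenly spaced through
#'   the retained chain; default 4000, minimum 1000).
#' @param seed integer seed for the replicate tables.
#' @return an object of class `ppc_result` with the p-value and
#'   discrepancy summaries.
#' @export
posterior_predictive_check <- function(fit, data = fit$data,
                                       n_draws = 4000, seed = 1) {
  m <- fit$model
  if (m$n_beta1 > 1 || m$n_beta2 > 1) {
    stop("the posterior predictive check is frequency-level and requires a ",
         "covariate-free model; refit without cheating covariates")
  }
  if (n_draws < 1000) stop("use at least 1000 posterior draws")
  if (is.data.frame(data)) data <- tabulate_records(data, m$K)
  K <- m$K
  obs <- c(data[["1"]]$counts, data[["2"]]$counts)
  ns <- c(data[["1"]]$n, data[["2"]]$n)
  T_total <- nrow(fit$draws)
  idx <- unique(round(seq(1, T_total, length.out = min(n_draws, T_total))))
  pis <- pi_draws(fit)
  P1 <- unclass(m$P1); P2 <- unclass(m$P2)
  i_b1 <- m$n_lambda + 1
  i_b2 <- m$n_lambda + 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  guarded <- FALSE
  T_obs <- T_rep <- numeric(length(idx))
  for (d in seq_along(idx)) {
    i <- idx[d]
    pi <- pis[i, ]
    t1 <- stats::plogis(fit$draws[i, i_b1])
    t2 <- stats::plogis(fit$draws[i, i_b2])
    p1 <- (1 - t1) * drop(P1 %*% pi); p1[K] <- p1[K] + t1
    p2 <- (1 - t2) * drop(P2 %*% pi); p2[K] <- p2[K] + t2
    mu <- c(ns[1] * p1, ns[2] * p2)
    if (any(mu < 1e-8)) { guarded <- TRUE; mu <- pmax(mu, 1e-8) }
    T_obs[d] <- sum((obs - mu)^2 / mu)
    rep_counts <- c(drop(stats::rmultinom(1, ns[1], p1)),
                    drop(stats::rmultinom(1, ns[2], p2)))
    T_rep[d] <- sum((rep_counts - mu)^2 / mu)
  }
  if (guarded) {
    warning("expected cell counts below 1e-8 were guarded in the Pearson ",
            "denominator")
  }
  structure(list(p_value = mean(T_rep >= T_obs),
                 T_obs = summary(T_obs), T_rep = summary(T_rep),
                 n_draws = length(idx), seed = seed),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Posterior predictive check (Pearson chi-square, %d draws)\n",
    "  p-value = %.3f\n"), x$n_draws, x$p_value))
  cat("  realized discrepancy:  "); print(round(x$T_obs, 1))
  cat("  replicated discrepancy:"); print(round(x$T_rep, 1))
  invisible(x)
}

#' Marginalize a profile frequency table onto a subset of questions
#'
#' Sums the K = 2^J profile counts over the dropped questions, yielding
#' the 2^|keep| profile counts of the retained questions (profile order
#' preserved).
#'
#' @param ft a [freq_table()] over 2^J profiles.
#' @param J number of questions in `ft`.
#' @param keep integer vector of question indices to retain.
#' @return a [freq_table()] over the retained profiles.
#' @export
marginalize_freq <- function(ft, J, keep) {
  keep <- sort(unique(as.integer(keep)))
  if (any(keep < 1 | keep > J)) stop("keep must index questions 1..J")
  ans <- profile_answers(seq_len(2^J), J)
  newk <- profile_index(ans[, keep, drop = FALSE])
  freq_table(drop(rowsum(ft$counts, newk)), sample = ft$sample)
}

#' Pairwise-question sensitivity analysis
#'
#' For J >= 3 questions, refits the covariate-free dual mixture model on
#' every two-question marginal of the data (frequency tables summed over
#' the dropped question, designs rebuilt as the Kronecker product of the
#' two retained per-question matrices) and reports the cheating summaries
#' next to the full-model fit. Stability of the cheating estimates across
#' the marginal models indicates robustness of the cheating inference.
#'
#' @param question_designs list of J per-question 2 x 2 [rr_matrix()]
#'   objects for the randomized-response sample.
#' @param data named list of [freq_table()]s (or records, which are
#'   tabulated).
#' @param method `"ml"` or `"mcmc"`.
#' @param ... further arguments to [fit_ml()] or [fit_bayes()].
#' @return data.frame with one row per model (full first): tau_1, tau_2
#'   and, for MCMC, their 95% interval bounds and a `ci_disjoint` flag
#'   (TRUE when the RR and DQ cheating intervals do not overlap).
#' @export
pairwise_sensitivity <- function(question_designs, data,
                                 method = c("ml", "mcmc"), ...) {
  method <- match.arg(method)
  J <- length(question_designs)
  if (J < 3) {
    stop("pairwise sensitivity needs at least three questions; with J = 2 ",
         "there is no question to drop")
  }
  if (is.data.frame(data)) data <- tabulate_records(data, 2^J)
  fit_one <- function(keep) {
    P1 <- profile_design(question_designs[keep])
    m <- dual_model(P1)
    d <- list(`1` = marginalize_freq(data[["1"]], J, keep),
              `2` = marginalize_freq(data[["2"]], J, keep))
    if (identical(keep, seq_len(J))) d <- data
    if (method == "ml") {
      f <- fit_ml(m, d, ...)
      c(tau_1 = unname(f$tau_bar[1]), tau_2 = unname(f$tau_bar[2]),
        tau_1_lo = NA, tau_1_hi = NA, tau_2_lo = NA, tau_2_hi = NA)
    } else {
      f <- fit_bayes(m, d, ...)
      s <- posterior_summary(f)
      r1 <- s[s$parameter == "tau_1", ]
      r2 <- s[s$parameter == "tau_2", ]
      c(tau_1 = r1$mean, tau_2 = r2$mean,
        tau_1_lo = r1$lower, tau_1_hi = r1$upper,
        tau_2_lo = r2$lower, tau_2_hi = r2$upper)
    }
  }
  keeps <- c(list(seq_len(J)), utils::combn(J, 2, simplify = FALSE))
  rows <- lapply(keeps, fit_one)
  tab <- as.data.frame(do.call(rbind, rows))
  tab$model <- vapply(keeps, function(k) {
    if (length(k) == J) "full" else paste0("q", paste(k, collapse = "q"))
  }, character(1))
  tab$ci_disjoint <- with(tab, ifelse(is.na(tau_1_hi), NA,
                                      tau_1_hi < tau_2_lo | tau_2_hi < tau_1_lo))
  tab[, c("model", "tau_1", "tau_1_lo", "tau_1_hi",
          "tau_2", "tau_2_lo", "tau_2_hi", "ci_disjoint")]
}
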