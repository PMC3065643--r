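# naive latent-prevalence starting value: smoothed direct-questioning
# proportions when available, otherwise the moment estimate P1^{-1} p-hat,
# clipped to the interior of the simplex.
naive_pi_start <- function(model, data) {
  K <- model$K
  counts2 <- counts1 <- NULL
  if (is.data.frame(data)) {
    tabs <- tabulate_records(data, K)
    counts1 <- tabs[["1"]]$counts
    counts2 <- tabs[["2"]]$counts
  } else {
    counts1 <- data[["1"]]$counts
    counts2 <- data[["2"]]$counts
  }
  pi0 <- if (!is.null(counts2) && sum(counts2) > 0) {
    counts2 / sum(counts2)
  } else if (!is.null(counts1) && sum(counts1) > 0) {
    drop(solve(unclass(model$P1), counts1 / sum(counts1)))
  } else {
    rep(1 / K, K)
  }
  pi0 <- pmax(pi0, 0)
  pi0 <- (pi0 + 0.01) / sum(pi0 + 0.01)
  pi0
}

n_total_of <- function(data) {
  if (is.data.frame(data)) nrow(data)
  else sum(vapply(data, function(f) f$n, numeric(1)))
}

# coarse fingerprint so fits being compared can be checked to share data
data_fingerprint <- function(data) {
  if (is.data.frame(data)) {
    paste0("records:", nrow(data), ":",
           paste(colSums(data[vapply(data, is.numeric, TRUE)]), collapse = ","))
  } else {
    paste0("freq:", paste(unlist(lapply(data, function(f)
      c(f$sample, f$counts))), collapse = ","))
  }
}

#' Maximum-likelihood fit of the dual mixture model
#'
#' Maximizes the log-likelihood over the unconstrained parameter vector
#' (lambda, beta1, beta2) by multi-start quasi-Newton (BFGS) optimization
#' with the analytic score. Starting values take lambda from
#' [lambda_from_pi()] of an epsilon-smoothed naive prevalence estimate and
#' the cheating intercepts from logits of coarse cheating guesses;
#' additional starts are jittered. Deterministic given `seed`.
#'
#' @param model a [dual_model()].
#' @param data records data.frame or named list of [freq_table()]s.
#' @param n_starts number of optimizer starts (default 10).
#' @param seed integer seed for start jittering.
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @return an object of class `dual_ml_fit` with the estimates, maximized
#'   log-likelihood, BIC (using the total respondent count across both
#'   samples), observed-information standard errors and convergence
#'   diagnostics.
#' @examples
#' fit <- fit_ml(model_preset("model-I"), benefit_survey(), n_starts = 3)
#' fit$minus2LL
#' @export
fit_ml <- function(model, data, n_starts = 10, seed = 1, reltol = 1e-12) {
  if (is.data.frame(data)) data <- validate_records(data, model$K)
  idc <- identifiability_count(model$J,
                               cheat_params = c(model$n_beta1, model$n_beta2))
  if (!idc$identified) {
    warning("model has more parameters (", idc$parameters,
            ") than independent frequencies (", idc$frequencies,
            "); proceeding, but estimates may not be identified")
  }
  pi0 <- naive_pi_start(model, data)
  lam0 <- lambda_from_pi(pi0, model$Z)
  base <- c(lam0,
            stats::qlogis(0.1), rep(0, model$n_beta1 - 1),
            stats::qlogis(0.3), rep(0, model$n_beta2 - 1))
  nll <- function(th) {
    v <- dual_loglik_core(model, th, data, gradient = FALSE)$loglik
    if (!is.finite(v)) 1e10 else -v
  }
  ngr <- function(th) {
    r <- dual_loglik_core(model, th, data, gradient = TRUE)
    if (!is.finite(r$loglik)) rep(0, length(th)) else -r$grad
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  n_failed <- 0
  for (r in seq_len(n_starts)) {
    st <- if (r == 1) base else base + stats::rnorm(length(base), 0, 0.5)
    o <- tryCatch(
      suppressWarnings(stats::optim(st, nll, ngr, method = "BFGS",
                  control = list(maxit = 2000, reltol = reltol))),
      error = function(e) NULL)
    if (is.null(o)) { n_failed <- n_failed + 1; next }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop("all ", n_starts, " optimizer starts failed to converge")
  }
  theta <- stats::setNames(best$par, model$par_names)
  ll <- -best$value
  gnorm <- sqrt(sum(ngr(theta)^2))
  n_total <- n_total_of(data)
  pars <- split_theta(model, theta)
  pi_hat <- pi_from_lambda(pars$lambda, model$Z)
  names(pi_hat) <- paste0("pi_", rownames(model$Z))
  H <- tryCatch(stats::optimHess(theta, nll, ngr), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(vc) && any(!is.finite(diag(vc)))) vc <- NULL
  # mean fitted cheating probability per sample (equals tau_s when
  # intercept-only); boundary-flag intercepts escaping to +/- infinity
  taubar <- c(NA_real_, NA_real_)
  for (s in 1:2) {
    beta <- if (s == 1) pars$beta1 else pars$beta2
    X <- if (is.data.frame(data)) {
      rec <- data[data$sample == s, , drop = FALSE]
      if (nrow(rec)) cheat_design(model, rec, s) else matrix(1, 1, length(beta))
    } else matrix(1, 1, length(beta))
    taubar[s] <- mean(cheating_prob(beta, X))
  }
  boundary <- abs(c(pars$beta1[1], pars$beta2[1])) > 15
  structure(list(
    model = model, theta = theta, loglik = ll, minus2LL = -2 * ll,
    n_par = model$n_par, n_total = n_total,
    bic = -2 * ll + model$n_par * log(n_total),
    pi = pi_hat, tau_bar = stats::setNames(taubar, c("tau_1", "tau_2")),
    boundary = boundary, vcov = vc, gradient_norm = gnorm,
    n_starts = n_starts, n_failed_starts = n_failed, seed = seed,
    data = data,
    fingerprint = data_fingerprint(data)), class = "dual_ml_fit")
}

# save/restore the global RNG state so fitters do not disturb user RNG flow
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.dual_ml_fit <- function(x, ...) {
  cat("Dual-sample SP-no mixture model, maximum likelihood\n")
  cat(sprintf("  n = %d (%d parameters), -2LL = %.1f, BIC = %.1f\n",
              x$n_total, x$n_par, x$minus2LL, x$bic))
  cat(sprintf("  mean cheating: tau_1 = %.3f, tau_2 = %.3f%s\n",
              x$tau_bar[1], x$tau_bar[2],
              if (any(x$boundary)) "  [boundary solution]" else ""))
  cat("  latent prevalence:\n")
  print(round(x$pi, 4))
  invisible(x)
}

#' @export
logLik.dual_ml_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_total,
            class = "logLik")
}

#' Fitted expected cell counts of an ML fit
#'
#' @param fit a `dual_ml_fit` from a covariate-free model.
#' @return K x 2 matrix of expected counts (columns = samples).
#' @export
expected_counts <- function(fit) {
  m <- fit$model
  if (m$n_beta1 > 1 || m$n_beta2 > 1) {
    stop("expected counts on the frequency scale require a covariate-free model")
  }
  data <- fit$data
  if (is.data.frame(data)) data <- tabulate_records(data, m$K)
  out <- matrix(NA_real_, m$K, 2)
  for (s in 1:2) {
    p <- cell_probabilities(m, fit$theta, sample = s)
    n_s <- if (is.null(data[[as.character(s)]])) 0
           else data[[as.character(s)]]$n
    out[, s] <- n_s * p
  }
  rownames(out) <- rownames(m$Z)
  colnames(out) <- c("sample1", "sample2")
  out
}

#' Compare fitted models by BIC
#'
#' @param fits named list of `dual_ml_fit` objects fitted to the same
#'   data.
#' @param nested if `TRUE`, the fits are declared nested in the given
#'   order (smallest first) and -2LL is checked to be non-increasing.
#' @return data.frame with columns model, n_params, minus2LL, BIC, in
#'   ascending BIC order (stable for ties).
#' @export
compare_bic <- function(fits, nested = FALSE) {
  fps <- vapply(fits, function(f) f$fingerprint, character(1))
  if (length(unique(fps)) > 1) {
    stop("fits were not computed on identical data (fingerprints differ)")
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("fit", seq_along(fits))
  tab <- data.frame(
    model = nm,
    n_params = vapply(fits, function(f) f$n_par, numeric(1)),
    minus2LL = vapply(fits, function(f) f$minus2LL, numeric(1)),
    BIC = vapply(fits, function(f) f$bic, numeric(1)),
    row.names = NULL)
  if (nested && any(diff(tab$minus2LL) > 1e-6)) {
    warning("-2LL increases along the declared nesting; a larger model ",
            "fits worse -- check optimizer convergence")
  }
  tab[order(tab$BIC), , drop = FALSE]
}

#' Univariate Wald screening of coefficients
#'
#' Reports z = estimate / standard error and two-sided p-values from the
#' observed information at the optimum, flagging coefficients significant
#' at `level` (default 10%, supporting covariate selection of the
#' model-II kind). Advisory output only; no automatic selection is done.
#'
#' @param fit a `dual_ml_fit`.
#' @param level significance level for flagging.
#' @return data.frame with columns parameter, estimate, se, z, p, flagged.
#' @export
wald_screen <- function(fit, level = 0.1) {
  est <- fit$theta
  se <- if (is.null(fit$vcov)) rep(NA_real_, length(est))
        else sqrt(pmax(diag(fit$vcov), 0))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(parameter = names(est), estimate = unname(est), se = se,
             z = unname(z), p = unname(p),
             flagged = !is.na(p) & p < level, row.names = NULL)
}
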