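#' Dual-sample self-protective-no mixture model specification
#'
#' Specifies the mixture model for a dual sampling scheme in which the same
#' J binary sensitive questions are asked under a randomized-response
#' design (sample 1, misclassification matrix `P1`) and under direct
#' questioning (sample 2, `P2`, identity by default). For respondent i in
#' sample s the observed profile distribution is
#' \deqn{\pi^*_{is} = (1 - \tau_{is}) P_s \pi + \tau_{is} v,}
#' where pi is the latent profile prevalence, v is the K-th unit vector
#' (the degenerate all-no cheating component) and the cheating probability
#' follows a logistic regression
#' \eqn{\tau_{is} = \mathrm{logit}^{-1}(x_{is}^T \beta_s)}.
#' The latent prevalence is parameterized by a log-linear model
#' pi = g(Z lambda) (see [pi_from_lambda()]), so maximization is over an
#' unconstrained parameter vector theta = (lambda, beta1, beta2).
#'
#' @param P1 [rr_matrix()] for the randomized-response sample.
#' @param P2 [rr_matrix()] for the second sample; identity (direct
#'   questioning) by default.
#' @param latent_terms log-linear terms for the latent distribution, passed
#'   to [loglinear_matrix()]; saturated by default.
#' @param covariates1,covariates2 character vectors naming the cheating
#'   covariates per sample (an intercept is always included first).
#' @return an object of class `dual_model`.
#' @examples
#' P1 <- profile_design(rep(list(forced_response_matrix(two_dice_device())), 3))
#' dual_model(P1)
#' @export
dual_model <- function(P1, P2 = NULL, latent_terms = "saturated",
                       covariates1 = character(), covariates2 = character()) {
  P1 <- rr_matrix(P1)
  K <- nrow(P1)
  J <- as.integer(round(log2(K)))
  if (2^J != K) stop("K must be a power of two (binary question profiles)")
  if (is.null(P2)) P2 <- rr_matrix(diag(K))
  P2 <- rr_matrix(P2)
  if (nrow(P2) != K) stop("P1 and P2 must have the same dimension")
  Z <- loglinear_matrix(J, latent_terms)
  m <- structure(list(
    P1 = P1, P2 = P2, Z = Z, K = K, J = J,
    covariates1 = as.character(covariates1),
    covariates2 = as.character(covariates2)), class = "dual_model")
  m$n_lambda <- ncol(Z)
  m$n_beta1 <- 1L + length(m$covariates1)
  m$n_beta2 <- 1L + length(m$covariates2)
  m$n_par <- m$n_lambda + m$n_beta1 + m$n_beta2
  m$par_names <- c(paste0("lambda_", colnames(Z)),
                   paste0("beta1_", c("0", m$covariates1)),
                   paste0("beta2_", c("0", m$covariates2)))
  m
}

#' @export
print.dual_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Dual-sample SP-no mixture model: %d questions (K = %d profiles)\n",
    "  latent log-linear terms: %d; cheating covariates: sample 1 [%s], ",
    "sample 2 [%s]\n  free parameters: %d\n"),
    x$J, x$K, x$n_lambda,
    paste(x$covariates1, collapse = ", "),
    paste(x$covariates2, collapse = ", "), x$n_par))
  invisible(x)
}

#' Named model presets for the benefit-survey analysis
#'
#' `"model-I"` has no cheating covariates (9 parameters for J = 3),
#' `"model-II"` uses Sex and Advantage in the randomized-response sample
#' and Advantage in the direct-questioning sample (12 parameters), and
#' `"model-III"` uses Age, Sex, Reason and Advantage in both samples
#' (17 parameters). All three use the saturated latent log-linear model.
#'
#' @param name `"model-I"`, `"model-II"` or `"model-III"`.
#' @param device per-question [rr_device()] for the randomized-response
#'   sample; two-dice by default.
#' @param J number of questions.
#' @return a [dual_model()].
#' @export
model_preset <- function(name = c("model-I", "model-II", "model-III"),
                         device = two_dice_device(), J = 3) {
  name <- match.arg(name)
  P1 <- profile_design(rep(list(forced_response_matrix(device)), J))
  cov1 <- switch(name, "model-I" = character(),
                 "model-II" = c("Sex", "Advantage"),
                 "model-III" = c("Age", "Sex", "Reason", "Advantage"))
  cov2 <- switch(name, "model-I" = character(),
                 "model-II" = "Advantage",
                 "model-III" = c("Age", "Sex", "Reason", "Advantage"))
  dual_model(P1, covariates1 = cov1, covariates2 = cov2)
}

#' Split a packed parameter vector into its components
#'
#' @param model a [dual_model()].
#' @param theta numeric vector c(lambda, beta1, beta2).
#' @return list with elements `lambda`, `beta1`, `beta2`.
#' @export
split_theta <- function(model, theta) {
  if (length(theta) != model$n_par) {
    stop("theta must have length ", model$n_par)
  }
  i1 <- model$n_lambda
  i2 <- i1 + model$n_beta1
  list(lambda = theta[seq_len(i1)],
       beta1 = theta[(i1 + 1):i2],
       beta2 = theta[(i2 + 1):model$n_par])
}

#' Cheating probability from a logistic regression
#'
#' \eqn{\tau = \mathrm{logit}^{-1}(x^T \beta)} with x leading with the
#' constant 1.
#'
#' @param beta coefficient vector, intercept first.
#' @param x covariate vector (leading 1) or matrix with one row per
#'   respondent.
#' @return probability (vector) in (0, 1).
#' @examples
#' cheating_prob(stats::qlogis(0.157), 1)
#' @export
cheating_prob <- function(beta, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(beta)) stop("x and beta are not conformable")
  if (any(!is.finite(x))) stop("covariates must be finite")
  stats::plogis(drop(x %*% beta))
}

# design matrix (leading 1) for the cheating regression of sample s
cheat_design <- function(model, records_s, sample) {
  covs <- if (sample == 1) model$covariates1 else model$covariates2
  n <- nrow(records_s)
  if (!length(covs)) return(matrix(1, n, 1))
  miss <- setdiff(covs, names(records_s))
  if (length(miss)) {
    stop("records lack covariate(s): ", paste(miss, collapse = ", "))
  }
  X <- cbind(1, as.matrix(records_s[covs]))
  if (any(!is.finite(X))) {
    stop("missing or non-finite covariate values; covariate models require ",
         "complete records")
  }
  X
}

#' Observed-profile cell probabilities under the mixture model
#'
#' Computes \eqn{\pi^* = (1 - \tau) P_s \pi + \tau v} for one respondent.
#'
#' @param model a [dual_model()].
#' @param theta packed parameter vector.
#' @param sample 1 or 2.
#' @param x covariate vector for the respondent's cheating regression
#'   (leading 1); defaults to intercept only.
#' @return probability vector of length K.
#' @export
cell_probabilities <- function(model, theta, sample = 1, x = NULL) {
  pars <- split_theta(model, theta)
  pi <- pi_from_lambda(pars$lambda, model$Z)
  beta <- if (sample == 1) pars$beta1 else pars$beta2
  if (is.null(x)) x <- c(1, rep(0, length(beta) - 1))
  tau <- cheating_prob(beta, x)
  P <- if (sample == 1) model$P1 else model$P2
  p <- (1 - tau) * drop(unclass(P) %*% pi)
  p[model$K] <- p[model$K] + tau
  p
}

# internal: log-likelihood and score for records or frequency tables.
# data: either a data.frame of records or a named list of freq_table.
# Returns list(loglik, grad) (grad NULL unless gradient = TRUE).
dual_loglik_core <- function(model, theta, data, gradient = FALSE) {
  pars <- split_theta(model, theta)
  pi <- pi_from_lambda(pars$lambda, model$Z)
  dlog <- if (gradient) dlogpi_dlambda(pars$lambda, model$Z) # K x q
  K <- model$K
  ll <- 0
  gr <- if (gradient) numeric(model$n_par)
  i1 <- model$n_lambda
  off <- list(`1` = i1, `2` = i1 + model$n_beta1)
  zero_warned <- FALSE
  for (s in c(1L, 2L)) {
    P <- unclass(if (s == 1) model$P1 else model$P2)
    q <- drop(P %*% pi)
    beta <- if (s == 1) pars$beta1 else pars$beta2
    if (is.data.frame(data)) {
      rec <- data[data$sample == s, , drop = FALSE]
      if (!nrow(rec)) next
      X <- cheat_design(model, rec, s)
      k <- rec$category
      w <- rep(1, nrow(rec))
    } else {
      ft <- data[[as.character(s)]]
      if (is.null(ft)) next
      X <- matrix(1, K, length(beta))
      if (ncol(X) > 1) {
        stop("covariate models require individual records, not frequency tables")
      }
      k <- seq_len(K)
      w <- ft$counts
    }
    tau <- cheating_prob(beta, X)
    delta <- as.numeric(k == K)
    p <- (1 - tau) * q[k] + tau * delta
    if (any(p[w > 0] <= 0)) {
      if (!zero_warned) {
        warning("zero predicted probability for an observed cell; ",
                "log-likelihood is -Inf")
        zero_warned <- TRUE
      }
      return(list(loglik = -Inf, grad = NULL))
    }
    ll <- ll + sum(w * log(pmax(p, .Machine$double.xmin)))
    if (gradient) {
      # lambda part: d p / d lambda_j = (1-tau) * (P %*% (pi * dlog[,j]))[k]
      A <- P %*% (pi * dlog)                      # K x q
      gl <- colSums((w * (1 - tau) / p) * A[k, , drop = FALSE])
      # beta part: d p / d beta = (delta - q[k]) tau (1-tau) x
      gb <- colSums((w * (delta - q[k]) * tau * (1 - tau) / p) *
                      X, na.rm = FALSE)
      gr[seq_len(i1)] <- gr[seq_len(i1)] + gl
      gr[off[[as.character(s)]] + seq_along(beta)] <-
        gr[off[[as.character(s)]] + seq_along(beta)] + gb
    }
  }
  list(loglik = ll, grad = gr)
}

#' Log-likelihood of the dual mixture model
#'
#' Sum over samples and respondents of the log observed-cell probability.
#' For covariate-free specifications the computation from per-sample
#' frequency tables is equivalent to the record-level sum.
#'
#' @param model a [dual_model()].
#' @param theta packed parameter vector.
#' @param data a data.frame of records ([load_records()]) or a named list
#'   of [freq_table()] objects (names "1", "2").
#' @return the log-likelihood (`-Inf`, with a warning, if any observed
#'   cell has zero predicted probability).
#' @export
dual_loglik <- function(model, theta, data) {
  dual_loglik_core(model, theta, data, gradient = FALSE)$loglik
}

#' Counting identifiability of the SP-no models
#'
#' Compares the number of independently observed frequencies with the
#' number of free parameters. In the dual scheme with J questions there
#' are 2(2^J - 1) independent frequencies; the covariate-free model has
#' (2^J - 1) latent parameters plus one cheating intercept per sample.
#' An intrinsic identifiability problem is flagged when parameters exceed
#' frequencies (more parameters than independent observations).
#'
#' @param J number of binary questions.
#' @param dual `TRUE` for the two-sample scheme, `FALSE` for a single
#'   SP-no sample.
#' @param cheat_params number of cheating-regression parameters per sample
#'   (length 2 when `dual`, else length 1); default intercept-only.
#' @return list with `frequencies`, `parameters` and `identified`.
#' @examples
#' identifiability_count(3)   # 14 frequencies, 9 parameters
#' identifiability_count(2)   # 6 frequencies, 5 parameters
#' @export
identifiability_count <- function(J, dual = TRUE,
                                  cheat_params = if (dual) c(1, 1) else 1) {
  if (J < 1) stop("J must be at least 1")
  K <- 2^J
  nfreq <- if (dual) 2 * (K - 1) else K - 1
  npar <- (K - 1) + sum(cheat_params)
  list(frequencies = nfreq, parameters = npar,
       identified = npar <= nfreq)
}

#' Clark-Desharnais model parameters
#'
#' The CD model describes two samples under forced-yes designs with a
#' shared cheating proportion: `alpha` honest-yes respondents, `beta_cd`
#' honest-no respondents and `gamma` cheaters, with
#' alpha + beta_cd + gamma = 1. `theta1`, `theta2` are the forced-yes
#' probabilities of the two designs.
#'
#' @param alpha,beta_cd,gamma population proportions summing to 1.
#' @param theta1,theta2 forced-yes probabilities in \[0, 1).
#' @return an object of class `cd_parameters`.
#' @export
cd_parameters <- function(alpha, beta_cd, gamma, theta1 = 0.5, theta2 = 0.25) {
  p <- c(alpha, beta_cd, gamma)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1) ||
      abs(sum(p) - 1) > 1e-12) {
    stop("alpha, beta_cd, gamma must lie in [0,1] and sum to 1")
  }
  for (th in c(theta1, theta2)) {
    if (!is.finite(th) || th < 0 || th >= 1) stop("theta must lie in [0, 1)")
  }
  structure(list(alpha = alpha, beta_cd = beta_cd, gamma = gamma,
                 theta1 = theta1, theta2 = theta2),
            class = "cd_parameters")
}

#' Map between Clark-Desharnais and SP-no parameterizations
#'
#' The CD model is the dual SP-no model with a single binary question,
#' forced-yes designs and equal cheating in both samples: tau = gamma and
#' pi_yes = alpha / (alpha + beta_cd). The inverse map is
#' alpha = (1 - tau) pi, beta_cd = (1 - tau)(1 - pi), gamma = tau.
#' Reporting pi as the prevalence assumes the cheaters are a random sample
#' from the population.
#'
#' @param cd a [cd_parameters()] object.
#' @return `cd_to_spno()`: list with `pi_yes` and `tau`;
#'   `spno_to_cd()`: a [cd_parameters()].
#' @examples
#' cd_to_spno(cd_parameters(0.3, 0.5, 0.2))
#' @export
cd_to_spno <- function(cd) {
  if (cd$alpha + cd$beta_cd <= 0) {
    stop("alpha + beta_cd = 0: prevalence pi is undefined (everyone cheats)")
  }
  list(pi_yes = cd$alpha / (cd$alpha + cd$beta_cd), tau = cd$gamma)
}

#' @rdname cd_to_spno
#' @param pi_yes latent prevalence of the sensitive (yes) category.
#' @param tau shared cheating probability.
#' @inheritParams cd_parameters
#' @export
spno_to_cd <- function(pi_yes, tau, theta1 = 0.5, theta2 = 0.25) {
  cd_parameters((1 - tau) * pi_yes, (1 - tau) * (1 - pi_yes), tau,
                theta1, theta2)
}

#' Observed yes/no probabilities under the Clark-Desharnais model
#'
#' In sample s the observed yes probability is alpha + theta_s beta_cd and
#' the observed no probability is (1 - theta_s) beta_cd + gamma.
#'
#' @param cd a [cd_parameters()] object.
#' @param sample 1 or 2.
#' @return length-2 probability vector (yes, no).
#' @export
cd_cell_probabilities <- function(cd, sample = 1) {
  th <- if (sample == 1) cd$theta1 else cd$theta2
  c(cd$alpha + th * cd$beta_cd, (1 - th) * cd$beta_cd + cd$gamma)
}

#' Log-likelihood of the Clark-Desharnais model
#'
#' @param cd a [cd_parameters()] object.
#' @param counts list of two length-2 count vectors (yes, no), one per
#'   sample.
#' @return log-likelihood.
#' @export
cd_loglik <- function(cd, counts) {
  ll <- 0
  for (s in 1:2) {
    p <- cd_cell_probabilities(cd, s)
    if (any(p[counts[[s]] > 0] <= 0)) return(-Inf)
    ll <- ll + sum(counts[[s]] * log(pmax(p, .Machine$double.xmin)))
  }
  ll
}
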