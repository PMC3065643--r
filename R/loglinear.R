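#' Effect-coded log-linear model matrix for binary question profiles
#'
#' Builds the K x q model matrix Z for the latent profile distribution of J
#' binary questions, with effect coding +1 for yes and -1 for no. Rows are
#' the K = 2^J profiles in lexicographic order (yes before no); columns are
#' the requested terms. The saturated matrix for three questions has the
#' seven columns q1, q2, q3, q1:q2, q1:q3, q2:q3, q1:q2:q3, matching the
#' conventional ordering lambda_1, ..., lambda_7.
#'
#' Effect coding is used (rather than dummy coding) because it gives the
#' three-factor parameter its clean odds-ratio-ratio interpretation: for
#' J = 3 the ratio of the conditional odds ratios of questions 1 and 2
#' across the levels of question 3 equals exp(8 * lambda_7).
#'
#' @param J number of binary questions.
#' @param terms `"saturated"` (default), `"main"` for main effects only, or
#'   an integer vector of interaction orders to retain (e.g. `1:2`).
#' @return a K x q numeric matrix with named columns.
#' @examples
#' loglinear_matrix(3)
#' @export
loglinear_matrix <- function(J, terms = "saturated") {
  J <- as.integer(J)
  if (J < 1) stop("J must be at least 1")
  orders <- if (identical(terms, "saturated")) seq_len(J)
            else if (identical(terms, "main")) 1L
            else as.integer(terms)
  if (any(orders < 1 | orders > J)) stop("term orders must lie in 1..J")
  # profile rows: lexicographic, question 1 varies slowest; yes=+1, no=-1
  ans <- as.matrix(expand.grid(rev(rep(list(c(1, -1)), J)))[, J:1, drop = FALSE])
  colnames(ans) <- paste0("q", seq_len(J))
  cols <- list()
  for (ord in sort(unique(orders))) {
    for (set in utils::combn(J, ord, simplify = FALSE)) {
      nm <- paste0("q", paste(set, collapse = ""))
      cols[[nm]] <- apply(ans[, set, drop = FALSE], 1, prod)
    }
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- apply(ifelse(ans == 1, "1", "2"), 1, paste, collapse = "")
  Z
}

#' Latent prevalence vector from log-linear parameters
#'
#' Computes \eqn{\pi_k = \exp(\lambda_0 + (Z\lambda)_k)} with the
#' normalizing constant \eqn{\lambda_0 = -\log \sum_m \exp((Z\lambda)_m)}
#' derived from Z and lambda, so that pi sums to one by construction. The
#' maximum of Z lambda is subtracted before exponentiation for overflow
#' safety.
#'
#' @param lambda numeric vector of q free log-linear parameters.
#' @param Z K x q model matrix (see [loglinear_matrix()]).
#' @return a length-K probability vector.
#' @export
pi_from_lambda <- function(lambda, Z) {
  if (length(lambda) != ncol(Z)) {
    stop("length(lambda) must equal ncol(Z)")
  }
  if (qr(Z)$rank < ncol(Z)) stop("model matrix Z is rank deficient")
  eta <- unname(drop(Z %*% lambda))
  eta <- eta - max(eta)
  p <- exp(eta)
  p / sum(p)
}

#' Log-linear parameters from a latent prevalence vector
#'
#' Inverse of [pi_from_lambda()]: least-squares solution of
#' \eqn{Z\lambda = \log\pi - \overline{\log\pi}}, exact when Z is
#' saturated or log pi lies in the column space of Z.
#'
#' @param pi strictly positive probability vector of length K.
#' @param Z K x q model matrix.
#' @return numeric vector lambda of length q.
#' @export
lambda_from_pi <- function(pi, Z) {
  if (length(pi) != nrow(Z)) stop("length(pi) must equal nrow(Z)")
  if (any(pi <= 0)) {
    stop("pi must be strictly positive; perturb zero cells by a small ",
         "epsilon before inverting")
  }
  lp <- log(pi)
  drop(qr.coef(qr(Z), lp - mean(lp)))
}

#' Gradient of log pi with respect to lambda
#'
#' Returns the K x q matrix with rows \eqn{Z_k - \sum_m \pi_m Z_m}, the
#' derivative of each log cell probability with respect to the free
#' parameters. Used by the maximum-likelihood fitter.
#'
#' @inheritParams pi_from_lambda
#' @return K x q numeric matrix.
#' @keywords internal
#' @export
dlogpi_dlambda <- function(lambda, Z) {
  pi <- pi_from_lambda(lambda, Z)
  sweep(Z, 2, colSums(pi * Z), "-")
}
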