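#' Randomized-response misclassification matrices
#'
#' An `rr_matrix` is a column-stochastic, non-singular K x K matrix of
#' conditional misclassification probabilities \eqn{p(X^* = k \mid X = l)},
#' where the row index is the observed category and the column index the
#' true (latent) category. Categories are ordered lexicographically with
#' yes (1) before no (2), so for question profiles the all-no profile -- the
#' least stigmatizing answer -- is always category K.
#'
#' @param x numeric K x K matrix of conditional probabilities, columns
#'   indexed by true category.
#' @param max_condition condition-number threshold beyond which the matrix
#'   is rejected as (numerically) singular. The matrix must be invertible
#'   for moment-type estimation of the latent prevalence.
#' @return an object of class `rr_matrix` (a validated numeric matrix).
#' @examples
#' rr_matrix(diag(2))
#' @export
rr_matrix <- function(x, max_condition = 1e12) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop("an rr_matrix must be square, got ", nrow(x), " x ", ncol(x))
  }
  if (any(!is.finite(x)) || any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("rr_matrix entries must be probabilities in [0, 1]")
  }
  cs <- colSums(x)
  if (any(abs(cs - 1) > 1e-12)) {
    stop("rr_matrix columns must each sum to 1 (true-category conditionals); ",
         "column sums: ", paste(format(cs), collapse = ", "))
  }
  d <- svd(x, nu = 0, nv = 0)$d
  cond <- if (min(d) <= 0) Inf else max(d) / min(d)
  if (cond > max_condition) {
    stop("rr_matrix is singular or ill-conditioned (condition number > ",
         format(max_condition), "); the design is not invertible")
  }
  structure(x, class = c("rr_matrix", class(x)))
}

#' @export
print.rr_matrix <- function(x, ...) {
  cat("Randomized-response design matrix (", nrow(x), " categories)\n",
      sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Forced-response randomizing device
#'
#' Describes a randomizing device for a binary question: with probability
#' `p_truth` the respondent answers truthfully, with probability
#' `p_forced_yes` the device forces a yes, and with probability
#' `p_forced_no` it forces a no. The classical two-dice device answers yes
#' for a sum of 2--4 (6/36), no for 11--12 (3/36), and truthfully otherwise
#' (27/36).
#'
#' @param p_truth probability of a truthful answer.
#' @param p_forced_yes probability of a forced yes.
#' @param p_forced_no probability of a forced no.
#' @return an object of class `rr_device`.
#' @examples
#' two_dice_device()
#' @export
rr_device <- function(p_truth, p_forced_yes, p_forced_no) {
  p <- c(p_truth = p_truth, p_forced_yes = p_forced_yes,
         p_forced_no = p_forced_no)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("device probabilities must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("device probabilities must sum to 1, got ", format(sum(p)))
  }
  structure(as.list(p), class = "rr_device")
}

#' @rdname rr_device
#' @export
two_dice_device <- function() rr_device(27 / 36, 6 / 36, 3 / 36)

#' @export
print.rr_device <- function(x, ...) {
  cat(sprintf(
    "Forced-response device: truthful %.4f, forced yes %.4f, forced no %.4f\n",
    x$p_truth, x$p_forced_yes, x$p_forced_no))
  invisible(x)
}

#' Misclassification matrix of a forced-response design
#'
#' For a binary question under a forced-response device, the observed
#' answer is yes with probability `p_forced_yes + p_truth` given a true
#' yes, and with probability `p_forced_yes` given a true no.
#'
#' @param device an [rr_device()].
#' @return a 2 x 2 [rr_matrix()], category 1 = yes, category 2 = no.
#' @examples
#' forced_response_matrix(two_dice_device())
#' @export
forced_response_matrix <- function(device) {
  if (!inherits(device, "rr_device")) device <- do.call(rr_device, as.list(device))
  rr_matrix(matrix(
    c(device$p_forced_yes + device$p_truth, device$p_forced_no,
      device$p_forced_yes, device$p_forced_no + device$p_truth),
    nrow = 2, ncol = 2))
}

#' Misclassification matrix of a forced-yes (Clark-Desharnais) design
#'
#' In this design a latent yes always yields an observed yes; privacy is
#' protected by forcing yes answers from true-no respondents with
#' probability `theta`. There are no forced no answers.
#'
#' @param theta probability of a forced yes given a true no; must satisfy
#'   `0 <= theta < 1` (at `theta = 1` the design is singular).
#' @return a 2 x 2 [rr_matrix()].
#' @export
cd_design_matrix <- function(theta) {
  if (!is.finite(theta) || theta < 0 || theta >= 1) {
    stop("theta must lie in [0, 1); theta = 1 gives a singular design")
  }
  rr_matrix(matrix(c(1, 0, theta, 1 - theta), nrow = 2, ncol = 2))
}

#' Kronecker profile design for a series of questions
#'
#' Combining J binary questions yields K = 2^J answer profiles. Under the
#' assumption that the randomizing devices act independently across
#' questions, the profile design is the Kronecker product of the
#' per-question matrices. Profiles are ordered lexicographically in
#' (answer 1, ..., answer J) with yes = 1 before no = 2, so profile K is
#' all-no.
#'
#' @param matrices a list of 2 x 2 [rr_matrix()] objects (or a single
#'   matrix), first question first.
#' @return a 2^J x 2^J [rr_matrix()].
#' @examples
#' P <- profile_design(rep(list(forced_response_matrix(two_dice_device())), 3))
#' dim(P)
#' @export
profile_design <- function(matrices) {
  if (inherits(matrices, "rr_matrix")) matrices <- list(matrices)
  if (length(matrices) < 1) stop("need at least one design matrix")
  matrices <- lapply(matrices, rr_matrix)
  out <- matrices[[1]]
  for (m in matrices[-1]) out <- out %x% m
  rr_matrix(out)
}

#' Self-protective-no misclassification matrix
#'
#' With cheating probability `tau`, a fraction tau of respondents answer
#' category K (all-no) irrespective of the device. As a misclassification
#' model this is \eqn{P_\tau = (1 - \tau) P + \tau E} where E has its K-th
#' row equal to one and zeros elsewhere. Note `P_tau` is singular at
#' `tau = 1`, so the result is validated for column stochasticity only.
#'
#' @param P a [rr_matrix()].
#' @param tau cheating probability in \[0, 1\].
#' @return a column-stochastic K x K matrix (not necessarily invertible).
#' @export
sp_no_matrix <- function(P, tau) {
  P <- rr_matrix(P)
  if (!is.finite(tau) || tau < 0 || tau > 1) {
    stop("tau must lie in [0, 1]")
  }
  K <- nrow(P)
  E <- matrix(0, K, K)
  E[K, ] <- 1
  out <- (1 - tau) * unclass(P) + tau * E
  structure(out, class = c("rr_matrix", "matrix", "array"))
}

#' Read a randomized-response design from a configuration file
#'
#' The configuration is key-value text (YAML). Either a per-question device
#' (`p_truth`, `p_forced_yes`, `p_forced_no`, optionally `questions: J`) or
#' an explicit matrix given row-wise under `matrix:`.
#'
#' @param path path to the configuration file.
#' @return an [rr_matrix()].
#' @export
read_design_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read design configuration files")
  }
  cfg <- yaml::yaml.load_file(path)
  if (!is.null(cfg$matrix)) {
    m <- do.call(rbind, lapply(cfg$matrix, as.numeric))
    return(rr_matrix(m))
  }
  dev <- rr_device(cfg$p_truth, cfg$p_forced_yes, cfg$p_forced_no)
  J <- if (is.null(cfg$questions)) 1L else as.integer(cfg$questions)
  profile_design(rep(list(forced_response_matrix(dev)), J))
}

#' Write a design matrix as delimited text for audit
#'
#' @param P an [rr_matrix()].
#' @param path output path (CSV, no header).
#' @export
write_design_matrix <- function(P, path) {
  utils::write.table(unclass(rr_matrix(P)), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
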