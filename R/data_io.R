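#' Frequency table of observed answer profiles
#'
#' Per-sample vector of observed counts over the K answer profiles, in
#' lexicographic profile order (profile 1 = all yes, ..., profile K = all
#' no).
#'
#' @param counts non-negative integer vector of length K.
#' @param sample sample label, 1 (randomized response) or 2 (direct
#'   questioning).
#' @return an object of class `freq_table` with fields `sample`, `counts`
#'   and `n`.
#' @export
freq_table <- function(counts, sample = 1L) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be non-negative integers")
  }
  sample <- as.integer(sample)
  if (!sample %in% c(1L, 2L)) stop("sample label must be 1 (RR) or 2 (DQ)")
  structure(list(sample = sample, counts = counts, n = sum(counts)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("Sample %d (%s), n = %d\n", x$sample,
              if (x$sample == 1) "randomized response" else "direct questioning",
              as.integer(x$n)))
  K <- length(x$counts)
  J <- as.integer(round(log2(K)))
  lab <- if (2^J == K) profile_labels(J) else as.character(seq_len(K))
  print(stats::setNames(x$counts, lab))
  invisible(x)
}

#' Profile labels and index conversion
#'
#' Answer profiles over J binary questions are indexed lexicographically in
#' (answer 1, ..., answer J) with yes = 1 before no = 2, so index 1 is
#' all-yes and index K = 2^J is all-no.
#'
#' @param answers integer vector (length J) or matrix (rows = respondents)
#'   of per-question answers coded 1 = yes, 2 = no.
#' @return `profile_index()`: integer profile index in 1..2^J;
#'   `profile_answers()`: integer matrix of answers; `profile_labels()`:
#'   character vector such as "111", "112", ....
#' @examples
#' profile_index(c(1, 2, 1))
#' profile_labels(3)
#' @export
profile_index <- function(answers) {
  a <- if (is.matrix(answers)) answers else matrix(answers, nrow = 1)
  if (any(!a %in% c(1, 2))) stop("answers must be coded 1 (yes) or 2 (no)")
  J <- ncol(a)
  idx <- as.integer(1 + (a - 1) %*% 2^((J - 1):0))
  if (is.matrix(answers)) idx else idx[1]
}

#' @rdname profile_index
#' @param k profile index (vector allowed).
#' @param J number of questions.
#' @export
profile_answers <- function(k, J) {
  if (any(k < 1 | k > 2^J)) stop("profile index out of range")
  out <- matrix(0L, length(k), J)
  r <- as.integer(k) - 1L
  for (j in J:1) {
    out[, j] <- r %% 2L + 1L
    r <- r %/% 2L
  }
  out
}

#' @rdname profile_index
#' @export
profile_labels <- function(J) {
  apply(profile_answers(seq_len(2^J), J), 1, paste, collapse = "")
}

#' Read individual survey records from delimited text
#'
#' Expects a comma-delimited file with a header row, a `sample` column
#' (1 = randomized response, 2 = direct questioning) and either a
#' `category` column (1-based profile index) or J per-question answer
#' columns `q1..qJ` coded 1 = yes / 2 = no. Any further columns are kept
#' as covariates. The attitude covariates `Reason` and `Advantage`, when
#' present, must be integers in -2..2 (centred agreement scores); `Sex` is
#' 0 for women and 1 for men; `Age` is in years centred at 50.
#'
#' @param path path to the CSV file.
#' @param K number of answer categories (inferred from the answer columns
#'   when absent).
#' @return a `data.frame` of validated records with columns `sample`,
#'   `category` and any covariates.
#' @export
load_records <- function(path, K = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  validate_records(df, K)
}

#' @rdname load_records
#' @param records a data.frame of records.
#' @export
validate_records <- function(records, K = NULL) {
  df <- as.data.frame(records)
  if (!"sample" %in% names(df)) stop("records need a 'sample' column")
  bad <- which(!df$sample %in% c(1, 2))
  if (length(bad)) {
    stop("unknown sample label in row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  qcols <- grep("^q[0-9]+$", names(df), value = TRUE)
  if (!"category" %in% names(df)) {
    if (!length(qcols)) stop("records need a 'category' or q1..qJ columns")
    qcols <- paste0("q", seq_along(qcols))
    ansbad <- which(apply(df[qcols], 1, function(r) any(!r %in% c(1, 2))))
    if (length(ansbad)) {
      stop("malformed answer (must be 1/2) in row(s) ",
           paste(utils::head(ansbad, 5), collapse = ", "))
    }
    df$category <- profile_index(as.matrix(df[qcols]))
  }
  if (is.null(K)) {
    K <- if (length(qcols)) 2^length(qcols) else max(df$category)
  }
  bad <- which(df$category < 1 | df$category > K |
                 df$category != round(df$category))
  if (length(bad)) {
    stop("category out of range 1..", K, " in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  for (v in intersect(c("Reason", "Advantage"), names(df))) {
    bad <- which(!is.na(df[[v]]) & !df[[v]] %in% (-2:2))
    if (length(bad)) {
      stop("malformed covariate ", v, " (must be integer -2..2) in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  df
}

#' Write individual survey records as delimited text
#'
#' @param records data.frame of records.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabulate records into per-sample frequency tables
#'
#' @param records data.frame with `sample` and `category` columns (see
#'   [load_records()]).
#' @param K number of categories.
#' @return a named list of [freq_table()] objects, one per sample present,
#'   names `"1"` and `"2"`.
#' @export
tabulate_records <- function(records, K = max(records$category)) {
  records <- validate_records(records, K)
  out <- list()
  for (s in sort(unique(records$sample))) {
    cat_s <- records$category[records$sample == s]
    out[[as.character(s)]] <-
      freq_table(tabulate(cat_s, nbins = K), sample = s)
  }
  out
}

#' The Dutch social-benefit compliance survey (aggregated)
#'
#' Aggregated answer-profile frequencies from a 2002 Dutch survey of
#' disability-benefit recipients asked three binary questions about
#' violations of benefit regulations: 1760 respondents under a
#' forced-response randomized-response design and 467 under direct
#' questioning. Profiles are ordered 111, 112, ..., 222 (1 = yes, 2 = no).
#'
#' @return a named list with elements `"1"` (RR sample) and `"2"` (DQ
#'   sample), each a [freq_table()].
#' @examples
#' benefit_survey()
#' @export
benefit_survey <- function() {
  path <- system.file("extdata", "benefit_survey.csv", package = "dualRR",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  out <- list()
  for (s in sort(unique(df$sample))) {
    d <- df[df$sample == s, ]
    out[[as.character(s)]] <-
      freq_table(d$count[order(d$category)], sample = s)
  }
  out
}

#' Attitude-statement marginal distributions
#'
#' Marginal distributions of the two attitude covariates -- Reason ("the
#' rules are very reasonable", -2 completely agree .. 2 completely
#' disagree) and Advantage ("not following the rules can be advantageous
#' for me", -2 completely disagree .. 2 completely agree) -- by survey
#' design, as observed in the benefit survey. Used by the simulator's
#' covariate generator.
#'
#' @return a data.frame with columns `design` ("RR"/"DQ"), `statement`
#'   ("Reason"/"Advantage"), `score` (-2..2) and `proportion`.
#' @export
attitude_marginals <- function() {
  path <- system.file("extdata", "attitude_marginals.csv",
                      package = "dualRR", mustWork = TRUE)
  utils::read.csv(path)
}
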