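# shared fixtures built in code

dice_matrix <- function() forced_response_matrix(two_dice_device())

dice_profile <- function(J = 3) {
  profile_design(rep(list(dice_matrix()), J))
}

# frequency data as the fit functions expect it
freq_pair <- function(c1, c2) {
  list(`1` = freq_table(c1, sample = 1), `2` = freq_table(c2, sample = 2))
}

# published posterior means used as simulation truth in recovery studies
published_modelI_pi <- function() {
  p <- c(0.017, 0.002, 0.058, 0.115, 0.006, 0.006, 0.019, 0.776)
  p / sum(p)
}

published_modelII_truth <- function(model) {
  p <- c(0.017, 0.002, 0.059, 0.120, 0.006, 0.007, 0.021, 0.768)
  c(lambda_from_pi(p / sum(p), model$Z),
    -1.899, -0.968, -0.845, -0.292, -1.370)
}

# derived-scale transform: latent profile probabilities plus the cheating
# regression coefficients (the reporting scale of the analysis)
pi_beta_transform <- function(model) {
  force(model)
  function(th) {
    pr <- split_theta(model, th)
    c(stats::setNames(pi_from_lambda(pr$lambda, model$Z),
                      paste0("pi_", rownames(model$Z))),
      stats::setNames(c(pr$beta1, pr$beta2),
                      model$par_names[-seq_len(model$n_lambda)]))
  }
}

# model-I parameter vector for a given prevalence and cheating pair
theta_modelI <- function(model, pi, tau1, tau2) {
  c(lambda_from_pi(pi, model$Z), stats::qlogis(tau1), stats::qlogis(tau2))
}
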