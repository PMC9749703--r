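# Shared fixtures: the canonical three-node Bernoulli model, its exact
# oracle, correctly specified (saturated) model formulas for it, and a
# Monte-Carlo standard-error yardstick for plug-in estimates.

toy1 <- sem_toy1()
toy1_oracle <- enumerate_oracle(toy1)

oracle_value <- function(oracle, estimand, pathway = "all") {
  tab <- oracle$table
  row <- tab[tab$estimand == estimand & tab$pathway == pathway, ]
  stopifnot(nrow(row) == 1)
  row$value
}

# saturated specifications for toy1 (binary A, binary M, no covariates)
toy1_fit <- function(study, ...) {
  estimate_paf(study, outcome_formula = y ~ a * m,
               mediator_formulas = list(m = .m_ind ~ a), ...)
}

# lean refit-and-estimate pipeline returning only the PS-PAF for toy1;
# used where many bootstrap replicates are needed
toy1_pspaf_pipeline <- function(study) {
  om <- fit_outcome_model(study, formula = y ~ a * m)
  mm <- fit_mediator_model(study, "m", formula = .m_ind ~ a)
  paf_pathway(study, om, mm)
}

# influence-function (delta-method) Monte-Carlo SE for a plug-in estimate
# 1 - mean(w q) / mean(w y), treating the fitted q as fixed; a lower bound
# on the sampling SD used as a yardstick scale, not as inference
plugin_mc_se <- function(study, qhat) {
  w <- study$data$.w
  y <- study$data[[study$outcome]]
  n <- length(y)
  mu_y <- mean(w * y)
  mu_q <- mean(w * qhat)
  phi <- -(w * qhat - mu_q) / mu_y + mu_q * (w * y - mu_y) / mu_y^2
  stats::sd(phi) / sqrt(n)
}

estimate_of <- function(fit, estimand, pathway) {
  fit$estimate[fit$estimand == estimand & fit$pathway == pathway]
}

# a cohort table given per-cell counts over (a, m, y) cells
counts_to_table <- function(counts) {
  # counts: data.frame with columns a, m, y, n
  idx <- rep(seq_len(nrow(counts)), counts$n)
  counts[idx, c("a", "m", "y")]
}
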