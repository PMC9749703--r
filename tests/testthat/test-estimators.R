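test_that("all toy1 estimators match the enumeration oracle on a large cohort", {
  st <- simulate_cohort(toy1, n = 100000, seed = 11)
  fit <- toy1_fit(st)
  om <- attr(fit, "models")$outcome
  mm <- attr(fit, "models")$mediators$m
  for (row in list(c("total", "all"), c("direct", "all"),
                   c("direct_single", "m"), c("indirect", "m"),
                   c("ps_paf", "m"))) {
    est <- estimate_of(fit, row[1], row[2])
    truth <- oracle_value(toy1_oracle, row[1], row[2])
    # yardstick: influence SE of the matching plug-in, floor at binomial scale
    se <- max(plugin_mc_se(st, rep(mean(st$data$y), nrow(st$data))), 1e-3)
    expect_lt(abs(est - truth), 5 * se)
  }
})

test_that("a null mediator model forces a zero PS-PAF (score identity)", {
  # identical mediator values in both exposure arms -> zero fitted shift
  m_vals <- rep(seq(-2, 2, length.out = 50), 4)
  y <- withr::with_seed(5, rbinom(200, 1, plogis(-0.5 + 0.4 * m_vals)))
  d <- data.frame(y = pmax(y, c(1, rep(0, 199))),
                  a = rep(c(0, 1), each = 100), m = m_vals)
  st <- paf_study(d, "y", "a", mediator_continuous("m"))
  om <- fit_outcome_model(st)
  mm <- fit_mediator_model(st, "m")
  est <- paf_pathway(st, om, mm)$estimate
  expect_lt(abs(est), 1e-6)
})

test_that("discrete PS-PAF is zero when the mediator law is identical across arms", {
  # constructed so the empirical P(M | A = a) is the same for a = 0, 1
  counts <- expand.grid(a = c(0, 1), m = c(0, 1), y = c(0, 1))
  counts$n <- c(30, 30, 20, 20, 10, 10, 15, 15) # m-margin equal across a
  d <- counts_to_table(counts)
  st <- paf_study(d, "y", "a", mediator_discrete("m", c(0, 1)))
  om <- fit_outcome_model(st, formula = y ~ a * m)
  mm <- fit_mediator_model(st, "m", formula = .m_ind ~ a)
  expect_lt(abs(paf_pathway(st, om, mm)$estimate), 1e-6)
})

test_that("binary mediators: level-sum and mean-shift routes agree under saturated models", {
  st <- simulate_cohort(toy1, n = 20000, seed = 13)
  om <- fit_outcome_model(st, formula = y ~ a * m)
  mm <- fit_mediator_model(st, "m", formula = .m_ind ~ a)
  disc <- paf_pathway(st, om, mm, method = "discrete")$estimate
  shift <- paf_pathway(st, om, mm, method = "shift")$estimate
  # with saturated models and no covariates the two routes cancel exactly
  expect_lt(abs(disc - shift), 1e-10)
})

test_that("exposure-null outcome model gives zero direct PAF", {
  st <- simulate_cohort(toy1, n = 5000, seed = 14)
  om <- fit_outcome_model(st, formula = y ~ m) # no exposure term
  expect_lt(abs(paf_direct(st, om)$estimate), 1e-8)
  expect_lt(abs(paf_direct_single(st, "m", outcome_model_k = om)$estimate),
            1e-8)
})

test_that("with one mediator the two direct PAFs coincide", {
  st <- simulate_cohort(toy1, n = 20000, seed = 15)
  fit <- toy1_fit(st)
  expect_equal(estimate_of(fit, "direct", "all"),
               estimate_of(fit, "direct_single", "m"), tolerance = 1e-12)
})

test_that("indirect + single-mediator direct equals total exactly", {
  st <- simulate_cohort(toy1, n = 10000, seed = 16)
  fit <- toy1_fit(st)
  expect_identical(
    estimate_of(fit, "indirect", "m"),
    estimate_of(fit, "total", "all") - estimate_of(fit, "direct_single", "m"))

  m2 <- random_discrete_sem(31, n_mediators = 2)
  st2 <- simulate_cohort(m2, n = 20000, seed = 17)
  fit2 <- estimate_paf(st2)
  for (k in c("m1", "m2")) {
    expect_identical(
      estimate_of(fit2, "indirect", k),
      estimate_of(fit2, "total", "all") - estimate_of(fit2, "direct_single", k))
  }
})

test_that("every estimate is bounded above by 1", {
  for (seed in 1:5) {
    m <- random_discrete_sem(seed, n_mediators = 2)
    st <- simulate_cohort(m, n = 4000, seed = seed + 100)
    fit <- estimate_paf(st)
    expect_true(all(fit$estimate <= 1))
  }
})

test_that("joint and single-mediator PS-PAF estimators agree on d-separated models", {
  m2 <- random_discrete_sem(42, n_mediators = 2)
  st <- simulate_cohort(m2, n = 100000, seed = 18)
  joint <- fit_outcome_model(st, formula = y ~ a * m1 * m2 * c0)
  mm1 <- fit_mediator_model(st, "m1", formula = .m_ind ~ a * c0)
  est_joint <- paf_pathway(st, joint, mm1, "m1")$estimate
  single <- fit_outcome_model(st, mediators = "m1",
                              formula = y ~ a * m1 * c0)
  est_single <- paf_pathway(st, single, mm1, "m1")$estimate
  oracle <- enumerate_oracle(m2)
  truth <- oracle_value(oracle, "ps_paf", "m1")
  se <- max(plugin_mc_se(st, rep(mean(st$data$y), nrow(st$data))), 1e-3)
  expect_lt(abs(est_joint - truth), 5 * se)
  expect_lt(abs(est_single - truth), 5 * se)
})

test_that("mediators on a shared pathway are refused by joint estimators", {
  m2 <- random_discrete_sem(77, n_mediators = 2, sequential = TRUE)
  st <- simulate_cohort(m2, n = 2000, seed = 19)
  expect_false(st$mediators$m1$d_separated)
  expect_error(estimate_paf(st),
               class = "pspaf_unsupported_structure_error")
})

test_that("impact fractions reduce to the PS-PAF and to zero at the extremes", {
  st <- simulate_cohort(toy1, n = 20000, seed = 20)
  om <- fit_outcome_model(st, formula = y ~ a * m)
  mm <- fit_mediator_model(st, "m", formula = .m_ind ~ a)

  pr0 <- predict_mediator_probs(mm, st$data, 0)
  expect_lt(abs(impact_fraction(st, om, "m", new_probs = pr0)$estimate -
                  paf_pathway(st, om, mm)$estimate), 1e-12)

  obs <- st$data$m
  obs_probs <- cbind(1 - obs, obs)
  expect_lt(abs(impact_fraction(st, om, "m", new_probs = obs_probs)$estimate),
            1e-6)

  # 50% attenuation of the counterfactual shift sits between 0 and the PS-PAF
  half <- (pr0 + obs_probs) / 2
  mid <- impact_fraction(st, om, "m", new_probs = half)$estimate
  full <- paf_pathway(st, om, mm)$estimate
  expect_gt(mid, 0)
  expect_lt(mid, full)

  expect_error(impact_fraction(st, om, "m"), class = "pspaf_contract_error")
  expect_error(impact_fraction(st, om, "m", new_probs = pr0[, 2:1] * 2),
               class = "pspaf_contract_error")
})

test_that("estimates are invariant to record order and record duplication", {
  st <- simulate_cohort(toy1, n = 5000, seed = 22)
  fit <- toy1_fit(st)
  perm <- withr::with_seed(23, sample.int(nrow(st$data)))
  stp <- st
  stp$data <- st$data[perm, ]
  expect_equal(toy1_fit(stp)$estimate, fit$estimate, tolerance = 1e-9)

  std <- st
  std$data <- st$data[rep(seq_len(nrow(st$data)), 2), ]
  expect_equal(toy1_fit(std)$estimate, fit$estimate, tolerance = 1e-9)
})

test_that("reduced-model total PAF agrees with the mediated route on toy1", {
  st <- simulate_cohort(toy1, n = 100000, seed = 24)
  mediated <- toy1_fit(st)
  reduced <- paf_total(st, method = "reduced")$estimate
  truth <- oracle_value(toy1_oracle, "total")
  expect_lt(abs(reduced - truth), 0.02)
  expect_lt(abs(estimate_of(mediated, "total", "all") - truth), 0.02)
})

test_that("tidy, glance and autoplot work on fits", {
  st <- simulate_cohort(toy1, n = 2000, seed = 25)
  fit <- toy1_fit(st)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(glance(fit)$n_estimands == nrow(fit))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  om <- attr(fit, "models")$outcome
  expect_true(all(c("term", "estimate") %in% names(tidy(om))))
  expect_true(is.finite(glance(om)$deviance))
})
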