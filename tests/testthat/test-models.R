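make_2x2_study <- function() {
  # A=0: 10 cases / 90 non-cases; A=1: 30 / 70; dummy mediator
  d <- data.frame(
    y = c(rep(1, 10), rep(0, 90), rep(1, 30), rep(0, 70)),
    a = rep(c(0, 1), each = 100)
  )
  d$m <- rep_len(c(-0.5, 0.5), nrow(d))
  paf_study(d, "y", "a", mediator_continuous("m"))
}

test_that("saturated outcome fit reproduces empirical risks and the score identity", {
  st <- make_2x2_study()
  om <- fit_outcome_model(st, mediators = character(0), formula = y ~ a)
  p0 <- predict_response(om, data.frame(a = 0, m = 0))
  p1 <- predict_response(om, data.frame(a = 1, m = 0))
  expect_equal(p0, 0.10, tolerance = 1e-8)
  expect_equal(p1, 0.30, tolerance = 1e-8)
  expect_lt(abs(om$score_intercept), 1e-6)
})

test_that("weighted logistic regression recovers known coefficients", {
  truth <- c(-2, 0.8, 0.5, -0.4)
  n <- 50000
  dat <- withr::with_seed(123, {
    a <- rbinom(n, 1, 0.4)
    c1 <- rnorm(n)
    m <- rnorm(n, 1 + 0.5 * a)
    y <- rbinom(n, 1, plogis(truth[1] + truth[2] * a + truth[3] * c1 +
                               truth[4] * m))
    data.frame(y = y, a = a, c1 = c1, m = m)
  })
  st <- paf_study(dat, "y", "a", mediator_continuous("m"),
                  covariates = "c1")
  om <- fit_outcome_model(st)
  est <- coef(om$fit)
  se <- summary(om$fit)$coefficients[, 2]
  expect_true(all(abs(est - truth) < 3 * se))
  expect_lt(abs(om$score_intercept), 1e-6)
})

test_that("the intercept score identity holds under case-control weights", {
  cc <- sample_case_control(toy1, n_cases = 500, r = 2, seed = 21)
  om <- fit_outcome_model(cc, formula = y ~ a * m)
  expect_lt(abs(om$score_intercept) / sum(cc$data$.w), 1e-9)
})

test_that("rank-deficient designs are reported with the collinear term", {
  st <- make_2x2_study()
  st$data$acopy <- st$data$a
  st$covariates <- "acopy"
  expect_error(fit_outcome_model(st), regexp = "acopy",
               class = "pspaf_estimation_error")
})

test_that("continuous mediator model recovers the exposure effect", {
  n <- 10000
  dat <- withr::with_seed(7, {
    a <- rbinom(n, 1, 0.5)
    m <- 1 + 2 * a + rnorm(n)
    y <- rbinom(n, 1, 0.2)
    data.frame(y = y, a = a, m = m)
  })
  dat$y[1] <- 1  # ensure at least one case regardless of the draw
  st <- paf_study(dat, "y", "a", mediator_continuous("m"))
  mm <- fit_mediator_model(st, "m")
  est <- coef(mm$fit)["a"]
  se <- summary(mm$fit)$coefficients["a", 2]
  expect_lt(abs(est - 2), 3 * se)
  expect_error(predict_mediator_probs(mm, st$data, 0),
               class = "pspaf_contract_error")
})

test_that("binary mediator model detects no exposure effect when absent", {
  n <- 20000
  dat <- withr::with_seed(8, {
    a <- rbinom(n, 1, 0.5)
    m <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, 0.1 + 0.2 * m)
    data.frame(y = y, a = a, m = m)
  })
  st <- paf_study(dat, "y", "a", mediator_discrete("m", c(0, 1)))
  mm <- fit_mediator_model(st, "m")
  est <- coef(mm$fit)["a"]
  se <- summary(mm$fit)$coefficients["a", 2]
  expect_lt(abs(est), 3 * se)
  p1 <- predict_mediator_probs(mm, st$data[1:5, ], 1)[, 2]
  p0 <- predict_mediator_probs(mm, st$data[1:5, ], 0)[, 2]
  expect_true(all(abs(p1 - p0) < 3 * se))
})

test_that("multi-level mediator probabilities normalise and need full support", {
  n <- 3000
  dat <- withr::with_seed(9, {
    a <- rbinom(n, 1, 0.5)
    c1 <- rnorm(n)
    pr <- cbind(0.5 - 0.2 * a, 0.3, 0.2 + 0.2 * a)
    m <- vapply(seq_len(n), function(i) sample(1:3, 1, prob = pr[i, ]),
                numeric(1))
    y <- rbinom(n, 1, 0.2)
    data.frame(y = pmax(y, c(1, rep(0, n - 1))), a = a, c1 = c1, m = m)
  })
  st <- paf_study(dat, "y", "a", mediator_discrete("m", 1:3),
                  covariates = "c1")
  mm <- fit_mediator_model(st, "m")
  pr <- predict_mediator_probs(mm, st$data, 0)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-10))
  pr1 <- predict_mediator_probs(mm, st$data, 1)
  expect_true(all(abs(rowSums(pr1) - 1) < 1e-10))

  st4 <- st
  st4$mediators$m$levels <- 1:4
  expect_error(fit_mediator_model(st4, "m"), regexp = "4",
               class = "pspaf_estimation_error")
})

test_that("shifted mediator values implement the mean-shift formula", {
  d <- data.frame(y = rep(c(0, 1), 10), a = rep(c(0, 1), each = 10),
                  m = rnorm(20, 2))
  st <- paf_study(d, "y", "a", mediator_continuous("m"))
  mm <- fit_mediator_model(st, "m")
  sh <- shifted_mediator_values(st, mm)
  a <- st$data$a
  # unexposed records unchanged
  expect_equal(sh[a == 0], st$data$m[a == 0])
  # exposed records shifted by the fitted mean difference
  delta <- coef(mm$fit)["a"]
  expect_equal(sh[a == 1], st$data$m[a == 1] - unname(delta))
  # discrete models are rejected
  std <- paf_study(data.frame(y = d$y, a = d$a, m = rep(c(0, 1), 10)),
                   "y", "a", mediator_discrete("m", c(0, 1)))
  mmd <- fit_mediator_model(std, "m")
  expect_error(shifted_mediator_values(std, mmd),
               class = "pspaf_contract_error")
})

test_that("a zero fitted exposure effect leaves the mediator untouched", {
  # identical mediator values in both arms -> fitted shift is exactly 0
  m_vals <- seq(-1.5, 1.5, length.out = 50)
  d <- data.frame(y = rep_len(c(0, 1), 200), a = rep(c(0, 1), each = 100),
                  m = rep(m_vals, 4))
  st <- paf_study(d, "y", "a", mediator_continuous("m"))
  mm <- fit_mediator_model(st, "m")
  sh <- shifted_mediator_values(st, mm)
  expect_equal(max(abs(sh - st$data$m)), 0, tolerance = 1e-12)
})

test_that("spline bases are deterministic and order-invariant", {
  n <- 500
  dat <- withr::with_seed(10, {
    a <- rbinom(n, 1, 0.5)
    m <- rnorm(n, 1 + a)
    y <- rbinom(n, 1, plogis(-1 + 0.5 * a + 0.3 * m))
    data.frame(y = pmax(y, c(1, rep(0, n - 1))), a = a, m = m)
  })
  st <- paf_study(dat, "y", "a", mediator_continuous("m"))
  om1 <- fit_outcome_model(st, spline_df = c(m = 5))
  om2 <- fit_outcome_model(st, spline_df = c(m = 5))
  expect_identical(coef(om1$fit), coef(om2$fit))

  perm <- withr::with_seed(11, sample.int(n))
  stp <- paf_study(dat[perm, ], "y", "a", mediator_continuous("m"))
  omp <- fit_outcome_model(stp, spline_df = c(m = 5))
  expect_equal(predict_response(om1, dat[1:10, ]),
               predict_response(omp, dat[1:10, ]), tolerance = 1e-8)
})
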