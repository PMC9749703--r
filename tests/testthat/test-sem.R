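test_that("toy1 enumeration reproduces the hand-computed functionals exactly", {
  fx <- toy1_oracle$functionals
  expect_equal(fx$p_y, 0.45, tolerance = 1e-12)
  expect_equal(fx$p_y0, 0.18, tolerance = 1e-12)
  expect_equal(fx$p_direct_all, 0.30, tolerance = 1e-12)
  expect_equal(fx$p_interventional_m, 0.33, tolerance = 1e-12)
  expect_equal(fx$p_mechanistic_m, 0.33, tolerance = 1e-12)
  expect_equal(oracle_value(toy1_oracle, "total"), 0.6, tolerance = 1e-12)
  expect_equal(oracle_value(toy1_oracle, "direct"), 1 / 3,
               tolerance = 1e-12)
  expect_equal(oracle_value(toy1_oracle, "ps_paf", "m"), 4 / 15,
               tolerance = 1e-12)
  expect_equal(oracle_value(toy1_oracle, "indirect", "m"), 4 / 15,
               tolerance = 1e-12)
})

test_that("a blocked mediator pathway gives a PS-PAF of exactly zero", {
  m <- structural_model(
    nodes = list(
      sem_node("a", levels = c(0, 1), prob = c(0.5, 0.5)),
      sem_node("m", parents = "a", levels = c(0, 1),
               cpt = data.frame(a = c(0, 1), p1 = c(0.8, 0.2),
                                p2 = c(0.2, 0.8))),
      sem_node("y", parents = "a", levels = c(0, 1),
               cpt = data.frame(a = c(0, 1), p1 = c(0.9, 0.5),
                                p2 = c(0.1, 0.5)))
    ),
    exposure = "a", outcome = "y", mediators = "m")
  o <- enumerate_oracle(m)
  expect_equal(oracle_value(o, "ps_paf", "m"), 0, tolerance = 1e-14)
  expect_equal(oracle_value(o, "ps_paf_mechanistic", "m"), 0,
               tolerance = 1e-14)
})

test_that("interventional and mechanistic functionals coincide on d-separated models", {
  for (seed in 1:20) {
    k_med <- 1 + seed %% 2
    m <- random_discrete_sem(seed, n_mediators = k_med)
    rep <- verify_identification_equivalence(m)
    expect_true(all(rep$gap <= 1e-12))
    expect_true(all(rep$asserted))
  }
})

test_that("sequential mediator structures report a gap without asserting", {
  m <- random_discrete_sem(301, n_mediators = 2, sequential = TRUE)
  expect_identical(m$mediator_structure, "sequential")
  rep <- verify_identification_equivalence(m)
  expect_false(any(rep$asserted))
  expect_true(all(is.finite(rep$gap)))
})

test_that("oracle orderings hold on monotone-deleterious models", {
  for (seed in 1:30) {
    m <- random_discrete_sem(seed + 1000, n_mediators = 1 + seed %% 2,
                             monotone = TRUE)
    o <- enumerate_oracle(m)
    total <- oracle_value(o, "total")
    for (k in m$mediators) {
      expect_gte(oracle_value(o, "ps_paf", k) + 1e-12,
                 oracle_value(o, "indirect", k))
      expect_gte(total + 1e-12, oracle_value(o, "ps_paf", k))
    }
  }
})

test_that("simulated cohorts match the model law and are reproducible", {
  expect_error(simulate_cohort(toy1, n = 0), class = "pspaf_config_error")
  n <- 50000
  st <- simulate_cohort(toy1, n = n, seed = 5)
  expect_equal(nrow(st$data), n)
  expect_lt(abs(mean(st$data$y) - 0.45), 3 * sqrt(0.45 * 0.55 / n))
  expect_lt(abs(mean(st$data$a) - 0.5), 3 * sqrt(0.25 / n))
  st2 <- simulate_cohort(toy1, n = n, seed = 5)
  expect_identical(st$data, st2$data)
  st3 <- simulate_cohort(toy1, n = n, seed = 6)
  expect_false(identical(st$data$y, st3$data$y))
})

test_that("case-control samples have exact counts and recover the cohort law", {
  cc <- sample_case_control(toy1, n_cases = 1000, r = 1, seed = 7)
  expect_equal(sum(cc$data$y == 1), 1000)
  expect_equal(sum(cc$data$y == 0), 1000)
  expect_equal(cc$design$kind, "case_control")
  expect_equal(cc$design$prevalence, 0.45, tolerance = 1e-12)
  expect_equal(unique(cc$data$.w[cc$data$y == 0]), (1 / 0.45 - 1) / 1,
               tolerance = 1e-12)

  # weighted exposure prevalence ~ population exposure prevalence (0.5)
  w <- cc$data$.w
  wp <- sum(w * cc$data$a) / sum(w)
  expect_lt(abs(wp - 0.5), 3 * sqrt(0.25 / nrow(cc$data)) *
              max(w) / mean(w))

  cc2 <- sample_case_control(toy1, n_cases = 200, r = 2, seed = 8)
  expect_equal(sum(cc2$data$y == 0), 400)
})

test_that("enumeration refuses continuous nodes and oversized supports", {
  m_cont <- structural_model(
    nodes = list(
      sem_node("a", levels = c(0, 1), prob = c(0.5, 0.5)),
      sem_node("m", parents = "a",
               rfun = function(p, u) qnorm(u, p$a)),
      sem_node("y", parents = c("a", "m"), levels = c(0, 1),
               prob = function(p) {
                 pr <- plogis(-1 + p$a + 0.5 * p$m)
                 cbind(1 - pr, pr)
               })
    ),
    exposure = "a", outcome = "y", mediators = "m")
  expect_error(enumerate_oracle(m_cont), class = "pspaf_unsupported_error")

  big_levels <- seq_len(300)
  nodes <- list(sem_node("c1", levels = big_levels,
                         prob = rep(1 / 300, 300)),
                sem_node("c2", levels = big_levels,
                         prob = rep(1 / 300, 300)),
                sem_node("c3", levels = big_levels,
                         prob = rep(1 / 300, 300)),
                sem_node("a", levels = c(0, 1), prob = c(0.5, 0.5)),
                sem_node("m", levels = c(0, 1), prob = c(0.5, 0.5)),
                sem_node("y", parents = "a", levels = c(0, 1),
                         cpt = data.frame(a = c(0, 1), p1 = c(0.9, 0.5),
                                          p2 = c(0.1, 0.5))))
  m_big <- structural_model(nodes, exposure = "a", outcome = "y",
                            mediators = "m")
  expect_error(enumerate_oracle(m_big), class = "pspaf_resource_error")
})

test_that("model validation catches bad orderings and roles", {
  expect_error(
    structural_model(
      nodes = list(
        sem_node("m", parents = "a", levels = c(0, 1),
                 cpt = data.frame(a = c(0, 1), p1 = c(0.5, 0.5),
                                  p2 = c(0.5, 0.5))),
        sem_node("a", levels = c(0, 1), prob = c(0.5, 0.5)),
        sem_node("y", parents = "a", levels = c(0, 1),
                 cpt = data.frame(a = c(0, 1), p1 = c(0.9, 0.5),
                                  p2 = c(0.1, 0.5)))),
      exposure = "a", outcome = "y", mediators = "m"),
    class = "pspaf_config_error")
  expect_error(sem_node("x", levels = c(0, 1)),
               class = "pspaf_config_error")
  expect_error(sem_node("x"), class = "pspaf_config_error")
})

test_that("yaml round trip preserves the model's oracle", {
  path <- withr::local_tempfile(fileext = ".yaml")
  m <- random_discrete_sem(55, n_mediators = 2)
  write_sem_yaml(m, path)
  m2 <- read_sem_yaml(path)
  o1 <- enumerate_oracle(m)
  o2 <- enumerate_oracle(m2)
  expect_equal(o1$table$value, o2$table$value, tolerance = 1e-12)

  expect_error(read_sem_yaml("no/such/file.yaml"), class = "pspaf_io_error")
  m_cont <- interstroke_model()
  expect_error(write_sem_yaml(m_cont, path),
               class = "pspaf_unsupported_error")
})

test_that("the shipped toy1 yaml matches the built-in model", {
  path <- system.file("extdata", "toy1.yaml", package = "pspaf")
  expect_true(nzchar(path))
  m <- read_sem_yaml(path)
  o <- enumerate_oracle(m)
  expect_equal(o$table$value, toy1_oracle$table$value, tolerance = 1e-12)
})

test_that("monte carlo oracle agrees with enumeration on toy1", {
  o_mc <- mc_oracle(toy1, n = 200000, seed = 9)
  merged <- merge(as.data.frame(o_mc$table),
                  as.data.frame(toy1_oracle$table),
                  by = c("estimand", "pathway"))
  expect_true(all(abs(merged$value.x - merged$value.y) <
                    3 * pmax(merged$mc_se, 1e-4)))
})
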