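# A synthetic stroke case-control test-bed with the causal structure of a
# large international stroke risk-factor study: baseline confounders (age,
# sex, region, education, diet score, stress, smoking, alcohol), a binary
# physical-inactivity exposure, one binary mediator (diagnosed
# hypertension), two Gaussian mediators (waist-hip ratio, ApoB/ApoA ratio)
# and a rare binary stroke outcome with marginal yearly incidence
# calibrated to 0.0035. All parameter values are plausible fabrications
# chosen once for realism; the generator does not claim to reproduce any
# real study's joint distribution.

interstroke_stroke_eta <- function(p) {
  0.5 * p$phys + 0.7 * p$hbp +
    2.5 * (p$whr - 0.9) + 0.8 * (p$apob - 0.9) +
    0.045 * (p$age - 55) + 0.25 * p$sex + 0.4 * p$smoke +
    0.3 * p$stress + 0.15 * p$alcoh - 0.1 * p$diet +
    0.1 * (p$region == 3) + 0.15 * (p$educ == 3)
}

interstroke_nodes <- function(b0, phys_null = FALSE) {
  ph <- if (phys_null) 0 else 1  # switch off every arrow out of phys
  list(
    sem_node("age", rfun = function(p, u) qnorm(u, 55, 10)),
    sem_node("sex", levels = c(0, 1), prob = c(0.5, 0.5)),
    sem_node("region", levels = 1:3, prob = c(0.4, 0.35, 0.25),
             as_factor = TRUE),
    sem_node("educ", levels = 1:3, prob = c(0.3, 0.45, 0.25),
             as_factor = TRUE),
    sem_node("stress", levels = c(0, 1), prob = c(0.75, 0.25)),
    sem_node("smoke", levels = c(0, 1), prob = c(0.78, 0.22)),
    sem_node("alcoh", levels = c(0, 1), prob = c(0.70, 0.30)),
    sem_node("diet", rfun = function(p, u) qnorm(u)),
    sem_node("phys",
             parents = c("age", "sex", "region", "educ", "stress", "diet"),
             levels = c(0, 1),
             prob = function(p) {
               pr <- plogis(0.6 + 0.02 * (p$age - 55) + 0.15 * p$sex -
                              0.1 * (p$region == 2) + 0.2 * (p$region == 3) -
                              0.15 * (p$educ == 2) - 0.3 * (p$educ == 3) +
                              0.1 * p$stress - 0.1 * p$diet)
               cbind(1 - pr, pr)
             }),
    sem_node("hbp",
             parents = c("phys", "age", "sex", "stress", "smoke", "alcoh",
                         "diet"),
             levels = c(0, 1),
             prob = function(p) {
               pr <- plogis(-0.9 + 0.35 * ph * p$phys +
                              0.035 * (p$age - 55) + 0.12 * p$sex +
                              0.1 * p$smoke + 0.15 * p$alcoh +
                              0.1 * p$stress - 0.05 * p$diet)
               cbind(1 - pr, pr)
             }),
    sem_node("whr",
             parents = c("phys", "age", "sex", "diet", "alcoh"),
             rfun = function(p, u) {
               0.88 + 0.025 * ph * p$phys + 0.0012 * (p$age - 55) +
                 0.05 * p$sex - 0.02 * p$diet + 0.01 * p$alcoh +
                 0.06 * qnorm(u)
             }),
    sem_node("apob",
             parents = c("phys", "age", "sex", "smoke", "diet"),
             rfun = function(p, u) {
               0.85 + 0.06 * ph * p$phys + 0.001 * (p$age - 55) +
                 0.05 * p$smoke + 0.03 * p$sex - 0.04 * p$diet +
                 0.2 * qnorm(u)
             }),
    sem_node("stroke",
             parents = c("phys", "hbp", "whr", "apob", "age", "sex",
                         "region", "educ", "stress", "smoke", "alcoh",
                         "diet"),
             levels = c(0, 1),
             prob = function(p) {
               eta <- interstroke_stroke_eta(p)
               if (phys_null) eta <- eta - 0.5 * p$phys
               pr <- plogis(b0 + eta)
               cbind(1 - pr, pr)
             })
  )
}

# solve the stroke intercept so the marginal incidence hits the target;
# deterministic (fixed internal calibration sample)
interstroke_intercept <- function(target, phys_null = FALSE) {
  nodes <- interstroke_nodes(b0 = 0, phys_null = phys_null)
  model <- structural_model(nodes, exposure = "phys", outcome = "stroke",
                            mediators = c("hbp", "whr", "apob"))
  eta <- withr::with_seed(104729L, {
    n_cal <- 2e5
    U <- matrix(runif(n_cal * length(model$nodes)), nrow = n_cal,
                dimnames = list(NULL, names(model$nodes)))
    sim <- eval_world(model, U)
    e <- interstroke_stroke_eta(sim)
    if (phys_null) e - 0.5 * sim$phys else e
  })
  uniroot(function(b0) mean(plogis(b0 + eta)) - target,
          interval = c(-20, 5), tol = 1e-10)$root
}

#' Synthetic stroke-study structural model
#'
#' Builds the structural model described above: binary physical-inactivity
#' exposure `phys`, mediators `hbp` (binary hypertension diagnosis), `whr`
#' and `apob` (Gaussian given exposure and covariates), baseline covariates
#' age, sex, region, education, stress, smoking, alcohol and a diet score,
#' and a rare binary `stroke` outcome whose intercept is calibrated so the
#' marginal incidence equals `incidence`. Mediators are d-separated given
#' exposure and covariates. True functionals are available through
#' [mc_oracle()] (the model has continuous nodes, so exact enumeration does
#' not apply).
#'
#' @param incidence Target marginal outcome probability (default 0.0035).
#' @param phys_null Sever every arrow out of the exposure (all true
#'   attributable fractions become 0); useful as a global null.
#' @return A [structural_model()] with `p_y` set to `incidence`.
#' @export
interstroke_model <- function(incidence = 0.0035, phys_null = FALSE) {
  b0 <- interstroke_intercept(incidence, phys_null = phys_null)
  model <- structural_model(
    interstroke_nodes(b0 = b0, phys_null = phys_null),
    exposure = "phys", outcome = "stroke",
    mediators = c("hbp", "whr", "apob"),
    p_y = incidence
  )
  model
}

#' Simulate a synthetic stroke study
#'
#' Convenience wrapper around [interstroke_model()]: draws either a cohort
#' of `n` records or a 1:`r` frequency-matched case-control sample with
#' `n_cases` cases (design prevalence set to the model's calibrated
#' incidence).
#'
#' @param seed Integer seed.
#' @param n Cohort size (cohort mode).
#' @param n_cases,r Case count and matching ratio (case-control mode).
#' @param model Optionally a prebuilt [interstroke_model()] (saves the
#'   calibration step when simulating repeatedly).
#' @return A `paf_study` with the model attached as attribute `"model"`.
#' @export
sim_interstroke <- function(seed = 1, n = NULL, n_cases = NULL, r = 1,
                            model = NULL) {
  if (is.null(model)) model <- interstroke_model()
  if (is.null(n) == is.null(n_cases)) {
    abort("supply exactly one of `n` (cohort) or `n_cases` (case-control).",
          class = "pspaf_config_error")
  }
  if (!is.null(n)) {
    simulate_cohort(model, n = n, seed = seed)
  } else {
    sample_case_control(model, n_cases = n_cases, r = r, seed = seed,
                        prevalence = model$p_y)
  }
}
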