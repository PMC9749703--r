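# Nuisance regressions behind the attributable-fraction estimators:
# an outcome model P(Y=1 | A, C, M...) and one model per mediator,
# E[M | A, C] (continuous) or P(M = m | A, C) (discrete).

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) - 0.5 * w
  cw <- cw / sum(w)
  # linear interpolation on the weighted empirical cdf; deterministic
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    stats::approx(cw, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

# spline descriptor: internal knots at weighted quantiles, boundary knots at
# the observed range, so the basis is fully determined by the fitting data
spline_info <- function(x, w, df) {
  if (df < 2) {
    abort("spline df must be >= 2.", class = "pspaf_config_error")
  }
  probs <- seq(0, 1, length.out = df + 1)[-c(1, df + 1)]
  list(knots = weighted_quantile(x, w, probs), boundary = range(x))
}

# Build a model formula from roles. `spline_df` is a named vector giving
# natural-cubic-spline degrees of freedom for continuous terms; discrete
# mediators enter as factors over their declared levels. Returns the formula
# plus the environment carrying knot positions and level sets.
build_formula <- function(response, terms, study, spline_df = NULL,
                          env_parent = parent.frame()) {
  env <- new.env(parent = env_parent)
  env$.spline_knots <- list()
  env$.med_levels <- list()
  rhs <- character(0)
  dat <- study$data
  for (tm in terms) {
    spec <- study$mediators[[tm]]
    if (!is.null(spec) && spec$kind == "discrete") {
      env$.med_levels[[tm]] <- spec$levels
      rhs <- c(rhs, paste0("factor(", tm, ", levels = .med_levels[['",
                           tm, "']])"))
    } else if (!is.null(spline_df) && tm %in% names(spline_df)) {
      if (!is.numeric(dat[[tm]]) || is.factor(dat[[tm]])) {
        abort(paste0("spline term '", tm, "' must be continuous."),
              class = "pspaf_config_error")
      }
      env$.spline_knots[[tm]] <- spline_info(dat[[tm]], dat$.w,
                                             spline_df[[tm]])
      rhs <- c(rhs, paste0(
        "splines::ns(", tm, ", knots = .spline_knots[['", tm, "']]$knots, ",
        "Boundary.knots = .spline_knots[['", tm, "']]$boundary)"))
    } else {
      rhs <- c(rhs, tm)
    }
  }
  if (!length(rhs)) rhs <- "1"
  f <- as.formula(paste(response, "~", paste(rhs, collapse = " + ")), env = env)
  f
}

check_fit <- function(fit, what) {
  cf <- coef(fit)
  if (any(is.na(cf))) {
    abort(paste0(what, ": rank-deficient design; collinear term(s): ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "pspaf_estimation_error")
  }
  if (inherits(fit, "glm")) {
    if (!fit$converged) {
      abort(paste0(what, ": IRLS did not converge."),
            class = "pspaf_estimation_error")
    }
    if (max(abs(cf)) > 30) {
      abort(paste0(what, ": extreme coefficients suggest perfect separation."),
            class = "pspaf_estimation_error")
    }
  }
  invisible(fit)
}

fit_weights <- function(study) {
  if (!study$weight_fitting) return(rep(1, nrow(study$data)))
  w <- study$data$.w
  # rescale to mean 1: the weighted MLE is invariant, and large raw
  # case-control weights destabilise IRLS
  w / mean(w)
}

#' Fit the outcome model
#'
#' Fits a weighted logistic regression for `P(Y = 1 | A, C, M...)` with the
#' exposure, all covariates and the requested mediators as main effects.
#' Continuous terms listed in `spline_df` enter as natural cubic splines with
#' internal knots at weighted quantiles of the fitting data; discrete
#' mediators enter as factors over their declared levels. A full formula
#' override is available for non-additive (e.g. saturated) specifications.
#'
#' @param study A [paf_study()].
#' @param mediators Names of mediators to condition on; default all declared
#'   mediators (the joint outcome model).
#' @param spline_df Named numeric vector of spline degrees of freedom for
#'   continuous terms, e.g. `c(whr = 5)`.
#' @param formula Optional full formula override (response must be the
#'   outcome column).
#' @param link `"logit"` (default). `"identity"` and `"log"` are accepted but
#'   experimental: out-of-range predictions are clipped into
#'   `[1e-12, 1 - 1e-12]` and the clip count recorded.
#' @return A `paf_outcome_model`.
#' @export
fit_outcome_model <- function(study, mediators = NULL, spline_df = NULL,
                              formula = NULL, link = c("logit", "identity",
                                                       "log")) {
  stopifnot(inherits(study, "paf_study"))
  link <- match.arg(link)
  if (is.null(mediators)) mediators <- names(study$mediators)
  stray <- setdiff(mediators, names(study$mediators))
  if (length(stray)) {
    abort(paste0("undeclared mediator(s): ", paste(stray, collapse = ", ")),
          class = "pspaf_config_error")
  }
  if (is.null(formula)) {
    formula <- build_formula(study$outcome,
                             c(study$exposure, study$covariates, mediators),
                             study, spline_df)
  } else {
    environment(formula) <- new.env(parent = environment(formula))
  }
  dat <- study$data
  dat$.fw <- fit_weights(study)
  fam <- quasibinomial(link = link)
  fit <- withCallingHandlers(
    glm(formula, family = fam, data = dat, weights = .fw,
        control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  check_fit(fit, "outcome model")
  p <- as.numeric(fit$fitted.values)
  score <- sum(dat$.fw * (dat[[study$outcome]] - p))
  structure(
    list(fit = fit, formula = formula, link = link, mediators = mediators,
         outcome = study$outcome, exposure = study$exposure,
         score_intercept = score, n_clipped = 0L),
    class = "paf_outcome_model"
  )
}

#' Predicted outcome probabilities
#'
#' @param model A `paf_outcome_model`.
#' @param newdata Data frame of records to predict for.
#' @return Numeric vector of probabilities in (0, 1); for experimental links
#'   predictions are clipped into `[1e-12, 1 - 1e-12]` with a warning.
#' @export
predict_response <- function(model, newdata) {
  p <- as.numeric(predict(model$fit, newdata = newdata, type = "response"))
  out_of_range <- p < 1e-12 | p > 1 - 1e-12
  if (any(out_of_range)) {
    if (model$link != "logit") {
      warn(paste0("clipped ", sum(out_of_range),
                  " prediction(s) into [1e-12, 1-1e-12]."))
    }
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  p
}

#' @export
print.paf_outcome_model <- function(x, ...) {
  cat("<paf_outcome_model> link:", x$link, "\n")
  cat("  mediators:", paste(x$mediators, collapse = ", "), "\n")
  cat("  intercept score residual:", format(x$score_intercept), "\n")
  invisible(x)
}

#' @export
tidy.paf_outcome_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @export
glance.paf_outcome_model <- function(x, ...) {
  tibble(
    n = length(x$fit$y), deviance = x$fit$deviance,
    converged = x$fit$converged, link = x$link,
    score_intercept = x$score_intercept
  )
}

#' Fit a mediator model
#'
#' Continuous mediators get a weighted least-squares conditional-mean model
#' `E[M | A, C]`; discrete mediators a weighted logistic (2 levels) or
#' multinomial (3+ levels) level-probability model `P(M = m | A, C)`. The
#' exposure is always a term.
#'
#' @param study A [paf_study()].
#' @param name Mediator name (must match a declared spec).
#' @param spline_df Optional named spline degrees of freedom for continuous
#'   covariate terms.
#' @param formula Optional full formula override. Continuous mediators use
#'   the mediator column as response; discrete mediators are modelled
#'   through internal responses: `.m_ind` (indicator of the second level,
#'   binary) or `.m_fac` (factor over declared levels, 3+ levels), e.g.
#'   `.m_ind ~ a * c` for a saturated binary mediator model.
#' @return A `paf_mediator_model`.
#' @export
fit_mediator_model <- function(study, name, spline_df = NULL, formula = NULL) {
  stopifnot(inherits(study, "paf_study"))
  spec <- study$mediators[[name]]
  if (is.null(spec)) {
    abort(paste0("undeclared mediator: ", name), class = "pspaf_config_error")
  }
  dat <- study$data
  dat$.fw <- fit_weights(study)
  terms <- c(study$exposure, study$covariates)

  if (spec$kind == "continuous") {
    if (is.null(formula)) {
      formula <- build_formula(name, terms, study, spline_df)
    }
    fit <- lm(formula, data = dat, weights = .fw)
    check_fit(fit, paste0("mediator model '", name, "'"))
    kind <- "continuous"
  } else {
    present <- spec$levels %in% dat[[name]]
    if (!all(present)) {
      abort(paste0("mediator '", name, "' has empty declared level(s): ",
                   paste(spec$levels[!present], collapse = ", ")),
            class = "pspaf_estimation_error")
    }
    if (length(spec$levels) == 2) {
      dat$.m_ind <- as.numeric(dat[[name]] == spec$levels[2])
      if (is.null(formula)) {
        formula <- build_formula(".m_ind", terms, study, spline_df)
      }
      fit <- glm(formula, family = quasibinomial(), data = dat,
                 weights = .fw, control = list(epsilon = 1e-12, maxit = 100))
      check_fit(fit, paste0("mediator model '", name, "'"))
      kind <- "binary"
    } else {
      dat$.m_fac <- factor(dat[[name]], levels = spec$levels)
      if (is.null(formula)) {
        formula <- build_formula(".m_fac", terms, study, spline_df)
      }
      fit <- nnet::multinom(formula, data = dat, weights = .fw,
                            trace = FALSE, maxit = 500)
      if (fit$convergence != 0) {
        abort(paste0("mediator model '", name, "' did not converge."),
              class = "pspaf_estimation_error")
      }
      kind <- "multinomial"
    }
  }
  structure(
    list(fit = fit, spec = spec, kind = kind, exposure = study$exposure,
         formula = formula),
    class = "paf_mediator_model"
  )
}

#' @export
print.paf_mediator_model <- function(x, ...) {
  cat("<paf_mediator_model>", x$spec$name, "(", x$kind, ")\n")
  invisible(x)
}

#' @export
tidy.paf_mediator_model <- function(x, ...) {
  if (x$kind == "multinomial") {
    cf <- coef(x$fit)
    as_tibble(as.data.frame.table(cf, responseName = "estimate")) %>%
      dplyr::rename(level = 1, term = 2)
  } else {
    s <- summary(x$fit)$coefficients
    tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
  }
}

# mediator predictions at exposure level `a` with covariates as in `newdata`
predict_mediator_mean <- function(model, newdata, a) {
  stopifnot(model$kind == "continuous")
  newdata[[model$exposure]] <- a
  as.numeric(predict(model$fit, newdata = newdata))
}

#' Mediator level probabilities at a set exposure
#'
#' Evaluates the fitted `P(M = m | A = a, C)` for every declared level at
#' each record's covariates.
#'
#' @param model A discrete `paf_mediator_model`.
#' @param newdata Records providing covariates.
#' @param a Exposure value to condition on (e.g. 0 for the no-exposure
#'   counterfactual distribution).
#' @return Matrix (records x levels); rows sum to 1.
#' @export
predict_mediator_probs <- function(model, newdata, a) {
  if (model$kind == "continuous") {
    abort("level probabilities are only defined for discrete mediators.",
          class = "pspaf_contract_error")
  }
  newdata[[model$exposure]] <- a
  if (model$kind == "binary") {
    p1 <- as.numeric(predict(model$fit, newdata = newdata, type = "response"))
    pr <- cbind(1 - p1, p1)
  } else {
    pr <- predict(model$fit, newdata = newdata, type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
  }
  colnames(pr) <- as.character(model$spec$levels)
  bad <- abs(rowSums(pr) - 1) > 1e-10
  if (any(bad)) {
    abort("mediator level probabilities do not sum to 1.",
          class = "pspaf_contract_error")
  }
  pr
}

#' Exposure-shifted mediator values
#'
#' For a continuous mediator, subtracts from each exposed record the fitted
#' exposure-attributable mean difference at that record's covariates:
#' `M_i - A_i * (E[M | A = 1, C_i] - E[M | A = 0, C_i])`. Unexposed records
#' are returned unchanged. These shifted values represent a draw-free
#' stand-in for the mediator's distribution had the exposure been absent.
#'
#' @param study A [paf_study()].
#' @param model The continuous `paf_mediator_model` for one of the study's
#'   mediators.
#' @return Numeric vector, one value per record.
#' @export
shifted_mediator_values <- function(study, model) {
  stopifnot(inherits(study, "paf_study"),
            inherits(model, "paf_mediator_model"))
  if (model$kind != "continuous") {
    abort("shifted values are only defined for continuous mediators.",
          class = "pspaf_contract_error")
  }
  dat <- study$data
  a <- dat[[study$exposure]]
  m1 <- predict_mediator_mean(model, dat, 1)
  m0 <- predict_mediator_mean(model, dat, 0)
  dat[[model$spec$name]] - a * (m1 - m0)
}
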