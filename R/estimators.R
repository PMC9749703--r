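# Plug-in estimators for total, direct, indirect and pathway-specific
# attributable fractions. Every estimator is a weighted average of fitted
# outcome probabilities under a counterfactual substitution, divided into the
# weighted case count:
#   PAF-hat = (sum w_i Y_i - sum w_i q_i) / (sum w_i Y_i)
# where q_i is the outcome model evaluated with the relevant substitution.

sum_wy <- function(study) {
  swy <- sum(study$data$.w * study$data[[study$outcome]])
  if (swy <= 0) {
    abort("no weighted cases; attributable fractions are undefined.",
          class = "pspaf_degenerate_error")
  }
  swy
}

plugin_paf <- function(study, qhat) {
  swy <- sum_wy(study)
  (swy - sum(study$data$.w * qhat)) / swy
}

paf_row <- function(estimand, pathway, estimate) {
  tibble(estimand = estimand, pathway = pathway, estimate = estimate)
}

require_d_separated <- function(study, mediators) {
  if (length(mediators) > 1) {
    bad <- mediators[!map_lgl(study$mediators[mediators], "d_separated")]
    if (length(bad)) {
      abort(paste0(
        "mediator(s) ", paste(bad, collapse = ", "), " are not asserted ",
        "d-separated: joint-outcome-model estimation with mediators on the ",
        "same causal pathway (post-treatment confounding) is unsupported; ",
        "fit single-mediator models for interventional PS-PAFs instead."),
        class = "pspaf_unsupported_structure_error")
    }
  }
  invisible(TRUE)
}

# q_i for the pathway-k substitution: mediator k replaced by its no-exposure
# counterfactual representation, exposure and other mediators as observed.
pathway_qhat <- function(study, outcome_model, mediator_model, k,
                         new_values = NULL, new_probs = NULL) {
  dat <- study$data
  spec <- study$mediators[[k]]
  if (spec$kind == "continuous" || !is.null(new_values)) {
    vals <- if (!is.null(new_values)) new_values else
      shifted_mediator_values(study, mediator_model)
    if (length(vals) != nrow(dat)) {
      abort("mediator substitution must supply one value per record.",
            class = "pspaf_contract_error")
    }
    nd <- dat
    nd[[k]] <- vals
    predict_response(outcome_model, nd)
  } else {
    pr <- if (!is.null(new_probs)) new_probs else
      predict_mediator_probs(mediator_model, dat, a = 0)
    if (!is.matrix(pr) || nrow(pr) != nrow(dat) ||
        ncol(pr) != length(spec$levels) ||
        any(abs(rowSums(pr) - 1) > 1e-10)) {
      abort("level probabilities must be a records x levels matrix with rows summing to 1.",
            class = "pspaf_contract_error")
    }
    q <- numeric(nrow(dat))
    for (j in seq_along(spec$levels)) {
      nd <- dat
      nd[[k]] <- spec$levels[j]
      q <- q + pr[, j] * predict_response(outcome_model, nd)
    }
    q
  }
}

#' Pathway-specific PAF (interventional PS-PAF)
#'
#' Plug-in estimator of the relative change in disease prevalence from
#' shifting mediator `k`'s distribution to the distribution it would have if
#' the exposure were eliminated, everything else (including the exposure)
#' unchanged. Continuous mediators use the mean-shift substitution from
#' [shifted_mediator_values()]; discrete mediators average the outcome model
#' over the fitted no-exposure level probabilities. The outcome model may be
#' the joint model over all mediators (other mediators held at observed
#' values; requires every mediator to be d-separated) or a single-mediator
#' model.
#'
#' @param study A [paf_study()].
#' @param outcome_model A `paf_outcome_model` conditioning on mediator `k`
#'   (and possibly the others).
#' @param mediator_model The `paf_mediator_model` for mediator `k`.
#' @param k Mediator name; defaults to the mediator of `mediator_model`.
#' @param method For binary mediators either `"discrete"` (default; exact
#'   level sum) or `"shift"` (mean-shift route, useful as a diagnostic).
#' @return One-row tibble: `estimand`, `pathway`, `estimate`.
#' @export
paf_pathway <- function(study, outcome_model, mediator_model,
                        k = mediator_model$spec$name,
                        method = c("discrete", "shift")) {
  stopifnot(inherits(study, "paf_study"),
            inherits(outcome_model, "paf_outcome_model"))
  method <- match.arg(method)
  spec <- study$mediators[[k]]
  if (is.null(spec)) {
    abort(paste0("undeclared mediator: ", k), class = "pspaf_config_error")
  }
  if (!(k %in% outcome_model$mediators)) {
    abort(paste0("outcome model does not condition on mediator '", k, "'."),
          class = "pspaf_config_error")
  }
  require_d_separated(study, outcome_model$mediators)
  if (spec$kind == "discrete" && method == "shift") {
    if (length(spec$levels) != 2) {
      abort("the mean-shift route applies to binary or continuous mediators.",
            class = "pspaf_config_error")
    }
    # treat the binary mediator numerically: its fitted level-1 probability
    # difference plays the role of the conditional-mean shift, and the
    # outcome model is evaluated linearly between the two levels (a
    # fractional shifted value is a mixture weight, not a covariate value)
    dat <- study$data
    p1 <- predict_mediator_probs(mediator_model, dat, 1)[, 2]
    p0 <- predict_mediator_probs(mediator_model, dat, 0)[, 2]
    base <- as.numeric(dat[[k]] == spec$levels[2])
    vals <- base - dat[[study$exposure]] * (p1 - p0)
    pr <- cbind(1 - vals, vals)
    q <- numeric(nrow(dat))
    for (j in 1:2) {
      nd <- dat
      nd[[k]] <- spec$levels[j]
      q <- q + pr[, j] * predict_response(outcome_model, nd)
    }
  } else {
    q <- pathway_qhat(study, outcome_model, mediator_model, k)
  }
  paf_row("ps_paf", k, plugin_paf(study, q))
}

#' Direct PAF through all non-mediated pathways
#'
#' Plug-in estimator of the relative change in disease prevalence from
#' disabling every pathway from exposure to outcome that does not run
#' through the declared mediators: the joint outcome model is evaluated at
#' exposure 0 with covariates and all mediators at their observed values.
#'
#' @inheritParams paf_pathway
#' @param outcome_model The joint `paf_outcome_model` over all mediators.
#' @return One-row tibble.
#' @export
paf_direct <- function(study, outcome_model) {
  stopifnot(inherits(study, "paf_study"),
            inherits(outcome_model, "paf_outcome_model"))
  nd <- study$data
  nd[[study$exposure]] <- 0
  paf_row("direct", "all", plugin_paf(study, predict_response(outcome_model, nd)))
}

#' Single-mediator direct PAF (Sjolander's direct PAF)
#'
#' Direct PAF relative to one mediating pathway `k`: the outcome model
#' conditions on the exposure, covariates and mediator `k` only, and is
#' evaluated at exposure 0 with mediator `k` at its observed value.
#'
#' @inheritParams paf_pathway
#' @param outcome_model_k Outcome model conditioning on mediator `k` only;
#'   fitted internally (main effects, optional `spline_df`) when `NULL`.
#' @param spline_df Passed to [fit_outcome_model()] when fitting internally.
#' @return One-row tibble.
#' @export
paf_direct_single <- function(study, k, outcome_model_k = NULL,
                              spline_df = NULL) {
  stopifnot(inherits(study, "paf_study"))
  if (is.null(study$mediators[[k]])) {
    abort(paste0("undeclared mediator: ", k), class = "pspaf_config_error")
  }
  if (is.null(outcome_model_k)) {
    outcome_model_k <- fit_outcome_model(study, mediators = k,
                                         spline_df = spline_df)
  }
  if (!identical(sort(outcome_model_k$mediators), sort(k))) {
    abort("`outcome_model_k` must condition on mediator k only.",
          class = "pspaf_config_error")
  }
  nd <- study$data
  nd[[study$exposure]] <- 0
  paf_row("direct_single", k,
          plugin_paf(study, predict_response(outcome_model_k, nd)))
}

# grid over the product law of the discrete mediators at exposure 0; used by
# the total-PAF standardization
discrete_counterfactual_qhat <- function(study, outcome_model, nd,
                                         mediator_models, discrete_names) {
  dat <- study$data
  probs <- map(discrete_names, function(k) {
    predict_mediator_probs(mediator_models[[k]], dat, a = 0)
  })
  names(probs) <- discrete_names
  levels_list <- map(study$mediators[discrete_names], "levels")
  grid <- expand.grid(levels_list, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  q <- numeric(nrow(dat))
  for (g in seq_len(nrow(grid))) {
    ndg <- nd
    wg <- rep(1, nrow(dat))
    for (k in discrete_names) {
      lev <- grid[[k]][g]
      ndg[[k]] <- lev
      wg <- wg * probs[[k]][, match(lev, study$mediators[[k]]$levels)]
    }
    q <- q + wg * predict_response(outcome_model, ndg)
  }
  q
}

#' Total PAF
#'
#' Plug-in estimator of the relative change in disease prevalence if the
#' exposure were absent from the population. The default `"mediated"` route
#' standardises through the joint outcome model evaluated at exposure 0 with
#' every continuous mediator replaced by its shifted values and every
#' discrete mediator integrated over its fitted no-exposure level
#' probabilities (g-formula under d-separated mediators), keeping the total,
#' direct and indirect estimates internally coherent. The `"reduced"` route
#' instead fits `Y ~ A + C` and standardises it at exposure 0, and is
#' offered for comparison.
#'
#' @inheritParams paf_direct
#' @param mediator_models Named list of `paf_mediator_model`s, one per
#'   declared mediator (mediated route only).
#' @param method `"mediated"` (default) or `"reduced"`.
#' @param spline_df Covariate spline settings for the reduced-route refit.
#' @return One-row tibble.
#' @export
paf_total <- function(study, outcome_model = NULL, mediator_models = NULL,
                      method = c("mediated", "reduced"), spline_df = NULL) {
  stopifnot(inherits(study, "paf_study"))
  method <- match.arg(method)
  if (method == "reduced") {
    red <- fit_outcome_model(study, mediators = character(0),
                             spline_df = spline_df)
    nd <- study$data
    nd[[study$exposure]] <- 0
    return(paf_row("total", "all",
                   plugin_paf(study, predict_response(red, nd))))
  }
  stopifnot(inherits(outcome_model, "paf_outcome_model"))
  med_names <- names(study$mediators)
  require_d_separated(study, med_names)
  if (!setequal(outcome_model$mediators, med_names)) {
    abort("the mediated total-PAF route needs the joint outcome model.",
          class = "pspaf_config_error")
  }
  missing_models <- setdiff(med_names, names(mediator_models))
  if (length(missing_models)) {
    abort(paste0("missing mediator model(s): ",
                 paste(missing_models, collapse = ", ")),
          class = "pspaf_config_error")
  }
  nd <- study$data
  nd[[study$exposure]] <- 0
  cont <- med_names[map_chr(study$mediators, "kind") == "continuous"]
  disc <- setdiff(med_names, cont)
  for (k in cont) {
    nd[[k]] <- shifted_mediator_values(study, mediator_models[[k]])
  }
  q <- if (length(disc)) {
    discrete_counterfactual_qhat(study, outcome_model, nd, mediator_models,
                                 disc)
  } else {
    predict_response(outcome_model, nd)
  }
  paf_row("total", "all", plugin_paf(study, q))
}

#' Indirect PAF
#'
#' Defined by subtraction so that it sums with the single-mediator direct
#' PAF to the total PAF: `indirect_k = total - direct_single_k`. No
#' refitting; exact floating-point subtraction of the two supplied results.
#'
#' @param total,direct_single One-row results from [paf_total()] and
#'   [paf_direct_single()].
#' @return One-row tibble.
#' @export
paf_indirect <- function(total, direct_single) {
  stopifnot(identical(total$estimand, "total"),
            identical(direct_single$estimand, "direct_single"))
  paf_row("indirect", direct_single$pathway,
          total$estimate - direct_single$estimate)
}

#' Pathway-specific impact fraction
#'
#' Generalises the PS-PAF to a supplied post-intervention mediator
#' distribution: the no-exposure counterfactual distribution is replaced by
#' the distribution the intervention would produce, given per-record shifted
#' values (continuous mediators) or per-record level probabilities (discrete
#' mediators). Supplying the fitted no-exposure distribution recovers the
#' PS-PAF; supplying the observed mediator values gives 0.
#'
#' @inheritParams paf_pathway
#' @param new_values Numeric vector of post-intervention mediator values,
#'   one per record (continuous mediators).
#' @param new_probs Records x levels matrix of post-intervention level
#'   probabilities (discrete mediators).
#' @return One-row tibble with estimand `"impact_fraction"`.
#' @export
impact_fraction <- function(study, outcome_model, k, new_values = NULL,
                            new_probs = NULL) {
  stopifnot(inherits(study, "paf_study"),
            inherits(outcome_model, "paf_outcome_model"))
  spec <- study$mediators[[k]]
  if (is.null(spec)) {
    abort(paste0("undeclared mediator: ", k), class = "pspaf_config_error")
  }
  if (is.null(new_values) == is.null(new_probs)) {
    abort("supply exactly one of `new_values` or `new_probs`.",
          class = "pspaf_contract_error")
  }
  if (!is.null(new_probs) && spec$kind != "discrete") {
    abort("`new_probs` applies to discrete mediators only.",
          class = "pspaf_contract_error")
  }
  q <- pathway_qhat(study, outcome_model, NULL, k, new_values = new_values,
                    new_probs = new_probs)
  paf_row("impact_fraction", k, plugin_paf(study, q))
}

#' Estimate all attributable fractions for a study
#'
#' One-stop pipeline: fits the joint outcome model, one outcome model per
#' single mediator and one mediator model per pathway, then returns the
#' total PAF, the direct PAF through all non-mediated pathways, and for each
#' mediator the single-mediator direct PAF, the indirect PAF (by
#' subtraction) and the pathway-specific PAF.
#'
#' @param study A [paf_study()].
#' @param spline_df Named spline degrees of freedom for continuous terms in
#'   the outcome model (e.g. `c(whr = 5, apob = 5)`).
#' @param outcome_formula,mediator_formulas Optional formula overrides: a
#'   full outcome-model formula and/or a named list of mediator-model
#'   formulas (e.g. saturated specifications).
#' @param single_outcome_formulas Optional named list of formula overrides
#'   for the single-mediator outcome models behind the per-pathway direct
#'   PAFs (only relevant with 2+ mediators).
#' @param total_method Passed to [paf_total()].
#' @param boot Optional [boot_config()]; when supplied the whole pipeline is
#'   bootstrapped and standard errors and confidence intervals are attached.
#' @return A `paf_fit` tibble with one row per (estimand, pathway).
#' @examples
#' model <- sem_toy1()
#' study <- simulate_cohort(model, n = 2000, seed = 1)
#' estimate_paf(study)
#' @export
estimate_paf <- function(study, spline_df = NULL, outcome_formula = NULL,
                         mediator_formulas = list(),
                         single_outcome_formulas = list(),
                         total_method = c("mediated", "reduced"),
                         boot = NULL) {
  stopifnot(inherits(study, "paf_study"))
  total_method <- match.arg(total_method)
  if (!is.null(boot)) {
    return(paf_boot(
      study, config = boot,
      pipeline = function(s) {
        estimate_paf(s, spline_df = spline_df,
                     outcome_formula = outcome_formula,
                     mediator_formulas = mediator_formulas,
                     single_outcome_formulas = single_outcome_formulas,
                     total_method = total_method)
      }))
  }
  med_names <- names(study$mediators)
  require_d_separated(study, med_names)
  joint <- fit_outcome_model(study, spline_df = spline_df,
                             formula = outcome_formula)
  med_models <- map(med_names, function(k) {
    fit_mediator_model(study, k, formula = mediator_formulas[[k]])
  })
  names(med_models) <- med_names

  total <- paf_total(study, joint, med_models, method = total_method,
                     spline_df = spline_df)
  rows <- list(total, paf_direct(study, joint))
  for (k in med_names) {
    om_k <- if (length(med_names) == 1) joint else
      fit_outcome_model(study, mediators = k, spline_df = spline_df,
                        formula = single_outcome_formulas[[k]])
    ds <- paf_direct_single(study, k, outcome_model_k = om_k)
    rows <- c(rows, list(
      ds,
      paf_indirect(total, ds),
      paf_pathway(study, joint, med_models[[k]], k)
    ))
  }
  out <- bind_rows(rows)
  attr(out, "models") <- list(outcome = joint, mediators = med_models)
  attr(out, "design") <- study$design
  class(out) <- c("paf_fit", class(out))
  out
}

#' @export
tidy.paf_fit <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.paf_fit <- function(x, ...) {
  tibble(
    n_estimands = nrow(x),
    n_pathways = length(setdiff(unique(x$pathway), "all")),
    design = attr(x, "design")$kind %||% NA_character_,
    bootstrapped = "se" %in% names(x)
  )
}

#' Bar chart of estimated attributable fractions
#'
#' @param object A `paf_fit` tibble from [estimate_paf()] or [paf_boot()].
#' @param ... Unused.
#' @return A ggplot object; error bars are drawn when bootstrap confidence
#'   intervals are present.
#' @export
autoplot.paf_fit <- function(object, ...) {
  dat <- as_tibble(object) %>%
    mutate(label = ifelse(pathway == "all", estimand,
                          paste0(estimand, " [", pathway, "]")))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = label, y = estimate,
                                         fill = estimand)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "attributable fraction") +
    ggplot2::theme_minimal()
  if (all(c("ci_low", "ci_high") %in% names(dat))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = ci_low, ymax = ci_high), width = 0.25)
  }
  p
}

#' @export
plot.paf_fit <- function(x, ...) print(autoplot(x, ...))

#' Write estimation results to CSV and JSON
#'
#' @param fit A `paf_fit` tibble.
#' @param csv,json Optional output paths.
#' @return `fit`, invisibly.
#' @export
write_paf_results <- function(fit, csv = NULL, json = NULL) {
  if (!is.null(csv)) readr::write_csv(as_tibble(fit), csv)
  if (!is.null(json)) {
    jsonlite::write_json(as_tibble(fit), json, digits = NA, auto_unbox = TRUE)
  }
  invisible(fit)
}
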