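#' Study designs
#'
#' A study design records how the analysed records were sampled from the
#' source population. Cohort and cross-sectional samples are taken as
#' representative (all record weights equal 1). A frequency-matched
#' case-control sample with matching ratio 1:`matching_ratio` is mapped back
#' to the source population by upweighting controls by `(1/prevalence - 1) /
#' matching_ratio`, with cases keeping weight 1.
#'
#' @param kind One of `"cohort"`, `"cross_sectional"`, `"case_control"`.
#' @param prevalence Disease prevalence (or incidence for rare outcomes)
#'   `pi` in (0, 1); required for case-control designs.
#' @param matching_ratio Controls per case `r >= 1`; required for
#'   case-control designs.
#' @return A `study_design` object.
#' @examples
#' design_cohort()
#' design_case_control(prevalence = 0.0035, matching_ratio = 1)
#' @export
study_design <- function(kind = c("cohort", "cross_sectional", "case_control"),
                         prevalence = NULL, matching_ratio = NULL) {
  kind <- match.arg(kind)
  if (kind == "case_control") {
    if (is.null(prevalence) || is.null(matching_ratio)) {
      abort("case-control designs require `prevalence` and `matching_ratio`.",
            class = "pspaf_config_error")
    }
    if (!is.numeric(prevalence) || length(prevalence) != 1 ||
        prevalence <= 0 || prevalence >= 1) {
      abort("`prevalence` must be a single number in (0, 1).",
            class = "pspaf_config_error")
    }
    if (!is.numeric(matching_ratio) || length(matching_ratio) != 1 ||
        matching_ratio < 1) {
      abort("`matching_ratio` must be a single number >= 1.",
            class = "pspaf_config_error")
    }
  } else if (!is.null(prevalence) || !is.null(matching_ratio)) {
    abort("`prevalence`/`matching_ratio` only apply to case-control designs.",
          class = "pspaf_config_error")
  }
  structure(
    list(kind = kind, prevalence = prevalence, matching_ratio = matching_ratio),
    class = "study_design"
  )
}

#' @rdname study_design
#' @export
design_cohort <- function() study_design("cohort")

#' @rdname study_design
#' @export
design_cross_sectional <- function() study_design("cross_sectional")

#' @rdname study_design
#' @export
design_case_control <- function(prevalence, matching_ratio = 1) {
  study_design("case_control", prevalence = prevalence,
               matching_ratio = matching_ratio)
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>", x$kind, "\n")
  if (x$kind == "case_control") {
    cat("  prevalence:", x$prevalence,
        " matching 1:", x$matching_ratio,
        " control weight:", format(control_weight(x)), "\n")
  }
  invisible(x)
}

control_weight <- function(design) {
  (1 / design$prevalence - 1) / design$matching_ratio
}

#' Per-record sampling weights for a study design
#'
#' Cohort and cross-sectional records get weight 1. In a 1:r case-control
#' sample with known disease prevalence `pi`, cases get weight 1 and controls
#' `(1/pi - 1)/r`, so that weighted summaries of the sample estimate their
#' source-population counterparts.
#'
#' @param outcome Binary 0/1 outcome vector (1 = case).
#' @param design A [study_design()].
#' @return Numeric weight vector, one per record, all positive.
#' @examples
#' compute_weights(c(1, 0, 0), design_case_control(0.1, matching_ratio = 4))
#' @export
compute_weights <- function(outcome, design) {
  stopifnot(inherits(design, "study_design"))
  check_binary(outcome, "outcome")
  if (design$kind != "case_control") {
    return(rep(1, length(outcome)))
  }
  ifelse(outcome == 1, 1, control_weight(design))
}

#' Declare a mediator column
#'
#' Each mediator on a pathway of interest is declared by name and kind.
#' Discrete mediators carry their full set of levels; continuous mediators
#' are modelled through a conditional-mean regression. `d_separated`
#' asserts the mediator lies on its own causal pathway, d-separated from the
#' other declared mediators given exposure and covariates; the multi-mediator
#' estimators require this for every mediator.
#'
#' @param name Column name.
#' @param kind `"continuous"` or `"discrete"`.
#' @param levels For discrete mediators, the ordered vector of possible
#'   values (at least 2).
#' @param d_separated Logical assertion of pathway separation (default TRUE).
#' @return A `mediator_spec` object.
#' @examples
#' mediator_discrete("hbp", levels = c(0, 1))
#' mediator_continuous("whr")
#' @export
mediator_spec <- function(name, kind = c("continuous", "discrete"),
                          levels = NULL, d_separated = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1)
  if (kind == "discrete") {
    if (is.null(levels) || length(levels) < 2) {
      abort(paste0("discrete mediator '", name, "' needs >= 2 levels."),
            class = "pspaf_config_error")
    }
    if (anyDuplicated(levels)) {
      abort(paste0("duplicate levels for mediator '", name, "'."),
            class = "pspaf_config_error")
    }
  } else if (!is.null(levels)) {
    abort("`levels` only applies to discrete mediators.",
          class = "pspaf_config_error")
  }
  structure(
    list(name = name, kind = kind, levels = levels,
         d_separated = isTRUE(d_separated)),
    class = "mediator_spec"
  )
}

#' @rdname mediator_spec
#' @export
mediator_continuous <- function(name, d_separated = TRUE) {
  mediator_spec(name, "continuous", d_separated = d_separated)
}

#' @rdname mediator_spec
#' @export
mediator_discrete <- function(name, levels, d_separated = TRUE) {
  mediator_spec(name, "discrete", levels = levels, d_separated = d_separated)
}

#' @export
print.mediator_spec <- function(x, ...) {
  cat("<mediator_spec>", x$name, "(", x$kind,
      if (x$kind == "discrete") paste0("; levels: ",
                                       paste(x$levels, collapse = ", ")),
      ")\n")
  invisible(x)
}

check_binary <- function(x, what) {
  bad <- unique(x[!(x %in% c(0, 1))])
  if (length(bad) > 0) {
    abort(paste0("`", what, "` must be 0/1; found value(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "pspaf_validation_error")
  }
  invisible(TRUE)
}

#' Assemble an analysis-ready attributable-fraction study
#'
#' Validates the raw records, drops incomplete rows, attaches design weights
#' and returns the container every estimator in the package consumes. Columns
#' not named in a role are dropped. Character or factor covariates are
#' re-encoded as factors with levels in sorted order (the first sorted level
#' is the reference in model matrices).
#'
#' @param data Data frame of individual records.
#' @param outcome,exposure Column names of the binary 0/1 outcome and
#'   exposure.
#' @param mediators A [mediator_spec()] or list of them.
#' @param covariates Character vector of baseline covariate columns
#'   (default none).
#' @param design A [study_design()]; default cohort.
#' @param weight_fitting Should design weights also be used when fitting the
#'   nuisance regressions (default TRUE), or only in the estimator averages?
#' @return A `paf_study` object: list with the cleaned `data` tibble
#'   (including a `.w` weight column), role names, mediator specs, design,
#'   and the count of dropped incomplete records.
#' @examples
#' d <- data.frame(y = c(0, 1, 0, 1), a = c(0, 0, 1, 1), m = c(1.2, 0.8, 2, 1.5))
#' paf_study(d, outcome = "y", exposure = "a",
#'           mediators = mediator_continuous("m"))
#' @export
paf_study <- function(data, outcome, exposure, mediators,
                      covariates = character(), design = design_cohort(),
                      weight_fitting = TRUE) {
  stopifnot(is.data.frame(data), inherits(design, "study_design"))
  if (inherits(mediators, "mediator_spec")) mediators <- list(mediators)
  if (!length(mediators) ||
      !all(map_lgl(mediators, inherits, "mediator_spec"))) {
    abort("`mediators` must be one or more mediator_spec objects.",
          class = "pspaf_config_error")
  }
  med_names <- map_chr(mediators, "name")
  names(mediators) <- med_names
  used <- c(outcome, exposure, covariates, med_names)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")),
          class = "pspaf_config_error")
  }
  if (anyDuplicated(used)) {
    abort("a column may hold only one role.", class = "pspaf_config_error")
  }

  dat <- as_tibble(data)[used]
  keep_rows <- complete.cases(dat)
  n_dropped <- sum(!keep_rows)
  if (n_dropped > 0) {
    inform(paste0("paf_study: dropped ", n_dropped,
                  " record(s) with missing values."))
  }
  dat <- dat[keep_rows, ]
  if (nrow(dat) == 0) {
    abort("no complete records remain.", class = "pspaf_degenerate_error")
  }

  check_binary(dat[[outcome]], outcome)
  check_binary(dat[[exposure]], exposure)
  if (all(dat[[exposure]] == 1) || all(dat[[exposure]] == 0)) {
    abort("need both exposed and unexposed records.",
          class = "pspaf_degenerate_error")
  }
  if (!any(dat[[outcome]] == 1)) {
    abort("need at least one case (outcome == 1).",
          class = "pspaf_degenerate_error")
  }

  for (cv in covariates) {
    if (is.character(dat[[cv]]) || is.factor(dat[[cv]]) ||
        is.logical(dat[[cv]])) {
      dat[[cv]] <- factor(as.character(dat[[cv]]),
                          levels = sort(unique(as.character(dat[[cv]]))))
    }
  }
  for (spec in mediators) {
    x <- dat[[spec$name]]
    if (spec$kind == "discrete") {
      stray <- unique(x[!(x %in% spec$levels)])
      if (length(stray)) {
        abort(paste0("mediator '", spec$name, "' has value(s) outside its ",
                     "declared levels: ", paste(head(stray, 5), collapse = ", ")),
              class = "pspaf_validation_error")
      }
    } else if (!is.numeric(x)) {
      abort(paste0("continuous mediator '", spec$name, "' must be numeric."),
            class = "pspaf_validation_error")
    }
  }

  dat$.w <- compute_weights(dat[[outcome]], design)

  structure(
    list(
      data = dat,
      outcome = outcome,
      exposure = exposure,
      covariates = covariates,
      mediators = mediators,
      design = design,
      weight_fitting = isTRUE(weight_fitting),
      n_dropped = n_dropped
    ),
    class = "paf_study"
  )
}

#' @export
print.paf_study <- function(x, ...) {
  cat("<paf_study> ", nrow(x$data), " records (", x$n_dropped, " dropped), ",
      sum(x$data[[x$outcome]] == 1), " cases; design: ", x$design$kind, "\n",
      sep = "")
  cat("  outcome:", x$outcome, " exposure:", x$exposure, "\n")
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  mediators:",
      paste(map_chr(x$mediators,
                    ~ paste0(.x$name, " (", .x$kind, ")")), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
glance.paf_study <- function(x, ...) {
  tibble(
    n = nrow(x$data),
    n_cases = sum(x$data[[x$outcome]] == 1),
    n_exposed = sum(x$data[[x$exposure]] == 1),
    n_dropped = x$n_dropped,
    design = x$design$kind,
    weight_min = min(x$data$.w),
    weight_max = max(x$data$.w),
    weighted_case_fraction =
      sum(x$data$.w * x$data[[x$outcome]]) / sum(x$data$.w)
  )
}

#' Validation report for a study
#'
#' Record counts, dropped-row count and a weight summary, as a list ready for
#' JSON serialisation.
#'
#' @param study A [paf_study()].
#' @return A list.
#' @export
validation_report <- function(study) {
  stopifnot(inherits(study, "paf_study"))
  g <- glance(study)
  list(
    n_records = g$n, n_cases = g$n_cases, n_exposed = g$n_exposed,
    n_dropped = g$n_dropped, design = g$design,
    weights = list(min = g$weight_min, max = g$weight_max,
                   sum = sum(study$data$.w)),
    weighted_case_fraction = g$weighted_case_fraction
  )
}

# rebuild a study from resampled rows, recomputing weights from the design
rebuild_study <- function(study, rows) {
  dat <- study$data[rows, , drop = FALSE]
  dat$.w <- compute_weights(dat[[study$outcome]], study$design)
  out <- study
  out$data <- dat
  out
}
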