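# Bootstrap standard errors and confidence intervals. Every replicate
# resamples records, recomputes design weights and refits all nuisance
# models before re-running the estimation pipeline.

#' Bootstrap configuration
#'
#' @param n_boot Number of bootstrap replicates (>= 2; default 200).
#' @param seed Integer master seed; per-replicate seeds are drawn from it
#'   (one `sample.int` stream, replicate b uses the b-th drawn seed), so the
#'   full set of replicates is reproducible.
#' @param stratified Resample cases and controls separately, preserving
#'   their counts. `NULL` (default) means TRUE for case-control designs and
#'   FALSE otherwise.
#' @param ci `"normal"` (default; estimate +/- 1.96 SE at the 95% level) or
#'   `"percentile"`.
#' @param level Confidence level (default 0.95).
#' @return A `boot_config` object.
#' @export
boot_config <- function(n_boot = 200, seed = 1, stratified = NULL,
                        ci = c("normal", "percentile"), level = 0.95) {
  ci <- match.arg(ci)
  if (!is.numeric(n_boot) || n_boot < 2) {
    abort("`n_boot` must be >= 2.", class = "pspaf_config_error")
  }
  structure(
    list(n_boot = as.integer(n_boot), seed = as.integer(seed),
         stratified = stratified, ci = ci, level = level),
    class = "boot_config"
  )
}

boot_indices <- function(study, stratified) {
  y <- study$data[[study$outcome]]
  n <- length(y)
  if (stratified) {
    cases <- which(y == 1)
    controls <- which(y == 0)
    c(sample(cases, length(cases), replace = TRUE),
      sample(controls, length(controls), replace = TRUE))
  } else {
    sample.int(n, n, replace = TRUE)
  }
}

#' Bootstrap an estimation pipeline
#'
#' Runs `pipeline` on the study to get point estimates, then on `n_boot`
#' resampled studies (weights recomputed from the design each time, all
#' models refitted) to get standard errors and confidence intervals.
#' Replicates in which any model fails are dropped and counted; if more
#' than 10% fail a warning is attached to the result.
#'
#' @param study A [paf_study()].
#' @param pipeline Function taking a `paf_study` and returning a tibble with
#'   columns `estimand`, `pathway`, `estimate` (default [estimate_paf()]).
#' @param config A [boot_config()].
#' @return A `paf_fit` tibble with `estimate`, `se`, `ci_low`, `ci_high`,
#'   `n_boot` columns; the replicate matrix is attached as attribute
#'   `"replicates"`.
#' @export
paf_boot <- function(study, pipeline = estimate_paf, config = boot_config()) {
  stopifnot(inherits(study, "paf_study"), inherits(config, "boot_config"))
  stratified <- config$stratified %||%
    (study$design$kind == "case_control")

  point <- pipeline(study)
  key <- paste(point$estimand, point$pathway, sep = "|")

  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max, config$n_boot))
  reps <- matrix(NA_real_, nrow = config$n_boot, ncol = nrow(point),
                 dimnames = list(NULL, key))
  n_failed <- 0L
  for (b in seq_len(config$n_boot)) {
    res <- withr::with_seed(seeds[b], {
      rows <- boot_indices(study, stratified)
      tryCatch(pipeline(rebuild_study(study, rows)),
               error = function(e) NULL)
    })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      reps[b, paste(res$estimand, res$pathway, sep = "|")] <- res$estimate
    }
  }
  n_ok <- config$n_boot - n_failed
  if (n_ok == 0) {
    abort("all bootstrap replicates failed.", class = "pspaf_inference_error")
  }
  if (n_failed > 0.1 * config$n_boot) {
    warn(paste0(n_failed, " of ", config$n_boot,
                " bootstrap replicates failed; standard errors may be ",
                "unreliable."))
  }

  se <- apply(reps, 2, sd, na.rm = TRUE)
  out <- point
  out$se <- unname(se[key])
  z <- if (identical(config$level, 0.95)) 1.96 else
    qnorm((1 + config$level) / 2)
  if (config$ci == "normal") {
    out$ci_low <- out$estimate - z * out$se
    out$ci_high <- out$estimate + z * out$se
  } else {
    alpha <- (1 - config$level) / 2
    qs <- apply(reps, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
    out$ci_low <- unname(qs[1, key])
    out$ci_high <- unname(qs[2, key])
  }
  out$n_boot <- n_ok
  attr(out, "replicates") <- reps
  attr(out, "n_failed") <- n_failed
  attr(out, "design") <- study$design
  if (!inherits(out, "paf_fit")) class(out) <- c("paf_fit", class(out))
  out
}
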