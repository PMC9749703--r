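# Structural-equation simulator and ground-truth oracle. Models are
# non-parametric structural equations with independent errors (NPSEM-IE):
# each node is a deterministic function of its parents and one independent
# uniform noise term (inverse-cdf construction for discrete nodes).
# Counterfactual worlds are evaluated by substituting interventions into the
# assignment functions while sharing the noise across worlds, so all the
# counterfactual functionals behind total, direct, indirect and
# pathway-specific attributable fractions are available exactly (finite
# support) or by seeded Monte Carlo.

#' Declare a structural-equation node
#'
#' Discrete nodes carry a finite `levels` vector and either a conditional
#' probability table `cpt` or a probability function `prob`; the node's
#' value is the inverse cdf of its conditional distribution applied to its
#' uniform noise. Continuous nodes carry `rfun`, a quantile-style assignment
#' `function(parents, u)` mapping the parent values (data frame) and uniform
#' noise to the node's value.
#'
#' @param name Node (column) name.
#' @param parents Names of parent nodes; must precede this node in the
#'   model's node list.
#' @param levels Finite support (discrete nodes).
#' @param prob For discrete nodes: a `function(parents)` returning a matrix
#'   of level probabilities (rows = records, columns = levels), or a plain
#'   probability vector for root nodes.
#' @param cpt For discrete nodes: data frame with one column per parent and
#'   probability columns `p1 ... pL` (one per level), one row per parent
#'   configuration.
#' @param rfun For continuous nodes: `function(parents, u)`.
#' @param as_factor Treat the simulated column as a categorical covariate
#'   when building studies.
#' @return A `sem_node`.
#' @examples
#' sem_node("a", levels = c(0, 1), prob = c(0.5, 0.5))
#' sem_node("m", parents = "a", levels = c(0, 1),
#'          prob = function(p) cbind(1 - (0.2 + 0.6 * p$a), 0.2 + 0.6 * p$a))
#' @export
sem_node <- function(name, parents = character(), levels = NULL, prob = NULL,
                     cpt = NULL, rfun = NULL, as_factor = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.null(levels)) {
    if (length(levels) < 2 || anyDuplicated(levels)) {
      abort(paste0("node '", name, "': levels must be >= 2 distinct values."),
            class = "pspaf_config_error")
    }
    if (is.null(prob) && is.null(cpt)) {
      abort(paste0("node '", name, "': supply `prob` or `cpt`."),
            class = "pspaf_config_error")
    }
    if (!is.null(cpt)) {
      pcols <- paste0("p", seq_along(levels))
      if (!all(c(parents, pcols) %in% names(cpt))) {
        abort(paste0("node '", name, "': cpt needs columns ",
                     paste(c(parents, pcols), collapse = ", ")),
              class = "pspaf_config_error")
      }
    }
    if (is.numeric(prob)) {
      if (length(parents)) {
        abort(paste0("node '", name,
                     "': vector `prob` only allowed for root nodes."),
              class = "pspaf_config_error")
      }
      if (length(prob) != length(levels)) {
        abort(paste0("node '", name, "': `prob` length must match levels."),
              class = "pspaf_config_error")
      }
    }
  } else if (is.null(rfun)) {
    abort(paste0("node '", name,
                 "': continuous nodes need an assignment function `rfun`."),
          class = "pspaf_config_error")
  }
  structure(
    list(name = name, parents = parents, levels = levels, prob = prob,
         cpt = cpt, rfun = rfun, as_factor = isTRUE(as_factor)),
    class = "sem_node"
  )
}

node_is_discrete <- function(node) !is.null(node$levels)

# level probabilities for each row of `parents` (data frame, possibly 0 cols)
node_probs <- function(node, parents, n) {
  L <- length(node$levels)
  if (!is.null(node$cpt)) {
    if (length(node$parents)) {
      key_data <- do.call(paste, c(parents[node$parents], sep = "\r"))
      key_cpt <- do.call(paste, c(node$cpt[node$parents], sep = "\r"))
      idx <- match(key_data, key_cpt)
      if (anyNA(idx)) {
        abort(paste0("node '", node$name,
                     "': parent configuration missing from cpt."),
              class = "pspaf_config_error")
      }
    } else {
      idx <- rep(1L, n)
    }
    pr <- as.matrix(node$cpt[idx, paste0("p", seq_len(L)), drop = FALSE])
  } else if (is.function(node$prob)) {
    pr <- node$prob(parents)
    if (is.null(dim(pr))) pr <- matrix(pr, ncol = L)
  } else {
    pr <- matrix(node$prob, nrow = n, ncol = L, byrow = TRUE)
  }
  if (nrow(pr) != n || ncol(pr) != L) {
    abort(paste0("node '", node$name, "': probability matrix has wrong shape."),
          class = "pspaf_config_error")
  }
  if (any(pr < -1e-12) || any(pr > 1 + 1e-12) ||
      any(abs(rowSums(pr) - 1) > 1e-8)) {
    abort(paste0("node '", node$name,
                 "': probabilities must be in [0,1] and rows sum to 1."),
          class = "pspaf_config_error")
  }
  unname(pr)
}

#' Assemble a structural model
#'
#' @param nodes List of [sem_node()]s in topological order (each node's
#'   parents must come earlier; the causal order C, A, M, Y of the assumed
#'   graph).
#' @param exposure,outcome Names of the binary exposure and outcome nodes
#'   (both must have levels `c(0, 1)`).
#' @param mediators Names of the mediator nodes.
#' @param covariates Baseline covariate nodes; defaults to all remaining
#'   nodes.
#' @param p_y Optional known marginal outcome probability (used as the
#'   case-control design prevalence when the model cannot be enumerated).
#' @return A `structural_model` with a `mediator_structure` flag:
#'   `"d_separated"` when no mediator is a parent of another, otherwise
#'   `"sequential"`.
#' @examples
#' sem_toy1()
#' @export
structural_model <- function(nodes, exposure, outcome, mediators,
                             covariates = NULL, p_y = NULL) {
  names(nodes) <- map_chr(nodes, "name")
  seen <- character(0)
  for (nd in nodes) {
    stray <- setdiff(nd$parents, seen)
    if (length(stray)) {
      abort(paste0("node '", nd$name, "': parent(s) ",
                   paste(stray, collapse = ", "),
                   " do not precede it (model must be acyclic and in ",
                   "topological order)."),
            class = "pspaf_config_error")
    }
    seen <- c(seen, nd$name)
  }
  for (role in c(exposure, outcome, mediators)) {
    if (!role %in% names(nodes)) {
      abort(paste0("role column '", role, "' is not a node."),
            class = "pspaf_config_error")
    }
  }
  for (role in c(exposure, outcome)) {
    if (!identical(as.numeric(nodes[[role]]$levels), c(0, 1))) {
      abort(paste0("'", role, "' must be binary with levels c(0, 1)."),
            class = "pspaf_config_error")
    }
  }
  if (any(map_lgl(nodes, ~ outcome %in% .x$parents))) {
    abort("the outcome cannot be a parent of another node.",
          class = "pspaf_config_error")
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(nodes), c(exposure, outcome, mediators))
  }
  sequential <- any(map_lgl(nodes[mediators],
                            ~ any(mediators %in% .x$parents)))
  structure(
    list(nodes = nodes, exposure = exposure, outcome = outcome,
         mediators = mediators, covariates = covariates,
         mediator_structure = if (sequential) "sequential" else "d_separated",
         p_y = p_y),
    class = "structural_model"
  )
}

#' @export
print.structural_model <- function(x, ...) {
  cat("<structural_model> ", length(x$nodes), " nodes (",
      x$mediator_structure, " mediators)\n", sep = "")
  for (nd in x$nodes) {
    role <- if (nd$name == x$exposure) "exposure"
    else if (nd$name == x$outcome) "outcome"
    else if (nd$name %in% x$mediators) "mediator"
    else "covariate"
    cat("  ", nd$name, " <- {", paste(nd$parents, collapse = ", "), "} [",
        if (node_is_discrete(nd)) paste0("discrete ", length(nd$levels))
        else "continuous", "; ", role, "]\n", sep = "")
  }
  invisible(x)
}

# Evaluate one world: `U` is the noise matrix (columns named by node),
# `fix` fixes node values outright (cross-world substitutions), and
# `a_input` overrides the exposure value *seen by* specific child nodes.
eval_world <- function(model, U, fix = list(), a_input = list()) {
  n <- nrow(U)
  vals <- list()
  for (nd in model$nodes) {
    nm <- nd$name
    if (!is.null(fix[[nm]])) {
      vals[[nm]] <- rep_len(fix[[nm]], n)
      next
    }
    parents <- if (length(nd$parents)) {
      as.data.frame(vals[nd$parents], optional = TRUE)
    } else {
      as.data.frame(matrix(nrow = n, ncol = 0))
    }
    ov <- a_input[[nm]]
    if (!is.null(ov) && model$exposure %in% nd$parents) {
      parents[[model$exposure]] <- ov
    }
    u <- U[, nm]
    if (node_is_discrete(nd)) {
      pr <- node_probs(nd, parents, n)
      idx <- rep(1L, n)
      acc <- pr[, 1]
      for (j in seq_len(ncol(pr) - 1)) {
        idx <- idx + (u > acc)
        acc <- acc + pr[, j + 1]
      }
      vals[[nm]] <- nd$levels[idx]
    } else {
      vals[[nm]] <- nd$rfun(parents, u)
    }
  }
  as_tibble(vals)
}

# noise partition for exact enumeration: within each interval of [0,1] the
# node's inverse-cdf value is constant for every parent configuration, so a
# representative noise point plus the interval length is exact
enum_noise <- function(model) {
  support_size <- prod(map_dbl(model$nodes, ~ length(.x$levels)))
  if (support_size > 1e7) {
    abort("joint support too large to enumerate (> 1e7 configurations).",
          class = "pspaf_resource_error")
  }
  per_node <- map(model$nodes, function(nd) {
    if (!node_is_discrete(nd)) {
      abort(paste0("node '", nd$name, "' is continuous; exact enumeration ",
                   "needs finite support (use mc_oracle instead)."),
            class = "pspaf_unsupported_error")
    }
    grid <- if (length(nd$parents)) {
      expand.grid(map(model$nodes[nd$parents], "levels"),
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) %>%
        setNames(nd$parents)
    } else {
      as.data.frame(matrix(nrow = 1, ncol = 0))
    }
    pr <- node_probs(nd, grid, nrow(grid))
    cums <- t(apply(pr, 1, cumsum))
    breaks <- sort(unique(c(0, 1, as.numeric(cums))))
    breaks <- breaks[breaks >= 0 & breaks <= 1]
    list(rep = (head(breaks, -1) + breaks[-1]) / 2, w = diff(breaks))
  })
  n_cells <- prod(map_dbl(per_node, ~ length(.x$rep)))
  if (n_cells > 2e6) {
    abort("noise partition too large to enumerate.",
          class = "pspaf_resource_error")
  }
  idx <- expand.grid(map(per_node, ~ seq_along(.x$rep)),
                     KEEP.OUT.ATTRS = FALSE)
  U <- mapply(function(pn, i) pn$rep[i], per_node, idx)
  if (is.null(dim(U))) U <- matrix(U, nrow = 1)
  colnames(U) <- names(model$nodes)
  w <- Reduce(`*`, mapply(function(pn, i) pn$w[i], per_node, idx,
                          SIMPLIFY = FALSE))
  list(U = U, w = w)
}

# all children of the exposure get exposure input 0, except `except`
a_zero_inputs <- function(model, except = character(0)) {
  kids <- names(keep(model$nodes, ~ model$exposure %in% .x$parents))
  kids <- setdiff(kids, except)
  setNames(as.list(rep(0, length(kids))), kids)
}

# interventional functional E_{A,C} E_{Mk|A=0,C} P(Y=1|A,C,Mk) computed from
# the observational joint distribution (Eq-5-style identification route,
# deliberately distinct from the counterfactual-world route)
interventional_from_joint <- function(joint, model, k) {
  e <- model$exposure
  y <- model$outcome
  keys <- c(".key", model$covariates)
  j <- joint %>% mutate(.key = 1L)
  p_ac <- j %>%
    group_by(across(all_of(c(keys, e)))) %>%
    summarise(.p_ac = sum(.data$.wt), .groups = "drop")
  p_m0c <- j %>%
    filter(.data[[e]] == 0) %>%
    group_by(across(all_of(c(keys, k)))) %>%
    summarise(.wm = sum(.data$.wt), .groups = "drop_last") %>%
    mutate(.p_m = .data$.wm / sum(.data$.wm)) %>%
    ungroup() %>%
    select(all_of(c(keys, k)), ".p_m")
  p_yacm <- j %>%
    group_by(across(all_of(c(keys, e, k)))) %>%
    summarise(.p_y = sum(.data$.wt * .data[[y]]) / sum(.data$.wt),
              .groups = "drop")
  p_ac %>%
    left_join(p_m0c, by = keys, relationship = "many-to-many") %>%
    left_join(p_yacm, by = c(keys, e, k)) %>%
    summarise(v = sum(.data$.p_ac * .data$.p_m * .data$.p_y)) %>%
    dplyr::pull("v")
}

paf_from <- function(p_y, p_cf) (p_y - p_cf) / p_y

build_oracle <- function(model, worlds, w, p_int, method, n = NA_real_,
                         se_fun = NULL) {
  y <- model$outcome
  p <- function(v) sum(w * v) / sum(w)
  p_y <- p(worlds$natural[[y]])
  fx <- list(
    p_y = p_y,
    p_y0 = p(worlds$a0[[y]]),
    p_direct_all = p(worlds$direct_all[[y]])
  )
  rows <- list(
    tibble(estimand = "total", pathway = "all",
           value = paf_from(p_y, fx$p_y0)),
    tibble(estimand = "direct", pathway = "all",
           value = paf_from(p_y, fx$p_direct_all))
  )
  for (k in model$mediators) {
    fx[[paste0("p_direct_", k)]] <- p(worlds[[paste0("direct_", k)]][[y]])
    fx[[paste0("p_mechanistic_", k)]] <- p(worlds[[paste0("mech_", k)]][[y]])
    fx[[paste0("p_separable_", k)]] <- p(worlds[[paste0("sep_", k)]][[y]])
    fx[[paste0("p_interventional_", k)]] <- p_int[[k]]
    rows <- c(rows, list(
      tibble(estimand = "direct_single", pathway = k,
             value = paf_from(p_y, fx[[paste0("p_direct_", k)]])),
      tibble(estimand = "indirect", pathway = k,
             value = paf_from(p_y, fx$p_y0) -
               paf_from(p_y, fx[[paste0("p_direct_", k)]])),
      tibble(estimand = "ps_paf", pathway = k,
             value = paf_from(p_y, p_int[[k]])),
      tibble(estimand = "ps_paf_mechanistic", pathway = k,
             value = paf_from(p_y, fx[[paste0("p_mechanistic_", k)]])),
      tibble(estimand = "ps_paf_separable", pathway = k,
             value = paf_from(p_y, fx[[paste0("p_separable_", k)]]))
    ))
  }
  tab <- bind_rows(rows)
  if (!is.null(se_fun)) tab$mc_se <- se_fun(tab)
  structure(
    list(functionals = fx, table = tab, method = method, n = n,
         mediator_structure = model$mediator_structure),
    class = "paf_oracle"
  )
}

#' Exact counterfactual functionals by enumeration
#'
#' For a finite-support model, computes every counterfactual functional by
#' exact summation over a partition of the joint noise space (shared noise
#' across worlds, NPSEM-IE): observed risk, risk under exposure
#' elimination, the direct-pathway risks, and for each mediator the
#' mechanistic and separable pathway-disabling risks. The interventional
#' PS-PAF functional is computed independently through its identification
#' formula on the observational joint distribution, so agreement between
#' the `ps_paf` and `ps_paf_mechanistic` rows is a genuine cross-check of
#' the two routes.
#'
#' @param model A [structural_model()] whose nodes all have finite support.
#' @return A `paf_oracle`: list with `functionals` (named probabilities) and
#'   `table` (tibble of estimand/pathway/value rows).
#' @examples
#' enumerate_oracle(sem_toy1())$table
#' @export
enumerate_oracle <- function(model) {
  stopifnot(inherits(model, "structural_model"))
  noise <- enum_noise(model)
  U <- noise$U
  w <- noise$w
  worlds <- list(
    natural = eval_world(model, U),
    a0 = eval_world(model, U, fix = setNames(list(0), model$exposure)),
    direct_all = eval_world(model, U,
                            a_input = setNames(list(0), model$outcome))
  )
  for (k in model$mediators) {
    worlds[[paste0("direct_", k)]] <- eval_world(
      model, U,
      fix = setNames(list(worlds$natural[[k]]), k),
      a_input = a_zero_inputs(model, except = k))
    worlds[[paste0("mech_", k)]] <- eval_world(
      model, U, fix = setNames(list(worlds$a0[[k]]), k))
    worlds[[paste0("sep_", k)]] <- eval_world(
      model, U, a_input = setNames(list(0), k))
  }
  joint <- worlds$natural %>%
    mutate(.wt = w) %>%
    group_by(across(all_of(names(model$nodes)))) %>%
    summarise(.wt = sum(.data$.wt), .groups = "drop")
  p_int <- map(setNames(model$mediators, model$mediators),
               ~ interventional_from_joint(joint, model, .x))
  build_oracle(model, worlds, w, p_int, method = "enumeration")
}

#' Counterfactual functionals by seeded Monte Carlo
#'
#' Same functionals as [enumerate_oracle()] for models with continuous
#' nodes: shared-noise counterfactual worlds are simulated and averaged.
#' The interventional functional draws the mediator afresh from its
#' no-exposure conditional distribution given the individual's covariates.
#' Each attributable fraction carries a delta-method Monte Carlo standard
#' error.
#'
#' @param model A [structural_model()].
#' @param n Number of Monte Carlo draws (default 1e6).
#' @param seed Integer seed.
#' @return A `paf_oracle` with an `mc_se` column in its table.
#' @export
mc_oracle <- function(model, n = 1e6, seed = 1) {
  stopifnot(inherits(model, "structural_model"))
  node_names <- names(model$nodes)
  y <- model$outcome
  sims <- withr::with_seed(seed, {
    U <- matrix(runif(n * length(node_names)), nrow = n,
                dimnames = list(NULL, node_names))
    fresh <- setdiff(node_names, model$covariates)
    UG <- U
    UG[, fresh] <- runif(n * length(fresh))
    list(U = U, UG = UG)
  })
  U <- sims$U
  worlds <- list(
    natural = eval_world(model, U),
    a0 = eval_world(model, U, fix = setNames(list(0), model$exposure)),
    direct_all = eval_world(model, U,
                            a_input = setNames(list(0), model$outcome))
  )
  g_world <- eval_world(model, sims$UG,
                        fix = setNames(list(0), model$exposure))
  p_int <- list()
  int_y <- list()
  for (k in model$mediators) {
    worlds[[paste0("direct_", k)]] <- eval_world(
      model, U, fix = setNames(list(worlds$natural[[k]]), k),
      a_input = a_zero_inputs(model, except = k))
    worlds[[paste0("mech_", k)]] <- eval_world(
      model, U, fix = setNames(list(worlds$a0[[k]]), k))
    worlds[[paste0("sep_", k)]] <- eval_world(
      model, U, a_input = setNames(list(0), k))
    int_world <- eval_world(model, U, fix = setNames(list(g_world[[k]]), k))
    int_y[[k]] <- int_world[[y]]
    p_int[[k]] <- mean(int_world[[y]])
  }
  ynat <- worlds$natural[[y]]
  paf_se <- function(ycf) {
    S <- stats::cov(cbind(ynat, ycf)) / n
    py <- mean(ynat)
    px <- mean(ycf)
    g <- c(px / py^2, -1 / py)
    sqrt(max(0, as.numeric(t(g) %*% S %*% g)))
  }
  se_fun <- function(tab) {
    map_dbl(seq_len(nrow(tab)), function(i) {
      es <- tab$estimand[i]
      k <- tab$pathway[i]
      switch(es,
        total = paf_se(worlds$a0[[y]]),
        direct = paf_se(worlds$direct_all[[y]]),
        direct_single = paf_se(worlds[[paste0("direct_", k)]][[y]]),
        indirect = sqrt(paf_se(worlds$a0[[y]])^2 +
                          paf_se(worlds[[paste0("direct_", k)]][[y]])^2),
        ps_paf = paf_se(int_y[[k]]),
        ps_paf_mechanistic = paf_se(worlds[[paste0("mech_", k)]][[y]]),
        ps_paf_separable = paf_se(worlds[[paste0("sep_", k)]][[y]])
      )
    })
  }
  build_oracle(model, worlds, rep(1, n), p_int, method = "monte_carlo",
               n = n, se_fun = se_fun)
}

#' @export
print.paf_oracle <- function(x, ...) {
  cat("<paf_oracle> (", x$method,
      if (!is.na(x$n)) paste0(", n = ", format(x$n, big.mark = ",")),
      ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @export
tidy.paf_oracle <- function(x, ...) x$table

#' Check interventional/mechanistic identification equivalence
#'
#' For d-separated mediator structures without post-treatment confounding,
#' the interventional and mechanistic pathway-disabling functionals share
#' one identification formula and must agree; this verifies the enumeration
#' gap is below `tol` and errors otherwise. For sequential structures the
#' (possibly nonzero) gap is reported without assertion.
#'
#' @param model A finite-support [structural_model()].
#' @param tol Equality tolerance (default 1e-12).
#' @return Tibble with one row per mediator: the two functionals, their gap
#'   and whether equivalence is asserted.
#' @export
verify_identification_equivalence <- function(model, tol = 1e-12) {
  oracle <- enumerate_oracle(model)
  rows <- map(model$mediators, function(k) {
    pi_ <- oracle$functionals[[paste0("p_interventional_", k)]]
    pm <- oracle$functionals[[paste0("p_mechanistic_", k)]]
    tibble(pathway = k, p_interventional = pi_, p_mechanistic = pm,
           gap = abs(pi_ - pm),
           asserted = model$mediator_structure == "d_separated")
  })
  out <- bind_rows(rows)
  if (model$mediator_structure == "d_separated" && any(out$gap > tol)) {
    abort(paste0("interventional and mechanistic functionals disagree ",
                 "(max gap ", format(max(out$gap)), ") on a d-separated ",
                 "model; this indicates a modelling inconsistency."),
          class = "pspaf_identification_error")
  }
  out
}

model_mediator_specs <- function(model) {
  d_sep <- model$mediator_structure == "d_separated"
  specs <- map(model$mediators, function(k) {
    nd <- model$nodes[[k]]
    if (node_is_discrete(nd)) {
      mediator_discrete(k, levels = nd$levels, d_separated = d_sep)
    } else {
      mediator_continuous(k, d_separated = d_sep)
    }
  })
  specs
}

as_study <- function(model, dat, design) {
  for (cv in model$covariates) {
    if (model$nodes[[cv]]$as_factor) dat[[cv]] <- factor(dat[[cv]])
  }
  study <- paf_study(dat, outcome = model$outcome, exposure = model$exposure,
                     mediators = model_mediator_specs(model),
                     covariates = model$covariates, design = design)
  attr(study, "model") <- model
  study
}

#' Simulate a cohort from a structural model
#'
#' Draws `n` i.i.d. records from the model's observational distribution and
#' packages them as a cohort [paf_study()] (all weights 1).
#'
#' @param model A [structural_model()].
#' @param n Number of records (>= 1).
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return A `paf_study`.
#' @examples
#' simulate_cohort(sem_toy1(), n = 100, seed = 42)
#' @export
simulate_cohort <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "structural_model"))
  if (n < 1) {
    abort("`n` must be >= 1.", class = "pspaf_config_error")
  }
  dat <- withr::with_seed(seed, {
    U <- matrix(runif(n * length(model$nodes)), nrow = n,
                dimnames = list(NULL, names(model$nodes)))
    eval_world(model, U)
  })
  as_study(model, dat, design_cohort())
}

#' Sample a frequency-matched case-control study from a structural model
#'
#' Draws `n_cases` records from the model's conditional law given disease
#' and `r * n_cases` given no disease (rejection sampling from the
#' observational distribution), and attaches a case-control design whose
#' prevalence is the model's true marginal outcome probability (enumerated
#' when possible, else `model$p_y` or the `prevalence` argument).
#'
#' @param model A [structural_model()].
#' @param n_cases Number of cases.
#' @param r Controls per case (default 1).
#' @param seed Integer seed.
#' @param prevalence Optional prevalence override for the design.
#' @return A `paf_study` with a case-control design and control weights
#'   `(1/prevalence - 1)/r`.
#' @export
sample_case_control <- function(model, n_cases, r = 1, seed = 1,
                                prevalence = NULL) {
  stopifnot(inherits(model, "structural_model"))
  if (n_cases < 1 || r < 1) {
    abort("`n_cases` must be >= 1 and `r` >= 1.",
          class = "pspaf_config_error")
  }
  if (is.null(prevalence)) {
    prevalence <- model$p_y %||%
      tryCatch(enumerate_oracle(model)$functionals$p_y, error = function(e) NULL)
    if (is.null(prevalence)) {
      abort("supply `prevalence` (model has continuous nodes and no p_y).",
            class = "pspaf_config_error")
    }
  }
  n_controls <- round(r * n_cases)
  y <- model$outcome
  dat <- withr::with_seed(seed, {
    cases <- list()
    controls <- list()
    got_cases <- 0
    got_controls <- 0
    while (got_cases < n_cases || got_controls < n_controls) {
      need <- max(n_cases - got_cases, 0) / max(prevalence, 1e-6) +
        max(n_controls - got_controls, 0) / max(1 - prevalence, 1e-6)
      batch <- min(2e6, max(2e4, ceiling(1.2 * need)))
      U <- matrix(runif(batch * length(model$nodes)), nrow = batch,
                  dimnames = list(NULL, names(model$nodes)))
      sim <- eval_world(model, U)
      is_case <- sim[[y]] == 1
      if (got_cases < n_cases) {
        cases <- c(cases, list(sim[is_case, , drop = FALSE]))
        got_cases <- got_cases + sum(is_case)
      }
      if (got_controls < n_controls) {
        controls <- c(controls, list(sim[!is_case, , drop = FALSE]))
        got_controls <- got_controls + sum(!is_case)
      }
    }
    bind_rows(
      head(bind_rows(cases), n_cases),
      head(bind_rows(controls), n_controls)
    )
  })
  as_study(model, dat,
           design_case_control(prevalence = prevalence, matching_ratio = r))
}

#' The canonical three-node Bernoulli test-bed model
#'
#' `A ~ Bern(0.5)`, `M | A ~ Bern(0.2 + 0.6 A)`,
#' `Y | A, M ~ Bern(0.1 + 0.3 A + 0.4 M)`: a fully additive-risk model whose
#' functionals enumerate by hand — observed risk 0.45, risk 0.18 under
#' exposure elimination, total PAF 0.6, direct PAF 1/3, interventional
#' PS-PAF and indirect PAF both 4/15.
#'
#' @return A [structural_model()].
#' @export
sem_toy1 <- function() {
  structural_model(
    nodes = list(
      sem_node("a", levels = c(0, 1), prob = c(0.5, 0.5)),
      sem_node("m", parents = "a", levels = c(0, 1),
               cpt = data.frame(a = c(0, 1), p1 = c(0.8, 0.2),
                                p2 = c(0.2, 0.8))),
      sem_node("y", parents = c("a", "m"), levels = c(0, 1),
               prob = function(p) {
                 pr <- 0.1 + 0.3 * p$a + 0.4 * p$m
                 cbind(1 - pr, pr)
               })
    ),
    exposure = "a", outcome = "y", mediators = "m"
  )
}

#' Random finite-support structural models for property checks
#'
#' Generates a Bernoulli structural model with one binary covariate, a
#' binary exposure, `n_mediators` binary mediators and a binary outcome,
#' with additive-risk assignment functions whose coefficients are drawn
#' uniformly (and rescaled so every probability stays inside (0.02, 0.98)).
#' With `monotone = TRUE` all exposure, mediator and covariate effects are
#' risk-increasing ("monotone-deleterious"); otherwise signs are random.
#' With `sequential = TRUE` the first mediator is a parent of the second
#' (post-treatment confounding structure).
#'
#' @param seed Integer seed.
#' @param n_mediators 1 or 2 (default 1; 2 required when `sequential`).
#' @param monotone All structural effects risk-increasing (default FALSE).
#' @param sequential Chain the mediators (default FALSE).
#' @return A [structural_model()].
#' @export
random_discrete_sem <- function(seed, n_mediators = 1, monotone = FALSE,
                                sequential = FALSE) {
  stopifnot(n_mediators %in% c(1, 2))
  if (sequential && n_mediators != 2) {
    abort("sequential structures need 2 mediators.",
          class = "pspaf_config_error")
  }
  withr::with_seed(seed, {
    # additive-risk assignment p = base + v . effects, with effect sizes and
    # base drawn so every reachable probability stays inside (0.02, 0.98)
    rand_risk <- function(k) {
      sgn <- if (monotone) rep(1, k) else sample(c(-1, 1), k, replace = TRUE)
      e <- sgn * runif(k, 0.03, 0.4 / k)
      neg <- -sum(pmin(e, 0))
      pos <- sum(pmax(e, 0))
      base <- runif(1, 0.03 + neg, 0.97 - pos)
      function(vals) {
        base + as.numeric(as.matrix(vals) %*% e)
      }
    }
    bern <- function(f, pars) {
      force(f)
      force(pars)
      function(p) {
        pr <- f(p[pars])
        cbind(1 - pr, pr)
      }
    }
    meds <- paste0("m", seq_len(n_mediators))
    c_risk <- runif(1, 0.2, 0.8)
    a_node <- sem_node("a", parents = "c0", levels = c(0, 1),
                       prob = bern(rand_risk(1), "c0"))
    med_nodes <- list()
    for (j in seq_len(n_mediators)) {
      pars <- c("a", "c0")
      if (sequential && j == 2) pars <- c(pars, "m1")
      med_nodes[[j]] <- sem_node(meds[j], parents = pars, levels = c(0, 1),
                                 prob = bern(rand_risk(length(pars)), pars))
    }
    y_pars <- c("a", meds, "c0")
    y_node <- sem_node("y", parents = y_pars, levels = c(0, 1),
                       prob = bern(rand_risk(length(y_pars)), y_pars))
    structural_model(
      nodes = c(list(sem_node("c0", levels = c(0, 1),
                              prob = c(1 - c_risk, c_risk)),
                     a_node),
                med_nodes, list(y_node)),
      exposure = "a", outcome = "y", mediators = meds
    )
  })
}
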