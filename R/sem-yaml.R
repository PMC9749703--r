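# YAML serialisation for finite-support structural models (node list,
# parent lists, conditional probability tables) and CSV dataset output
# compatible with the study reader.

#' Read or write a finite-support structural model as YAML
#'
#' The YAML document lists the exposure/outcome/mediator roles and one
#' entry per node with its parents, levels and conditional probability
#' table (one row per parent configuration with a `prob` vector over
#' levels). Only finite-support models are serialisable; writing a model
#' whose discrete nodes use probability functions evaluates them over the
#' parent grid first, and writing continuous nodes is an error.
#'
#' @param path File path.
#' @return `read_sem_yaml` returns a [structural_model()];
#'   `write_sem_yaml` returns `path` invisibly.
#' @export
read_sem_yaml <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("model file not found: ", path), class = "pspaf_io_error")
  }
  doc <- yaml::read_yaml(path)
  for (field in c("exposure", "outcome", "mediators", "nodes")) {
    if (is.null(doc[[field]])) {
      abort(paste0("model yaml is missing field '", field, "'."),
            class = "pspaf_config_error")
    }
  }
  nodes <- map(doc$nodes, function(nd) {
    parents <- as.character(nd$parents %||% character(0))
    levels <- unlist(nd$levels)
    L <- length(levels)
    rows <- map(nd$cpt, function(row) {
      pr <- unlist(row$prob)
      if (length(pr) != L) {
        abort(paste0("node '", nd$name, "': prob vector length != levels."),
              class = "pspaf_config_error")
      }
      vals <- row[parents]
      as.data.frame(c(vals, setNames(as.list(pr), paste0("p", seq_len(L)))))
    })
    sem_node(nd$name, parents = parents, levels = levels,
             cpt = bind_rows(rows), as_factor = isTRUE(nd$as_factor))
  })
  structural_model(nodes, exposure = doc$exposure, outcome = doc$outcome,
                   mediators = unlist(doc$mediators),
                   covariates = unlist(doc$covariates))
}

#' @rdname read_sem_yaml
#' @param model A finite-support [structural_model()].
#' @export
write_sem_yaml <- function(model, path) {
  stopifnot(inherits(model, "structural_model"))
  nodes <- map(unname(model$nodes), function(nd) {
    if (!node_is_discrete(nd)) {
      abort(paste0("node '", nd$name,
                   "' is continuous and cannot be serialised to yaml."),
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
    cpt <- map(seq_len(nrow(grid)), function(i) {
      c(as.list(grid[i, , drop = FALSE]), list(prob = as.numeric(pr[i, ])))
    })
    out <- list(name = nd$name, parents = as.list(nd$parents),
                levels = as.list(nd$levels), cpt = cpt)
    if (nd$as_factor) out$as_factor <- TRUE
    out
  })
  yaml::write_yaml(
    list(exposure = model$exposure, outcome = model$outcome,
         mediators = as.list(model$mediators),
         covariates = as.list(model$covariates), nodes = nodes),
    path, precision = 17)
  invisible(path)
}
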