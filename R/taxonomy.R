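# Three-dimensional classification of selection processes:
#   level     (1 population-level | 2 study-specific)
#   mechanism (1 selection in exposure | 2 selection in population composition)
#   timing    (1 at exposure entry | 2 during exposure | 3 post-outcome)
# Every selection process lands in a cell "L.M.T" of this grid; the
# uni-/multifactorial distinction and canonical epidemiological labels are
# carried as derived annotations rather than as extra axes.

#' Identify selection processes in a causal graph
#'
#' A selection process is a node that receives directed selection arrows:
#' every exposure node with at least one parent (selection in exposure —
#' any arrow ending in initiated, continued or terminated exposure), and
#' every conditioned ("boxed") node (selection in population composition,
#' i.e. conditioning by nature or design). One process is returned per such
#' target, in deterministic order (target time, then id).
#'
#' @param graph A [build_graph()] diagram.
#' @return A list of `selection_process` objects, each with `target`
#'   (node id), `origins` (its parents, canonical order) and
#'   `mediated_by_side_effect` (`TRUE` when some origin descends from an
#'   earlier exposure node, as when a side effect of exposure drives
#'   exposure continuation).
#' @export
identify_processes <- function(graph) {
  nd <- graph$nodes
  is_target <- (nd$role == "exposure" &
                  nd$id %in% graph$edges$head) | nd$conditioned
  targets <- nd$id[is_target]
  targets <- targets[order(nd$time[is_target], targets)]
  exp_nodes <- nd[nd$role == "exposure", , drop = FALSE]
  lapply(targets, function(tg) {
    org <- parents(graph, tg)
    t_tg <- nd$time[nd$id == tg]
    earlier_exp <- exp_nodes$id[exp_nodes$time < t_tg]
    side_desc <- unique(unlist(lapply(earlier_exp, descendants,
                                      graph = graph)))
    med <- any(org %in% setdiff(side_desc, exp_nodes$id))
    structure(list(target = tg, origins = org,
                   mediated_by_side_effect = med),
              class = "selection_process")
  })
}

#' @export
print.selection_process <- function(x, ...) {
  cat(sprintf("selection process: %s <- {%s}%s\n", x$target,
              paste(x$origins, collapse = ", "),
              if (x$mediated_by_side_effect) " (side-effect mediated)" else ""))
  invisible(x)
}

#' Classify a selection process on the three framework dimensions
#'
#' @details
#' The dimensions are decided structurally:
#' * **mechanism** — `in_exposure` when the target is an exposure node
#'   (the arrows change who is exposed without altering the population
#'   boundary); otherwise `in_population_composition` (a boxed node splits
#'   the population itself).
#' * **timing** — `post_outcome` when some origin is an outcome node at an
#'   earlier time (reversed causality, Berkson-type structures);
#'   otherwise `during_exposure` when the graph holds an exposure node
#'   strictly earlier than the target (the process acts on an already
#'   exposed population); otherwise `at_exposure_entry`.
#' * **level** — `study_specific` when the target is flagged as arising
#'   from the study rather than the population.
#'
#' The `factors` annotation is `multifactorial` when at least two distinct
#' origin variables remain after discounting persistence arrows (same
#' variable at an earlier time, e.g. `E0 -> E1`), which carry the exposure
#' history rather than an external selection source.
#'
#' Cell codes `"L.M.T"` use digits level (1 population, 2 study-specific),
#' mechanism (1 exposure, 2 population composition) and timing (1 entry,
#' 2 during, 3 post-outcome).
#'
#' @param process A `selection_process` from [identify_processes()].
#' @param graph The graph that produced it.
#' @return A `classification` object: list with `level`, `mechanism`,
#'   `timing`, `factors`, `cell_code` and `label` (canonical synonym if the
#'   graph matches a registry template, otherwise empty).
#' @export
classify <- function(process, graph) {
  nd <- graph$nodes
  if (!process$target %in% nd$id ||
      !setequal(process$origins, parents(graph, process$target)))
    sp_stop("process does not belong to this graph", "selproc_mismatch")
  tgt <- node_row(graph, process$target)

  mechanism <- if (tgt$role == "exposure") "in_exposure"
               else "in_population_composition"

  org <- nd[match(process$origins, nd$id), , drop = FALSE]
  exp_times <- nd$time[nd$role == "exposure"]
  if (any(org$role == "outcome" & org$time < tgt$time)) {
    timing <- "post_outcome"
  } else if (length(exp_times) && any(exp_times < tgt$time)) {
    timing <- "during_exposure"
  } else {
    if (!length(exp_times) && tgt$conditioned)
      sp_warn(sprintf(
        "graph has no exposure node; timing for conditioned node '%s' defaults to at_exposure_entry",
        tgt$id), "selproc_no_exposure")
    timing <- "at_exposure_entry"
  }

  level <- if (tgt$study_specific) "study_specific" else "population"

  persistence <- org$variable == tgt$variable & org$time < tgt$time
  n_factors <- length(unique(org$variable[!persistence]))
  factors <- if (n_factors >= 2) "multifactorial" else "unifactorial"

  code <- paste(c(population = 1, study_specific = 2)[level],
                c(in_exposure = 1, in_population_composition = 2)[mechanism],
                c(at_exposure_entry = 1, during_exposure = 2,
                  post_outcome = 3)[timing],
                sep = ".")

  structure(list(level = level, mechanism = mechanism, timing = timing,
                 factors = factors, cell_code = code,
                 label = scenario_label(graph, process$target)),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("cell %s: %s / %s / %s (%s)%s\n", x$cell_code, x$level,
              x$mechanism, x$timing, x$factors,
              if (nzchar(x$label)) paste0(" -- ", x$label) else ""))
  invisible(x)
}

#' Tabulate all selection processes of a graph with their classifications
#'
#' One row per process identified by [identify_processes()], in stable
#' order, with the framework cell code and canonical label (when the graph
#' matches a registry template).
#'
#' @param graph A `causal_graph`.
#' @return A `data.frame` with columns `target`, `origins` (comma-joined),
#'   `mediated_by_side_effect`, `level`, `mechanism`, `timing`, `factors`,
#'   `cell_code`, `label`. Zero rows when the graph holds no selection
#'   process.
#' @export
framework_report <- function(graph) {
  procs <- identify_processes(graph)
  rows <- lapply(procs, function(p) {
    cl <- classify(p, graph)
    data.frame(target = p$target,
               origins = paste(p$origins, collapse = ","),
               mediated_by_side_effect = p$mediated_by_side_effect,
               level = cl$level, mechanism = cl$mechanism,
               timing = cl$timing, factors = cl$factors,
               cell_code = cl$cell_code, label = cl$label,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(target = character(), origins = character(),
                      mediated_by_side_effect = logical(),
                      level = character(), mechanism = character(),
                      timing = character(), factors = character(),
                      cell_code = character(), label = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Structural signature used to recognize registry templates (canonical
# labels are attached by template match, never inferred from arbitrary
# graphs). Time indices are normalized to start at 0 so that shifting all
# windows by a constant does not defeat the match.
graph_signature <- function(graph) {
  nd <- graph$nodes
  t0 <- if (nrow(nd)) min(nd$time) else 0L
  paste(paste(sprintf("%s:%s:%d:%s:%d:%d", nd$variable, nd$role,
                      nd$time - t0, nd$conditioned, nd$conditioned_value,
                      nd$study_specific), collapse = ";"),
        paste(sprintf("%s>%s", graph$edges$tail, graph$edges$head),
              collapse = ";"),
        sep = "|")
}

scenario_label <- function(graph, target) {
  reg <- scenario_signature_registry()
  hit <- reg[[graph_signature(graph)]]
  if (is.null(hit)) return("")
  lbl <- hit[[target]]
  if (is.null(lbl)) "" else lbl
}
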