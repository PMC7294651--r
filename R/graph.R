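# Time-indexed causal DAG with role annotations: the substrate on which
# selection processes are identified, classified and simulated.

NODE_ROLES <- c("exposure", "outcome", "covariate", "unknown_cause",
                "selection", "side_effect")

sp_stop <- function(msg, class) {
  stop(structure(list(message = msg, call = NULL),
                 class = c(class, "selproc_error", "error", "condition")))
}

sp_warn <- function(msg, class) {
  warning(structure(list(message = msg, call = NULL),
                    class = c(class, "selproc_warning", "warning",
                              "condition")))
}

#' Define a node of a time-indexed causal diagram
#'
#' A node is a binary variable at a discrete time window, annotated with the
#' role it plays in the selection framework. Conventionally the id is the
#' base symbol followed by the time index, e.g. `"E1"` for exposure in
#' window 1, matching the usual diagram notation (`E` exposure, `D` disease
#' outcome, `C` known covariate, `U` unknown cause, `S` selection event,
#' `A` side effect).
#'
#' @param id Unique node label, e.g. `"E1"`.
#' @param variable Base variable symbol, e.g. `"E"`. Defaults to `id`
#'   stripped of trailing digits.
#' @param time Non-negative integer time-window index. Defaults to the
#'   trailing digits of `id`.
#' @param role One of `"exposure"`, `"outcome"`, `"covariate"`,
#'   `"unknown_cause"`, `"selection"`, `"side_effect"`.
#' @param conditioned Logical; `TRUE` for a "boxed" node, i.e. one that the
#'   population (conditioning by nature) or the study design conditions on.
#'   Only selection nodes (always) and outcome nodes (the
#'   depletion-of-susceptibles pattern) may be conditioned.
#' @param study_specific Logical; `TRUE` when the process creating this
#'   node's value arises from the study itself rather than the population.
#' @param conditioned_value Value (0 or 1) the boxed node is held at;
#'   defaults to 1 (e.g. "selected", "survived"). Depletion of susceptibles
#'   conditions an early outcome node at 0.
#' @return A one-row `data.frame` suitable for [build_graph()].
#' @seealso [build_graph()]
#' @export
timed_node <- function(id, variable = NULL, time = NULL, role = "covariate",
                       conditioned = FALSE, study_specific = FALSE,
                       conditioned_value = 1L) {
  if (is.null(variable)) variable <- sub("[0-9]+$", "", id)
  if (is.null(time)) {
    digits <- regmatches(id, regexpr("[0-9]+$", id))
    if (length(digits) == 0L)
      sp_stop(sprintf("node '%s': no trailing time index and no `time` given", id),
              "selproc_bad_node")
    time <- as.integer(digits)
  }
  data.frame(id = as.character(id), variable = as.character(variable),
             time = as.integer(time), role = as.character(role),
             conditioned = as.logical(conditioned),
             study_specific = as.logical(study_specific),
             conditioned_value = as.integer(conditioned_value),
             stringsAsFactors = FALSE)
}

normalize_nodes <- function(nodes) {
  if (is.data.frame(nodes)) {
    defaults <- list(role = "covariate", conditioned = FALSE,
                     study_specific = FALSE, conditioned_value = 1L)
    for (nm in names(defaults))
      if (is.null(nodes[[nm]])) nodes[[nm]] <- defaults[[nm]]
    if (is.null(nodes$variable)) nodes$variable <- sub("[0-9]+$", "", nodes$id)
    if (is.null(nodes$time))
      nodes$time <- as.integer(sub("^.*?([0-9]+)$", "\\1", nodes$id))
    return(nodes[, c("id", "variable", "time", "role", "conditioned",
                     "study_specific", "conditioned_value")])
  }
  do.call(rbind, lapply(nodes, function(n) {
    if (is.data.frame(n)) return(n)
    do.call(timed_node, as.list(n))
  }))
}

normalize_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L)
    return(data.frame(tail = character(), head = character(),
                      stringsAsFactors = FALSE))
  if (is.data.frame(edges))
    return(data.frame(tail = as.character(edges$tail),
                      head = as.character(edges$head),
                      stringsAsFactors = FALSE))
  if (is.matrix(edges))
    return(data.frame(tail = as.character(edges[, 1]),
                      head = as.character(edges[, 2]),
                      stringsAsFactors = FALSE))
  data.frame(tail = vapply(edges, function(e) as.character(e[[1]]), ""),
             head = vapply(edges, function(e) as.character(e[[2]]), ""),
             stringsAsFactors = FALSE)
}

#' Build and validate a time-indexed causal graph
#'
#' Assembles nodes and directed edges into a validated acyclic diagram.
#' Node order is canonicalized by (time, variable). Validation enforces:
#' unique ids and unique (variable, time) pairs; known roles; selection
#' nodes conditioned; conditioning allowed only on selection and outcome
#' nodes; edges reference existing nodes, never run backwards in time and
#' never self-loop; the graph is acyclic; at most one exposure variable and
#' one outcome variable (multiple time indices of each are allowed).
#' Same-window edges (`tail.time == head.time`) are permitted with a
#' warning, since simultaneous processes are drawn vertically aligned.
#'
#' @param nodes A `data.frame` with columns `id`, and optionally `variable`,
#'   `time`, `role`, `conditioned`, `study_specific`, `conditioned_value`
#'   (see [timed_node()] for defaults), or a list of [timed_node()] rows.
#' @param edges A two-column `data.frame`/matrix (`tail`, `head`) or a list
#'   of length-2 vectors; may be empty.
#' @return An object of class `causal_graph`: a list with canonical `nodes`
#'   and `edges` data frames.
#' @examples
#' g <- build_graph(
#'   nodes = data.frame(id = c("C0", "E1", "D2"),
#'                      role = c("covariate", "exposure", "outcome")),
#'   edges = list(c("C0", "E1"), c("C0", "D2"), c("E1", "D2")))
#' parents(g, "E1")
#' @export
build_graph <- function(nodes, edges = NULL) {
  nodes <- normalize_nodes(nodes)
  edges <- normalize_edges(edges)

  if (anyDuplicated(nodes$id))
    sp_stop(sprintf("duplicate node id(s): %s",
                    paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")),
            "selproc_duplicate_id")
  vt <- paste(nodes$variable, nodes$time)
  if (anyDuplicated(vt))
    sp_stop(sprintf("duplicate (variable, time) pair(s): %s",
                    paste(unique(vt[duplicated(vt)]), collapse = "; ")),
            "selproc_duplicate_id")
  bad_role <- setdiff(nodes$role, NODE_ROLES)
  if (length(bad_role))
    sp_stop(sprintf("unknown role(s): %s", paste(bad_role, collapse = ", ")),
            "selproc_bad_role")
  if (any(nodes$time < 0))
    sp_stop("time indices must be non-negative", "selproc_bad_node")
  sel_uncond <- nodes$role == "selection" & !nodes$conditioned
  if (any(sel_uncond))
    sp_stop(sprintf("selection node(s) must be conditioned: %s",
                    paste(nodes$id[sel_uncond], collapse = ", ")),
            "selproc_bad_node")
  # conditioning is only meaningful on selection events and on an early
  # outcome (depletion of susceptibles); reject other combinations
  bad_cond <- nodes$conditioned & !(nodes$role %in% c("selection", "outcome"))
  if (any(bad_cond))
    sp_stop(sprintf("conditioned node(s) with role other than selection/outcome: %s",
                    paste(nodes$id[bad_cond], collapse = ", ")),
            "selproc_bad_node")
  if (!all(nodes$conditioned_value %in% c(0L, 1L)))
    sp_stop("conditioned_value must be 0 or 1", "selproc_bad_node")

  for (rl in c("exposure", "outcome")) {
    vars <- unique(nodes$variable[nodes$role == rl])
    if (length(vars) > 1L)
      sp_stop(sprintf("more than one %s variable: %s", rl,
                      paste(vars, collapse = ", ")),
              "selproc_bad_node")
  }

  unknown <- setdiff(c(edges$tail, edges$head), nodes$id)
  if (length(unknown))
    sp_stop(sprintf("edge references unknown node(s): %s",
                    paste(unique(unknown), collapse = ", ")),
            "selproc_unknown_node")
  if (any(edges$tail == edges$head))
    sp_stop("self-edges are not allowed", "selproc_bad_edge")
  t_tail <- nodes$time[match(edges$tail, nodes$id)]
  t_head <- nodes$time[match(edges$head, nodes$id)]
  if (any(t_tail > t_head)) {
    i <- which(t_tail > t_head)[1]
    sp_stop(sprintf("edge %s -> %s runs backwards in time (t=%d -> t=%d)",
                    edges$tail[i], edges$head[i], t_tail[i], t_head[i]),
            "selproc_backward_edge")
  }
  if (any(t_tail == t_head)) {
    i <- which(t_tail == t_head)
    sp_warn(sprintf("same-time-window edge(s): %s",
                    paste(sprintf("%s->%s", edges$tail[i], edges$head[i]),
                          collapse = ", ")),
            "selproc_same_time_edge")
  }
  if (anyDuplicated(paste(edges$tail, edges$head)))
    sp_stop("duplicate edge(s)", "selproc_bad_edge")

  # canonical ordering
  nodes <- nodes[order(nodes$time, nodes$variable), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges)) {
    edges <- edges[order(match(edges$head, nodes$id),
                         match(edges$tail, nodes$id)), , drop = FALSE]
    rownames(edges) <- NULL
  }

  g <- structure(list(nodes = nodes, edges = edges), class = "causal_graph")
  if (!igraph::is_dag(as_igraph(g)))
    sp_stop("graph contains a cycle", "selproc_cycle")
  g
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes$id)
}

node_row <- function(graph, node_id) {
  i <- match(node_id, graph$nodes$id)
  if (is.na(i))
    sp_stop(sprintf("unknown node '%s'", node_id), "selproc_unknown_node")
  graph$nodes[i, , drop = FALSE]
}

canonical_ids <- function(graph, ids) {
  ids[order(match(ids, graph$nodes$id))]
}

#' Graph relations: parents, children, ancestors, descendants
#'
#' Standard directed-graph relations on a [build_graph()] diagram, returned
#' as node ids in canonical (time, variable) order. `ancestors()` and
#' `descendants()` exclude the node itself.
#'
#' @param graph A `causal_graph`.
#' @param node_id A node id present in the graph.
#' @return Character vector of node ids (possibly empty).
#' @export
parents <- function(graph, node_id) {
  node_row(graph, node_id)
  canonical_ids(graph, graph$edges$tail[graph$edges$head == node_id])
}

#' @rdname parents
#' @export
children <- function(graph, node_id) {
  node_row(graph, node_id)
  canonical_ids(graph, graph$edges$head[graph$edges$tail == node_id])
}

reachable <- function(graph, node_id, mode) {
  node_row(graph, node_id)
  ig <- as_igraph(graph)
  ids <- names(igraph::subcomponent(ig, node_id, mode = mode))
  canonical_ids(graph, setdiff(ids, node_id))
}

#' @rdname parents
#' @export
ancestors <- function(graph, node_id) reachable(graph, node_id, "in")

#' @rdname parents
#' @export
descendants <- function(graph, node_id) reachable(graph, node_id, "out")

#' Collider nodes of a causal graph
#'
#' A collider is a node where two or more directed selection mechanisms
#' meet, i.e. a node with in-degree at least 2. Conditioning on a collider
#' induces associations among its causes (collider stratification / index
#' event bias).
#'
#' @param graph A `causal_graph`.
#' @return Character vector of node ids with two or more parents, in
#'   canonical order.
#' @export
colliders <- function(graph) {
  if (!nrow(graph$edges)) return(character())
  indeg <- table(graph$edges$head)
  canonical_ids(graph, names(indeg)[indeg >= 2])
}

topological_order <- function(graph) {
  ord <- names(igraph::topo_sort(as_igraph(graph), mode = "out"))
  # stable: break igraph ties back to canonical order within topo constraint
  ord
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("causal_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  flags <- ifelse(x$nodes$conditioned,
                  sprintf(" [boxed=%d]", x$nodes$conditioned_value), "")
  flags <- paste0(flags, ifelse(x$nodes$study_specific, " [study]", ""))
  cat(sprintf("  %s (t=%d, %s)%s\n", x$nodes$id, x$nodes$time,
              x$nodes$role, flags), sep = "")
  if (nrow(x$edges))
    cat("  edges:", paste(sprintf("%s->%s", x$edges$tail, x$edges$head),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a graph back to its spec representation
#'
#' Inverse of [build_graph()]: the returned list has `nodes` and `edges`
#' entries in the JSON model-spec dialect, so that
#' `build_graph(spec$nodes, spec$edges)` round-trips (up to canonical
#' ordering).
#'
#' @param graph A `causal_graph`.
#' @return A list with `nodes` (data.frame) and `edges` (list of
#'   `c(tail, head)` pairs).
#' @export
graph_spec <- function(graph) {
  list(nodes = graph$nodes,
       edges = if (nrow(graph$edges))
         lapply(seq_len(nrow(graph$edges)),
                function(i) c(graph$edges$tail[i], graph$edges$head[i]))
       else list())
}
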