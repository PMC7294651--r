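# Binary structural causal model over a causal_graph: every node is
# Bernoulli given its parents. Inference is by exact enumeration of the
# joint (all scenarios here have few nodes), so conditioning by nature,
# marginals and expected cohorts are computed without sampling error;
# seeded ancestral sampling provides finite-cohort realizations.

MAX_ENUM_NODES <- 20L

#' Conditional Bernoulli table for one node
#'
#' `p1` gives P(node = 1 | parent configuration) for each of the `2^k`
#' configurations of the `k` parents. Configurations are ordered with the
#' first parent as the most significant bit: for parents `(A, B)` the order
#' is `A=0,B=0`, `A=0,B=1`, `A=1,B=0`, `A=1,B=1`. Alternatively `p1` may be
#' named with configuration labels such as `"A=1,B=0"` (any order), which
#' are matched explicitly.
#'
#' @param node Node id the table belongs to.
#' @param parents Character vector of parent node ids (may be empty).
#' @param p1 Numeric vector of length `2^length(parents)`, values in
#'   `[0, 1]`; optionally named by configuration label.
#' @return A `cond_table` object.
#' @export
cond_table <- function(node, parents = character(), p1) {
  k <- length(parents)
  p1 <- unlist(p1)
  if (length(p1) != 2^k)
    sp_stop(sprintf("table for '%s': expected %d probabilities, got %d",
                    node, 2^k, length(p1)), "selproc_bad_table")
  if (!is.null(names(p1)) && k > 0L && any(nzchar(names(p1)))) {
    idx <- vapply(names(p1), parse_config_key, 0L, parents = parents,
                  node = node)
    if (anyDuplicated(idx))
      sp_stop(sprintf("table for '%s': duplicate configuration keys", node),
              "selproc_bad_table")
    p1 <- p1[order(idx)]
  }
  p1 <- as.numeric(p1)
  if (anyNA(p1) || any(p1 < 0 | p1 > 1))
    sp_stop(sprintf("table for '%s': probabilities must lie in [0, 1]", node),
            "selproc_bad_table")
  structure(list(node = node, parents = as.character(parents), p1 = p1),
            class = "cond_table")
}

# "C0=1,U0=0" -> 1-based index into the p1 vector (first parent = MSB).
# Bare variable symbols are accepted when they identify the parent uniquely.
parse_config_key <- function(key, parents, node) {
  if (length(parents) == 0L) return(1L)
  vals <- integer(length(parents))
  seen <- logical(length(parents))
  parts <- strsplit(gsub("[[:space:]]", "", key), ",", fixed = TRUE)[[1]]
  for (part in parts) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      sp_stop(sprintf("table for '%s': malformed configuration key '%s'",
                      node, key), "selproc_bad_table")
    i <- match(kv[1], parents)
    if (is.na(i)) i <- match(kv[1], sub("[0-9]+$", "", parents))
    if (is.na(i))
      sp_stop(sprintf("table for '%s': key '%s' names no parent", node, key),
              "selproc_bad_table")
    seen[i] <- TRUE
    vals[i] <- as.integer(kv[2])
  }
  if (!all(seen))
    sp_stop(sprintf("table for '%s': key '%s' misses a parent", node, key),
            "selproc_bad_table")
  if (!all(vals %in% 0:1))
    sp_stop(sprintf("table for '%s': key '%s' has non-binary value", node, key),
            "selproc_bad_table")
  k <- length(parents)
  as.integer(1L + sum(vals * 2^((k - 1):0)))
}

#' Assemble a structural causal model
#'
#' Couples a validated [build_graph()] diagram with one [cond_table()] per
#' node and a cohort size. Each table's parent set must equal the node's
#' graph parents (reordered to canonical order automatically).
#'
#' @param graph A `causal_graph`.
#' @param tables Named list (by node id). Each element is a [cond_table()],
#'   or shorthand: a bare numeric (root-node P(node = 1)), or a list with
#'   `parents` and `p1`.
#' @param cohort_size Positive cohort size N (need not be integer; expected
#'   cohorts are real-valued).
#' @return A `structural_model` object.
#' @export
structural_model <- function(graph, tables, cohort_size) {
  if (!inherits(graph, "causal_graph"))
    sp_stop("`graph` must be a causal_graph", "selproc_bad_model")
  if (!is.numeric(cohort_size) || length(cohort_size) != 1L || cohort_size < 0)
    sp_stop("`cohort_size` must be a single non-negative number",
            "selproc_bad_model")
  ids <- graph$nodes$id
  missing <- setdiff(ids, names(tables))
  if (length(missing))
    sp_stop(sprintf("missing conditional table(s) for node(s): %s",
                    paste(missing, collapse = ", ")), "selproc_bad_table")
  tabs <- lapply(ids, function(id) {
    tb <- tables[[id]]
    gp <- parents(graph, id)
    if (is.numeric(tb) && !inherits(tb, "cond_table"))
      tb <- cond_table(id, gp, tb)   # shorthand: p1 in canonical parent order
    else if (!inherits(tb, "cond_table"))
      tb <- cond_table(id, tb$parents %||% character(), tb$p1)
    if (!setequal(tb$parents, gp))
      sp_stop(sprintf(
        "table for '%s' has parents {%s} but the graph gives {%s}", id,
        paste(tb$parents, collapse = ","), paste(gp, collapse = ",")),
        "selproc_bad_table")
    if (!identical(tb$parents, gp)) {
      # reorder p1 to canonical parent order
      k <- length(gp)
      old <- tb$parents
      cfg <- as.matrix(binary_configs(k))  # canonical-order configs
      idx_old <- 1L + cfg[, match(old, gp), drop = FALSE] %*% 2^((k - 1):0)
      tb <- cond_table(id, gp, tb$p1[idx_old])
    }
    tb
  })
  names(tabs) <- ids
  structure(list(graph = graph, tables = tabs,
                 cohort_size = as.numeric(cohort_size)),
            class = "structural_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All 2^k binary configurations as a data.frame in binary-counting order,
# first column most significant.
binary_configs <- function(k, names = NULL) {
  if (k == 0L) return(data.frame(row.names = 1L))
  cols <- lapply(seq_len(k), function(i)
    rep(rep(0:1, each = 2^(k - i)), times = 2^(i - 1)))
  df <- as.data.frame(cols, col.names = names %||% paste0("V", seq_len(k)))
  names(df) <- names %||% paste0("V", seq_len(k))
  df
}

#' @export
print.structural_model <- function(x, ...) {
  cat(sprintf("structural_model: %d binary nodes, cohort_size = %g\n",
              nrow(x$graph$nodes), x$cohort_size))
  print(x$graph)
  invisible(x)
}

joint_table <- function(configs, prob) {
  stopifnot(abs(sum(prob) - 1) < 1e-12)
  structure(cbind(configs, prob = prob),
            class = c("joint_table", "data.frame"))
}

joint_vars <- function(joint) setdiff(names(joint), "prob")

#' Exact joint distribution of a structural model
#'
#' Enumerates all binary configurations and multiplies the factorized
#' conditional probabilities; no sampling is involved, so downstream
#' conditioning and marginalization are exact.
#'
#' @param model A [structural_model()].
#' @return A `joint_table`: data.frame with one 0/1 column per node
#'   (canonical order) plus `prob`, rows in binary-counting order and
#'   summing to 1.
#' @export
enumerate_joint <- function(model) {
  ids <- model$graph$nodes$id
  k <- length(ids)
  if (k > MAX_ENUM_NODES)
    sp_stop(sprintf("exact enumeration capped at %d nodes (model has %d)",
                    MAX_ENUM_NODES, k), "selproc_too_large")
  cfg <- binary_configs(k, ids)
  prob <- rep(1, nrow(cfg))
  for (id in ids) {
    tb <- model$tables[[id]]
    kp <- length(tb$parents)
    idx <- if (kp == 0L) rep(1L, nrow(cfg))
           else 1L + as.vector(as.matrix(cfg[tb$parents]) %*% 2^((kp - 1):0))
    p1 <- tb$p1[idx]
    prob <- prob * ifelse(cfg[[id]] == 1L, p1, 1 - p1)
  }
  joint_table(cfg, prob)
}

resolve_vars <- function(available, vars) {
  vapply(vars, function(v) {
    if (v %in% available) return(v)
    hit <- available[sub("[0-9]+$", "", available) == v]
    if (length(hit) == 1L) return(hit)
    if (length(hit) == 0L)
      sp_stop(sprintf("unknown variable '%s'", v), "selproc_unknown_node")
    sp_stop(sprintf("variable '%s' is ambiguous (matches %s); use a node id",
                    v, paste(hit, collapse = ", ")), "selproc_unknown_node")
  }, "")
}

match_assignment <- function(joint, assignment) {
  if (!length(assignment)) return(rep(TRUE, nrow(joint)))
  ids <- resolve_vars(joint_vars(joint), names(assignment))
  keep <- rep(TRUE, nrow(joint))
  for (i in seq_along(ids))
    keep <- keep & joint[[ids[i]]] == as.integer(assignment[[i]])
  keep
}

#' Condition a joint table on an assignment ("conditioning by nature")
#'
#' Restricts the joint mass to configurations consistent with `assignment`
#' and renormalizes, mirroring population-level conditioning on an event
#' such as survival or disease onset: downstream causal action then occurs
#' only in the selected subpopulation.
#'
#' @param joint A `joint_table` from [enumerate_joint()].
#' @param assignment Named vector/list, names are node ids (or unambiguous
#'   variable symbols), values 0/1. Must have positive probability.
#' @return The conditioned `joint_table` (same variables).
#' @export
condition_joint <- function(joint, assignment) {
  keep <- match_assignment(joint, assignment)
  mass <- sum(joint$prob[keep])
  if (mass <= 0)
    sp_stop("conditioning event has zero probability", "selproc_zero_mass")
  out <- joint
  out$prob <- ifelse(keep, joint$prob / mass, 0)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("joint_table", "data.frame"))
}

#' Marginal distribution over a subset of variables
#'
#' @param joint A `joint_table`.
#' @param vars Variables to keep (ids or unambiguous symbols).
#' @return A `joint_table` over `vars` (original canonical order), rows in
#'   binary-counting order.
#' @export
marginal_joint <- function(joint, vars) {
  ids <- resolve_vars(joint_vars(joint), vars)
  ids <- ids[order(match(ids, joint_vars(joint)))]
  if (!length(ids)) sp_stop("no variables to keep", "selproc_unknown_node")
  cfg <- binary_configs(length(ids), ids)
  key_all <- interaction(joint[ids], drop = FALSE)
  agg <- tapply(joint$prob, key_all, sum, default = 0)
  key_cfg <- interaction(cfg, drop = FALSE)
  joint_table(cfg, as.numeric(agg[as.character(key_cfg)]))
}

#' Probability of an event, optionally conditional
#'
#' @param joint A `joint_table`.
#' @param event Named 0/1 vector/list describing the event.
#' @param given Optional named 0/1 vector/list to condition on.
#' @return A probability in `[0, 1]`.
#' @export
prob_event <- function(joint, event, given = NULL) {
  keep_g <- match_assignment(joint, given %||% list())
  denom <- sum(joint$prob[keep_g])
  if (denom <= 0)
    sp_stop("conditioning event has zero probability", "selproc_zero_mass")
  keep_e <- match_assignment(joint, event)
  sum(joint$prob[keep_e & keep_g]) / denom
}

make_cohort <- function(configs, count, selected, mode, selected_only,
                        conditioned) {
  structure(cbind(configs, count = count, in_population = selected),
            class = c("cohort", "data.frame"), mode = mode,
            selected_only = selected_only, conditioned = conditioned)
}

cohort_conditioned <- function(graph) {
  nd <- graph$nodes[graph$nodes$conditioned, , drop = FALSE]
  stats::setNames(nd$conditioned_value, nd$id)
}

#' Expected cohort of a structural model
#'
#' The deterministic cohort with one row per binary configuration and
#' real-valued count `N * P(configuration)` — the layout of a full
#' cross-classified cohort table.
#'
#' @param model A [structural_model()].
#' @return A `cohort`: data.frame of configurations plus `count` and
#'   `in_population` (all `TRUE` until [apply_selection()]), with
#'   attributes `mode = "expected"` and `selected_only = FALSE`.
#' @export
expected_cohort <- function(model) {
  joint <- enumerate_joint(model)
  cfg <- joint[joint_vars(joint)]
  make_cohort(cfg, model$cohort_size * joint$prob,
              rep(TRUE, nrow(cfg)), "expected", FALSE,
              cohort_conditioned(model$graph))
}

#' Sample a finite cohort by seeded ancestral simulation
#'
#' Draws `n` independent individuals node-by-node in topological order
#' (each node Bernoulli given its sampled parents) using R's default
#' Mersenne-Twister generator seeded with `seed`, so results are exactly
#' reproducible.
#'
#' @param model A [structural_model()].
#' @param n Number of individuals (positive integer).
#' @param seed Integer random seed (required).
#' @return A `cohort` with integer counts over all configurations
#'   (zero-count configurations retained), `mode = "sampled"`.
#' @export
sample_cohort <- function(model, n, seed) {
  if (missing(seed) || is.null(seed))
    sp_stop("`seed` is required for sampling", "selproc_bad_model")
  n <- as.integer(n)
  if (is.na(n) || n <= 0L)
    sp_stop("`n` must be a positive integer", "selproc_bad_model")
  ids <- model$graph$nodes$id
  k <- length(ids)
  if (k > MAX_ENUM_NODES)
    sp_stop(sprintf("sampling capped at %d nodes", MAX_ENUM_NODES),
            "selproc_too_large")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  draws <- matrix(0L, nrow = n, ncol = k, dimnames = list(NULL, ids))
  for (id in topological_order(model$graph)) {
    tb <- model$tables[[id]]
    kp <- length(tb$parents)
    idx <- if (kp == 0L) rep(1L, n)
           else 1L + as.vector(draws[, tb$parents, drop = FALSE] %*%
                                 2^((kp - 1):0))
    draws[, id] <- stats::rbinom(n, 1L, tb$p1[idx])
  }
  cfg <- binary_configs(k, ids)
  idx_all <- 1L + as.vector(draws %*% 2^((k - 1):0))
  counts <- tabulate(idx_all, nbins = 2^k)
  make_cohort(cfg, as.integer(counts), rep(TRUE, nrow(cfg)),
              "sampled", FALSE, cohort_conditioned(model$graph))
}

#' Apply the model's conditioning ("selection") to a cohort
#'
#' Restricts the cohort to configurations where every conditioned node sits
#' at its conditioned value (1 for a selection event; 0 for e.g. survivors
#' of an early outcome in depletion of susceptibles). Expected-mode cohorts
#' drop the filtered rows; sampled-mode cohorts retain them with
#' `in_population = FALSE` so pre-selection truths stay computable.
#'
#' @param cohort A `cohort` with `selected_only = FALSE`.
#' @return The selected `cohort` (`selected_only = TRUE`). A cohort from a
#'   model with no conditioned node is returned unchanged.
#' @export
apply_selection <- function(cohort) {
  if (isTRUE(attr(cohort, "selected_only")))
    sp_stop("selection already applied", "selproc_bad_model")
  cond <- attr(cohort, "conditioned")
  if (!length(cond)) return(cohort)
  keep <- rep(TRUE, nrow(cohort))
  for (id in names(cond)) keep <- keep & cohort[[id]] == cond[[id]]
  if (sum(cohort$count[keep]) <= 0)
    sp_stop("selection removes the entire cohort", "selproc_zero_mass")
  mode <- attr(cohort, "mode")
  if (mode == "expected") {
    out <- cohort[keep, , drop = FALSE]
    rownames(out) <- NULL
    make_cohort(out[setdiff(names(out), c("count", "in_population"))],
                out$count, rep(TRUE, nrow(out)), mode, TRUE, cond)
  } else {
    make_cohort(cohort[setdiff(names(cohort), c("count", "in_population"))],
                cohort$count, keep, mode, TRUE, cond)
  }
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort (%s%s): %d configurations, total count %g\n",
              attr(x, "mode"),
              if (isTRUE(attr(x, "selected_only"))) ", selected" else "",
              nrow(x), sum(x$count[x$in_population])))
  print.data.frame(x, ...)
  invisible(x)
}

cohort_vars <- function(cohort)
  setdiff(names(cohort), c("count", "in_population"))

# rows currently in the population (post-selection membership)
cohort_active <- function(cohort) {
  cohort[cohort$in_population, , drop = FALSE]
}
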