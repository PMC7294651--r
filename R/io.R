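# JSON model-spec dialect and CSV serialization.
#
# Model spec (JSON object):
#   "nodes":  list of {id, variable?, time?, role?, conditioned?,
#             study_specific?, conditioned_value?}  (role defaults
#             "covariate", booleans default false)
#   "edges":  list of [tail, head]
#   "tables": {node: {"parents": [...], "p1": number | {config: p}}}
#             with config keys like "C0=1,U0=0" (bare variable symbols
#             accepted when unambiguous)
#   "cohort_size": N
# "tables"/"cohort_size" may be omitted when only the diagram is needed
# (e.g. for classification).

#' Read a model specification from JSON
#'
#' Parses and fully validates the JSON model-spec dialect. Error messages
#' name the offending field (e.g. `tables.E1`).
#'
#' @param path Path to a JSON file.
#' @return A [structural_model()] when the spec carries `tables` and
#'   `cohort_size`; otherwise the validated [build_graph()] diagram.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path))
    sp_stop(sprintf("file not found: %s", path), "selproc_io")
  spec <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                      simplifyVector = FALSE),
                   error = function(e)
                     sp_stop(sprintf("JSON parse error in %s: %s", path,
                                     conditionMessage(e)), "selproc_io"))
  model_from_spec(spec)
}

#' Build a model (or graph) from a parsed spec list
#'
#' @param spec A list with `nodes`, `edges` and optionally `tables` and
#'   `cohort_size`, as produced by parsing the JSON dialect.
#' @return As [read_model_spec()].
#' @export
model_from_spec <- function(spec) {
  if (is.null(spec$nodes))
    sp_stop("spec is missing 'nodes'", "selproc_io")
  nodes <- do.call(rbind, lapply(seq_along(spec$nodes), function(i) {
    n <- spec$nodes[[i]]
    if (is.null(n$id))
      sp_stop(sprintf("nodes[%d] is missing 'id'", i), "selproc_io")
    timed_node(id = n$id, variable = n$variable, time = n$time,
               role = n$role %||% "covariate",
               conditioned = isTRUE(n$conditioned),
               study_specific = isTRUE(n$study_specific),
               conditioned_value = n$conditioned_value %||% 1L)
  }))
  edges <- lapply(spec$edges %||% list(), function(e) {
    e <- unlist(e)
    if (length(e) != 2L)
      sp_stop("each edge must be a [tail, head] pair", "selproc_io")
    e
  })
  graph <- build_graph(nodes, edges)
  if (is.null(spec$tables)) return(graph)
  if (is.null(spec$cohort_size))
    sp_stop("spec has 'tables' but no 'cohort_size'", "selproc_io")
  tables <- lapply(graph$nodes$id, function(id) {
    tb <- spec$tables[[id]]
    if (is.null(tb))
      sp_stop(sprintf("tables.%s is missing", id), "selproc_io")
    pars <- as.character(unlist(tb$parents %||% character()))
    p1 <- tb$p1
    if (is.null(p1))
      sp_stop(sprintf("tables.%s is missing 'p1'", id), "selproc_io")
    if (is.list(p1)) p1 <- unlist(p1)
    cond_table(id, pars, p1)
  })
  names(tables) <- graph$nodes$id
  structural_model(graph, tables, spec$cohort_size)
}

config_label <- function(parents, idx) {
  k <- length(parents)
  bits <- as.integer(intToBits(idx - 1L))[k:1]
  paste(parents, bits, sep = "=", collapse = ",")
}

#' Serialize a model to the spec list / JSON file
#'
#' Inverse of [read_model_spec()]; `write_model_spec()` writes JSON such
#' that read-back reproduces the model exactly (round-trip identity up to
#' canonical ordering).
#'
#' @param model A [structural_model()] or `causal_graph`.
#' @param path Output path for `write_model_spec()`.
#' @return `model_spec()`: the spec list. `write_model_spec()`: `path`,
#'   invisibly.
#' @export
model_spec <- function(model) {
  graph <- if (inherits(model, "causal_graph")) model else model$graph
  nd <- graph$nodes
  spec <- list(
    nodes = lapply(seq_len(nrow(nd)), function(i)
      list(id = nd$id[i], variable = nd$variable[i], time = nd$time[i],
           role = nd$role[i], conditioned = nd$conditioned[i],
           study_specific = nd$study_specific[i],
           conditioned_value = nd$conditioned_value[i])),
    edges = graph_spec(graph)$edges)
  if (inherits(model, "structural_model")) {
    spec$tables <- lapply(model$tables, function(tb) {
      k <- length(tb$parents)
      if (k == 0L) return(list(parents = list(), p1 = tb$p1))
      list(parents = as.list(tb$parents),
           p1 = stats::setNames(as.list(tb$p1),
                                vapply(seq_len(2^k), config_label, "",
                                       parents = tb$parents)))
    })
    spec$cohort_size <- model$cohort_size
  }
  spec
}

#' @rdname model_spec
#' @export
write_model_spec <- function(model, path) {
  jsonlite::write_json(model_spec(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a cohort as CSV
#'
#' One row per binary configuration in canonical binary-counting order;
#' columns are the variables, the unrounded `count` and the
#' `in_population` membership flag. `read_cohort()` reproduces the counts
#' exactly.
#'
#' @param cohort A `cohort`.
#' @param path File path.
#' @return `write_cohort()`: `path`, invisibly. `read_cohort()`: a
#'   `cohort`.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  # 17 significant digits so that read-back reproduces doubles exactly
  df$count <- sprintf("%.17g", df$count)
  meta <- sprintf("# selproc cohort mode=%s selected_only=%s conditioned=%s",
                  attr(cohort, "mode"),
                  isTRUE(attr(cohort, "selected_only")),
                  paste(sprintf("%s:%d", names(attr(cohort, "conditioned")),
                                attr(cohort, "conditioned")), collapse = ";"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    sp_stop(sprintf("file not found: %s", path), "selproc_io")
  meta <- readLines(path, n = 1L)
  if (!startsWith(meta, "# selproc cohort"))
    sp_stop("not a selproc cohort file (missing header comment)",
            "selproc_io")
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  mode <- sub(".*mode=([^ ]+).*", "\\1", meta)
  sel <- sub(".*selected_only=([^ ]+).*", "\\1", meta)
  cond_str <- sub(".*conditioned=([^ ]*).*", "\\1", meta)
  cond <- stats::setNames(integer(), character())
  if (nzchar(cond_str)) {
    pairs <- do.call(rbind, strsplit(strsplit(cond_str, ";")[[1]], ":"))
    cond <- stats::setNames(as.integer(pairs[, 2]), pairs[, 1])
  }
  vars <- setdiff(names(df), c("count", "in_population"))
  make_cohort(df[vars], df$count, as.logical(df$in_population),
              mode, identical(sel, "TRUE"), cond)
}

#' Write a framework or bias report as CSV
#'
#' Numeric columns are written unrounded, with display-precision
#' duplicates (risk ratios to 2 decimals) in `*_display` columns;
#' undefined estimates become empty fields with a `status` column.
#'
#' @param report A `data.frame` (e.g. [framework_report()]), a
#'   `bias_report`, or a list of `effect_estimate`s.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "bias_report")) {
    df <- report$estimates
  } else if (is.data.frame(report)) {
    df <- report
  } else {
    df <- estimates_df(report)
  }
  for (col in intersect("value", names(df)))
    df$value_display <- ifelse(is.na(df[[col]]), "",
                               sprintf("%.2f", df[[col]]))
  if ("value" %in% names(df))
    df$status <- ifelse(is.na(df$value), "undefined", "ok")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}
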