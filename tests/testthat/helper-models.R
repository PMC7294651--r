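# Shared fixtures: small diagram builders, random models and brute-force
# oracles, all generated in code.

fig2a_graph <- function() {
  build_graph(data.frame(id = c("C0", "E1", "D2"),
                         role = c("covariate", "exposure", "outcome")),
              list(c("C0", "E1"), c("C0", "D2"), c("E1", "D2")))
}

fig2c_graph <- function() make_scenario("fig2c")$model$graph
fig3b_graph <- function() make_scenario("fig3b")$model$graph

# random forward-in-time DAG over k nodes, one node per time window so no
# same-time warnings arise
random_graph <- function(k, p_edge = 0.5) {
  ids <- paste0("V", seq_len(k) - 1L)
  nodes <- data.frame(id = ids, variable = ids, time = seq_len(k) - 1L,
                      role = "covariate")
  edges <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (stats::runif(1) < p_edge) edges[[length(edges) + 1L]] <-
        c(ids[i], ids[j])
  build_graph(nodes, edges)
}

# random structural model on a random DAG, probabilities kept away from
# 0/1 so all configurations have positive mass
random_model <- function(k, cohort_size = 1000) {
  g <- random_graph(k)
  tables <- lapply(g$nodes$id, function(id) {
    np <- length(parents(g, id))
    cond_table(id, parents(g, id), stats::runif(2^np, 0.05, 0.95))
  })
  names(tables) <- g$nodes$id
  structural_model(g, tables, cohort_size)
}

# random cohort over named binary variables with integer counts
random_cohort <- function(vars, max_count = 50) {
  m <- random_model(length(vars))
  co <- expected_cohort(m)
  names(co)[seq_along(vars)] <- vars
  co$count <- stats::rpois(nrow(co), max_count / 2)
  co
}

# brute-force 2x2 oracle computed directly from configuration counts
oracle_rr <- function(cohort, exposure, outcome, stratum = list()) {
  d <- as.data.frame(cohort)
  d <- d[d$in_population, ]
  for (v in names(stratum)) d <- d[d[[v]] == stratum[[v]], ]
  a <- sum(d$count[d[[exposure]] == 1 & d[[outcome]] == 1])
  n1 <- sum(d$count[d[[exposure]] == 1])
  c_ <- sum(d$count[d[[exposure]] == 0 & d[[outcome]] == 1])
  n0 <- sum(d$count[d[[exposure]] == 0])
  if (n1 == 0 || n0 == 0 || c_ == 0) return(NA_real_)
  (a / n1) / (c_ / n0)
}

oracle_or <- function(cohort, a, b, given = list()) {
  d <- as.data.frame(cohort)
  d <- d[d$in_population, ]
  for (v in names(given)) d <- d[d[[v]] == given[[v]], ]
  n <- function(va, vb) sum(d$count[d[[a]] == va & d[[b]] == vb])
  if (min(n(1, 1), n(0, 0), n(1, 0), n(0, 1)) == 0) return(NA_real_)
  n(1, 1) * n(0, 0) / (n(1, 0) * n(0, 1))
}

expect_no_selproc_warning <- function(expr) {
  expect_silent(suppressMessages(expr))
}
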