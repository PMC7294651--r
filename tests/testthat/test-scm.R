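test_that("exact enumeration factorizes the hypothetical-cohort model", {
  j <- enumerate_joint(table1_model())
  # P(C=1, U=1, E=1, D=1) = 0.5 * 0.5 * 0.5 * 0.8
  expect_equal(prob_event(j, c(C0 = 1, U0 = 1, E1 = 1, D2 = 1)), 0.10,
               tolerance = 1e-12)
  expect_equal(sum(j$prob), 1, tolerance = 1e-12)
})

test_that("independent nodes and degenerate probabilities enumerate exactly", {
  g <- build_graph(data.frame(id = c("A0", "B1", "C2")))
  m <- structural_model(g, list(A0 = 0.5, B1 = 0.5, C2 = 0.5), 1)
  j <- enumerate_joint(m)
  expect_equal(j$prob, rep(0.125, 8))

  g1 <- build_graph(data.frame(id = "A0"))
  m1 <- structural_model(g1, list(A0 = 1), 1)
  j1 <- enumerate_joint(m1)
  expect_equal(prob_event(j1, c(A0 = 1)), 1)
  expect_equal(prob_event(j1, c(A0 = 0)), 0)
})

test_that("probabilities outside [0,1] are rejected", {
  expect_error(cond_table("A0", character(), 1.2),
               class = "selproc_bad_table")
  expect_error(make_scenario("fig2a", overrides = list(E1 = c(0.2, 1.6))),
               class = "selproc_bad_table")
})

test_that("conditioning by nature renormalizes and detects zero mass", {
  scn <- make_scenario("fig2d")
  j <- enumerate_joint(scn$model)
  # marginally E and U are independent causes of S
  expect_equal(prob_event(j, c(E1 = 1), c(U0 = 1)),
               prob_event(j, c(E1 = 1)), tolerance = 1e-12)
  js <- condition_joint(j, c(S1 = 1))
  expect_equal(sum(js$prob), 1, tolerance = 1e-12)
  # collider conditioning induces the inverse association
  or_sel <- prob_event(js, c(E1 = 1, U0 = 1)) *
    prob_event(js, c(E1 = 0, U0 = 0)) /
    (prob_event(js, c(E1 = 1, U0 = 0)) * prob_event(js, c(E1 = 0, U0 = 1)))
  expect_lt(or_sel, 1)

  g1 <- build_graph(data.frame(id = "A0"))
  m1 <- structural_model(g1, list(A0 = 1), 1)
  expect_error(condition_joint(enumerate_joint(m1), c(A0 = 0)),
               class = "selproc_zero_mass")
})

test_that("conditioning on an independent node leaves other margins unchanged", {
  g <- build_graph(data.frame(id = c("A0", "B1")))
  m <- structural_model(g, list(A0 = 0.3, B1 = 0.7), 1)
  j <- enumerate_joint(m)
  expect_equal(prob_event(condition_joint(j, c(B1 = 1)), c(A0 = 1)), 0.3,
               tolerance = 1e-12)
})

test_that("marginals and conditional probabilities match the printed table", {
  j <- enumerate_joint(table1_model())
  expect_equal(prob_event(j, c(E1 = 1)), 0.275, tolerance = 1e-12)
  expect_equal(prob_event(j, c(D2 = 1), c(E1 = 1, C0 = 1, U0 = 1)), 0.8,
               tolerance = 1e-12)
  # marginal over all variables is the identity
  expect_equal(marginal_joint(j, c("C0", "U0", "E1", "D2")), j)
  expect_error(marginal_joint(j, "Z9"), class = "selproc_unknown_node")
})

test_that("condition then marginal commutes with marginal of the conditioned", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_model(sample(3:5, 1))
    j <- enumerate_joint(m)
    v <- m$graph$nodes$id
    cond_on <- stats::setNames(sample(0:1, 1), v[1])
    keep <- v[-1]
    a <- marginal_joint(condition_joint(j, cond_on), keep)
    # brute force: restrict full table, renormalize, then sum out
    jj <- j[j[[v[1]]] == cond_on[[1]], ]
    jj$prob <- jj$prob / sum(jj$prob)
    for (r in seq_len(nrow(a))) {
      sel <- rep(TRUE, nrow(jj))
      for (u in keep) sel <- sel & jj[[u]] == a[[u]][r]
      expect_equal(a$prob[r], sum(jj$prob[sel]), tolerance = 1e-12)
    }
  }
})

test_that("the expected cohort scales masses to counts that conserve N", {
  m <- table1_model()
  co <- expected_cohort(m)
  expect_equal(sum(co$count), 4000, tolerance = 1e-9)
  get <- function(C, U, E, D)
    co$count[co$C0 == C & co$U0 == U & co$E1 == E & co$D2 == D]
  expect_equal(get(0, 0, 1, 1), 20, tolerance = 1e-9)
  expect_equal(get(1, 1, 1, 1), 400, tolerance = 1e-9)

  m0 <- structural_model(m$graph, m$tables, 0)
  expect_true(all(expected_cohort(m0)$count == 0))
})

test_that("sampling is reproducible and respects degenerate models", {
  m <- table1_model()
  s1 <- sample_cohort(m, 2000, seed = 9)
  s2 <- sample_cohort(m, 2000, seed = 9)
  expect_identical(s1$count, s2$count)
  expect_identical(sum(s1$count), 2000L)
  expect_error(sample_cohort(m, 10), class = "selproc_bad_model")

  g <- build_graph(data.frame(id = c("A0", "B1")), list(c("A0", "B1")))
  md <- structural_model(g, list(A0 = 1, B1 = c(0, 1)), 1)
  sd <- sample_cohort(md, 50, seed = 1)
  expect_identical(sd$count[sd$A0 == 1 & sd$B1 == 1], 50L)
})

test_that("sampled frequencies converge to the enumerated masses", {
  m <- table1_model()
  n <- 20000
  s <- sample_cohort(m, n, seed = 123)
  p <- enumerate_joint(m)$prob
  se <- sqrt(n * p * (1 - p))
  expect_true(all(abs(s$count - n * p) <= 4 * se))
  gof <- stats::chisq.test(s$count, p = p)
  expect_gt(gof$p.value, 0.001)
})

test_that("apply_selection removes or flags configurations off the boxed value", {
  scn <- make_scenario("fig3c")
  co <- apply_selection(expected_cohort(scn$model))
  expect_true(all(co$S1 == 1))
  expect_true(isTRUE(attr(co, "selected_only")))
  expect_error(apply_selection(co), class = "selproc_bad_model")

  # sampled mode retains non-members with a membership flag
  cs <- apply_selection(sample_cohort(scn$model, 1000, seed = 4))
  expect_true(any(!cs$in_population))
  expect_identical(sum(cs$count), 1000L)
  expect_true(all(cs$S1[cs$in_population] == 1))

  # a model without conditioned nodes is unchanged
  co2a <- expected_cohort(make_scenario("fig2a")$model)
  expect_identical(apply_selection(co2a), co2a)
})

test_that("depletion of susceptibles induces the inverse association among survivors", {
  scn <- make_scenario("fig3d")
  j <- enumerate_joint(scn$model)
  expect_lt(prob_event(j, c(U0 = 1), c(E0 = 1, D1 = 0)),
            prob_event(j, c(U0 = 1), c(E0 = 0, D1 = 0)))
  co <- apply_selection(expected_cohort(scn$model))
  expect_true(all(co$D1 == 0))
})

test_that("enumeration is capped with a clear error", {
  ids <- sprintf("V%d", 0:20)
  g <- build_graph(data.frame(id = ids, variable = ids, time = 0:20))
  tables <- stats::setNames(as.list(rep(0.5, 21)), ids)
  m <- structural_model(g, tables, 1)
  expect_error(enumerate_joint(m), class = "selproc_too_large")
})
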