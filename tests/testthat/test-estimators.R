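t1_cohort <- function() expected_cohort(table1_model())

test_that("risks reproduce the printed stratum risks", {
  co <- t1_cohort()
  expect_equal(risk(co, "D", c(E1 = 1, C0 = 0, U0 = 0))$value, 0.20,
               tolerance = 1e-12)
  expect_equal(risk(co, "D", c(E1 = 0))$value, 475 / 2900,
               tolerance = 1e-12)
  # empty restriction on an all-outcome-positive cohort
  g <- build_graph(data.frame(id = "D0", role = "outcome"))
  m <- structural_model(g, list(D0 = 1), 10)
  expect_equal(risk(expected_cohort(m), "D")$value, 1)
})

test_that("zero denominators yield undefined estimates, not errors", {
  g <- build_graph(data.frame(id = c("E0", "D1"),
                              role = c("exposure", "outcome")))
  m <- structural_model(g, list(E0 = 1, D1 = 0.5), 100)
  r <- risk(expected_cohort(m), "D", c(E0 = 0))  # empty arm
  expect_identical(r$value, NA_real_)
  expect_true(r$undefined)
  co <- t1_cohort()
  co0 <- co
  co0$count[co0$E1 == 0] <- 0
  expect_true(risk_ratio(co0, "E", "D")[[1]]$undefined)
})

test_that("stratum risk ratios are constant at 2 and collapse as printed", {
  co <- t1_cohort()
  rr4 <- risk_ratio(co, "E", "D", c("C", "U"))
  expect_length(rr4, 4L)
  for (e in rr4) expect_equal(e$value, 2, tolerance = 1e-12)
  rrC <- risk_ratio(co, "E", "D", "C")
  expect_equal(rrC[[1]]$value, 2, tolerance = 1e-12)           # C = 0
  expect_equal(round(rrC[[2]]$value, 2), 2.41)                 # C = 1
  expect_equal(rrC[[2]]$value, (490 / 800) / (305 / 1200),
               tolerance = 1e-12)
})

test_that("independent exposure gives a crude risk ratio of 1", {
  g <- build_graph(data.frame(id = c("E0", "D1"),
                              role = c("exposure", "outcome")))
  m <- structural_model(g, list(E0 = 0.4, D1 = 0.2), 1000)
  expect_equal(risk_ratio(expected_cohort(m), "E", "D")[[1]]$value, 1,
               tolerance = 1e-12)
})

test_that("Mantel-Haenszel summarizes strata as expected", {
  co <- t1_cohort()
  # single stratum collapses to the crude RR
  expect_equal(mh_risk_ratio(co, "E", "D")$value,
               risk_ratio(co, "E", "D")[[1]]$value, tolerance = 1e-12)
  # C-only adjustment is biased above the constant stratum RR of 2
  mh <- mh_risk_ratio(co, "E", "D", "C")
  expect_equal(mh$value, (60 * 1700 / 2000 + 490 * 1200 / 2000) /
                 (170 * 300 / 2000 + 305 * 800 / 2000), tolerance = 1e-12)
  expect_gt(mh$value, 2)
  # full stratification with homogeneous RRs returns the common value
  expect_equal(mh_risk_ratio(co, "E", "D", c("C", "U"))$value, 2,
               tolerance = 1e-12)
})

test_that("MH lies between the extreme stratum RRs", {
  set.seed(31)
  for (i in 1:10) {
    co <- random_cohort(c("Z0", "E1", "D2"))
    rrs <- vapply(risk_ratio(co, "E1", "D2", "Z0"),
                  function(e) e$value, 0)
    if (anyNA(rrs)) next
    mh <- mh_risk_ratio(co, "E1", "D2", "Z0")$value
    expect_gte(mh, min(rrs) - 1e-9)
    expect_lte(mh, max(rrs) + 1e-9)
  }
})

test_that("standardization to the total population recovers the causal contrast", {
  co <- t1_cohort()
  expect_equal(standardized_risk_ratio(co, "E", "D", c("C", "U"))$value,
               ((0.2 + 0.3 + 0.2 + 0.8) / 4) / ((0.1 + 0.15 + 0.1 + 0.4) / 4),
               tolerance = 1e-12)
  expect_equal(standardized_risk_ratio(co, "E", "D", c("C", "U"))$value, 2,
               tolerance = 1e-12)
  # single stratum = crude; homogeneous risks identical across weights
  expect_equal(standardized_risk_ratio(co, "E", "D")$value,
               risk_ratio(co, "E", "D")[[1]]$value, tolerance = 1e-12)
  g <- build_graph(data.frame(id = c("C0", "E1", "D2"),
                              role = c("covariate", "exposure", "outcome")),
                   list(c("C0", "E1"), c("E1", "D2")))
  m <- structural_model(g, list(C0 = 0.5, E1 = c(0.2, 0.7),
                                D2 = c(0.1, 0.3)), 1000)
  ch <- expected_cohort(m)
  vals <- vapply(c("total", "exposed", "unexposed"), function(w)
    standardized_risk_ratio(ch, "E", "D", "C", w)$value, 0)
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
})

test_that("odds ratios expose the induced inverse association", {
  co <- t1_cohort()
  expect_equal(odds_ratio(co, "C", "U")$value, 1, tolerance = 1e-12)
  or_exposed <- odds_ratio(co, "C", "U", c(E1 = 1))
  expect_equal(or_exposed$value, (0.5 * 0.1) / (0.3 * 0.2),
               tolerance = 1e-12)
  expect_lt(or_exposed$value, 1)
  expect_error(odds_ratio(co, "C", "C"), class = "selproc_bad_estimate")
  # zero cell: undefined without continuity correction
  co0 <- co
  co0$count[co0$C0 == 1 & co0$U0 == 1] <- 0
  expect_true(odds_ratio(co0, "C", "U")$undefined)
})

test_that("IPW with the full propensity recovers the truth; partial does not", {
  m <- table1_model()
  co <- expected_cohort(m)
  expect_equal(ipw_risk_ratio(co, "E", "D", c("C", "U"))$value, 2,
               tolerance = 1e-10)
  expect_equal(ipw_risk_ratio(co, "E", "D", c("C", "U"),
                              weight_source = "true_model",
                              model = m)$value, 2, tolerance = 1e-10)
  expect_gt(abs(ipw_risk_ratio(co, "E", "D", "C")$value - 2), 0.05)
  # randomized exposure: IPW equals the crude RR
  g <- build_graph(data.frame(id = c("C0", "E1", "D2"),
                              role = c("covariate", "exposure", "outcome")),
                   list(c("C0", "D2"), c("E1", "D2")))
  mr <- structural_model(g, list(C0 = 0.5, E1 = 0.3,
                                 D2 = c(0.1, 0.2, 0.3, 0.6)), 1000)
  cr <- expected_cohort(mr)
  expect_equal(ipw_risk_ratio(cr, "E", "D", "C")$value,
               risk_ratio(cr, "E", "D")[[1]]$value, tolerance = 1e-10)
})

test_that("IPW with saturated weights equals total-population standardization", {
  for (nm in c("fig2a", "fig2c", "fig3a", "table1")) {
    co <- expected_cohort(make_scenario(nm)$model)
    nd <- make_scenario(nm)$model$graph$nodes
    covs <- nd$id[nd$role %in% c("covariate", "unknown_cause")]
    exposure <- nd$id[nd$role == "exposure"]
    exposure <- exposure[length(exposure)]
    outcome <- nd$id[nd$role == "outcome"]
    expect_equal(ipw_risk_ratio(co, exposure, outcome, covs)$value,
                 standardized_risk_ratio(co, exposure, outcome, covs)$value,
                 tolerance = 1e-10, info = nm)
  }
})

test_that("estimators agree with the brute-force oracle on random cohorts", {
  set.seed(41)
  for (i in 1:15) {
    co <- random_cohort(c("C0", "E1", "D2"))
    expect_equal(risk_ratio(co, "E1", "D2")[[1]]$value,
                 oracle_rr(co, "E1", "D2"), tolerance = 1e-12)
    for (z in 0:1)
      expect_equal(risk_ratio(co, "E1", "D2", "C0")[[z + 1]]$value,
                   oracle_rr(co, "E1", "D2", list(C0 = z)),
                   tolerance = 1e-12)
    expect_equal(odds_ratio(co, "C0", "E1")$value,
                 oracle_or(co, "C0", "E1"), tolerance = 1e-12)
  }
})

test_that("estimates are invariant to scaling all counts", {
  co <- t1_cohort()
  co3 <- co
  co3$count <- co3$count * 3.7
  expect_equal(risk_ratio(co3, "E", "D")[[1]]$value,
               risk_ratio(co, "E", "D")[[1]]$value, tolerance = 1e-12)
  expect_equal(mh_risk_ratio(co3, "E", "D", "C")$value,
               mh_risk_ratio(co, "E", "D", "C")$value, tolerance = 1e-12)
  expect_equal(odds_ratio(co3, "C", "U", c(E1 = 1))$value,
               odds_ratio(co, "C", "U", c(E1 = 1))$value, tolerance = 1e-12)
  expect_equal(ipw_risk_ratio(co3, "E", "D", c("C", "U"))$value,
               ipw_risk_ratio(co, "E", "D", c("C", "U"))$value,
               tolerance = 1e-12)
})

test_that("ambiguous variable symbols are rejected with guidance", {
  co <- expected_cohort(make_scenario("fig3a")$model)
  expect_error(risk_ratio(co, "E", "D2"), class = "selproc_unknown_node")
  expect_equal(risk_ratio(co, "E1", "D2")[[1]]$measure, "risk_ratio")
})
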