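test_that("identify_processes finds arrow-receiving exposures and boxed nodes", {
  procs <- identify_processes(fig2a_graph())
  expect_length(procs, 1L)
  expect_identical(procs[[1]]$target, "E1")
  expect_identical(procs[[1]]$origins, "C0")
  expect_false(procs[[1]]$mediated_by_side_effect)

  # no arrows into E, nothing conditioned: no processes
  g <- build_graph(data.frame(id = c("E1", "D2"),
                              role = c("exposure", "outcome")),
                   list(c("E1", "D2")))
  expect_length(identify_processes(g), 0L)
})

test_that("side-effect mediation is flagged when an origin descends from exposure", {
  procs <- identify_processes(fig3b_graph())
  expect_length(procs, 1L)
  expect_identical(procs[[1]]$target, "E2")
  expect_true(procs[[1]]$mediated_by_side_effect)
  # but plain continuation with an external covariate is not mediated
  p3a <- identify_processes(make_scenario("fig3a")$model$graph)
  expect_false(p3a[[1]]$mediated_by_side_effect)
})

test_that("classification reproduces the framework cells of the templates", {
  cells <- c(fig2a = "1.1.1", fig2b = "1.2.1", fig2c = "1.1.1",
             fig2d = "1.2.1", fig3a = "1.1.2", fig3b = "1.1.2",
             fig3c = "1.2.2", fig3d = "1.2.2", fig4a = "1.1.3",
             fig4b = "1.2.3")
  for (nm in names(cells)) {
    scn <- make_scenario(nm)
    fr <- framework_report(scn$model$graph)
    expect_identical(nrow(fr), 1L, info = nm)
    expect_identical(fr$cell_code, unname(cells[nm]), info = nm)
    expect_mapequal(stats::setNames(fr$cell_code, fr$target),
                    scn$expected_cells)
  }
})

test_that("multifactorial status counts distinct external origin variables", {
  expect_identical(framework_report(fig2c_graph())$factors, "multifactorial")
  # persistence edge E0 -> E1 does not make continuation multifactorial
  expect_identical(framework_report(make_scenario("fig3a")$model$graph)$factors,
                   "unifactorial")
  expect_identical(framework_report(fig3b_graph())$factors, "unifactorial")
})

test_that("timing precedence is post-outcome > during-exposure > entry", {
  expect_identical(framework_report(make_scenario("fig4a")$model$graph)$timing,
                   "post_outcome")
  # fig4b has both an earlier exposure and an earlier outcome origin
  expect_identical(framework_report(make_scenario("fig4b")$model$graph)$timing,
                   "post_outcome")
  expect_identical(framework_report(make_scenario("fig3c")$model$graph)$timing,
                   "during_exposure")
  expect_identical(framework_report(make_scenario("fig3d")$model$graph)$timing,
                   "during_exposure")
})

test_that("the classifier is a pure function of the graph", {
  g <- make_scenario("fig3d")$model$graph
  expect_identical(framework_report(g), framework_report(g))
})

test_that("toggling study_specific changes only the level digit", {
  for (nm in c("fig2a", "fig2d", "fig3c", "fig4b")) {
    g <- make_scenario(nm)$model$graph
    fr1 <- framework_report(g)
    target <- fr1$target
    nodes <- g$nodes
    nodes$study_specific[nodes$id == target] <- TRUE
    g2 <- suppressWarnings(build_graph(nodes, graph_spec(g)$edges))
    fr2 <- framework_report(g2)
    expect_identical(fr2$level, "study_specific")
    expect_identical(substr(fr2$cell_code, 1, 1), "2")
    expect_identical(substr(fr2$cell_code, 2, 5), substr(fr1$cell_code, 2, 5))
    expect_identical(fr2[c("mechanism", "timing", "factors")],
                     fr1[c("mechanism", "timing", "factors")])
  }
})

test_that("shifting all time windows by a constant changes nothing", {
  for (nm in c("fig2c", "fig3b", "fig4b")) {
    g <- make_scenario(nm)$model$graph
    nodes <- g$nodes
    nodes$time <- nodes$time + 3L
    g2 <- suppressWarnings(build_graph(nodes, graph_spec(g)$edges))
    fr1 <- framework_report(g)
    fr2 <- framework_report(g2)
    expect_identical(fr2[-1], fr1[-1])  # targets keep ids, rest identical
  }
})

test_that("adding an external origin never changes the timing", {
  base <- make_scenario("fig2a")$model$graph
  spec <- graph_spec(base)
  spec$nodes <- rbind(spec$nodes, timed_node("U0", role = "unknown_cause"))
  spec$edges <- c(spec$edges, list(c("U0", "E1")))
  g2 <- build_graph(spec$nodes, spec$edges)
  expect_identical(framework_report(g2)$timing,
                   framework_report(base)$timing)
  expect_identical(framework_report(g2)$factors, "multifactorial")
})

test_that("edgeless graphs yield an empty report", {
  g <- build_graph(data.frame(id = c("C0", "E1"),
                              role = c("covariate", "exposure")))
  fr <- framework_report(g)
  expect_identical(nrow(fr), 0L)
  expect_true(all(c("target", "cell_code", "label") %in% names(fr)))
})

test_that("a conditioned node without any exposure warns and defaults to entry", {
  g <- build_graph(data.frame(id = c("C0", "S1"),
                              role = c("covariate", "selection"),
                              conditioned = c(FALSE, TRUE)),
                   list(c("C0", "S1")))
  expect_warning(fr <- framework_report(g), class = "selproc_no_exposure")
  expect_identical(fr$timing, "at_exposure_entry")
})

test_that("canonical labels come from the template registry only", {
  expect_identical(framework_report(make_scenario("fig4b")$model$graph)$label,
                   "Berkson's fallacy")
  expect_identical(framework_report(make_scenario("fig3d")$model$graph)$label,
                   "depletion of susceptibles")
  # an arbitrary graph gets an empty label, not an invented one
  g <- build_graph(data.frame(id = c("X0", "E1"),
                              role = c("covariate", "exposure")),
                   list(c("X0", "E1")))
  expect_identical(framework_report(g)$label, "")
})

test_that("classify rejects a process from a different graph", {
  p <- identify_processes(fig2c_graph())[[1]]
  expect_error(classify(p, fig2a_graph()), class = "selproc_mismatch")
})
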