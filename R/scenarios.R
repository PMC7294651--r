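# Registry of ready-made structural models, one per classical selection
# phenomenon: selection at exposure entry (unifactorial and multifactorial,
# in exposure and in population composition), selection during exposure
# (healthy worker survivor effect, side effects, competing events,
# depletion of susceptibles) and post-outcome selection (reversed
# causality, Berkson's fallacy).
#
# Only the hypothetical-cohort model (`table1`) carries externally given
# parameters; every other scenario's probabilities are this package's own
# illustrative constants, chosen once in [0.05, 0.95] so that the
# scenario's qualitative bias signature holds under exact enumeration.

muffle_same_time <- function(expr) {
  withCallingHandlers(expr, selproc_same_time_edge = function(w)
    invokeRestart("muffleWarning"))
}

# -- signature helpers (all exact: computed on the expected cohort) --------

sig <- function(description, check) list(description = description,
                                         check = check)

sel_cohort <- function(scn) {
  co <- expected_cohort(scn$model)
  if (length(attr(co, "conditioned"))) apply_selection(co) else co
}

full_cohort <- function(scn) expected_cohort(scn$model)

# -- scenario definitions --------------------------------------------------

scenario_defs <- function() {
  defs <- list()

  defs$fig2a <- list(
    description = paste(
      "Unifactorial selection in exposure at exposure entry: a known",
      "covariate C makes exposure more likely and independently raises",
      "disease risk (the healthy worker hire pattern, with C read as",
      "ill-health)."),
    nodes = data.frame(id = c("C0", "E1", "D2"),
                       role = c("covariate", "exposure", "outcome")),
    edges = list(c("C0", "E1"), c("C0", "D2"), c("E1", "D2")),
    p = list(C0 = 0.5, E1 = c(0.2, 0.6), D2 = c(0.05, 0.15, 0.15, 0.25)),
    N = 10000,
    expected_cells = c(E1 = "1.1.1"),
    labels = c(E1 = "self-selection / healthy worker hire effect"),
    signatures = list(
      sig("crude RR exceeds the C-standardized RR (confounding by C)",
          function(scn) {
            co <- full_cohort(scn)
            crude <- risk_ratio(co, "E", "D")[[1]]$value
            adj <- standardized_risk_ratio(co, "E", "D", "C")$value
            list(value = crude - adj, pass = crude > adj)
          })))

  defs$fig2b <- list(
    description = paste(
      "Unifactorial selection in population composition at exposure",
      "entry: C drives a boxed selection event S (conditioning by nature)",
      "before exposure becomes available, so the eligible population is",
      "enriched in C."),
    nodes = data.frame(id = c("C0", "S1", "E2"),
                       role = c("covariate", "selection", "exposure"),
                       conditioned = c(FALSE, TRUE, FALSE)),
    edges = list(c("C0", "S1")),
    p = list(C0 = 0.5, S1 = c(0.3, 0.8), E2 = 0.3),
    N = 10000,
    expected_cells = c(S1 = "1.2.1"),
    labels = c(S1 = "self-selection (population composition)"),
    signatures = list(
      sig("selected population is enriched in C: P(C=1|S=1) > P(C=1)",
          function(scn) {
            j <- enumerate_joint(scn$model)
            p_sel <- prob_event(j, c(C0 = 1), c(S1 = 1))
            p_all <- prob_event(j, c(C0 = 1))
            list(value = p_sel - p_all, pass = p_sel > p_all)
          })))

  defs$fig2c <- list(
    description = paste(
      "Multifactorial selection in exposure at exposure entry: exposure",
      "has a known cause C and an unknown cause U, both of which also",
      "affect the outcome; adjustment for C alone leaves residual bias."),
    nodes = data.frame(id = c("C0", "U0", "E1", "D2"),
                       role = c("covariate", "unknown_cause", "exposure",
                                "outcome")),
    edges = list(c("C0", "E1"), c("U0", "E1"), c("C0", "D2"),
                 c("U0", "D2"), c("E1", "D2")),
    p = list(C0 = 0.5, U0 = 0.5,
             E1 = c(0.15, 0.25, 0.35, 0.55),
             # 0.05 * 2^E * (1 + 2U)^C, order (C0, U0, E1)
             D2 = c(0.05, 0.10, 0.05, 0.10, 0.05, 0.10, 0.15, 0.30)),
    N = 10000,
    expected_cells = c(E1 = "1.1.1"),
    labels = c(E1 = "healthy worker hire effect (multifactorial)"),
    signatures = list(
      sig("C and U independent marginally: OR(C,U) = 1",
          function(scn) {
            v <- odds_ratio(full_cohort(scn), "C", "U")$value
            list(value = v, pass = abs(v - 1) < 1e-9)
          }),
      sig("induced inverse association within the exposed: OR(C,U|E=1) < 1",
          function(scn) {
            v <- odds_ratio(full_cohort(scn), "C", "U",
                            given = c(E1 = 1))$value
            list(value = v, pass = v < 1)
          }),
      sig("C-only MH adjustment differs from the (C,U)-standardized truth",
          function(scn) {
            co <- full_cohort(scn)
            mh <- mh_risk_ratio(co, "E", "D", "C")$value
            tr <- standardized_risk_ratio(co, "E", "D", c("C", "U"))$value
            list(value = mh - tr, pass = abs(mh - tr) > 1e-6)
          })))

  defs$fig2d <- list(
    description = paste(
      "Multifactorial selection in population composition at exposure",
      "entry: exposure E and an unknown cause U jointly determine entry",
      "into the boxed index population S; conditioning by nature on S",
      "induces an inverse E-U association among the selected."),
    nodes = data.frame(id = c("U0", "E1", "S1"),
                       role = c("unknown_cause", "exposure", "selection"),
                       conditioned = c(FALSE, FALSE, TRUE)),
    edges = list(c("U0", "S1"), c("E1", "S1")),
    p = list(U0 = 0.5, E1 = 0.4, S1 = c(0.1, 0.5, 0.5, 0.9)),
    N = 10000,
    expected_cells = c(S1 = "1.2.1"),
    labels = c(S1 = "index event bias"),
    signatures = list(
      sig("E and U independent marginally: OR(E,U) = 1",
          function(scn) {
            v <- odds_ratio(full_cohort(scn), "E", "U")$value
            list(value = v, pass = abs(v - 1) < 1e-9)
          }),
      sig("collider conditioning induces OR(E,U|S=1) < 1",
          function(scn) {
            v <- odds_ratio(sel_cohort(scn), "E", "U")$value
            list(value = v, pass = v < 1)
          })))

  defs$fig3a <- list(
    description = paste(
      "Selection in exposure during exposure: C does not influence",
      "exposure initiation E0 but does influence continuation E1 (the",
      "healthy worker survivor pattern); the effect contrast is continued",
      "exposure vs quit."),
    nodes = data.frame(id = c("C0", "E0", "E1", "D2"),
                       role = c("covariate", "exposure", "exposure",
                                "outcome")),
    edges = list(c("C0", "E1"), c("E0", "E1"), c("C0", "D2"),
                 c("E1", "D2")),
    p = list(C0 = 0.5, E0 = 0.4,
             # order (C0, E0): continuation only among initiators,
             # dampened when C = 1
             E1 = c(0.05, 0.8, 0.05, 0.5),
             # order (C0, E1)
             D2 = c(0.1, 0.2, 0.2, 0.3)),
    N = 10000,
    expected_cells = c(E1 = "1.1.2"),
    labels = c(E1 = "healthy worker survivor effect"),
    signatures = list(
      sig("continuers differ in C from quitters: P(C=1|E1=1,E0=1) < P(C=1|E1=0,E0=1)",
          function(scn) {
            j <- enumerate_joint(scn$model)
            p1 <- prob_event(j, c(C0 = 1), c(E1 = 1, E0 = 1))
            p0 <- prob_event(j, c(C0 = 1), c(E1 = 0, E0 = 1))
            list(value = p1 - p0, pass = p1 < p0)
          }),
      sig("crude continuation RR is below the C-standardized RR",
          function(scn) {
            co <- full_cohort(scn)
            crude <- risk_ratio(co, "E1", "D2")[[1]]$value
            adj <- standardized_risk_ratio(co, "E1", "D2", "C0")$value
            list(value = crude - adj, pass = crude < adj)
          })))

  defs$fig3b <- list(
    description = paste(
      "Selection in exposure during exposure, mediated by a side effect:",
      "initial exposure E0 causes an adverse event A1 (e.g. bad cough)",
      "which lowers the probability of continued exposure E2, so",
      "continuing exposed individuals under-represent the side effect."),
    nodes = data.frame(id = c("E0", "A1", "E2"),
                       role = c("exposure", "side_effect", "exposure")),
    edges = list(c("E0", "A1"), c("E0", "E2"), c("A1", "E2")),
    p = list(E0 = 0.5, A1 = c(0.05, 0.5),
             # order (E0, A1)
             E2 = c(0.05, 0.05, 0.9, 0.4)),
    N = 10000,
    expected_cells = c(E2 = "1.1.2"),
    labels = c(E2 = "side effects causing exposure changes"),
    signatures = list(
      sig("continuers experienced the side effect less: P(A=1|E2=1,E0=1) < P(A=1|E2=0,E0=1)",
          function(scn) {
            j <- enumerate_joint(scn$model)
            p1 <- prob_event(j, c(A1 = 1), c(E2 = 1, E0 = 1))
            p0 <- prob_event(j, c(A1 = 1), c(E2 = 0, E0 = 1))
            list(value = p1 - p0, pass = p1 < p0)
          })))

  defs$fig3c <- list(
    description = paste(
      "Competing event during exposure: exposure E and an unknown",
      "determinant U (read: frailty) each cause a competing event, so",
      "each lowers the chance of remaining in the population at risk",
      "(boxed S = event-free survival); among those still at risk the",
      "exposed are depleted of U, which also raises the disease risk,",
      "masking part of the true effect on D."),
    nodes = data.frame(id = c("E0", "U0", "S1", "D2"),
                       role = c("exposure", "unknown_cause", "selection",
                                "outcome"),
                       conditioned = c(FALSE, FALSE, TRUE, FALSE)),
    edges = list(c("E0", "S1"), c("U0", "S1"), c("E0", "D2"),
                 c("U0", "D2")),
    p = list(E0 = 0.5, U0 = 0.5,
             # order (E0, U0): both E and U cut event-free survival
             S1 = c(0.9, 0.5, 0.7, 0.1),
             # order (E0, U0): true RR for E is 2 within U strata,
             # U raises the disease risk
             D2 = c(0.1, 0.3, 0.2, 0.6)),
    N = 10000,
    expected_cells = c(S1 = "1.2.2"),
    labels = c(S1 = "competing event"),
    signatures = list(
      sig("induced inverse E-U association among survivors: OR(E,U|S=1) < 1",
          function(scn) {
            v <- odds_ratio(sel_cohort(scn), "E", "U")$value
            list(value = v, pass = v < 1)
          }),
      sig("crude RR among survivors falls below the within-U RR of 2",
          function(scn) {
            crude <- risk_ratio(sel_cohort(scn), "E", "D")[[1]]$value
            list(value = crude, pass = crude < 2)
          }),
      sig("U-stratum RRs among survivors remain exactly 2",
          function(scn) {
            rrs <- risk_ratio(sel_cohort(scn), "E", "D", strata = "U")
            v <- vapply(rrs, function(e) e$value, 0)
            list(value = max(abs(v - 2)), pass = all(abs(v - 2) < 1e-9))
          })))

  defs$fig3d <- list(
    description = paste(
      "Depletion of susceptibles: exposure E and an unknown determinant U",
      "both cause early disease D1; later disease D2 can only be observed",
      "among those without an early event (boxed D1 = 0), so exposed",
      "survivors are depleted of U and the apparent later effect shrinks."),
    nodes = data.frame(id = c("E0", "U0", "D1", "D2"),
                       role = c("exposure", "unknown_cause", "outcome",
                                "outcome"),
                       conditioned = c(FALSE, FALSE, TRUE, FALSE),
                       conditioned_value = c(1L, 1L, 0L, 1L)),
    edges = list(c("E0", "D1"), c("U0", "D1"), c("E0", "D2"),
                 c("U0", "D2")),
    p = list(E0 = 0.5, U0 = 0.5,
             # order (E0, U0): both raise early disease
             D1 = c(0.1, 0.4, 0.2, 0.6),
             # order (E0, U0): true RR for E is 2 within U strata
             D2 = c(0.1, 0.3, 0.2, 0.6)),
    N = 10000,
    expected_cells = c(D1 = "1.2.2"),
    labels = c(D1 = "depletion of susceptibles"),
    signatures = list(
      sig("survivors show the induced inverse association: P(U=1|E=1,D1=0) < P(U=1|E=0,D1=0)",
          function(scn) {
            j <- enumerate_joint(scn$model)
            p1 <- prob_event(j, c(U0 = 1), c(E0 = 1, D1 = 0))
            p0 <- prob_event(j, c(U0 = 1), c(E0 = 0, D1 = 0))
            list(value = p1 - p0, pass = p1 < p0)
          }),
      sig("crude RR among survivors falls below the within-U RR of 2",
          function(scn) {
            crude <- risk_ratio(sel_cohort(scn), "E", "D2")[[1]]$value
            list(value = crude, pass = crude < 2)
          }),
      sig("U-stratum RRs among survivors remain exactly 2",
          function(scn) {
            rrs <- risk_ratio(sel_cohort(scn), "E", "D2", strata = "U")
            v <- vapply(rrs, function(e) e$value, 0)
            list(value = max(abs(v - 2)), pass = all(abs(v - 2) < 1e-9))
          })))

  defs$fig4a <- list(
    description = paste(
      "Reversed causality: the disease outcome D0 changes subsequent",
      "exposure E1 (e.g. subclinical symptoms trigger exposure), so a",
      "naive cross-sectional analysis misreads the D0-E1 association as",
      "an exposure effect; no later outcome exists to estimate against."),
    nodes = data.frame(id = c("D0", "E1"),
                       role = c("outcome", "exposure")),
    edges = list(c("D0", "E1")),
    p = list(D0 = 0.3, E1 = c(0.2, 0.6)),
    N = 10000,
    expected_cells = c(E1 = "1.1.3"),
    labels = c(E1 = "reversed causality / subclinical symptoms causing exposure changes"),
    signatures = list(
      sig("cross-lagged association: P(D0=1|E1=1) / P(D0=1|E1=0) > 1 without any E->D arrow",
          function(scn) {
            j <- enumerate_joint(scn$model)
            v <- prob_event(j, c(D0 = 1), c(E1 = 1)) /
              prob_event(j, c(D0 = 1), c(E1 = 0))
            list(value = v, pass = v > 1)
          })))

  defs$fig4b <- list(
    description = paste(
      "Post-outcome selection in population composition (Berkson's",
      "fallacy): membership of the observed population S (e.g. hospital",
      "attendance) depends on both the disease outcome D0 and the",
      "exposure E0, distorting their association among the selected."),
    nodes = data.frame(id = c("D0", "E0", "S1"),
                       role = c("outcome", "exposure", "selection"),
                       conditioned = c(FALSE, FALSE, TRUE)),
    edges = list(c("D0", "S1"), c("E0", "S1")),
    p = list(D0 = 0.2, E0 = 0.4,
             # order (D0, E0)
             S1 = c(0.1, 0.6, 0.6, 0.9)),
    N = 10000,
    expected_cells = c(S1 = "1.2.3"),
    labels = c(S1 = "Berkson's fallacy"),
    signatures = list(
      sig("E and D independent marginally: OR(E,D) = 1",
          function(scn) {
            v <- odds_ratio(full_cohort(scn), "E", "D")$value
            list(value = v, pass = abs(v - 1) < 1e-9)
          }),
      sig("selection distorts the association: OR(E,D|S=1) < 1",
          function(scn) {
            v <- odds_ratio(sel_cohort(scn), "E", "D")$value
            list(value = v, pass = v < 1)
          })))

  defs$table1 <- list(
    description = paste(
      "Hypothetical cohort with multifactorial selection in exposure:",
      "E is caused by a known source C and an unknown source U, the",
      "relative effect of E on D is constant (RR = 2.0) across C-U",
      "strata, and U modifies the effect of C on D (RR 1.5 when U = 0,",
      "4.0 when U = 1), so C-only adjustment remains biased."),
    nodes = data.frame(id = c("C0", "U0", "E1", "D2"),
                       role = c("covariate", "unknown_cause", "exposure",
                                "outcome")),
    edges = list(c("C0", "E1"), c("U0", "E1"), c("C0", "D2"),
                 c("U0", "D2"), c("E1", "D2")),
    p = list(C0 = 0.5, U0 = 0.5,
             # order (C0, U0)
             E1 = c(0.10, 0.20, 0.30, 0.50),
             # 0.10 * 2^E * (1.5*(1-U) + 4*U)^C, order (C0, U0, E1)
             D2 = c(0.10, 0.20, 0.10, 0.20, 0.15, 0.30, 0.40, 0.80)),
    N = 4000,
    expected_cells = c(E1 = "1.1.1"),
    labels = c(E1 = "healthy worker hire effect (multifactorial)"),
    signatures = list(
      sig("RR of E on D equals 2.0 in every C-U stratum",
          function(scn) {
            rrs <- risk_ratio(full_cohort(scn), "E", "D", c("C", "U"))
            v <- vapply(rrs, function(e) e$value, 0)
            list(value = max(abs(v - 2)), pass = all(abs(v - 2) < 1e-9))
          }),
      sig("C and U independent marginally: OR(C,U) = 1",
          function(scn) {
            v <- odds_ratio(full_cohort(scn), "C", "U")$value
            list(value = v, pass = abs(v - 1) < 1e-9)
          }),
      sig("induced inverse association within the exposed: OR(C,U|E=1) < 1",
          function(scn) {
            v <- odds_ratio(full_cohort(scn), "C", "U",
                            given = c(E1 = 1))$value
            list(value = v, pass = v < 1)
          }),
      sig("C-only MH adjustment stays biased above the true RR of 2.0",
          function(scn) {
            v <- mh_risk_ratio(full_cohort(scn), "E", "D", "C")$value
            list(value = v, pass = v > 2)
          }),
      sig("full (C,U) standardization recovers the true RR of 2.0",
          function(scn) {
            v <- standardized_risk_ratio(full_cohort(scn), "E", "D",
                                         c("C", "U"))$value
            list(value = v, pass = abs(v - 2) < 1e-9)
          })))

  defs
}

scenario_aliases <- c(healthy_worker_hire = "fig2a",
                      healthy_worker_survivor = "fig3a",
                      berkson = "fig4b",
                      index_event = "fig2d",
                      depletion = "fig3d")

#' Names of the builtin scenarios
#'
#' @return Character vector of registry keys accepted by
#'   [make_scenario()]: the ten diagram templates (`fig2a`-`fig4b`), the
#'   hypothetical cohort (`table1`) and phenomenon aliases
#'   (`healthy_worker_hire`, `healthy_worker_survivor`, `berkson`,
#'   `index_event`, `depletion`).
#' @export
scenario_names <- function() {
  c(names(scenario_defs()), names(scenario_aliases))
}

#' Build a builtin scenario, optionally with overridden probabilities
#'
#' Instantiates one of the registry templates as a full structural model
#' together with its expected framework classification and its qualitative
#' bias signature (machine-checkable predicates evaluated by
#' [bias_report()]).
#'
#' @param name A registry key; see [scenario_names()].
#' @param overrides Optional named list, node id -> replacement `p1`
#'   vector (length `2^k` in canonical parent order, or named
#'   configuration labels as in [cond_table()]). Values outside `[0, 1]`
#'   are rejected.
#' @return A `scenario` object: list with `name`, `description`, `model`,
#'   `expected_cells` (target -> framework cell code), `labels` and
#'   `bias_signature`.
#' @examples
#' scn <- make_scenario("fig2d")
#' framework_report(scn$model$graph)
#' @export
make_scenario <- function(name, overrides = NULL) {
  defs <- scenario_defs()
  key <- if (name %in% names(scenario_aliases)) scenario_aliases[[name]]
         else name
  def <- defs[[key]]
  if (is.null(def))
    sp_stop(sprintf("unknown scenario '%s' (known: %s)", name,
                    paste(scenario_names(), collapse = ", ")),
            "selproc_unknown_scenario")
  p <- def$p
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      sp_stop(sprintf("override(s) for unknown node(s): %s",
                      paste(bad, collapse = ", ")),
              "selproc_bad_table")
    p[names(overrides)] <- overrides
  }
  graph <- muffle_same_time(build_graph(def$nodes, def$edges))
  tables <- lapply(names(p), function(id)
    cond_table(id, parents(graph, id), p[[id]]))
  names(tables) <- names(p)
  model <- structural_model(graph, tables, def$N)
  structure(list(name = name, description = def$description, model = model,
                 expected_cells = def$expected_cells, labels = def$labels,
                 bias_signature = def$signatures),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s'\n%s\n", x$name,
              paste(strwrap(x$description, indent = 2, exdent = 2),
                    collapse = "\n")))
  print(x$model$graph)
  invisible(x)
}

#' The generating model of the hypothetical multifactorial-selection cohort
#'
#' The binary structural model behind the worked cohort example: C and U
#' are independent with P = 0.5 each; P(E=1|C,U) is 0.10, 0.30, 0.20, 0.50
#' for (C,U) = (0,0), (1,0), (0,1), (1,1); and
#' `P(D=1|E,C,U) = 0.10 * 2^E * (1.5*(1-U) + 4*U)^C`, so the risk ratio of
#' E on D is 2.0 in every stratum while U modifies the C effect (1.5 vs
#' 4.0). With a cohort of N = 4000 the expected cohort reproduces every
#' printed cell count of the worked table exactly.
#'
#' @return A [structural_model()] over nodes C0, U0, E1, D2 with
#'   `cohort_size = 4000`.
#' @examples
#' co <- expected_cohort(table1_model())
#' risk(co, "D", given = c(E1 = 1, C0 = 1, U0 = 1))  # 0.8
#' @export
table1_model <- function() make_scenario("table1")$model

# signature -> labels lookup used by the classifier for canonical labels;
# built once per session
sig_registry_env <- new.env(parent = emptyenv())

scenario_signature_registry <- function() {
  if (!is.null(sig_registry_env$reg)) return(sig_registry_env$reg)
  reg <- list()
  for (nm in names(scenario_defs())) {
    scn <- make_scenario(nm)
    reg[[graph_signature(scn$model$graph)]] <- as.list(scn$labels)
  }
  sig_registry_env$reg <- reg
  reg
}

#' Contrast true and naive effect estimates for a scenario
#'
#' Computes, on the exact expected cohort (after applying the scenario's
#' conditioning, if any, for the naive analyses):
#' * the true standardized risk ratio adjusting for all covariates,
#'   known and unknown, on the full pre-selection cohort;
#' * the crude risk ratio;
#' * the Mantel-Haenszel risk ratio adjusted for observed covariates only;
#' * the IPW risk ratio weighting on observed covariates only;
#' * the IPW risk ratio weighting on the full covariate set.
#'
#' Each naive row carries its absolute and relative bias against the
#' truth. Scenarios without a post-exposure outcome (e.g. reversed
#' causality, where only the cross-lagged association exists) yield
#' undefined estimate rows; their content lives in the signature values.
#' Every predicate of the scenario's bias signature is evaluated under
#' exact enumeration and reported with its value and pass/fail status.
#'
#' @param scenario A [make_scenario()] object.
#' @return A `bias_report`: list with `scenario`, `estimates` (data.frame
#'   rows truth/crude/adjusted_observed/ipw_observed/ipw_full with
#'   `value`, `abs_bias`, `rel_bias`) and `signatures` (data.frame with
#'   `description`, `value`, `pass`).
#' @export
bias_report <- function(scenario) {
  nd <- scenario$model$graph$nodes
  exp_nodes <- nd[nd$role == "exposure", , drop = FALSE]
  exposure <- if (nrow(exp_nodes)) exp_nodes$id[which.max(exp_nodes$time)]
              else NA_character_
  out_nodes <- nd[nd$role == "outcome" & !nd$conditioned, , drop = FALSE]
  outcome <- NA_character_
  if (!is.na(exposure) && nrow(out_nodes)) {
    later <- out_nodes[out_nodes$time > nd$time[nd$id == exposure], ,
                       drop = FALSE]
    if (nrow(later)) outcome <- later$id[which.max(later$time)]
  }
  observed <- nd$id[nd$role == "covariate"]
  full_covs <- nd$id[nd$role %in% c("covariate", "unknown_cause")]

  full <- expected_cohort(scenario$model)
  analysis <- if (length(attr(full, "conditioned"))) apply_selection(full)
              else full

  val <- function(x) if (is.null(x) || is.na(x)) NA_real_ else x
  if (!is.na(exposure) && !is.na(outcome)) {
    truth <- standardized_risk_ratio(full, exposure, outcome, full_covs)$value
    crude <- risk_ratio(analysis, exposure, outcome)[[1]]$value
    adj_obs <- mh_risk_ratio(analysis, exposure, outcome, observed)$value
    ipw_obs <- ipw_risk_ratio(analysis, exposure, outcome, observed)$value
    ipw_full <- ipw_risk_ratio(analysis, exposure, outcome, full_covs)$value
  } else {
    truth <- crude <- adj_obs <- ipw_obs <- ipw_full <- NA_real_
  }
  vals <- c(truth = val(truth), crude = val(crude),
            adjusted_observed = val(adj_obs), ipw_observed = val(ipw_obs),
            ipw_full = val(ipw_full))
  est <- data.frame(estimate = names(vals), value = unname(vals),
                    abs_bias = unname(vals) - vals[["truth"]],
                    rel_bias = unname(vals) / vals[["truth"]] - 1,
                    stringsAsFactors = FALSE)
  est$abs_bias[1] <- est$rel_bias[1] <- 0
  if (is.na(vals[["truth"]])) est$abs_bias <- est$rel_bias <- NA_real_

  sigs <- do.call(rbind, lapply(scenario$bias_signature, function(s) {
    r <- s$check(scenario)
    data.frame(description = s$description, value = r$value, pass = r$pass,
               stringsAsFactors = FALSE)
  }))

  structure(list(scenario = scenario$name, estimates = est,
                 signatures = sigs),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("bias report for scenario '%s'\n", x$scenario))
  est <- x$estimates
  est$value <- round(est$value, 4)
  est$abs_bias <- round(est$abs_bias, 4)
  est$rel_bias <- round(est$rel_bias, 4)
  print.data.frame(est, row.names = FALSE)
  cat("signatures:\n")
  sg <- x$signatures
  sg$value <- signif(sg$value, 4)
  print.data.frame(sg, row.names = FALSE)
  invisible(x)
}
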