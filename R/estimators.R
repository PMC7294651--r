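# Risk-based effect estimators computed from cohort configuration counts.
# Working from counts (not model parameters) lets the same code path serve
# exact expected cohorts and sampled finite cohorts; selection effects then
# show up as discrepancies between estimators, not as coding differences.

effect_estimate <- function(measure, value, numerator, denominator,
                            stratum = list(), method = "crude") {
  undefined <- is.na(value)
  structure(list(measure = measure,
                 value = if (undefined) NA_real_ else as.numeric(value),
                 undefined = undefined,
                 numerator_detail = numerator,
                 denominator_detail = denominator,
                 stratum = stratum, method = method),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  strat <- if (length(x$stratum))
    paste0(" | ", paste(names(x$stratum), unlist(x$stratum), sep = "=",
                        collapse = ", ")) else ""
  val <- if (x$undefined) "undefined" else format(x$value, digits = 6)
  cat(sprintf("%s (%s)%s = %s\n", x$measure, x$method, strat, val))
  invisible(x)
}

#' Convert effect estimates to a data frame
#'
#' @param x An `effect_estimate` or a list of them.
#' @param ... Unused.
#' @return data.frame with columns `measure`, `method`, `stratum`, `value`,
#'   `undefined`.
#' @export
estimates_df <- function(x, ...) {
  if (inherits(x, "effect_estimate")) x <- list(x)
  do.call(rbind, lapply(x, function(e) {
    data.frame(measure = e$measure, method = e$method,
               stratum = if (length(e$stratum))
                 paste(names(e$stratum), unlist(e$stratum), sep = "=",
                       collapse = ",") else "",
               value = e$value, undefined = e$undefined,
               stringsAsFactors = FALSE)
  }))
}

restrict_counts <- function(cohort, given) {
  d <- cohort_active(cohort)
  if (length(given)) {
    ids <- resolve_vars(cohort_vars(cohort), names(given))
    for (i in seq_along(ids)) d <- d[d[[ids[i]]] == as.integer(given[[i]]), ,
                                     drop = FALSE]
  }
  d
}

count_where <- function(d, var, value) sum(d$count[d[[var]] == value])

#' Risk of an outcome in a (restricted) cohort
#'
#' `count(outcome = 1 & given) / count(given)`. A zero denominator yields
#' an undefined estimate (value `NA`), not an error.
#'
#' @param cohort A `cohort`.
#' @param outcome Outcome node id or unambiguous variable symbol.
#' @param given Optional named 0/1 restriction (e.g. `list(E = 1, C = 0)`).
#' @return An `effect_estimate` with `measure = "risk"`.
#' @export
risk <- function(cohort, outcome, given = NULL) {
  outcome <- resolve_vars(cohort_vars(cohort), outcome)
  d <- restrict_counts(cohort, given %||% list())
  num <- count_where(d, outcome, 1L)
  den <- sum(d$count)
  effect_estimate("risk", if (den > 0) num / den else NA_real_,
                  num, den, as.list(given %||% list()), "crude")
}

strata_grid <- function(cohort, strata) {
  if (!length(strata)) return(list(list()))
  ids <- resolve_vars(cohort_vars(cohort), strata)
  cfg <- binary_configs(length(ids), ids)
  lapply(seq_len(nrow(cfg)), function(i) as.list(cfg[i, , drop = FALSE]))
}

rr_in <- function(cohort, exposure, outcome, stratum, method) {
  d <- restrict_counts(cohort, stratum)
  a  <- sum(d$count[d[[exposure]] == 1L & d[[outcome]] == 1L])
  n1 <- count_where(d, exposure, 1L)
  c_ <- sum(d$count[d[[exposure]] == 0L & d[[outcome]] == 1L])
  n0 <- count_where(d, exposure, 0L)
  val <- if (n1 > 0 && n0 > 0 && c_ > 0) (a / n1) / (c_ / n0) else NA_real_
  effect_estimate("risk_ratio", val,
                  list(exposed_cases = a, exposed_total = n1),
                  list(unexposed_cases = c_, unexposed_total = n0),
                  stratum, method)
}

#' Crude and stratum-specific risk ratios
#'
#' With an empty `strata` list, the crude risk ratio of `exposure` on
#' `outcome`; otherwise one estimate per joint stratum of the stratifying
#' variables (collapsing over everything else).
#'
#' @param cohort A `cohort`.
#' @param exposure,outcome Node ids or unambiguous variable symbols.
#' @param strata Character vector of stratifying variables (possibly empty).
#' @return A list of `effect_estimate`s (length 1 when `strata` is empty).
#' @seealso [mh_risk_ratio()], [standardized_risk_ratio()],
#'   [ipw_risk_ratio()]
#' @export
risk_ratio <- function(cohort, exposure, outcome, strata = character()) {
  vars <- cohort_vars(cohort)
  exposure <- resolve_vars(vars, exposure)
  outcome <- resolve_vars(vars, outcome)
  method <- if (length(strata)) "stratified" else "crude"
  lapply(strata_grid(cohort, strata), function(s)
    rr_in(cohort, exposure, outcome, s, method))
}

#' Mantel-Haenszel common risk ratio
#'
#' The standard stratified summary
#' \deqn{RR_{MH} = \frac{\sum_i a_i n_{0i}/T_i}{\sum_i c_i n_{1i}/T_i}}
#' with \eqn{a_i, c_i} exposed/unexposed cases, \eqn{n_{1i}, n_{0i}} the arm
#' totals and \eqn{T_i} the stratum total. Uninformative strata (zero
#' total) contribute nothing; if all strata are uninformative the estimate
#' is undefined.
#'
#' @inheritParams risk_ratio
#' @return A single `effect_estimate` with `method = "mantel_haenszel"`.
#' @export
mh_risk_ratio <- function(cohort, exposure, outcome, strata = character()) {
  vars <- cohort_vars(cohort)
  exposure <- resolve_vars(vars, exposure)
  outcome <- resolve_vars(vars, outcome)
  num <- den <- 0
  for (s in strata_grid(cohort, strata)) {
    d <- restrict_counts(cohort, s)
    Ti <- sum(d$count)
    if (Ti <= 0) next
    a  <- sum(d$count[d[[exposure]] == 1L & d[[outcome]] == 1L])
    n1 <- count_where(d, exposure, 1L)
    c_ <- sum(d$count[d[[exposure]] == 0L & d[[outcome]] == 1L])
    n0 <- count_where(d, exposure, 0L)
    num <- num + a * n0 / Ti
    den <- den + c_ * n1 / Ti
  }
  effect_estimate("risk_ratio", if (den > 0) num / den else NA_real_,
                  list(mh_numerator = num), list(mh_denominator = den),
                  list(), "mantel_haenszel")
}

#' Standardized (weighted-average-risk) risk ratio
#'
#' Ratio of stratum-weighted average risks under a common stratum weight
#' distribution: total population (the marginal/causal contrast under
#' exchangeability given the strata), the exposed, or the unexposed.
#'
#' @inheritParams risk_ratio
#' @param weight_source `"total"`, `"exposed"` or `"unexposed"` — whose
#'   stratum distribution supplies the weights.
#' @return A single `effect_estimate` with `method = "standardized"`.
#' @export
standardized_risk_ratio <- function(cohort, exposure, outcome,
                                    strata = character(),
                                    weight_source = c("total", "exposed",
                                                      "unexposed")) {
  weight_source <- match.arg(weight_source)
  vars <- cohort_vars(cohort)
  exposure <- resolve_vars(vars, exposure)
  outcome <- resolve_vars(vars, outcome)
  w_r1 <- w_r0 <- w_tot <- 0
  for (s in strata_grid(cohort, strata)) {
    d <- restrict_counts(cohort, s)
    a  <- sum(d$count[d[[exposure]] == 1L & d[[outcome]] == 1L])
    n1 <- count_where(d, exposure, 1L)
    c_ <- sum(d$count[d[[exposure]] == 0L & d[[outcome]] == 1L])
    n0 <- count_where(d, exposure, 0L)
    w <- switch(weight_source, total = n1 + n0, exposed = n1, unexposed = n0)
    if (w <= 0) next
    if (n1 <= 0 || n0 <= 0)
      return(effect_estimate("risk_ratio", NA_real_, list(), list(), list(),
                             "standardized"))
    w_r1 <- w_r1 + w * a / n1
    w_r0 <- w_r0 + w * c_ / n0
    w_tot <- w_tot + w
  }
  val <- if (w_tot > 0 && w_r0 > 0) w_r1 / w_r0 else NA_real_
  effect_estimate("risk_ratio", val,
                  list(weighted_risk_exposed = w_r1 / max(w_tot, 1)),
                  list(weighted_risk_unexposed = w_r0 / max(w_tot, 1)),
                  list(), "standardized")
}

#' Odds ratio between two binary variables
#'
#' Cross-product ratio of the 2x2 table of `a` by `b` within an optional
#' restriction — the lens for induced (collider) associations such as the
#' inverse C-U association within strata of exposure. Zero cells give an
#' undefined estimate; no continuity correction is applied.
#'
#' @param cohort A `cohort`.
#' @param a,b Node ids or unambiguous variable symbols (must differ).
#' @param given Optional named 0/1 restriction.
#' @return An `effect_estimate` with `measure = "odds_ratio"`.
#' @export
odds_ratio <- function(cohort, a, b, given = NULL) {
  vars <- cohort_vars(cohort)
  a <- resolve_vars(vars, a)
  b <- resolve_vars(vars, b)
  if (a == b)
    sp_stop("odds ratio of a variable with itself is degenerate",
            "selproc_bad_estimate")
  d <- restrict_counts(cohort, given %||% list())
  n11 <- sum(d$count[d[[a]] == 1L & d[[b]] == 1L])
  n10 <- sum(d$count[d[[a]] == 1L & d[[b]] == 0L])
  n01 <- sum(d$count[d[[a]] == 0L & d[[b]] == 1L])
  n00 <- sum(d$count[d[[a]] == 0L & d[[b]] == 0L])
  val <- if (min(n11, n10, n01, n00) > 0) (n11 * n00) / (n10 * n01)
         else NA_real_
  effect_estimate("odds_ratio", val, list(n11 = n11, n00 = n00),
                  list(n10 = n10, n01 = n01), as.list(given %||% list()),
                  "crude")
}

#' Inverse-probability-weighted risk ratio
#'
#' Weights each individual by the inverse probability of the exposure level
#' actually received given the covariates, creating a pseudo-population in
#' which exposure is unconfounded by those covariates, then takes the crude
#' risk ratio on the weighted counts. IPW is the preferred analytic
#' correction for factors causing selection, since regression adjustment
#' can open new backdoor paths by conditioning on colliders.
#'
#' Propensities are saturated empirical frequencies per covariate pattern
#' (`weight_source = "fitted"`, the default) — no parametric model is
#' imposed — or exact model-implied probabilities
#' (`weight_source = "true_model"`, requires `model`), which can include
#' unknown causes an analyst could not observe.
#'
#' @inheritParams risk_ratio
#' @param covariates Character vector of covariate variables to weight on.
#' @param weight_source `"fitted"` or `"true_model"`.
#' @param model A [structural_model()]; required for `"true_model"`.
#' @return A single `effect_estimate` with `method = "ipw"`.
#' @export
ipw_risk_ratio <- function(cohort, exposure, outcome, covariates,
                           weight_source = c("fitted", "true_model"),
                           model = NULL) {
  weight_source <- match.arg(weight_source)
  vars <- cohort_vars(cohort)
  exposure <- resolve_vars(vars, exposure)
  outcome <- resolve_vars(vars, outcome)
  covariates <- resolve_vars(vars, covariates)
  d <- cohort_active(cohort)

  if (weight_source == "fitted") {
    key <- if (length(covariates)) interaction(d[covariates], drop = FALSE)
           else factor(rep(1L, nrow(d)))
    tot <- tapply(d$count, key, sum)
    exp1 <- tapply(d$count * (d[[exposure]] == 1L), key, sum)
    p1 <- as.numeric(exp1[as.character(key)] / tot[as.character(key)])
  } else {
    if (is.null(model))
      sp_stop("`model` required when weight_source = \"true_model\"",
              "selproc_bad_estimate")
    joint <- enumerate_joint(model)
    p1 <- vapply(seq_len(nrow(d)), function(i) {
      given <- as.list(d[i, covariates, drop = FALSE])
      prob_event(joint, stats::setNames(list(1L), exposure), given)
    }, 0)
  }
  p_obs <- ifelse(d[[exposure]] == 1L, p1, 1 - p1)
  if (any(d$count > 0 & p_obs <= 0))
    sp_stop("zero estimated propensity for an observed configuration",
            "selproc_zero_mass")
  w <- ifelse(d$count > 0, 1 / p_obs, 0)
  wc <- d$count * w
  a  <- sum(wc[d[[exposure]] == 1L & d[[outcome]] == 1L])
  n1 <- sum(wc[d[[exposure]] == 1L])
  c_ <- sum(wc[d[[exposure]] == 0L & d[[outcome]] == 1L])
  n0 <- sum(wc[d[[exposure]] == 0L])
  val <- if (n1 > 0 && n0 > 0 && c_ > 0) (a / n1) / (c_ / n0) else NA_real_
  effect_estimate("risk_ratio", val,
                  list(weighted_exposed_cases = a, weighted_exposed = n1),
                  list(weighted_unexposed_cases = c_, weighted_unexposed = n0),
                  list(), "ipw")
}
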