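# Registry of the named in-silico perturbation scenarios. Each entry is the
# exact override set applied on top of the baseline parameterization.
.scenarioRegistry <- function() {
  rec <- function(description, overrides) list(description = description,
                                               overrides = overrides)
  kd <- list(inputOverride("c", 0))
  crosstalkOff <- list(
    weightOverride("pdgfrA", "c", 0),
    weightOverride("pdgfrB", "cdh11", 0),
    weightOverride("dusp1", "Bcat", 0))
  receptorOff <- list(
    weightOverride("pdgfrA", "c", 0),
    weightOverride("pdgfrB", "cdh11", 0))
  downstreamOff <- list(weightOverride("dusp1", "Bcat", 0))
  list(
    "baseline" = rec(
      "All interactions active; unaltered baseline parameterization.",
      list()),
    "cadherin-11-knockdown" = rec(
      paste("Full cadherin-11 knockdown: cell-cell contact input c set to 0",
            "so cadherin-11 can never become active."),
      kd),
    "contact-off-pdgfra-binding-off" = rec(
      paste("Cadherin-11 cannot dimerize with adjacent-cell cadherin-11 or",
            "bind PDGFR-alpha (c=0, beta-catenin inhibition released), but",
            "still inhibits PDGFR-beta; cdh11 held at its baseline steady",
            "level 0.18."),
      list(inputOverride("c", 0),
           weightOverride("Bcat", "cdh11", 0),
           clampOverride("cdh11", 0.18))),
    "contact-off-pdgfrb-binding-off" = rec(
      paste("Cadherin-11/PDGFR-beta membrane interaction blocked: the",
            "contact input can no longer activate the cdh11 node, while",
            "PDGFR-alpha binding via c stays possible."),
      list(weightOverride("cdh11", "c", 0))),
    "crosstalk-disabled" = rec(
      paste("All crosstalk removed: PDGFR-alpha activation by cadherin-11,",
            "PDGFR-beta inhibition by cadherin-11, and DUSP1 inhibition by",
            "beta-catenin."),
      crosstalkOff),
    "crosstalk-disabled+kd" = rec(
      "Crosstalk disabled combined with the cadherin-11 knockdown (c=0).",
      c(crosstalkOff, kd)),
    "receptor-disabled" = rec(
      "Receptor-level crosstalk only removed (PDGFR-alpha/-beta edges).",
      receptorOff),
    "receptor-disabled+kd" = rec(
      "Receptor-level crosstalk removed plus cadherin-11 knockdown (c=0).",
      c(receptorOff, kd)),
    "downstream-disabled" = rec(
      "Downstream crosstalk only removed (beta-catenin -| DUSP1).",
      downstreamOff),
    "downstream-disabled+kd" = rec(
      "Downstream crosstalk removed plus cadherin-11 knockdown (c=0).",
      c(downstreamOff, kd))
  )
}

#' Named perturbation scenarios
#'
#' `scenarioNames()` lists the registered in-silico experiments;
#' `makeScenario()` returns one scenario as a list with elements `name`,
#' `description` and `overrides` (a list of [overrides]); `runScenario()`
#' solves both the baseline and the perturbed network to steady state and
#' tabulates the comparison.
#'
#' The registered scenarios are the baseline, the full cadherin-11
#' knockdown (`c = 0`), two receptor-binding-blocked setups
#' (`contact-off-pdgfra-binding-off`, which also clamps cdh11 at its
#' baseline steady level 0.18, and `contact-off-pdgfrb-binding-off`), and
#' the crosstalk-ablation setups (`crosstalk-disabled`,
#' `receptor-disabled`, `downstream-disabled`), each also in a `+kd`
#' variant combined with the knockdown.
#'
#' Because the percent change depends on the denominator, both conventions
#' are reported: `pct_vs_baseline` is \eqn{100(s-b)/b} and
#' `pct_vs_scenario` is \eqn{100(s-b)/s} (NA where the denominator is 0).
#' The direction label is `increase` if \eqn{s-b > \epsilon}, `decrease` if
#' \eqn{s-b < -\epsilon}, else `unchanged`.
#'
#' @param name a registered scenario name.
#' @param epsilon tolerance below which a change counts as `unchanged`
#'   (default 0.01).
#' @param tolerance steady-state convergence tolerance, passed to the
#'   solver.
#' @param method `"integration"` ([steadyState()]) or `"fixed-point"`
#'   ([algebraicFixedPoint()]).
#' @param network the unperturbed network (default [baselineNetwork()]).
#' @return `runScenario()` returns a data.frame with one row per node and
#'   columns `node`, `baseline_ss`, `scenario_ss`, `diff`,
#'   `pct_vs_baseline`, `pct_vs_scenario`, `direction`; its attributes
#'   `scenario` and `epsilon` record the setup.
#' @examples
#' scenarioNames()
#' cmp <- runScenario("cadherin-11-knockdown")
#' subset(cmp, node %in% c("pdgfrA", "pdgfrB"))
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenarioNames <- function() names(.scenarioRegistry())

#' @rdname scenarios
#' @export
makeScenario <- function(name) {
  reg <- .scenarioRegistry()
  if (length(name) != 1L || !name %in% names(reg))
    stop(sprintf("unknown scenario '%s'; registered scenarios: %s",
                 paste(name, collapse = ", "),
                 paste(names(reg), collapse = ", ")))
  c(list(name = name), reg[[name]])
}

.solveSS <- function(network, tolerance, method) {
  rep <- switch(method,
    "integration" = steadyState(network, tolerance = tolerance),
    "fixed-point" = algebraicFixedPoint(network, tolerance = tolerance),
    stop("method must be 'integration' or 'fixed-point'"))
  if (!converged(rep))
    stop(sprintf("steady-state solve did not converge (residual %.3g)",
                 residual(rep)))
  rep
}

.direction <- function(diff, epsilon) {
  ifelse(diff > epsilon, "increase",
         ifelse(diff < -epsilon, "decrease", "unchanged"))
}

#' @rdname scenarios
#' @export
runScenario <- function(name, epsilon = 0.01, tolerance = 1e-9,
                        method = c("integration", "fixed-point"),
                        network = baselineNetwork()) {
  method <- match.arg(method)
  sc <- makeScenario(name)
  base <- activities(.solveSS(network, tolerance, method))
  pert <- applyOverrides(network, sc$overrides)
  scen <- activities(.solveSS(pert, tolerance, method))
  d <- scen - base
  out <- data.frame(
    node = names(base),
    baseline_ss = unname(base),
    scenario_ss = unname(scen),
    diff = unname(d),
    pct_vs_baseline = unname(ifelse(base != 0, 100 * d / base, NA_real_)),
    pct_vs_scenario = unname(ifelse(scen != 0, 100 * d / scen, NA_real_)),
    direction = .direction(unname(d), epsilon),
    stringsAsFactors = FALSE)
  attr(out, "scenario") <- name
  attr(out, "epsilon") <- epsilon
  out
}

#' Cadherin-11 knockdown efficiency sweep
#'
#' A knockdown of efficiency \eqn{e} scales the cell--cell contact input to
#' \eqn{(1-e)\,c}; the same-cell cdh11 node then tracks the reduced input
#' through its own dynamics. Efficiency 0 is the baseline and efficiency 1
#' the full knockdown.
#'
#' @param efficiencies numeric vector of knockdown efficiencies in
#'   \eqn{[0,1]} (default the panel `c(0.25, 0.5, 0.75, 0.8, 1)`).
#' @param tolerance,method steady-state solver settings (see [scenarios]).
#' @param network the unperturbed network.
#' @return data.frame with columns `efficiency`, `pdgfrA`, `pdgfrB`
#'   (steady-state receptor activities).
#' @examples
#' knockdownEfficiencySweep(c(0, 0.5, 1))
#' @export
knockdownEfficiencySweep <- function(efficiencies = c(0.25, 0.5, 0.75, 0.8, 1),
                                     tolerance = 1e-9,
                                     method = c("integration", "fixed-point"),
                                     network = baselineNetwork()) {
  method <- match.arg(method)
  if (anyNA(efficiencies) || any(efficiencies < 0 | efficiencies > 1))
    stop("knockdown efficiencies must lie in [0, 1]")
  c0 <- networkInputs(network)[["c"]]
  rows <- lapply(efficiencies, function(e) {
    net <- applyOverrides(network, list(inputOverride("c", (1 - e) * c0)))
    ss <- activities(.solveSS(net, tolerance, method))
    data.frame(efficiency = e, pdgfrA = unname(ss[["pdgfrA"]]),
               pdgfrB = unname(ss[["pdgfrB"]]))
  })
  do.call(rbind, rows)
}

#' Proliferation readout from a steady state
#'
#' The change-in-proliferation statistic is the difference
#' \eqn{\Delta =} cyclin-D1 minus ERK steady-state activity: \eqn{\Delta >
#' \epsilon} is classified as increased proliferation, \eqn{\Delta <
#' -\epsilon} as decreased, otherwise unchanged. The default
#' \eqn{\epsilon = 0.01} makes the baseline gap (\eqn{\approx -0.007})
#' classify as no change, matching the convention that baseline cyclin-D1
#' and ERK activities are numerically equal.
#'
#' @param state a named activity vector or a [SteadyStateReport-class]
#'   containing `erk` and `cyclinD1`.
#' @param epsilon positive classification tolerance (default 0.01).
#' @return list of class `ProliferationReadout` with elements `delta`,
#'   `label` (`"increased"`, `"decreased"` or `"unchanged"`) and `epsilon`.
#' @examples
#' proliferationChange(steadyState(baselineNetwork()))
#' @export
proliferationChange <- function(state, epsilon = 0.01) {
  if (is(state, "SteadyStateReport")) state <- activities(state)
  if (!all(c("erk", "cyclinD1") %in% names(state)))
    stop("state must contain 'erk' and 'cyclinD1' activities")
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon <= 0)
    stop("epsilon must be a single positive number")
  delta <- unname(state[["cyclinD1"]] - state[["erk"]])
  label <- if (delta > epsilon) "increased"
           else if (delta < -epsilon) "decreased" else "unchanged"
  structure(list(delta = delta, label = label, epsilon = epsilon),
            class = "ProliferationReadout")
}

#' @export
print.ProliferationReadout <- function(x, ...) {
  cat(sprintf("Proliferation change: delta = %.4f -> %s (epsilon = %g)\n",
              x$delta, x$label, x$epsilon))
  invisible(x)
}
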