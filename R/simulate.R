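# Precompile a network into index/weight vectors so the ODE right-hand side
# avoids name lookups inside the integrator. Lookup vector layout:
# c(node activities, external inputs).
.compileNetwork <- function(network) {
  nms <- nodeNames(network)
  lookup <- c(nms, names(network@inputs))
  nodes <- lapply(network@nodes, function(n) {
    act <- n@activators[n@activators$norm > 0, , drop = FALSE]
    inh <- n@inhibitors[n@inhibitors$norm > 0, , drop = FALSE]
    list(actIdx = match(act$source, lookup), actW = act$weight,
         actNorm = sum(act$norm),
         inhIdx = match(inh$source, lookup), inhW = inh$weight,
         inhNorm = sum(inh$norm),
         constitutive = n@constitutive)
  })
  list(
    names = nms,
    nodes = nodes,
    gain = network@gain,
    decay = vapply(network@nodes, function(n) n@decay, numeric(1)),
    initial = vapply(network@nodes, function(n) n@initial, numeric(1)),
    clamp = vapply(network@nodes, function(n) n@clamp, numeric(1)),
    inputVals = unname(network@inputs)
  )
}

# Unchecked activation response for the compiled path: the integrator may
# probe trial states a round-off outside [0,1], so the RHS is extended
# continuously by clamping instead of erroring like activationResponse().
.activationRaw <- function(omega, gain) {
  e <- exp(-gain * (omega - 0.5))
  (-exp(0.5 * gain) + e) / ((1 - exp(0.5 * gain)) * (1 + e))
}

.compiledOmegas <- function(cn, state) {
  full <- c(pmin(pmax(state, 0), 1), cn$inputVals)
  vapply(cn$nodes, function(nd) {
    if (length(nd$actIdx) == 0) {
      a <- if (nd$constitutive) 1 else 0
    } else {
      s <- sum(full[nd$actIdx] * nd$actW)
      a <- (1 + nd$actNorm) / nd$actNorm * s / (1 + s)
    }
    if (length(nd$inhIdx) == 0) {
      i <- 1
    } else {
      s <- sum(nd$inhW * full[nd$inhIdx])
      i <- 1 - (1 + nd$inhNorm) / nd$inhNorm * s / (1 + s)
    }
    a * i
  }, numeric(1))
}

.compiledDerivs <- function(cn, state) {
  om <- pmin(pmax(.compiledOmegas(cn, state), 0), 1)
  d <- .activationRaw(om, cn$gain) - cn$decay * state
  d[!is.na(cn$clamp)] <- 0
  d
}

.initialState <- function(cn) {
  x <- cn$initial
  cl <- !is.na(cn$clamp)
  x[cl] <- cn$clamp[cl]
  stats::setNames(x, cn$names)
}

# Activities can leave [0,1] only by integrator round-off; snap those back
# and fail loudly on anything larger.
.snapUnit <- function(x, slack = 1e-8, context = "state") {
  if (any(x < -slack | x > 1 + slack))
    stop(sprintf("%s left [0,1] by more than %g; integration failed", context,
                 slack))
  pmin(pmax(x, 0), 1)
}

#' Simulate a logic-ODE network trajectory
#'
#' Integrates the system \eqn{dX_i/dt = f_h(\omega_i) - k_i X_i} from the
#' nodes' initial activities with `deSolve::ode()` (lsoda). Clamped nodes are
#' held constant at their clamp value while remaining visible to the omega
#' functions of the other nodes. Time is in the arbitrary units of the
#' formalism (the relaxation scale is \eqn{1/k_i}); only steady states carry
#' quantitative meaning.
#'
#' @param network a [LogicNetwork-class].
#' @param tEnd positive end time.
#' @param nSteps number of reported time points after 0 (default 200).
#' @param initial optional named numeric vector overriding the nodes'
#'   declared initial activities (clamped nodes stay at their clamp).
#' @param rtol,atol relative/absolute integrator tolerances.
#' @return data.frame with a `time` column and one activity column per node;
#'   every reported activity lies in \eqn{[0,1]}.
#' @examples
#' traj <- simulateNetwork(baselineNetwork(), tEnd = 20)
#' tail(traj, 1)
#' @export
simulateNetwork <- function(network, tEnd = 100, nSteps = 200, initial = NULL,
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(is(network, "LogicNetwork"))
  if (!is.numeric(tEnd) || length(tEnd) != 1L || tEnd <= 0)
    stop("tEnd must be a single positive number")
  cn <- .compileNetwork(network)
  x0 <- .initialState(cn)
  if (!is.null(initial)) {
    if (!all(names(initial) %in% cn$names))
      stop("initial overrides refer to unknown nodes")
    x0[names(initial)] <- as.numeric(initial)
    cl <- !is.na(cn$clamp)
    x0[cl] <- cn$clamp[cl]
    if (any(x0 < 0 | x0 > 1)) stop("initial activities must lie in [0, 1]")
  }
  times <- seq(0, tEnd, length.out = nSteps + 1)
  rhs <- function(t, y, parms) list(.compiledDerivs(cn, y))
  sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; see deSolve diagnostics")
  out <- as.data.frame(sol)
  out[cn$names] <- .snapUnit(as.matrix(out[cn$names]), context = "trajectory")
  out
}

#' Steady state by relaxation
#'
#' Integrates the network in chunks until the maximum absolute
#' time-derivative over free nodes falls below `tolerance`, or the time cap
#' `tEnd` is reached (reported as non-converged, never silently). The result
#' can be cross-checked against the independent [algebraicFixedPoint()]
#' solver.
#'
#' @param network a [LogicNetwork-class].
#' @param tolerance convergence threshold on \eqn{\max_i |dX_i/dt|}
#'   (default 1e-9).
#' @param tEnd time cap in arbitrary units (default 200; the relaxation
#'   scale of the system is \eqn{1/k \approx 1}).
#' @param initial optional named initial-state override (see
#'   [simulateNetwork()]).
#' @param chunk integration time per convergence check (default 25).
#' @return a [SteadyStateReport-class] with `method = "integration"`.
#' @examples
#' rep <- steadyState(baselineNetwork())
#' activities(rep)
#' @export
steadyState <- function(network, tolerance = 1e-9, tEnd = 200, initial = NULL,
                        chunk = 25) {
  stopifnot(is(network, "LogicNetwork"))
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("tolerance must be a single positive number")
  cn <- .compileNetwork(network)
  x <- .initialState(cn)
  if (!is.null(initial)) {
    if (!all(names(initial) %in% cn$names))
      stop("initial overrides refer to unknown nodes")
    x[names(initial)] <- as.numeric(initial)
    cl <- !is.na(cn$clamp)
    x[cl] <- cn$clamp[cl]
    if (any(x < 0 | x > 1)) stop("initial activities must lie in [0, 1]")
  }
  rhs <- function(t, y, parms) list(.compiledDerivs(cn, y))
  t <- 0
  res <- max(abs(.compiledDerivs(cn, x)))
  while (res > tolerance && t < tEnd) {
    span <- min(chunk, tEnd - t)
    sol <- deSolve::ode(y = x, times = c(0, span), func = rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-12)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed while seeking the steady state")
    x <- .snapUnit(sol[nrow(sol), cn$names], context = "state")
    t <- t + span
    res <- max(abs(.compiledDerivs(cn, x)))
  }
  new("SteadyStateReport",
      activities = stats::setNames(as.numeric(x), cn$names),
      time = t, converged = res <= tolerance, residual = res,
      tolerance = tolerance, method = "integration")
}

#' Steady state by damped algebraic fixed-point iteration
#'
#' Independent cross-check for [steadyState()]: a steady state of the
#' logic-ODE system solves \eqn{X_i = f_h(\omega_i(X))/k_i}, so the solver
#' iterates \eqn{X \leftarrow (1-\lambda)X + \lambda\, f_h(\omega(X))/k}
#' per node. Negative-feedback loops (ERK--DUSP1 in the baseline network)
#' make the undamped map oscillate, hence the default damping
#' \eqn{\lambda = 0.5}; if the residual stalls, the damping is halved
#' automatically (down to 1/32 of the starting value) before giving up.
#' Clamped nodes are held at their clamp value.
#'
#' @param network a [LogicNetwork-class].
#' @param damping step fraction \eqn{\lambda \in (0,1]} (default 0.5).
#' @param tolerance convergence threshold on \eqn{\max_i |dX_i/dt|} at the
#'   iterate (default 1e-10).
#' @param maxIter iteration cap (default 100000).
#' @param initial optional named initial-state override.
#' @return a [SteadyStateReport-class] with `method = "fixed-point"`.
#' @examples
#' fp <- algebraicFixedPoint(baselineNetwork())
#' max(abs(activities(fp) - activities(steadyState(baselineNetwork()))))
#' @export
algebraicFixedPoint <- function(network, damping = 0.5, tolerance = 1e-10,
                                maxIter = 100000, initial = NULL) {
  stopifnot(is(network, "LogicNetwork"))
  if (!is.numeric(damping) || length(damping) != 1L || damping <= 0 ||
      damping > 1)
    stop("damping must lie in (0, 1]")
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("tolerance must be a single positive number")
  cn <- .compileNetwork(network)
  x <- .initialState(cn)
  if (!is.null(initial)) {
    if (!all(names(initial) %in% cn$names))
      stop("initial overrides refer to unknown nodes")
    x[names(initial)] <- as.numeric(initial)
    cl <- !is.na(cn$clamp)
    x[cl] <- cn$clamp[cl]
    if (any(x < 0 | x > 1)) stop("initial activities must lie in [0, 1]")
  }
  free <- is.na(cn$clamp)
  lam <- damping
  minLam <- damping / 32
  bestRes <- Inf
  sinceImprove <- 0L
  it <- 0L
  res <- Inf
  while (it < maxIter) {
    it <- it + 1L
    om <- pmin(pmax(.compiledOmegas(cn, x), 0), 1)
    target <- .activationRaw(om, cn$gain) / cn$decay
    res <- max(abs((target - x)[free] * cn$decay[free]), 0)
    if (res <= tolerance) break
    x[free] <- (1 - lam) * x[free] + lam * target[free]
    # damped iterates of a map into [0,1]/k stay bounded, but guard anyway
    x <- pmin(pmax(x, 0), 1)
    if (res < bestRes * 0.999) {
      bestRes <- res
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
      if (sinceImprove >= 500L && lam > minLam) {
        lam <- lam / 2   # oscillation: damp harder
        sinceImprove <- 0L
      }
    }
  }
  new("SteadyStateReport",
      activities = stats::setNames(as.numeric(x), cn$names),
      time = as.numeric(it), converged = res <= tolerance, residual = res,
      tolerance = tolerance, method = "fixed-point")
}
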