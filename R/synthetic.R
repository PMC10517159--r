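# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random logic-ODE network
#'
#' Samples a network in the same formalism as the curated model so engine
#' properties (trajectory boundedness, solver agreement, independence from
#' initial conditions) can be tested far beyond a single topology. Every
#' ordered node pair (self-loops included) receives an activator edge with
#' probability `pActivator` and, independently, an inhibitor edge with
#' probability `pInhibitor`; every node draws edges from the external
#' inputs the same way. Weights are sampled log-uniformly on `weightRange`
#' (default \eqn{[0.1, 10]}, the scan range), decays uniformly on
#' `decayRange` (default \eqn{[1, 2]}, bracketing the curated values),
#' input levels and initial activities uniformly on \eqn{[0,1]}. Nodes left
#' without activators become constitutive with probability
#' `pConstitutive`, otherwise they stay silent (and simply decay). Feedback
#' loops are permitted — the curated network itself contains one — which is
#' why the fixed-point solver always iterates damped.
#'
#' @param nNodes number of nodes (>= 1).
#' @param nInputs number of external inputs (>= 0).
#' @param pActivator,pInhibitor per-pair edge probabilities in \eqn{[0,1]}.
#' @param weightRange,decayRange positive ranges for sampled weights and
#'   decays.
#' @param pConstitutive probability that an activator-less node is flagged
#'   constitutive.
#' @param seed integer seed; the same seed reproduces the identical
#'   network. The caller's RNG state is left untouched.
#' @return a validated [LogicNetwork-class] with nodes `n1, n2, ...` and
#'   inputs `u1, u2, ...`.
#' @examples
#' net <- randomNetwork(5, seed = 42)
#' identical(net, randomNetwork(5, seed = 42))
#' @export
randomNetwork <- function(nNodes, nInputs = 2, pActivator = 0.25,
                          pInhibitor = 0.15, weightRange = c(0.1, 10),
                          decayRange = c(1, 2), pConstitutive = 0.5,
                          seed = NULL) {
  if (!is.numeric(nNodes) || length(nNodes) != 1L || nNodes < 1)
    stop("nNodes must be a positive integer")
  if (nInputs < 0) stop("nInputs must be non-negative")
  probs <- c(pActivator, pInhibitor, pConstitutive)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(weightRange <= 0) || any(decayRange <= 0))
    stop("weightRange and decayRange must be positive")
  .withSeed(seed, {
    nodeIds <- paste0("n", seq_len(nNodes))
    inputIds <- if (nInputs > 0) paste0("u", seq_len(nInputs)) else character(0)
    sources <- c(nodeIds, inputIds)
    rWeight <- function(n) exp(stats::runif(n, log(weightRange[1]),
                                            log(weightRange[2])))
    nodes <- lapply(nodeIds, function(id) {
      isAct <- stats::runif(length(sources)) < pActivator
      isInh <- stats::runif(length(sources)) < pInhibitor
      act <- if (any(isAct)) {
        stats::setNames(rWeight(sum(isAct)), sources[isAct])
      } else NULL
      inh <- if (any(isInh)) {
        stats::setNames(rWeight(sum(isInh)), sources[isInh])
      } else NULL
      constitutive <- is.null(act) && stats::runif(1) < pConstitutive
      logicNode(id, activators = act, inhibitors = inh,
                decay = stats::runif(1, decayRange[1], decayRange[2]),
                initial = stats::runif(1), constitutive = constitutive)
    })
    inputs <- if (nInputs > 0) {
      stats::setNames(stats::runif(nInputs), inputIds)
    } else numeric(0)
    logicNetwork(nodes = nodes, inputs = inputs, gain = 1)
  })
}

#' Randomly perturb all edge weights of a network
#'
#' Multiplies every activator and inhibitor weight by an independent draw
#' from `range` (log-uniform), leaving the topology, decays, inputs and
#' initial activities unchanged. Used to fuzz the solver-agreement
#' property around a given topology.
#'
#' @param network a [LogicNetwork-class].
#' @param range positive multiplier interval; `c(1, 1)` leaves the network
#'   unchanged.
#' @param seed integer seed for reproducible draws.
#' @return a validated [LogicNetwork-class] copy.
#' @examples
#' p <- perturbWeights(baselineNetwork(), c(0.5, 2), seed = 7)
#' identical(p, perturbWeights(baselineNetwork(), c(0.5, 2), seed = 7))
#' @export
perturbWeights <- function(network, range = c(0.5, 2), seed = NULL) {
  stopifnot(is(network, "LogicNetwork"))
  if (length(range) != 2L || any(range <= 0) || range[2] < range[1])
    stop("range must be a positive interval c(lo, hi)")
  .withSeed(seed, {
    mult <- function(edges) {
      m <- exp(stats::runif(nrow(edges), log(range[1]), log(range[2])))
      edges$weight <- edges$weight * m
      edges$norm <- edges$norm * m
      edges
    }
    network@nodes <- lapply(network@nodes, function(n) {
      if (nrow(n@activators)) n@activators <- mult(n@activators)
      if (nrow(n@inhibitors)) n@inhibitors <- mult(n@inhibitors)
      n
    })
    validObject(network)
    network
  })
}

#' Write a reproducible corpus of random networks
#'
#' Generates `n` random networks from consecutive seeds derived from
#' `seed` and writes each to `<dir>/network_<i>.json` in the standard JSON
#' format, for use as an external test corpus.
#'
#' @param dir output directory (created if missing).
#' @param n number of networks.
#' @param nNodes nodes per network.
#' @param seed base integer seed.
#' @param ... further arguments passed to [randomNetwork()].
#' @return invisibly, the vector of file paths written.
#' @export
writeNetworkCorpus <- function(dir, n = 10, nNodes = 10, seed = 1, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_len(n), function(i) {
    net <- randomNetwork(nNodes, seed = seed + i - 1, ...)
    p <- file.path(dir, sprintf("network_%03d.json", i))
    writeNetworkJSON(net, p)
    p
  }, character(1))
  invisible(paths)
}
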