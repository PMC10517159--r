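#' Normalized sigmoidal activation response
#'
#' Maps a total input \eqn{\omega \in [0,1]} to an activation rate in
#' \eqn{[0,1]} through the normalized logistic response of the continuous
#' logical (Mendoza--Xenarios) formalism:
#' \deqn{f_h(\omega) = \frac{-e^{0.5h} + e^{-h(\omega-0.5)}}
#'   {(1-e^{0.5h})\,(1+e^{-h(\omega-0.5)})}.}
#' The normalization pins \eqn{f_h(0)=0}, \eqn{f_h(0.5)=0.5} and
#' \eqn{f_h(1)=1} for every gain \eqn{h>0}, and \eqn{f_h} is strictly
#' increasing, so activity levels can never leave \eqn{[0,1]}.
#'
#' @param omega total input value(s) in \eqn{[0,1]}; vectorized.
#' @param gain positive sigmoid steepness \eqn{h}.
#' @return numeric vector of the same length as `omega`, values in
#'   \eqn{[0,1]}.
#' @examples
#' activationResponse(c(0, 0.5, 1), gain = 1)
#' @export
activationResponse <- function(omega, gain) {
  if (length(gain) != 1L || is.na(gain) || gain <= 0)
    stop("gain must be a single positive number")
  if (anyNA(omega) || any(omega < 0 | omega > 1))
    stop("omega must lie in [0, 1]")
  e <- exp(-gain * (omega - 0.5))
  (-exp(0.5 * gain) + e) / ((1 - exp(0.5 * gain)) * (1 + e))
}

# Resolve edge source activities against a combined node-state + input lookup.
.sourceValues <- function(sources, state, inputs) {
  v <- state[sources]
  missing <- !(sources %in% names(state))
  if (any(missing)) {
    fromInput <- sources[missing] %in% names(inputs)
    if (!all(fromInput))
      stop(sprintf("unresolvable edge source(s): %s",
                   paste(sQuote(sources[missing][!fromInput]), collapse = ", ")))
    v[missing] <- inputs[sources[missing]]
  }
  unname(v)
}

#' Total input (omega) to one node
#'
#' Evaluates the saturating total-input function of the formalism: the
#' product of an activation factor
#' \deqn{\frac{1+\sum\alpha}{\sum\alpha}\cdot
#'   \frac{\sum x^a \alpha}{1+\sum x^a \alpha}}
#' over the node's activator edges and a complementary inhibition factor
#' \deqn{1-\frac{1+\sum\beta}{\sum\beta}\cdot
#'   \frac{\sum \beta x^i}{1+\sum \beta x^i}}
#' over its inhibitor edges. The weighted-activity sums \eqn{\sum x \alpha}
#' use the current edge weights, while the prefactor sums \eqn{\sum\alpha}
#' use the edges' normalization weights: for an intact edge the two are
#' equal, but an interaction ablated by a zero-weight override contributes
#' nothing to the signal yet keeps its share of the saturating
#' normalization. This makes ablation well-behaved — blocking an input whose
#' source is already inactive changes nothing, and blocking one of several
#' inputs never amplifies the survivors. Edges constructed with weight 0
#' are dropped from both sums before they are formed.
#'
#' With no (surviving) activator edges the activation factor is 0 — or 1 if
#' the node is constitutive; with no inhibitor edges the inhibition factor
#' is 1. The result always lies in \eqn{[0,1]} when all referenced
#' activities do.
#'
#' @param node a [LogicNode-class].
#' @param state named numeric vector of current node activities.
#' @param inputs named numeric vector of constant external inputs.
#' @return scalar omega in \eqn{[0,1]}.
#' @examples
#' nd <- logicNode("cdh11", activators = c(c = 1))
#' nodeOmega(nd, state = numeric(0), inputs = c(c = 0.1))  # 2 * 0.1/1.1
#' @export
nodeOmega <- function(node, state, inputs = numeric(0)) {
  act <- node@activators
  act <- act[act$norm > 0, , drop = FALSE]
  inh <- node@inhibitors
  inh <- inh[inh$norm > 0, , drop = FALSE]

  if (nrow(act) == 0) {
    a <- if (node@constitutive) 1 else 0
  } else {
    x <- .sourceValues(act$source, state, inputs)
    s <- sum(x * act$weight)
    a <- (1 + sum(act$norm)) / sum(act$norm) * s / (1 + s)
  }
  if (nrow(inh) == 0) {
    i <- 1
  } else {
    x <- .sourceValues(inh$source, state, inputs)
    s <- sum(inh$weight * x)
    i <- 1 - (1 + sum(inh$norm)) / sum(inh$norm) * s / (1 + s)
  }
  a * i
}

#' Omegas and time-derivatives for a whole network
#'
#' `networkOmegas()` evaluates [nodeOmega()] for every node at the given
#' state. `networkDerivatives()` evaluates the right-hand side of the
#' logic-ODE system,
#' \deqn{dX_i/dt = f_h(\omega_i) - k_i X_i,}
#' returning 0 for clamped nodes (they are excluded from integration).
#'
#' @param network a [LogicNetwork-class].
#' @param state named numeric vector covering all nodes of the network.
#' @return named numeric vector over the network's nodes.
#' @examples
#' net <- baselineNetwork()
#' st <- stats::setNames(rep(0.5, 10), nodeNames(net))
#' networkDerivatives(net, st)
#' @export
networkOmegas <- function(network, state) {
  om <- vapply(network@nodes,
               function(n) nodeOmega(n, state, network@inputs),
               numeric(1), USE.NAMES = FALSE)
  stats::setNames(om, nodeNames(network))
}

#' @rdname networkOmegas
#' @export
networkDerivatives <- function(network, state) {
  nms <- nodeNames(network)
  if (!all(nms %in% names(state)))
    stop("state must cover every node of the network")
  state <- state[nms]
  om <- networkOmegas(network, state)
  k <- vapply(network@nodes, function(n) n@decay, numeric(1))
  d <- activationResponse(om, network@gain) - k * state
  d[nms %in% clampedNodes(network)] <- 0
  stats::setNames(as.numeric(d), nms)
}
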