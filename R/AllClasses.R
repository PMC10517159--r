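#' @import methods
NULL

.emptyEdges <- function() data.frame(source = character(0), weight = numeric(0),
                                     norm = numeric(0), stringsAsFactors = FALSE)

.checkEdgeFrame <- function(edges, what) {
  msg <- character(0)
  if (!is.data.frame(edges) ||
      !all(c("source", "weight", "norm") %in% names(edges))) {
    return(sprintf(
      "%s must be a data.frame with columns 'source', 'weight' and 'norm'",
      what))
  }
  if (nrow(edges) > 0) {
    if (!is.character(edges$source) || anyNA(edges$source) ||
        any(!nzchar(edges$source)))
      msg <- c(msg, sprintf("%s sources must be non-empty strings", what))
    if (!is.numeric(edges$weight) || anyNA(edges$weight) ||
        any(edges$weight < 0))
      msg <- c(msg, sprintf("%s weights must be non-negative numbers", what))
    if (!is.numeric(edges$norm) || anyNA(edges$norm) ||
        any(edges$norm < edges$weight))
      msg <- c(msg, sprintf(
        "%s normalization weights must be numbers >= the edge weight", what))
  }
  msg
}

#' LogicNode: one signalling species in a logic-ODE network
#'
#' A node carries its incoming regulation (activator and inhibitor edges with
#' non-negative weights), a first-order decay rate, an initial activity, a
#' constitutive flag and an optional clamp. Activity is a unitless level in
#' \eqn{[0,1]}: the net effect of the protein in its active (phosphorylated or
#' otherwise functional) form, not a molar concentration.
#'
#' Each edge also carries a *normalization weight* (`norm`), the value that
#' enters the saturating prefactor of the total-input function. At
#' construction `norm` equals `weight`; when an interaction is ablated by a
#' zero-weight override the normalization weight is retained, so blocking
#' one of several inputs silences its signal without re-scaling the
#' saturating capacity shared with the remaining inputs (see
#' [nodeOmega()]).
#'
#' A *constitutive* node has no activators and its activation factor is
#' identically 1, so its total input reduces to one minus its inhibition
#' factor (the beta-catenin form). A *clamped* node is held at the clamp
#' value, excluded from integration, but remains fully visible as an input to
#' the omega functions of other nodes.
#'
#' @slot name single node identifier.
#' @slot activators data.frame with columns `source`, `weight` (the alpha
#'   weights).
#' @slot inhibitors data.frame with columns `source`, `weight` (the beta
#'   weights).
#' @slot decay positive decay rate \eqn{k_i}.
#' @slot initial initial activity in \eqn{[0,1]}.
#' @slot constitutive logical; activation factor identically 1 (requires an
#'   empty activator list).
#' @slot clamp activity at which the node is held, or `NA_real_` for a free
#'   (dynamic) node.
#'
#' @seealso [logicNode()] for the user-facing constructor, [LogicNetwork-class]
#' @exportClass LogicNode
setClass("LogicNode",
  representation(
    name = "character",
    activators = "data.frame",
    inhibitors = "data.frame",
    decay = "numeric",
    initial = "numeric",
    constitutive = "logical",
    clamp = "numeric"
  ),
  prototype(
    activators = .emptyEdges(),
    inhibitors = .emptyEdges(),
    decay = 1,
    initial = 0,
    constitutive = FALSE,
    clamp = NA_real_
  )
)

setValidity("LogicNode", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  msg <- c(msg, .checkEdgeFrame(object@activators, "activators"))
  msg <- c(msg, .checkEdgeFrame(object@inhibitors, "inhibitors"))
  if (length(object@decay) != 1L || is.na(object@decay) || object@decay <= 0)
    msg <- c(msg, "decay must be a single positive number")
  if (length(object@initial) != 1L || is.na(object@initial) ||
      object@initial < 0 || object@initial > 1)
    msg <- c(msg, "initial activity must lie in [0, 1]")
  if (length(object@constitutive) != 1L || is.na(object@constitutive))
    msg <- c(msg, "constitutive must be TRUE or FALSE")
  if (isTRUE(object@constitutive) && nrow(object@activators) > 0)
    msg <- c(msg, "a constitutive node must have no activator edges")
  if (length(object@clamp) != 1L)
    msg <- c(msg, "clamp must be a single value (NA for a free node)")
  else if (!is.na(object@clamp) && (object@clamp < 0 || object@clamp > 1))
    msg <- c(msg, "clamp value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' LogicNetwork: a normalized logic-ODE model
#'
#' The full declarative model: the shared sigmoid gain \eqn{h}, the constant
#' external inputs (ligand/contact levels), and an ordered list of
#' [LogicNode-class] species. Every edge source must resolve to exactly one
#' declared node or external input.
#'
#' Each free node evolves as
#' \deqn{dX_i/dt = f_h(\omega_i) - k_i X_i}
#' where \eqn{f_h} is the normalized sigmoidal activation response (see
#' [activationResponse()]) and \eqn{\omega_i} the saturating total input
#' computed from the node's activator and inhibitor edges (see [nodeOmega()]).
#'
#' @slot gain positive sigmoid steepness \eqn{h} shared by all omega
#'   responses.
#' @slot inputs named numeric vector of constant external inputs (may be
#'   empty); values must be non-negative.
#' @slot nodes list of [LogicNode-class] objects with unique names.
#'
#' @seealso [logicNetwork()], [baselineNetwork()], [steadyState()]
#' @exportClass LogicNetwork
setClass("LogicNetwork",
  representation(
    gain = "numeric",
    inputs = "numeric",
    nodes = "list"
  ),
  prototype(gain = 1, inputs = numeric(0), nodes = list())
)

setValidity("LogicNetwork", function(object) {
  msg <- character(0)
  if (length(object@gain) != 1L || is.na(object@gain) || object@gain <= 0)
    msg <- c(msg, "gain must be a single positive number")
  if (length(object@inputs) > 0) {
    if (is.null(names(object@inputs)) || any(!nzchar(names(object@inputs))) ||
        anyDuplicated(names(object@inputs)))
      msg <- c(msg, "inputs must be uniquely named")
    if (anyNA(object@inputs) || any(object@inputs < 0))
      msg <- c(msg, "input values must be non-negative")
  }
  if (length(object@nodes) < 1L)
    msg <- c(msg, "a network needs at least one node")
  if (!all(vapply(object@nodes, is, logical(1), "LogicNode")))
    return(c(msg, "all nodes must be LogicNode objects"))
  nodeNames <- vapply(object@nodes, function(n) n@name, character(1))
  if (anyDuplicated(nodeNames))
    msg <- c(msg, "node names must be unique")
  if (any(nodeNames %in% names(object@inputs)))
    msg <- c(msg, "node names must not collide with input names")
  known <- c(nodeNames, names(object@inputs))
  for (node in object@nodes) {
    bad <- setdiff(c(node@activators$source, node@inhibitors$source), known)
    if (length(bad))
      msg <- c(msg, sprintf("node '%s': unresolvable edge source(s) %s",
                            node@name, paste(sQuote(bad), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' SteadyStateReport: result of a steady-state computation
#'
#' Bundles the final activity vector with convergence diagnostics so a
#' non-converged solve is never silent.
#'
#' @slot activities named numeric vector of node activities in \eqn{[0,1]}.
#' @slot time simulated (or iteration pseudo-) time at which the state was
#'   reached.
#' @slot converged logical convergence flag.
#' @slot residual maximum absolute time-derivative over free nodes at the
#'   final state.
#' @slot tolerance the convergence tolerance that was requested.
#' @slot method `"integration"` or `"fixed-point"`.
#'
#' @seealso [steadyState()], [algebraicFixedPoint()], [activities()]
#' @exportClass SteadyStateReport
setClass("SteadyStateReport",
  representation(
    activities = "numeric",
    time = "numeric",
    converged = "logical",
    residual = "numeric",
    tolerance = "numeric",
    method = "character"
  )
)

setValidity("SteadyStateReport", function(object) {
  msg <- character(0)
  if (is.null(names(object@activities)))
    msg <- c(msg, "activities must be named")
  if (length(object@converged) != 1L || is.na(object@converged))
    msg <- c(msg, "converged must be TRUE or FALSE")
  if (length(object@residual) != 1L || length(object@tolerance) != 1L)
    msg <- c(msg, "residual and tolerance must be single numbers")
  else if (isTRUE(object@converged) && object@residual > object@tolerance)
    msg <- c(msg, "converged reports must satisfy residual <= tolerance")
  if (!object@method %in% c("integration", "fixed-point"))
    msg <- c(msg, "method must be 'integration' or 'fixed-point'")
  if (length(msg)) msg else TRUE
})

#' Construct a signalling node
#'
#' @param name node identifier.
#' @param activators named numeric vector of activator weights, e.g.
#'   `c(mek = 1)` for activation by MEK with weight 1. `NULL` for none.
#' @param inhibitors named numeric vector of inhibitor weights. `NULL` for
#'   none.
#' @param decay positive decay rate (default 1, the conventional choice).
#' @param initial initial activity in \eqn{[0,1]} (default 0).
#' @param constitutive logical; if `TRUE` the node has activation factor 1
#'   despite having no activators (e.g. beta-catenin).
#' @param clamp optional activity at which the node is held throughout
#'   simulation; `NA` (default) leaves the node dynamic.
#'
#' @return A [LogicNode-class] object.
#' @examples
#' logicNode("erk", activators = c(mek = 1), inhibitors = c(dusp1 = 1))
#' @export
logicNode <- function(name, activators = NULL, inhibitors = NULL, decay = 1,
                      initial = 0, constitutive = FALSE, clamp = NA_real_) {
  new("LogicNode",
      name = as.character(name),
      activators = .edgesFromVector(activators),
      inhibitors = .edgesFromVector(inhibitors),
      decay = as.numeric(decay),
      initial = as.numeric(initial),
      constitutive = isTRUE(constitutive),
      clamp = as.numeric(clamp))
}

.edgesFromVector <- function(w) {
  if (is.null(w) || length(w) == 0) return(.emptyEdges())
  if (is.data.frame(w)) {
    stopifnot(all(c("source", "weight") %in% names(w)))
    return(data.frame(source = as.character(w$source),
                      weight = as.numeric(w$weight),
                      norm = as.numeric(if (is.null(w$norm)) w$weight
                                        else w$norm),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(w)))
    stop("edge weights must be named by their source species/input")
  data.frame(source = names(w), weight = as.numeric(w), norm = as.numeric(w),
             stringsAsFactors = FALSE)
}

#' Construct a logic-ODE network
#'
#' @param nodes list of [LogicNode-class] objects (order is preserved).
#' @param inputs named numeric vector of constant external inputs.
#' @param gain positive sigmoid gain \eqn{h} shared by all nodes (default 1).
#'
#' @return A validated [LogicNetwork-class] object.
#' @examples
#' net <- logicNetwork(
#'   nodes = list(logicNode("x", activators = c(u = 1))),
#'   inputs = c(u = 0.5))
#' steadyState(net)
#' @export
logicNetwork <- function(nodes, inputs = numeric(0), gain = 1) {
  if (is(nodes, "LogicNode")) nodes <- list(nodes)
  inputs <- if (length(inputs)) {
    stats::setNames(as.numeric(inputs), names(inputs))
  } else numeric(0)
  new("LogicNetwork", gain = as.numeric(gain), inputs = inputs, nodes = nodes)
}
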