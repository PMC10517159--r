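#' Accessors for LogicNetwork and SteadyStateReport objects
#'
#' Small accessor layer so downstream code never touches slots directly:
#' `nodeNames()` returns the ordered node identifiers, `networkInputs()` the
#' named constant-input vector, `networkGain()` the shared sigmoid gain,
#' `getNode()` one [LogicNode-class] by name, `clampedNodes()` the names of
#' clamped species, and, for reports, `activities()`, `converged()` and
#' `residual()` the state vector and its convergence diagnostics.
#'
#' @param x a [LogicNetwork-class] (or [SteadyStateReport-class] for the
#'   report accessors).
#' @param name node identifier for `getNode()`.
#' @return see the individual descriptions above.
#' @examples
#' net <- baselineNetwork()
#' nodeNames(net)
#' networkInputs(net)
#' getNode(net, "Bcat")
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname accessors
#' @export
setGeneric("networkInputs", function(x) standardGeneric("networkInputs"))

#' @rdname accessors
#' @export
setGeneric("networkGain", function(x) standardGeneric("networkGain"))

#' @rdname accessors
#' @export
setGeneric("getNode", function(x, name) standardGeneric("getNode"))

#' @rdname accessors
#' @export
setGeneric("clampedNodes", function(x) standardGeneric("clampedNodes"))

#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("residual", function(x) standardGeneric("residual"))

#' @rdname accessors
setMethod("nodeNames", "LogicNetwork", function(x)
  vapply(x@nodes, function(n) n@name, character(1)))

#' @rdname accessors
setMethod("networkInputs", "LogicNetwork", function(x) x@inputs)

#' @rdname accessors
setMethod("networkGain", "LogicNetwork", function(x) x@gain)

#' @rdname accessors
setMethod("getNode", "LogicNetwork", function(x, name) {
  idx <- match(name, nodeNames(x))
  if (is.na(idx))
    stop(sprintf("no node named '%s' in the network", name))
  x@nodes[[idx]]
})

#' @rdname accessors
setMethod("clampedNodes", "LogicNetwork", function(x) {
  nms <- nodeNames(x)
  nms[vapply(x@nodes, function(n) !is.na(n@clamp), logical(1))]
})

#' @rdname accessors
setMethod("activities", "SteadyStateReport", function(x) x@activities)

#' @rdname accessors
setMethod("converged", "SteadyStateReport", function(x) x@converged)

#' @rdname accessors
setMethod("residual", "SteadyStateReport", function(x) x@residual)

setMethod("show", "LogicNode", function(object) {
  role <- if (!is.na(object@clamp)) {
    sprintf("clamped at %.4g", object@clamp)
  } else if (object@constitutive) "constitutive" else "dynamic"
  cat(sprintf("LogicNode '%s' (%s): %d activator(s), %d inhibitor(s), k=%g, X0=%g\n",
              object@name, role, nrow(object@activators),
              nrow(object@inhibitors), object@decay, object@initial))
})

setMethod("show", "LogicNetwork", function(object) {
  nms <- nodeNames(object)
  nEdges <- sum(vapply(object@nodes, function(n)
    nrow(n@activators) + nrow(n@inhibitors), integer(1)))
  cat(sprintf("LogicNetwork: %d nodes, %d edges, %d external input(s), gain h=%g\n",
              length(nms), nEdges, length(object@inputs), object@gain))
  cat("  nodes:", paste(nms, collapse = ", "), "\n")
  if (length(object@inputs))
    cat("  inputs:", paste(sprintf("%s=%g", names(object@inputs),
                                   object@inputs), collapse = ", "), "\n")
  cl <- clampedNodes(object)
  if (length(cl))
    cat("  clamped:", paste(cl, collapse = ", "), "\n")
})

setMethod("show", "SteadyStateReport", function(object) {
  cat(sprintf("SteadyStateReport (%s): %s, residual %.3g (tol %.3g), t=%g\n",
              object@method,
              if (object@converged) "converged" else "NOT converged",
              object@residual, object@tolerance, object@time))
  print(round(object@activities, 4))
})
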