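#' Parameter overrides
#'
#' Overrides describe a single named change to a [LogicNetwork-class]:
#' an external input value, an edge weight, a node clamp, a node decay or a
#' node initial activity. They are the building blocks of the perturbation
#' scenarios and the two-parameter scans. Setting an edge weight to a
#' positive value re-parameterizes the interaction; setting it to exactly 0
#' ablates it — the edge transmits no signal but keeps its normalization
#' weight, so the remaining inputs of the node are not re-scaled (see
#' [nodeOmega()]). This is how interactions are blocked in-silico.
#'
#' @param name input name (`inputOverride`).
#' @param node target node name.
#' @param source source species/input of the targeted edge
#'   (`weightOverride`).
#' @param value the new value (non-negative; clamps and initials must lie in
#'   \eqn{[0,1]}, `clampOverride(value = NA)` releases a clamp).
#' @param role `"auto"` resolves the edge among activators then inhibitors;
#'   set `"activator"` or `"inhibitor"` explicitly if a source regulates the
#'   same node in both roles.
#' @return an object of class `ParameterOverride`.
#' @examples
#' kd <- inputOverride("c", 0)                   # cadherin-11 knockdown
#' applyOverrides(baselineNetwork(), list(kd))
#' @name overrides
NULL

.override <- function(kind, value, ...) {
  if (length(value) != 1L || (is.na(value) && kind != "clamp"))
    stop("override value must be a single number")
  structure(list(kind = kind, value = as.numeric(value), ...),
            class = "ParameterOverride")
}

#' @rdname overrides
#' @export
inputOverride <- function(name, value) {
  if (value < 0) stop("input values must be non-negative")
  .override("input", value, name = as.character(name))
}

#' @rdname overrides
#' @export
weightOverride <- function(node, source, value,
                           role = c("auto", "activator", "inhibitor")) {
  if (value < 0) stop("edge weights must be non-negative")
  .override("weight", value, node = as.character(node),
            source = as.character(source), role = match.arg(role))
}

#' @rdname overrides
#' @export
clampOverride <- function(node, value) {
  if (!is.na(value) && (value < 0 || value > 1))
    stop("clamp values must lie in [0, 1]")
  .override("clamp", value, node = as.character(node))
}

#' @rdname overrides
#' @export
decayOverride <- function(node, value) {
  if (value <= 0) stop("decay must be positive")
  .override("decay", value, node = as.character(node))
}

#' @rdname overrides
#' @export
initialOverride <- function(node, value) {
  if (value < 0 || value > 1) stop("initial activities must lie in [0, 1]")
  .override("initial", value, node = as.character(node))
}

#' @export
print.ParameterOverride <- function(x, ...) {
  desc <- switch(x$kind,
    input = sprintf("input %s = %g", x$name, x$value),
    weight = sprintf("weight %s <- %s = %g (%s)", x$node, x$source, x$value,
                     x$role),
    clamp = if (is.na(x$value)) sprintf("release clamp on %s", x$node)
            else sprintf("clamp %s at %g", x$node, x$value),
    decay = sprintf("decay of %s = %g", x$node, x$value),
    initial = sprintf("initial %s = %g", x$node, x$value))
  cat("ParameterOverride:", desc, "\n")
  invisible(x)
}

.findNodeIndex <- function(network, node) {
  idx <- match(node, nodeNames(network))
  if (is.na(idx))
    stop(sprintf("override target: no node named '%s'", node))
  idx
}

.applyOne <- function(network, ov) {
  stopifnot(inherits(ov, "ParameterOverride"))
  switch(ov$kind,
    input = {
      if (!ov$name %in% names(network@inputs))
        stop(sprintf("override target: no external input named '%s'",
                     ov$name))
      network@inputs[[ov$name]] <- ov$value
    },
    weight = {
      idx <- .findNodeIndex(network, ov$node)
      nd <- network@nodes[[idx]]
      inAct <- which(nd@activators$source == ov$source)
      inInh <- which(nd@inhibitors$source == ov$source)
      role <- ov$role
      if (role == "auto") {
        if (length(inAct) && length(inInh))
          stop(sprintf(
            "'%s' is both activator and inhibitor of '%s'; set role=",
            ov$source, ov$node))
        role <- if (length(inAct)) "activator" else "inhibitor"
      }
      # value > 0 re-parameterizes the interaction (signal and
      # normalization); value 0 ablates it, keeping the normalization
      # weight so the remaining inputs are not re-scaled
      if (role == "activator") {
        if (!length(inAct))
          stop(sprintf("no activator edge %s -> %s", ov$source, ov$node))
        nd@activators$weight[inAct] <- ov$value
        if (ov$value > 0) nd@activators$norm[inAct] <- ov$value
      } else {
        if (!length(inInh))
          stop(sprintf("no inhibitor edge %s -| %s", ov$source, ov$node))
        nd@inhibitors$weight[inInh] <- ov$value
        if (ov$value > 0) nd@inhibitors$norm[inInh] <- ov$value
      }
      network@nodes[[idx]] <- nd
    },
    clamp = {
      idx <- .findNodeIndex(network, ov$node)
      network@nodes[[idx]]@clamp <- ov$value
    },
    decay = {
      idx <- .findNodeIndex(network, ov$node)
      network@nodes[[idx]]@decay <- ov$value
    },
    initial = {
      idx <- .findNodeIndex(network, ov$node)
      network@nodes[[idx]]@initial <- ov$value
    },
    stop("unknown override kind: ", ov$kind))
  network
}

#' Apply parameter overrides to a network
#'
#' Returns a modified copy of the network; the input object is untouched.
#' Every override target must resolve to exactly one element of the network,
#' otherwise a configuration error names the offending target.
#'
#' @param network a [LogicNetwork-class].
#' @param overrides a single `ParameterOverride` or a list of them.
#' @return a validated [LogicNetwork-class] copy with all overrides applied.
#' @examples
#' kd <- applyOverrides(baselineNetwork(), list(inputOverride("c", 0)))
#' networkInputs(kd)[["c"]]
#' @export
applyOverrides <- function(network, overrides) {
  stopifnot(is(network, "LogicNetwork"))
  if (inherits(overrides, "ParameterOverride")) overrides <- list(overrides)
  for (ov in overrides) network <- .applyOne(network, ov)
  validObject(network)
  network
}
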