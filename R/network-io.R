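#' Read and write networks as JSON
#'
#' The interchange format is a plain JSON document:
#' \preformatted{
#' {
#'   "gain": 1,
#'   "inputs": {"c": 0.1, "a": 0.1, "b": 0.4},
#'   "nodes": [
#'     {"name": "cdh11", "decay": 1, "initial": 0,
#'      "constitutive": false, "clamp": null,
#'      "activators": [{"source": "c", "weight": 1}],
#'      "inhibitors": []},
#'     ...
#'   ]
#' }
#' }
#' `clamp: null` marks a free node. An ablated edge (weight 0 with retained
#' saturating normalization, see [overrides]) carries an additional `norm`
#' field. A round trip through
#' `writeNetworkJSON()` / `readNetworkJSON()` reproduces the network
#' exactly. The packaged baseline model ships as
#' `system.file("extdata", "baseline_network.json", package = "cdh11net")`.
#'
#' @param network a [LogicNetwork-class].
#' @param path file path.
#' @return `readNetworkJSON()` returns a validated [LogicNetwork-class];
#'   `writeNetworkJSON()` invisibly returns `path`;
#'   `validateNetworkFile()` returns `TRUE` or stops with the validity
#'   failure.
#' @examples
#' p <- tempfile(fileext = ".json")
#' writeNetworkJSON(baselineNetwork(), p)
#' net <- readNetworkJSON(p)
#' @name network-io
NULL

.edgeList <- function(edges) {
  if (nrow(edges) == 0) return(list())
  lapply(seq_len(nrow(edges)), function(i) {
    e <- list(source = edges$source[i], weight = edges$weight[i])
    # the normalization weight only differs from the signal weight for
    # ablated interactions; omit it otherwise
    if (edges$norm[i] != edges$weight[i]) e$norm <- edges$norm[i]
    e
  })
}

#' @rdname network-io
#' @export
writeNetworkJSON <- function(network, path) {
  stopifnot(is(network, "LogicNetwork"))
  validObject(network)
  doc <- list(
    gain = network@gain,
    inputs = as.list(network@inputs),
    nodes = lapply(network@nodes, function(n) list(
      name = n@name,
      decay = n@decay,
      initial = n@initial,
      constitutive = n@constitutive,
      clamp = if (is.na(n@clamp)) NULL else n@clamp,
      activators = .edgeList(n@activators),
      inhibitors = .edgeList(n@inhibitors)
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.edgesFromJSON <- function(lst) {
  if (length(lst) == 0) return(NULL)
  data.frame(
    source = vapply(lst, function(e) as.character(e$source), character(1)),
    weight = vapply(lst, function(e) as.numeric(e$weight), numeric(1)),
    norm = vapply(lst, function(e)
      as.numeric(if (is.null(e$norm)) e$weight else e$norm), numeric(1)),
    stringsAsFactors = FALSE)
}

#' @rdname network-io
#' @export
readNetworkJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$gain) || is.null(doc$nodes))
    stop("network JSON must contain 'gain' and 'nodes'")
  inputs <- if (length(doc$inputs)) {
    stats::setNames(vapply(doc$inputs, as.numeric, numeric(1)),
                    names(doc$inputs))
  } else numeric(0)
  nodes <- lapply(doc$nodes, function(n) {
    logicNode(
      name = n$name,
      activators = .edgesFromJSON(n$activators),
      inhibitors = .edgesFromJSON(n$inhibitors),
      decay = if (is.null(n$decay)) 1 else n$decay,
      initial = if (is.null(n$initial)) 0 else n$initial,
      constitutive = isTRUE(n$constitutive),
      clamp = if (is.null(n$clamp)) NA_real_ else n$clamp)
  })
  logicNetwork(nodes = nodes, inputs = inputs, gain = as.numeric(doc$gain))
}

#' @rdname network-io
#' @export
validateNetworkFile <- function(path) {
  net <- readNetworkJSON(path)
  validObject(net)
  TRUE
}
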