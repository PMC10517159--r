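.scanGrid <- c(0.1, 0.5, 1, 5, 10)
.bcatGrid <- c(0.1, 0.3, 0.5, 0.7, 1.0)

# Each axis: a label, a value grid, a factory turning a value into a
# ParameterOverride, and the baseline value (for marking the reference cell).
.scanRegistry <- function() {
  axis <- function(name, values, baseline, factory)
    list(name = name, values = values, baseline = baseline,
         factory = factory)
  list(
    A = list(
      axis1 = axis("beta_dusp1_by_Bcat", .scanGrid, 1,
                   function(v) weightOverride("dusp1", "Bcat", v)),
      axis2 = axis("Bcat_initial", .bcatGrid, 1,
                   function(v) initialOverride("Bcat", v))),
    B = list(
      axis1 = axis("beta_dusp1_by_Bcat", .scanGrid, 1,
                   function(v) weightOverride("dusp1", "Bcat", v)),
      axis2 = axis("alpha_dusp1_by_erk", .scanGrid, 1,
                   function(v) weightOverride("dusp1", "erk", v))),
    C = list(
      axis1 = axis("beta_erk_by_dusp1", .scanGrid, 1,
                   function(v) weightOverride("erk", "dusp1", v)),
      axis2 = axis("alpha_erk_by_mek", .scanGrid, 1,
                   function(v) weightOverride("erk", "mek", v))),
    D = list(
      axis1 = axis("beta_erk_by_dusp1", .scanGrid, 1,
                   function(v) weightOverride("erk", "dusp1", v)),
      axis2 = axis("alpha_cyclinD1_by_dusp1", .scanGrid, 1,
                   function(v) weightOverride("cyclinD1", "dusp1", v)))
  )
}

#' Two-parameter scans of the proliferation readout
#'
#' Four 5x5 scans probe the parameters around the proposed downstream
#' crosstalk, each cell solved to steady state on the baseline network with
#' the two axis overrides applied, and summarized by
#' \eqn{\Delta =} cyclin-D1 \eqn{-} ERK steady-state activity:
#' \describe{
#'   \item{A}{inhibition of DUSP1 by beta-catenin
#'     (\eqn{\beta \in \{0.1,0.5,1,5,10\}}) against the initial
#'     beta-catenin activity (\eqn{\{0.1,0.3,0.5,0.7,1\}}). Steady states do
#'     not depend on initial conditions, so the columns of this scan are
#'     degenerate by design — that is itself a checked property.}
#'   \item{B}{inhibition of DUSP1 by beta-catenin against activation of
#'     DUSP1 by ERK, both on \eqn{\{0.1,0.5,1,5,10\}}.}
#'   \item{C}{inhibition of ERK by DUSP1 against activation of ERK by MEK.}
#'   \item{D}{inhibition of ERK by DUSP1 against activation of cyclin-D1 by
#'     DUSP1.}
#' }
#'
#' `scanSpec()` returns the grid definition; `runScan()` executes all 25
#' cells; `summarizeScan()` aggregates per axis-1 value;
#' `plotScan()` renders a Fig.-style heatmap (axis 2 horizontal, axis 1
#' vertical, baseline cell marked with an X; requires ggplot2).
#'
#' @param id scan identifier, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param epsilon classification tolerance for the `label` column (see
#'   [proliferationChange()]).
#' @param tolerance,method steady-state solver settings.
#' @param network the unperturbed network (default [baselineNetwork()]).
#' @param result a data.frame returned by `runScan()`.
#' @return `runScan()` returns a 25-row data.frame with columns `scan_id`,
#'   `axis1_name`, `axis1_value`, `axis2_name`, `axis2_value`, `delta`,
#'   `label` and `baseline_cell` (logical marker of the unperturbed
#'   parameter pair). `summarizeScan()` returns one row per axis-1 value
#'   with `min_delta`, `max_delta` and a `sign` column
#'   (`"negative"`/`"positive"`/`"mixed"`, zero within `epsilon`).
#' @examples
#' scanA <- runScan("A")
#' summarizeScan(scanA)
#' @name parameter-scan
NULL

#' @rdname parameter-scan
#' @export
scanSpec <- function(id) {
  reg <- .scanRegistry()
  if (length(id) != 1L || !id %in% names(reg))
    stop(sprintf("unknown scan '%s'; available scans: %s",
                 paste(id, collapse = ", "),
                 paste(names(reg), collapse = ", ")))
  c(list(id = id), reg[[id]])
}

#' @rdname parameter-scan
#' @export
runScan <- function(id, epsilon = 0.01, tolerance = 1e-9,
                    method = c("integration", "fixed-point"),
                    network = baselineNetwork()) {
  method <- match.arg(method)
  spec <- scanSpec(id)
  grid <- expand.grid(axis1_value = spec$axis1$values,
                      axis2_value = spec$axis2$values,
                      KEEP.OUT.ATTRS = FALSE)
  delta <- vapply(seq_len(nrow(grid)), function(i) {
    net <- applyOverrides(network, list(
      spec$axis1$factory(grid$axis1_value[i]),
      spec$axis2$factory(grid$axis2_value[i])))
    rep <- .solveSS(net, tolerance, method)
    if (!converged(rep))
      stop(sprintf("scan %s cell (%g, %g) did not converge", spec$id,
                   grid$axis1_value[i], grid$axis2_value[i]))
    ss <- activities(rep)
    unname(ss[["cyclinD1"]] - ss[["erk"]])
  }, numeric(1))
  lab <- ifelse(delta > epsilon, "increased",
                ifelse(delta < -epsilon, "decreased", "unchanged"))
  data.frame(
    scan_id = spec$id,
    axis1_name = spec$axis1$name,
    axis1_value = grid$axis1_value,
    axis2_name = spec$axis2$name,
    axis2_value = grid$axis2_value,
    delta = delta,
    label = lab,
    baseline_cell = grid$axis1_value == spec$axis1$baseline &
      grid$axis2_value == spec$axis2$baseline,
    stringsAsFactors = FALSE)
}

#' @rdname parameter-scan
#' @export
summarizeScan <- function(result, epsilon = 0.01) {
  need <- c("axis1_name", "axis1_value", "delta")
  if (!is.data.frame(result) || !all(need %in% names(result)) ||
      nrow(result) == 0)
    stop("result must be a non-empty data.frame from runScan()")
  vals <- sort(unique(result$axis1_value))
  rows <- lapply(vals, function(v) {
    d <- result$delta[result$axis1_value == v]
    sign <- if (max(d) < -epsilon) "negative"
            else if (min(d) > epsilon) "positive" else "mixed"
    data.frame(axis1_name = result$axis1_name[1], axis1_value = v,
               min_delta = min(d), max_delta = max(d), sign = sign,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname parameter-scan
#' @export
plotScan <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotScan() needs the ggplot2 package")
  need <- c("axis1_value", "axis2_value", "delta", "baseline_cell")
  if (!is.data.frame(result) || !all(need %in% names(result)))
    stop("result must come from runScan()")
  df <- result
  df$axis1 <- factor(df$axis1_value)
  df$axis2 <- factor(df$axis2_value)
  lim <- max(abs(df$delta), 1e-6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis2, y = .data$axis1,
                                   fill = .data$delta)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(
      data = df[df$baseline_cell, , drop = FALSE],
      ggplot2::aes(x = .data$axis2, y = .data$axis1, label = "X"),
      inherit.aes = FALSE) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-lim, lim),
                                  name = "cyclinD1 - ERK") +
    ggplot2::labs(x = df$axis2_name[1], y = df$axis1_name[1],
                  title = sprintf("Scan %s: change in proliferation",
                                  df$scan_id[1]))
}
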