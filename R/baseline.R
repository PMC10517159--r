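#' The baseline cadherin-11/PDGFR crosstalk network
#'
#' Builds the curated ten-node model: cadherin-11 (cdh11) driven by
#' cell--cell contact `c`; PDGFR-alpha (pdgfrA) activated by its ligand `a`
#' and by adjacent-cell cadherin-11 (the external input `c`, not the dynamic
#' cdh11 node); PDGFR-beta (pdgfrB) activated by its ligand `b` and inhibited
#' by same-cell cadherin-11; the RAS--RAF--MEK--ERK cascade fed equally by
#' both receptors; the ERK--DUSP1 negative feedback; constitutive
#' beta-catenin (Bcat) inhibited by cdh11 and in turn inhibiting DUSP1 (the
#' proposed downstream crosstalk); and cyclin-D1 activated by DUSP1.
#'
#' Parameterization: inputs `c = 0.1`, `a = 0.1`, `b = 0.4`; gain `h = 1`;
#' all edge weights 1 except the three receptor--ligand weights
#' (`a`/`c` on pdgfrA and `b` on pdgfrB) at 0.5; all decays 1 except
#' beta-catenin at 2 (compensating its high initial activity and its
#' involvement in other pathways); initial activities 0 except beta-catenin
#' at 1.
#'
#' @return a validated [LogicNetwork-class] with nodes
#'   `cdh11, pdgfrA, pdgfrB, ras, raf, mek, erk, dusp1, Bcat, cyclinD1`.
#' @examples
#' net <- baselineNetwork()
#' net
#' round(activities(steadyState(net)), 3)
#' @export
baselineNetwork <- function() {
  logicNetwork(
    gain = 1,
    inputs = c(c = 0.1, a = 0.1, b = 0.4),
    nodes = list(
      logicNode("cdh11",    activators = c(c = 1)),
      logicNode("pdgfrA",   activators = c(a = 0.5, c = 0.5)),
      logicNode("pdgfrB",   activators = c(b = 0.5),
                inhibitors = c(cdh11 = 1)),
      logicNode("ras",      activators = c(pdgfrA = 1, pdgfrB = 1)),
      logicNode("raf",      activators = c(ras = 1)),
      logicNode("mek",      activators = c(raf = 1)),
      logicNode("erk",      activators = c(mek = 1),
                inhibitors = c(dusp1 = 1)),
      logicNode("dusp1",    activators = c(erk = 1),
                inhibitors = c(Bcat = 1)),
      logicNode("Bcat",     inhibitors = c(cdh11 = 1),
                decay = 2, initial = 1, constitutive = TRUE),
      logicNode("cyclinD1", activators = c(dusp1 = 1))
    )
  )
}
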