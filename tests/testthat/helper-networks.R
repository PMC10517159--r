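# Frozen reference steady states, computed with a standalone damped
# fixed-point iteration on the algebraic system X = f(omega(X))/k before the
# package solvers were written (rounded to 4 decimals).
expectedBaselineSS <- c(
  cdh11 = 0.1779, pdgfrA = 0.1779, pdgfrB = 0.3461, ras = 0.5161,
  raf = 0.6841, mek = 0.8163, erk = 0.4763, dusp1 = 0.3068,
  Bcat = 0.3507, cyclinD1 = 0.4690)

expectedKnockdownSS <- c(
  cdh11 = 0, pdgfrA = 0.0924, pdgfrB = 0.5, ras = 0.5592,
  raf = 0.7209, mek = 0.8416, erk = 0.5653, dusp1 = 0.2368,
  Bcat = 0.5, cyclinD1 = 0.3807)

# one constitutive node, no edges: omega = 1, steady state f(1)/k = 1/k
constitutiveNode <- function(decay = 1) {
  logicNetwork(logicNode("x", constitutive = TRUE, decay = decay))
}

# linear cascade u -> x1 -> x2 -> ... with unit weights
cascadeNetwork <- function(n = 3, input = 0.5) {
  nodes <- lapply(seq_len(n), function(i) {
    src <- if (i == 1) "u" else paste0("x", i - 1)
    logicNode(paste0("x", i), activators = stats::setNames(1, src))
  })
  logicNetwork(nodes, inputs = c(u = input))
}

solverPair <- function(network, tol = 1e-9) {
  list(integration = activities(steadyState(network, tolerance = tol)),
       fixedPoint = activities(algebraicFixedPoint(network, tolerance = tol)))
}
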