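test_that("the curated baseline network has the published structure", {
  net <- baselineNetwork()
  expect_identical(nodeNames(net),
                   c("cdh11", "pdgfrA", "pdgfrB", "ras", "raf", "mek",
                     "erk", "dusp1", "Bcat", "cyclinD1"))
  expect_equal(networkInputs(net), c(c = 0.1, a = 0.1, b = 0.4))
  expect_identical(networkGain(net), 1)

  pa <- getNode(net, "pdgfrA")
  expect_equal(pa@activators$source, c("a", "c"))
  expect_equal(pa@activators$weight, c(0.5, 0.5))

  pb <- getNode(net, "pdgfrB")
  expect_equal(pb@activators$weight, 0.5)
  expect_equal(pb@inhibitors$source, "cdh11")

  bcat <- getNode(net, "Bcat")
  expect_true(bcat@constitutive)
  expect_identical(bcat@decay, 2)
  expect_identical(bcat@initial, 1)
  expect_equal(bcat@inhibitors$source, "cdh11")

  # everything else: unit weights, decay 1, initial 0, free
  others <- setdiff(nodeNames(net), "Bcat")
  for (nm in others) {
    nd <- getNode(net, nm)
    expect_identical(nd@decay, 1)
    expect_identical(nd@initial, 0)
    expect_false(nd@constitutive)
    expect_true(is.na(nd@clamp))
  }
  expect_identical(clampedNodes(net), character(0))
})

test_that("network validity catches malformed specifications", {
  a <- logicNode("a", activators = c(u = 1))
  expect_error(logicNetwork(list(a, a), inputs = c(u = 1)), "unique")
  expect_error(logicNetwork(list(a)), "unresolvable")
  expect_error(logicNode("a", decay = 0), "decay")
  expect_error(logicNode("a", initial = 1.5), "initial|\\[0, 1\\]")
  expect_error(logicNode("a", activators = c(u = -1)), "non-negative")
  expect_error(logicNode("a", activators = c(u = 1), constitutive = TRUE),
               "constitutive")
  expect_error(logicNode("a", clamp = 2), "clamp")
  expect_error(logicNetwork(list(a), inputs = c(u = 1), gain = 0), "gain")
  # node names must not shadow input names
  expect_error(logicNetwork(list(logicNode("u", constitutive = TRUE)),
                            inputs = c(u = 1)), "collide")
  expect_error(getNode(baselineNetwork(), "nope"), "no node")
})

test_that("networks round-trip through the JSON interchange format", {
  net <- baselineNetwork()
  path <- withr::local_tempfile(fileext = ".json")
  writeNetworkJSON(net, path)
  expect_identical(readNetworkJSON(path), net)
  expect_true(validateNetworkFile(path))

  # clamps and random topologies survive the round trip too
  clamped <- applyOverrides(net, clampOverride("cdh11", 0.18))
  writeNetworkJSON(clamped, path)
  expect_identical(readNetworkJSON(path), clamped)

  # sampled weights round-trip to near machine precision (the JSON writer
  # keeps ~15 significant digits)
  rnd <- randomNetwork(6, seed = 3)
  writeNetworkJSON(rnd, path)
  expect_equal(readNetworkJSON(path), rnd, tolerance = 1e-12)
})

test_that("the packaged baseline fixture equals the built network", {
  fixture <- system.file("extdata", "baseline_network.json",
                         package = "cdh11net")
  expect_true(nzchar(fixture))
  expect_identical(readNetworkJSON(fixture), baselineNetwork())
})

test_that("overrides return a modified copy and leave the original intact", {
  net <- baselineNetwork()
  kd <- applyOverrides(net, list(inputOverride("c", 0)))
  expect_identical(networkInputs(kd)[["c"]], 0)
  expect_identical(networkInputs(net)[["c"]], 0.1)

  expect_identical(applyOverrides(net, list()), net)

  w <- applyOverrides(net, weightOverride("dusp1", "Bcat", 0))
  expect_identical(getNode(w, "dusp1")@inhibitors$weight, 0)

  cl <- applyOverrides(net, clampOverride("cdh11", 0.18))
  expect_identical(clampedNodes(cl), "cdh11")
  released <- applyOverrides(cl, clampOverride("cdh11", NA))
  expect_identical(clampedNodes(released), character(0))

  dk <- applyOverrides(net, list(decayOverride("erk", 2),
                                 initialOverride("erk", 0.4)))
  expect_identical(getNode(dk, "erk")@decay, 2)
  expect_identical(getNode(dk, "erk")@initial, 0.4)
})

test_that("override targets must resolve to exactly one element", {
  net <- baselineNetwork()
  expect_error(applyOverrides(net, inputOverride("zz", 0)), "no external input")
  expect_error(applyOverrides(net, weightOverride("erk", "raf", 1)),
               "no activator|no inhibitor")
  expect_error(applyOverrides(net, clampOverride("nope", 0.5)), "no node")
  expect_error(inputOverride("c", -1), "non-negative")
  expect_error(weightOverride("erk", "mek", -2), "non-negative")
  expect_error(initialOverride("erk", 2), "\\[0, 1\\]")
  expect_error(decayOverride("erk", 0), "positive")
})

test_that("ablation silences an edge without re-scaling its neighbours", {
  net <- baselineNetwork()
  state <- expectedBaselineSS

  # blocking a node's sole inhibitor is the same as having none
  zeroed <- applyOverrides(net, weightOverride("dusp1", "Bcat", 0))
  nd <- logicNode("dusp1", activators = c(erk = 1))
  expect_identical(nodeOmega(getNode(zeroed, "dusp1"), state),
                   nodeOmega(nd, state))

  # blocking one of two activators keeps the saturating normalization of
  # the survivor: prefactor stays (1+1)/1, not (1+0.5)/0.5
  pa <- applyOverrides(net, weightOverride("pdgfrA", "c", 0))
  inputs <- networkInputs(net)
  expect_equal(nodeOmega(getNode(pa, "pdgfrA"), state, inputs),
               2 * (0.1 * 0.5) / (1 + 0.1 * 0.5), tolerance = 1e-12)
  # so blocking an input whose source is absent is a no-op
  kd <- applyOverrides(net, inputOverride("c", 0))
  kdBlocked <- applyOverrides(kd, weightOverride("pdgfrA", "c", 0))
  expect_equal(activities(steadyState(kdBlocked)),
               activities(steadyState(kd)), tolerance = 1e-9)

  # a positive override re-parameterizes signal and normalization together
  rw <- applyOverrides(pa, weightOverride("pdgfrA", "c", 2))
  e <- getNode(rw, "pdgfrA")@activators
  expect_identical(e$weight[e$source == "c"], 2)
  expect_identical(e$norm[e$source == "c"], 2)
})
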