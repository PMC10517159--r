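test_that("the scenario registry covers all named simulation setups", {
  expect_setequal(scenarioNames(), c(
    "baseline", "cadherin-11-knockdown",
    "contact-off-pdgfra-binding-off", "contact-off-pdgfrb-binding-off",
    "crosstalk-disabled", "crosstalk-disabled+kd",
    "receptor-disabled", "receptor-disabled+kd",
    "downstream-disabled", "downstream-disabled+kd"))
})

test_that("scenarios carry the exact documented override sets", {
  expect_length(makeScenario("baseline")$overrides, 0)

  kd <- makeScenario("cadherin-11-knockdown")$overrides
  expect_length(kd, 1)
  expect_identical(kd[[1]]$kind, "input")
  expect_identical(kd[[1]]$value, 0)

  pa <- makeScenario("contact-off-pdgfra-binding-off")$overrides
  kinds <- vapply(pa, function(o) o$kind, character(1))
  expect_setequal(kinds, c("input", "weight", "clamp"))
  clamp <- pa[[which(kinds == "clamp")]]
  expect_identical(clamp$node, "cdh11")
  expect_identical(clamp$value, 0.18)

  ct <- makeScenario("crosstalk-disabled")$overrides
  expect_length(ct, 3)
  expect_true(all(vapply(ct, function(o) o$kind, character(1)) == "weight"))
  expect_true(all(vapply(ct, function(o) o$value, numeric(1)) == 0))
  expect_length(makeScenario("crosstalk-disabled+kd")$overrides, 4)
  expect_length(makeScenario("receptor-disabled")$overrides, 2)
  expect_length(makeScenario("downstream-disabled")$overrides, 1)

  expect_error(makeScenario("not-a-scenario"), "registered scenarios")
})

test_that("baseline compared against itself reports no change anywhere", {
  cmp <- runScenario("baseline")
  expect_identical(nrow(cmp), 10L)
  expect_true(all(abs(cmp$diff) < 1e-9))
  expect_true(all(cmp$direction == "unchanged"))
})

test_that("the knockdown moves every node in the published direction", {
  cmp <- runScenario("cadherin-11-knockdown")
  dir <- stats::setNames(cmp$direction, cmp$node)
  expect_identical(unname(dir[c("pdgfrA", "dusp1", "cyclinD1")]),
                   rep("decrease", 3))
  expect_identical(unname(dir[c("pdgfrB", "erk", "Bcat")]),
                   rep("increase", 3))
})

test_that("knockdown receptor numbers match both percent conventions", {
  cmp <- runScenario("cadherin-11-knockdown")
  row <- function(n) cmp[cmp$node == n, ]
  expect_equal(row("pdgfrB")$scenario_ss, 0.5, tolerance = 1e-7)
  expect_equal(row("pdgfrB")$baseline_ss, 0.3461, tolerance = 5e-4)
  # the decrease reads off the baseline denominator, the increase off the
  # cadherin-free scenario denominator
  expect_equal(row("pdgfrA")$pct_vs_baseline, -48.07, tolerance = 1e-3)
  expect_equal(row("pdgfrB")$pct_vs_scenario, 30.78, tolerance = 1e-3)
  expect_equal(row("pdgfrB")$pct_vs_baseline, 44.46, tolerance = 1e-3)
})

test_that("binding-blocked setups leave the untouched receptor unchanged", {
  pa <- runScenario("contact-off-pdgfra-binding-off")
  expect_lt(abs(pa$diff[pa$node == "pdgfrB"]), 0.01)
  expect_equal(pa$pct_vs_baseline[pa$node == "pdgfrA"], -48.07,
               tolerance = 1e-3)

  pb <- runScenario("contact-off-pdgfrb-binding-off")
  expect_lt(abs(pb$diff[pb$node == "pdgfrA"]), 0.01)
  expect_equal(pb$pct_vs_scenario[pb$node == "pdgfrB"], 30.78,
               tolerance = 1e-3)
})

test_that("ablation scenarios collapse onto the published equivalences", {
  ss <- function(nm) {
    net <- applyOverrides(baselineNetwork(), makeScenario(nm)$overrides)
    activities(steadyState(net))
  }
  kd <- ss("cadherin-11-knockdown")
  rkd <- ss("receptor-disabled+kd")
  expect_lt(max(abs(rkd[c("erk", "cyclinD1")] - kd[c("erk", "cyclinD1")])),
            1e-6)

  ckd <- ss("crosstalk-disabled+kd")
  dkd <- ss("downstream-disabled+kd")
  expect_lt(max(abs(dkd - ckd)), 1e-6)

  # under the knockdown only beta-catenin (released from inhibition) and
  # cadherin-11 itself (tracking the zeroed contact input) move; the five
  # reported proteins and the cascade stay put
  ct <- ss("crosstalk-disabled")
  gaps <- abs(ckd - ct)
  expect_gt(gaps[["Bcat"]], 0.01)
  expect_equal(unname(ckd[["cdh11"]]), 0, tolerance = 1e-9)
  expect_lt(max(gaps[setdiff(names(gaps), c("Bcat", "cdh11"))]), 1e-6)
})

test_that("steady states respond monotonically to the contact input", {
  cs <- c(0, 0.05, 0.1, 0.2)
  states <- sapply(cs, function(cv) {
    net <- applyOverrides(baselineNetwork(), inputOverride("c", cv))
    activities(steadyState(net))
  })
  expect_true(all(diff(states["cdh11", ]) >= -1e-9))
  expect_true(all(diff(states["pdgfrA", ]) >= -1e-9))
  expect_true(all(diff(states["Bcat", ]) <= 1e-9))
})

test_that("the knockdown-efficiency sweep is anchored and monotone", {
  sw <- knockdownEfficiencySweep(c(0, 0.25, 0.5, 0.75, 0.8, 1))
  expect_identical(names(sw), c("efficiency", "pdgfrA", "pdgfrB"))
  # e = 0 is the baseline, e = 1 the full knockdown
  expect_equal(sw$pdgfrA[1], expectedBaselineSS[["pdgfrA"]], tolerance = 5e-4)
  expect_equal(sw$pdgfrB[sw$efficiency == 1], 0.5, tolerance = 1e-7)
  kd <- runScenario("cadherin-11-knockdown")
  expect_equal(sw$pdgfrA[sw$efficiency == 1],
               kd$scenario_ss[kd$node == "pdgfrA"], tolerance = 1e-7)
  expect_true(all(diff(sw$pdgfrA) < 0))
  expect_true(all(diff(sw$pdgfrB) > 0))
  expect_error(knockdownEfficiencySweep(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the proliferation readout classifies by the epsilon rule", {
  base <- proliferationChange(steadyState(baselineNetwork()))
  expect_equal(base$delta, -0.00732, tolerance = 1e-3)
  expect_identical(base$label, "unchanged")

  kdNet <- applyOverrides(baselineNetwork(), inputOverride("c", 0))
  kd <- proliferationChange(steadyState(kdNet))
  expect_equal(kd$delta, -0.1846, tolerance = 1e-3)
  expect_identical(kd$label, "decreased")

  expect_identical(proliferationChange(c(erk = 0.4, cyclinD1 = 0.4))$label,
                   "unchanged")
  expect_identical(proliferationChange(c(erk = 0.2, cyclinD1 = 0.5))$label,
                   "increased")
  expect_identical(
    proliferationChange(c(erk = 0.4763, cyclinD1 = 0.4690),
                        epsilon = 0.001)$label,
    "decreased")
  expect_error(proliferationChange(c(erk = 0.5)), "cyclinD1")
  expect_error(proliferationChange(c(erk = 0.5, cyclinD1 = 0.5),
                                   epsilon = 0), "epsilon")
})
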