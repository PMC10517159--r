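---
title: "Logic-ODE modelling of cadherin-11/PDGFR signalling crosstalk"
author: "cdh11net authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-ODE modelling of cadherin-11/PDGFR signalling crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdh11net)
```

## The biological question

Cadherin-11, a type II classical cadherin involved in the fate commitment
of human mesenchymal stem cells, has no intrinsic signalling activity but
interacts physically with both PDGF receptors: binding to extracellular
cadherin-11 regions *raises* PDGFR-α activity, while the membrane
interaction with PDGFR-β *suppresses* that receptor. Cadherin-11 knockdown
nevertheless decreases proliferation through the ERK pathway — an effect
that receptor-level interactions alone struggle to explain. `cdh11net`
implements a qualitative dynamical model of this system to ask whether an
additional, downstream layer of crosstalk — β-catenin (downstream of
cadherin-11) inhibiting an ERK phosphatase such as DUSP1 — is required to
reproduce the observed knockdown phenotype.

## The formalism

Each of the ten species carries a unitless activity $X_i \in [0,1]$ (the
net effect of the active, e.g. phosphorylated, form — not a concentration)
obeying a normalized logic ODE in the continuous-logical style:

$$\frac{dX_i}{dt} \;=\;
\frac{-e^{0.5h} + e^{-h(\omega_i - 0.5)}}
     {\left(1 - e^{0.5h}\right)\left(1 + e^{-h(\omega_i - 0.5)}\right)}
\;-\; k_i X_i ,$$

a sigmoidal activation response $f_h(\omega_i)$ minus first-order decay.
The normalization pins $f_h(0)=0$, $f_h(1/2)=1/2$, $f_h(1)=1$ for every
gain $h>0$, so activities can never leave $[0,1]$ (`activationResponse()`
enforces this and the test suite asserts it to $10^{-12}$). The total
input $\omega_i$ is the product of a saturating activation factor and a
complementary inhibition factor over the node's regulators:

$$\omega_i = \underbrace{\frac{1+\sum \alpha_n}{\sum \alpha_n}\cdot
  \frac{\sum x^a_n \alpha_n}{1+\sum x^a_n \alpha_n}}_{\text{activation}}
  \cdot
  \underbrace{\left(1 - \frac{1+\sum \beta_n}{\sum \beta_n}\cdot
  \frac{\sum \beta_n x^i_n}{1+\sum \beta_n x^i_n}\right)}_{\text{inhibition}},$$

with $\alpha$ (activator) and $\beta$ (inhibitor) weights. A node without
activators is either *silent* (activation factor 0, it simply decays) or
*constitutive* (factor 1), the latter being the β-catenin form: its
$\omega$ is one minus its inhibition by cadherin-11. Time is in arbitrary
units (the relaxation scale is $1/k_i$); only steady states carry
quantitative meaning, which is why every analysis in the package reports
converged steady states, never transients.

## The curated network and its parameters

`baselineNetwork()` encodes the ten species — cdh11, pdgfrA, pdgfrB, ras,
raf, mek, erk, dusp1, Bcat, cyclinD1 — three constant external inputs, and
fifteen edges:

* cell–cell contact `c = 0.1` activates cdh11 ($\alpha=1$) and, as
  adjacent-cell cadherin, pdgfrA ($\alpha=0.5$, alongside its ligand
  `a = 0.1` at $\alpha=0.5$). The distinction matters: the *external*
  input `c` is the neighbour's cadherin and drives PDGFR-α, while the
  *dynamic* cdh11 node is the same-cell cadherin that inhibits PDGFR-β
  and β-catenin.
* ligand `b = 0.4` activates pdgfrB ($\alpha=0.5$), inhibited by cdh11
  ($\beta=1$);
* both receptors feed RAS equally, then RAF → MEK → ERK ($\alpha=1$
  each), with DUSP1 inhibiting ERK and ERK activating DUSP1 (a negative
  feedback loop), and DUSP1 activating cyclin-D1;
* constitutive Bcat is inhibited by cdh11 and inhibits DUSP1 — the
  proposed downstream crosstalk.

Gain $h=1$ everywhere; all decays $k_i = 1$ except β-catenin's $k = 2$,
compensating its full initial activity ($X_{Bcat}(0)=1$; all other
initials are 0) and its involvement in other pathways. Ligand and contact
levels were chosen to reproduce the knockdown calibration below; all other
weights default to 1, the conventional choice when quantitative data are
lacking.

```{r}
net <- baselineNetwork()
round(activities(steadyState(net)), 4)
```

## Steady-state machinery and numerical choices

Two independent solvers are exported and cross-checked everywhere:

* `steadyState()` integrates the ODEs (`deSolve::ode`, lsoda, with tight
  tolerances) in chunks of 25 time units until
  $\max_i |dX_i/dt| \le 10^{-9}$, capped at $t = 200$ — generous against
  the $1/k \approx 1$ relaxation scale. Hitting the cap is reported as
  `converged = FALSE`, never silently.
* `algebraicFixedPoint()` solves the algebraic system
  $X_i = f_h(\omega_i(X))/k_i$ by damped iteration
  $X \leftarrow (1-\lambda)X + \lambda f_h(\omega(X))/k$. The ERK–DUSP1
  negative feedback makes the undamped map oscillate, hence the default
  $\lambda = 0.5$; if the residual stalls over 500 iterations the damping
  halves automatically (down to $\lambda/32$) before the solver reports
  failure.

The suite requires the two routes to agree to $10^{-6}$ on the curated
network, on every registered scenario, and on dozens of random networks;
steady states are also required to be independent of the starting point
(ten random initial states per network). Both facts justify not treating
the unlisted initial activities as meaningful parameters. Inside the
integrator the right-hand side is extended continuously by clamping trial
states (and the resulting $\omega$) into $[0,1]$, so round-off-level
excursions cannot trip the strict domain checks of the exported
functions; reported trajectories are snapped back into $[0,1]$ only
within $10^{-8}$, and anything larger is an error.

### Ablation semantics

How should "interaction X is disabled" be encoded? The natural-looking
choice — set the weight to zero and drop the edge from both sums of
$\omega$ — has a defect for nodes with several inputs: removing one
activator *re-scales* the saturating prefactor $(1+\sum\alpha)/\sum\alpha$
of the survivors (for PDGFR-α from 2 to 3), so blocking the binding of a
ligand that is already absent would *change* the node's activity. That is
unphysical, and it breaks the scenario equivalences this model family is
built to exhibit (e.g. disabling receptor crosstalk on top of a full
knockdown must be a no-op for the ERK arm).

`cdh11net` therefore distinguishes an edge's *signal weight* from its
*normalization weight*: a zero-weight override blocks transmission but
retains the edge's share of the saturating capacity, while a positive
override re-parameterizes both together (so parameter scans behave
exactly as a re-parameterized model). Edges constructed with weight 0
are simply absent. Under this convention the three published
equivalences hold exactly:

* receptor-crosstalk-disabled + knockdown $\equiv$ plain knockdown;
* downstream-disabled + knockdown $\equiv$ all-crosstalk-disabled +
  knockdown on every node;
* with all crosstalk disabled, a knockdown moves only β-catenin (and the
  cdh11 node itself, which tracks its zeroed input).

## Scenarios and comparison metrics

`scenarioNames()` registers ten setups: baseline, full cadherin-11
knockdown (`c = 0`), the two binding-blocked calibration scenarios, and
the crosstalk ablations (receptor-level, downstream, both), each also
combined with the knockdown. One subtlety is the
`contact-off-pdgfra-binding-off` scenario: cadherin-11 is prevented from
dimerizing (so `c = 0` and β-catenin is released) yet still inhibits
PDGFR-β through intramembrane contacts — this requires *clamping* cdh11 at
its baseline steady level 0.18, holding it during integration while it
remains visible to other nodes' $\omega$. Merely initializing it there
would let it decay and spuriously release PDGFR-β.

`runScenario()` reports, per node, the baseline and scenario steady
states, their difference, and the percent change under *both*
denominators: the knockdown calibration figures only reproduce as a
mixture — the PDGFR-α "50 % decrease" is relative to baseline
($-48.1\%$), while the PDGFR-β "30 % increase" is relative to the
cadherin-free scenario value ($+30.8\%$; relative to baseline it is
$+44.5\%$). Since the fixed-point arithmetic is unambiguous (knockdown
PDGFR-β is exactly $0.5$, because its $\omega$ collapses to $0.5$ and
$f_h(0.5)=0.5$; baseline is $0.346$), reporting both conventions makes
every printed number reproducible without guessing intent.

```{r}
cmp <- runScenario("cadherin-11-knockdown")
cmp[cmp$node %in% c("pdgfrA", "pdgfrB", "erk", "cyclinD1"), ]
```

Direction labels use a tolerance $\varepsilon = 0.01$: the baseline
cyclin-D1 − ERK gap ($\approx -0.007$) must classify as "no change", as
the baseline parameterization is defined to have numerically equal ERK
and cyclin-D1 activities; $0.01$ is the coarsest round number above that
gap and well below every genuine effect in the model (the smallest is
$\approx 0.02$).

Fractional knockdowns (`knockdownEfficiencySweep()`) scale the contact
input to $(1-e)\,c$, letting the same-cell cdh11 node track the loss
through its own dynamics; receptor activities respond monotonically over
the tested efficiencies $\{0.25, 0.5, 0.75, 0.8, 1\}$.

## The proliferation readout and the parameter scans

The change-in-proliferation statistic is the raw signed difference
$\Delta = X_{cyclinD1} - X_{erk}$ at steady state ($\Delta > \varepsilon$:
increased; $\Delta < -\varepsilon$: decreased). Four 5×5 scans probe the
parameters around the proposed crosstalk, each cell a steady-state solve
of the re-parameterized baseline network:

* **A** β(dusp1 ⊣ Bcat) ∈ {0.1, 0.5, 1, 5, 10} × initial Bcat ∈
  {0.1, 0.3, 0.5, 0.7, 1};
* **B** β(dusp1 ⊣ Bcat) × α(dusp1 ← erk), both on {0.1, 0.5, 1, 5, 10};
* **C** β(erk ⊣ dusp1) × α(erk ← mek);
* **D** β(erk ⊣ dusp1) × α(cyclinD1 ← dusp1).

Scan A's second axis deliberately varies only an initial condition; since
steady states are initial-condition independent, its columns are
degenerate — a property the tests assert rather than a bug. The suite
checks the sign structure: strong DUSP1 inhibition by β-catenin
(β ∈ {5, 10}) forces $\Delta < 0$ in scans A and B, weak inhibition with
strong DUSP1 activation forces $\Delta > 0$, scan C stays numerically
small across the grid (robust control of ERK), and strong cyclin-D1
activation (α ∈ {5, 10}) keeps $\Delta > 0$ throughout scan D, growing
with ERK inhibition.

```{r}
summarizeScan(runScan("A"))
```

`plotScan()` renders a heatmap (axis 2 horizontal, axis 1 vertical,
baseline cell marked "X") when ggplot2 is available.

## Random networks: what the generator emulates

`randomNetwork()` samples arbitrary topologies in the same formalism —
log-uniform weights on $[0.1, 10]$ (the scan range), decays on $[1, 2]$
(bracketing the curated values), Bernoulli edges, optional constitutive
flags, seeded determinism — so that engine guarantees are exercised far
beyond one hand-built model: trajectory boundedness, solver agreement and
seed reproducibility are asserted on dozens of generated instances, and
`perturbWeights()` fuzzes the curated topology. Feedback loops are
allowed (the curated network contains one), which is why the fixed-point
solver always runs damped and any solver disagreement on a cyclic
instance surfaces as a test failure rather than being skipped.

The generator emulates the *formalism*, not biology: random topologies
have no scale-free structure, no mass-action interpretation, and no
claim to realism. Passing properties on them demonstrates numerical
correctness of the engine, not validity of any particular biological
network — and likewise, reproducing the curated model's steady states
shows the qualitative model is faithfully implemented, not that the real
signalling system behaves this way.

## Known limitations

* The model is qualitative by construction: activities are relative,
  time is arbitrary, and transients are not interpretable. Questions
  about kinetics require a mechanistic (mass-action) re-parameterization,
  which is out of scope.
* All co-activating inputs are assumed to contribute equally (weights
  from the curated table); only the scan module explores alternatives.
* The ablation semantics above is a modelling choice; a variant that
  re-scales the saturating capacity on ablation can be built with
  `logicNode()` directly (construct the node without the edge), and
  differs only for nodes with multiple same-sign regulators.
* Partial-efficiency variants of the binding-blocked scenarios are not
  modelled, and DUSP1 stands in for the whole DUSP family.
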