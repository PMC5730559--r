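---
title: "Modeling directional pharmacodynamic interactions on checkerboard data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling directional pharmacodynamic interactions on checkerboard data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdi)
```

## The problem

Checkerboard experiments cross the concentration tiers of two drugs and read
out a joint response — typically growth inhibition of a microorganism.
Classical analyses compress such a surface into a single synergy/antagonism
score against a null-interaction reference (Loewe Additivity or Bliss
Independence). A single score hides two things that matter pharmacologically:
*which* drug drives the interaction, and *how the interaction itself depends
on concentration*. This package implements an interaction model that keeps
both: each drug's pharmacodynamic (PD) parameters can be shifted by a
saturable function of the partner drug's concentration, so a pair of drugs
gets two *directional* interaction estimates (perpetrator on victim, and the
reverse) rather than one symmetric label.

## Model

Single-drug exposure–response uses the sigmoidal maximum-effect (Hill) model

$$E(C) = \frac{E_{max} C^{H}}{EC_{50}^{H} + C^{H}},$$

with effect scale 1 = full growth inhibition. Linear slope ($E = S\,C$) and
power ($E = S\,C^{H}$) forms are provided for designs whose highest tier sits
well below the EC50.

The interaction term multiplies a PD parameter $\theta$ of the victim drug by

$$1 + \frac{INT \cdot C_{perp}^{H_{INT}}}{EC_{50,INT}^{H_{INT}} + C_{perp}^{H_{INT}}},$$

where $INT \in [-1, \infty)$ is the maximum fractional change of $\theta$,
$EC_{50,INT}$ the perpetrator's interaction potency and $H_{INT}$ its
sigmoidicity (1 unless deliberately estimated). On the EC50 the term encodes
competitive-type behavior — negative $INT$ potentiates the victim (synergy),
positive $INT$ inhibits it (antagonism); on the Emax the polarity reverses
(allosteric type). Several perpetrators compose as a product of such factors,
and a third drug can *modulate* a pairwise $INT$ through a nested term of the
same form, which is how emergent higher-order interactions are expressed.
The shifted EC50 enters the Hill equation before exponentiation,
$(EC_{50} f)^{H}$ — the factor acts on the concentration scale.

Shifted single-drug effects are combined under a chosen additivity
criterion:

* **Bliss Independence**: $E = 1 - \prod_i (1 - E_i)$;
* **Loewe Additivity**: the implicit dose-substitution equation
  $\sum_i C_i / (EC_{50,i} f_i\,(E/(E_{max,i}-E))^{1/H_i}) = 1$, solved for
  $E$ by bracketed root finding (the left side is monotone decreasing in
  $E$, so the root in $(0, \min E_{max})$ is unique; the residual at the
  returned root is below $10^{-10}$). Loewe admits only EC50-level terms;
* simple effect addition and highest single agent, mostly as references.

Comparator models from the response-surface literature are included: the
Greco surface (Loewe plus a single interaction index $\alpha$, solved with
the same bracketing machinery; $\alpha > 0$ synergy), the empiric Bliss model
$E = E_A + E_B - \beta E_A E_B$ ($\beta < 1$ synergy), and the isobole
curvature score $\gamma = \text{logit}(x) - \text{logit}(y)$ on MIC-normalized
equi-effect points ($\gamma < 0$ synergy; the log base only rescales the
score, natural log by default).

For longitudinal optical-density read-outs a two-state growth model links the
combined effect to the data: a lag state drains into a logistically growing
state whose growth term is scaled by $(1 - E_{comb})$. Integration uses a
non-stiff solver at relative tolerance $10^{-10}$ with a stiff fallback. Note
that the lag inflow can push the growing state marginally above the carrying
capacity (bounded by the residual lag mass); this is a property of the model,
not of the solver.

## Estimation

All fitting is maximum likelihood with additive Gaussian residuals on the
observation scale; the residual SD can be fixed or profiled out at its ML
value. Parameters are estimated on transformed scales — log for
concentration-like, rate and sigmoidicity parameters, $\log(1 + INT)$ for
interaction magnitudes (keeping the shift factor positive), logit for an Emax
estimated inside $(0,1)$ — so no constrained optimizer is needed. Each fit
runs a Nelder–Mead simplex from the nominal start plus four jittered starts
(seeded by the caller), polishing the best result with BFGS; one-dimensional
fits use bounded Brent search. Standard errors come from the numerical
Hessian of the objective (observed Fisher information); near-singular
Hessians — e.g. when a saturated interaction leaves $INT$ and $EC_{50,INT}$
jointly unidentified along a ridge — are inverted by eigenvalue truncation
and the affected parameters are reported as `NA` rather than as misleading
numbers.

Model building is stepwise:

1. monotherapy arms only: Emax (fixed at 1 for turbidity data by
   convention, optionally estimated), EC50 and $H$ per drug, plus shared
   growth parameters for time-course data;
2. a *reduced* interaction model — one shared $INT$ for both directions,
   each direction's $EC_{50,INT}$ tied to the perpetrator's EC50 — is fitted
   first and then expanded greedily one parameter at a time (directional
   split of $INT$, freeing each $EC_{50,INT}$, optionally the $H_{INT}$s).
   An expansion is kept only if the objective (−2 log-likelihood) drops by at
   least 3.84, the $\chi^2_1$ criterion at $\alpha = 0.05$. Ties prefer the
   directional split, then the lexicographically first candidate;
3. modulator terms would be tested on data with three or more drugs; a
   two-drug checkerboard has none, so the structure is final after step 2;
4. all retained parameters are re-estimated jointly and standard errors are
   reported from that fit.

One design choice deserves emphasis. The textbook staged procedure fixes the
step-1 single-drug estimates during step 2. That is innocuous when the
monotherapy information is rich (long time-courses), but with a single
endpoint read per well the step-1 estimates carry enough error that the
candidate LRT becomes sharply anti-conservative: in our null simulations the
directional split was accepted in roughly a quarter of replicates instead of
5%, because directional interaction parameters absorb drug-specific error in
the fixed EC50/Hill values. The default here therefore re-estimates the
single-drug parameters inside every candidate fit, which restores the nested
$\chi^2_1$ comparison and the nominal error rate; `stepwise_config(fix_single
= TRUE)` recovers the strict staged variant for rich data.

Fitted interactions are summarized as the fractional change of the victim's
EC50 at the perpetrator's own EC50 (so a saturated $INT = 3.32$ reads as "the
victim EC50 rises to 432% of baseline"). In the reduced model this summary
equals $INT/2$ exactly, since the potency tie puts the perpetrator EC50 at
the interaction midpoint. Pairs are classified six ways against an additivity
margin on that shift: additive, bidirectional synergy/antagonism,
monodirectional synergy/antagonism, and bidirectional-asymmetric (both
directions outside the margin with opposite polarity — concentration-
dependent synergy/antagonism). The default margin is the pragmatic fixed
$(-0.5, 0.5)$; an empirical margin can be derived as the 10th–90th percentile
of shifts fitted to sham (drug-versus-itself) checkerboards, which carry no
true interaction. Boundary values count as additive (conservative calling).
Sham fits against Bliss drift towards apparent self-synergy — a drug cannot
act independently of itself — which is why the sham margin is derived under
Loewe and reused for the Bliss-based calls.

For network analysis, calls from the Loewe- and Bliss-based fits are joined
*exclusively*: a directed perpetrator→victim edge survives only if the shift
is outside the margin under both criteria with the same polarity (conflicting
polarities are dropped and logged; the criteria disagree about such pairs and
no unbiased direction exists). Edge values carry the Loewe shift as primary
and the Bliss shift as a secondary attribute. Per-drug profiles tally in- and
out-edges by polarity and flag sole perpetrators and sole victims.

## Design identifiability

Before running an experiment one can ask how precisely a checkerboard design
could estimate the interaction parameters at all. The expected Fisher
information of a design is $FIM = J^\top J / \sigma^2$ with $J$ the Jacobian
of the predicted effects with respect to the free parameters (central finite
differences, relative step $10^{-6}$); anticipated relative standard errors
are $100\sqrt{\text{diag}(FIM^{-1})}/|\theta|$. `identifiability_study()`
repeats this over random scenarios of a symmetric two-drug Bliss-based
interaction model — both partners share the sampled Emax, EC50 and $H$, and a
symmetric bidirectional term shares $INT$ and $EC_{50,INT}$, giving the
five-parameter free vector (Emax, EC50, $H$, $INT$, $EC_{50,INT}$). Scenarios
draw Emax ~ U(0.5, 1), EC50 ~ U(0.5, 2), $H$ ~ U(1, 4), $INT$ from
U(−0.9, −0.5) or U(0.5, 20) by fair coin (no weighting is prescribed between
the synergy and antagonism sub-ranges), $EC_{50,INT}$ ~ U(0.1, 1), with
$\sigma = 0.03$ on the effect scale — the variability typical of in vitro
interaction read-outs.

Two 8×8 tier layouts are compared. The log2 design uses 0 plus seven
two-fold steps up to the top concentration 8 (one defensible reading of
"tiers from 0 to 8 in base-2 steps"; the tier vectors are user-overridable).
The linear design spaces tiers evenly from 0 to 8 and repositions the
potency parameters into the middle of the studied range: both EC50 and
$EC_{50,INT}$ are drawn from U(0.4, 0.6) × c\_max. We read the repositioning
as applying to both potency parameters — they are both "EC50 values" on the
concentration scale — and note that repositioning only the single-drug EC50
would leave the interaction nearly saturated above the first non-zero tier
and produce markedly smaller (more optimistic) anticipated RSEs for $INT$.
Under these settings the log2 design anticipates median RSEs of roughly 8%
for $INT$ and 20% for $EC_{50,INT}$, against roughly 30% and 52% for the
linear design: log-spaced dilutions are clearly preferable, which is the
practical message of the study.

## Synthetic data

`generate_checkerboard()` emulates the screening setting end to end: a truth
model and design produce either endpoint effect observations or
lag-logistic OD time-courses (default 20 points over 24 h), with additive
Gaussian noise (default SD 0.03) and truncation of negative observations at
zero (events counted). `generate_sham()` crosses a drug with itself for
margin calibration. Defaults — 8×8 log2 tiers, $\sigma = 0.03$, 24 h
read-out — mirror the anti-infective screening design the package targets;
the growth defaults ($k_{lag} = 0.5\,h^{-1}$, $k_{growth} = 0.7\,h^{-1}$,
$B_{max} = 1$ OD, inoculum 0.02 OD placed in the lag state) are plausible
for yeast turbidity experiments but are conventions, not measured values.
What the generator does *not* emulate: plate-reader artifacts (edge effects,
evaporation, drift), drug degradation, regrowth/resistance, and
inter-experiment variability. Passing tests on these fixtures therefore
demonstrates correctness of the estimation machinery under the stated noise
model, not robustness to real assay pathologies.

```{r example, eval = FALSE}
truth <- interaction_model(
  list(pd_drug("A", emax = 1, ec50 = 1, hill = 2),
       pd_drug("B", emax = 1, ec50 = 2, hill = 3)),
  gpdi_term("B", "A", "EC50", int = 3, ec50_int = 0.5),
  criterion = "bliss")
dat <- generate_checkerboard(truth, checkerboard_design("log2"),
                             sigma = 0.03, seed = 4)
fit <- fit_gpdi_stepwise(dat, "bliss")
fit$history   # every tested expansion and its OFV drop
```

## Numerical choices and limitations

* Loewe/Greco root finding brackets $[10^{-12}, \min E_{max}(1 - 10^{-12})]$;
  dose-fraction overflow near $E = 0$ (possible for very shallow Hill slopes
  during optimization) is clamped to a large finite residual. When the
  combined effect presses against an unequal smaller Emax the value is capped
  and flagged rather than failing, and for strongly negative $\alpha$ the
  Greco equation may lose its root, in which case the boundary value is
  returned with a flag so batch fits proceed.
* Effect addition clips at 1 by default (the inhibition ceiling); `clip =
  FALSE` disables this.
* The Hill function is evaluated through a logistic form in log-concentration
  space, so extreme $C/EC_{50}$ ratios neither overflow nor lose the
  asymptote; $E(0) = 0$ exactly, including $H < 1$.
* Stepwise simulations in the test-suite run at the 8×8 endpoint scale (100
  null replicates, 50 asymmetric replicates; 1000-scenario identifiability
  studies), sizes chosen so the whole suite runs on a laptop in minutes while
  leaving Monte-Carlo error well inside the asserted bounds.
* Two-drug estimation is first-class; n-drug models (products of shift
  factors, nested modulation) are fully supported for simulation and
  evaluation, but the stepwise *search* over modulator structures (step 3)
  engages only when a dataset carries three or more drugs, and the bundled
  data containers are two-drug checkerboards.
* A drug may in principle carry EC50- and Emax-level terms from the same
  perpetrator; the model type permits it, but the stepwise search never
  proposes that combination, and under Loewe it is rejected outright.
* Bootstrap confidence intervals, population (mixed-effects) estimation and
  optimal-design search are out of scope.
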