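---
title: "An expert-elicited Bayesian network for serious spinal pathology screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An expert-elicited Bayesian network for serious spinal pathology screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sspbn)
```

## The problem

Serious spinal pathologies (SSPs) — cauda equina syndrome, spinal
malignancy, spinal infection, vertebral fracture, inflammatory disease —
are rare but devastating causes of low back pain, and conventional
*red-flag* checklists discriminate poorly. `sspbn` implements a clinical
decision-support model for this screening problem: a causal Bayesian
network whose structure and probabilities come from a structured expert
panel rather than from data, together with the consensus mathematics that
built it and the validation instruments that tested it.

## The model

The network is a three-layer directed acyclic graph over 38 binary
variables:

* **risk factors** (10 nodes) — antecedents such as trauma, bone health,
  steroid use, cancer history;
* **judgment factors** (11 nodes) — the candidate pathologies and related
  clinical judgments (deliberately not called "diagnoses");
* **signs and symptoms** (17 nodes) — observables such as saddle sensory
  disturbance, fever, night pain.

Edges run causally downward only (risk → judgment → sign), which makes the
graph acyclic by construction; acyclicity is nevertheless re-checked
independently by depth-first search. Every node and edge carries a
provenance tag recording how it was recovered from the published
elicitation summary; elements that cannot be reconstructed are explicit
placeholders with a stated reason.

```{r structure}
net <- build_default_network()
validate_structure(net)
provenance_report(net)
```

A design point worth stating: the published risk-factor lists name eleven
distinct antecedents while fixing the layer at ten variables. We reconcile
this by carrying uveitis and inflammatory bowel disease — two
extra-articular features of the same spondyloarthropathy spectrum — as a
single grouped risk node. The nomological reference map aliases both
published factor labels to that node, so every published containment mark
is still reproduced exactly.

### Conditional probabilities: leaky noisy-OR

The elicitation gathered *partial* probability judgments, one scenario at a
time. We complete them with the standard model for expert-elicited
cause–effect networks, the **leaky noisy-OR**: each active parent $i$
independently triggers the child with link strength $s_i$, and a leak $l$
absorbs causes outside the model,

$$P(\text{child present} \mid A) \;=\; 1 - (1 - l)\prod_{i \in A} (1 - s_i),$$

where $A$ is the set of parents in the *present* state. This needs exactly
one number per edge plus one leak per node — matching the scenario-based
elicitation format — and is monotone: switching a parent on never lowers
the child's probability.

The elicited values themselves were never published, so the packaged
default parameterization draws them reproducibly from documented ranges:
risk-factor priors uniform on $[0.05, 0.4]$; judgment leaks and judgment
root priors uniform on $[0.001, 0.02]$ (serious pathologies are rare); sign
leaks uniform on $[0.01, 0.05]$; link strengths uniform on $[0.2, 0.9]$.
Unlinked sign nodes (background symptoms such as sleep disturbance) take
priors from the risk range, reflecting ordinary symptom prevalence. Where
an edge carries an elicited 0–3 strength, it seeds the link through the
fixed map $\{0 \to 0,\ 1 \to 0.3,\ 2 \to 0.6,\ 3 \to 0.85\}$, preserving
the elicited ordering. Because a judgment factor's baseline rate must stay
rare, each judgment node's incoming link strengths are then shrunk by a
single scale factor — solved exactly with `uniroot` on the closed-form
marginal $1 - (1-l)\prod_i (1 - p_i \lambda s_i)$ — until its no-evidence
marginal is at most 0.1. All draws are pure functions of the seed
(Mersenne-Twister, R's default generator).

```{r params}
params <- default_parameterization(net, seed = 1)
pnet <- attach_parameters(net, params)
round(posterior_judgments(pnet)$posteriors, 4)
```

### Inference

Queries are answered exactly by **variable elimination** with a min-fill
elimination order and deterministic lexicographic tie-breaking, in linear
probability space (at 38 binary nodes underflow is not a concern, and
linear space keeps comparisons with the enumeration oracle exact).
*Unknown* is not a node state: an unobserved node is simply omitted from
the evidence and marginalized, which is precisely the "prior baseline
assumption" behavior the elicitation asked for. Two structural
optimizations are applied before elimination, both exact: barren leaves
(unobserved, unqueried, childless) are dropped, and factors disconnected
from the query after evidence reduction are discarded, since their product
is a constant that cancels in normalization. The second matters beyond
speed — it makes posteriors that are analytically constant across cases
come out bit-identical, so chance-level experiments produce exact score
ties rather than $10^{-16}$ noise.

`brute_force_posterior()` is an independent oracle that sums the full
joint; it shares no code with the elimination path and is guarded to 20
nodes. The test suite and the acceptance script compare the two on
hundreds of randomly structured and parameterized three-layer networks;
agreement is at machine precision (tolerance $10^{-9}$).

```{r infer}
ev <- c(saddle_sensory_disturbance = "present",
        bladder_function_change = "present")
round(posterior_judgments(pnet, ev)$posteriors, 4)
```

## Consensus mathematics of the elicitation

Panelists scored candidate relationships on a 0–3 scale; a relationship
became an edge when the panel's **median** was high and its
**interpercentile range (IPR)** low. The package uses the 30th–70th
percentiles (the convention of the appropriateness-method literature the
elicitation followed), computed by linear interpolation at the Weibull
plotting position $(n+1)p$ (`quantile` type 6) — the variant consistent
with worked reference examples such as scores $(2,2,3,3,3)$ giving
$P_{30}=2$, $P_{70}=3$. Default thresholds are median $\ge 2$ and IPR
$\le 1$; the published account states only "high median, low
interpercentile range", so both are configurable and are recorded in every
result. With a single panelist the IPR is zero by construction and the
rule reduces to the median threshold. Stage-1 importance rankings are
aggregated by ascending median rank with lexicographic tie-breaking.

```{r consensus}
edge_decision(c(0, 0, 0, 3, 3, 3, 3))   # split panel: excluded
edge_decision(c(2, 2, 3, 3, 3))          # consensus: included
```

## The validation harness

Four of the seven domains of the model-validation framework are
computable here; the three comparator-based domains (concurrent,
convergent, discriminant) require an independent model of the same
construct, which does not exist, and are deferred:

```{r registry}
validation_registry()[, c("domain", "implementable")]
```

**Content/face agreement — Gwet AC2.** Expert review responses are compared
with the original panel using Gwet's chance-corrected weighted coefficient
$(p_a - p_e)/(1 - p_e)$, with $p_e$ built from category propensities
$\pi_k$ and the total weight $T_w$; identity weights (the default, for
nominal categories) reduce AC2 to AC1, and ordinal weight schemes are
available. Coefficients are interpreted on the conventional bands (poor →
almost perfect), implemented as half-open intervals so the function is
total — the printed band edges leave gaps (e.g. 0.2 vs 0.21) that an
implementation must close. Banding the published per-variable coefficients
reproduces the published 9-of-11 "almost perfect" count:

```{r banding}
band_summary(expert_agreement_coefficients())
```

**Nomological containment.** The packaged reference maps each of six
conditions to its published guideline factor list. A factor counts as
*contained* when its node exists **and is linked to that condition** —
node existence alone would overcount (age is in the network but is
deliberately not linked to nerve-root condition). Under this definition
the computed table reproduces every published containment mark, including
the headline 1-of-7 for the nerve-root guideline factors:

```{r containment}
containment_check(net)
```

**Predictive validation — ROC/AUC.** Cases carry partial evidence and 0/1
labels for the six predictable conditions. Each case is scored with the
exact posterior of each condition; AUC is computed by rank-sum pair
counting with ties worth one half, and the tie-grouped ROC curve is
returned alongside (pair counting and trapezoidal integration of that
curve agree to machine precision; tests also cross-check against pROC).
Single-class label sets yield an *undefined* AUC with a diagnostic, never
an error. The three published sensitivity variations are reproduced
deterministically: `higher_risk` switches on the first (canonical node
order) not-yet-present sign linked to the labeled condition —
deterministic rather than random for reproducibility — and the
add-cancer/add-inflammatory variations switch on every sign linked to
those conditions. Labels are never altered.

## What the synthetic generators emulate — and what they do not

The clinical case series behind the published ROC analysis was never
released, so the package ships seeded generators instead:

* `forward_sample()` — ancestral sampling of labeled cases (judgment states
  hidden into labels, risks and signs observed);
* `synth_rating_matrix()` — panel ratings mixing a designated score with
  uniform noise at a set concordance;
* `synth_agreement_table()` — categorical ratings matching a designated
  category at a set agreement level.

These reproduce the *statistical structure* the instruments assume
(sampling–inference consistency holds within three standard errors at
$n = 10{,}000$; AUC recovery reaches $\ge 0.9$ under strong signal and sits
at chance when a condition's outgoing links are zeroed). They do **not**
emulate real referral populations: no case-mix, no correlated missingness,
no measurement error in sign reporting, and prevalence is whatever the
configured priors imply. Passing tests therefore demonstrate that the
machinery is correct, not that the published accuracy figures transfer to
clinical data — the published AUCs are deliberately not acceptance targets
because the elicited probability tables and the codified case evidence are
unpublished.

```{r recovery}
strong <- attach_parameters(net, default_parameterization(
  net, 7, judgment_leak_range = c(0.001, 0.01),
  sign_leak_range = c(0.001, 0.01), link_range = c(0.8, 0.95)))
auc_recovery_experiment(strong, 300, seed = 7)
```

## Numerical choices and degenerate inputs

* Percentiles: `quantile` type 6; medians by the standard even/odd rule.
* Conditional table rows must sum to 1 within $10^{-9}$; noisy-OR
  expansion matches the closed form within $10^{-12}$; serialization
  writes probabilities with 15 significant digits so round trips preserve
  doubles.
* Elimination order: min-fill, ties broken lexicographically; recorded in
  each report's diagnostics.
* Structure problems are *reported*, not thrown (`validate_structure()`),
  so malformed files can be diagnosed; evidence errors name the offending
  node or state; a single-class ROC is undefined rather than an error; an
  exhausted `higher_risk` variation is an error because silently returning
  the unchanged case would corrupt a sensitivity analysis.
* Problem sizes used by the shipped checks: 200 random networks of ≤ 12
  nodes for the oracle-equivalence sweep, $n = 2000$ cases for the AUC
  recovery experiments, $n = 10{,}000$ for sampling consistency — sizes at
  which the binomial error bars are tight enough for three-standard-error
  assertions while the full run stays comfortably on one CPU.

## Known limitations

* The packaged structure is a reconstruction: the complete elicited edge
  list was published only as a figure, so two sign nodes are placeholders
  and elicited 0–3 strengths are absent (the seeding map is tested on
  constructed edges instead).
* The packaged probabilities are documented random draws, not the elicited
  values; any conclusion about real-world screening accuracy requires the
  original tables or clinical data.
* Judgment factors are assumed mutually unlinked (no
  condition-to-condition edges) and all nodes binary; nothing in the
  published account requires otherwise.
* No approximate inference and no structure learning — the network is
  small enough for exact computation, and refining the tables from data is
  explicitly future work.
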