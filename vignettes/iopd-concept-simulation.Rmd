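---
title: "Qualitative concept-network simulation of IOPD: model, choices, limits"
author: "fcmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative concept-network simulation of IOPD: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmsim)
```

## The model and its assumptions

`fcmsim` treats a cell as a fuzzy cognitive map: a signed, weighted
directed graph whose nodes (genes, proteins, phenotypic states,
compounds) carry activation levels in $[-1, 1]$, iterated synchronously
through a bounded squashing function,

$$x_i(t+1) = \tanh\!\Big(g\big[\textstyle\sum_j W_{ij}\,x_j(t) + \mu\,
x_i(t)\big]\Big),$$

followed by clamp overwrites. The modelling commitments this makes:

- **Qualitative levels, not concentrations.** A value near $+1$ means
  "strongly expressed / present", near $-1$ "repressed / absent". Only
  directions and orderings are interpretable; magnitudes have no units.
- **Synchronous discrete time.** All concepts update together; an
  "iteration" is not a physical time unit, so published iteration counts
  for other networks are not comparable quantities.
- **Monotone signed influence.** An edge contributes its weight times the
  source activation, summed linearly before squashing. Saturating
  combinatorial logic (AND-gates etc.) is not representable.
- **State memory.** With $\mu = 1$ each concept feeds its own previous
  value back into its update. Because $\tanh$ has unit slope at the
  origin, a *single* concept with memory still has a unique driven fixed
  point; bistability (hysteresis) arises only from network feedback loops
  whose gain exceeds 1 — which is exactly how the bundled network encodes
  cell identity (below).

The interface for interventions distinguishes two clamp semantics.
*Initial-only* clamps model transient inputs: the concept starts at the
clamp value and then evolves freely (a reprogramming-factor pulse).
*Hold* clamps overwrite the concept every iteration from `active_from`
onwards: gene deletion (hold at $-1$), a continuously present drug or
transgene (hold at $+1$), fractional inhibition of a dose $f$ (hold at
$-f$). Hold clamps are applied *after* squashing, so clamped entries are
exact — the full loss of a deleted gene propagates undiluted through the
weight matrix at every iteration.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `tol` (ε) | `1e-4` | convergence tolerance on the max-norm of successive state differences; steady-state values are only meaningful to this resolution |
| `window` (k) | 5 | consecutive sub-ε steps required; guards against declaring convergence inside a slow oscillation |
| `maxIterations` | 1000 | iteration budget; doubles as the horizon of the "overtraining" check (a classified fixed point must persist to the budget when `overtrain = TRUE`) |
| `memory` (μ) | 1 | state-memory coefficient; μ = 0 recovers the memoryless map and is exposed because both variants are standard in the fuzzy-cognitive-map family |
| `squashGain` (g) | 1 | slope of the squashing at 0; higher gains sharpen switching (the limit-cycle tests use g = 5) |
| `noiseSigma` | 0.05 | half-width of the uniform jitter applied to initial values of unclamped concepts in replicate runs; 0 disables noise |
| `seed` | 1 | controls all randomness; replicate r of an ensemble uses the r-th seed derived deterministically from it |

The update rule, squashing and convergence criterion are the package's
own specification: the family of commercial simulators this work emulates
describes itself only as a hybrid of recurrent networks and cognitive
maps, so the standard tanh-squashed FCM with a state-memory term was
chosen and every free parameter is exposed in `simConfig()` rather than
hard-coded. Published iteration counts from those systems are therefore
*not* reproduction targets; the package's own convergence behaviour is.

## Replicate noise: what the error bars mean

A deterministic map gives identical replicates, yet simulation studies in
this genre report mean ± SEM over "independent simulation experiments".
The package's noise model makes that operational: each replicate jitters
the *initial values* of unclamped concepts by i.i.d. uniform noise of
magnitude `noiseSigma` (an alternative mode jitters edge weights
instead). Because the study attractors are robust to a 0.05 perturbation,
replicate terminal states agree to within the convergence tolerance and
SEMs are tiny — the error bars certify attractor robustness, not
biological variability. With `noiseSigma = 0`, SEM is exactly 0.

A sharp consequence, discovered by the test suite: sub-tolerance
convergence residuals ($\sim 10^{-7}$) are *systematically ordered*
between ensembles that stop at different iteration counts, so a
rank test on raw terminal values can report spuriously perfect separation
for a concept whose steady state is genotype-invariant.
`rankCandidateBiomarkers()` therefore snaps values to the `tol` grid
before testing (disable with `tol = 0` for measured data).

## The bundled IOPD network

The 53-concept, 92-edge network is a deliberately small,
literature-anchored surrogate for proprietary multi-thousand-concept
databases. It is built to reproduce *directional steady-state calls*, not
network scale, degree statistics or iteration counts (the seeded random
generator, not this network, carries the published ~8-degree / 0.66
positive-sign statistics for property testing). Its design:

- **Cell identity as bistable attractors.** OCT4–SOX2–NANOG form a
  mutually activating core with loop gain > 1: a transient OSKM pulse at
  iteration 0 switches the latch on, after which it self-sustains — the
  pluripotent state. Mutual antagonism between the core and MyoD1 makes
  pluripotency and the muscle program (MyoD1 → Myogenin/CKM/MyHC, Pax7
  repressed) exclusive: with an OSKM pulse the core wins and endogenous
  MyoD1 is suppressed despite the held transgene; without it, the MyoD1
  program latches and drives the core negative. This is why the
  *same* held Doxycycline + exogenous-MyoD1 recipe yields pluripotent
  cells with OSKM and muscle cells without.
- **Disease as a feed-forward cascade.** GAA (context-driven to a mildly
  positive baseline in wild type) inhibits lysosomal glycogen; locking
  GAA off flips glycogen positive, which drives LAMP2 and glucose
  deprivation, suppresses mTORC1 (hence p70S6K/p4EBP1 phosphorylation,
  hence de-repressed autophagy with LC3/p62 accumulation), and — with
  the calcium axis (glucose deprivation → VDCC → intracellular calcium →
  calpain) — drives mitochondrial dysfunction and its outputs (ROS,
  CytC, AIF, Caspase3, apoptosis, cell death, DNM1L, MFN2, ADP up, ATP
  down). The cascade deliberately contains no high-gain positive loop, so
  disease steady states are unique given the clamps: treatment clamps
  applied *after* disease onset can reverse them (no pathological
  hysteresis), and dose–response is monotone.
- **A genotype-invariant control.** Lysosomal calcium receives only
  context drive, so the wild-type and disease models agree on it — the
  "unchanged" call that `compareGenotypes()` makes with its ±0.05
  dead-band.
- **Deliberate absences.** TRA-1-60, Park2, FIS1, OPA1, COX4l1 and
  mitochondrial calcium are not modelled, mirroring the absences of the
  system emulated.
- Every edge carries a provenance note: `literature:` (restating, in our
  words, a mechanism reported for the wet-lab or simulated IOPD models)
  or `curated: closure edge` (added so signals propagate). Tests can
  therefore distinguish anchored from inferred structure.

Edge weights default to sign-plus-strength values chosen once so that
signal chains neither die out nor saturate everything; no weighting
scheme is published for the emulated system.

What passing the concordance suites does **not** show: that the network
generalises beyond its curated scope, that magnitudes mean anything, or
that the real disease follows these mechanisms — the network encodes the
literature's qualitative claims and the tests verify the dynamics
recover them at steady state, a consistency check, not wet-lab evidence.

## Validation statistics

**Bias-adjusted binomial.** Large curated networks of this kind carry a
positive-edge excess, so a positive prediction is right "by chance" more
often than 0.5; the chance-success probability is the pretest positive
probability $p_0$ (0.66 here, `networkStats()` computes it for any
network). The default `uniform` mode applies $p_0$ to every feature —
the convention under which all-correct agreement on $N$ features has
one-sided $p = p_0^N$ (0.000856 at $N = 17$, 0.0546 at $N = 7$, 0.0238
at $N = 9$). The `per_direction` mode instead gives expected-down
features chance $1 - p_0$, yielding a Poisson-binomial null computed by
exact convolution; it is the more defensible null for mixed-direction
profiles but is not the convention the printed values follow, so it is
opt-in. Two-sided p uses the method of small likelihoods (as
`binom.test` does). Note that with a biased null the two-sided p
dominates the upper-tail one-sided p only when the observed count is at
or above the null mode — the validation regime; below the mode the
small-likelihood two-sided p can be smaller than $P(X \ge a)$.

**Exact Mann–Whitney.** The permutation null given the pooled values is
enumerated completely — a subset-sum recursion counts, for every
achievable rank-sum, the number of group assignments realising it
(midranks doubled to integers; ties thereby handled exactly). This is
mathematically identical to brute-force enumeration of all
$\binom{n+m}{n}$ assignments (the test suite verifies this for all
$n + m \le 10$) but feasible to $n + m = 40$; beyond that the function
refuses rather than approximate. Completely separated equal groups of 15
give $p = 2/\binom{30}{15} = 1.289\times10^{-8}$. Two-sided p sums both
tails at the observed distance from the null mean, which is exact because
the midrank subset-sum distribution is symmetric.

**Replicate summaries** use SEM $= s/\sqrt{n}$ and t-based confidence
half-widths (99% by default, matching the genre's reporting).

## Treatments, scheduling and establishment

Fractional inhibition of dose $f$ is a hold clamp at $-f$: $f = 1$ is
exactly a knockout, and $f = 0$ clamps the target *to neutral*, which
silences it — not the same as no treatment. Dose–response sweeps
therefore use a **no-treatment sentinel** at the 0 grid point (no clamp
at all), since a 0% dose plainly means untreated.

Two schedules are implemented because the emulated study's narrative
("improvement after the initial establishment of the disease phenotype")
implies treatment after onset while leaving the alternative open:
`after_disease_steady_state` (phase 1 disease, phase 2 continues from the
phase-1 state with the treatment clamp added) and `from_start` (clamp
active from iteration 0). "Phenotype established" is operationalised as
*every* concept of a named phenotype set (default: lysosomal glycogen,
mitochondrial dysfunction, intracellular calcium, cell death)
simultaneously above a strict margin of 0.05 — the expression-call rule
($\ge 0$) would count the all-zero initial state as "present", so
establishment needs a margin. Under `from_start` the check scans every
recorded iteration, capturing transient establishment before reversal.

On the bundled network, CCB-style VDCC inhibition improves all four
default readouts at every dose from 25% up, and calpain inhibition from
10% up, both monotonically — matching the qualitative claims the network
was curated from. Low-dose calpain inhibition from the start does not
prevent phenotype establishment while a full knockout does; the exact
crossover dose depends on curated weights and is not asserted.

## Biomarker discovery

Candidate ranking uses the exact Mann–Whitney p with the mean-difference
magnitude as tie-break — on the bundled network the whole calcium axis
separates completely, so VDCC, intracellular calcium and calpain tie at
the exact-p floor and calpain is "among the top-ranked" rather than
uniquely first there; the synthetic-data recovery property uses the
generator, where calpain is the designed strongest marker.

The labelled-profile generator draws each marker from class-conditional
Gaussians truncated to $[-1, 1]$ (exact inverse-CDF truncation). The
default dataset is 75 rows, 36 Normal / 39 IOPD — the minimal confusion
structure consistent with the precision/recall pair this genre reports —
and the default effect table follows the sign and rough magnitude of the
bundled network's steady-state separation, with calpain given the
smallest dispersion (the "stood out" marker) and lysosomal calcium a
genotype-invariant null.

The discriminant is a one-variable logistic fit: the published analogue
was an evolved single linear term, so the hypothesis class (one marker,
one slope, one intercept, threshold at 0 for the Normal outcome) is
preserved while the evolutionary search is not. Coefficient magnitudes
are dataset-dependent and deliberately not compared; the sign (negative
for a disease-elevated marker, with Normal as positive outcome) is.
Perfect separation is tolerated: glm's coefficients diverge but scores
still order and classify correctly, which is all the decision rule, the
CV metrics and the rank-based AUC use. Cross-validation is stratified by
class with seed-deterministic fold assignment; metrics are pooled over
held-out predictions, and AUC is computed by the rank (U-statistic)
formulation, which the suite checks against `exactMannWhitney` as a
cross-module identity.

## Numerical choices and degenerate inputs

- Terminal value exactly 0 calls *expressed* (the ≥ 0 rule); only clamps
  can produce exact ±1 (finite inflow keeps tanh strictly inside).
- Duplicate edge rows: error in strict parsing, last-wins with a warning
  otherwise; weight 0 or |w| > 1 rows are rejected outright.
- An empty clamp set on a quiescent network converges at the window
  length with the zero state — zero is always a fixed point of the
  unclamped map.
- Non-convergent replicates are flagged in profiles and warned about,
  never dropped; phase-1 non-convergence aborts a two-phase run.
- Limit-cycle detection scans terminal-window periods 2..20 and reports
  the smallest period that repeats within tolerance and is not a fixed
  point in disguise.
- `deriveSeeds()` gives replicate r the r-th seed derived from the master
  seed, so ensembles are reproducible and extendable.

## Problem sizes

The shipped tests and the acceptance script run the 53-concept network
with 1–15 replicates per ensemble (a run converges in ~20–60 iterations;
sweeps use ε = 1e−9 to resolve small dose effects), 100 synthetic
datasets of 30 rows for recovery, and one 75-row dataset for
cross-validation — sizes chosen so the whole suite characterises the
method in seconds while exercising every code path at the study's
published feature counts (17/7/9 features, 15-per-group ensembles, the
25–100% and 10–100% dose grids).

## Known limitations

- Qualitative semantics only: no concentrations, kinetics or physical
  time; no dose units (fractions are abstract inhibition levels).
- Synchronous deterministic updates: no asynchronous or stochastic
  dynamics, no continuous-time ODE semantics, and no weight learning.
- The bundled network is a curated miniature: its closure edges are
  inference, its weights are design choices, and conclusions transfer to
  real IOPD biology only insofar as the encoded literature claims do.
- The exact Mann–Whitney is limited to n + m ≤ 40 by design; the package
  offers no approximate fallback.
- The binomial validation treats features as independent predictions;
  correlated features (e.g. a marker panel driven by one hub) overstate
  the evidence, in this package exactly as in the emulated system.
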