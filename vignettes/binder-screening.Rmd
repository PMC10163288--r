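---
title: "Screening designed binders with structure-prediction metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening designed binders with structure-prediction metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binderscreen)
```

## The screening problem

De novo binder design pipelines emit on the order of 10^5^–10^6^ candidate
minibinders per target, of which a fraction of a percent bind when tested.
Failures divide into two classes: the designed sequence does not fold to
the designed monomer structure (Type I), or the monomer folds but does not
form the designed interface (Type II). Structure predictors expose both:
a predicted monomer far from the design model (high monomer Cα RMSD, low
binder pLDDT) flags Type I; a predicted complex that disagrees with the
designed binding mode (high target-aligned complex RMSD, high interface
predicted-aligned-error) flags Type II. `binderscreen` implements these
metrics, the threshold and multi-objective selection layers that consume
them, the yeast-display SC50 readout used to label designs as
experimental successes, and the bookkeeping that turns pass rates and
compute costs into a pipeline-efficiency figure.

The package deliberately stops at the predictor's outputs: it builds the
initial-guess prediction request (sequences, full design Cα coordinates
for the first recycle, target-template flags) and consumes pLDDT/pAE
payloads, but performs no neural-network inference and no physics-based
energy calculation. Sequence designers and structure relaxers enter only
as pluggable stage contracts with deterministic mock implementations.

## Metrics

**Superposition.** All RMSDs rest on a Kabsch least-squares fit via the
singular value decomposition of the 3×3 cross-covariance of centred
coordinate sets. The sign of `det(V Uᵀ)` corrects the last singular
vector so only proper rotations (determinant +1) are returned —
reflections would let a mirror image score perfectly. A degenerate zero
determinant (exactly planar/collinear sets) falls back to the positive
branch, either being optimal. At least three points are required.

**Monomer Cα RMSD** superposes the predicted binder on the designed
binder, residues paired strictly by order; designed and predicted
sequences are identical by construction, so no alignment step is needed
or attempted.

**Complex Cα RMSD** fits the superposition on target-chain Cα *only*,
then evaluates the deviation over the requested scope without refitting.
Fitting on the target rather than the whole complex is what makes the
metric a binding-mode check: it asks whether the binder lands in the
right place relative to the target, not whether the overall shapes agree.
Both an `all_residues` and a `binder_only` scope are exposed; the filter
default is `all_residues`. For a pure binder translation of *d* Å the
`binder_only` value equals *d* exactly, which the tests assert.

**pAE_interaction** is the mean of the two interchain blocks of the pAE
matrix, averaged: `(mean(pae[b, t]) + mean(pae[t, b])) / 2`. With equal
block cardinalities this equals the grand mean over ordered interchain
pairs. Intrachain entries and the diagonal never contribute, and because
both directed blocks are averaged the statistic is invariant to
transposing the input matrix — the matrix orientation convention of the
upstream predictor therefore cannot corrupt it. Units are Å throughout;
pLDDT is kept on the 0–100 scale, and inputs detected on [0, 1] are
rescaled with a warning rather than silently misread.

## Filtering and selection

The production filter keeps designs with `pAE_interaction < 10` and
`af2_complex_rmsd < 5` Å. Both thresholds are *strict* inequalities —
the boundary values 10.0 and 5.0 fail — and strictness and direction are
configurable per criterion. A design missing a criterion's metric fails
closed with the metric recorded under `missing_metrics`: in a screening
context an unscorable design is an untrusted design.

Multi-objective selection follows the pareto-front approach: the
non-dominated set under direction-aware domination, peeled front by front
into a selection until a whole front no longer fits the quota; the final
partial front is admitted in ascending order of a tie-break metric
(default `pae_interaction`, the most discriminative single metric, so the
arbitrary tail of the selection is at least ordered by the best available
evidence). Top-fraction selection takes the best ⌈fraction·n⌉ designs
with ties broken lexicographically by `design_id`, making selections
reproducible across runs and platforms.

## SC50 from yeast display

A display library is sorted once for expression, once with multivalent
(avidity) target presentation to retain weak binders, and then at a
titration of target concentrations; deep sequencing gives each design's
frequency in each collected pool. The collection fraction of a design at
concentration *c* is its frequency in that sort times the cells
collected, normalised by the same product in the expression reference
sort, clipped to [0, 1] (when cell totals are unavailable the raw
frequency ratio is used unclipped). Avidity sorts are excluded from
fitting: multivalent presentation distorts the monovalent concentration
dependence, so they serve only as an upstream enrichment gate.

SC50 — the concentration at which half of a design's expressing cells are
collected — is estimated by least squares under a one-site saturable
isotherm `f(c) = f_max · c / (c + SC50)`, chosen over a free-slope
logistic because it matches the half-of-expressing-cells semantics with
the fewest parameters (a Hill-slope variant is available behind the
`hill` flag for diagnostics). SC50 is parameterised in log-concentration
and optimised by multi-start L-BFGS-B from a log-spaced grid spanning the
tested range extended one decade each side, with `f_max` bounded in
(0, 1]. Defining the starts relative to the tested concentrations makes
the noiseless fit exactly scale-equivariant: scaling all concentrations
by *k* scales the recovered SC50 by *k*. Two censoring rules guard
against over-interpretation, both configurable: a design whose maximal
observed fraction is below 0.1 is reported `no_binding` without fitting,
and a fitted SC50 above 10× the highest tested concentration is reported
`out_of_range` — in both cases no SC50 value is returned. Success is
called strictly below 4 μM, and only for converged fits.

## The synthetic benchmark

The generator module stands in for the retrospective datasets the
screening metrics were validated on, at desk scale and with ground truth
known by construction.

- `make_toy_complex` builds idealised α-helical Cα traces (1.5 Å rise,
  100° per residue, radius 2.28 Å, consecutive Cα ≈ 3.8 Å) for a binder
  and one or more target chains placed in contact, with a small seeded
  jitter and seeded random sequences.
- `perturb_structure` realises a requested RMSD by scaling a seeded
  displacement field — a low-frequency sinusoid along the chain plus
  residue-level jitter and a rigid component. For the binder scope the
  realised `binder_only` complex RMSD is exactly linear in the scale
  (the target chains, hence the alignment frame, are untouched), so the
  scale is solved in closed form; for monomer and all-chain scopes, where
  refitting makes the response nonlinear, the scale is found by root
  bisection to 0.01% and verified within the 2% contract.
- `make_confidence` draws a *design-level* interface-pAE centre from
  N(μ₀, σ) for non-binders and N(μ₀ − δ, σ) for binders, then fills the
  interchain blocks with entry-level jitter (s.d. 1.5 Å) around it.
  Drawing individual entries at σ directly would shrink the per-design
  `pAE_interaction` spread by √(number of pairs) and erase the
  separation the benchmark is parameterised by. Intrachain pAE is low
  (mean 4 Å), the diagonal is near zero, all entries are truncated to
  [0, 31.75] Å (the conventional encoding ceiling of predictor pAE
  outputs), and pLDDT is drawn anti-correlated with the interface pAE
  (centre 95 − 1.2·pAE), mirroring the empirical pattern that confident
  predictions succeed more often.
- `make_sort_counts` simulates the sequencing readout: the design
  occupies a fraction `p_ref` (default 5×10⁻³) of the expressing
  library, collects per the isotherm while the background library
  collects at an average fraction 0.3, and read counts are binomially
  sampled at the requested depth from the design's frequency in each
  collected pool.
- `make_benchmark` combines these into a labelled score table:
  `round(binder_fraction · n)` designs are binders; confidence metrics
  come from `make_confidence` scored by the package's own
  `pae_interaction`/`binder_plddt`, and the structural metrics are
  realised by actually perturbing a shared toy complex to label-dependent
  target RMSDs (binders: monomer ~0.6 Å, complex ~1.5 Å lognormal;
  non-binders: ~2.5 Å and ~6 Å) and measuring them back — a closed loop
  through the metrics module. `realize_structures = FALSE` records the
  sampled targets directly for analyses that only exercise the
  confidence metric.

Defaults (n = 1000, binder fraction 0.05, δ = 8 Å, σ = 4 Å, μ₀ = 18 Å)
were set once so that non-binders sit two standard deviations above the
10 Å threshold — a ~2.3% leak-through — and the joint default filter
passes roughly 2–3% of designs, a realistic stringency for this kind of
screen.

**What the fixtures do not emulate.** Real designs have full-atom
physics, correlated metric errors, target-specific difficulty, and
experimental base rates as low as 10⁻⁵; the helical toys have no packing,
loops or clashes, metric noise is independent across designs, and labels
are drawn rather than earned. Passing tests therefore demonstrate that
the estimators, filters and selectors are *correct* — that they compute
what they claim and recover known generating parameters — not that the
thresholds would achieve any particular enrichment on new experimental
campaigns.

## Numerical and design choices

- Residue indexing into pAE matrices is binder-chain-first, then target
  chains in declared order; `complex_structure` stores chains in that
  order regardless of construction order so structures and confidence
  bundles can never disagree on the convention.
- Only Cα coordinates are retained anywhere; all structural metrics are
  Cα quantities. mmCIF, multi-model files, ligands and insertion codes
  are out of scope; alternate locations resolve to the first-listed
  record.
- Score tables round-trip numerics at 10 significant digits (beyond the
  6 the format guarantees); empty cells are absent metrics (`NA`), never
  zeros. Evaluation reports round to 6 significant digits.
- The design/relax cycle validates its stage contracts every iteration:
  binder sequence length constant, chain topology unchanged, target
  sequences untouched. The default cycle count is 3 — enough for the
  sequence/structure alternation to settle in mock runs while keeping
  the loop cheap; real deployments should tune it to their relaxer.
- Heterogeneous per-design compute timings are summed and divided by the
  total design count before entering the efficiency formula, which is
  defined per design.
- Whether the published complex-RMSD filter was computed over all
  residues or binder residues after target alignment is ambiguous in the
  field's descriptions; both scopes are exposed and `all_residues` is the
  filter default, with `binder_only` used where a pure-translation
  identity is wanted.

## Problem sizes in the test suite

The suite exercises oracle comparisons on 50 random 6–30-point
superpositions, 100 random confidence bundles, 100 random 2–4-objective
pareto instances and 30-record ROC tables; discrimination checks run on
2000-design benchmarks; SC50 recovery uses 20 simulated 6-point
titrations at 10⁵ reads per sort. These sizes give stable statistics
while keeping the full suite under half a minute on one CPU.

## Known limitations

- SC50 estimation assumes the one-site isotherm; cooperative or
  avidity-contaminated titrations will fit poorly (use the residual and
  the Hill-slope diagnostic).
- The frequency-ratio fallback (no cell counts) is unclipped and can
  exceed 1 under sampling noise.
- `pareto_select` peels fronts exactly and is quadratic in the worst
  case; it is intended for ~10⁴–10⁵ records, not millions.
- The PDB writer emits Cα-only ATOM records; files are valid but not
  full-atom models.
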