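---
title: "Shape and divergence pipelines: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape and divergence pipelines: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodiv)
```

This vignette is the package's own account of the methods it
implements: what each stage assumes, which tunable parameters matter,
what the synthetic-data generator does and does not emulate, and where
design choices were genuinely open.

## The morphometric model

A specimen is an ordered set of 27 dorsal landmarks: the posterior eye
margins at the body perimeter (1, 25), the posterior-most point of each
body segment (2–11 left, 15–24 right), the lateral posterior pleotelson
points (12, 14), the pleotelson tip (13), and the medial eye margins
(26, 27). All landmarks except the pleotelson tip come in bilateral
pairs, so the two sides are not independent data.

**Symmetrization.** `symmetrize()` reflects each configuration across
its own midline — the line through the pleotelson tip and the midpoint
of the medial eye landmarks — swaps paired labels, and averages the
original with the reflected copy. The output is exactly
mirror-symmetric and the operation is idempotent; the only degenerate
input is a configuration whose tip coincides with the eye midpoint
(axis undefined, refused with an error).

**Unique-landmark reduction.** After symmetrization every pair carries
one independent position, so the pipeline reduces each configuration to
its 14 unique landmarks (one per pair plus the midline point) before
superimposition. This is a deliberate design decision with a
dimensional argument behind it: GPA plus tangent projection on
generic 14-point configurations leaves exactly 2·14 − 4 = 24 shape
dimensions, which is the observed rank of symmetrized datasets of this
landmark scheme. Carrying the full 27-point symmetric configurations
instead leaves 25 dimensions (the symmetric component of a 13-pair +
1-midline scheme is 2·13 + 1 − 2 = 25): the extra dimension is the
orientation of the half-configuration relative to the symmetry axis,
which the unique-landmark analysis treats as rotational nuisance. The
24-dimensional convention matches how such data are analyzed in
practice and is asserted throughout the tests. `gpa()` itself is
agnostic and accepts any landmark count.

**Superimposition.** `gpa()` centers each configuration, scales it to
unit centroid size, and iteratively rotates all configurations onto the
renormalized mean until the consensus changes by less than 1e-10
(maximum 100 iterations, warning and current state on non-convergence).
Rotations are restricted to det = +1: specimens are digitized dorsally
in consistent orientation and symmetrized first, so reflections can
only mask digitizing errors. The aligned set is finally rotated to a
canonical frame — principal axes of the consensus with the major
(body-long) axis on y, sign fixed on the largest coordinate — which
makes the output invariant to arbitrary rotation, translation and
rescaling of the inputs (tested at 1e-8). Each configuration is then
projected orthogonally onto the Kendall tangent space at the consensus
by removing its component along the consensus vector. Centroid sizes
are stored pre-scaling, in physical units.

**Centroid size.** CS is the square root of the summed squared
landmark distances from the centroid. One primary source describes the
quantity verbally without the root; the root form is what the cited
morphometric literature and the tps-family software compute, so the
root is the default and `centroid_size(root = FALSE)` provides the
literal reading.

**Shape variables.** `shape_pca()` eigendecomposes the covariance of
the tangent coordinates. Eigenvalues below 1e-10 of the largest are
treated as zero. The retained dimension is the smallest k whose
cumulative share of non-zero variance reaches the threshold (default
0.95). On symmetrized data the non-zero count is exactly 24 once
n > 25.

## Inference

**MANCOVA.** `fit_mancova()` uses sum-to-zero (effect) coding and
Type III (partial) hypothesis SSCPs against the shared error SSCP —
the only combination that reproduces the published degrees of freedom
for an unbalanced design of this structure (e.g., with n = 84, p = 11
and lineage(3) + sex(3) + size + two-way interactions: lineage df
(22, 120), lineage × sex (44, 231.5)). Wilks' Λ is converted to F by
Rao's approximation and the effect size is η_p² = 1 − Λ^(1/s). With
p = 1 and one hypothesis df the machinery reduces exactly to the
univariate partial F test, which the tests exploit as an oracle. The
size covariate enters untransformed by default (`log_size = TRUE` in
`run_morpho()` for the log form): the allometric signal in this system
is approximately linear over the observed size range, and the
untransformed covariate is what the original workflow used.

**Hierarchical pruning.** `prune_and_refit()` fits the full factorial,
then repeatedly removes the highest-order interaction whose p value is
at or above alpha (default 0.05), never removing a term contained in a
retained higher-order term and never removing main effects. This is the
standard hierarchy-respecting backward pass; ties are broken toward the
largest p value, making the procedure deterministic.

**Residualization.** Before discrimination, shape scores are
residualized on the nuisance terms only — sex and size and their
retained interactions, *excluding* lineage. Which terms the
"preliminary model" of the original workflow contained is not
documented; regressing out lineage itself would destroy the signal the
classifier is asked to find, so the nuisance-only choice is the one
defensible reading. It is recorded here as this package's decision,
not as a claim about the original software settings.

**QDA with LOOCV.** `qda_loocv()` scores each specimen under
class-specific Gaussian densities with equal priors; ties go to the
alphabetically first clade label (deterministic). LOOCV refits only the
left-out specimen's class mean and covariance — residualization is a
fixed preprocessing step and is not refit inside the loop, matching the
two-stage workflow the pipeline mirrors; a full-pipeline LOOCV would
re-estimate the nuisance regression n times and is intentionally out of
scope. Class covariances use the unbiased (n−1) denominator. No
shrinkage is applied by default; `ridge` adds λ·trace(Σ)/p to the
diagonal for near-singular classes (n_k close to p, as happens with a
15-specimen clade and 11 shape variables).

## Thin-plate splines

`fit_tps()` solves the standard 2-D interpolation system with kernel
U(r) = r² ln r (U(0) = 0; equivalent to r² ln r² up to a constant
absorbed by the weights). The transform maps reference landmarks
exactly onto targets (tested at 1e-8); bending energy wᵀKw is zero
precisely on affine maps. `warp_grid()` evaluates the map on a regular
grid with a 10% margin and applies display magnification as
reference + m·(warp − reference) — m = 10 reproduces the exaggerated
style of published shape-difference figures; magnification is a display
convention only and never enters any statistic. `canonical_warp()`
computes canonical axes of a fitted term (eigenvectors of E⁻¹H),
regresses tangent coordinates on the canonical scores, and predicts the
configuration at each group's mean score: the per-clade average shape
deformation. For rendering a whole body, predicted unique-landmark
configurations are mirror-expanded by aligning onto the template half
and reflecting — a display convention, exact for symmetric shapes in
template pose.

## Molecular divergence

**K2P distances.** `k2p()` counts transition and transversion
proportions over columns that are unmasked and carry unambiguous bases
in *both* sequences (pairwise deletion), the natural reading of
"excluding ambiguous sites"; `k2p_matrix(deletion = "complete")`
offers the stricter mode since the original software setting is not
recorded. Saturated pairs (non-positive log argument) and pairs with no
comparable sites return NA with a reason attribute, never a negative
number. Exclusion masks are consumed as given (e.g., from alignment-
confidence screening); the package never recomputes them.

**Haplotype collapsing.** Sequences join a haplotype when compatible at
every mutually resolved site, with ambiguity codes treated as missing
and gaps missing by default (`gap_as_state = TRUE` for the 5-state
reading — the original tool's default treatment of ambiguities is not
documented, so both are provided). First-occurrence order makes the
result deterministic.

**Connection limit.** The statistical-parsimony limit is the largest
step count j whose probability of a homoplasy-free connection is at
least 95%. The probability is computed under an explicit Poisson
multiple-hit model with Jukes–Cantor state dynamics: the per-site
expected hit count is estimated by inverting the observed difference
fraction j/L, and P_j is the probability that every differing site was
hit exactly once and every identical site not at all, taken through a
monotone (running-minimum) envelope so that longer connections are
never more plausible. This model is stated openly because the classic
operationalization of the same limit is coalescent-based and yields
more liberal limits (roughly 14 steps at L ≈ 700 versus 8 here); the
package's limit is conservative, every qualitative property (monotone
in j, non-decreasing in L, everything connectable as confidence → 0) is
tested, and `fixed_limit` reproduces any published limit exactly when
comparability matters.

**Network construction.** Candidate connections are processed in
increasing step order (lexicographic tie-break); one is realized only
if it joins two components (minimum-spanning core). Equal-step
alternatives that would close a cycle at the step level where their
endpoints were first joined are reported as "ambiguous loops" rather
than resolved — the frequency- and topology-based loop-breaking
heuristics of the classic software are out of scope. Realized s-step
connections pass through s − 1 anonymous inferred alleles; no sequence
reconstruction is attempted for them.

## The synthetic-data generator

`simulate_landmarks()` deforms a procedural, exactly symmetric
27-landmark template (a parameterized outline — only its symmetry and
ordering semantics are contractual, nothing is traced from images).
Per specimen it applies, in template units and before scaling:

* a clade effect — mid-body width multiplier (x of segment landmarks
  4–9 and partners), inter-eye gap offset (medial eye landmarks), and
  pleotelson protrusion offset (tip);
* a sex effect — anterior-segment widening for gravid females (F);
* allometry — elongation proportional to centered log size, with a
  compensating width change (shape effects are applied pre-scaling, so
  allometry is injected explicitly, never as an artifact of scaling);
* smooth biological variation — random coefficients on non-affine
  polynomial deformation fields (degrees 2–3) with geometrically
  decaying amplitudes. Individual variation in real organisms is
  spatially integrated, which is what gives real landmark datasets
  their decaying eigen-spectra; independent per-landmark noise alone
  would spread variance flatly across all 24 dimensions. Affine fields
  are excluded because aspect and width variation are already modeled
  by the allometric and clade terms;
* digitization noise — isotropic Gaussian on every landmark — and
  asymmetry noise applied to one body side only, so symmetrization has
  real work to do in tests.

Coordinates are finally scaled by a log-normal size. Defaults are
chosen once to emulate the study conditions of the motivating system:
84 specimens with clade totals 15/35/34 split near-evenly over the
three sex categories; effect and noise amplitudes set so that the 95%
rule retains about 11 components, the size and sex effects are strong
(η_p² ≈ 0.5–0.8), and the clades overlap enough that leave-one-out
classification lands near 60% while resubstitution stays above 90% —
the regime a field dataset of this kind actually shows. What the
generator does **not** emulate: digitizing error that correlates with
specimen size or camera setup, missing landmarks, curved semilandmarks,
directional asymmetry, and measurement batch effects. Passing tests
therefore demonstrate correctness of the algorithms under a known
truth, not robustness to every artifact of real imagery.

`simulate_haplotypes()` draws a random ancestral sequence and walks a
user-supplied mutation tree, substituting each edge's steps at sites
used by no other edge — so Hamming distances equal path step sums
exactly, and network recovery can be checked against the truth graph.
Cyclic graphs are refused (edge-disjoint sites cannot produce
consistent distances on a cycle), and homoplasy is deliberately absent:
the generator tests the network machinery, not the parsimony model.

## Numerical choices and degenerate inputs

* GPA convergence: 1e-10 on the consensus update, 100 iterations;
  non-convergence is a warning, not an error.
* Zero-eigenvalue threshold: 1e-10 relative to the largest eigenvalue.
* Singular error SSCP or class covariance: refused with advice (fewer
  PCs, more specimens, or the ridge flag) naming the offending clade.
* Rank-deficient designs: refused naming the aliased columns.
* Collinear TPS references: refused (singular system).
* Classification ties: alphabetically first label, documented above.
* TPS file output: 6 significant digits, the precision of the
  digitizing software the format comes from; round trips are lossless
  at that precision.
* Coordinates are right-handed (y up); `read_tps(y_down = TRUE)`
  negates y for image-digitized files.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
data: the default 84-specimen morphometric dataset, alignments of a few
hundred to a few thousand sites, and a 500-replicate null calibration
of the MANCOVA type-I error at n = 36, p = 2 (rejection rate at
α = 0.05 must fall in [0.03, 0.08]). These sizes make every statistical
property checkable in seconds while keeping each estimator in the
regime it was designed for.

## Known limitations

* The parsimony-probability model is conservative relative to the
  classic coalescent-based limit (see above); cross-study comparisons
  should use `fixed_limit`.
* Ambiguous loops are reported, not resolved.
* No sliding semilandmarks, 3-D landmarks, or asymmetry decomposition
  (directional vs fluctuating); the symmetric component is the object
  of study here.
* Wilks' Λ only (as in the workflow this mirrors) — no Pillai or
  Hotelling statistics, and no permutation MANOVA.
* Published effect sizes and classification tables from the motivating
  study depend on its archived specimen data and are validated only
  when a user supplies those data; the package's claims otherwise rest
  on oracle equivalence and parameter recovery under simulation.
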