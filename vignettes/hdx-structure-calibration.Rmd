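---
title: "Calibrating in-droplet HDX reactivity against MD ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating in-droplet HDX reactivity against MD ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxcalib)
```

# Overview

hdxcalib relates a single per-peptide observable — the percentage of
backbone amide hydrogens exchanged during a brief in-droplet D₂O exposure —
to the peptide's conformational ensemble. The pipeline has two arms that
meet in a linear calibration:

1. **Experimental**: isotopic-envelope centroids → internal-standard scaling
   → side-chain decomposition → experimental %BB exchange.
2. **Theoretical**: per-frame open/closed classification of each backbone
   amide in an MD trajectory → protection factors → digital or combined
   kinetic exchange → theoretical %BB exchange.

This vignette records the models, the tunable parameters and the reasoning
behind every genuinely open design choice, the synthetic-data strategy used
for validation, and the known limitations.

# The experimental arm

## Centroids and uptake

Deuterium uptake is the difference of intensity-weighted centroid masses of
the isotopic envelope after and before exposure, converted to neutral mass
with the proton mass (1.00728 Da). Expressed against the ion's exchangeable
site count it becomes a percent incorporation using the D–H mass difference
Δm_D = 1.00628 Da per exchanged hydrogen. The distinction matters at the
third digit: a 5.16 Da shift over 6 sites is 86.0 % by the naive ratio but
85.5 % per deuterium actually weighs.

Single-centroid uncertainty is the intensity-weighted standard error over
the isotopic peaks — a deliberately simple model of peak statistics,
configurable by replacing the peak lists with replicate measurements and
pooling. Negative shifts beyond 0.05 Da are flagged as back-exchange but
not rejected; clamping to zero is opt-in, because silently truncating a
distribution of small shifts biases pooled means upward.

## Internal-standard scaling

Droplet D₂O exposure varies between replicates, so analyte uptake is
regressed on the percent exchange of a co-sprayed free-lysine standard
across exposures and the fitted line evaluated at a 75 % reference level.
The evaluation uncertainty comes from the slope/intercept covariance of the
ordinary least-squares fit (the standard error of the predicted mean
response). Two or more exposures are accepted; with exact data the line
interpolates, a property the tests pin down.

## Pooling charge states

Charge states are pooled by a weighted mean. The default weights are total
ion intensities; inverse-variance weighting is available behind a flag.
Both schemes are reported with the propagated uncertainty
√Σ(wᵢuᵢ)²⁄Σwᵢ treated at fixed weights. Neither scheme is claimed to be
uniquely correct — with equal uncertainties they coincide — so both are
first-class and the choice is recorded in the output.

## Side-chain decomposition

Exchangeable hydrogens are inventoried per site class in neutral forms:
lysine amine 2, arginine guanidino 4, serine/threonine/tyrosine hydroxyl 1,
aspartate/glutamate carboxyl 1, asparagine/glutamine side amide 2,
histidine 1, tryptophan 1, cysteine 1; a free N-terminus carries 2, a free
C-terminal acid 1, a C-terminal amide 2. N-terminal acetylation removes the
amine hydrogens and converts residue 1's nitrogen into an amide (counted
with the backbone, unless residue 1 is proline). Charging protons are
added to the total for MS-ion bookkeeping of the free-amino-acid standards
only.

Class propensities are solved from the standards by nonnegative least
squares (Lawson–Hanson active set, via pracma). Whenever the unconstrained
ordinary-least-squares solution of the normal equations is already
nonnegative the two coincide; the package computes both and keeps the OLS
solution attached as a cross-check. Rank-deficient designs are rejected
naming the unresolvable classes. Because every free amino acid carries
both termini, the two terminal classes are inseparable by design and are
pooled into a single `terminal` column by `standard_design()`; the pooling
map is explicit and configurable wherever a propensity table is consumed.
Propensities above 1 are clipped with a warning: a propensity is a
fraction of a class's hydrogens, so values above 1 are misfit, not physics.

Percent backbone exchange is then
100·(D_total − D_side)/n_bb, with uncertainty propagated from the total
(the side contribution is treated as exact unless its own uncertainty is
supplied). Negative results are flagged, not rejected — they are real
outcomes of over-subtraction and should stay visible.

# The theoretical arm

## State classification

Each backbone amide (residues 2..n, prolines excluded) is classified per
frame:

- **inter** model: open iff SASA(NH) ≥ 8.3 Å² **and** at least 2 water
  molecules are in hydrogen-bond geometry with the amide hydrogen;
- **intra** model: closed iff SASA(NH) < 8.3 Å² **or** the amide hydrogen
  donates any intramolecular hydrogen bond; open otherwise.

Under shared geometry parameters the inter open condition is strictly
stronger, so the intra open set contains the inter open set frame by frame
— an invariant the test suite asserts on every fixture, and the reason the
intra treatment always predicts at least as much digital exchange.

SASA is per-atom Shrake–Rupley: deterministic golden-spiral test points
(default 960) on the probe-expanded sphere (probe 1.4 Å), Bondi radii
including hydrogens (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80 Å). The
threshold comparison uses ≥ for open. Waters do not occlude by default
(the probe is the solvent), with `"protein"` and `"all"` occluder sets
selectable. Doubling the point count moves converged values by well under
1 %; the brute-force checks in the tests use an independent Monte-Carlo
surface integration.

Hydrogen-bond geometry needed an explicit convention, since "within
3.3 Å and a 30° angle" does not by itself name the anchor atoms. The
package measures the distance from the **amide hydrogen** to the acceptor
(water oxygen, or protein N/O for the intramolecular test) and the
N–H···acceptor angle at the hydrogen, requiring ≥ 150°. Rationale:
exchange chemistry requires the water to engage the amide hydrogen itself,
and the H-anchored distance composes naturally with the angle criterion.
The N-anchored distance convention is selectable (`dist_mode = "n_o"`).
The donor's own backbone nitrogen is excluded from the acceptor set; the
adjacent carbonyl needs no special casing because its N–H···O angle is
near 25° and fails the linearity test by a wide margin.

Trajectories longer than 25 000 frames are subsampled to that count by an
even stride before classification; the cap is configurable.

## Protection factors and exchange

PF = f_c/f_o per residue. To keep PF finite at saturated statistics,
f_o is clamped to [1/n, 1 − 1/n] (n = frames analysed) and clamped
residues are flagged; truncation was chosen over Laplace smoothing because
it leaves every unsaturated residue's estimate exactly equal to the
population ratio, which the construction-known fixtures check to machine
precision.

The digital rule counts a residue as exchanged when ln PF < 0, with
ln PF = 0 counting as **not** exchanged (strict inequality; a tie means
open states do not dominate). The combined model integrates the
steady-state EX2-like observed rate k_obs = k_int/PF over a reaction time
t: HDX_i = 1 − exp(−k_int,i·t/PF_i). The exponential-saturation form is
the direct integration of that first-order rate; t defaults to 1 s with
bulk-solution intrinsic rates, and rescaling t is equivalent to rescaling
all k_int, so the calibration slope, not t, carries the information.

Replicate trajectories are classified independently and aggregated by
averaging per-residue open fractions before forming PF (default); ln PF
averaging is available behind a flag. Population averaging was made
primary because the digital rule then thresholds the pooled ensemble
rather than a mean of logs, and because it degrades gracefully when a
replicate saturates. The standard error of the mean across replicates is
attached either way.

## Intrinsic rates

k_int per amide is the sum of acid-, base- and water-catalysed channels:
each a poly-DL-alanine reference rate times log-additive corrections from
the residue's own side chain and its left neighbour, with extra terms for
the residue-2 amide next to a free protonated N-terminus and the final
amide next to a free carboxylate. Arrhenius factors (14/17/19 kcal·mol⁻¹)
scale the three channels from the 293 K reference; pD is the pH meter
reading plus a configurable 0.4 offset; pK(D₂O) = 15.05 is held fixed.
The factor table ships as a versioned TSV
(`inst/extdata/kint_factors.tsv`) and can be swapped wholesale. The
conditions (pH 7.0, 300 K) are defaults, not claims about any particular
experiment; both are explicit arguments. Near neutral pH base catalysis
dominates, so raising the pH by one unit multiplies k_int by just under
10 — a closed-form property the tests assert.

# Structural descriptors

- **Shape**: per-frame gyration tensor (mass-weighted by default);
  R_g = √(λ₁+λ₂+λ₃) and asphericity
  δ = 1 − 3(λ₁λ₂+λ₂λ₃+λ₃λ₁)/(λ₁+λ₂+λ₃)², 0 for spherical, 1 for
  collinear ensembles.
- **Backbone RMSD** to a reference frame after optimal superposition
  (Kabsch, via bio3d), or without fitting on request.
- **Contact maps**: fraction of frames with minimum heavy-atom distance
  ≤ 4.5 Å between residues at sequence separation ≥ 2. The 4.5 Å default
  sits in the gap that inter-residue distance distributions show between
  bonded-neighbour and through-space contact; it is configurable.
- **Helicity**: a residue is helical in a frame iff φ ∈ −57° ± 30° and
  ψ ∈ −47° ± 30°. This dihedral window is an approximation chosen for
  transparency and zero external dependencies; it is **not** a
  hydrogen-bond-pattern secondary-structure assignment, and the window is
  a parameter.

# Synthetic data: what it emulates and what it does not

The generators exist so that every pipeline stage can be tested against
construction-known ground truth, without MD engines or instruments.

- `make_toy_trajectory()` emits a multi-model PDB in which each amide's
  open/closed state is dialled frame by frame: two rigid waters are placed
  inside (2.9–3.0 Å, near-linear) or far outside the hydrogen-bond
  acceptance cone, and in `"bury"` mode six carbons octahedrally enclose
  the amide hydrogen to drive its SASA to zero. Open-frame schedules are
  deterministic (even Bresenham spread by default), so the realized open
  fraction equals the target to within 1/n_frames and the whole state
  matrix is known in advance. The default `"dilute"` family holds rigid
  amide units 9 Å apart: every hydrogen then has high, frame-constant
  exposure and a burial cage on one residue cannot shadow its neighbours,
  which is what makes the ground truth exact. Ideal-helix, extended and
  random-coil families (internal-coordinate chain building at canonical
  φ/ψ, with clash-rejected sampling for coils) provide realistic
  geometries for the hydrogen-bond and descriptor fixtures instead.
- `make_envelope()` convolves a base isotopic envelope with an exact
  Binomial(n, p) deuterium count; the centroid shift is n·p·Δm_D by
  construction, so uptake recovery is tested at 10⁻⁹, not "close enough".
- `make_standards()` produces amino-acid-standard observations from a
  known propensity table plus seeded noise.

What passing these tests shows: the operators implement their definitions
exactly, the solvers recover planted truth at the stated noise, and the
pipeline composes end to end. What it does not show: that real droplet
chemistry obeys the state models, that force-field ensembles are right, or
that the side-chain propensity table transfers across solution conditions
— those are scientific questions the calibration itself is designed to
probe, not software properties.

# Validation problem sizes

The shipped suite uses: 1000-frame six-residue fixtures for exact state
recovery under both closure modes; 100 random hydrated frames for the
SASA and hydrogen-bond brute-force comparisons (plus an independent
closed-form two-sphere check); a five-"peptide" end-to-end study (60
frames each) that produces R² = 1 on a collinear construction and recovers
a planted calibration slope within 5 % under 2 % measurement noise. These
sizes make the whole suite run in well under a minute on one core while
leaving every exactness assertion exact.

# Numerical and degenerate-input policy

- Strict/weak comparisons are fixed and documented: SASA ≥ threshold opens;
  ln PF < 0 exchanges; hydrogen-bond cutoffs are inclusive.
- Zero-variance predictors, all-zero intensity envelopes, rank-deficient
  designs and mismatched residue sets are rejected with named causes.
- Percent error excludes zero-valued observations with a warning; the
  denominator is the experimental value by default (the prediction-side
  convention is a flag, since either direction is defensible).
- All randomness is seed-threaded; generators are bit-reproducible.

# Known limitations

- EX2-like steady state only; EX1 kinetics and explicit opening/closing
  rate constants are out of scope.
- Trajectory input is PDB (single or multi-model) and DCD; XTC is not
  read. No periodic-boundary imaging is performed — trajectories should be
  whole-molecule imaged beforehand.
- The dihedral helicity measure deliberately trades fidelity to
  pattern-based assignments for transparency.
- The intrinsic-rate table fixes near-neutral ionization states (Asp/Glu
  carboxylate, single histidine entry); strongly acidic or basic
  conditions need a swapped table.
- Gas-phase exchange during ion transit is not modelled anywhere; the
  package treats uptake as solution-phase.
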