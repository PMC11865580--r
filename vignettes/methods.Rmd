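---
title: "Methods: interface convexity and concave-scaffold screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface convexity and concave-scaffold screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concavebind)
```

`concavebind` quantifies the geometry of protein–protein interfaces for
binder design on concave five-helix scaffolds, and the sequence-level
analyses used to optimize such binders. This vignette is the package's
account of the methods: the models, the assumptions, the parameters that
matter, and the deliberate numerical choices.

## Solvent-accessible surface area and interface definition

SASA is computed with the Shrake–Rupley method: each heavy atom's sphere
of radius $r_\mathrm{vdW} + r_\mathrm{probe}$ is sampled at $n$ points,
and the accessible fraction is the fraction of points not inside any
neighbor's sphere. Three choices matter.

**Radii.** A Chothia-style element-level set is pinned
(`vdw_radii_default()`): C 1.87, N 1.65, O 1.40, S 1.85 Å, fallback
1.80 Å, overridable per call. SASA magnitudes depend directly on the
radii set, so absolute buried areas computed with a different set (or
with atom-type-level radii) can differ by a few percent; comparisons
should hold the set fixed.

**Probe radius.** 1.4 Å, the standard water probe; exposed as a flag.

**Sampling.** A golden-section spiral of $n = 960$ points (flag;
minimum 60). The point set is deterministic, which has a consequence we
rely on: with an identical point set, adding atoms can only occlude
sample points, never expose them. Interfaces are defined from the
difference between each partner's SASA computed in isolation (apo,
the partner's atoms extracted from the complex without re-relaxation)
and within the two-partner complex (holo); the shared point set makes
every per-atom dSASA = apo − holo exactly non-negative, rather than
non-negative only in expectation. Heavy atoms with dSASA ≥ 0.5 Å² are
interfacial. A residue-level convenience view exists for reporting, but
all downstream geometry consumes atoms.

Sampling is evaluated in a canonical molecular frame (principal axes of
the heavy atoms, axes oriented by third moments), so SASA, dSASA and
buried areas are invariant under rigid motions of the input to
numerical precision, not merely to sampling accuracy. For point clouds
with vanishing third moments (exactly mirror-symmetric fixtures) the
frame orientation falls back to the eigenvector orientation, which is
still deterministic for identical input. At $n = 960$ the per-atom
areas agree with $n = 3840$ to better than 2 % on moderately packed
20-atom test clouds, and isolated atoms are exact by construction.

Buried area is split by an element-level polarity rule: polar = N or O,
apolar = all other heavy elements (S and C apolar). This is the
simplest convention consistent with common buried-area reporting; any
deviation from splits computed with chemistry-aware typing is
interpretable against this rule. Totals are reported summed over both
partners, with a per-partner breakdown.

## Signed convexity of an interfacial patch

The shape descriptor at the core of the package is the **signed
convexity** of an interfacial atom patch: fit a sphere to the patch
coordinates, and report $c = s / r$ in 1/Å, where $r$ is the fitted
radius and $s = \pm 1$ a concave/convex sign. Typical binding-site
patches give $|c|$ in the 0.03–0.17 1/Å range (sphere radii of 6–30 Å);
concave binder faces are negative.

**Sphere fitting.** RANSAC with minimal samples of 4 points (the
minimal determining set of a sphere), an inlier threshold of 1 Å on the
absolute radial residual, and a default iteration cap of 100 000.
Near-coplanar samples (relative determinant below $10^{-8}$,
the analogue of a condition-number cutoff near $10^8$) are rejected but
still consume iterations. Candidates are ranked by inlier count, ties
by inlier RMSE, then by iteration order — fully deterministic given the
seed, which all randomized operations take explicitly. The winning
candidate is refit by the closed-form algebraic least-squares sphere
(linearizing $\|x\|^2 = 2c\cdot x + (r^2 - \|c\|^2)$) on its inliers,
and inliers are re-classified once against the refit sphere; the refit
shifts the radius slightly but reduces variance. Search exits early
when every point is an inlier. Degenerate inputs (< 4 points, coplanar
point sets, no valid sample within the cap) raise errors rather than
returning fits.

**Sign.** Let $g_p$ be the centroid of all heavy atoms of the molecule
carrying the patch, $g_i$ the centroid of the interfacial atoms and
$c_s$ the fitted center. The sign test is the inner product
$(g_p - g_i)\cdot(c_s - g_i)$, both vectors rooted at the patch
centroid: negative means the sphere center lies opposite the molecular
body — a pocket (concave, $s=-1$); positive means it lies inside the
body — a knob (convex, $s=+1$). The vector orientations admit a second
reading (rooting at the other points); the implemented convention is
the one that makes pockets negative. An inner product of exactly zero
is an indeterminate-sign error, left to the caller (perturb or report
flat) rather than silently resolved.

The fit uses the interfacial heavy-atom coordinates directly, without
dSASA weighting: the descriptor is purely geometric.

## Five-helix scaffold screening

Candidate scaffolds are admitted by four rules, all reported even when
one fails: exactly 5 helices; every helix 18–22 residues (5–6 turns —
long enough to be independently stable, short enough to keep the
protein small); at most 119 residues total; and a concave interfacial
face formed by the odd-numbered helices (H1/H3/H5, overridable).

**Helix assignment** uses backbone dihedral windows
($\varphi \in [-100°, -30°]$, $\psi \in [-80°, -5°]$) rather than
hydrogen-bond-pattern methods: no external binary, and ideal and
near-ideal helices are what the screen must recognize. Terminal
residues and chain breaks (non-consecutive residue numbering) are
classified on the dihedrals that exist; single dropouts inside a run
are smoothed over a window of 4; runs of ≥ 6 residues become segments.

**Face atoms** are the Cβ positions (Cα for glycine) of face-helix
residues whose side chains point toward the open face, judged by the
projection of the Cα→Cβ vector onto the face direction (the component
of bundle-centroid → face-centroid orthogonal to the bundle axis). The
full positive-projection set describes the face for reporting; for the
curvature fit the screen restricts to side chains within 30° of the
face direction. The reason is geometric: Cβ atoms at grazing angles
trace their own helix's ring (radius ≈ 3.3 Å) and superimpose a
scalloped, multi-modal structure on the patch that a sphere consensus
can lock onto; the face-presenting residue of each helical turn is what
actually meets the target. The cone angle is a parameter.

**Generator.** `make_toy_bundle()` builds idealized antiparallel
bundles: ideal α-helices (φ = −57°, ψ = −47°, standard bond geometry,
Cβ at the L-configuration improper of −122.6°) with axes placed on a
circular arc of radius $1/|\kappa|$ for face curvature κ (front row),
buttressed by a back row 10 Å behind. Loops are reserved in the
numbering (3 residues by default) but not built: constructing
stereochemically valid loop closures is a design-software task outside
this package's scope, and helix detection treats the gap as a chain
break. The generator emulates exactly what the screen measures —
helix counts, lengths, total length, cross-face curvature — and *not*
real scaffold features such as loop geometry, side-chain packing,
sequence design or per-helix supercoiling. Passing screens on toy
bundles therefore demonstrate the correctness of the measurement, not
the designability of any particular backbone. Closure holds by
construction and is tested: over κ ∈ {−0.02, −0.05, −0.08} 1/Å and 10
RANSAC seeds each, the recovered sign is concave 30/30, recovered
|convexity| increases monotonically with |κ| (0.0198, 0.0482, 0.0735
1/Å), and doubling κ from −0.05 to −0.10 scales the fit by 1.71 — below
2 because the straight helices make the face a section of a cylinder,
whose sphere fit compromises between the curved and the flat direction.

`make_ball_socket()` provides the complementary two-chain fixture: a
convex pseudo-atom ball (radius 6 Å) docked in a concave shell (radius
10 Å), for which profiling recovers the construction exactly
(convexities +1/6 and −1/10, signs +1/−1).

## SSM enrichment and conservation

Counts are position × 20 matrices over the alphabetically ordered
canonical amino acids, for a selected and a reference pool.

$$E[p,a] = \log_2 \frac{(n_\mathrm{sel}[p,a] + \alpha) / N_\mathrm{sel}}
                       {(n_\mathrm{ref}[p,a] + \alpha) / N_\mathrm{ref}}$$

with pseudocount α = 1 and whole-pool normalization ($N$ = sum over the
full matrix after pseudocounting). These are standard deep-mutational-
scanning conventions; base, normalization and pseudocount are exposed
as flags, and absolute heatmap values depend on them (and on rounds of
selection), so only the qualitative structure — conservation of core
and interface positions — is comparable across pipelines. Parent-
residue cells are retained (they carry wild-type synonym reads); a
masking flag exists. Swapping the pools negates the matrix exactly, and
scaling either pool leaves it unchanged.

Conservation is the Shannon entropy of the selected-pool frequencies,
$H[p] = -\sum_a q \log_2 q$ bits with $0\log 0 = 0$, bounded by
$[0, \log_2 20 \approx 4.32]$; it is computed from frequencies, not
from enrichment values. Positions are classed
conserved/intermediate/variable by profile quantiles (0.25/0.75,
strict inequalities — a constant profile is all-intermediate by
construction).

`simulate_ssm_counts()` emulates one round of FACS sorting: uniform
multinomial reference (depth 10 000 reads/position), selected pool
reweighted by a per-variant fitness (parent 1; substitutions at
conserved positions 0.005, i.e. strongly depleted, as interface and
core substitutions are in enriched binder pools; elsewhere log-normal
with σ = 0.5). It does not model FACS gate shapes, sequencing error,
epistasis or multiple rounds. Under these conditions recovered
enrichment rank-correlates with the generating fitness at ρ > 0.9 and
≥ 90 % of generated-conserved positions are classed conserved.

## Degenerate-codon library design

Codon selection is exhaustive: all $15^3 = 3375$ IUPAC triplets are
expanded against the standard genetic code (no organism-specific
weighting), those covering the desired residue set are ranked by
(fewest off-target distinct residues — stops count as off-target —
then smallest DNA degeneracy, then lexicographic triplet), and the
ranking is returned in full. Stops are forbidden by default; when no
stop-free covering codon exists the error names the best
stop-permitting alternative. The selection objective is a package
choice — the problem is small enough that exhaustive search makes any
objective exact and deterministic.

Library accounting multiplies per-position DNA degeneracies and
distinct-residue counts into exact DNA and protein diversities. The
capacity check compares **DNA** diversity against 10⁷ — typical yeast
transformation efficiency — because transformation limits act on DNA
molecules; both diversities are reported. Each varied position must
retain the parent residue by default (combinatorial libraries sample
subsets of beneficial substitutions, so the parent must stay
encodable); the precondition is relaxable by flag. Twelve positions of
exact 4-fold codons give $4^{12} = 16\,777\,216 > 10^7$: flagged, not
an error.

The design-metric gate (`apply_design_filters()`) encodes the
admission inequalities ddG ≤ −40, contact molecular surface ≥ 400 Å²,
pAE ≤ 10, optional mean pLDDT ≥ 80, applied in order with per-rule
attrition; missing values fail their rule and are counted separately;
rows exactly at a bound pass but are flagged. The metrics themselves
are external-tool outputs consumed as data.

## Structural comparison

Kabsch superposition via SVD of the cross-covariance, with the
determinant sign correction that excludes reflections (chirality must
be preserved). Collinear inputs are a geometry error. Cα RMSD pairs
residues by ungapped-scoring global sequence alignment by default
(match 1 / mismatch 0 / gap −1), or by shared residue numbers; the
pairing and atom count are always reported, since published RMSDs vary
in their pairing convention (all-Cα versus aligned subsets) by amounts
comparable to the values themselves at the sub-ångström level.
Sequence identity over equal-length variants uses the full length as
denominator and reports two decimals; global mode divides matches by
alignment columns. `X` is tolerated, never a match. One published
pairwise value is printed as a "similarity" where the others are
identities; the package computes identity and leaves any mismatch
visible rather than redefining the term.

## Problem sizes and runtime choices

The test suite and the acceptance script run on synthetic inputs sized
for completeness of coverage rather than scale: point clouds of
60–100 atoms for sphere fits (200 seeded noisy-patch trials across
radii 10–40 Å), toy bundles of 380 atoms, a 100-position simulated SSM
library at 10 000 reads/position, 100-row metric tables, and
brute-force oracles up to 12 points (all 495 four-point subsets).
RANSAC validation uses the full 10⁵-iteration default where the
contract requires it and smaller caps (2000) for noisy-patch
statistics, where consensus saturates within a few hundred iterations.

## Known limitations

- SASA is sampled (Shrake–Rupley), not analytic; per-atom areas carry
  ~1 % sampling error at the default 960 points.
- Buried-area absolutes depend on the pinned radii set and the
  element-level polarity rule; cross-pipeline comparisons of a few
  percent are expected.
- The convexity of quasi-cylindrical faces (straight helix bundles)
  under-estimates the cross-face curvature by a geometry-dependent
  factor; signs and orderings are robust, absolute values are
  convention-bound.
- The toy generators produce idealized geometry only; they are
  measurement fixtures, not backbone designs.
- Sequence alignment is ungapped-scoring global alignment; no
  structure-based alignment, flexible fitting or TM-score.
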