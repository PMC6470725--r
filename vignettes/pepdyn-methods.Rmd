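---
title: "Ensemble analyses for disulfide-substituted peptides: models, parameters and design"
author: "pepdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analyses for disulfide-substituted peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdyn)
```

# Scope and data model

`pepdyn` implements the trajectory-analysis layer used to compare a
disulfide-rich peptide (chlorotoxin-like, 36 residues, four disulfide
bonds) against analogs in which Cys pairs are replaced by Abu or Ser. The
package does not run molecular dynamics; it consumes conformational
ensembles (multi-model PDB or GRO input, or synthetic ensembles generated
in-package) and produces the derived quantities such a comparison reports.

Internal units are nm, ns and kJ·mol⁻¹ throughout; the Kabsch–Sander
hydrogen-bond energy is kept in kcal·mol⁻¹, following DSSP convention.
Residue numbering is 1-based author numbering. Central containers are S4
classes with validity checks: `MolecularTopology` (atoms with
backbone/sidechain/solvent/ion roles and disulfide pairs),
`ConformationalEnsemble` (frames × atoms × 3 nm coordinates with strictly
increasing times), `DihedralSeries`, `SecondaryStructureTrace`,
`ContactMap`, `DPCAModel`, `FELGrid`, `ClusterModel` and `EssentialBasis`.

Two deliberate restrictions keep the scope honest. Periodic-boundary
re-imaging is out of scope: when a box is declared and a bonded backbone
pair exceeds 0.25 nm, the reader raises a "broken molecule" error rather
than silently re-imaging. Hydrogen reconstruction is also out of scope:
operations that need amide or β hydrogens (Kabsch–Sander energies, H-bond
geometry, the CβHβ center-of-mass statistic) error when they are absent;
the synthetic generator always places them.

Preprocessing follows the study protocol: an equilibration prefix is
discarded (frames with *t* ≤ discard) and the remainder subsampled at a
stride that must be an integer multiple of the native spacing. With a
4200 ns ensemble sampled at 0.1 ns and a 200 ns discard this yields the
40,000 analysis frames the protocol implies, and the operation is
idempotent.

# Secondary structure

Hydrogen bonds use the Kabsch–Sander electrostatic model,
*E* = 0.084·(1/r~ON~ + 1/r~CH~ − 1/r~OH~ − 1/r~CN~)·332 kcal·mol⁻¹
(distances in Å internally), with a bond when *E* < −0.5 kcal·mol⁻¹ and a
0.9 nm Cα–Cα prefilter. Patterns then follow DSSP: consecutive n-turns
give helices (G/H/I), bridge patterns give B, ladders E, remaining turn
interiors T, Cα kinks above 70° S, else coil; assignment priority is
H > E > B > G > I > T > S. Prolines donate no H-bond; chain termini
naturally fall out of the turn patterns.

The three reported classes pool the eight labels as H → α-helix, E and
B → β-sheet, T and S → β-turn/bend, everything else coil. Whether 3₁₀
helix should count toward the helix class is genuinely open in this kind
of report; G is rare in these peptides, so the default sends G and I to
coil, and the reduction map is an explicit argument
(`defaultSSReduction()`) so either reading is one line away. Class
fractions partition to 1 by construction, per residue and globally.

# Superposition, RMSD, RMSF

`kabsch()` solves the weighted orthogonal Procrustes problem via SVD with
the determinant correction that excludes reflections. `rmsdSeries()`
superposes every frame on the reference before measuring; `meanStructure()`
iterates fit-then-average until the mean moves less than `tol` (default
10⁻⁶ nm). `rmsf()` measures fluctuations about the superposed ensemble
mean, with either the ensemble's own average or an external reference
(positional residue correspondence — substitutions here are isosteric, so
no alignment is needed).

One numerical consequence is worth knowing: superposition removes six
rigid-body degrees of freedom, so an isotropic per-coordinate fluctuation
of σ yields RMSF ≈ σ√3·√(1 − 2/n) for n fitted atoms. Validation
ensembles therefore use n = 100 pseudo-atoms, where the deficit (≈1%) is
inside the 2% check band; with a 10-atom trace it would not be.

# Contacts and the CβHβ statistic

Contacts are frame fractions in which the minimum heavy-atom distance
between two residues (within the backbone or sidechain role) is at most
0.5 nm. Backbone means {N, Cα, C, O}; all other heavy atoms are
sidechain. Glycine has no sidechain heavy atom: its SC–SC entries are NA
("missing"), never zero, so absence of data is distinguishable from
absence of contact. Hydrogen bonds use the geometric criterion
(donor–acceptor ≤ 0.35 nm, deviation from linearity at H ≤ 30°); the
angle convention is switchable to angle-at-donor for parity with other
tools.

The CβHβ^1,2^ center-of-mass distance is the NMR-visible proxy for a
disulfide: per frame, the distance between the mass-weighted centers
(C 12.011, H 1.008) of {Cβ, Hβ1, Hβ2} of the paired residues. The
contact probability ρ uses the 0.26 nm threshold — the one-sided 95th
percentile of the reference disulfide-bonded dipeptide's distance
distribution (mean 0.23 ± 0.03 nm); `ci95Threshold()` recomputes such a
threshold from any reference distance series as an empirical percentile.
Note that a normal fit to 0.23 ± 0.03 would put the 95th percentile near
0.28 nm; the published 0.26 nm implies a tighter-than-normal empirical
distribution, which is why the threshold is taken from the empirical
distribution rather than a parametric fit.

# Solvation

SASA is Shrake–Rupley with deterministic golden-spiral points (1000 per
sphere by default, probe 0.14 nm) on heavy atoms with Lee & Richards
radii (shipped, overridable). rSASA divides by the reference maxima
mSASA — Cys 0.758, Ser 1.219, Abu 1.347 nm², measured on capped
Ala-Xaa-Ala peptides (Cys as the disulfide-bonded dimer). Values above 1
are possible for conformations more exposed than the reference and are
flagged, not clipped.

The hydration-shell "probability of finding water within 0.5 nm" admits
more than one normalisation, and the published reference values do not
disambiguate it. Both readings are implemented and labelled:
`shell_occupancy_norm` (default) divides the mean water-oxygen count in
the shell by the bulk-density expectation for the same volume — the
integral of the radial distribution function over the shell, a
dimensionless number on the 0–1 scale of the published tables for
partially shielded sites — and `mean_count` reports the raw mean count.
The RDF itself is standard shell counting normalised by bulk density
(from the box volume and water count unless given explicitly).

# Dihedral PCA and the free-energy landscape

φ = (C⁻¹, N, Cα, C) and ψ = (N, Cα, C, N⁺¹) with IUPAC sign convention,
over an interior residue range (2..35 for a 36-residue chain). Each angle
is encoded as (cos, sin), removing the ±π seam; shifting all angles by a
wrap-around constant is an orthogonal transformation of the encoded data,
so eigenvalues are invariant — the suite asserts this to 10⁻⁸. PCA is a
covariance eigendecomposition with each eigenvector's sign fixed so its
largest-magnitude loading is positive, making projections reproducible.

The landscape is ΔG(x, y) = −RT·ln(ρ/ρ~max~) on a regular grid over the
first two components, T = 310 K (the study temperature) and
R = 8.314×10⁻³ kJ·mol⁻¹·K⁻¹. The modal bin is exactly 0; empty bins are
masked NA and never rendered as high energy. The default grid is
100 × 100 over the bounding box expanded by 1% — the source protocol
says only "grids", so this is a package default, not an inherited
choice. Basin identification is k-means (`stats::kmeans`, 50 restarts,
fixed seed) with SSE, average silhouette width and silhouette coefficient
per candidate k (`cluster::silhouette`, computed on a 4000-frame
subsample when frames are many); the default selection is maximum average
silhouette width, replacing visual inspection with a documented,
overridable rule. Representative conformers are, per cluster, the frame
nearest the center of the cluster's minimum-ΔG occupied bin, ordered by
that minimum.

# Essential subspaces: RMSIP and nRMSIP

The essential basis is the set of top eigenvectors of the covariance of
flattened Cα coordinates after superposing frames on their iterative mean
(uniform weights, Cα-trace convention; whether heavier selections were
used in the source workflow is unstated, and Cα is consistent with its
Cα-trace RMSD/RMSF reporting). N, the number of eigenvectors compared,
is never implied by the statistic itself; the default is 10 and every
output records it. For generated ensembles that already share a fixed
reference frame, `fit = FALSE` skips superposition — refitting such data
would mix the prescribed fluctuation modes with rigid-body ones and leak
rank (a rank-2 specification would no longer yield exactly two nonzero
eigenvalues).

RMSIP(A,B) = √((1/N)·ΣᵢΣⱼ(ηᵢᴬ·ηⱼᴮ)²) is 1 for identical subspaces, 0 for
orthogonal ones, and ≈ √(N/d) for random N-dimensional subspaces of
dimension d — the Monte-Carlo baseline the suite checks at N = 10,
d = 100 (√(N/d) ≈ 0.316). nRMSIP divides the cross-trajectory RMSIP by
the geometric mean of each trajectory's first-half/second-half
self-overlap (halves split by frame count, each half superposed on its
own mean), correcting raw overlap for finite sampling. The ratio can
algebraically exceed 1 when cross-overlap beats self-consistency; it is
then flagged with a warning and reported unclipped. Values are classified
into the reporting bands below 0.65, [0.65, 0.75), [0.75, 0.85),
[0.85, 0.95) and [0.95, ∞).

# The synthetic-data layer

The generators define the conditions under which the analyses are
validated; they are first-class, tested code.

**Markov–von Mises dihedrals.** Hidden states follow a discrete Markov
chain (row-stochastic to 10⁻¹²); per residue and angle, emissions are von
Mises around state means (Best–Fisher rejection sampling). Every
generator takes an explicit seed, uses a private RNG stream, restores the
caller's RNG state, and is bit-reproducible.

**Chain reconstruction.** NeRF placement with ideal trans-peptide
geometry (N–Cα 0.1458, Cα–C 0.1525, C–N 0.1329 nm; ω = 180°) produces
poly-Ala-like backbones with amide H placed anti to the preceding
carbonyl (DSSP's own convention) and optional Cβ/Hβ1/Hβ2 pseudo-atoms so
contact statistics have targets. Round-tripping dihedrals through the
rebuilt chain is exact to 10⁻⁶ rad; consecutive Cα–Cα distances are
0.380 nm. Full sidechain rotamers are not modelled.

**Two-state study conditions.** The frozen validation ensemble uses six
switching residues with a helix-like state (−57°, −47°) and its
*antipodal* state (+123°, +133°), κ = 200, chain
[[0.85, 0.15], [0.45, 0.55]] (stationary 3:1, spectral gap 0.4), 20,000
frames, and a 20 × 20 landscape grid. Antipodality is load-bearing: the
(cos, sin) covariance of an angle about its mean is invariant under a
180° shift but not under other reflections, so antipodal states give the
two basins identical shapes in the encoded space and basin peak densities
then reflect occupancies alone. With mirror-but-not-antipodal states the
shared PC2 fits one basin's within-state covariance better than the
other's and biases basin ΔΔG by several tenths of kJ·mol⁻¹ — a property
of the landscape methodology worth knowing when interpreting real maps.
The 20-bin grid keeps modal-bin counts in the thousands, where the
extreme-value bias of "max count per basin" is negligible against the
0.2 kJ·mol⁻¹ check band.

**Gaussian fluctuation ensembles.** Frames are reference + *Lz* with
*z* ~ N(0, I); the covariance may be a scalar σ, per-coordinate SDs, a
low-rank factor, or a full PSD matrix. Used for RMSF closed forms
(σ√3) and rank-recovery of essential bases.

**Solvation scenes.** Single-site water oxygens at bulk density
33.4 nm⁻³ (liquid water), with per-tagged-atom shell density scaled by a
multiplier between an exclusion radius and the 0.5 nm shell radius. The
total water count is fixed across frames (the ensemble container requires
a constant atom count); the split across regions is redrawn per frame by
multinomial allocation so per-region means converge to density × volume.
Shells must fit inside the box and must not overlap each other.

# What passing tests do and do not show

The synthetic conditions exercise the estimators, not the physics: von
Mises emissions are unimodal and isotropic per angle, switching is
memoryless, fluctuations are Gaussian, waters are ideal-gas single
sites. Real trajectories have correlated multi-residue motions,
anharmonic basins, structured hydration shells and slow degrees of
freedom; published table values from microsecond simulations are
therefore *not* reproduction targets here, and the checks are anchored to
the defining equations, parameter values and recoverable ground truth
instead.

# Numerical choices and degenerate inputs

- Kabsch requires ≥ 3 non-collinear points; collinear input errors.
- Sample SD uses the n−1 denominator everywhere a mean ± SD is reported.
- `ci95Threshold()` requires ≥ 100 samples (type-7 empirical quantile).
- Zero-variance PCA input returns a model with all-zero eigenvalues
  rather than erroring; eigenvalues are clamped at 0 against round-off.
- k-means requires k below the number of distinct points; empty clusters
  in conformer extraction are skipped with a warning.
- Silhouettes are evaluated on a seeded 4000-frame subsample above that
  size (pairwise distances are quadratic in frames).
- The acceptance script and test suite use problem sizes chosen so each
  statistic's sampling error sits well inside its check band: 20,000
  frames for occupancy/ΔΔG/subspace recovery, 50,000 frames × 100 atoms
  for the RMSF closed form, 150–200 frames for hydration scenes, 200
  Monte-Carlo draws for the random-subspace baseline.

# Known limitations

XTC/DCD binary trajectories are not read (no reader in the supported
dependency set); multi-model PDB is the trajectory interchange format and
GRO is read as a single frame. PBC re-imaging, hydrogen reconstruction,
sequence alignment across peptides of different lengths, extended DSSP
4.x classes, and free-energy estimators beyond histogram inversion
(MBAR/WHAM) are out of scope. The hydration-shell normalisation is an
interpretation (documented above) rather than a reproduction of an
unstated convention.
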