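---
title: "Methods: divide-and-conquer modelling of a single-pass cytokine receptor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divide-and-conquer modelling of a single-pass cytokine receptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlrarch)
```

## The problem

Single-pass class I cytokine receptors — the prolactin receptor is the
worked example throughout this package — combine three structurally
incompatible regions: a folded extracellular domain (ECD), a single
transmembrane helix (TMD), and a long intrinsically disordered
intracellular domain (ICD). No single experimental technique resolves the
whole chain, so the receptor is modelled *divide-and-conquer*: each domain
is characterised by the technique suited to it (solution NMR for the TMD in
micelles, small-angle X-ray scattering for the ECD, statistical-coil
ensemble modelling validated by diffusion NMR for the ICD), and the pieces
are joined at deliberately overlapping construct boundaries into full-length
models arranged across a membrane slab.

`prlrarch` implements every computational stage of that pipeline:
restraint derivation from NMR observables, helix geometry, coil-ensemble
generation with hydrodynamic validation, Debye-level scattering
observables, and the final membrane-aware assembly with a bilayer
fold-back filter. The `analysis/` scripts in the source repository run the
stages in order on seeded synthetic data.

## Coordinate conventions

Residues are numbered in the mature-receptor convention (1-based; Q1 is
the first extracellular residue). The canonical architecture is encoded in
`assembly_spec()`: ECD Q1–I202, juxtamembrane linker 1 P203–N209, TMD
D210–G236, juxtamembrane linker 2 Y237–C242, ICD I243–H598. Domain
constructs overlap at F206–D210 (ECD/TMD) and G236–V240 (TMD/ICD); the
membrane-embedded stretch is T211–L234. Expression-tag residues (the G-S
pair preceding F206 in the TMD construct) are numbered 204–205 and flagged
as tag residues, never treated as receptor sequence. All coordinates are
in ångström; the membrane normal is the +z axis, extracellular side up.

## Backbone geometry

`build_backbone()` extends a chain residue by residue from (φ, ψ, ω)
dihedrals with fixed ideal bond lengths (N–CA 1.458 Å, CA–C 1.525 Å,
C–N 1.329 Å, C=O 1.231 Å). For the N–CA–C angle we use the tetrahedral
109.5°: among the standard ideal-geometry choices this is the one under
which the canonical α-helix (φ = −57°, ψ = −47°) reproduces the textbook
rise of 1.50 Å per residue, which in turn anchors the package's definition
of helix length. Quoted helical lengths are *residue count × 1.5 Å* (so
the 24-residue helix D210–A233 is 36 Å); the axis-projected CA extent is
reported as a secondary diagnostic and is one rise shorter (n residues
span n − 1 rises, ≈ 34.5 Å here).

`fit_helix_axis()` evaluates two estimators — the mean cross product of
successive CA bisectors (exact on an ideal helix of any length) and the
principal direction of the CA cloud (robust on non-helical stretches) —
and keeps whichever gives the more cylinder-like fit (most nearly constant
per-CA axis distance). This matters for bend angles: a principal-axis fit
on an 11-residue helical flank is biased by several degrees by its partial
final turn, which would swamp a genuine ~6° kink. `bend_angle()` fits
axes to two flanking ranges; when a single pivot residue is quoted (S221
for this receptor) the flanks exclude the pivot (…220 / 222…) so the kink
does not contaminate either fit. How the deposited structure's bend was
originally computed is not recorded anywhere, so this segment convention
is a declared package convention, not a reproduction of an external one.

`superpose()` is the closed-form Kabsch solution; `ensemble_pairwise_rmsd()`
superposes every unordered model pair independently (not onto a medoid)
and reports mean ± sd, the standard NMR-ensemble precision statistic.

## NMR observables

**Secondary chemical shifts.** `compute_scs()` subtracts a bundled
random-coil reference table (CA, CB, C′, HA for the 20 standard residues;
`random_coil_table()`) from observed shifts. Published random-coil scales
differ by small systematic offsets; all synthetic fixtures in this package
generate observed shifts *from* the bundled table, so every test outcome
is independent of which scale is shipped. The per-residue helix score is
ΔδCA − ΔδCB (falling back to ΔδCA when CB is unavailable).

**Helix calling.** `call_helix_segments()` smooths the score with a
centred 3-residue window and calls maximal runs where both the raw and the
smoothed score exceed 0.7 ppm, keeping runs of ≥ 4 residues. Requiring the
raw score as well prevents the window from bleeding a call one residue
past the true boundary — with smoothing alone, a noise-free helix built on
residues 210–233 is called as 209–234. There is no community-standard SCS
helix criterion; threshold, window and minimum length are exposed as
configuration. Sub-threshold positive SCS beyond a called segment (the
transient helical turn at L234–G236 in this receptor) is visible in the
profile but deliberately not called as helix.

**Couplings.** The Karplus relation ³J(φ) = A cos²(φ−60°) + B cos(φ−60°) +
C with the HNHA calibration A = 6.51, B = −1.75, C = 1.60 Hz maps φ to
³J(HN–Hα); `karplus_invert()` solves the quadratic in cos(φ−60°)
analytically, returning up to four φ branches and an empty set (with a
warning) for couplings outside the curve's attainable range [1.48, 9.86]
Hz — a useful consistency check on measured values. `j_from_hnha()`
implements the standard cross/diagonal tangent relation of the
quantitative-J HNHA experiment; the evolution delay ζ is a required input
because it is a property of the pulse sequence, not of the analysis.

**Hydrogen-bond restraints.** `derive_hbond_restraints()` encodes the
helical rule: an i → i−4 backbone hydrogen bond (amide of residue i to
carbonyl of i−4) is emitted when ³J < 5 Hz *and* both donor and acceptor
lie inside the same called helical segment, the segment standing in for
the helical NOE-pattern requirement. Restraints export both as a plain
table and as CNS-style `assign` lines.

**Relaxation and exchange.** `fit_exponential_decay()` fits single
exponentials with a log-linear start refined by `nls` (port algorithm),
flagging non-decaying series instead of fabricating a rate.
`hd_protection()` reduces a quasi-stationary H–D exchange series to a
[0, 1] protection score: the slope of intensity against proton fraction
(1 − f(D₂O)) is 1 for a freely exchanging amide and 0 for a fully
protected one.

## The statistical-coil ensemble

`sample_conformer()` draws (φ, ψ) per residue from a four-class dihedral
library (generic, glycine, proline, pre-proline) and rejects steric
clashes: any CA pair at sequence separation ≥ 3 closer than 4.0 Å triggers
a rewind of up to 5 residues and a redraw, bounded by a total budget of
10⁴ redraws. The bundled library (`coil_library()`, also shipped as
`inst/extdata/coil_library_default.tsv` to document the swappable file
format) uses α/β/polyproline-II basins at weights 0.3/0.3/0.4 for generic
residues, a symmetric extended set for glycine, fixed φ ≈ −65° with
bimodal ψ for proline, and an extended-shifted set for pre-proline, each
basin represented by a few grid points jittered by a 10° Gaussian at draw
time. Basin centres and jitter were fixed once from standard Ramachandran
statistics when the library was written. The true dihedral library of the
established statistical-coil generator used in the original study is not
published, so the bundled library is a declared surrogate: ensemble
observables carry library-choice uncertainty of a few ångström.

The generator is deterministic: per-conformer seeds derive from the master
seed, and identical inputs give bit-identical ensembles. On seeded runs
the 363-residue surrogate ICD chain (uniform composition, 5% proline —
the real sequence would require a download) shows mean Rg ≈ 55–61 Å and an
apparent scaling exponent ν ≈ 0.57–0.60, inside the excluded-volume coil
window [0.50, 0.65] asserted by the test suite.

## Hydrodynamics

Per-conformer hydrodynamic radii use the Kirkwood bead approximation on
one CA bead per residue, 1/R_H = (1/N²)(N/a + Σ_{i≠j} 1/r_ij), with bead
radius a = 4.5 Å (configurable; 4–7 Å is reasonable). The two-bead closed
form 2ar/(a+r) and the single-bead limit R_H = a are exact and are tested
against the general double sum. Ensemble averaging is the harmonic mean
⟨R_H⁻¹⟩⁻¹, appropriate for a fast-exchanging ensemble observed through
translational diffusion. `rh_from_decays()` provides the experimental
route: Gaussian-in-gradient decays S = S₀ exp(−d g²) are fitted for the
protein and a reference compound on the same gradient axis, and
R_H = R_H,ref · d_ref/d_protein — all pulse-timing factors cancel in the
ratio (7.52 Å, the α-cyclodextrin value, is the reference used in the
worked examples).

**Known limitation.** The Kirkwood pair sum systematically underestimates
R_H for expanded disordered chains relative to shell-model hydrodynamics
computed on full-atom conformers: on the seeded 363-residue coil ensemble
it yields ≈ 43 Å where shell-model calculations on comparable ensembles
give ≈ 58 Å and experiment gives ≈ 74 Å. The bead-radius self-term is
only ~2.5% of the double sum at this chain length, so no calibration of a
within [4, 7] Å changes the picture. The package reports the Kirkwood
value as what it is; conclusions about absolute compactness of a real
chain should rest on the diffusion-decay route, with the ensemble value
used for relative comparisons between ensembles.

## Scattering observables

`debye_curve()` evaluates the exact orientation-averaged Debye double sum
I(q) = ΣΣ f_i f_j sin(qr_ij)/(qr_ij) over one scatterer per residue at the
CA position, with uniform (default) or residue-mass weights and the
analytic i = j and q → 0 limits (I(0) = (Σf)²). There is no hydration
shell and no atomic form factor, so absolute χ² values against real
measured curves are not comparable to those from full atomic-scattering
programs; the stage is validated by analytic limits and matched-noise
simulation instead (reduced χ² ≈ 1 when the noise model matches, exactly 0
on proportional curves). `fit_scale_chi2()` finds scale (and optional
constant background) at the weighted least-squares optimum in closed form
and reports reduced χ² with n − p degrees of freedom, interpolating
linearly when q grids differ. `guinier_rg()` iteratively shrinks the
low-q window until q_max·R_g ≤ 1.3; `pair_distance_distribution()` gives
the weighted pair-distance histogram and D_max.

## Assembly across the membrane slab

The slab is ±15 Å about z = 0 (30 Å, a POPC-like hydrocarbon core;
configurable). `place_tmd()` orients the helix axis fitted over the
embedded range parallel to the membrane normal, N-terminal (extracellular)
end up, and centres the embedded-range CA centroid at the slab centre —
a 36 Å helix therefore protrudes at both faces of a 30 Å slab, consistent
with flanking charged anchors. `orient_ecd()` canonicalizes the
extracellular domain: longest principal axis along z ("perpendicular to
the membrane", operationalized this way because no quantitative definition
exists for it), C-terminal end facing the membrane, in-plane axes fixed by
coordinate third moments so rigidly rotated copies produce identical
poses; near-spherical domains fall back to the termini vector with a
warning.

`join_at_overlap()` rigid-body superposes the downstream construct onto
the upstream one over the overlap CAs, keeps the upstream coordinates for
the overlap, and refuses overlaps shorter than 3 residues or with
post-superposition RMSD above 5 Å (conformationally incompatible
constructs). There is no post-join refinement: joints are rigid
superpositions and joint quality is reported as the overlap RMSD. In
`assemble_full_receptor()` the TMD stays fixed in the membrane frame (the
ECD join is applied and then the joint transform inverted on the merged
chain), each ICD conformer is attached at the TMD-side overlap, and the
fold-back filter `membrane_clash_filter()` discards every model with any
heavy atom of a non-exempt residue strictly inside the slab — only the
embedded TMD range is exempt; juxtamembrane linkers are not. Vertical
extents are reported per model and as ensemble percentiles rather than as
a single number, since a disordered ICD makes "the" receptor height a
distribution.

## Synthetic data: what it does and does not show

Every input class has a seeded generator (`gen_helix_shift_table`,
`gen_coupling_table`, `gen_decay`, `gen_toy_domains`, `gen_tmd_ensemble`,
`gen_saxs_from_chain`) producing data with the statistical structure the
analysis assumes: helical shift offsets (CA +2.5, CB −0.5, C′ +1.5, HA
−0.3 ppm — canonical literature-style constants of the fixture) on the
bundled random-coil baseline, couplings through the Karplus curve,
exponential/Gaussian decays with known constants, rigid-compatible toy
domains with the 5-residue overlaps, and Debye curves with multiplicative
noise. Passing the parameter-recovery suite therefore shows the
*operations* are correct — it does not show that real spectra are this
well-behaved. Real data add baseline distortions, peak overlap,
non-uniform noise and reference-frame offsets that these generators
deliberately omit.

## Problem sizes and numerical choices

The test suite and the acceptance script use 200–250 conformers for
ensemble quantities (the per-conformer R_H spread of ≈ 4.6 Å makes the
harmonic mean stable to well under 1 Å at that depth), 100-replicate
simulations for noise studies, and a 1° grid for the Karplus round trip.
Curve fits use closed forms wherever they exist (scale/background,
Kabsch, Karplus inversion) and guarded iterative fits elsewhere
(exponential decays, Guinier window). Degenerate inputs error loudly:
empty sequences, overlapping bend ranges, non-decaying series, coincident
beads, couplings outside the Karplus range, q grids without overlap.
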