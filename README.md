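# prlrarch

Integrative, divide-and-conquer structural modelling of a single-pass
class I cytokine receptor, worked through on the monomeric human prolactin
receptor: NMR-restraint derivation for the transmembrane helix,
statistical-coil ensembles of the disordered intracellular domain with
hydrodynamic validation, Debye-level small-angle scattering observables
for the extracellular domain, and assembly of full-length receptor models
across a membrane slab with a bilayer fold-back filter.

The package is for structural biologists and modellers who need the
computational stages of such a pipeline as reusable, tested functions —
each stage works on standard text formats (multi-model PDB, shift-table
CSV or reduced NMR-STAR, 3-column SAXS curves, decay series) and on seeded
synthetic data emulating all of them, so the whole pipeline runs and is
testable without downloads.

## The models at the core

* **Secondary chemical shifts and helix calling** — Δδ = δ_obs − δ_rc per
  (residue, atom) against a bundled random-coil table; helix score
  ΔδCA − ΔδCB, smoothed over a 3-residue window, threshold 0.7 ppm,
  minimum run 4.
* **Karplus relation** — ³J(HN–Hα) = A cos²(φ−60°) + B cos(φ−60°) + C with
  A = 6.51, B = −1.75, C = 1.60 Hz; analytic inversion with up to four φ
  branches; HNHA cross/diagonal extraction
  J = atan(√(−S_cross/S_diag))/(2πζ).
* **Hydrogen-bond rule** — restraint H(i)→O(i−4) whenever ³J < 5 Hz and
  donor and acceptor sit inside the same called helix.
* **Statistical coil** — per-residue (φ, ψ) draws from a four-class
  dihedral library with CA-sphere self-avoidance (4.0 Å, |i−j| ≥ 3),
  deterministic under a master seed.
* **Kirkwood hydrodynamics** — 1/R_H = (1/N²)(N/a + Σ_{i≠j} 1/r_ij) on CA
  beads (a = 4.5 Å default), ensemble-averaged as the harmonic mean
  ⟨R_H⁻¹⟩⁻¹; experimental route from paired pulsed-gradient diffusion
  decays against a 7.52 Å reference compound.
* **Debye scattering** — I(q) = ΣΣ f_i f_j sin(qr)/(qr), closed-form
  scale/background χ² fitting, iterative Guinier R_g (q_max·R_g ≤ 1.3),
  pair-distance distribution with D_max.
* **Membrane assembly** — helix axis of the embedded range (T211–L234)
  aligned to the membrane normal and centred in a 30 Å slab; domains
  joined by rigid superposition over their 5-residue construct overlaps
  (F206–D210, G236–V240); models whose disordered domain folds back into
  the slab are discarded.

See `vignettes/receptor-architecture-methods.Rmd` for assumptions,
parameter choices and known limitations (in particular why Kirkwood R_H
values on coil ensembles are systematically below shell-model and
experimental values).

## Worked example

The numbered drivers under `analysis/` run the five pipeline stages on
seeded synthetic data and write tables under `results/`. For example:

```sh
Rscript analysis/01_tmd_nmr.R
#> called helical segment(s): 210-233
#> mean |phi error| from inverted couplings: 1.9 deg
#> 20 helical i -> i-4 hydrogen-bond restraints
#> median fitted T2: 47.0 ms (truth 48 ms)
#> protection scores: buried amide 1.00, exposed amide 0.00

Rscript analysis/05_full_assembly.R
#> fold-back filter: 22 of 100 models survive (22%)
#> overlap RMSD: ECD/TMD 1.61e-14 A; TMD/ICD median 1.51 A
#> vertical extent: median 205 A (5-95%: 156-279 A)
#> first survivor: 190 A tall; domain fractions ECD 0.24 TMD 0.22 ICD 0.47
```

Stage 1 recovers the constructed helix window (210–233) from noisy
synthetic shifts, inverts Karplus couplings back to helical φ within ~2°,
and emits the i→i−4 hydrogen bonds the coupling rule licenses. Stage 5
embeds the toy transmembrane helix in the slab, joins the three domains at
their overlaps (the exactly-compatible ECD/TMD overlap superposes to
numerical zero; coil conformers join at ~1–3 Å), and keeps only conformers
whose intracellular domain stays out of the bilayer — the surviving
fraction and the spread of vertical extents are the quantities a
full-length disordered receptor model is summarised by.

In an R session, the same stages are three calls:

```r
library(prlrarch)
ens <- generate_ensemble(surrogate_icd_sequence(), n = 250, seed = 31,
                         start_id = 236L)
rh  <- ensemble_rh(vapply(ens$conformers, kirkwood_rh, numeric(1)))
chain_statistics(ens)$nu   # ~0.58, excluded-volume coil
rh                         # ~42 A (Kirkwood CA-bead, harmonic mean)
```

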