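#!/usr/bin/env Rscript
# Stage 3 — statistical-coil ensemble of the disordered intracellular
# domain and its hydrodynamic validation.
#
# Generates a seeded self-avoiding coil ensemble of the 363-residue
# surrogate chain (numbered 236-598), summarises its polymer statistics,
# computes per-conformer Kirkwood hydrodynamic radii with harmonic-mean
# averaging, and demonstrates the experimental route: paired
# pulsed-gradient diffusion decays against a reference compound of known
# hydrodynamic radius (7.52 A). Writes results/03_icd_ensemble/.

suppressMessages(library(prlrarch))
out_dir <- "results/03_icd_ensemble"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_conf <- 250
ens <- generate_ensemble(surrogate_icd_sequence(), n = n_conf, seed = 31,
                         start_id = 236L)
st <- chain_statistics(ens)
message(sprintf("coil statistics: mean Rg %.1f A, mean end-to-end %.1f A, nu %.2f",
                st$mean_rg, st$mean_end_to_end, st$nu))

rh_each <- vapply(ens$conformers, kirkwood_rh, numeric(1))
rh <- ensemble_rh(rh_each)
message(sprintf(
  "Kirkwood ensemble RH: %.1f A (harmonic mean over %d conformers, sd %.1f A)",
  rh, n_conf, stats::sd(rh_each)))
write.table(data.frame(conformer = seq_len(n_conf), rh = rh_each),
            file.path(out_dir, "per_conformer_rh.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(st$scaling, file.path(out_dir, "subchain_scaling.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

# experimental route: decays constructed so the protein diffuses as a 74 A
# particle relative to the 7.52 A reference
g <- seq(0.1, 3.0, length.out = 12)
ref <- gen_decay("diffusion", truth = 2.0, x = g, noise_sd = 0.01, seed = 32)
pro <- gen_decay("diffusion", truth = 2.0 * 7.52 / 74, x = g,
                 noise_sd = 0.01, seed = 33)
dd <- rh_from_decays(pro, ref, rh_ref = 7.52)
message(sprintf("diffusion-derived RH: %.1f A (decay-constant ratio %.4f)",
                dd$rh, dd$d_protein / dd$d_reference))
message("note: the coil-ensemble Kirkwood RH underestimates shell-model and ",
        "experimental values for disordered chains; see the methods vignette")
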