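# Canonical helical secondary-shift offsets (ppm) used by the shift-table
# generator; fixture constants, not fitted quantities.
HELIX_OFFSETS <- c(CA = 2.5, CB = -0.5, C = 1.5, HA = -0.3)

surrogate_names <- function(residues) {
  pool <- c("ALA", "LEU", "SER", "VAL", "ILE", "THR", "PHE", "LYS", "GLU",
            "TRP", "MET", "ASN", "GLN", "ASP", "ARG", "TYR", "HIS", "CYS")
  pool[(residues %% length(pool)) + 1L]
}

#' Synthetic helical chemical-shift table
#'
#' Observed shifts are the bundled random-coil values plus canonical
#' helical offsets (CA +2.5, CB -0.5, C' +1.5, HA -0.3 ppm) inside the
#' helix window, plus Gaussian noise — the signature that secondary-shift
#' analysis is designed to detect.
#'
#' @param residues residue ids covered by the table (default 206:240, a
#'   TMD-construct span).
#' @param helix `c(first, last)` helical window, or `NULL` for no helix.
#' @param noise_sd shift noise in ppm (default 0).
#' @param seed integer seed.
#' @param residue_names optional three-letter codes (default deterministic
#'   surrogate names).
#' @return a [shift_table()] with rows for CA, CB, C', HA (no CB on GLY).
#' @export
gen_helix_shift_table <- function(residues = 206:240, helix = c(210, 233),
                                  noise_sd = 0, seed = 1L,
                                  residue_names = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(helix) &&
      (helix[1] < min(residues) || helix[2] > max(residues)))
    stop("helix window outside the residue span")
  set.seed(seed)
  if (is.null(residue_names)) residue_names <- surrogate_names(residues)
  coil <- random_coil_table()
  rows <- list()
  for (k in seq_along(residues)) {
    id <- residues[k]; rn <- residue_names[k]
    in_helix <- !is.null(helix) && id >= helix[1] && id <= helix[2]
    for (a in c("CA", "CB", "C", "HA")) {
      base <- coil$shift[coil$residue_name == rn & coil$atom == a]
      if (!length(base) || is.na(base)) next
      val <- base + (if (in_helix) HELIX_OFFSETS[[a]] else 0) +
        (if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0)
      rows[[length(rows) + 1L]] <-
        data.frame(residue_id = id, residue_name = rn, atom = a,
                   shift = val)
    }
  }
  df <- do.call(rbind, rows)
  shift_table(df$residue_id, df$residue_name, df$atom, df$shift)
}

#' Synthetic coupling table from true phi angles
#'
#' Couplings are generated through the Karplus curve from per-residue true
#' phi values, with Gaussian noise, clipped at zero.
#'
#' @param phi named numeric vector: names are residue ids, values true phi
#'   in degrees.
#' @param noise_sd coupling noise in Hz (default 0).
#' @param seed integer seed.
#' @param params a [karplus_parameters()].
#' @return a [coupling_table()].
#' @export
gen_coupling_table <- function(phi, noise_sd = 0, seed = 1L,
                               params = karplus_parameters()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  J <- karplus_forward(as.numeric(phi), params)
  if (noise_sd > 0) J <- J + stats::rnorm(length(J), 0, noise_sd)
  coupling_table(as.integer(names(phi)), pmax(J, 0))
}

#' Synthetic 1-D decay series
#'
#' Relaxation: y = amplitude * exp(-x / truth) (truth = time constant, ms).
#' Diffusion: y = amplitude * exp(-truth * x^2) (truth = decay constant per
#' gradient-unit squared). Gaussian noise is added with sd `noise_sd *
#' amplitude`.
#'
#' @param kind `"relaxation"` or `"diffusion"`.
#' @param truth the true time constant (relaxation) or decay constant
#'   (diffusion).
#' @param x sampling grid (delays in ms, or gradient strengths).
#' @param noise_sd fractional noise level (>= 0).
#' @param seed integer seed.
#' @param amplitude signal at x = 0 (default 1).
#' @return a [decay_series()].
#' @export
gen_decay <- function(kind = c("relaxation", "diffusion"), truth,
                      x = seq(10, 130, length.out = 7), noise_sd = 0,
                      seed = 1L, amplitude = 1) {
  kind <- match.arg(kind)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  y <- if (kind == "relaxation") amplitude * exp(-x / truth)
       else amplitude * exp(-truth * x^2)
  if (noise_sd > 0) y <- y + stats::rnorm(length(x), 0, noise_sd * amplitude)
  decay_series(x, y, kind)
}

#' Toy domain fixtures for assembly tests
#'
#' Builds rigid-compatible toy constructs mirroring the real domain layout:
#' an elongated two-helix extracellular domain numbered 150-210 whose
#' C-terminal helix carries the ECD/TMD overlap (206-210), and an ideal TMD
#' helix construct numbered 204-240 (with 204-205 flagged as expression-tag
#' residues) that is helical through the transmembrane span and extended
#' beyond residue 236. Both overlap windows are built with identical ideal
#' geometry, so joining succeeds with negligible overlap RMSD.
#'
#' @param seed integer seed (reserved; the toy domains are deterministic).
#' @return list with `ecd`, `tmd` (`chain_coordinates`) and `spec`
#'   (an [assembly_spec()] with `ecd = c(150, 202)`).
#' @export
gen_toy_domains <- function(seed = 1L) {
  tmd_res <- 204:240
  n_tmd <- length(tmd_res)
  phi <- rep(-57, n_tmd); psi <- rep(-47, n_tmd)
  ext <- tmd_res > 236
  phi[ext] <- -120; psi[ext] <- 140
  tmd <- build_backbone(surrogate_names(tmd_res),
                        dihedral_set(phi, psi), start_id = 204L)
  attr(tmd, "tag_residues") <- c(204L, 205L)

  ecd_res <- 150:210
  n_ecd <- length(ecd_res)
  phi_e <- rep(-57, n_ecd); psi_e <- rep(-47, n_ecd)
  turn <- ecd_res >= 176 & ecd_res <= 180
  phi_e[turn] <- c(-90, 80, -90, -120, -70)
  psi_e[turn] <- c(0, 30, 120, 140, -30)
  ecd <- build_backbone(surrogate_names(ecd_res),
                        dihedral_set(phi_e, psi_e), start_id = 150L)
  spec <- assembly_spec(ecd = c(150L, 202L))
  list(ecd = ecd, tmd = tmd, spec = spec)
}

#' Synthetic multi-model TMD-like ensemble
#'
#' Emulates an NMR structure bundle: an ideal transmembrane helix with a
#' built-in kink at a pivot residue (one perturbed psi), reproduced `n`
#' times with small independent dihedral jitter so the models scatter like
#' a refined ensemble while keeping ideal bond geometry.
#'
#' @param n number of models (default 10).
#' @param residues residue span (default 206:240).
#' @param helix helical window (default c(210, 233)).
#' @param pivot kink pivot residue (default 221).
#' @param kink_psi psi perturbation at the pivot, degrees (default 8.3,
#'   emulating the slight ~6 degree mid-helix bend of a transmembrane helix).
#' @param jitter_sd per-model dihedral jitter, degrees (default 1.2).
#' @param seed integer seed.
#' @return list with `models` (list of `chain_coordinates`) and `clean`
#'   (the jitter-free kinked chain).
#' @export
gen_tmd_ensemble <- function(n = 10L, residues = 206:240,
                             helix = c(210, 233), pivot = 221L,
                             kink_psi = 8.3, jitter_sd = 1.2, seed = 1L) {
  set.seed(seed)
  m <- length(residues)
  phi0 <- rep(-57, m); psi0 <- rep(-47, m)
  outside <- residues < helix[1] | residues > helix[2]
  phi0[outside] <- -120; psi0[outside] <- 140
  psi0[residues == pivot] <- -47 + kink_psi
  nm <- surrogate_names(residues)
  clean <- build_backbone(nm, dihedral_set(phi0, psi0),
                          start_id = min(residues))
  models <- lapply(seq_len(n), function(i) {
    build_backbone(nm, dihedral_set(phi0 + stats::rnorm(m, 0, jitter_sd),
                                    psi0 + stats::rnorm(m, 0, jitter_sd)),
                   start_id = min(residues))
  })
  list(models = models, clean = clean)
}

#' Synthetic noisy scattering curve from coordinates
#'
#' Debye curve of the chain with multiplicative Gaussian noise; the sigma
#' column is set to the true noise level (`noise_frac * I`), so a matched
#' fit has reduced chi-square near 1.
#'
#' @param chain a `chain_coordinates` object.
#' @param q_grid scattering vector grid in 1/A.
#' @param noise_frac fractional intensity noise (>= 0).
#' @param seed integer seed.
#' @param ff optional per-residue form factors.
#' @return a [scattering_curve()].
#' @export
gen_saxs_from_chain <- function(chain, q_grid = seq(0.005, 0.5, by = 0.005),
                                noise_frac = 0, seed = 1L, ff = NULL) {
  if (noise_frac < 0) stop("noise_frac must be >= 0")
  set.seed(seed)
  calc <- debye_curve(chain, q_grid, ff)
  if (noise_frac == 0) return(calc)
  sigma <- noise_frac * calc$I
  I_noisy <- calc$I + stats::rnorm(length(sigma), 0, sigma)
  scattering_curve(calc$q, I_noisy, sigma)
}
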