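#' Hydrodynamic bead-model parameters
#'
#' One bead per residue, centred on CA, with a common hydrodynamic bead
#' radius. The default 4.5 A is a desk-scale calibration for CA-bead
#' protein models; values in 4-7 A are reasonable.
#'
#' @param bead_radius bead radius a in A (> 0, default 4.5).
#' @return a `hydro_parameters` list.
#' @export
hydro_parameters <- function(bead_radius = 4.5) {
  if (bead_radius <= 0) stop("bead radius must be > 0")
  structure(list(bead_radius = bead_radius), class = "hydro_parameters")
}

#' Kirkwood hydrodynamic radius of a conformer
#'
#' The Kirkwood bead approximation on one CA bead per residue:
#' 1/RH = (1/N^2) (N/a + sum_{i != j} 1 / r_ij).
#' It has the correct single-bead (RH = a) and far-separated (additive
#' friction) limits and is the standard desk-scale estimate for
#' conformer-resolved hydrodynamics of disordered chains.
#'
#' @param chain a `chain_coordinates` object (>= 1 residue).
#' @param params a [hydro_parameters()].
#' @return hydrodynamic radius in A.
#' @export
kirkwood_rh <- function(chain, params = hydro_parameters()) {
  ca <- atom_xyz(chain, "CA")
  n <- nrow(ca)
  if (n == 0L) stop("no CA beads in chain")
  if (n == 1L) return(params$bead_radius)
  d <- stats::dist(ca)
  if (any(d == 0)) stop("coincident beads (zero inter-bead distance)")
  inv_sum <- 2 * sum(1 / d)  # dist() holds each unordered pair once
  inv_rh <- (n / params$bead_radius + inv_sum) / n^2
  1 / inv_rh
}

#' Harmonic-mean ensemble hydrodynamic radius
#'
#' Ensemble averaging of per-conformer RH values as the inverse mean
#' inverse, <RH^-1>^-1 — the average appropriate for a fast-exchanging
#' ensemble observed through translational diffusion.
#'
#' @param values per-conformer RH values in A (all > 0).
#' @return ensemble RH in A.
#' @export
ensemble_rh <- function(values) {
  if (!length(values)) stop("empty RH vector")
  if (any(values <= 0)) stop("RH values must be > 0")
  length(values) / sum(1 / values)
}

#' Hydrodynamic radius from paired diffusion decays
#'
#' Fits the Gaussian-in-gradient diffusion decay S = S0 exp(-d g^2) to a
#' protein series and a reference-compound series recorded on the same
#' gradient axis; since RH is inversely proportional to the diffusion
#' coefficient, RH = RH_ref * d_ref / d_protein. All pulse-timing factors
#' cancel in the ratio.
#'
#' @param protein,reference [decay_series()] objects of kind `diffusion`
#'   on the same gradient axis.
#' @param rh_ref reference-compound hydrodynamic radius in A (e.g. 7.52 A
#'   for alpha-cyclodextrin).
#' @return list with `rh` (A), `d_protein`, `d_reference` (decay constants
#'   per gradient-unit squared).
#' @export
rh_from_decays <- function(protein, reference, rh_ref) {
  for (s in list(protein, reference))
    if (attr(s, "kind") != "diffusion")
      stop("series must be of kind 'diffusion'")
  if (nrow(protein) != nrow(reference) ||
      any(abs(protein$x - reference$x) > 1e-9))
    stop("protein and reference must share the gradient axis")
  fit_d <- function(series) {
    g2 <- series$x^2
    y <- series$y
    pos <- y > 0
    if (sum(pos) < 3L) stop("too few positive intensities")
    cf <- stats::coef(stats::lm(log(y[pos]) ~ g2[pos]))
    d0 <- -cf[2]
    if (!is.finite(d0) || d0 <= 0) stop("non-decaying diffusion series")
    fit <- stats::nls(y ~ s0 * exp(-d * g2),
                      start = list(s0 = exp(cf[1]), d = d0),
                      control = stats::nls.control(maxiter = 200),
                      algorithm = "port", lower = c(0, 1e-12))
    unname(stats::coef(fit)["d"])
  }
  dp <- fit_d(protein)
  dr <- fit_d(reference)
  list(rh = rh_ref * dr / dp, d_protein = dp, d_reference = dr)
}
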