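# Bundled random-coil chemical-shift reference (ppm), one value per
# (residue, atom) for CA, CB, C', HA. Literature-style water-referenced
# values; GLY has no CB. All synthetic fixtures generate observed shifts
# FROM this table, so downstream tests do not depend on the exact entries.
RANDOM_COIL_SHIFTS <- local({
  res <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  ca <- c(52.5, 56.0, 53.1, 54.2, 58.2, 55.7, 56.6, 45.1, 55.0, 61.1,
          55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 57.5, 57.9, 62.2)
  cb <- c(19.1, 30.9, 38.9, 41.1, 28.0, 29.4, 29.9, NA, 29.0, 38.8,
          42.4, 33.1, 32.9, 39.6, 32.1, 63.8, 69.8, 29.6, 38.8, 32.9)
  co <- c(177.8, 176.3, 175.2, 176.3, 174.6, 176.0, 176.6, 174.9, 174.1,
          176.4, 177.6, 176.6, 176.3, 175.8, 177.3, 174.6, 174.7, 176.1,
          175.9, 176.3)
  ha <- c(4.32, 4.34, 4.74, 4.64, 4.71, 4.34, 4.35, 3.96, 4.73, 4.17,
          4.34, 4.32, 4.48, 4.62, 4.42, 4.47, 4.35, 4.66, 4.55, 4.12)
  data.frame(residue_name = rep(res, 4),
             atom = rep(c("CA", "CB", "C", "HA"), each = length(res)),
             shift = c(ca, cb, co, ha),
             stringsAsFactors = FALSE)
})

#' Random-coil reference shift table
#'
#' The bundled per-residue random-coil chemical shifts for CA, CB, C' and
#' HA used as the reference in secondary-chemical-shift analysis.
#'
#' @return data frame with columns `residue_name`, `atom`, `shift` (ppm);
#'   glycine CB is `NA` (glycine has no CB).
#' @export
random_coil_table <- function() RANDOM_COIL_SHIFTS

#' Secondary chemical shifts
#'
#' Computes the secondary chemical shift (SCS) profile: observed shift minus
#' the residue-specific random-coil reference, per (residue, atom), for the
#' atoms the reference covers (CA, CB, C', HA). Positive CA and negative CB
#' deviations are the canonical helix signature. Also derives a per-residue
#' helix score, delta(CA) - delta(CB), falling back to delta(CA) where CB is
#' unavailable (glycine, missing assignments).
#'
#' @param shifts a [shift_table()] of observed shifts.
#' @param coil random-coil reference (default the bundled table).
#' @return an `scs_profile` list with `table` (residue_id, residue_name,
#'   atom, delta ppm) and `score` (per-residue helix score, named by id).
#' @export
compute_scs <- function(shifts, coil = random_coil_table()) {
  sub <- shifts[shifts$atom %in% unique(coil$atom), , drop = FALSE]
  miss <- setdiff(unique(sub$residue_name), unique(coil$residue_name))
  if (length(miss))
    stop("residue name(s) absent from random-coil table: ",
         paste(miss, collapse = ", "))
  key <- paste(sub$residue_name, sub$atom)
  ref <- coil$shift[match(key, paste(coil$residue_name, coil$atom))]
  tab <- data.frame(residue_id = sub$residue_id,
                    residue_name = sub$residue_name,
                    atom = sub$atom,
                    delta = sub$shift - ref,
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$delta), , drop = FALSE]
  ids <- sort(unique(tab$residue_id))
  score <- vapply(ids, function(id) {
    dca <- tab$delta[tab$residue_id == id & tab$atom == "CA"]
    dcb <- tab$delta[tab$residue_id == id & tab$atom == "CB"]
    if (!length(dca)) return(NA_real_)
    if (length(dcb)) dca - dcb else dca
  }, numeric(1))
  names(score) <- ids
  out <- list(table = tab, score = score[!is.na(score)])
  class(out) <- "scs_profile"
  out
}

#' Call helical segments from an SCS profile
#'
#' Smooths the per-residue helix score (delta CA - delta CB) with a centred
#' moving average and reports the maximal runs of consecutive residues whose
#' smoothed *and* raw scores both exceed the threshold, keeping runs of at
#' least `min_len` residues. Requiring the raw score too prevents the
#' smoothing window from bleeding a helix call one residue beyond its true
#' boundaries. Residues without a score break runs. The returned intervals
#' are disjoint and sorted.
#'
#' @param profile an `scs_profile` from [compute_scs()].
#' @param min_len minimum helix length in residues (default 4).
#' @param threshold score threshold in ppm (default 0.7).
#' @param window odd smoothing window in residues (default 3).
#' @return list of integer vectors `c(first, last)`, one per called segment.
#' @export
call_helix_segments <- function(profile, min_len = 4, threshold = 0.7,
                                window = 3) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  score <- profile$score
  if (!length(score)) return(list())
  ids <- as.integer(names(score))
  full <- seq(min(ids), max(ids))
  s <- rep(NA_real_, length(full))
  s[match(ids, full)] <- score
  half <- (window - 1) / 2
  sm <- vapply(seq_along(full), function(i) {
    w <- s[max(1, i - half):min(length(full), i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  helical <- !is.na(s) & !is.na(sm) & sm > threshold & s > threshold
  segs <- list()
  r <- rle(helical)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_len)
      segs[[length(segs) + 1L]] <- c(full[starts[k]], full[ends[k]])
  }
  segs
}

#' Karplus parameters for the three-bond HN-HA coupling
#'
#' Coefficients of 3J(phi) = A cos^2(phi - 60 deg) + B cos(phi - 60 deg) + C.
#' Defaults are the HNHA calibration used for backbone phi restraints
#' (A = 6.51, B = -1.75, C = 1.60 Hz).
#'
#' @param A,B,C coefficients in Hz; `A` must be positive.
#' @return a `karplus_parameters` list.
#' @export
karplus_parameters <- function(A = 6.51, B = -1.75, C = 1.60) {
  if (A <= 0) stop("Karplus A must be > 0")
  structure(list(A = A, B = B, C = C), class = "karplus_parameters")
}

#' Karplus forward map: phi to 3J
#'
#' @param phi backbone phi dihedral(s), degrees.
#' @param params a [karplus_parameters()].
#' @return 3J(HN-HA) in Hz.
#' @export
karplus_forward <- function(phi, params = karplus_parameters()) {
  ct <- cos((phi - 60) * pi / 180)
  params$A * ct^2 + params$B * ct + params$C
}

#' Karplus inverse map: 3J to candidate phi values
#'
#' Solves A c^2 + B c + (C - J) = 0 for c = cos(phi - 60 deg) and expands
#' each root in \[-1, 1\] to its two phi branches, giving up to four
#' solutions in (-180, 180]. A coupling outside the attainable range of the
#' curve returns an empty set with a warning (an inconsistent measurement).
#'
#' @param J observed coupling in Hz (>= 0).
#' @param params a [karplus_parameters()].
#' @return numeric vector of phi solutions in degrees, sorted.
#' @export
karplus_invert <- function(J, params = karplus_parameters()) {
  if (J < 0) stop("J must be >= 0")
  disc <- params$B^2 - 4 * params$A * (params$C - J)
  if (disc < 0) {
    warning("J below the minimum of the Karplus curve; no phi solution")
    return(numeric(0))
  }
  roots <- (-params$B + c(-1, 1) * sqrt(disc)) / (2 * params$A)
  roots <- roots[abs(roots) <= 1]
  if (!length(roots)) {
    warning("J outside the attainable range of the Karplus curve")
    return(numeric(0))
  }
  theta <- acos(roots) * 180 / pi
  phi <- c(theta, -theta) + 60
  phi <- ((phi + 180) %% 360) - 180
  phi[phi == -180] <- 180
  sort(unique(phi))
}

#' Coupling constant from HNHA cross/diagonal intensities
#'
#' The standard quantitative-J relation of the HNHA experiment:
#' S_cross / S_diag = -tan^2(2 pi J zeta), hence
#' J = atan(sqrt(-S_cross / S_diag)) / (2 pi zeta).
#'
#' @param s_cross cross-peak intensity (opposite sign to the diagonal).
#' @param s_diag diagonal-peak intensity (nonzero).
#' @param zeta evolution delay in seconds (> 0); no default — it is a
#'   property of the experiment.
#' @return 3J(HN-HA) in Hz.
#' @export
j_from_hnha <- function(s_cross, s_diag, zeta) {
  if (s_diag == 0) stop("diagonal intensity must be nonzero")
  if (zeta <= 0) stop("zeta must be > 0")
  ratio <- s_cross / s_diag
  if (ratio > 0) stop("positive cross/diagonal ratio is unphysical")
  atan(sqrt(-ratio)) / (2 * pi * zeta)
}

#' Coupling table
#' @param residue_id integer residue ids.
#' @param J 3J(HN-HA) couplings in Hz (>= 0).
#' @param sigma optional uncertainties in Hz.
#' @return a `coupling_table` data frame.
#' @export
coupling_table <- function(residue_id, J, sigma = NA_real_) {
  if (any(J < 0)) stop("couplings must be >= 0")
  if (length(sigma) == 1L) sigma <- rep(sigma, length(residue_id))
  out <- data.frame(residue_id = as.integer(residue_id), J = as.numeric(J),
                    sigma = as.numeric(sigma))
  class(out) <- c("coupling_table", "data.frame")
  out
}

#' Derive helical hydrogen-bond restraints
#'
#' Emits an i -> i-4 backbone hydrogen-bond restraint (amide H/N of residue
#' i to carbonyl O of residue i-4) for every residue whose coupling is below
#' the cutoff, provided both donor and acceptor lie inside the same called
#' helical segment — the small-coupling + helix-pattern rule used to
#' restrain helical structure.
#'
#' @param couplings a [coupling_table()].
#' @param helix_segments list of `c(first, last)` intervals from
#'   [call_helix_segments()].
#' @param j_cutoff coupling cutoff in Hz (default 5.0).
#' @return a `restraint_set` data frame with columns `donor` (residue i),
#'   `acceptor` (residue i - 4) and `type`.
#' @export
derive_hbond_restraints <- function(couplings, helix_segments,
                                    j_cutoff = 5.0) {
  donors <- integer(0)
  for (i in seq_len(nrow(couplings))) {
    id <- couplings$residue_id[i]
    if (couplings$J[i] >= j_cutoff) next
    inside <- any(vapply(helix_segments, function(seg) {
      id >= seg[1] && id <= seg[2] && (id - 4L) >= seg[1]
    }, logical(1)))
    if (inside) donors <- c(donors, id)
  }
  out <- data.frame(donor = donors, acceptor = donors - 4L,
                    type = rep("helical_hbond", length(donors)))
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Write restraints as a simple table and CNS-style assign lines
#'
#' @param restraints a `restraint_set`.
#' @param path output path for the tabular format; a companion file with
#'   extension `.tbl` receives CNS-style `assign` lines (H(i) to O(i-4),
#'   2.0 +/- 0.3 A) for interoperability.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  utils::write.table(restraints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tbl <- sub("(\\.[^.]*)?$", ".tbl", path)
  lines <- sprintf(
    "assign (resid %d and name HN) (resid %d and name O) 2.0 0.3 0.3",
    restraints$donor, restraints$acceptor)
  writeLines(lines, tbl)
  invisible(path)
}

#' Fit a single-exponential decay
#'
#' Least-squares fit of y = a exp(-x / T) to a relaxation series, with a
#' log-linear start refined by nonlinear least squares. A non-decaying
#' series (fitted rate <= 0) is flagged: `T` is `Inf` and `non_decaying`
#' is `TRUE`.
#'
#' @param series a [decay_series()] of kind `relaxation`.
#' @return list with `amplitude`, `T` (time constant, same units as `x`),
#'   `residual` (RMS of fit residuals) and `non_decaying`.
#' @export
fit_exponential_decay <- function(series) {
  if (attr(series, "kind") != "relaxation")
    stop("series must be of kind 'relaxation'")
  x <- series$x; y <- series$y
  pos <- y > 0
  if (sum(pos) < 3L) stop("too few positive intensities to fit")
  lf <- stats::lm(log(y[pos]) ~ x[pos])
  rate0 <- -stats::coef(lf)[2]
  a0 <- exp(stats::coef(lf)[1])
  if (!is.finite(rate0) || rate0 <= 1e-12) {
    return(list(amplitude = mean(y), T = Inf, residual = stats::sd(y),
                non_decaying = TRUE))
  }
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-x / Tc), start = list(a = a0, Tc = 1 / rate0),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE),
               algorithm = "port", lower = c(0, 1e-9)),
    error = function(e) stop("exponential fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  list(amplitude = unname(cf["a"]), T = unname(cf["Tc"]),
       residual = sqrt(mean(stats::residuals(fit)^2)),
       non_decaying = FALSE)
}

#' Hydrogen-deuterium protection score
#'
#' In a quasi-stationary H-D exchange series the amide peak intensity of a
#' fully exchanging residue tracks the proton fraction (1 - f_D2O), while a
#' fully protected amide keeps its intensity regardless of the solvent.
#' The score is 1 minus the least-squares slope of intensity against
#' (1 - f_D2O), clipped to \[0, 1\].
#'
#' @param intensity_by_fraction named numeric vector: names are D2O volume
#'   fractions in \[0, 1\] (>= 3 of them), values are normalized peak
#'   intensities.
#' @return protection score in \[0, 1\]; 1 = fully protected.
#' @export
hd_protection <- function(intensity_by_fraction) {
  f <- as.numeric(names(intensity_by_fraction))
  y <- as.numeric(intensity_by_fraction)
  if (length(f) < 3L) stop("need >= 3 D2O fractions")
  if (any(is.na(f)) || any(f < 0) || any(f > 1))
    stop("D2O fractions must lie in [0, 1]")
  h <- 1 - f
  slope <- stats::coef(stats::lm(y ~ h))[2]
  min(1, max(0, 1 - unname(slope)))
}
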