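#' Per-residue form-factor model
#'
#' Effective scattering weight per residue used by the Debye sum. The
#' default is a uniform weight of 1 per residue; `mass_weighted = TRUE`
#' weights each residue by its average residue mass instead.
#'
#' @param chain a `chain_coordinates` object.
#' @param mass_weighted use average residue masses as weights.
#' @return numeric vector of positive weights, one per residue.
#' @export
form_factors <- function(chain, mass_weighted = FALSE) {
  rid <- residue_ids(chain)
  if (!mass_weighted) return(rep(1, length(rid)))
  code3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  resn <- vapply(rid, function(id)
    chain$residue_name[chain$residue_id == id][1], character(1))
  w <- AA_AVG_MASS[code3to1[resn]]
  if (anyNA(w)) stop("unknown residue name for mass weighting")
  unname(w)
}

#' Theoretical scattering curve by the Debye formula
#'
#' Orientation-averaged point-scatterer intensity
#' I(q) = sum_i sum_j f_i f_j sin(q r_ij) / (q r_ij), with the i = j and
#' q = 0 limits equal to f_i f_j. One scatterer per residue at the CA
#' position; no hydration shell.
#'
#' @param chain a `chain_coordinates` object (non-empty).
#' @param q_grid scattering vector magnitudes in 1/A (>= 0).
#' @param ff per-residue scattering weights (default uniform 1).
#' @return a [scattering_curve()] on `q_grid` (sigma defaulted).
#' @export
debye_curve <- function(chain, q_grid, ff = NULL) {
  ca <- atom_xyz(chain, "CA")
  n <- nrow(ca)
  if (n == 0L) stop("empty chain")
  if (is.null(ff)) ff <- rep(1, n)
  if (length(ff) != n) stop("form-factor length mismatch")
  if (any(ff <= 0)) stop("form factors must be > 0")
  if (any(q_grid < 0)) stop("q must be >= 0")
  self_term <- sum(ff^2)
  if (n == 1L) {
    I <- rep(self_term, length(q_grid))
    return(scattering_curve(q_grid, I))
  }
  d <- as.numeric(stats::dist(ca))
  pair_w <- ff[rep(seq_len(n - 1L), times = (n - 1L):1L)]
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  pair_w <- 2 * pair_w * ff[jj]
  I <- vapply(q_grid, function(q) {
    if (q == 0) return(self_term + sum(pair_w))
    qr <- q * d
    self_term + sum(pair_w * sin(qr) / qr)
  }, numeric(1))
  scattering_curve(q_grid, I)
}

#' Least-squares scale (and background) fit with reduced chi-square
#'
#' Fits I_exp ~ c * I_calc (+ b) by weighted linear least squares in closed
#' form and reports the reduced chi-square
#' chi^2 = 1/(n - p) sum ((I_exp - c I_calc - b) / sigma)^2.
#' When the q grids differ, the experimental curve is linearly interpolated
#' onto the calculated grid over the overlapping q range.
#'
#' @param calc calculated [scattering_curve()].
#' @param exp experimental [scattering_curve()] with uncertainties.
#' @param fit_background also fit a constant background b (default FALSE).
#' @return a `chi_square_fit` list: `scale`, `background`, `chi2`, `n`.
#' @export
fit_scale_chi2 <- function(calc, exp, fit_background = FALSE) {
  if (nrow(calc) == nrow(exp) && all(abs(calc$q - exp$q) < 1e-12)) {
    qs <- calc$q; Ic <- calc$I; Ie <- exp$I; se <- exp$sigma
  } else {
    lo <- max(min(calc$q), min(exp$q))
    hi <- min(max(calc$q), max(exp$q))
    keep <- calc$q >= lo & calc$q <= hi
    if (sum(keep) < 3L) stop("fewer than 3 overlapping q points")
    qs <- calc$q[keep]
    Ic <- calc$I[keep]
    Ie <- stats::approx(exp$q, exp$I, xout = qs)$y
    se <- stats::approx(exp$q, exp$sigma, xout = qs)$y
  }
  n <- length(qs)
  if (n < 3L) stop("fewer than 3 overlapping q points")
  w <- 1 / se^2
  if (fit_background) {
    X <- cbind(Ic, 1)
    cf <- solve(crossprod(X * sqrt(w)), crossprod(X * w, Ie))
    scale <- cf[1]; bg <- cf[2]
    p <- 2L
  } else {
    scale <- sum(w * Ic * Ie) / sum(w * Ic^2)
    bg <- 0
    p <- 1L
  }
  if (scale <= 0) warning("fitted scale is non-positive")
  chi2 <- sum(((Ie - scale * Ic - bg) / se)^2) / (n - p)
  structure(list(scale = as.numeric(scale), background = as.numeric(bg),
                 chi2 = chi2, n = n), class = "chi_square_fit")
}

#' Guinier analysis
#'
#' Iteratively fits ln I = ln I0 - q^2 Rg^2 / 3 on the low-q points,
#' shrinking the fit window until q_max * Rg <= `qmax_rg` (the standard
#' validity limit of the Guinier approximation).
#'
#' @param curve a [scattering_curve()] extending to low q.
#' @param qmax_rg dimensionless validity limit (default 1.3).
#' @param min_points minimum points in the fit window (default 5).
#' @return list with `rg` (A), `I0`, `qmax_used`, `n_points`.
#' @export
guinier_rg <- function(curve, qmax_rg = 1.3, min_points = 5L) {
  q <- curve$q; I <- curve$I
  keep <- I > 0 & q > 0
  q <- q[keep]; I <- I[keep]
  if (length(q) < min_points) stop("too few positive points for Guinier fit")
  n_use <- length(q)
  for (iter in 1:100) {
    cf <- stats::coef(stats::lm(log(I[1:n_use]) ~ I(q[1:n_use]^2)))
    rg2 <- -3 * cf[2]
    rg <- if (rg2 > 0) sqrt(rg2) else 0
    if (rg == 0 || q[n_use] * rg <= qmax_rg)
      return(list(rg = unname(rg), I0 = unname(exp(cf[1])),
                  qmax_used = q[n_use], n_points = n_use))
    n_new <- max(min_points, sum(q * rg <= qmax_rg))
    if (n_new >= n_use) n_new <- n_use - 1L
    if (n_new < min_points)
      stop("Guinier fit did not converge within the validity window")
    n_use <- n_new
  }
  stop("Guinier fit did not converge")
}

#' Pair-distance distribution of a bead model
#'
#' Histogram of all inter-residue CA distances weighted by f_i f_j, the
#' real-space counterpart of the scattering curve; its support ends at the
#' maximum intramolecular distance Dmax.
#'
#' @param chain a `chain_coordinates` object (>= 2 residues).
#' @param bin_width histogram bin width in A (default 1.0).
#' @param ff per-residue scattering weights (default uniform).
#' @return list with `r` (bin centres, A), `p` (weighted counts per bin),
#'   `dmax` (A).
#' @export
pair_distance_distribution <- function(chain, bin_width = 1.0, ff = NULL) {
  ca <- atom_xyz(chain, "CA")
  n <- nrow(ca)
  if (n < 2L) stop("need >= 2 beads")
  if (is.null(ff)) ff <- rep(1, n)
  d <- as.numeric(stats::dist(ca))
  wi <- ff[rep(seq_len(n - 1L), times = (n - 1L):1L)]
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  w <- wi * ff[jj]
  dmax <- max(d)
  breaks <- seq(0, ceiling(dmax / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 2L) breaks <- c(0, bin_width)
  bins <- findInterval(d, breaks, rightmost.closed = TRUE)
  p <- vapply(seq_len(length(breaks) - 1L),
              function(b) sum(w[bins == b]), numeric(1))
  list(r = breaks[-1] - bin_width / 2, p = p, dmax = dmax)
}
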