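# Ideal backbone geometry (Engh-Huber-style values)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_CA_CB <- 1.530
ANG_N_CA_C <- 109.5  # tetrahedral; gives the textbook 1.5 A rise at (-57,-47)
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

#' Per-residue backbone dihedral set
#'
#' @param phi,psi backbone dihedrals in degrees, one per residue; values in
#'   (-180, 180]. The first residue's phi and the last residue's psi may be
#'   `NA` (they are undefined at chain termini).
#' @param omega peptide-bond dihedral, degrees; defaults to 180 (trans).
#' @return a `dihedral_set` data frame with columns `phi`, `psi`, `omega`.
#' @export
dihedral_set <- function(phi, psi, omega = 180) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  chk <- function(v, nm) {
    bad <- !is.na(v) & (v <= -180 | v > 180)
    if (any(bad)) stop(nm, " outside (-180, 180]")
  }
  chk(phi, "phi"); chk(psi, "psi"); chk(omega, "omega")
  out <- data.frame(phi = phi, psi = psi, omega = omega)
  class(out) <- c("dihedral_set", "data.frame")
  out
}

unit3 <- function(v) v / sqrt(sum(v * v))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Natural extension reference frame: position of atom D given A-B-C, the
# C-D bond length, the B-C-D angle and the A-B-C-D torsion (degrees).
place_atom <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  bc <- unit3(c_ - b)
  n <- unit3(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c_)
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return torsion angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

place_cb <- function(n, ca, c_) {
  # ideal tetrahedral branch off CA, in the frame set by N and C
  v1 <- unit3(n - ca); v2 <- unit3(c_ - ca)
  bis <- unit3(v1 + v2)
  perp <- unit3(cross3(v2, v1))
  gamma <- 0.9151  # rad; yields N-CA-CB close to 110.5 deg
  ca + BOND_CA_CB * (-bis * cos(gamma) + perp * sin(gamma))
}

#' Build a backbone chain from dihedral angles
#'
#' Extends an ideal-geometry polypeptide residue by residue from a dihedral
#' set (standard chain extension with fixed bond lengths and angles). The
#' first residue's N is placed at the origin with its CA on the +x axis; the
#' first phi is not consumed (it is undefined). CB atoms are added at ideal
#' tetrahedral positions except on glycine.
#'
#' @param sequence character vector of three-letter residue codes.
#' @param dihedrals a [dihedral_set()] with one row per residue.
#' @param start_id residue id of the first residue (default 1).
#' @return a [chain_coordinates()] satisfying the bond invariants.
#' @export
build_backbone <- function(sequence, dihedrals, start_id = 1L) {
  n <- length(sequence)
  if (n == 0L) stop("empty sequence")
  if (nrow(dihedrals) != n) stop("sequence and dihedral lengths differ")
  phi <- dihedrals$phi; psi <- dihedrals$psi; omega <- dihedrals$omega
  omega[is.na(omega)] <- 180
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  ang <- ANG_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_N,
                               ANG_CA_C_N,
                               if (is.na(psi[i])) 180 else psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], BOND_N_CA,
                                ANG_C_N_CA, omega[i])
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], BOND_CA_C,
                               ANG_N_CA_C,
                               if (is.na(phi[i + 1])) -120 else phi[i + 1])
      # carbonyl O anti to the next N across the sp2 carbonyl carbon
      O[i, ] <- place_atom(CA[i + 1, ], N[i + 1, ], C[i, ], BOND_C_O,
                           ANG_CA_C_O + 2.2, 180)
    } else {
      psi_last <- if (is.na(psi[i])) 180 else psi[i]
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_O,
                           ANG_CA_C_O, psi_last + 180)
    }
  }
  ids <- atoms <- resn <- list()
  xyz <- list()
  seqU <- toupper(sequence)
  for (i in seq_len(n)) {
    a_names <- c("N", "CA", "C", "O")
    a_xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (seqU[i] != "GLY") {
      a_names <- c(a_names, "CB")
      a_xyz <- rbind(a_xyz, place_cb(N[i, ], CA[i, ], C[i, ]))
    }
    ids[[i]] <- rep(start_id + i - 1L, length(a_names))
    atoms[[i]] <- a_names
    resn[[i]] <- rep(seqU[i], length(a_names))
    xyz[[i]] <- a_xyz
  }
  chain_coordinates(unlist(ids), unlist(resn), unlist(atoms),
                    do.call(rbind, xyz))
}

#' Fit the axis of a helical segment
#'
#' Two axis estimators are evaluated and the better cylinder fit kept:
#' (i) the mean of cross products of successive CA bisector vectors, which
#' is exact for an ideal helix of any length, and (ii) the principal
#' direction of the centroid-centred CA cloud, which is robust for
#' non-helical (extended) stretches. The winner is the direction for which
#' the per-CA perpendicular distances are most nearly constant (smallest
#' standard deviation) — the defining property of a cylinder axis. The sign
#' points from the N-terminal towards the C-terminal end; the radius is the
#' RMS distance of the CA atoms from the axis line.
#'
#' @param chain a `chain_coordinates` object.
#' @param residues integer vector of residue ids (>= 7 required).
#' @return a `helix_axis` list with `origin` (centroid), unit `direction`
#'   and `radius` (A).
#' @export
fit_helix_axis <- function(chain, residues) {
  ca <- atom_xyz(chain, "CA", residues)
  n <- nrow(ca)
  if (n < 7L) stop("helix axis fit needs >= 7 residues, got ", n)
  ctr <- colMeans(ca)
  cc <- sweep(ca, 2, ctr)
  cands <- list(svd(cc, nu = 0, nv = 1)$v[, 1])
  # bisector-cross estimator: for an ideal helix the bisector at each
  # interior CA is purely radial, so successive bisectors cross to the axis
  bis <- t(vapply(2:(n - 1), function(i) {
    v <- (ca[i - 1, ] - ca[i, ]) + (ca[i + 1, ] - ca[i, ])
    unit3(v)
  }, numeric(3)))
  if (nrow(bis) >= 2L) {
    crosses <- t(vapply(seq_len(nrow(bis) - 1L), function(i) {
      w <- cross3(bis[i, ], bis[i + 1, ])
      nw <- sqrt(sum(w^2))
      if (nw < 1e-8) c(0, 0, 0) else w / nw
    }, numeric(3)))
    ref <- crosses[1, ]
    sgn <- sign(crosses %*% ref)
    sgn[sgn == 0] <- 1
    mk <- colSums(crosses * as.numeric(sgn))
    if (sqrt(sum(mk^2)) > 1e-6) cands <- c(cands, list(unit3(mk)))
  }
  score <- function(v) {
    proj <- cc %*% v
    stats::sd(sqrt(pmax(rowSums(cc^2) - proj^2, 0)))
  }
  v <- cands[[which.min(vapply(cands, score, numeric(1)))]]
  if (sum(v * (ca[n, ] - ca[1, ])) < 0) v <- -v
  proj <- cc %*% v
  perp2 <- rowSums(cc^2) - proj^2
  out <- list(origin = ctr, direction = as.numeric(v),
              radius = sqrt(mean(pmax(perp2, 0))))
  class(out) <- "helix_axis"
  out
}

#' Bend angle between two helical sub-segments
#'
#' Fits an axis to each residue range and returns the angle between the two
#' axis directions — the kink of a bent helix. When a single pivot residue is
#' quoted for the bend, the flanking ranges should exclude it so the kink
#' does not contaminate either axis fit.
#'
#' @param chain a `chain_coordinates` object.
#' @param residues1,residues2 disjoint residue-id vectors, each >= 7 long.
#' @return bend angle in degrees, in \[0, 180).
#' @export
bend_angle <- function(chain, residues1, residues2) {
  if (length(intersect(residues1, residues2)))
    stop("bend ranges overlap")
  a1 <- fit_helix_axis(chain, residues1)
  a2 <- fit_helix_axis(chain, residues2)
  d <- sum(a1$direction * a2$direction)
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Axial length of a helical segment
#'
#' The quoted length of an alpha-helix is the residue count times the
#' canonical rise of 1.5 A per residue. When a chain is supplied, the CA
#' extent projected on the fitted axis is reported as a secondary diagnostic
#' (it is one rise shorter: n residues span n - 1 rises).
#'
#' @param residues integer vector of residue ids in the helix.
#' @param chain optional `chain_coordinates` for the projected extent.
#' @param rise canonical rise per residue, A (default 1.5).
#' @return list with `nominal` (count x rise, A) and, when `chain` is given,
#'   `projected` (CA extent along the fitted axis, A).
#' @export
helix_axial_length <- function(residues, chain = NULL, rise = 1.5) {
  if (!length(residues)) stop("empty residue range")
  out <- list(nominal = length(residues) * rise)
  if (!is.null(chain)) {
    ax <- fit_helix_axis(chain, residues)
    ca <- atom_xyz(chain, "CA", residues)
    proj <- sweep(ca, 2, ax$origin) %*% ax$direction
    out$projected <- max(proj) - min(proj)
  }
  out
}

kabsch <- function(P, Q) {
  # rotation R and translation t minimizing ||P R + t - Q||; row vectors
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- t(P - matrix(pc, nrow(P), 3, byrow = TRUE)) %*%
    (Q - matrix(qc, nrow(Q), 3, byrow = TRUE))
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- qc - as.numeric(pc %*% R)
  list(rotation = R, translation = t_vec)
}

#' Least-squares rigid superposition
#'
#' Superposes `mobile` onto `reference` over a residue/atom selection by the
#' closed-form Kabsch solution, returning the transform, the minimal RMSD
#' over the selection and the fully transformed mobile chain.
#'
#' @param mobile,reference `chain_coordinates` objects.
#' @param residues residue ids of the selection (must exist in both).
#' @param atoms atom names of the selection (default backbone N, CA, C, O).
#' @return list with `rotation` (3x3, applied to row vectors),
#'   `translation`, `rmsd` (A) and `mobile` (the transformed chain).
#' @export
superpose <- function(mobile, reference, residues,
                      atoms = c("N", "CA", "C", "O")) {
  sel <- function(ch) {
    sub <- ch[ch$residue_id %in% residues & ch$atom %in% atoms, ,
              drop = FALSE]
    sub[order(sub$residue_id, match(sub$atom, atoms)), , drop = FALSE]
  }
  sm <- sel(mobile); sr <- sel(reference)
  key_m <- paste(sm$residue_id, sm$atom)
  key_r <- paste(sr$residue_id, sr$atom)
  common <- intersect(key_m, key_r)
  if (length(common) < 3L)
    stop("superposition needs >= 3 common atoms, got ", length(common))
  P <- cbind(sm$x, sm$y, sm$z)[match(common, key_m), , drop = FALSE]
  Q <- cbind(sr$x, sr$y, sr$z)[match(common, key_r), , drop = FALSE]
  tr <- kabsch(P, Q)
  Pt <- P %*% tr$rotation +
    matrix(tr$translation, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Pt - Q)^2)))
  moved <- transform_chain(mobile, t(tr$rotation), tr$translation)
  # transform_chain applies xyz %*% t(rotation); pass transpose so the net
  # effect is xyz %*% tr$rotation + t
  list(rotation = tr$rotation, translation = tr$translation,
       rmsd = rmsd, mobile = moved)
}

#' Mean pairwise RMSD of a conformer ensemble
#'
#' Every unordered model pair is independently superposed on the selection
#' and its RMSD recorded; the mean and standard deviation over pairs is the
#' conventional precision statistic of an NMR ensemble.
#'
#' @param models list of `chain_coordinates` (>= 2).
#' @param residues residue ids of the selection.
#' @param atoms atom names of the selection (default backbone).
#' @return list with `mean`, `sd` (A; `sd` is 0 for a single pair) and the
#'   vector of per-pair `rmsd` values.
#' @export
ensemble_pairwise_rmsd <- function(models, residues,
                                   atoms = c("N", "CA", "C", "O")) {
  if (length(models) < 2L) stop("need >= 2 models")
  pairs <- utils::combn(length(models), 2)
  r <- apply(pairs, 2, function(ij) {
    superpose(models[[ij[1]]], models[[ij[2]]], residues, atoms)$rmsd
  })
  list(mean = mean(r), sd = if (length(r) > 1L) stats::sd(r) else 0,
       rmsd = r)
}
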