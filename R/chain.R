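#' Per-residue backbone coordinates
#'
#' `chain_coordinates` is the structural currency of the package: one protein
#' chain (or chain fragment) represented by its backbone heavy atoms
#' (N, CA, C, O and, where present, CB), one row per atom, with positions in
#' Angstrom. Residue numbering follows the mature-receptor convention
#' (1-based; Q1 is the first extracellular residue); expression-tag residues
#' in construct fixtures carry numbers below the construct start and are
#' flagged by `tag`.
#'
#' @param residue_id integer vector, one per atom row; strictly increasing
#'   across residues.
#' @param residue_name three-letter residue codes, one per atom row.
#' @param atom atom names, each in `N, CA, C, O, CB`.
#' @param xyz numeric matrix (n x 3) of positions in Angstrom.
#' @param tag optional integer vector of residue ids that are expression-tag
#'   residues rather than receptor residues.
#' @param validate if `TRUE`, check type invariants (see
#'   [validate_chain()]) and stop on violation.
#'
#' @return An object of class `chain_coordinates`: a data frame with columns
#'   `residue_id`, `residue_name`, `atom`, `x`, `y`, `z` and attribute
#'   `tag_residues`.
#' @export
chain_coordinates <- function(residue_id, residue_name, atom, xyz,
                              tag = integer(), validate = TRUE) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(residue_id),
            length(residue_name) == length(residue_id),
            length(atom) == length(residue_id))
  obj <- data.frame(
    residue_id = as.integer(residue_id),
    residue_name = as.character(residue_name),
    atom = as.character(atom),
    x = as.numeric(xyz[, 1]), y = as.numeric(xyz[, 2]),
    z = as.numeric(xyz[, 3]),
    stringsAsFactors = FALSE
  )
  attr(obj, "tag_residues") <- as.integer(tag)
  class(obj) <- c("chain_coordinates", "data.frame")
  if (validate) validate_chain(obj)
  obj
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
ALLOWED_ATOMS <- c(BACKBONE_ATOMS, "CB")

#' Validate chain invariants
#'
#' Checks the `chain_coordinates` type invariants: known atom names, all
#' coordinates finite, strictly increasing residue ids, a complete backbone
#' (N, CA, C, O) for every residue, consecutive-residue CA-CA distances of
#' 3.80 +/- 0.15 A and peptide C-N bonds of 1.33 +/- 0.05 A. Bond checks are
#' only applied between residues whose ids differ by exactly 1 (chain breaks
#' across numbering gaps are legal).
#'
#' @param chain a `chain_coordinates` object.
#' @param check_bonds check CA-CA and C-N bond-length invariants (default
#'   `TRUE`). Assembled multi-domain models relax bond checks at domain
#'   joints, so callers may disable them.
#' @return `chain`, invisibly; stops with a descriptive error on violation.
#' @export
validate_chain <- function(chain, check_bonds = TRUE) {
  stopifnot(inherits(chain, "chain_coordinates"))
  if (nrow(chain) == 0L) stop("chain has no atoms")
  bad_atom <- setdiff(unique(chain$atom), ALLOWED_ATOMS)
  if (length(bad_atom))
    stop("unknown atom name(s): ", paste(bad_atom, collapse = ", "))
  if (!all(is.finite(chain$x) & is.finite(chain$y) & is.finite(chain$z)))
    stop("non-finite coordinates in chain")
  rid <- unique(chain$residue_id)
  if (any(diff(rid) <= 0))
    stop("residue ids are not strictly increasing")
  for (id in rid) {
    atoms <- chain$atom[chain$residue_id == id]
    miss <- setdiff(BACKBONE_ATOMS, atoms)
    if (length(miss))
      stop("residue ", id, " is missing backbone atom(s): ",
           paste(miss, collapse = ", "))
    if (anyDuplicated(atoms))
      stop("residue ", id, " has duplicated atom names")
  }
  if (check_bonds && length(rid) > 1L) {
    ca <- atom_xyz(chain, "CA")
    co <- atom_xyz(chain, "C")
    nn <- atom_xyz(chain, "N")
    bonded <- which(diff(rid) == 1L)
    if (length(bonded)) {
      dca <- sqrt(rowSums((ca[bonded + 1L, , drop = FALSE] -
                           ca[bonded, , drop = FALSE])^2))
      if (any(abs(dca - 3.80) > 0.15))
        stop("CA-CA distance outside 3.80 +/- 0.15 A between residues ",
             rid[bonded[which.max(abs(dca - 3.80))]], " and its successor")
      dcn <- sqrt(rowSums((nn[bonded + 1L, , drop = FALSE] -
                           co[bonded, , drop = FALSE])^2))
      if (any(abs(dcn - 1.33) > 0.05))
        stop("peptide C-N bond outside 1.33 +/- 0.05 A after residue ",
             rid[bonded[which.max(abs(dcn - 1.33))]])
    }
  }
  invisible(chain)
}

#' Residue ids of a chain
#' @param chain a `chain_coordinates` object.
#' @return integer vector of unique residue ids, in chain order.
#' @export
residue_ids <- function(chain) unique(chain$residue_id)

#' Extract coordinates of one atom type per residue
#'
#' @param chain a `chain_coordinates` object.
#' @param atom single atom name (default `"CA"`).
#' @param residues optional integer vector restricting to these residue ids.
#' @return numeric matrix (n_residues x 3), rows in residue order, with the
#'   residue ids as rownames.
#' @export
atom_xyz <- function(chain, atom = "CA", residues = NULL) {
  keep <- chain$atom == atom
  if (!is.null(residues)) keep <- keep & chain$residue_id %in% residues
  sub <- chain[keep, , drop = FALSE]
  m <- cbind(sub$x, sub$y, sub$z)
  rownames(m) <- sub$residue_id
  m
}

#' Subset a chain by residue interval
#' @param chain a `chain_coordinates` object.
#' @param residues integer vector of residue ids to keep.
#' @return a `chain_coordinates` object (not bond-revalidated: the subset may
#'   legally contain numbering gaps).
#' @export
chain_subset <- function(chain, residues) {
  sub <- chain[chain$residue_id %in% residues, , drop = FALSE]
  attr(sub, "tag_residues") <- intersect(attr(chain, "tag_residues"),
                                         residues)
  class(sub) <- class(chain)
  sub
}

#' Apply a rigid transform to a chain
#' @param chain a `chain_coordinates` object.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector, applied after rotation.
#' @return the transformed chain.
#' @export
transform_chain <- function(chain, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  m <- cbind(chain$x, chain$y, chain$z) %*% t(rotation)
  chain$x <- m[, 1] + translation[1]
  chain$y <- m[, 2] + translation[2]
  chain$z <- m[, 3] + translation[3]
  chain
}

#' @export
print.chain_coordinates <- function(x, ...) {
  rid <- residue_ids(x)
  cat(sprintf("<chain_coordinates> %d residues (%d-%d), %d atoms\n",
              length(rid), min(rid), max(rid), nrow(x)))
  invisible(x)
}

#' Radius of gyration of a coordinate set
#' @param xyz numeric matrix (n x 3).
#' @param weights optional per-point weights (default uniform).
#' @return radius of gyration in the units of `xyz`.
#' @export
radius_of_gyration <- function(xyz, weights = NULL) {
  xyz <- as.matrix(xyz)
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  w <- weights / sum(weights)
  ctr <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
}
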