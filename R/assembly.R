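#' Membrane slab
#'
#' The planar region standing in for the bilayer hydrocarbon core. The
#' membrane normal is the +z axis throughout; the extracellular side is
#' above `z_upper`, the cytosol below `z_lower`. Default thickness 30 A
#' (a POPC-like hydrocarbon core).
#'
#' @param z_lower,z_upper slab faces in A (`z_upper > z_lower`).
#' @return a `membrane_slab` list with `z_lower`, `z_upper`, `centre`.
#' @export
membrane_slab <- function(z_lower = -15, z_upper = 15) {
  if (z_upper <= z_lower) stop("z_upper must exceed z_lower")
  structure(list(z_lower = z_lower, z_upper = z_upper,
                 centre = (z_lower + z_upper) / 2),
            class = "membrane_slab")
}

#' Assembly specification
#'
#' Domain boundaries, overlap windows, the membrane-embedded range and
#' ensemble bookkeeping for full-length assembly. Defaults are the mature
#' receptor architecture: ECD Q1-I202, juxtamembrane linker 1 P203-N209,
#' TMD D210-G236, juxtamembrane linker 2 Y237-C242, ICD I243-H598; domain
#' constructs overlap at F206-D210 (ECD/TMD) and G236-V240 (TMD/ICD); the
#' membrane-embedded stretch is T211-L234.
#'
#' @param ecd,jml1,tmd,jml2,icd length-2 `c(first, last)` residue intervals.
#' @param overlap_ecd_tmd,overlap_tmd_icd 5-residue overlap windows.
#' @param embedded membrane-embedded residue interval (inside `tmd`).
#' @param n_models ensemble size for full-length assembly (default 1000).
#' @param seed master seed.
#' @return an `assembly_spec` list.
#' @export
assembly_spec <- function(ecd = c(1L, 202L), jml1 = c(203L, 209L),
                          tmd = c(210L, 236L), jml2 = c(237L, 242L),
                          icd = c(243L, 598L),
                          overlap_ecd_tmd = c(206L, 210L),
                          overlap_tmd_icd = c(236L, 240L),
                          embedded = c(211L, 234L),
                          n_models = 1000L, seed = 1L) {
  iv <- function(x) { stopifnot(length(x) == 2L, x[2] >= x[1]); as.integer(x) }
  spec <- list(ecd = iv(ecd), jml1 = iv(jml1), tmd = iv(tmd),
               jml2 = iv(jml2), icd = iv(icd),
               overlap_ecd_tmd = iv(overlap_ecd_tmd),
               overlap_tmd_icd = iv(overlap_tmd_icd),
               embedded = iv(embedded),
               n_models = as.integer(n_models), seed = as.integer(seed))
  if (spec$embedded[1] < spec$tmd[1] - 1L || spec$embedded[2] > spec$tmd[2])
    stop("embedded range must lie inside the TMD")
  class(spec) <- "assembly_spec"
  spec
}

span_seq <- function(iv) seq(iv[1], iv[2])

rotation_between <- function(v, w) {
  # rotation matrix (for row vectors: x %*% R) taking unit v onto unit w
  v <- unit3(v); w <- unit3(w)
  c_ <- sum(v * w)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 deg turn about any axis perpendicular to v
    a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    k <- unit3(cross3(v, a))
    return(t(2 * outer(k, k) - diag(3)))
  }
  k <- cross3(v, w)
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  R_col <- diag(3) + K + K %*% K / (1 + c_)
  t(R_col)
}

#' Embed the TMD helix in the membrane slab
#'
#' Rigidly orients the TMD so the helix axis fitted over the embedded range
#' is parallel to the membrane normal (z), with the N-terminal end on the
#' extracellular side (higher z), and centres the embedded-range CA
#' centroid on the slab centre (x = y = 0). Idempotent: re-applying to its
#' own output is the identity to numerical precision.
#'
#' @param tmd `chain_coordinates` covering the embedded range.
#' @param spec an [assembly_spec()].
#' @param slab a [membrane_slab()].
#' @return the placed chain.
#' @export
place_tmd <- function(tmd, spec = assembly_spec(), slab = membrane_slab()) {
  emb <- span_seq(spec$embedded)
  ax <- fit_helix_axis(tmd, emb)
  # axis sign is N->C; the chain runs extracellular -> cytosolic, so N->C
  # must point along -z
  R <- rotation_between(ax$direction, c(0, 0, -1))
  out <- transform_chain(tmd, t(R))
  ca <- atom_xyz(out, "CA", emb)
  ctr <- colMeans(ca)
  transform_chain(out, diag(3), c(-ctr[1], -ctr[2], slab$centre - ctr[3]))
}

#' Canonically orient the extracellular domain
#'
#' Aligns the longest principal axis of the CA cloud with the membrane
#' normal, with the C-terminal end (which connects down to the TMD) facing
#' the extracellular slab face, and parks the domain just above the slab
#' (lowest atom 2 A above `z_upper`). The in-plane axes are fixed by the
#' coordinate third moments, so any rigidly rotated copy of the same domain
#' canonicalizes to the same pose. Near-spherical domains (degenerate
#' inertia) fall back, with a warning, to orienting the termini vector.
#'
#' @param ecd `chain_coordinates` with >= 50 residues.
#' @param slab a [membrane_slab()].
#' @return the oriented chain.
#' @export
orient_ecd <- function(ecd, slab = membrane_slab()) {
  rid <- residue_ids(ecd)
  if (length(rid) < 50L) stop("ECD must have >= 50 residues")
  ca <- atom_xyz(ecd, "CA")
  ctr <- colMeans(ca)
  cc <- sweep(ca, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  term_vec <- ca[1, ] - ca[nrow(ca), ]  # C-term -> N-term
  if (ev$values[2] / ev$values[1] > 0.95) {
    warning("near-degenerate inertia; orienting by the termini vector")
    w3 <- unit3(term_vec)
    a <- if (abs(w3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w1 <- unit3(cross3(w3, a))
  } else {
    w3 <- ev$vectors[, 1]
    if (sum(w3 * term_vec) < 0) w3 <- -w3  # N-term up, C-term down
    w1 <- ev$vectors[, 2]
    if (sum((cc %*% w1)^3) < 0) w1 <- -w1  # sign by third moment
    w1 <- unit3(w1 - sum(w1 * w3) * w3)
  }
  w2 <- cross3(w3, w1)
  Q <- cbind(w1, w2, w3)  # new coords = centered %*% Q; w3 -> +z
  out <- transform_chain(ecd, t(Q), -as.numeric(ctr %*% Q))
  zmin <- min(out$z)
  transform_chain(out, diag(3), c(0, 0, slab$z_upper + 2 - zmin))
}

#' Join two domain constructs at an overlap window
#'
#' Rigid-body superposes the downstream construct onto the upstream one over
#' the CA atoms of the shared overlap window, keeps the upstream coordinates
#' for the overlap residues, and appends the downstream residues beyond it.
#' The overlap RMSD after superposition is reported (attribute
#' `overlap_rmsd`) and must not exceed 5 A — larger values signal
#' conformationally incompatible constructs.
#'
#' @param upstream,downstream `chain_coordinates` sharing the overlap.
#' @param overlap length-2 `c(first, last)` residue interval (>= 3
#'   residues).
#' @return merged `chain_coordinates` with attributes `overlap_rmsd` and
#'   `join_transform` (the rotation/translation applied to `downstream`).
#' @export
join_at_overlap <- function(upstream, downstream, overlap) {
  ov <- span_seq(overlap)
  if (length(ov) < 3L) stop("overlap must span >= 3 residues")
  if (!all(ov %in% residue_ids(upstream)) ||
      !all(ov %in% residue_ids(downstream)))
    stop("overlap residues missing from one of the constructs")
  sp <- superpose(downstream, upstream, ov, atoms = "CA")
  if (sp$rmsd > 5)
    stop(sprintf(
      "overlap RMSD %.2f A exceeds 5 A: incompatible conformations",
      sp$rmsd))
  keep_down <- residue_ids(downstream)[residue_ids(downstream) > max(ov)]
  merged_df <- rbind(as.data.frame(upstream),
                     as.data.frame(chain_subset(sp$mobile, keep_down)))
  merged <- chain_coordinates(merged_df$residue_id, merged_df$residue_name,
                              merged_df$atom,
                              cbind(merged_df$x, merged_df$y, merged_df$z),
                              validate = FALSE)
  if (any(diff(unique(merged$residue_id)) <= 0))
    stop("merged numbering is not strictly increasing")
  validate_chain(merged, check_bonds = FALSE)
  attr(merged, "overlap_rmsd") <- sp$rmsd
  attr(merged, "join_transform") <- list(rotation = sp$rotation,
                                         translation = sp$translation)
  merged
}

#' Full-length receptor model
#'
#' Wraps a merged full-length chain with its provenance and architecture
#' metrics, checking that the embedded-range midpoint sits on the slab
#' centre (within 2 A).
#'
#' @param chain merged `chain_coordinates`.
#' @param spec an [assembly_spec()].
#' @param slab a [membrane_slab()].
#' @param provenance free-form list (which domain models were joined).
#' @return a `full_receptor_model` list.
#' @export
full_receptor_model <- function(chain, spec, slab, provenance = list()) {
  emb <- span_seq(spec$embedded)
  ca <- atom_xyz(chain, "CA", emb)
  if (nrow(ca) == 0L) stop("embedded range missing from model")
  mid <- mean(ca[, 3])
  if (abs(mid - slab$centre) > 2)
    stop("embedded-range midpoint is off the slab centre by more than 2 A")
  structure(list(chain = chain, spec = spec, slab = slab,
                 provenance = provenance,
                 vertical_extent = max(chain$z) - min(chain$z)),
            class = "full_receptor_model")
}

slab_violations <- function(chain, slab, exempt) {
  inside <- chain$z > slab$z_lower & chain$z < slab$z_upper
  sum(inside & !(chain$residue_id %in% exempt))
}

#' Bilayer fold-back filter
#'
#' Discards every model with at least one heavy atom of a non-exempt
#' residue strictly inside the membrane slab — conformers whose disordered
#' domain folds back into the region occupied by the bilayer. Only the
#' membrane-embedded TMD range is exempt; juxtamembrane linkers are not.
#'
#' @param models list of [full_receptor_model()]s.
#' @param slab a [membrane_slab()].
#' @param exempt residue ids allowed inside the slab (the embedded range).
#' @return list with `models` (survivors), `n_total`, `n_rejected`.
#' @export
membrane_clash_filter <- function(models, slab, exempt) {
  keep <- vapply(models, function(m)
    slab_violations(m$chain, slab, exempt) == 0L, logical(1))
  list(models = models[keep], n_total = length(models),
       n_rejected = sum(!keep))
}

#' Assemble full-length receptor models
#'
#' The integration stage: embed the TMD in the slab, canonically orient the
#' ECD, join ECD to TMD at their overlap (the TMD stays fixed in the
#' membrane frame), then join each disordered-domain conformer at the
#' TMD-side overlap and apply the bilayer fold-back filter. Deterministic
#' given its inputs.
#'
#' @param ecd,tmd `chain_coordinates` for the folded domains.
#' @param icd_ensemble a `conformer_ensemble` of disordered-domain
#'   conformers (numbered to contain the TMD/ICD overlap).
#' @param spec an [assembly_spec()].
#' @param slab a [membrane_slab()].
#' @return list with `models` (surviving [full_receptor_model()]s) and
#'   `report` (overlap RMSDs, survivor counts, vertical extents).
#' @export
assemble_full_receptor <- function(ecd, tmd, icd_ensemble,
                                   spec = assembly_spec(),
                                   slab = membrane_slab()) {
  tmd_placed <- place_tmd(tmd, spec, slab)
  ecd_oriented <- orient_ecd(ecd, slab)
  stem <- join_at_overlap(ecd_oriented, tmd_placed, spec$overlap_ecd_tmd)
  # the join moved the TMD out of the slab frame; undo its transform on the
  # whole merged chain so the TMD returns to its membrane placement
  tr <- attr(stem, "join_transform")
  stem_fixed <- transform_chain(
    stem, tr$rotation,
    -as.numeric(tr$translation %*% t(tr$rotation)))
  rmsd1 <- attr(stem, "overlap_rmsd")
  exempt <- span_seq(spec$embedded)
  models <- list()
  rmsd2 <- numeric(0)
  for (k in seq_along(icd_ensemble$conformers)) {
    icd <- icd_ensemble$conformers[[k]]
    full <- join_at_overlap(stem_fixed, icd, spec$overlap_tmd_icd)
    rmsd2[k] <- attr(full, "overlap_rmsd")
    models[[k]] <- full_receptor_model(
      full, spec, slab,
      provenance = list(icd_conformer = k,
                        icd_seed = icd_ensemble$metadata$sub_seeds[k]))
  }
  filt <- membrane_clash_filter(models, slab, exempt)
  extents <- vapply(filt$models, function(m) m$vertical_extent, numeric(1))
  list(models = filt$models,
       report = list(overlap_rmsd_ecd_tmd = rmsd1,
                     overlap_rmsd_tmd_icd = rmsd2,
                     n_total = filt$n_total,
                     n_rejected = filt$n_rejected,
                     survivor_fraction = length(filt$models) / filt$n_total,
                     vertical_extent = extents))
}

#' Vertical-extent report of a full-length model
#'
#' Total extent along the membrane normal and the fraction of it spanned by
#' each structured domain (extracellular, transmembrane, intracellular).
#' Fractions of the three domains may sum to less than 1 because the
#' juxtamembrane linkers contribute extent of their own.
#'
#' @param model a [full_receptor_model()].
#' @return list with `total` (A) and `fractions` (named: ecd, tmd, icd).
#' @export
extent_report <- function(model) {
  ch <- model$chain
  spec <- model$spec
  total <- max(ch$z) - min(ch$z)
  dom_extent <- function(iv) {
    z <- ch$z[ch$residue_id %in% span_seq(iv)]
    if (!length(z)) return(NA_real_)
    max(z) - min(z)
  }
  fr <- c(ecd = dom_extent(spec$ecd), tmd = dom_extent(spec$tmd),
          icd = dom_extent(spec$icd)) / total
  list(total = total, fractions = fr)
}
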