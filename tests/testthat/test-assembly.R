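# helper: build an ICD-like conformer from explicit dihedrals, with the
# TMD-matching extended overlap 236-240, and wrap chains as an ensemble
make_icd <- function(res = 236:360, turn_phi = NULL, turn_psi = NULL,
                     turn_at = 261:262) {
  n <- length(res)
  phi <- rep(-57, n); psi <- rep(-47, n)
  ext <- res <= 240
  phi[ext] <- -120; psi[ext] <- 140
  if (!is.null(turn_phi)) {
    tr <- res %in% turn_at
    phi[tr] <- turn_phi; psi[tr] <- turn_psi
  }
  build_backbone(prlrarch:::surrogate_names(res), dihedral_set(phi, psi),
                 start_id = min(res))
}

as_ensemble <- function(chains) {
  structure(list(conformers = chains, seed = 0L,
                 metadata = list(n = length(chains),
                                 sub_seeds = seq_along(chains))),
            class = "conformer_ensemble")
}

test_that("TMD placement aligns the helix axis with the membrane normal", {
  toy <- gen_toy_domains()
  slab <- membrane_slab()
  placed <- place_tmd(toy$tmd, toy$spec, slab)
  ax <- fit_helix_axis(placed, 211:234)
  expect_gte(abs(ax$direction[3]), 0.9998)
  ca <- atom_xyz(placed, "CA", 211:234)
  expect_equal(mean(ca[, 3]), slab$centre, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(ca)[1:2])), 1e-9)
  # extracellular N-terminal side up
  expect_gt(atom_xyz(placed, "CA", 206)[3],
            atom_xyz(placed, "CA", 240)[3])
})

test_that("a 36 A embedded helix protrudes beyond a 30 A slab at both faces", {
  toy <- gen_toy_domains()
  slab <- membrane_slab()
  placed <- place_tmd(toy$tmd, toy$spec, slab)
  expect_gt(atom_xyz(placed, "CA", 210)[3], slab$z_upper)
  expect_lt(atom_xyz(placed, "CA", 235)[3], slab$z_lower)
})

test_that("TMD placement is idempotent", {
  toy <- gen_toy_domains()
  placed <- place_tmd(toy$tmd, toy$spec)
  again <- place_tmd(placed, toy$spec)
  expect_true(coords_equal(placed, again, tol = 1e-3))
})

test_that("ECD orientation aligns, parks above the slab and canonicalizes", {
  toy <- gen_toy_domains()
  slab <- membrane_slab()
  or1 <- orient_ecd(toy$ecd, slab)
  ca <- atom_xyz(or1, "CA")
  cc <- sweep(ca, 2, colMeans(ca))
  pa <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
  expect_gte(abs(pa[3]), cos(1 * pi / 180))
  expect_gte(min(or1$z), slab$z_upper)
  # C-terminal residue nearest the extracellular face
  expect_lt(atom_xyz(or1, "CA", 210)[3], atom_xyz(or1, "CA", 150)[3])
  # idempotence
  or2 <- orient_ecd(or1, slab)
  expect_true(coords_equal(or1, or2, tol = 1e-3))
  # equivariance: a rigidly moved copy canonicalizes to the same pose
  or3 <- orient_ecd(rigid_copy(toy$ecd, 31), slab)
  expect_true(coords_equal(or1, or3, tol = 1e-3))
})

test_that("orientation of a spherical domain warns and falls back", {
  # cubic-lattice ball: exactly degenerate inertia tensor
  g <- expand.grid(x = -4:4, y = -4:4, z = -4:4) * 3
  g <- g[rowSums(g^2) <= 12^2, ]
  ball <- bead_chain(as.matrix(g))
  expect_warning(orient_ecd(ball), "degenerate")
})

test_that("joining identical helices at a 5-residue overlap is exact", {
  a <- ideal_helix(20, start_id = 1L)
  b <- ideal_helix(20, start_id = 16L)
  merged <- join_at_overlap(a, b, c(16L, 20L))
  expect_lt(attr(merged, "overlap_rmsd"), 1e-6)
  expect_length(residue_ids(merged), 2 * 20 - 5)
  expect_error(join_at_overlap(a, b, c(19L, 20L)), ">= 3")
})

test_that("toy domains join into a gap-free numbered chain", {
  toy <- gen_toy_domains()
  merged <- join_at_overlap(toy$ecd, toy$tmd, toy$spec$overlap_ecd_tmd)
  ids <- residue_ids(merged)
  expect_identical(ids, 150:240)
  expect_lt(attr(merged, "overlap_rmsd"), 1e-6)
})

test_that("a corrupted overlap conformation is rejected as incompatible", {
  toy <- gen_toy_domains()
  bad <- toy$tmd
  sel <- bad$residue_id %in% 206:210
  bad$x[sel] <- bad$x[sel] + c(0, 10, -10, 10, 0)[
    match(bad$residue_id[sel], 206:210)]
  expect_error(join_at_overlap(toy$ecd, bad, c(206L, 210L)),
               "incompatible")
})

test_that("fold-back filter keeps below-slab models and rejects intruders", {
  toy <- gen_toy_domains()
  slab <- membrane_slab()
  spec <- toy$spec
  good <- assemble_full_receptor(toy$ecd, toy$tmd,
                                 as_ensemble(list(make_icd())), spec, slab)
  expect_length(good$models, 1)
  m <- good$models[[1]]
  # poke one ICD atom into the slab interior -> rejected
  bad_chain <- m$chain
  idx <- which(bad_chain$residue_id == 300 & bad_chain$atom == "CA")
  bad_chain$z[idx] <- 0
  bad_model <- list(chain = bad_chain, spec = spec, slab = slab)
  class(bad_model) <- "full_receptor_model"
  filt <- membrane_clash_filter(list(m, bad_model), slab,
                                seq(spec$embedded[1], spec$embedded[2]))
  expect_length(filt$models, 1)
  expect_identical(filt$n_rejected, 1L)
})

test_that("an ICD engineered to cross the slab leaves no survivors", {
  toy <- gen_toy_domains()
  crossing <- make_icd(turn_phi = 113, turn_psi = 180)
  out <- assemble_full_receptor(toy$ecd, toy$tmd,
                                as_ensemble(list(crossing)), toy$spec)
  expect_length(out$models, 0)
  expect_identical(out$report$n_rejected, 1L)
})

test_that("survivors contain no non-exempt atom inside the slab", {
  toy <- gen_toy_domains()
  slab <- membrane_slab()
  ens <- generate_ensemble(surrogate_icd_sequence(120), 25, seed = 55,
                           start_id = 236L)
  out <- assemble_full_receptor(toy$ecd, toy$tmd, ens, toy$spec, slab)
  frac <- out$report$survivor_fraction
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  exempt <- seq(toy$spec$embedded[1], toy$spec$embedded[2])
  for (m in out$models) {
    ch <- m$chain
    inside <- ch$z > slab$z_lower & ch$z < slab$z_upper
    expect_identical(sum(inside & !(ch$residue_id %in% exempt)), 0L)
    # the exempt range genuinely occupies the slab interior
    expect_gt(sum(inside & ch$residue_id %in% exempt), 0L)
  }
  # bit-reproducible under the same inputs
  out2 <- assemble_full_receptor(toy$ecd, toy$tmd, ens, toy$spec, slab)
  expect_identical(lapply(out$models, `[[`, "chain"),
                   lapply(out2$models, `[[`, "chain"))
})

test_that("three-domain joining is associative on shared atoms", {
  toy <- gen_toy_domains()
  icd <- make_icd()
  ab <- join_at_overlap(toy$ecd, toy$tmd, c(206L, 210L))
  ab_c <- join_at_overlap(ab, icd, c(236L, 240L))
  bc <- join_at_overlap(toy$tmd, icd, c(236L, 240L))
  a_bc <- join_at_overlap(toy$ecd, bc, c(206L, 210L))
  expect_identical(residue_ids(ab_c), residue_ids(a_bc))
  sp <- superpose(a_bc, ab_c, 150:360, atoms = "CA")
  expect_lt(sp$rmsd, 1e-3)
})

test_that("extent report fractions mirror the constructed architecture", {
  toy <- gen_toy_domains()
  icd <- make_icd(res = 236:395)  # 160 extended-helical residues downward
  out <- assemble_full_receptor(toy$ecd, toy$tmd, as_ensemble(list(icd)),
                                toy$spec)
  expect_length(out$models, 1)
  er <- extent_report(out$models[[1]])
  expect_equal(sum(is.na(er$fractions)), 0)
  expect_lte(sum(er$fractions), 1 + 1e-9)
  manual <- vapply(list(toy$spec$ecd, toy$spec$tmd, toy$spec$icd),
                   function(iv) {
                     z <- out$models[[1]]$chain$z[
                       out$models[[1]]$chain$residue_id %in%
                         seq(iv[1], iv[2])]
                     (max(z) - min(z)) / er$total
                   }, numeric(1))
  expect_equal(unname(er$fractions), manual, tolerance = 1e-12)
  # invariance under global z-translation
  shifted <- out$models[[1]]
  shifted$chain$z <- shifted$chain$z + 40
  er2 <- extent_report(shifted)
  expect_equal(er2$fractions, er$fractions, tolerance = 1e-12)
  expect_equal(er2$total, er$total, tolerance = 1e-12)
})

test_that("a single-domain model reports fraction one for its own span", {
  helix <- ideal_helix(27, start_id = 210L)
  spec <- assembly_spec(ecd = c(1L, 2L), icd = c(400L, 500L))
  slab <- membrane_slab()
  placed <- place_tmd(helix, spec, slab)
  model <- full_receptor_model(placed, spec, slab)
  er <- extent_report(model)
  expect_equal(unname(er$fractions["tmd"]), 1, tolerance = 1e-9)
  expect_true(is.na(er$fractions["ecd"]))
})
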