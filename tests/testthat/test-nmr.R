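test_that("secondary chemical shifts are zero on coil and linear in the offset", {
  tab <- gen_helix_shift_table(helix = NULL, noise_sd = 0)
  prof <- compute_scs(tab)
  expect_true(all(abs(prof$table$delta) < 1e-12))
  helix <- gen_helix_shift_table(noise_sd = 0)
  p1 <- compute_scs(helix)
  doubled <- helix
  coil <- random_coil_table()
  ref <- coil$shift[match(paste(doubled$residue_name, doubled$atom),
                          paste(coil$residue_name, coil$atom))]
  doubled$shift <- ref + 2 * (doubled$shift - ref)
  p2 <- compute_scs(doubled)
  expect_equal(p2$table$delta, 2 * p1$table$delta, tolerance = 1e-12)
})

test_that("SCS errors on residues missing from the coil table", {
  tab <- shift_table(c(1, 2), c("ALA", "XXX"), c("CA", "CA"), c(52.5, 55))
  expect_error(compute_scs(tab), "XXX")
})

test_that("helix calling recovers the constructed window exactly without noise", {
  prof <- compute_scs(gen_helix_shift_table(noise_sd = 0))
  expect_identical(call_helix_segments(prof), list(c(210L, 233L)))
  flat <- compute_scs(gen_helix_shift_table(helix = NULL, noise_sd = 0))
  expect_identical(call_helix_segments(flat), list())
  short <- compute_scs(gen_helix_shift_table(helix = c(220, 222),
                                             noise_sd = 0))
  expect_identical(call_helix_segments(short), list())
  expect_error(call_helix_segments(prof, window = 2), "odd")
})

test_that("helix calls stay within one residue of the truth under noise", {
  hits <- 0L
  for (s in 1:200) {
    prof <- compute_scs(gen_helix_shift_table(noise_sd = 0.2, seed = s))
    segs <- call_helix_segments(prof)
    if (length(segs) >= 1L) {
      main <- segs[[which.max(vapply(segs, diff, numeric(1)))]]
      if (abs(main[1] - 210) <= 1 && abs(main[2] - 233) <= 1)
        hits <- hits + 1L
    }
  }
  expect_gte(hits / 200, 0.95)
})

test_that("called segments never overlap and never cover unscored residues", {
  set.seed(77)
  for (rep in 1:20) {
    ids <- sort(sample(1:60, 40))
    score <- stats::rnorm(40, 0.5, 0.8)
    prof <- structure(list(score = stats::setNames(score, ids)),
                      class = "scs_profile")
    segs <- call_helix_segments(prof)
    covered <- unlist(lapply(segs, function(s) seq(s[1], s[2])))
    expect_identical(anyDuplicated(covered), 0L)
    expect_true(all(covered %in% ids))
  }
})

test_that("Karplus forward map reproduces its calibration coefficients", {
  expect_equal(karplus_forward(-57), 3.74, tolerance = 0.005 / 3.74)
  expect_equal(karplus_forward(60), 6.51 - 1.75 + 1.60, tolerance = 1e-12)
  expect_equal(karplus_forward(150), 1.60, tolerance = 1e-12)
})

test_that("Karplus inversion is exact over the full phi grid", {
  for (phi in seq(-179, 180, by = 1)) {
    sols <- karplus_invert(karplus_forward(phi))
    expect_lt(min(abs(sols - phi)), 0.1)
    for (s in sols)
      expect_lt(abs(karplus_forward(s) - karplus_forward(phi)), 1e-6)
  }
})

test_that("Karplus inversion handles out-of-range and boundary couplings", {
  expect_warning(out <- karplus_invert(20), "range")
  expect_length(out, 0)
  sols <- karplus_invert(1.60)
  expect_true(any(abs(sols - 150) < 0.1))
  expect_true(any(abs(sols - (-30)) < 0.1))
  expect_lte(length(sols), 4)
})

test_that("HNHA intensity ratio converts to couplings and back", {
  expect_identical(j_from_hnha(0, 1, 0.01305), 0)
  zeta <- 0.01305
  ratio <- -tan(2 * pi * 5 * zeta)^2
  expect_equal(j_from_hnha(ratio, 1, zeta), 5, tolerance = 1e-9)
  expect_error(j_from_hnha(0.3, 1, zeta), "unphysical")
  expect_error(j_from_hnha(-0.3, 0, zeta), "nonzero")
})

test_that("hydrogen-bond rule fires only inside segments with a valid acceptor", {
  seg <- list(c(210L, 233L))
  empty <- derive_hbond_restraints(coupling_table(integer(0), numeric(0)),
                                   seg)
  expect_identical(nrow(empty), 0L)
  one <- derive_hbond_restraints(coupling_table(214L, 4), seg)
  expect_identical(one$donor, 214L)
  expect_identical(one$acceptor, 210L)
  boundary <- derive_hbond_restraints(coupling_table(212L, 4), seg)
  expect_identical(nrow(boundary), 0L)
  high_j <- derive_hbond_restraints(coupling_table(214L, 6.5), seg)
  expect_identical(nrow(high_j), 0L)
})

test_that("restraint export writes the tabular and assign formats", {
  rs <- derive_hbond_restraints(
    gen_coupling_table(stats::setNames(rep(-57, 24), 210:233)),
    list(c(210L, 233L)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_restraints(rs, path)
  expect_identical(nrow(utils::read.delim(path)), nrow(rs))
  tbl <- readLines(sub("\\.txt$", ".tbl", path))
  expect_true(all(startsWith(tbl, "assign")))
  expect_length(tbl, nrow(rs))
})

test_that("single-exponential fit recovers the time constant", {
  clean <- gen_decay("relaxation", truth = 50, noise_sd = 0)
  fit <- fit_exponential_decay(clean)
  expect_equal(fit$T, 50, tolerance = 0.001)
  expect_false(fit$non_decaying)
  flat <- decay_series(1:5, rep(0.8, 5))
  ffit <- fit_exponential_decay(flat)
  expect_true(ffit$non_decaying)
  expect_identical(ffit$T, Inf)
  expect_error(fit_exponential_decay(gen_decay("diffusion", 1,
                                               x = seq(0.1, 1, 0.1))),
               "relaxation")
})

test_that("noisy relaxation fits stay within 10% median error", {
  errs <- vapply(1:100, function(s) {
    d <- gen_decay("relaxation", truth = 50, noise_sd = 0.05, seed = s)
    abs(fit_exponential_decay(d)$T - 50) / 50
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("H-D protection score spans its limits linearly", {
  f <- c(0.1, 0.3, 0.4, 0.5, 0.7, 0.9)
  expect_equal(hd_protection(stats::setNames(rep(1, 6), f)), 1)
  expect_equal(hd_protection(stats::setNames(1 - f, f)), 0,
               tolerance = 1e-12)
  expect_equal(hd_protection(stats::setNames(0.5 + 0.5 * (1 - f), f)), 0.5,
               tolerance = 1e-12)
  expect_error(hd_protection(stats::setNames(c(1, 1, 1), c(0.1, 0.5, 1.2))),
               "fractions")
  expect_error(hd_protection(stats::setNames(c(1, 1), c(0.1, 0.5))), ">= 3")
})
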