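# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from disk except files the tests themselves write to tempdir().

ideal_helix <- function(n = 24, start_id = 1L, phi = -57, psi = -47) {
  build_backbone(rep("ALA", n), dihedral_set(rep(phi, n), rep(psi, n)),
                 start_id = start_id)
}

# bare CA-bead cloud (no bond invariants), for hydro / SAXS closed forms
bead_chain <- function(xyz, ids = seq_len(nrow(xyz))) {
  chain_coordinates(ids, rep("ALA", nrow(xyz)), rep("CA", nrow(xyz)),
                    xyz, validate = FALSE)
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rigid_copy <- function(chain, seed = 1) {
  R <- random_rotation(seed)
  transform_chain(chain, R, stats::rnorm(3, sd = 10))
}

coords_equal <- function(a, b, tol = 1e-6) {
  max(abs(cbind(a$x, a$y, a$z) - cbind(b$x, b$y, b$z))) < tol
}

# uniform bead sphere of radius R (deterministic under seed)
bead_sphere <- function(R = 20, n = 500, seed = 7) {
  set.seed(seed)
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n) {
    p <- matrix(stats::runif(3 * n, -R, R), ncol = 3)
    p <- p[rowSums(p^2) <= R^2, , drop = FALSE]
    pts <- rbind(pts, p)
  }
  bead_chain(pts[seq_len(n), ])
}

# small shared coil ensemble (full-length surrogate chain), reused by the
# coil, hydro and acceptance tests to keep the suite fast
shared_icd_ensemble <- local({
  cache <- NULL
  function(n = 30, seed = 101) {
    if (is.null(cache))
      cache <<- generate_ensemble(surrogate_icd_sequence(), n = n,
                                  seed = seed, start_id = 236L)
    cache
  }
})
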