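# Shared fixtures and independent oracles for the test suite.

# one pseudo-atom model from a coordinate table
atom_model <- function(xyz, element = "C", radius = NULL,
                       resno = seq_len(nrow(xyz)), name = "CA",
                       resid = "GLY", chain = "A") {
  m <- structure_model(data.frame(
    serial = seq_len(nrow(xyz)), name = name, element = element,
    resno = resno, resid = resid, chain = chain,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE))
  if (!is.null(radius)) m$atoms$radius <- radius
  m
}

# independent brute-force Monte-Carlo surface integration: random (not
# spiral) points on each probe-expanded sphere, occlusion by direct test
# against every other sphere.
mc_sasa_oracle <- function(xyz, radius, probe = 1.4, n_samples = 2e5,
                           seed = 1) {
  set.seed(seed)
  er <- radius + probe
  total <- 0
  for (i in seq_along(er)) {
    u <- matrix(rnorm(3 * n_samples), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * er[i], 2L, xyz[i, ], "+")
    free <- rep(TRUE, n_samples)
    for (j in seq_along(er)[-i]) {
      free <- free & rowSums(sweep(pts, 2L, xyz[j, ])^2) >= er[j]^2
    }
    total <- total + 4 * pi * er[i]^2 * mean(free)
  }
  total
}

# centre-to-centre distances between assembly copies
copy_center_dists <- function(assembly) {
  d <- as.matrix(dist(model_center(assembly, by_copy = TRUE)))
  diag(d) <- Inf
  d
}

expect_no_clashes <- function(assembly) {
  expect_identical(nrow(clash_check(assembly)), 0L)
}
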