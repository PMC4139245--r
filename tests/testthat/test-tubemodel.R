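# Nanotube geometry and construction: ring stacks and helical wraps.

test_that("ring geometry closed forms are exact", {
  g12 <- ring_geometry(12L, 67.2)
  expect_identical(g12$interior_angle, 150)
  expect_identical(g12$tilt, 30)
  expect_equal(g12$centerline_radius, 67.2 / (2 * sin(pi / 12)))
  g6 <- ring_geometry(6L)
  expect_identical(g6$interior_angle, 120)
  expect_identical(g6$tilt, 60)
  for (n in 3:24) {
    g <- ring_geometry(n, 67.2)
    expect_equal(g$tilt * n, 360)
    expect_equal(g$interior_angle + g$tilt, 180)
  }
  # tube -> plane limit: tilt falls and radius grows monotonically
  radii <- vapply(3:24, function(n) ring_geometry(n)$centerline_radius,
                  numeric(1))
  tilts <- vapply(3:24, function(n) ring_geometry(n)$tilt, numeric(1))
  expect_true(all(diff(radii) > 0))
  expect_true(all(diff(tilts) < 0))
  expect_error(ring_geometry(2L), "domain error")
})

test_that("diameters are reported under all three conventions", {
  g <- ring_geometry(12L, 67.2, thickness_estimate = 20)
  expect_equal(g$diameter_nm[["centerline"]],
               2 * g$centerline_radius / 10)
  expect_equal(g$diameter_nm[["outer"]] - g$diameter_nm[["lumen"]], 4)
  expect_gt(g$diameter_nm[["outer"]], g$diameter_nm[["centerline"]])
})

test_that("a 12-ring holds 72 subunits with exact spacing and tilt", {
  hx <- make_ideal_hexamer()
  ring <- build_ring_tube(hx, tube_spec("ring", 12L,
                                        n_turns_or_rings = 1L))
  expect_length(unique(ring$atoms$copy), 12L)
  expect_length(unique(ring$atoms$chain), 72L)
  ctr <- attr(ring, "centers")
  d <- as.matrix(dist(ctr)); diag(d) <- Inf
  expect_equal(min(d), 67.2, tolerance = 1e-6)
  # each hexamer has exactly two in-ring neighbours at the spacing
  expect_equal(unname(sort(d[1L, ])[1:2]), rep(67.2, 2L),
               tolerance = 1e-6)
  # neighbouring 6-fold axes (radial directions) meet at the tilt angle
  u <- ctr / sqrt(rowSums(ctr^2))
  ang <- acos(pmin(1, sum(u[1L, ] * u[2L, ]))) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-6)
})

test_that("odd hexamer counts are rejected in ring mode", {
  expect_error(tube_spec("ring", 11L), "even")
  expect_error(tube_spec("ring", 11L), "interdigitat")
})

test_that("stacked rings are clash-free with full marker contact", {
  hx <- make_ideal_hexamer()
  tube <- build_ring_tube(hx, tube_spec("ring", 12L,
                                        n_turns_or_rings = 3L))
  expect_no_clashes(tube)
  expect_identical(contact_preservation(tube), 1)
})

test_that("the two-start helical wrap preserves sheet contacts", {
  hx <- make_ideal_hexamer()
  hel <- build_helical_tube(hx, tube_spec("helix", 10L,
                                          n_turns_or_rings = 2L,
                                          n_starts = 2L))
  expect_no_clashes(hel)
  expect_identical(contact_preservation(hel), 1)
  expect_length(unique(hel$atoms$copy), 40L)
  g <- attr(hel, "geometry")
  # close-packed default pitch and its nominal rise
  expect_equal(g$pitch, 2 * 67.2 * sqrt(3) / 2)
  expect_equal(g$rise_per_hexamer, g$pitch / 10)
})

test_that("helix pitch override is honoured in the reported geometry", {
  hx <- make_ideal_hexamer()
  hel <- build_helical_tube(hx, tube_spec("helix", 10L,
                                          n_turns_or_rings = 1L,
                                          n_starts = 2L, pitch = 138))
  g <- attr(hel, "geometry")
  expect_equal(g$pitch, 138)
  expect_equal(g$rise_per_hexamer, 13.8)
  expect_identical(g$n_starts, 2L)
  # one turn per strand, two starts: 20 hexamers in total
  expect_length(unique(hel$atoms$copy), 20L)
  expect_no_clashes(hel)
  expect_error(tube_spec("helix", 10L, pitch = -1), "pitch")
})

test_that("helix builders are deterministic", {
  hx <- make_ideal_hexamer()
  spec <- tube_spec("helix", 10L, n_turns_or_rings = 1L, n_starts = 2L)
  expect_identical(coords(build_helical_tube(hx, spec)),
                   coords(build_helical_tube(hx, spec)))
  rspec <- tube_spec("ring", 12L, n_turns_or_rings = 2L)
  expect_identical(coords(build_ring_tube(hx, rspec)),
                   coords(build_ring_tube(hx, rspec)))
})

test_that("clash detection flags overlaps and only overlaps", {
  hx <- make_ideal_hexamer()
  far <- hexamer_context(hx, 200, "pair")
  expect_no_clashes(far)
  dup <- hexshell:::combine_models(list(hx, hx))
  hits <- clash_check(dup)
  expect_gte(nrow(hits), nrow(hx$atoms))   # atoms^2-scale degenerate case
  expect_true(all(hits$distance < hits$threshold))
})

test_that("contact preservation distinguishes tiled from dispersed sheets", {
  hx <- make_ideal_hexamer()
  expect_identical(contact_preservation(hexamer_context(hx, 67.2, "sheet")),
                   1)
  expect_identical(contact_preservation(hexamer_context(hx, 134.4, "sheet")),
                   0)
  expect_error(contact_preservation(hexamer_context(hx, 67.2, "pair"),
                                    marker_residue = 999L),
               "selection error")
})
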