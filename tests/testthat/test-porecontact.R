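# Pore-axis geometry and hydrogen-bond inventories.

# a donor (with antecedent) and an acceptor at a chosen separation
hbond_fixture <- function(d_acc, antecedent_angle = 180) {
  th <- antecedent_angle * pi / 180
  xyz <- rbind(c(0, 0, 0),                       # donor N
               c(cos(th) * 1.5, sin(th) * 1.5, 0),  # antecedent C
               c(d_acc, 0, 0))                   # acceptor O
  atom_model(xyz, element = c("N", "C", "O"),
             name = c("NZ", "CE", "O"),
             resno = c(26L, 26L, 80L), resid = c("LYS", "LYS", "GLY"),
             chain = c("A", "A", "B"))
}

test_that("hydrogen bonds are detected within the cutoff only", {
  hb <- detect_hbonds(hbond_fixture(2.9))
  expect_identical(nrow(hb), 1L)
  expect_identical(hb$donor_atom, "NZ")
  expect_identical(hb$acceptor_atom, "O")
  expect_equal(hb$distance, 2.9)
  expect_identical(nrow(detect_hbonds(hbond_fixture(4.0))), 0L)
})

test_that("the antecedent angle criterion filters bent geometries", {
  # antecedent opposite the acceptor: fine
  expect_identical(nrow(detect_hbonds(hbond_fixture(2.9, 180),
                                      require_geometry = TRUE)), 1L)
  # antecedent on the acceptor side (angle 30 degrees): rejected
  expect_identical(nrow(detect_hbonds(hbond_fixture(2.9, 30),
                                      require_geometry = TRUE)), 0L)
})

test_that("bonds are classified by chain and copy relationship", {
  hx <- make_ideal_hexamer()
  pair <- hexamer_context(hx, 67.2, "pair")
  hb <- detect_hbonds(pair)
  expect_gt(nrow(hb), 0L)
  expect_true(all(hb$class == "inter-hexamer"))
  # the dyad-contact marker pair bonds across the interface
  expect_true(any(hb$donor_resno == 26L & hb$acceptor_resno == 26L))
  # invariance under rigid motion
  t <- axis_rotation(c(2, 1, 5), 77, c(1, 2, 3))
  hb2 <- detect_hbonds(apply_transform(pair, t))
  expect_equal(hb2$distance, hb$distance, tolerance = 1e-9)
  expect_identical(hb2[, c("donor_chain", "donor_resno", "class")],
                   hb[, c("donor_chain", "donor_resno", "class")])
})

test_that("interface comparison buckets shared and unique bonds", {
  mk <- function(donor_resid, donor_resno, acc_resid, acc_resno) {
    data.frame(donor_resid = donor_resid, donor_resno = donor_resno,
               acceptor_resid = acc_resid, acceptor_resno = acc_resno,
               class = "inter-hexamer", stringsAsFactors = FALSE)
  }
  a <- mk("LYS", 26L, "GLY", 80L)
  b <- rbind(mk("ARG", 79L, "ASP", 22L), mk("ARG", 79L, "GLY", 83L),
             mk("ARG", 79L, "GLY", 84L))
  cmp <- compare_interfaces(a, b)
  expect_identical(sum(cmp$status == "shared"), 0L)
  expect_identical(sum(cmp$status == "only_a"), 1L)
  expect_identical(sum(cmp$status == "only_b"), 3L)
  same <- compare_interfaces(b, b)
  expect_true(all(same$status == "shared"))
  none <- compare_interfaces(a[0, ], b[0, ])
  expect_identical(nrow(none), 0L)
})

test_that("pore cross separations and radius follow the construction", {
  hx <- make_ideal_hexamer()
  pp <- pore_profile(hx)
  # loop markers on a 4.5-Angstrom circle: three equal 9.0 separations
  expect_equal(unname(pp$cross_separations), rep(9, 3L),
               tolerance = 1e-9)
  expect_equal(pp$anisotropy, 0, tolerance = 1e-9)
  expect_equal(pp$min_radius, 4.5 - vdw_radii()[["N"]],
               tolerance = 0.05)
  expect_error(pore_profile(select_chains(hx, LETTERS[1:5])), "6-chain")
  expect_error(pore_profile(hx, loop_atom_spec = c(40, "XX")),
               "chain A")
})

test_that("a stretched pore shows the constructed anisotropy", {
  hx <- make_ideal_hexamer()
  a <- hx$atoms
  # stretch one cross axis: displace the A/D loop atoms outward 0.7 A
  sel <- a$resno == 40L & a$chain %in% c("A", "D")
  sgn <- ifelse(a$chain[sel] == "A", 1, -1)
  u <- cbind(cos(pi / 6), sin(pi / 6), 0)   # A-loop radial direction
  hx$atoms[sel, c("x", "y", "z")] <-
    a[sel, c("x", "y", "z")] + 0.7 * sgn * u[rep(1L, sum(sel)), ]
  pp <- pore_profile(hx, axis = fit_symmetry_axis(make_ideal_hexamer(), 6L))
  expect_equal(max(pp$cross_separations) - min(pp$cross_separations),
               1.4, tolerance = 1e-6)
  expect_equal(which.max(pp$cross_separations), c(`A-D` = 1L))
})

test_that("a closed ring of atoms bounds the pore at the closed form", {
  th <- seq(0, 2 * pi, length.out = 13L)[-13L]
  ring <- atom_model(cbind(3 * cos(th), 3 * sin(th), 0),
                     radius = rep(1.5, 12L),
                     chain = rep(LETTERS[1:6], each = 2L),
                     resno = rep(c(40L, 41L), 6L),
                     name = rep(c("N", "CA"), 6L))
  pp <- pore_profile(ring, axis = fit_symmetry_axis(ring, 6L), step = 0.25)
  expect_equal(pp$min_radius, 1.5, tolerance = 1e-6)
})

test_that("adding atoms can only narrow the pore", {
  hx <- make_ideal_hexamer()
  axis <- fit_symmetry_axis(hx, 6L)
  base <- pore_profile(hx, axis = axis)
  plug <- hx
  extra <- plug$atoms[plug$atoms$resno == 40L, ]
  extra$x <- extra$x * 0.8
  extra$y <- extra$y * 0.8
  extra$resno <- 41L
  extra$serial <- max(plug$atoms$serial) + seq_len(nrow(extra))
  plug$atoms <- rbind(plug$atoms, extra)
  narrowed <- pore_profile(plug, axis = axis)
  expect_lte(narrowed$min_radius, base$min_radius)
})

test_that("probe fitting reports the passing corridor", {
  hx <- make_ideal_hexamer()
  pp <- pore_profile(hx)
  all_pass <- probe_fit(pp, 0)
  expect_true(all(all_pass$pass))
  expect_true(attr(all_pass, "summary")$continuous)
  none <- probe_fit(pp, max(pp$samples$radius) + 1)
  expect_false(any(none$pass))
  # a glycerol-sized probe traverses the default synthetic pore
  glyc <- probe_fit(pp, 2.6)
  expect_true(attr(glyc, "summary")$continuous)
  expect_error(probe_fit(pp, -0.1), "domain error")
})
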