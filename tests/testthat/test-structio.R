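# Structure I/O, rigid transforms and lattice-translation geometry.

test_that("a one-atom model round-trips through PDB to coordinate precision", {
  m <- atom_model(matrix(c(1.234, -5.678, 9.012), 1L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), 1L)
  expect_equal(coords(m2), coords(m), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("synthetic hexamer written then re-read is identical to PDB precision", {
  hx <- make_ideal_hexamer()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(hx, f)
  hx2 <- read_structure(f)
  expect_lt(max(abs(coords(hx2) - coords(hx))), 1e-3 + 1e-12)
  expect_identical(hx2$atoms$chain, hx$atoms$chain)
  expect_identical(hx2$atoms$resno, hx$atoms$resno)
  # write(read(x)) is idempotent
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(hx2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("read_structure matches an independent PDB parser", {
  skip_if_not_installed("bio3d")
  hx <- make_ideal_hexamer()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(hx, f)
  ref <- bio3d::read.pdb(f)
  mine <- read_structure(f)
  expect_equal(matrix(ref$xyz, ncol = 3L, byrow = TRUE), coords(mine),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ref$atom$resno, mine$atoms$resno)
})

test_that("reader errors are specific", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f), "no ATOM records")
  writeLines(c("ATOM      1  CA  GLY A   1      1.0foo   2.000   3.000"),
             f)
  expect_error(read_structure(f), "line 1")
  expect_error(read_structure(file.path(tempdir(), "absent-xyz.pdb")),
               "cannot read")
})

test_that("a 72-chain ring tube uses the two-character chain scheme", {
  tube <- build_ring_tube(make_ideal_hexamer(),
                          tube_spec("ring", 12L, n_turns_or_rings = 1L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tube, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^TER", lines)), 72L)
  back <- read_structure(f)
  expect_length(unique(back$atoms$chain), 72L)
  expect_lt(max(abs(coords(back) - coords(tube))), 1e-3 + 1e-12)
})

test_that("an attached crystal cell round-trips through CRYST1", {
  hx <- make_ideal_hexamer()
  hx$cell <- crystal_cell(45.2, 93.3, 63.1, 90, 105.0, 90, "P 1 21 1")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(hx, f)
  cl <- read_structure(f)$cell
  expect_equal(c(cl$a, cl$b, cl$c), c(45.2, 93.3, 63.1))
  expect_equal(cl$beta, 105.0)
  expect_identical(cl$space_group_label, "P 1 21 1")
})

test_that("altloc handling keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 2.0)
})

test_that("rigid transforms preserve internal geometry", {
  hx <- make_ideal_hexamer()
  expect_equal(coords(apply_transform(hx, rigid_transform())), coords(hx))
  # 60-degree rotation about the C6 axis superposes the hexamer on itself
  rot <- axis_rotation(c(0, 0, 1), 60)
  moved <- apply_transform(hx, rot)
  a <- hx$atoms
  blocks <- split(seq_len(nrow(a)), factor(a$chain, LETTERS[1:6]))
  target <- unlist(blocks[c(2:6, 1L)], use.names = FALSE)
  expect_lt(sqrt(mean(rowSums((coords(moved) -
                                 coords(hx)[target, ])^2))), 1e-6)
  # distances preserved under an arbitrary transform
  t <- axis_rotation(c(1, 2, 3), 37.5, c(4, -1, 2))
  m2 <- apply_transform(hx, t)
  i <- c(1L, 50L, 200L)
  j <- c(400L, 300L, 100L)
  expect_equal(sqrt(rowSums((coords(m2)[i, ] - coords(m2)[j, ])^2)),
               sqrt(rowSums((coords(hx)[i, ] - coords(hx)[j, ])^2)),
               tolerance = 1e-9)
  # translation by the lattice spacing moves the centre by exactly that
  sh <- apply_transform(hx, rigid_transform(diag(3), c(67.2, 0, 0)))
  expect_equal(sqrt(sum((model_center(sh) - model_center(hx))^2)), 67.2)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("lattice translation lengths follow the cell geometry", {
  type1 <- crystal_cell(45.2, 93.3, 63.1, 90, 105.0, 90, "P 1 21 1")
  # the ac-diagonal of the strip-forming monoclinic cell
  expect_equal(lattice_translation_length(type1, c(1, 0, 1)), 67.4,
               tolerance = 0.1 / 67.4)
  expect_equal(lattice_translation_length(type1, c(1, 0, 0)), 45.2)
  ortho <- crystal_cell(3, 4, 5)
  expect_equal(lattice_translation_length(ortho, c(1, 1, 1)), sqrt(50))
  # orthorhombic general property + sign-flip symmetry
  for (uvw in list(c(2, -1, 3), c(0, 1, 0), c(-1, -1, 2))) {
    expect_equal(lattice_translation_length(ortho, uvw),
                 sqrt(sum((uvw * c(3, 4, 5))^2)))
    expect_equal(lattice_translation_length(type1, uvw),
                 lattice_translation_length(type1, -uvw))
  }
  expect_error(lattice_translation_length(type1, c(0, 0, 0)), "zero")
})

test_that("expand_neighbors produces translated, relabelled copies", {
  hx <- make_ideal_hexamer()
  cell_hex <- crystal_cell(67.2, 67.2, 40, 90, 90, 120, "P 62 2 2")
  one <- expand_neighbors(hx, cell_hex, list(c(0, 0, 0)))
  expect_equal(coords(one), coords(hx), ignore_attr = TRUE)
  # in-plane first neighbours of a gamma = 120 degree hexagonal cell
  nb6 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(1, 1, 0), c(-1, -1, 0))
  asm <- expand_neighbors(hx, cell_hex, c(list(c(0, 0, 0)), nb6))
  ctr <- model_center(asm, by_copy = TRUE)
  d0 <- sqrt(rowSums(sweep(ctr[-1, ], 2L, ctr[1L, ])^2))
  expect_equal(unname(d0), rep(67.2, 6L))
  # per-copy internal geometry unchanged
  a2 <- asm$atoms[asm$atoms$copy == 3L, ]
  expect_equal(max(abs(dist(coords(hx)[1:50, ]) -
                         dist(as.matrix(a2[1:50, c("x", "y", "z")])))),
               0, tolerance = 1e-9)
  two <- expand_neighbors(hx, crystal_cell(45.2, 93.3, 63.1, 90, 105, 90),
                          list(c(0, 0, 0), c(1, 0, 1)))
  cc <- model_center(two, by_copy = TRUE)
  expect_equal(sqrt(sum((cc[2L, ] - cc[1L, ])^2)), 67.4,
               tolerance = 0.1 / 67.4)
  expect_error(expand_neighbors(hx, cell_hex,
                                list(c(0, 0, 0), c(0, 0, 0))),
               "duplicate")
})

test_that("radii table and config override behave", {
  expect_equal(unname(vdw_radii()[c("C", "N", "O", "S")]),
               c(1.70, 1.55, 1.52, 1.80))
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("C = 1.75", "default = 1.6", "chain_scheme = two-char"), f)
  cfg <- read_radii_config(f)
  expect_equal(cfg$radii[["C"]], 1.75)
  expect_identical(cfg$chain_scheme, "two-char")
  rad <- vdw_radii(cfg$radii)
  m <- atom_model(matrix(0, 1L, 3L), element = "ZZ")
  m2 <- structure_model(m$atoms[, !(names(m$atoms) == "radius")],
                        radii = rad)
  expect_equal(m2$atoms$radius, 1.6)
})
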