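# Synthetic-data generators: the coarse-grained hexamer, symmetry
# perturbation, TEM-like measurement samples and alignment fixtures.

test_that("the ideal hexamer is strictly 6-fold symmetric with protruding arms", {
  hx <- make_ideal_hexamer()
  a <- hx$atoms
  expect_length(unique(a$chain), 6L)
  expect_length(unique(table(a$chain)), 1L)
  expect_lt(symmetry_deviation(hx, 6L), 1e-9)
  # the arm marker protrudes beyond the hexagonal outline of the body
  r79 <- sqrt(a$x^2 + a$y^2)[a$resno == 79L]
  expect_true(all(r79 > attr(hx, "hexamer_spec")$outer_radius))
  # all marker roles present in every chain
  for (ch in unique(a$chain))
    expect_true(all(c(22L, 26L, 40L, 51L, 79L) %in%
                      a$resno[a$chain == ch]))
})

test_that("generators are seed-deterministic", {
  expect_identical(make_ideal_hexamer(), make_ideal_hexamer())
  hx <- make_ideal_hexamer()
  p1 <- perturb_hexamer(hx, 0.5, seed = 11L)
  p2 <- perturb_hexamer(hx, 0.5, seed = 11L)
  p3 <- perturb_hexamer(hx, 0.5, seed = 12L)
  expect_identical(coords(p1), coords(p2))
  expect_gt(max(abs(coords(p1) - coords(p3))), 0)
  expect_identical(coords(perturb_hexamer(hx, 0, seed = 1L)), coords(hx))
  expect_error(perturb_hexamer(hx, -0.1), "non-negative")
  s1 <- sample_diameters(20.4, 1.1, 20, seed = 5L)
  s2 <- sample_diameters(20.4, 1.1, 20, seed = 5L)
  expect_identical(s1$values, s2$values)
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(sample_diameters(20, 1, 5, seed = 9L))
  invisible(perturb_hexamer(hx, 0.2, seed = 9L))
  expect_identical(rnorm(1), before)
})

test_that("perturbation breaks symmetry by the expected amount", {
  hx <- make_ideal_hexamer()
  expect_gt(symmetry_deviation(perturb_hexamer(hx, 0.5, seed = 3L), 6L),
            0.4)
})

test_that("hexamers tile at the native spacing: contacts without clashes", {
  hx <- make_ideal_hexamer()
  pair <- hexamer_context(hx, 67.2, "pair")
  a <- pair$atoms
  m1 <- as.matrix(a[a$copy == 1L & a$resno == 26L, c("x", "y", "z")])
  m2 <- as.matrix(a[a$copy == 2L & a$resno == 26L, c("x", "y", "z")])
  cross <- sqrt(outer(rowSums(m1^2), rowSums(m2^2), "+") -
                  2 * tcrossprod(m1, m2))
  expect_lt(min(cross), 6)
  expect_no_clashes(pair)
  expect_no_clashes(hexamer_context(hx, 67.2, "sheet"))
})

test_that("diameter samples reproduce the requested distribution", {
  # sample mean lands in the reporting-convention n = 20 window
  means <- vapply(1:40, function(s)
    sample_diameters(20.4, 1.1, 20, seed = s)$mean, numeric(1))
  expect_gte(mean(means >= 19.6 & means <= 21.2), 0.95)
  # zero variance gives exact values
  s0 <- sample_diameters(18.3, 0, 40, seed = 1L)
  expect_true(all(s0$values == 18.3))
  # large-n sd consistency
  big <- sample_diameters(20.4, 1.1, 10000, seed = 2L)
  expect_equal(big$sd, 1.1, tolerance = 0.03)
  expect_error(sample_diameters(20.4, 1.1, 0), "domain error")
  expect_error(sample_diameters(-1, 1.1, 10), "domain error")
})

test_that("measurement report uses the m +/- s (n measurements) style", {
  s <- sample_diameters(20.4, 1.1, 20, seed = 7L)
  expect_match(format_measurement(s),
               "^[0-9]+\\.[0-9] ± [0-9]+\\.[0-9] nm \\(20 measurements\\)$")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_measurement_tsv(s, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$diameter_nm, s$values)
})

test_that("alignment fixtures honour conserved columns and gaps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  make_alignment_fixture(6, 100, c(`26` = "K", `51` = "V"), seed = 4L,
                         path = f)
  msa <- read_alignment(f)
  cons <- column_conservation(msa, c(26, 51))
  expect_equal(cons$identity, c(1, 1))
  expect_equal(cons$consensus, c("K", "V"))
  # identical fixture text for identical seeds
  expect_identical(make_alignment_fixture(4, 30, seed = 8L),
                   make_alignment_fixture(4, 30, seed = 8L))
  expect_error(make_alignment_fixture(4, 30, c(`31` = "K")),
               "out of range")
  # unconstrained uniform columns: mean conservation near 1/20 plus the
  # positive bias of taking the modal letter in 6 draws
  ids <- vapply(1:50, function(s) {
    g <- withr::local_tempfile(fileext = ".fasta")
    make_alignment_fixture(6, 50, seed = s, path = g)
    mean(column_conservation(read_alignment(g), 1:50)$identity)
  }, numeric(1))
  expect_gt(mean(ids), 1 / 20)
  expect_lt(mean(ids), 0.45)
  expect_true(all(ids >= 1 / 6 & ids <= 1))
})
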