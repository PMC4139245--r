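# Synthetic inputs: a coarse-grained C6 shell-protein hexamer, symmetry
# perturbations, TEM-like diameter samples and alignment fixtures.
#
# The hexamer is a wedge-bevelled pseudo-atom disc ~70 Angstrom across,
# built so that edge-to-edge tiling reproduces the 67.2-Angstrom centre
# spacing of the native shell-protein lattice.  Marker pseudo-atoms carry
# the residue numbers of the interface and pore positions they emulate
# (22, 26, 40, 51, 79) under standard residue names, so selection logic is
# the same for synthetic and real structures.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Specification of the synthetic hexamer
#'
#' @param outer_radius hexagon circumradius of the body in Angstrom.  The
#'   default (35) makes the disc ~70 Angstrom across so that hexamers tile
#'   at the native 67.2 Angstrom centre spacing with edge surfaces in
#'   contact distance but free of clashes.
#' @param thickness disc thickness at the centre, Angstrom.  20 is adopted
#'   as a generic single-BMC-domain disc height.
#' @param bevel_angle total wedge taper of the rim in degrees (each face
#'   slopes by half this angle), which is what lets adjacent hexamers bend
#'   out of plane by up to the bevel angle without interpenetrating.
#' @param atoms_per_subunit approximate pseudo-atom count per subunit
#'   (controls body sampling density; markers and edge atoms are fixed).
#' @param sagitta depth (Angstrom) of the spherical-cap offset that makes
#'   the two faces inequivalent (the flatter, dimpled face is designated
#'   the concave face and is oriented outward in tube models).
#' @param pore_marker_radius radial distance of the pore-loop (residue 40)
#'   markers from the 6-fold axis, Angstrom.
#' @param marker_positions named character vector mapping residue numbers
#'   to roles; the default encodes the interface markers (22 dyad-acidic,
#'   26 dyad-contact, 51 mid-edge, 79 protruding-arm) and the pore loop
#'   (40).
#' @param seed integer seed recorded with the spec (the ideal hexamer is
#'   deterministic; the seed is carried for downstream perturbations).
#' @return object of class `hexamer_spec`.
#' @export
hexamer_spec <- function(outer_radius = 35, thickness = 20,
                         bevel_angle = 30, atoms_per_subunit = 90,
                         sagitta = 4, pore_marker_radius = 4.5,
                         marker_positions = c(`22` = "dyad-acidic",
                                              `26` = "dyad-contact",
                                              `40` = "pore-loop",
                                              `51` = "mid-edge",
                                              `79` = "protruding-arm"),
                         seed = 1L) {
  if (outer_radius <= thickness / 2)
    stop("outer_radius must exceed thickness/2", call. = FALSE)
  if (bevel_angle < 0 || bevel_angle >= 90)
    stop("bevel_angle must lie in [0, 90) degrees", call. = FALSE)
  if (atoms_per_subunit < 1) stop("atoms_per_subunit must be positive",
                                  call. = FALSE)
  pos <- as.integer(names(marker_positions))
  if (anyNA(pos) || anyDuplicated(pos))
    stop("marker positions must be distinct residue numbers", call. = FALSE)
  structure(list(outer_radius = outer_radius, thickness = thickness,
                 bevel_angle = bevel_angle,
                 atoms_per_subunit = atoms_per_subunit,
                 sagitta = sagitta,
                 pore_marker_radius = pore_marker_radius,
                 marker_positions = marker_positions, seed = seed),
            class = "hexamer_spec")
}

# marker atom table for subunit 0 (sector 0..60 degrees), in the hexamer
# mid-plane.  Positions are expressed at the default 35-Angstrom body and
# scaled with outer_radius; they are frozen so that at default spec the
# 67.2-Angstrom tiling gives dyad-contact (26) marker pairs within contact
# distance, interdigitating across the interface mid-line, and protruding
# arms (79) meeting in threes around the lattice holes without clashes.
marker_atoms <- function(spec) {
  s <- spec$outer_radius / 35
  p <- spec$pore_marker_radius
  tab <- rbind(
    data.frame(resno = 22L, resid = "ASP", name = c("CG", "OD1"),
               element = c("C", "O"),
               x = c(29.0, 30.2) * s, y = c(4.6, 5.2) * s),
    data.frame(resno = 26L, resid = "LYS", name = c("CE", "NZ"),
               element = c("C", "N"),
               x = c(31.6, 34.0) * s, y = c(1.7, 1.3) * s),
    data.frame(resno = 40L, resid = "SER", name = "N", element = "N",
               x = p * cos(pi / 6), y = p * sin(pi / 6)),
    data.frame(resno = 51L, resid = "VAL", name = "CB", element = "C",
               x = 31.3 * s, y = 7.8 * s),
    data.frame(resno = 79L, resid = "ARG",
               name = c("NE", "CZ", "NH1", "NH2"),
               element = c("N", "C", "N", "N"),
               x = c(32.2, 32.8, 33.3, 33.85) * s,
               y = c(15.7, 16.7, 17.9, 15.4) * s))
  keep <- tab$resno %in% as.integer(names(spec$marker_positions))
  tab <- tab[keep, , drop = FALSE]
  tab$z <- 0
  tab
}

# half-thickness of the wedge at radial distance r
wedge_half_thickness <- function(r, spec) {
  r0 <- 0.1 * spec$outer_radius
  h <- spec$thickness / 2 -
    pmax(0, r - r0) * tan(spec$bevel_angle / 2 * pi / 180)
  pmax(h, 0.75)
}

# spherical-cap z offset (negative: the convex bulge is on -z, the
# flatter "concave" face on +z)
dome_shift <- function(r, spec) {
  A <- spec$outer_radius * cos(pi / 6)
  -spec$sagitta * pmax(0, 1 - (r / A)^2)
}

# body + edge pseudo-atoms of subunit 0 (sector 0..60 degrees)
subunit_body <- function(spec) {
  Ro <- spec$outer_radius
  A <- Ro * cos(pi / 6)
  shells <- Ro * c(6, 12, 18, 24, 28) / 35
  dens <- spec$atoms_per_subunit / 90
  rows <- list()
  for (r in shells) {
    n <- max(2L, as.integer(round(r * (pi / 3) / 4.5 * dens)))
    phi <- ((seq_len(n) - 0.5) / n) * (pi / 3)
    zs <- if (r < 0.5 * Ro) c(-1, 1) else c(-1, 0, 1)
    h <- wedge_half_thickness(r, spec)
    for (zf in zs)
      rows[[length(rows) + 1L]] <-
        data.frame(x = r * cos(phi), y = r * sin(phi),
                   z = zf * h + dome_shift(r, spec))
  }
  # edge walls: the subunit's half of the edge centred at 0 degrees
  # (y > 0 half) and of the edge centred at 60 degrees (lower half)
  ys <- Ro * c(1.5, 6, 10.5, 15) / 35
  e0 <- cbind(A, ys)
  rot60 <- matrix(c(cos(pi / 3), sin(pi / 3), -sin(pi / 3), cos(pi / 3)),
                  2L, 2L)
  e60 <- t(rot60 %*% t(cbind(A, -ys)))
  for (edge in list(e0, e60)) {
    r <- sqrt(rowSums(edge^2))
    h <- wedge_half_thickness(r, spec)
    sh <- dome_shift(r, spec)
    for (zf in c(-1, 0, 1))
      rows[[length(rows) + 1L]] <-
        data.frame(x = edge[, 1L], y = edge[, 2L], z = zf * h + sh)
  }
  out <- do.call(rbind, rows)
  data.frame(resno = 100L + seq_len(nrow(out)), resid = "GLY",
             name = "CA", element = "C",
             x = out$x, y = out$y, z = out$z)
}

#' Generate the ideal C6 synthetic hexamer
#'
#' Builds six identical wedge-shaped pseudo-atom subunits by exact 60
#' degree rotations about z, so the result has strict 6-fold symmetry
#' ([symmetry_deviation()] of 0 to machine precision).  Subunit k occupies
#' the azimuthal sector `[60k, 60k+60)` degrees; each hexagon edge is
#' built from two adjacent subunits, with the inter-hexamer dyad of a
#' tiling falling at the subunit boundary, as in the native lattice.
#' Marker pseudo-atoms sit at the interface positions (22, 26, 51, 79 at
#' increasing distance from that boundary; 79 protruding beyond the
#' hexagonal outline) and at the pore (40, on a circle of
#' `pore_marker_radius` about the axis).
#'
#' @param spec a [hexamer_spec()].
#' @return a [structure_model()] with 6 chains (A-F) of equal atom count;
#'   the spec is attached as attribute `"hexamer_spec"`.
#' @examples
#' hx <- make_ideal_hexamer()
#' symmetry_deviation(hx, 6)
#' @export
make_ideal_hexamer <- function(spec = hexamer_spec()) {
  stopifnot(inherits(spec, "hexamer_spec"))
  mk <- marker_atoms(spec)
  if (nrow(mk) > 1L) {
    d <- as.matrix(dist(mk[, c("x", "y", "z")]))
    diag(d) <- Inf
    if (min(d) < 1)
      stop("generation error: marker atoms collide (pairwise distance < 1)",
           call. = FALSE)
  }
  sub0 <- rbind(subunit_body(spec),
                mk[, c("resno", "resid", "name", "element", "x", "y", "z")])
  chains <- LETTERS[1:6]
  parts <- lapply(0:5, function(k) {
    th <- k * pi / 3
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
    xyz <- as.matrix(sub0[, c("x", "y", "z")]) %*% t(R)
    data.frame(serial = 0L, name = sub0$name, element = sub0$element,
               resno = sub0$resno, resid = sub0$resid, chain = chains[k + 1L],
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, label = "ideal-hexamer")
  attr(model, "hexamer_spec") <- spec
  model
}

#' Perturb a hexamer with Gaussian coordinate noise
#'
#' Adds i.i.d. zero-mean Gaussian displacements (standard deviation
#' `sigma` per coordinate) to every atom - the generator's model of
#' 6-fold-symmetry breaking.  Seed-deterministic: the same seed always
#' yields the same output, and the caller's RNG state is untouched.
#'
#' @param model a [structure_model()].
#' @param sigma displacement standard deviation per coordinate, Angstrom
#'   (>= 0).
#' @param seed integer seed.
#' @return the perturbed `structure_model`.
#' @export
perturb_hexamer <- function(model, sigma, seed = 1L) {
  stopifnot(inherits(model, "structure_model"))
  if (is.na(sigma) || sigma < 0)
    stop("domain error: sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(model)
  xyz <- coords(model)
  noise <- with_seed(seed,
    matrix(rnorm(length(xyz), sd = sigma), nrow(xyz), 3L))
  set_coords(model, xyz + noise)
}

#' Draw a TEM-like diameter measurement sample
#'
#' Emulates a set of tube-diameter measurements from micrographs: `n`
#' draws from Normal(mean, sd), reported in the conventional
#' "m +/- s (n measurements)" style via [format_measurement()].
#'
#' @param mean true mean diameter, nm (> 0).
#' @param sd measurement standard deviation, nm (>= 0).
#' @param n number of measurements (>= 1).
#' @param seed integer seed.
#' @return object of class `measurement_sample`: list with `values`, `n`,
#'   `mean`, `sd` (sample statistics) and `seed`.
#' @examples
#' format_measurement(sample_diameters(20.4, 1.1, 20, seed = 7))
#' @export
sample_diameters <- function(mean, sd, n, seed = 1L) {
  if (is.na(mean) || mean <= 0) stop("domain error: mean must be positive",
                                     call. = FALSE)
  if (is.na(sd) || sd < 0) stop("domain error: sd must be non-negative",
                                call. = FALSE)
  if (is.na(n) || n < 1) stop("domain error: n must be at least 1",
                              call. = FALSE)
  values <- with_seed(seed, rnorm(n, mean, sd))
  structure(list(values = values, n = as.integer(n),
                 mean = base::mean(values),
                 sd = if (n > 1L) stats::sd(values) else 0,
                 seed = seed),
            class = "measurement_sample")
}

#' Format a measurement sample in "m +/- s (n measurements)" style
#'
#' @param sample a `measurement_sample` from [sample_diameters()].
#' @param unit unit string appended after the values.
#' @param digits decimal places for mean and sd.
#' @return a character scalar such as `"20.4 ± 1.1 nm (20 measurements)"`.
#' @export
format_measurement <- function(sample, unit = "nm", digits = 1) {
  stopifnot(inherits(sample, "measurement_sample"))
  sprintf("%.*f ± %.*f %s (%d measurements)",
          digits, sample$mean, digits, sample$sd, unit, sample$n)
}

#' @export
print.measurement_sample <- function(x, ...) {
  cat(format_measurement(x), "\n")
  invisible(x)
}

#' Write a measurement sample to TSV
#'
#' @param sample a `measurement_sample`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurement_tsv <- function(sample, path) {
  write.table(data.frame(measurement = seq_len(sample$n),
                         diameter_nm = sample$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate an aligned-FASTA alignment fixture
#'
#' Produces `n_sequences` aligned sequences of the given length: the
#' specified columns are fixed to the given residue letters across all
#' sequences, every other column is drawn uniformly from the 20-letter
#' amino-acid alphabet, and an optional fraction of the random positions
#' is gapped.
#'
#' @param n_sequences number of sequences.
#' @param length alignment length (columns).
#' @param conserved_columns named character vector: names are 1-based
#'   column indices, values single residue letters.
#' @param seed integer seed.
#' @param gap_fraction fraction of non-conserved positions replaced by
#'   gaps ("-").
#' @param path optional output file; when given the text is also written.
#' @return character vector of aligned-FASTA lines (invisibly if `path`
#'   is given).
#' @examples
#' make_alignment_fixture(6, 100, c(`26` = "K"), seed = 1)[1:2]
#' @export
make_alignment_fixture <- function(n_sequences, length,
                                   conserved_columns = character(0),
                                   seed = 1L, gap_fraction = 0,
                                   path = NULL) {
  stopifnot(n_sequences >= 1, length >= 1)
  cols <- as.integer(names(conserved_columns))
  if (base::length(conserved_columns) &&
      (anyNA(cols) || any(cols < 1L) || any(cols > length)))
    stop("domain error: conserved column index out of range", call. = FALSE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  mat <- with_seed(seed, {
    m <- matrix(sample(aa, n_sequences * length, replace = TRUE),
                n_sequences, length)
    if (gap_fraction > 0) {
      gap <- matrix(runif(n_sequences * length) < gap_fraction,
                    n_sequences, length)
      m[gap] <- "-"
    }
    m
  })
  if (base::length(cols))
    mat[, cols] <- matrix(rep(unname(unlist(conserved_columns)),
                              each = n_sequences),
                          n_sequences, base::length(cols))
  seqs <- apply(mat, 1L, paste, collapse = "")
  lines <- as.vector(rbind(sprintf(">seq%02d", seq_len(n_sequences)), seqs))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
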