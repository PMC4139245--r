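# Solvent-accessible surface area, per-residue burial upon assembly, and
# interface hot-spot ranking.
#
# The SASA engine is a Shrake-Rupley implementation with a deterministic
# generalized-spiral point set, so results are bit-reproducible at a fixed
# point count.  Areas are reported at the probe-expanded surface
# (radius + probe), the convention under which an isolated C atom with a
# 1.4-Angstrom probe has area 4*pi*(1.7+1.4)^2 ~ 120.8 Angstrom^2.

#' Compute solvent-accessible surface area
#'
#' @param model a [structure_model()].
#' @param probe_radius probe sphere radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param n_points number of deterministic sphere-sample points per atom
#'   (>= 60; default 960).  Doubling it changes reported areas by well
#'   under 1%.
#' @param include_het include HETATM atoms (default `FALSE`: protein
#'   surfaces only, heteroatoms neither contribute nor occlude).
#' @return an `area_report`: list with `per_atom` (numeric vector along
#'   the atom table), `per_residue` (data frame chain/resno/resid/area),
#'   `total`, `probe_radius`, `n_points`.
#' @examples
#' one <- structure_model(data.frame(serial = 1, name = "CA",
#'   element = "C", resno = 1, resid = "GLY", chain = "A",
#'   x = 0, y = 0, z = 0))
#' compute_sasa(one)$total  # 4*pi*(1.7+1.4)^2
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                         include_het = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (is.na(probe_radius) || probe_radius < 0)
    stop("probe_radius must be non-negative", call. = FALSE)
  if (n_points < 60)
    stop("accuracy error: n_points must be at least 60", call. = FALSE)
  a <- model$atoms
  use <- if (include_het) rep(TRUE, nrow(a)) else !a$het
  if (!any(use)) stop("no atoms selected for SASA", call. = FALSE)
  sub <- a[use, , drop = FALSE]
  per_atom_sub <- sasa_values(as.matrix(sub[, c("x", "y", "z")]),
                              sub$radius, probe_radius, n_points,
                              seq_len(nrow(sub)))
  per_atom <- numeric(nrow(a))
  per_atom[use] <- per_atom_sub
  key <- paste(a$chain, a$resno)
  keep <- use
  per_res <- aggregate_residues(a[keep, , drop = FALSE], per_atom[keep])
  structure(list(per_atom = per_atom,
                 per_residue = per_res,
                 total = sum(per_atom_sub),
                 probe_radius = probe_radius,
                 n_points = as.integer(n_points)),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf(
    "<area_report> total %.1f A^2 over %d residues (probe %.2f, %d points)\n",
    x$total, nrow(x$per_residue), x$probe_radius, x$n_points))
  invisible(x)
}

# kernel wrapper handling exactly coincident identical atoms: such a group
# is collapsed to one representative for the occlusion computation and the
# representative's area is split equally among the group (symmetric tie
# rule).
sasa_values <- function(xyz, radius, probe, n_points, subset) {
  key <- paste(xyz[, 1L], xyz[, 2L], xyz[, 3L], radius)
  if (!anyDuplicated(key)) {
    return(.sasa_kernel(xyz, radius, probe, as.integer(n_points),
                        as.integer(subset)))
  }
  grp <- match(key, key)           # representative index per atom
  reps <- which(grp == seq_along(grp))
  size <- tabulate(match(grp, reps), nbins = length(reps))
  sub_rep <- match(grp[subset], reps)
  vals <- .sasa_kernel(xyz[reps, , drop = FALSE], radius[reps], probe,
                       as.integer(n_points),
                       as.integer(unique(sub_rep)))
  lut <- numeric(length(reps))
  lut[unique(sub_rep)] <- vals
  lut[sub_rep] / size[sub_rep]
}

aggregate_residues <- function(atoms, areas) {
  key <- paste(atoms$chain, atoms$resno)
  first <- !duplicated(key)
  out <- data.frame(chain = atoms$chain[first],
                    resno = atoms$resno[first],
                    resid = atoms$resid[first],
                    area = as.numeric(tapply(areas, factor(key, unique(key)),
                                             sum)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-residue loss of accessible area upon assembly
#'
#' For every residue of a unit, Delta-ASA = ASA(residue | unit alone) -
#' ASA(residue | unit within the assembly).  This is the quantity whose
#' large values mark interface hot spots when hexamers are brought
#' together into a sheet.  Values that come out slightly negative (point
#' sampling noise) are floored at zero; the count of floored residues is
#' attached as attribute `"n_floored"`.
#'
#' @param unit a [structure_model()] - e.g. one hexamer.
#' @param assembly a `structure_model` containing the unit (same internal
#'   coordinates, RMSD < 0.1 Angstrom after superposition).
#' @param unit_selector chains of `assembly` that constitute the unit;
#'   default: the chains of assembly copy 1.
#' @param probe_radius,n_points SASA parameters, see [compute_sasa()].
#' @return data frame with columns `chain`, `resno`, `resid`,
#'   `asa_isolated`, `asa_assembly`, `delta` (all areas in Angstrom^2);
#'   chains/residues are those of the assembly subset.
#' @export
delta_asa <- function(unit, assembly, unit_selector = NULL,
                      probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(unit, "structure_model"),
            inherits(assembly, "structure_model"))
  aa <- assembly$atoms
  if (is.null(unit_selector))
    unit_selector <- unique(aa$chain[aa$copy == aa$copy[1L]])
  if (!all(unit_selector %in% aa$chain))
    stop("selection error: chain(s) ",
         paste(setdiff(unit_selector, aa$chain), collapse = ", "),
         " absent from assembly", call. = FALSE)
  idx <- which(aa$chain %in% unit_selector & !aa$het)
  ua <- unit$atoms[!unit$atoms$het, , drop = FALSE]
  if (length(idx) != nrow(ua))
    stop("selection error: assembly subset (", length(idx),
         " atoms) does not match unit (", nrow(ua), " atoms)",
         call. = FALSE)
  fit <- kabsch(as.matrix(aa[idx, c("x", "y", "z")]),
                as.matrix(ua[, c("x", "y", "z")]))
  if (fit$rmsd > 0.1)
    stop("unit does not appear in assembly with identical internal ",
         sprintf("coordinates (RMSD %.3f A)", fit$rmsd), call. = FALSE)
  iso <- compute_sasa(structure_model(ua, label = "unit"),
                      probe_radius, n_points)
  occ <- aa[!aa$het, , drop = FALSE]
  sub_in_occ <- match(idx, which(!aa$het))
  asm_atom <- sasa_values(as.matrix(occ[, c("x", "y", "z")]), occ$radius,
                          probe_radius, n_points, sub_in_occ)
  res_iso <- aggregate_residues(ua, iso$per_atom[!unit$atoms$het])
  res_asm <- aggregate_residues(aa[idx, , drop = FALSE], asm_atom)
  delta <- res_iso$area - res_asm$area
  n_floored <- sum(delta < 0)
  delta[delta < 0] <- 0
  out <- data.frame(chain = res_asm$chain, resno = res_asm$resno,
                    resid = res_asm$resid,
                    asa_isolated = res_iso$area,
                    asa_assembly = res_asm$area,
                    delta = delta, stringsAsFactors = FALSE)
  attr(out, "n_floored") <- n_floored
  out
}

#' Buried surface area between two parts
#'
#' Two-sided convention: BSA = ASA(A) + ASA(B) - ASA(A united with B),
#' i.e. the burial summed over both partners.  Symmetric in its arguments
#' (identical point sets are used either way).
#'
#' @param part_a,part_b [structure_model()] objects; chains are relabelled
#'   internally so the union is unambiguous.
#' @param probe_radius,n_points SASA parameters, see [compute_sasa()].
#' @return buried area in Angstrom^2.
#' @export
buried_surface_area <- function(part_a, part_b, probe_radius = 1.4,
                                n_points = 960) {
  both <- combine_models(list(part_a, part_b), label = "bsa-pair")
  b <- both$atoms
  cl <- .clash_kernel(as.matrix(b[, c("x", "y", "z")]), b$radius,
                      as.integer(b$copy), 0.6)
  n_min <- min(nrow(part_a$atoms), nrow(part_b$atoms))
  if (nrow(cl) > 0.5 * n_min)
    stop("likely-duplicate error: parts overlap in space (",
         nrow(cl), " clashing atom pairs)", call. = FALSE)
  asa_a <- compute_sasa(part_a, probe_radius, n_points)$total
  asa_b <- compute_sasa(part_b, probe_radius, n_points)$total
  asa_ab <- compute_sasa(both, probe_radius, n_points)$total
  asa_a + asa_b - asa_ab
}

# side-chain terminal atom used for dyad distances, by residue type
terminal_atom_name <- c(LYS = "NZ", ARG = "CZ", VAL = "CB", ASP = "CG",
                        SER = "OG", GLU = "CD", ASN = "CG", GLN = "CD")

terminal_positions <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno)
  out <- lapply(split(seq_len(nrow(atoms)), factor(key, unique(key))),
                function(i) {
    res <- atoms[i, , drop = FALSE]
    want <- terminal_atom_name[res$resid[1L]]
    hit <- if (!is.na(want)) which(res$name == want) else integer(0)
    if (length(hit) == 1L)
      return(as.numeric(res[hit, c("x", "y", "z")]))
    side <- res[!res$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
    if (nrow(side) == 0L) side <- res
    colMeans(as.matrix(side[, c("x", "y", "z")]))
  })
  do.call(rbind, out)
}

#' Rank interface hot spots by Delta-ASA with dyad proximity
#'
#' Ranks the residues buried when a hexamer joins an assembly, annotating
#' each with its distance to its own image under the 2-fold (dyad) that
#' relates adjacent hexamers.  Residues whose aspartate substitution would
#' meet its own symmetry mate (small dyad distance) are predicted to be
#' the most disruptive like-charge substitutions.
#'
#' @param hexamer a [structure_model()], the repeating unit.
#' @param assembly assembly containing the hexamer (pair or sheet
#'   context).
#' @param dyad a [rigid_transform()] of order 2 (its square must be the
#'   identity within 1e-6) relating adjacent hexamers.
#' @param context_label `"pair"` or `"sheet"`, recorded in the result.
#' @param aggregate `"max"` (default): one entry per residue number, the
#'   largest Delta-ASA over chains and the smallest dyad distance;
#'   `"none"`: one entry per (chain, residue).
#' @param probe_radius,n_points SASA parameters.
#' @return a `hotspot_ranking`: data frame with `residue` (e.g.
#'   `"ARG-79"`), `resno`, `resid`, `delta_asa`, `dyad_distance`, sorted
#'   by `delta_asa` descending (ties: residue number ascending); residues
#'   with zero Delta-ASA are omitted.
#' @export
rank_interface_hotspots <- function(hexamer, assembly, dyad,
                                    context_label = "sheet",
                                    aggregate = c("max", "none"),
                                    probe_radius = 1.4, n_points = 960) {
  aggregate <- match.arg(aggregate)
  if (!inherits(dyad, "rigid_transform"))
    stop("dyad must be a rigid_transform", call. = FALSE)
  sq <- compose_transforms(dyad, dyad)
  if (max(abs(sq$rotation - diag(3))) > 1e-6 ||
      max(abs(sq$translation)) > 1e-6)
    stop("validation error: dyad transform is not of order 2", call. = FALSE)
  d <- delta_asa(hexamer, assembly, probe_radius = probe_radius,
                 n_points = n_points)
  aa <- assembly$atoms
  sel <- unique(aa$chain[aa$copy == aa$copy[1L]])
  atoms <- aa[aa$chain %in% sel & !aa$het, , drop = FALSE]
  term <- terminal_positions(atoms)
  img <- transform_points(term, dyad)
  dyad_dist <- sqrt(rowSums((term - img)^2))
  d$dyad_distance <- dyad_dist
  d <- d[d$delta > 1e-6, , drop = FALSE]
  if (aggregate == "max" && nrow(d)) {
    sp <- split(d, d$resno)
    d <- do.call(rbind, lapply(sp, function(g)
      data.frame(chain = "*", resno = g$resno[1L], resid = g$resid[1L],
                 asa_isolated = max(g$asa_isolated),
                 asa_assembly = g$asa_assembly[which.max(g$delta)],
                 delta = max(g$delta),
                 dyad_distance = min(g$dyad_distance),
                 stringsAsFactors = FALSE)))
  }
  ord <- order(-d$delta, d$resno)
  d <- d[ord, , drop = FALSE]
  out <- data.frame(residue = paste0(d$resid, "-", d$resno),
                    resno = d$resno, resid = d$resid,
                    delta_asa = d$delta,
                    dyad_distance = d$dyad_distance,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "context") <- context_label
  class(out) <- c("hotspot_ranking", class(out))
  out
}
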