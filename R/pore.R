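# Pore-axis geometry and interface hydrogen-bond inventories.

#' Detect hydrogen bonds geometrically
#'
#' Donor-acceptor N/O pairs within `d_max`, excluding intra-residue
#' pairs, pairs at covalent range (< 2.0 Angstrom) and backbone pairs of
#' sequence-adjacent residues (1-3 neighbours across the peptide bond).
#' Hydrogen positions are not inferred: with `require_geometry` the
#' heavy-atom antecedent-donor-acceptor angle must be >= 90 degrees
#' (the antecedent is the donor's nearest covalent-range neighbour in
#' its own residue; atoms without one skip the angle test).  When both
#' atoms could donate, N is taken as donor over O; ties fall to the
#' lower serial.
#'
#' @param assembly a [structure_model()].
#' @param d_max heavy-atom donor-acceptor cutoff in Angstrom (default
#'   3.5).
#' @param require_geometry apply the antecedent angle criterion.
#' @return data frame (class `hbond_table`) with donor/acceptor chain,
#'   residue, atom, copies, `distance` and `class` (`"intra-subunit"`,
#'   `"intra-hexamer"` or `"inter-hexamer"`).
#' @export
detect_hbonds <- function(assembly, d_max = 3.5, require_geometry = FALSE) {
  stopifnot(inherits(assembly, "structure_model"))
  a <- assembly$atoms
  cand <- which(a$element %in% c("N", "O"))
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resid = character(0), donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_resid = character(0),
                      acceptor_atom = character(0),
                      donor_copy = integer(0), acceptor_copy = integer(0),
                      distance = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (length(cand) < 2L) return(structure(empty, class = c("hbond_table",
                                                           "data.frame")))
  xyz <- as.matrix(a[cand, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  pair <- which(d <= d_max & d >= 2.0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(pair) == 0L) return(structure(empty, class = c("hbond_table",
                                                          "data.frame")))
  i <- cand[pair[, 1L]]; j <- cand[pair[, 2L]]
  same_res <- a$chain[i] == a$chain[j] & a$resno[i] == a$resno[j] &
    a$copy[i] == a$copy[j]
  bb <- c("N", "CA", "C", "O")
  seq_adj <- a$chain[i] == a$chain[j] & a$copy[i] == a$copy[j] &
    abs(a$resno[i] - a$resno[j]) == 1L &
    a$name[i] %in% bb & a$name[j] %in% bb
  keep <- !same_res & !seq_adj
  i <- i[keep]; j <- j[keep]
  dd <- d[pair][keep]
  if (length(i) == 0L) return(structure(empty, class = c("hbond_table",
                                                         "data.frame")))
  # donor/acceptor roles: N over O, then lower serial
  pref <- function(k) ifelse(a$element[k] == "N", 0L, 1L)
  swap <- pref(i) > pref(j) | (pref(i) == pref(j) & i > j)
  don <- ifelse(swap, j, i); acc <- ifelse(swap, i, j)
  if (require_geometry) {
    ok <- vapply(seq_along(don), function(k) {
      dn <- don[k]
      res <- which(a$chain == a$chain[dn] & a$resno == a$resno[dn] &
                     a$copy == a$copy[dn])
      res <- setdiff(res, dn)
      if (!length(res)) return(TRUE)
      p <- as.numeric(a[dn, c("x", "y", "z")])
      q <- as.matrix(a[res, c("x", "y", "z"), drop = FALSE])
      dres <- sqrt(rowSums(sweep(q, 2L, p)^2))
      if (min(dres) > 2.0) return(TRUE)   # no covalent antecedent
      ante <- q[which.min(dres), ]
      v1 <- ante - p
      v2 <- as.numeric(a[acc[k], c("x", "y", "z")]) - p
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      cosang <= 0   # angle >= 90 degrees
    }, logical(1))
    don <- don[ok]; acc <- acc[ok]; dd <- dd[ok]
  }
  cls <- ifelse(a$copy[don] != a$copy[acc], "inter-hexamer",
                ifelse(a$chain[don] != a$chain[acc], "intra-hexamer",
                       "intra-subunit"))
  out <- data.frame(donor_chain = a$chain[don], donor_resno = a$resno[don],
                    donor_resid = a$resid[don], donor_atom = a$name[don],
                    acceptor_chain = a$chain[acc],
                    acceptor_resno = a$resno[acc],
                    acceptor_resid = a$resid[acc],
                    acceptor_atom = a$name[acc],
                    donor_copy = a$copy[don], acceptor_copy = a$copy[acc],
                    distance = dd, class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$donor_chain, out$donor_resno, out$acceptor_chain,
                   out$acceptor_resno, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hbond_table", "data.frame"))
}

#' Compare two hydrogen-bond inventories
#'
#' Bonds are keyed by (donor residue, acceptor residue, class); the
#' result lists keys found in both reports, only in the first, or only
#' in the second - the native-versus-mutant interface comparison.
#'
#' @param report_a,report_b `hbond_table` data frames from
#'   [detect_hbonds()] (or any data frame with the same residue-level
#'   columns).
#' @return data frame with `donor`, `acceptor`, `class`, `status`
#'   (`"shared"`, `"only_a"`, `"only_b"`), sorted by key.
#' @export
compare_interfaces <- function(report_a, report_b) {
  keyify <- function(r) {
    if (nrow(r) == 0L) return(character(0))
    unique(paste(paste0(r$donor_resid, "-", r$donor_resno),
                 paste0(r$acceptor_resid, "-", r$acceptor_resno),
                 r$class, sep = "|"))
  }
  ka <- keyify(report_a); kb <- keyify(report_b)
  keys <- sort(union(ka, kb))
  if (!length(keys))
    return(data.frame(donor = character(0), acceptor = character(0),
                      class = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(donor = parts[, 1L], acceptor = parts[, 2L],
             class = parts[, 3L],
             status = ifelse(keys %in% ka & keys %in% kb, "shared",
                             ifelse(keys %in% ka, "only_a", "only_b")),
             stringsAsFactors = FALSE)
}

#' Profile the central pore along the symmetry axis
#'
#' Samples the pore radius along the hexamer's 6-fold axis: at each
#' axial position the radius is the smallest clearance to any atom
#' (distance from the atom centre to the axis point minus the atom's
#' vdW radius, floored at 0).  Also reports the three cross separations
#' between the designated pore-loop atoms of opposite subunits (chain k
#' versus chain k+3, in rotational chain order): for a strict C6 hexamer
#' all three are equal, and their spread (anisotropy) diagnoses
#' symmetry breaking at the pore.
#'
#' @param hexamer a [structure_model()] with 6 chains.
#' @param axis a `symmetry_fit` from [fit_symmetry_axis()], or `NULL` to
#'   fit a C6 axis internally.
#' @param step axial sampling step in Angstrom.
#' @param loop_atom_spec `(residue number, atom name)` of the pore-loop
#'   atom; default `(40, "N")`, the main-chain amide of the pore loop.
#' @return a `pore_profile`: list with `samples` (data frame z/radius),
#'   `min_radius`, `cross_separations` (named length-3 vector),
#'   `anisotropy` (max - min separation).
#' @examples
#' pp <- pore_profile(make_ideal_hexamer())
#' pp$cross_separations
#' @export
pore_profile <- function(hexamer, axis = NULL, step = 0.5,
                         loop_atom_spec = c(40, "N")) {
  stopifnot(inherits(hexamer, "structure_model"))
  a <- hexamer$atoms
  chains <- unique(a$chain)
  if (length(chains) != 6L)
    stop("pore profiling requires a 6-chain hexamer", call. = FALSE)
  if (is.null(axis)) axis <- fit_symmetry_axis(hexamer, 6L)
  u <- axis$axis_direction
  ctr <- axis$center
  xyz <- coords(hexamer)
  rel <- sweep(xyz, 2L, ctr)
  t_along <- as.numeric(rel %*% u)
  zs <- seq(min(t_along), max(t_along), by = step)
  radial <- function(z0) {
    p <- ctr + z0 * u
    max(0, min(sqrt(rowSums(sweep(xyz, 2L, p)^2)) - a$radius))
  }
  radii <- vapply(zs, radial, numeric(1))
  resno <- as.integer(loop_atom_spec[[1L]])
  aname <- as.character(loop_atom_spec[[2L]])
  loop <- lapply(chains, function(ch) {
    hit <- which(a$chain == ch & a$resno == resno & a$name == aname)
    if (length(hit) != 1L)
      stop("selection error: pore-loop atom ", aname, " of residue ",
           resno, " missing (or ambiguous) in chain ", ch, call. = FALSE)
    xyz[hit, ]
  })
  sep <- vapply(1:3, function(k)
    sqrt(sum((loop[[k]] - loop[[k + 3L]])^2)), numeric(1))
  names(sep) <- paste0(chains[1:3], "-", chains[4:6])
  structure(list(samples = data.frame(z = zs, radius = radii),
                 min_radius = min(radii),
                 cross_separations = sep,
                 anisotropy = max(sep) - min(sep),
                 axis = axis,
                 loop_atom = list(resno = resno, name = aname)),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("<pore_profile> min radius %.2f A; cross separations %s A\n",
              x$min_radius,
              paste(sprintf("%.2f", x$cross_separations), collapse = "/")))
  invisible(x)
}

#' Test whether a probe fits through the pore
#'
#' Marks each axial sample pass/fail against a probe radius and states
#' whether an uninterrupted passing corridor spans the profiled range -
#' i.e. whether a substrate-sized molecule could traverse the pore.
#'
#' @param profile a `pore_profile` from [pore_profile()].
#' @param probe_radius probe radius in Angstrom (>= 0).
#' @return data frame `z`, `radius`, `pass` with attribute `"summary"`:
#'   list (`continuous`, `fraction_pass`, `probe_radius`).
#' @export
probe_fit <- function(profile, probe_radius) {
  stopifnot(inherits(profile, "pore_profile"))
  if (is.na(probe_radius) || probe_radius < 0)
    stop("domain error: probe radius must be non-negative", call. = FALSE)
  out <- profile$samples
  out$pass <- out$radius >= probe_radius
  attr(out, "summary") <- list(continuous = all(out$pass),
                               fraction_pass = mean(out$pass),
                               probe_radius = probe_radius)
  out
}
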