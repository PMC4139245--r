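# High-level analysis entry points: each builds the needed context,
# runs the module computations and (optionally) writes machine-readable
# TSV/JSON reports with a provenance block.

provenance <- function(params) {
  list(package = "hexshell",
       version = as.character(utils::packageVersion("hexshell")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       parameters = params)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Place a hexamer in its tiling context
#'
#' Builds the assembly used for burial calculations: the hexamer plus
#' either all six in-plane lattice neighbours (`"sheet"`, matching the
#' bringing-together of hexamers into a sheet of molecules) or a single
#' neighbour (`"pair"`).  Neighbours sit at the given centre spacing
#' along the hexagon edge-normal directions; the hexamer's symmetry axis
#' is assumed along z.
#'
#' @param hexamer a [structure_model()].
#' @param spacing centre spacing in Angstrom (default 67.2).
#' @param context `"sheet"` or `"pair"`.
#' @return a `structure_model` assembly; copy 1 is the central hexamer
#'   with its original chain labels preserved in order.
#' @export
hexamer_context <- function(hexamer, spacing = 67.2,
                            context = c("sheet", "pair")) {
  context <- match.arg(context)
  angles <- if (context == "sheet") (0:5) * 60 else 0
  copies <- c(list(hexamer),
              lapply(angles, function(th) {
                t <- c(cos(th * pi / 180), sin(th * pi / 180), 0) * spacing
                apply_transform(hexamer, rigid_transform(diag(3), t))
              }))
  combine_models(copies, label = paste0("hexamer-", context))
}

#' The dyad relating two adjacent hexamers
#'
#' For hexamers related by a lattice translation, the 2-fold axis lies
#' at the interface midpoint, parallel to the hexamer symmetry axes.
#'
#' @param center1,center2 centres of the two hexamers.
#' @param axis direction of the hexamer symmetry axis (default z).
#' @return a [rigid_transform()] of order 2.
#' @export
interface_dyad <- function(center1, center2, axis = c(0, 0, 1)) {
  axis_rotation(axis, 180, (center1 + center2) / 2)
}

#' Interface burial report with mutation-design summary
#'
#' Runs the sheet (or pair) burial analysis on a hexamer: per-residue
#' Delta-ASA, hot-spot ranking with dyad distances, and a ranking of
#' candidate aspartate substitutions by predicted disruptiveness
#' (largest burial closest to the dyad first).  With no structure given,
#' the synthetic ideal hexamer is analysed.
#'
#' @param structure a [structure_model()] hexamer or `NULL` for the
#'   synthetic default.
#' @param spacing hexamer centre spacing in Angstrom.
#' @param context `"sheet"` (default) or `"pair"`.
#' @param probe_radius,n_points SASA parameters.
#' @param output_dir when given, writes `delta_asa.tsv`,
#'   `hotspots.tsv` and `interface_report.json` there.
#' @return list with `delta_asa`, `hotspots`, `mutation_design`,
#'   `totals` and `provenance`.
#' @export
interface_report <- function(structure = NULL, spacing = 67.2,
                             context = "sheet", probe_radius = 1.4,
                             n_points = 960, output_dir = NULL) {
  hx <- if (is.null(structure)) make_ideal_hexamer() else structure
  asm <- hexamer_context(hx, spacing, context)
  ctr <- model_center(hx)
  dyad <- interface_dyad(ctr, ctr + c(spacing, 0, 0))
  hot <- rank_interface_hotspots(hx, asm, dyad, context_label = context,
                                 probe_radius = probe_radius,
                                 n_points = n_points)
  das <- delta_asa(hx, asm, probe_radius = probe_radius,
                   n_points = n_points)
  md <- hot[order(-hot$delta_asa / pmax(hot$dyad_distance, 1)), ,
            drop = FALSE]
  md$note <- ifelse(md$dyad_distance < 6,
                    "substitution meets its own symmetry mate at the dyad",
                    "far from the dyad; like-charge clash unlikely")
  totals <- list(unit_total_asa = compute_sasa(hx, probe_radius,
                                               n_points)$total,
                 unit_buried = sum(das$delta))
  out <- list(delta_asa = das, hotspots = hot, mutation_design = md,
              totals = totals,
              provenance = provenance(list(spacing = spacing,
                                           context = context,
                                           probe_radius = probe_radius,
                                           n_points = n_points)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(das, file.path(output_dir, "delta_asa.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(hot), file.path(output_dir, "hotspots.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_report(list(totals = totals,
                           hotspots = as.data.frame(hot),
                           mutation_design = as.data.frame(md),
                           provenance = out$provenance),
                      file.path(output_dir, "interface_report.json"))
  }
  out
}

#' Build and validate a nanotube model
#'
#' Constructs the requested architecture from a hexamer (synthetic by
#' default), validates it with [clash_check()] and
#' [contact_preservation()], and optionally writes the PDB model plus a
#' geometry JSON embedding the validation results.
#'
#' @param mode `"ring"` or `"helix"`.
#' @param n_per_turn hexamers per turn.
#' @param spacing centre spacing in Angstrom.
#' @param n_turns_or_rings rings (ring mode) or turns per strand
#'   (helix).
#' @param n_starts helical strand count.
#' @param pitch helix pitch override in Angstrom (`NULL`: close-packed
#'   default).
#' @param hexamer a [structure_model()] or `NULL` for the synthetic
#'   default.
#' @param output_dir when given, writes `tube.pdb` and `geometry.json`.
#' @return list with `model`, `geometry`, `clashes`,
#'   `contact_preservation`, `subunit_count` and `provenance`.
#' @export
build_models <- function(mode = "ring", n_per_turn = 12L, spacing = 67.2,
                         n_turns_or_rings = 3L, n_starts = 2L,
                         pitch = NULL, hexamer = NULL,
                         output_dir = NULL) {
  hx <- if (is.null(hexamer)) make_ideal_hexamer() else hexamer
  spec <- tube_spec(mode, n_per_turn, spacing, n_turns_or_rings,
                    n_starts, pitch)
  model <- if (mode == "ring") build_ring_tube(hx, spec)
           else build_helical_tube(hx, spec)
  geom <- attr(model, "geometry")
  clashes <- clash_check(model)
  cp <- contact_preservation(model)
  n_subunits <- length(unique(model$atoms$chain))
  out <- list(model = model, geometry = geom, clashes = clashes,
              contact_preservation = cp, subunit_count = n_subunits,
              provenance = provenance(list(mode = mode,
                                           n_per_turn = n_per_turn,
                                           spacing = spacing,
                                           n_turns_or_rings =
                                             n_turns_or_rings,
                                           n_starts = n_starts,
                                           pitch = pitch)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_structure(model, file.path(output_dir, "tube.pdb"))
    gj <- unclass(geom)
    gj$diameter_nm <- as.list(geom$diameter_nm)
    write_json_report(list(geometry = gj,
                           subunit_count = n_subunits,
                           n_clashes = nrow(clashes),
                           contact_preservation = cp,
                           provenance = out$provenance),
                      file.path(output_dir, "geometry.json"))
  }
  out
}

#' Symmetry and pore report for a hexamer
#'
#' Fits the 6-fold axis, scores the symmetry deviation, profiles the
#' pore and reports the three pore-loop cross separations, flagging
#' anisotropy (max - min separation above the threshold) - the
#' signature of a symmetry-broken pore.
#'
#' @param structure a [structure_model()] hexamer.
#' @param order rotational order (default 6).
#' @param anisotropy_threshold flag threshold in Angstrom (default 0.5).
#' @param output_dir when given, writes `symmetry_report.json`.
#' @return list with `fit`, `deviation`, `pore`, `anisotropy_flag`,
#'   `provenance`.
#' @export
symmetry_report <- function(structure, order = 6L,
                            anisotropy_threshold = 0.5,
                            output_dir = NULL) {
  fit <- fit_symmetry_axis(structure, order)
  pp <- pore_profile(structure, axis = if (order == 6L) fit else NULL)
  out <- list(fit = fit, deviation = fit$deviation_rmsd, pore = pp,
              anisotropy_flag = pp$anisotropy > anisotropy_threshold,
              provenance = provenance(list(order = order,
                                           anisotropy_threshold =
                                             anisotropy_threshold)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_json_report(
      list(axis_direction = fit$axis_direction, center = fit$center,
           order = fit$order, deviation_rmsd = fit$deviation_rmsd,
           per_chain_rmsd = as.list(fit$per_chain_rmsd),
           cross_separations = as.list(pp$cross_separations),
           min_pore_radius = pp$min_radius,
           anisotropy = pp$anisotropy,
           anisotropy_flag = out$anisotropy_flag,
           provenance = out$provenance),
      file.path(output_dir, "symmetry_report.json"))
  }
  out
}
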