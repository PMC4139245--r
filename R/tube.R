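# Nanotube architectures: even-N ring stacks with inter-hexamer wedge
# tilt, and multi-start helical wraps of the hexagonal sheet.
#
# Rolling a hexagonal sheet of N hexamers per turn bends adjacent
# hexamers out of plane by the tilt 360/N (the polygon exterior angle);
# the corresponding interior angle is (N-2)*180/N.  For N = 12 this is
# the 150 degree / 30 degree geometry that the wedge-bevelled hexamer
# edge accommodates without distortion.

#' Specification of a nanotube model
#'
#' @param mode `"ring"` (stacked closed rings with interdigitated
#'   vertices; requires even `n_per_turn`) or `"helix"` (multi-start
#'   helical wrap with hexamer edges approximately parallel to the tube
#'   axis).
#' @param n_per_turn hexamers per turn (>= 3; even for ring mode).
#' @param spacing hexamer centre spacing in Angstrom (default 67.2).
#' @param n_turns_or_rings number of rings (ring mode) or turns per
#'   strand (helix mode).
#' @param n_starts number of interleaved helical strands (helix only,
#'   default 2).
#' @param pitch helix pitch per strand in Angstrom; default
#'   `n_starts * spacing * sqrt(3)/2` (close-packed rows), overridable
#'   (e.g. 138 to reproduce a relaxed two-hexamer pitch).
#' @param thickness_estimate hexamer disc thickness (Angstrom) used for
#'   the outer/lumen diameter conventions.
#' @param diameter_convention which diameter to treat as "the" diameter
#'   in summaries: `"centerline"`, `"outer"` or `"lumen"`; all three are
#'   always reported.
#' @return object of class `tube_spec`.
#' @export
tube_spec <- function(mode = c("ring", "helix"), n_per_turn = 12L,
                      spacing = 67.2, n_turns_or_rings = 3L,
                      n_starts = 2L, pitch = NULL,
                      thickness_estimate = 20,
                      diameter_convention = c("centerline", "outer",
                                              "lumen")) {
  mode <- match.arg(mode)
  diameter_convention <- match.arg(diameter_convention)
  if (is.na(n_per_turn) || n_per_turn < 3)
    stop("domain error: n_per_turn must be at least 3", call. = FALSE)
  if (mode == "ring" && n_per_turn %% 2 != 0)
    stop("even-constraint error: a ring tube interdigitates the sheet ",
         "vertices, which requires an even number of hexamers per turn",
         call. = FALSE)
  if (is.na(spacing) || spacing <= 0)
    stop("spacing must be positive", call. = FALSE)
  if (n_turns_or_rings < 1)
    stop("domain error: need at least one ring/turn", call. = FALSE)
  if (mode == "helix" && n_starts < 1)
    stop("domain error: n_starts must be at least 1", call. = FALSE)
  if (!is.null(pitch) && (is.na(pitch) || pitch <= 0))
    stop("domain error: pitch override must be positive", call. = FALSE)
  structure(list(mode = mode, n_per_turn = as.integer(n_per_turn),
                 spacing = spacing,
                 n_turns_or_rings = as.integer(n_turns_or_rings),
                 n_starts = as.integer(n_starts), pitch = pitch,
                 thickness_estimate = thickness_estimate,
                 diameter_convention = diameter_convention),
            class = "tube_spec")
}

#' Closed-form geometry of an N-hexamer ring
#'
#' For `n_per_turn` hexamers per turn at a given centre spacing:
#' interior angle (n-2)*180/n, inter-hexamer tilt 360/n, centreline
#' radius spacing / (2 sin(180/n)).  Diameters are reported in nm under
#' all three conventions (centreline; outer = centreline + thickness;
#' lumen = centreline - thickness) with the convention flagged - a
#' TEM wall-to-wall measurement is not necessarily any one of them.
#'
#' @param n_per_turn hexamers per turn (>= 3).
#' @param spacing centre spacing in Angstrom.
#' @param thickness_estimate hexamer thickness in Angstrom for the
#'   outer/lumen conventions.
#' @return a `tube_geometry`: list with `interior_angle`, `tilt`
#'   (degrees), `centerline_radius` (Angstrom), `diameter_nm` (named
#'   vector: centerline, outer, lumen).
#' @examples
#' g <- ring_geometry(12)
#' c(g$interior_angle, g$tilt)  # 150, 30
#' @export
ring_geometry <- function(n_per_turn, spacing = 67.2,
                          thickness_estimate = 20) {
  if (is.na(n_per_turn) || n_per_turn < 3)
    stop("domain error: n_per_turn must be at least 3", call. = FALSE)
  n <- n_per_turn
  r <- spacing / (2 * sin(pi / n))
  structure(list(n_per_turn = as.integer(n), spacing = spacing,
                 interior_angle = (n - 2) * 180 / n,
                 tilt = 360 / n,
                 centerline_radius = r,
                 diameter_nm = c(centerline = 2 * r / 10,
                                 outer = (2 * r + thickness_estimate) / 10,
                                 lumen = (2 * r - thickness_estimate) / 10)),
            class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf(
    "<tube_geometry> n=%d: interior %.1f deg, tilt %.1f deg, R %.1f A\n",
    x$n_per_turn, x$interior_angle, x$tilt, x$centerline_radius))
  cat(sprintf("  diameter (nm): centerline %.1f | outer %.1f | lumen %.1f\n",
              x$diameter_nm[["centerline"]], x$diameter_nm[["outer"]],
              x$diameter_nm[["lumen"]]))
  if (!is.null(x$pitch))
    cat(sprintf("  helix: %d start(s), pitch %.1f A, rise/hexamer %.2f A\n",
                x$n_starts, x$pitch, x$rise_per_hexamer))
  invisible(x)
}

# place hexamer copies on a cylinder: one rigid transform per site.
# theta in degrees; psi rotates the hexamer in its tangent plane; the
# hexamer's +z (concave face) is mapped onto the outward radial vector.
tube_place <- function(hexamer, radius, theta, z, psi = 0) {
  lapply(seq_along(theta), function(i) {
    th <- theta[i] * pi / 180
    u_t <- c(-sin(th), cos(th), 0)
    u_r <- c(cos(th), sin(th), 0)
    M <- cbind(u_t, c(0, 0, 1), u_r)      # local (x, y, z) -> global
    ps <- psi * pi / 180
    Rz <- matrix(c(cos(ps), sin(ps), 0, -sin(ps), cos(ps), 0, 0, 0, 1),
                 3L, 3L)
    apply_transform(hexamer,
                    rigid_transform(M %*% Rz,
                                    radius * u_r + c(0, 0, z[i])))
  })
}

#' Build a ring-stack nanotube
#'
#' Each ring holds `n_per_turn` hexamers at equal azimuthal steps on the
#' centreline circle, every hexamer's 6-fold axis radial with the
#' concave face outward; successive rings are offset azimuthally by half
#' a step (vertex interdigitation - whence the even-N constraint) and
#' axially by spacing*sqrt(3)/2, so packing within and between rings is
#' equivalent.  Adjacent in-ring centres are exactly `spacing` apart and
#' neighbouring hexamer axes meet at the tilt angle 360/n.
#'
#' @param hexamer a [structure_model()] with its 6-fold axis along z
#'   (e.g. from [make_ideal_hexamer()]).
#' @param spec a [tube_spec()] with `mode = "ring"`.
#' @return a `structure_model` assembly; attributes `"centers"` and
#'   `"geometry"` carry the site centres and the [ring_geometry()].
#' @examples
#' tube <- build_ring_tube(make_ideal_hexamer(),
#'                         tube_spec("ring", 12, n_turns_or_rings = 1))
#' @export
build_ring_tube <- function(hexamer, spec = tube_spec("ring", 12L)) {
  stopifnot(inherits(hexamer, "structure_model"),
            inherits(spec, "tube_spec"))
  if (spec$mode != "ring") stop("spec mode must be 'ring'", call. = FALSE)
  n <- spec$n_per_turn
  geom <- ring_geometry(n, spec$spacing, spec$thickness_estimate)
  step <- 360 / n
  rise <- spec$spacing * sqrt(3) / 2
  site <- expand.grid(k = seq_len(n) - 1L,
                      ring = seq_len(spec$n_turns_or_rings) - 1L)
  theta <- (site$k + (site$ring %% 2) / 2) * step
  z <- site$ring * rise
  copies <- tube_place(hexamer, geom$centerline_radius, theta, z)
  out <- combine_models(copies, label = sprintf("ring-tube-n%d", n))
  th <- theta * pi / 180
  attr(out, "centers") <- cbind(x = geom$centerline_radius * cos(th),
                                y = geom$centerline_radius * sin(th),
                                z = z)
  attr(out, "geometry") <- geom
  out
}

#' Build a multi-start helical nanotube
#'
#' Rolls the hexagonal sheet the alternative way, with hexamer edges
#' approximately parallel to the tube axis.  The sheet (strand step
#' `a1 = (s, 0)`, row step `a2 = (s/2, h)` with inter-row spacing
#' `h = pitch/n_starts`) is wrapped isometrically about the cylinder
#' whose circumference is the wrap vector `W = n a1 - n_starts a2`:
#' travelling `n` hexamers along a strand comes back around the tube
#' `n_starts` rows up, which is exactly the multi-start identification.
#' Every in-sheet neighbour relationship (and therefore every edge
#' contact) is preserved; bending only shortens centre distances by the
#' arc-to-chord correction.  The strands are the sheet rows.
#'
#' The nominal descriptors (`pitch`, `rise_per_hexamer = pitch/n`) are
#' reported verbatim in the geometry; the realised helix is slightly
#' different (`measured_per_turn`, `measured_rise`, also reported)
#' because an inextensible sheet cannot wrap with both the azimuthal
#' step and the rise held exactly at their nominal values.
#'
#' @param hexamer a [structure_model()] with its 6-fold axis along z.
#' @param spec a [tube_spec()] with `mode = "helix"`; `pitch = NULL`
#'   uses close-packed rows (`h = spacing*sqrt(3)/2`), an override such
#'   as 138 Angstrom relaxes the rows (h = 69 for two starts).
#' @param psi in-tangent-plane rotation of each hexamer in degrees;
#'   `NULL` (default) uses the sheet orientation carried through the
#'   wrap.
#' @return a `structure_model` assembly with `"centers"` and
#'   `"geometry"` attributes.
#' @examples
#' tube <- build_helical_tube(make_ideal_hexamer(),
#'   tube_spec("helix", 10, n_turns_or_rings = 1, n_starts = 2,
#'             pitch = 138))
#' @export
build_helical_tube <- function(hexamer,
                               spec = tube_spec("helix", 10L,
                                                n_turns_or_rings = 2L,
                                                pitch = 138),
                               psi = NULL) {
  stopifnot(inherits(hexamer, "structure_model"),
            inherits(spec, "tube_spec"))
  if (spec$mode != "helix") stop("spec mode must be 'helix'", call. = FALSE)
  n <- spec$n_per_turn
  m <- spec$n_starts
  s <- spec$spacing
  pitch <- if (is.null(spec$pitch)) m * s * sqrt(3) / 2 else spec$pitch
  h <- pitch / m
  a1 <- c(s, 0)
  a2 <- c(s / 2, h)
  W <- n * a1 - m * a2
  wlen <- sqrt(sum(W^2))
  w_hat <- W / wlen
  w_perp <- c(-W[2L], W[1L]) / wlen      # a1 . w_perp > 0 (rise up)
  radius <- wlen / (2 * pi)
  if (is.null(psi)) psi <- -atan2(W[2L], W[1L]) * 180 / pi
  ks <- seq_len(spec$n_turns_or_rings * n) - 1L
  site <- expand.grid(k = ks, start = seq_len(m) - 1L)
  p <- cbind(site$k * a1[1L] + site$start * a2[1L],
             site$k * a1[2L] + site$start * a2[2L])
  theta <- 360 * (p %*% w_hat) / wlen
  z <- as.numeric(p %*% w_perp)
  geom <- ring_geometry(n, s, spec$thickness_estimate)
  geom$mode <- "helix"
  geom$n_starts <- m
  geom$pitch <- pitch
  geom$rise_per_hexamer <- pitch / n
  geom$centerline_radius <- radius
  geom$diameter_nm <- c(centerline = 2 * radius / 10,
                        outer = (2 * radius +
                                   spec$thickness_estimate) / 10,
                        lumen = (2 * radius -
                                   spec$thickness_estimate) / 10)
  step_theta <- 360 * sum(a1 * w_hat) / wlen
  geom$measured_per_turn <- 360 / step_theta
  geom$measured_rise <- sum(a1 * w_perp)
  copies <- tube_place(hexamer, radius, as.numeric(theta), z, psi)
  out <- combine_models(copies,
                        label = sprintf("helical-tube-n%d-%dstart", n, m))
  th <- as.numeric(theta) * pi / 180
  attr(out, "centers") <- cbind(x = radius * cos(th),
                                y = radius * sin(th), z = z)
  attr(out, "geometry") <- geom
  out
}

#' Detect steric clashes between assembly copies
#'
#' Reports atom pairs from different hexamer copies closer than
#' `overlap_fraction` times the sum of their vdW radii.  An empty result
#' means the assembly has no interpenetrating surfaces.
#'
#' @param assembly a [structure_model()] with at least 2 chains; copies
#'   are taken from the `copy` column (per-chain if absent).
#' @param overlap_fraction fraction of the radius sum defining a clash
#'   (default 0.6).
#' @return data frame with one row per clashing pair: atom serials,
#'   copies, distance and threshold.
#' @export
clash_check <- function(assembly, overlap_fraction = 0.6) {
  stopifnot(inherits(assembly, "structure_model"))
  a <- assembly$atoms
  if (length(unique(a$chain)) < 2L)
    stop("assembly must have at least 2 chains", call. = FALSE)
  cp <- if (length(unique(a$copy)) > 1L) a$copy
        else match(a$chain, unique(a$chain))
  hits <- .clash_kernel(as.matrix(a[, c("x", "y", "z")]), a$radius,
                        as.integer(cp), overlap_fraction)
  i <- hits[, 1L]; j <- hits[, 2L]
  data.frame(serial_i = a$serial[i], serial_j = a$serial[j],
             copy_i = cp[i], copy_j = cp[j],
             distance = hits[, 3L],
             threshold = overlap_fraction * (a$radius[i] + a$radius[j]))
}

#' Fraction of adjacent hexamer pairs keeping a marker contact
#'
#' Adjacency is derived from copy centres (pairs closer than 1.25 times
#' the minimum centre distance); a pair preserves the contact when the
#' closest distance between its copies' marker-residue atoms is within
#' the cutoff.  A hexagonally tiled sheet at native spacing scores 1.0;
#' so must any tube model that maintains the key inter-hexamer
#' interaction while bending.
#'
#' @param assembly a [structure_model()] with >= 2 copies.
#' @param marker_residue residue number of the contact marker (default
#'   26, the dyad-contact position).
#' @param contact_cutoff contact distance in Angstrom (default 6).
#' @return fraction in `[0, 1]`.
#' @export
contact_preservation <- function(assembly, marker_residue = 26L,
                                 contact_cutoff = 6.0) {
  stopifnot(inherits(assembly, "structure_model"))
  a <- assembly$atoms
  copies <- sort(unique(a$copy))
  if (length(copies) < 2L)
    stop("assembly must contain at least two hexamer copies", call. = FALSE)
  if (!any(a$resno == marker_residue))
    stop("selection error: marker residue ", marker_residue,
         " absent from assembly", call. = FALSE)
  ctr <- model_center(assembly, by_copy = TRUE)
  d <- as.matrix(dist(ctr))
  diag(d) <- Inf
  adj <- which(d < 1.25 * min(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(adj) == 0L) return(NaN)
  mk <- lapply(copies, function(cc)
    as.matrix(a[a$copy == cc & a$resno == marker_residue,
                c("x", "y", "z"), drop = FALSE]))
  ok <- vapply(seq_len(nrow(adj)), function(r) {
    A <- mk[[adj[r, 1L]]]; B <- mk[[adj[r, 2L]]]
    cross <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") -
                    2 * tcrossprod(A, B))
    min(cross) <= contact_cutoff
  }, logical(1))
  mean(ok)
}
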