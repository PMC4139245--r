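# Planar hexagonal sheet construction and tiling-dimensionality
# classification.

#' Specification of a hexagonal sheet
#'
#' @param spacing nearest-neighbour centre distance in Angstrom (default
#'   67.2, the native shell-protein lattice spacing).
#' @param rows,cols lattice extent (>= 1 each).
#' @return object of class `sheet_spec`.
#' @export
sheet_spec <- function(spacing = 67.2, rows = 3L, cols = 3L) {
  if (is.na(spacing) || spacing <= 0)
    stop("spacing must be positive", call. = FALSE)
  if (rows < 1 || cols < 1)
    stop("domain error: rows and cols must be at least 1", call. = FALSE)
  structure(list(spacing = spacing, rows = as.integer(rows),
                 cols = as.integer(cols), lattice_type = "hexagonal"),
            class = "sheet_spec")
}

sheet_centers <- function(spec) {
  s <- spec$spacing
  g <- expand.grid(col = seq_len(spec$cols) - 1L,
                   row = seq_len(spec$rows) - 1L)
  cbind(x = (g$col + (g$row %% 2) / 2) * s,
        y = g$row * s * sqrt(3) / 2,
        z = 0)
}

#' Build a hexagonally tiled sheet of hexamers
#'
#' Places `rows * cols` copies of the hexamer on a hexagonal lattice
#' (row offset spacing/2, row separation spacing*sqrt(3)/2) so every
#' nearest-neighbour centre distance equals the spacing exactly.  The
#' hexamer's symmetry axis is assumed to lie along z (normal to the
#' sheet plane), as produced by [make_ideal_hexamer()]; fit and re-orient
#' with [fit_symmetry_axis()] first for arbitrary input.
#'
#' @param hexamer a [structure_model()].
#' @param spec a [sheet_spec()].
#' @return a `structure_model` assembly (one `copy` per lattice site)
#'   with the centre matrix attached as attribute `"centers"`.  A 1x1
#'   sheet returns the hexamer itself.
#' @examples
#' sheet <- build_sheet(make_ideal_hexamer(), sheet_spec(67.2, 2, 2))
#' @export
build_sheet <- function(hexamer, spec = sheet_spec()) {
  stopifnot(inherits(hexamer, "structure_model"),
            inherits(spec, "sheet_spec"))
  ctr <- sheet_centers(spec)
  if (nrow(ctr) == 1L) {
    attr(hexamer, "centers") <- ctr
    return(hexamer)
  }
  base <- model_center(hexamer)
  copies <- lapply(seq_len(nrow(ctr)), function(i)
    apply_transform(hexamer, rigid_transform(diag(3), ctr[i, ])))
  out <- combine_models(copies, label = "sheet")
  attr(out, "centers") <- sweep(ctr, 2L, base, "+")
  attr(out, "spacing") <- spec$spacing
  out
}

#' Classify tiling dimensionality of a set of centres
#'
#' Returns the rank of the span of nearest-neighbour difference vectors:
#' 0 for a single centre, 1 for a strip (one lattice direction), 2 for a
#' sheet.  Neighbours are pairs within `(1 + spacing_tolerance)` times
#' the minimum pairwise distance.
#'
#' @param centers numeric matrix (one row per centre) or list of
#'   3-vectors.
#' @param spacing_tolerance fractional tolerance defining the
#'   nearest-neighbour shell (default 0.05; strips and sheets in shell
#'   protein crystals differ by ~1% in spacing, so 5% separates
#'   neighbour classes safely).
#' @return integer 0, 1 or 2 (3 for a 3-D lattice).
#' @examples
#' strip <- t(sapply(0:4, function(i) c(67.4 * i, 0, 0)))
#' tiling_dimensionality(strip)
#' @export
tiling_dimensionality <- function(centers, spacing_tolerance = 0.05) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- as.matrix(centers)
  if (nrow(centers) == 0L)
    stop("domain error: empty centre list", call. = FALSE)
  if (nrow(centers) == 1L) return(0L)
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  dmin <- min(d)
  nb <- which(d <= (1 + spacing_tolerance) * dmin & upper.tri(d),
              arr.ind = TRUE)
  diffs <- centers[nb[, 2L], , drop = FALSE] -
    centers[nb[, 1L], , drop = FALSE]
  sv <- svd(diffs)$d
  sum(sv > 1e-6 * sv[1L])
}
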