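# Crystal cell arithmetic: fractional -> Cartesian convention with the a
# axis along x and b in the xy-plane (standard crystallographic setting).

#' Construct a crystal cell
#'
#' @param a,b,c cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @param space_group_label free-text space-group symbol (e.g. "P 62 2 2",
#'   "P 1 21 1"); emitted verbatim on CRYST1 output.
#' @return object of class `crystal_cell`.
#' @examples
#' # the type I monoclinic cell of a shell-protein crystal
#' crystal_cell(45.2, 93.3, 63.1, 90, 105.0, 90, "P 1 21 1")
#' @export
crystal_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                         space_group_label = "P 1") {
  vals <- c(a = a, b = b, c = c)
  if (anyNA(vals) || any(vals <= 0))
    stop("cell lengths must be positive", call. = FALSE)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (anyNA(ang) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, space_group_label = space_group_label),
            class = "crystal_cell")
}

#' @export
print.crystal_cell <- function(x, ...) {
  cat(sprintf("<crystal_cell> %.2f %.2f %.2f / %.1f %.1f %.1f [%s]\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma,
              x$space_group_label))
  invisible(x)
}

#' Fractional-to-Cartesian matrix of a cell
#'
#' Columns are the cell vectors **a**, **b**, **c** in Cartesian Angstrom,
#' with **a** along x and **b** in the xy-plane.
#'
#' @param cell a [crystal_cell()].
#' @return 3x3 numeric matrix.
#' @export
cell_matrix <- function(cell) {
  stopifnot(inherits(cell, "crystal_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 0) stop("degenerate cell: angles incompatible", call. = FALSE)
  cbind(c(cell$a, 0, 0),
        c(cell$b * cg, cell$b * sg, 0),
        c(cell$c * cb, cell$c * (ca - cb * cg) / sg,
          cell$c * sqrt(v) / sg))
}

#' Length of a lattice translation
#'
#' Returns |u a + v b + w c| for integer indices (u, v, w) - e.g. the
#' hexamer separation along a one-dimensional tiling diagonal of a
#' monoclinic cell.
#'
#' @param cell a [crystal_cell()].
#' @param indices integer vector of length 3, not all zero.
#' @return translation length in Angstrom.
#' @examples
#' cell <- crystal_cell(45.2, 93.3, 63.1, 90, 105.0, 90)
#' lattice_translation_length(cell, c(1, 0, 1))  # ac-plane diagonal
#' @export
lattice_translation_length <- function(cell, indices) {
  if (length(indices) != 3L || anyNA(indices))
    stop("indices must be an integer triple", call. = FALSE)
  if (all(indices == 0))
    stop("domain error: lattice translation indices must not all be zero",
         call. = FALSE)
  sqrt(sum((cell_matrix(cell) %*% as.numeric(indices))^2))
}

#' Expand a model over lattice translations
#'
#' Builds an assembly with one copy of the model per index triple, each
#' translated by u a + v b + w c and relabelled to unique chains.  The
#' copy at (0,0,0), when requested, is identical to the input.
#'
#' @param model a [structure_model()].
#' @param cell a [crystal_cell()].
#' @param index_list list of integer triples (or a 3-column matrix).
#' @return a `structure_model` assembly with one `copy` per triple.
#' @examples
#' hx <- make_ideal_hexamer()
#' cell <- crystal_cell(67.2, 67.2, 20, 90, 90, 120, "P 62 2 2")
#' pair <- expand_neighbors(hx, cell, list(c(0, 0, 0), c(1, 0, 0)))
#' @export
expand_neighbors <- function(model, cell, index_list) {
  stopifnot(inherits(model, "structure_model"))
  if (is.matrix(index_list))
    index_list <- lapply(seq_len(nrow(index_list)),
                         function(i) index_list[i, ])
  if (!length(index_list)) stop("no index triples given", call. = FALSE)
  key <- vapply(index_list, paste, "", collapse = ",")
  if (anyDuplicated(key))
    stop("validation error: duplicate index triples", call. = FALSE)
  M <- cell_matrix(cell)
  copies <- lapply(index_list, function(uvw) {
    t <- as.numeric(M %*% as.numeric(uvw))
    apply_transform(model, rigid_transform(diag(3), t))
  })
  out <- combine_models(copies, label = paste0(model$label, "-lattice"))
  out$cell <- cell
  out
}
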