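# Structure model container: a flat atom table plus optional crystal cell.
# The atom table is the common currency of every stage in the package.

#' Van der Waals radius table
#'
#' Element-to-radius mapping used when structures are read or generated.
#' The default bundles the standard heavy-atom radii (C 1.70, N 1.55,
#' O 1.52, S 1.80 Angstrom) with a 1.70 Angstrom fallback for pseudo-atoms
#' and unknown elements.  Surface-area programs differ slightly in their
#' radii, so the table can be overridden per call or via a key-value
#' config file (see [read_radii_config()]).
#'
#' @param override named numeric vector of element -> radius (Angstrom)
#'   entries that replace or extend the defaults.  The special name
#'   `"default"` replaces the fallback radius.
#' @return named numeric vector of radii, with a `"default"` entry.
#' @examples
#' vdw_radii()[["N"]]
#' vdw_radii(c(C = 1.75))[["C"]]
#' @export
vdw_radii <- function(override = NULL) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
           default = 1.70)
  if (!is.null(override)) {
    if (is.null(names(override)) || any(!nzchar(names(override))))
      stop("radius override must be a named numeric vector", call. = FALSE)
    tab[names(override)] <- override
  }
  if (any(tab <= 0)) stop("van der Waals radii must be positive", call. = FALSE)
  tab
}

#' Read a radii/config override file
#'
#' Parses a simple `key = value` text file.  Keys that look like element
#' symbols become radius overrides; the key `chain_scheme` may be set to
#' `"single"` or `"two-char"` to force a chain-relabelling scheme in
#' [write_structure()].
#'
#' @param path file path to a key-value text file.
#' @return list with elements `radii` (named numeric) and `chain_scheme`
#'   (character or `NULL`).
#' @export
read_radii_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  scheme <- NULL
  if ("chain_scheme" %in% keys) {
    scheme <- match.arg(vals[keys == "chain_scheme"][1L],
                        c("single", "two-char"))
    vals <- vals[keys != "chain_scheme"]
    keys <- keys[keys != "chain_scheme"]
  }
  radii <- NULL
  if (length(keys)) {
    radii <- suppressWarnings(as.numeric(vals))
    if (anyNA(radii))
      stop("non-numeric radius value in config", call. = FALSE)
    names(radii) <- keys
  }
  list(radii = radii, chain_scheme = scheme)
}

element_radius <- function(element, radii = vdw_radii()) {
  r <- radii[element]
  r[is.na(r)] <- radii[["default"]]
  unname(r)
}

#' Construct a structure model
#'
#' A `structure_model` holds an ordered atom table (serial, name, element,
#' residue number/name, chain, Cartesian coordinates in Angstrom, vdW
#' radius, HETATM flag, assembly copy index), an optional attached
#' [crystal_cell()], and a label.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resno`, `resid`, `chain`, `x`, `y`, `z`; optional `radius`, `het`,
#'   `copy` columns are filled with defaults.
#' @param cell optional `crystal_cell` attached to the model.
#' @param label free-text label carried through transformations.
#' @param radii radius table used to assign missing `radius` values.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, cell = NULL, label = "model",
                            radii = vdw_radii()) {
  req <- c("serial", "name", "element", "resno", "resid", "chain",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates", call. = FALSE)
  if (is.null(atoms$radius))
    atoms$radius <- element_radius(atoms$element, radii)
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0))
    stop("all vdW radii must be positive and finite", call. = FALSE)
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$copy)) atoms$copy <- 1L
  atoms$chain <- as.character(atoms$chain)
  rownames(atoms) <- NULL
  if (!is.null(cell) && !inherits(cell, "crystal_cell"))
    stop("cell must be a crystal_cell", call. = FALSE)
  structure(list(atoms = atoms, cell = cell, label = label),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %s: %d atoms, %d chain(s), %d copy(ies)\n",
              x$label, nrow(a), length(unique(a$chain)),
              length(unique(a$copy))))
  if (!is.null(x$cell))
    cat(sprintf("  cell: a=%.1f b=%.1f c=%.1f alpha=%.1f beta=%.1f gamma=%.1f [%s]\n",
                x$cell$a, x$cell$b, x$cell$c,
                x$cell$alpha, x$cell$beta, x$cell$gamma,
                x$cell$space_group_label))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param model a `structure_model`.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

set_coords <- function(model, xyz) {
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

#' Geometric centre of a model (or of each assembly copy)
#'
#' @param model a `structure_model`.
#' @param by_copy if `TRUE`, return one centre per assembly copy.
#' @return numeric vector of length 3, or a matrix with one row per copy.
#' @export
model_center <- function(model, by_copy = FALSE) {
  xyz <- coords(model)
  if (!by_copy) return(colMeans(xyz))
  cp <- model$atoms$copy
  out <- t(vapply(split(seq_len(nrow(xyz)), cp),
                  function(i) colMeans(xyz[i, , drop = FALSE]),
                  numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Select chains from a model
#'
#' @param model a `structure_model`.
#' @param chains character vector of chain identifiers to keep.
#' @return a `structure_model` restricted to the requested chains.
#' @export
select_chains <- function(model, chains) {
  keep <- model$atoms$chain %in% chains
  if (!any(keep))
    stop("selection error: chain(s) ",
         paste(setdiff(chains, model$atoms$chain), collapse = ", "),
         " absent from model", call. = FALSE)
  structure_model(model$atoms[keep, , drop = FALSE], cell = model$cell,
                  label = model$label)
}

# Combine several models into one assembly, relabelling chains uniquely and
# tagging each input model as a distinct copy.
combine_models <- function(models, label = "assembly") {
  n_chains <- sum(vapply(models, function(m) length(unique(m$atoms$chain)),
                         integer(1)))
  labels <- chain_labels(n_chains)
  k <- 0L
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    a <- models[[i]]$atoms
    old <- unique(a$chain)
    map <- setNames(labels[k + seq_along(old)], old)
    k <- k + length(old)
    a$chain <- unname(map[a$chain])
    a$copy <- i
    out[[i]] <- a
  }
  atoms <- do.call(rbind, out)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, cell = models[[1L]]$cell, label = label)
}

# Deterministic chain labelling: A-Z, a-z, 0-9 while <= 62 chains are
# needed; beyond that, two-character labels AA, AB, ... (occupying PDB
# columns 21-22 on output).
chain_labels <- function(n) {
  single <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(single)) return(single[seq_len(n)])
  two <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  if (n > length(two))
    stop("capacity error: cannot label ", n, " chains", call. = FALSE)
  two[seq_len(n)]
}
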