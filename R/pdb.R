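# Fixed-column PDB reading and writing.
#
# The writer emits ATOM/HETATM/TER/CRYST1/END records.  Chain identifiers
# use the single-character PDB alphabet (A-Z, a-z, 0-9) while the model has
# at most 62 chains; larger assemblies (e.g. multi-ring nanotubes) fall back
# to a deterministic two-character scheme (AA, AB, ...) written in columns
# 21-22, which this package's reader parses back.  Standard files leave
# column 21 blank, so the extension is backward compatible.

#' Read a structure from a PDB file
#'
#' Parses ATOM and HETATM records in file order.  A CRYST1 record, when
#' present, is attached to the model as a [crystal_cell()].  HETATM records
#' are retained and flagged in the `het` column.  For alternate locations
#' the highest-occupancy conformer is kept (ties: first in file).
#'
#' @param path path to a PDB-format file.
#' @param radii radius table used to assign vdW radii (see [vdw_radii()]).
#' @return a [structure_model()] with the file's atoms; `model$cell` holds
#'   the crystal cell when a CRYST1 record was present.
#' @examples
#' hx <- make_ideal_hexamer()
#' f <- tempfile(fileext = ".pdb")
#' write_structure(hx, f)
#' hx2 <- read_structure(f)
#' @export
read_structure <- function(path, radii = vdw_radii()) {
  if (!file.exists(path))
    stop("I/O error: cannot read '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  cell <- NULL
  cr <- which(rec == "CRYST1")
  if (length(cr)) {
    ln <- lines[cr[1L]]
    num <- function(a, b) suppressWarnings(as.numeric(substr(ln, a, b)))
    cell <- crystal_cell(num(7, 15), num(16, 24), num(25, 33),
                         num(34, 40), num(41, 47), num(48, 54),
                         space_group_label = trimws(substr(ln, 56, 66)))
  }
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom))
    stop("empty-structure error: no ATOM records in '", path, "'",
         call. = FALSE)
  idx <- which(is_atom)
  ln <- lines[idx]
  numfield <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(substr(ln, a, b)))
    if (anyNA(v))
      stop("parse error: malformed ", what, " field at line ",
           idx[which(is.na(v))[1L]], " of '", path, "'", call. = FALSE)
    v
  }
  element <- trimws(substr(ln, 77, 78))
  name <- trimws(substr(ln, 13, 16))
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", name), 1L, 1L))
  element <- ifelse(nzchar(element), element, guess)
  atoms <- data.frame(
    serial = numfield(7, 11, "serial"),
    name = name,
    element = element,
    resno = as.integer(numfield(23, 26, "residue number")),
    resid = trimws(substr(ln, 18, 20)),
    chain = trimws(substr(ln, 21, 22)),
    x = numfield(31, 38, "x coordinate"),
    y = numfield(39, 46, "y coordinate"),
    z = numfield(47, 54, "z coordinate"),
    het = rec[idx] == "HETATM",
    stringsAsFactors = FALSE)
  altloc <- substr(ln, 17, 17)
  if (any(altloc != " ")) {
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    occ[is.na(occ)] <- 1
    key <- paste(atoms$chain, atoms$resno, atoms$name)
    keep <- rep(TRUE, nrow(atoms))
    for (k in unique(key[altloc != " "])) {
      i <- which(key == k)
      if (length(i) > 1L) {
        best <- i[which.max(occ[i])]  # which.max keeps first on ties
        keep[setdiff(i, best)] <- FALSE
      }
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  structure_model(atoms, cell = cell,
                  label = sub("\\.pdb$", "", basename(path)),
                  radii = radii)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records with TER records between chains,
#' a CRYST1 record when the model has an attached cell (the space-group
#' label is written verbatim), and a terminal END record.  Models with more
#' than 62 chains use the two-character chain scheme described in the
#' package format notes (columns 21-22).
#'
#' @param model a [structure_model()] with fewer than 100,000 atoms (PDB
#'   serial field capacity).
#' @param path output file path.
#' @param chain_scheme `"auto"` (default: single-character labels while
#'   they suffice), `"single"` or `"two-char"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, chain_scheme = "auto") {
  stopifnot(inherits(model, "structure_model"))
  chain_scheme <- match.arg(chain_scheme, c("auto", "single", "two-char"))
  a <- model$atoms
  if (nrow(a) >= 1e5)
    stop("capacity error: ", nrow(a), " atoms exceed the PDB serial field;",
         " split the assembly into multiple output models", call. = FALSE)
  chains <- unique(a$chain)
  need_two <- length(chains) > 62L || any(nchar(chains) > 1L)
  if (chain_scheme == "single" && need_two)
    stop("capacity error: ", length(chains), " chains cannot use the ",
         "single-character scheme", call. = FALSE)
  if (chain_scheme == "two-char" || need_two) {
    lab <- chain_labels(max(63L, length(chains)))[seq_along(chains)]
    if (length(chains) <= 62L)  # forced two-char scheme
      lab <- as.vector(t(outer(LETTERS, LETTERS, paste0)))[seq_along(chains)]
  } else {
    lab <- chain_labels(length(chains))
  }
  map <- setNames(lab, chains)
  ch <- unname(map[a$chain])
  ch_field <- formatC(ch, width = 2L, flag = " ")  # right-justified in 21-22
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$name) < 4L & nchar(a$element) == 1L,
                  sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  lines <- sprintf("%s%5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)) %% 100000L, name4, a$resid,
                   ch_field, a$resno, a$x, a$y, a$z, 1, 0,
                   formatC(a$element, width = 2L, flag = " "))
  # TER after each chain block
  out <- character(0)
  if (!is.null(model$cell)) {
    cl <- model$cell
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                   cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                   cl$space_group_label)
  }
  last_of_chain <- c(ch[-1L] != ch[-length(ch)], TRUE)
  body <- character(nrow(a) + sum(last_of_chain))
  j <- 1L
  for (i in seq_len(nrow(a))) {
    body[j] <- lines[i]; j <- j + 1L
    if (last_of_chain[i]) { body[j] <- "TER"; j <- j + 1L }
  }
  writeLines(c(out, body, "END"), path)
  invisible(path)
}
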