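# Alignment column conservation mapped to reference-sequence positions.

#' Read a multiple sequence alignment
#'
#' Reads Clustal or aligned-FASTA alignments (via Biostrings) into a
#' light-weight `msa` object: sequences are upper-cased and '.' gaps are
#' normalised to '-'.
#'
#' @param path alignment file path.
#' @param format `"auto"` (detect from the first line), `"fasta"` or
#'   `"clustal"`.
#' @param reference_id identifier of the reference record (default: the
#'   first record).
#' @return an `msa`: list with `ids`, `seqs` (equal-length character
#'   vector) and `reference_id`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal"),
                           reference_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("I/O error: cannot read '", path, "'", call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 10L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && grepl("^CLUSTAL", first[1L],
                                         ignore.case = TRUE))
      "clustal" else "fasta"
  }
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) {
      if (format == "fasta") {
        ss <- tryCatch(Biostrings::readAAStringSet(path),
                       error = function(e2) NULL)
        if (!is.null(ss)) {
          w <- Biostrings::width(ss)
          bad <- names(ss)[w != max(w)]
          if (length(bad))
            stop("alignment error: ragged sequence length(s) for: ",
                 paste(bad, collapse = ", "), call. = FALSE)
        }
      }
      stop("alignment error: ", conditionMessage(e), call. = FALSE)
    })
  seqs <- toupper(as.character(aln))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (is.null(reference_id)) reference_id <- ids[1L]
  if (!reference_id %in% ids)
    stop("reference '", reference_id, "' absent from alignment",
         call. = FALSE)
  structure(list(ids = ids, seqs = unname(seqs),
                 reference_id = reference_id),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns (reference: %s)\n",
              length(x$ids), nchar(x$seqs[1L]), x$reference_id))
  invisible(x)
}

#' Column conservation at reference positions
#'
#' Maps 1-based ungapped positions of the reference sequence to their
#' alignment columns and scores each column's conservation as the
#' consensus identity fraction: the share of non-gap letters equal to
#' the column consensus (mode; ties broken alphabetically).  Gaps are
#' excluded from both numerator and denominator.
#'
#' @param msa an `msa` from [read_alignment()].
#' @param reference_positions integer vector of 1-based positions in the
#'   ungapped reference sequence.
#' @return data frame with `position`, `column`, `consensus`,
#'   `identity`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' make_alignment_fixture(6, 60, c(`26` = "K"), seed = 1, path = f)
#' column_conservation(read_alignment(f), 26)
#' @export
column_conservation <- function(msa, reference_positions) {
  stopifnot(inherits(msa, "msa"))
  mat <- do.call(rbind, strsplit(msa$seqs, ""))
  ref <- mat[match(msa$reference_id, msa$ids), ]
  ungapped <- which(ref != "-")
  pos <- as.integer(reference_positions)
  if (anyNA(pos) || any(pos < 1L) || any(pos > length(ungapped)))
    stop("domain error: reference position beyond ungapped reference ",
         "length (", length(ungapped), ")", call. = FALSE)
  cols <- ungapped[pos]
  res <- lapply(seq_along(pos), function(k) {
    col <- mat[, cols[k]]
    col <- col[col != "-"]
    if (!length(col))
      return(data.frame(position = pos[k], column = cols[k],
                        consensus = NA_character_, identity = NA_real_))
    tab <- table(col)
    top <- sort(names(tab)[tab == max(tab)])[1L]
    data.frame(position = pos[k], column = cols[k], consensus = top,
               identity = sum(col == top) / length(col),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
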