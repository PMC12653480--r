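#' Read a protein family from FASTA
#'
#' Reads protein sequences and optionally enforces the aligned-family
#' contract (all members the same length). Record ids are taken verbatim
#' up to the first whitespace of the FASTA header. Residues are
#' upper-cased; the allowed alphabet is the 20 amino-acid letters, the
#' ambiguity codes `X`, `B`, `Z`, and the gap character `-`.
#'
#' @param path path to a FASTA file.
#' @param aligned logical; if `TRUE`, sequences must share one length and
#'   an `aligned_family` is returned, otherwise a plain list of records.
#' @param reference id of the focal (reference) sequence when
#'   `aligned = TRUE`; defaults to the first record.
#' @return For `aligned = TRUE` an [aligned_family()]; otherwise a named
#'   character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE, reference = NULL) {
  if (!file.exists(path)) stop_format(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_format(
                    sprintf("not parseable as FASTA (%s): %s", path, conditionMessage(e))))
  if (length(set) == 0L) stop_format(sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  validate_residues(seqs)
  if (!aligned) return(seqs)
  aligned_family(seqs, reference = reference)
}

validate_residues <- function(seqs) {
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop_format(sprintf("duplicate sequence id: %s", ids[duplicated(ids)][1L]))
  }
  allowed <- c(AA20, AA_AMBIG, AA_GAP)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) stop_format(sprintf("record '%s' has an empty sequence", ids[i]))
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad)) {
      stop_format(sprintf("record '%s' contains non-alphabet character(s): %s",
                          ids[i], paste(bad, collapse = ", ")))
    }
  }
  invisible(seqs)
}

#' Construct an aligned protein family
#'
#' An `aligned_family` holds a gapped multiple alignment with a designated
#' reference sequence; it is the carrier of columns for conservation
#' scoring and bootstrap resampling.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (names are the member ids).
#' @param reference id of the reference member; defaults to the first.
#' @return An object of class `aligned_family` with elements `ids`,
#'   `seqs`, `mat` (character matrix, members in rows), `L` (columns) and
#'   `reference_id`.
#' @export
aligned_family <- function(seqs, reference = NULL) {
  if (is.list(seqs)) seqs <- unlist(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop_validation("aligned_family requires named sequences")
  }
  if (length(seqs) < 2L) stop_validation("an aligned family needs at least 2 members")
  seqs <- toupper(seqs)
  validate_residues(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop_orsite(sprintf(
      "aligned sequences differ in length (%s); not a valid alignment",
      paste(paste0(names(seqs), "=", lens), collapse = ", ")),
      c("orsite_alignment_shape_error", "orsite_format_error"))
  }
  if (is.null(reference)) reference <- names(seqs)[1L]
  if (!reference %in% names(seqs)) {
    stop_validation(sprintf("reference id '%s' is not a member of the family", reference))
  }
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(names(seqs), NULL))
  structure(list(ids = names(seqs), seqs = seqs, mat = mat,
                 L = unname(lens[1L]), reference_id = reference),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("aligned_family: %d members x %d columns (reference: %s)\n",
              length(x$ids), x$L, x$reference_id))
  invisible(x)
}

#' Write sequences to FASTA
#'
#' @param x an [aligned_family()] or a named character vector of sequences.
#' @param path output file path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  seqs <- if (inherits(x, "aligned_family")) x$seqs else x
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Ungapped reference sequence of an aligned family
#'
#' @param family an [aligned_family()].
#' @return Named character vector of reference residues; names are the
#'   1-based reference positions.
#' @export
reference_residues <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  row <- family$mat[family$reference_id, ]
  res <- row[row != AA_GAP]
  names(res) <- seq_along(res)
  res
}
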