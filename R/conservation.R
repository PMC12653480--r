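#' Per-column conservation profile of an aligned family
#'
#' For every alignment column the conservation score is the frequency of
#' the most common valid residue: `Ci = max(count(r)) / ni`, where `ni`
#' counts the valid residues in the column. Gaps (`-`) and the ambiguity
#' codes `X`, `B`, `Z` are excluded from both the numerator and `ni`.
#' Columns with no valid residue at all are flagged (`no_data`) and given
#' `Ci = 0`, so downstream thresholds never select them. When several
#' residues tie for the mode the score is unaffected and the
#' alphabetically first tied residue is reported, for reproducible output.
#'
#' @param family an [aligned_family()].
#' @return A data frame of class `conservation_profile` with one row per
#'   column: `column` (1-based), `ref_position` (1-based ungapped position
#'   in the reference, `NA` where the reference is gapped),
#'   `modal_residue`, `ni`, `Ci`, `no_data`.
#' @export
conservation_profile <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  mat <- family$mat
  L <- family$L
  Ci <- numeric(L); ni <- integer(L)
  modal <- character(L); nodata <- logical(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    valid <- col[col %in% AA20]
    ni[j] <- length(valid)
    if (ni[j] == 0L) {
      Ci[j] <- 0; modal[j] <- NA_character_; nodata[j] <- TRUE
    } else {
      counts <- table(valid)
      top <- max(counts)
      Ci[j] <- top / ni[j]
      # names(counts) is sorted alphabetically, so the first maximal
      # entry is the alphabetically first tied residue
      modal[j] <- names(counts)[counts == top][1L]
    }
  }
  refrow <- mat[family$reference_id, ]
  ref_position <- ifelse(refrow == AA_GAP, NA_integer_, cumsum(refrow != AA_GAP))
  out <- data.frame(column = seq_len(L), ref_position = as.integer(ref_position),
                    modal_residue = modal, ni = ni, Ci = Ci, no_data = nodata,
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", "data.frame")
  attr(out, "reference_id") <- family$reference_id
  attr(out, "n_members") <- length(family$ids)
  out
}

#' Summarize a conservation profile
#'
#' Classifies columns against two thresholds: highly conserved columns
#' have `Ci > t_high` (strict, matching the ">90% identity" convention for
#' reporting) and variable columns have `Ci <= t_var`. Candidate selection
#' elsewhere uses a non-strict `>=` threshold; the two conventions are
#' deliberately distinct configuration values.
#'
#' @param profile a [conservation_profile()].
#' @param t_var variable-column threshold (default 0.7).
#' @param t_high highly-conserved threshold (default 0.9).
#' @return A list of class `conservation_summary`: `L`, `mean`, `median`,
#'   `n_high`, `n_variable`, `thresholds`.
#' @export
summarize_conservation <- function(profile, t_var = 0.7, t_high = 0.9) {
  if (nrow(profile) == 0L) stop_validation("empty conservation profile")
  if (!(t_var >= 0 && t_var <= t_high && t_high <= 1)) {
    stop_validation("thresholds must satisfy 0 <= t_var <= t_high <= 1")
  }
  s <- profile$Ci
  structure(list(L = length(s), mean = mean(s), median = median(s),
                 n_high = sum(s > t_high), n_variable = sum(s <= t_var),
                 thresholds = c(t_var = t_var, t_high = t_high)),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "conservation over %d columns: mean %.3f, median %.3f\n",
    "  highly conserved (Ci > %.2f): %d (%.1f%%)\n",
    "  variable (Ci <= %.2f): %d (%.1f%%)\n"),
    x$L, x$mean, x$median,
    x$thresholds["t_high"], x$n_high, 100 * x$n_high / x$L,
    x$thresholds["t_var"], x$n_variable, 100 * x$n_variable / x$L))
  invisible(x)
}

#' Conservation by reference position
#'
#' Projects a column profile onto the ungapped coordinates of the
#' reference sequence, so results can be reported in the familiar
#' "Thr103" style. Columns where the reference carries a gap have no
#' reference position and are dropped.
#'
#' @param profile a [conservation_profile()].
#' @return Named numeric vector of `Ci` values; names are reference
#'   positions `1..n` (ungapped reference length).
#' @export
residue_conservation <- function(profile) {
  keep <- !is.na(profile$ref_position)
  setNames(profile$Ci[keep], profile$ref_position[keep])
}

#' Export a conservation profile as TSV
#'
#' Columns: `column`, `ref_position`, `modal_residue`, `ni`, `Ci`.
#' `Ci` is rounded to 4 decimals at serialization.
#'
#' @param profile a [conservation_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(profile, path) {
  out <- profile[, c("column", "ref_position", "modal_residue", "ni", "Ci")]
  out$Ci <- round(out$Ci, 4)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
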