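#' Read alpha-carbon coordinates from a PDB file
#'
#' Keeps only `ATOM` records with atom name `CA` from the first model of
#' the selected chain (multi-model files beyond model 1 are ignored with
#' a message). Alternate locations are resolved by highest occupancy,
#' then first-seen. `HETATM` records are ignored.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier, or `NULL` for the first chain that
#'   carries CA atoms.
#' @return An object of class `ca_structure`: data.frame `residues`
#'   (`resno`, `resid`, `x`, `y`, `z`), `chain`, `source`.
#' @export
read_ca <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_format(sprintf("PDB file not found: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop_format(
                    sprintf("not parseable as PDB (%s): %s", path, conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0L) stop_format("no CA ATOM records found in PDB input")
  if (is.null(chain)) {
    chain <- at$chain[1L]
    if (is.na(chain)) chain <- ""
  }
  sel <- if (nzchar(chain)) !is.na(at$chain) & at$chain == chain else is.na(at$chain) | at$chain == ""
  at <- at[sel, , drop = FALSE]
  if (nrow(at) == 0L) stop_format(sprintf("no CA atoms on chain '%s'", chain))
  # altloc resolution: best occupancy first, ties by original order
  occ <- ifelse(is.na(at$o), 1, at$o)
  at <- at[order(at$resno, -occ, seq_len(nrow(at))), , drop = FALSE]
  # a residue number repeated with *blank* altloc is a malformed file;
  # genuine altlocs collapse to the best-occupancy copy
  blank <- is.na(at$alt) | at$alt %in% c("", ".")
  if (any(duplicated(at$resno[blank]))) {
    stop_format(sprintf("duplicate CA for residue %d after altloc resolution",
                        at$resno[blank][duplicated(at$resno[blank])][1L]))
  }
  at_first <- at[!duplicated(at$resno), , drop = FALSE]
  res <- data.frame(resno = at_first$resno, resid = at_first$resid,
                    x = at_first$x, y = at_first$y, z = at_first$z,
                    stringsAsFactors = FALSE)
  res <- res[order(res$resno), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(residues = res, chain = chain, source = path),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("ca_structure: %d residues, chain '%s' (%s)\n",
              nrow(x$residues), x$chain, x$source))
  invisible(x)
}

#' Write a CA-only structure as PDB
#'
#' @param structure a `ca_structure` (or anything with a `residues`
#'   data.frame holding `resno`, `resid`, `x`, `y`, `z`).
#' @param path output path.
#' @param chain chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_ca <- function(structure, path, chain = "A") {
  res <- structure$residues
  n <- nrow(res)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(res[, c("x", "y", "z")]))),
                   type = rep("ATOM", n),
                   resno = res$resno,
                   resid = res$resid,
                   eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = rep(chain, n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Neighbor counts and nearest-neighbor distances of CA atoms
#'
#' For each residue, `Ni` counts the other CA atoms within `radius`
#' (inclusive boundary, self excluded) and `Di` is the minimum Euclidean
#' distance to any other CA atom — over all residues of the chain, not
#' only those inside the radius.
#'
#' @param structure a [read_ca()] result.
#' @param radius neighbor radius in Angstrom (default 8.0).
#' @return data.frame with `resno`, `Ni`, `Di`.
#' @export
neighbor_stats <- function(structure, radius = 8.0) {
  res <- structure$residues
  n <- nrow(res)
  if (n < 2L) stop_validation("neighbor statistics need at least 2 residues")
  D <- as.matrix(dist(as.matrix(res[, c("x", "y", "z")])))
  diag(D) <- Inf
  data.frame(resno = res$resno,
             Ni = as.integer(rowSums(D <= radius)),
             Di = apply(D, 1L, min))
}

#' Simplified CA-based solvent-accessibility score (raw)
#'
#' `asa_raw = max(0, 20 - Ni) + 2 * Di`: low local density (few CA
#' neighbors within the radius) and a distant nearest neighbor both
#' indicate surface exposure. The density term clamps at 0 for
#' `Ni >= 20`.
#'
#' @param Ni neighbor count(s), `>= 0`.
#' @param Di nearest-neighbor distance(s) in Angstrom, `> 0`.
#' @return Numeric raw exposure score(s), `>= 0`.
#' @export
asa_raw <- function(Ni, Di) {
  if (any(Ni < 0)) stop_validation("Ni must be >= 0")
  if (any(Di <= 0)) stop_validation("Di must be > 0")
  pmax(0, 20 - Ni) + 2 * Di
}

#' Linearly normalize raw exposure scores to [0, 100]
#'
#' `x -> 100 * (x - min) / (max - min)`. When all raw scores are equal
#' the mapping is degenerate; every value is set to 0 (never 100, so no
#' residue is spuriously reported as most exposed) and a warning is
#' raised.
#'
#' @param raws nonempty numeric vector of raw scores.
#' @return Numeric vector in `[0, 100]`.
#' @export
normalize_scores <- function(raws) {
  if (length(raws) == 0L) stop_validation("no raw scores to normalize")
  rng <- range(raws)
  if (rng[1] == rng[2]) {
    warning("all raw exposure scores are equal; normalized scores degenerate to 0",
            call. = FALSE)
    return(rep(0, length(raws)))
  }
  100 * (raws - rng[1]) / (rng[2] - rng[1])
}

#' Per-residue exposure score table
#'
#' Convenience wrapper chaining [neighbor_stats()], [asa_raw()] and
#' [normalize_scores()] over a whole structure.
#'
#' @param structure a [read_ca()] result.
#' @param radius neighbor radius in Angstrom.
#' @param normalize logical; add the `normalized` column (over all
#'   residues of the structure).
#' @return data.frame of class `asa_scores`: `resno`, `Ni`, `Di`, `raw`
#'   and (optionally) `normalized`.
#' @export
asa_scores <- function(structure, radius = 8.0, normalize = TRUE) {
  ns <- neighbor_stats(structure, radius)
  ns$raw <- asa_raw(ns$Ni, ns$Di)
  if (normalize) ns$normalized <- normalize_scores(ns$raw)
  class(ns) <- c("asa_scores", "data.frame")
  ns
}
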