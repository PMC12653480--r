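#' Transmembrane topology specification
#'
#' Holds the externally predicted topology of a membrane protein: the
#' ordered transmembrane (TM) segment ranges and the membrane side of the
#' N-terminus. Ranges are 1-based inclusive.
#'
#' @param protein_length total residue count.
#' @param tm_segments a two-column matrix or list of `c(start, end)`
#'   pairs, ordered along the chain.
#' @param n_term_side `"cytoplasmic"` or `"extracellular"`.
#' @return An object of class `topology_spec`.
#' @export
topology_spec <- function(protein_length, tm_segments,
                          n_term_side = c("cytoplasmic", "extracellular")) {
  n_term_side <- match.arg(n_term_side)
  if (is.list(tm_segments)) tm_segments <- do.call(rbind, tm_segments)
  tm_segments <- matrix(as.integer(tm_segments), ncol = 2L,
                        dimnames = list(NULL, c("start", "end")))
  protein_length <- as.integer(protein_length)
  if (protein_length < 1L) stop_validation("protein_length must be positive")
  if (nrow(tm_segments) < 1L) stop_validation("at least one TM segment is required")
  if (any(tm_segments[, 1] > tm_segments[, 2])) {
    stop_validation("TM segment with start > end")
  }
  if (any(tm_segments < 1L) || any(tm_segments > protein_length)) {
    stop_validation("TM segment outside 1..protein_length")
  }
  if (nrow(tm_segments) > 1L) {
    gaps <- tm_segments[-1L, 1] - tm_segments[-nrow(tm_segments), 2]
    if (any(gaps < 1L)) stop_validation("TM segments overlap or are unsorted")
  }
  structure(list(protein_length = protein_length, tm_segments = tm_segments,
                 n_term_side = n_term_side),
            class = "topology_spec")
}

#' Read a topology specification from a plain-text file
#'
#' The file holds one `start<TAB>end` pair per line for the TM segments,
#' plus two header comments: `# protein_length: <n>` and
#' `# n_term_side: <cytoplasmic|extracellular>`.
#'
#' @param path file path.
#' @return A [topology_spec()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("topology file not found: %s", path))
  lines <- readLines(path)
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (length(m) != 1L) stop_format(sprintf("topology file must declare '# %s: ...' exactly once", key))
    trimws(sub(sprintf("^#\\s*%s:", key), "", m))
  }
  len <- suppressWarnings(as.integer(get_meta("protein_length")))
  if (is.na(len)) stop_format("invalid protein_length in topology file")
  side <- get_meta("n_term_side")
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0L) stop_format("topology file lists no TM segments")
  seg <- do.call(rbind, lapply(strsplit(body, "[ \t]+"), function(f) {
    v <- suppressWarnings(as.integer(f[nzchar(f)]))
    if (length(v) != 2L || anyNA(v)) stop_format("topology segment lines must hold two integers")
    v
  }))
  topology_spec(len, seg, side)
}

#' Write a topology specification to the plain-text format of
#' [read_topology()]
#'
#' @param spec a [topology_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(spec, path) {
  lines <- c(sprintf("# protein_length: %d", spec$protein_length),
             sprintf("# n_term_side: %s", spec$n_term_side),
             sprintf("%d\t%d", spec$tm_segments[, 1], spec$tm_segments[, 2]))
  writeLines(lines, path)
  invisible(path)
}

flip_side <- function(side) {
  if (side == "cytoplasmic") "extracellular" else "cytoplasmic"
}

#' Derive loop and tail annotations from a topology
#'
#' Walks the chain through the TM segments, alternating the membrane side
#' at each crossing starting from the N-terminal side. Inter-TM gaps
#' become extracellular (`EL`) or intracellular (`IL`) loops numbered
#' along the chain; the stretches before the first and after the last TM
#' are the `N_tail` and `C_tail`. Zero-length loops and tails are
#' recorded as empty ranges and flagged rather than dropped.
#'
#' @param spec a [topology_spec()].
#' @return An object of class `region_annotation`: the `spec`, a region
#'   `table` (data.frame with `label`, `start`, `end`, `length`, `side`)
#'   and `labels`, the per-residue label vector of length
#'   `protein_length`.
#' @export
derive_regions <- function(spec) {
  stopifnot(inherits(spec, "topology_spec"))
  seg <- spec$tm_segments
  k <- nrow(seg)
  rows <- list()
  add <- function(label, start, end, side) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, start = start, end = end,
      length = max(0L, end - start + 1L), side = side,
      stringsAsFactors = FALSE)
  }
  side <- spec$n_term_side
  add("N_tail", 1L, seg[1L, 1] - 1L, side)
  n_el <- 0L; n_il <- 0L
  for (i in seq_len(k)) {
    add(sprintf("TM%d", i), seg[i, 1], seg[i, 2], "membrane")
    side <- flip_side(side)
    if (i < k) {
      if (side == "extracellular") {
        n_el <- n_el + 1L; lab <- sprintf("EL%d", n_el)
      } else {
        n_il <- n_il + 1L; lab <- sprintf("IL%d", n_il)
      }
      add(lab, seg[i, 2] + 1L, seg[i + 1L, 1] - 1L, side)
    }
  }
  add("C_tail", seg[k, 2] + 1L, spec$protein_length, side)
  tab <- do.call(rbind, rows)
  labels <- character(spec$protein_length)
  for (r in seq_len(nrow(tab))) {
    if (tab$length[r] > 0L) labels[tab$start[r]:tab$end[r]] <- tab$label[r]
  }
  stopifnot(all(nzchar(labels)))   # the regions partition the chain
  structure(list(spec = spec, table = tab, labels = labels),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("region_annotation over %d residues (%d TM segments, N-terminus %s)\n",
              x$spec$protein_length, nrow(x$spec$tm_segments), x$spec$n_term_side))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Look up the region of a single residue
#'
#' @param annotation a [derive_regions()] result.
#' @param position 1-based residue index.
#' @return List with `label` and `side`.
#' @export
classify_residue <- function(annotation, position) {
  stopifnot(inherits(annotation, "region_annotation"))
  n <- annotation$spec$protein_length
  if (length(position) != 1L || is.na(position) || position < 1L || position > n) {
    stop_validation(sprintf("position must be in 1..%d", n))
  }
  lab <- annotation$labels[position]
  row <- annotation$table[annotation$table$label == lab, ]
  list(label = lab, side = row$side[1L])
}

#' Candidate-region mask
#'
#' Builds the set of residue positions considered plausible for ligand
#' contact. Two rules are provided:
#'
#' * `"loops_plus_full_tms"` (default): all extracellular-loop residues
#'   plus every residue of the TM helices with index `>= tm_min_index`
#'   (default 3) — the rule consistent with marking whole TM3-TM7
#'   helices alongside EL1-EL3.
#' * `"loops_plus_tm_termini"`: all extracellular-loop residues plus the
#'   `w` residues at the extracellular-facing end of every TM helix —
#'   the literal "termini of transmembrane segments" reading.
#'
#' @param annotation a [derive_regions()] result.
#' @param mode mask rule, see above.
#' @param tm_min_index first TM index included in
#'   `"loops_plus_full_tms"` mode.
#' @param w terminal window width (residues) in
#'   `"loops_plus_tm_termini"` mode.
#' @return An object of class `candidate_mask`: sorted `positions`,
#'   `mode`, `params`, `protein_length`.
#' @export
candidate_mask <- function(annotation,
                           mode = c("loops_plus_full_tms", "loops_plus_tm_termini"),
                           tm_min_index = 3L, w = 4L) {
  stopifnot(inherits(annotation, "region_annotation"))
  mode <- match.arg(mode)
  tab <- annotation$table
  n_tm <- nrow(annotation$spec$tm_segments)
  el <- tab[grepl("^EL", tab$label) & tab$length > 0L, ]
  pos <- unlist(lapply(seq_len(nrow(el)), function(r) el$start[r]:el$end[r]),
                use.names = FALSE)
  if (mode == "loops_plus_full_tms") {
    if (tm_min_index < 1L || tm_min_index > n_tm) {
      stop_validation(sprintf("tm_min_index must be in 1..%d", n_tm))
    }
    for (i in tm_min_index:n_tm) {
      seg <- annotation$spec$tm_segments[i, ]
      pos <- c(pos, seg[1]:seg[2])
    }
    params <- list(tm_min_index = as.integer(tm_min_index))
  } else {
    if (w < 0L) stop_validation("terminal window w must be >= 0")
    side <- annotation$spec$n_term_side
    for (i in seq_len(n_tm)) {
      seg <- annotation$spec$tm_segments[i, ]
      side_after <- flip_side(side)
      len <- seg[2] - seg[1] + 1L
      ww <- min(as.integer(w), len)
      if (ww > 0L) {
        win <- if (side_after == "extracellular") {
          (seg[2] - ww + 1L):seg[2]    # helix exits to the outside: top end
        } else {
          seg[1]:(seg[1] + ww - 1L)    # helix entered from the outside
        }
        pos <- c(pos, win)
      }
      side <- side_after
    }
    params <- list(w = as.integer(w))
  }
  structure(list(positions = sort(unique(as.integer(pos))), mode = mode,
                 params = params,
                 protein_length = annotation$spec$protein_length),
            class = "candidate_mask")
}

#' Export the region table as TSV
#'
#' @param annotation a [derive_regions()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_tsv <- function(annotation, path) {
  write.table(annotation$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Regions as BED-style intervals
#'
#' Converts the 1-based inclusive region ranges to the 0-based half-open
#' convention (`bed_start = start - 1`, `bed_end = end`); zero-length
#' regions are dropped, as BED cannot represent them.
#'
#' @param annotation a [derive_regions()] result.
#' @param name sequence name for the first BED column.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
regions_to_bed <- function(annotation, name = "protein") {
  tab <- annotation$table[annotation$table$length > 0L, ]
  data.frame(chrom = name, start = tab$start - 1L, end = tab$end,
             name = tab$label, stringsAsFactors = FALSE)
}
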