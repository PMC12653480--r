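#' Maximum-likelihood JTT distance between two aligned sequences
#'
#' Estimates the evolutionary distance (expected substitutions per site)
#' between two rows of an alignment by maximizing the pairwise likelihood
#' `sum(log(pi[a] * P[a, b](t)))` over the columns where both sequences
#' carry a valid residue (gaps and ambiguity codes are skipped). The
#' optimum is located by bracketed scalar maximization on `[0, cap]` to a
#' tolerance of 1e-6. Identical sequences return exactly 0; estimates
#' that press against the cap are flagged as saturated.
#'
#' @param a,b aligned residue strings (or character vectors) of equal
#'   length.
#' @param model a [jtt_model()].
#' @param cap maximum distance considered (expected substitutions/site).
#' @return A list with `distance` and logical `saturated`.
#' @export
jtt_distance <- function(a, b, model = jtt_model(), cap = 10) {
  av <- if (length(a) == 1L) strsplit(toupper(a), "")[[1]] else toupper(a)
  bv <- if (length(b) == 1L) strsplit(toupper(b), "")[[1]] else toupper(b)
  if (length(av) != length(bv)) stop_validation("sequences must be aligned to equal length")
  ia <- match(av, model$alphabet)
  ib <- match(bv, model$alphabet)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) {
    stop_orsite("no shared valid column between the two sequences; distance undefined",
                c("orsite_undefined_distance_error", "orsite_validation_error"))
  }
  ia <- ia[ok]; ib <- ib[ok]
  if (all(ia == ib)) return(list(distance = 0, saturated = FALSE))
  # compress to pair-pattern counts: likelihood is sum(n_ab * log(pi_a P_ab))
  counts <- tabulate((ia - 1L) * 20L + ib, nbins = 400L)
  nz <- which(counts > 0L)
  n_ab <- counts[nz]
  logpi <- log(model$pi)[((nz - 1L) %/% 20L) + 1L]
  loglik <- function(t) {
    P <- prob_matrix(model, t)
    sum(n_ab * (logpi + log(P[nz])))
  }
  opt <- optimize(loglik, interval = c(0, cap), maximum = TRUE, tol = 1e-6)
  d <- opt$maximum
  saturated <- (cap - d) < 1e-4
  if (saturated) d <- cap
  list(distance = d, saturated = saturated)
}

#' Pairwise JTT distance matrix of an aligned family
#'
#' @param family an [aligned_family()].
#' @param model a [jtt_model()].
#' @param cap distance cap (expected substitutions/site, default 10).
#' @param on_undefined what to do when a pair shares no valid column:
#'   `"cap"` (default) records the pair at the cap and flags it
#'   saturated; `"error"` raises an undefined-distance error (used by the
#'   bootstrap to skip a replicate).
#' @return An object of class `jtt_dist`: `labels`, symmetric matrix `d`
#'   (zero diagonal), logical matrix `saturated`.
#' @export
distance_matrix <- function(family, model = jtt_model(), cap = 10,
                            on_undefined = c("cap", "error")) {
  stopifnot(inherits(family, "aligned_family"))
  on_undefined <- match.arg(on_undefined)
  n <- length(family$ids)
  d <- matrix(0, n, n, dimnames = list(family$ids, family$ids))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      res <- tryCatch(
        jtt_distance(family$mat[i, ], family$mat[j, ], model, cap),
        orsite_undefined_distance_error = function(e) {
          if (on_undefined == "error") stop(e)
          list(distance = cap, saturated = TRUE)
        })
      d[i, j] <- d[j, i] <- res$distance
      sat[i, j] <- sat[j, i] <- res$saturated
    }
  }
  structure(list(labels = family$ids, d = d, saturated = sat),
            class = "jtt_dist")
}

#' @export
print.jtt_dist <- function(x, ...) {
  up <- x$d[upper.tri(x$d)]
  cat(sprintf("jtt_dist over %d taxa: mean %.4f, max %.4f%s\n",
              length(x$labels), mean(up), max(up),
              if (any(x$saturated)) sprintf(" (%d saturated pairs)",
                                            sum(x$saturated[upper.tri(x$saturated)]))
              else ""))
  invisible(x)
}

#' Summary statistics of a distance matrix
#'
#' @param dm a [distance_matrix()] result.
#' @param pair optional character vector of two labels; when given, the
#'   distance of that pair is returned as element `pair`.
#' @return List with `mean`, `max` over the off-diagonal entries, and
#'   optionally `pair`.
#' @export
distance_summary <- function(dm, pair = NULL) {
  up <- dm$d[upper.tri(dm$d)]
  out <- list(mean = mean(up), max = max(up))
  if (!is.null(pair)) {
    if (!all(pair %in% dm$labels)) stop_validation("unknown label in 'pair'")
    out$pair <- dm$d[pair[1L], pair[2L]]
  }
  out
}

#' Export a distance matrix
#'
#' `write_distance_tsv()` writes a labeled square TSV (the heatmap-ready
#' layout); `write_distance_phylip()` writes the PHYLIP square format.
#' Distances are rounded to 4 decimals at serialization.
#'
#' @param dm a [distance_matrix()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  m <- round(dm$d, 4)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
write_distance_phylip <- function(dm, path) {
  n <- length(dm$labels)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(dm$labels[i], width = -10),
                      paste(sprintf("%.4f", dm$d[i, ]), collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion with the standard NJ
#' branch-length formulas. Ties in the Q-criterion are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is
#' labeled by its alphabetically first leaf), so the result is
#' reproducible. Negative branch-length estimates are clamped to 0 with
#' a warning. Exact on additive matrices.
#'
#' @param dm a [distance_matrix()] result, a `dist`, or a symmetric
#'   labeled matrix.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  D <- if (inherits(dm, "jtt_dist")) dm$d else as.matrix(dm)
  if (is.null(rownames(D))) stop_validation("distance matrix must be labeled")
  n <- nrow(D)
  if (n < 2L) stop_validation("Neighbor-Joining needs at least 2 taxa")
  labels <- rownames(D)
  if (n == 2L) {
    half <- D[1L, 2L] / 2
    txt <- sprintf("(%s:%.10g,%s:%.10g);", labels[1L], half, labels[2L], half)
    return(ape::read.tree(text = txt))
  }
  frag <- labels                 # newick fragment per active cluster
  rep_lab <- labels              # smallest leaf label per cluster
  clamp <- function(x) {
    if (x < 0) {
      warning("negative NJ branch length clamped to 0", call. = FALSE)
      0
    } else x
  }
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- clamp(0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(D[i, j] - vi)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    newrep <- min(rep_lab[i], rep_lab[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_lab <- c(rep_lab[keep], newrep)
    D <- D2
  }
  # three clusters left: closed-form three-point pendant lengths
  v1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], v1, frag[2], v2, frag[3], v3)
  ape::read.tree(text = txt)
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the taxon set in two; the split is
#' canonicalized as the sorted side that does not contain the
#' alphabetically first taxon, joined with `|`.
#'
#' @param tree a `phylo`.
#' @return Character vector of canonical bipartition keys (possibly
#'   empty).
#' @export
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  if (length(tips) < 4L) return(character(0))
  first <- sort(tips)[1L]
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    side <- tips[idx]
    if (first %in% side) side <- setdiff(tips, side)
    k <- length(side)
    if (k < 2L || k > length(tips) - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

# bipartition key of each internal node (NA for trivial ones), in
# node-number order Ntip+1 .. Ntip+Nnode of the stored (rooted) layout
node_bipartitions <- function(tree) {
  tips <- tree$tip.label
  first <- sort(tips)[1L]
  pp <- ape::prop.part(tree)
  vapply(pp, function(idx) {
    side <- tips[idx]
    if (first %in% side) side <- setdiff(tips, side)
    k <- length(side)
    if (k < 2L || k > length(tips) - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
}

#' Bootstrap bipartition support for the NJ tree of a family
#'
#' Builds the original NJ tree from the full alignment, then resamples
#' alignment columns with replacement (`L` columns per replicate),
#' recomputes distances and the NJ tree, and scores each internal
#' bipartition of the original tree as
#' `100 * replicates containing it / replicates`. Replicates in which
#' some pair shares no valid column are skipped with a message; if more
#' than half are skipped the run fails (and skipped replicates are
#' excluded from the denominator). Per-replicate random streams are
#' derived from the master seed by replicate index, so any replicate is
#' reproducible in isolation.
#'
#' @param family an [aligned_family()].
#' @param model a [jtt_model()].
#' @param replicates number of bootstrap replicates (default 100).
#' @param seed master integer seed.
#' @param cap distance cap passed to [distance_matrix()].
#' @return The original NJ `phylo` with integer support percentages as
#'   `node.label` (empty for trivial nodes) and an attribute `support`:
#'   a named numeric vector keyed by canonical bipartition.
#' @export
bootstrap_support <- function(family, model = jtt_model(), replicates = 100L,
                              seed = 1L, cap = 10) {
  stopifnot(inherits(family, "aligned_family"))
  if (replicates < 1L) stop_validation("replicates must be >= 1")
  dm <- distance_matrix(family, model, cap)
  tree <- nj_tree(dm)
  orig <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(orig)), orig)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  skipped <- 0L
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    cols <- sample.int(family$L, family$L, replace = TRUE)
    mat <- family$mat[, cols, drop = FALSE]
    seqs <- setNames(apply(mat, 1L, paste, collapse = ""), family$ids)
    fam_r <- aligned_family(seqs, reference = family$reference_id)
    rep_tree <- tryCatch(
      nj_tree(distance_matrix(fam_r, model, cap, on_undefined = "error")),
      orsite_undefined_distance_error = function(e) NULL)
    if (is.null(rep_tree)) {
      skipped <- skipped + 1L
      message(sprintf("bootstrap replicate %d skipped: undefined distance", r))
      next
    }
    hits <- orig %in% tree_bipartitions(rep_tree)
    counts[hits] <- counts[hits] + 1
  }
  used <- replicates - skipped
  if (skipped > replicates / 2) {
    stop_validation(sprintf("more than half of the bootstrap replicates were skipped (%d of %d)",
                            skipped, replicates))
  }
  support <- 100 * counts / used
  nodekeys <- node_bipartitions(tree)
  tree$node.label <- ifelse(is.na(nodekeys), "",
                            as.character(round(support[nodekeys])))
  attr(tree, "support") <- support
  attr(tree, "replicates_used") <- used
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept; integer bootstrap support values (if present
#' as `node.label`) become internal node labels. An optional outgroup
#' roots the tree for display only — the underlying unrooted bipartition
#' set is unchanged.
#'
#' @param tree a `phylo`.
#' @param path output path, or `NULL` to return the Newick text.
#' @param outgroup leaf label to root on for display, or `NULL`.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL, outgroup = NULL) {
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop_validation(sprintf("outgroup '%s' is not a leaf of the tree", outgroup))
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
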