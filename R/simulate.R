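#' Specification for simulating an ortholog family alignment
#'
#' The generator draws an ancestral sequence from the JTT equilibrium
#' frequencies and evolves it down a tree under three column rate
#' classes: invariant (rate 0), moderate and fast. Class fractions
#' default to the conservation-class proportions observed in real
#' Dipteran OR45a ortholog sets (about 20% near-invariant and 54%
#' fast/variable columns). Ragged ends — terminal deletions in
#' non-reference taxa — emulate the 315-415 aa length spread of real
#' orthologs while keeping internal column indexing trivial.
#'
#' @param n_taxa number of sequences (default 11).
#' @param L alignment length in columns (default 400).
#' @param tree optional rooted `phylo` with branch lengths in expected
#'   substitutions/site; when `NULL` a random tree is drawn and rescaled
#'   to `mean_pairwise` average path length.
#' @param fraction_invariant,fraction_fast column class fractions (the
#'   remainder is the moderate class).
#' @param rate_multipliers rates of the three classes.
#' @param ragged_frac maximum fraction of `L` deleted from each end of a
#'   non-reference taxon (uniform 0..`ragged_frac * L` per end).
#' @param mean_pairwise target mean pairwise path length of the random
#'   tree before class multipliers (expected substitutions/site); the
#'   default is calibrated so the realized mean pairwise JTT distance of
#'   a default family is close to the ~1.1 observed for real Dipteran
#'   OR45a ortholog sets.
#' @param planted positions forced to be invariant columns (the planted
#'   "key residues" of recovery experiments).
#' @return A list of class `family_sim_spec`.
#' @export
family_sim_spec <- function(n_taxa = 11L, L = 400L, tree = NULL,
                            fraction_invariant = 0.20, fraction_fast = 0.54,
                            rate_multipliers = c(invariant = 0, moderate = 1, fast = 4),
                            ragged_frac = 0.12, mean_pairwise = 0.7,
                            planted = integer(0)) {
  if (n_taxa < 2L) stop_validation("n_taxa must be >= 2")
  if (L < 1L) stop_validation("L must be positive")
  fr <- c(fraction_invariant, fraction_fast)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop_validation("class fractions must lie in [0,1] and sum to at most 1")
  }
  if (length(planted) && (any(planted < 1L) || any(planted > L))) {
    stop_validation("planted positions must lie in 1..L")
  }
  structure(list(n_taxa = as.integer(n_taxa), L = as.integer(L), tree = tree,
                 fraction_invariant = fraction_invariant,
                 fraction_fast = fraction_fast,
                 rate_multipliers = rate_multipliers,
                 ragged_frac = ragged_frac, mean_pairwise = mean_pairwise,
                 planted = as.integer(planted)),
            class = "family_sim_spec")
}

#' Simulate an aligned ortholog family
#'
#' @param spec a [family_sim_spec()].
#' @param model a [jtt_model()].
#' @param seed integer seed; the whole simulation (tree included) is
#'   deterministic given the seed.
#' @return List with `family` (an [aligned_family()], reference =
#'   `seq01`), `truth` (data.frame of `position`, `class` for planted
#'   positions), and `classes` (the per-column rate class).
#' @export
simulate_family <- function(spec, model = jtt_model(), seed = 1L) {
  stopifnot(inherits(spec, "family_sim_spec"))
  set.seed(seed)
  n <- spec$n_taxa
  L <- spec$L
  tree <- spec$tree
  if (is.null(tree)) {
    tree <- ape::rtree(n, rooted = TRUE,
                       tip.label = sprintf("seq%02d", seq_len(n)))
    # rescale so the mean pairwise path length matches the target
    coph <- ape::cophenetic.phylo(tree)
    m <- mean(coph[upper.tri(coph)])
    tree$edge.length <- tree$edge.length * spec$mean_pairwise / m
  }
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)

  # column classes: planted positions are always invariant
  n_inv <- round(spec$fraction_invariant * L)
  n_fast <- round(spec$fraction_fast * L)
  classes <- rep("moderate", L)
  pool <- setdiff(seq_len(L), spec$planted)
  inv_extra <- max(0L, n_inv - length(spec$planted))
  inv_cols <- c(spec$planted, sample(pool, min(inv_extra, length(pool))))
  classes[inv_cols] <- "invariant"
  pool <- setdiff(pool, inv_cols)
  classes[sample(pool, min(n_fast, length(pool)))] <- "fast"

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs_idx <- vector("list", ntip + nnode)
  root_node <- ntip + 1L
  seqs_idx[[root_node]] <- sample.int(20L, L, replace = TRUE, prob = model$pi)
  # preorder edge walk: children inherit by one P(rate * edge) step
  tr <- ape::reorder.phylo(tree, "cladewise")
  edge_ord <- tr$edge
  elen <- tr$edge.length
  for (e in seq_len(nrow(edge_ord))) {
    parent <- seqs_idx[[edge_ord[e, 1]]]
    child <- parent
    t_edge <- elen[e]
    for (cl in c("moderate", "fast")) {
      r <- spec$rate_multipliers[cl]
      cols <- which(classes == cl)
      if (!length(cols) || r * t_edge == 0) next
      P <- prob_matrix(model, r * t_edge)
      for (a in unique(parent[cols])) {
        ca <- cols[parent[cols] == a]
        child[ca] <- sample.int(20L, length(ca), replace = TRUE, prob = P[a, ])
      }
    }
    seqs_idx[[edge_ord[e, 2]]] <- child
  }
  mat <- do.call(rbind, lapply(seq_len(ntip), function(i) model$alphabet[seqs_idx[[i]]]))
  rownames(mat) <- tree$tip.label
  mat <- mat[order(rownames(mat)), , drop = FALSE]

  # ragged ends: terminal deletions in non-reference taxa only
  max_del <- floor(spec$ragged_frac * L)
  if (max_del > 0L) {
    for (i in 2:nrow(mat)) {
      d5 <- sample.int(max_del + 1L, 1L) - 1L
      d3 <- sample.int(max_del + 1L, 1L) - 1L
      if (d5 > 0L) mat[i, seq_len(d5)] <- AA_GAP
      if (d3 > 0L) mat[i, (L - d3 + 1L):L] <- AA_GAP
    }
  }
  seqs <- setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
  family <- aligned_family(seqs, reference = rownames(mat)[1L])
  truth <- if (length(spec$planted)) {
    data.frame(position = spec$planted, class = "key", stringsAsFactors = FALSE)
  } else {
    data.frame(position = integer(0), class = character(0), stringsAsFactors = FALSE)
  }
  list(family = family, truth = truth, classes = classes, tree = tree)
}

#' Specification for an idealized 7-helix bundle CA trace
#'
#' Helices are ideal alpha-helical CA traces (1.5 Angstrom rise and 100
#' degrees twist per residue on a 2.3 Angstrom helical radius — standard
#' alpha-helix geometry) whose vertical axes sit on a circle of radius
#' `bundle_radius`, alternating up/down so consecutive helices connect
#' top-to-top and bottom-to-bottom through smooth loop arcs that bulge
#' away from the membrane slab. The z < 0 side is taken as cytoplasmic
#' and the first helix runs upward, giving the inverted-OR topology
#' (cytoplasmic N-terminus) when tails default to the N-side bottom.
#'
#' @param n_helices number of TM helices (default 7).
#' @param helix_len residues per helix (default 21).
#' @param n_tail,c_tail tail lengths in residues.
#' @param loop_lengths integer vector of the `n_helices - 1` loop
#'   lengths.
#' @param rise,twist_deg,helix_radius ideal helix geometry.
#' @param bundle_radius placement circle radius in Angstrom.
#' @param jitter Gaussian coordinate noise sigma in Angstrom.
#' @return A list of class `bundle_sim_spec`.
#' @export
bundle_sim_spec <- function(n_helices = 7L, helix_len = 21L, n_tail = 10L,
                            c_tail = 28L,
                            loop_lengths = c(10L, 45L, 35L, 60L, 10L, 55L),
                            rise = 1.5, twist_deg = 100, helix_radius = 2.3,
                            bundle_radius = 8.5, jitter = 0.2) {
  if (n_helices < 1L || helix_len < 2L) stop_validation("need >= 1 helix of >= 2 residues")
  if (length(loop_lengths) != n_helices - 1L) {
    stop_validation("loop_lengths must have n_helices - 1 entries")
  }
  if (any(loop_lengths < 1L) || n_tail < 0L || c_tail < 0L) {
    stop_validation("loop and tail lengths must be non-negative (loops >= 1)")
  }
  total <- n_tail + n_helices * helix_len + sum(loop_lengths) + c_tail
  structure(list(n_helices = as.integer(n_helices), helix_len = as.integer(helix_len),
                 n_tail = as.integer(n_tail), c_tail = as.integer(c_tail),
                 loop_lengths = as.integer(loop_lengths), rise = rise,
                 twist_deg = twist_deg, helix_radius = helix_radius,
                 bundle_radius = bundle_radius, jitter = jitter,
                 total = as.integer(total)),
            class = "bundle_sim_spec")
}

# m interior points along a circular arc from p to q in the plane
# spanned by the chord and the bulge direction u, with (near-)uniform
# consecutive spacing so nearest-neighbor distances in loops match the
# CA-CA step. The arc radius is chosen so total arc length is
# spacing * (m + 1); when the chord alone is longer than that, points
# fall back to linear interpolation.
loop_arc <- function(p, q, m, u, spacing = 3.8) {
  chord_vec <- q - p
  c_len <- sqrt(sum(chord_vec^2))
  c_hat <- chord_vec / c_len
  u_perp <- u - sum(u * c_hat) * c_hat
  if (sqrt(sum(u_perp^2)) < 1e-8) {           # u parallel to chord: any normal
    u_perp <- c(-c_hat[2], c_hat[1], 0)
    if (sqrt(sum(u_perp^2)) < 1e-8) u_perp <- c(0, -c_hat[3], c_hat[2])
  }
  u_hat <- u_perp / sqrt(sum(u_perp^2))
  s_len <- spacing * (m + 1)
  frac <- seq_len(m) / (m + 1)
  if (s_len <= c_len * 1.001) {
    return(t(vapply(frac, function(f) p + f * chord_vec, numeric(3))))
  }
  # solve arc half-angle phi from arc/chord ratio: s/c = phi / sin(phi)
  ratio <- s_len / c_len
  phi <- stats::uniroot(function(x) x / sin(x) - ratio,
                        lower = 1e-6, upper = pi - 1e-6)$root
  r <- c_len / (2 * sin(phi))
  center <- (p + q) / 2 - r * cos(phi) * u_hat  # signed: arcs can exceed a semicircle
  # sweep from p to q through the bulge at equal angular steps
  ang <- (2 * frac - 1) * phi                  # -phi..phi excluding ends
  t(vapply(ang, function(a) {
    center + r * sin(a) * c_hat + r * cos(a) * u_hat
  }, numeric(3)))
}

#' Simulate an idealized helix-bundle CA structure
#'
#' @param spec a [bundle_sim_spec()].
#' @param seed integer seed (used for the coordinate jitter).
#' @return List with `structure` (a `ca_structure`), `topology` (the
#'   matching [topology_spec()], TM ranges = helical segments,
#'   cytoplasmic N-terminus), and `truth` (data.frame `position`,
#'   `class` in `exposed`/`buried`: loop/tail residues and
#'   outward-facing helix residues are `exposed`, inward-facing helix
#'   residues `buried`).
#' @export
simulate_bundle <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "bundle_sim_spec"))
  set.seed(seed)
  k <- spec$n_helices
  hl <- spec$helix_len
  rise <- spec$rise
  omega <- spec$twist_deg * pi / 180
  a <- spec$helix_radius
  R <- spec$bundle_radius
  zhalf <- (hl - 1L) * rise / 2
  centers <- t(vapply(seq_len(k), function(i) {
    th <- 2 * pi * (i - 1) / k
    c(R * cos(th), R * sin(th))
  }, numeric(2)))

  helix_xyz <- function(i) {
    up <- (i %% 2L) == 1L
    idx <- seq_len(hl) - 1L
    z <- if (up) -zhalf + idx * rise else zhalf - idx * rise
    phi <- idx * omega + 2 * pi * (i - 1) / k     # phase offset per helix
    cbind(centers[i, 1] + a * cos(phi),
          centers[i, 2] + a * sin(phi),
          z)
  }

  helices <- lapply(seq_len(k), helix_xyz)
  coords <- NULL
  tm_start <- integer(k); tm_end <- integer(k)
  pos <- spec$n_tail

  # N tail: walk down and outward from the first helix start (bottom)
  h1 <- helices[[1L]]
  out_dir <- c(centers[1, ] / sqrt(sum(centers[1, ]^2)), 0)
  ntail <- if (spec$n_tail > 0L) {
    t(vapply(rev(seq_len(spec$n_tail)), function(j) {
      h1[1L, ] + j * 3.8 * (0.4 * out_dir + c(0, 0, -1)) / sqrt(1 + 0.16)
    }, numeric(3)))
  } else NULL
  coords <- rbind(coords, ntail)

  for (i in seq_len(k)) {
    tm_start[i] <- pos + 1L
    coords <- rbind(coords, helices[[i]])
    pos <- pos + hl
    tm_end[i] <- pos
    if (i < k) {
      m <- spec$loop_lengths[i]
      p <- helices[[i]][hl, ]
      q <- helices[[i + 1L]][1L, ]
      mid <- (centers[i, ] + centers[i + 1L, ]) / 2
      radial <- c(mid / sqrt(sum(mid^2)), 0)
      vertical <- c(0, 0, if ((i %% 2L) == 1L) 1 else -1)  # odd helix ends on top
      u <- 0.5 * radial + vertical
      u <- u / sqrt(sum(u^2))
      coords <- rbind(coords, loop_arc(p, q, m, u))
      pos <- pos + m
    }
  }

  # C tail: walk up/out from the last helix end
  hk <- helices[[k]]
  out_dir <- c(centers[k, ] / sqrt(sum(centers[k, ]^2)), 0)
  zdir <- if ((k %% 2L) == 1L) 1 else -1
  ctail <- if (spec$c_tail > 0L) {
    t(vapply(seq_len(spec$c_tail), function(j) {
      hk[hl, ] + j * 3.8 * (0.4 * out_dir + c(0, 0, zdir)) / sqrt(1 + 0.16)
    }, numeric(3)))
  } else NULL
  coords <- rbind(coords, ctail)

  stopifnot(nrow(coords) == spec$total)
  if (spec$jitter > 0) {
    coords <- coords + matrix(rnorm(length(coords), 0, spec$jitter), ncol = 3L)
  }

  res <- data.frame(resno = seq_len(spec$total), resid = "ALA",
                    x = round(coords[, 1], 3), y = round(coords[, 2], 3),
                    z = round(coords[, 3], 3), stringsAsFactors = FALSE)
  structure_ca <- structure(list(residues = res, chain = "A", source = "simulate_bundle"),
                            class = "ca_structure")
  topo <- topology_spec(spec$total, cbind(tm_start, tm_end), "cytoplasmic")

  # ground truth: loop/tail residues and outward-facing helix residues
  # are exposed; inward-facing helix residues are buried
  in_helix <- logical(spec$total)
  for (i in seq_len(k)) in_helix[tm_start[i]:tm_end[i]] <- TRUE
  radial_dist <- sqrt(coords[, 1]^2 + coords[, 2]^2)
  cls <- ifelse(!in_helix | radial_dist > R, "exposed",
                ifelse(radial_dist < R - 1, "buried", "intermediate"))
  truth <- data.frame(position = seq_len(spec$total), class = cls,
                      stringsAsFactors = FALSE)
  list(structure = structure_ca, topology = topo, truth = truth)
}

#' Write a self-contained demo fixture
#'
#' Generates a coordinated family + structure + topology dataset: the
#' bundle defines the protein length and TM ranges, the family is
#' simulated at the same reference length, and key residues (fully
#' conserved, surface-placed) plus decoys (conserved but buried) are
#' planted with their positions recorded in a truth JSON. The fixture
#' loads through [run_pipeline()] unchanged.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; the fixture is byte-reproducible given the
#'   seed.
#' @param bundle_spec a [bundle_sim_spec()].
#' @param n_keys planted key residues, one per distinct extracellular
#'   loop apex (at most the number of extracellular loops).
#' @param n_buried_decoys planted conserved-but-buried helix residues.
#' @param fraction_invariant,fraction_fast background column class
#'   fractions passed to [family_sim_spec()]; set
#'   `fraction_invariant = 0` (with `fraction_fast = 1` and a deep
#'   `mean_pairwise`) for recovery experiments where the planted keys
#'   must be the only highly conserved sites.
#' @param mean_pairwise tree depth passed to [family_sim_spec()].
#' @return List with the file `paths`, the planted `truth`, and the
#'   simulated objects.
#' @export
write_fixture <- function(dir, seed = 42L, bundle_spec = bundle_sim_spec(),
                          n_keys = 3L, n_buried_decoys = 2L,
                          fraction_invariant = 0.20, fraction_fast = 0.54,
                          mean_pairwise = 0.7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulate_bundle(bundle_spec, seed = seed)
  ann <- derive_regions(bundle$topology)

  # keys: apex (middle) residues of extracellular loops, most exposed
  el <- ann$table[grepl("^EL", ann$table$label) & ann$table$length > 0L, ]
  if (n_keys > nrow(el)) stop_validation("more keys requested than extracellular loops")
  keys <- vapply(seq_len(n_keys), function(i) {
    as.integer((el$start[i] + el$end[i]) %/% 2)
  }, integer(1))

  # decoys: inward-facing (buried) residues of the masked TM helices
  buried <- bundle$truth$position[bundle$truth$class == "buried"]
  tm_mask <- candidate_mask(ann, "loops_plus_full_tms", tm_min_index = 3L)
  decoy_pool <- intersect(buried, tm_mask$positions)
  decoys <- head(decoy_pool, n_buried_decoys)

  fspec <- family_sim_spec(L = bundle_spec$total,
                           fraction_invariant = fraction_invariant,
                           fraction_fast = fraction_fast,
                           mean_pairwise = mean_pairwise,
                           planted = c(keys, decoys))
  fam <- simulate_family(fspec, seed = seed + 1L)

  paths <- list(alignment = file.path(dir, "family.fasta"),
                pdb = file.path(dir, "structure.pdb"),
                topology = file.path(dir, "topology.tsv"),
                truth = file.path(dir, "truth.json"))
  write_fasta(fam$family, paths$alignment)
  write_ca(bundle$structure, paths$pdb)
  write_topology(bundle$topology, paths$topology)
  truth <- list(seed = seed, protein_length = bundle_spec$total,
                keys = keys, buried_decoys = decoys)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  list(paths = paths, truth = truth, family = fam$family,
       bundle = bundle, annotation = ann)
}
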