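#' Pipeline configuration
#'
#' Collects the paths, thresholds and switches of the full
#' residue-prioritization run. Thresholds follow the published
#' conventions: candidate selection keeps residues with conservation
#' `>= candidate_threshold` (default 0.9) inside the candidate-region
#' mask; the reporting thresholds `t_var`/`t_high` classify columns for
#' the conservation summary.
#'
#' @param alignment path to the aligned family FASTA.
#' @param pdb path to the CA structure (PDB).
#' @param topology path to the topology file ([read_topology()]).
#' @param reference reference sequence id (default: first record).
#' @param candidate_threshold conservation threshold for selection.
#' @param t_var,t_high summary classification thresholds.
#' @param mask_mode,tm_min_index,w candidate-region rule, see
#'   [candidate_mask()].
#' @param radius CA neighbor radius in Angstrom.
#' @param norm_scope `"candidates"` (normalize exposure over the selected
#'   candidates, the default) or `"all"` (over every residue).
#' @param top_k number of key residues reported after ranking.
#' @param phylogeny logical; run the JTT/NJ/bootstrap stage (report-only;
#'   selection never depends on the tree).
#' @param replicates bootstrap replicate count.
#' @param outgroup optional taxon label used to root the written tree
#'   for display.
#' @param pdb_offset integer added to PDB residue numbers to map them
#'   onto the 1-based reference numbering.
#' @param seed integer seed for the bootstrap stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment, pdb, topology, reference = NULL,
                            candidate_threshold = 0.9, t_var = 0.7, t_high = 0.9,
                            mask_mode = "loops_plus_full_tms", tm_min_index = 3L,
                            w = 4L, radius = 8.0,
                            norm_scope = c("candidates", "all"), top_k = 5L,
                            phylogeny = TRUE, replicates = 100L,
                            outgroup = NULL, pdb_offset = 0L, seed = 1L) {
  norm_scope <- match.arg(norm_scope)
  for (th in c(candidate_threshold = candidate_threshold, t_var = t_var, t_high = t_high)) {
    if (!is.numeric(th) || th < 0 || th > 1) {
      stop_validation("thresholds must lie in [0, 1]")
    }
  }
  if (top_k < 1L) stop_validation("top_k must be >= 1")
  if (replicates < 1L) stop_validation("replicates must be >= 1")
  structure(list(alignment = alignment, pdb = pdb, topology = topology,
                 reference = reference,
                 candidate_threshold = candidate_threshold,
                 t_var = t_var, t_high = t_high,
                 mask_mode = mask_mode, tm_min_index = as.integer(tm_min_index),
                 w = as.integer(w), radius = radius, norm_scope = norm_scope,
                 top_k = as.integer(top_k), phylogeny = isTRUE(phylogeny),
                 replicates = as.integer(replicates), outgroup = outgroup,
                 pdb_offset = as.integer(pdb_offset), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the directory of the config file.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_validation("reading YAML configs requires the 'yaml' package")
  }
  if (!file.exists(path)) stop_format(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("alignment", "pdb", "topology")) {
    if (!is.null(vals[[key]]) && !grepl("^/", vals[[key]])) {
      vals[[key]] <- file.path(base, vals[[key]])
    }
  }
  do.call(pipeline_config, vals)
}

#' Select preliminary candidate residues
#'
#' A residue is a preliminary candidate when its conservation score is at
#' or above the threshold *and* its position lies inside the
#' candidate-region mask. The selection is a pure set intersection:
#' order-independent, monotone in the threshold and in the mask.
#'
#' @param res_conservation named numeric vector of conservation by
#'   reference position ([residue_conservation()]).
#' @param residues named character vector of reference residue letters
#'   ([reference_residues()]).
#' @param mask a [candidate_mask()].
#' @param threshold conservation threshold (selection uses `>=`).
#' @param annotation optional [derive_regions()] result; adds the
#'   `region` column.
#' @return data.frame with `position`, `residue`, `conservation` and
#'   (with `annotation`) `region`, ordered by position; unranked.
#' @export
select_candidates <- function(res_conservation, residues, mask, threshold = 0.9,
                              annotation = NULL) {
  stopifnot(inherits(mask, "candidate_mask"))
  npos <- length(res_conservation)
  if (npos != mask$protein_length) {
    stop_consistency(sprintf(
      "coordinate systems disagree: alignment reference has %d positions but the topology covers %d residues",
      npos, mask$protein_length))
  }
  pos <- as.integer(names(res_conservation))
  keep <- res_conservation >= threshold & pos %in% mask$positions
  sel <- pos[keep]
  out <- data.frame(position = sel,
                    residue = unname(residues[as.character(sel)]),
                    conservation = unname(res_conservation[keep]),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    out$region <- annotation$labels[out$position]
  }
  out[order(out$position), , drop = FALSE]
}

#' Rank candidate residues by exposure
#'
#' Joins the exposure table onto the candidates and orders them by
#' descending normalized score, breaking ties by smaller `Ni`, then
#' larger `Di`, then smaller position. The result is truncated to
#' `top_k` rows and given 1-based contiguous ranks.
#'
#' @param candidates output of [select_candidates()].
#' @param asa an exposure table with `resno`, `Ni`, `Di`, `raw`,
#'   `normalized` (see [asa_scores()]); `resno` must be in reference
#'   numbering.
#' @param top_k number of rows kept.
#' @return data.frame with the candidate columns plus `Ni`, `Di`, `raw`,
#'   `normalized`, `rank`.
#' @export
rank_candidates <- function(candidates, asa, top_k = 5L) {
  if (nrow(candidates) == 0L) {
    out <- cbind(candidates, Ni = integer(0), Di = numeric(0), raw = numeric(0),
                 normalized = numeric(0), rank = integer(0))
    return(out)
  }
  idx <- match(candidates$position, asa$resno)
  if (anyNA(idx)) {
    stop_consistency(sprintf(
      "candidate position(s) missing from the structure: %s",
      paste(candidates$position[is.na(idx)], collapse = ", ")))
  }
  out <- cbind(candidates, asa[idx, c("Ni", "Di", "raw", "normalized"), drop = FALSE])
  ord <- order(-out$normalized, out$Ni, -out$Di, out$position)
  out <- out[ord, , drop = FALSE]
  out <- head(out, top_k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full residue-prioritization pipeline
#'
#' Executes conservation scoring, the (optional) JTT/NJ/bootstrap
#' phylogeny, topology annotation, exposure scoring, candidate selection
#' and ranking, and writes a deterministic report bundle:
#' `conservation.tsv`, `candidates.tsv` (all selected candidates with
#' exposure columns and ranks, `top_k` marked), `distances.tsv`,
#' `distances.phy`, `tree.nwk`, and `manifest.json` (config, seed,
#' package version, input checksums). Floating-point report fields are
#' rounded to 4 decimals at serialization; identical config and inputs
#' give byte-identical outputs. Any stage failure aborts the run with
#' the stage name and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with `candidates` (ranked, full precision),
#'   `all_candidates`, `profile`, `summary`, `tree` (or `NULL`), `dm`
#'   (or `NULL`), `mask`, `annotation`, `files`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  for (key in c("alignment", "pdb", "topology")) {
    if (!is.character(config[[key]]) || !file.exists(config[[key]])) {
      stop_validation(sprintf("input file for '%s' not found: %s", key, config[[key]]))
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(outdir, name)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  res <- tryCatch({
    stage <- "conservation"
    family <- read_fasta(config$alignment, aligned = TRUE, reference = config$reference)
    profile <- conservation_profile(family)
    summ <- summarize_conservation(profile, config$t_var, config$t_high)
    res_cons <- residue_conservation(profile)
    ref_res <- reference_residues(family)
    write_conservation_tsv(profile, out("conservation.tsv"))

    tree <- NULL; dm <- NULL
    if (config$phylogeny) {
      stage <- "phylogeny"
      model <- jtt_model()
      dm <- distance_matrix(family, model)
      tree <- bootstrap_support(family, model, replicates = config$replicates,
                                seed = config$seed)
      write_distance_tsv(dm, out("distances.tsv"))
      write_distance_phylip(dm, out("distances.phy"))
      write_newick(tree, out("tree.nwk"), outgroup = config$outgroup)
    }

    stage <- "topology"
    topo <- read_topology(config$topology)
    annotation <- derive_regions(topo)
    mask <- candidate_mask(annotation, mode = config$mask_mode,
                           tm_min_index = config$tm_min_index, w = config$w)

    stage <- "exposure"
    structure_ca <- read_ca(config$pdb)
    structure_ca$residues$resno <- structure_ca$residues$resno + config$pdb_offset
    n_ref <- length(res_cons)
    n_str <- nrow(structure_ca$residues)
    if (n_ref != topo$protein_length || n_str != topo$protein_length) {
      stop_consistency(sprintf(
        "lengths disagree: alignment reference %d, topology %d, structure %d residues",
        n_ref, topo$protein_length, n_str))
    }
    ns <- asa_scores(structure_ca, radius = config$radius, normalize = TRUE)

    stage <- "selection"
    cands <- select_candidates(res_cons, ref_res, mask,
                               threshold = config$candidate_threshold,
                               annotation = annotation)

    stage <- "ranking"
    asa_tab <- ns
    if (config$norm_scope == "candidates" && nrow(cands) > 0L) {
      sub <- ns[ns$resno %in% cands$position, , drop = FALSE]
      asa_tab$normalized <- NA_real_
      asa_tab$normalized[match(sub$resno, asa_tab$resno)] <- normalize_scores(sub$raw)
    }
    ranked_all <- rank_candidates(cands, asa_tab, top_k = nrow(cands))
    ranked <- head(ranked_all, config$top_k)

    stage <- "report"
    rep_tab <- ranked_all
    rep_tab$key_residue <- rep_tab$rank <= config$top_k
    for (cc in c("conservation", "Di", "raw", "normalized")) {
      rep_tab[[cc]] <- round(rep_tab[[cc]], 4)
    }
    write.table(rep_tab, out("candidates.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- list(
      package = "orsite",
      version = as.character(utils::packageVersion("orsite")),
      config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
      inputs = list(
        alignment = unname(tools::md5sum(config$alignment)),
        pdb = unname(tools::md5sum(config$pdb)),
        topology = unname(tools::md5sum(config$topology))),
      n_candidates = nrow(cands),
      conservation = list(L = summ$L, mean = round(summ$mean, 4),
                          median = round(summ$median, 4),
                          n_high = summ$n_high, n_variable = summ$n_variable))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    list(candidates = ranked, all_candidates = ranked_all, profile = profile,
         summary = summ, tree = tree, dm = dm, mask = mask,
         annotation = annotation, files = written)
  }, orsite_error = function(e) {
    unlink(written)
    stop_orsite(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
                class(e)[1L])
  })
  invisible(res)
}
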