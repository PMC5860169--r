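# End-to-end orchestration: distance matrix -> support tree -> clusters ->
# taxon-support report, plus full settings-grid evaluation with two-step
# Pareto selection.

read_genome_inputs <- function(genomes, seq_type) {
  if (is.character(genomes))
    genomes <- lapply(genomes, read_genome_fasta, seq_type = seq_type)
  stopifnot(all(vapply(genomes, inherits, TRUE, "genome_record")))
  genomes
}

#' Run the full classification workflow
#'
#' Builds the distance matrix (with pseudo-bootstrap replicates), infers the
#' neighbour-joining tree, midpoint-roots it, annotates branch support from
#' the replicate trees, clusters each rank at the supplied or default
#' thresholds and, when a taxonomy is given, scores taxon support per rank.
#' With `out_dir` set, all artifacts are written (PHYLIP matrix plus
#' numbered replicate matrices, Newick support tree, cluster and
#' taxon-support TSVs, and a run log); a partially written output directory
#' is removed on failure.
#'
#' @param genomes List of [genome_record()]s or character vector of FASTA
#'   paths.
#' @param settings A [gbdp_settings()]; its `seq_type` must match the
#'   genomes.
#' @param taxonomy Optional taxonomy tibble (see [read_taxonomy()]).
#' @param thresholds Optional named numeric vector of per-rank thresholds;
#'   defaults to [default_rank_thresholds()] for the settings' sequence
#'   type.
#' @param f Linkage fraction for clustering.
#' @param out_dir Optional output directory.
#' @return An object of class `gbdp_run`: `matrix` (`gbdp_dist`), `tree`
#'   (rooted, support-annotated), `clusters` (tibble with one row per
#'   genome and rank), `taxon_support` (list of [taxon_support()] results
#'   per rank), `settings`, `log`.
#' @export
run_gbdp <- function(genomes, settings = NULL, taxonomy = NULL,
                     thresholds = NULL, f = 0.5, out_dir = NULL) {
  seq_type <- if (!is.null(settings)) settings$seq_type
              else if (!is.character(genomes)) genomes[[1L]]$seq_type
              else "nucleotide"
  genomes <- read_genome_inputs(genomes, seq_type)
  if (is.null(settings)) settings <- gbdp_settings(genomes[[1L]]$seq_type)
  if (length(genomes) < 2L) stop("need at least 2 genomes", call. = FALSE)
  if (length(genomes) > 100L)
    warning("more than 100 genomes; expect long runtimes", call. = FALSE)
  types <- unique(vapply(genomes, function(g) g$seq_type, ""))
  if (length(types) != 1L || types != settings$seq_type)
    stop("sequence type mismatch between genomes and settings", call. = FALSE)
  if (any(vapply(genomes, function(g) isTRUE(g$incomplete), TRUE)) &&
      settings$formula != "d4")
    warning("some input genomes are flagged incomplete; formula d4 is ",
            "recommended for incomplete genome sequences", call. = FALSE)
  if (is.null(thresholds)) {
    th <- default_rank_thresholds()
    th <- th[th$seq_type == settings$seq_type, ]
    thresholds <- stats::setNames(th$threshold, th$rank)
  }

  created <- !is.null(out_dir) && !dir.exists(out_dir)
  result <- tryCatch({
    m <- build_matrix(genomes, settings)
    tree <- midpoint_root(nj_tree(m))
    tree <- if (length(m$replicates) > 0)
      branch_support(tree, lapply(m$replicates, nj_tree))
    else { tree$node.label <- rep("100", tree$Nnode); tree }

    clusters <- bind_rows(lapply(names(thresholds), function(rk) {
      threshold_cluster(m, thresholds[[rk]], f) |>
        mutate(rank = rk, threshold = thresholds[[rk]])
    }))

    ts <- NULL
    if (!is.null(taxonomy)) {
      ranks <- intersect(c("species", "genus", "subfamily", "family"),
                         names(taxonomy))
      ranks <- ranks[vapply(ranks, function(rk)
        any(nzchar(taxonomy[[rk]][match(tree$tip.label, taxonomy$genome_id)])),
        TRUE)]
      ts <- lapply(ranks, function(rk) taxon_support(tree, taxonomy, rk))
      names(ts) <- ranks
    }

    log <- c(
      paste0("virotax ", as.character(utils::packageVersion("virotax"))),
      paste0("genomes: ", length(genomes)),
      paste0("seq_type: ", settings$seq_type),
      paste0("word_length: ", settings$word_length),
      paste0("evalue_max: ", format(settings$evalue_max)),
      paste0("algorithm: ", settings$algorithm),
      paste0("formula: ", settings$formula),
      paste0("replicates: ", settings$n_replicates),
      paste0("seed: ", settings$seed),
      paste0("F: ", f),
      paste0("thresholds: ",
             paste(names(thresholds), format(thresholds), sep = "=",
                   collapse = " "))
    )

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_phylip_matrix(m, file.path(out_dir, "distances.phylip"))
      for (r in seq_along(m$replicates))
        write_phylip_matrix(m$replicates[[r]],
                            file.path(out_dir, sprintf("distances_rep%03d.phylip", r)))
      write_newick(tree, file.path(out_dir, "tree.nwk"))
      utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(ts)) {
        rep_all <- bind_rows(lapply(ts, tidy))
        utils::write.table(rep_all, file.path(out_dir, "taxon_support.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        log <- c(log, vapply(ts, function(x)
          paste0("taxon_support ", x$rank, ": ", format(round(x$overall, 4))),
          ""))
      }
      writeLines(log, file.path(out_dir, "run_log.txt"))
    }
    structure(list(matrix = m, tree = tree, clusters = clusters,
                   taxon_support = ts, settings = settings, log = log),
              class = "gbdp_run")
  }, error = function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    stop(e)
  })
  result
}

#' @export
print.gbdp_run <- function(x, ...) {
  cat("<gbdp_run> ", length(x$matrix$labels), " genomes (",
      x$settings$seq_type, ", ", x$settings$formula, ", ",
      x$settings$algorithm, ")\n", sep = "")
  if (!is.null(x$taxon_support)) {
    for (ts in x$taxon_support)
      cat("  taxon support [", ts$rank, "]: ", round(ts$overall, 4), "\n",
          sep = "")
  }
  invisible(x)
}

# point + per-replicate summaries for both directions of a pair, given the
# retained HSP lists; replicate RNG streams identical to pair_distance()
pair_summary_bundle <- function(ret_ab, ret_ba, algorithm, seed, id_a, id_b,
                                n_replicates) {
  point <- list(ab = resample_summary(ret_ab, algorithm),
                ba = resample_summary(ret_ba, algorithm))
  reps <- lapply(seq_len(n_replicates), function(r) {
    with_seed(pair_seed(seed, id_a, id_b, r), {
      res_ab <- if (nrow(ret_ab) > 0)
        ret_ab[sample.int(nrow(ret_ab), nrow(ret_ab), TRUE), , drop = FALSE]
        else ret_ab
      res_ba <- if (nrow(ret_ba) > 0)
        ret_ba[sample.int(nrow(ret_ba), nrow(ret_ba), TRUE), , drop = FALSE]
        else ret_ba
      list(ab = resample_summary(res_ab, algorithm),
           ba = resample_summary(res_ba, algorithm))
    })
  })
  list(point = point, reps = reps)
}

#' Evaluate the full settings grid
#'
#' For every settings point, builds the distance matrix (HSPs are computed
#' once per sequence type at the most permissive e-value and re-filtered),
#' scores taxon support per rank on the midpoint-rooted support tree, and
#' optimises the clustering threshold per rank for the agreement index.
#' Settings are then flagged by the two-step Pareto selection within each
#' sequence type.
#'
#' @param genomes_nt,genomes_aa Genome lists per sequence type (either may
#'   be `NULL`; grid rows without data are skipped).
#' @param taxonomy Reference taxonomy tibble (required).
#' @param grid Settings grid from [settings_grid()].
#' @param ranks Ranks scored as objectives.
#' @param f Linkage fraction.
#' @param n_replicates Pseudo-bootstrap replicates per settings point.
#' @param seed Seed for the replicate streams.
#' @return Grid tibble with objective columns `ts_<rank>` / `mri_<rank>` and
#'   Pareto flags from [two_step_selection()].
#' @export
evaluate_grid <- function(genomes_nt = NULL, genomes_aa = NULL, taxonomy,
                          grid = settings_grid(), ranks = c("species", "genus", "family"),
                          f = 0.5, n_replicates = 100L, seed = 1L) {
  if (missing(taxonomy) || is.null(taxonomy))
    stop("a reference taxonomy is required", call. = FALSE)
  sets <- list(nucleotide = genomes_nt, amino_acid = genomes_aa)
  grid <- grid[vapply(grid$seq_type, function(st) !is.null(sets[[st]]), TRUE), ,
               drop = FALSE]
  if (nrow(grid) == 0L) stop("no genomes supplied for any grid row", call. = FALSE)

  rows <- vector("list", nrow(grid))
  for (st in unique(grid$seq_type)) {
    genomes <- sets[[st]]
    ids <- vapply(genomes, function(g) g$genome_id, "")
    n <- length(genomes)
    gsub <- which(grid$seq_type == st)
    scheme <- scoring_scheme(st, word_length = grid$word_length[gsub[1L]])
    pairs <- utils::combn(n, 2L)
    hsps <- lapply(seq_len(ncol(pairs)), function(k) {
      bidirectional_hsps(genomes[[pairs[1L, k]]], genomes[[pairs[2L, k]]],
                         scheme, evalue_max = max(grid$evalue_max[gsub]))
    })
    for (gi in gsub) {
      ev <- grid$evalue_max[gi]
      alg <- grid$algorithm[gi]
      frm <- grid$formula[gi]
      values <- matrix(0, n, n, dimnames = list(ids, ids))
      reps <- replicate(n_replicates, values, simplify = FALSE)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        ab <- filter(hsps[[k]]$ab, .data$evalue <= ev)
        ba <- filter(hsps[[k]]$ba, .data$evalue <= ev)
        f_ab <- filter_hsps(ab, alg)
        f_ba <- filter_hsps(ba, alg)
        bundle <- pair_summary_bundle(f_ab$hsps, f_ba$hsps, alg, seed,
                                      ids[i], ids[j], n_replicates)
        l_i <- genomes[[i]]$total_length; l_j <- genomes[[j]]$total_length
        dd <- function(su) (formula_distance(su$ab, l_i, l_j, frm) +
                              formula_distance(su$ba, l_j, l_i, frm)) / 2
        values[i, j] <- values[j, i] <- dd(bundle$point)
        for (r in seq_len(n_replicates))
          reps[[r]][i, j] <- reps[[r]][j, i] <- dd(bundle$reps[[r]])
      }
      settings <- gbdp_settings(st, word_length = grid$word_length[gi],
                                evalue_max = ev, algorithm = alg,
                                formula = frm, n_replicates = n_replicates,
                                seed = seed)
      m <- new_gbdp_dist(ids, values, reps, settings)
      tree <- midpoint_root(nj_tree(m))
      tree <- if (n_replicates > 0)
        branch_support(tree, lapply(m$replicates, nj_tree))
      else { tree$node.label <- rep("100", tree$Nnode); tree }
      row <- grid[gi, ]
      for (rk in ranks) {
        ts <- taxon_support(tree, taxonomy, rk)
        fit <- rank_pipeline(m, taxonomy, rk, f)
        row[[paste0("ts_", rk)]] <- ts$overall
        row[[paste0("mri_", rk)]] <- fit$mri
      }
      rows[[gi]] <- row
    }
  }
  scores <- bind_rows(rows)
  two_step_selection(scores,
                     support_cols = paste0("ts_", ranks),
                     mri_cols = paste0("mri_", ranks))
}
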