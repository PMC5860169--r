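# Distance formulas, direction averaging, pseudo-bootstrap replication and
# distance-matrix assembly.

#' Canonical e-value filter settings
#'
#' The six e-value thresholds explored in the settings grid.
#' @return Numeric vector.
#' @export
gbdp_evalue_filters <- function() c(10, 1, 1e-1, 1e-2, 1e-3, 1e-8)

#' Distance formula registry
#'
#' The three normative formulas are `d0` (matched fraction of the summed
#' genome lengths, a gene-content signal), `d4` (identities per alignment
#' column, robust against incomplete genomes) and `d6` (identities per summed
#' genome length, combining both signals). With `all = TRUE` the registry is
#' padded with seven placeholder variants (content/combined/column families
#' over `2*min` or `2*max` genome-length denominators) whose only purpose is
#' to enumerate the full ten-formula grid shape; they are this package's
#' stubs, not formulas taken from the genome-distance literature, and are off
#' by default.
#'
#' @param all Include the placeholder formulas.
#' @return Character vector of formula names.
#' @export
gbdp_formulas <- function(all = FALSE) {
  if (all) paste0("d", 0:9) else c("d0", "d4", "d6")
}

#' Intergenomic distance from a match summary
#'
#' With `A` = matched positions over both genomes
#' (`matched_query + matched_subject`), `C` = retained alignment columns and
#' `I` = retained identities:
#' \deqn{d_0 = 1 - A/(L_A+L_B), \quad d_4 = 1 - I/C, \quad d_6 = 1 - 2I/(L_A+L_B)}
#' `d4` is defined as 1 when `C = 0` (no retained alignment); all results are
#' clamped to `[0, 1]`.
#'
#' @param summary One-row match summary from [greedy_trim()] /
#'   [coverage_filter()].
#' @param l_query,l_subject Total genome lengths of query and subject.
#' @param formula Formula name from [gbdp_formulas()].
#' @return Distance in `[0, 1]`.
#' @export
formula_distance <- function(summary, l_query, l_subject,
                             formula = c("d0", "d4", "d6", "d1", "d2", "d3",
                                         "d5", "d7", "d8", "d9")) {
  formula <- match.arg(formula)
  stopifnot(l_query > 0, l_subject > 0)
  A <- summary$matched_query + summary$matched_subject
  C <- summary$columns
  I <- summary$identities
  if (any(c(A, C, I) < 0))
    stop("negative match-summary fields", call. = FALSE)
  lsum <- l_query + l_subject
  lmin2 <- 2 * min(l_query, l_subject)
  lmax2 <- 2 * max(l_query, l_subject)
  d <- switch(formula,
    d0 = 1 - A / lsum,
    d4 = if (C == 0) 1 else 1 - I / C,
    d6 = 1 - 2 * I / lsum,
    # placeholder registry stubs (see gbdp_formulas)
    d1 = 1 - A / lmin2,
    d2 = 1 - A / lmax2,
    d3 = 1 - 2 * I / lmin2,
    d5 = 1 - 2 * I / lmax2,
    d7 = 1 - 2 * C / lsum,
    d8 = 1 - C / lmin2 * 2,
    d9 = 1 - C / lmax2 * 2
  )
  min(max(d, 0), 1)
}

#' GBDP parameter settings
#'
#' One point in the parameter grid. Defaults are the optimal settings for
#' each sequence type: amino acid = word length 3, e-value 0.1, trimming,
#' d6; nucleotide = word length 11, e-value 1.0, trimming, d0.
#'
#' @param seq_type `"nucleotide"` or `"amino_acid"`.
#' @param word_length Seed word length; default 11 (nucleotide) / 3
#'   (amino acid).
#' @param evalue_max E-value filter; canonically one of
#'   [gbdp_evalue_filters()].
#' @param algorithm HSP filtering algorithm, `"trimming"` or `"coverage"`.
#' @param formula Distance formula, see [gbdp_formulas()].
#' @param n_replicates Number of pseudo-bootstrap replicates.
#' @param seed Integer seed for the replicate resampling streams.
#' @return An object of class `gbdp_settings`.
#' @export
gbdp_settings <- function(seq_type = c("amino_acid", "nucleotide"),
                          word_length = NULL, evalue_max = NULL,
                          algorithm = c("trimming", "coverage"),
                          formula = NULL, n_replicates = 100L, seed = 1L) {
  seq_type <- match.arg(seq_type)
  algorithm <- match.arg(algorithm)
  if (is.null(word_length))
    word_length <- if (seq_type == "nucleotide") 11L else 3L
  if (is.null(evalue_max))
    evalue_max <- if (seq_type == "nucleotide") 1.0 else 0.1
  if (is.null(formula))
    formula <- if (seq_type == "nucleotide") "d0" else "d6"
  formula <- match.arg(formula, gbdp_formulas(all = TRUE))
  stopifnot(evalue_max > 0, n_replicates >= 0)
  structure(
    list(seq_type = seq_type, word_length = as.integer(word_length),
         evalue_max = evalue_max, algorithm = algorithm, formula = formula,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "gbdp_settings"
  )
}

#' @export
print.gbdp_settings <- function(x, ...) {
  cat("<gbdp_settings> ", x$seq_type, ", word ", x$word_length,
      ", e-value ", format(x$evalue_max), ", ", x$algorithm, ", ",
      x$formula, ", ", x$n_replicates, " replicates, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# distance of one direction from a filtered summary
direction_distance <- function(summary, l_q, l_s, formula) {
  formula_distance(summary, l_q, l_s, formula)
}

# resampled summaries for replicate r of one pair; the RNG stream is keyed by
# (seed, unordered pair, replicate) so results do not depend on computation
# order. Draws: first the A->B indices, then B->A, in one stream.
replicate_distance <- function(ret_ab, ret_ba, l_a, l_b, settings,
                               id_a, id_b, r) {
  with_seed(pair_seed(settings$seed, id_a, id_b, r), {
    res_ab <- if (nrow(ret_ab) > 0)
      ret_ab[sample.int(nrow(ret_ab), nrow(ret_ab), replace = TRUE), ,
             drop = FALSE] else ret_ab
    res_ba <- if (nrow(ret_ba) > 0)
      ret_ba[sample.int(nrow(ret_ba), nrow(ret_ba), replace = TRUE), ,
             drop = FALSE] else ret_ba
    d_ab <- direction_distance(resample_summary(res_ab, settings$algorithm),
                               l_a, l_b, settings$formula)
    d_ba <- direction_distance(resample_summary(res_ba, settings$algorithm),
                               l_b, l_a, settings$formula)
    (d_ab + d_ba) / 2
  })
}

#' Intergenomic distance of one genome pair
#'
#' Finds HSPs in both search directions, filters them with the settings'
#' algorithm, computes the distance formula per direction and averages the
#' two directions (which enforces symmetry). Pseudo-bootstrap replicates
#' resample each direction's retained HSP list with replacement (same count)
#' and recompute the formula from the resampled summaries without
#' re-filtering.
#'
#' @param genome_a,genome_b [genome_record()] objects of equal `seq_type`.
#' @param settings A [gbdp_settings()].
#' @param hsps_ab,hsps_ba Optional external hit tables per direction
#'   (see [bidirectional_hsps()]).
#' @param scheme Optional [scoring_scheme()] (built from the settings when
#'   absent).
#' @return A list with `distance` and numeric `replicates`.
#' @export
pair_distance <- function(genome_a, genome_b, settings = gbdp_settings(),
                          hsps_ab = NULL, hsps_ba = NULL, scheme = NULL) {
  if (genome_a$seq_type != settings$seq_type)
    stop("settings sequence type does not match the genomes", call. = FALSE)
  if (is.null(scheme) && is.null(hsps_ab) && is.null(hsps_ba))
    scheme <- scoring_scheme(settings$seq_type,
                             word_length = settings$word_length)
  hh <- bidirectional_hsps(genome_a, genome_b, scheme, settings$evalue_max,
                           hsps_ab, hsps_ba)
  f_ab <- filter_hsps(hh$ab, settings$algorithm)
  f_ba <- filter_hsps(hh$ba, settings$algorithm)
  l_a <- genome_a$total_length; l_b <- genome_b$total_length
  d_ab <- direction_distance(f_ab$summary, l_a, l_b, settings$formula)
  d_ba <- direction_distance(f_ba$summary, l_b, l_a, settings$formula)
  reps <- vapply(seq_len(settings$n_replicates), function(r)
    replicate_distance(f_ab$hsps, f_ba$hsps, l_a, l_b, settings,
                       genome_a$genome_id, genome_b$genome_id, r), 0)
  list(distance = (d_ab + d_ba) / 2, replicates = reps)
}

new_gbdp_dist <- function(labels, values, replicates, settings) {
  labels <- unname(labels)
  dimnames(values) <- list(labels, labels)
  replicates <- lapply(replicates, function(r) {
    dimnames(r) <- list(labels, labels)
    r
  })
  structure(list(labels = labels, values = values, replicates = replicates,
                 settings = settings),
            class = "gbdp_dist")
}

#' Pairwise intergenomic distance matrix
#'
#' Computes [pair_distance()] for every unordered genome pair and assembles
#' the symmetric distance matrix (diagonal 0) together with the replicate
#' matrices, assembled replicate-wise. Deterministic for a fixed settings
#' seed, independently of genome input order.
#'
#' @param genomes List of [genome_record()] objects with unique ids.
#' @inheritParams pair_distance
#' @return An object of class `gbdp_dist`: fields `labels`, `values`
#'   (symmetric matrix), `replicates` (list of matrices), `settings`.
#' @export
build_matrix <- function(genomes, settings = gbdp_settings()) {
  ids <- vapply(genomes, function(g) g$genome_id, "")
  if (anyDuplicated(ids))
    stop("duplicate genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  n <- length(genomes)
  if (n < 2L) stop("need at least 2 genomes", call. = FALSE)
  scheme <- scoring_scheme(settings$seq_type,
                           word_length = settings$word_length)
  values <- matrix(0, n, n)
  reps <- replicate(settings$n_replicates, matrix(0, n, n), simplify = FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pd <- pair_distance(genomes[[i]], genomes[[j]], settings,
                          scheme = scheme)
      values[i, j] <- values[j, i] <- pd$distance
      for (r in seq_along(reps))
        reps[[r]][i, j] <- reps[[r]][j, i] <- pd$replicates[r]
    }
  }
  new_gbdp_dist(ids, values, reps, settings)
}

#' @export
as.matrix.gbdp_dist <- function(x, ...) x$values

#' @export
print.gbdp_dist <- function(x, ...) {
  cat("<gbdp_dist> ", length(x$labels), " genomes, ",
      length(x$replicates), " replicate matrices (",
      x$settings$seq_type, ", ", x$settings$algorithm, ", ",
      x$settings$formula, ")\n", sep = "")
  print(utils::head(round(x$values, 4), 6L))
  invisible(x)
}

#' @method tidy gbdp_dist
#' @export
tidy.gbdp_dist <- function(x, ...) {
  m <- x$values
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(genome_a = x$labels[idx[, 1]], genome_b = x$labels[idx[, 2]],
         distance = m[idx])
}

#' Default per-rank clustering thresholds
#'
#' The distance thresholds delineating taxa at each rank under the optimal
#' settings for each sequence type (threshold optimisation against the
#' reference taxonomy; subfamily thresholds from the reduced
#' subfamily-annotated set).
#'
#' @return Tibble with columns `seq_type`, `rank`, `threshold`.
#' @export
default_rank_thresholds <- function() {
  tibble(
    seq_type = rep(c("amino_acid", "nucleotide"), each = 4L),
    rank = rep(c("species", "genus", "subfamily", "family"), 2L),
    threshold = c(0.118980, 0.749680, 0.888940, 0.985225,
                  0.022085, 0.842700, 0.997270, 0.997455)
  )
}
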