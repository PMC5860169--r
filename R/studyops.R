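# Settings-grid enumeration, Pareto selection and host-specificity
# summaries.

#' Enumerate the GBDP settings grid
#'
#' Full Cartesian grid over sequence type, e-value filter, filtering
#' algorithm and distance formula, in that deterministic order. With the
#' default three-formula registry the grid has 2 x 6 x 2 x 3 = 72 entries;
#' with all ten formula slots enabled, 240.
#'
#' @param seq_types,evalues,algorithms,formulas Grid axes.
#' @return Tibble with one row per settings point (word length filled in per
#'   sequence type).
#' @export
settings_grid <- function(seq_types = c("nucleotide", "amino_acid"),
                          evalues = gbdp_evalue_filters(),
                          algorithms = c("trimming", "coverage"),
                          formulas = gbdp_formulas()) {
  tidyr::expand_grid(seq_type = seq_types, evalue_max = evalues,
                     algorithm = algorithms, formula = formulas) |>
    mutate(word_length = ifelse(.data$seq_type == "nucleotide", 11L, 3L),
           .after = "seq_type")
}

dominates <- function(a, b) all(a >= b) && any(a > b)

#' Pareto frontier of a set of points
#'
#' Returns exactly the non-dominated rows (point p dominates q when p is at
#' least as good on every objective and strictly better on at least one),
#' preserving input order.
#'
#' @param points Data frame of points.
#' @param objectives Names of the objective columns.
#' @param maximize Logical: maximise (default) or minimise all objectives.
#' @return The non-dominated subset of `points`.
#' @export
pareto_front <- function(points, objectives, maximize = TRUE) {
  if (nrow(points) == 0L) return(points)
  obj <- as.matrix(points[, objectives, drop = FALSE])
  if (!maximize) obj <- -obj
  keep <- vapply(seq_len(nrow(obj)), function(i) {
    !any(vapply(seq_len(nrow(obj)), function(j)
      j != i && dominates(obj[j, ], obj[i, ]), TRUE))
  }, TRUE)
  points[keep, , drop = FALSE]
}

#' Two-step Pareto selection of GBDP settings
#'
#' Within each sequence type, the Pareto frontier on the three per-rank
#' taxon-support objectives is computed first; the resulting subset is then
#' reduced by the frontier on the three per-rank agreement-index (MRI)
#' objectives. The step order matters: a setting dominated on taxon support
#' is excluded even if it excels on MRI.
#'
#' @param scores Tibble with a `seq_type` column plus the six objective
#'   columns.
#' @param support_cols,mri_cols Objective column names.
#' @return `scores` with added logical columns `pareto_support` (survived
#'   step one) and `selected` (survived both steps).
#' @export
two_step_selection <- function(scores,
                               support_cols = c("ts_species", "ts_genus", "ts_family"),
                               mri_cols = c("mri_species", "mri_genus", "mri_family")) {
  if (nrow(scores) == 0L) {
    scores$pareto_support <- logical(0)
    scores$selected <- logical(0)
    return(scores)
  }
  scores$.row <- seq_len(nrow(scores))
  scores$pareto_support <- FALSE
  scores$selected <- FALSE
  for (st in unique(scores$seq_type)) {
    sub <- scores[scores$seq_type == st, , drop = FALSE]
    step1 <- pareto_front(sub, support_cols)
    scores$pareto_support[scores$.row %in% step1$.row] <- TRUE
    step2 <- pareto_front(step1, mri_cols)
    scores$selected[scores$.row %in% step2$.row] <- TRUE
  }
  scores$.row <- NULL
  scores
}

#' Host specificity of clusters
#'
#' Berger-Parker style index `m/N` per cluster, with `N` the number of
#' genomes carrying a non-empty host annotation and `m` the frequency of the
#' most frequent host. Host names are standardised "Genus species" strings;
#' at the genus rank only the first token is compared. Rows whose host
#' string contains no alphabetic token are skipped with a warning; clusters
#' with `N = 0` are omitted.
#'
#' @param partition Partition tibble or named vector (see [mri()]).
#' @param hosts Tibble with columns `genome_id`, `host`.
#' @param host_rank `"species"` (full name) or `"genus"` (first token).
#' @return Tibble with columns `cluster`, `n_hosts`, `modal_count`, `index`,
#'   `modal_host` (ties: lexicographically smallest modal host).
#' @export
host_specificity <- function(partition, hosts, host_rank = c("species", "genus")) {
  host_rank <- match.arg(host_rank)
  part <- as_partition_vec(partition)
  df <- tibble(genome_id = names(part), cluster = unname(part)) |>
    left_join(hosts, by = "genome_id") |>
    mutate(host = trimws(gsub("[[:space:]]+", " ", .data$host)))
  df <- df[!is.na(df$host) & nzchar(df$host), , drop = FALSE]
  bad <- !grepl("[[:alpha:]]", df$host)
  if (any(bad)) {
    warning(sum(bad), " host entr", if (sum(bad) == 1) "y" else "ies",
            " without an alphabetic token skipped", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (host_rank == "genus")
    df$host <- vapply(strsplit(df$host, " ", fixed = TRUE), `[`, "", 1L)
  df |>
    group_by(.data$cluster) |>
    summarise(
      n_hosts = dplyr::n(),
      modal_count = max(table(.data$host)),
      index = .data$modal_count / .data$n_hosts,
      modal_host = {
        tab <- table(.data$host)
        sort(names(tab)[tab == max(tab)])[1L]
      },
      .groups = "drop"
    )
}
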