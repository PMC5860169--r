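# Threshold clustering with linkage fraction F, the partition-agreement
# index, and threshold optimisation against a reference taxonomy.

# normalise a partition (tibble genome_id/cluster, named vector, or factor)
# to a named character vector
as_partition_vec <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(all(c("genome_id", "cluster") %in% names(p)))
    return(stats::setNames(as.character(p$cluster), p$genome_id))
  }
  if (is.null(names(p))) stop("partition must be named", call. = FALSE)
  stats::setNames(as.character(p), names(p))
}

partition_tbl <- function(members, labels) {
  # members: list of integer index blocks; deterministic cluster names by
  # smallest member label
  blocks <- lapply(members, function(ix) sort(labels[ix]))
  blocks <- blocks[order(vapply(blocks, `[`, "", 1L))]
  bind_rows(lapply(seq_along(blocks), function(b)
    tibble(genome_id = blocks[[b]], cluster = sprintf("c%03d", b)))) |>
    arrange(.data$genome_id)
}

#' Threshold clustering with linkage fraction F
#'
#' Pairs at distance `d <= threshold` are links. Starting from singletons,
#' the cluster pair (P, Q) maximising the link fraction
#' `f = links(P,Q) / (|P|*|Q|)` is merged, subject to `f >= F` and at least
#' one link; ties on `f` are broken by the smallest minimum inter-cluster
#' distance, then by the lexicographically smallest member labels. Merging
#' stops when no pair qualifies. `F = 0` gives single linkage (connected
#' components of the link graph), `F = 1` complete linkage (every cluster a
#' clique).
#'
#' @param m A `gbdp_dist` or symmetric labelled matrix.
#' @param threshold Distance threshold `T`.
#' @param f Linkage fraction `F` in `[0, 1]`; default 0.5.
#' @return Partition tibble with columns `genome_id`, `cluster`.
#' @export
threshold_cluster <- function(m, threshold, f = 0.5) {
  if (inherits(m, "gbdp_dist")) m <- as.matrix(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), f >= 0, f <= 1)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(m)))
  n <- nrow(m)
  link <- m <= threshold
  diag(link) <- FALSE
  members <- lapply(seq_len(n), identity)
  repeat {
    best <- NULL
    for (p in seq_along(members)) {
      for (q in seq_along(members)) {
        if (q <= p) next
        P <- members[[p]]; Q <- members[[q]]
        nl <- sum(link[P, Q])
        if (nl < 1L) next
        frac <- nl / (length(P) * length(Q))
        if (frac < f) next
        mind <- min(m[P, Q])
        key <- sort(c(min(labels[P]), min(labels[Q])))
        cand <- list(p = p, q = q, frac = frac, mind = mind, key = key)
        if (is.null(best) ||
            cand$frac > best$frac + 1e-12 ||
            (abs(cand$frac - best$frac) <= 1e-12 &&
             (cand$mind < best$mind - 1e-12 ||
              (abs(cand$mind - best$mind) <= 1e-12 &&
               (cand$key[1] < best$key[1] ||
                (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    members[[best$p]] <- c(members[[best$p]], members[[best$q]])
    members[[best$q]] <- NULL
  }
  partition_tbl(members, labels)
}

#' Partition agreement index (MRI)
#'
#' Chance-corrected agreement between two partitions of the same elements,
#' realised as the Hubert-Arabie adjusted Rand index computed from the
#' pair-count contingency table. Equals 1 exactly for identical partitions
#' and decreases with disagreement (it can be negative).
#'
#' @param p1,p2 Partitions: tibbles with `genome_id`/`cluster` columns or
#'   named vectors.
#' @return A number `<= 1`.
#' @export
mri <- function(p1, p2) {
  v1 <- as_partition_vec(p1)
  v2 <- as_partition_vec(p2)
  if (!setequal(names(v1), names(v2)))
    stop("partitions cover different element sets", call. = FALSE)
  v2 <- v2[names(v1)]
  ct <- table(v1, v2)
  choose2 <- function(x) x * (x - 1) / 2
  a <- sum(choose2(ct))
  ra <- sum(choose2(rowSums(ct)))
  rb <- sum(choose2(colSums(ct)))
  npairs <- choose2(length(v1))
  expected <- ra * rb / npairs
  maxidx <- (ra + rb) / 2
  if (abs(maxidx - expected) < 1e-12) return(1)  # both partitions trivial
  (a - expected) / (maxidx - expected)
}

new_threshold_fit <- function(threshold, mri, partition, scan, f, rank = NA_character_) {
  structure(list(threshold = threshold, mri = mri, partition = partition,
                 scan = scan, f = f, rank = rank),
            class = "threshold_fit")
}

#' Optimise the clustering threshold against a reference partition
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' off-diagonal distances, plus one value below the minimum and one above
#' the maximum (the agreement index is piecewise constant in the threshold,
#' so the midpoints cover every attainable clustering). Returns the
#' candidate maximising the agreement index; ties take the smallest
#' threshold.
#'
#' @param m A `gbdp_dist` or symmetric labelled matrix.
#' @param reference Reference partition covering all matrix labels.
#' @param f Linkage fraction, default 0.5.
#' @return A `threshold_fit`: `threshold`, `mri`, `partition` and the full
#'   `scan` tibble (`threshold`, `mri`, `n_clusters`).
#' @export
optimize_threshold <- function(m, reference, f = 0.5) {
  if (inherits(m, "gbdp_dist")) m <- as.matrix(m)
  ref <- as_partition_vec(reference)
  labels <- rownames(m)
  if (!all(labels %in% names(ref)))
    stop("reference partition does not cover all matrix labels", call. = FALSE)
  ref <- ref[labels]
  d <- sort(unique(m[upper.tri(m)]))
  gap <- if (length(d) > 1L) min(diff(d)) / 2 else max(abs(d[1L]) / 2, 1e-6)
  gap <- max(gap, 1e-9)
  cands <- c(d[1L] - gap,
             if (length(d) > 1L) (d[-length(d)] + d[-1L]) / 2,
             d[length(d)] + gap)
  scan <- lapply(cands, function(tt) {
    part <- threshold_cluster(m, tt, f)
    tibble(threshold = tt, mri = mri(part, ref),
           n_clusters = length(unique(part$cluster)))
  })
  scan <- bind_rows(scan)
  best <- which.max(scan$mri)  # first maximum = smallest threshold
  part <- threshold_cluster(m, scan$threshold[best], f)
  new_threshold_fit(scan$threshold[best], scan$mri[best], part, scan, f)
}

#' Per-rank clustering pipeline
#'
#' Drops genomes with an empty value at the requested rank (e.g. species not
#' assigned to a genus when analysing the genus rank), then either optimises
#' the threshold against the taxonomy reduced to that rank, or — when
#' `threshold` is supplied — clusters at that fixed threshold and reports
#' its agreement.
#'
#' @inheritParams optimize_threshold
#' @param taxonomy Tibble with `genome_id` and rank columns.
#' @param rank Rank column to use.
#' @param threshold Optional fixed threshold (skips optimisation).
#' @return A `threshold_fit` (its `rank` field set).
#' @export
rank_pipeline <- function(m, taxonomy, rank, f = 0.5, threshold = NULL) {
  if (inherits(m, "gbdp_dist")) m <- as.matrix(m)
  if (!rank %in% names(taxonomy))
    stop("taxonomy has no rank column '", rank, "'", call. = FALSE)
  tax <- taxonomy[match(rownames(m), taxonomy$genome_id), ]
  val <- tax[[rank]]
  val[is.na(val)] <- ""
  keep <- nzchar(val)
  if (!any(keep))
    stop("no genomes with a non-empty '", rank, "' assignment", call. = FALSE)
  m2 <- m[keep, keep, drop = FALSE]
  ref <- stats::setNames(val[keep], rownames(m)[keep])
  if (is.null(threshold)) {
    fit <- optimize_threshold(m2, ref, f)
  } else {
    part <- threshold_cluster(m2, threshold, f)
    fit <- new_threshold_fit(threshold, mri(part, ref), part,
                             tibble(threshold = threshold,
                                    mri = mri(part, ref),
                                    n_clusters = length(unique(part$cluster))),
                             f)
  }
  fit$rank <- rank
  fit
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("<threshold_fit>", if (!is.na(x$rank)) paste0(" rank ", x$rank), " T = ",
      format(x$threshold), ", MRI = ", round(x$mri, 4), ", ",
      length(unique(x$partition$cluster)), " clusters (F = ", x$f, ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy threshold_fit
#' @export
tidy.threshold_fit <- function(x, ...) x$scan

#' @method glance threshold_fit
#' @export
glance.threshold_fit <- function(x, ...) {
  tibble(rank = x$rank, threshold = x$threshold, mri = x$mri,
         n_clusters = length(unique(x$partition$cluster)), f = x$f)
}
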