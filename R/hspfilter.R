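# The two GBDP filters correcting for overlapping / paralogous matches before
# distances are computed. Both process HSPs in decreasing raw score (ties:
# longer first, then input order). All interval arithmetic is on 0-based
# half-open forward-strand coordinates, kept separately per sequence record
# (relevant in amino-acid mode, where coordinates live in per-protein space).

check_one_pair <- function(hsps) {
  if (nrow(hsps) == 0L) return(invisible(TRUE))
  if (length(unique(hsps$query_id)) > 1L ||
      length(unique(hsps$subject_id)) > 1L)
    stop("HSPs must all belong to one ordered genome pair", call. = FALSE)
  invisible(TRUE)
}

order_hsps <- function(hsps) {
  score <- hsps$raw_score
  if (anyNA(score)) score[is.na(score)] <- hsps$bit_score[is.na(score)]
  hsps[order(-score, -hsps$length), , drop = FALSE]
}

# per-record union width, summed over records
union_width <- function(starts, ends, recs) {
  if (length(starts) == 0L) return(0)
  total <- 0
  for (r in unique(recs)) {
    i <- recs == r
    total <- total + iv_width(iv_merge(cbind(starts[i], ends[i])))
  }
  total
}

# summary of an already-filtered (or resampled) HSP multiset: union-based
# matched positions, total alignment columns and identities
plain_summary <- function(hsps) {
  tibble(
    matched_query = union_width(hsps$q_start, hsps$q_end, hsps$q_rec),
    matched_subject = union_width(hsps$s_start, hsps$s_end, hsps$s_rec),
    columns = sum(hsps$length),
    identities = sum(hsps$identities),
    n_hsps = nrow(hsps)
  )
}

#' Greedy-with-trimming HSP filter
#'
#' HSPs are accepted in decreasing score order; each candidate is shortened
#' by `t = max(overlap_q, overlap_s)` columns, where the overlaps count
#' candidate positions already occupied by previously accepted HSPs on the
#' query and subject genome respectively. Columns are removed from the
#' overlapping end(s): the side with the larger overlap contributes its
#' contiguous covered run at the left end, the remainder is taken from the
#' right end, and the removal is mirrored onto the other genome
#' (strand-aware). Shortening repeats until the candidate no longer overlaps
#' occupied positions, which makes the filter idempotent; candidates trimmed
#' to length 0 are dropped. Identities are scaled proportionally
#' (`id * len'/len`, kept real-valued).
#'
#' @param hsps Tibble of HSPs of one ordered genome pair.
#' @return A list with `hsps` (retained, trimmed) and `summary` (one-row
#'   tibble: `matched_query`, `matched_subject`, `columns`, `identities`,
#'   `n_hsps`).
#' @export
greedy_trim <- function(hsps) {
  check_one_pair(hsps)
  hsps <- order_hsps(hsps)
  occ_q <- list()
  occ_s <- list()
  keep <- logical(nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    qr <- hsps$q_rec[i]; sr <- hsps$s_rec[i]
    if (is.null(occ_q[[qr]])) occ_q[[qr]] <- iv_empty()
    if (is.null(occ_s[[sr]])) occ_s[[sr]] <- iv_empty()
    qs <- hsps$q_start[i]; qe <- hsps$q_end[i]
    ss <- hsps$s_start[i]; se <- hsps$s_end[i]
    minus <- hsps$strand[i] == "-"
    len0 <- hsps$length[i]
    len <- len0
    dropped <- FALSE
    repeat {
      ov_q <- iv_overlap(occ_q[[qr]], qs, qe)
      ov_s <- iv_overlap(occ_s[[sr]], ss, se)
      tr <- max(ov_q, ov_s)
      if (tr == 0) break
      if (tr >= len) { dropped <- TRUE; break }
      if (ov_q >= ov_s) {
        l <- min(iv_left_run(occ_q[[qr]], qs, qe), tr)
        rl_q <- l; rr_q <- tr - l
        rl_s <- if (minus) rr_q else rl_q
        rr_s <- if (minus) rl_q else rr_q
      } else {
        l <- min(iv_left_run(occ_s[[sr]], ss, se), tr)
        rl_s <- l; rr_s <- tr - l
        rl_q <- if (minus) rr_s else rl_s
        rr_q <- if (minus) rl_s else rr_s
      }
      qs <- qs + rl_q; qe <- qe - rr_q
      ss <- ss + rl_s; se <- se - rr_s
      len <- len - tr
      if (len <= 0 || qe <= qs || se <= ss) { dropped <- TRUE; break }
    }
    if (dropped) next
    keep[i] <- TRUE
    hsps$q_start[i] <- qs; hsps$q_end[i] <- qe
    hsps$s_start[i] <- ss; hsps$s_end[i] <- se
    hsps$identities[i] <- hsps$identities[i] * len / len0
    hsps$length[i] <- len
    occ_q[[qr]] <- iv_add(occ_q[[qr]], qs, qe)
    occ_s[[sr]] <- iv_add(occ_s[[sr]], ss, se)
  }
  retained <- hsps[keep, , drop = FALSE]
  list(hsps = retained, summary = plain_summary(retained))
}

# core of the coverage algorithm, callable on resampled multisets
coverage_summary <- function(hsps) {
  hsps <- order_hsps(hsps)
  occ_q <- list()
  occ_s <- list()
  id_acc <- 0
  for (i in seq_len(nrow(hsps))) {
    qr <- hsps$q_rec[i]; sr <- hsps$s_rec[i]
    if (is.null(occ_q[[qr]])) occ_q[[qr]] <- iv_empty()
    if (is.null(occ_s[[sr]])) occ_s[[sr]] <- iv_empty()
    qs <- hsps$q_start[i]; qe <- hsps$q_end[i]
    new_q <- (qe - qs) - iv_overlap(occ_q[[qr]], qs, qe)
    if (hsps$length[i] > 0)
      id_acc <- id_acc + hsps$identities[i] * new_q / hsps$length[i]
    occ_q[[qr]] <- iv_add(occ_q[[qr]], qs, qe)
    occ_s[[sr]] <- iv_add(occ_s[[sr]], hsps$s_start[i], hsps$s_end[i])
  }
  matched_q <- sum(vapply(occ_q, iv_width, 0))
  matched_s <- sum(vapply(occ_s, iv_width, 0))
  tibble(matched_query = matched_q, matched_subject = matched_s,
         columns = matched_q, identities = id_acc, n_hsps = nrow(hsps))
}

#' Coverage HSP filter
#'
#' Counts every genome position at most once via per-position interval
#' unions: matched positions are the unions of the query and subject
#' intervals, alignment columns equal the matched query positions, and
#' identities accumulate per HSP (in descending score order) proportionally
#' to its newly covered query positions, so multiply-covered positions
#' contribute once.
#'
#' @inheritParams greedy_trim
#' @return A list with `hsps` (unchanged input, score-sorted) and `summary`
#'   as in [greedy_trim()].
#' @export
coverage_filter <- function(hsps) {
  check_one_pair(hsps)
  hsps <- order_hsps(hsps)
  list(hsps = hsps, summary = coverage_summary(hsps))
}

#' Filter HSPs with either GBDP algorithm
#'
#' @inheritParams greedy_trim
#' @param algorithm `"trimming"` or `"coverage"`.
#' @return As [greedy_trim()] / [coverage_filter()].
#' @export
filter_hsps <- function(hsps, algorithm = c("trimming", "coverage")) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "trimming") greedy_trim(hsps) else coverage_filter(hsps)
}

# summary of a with-replacement resample of a retained HSP list, without
# re-filtering: the trimming branch treats the resampled HSPs as fixed
# (union-based matched positions, additive columns/identities); the coverage
# branch re-applies its per-position accumulation to the multiset
resample_summary <- function(hsps, algorithm) {
  if (algorithm == "trimming") plain_summary(hsps) else coverage_summary(hsps)
}
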