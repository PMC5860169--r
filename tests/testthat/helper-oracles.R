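# Independent oracles and fixture builders used across the suite.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

nt_genome <- function(id, seq) {
  genome_record(id, stats::setNames(seq, id), "nucleotide")
}

# build an HSP tibble row by row (built-in style: ungapped, widths == length)
make_hsps <- function(qs, qe, ss, se, score, identities = NULL,
                      strand = NULL, qid = "A", sid = "B",
                      qrec = "A", srec = "B") {
  n <- length(qs)
  if (is.null(identities)) identities <- qe - qs
  if (is.null(strand)) strand <- rep("+", n)
  tibble::tibble(
    query_id = qid, subject_id = sid,
    q_rec = rep_len(qrec, n), s_rec = rep_len(srec, n),
    q_start = as.integer(qs), q_end = as.integer(qe),
    s_start = as.integer(ss), s_end = as.integer(se),
    strand = strand, length = as.integer(qe - qs),
    identities = as.numeric(identities), raw_score = as.numeric(score),
    bit_score = as.numeric(score), evalue = rep(1e-10, n)
  )
}

# ---- position-level brute force of the greedy trimming rule ----------------
# Applies the identical score-ordered rule on per-position bitmaps: candidate
# shortened by max(overlap_q, overlap_s), removal split between ends via the
# driver side's contiguous end runs (remainder from the right), mirrored onto
# the other genome strand-aware, iterated until no overlap remains.
oracle_trim <- function(hsps, maxlen = 2000L) {
  ord <- order(-hsps$raw_score, -hsps$length)
  hsps <- hsps[ord, , drop = FALSE]
  occ_q <- new.env(parent = emptyenv())
  occ_s <- new.env(parent = emptyenv())
  bitmap <- function(env, rec) {
    if (is.null(env[[rec]])) env[[rec]] <- rep(FALSE, maxlen)
    env[[rec]]
  }
  run_from_left <- function(bits, s, e) {
    # number of consecutive covered positions starting at s (0-based half-open)
    r <- 0L
    for (p in (s + 1L):e) { if (!bits[p]) break; r <- r + 1L }
    r
  }
  keep <- logical(nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    bq <- bitmap(occ_q, hsps$q_rec[i])
    bs <- bitmap(occ_s, hsps$s_rec[i])
    qs <- hsps$q_start[i]; qe <- hsps$q_end[i]
    ss <- hsps$s_start[i]; se <- hsps$s_end[i]
    minus <- hsps$strand[i] == "-"
    len0 <- hsps$length[i]; len <- len0
    dropped <- FALSE
    repeat {
      ov_q <- sum(bq[(qs + 1L):qe])
      ov_s <- sum(bs[(ss + 1L):se])
      tr <- max(ov_q, ov_s)
      if (tr == 0L) break
      if (tr >= len) { dropped <- TRUE; break }
      if (ov_q >= ov_s) {
        l <- min(run_from_left(bq, qs, qe), tr)
        rl_q <- l; rr_q <- tr - l
        rl_s <- if (minus) rr_q else rl_q
        rr_s <- if (minus) rl_q else rr_q
      } else {
        l <- min(run_from_left(bs, ss, se), tr)
        rl_s <- l; rr_s <- tr - l
        rl_q <- if (minus) rr_s else rl_s
        rr_q <- if (minus) rl_s else rr_s
      }
      qs <- qs + rl_q; qe <- qe - rr_q
      ss <- ss + rl_s; se <- se - rr_s
      len <- len - tr
      if (len <= 0L || qe <= qs || se <= ss) { dropped <- TRUE; break }
    }
    if (dropped) next
    keep[i] <- TRUE
    hsps$identities[i] <- hsps$identities[i] * len / len0
    hsps$q_start[i] <- qs; hsps$q_end[i] <- qe
    hsps$s_start[i] <- ss; hsps$s_end[i] <- se
    hsps$length[i] <- len
    bq[(qs + 1L):qe] <- TRUE; occ_q[[hsps$q_rec[i]]] <- bq
    bs[(ss + 1L):se] <- TRUE; occ_s[[hsps$s_rec[i]]] <- bs
  }
  hsps[keep, , drop = FALSE]
}

# random trimming instance: k HSPs on genomes of <= 300 positions
random_trim_instance <- function(k, seed) {
  set.seed(seed)
  qs <- ss <- qe <- se <- score <- integer(k)
  strand <- character(k)
  for (i in seq_len(k)) {
    w <- sample(10:120, 1)
    qs[i] <- sample(0:(300 - w), 1); qe[i] <- qs[i] + w
    ss[i] <- sample(0:(300 - w), 1); se[i] <- ss[i] + w
    strand[i] <- sample(c("+", "-"), 1)
  }
  score <- sample(1000, k)  # distinct scores
  make_hsps(qs, qe, ss, se, score, identities = round((qe - qs) * 0.9, 1),
            strand = strand)
}

# ---- agreement-index oracle: pair-count formulation ------------------------
oracle_ari <- function(v1, v2) {
  v2 <- v2[names(v1)]
  n <- length(v1)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      t1 <- v1[i] == v1[j]; t2 <- v2[i] == v2[j]
      if (t1 && t2) n11 <- n11 + 1
      else if (!t1 && !t2) n00 <- n00 + 1
      else if (t1) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# all set partitions of n elements, as integer block-label vectors
all_partitions <- function(n) {
  grow <- function(assign) {
    if (length(assign) == n) return(list(assign))
    k <- if (length(assign)) max(assign) else 0L
    out <- list()
    for (b in seq_len(k + 1L))
      out <- c(out, grow(c(assign, b)))
    out
  }
  grow(integer(0))
}

# ---- Pareto brute force ----------------------------------------------------
oracle_pareto_keep <- function(obj) {
  n <- nrow(obj)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(obj[j, ] >= obj[i, ]) && any(obj[j, ] > obj[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# ---- exhaustive minimum-change oracle on small rooted trees ----------------
# enumerates all internal-state assignments of the binary membership
# character and returns whether "member" at `node` attains the global
# minimum number of state changes
oracle_mp_member <- function(tree, member_tips, node) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  states <- rep(0L, ntip)
  states[member_tips] <- 1L
  best <- Inf
  best_at_node <- Inf
  for (mask in 0:(2^nn - 1L)) {
    int_states <- as.integer(intToBits(mask))[seq_len(nn)]
    full <- c(states, int_states)
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    if (changes < best) best <- changes
    if (full[node] == 1L && changes < best_at_node) best_at_node <- changes
  }
  best_at_node <= best
}

# unrooted-topology equality
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# hand-built three-clade tree with well-separated rates: 3 species x 3 taxa
three_species_tree <- function() {
  txt <- paste0(
    "((g01:0.005,g02:0.005,g03:0.005):0.15,",
    "(g04:0.005,g05:0.005,g06:0.005):0.15,",
    "(g07:0.005,g08:0.005,g09:0.005):0.15);")
  ape::read.tree(text = txt)
}
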