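# Robinson & Robinson (1991) amino-acid background frequencies, in the order
# ARNDCQEGHILKMFPSTWYV; used for the Karlin-Altschul lambda of the built-in
# protein scorer.
AA_ORDER <- c("A","R","N","D","C","Q","E","G","H","I",
              "L","K","M","F","P","S","T","W","Y","V")
AA_FREQS <- c(0.07805, 0.05129, 0.04487, 0.05364, 0.01925,
              0.04264, 0.06295, 0.07377, 0.02199, 0.05142,
              0.09019, 0.05744, 0.02243, 0.03856, 0.05203,
              0.07120, 0.05841, 0.01330, 0.03216, 0.06441)

#' Scoring scheme for the built-in local aligner
#'
#' Nucleotide mode scores +2/-3 (match/mismatch) with word length 11;
#' amino-acid mode uses BLOSUM62 with word length 3. These are the aligner
#' defaults used throughout; the word lengths are the ones selected as
#' optimal for each sequence type. The Karlin-Altschul parameter lambda is
#' solved from the scores and background frequencies; K is fixed at 0.1 and
#' e-values of the built-in aligner are an internally consistent filter
#' quantity, not a reproduction of any external tool's statistics.
#'
#' @param seq_type `"nucleotide"` or `"amino_acid"`.
#' @param match,mismatch Nucleotide match/mismatch scores (ignored in
#'   amino-acid mode).
#' @param word_length Seed length; defaults to 11 (nucleotide) or 3
#'   (amino acid).
#' @param xdrop Raw-score drop-off terminating ungapped extension.
#' @param K Karlin-Altschul K used in the e-value `K * m * n * exp(-lambda * S)`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(seq_type = c("nucleotide", "amino_acid"),
                           match = 2L, mismatch = -3L,
                           word_length = NULL, xdrop = NULL, K = 0.1) {
  seq_type <- match.arg(seq_type)
  if (seq_type == "nucleotide") {
    if (is.null(word_length)) word_length <- 11L
    if (is.null(xdrop)) xdrop <- 20L
    # codes 0..3 = ACGT (seedable), 4 = any other IUPAC letter
    score <- matrix(as.integer(mismatch), 5L, 5L)
    diag(score)[1:4] <- as.integer(match)
    score[5L, 5L] <- as.integer(mismatch)
    freqs <- rep(0.25, 4)
    n_seed_codes <- 4L
    alphabet <- c("A", "C", "G", "T")
  } else {
    if (is.null(word_length)) word_length <- 3L
    if (is.null(xdrop)) xdrop <- 16L
    data("BLOSUM62", package = "Biostrings", envir = environment())
    b62 <- get("BLOSUM62", envir = environment())
    # codes 0..19 = standard residues (seedable), 20 = X
    alphabet <- c(AA_ORDER, "X")
    score <- b62[alphabet, alphabet]
    storage.mode(score) <- "integer"
    freqs <- AA_FREQS
    n_seed_codes <- 20L
  }
  scheme <- structure(
    list(seq_type = seq_type, score = unname(score), alphabet = alphabet,
         n_seed_codes = n_seed_codes, word_length = as.integer(word_length),
         xdrop = as.integer(xdrop), K = K, freqs = freqs, lambda = NA_real_),
    class = "scoring_scheme"
  )
  scheme$lambda <- solve_lambda(scheme)
  scheme
}

#' Solve the Karlin-Altschul lambda of a scoring scheme
#'
#' Finds the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` by bisection to 1e-9, where the
#' sum runs over the seedable residues with background frequencies `p`.
#' A valid scheme must have negative expected score per aligned pair.
#'
#' @param scheme A [scoring_scheme()].
#' @return The positive root lambda.
#' @export
solve_lambda <- function(scheme) {
  k <- scheme$n_seed_codes
  s <- scheme$score[seq_len(k), seq_len(k), drop = FALSE]
  p <- scheme$freqs
  pp <- outer(p, p)
  if (sum(pp * s) >= 0)
    stop("invalid scoring scheme: expected score per pair must be negative",
         call. = FALSE)
  if (max(s) <= 0)
    stop("invalid scoring scheme: some score must be positive", call. = FALSE)
  f <- function(lambda) sum(pp * exp(lambda * s)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 1e-9   # exclude the trivial root at lambda = 0 (f'(0) < 0)
  while (f(lo) > 0) lo <- lo / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-9) break
  }
  (lo + hi) / 2
}

# residue string -> integer codes for the C++ scanner
encode_seq <- function(s, scheme) {
  codes <- integer(256)
  codes[] <- scheme$n_seed_codes  # non-seedable catch-all (ambiguity / X)
  codes[utf8ToInt(paste(scheme$alphabet, collapse = ""))] <-
    seq_along(scheme$alphabet) - 1L
  codes[utf8ToInt(s)]
}

revcomp <- function(s) {
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", s)
  intToUtf8(rev(utf8ToInt(comp)))
}

hsp_rows_to_tibble <- function(m, qid, sid, qrec, srec, strand, s_len, scheme,
                               mn) {
  if (nrow(m) == 0L) return(empty_hsps())
  s_start <- m[, "s_start"]; s_end <- m[, "s_end"]
  if (strand == "-") {       # map reverse-complement coordinates to forward
    tmp <- s_len - s_end
    s_end <- s_len - s_start
    s_start <- tmp
  }
  lambda <- scheme$lambda
  tibble(
    query_id = qid, subject_id = sid, q_rec = qrec, s_rec = srec,
    q_start = as.integer(m[, "q_start"]), q_end = as.integer(m[, "q_end"]),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    strand = strand, length = as.integer(m[, "length"]),
    identities = as.numeric(m[, "identities"]),
    raw_score = as.numeric(m[, "raw_score"]),
    bit_score = (lambda * m[, "raw_score"] - log(scheme$K)) / log(2),
    evalue = scheme$K * mn * exp(-lambda * m[, "raw_score"])
  )
}

#' Find high-scoring segment pairs between two genomes
#'
#' Runs the built-in ungapped seed-and-extend aligner: every exact
#' `word_length` match (on both strands in nucleotide mode; between every
#' protein pair in amino-acid mode) is extended in both directions with an
#' X-drop cut-off. E-values are `K * m * n * exp(-lambda * raw_score)` with
#' `m`, `n` the total genome lengths; hits above `evalue_max` are discarded.
#' The result is sorted by descending raw score, ties by query then subject
#' start.
#'
#' @param genome_a,genome_b [genome_record()] objects of the same `seq_type`
#'   (`genome_a` is the query).
#' @param scheme A [scoring_scheme()]; defaults to the standard scheme for
#'   the genomes' sequence type.
#' @param evalue_max E-value filter threshold.
#' @return A tibble of HSPs.
#' @export
find_hsps <- function(genome_a, genome_b, scheme = NULL, evalue_max = 10) {
  stopifnot(inherits(genome_a, "genome_record"),
            inherits(genome_b, "genome_record"))
  if (genome_a$seq_type != genome_b$seq_type)
    stop("genomes have different sequence types (",
         genome_a$seq_type, " vs ", genome_b$seq_type, ")", call. = FALSE)
  if (is.null(scheme)) scheme <- scoring_scheme(genome_a$seq_type)
  if (scheme$seq_type != genome_a$seq_type)
    stop("scoring scheme sequence type does not match the genomes",
         call. = FALSE)
  mn <- as.numeric(genome_a$total_length) * genome_b$total_length
  out <- list()
  for (qi in seq_along(genome_a$sequences)) {
    qseq <- genome_a$sequences[[qi]]
    qcodes <- encode_seq(qseq, scheme)
    for (si in seq_along(genome_b$sequences)) {
      sseq <- genome_b$sequences[[si]]
      scodes <- encode_seq(sseq, scheme)
      hits <- hsp_scan_cpp(qcodes, scodes, scheme$score, scheme$word_length,
                           scheme$xdrop, scheme$n_seed_codes)
      out[[length(out) + 1L]] <- hsp_rows_to_tibble(
        hits, genome_a$genome_id, genome_b$genome_id,
        names(genome_a$sequences)[qi], names(genome_b$sequences)[si],
        "+", nchar(sseq), scheme, mn)
      if (scheme$seq_type == "nucleotide") {
        rc <- encode_seq(revcomp(sseq), scheme)
        hits <- hsp_scan_cpp(qcodes, rc, scheme$score, scheme$word_length,
                             scheme$xdrop, scheme$n_seed_codes)
        out[[length(out) + 1L]] <- hsp_rows_to_tibble(
          hits, genome_a$genome_id, genome_b$genome_id,
          names(genome_a$sequences)[qi], names(genome_b$sequences)[si],
          "-", nchar(sseq), scheme, mn)
      }
    }
  }
  hsps <- bind_rows(out)
  if (nrow(hsps) == 0L) return(empty_hsps())
  hsps |>
    filter(.data$evalue <= evalue_max) |>
    arrange(desc(.data$raw_score), .data$q_start, .data$s_start)
}

# swap query and subject roles of an HSP table
mirror_hsps <- function(hsps) {
  mutate(hsps,
         query_id = hsps$subject_id, subject_id = hsps$query_id,
         q_rec = hsps$s_rec, s_rec = hsps$q_rec,
         q_start = hsps$s_start, q_end = hsps$s_end,
         s_start = hsps$q_start, s_end = hsps$q_end) |>
    arrange(desc(.data$raw_score), .data$q_start, .data$s_start)
}

#' HSPs for both search directions of a genome pair
#'
#' The distance of a genome pair averages the two search directions. For the
#' built-in (symmetric) scorer the B-vs-A hits are the coordinate-swapped
#' mirror of the A-vs-B hits; externally supplied hits for one direction are
#' mirrored the same way when the other direction is absent.
#'
#' @inheritParams find_hsps
#' @param hsps_ab,hsps_ba Optional externally computed hit tables for either
#'   direction.
#' @return A list with elements `ab` and `ba`.
#' @export
bidirectional_hsps <- function(genome_a, genome_b, scheme = NULL,
                               evalue_max = 10,
                               hsps_ab = NULL, hsps_ba = NULL) {
  if (is.null(hsps_ab) && is.null(hsps_ba)) {
    ab <- find_hsps(genome_a, genome_b, scheme, evalue_max)
    return(list(ab = ab, ba = mirror_hsps(ab)))
  }
  if (is.null(hsps_ab)) hsps_ab <- mirror_hsps(hsps_ba)
  if (is.null(hsps_ba)) hsps_ba <- mirror_hsps(hsps_ab)
  list(ab = filter(hsps_ab, .data$evalue <= evalue_max),
       ba = filter(hsps_ba, .data$evalue <= evalue_max))
}
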