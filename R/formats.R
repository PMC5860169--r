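#' Construct a genome record
#'
#' A genome record holds the sequence data of one virus genome: a single DNA
#' sequence in nucleotide mode, or the set of protein sequences of its
#' proteome in amino-acid mode.
#'
#' @param genome_id Character label for the genome.
#' @param sequences Named character vector of residue strings; names are the
#'   record (sequence) identifiers.
#' @param seq_type `"nucleotide"` or `"amino_acid"`.
#' @param n_proteins Number of annotated proteins accompanying the genome
#'   (used by [deduplicate_genomes()]); defaults to the number of records in
#'   amino-acid mode and `NA` otherwise.
#' @param incomplete Logical flag marking the genome sequence as incomplete
#'   (e.g. truncated); [run_gbdp()] recommends the d4 formula for such input.
#'
#' @return An object of class `genome_record` with fields `genome_id`,
#'   `sequences`, `seq_type`, `total_length`, `n_proteins`, `incomplete`.
#' @export
genome_record <- function(genome_id, sequences, seq_type = c("nucleotide", "amino_acid"),
                          n_proteins = NA_integer_, incomplete = FALSE) {
  seq_type <- match.arg(seq_type)
  if (length(sequences) == 0L)
    stop("genome '", genome_id, "': no sequence records", call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- paste0(genome_id, "_", seq_along(sequences))
  sequences <- stats::setNames(toupper(as.character(sequences)),
                               names(sequences))
  validate_residues(sequences, seq_type, genome_id)
  total <- sum(nchar(sequences))
  if (total == 0L)
    stop("genome '", genome_id, "': total sequence length is 0", call. = FALSE)
  if (is.na(n_proteins) && seq_type == "amino_acid")
    n_proteins <- length(sequences)
  structure(
    list(genome_id = genome_id, sequences = sequences, seq_type = seq_type,
         total_length = total, n_proteins = as.integer(n_proteins),
         incomplete = isTRUE(incomplete)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, ": ", length(x$sequences), " ",
      x$seq_type, " record(s), ", x$total_length, " residues\n", sep = "")
  invisible(x)
}

NT_ALPHABET <- "ACGTMRWSYKVHDBN"           # IUPAC DNA
AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYX"     # 20 standard residues plus X

validate_residues <- function(sequences, seq_type, genome_id) {
  alphabet <- if (seq_type == "nucleotide") NT_ALPHABET else AA_ALPHABET
  pat <- paste0("[^", alphabet, "]")
  for (i in seq_along(sequences)) {
    bad <- regexpr(pat, sequences[[i]])
    if (bad > 0L) {
      stop("genome '", genome_id, "', record '", names(sequences)[i],
           "': illegal ", sub("_", "-", seq_type), " residue '",
           substr(sequences[[i]], bad, bad), "' at position ", bad,
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a genome from a FASTA file
#'
#' The genome id is the file name without directory or extension; record ids
#' are FASTA headers up to the first whitespace. Wrapped sequence lines are
#' concatenated.
#'
#' @param path Path to a FASTA file with at least one record.
#' @inheritParams genome_record
#' @return A [genome_record()].
#' @export
read_genome_fasta <- function(path, seq_type = c("nucleotide", "amino_acid")) {
  seq_type <- match.arg(seq_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  seqs <- stats::setNames(as.character(set), ids)
  genome_record(tools::file_path_sans_ext(basename(path)), seqs, seq_type)
}

#' Write a genome record to a FASTA file
#'
#' @param record A [genome_record()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(record, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(record$sequences)) {
    writeLines(paste0(">", names(record$sequences)[i]), con)
    s <- record$sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# canonical empty HSP table; all coordinates 0-based half-open on the forward
# strand (tabular input, 1-based inclusive, is converted on read)
empty_hsps <- function() {
  tibble(query_id = character(), subject_id = character(),
         q_rec = character(), s_rec = character(),
         q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(),
         strand = character(), length = integer(),
         identities = numeric(), raw_score = numeric(),
         bit_score = numeric(), evalue = numeric())
}

#' Read local-alignment hits in 12-column tabular format
#'
#' Parses the standard 12-column tab-separated dialect (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) as written by external local-alignment tools. Identities are
#' reconstructed as `round(pident/100 * length)`; subject coordinates with
#' sstart > send mark the reverse strand and are normalised to forward
#' (min, max) order with `strand = "-"`; all coordinates are stored 0-based
#' half-open.
#'
#' @param path Path to the tabular file.
#' @param query_id,subject_id Genome ids to attach to the hits; default to the
#'   per-line sequence ids.
#' @return A tibble of HSPs (one row per hit).
#' @export
read_alignment_tab <- function(path, query_id = NULL, subject_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hsps())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L)) {
    stop("line ", which(nc != 12L)[1L], ": expected 12 tab-separated columns, found ",
         nc[nc != 12L][1L], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))[1L]
    stop("line ", bad, ": non-numeric value in a numeric column", call. = FALSE)
  }
  pident <- num[, 1]; len <- as.integer(num[, 2])
  qstart <- as.integer(num[, 5]); qend <- as.integer(num[, 6])
  sstart <- as.integer(num[, 7]); send <- as.integer(num[, 8])
  rev <- sstart > send
  tibble(
    query_id = if (is.null(query_id)) m[, 1] else query_id,
    subject_id = if (is.null(subject_id)) m[, 2] else subject_id,
    q_rec = m[, 1], s_rec = m[, 2],
    q_start = qstart - 1L, q_end = qend,
    s_start = ifelse(rev, send, sstart) - 1L,
    s_end = ifelse(rev, sstart, send),
    strand = ifelse(rev, "-", "+"),
    length = len,
    identities = round(pident / 100 * len),
    raw_score = NA_real_,
    bit_score = num[, 10],
    evalue = num[, 9]
  )
}

#' Write HSPs back to the 12-column tabular dialect
#'
#' @param hsps A tibble of HSPs as produced by [find_hsps()] or
#'   [read_alignment_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tab <- function(hsps, path) {
  rev <- hsps$strand == "-"
  df <- data.frame(
    hsps$q_rec, hsps$s_rec,
    sprintf("%.3f", ifelse(hsps$length > 0, 100 * hsps$identities / hsps$length, 0)),
    hsps$length,
    as.integer(round(hsps$length - hsps$identities)), 0L,
    hsps$q_start + 1L, hsps$q_end,
    ifelse(rev, hsps$s_end, hsps$s_start + 1L),
    ifelse(rev, hsps$s_start + 1L, hsps$s_end),
    format(hsps$evalue, digits = 3), sprintf("%.1f", hsps$bit_score)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a square distance matrix in relaxed PHYLIP format
#'
#' The relaxed dialect keeps full-length whitespace-separated labels (genome
#' ids routinely exceed the 10 characters of strict PHYLIP). The first line
#' holds the taxon count; each following line holds a label and a full row of
#' the symmetric matrix.
#'
#' @param m Square symmetric numeric matrix with row/column labels, or a
#'   distance-matrix object from [build_matrix()].
#' @param path File path.
#' @return `write_phylip_matrix()` returns `path` invisibly;
#'   `read_phylip_matrix()` returns a labelled symmetric matrix.
#' @export
write_phylip_matrix <- function(m, path) {
  if (inherits(m, "gbdp_dist")) m <- as.matrix(m)
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("'m' must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-9)
    stop("matrix is asymmetric beyond tolerance 1e-9", call. = FALSE)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(labels[i],
                     paste(formatC(m[i, ], format = "g", digits = 12),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_phylip_matrix
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("malformed PHYLIP file: first line must be the taxon count",
         call. = FALSE)
  if (length(lines) < n + 1L)
    stop("malformed PHYLIP file: expected ", n, " rows", call. = FALSE)
  labels <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(parts) != n + 1L)
      stop("malformed PHYLIP file: row ", i, " has ", length(parts) - 1L,
           " values, expected ", n, call. = FALSE)
    labels[i] <- parts[1L]
    m[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' Write / read trees in Newick format
#'
#' Thin wrappers around [ape::write.tree()] / [ape::read.tree()] that keep
#' integer branch-support values as internal node labels and report malformed
#' parentheses with a character offset.
#'
#' @param tree An [ape::phylo] tree (branch lengths required for writing).
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` returns
#'   an [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("malformed Newick: unmatched ')' at character ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of input (character ",
         nchar(txt), ")", call. = FALSE)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree))
    stop("malformed Newick: could not parse tree", call. = FALSE)
  tree
}

# MD5 checksum of the concatenated upper-case nucleotide sequence
genome_checksum <- function(record) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(record$sequences, collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' Remove duplicate genomes by sequence checksum
#'
#' Genomes with identical MD5 checksums of their concatenated upper-case
#' nucleotide sequence (typically the same genome under distinct annotation
#' versions) are collapsed: the version with the most protein sequences is
#' kept; ties keep the lexicographically smallest genome id.
#'
#' @param records List of [genome_record()] objects (their `n_proteins` field
#'   is the protein count; missing counts are treated as 0).
#' @return The retained records, in input order.
#' @export
deduplicate_genomes <- function(records) {
  if (length(records) == 0L) return(records)
  info <- tibble(
    idx = seq_along(records),
    genome_id = vapply(records, function(r) r$genome_id, ""),
    checksum = vapply(records, genome_checksum, ""),
    n_prot = vapply(records, function(r) {
      p <- r$n_proteins
      if (is.na(p)) 0L else p
    }, 0L)
  )
  keep <- info |>
    group_by(.data$checksum) |>
    arrange(desc(.data$n_prot), .data$genome_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup() |>
    pull(.data$idx)
  records[sort(keep)]
}

#' Read a taxonomy table
#'
#' Tab-separated with a header line; columns `genome_id`, `species`, `genus`,
#' `subfamily`, `family`. Empty strings mark unassigned ranks.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("genome_id", "species", "genus", "subfamily", "family")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$genome_id))
    stop("duplicated genome_id in taxonomy table", call. = FALSE)
  as_tibble(df[need])
}

#' Read a host table
#'
#' Tab-separated with a header line; columns `genome_id` and `host`
#' (standardised "Genus species" names; empty string for unknown hosts).
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_hosts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (!all(c("genome_id", "host") %in% names(df)))
    stop("host table needs columns 'genome_id' and 'host'", call. = FALSE)
  as_tibble(df[c("genome_id", "host")])
}
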