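# Synthetic genome sets evolved along a known tree, with a designed
# taxonomy and host table, so every pipeline stage is testable without
# external data.

#' Specification of a simulated genome set
#'
#' Branch lengths are in expected substitutions per site: each branch of
#' length `b` applies `Poisson(substitution_rate * b * genome_length)`
#' random site replacements (with one of the three other bases, a
#' Jukes-Cantor-like model without rate heterogeneity). Branch lengths are
#' drawn as `brlen_min + Exp(mean = brlen_mean - brlen_min)`; the small
#' floor guarantees that taxa are distinct. Optional block deletions and
#' inversions model structural change, and a truncation fraction applied to
#' designated leaves emulates incomplete genome sequences. Taxonomy ranks
#' are assigned to consecutive leaf blocks of the stated sizes (which must
#' nest), matching clades on balanced trees.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param tree_shape `"balanced"`, `"caterpillar"` or `"random"`.
#' @param genome_length Root genome length in bases.
#' @param substitution_rate Substitution events per site per unit branch
#'   length.
#' @param brlen_mean,brlen_min Mean and floor of branch lengths.
#' @param deletion_rate,inversion_rate Expected structural events per unit
#'   branch length.
#' @param block_mean Mean length (nt) of deleted/inverted blocks.
#' @param truncate_taxa Leaf labels whose genomes are truncated.
#' @param truncation Fraction of the genome removed from the end of
#'   truncated leaves, in `[0, 1)`.
#' @param species_size,genus_size,subfamily_size,family_size Number of
#'   leaves per taxon block at each rank (`NA` leaves the rank unassigned).
#' @param proteome Also derive amino-acid proteomes (fixed-length translated
#'   blocks of the genome; no gene finding).
#' @param protein_length Protein length (aa) of the translated blocks.
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_taxa = 8L, tree_shape = c("balanced", "caterpillar", "random"),
                            genome_length = 20000L, substitution_rate = 1,
                            brlen_mean = 0.02, brlen_min = 0.002,
                            deletion_rate = 0, inversion_rate = 0,
                            block_mean = 200, truncate_taxa = character(0),
                            truncation = 0,
                            species_size = 1L, genus_size = NA_integer_,
                            subfamily_size = NA_integer_, family_size = NA_integer_,
                            proteome = FALSE, protein_length = 300L, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_taxa >= 2, genome_length >= 100, substitution_rate >= 0,
            deletion_rate >= 0, inversion_rate >= 0,
            truncation >= 0, truncation < 1,
            brlen_min >= 0, brlen_mean > brlen_min)
  structure(as.list(environment()), class = "simulation_spec")
}

balanced_newick <- function(labels) {
  if (length(labels) == 1L) return(labels)
  h <- ceiling(length(labels) / 2)
  paste0("(", balanced_newick(labels[seq_len(h)]), ",",
         balanced_newick(labels[-seq_len(h)]), ")")
}

caterpillar_newick <- function(labels) {
  out <- labels[1L]
  for (k in 2:length(labels)) out <- paste0("(", out, ",", labels[k], ")")
  out
}

#' Simulate the true tree of a genome set
#'
#' @param spec A [simulation_spec()].
#' @return A rooted [ape::phylo] tree with branch lengths; deterministic for
#'   the spec's seed.
#' @export
simulate_tree <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$n_taxa < 2L) stop("need n_taxa >= 2", call. = FALSE)
  labels <- sprintf("g%02d", seq_len(spec$n_taxa))
  with_seed(spec$seed, {
    tree <- switch(spec$tree_shape,
      balanced = ape::read.tree(text = paste0(balanced_newick(labels), ";")),
      caterpillar = ape::read.tree(text = paste0(caterpillar_newick(labels), ";")),
      random = {
        tr <- ape::rtopology(spec$n_taxa, rooted = TRUE)
        tr$tip.label <- sample(labels)
        tr
      })
    ne <- nrow(tree$edge)
    tree$edge.length <- spec$brlen_min +
      stats::rexp(ne, rate = 1 / (spec$brlen_mean - spec$brlen_min))
    tree
  })
}

mutate_seq <- function(chars, bl, spec) {
  len <- length(chars)
  bases <- c("A", "C", "G", "T")
  n_sub <- stats::rpois(1L, spec$substitution_rate * bl * len)
  if (n_sub > 0L) {
    pos <- sample.int(len, n_sub, replace = TRUE)
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
  }
  n_del <- stats::rpois(1L, spec$deletion_rate * bl)
  for (k in seq_len(n_del)) {
    if (length(chars) < 200L) break
    w <- 1L + stats::rgeom(1L, 1 / spec$block_mean)
    w <- min(w, length(chars) - 100L)
    start <- sample.int(length(chars) - w + 1L, 1L)
    chars <- chars[-(start:(start + w - 1L))]
  }
  n_inv <- stats::rpois(1L, spec$inversion_rate * bl)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in seq_len(n_inv)) {
    w <- min(1L + stats::rgeom(1L, 1 / spec$block_mean), length(chars))
    start <- sample.int(length(chars) - w + 1L, 1L)
    seg <- chars[start:(start + w - 1L)]
    chars[start:(start + w - 1L)] <- rev(unname(comp[seg]))
  }
  chars
}

rank_blocks <- function(n, size, prefix) {
  if (is.na(size)) return(rep("", n))
  sprintf("%s%02d", prefix, ceiling(seq_len(n) / size))
}

translate_blocks <- function(seq, protein_length) {
  block_nt <- protein_length * 3L
  n_blocks <- max(nchar(seq) %/% block_nt, 1L)
  prots <- character(n_blocks)
  for (b in seq_len(n_blocks)) {
    sub <- substr(seq, (b - 1L) * block_nt + 1L,
                  min(b * block_nt, nchar(seq)))
    sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
    if (nchar(sub) < 3L) next
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
    prots[b] <- gsub("\\*", "X", aa)
  }
  prots[nzchar(prots)]
}

#' Evolve genomes along a tree
#'
#' The root sequence is uniform random; each branch applies substitutions
#' (and optional deletions/inversions), and designated leaves are truncated.
#' Taxonomy and host tables follow the spec's block design: hosts share a
#' genus token within a genus block and a species epithet within a species
#' block, so virus clusters are host-specific by construction.
#'
#' @param tree Tree from [simulate_tree()].
#' @param spec A [simulation_spec()].
#' @return List with `genomes` (nucleotide [genome_record()]s), `proteomes`
#'   (amino-acid records, if `spec$proteome`), `taxonomy` and `hosts`
#'   tibbles.
#' @export
evolve_genomes <- function(tree, spec) {
  stopifnot(inherits(tree, "phylo"), inherits(spec, "simulation_spec"))
  ntip <- ape::Ntip(tree)
  with_seed(spec$seed + 104729L, {
    root_chars <- sample(c("A", "C", "G", "T"), spec$genome_length,
                         replace = TRUE)
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1L]] <- root_chars
    cw <- ape::reorder.phylo(tree, "cladewise")
    pre <- cw$edge
    elen <- cw$edge.length
    for (k in seq_len(nrow(pre))) {
      u <- pre[k, 1]; v <- pre[k, 2]
      seqs[[v]] <- mutate_seq(seqs[[u]], elen[k], spec)
    }
    genomes <- vector("list", ntip)
    for (t in seq_len(ntip)) {
      lab <- tree$tip.label[t]
      chars <- seqs[[t]]
      truncated <- lab %in% spec$truncate_taxa && spec$truncation > 0
      if (truncated) {
        keep <- round((1 - spec$truncation) * length(chars))
        chars <- chars[seq_len(keep)]
      }
      genomes[[t]] <- genome_record(lab,
                                    stats::setNames(paste(chars, collapse = ""), lab),
                                    "nucleotide", incomplete = truncated)
    }
    names(genomes) <- tree$tip.label
    ord <- tree$tip.label  # block design follows the tree's tip order
    taxonomy <- tibble(
      genome_id = ord,
      species = rank_blocks(ntip, spec$species_size, "s"),
      genus = rank_blocks(ntip, spec$genus_size, "gen"),
      subfamily = rank_blocks(ntip, spec$subfamily_size, "sf"),
      family = rank_blocks(ntip, spec$family_size, "fam")
    )
    gblock <- if (is.na(spec$genus_size)) rank_blocks(ntip, spec$species_size, "b")
              else rank_blocks(ntip, spec$genus_size, "b")
    sblock <- rank_blocks(ntip, spec$species_size, "sp")
    hosts <- tibble(
      genome_id = ord,
      host = paste0("Hostus", substring(gblock, 2L), " ", sblock)
    )
    proteomes <- NULL
    if (isTRUE(spec$proteome)) {
      proteomes <- lapply(genomes, function(g) {
        prots <- translate_blocks(g$sequences[[1L]], spec$protein_length)
        genome_record(g$genome_id,
                      stats::setNames(prots, sprintf("%s_p%03d", g$genome_id,
                                                     seq_along(prots))),
                      "amino_acid", incomplete = g$incomplete)
      })
    }
    list(genomes = genomes, proteomes = proteomes, taxonomy = taxonomy,
         hosts = hosts)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_tree()] plus [evolve_genomes()].
#'
#' @param spec A [simulation_spec()].
#' @return List with `tree`, `genomes`, `proteomes`, `taxonomy`, `hosts`.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  tree <- simulate_tree(spec)
  out <- evolve_genomes(tree, spec)
  c(list(tree = tree), out)
}
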