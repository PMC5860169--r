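test_that("FASTA reading concatenates wrapped lines and sums record lengths", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 some description", "MKV", "LA"), f)
  g <- read_genome_fasta(f, "amino_acid")
  expect_equal(g$total_length, 5L)
  expect_equal(length(g$sequences), 1L)
  expect_equal(names(g$sequences), "p1")
  expect_equal(g$genome_id, tools::file_path_sans_ext(basename(f)))

  f2 <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MKV", ">p2", "MKVL"), f2)
  expect_equal(read_genome_fasta(f2, "amino_acid")$total_length, 7L)
})

test_that("illegal residues are rejected with record and position", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MKJLA"), f)
  expect_error(read_genome_fasta(f, "amino_acid"), "p1.*'J' at position 3")
  expect_error(genome_record("g", c(r1 = "ACGU"), "nucleotide"),
               "position 4")
  f3 <- withr::local_tempfile(fileext = ".fna")
  file.create(f3)
  expect_error(read_genome_fasta(f3, "nucleotide"), "no records|parse")
})

test_that("tabular alignment hits are parsed with coordinate normalisation", {
  f <- withr::local_tempfile(fileext = ".tab")
  writeLines(c(
    "A\tB\t100.000\t50\t0\t0\t1\t50\t1\t50\t1e-20\t95.0",
    "A\tB\t90.0\t40\t4\t0\t10\t49\t5\t44\t1e-5\t50.0",
    "A\tB\t95.0\t40\t2\t0\t1\t40\t100\t61\t1e-8\t60.0"), f)
  h <- read_alignment_tab(f)
  expect_equal(nrow(h), 3L)
  expect_equal(h$identities, c(50, 36, 38))  # round(pident/100 * length)
  expect_equal(h$strand, c("+", "+", "-"))
  # 1-based inclusive -> 0-based half-open
  expect_equal(h$q_start[1], 0L)
  expect_equal(h$q_end[1], 50L)
  # reversed subject coordinates (100, 61) -> forward half-open (60, 100)
  expect_equal(h$s_start[3], 60L)
  expect_equal(h$s_end[3], 100L)
  expect_true(all(h$identities <= h$length))
})

test_that("tabular parser reports malformed lines by number", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB\t100\t50\t0\t0\t1\t50\t1\t50\t1e-20\t95.0",
               "A\tB\t100\t50"), f)
  expect_error(read_alignment_tab(f), "line 2.*12")
  f2 <- withr::local_tempfile()
  writeLines("A\tB\t100\t50\t0\t0\tx\t50\t1\t50\t1e-20\t95.0", f2)
  expect_error(read_alignment_tab(f2), "line 1.*non-numeric")
})

test_that("alignment hits round-trip through the tabular dialect", {
  g1 <- nt_genome("qq", random_dna(600, seed = 11))
  g2 <- nt_genome("ss", paste0(substr(g1$sequences[[1]], 100, 400),
                               random_dna(200)))
  h <- find_hsps(g1, g2)
  f <- withr::local_tempfile()
  write_alignment_tab(h, f)
  h2 <- read_alignment_tab(f, query_id = "qq", subject_id = "ss")
  expect_equal(h2$q_start, h$q_start)
  expect_equal(h2$s_start, h$s_start)
  expect_equal(h2$strand, h$strand)
  expect_equal(h2$length, h$length)
})

test_that("PHYLIP square matrices round-trip in the relaxed dialect", {
  m <- matrix(c(0, .5, .5, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  f <- withr::local_tempfile()
  write_phylip_matrix(m, f)
  expect_equal(trimws(readLines(f)[1]), "2")
  expect_equal(read_phylip_matrix(f), m, tolerance = 1e-9)

  m1 <- matrix(0, 1, 1, dimnames = list("only", "only"))
  write_phylip_matrix(m1, f)
  expect_equal(read_phylip_matrix(f), m1)

  labs <- c("Escherichia_virus_Lambda_NC001416", "Bacillus_phage_SPP1_X97")
  set.seed(4)
  v <- runif(1)
  m2 <- matrix(c(0, v, v, 0), 2, dimnames = list(labs, labs))
  write_phylip_matrix(m2, f)
  expect_equal(read_phylip_matrix(f), m2, tolerance = 1e-9)

  set.seed(7)
  r <- matrix(runif(25), 5)
  r <- (r + t(r)) / 2; diag(r) <- 0
  dimnames(r) <- list(paste0("g", 1:5), paste0("g", 1:5))
  write_phylip_matrix(r, f)
  expect_equal(read_phylip_matrix(f), r, tolerance = 1e-9)

  bad <- r; bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(write_phylip_matrix(bad, f), "asymmetric")
})

test_that("Newick I/O preserves topology, lengths and supports", {
  f <- withr::local_tempfile()
  t2 <- ape::read.tree(text = "(A:1,B:2);")
  write_newick(t2, f)
  expect_match(readLines(f), "^\\(A:1,B:2\\);$")
  rt <- read_newick(f)
  expect_equal(sort(rt$tip.label), c("A", "B"))
  expect_equal(sort(rt$edge.length), c(1, 2))

  tq <- ape::read.tree(text = "((A:1,B:1)87:2,(C:1,D:1):1);")
  write_newick(tq, f)
  rq <- read_newick(f)
  expect_true("87" %in% rq$node.label)
  expect_true(same_topology(tq, rq))
  expect_equal(sort(rq$edge.length), sort(tq$edge.length), tolerance = 1e-9)

  writeLines("((A:1,B:1)50:2,C:3);", f)
  rp <- read_newick(f)
  expect_true("50" %in% rp$node.label)
})

test_that("malformed Newick parentheses are reported with an offset", {
  f <- withr::local_tempfile()
  writeLines("((A:1,B:1):2,C:3;", f)
  expect_error(read_newick(f), "unclosed '\\('")
  writeLines("(A:1,B:1)):2;", f)
  expect_error(read_newick(f), "character 10")
})

test_that("duplicate genomes collapse to the best-annotated version", {
  s <- random_dna(300, seed = 2)
  rec <- function(id, seq, np) genome_record(id, stats::setNames(seq, id),
                                             "nucleotide", n_proteins = np)
  # identical sequences, different protein counts: keep the richer one
  out <- deduplicate_genomes(list(rec("v1", s, 10L), rec("v2", s, 12L)))
  expect_equal(vapply(out, function(r) r$genome_id, ""), "v2")
  # lower-case copy has the same checksum (uppercased before hashing)
  out <- deduplicate_genomes(list(rec("v1", tolower(s), 10L), rec("v2", s, 12L)))
  expect_equal(vapply(out, function(r) r$genome_id, ""), "v2")
  # all distinct: unchanged
  g3 <- rec("v3", random_dna(300, seed = 3), 0L)
  out <- deduplicate_genomes(list(rec("v1", s, 10L), g3))
  expect_equal(length(out), 2L)
  # tie on protein count: lexicographically smallest id wins
  out <- deduplicate_genomes(list(rec("B", s, 5L), rec("A", s, 5L)))
  expect_equal(vapply(out, function(r) r$genome_id, ""), "A")
})

test_that("taxonomy and host tables read with validation", {
  f <- withr::local_tempfile()
  writeLines(c("genome_id\tspecies\tgenus\tsubfamily\tfamily",
               "g1\tsp1\tgen1\t\tfam1",
               "g2\tsp2\t\t\tfam1"), f)
  tax <- read_taxonomy(f)
  expect_equal(nrow(tax), 2L)
  expect_equal(tax$genus, c("gen1", ""))
  writeLines(c("genome_id\tspecies", "g1\tsp1"), f)
  expect_error(read_taxonomy(f), "lacks column")
  writeLines(c("genome_id\thost", "g1\tEscherichia coli"), f)
  expect_equal(read_hosts(f)$host, "Escherichia coli")
})
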