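test_that("NJ solves the three-point closed form", {
  m <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(m)
  pend <- stats::setNames(tr$edge.length[tr$edge[, 2] <= 3],
                          tr$tip.label[tr$edge[, 2][tr$edge[, 2] <= 3]])
  expect_equal(pend[["A"]], 0.5)
  expect_equal(pend[["B"]], 1.5)
  expect_equal(pend[["C"]], 2.5)
})

test_that("NJ recovers the additive quartet", {
  m <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 2
  m["C", "D"] <- m["D", "C"] <- 2
  diag(m) <- 0
  tr <- nj_tree(m)
  # split AB|CD present; internal branch length follows from additivity:
  # dAC = 1 + t + 1 = 4  =>  t = 2
  want <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):0);")
  expect_true(same_topology(tr, want))
  expect_equal(stats::cophenetic(tr)[rownames(m), colnames(m)], m)
})

test_that("NJ reconstructs random additive trees exactly", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:8, 1)
    true <- ape::rtree(n)
    m <- stats::cophenetic(true)
    tr <- nj_tree(m)
    expect_true(same_topology(tr, true), info = paste("seed", seed))
    expect_equal(stats::cophenetic(tr)[rownames(m), colnames(m)], m,
                 tolerance = 1e-8)
  }
})

test_that("degenerate matrices are handled", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(nj_tree(z)$edge.length == 0))
  m2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(m2)
  expect_equal(ape::Ntip(t2), 2L)
  expect_equal(t2$edge.length, c(1.5, 1.5))
})

test_that("midpoint rooting balances the longest leaf path", {
  # two-leaf tree: root at the middle of the single edge
  t2 <- midpoint_root(ape::read.tree(text = "(A:3,B:1);"))
  expect_equal(t2$edge.length, c(2, 2))
  # symmetric quartet: root at the centre of the internal edge
  tq <- midpoint_root(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  droot <- ape::dist.nodes(tq)[1:4, ape::Ntip(tq) + 1L]
  expect_equal(unname(droot), rep(2, 4))
  # a long pendant branch attracts the root
  tl <- midpoint_root(ape::read.tree(text = "((A:10,B:1):1,(C:1,D:1):1);"))
  dl <- ape::dist.nodes(tl)[1:4, ape::Ntip(tl) + 1L]
  expect_equal(unname(dl[1]), 6.5)  # A
  expect_equal(max(stats::cophenetic(tl)), 13)
  expect_true(ape::is.rooted(tl))
})

test_that("midpoint rooting equalises the two most distant leaves (property)", {
  for (seed in 1:8) {
    set.seed(seed)
    tr <- ape::rtree(sample(4:10, 1))
    rooted <- midpoint_root(tr)
    d <- stats::cophenetic(rooted)
    droot <- ape::dist.nodes(rooted)[seq_len(ape::Ntip(rooted)),
                                     ape::Ntip(rooted) + 1L]
    # the root sits at half the tree diameter from its farthest leaves
    expect_equal(max(droot), max(d) / 2, tolerance = 1e-9)
    # some diameter pair is equidistant from the root
    ends <- which(d >= max(d) - 1e-12, arr.ind = TRUE)
    expect_true(any(abs(droot[ends[, 1]] - droot[ends[, 2]]) < 1e-9))
    # rooting preserves all leaf-to-leaf distances
    expect_equal(d[rownames(stats::cophenetic(tr)), colnames(stats::cophenetic(tr))],
                 stats::cophenetic(tr), tolerance = 1e-9)
  }
})

test_that("all-zero branch lengths root at the smallest leaf's edge", {
  tr <- ape::read.tree(text = "((b:0,a:0):0,(c:0,d:0):0);")
  rooted <- midpoint_root(tr)
  expect_true(ape::is.rooted(rooted))
  expect_equal(sum(rooted$edge.length), 0)
})

test_that("branch support counts replicate bipartitions", {
  ref <- midpoint_root(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,(E:1,F:1):1);"))
  # all replicates identical to the reference: everything 100
  bs <- branch_support(ref, replicate(10, ref, simplify = FALSE))
  expect_true(all(as.integer(bs$node.label) == 100L))
  # star replicates carry no internal bipartitions: non-trivial branches 0
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  bs0 <- branch_support(ref, replicate(10, star, simplify = FALSE))
  sup <- as.integer(bs0$node.label)
  expect_equal(sort(unique(sup)), c(0L, 100L))  # root/trivial stay 100
  expect_equal(sum(sup == 100L), 1L)            # only the root is trivial
  expect_equal(sum(sup == 0L), bs0$Nnode - 1L)
  # a bipartition present in half the replicates scores 50
  alt <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1,(E:1,F:1):1);")
  bs50 <- branch_support(ref, c(replicate(5, ref, simplify = FALSE),
                                replicate(5, alt, simplify = FALSE)))
  expect_true("50" %in% bs50$node.label)
  # leaf-set mismatch is an informative error
  bad <- ape::read.tree(text = "((A:1,B:1):1,(C:1,X:1):1);")
  expect_error(branch_support(ref, list(bad)), "X")
})

test_that("support is invariant under replicate leaf-order permutation", {
  set.seed(42)
  reps <- replicate(20, ape::rtree(6), simplify = FALSE)
  reps <- lapply(reps, function(t) { t$tip.label <- sample(paste0("t", 1:6)); t })
  ref <- midpoint_root(reps[[1]])
  s1 <- branch_support(ref, reps)$node.label
  perm <- lapply(reps, function(t) ape::rotateConstr(t, sample(t$tip.label)))
  s2 <- branch_support(ref, perm)$node.label
  expect_equal(s1, s2)
})

test_that("support counting agrees with ape::prop.clades", {
  set.seed(43)
  for (trial in 1:3) {
    reps <- replicate(25, ape::rtree(7), simplify = FALSE)
    reps <- lapply(reps, function(t) { t$tip.label <- sample(paste0("t", 1:7)); t })
    ref <- midpoint_root(reps[[1]])
    got <- as.integer(branch_support(ref, reps)$node.label)
    pc <- ape::prop.clades(ref, reps, rooted = FALSE)
    want <- as.integer(round(100 * pc / length(reps)))
    nontrivial <- !is.na(pc)
    expect_equal(got[nontrivial], want[nontrivial])
  }
})

test_that("monophyly classification follows the minimum-change criterion", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(classify_taxon(tr, c("A", "B")), "monophyletic")
  expect_equal(classify_taxon(tr, "A"), "trivial")
  expect_equal(classify_taxon(tr, c("A", "C")), "paraphyletic")
  expect_equal(classify_taxon(tr, c("A", "B", "C", "D")), "monophyletic")
  expect_error(classify_taxon(tr, c("A", "Z")), "unknown leaves")
  # members scattered among large non-member clades need >= 2 gains
  big <- ape::read.tree(text = paste0(
    "(((A:1,(a1:1,a2:1,a3:1):1):1,(B:1,(b1:1,b2:1,b3:1):1):1):1,",
    "((C:1,(c1:1,c2:1,c3:1):1):1,(D:1,d1:1):1):1);"))
  expect_equal(classify_taxon(big, c("A", "B", "C")), "polyphyletic")
})

test_that("classification matches the exhaustive reconstruction oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(5:8, 1)
    tr <- ape::rtree(n)
    k <- sample(2:(n - 1), 1)
    members <- sample(tr$tip.label, k)
    status <- classify_taxon(tr, members)
    tips <- match(members, tr$tip.label)
    mrca <- ape::getMRCA(tr, tips)
    clade <- virotax:::clade_tip_sets(tr)[[as.character(mrca)]]
    if (setequal(clade, tips)) {
      expect_equal(status, "monophyletic")
    } else {
      want <- if (oracle_mp_member(tr, tips, mrca)) "paraphyletic"
              else "polyphyletic"
      expect_equal(status, want, info = paste("seed", seed))
    }
  }
})

test_that("taxon support rewards monophyly and penalises conflict", {
  tr <- ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)80:1)100;")
  tax <- tibble::tibble(genome_id = c("A", "B", "C", "D"),
                        species = c("s1", "s1", "s2", "s2"))
  ts <- taxon_support(tr, tax, "species")
  expect_equal(sort(ts$report$signed_support), c(80, 100))
  expect_equal(ts$overall, 1)
  # both taxa crossed by maximally supported clades
  tax2 <- tibble::tibble(genome_id = c("A", "B", "C", "D"),
                         species = c("s1", "s2", "s1", "s2"))
  ts2 <- taxon_support(tr, tax2, "species")
  expect_equal(ts2$report$signed_support, c(-100, -100))
  expect_equal(ts2$overall, -1)
  expect_true(all(ts2$report$status %in% c("paraphyletic", "polyphyletic")))
  # one +100 and one -100 cancel to overall 0
  tr8 <- ape::read.tree(text = paste0(
    "(((A:1,B:1)100:1,(C:1,D:1)100:1)100:1,",
    "((E:1,F:1)100:1,(G:1,H:1)100:1)100:1)100;"))
  tax3 <- tibble::tibble(
    genome_id = LETTERS[1:8],
    family = c("f1", "f1", "", "", "f2", "", "f2", ""))
  ts3 <- taxon_support(tr8, tax3, "family")
  expect_equal(ts3$overall, 0)
  sup <- stats::setNames(ts3$report$signed_support, ts3$report$taxon)
  expect_equal(sup[["f1"]], 100)
  expect_equal(sup[["f2"]], -100)
  # trivial taxa are reported but excluded from the overall statistic
  tax4 <- tibble::tibble(genome_id = c("A", "B", "C", "D"),
                         species = c("s1", "s1", "s2", "s3"))
  ts4 <- taxon_support(tr, tax4, "species")
  expect_equal(ts4$report$status[ts4$report$taxon %in% c("s2", "s3")],
               rep("trivial", 2))
  expect_equal(ts4$overall, 1)
  expect_error(taxon_support(tr, tax, "genus"), "no rank column")
})

test_that("taxon support report tidiers expose the overall statistic", {
  tr <- ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)80:1)100;")
  tax <- tibble::tibble(genome_id = c("A", "B", "C", "D"),
                        species = c("s1", "s1", "s2", "s2"))
  ts <- taxon_support(tr, tax, "species")
  expect_s3_class(tidy(ts), "tbl_df")
  g <- glance(ts)
  expect_equal(g$overall, 1)
  expect_equal(g$n_monophyletic, 2L)
  expect_s3_class(autoplot(ts), "ggplot")
})
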