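summary_row <- function(mq, ms, cols, id) {
  tibble::tibble(matched_query = mq, matched_subject = ms, columns = cols,
                 identities = id, n_hsps = NA_integer_)
}

test_that("distance formulas reproduce the defining substitutions", {
  # full-length perfect self-match
  s <- summary_row(1000, 1000, 1000, 1000)
  expect_equal(formula_distance(s, 1000, 1000, "d0"), 0)
  expect_equal(formula_distance(s, 1000, 1000, "d4"), 0)
  expect_equal(formula_distance(s, 1000, 1000, "d6"), 0)
  # no HSPs at all
  z <- summary_row(0, 0, 0, 0)
  expect_equal(formula_distance(z, 1000, 1000, "d0"), 1)
  expect_equal(formula_distance(z, 1000, 1000, "d4"), 1)  # by convention
  expect_equal(formula_distance(z, 1000, 1000, "d6"), 1)
  # half coverage at full identity: d4 ignores the missing half
  h <- summary_row(500, 500, 500, 500)
  expect_equal(formula_distance(h, 1000, 1000, "d0"), 0.5)
  expect_equal(formula_distance(h, 1000, 1000, "d4"), 0.0)
  expect_equal(formula_distance(h, 1000, 1000, "d6"), 0.5)
  # malformed summaries are rejected
  expect_error(formula_distance(summary_row(-1, 0, 0, 0), 10, 10, "d0"),
               "negative")
})

test_that("identical genomes are at distance 0 with all replicates 0", {
  g <- nt_genome("A", random_dna(400, seed = 61))
  g2 <- nt_genome("B", g$sequences[[1]])
  for (alg in c("trimming", "coverage")) {
    pd <- pair_distance(g, g2, gbdp_settings("nucleotide", algorithm = alg,
                                             n_replicates = 10))
    expect_equal(pd$distance, 0)
    expect_equal(pd$replicates, rep(0, 10))
  }
})

test_that("a single retained HSP makes every replicate equal the point estimate", {
  shared <- random_dna(500, seed = 71)
  gA <- nt_genome("A", paste0(shared, strrep("A", 300)))
  gB <- nt_genome("B", paste0(shared, strrep("C", 300)))
  st <- gbdp_settings("nucleotide", formula = "d6", n_replicates = 25)
  hh <- bidirectional_hsps(gA, gB, scoring_scheme("nucleotide"), st$evalue_max)
  expect_equal(nrow(greedy_trim(hh$ab)$hsps), 1L)
  pd <- pair_distance(gA, gB, st)
  expect_equal(pd$replicates, rep(pd$distance, 25))
})

test_that("two retained HSPs give the enumerated resampling distribution", {
  p <- random_dna(400, seed = 81)
  q <- random_dna(250, seed = 82)
  gA <- nt_genome("A", paste0(p, strrep("A", 300), q))
  gB <- nt_genome("B", paste0(p, strrep("C", 300), q))
  st <- gbdp_settings("nucleotide", formula = "d6", n_replicates = 1000)
  hh <- bidirectional_hsps(gA, gB, scoring_scheme("nucleotide"), st$evalue_max)
  ret <- greedy_trim(hh$ab)$hsps
  expect_equal(nrow(ret), 2L)

  # enumerate the four equiprobable per-direction resamples by hand
  l_a <- gA$total_length; l_b <- gB$total_length
  ident <- ret$identities
  d6_of <- function(ids) 1 - 2 * sum(ids) / (l_a + l_b)
  dir_vals <- c(d6_of(ident[c(1, 1)]), d6_of(ident[c(1, 2)]),
                d6_of(ident[c(2, 1)]), d6_of(ident[c(2, 2)]))
  pair_vals <- outer(dir_vals, dir_vals, function(a, b) (a + b) / 2)
  expected <- table(round(as.vector(pair_vals), 12)) / 16

  pd <- pair_distance(gA, gB, st)
  observed <- table(round(pd$replicates, 12)) / 1000
  expect_true(all(names(observed) %in% names(expected)))
  for (v in names(expected)) {
    obs <- if (v %in% names(observed)) observed[[v]] else 0
    p0 <- expected[[v]]
    expect_lt(abs(obs - p0), 4 * sqrt(p0 * (1 - p0) / 1000) + 1e-9)
  }
})

test_that("replicate mean approaches the point estimate for d6", {
  sim <- simulate_dataset(simulation_spec(n_taxa = 2, genome_length = 4000,
                                          brlen_mean = 0.05, seed = 5))
  st <- gbdp_settings("nucleotide", formula = "d6", n_replicates = 200)
  pd <- pair_distance(sim$genomes[[1]], sim$genomes[[2]], st)
  se <- stats::sd(pd$replicates) / sqrt(200)
  expect_lt(abs(mean(pd$replicates) - pd$distance), 3 * se + 1e-9)
})

test_that("matrices are symmetric, bounded, zero-diagonal and complete", {
  sim <- simulate_dataset(simulation_spec(n_taxa = 4, genome_length = 2000,
                                          seed = 6))
  st <- gbdp_settings("nucleotide", formula = "d6", n_replicates = 5)
  m <- build_matrix(sim$genomes, st)
  expect_equal(m$values, t(m$values))
  expect_equal(diag(m$values), stats::setNames(rep(0, 4), m$labels))
  expect_true(all(m$values >= 0 & m$values <= 1))
  expect_equal(length(m$replicates), 5L)
  for (r in m$replicates) {
    expect_equal(r, t(r))
    expect_true(all(r >= 0 & r <= 1))
  }
  # three identical genomes: all off-diagonal 0
  g <- nt_genome("x1", random_dna(300, seed = 7))
  gs <- list(g, nt_genome("x2", g$sequences[[1]]),
             nt_genome("x3", g$sequences[[1]]))
  m0 <- build_matrix(gs, gbdp_settings("nucleotide", n_replicates = 0))
  expect_true(all(m0$values == 0))
  # duplicate ids are rejected
  expect_error(build_matrix(list(g, g), st), "duplicate genome ids")
})

test_that("genome input order does not change the matrix (pair-keyed seeds)", {
  sim <- simulate_dataset(simulation_spec(n_taxa = 4, genome_length = 1500,
                                          seed = 8))
  st <- gbdp_settings("nucleotide", formula = "d6", n_replicates = 3)
  m1 <- build_matrix(sim$genomes, st)
  m2 <- build_matrix(rev(sim$genomes), st)
  expect_equal(m2$values[m1$labels, m1$labels], m1$values)
  for (r in 1:3)
    expect_equal(m2$replicates[[r]][m1$labels, m1$labels], m1$replicates[[r]])
})

test_that("d4 and d6 increase with the substitution rate", {
  rates <- c(0.01, 0.03, 0.06, 0.09, 0.13)
  d4 <- d6 <- numeric(length(rates))
  for (k in seq_along(rates)) {
    sim <- simulate_dataset(simulation_spec(
      n_taxa = 2, genome_length = 5000, brlen_mean = rates[k],
      brlen_min = rates[k] * 0.9, seed = 99))
    hh <- bidirectional_hsps(sim$genomes[[1]], sim$genomes[[2]],
                             scoring_scheme("nucleotide"), 1)
    f <- greedy_trim(hh$ab)
    l <- vapply(sim$genomes, function(g) g$total_length, 0)
    d4[k] <- formula_distance(f$summary, l[1], l[2], "d4")
    d6[k] <- formula_distance(f$summary, l[1], l[2], "d6")
  }
  # non-decreasing trend, allowing a single noisy step
  expect_lte(sum(diff(d4) < 0), 1)
  expect_lte(sum(diff(d6) < 0), 1)
  expect_gt(d4[5], d4[1])
  expect_gt(d6[5], d6[1])
})

test_that("d4 is more robust to genome truncation than d0 and d6", {
  base <- simulation_spec(n_taxa = 2, genome_length = 5000,
                          brlen_mean = 0.005, brlen_min = 0.001, seed = 12)
  full <- simulate_dataset(base)
  trunc <- simulate_dataset(simulation_spec(
    n_taxa = 2, genome_length = 5000, brlen_mean = 0.005, brlen_min = 0.001,
    truncate_taxa = "g02", truncation = 0.3, seed = 12))
  dist_of <- function(ds, frm) {
    pair_distance(ds$genomes[[1]], ds$genomes[[2]],
                  gbdp_settings("nucleotide", formula = frm,
                                n_replicates = 0))$distance
  }
  deltas <- vapply(c("d0", "d4", "d6"), function(frm)
    abs(dist_of(trunc, frm) - dist_of(full, frm)), 0)
  expect_lt(deltas[["d4"]], deltas[["d0"]])
  expect_lt(deltas[["d4"]], deltas[["d6"]])
})
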