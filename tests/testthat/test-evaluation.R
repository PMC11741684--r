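# Exhaustive hypergeometric tail oracle for small universes.
hyper_tail_oracle <- function(k, sizeA, sizeB, universe) {
  j <- max(k, 0):min(sizeA, sizeB)
  sum(choose(sizeB, j) * choose(universe - sizeB, sizeA - j)) /
    choose(universe, sizeA)
}

test_that("fisher overlap matches enumeration and is tail-monotone", {
  expect_equal(fisher_overlap(c("a", "b"), c("c", "d"), 10)$p_value, 1)
  r <- fisher_overlap(c("a", "b"), c("a", "b"), 10)
  expect_equal(r$overlap, 2)
  expect_equal(r$p_value, 1 / 45)

  set.seed(10)
  universe <- paste0("g", 1:30)
  for (i in 1:15) {
    A <- sample(universe, sample(1:15, 1))
    B <- sample(universe, sample(1:15, 1))
    got <- fisher_overlap(A, B, 30)
    expect_equal(got$p_value,
                 hyper_tail_oracle(got$overlap, length(A), length(B), 30),
                 tolerance = 1e-12)
  }

  # at fixed margins the tail p never increases with the observed overlap
  ps <- vapply(0:5, function(k) {
    A <- paste0("s", 1:5)
    B <- c(paste0("s", seq_len(k)), paste0("t", seq_len(5 - k)))
    fisher_overlap(A, B, 30)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("three-way overlap uses the product-of-marginals binomial tail", {
  expect_equal(three_way_overlap_test("a", "b", "c", 10)$p_value, 1)
  # k=1, n=10, marginal rates all 0.2: 1 - (1 - 0.008)^10
  r <- three_way_overlap_test(c("x", "p1"), c("x", "p2"), c("x", "p3"), 10)
  expect_equal(r$overlap, 1)
  expect_equal(r$p_value, 1 - (1 - 0.008)^10)
  # larger triple overlap at the same margins is more surprising
  r2 <- three_way_overlap_test(c("x", "y"), c("x", "y"), c("x", "y"), 10)
  expect_lt(r2$p_value, r$p_value)
})

test_that("gene-set enrichment is hypergeometric with BH adjustment", {
  universe <- paste0("g", 1:50)
  gmt <- list(hit = paste0("g", 1:10), other = paste0("g", 30:39))
  res <- geneset_enrichment(paste0("g", 1:10), gmt, universe)
  expect_equal(res$overlap[res$set == "hit"], 10)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(50, 10))
  expect_true(all(res$q_value >= res$p_value))

  # sets disjoint from the universe are dropped with a warning
  expect_warning(
    res2 <- geneset_enrichment("g1", c(gmt, list(alien = c("zz1", "zz2"))),
                               universe),
    "disjoint")
  expect_false("alien" %in% res2$set)
  expect_error(geneset_enrichment("g1", gmt, character()), "universe")
})

test_that("enrichment p-values are sub-uniform under random selection", {
  set.seed(77)
  universe <- paste0("g", 1:100)
  gmt <- lapply(1:4, function(i) sample(universe, 20))
  names(gmt) <- paste0("set", 1:4)
  ps <- replicate(300, {
    sel <- sample(universe, 10)
    geneset_enrichment(sel, gmt, universe)$p_value
  })
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    frac <- mean(ps <= t)
    se <- sqrt(t * (1 - t) / length(ps))
    expect_lte(frac, t + 4 * se)   # valid (conservative) p-values
  }
})

test_that("hidden single-gene evidence is recovered exactly when the network
           still points at the gene", {
  # locus B's flagged gene BFAR is a hub tied to two frozen single-gene
  # loci; hiding its flag leaves the network pull, so it stays selected
  snps <- gwas_df(c("rs1", "rs2", "rs3"), c("chr1", "chr2", "chr3"),
                  rep(1e6, 3), rep(1e-9, 3))
  genes <- genes_df(c("H1", "H2", "BNEAR", "BFAR"),
                    c("chr1", "chr2", "chr3", "chr3"), "+",
                    c(1e6 + 5e4, 1e6 + 5e4, 1e6 + 3e4, 1e6 + 6e4), 0)
  genes$end <- genes$start + 10
  ls <- make_locus_set(snps, genes, coloc = "BFAR")
  ppi <- edge_df("BFAR", "H1", "BFAR", "H2")
  before <- ls
  res <- hide_information_experiment(ls, ppi = ppi, n_runs = 3, seed = 2)
  expect_identical(ls, before)                       # input left untouched
  expect_equal(nrow(res$detail), 1L)
  expect_true(res$detail$recovered)
  expect_equal(res$by_category$recovered[res$by_category$category == "coloc"], 1L)

  # with no edges and a nearer competitor, the hidden gene is lost
  ls2 <- make_locus_set(snps, genes, coloc = "BFAR")
  res2 <- hide_information_experiment(ls2, ppi = NULL, n_runs = 3, seed = 2)
  expect_false(res2$detail$recovered)
})

test_that("subset robustness shows zero dispersion at fraction one and
           pseudocount shrinkage below it", {
  # deterministic evidence-free toy: every subset run lands on MinDist
  ls <- toy_three_locus()
  full <- subset_robustness(ls, fraction = 1, n_subsets = 4, seed = 5)
  expect_true(all(full$summary$sd < 1e-12))

  # all planted genes flagged and selected: counts scale with the subset,
  # so pseudocounts pull the mean subset score below the full-data score
  d <- tempfile()
  simulate_study(sim_config(n_loci = 40, p_coloc = 1, p_mendelian = 0,
                            p_exome = 0, bg_mendelian = 0, bg_exome = 0,
                            bg_coloc = 0, n_singleton_mendelian = 0,
                            seed = 31), d)
  st <- load_study(d)
  fit_full <- signet(st$loci, n_runs = 1, seed = 2)
  sub <- subset_robustness(st$loci, fraction = 0.8, n_subsets = 5, seed = 2)
  expect_lt(sub$summary$mean[sub$summary$parameter == "S_coloc"],
            fit_full$runs$S_coloc)

  # seeded draws reproduce
  sub2 <- subset_robustness(st$loci, fraction = 0.8, n_subsets = 5, seed = 2)
  expect_identical(sub$per_subset, sub2$per_subset)
})

test_that("rank concordance is baseline-invariant and detects reversal", {
  ls <- toy_three_locus()
  g <- ls$genes
  a <- data.frame(symbol = g$symbol, score = seq_len(nrow(g)) * 1.0)
  same <- rank_concordance(a, a, ls)
  expect_equal(same$spearman, 1)
  expect_equal(same$pearson, 1)

  # per-locus constant shifts change nothing after baseline subtraction
  b <- a
  b$score <- a$score + 100 * as.integer(factor(g$locus_id))
  shifted <- rank_concordance(a, b, ls)
  expect_equal(shifted$per_gene$rankA, shifted$per_gene$rankB)
  expect_equal(shifted$spearman, 1)

  # reversing scores within loci reverses every within-locus ranking
  r <- a
  r$score <- stats::ave(a$score, g$locus_id, FUN = function(v) sum(range(v)) - v)
  rev <- rank_concordance(a, r, ls)
  n_per_locus <- stats::ave(rev$per_gene$rankA, rev$per_gene$locus_id,
                            FUN = length)
  expect_equal(rev$per_gene$rankB, n_per_locus + 1 - rev$per_gene$rankA)

  # missing genes are dropped and counted; no shared genes is an error
  a_sub <- a[-1, ]
  part <- rank_concordance(a_sub, a, ls)
  expect_equal(part$n_shared, nrow(g) - 1L)
  expect_equal(part$n_dropped, 1L)
  expect_error(rank_concordance(a[1:2, ], a[3:4, ], ls), "shared")
})
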