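test_that("best-guess initialization follows the evidence priority order", {
  # Mendelian beats coloc; exome beats coloc; no evidence falls to MinDist
  ls <- toy_three_locus(mendelian = "A2", exome = "B2", coloc = c("A1", "B1", "C2"))
  set.seed(1)
  cfg <- initialize_best_guess(ls)
  lid_of <- function(sym) ls$genes$locus_id[ls$genes$symbol == sym]
  expect_equal(unname(cfg[lid_of("A2")]), "A2")  # Mendelian > coloc
  expect_equal(unname(cfg[lid_of("B2")]), "B2")  # exome > coloc
  expect_equal(unname(cfg[lid_of("C2")]), "C2")  # coloc beats distance

  ls2 <- toy_three_locus()                       # information-poor: MinDist
  cfg2 <- initialize_best_guess(ls2)
  expect_equal(sort(unname(cfg2)), c("A1", "B1", "C1"))

  # two genes in the top class: seeded choice is reproducible
  ls3 <- toy_three_locus(mendelian = c("A1", "A2"))
  picks <- vapply(1:5, function(i) {
    set.seed(99)
    initialize_best_guess(ls3)[[lid_of("A1")]]
  }, character(1))
  expect_equal(length(unique(picks)), 1L)
})

test_that("random initialization is uniform within loci and pins singletons", {
  snps <- gwas_df("rs1", "chr1", 1e6, 1e-9)
  genes <- genes_df(c("G1", "G2", "G3", "G4", "FAR"),
                    c(rep("chr1", 4), "chr9"), "+",
                    c(1e6 + (1:4) * 1e3, 7e6), 0)
  genes$end <- genes$start + 10
  ls <- make_locus_set(snps, genes, mendelian = "FAR")
  set.seed(5)
  draws <- replicate(2000, initialize_random(ls)[["locus_0001"]])
  freq <- table(draws) / 2000
  expect_equal(sort(names(freq)), c("G1", "G2", "G3", "G4"))
  # binomial 3-sigma band around 1/4
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 2000)))
  expect_true(all(replicate(20, initialize_random(ls)[["mendelian_FAR"]]) == "FAR"))
})

test_that("a sweep trades distance against network gain as the score says", {
  # locus A holds a single frozen hub; locus B chooses between a near gene
  # with no edges and a far gene wired to the hub
  snps <- gwas_df(c("rsA", "rsB"), c("chr1", "chr2"), c(1e6, 1e6),
                  rep(1e-9, 2))
  genes <- genes_df(c("HUB", "BNEAR", "BFAR"),
                    c("chr1", "chr2", "chr2"), "+",
                    c(1e6 + 100, 1e6 + 1e3, 1e6 + 5e4), 0)
  genes$end <- genes$start + 10
  ls <- make_locus_set(snps, genes)
  ppi <- build_network_model(edge_df("HUB", "BFAR"), ls, directed = FALSE)
  params <- list(gamma = 150000, S = c(mendelian = 0, exome = 0, coloc = 0))
  lidB <- ls$genes$locus_id[ls$genes$symbol == "BNEAR"]
  lidA <- ls$genes$locus_id[ls$genes$symbol == "HUB"]
  config <- stats::setNames(c("HUB", "BNEAR"), c(lidA, lidB))

  set.seed(2)
  res <- signet:::sweep_pass(config, ls, list(ppi = ppi, gri = NULL), params)

  # independent arithmetic: T = 1 pair; far gene lifts E 0 -> 1 with
  # E0 = delta_HUB * delta_BFAR = 0.25; near gene has delta = 0
  lam <- function(E, E0, T) lgamma(E + 1) - ifelse(E > 0, E * log(E0), 0) +
    E0 - log(T + 1)
  s_refl <- function(E, E0, T) {
    l0 <- lam(E0, E0, T)
    l0 + sign(E - E0) * abs(lam(E, E0, T) - l0)
  }
  gain_net <- s_refl(1, 0.25, 1) - (-log(2))      # E0 = 0 baseline = -ln(T+1)
  loss_dist <- (5e4 - 1e3) / 150000
  expect_true(gain_net > loss_dist)                # so the far gene must win
  expect_equal(unname(res$config[lidB]), "BFAR")
  expect_true(res$changed)

  # a converged configuration is a fixed point of further sweeps
  set.seed(3)
  res2 <- signet:::sweep_pass(res$config, ls, list(ppi = ppi, gri = NULL),
                              params)
  expect_false(res2$changed)
  expect_equal(res2$config, res$config)
})

test_that("parameter updates delegate to the scoring formulas and are a
           fixed point for an unchanged configuration", {
  ls <- toy_three_locus(mendelian = "A2")
  lids <- ls$loci$locus_id
  config <- stats::setNames(c("A2", "B1", "C1"), lids)
  p1 <- signet:::update_parameters(config, ls)
  p2 <- signet:::update_parameters(config, ls, prev = p1)
  expect_identical(p1$S, p2$S)
  expect_identical(p1$gamma, p2$gamma)
  # gamma equals the mean |x| of the active non-singleton genes
  ax <- abs(ls$genes$x[ls$genes$symbol %in% config])
  expect_equal(p1$gamma, mean(ax))
  # hand-tallied counts: active flagged 1, active unflagged 2, inactive 3
  expect_equal(p1$S[["mendelian"]],
               feature_score(n00 = 3, n01 = 0, n10 = 2, n11 = 1))
})

test_that("runs converge to valid, locally optimal configurations", {
  d <- tempfile()
  simulate_study(sim_config(n_loci = 20, seed = 11), d)
  st <- load_study(d)
  networks <- list(ppi = build_network_model(st$ppi, st$loci),
                   gri = build_network_model(st$gri, st$loci, directed = TRUE))
  one <- signet:::run_single(st$loci, networks, run_seed = 4)
  expect_true(one$converged)
  ls <- st$loci

  # configuration validity: one active gene per locus, singletons pinned
  expect_equal(length(one$config), ls$L + ls$M)
  expect_equal(sort(names(one$config)), sort(ls$loci$locus_id))
  singles <- ls$genes$symbol[ls$genes$is_singleton]
  expect_true(all(singles %in% one$config))
  for (lid in names(one$config)) {
    expect_true(one$config[[lid]] %in%
                  ls$genes$symbol[ls$genes$locus_id == lid])
  }

  # local optimality: no single-locus reassignment beats the converged gene
  for (lid in ls$loci$locus_id[!ls$loci$is_singleton]) {
    syms <- ls$genes$symbol[ls$genes$locus_id == lid]
    scores <- vapply(syms, function(s) {
      gene_total_score(s, one$config, ls, networks, one$params)[["total"]]
    }, numeric(1))
    expect_lte(max(scores) - scores[[one$config[[lid]]]], 1e-9)
  }
})

test_that("single-gene loci converge in one pass and a strict optimum is
           seed-independent", {
  snps <- gwas_df(c("rs1", "rs2"), c("chr1", "chr2"), c(1e6, 1e6),
                  rep(1e-9, 2))
  genes <- genes_df(c("X", "Y"), c("chr1", "chr2"), "+",
                    c(1e6 + 50, 1e6 + 70), 0)
  genes$end <- genes$start + 10
  ls <- make_locus_set(snps, genes)
  one <- signet:::run_single(ls, list(ppi = NULL, gri = NULL), run_seed = 1)
  expect_true(one$converged)
  expect_equal(one$passes, 1L)

  # evidence-free toy has one strict optimum (the MinDist configuration):
  # every seed and both initializations land on it
  ls2 <- toy_three_locus()
  finals <- lapply(1:6, function(s) {
    cfg <- signet:::run_single(ls2, list(ppi = NULL, gri = NULL),
                               run_seed = s,
                               init = if (s %% 2) "best_guess" else
                                 "random")$config
    sort(unname(cfg))
  })
  for (f in finals) expect_equal(f, c("A1", "B1", "C1"))
})

test_that("multi-run aggregation yields conserved frequencies and gene lists", {
  ls <- toy_three_locus(mendelian = "A2", coloc = c("B1", "B2"))
  fit1 <- signet(ls, n_runs = 1, seed = 3)
  expect_true(all(fit1$genes$selection_frequency %in% c(0, 1)))
  fit <- signet(ls, n_runs = 6, seed = 3)
  freq_sums <- tapply(fit$genes$selection_frequency, fit$genes$locus_id, sum)
  w_sums <- tapply(fit$genes$mean_weight, fit$genes$locus_id, sum)
  expect_true(all(abs(freq_sums - 1) < 1e-12))
  expect_true(all(abs(w_sums - 1) < 1e-9))

  lists <- extract_gene_lists(fit)
  plus <- strsplit(lists$signet_plus, ",")
  for (i in seq_len(nrow(lists))) {
    # SigNet gene always a member of its SigNet+ set
    expect_true(lists$signet[i] %in% plus[[i]])
  }
  # locus with two flagged genes, one selected: SigNet+ has both
  lidB <- ls$genes$locus_id[ls$genes$symbol == "B1"]
  expect_equal(sort(plus[[match(lidB, lists$locus_id)]]), c("B1", "B2"))
  # information-poor locus: SigNet+ collapses to the SigNet singleton
  lidC <- ls$genes$locus_id[ls$genes$symbol == "C1"]
  expect_equal(plus[[match(lidC, lists$locus_id)]],
               lists$signet[match(lidC, lists$locus_id)])
})

test_that("with no networks, best-guess starts are already fixed points on
           evidence-free studies", {
  d <- tempfile()
  simulate_study(sim_config(n_loci = 25, seed = 21, p_mendelian = 0,
                            p_exome = 0, p_coloc = 0, bg_mendelian = 0,
                            bg_exome = 0, bg_coloc = 0,
                            n_singleton_mendelian = 0), d)
  st <- load_study(d)
  set.seed(8)
  bg <- initialize_best_guess(st$loci)
  one <- signet:::run_single(st$loci, list(ppi = NULL, gri = NULL),
                             run_seed = 8)
  expect_equal(one$config[order(names(one$config))], bg[order(names(bg))])
  expect_equal(one$passes, 1L)
})

test_that("the adversarial pass cap reports non-convergence", {
  ls <- toy_three_locus()
  networks <- list(ppi = NULL, gri = NULL)
  one <- signet:::run_single(ls, networks, run_seed = 1, max_passes = 0)
  expect_false(one$converged)
})
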