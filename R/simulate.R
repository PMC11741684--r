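#' Configuration for a synthetic GWAS study
#'
#' Defaults describe a mid-sized electrocardiogram-style study: 100 loci
#' of 5 candidate genes each, a 250 kb flank, a 150 kb exponential
#' distance scale for the planted causal gene, sparse evidence flags
#' concentrated on planted genes, and protein-interaction edges enriched
#' among planted genes relative to a sparse background.
#'
#' @param n_loci Number of GWAS loci.
#' @param genes_per_locus Genes per locus (single integer >= 1).
#' @param flank_D Flank distance in bp.
#' @param gamma_true Scale (bp) of the two-sided exponential distance of
#'   the planted causal gene from the locus SNP; draws are truncated at
#'   \code{flank_D} so the planted gene always falls inside its locus.
#' @param p_mendelian,p_exome,p_coloc Evidence-flag rates on planted genes.
#' @param bg_mendelian,bg_exome,bg_coloc Background flag rates on decoys.
#' @param planted_edge_prob Extra PPI edge probability between planted
#'   genes, on top of the background (0 = no planted enrichment, the null
#'   construction under which planted and decoy genes are exchangeable in
#'   network terms).
#' @param background_edge_prob Mean background PPI edge probability. The
#'   background is a weighted random graph: every gene, planted or not,
#'   carries a lognormal propensity (spread \code{degree_sdlog}) and pair
#'   probabilities are proportional to propensity products, giving the
#'   heavy-tailed, causality-independent degree distribution of real
#'   interaction databases.
#' @param degree_sdlog Log-sd of the background degree propensities
#'   (0 = homogeneous Erdos-Renyi background).
#' @param n_decoy_modules Number of decoy network modules. Each module
#'   picks one decoy gene per locus and receives the same extra
#'   within-module edge probability as the planted module, mimicking the
#'   many dense pathway modules of real interactomes: module membership
#'   is then invisible in the degree sequence, and only the planted
#'   module's alignment with small SNP distances (and evidence flags)
#'   identifies the causal genes. Requires
#'   \code{genes_per_locus > n_decoy_modules}.
#' @param n_gri_edges Number of directed regulatory edges drawn among
#'   ordered within-module pairs, for the planted module and each decoy
#'   module alike; three times as many background directed edges are
#'   drawn with propensity-weighted endpoints.
#' @param n_singleton_mendelian Mendelian genes placed outside all loci.
#' @param seed Integer seed; the full bundle is a deterministic function
#'   of the configuration.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_loci = 100, genes_per_locus = 5,
                       flank_D = 250000, gamma_true = 150000,
                       p_mendelian = 0.08, p_exome = 0.05, p_coloc = 0.15,
                       bg_mendelian = 0.005, bg_exome = 0.005,
                       bg_coloc = 0.005,
                       planted_edge_prob = 0.15,
                       background_edge_prob = 0.025,
                       degree_sdlog = 0.6, n_decoy_modules = 3,
                       n_gri_edges = 50, n_singleton_mendelian = 8,
                       seed = 1) {
  cfg <- list(n_loci = n_loci, genes_per_locus = genes_per_locus,
              flank_D = flank_D, gamma_true = gamma_true,
              p_mendelian = p_mendelian, p_exome = p_exome,
              p_coloc = p_coloc, bg_mendelian = bg_mendelian,
              bg_exome = bg_exome, bg_coloc = bg_coloc,
              planted_edge_prob = planted_edge_prob,
              background_edge_prob = background_edge_prob,
              degree_sdlog = degree_sdlog,
              n_decoy_modules = n_decoy_modules,
              n_gri_edges = n_gri_edges,
              n_singleton_mendelian = n_singleton_mendelian,
              seed = seed)
  probs <- unlist(cfg[c("p_mendelian", "p_exome", "p_coloc", "bg_mendelian",
                        "bg_exome", "bg_coloc", "planted_edge_prob",
                        "background_edge_prob")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]")
  if (genes_per_locus < 1) stop("genes_per_locus must be >= 1")
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (gamma_true <= 0 || flank_D <= 0) stop("scales must be positive")
  if (degree_sdlog < 0) stop("degree_sdlog must be >= 0")
  if (n_decoy_modules < 0) stop("n_decoy_modules must be >= 0")
  if (n_decoy_modules >= genes_per_locus)
    stop("need genes_per_locus > n_decoy_modules (one decoy per module per locus)")
  class(cfg) <- "sim_config"
  cfg
}

## two-sided exponential, truncated at +-bound (resampling)
rtrunc_dexp <- function(n, scale, bound) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    d <- stats::rexp(length(todo), rate = 1 / scale) *
      sample(c(-1, 1), length(todo), replace = TRUE)
    ok <- abs(d) <= bound
    out[todo[ok]] <- d[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a complete synthetic study with planted causal genes
#'
#' Writes a file bundle in the package's input dialects: GWAS
#' associations (one SNP per locus), gene annotation, PPI and GRI edge
#' lists, the three evidence gene lists, and a ground-truth table naming
#' the planted causal gene of each locus. Each locus holds one planted
#' gene whose TSS sits at a signed distance drawn from a two-sided
#' exponential with scale \code{gamma_true} (truncated at the flank), and
#' decoy genes at uniform distances within the flank. Loci are spaced so
#' windows never merge. The same configuration (including seed)
#' reproduces the bundle byte-identically.
#'
#' @param sim A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths (\code{files}) and the
#'   ground truth data frame (\code{truth}: locus id, planted symbol,
#'   true parameters).
#' @export
simulate_study <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_config"))
  rs <- local_rng(sim$seed)
  on.exit(restore_rng(rs), add = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  n <- sim$n_loci
  k <- sim$genes_per_locus
  ## lay loci on 22 chromosomes, spaced so flanking windows cannot merge
  spacing <- 2 * sim$flank_D + 2e6
  chrom <- sprintf("chr%d", (seq_len(n) - 1) %% 22 + 1)
  slot <- (seq_len(n) - 1) %/% 22
  snp_pos <- as.integer(sim$flank_D + 1e6 + slot * spacing)

  gene_rows <- list()
  truth_rows <- list()
  mend <- exome <- coloc <- character(0)
  planted_syms <- character(n)
  n_mod <- sim$n_decoy_modules
  module_syms <- matrix("", nrow = max(n_mod, 0), ncol = n)
  for (l in seq_len(n)) {
    planted_j <- sample.int(k, 1L)
    syms <- sprintf("g%d_%d", l, seq_len(k))
    x <- stats::runif(k, -sim$flank_D, sim$flank_D)
    x[planted_j] <- rtrunc_dexp(1, sim$gamma_true, sim$flank_D)
    strand <- sample(c("+", "-"), k, replace = TRUE)
    ## x = pos - tss (+ strand), tss - pos (- strand)
    tss <- ifelse(strand == "+", snp_pos[l] - x, snp_pos[l] + x)
    len <- round(stats::runif(k, 5e3, 1e5))
    start <- ifelse(strand == "+", tss, tss - len)
    end <- ifelse(strand == "+", tss + len, tss)
    gene_rows[[l]] <- data.frame(
      symbol = syms, chrom = chrom[l], strand = strand,
      start = as.integer(round(start)), end = as.integer(round(end)),
      stringsAsFactors = FALSE
    )
    planted <- planted_j == seq_len(k)
    p_m <- ifelse(planted, sim$p_mendelian, sim$bg_mendelian)
    p_e <- ifelse(planted, sim$p_exome, sim$bg_exome)
    p_c <- ifelse(planted, sim$p_coloc, sim$bg_coloc)
    mend <- c(mend, syms[stats::runif(k) < p_m])
    exome <- c(exome, syms[stats::runif(k) < p_e])
    coloc <- c(coloc, syms[stats::runif(k) < p_c])
    planted_syms[l] <- syms[planted_j]
    if (n_mod > 0L) {
      decoy_idx <- setdiff(seq_len(k), planted_j)
      pick <- if (length(decoy_idx) == 1L) decoy_idx else
        sample(decoy_idx, n_mod)
      module_syms[, l] <- syms[pick]
    }
    truth_rows[[l]] <- data.frame(
      locus = l, planted = syms[planted_j], x = x[planted_j],
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, gene_rows)

  ## singleton Mendelian genes placed far beyond every locus window
  if (sim$n_singleton_mendelian > 0L) {
    m <- sim$n_singleton_mendelian
    msym <- sprintf("m%d", seq_len(m))
    mpos <- as.integer(1e6 + (seq_len(m)) * spacing)
    genes <- rbind(genes, data.frame(
      symbol = msym, chrom = "chr23", strand = "+",
      start = mpos, end = mpos + 10000L, stringsAsFactors = FALSE
    ))
    mend <- c(mend, msym)
  }

  ## GWAS table: one genome-wide-significant SNP per locus
  gwas <- data.frame(
    rsid = sprintf("rs%d", seq_len(n)), chrom = chrom, pos = snp_pos,
    trait = "sim_trait",
    pvalue = signif(10^-stats::runif(n, 8, 30), 6),
    stringsAsFactors = FALSE
  )

  ## PPI background: weighted random graph with lognormal propensities
  ## drawn independently of plantedness, so vertex degree is heavy-tailed
  ## but carries no causal signal on its own; planted-planted pairs get
  ## extra edge probability planted_edge_prob on top (independent union).
  all_syms <- unlist(lapply(gene_rows, `[[`, "symbol"))
  n_all <- length(all_syms)
  v <- exp(stats::rnorm(n_all, 0, sim$degree_sdlog))
  v <- v / mean(v)
  idx <- which(upper.tri(matrix(0, n_all, n_all)), arr.ind = TRUE)
  p_bg <- pmin(sim$background_edge_prob * v[idx[, 1]] * v[idx[, 2]], 1)
  ## module list: the planted module first, then the decoy modules
  modules <- c(list(planted_syms),
               if (n_mod > 0L) lapply(seq_len(n_mod), function(m)
                 module_syms[m, ]) else list())
  same_module <- rep(FALSE, nrow(idx))
  for (mod in modules) {
    inm <- all_syms %in% mod
    same_module <- same_module | (inm[idx[, 1]] & inm[idx[, 2]])
  }
  p_edge <- 1 - (1 - p_bg) * (1 - sim$planted_edge_prob * same_module)
  keep <- stats::runif(length(p_edge)) < p_edge
  ppi <- data.frame(from = pmin(all_syms[idx[keep, 1]], all_syms[idx[keep, 2]]),
                    to = pmax(all_syms[idx[keep, 1]], all_syms[idx[keep, 2]]),
                    stringsAsFactors = FALSE)
  ## GRI: directed within-module edges (planted and decoy modules alike),
  ## plus propensity-weighted background
  gri <- data.frame(from = character(), to = character(),
                    stringsAsFactors = FALSE)
  if (sim$n_gri_edges > 0 && n >= 2) {
    parts <- lapply(modules, function(mod) {
      fi <- sample.int(n, sim$n_gri_edges, replace = TRUE)
      ti <- sample.int(n, sim$n_gri_edges, replace = TRUE)
      ok <- fi != ti
      data.frame(from = mod[fi[ok]], to = mod[ti[ok]],
                 stringsAsFactors = FALSE)
    })
    n_bg_gri <- 3L * sim$n_gri_edges
    bi <- sample.int(n_all, n_bg_gri, replace = TRUE, prob = v)
    bj <- sample.int(n_all, n_bg_gri, replace = TRUE, prob = v)
    ok <- bi != bj
    gri <- rbind(do.call(rbind, parts),
                 data.frame(from = all_syms[bi[ok]], to = all_syms[bj[ok]],
                            stringsAsFactors = FALSE))
    gri <- gri[!duplicated(paste(gri$from, gri$to)), , drop = FALSE]
  }

  files <- list(
    gwas = file.path(dir, "gwas.tsv"),
    genes = file.path(dir, "genes.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    gri = file.path(dir, "gri.tsv"),
    mendelian = file.path(dir, "mendelian.txt"),
    exome = file.path(dir, "exome.txt"),
    coloc = file.path(dir, "coloc.txt"),
    truth = file.path(dir, "truth.tsv")
  )
  wt <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  wt(gwas, files$gwas)
  wt(genes, files$genes)
  utils::write.table(ppi, files$ppi, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(gri, files$gri, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sort(unique(mend)), files$mendelian)
  writeLines(sort(unique(exome)), files$exome)
  writeLines(sort(unique(coloc)), files$coloc)
  truth <- do.call(rbind, truth_rows)
  truth$gamma_true <- sim$gamma_true
  wt(truth, files$truth)
  invisible(list(files = files, truth = truth, sim = sim))
}

#' Load a study bundle written by \code{simulate_study}
#'
#' Reads the bundle back through the package's standard readers and
#' assembles the locus set (with evidence attached) and the two edge
#' lists, ready for \code{\link{signet}}.
#'
#' @param dir Directory holding the bundle.
#' @param flank_D Flank distance for locus construction.
#' @return List with \code{loci} (a \code{locus_set}), \code{ppi} and
#'   \code{gri} edge data frames, and \code{truth} (NULL when absent).
#' @export
load_study <- function(dir, flank_D = 250000) {
  snps <- read_gwas_associations(file.path(dir, "gwas.tsv"))
  ann <- read_gene_annotation(file.path(dir, "genes.tsv"))
  ls <- build_loci(snps, ann, flank_D = flank_D)
  ls <- attach_evidence(ls,
                        mendelian = read_gene_list(file.path(dir, "mendelian.txt")),
                        exome = read_gene_list(file.path(dir, "exome.txt")),
                        coloc = read_gene_list(file.path(dir, "coloc.txt")))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    utils::read.delim(truth_path, stringsAsFactors = FALSE) else NULL
  list(loci = ls,
       ppi = read_edge_list(file.path(dir, "ppi.tsv"), directed = FALSE),
       gri = read_edge_list(file.path(dir, "gri.tsv"), directed = TRUE),
       truth = truth)
}

#' Planted-gene recovery rates under several fitting variants
#'
#' Generates a study, fits the requested variants, and reports for each
#' the fraction of non-singleton loci at which the planted causal gene is
#' recovered: \code{signet} (full model), \code{mindist}
#' (minimum-distance baseline), \code{best_guess} (evidence-priority
#' initialization, no optimization), \code{no_network} (fit with both
#' networks withheld), and \code{shuffled} (fit on degree-preserving
#' shuffles of both networks).
#'
#' @param sim A \code{\link{sim_config}}.
#' @param n_runs Restarts per fit.
#' @param variants Character subset of
#'   \code{c("signet","mindist","best_guess","no_network","shuffled")}.
#' @param seed Fitting seed (independent of the generator seed).
#' @param dir Directory for the generated bundle (default tempdir).
#' @return A data frame with columns \code{variant} and \code{recovery}.
#' @export
recovery_experiment <- function(sim, n_runs = 10,
                                variants = c("signet", "mindist",
                                             "best_guess", "no_network",
                                             "shuffled"),
                                seed = 1, dir = tempfile("study")) {
  variants <- match.arg(variants, several.ok = TRUE)
  bundle <- simulate_study(sim, dir)
  study <- load_study(dir, flank_D = sim$flank_D)
  ls <- study$loci
  ## locate each planted gene's locus in the rebuilt locus set
  truth <- stats::setNames(
    bundle$truth$planted,
    ls$genes$locus_id[match(bundle$truth$planted, ls$genes$symbol)])
  rate <- function(sel_by_locus) {
    lids <- names(truth)
    mean(sel_by_locus[lids] == truth[lids], na.rm = TRUE)
  }
  fit_rate <- function(ppi, gri) {
    fit <- signet(ls, ppi = ppi, gri = gri, n_runs = n_runs, seed = seed)
    rate(stats::setNames(fit$loci$signet, fit$loci$locus_id))
  }
  out <- list()
  for (v in variants) {
    out[[v]] <- switch(
      v,
      signet = fit_rate(study$ppi, study$gri),
      no_network = fit_rate(NULL, NULL),
      shuffled = {
        ppi_m <- build_network_model(study$ppi, ls, directed = FALSE)
        gri_m <- build_network_model(study$gri, ls, directed = TRUE)
        fit_rate(shuffle_degree_preserving(ppi_m, seed + 7717),
                 shuffle_degree_preserving(gri_m, seed + 7718))
      },
      mindist = {
        g <- ls$genes[ls$genes$is_mindist, ]
        rate(stats::setNames(g$symbol, g$locus_id))
      },
      best_guess = {
        rs <- local_rng(seed)
        cfg <- initialize_best_guess(ls)
        restore_rng(rs)
        rate(cfg)
      }
    )
  }
  data.frame(variant = names(out), recovery = unlist(out),
             row.names = NULL, stringsAsFactors = FALSE)
}
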