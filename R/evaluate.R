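#' One-sided Fisher overlap test of two gene sets
#'
#' Hypergeometric upper-tail probability P(X >= observed overlap) for two
#' sets drawn from a common universe, the direction of interest being
#' enrichment.
#'
#' @param setA,setB Character vectors of gene symbols (subsets of the
#'   universe).
#' @param universe_size Size of the common universe.
#' @return A list (class \code{overlap_result}): \code{overlap},
#'   \code{universe}, \code{p_value}, \code{test}.
#' @export
fisher_overlap <- function(setA, setB, universe_size) {
  setA <- unique(setA)
  setB <- unique(setB)
  k <- length(intersect(setA, setB))
  if (length(setA) > universe_size || length(setB) > universe_size)
    stop("sets larger than the universe")
  ## P(X >= k), X ~ Hypergeometric(|A| draws from |B| of universe)
  p <- stats::phyper(k - 1, length(setB), universe_size - length(setB),
                     length(setA), lower.tail = FALSE)
  structure(list(overlap = k, universe = universe_size,
                 p_value = min(max(p, 0), 1), test = "fisher_one_sided"),
            class = "overlap_result")
}

#' Binomial test of a three-way gene-set overlap
#'
#' The triple overlap is compared with a binomial null in which each of
#' the \code{universe_size} genes independently belongs to all three sets
#' with probability equal to the product of the marginal membership
#' rates; the reported p-value is the upper tail P(X >= k).
#'
#' @param setA,setB,setC Character vectors of gene symbols.
#' @param universe_size Size of the common universe.
#' @return An \code{overlap_result} list.
#' @export
three_way_overlap_test <- function(setA, setB, setC, universe_size) {
  setA <- unique(setA); setB <- unique(setB); setC <- unique(setC)
  k <- length(Reduce(intersect, list(setA, setB, setC)))
  p0 <- prod(length(setA), length(setB), length(setC)) / universe_size^3
  p <- stats::pbinom(k - 1, universe_size, p0, lower.tail = FALSE)
  structure(list(overlap = k, universe = universe_size,
                 p_value = min(max(p, 0), 1), test = "binomial_three_way"),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("%s: overlap %d of universe %d, p = %.3g\n",
              x$test, x$overlap, x$universe, x$p_value))
  invisible(x)
}

#' Hypergeometric gene-set enrichment of a selection
#'
#' For each gene set, the overlap between the selected genes and the set
#' (both intersected with the universe first) is tested with the
#' hypergeometric upper tail, and p-values are Benjamini-Hochberg
#' adjusted across sets. Sets disjoint from the universe are dropped with
#' a warning.
#'
#' @param selected Character vector of selected gene symbols.
#' @param gmt Named list of gene sets, as from \code{\link{read_gmt}}.
#' @param universe Character vector of universe gene symbols (e.g. all
#'   locus genes).
#' @return Data frame with one row per tested set: \code{set},
#'   \code{set_size}, \code{overlap}, \code{p_value}, \code{q_value},
#'   ordered by p-value.
#' @export
geneset_enrichment <- function(selected, gmt, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  selected <- intersect(unique(selected), universe)
  rows <- list()
  dropped <- character(0)
  for (nm in names(gmt)) {
    s <- intersect(gmt[[nm]], universe)
    if (length(s) == 0L) {
      dropped <- c(dropped, nm)
      next
    }
    k <- length(intersect(selected, s))
    p <- stats::phyper(k - 1, length(s), length(universe) - length(s),
                       length(selected), lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, set_size = length(s), overlap = k,
                             p_value = p, stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0L)
    warning(sprintf("%d set(s) disjoint from the universe dropped: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  if (length(rows) == 0L)
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hidden-evidence recovery experiment
#'
#' For every locus where exactly one gene carries any evidence flag, the
#' flags of that gene are cleared, the model is refit, and the test
#' records whether the gene is still the most-selected gene of its locus.
#' The locus set is restored unchanged after each test. Results are
#' tabulated by the gene's highest evidence category (Mendelian > exome >
#' colocalization).
#'
#' @param locus_set A \code{locus_set} with evidence attached.
#' @param ppi,gri Edge data frames (or NULL), as for \code{\link{signet}}.
#' @param n_runs Restarts per refit.
#' @param seed Fitting seed.
#' @return A list with \code{detail} (one row per tested gene:
#'   locus, symbol, category, recovered) and \code{by_category}
#'   (recovered / total per category).
#' @export
hide_information_experiment <- function(locus_set, ppi = NULL, gri = NULL,
                                        n_runs = 10, seed = 1) {
  g <- locus_set$genes
  flagged <- g$has_mendelian | g$has_exome | g$has_coloc
  n_flagged <- tapply(flagged, g$locus_id, sum)
  target_loci <- names(n_flagged)[n_flagged == 1]
  target_loci <- target_loci[!locus_set$loci$is_singleton[
    match(target_loci, locus_set$loci$locus_id)]]
  rows <- list()
  for (lid in target_loci) {
    row <- which(g$locus_id == lid & flagged)
    category <- if (g$has_mendelian[row]) "mendelian" else
      if (g$has_exome[row]) "exome" else "coloc"
    hidden <- locus_set
    hidden$genes[row, c("has_mendelian", "has_exome", "has_coloc")] <- FALSE
    fit <- signet(hidden, ppi = ppi, gri = gri, n_runs = n_runs, seed = seed)
    sel <- fit$loci$signet[fit$loci$locus_id == lid]
    rows[[lid]] <- data.frame(
      locus_id = lid, symbol = g$symbol[row], category = category,
      recovered = identical(sel, g$symbol[row]), stringsAsFactors = FALSE
    )
  }
  detail <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(locus_id = character(), symbol = character(),
               category = character(), recovered = logical(),
               stringsAsFactors = FALSE)
  rownames(detail) <- NULL
  cats <- c("mendelian", "exome", "coloc")
  by_category <- data.frame(
    category = cats,
    total = vapply(cats, function(cc) sum(detail$category == cc), integer(1)),
    recovered = vapply(cats, function(cc)
      sum(detail$recovered[detail$category == cc]), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(by_category) <- NULL
  list(detail = detail, by_category = by_category)
}

#' Parameter dispersion over random locus subsets
#'
#' Repeatedly samples a fraction of the loci without replacement, runs
#' one fit per subset, and reports the mean and standard deviation of the
#' converged parameters across subsets. Pseudocount shrinkage makes the
#' evidence scores of subsets slightly smaller than the full-data scores
#' when the flagged-inactive cells are empty.
#'
#' @param locus_set A \code{locus_set} with evidence attached.
#' @param ppi,gri Edge data frames (or NULL).
#' @param fraction Fraction of loci per subset, in (0, 1].
#' @param n_subsets Number of subsets.
#' @param seed Seed for the subset draws and fits.
#' @param max_passes Pass cap per run.
#' @return A list with \code{per_subset} (one row of converged parameters
#'   per subset) and \code{summary} (mean and sd per parameter).
#' @export
subset_robustness <- function(locus_set, ppi = NULL, gri = NULL,
                              fraction = 0.8, n_subsets = 100, seed = 1,
                              max_passes = 100) {
  stopifnot(fraction > 0, fraction <= 1)
  n_loci <- nrow(locus_set$loci)
  n_take <- ceiling(fraction * n_loci)
  rows <- vector("list", n_subsets)
  for (s in seq_len(n_subsets)) {
    rs <- local_rng(seed + s)
    take <- sort(sample.int(n_loci, n_take))
    restore_rng(rs)
    sub <- subset_locus_set(locus_set, locus_set$loci$locus_id[take])
    fit <- signet(sub, ppi = ppi, gri = gri, n_runs = 1, seed = seed + s,
                  max_passes = max_passes)
    rows[[s]] <- data.frame(subset = s, fit$runs[, c("gamma", "S_mendelian",
                                                     "S_exome", "S_coloc")],
                            stringsAsFactors = FALSE)
  }
  per_subset <- do.call(rbind, rows)
  rownames(per_subset) <- NULL
  pars <- c("gamma", "S_mendelian", "S_exome", "S_coloc")
  summary <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) mean(per_subset[[p]]), numeric(1)),
    sd = vapply(pars, function(p) stats::sd(per_subset[[p]]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(per_subset = per_subset, summary = summary)
}

## restrict a locus_set to a subset of locus ids
subset_locus_set <- function(locus_set, lids) {
  out <- locus_set
  out$loci <- locus_set$loci[locus_set$loci$locus_id %in% lids, , drop = FALSE]
  out$genes <- locus_set$genes[locus_set$genes$locus_id %in% lids, ,
                               drop = FALSE]
  out$snps <- locus_set$snps[locus_set$snps$locus_id %in% lids, , drop = FALSE]
  rownames(out$loci) <- rownames(out$genes) <- rownames(out$snps) <- NULL
  out$L <- sum(!out$loci$is_singleton)
  out$M <- sum(out$loci$is_singleton)
  out$G <- sum(out$loci$n_genes[!out$loci$is_singleton])
  out
}

#' Within-locus rank concordance between two per-gene score tables
#'
#' Subtracts the within-locus maximum from each score table (a monotone
#' per-locus baseline shift), ranks genes within each locus in descending
#' score order, and reports the global Spearman rank correlation and the
#' Pearson correlation of the baseline-subtracted scores over the genes
#' present in both tables. Genes missing from either table are dropped
#' and counted.
#'
#' @param scoresA,scoresB Data frames with columns \code{symbol} and
#'   \code{score}.
#' @param locus_set The \code{locus_set} defining the within-locus
#'   grouping.
#' @return A list: \code{per_gene} (symbol, locus, both centered scores
#'   and ranks), \code{spearman}, \code{pearson}, \code{n_shared},
#'   \code{n_dropped}.
#' @export
rank_concordance <- function(scoresA, scoresB, locus_set) {
  g <- locus_set$genes
  shared <- intersect(intersect(scoresA$symbol, scoresB$symbol), g$symbol)
  n_dropped <- length(union(intersect(scoresA$symbol, g$symbol),
                            intersect(scoresB$symbol, g$symbol))) -
    length(shared)
  if (length(shared) == 0L) stop("no shared genes between the score tables")
  tab <- data.frame(
    symbol = shared,
    locus_id = g$locus_id[match(shared, g$symbol)],
    scoreA = scoresA$score[match(shared, scoresA$symbol)],
    scoreB = scoresB$score[match(shared, scoresB$symbol)],
    stringsAsFactors = FALSE
  )
  center_rank <- function(x, lid) {
    cx <- x - stats::ave(x, lid, FUN = max)
    rk <- stats::ave(-cx, lid, FUN = rank)
    list(centered = cx, rank = rk)
  }
  a <- center_rank(tab$scoreA, tab$locus_id)
  b <- center_rank(tab$scoreB, tab$locus_id)
  tab$centeredA <- a$centered; tab$rankA <- a$rank
  tab$centeredB <- b$centered; tab$rankB <- b$rank
  list(per_gene = tab,
       spearman = stats::cor(tab$centeredA, tab$centeredB,
                             method = "spearman"),
       pearson = stats::cor(tab$centeredA, tab$centeredB),
       n_shared = length(shared), n_dropped = n_dropped)
}
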