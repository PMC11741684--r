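#' Log-density of the exponential SNP-to-TSS distance model
#'
#' The distance score of an active gene at signed distance \code{x} is the
#' log of a two-sided exponential density with scale \code{gamma}:
#' \code{-log(2*gamma) - |x|/gamma}. The normalizer \code{1/(2*gamma)}
#' makes \code{exp(score)} integrate to 1 over the real line. Singleton
#' Mendelian genes are scored at \code{x = 0}.
#'
#' @param x Signed distance(s) in bp.
#' @param gamma Scale of the exponential decay in bp (positive; fitted
#'   values are floored at 1 bp by \code{\link{update_gamma}}).
#' @return Log-density value(s) in nats.
#' @export
distance_log_density <- function(x, gamma) {
  stopifnot(gamma > 0)
  -log(2 * gamma) - abs(x) / gamma
}

#' Maximum-likelihood update of the distance scale
#'
#' The stationary point of the active-gene distance log-likelihood in
#' \code{gamma} is the mean absolute distance of the active genes at GWAS
#' loci. Singleton Mendelian genes (pinned at x = 0) are excluded from the
#' update. The result is floored at 1 bp to guard degenerate inputs; if no
#' eligible gene exists the previous value is kept with a warning.
#'
#' @param x Signed distances of the active genes at GWAS (non-singleton)
#'   loci, in bp.
#' @param prev Previous gamma, returned when \code{x} is empty.
#' @return Updated gamma in bp.
#' @export
update_gamma <- function(x, prev = NULL) {
  if (length(x) == 0L) {
    warning("no active non-singleton genes; keeping previous gamma")
    if (is.null(prev)) stop("update_gamma: no eligible genes and no previous value")
    return(prev)
  }
  max(mean(abs(x)), 1)
}

#' Log-odds score of a categorical evidence feature
#'
#' The pseudocounted maximum-likelihood log-odds ratio
#' \code{log((n11+c)/(n10+c)) - log((n01+c)/(n00+c))}, where n11/n10 are
#' active genes with/without the feature and n01/n00 inactive genes
#' with/without it. Counts may be fractional (e.g. expected counts under
#' proportional subsampling).
#'
#' @param n00,n01,n10,n11 Nonnegative (possibly fractional) counts.
#' @param c Pseudocount added to every cell (default 1).
#' @return The feature score S_f in nats.
#' @export
feature_score <- function(n00, n01, n10, n11, c = 1) {
  stopifnot(n00 >= 0, n01 >= 0, n10 >= 0, n11 >= 0, c >= 0)
  log((n11 + c) / (n10 + c)) - log((n01 + c) / (n00 + c))
}

#' Categorical evidence contribution of an active gene
#'
#' Sum over the evidence categories of the feature score for each flag the
#' gene carries; a gene without a feature contributes 0 for that feature.
#' The per-locus baseline (all genes inactive) is constant within a locus
#' and omitted.
#'
#' @param flags Named logical vector (or list) with elements
#'   \code{has_mendelian}, \code{has_exome}, \code{has_coloc}.
#' @param S Named numeric vector with elements \code{mendelian},
#'   \code{exome}, \code{coloc}: the current feature scores.
#' @return The summed log-score contribution.
#' @export
categorical_contribution <- function(flags, S) {
  (if (isTRUE(flags[["has_mendelian"]])) S[["mendelian"]] else 0) +
    (if (isTRUE(flags[["has_exome"]])) S[["exome"]] else 0) +
    (if (isTRUE(flags[["has_coloc"]])) S[["coloc"]] else 0)
}

#' Network log-likelihood ratio for an observed edge count
#'
#' Log ratio of the flat (integrated Bernoulli) alternative to the Poisson
#' degree-corrected null for E observed edges among active genes:
#' \code{lgamma(E+1) - E*log(E0) + E0 - log(T+1)}, with the convention
#' \code{0*log(0) = 0}, so \code{E = 0, E0 = 0} gives \code{-log(T+1)}.
#' \code{E0 = 0} with \code{E > 0} is impossible for a propensity-derived
#' E0 (any connected active pair has positive degrees) and raises an error.
#'
#' @param E Observed edge count (nonnegative; may be real when evaluating
#'   the baseline at E = E0).
#' @param E0 Expected count under the null (nonnegative real).
#' @param T_pairs Total number of (un)ordered gene pairs.
#' @return The log-likelihood ratio Lambda in nats.
#' @export
network_log_likelihood_ratio <- function(E, E0, T_pairs) {
  stopifnot(E >= 0, E0 >= 0, T_pairs >= 0)
  if (E0 == 0) {
    if (E > 0) stop("E0 = 0 with E > 0 violates the degree-corrected null")
    return(-log(T_pairs + 1))
  }
  lgamma(E + 1) - E * log(E0) + E0 - log(T_pairs + 1)
}

#' Enrichment-only network score
#'
#' Reflects the network log-likelihood ratio about its baseline at
#' \code{E = E0} so that only edge enrichment, never depletion, is
#' rewarded: \code{S = Lambda(E0) + sgn(E - E0) * |Lambda(E) - Lambda(E0)|}.
#' The baseline uses the continuous log-gamma extension at the generally
#' non-integer E0.
#'
#' @inheritParams network_log_likelihood_ratio
#' @return The network score in nats.
#' @export
network_score <- function(E, E0, T_pairs) {
  lam0 <- network_log_likelihood_ratio(E0, E0, T_pairs)
  lam <- network_log_likelihood_ratio(E, E0, T_pairs)
  lam0 + sign(E - E0) * abs(lam - lam0)
}

#' Softmax weights of within-locus gene scores
#'
#' \code{w_i = exp(S_i) / sum_j exp(S_j)} over the genes of one locus,
#' computed with max-subtraction for numerical stability. Weights are
#' invariant to any constant shift of the scores and sum to 1.
#'
#' @param S Numeric vector of total gene scores at one locus.
#' @return Numeric vector of weights summing to 1.
#' @export
locus_weights <- function(S) {
  stopifnot(length(S) >= 1)
  e <- exp(S - max(S))
  e / sum(e)
}

#' Tally evidence-feature contingency counts for a configuration
#'
#' For each evidence category, counts over all genes in GWAS loci
#' (singleton Mendelian loci are excluded entirely): n11 active with the
#' feature, n10 active without, n01 inactive with, n00 inactive without.
#' Within each category the active counts total L (the number of GWAS
#' loci) and all four cells total G.
#'
#' @param config Named character vector mapping locus id to active gene.
#' @param locus_set The \code{locus_set}.
#' @return A list with one \code{c(n00, n01, n10, n11)} vector per
#'   category: \code{mendelian}, \code{exome}, \code{coloc}.
#' @export
update_feature_counts <- function(config, locus_set) {
  g <- locus_set$genes[!locus_set$genes$is_singleton, , drop = FALSE]
  active <- g$symbol == unname(config[g$locus_id])
  tally <- function(flag) {
    n11 <- sum(active & flag)
    n10 <- sum(active & !flag)
    n01 <- sum(!active & flag)
    n00 <- sum(!active & !flag)
    c(n00 = n00, n01 = n01, n10 = n10, n11 = n11)
  }
  list(mendelian = tally(g$has_mendelian),
       exome = tally(g$has_exome),
       coloc = tally(g$has_coloc))
}

#' Total score of a candidate gene at its locus
#'
#' The sum of the six score components for gene \code{symbol} substituted
#' as the active gene of its locus, with the active genes at all other
#' loci frozen: distance, three categorical evidence terms, and the PPI
#' and GRI network scores (evaluated through the per-network cache).
#'
#' @param symbol Candidate gene symbol.
#' @param config Named character vector, the current configuration.
#' @param locus_set The \code{locus_set}.
#' @param networks List with elements \code{ppi} and \code{gri}
#'   (\code{network_model} or NULL).
#' @param params List with \code{gamma} and \code{S} (named feature scores).
#' @return A named numeric vector of the six components and their sum
#'   \code{total}.
#' @export
gene_total_score <- function(symbol, config, locus_set, networks, params) {
  g <- locus_set$genes
  row <- match(symbol, g$symbol)
  stopifnot(!is.na(row))
  lid <- g$locus_id[row]
  cfg <- config
  cfg[lid] <- symbol
  active <- g$symbol %in% unname(cfg)
  s_dist <- distance_log_density(g$x[row], params$gamma)
  s_mend <- if (g$has_mendelian[row]) params$S[["mendelian"]] else 0
  s_exome <- if (g$has_exome[row]) params$S[["exome"]] else 0
  s_coloc <- if (g$has_coloc[row]) params$S[["coloc"]] else 0
  s_ppi <- if (is.null(networks$ppi)) 0 else
    cached_network_score(networks$ppi, active)
  s_gri <- if (is.null(networks$gri)) 0 else
    cached_network_score(networks$gri, active)
  total <- s_dist + s_mend + s_exome + s_coloc + s_ppi + s_gri
  c(S_Distance = s_dist, S_Mendelian = s_mend, S_Exome = s_exome,
    S_Colocalization = s_coloc, S_PPI = s_ppi, S_GRI = s_gri,
    total = total)
}

#' Profile score of a whole configuration
#'
#' A single number summarizing a configuration with its own
#' maximum-likelihood parameters: distance log-density summed over active
#' genes (gamma profiled on the active non-singleton genes), the
#' categorical contribution \code{S_f * n11} per feature with S_f profiled
#' from the configuration's own counts, and the two enrichment-only
#' network scores. Used to compare converged fits against exhaustive
#' enumeration on small instances.
#'
#' @inheritParams gene_total_score
#' @param pseudocount Pseudocount for the feature scores.
#' @return The profile score in nats.
#' @export
config_score <- function(config, locus_set, networks, pseudocount = 1) {
  g <- locus_set$genes
  active <- g$symbol %in% unname(config)
  ax <- g$x[active & !g$is_singleton]
  gamma <- if (length(ax) > 0) max(mean(abs(ax)), 1) else 1
  counts <- update_feature_counts(config, locus_set)
  s <- 0
  for (nm in names(counts)) {
    cc <- counts[[nm]]
    s <- s + feature_score(cc["n00"], cc["n01"], cc["n10"], cc["n11"],
                           pseudocount) * cc[["n11"]]
  }
  s <- s + sum(distance_log_density(g$x[active], gamma))
  for (nm in c("ppi", "gri")) {
    if (!is.null(networks[[nm]]))
      s <- s + cached_network_score(networks[[nm]], active)
  }
  unname(s)
}
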