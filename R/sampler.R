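#' Best-guess initial configuration
#'
#' Picks the most plausible causal gene per locus by evidence priority:
#' Mendelian first, then exome, then colocalized; a locus with no flagged
#' gene starts from its minimum-distance gene. Ties within the winning
#' priority class are broken uniformly at random with the current RNG.
#' Singleton Mendelian loci are always assigned their gene.
#'
#' @param locus_set A \code{locus_set} with evidence attached.
#' @return Named character vector mapping locus id to active gene symbol.
#' @export
initialize_best_guess <- function(locus_set) {
  g <- locus_set$genes
  out <- character(0)
  for (lid in locus_set$loci$locus_id) {
    rows <- which(g$locus_id == lid)
    pick <- NULL
    for (flag in c("has_mendelian", "has_exome", "has_coloc")) {
      cand <- rows[g[[flag]][rows]]
      if (length(cand) > 0L) { pick <- cand; break }
    }
    if (is.null(pick)) pick <- rows[g$is_mindist[rows]]
    if (length(pick) == 0L) pick <- rows
    sel <- if (length(pick) == 1L) pick else pick[sample.int(length(pick), 1L)]
    out[lid] <- g$symbol[sel]
  }
  out
}

#' Random initial configuration
#'
#' Selects one gene uniformly at random per locus; singleton loci are
#' still forced to their gene.
#'
#' @inheritParams initialize_best_guess
#' @return Named character vector mapping locus id to active gene symbol.
#' @export
initialize_random <- function(locus_set) {
  g <- locus_set$genes
  out <- character(0)
  for (lid in locus_set$loci$locus_id) {
    rows <- which(g$locus_id == lid)
    sel <- if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
    out[lid] <- g$symbol[sel]
  }
  out
}

## Per-pass parameter update: gamma by ML on active non-singleton genes,
## feature scores from the configuration's contingency counts.
update_parameters <- function(config, locus_set, prev = NULL,
                              pseudocount = 1) {
  g <- locus_set$genes
  active <- g$symbol %in% unname(config)
  ax <- g$x[active & !g$is_singleton]
  gamma <- if (length(ax) == 0L) {
    update_gamma(numeric(0), prev = if (is.null(prev)) locus_set$flank_D
                 else prev$gamma)
  } else update_gamma(ax)
  counts <- update_feature_counts(config, locus_set)
  S <- vapply(counts, function(cc) {
    feature_score(cc[["n00"]], cc[["n01"]], cc[["n10"]], cc[["n11"]],
                  pseudocount)
  }, numeric(1))
  list(gamma = gamma, S = S, counts = counts)
}

## One optimization pass: visit the non-singleton loci in a fresh random
## permutation; at each locus freeze all others, score every member gene as
## the locus's active gene, and set the active gene to the argmax (ties
## broken uniformly at random). Returns the new configuration, whether any
## locus changed, and the softmax weights recorded at each visit.
sweep_pass <- function(config, locus_set, networks, params,
                       greedy = TRUE) {
  g <- locus_set$genes
  active <- g$symbol %in% unname(config)
  lids <- locus_set$loci$locus_id[!locus_set$loci$is_singleton]
  if (length(lids) > 1L && greedy) lids <- sample(lids)
  weights <- rep(NA_real_, nrow(g))
  locus_rows <- split(seq_len(nrow(g)), g$locus_id)
  changed <- FALSE
  ## precompute per-gene within-locus score pieces that do not depend on
  ## the configuration
  s_local <- distance_log_density(g$x, params$gamma) +
    ifelse(g$has_mendelian, params$S[["mendelian"]], 0) +
    ifelse(g$has_exome, params$S[["exome"]], 0) +
    ifelse(g$has_coloc, params$S[["coloc"]], 0)
  for (lid in lids) {
    rows <- locus_rows[[lid]]
    cur <- rows[active[rows]]
    S <- s_local[rows]
    if (!is.null(networks$ppi) || !is.null(networks$gri)) {
      active[cur] <- FALSE
      for (k in seq_along(rows)) {
        active[rows[k]] <- TRUE
        if (!is.null(networks$ppi))
          S[k] <- S[k] + cached_network_score(networks$ppi, active)
        if (!is.null(networks$gri))
          S[k] <- S[k] + cached_network_score(networks$gri, active)
        active[rows[k]] <- FALSE
      }
    } else {
      active[cur] <- FALSE
    }
    weights[rows] <- locus_weights(S)
    if (greedy) {
      mx <- max(S)
      best <- which(S == mx)
      sel <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    } else {
      sel <- which(rows == cur)
    }
    new_row <- rows[sel]
    active[new_row] <- TRUE
    if (new_row != cur) {
      changed <- TRUE
      config[lid] <- g$symbol[new_row]
    }
  }
  ## singleton loci have a single permanently active gene
  weights[g$is_singleton] <- 1
  list(config = config, changed = changed, weights = weights)
}

## One full run: initialize, iterate sweeps with end-of-pass parameter
## updates until a pass changes nothing (or max_passes), then one
## scoring-only sweep for the final weights.
run_single <- function(locus_set, networks, run_seed,
                       init = c("best_guess", "random"),
                       max_passes = 100, pseudocount = 1) {
  init <- match.arg(init)
  rs <- local_rng(run_seed)
  on.exit(restore_rng(rs), add = TRUE)
  config <- if (init == "best_guess") initialize_best_guess(locus_set)
            else initialize_random(locus_set)
  params <- update_parameters(config, locus_set, pseudocount = pseudocount)
  init_params <- params
  converged <- FALSE
  passes <- 0L
  while (passes < max_passes) {
    passes <- passes + 1L
    res <- sweep_pass(config, locus_set, networks, params)
    config <- res$config
    params <- update_parameters(config, locus_set, prev = params,
                                pseudocount = pseudocount)
    if (!res$changed) {
      converged <- TRUE
      break
    }
  }
  final <- sweep_pass(config, locus_set, networks, params, greedy = FALSE)
  list(config = config, weights = final$weights, passes = passes,
       converged = converged, params = params, init_params = init_params)
}

#' Fit the causal-gene selection model
#'
#' Runs the iterative greedy sampler \code{n_runs} times from independent
#' seeded starts, each run sweeping the loci in random order, selecting
#' the highest-scoring gene per locus with all other loci frozen, and
#' updating the distance scale and evidence scores by maximum likelihood
#' at the end of each pass until the configuration is a fixed point.
#' Results are aggregated into per-gene selection frequencies and mean
#' final weights, and per-locus SigNet / SigNet+ / MinDist gene lists.
#'
#' @param loci A \code{locus_set} built by \code{\link{build_loci}} and
#'   \code{\link{attach_evidence}}.
#' @param ppi Undirected protein-protein edges: a data frame with columns
#'   \code{from}/\code{to}, a prebuilt \code{network_model}, or NULL for
#'   no PPI evidence.
#' @param gri Directed regulator-to-target edges, same forms as \code{ppi}.
#' @param n_runs Number of independent restarts (default 100).
#' @param init Initialization mode: \code{"best_guess"} (evidence priority,
#'   then minimum distance) or \code{"random"}.
#' @param max_passes Pass cap per run (default 100).
#' @param pseudocount Pseudocount for the evidence feature scores.
#' @param seed Base seed; run r uses \code{seed + r}.
#' @return An object of class \code{"signet"} with components
#'   \code{genes} (per-gene table with selection frequencies, mean
#'   weights and selection indicators), \code{loci} (per-locus gene
#'   lists), \code{runs} (per-run convergence and parameter log),
#'   \code{locus_set}, and \code{networks}.
#' @seealso \code{\link{summary.signet}}, \code{\link{write_summary_table}},
#'   \code{\link{simulate_study}}
#' @export
signet <- function(loci, ppi = NULL, gri = NULL, n_runs = 100,
                   init = c("best_guess", "random"), max_passes = 100,
                   pseudocount = 1, seed = 1) {
  stopifnot(inherits(loci, "locus_set"), n_runs >= 1)
  init <- match.arg(init)
  networks <- list(
    ppi = as_network_model(ppi, loci, directed = FALSE),
    gri = as_network_model(gri, loci, directed = TRUE)
  )
  g <- loci$genes
  n_sel <- numeric(nrow(g))
  w_sum <- numeric(nrow(g))
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    one <- run_single(loci, networks, run_seed = seed + r, init = init,
                      max_passes = max_passes, pseudocount = pseudocount)
    sel <- g$symbol %in% unname(one$config)
    n_sel <- n_sel + sel
    w_sum <- w_sum + one$weights
    runs[[r]] <- data.frame(
      run = r, seed = seed + r, passes = one$passes,
      converged = one$converged, gamma = one$params$gamma,
      S_mendelian = one$params$S[["mendelian"]],
      S_exome = one$params$S[["exome"]],
      S_coloc = one$params$S[["coloc"]], stringsAsFactors = FALSE
    )
  }
  g$selection_frequency <- n_sel / n_runs
  g$mean_weight <- w_sum / n_runs

  ## per-locus gene lists: SigNet = most selected (ties lexicographic),
  ## SigNet+ = SigNet union flagged genes, MinDist as built
  locus_rows <- split(seq_len(nrow(g)), g$locus_id)
  loci_tab <- loci$loci
  loci_tab$signet <- NA_character_
  loci_tab$signet_plus <- NA_character_
  loci_tab$mindist <- NA_character_
  loci_tab$signet_tie <- FALSE
  g$is_signet <- FALSE
  g$is_signet_plus <- FALSE
  for (i in seq_len(nrow(loci_tab))) {
    rows <- locus_rows[[loci_tab$locus_id[i]]]
    f <- g$selection_frequency[rows]
    top <- rows[f == max(f)]
    pick <- top[order(g$symbol[top])][1]
    loci_tab$signet_tie[i] <- length(top) > 1L
    loci_tab$signet[i] <- g$symbol[pick]
    g$is_signet[pick] <- TRUE
    plus <- union(g$symbol[pick],
                  g$symbol[rows][g$has_mendelian[rows] | g$has_exome[rows] |
                                   g$has_coloc[rows]])
    plus <- sort(plus)
    loci_tab$signet_plus[i] <- paste(plus, collapse = ",")
    g$is_signet_plus[rows] <- g$symbol[rows] %in% plus
    md <- rows[g$is_mindist[rows]]
    loci_tab$mindist[i] <- if (length(md) == 1L) g$symbol[md] else
      g$symbol[rows][1]
  }
  fit <- list(
    genes = g,
    loci = loci_tab,
    runs = do.call(rbind, runs),
    locus_set = loci,
    networks = networks,
    n_runs = n_runs,
    init = init,
    seed = seed,
    pseudocount = pseudocount,
    call = match.call()
  )
  class(fit) <- "signet"
  fit
}

as_network_model <- function(x, locus_set, directed) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "network_model")) return(x)
  build_network_model(x, locus_set, directed = directed)
}

#' Per-locus gene lists from a fit
#'
#' @param fit A fitted \code{signet} object.
#' @return A data frame with one row per locus: the SigNet gene (most
#'   frequently selected over runs), the SigNet+ set (SigNet gene plus all
#'   genes with any evidence flag, comma-separated), and the MinDist gene.
#' @export
extract_gene_lists <- function(fit) {
  stopifnot(inherits(fit, "signet"))
  fit$loci[, c("locus_id", "signet", "signet_plus", "mindist", "signet_tie")]
}

#' @export
print.signet <- function(x, ...) {
  cat(sprintf("signet fit: %d GWAS loci (%d genes) + %d singleton Mendelian loci\n",
              x$locus_set$L, x$locus_set$G, x$locus_set$M))
  cat(sprintf("  %d runs (%s init), %d/%d converged, median %g passes\n",
              x$n_runs, x$init, sum(x$runs$converged), x$n_runs,
              stats::median(x$runs$passes)))
  cv <- coef(x)
  cat(sprintf("  gamma = %.1f kb; S_Mendelian = %.2f, S_Exome = %.2f, S_Coloc = %.2f\n",
              cv[["gamma"]] / 1000, cv[["S_mendelian"]], cv[["S_exome"]],
              cv[["S_coloc"]]))
  agree <- sum(x$loci$signet == x$loci$mindist & !x$loci$is_singleton)
  cat(sprintf("  SigNet = MinDist at %d of %d GWAS loci\n",
              agree, sum(!x$loci$is_singleton)))
  invisible(x)
}

#' Mean converged parameters of a fit
#'
#' @param object A fitted \code{signet} object.
#' @param ... Unused.
#' @return Named vector: mean over runs of the converged distance scale
#'   \code{gamma} (bp) and the three evidence scores (nats).
#' @export
coef.signet <- function(object, ...) {
  c(gamma = mean(object$runs$gamma),
    S_mendelian = mean(object$runs$S_mendelian),
    S_exome = mean(object$runs$S_exome),
    S_coloc = mean(object$runs$S_coloc))
}

#' Summary of a fit
#'
#' @param object A fitted \code{signet} object.
#' @param ... Unused.
#' @return An object of class \code{summary.signet}: the per-gene summary
#'   table, per-locus gene lists, and the mean and standard deviation of
#'   the converged parameters across runs.
#' @export
summary.signet <- function(object, ...) {
  pr <- object$runs
  par_tab <- data.frame(
    parameter = c("gamma", "S_mendelian", "S_exome", "S_coloc"),
    mean = c(mean(pr$gamma), mean(pr$S_mendelian), mean(pr$S_exome),
             mean(pr$S_coloc)),
    sd = c(stats::sd(pr$gamma), stats::sd(pr$S_mendelian),
           stats::sd(pr$S_exome), stats::sd(pr$S_coloc)),
    stringsAsFactors = FALSE
  )
  out <- list(genes = summary_gene_table(object),
              loci = extract_gene_lists(object),
              parameters = par_tab,
              n_runs = object$n_runs)
  class(out) <- "summary.signet"
  out
}

#' @export
print.summary.signet <- function(x, ...) {
  cat(sprintf("Converged parameters over %d runs:\n", x$n_runs))
  print(x$parameters, row.names = FALSE, digits = 4)
  cat(sprintf("\n%d loci; first selections:\n", nrow(x$loci)))
  print(utils::head(x$loci, 10), row.names = FALSE)
  invisible(x)
}

#' Selection-frequency versus gene-weight plot
#'
#' Scatter of per-gene selection frequency (fraction of runs the gene
#' ends active) against mean final weight (softmax probability under the
#' converged configuration), both in [0,1]. A well-converged fit shows
#' points concentrated near (0,0) and (1,1), with the greedy selection
#' frequency more extreme than the weight.
#'
#' @param x A fitted \code{signet} object.
#' @param ... Passed to \code{plot}.
#' @export
plot.signet <- function(x, ...) {
  g <- x$genes
  graphics::plot(g$mean_weight, g$selection_frequency,
                 xlab = "mean gene weight", ylab = "selection frequency",
                 xlim = c(0, 1), ylim = c(0, 1),
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.5),
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Per-gene residual selection signal
#'
#' Difference between the greedy selection frequency and the model weight
#' for every gene: large positive values mark genes the argmax rule locks
#' in more strongly than their posterior weight alone would suggest.
#'
#' @param object A fitted \code{signet} object.
#' @param ... Unused.
#' @return Named numeric vector (gene symbols).
#' @export
residuals.signet <- function(object, ...) {
  stats::setNames(object$genes$selection_frequency - object$genes$mean_weight,
                  object$genes$symbol)
}
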