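#' Build a degree-corrected network model over locus genes
#'
#' Restricts an edge list to pairs whose both endpoints are locus genes
#' (GWAS locus members plus singleton Mendelian genes), computes vertex
#' degrees and the degree-corrected edge propensities on this restricted
#' network, and fixes the pair-count constant \code{T} used by the network
#' score. For an undirected network (PPI) the propensity of gene i is
#' \code{delta_i = d_i / (2 E_tot)} and \code{T = (L+M)(L+M-1)/2}, the
#' number of unordered pairs of active genes. For a directed network (GRI,
#' regulator to target) in- and out-degrees are kept separately,
#' \code{delta_in = d_in / E_tot}, \code{delta_out = d_out / E_tot}, and
#' \code{T = (G+M)(G+M-1)}, the number of ordered pairs of genes. Genes
#' absent from the edge list have zero propensity. An empty restricted
#' network yields \code{E_tot = 0} and all-zero propensities, so the score
#' contributes a constant.
#'
#' @param edges Edge data frame with columns \code{from}, \code{to}, as
#'   from \code{\link{read_edge_list}}.
#' @param locus_set A \code{locus_set} with evidence attached.
#' @param directed Logical; directed (regulatory) or undirected (PPI).
#' @return A \code{network_model} object.
#' @export
build_network_model <- function(edges, locus_set, directed = FALSE) {
  stopifnot(inherits(locus_set, "locus_set"))
  genes <- locus_set$genes$symbol
  n_active <- locus_set$L + locus_set$M
  n_genes <- length(genes)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  keep <- edges$from %in% genes & edges$to %in% genes & edges$from != edges$to
  edges <- edges[keep, , drop = FALSE]
  if (!directed) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges$from <- a
    edges$to <- b
  }
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  ei <- match(edges$from, genes)
  ej <- match(edges$to, genes)
  E_tot <- nrow(edges)
  model <- list(
    directed = directed,
    genes = genes,
    edges = edges,
    ei = ei, ej = ej,
    E_tot = E_tot,
    n_active = n_active,
    cache = new.env(parent = emptyenv())
  )
  if (directed) {
    d_in <- tabulate(ej, nbins = n_genes)
    d_out <- tabulate(ei, nbins = n_genes)
    model$d_in <- stats::setNames(d_in, genes)
    model$d_out <- stats::setNames(d_out, genes)
    model$delta_in <- if (E_tot > 0) d_in / E_tot else rep(0, n_genes)
    model$delta_out <- if (E_tot > 0) d_out / E_tot else rep(0, n_genes)
    names(model$delta_in) <- names(model$delta_out) <- genes
    model$T_pairs <- n_genes * (n_genes - 1)
    model$nonzero <- which(d_in + d_out > 0)
  } else {
    d <- tabulate(ei, nbins = n_genes) + tabulate(ej, nbins = n_genes)
    model$degree <- stats::setNames(d, genes)
    model$delta <- if (E_tot > 0) d / (2 * E_tot) else rep(0, n_genes)
    names(model$delta) <- genes
    model$T_pairs <- n_active * (n_active - 1) / 2
    model$nonzero <- which(d > 0)
  }
  class(model) <- "network_model"
  model
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("%s network model: %d genes, %d edges, T = %g\n",
              if (x$directed) "Directed" else "Undirected",
              length(x$genes), x$E_tot, x$T_pairs))
  invisible(x)
}

## Coerce an active-gene specification (symbols or logical over model$genes)
## to a logical membership vector.
active_mask <- function(model, active) {
  if (is.logical(active)) {
    stopifnot(length(active) == length(model$genes))
    return(active)
  }
  model$genes %in% active
}

#' Observed edge count among active genes
#'
#' Counts edges of the restricted network whose both endpoints are active:
#' unordered pairs for an undirected model, ordered pairs for a directed
#' model; self-edges were already removed at model construction.
#'
#' @param model A \code{network_model}.
#' @param active Character vector of active gene symbols, or a logical
#'   vector over \code{model$genes}.
#' @return Integer edge count E.
#' @export
count_active_edges <- function(model, active) {
  m <- active_mask(model, active)
  sum(m[model$ei] & m[model$ej])
}

#' Expected edge count among active genes under the degree-corrected null
#'
#' The factorized form of the pairwise sum of propensity products:
#' undirected \code{E0 = (sum delta)^2/2 - sum(delta^2)/2}; directed
#' \code{E0 = (sum delta_in)(sum delta_out) - sum(delta_in * delta_out)},
#' both over the active genes (self-pairs subtracted).
#'
#' @inheritParams count_active_edges
#' @return The real-valued expected count E0.
#' @export
expected_active_edges <- function(model, active) {
  m <- active_mask(model, active)
  if (model$directed) {
    di <- model$delta_in[m]
    do <- model$delta_out[m]
    sum(di) * sum(do) - sum(di * do)
  } else {
    d <- model$delta[m]
    0.5 * sum(d)^2 - 0.5 * sum(d * d)
  }
}

#' Degree-preserving shuffle of a network model
#'
#' Configuration-model resampling by stub matching: each edge endpoint
#' becomes a stub, stubs are paired by a seeded random permutation (for a
#' directed model, out-stubs are matched to permuted in-stubs), and the
#' resulting multigraph is collapsed by dropping self-edges and duplicate
#' edges, as in standard configuration-model practice. The stub multiset
#' always equals the original degree sequence exactly; the collapsed
#' simple graph may lose a few edges. The same seed reproduces the same
#' shuffled model.
#'
#' @param model A \code{network_model}.
#' @param seed Integer seed for the permutation.
#' @return A new \code{network_model} over the same genes, with the same
#'   \code{T} constant, rebuilt from the shuffled edges.
#' @export
shuffle_degree_preserving <- function(model, seed) {
  if (model$E_tot == 0L) return(model)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs), add = TRUE)
  if (model$directed) {
    from <- model$genes[model$ei]
    to <- model$genes[sample(model$ej)]
  } else {
    stubs <- c(model$ei, model$ej)
    stubs <- sample(stubs)
    half <- length(stubs) / 2
    from <- model$genes[stubs[seq_len(half)]]
    to <- model$genes[stubs[half + seq_len(half)]]
  }
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  ls_stub <- list(genes = data.frame(symbol = model$genes,
                                     stringsAsFactors = FALSE),
                  L = model$n_active, M = 0L)
  class(ls_stub) <- "locus_set"
  out <- build_network_model(edges, ls_stub, directed = model$directed)
  ## keep the original pair-count constants (locus structure unchanged)
  out$T_pairs <- model$T_pairs
  out$n_active <- model$n_active
  out
}

#' Cached network score of an active gene set
#'
#' Computes \code{score_fn(E, E0, T)} for the active set, caching the
#' result keyed by the sorted active genes with nonzero degree in this
#' network: zero-degree genes cannot change E or E0, so configurations
#' differing only in zero-degree genes share one cache entry. Cache hits
#' return the stored value bit-identically.
#'
#' @inheritParams count_active_edges
#' @param score_fn A pure function of \code{(E, E0, T)}; defaults to
#'   \code{\link{network_score}}.
#' @return The (possibly cached) score.
#' @export
cached_network_score <- function(model, active, score_fn = network_score) {
  m <- active_mask(model, active)
  nz <- model$nonzero[m[model$nonzero]]
  key <- paste0("k", paste(nz, collapse = ","))
  hit <- get0(key, envir = model$cache)
  if (!is.null(hit)) return(hit)
  E <- sum(m[model$ei] & m[model$ej])
  E0 <- expected_active_edges(model, m)
  val <- score_fn(E, E0, model$T_pairs)
  assign(key, val, envir = model$cache)
  val
}

## Seed-scoped RNG helpers: save the caller's RNG state, seed, and restore.
local_rng <- function(seed) {
  rs <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  rs
}

restore_rng <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", rs, envir = globalenv())
  }
  invisible(NULL)
}
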