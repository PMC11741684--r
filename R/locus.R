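#' Genes within the flanking window of a SNP
#'
#' Returns the genes on the SNP's chromosome whose TSS lies within
#' \code{D} bp of the SNP (inclusive boundary). If no TSS falls inside the
#' window, the window is extended to the single nearest-TSS gene so every
#' significant SNP maps to at least one candidate.
#'
#' @param snp A one-row data frame (or list) with \code{chrom} and \code{pos}.
#' @param genes Gene annotation as from \code{\link{read_gene_annotation}}.
#' @param D Flank distance in bp (default 250000).
#' @return Character vector of gene symbols in the window.
#' @export
snp_window <- function(snp, genes, D = 250000) {
  on_chrom <- genes[genes$chrom == snp$chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0L)
    stop(sprintf("no annotated genes on chromosome '%s'", snp$chrom))
  dist <- abs(on_chrom$tss - snp$pos)
  hit <- dist <= D
  if (!any(hit)) {
    ## fallback: extend to the closest gene
    nearest <- order(dist, on_chrom$symbol)[1]
    return(on_chrom$symbol[nearest])
  }
  on_chrom$symbol[hit]
}

#' Build merged GWAS loci from significant SNPs
#'
#' Maps each SNP to its flanking-window gene set and merges windows that
#' share at least one gene into a single candidate locus (transitive
#' closure under the shared-gene relation). SNPs from all traits are
#' pooled before windowing. For every member gene the signed distance
#' \code{x} to the nearest locus SNP is computed (negative when the SNP
#' lies 5' of the TSS on the gene's sense strand), and the gene with the
#' smallest \code{|x|} is marked as the MinDist gene of the locus (ties
#' broken by symbol).
#'
#' @param snps Associations as from \code{\link{read_gwas_associations}}.
#' @param genes Annotation as from \code{\link{read_gene_annotation}}.
#' @param flank_D Flank distance D in bp (default 250000).
#' @return A \code{locus_set} object: a list with per-gene assignments
#'   (\code{genes}), per-locus table (\code{loci}), SNP table
#'   (\code{snps}), and the counts \code{L} (GWAS loci), \code{M}
#'   (singleton Mendelian loci, 0 until \code{\link{attach_evidence}}),
#'   and \code{G} (genes in GWAS loci).
#' @export
build_loci <- function(snps, genes, flank_D = 250000) {
  stopifnot(nrow(snps) >= 0, nrow(genes) >= 1)
  if (nrow(snps) == 0L) {
    ls <- empty_locus_set(flank_D)
    ls$annotation <- genes
    return(ls)
  }
  windows <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    windows[[i]] <- snp_window(snps[i, ], genes, flank_D)
  }
  ## union-find over windows, joined through shared genes
  parent <- seq_len(nrow(snps))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  gene_owner <- new.env(parent = emptyenv())
  for (i in seq_along(windows)) {
    for (g in windows[[i]]) {
      j <- get0(g, envir = gene_owner)
      if (is.null(j)) {
        assign(g, i, envir = gene_owner)
      } else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_along(windows), find, integer(1))
  comps <- split(seq_along(windows), comp)

  ## deterministic locus ids: order components by chromosome, then min pos
  chrom_of <- vapply(comps, function(ix) snps$chrom[ix[1]], character(1))
  minpos <- vapply(comps, function(ix) min(snps$pos[ix]), numeric(1))
  comps <- comps[order(chrom_of, minpos)]

  gene_rows <- list()
  loci_rows <- list()
  snp_rows <- list()
  ann <- genes
  rownames(ann) <- ann$symbol
  for (k in seq_along(comps)) {
    ix <- comps[[k]]
    lid <- sprintf("locus_%04d", k)
    members <- sort(unique(unlist(windows[ix])))
    lsnps <- snps[ix, , drop = FALSE]
    grec <- ann[members, , drop = FALSE]
    x <- vapply(seq_along(members), function(m) {
      signed_distance(grec[m, ], lsnps)
    }, numeric(1))
    mind <- order(abs(x), members)[1]
    gene_rows[[k]] <- data.frame(
      locus_id = lid, symbol = members, chrom = grec$chrom,
      strand = grec$strand, tss = grec$tss, start = grec$start,
      end = grec$end, x = x,
      has_mendelian = FALSE, has_exome = FALSE, has_coloc = FALSE,
      is_mindist = seq_along(members) == mind,
      is_singleton = FALSE, stringsAsFactors = FALSE
    )
    loci_rows[[k]] <- data.frame(
      locus_id = lid, chrom = lsnps$chrom[1], n_genes = length(members),
      n_snps = nrow(lsnps), is_singleton = FALSE, stringsAsFactors = FALSE
    )
    lsnps$locus_id <- lid
    snp_rows[[k]] <- lsnps
  }
  gene_tab <- do.call(rbind, gene_rows)
  if (anyDuplicated(gene_tab$symbol))
    stop("internal error: a gene was assigned to two loci")
  out <- list(
    genes = gene_tab,
    loci = do.call(rbind, loci_rows),
    snps = do.call(rbind, snp_rows),
    L = length(comps),
    M = 0L,
    G = nrow(gene_tab),
    flank_D = flank_D,
    annotation = genes
  )
  class(out) <- "locus_set"
  out
}

empty_locus_set <- function(flank_D) {
  out <- list(
    genes = data.frame(locus_id = character(), symbol = character(),
                       chrom = character(), strand = character(),
                       tss = integer(), start = integer(), end = integer(),
                       x = numeric(), has_mendelian = logical(),
                       has_exome = logical(), has_coloc = logical(),
                       is_mindist = logical(), is_singleton = logical(),
                       stringsAsFactors = FALSE),
    loci = data.frame(locus_id = character(), chrom = character(),
                      n_genes = integer(), n_snps = integer(),
                      is_singleton = logical(), stringsAsFactors = FALSE),
    snps = data.frame(rsid = character(), chrom = character(),
                      pos = integer(), trait = character(),
                      pvalue = numeric(), locus_id = character(),
                      stringsAsFactors = FALSE),
    L = 0L, M = 0L, G = 0L, flank_D = flank_D, annotation = NULL
  )
  class(out) <- "locus_set"
  out
}

#' Signed SNP-to-TSS distance of minimum magnitude
#'
#' The distance from a gene's TSS to the closest of the given SNPs, signed
#' by orientation: negative when the SNP lies 5' of the TSS on the gene's
#' sense strand, positive when it lies 3' of the TSS (within or beyond the
#' gene body). On the + strand this is \code{pos - tss}; on the - strand,
#' \code{tss - pos}.
#'
#' @param gene One-row data frame (or list) with \code{tss} and \code{strand}.
#' @param snps Data frame of SNPs with a \code{pos} column; must be non-empty.
#' @return The signed distance (bp) of minimum absolute value.
#' @export
signed_distance <- function(gene, snps) {
  if (nrow(snps) == 0L) stop("signed_distance requires at least one SNP")
  s <- if (gene$strand == "+") snps$pos - gene$tss else gene$tss - snps$pos
  s[order(abs(s), -s)][1]
}

#' Attach functional evidence and create singleton Mendelian loci
#'
#' Sets the Mendelian / exome / colocalization flags on locus member genes.
#' A Mendelian gene that falls outside every GWAS locus becomes a new
#' single-gene locus with distance \code{x = 0}; such singleton loci keep
#' their gene permanently active during fitting. Evidence symbols absent
#' from the annotation raise a warning and are skipped.
#'
#' @param locus_set A \code{locus_set} from \code{\link{build_loci}}.
#' @param mendelian,exome,coloc Character vectors of gene symbols (any may
#'   be empty).
#' @param annotation Gene annotation used to place singleton Mendelian
#'   genes; defaults to the annotation captured by \code{build_loci}.
#' @return The updated \code{locus_set} with flags set and \code{M} updated.
#' @export
attach_evidence <- function(locus_set, mendelian = character(),
                            exome = character(), coloc = character(),
                            annotation = locus_set$annotation) {
  stopifnot(inherits(locus_set, "locus_set"))
  g <- locus_set$genes
  known <- if (is.null(annotation)) g$symbol else
    union(annotation$symbol, g$symbol)
  for (nm in c("mendelian", "exome", "coloc")) {
    ev <- get(nm)
    missing_syms <- setdiff(ev, known)
    if (length(missing_syms) > 0L) {
      warning(sprintf("%d %s evidence symbol(s) absent from annotation, skipped: %s",
                      length(missing_syms), nm,
                      paste(utils::head(missing_syms, 5), collapse = ", ")))
    }
  }
  mendelian <- intersect(mendelian, known)
  exome <- intersect(exome, known)
  coloc <- intersect(coloc, known)
  g$has_mendelian <- g$has_mendelian | g$symbol %in% mendelian
  g$has_exome <- g$has_exome | g$symbol %in% exome
  g$has_coloc <- g$has_coloc | g$symbol %in% coloc

  ## Mendelian genes outside every locus become singleton loci, x = 0
  outside <- setdiff(mendelian, g$symbol)
  outside <- sort(intersect(outside,
                            if (is.null(annotation)) character() else annotation$symbol))
  if (length(outside) > 0L) {
    ann <- annotation
    rownames(ann) <- ann$symbol
    rec <- ann[outside, , drop = FALSE]
    lid <- sprintf("mendelian_%s", outside)
    add <- data.frame(
      locus_id = lid, symbol = outside, chrom = rec$chrom,
      strand = rec$strand, tss = rec$tss, start = rec$start, end = rec$end,
      x = 0,
      has_mendelian = TRUE,
      has_exome = outside %in% exome,
      has_coloc = outside %in% coloc,
      is_mindist = FALSE, is_singleton = TRUE, stringsAsFactors = FALSE
    )
    g <- rbind(g, add)
    locus_set$loci <- rbind(locus_set$loci, data.frame(
      locus_id = lid, chrom = rec$chrom, n_genes = 1L, n_snps = 0L,
      is_singleton = TRUE, stringsAsFactors = FALSE
    ))
  }
  rownames(g) <- NULL
  locus_set$genes <- g
  locus_set$M <- sum(locus_set$loci$is_singleton)
  locus_set
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Locus set: %d GWAS loci (%d genes) + %d singleton Mendelian loci\n",
              x$L, x$G, x$M))
  cat(sprintf("  flank D = %d bp; %d SNPs; evidence flags: %d Mendelian, %d exome, %d coloc\n",
              x$flank_D, nrow(x$snps), sum(x$genes$has_mendelian),
              sum(x$genes$has_exome), sum(x$genes$has_coloc)))
  invisible(x)
}
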