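#' Read GWAS summary associations
#'
#' Reads a tab-delimited table of genome-wide association results and keeps
#' the genome-wide-significant records. Columns are located by header name
#' (case-insensitive): \code{rsid}, \code{chrom}, \code{pos}, \code{trait},
#' \code{pvalue}. Rows with a p-value above \code{p_threshold} are dropped,
#' and duplicated (rsid, trait) pairs are collapsed keeping the smallest
#' p-value, so re-reading a written subset is idempotent.
#'
#' @param path Path to a tab-delimited file with a header line.
#' @param p_threshold Retain associations with \code{pvalue <= p_threshold}.
#'   Default \code{5e-8}, the conventional genome-wide significance level.
#' @return A data frame with columns \code{rsid}, \code{chrom}, \code{pos},
#'   \code{trait}, \code{pvalue}, one row per retained association.
#' @export
read_gwas_associations <- function(path, p_threshold = 5e-8) {
  tab <- read_tsv_checked(path, c("rsid", "chrom", "pos", "trait", "pvalue"))
  if (nrow(tab) == 0L) return(tab)
  pos <- suppressWarnings(as.numeric(tab$pos))
  bad <- which(!is.finite(pos) | pos < 1)
  if (length(bad) > 0L) {
    stop(sprintf("unparseable position in '%s' at data line %d: '%s'",
                 path, bad[1], tab$pos[bad[1]]))
  }
  tab$pos <- as.integer(round(pos))
  pv <- suppressWarnings(as.numeric(tab$pvalue))
  bad <- which(!is.finite(pv) | pv < 0 | pv > 1)
  if (length(bad) > 0L) {
    stop(sprintf("p-value outside [0,1] in '%s' at data line %d: '%s'",
                 path, bad[1], tab$pvalue[bad[1]]))
  }
  tab$pvalue <- pv
  if (any(!nzchar(tab$rsid))) stop(sprintf("empty rsid in '%s'", path))
  tab <- tab[tab$pvalue <= p_threshold, , drop = FALSE]
  ## deduplicate (rsid, trait), keeping the smallest p-value
  o <- order(tab$rsid, tab$trait, tab$pvalue)
  tab <- tab[o, , drop = FALSE]
  key <- paste(tab$rsid, tab$trait, sep = "\r")
  tab <- tab[!duplicated(key), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read a gene annotation table
#'
#' Reads a tab-delimited annotation with columns \code{symbol},
#' \code{chrom}, \code{strand}, \code{start}, \code{end} (1-based,
#' inclusive). The transcription start site is derived from the maximal
#' gene boundary: \code{start} on the + strand, \code{end} on the - strand.
#' Duplicate symbols are collapsed to the widest bounds (union) before the
#' TSS is derived, so a symbol appears at most once in the result.
#'
#' @param path Path to a tab-delimited file with a header line.
#' @return A data frame with columns \code{symbol}, \code{chrom},
#'   \code{strand}, \code{tss}, \code{start}, \code{end}.
#' @export
read_gene_annotation <- function(path) {
  tab <- read_tsv_checked(path, c("symbol", "chrom", "strand", "start", "end"))
  if (nrow(tab) > 0L && !all(tab$strand %in% c("+", "-"))) {
    bad <- which(!(tab$strand %in% c("+", "-")))[1]
    stop(sprintf("strand must be '+' or '-' in '%s' at data line %d: '%s'",
                 path, bad, tab$strand[bad]))
  }
  tab$start <- as_coord(tab$start, path, "start")
  tab$end <- as_coord(tab$end, path, "end")
  if (any(tab$start > tab$end)) stop(sprintf("start > end in '%s'", path))
  if (nrow(tab) > 0L && anyDuplicated(tab$symbol)) {
    ## collapse duplicate symbols to the union of bounds
    start <- tapply(tab$start, tab$symbol, min)
    end <- tapply(tab$end, tab$symbol, max)
    first <- tab[!duplicated(tab$symbol), , drop = FALSE]
    chr <- tapply(tab$chrom, tab$symbol, function(v) v[1])
    if (any(tapply(tab$chrom, tab$symbol, function(v) length(unique(v))) > 1L))
      stop(sprintf("duplicate symbol on different chromosomes in '%s'", path))
    first$start <- as.integer(start[first$symbol])
    first$end <- as.integer(end[first$symbol])
    tab <- first
  }
  tab$tss <- ifelse(tab$strand == "+", tab$start, tab$end)
  rownames(tab) <- NULL
  tab[, c("symbol", "chrom", "strand", "tss", "start", "end")]
}

#' Read a two-column edge list
#'
#' Reads a tab-delimited edge list of gene symbols. Self-edges are always
#' dropped. In undirected mode each pair is stored unordered (the smaller
#' symbol first) and duplicates, including reversed duplicates, are
#' collapsed. In directed mode the order (source regulator, target) is
#' preserved and only exact duplicates are collapsed.
#'
#' @param path Path to a tab-delimited file; a header line is detected and
#'   skipped when its first two fields are \code{from}/\code{to} (any case).
#' @param directed Logical; interpret rows as ordered source-target pairs.
#' @return A data frame with columns \code{from} and \code{to}.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- vapply(parts, length, integer(1))
  if (any(nc < 2L)) {
    stop(sprintf("edge list '%s' needs 2 tab-separated columns; line %d has %d",
                 path, which(nc < 2L)[1], nc[which(nc < 2L)[1]]))
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  if (tolower(from[1]) %in% c("from", "source") &&
      tolower(to[1]) %in% c("to", "target")) {
    from <- from[-1]
    to <- to[-1]
  }
  keep <- from != to                      # self-edges are ignored
  from <- from[keep]
  to <- to[keep]
  if (!directed) {
    a <- pmin(from, to)
    b <- pmax(from, to)
    from <- a
    to <- b
  }
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to a text file with one gene symbol per line; blank
#'   lines and lines starting with '#' are skipped.
#' @return A character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-delimited, fields are set
#' name, description, then member symbols.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(sprintf("GMT line with fewer than 3 fields in '%s'", path))
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' Write the per-gene summary table of a fit
#'
#' Writes one row per gene: locus id, symbol, signed SNP-to-TSS distance,
#' evidence flags, mean weight, selection frequency, and indicator columns
#' for the SigNet, SigNet+ and MinDist selections. Rows are ordered by
#' locus id then absolute distance, so output is deterministic and
#' round-trips through \code{read.delim} unchanged.
#'
#' @param fit A fitted \code{signet} object (see \code{\link{signet}}).
#' @param path Output path for the tab-delimited table.
#' @return Invisibly, the data frame written.
#' @export
write_summary_table <- function(fit, path) {
  stopifnot(inherits(fit, "signet"))
  tab <- summary_gene_table(fit)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(tab)
}

## Build the summary data frame for write_summary_table / summary().
summary_gene_table <- function(fit) {
  g <- fit$genes
  tab <- data.frame(
    locus_id = g$locus_id,
    symbol = g$symbol,
    distance = g$x,
    mendelian = as.integer(g$has_mendelian),
    exome = as.integer(g$has_exome),
    coloc = as.integer(g$has_coloc),
    mean_weight = g$mean_weight,
    selection_frequency = g$selection_frequency,
    signet = as.integer(g$is_signet),
    signet_plus = as.integer(g$is_signet_plus),
    mindist = as.integer(g$is_mindist),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$locus_id, abs(tab$distance), tab$symbol), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

## --- internal helpers -----------------------------------------------------

## Read a header-named TSV and map required columns case-insensitively.
read_tsv_checked <- function(path, required) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  nm <- tolower(trimws(names(tab)))
  idx <- match(required, nm)
  if (anyNA(idx)) {
    stop(sprintf("file '%s' is missing required column '%s'",
                 path, required[which(is.na(idx))[1]]))
  }
  out <- tab[, idx, drop = FALSE]
  names(out) <- required
  out
}

as_coord <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(v) | v < 1)
  if (length(bad) > 0L) {
    stop(sprintf("unparseable %s coordinate in '%s' at data line %d: '%s'",
                 what, path, bad[1], x[bad[1]]))
  }
  as.integer(round(v))
}
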