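# Fixture builders shared across test files. All fixtures are built in code.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

write_lines <- function(x, path = tempfile(fileext = ".txt")) {
  writeLines(x, path)
  path
}

gwas_df <- function(rsid, chrom, pos, pvalue, trait = "t1") {
  data.frame(rsid = rsid, chrom = rep_len(chrom, length(rsid)),
             pos = pos, trait = rep_len(trait, length(rsid)),
             pvalue = pvalue, stringsAsFactors = FALSE)
}

genes_df <- function(symbol, chrom, strand, start, end) {
  data.frame(symbol = symbol, chrom = chrom, strand = strand,
             start = start, end = end, stringsAsFactors = FALSE)
}

# A hand-sized locus set: helper builds it straight from in-memory tables.
make_locus_set <- function(snps, genes, flank_D = 250000,
                           mendelian = character(), exome = character(),
                           coloc = character()) {
  ls <- build_loci(snps, read_gene_annotation(write_tsv(genes)),
                   flank_D = flank_D)
  suppressWarnings(
    attach_evidence(ls, mendelian = mendelian, exome = exome, coloc = coloc)
  )
}

# Three loci on separate chromosomes, two genes each, at controlled
# distances; used by sampler and scoring tests.
toy_three_locus <- function(mendelian = character(), exome = character(),
                            coloc = character()) {
  snps <- gwas_df(paste0("rs", 1:3), paste0("chr", 1:3),
                  c(1e6, 1e6, 1e6), rep(1e-9, 3))
  genes <- genes_df(
    symbol = c("A1", "A2", "B1", "B2", "C1", "C2"),
    chrom = rep(paste0("chr", 1:3), each = 2),
    strand = "+",
    start = c(1e6 + 1e3, 1e6 + 5e4,    # locus A: 1 kb and 50 kb
              1e6 + 2e3, 1e6 + 8e4,    # locus B
              1e6 + 3e3, 1e6 + 6e4),   # locus C
    end = c(1e6 + 1e3, 1e6 + 5e4, 1e6 + 2e3, 1e6 + 8e4,
            1e6 + 3e3, 1e6 + 6e4) + 500
  )
  make_locus_set(snps, genes, mendelian = mendelian, exome = exome,
                 coloc = coloc)
}

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
}

# Brute-force pairwise E0 oracle (the spec's double-sum form).
e0_pairwise <- function(model, active) {
  m <- model$genes %in% active
  if (model$directed) {
    din <- model$delta_in[m]
    dout <- model$delta_out[m]
    tot <- 0
    for (i in seq_along(din)) {
      for (j in seq_along(dout)) {
        if (i != j) tot <- tot + din[i] * dout[j]
      }
    }
    unname(tot)
  } else {
    d <- model$delta[m]
    tot <- 0
    if (length(d) >= 2) {
      for (i in seq_len(length(d) - 1)) {
        for (j in (i + 1):length(d)) tot <- tot + d[i] * d[j]
      }
    }
    unname(tot)
  }
}

# Enumerate all configurations of a locus_set (small instances only).
enumerate_configs <- function(locus_set) {
  g <- locus_set$genes
  lids <- locus_set$loci$locus_id
  choices <- lapply(lids, function(l) {
    if (locus_set$loci$is_singleton[match(l, lids)])
      g$symbol[g$locus_id == l]
    else g$symbol[g$locus_id == l]
  })
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  names(grid) <- lids
  grid
}
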