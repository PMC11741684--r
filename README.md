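# signet

Causal-gene prioritization at GWAS loci by Bayesian data integration.

A genome-wide association study points at SNPs, not genes: each
significant locus typically contains several candidate genes, and the
gene nearest the signal is causal only about two-thirds of the time.
`signet` selects one active gene per locus by combining, in a single
log-likelihood score per gene,

- an exponential SNP-to-TSS **distance** model, `S_Dist(x) = −ln(2γ) − |x|/γ`,
  with γ re-estimated by maximum likelihood each pass;
- three binary **evidence** flags (Mendelian disease, exome variant, eQTL
  colocalization), each scored as a pseudocounted log-odds ratio
  `S_f = ln[(n11+1)/(n10+1)] − ln[(n01+1)/(n00+1)]` learned from the current
  selection;
- **network enrichment** among the selected genes in a protein–protein
  (undirected) and a gene-regulatory (directed) network, scored as
  `Λ(E) = lnΓ(E+1) − E ln E0 + E0 − ln(T+1)` against a degree-corrected
  expected count `E0` (products of normalized vertex degrees), reflected
  about its baseline at `E = E0` so only edge *excess* over the null is
  rewarded — hub genes get no free ride.

Optimization is an iterative greedy coordinate ascent: passes visit loci
in random order, swap in the argmax gene with all other loci frozen, and
update the parameters at the end of each pass until the configuration is
a fixed point. One hundred independent restarts are aggregated into
per-gene selection frequencies and per-locus gene lists: **SigNet** (most
frequently selected gene), **SigNet+** (SigNet plus all evidence-flagged
genes), and the **MinDist** baseline.

The package also ships a synthetic-study generator with planted causal
genes (`simulate_study`), degree-preserving network shuffles, and
evaluation utilities (Fisher/binomial overlap tests, hypergeometric
gene-set enrichment with BH correction, hidden-evidence recovery, subset
robustness, within-locus rank concordance).

## Worked example

```r
library(signet)

dir <- tempfile()
simulate_study(sim_config(n_loci = 60, seed = 1), dir)  # synthetic study
study <- load_study(dir)                                # back through the readers
fit <- signet(study$loci, ppi = study$ppi, gri = study$gri,
              n_runs = 20, seed = 1)
print(fit)
#> signet fit: 60 GWAS loci (300 genes) + 8 singleton Mendelian loci
#>   20 runs (best_guess init), 20/20 converged, median 4 passes
#>   gamma = 91.5 kb; S_Mendelian = 2.02, S_Exome = 1.39, S_Coloc = 3.56
#>   SigNet = MinDist at 18 of 60 GWAS loci

head(extract_gene_lists(fit), 3)
#>    locus_id signet signet_plus mindist signet_tie
#>  locus_0001   g1_1        g1_1    g1_2      FALSE
#>  locus_0002  g23_5       g23_5   g23_5      FALSE
#>  locus_0003  g45_3       g45_3   g45_1      FALSE
```

Reading the output: γ converged to 91.5 kb (the mean |TSS–SNP| distance of
the selected genes; the generator truncates planted distances at the
250 kb flank, so this sits below the 150 kb generating scale), the
evidence log-odds scores are in the 1.4–3.6 nat range (exp of a score is
the selection odds a flag confers), and at 42 of 60 loci the network and
evidence moved the selection away from the nearest gene. On this study
the selected genes recover the planted causal gene at 60/60 loci, versus
~20 for the MinDist baseline. The companion vignette
(`vignettes/signet-methods.Rmd`) documents the model, the update
formulas, the generator's design, and the package's numerical choices.

Real studies are fit the same way from files — `read_gwas_associations()`,
`read_gene_annotation()`, `read_edge_list()`, `build_loci()`,
`attach_evidence()` — or from the shell:

```sh
exec/signet run --gwas gwas.tsv --genes genes.tsv --ppi ppi.tsv \
    --gri gri.tsv --mendelian omim.txt --exome exome.txt --coloc coloc.txt \
    --flank 250000 --runs 100 --seed 1 --out out/
exec/signet simulate --config sim.yaml --out study/
exec/signet evaluate --selected selected.txt --gmt pathways.gmt \
    --universe universe.txt --out eval/
```

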