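# coexpair

Cell-type-resolved co-expression analysis of genes encoding interacting
proteins, for droplet single-cell (scRNA-seq) and single-nucleus
(sNucRNA-seq) UMI data.

## The question

Two proteins can only form a complex if they are present in the same cell
at the same time. Given a list of high-confidence protein–protein
interaction pairs (e.g. membrane-protein pairs from size-exclusion
chromatography + mass spectrometry), their encoding genes should therefore
be *co-expressed within the same cell type*. `coexpair` tests this
transcriptional support for an interactome, cluster by cluster:

1. **Per-cluster average expression.** Counts are library-size normalized
   (`x_gi -> log(1 + 10^4 * x_gi / sum_g x_gi)`) and averaged per cluster
   on the de-logged scale, giving a pseudobulk profile `avg[g, c]`.
2. **Co-expression filter.** A pair `(a, b)` is *co-expressed* in cluster
   `c` iff `avg[a, c] >= 0.15` **and** `avg[b, c] >= 0.15` (inclusive).
3. **Per-cluster Pearson correlation.** Over the retained pairs of each
   cluster, `r_c = cor(avg[a, c], avg[b, c])` across pairs — do the two
   members of a pair tend to sit at similar expression levels?
4. **Random-pair null.** The identical filter + correlation pipeline is run
   on replicates of equally many uniformly drawn random gene pairs; the
   comparison statistic is `delta_r = r_true − mean(r_null)` per cluster.

Supporting stages: 10x-style MTX ingestion, percentile-interval barcode QC
(total UMIs and detected genes inside the central 95%), marker-gene
dot-plot statistics (`pct_expressing`, `mean_expression`) with z-score
cluster annotation, and barcode-majority label transfer between
clusterings. A negative-binomial simulator with planted co-regulated pairs,
cluster markers, and a cell-vs-nucleus depth contrast provides ground truth
for every claim the test suite makes. Cluster labels are *inputs*
(alignment, ambient-RNA cleanup, doublet removal, integration, and
clustering are out of scope).

## Worked example

```r
library(coexpair)
sim  <- simulate_counts(sim_config(n_clusters = 3, cells_per_cluster = 150,
                                   n_genes = 500, n_pairs = 50, seed = 7))
mat  <- filter_outliers(sim$matrix, level = 0.95)$matrix
norm <- normalize_counts(mat)
prof <- average_by_cluster(norm, cluster_assignment(sim$truth$cluster_of))
res  <- coexpressed_pairs(prof, sim$truth$true_pairs, coexpr_config())
print(res)
#> <pair_coexpr> 50 pairs; union co-expressed 45 (90%)
#>  cluster n_coexpressed pct_coexpressed pearson_r
#>      C01            43              86 0.2552276
#>      C02            44              88 0.3356499
#>      C03            42              84 0.3572722

reps <- draw_random_pairs(rownames(prof$avg)[rowSums(prof$avg) > 0],
                          sim$truth$true_pairs,
                          null_config(n_draws = 10, seed = 7))
compare_to_null(res, null_coexpression(prof, reps))
#>   cluster r_true mean_r_null delta_r n_coexpressed_true mean_n_coexpressed_null
#> 1     C01  0.255     0.01169   0.244                 43                    38.4
#> 2     C02  0.336     0.00222   0.333                 44                    40.1
#> 3     C03  0.357     0.02354   0.334                 42                    37.6
```

Reading: 43 of the 50 interaction pairs pass the 0.15 filter in cluster
C01 (86%); their members' average expressions correlate at r = 0.26, while
equally many random pairs correlate at ~0.01 — the planted co-regulation
(latent correlation 0.6, attenuated at the cluster-average level) is
detected in every cluster. Percentages round half-up:
`pct(516, 1752)` is `29.5`, `pct(1099, 1752)` is `62.7`.

One-command demo (simulate → QC → profiles → annotate → co-expression →
null → report): `run_demo(seed = 1)`, or from the shell via the CLI:

```sh
Rscript inst/cli/coexpair.R demo --seed 1
Rscript inst/cli/coexpair.R coexpr --matrix fixture/ \
    --clusters fixture/clusters.tsv --pairs fixture/pairs.tsv --min-expr 0.15
```

(After installation the launcher lives at
`system.file("cli", "coexpair.R", package = "coexpair")`.)

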