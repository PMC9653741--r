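# paircoda

Compositionality-aware analysis of paired luminal (stool) and
tumor-associated (brush biopsy) gut microbiome profiles from patients with
precancerous colorectal lesions — and of how community composition relates
to lesion characteristics (location, number, size, NICE category,
malignization pathway).

16S count tables only carry *relative* information, so every statistic here
lives in Aitchison's simplex geometry. For a composition `x` with `D`
parts,

```
clr(x)_i = ln x_i − (1/D) Σ_j ln x_j
```

and the Aitchison distance between samples is the Euclidean distance of
their clr vectors. A **balance** between disjoint taxon sets `B+` (size
`k+`) and `B−` (size `k−`) is the normalized log-contrast

```
b(x) = sqrt(k+ k− / (k+ + k−)) · [ mean ln x_{B+} − mean ln x_{B−} ]
```

whose contrast vector has unit norm in clr space. The package's core method
is the **nearest balance**: given per-taxon clr regression coefficients
`b ∈ R^D` for a factor, find the balance whose contrast maximizes cosine
similarity with `b`, then keep only the taxa assigned to the same side in
more than 80% of 500 refits on random 50% subsamples.

## What's inside

| module | functions |
|---|---|
| I/O | `read_count_table` (TSV/BIOM), `read_metadata`, `remove_contaminants`, `aggregate_metadata` |
| CoDA core | `zero_replace` (0.5 pseudocount), `clr`, `ilr`/`ilr_inverse`, `aitchison_distance`, `perturb`, `sample_type_correction`, `aggregate_to_rank` |
| Diversity | `rarefy`, `shannon`, `chao1`, `alpha_diversity` |
| Balances | `clr_association`, `nearest_balance`, `reproducible_balance`, `balance_value`, `evaluate_balance_external`, `sample_type_auc` |
| Association stats | `permanova` (covariates + strata), `alpha_association`, `componentwise`, `bh_adjust` |
| Cooperatives | `prevalence_filter`, `mb_network` (neighborhood selection + StARS), `louvain_clusters`, `cooperative_association` |
| Synthetic data | `synthetic_truth`, `generate_cohort`, `generate_block_cohort`, `truth_metrics` |
| Pipeline | `pipeline_config`, `run_pipeline`, CLI at `inst/cli/paircoda.R` |

## Worked example

Simulate a 50-patient paired cohort (150 taxa, two batches, a planted
balance linked to the number of lesions), then recover that balance from
the stool samples and test the stool-vs-biopsy contrast:

```r
library(paircoda)
coh <- generate_cohort(n_patients = 50, n_taxa = 150, seed = 7)

des   <- assoc_design("n_lesions", random = "batch")
stool <- coh$metadata$sample_id[coh$metadata$sample_type == "stool"]
fit <- reproducible_balance(subset_count_table(coh$counts, samples = stool),
                            coh$metadata, des, n_iter = 500, seed = 7)
fit
#> balance_fit (fixed, 500 iterations, threshold 0.80):
#> balance: 6 numerator vs 5 denominator taxa
#>   num: t006, t023, t081, t086, t091, t149
#>   den: t002, t008, t029, t036, t103
#>   cosine with full-data coefficients: 0.8967

unlist(truth_metrics(fit, coh$truth))
#>   jaccard_num   jaccard_den jaccard_union        cosine
#>     0.8333333     1.0000000     0.9090909     0.8818386
```

All five planted denominator taxa and five of six numerator taxa are the
planted ones (`t149` is a rare-taxon false positive — see the vignette on
zero-replacement artifacts); set-overlap Jaccard with the planted balance
is 0.91.

```r
comp <- zero_replace(coh$counts)          # 0.5 pseudocount, closed
meta <- coh$metadata
meta$shannon <- alpha_diversity(rarefy(coh$counts, seed = 1))$shannon
permanova(aitchison_distance(comp), meta,
          assoc_design("sample_type", covariates = "shannon",
                       random = "patient_id", strata = "patient_id"),
          n_perm = 999, seed = 7)
#> PERMANOVA: sample_type  R2 = 0.1574  pseudo-F = 25.344  p = 0.001 (999 perms, n = 100)
```

The paired stool-vs-biopsy contrast explains ~16% of Aitchison-distance
variance in this synthetic cohort and is maximally significant at 999
within-patient permutations.

## Command line

Every stage is a subcommand of `inst/cli/paircoda.R`:

```sh
Rscript inst/cli/paircoda.R simulate --n-patients 50 --seed 1 --out demo
Rscript inst/cli/paircoda.R run-all --counts demo/counts.tsv \
    --metadata demo/metadata.tsv --out demo/results --seed 1
```

Subcommands: `simulate`, `filter`, `diversity`, `compare-types`, `correct`,
`permanova-screen`, `nearest-balance`, `cooperatives`, `componentwise`,
`run-all`.

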