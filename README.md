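# preproscan

Peptide-centric detection of partially processed chloroplast preproteins
from data-independent-acquisition (DIA) proteomics.

## The problem

Nuclear-encoded chloroplast proteins are imported as preproteins with an
N-terminal chloroplast transit peptide (cTP); thylakoid-lumen proteins
(PsbO/PsbP/PsbQ of the oxygen-evolving complex, PsaN, PsaF) carry a
bipartite presequence whose second part, the lumenal targeting peptide
(lTP), is cleaved only after translocation across the thylakoid membrane.
When processing stalls — for instance when photosynthesis collapses in
conditional Arabidopsis mutants under monochromatic red light — partially
processed intermediates accumulate. In bottom-up proteomics this leaves a
precise peptide-level fingerprint: tryptic peptides spanning the
presequence go **up** while the parent protein (and every peptide wholly in
its mature region) goes **down**.

`preproscan` turns that fingerprint into a tested pipeline for proteomics
analysts. For a mutant-vs-control comparison it computes, per peptide on
the log2 scale,

```
gap = peptide_ratio - protein_ratio
```

and keeps peptides with `protein_ratio < -0.4` and `gap >= 1.0` (the
ratio-gap filter; a strict mode additionally requires the peptide's own BH
q-value < 0.05 and a positive ratio). Candidates are mapped onto annotated
cTP/lTP regions, and a protein with targeting-region candidates plus a
depleted protein ratio is called an **accumulator**.

Around this core the package implements the supporting stages: protein
summarization by summing assigned peptide intensities, minimum-valid-value
filtering, down-shifted-normal imputation of left-censored intensities
(reference-column-only for peptide fold changes), median normalization,
pooled-variance t-tests with per-comparison Benjamini–Hochberg control, 1D
annotation enrichment (Mann–Whitney with rank-biserial scores), PCA,
average-linkage clustering, in-silico Trypsin/P digestion, chlorophyll
fluorescence utilities — and a synthetic DIA generator with planted ground
truth that validates every stage at desk scale.

## Worked example

Simulate a two-condition experiment (Col vs abc1k1 analogs under red
light, 4 replicates each) with 12 planted preprotein accumulators among
120 proteins, run the full pipeline, and inspect the calls:

```r
library(preproscan)

cfg <- run_config(seed = 42,
                  sim = simulation_params(n_proteins = 120L,
                                          n_accumulators = 12L))
res <- run_all(cfg, "demo_run")

res$protein_processed
#> quant_matrix: 120 protein features x 8 samples [log2 scale], 0 missing (0.0%)
#> groups: abc1k1_RL (n=4), Col_RL (n=4)

res$summary
#>         comparison n_significant percent
#> 1 Col_RL-abc1k1_RL            25   20.83

calls <- subset(res$calls, verdict == "accumulator")
head(calls[, c("protein_id", "protein_ratio",
               "n_targeting_candidates", "mature_consistent")], 5)
#>  protein_id protein_ratio n_targeting_candidates mature_consistent
#>    PROT0002    -0.8569614                     18              TRUE
#>    PROT0004    -0.8783933                     10              TRUE
#>    PROT0005    -0.9986080                     10              TRUE
#>    PROT0007    -0.8444793                     11              TRUE
#>    PROT0008    -0.9021668                     14              TRUE
```

Reading the output: 25 of 120 proteins (20.83 % of total) differ
significantly between the conditions; the called accumulators are depleted
at the protein level (ratios near the planted −1.0 log2) while 10–18 of
their presequence-spanning peptides pass the ratio-gap filter, and their
wholly-mature peptides stay consistent with the protein trend. In this run
all 12 planted accumulators are recovered. The 1D enrichment table shows
the photosynthesis class strongly depleted in the mutant comparison
(median log2 difference −0.95, q ≈ 1.5e-11):

```r
res$enrichment
#>            term size      score median_diff      q_value significant
#>     Chloroplast   48 -0.9890046 -0.15790312 8.366952e-20        TRUE
#>         Cytosol   72  0.9890046  0.02130041 8.366952e-20        TRUE
#>  Photosynthesis   18 -1.0000000 -0.94757089 1.549087e-11        TRUE
```

`run_all()` writes every stage as TSV (`differential.tsv`,
`peptide_ratios.tsv`, `candidates.tsv`, `calls.tsv`, `summary.tsv`, ...)
plus a `run.log`; outputs are byte-identical for the same configuration
and seed. `make_report("demo_run")` builds the volcano plot, the
gap-vs-protein-ratio plane with the threshold guides, and positional
profiles of called accumulators.

A thin command-line front-end is available at
`inst/scripts/preproscan.R` (`run`, `simulate`, `report` subcommands), and
`vignettes/preproscan-methods.Rmd` documents the model, parameter choices
and validation strategy in detail.

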