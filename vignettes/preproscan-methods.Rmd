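---
title: "Detecting partially processed thylakoid preproteins from peptide-level DIA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting partially processed thylakoid preproteins from peptide-level DIA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preproscan)
```

## The biological question

Most photosynthesis-associated proteins of the chloroplast are encoded in
the nucleus and imported as preproteins carrying an N-terminal chloroplast
transit peptide (cTP). Thylakoid-lumen residents — PsbO/PsbP/PsbQ of the
oxygen-evolving complex, PsaN and PsaF of the plastocyanin docking site —
carry a *bipartite* presequence: the cTP (cleaved by the stromal processing
peptidase after envelope import) followed by a lumenal targeting peptide
(lTP, cleaved by the thylakoid processing peptidase after translocation
across the thylakoid membrane). When thylakoid translocation stalls, the
cell accumulates partially processed intermediates that still carry part of
their presequence.

Bottom-up proteomics sees this as a distinctive, peptide-level signature.
Tryptic peptides that span the presequence exist only in the unprocessed
precursor, so they are near the detection limit in healthy tissue. If a
genotype or treatment stalls processing while the mature protein pool is
simultaneously depleted, presequence-spanning peptides *rise* while all
peptides from the mature region *fall* with the protein. `preproscan`
operationalizes this signature as a reusable, tested pipeline: peptide-level
differential statistics, a ratio-gap filter, positional mapping of peptides
onto cTP/lTP regions, and per-protein verdicts — together with a synthetic
DIA generator so the whole chain is validated against known ground truth.

## The detection rule

For one comparison (mutant vs control, log2 scale throughout):

* `protein_ratio` — difference of group means of the summarized protein
  quantity (sum of assigned peptide intensities);
* `peptide_ratio` — difference of group means of the peptide intensity;
* `gap = peptide_ratio - protein_ratio`.

A peptide is a **candidate** processing-intermediate signature when

* `protein_ratio < protein_ratio_max` (default **-0.4** log2: the parent
  protein is depleted), and
* `gap >= ratio_gap_min` (default **1.0** log2: the peptide outruns its
  protein by at least one doubling).

This *extended* mode is exactly the published selection rule; *strict* mode
additionally requires the peptide's own BH q-value `< 0.05` and
`peptide_ratio > 0` (the "opposite trend" reading: the peptide must itself
go up). Both are provided because the two published peptide sets (the
selected table vs the opposite-trend figure) plausibly correspond to the
two rules.

A **protein** is called an accumulator when at least one candidate peptide
overlaps its annotated presequence (`[1, ctp_end]` or `(ctp_end, ltp_end]`)
and the protein passes the depletion ceiling. A `mature_consistent` flag —
not a gate — records whether every quantified peptide lying wholly
C-terminal of the presequence stays below the gap threshold; a
boundary-spanning peptide still carries presequence residues and may
legitimately accumulate, so it is excluded from that check.

Because protein quantities are peptide sums, `gap` is identical (to float
precision) to the log2 ratio of the *protein-relative* peptide intensity
(peptide divided by its parent's quantity per sample); both formulations
are implemented and their equality is asserted in the tests.

## The supporting pipeline

Processing order for the protein table is summarize (raw) -> log2 ->
minimum-valid filter -> impute -> median normalization:

1. **Summarization** (`summarize_protein`): protein quantity per sample is
   the sum of non-missing member-peptide raw intensities; missing only when
   all members are missing. Shared (non-proteotypic) peptides are kept in
   the data model but excluded from sums to avoid double counting.
2. **Filtering** (`filter_min_valid`): keep proteins quantified in at least
   `min_reps` (default 3) replicates of at least one (genotype, light)
   condition.
3. **Imputation** (`impute_downshift`): missing log2 values are drawn from
   `Normal(mu - shift * sigma, (width * sigma)^2)` computed per sample
   column; `width = 0.3`, `shift = 1.8` are the conventional parameters of
   this scheme and are exposed as configuration because reproducibility
   demands explicit numbers. Imputation is per column, matching the
   left-censoring rationale: MS missingness concentrates at low intensity,
   so plausible replacements sit in the left tail of that sample's
   distribution. For *peptide* fold changes the default imputes **only the
   control-group columns** (`peptide_ratios`): presequence peptides are
   expected to be censored in the reference condition, and imputing the
   mutant side would manufacture signal where there is none. Observed
   values are never altered.
4. **Normalization** (`median_normalize`): per-sample medians are equalized
   at the grand median. Whether normalization precedes or follows
   summarization is not uniquely determined by convention; the order above
   is the package default and both stages operate on explicit objects, so
   the alternative order is one function call away.
5. **Statistics** (`pairwise_ttests`): two-sample Student's t with pooled
   variance per feature for every condition pair (Welch behind a flag),
   with Benjamini-Hochberg control applied *within each comparison* — each
   pairwise comparison is its own testing family against the same total
   feature count, which is how per-comparison significance counts and
   percentages are reported (`summarize_significance`, half-up rounding to
   two decimals, matching how such tables are rendered).
6. **Structure** (`pca_samples`, `zscore_rows`, `hier_cluster`): sample PCA
   on centered features; row z-scoring; agglomerative clustering with
   Euclidean distance and average linkage, with optional k-means
   pre-aggregation for large matrices (off by default at desk scale).
7. **Enrichment** (`enrich_1d`, `category_medians`): for each annotation
   term, a two-sided Mann-Whitney test of in-term vs out-of-term fold
   changes. The effect size is the rank-biserial correlation
   `2U/(n_in * n_out) - 1`, chosen as the concrete score because it is
   bounded in [-1, 1], exactly zero under exchangeability, and its sign
   equals the sign of the mean-rank shift between members and
   non-members. Terms smaller than `min_size` (default 10) are dropped;
   BH across terms at `q < 0.02`.

## The synthetic-data generator

`simulation_params()` / `simulate_experiment()` emulate the structure of a
peptide-level DIA experiment with planted truth. The latent model for
peptide *p* of protein *g* in sample *j* is

```
log2 I[p, j] = base_g + offset_p + effect[class(g), cond(j)]
               + planted[p, cond(j)] + noise
```

* `base_g ~ Normal(20, 2^2)` log2 units — protein base abundance;
* `offset_p ~ Normal(0, 1)` — a fixed per-peptide ionization offset, drawn
  once, so it cancels exactly from every ratio;
* class effects per condition (defaults: photosynthesis-class proteins at
  -1.0 log2 in the affected condition, other chloroplast proteins -0.15,
  background 0);
* `planted` adds `preprotein_peptide_effect_log2` (default +3.0) to
  presequence-overlapping peptides of accumulator proteins in the affected
  condition — the planted effect magnitudes sit inside the ratio range of
  the published selection (-1.5 to +4.1 log2);
* `noise ~ Normal(0, 0.25^2)` per replicate; `noise_sd = 0` gives the exact
  zero-noise limit used by the calibration tests;
* presequence-overlapping peptides additionally start
  `targeting_baseline_log2 = -5` lower: preproteins are a minority species
  (a few percent) in control tissue, so presequence-spanning peptides sit
  near the detection limit. This matters for realism twice over — it makes
  those peptides preferentially censored in controls (motivating
  reference-only imputation), and it keeps the planted +3 gain from
  inflating the parent protein's summed quantity, which would otherwise
  mask the depletion the rule requires.

Sequences are built from tryptic segments so each protein yields several
quantifiable peptides under Trypsin/P digestion (cleave after every K or R,
no proline exception; fragments with at most 2 missed cleavage sites and
length 7-52 residues). Lumenal (photosynthesis-class) proteins receive
`ctp_end` in 25-60 and `ltp_end` 15-45 residues further, and are drawn
longer (220-400 residues) than the rest (100-400): real lumenal preproteins
are dominated by their mature domain, and that dominance is what lets the
summed protein quantity track the mature pool. Missingness is
missing-not-at-random: cells in the lowest `mnar_quantile = 0.10` of latent
log2 intensity drop out with probability 0.5 — the left-censoring regime
that down-shifted imputation presumes.

Replicate count defaults to 4 per condition; the study conditions state a
minimum of three replicates, and 4 is a typical DIA design choice.

What the generator does **not** emulate: chromatographic or retention-time
structure, charge states, interference between co-eluting precursors,
shared-peptide ambiguity, protein-inference ambiguity, or biological
covariation between proteins. Passing the recovery tests therefore shows
the *statistical machinery* behaves correctly under the stated abundance
model, not that the thresholds are optimal for any particular instrument
or organism.

## Validation strategy and problem sizes

All validation runs at desk scale with planted ground truth:

* digestion is checked exactly against an exhaustive brute-force
  enumeration (100 random sequences);
* BH adjustment is checked exactly against an independent step-up
  implementation (1000 random p-vectors);
* type-I control: under a global-null simulation (200 datasets of 150
  features, 4 vs 4), the pooled fraction of q < 0.05 features stays within
  three binomial standard errors of the nominal level;
* parameter recovery: 200-protein proteomes with 20 planted accumulators
  (protein effect -1.0, targeting effect +3.0, noise 0.25 log2, n = 4),
  over 50 seeds — sensitivity and empirical FDR of accumulator verdicts
  are computed by `scripts/acceptance.R` and asserted at >= 0.90 / <= 0.10;
* null control: the same proteome with no planted effect over 50 seeds,
  asserting at most one false accumulator call per proteome on average;
* the zero-noise limit recovers every planted ratio exactly;
* imputation draws are checked against the stated normal at 10^4 draws.

The published significance percentages and the published 24-peptide
selection are reproduced from their printed inputs (counts over m = 9086;
the (protein ratio, peptide ratio) pairs), which ship as plain-text
reference tables under `inst/extdata/`.

## Numerical and degenerate-input conventions

* Coordinates are 1-based and inclusive on both ends, in the full
  unprocessed preprotein.
* Raw-scale zeros are missing by default (MS intensity convention);
  `zero_is_value` keeps them, and log2 transformation then fails loudly.
* Region labels use maximal residue overlap with ties broken toward the
  more N-terminal region; targeting evidence needs only one presequence
  residue. Proteins with a cTP but no lTP (stromal) yield evidence from
  the cTP alone; unannotated proteins map to mature and are flagged
  `unmapped` rather than dropped.
* Peptides with fewer than two observed values in either group after
  imputation are excluded from ratio records with a reported count, not an
  error; an all-zero-variance group is an error for the t-test (the
  zero-noise limit is served by the difference-of-means estimator).
* Average-linkage merges are deterministic; duplicate rows merge at height
  zero. A constant row is an error for z-scoring, naming the feature.
* All randomness (simulation, imputation) is seed-controlled;
  `run_all()` expands one master seed into fixed per-stage seeds, and two
  runs of the same configuration produce byte-identical outputs.

## Phenotype utilities

Chlorophyll-fluorescence yields are included for completeness of simulated
phenotype reports: the dark-adapted maximum quantum yield of PSII
`phi_max = (FM - FO)/FM` and the operating yield at a light step
`phi_psii = (FM' - FS)/FM'`, both scale-invariant by construction. An
`FO'` input (fluorescence after far-red exposure) is accepted in data
tables but enters no formula. Total chlorophyll uses two-wavelength linear
forms with coefficients shipped as configuration (defaults for
dimethylformamide extracts) and an extraction-volume scale factor, giving
ng per mg fresh weight.

## Known limitations

* The artifact starts from a peptide quantification table; everything
  upstream (identification, XIC extraction, run alignment, identification
  FDR) is out of scope.
* No semi-tryptic or neo-N-terminus inference: presequence boundaries come
  from the annotation file, not from the data.
* The method cannot distinguish a non-translocated precursor from a
  translocated-but-uncleaved one; that distinction needs orthogonal
  evidence.
* Thresholds (-0.4, 1.0) are the published operating point, exposed as
  configuration; their optimality under other designs is untested here.
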