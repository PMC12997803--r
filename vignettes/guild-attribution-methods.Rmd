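---
title: "Methods: gene-centric guild quantification and MeHg attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centric guild quantification and MeHg attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

paddyMeHg quantifies methane- and mercury-cycling microbial guilds from
gene-centric metagenome searches and attributes methylmercury (MeHg)
variability in paddy soils to those guilds and to soil geochemistry. This
vignette explains the models and procedures the package implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices behind the implementation.

## Marker-gene validation

Raw HMM hits for environmental marker genes are noisy: pmoA (particulate
methane monooxygenase) is homologous to amoA of ammonia oxidizers, mbnT is a
TonB-dependent transporter with homologs far outside methanotrophs, and
hgcA-like sequences occur without the diagnostic cap-helix. The validation
cascade in `validate_all()` therefore applies, per gene family and in a
fixed, observable order:

1. **Score / E-value gates** on the full-sequence bit score and E-value of
   the hmmsearch per-domain table (defaults: E ≤ 1e-5 for most families;
   bit-score cutoffs 392.9 for dsrA/TIGR02064.1 and 223.5 for
   mbnT/TIGR01783). The per-domain score is available as an alternative
   filtering field; the full-sequence fields are the default because that is
   what hmmsearch reports first and what per-gene sequence cutoffs refer to.
2. **BLAST-title keywords** (case-insensitive substrings of the best-hit
   title): "methyl coenzyme M reductase" for McrA, "methane monooxygenase"
   for PmoA/MmoX.
3. **Taxon allow-lists**: pmoA hits must be classified to known
   methanotrophic families (packaged default: Methylomonadaceae,
   Beijerinckiaceae, Methylococcaceae, Methylocystaceae); mbnT hits to the
   demethylating genera Methylomicrobium, Methylocystis, Methylosinus.
   Allow-list entries may be rank-prefixed (`f__X` matches at family rank),
   full semicolon paths (prefix match), or bare names (any rank).
4. **Conserved motifs**: `N[VI]WCA[AG]GK` for HgcA, `C[MI]ECGA` for HgcB,
   and cysteine/aspartate residue-context signatures for MerB. Matching is
   unanchored but exact per position — a character class either contains the
   residue or it does not; there is no mismatch tolerance, so
   hamming-distance-1 near-motifs are rejected.

Each rejected hit carries the first failing criterion as a reason code,
making the cascade order observable and testable. The cheap gates run first
purely as an implementation choice; the retained set is order-independent.

The MerB residue signatures shipped in `inst/extdata/validation_rules.tsv`
are synthetic stand-ins: the curated positions from the literature are not
redistributed here, and the rule file is data, not code, precisely so users
can substitute curated patterns. The methanotroph family allow-list is
likewise user-replaceable.

Methanobactin cluster typing (`profile_mbn()`) classifies genomes as
`producer` (mbnA, mbnB, mbnC all present), `uptake_only` (mbnT without the
biosynthesis core), or `none`. The class is monotone under adding genes. A
per-genome override list exists for genes detectable only by annotation
(e.g. a pseudogene missed by HMM search); thresholds are never relaxed.

## Coverage normalization and guild aggregation

Cross-sample comparability uses

> normalized coverage = taxon coverage / (total reads × HMM length)

where "taxon coverage" is the **sum** of per-ORF mean read coverages
attributed to the taxon for the family. Sum (not mean) is deliberate: it
makes per-taxon values conserve — the per-taxon table sums to the family
total within 1e-12 relative error, which the tests assert. Typical values
land around 1e-8, which is why the synthetic generator draws log-normal
abundances at that magnitude.

"Total reads" should be the **effective library size**: raw library size
times a TMM normalization factor (`effective_library_sizes()`, computed by
edgeR with the published defaults — trim 0.3 on M values and 0.05 on A
values, precision weighting, factors rescaled to geometric mean 1). The
tests pin the no-trim factor against an independent hand computation of the
weighted mean-of-M definition.

Guild columns: `methanogen` (mcrA), `methanotroph` (pmoA ∪ mmoX with
per-ORF deduplication — an ORF hit by both HMMs is counted once, under its
higher-scoring family), `hgcA_total` and its split into methanogen-, SRB-,
IRB-, and syntroph-associated hgcA via a lineage map (most specific rank
wins; unclassified hgcA stays in the total), `merB`, `dsrA_SRB`,
`mbnT_demethylator` (genus-allow-listed hits only), and `IRB`.
Methanoperedenaceae (ANME) mcrA hits are flagged and excluded from the
methanogen guild by default — their methylation capacity is unestablished —
with `include_anme = TRUE` to opt back in. Iron-reducer abundance is also
available in its gene-set form: summed coverages over total coding-sequence
counts (`irb_abundance()`).

## Regression and model selection

`aicc_select()` fits a candidate family of linear models to the same
complete-case rows and ranks them by
`AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`, with `k` counting the intercept,
slopes, **and the error variance** (the common model-selection convention;
the test oracles assume it). Akaike weights and ΔAICc follow the standard
definitions, and models whose added interaction term raises AICc by ≥ 2 are
flagged as "interaction adds nothing". Residual normality (Shapiro-Wilk)
and heteroscedasticity (Breusch-Pagan) diagnostics are reported per model.

The default seven-model family spans the hypotheses of interest for MeHg:
intercept-only; F1-Hg; hgcA; F1-Hg + hgcA; those plus site and compartment;
and the two interaction variants. It is a documented stand-in — the exact
hypothesis set is config-replaceable.

Standardization: `standardize = TRUE` z-scores the **continuous predictors**
only, so coefficients are per-SD effects on the response's original scale
(the convention under which the generator's F1-Hg coefficient of 0.73 is
recoverable); `scale_response = TRUE` additionally z-scores the response.
Scaling both makes a single-predictor coefficient collapse to the
correlation, which is why it is off by default.

Small-sample note: with `k` counting the error variance, a one-predictor
model has `k = 3`, so AICc is undefined (division by `n - k - 1 ≤ 0`) for
`n ≤ 4`; such specs raise an error by name rather than returning infinities.

## Community structure

Bray-Curtis dissimilarity, PCoA, PERMANOVA, and db-RDA wrap the standard
vegan implementations behind validated surfaces. Numerical choices:

* PCoA drops axes with eigenvalue ≤ 1e-10 × the largest, and drops
  negative-eigenvalue axes outright, logging their total magnitude — no
  Lingoes/Cailliez correction is applied by default.
* db-RDA reports the constrained fraction as canonical eigenvalue sum over
  the total positive eigenvalue sum; overall and marginal significance use
  row permutations with `p = (1 + #{null ≥ obs}) / (1 + n_perm)`.
* PERMANOVA permutations are unrestricted (no strata). Pairwise tests
  re-run the statistic on each group-pair sub-matrix and multiply p by the
  number of comparisons, capped at 1 (Bonferroni).
* Every permutation p is seeded and bit-reproducible.

## Random-forest attribution protocol

`run_rf_protocol()` implements the repeated-split attribution design: for
each of `n_splits` (default 100) seeded 70/30 train/test splits, fit a
randomForest (default 2001 trees, `mtry = 4`), record held-out RMSE, MAE,
R², and Pearson r, and read off each predictor's %IncMSE — the mean
out-of-bag MSE increase after within-OOB permutation of that predictor,
SE-scaled by convention (an unscaled option exists). Per-split variable
significance compares the variable's importance against null importances
from forests refit on the training response permuted within the training
rows; across splits each variable gets a significance rate (fraction of
splits with p < 0.05) and a mean p.

Two numerical details matter:

* The null comparison uses the **unscaled** MSE increase. The SE-scaled
  statistic grows with tree count, so comparing a large observed forest
  against smaller null forests would be systematically anti-conservative;
  the unscaled statistic's expectation is tree-count invariant, making
  smaller null forests a conservative economy rather than a bias.
* All split and permutation seeds derive from the protocol seed by a
  documented counter scheme (`derive_seed(seed, split, perm)`), so any
  single split is reproducible in isolation and a rerun is bit-identical.

The default 12-predictor set (nine guild columns including the
methanogen × methanotroph product, plus F1-Hg, DOM, SUVA254) is a documented
stand-in; `build_feature_table()` builds product columns for any pair and
the predictor list is configurable, as is whether the product counts within
or beyond the twelve.

A limitation worth knowing: with a single dataset of n = 66, the per-split
permutation test measures association *within that dataset*. Roughly one in
three pure-noise panels contains chance multivariate structure that the
protocol then legitimately flags across many splits — a property of
single-dataset nulls, not a defect of the test. Size statements about the
protocol are therefore best read at fixed dataset seed or averaged over
dataset replicates.

## Local similarity analysis

For short, evenly indexed series (11 time points in the emulated design),
`local_similarity()` rank-normalizes each series
(midranks through `qnorm((r - 0.5)/n)`) and maximizes
`|Σ x[i]·y[i+d]|` over all contiguous windows and delays `|d| ≤ D`,
normalized by the full series length n (the canonical definition, not the
window length). The scan is the running-maximum (Kadane) recursion per
delay; because windows accumulate left-to-right exactly as naive
enumeration does, the tests can and do assert bit-exact agreement with
brute force over a thousand random pairs. Ties break toward smaller |d|,
then toward positive sign. A positive delay means the series lags the
target.

Eleven points are far too few for asymptotic p-values, so whole-series
permutation is the only inference path (`p = (1 + #{perm ≥ obs})/(1 +
n_perm)`), with BH FDR across all pairs tested together. Block permutation
for autocorrelated series is a config option; the default matches the
whole-series convention for short series.

## The synthetic-data generator

`sim_config()` fixes the emulated study design: 3 sites (HX, GX, SK) × 2
compartments (surface, rhizosphere) × 11 time points at 33-day spacing
(days 0–330), flooding for days ≤ 100, site-level MeHg baselines at the
field magnitudes (0.78, 3.44, 2.42 µg/kg), guild coverages log-normal
around 1e-8 with methanotrophs an order of magnitude below methanogens and
their log-abundances coupled at ρ = 0.5. MeHg follows a stated linear
model: site and compartment offsets plus per-SD effects of F1-Hg (0.73, the
stylized headline coefficient), methanogen abundance, optionally total
hgcA, and a methanogen × methanotroph product active only while flooded,
plus Gaussian noise (SD 0.3 by default); a pure-noise covariate is always
included and the truth coefficients are returned. Presets switch effects on
and off (`null`, `dominant_f1`, `flooded_interaction`, `model5`) without
touching the design constants.

Sequence fixtures embed exact motif instances in true sequences and
hamming-distance-1 near-motifs in ≥ 20% of decoys (one class position
mutated outside its class), so only exact character-class matching can
separate the labels; every other family's decoys fail at exactly one
designated cascade stage (title for mcrA/mmoX, taxon for pmoA confounders
and out-of-genus mbnT, score for dsrA, E-value for iron-reduction genes).
All generation is seeded through the same counter scheme and is
byte-identical across platforms (Mersenne-Twister with inversion sampling).

What the generator does **not** emulate: read-level noise, assembly and
binning artifacts, compositionality of relative abundances, spatial or
temporal autocorrelation beyond the flooded gate, missing-data patterns,
and real lineage ambiguity. Passing tests therefore certify the statistical
machinery and its contracts on data of known structure — not performance on
field metagenomes.

## Problem sizes used by the tests

The test-suite simulations are sized for a single CPU: 200 seeds for AICc
recovery (n = 66 each), 100 fresh null panels with one split and 99 null
permutations each for the RF size check (equal observed/null tree counts,
so the per-split permutation test is exchangeable and exact; fresh panels
per split because the size statement is marginal — see the limitation
above), 50 protocol runs for the dominant-predictor check, 1000 pairs for
the LSA brute-force identity, 200 seeds × 50 pairs for LSA size, and 500
null datasets (n = 30, 199 permutations) each for PERMANOVA and db-RDA
size. These are the package's
chosen simulation sizes; the generative conditions (n = 66, noise SD 0.3,
effect sizes above) are fixed by the emulated design, not tuned per run.

## Known limitations

* The validation rules ship with documented stand-ins where the literature
  does not print the exact criteria (MerB signatures, methanotroph
  allow-list, FeGenie per-gene cutoffs collapsed to one E-value).
* TMM assumes most genes are not differentially abundant between samples;
  guild tables with few, strongly varying families violate this, which is
  why normalization runs on the full ORF count table, not on guild columns.
* PERMANOVA/db-RDA p-values assume exchangeable rows; site-blocked designs
  need the strata option rather than the default unrestricted permutations.
* RF %IncMSE shares importance among correlated predictors (e.g.
  `hgcA_total` and its components); ranks are stable in the generator's
  presets but should be read jointly with the significance rates.
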