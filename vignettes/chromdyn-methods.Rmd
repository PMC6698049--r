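---
title: "chromdyn: methods, models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromdyn: methods, models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(chromdyn)
```

## Scope

chromdyn implements a chromatin-state segmentation and dynamics workflow of
the kind used to compare epigenomes between two conditions: learn a
multivariate hidden Markov model over binarized mark tracks, decode each
condition, and relate state changes to gene expression, DNA methylation and
GWAS signal. This vignette documents the statistical model, every default
parameter and why it was chosen, what the synthetic-data generator does and
does not emulate, and the numerical decisions that make results exact and
reproducible.

## The chromatin-state model

### Data representation

The genome is tiled into fixed windows of `window_size = 200` bp (the
standard resolution for chromatin-state maps; fine enough to separate a
promoter from its flanks, coarse enough that per-window mark calls are
stable). All interval tables use the BED convention — 0-based, half-open —
throughout; conversion to the 1-based closed convention of GenomicRanges
happens only inside interval-arithmetic helpers.

### Binarization

`binarize_counts()` calls mark *m* present in window *i* when the Poisson
upper tail P(X ≥ x<sub>i</sub>) under rate λ<sub>m</sub> ·
c<sub>i</sub>/mean(c) falls below `p_threshold = 1e-4`, where λ<sub>m</sub>
is the mark's genome-wide mean count and c is the optional control (input)
track. The control scales the local background rather than acting as a
seventh mark, matching standard binarization practice. The threshold 1e-4 is
the conventional default for this style of Poisson-tail binarization.

### The HMM

Hidden states follow a first-order Markov chain along each chromosome;
chromosomes are independent sequences restarting from the initial
distribution. Emissions are conditionally independent Bernoullis per mark
(`P(x|s=k) = ∏ p_km^x (1-p_km)^(1-x)`). Fitting is Baum–Welch EM:

- E-step: scaled forward–backward recursions (compiled C++), returning
  posterior marginals γ, summed pairwise posteriors ξ, and the exact
  log-likelihood from the scaling constants.
- M-step: closed-form updates of π, A, p from the accumulated posteriors.
- Initialization: emissions uniform(0.2, 0.8) drawn from `seed`; transitions
  0.5 on the diagonal, remainder uniform; initial distribution uniform. A
  single seed makes the whole fit deterministic.
- Stopping: `max_iter = 200` or log-likelihood improvement below
  `tol = 1e-4`. The log-likelihood is non-decreasing every iteration — a
  property the test suite asserts on every fit it makes.

Emission probabilities are clamped to [1e-6, 1 − 1e-6] inside likelihood
computations only, so logs are finite even when EM drives a probability to
the boundary; the stored parameters are not clamped.

`decode_states()` uses posterior (max-marginal) decoding by default — the
choice that matches per-window segmentation outputs of standard tools — with
Viterbi available for the jointly most probable path. The number of states is
the analyst's choice; the study design this package mirrors used 15 states
over 6 marks plus controls, while the package's default toy scale uses K = 8.

## Downstream statistics

### Fold enrichment and the log-space Fisher test

For a state covering A bases, an annotation covering B bases, C shared bases
and a genome of D bases, enrichment is (C/A)/(B/D). Significance comes from
the two-sided Fisher exact test on [[C, A−C], [B−C, D−A−B+C]]. At
genome-scale counts the p-value underflows double precision, so
`fisher_exact()` accumulates hypergeometric log-probabilities (from `dhyper`)
with a log-sum-exp, reporting both `p` and a finite `log10p` even when
`p == 0`. The two-sided rule — sum all tables with probability ≤ the observed
table's, with a 1 + 1e-7 tolerance factor — is the same as
`stats::fisher.test`, and the tests verify agreement with both
`fisher.test` and exhaustive enumeration from factorials over every table
with total ≤ 40. When A or B is zero the fold is undefined and returned as
`NA` with a reason string rather than an error, so per-state loops never
abort.

### Positional profiles

`positional_profile()` measures, for each strand-oriented offset in
[−flank, +flank) at `bin = 200` bp, the fraction of anchors whose bin
overlaps the state, divided by the state's genome-wide coverage fraction
(ratio 1 = no enrichment). Bins truncated by a chromosome edge are excluded
from that offset's denominator instead of being zero-filled. Default
`flank = 2000` matches the conventional ±2-kb TSS/TES metaprofile.

### GWAS marker-set test

T<sub>sum</sub> = Σ b² over SNPs inside a feature. The null distribution
rotates the genome-ordered squared-effect vector by a uniform offset
k ∈ {1, …, m−1} against the fixed feature mask — circular permutation, which
preserves the local correlation structure of effect sizes, unlike independent
shuffling. Decisions, all configurable:

- One genome-wide circle by default (`per_chromosome = FALSE` rotates within
  chromosomes on request).
- The effect vector is rotated, not the genotypes: b is precomputed per SNP,
  so rotating b against the mask is the operational form of rotating
  genotypes.
- Empirical p is reported two ways: `p_emp = (r+1)/(n+1)` (the standard
  correction that avoids exact zeros and makes the null p uniform on a
  lattice) and `p_literal = r/n`, the literal proportion historically
  reported in this workflow.
- Ties use strict `>` by default (`tie = ">="` available).
- Default `n_perm = 10000`, the permutation count of the workflow this
  mirrors; the calibration harness uses 2,000 to keep 500 replicates fast.

### State dynamics

`state_transition_matrix()` cross-tabulates two segmentations on the same
window grid, weighting windows by width, so the K×K matrix's total is the
windowed genome length and its margins are exactly the two per-state
coverages (asserted in acceptance testing). Retention of state k is the
diagonal over the row sum; relative change is |after − before|/before
coverage. `transition_associated_genes()` reads "a gene is associated with a
transition" as: at least one window within the gene's TSS ± 20 kb flank
(`anchor = "body"` for body ± flank) moved from a `from_states` member to a
`to_states` member. The ±20-kb reading of "gene flank" is the study default
and is configurable.

### Gene classification

`classify_genes()` assigns a gene to a category when any window overlapping
its body ± 1 kb (`promoter_flank`) carries one of the category's states. The
first category (active promoter) takes priority and is exclusive; later
categories (poised enhancer, bivalent, Polycomb-repressed by default) may
overlap one another. This mirrors the published four-category scheme in which
active-promoter genes are pulled out first.

### Differential expression and methylation

- `deg_filter()`: Bonferroni-corrected p strictly below 0.05 and |log2FC|
  strictly above 2. The package supplies `simple_de_test()` (Welch t on
  log2(FPKM+1)) as a pluggable stand-in for synthetic data; any per-gene
  `p`/`log2fc` table can be filtered.
- DMR pipeline: CpGs with under `min_coverage = 10` reads in any sample are
  removed (per-sample rule; a per-condition pooled rule is available), counts
  are summed into 500-bp windows (window = step by default; sliding windows
  supported), replicates are pooled per condition, and each window gets a
  1-df likelihood-ratio test of a two-level binomial logistic regression —
  `dmr_test()` fits it via `glm`, and `dmr_test_all()` uses the equivalent
  closed form for the saturated two-group model (the tests assert equality
  of the two routes). DMRs are windows with q < 0.05 and |difference| > 10
  percentage points.
- The original workflow's SLIM q-values are replaced by Benjamini–Hochberg:
  SLIM has no maintained implementation in this stack, BH is the standard
  step-up FDR control, and `dmr_filter(q_fun = )` accepts any replacement.

## The synthetic-data generator

`sim_config()` bundles every tunable with defaults emulating a two-condition,
three-replicate epigenome study at desk scale: 2 chromosomes × 1 Mb (10,000
windows of 200 bp), 6 marks, 8 states, 500 genes, 20,000 SNPs, 50,000 CpGs.
One master seed drives every sub-generator through fixed offsets, so a config
reproduces end to end.

What it emulates:

- A sticky ground-truth HMM (self-transition 0.9, overlapping two-mark
  emission profiles at 0.9/0.05) sampled per chromosome; Poisson read counts
  (signal rate 15, background 0.5) plus a background-rate control track.
- Condition 2 as *localized region reassignment*: 40 regions of 10 windows
  are redrawn and re-emitted, everything else shares condition 1's calls and
  counts. Planted transitions are therefore countable, which the tests
  exploit.
- Planted differential expression (5% of genes, ±3 log2FC, log-normal
  replicate noise), feature-localized SNP-effect variance inflation (5×), and
  planted DMR windows (+30 percentage points in condition 2, negative
  binomial coverage).

What it does not emulate: read-level data (FASTQ), mappability and GC biases,
linkage disequilibrium beyond genomic ordering of SNPs, spatial
autocorrelation of methylation outside planted windows, and realistic gene
structure (single-exon bodies only). Conclusions about those phenomena cannot
be drawn from this simulator; it exists to verify the statistical machinery.

## Reproducibility and numerics

- All stochastic stages take explicit integer seeds; the pipeline is
  single-threaded, so results are independent of any thread setting.
- Output TSVs carry a three-line header — package version, seed, config
  hash — and no timestamps, so reruns are byte-identical (asserted by test).
- Likelihoods are computed with scaling (not log-space recursions) in the
  forward–backward pass, giving exact log-likelihoods via the scaling
  constants; Viterbi runs fully in log space.
- Fisher p-values are assembled in log space (see above); the hypergeometric
  gene-set test uses `phyper` directly as it operates at gene-set scales
  where underflow is not a concern.

## Verification harness sizes

The problem sizes in the acceptance harness are the package's own choices,
fixed before any results were observed: ≤10-window toys for exhaustive path
enumeration (tolerance 1e-9); 50,000 windows for 3-state/4-mark parameter
recovery (tolerance 0.05 after optimal state matching); all 2×2 tables and
set configurations with totals ≤ 40 for the exact-test oracles; 500
replicates × 2,000 rotations for null calibration of the permutation test
(KS uniformity, rejection rate in [0.03, 0.07]) and 100 replicates for power
under 5× inflation; 100 random 10-kb interval pairs for the per-base fold
oracle; 7 planted +30-point DMRs among 300 null windows across 20 seeds for
recovery (with at most one false positive per run) and 1,000 null windows for
the type-I rate; and two full default-scale pipeline runs compared byte for
byte. `scripts/acceptance.R` re-runs all of these against the installed
package and writes the measured quantities as JSON.

## Limitations

- The Bernoulli-product emission ignores count magnitude beyond the
  binarization step, as in standard chromatin-state practice.
- EM finds a local optimum; the packaged initialization is deterministic per
  seed, and state identity is only defined up to relabeling (the recovery
  harness matches states by minimal emission distance).
- BH controls FDR under positive dependence assumptions that windowed
  methylation data usually satisfies approximately; it is not SLIM, and
  q-values will differ from pipelines that used SLIM.
- The DEG stand-in test is a Welch t-test on log FPKM, not a count-based
  negative-binomial model; with the default three replicates its power at
  Bonferroni thresholds is limited, which is faithful to the filter's
  behaviour but means planted-DEG recovery harnesses use more replicates.
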