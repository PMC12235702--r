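---
title: "Delta synergy scoring and TMT differential expression: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta synergy scoring and TMT differential expression: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synprot)
```

synprot analyses combination drug-treatment experiments in two arms: a
dose-response arm that scores pharmacological interaction between two
drugs, and a proteomics arm that quantifies the treatment's impact on
protein expression and interprets it through gene-set enrichment. This
vignette explains the models, the tunable parameters, and the design
choices that were genuinely open.

## The delta synergy score

Cell viability is measured (typically by colony formation) on a grid of
concentration pairs: rows follow the ladder of drug S, columns the
ladder of drug P, with a zero dose first in each ladder so the margins
carry the single-agent responses. The inhibition rate at each cell is

$$I = 100 - \text{viability},$$

with no clamping: inhibitions below 0 or above 100 are measurement
noise and propagate untouched. Under the default independent-action
expectation, the combination of drug S at row concentration $i$ and
drug P at column concentration $j$ is expected to inhibit

$$E_{ij} = \frac{I_{i0} \times I_{0j}}{100},$$

where $I_{i0}$ and $I_{0j}$ are the single-agent inhibitions read off
the zero-dose column and row. The synergy score is the residual

$$\Delta_{ij} = I_{ij} - E_{ij},$$

in percentage points: positive values indicate synergy, values near
zero additivity, negative values antagonism.

Three choices here deserve comment.

**The expectation model.** The product rule above is the package
default (`mode = "product"`). Note that classical Bliss independence on
inhibition rates is $E = I_{i0} + I_{0j} - I_{i0} I_{0j} / 100$, which
treats the two *surviving* fractions as independent; the product rule
instead multiplies the inhibited fractions and is therefore a more
conservative null (its expectation is smaller, so more of the observed
effect is attributed to interaction). Both are available;
`mode = "bliss"` switches to the classical form. The two agree only
when one of the single agents is at 0% or 100% inhibition.

**Margins.** At a zero-dose margin cell only one drug is present, so
there is no interaction to score: the expectation at those cells is the
margin's own single-agent inhibition, making $\Delta = 0$ there by
construction, and the zero-zero cell takes the formula value
$I_{00}^2/100$ (zero in practice). When the supplied matrix has no
zero-dose ladders, explicit single-agent vectors must be passed and
every cell is treated as a combination measurement.

**The additivity band.** "Near zero" needs a number to make the
three-way classification total. The default band is 5 percentage
points, roughly the scale of replicate noise in colony-formation
viabilities; it is a pure reporting choice (`additivity_band`) and does
not affect the delta values themselves.

Replicate matrices, when supplied as a list, are averaged on the
viability scale per cell before the transform; fold this into the
design stage rather than averaging deltas, since the transform chain is
linear and the two orders agree.

## TMT differential expression

The quantification input is a protein-groups table in the MaxQuant
dialect: per-channel reporter intensities with marker columns flagging
reverse-database hits, potential contaminants, and site-only
identifications, all of which are removed and counted on ingestion.
Zero reporter intensities are recorded as missing, the standard
interpretation of unquantified channels. A design table maps each
channel to its condition (CTL, P, S, PS) and MS batch.

Intensities are log2-transformed and, by default, median-centered per
sample (`normalization = "median_center"`), which removes loading
differences between channels without touching between-protein
structure. For each contrast the package computes a two-sided
two-sample Student t-test (equal variance pooled over the two groups;
Welch available via `var_equal = FALSE`) and the log2 fold change as
the difference of group means on the log2 scale. A protein needs at
least two non-missing values per group; proteins failing that, or with
zero pooled variance and a nonzero mean difference, are flagged rather
than silently dropped, and no imputation is performed.

Two selection rules are implemented side by side because they serve
different purposes and are not interchangeable:

* **DEP rule** (`filter_deps`): `p < 0.05` and `|log2FC| > 0.58`
  (about 1.5-fold), the conventional volcano-plot cut. No
  multiple-testing correction is applied to the call itself; a
  Benjamini-Hochberg column can be added downstream where needed.
* **SD rule** (`filter_sd_down`): `p < 0.05` and a log2 fold change
  more than 1.96 standard deviations below the contrast's mean fold
  change. This z-score form adapts to each contrast's spread and is the
  input rule for over-representation analysis of down-regulated
  functions.

Batches are never pooled across in a contrast by default: TMT batches
are separate labelings and runs, and a condition effect estimated
across batches would be confounded with the batch offset. The default
contrast set runs P/CTL, S/CTL and PS/CTL within batch 1 and PS/CTL,
PS/P and PS/S within batch 2.

## Enrichment

**Over-representation** uses the one-sided upper-tail hypergeometric
test: for a query of $n$ genes drawn from a universe of $N$, a set with
$K$ in-universe members and overlap $k$ gets $p = P[X \ge k]$,
$X \sim \mathrm{Hypergeom}(N, K, n)$. Significance is called on the
nominal p-value at 0.05 (a BH q-value column is reported alongside).
The universe is the set of all quantified gene symbols, not the genome:
the question is whether the selected proteins concentrate in a function
relative to what was measurable.

**Preranked GSEA** takes a ranking (by default the contrast's log2 fold
changes) and computes the weighted Kolmogorov-Smirnov running-sum
statistic: walking down the ranking, the sum rises by
$|s|^w / \sum_{\text{hits}} |s|^w$ at genes in the set and falls by
$1/(N - N_h)$ otherwise; the enrichment score (ES) is the signed
extremum, in $[-1, 1]$. The weight default is $w = 1$ (the
classic weighted form); $w = 0$ gives the unweighted KS statistic,
useful because it is analytically tractable in small cases. When the
running sum's peak and trough have exactly equal magnitude the signed
extremum is ambiguous; the positive extremum is taken, a tie that
cannot occur with generic real-valued weights.

Significance comes from a gene-label permutation null: for each set
size, random positions in the ranking are drawn `n_perm` times
(default 1000), and the nominal p-value is the add-one-smoothed
fraction of same-sign null scores at least as extreme as the observed
ES. The normalized enrichment score divides ES by the mean same-sign
null magnitude, and the FDR q-value compares the observed NES against
the pooled null NES distribution in the standard way. A set is called
significantly enriched when FDR < 0.25 and nominal p < 0.05. For tiny
problems `exhaustive = TRUE` replaces sampling with complete
enumeration of all $\binom{N}{N_h}$ placements, which is what the exact
small-scale tests use. Set-size bounds default to 5-500 after
intersection with the ranking; rank ties keep stable input order.

## PCA quality control

Sample-level PCA is run on the proteins quantified in every sample
(complete cases), centered but not scaled — the `prcomp` default — and
the first three components are exported for a 3-D view of within-group
similarity. Component signs are arbitrary in any PCA; they are fixed by
making the largest-magnitude loading of each component positive, so
repeated runs are identical to the byte.

## What the synthetic data emulate — and what they do not

The generator exists so that every stage can be verified against
planted ground truth without any external download.

* `synth_dose_response` draws single-agent inhibitions from monotone
  Hill curves ($I(c) = I_{\max} c^h / (EC_{50}^h + c^h)$, defaults:
  drug S $EC_{50}$ 6 µM, slope 1.2, $I_{\max}$ 85%; drug P $EC_{50}$
  0.4 µM, slope 1.5, $I_{\max}$ 90%, on ladders 0-16 µM and 0-1 µM),
  builds combination cells as the product expectation plus a chosen
  true delta surface, and applies multiplicative Gaussian
  noise to viability (`1 + N(0, 0.05)`). Multiplicative noise on viability
  leaves the recovered delta unbiased, which the tests exploit.
* `synth_tmt` builds log2 intensities as baseline
  ($N(20, 2)$) + condition effect + per-protein batch offset
  ($N(0, 0.3)$) + replicate noise ($N(0, 0.25)$), exponentiates to the
  reporter scale, and injects missing values (default 5%, MCAR; an
  intensity-dependent mode is available). A 10% subset of proteins
  receives a ±1 log2-unit effect in one of P, S, PS. The design is 4
  conditions × 3 replicates × 2 batches; real 11-plex TMT layouts are
  unbalanced, but balanced triplicates are the smallest design
  supporting all six default contrasts.
* `synth_gene_sets` plants sets whose members are drawn with 20:1 odds
  in favour of perturbed genes, next to uniformly drawn decoys.

The generators deliberately do not model ratio compression from
co-isolation interference, peptide-to-protein rollup, intensity-
dependent variance, or correlated proteins; passing tests demonstrate
the correctness of the computations under the stated model, not
robustness to those real-data pathologies.

## Numerical and testing choices

Problem sizes in the test-suite and in the reproduction script are
chosen to make the Monte-Carlo answers decisive at interactive runtimes:
100 random matrices for the vectorization check, 1000 noisy matrices
for delta-recovery bias, 2000 proteins for t-test calibration and
power, 1000 permutations (or exhaustive enumeration at $N \le 6$) for
GSEA, 100 seeded repeats for the decoy false-call rate, and a 500-
protein end-to-end pipeline run executed twice for byte-identity.
Every random draw flows from a single seed; the pipeline derives
per-stage seeds from it by fixed offsets so stages stay independently
reproducible. Exact-formula paths (inhibition transform, delta,
hypergeometric p, ES at small N) are compared against independent
oracles at 1e-10 to 1e-12; floating-point-accumulation paths (PCA
reconstruction) at 1e-8.

## Known limitations

* No dose-response curve fitting: the expectation uses the measured
  single-agent inhibitions directly, so margin noise propagates into
  every cell of the expected surface.
* No confidence intervals on delta and no moderated (limma-style)
  variance estimation for the t-tests.
* ORA re-implements the standard hypergeometric test, not any annotation
  database or modified scoring a specific web service applies on top.
* Phenotype-permutation GSEA is out of scope; the null permutes gene
  labels, which tests set membership against the ranking, not the
  between-sample design.
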