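---
title: "Scoring cytogenetic regions for cancer susceptibility from multi-cancer transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cytogenetic regions for cancer susceptibility from multi-cancer transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsrscan)
```

## The problem and the model

Expression changes in tumours are not scattered uniformly over the genome:
copy-number gains and losses, methylation blocks and regulatory variants tend
to perturb whole cytogenetic neighbourhoods, and some of those
neighbourhoods recur across unrelated cancer types. `pcsrscan` turns that
observation into a screening statistic. Given normalized case/control
expression matrices for a panel of cancers, it counts, for every cytogenetic
band, how many probesets on the chip are called over- or down-expressed,
pooled over the panel, and expresses the load as a *participation
percentage*:

$$
P_{\mathrm{over}}(r) \;=\; 100 \cdot \frac{\mathrm{FOR}(r)}{n \cdot \mathrm{FTP}(r)},
\qquad
P_{\mathrm{down}}(r) \;=\; 100 \cdot \frac{\mathrm{FDR}(r)}{n \cdot \mathrm{FTP}(r)},
$$

where FOR and FDR are the counts of over- and down-expressed probesets in
band $r$ summed over the $n$ cancers and FTP is the number of probesets the
chip annotates to the band. The denominator $n \cdot \mathrm{FTP}$ is the
maximum attainable count (every probe altered in every cancer), so the
percentage is a normalized cross-cancer recurrence measure that is comparable
between gene-dense and gene-poor bands. For each chromosome and each
direction, the five bands with the highest percentage are reported as
*potential cancer-susceptibility regions* (PCSRs). The same construction at
chromosome level (FOC, FDC, FCTP) feeds a goodness-of-fit chi-square test of
whether alterations distribute proportionally to each chromosome's probe
content.

A division by FTP alone (not $n\cdot$FTP) changes no ranking within a fixed
panel — it rescales every band by the same constant — but changes the
absolute scale; both variants are available through the `denominator`
argument of `participation_percent()`, with $n \cdot \mathrm{FTP}$ the
default, matching the definition above.

Around the core statistic the package implements the supporting stages of a
multi-cancer susceptibility screen:

* **Differential calls** (`de_table()`): per-probe log2 fold change (case
  mean minus control mean) and a two-sided Welch t-test, thresholded at
  symmetric fold cutoffs — 2.0 for mRNA probes, 1.5 for miRNA probes, and a
  permissive 1.2 used only to trace cross-cancer commonality. The cutoffs
  are inclusive ("at least 2-fold" means $|\log_2 \mathrm{FC}| \ge 1$).
* **Digital differential display** (`ddd_screen()`): per-cluster EST
  fractions in a normal pool A and a cancer pool B, Fisher's exact test on
  the 2×2 pool table, and a strict >10-fold ratio screen.
* **Cross-cancer integration** (`collect_common()`, `assign_class()`,
  `detect_mirna_clusters()`): genes altered in at least 6 of 11 cancers,
  classified as Class I (consistently over), II (consistently down) or III
  (mixed), flagged when they sit on a PCSR, and miRNAs grouped into same-band
  clusters.
* **Promoter scanning** (`pfm_to_pwm()`, `pscan_ztest()`,
  `common_regulators()`): JASPAR-style log-odds matrices, two-strand
  relative-profile-score scans at a 0.99 threshold, and a pscan-style z-test
  of mean best-hit scores against a background promoter population at
  p < 0.1.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fold_mrna` / `fold_mirna` / `fold_trace` | 2.0 / 1.5 / 1.2 | linear fold | standard microarray effect-size cutoffs; miRNAs move less than mRNAs; 1.2 only traces commonality, never defines a region |
| `alpha` | 0.05 | — | per-probe test level; no multiplicity correction is applied because downstream counting consumes binary calls, not inference |
| `top_n` | 200 | probes | alternative region threshold by rank instead of effect size, a robustness check for the fold cutoff |
| `k` | 5 | bands | regions reported per chromosome and direction |
| `min_cancers` | 6 (of 11) | cancers | strict majority of the panel |
| `ddd_ratio` | 10 | fold | strict inequality; EST fractions are noisy, so only order-of-magnitude differences are kept |
| `pscan_alpha` | 0.1 | — | permissive by design: enrichment must hold in *every* gene set considered, which multiplies the stringency |
| `rel_score` | 0.99 | relative score | near-perfect motif matches only |
| PWM pseudocount | 0.8 | counts | split by background composition; common JASPAR practice, keeps log-odds finite for zero counts |

## Design choices where the design was open

* **Moderated vs plain t-test.** Differential calls use Welch's
  unequal-variance t-test. An empirical-Bayes moderated test would shrink
  per-probe variances, but the region statistic consumes only the binary
  over/down/unchanged calls, and at the sample sizes the package targets the
  two tests disagree on few boundary probes. The call layer is a single
  function (`welch_t()`), deliberately kept swappable.
* **Top-n ranking and the p filter.** The top-200 alternative threshold is
  computed per direction among probes significant at `alpha`
  (`top_n_p_filter = TRUE`); both the filter and whether `n` applies per
  direction are flags, since either convention is defensible.
* **Ties.** Ranking ties — in `top_n_by_fold()` and in `select_pcsrs()` —
  are broken deterministically: lexicographic probe id for probes, genomic
  order (chromosome, band start) for bands. Determinism here is what makes
  whole-pipeline byte-identical reruns possible.
* **Bands with no probes.** A band with FTP = 0 is *omitted* from
  participation scores rather than scored 0, so chips that do not cover a
  band can never push it into a top-5 list.
* **DDD direction.** The pool ratio is screened symmetrically by default
  (`max(B/A, A/B)` with the direction recorded) so that strong depletion in
  cancer is caught as well as enrichment; the plain B/A mode is available.
  Fisher's test is two-sided. A cluster absent from pool A but present in B
  has infinite fold and passes the ratio arm (no pseudocounts).
* **Expression classes.** "Consistently over/down" is operationalized as
  *purity*: one opposing call in any cancer demotes a gene to Class III.
  This is the strictest reading; a configurable tolerance was considered and
  rejected because the class labels feed qualitative interpretation, not
  statistics.
* **pscan statistic.** The published pscan tool's internals are approximated
  by a one-sample z-test of the input mean best-hit score against the
  background score distribution. With input sets much smaller than the
  background this is the same large-sample approximation; the background must
  be large enough (≥ 30, ideally hundreds) for its standard deviation to be
  stable.
* **Coordinates.** Everything is 0-based half-open, the UCSC cytoBand
  dialect. Probes are point features; callers with interval probes should
  pass midpoints.

## What the synthetic data emulates — and what it does not

`sim_config()` defines a desk-scale study whose defaults are the package's
reference conditions: 5 chromosomes × 8 bands × 40 probes, 11 cancers with 5
case and 5 control samples each, i.i.d. Gaussian log2 noise (sd 0.25) around
a flat baseline, and three planted bands in which 30% of probes are shifted
by 1.5 log2 units in 8 of the 11 cancers. EST pools hold 200 clusters with a
gamma(5) abundance profile and 10⁵ ESTs per pool — the depth of aggregated
UniGene pools — with planted clusters inflated 50-fold before
renormalization. Promoter sets are uniform random DNA with a consensus motif
planted into input promoters.

The generators emulate the *statistical* structure the analysis assumes:
group mean shifts on a log scale, region-level coherence, partial sharing
across cancers, multinomial EST sampling, and motif planting with exact
ground truth. They deliberately do **not** emulate probe-level chip
artefacts, batch effects, correlated noise between probes of one gene,
chip-specific probe sets, or the heavy-tailed variance structure of real
microarray data. Tests passing on these generators therefore demonstrate
that the statistics recover the signals they are defined to recover at
realistic effect sizes and noise — not that any particular biological
dataset will yield stable PCSRs.

Two calibration facts the test suite itself establishes are worth knowing.
First, with the planted effect set to zero, top-5 membership of a planted
band is governed purely by the deterministic genomic-order tie-break among
all-zero percentages, i.e. 5/8 per band under the default layout — the null
"recovery" rate is chance, not zero. Second, the two-sided Fisher exact test
is conservative on discrete support: at 10⁵ ESTs per pool its null pass rate
is ≈ 0.04 at a nominal 0.05, and it approaches the nominal level only for
pools an order of magnitude deeper. This is a property of exact conditional
tests, not of the implementation (which agrees with exhaustive
hypergeometric enumeration to 10⁻⁹), and it makes the DDD screen err on the
conservative side.

## Numerical details and degenerate inputs

* Zero variance in both groups with equal means gives p = 1 (no evidence),
  with unequal means p = 0.
* `fisher_exact_2x2()` sums hypergeometric probabilities ≤ the observed
  table's probability with a 1 + 10⁻⁷ relative tolerance (the same rule as
  `stats::fisher.test`); an all-zero table is an error.
* PWM windows containing `N` are skipped on both strands; a sequence with no
  clean window scores `NA` with a warning; a degenerate motif with equal
  minimum and maximum attainable scores has relative score 1 by convention.
* `chromosome_chi_square()` refuses chromosomes with zero chip probes
  (expected count 0) and instructs the caller to merge or exclude them.
* All generators save and restore the caller's RNG state; every analysis
  stage after generation is deterministic, so `run_pipeline()` is a pure
  function of (inputs, configuration).

## Problem sizes used by the test suite

The shipped tests run the reference simulation over 50 seeds for the
recovery study (and 50 for its null), 20 seeds × 200 clusters for DDD
calibration, 200 seeds for the pscan and chi-square uniformity checks, an
exhaustive Fisher sweep over all 2×2 tables with margins ≤ 30, and 100
random sequence/PWM pairs against a brute-force scanner. These sizes keep
each property estimate's Monte-Carlo error small relative to the tolerance
it is tested at while staying comfortable on a single CPU.

## Worked example

```{r example, eval = FALSE}
library(pcsrscan)

# same-band miRNA clusters in the shipped multi-cancer catalogue
mir <- read_mirna_table(pcsr_example_file("common_mirna.tsv"))
clusters <- detect_mirna_clusters(mir$mirnas)
flag_pcsr(transform(clusters, location = band),
          unique(mir$mirnas$location[mir$mirnas$pcsr]))

# a full synthetic run
dir <- tempfile()
simulate_inputs(sim_config(seed = 1), dir)
reports <- run_pipeline(dir, file.path(dir, "out"))
head(reports$regions$pcsr)
```

## Known limitations

* The region statistic inherits every bias of the probe annotation: a stale
  or build-mismatched annotation shifts counts between neighbouring bands.
  The annotation table is treated as authoritative input.
* Pooling panels that used different chips is only supported through the
  shared-chip assumption on FTP; heterogeneous-chip panels need external
  reconciliation before counting.
* No multiplicity correction is applied at the probe level, by design; the
  participation percentage is a descriptive recurrence score, and its top-5
  lists carry no significance statement. Permutation calibration of the
  percentages would be a natural extension.
* The pscan z-test assumes approximate normality of mean best-hit scores;
  for very short input lists (< 5 promoters) the one-sample approximation is
  rough and the `all_members` scan mode is preferable.
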