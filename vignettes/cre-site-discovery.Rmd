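---
title: "Methods: PSSM construction, threshold calibration and cross-species operator scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSSM construction, threshold calibration and cross-species operator scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crescan)
```

## The model

`crescan` scores DNA with an additive position-specific scoring matrix
(PSSM). Given $n$ aligned binding sites of width $k$, the count of base
$b$ at position $i$ is normalized with a pseudocount $a$,

$$f_{b,i} = \frac{c_{b,i} + a}{n + 4a},$$

and converted to log-odds bits against a background distribution $p$:

$$w_{b,i} = \log_2 \frac{f_{b,i}}{p_b}, \qquad
  S(x) = \sum_{i=1}^{k} w_{x_i,\,i}.$$

The model's assumptions are exactly what the arithmetic implies:

* **Independence across positions.** $S$ is a sum, so inter-position
  dependencies (dinucleotide stacking, variable spacers) are invisible
  to it. The synthetic generator deliberately simulates the same
  product-multinomial process, so tests probe the estimator, not the
  adequacy of the independence assumption for real operators.
* **A 0th-order background.** A window drawn i.i.d. from $p$ has
  expected score $-\sum_i \mathrm{KL}(p \,\|\, f_{\cdot i}) \le 0$,
  which is why genome-wide score averages are strongly negative and true
  sites appear as rare positive excursions. The per-column conservation
  is the relative entropy
  $IC_i = \sum_b f_{b,i} \log_2 (f_{b,i}/p_b)$ (with $0\log 0 = 0$),
  which reduces to $2 - H_i$ bits under a uniform background.

The consensus (optimum) sequence picks $\arg\max_b w_{b,i}$ per column —
valid for an additive score, and verified in the test suite against
exhaustive enumeration of all $4^k$ sequences for $k \le 6$.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| pseudocount $a$ | 0.5 per cell | Keeps all log-odds finite for collections of a few dozen sites while perturbing a 44-site column by at most ~1%. $a=0$ is allowed; zero cells then score $-\infty$ (or error under `on_zero = "error"`). |
| background | estimated from the scanned/calibration genome | A uniform background caps any score at $2k$ bits; published bit scores for 14-mers above 28 can only arise from a skewed composition background, so composition estimation is the default and uniform is one call away. |
| strand mode | `"forward"` | Mirrors single-strand "every k-mer" scans; `"both"` scores each window's reverse complement too and by default keeps the better strand per position. |
| threshold grid | integers 9–19 bits | The customary calibration sweep for ~14-bp operator matrices; any `"lo:hi:step"` grid is accepted, and ROC endpoint anchoring needs a grid spanning the observed score range. |
| upstream window | 500 bp | A generous bacterial promoter region: hits not inside a CDS are called `"upstream"` only if a gene start (strand-aware) lies within this many bp. |
| negative-set slack | $\lfloor k/2 \rfloor$ bp | Windows overlapping a known site by at least half the motif are neither positives nor fair negatives; they are excluded from ROC labeling unless `strict = TRUE`. |

## Numerical and policy choices

* **Ties and degeneracy.** Consensus ties break lexicographically
  A < C < G < T. Thresholding uses `score >= t` (a tie is a detection).
  Windows containing non-A/C/G/T characters are skipped and counted
  rather than zero-scored, keeping the score distribution clean;
  training sites must be pure A/C/G/T.
* **Background floor.** Estimated background probabilities of zero are
  floored at $10^{-6}$ and renormalized (with a warning) so log-odds
  stay finite on degenerate inputs.
* **Streaming summary.** Scan statistics (mean, sd, min, max) are
  accumulated chunk-wise with the numerically stable Welford/Chan
  update, so summaries never require the full score vector resident;
  `return_windows = FALSE` scans arbitrarily long genomes in bounded
  memory.
* **AUROC.** The rank-based (Mann–Whitney) estimator with midrank ties
  is the primary statistic; the test suite cross-checks it against an
  $O(n^2)$ pairwise oracle and against `pROC`, and verifies agreement
  with trapezoidal integration over a dense threshold grid to $10^{-3}$.
* **Coordinates.** All internal coordinates are 1-based inclusive;
  `write_bed()` converts to BED's 0-based half-open convention, writes
  bit scores to two decimals without rescaling to 0–1000, and always
  emits a header comment so output is self-describing and
  byte-deterministic.
* **Training orientation.** Site collections are counted as supplied, in
  one orientation. Operator dyad symmetry can be assessed afterwards
  with `palindrome_positions()`; symmetrizing the training set is left
  to the user (append `revcomp(sites)` before counting) because
  automatic symmetrization would silently halve the information of
  genuinely asymmetric motifs.
* **Matrix interchange.** `read_matrix_tsv()` accepts both the
  per-position (`pos A C G T`) and the transposed 4-row layout,
  round-tripping to six decimals, so published matrices can be loaded
  verbatim whichever way they were normalized; `read_jaspar()` covers
  JASPAR-style count matrices.

## What the synthetic generator emulates — and what it does not

`simulate_benchmark()` reproduces the statistical structure the pipeline
assumes, at the scale of a typical curated study:

* **44 training sites of width 14** drawn column-independently from
  `cre_like_motif()`, a frequency matrix shaped on the degenerate
  consensus `TGNAANCGNWNNCW` with weight 0.94 on each fully specified
  base and 0.47/0.47 on A/T at `W` positions. That conservation level is
  typical of curated bacterial operator alignments and gives the motif
  ≈ 12.4 bits of total information — enough, by the standard extreme-
  value argument, for planted sites to clear the background maximum in
  genomes up to ~1 Mb with high probability.
* **A 100 kb background genome** at GC 0.435 (a Firmicutes-like
  composition), drawn i.i.d.
* **10 planted sites**, substituted in place (never inserted, so all
  downstream coordinates are preserved) at non-overlapping recorded
  positions, reverse-complemented when planted on the minus strand.

All generators are seed-deterministic down to the byte, which is what
makes the end-to-end disk artifacts reproducible.

What is *not* emulated: dinucleotide or higher-order background
structure, repeats and low-complexity tracts, mosaic composition
(horizontally transferred islands), curation biases in real site
collections, and any inter-position dependence within sites. A green
test suite therefore demonstrates that the estimator and the scanning
machinery are correct under the model's own assumptions — not that the
model suffices for any particular real genome, where false-positive
rates are typically higher than the i.i.d. background predicts.

## Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` run the pipeline at desk
scale, chosen so every property is measurable in seconds: 5–50 kb
genomes for oracle (brute-force) score comparisons, the 100 kb / 44-site
/ 10-site benchmark for ROC and recovery, $10^4$ sampled sites for
large-sample parameter recovery (the Hoeffding envelope at that $n$ is
±0.02 per cell at 95% confidence), and exhaustive $4^k$ enumeration up
to $k = 6$ for consensus optimality.

## Known limitations

* No motif discovery: training sites must be pre-aligned and
  equal-width. No EM/Gibbs realignment is attempted.
* Single-motif, fixed-width scanning; no gapped or bipartite operators.
* The ROC calibration treats every non-site window as a potential
  negative; in real genomes undiscovered true sites deflate the apparent
  specificity.
* Palindrome analysis requires even width and rejects odd-width input
  rather than guessing a spacer.
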