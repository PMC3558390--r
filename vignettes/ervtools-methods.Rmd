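---
title: "Methods: retro-element chromatin association and expression quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retro-element chromatin association and expression quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervtools)
```

This vignette documents the statistical model behind each `ervtools`
module, the parameters that matter, the numerical choices made where the
design was genuinely open, and — importantly — what the synthetic-data
generator does and does not establish about behaviour on real data.

## 1. The association model

Endogenous proviruses are fixed in the genome, so unlike integration-site
studies there is no "pre-integration" sample: association with a chromatin
feature has to be read off the standing positions. A marker is reduced to
point peaks $\{m_1, \dots, m_N\}$ per chromosome (ChIP-seq summit when the
input provides one, interval midpoint otherwise — the choice is exposed
because public peak sets vary). The distance between a provirus spanning
$[V^s, V^e)$ and a peak $m$ is

$$d(V, m) = \min(|V^s - m|,\; |V^e - m|),$$

equal to $|V^c - m| - (V^e - V^s)/2$ with $V^c$ the element center. The
center form goes negative when the peak lies inside the element; we clamp
to zero (a marker inside the provirus is at distance 0 — the biological
reading).

An element is *within* at window $w$ (default 2000 bp) when its nearest
peak distance is $\le w$. The same classification is applied to $n_0$
random control loci (default 100,000, uniform over the genome with
chromosomes weighted by length). Writing $x_1/n_1$ for the element
within-rate and $x_0/n_0$ for the control within-rate:

$$R = \frac{x_1}{n_1}, \qquad
  P = \frac{x_1/n_1}{x_1/n_1 + x_0/n_0}, \qquad
  F_\beta = \frac{(1+\beta^2) P R}{\beta^2 P + R},\quad \beta = 0.5.$$

**Why rates, not raw counts.** The control set (10^5) dwarfs any element
family (~10^3). Raw-count precision $x_1/(x_1+x_0)$ would shrink with every
extra control locus; the rate form is invariant to the control sample size,
which is the only construction under which F values are comparable across
runs. This is a design decision of this package: the originating method
literature delegates the exact contingency construction to earlier work.

**Significance.** One-sided (enrichment) Fisher exact test on the 2×2
table, computed as the hypergeometric upper tail via `phyper(log.p=TRUE)`.
Genome-scale contrasts yield p-values below 10^-300, which underflow double
precision; all p-values are therefore carried and reported in natural-log
space. The test suite checks the log-tail against an independent
enumeration of binomial-coefficient terms.

**Profiles and clustering.** F as a function of $w$ over
$\{500, 1000, \dots, 10000\}$ bp (distances are computed once and
thresholded per window). Cell types are clustered on the Euclidean distance
between their profiles with agglomerative linkage. The linkage method is
not recoverable from the analysis this reimplements; the default is
*average*, configurable, and the tests use planted structure that is robust
to that choice. `k = 3` by default (high/medium/low association), with a
height-threshold cut also exposed; clusters are relabelled in descending
mean-F order so cluster 1 is always "high".

## 2. Multiread reassignment and RPKM

Repeat families share short conserved stretches, so a read may align
equally well to $M$ regions $\{s_1,\dots,s_M\}$. For each candidate region,
its *context* $c_i$ is the pair of flanks of $n$ bp on either side
(default $n$ = 10,000 per side; the value is a package choice — large
enough to estimate local background, local enough to stay "surrounding").
Under the assumption that read density tracks local mRNA abundance, the
read is split

$$P(r \in s_i) = \frac{R(c_i)}{\sum_j R(c_j)},$$

where $R(\cdot)$ counts uniquely-mapped reads (midpoint rule). When all
context counts are zero the formula is 0/0 and the read is split uniformly
(maximum-entropy completion). One assignment round only — this is a single
probabilistic partition, not an EM iteration.

Two exclusion rules keep contexts honest, both instances of the same
principle (sister copies must not masquerade as local background):

* an element's own context excludes other copies of its family;
* a multiread hit's context excludes same-family copies *other than* the
  element containing the hit (reads in the containing element are exactly
  the evidence that should attract the read).

The second rule matters in practice: without it, a sister copy inside a
hit's flank inflates the wrong candidate's context and per-element RPKM
recovery degrades from ~6% to ~15% worst-case on the 50k-read fixture.

Expression is $E_r = 10^6 N_r / (L_r N_T)$ (RPKM), with $N_r$ the assigned
read mass, $L_r$ the element length in kB, and $N_T$ the total read count.
$N_T$ counts each read once, unique or multi — the alternative (per-hit)
would make the normaliser depend on the repeat content of the genome.

## 3. Specific vs unspecific transcription

A repeat inside an expressed gene accumulates reads without being
independently transcribed. The read count over a region is modelled as
$R(s) = U(s) + T(s) + \sigma^2$ with $U$ unspecific (read-through), $T$
specific, and zero-mean noise $\sigma^2$ (modelled, never estimated). The
unspecific component is estimated from the context, $U(s) = R(c)/2$, giving

$$\hat T(s) = \max\!\big(0,\; R(s) - R(c)/2\big), \qquad
  \text{specificity} = \hat T(s) / R(s).$$

The $R(c)/2$ form implicitly assumes each flank is comparable in length to
the element. With fixed 10 kB flanks this does not hold, so `quantify()`
rescales the raw context count to *two element lengths* (one
element-length equivalent per side) before halving. This is the only
scaling under which the two boundary cases come out right: equal read
density in element and context (pure read-through) gives specificity ≈ 0,
and a silent context gives specificity 1. The clamp at zero exists because
noise can push the raw estimate negative. `specific_expression()` itself
keeps the literal $r_c/2$ contract and documents the expected scale of its
input.

## 4. TSS geometry of transcription-factor binding

The TSS of a provirus is its strand-aware 5′ end (the promoter sits in the
5′ LTR). `tf_proximity()` reports, per factor: the mean nearest-peak
distance to the TSS over bound elements (and, separately, over all elements
with censoring at `max_bp` — analyses differ in which population they
average over, so both counts are reported); the F-vs-distance curve; and
the window of maximal F. The F curve uses TSS *point* distances rather than
element-span distances — factor peaks typically lie inside the LTR, where
the span distance is identically zero and a span-based curve would be flat.

Under uniform placement of a peak within $[0, D]$ of the TSS, the mean
distance is $D/2$ while the association curve saturates at $D$ — the
half-window relation. The package reports the ratio as a diagnostic rather
than asserting it, since real binding is not exactly uniform.

`tf_order_fraction()` checks strict ordering of per-factor nearest-peak
distances (ties count as violations; under independent uniform placement of
three factors each ordering has probability 1/6, which the tests verify by
Monte-Carlo). `binding_fraction()` is the fraction of elements with a peak
within a window of the TSS (default 500 bp — the LTR region) or of the
element span.

## 5. The synthetic generator: what it emulates, what it does not

`sim_config()` states the simulated world once; all generators are
deterministic given the seed.

| parameter | default | rationale |
|---|---|---|
| genome | 5 × 20 Mb | desk-scale; element density within an order of magnitude of genome-wide HERV-H density |
| focal elements | 100 × ~5.5 ± 0.4 kb | full-length gammaretroviral proviruses run 5–6 kb |
| background | 150 LINE (1–6 kb), 200 SINE (0.2–0.4 kb) | the other abundant repeat classes |
| `assoc_fraction` | 0.8 | strong pluripotent-cell-like association (F ≈ 0.9 at w = 2 kB) |
| `assoc_window` | 2000 bp | the standard analysis window |
| `unique_fraction` | 0.8 | the observed 80:20 unique:multiread split |
| `sister_max` | 4 | multiread hit lists add 1–4 same-family copies at the same relative offset, mimicking shared ~100 bp conserved stretches |
| `focal_rna_fraction` | 0.02 | focal family ≈ 2% of total RNA |
| `top_fraction` / `top_share` | 0.1 / 0.8 | ~10% of copies carry 80% of family RNA |
| `flank` (context) | 10,000 bp/side | see §2 |
| decay rates | focal 0.5, NANOG 0.5, OCT4 0.6, SOX2 0.95, BRD2 1.0 | sharp focal/NANOG decay, near-flat SOX2, flat housekeeping normaliser |

Reads are emitted as *alignment records*, not sequences: the pipeline
consumes alignments, and its correctness depends on hit structure, not base
calls. Gene-embedded background elements get reads from a transcript
spanning the element ± 15 kb (so the whole context sits inside the gene),
creating genuine read-through.

What a green test does **not** establish: the generator plants exactly the
structure the estimators assume (uniform placements, proportional read
density, single-family multread sharing, no mapping errors or mismatch
structure, no GC or mappability bias, point-like peaks). Recovery results
are therefore statements about estimator correctness and convergence, not
about robustness to the violations real data exhibits.

A note on the quantification recovery fixture: per-element RPKM accuracy at
a fixed tolerance is a sample-size statement. Under the default two-tier
expression model, low-tier elements receive ~80 reads at a 50k budget, and
the reassignment noise floor alone (~√reads) exceeds 10% for them. The
recovery fixture therefore spreads the 50k reads across 100 elements with
jittered weights (several hundred reads each), which tests the estimator
rather than Poisson noise; the two-tier concentration structure is
recovered in a separate test via `top_k_concentration()`.

## 6. Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; 1-based formats
  (RepeatMasker, SAM) are converted at parse boundaries only.
* Nearest-peak queries are binary searches over sorted per-chromosome
  position vectors; a chromosome with no peaks yields `Inf` (never NA).
* Read–region membership uses the hit midpoint throughout, so a read is
  counted exactly once across a partition of the genome.
* `top_k_concentration()` breaks RPKM ties by element id (deterministic).
* Correlations across 3–4 differentiation stages are descriptive; no
  p-value is attached (meaningless at n = 4). Spearman is the default
  (Pearson exposed); constant series return an `undefined` flag rather
  than erroring or emitting bare NaN.
* Mandala radius is $1 - \log(1+d)/\log(1+d_{max})$, clamped to $[0,1]$:
  distance 0 on the perimeter, $d \ge d_{max}$ (1 Mb) at the center. The
  $\log(1+d)$ form (vs $\log d$ with a floor) is a package choice; the two
  are visually indistinguishable. Dot *area* scales with expression
  (radius ∝ √RPKM).
* SVG mandalas are written directly as XML — deterministic output,
  testable coordinates, no cairo dependence.

## 7. Known limitations

* Single reassignment round; no EM, no isoform model, no paired-end
  fragment model (mate pairs are treated as grouped hits of one read).
* Element intervals passed to `quantify()` must be non-overlapping;
  overlap must be resolved upstream via exclusion sets.
* The Fisher test treats control loci as independent draws; spatial
  autocorrelation of real chromatin would make nominal p-values
  anti-conservative (the F > 0.5 rule, not the p-value, is the primary
  significance criterion).
* Clustering reports a point partition; no stability/bootstrap assessment.
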