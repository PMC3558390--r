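# ervtools

Association and expression analysis of endogenous retroviral elements (ERVs).

Endogenous retroviruses are remnants of ancient germline infections; some
families — notably the gammaretrovirus family HERV-H, present in roughly a
thousand copies in the human genome — remain transcriptionally active in
specific cell states. Two computational problems recur when studying them:

1. **Chromatin association.** Are the genomic positions of a repeat family
   preferentially close to cell-type-specific ChIP-seq peaks (histone marks
   such as H3K4me3, or transcription factors such as NANOG/OCT4/SOX2)?
2. **Expression quantification.** Repeat copies share short conserved
   stretches, so a large fraction of RNA-seq reads map to several loci
   ("multireads") and naive unique-read counting systematically
   underestimates repeat expression. A further confounder is read-through:
   an element inside an expressed gene accumulates reads without being
   independently transcribed.

`ervtools` implements both analyses end-to-end, plus a deterministic
synthetic-data generator so the entire pipeline is testable offline.

## Methods at a glance

**Proximity statistic.** The distance between a point marker at `m` and a
provirus spanning `[V_s, V_e)` is `d = min(|V_s − m|, |V_e − m|)`, clamped
to 0 inside the element. Elements within a window `w` (default 2 kB) are
compared against `n = 100,000` random control loci through the rates
`rate_TP = x1/n1`, `rate_FP = x0/n0`, giving sensitivity `R = rate_TP`,
precision `P = rate_TP / (rate_TP + rate_FP)` and the F-beta score

    F_β = (1 + β²) · P · R / (β² · P + R),   β = 0.5

(β = 0.5 weights precision over sensitivity; F > 0.5 is read as significant
association). Significance is a one-sided Fisher exact test computed in log
space, so p-values far below the double-precision underflow limit remain
exact. Window sweeps (0.5 kB steps) yield association profiles, which can be
clustered across cell types (Euclidean distance, agglomerative linkage) into
high/medium/low association groups.

**Multiread reassignment and RPKM.** A multiread aligning to M regions is
split across them in proportion to the uniquely-mapped read counts of each
region's flanking *context*: `P(r ∈ s_i) = R(c_i) / Σ_j R(c_j)`. Expression
is reported as `RPKM = 10⁶ · N_r / (L_kb · N_T)`. Specific (element-driven)
transcription is separated from read-through with `U(s) = R(c)/2`,
`T(s) = max(0, R(s) − U(s))`, specificity `T(s)/R(s)`.

**TF geometry at the 5′ LTR.** Per element, the distance from the
strand-aware TSS to the nearest peak of each factor; under uniform placement
within `[0, D]` of the TSS the mean distance is `D/2` and the F-vs-distance
curve peaks near `D` (the "half-window" relation). Binding fractions and
strict TF ordering (e.g. NANOG < OCT4 < SOX2) are reported over any element
subset, such as the top-k most expressed copies.

**Mandalas.** One polar plot per chromosome: angle = linear position,
radius = log-scaled distance to the nearest marker (perimeter = distance 0,
center ≥ 1 Mb), blue/red = within/beyond the window, dot area ∝ expression.

## Worked example

```r
library(ervtools)

cfg <- sim_config(seed = 42)                 # 100 HERV-H-like + 350 background elements
ann <- simulate_annotation(cfg)              # 5 x 20 Mb genome, 80% planted association
pk  <- simulate_peaks(ann, cfg)              # H3K4me3-like peak set
ctl <- generate_control_loci(ann$sizes, 20000, seed = 7)

foc <- ann$elements[ann$elements$family == "HERV-H", ]
associate(foc, pk$peaks, ctl, window_bp = 2000)
#> <association_result> w=2000 bp: 85/100 elements, 1604/20000 controls within
#>   P=0.9138 R=0.8500 F_0.5=0.9003 log(p)=-173.65
```

85 of 100 elements lie within 2 kB of a peak versus an 8% background rate,
giving F = 0.90 — far above the 0.5 significance line — with a log-scale
Fisher p of e^−174. Quantification on the same world:

```r
cfg2 <- sim_config(seed = 11, n_background = c(LINE = 0L, SINE = 0L), top_fraction = 1)
ann2 <- simulate_annotation(cfg2)
sim  <- simulate_alignments(ann2, cfg2, gene_read_fraction = 0)  # 50k reads, 80:20 unique:multi
expr <- quantify(sim$alignments, ann2$elements, ann2$sizes)
m <- merge(as.data.frame(expr), sim$truth, by = "element_id")
median(abs(m$rpkm - m$true_rpkm) / m$true_rpkm)
#> [1] 0.01227324
```

Median per-element RPKM error after reassignment is ~1.2% (worst case ~6%),
while unique-only counting underestimates every element by ~20% — the
multiread fraction.

The same operations are available from the command line:

```sh
Rscript -e 'quit(status = ervtools::erv_cli(commandArgs(TRUE)))' \
  simulate --seed 5 --outdir fixtures
Rscript -e 'quit(status = ervtools::erv_cli(commandArgs(TRUE)))' \
  associate --elements fixtures/elements.out --family HERV-H \
  --peaks fixtures/peaks.bed --sizes fixtures/genome.chrom.sizes \
  --controls 100000 --seed 6 --out assoc.tsv
```

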