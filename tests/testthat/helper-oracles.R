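# Independent brute-force oracles and tiny fixture builders.  These stay
# deliberately naive (all-pairs scans, explicit enumeration) so they check
# the optimised implementations rather than mirroring them.

# all-pairs nearest distance from interval elements to point peaks
brute_nearest_distance <- function(elements, peak_df) {
  vapply(seq_len(nrow(elements)), function(i) {
    p <- peak_df$pos[peak_df$chrom == elements$chrom[i]]
    if (length(p) == 0L) return(Inf)
    min(vapply(p, function(m) {
      if (m >= elements$start[i] && m <= elements$end[i]) 0
      else min(abs(elements$start[i] - m), abs(elements$end[i] - m))
    }, 0))
  }, 0)
}

# one-sided Fisher (enrichment) tail by explicit hypergeometric enumeration
brute_fisher_tail <- function(x1, n1, x0, n0) {
  m <- x1 + x0
  k_max <- min(n1, m)
  sum(vapply(x1:k_max, function(k)
    choose(m, k) * choose(n1 + n0 - m, n1 - k) / choose(n1 + n0, n1), 0))
}

# per-element independent recomputation of quantify(): unique counts by
# midpoint, then explicit per-read reassignment with sister-excised contexts
brute_quantify_mass <- function(aln, elements, flank) {
  nh <- table(aln$read_id)
  uniq <- aln[nh[aln$read_id] == 1L, , drop = FALSE]
  umid <- floor((uniq$start + uniq$end) / 2)
  in_iv <- function(pos, chrom, s, e, chr) chrom == chr & pos >= s & pos < e
  elem_of <- function(pos, chrom) {
    for (j in seq_len(nrow(elements)))
      if (in_iv(pos, chrom, elements$start[j], elements$end[j], elements$chrom[j]))
        return(j)
    NA_integer_
  }
  # unique count in [lo,hi), excluding reads inside same-family copies other
  # than element `own`
  ctx_count <- function(chrom, lo, hi, own) {
    n <- 0
    for (r in seq_len(nrow(uniq))) {
      if (uniq$chrom[r] != chrom || umid[r] < lo || umid[r] >= hi) next
      e <- elem_of(umid[r], uniq$chrom[r])
      if (!is.na(own) && !is.na(e) && e != own &&
          elements$family[e] == elements$family[own]) next
      n <- n + uniq$weight[r]
    }
    n
  }
  mass <- setNames(numeric(nrow(elements)), elements$element_id)
  for (r in seq_len(nrow(uniq))) {
    e <- elem_of(umid[r], uniq$chrom[r])
    if (!is.na(e)) mass[e] <- mass[e] + uniq$weight[r]
  }
  multi <- aln[nh[aln$read_id] > 1L, , drop = FALSE]
  for (rid in unique(multi$read_id)) {
    hits <- multi[multi$read_id == rid, , drop = FALSE]
    own <- vapply(seq_len(nrow(hits)), function(h)
      elem_of(floor((hits$start[h] + hits$end[h]) / 2), hits$chrom[h]), 0L)
    cnt <- vapply(seq_len(nrow(hits)), function(h)
      ctx_count(hits$chrom[h], max(0, hits$start[h] - flank), hits$start[h], own[h]) +
      ctx_count(hits$chrom[h], hits$end[h], hits$end[h] + flank, own[h]), 0)
    p <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(1 / nrow(hits), nrow(hits))
    for (h in seq_len(nrow(hits)))
      if (!is.na(own[h])) mass[own[h]] <- mass[own[h]] + hits$weight[h] * p[h]
  }
  mass
}

# small deterministic fixture: 3 elements, hand-placed peaks
tiny_genome <- function() chrom_sizes(c(chrA = 100000, chrB = 50000))

tiny_elements <- function(sizes = tiny_genome()) {
  iv <- genomic_intervals(c("chrA", "chrA", "chrB"),
                          c(10000, 40000, 5000),
                          c(15000, 46000, 5300),
                          c("+", "-", "+"), sizes = sizes)
  provirus_records(c("e1", "e2", "e3"), c("HERV-H", "HERV-H", "LINE"), iv)
}
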