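test_that("count_reads applies the midpoint rule", {
  aln <- alignments(c("r1", "r2", "r3", "r4", "r5", "r6", "r7", "r8"),
                    "c", c(100, 150, 200, 250, 300, 900, 950, 460),
                    c(175, 225, 275, 325, 375, 975, 1025, 560))
  # midpoints: 137,187,237,287,337,937,987,510 -> 5 unique inside [100,400)
  expect_equal(count_reads(aln, "c", 100, 400, mode = "unique_only"), 5)
  # straddling read r8 (460-560, midpoint 510) counted by midpoint
  expect_equal(count_reads(aln, "c", 500, 520, mode = "unique_only"), 1)
  expect_equal(count_reads(aln, "c", 5000, 6000, mode = "unique_only"), 0)
  # multireads are excluded from unique counting
  aln2 <- alignments(c("m", "m", "u"), "c", c(100, 500, 120), c(140, 540, 160))
  expect_equal(count_reads(aln2, "c", 0, 200, mode = "unique_only"), 1)
  expect_error(count_reads(aln2, "c", 0, 200, mode = "all_assigned"), "mass")
})

test_that("make_context builds clipped flanks minus exclusions", {
  sizes <- chrom_sizes(c(c = 10000))
  ctx <- make_context("c", 5000, 6000, 1000, sizes)
  expect_equal(ctx$intervals$start, c(4000, 6000))
  expect_equal(ctx$intervals$end, c(5000, 7000))
  expect_equal(ctx$length, 2000)

  # left flank clipped at chromosome start
  ctx <- make_context("c", 300, 800, 1000, sizes)
  expect_equal(ctx$intervals$start[1], 0)
  expect_equal(ctx$length, 300 + 1000)

  # exclusion covering the right flank leaves only the left
  ctx <- make_context("c", 5000, 6000, 1000, sizes,
                      exclusions = data.frame(chrom = "c", start = 6000, end = 7500))
  expect_equal(nrow(ctx$intervals), 1L)
  expect_equal(unlist(ctx$intervals), c(start = 4000, end = 5000))
  # fully excluded context is legal with length 0
  ctx <- make_context("c", 5000, 6000, 1000, sizes,
                      exclusions = data.frame(chrom = "c", start = 3000, end = 8000))
  expect_equal(ctx$length, 0)
  expect_error(make_context("c", 10, 20, 0, sizes), "positive")
})

test_that("multiread reassignment follows the context-count formula", {
  expect_equal(reassign_multiread(c(30, 10)), c(0.75, 0.25))
  expect_equal(reassign_multiread(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(reassign_multiread(5), 1)
  expect_error(reassign_multiread(c(-1, 2)), "negative")
  # always a probability vector
  set.seed(2)
  for (i in 1:20) {
    v <- rpois(sample(1:6, 1), 3)
    expect_equal(sum(reassign_multiread(v)), 1)
  }
})

test_that("specific_expression decomposes counts and clamps at zero", {
  r <- specific_expression(100, 40)
  expect_equal(r$u_s, 20)
  expect_equal(r$t_s, 80)
  expect_equal(r$specificity, 0.8)
  r <- specific_expression(50, 200)
  expect_equal(r$t_s, 0)
  expect_equal(r$specificity, 0)
  r <- specific_expression(50, 0)
  expect_equal(r$t_s, 50)
  expect_equal(r$specificity, 1)
  expect_equal(specific_expression(0, 10)$specificity, 0)
  expect_error(specific_expression(-1, 2), "negative")
})

test_that("quantify computes RPKM and reduces to unique counting without multireads", {
  sizes <- chrom_sizes(c(c = 1e6))
  el <- provirus_records(c("a", "b"), "F",
                         genomic_intervals(c("c", "c"), c(10000, 50000),
                                           c(12000, 51000)))
  # 1000 reads total: 100 in a (2 kb), 50 in b (1 kb), rest elsewhere
  starts <- c(seq(10100, 11800, length.out = 100),
              seq(50100, 50800, length.out = 50),
              seq(200000, 900000, length.out = 850))
  aln <- alignments(sprintf("r%d", seq_along(starts)), "c",
                    floor(starts), floor(starts) + 75)
  expr <- quantify(aln, el, sizes)
  expect_equal(attr(expr, "n_total_reads"), 1000)
  expect_equal(expr$n_reads, c(100, 50))
  # RPKM = 1e6 * N_r / (L_kb * N_T)
  expect_equal(expr$rpkm, c(1e6 * 100 / (2 * 1000), 1e6 * 50 / (1 * 1000)))
  # unique-only equivalence when no multireads exist
  expect_equal(expr$n_reads[1],
               count_reads(aln, "c", 10000, 12000, mode = "unique_only"))
  expect_error(quantify(aln[0, ], el, sizes), "N_T = 0")
})

test_that("quantify conserves read mass and matches the brute-force oracle", {
  set.seed(31)
  sizes <- chrom_sizes(c(c1 = 200000, c2 = 150000))
  el <- provirus_records(
    c("a", "b", "c", "d"), c("F", "F", "F", "G"),
    genomic_intervals(c("c1", "c1", "c2", "c2"),
                      c(20000, 60000, 30000, 90000),
                      c(24000, 64000, 34000, 92000)))
  # ~80 reads: unique in elements, multireads across the F copies, background
  mk <- function(n, lo, hi) floor(runif(n, lo, hi))
  s1 <- mk(30, 20000, 23900); s2 <- mk(15, 60000, 63900)
  s3 <- mk(10, 30000, 33900); s4 <- rep(mk(8, 0, 2000), each = 3)
  s5 <- mk(20, 100000, 140000)
  aln <- rbind(
    alignments(sprintf("u%d", 1:30), "c1", s1, s1 + 75),
    alignments(sprintf("v%d", 1:15), "c1", s2, s2 + 75),
    alignments(sprintf("w%d", 1:10), "c2", s3, s3 + 75),
    alignments(rep(sprintf("m%d", 1:8), each = 3),
               rep(c("c1", "c1", "c2"), 8),
               rep(c(21000, 61000, 31000), 8) + s4,
               rep(c(21075, 61075, 31075), 8) + s4),
    alignments(sprintf("bg%d", 1:20), "c2", s5, s5 + 75))
  aln <- alignments(aln$read_id, aln$chrom, aln$start, aln$end)

  expr <- quantify(aln, el, sizes, flank_bp = 5000)
  # per-multiread probabilities sum to 1 -> global mass <= N_T
  hm <- attr(expr, "hit_mass")
  per_read <- tapply(hm$mass, hm$read_id, sum)
  expect_equal(as.vector(per_read[startsWith(names(per_read), "m")]), rep(1, 8))
  expect_lte(sum(expr$n_reads), attr(expr, "n_total_reads") + 1e-9)

  # independent per-element recomputation
  oracle <- brute_quantify_mass(aln, el, flank = 5000)
  expect_equal(expr$n_reads, unname(oracle[el$element_id]), tolerance = 1e-9)

  # all_assigned counting over an element equals its assigned mass
  expect_equal(count_reads(hm, "c1", 20000, 24000, mode = "all_assigned"),
               expr$n_reads[1], tolerance = 1e-12)
})

test_that("reassignment recovers planted RPKM and beats unique-only counting", {
  cfg <- sim_config(seed = 21, n_focal = 60L,
                    n_background = c(LINE = 0L, SINE = 0L),
                    top_fraction = 1, n_reads = 20000L)
  ann <- simulate_annotation(cfg)
  sim <- simulate_alignments(ann, cfg, gene_read_fraction = 0)
  expr <- quantify(sim$alignments, ann$elements, ann$sizes)
  m <- merge(as.data.frame(expr), sim$truth, by = "element_id")
  expect_true(all(abs(m$rpkm - m$true_rpkm) / m$true_rpkm < 0.1))
  # unique-only underestimates multiread-rich elements; reassignment reduces
  # the absolute error for every element
  uo <- vapply(seq_len(nrow(ann$elements)), function(i)
    count_reads(sim$alignments, ann$elements$chrom[i], ann$elements$start[i],
                ann$elements$end[i], mode = "unique_only"), 0)
  uo_rpkm <- 1e6 * uo / (((ann$elements$end - ann$elements$start) / 1000) * sim$n_reads)
  m$uo_rpkm <- uo_rpkm[match(m$element_id, ann$elements$element_id)]
  expect_true(all(m$uo_rpkm < m$true_rpkm))
  expect_true(all(abs(m$rpkm - m$true_rpkm) < abs(m$uo_rpkm - m$true_rpkm)))
})

test_that("specificity separates independent from gene-embedded transcription", {
  cfg <- sim_config(seed = 77, n_focal = 20L,
                    n_background = c(LINE = 30L, SINE = 0L),
                    n_reads = 30000L, focal_rna_fraction = 0.3)
  ann <- simulate_annotation(cfg)
  targets <- sim_expression_targets(ann, cfg, n_embedded = 8L)
  sim <- simulate_alignments(ann, cfg, targets = targets)
  expr <- quantify(sim$alignments, ann$elements, ann$sizes)
  embedded <- expr$element_id %in% targets$embedded_ids
  focal <- expr$family == "HERV-H" & expr$n_reads > 20
  expect_gt(mean(expr$specificity[focal]), 0.85)
  expect_lt(mean(expr$specificity[embedded]), 0.15)
})

test_that("family aggregation sums RPKM and partitions read fractions", {
  expr <- structure(
    data.frame(element_id = c("h1", "h2", "l1"),
               family = c("HERV-H", "HERV-H", "LINE"),
               length_kb = c(2, 1, 3), n_reads = c(300, 200, 100),
               rpkm = c(300, 200, 50), r_s = c(300, 200, 100),
               r_c = 0, u_s = 0, t_s = c(300, 200, 100), specificity = 1),
    n_total_reads = 1000,
    class = c("element_expression", "data.frame"))
  agg <- aggregate_family(expr)
  expect_equal(agg$rpkm[agg$family == "HERV-H"], 500)
  expect_equal(agg$read_fraction[agg$family == "HERV-H"], 0.5)
  expect_equal(sum(agg$read_fraction), sum(expr$n_reads) / 1000)
  # remapping families
  agg2 <- aggregate_family(expr, family_map = c("HERV-H" = "HERV", LINE = "repeat"))
  expect_equal(sort(agg2$family), c("HERV", "repeat"))
})
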