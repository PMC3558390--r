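make_region_element <- function() {
  sizes <- chrom_sizes(c(c = 100000))
  iv <- genomic_intervals("c", 10000, 16000, "+", sizes = sizes)
  regions <- list(e1 = data.frame(
    region = c("5LTR", "gag", "pro", "pol", "env", "3LTR"),
    start = c(10000, 10500, 12000, 12700, 14500, 15500),
    end = c(10500, 12000, 12700, 14500, 15500, 16000)))
  list(sizes = sizes,
       elements = provirus_records("e1", "HERV-H", iv, regions = regions))
}

test_that("region coverage normalises to the 5' LTR", {
  fx <- make_region_element()
  mids <- c(rep(10250, 100), rep(11000, 80), rep(12350, 60),
            rep(13000, 2), rep(15000, 1), rep(15750, 90))
  aln <- alignments(sprintf("r%d", seq_along(mids)), "c", mids - 37, mids + 38)
  expr <- quantify(aln, fx$elements, fx$sizes)
  cov <- region_coverage(attr(expr, "hit_mass"), fx$elements, "e1")
  expect_equal(unname(cov$counts), c(100, 80, 60, 2, 1, 90))
  expect_equal(unname(cov$normalized), c(1, 0.8, 0.6, 0.02, 0.01, 0.9))
  # scale invariance: doubling reads leaves the normalised profile unchanged
  aln2 <- alignments(c(sprintf("a%d", seq_along(mids)), sprintf("b%d", seq_along(mids))),
                     "c", rep(mids - 37, 2), rep(mids + 38, 2))
  expr2 <- quantify(aln2, fx$elements, fx$sizes)
  cov2 <- region_coverage(attr(expr2, "hit_mass"), fx$elements, "e1")
  expect_equal(cov2$normalized, cov$normalized)
  # zero 5LTR count -> undefined flag, not a crash
  aln3 <- alignments("x", "c", 13000, 13075)
  cov3 <- region_coverage(attr(quantify(aln3, fx$elements, fx$sizes), "hit_mass"),
                          fx$elements, "e1")
  expect_true(cov3$undefined)
  expect_error(region_coverage(aln, fx$elements, "nope"), "no region map")
})

test_that("reads from a 5LTR-gag-pro-3LTR transcript leave pol/env empty", {
  cfg <- sim_config(seed = 13, n_focal = 5L, n_background = c(LINE = 0L, SINE = 0L))
  ann <- simulate_annotation(cfg)
  id <- ann$elements$element_id[1]
  aln <- simulate_transcript_reads(ann$elements, id, n = 2000, seed = 14)
  expr <- quantify(aln, ann$elements, ann$sizes)
  cov <- region_coverage(attr(expr, "hit_mass"), ann$elements, id)
  expect_lt(cov$normalized[["pol"]], 0.05)
  expect_lt(cov$normalized[["env"]], 0.05)
  expect_gt(cov$normalized[["gag"]], 0.5)
})

test_that("top-k concentration sorts by RPKM and is monotone in k", {
  expr <- structure(data.frame(element_id = c("a", "b", "c"),
                               rpkm = c(50, 30, 20)),
                    class = c("element_expression", "data.frame"))
  r <- top_k_concentration(expr, 2)
  expect_equal(r$fraction, 0.8)
  expect_equal(r$top, c("a", "b"))
  expect_equal(top_k_concentration(expr, 3)$fraction, 1)
  eq <- structure(data.frame(element_id = letters[1:4], rpkm = rep(5, 4)),
                  class = c("element_expression", "data.frame"))
  expect_equal(top_k_concentration(eq, 2)$fraction, 0.5)
  fr <- vapply(1:3, function(k) top_k_concentration(expr, k)$fraction, 0)
  expect_true(all(diff(fr) >= 0))
  expect_error(top_k_concentration(expr, 5), "exceeds")
  expect_error(top_k_concentration(expr[0, ], 1), "empty")
})

test_that("trajectory normalisation rescales by housekeeping and stage 0", {
  s <- stage_series(c(10, 5, 2, 1), normalizer = rep(3, 4))
  expect_equal(normalize_trajectory(s), c(1, 0.5, 0.2, 0.1))
  prop <- stage_series(c(4, 2, 1), normalizer = c(8, 4, 2))
  expect_equal(normalize_trajectory(prop), c(1, 1, 1))
  expect_error(normalize_trajectory(stage_series(1:3, normalizer = c(1, 0, 1))),
               "strictly positive")
  # synthetic decaying series is monotone decreasing after normalisation
  cfg <- sim_config(seed = 5)
  ser <- simulate_differentiation(cfg)
  v <- normalize_trajectory(ser$focal)
  expect_equal(v, 0.5^(0:3))
  expect_true(all(diff(v) < 0))
})

test_that("trajectory correlation defaults to Spearman and flags constants", {
  expect_equal(correlate_trajectories(1:4, 1:4)$rho, 1)
  expect_equal(correlate_trajectories(c(4, 3, 2, 1), c(8, 6, 4, 3))$rho, 1)
  expect_equal(correlate_trajectories(1:4, 4:1)$rho, -1)
  p <- correlate_trajectories(c(1, 2, 3), c(2, 4, 6), method = "pearson")
  expect_equal(p$rho, 1)
  const <- correlate_trajectories(c(1, 1, 1), c(1, 2, 3), method = "pearson")
  expect_true(const$undefined)
  expect_true(is.na(const$rho))
  expect_error(correlate_trajectories(1:2, 1:2), ">= 3")
  # matched decay rates give rho = 1 on simulated series
  ser <- simulate_differentiation(sim_config(seed = 9))
  expect_equal(correlate_trajectories(ser$focal, ser$NANOG)$rho, 1)
})

test_that("TF proximity mean approaches D/2 under uniform placement", {
  cfg <- sim_config(seed = 51, n_focal = 2000L,
                    n_background = c(LINE = 0L, SINE = 0L),
                    sizes = chrom_sizes(stats::setNames(rep(1e8, 4), paste0("chr", 1:4))))
  ann <- simulate_annotation(cfg)
  for (D in c(500, 4000)) {
    pk <- simulate_peaks(ann, cfg, marker = "TF", tf_mode = TRUE, tf_window = D,
                         seed_offset = D)
    res <- tf_proximity(ann$elements, pk$peaks, max_bp = 2 * D)
    # Monte-Carlo error of the mean ~ D/sqrt(12 n)
    expect_equal(res$mean_distance_bp, D / 2,
                 tolerance = 4 * (D / sqrt(12 * 2000)) / (D / 2))
    expect_equal(res$n_bound, 2000L)
  }
  # peaks exactly at the TSS -> mean 0
  tss <- element_tss(ann$elements)
  pk0 <- marker_peaks("TF", "ES", data.frame(chrom = ann$elements$chrom, pos = tss))
  expect_equal(tf_proximity(ann$elements, pk0, max_bp = 1000)$mean_distance_bp, 0)
  # F curve peaks near D and the half-window diagnostic is ~0.5
  ctl <- generate_control_loci(ann$sizes, 20000, seed = 52)
  pk <- simulate_peaks(ann, cfg, tf_mode = TRUE, tf_window = 2000, seed_offset = 9)
  res <- tf_proximity(ann$elements, pk$peaks, ctl, bin_bp = 500, max_bp = 10000)
  expect_equal(res$max_assoc_window_bp, 2000)
  expect_equal(res$half_window_ratio, 0.5, tolerance = 0.1)
  expect_error(tf_proximity(ann$elements, pk$peaks, subset = "none"), "empty")
})

test_that("TF order fraction detects strict distance ordering", {
  sizes <- chrom_sizes(c(c = 1e6))
  n <- 30
  start <- seq(10000, by = 20000, length.out = n)
  el <- provirus_records(sprintf("e%d", 1:n), "F",
                         genomic_intervals(rep("c", n), start, start + 5000,
                                           strand = "+"))
  mk <- function(d) marker_peaks("TF", "ES", list(c = start + d))
  res <- tf_order_fraction(el, list(mk(100), mk(800), mk(1800)))
  expect_equal(res$fraction, 1)
  expect_equal(res$n_included, n)
  expect_equal(tf_order_fraction(el, list(mk(1800), mk(800), mk(100)))$fraction, 0)
  # ties violate strict order
  expect_equal(tf_order_fraction(el, list(mk(500), mk(500)))$fraction, 0)
  # elements without all TFs nearby are excluded and counted
  far <- marker_peaks("TF", "ES", list(c = start[1] + 100))
  res2 <- tf_order_fraction(el, list(far, mk(800)), max_bp = 5000)
  expect_equal(res2$n_included, 1L)
  expect_equal(res2$n_excluded, n - 1L)

  # random independent placement -> every ordering of 3 TFs equally likely
  set.seed(60)
  hits <- replicate(400, {
    d <- runif(3, 0, 2000)
    all(diff(d) > 0)
  })
  expect_equal(mean(hits), 1 / 6, tolerance = 3 * sqrt((1 / 6) * (5 / 6) / 400) * 6)
  # and through the full API with per-element independent uniform peaks
  n2 <- 300
  start2 <- seq(10000, by = 3000 + 20000, length.out = n2)
  el2 <- provirus_records(sprintf("x%d", 1:n2), "F",
                          genomic_intervals(rep("c", n2) , start2, start2 + 2000,
                                            strand = "+", sizes = chrom_sizes(c(c = 1e8))))
  mkr <- function(seed) {
    set.seed(seed)
    marker_peaks("TF", "ES", list(c = sort(start2 + floor(runif(n2, 0, 2000)))))
  }
  resr <- tf_order_fraction(el2, list(mkr(1), mkr(2), mkr(3)), max_bp = 2500)
  expect_equal(resr$fraction, 1 / 6, tolerance = 0.09)
})

test_that("binding fraction counts elements with a peak near the anchor", {
  fx <- tiny_elements()
  tss <- element_tss(fx)
  all_pk <- marker_peaks("N", "ES", data.frame(chrom = fx$chrom, pos = tss + c(100, -200, 300)))
  expect_equal(binding_fraction(fx, all_pk, window_bp = 500), 1)
  none <- marker_peaks("N", "ES", list(chrA = 99000))
  expect_equal(binding_fraction(fx, none, window_bp = 500), 0)
  # planted 96%-bound fixture recovers exactly
  n <- 50
  start <- seq(10000, by = 10000, length.out = n)
  el <- provirus_records(sprintf("p%d", 1:n), "F",
                         genomic_intervals(rep("c", n), start, start + 5000, "+"))
  bound <- 1:48  # 96% of 50
  pk <- marker_peaks("N", "ES", list(c = start[bound] + 250))
  expect_equal(binding_fraction(el, pk, window_bp = 500), 0.96)
})
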