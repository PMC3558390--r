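## Deterministic synthetic-data generator: genomes, element annotations,
## peak sets, alignment records and differentiation series with the
## statistical structure the analysis assumes, plus the ground truth needed
## to test every downstream stage without external downloads.

#' Simulation configuration
#'
#' Defaults encode the conditions the analysis expects of real data:
#' an 80:20 unique:multiread split, a focal repeat family contributing ~2%
#' of total RNA with ~80% of that RNA concentrated in the top ~10% of
#' copies, a 2 kB association window, and TF peaks placed uniformly within a
#' per-TF window downstream of the TSS.
#'
#' @param seed integer RNG seed; the same seed reproduces every generator
#'   output end-to-end.
#' @param sizes [chrom_sizes()] of the synthetic genome (default 5 x 20 Mb).
#' @param n_focal number of focal-family (HERV-H-like) elements.
#' @param n_background named vector of background family sizes.
#' @param focal_len_mean,focal_len_sd focal element length distribution (bp);
#'   full-length gammaretroviral proviruses run 5-6 kb.
#' @param background_len named list: family -> c(min, max) length range.
#' @param assoc_fraction fraction `a` of focal elements given a private peak
#'   within `assoc_window` (the planted association signal).
#' @param assoc_window association window `w` in bp (default 2000).
#' @param n_background_peaks peaks placed uniformly over the genome.
#' @param tf_window per-TF uniform placement window `D` in bp (TF mode).
#' @param n_reads total read budget for [simulate_alignments()].
#' @param read_len read length in bp (paper-era RNA-seq: 25-75 nt).
#' @param unique_fraction probability a focal-element read maps uniquely.
#' @param sister_max maximum sister hits added to a multiread (1..sister_max).
#' @param focal_rna_fraction share of total RNA from the focal family.
#' @param top_fraction,top_share expression concentration: `top_fraction` of
#'   focal copies carry `top_share` of the family's RNA.
#' @param gene_extent half-width (bp) of the transcript spanning a
#'   gene-embedded element, beyond the element on each side.
#' @param margin placement margin kept free at chromosome ends (bp).
#' @param decay_rates per-stage geometric decay of the differentiation
#'   series (1 = flat).
#' @param n_stages number of differentiation stages.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       sizes = chrom_sizes(stats::setNames(rep(2e7, 5),
                                                           paste0("chr", 1:5))),
                       n_focal = 100L,
                       n_background = c(LINE = 150L, SINE = 200L),
                       focal_len_mean = 5500, focal_len_sd = 400,
                       background_len = list(LINE = c(1000, 6000),
                                             SINE = c(200, 400)),
                       assoc_fraction = 0.8, assoc_window = 2000,
                       n_background_peaks = 2000L,
                       tf_window = 500,
                       n_reads = 50000L, read_len = 75L,
                       unique_fraction = 0.8, sister_max = 4L,
                       focal_rna_fraction = 0.02,
                       top_fraction = 0.1, top_share = 0.8,
                       gene_extent = 15000,
                       margin = 10000,
                       decay_rates = c(focal = 0.5, NANOG = 0.5,
                                       OCT4 = 0.6, SOX2 = 0.95, BRD2 = 1.0),
                       n_stages = 4L) {
  stopifnot(assoc_fraction >= 0, assoc_fraction <= 1,
            unique_fraction >= 0, unique_fraction <= 1,
            top_fraction >= 0, top_fraction <= 1,
            top_share >= 0, top_share <= 1,
            n_focal >= 0, n_reads >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# region map proportions for a full-length provirus
REGION_PROPS <- c("5LTR" = 0.08, gag = 0.25, pro = 0.12,
                  pol = 0.30, env = 0.17, "3LTR" = 0.08)

# place k non-overlapping lengths uniformly on [margin, size - margin]:
# draw k points in the free space, sort, shift by cumulative lengths
place_nonoverlapping <- function(lengths, size, margin) {
  k <- length(lengths)
  if (k == 0L) return(numeric())
  usable <- size - 2 * margin
  free <- usable - sum(lengths)
  if (free < 0) stop("simulate_annotation: genome too small to place all elements")
  pts <- sort(stats::runif(k, 0, free))
  o <- sample.int(k)  # random order of which element takes which slot
  starts <- numeric(k)
  starts[o] <- margin + pts + c(0, cumsum(lengths[o]))[seq_len(k)]
  floor(starts)
}

#' Simulate a genome annotation
#'
#' Places focal and background elements non-overlapping and uniformly over
#' the genome (chromosome chosen proportionally to length).  Focal elements
#' carry a proportional 5LTR-gag-pro-pol-env-3LTR region map; strands are
#' random.
#'
#' @param config [sim_config()].
#' @return list: `sizes` ([chrom_sizes()]), `elements` (`provirus_records`
#'   with focal family `"HERV-H"`).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  sizes <- config$sizes
  fam <- c(rep("HERV-H", config$n_focal),
           rep(names(config$n_background), config$n_background))
  n <- length(fam)
  if (n == 0L)
    return(list(sizes = sizes,
                elements = provirus_records(character(), character(),
                                            genomic_intervals(character(), numeric(), numeric()))))
  len <- numeric(n)
  foc <- fam == "HERV-H"
  len[foc] <- pmax(1000, round(stats::rnorm(sum(foc), config$focal_len_mean,
                                            config$focal_len_sd)))
  for (bf in names(config$n_background)) {
    sel <- fam == bf
    rng <- config$background_len[[bf]]
    len[sel] <- round(stats::runif(sum(sel), rng[1], rng[2]))
  }
  chrom <- sample(names(sizes), n, replace = TRUE,
                  prob = as.numeric(sizes) / sum(as.numeric(sizes)))
  start <- numeric(n)
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    start[sel] <- place_nonoverlapping(len[sel], sizes[[chr]], config$margin)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("%s_%04d", fam, stats::ave(seq_len(n), fam, FUN = seq_along))
  iv <- genomic_intervals(chrom, start, start + len, strand, sizes = sizes)
  regions <- lapply(which(foc), function(i) {
    props <- REGION_PROPS
    if (strand[i] == "-") props <- rev(props)  # strand-ordered: 5LTR at 5' end
    bounds <- round(start[i] + len[i] * cumsum(c(0, props)))
    data.frame(region = names(props), start = bounds[-length(bounds)],
               end = bounds[-1], stringsAsFactors = FALSE)
  })
  names(regions) <- ids[foc]
  list(sizes = sizes,
       elements = provirus_records(ids, fam, iv, regions = regions))
}

#' Simulate a ChIP-seq peak set
#'
#' In association mode (`tf_mode = FALSE`), a fraction `a` of focal elements
#' receives one peak uniform within `w` bp of a random element edge
#' (outside the element); the remaining peaks are uniform over the genome.
#' In TF mode, each focal element receives a peak uniform in `[0, D]`
#' downstream of its TSS (i.e. inside the promoter-proximal LTR).
#'
#' @param annotation result of [simulate_annotation()].
#' @param config [sim_config()].
#' @param marker,cell_type labels for the peak set.
#' @param tf_mode place peaks relative to the TSS instead of element edges.
#' @param tf_window override of `config$tf_window` (bp).
#' @param seed_offset added to `config$seed` so several peak sets from one
#'   config are independent.
#' @return list: `peaks` ([marker_peaks()]), `truth` (logical vector: which
#'   elements got a planted peak).
#' @export
simulate_peaks <- function(annotation, config, marker = "H3K4me3",
                           cell_type = "ES", tf_mode = FALSE,
                           tf_window = config$tf_window, seed_offset = 1000L) {
  set.seed(config$seed + seed_offset)
  el <- annotation$elements
  sizes <- annotation$sizes
  foc <- which(el$family == "HERV-H")
  chrom <- character(); pos <- numeric()
  planted <- rep(FALSE, nrow(el))
  if (tf_mode) {
    planted[foc] <- TRUE
    tss <- element_tss(el)[foc]
    u <- stats::runif(length(foc), 0, tf_window)
    p <- ifelse(el$strand[foc] == "-", tss - u, tss + u)
    chrom <- el$chrom[foc]
    pos <- floor(pmin(pmax(p, 0), sizes[el$chrom[foc]]))
  } else if (length(foc)) {
    hit <- foc[stats::runif(length(foc)) < config$assoc_fraction]
    planted[hit] <- TRUE
    if (length(hit)) {
      u <- stats::runif(length(hit), 0, config$assoc_window)
      left <- stats::runif(length(hit)) < 0.5
      p <- ifelse(left, el$start[hit] - u, el$end[hit] + u)
      chrom <- el$chrom[hit]
      pos <- floor(pmin(pmax(p, 0), sizes[el$chrom[hit]]))
    }
  }
  nbg <- if (tf_mode) 0L else config$n_background_peaks
  if (nbg > 0L) {
    bg <- generate_control_loci(sizes, nbg, seed = config$seed + seed_offset + 1L)
    chrom <- c(chrom, bg$chrom); pos <- c(pos, bg$pos)
  }
  list(peaks = marker_peaks(marker, cell_type,
                            data.frame(chrom = chrom, pos = pos), sizes = sizes),
       truth = planted)
}

#' Expression targets for the simulated annotation
#'
#' Two-tier focal expression (`top_fraction` of copies carry `top_share` of
#' the family RNA), a set of expressed genes carrying the non-focal RNA, and
#' optionally gene-embedded background elements transcribed only as part of
#' a spanning gene.
#'
#' @param annotation result of [simulate_annotation()].
#' @param config [sim_config()].
#' @param n_embedded number of background elements embedded in expressed
#'   genes (default 10, capped at the background count).
#' @return list: `element_weight` (named, expected share of element-origin
#'   reads per focal element), `embedded_ids` (background elements inside
#'   expressed genes), `genes` (data.frame of gene intervals with `weight`).
#' @export
sim_expression_targets <- function(annotation, config, n_embedded = 10L) {
  set.seed(config$seed + 2000L)
  el <- annotation$elements
  foc <- which(el$family == "HERV-H")
  w <- stats::setNames(numeric(length(foc)), el$element_id[foc])
  if (length(foc)) {
    n_top <- max(1L, round(config$top_fraction * length(foc)))
    top <- sample(seq_along(foc), n_top)
    jitter <- function(k) { x <- stats::runif(k, 0.5, 1.5); x / sum(x) }
    w[top] <- config$top_share * jitter(n_top)
    if (length(foc) > n_top)
      w[-top] <- (1 - config$top_share) * jitter(length(foc) - n_top)
  }
  bg <- which(el$family != "HERV-H")
  embedded <- integer()
  genes <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(bg) && n_embedded > 0L) {
    embedded <- sample(bg, min(n_embedded, length(bg)))
    genes <- data.frame(chrom = el$chrom[embedded],
                        start = pmax(0, el$start[embedded] - config$gene_extent),
                        end = pmin(unname(annotation$sizes[el$chrom[embedded]]),
                                   el$end[embedded] + config$gene_extent),
                        weight = stats::runif(length(embedded), 0.5, 1.5),
                        stringsAsFactors = FALSE)
    genes$weight <- genes$weight / sum(genes$weight)
  }
  list(element_weight = w / ifelse(sum(w) > 0, sum(w), 1),
       embedded_ids = el$element_id[embedded],
       genes = genes)
}

#' Simulate RNA-seq alignment records
#'
#' Reads are emitted as alignment records (hit structure, not sequence).
#' Element-origin reads are drawn per focal element in proportion to its
#' expression weight; each is unique with probability `unique_fraction`,
#' otherwise a multiread whose hit list adds 1..`sister_max` sister copies of
#' the same family at the same relative offset (mimicking short conserved
#' regions shared across copies).  Gene reads are uniform over the gene
#' interval and always unique, creating unspecific (read-through) coverage
#' over any embedded element.
#'
#' @param annotation result of [simulate_annotation()].
#' @param config [sim_config()].
#' @param targets result of [sim_expression_targets()] (built from the
#'   config when omitted).
#' @param gene_read_fraction share of the read budget drawn from genes
#'   (default `1 - config$focal_rna_fraction` when genes exist, else 0).
#' @return list: `alignments` (`alignments` frame), `truth` (data.frame
#'   `element_id`, `true_reads`, `true_rpkm`), `n_reads` (total emitted),
#'   `targets`.
#' @export
simulate_alignments <- function(annotation, config,
                                targets = sim_expression_targets(annotation, config),
                                gene_read_fraction = NULL) {
  set.seed(config$seed + 3000L)
  el <- annotation$elements
  rl <- config$read_len
  if (is.null(gene_read_fraction))
    gene_read_fraction <- if (nrow(targets$genes) > 0L)
      1 - config$focal_rna_fraction else 0
  n_gene <- round(config$n_reads * gene_read_fraction)
  n_elem <- config$n_reads - n_gene

  w <- targets$element_weight
  ids <- names(w)
  idx <- match(ids, el$element_id)
  counts <- if (n_elem > 0L && length(w) && sum(w) > 0)
    as.integer(stats::rmultinom(1, n_elem, w)) else integer(length(w))

  blocks <- list()
  read_no <- 0L
  for (k in seq_along(ids)) {
    ni <- counts[k]
    if (ni == 0L) next
    i <- idx[k]
    len_i <- el$end[i] - el$start[i]
    frac <- stats::runif(ni)  # relative position of the read in the element
    s <- floor(el$start[i] + frac * max(1, len_i - rl))
    rid <- sprintf("r%07d", read_no + seq_len(ni))
    read_no <- read_no + ni
    blocks[[length(blocks) + 1L]] <-
      data.frame(read_id = rid, chrom = el$chrom[i], start = s, end = s + rl,
                 stringsAsFactors = FALSE)
    sisters_all <- setdiff(which(el$family == el$family[i]), i)
    multi <- which(stats::runif(ni) >= config$unique_fraction)
    if (length(multi) && length(sisters_all)) {
      ns <- sample.int(min(config$sister_max, length(sisters_all)),
                       length(multi), replace = TRUE)
      sis <- unlist(lapply(ns, function(n)
        sisters_all[sample.int(length(sisters_all), n)]))
      rep_r <- rep(multi, ns)
      len_s <- el$end[sis] - el$start[sis]
      ss <- floor(el$start[sis] + frac[rep_r] * pmax(1, len_s - rl))
      blocks[[length(blocks) + 1L]] <-
        data.frame(read_id = rid[rep_r], chrom = el$chrom[sis],
                   start = ss, end = ss + rl, stringsAsFactors = FALSE)
    }
  }
  gene_counts <- integer(nrow(targets$genes))
  if (n_gene > 0L && nrow(targets$genes) > 0L) {
    gene_counts <- as.integer(stats::rmultinom(1, n_gene, targets$genes$weight))
    for (g in seq_len(nrow(targets$genes))) {
      ng <- gene_counts[g]
      if (ng == 0L) next
      s <- floor(stats::runif(ng, targets$genes$start[g],
                              targets$genes$end[g] - rl))
      rid <- sprintf("g%07d", read_no + seq_len(ng))
      read_no <- read_no + ng
      blocks[[length(blocks) + 1L]] <-
        data.frame(read_id = rid, chrom = targets$genes$chrom[g],
                   start = s, end = s + rl, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(blocks)) do.call(rbind, blocks)
          else data.frame(read_id = character(), chrom = character(),
                          start = numeric(), end = numeric())
  aln <- alignments(hits$read_id, hits$chrom, hits$start, hits$end)
  n_total <- length(unique(hits$read_id))
  true_reads <- stats::setNames(numeric(nrow(el)), el$element_id)
  true_reads[ids] <- counts
  truth <- data.frame(element_id = el$element_id,
                      family = el$family,
                      true_reads = unname(true_reads),
                      true_rpkm = 1e6 * unname(true_reads) /
                        (((el$end - el$start) / 1000) * n_total),
                      stringsAsFactors = FALSE)
  list(alignments = aln, truth = truth, n_reads = n_total, targets = targets)
}

#' Simulate reads from a structured provirus transcript
#'
#' Emits uniquely-mapping reads whose midpoints are uniform over the union
#' of the named internal regions of one provirus — emulating a transcript
#' that retains some regions (e.g. 5LTR-gag-pro-3LTR) and has lost others
#' (pol, env).
#'
#' @param elements `provirus_records` with a region map for `element_id`.
#' @param element_id the provirus to transcribe.
#' @param transcript_regions region labels included in the transcript.
#' @param n number of reads.
#' @param read_len read length in bp.
#' @param seed RNG seed.
#' @return `alignments` frame of unique reads.
#' @export
simulate_transcript_reads <- function(elements, element_id,
                                      transcript_regions = c("5LTR", "gag",
                                                             "pro", "3LTR"),
                                      n = 1000L, read_len = 75L, seed = 1L) {
  regions <- attr(elements, "regions")[[element_id]]
  if (is.null(regions))
    stop("simulate_transcript_reads: element has no region map")
  regions <- regions[regions$region %in% transcript_regions, , drop = FALSE]
  if (nrow(regions) == 0L)
    stop("simulate_transcript_reads: no matching regions")
  set.seed(seed)
  w <- regions$end - regions$start
  reg <- sample.int(nrow(regions), n, replace = TRUE, prob = w / sum(w))
  mid <- floor(regions$start[reg] + stats::runif(n) * w[reg])
  chrom <- elements$chrom[match(element_id, elements$element_id)]
  alignments(sprintf("t%06d", seq_len(n)), chrom,
             mid - floor(read_len / 2), mid - floor(read_len / 2) + read_len)
}

#' Simulate differentiation stage series
#'
#' Geometric decay per stage at the configured rates: the focal family and
#' NANOG-like factor decay sharply, OCT4-like somewhat less, SOX2-like is
#' near-flat, and the BRD2-like housekeeping normaliser is flat.
#'
#' @param config [sim_config()].
#' @param noise_sd optional multiplicative log-normal noise (0 = none).
#' @return named list of [stage_series()], one per configured series, each
#'   normalised against the BRD2-like series.
#' @export
simulate_differentiation <- function(config, noise_sd = 0) {
  set.seed(config$seed + 4000L)
  stages <- paste0("N", seq_len(config$n_stages) - 1L)
  brd2 <- config$decay_rates[["BRD2"]]^(seq_len(config$n_stages) - 1L)
  out <- lapply(names(config$decay_rates), function(nm) {
    v <- config$decay_rates[[nm]]^(seq_len(config$n_stages) - 1L)
    if (noise_sd > 0)
      v <- v * exp(stats::rnorm(length(v), 0, noise_sd))
    stage_series(v, normalizer = brd2, stages = stages)
  })
  stats::setNames(out, names(config$decay_rates))
}

#' Write a full synthetic fixture set to a directory
#'
#' Emits chrom.sizes, elements as RepeatMasker-style `.out` and BED, peaks
#' as BED, alignments in the tabular dialect, and truth tables as TSV.
#'
#' @param config [sim_config()].
#' @param outdir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
simulate_to_dir <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(config)
  pk <- simulate_peaks(ann, config)
  sim <- simulate_alignments(ann, config)
  paths <- list(
    sizes = file.path(outdir, "genome.chrom.sizes"),
    elements_out = file.path(outdir, "elements.out"),
    elements_bed = file.path(outdir, "elements.bed"),
    peaks = file.path(outdir, "peaks.bed"),
    alignments = file.path(outdir, "alignments.tsv"),
    truth = file.path(outdir, "truth_expression.tsv"),
    peak_truth = file.path(outdir, "truth_peaks.tsv"))
  write_chrom_sizes(ann$sizes, paths$sizes)
  write_repeatmasker_out(ann$elements, paths$elements_out)
  iv <- genomic_intervals(ann$elements$chrom, ann$elements$start,
                          ann$elements$end, ann$elements$strand)
  iv$name <- ann$elements$element_id
  write_bed(iv, paths$elements_bed)
  pk_df <- do.call(rbind, lapply(names(pk$peaks$peaks), function(chr)
    data.frame(chrom = chr, start = pk$peaks$peaks[[chr]],
               end = pk$peaks$peaks[[chr]] + 1)))
  write_bed(genomic_intervals(pk_df$chrom, pk_df$start, pk_df$end), paths$peaks)
  write_alignments(sim$alignments, paths$alignments)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(element_id = ann$elements$element_id,
                                planted_peak = pk$truth),
                     paths$peak_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
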