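## Proximity association between retro-element loci and ChIP-seq peak sets:
## edge distance, F-beta score against random control loci, log-space Fisher
## exact significance, and window-sweep association profiles.

#' Distance from a provirus to a marker position
#'
#' The distance from a point marker at position `m` to a provirus spanning
#' `[start, end)` is `min(|start - m|, |end - m|)`, clamped to 0 when the
#' marker lies inside the element.  Equivalently `|center - m| - len/2`
#' (clamped at 0), with `center = (start + end)/2`.
#'
#' @param elements `provirus_records` (or any interval data.frame); all rows
#'   must share the chromosome of `position`.
#' @param position marker position(s) in bp; recycled against elements.
#' @param chrom chromosome of the position(s); checked against the elements.
#' @return numeric vector of distances in bp (0 when inside).
#' @export
distance_element_to_marker <- function(elements, position, chrom = NULL) {
  if (!is.null(chrom) && any(elements$chrom != chrom))
    stop("distance_element_to_marker: element and marker on different chromosomes; partition by chromosome first")
  d <- pmin(abs(elements$start - position), abs(elements$end - position))
  inside <- position >= elements$start & position <= elements$end
  d[inside] <- 0
  d
}

# distance from each element to its nearest peak in a sorted position vector;
# binary search via findInterval, O(log N) per element.
nearest_dist_sorted <- function(start, end, peaks) {
  if (length(peaks) == 0L) return(rep(Inf, length(start)))
  d_edge <- function(edge) {
    i <- findInterval(edge, peaks)
    lo <- ifelse(i >= 1L, abs(edge - peaks[pmax(i, 1L)]), Inf)
    hi <- ifelse(i < length(peaks), abs(peaks[pmin(i + 1L, length(peaks))] - edge), Inf)
    pmin(lo, hi)
  }
  d <- pmin(d_edge(start), d_edge(end))
  # any peak inside [start, end] -> distance 0
  n_in <- findInterval(end, peaks) - findInterval(start, peaks)
  inside <- n_in > 0L | (findInterval(start, peaks) >= 1L &
                           peaks[pmax(findInterval(start, peaks), 1L)] == start)
  d[inside] <- 0
  d
}

#' Distance from each element to the nearest marker peak
#'
#' Binary search over the sorted per-chromosome peak positions.  Elements on
#' chromosomes with no peaks get `Inf`.
#'
#' @param elements `provirus_records`.
#' @param peaks a [marker_peaks()] object.
#' @return numeric vector of bp distances, aligned to `elements` rows.
#' @export
nearest_marker_distance <- function(elements, peaks) {
  d <- rep(Inf, nrow(elements))
  for (chr in unique(elements$chrom)) {
    sel <- elements$chrom == chr
    d[sel] <- nearest_dist_sorted(elements$start[sel], elements$end[sel],
                                  peaks$peaks[[chr]])
  }
  d
}

#' Distance from point loci to the nearest marker peak
#'
#' @param chrom,position control locus coordinates.
#' @param peaks a [marker_peaks()] object.
#' @return numeric vector of bp distances (`Inf` when the chromosome has no
#'   peaks).
#' @export
nearest_peak_distance_points <- function(chrom, position, peaks) {
  nearest <- function(pos, p) {
    if (length(p) == 0L) return(rep(Inf, length(pos)))
    i <- findInterval(pos, p)
    lo <- ifelse(i >= 1L, abs(pos - p[pmax(i, 1L)]), Inf)
    hi <- ifelse(i < length(p), abs(p[pmin(i + 1L, length(p))] - pos), Inf)
    pmin(lo, hi)
  }
  d <- rep(Inf, length(position))
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    d[sel] <- nearest(position[sel], peaks$peaks[[chr]])
  }
  d
}

#' Draw random control loci over a genome
#'
#' Positions are uniform over the concatenated genome: chromosomes are chosen
#' with probability proportional to length, positions uniform within the
#' chromosome.  Reproducible for a given seed.
#'
#' @param sizes [chrom_sizes()].
#' @param n number of control loci (default 100000).
#' @param seed integer RNG seed.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
generate_control_loci <- function(sizes, n = 100000L, seed = 1L) {
  if (length(sizes) == 0L) stop("generate_control_loci: empty chrom sizes")
  if (n < 1L) stop("generate_control_loci: n must be >= 1")
  set.seed(seed)
  chrom <- sample(names(sizes), n, replace = TRUE,
                  prob = as.numeric(sizes) / sum(as.numeric(sizes)))
  pos <- floor(stats::runif(n) * unname(sizes[chrom]))
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' F-beta score
#'
#' `F_beta = (1 + beta^2) * P * R / (beta^2 * P + R)`, the beta-weighted
#' harmonic mean of precision P and sensitivity R.  `beta = 0.5` (the
#' default) weights precision more heavily than sensitivity.  Defined as 0
#' when `P = R = 0`.
#'
#' @param precision,sensitivity values in `[0, 1]`.
#' @param beta positive weight.
#' @return F-beta score in `[0, 1]`.
#' @examples
#' f_beta(0.9, 0.5)          # 0.7759...
#' f_beta(1, 1, beta = 2)    # 1
#' @export
f_beta <- function(precision, sensitivity, beta = 0.5) {
  if (any(precision < 0 | precision > 1) || any(sensitivity < 0 | sensitivity > 1))
    stop("f_beta: precision and sensitivity must be in [0, 1]")
  if (any(beta <= 0)) stop("f_beta: beta must be positive")
  num <- (1 + beta^2) * precision * sensitivity
  den <- beta^2 * precision + sensitivity
  ifelse(den > 0, num / den, 0)
}

#' One-sided Fisher exact test in log space
#'
#' Natural-log p-value of the one-sided (enrichment) Fisher exact test on the
#' 2x2 table {element, control} x {within, not-within}: the hypergeometric
#' upper-tail probability of observing at least `x1` within-window elements.
#' Computed in log space so extremely small p-values (< 1e-300) do not
#' underflow.
#'
#' @param x1 elements within the window.
#' @param n1 total elements.
#' @param x0 controls within the window.
#' @param n0 total controls.
#' @return natural-log p-value (<= 0).
#' @export
fisher_log_p <- function(x1, n1, x0, n0) {
  stats::phyper(x1 - 1, m = x1 + x0, n = n1 + n0 - x1 - x0, k = n1,
                lower.tail = FALSE, log.p = TRUE)
}

#' Association between elements and a marker peak set
#'
#' Classifies each element (nearest marker distance <= window) and each
#' control locus (point distance to nearest peak <= window), then scores the
#' association.  Precision and sensitivity are computed from *rates*, not raw
#' counts, so the result does not depend on the size of the control set:
#' `rate_TP = x1/n1` (element within-rate), `rate_FP = x0/n0` (control
#' within-rate), `R = rate_TP`, `P = rate_TP / (rate_TP + rate_FP)`.
#'
#' @param elements `provirus_records`.
#' @param peaks [marker_peaks()].
#' @param controls data.frame `chrom`, `pos` from [generate_control_loci()].
#' @param window_bp association window in bp (default 2000).
#' @param beta F-score beta (default 0.5).
#' @param element_dist,control_dist optional precomputed nearest distances
#'   (used by [association_profile()] to avoid rescanning per window).
#' @return An `association_result` list: `window_bp`, `n_elements`,
#'   `n_elements_within`, `n_controls`, `n_controls_within`, `precision`,
#'   `sensitivity`, `beta`, `f_score`, `log_p`.
#' @export
associate <- function(elements, peaks, controls, window_bp = 2000,
                      beta = 0.5, element_dist = NULL, control_dist = NULL) {
  if (is.null(element_dist)) {
    if (is.null(elements) || nrow(elements) == 0L)
      stop("associate: empty element set")
    element_dist <- nearest_marker_distance(elements, peaks)
  }
  if (is.null(control_dist)) {
    if (is.null(controls) || nrow(controls) == 0L)
      stop("associate: empty control set")
    control_dist <- nearest_peak_distance_points(controls$chrom, controls$pos, peaks)
  }
  n1 <- length(element_dist); n0 <- length(control_dist)
  x1 <- sum(element_dist <= window_bp)
  x0 <- sum(control_dist <= window_bp)
  rate_tp <- x1 / n1
  rate_fp <- x0 / n0
  sens <- rate_tp
  prec <- if (rate_tp + rate_fp > 0) rate_tp / (rate_tp + rate_fp) else 0
  structure(list(window_bp = window_bp,
                 n_elements = n1, n_elements_within = x1,
                 n_controls = n0, n_controls_within = x0,
                 precision = prec, sensitivity = sens, beta = beta,
                 f_score = f_beta(prec, sens, beta),
                 log_p = fisher_log_p(x1, n1, x0, n0)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> w=%d bp: %d/%d elements, %d/%d controls within\n",
              x$window_bp, x$n_elements_within, x$n_elements,
              x$n_controls_within, x$n_controls))
  cat(sprintf("  P=%.4f R=%.4f F_%.2g=%.4f log(p)=%.2f\n",
              x$precision, x$sensitivity, x$beta, x$f_score, x$log_p))
  invisible(x)
}

#' Window-sweep association profile
#'
#' F-beta score as a function of window size over the grid
#' `{step, 2*step, ..., w_max}` (default 0.5 kB steps up to 10 kB).  Nearest
#' distances are computed once and thresholded per window.
#'
#' @inheritParams associate
#' @param w_max largest window (bp).
#' @param step grid step (bp).
#' @param cell_type,marker labels carried on the profile (defaults taken from
#'   `peaks`).
#' @return An `association_profile` list: `cell_type`, `marker`, `windows`,
#'   `f_scores`, plus the per-window `results` list.
#' @export
association_profile <- function(elements, peaks, controls, w_max = 10000,
                                step = 500, beta = 0.5,
                                cell_type = peaks$cell_type,
                                marker = peaks$marker) {
  if (step <= 0) stop("association_profile: step must be positive")
  if (w_max < step) stop("association_profile: w_max must be >= step")
  windows <- seq(step, w_max, by = step)
  ed <- nearest_marker_distance(elements, peaks)
  cd <- nearest_peak_distance_points(controls$chrom, controls$pos, peaks)
  results <- lapply(windows, function(w)
    associate(NULL, NULL, NULL, window_bp = w, beta = beta,
              element_dist = ed, control_dist = cd))
  structure(list(cell_type = cell_type, marker = marker,
                 windows = windows,
                 f_scores = vapply(results, `[[`, 0, "f_score"),
                 results = results),
            class = "association_profile")
}

#' @export
print.association_profile <- function(x, ...) {
  cat(sprintf("<association_profile> %s / %s over %d windows (%d..%d bp), max F=%.3f\n",
              x$marker, x$cell_type, length(x$windows),
              min(x$windows), max(x$windows), max(x$f_scores)))
  invisible(x)
}

#' Write an association result as TSV
#' @param result `association_result`.
#' @param path output path.
#' @export
write_association_tsv <- function(result, path) {
  flat <- unclass(result)
  utils::write.table(data.frame(field = names(flat),
                                value = vapply(flat, function(v) format(v, digits = 12), "")),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
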