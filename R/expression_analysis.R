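## Downstream analyses of per-element expression: provirus-internal coverage
## profiles, top-k expression concentration, differentiation trajectories,
## and transcription-factor proximity/ordering at the proviral 5' LTR.

PROVIRUS_REGIONS <- c("5LTR", "gag", "pro", "pol", "env", "3LTR")

#' Per-region read coverage of a provirus, normalised to the 5' LTR
#'
#' Counts assigned read mass (unique + reassigned multiread mass) falling in
#' each internal region of one provirus and divides by the 5' LTR count.
#'
#' @param hit_mass per-hit mass frame (`attr(quantify(...), "hit_mass")`), or
#'   any `alignments` frame with a `mass` column.
#' @param elements `provirus_records` with a region map for `element_id`.
#' @param element_id which element to profile.
#' @return A `region_coverage` list: `element_id`, `counts` (named by
#'   region), `normalized` (counts / 5LTR count; `NA` and `undefined = TRUE`
#'   when the 5LTR count is 0).
#' @export
region_coverage <- function(hit_mass, elements, element_id) {
  regions <- attr(elements, "regions")[[element_id]]
  if (is.null(regions))
    stop("region_coverage: element ", element_id, " has no region map")
  i <- match(element_id, elements$element_id)
  counts <- stats::setNames(numeric(nrow(regions)), regions$region)
  for (j in seq_len(nrow(regions)))
    counts[j] <- count_reads(hit_mass, elements$chrom[i],
                             regions$start[j], regions$end[j],
                             mode = "all_assigned")
  ltr <- counts[["5LTR"]]
  undefined <- is.na(ltr) || ltr == 0
  structure(list(element_id = element_id, counts = counts,
                 normalized = if (undefined) rep(NA_real_, length(counts))
                              else counts / ltr,
                 undefined = undefined),
            class = "region_coverage")
}

#' Expression concentration of the top-k elements
#'
#' Sorts elements by RPKM (descending, ties broken by `element_id`) and
#' reports which fraction of the summed RPKM the top k account for.
#'
#' @param expressions `element_expression` data.frame.
#' @param k number of top elements.
#' @return list: `top` (element ids), `fraction` (top-k RPKM / total RPKM).
#' @export
top_k_concentration <- function(expressions, k) {
  if (nrow(expressions) == 0L) stop("top_k_concentration: empty expression table")
  if (k > nrow(expressions)) stop("top_k_concentration: k exceeds element count")
  o <- order(-expressions$rpkm, expressions$element_id)
  total <- sum(expressions$rpkm)
  list(top = expressions$element_id[o][seq_len(k)],
       fraction = if (total > 0) sum(expressions$rpkm[o][seq_len(k)]) / total else 0)
}

#' Differentiation stage series
#'
#' Expression of one transcript class across ordered differentiation stages,
#' with a housekeeping normaliser (e.g. BRD2-like: flat across stages).
#'
#' @param values expression per stage.
#' @param normalizer housekeeping expression per stage (strictly positive).
#' @param stages stage labels (default N0..N3, undifferentiated through
#'   pre-glial).
#' @return A `stage_series` list.
#' @export
stage_series <- function(values, normalizer = rep(1, length(values)),
                         stages = paste0("N", seq_along(values) - 1L)) {
  if (length(values) != length(stages) || length(normalizer) != length(values))
    stop("stage_series: values, normalizer and stages must have equal length")
  structure(list(stages = stages, values = as.numeric(values),
                 normalizer = as.numeric(normalizer)),
            class = "stage_series")
}

#' Normalise a stage series by its housekeeping reference
#'
#' Divides each stage value by the normaliser at that stage, then rescales so
#' the first stage equals 1.
#'
#' @param series a [stage_series()].
#' @return numeric vector of normalised values (first element 1).
#' @export
normalize_trajectory <- function(series) {
  if (any(series$normalizer <= 0))
    stop("normalize_trajectory: normalizer must be strictly positive")
  v <- series$values / series$normalizer
  if (v[1] == 0) stop("normalize_trajectory: first-stage value is zero")
  v / v[1]
}

#' Correlation between two stage trajectories
#'
#' With only 3-4 differentiation stages this is descriptive; no p-value is
#' attached.  Constant input under Pearson (or tied-to-constant ranks under
#' Spearman) yields `NA` with `undefined = TRUE` rather than an error.
#'
#' @param x,y numeric vectors (or [stage_series()]) of equal length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list: `rho`, `method`, `undefined`.
#' @export
correlate_trajectories <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (inherits(x, "stage_series")) x <- x$values
  if (inherits(y, "stage_series")) y <- y$values
  if (length(x) != length(y) || length(x) < 3L)
    stop("correlate_trajectories: need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, method = method, undefined = TRUE))
  list(rho = stats::cor(x, y, method = method), method = method,
       undefined = FALSE)
}

#' Transcription-factor proximity to proviral TSSs
#'
#' For each element, the distance from its strand-aware TSS (5' end) to the
#' nearest peak of one TF.  Reports the mean over elements with a peak within
#' `max_bp` (and, for reference, over all elements counting censored
#' distances at `max_bp`), the F-vs-distance curve over the window grid, and
#' the window of maximal F.  Under a uniform-placement model with peaks
#' within `[0, D]` of the TSS, the mean distance converges to `D/2` and the
#' F curve peaks near `D` — the reported `half_window_ratio`
#' (mean / max-F window) is the diagnostic of that relation.
#'
#' @param elements `provirus_records` (strand required for the TSS).
#' @param peaks [marker_peaks()] for one TF.
#' @param controls control loci data.frame (for the F curve).
#' @param bin_bp window grid step for the F curve (default 500).
#' @param max_bp maximum distance considered bound (default 10000).
#' @param subset optional element ids restricting the analysis (e.g. the
#'   top-50 most expressed).
#' @param beta F-score beta.
#' @return A `tf_proximity` list: `tf`, `n_elements`, `n_bound`,
#'   `mean_distance_bp` (bound elements only), `mean_distance_all_bp`,
#'   `max_assoc_window_bp`, `f_curve` (an [association_profile()]),
#'   `half_window_ratio`, `distances`.
#' @export
tf_proximity <- function(elements, peaks, controls = NULL, bin_bp = 500,
                         max_bp = 10000, subset = NULL, beta = 0.5) {
  if (bin_bp <= 0) stop("tf_proximity: bin_bp must be positive")
  if (!is.null(subset)) {
    elements <- elements[elements$element_id %in% subset, , drop = FALSE]
    if (nrow(elements) == 0L) stop("tf_proximity: empty element subset")
  }
  d <- tss_peak_distance(elements, peaks)
  bound <- is.finite(d) & d <= max_bp
  mean_bound <- if (any(bound)) mean(d[bound]) else NA_real_
  f_curve <- NULL; max_w <- NA_real_
  if (!is.null(controls)) {
    # F as a function of distance from the TSS (not the element span):
    # element distances are TSS point distances, thresholded per window
    cd <- nearest_peak_distance_points(controls$chrom, controls$pos, peaks)
    windows <- seq(bin_bp, max_bp, by = bin_bp)
    results <- lapply(windows, function(w)
      associate(NULL, NULL, NULL, window_bp = w, beta = beta,
                element_dist = d, control_dist = cd))
    f_curve <- structure(list(cell_type = peaks$cell_type,
                              marker = peaks$marker, windows = windows,
                              f_scores = vapply(results, `[[`, 0, "f_score"),
                              results = results),
                         class = "association_profile")
    max_w <- f_curve$windows[which.max(f_curve$f_scores)]
  }
  structure(list(tf = peaks$marker,
                 n_elements = nrow(elements), n_bound = sum(bound),
                 mean_distance_bp = mean_bound,
                 mean_distance_all_bp = mean(pmin(d, max_bp)),
                 max_assoc_window_bp = max_w,
                 f_curve = f_curve,
                 half_window_ratio = if (is.na(max_w)) NA_real_
                                     else mean_bound / max_w,
                 distances = d),
            class = "tf_proximity")
}

#' Distance from each element TSS to the nearest peak
#'
#' @param elements `provirus_records`.
#' @param peaks [marker_peaks()].
#' @return numeric vector of |distance| in bp (`Inf` when the chromosome has
#'   no peaks).
#' @export
tss_peak_distance <- function(elements, peaks) {
  tss <- element_tss(elements)
  nearest_peak_distance_points(elements$chrom, tss, peaks)
}

#' Fraction of elements where TFs bind in a given order
#'
#' For each element, takes the nearest-peak TSS distance per TF (in the order
#' the peak sets are supplied) and checks whether the distances are strictly
#' increasing.  Elements with no peak of some TF within `max_bp` are excluded
#' and counted.  Ties violate strict order.
#'
#' @param elements `provirus_records`.
#' @param peak_sets ordered list of [marker_peaks()], one per TF.
#' @param max_bp inclusion radius per TF (default 10000).
#' @return list: `fraction`, `n_included`, `n_excluded`, `order` (TF names).
#' @export
tf_order_fraction <- function(elements, peak_sets, max_bp = 10000) {
  dmat <- vapply(peak_sets, function(p) tss_peak_distance(elements, p),
                 numeric(nrow(elements)))
  dmat <- matrix(dmat, nrow = nrow(elements))
  included <- apply(dmat, 1L, function(r) all(is.finite(r) & r <= max_bp))
  ordered_ok <- apply(dmat, 1L, function(r) all(diff(r) > 0))
  n_inc <- sum(included)
  list(fraction = if (n_inc > 0) sum(ordered_ok & included) / n_inc else NA_real_,
       n_included = n_inc, n_excluded = sum(!included),
       order = vapply(peak_sets, `[[`, "", "marker"))
}

#' Fraction of elements bound within a window of an anchor
#'
#' @param elements `provirus_records`.
#' @param peaks [marker_peaks()].
#' @param window_bp binding window (bp, > 0); e.g. 500 bp for the LTR region
#'   downstream of the TSS.
#' @param anchor `"TSS"` (strand-aware 5' end, also the 5' LTR start) or
#'   `"element"` (whole element span).
#' @return fraction in `[0, 1]`.
#' @export
binding_fraction <- function(elements, peaks, window_bp = 500,
                             anchor = c("TSS", "element")) {
  anchor <- match.arg(anchor)
  if (window_bp <= 0) stop("binding_fraction: window_bp must be positive")
  d <- if (anchor == "TSS") tss_peak_distance(elements, peaks)
       else nearest_marker_distance(elements, peaks)
  mean(is.finite(d) & d <= window_bp)
}
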