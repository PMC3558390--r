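## Repeat-element expression quantification from alignment records:
## unique-read counting, context-based probabilistic reassignment of
## multimapping reads, RPKM, and separation of specific (element-driven)
## from unspecific (read-through) transcription.
##
## Read membership uses hit midpoints throughout: a hit belongs to a region
## iff its midpoint lies inside it.

read_midpoint <- function(aln) floor((aln$start + aln$end) / 2)

# sorted midpoint index per chromosome for O(log n) range counting
midpoint_index <- function(aln) {
  mids <- read_midpoint(aln)
  lapply(split(seq_len(nrow(aln)), aln$chrom), function(i) {
    o <- order(mids[i])
    w <- aln$weight[i][o]
    list(pos = mids[i][o], w = w, cw = cumsum(w))
  })
}

# weighted count of indexed midpoints in [lo, hi) on one chromosome
count_range <- function(index, chrom, lo, hi) {
  ix <- index[[chrom]]
  if (is.null(ix) || length(ix$pos) == 0L || hi <= lo) return(0)
  a <- findInterval(lo - 0.5, ix$pos)
  b <- findInterval(hi - 0.5, ix$pos)
  if (b <= a) 0 else sum(ix$w[(a + 1L):b])
}

# vectorised weighted counts over many [lo, hi) ranges
count_ranges <- function(index, chrom, lo, hi) {
  out <- numeric(length(lo))
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    ix <- index[[chr]]
    if (is.null(ix) || length(ix$pos) == 0L) next
    a <- findInterval(lo[sel] - 0.5, ix$pos)
    b <- findInterval(hi[sel] - 0.5, ix$pos)
    cw <- c(0, ix$cw)
    v <- cw[b + 1L] - cw[a + 1L]
    v[hi[sel] <= lo[sel]] <- 0
    out[sel] <- v
  }
  out
}

#' Count reads mapping to a genomic region
#'
#' A read (hit) is counted when its midpoint lies inside the region.  With
#' `mode = "unique_only"` only uniquely-mapping reads contribute, each with
#' its weight.  With `mode = "all_assigned"` the fractional multiread mass
#' previously assigned by [quantify()] (carried in a `mass` column) is summed
#' as well.
#'
#' @param aln `alignments` data.frame; for `all_assigned` it must carry a
#'   `mass` column (per-hit assigned mass) as produced by [quantify()].
#' @param chrom,start,end the region (0-based half-open).
#' @param mode counting mode.
#' @return weighted read count (real).
#' @export
count_reads <- function(aln, chrom, start, end,
                        mode = c("unique_only", "all_assigned")) {
  mode <- match.arg(mode)
  mids <- read_midpoint(aln)
  in_region <- aln$chrom == chrom & mids >= start & mids < end
  if (mode == "all_assigned") {
    if (is.null(aln$mass))
      stop("count_reads: all_assigned requires a 'mass' column (run quantify first)")
    return(sum(aln$mass[in_region]))
  }
  nh <- table(aln$read_id)
  unique_read <- nh[aln$read_id] == 1L
  sum(aln$weight[in_region & unique_read])
}

#' Build the context region flanking a target interval
#'
#' The context of a target `[start, end)` with flank `n` is
#' `[start - n, start) U [end, end + n)`, clipped to the chromosome and minus
#' any exclusion intervals (e.g. other annotated copies of the same repeat
#' family, which would contaminate the local background estimate).
#'
#' @param chrom,start,end target interval.
#' @param flank_bp flank width per side (bp, > 0).
#' @param sizes [chrom_sizes()] used for clipping.
#' @param exclusions optional data.frame `chrom`,`start`,`end` of intervals to
#'   subtract from the context.
#' @return A `context_region` list: `chrom`, `intervals` (data.frame
#'   `start`,`end`, possibly empty), `length` (total bp).
#' @export
make_context <- function(chrom, start, end, flank_bp, sizes, exclusions = NULL) {
  if (flank_bp <= 0) stop("make_context: flank_bp must be positive")
  chrom_len <- if (chrom %in% names(sizes)) sizes[[chrom]] else Inf
  iv <- data.frame(start = c(max(0, start - flank_bp), min(end, chrom_len)),
                   end = c(max(0, start), min(end + flank_bp, chrom_len)))
  iv <- iv[iv$end > iv$start, , drop = FALSE]
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    ex <- exclusions[exclusions$chrom == chrom, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      pieces <- list()
      for (i in seq_len(nrow(iv))) {
        s <- iv$start[i]; e <- iv$end[i]
        if (ex$end[j] <= s || ex$start[j] >= e) {
          pieces[[length(pieces) + 1L]] <- c(s, e)
        } else {
          if (ex$start[j] > s) pieces[[length(pieces) + 1L]] <- c(s, ex$start[j])
          if (ex$end[j] < e) pieces[[length(pieces) + 1L]] <- c(ex$end[j], e)
        }
      }
      iv <- if (length(pieces))
        as.data.frame(do.call(rbind, pieces)) else data.frame(V1 = numeric(), V2 = numeric())
      names(iv) <- c("start", "end")
    }
  }
  structure(list(chrom = chrom, intervals = iv,
                 length = sum(iv$end - iv$start)),
            class = "context_region")
}

context_count <- function(ctx, index) {
  if (nrow(ctx$intervals) == 0L) return(0)
  sum(vapply(seq_len(nrow(ctx$intervals)), function(i)
    count_range(index, ctx$chrom, ctx$intervals$start[i], ctx$intervals$end[i]), 0))
}

#' Probabilistic reassignment of one multiread
#'
#' A multiread aligning to M candidate regions is split across them in
#' proportion to the uniquely-mapping read counts of each candidate's context
#' region: `P_i = R(c_i) / sum_j R(c_j)`.  When every context count is zero
#' the formula is 0/0 and the read is split uniformly (maximum-entropy
#' completion).  A unique read (M = 1) gets probability 1.
#'
#' @param context_counts numeric vector of unique-read counts `R(c_i)`, one
#'   per candidate hit.
#' @return probability vector of the same length, summing to 1.
#' @examples
#' reassign_multiread(c(30, 10))   # c(0.75, 0.25)
#' reassign_multiread(c(0, 0, 0))  # uniform 1/3
#' @export
reassign_multiread <- function(context_counts) {
  if (length(context_counts) == 0L) stop("reassign_multiread: no hits")
  if (any(context_counts < 0)) stop("reassign_multiread: negative context count")
  tot <- sum(context_counts)
  if (tot == 0) rep(1 / length(context_counts), length(context_counts))
  else context_counts / tot
}

# locate the element (row index) containing each midpoint; elements must be
# non-overlapping.  Returns NA where no element contains the point.
locate_in_elements <- function(chrom, pos, elements) {
  res <- rep(NA_integer_, length(pos))
  for (chr in unique(chrom)) {
    rows <- which(elements$chrom == chr)
    if (length(rows) == 0L) next
    o <- order(elements$start[rows])
    rows <- rows[o]
    sel <- which(chrom == chr)
    i <- findInterval(pos[sel], elements$start[rows])
    ok <- i >= 1L & pos[sel] < elements$end[rows][pmax(i, 1L)]
    res[sel[ok]] <- rows[i[ok]]
  }
  res
}

#' Quantify element expression with multiread reassignment
#'
#' Two-pass procedure. Pass 1 counts uniquely-mapping reads per element and
#' per context region. Pass 2 distributes each multiread's weight across its
#' candidate hits with [reassign_multiread()], using the unique coverage of
#' each hit's own flanking context, and accumulates the fractional mass onto
#' the element containing each hit midpoint.
#'
#' Outputs per element: assigned read mass `n_reads` (N_r), RPKM
#' `E_r = K * N_r / (L_r * N_T)` with `K = 1e6`, `L_r` in kB and `N_T` the
#' total read count (unique + multireads, each read counted once); and the
#' specificity decomposition of [specific_expression()], where the element's
#' context count is rescaled to twice the element length (one element-length
#' equivalent per side) before applying `U(s) = R(c)/2`.
#'
#' @param aln `alignments` data.frame.
#' @param elements `provirus_records`; element intervals must not overlap.
#' @param sizes [chrom_sizes()].
#' @param flank_bp context flank per side (default 10000 bp).
#' @param exclude_family_from_context exclude sister elements of the same
#'   family from each element's context (default TRUE).
#' @return data.frame of class `element_expression` with columns
#'   `element_id`, `family`, `length_kb`, `n_reads`, `rpkm`, `r_s`, `r_c`,
#'   `u_s`, `t_s`, `specificity`; attributes `n_total_reads` and `hit_mass`
#'   (the per-hit assigned-mass frame usable with
#'   `count_reads(mode = "all_assigned")`).
#' @export
quantify <- function(aln, elements, sizes, flank_bp = 10000,
                     exclude_family_from_context = TRUE) {
  nh <- table(aln$read_id)
  n_total <- sum(tapply(aln$weight, aln$read_id, `[`, 1L))
  if (length(nh) == 0L || n_total == 0) stop("quantify: no reads (N_T = 0)")
  is_unique <- nh[aln$read_id] == 1L
  uniq <- aln[is_unique, , drop = FALSE]
  multi <- aln[!is_unique, , drop = FALSE]
  index <- midpoint_index(uniq)

  n <- nrow(elements)
  elen <- elements$end - elements$start
  mass <- numeric(nrow(aln))

  # pass 1: unique reads -> containing element
  umid <- read_midpoint(uniq)
  uloc <- locate_in_elements(uniq$chrom, umid, elements)
  r_s <- vapply(seq_len(n), function(i)
    sum(uniq$weight[which(uloc == i)]), 0)
  mass[which(is_unique)] <- uniq$weight

  # element-level contexts (for the specificity correction)
  contexts <- lapply(seq_len(n), function(i) {
    excl <- NULL
    if (exclude_family_from_context) {
      sis <- elements[elements$family == elements$family[i] &
                        elements$element_id != elements$element_id[i], , drop = FALSE]
      if (nrow(sis)) excl <- sis[, c("chrom", "start", "end")]
    }
    make_context(elements$chrom[i], elements$start[i], elements$end[i],
                 flank_bp, sizes, exclusions = excl)
  })
  r_c_raw <- vapply(contexts, context_count, 0, index = index)
  ctx_len <- vapply(contexts, `[[`, 0, "length")

  # pass 2: multireads, split by unique coverage of each hit's own context.
  # Sister copies of the hit's family are excised from hit contexts (same
  # exclusion rule as element contexts): unique reads inside the hit's own
  # element count, reads inside other family copies do not.
  if (nrow(multi) > 0L) {
    mloc <- locate_in_elements(multi$chrom, read_midpoint(multi), elements)
    lo1 <- pmax(0, multi$start - flank_bp); hi1 <- multi$start
    lo2 <- multi$end; hi2 <- multi$end + flank_bp
    cnt <- count_ranges(index, multi$chrom, lo1, hi1) +
      count_ranges(index, multi$chrom, lo2, hi2)
    if (exclude_family_from_context && any(!is.na(mloc))) {
      umid <- read_midpoint(uniq)
      for (fam in unique(elements$family[mloc[!is.na(mloc)]])) {
        sel <- which(!is.na(mloc) & elements$family[mloc] == fam)
        fam_rows <- elements[elements$family == fam, , drop = FALSE]
        in_fam <- !is.na(locate_in_elements(uniq$chrom, umid, fam_rows))
        idx_out <- midpoint_index(uniq[!in_fam, , drop = FALSE])
        si <- elements$start[mloc[sel]]; ei <- elements$end[mloc[sel]]
        cnt[sel] <-
          count_ranges(idx_out, multi$chrom[sel], lo1[sel], hi1[sel]) +
          count_ranges(idx_out, multi$chrom[sel], lo2[sel], hi2[sel]) +
          count_ranges(index, multi$chrom[sel],
                       pmax(lo1[sel], si), pmin(hi1[sel], ei)) +
          count_ranges(index, multi$chrom[sel],
                       pmax(lo2[sel], si), pmin(hi2[sel], ei))
      }
    }
    grp <- factor(multi$read_id)
    tot <- tapply(cnt, grp, sum)[grp]
    nhit <- tabulate(grp)[as.integer(grp)]
    p <- ifelse(tot > 0, cnt / tot, 1 / nhit)
    m <- multi$weight * p
    mass[which(!is_unique)] <- m
    ok <- !is.na(mloc)
    if (any(ok)) {
      add <- rowsum(m[ok], mloc[ok])
      r_s[as.integer(rownames(add))] <- r_s[as.integer(rownames(add))] + add[, 1]
    }
  }

  # context counts rescaled to two element-lengths so U(s) = r_c/2 estimates
  # the read-through expectation inside the element
  r_c_scaled <- ifelse(ctx_len > 0, r_c_raw * (2 * elen) / ctx_len, 0)
  spec <- specific_expression(r_s, r_c_scaled)

  hit_mass <- aln
  hit_mass$mass <- mass
  out <- data.frame(element_id = elements$element_id,
                    family = elements$family,
                    length_kb = elen / 1000,
                    n_reads = r_s,
                    rpkm = 1e6 * r_s / ((elen / 1000) * n_total),
                    r_s = r_s, r_c = r_c_scaled,
                    u_s = spec$u_s, t_s = spec$t_s,
                    specificity = spec$specificity,
                    stringsAsFactors = FALSE)
  structure(out, n_total_reads = n_total, hit_mass = hit_mass,
            class = c("element_expression", "data.frame"))
}

#' Specific vs unspecific transcription decomposition
#'
#' Models the read count of a region as specific (element-driven) plus
#' unspecific (read-through from a spanning transcript) components:
#' `U(s) = R(c)/2` estimates the unspecific part from the context count, and
#' `T(s) = max(0, R(s) - U(s))` the specific part (clamped at 0; noise can
#' drive the raw estimate negative).  Specificity is `T(s)/R(s)` (0 when
#' `R(s) = 0`).
#'
#' @param r_s read count over the element.
#' @param r_c read count over the context, normalised so that the context
#'   corresponds to twice the element length ([quantify()] does this
#'   rescaling).
#' @return list with vectors `u_s`, `t_s`, `specificity`.
#' @examples
#' specific_expression(100, 40)  # u = 20, t = 80, specificity 0.8
#' @export
specific_expression <- function(r_s, r_c) {
  if (any(r_s < 0) || any(r_c < 0))
    stop("specific_expression: negative read count")
  u <- r_c / 2
  t <- pmax(0, r_s - u)
  list(u_s = u, t_s = t,
       specificity = ifelse(r_s > 0, t / r_s, 0))
}

#' Aggregate expression over repeat families
#'
#' Sums RPKM and the fraction of the total read mass per family label
#' (e.g. HERV-H, all HERVs, LINE, SINE, gene).
#'
#' @param expressions `element_expression` data.frame from [quantify()].
#' @param family_map optional named character vector remapping element
#'   families to aggregate labels (unmapped families keep their own label).
#' @return data.frame with columns `family`, `n_elements`, `rpkm`,
#'   `read_fraction` (share of total reads `N_T`).
#' @export
aggregate_family <- function(expressions, family_map = NULL) {
  fam <- expressions$family
  if (!is.null(family_map)) {
    mapped <- family_map[fam]
    fam <- ifelse(is.na(mapped), fam, mapped)
  }
  n_total <- attr(expressions, "n_total_reads")
  if (is.null(n_total)) n_total <- sum(expressions$n_reads)
  agg <- function(v) tapply(v, fam, sum)
  fams <- sort(unique(fam))
  data.frame(family = fams,
             n_elements = as.integer(table(fam)[fams]),
             rpkm = as.numeric(agg(expressions$rpkm)[fams]),
             read_fraction = as.numeric(agg(expressions$n_reads)[fams]) / n_total,
             stringsAsFactors = FALSE)
}

#' Write element expression as TSV
#' @param expressions `element_expression` data.frame.
#' @param path output path.
#' @export
write_expression_tsv <- function(expressions, path) {
  utils::write.table(as.data.frame(expressions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an element expression TSV
#' @param path input path.
#' @return `element_expression` data.frame.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("element_expression", "data.frame"))
}
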