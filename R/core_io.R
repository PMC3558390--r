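## Domain types and readers/writers for the external formats the pipeline
## touches.  All internal coordinates are 0-based half-open; conversions to
## and from 1-based conventions happen only at parse/write boundaries.

#' Chromosome size table
#'
#' @param lengths named numeric vector mapping chromosome name to length in bp.
#' @return A `chrom_sizes` object (named integer-valued numeric vector).
#' @examples
#' chrom_sizes(c(chr1 = 1e6, chr2 = 5e5))
#' @export
chrom_sizes <- function(lengths) {
  if (length(lengths) == 0L) stop("chrom_sizes: empty size table")
  nm <- names(lengths)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("chrom_sizes: all chromosomes must be named")
  if (anyDuplicated(nm)) stop("chrom_sizes: duplicated chromosome names")
  lengths <- as.numeric(lengths)
  if (anyNA(lengths) || any(lengths <= 0))
    stop("chrom_sizes: all lengths must be positive")
  structure(stats::setNames(lengths, nm), class = "chrom_sizes")
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a tab-separated file with columns chromosome, length.
#' @return A [chrom_sizes()] object.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  chrom_sizes(stats::setNames(df$length, df$chrom))
}

#' Write a chrom.sizes file
#' @param sizes a [chrom_sizes()] object.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(chrom = names(sizes), length = unname(as.numeric(sizes))),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a set of genomic intervals
#'
#' Intervals are 0-based, half-open (`start < end`), validated against a
#' chromosome size table when one is supplied.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open coordinates.
#' @param strand strand per interval: `"+"`, `"-"` or `"*"` (unknown).
#' @param sizes optional [chrom_sizes()] table for bounds validation.
#' @return data.frame of class `genomic_intervals` with columns
#'   `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", sizes = NULL) {
  n <- length(chrom)
  strand <- rep_len(as.character(strand), n)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != n || length(end) != n)
    stop("genomic_intervals: chrom/start/end lengths differ")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop(sprintf("genomic_intervals: invalid interval at position %d (start=%s, end=%s); need 0 <= start < end",
                 bad[1], format(start[bad[1]]), format(end[bad[1]])))
  if (!all(strand %in% c("+", "-", "*")))
    stop("genomic_intervals: strand must be one of '+', '-', '*'")
  if (!is.null(sizes)) {
    unknown <- setdiff(unique(chrom), names(sizes))
    if (length(unknown))
      stop("genomic_intervals: chromosome(s) not in size table: ",
           paste(unknown, collapse = ", "))
    over <- which(end > unname(sizes[chrom]))
    if (length(over))
      stop(sprintf("genomic_intervals: interval %d (%s:%s-%s) extends beyond chromosome end",
                   over[1], chrom[over[1]], format(start[over[1]]), format(end[over[1]])))
  }
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       strand = strand, stringsAsFactors = FALSE),
            class = c("genomic_intervals", "data.frame"))
}

#' Read a BED3+ file
#'
#' Parses BED (tab-separated, 0-based half-open).  Columns beyond the sixth
#' are ignored; column 4 (name) and 6 (strand) are used when present.
#'
#' @param path BED file path.
#' @param sizes optional [chrom_sizes()] for validation.
#' @return `genomic_intervals` data.frame; a `name` column is attached when
#'   the file has one.
#' @export
read_bed <- function(path, sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(genomic_intervals(character(), numeric(), numeric(), sizes = sizes))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("read_bed: malformed line %d in %s (fewer than 3 columns)",
                 which(nf < 3L)[1], path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("read_bed: malformed line %d in %s (non-numeric coordinates)",
                 bad[1], path))
  badint <- which(start >= end)
  if (length(badint))
    stop(sprintf("read_bed: line %d in %s: start >= end", badint[1], path))
  strand <- rep("*", length(lines))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  iv <- genomic_intervals(chrom, start, end, strand, sizes = sizes)
  if (any(nf >= 4L)) {
    nm <- rep(NA_character_, length(lines))
    nm[nf >= 4L] <- vapply(fields[nf >= 4L], `[[`, "", 4L)
    iv$name <- nm
  }
  iv
}

#' Write intervals as BED
#'
#' BED6 when a strand or name is informative, BED3 otherwise.  Round-trips
#' coordinates bit-exactly with [read_bed()].
#'
#' @param intervals a `genomic_intervals` data.frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (!is.null(intervals$name) || any(intervals$strand != "*")) {
    nm <- if (is.null(intervals$name)) rep(".", nrow(intervals)) else intervals$name
    strand <- ifelse(intervals$strand == "*", ".", intervals$strand)
    out <- paste(intervals$chrom, fmt(intervals$start), fmt(intervals$end),
                 nm, 0L, strand, sep = "\t")
  } else {
    out <- paste(intervals$chrom, fmt(intervals$start), fmt(intervals$end), sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Build provirus records
#'
#' A provirus record is one annotated retro-element locus with a family
#' label and an optional internal region map (5LTR/gag/pro/pol/env/3LTR).
#'
#' @param element_id unique id per element.
#' @param family repeat family label (e.g. `"HERV-H"`, `"LINE"`).
#' @param intervals `genomic_intervals` of the element spans.
#' @param regions optional named list: `element_id` -> data.frame with
#'   columns `region`, `start`, `end` (0-based half-open sub-intervals,
#'   non-overlapping, contained in the element).
#' @return data.frame of class `provirus_records` with columns `element_id`,
#'   `family`, `chrom`, `start`, `end`, `strand` and a `regions` attribute.
#' @export
provirus_records <- function(element_id, family, intervals, regions = NULL) {
  if (anyDuplicated(element_id)) stop("provirus_records: element_id not unique")
  n <- nrow(intervals)
  if (length(element_id) != n) stop("provirus_records: id/interval length mismatch")
  df <- data.frame(element_id = as.character(element_id),
                   family = rep_len(as.character(family), n),
                   chrom = intervals$chrom, start = intervals$start,
                   end = intervals$end, strand = intervals$strand,
                   stringsAsFactors = FALSE)
  if (!is.null(regions)) {
    for (id in names(regions)) {
      i <- match(id, df$element_id)
      if (is.na(i)) stop("provirus_records: region map for unknown element ", id)
      r <- regions[[id]]
      r <- r[order(r$start), , drop = FALSE]
      if (any(r$start < df$start[i]) || any(r$end > df$end[i]))
        stop("provirus_records: region outside element for ", id)
      if (nrow(r) > 1L && any(r$start[-1] < r$end[-nrow(r)]))
        stop("provirus_records: overlapping regions for ", id)
      regions[[id]] <- r
    }
  }
  structure(df, regions = regions, class = c("provirus_records", "data.frame"))
}

#' Element centers and transcription start sites
#'
#' The center is `(start + end) / 2`.  The TSS is the strand-aware 5' end:
#' `start` on the + strand, `end` on the - strand (unknown strand falls back
#' to `start`).
#'
#' @param elements a `provirus_records` (or any interval) data.frame.
#' @return numeric vector.
#' @export
element_center <- function(elements) (elements$start + elements$end) / 2

#' @rdname element_center
#' @export
element_tss <- function(elements) {
  ifelse(elements$strand == "-", elements$end, elements$start)
}

#' Read a RepeatMasker .out annotation file
#'
#' Standard RepeatMasker layout: three header lines, then whitespace-separated
#' columns (score, divergence, deletion, insertion, query, begin, end, left,
#' strand C/+, repeat name, class/family, ...).  1-based inclusive begin/end
#' coordinates are converted to 0-based half-open; strand `"C"` maps to `"-"`.
#'
#' @param path RepeatMasker `.out` file.
#' @param sizes [chrom_sizes()] for validation.
#' @param family_filter optional prefix; keeps rows whose repeat name starts
#'   with this string.
#' @return `provirus_records`; the repeat name column becomes the family
#'   label.  Unparseable rows are skipped with one summarising warning; a file
#'   with no usable rows is an error.
#' @export
read_repeatmasker_out <- function(path, sizes, family_filter = NULL) {
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character()
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("read_repeatmasker_out: no annotation rows in ", path)
  parsed <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    if (length(f) < 11L) return(NULL)
    begin <- suppressWarnings(as.numeric(f[6]))
    end <- suppressWarnings(as.numeric(f[7]))
    if (is.na(begin) || is.na(end) || begin < 1 || end < begin) return(NULL)
    if (!f[9] %in% c("+", "C")) return(NULL)
    list(chrom = f[5], begin = begin, end = end,
         strand = if (f[9] == "C") "-" else "+", name = f[10])
  })
  n_skipped <- sum(vapply(parsed, is.null, TRUE))
  parsed <- parsed[!vapply(parsed, is.null, TRUE)]
  if (n_skipped > 0L)
    warning(sprintf("read_repeatmasker_out: skipped %d unparseable row(s)", n_skipped))
  if (length(parsed) == 0L)
    stop("read_repeatmasker_out: all rows unparseable in ", path)
  chrom <- vapply(parsed, `[[`, "", "chrom")
  name <- vapply(parsed, `[[`, "", "name")
  begin <- vapply(parsed, `[[`, 0, "begin")
  end <- vapply(parsed, `[[`, 0, "end")
  strand <- vapply(parsed, `[[`, "", "strand")
  if (!is.null(family_filter)) {
    keep <- startsWith(name, family_filter)
    if (!any(keep))
      stop("read_repeatmasker_out: no rows match family filter ", family_filter)
    chrom <- chrom[keep]; name <- name[keep]
    begin <- begin[keep]; end <- end[keep]; strand <- strand[keep]
  }
  iv <- genomic_intervals(chrom, begin - 1, end, strand, sizes = sizes)
  provirus_records(sprintf("%s_%s_%d", name, chrom, as.integer(begin - 1)),
                   name, iv)
}

#' Write provirus records in RepeatMasker .out layout
#'
#' Inverse of [read_repeatmasker_out()]: 0-based half-open coordinates become
#' 1-based inclusive; `-` strand becomes `"C"`.
#'
#' @param elements `provirus_records`.
#' @param path output path.
#' @export
write_repeatmasker_out <- function(elements, path) {
  hdr <- c("   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
           "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
           "")
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  rows <- sprintf("%5d %5.1f %4.1f %4.1f  %s %10s %10s (0) %s %-14s %s 1 100 (0) %d",
                  1000L, 10.0, 0.0, 0.0, elements$chrom,
                  fmt(elements$start + 1), fmt(elements$end),
                  ifelse(elements$strand == "-", "C", "+"),
                  elements$family, "LTR/ERV1", seq_len(nrow(elements)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Construct a marker peak set
#'
#' A ChIP-seq factor or chromatin mark in one cell type, reduced to single
#' peak positions per chromosome (sorted ascending).
#'
#' @param marker factor/mark name (e.g. `"H3K4me3"`, `"NANOG"`).
#' @param cell_type cell type label.
#' @param positions named list: chromosome -> numeric vector of positions, or
#'   a data.frame with columns `chrom`, `pos`.
#' @param sizes optional [chrom_sizes()] for validation.
#' @return A `marker_peaks` object (list with `marker`, `cell_type`, `peaks`).
#' @export
marker_peaks <- function(marker, cell_type, positions, sizes = NULL) {
  if (is.data.frame(positions))
    positions <- split(positions$pos, positions$chrom)
  positions <- lapply(positions, function(p) sort(as.numeric(p)))
  if (!is.null(sizes)) {
    for (chr in names(positions)) {
      if (!chr %in% names(sizes))
        stop("marker_peaks: chromosome not in size table: ", chr)
      p <- positions[[chr]]
      if (length(p) && (min(p) < 0 || max(p) > sizes[[chr]]))
        stop("marker_peaks: peak position outside chromosome ", chr)
    }
  }
  structure(list(marker = marker, cell_type = cell_type, peaks = positions),
            class = "marker_peaks")
}

#' @export
print.marker_peaks <- function(x, ...) {
  cat(sprintf("<marker_peaks> %s in %s: %d peaks on %d chromosome(s)\n",
              x$marker, x$cell_type, sum(lengths(x$peaks)), length(x$peaks)))
  invisible(x)
}

#' Read ChIP-seq peaks (BED or narrowPeak) as point positions
#'
#' Each peak interval is reduced to a single position.  For ENCODE narrowPeak
#' input, column 10 is the summit offset from the interval start (-1 when
#' unknown).  With `mode = "summit"` the summit is used when available,
#' falling back to the interval midpoint; `mode = "midpoint"` always uses the
#' midpoint (integer floor).
#'
#' @param path BED3+/narrowPeak file.
#' @param mode `"summit"` or `"midpoint"`.
#' @param marker,cell_type labels stored on the result.
#' @param sizes optional [chrom_sizes()].
#' @return A [marker_peaks()] object.
#' @export
read_peaks <- function(path, mode = c("summit", "midpoint"),
                       marker = "marker", cell_type = "cell", sizes = NULL) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("read_peaks: malformed line %d in %s", which(nf < 3L)[1], path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end   <- as.numeric(vapply(fields, `[[`, "", 3L))
  if (anyNA(start) || anyNA(end) || any(start >= end))
    stop("read_peaks: invalid coordinates in ", path)
  mid <- floor((start + end) / 2)
  pos <- mid
  if (mode == "summit") {
    has_offset <- nf >= 10L
    offset <- rep(-1, length(lines))
    offset[has_offset] <- suppressWarnings(
      as.numeric(vapply(fields[has_offset], `[[`, "", 10L)))
    offset[is.na(offset)] <- -1
    use <- offset >= 0
    pos[use] <- start[use] + offset[use]
  }
  marker_peaks(marker, cell_type, data.frame(chrom = chrom, pos = pos),
               sizes = sizes)
}

#' Read alignment records
#'
#' Accepts either plain-text SAM (multiple hits of one read grouped under the
#' same QNAME across primary and secondary records) or this package's tabular
#' alignment dialect: a header line `#read_id chrom start end` followed by one
#' tab-separated hit per line, 0-based half-open.  Hits sharing a `read_id`
#' form one alignment record; a read is *unique* iff it has exactly one hit.
#' Unmapped SAM records are dropped and counted.
#'
#' @param path SAM or tabular alignments file (format auto-detected: SAM when
#'   a line has >= 11 fields and an integer FLAG column, or an `@` header).
#' @return data.frame of class `alignments` with columns `read_id`, `chrom`,
#'   `start`, `end`, `weight` (one row per hit) and attributes `n_reads`,
#'   `n_dropped`.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  is_sam <- any(startsWith(lines, "@")) ||
    (length(lines) > 0L && {
      f1 <- strsplit(lines[!startsWith(lines, "#")][1], "\t", fixed = TRUE)[[1]]
      length(f1) >= 11L && !is.na(suppressWarnings(as.integer(f1[2])))
    })
  if (is_sam) parse_sam_lines(lines) else parse_tabular_alignments(lines)
}

parse_tabular_alignments <- function(lines) {
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(alignments_frame(character(), character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("read_alignments: tabular line with fewer than 4 fields")
  alignments_frame(vapply(fields, `[[`, "", 1L),
                   vapply(fields, `[[`, "", 2L),
                   as.numeric(vapply(fields, `[[`, "", 3L)),
                   as.numeric(vapply(fields, `[[`, "", 4L)))
}

# reference-consuming CIGAR ops: M, D, N, =, X
cigar_ref_width <- function(cigar, seq_len_fallback) {
  w <- vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (cg == "*") return(seq_len_fallback[i])
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.numeric(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 0)
  w[w == 0] <- seq_len_fallback[w == 0]
  w
}

parse_sam_lines <- function(lines) {
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L)
    return(alignments_frame(character(), character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) stop("read_alignments: truncated SAM record")
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.numeric(vapply(fields, `[[`, "", 4L))
  cigar <- vapply(fields, `[[`, "", 6L)
  seq <- vapply(fields, `[[`, "", 10L)
  unmapped <- bitwAnd(flag, 4L) != 0L | rname == "*"
  n_dropped <- sum(unmapped)
  if (n_dropped > 0L)
    message(sprintf("read_alignments: dropped %d unmapped record(s)", n_dropped))
  keep <- !unmapped
  qname <- qname[keep]; rname <- rname[keep]; pos <- pos[keep]
  width <- cigar_ref_width(cigar[keep],
                           ifelse(seq[keep] == "*", 1, nchar(seq[keep])))
  # SAM POS is 1-based; grouping relies on shared QNAME being contiguous or not;
  # aggregation by read_id handles either, so no name-sort requirement here.
  alignments_frame(qname, rname, pos - 1, pos - 1 + width, n_dropped = n_dropped)
}

alignments_frame <- function(read_id, chrom, start, end, weight = 1,
                             n_dropped = 0L) {
  df <- data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
                   weight = rep_len(as.numeric(weight), length(read_id)),
                   stringsAsFactors = FALSE)
  structure(df,
            n_reads = length(unique(read_id)),
            n_dropped = n_dropped,
            class = c("alignments", "data.frame"))
}

#' Construct alignment records from hit vectors
#'
#' @param read_id read identifier per hit (a read with several rows is a
#'   multiread).
#' @param chrom,start,end hit coordinates (0-based half-open).
#' @param weight per-read weight (default 1); all hits of one read share it.
#' @return `alignments` data.frame.
#' @export
alignments <- function(read_id, chrom, start, end, weight = 1) {
  if (length(read_id) == 0L)
    return(alignments_frame(character(), character(), numeric(), numeric()))
  if (any(end <= start)) stop("alignments: hit with end <= start")
  alignments_frame(as.character(read_id), as.character(chrom),
                   as.numeric(start), as.numeric(end), weight)
}

#' Write alignments in the tabular dialect
#' @param aln `alignments` data.frame.
#' @param path output path.
#' @export
write_alignments <- function(aln, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(c("#read_id\tchrom\tstart\tend",
               paste(aln$read_id, aln$chrom, fmt(aln$start), fmt(aln$end),
                     sep = "\t")), path)
  invisible(path)
}

#' Number of hits per read
#' @param aln `alignments` data.frame.
#' @return named integer vector: read_id -> hit count.
#' @export
hits_per_read <- function(aln) {
  tab <- table(aln$read_id)
  stats::setNames(as.integer(tab), names(tab))
}
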