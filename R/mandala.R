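## Chromosome projection mandalas: one polar plot per chromosome, each
## provirus a dot.  Angle encodes linear chromosomal position; radius encodes
## (log-scaled) distance to the nearest marker, perimeter = distance 0.

#' Polar coordinates of a mandala dot
#'
#' Angle is `2*pi * position / chrom_len`.  Radius is
#' `1 - log(1 + d) / log(1 + d_max)`, clamped to `[0, 1]`: distance 0 sits on
#' the perimeter (radius 1), distances >= `d_max` (default 1 Mb) at the
#' center (radius 0).
#'
#' @param position genomic position(s) in bp, `0 <= position <= chrom_len`.
#' @param chrom_len chromosome length in bp (> 0).
#' @param distance distance(s) to the nearest marker in bp.
#' @param d_max distance mapped to the center (default 1e6).
#' @return list with vectors `angle` (radians, in `[0, 2*pi)`) and `radius`
#'   (in `[0, 1]`).
#' @export
mandala_coords <- function(position, chrom_len, distance, d_max = 1e6) {
  if (chrom_len <= 0) stop("mandala_coords: chrom_len must be positive")
  if (d_max <= 0) stop("mandala_coords: d_max must be positive")
  if (any(position < 0 | position > chrom_len))
    stop("mandala_coords: position outside chromosome")
  angle <- 2 * pi * position / chrom_len
  angle[angle >= 2 * pi] <- 0
  radius <- 1 - log1p(pmin(distance, d_max)) / log1p(d_max)
  list(angle = angle, radius = pmin(pmax(radius, 0), 1))
}

#' Build mandala dots for one chromosome
#'
#' @param elements `provirus_records` on one chromosome.
#' @param peaks [marker_peaks()].
#' @param chrom_len chromosome length (bp).
#' @param window_bp within/beyond colour threshold (default 2000).
#' @param d_max radial scale limit (default 1 Mb).
#' @param expression optional `element_expression` table; when present, dot
#'   area is scaled to RPKM (size = sqrt of relative expression).
#' @param ltr_window_bp peaks within this window of the TSS get the green
#'   LTR ring mark (default 500; set NULL to disable).
#' @return data.frame of class `mandala_dots`: `element_id`, `angle`,
#'   `radius`, `within` (logical), `size`, `ring_mark`.
#' @export
mandala_dots <- function(elements, peaks, chrom_len, window_bp = 2000,
                         d_max = 1e6, expression = NULL, ltr_window_bp = 500) {
  if (length(unique(elements$chrom)) > 1L)
    stop("mandala_dots: elements span multiple chromosomes")
  d <- nearest_marker_distance(elements, peaks)
  co <- mandala_coords(element_center(elements), chrom_len, d, d_max)
  size <- rep(1, nrow(elements))
  if (!is.null(expression)) {
    rpkm <- expression$rpkm[match(elements$element_id, expression$element_id)]
    rpkm[is.na(rpkm)] <- 0
    size <- if (max(rpkm) > 0) sqrt(rpkm / max(rpkm)) else size
  }
  ring <- rep(FALSE, nrow(elements))
  if (!is.null(ltr_window_bp)) {
    dtss <- tss_peak_distance(elements, peaks)
    ring <- is.finite(dtss) & dtss <= ltr_window_bp
  }
  structure(data.frame(element_id = elements$element_id,
                       angle = co$angle, radius = co$radius,
                       within = d <= window_bp, size = size,
                       ring_mark = ring, stringsAsFactors = FALSE),
            class = c("mandala_dots", "data.frame"))
}

#' Render a chromosome projection mandala
#'
#' Polar scatter: blue dots are elements within the window of the nearest
#' marker, red dots beyond; optional green ring for dots with a peak in the
#' 5' LTR region; the F score is written under the plot.  SVG output is
#' written directly (deterministic, parseable XML); PNG output uses base
#' graphics.
#'
#' @param dots `mandala_dots` data.frame.
#' @param chrom chromosome label for the title.
#' @param f_score optional association F score for the caption.
#' @param out output file path ending in `.svg` or `.png`.
#' @param size_px canvas size in pixels (default 480).
#' @param max_dot_px maximum dot radius in pixels (default 6).
#' @return `out`, invisibly.
#' @export
render_mandala <- function(dots, chrom, f_score = NULL, out,
                           size_px = 480, max_dot_px = 6) {
  if (nrow(dots) == 0L)
    warning("render_mandala: empty dot list; rendering empty plot")
  caption <- if (is.null(f_score)) chrom
             else sprintf("%s  F = %.3f", chrom, f_score)
  ext <- tolower(tools::file_ext(out))
  if (ext == "svg") render_mandala_svg(dots, caption, out, size_px, max_dot_px)
  else if (ext == "png") render_mandala_png(dots, caption, out, size_px, max_dot_px)
  else stop("render_mandala: unsupported output format: ", ext)
  invisible(out)
}

# dot center in canvas pixels: angle 0 points up, clockwise, like a clock face
mandala_xy <- function(dots, size_px) {
  cx <- size_px / 2
  r_px <- dots$radius * (size_px / 2 - 20)
  list(x = cx + r_px * sin(dots$angle),
       y = cx - r_px * cos(dots$angle))
}

render_mandala_svg <- function(dots, caption, out, size_px, max_dot_px) {
  xy <- mandala_xy(dots, size_px)
  cx <- size_px / 2
  fmt <- function(v) formatC(v, format = "f", digits = 3)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            size_px, size_px + 30L, size_px, size_px + 30L),
    sprintf('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#888" stroke-width="1"/>',
            fmt(cx), fmt(cx), fmt(size_px / 2 - 20)))
  if (nrow(dots) > 0L) {
    ring <- which(dots$ring_mark)
    lines <- c(lines, sprintf(
      '<circle class="ring" cx="%s" cy="%s" r="%s" fill="none" stroke="green" stroke-width="1.5"/>',
      fmt(xy$x[ring]), fmt(xy$y[ring]), fmt(pmax(dots$size[ring], 0.2) * max_dot_px + 2)))
    lines <- c(lines, sprintf(
      '<circle class="dot" id="%s" cx="%s" cy="%s" r="%s" fill="%s"/>',
      dots$element_id, fmt(xy$x), fmt(xy$y),
      fmt(pmax(dots$size, 0.2) * max_dot_px),
      ifelse(dots$within, "blue", "red")))
  }
  lines <- c(lines,
             sprintf('<text x="%s" y="%d" text-anchor="middle" font-size="14">%s</text>',
                     fmt(cx), size_px + 20L, caption),
             "</svg>")
  writeLines(lines, out)
}

render_mandala_png <- function(dots, caption, out, size_px, max_dot_px) {
  grDevices::png(out, width = size_px, height = size_px + 30L)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, size_px), ylim = c(size_px + 30, 0), asp = 1)
  theta <- seq(0, 2 * pi, length.out = 200)
  cx <- size_px / 2
  graphics::lines(cx + (cx - 20) * sin(theta), cx - (cx - 20) * cos(theta),
                  col = "grey50")
  if (nrow(dots) > 0L) {
    xy <- mandala_xy(dots, size_px)
    graphics::symbols(xy$x, xy$y,
                      circles = pmax(dots$size, 0.2) * max_dot_px,
                      inches = FALSE, add = TRUE,
                      bg = ifelse(dots$within, "blue", "red"),
                      fg = ifelse(dots$ring_mark, "green", NA))
  }
  graphics::text(cx, size_px + 20, caption)
}
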