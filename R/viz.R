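# Deterministic SVG rendering of homologous-gene dotplots and dual-scheme
# karyogram paintings. Output is a pure function of (data, scheme, canvas):
# fixed number formatting and stable ordering make the SVG byte-stable.

#' Colour scheme for chromosome labels and hit ranks
#'
#' Seven proto-chromosome colours (A1-A7), twelve reference colours
#' (Os1-Os12) derived from the proto palette, and a best/second/other hit
#' palette. Shipped as JSON under `extdata`; exact hues approximate the
#' conventional grass karyotype palette and are configuration, not results.
#' @param path optional JSON file overriding the bundled scheme
#' @return list with `labels` (named colours) and `ranks`
#' @export
color_scheme <- function(path = NULL) {
  path <- path %||% system.file("extdata", "color_scheme.json",
                                package = "karyofuse", mustWork = TRUE)
  sc <- jsonlite::fromJSON(path)
  list(labels = unlist(sc$labels), ranks = unlist(sc$ranks))
}

label_color <- function(label, scheme) {
  col <- scheme$labels[label]
  ifelse(is.na(col), "#999999", col)
}

svg_header <- function(width, height) {
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                 'height="%d" viewBox="0 0 %d %d">'),
          width, height, width, height)
}

fmt <- function(x) formatC(x, format = "f", digits = 2)

chrom_layout <- function(genome, span_px) {
  ids <- names(genome$chromosomes)
  lens <- vapply(genome$chromosomes, function(ch) {
    if (n_loci(ch) == 0L) return(1)
    max(ch$loci$end_bp)
  }, numeric(1))
  total <- sum(lens)
  offs <- cumsum(c(0, head(lens, -1)))
  data.frame(chrom_id = ids, len = lens, off = offs,
             px0 = offs / total * span_px,
             px1 = (offs + lens) / total * span_px,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Render a homologous-gene dotplot as SVG
#'
#' Chromosomes of the two genomes tile the horizontal and vertical axes
#' (base-pair proportional) with boundary lines; each hit is a point coloured
#' by rank class (best / second / other) or, when `color_by = "layer"`, by
#' the hit's homology layer. Output is deterministic for identical input.
#'
#' @param hits data.frame with query_id, subject_id and (for rank colouring)
#'   `rank`
#' @param genome_x,genome_y genomes providing gene placements (query on x)
#' @param path output SVG file
#' @param scheme a [color_scheme()]
#' @param color_by `"rank"` or `"layer"`
#' @param size canvas size in pixels
#' @return the output path, invisibly
#' @export
render_dotplot <- function(hits, genome_x, genome_y, path,
                           scheme = color_scheme(),
                           color_by = c("rank", "layer"), size = 800) {
  color_by <- match.arg(color_by)
  margin <- 40
  span <- size - 2 * margin
  lx <- chrom_layout(genome_x, span)
  ly <- chrom_layout(genome_y, span)
  px <- position_table(genome_x)
  py <- position_table(genome_y)
  out <- c(svg_header(size, size),
           sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="white" stroke="black"/>',
                   margin, margin, span, span))
  for (i in seq_len(nrow(lx)))
    out <- c(out,
      sprintf('<line x1="%s" y1="%d" x2="%s" y2="%d" stroke="#cccccc"/>',
              fmt(margin + lx$px1[i]), margin, fmt(margin + lx$px1[i]),
              margin + span),
      sprintf('<text x="%s" y="%s" font-size="10" text-anchor="middle">%s</text>',
              fmt(margin + (lx$px0[i] + lx$px1[i]) / 2), fmt(margin - 6),
              lx$chrom_id[i]))
  for (i in seq_len(nrow(ly)))
    out <- c(out,
      sprintf('<line x1="%d" y1="%s" x2="%d" y2="%s" stroke="#cccccc"/>',
              margin, fmt(margin + ly$px1[i]), margin + span,
              fmt(margin + ly$px1[i])),
      sprintf('<text x="%s" y="%s" font-size="10" text-anchor="end">%s</text>',
              fmt(margin - 4), fmt(margin + (ly$px0[i] + ly$px1[i]) / 2),
              ly$chrom_id[i]))
  if (nrow(hits)) {
    qi <- match(hits$query_id, px$gene_id)
    si <- match(hits$subject_id, py$gene_id)
    if (anyNA(qi) || anyNA(si))
      stop("mapping error: hit genes missing from genome placements")
    offx <- setNames(lx$off, lx$chrom_id)
    offy <- setNames(ly$off, ly$chrom_id)
    totx <- sum(lx$len); toty <- sum(ly$len)
    xx <- margin + (offx[px$chrom_id[qi]] + px$mid_bp[qi]) / totx * span
    yy <- margin + (offy[py$chrom_id[si]] + py$mid_bp[si]) / toty * span
    col <- if (color_by == "rank") {
      rk <- hits$rank %||% rep(3L, nrow(hits))
      ifelse(rk == 1, scheme$ranks[["best"]],
             ifelse(rk == 2, scheme$ranks[["second"]],
                    scheme$ranks[["other"]]))
    } else {
      ifelse(hits$layer %in% c("ortholog", "self"), scheme$ranks[["best"]],
             ifelse(hits$layer == "outparalog", scheme$ranks[["second"]],
                    scheme$ranks[["other"]]))
    }
    ord <- order(xx, yy, col)
    out <- c(out, sprintf('<circle cx="%s" cy="%s" r="1.2" fill="%s"/>',
                          fmt(xx[ord]), fmt(yy[ord]), col[ord]))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

#' Render a dual-scheme karyogram painting as SVG
#'
#' Each chromosome is a vertical bar split into a left half (ancestral
#' seven-chromosome scheme) and a right half (twelve-chromosome reference
#' scheme), with paint segments coloured by their reference label.
#'
#' @param karyogram_pair list of two `karyogram`s covering the same
#'   chromosomes: first in the ancestral scheme, second in the reference
#'   scheme
#' @param path output SVG file
#' @param scheme a [color_scheme()]
#' @param width,height canvas size in pixels
#' @return the output path, invisibly
#' @export
render_karyogram <- function(karyogram_pair, path, scheme = color_scheme(),
                             width = 800, height = 500) {
  kg_l <- karyogram_pair[[1]]
  kg_r <- karyogram_pair[[2]]
  ids <- names(kg_r$paints)
  if (!setequal(ids, names(kg_l$paints)))
    stop("configuration error: the two karyograms cover different chromosomes")
  check_labels <- function(kg) {
    labs <- unique(unlist(lapply(kg$paints, function(p) p$ref_label)))
    missing <- setdiff(labs, names(scheme$labels))
    if (length(missing))
      stop("configuration error: colour scheme missing labels: ",
           paste(missing, collapse = ", "))
  }
  check_labels(kg_l); check_labels(kg_r)
  margin <- 40
  n <- length(ids)
  slot <- (width - 2 * margin) / max(n, 1)
  barw <- slot * 0.5
  maxbp <- max(1, unlist(lapply(c(kg_l$paints, kg_r$paints),
                                function(p) p$end_bp)))
  yscale <- (height - 2 * margin) / maxbp
  out <- svg_header(width, height)
  for (i in seq_along(ids)) {
    cid <- ids[i]
    x0 <- margin + (i - 1) * slot + (slot - barw) / 2
    draw_half <- function(segs, xoff, w) {
      unlist(lapply(seq_len(nrow(segs)), function(j) {
        y <- margin + segs$start_bp[j] * yscale
        h <- (segs$end_bp[j] - segs$start_bp[j] + 1) * yscale
        sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="black" stroke-width="0.3"/>',
                fmt(x0 + xoff), fmt(y), fmt(w), fmt(h),
                label_color(segs$ref_label[j], scheme))
      }))
    }
    out <- c(out,
             draw_half(kg_l$paints[[cid]], 0, barw / 2),
             draw_half(kg_r$paints[[cid]], barw / 2, barw / 2),
             sprintf('<text x="%s" y="%s" font-size="11" text-anchor="middle">%s</text>',
                     fmt(x0 + barw / 2), fmt(height - margin / 2), cid))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}
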