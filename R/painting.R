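# Ancestral-origin painting: converting primary collinear blocks into an
# ordered segment paint of each extant chromosome, in either reference scheme
# (twelve rice-like reference chromosomes or seven proto-chromosomes).

#' Paint one chromosome from collinear blocks
#'
#' Paints at anchor resolution: every gene claimed by an anchor of a
#' significant block votes for that block's reference chromosome, weighted by
#' the anchor match score (so an orthologous anchor outweighs a paralogous
#' one covering the same gene; ties break by block score, then lexicographic
#' reference label). Gene-level claims are collapsed into maximal same-label
#' runs; runs supported by fewer than `min_segment_anchors` anchors are
#' absorbed into their flanks when both neighbours carry one label and
#' dropped otherwise. This per-gene resolution is what keeps a chain that
#' drifted from orthologous into paralogous territory from claiming a whole
#' region under the wrong label.
#'
#' @param blocks a `collinear_blocks` data.frame (query genome on the A side,
#'   reference on the B side) that already passed the significance filter
#' @param chrom extant chromosome id (matched against `chrom_a`)
#' @param min_segment_anchors minimum supporting anchors per reported
#'   segment (default 5)
#' @return data.frame of `PaintSegment`s: (chrom_id, start_bp, end_bp,
#'   ref_label, n_anchors, orientation), ordered and non-overlapping
#' @export
paint_chromosome <- function(blocks, chrom, min_segment_anchors = 5) {
  empty <- data.frame(chrom_id = character(), start_bp = numeric(),
                      end_bp = numeric(), ref_label = character(),
                      n_anchors = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  b <- blocks[blocks$chrom_a == chrom, , drop = FALSE]
  if (nrow(b) == 0L) return(empty)
  votes <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    a <- b$anchors[[i]]
    data.frame(ia = a$ia, sa = a$sa, ea = a$ea, w = a$w,
               score = b$score[i], ref_label = b$chrom_b[i],
               orientation = b$orientation[i], stringsAsFactors = FALSE)
  }))
  votes <- votes[order(votes$ia, -votes$w, -votes$score, votes$ref_label), ,
                 drop = FALSE]
  votes <- votes[!duplicated(votes$ia), , drop = FALSE]  # best claim per gene
  votes <- votes[order(votes$ia), , drop = FALSE]
  r <- rle(votes$ref_label)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  segs <- data.frame(chrom_id = chrom,
                     start_bp = votes$sa[starts], end_bp = votes$ea[ends],
                     ref_label = r$values, n_anchors = r$lengths,
                     orientation = votes$orientation[starts],
                     stringsAsFactors = FALSE)
  # absorb or drop weakly supported fragments; a weak run whose label also
  # has a well-supported segment on this chromosome is kept — it is the thin
  # flank of a nested insertion near a segment boundary, not a noise island
  repeat {
    strong <- unique(segs$ref_label[segs$n_anchors >= min_segment_anchors])
    weak <- which(segs$n_anchors < min_segment_anchors &
                  !(segs$ref_label %in% strong))
    if (length(weak) == 0L) break
    i <- weak[1L]
    left <- if (i > 1L) segs$ref_label[i - 1L] else NA
    right <- if (i < nrow(segs)) segs$ref_label[i + 1L] else NA
    if (!is.na(left) && !is.na(right) && left == right) {
      segs$end_bp[i - 1L] <- segs$end_bp[i]
      segs <- segs[-i, , drop = FALSE]
    } else {
      segs <- segs[-i, , drop = FALSE]
    }
    segs <- merge_paint_segments(segs)
  }
  # laminar repair: a weak run that makes the label spans cross (impossible
  # under nesting + concatenation) is a mis-voted island, not structure;
  # drop such runs weakest-first until the spans form a laminar family
  repeat {
    if (nrow(segs) <= 2L) break
    sp <- label_spans(segs$ref_label)
    if (spans_laminar(sp)) break
    crossing <- crossing_labels(sp)
    weak <- which(segs$n_anchors < min_segment_anchors &
                  segs$ref_label %in% crossing)
    if (length(weak) == 0L) break   # strong conflict: leave for the parser
    i <- weak[order(segs$n_anchors[weak], -weak)][1L]
    segs <- merge_paint_segments(segs[-i, , drop = FALSE])
  }
  rownames(segs) <- NULL
  segs
}

crossing_labels <- function(sp) {
  out <- character()
  n <- nrow(sp)
  if (n <= 1L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s1 <- sp$s[i]; e1 <- sp$e[i]; s2 <- sp$s[j]; e2 <- sp$e[j]
    overlap <- s1 <= e2 && s2 <= e1
    nested <- (s1 < s2 && e2 < e1) || (s2 < s1 && e1 < e2)
    if (overlap && !nested) out <- c(out, sp$label[i], sp$label[j])
  }
  unique(out)
}

merge_paint_segments <- function(segs) {
  if (nrow(segs) <= 1L) return(segs)
  out <- segs[1, , drop = FALSE]
  for (i in 2:nrow(segs)) {
    k <- nrow(out)
    if (segs$ref_label[i] == out$ref_label[k]) {
      out$end_bp[k] <- segs$end_bp[i]
      out$n_anchors[k] <- out$n_anchors[k] + segs$n_anchors[i]
    } else {
      out <- rbind(out, segs[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Paint a whole genome from collinear blocks
#'
#' @param blocks classified `collinear_blocks` (query genome on the A side)
#' @param genome the query `genome` (provides the chromosome list)
#' @param min_segment_anchors see [paint_chromosome()]
#' @param scheme reference scheme tag stored on the karyogram
#' @return a `karyogram`: list with `genome_id`, `scheme`, and `paints` (one
#'   ordered segment data.frame per chromosome)
#' @export
paint_genome <- function(blocks, genome, min_segment_anchors = 5,
                         scheme = "reference12") {
  ids <- names(genome$chromosomes)
  ids <- ids[!vapply(genome$chromosomes, function(ch) ch$is_satellite,
                     logical(1))]
  paints <- lapply(ids, function(cid)
    paint_chromosome(blocks, cid, min_segment_anchors))
  names(paints) <- ids
  structure(list(genome_id = genome$genome_id, scheme = scheme,
                 paints = paints),
            class = "karyogram")
}

#' Paint a genome from its ground-truth origin labels
#'
#' Bypasses similarity and chaining: paints each chromosome by the runs of
#' the origin labels its loci carry. Used when replaying scripted
#' trajectories, where the ancestry of every gene is known exactly.
#' @param genome a `genome`
#' @param scheme scheme tag (default `"reference12"`)
#' @return a `karyogram`
#' @export
paint_from_origins <- function(genome, scheme = "reference12") {
  ids <- names(genome$chromosomes)
  ids <- ids[!vapply(genome$chromosomes, function(ch) ch$is_satellite,
                     logical(1))]
  paints <- lapply(ids, function(cid) {
    ch <- genome$chromosomes[[cid]]
    if (n_loci(ch) == 0L)
      return(data.frame(chrom_id = character(), start_bp = numeric(),
                        end_bp = numeric(), ref_label = character(),
                        n_anchors = integer(), orientation = character(),
                        stringsAsFactors = FALSE))
    r <- rle(ch$loci$origin_label)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    data.frame(chrom_id = cid,
               start_bp = ch$loci$start_bp[starts],
               end_bp = ch$loci$end_bp[ends],
               ref_label = r$values, n_anchors = r$lengths,
               orientation = "forward", stringsAsFactors = FALSE)
  })
  names(paints) <- ids
  structure(list(genome_id = genome$genome_id, scheme = scheme,
                 paints = paints),
            class = "karyogram")
}

#' Project a karyogram onto the seven-proto-chromosome scheme
#'
#' Relabels every paint segment through the reference-to-proto map and merges
#' adjacent segments that become same-label. Projection never increases the
#' segment count; segment order and physical extents are preserved.
#' @param karyogram a `karyogram` in the reference scheme
#' @param ref_to_proto named character vector, e.g. [os_to_proto_map()]
#' @return a `karyogram` with `scheme = "ancestral7"`
#' @export
project_to_ancestral <- function(karyogram, ref_to_proto = os_to_proto_map()) {
  karyogram$paints <- lapply(karyogram$paints, function(segs) {
    if (nrow(segs) == 0L) return(segs)
    lab <- ref_to_proto[segs$ref_label]
    if (anyNA(lab))
      stop("mapping error: labels missing from ref_to_proto map: ",
           paste(unique(segs$ref_label[is.na(lab)]), collapse = ", "))
    segs$ref_label <- unname(lab)
    merge_paint_segments(segs)
  })
  karyogram$scheme <- "ancestral7"
  karyogram
}

#' @export
print.karyogram <- function(x, ...) {
  cat(sprintf("<karyogram %s [%s], %d chromosomes>\n", x$genome_id, x$scheme,
              length(x$paints)))
  for (cid in names(x$paints)) {
    labs <- x$paints[[cid]]$ref_label
    cat(sprintf("  %s: %s\n", cid,
                if (length(labs)) paste(labs, collapse = " | ") else "(empty)"))
  }
  invisible(x)
}

#' Write a karyogram as BED
#'
#' 0-based half-open intervals with the reference label in the name column.
#' @param karyogram a `karyogram`
#' @param path output file
#' @export
write_karyogram_bed <- function(karyogram, path) {
  rows <- do.call(rbind, lapply(names(karyogram$paints), function(cid) {
    segs <- karyogram$paints[[cid]]
    if (nrow(segs) == 0L) return(NULL)
    data.frame(chrom = cid, start = segs$start_bp - 1L, end = segs$end_bp,
               name = segs$ref_label, score = segs$n_anchors,
               strand = ifelse(segs$orientation == "reverse", "-", "+"),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Fraction of gene-bearing extent covered by paint
#' @param karyogram a `karyogram`
#' @param genome the painted `genome`
#' @return named numeric vector, one coverage fraction per chromosome
#' @export
paint_coverage <- function(karyogram, genome) {
  vapply(names(karyogram$paints), function(cid) {
    ch <- genome$chromosomes[[cid]]
    if (is.null(ch) || n_loci(ch) == 0L) return(NA_real_)
    segs <- karyogram$paints[[cid]]
    if (nrow(segs) == 0L) return(0)
    covered <- sum(segs$end_bp - segs$start_bp + 1)
    total <- max(ch$loci$end_bp) - min(ch$loci$start_bp) + 1
    min(covered / total, 1)
  }, numeric(1))
}
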