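# Filtering raw similarity hits into the homologous-pair set used for
# chaining: best-five-hits at E <= 1e-5, with large tandem/dispersed families
# removed.

#' Filter similarity hits into homologous pairs
#'
#' Per query, keeps at most `top_k` non-self hits with E-value at or below
#' `evalue_threshold`, then deduplicates pairs. For a within-genome
#' comparison the pair is stored canonically (lexicographic order) and
#' self-hits never become pairs; between genomes the (query, subject)
#' direction is collapsed keeping the best E-value.
#'
#' @param hits data.frame with columns query_id, subject_id, log10_evalue
#'   (from [emit_similarity()] or [read_blast_tab()])
#' @param evalue_threshold maximum E-value (default 1e-5)
#' @param top_k hits retained per query (default 5, counting non-self hits)
#' @param within_genome is this a self-comparison of one genome?
#' @return data.frame (gene_a, gene_b, log10_evalue) of class `homolog_pairs`
#' @export
filter_hits <- function(hits, evalue_threshold = 1e-5, top_k = 5,
                        within_genome = FALSE) {
  if (!("query_id" %in% names(hits)) && all(c("gene_a", "gene_b") %in%
                                            names(hits))) {
    names(hits)[match(c("gene_a", "gene_b"), names(hits))] <-
      c("query_id", "subject_id")  # accept our own output, so the filter is
                                   # idempotent
  }
  need <- c("query_id", "subject_id", "log10_evalue")
  if (!all(need %in% names(hits)))
    stop("hits must have columns ", paste(need, collapse = ", "))
  h <- hits[hits$log10_evalue <= log10(evalue_threshold), need, drop = FALSE]
  if (within_genome) h <- h[h$query_id != h$subject_id, , drop = FALSE]
  if (nrow(h)) {
    h <- h[order(h$query_id, h$log10_evalue, h$subject_id), , drop = FALSE]
    keep <- sequence(rle(h$query_id)$lengths) <= top_k
    h <- h[keep, , drop = FALSE]
  }
  if (within_genome && nrow(h)) {
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    h$query_id <- a; h$subject_id <- b
  }
  if (nrow(h)) {
    h <- h[order(h$query_id, h$subject_id, h$log10_evalue), , drop = FALSE]
    h <- h[!duplicated(paste(h$query_id, h$subject_id, sep = "\r")), ,
           drop = FALSE]
  }
  out <- data.frame(gene_a = h$query_id, gene_b = h$subject_id,
                    log10_evalue = h$log10_evalue, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("homolog_pairs", "data.frame")
  out
}

#' Remove pairs touching large gene families
#'
#' A family with `max_family_size` or more members on a single chromosome is
#' removed entirely: any pair with either gene in such a family is dropped.
#' Large clustered families blur collinearity and are excluded from the
#' analysis.
#'
#' @param pairs a `homolog_pairs` data.frame
#' @param families data.frame (gene_id, family_id, chrom_id) — see
#'   [family_table()]
#' @param max_family_size removal threshold (default 30; families of 30 or
#'   more on one chromosome are removed)
#' @return the filtered pairs
#' @export
remove_large_families <- function(pairs, families, max_family_size = 30) {
  need <- c("gene_id", "family_id", "chrom_id")
  if (!all(need %in% names(families)))
    stop("families must have columns ", paste(need, collapse = ", "))
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(genes, families$gene_id)
  if (length(missing))
    stop("mapping error: genes absent from the family table: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  per_chrom <- table(families$family_id, families$chrom_id)
  bad_fams <- rownames(per_chrom)[apply(per_chrom, 1,
                                        function(x) any(x >= max_family_size))]
  if (length(bad_fams) == 0L) return(pairs)
  fam_of <- setNames(families$family_id, families$gene_id)
  drop <- fam_of[pairs$gene_a] %in% bad_fams |
          fam_of[pairs$gene_b] %in% bad_fams
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer gene families by single-linkage clustering of pairs
#'
#' Used when no family table accompanies the input: connected components of
#' the homolog-pair graph become families.
#' @param pairs a `homolog_pairs` data.frame
#' @param all_genes optional vector of gene ids to include as singletons
#' @return data.frame (gene_id, family_id)
#' @export
infer_families <- function(pairs, all_genes = NULL) {
  verts <- unique(c(pairs$gene_a, pairs$gene_b, all_genes))
  if (length(verts) == 0L)
    return(data.frame(gene_id = character(), family_id = character(),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    pairs[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  data.frame(gene_id = names(comp),
             family_id = sprintf("FAM%05d", as.integer(comp)),
             stringsAsFactors = FALSE)
}

#' Write homolog pairs as TSV
#' @param pairs a `homolog_pairs` data.frame
#' @param path output file
#' @export
write_pairs_tsv <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
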