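#' @importFrom stats rnorm runif rbinom median sd setNames
#' @importFrom utils head tail read.table write.table modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Columns of a locus table
#'
#' Every chromosome stores its genes as an ordered data.frame with these
#' columns. Coordinates are 1-based inclusive base pairs; `origin_label` is the
#' ancestral/reference chromosome tag carried through rearrangements;
#' `lineage_id` identifies the post-duplication gene copy lineage (it differs
#' between the two copies created by a whole-genome duplication, while
#' `family_id` is shared).
#' @keywords internal
locus_columns <- function() {
  c("gene_id", "family_id", "start_bp", "end_bp", "strand",
    "origin_label", "lineage_id")
}

empty_loci <- function() {
  data.frame(gene_id = character(), family_id = character(),
             start_bp = numeric(), end_bp = numeric(), strand = character(),
             origin_label = character(), lineage_id = character(),
             stringsAsFactors = FALSE)
}

#' Recompute physical coordinates of a locus table
#'
#' Genes are laid end-to-end preserving each gene's original length, with a
#' fixed inter-gene gap. Rearrangement operators call this after every edit so
#' that base-pair distances (used by the chaining gap penalty) stay defined.
#'
#' @param loci a locus data.frame
#' @param gap_bp inter-gene gap in base pairs (default 10 kb)
#' @return the locus data.frame with `start_bp`/`end_bp` recomputed
#' @keywords internal
relayout_loci <- function(loci, gap_bp = 10000) {
  n <- nrow(loci)
  if (n == 0L) return(loci)
  lens <- loci$end_bp - loci$start_bp + 1
  starts <- cumsum(c(1, head(lens + gap_bp, -1)))
  loci$start_bp <- starts
  loci$end_bp <- starts + lens - 1
  rownames(loci) <- NULL
  loci
}

#' Construct a chromosome
#'
#' A chromosome is an ordered list of gene loci with a centromere split point
#' (an ordinal in `0..n`, i.e. between genes), a satellite flag and an
#' active-centromere flag. Centromeres inherited from fusion partners are kept
#' as inactive split points rather than deleted, so painting and inference can
#' still see them.
#'
#' @param chrom_id chromosome identifier
#' @param loci locus data.frame (see [locus_columns()])
#' @param centromere_index ordinal split point in `0..nrow(loci)`; defaults to
#'   the midpoint
#' @param is_satellite is this a satellite chromosome (fusion byproduct)?
#' @param active_centromere does the chromosome carry an active centromere?
#' @param inactive_centromeres integer vector of inactive centromere ordinals
#' @param relayout recompute physical coordinates?
#' @param gap_bp inter-gene gap used when relaying out
#' @return an object of class `chromosome`
#' @export
new_chromosome <- function(chrom_id, loci, centromere_index = NULL,
                           is_satellite = FALSE,
                           active_centromere = !is_satellite,
                           inactive_centromeres = integer(),
                           relayout = TRUE, gap_bp = 10000) {
  stopifnot(is.character(chrom_id), length(chrom_id) == 1L)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  missing_cols <- setdiff(locus_columns(), names(loci))
  if (length(missing_cols))
    stop("locus table is missing columns: ", paste(missing_cols, collapse = ", "))
  loci <- loci[, locus_columns()]
  if (relayout) loci <- relayout_loci(loci, gap_bp)
  n <- nrow(loci)
  cm <- as.integer(centromere_index %||% floor(n / 2))
  if (cm < 0L || cm > n)
    stop("centromere_index must lie in 0..", n, " for chromosome ", chrom_id)
  structure(list(chrom_id = chrom_id, loci = loci,
                 centromere_index = cm,
                 is_satellite = isTRUE(is_satellite),
                 active_centromere = isTRUE(active_centromere),
                 inactive_centromeres = as.integer(inactive_centromeres),
                 gap_bp = gap_bp),
            class = "chromosome")
}

#' Number of gene loci on a chromosome
#' @param chrom a `chromosome`
#' @export
n_loci <- function(chrom) nrow(chrom$loci)

#' Collapsed origin-label sequence of a chromosome
#'
#' Runs of consecutive loci with the same ancestral origin label are collapsed
#' to a single entry; this is the symbol sequence consumed by fusion-event
#' inference.
#' @param chrom a `chromosome`
#' @return character vector of origin labels, adjacent duplicates merged
#' @export
label_sequence <- function(chrom) {
  if (n_loci(chrom) == 0L) return(character())
  rle(chrom$loci$origin_label)$values
}

validate_chromosome <- function(chrom) {
  stopifnot(inherits(chrom, "chromosome"))
  loci <- chrom$loci
  if (nrow(loci)) {
    if (any(loci$start_bp > loci$end_bp))
      stop("chromosome ", chrom$chrom_id, ": start_bp > end_bp")
    if (is.unsorted(loci$start_bp, strictly = TRUE))
      stop("chromosome ", chrom$chrom_id, ": loci not sorted by start_bp")
  }
  if (chrom$centromere_index < 0L || chrom$centromere_index > nrow(loci))
    stop("chromosome ", chrom$chrom_id, ": centromere_index out of range")
  if (!chrom$is_satellite && !chrom$active_centromere)
    stop("chromosome ", chrom$chrom_id,
         ": non-satellite chromosome must carry an active centromere")
  invisible(chrom)
}

#' Construct a genome
#'
#' @param genome_id genome identifier
#' @param chromosomes list of [new_chromosome()] objects
#' @param homoeolog_pairs data.frame with columns `a`, `b`: unordered pairs of
#'   homoeologous chromosome identifiers (or ancestral origin labels)
#' @param event_log list of fusion events already applied
#' @param validate run integrity checks?
#' @return an object of class `genome`
#' @export
new_genome <- function(genome_id, chromosomes,
                       homoeolog_pairs = NULL, event_log = list(),
                       validate = TRUE) {
  ids <- vapply(chromosomes, function(ch) ch$chrom_id, character(1))
  names(chromosomes) <- ids
  hp <- homoeolog_pairs %||%
    data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  g <- structure(list(genome_id = genome_id, chromosomes = chromosomes,
                      homoeolog_pairs = hp, event_log = event_log),
                 class = "genome")
  if (validate) validate_genome(g)
  g
}

#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "genome"))
  ids <- names(genome$chromosomes)
  if (anyDuplicated(ids)) stop("duplicate chromosome ids")
  for (ch in genome$chromosomes) validate_chromosome(ch)
  gene_ids <- unlist(lapply(genome$chromosomes, function(ch) ch$loci$gene_id),
                     use.names = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene_ids are not unique genome-wide")
  invisible(genome)
}

#' @export
chrom_ids <- function(genome) names(genome$chromosomes)

#' Total number of gene loci in a genome
#' @param genome a `genome`
#' @export
gene_count <- function(genome) {
  sum(vapply(genome$chromosomes, n_loci, integer(1)))
}

#' Number of chromosomes, optionally excluding satellites
#' @param genome a `genome`
#' @param include_satellites count satellite chromosomes too?
#' @export
n_chromosomes <- function(genome, include_satellites = TRUE) {
  if (include_satellites) return(length(genome$chromosomes))
  sum(!vapply(genome$chromosomes, function(ch) ch$is_satellite, logical(1)))
}

get_chromosome <- function(genome, chrom_id) {
  ch <- genome$chromosomes[[chrom_id]]
  if (is.null(ch)) stop("unknown chromosome: ", chrom_id)
  ch
}

#' Gene position index of a genome
#'
#' One row per gene with its chromosome, 0-based ordinal and physical
#' coordinates; the lookup table used by anchor chaining and rendering.
#' @param genome a `genome`
#' @return data.frame (gene_id, chrom_id, idx, start_bp, end_bp, mid_bp,
#'   family_id, lineage_id, origin_label)
#' @export
position_table <- function(genome) {
  tabs <- lapply(genome$chromosomes, function(ch) {
    n <- n_loci(ch)
    if (n == 0L) return(NULL)
    data.frame(gene_id = ch$loci$gene_id, chrom_id = ch$chrom_id,
               idx = seq_len(n) - 1L,
               start_bp = ch$loci$start_bp, end_bp = ch$loci$end_bp,
               mid_bp = (ch$loci$start_bp + ch$loci$end_bp) / 2,
               family_id = ch$loci$family_id,
               lineage_id = ch$loci$lineage_id,
               origin_label = ch$loci$origin_label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Gene-to-family table of a genome
#' @param genome a `genome`
#' @return data.frame (gene_id, family_id, chrom_id, origin_label)
#' @export
family_table <- function(genome) {
  pt <- position_table(genome)
  pt[, c("gene_id", "family_id", "chrom_id", "origin_label")]
}

#' Build an unrearranged reference genome
#'
#' Constructs a genome of `n_chrom` chromosomes, each carrying
#' `genes_per_chrom` genes in singleton families, the centromere at the
#' midpoint and the origin label equal to the chromosome's own identifier.
#' With the defaults this is the 12-chromosome rice-like reference (Os1..Os12)
#' used to replay the bundled Triticeae and Brachypodium event scripts.
#'
#' @param n_chrom number of chromosomes
#' @param genes_per_chrom genes per chromosome
#' @param prefix chromosome id prefix
#' @param genome_id genome identifier
#' @param gene_length_bp fixed gene length
#' @param gap_bp inter-gene gap
#' @param homoeolog_pairs optional homoeolog pair data.frame; for the default
#'   rice-like reference use [os_homoeolog_pairs()]
#' @return a `genome`
#' @export
make_reference_genome <- function(n_chrom = 12, genes_per_chrom = 200,
                                  prefix = "Os", genome_id = "reference",
                                  gene_length_bp = 2000, gap_bp = 10000,
                                  homoeolog_pairs = NULL) {
  stopifnot(n_chrom >= 1, genes_per_chrom >= 1)
  chroms <- lapply(seq_len(n_chrom), function(i) {
    cid <- paste0(prefix, i)
    gid <- sprintf("%sg%04d", cid, seq_len(genes_per_chrom))
    loci <- data.frame(gene_id = gid, family_id = paste0("F_", gid),
                       start_bp = 1, end_bp = gene_length_bp, strand = "+",
                       origin_label = cid, lineage_id = gid,
                       stringsAsFactors = FALSE)
    new_chromosome(cid, loci, gap_bp = gap_bp)
  })
  new_genome(genome_id, chroms, homoeolog_pairs = homoeolog_pairs)
}

#' Rice-like homoeologous chromosome pairs
#'
#' The classical duplicated-block pairing of the twelve rice chromosomes that
#' descends from the grass-common whole-genome duplication: seven ancestral
#' pairs, with chromosomes 2 and 3 each combining two ancestral units (hence
#' appearing twice). Shipped as a plain-text table under `extdata`; this
#' function reads it.
#'
#' @param prefix chromosome label prefix (default "Os")
#' @return data.frame with columns `a`, `b`
#' @export
os_homoeolog_pairs <- function(prefix = "Os") {
  path <- system.file("extdata", "os_homoeolog_pairs.tsv",
                      package = "karyofuse", mustWork = TRUE)
  hp <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (prefix != "Os") {
    hp$a <- sub("^Os", prefix, hp$a)
    hp$b <- sub("^Os", prefix, hp$b)
  }
  hp
}

#' Map of rice-like reference labels to the seven proto-chromosomes
#'
#' Reads the bundled Os-to-A projection used for the dual-scheme karyogram
#' display. Chromosomes 2 and 3 straddle two ancestral units; the map assigns
#' each whole label to its dominant ancestral chromosome and is explicitly an
#' editable configuration file, not a derived result.
#' @return named character vector, e.g. `c(Os1 = "A1", ...)`
#' @export
os_to_proto_map <- function() {
  path <- system.file("extdata", "os_to_proto_map.tsv",
                      package = "karyofuse", mustWork = TRUE)
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(m$proto, m$ref)
}

is_homoeologous_pair <- function(a, b, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(FALSE)
  any((pairs$a == a & pairs$b == b) | (pairs$a == b & pairs$b == a))
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf("<chromosome %s: %d genes, centromere at %d%s%s>\n",
              x$chrom_id, n_loci(x), x$centromere_index,
              if (x$is_satellite) ", satellite" else "",
              if (!x$active_centromere) ", centromere inactive" else ""))
  labs <- label_sequence(x)
  if (length(labs)) cat("  origin paint: ", paste(labs, collapse = " | "), "\n")
  invisible(x)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome %s: %d chromosomes (%d satellite), %d genes, %d events>\n",
              x$genome_id, length(x$chromosomes),
              sum(vapply(x$chromosomes, function(ch) ch$is_satellite, logical(1))),
              gene_count(x), length(x$event_log)))
  invisible(x)
}

#' Serialize a genome to JSON
#'
#' Deterministic, byte-stable serialization of the genome state (loci tables,
#' centromeres, satellite flags, homoeolog pairs and the event log).
#' @param genome a `genome`
#' @param path optional output file; if omitted the JSON string is returned
#' @export
genome_to_json <- function(genome, path = NULL) {
  obj <- list(
    genome_id = genome$genome_id,
    chromosomes = lapply(unname(genome$chromosomes), function(ch) {
      list(chrom_id = ch$chrom_id, loci = ch$loci,
           centromere_index = ch$centromere_index,
           is_satellite = ch$is_satellite,
           active_centromere = ch$active_centromere,
           inactive_centromeres = ch$inactive_centromeres)
    }),
    homoeolog_pairs = genome$homoeolog_pairs,
    event_log = lapply(genome$event_log, unclass))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a genome back from its JSON serialization
#' @param path JSON file written by [genome_to_json()]
#' @return a `genome`
#' @export
genome_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  chroms <- lapply(seq_len(nrow(obj$chromosomes)), function(i) {
    row <- obj$chromosomes[i, ]
    loci <- row$loci[[1]]
    if (is.null(loci) || length(loci) == 0L || nrow(as.data.frame(loci)) == 0L)
      loci <- empty_loci()
    new_chromosome(row$chrom_id, loci,
                   centromere_index = row$centromere_index,
                   is_satellite = row$is_satellite,
                   active_centromere = row$active_centromere,
                   inactive_centromeres = unlist(row$inactive_centromeres),
                   relayout = FALSE)
  })
  hp <- as.data.frame(obj$homoeolog_pairs, stringsAsFactors = FALSE)
  new_genome(obj$genome_id, chroms, homoeolog_pairs = hp,
             event_log = obj$event_log %||% list(), validate = FALSE)
}

#' Export gene models as GFF3
#'
#' Writes one `gene` feature per locus (1-based inclusive coordinates) with
#' the family and origin label as attributes. Uses rtracklayer when available.
#' @param genome a `genome`
#' @param path output file
#' @export
write_genome_gff3 <- function(genome, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("GFF3 export requires the rtracklayer and GenomicRanges packages")
  pt <- position_table(genome)
  gr <- GenomicRanges::GRanges(
    seqnames = pt$chrom_id,
    ranges = IRanges::IRanges(start = pt$start_bp, end = pt$end_bp),
    strand = vapply(seq_len(nrow(pt)), function(i) {
      ch <- genome$chromosomes[[pt$chrom_id[i]]]
      ch$loci$strand[pt$idx[i] + 1L]
    }, character(1)),
    type = "gene", ID = pt$gene_id,
    family_id = pt$family_id, origin_label = pt$origin_label)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write the gene family / origin map as TSV
#' @param genome a `genome`
#' @param path output file
#' @export
write_family_tsv <- function(genome, path) {
  ft <- family_table(genome)
  write.table(ft, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
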