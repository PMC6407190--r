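# Shared builders and independent oracles for the test suite.

# A genome built from explicit per-locus origin labels: spec is a named list
# chrom_id -> character vector of origin labels, one gene per element.
toy_genome <- function(spec, genome_id = "toy", gene_length = 2000,
                       gap_bp = 10000, centromeres = NULL) {
  counter <- 0L
  chroms <- lapply(names(spec), function(cid) {
    labs <- spec[[cid]]
    n <- length(labs)
    ids <- sprintf("%s_g%03d", cid, seq_len(n) + counter)
    counter <<- counter + n
    loci <- data.frame(gene_id = ids, family_id = paste0("F_", ids),
                       start_bp = 1, end_bp = gene_length, strand = "+",
                       origin_label = labs, lineage_id = ids,
                       stringsAsFactors = FALSE)
    new_chromosome(cid, loci,
                   centromere_index = centromeres[[cid]] %||% floor(n / 2),
                   gap_bp = gap_bp)
  })
  new_genome(genome_id, chroms)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Position-table row constructor for hand-built chaining fixtures.
make_positions <- function(gene_id, chrom_id, idx, mid_bp,
                           gene_length = 2000) {
  data.frame(gene_id = gene_id, chrom_id = chrom_id, idx = idx,
             start_bp = mid_bp - gene_length / 2,
             end_bp = mid_bp + gene_length / 2 - 1, mid_bp = mid_bp,
             family_id = paste0("F_", gene_id), lineage_id = gene_id,
             origin_label = chrom_id, stringsAsFactors = FALSE)
}

# Independent brute-force oracle for the chaining DP: enumerates every anchor
# subset, checks chain validity (strict monotonicity both sides, mg gap cap)
# in both orientations, and scores it sum(w) - sum(gap penalties).
brute_force_best_score <- function(anchors, params) {
  m <- nrow(anchors)
  stopifnot(m <= 12)
  best <- -Inf
  score_orient <- function(a) {
    ord <- order(a$ia, a$ib)
    a <- a[ord, , drop = FALSE]
    top <- -Inf
    for (mask in seq_len(2^m) - 1L) {
      rows <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
      if (length(rows) == 0L) next
      ia <- a$ia[rows]; ib <- a$ib[rows]
      pa <- a$pa[rows]; pb <- a$pb[rows]
      if (length(rows) > 1L) {
        if (any(diff(ia) <= 0) || any(diff(ib) <= 0)) next
        if (any(diff(ia) - 1 > params$mg) || any(diff(ib) - 1 > params$mg))
          next
      }
      pen <- if (length(rows) > 1L)
        sum((abs(diff(pa)) + abs(diff(pb))) / 10000 *
              params$gap_penalty_per_10kb)
      else 0
      top <- max(top, sum(a$w[rows]) - pen)
    }
    top
  }
  fwd <- score_orient(anchors)
  rev_a <- anchors
  rev_a$ib <- -rev_a$ib
  rev_a$pb <- -rev_a$pb
  max(fwd, score_orient(rev_a))
}

# The DP's best single-chain score over both orientations (internal access).
dp_best_score <- function(anchors, params) {
  fwd <- karyofuse:::best_chain(anchors, params)
  rev_a <- anchors
  rev_a$ib <- -rev_a$ib
  rev_a$pb <- -rev_a$pb
  rev_ <- karyofuse:::best_chain(rev_a, params)
  max(fwd$score, rev_$score)
}

random_anchor_instance <- function(m, seed) {
  set.seed(seed)
  ia <- sort(sample.int(30, m))
  ib <- sample.int(30, m)
  data.frame(gene_a = paste0("qa", seq_len(m)),
             gene_b = paste0("qb", seq_len(m)),
             ia = ia, ib = ib,
             pa = ia * 12000, pb = ib * 12000,
             sa = ia * 12000 - 1000, ea = ia * 12000 + 999,
             sb = ib * 12000 - 1000, eb = ib * 12000 + 999,
             w = round(runif(m, 5, 50), 1), stringsAsFactors = FALSE)
}

replay_fixture_trajectory <- function(name, genes_per_chrom = 100) {
  g <- run_simulate(fixture_script(name), genes_per_chrom = genes_per_chrom)
  assemble_trajectory(paint_from_origins(g), os_homoeolog_pairs())
}
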