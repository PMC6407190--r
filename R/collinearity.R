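# Collinear-block detection: sparse dynamic-programming chaining of
# homologous gene pairs with a capped match score and a physical-distance gap
# penalty, followed by a block-level significance filter and
# primary/secondary (orthology/paralogy) classification.

#' Chaining parameters
#'
#' @param mg maximum number of intervening genes between consecutive anchors
#'   on either chromosome (default 40)
#' @param match_cap per-anchor match score cap: anchor score is
#'   `min(-log10 E, match_cap)` (default 50)
#' @param gap_penalty_per_10kb penalty per 10 kb of physical distance between
#'   consecutive anchors, summed over both chromosomes (default 1)
#' @param block_evalue_threshold blocks with a larger E-value are discarded
#'   (default 1e-10)
#' @param min_anchors minimum anchors per reported block (default 5)
#' @param significance `"poisson"` (closed-form approximation, default) or
#'   `"permutation"` (shuffling null with tail fit)
#' @param perm_reps permutation replicates when `significance="permutation"`
#' @param gap_mode `"sum"` (default; base-pair gaps summed over both
#'   chromosomes) or `"max"` (per-chromosome maximum)
#' @return a list of class `chaining_params`
#' @export
chaining_params <- function(mg = 40, match_cap = 50, gap_penalty_per_10kb = 1,
                            block_evalue_threshold = 1e-10, min_anchors = 5,
                            significance = c("poisson", "permutation"),
                            perm_reps = 1000, gap_mode = c("sum", "max")) {
  stopifnot(mg >= 1, match_cap > 0)
  structure(list(mg = mg, match_cap = match_cap,
                 gap_penalty_per_10kb = gap_penalty_per_10kb,
                 block_evalue_threshold = block_evalue_threshold,
                 min_anchors = min_anchors,
                 significance = match.arg(significance),
                 perm_reps = perm_reps, gap_mode = match.arg(gap_mode)),
            class = "chaining_params")
}

anchor_weight <- function(log10_evalue, match_cap) {
  w <- -log10_evalue            # E = 0 gives +Inf, capped below
  pmin(w, match_cap)
}

# Best-scoring chain among anchors of one chromosome pair and orientation.
# anchors: data.frame with ia, ib (ordinals), pa, pb (mid bp), w (weight).
# For orientation "reverse", ib/pb are negated by the caller so that a valid
# chain is strictly increasing in both coordinates either way.
best_chain <- function(anchors, params) {
  m <- nrow(anchors)
  if (m == 0L) return(NULL)
  ord <- order(anchors$ia, anchors$ib)
  a <- anchors[ord, , drop = FALSE]
  dp <- a$w
  prev <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    if (j == 1L) next
    i <- seq_len(j - 1L)
    gap_a <- a$ia[j] - a$ia[i] - 1L
    gap_b <- a$ib[j] - a$ib[i] - 1L
    valid <- a$ia[i] < a$ia[j] & a$ib[i] < a$ib[j] &
      gap_a <= params$mg & gap_b <= params$mg
    if (!any(valid)) next
    dist <- abs(a$pa[j] - a$pa[i]) + abs(a$pb[j] - a$pb[i])
    if (params$gap_mode == "max")
      dist <- pmax(abs(a$pa[j] - a$pa[i]), abs(a$pb[j] - a$pb[i]))
    pen <- params$gap_penalty_per_10kb * dist / 10000
    cand <- dp[i] - pen
    cand[!valid] <- -Inf
    best <- which.max(cand)
    if (cand[best] > 0) {
      dp[j] <- a$w[j] + cand[best]
      prev[j] <- best
    }
  }
  end <- which.max(dp)
  chain <- integer()
  k <- end
  while (!is.na(k)) { chain <- c(k, chain); k <- prev[k] }
  list(score = dp[end], rows = ord[chain])
}

#' Chain homologous gene pairs into collinear blocks
#'
#' Per chromosome pair and orientation, maximal-scoring chains are extracted
#' by sparse dynamic programming (anchor score `min(-log10 E, match_cap)`;
#' transition penalty `gap_penalty_per_10kb` per 10 kb of inter-anchor
#' distance summed over both chromosomes; at most `mg` intervening genes on
#' either chromosome). Chains are peeled greedily best-first with their
#' anchors removed, so each anchor belongs to at most one block; chains with
#' fewer than `min_anchors` anchors or failing the E-value filter are
#' discarded.
#'
#' When `rescue = TRUE`, chains that fail the anchor-count or significance
#' filter but carry at least two anchors are retained with `rescued = TRUE`:
#' they are too weak to report as blocks, but their anchors still carry
#' origin information for segment painting (an enrichment of small
#' homologous blocks). Rescued blocks are excluded from classification.
#'
#' @param pairs a `homolog_pairs` data.frame (gene_a, gene_b, log10_evalue)
#' @param pos_a,pos_b position tables of the two genomes
#'   (see [position_table()]); `pos_b = pos_a` for a self-comparison
#' @param params a [chaining_params()]
#' @param rescue keep sub-threshold chains as low-confidence blocks?
#' @return a `collinear_blocks` data.frame, one row per block, with columns
#'   chrom_a, chrom_b, orientation, n_anchors, score, evalue, start_a, end_a,
#'   start_b, end_b, homology_class, rescued, and an `anchors` list-column
#' @export
chain_blocks <- function(pairs, pos_a, pos_b, params = chaining_params(),
                         rescue = FALSE) {
  ia <- match(pairs$gene_a, pos_a$gene_id)
  ib <- match(pairs$gene_b, pos_b$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("mapping error: genes in pairs missing from position tables")
  an <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                   chrom_a = pos_a$chrom_id[ia], chrom_b = pos_b$chrom_id[ib],
                   ia = pos_a$idx[ia], ib = pos_b$idx[ib],
                   pa = pos_a$mid_bp[ia], pb = pos_b$mid_bp[ib],
                   sa = pos_a$start_bp[ia], ea = pos_a$end_bp[ia],
                   sb = pos_b$start_bp[ib], eb = pos_b$end_bp[ib],
                   w = anchor_weight(pairs$log10_evalue, params$match_cap),
                   stringsAsFactors = FALSE)
  cp_key <- paste(an$chrom_a, an$chrom_b, sep = "\r")
  blocks <- list()
  for (key in sort(unique(cp_key))) {
    sub <- an[cp_key == key, , drop = FALSE]
    n_bg <- list(
      n_a = sum(pos_a$chrom_id == sub$chrom_a[1]),
      n_b = sum(pos_b$chrom_id == sub$chrom_b[1]),
      n_pairs = nrow(sub),
      anchors = if (params$significance == "permutation") sub)
    repeat {
      if (nrow(sub) == 0L) break
      fwd <- best_chain(sub, params)
      rsub <- sub
      rsub$ib <- -rsub$ib; rsub$pb <- -rsub$pb
      rev_ <- best_chain(rsub, params)
      use_fwd <- fwd$score >= rev_$score  # deterministic: forward wins ties
      ch <- if (use_fwd) fwd else rev_
      rows <- ch$rows
      anchors <- sub[rows, c("gene_a", "gene_b", "ia", "ib",
                             "sa", "ea", "sb", "eb", "w"), drop = FALSE]
      rownames(anchors) <- NULL
      blk <- list(chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
                  orientation = if (use_fwd) "forward" else "reverse",
                  n_anchors = nrow(anchors), score = ch$score,
                  start_a = min(anchors$sa), end_a = max(anchors$ea),
                  start_b = min(anchors$sb), end_b = max(anchors$eb),
                  anchors = anchors, background = n_bg)
      blocks[[length(blocks) + 1L]] <- blk
      sub <- sub[-rows, , drop = FALSE]
      if (nrow(sub) < 1L) break
    }
  }
  # significance + filters; optionally keep sub-threshold chains as
  # low-confidence "rescued" blocks (small-block enrichment for painting)
  keep <- list()
  for (blk in blocks) {
    blk$evalue <- block_significance(blk, blk$background, params)
    pass <- blk$n_anchors >= params$min_anchors &&
      blk$evalue <= params$block_evalue_threshold
    if (!pass && !(rescue && blk$n_anchors >= 2L)) next
    blk$rescued <- !pass
    keep[[length(keep) + 1L]] <- blk
  }
  blocks_df(keep)
}

blocks_df <- function(blocks) {
  if (length(blocks) == 0L) {
    out <- data.frame(chrom_a = character(), chrom_b = character(),
                      orientation = character(), n_anchors = integer(),
                      score = numeric(), evalue = numeric(),
                      start_a = numeric(), end_a = numeric(),
                      start_b = numeric(), end_b = numeric(),
                      homology_class = character(), rescued = logical(),
                      stringsAsFactors = FALSE)
    out$anchors <- list()
    class(out) <- c("collinear_blocks", "data.frame")
    return(out)
  }
  out <- data.frame(
    chrom_a = vapply(blocks, `[[`, character(1), "chrom_a"),
    chrom_b = vapply(blocks, `[[`, character(1), "chrom_b"),
    orientation = vapply(blocks, `[[`, character(1), "orientation"),
    n_anchors = vapply(blocks, `[[`, integer(1), "n_anchors"),
    score = vapply(blocks, `[[`, numeric(1), "score"),
    evalue = vapply(blocks, function(b) b$evalue %||% NA_real_, numeric(1)),
    start_a = vapply(blocks, `[[`, numeric(1), "start_a"),
    end_a = vapply(blocks, `[[`, numeric(1), "end_a"),
    start_b = vapply(blocks, `[[`, numeric(1), "start_b"),
    end_b = vapply(blocks, `[[`, numeric(1), "end_b"),
    homology_class = NA_character_,
    rescued = vapply(blocks, function(b) isTRUE(b$rescued), logical(1)),
    stringsAsFactors = FALSE)
  out$anchors <- lapply(blocks, `[[`, "anchors")
  # deterministic ordering: score desc, anchors desc, ids, leftmost start
  ord <- order(-out$score, -out$n_anchors, out$chrom_a, out$chrom_b,
               out$start_a)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("collinear_blocks", "data.frame")
  out
}

#' Block significance
#'
#' Assigns an E-value to a chained block. The closed-form method treats
#' anchors as a marked Poisson field: with homolog density
#' `p = n_pairs / (n_a * n_b)`, the chance that a chain step lands an anchor
#' inside its observed gap window of `(gap_a+1) x (gap_b+1)` gene cells is
#' `1 - (1-p)^cells`, and the block E-value is `n_pairs` times the product of
#' its step probabilities — monotone decreasing in anchor count. The
#' permutation method shuffles gene order on the second chromosome,
#' re-chains, and estimates the tail with a Gumbel fit to the permuted
#' maximum scores. A block with no anchors has E-value 1 by convention.
#'
#' @param block a block (row of a `collinear_blocks` or the internal list)
#' @param background list with `n_a`, `n_b` (gene counts of the chromosome
#'   pair) and `n_pairs` (homolog pairs between them)
#' @param params a [chaining_params()]
#' @param seed RNG seed for the permutation method
#' @return an E-value
#' @export
block_significance <- function(block, background, params = chaining_params(),
                               seed = 1) {
  if (is.null(background) || is.null(background$n_a) ||
      background$n_a <= 0 || background$n_b <= 0)
    stop("configuration error: empty background for block significance")
  anchors <- if (is.data.frame(block$anchors)) block$anchors
             else block$anchors[[1]]
  m <- nrow(anchors)
  if (m == 0L) return(1)
  if (params$significance == "poisson") {
    p <- min(background$n_pairs / (background$n_a * background$n_b), 0.999)
    if (m == 1L) return(min(background$n_pairs, 1e6))
    ord <- order(anchors$ia)
    ga <- diff(anchors$ia[ord]) - 1L
    gb <- abs(diff(anchors$ib[ord])) - 1L
    cells <- (pmax(ga, 0) + 1) * (pmax(gb, 0) + 1)
    step <- 1 - (1 - p)^cells
    return(background$n_pairs * prod(step))
  }
  # permutation null: shuffle the subject chromosome's gene order, re-chain
  # the full anchor field of the chromosome pair, and compare the block score
  # with the permuted maxima (Gumbel tail fit when the empirical count is 0)
  set.seed(seed)
  obs <- block$score
  an <- background$anchors %||% anchors
  spacing_b <- if (nrow(an) > 1) {
    mid <- (an$sb + an$eb) / 2
    max((max(mid) - min(mid)) / max(max(an$ib) - min(an$ib), 1), 1)
  } else 12000
  scores <- numeric(params$perm_reps)
  for (r in seq_len(params$perm_reps)) {
    old <- unique(an$ib)
    relab <- setNames(sample.int(background$n_b, length(old)), old)
    new_ib <- unname(relab[as.character(an$ib)])
    shuf <- data.frame(ia = an$ia, ib = new_ib,
                       pa = (an$sa + an$ea) / 2, pb = new_ib * spacing_b,
                       w = an$w)
    scores[r] <- best_chain(shuf, params)$score
  }
  emp <- (1 + sum(scores >= obs)) / (params$perm_reps + 1)
  mu <- mean(scores); s <- sd(scores)
  if (is.na(s) || s == 0) return(emp)
  beta <- s * sqrt(6) / pi
  loc <- mu - 0.5772 * beta
  gumbel_p <- 1 - exp(-exp(-(obs - loc) / beta))
  if (sum(scores >= obs) == 0) max(gumbel_p, 1e-300) else emp
}

#' Classify blocks as primary (orthologous) or secondary (paralogous)
#'
#' For each region of the query chromosome the best-scoring overlapping block
#' is labelled primary; lower-scoring blocks overlapping an already-primary
#' footprint by more than `overlap_frac` of their length become secondary.
#' All blocks of a within-genome self-comparison are secondary (paralogy from
#' the ancestral polyploidy). Ties break by lower subject chromosome id, so
#' classification is deterministic.
#'
#' @param blocks a `collinear_blocks` data.frame
#' @param self_comparison blocks from a genome compared against itself?
#' @param overlap_frac overlap fraction (of the smaller footprint) that
#'   triggers demotion (default 0.5)
#' @return the blocks with `homology_class` filled in
#' @export
classify_homology_layer <- function(blocks, self_comparison = FALSE,
                                    overlap_frac = 0.5) {
  if (nrow(blocks) == 0L) return(blocks)
  if (self_comparison) {
    blocks$homology_class <- "secondary"
    return(blocks)
  }
  ord <- order(-blocks$score, -blocks$n_anchors, blocks$chrom_b,
               blocks$start_a)
  ord <- ord[!blocks$rescued[ord]]   # rescued blocks stay unclassified
  cls <- rep(NA_character_, nrow(blocks))
  claimed <- list()  # per chrom_a: matrix of primary footprints
  for (i in ord) {
    ca <- blocks$chrom_a[i]
    s <- blocks$start_a[i]; e <- blocks$end_a[i]
    prim <- claimed[[ca]]
    demote <- FALSE
    if (!is.null(prim)) {
      ov <- pmin(e, prim[, 2]) - pmax(s, prim[, 1])
      len <- pmin(e - s, prim[, 2] - prim[, 1])
      demote <- any(ov > overlap_frac * pmax(len, 1))
    }
    if (demote) {
      cls[i] <- "secondary"
    } else {
      cls[i] <- "primary"
      claimed[[ca]] <- rbind(prim, c(s, e))
    }
  }
  blocks$homology_class <- cls
  blocks
}

#' Write blocks and anchors as TSV
#'
#' The block table uses 1-based inclusive base-pair coordinates; a companion
#' anchors file maps block ids to gene pairs.
#' @param blocks a `collinear_blocks` data.frame
#' @param path block table output file
#' @param anchors_path optional anchors file
#' @export
write_blocks_tsv <- function(blocks, path, anchors_path = NULL) {
  tab <- blocks[, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                    "end_b", "orientation", "n_anchors", "score", "evalue",
                    "homology_class")]
  names(tab)[11] <- "class"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(anchors_path)) {
    an <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
      a <- blocks$anchors[[i]]
      data.frame(block_id = i, gene_a = a$gene_a, gene_b = a$gene_b,
                 stringsAsFactors = FALSE)
    }))
    write.table(an, anchors_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
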