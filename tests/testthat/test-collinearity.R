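# Anchor chaining by dynamic programming, block significance, and
# primary/secondary classification.

diagonal_fixture <- function(n = 6, spacing = 10000, log10e = -60) {
  # n anchor pairs on a perfect diagonal, gene midpoints `spacing` apart
  pos_a <- make_positions(paste0("a", 1:n), "qa", 0:(n - 1),
                          (1:n) * spacing)
  pos_b <- make_positions(paste0("b", 1:n), "sb", 0:(n - 1),
                          (1:n) * spacing)
  pairs <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                      log10_evalue = log10e, stringsAsFactors = FALSE)
  list(pairs = pairs, pos_a = pos_a, pos_b = pos_b)
}

test_that("a perfect diagonal chains to the hand-computed score", {
  fx <- diagonal_fixture()
  params <- chaining_params(block_evalue_threshold = 1, min_anchors = 2)
  blocks <- chain_blocks(fx$pairs, fx$pos_a, fx$pos_b, params)
  expect_equal(nrow(blocks), 1)
  # 6 anchors capped at 50 each; 5 transitions of 10 kb on each chromosome
  expect_equal(blocks$score, 6 * 50 - 5 * (20000 / 10000))
  expect_equal(blocks$orientation, "forward")
  expect_equal(blocks$n_anchors, 6L)
})

test_that("a single pair cannot form a reportable block at min_anchors = 5", {
  fx <- diagonal_fixture(n = 1)
  blocks <- chain_blocks(fx$pairs, fx$pos_a, fx$pos_b,
                         chaining_params(block_evalue_threshold = 1))
  expect_equal(nrow(blocks), 0)
})

test_that("anchors separated by more than mg intervening genes never chain", {
  pos_a <- make_positions(c("a1", "a2"), "qa", c(0L, 42L), c(10000, 50000))
  pos_b <- make_positions(c("b1", "b2"), "sb", c(0L, 1L), c(10000, 22000))
  pairs <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                      log10_evalue = -60, stringsAsFactors = FALSE)
  params <- chaining_params(mg = 40, min_anchors = 1,
                            block_evalue_threshold = 1e6)
  blocks <- chain_blocks(pairs, pos_a, pos_b, params)
  expect_true(all(blocks$n_anchors == 1))   # 41 intervening genes: split
  pos_a$idx <- c(0L, 41L)                   # exactly mg intervening: chains
  blocks2 <- chain_blocks(pairs, pos_a, pos_b, params)
  expect_true(any(blocks2$n_anchors == 2))
})

test_that("the DP matches brute-force enumeration on random instances", {
  params <- chaining_params(mg = 8, min_anchors = 1)
  for (seed in 1:50) {
    m <- 3 + seed %% 6
    an <- random_anchor_instance(m, seed)
    expect_equal(dp_best_score(an, params),
                 brute_force_best_score(an, params),
                 tolerance = 1e-9, label = paste("instance seed", seed))
  }
})

test_that("reversing the subject chromosome flips orientation, not score", {
  fx <- diagonal_fixture()
  params <- chaining_params(block_evalue_threshold = 1, min_anchors = 2)
  fwd <- chain_blocks(fx$pairs, fx$pos_a, fx$pos_b, params)
  pos_b_rev <- fx$pos_b
  n <- nrow(pos_b_rev)
  pos_b_rev$idx <- (n - 1L):0L
  pos_b_rev$mid_bp <- rev(pos_b_rev$mid_bp)
  pos_b_rev$start_bp <- rev(pos_b_rev$start_bp)
  pos_b_rev$end_bp <- rev(pos_b_rev$end_bp)
  rev_ <- chain_blocks(fx$pairs, fx$pos_a, pos_b_rev, params)
  expect_equal(rev_$orientation, "reverse")
  expect_equal(rev_$score, fwd$score)
})

test_that("closed-form significance is monotone and bounded", {
  fx <- diagonal_fixture(n = 10)
  params <- chaining_params(block_evalue_threshold = 1, min_anchors = 2)
  blocks <- chain_blocks(fx$pairs, fx$pos_a, fx$pos_b, params)
  bg <- list(n_a = 200, n_b = 200, n_pairs = 400)
  full <- blocks[1, ]
  e_full <- block_significance(full, bg, params)
  # drop anchors: the E-value must not decrease
  sub <- full
  sub$anchors <- list(full$anchors[[1]][1:5, ])
  e_sub <- block_significance(sub, bg, params)
  expect_lte(e_full, e_sub)
  empty <- full
  empty$anchors <- list(full$anchors[[1]][0, ])
  expect_equal(block_significance(empty, bg, params), 1)
  expect_error(block_significance(full, list(), params), "configuration")
})

test_that("a long diagonal in a dense background is significant under both nulls", {
  # 20-anchor diagonal on a 200 x 200 gene chromosome pair at 1% homolog
  # density: far beyond what shuffled gene orders achieve
  fx <- diagonal_fixture(n = 20, spacing = 12000)
  params_p <- chaining_params(block_evalue_threshold = 1, min_anchors = 2)
  blocks <- chain_blocks(fx$pairs, fx$pos_a, fx$pos_b, params_p)
  bg <- list(n_a = 200, n_b = 200, n_pairs = 400)
  e_poisson <- block_significance(blocks[1, ], bg, params_p)
  expect_lt(e_poisson, 1e-10)
  params_perm <- chaining_params(significance = "permutation",
                                 perm_reps = 500,
                                 block_evalue_threshold = 1,
                                 min_anchors = 2)
  e_perm <- block_significance(blocks[1, ], bg, params_perm, seed = 7)
  expect_lt(e_perm, 1e-10)
})

test_that("raising the E-value threshold never removes a reported block", {
  cfg <- sim_config(genes_per_chrom = 30, n_proto = 3)
  g <- apply_wgd(make_proto_genome(cfg))
  ref <- g; ref$genome_id <- "ref"
  pairs <- filter_hits(emit_similarity(g, ref, cfg, seed = 8))
  strict <- chain_blocks(pairs, position_table(g), position_table(ref),
                         chaining_params(block_evalue_threshold = 1e-30))
  loose <- chain_blocks(pairs, position_table(g), position_table(ref),
                        chaining_params(block_evalue_threshold = 1e-10))
  key <- function(b) paste(b$chrom_a, b$chrom_b, b$start_a, b$n_anchors)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("classification marks the best block primary, ties deterministic", {
  mk_block <- function(chrom_b, score, start_a = 1, end_a = 1e5) {
    list(chrom_a = "q1", chrom_b = chrom_b, orientation = "forward",
         n_anchors = 10L, score = score, start_a = start_a, end_a = end_a,
         start_b = 1, end_b = 1e5, evalue = 1e-20, rescued = FALSE,
         anchors = data.frame(), background = list(n_a = 1, n_b = 1,
                                                   n_pairs = 1))
  }
  blocks <- karyofuse:::blocks_df(list(mk_block("sZ", 100),
                                       mk_block("sA", 100),
                                       mk_block("sB", 50, 2e5, 3e5)))
  out1 <- classify_homology_layer(blocks)
  out2 <- classify_homology_layer(blocks)
  expect_identical(out1, out2)
  prim <- out1[out1$homology_class == "primary", ]
  # equal scores: the lexicographically lower subject chromosome wins
  expect_true("sA" %in% prim$chrom_b)
  expect_equal(out1$homology_class[out1$chrom_b == "sZ"], "secondary")
  # a non-overlapping block stays primary regardless of score
  expect_equal(out1$homology_class[out1$chrom_b == "sB"], "primary")
  # self-comparison: everything is paralogy
  self <- classify_homology_layer(blocks, self_comparison = TRUE)
  expect_true(all(self$homology_class == "secondary"))
})
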