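# Ancestral-origin painting and scheme projection.

test_that("a replayed nested fusion paints as host-insert-host", {
  ref <- make_reference_genome(genes_per_chrom = 60,
                               homoeolog_pairs = os_homoeolog_pairs())
  ext <- apply_ncf(ref, "Os10", "Os5", 5, 55, "centromere",
                   product_id = "T1")
  ext <- drop_satellites(ext)
  ext$genome_id <- "extant"
  ref2 <- make_reference_genome(genes_per_chrom = 60)
  res <- run_full(ext, ref2, seed = 2)
  expect_equal(res$karyogram$paints[["T1"]]$ref_label,
               c("Os5", "Os10", "Os5"))
})

test_that("painting from blocks is deterministic and empty-safe", {
  cfg <- sim_config(genes_per_chrom = 30, n_proto = 2)
  g <- make_proto_genome(cfg)
  ref <- g; ref$genome_id <- "ref"
  pairs <- filter_hits(emit_similarity(g, ref, cfg, seed = 5))
  blocks <- chain_blocks(pairs, position_table(g), position_table(ref),
                         chaining_params())
  p1 <- paint_chromosome(blocks, "A1")
  p2 <- paint_chromosome(blocks, "A1")
  expect_identical(p1, p2)
  expect_equal(nrow(paint_chromosome(blocks, "no_such_chrom")), 0)
})

test_that("projection to the ancestral scheme merges and never splits", {
  segs <- data.frame(chrom_id = "c", start_bp = c(1, 101, 201),
                     end_bp = c(100, 200, 300),
                     ref_label = c("Os11", "Os12", "Os3"),
                     n_anchors = c(10L, 10L, 10L),
                     orientation = "forward", stringsAsFactors = FALSE)
  kg <- structure(list(genome_id = "g", scheme = "reference12",
                       paints = list(c = segs)), class = "karyogram")
  proj <- project_to_ancestral(kg, c(Os11 = "A4", Os12 = "A4", Os3 = "A5"))
  expect_equal(proj$scheme, "ancestral7")
  expect_equal(proj$paints$c$ref_label, c("A4", "A5"))
  expect_equal(proj$paints$c$start_bp, c(1, 201))   # extents preserved
  expect_lte(nrow(proj$paints$c), nrow(segs))
  # identity map leaves the karyogram unchanged
  idm <- setNames(unique(segs$ref_label), unique(segs$ref_label))
  expect_equal(project_to_ancestral(kg, idm)$paints$c, segs)
  expect_error(project_to_ancestral(kg, c(Os11 = "A4")), "mapping error")
})

test_that("the shipped reference-to-proto map projects the fixtures", {
  g <- run_simulate(fixture_script("brachypodium"), genes_per_chrom = 60)
  kg <- paint_from_origins(g)
  proj <- project_to_ancestral(kg, os_to_proto_map())
  expect_true(all(unlist(lapply(proj$paints, function(p) p$ref_label)) %in%
                  paste0("A", 1:7)))
  n_before <- vapply(kg$paints, nrow, integer(1))
  n_after <- vapply(proj$paints, nrow, integer(1))
  expect_true(all(n_after <= n_before))
})

test_that("pipeline paint covers nearly all of a clean genome", {
  r <- event_recovery_trial(5, retention_rate = 1, n_events = 3,
                            genes_per_chrom = 100)
  expect_true(r$match)
  # re-run the painted pipeline to inspect coverage directly
  cfg <- sim_config(genes_per_chrom = 60, n_proto = 4,
                    event_mix = c(NCF = 1), n_events = 2)
  dup <- apply_wgd(make_proto_genome(cfg))
  ref <- dup; ref$genome_id <- "ref"
  anc <- dup; anc$event_log <- list()
  ext <- random_trajectory(anc, cfg, seed = 9)
  ext$genome_id <- "extant"
  res <- run_full(ext, ref, config = cfg, seed = 9)
  cov <- paint_coverage(res$karyogram, ext)
  expect_true(all(cov >= 0.95))
})
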