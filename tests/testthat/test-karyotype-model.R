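# Event algebra: nested fusion, end-end joining, translocation, inversion,
# satellite loss, and script replay.

test_that("nested fusion moves the donor interior and creates one satellite", {
  g <- toy_genome(list(D = rep("D", 10), R = rep("R", 10)))
  before <- gene_count(g)
  g2 <- apply_ncf(g, "D", "R", 2, 8, 5)
  fused <- g2$chromosomes[["R"]]
  sats <- Filter(function(ch) ch$is_satellite, g2$chromosomes)
  expect_equal(n_loci(fused), 16)              # 10 + (8 - 2)
  expect_length(sats, 1)
  expect_equal(n_loci(sats[[1]]), 4)
  expect_equal(gene_count(g2), before)         # conservation
  expect_equal(n_chromosomes(g2), n_chromosomes(g))  # donor out, satellite in
  expect_equal(label_sequence(fused), c("R", "D", "R"))
  ev <- g2$event_log[[1]]
  expect_equal(ev$event_type, "NCF")
  expect_true(fused$active_centromere)
  expect_length(fused$inactive_centromeres, 1)
})

test_that("nested fusion of Os10 into Os5 paints the nested pattern", {
  ref <- make_reference_genome(genes_per_chrom = 60)
  g <- apply_ncf(ref, "Os10", "Os5", 5, 55, "centromere", product_id = "T1")
  expect_equal(label_sequence(g$chromosomes[["T1"]]),
               c("Os5", "Os10", "Os5"))
})

test_that("nested fusion validates participants and breakpoints", {
  g <- toy_genome(list(D = rep("D", 10), R = rep("R", 10)))
  expect_error(apply_ncf(g, "D", "D", 2, 8, 5), "differ")
  expect_error(apply_ncf(g, "D", "R", 0, 8, 5), "breakpoint")
  expect_error(apply_ncf(g, "D", "R", 8, 2, 5), "breakpoint")
  expect_error(apply_ncf(g, "D", "R", 2, 8, 0), "window")
  g2 <- apply_ncf(g, "D", "R", 2, 8, 5)
  sat_id <- names(Filter(function(ch) ch$is_satellite, g2$chromosomes))
  expect_error(apply_ncf(g2, sat_id, "R", 1, 3, 5), "satellite")
})

test_that("end-end joining merges major parts and banks fragments", {
  g <- toy_genome(list(A = rep("A", 8), B = rep("B", 8)))
  g2 <- apply_eej(g, "A", "B", 7, 1)
  fused <- g2$chromosomes[["A"]]
  sat <- Filter(function(ch) ch$is_satellite, g2$chromosomes)[[1]]
  expect_equal(n_loci(fused), 14)
  expect_equal(n_loci(sat), 2)
  expect_equal(label_sequence(fused), c("A", "B"))
  expect_equal(gene_count(g2), 16)
  ev <- g2$event_log[[1]]
  expect_equal(ev$event_type, "EEJ")
  expect_equal(c(ev$left_label, ev$right_label), c("A", "B"))
})

test_that("end-end joining tolerates empty distal fragments", {
  g <- toy_genome(list(A = rep("A", 8), B = rep("B", 8)))
  g2 <- apply_eej(g, "A", "B", 0, 8)
  sat <- Filter(function(ch) ch$is_satellite, g2$chromosomes)
  expect_length(sat, 1)
  expect_equal(n_loci(sat[[1]]), 0)
  expect_equal(n_loci(g2$chromosomes[["A"]]), 16)
})

test_that("reciprocal translocation exchanges distal arms without satellites", {
  g <- toy_genome(list(a = rep("A", 4), b = rep("B", 2)),
                  centromeres = list(a = 2L, b = 1L))
  ga <- g$chromosomes[["a"]]$loci$gene_id
  gb <- g$chromosomes[["b"]]$loci$gene_id
  g2 <- apply_reciprocal_translocation(g, "a", "b", 2, 1)
  expect_equal(g2$chromosomes[["a"]]$loci$gene_id, c(ga[1:2], gb[2]))
  expect_equal(g2$chromosomes[["b"]]$loci$gene_id, c(gb[1], ga[3:4]))
  expect_equal(label_sequence(g2$chromosomes[["a"]]), c("A", "B"))
  expect_equal(label_sequence(g2$chromosomes[["b"]]), c("B", "A"))
  expect_false(any(vapply(g2$chromosomes, function(ch) ch$is_satellite,
                          logical(1))))
  expect_equal(gene_count(g2), 6)
})

test_that("translocation with empty arms changes nothing but the log", {
  g <- toy_genome(list(a = rep("A", 4), b = rep("B", 4)))
  g2 <- apply_reciprocal_translocation(g, "a", "b", 4, 4)
  expect_equal(g2$chromosomes[["a"]]$loci$gene_id,
               g$chromosomes[["a"]]$loci$gene_id)
  expect_length(g2$event_log, 1)
})

test_that("inversion reverses loci, flips strands, and is an involution", {
  g <- toy_genome(list(c1 = rep("C", 4)))
  ids <- g$chromosomes[["c1"]]$loci$gene_id
  g2 <- apply_inversion(g, "c1", 1, 3)
  expect_equal(g2$chromosomes[["c1"]]$loci$gene_id,
               ids[c(1, 3, 2, 4)])
  expect_equal(g2$chromosomes[["c1"]]$loci$strand, c("+", "-", "-", "+"))
  g3 <- apply_inversion(g2, "c1", 1, 3)
  expect_equal(g3$chromosomes[["c1"]]$loci$gene_id, ids)
  expect_equal(g3$chromosomes[["c1"]]$loci$strand, rep("+", 4))
  # full inversion twice restores order too
  g4 <- apply_inversion(apply_inversion(g, "c1", 0, 4), "c1", 0, 4)
  expect_equal(g4$chromosomes[["c1"]]$loci$gene_id, ids)
  expect_error(apply_inversion(g, "c1", 3, 1), "range")
})

test_that("an inverted interval reverses its physical order against the reference", {
  ref <- make_reference_genome(n_chrom = 1, genes_per_chrom = 30)
  inv <- apply_inversion(ref, "Os1", 10, 20)
  p0 <- position_table(ref)
  p1 <- position_table(inv)
  shared <- p0$gene_id[11:20]   # the inverted interval, reference order
  m <- match(shared, p1$gene_id)
  expect_true(all(diff(p1$mid_bp[m]) < 0))   # anti-diagonal segment
  outside <- p0$gene_id[1:10]
  expect_true(all(diff(p1$mid_bp[match(outside, p1$gene_id)]) > 0))
})

test_that("satellite loss removes exactly the satellites and logs each", {
  g <- toy_genome(list(A = rep("A", 10), B = rep("B", 10),
                       C = rep("C", 10)))
  g2 <- apply_ncf(g, "A", "B", 2, 8, 5)
  g3 <- drop_satellites(g2)
  expect_equal(n_chromosomes(g3), 2)
  losses <- Filter(function(e) e$event_type == "SATELLITE_LOSS", g3$event_log)
  expect_length(losses, 1)
  expect_identical(drop_satellites(g3)$chromosomes, g3$chromosomes)
})

test_that("chromosome arithmetic holds: final = initial - NCFs - EEJs", {
  cfg <- sim_config(genes_per_chrom = 40, event_mix = c(NCF = 1, EEJ = 1),
                    n_events = 4, seed = 11)
  start <- make_reference_genome(n_chrom = 12, genes_per_chrom = 40)
  out <- random_trajectory(start, cfg, seed = 11)
  fus <- sum(vapply(out$event_log, function(e)
    e$event_type %in% c("NCF", "EEJ"), logical(1)))
  expect_equal(n_chromosomes(out), 12 - fus)
})

test_that("script replay is deterministic and byte-stable", {
  ref1 <- make_reference_genome(genes_per_chrom = 60,
                                homoeolog_pairs = os_homoeolog_pairs())
  ref2 <- make_reference_genome(genes_per_chrom = 60,
                                homoeolog_pairs = os_homoeolog_pairs())
  g1 <- replay_script(ref1, fixture_script("triticeae"))
  g2 <- replay_script(ref2, fixture_script("triticeae"))
  expect_identical(genome_to_json(g1), genome_to_json(g2))
  # the event log mirrors the script's event steps in order and type
  script <- read_event_script(fixture_script("triticeae"))
  script_types <- toupper(vapply(script, `[[`, character(1), "type"))
  script_types <- script_types[!script_types %in%
                                 c("RENAME", "DROP_SATELLITES")]
  log_types <- vapply(g1$event_log, `[[`, character(1), "event_type")
  log_types <- log_types[log_types != "SATELLITE_LOSS"]
  expect_equal(log_types, script_types)
})

test_that("replay of an empty script returns the genome unchanged", {
  ref <- make_reference_genome(genes_per_chrom = 30)
  expect_identical(genome_to_json(replay_script(ref, list())),
                   genome_to_json(ref))
})

test_that("replay aborts on the first invalid step with its index", {
  ref <- make_reference_genome(genes_per_chrom = 30)
  bad <- list(list(type = "NCF", donor = "nope", recipient = "Os1",
                   cuts = list(0.1, 0.9), insertion_point = "centromere"))
  expect_error(replay_script(ref, bad), "step 1")
})

test_that("genomes survive a JSON round trip", {
  g <- run_simulate(fixture_script("brachypodium"), genes_per_chrom = 40)
  path <- tempfile(fileext = ".json")
  genome_to_json(g, path)
  g2 <- genome_from_json(path)
  expect_equal(names(g2$chromosomes), names(g$chromosomes))
  expect_equal(gene_count(g2), gene_count(g))
  expect_equal(label_sequence(g2$chromosomes[["Bd4"]]),
               label_sequence(g$chromosomes[["Bd4"]]))
})
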