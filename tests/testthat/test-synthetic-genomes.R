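# Proto-genome construction, whole-genome duplication, fractionation, random
# trajectories, and synthetic similarity layers.

test_that("proto genome has the configured shape", {
  g <- make_proto_genome(sim_config(n_proto = 7, genes_per_chrom = 200))
  expect_equal(n_chromosomes(g), 7)
  expect_equal(gene_count(g), 1400)
  expect_equal(length(unique(family_table(g)$family_id)), 1400)
  expect_equal(names(g$chromosomes), paste0("A", 1:7))
  g1 <- make_proto_genome(sim_config(n_proto = 1, genes_per_chrom = 10))
  expect_equal(n_chromosomes(g1), 1)
})

test_that("whole-genome duplication doubles chromosomes and pairs them", {
  g <- apply_wgd(make_proto_genome(sim_config(genes_per_chrom = 20)))
  expect_equal(n_chromosomes(g), 14)
  expect_equal(nrow(g$homoeolog_pairs), 7)
  # perfect matching on chromosome ids
  expect_setequal(c(g$homoeolog_pairs$a, g$homoeolog_pairs$b),
                  names(g$chromosomes))
  fam <- table(family_table(g)$family_id)
  expect_true(all(fam == 2))
  expect_error(apply_wgd(g), "already")
})

test_that("fractionation keeps duplicates at about the retention rate", {
  g <- apply_wgd(make_proto_genome(sim_config(genes_per_chrom = 200)))
  expect_identical(gene_count(fractionate(g, 1, seed = 5)), 2800L)
  r <- 0.7
  g2 <- fractionate(g, r, seed = 5)
  n_dup <- 1400
  retained <- gene_count(g2) - 1400
  se <- sqrt(n_dup * r * (1 - r))
  expect_lt(abs(retained - n_dup * r), 3 * se)
  # survivor order preserved
  orig <- g$chromosomes[["A1_2"]]$loci$gene_id
  surv <- g2$chromosomes[["A1_2"]]$loci$gene_id
  expect_identical(surv, orig[orig %in% surv])
  expect_error(fractionate(make_proto_genome(sim_config()), 0.7), "WGD")
})

test_that("random trajectories are reproducible and respect the event mix", {
  ref <- make_reference_genome(n_chrom = 12, genes_per_chrom = 40)
  cfg0 <- sim_config(n_events = 0, genes_per_chrom = 40)
  expect_identical(genome_to_json(random_trajectory(ref, cfg0, seed = 1)),
                   genome_to_json(ref))
  cfg7 <- sim_config(event_mix = c(NCF = 1), n_events = 7,
                     genes_per_chrom = 40)
  out <- random_trajectory(ref, cfg7, seed = 2)
  expect_equal(n_chromosomes(out), 5)   # 12 chromosomes, 7 nested fusions
  out2 <- random_trajectory(ref, cfg7, seed = 2)
  expect_identical(event_multiset(out), event_multiset(out2))
  expect_identical(genome_to_json(out), genome_to_json(out2))
})

test_that("similarity layers are stratified: orthologs dominate outparalogs", {
  cfg <- sim_config(genes_per_chrom = 40)
  dup <- apply_wgd(make_proto_genome(cfg))
  ref <- dup
  ref$genome_id <- "ref"
  hits <- emit_similarity(dup, ref, cfg, seed = 3)
  expect_true(all(c("ortholog", "outparalog") %in% hits$layer))
  med_o <- median(hits$log10_evalue[hits$layer == "ortholog"])
  med_p <- median(hits$log10_evalue[hits$layer == "outparalog"])
  expect_lt(med_o, med_p)
  # with noise disabled every hit pair shares a family
  fam <- setNames(family_table(dup)$family_id, family_table(dup)$gene_id)
  expect_true(all(fam[hits$query_id] == fam[hits$subject_id]))
})

test_that("self-comparison yields rank-1 self-hits at the E-value floor", {
  cfg <- sim_config(genes_per_chrom = 15, n_proto = 2)
  g <- make_proto_genome(cfg)
  hits <- emit_similarity(g, g, cfg, seed = 4)
  selfs <- hits[hits$query_id == hits$subject_id, ]
  expect_equal(nrow(selfs), gene_count(g))
  expect_true(all(selfs$rank == 1))
  expect_true(all(selfs$log10_evalue == cfg$evalue_layers$floor))
})

test_that("BLAST tabular output round-trips through the reader", {
  cfg <- sim_config(genes_per_chrom = 10, n_proto = 2)
  g <- make_proto_genome(cfg)
  hits <- emit_similarity(g, g, cfg, seed = 6)
  path <- tempfile(fileext = ".tsv")
  write_blast_tab(hits, path)
  back <- read_blast_tab(path)
  expect_equal(nrow(back), nrow(hits))
  m <- merge(hits, back, by = c("query_id", "subject_id"))
  expect_true(all(abs(m$log10_evalue.x - m$log10_evalue.y) < 0.05 |
                  (m$log10_evalue.x <= -180 & m$log10_evalue.y <= -170)))
})
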