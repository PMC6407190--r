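# Pipeline orchestration: scripted replays and the full
# homology -> collinearity -> painting -> inference -> statistics chain,
# with a single global seed fanned out to per-stage seeds.

stage_seed <- function(seed, stage) {
  # stable per-stage fanout, kept below 2^31
  offsets <- c(simulate = 101L, fractionate = 211L, trajectory = 307L,
               similarity = 401L, significance = 503L)
  (as.integer(seed) * 7919L + (offsets[[stage]] %||% 997L)) %% 2147483647L
}

#' Replay a fixture or user script into a genome
#'
#' Builds the 12-chromosome reference genome, replays the event script, and
#' optionally writes the genome (JSON + family TSV) and ground-truth event
#' log.
#'
#' @param script path to an event script (see [read_event_script()]) or a
#'   parsed script list; the bundled trajectories are available via
#'   [fixture_script()]
#' @param genes_per_chrom reference genome scale (default 200)
#' @param out_dir optional output directory
#' @return the rearranged `genome`
#' @export
run_simulate <- function(script, genes_per_chrom = 200, out_dir = NULL) {
  ref <- make_reference_genome(genes_per_chrom = genes_per_chrom,
                               homoeolog_pairs = os_homoeolog_pairs())
  g <- replay_script(ref, script)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    genome_to_json(g, file.path(out_dir, paste0(g$genome_id, "_genome.json")))
    write_family_tsv(g, file.path(out_dir, paste0(g$genome_id, "_families.tsv")))
  }
  g
}

#' Run the full analysis on an extant genome against a reference
#'
#' Emits (or accepts) similarity hits, filters them into homologous pairs,
#' chains collinear blocks, classifies homology layers, paints the extant
#' chromosomes by reference origin, infers the fusion trajectory, and
#' evaluates the homoeologous-fusion null for the inferred counts.
#'
#' @param extant the derived `genome`
#' @param reference the reference `genome` (labels = its chromosome ids)
#' @param hits optional similarity hits (e.g. [read_blast_tab()]); when
#'   `NULL`, synthetic hits are generated with [emit_similarity()]
#' @param params a [chaining_params()]
#' @param config a [sim_config()] (similarity layers)
#' @param pair_map homoeolog pairs used to flag events (default: the
#'   reference genome's own pairs, falling back to [os_homoeolog_pairs()])
#' @param seed global seed fanned out to the stochastic stages
#' @param out_dir optional directory for intermediate artifacts (blocks TSV,
#'   karyogram BED/JSON, trajectory JSON, SVG renders)
#' @param n_pairs_null homoeologous pair count for the null (default 7)
#' @return list with `blocks`, `karyogram`, `trajectory`, `stats` and
#'   `summary` (a plain list suitable for JSON serialization)
#' @export
run_full <- function(extant, reference, hits = NULL,
                     params = chaining_params(), config = sim_config(),
                     pair_map = NULL, seed = 1, out_dir = NULL,
                     n_pairs_null = 7) {
  pair_map <- pair_map %||%
    (if (nrow(reference$homoeolog_pairs)) reference$homoeolog_pairs
     else os_homoeolog_pairs())
  if (is.null(hits))
    hits <- emit_similarity(extant, reference, config,
                            seed = stage_seed(seed, "similarity"))
  pairs <- filter_hits(hits)
  pairs <- remove_large_families(
    pairs, rbind(family_table(extant), family_table(reference)))
  blocks <- chain_blocks(pairs, position_table(extant),
                         position_table(reference), params, rescue = TRUE)
  blocks <- classify_homology_layer(blocks)
  kg <- paint_genome(blocks, extant,
                     min_segment_anchors = params$min_anchors)
  traj <- assemble_trajectory(kg, pair_map)
  k <- traj$n_homoeologous
  n_fus <- traj$n_ncf + traj$n_eej
  stats <- if (n_fus > 0 && k <= n_pairs_null) {
    fusion_null_summary(fusion_null_params(
      n_pairs = n_pairs_null, k_homoeologous = min(k, n_pairs_null),
      n_fusions_total = max(n_fus, k), reps = 1e4,
      seed = stage_seed(seed, "significance")))
  }
  summary <- list(
    genome_id = extant$genome_id,
    n_chromosomes = traj$chrom_count_final,
    n_ncf = traj$n_ncf, n_eej = traj$n_eej,
    n_translocations = traj$n_translocations,
    n_homoeologous = traj$n_homoeologous,
    n_satellites_implied = traj$n_satellites_implied,
    chrom_count_initial = traj$chrom_count_initial,
    events = event_multiset(traj),
    closed_form_probability = if (!is.null(stats)) stats$closed_form,
    mc_probability_first_k = if (!is.null(stats)) stats$p_first_k,
    seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_blocks_tsv(blocks, file.path(out_dir, "blocks.tsv"),
                     file.path(out_dir, "anchors.tsv"))
    write_karyogram_bed(kg, file.path(out_dir, "karyogram.bed"))
    trajectory_to_json(traj, file.path(out_dir, "trajectory.json"))
    writeLines(as.character(jsonlite::toJSON(summary, auto_unbox = TRUE,
                                             digits = NA, null = "null")),
               file.path(out_dir, "summary.json"))
    kg_anc <- tryCatch(project_to_ancestral(kg), error = function(e) NULL)
    if (!is.null(kg_anc))
      render_karyogram(list(kg_anc, kg), file.path(out_dir, "karyogram.svg"))
    render_dotplot(hits, extant, reference, file.path(out_dir, "dotplot.svg"))
  }
  list(blocks = blocks, karyogram = kg, trajectory = traj, stats = stats,
       summary = summary)
}

#' One seeded end-to-end event-recovery trial
#'
#' Builds a proto-genome, duplicates it (WGD), fractionates the duplicate
#' copies at `retention_rate`, applies a random NCF/EEJ trajectory, then runs
#' the full similarity pipeline against the unfractionated post-WGD reference
#' and compares the inferred event multiset with the ground-truth log.
#'
#' @param seed trial seed
#' @param retention_rate duplicate-copy survival probability (1 = clean)
#' @param n_events number of rearrangement events (drawn in 2..6 when `NULL`)
#' @param genes_per_chrom proto-chromosome gene count (default 100)
#' @param event_mix event-type weights (NCF and EEJ by default)
#' @return list with `truth`, `inferred` (event-key multisets) and `match`
#' @export
event_recovery_trial <- function(seed, retention_rate = 1, n_events = NULL,
                                 genes_per_chrom = 100,
                                 event_mix = c(NCF = 1, EEJ = 1)) {
  set.seed(stage_seed(seed, "simulate"))
  n_events <- n_events %||% sample(2:6, 1)
  cfg <- sim_config(genes_per_chrom = genes_per_chrom,
                    retention_rate = retention_rate,
                    event_mix = event_mix, n_events = n_events, seed = seed)
  proto <- make_proto_genome(cfg)
  dup <- apply_wgd(proto)
  reference <- dup
  reference$genome_id <- "wgd_reference"
  anc <- if (retention_rate < 1)
    fractionate(dup, retention_rate, seed = stage_seed(seed, "fractionate"))
  else dup
  anc$event_log <- list()  # fusion truth starts after fractionation
  extant <- random_trajectory(anc, cfg, seed = stage_seed(seed, "trajectory"))
  extant$genome_id <- "extant"
  res <- run_full(extant, reference, params = chaining_params(),
                  config = cfg, seed = seed)
  truth <- event_multiset(extant)
  inferred <- event_multiset(res$trajectory)
  list(truth = truth, inferred = inferred,
       match = identical(truth, inferred),
       n_events = n_events, trajectory = res$trajectory)
}
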