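# Synthetic post-tetraploidy grass genomes with ground truth.
#
# The generator emulates the study system: a proto-genome of seven
# chromosomes, a whole-genome duplication to fourteen, fractionation of
# duplicate gene copies, and a recent trajectory of telomere-centric fusion
# events; similarity scores are stratified by homology layer so ortholog hits
# stochastically dominate outparalog hits.

#' Simulation configuration
#'
#' @param n_proto number of proto-chromosomes (7, the ancestral grass
#'   karyotype)
#' @param genes_per_chrom genes per proto-chromosome
#' @param retention_rate probability a duplicated gene copy survives
#'   fractionation
#' @param event_mix named non-negative weights over event types
#'   (`NCF`, `EEJ`, `RECIPROCAL_TRANSLOCATION`, `INVERSION`)
#' @param n_events number of rearrangement events in a random trajectory
#' @param seed RNG seed
#' @param evalue_layers log10 E-value layer parameters: normal mean/sd for
#'   `ortholog` and `outparalog` layers, a `floor` (also the self-hit value)
#' @param gene_length_bp,gap_bp synthetic gene geometry (2 kb genes, 10 kb
#'   spacing, so gene-count gaps and the per-10 kb chaining penalty interact
#'   deterministically)
#' @param noise_hits uniform random noise hits per query (0 disables)
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_proto = 7, genes_per_chrom = 200,
                       retention_rate = 0.7,
                       event_mix = c(NCF = 1, EEJ = 1,
                                     RECIPROCAL_TRANSLOCATION = 0,
                                     INVERSION = 0),
                       n_events = 4, seed = 1,
                       evalue_layers = list(
                         ortholog = c(mean = -80, sd = 10),
                         outparalog = c(mean = -30, sd = 10),
                         floor = -180),
                       gene_length_bp = 2000, gap_bp = 10000,
                       noise_hits = 0) {
  stopifnot(retention_rate > 0, retention_rate <= 1,
            all(event_mix >= 0), any(event_mix > 0), n_proto >= 1)
  structure(list(n_proto = n_proto, genes_per_chrom = genes_per_chrom,
                 retention_rate = retention_rate, event_mix = event_mix,
                 n_events = n_events, seed = seed,
                 evalue_layers = evalue_layers,
                 gene_length_bp = gene_length_bp, gap_bp = gap_bp,
                 noise_hits = noise_hits),
            class = "sim_config")
}

#' Build a proto-genome
#'
#' `n_proto` chromosomes labelled A1..An, each gene in its own family,
#' centromere at the midpoint, origin label equal to the chromosome itself.
#' @param config a [sim_config()]
#' @return a `genome`
#' @export
make_proto_genome <- function(config = sim_config()) {
  make_reference_genome(n_chrom = config$n_proto,
                        genes_per_chrom = config$genes_per_chrom,
                        prefix = "A", genome_id = "proto",
                        gene_length_bp = config$gene_length_bp,
                        gap_bp = config$gap_bp)
}

#' Apply a whole-genome duplication
#'
#' Every chromosome is duplicated with suffixed ids; each duplicated gene
#' joins its progenitor's family but founds its own copy lineage.
#' `homoeolog_pairs` is populated with the duplicate pairs and a WGD event is
#' logged. A second call is an error.
#' @param genome a `genome`
#' @param suffix id suffix for the duplicated copies
#' @return the duplicated `genome`
#' @export
apply_wgd <- function(genome, suffix = "_2") {
  if (any(vapply(genome$event_log, function(e) e$event_type == "WGD",
                 logical(1))))
    stop("unsupported state: genome already carries a WGD event")
  dups <- lapply(genome$chromosomes, function(ch) {
    loci <- ch$loci
    if (nrow(loci)) {
      loci$gene_id <- paste0(loci$gene_id, suffix)
      loci$lineage_id <- loci$gene_id
      loci$origin_label <- paste0(ch$chrom_id, suffix)
    }
    new_chromosome(paste0(ch$chrom_id, suffix), loci,
                   centromere_index = ch$centromere_index,
                   gap_bp = ch$gap_bp, relayout = FALSE)
  })
  hp <- data.frame(a = names(genome$chromosomes),
                   b = paste0(names(genome$chromosomes), suffix),
                   stringsAsFactors = FALSE)
  ev <- new_fusion_event("WGD", donor_id = NA, recipient_id = NA,
                         breakpoints = list(),
                         products = paste0(names(genome$chromosomes), suffix),
                         is_homoeologous = FALSE)
  new_genome(genome$genome_id, c(genome$chromosomes, unname(dups)),
             homoeolog_pairs = rbind(genome$homoeolog_pairs, hp),
             event_log = c(genome$event_log, list(ev)))
}

#' Fractionate duplicated gene copies
#'
#' For every two-member family the duplicated (suffixed) copy is deleted
#' independently with probability `1 - retention_rate`, keeping one complete
#' reference lineage; `mode = "unbiased"` instead deletes a random copy of
#' the two. Survivor order is preserved. Logs a FRACTIONATION event with the
#' loss count.
#' @param genome a post-WGD `genome`
#' @param retention_rate survival probability of the duplicate copy
#' @param seed RNG seed
#' @param mode `"duplicate"` (default) or `"unbiased"`
#' @return the fractionated `genome`
#' @export
fractionate <- function(genome, retention_rate = 0.7, seed = 1,
                        mode = c("duplicate", "unbiased")) {
  mode <- match.arg(mode)
  if (!any(vapply(genome$event_log, function(e) e$event_type == "WGD",
                  logical(1))))
    stop("fractionate requires a genome with a WGD event")
  stopifnot(retention_rate > 0, retention_rate <= 1)
  set.seed(seed)
  ft <- family_table(genome)
  fam_n <- table(ft$family_id)
  dup_fams <- names(fam_n)[fam_n == 2L]
  n_lost <- 0L
  drop_ids <- character()
  if (length(dup_fams) && retention_rate < 1) {
    doomed <- dup_fams[runif(length(dup_fams)) > retention_rate]
    if (length(doomed)) {
      for (fam in doomed) {
        members <- ft$gene_id[ft$family_id == fam]
        victim <- if (mode == "duplicate") {
          members[which.max(nchar(members))]  # the suffixed copy is longer
        } else sample(members, 1L)
        drop_ids <- c(drop_ids, victim)
      }
      n_lost <- length(drop_ids)
      genome$chromosomes <- lapply(genome$chromosomes, function(ch) {
        keep <- !(ch$loci$gene_id %in% drop_ids)
        if (all(keep)) return(ch)
        new_cm <- ch$centromere_index - sum(!keep[seq_len(ch$centromere_index)])
        new_chromosome(ch$chrom_id, ch$loci[keep, , drop = FALSE],
                       centromere_index = new_cm,
                       is_satellite = ch$is_satellite,
                       active_centromere = ch$active_centromere,
                       gap_bp = ch$gap_bp)
      })
    }
  }
  ev <- new_fusion_event("FRACTIONATION", donor_id = NA, recipient_id = NA,
                         breakpoints = list(), products = character(),
                         n_lost = n_lost, is_homoeologous = FALSE)
  genome$event_log <- c(genome$event_log, list(ev))
  genome
}

single_origin_ids <- function(genome) {
  ids <- names(genome$chromosomes)
  keep <- vapply(genome$chromosomes, function(ch) {
    !ch$is_satellite && length(unique(ch$loci$origin_label)) == 1L &&
      n_loci(ch) >= 10L
  }, logical(1))
  ids[keep]
}

#' Sample a random rearrangement trajectory
#'
#' Draws `config$n_events` events with types from `config$event_mix` and
#' uniformly sampled valid participants and breakpoints within the model's
#' telomere-proximal and pericentromeric windows, then drops all satellites.
#' Nested-fusion donors are drawn from single-origin (not previously fused)
#' chromosomes, matching the observed grass trajectories in which every
#' invading chromosome is unrearranged. The true event log is retained on
#' the returned genome as ground truth.
#'
#' @param genome the starting `genome`
#' @param config a [sim_config()]
#' @param seed RNG seed (defaults to `config$seed`)
#' @return the rearranged `genome` (satellites dropped)
#' @export
random_trajectory <- function(genome, config = sim_config(), seed = NULL) {
  set.seed(seed %||% config$seed)
  mix <- config$event_mix[config$event_mix > 0]
  for (i in seq_len(config$n_events)) {
    type <- sample(names(mix), 1L, prob = mix)
    live <- names(genome$chromosomes)[!vapply(genome$chromosomes,
      function(ch) ch$is_satellite, logical(1))]
    genome <- switch(type,
      NCF = {
        donors <- single_origin_ids(genome)
        recips <- setdiff(live, character())
        ok <- FALSE
        for (attempt in seq_len(20L)) {
          if (length(donors) == 0L || length(recips) <= 1L) break
          d <- sample(donors, 1L)
          r <- sample(setdiff(recips, d), 1L)
          dn <- n_loci(genome$chromosomes[[d]])
          rn <- n_loci(genome$chromosomes[[r]])
          w <- max(1L, ceiling(0.1 * dn))
          l <- sample.int(w, 1L)
          rr <- dn - sample.int(w, 1L)
          cm <- genome$chromosomes[[r]]$centromere_index
          pw <- ceiling(0.05 * rn)
          ins <- max(0L, min(rn, cm + sample(seq(-pw, pw), 1L)))
          if (l >= rr) next
          ok <- TRUE
          genome <- apply_ncf(genome, d, r, l, rr, ins)
          break
        }
        if (!ok) stop("simulation exhausted: no valid NCF participants")
        genome
      },
      EEJ = {
        if (length(live) < 2L) stop("simulation exhausted: too few chromosomes")
        ab <- sample(live, 2L)
        na <- n_loci(genome$chromosomes[[ab[1]]])
        nb <- n_loci(genome$chromosomes[[ab[2]]])
        wa <- max(1L, ceiling(0.1 * na)); wb <- max(1L, ceiling(0.1 * nb))
        ca <- na - sample.int(wa, 1L)   # cut a's right telomere window
        cb <- sample.int(wb, 1L)        # cut b's left telomere window
        apply_eej(genome, ab[1], ab[2], ca, cb)
      },
      RECIPROCAL_TRANSLOCATION = {
        if (length(live) < 2L) stop("simulation exhausted: too few chromosomes")
        ab <- sample(live, 2L)
        cha <- genome$chromosomes[[ab[1]]]; chb <- genome$chromosomes[[ab[2]]]
        na <- n_loci(cha); nb <- n_loci(chb)
        ca <- sample(seq(cha$centromere_index + 1L, na - 1L), 1L)
        cb <- sample(seq(chb$centromere_index + 1L, nb - 1L), 1L)
        apply_reciprocal_translocation(genome, ab[1], ab[2], ca, cb)
      },
      INVERSION = {
        ch <- sample(live, 1L)
        n <- n_loci(genome$chromosomes[[ch]])
        f <- sample.int(n - 1L, 1L) - 1L
        t <- sample(seq(f + 1L, n), 1L)
        apply_inversion(genome, ch, f, t)
      },
      stop("unknown event type in event_mix: ", type))
  }
  drop_satellites(genome)
}

truncnorm_log10e <- function(n, mean, sd, floor) {
  pmin(pmax(rnorm(n, mean, sd), floor), 0)
}

#' Generate synthetic all-vs-all similarity hits
#'
#' Emulates a protein-level similarity search between two genomes sharing
#' gene families. Every query hits its same-family genes in the subject
#' genome: same copy lineage draws from the ortholog E-value layer, the
#' homoeologous copy from the (stochastically larger) outparalog layer.
#' Comparing a genome against itself yields a rank-1 self-hit at the E-value
#' floor. Optional uniform noise hits can be added per query.
#'
#' @param genome_a query `genome`
#' @param genome_b subject `genome` (may be `genome_a` itself)
#' @param config a [sim_config()] (layers, noise)
#' @param seed RNG seed
#' @return data.frame (query_id, subject_id, log10_evalue, rank, layer)
#' @export
emit_similarity <- function(genome_a, genome_b, config = sim_config(),
                            seed = 1) {
  set.seed(seed)
  pa <- position_table(genome_a)
  pb <- position_table(genome_b)
  same_genome <- identical(genome_a$genome_id, genome_b$genome_id)
  layers <- config$evalue_layers
  fl <- layers$floor
  qa <- data.frame(query_id = pa$gene_id, family_id = pa$family_id,
                   q_lineage = pa$lineage_id, stringsAsFactors = FALSE)
  sb <- data.frame(subject_id = pb$gene_id, family_id = pb$family_id,
                   s_lineage = pb$lineage_id, stringsAsFactors = FALSE)
  out <- merge(qa, sb, by = "family_id")
  layer <- ifelse(out$q_lineage == out$s_lineage, "ortholog", "outparalog")
  if (same_genome) layer[out$query_id == out$subject_id] <- "self"
  e <- numeric(nrow(out))
  for (ly in c("ortholog", "outparalog")) {
    w <- which(layer == ly)
    e[w] <- truncnorm_log10e(length(w), layers[[ly]][["mean"]],
                             layers[[ly]][["sd"]], fl)
  }
  e[layer == "self"] <- fl
  out <- data.frame(query_id = out$query_id, subject_id = out$subject_id,
                    log10_evalue = e, layer = layer, stringsAsFactors = FALSE)
  if (config$noise_hits > 0) {
    nq <- nrow(pa)
    noise <- data.frame(
      query_id = rep(pa$gene_id, config$noise_hits),
      subject_id = sample(pb$gene_id, nq * config$noise_hits, replace = TRUE),
      log10_evalue = runif(nq * config$noise_hits, -8, 0),
      layer = "noise", stringsAsFactors = FALSE)
    out <- rbind(out, noise)
  }
  out <- out[order(out$query_id, out$log10_evalue, out$subject_id), ]
  rnk <- sequence(rle(out$query_id)$lengths)
  out$rank <- rnk
  rownames(out) <- NULL
  out[, c("query_id", "subject_id", "log10_evalue", "rank", "layer")]
}

#' Write similarity hits as 12-column BLAST tabular output
#'
#' Standard outfmt-6 columns; only qseqid, sseqid and evalue carry real
#' information (the alignment statistics are filled with plausible
#' placeholders derived from the E-value).
#' @param hits data.frame from [emit_similarity()]
#' @param path output file
#' @export
write_blast_tab <- function(hits, path) {
  ev <- 10^pmax(hits$log10_evalue, -180)
  tab <- data.frame(hits$query_id, hits$subject_id, 90.0, 400L, 10L, 1L,
                    1L, 400L, 1L, 400L,
                    formatC(ev, format = "e", digits = 2),
                    round(-hits$log10_evalue * 2, 1))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read 12-column BLAST tabular hits
#' @param path BLAST outfmt-6 file
#' @return data.frame (query_id, subject_id, log10_evalue, rank)
#' @export
read_blast_tab <- function(path) {
  tab <- tryCatch(
    read.table(path, sep = "\t", stringsAsFactors = FALSE,
               col.names = c("qseqid", "sseqid", "pident", "length",
                             "mismatch", "gapopen", "qstart", "qend",
                             "sstart", "send", "evalue", "bitscore")),
    error = function(e) stop("malformed BLAST tabular file ", path, ": ",
                             conditionMessage(e)))
  out <- data.frame(query_id = tab$qseqid, subject_id = tab$sseqid,
                    log10_evalue = ifelse(tab$evalue <= 0, -Inf,
                                          log10(tab$evalue)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$query_id, out$log10_evalue, out$subject_id), ]
  out$rank <- sequence(rle(out$query_id)$lengths)
  rownames(out) <- NULL
  out
}

#' Thin a genome by random gene loss
#'
#' Deletes each gene independently with probability `1 - retention_rate`.
#' Used to emulate residual gene loss in a derived genome relative to an
#' intact reference.
#' @param genome a `genome`
#' @param retention_rate survival probability per gene
#' @param seed RNG seed
#' @return the thinned `genome`
#' @export
thin_genome <- function(genome, retention_rate, seed = 1) {
  stopifnot(retention_rate > 0, retention_rate <= 1)
  if (retention_rate == 1) return(genome)
  set.seed(seed)
  genome$chromosomes <- lapply(genome$chromosomes, function(ch) {
    n <- n_loci(ch)
    if (n == 0L) return(ch)
    keep <- runif(n) <= retention_rate
    new_cm <- ch$centromere_index - sum(!keep[seq_len(ch$centromere_index)])
    new_chromosome(ch$chrom_id, ch$loci[keep, , drop = FALSE],
                   centromere_index = new_cm,
                   is_satellite = ch$is_satellite,
                   active_centromere = ch$active_centromere,
                   gap_bp = ch$gap_bp)
  })
  genome
}
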