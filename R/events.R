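# Telomere-centric rearrangement operators.
#
# All split points are half-open ordinals: a cut at k separates loci [0,k)
# from [k,n). Every operator conserves the multiset of gene ids (except
# satellite loss), recomputes physical coordinates, and appends a typed event
# record to the genome's log.

resolve_ordinal <- function(x, n, what = "cut") {
  if (is.character(x)) stop("unresolved symbolic ", what, ": ", x)
  x <- as.numeric(x)
  if (length(x) != 1L || is.na(x)) stop("invalid ", what)
  # fractions in (0, 1) scale with chromosome length, so bundled scripts
  # replay at any simulation scale
  if (x > 0 && x < 1) x <- round(x * n)
  as.integer(x)
}

slice_loci <- function(loci, from, to) {
  # rows for ordinal interval [from, to), 0-based
  if (to <= from) return(loci[0, , drop = FALSE])
  loci[(from + 1L):to, , drop = FALSE]
}

flip_loci <- function(loci) {
  if (nrow(loci) == 0L) return(loci)
  loci <- loci[rev(seq_len(nrow(loci))), , drop = FALSE]
  loci$strand <- ifelse(loci$strand == "+", "-", "+")
  rownames(loci) <- NULL
  loci
}

#' Top-level origin labels of a label sequence
#'
#' Labels whose first-to-last span is not strictly contained in another
#' label's span; these are the "carrier" labels of a chromosome.
#' @param labels character vector of per-locus (or per-run) origin labels
#' @keywords internal
top_labels <- function(labels) {
  labs <- unique(labels)
  if (length(labs) <= 1L) return(labs)
  span <- t(vapply(labs, function(l) range(which(labels == l)), numeric(2)))
  keep <- vapply(seq_along(labs), function(i) {
    !any(span[, 1] < span[i, 1] & span[, 2] > span[i, 2])
  }, logical(1))
  labs[keep][order(span[keep, 1])]
}

carrier_label <- function(labels) {
  tl <- top_labels(labels)
  if (length(tl) == 0L) return(NA_character_)
  if (length(tl) == 1L) return(tl)
  sort(tl)[1L]
}

innermost_label_at <- function(labels, k) {
  # innermost origin label whose locus span strictly contains split point k
  # (i.e. has loci on both sides); falls back to the nearest neighbour label
  n <- length(labels)
  if (n == 0L) return(NA_character_)
  if (k <= 0L) return(labels[1L])
  if (k >= n) return(labels[n])
  if (labels[k] == labels[k + 1L]) return(labels[k])
  cand <- vapply(unique(labels), function(l) {
    w <- which(labels == l)
    if (min(w) <= k && max(w) > k) max(w) - min(w) else NA_real_
  }, numeric(1))
  cand <- cand[!is.na(cand)]
  if (length(cand) == 0L) return(labels[k])
  names(cand)[which.min(cand)]
}

new_fusion_event <- function(event_type, ...) {
  structure(c(list(event_type = event_type), list(...)),
            class = "fusion_event")
}

#' @export
print.fusion_event <- function(x, ...) {
  extra <- switch(x$event_type,
    NCF = sprintf("%s into %s", x$invading_label, x$invaded_label),
    EEJ = sprintf("%s + %s", x$left_label, x$right_label),
    RECIPROCAL_TRANSLOCATION = paste(x$products, collapse = " <-> "),
    "")
  cat(sprintf("<%s %s%s>\n", x$event_type, extra,
              if (isTRUE(x$is_homoeologous)) " [homoeologous]" else ""))
  invisible(x)
}

event_homoeologous <- function(invading_label, invaded_labels, pairs) {
  any(vapply(invaded_labels, function(l)
    is_homoeologous_pair(invading_label, l, pairs), logical(1)))
}

replace_chromosomes <- function(genome, drop_ids, new_chroms, event) {
  keep <- genome$chromosomes[setdiff(names(genome$chromosomes), drop_ids)]
  # insert fused products where the first dropped chromosome stood, so
  # chromosome order stays stable and replay output is deterministic
  pos <- match(drop_ids[1L], names(genome$chromosomes))
  ids_new <- vapply(new_chroms, function(ch) ch$chrom_id, character(1))
  names(new_chroms) <- ids_new
  all_ids <- names(genome$chromosomes)
  before <- intersect(all_ids[seq_len(pos - 1L)], names(keep))
  after <- setdiff(names(keep), before)
  genome$chromosomes <- c(keep[before], new_chroms, keep[after])
  genome$event_log <- c(genome$event_log, list(event))
  validate_genome(genome)
}

satellite_counter <- function(genome) {
  sum(vapply(genome$event_log, function(e)
    e$event_type %in% c("NCF", "EEJ"), logical(1))) + 1L
}

#' Apply a nested chromosome fusion (NCF)
#'
#' Telomere-proximal crossovers free the donor's ends; its centromere-bearing
#' interior `[donor_left_cut, donor_right_cut)` inserts into the
#' pericentromeric region of the recipient, while the donor's two distal
#' fragments join into a satellite chromosome. The recipient's centromere
#' stays active; the inserted donor centromere is flagged inactive. Total gene
#' count and chromosome count are conserved (the donor disappears as a
#' standalone chromosome, the satellite appears).
#'
#' @param genome a `genome`
#' @param donor,recipient chromosome ids (donor = "invading")
#' @param donor_left_cut,donor_right_cut donor split ordinals, `0 < left <
#'   right < n`; fractions in (0,1) are scaled by the chromosome length
#' @param insertion_point recipient split ordinal; must fall in the
#'   pericentromeric window (centromere +/- `ceiling(pericentromere_frac * n)`)
#'   unless `enforce_window = FALSE`. The string `"centromere"` targets the
#'   centromere itself.
#' @param invert insert the donor interior in reversed orientation?
#' @param product_id,satellite_id optional ids for the fused chromosome and
#'   the satellite (defaults: recipient id kept; `sat<k>_<donor>`)
#' @param pericentromere_frac half-width of the insertion window as a fraction
#'   of recipient gene count (default 0.05)
#' @param enforce_window validate the insertion-point window?
#' @return the updated `genome`
#' @export
apply_ncf <- function(genome, donor, recipient,
                      donor_left_cut, donor_right_cut, insertion_point,
                      invert = FALSE, product_id = NULL, satellite_id = NULL,
                      pericentromere_frac = 0.05, enforce_window = TRUE) {
  dch <- get_chromosome(genome, donor)
  rch <- get_chromosome(genome, recipient)
  if (donor == recipient) stop("NCF donor and recipient must differ")
  if (dch$is_satellite || rch$is_satellite)
    stop("invalid participant: satellite chromosomes cannot fuse")
  nd <- n_loci(dch); nr <- n_loci(rch)
  l <- resolve_ordinal(donor_left_cut, nd, "donor_left_cut")
  r <- resolve_ordinal(donor_right_cut, nd, "donor_right_cut")
  if (!(l > 0L && r > l && r < nd))
    stop("breakpoint error: NCF donor cuts must satisfy 0 < left < right < ",
         nd, " (got ", l, ", ", r, ")")
  if (dch$centromere_index < l || dch$centromere_index > r)
    stop("breakpoint error: donor interior must carry the donor centromere")
  window <- as.integer(ceiling(pericentromere_frac * nr))
  ins <- if (identical(insertion_point, "centromere")) rch$centromere_index
         else if (is.list(insertion_point) &&
                  !is.null(insertion_point$centromere_offset_frac))
           rch$centromere_index +
             as.integer(round(insertion_point$centromere_offset_frac * window))
         else resolve_ordinal(insertion_point, nr, "insertion_point")
  if (ins < 0L || ins > nr) stop("breakpoint error: insertion point out of range")
  if (enforce_window && abs(ins - rch$centromere_index) > window)
    stop("breakpoint error: insertion point ", ins,
         " outside pericentromeric window ",
         rch$centromere_index - window, "..", rch$centromere_index + window)

  interior <- slice_loci(dch$loci, l, r)
  if (isTRUE(invert)) interior <- flip_loci(interior)
  sat_loci <- rbind(slice_loci(dch$loci, 0L, l), slice_loci(dch$loci, r, nd))
  invaded_label <- innermost_label_at(rch$loci$origin_label, ins)
  invading_label <- carrier_label(interior$origin_label)

  fused_loci <- rbind(slice_loci(rch$loci, 0L, ins), interior,
                      slice_loci(rch$loci, ins, nr))
  k <- r - l
  new_cm <- if (ins < rch$centromere_index) rch$centromere_index + k
            else rch$centromere_index
  shift <- function(v) ifelse(v >= ins, v + k, v)
  donor_cm_new <- ins + (dch$centromere_index - l)
  fused <- new_chromosome(product_id %||% rch$chrom_id, fused_loci,
                          centromere_index = new_cm,
                          inactive_centromeres = c(shift(rch$inactive_centromeres),
                                                   donor_cm_new),
                          gap_bp = rch$gap_bp)
  sat_id <- satellite_id %||% sprintf("sat%d_%s", satellite_counter(genome), donor)
  sat <- new_chromosome(sat_id, sat_loci, centromere_index = 0L,
                        is_satellite = TRUE, active_centromere = FALSE,
                        gap_bp = dch$gap_bp)
  ev <- new_fusion_event("NCF", donor_id = donor, recipient_id = recipient,
    breakpoints = list(list(chrom_id = donor, ordinal = l),
                       list(chrom_id = donor, ordinal = r),
                       list(chrom_id = recipient, ordinal = ins)),
    products = c(fused$chrom_id, sat_id),
    invading_label = invading_label, invaded_label = invaded_label,
    is_homoeologous = event_homoeologous(invading_label,
                                         unique(rch$loci$origin_label),
                                         genome$homoeolog_pairs))
  replace_chromosomes(genome, c(recipient, donor), list(fused, sat), ev)
}

#' Apply an end-end joining (EEJ)
#'
#' An inter-chromosome telomere-proximal crossover: the centromere-bearing
#' major parts of the two chromosomes join end to end (the first chromosome's
#' centromere stays active, the second's is flagged inactive), and the two
#' distal fragments form one satellite chromosome (possibly gene-empty).
#'
#' @param genome a `genome`
#' @param chrom_a,chrom_b chromosome ids; `chrom_a`'s part comes first
#' @param cut_a,cut_b split ordinals; must lie in the telomere-proximal
#'   windows (outermost `telomere_frac` of ordinals per arm) unless
#'   `enforce_window = FALSE`. Fractions in (0,1) scale with length.
#' @param product_id,satellite_id optional product ids
#' @param telomere_frac telomere-window width as a fraction of gene count
#' @param enforce_window validate cut windows?
#' @return the updated `genome`
#' @export
apply_eej <- function(genome, chrom_a, chrom_b, cut_a, cut_b,
                      product_id = NULL, satellite_id = NULL,
                      telomere_frac = 0.1, enforce_window = TRUE) {
  if (chrom_a == chrom_b) stop("EEJ chromosomes must differ")
  cha <- get_chromosome(genome, chrom_a)
  chb <- get_chromosome(genome, chrom_b)
  if (cha$is_satellite || chb$is_satellite)
    stop("invalid participant: satellite chromosomes cannot fuse")
  na <- n_loci(cha); nb <- n_loci(chb)
  ca <- resolve_ordinal(cut_a, na, "cut_a")
  cb <- resolve_ordinal(cut_b, nb, "cut_b")
  if (ca < 0L || ca > na || cb < 0L || cb > nb)
    stop("breakpoint error: EEJ cut out of range")
  check_window <- function(cut, n, id) {
    w <- as.integer(ceiling(telomere_frac * n))
    if (cut > w && cut < n - w)
      stop("breakpoint error: EEJ cut ", cut, " on ", id,
           " outside telomere-proximal windows [0,", w, "] and [",
           n - w, ",", n, "]")
  }
  if (enforce_window) { check_window(ca, na, chrom_a); check_window(cb, nb, chrom_b) }

  split_major <- function(ch, cut) {
    n <- n_loci(ch)
    if (ch$centromere_index <= cut) {
      list(major = slice_loci(ch$loci, 0L, cut), cm = ch$centromere_index,
           frag = slice_loci(ch$loci, cut, n), cut_end = "right",
           inact = ch$inactive_centromeres[ch$inactive_centromeres <= cut])
    } else {
      list(major = slice_loci(ch$loci, cut, n), cm = ch$centromere_index - cut,
           frag = slice_loci(ch$loci, 0L, cut), cut_end = "left",
           inact = ch$inactive_centromeres[ch$inactive_centromeres >= cut] - cut)
    }
  }
  pa <- split_major(cha, ca)
  pb <- split_major(chb, cb)
  # orient so the cut (sticky) ends meet: a's on the right, b's on the left
  if (pa$cut_end == "left") {
    m <- nrow(pa$major)
    pa$major <- flip_loci(pa$major); pa$cm <- m - pa$cm
    pa$inact <- m - pa$inact
  }
  if (pb$cut_end == "right") {
    m <- nrow(pb$major)
    pb$major <- flip_loci(pb$major); pb$cm <- m - pb$cm
    pb$inact <- m - pb$inact
  }
  ma <- nrow(pa$major)
  left_label <- if (ma > 0) pa$major$origin_label[ma] else NA_character_
  right_label <- if (nrow(pb$major) > 0) pb$major$origin_label[1L] else NA_character_
  fused <- new_chromosome(product_id %||% cha$chrom_id,
                          rbind(pa$major, pb$major),
                          centromere_index = pa$cm,
                          inactive_centromeres = c(pa$inact, ma + pb$cm,
                                                   ma + pb$inact),
                          gap_bp = cha$gap_bp)
  sat_id <- satellite_id %||% sprintf("sat%d_%s_%s", satellite_counter(genome),
                                      chrom_a, chrom_b)
  sat <- new_chromosome(sat_id, rbind(pa$frag, pb$frag), centromere_index = 0L,
                        is_satellite = TRUE, active_centromere = FALSE,
                        gap_bp = cha$gap_bp)
  ev <- new_fusion_event("EEJ", donor_id = chrom_b, recipient_id = chrom_a,
    breakpoints = list(list(chrom_id = chrom_a, ordinal = ca),
                       list(chrom_id = chrom_b, ordinal = cb)),
    products = c(fused$chrom_id, sat_id),
    left_label = left_label, right_label = right_label,
    is_homoeologous = is_homoeologous_pair(left_label, right_label,
                                           genome$homoeolog_pairs))
  replace_chromosomes(genome, c(chrom_a, chrom_b), list(fused, sat), ev)
}

#' Apply a reciprocal translocation
#'
#' Arms distal to the two cuts are exchanged between the chromosomes; no
#' satellite is produced and gene count is conserved.
#' @param genome a `genome`
#' @param chrom_a,chrom_b chromosome ids
#' @param cut_a,cut_b split ordinals in `0..n` (fractions scale with length)
#' @param product_ids optional character(2) replacement ids
#' @return the updated `genome`
#' @export
apply_reciprocal_translocation <- function(genome, chrom_a, chrom_b,
                                           cut_a, cut_b, product_ids = NULL) {
  if (chrom_a == chrom_b) stop("translocation chromosomes must differ")
  cha <- get_chromosome(genome, chrom_a)
  chb <- get_chromosome(genome, chrom_b)
  if (cha$is_satellite || chb$is_satellite)
    stop("invalid participant: satellite chromosomes cannot translocate")
  na <- n_loci(cha); nb <- n_loci(chb)
  ca <- resolve_ordinal(cut_a, na, "cut_a")
  cb <- resolve_ordinal(cut_b, nb, "cut_b")
  if (ca < 0L || ca > na || cb < 0L || cb > nb)
    stop("breakpoint error: translocation cut out of range")
  arm_a <- slice_loci(cha$loci, ca, na)
  arm_b <- slice_loci(chb$loci, cb, nb)
  ids <- product_ids %||% c(chrom_a, chrom_b)
  # each product keeps whichever active centromere lies in its proximal part
  mk <- function(id, prox, prox_ch, cut, arm, arm_ch, arm_cut) {
    cm <- if (prox_ch$centromere_index <= cut) prox_ch$centromere_index
          else nrow(prox) + (arm_ch$centromere_index - arm_cut)
    inact <- c(prox_ch$inactive_centromeres[prox_ch$inactive_centromeres <= cut],
               nrow(prox) +
                 pmax(arm_ch$inactive_centromeres[arm_ch$inactive_centromeres >= arm_cut] - arm_cut, 0L))
    new_chromosome(id, rbind(prox, arm), centromere_index = cm,
                   inactive_centromeres = inact, gap_bp = prox_ch$gap_bp)
  }
  prod_a <- mk(ids[1L], slice_loci(cha$loci, 0L, ca), cha, ca, arm_b, chb, cb)
  prod_b <- mk(ids[2L], slice_loci(chb$loci, 0L, cb), chb, cb, arm_a, cha, ca)
  exch <- c(if (nrow(arm_a)) carrier_label(arm_a$origin_label) else NA_character_,
            if (nrow(arm_b)) carrier_label(arm_b$origin_label) else NA_character_)
  ev <- new_fusion_event("RECIPROCAL_TRANSLOCATION",
    donor_id = chrom_a, recipient_id = chrom_b,
    breakpoints = list(list(chrom_id = chrom_a, ordinal = ca),
                       list(chrom_id = chrom_b, ordinal = cb)),
    products = ids, exchanged_labels = exch, is_homoeologous = FALSE)
  replace_chromosomes(genome, c(chrom_a, chrom_b), list(prod_a, prod_b), ev)
}

#' Apply a chromosomal inversion
#'
#' Loci in `[from, to)` are reversed and their strands flipped. A centromere
#' inside the interval is reflected.
#' @param genome a `genome`
#' @param chrom chromosome id
#' @param from,to ordinal range, `0 <= from < to <= n`
#' @return the updated `genome`
#' @export
apply_inversion <- function(genome, chrom, from, to) {
  ch <- get_chromosome(genome, chrom)
  n <- n_loci(ch)
  f <- resolve_ordinal(from, n, "from")
  t <- resolve_ordinal(to, n, "to")
  if (!(f >= 0L && f < t && t <= n))
    stop("range error: inversion requires 0 <= from < to <= ", n)
  loci <- ch$loci
  loci[(f + 1L):t, ] <- flip_loci(loci[(f + 1L):t, , drop = FALSE])
  reflect <- function(v) ifelse(v > f & v < t, f + t - v, v)
  ch2 <- new_chromosome(ch$chrom_id, loci,
                        centromere_index = reflect(ch$centromere_index),
                        is_satellite = ch$is_satellite,
                        active_centromere = ch$active_centromere,
                        inactive_centromeres = reflect(ch$inactive_centromeres),
                        gap_bp = ch$gap_bp)
  ev <- new_fusion_event("INVERSION", donor_id = chrom, recipient_id = chrom,
    breakpoints = list(list(chrom_id = chrom, ordinal = f),
                       list(chrom_id = chrom, ordinal = t)),
    products = chrom, is_homoeologous = FALSE)
  genome$chromosomes[[chrom]] <- ch2
  genome$event_log <- c(genome$event_log, list(ev))
  genome
}

#' Remove all satellite chromosomes
#'
#' Deletes every chromosome flagged as a satellite, logging one SATELLITE_LOSS
#' event per removal. This is how the telomere-centric model realises
#' chromosome-number reduction.
#' @param genome a `genome`
#' @return the updated `genome`
#' @export
drop_satellites <- function(genome) {
  sat <- vapply(genome$chromosomes, function(ch) ch$is_satellite, logical(1))
  for (id in names(genome$chromosomes)[sat]) {
    ch <- genome$chromosomes[[id]]
    ev <- new_fusion_event("SATELLITE_LOSS", donor_id = id, recipient_id = NA,
      breakpoints = list(), products = character(),
      lost_genes = nrow(ch$loci),
      lost_labels = unique(ch$loci$origin_label), is_homoeologous = FALSE)
    genome$chromosomes[[id]] <- NULL
    genome$event_log <- c(genome$event_log, list(ev))
  }
  genome
}

#' Rename a chromosome
#' @param genome a `genome`
#' @param from,to old and new chromosome ids
#' @export
rename_chromosome <- function(genome, from, to) {
  ch <- get_chromosome(genome, from)
  if (to %in% names(genome$chromosomes) && to != from)
    stop("chromosome id already in use: ", to)
  ch$chrom_id <- to
  idx <- match(from, names(genome$chromosomes))
  genome$chromosomes[[idx]] <- ch
  names(genome$chromosomes)[idx] <- to
  genome
}
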