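# Inferring the fusion-event trajectory from an origin paint.
#
# A chromosome's collapsed origin-label sequence is parsed as a laminar
# nesting structure: a label returning after foreign material (X..Y..X)
# witnesses a nested chromosome fusion of Y into X; a top-level concatenation
# (X..Y with no return) witnesses an end-end joining; reciprocally exchanged
# terminal runs between two chromosomes witness a reciprocal translocation.

new_inferred_event <- function(event_type, carrier, ...) {
  structure(c(list(event_type = event_type, carrier = carrier), list(...)),
            class = "inferred_event")
}

#' @export
print.inferred_event <- function(x, ...) {
  desc <- switch(x$event_type,
    NCF = sprintf("NCF %s -> %s", x$invading_label, x$invaded_label),
    EEJ = sprintf("EEJ %s + %s", x$left_label, x$right_label),
    RECIPROCAL_TRANSLOCATION = sprintf("translocation with %s (%s)",
      x$partner, paste(x$exchanged_labels, collapse = "/")),
    x$event_type)
  cat(sprintf("<%s on %s%s>\n", desc, x$carrier,
              if (isTRUE(x$is_homoeologous)) " [homoeologous]" else ""))
  invisible(x)
}

label_runs_of <- function(paint) {
  if (is.character(paint)) {
    if (length(paint) == 0L) return(character())
    return(rle(paint)$values)
  }
  if (is.data.frame(paint)) {
    if (nrow(paint) == 0L) return(character())
    return(rle(paint$ref_label)$values)
  }
  stop("paint must be a character vector or a paint-segment data.frame")
}

label_spans <- function(runs) {
  labs <- unique(runs)
  data.frame(label = labs,
             s = vapply(labs, function(l) min(which(runs == l)), numeric(1)),
             e = vapply(labs, function(l) max(which(runs == l)), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

spans_laminar <- function(sp) {
  n <- nrow(sp)
  if (n <= 1L) return(TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s1 <- sp$s[i]; e1 <- sp$e[i]; s2 <- sp$s[j]; e2 <- sp$e[j]
    overlap <- s1 <= e2 && s2 <= e1
    nested <- (s1 < s2 && e2 < e1) || (s2 < s1 && e1 < e2)
    if (overlap && !nested) return(FALSE)
  }
  TRUE
}

#' Infer fusion events from one chromosome's origin paint
#'
#' Parses the collapsed label sequence: nested spans become nested chromosome
#' fusions (innermost-last in time; sibling insertions are ordered
#' left-to-right), top-level concatenations become end-end joinings with the
#' junction-adjacent labels, a single-origin chromosome yields a NONE event.
#' Sequences whose label spans cross (e.g. X,Y,X,Y) cannot arise from nesting
#' and concatenation alone and are flagged as a single AMBIGUOUS event rather
#' than guessed.
#'
#' Each event's `is_homoeologous` flag is evaluated at event time: a nested
#' fusion is homoeologous when the invading label is paired with any label
#' already present on the invaded chromosome.
#'
#' @param paint paint-segment data.frame (from [paint_chromosome()] or
#'   [paint_from_origins()]) or a character vector of origin labels
#' @param pair_map homoeolog pair data.frame (columns `a`, `b`), e.g.
#'   [os_homoeolog_pairs()]
#' @param carrier chromosome id recorded on the events
#' @return list of `inferred_event`s
#' @export
infer_chromosome_events <- function(paint, pair_map = NULL,
                                    carrier = NA_character_) {
  runs <- label_runs_of(paint)
  if (length(runs) == 0L) stop("no-call error: empty paint for ", carrier)
  if (is.data.frame(paint) && nrow(paint) > 0L && is.na(carrier))
    carrier <- paint$chrom_id[1]
  sp <- label_spans(runs)
  if (!spans_laminar(sp))
    return(list(new_inferred_event("AMBIGUOUS", carrier,
                                   labels = unique(runs),
                                   is_homoeologous = FALSE)))
  if (nrow(sp) == 1L)
    return(list(new_inferred_event("NONE", carrier, label = sp$label,
                                   is_homoeologous = FALSE)))
  # containment forest over label spans
  parent <- vapply(seq_len(nrow(sp)), function(i) {
    inside <- which(sp$s < sp$s[i] & sp$e > sp$e[i])
    if (length(inside) == 0L) return(NA_integer_)
    inside[which.min(sp$e[inside] - sp$s[inside])]
  }, integer(1))
  depth <- vapply(seq_len(nrow(sp)), function(i) {
    d <- 0L
    while (!is.na(parent[i])) { d <- d + 1L; i <- parent[i] }
    d
  }, integer(1))
  top <- which(is.na(parent))
  top <- top[order(sp$s[top])]
  events <- list()
  present <- sp$label[top]  # concatenations precede insertions by convention
  if (length(top) > 1L) {
    for (j in 2:length(top)) {
      l <- sp$label[top[j - 1L]]; r <- sp$label[top[j]]
      events[[length(events) + 1L]] <- new_inferred_event(
        "EEJ", carrier, left_label = l, right_label = r,
        is_homoeologous = is_homoeologous_pair(l, r, pair_map))
    }
  }
  nested <- setdiff(order(depth, sp$s), top)
  for (i in nested) {
    inv <- sp$label[i]
    host <- sp$label[parent[i]]
    events[[length(events) + 1L]] <- new_inferred_event(
      "NCF", carrier, invading_label = inv, invaded_label = host,
      is_homoeologous = any(vapply(present, function(l)
        is_homoeologous_pair(inv, l, pair_map), logical(1))))
    present <- c(present, inv)
  }
  events
}

#' Detect reciprocal translocations in a karyogram
#'
#' Looks for chromosome pairs whose terminal label runs were reciprocally
#' exchanged: a suffix of one chromosome whose labels are foreign to its own
#' core but split with (continue on) the partner, and vice versa. Each
#' detected pair yields one RECIPROCAL_TRANSLOCATION event; the exchanged
#' terminal runs are stripped so the per-chromosome fusion parser sees the
#' pre-translocation cores.
#'
#' @param karyogram a `karyogram`
#' @param pair_map homoeolog pair data.frame
#' @return list with `events` (list of `inferred_event`) and `cores` (named
#'   list of stripped label-run vectors per chromosome)
#' @export
infer_translocations <- function(karyogram, pair_map = NULL) {
  ids <- names(karyogram$paints)
  runs <- lapply(karyogram$paints, label_runs_of)
  cores <- runs
  events <- list()
  done <- character()
  find_junction <- function(r1, r2) {
    # exchanged suffixes: P1 = A-prefix + B-arm, P2 = B-prefix + A-arm,
    # both cuts splitting a segment (so each arm's labels continue on the
    # partner's prefix). Returns c(j1, j2) or NULL.
    n1 <- length(r1); n2 <- length(r2)
    for (j1 in rev(seq_len(n1 - 1L))) for (j2 in rev(seq_len(n2 - 1L))) {
      A <- r1[seq_len(j1)]; armB <- r1[(j1 + 1L):n1]
      B <- r2[seq_len(j2)]; armA <- r2[(j2 + 1L):n2]
      if (length(intersect(armB, A)) == 0L &&
          length(intersect(armA, B)) == 0L &&
          length(intersect(armB, B)) > 0L &&
          length(intersect(armA, A)) > 0L)
        return(c(j1, j2))
    }
    NULL
  }
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      c1 <- ids[i]; c2 <- ids[j]
      if (c1 %in% done || c2 %in% done) next
      r1 <- cores[[c1]]; r2 <- cores[[c2]]
      if (length(r1) < 2L || length(r2) < 2L) next
      if (length(intersect(r1, r2)) == 0L) next
      hit <- NULL
      for (f1 in c(FALSE, TRUE)) {
        for (f2 in c(FALSE, TRUE)) {
          s1 <- if (f1) rev(r1) else r1
          s2 <- if (f2) rev(r2) else r2
          jj <- find_junction(s1, s2)
          if (!is.null(jj)) { hit <- list(jj = jj, f1 = f1, f2 = f2); break }
        }
        if (!is.null(hit)) break
      }
      if (is.null(hit)) next
      s1 <- if (hit$f1) rev(r1) else r1
      s2 <- if (hit$f2) rev(r2) else r2
      armB <- s1[(hit$jj[1] + 1L):length(s1)]
      armA <- s2[(hit$jj[2] + 1L):length(s2)]
      core1 <- s1[seq_len(hit$jj[1])]
      core2 <- s2[seq_len(hit$jj[2])]
      cores[[c1]] <- if (hit$f1) rev(core1) else core1
      cores[[c2]] <- if (hit$f2) rev(core2) else core2
      exch <- sort(c(armB[1], armA[1]))
      events[[length(events) + 1L]] <- new_inferred_event(
        "RECIPROCAL_TRANSLOCATION", c1, partner = c2,
        exchanged_labels = exch,
        is_homoeologous = is_homoeologous_pair(exch[1], exch[2], pair_map))
      done <- c(done, c1, c2)
    }
  }
  list(events = events, cores = cores)
}

#' Assemble a genome-wide fusion trajectory from a karyogram
#'
#' Runs translocation detection, parses every chromosome's (stripped) paint
#' into nested-fusion and end-end-joining events, and aggregates: each NCF
#' and each EEJ implies one lost satellite chromosome, so the initial
#' chromosome count is the final count plus the implied satellites.
#' Chromosomes with unparseable paints are reported as AMBIGUOUS and excluded
#' from the counts, with a warning.
#'
#' @param karyogram a `karyogram` in the reference scheme
#' @param pair_map homoeolog pair data.frame, e.g. [os_homoeolog_pairs()]
#' @return an object of class `trajectory`: events, counts, implied
#'   satellites, and the reference alphabet in use
#' @export
assemble_trajectory <- function(karyogram, pair_map = NULL) {
  tr <- infer_translocations(karyogram, pair_map)
  events <- tr$events
  ambiguous <- character()
  for (cid in names(tr$cores)) {
    evs <- infer_chromosome_events(tr$cores[[cid]], pair_map, carrier = cid)
    types <- vapply(evs, `[[`, character(1), "event_type")
    if (any(types == "AMBIGUOUS")) {
      ambiguous <- c(ambiguous, cid)
      next
    }
    events <- c(events, evs[types != "NONE"])
  }
  if (length(ambiguous))
    warning("ambiguous paints excluded from trajectory counts: ",
            paste(ambiguous, collapse = ", "))
  types <- vapply(events, `[[`, character(1), "event_type")
  n_ncf <- sum(types == "NCF")
  n_eej <- sum(types == "EEJ")
  n_sat <- n_ncf + n_eej
  final <- length(karyogram$paints)
  alphabet <- sort(unique(unlist(lapply(karyogram$paints, label_runs_of))))
  structure(list(genome_id = karyogram$genome_id, events = events,
                 n_ncf = n_ncf, n_eej = n_eej,
                 n_translocations = sum(types == "RECIPROCAL_TRANSLOCATION"),
                 n_homoeologous = sum(vapply(events, function(e)
                   isTRUE(e$is_homoeologous), logical(1))),
                 n_satellites_implied = n_sat,
                 chrom_count_final = final,
                 chrom_count_initial = final + n_sat,
                 ambiguous = ambiguous, alphabet = alphabet),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: %d -> %d chromosomes>\n", x$genome_id,
              x$chrom_count_initial, x$chrom_count_final))
  cat(sprintf("  %d NCF, %d EEJ, %d reciprocal translocation(s); %d implied satellite(s); %d homoeologous fusion(s)\n",
              x$n_ncf, x$n_eej, x$n_translocations, x$n_satellites_implied,
              x$n_homoeologous))
  for (e in x$events) print(e)
  if (length(x$ambiguous))
    cat("  ambiguous chromosomes:", paste(x$ambiguous, collapse = ", "), "\n")
  invisible(x)
}

event_key <- function(e) {
  type <- e$event_type
  if (type == "NCF")
    return(paste("NCF", e$invading_label, e$invaded_label))
  if (type == "EEJ") {
    lr <- sort(c(e$left_label, e$right_label))
    return(paste("EEJ", lr[1], lr[2]))
  }
  if (type == "RECIPROCAL_TRANSLOCATION") {
    ex <- sort(e$exchanged_labels)
    return(paste("RT", paste(ex, collapse = " ")))
  }
  NA_character_
}

#' Comparable event keys of a trajectory or a genome's truth log
#'
#' Nested fusions keep their direction (invading -> invaded); end-end
#' joinings and translocations are canonicalized as unordered label pairs, so
#' the multiset is invariant under chromosome orientation.
#' @param x a `trajectory` or a `genome` carrying a ground-truth event log
#' @return sorted character vector of event keys (one entry per fusion event)
#' @export
event_multiset <- function(x) {
  evs <- if (inherits(x, "trajectory")) x$events
         else if (inherits(x, "genome")) x$event_log
         else stop("need a trajectory or a genome")
  keys <- vapply(evs, function(e) {
    if (!e$event_type %in% c("NCF", "EEJ", "RECIPROCAL_TRANSLOCATION"))
      return(NA_character_)
    event_key(e)
  }, character(1))
  sort(keys[!is.na(keys)])
}

#' Shared events between two trajectories
#'
#' Events match on (type, invading label, invaded label) for nested fusions
#' (direction matters) and on the unordered label pair for end-end joinings
#' and translocations.
#' @param t1,t2 `trajectory` objects over the same reference alphabet
#' @return character vector of shared event keys (multiset intersection;
#'   empty when the lineages share no event)
#' @export
compare_trajectories <- function(t1, t2) {
  stopifnot(inherits(t1, "trajectory"), inherits(t2, "trajectory"))
  if (length(intersect(t1$alphabet, t2$alphabet)) == 0L)
    stop("configuration error: trajectories use disjoint reference alphabets")
  k1 <- event_multiset(t1)
  k2 <- event_multiset(t2)
  shared <- character()
  for (k in unique(k1)) {
    n <- min(sum(k1 == k), sum(k2 == k))
    if (n > 0) shared <- c(shared, rep(k, n))
  }
  shared
}

#' Write a trajectory as JSON
#' @param trajectory a `trajectory`
#' @param path output file
#' @export
trajectory_to_json <- function(trajectory, path = NULL) {
  obj <- list(genome_id = trajectory$genome_id,
              events = lapply(trajectory$events, unclass),
              counts = list(ncf = trajectory$n_ncf, eej = trajectory$n_eej,
                            translocations = trajectory$n_translocations,
                            homoeologous = trajectory$n_homoeologous,
                            satellites_implied = trajectory$n_satellites_implied,
                            chrom_initial = trajectory$chrom_count_initial,
                            chrom_final = trajectory$chrom_count_final),
              ambiguous = trajectory$ambiguous)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
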