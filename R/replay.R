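# Driving the event algebra from JSON scripts.

#' Read an event script
#'
#' Scripts are JSON arrays of event objects. Recognised `type` values:
#' `NCF`, `EEJ`, `RECIPROCAL_TRANSLOCATION` (alias `RT`), `INVERSION`,
#' `DROP_SATELLITES`, `RENAME`. Cut positions may be integer ordinals or
#' fractions of the current chromosome length; NCF insertion points may also
#' be the string `"centromere"` or an object
#' `{"centromere_offset_frac": x}` (offset as a fraction of the
#' pericentromeric window half-width), which keeps bundled scripts valid at
#' any simulation scale. A `comment` field is ignored.
#'
#' @param path JSON file
#' @return list of event specifications
#' @export
read_event_script <- function(path) {
  if (!file.exists(path)) stop("event script not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = FALSE, simplifyDataFrame = FALSE)
}

#' Replay an event script on a genome
#'
#' Applies the scripted events in order. The first invalid step aborts with
#' its step index. `RENAME` steps relabel chromosomes without logging an
#' event, so after replay the event log matches the script's event steps in
#' order and type.
#'
#' @param genome the starting `genome`
#' @param script list of event specs (see [read_event_script()]) or a path to
#'   a JSON script
#' @return the rearranged `genome`
#' @export
replay_script <- function(genome, script) {
  if (is.character(script) && length(script) == 1L)
    script <- read_event_script(script)
  for (i in seq_along(script)) {
    ev <- script[[i]]
    genome <- tryCatch(apply_script_event(genome, ev),
      error = function(e) stop("script step ", i, " (", ev$type %||% "?",
                               "): ", conditionMessage(e), call. = FALSE))
  }
  genome
}

apply_script_event <- function(genome, ev) {
  type <- toupper(ev$type %||% stop("event has no type"))
  switch(type,
    NCF = apply_ncf(genome, donor = ev$donor, recipient = ev$recipient,
                    donor_left_cut = ev$cuts[[1]], donor_right_cut = ev$cuts[[2]],
                    insertion_point = ev$insertion_point,
                    invert = isTRUE(ev$invert),
                    product_id = ev$product_id, satellite_id = ev$satellite_id),
    EEJ = apply_eej(genome, chrom_a = ev$chrom_a, chrom_b = ev$chrom_b,
                    cut_a = ev$cuts[[1]], cut_b = ev$cuts[[2]],
                    product_id = ev$product_id, satellite_id = ev$satellite_id),
    RT = ,
    RECIPROCAL_TRANSLOCATION = apply_reciprocal_translocation(
      genome, chrom_a = ev$chrom_a, chrom_b = ev$chrom_b,
      cut_a = ev$cuts[[1]], cut_b = ev$cuts[[2]],
      product_ids = if (!is.null(ev$product_ids)) unlist(ev$product_ids)),
    INVERSION = apply_inversion(genome, chrom = ev$chrom,
                                from = ev$cuts[[1]], to = ev$cuts[[2]]),
    DROP_SATELLITES = drop_satellites(genome),
    RENAME = rename_chromosome(genome, ev$from, ev$to),
    stop("unknown event type: ", type))
}

#' Path to a bundled fixture event script
#'
#' `"triticeae"` encodes the 12-to-7 trajectory (4 nested chromosome fusions,
#' 1 end-end joining, 1 reciprocal translocation, satellite loss);
#' `"brachypodium"` the 12-to-5 trajectory (7 nested chromosome fusions,
#' satellite loss).
#' @param name `"triticeae"` or `"brachypodium"`
#' @return file path
#' @export
fixture_script <- function(name = c("triticeae", "brachypodium")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, "_script.json"),
              package = "karyofuse", mustWork = TRUE)
}
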