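# Parsing origin paints into fusion events, translocation detection,
# trajectory assembly, and cross-lineage comparison.

pm <- function() os_homoeolog_pairs()

ev_types <- function(evs) vapply(evs, `[[`, character(1), "event_type")

test_that("canonical paint patterns parse to the expected events", {
  # nested: host - insert - host
  evs <- infer_chromosome_events(c("Os5", "Os10", "Os5"), pm(), "T1")
  expect_equal(ev_types(evs), "NCF")
  expect_equal(evs[[1]]$invading_label, "Os10")
  expect_equal(evs[[1]]$invaded_label, "Os5")
  # single origin
  evs <- infer_chromosome_events("Os4", pm(), "Bd5")
  expect_equal(ev_types(evs), "NONE")
  # two siblings nested in one host
  evs <- infer_chromosome_events(c("Os2", "Os8", "Os2", "Os10", "Os2"),
                                 pm(), "Bd3")
  expect_equal(sort(vapply(evs, karyofuse:::event_key, character(1))),
               c("NCF Os10 Os2", "NCF Os8 Os2"))
  # boundary insertion: the unique two-fusion parse nests both into the host
  evs <- infer_chromosome_events(c("Os3", "Os7", "Os6", "Os3"), pm(), "Bd1")
  expect_equal(sort(vapply(evs, karyofuse:::event_key, character(1))),
               c("NCF Os6 Os3", "NCF Os7 Os3"))
  # concatenation with no return: end-end joining
  evs <- infer_chromosome_events(c("Os12", "Os9"), pm(), "Os12/9")
  expect_equal(ev_types(evs), "EEJ")
  expect_equal(c(evs[[1]]$left_label, evs[[1]]$right_label),
               c("Os12", "Os9"))
})

test_that("crossing label spans are flagged ambiguous, not guessed", {
  evs <- infer_chromosome_events(c("X", "Y", "X", "Y"), NULL, "c")
  expect_equal(ev_types(evs), "AMBIGUOUS")
  expect_error(infer_chromosome_events(character(), NULL, "c"), "no-call")
})

test_that("parsing is orientation-agnostic", {
  paints <- list(c("Os5", "Os10", "Os5"),
                 c("Os9", "Os12", "Os9", "Os11", "Os9"),
                 c("Os3", "Os7", "Os6", "Os3"),
                 c("Os12", "Os9"),
                 c("A", "B", "A", "C"))
  for (p in paints) {
    k1 <- sort(vapply(infer_chromosome_events(p, pm(), "c"),
                      karyofuse:::event_key, character(1)))
    k2 <- sort(vapply(infer_chromosome_events(rev(p), pm(), "c"),
                      karyofuse:::event_key, character(1)))
    expect_equal(k1, k2, label = paste(p, collapse = ","))
  }
})

test_that("homoeology is evaluated against labels present at event time", {
  # second insertion's invader is the homoeolog of the first insert
  evs <- infer_chromosome_events(c("Os9", "Os12", "Os9", "Os11", "Os9"),
                                 pm(), "Bd4")
  hom <- vapply(evs, function(e) isTRUE(e$is_homoeologous), logical(1))
  expect_equal(sum(hom), 1)
  inv <- vapply(evs, `[[`, character(1), "invading_label")
  expect_equal(inv[hom], "Os11")   # arrives after its partner Os12
  # direct homoeologous nesting
  evs <- infer_chromosome_events(c("Os1", "Os5", "Os1"), pm(), "Bd2")
  expect_true(evs[[1]]$is_homoeologous)
})

test_that("the replayed translocation pair is detected and stripped", {
  g <- run_simulate(fixture_script("triticeae"), genes_per_chrom = 100)
  kg <- paint_from_origins(g)
  tr <- infer_translocations(kg, pm())
  expect_length(tr$events, 1)
  e <- tr$events[[1]]
  expect_setequal(c(e$carrier, e$partner), c("T4", "T5"))
  expect_equal(e$exchanged_labels, c("Os3", "Os9"))
  expect_equal(tr$cores[["T4"]], c("Os3", "Os11", "Os3"))
  expect_equal(tr$cores[["T5"]], c("Os12", "Os9"))
  # single-origin chromosomes yield nothing
  ref <- make_reference_genome(genes_per_chrom = 20)
  expect_length(infer_translocations(paint_from_origins(ref), pm())$events, 0)
})

test_that("a scripted translocation is recovered across seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    ref <- make_reference_genome(genes_per_chrom = 60)
    ids <- sample(chrom_ids(ref), 4)
    g <- apply_ncf(ref, ids[1], ids[2], 6, 54, "centromere")
    cut_a <- sample(80:105, 1)   # in the trailing host run (the nested
                                 # segment occupies ordinals 30..77)
    cut_b <- sample(35:55, 1)
    g <- apply_reciprocal_translocation(g, ids[2], ids[3], cut_a, cut_b)
    g <- drop_satellites(g)
    traj <- assemble_trajectory(paint_from_origins(g), pm())
    expect_equal(traj$n_translocations, 1, label = paste("seed", seed))
    expect_equal(traj$n_ncf, 1, label = paste("seed", seed))
    rt <- Filter(function(e) e$event_type == "RECIPROCAL_TRANSLOCATION",
                 traj$events)
    expect_setequal(c(rt[[1]]$carrier, rt[[1]]$partner), ids[2:3])
  }
})

test_that("trajectory assembly reproduces both fixture lineages", {
  tt <- replay_fixture_trajectory("triticeae")
  expect_equal(tt$chrom_count_final, 7)
  expect_equal(tt$chrom_count_initial, 12)
  expect_equal(tt$n_ncf, 4)
  expect_equal(tt$n_eej, 1)
  expect_equal(tt$n_translocations, 1)
  expect_equal(tt$n_satellites_implied, 5)
  expect_equal(tt$n_homoeologous, 0)
  tb <- replay_fixture_trajectory("brachypodium")
  expect_equal(tb$chrom_count_final, 5)
  expect_equal(tb$chrom_count_initial, 12)
  expect_equal(tb$n_ncf, 7)
  expect_equal(tb$n_eej, 0)
  expect_equal(tb$n_satellites_implied, 7)
  expect_equal(tb$n_homoeologous, 3)
})

test_that("an unrearranged genome yields an empty trajectory", {
  ref <- make_reference_genome(genes_per_chrom = 20)
  traj <- assemble_trajectory(paint_from_origins(ref), pm())
  expect_equal(length(event_multiset(traj)), 0)
  expect_equal(traj$chrom_count_initial, traj$chrom_count_final)
  expect_equal(traj$n_satellites_implied, 0)
})

test_that("satellite arithmetic holds on both fixtures", {
  for (fx in c("triticeae", "brachypodium")) {
    tr <- replay_fixture_trajectory(fx)
    expect_equal(tr$chrom_count_initial,
                 tr$chrom_count_final + tr$n_satellites_implied)
  }
})

test_that("trajectory comparison is directional for nested fusions", {
  mk_traj <- function(inv, host) {
    structure(list(genome_id = "t", events = list(
      karyofuse:::new_inferred_event("NCF", "c", invading_label = inv,
                                     invaded_label = host,
                                     is_homoeologous = FALSE)),
      alphabet = c("Os1", "Os5")), class = "trajectory")
  }
  t1 <- mk_traj("Os5", "Os1")
  t2 <- mk_traj("Os1", "Os5")
  expect_length(compare_trajectories(t1, t2), 0)
  expect_length(compare_trajectories(t1, t1), 1)
  t3 <- mk_traj("Zm1", "Zm2")
  t3$alphabet <- c("Zm1", "Zm2")
  expect_error(compare_trajectories(t1, t3), "configuration")
})

test_that("the two grass lineages share no event", {
  tt <- replay_fixture_trajectory("triticeae")
  tb <- replay_fixture_trajectory("brachypodium")
  expect_length(compare_trajectories(tt, tb), 0)
  expect_equal(length(compare_trajectories(tt, tt)),
               length(event_multiset(tt)))
})
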