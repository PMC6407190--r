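---
title: "Telomere-centric karyotype evolution: model, inference, and null statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomere-centric karyotype evolution: model, inference, and null statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyofuse)
```

## The scientific problem

Grasses descend from a paleotetraploid ancestor: a whole-genome duplication
(cWGD, roughly 100 Mya) doubled a seven-chromosome proto-karyotype to
fourteen chromosomes, after which different lineages reduced their
chromosome numbers along different routes — rice retains twelve, the
Triticeae (wheat, barley, *Aegilops tauschii*) seven, *Brachypodium
distachyon* five. Under the telomere-centric model, reduction proceeds not
by simple end-to-end joining of whole chromosomes but by removal of
telomeres: crossovers in the telomere-proximal regions free a chromosome's
ends, the centromere-bearing body then either inserts into the
pericentromeric region of another chromosome (a *nested chromosome fusion*,
NCF) or joins another opened chromosome end-to-end (an *end-end joining*,
EEJ), and the excised telomeric fragments ligate into a small *satellite
chromosome* whose subsequent loss is what actually lowers the count.

karyofuse implements this model as a reusable, testable pipeline:

1. an exact event algebra over genomes (`apply_ncf()`, `apply_eej()`,
   `apply_reciprocal_translocation()`, `apply_inversion()`,
   `drop_satellites()`, driven by JSON scripts via `replay_script()`);
2. a synthetic-genome generator with ground truth (`make_proto_genome()`,
   `apply_wgd()`, `fractionate()`, `random_trajectory()`,
   `emit_similarity()`);
3. homology filtering and collinear-block detection (`filter_hits()`,
   `remove_large_families()`, `chain_blocks()`, `block_significance()`,
   `classify_homology_layer()`);
4. ancestral-origin painting (`paint_chromosome()`, `paint_genome()`,
   `project_to_ancestral()`);
5. trajectory inference from the paint (`assemble_trajectory()`,
   `infer_chromosome_events()`, `infer_translocations()`,
   `compare_trajectories()`);
6. the combinatorial null for homoeologous fusions
   (`homoeologous_fusion_pvalue()`, `monte_carlo_fusion_null()`).

Real genome assemblies are deliberately out of scope: every stage consumes
standard formats (GFF3, 12-column similarity tables, TSV/BED/JSON), so
externally produced tables can be substituted, but all bundled analyses run
from scripted or simulated inputs.

## The event algebra and its conventions

Genes are atomic units; a chromosome is an ordered list of gene loci with a
centromere split point, each locus carrying an *origin label* (the ancestral
or reference chromosome it descends from). All split points are half-open
ordinals: a cut at $k$ separates loci $[0,k)$ from $[k,n)$.

Where the narrative model is silent, the package fixes conventions:

* **Pericentromeric window.** An NCF insertion point must lie within
  $\pm\lceil 0.05\,n\rceil$ ordinals of the recipient centromere. The width
  is a parameter (`pericentromere_frac`); 5% is the default because the
  model only says insertions target "the centromeric regions".
* **Telomere-proximal window.** EEJ cuts (and simulated NCF donor cuts)
  fall in the outermost 10% of ordinals per arm (`telomere_frac`).
* **Centromere fate.** The recipient's (NCF) or first-listed chromosome's
  (EEJ) centromere remains active; the partner's is flagged inactive and
  retained as information rather than deleted.
* **Satellite composition.** The two distal fragments concatenate
  left-fragment-then-right-fragment — arbitrary but deterministic. An EEJ
  with cuts at the very ends produces a legitimate zero-gene satellite.
* **Coordinates.** After every event, physical coordinates are recomputed
  by laying genes end-to-end with their original lengths and a fixed 10 kb
  inter-gene gap. The model itself never tracks base pairs through events,
  but the chaining gap penalty needs distances.
* **Script portability.** Event scripts may give cuts as fractions of the
  current chromosome length and insertion points as `"centromere"` or as a
  fraction of the pericentromeric window half-width, so one fixture replays
  identically at any simulation scale; integer ordinals are also accepted.

The bundled fixtures encode the two grass trajectories. The Triticeae
script applies four NCFs (Os10→Os5 giving T1, Os7→Os4 giving T2, Os8→Os6
giving T7, Os11→Os3), one EEJ (Os12+Os9), and one reciprocal translocation
between the two intermediates (giving T4 and T5), then drops the five
satellites: twelve chromosomes become seven. The mechanisms of the T2 and
T7 fusions are reported only in aggregate ("4 NCFs and 1 end-end merge"),
so the script encodes them as NCFs with figure-derived direction, noted in
the fixture comments. The Brachypodium script applies seven NCFs (Os7 then
Os6 into Os3 giving Bd1; Os5→Os1 giving Bd2; Os8 and Os10 into Os2 giving
Bd3; Os11 and Os12 into Os9 giving Bd4; Os4 untouched as Bd5) and drops
seven satellites: twelve become five. Where the order of two sibling
insertions is undetermined (Bd3), the script fixes one order; both orders
give the same paint and the same homoeology count.

```{r replay}
g <- run_simulate(fixture_script("brachypodium"), genes_per_chrom = 100)
traj <- assemble_trajectory(paint_from_origins(g), os_homoeolog_pairs())
traj
```

## Homoeology and the shipped pair map

The twelve rice-like reference chromosomes descend from seven ancestral
pairs; the classical duplicated-block pairing (1–5, 2–4, 2–6, 3–7, 3–10,
8–9, 11–12, with chromosomes 2 and 3 each combining two ancestral units)
ships as `inst/extdata/os_homoeolog_pairs.tsv` and is configuration, not a
derived result. An event is flagged *homoeologous* when the invading
chromosome's lead origin label is paired with **any label already present
on the invaded chromosome at event time**. This at-event-time rule is a
deliberate design choice: it makes the flag identical whether computed
during replay (from the true chromosome contents) or during inference
(from the nesting order of the paint), and under it the Brachypodium
trajectory has exactly three homoeologous fusions of seven — Os7 into Os3,
Os5 into Os1, and the second Bd4 insertion, whose invader is the homoeolog
of the already-nested partner — while the Triticeae trajectory has none.
For sibling insertions whose true order is unknowable from the paint, the
order is fixed left-to-right along the chromosome; the homoeologous *count*
is invariant to that choice for the bundled trajectories.

The Os→A1–A7 projection map used by the dual-scheme karyogram display also
ships as an editable table (`os_to_proto_map()`): chromosomes 2 and 3
straddle two ancestral units, so their whole-chromosome assignment is an
explicit approximation.

## Collinearity detection

Similarity hits are filtered to the best five non-self hits per query at
E ≤ 1e-5, deduplicated, and pruned of gene families with 30 or more members
on a single chromosome (the two printed variants of that threshold, "30 or
more" and "more than 30", are reconciled in favour of the stricter
reading, and the cutoff is a parameter). Anchors are then chained per
chromosome pair and orientation by sparse dynamic programming with the
scoring scheme: per-anchor match score $\min(-\log_{10} E,\, 50)$, a gap
penalty of 1 per 10 kb of inter-anchor distance summed over both
chromosomes, and at most $mg = 40$ intervening genes on either chromosome
between consecutive anchors. The printed form of the match score,
"min(log10 E, 50)", is read sign-corrected: $\log_{10}E$ is negative for
any significant hit, so the literal reading would never engage the cap.
Chains are peeled greedily best-first (each anchor belongs to at most one
block), with deterministic tie-breaking.

No single closed form for block significance is canonical in this family of
collinearity methods, so two estimators are provided and selectable: a **closed-form approximation** treating anchors as a Poisson
field — with homolog density $p$, a chain step across an observed gap
window of $(g_a{+}1)(g_b{+}1)$ cells succeeds with probability
$1-(1-p)^{\text{cells}}$, and the block E-value is the pair count times the
product of step probabilities — and a **permutation null** that shuffles
the subject chromosome's gene order, re-chains, and fits a Gumbel tail to
the permuted maxima. The closed form is the fast default; the permutation
scheme is the independent oracle used in testing (at hundreds of
replicates with the tail fit, rather than brute-force shuffle counts).
Blocks need at least `min_anchors = 5` anchors and E ≤ 1e-10.

Blocks are classified **primary** (orthologous: the best-scoring block over
a region) or **secondary** (paralogous, from the ancestral polyploidy);
self-comparison blocks are always secondary.

## Painting and its smoothing rules

Painting assigns each extant chromosome an ordered sequence of
ancestral-origin segments. It operates at **anchor resolution**: every gene
claimed by an anchor of a significant block votes for that block's
reference chromosome, weighted by the anchor match score (ties by block
score, then lexicographic label), and gene-level claims collapse into
maximal same-label runs. Block-footprint resolution was rejected after
simulation showed that a chain drifting from orthologous into paralogous
territory — profitable under any positive match score — can claim a whole
region under the wrong label; per-gene votes let the stronger orthologous
anchor win locally. Two smoothing rules then apply, in order:

* a run with fewer than `min_segment_anchors = 5` supporting anchors is
  kept if its label also has a well-supported segment on the same
  chromosome (it is then the thin flank of a nested insertion near a
  segment boundary), absorbed into its flanks when both neighbours agree,
  and dropped otherwise;
* if the retained label spans *cross* (which no combination of nesting and
  concatenation can produce), weak runs involved in the crossing are
  removed weakest-first until the spans form a laminar family.

A deliberately small complementary mechanism feeds these rules: chains
failing the block filters but carrying at least two anchors are retained as
`rescued` low-confidence evidence for painting only (an enrichment of small
homologous blocks), never reported or classified as blocks. Without it, a
three-gene insertion flank isolated by the $mg$ constraint loses its
anchors entirely and the nesting becomes unrecoverable.

## Trajectory inference

The collapsed label sequence of each chromosome is parsed as a laminar
family of label spans: a span nested inside another's witnesses
NCF(inner into outer); the ordered top-level spans witness EEJs with the
junction-adjacent labels; a single span is an unrearranged chromosome.
Sequences whose spans cross (e.g. X,Y,X,Y) are flagged `AMBIGUOUS` rather
than guessed. Before per-chromosome parsing, reciprocally exchanged
terminal runs between two chromosomes — each arm foreign to its host's core
but continuing a label split with the partner — are detected as one
reciprocal translocation and stripped, so the parser sees the
pre-translocation cores. Inversions are not called from paint (they do not
change labels; they appear only as reversed block orientation in dotplots).

Counts aggregate as in the model: every NCF and every EEJ implies exactly
one satellite, so the initial chromosome count equals the final count plus
the implied satellites. Nested-fusion events keep their direction
(invading→invaded); EEJ and translocation label pairs are canonicalized as
unordered, which makes the inferred event multiset invariant under
chromosome orientation.

Known limitations, surfaced rather than hidden: a translocation whose cut
falls *inside* a nested segment leaves that segment's label split across
both products; the translocation itself is still detected, but the stripped
cores read as concatenations. Insertions closer than the paint resolution
(five genes) to a segment boundary may be attributed to the enclosing
rather than the split label under heavy gene loss. The temporal order of
independent events on different chromosomes is not inferred.

## The synthetic generator and what passing tests mean

`random_trajectory()` draws event types from configurable weights, with
participants and breakpoints uniform within the model's windows. Nested
fusion donors are drawn from single-origin (not previously fused)
chromosomes — an explicit model assumption, consistent with all eleven
fusion events in the two grass trajectories, and what makes paint-based
recovery well-posed. `emit_similarity()` draws $\log_{10}E$ per homology
layer — Normal(−80, 10) for same-lineage orthologs, Normal(−30, 10) for
homoeologous outparalogs, truncated to $[-180, 0]$ with self-hits at the
floor — so ortholog scores stochastically dominate; only this ordering, not
the absolute values, matters downstream. Genes are a uniform 2 kb with
10 kb spacing so the gene-count gap cap and the per-10 kb penalty interact
deterministically.

The end-to-end recovery study (`event_recovery_trial()`) builds a
seven-chromosome proto-genome of 100 genes per chromosome, duplicates it,
fractionates duplicate copies at the configured retention rate, applies
2–6 random NCF/EEJ events, and runs the full similarity pipeline against
the intact post-duplication reference. At these sizes a trial runs in
about a second, and the bundled acceptance checks use 20 seeds per
retention level; scale parameters up freely for heavier experiments. The
generator emulates layered E-values, fractionation, and rearrangement; it
does **not** model sequence evolution, tandem duplication, repeat content,
or assembly error, so passing recovery tests demonstrate correctness of
the inference machinery under the model's own assumptions, not performance
on real assemblies.

## The homoeologous-fusion null

Under the null, successive fusions pair uniformly random chromosomes
without replacement from the pool of $2m$ chromosomes in $m$ homoeologous
pairs. The probability that $k$ successive fusions each join a surviving
homoeologous pair is

$$P = \prod_{i=0}^{k-1} \frac{m-i}{\binom{2m-2i}{2}},$$

evaluated in exact integer arithmetic; for $m=7$, $k=3$ this is
$210/270270 \approx 0.00078$ (reported at two significant figures). Note
the quantity is the occurrence probability of the observed sequence, not a
tail probability; `monte_carlo_fusion_null()` therefore reports, clearly
labelled and side by side, (a) the probability that the first $k$ draws
are all homoeologous — the oracle for the closed form, simulated via the
equivalence between sequential uniform pairing and consecutive pairs of a
uniform permutation — and (b) the probability of exactly/at least $k$
homoeologous fusions among all $n$ observed fusions, each with its binomial
standard error. The closed form is strictly decreasing in $k$ except at
$k=m$, where the last fusion is forced.

```{r stats}
fusion_null_summary(fusion_null_params(n_pairs = 7, k_homoeologous = 3,
                                       n_fusions_total = 7, reps = 2e4))
```

## Rendering

`render_dotplot()` and `render_karyogram()` write SVG directly with fixed
number formatting and stable element ordering, so output is byte-identical
across runs — a testable contract. Dotplots colour hits by rank
(best/second/other) or homology layer; karyograms draw each chromosome as
a vertical bar split between the seven-proto-chromosome and
twelve-reference colour schemes (the palette ships as editable JSON; hues
are an approximation of the conventional grass palette). Trajectories are
presented as static vector frames; no animated output is produced.

## Reproducibility

Every stochastic stage takes an explicit seed; `run_full()` fans a single
global seed out to per-stage seeds by stable hashing, so stages are
independently reproducible. Genome serialization is deterministic JSON.
`scripts/acceptance.R` recomputes the three headline quantities (the
closed-form probability; the 12→7 and 12→5 reductions) from scratch
against the installed package.
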