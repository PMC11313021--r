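---
title: "Hybrid scaffolding with contigwire: model, parameters and design choices"
author: "contigwire authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid scaffolding with contigwire: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigwire)
```

## The problem

A draft assembly built from short reads arrives as contigs: accurate but
fragmented sequences whose order, orientation and spacing along the genome
are unknown. High-fidelity long reads (HiFi-class, ~10 kb, sub-percent
error) individually span several contig junctions and can therefore supply
exactly the missing information. contigwire consumes a contig FASTA and a
long-read FASTA/FASTQ and produces scaffolds: ordered, oriented sequences
of contigs with the intervening gaps filled by spanning-read bases where a
read covers them, together with an AGP 2.1 component map. The two
objectives are the usual ones for scaffolding: as few scaffolds as possible
(recall) without misordering, misorienting or misspacing contigs
(precision).

## The model

### Alignment-free end-mapping

Base-level alignment is unnecessary for deciding *which* contigs a read
touches. Each subject sequence is decomposed into canonical
(w, k)-minimizers (defaults k = 15, w = 10, chosen so that a 2 kb window
yields ~360 minimizers — dense enough for a stable sketch, sparse enough to
be cheap); a minhash sketch of T = 30 trials fingerprints each minimizer
set, and the fraction of agreeing sketch slots is an unbiased estimate of
the Jaccard index of the two sets (verified by the calibration tests
against exact Jaccard values).

Two asymmetries of scale are handled explicitly:

* **Query side.** Only the two `end_len` = 2000 bp ends of a read are
  sketched (labels 5p/3p; a read shorter than `end_len` is sketched whole).
  The interior of a long read maps nothing and would only dilute the
  estimate; the ends are what link two distant contigs.
* **Subject side.** Subjects are sketched in `end_len`-sized windows with
  half-window stride, and a subject's similarity to a read end is the
  maximum over its windows. Without this, a 2 kb end contained in a 30 kb
  subject has Jaccard ~0.07 regardless of a perfect match, and the
  similarity threshold becomes meaningless once subjects grow (as they do
  in the later phases, where partial scaffolds play the subject role).

A read end reports its best subject when the similarity reaches
`tau` = 0.2, and only the top `top_n` = 1 subject. Top-1 reporting means a
read maps to at most two contigs — one per end. Reporting secondary hits
(`top_n > 1`) is supported but not the default: near an exact repeat, a
read's end matches the true local subject *and* the other copy's flank, and
those secondary tuples inject chimeric cross-repeat edges into the graph;
with top-1 the true subject always outranks the partial repeat match.

### The contig graph

Grouping mapping tuples by read, every pair of distinct contigs mapped by
one read contributes that read's id to the pair's link set; an edge's
support is its link-set size. All contigs are vertices, so unmapped contigs
survive as isolated vertices and ultimately as singleton scaffolds —
dropping them would silently lose genome fraction.

Because the study regime has reads (~10 kb) longer than typical contigs
(~5 kb), a read frequently has its two ends in the contigs *flanking* a
short contig, creating a "skip" edge that parallels the two-step chain
through the middle. Skip edges inflate degrees and mislead any purely local
edge-choice rule. `reduce_transitive()` removes them the way string graphs
are reduced: edges are visited weakest-first and dropped when their
endpoints remain connected through a common neighbor. True chain edges
survive because their parallel long-range edges are weaker and disappear
first. The reduction is on by default (`cw_config(reduce = )`).

### Wiring

Wiring decides, independently at every vertex, which single pair of
incident edges a path may use through that contig — the step that keeps
path enumeration linear-time and repeat-safe. The ranking at a vertex is:

1. shared link-set size |L_i ∩ L_j| between the two edges (reads directly
   witnessing a through-path), then
2. combined edge support |L_i| + |L_j| (preferring the two strongest
   direct junctions over weak long-range edges), then
3. lexicographic order (a deterministic, input-order-free tie-break).

Degree-one vertices are wired against a dummy placeholder; degree-two
vertices always wire their unique pair (a chain vertex has one predecessor
and one successor — there is nothing to decide, and demanding shared reads
would require reads mapped to three contigs, which top-1 end-mapping
essentially never produces). At a branching vertex (degree ≥ 3) the top
pair must strictly beat the runner-up on criteria 1-2; a tied branch
carries no usable routing evidence and stays unwired, terminating any walk
that reaches it.

At realistic support levels (1-6 reads per edge) such ties are common, and
the package optionally breaks them with information the ID sets cannot
carry: geometry. `wire_graph()` with sequences supplied places each
candidate neighbor and the vertex on a shared linking read via anchor
chains; admissible pairs must flank the vertex on opposite sides, and the
pair with the smallest estimated gaps wins (large implied overlaps are as
suspect as large gaps). Vertices with no admissible pair stay unwired. The
pipeline always enables this; the pure ID-set behavior remains available
and is what the wiring unit tests pin down.

### Path enumeration

Paths grow from a queue of degree-one vertices (sorted by id); at each
vertex the walk continues only if the wiring entry pairs the arrival edge
with a departure edge. A walk terminates, appending the blocking vertex,
when it (a) reaches a vertex wired to a different predecessor, (b) reaches
an already-visited vertex, or reaches an unwired branch vertex; it
terminates normally at degree-one vertices. Three guarantees follow, and
are asserted over hundreds of random graphs in the test suite: no two
paths share an edge; no path revisits a vertex; and the output path set is
identical under any processing order.

Three small completions keep the bookkeeping exact:

* Pure-cycle components never reach the queue, so each is seeded from its
  smallest-id wired vertex; the visited check then clips the final edge,
  so a consistently wired triangle yields one two-edge path and the third
  edge stays unused.
* A walk closing onto its own start does not append the start again —
  appending would re-create precisely the cycle the termination rules
  exist to prevent.
* Terminal steps appended by cases (a)/(b) and unwired-vertex stops are
  "borrowed": they stay in the path (they are real evidence of where the
  walk stopped) but are excluded from ownership, so every contig is owned
  by exactly one path (its own singleton, if nothing else claims it). A
  contig inside an exact repeat can therefore appear as an interior step
  of at most one path — the structural property that limits repeat-driven
  chimerism.

### Batching and stitching

Paths are packed into batches of at most `batch_size` = 8192 contigs by
greedy first-fit in descending length (an oversize path forms its own
batch); batches are independent units of assembly work. The built-in
stitcher turns each path into sequence: for every consecutive owned pair it
scans the edge's linking reads, places both contigs on each read by anchor
chains (`anchor_k` = 21-mers unique in both sequences, densest diagonal
band, at least `min_anchors` = 5 anchors), and accepts the best-supported
placement that is geometrically consistent — second contig to the right of
the first, extending beyond it, with any implied overlap verified to be
genuinely shared sequence by k-mer agreement (a repeat-mediated pile-up
agrees only across the repeat copy and is rejected). A consistent
placement either merges an overlap (contig bases preferred over read
bases) or inserts the read's intervening bases as a gap-filling component
with full provenance in the AGP. Orientations propagate along the path; the
seed contig of a segment is re-oriented freely at its first junction, which
is what lets a scaffold grow leftward in genome coordinates.

When no linking read places a junction consistently, the default is to
*split* the scaffold there (`junction_fallback = "split"`): with ~10 reads
per true junction, unanimous geometric inconsistency is evidence the
adjacency was spurious, and bridging it with Ns would manufacture exactly
the misjoin the split avoids. The conventional N-gap join
(`junction_fallback = "gap"`, `gap_default` = 100 N) remains available.

### The three phases

1. **Contig expansion** maps reads to contigs and runs
   graph → wiring → paths → stitching, yielding first-generation partial
   scaffolds. Every read with at least one mapping tuple counts as used.
2. **Long-read island construction** remaps the unused reads against the
   gen-1 scaffolds; reads that now map are set aside as bridge candidates,
   and the rest — reads from regions no contig covers — are assembled into
   island scaffolds by the same machinery with the reads themselves in the
   subject role.
3. **Bridge linking** reruns the expansion machinery with all partial
   scaffolds as subjects. Two departures from a single literal pass make
   this phase effective: the query set defaults to *all* non-island reads
   (`bridge_reads = "all"`), because reads whose ends straddled a contig
   boundary in phase 1 map cleanly to the longer scaffold flanks and are
   precisely the missing-junction evidence; and the phase iterates to a
   fixpoint (`bridge_rounds`, default cap 4, stopping as soon as a round
   merges nothing), because while partials remain shorter than a read,
   skip edges dominate, and each round of lengthening makes junction
   evidence denser until convergence. Partials wholly contained in a
   linked partial are set aside before wiring (they only duplicate
   sequence and distort branch decisions) and pass through unchanged.

Used-read sets reported for the three phases are pairwise disjoint. Any
contig whose component citation is consumed by overlap deduplication during
merging re-enters the output as a pass-through singleton, so every input
contig appears exactly once across final component lists.

## Synthetic data and what the tests do (and do not) show

`simulate_scaffolding_dataset()` generates the reference study conditions:
a 200 kb i.i.d. random genome at GC 0.5 with one exact 3 kb repeat in two
copies; contigs shredded directly from the genome (lognormal lengths, mean
5 kb, CV 0.5, random strand, exponential gaps tuned to 85% coverage) —
shredding preserves the fragment-length, gap and strand structure a
short-read assembler would produce without requiring one; and long reads at
10x coverage, normal lengths with 10 kb median and 3.4 kb s.d. truncated at
1 kb, random strand, uniform substitution errors at 0.2%. All generators
are pure functions of their seed, and truth placements are recorded so
evaluation is exact rather than alignment-based.

Passing on these conditions demonstrates the algorithmic machinery —
end-mapping sensitivity, graph construction, wiring decisions, repeat
handling at the planted-repeat scale, gap filling, phase bookkeeping. It
does not demonstrate robustness to homopolymer indels or chimeric reads
(not simulated), to diploid heterozygosity, to repeat families longer or
more numerous than the planted one, or at chromosome scale. On the planted
conditions the pipeline typically reaches ~35-45x the input-contig NG50
with zero misjoins and ~99% genome fraction; when the two repeat copies
happen to land within a read length of each other, locally consistent
cross-copy joins can survive every guard, and occasional single misjoins
near such repeats are the known failure mode.

## Numerical and degenerate-input choices

* Sketch hashes are a fixed splitmix64-style mixer masked to 53 bits, so
  values are exact in doubles and identical across platforms; the mask is
  applied before the per-trial minimum so sketches are true minima of the
  reported values.
* Similarity ties in mapping are broken by subject id; wiring ties as
  described above; batch packing is stable; every stage iterates in sorted
  order — a fixed configuration reruns byte-identically.
* Sequences shorter than k + w − 1 are unsketchable: as subjects they are
  reported once and never matched; as read ends they produce no tuples.
* K-mers containing N are skipped everywhere (minimizers and anchors).
* IUPAC codes other than N are replaced by N on input with a warning.
* Anchor chains use the densest diagonal band (width `band` = 50 bp, ample
  for substitution-only HiFi error at 0.2%) and the median in-band
  diagonal as the offset estimate; `anchor_k` is capped at 26 so packed
  k-mer codes remain exact in doubles.
* `nx_metric()` returns 0 when the threshold is unreachable, and NG50-type
  calls simply pass the genome length as the denominator.

## Evaluation

`evaluate_against_truth()` works entirely from simulation truth: each
scaffold component maps to a genome interval by composing its scaffold
orientation with its source's truth strand. An adjacent component pair is a
misjoin if composed orientations differ, genome order contradicts scaffold
order, or the genome gap deviates from the scaffold gap by more than
`slack` (default 2000 bp, on the order of the mapped end length; evaluation
counts read-derived gap fillers too, since reads carry truth placements).
Reported metrics are N50, NG50, `ngm50` (NG50 after splitting scaffolds at
misjoined adjacencies — the truth-based analogue of alignment-corrected
NG50, which would otherwise require a genome aligner), genome fraction,
duplication ratio, misjoin count and adjacency accuracy.

## Worked example

```{r example, eval = FALSE}
library(contigwire)

ds <- simulate_scaffolding_dataset(seed = 1)
res <- run_pipeline(ds$contigs, ds$reads, workdir = "cw_out")
metrics <- evaluate_against_truth(
  res$final, rbind(ds$truth_contigs, ds$truth_reads), ds$genome_length)
metrics
nx_metric(nchar(ds$contigs), ds$genome_length) # input-contig NG50
```

The same computation is scripted end to end in `scripts/acceptance.R`,
which also measures the wiring guarantees and sketch calibration and
writes all quantities to JSON.
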