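---
title: "Hybrid assembly with a synthetic scaffolding graph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid assembly with a synthetic scaffolding graph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Short-read assemblies are accurate at the base level but fragment at
repeats; long reads (nanopore, PacBio) span repeats but carry 5–15% error.
The classical long-read route — all-versus-all read overlap, layout,
consensus — is expensive and pushes the error problem into heavy polishing.
`ssga` implements the alternative strategy of *starting* from short-read
contigs and using the long reads only where they add information: ordering
and orienting the contigs, and supplying sequence for the gaps between
them.

The device that makes this work is the **synthetic scaffolding graph
(SSG)**. From each long read we cut *synthetic mate pairs*: two 250-bp
pseudo-reads at a chosen distance *d* (the insert), in forward–reverse
orientation, sliding along the read in 150-bp steps. Repeating this over a
*spectrum* of insert sizes converts one long read into mate-pair libraries
at every scale from 0.5 kb up to (for ultralong reads) hundreds of kb.
Because each synthetic pair remembers the read it came from, its offset,
and the *inner sequence* between its mates, the graph built from these
pairs carries the full long-read information without any read-to-read
alignment.

The pipeline stages, each its own module surface:

1. **Contig QC** (`run_contig_qc`): short reads are pseudo-aligned back to
   the draft contigs; proper pairs become physical fragments; maximal
   intervals of fragment coverage below a depth threshold (default 7) are
   low-quality intervals (LQIs), classified as internal/start/end/whole,
   and contigs are split/trimmed there. This removes chimeric joins the
   de Bruijn assembler made inside repeats.
2. **Pseudo-alignment** (`build_index`, `map_sequence`, `map_pair`):
   canonical (w,k)-minimizers (2-bit packed, invertible 64-bit mix, so the
   sketch is deterministic and seedless) with per-(target, strand)
   co-linear chaining by longest strictly increasing subsequence. Mapping
   quality is `60·(1 − s2/s1)` over the best and second-best chain scores —
   the second-best is searched both across targets and *within* the best
   target group, so a two-copy repeat forces quality 0. Presets: `shortr`
   (10,21), and the synthetic presets (5,20) with 250-bp mates; `pacraw`
   adds homopolymer compression. Pairs are accepted only when both mates
   exceed the preset's mapping-quality and coverage thresholds strictly
   (>30 / >50% short; >40 / >65% synthetic).
3. **SSG construction** (`build_ssg`): an accepted inter-contig pair adds a
   mate edge between the contig-end vertices the mates point past, with
   length `l(e) = x − (l_i − pos_f) − (l_j − pos_r)` (the insert minus the
   two contig overhangs, positions normalized to the end each mate points
   away from; negative lengths = overlapping contigs). Edges between the
   same vertex pair are bundled by inverse variance: `l = p/q`,
   `σ = sqrt(1/q)`, `w = Σw_i`, with per-library `σ` attached to the raw
   edges. The labeling function maps every edge to the set of long reads
   that generated it.
4. **Repeat masking and transitive reduction** (`mask_repeats`,
   `transitive_reduce`): unique coverage `ū` is estimated from the longest
   10% of contigs; contigs above `1.5·ū` are masked. Mate edges are then
   processed in ascending length; an edge *e* is removed when a
   *long-read-coherent* path *P* exists between its endpoints —
   `|l(e) − l(P)| ≤ 4·max(σ(e), σ(P))` and `F(e) ⊆ F(edge)` for every edge
   of the path — and its weight is added to every mate edge of *P*. Each
   reduction is an implicit long-read overlap; the (edge, path) records
   form the path database used later.
5. **Backbone** (`matching_cover`, `break_cycles_extract_lines`,
   `validate_backbone`): a maximum-weight matching over unmasked mate edges
   of weight ≥ 5 (contig ends matched at most once); contig edges are added
   back, cycles destroyed at their lightest mate edge, and the resulting
   vertex-disjoint paths (*lines*) give contig order and orientation.
   Joins not covered by long-read physical fragments (reads ≥ 20 kb, or
   reduced edges whose in-line path length matches) are split when fewer
   than 4 reads support them.
6. **Gap filling** (`build_read_db`, `window_consensus`, `fill_gaps`): per
   matched edge, the 20 reads contributing the most synthetic pairs are
   selected (the top contributor is the template); reads are aligned to the
   template with a banded edit-distance DP, cut into 500-bp template
   windows, chunks under 65% identity dropped, and each window called by a
   partial-order-alignment consensus; contig ends (2-kb anchors) are then
   aligned into the consensus to fix the boundaries and splice the line
   sequence. Contig bases are never rewritten.
7. **Polishing** (`graph_polish`, `alignment_polish`, `emit_assembly`):
   leftover (masked/singleton) contigs are placed onto the filled consensus
   intervals — first via long-read-coherent paths with the backbone contigs
   masked, then via a (5,17)-minimizer scan with greedy non-overlapping hit
   layout — and spliced in when their alignment identity reaches the depth-
   dependent expectation (80% at depth 1 rising linearly to 99% at depth
   20) and covers at least 75% of the contig. The final assembly is one
   record per line plus unused contigs above 5 kb.

## The synthetic-data generator

`simulate_genome` plants mutated repeat families (per-base substitution at
the divergence rate) at disjoint loci in a uniform random chromosome.
`simulate_long_reads` draws lengths from a log-normal (sdlog 0.5)
truncated at a minimum, samples both strands uniformly, and injects
substitutions/insertions/deletions with an indel multiplier inside
homopolymer runs ≥ 3 — a caricature of the dominant nanopore error mode.
`simulate_short_pairs` produces error-free forward–reverse pairs with
Normal insert sizes: short-read error is not what any downstream stage
exercises, contig correctness is. `make_draft_contigs` cuts the genome at
random positions; by default the fragments tile the genome exactly, and an
optional per-break deletion (`gap_min`–`gap_max`) emulates the sequence a
short-read assembler loses around repeats and coverage troughs. Chimeric
drafts are fabricated by concatenating fragments ≥ 50 kb apart, with the
junction recorded.

The demonstration conditions (`demo_assembly`) are fixed: two 2-kb repeat
families at 4 copies and 2% divergence; 30× long reads of mean 15 kb
(minimum 1 kb) at 5% total error (2% substitution, 1.5% + 1.5% indel,
homopolymer bias 1.5); draft breaks every ~10 kb with deleted gaps uniform
on [0, 5000] bp. Gaps must vary for a gap-length-fidelity measurement to
be meaningful at all — with exact tiling every true gap is 0 and a
correlation is undefined in practice — and a 0–5-kb loss per break is a
realistic portrait of a draft assembly's repeat shadows.

What the generator does **not** model: diploid heterozygosity, chimeric
long reads, non-uniform coverage, context-dependent error, and real repeat
family structure (LINE/SINE nesting). Passing tests therefore demonstrate
algorithmic correctness under idealized noise, not performance on real
genomes.

## Numerical and design choices

* **Pair-filter coverage** is the fraction of read bases *inside the
  chain* (first to last chained anchor). The anchor footprint itself would
  be useless on error-bearing reads: at 5% error only ~36% of 20-mers are
  clean, yet the chain still spans the read.
* **Minimizer ties** select the leftmost minimal k-mer per window; the
  anchor-frequency cutoff (minimizers seen > 500 times in the index) keeps
  chaining near-linear on repeat-dense targets.
* **mapq formula**: only the ordering property (a strong secondary chain
  lowers confidence) is contractual; `round(60(1 − s2/s1))` is this
  package's concrete choice.
* **Spectrum**: the 24-entry schedule is dense (0.5–10 kb in 1-kb-ish
  steps) below 10 kb and takes decade steps above, spanning 0.5–200 kb;
  non-ultralong presets truncate at twice the read-length N50. Library
  `σ = max(50, 0.10·insert)`: long-read indels make distance error roughly
  proportional to the insert; the floor keeps small libraries from
  claiming unrealistic precision. Exposed via `default_spectrum()`.
* **Insert statistics**: sample moments after discarding distances above
  10× the median; fragments require the expected orientation and a
  distance within `x̄ ± 2.5σ`, and additionally near-full-length mate
  spans (≥ 85%) — a clipped mate is the signature of a junction and must
  not blanket the coverage dip it sits on.
* **LQI terminus exemption**: contig ends cannot accrue full physical
  coverage (no pair extends past an end), so terminal low-coverage runs no
  longer than the insert mean are tolerated. Without this every contig
  would be trimmed by an insert length at both ends.
* **Matching**: solved *exactly* per connected component of the eligible
  mate-edge graph by an O(2^n·n) subset DP (components ≤ 22 vertices),
  falling back to the sort-by-weight greedy heuristic on larger
  components. Because contig edges do not participate in the matching, the
  eligible graph decomposes into many small components and the exact path
  is the one taken in practice; the greedy fallback keeps the classical
  worst-case guarantee. Cycle ties break at the smallest edge id.
* **Reduction bookkeeping**: removing edge *e* adds `w(e)` to every mate
  edge of its path, so total weight grows by `w(e)·(|P|−1)` per reduction;
  support is never lost. DFS children are visited in ascending bundled
  length (ties by contig id) for determinism.
* **Edit alignment** is a banded unit-cost DP with traceback (default band
  15% of the longer sequence, auto-widened by the length difference),
  exact within the band and verified against a full-matrix oracle; the
  distance-only variant runs in O(band) memory for whole-assembly
  comparisons. Anchor placement uses a semi-global variant (query global,
  target free).
* **POA consensus**: graph seeded by the template chunk; each chunk
  aligned with match +2, mismatch −2, gap −2 and merged; the consensus is
  the heaviest path by *summed edge weight* (node support only breaks
  ties). Scoring node support in the path sum would let long, low-support
  detours outweigh a heavy direct edge and corrupt the consensus.
* **Per-window chunk identity** is computed from the global alignment cut
  at template window boundaries; the 65% filter is applied per chunk, and
  window depth (template + surviving chunks) is the depth used by the
  polishers' expected-identity rule, which interpolates linearly between
  the stated endpoints (80% at depth 1, 99% at depth ≥ 20).
* **Graph-polisher orientation**: a path entering a contig at its tail
  uses the forward sequence, at its head the reverse complement. The
  semi-global aligner is query-global, so the 75% contig-coverage
  condition is enforced by construction for spliced contigs.
* **Degenerate inputs**: reads shorter than the smallest insert contribute
  no pairs; an empty pair set yields a graph with contig edges only;
  windows with no surviving chunk pass the template through; a contig end
  failing its anchor alignment (identity < 0.80) leaves an N-gap of the
  estimated length, flagged in the fill report.

## Artifacts and restartability

With an output directory set, every run writes the corrected contigs, the
graph dump, the backbone table (line, order, contig, orientation, gap
estimate), the fill report and the final FASTA, plus checkpoints after the
two expensive stages (pair mapping; graph reduction). `resume = TRUE`
restarts a run from the last completed checkpoint; since every stage is a
pure function of its inputs and the seed, a resumed run reproduces the
direct run bit for bit.

## Problem sizes

The bundled demonstration and the acceptance computation use a 1-Mb
genome at 30× long-read coverage (~2,000 reads, ~1.5 million candidate
synthetic pairs, ~100 draft contigs), which exercises every stage —
repeat masking, reduction of >100 long-range edges, ~75 filled gaps —
in minutes on one core. The unit-test fixtures are one to two orders of
magnitude smaller. These sizes are the package's choice of a desk-scale
experiment; all thresholds are the defaults documented above and none
depends on the problem size.

## Limitations

* Scaffolding uses synthetic mate pairs only; real mate-pair, linked-read
  or optical-map evidence is out of scope.
* Lines mix haplotypes; there is no phasing.
* The consensus is sequence-only (no quality strings) and the POA is a
  plain scalar implementation.
* The simulator's error model is a convenience, not a calibrated
  instrument profile; absolute consensus accuracies on real data will
  differ from the simulated ones.
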