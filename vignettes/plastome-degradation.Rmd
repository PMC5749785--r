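---
title: "Methods: plastome structure, gene degradation and parsimony in plastodecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome structure, gene degradation and parsimony in plastodecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastodecay)
```

## The problem this package addresses

Chloroplast genomes (plastomes) of most flowering plants are ~140 kb circles
with a conserved quadripartite layout: a Large Single Copy (LSC) and a Small
Single Copy (SSC) region separated by two Inverted Repeats (IRa/IRb) that are
reverse complements of each other. In some lineages — typified by the
carnivorous Lentibulariaceae, where terrestrial *Genlisea* species show a
progressive loss of the eleven plastid *ndh* genes (*ndhA*–*ndhK*, subunits
of the thylakoid NAD(P)H-dehydrogenase-like complex) — individual genes decay
through a recognizable series of states: an intact gene accumulates lesions
(lost start or stop codon, internal stop, frameshift) and becomes a
**pseudogene**; further erosion leaves only a short positional remnant, a
**fragment** (also called a *decayed* gene); finally the locus is **deleted**
outright. Comparing these states across species, and tracing them on a
phylogeny, is the core analysis this package automates — together with the
supporting statistics such comparative studies report: composition and codon
usage, repeat content, divergence hotspots, and maximum-parsimony tree
statistics.

Because real accessions cannot be bundled, every stage is exercised against a
**synthetic plastome generator** with known ground truth; the simulator is
first-class, tested code, not a fixture.

## Gene state calling

`locate_gene()` finds local alignments of a reference CDS against both
strands of a query genome (Smith–Waterman via `Biostrings`, match +2,
mismatch −3, gap open 5, gap extend 2, iterating with masking to collect
multiple hits). Hits must be ≥ 25 bp long at ≥ 70% identity — the 25 bp floor
is the field's detection limit for recognizable gene remnants. On top of
these floors sits a significance filter (`min_score = 40`, i.e. 20 matched
bases net): under Karlin–Altschul statistics for this scoring scheme, score
40 corresponds to an expectation well below 10⁻³ against a plastome-sized
sequence, whereas unfiltered 25 bp/70% windows arise by chance several times
per genome and would turn truly deleted loci into phantom fragments.

`classify_gene_state()` then applies the four-state scheme:

| state | rule |
|---|---|
| deleted | no qualifying hit |
| fragment | reference coverage ≤ 0.20 (every hit still ≥ 25 bp) |
| complete | coverage ≥ 0.95 and an intact frame: ATG start, terminal stop, no internal stop, no frameshift |
| pseudogene | anything else disrupted; lesions `no_start` / `no_stop` / `internal_stop` / `frameshift` reported as evidence |

Choices worth stating explicitly:

* **Coverage floors.** The 0.20 fragment/pseudogene boundary operationalizes
  the ">20% of the coding region" pseudogene convention; the 0.95
  completeness floor is this package's own choice (no explicit criterion
  exists in the literature we mirror). Coverage is measured on nucleotide
  alignments.
* **Pseudogene without a listed lesion.** A locus with 0.20 < coverage <
  0.95 and a pure in-frame internal deletion carries none of the four
  canonical lesions. It is still called a pseudogene (it is neither complete
  nor a fragment); no generator recipe produces this case, but the rule is a
  deliberate superset so odd empirical loci do not fall through.
* **Boundary fuzziness.** A remnant within a few bp of a floor can land on
  either side because a local aligner may extend an exact remnant by a few
  lucky flanking matches — exactly as BLAST would. The generator therefore
  truncates fragments to 30 bp (strictly above the 25 bp floor) and uses
  genes ≥ 80 codons, so every planted state is unambiguous.
* **IR-duplicated genes** are scored once, preferring the most intact copy;
  the degradation simulator refuses to edit IR genes so the
  IRb = revcomp(IRa) invariant always holds.

`encode_ndh_matrix()` codes the 11 genes into 22 characters: characters 1–11
absent (0) / present (1); characters 12–22 pseudogenized (0), decayed (1),
complete (2), with `-` (inapplicable) exactly when the gene is absent —
complete → (1,2), pseudogene → (1,0), fragment → (1,1), deleted → (0,−).

## Quadripartite detection

`detect_quadripartite()` works on the doubled sequence (so rotation of the
circular molecule is immaterial), seeds on exact 25-mers shared between the
sequence and its reverse complement, clusters seeds per anti-diagonal, and
extends each cluster with an X-drop scheme (match +1, mismatch −3, drop 12)
that trims at the score maximum — exact planted IRs recover their exact
boundaries, and ≤ 1% scattered mismatch is tolerated. The larger inter-IR
segment is the LSC, ties broken by the lexicographically smaller segment;
output is rotated so the LSC starts at position 0. A genome without an
inverted pair ≥ `min_ir` (default 1000 bp) is reported as single-copy, not an
error.

## Repeats

`find_ssrs()` reports maximal perfect tandem runs with primitive units of
1–6 bp meeting MISA-style copy minima (mono ≥ 10, di ≥ 6, tri–hexa ≥ 5 —
the conventional settings; the tool we mirror does not list its own). Runs
whose unit is itself periodic are reported at the smallest period, and a run
contained in a kept run of smaller period is dropped. Compound/interrupted
SSRs are not merged (no merging distance is defined anywhere we could
borrow from).

`find_long_repeats()` mirrors a REPuter-style search: interval pairs ≥ 30 bp
whose second copy matches the first (direct) or its reverse complement
(palindromic) with ≤ 3 Hamming mismatches *and* ≥ 90% identity (both filters
hold). "Maximal" is made precise per (anti-)diagonal: a window bounded by the
4th mismatch or the sequence end on each side. Several shift-variants of one
underlying repeat can all be maximal under that definition; overlapping
windows on the same diagonal are collapsed to the best-scoring
representative. The full IRa/IRb pair necessarily appears as one giant
palindromic hit; it is reported but flagged `is_ir_pair` so summaries can
exclude it. Exact seeds of length ⌈(min_len − k)/(k + 1)⌉ cannot miss a
qualifying window (pigeonhole), so seeded search and the brute-force
all-diagonal oracle in the test suite agree exactly.

## Divergence statistics

`p_distance()` uses pairwise deletion: compared sites are columns where both
rows hold A/C/G/T; gaps and N are ignored, and a pair with zero comparable
sites yields `NA`. Site classes follow the standard definitions (variable:
≥ 2 states among A/C/G/T; parsimony-informative: ≥ 2 states each in ≥ 2
taxa; gaps/N never count as states). Per-partition means are unweighted over
all taxon pairs. `spearman_rho()` uses average ranks for ties and the
two-sided t-approximation p-value. `rank_hotspots()` sorts by PIC count
descending, ties by mean p-distance descending, then name — so marker
ranking is fully deterministic. Alignment construction itself is out of
scope: all statistics operate on any supplied aligned matrix.

## Maximum parsimony

All characters are unordered with unit costs; `?` (missing) and `-`
(inapplicable) are treated as the full state set in every pass — the
standard treatment, and the only one the classic software applies to such
codings. `search_mp()` offers:

* **exhaustive** (n ≤ 9): every unrooted topology, scored by a bitmask
  Fitch pass over unique site patterns (duplicate columns are collapsed with
  weights; columns with a state shared by all tips are dropped — both
  transformations leave tree lengths unchanged).
* **branch_and_bound** (n ≤ 16, the default): exact; partial trees whose
  length already exceeds the best complete tree are pruned; the initial
  bound comes from a stepwise-addition tree, and taxa are added
  farthest-first by Hamming distance (order affects speed only, never
  exactness). All minimal topologies are collected, deduplicated by
  canonical bipartition-set hashing.
* **heuristic**: random-addition replicates followed by SPR hill climbing.
  The classic heuristic uses TBR; SPR is a strict subset of the TBR
  neighbourhood and, at the ≤ 16-taxon scales this package targets (where
  branch-and-bound is exact and affordable), the heuristic is only a
  fallback — this is a deliberate simplification.

`ci_ri()` computes CI = Σm/Σs and RI = (Σg − Σs)/(Σg − Σm) over all
characters by default (the headline figure of the classic software), with
`informative_only = TRUE` as the documented alternative. `CI = 1` is
returned when Σs = 0 and RI is `NA` when Σg = Σm.

`acctran_map()` roots on a named outgroup and resolves the ambiguity among
Fitch-optimal reconstructions by accelerated transformation, implemented as
a Sankoff pass that minimizes the pair (changes, Σ depth of change edges)
lexicographically — placing changes as close to the root as possible, i.e.
preferring an early gain plus a reversal over two parallel gains. Traceback
ties prefer the parent's state, then the lowest state symbol, so the mapping
is deterministic. The per-character change counts always equal the Fitch
length (asserted by an enumeration oracle in the tests).

`bootstrap_support()` resamples characters with replacement, repeats the
search, and scores each bipartition by the fraction of replicates whose
strict consensus contains it. `strict_consensus()` delegates to
`ape::consensus(p = 1)`; the test suite verifies it against an independent
bipartition-set intersection.

## The synthetic world

`build_plastome()` lays out LSC | IRa | SSC | IRb with IRb the exact reverse
complement of IRa. The desk-scale default is ~14 kb — one tenth of a real
plastome — so complete pipelines run in seconds; a 140 kb "paper" preset
exists for stress testing. The roster carries the 11 ndh genes (80–100
codons each at desk scale; real ndh genes are larger, but proportions are
preserved), a few photosynthesis/housekeeping genes, one intron-containing
gene, a tRNA, and an rRNA inside the IR. Planted repeats (SSRs, a direct and
a palindromic pair) are recorded in a truth manifest that round-trips
through TSV.

`evolve_alignment()` applies Jukes–Cantor substitution (no indels, no rate
heterogeneity beyond an optional per-column rate vector) along a tree from
`generate_tree()`. Jukes–Cantor is a stand-in chosen for its closed-form
expected p-distance `3/4 (1 − e^{−4d/3})`, which the test suite uses as an
oracle; it is not a claim about any particular empirical dataset.
`repair_orfs()` restores starts/stops and removes chance in-frame stops
after simulation, emulating purifying selection so that planted degradation
states stay unambiguous. Degradation lesions are applied *after* evolution;
`apply_degradation()` shifts all downstream coordinates consistently through
excisions.

Randomness is organized as per-operation streams derived from
`(seed, operation name)`, so adding an operation never perturbs existing
fixtures, and every operation is a pure function of its arguments.

What a green synthetic test does **not** establish: realism of indel
processes (none are simulated), IR boundary shifts between species, rate
heterogeneity among sites, compound SSR structure, or any particular
empirical repeat count — those depend on unstated tool-level filtering in
the literature and are deliberately out of scope.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → classify → encode → search → trace →
divergence → repeats and writes TSV/FASTA/GFF3/Newick/JSON outputs plus a
manifest (package version, seed, thresholds, md5 checksums of every
artifact). Re-running the same configuration reproduces byte-identical
outputs; the test suite asserts it. Stage failures abort with the stage
name. The full desk-scale 6-taxon pipeline completes in well under two
minutes on one CPU (about 20 s without the repeat scan, the slowest stage).

```{r pipeline, eval = FALSE}
cfg <- run_config(mode = "synthetic", n_taxa = 6, seed = 1, rate = 0.005)
res <- run_pipeline(cfg, "plastodecay_out")
res$search          # most parsimonious trees, length, CI, RI
res$acctran         # per-branch ndh state changes
```

## Known limitations

* The heuristic search is SPR, not TBR (see above); use branch-and-bound
  for ≤ 16 taxa.
* Fragment/pseudogene calls within a few bp of the 25 bp / 20% floors
  inherit local-alignment boundary slop; the floors themselves are honored
  exactly for unambiguous inputs.
* `detect_quadripartite()` assumes a single IR pair; plastomes with
  additional large repeats near the detection threshold may need a larger
  `min_ir`.
* GenBank parsing is deliberately minimal (gene/CDS/tRNA/rRNA features,
  `complement`/`join` locations); exotic location operators are rejected
  with a parse error rather than guessed at.
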