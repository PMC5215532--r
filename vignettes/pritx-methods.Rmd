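---
title: "Annotating polycistronic pri-miRNA transcription units and their regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating polycistronic pri-miRNA transcription units and their regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pritx)
```

## The problem

Primary miRNA transcripts of the *let-7* family are hard to annotate from
steady-state RNA-seq: they are processed co-transcriptionally, so the mature
product appears while the primary transcript is nearly invisible.
Chromatin-associated (nascent) RNA-seq recovers the transcript while it is
still tethered to its template, revealing that many *let-7* members are
transcribed as very long (tens to hundreds of kb), often polycistronic
units whose extents and even strands can disagree with RefSeq gene models.
Once the units are known, two questions follow: which units are dynamically
regulated across a differentiation series versus constitutively transcribed,
and which promoter/enhancer elements and upstream transcription factors
drive the dynamic ones.

`pritx` implements that workflow as a deterministic, file-to-file pipeline:

1. **Unit calling** — maximal runs of nascent coverage above a threshold,
   with gap bridging and a length filter, per sample and strand, then
   unioned across samples into locus-level units; mature-miRNA loci are
   assigned by strand-matched containment to flag polycistrons.
2. **Dynamics** — a pseudocounted max/min fold statistic over the ordered
   sample series labels each unit dynamic, constitutive or silent, and
   derives the expressing-sample set.
3. **Regulatory elements** — within ±20 kb of each unit, bases covered by
   H3K27ac ∧ H3K4me3 ∧ DNase peaks in expressing samples (and by
   H3K27me3 ∨ H3K9me3 in non-expressing ones) are merged into candidate
   elements, classified as active/poised promoters or (genic/bivalent)
   enhancers, annotated with chromatin-state categories, poised→active
   transition indices, p300 overlap, and a localized acetylation dip at the
   DNase summit.
4. **Motifs and conservation** — degenerate IUPAC motifs (e.g. the
   forkhead-box consensus `[AC]A[AT]T[AG]TT[GT][AG][CT]T[CT]`, 128 concrete
   words) and log-odds PWMs are scanned on both strands; hits are gated by
   mean per-base conservation ≥ 0.8.
5. **TF nomination** — TF ChIP peaks overlapping the elements are crossed
   with expression contrasts between two conditions; candidates are ranked
   by |log2 fold change| with an optional gene-family prefix filter.

## Coordinate and strand conventions

All internal coordinates are 0-based half-open `[start, end)`, the BED and
bedGraph convention; conversion to 1-based closed coordinates happens only
in `write_gff3()`, and `read_gff3()` inverts it exactly (round-trip is the
identity). bedGraph has no strand column, so strand is an explicit track
attribute supplied per file through the run configuration — several of the
loci this pipeline was designed for initiate antisense to the RefSeq
annotation, so strand can never be inferred. Chromosome names are matched
by exact string equality; there is no "chr" aliasing. Readers reject
malformed records (non-integer or inverted coordinates, overlapping
bedGraph lines, overlapping state segments, negative values) with the
offending line number rather than repairing them silently; unknown
chromatin-state labels are the one deliberate exception — they are kept and
categorized `"other"`, because state vocabularies vary between
segmentation releases.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `min_cov` | 1 | coverage | base inclusion threshold for unit calling |
| `max_gap` | 500 | bp | largest sub-threshold gap bridged |
| `min_len` | 1000 | bp | minimum retained unit length |
| `pseudocount` | 0.5 | abundance | stabilizes the fold statistic at low signal |
| `fold_threshold` | 4 | fold | dynamic vs constitutive boundary |
| `expression_floor` | 1 | abundance | expressing-sample and silent-unit cutoff |
| `flank_bp` | 20000 | bp | search window half-width around a unit |
| `min_expressing_support` | 1 | samples | expressing samples a candidate base needs |
| `require_repressive` | TRUE | — | demand repressive marks in non-expressing samples |
| `merge_gap` | 200 | bp | re-merge distance for candidate fragments |
| `tss_distance_bp` | 2000 | bp | promoter vs enhancer distance rule |
| `dip min_depth_fraction` | 0.3 | fraction | required relative depth of the acetylation dip |
| `dip max_anchor_distance` | 250 | bp | search radius around the DNase summit |
| `dip shoulder_window` | 1000 | bp | shoulder search width |
| `conservation min_mean` | 0.8 | probability | mean-conservation gate on motif hits |
| `min_abs_log2fc` | 1 | log2 | differential-expression cutoff for TF candidates |

The ±20 kb flank, the active/repressive mark sets with their ∧/∨
semantics, the chromatin-state vocabulary and the 0.8 conservation gate are
fixed by the published procedure. The unit-calling and dynamics thresholds
are not stated there; the defaults above were chosen so that 10–200 kb
units survive sparse nascent coverage and the silent→expressed pattern is
reproduced with explicit, user-visible thresholds. Abundance is RPKM-style
— `sum(coverage) / (kb of unit) / (library size / 1e6)` — with
`library_size` always an explicit input, never inferred from a track, so
the floor of 1 has its usual RPKM-like meaning only when the caller
supplies a real library size.

## Design choices where the procedure was open

**Colocalization is base-wise intersection.** The published description
("colocalization of H3K27ac, H3K4me3, and DNase sensitivity…") does not
define colocalization; a proximity rule (peaks within some distance) was
rejected in favour of base-wise conjunction because the latter has an
exact per-base boolean oracle against which the implementation is tested.
The repressive-mark condition is likewise applied per base, before
merging. `colocalize()` is monotone: adding an active peak to an
expressing sample never removes candidate bases, and raising
`min_expressing_support` never adds them.

**One category per element, fixed precedence.** Promoter rules win
whenever the candidate is within `tss_distance_bp` of the unit's
strand-aware 5′ end and overlaps H3K4me3; the poised variant requires
H3K4me3 ∧ H3K27me3 in the *same* sample (bivalency is a property of one
chromatin, not of the sample set). Among enhancer-like candidates the
precedence is genic (inside the unit body) > bivalent > plain. The TSS is
always the called unit's 5′ boundary, not a RefSeq model, because the
called units are longer than the annotation at exactly the loci of
interest. `distance_to_tss` is nearest-edge and signed (negative
upstream); midpoint distance was rejected because it penalizes wide
elements that actually contain the TSS.

**Transition indices are 0-based.** `order_transitions()` and
`state_transition()` return the earliest index in the configured sample
order where the unit/element is active, provided it was silent/poised
earlier; `NA` when never or always active. The differentiation order is a
required configuration list — it is metadata, not something to infer from
the data.

**Dip calling is descriptive, not inferential.** `detect_dip()` reports a
dip iff the local minimum within `max_anchor_distance` of the DNase summit
is at most `(1 − min_depth_fraction)` times the smaller flanking shoulder
maximum. No significance test is attached: the source analysis names none,
and the rule is re-evaluable from the binned signal.

**Conservation gating is post-hoc by default.** The published order —
isolate conserved sub-regions, then scan — and the more testable order —
scan, then keep hits with mean conservation ≥ 0.8 — give identical hit
sets whenever islands are at least motif-sized; the implementation filters
hits post-hoc and records `mean_conservation` per hit. The filter is
idempotent and monotone in its threshold.

**Degenerate matching is exact.** No mismatches are tolerated (the source
motif shows none), `N` in the sequence never matches, and overlapping hits
are all reported. Matching uses IUPAC ambiguity codes on the pattern side
only; the test oracle instead expands the motif into all 128 concrete
words and string-searches each, keeping the two routes independent. PWM
scanning is plain log2-odds summation with a 0.01 pseudocount when
building from counts, and uniform background by default.

**TF ranking is a set intersection.** Candidates = bound TFs ∩
differentially expressed TFs (∩ family prefixes when given), sorted by
|log2FC| descending with lexicographic tie-break for determinism. The
expression contrast is a pseudocounted log2 ratio of condition means; the
"actively transcribed" requirement is a mean-expression floor in the
reference condition (default 1).

## The synthetic scenario

`generate_scenario()` writes a complete, self-consistent input set for one
run — the same text formats the pipeline consumes, never an in-memory
handoff — plus a ground-truth manifest. The default scenario is a 1 Mb
chromosome with four samples in differentiation order
(`ESC, iPSC, PSC_NPC, tissue_NPC`) emulating the structure of the real
data:

* a 60 kb **dynamic** unit on the plus strand, silent in the first three
  samples and expressed at 20× background in the last, and an 80 kb
  antisense **constitutive** unit at 10× background in every sample
  (coverage is Poisson per 10 bp bin, background rate 0.1 per bin);
* a **bivalent promoter** at the dynamic TSS (H3K4me3 + H3K27me3 early,
  full active triple late; state `Bivalent/Poised TSS` → `Active TSS`,
  planted transition index 3), an **alternative active promoter** 1.5 kb
  into the unit, and a **distal enhancer** 10 kb upstream with p300, a
  DNase summit, and a two-Gaussian acetylation profile (shoulders ±300 bp,
  σ = 120 bp, noise σ = 0.05 ≈ 0.5% of shoulder height) whose valley sits
  at the summit — the noise is kept below the valley's curvature per 25 bp
  bin so the planted minimum is identifiable at bin resolution;
* two **decoys**, each violating exactly one calling condition
  (acetylation without DNase; full active triple without any repressive
  mark), so false positives are attributable;
* three **forkhead-box motif words** planted verbatim inside 0.95-score
  conservation islands (background 0.2) in the enhancer;
* **regulator TFs** (FOXP2 bound at the enhancer, TFAP2C at the poised
  promoter) with ≥4× expression differences between PSC-derived and
  tissue-derived NPC conditions, plus bound-but-flat, DE-but-unbound and
  unbound-flat nulls, three replicates per condition with log-normal noise
  (σ = 0.08).

The generated run configuration sets `min_cov = 2` (one qualifying bin
needs two reads where background averages 0.1, so isolated noise bins
cannot chain through 500 bp gap bridging), `min_len = 5000` (an order of
magnitude below the shortest real unit of interest, yet long enough that
background bin chains cannot reach it), and `library_size = 5e8`, which
places background at ≈0.2 abundance units, the constitutive unit at ≈2 and
the expressed dynamic unit at ≈4 against the expression floor of 1. All
values were fixed from these rate calculations when the generator was
designed. Module defaults are unchanged; the scenario simply records its
own configuration, as any real run would.

A fixed seed reproduces every file byte for byte; paths inside
`config.yaml` are relative to the scenario directory so identical seeds
give identical trees anywhere.

What the scenario does *not* emulate: read-level artefacts (mappability,
duplicates, fragment-size effects), spliced transcripts, peak-calling
noise (peaks are planted, jittered by ≤40 bp, not re-called from signal),
inter-chromosomal structure, and realistic motif/background composition
beyond uniform random sequence. Passing the recovery tests therefore shows
the pipeline's logic is correct under its stated model, not that the
thresholds transfer untouched to real libraries.

## Numerical details and degenerate inputs

* Coverage tracks are run-length encoded; queries off any run return 0.
  Bookended equal-valued runs are coalesced at read time.
* Gap bridging is single-pass (threshold runs, then merge) — iterating the
  merge could cascade across arbitrarily long gaps and has no base-wise
  oracle.
* Ties in `detect_dip()` (equal minima) break toward the anchor, then
  leftward; ties in majority-state resolution break toward the more active
  state in a configured ranking, then alphabetically.
* An empty expressing set makes colocalization undefined; the function
  warns and returns no candidates rather than guessing.
* `scan_pwm()` skips windows containing `N`; with an arbitrarily low
  threshold it returns exactly `length(seq) − motif length + 1` windows
  per strand.
* All orderings that reach output files use locale-independent (radix or
  dplyr-default C-locale) sorts, so products are byte-identical across
  environments.
* Problem sizes used by the test-suite and the acceptance script — 100 ×
  10 kb sequences for motif-scan equivalence, 200 random tracks for the
  unit caller, 50 multi-sample configurations for colocalization, 50 noisy
  profiles for dip robustness, and the 1 Mb four-sample scenario run twice
  for determinism — were chosen as the smallest sets at which the binomial
  bounds in the recovery criteria are meaningful.

## Known limitations

* Multi-sample unit calling is union-based; a sample with a genuinely
  shorter isoform cannot shorten the locus-level unit.
* The dynamic/constitutive boundary is a single fold threshold; units
  hovering at the threshold flip with noise, and no significance test is
  attached (none exists in the source procedure at this stage).
* Enhancer–gene assignment is purely positional (the ±20 kb window);
  looping-based assignment is out of scope.
* Conservation input is consumed as given; the pipeline does not compute
  phastCons scores, call peaks, or train chromatin-state models.
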