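---
title: "Mining toxin-like precursors with single residue distribution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining toxin-like precursors with single residue distribution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srda)
```

## The problem

Venom peptides of sea anemones are small, disulfide-rich molecules whose
sequence similarity across families is often too low for homology search
to find new members, while their *cysteine scaffold* — the spacing of the
structure-forming cysteines — is strongly conserved. Expressed sequence
tag (EST) banks are single-pass cDNA reads: unannotated, frame-unknown,
error-prone, and full of untranslated sequence. `srda` mines such banks
for secreted toxin-like precursors using the scaffold itself as the query.

## Single residue distribution analysis

SRDA converts an amino acid sequence into a *pattern string* that keeps
only a chosen set of key residues and replaces every maximal run of other
residues by its length:

```{r}
srda_convert("MKACCGA", key_spec("C"))
srda_convert("GCKCDDGYCCA.", key_spec("C."))
```

A `key_spec("C.")` treats translation stops (written `'.'`) as key
symbols too; for cysteine-poor cytolysins, lysine (`"K."`) is the useful
key. Zero-length runs emit nothing, so adjacent cysteines appear as
`"CC"`. Counts are plain decimal with no padding, which is what makes a
two-character wildcard `##` mean "a two-digit spacing" in the motif
language below. `'X'` (an ambiguous codon) counts as a nonconserved
residue. Adding a key residue to the spec can only refine a pattern, and
the pattern always reconstructs the sequence length — both properties are
fuzz-tested.

## Screening lines

A *screening line* is a wildcard query over pattern strings: `?` matches
any one symbol, `#` any one digit, `*` a gap of zero or more symbols;
letters, digits and `'.'` are literal. Matching is character-level
substring search, reproducing the semantics of the `Like` operator the
method was originally built on — including the quirk that `#` may match
one digit of a three-digit count. The package ships a registry of fifteen
cysteine-scaffold lines for anemone toxin families plus the compound
motif K (`K >= 6 AND C <= 2` per fragment) that targets cysteine-free
cytolysins; the two most degenerate lines (`###.` and `##C`) are disabled
by default because they retrieve mostly noise. The matcher is written in
C++ and is verified in the test suite against an independently compiled
regular-expression oracle on ten thousand random motif/pattern pairs.

New lines can be derived from training sets with
`generalize_patterns()`, a greedy consensus over tokenized patterns:
identical tokens stay literal, counts of equal digit length become `#`
runs, and structurally divergent stretches collapse into one `*`. Ties
prefer `#` over `*`, keeping the derived line as specific as possible;
inputs are sorted first so the consensus is order-independent.

## Fragments, not frames

EST banks are translated conceptually in all six frames
(`six_frames()`, standard genetic code; a codon containing `N`
translates to `X` unless every resolution agrees). Matches are only
allowed inside *fragments*: maximal stop-free stretches that end with a
stop symbol. A trailing stretch with no terminating stop is rejected as
partially identified. This single rule is what keeps the false-positive
rate manageable: a cysteine run that resembles a motif only when read
across an internal stop codon can never match, because the two halves
live in different fragments. `min_len` filters fragments by residue
count; the default of 0 keeps everything, and 30 is the practical
setting when mining secreted precursors, since a signal peptide alone
occupies 15–45 residues.

## The signal-peptide heuristic

The original workflow delegated signal-peptide confirmation to an
external predictor. `srda` keeps that option
(`load_signalp_output()` overrides internal calls) and provides a
transparent internal heuristic, `signal_from()`, so the pipeline is
reproducible offline. For each candidate initiator Met within
`limitMet` (default 30) residues of the fragment start it scores

* the maximal Kyte–Doolittle hydropathy sum over a sliding window
  (length 8) placed at offsets 6–20 after the Met — the hydrophobic
  core; and
* a small-residue indicator (A, G, S, C, T) at the −3 and −1 positions
  of the best cleavage candidate among positions 15–45 after the Met,
  ties resolving to the candidate nearest the Met.

The combined score `w_hydro * core + w_cleave * indicator` (defaults 1
and 8) must reach the acceptance threshold (default 20, i.e. a solidly
hydrophobic core is required: an all-leucine window scores 30.4, a
polar one near zero). These weights are a documented reconstruction,
fixed in `signal_params()`; they are deliberately simple, and for
paper-faithful operation an external SignalP run remains the reference.

## Maturation and deduplication

After signal cleavage, `predict_mature_start()` looks for the
propeptide processing site: immediately after a dibasic `KR`/`RR`/`KK`,
or after an `R` with `E` at any of positions −2..−4 (a
processing-quadruplet-style rule); the site nearest the signal wins and
the fallback is "no propeptide". These rules approximate the maturation
logic of the source workflow, which was cited there but never restated;
they are pluggable through the call surface and labelled as
approximations. Mature domains identical as strings — ignoring signal
and propeptide variation — are collapsed by `dedup_matures()`;
multiplicity counts distinct EST clones, so a clone hit by two
overlapping motifs is not double-counted. Near-duplicates (point
mutants) are deliberately kept: natural toxin families behave like
combinatorial libraries on a shared scaffold, and a single-residue
variant is a real library member, not an artifact.

One call is kept per (record, motif): an EST clone encodes one
precursor, so competing fragments within a clone resolve to the
best-scoring signal. This also makes the per-motif stage chain
*retrieved ≥ signal-approved ≥ deduplicated* hold structurally; the
`total` row of `stage_report()` counts record-by-motif units for the
same reason.

## The synthetic bank generator

`generate_bank()` produces the test substrate: random-DNA noise
records, planted secreted precursors, and two decoy classes, with a
manifest sufficient to recompute every expected hit and call.
`sample_mature_for_motif()` inverts the matching relation — wildcards
are instantiated (each `#` a random digit without creating leading
zeros, `*` a short random token run, counts expanded into non-key
residues) and the draw is verified by converting and matching before it
is returned. `build_precursor()` wraps a mature domain in the canonical
architecture: Met + 12 hydrophobic residues + `ASA` (signal), a short
acidic propeptide ending in `KR`, then the mature domain.

Deliberate generator choices, fixed once:

* The signal core draws from L/V/I/F only. Alanine is hydrophobic but
  also a −3/−1-class small residue, and admitting it can fabricate a
  cleavage candidate one position early; excluding it makes the planted
  cleavage site unambiguous, which is what a recovery test needs.
* Mature-domain non-key positions exclude M (so the planted initiator
  Met is the only Met candidate) and C (the key residue).
* Reverse translation uses uniformly random synonymous codons and
  avoids in-frame stops on the planted strand only; spurious ORFs in
  the other five frames are left alone — they are exactly the
  wrong-frame noise the signal stage exists to reject.
* A stop codon is placed in frame immediately 5' of the planted ORF, as
  in-frame 5'-UTR stops commonly precede real initiation codons, so the
  planted fragment starts at the initiator Met.
* `*` instantiation is bounded (3 tokens, counts ≤ 99 via digit
  instantiation) to keep planted peptides toxin-sized.
* Default study-scale composition for end-to-end checks: 5,000 records
  with 120 planted precursors spread over motifs 1–4, 20 stop-split and
  20 signal-less decoys, the rest noise of 200–700 nt — small enough to
  scan in minutes, large enough that per-motif counts are meaningful.

What the generator does *not* emulate: sequencing error and chimeras,
vector contamination, realistic codon usage and expression-level
abundance. Passing the recovery tests therefore demonstrates that the
pipeline's logic is correct on clean planted signal, not that real EST
banks will yield comparable precision.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed intervals throughout; `aa_to_nt()`
  maps a residue to its codon start on the original strand (for minus
  frames, the smallest coordinate the codon occupies).
* Records shorter than 3 nt translate to six empty frames with a
  warning; empty fragments between consecutive stops are dropped.
* The matcher reports the leftmost match; later segments after a `*`
  are placed greedily as early as possible, which is complete for this
  wildcard language.
* Analysis commands are deterministic; all randomness lives in the
  generator behind a single integer seed, using only R's portable
  integer RNG. File outputs are written to a temporary name and renamed,
  so an interrupted run leaves no partial files.
* `frame = 0` in `translate_frame()` returns the reverse-complement
  nucleotide string, kept for compatibility with the original
  spreadsheet function it mirrors.

## Known limitations

The internal signal heuristic is not SignalP and is not meant to be;
its acceptance threshold was chosen for clean synthetic precursors and
errs toward rejecting weak signals. The maturation rules cover dibasic
and E-x-x-R processing only; multi-peptide precursors that require
re-cleaving downstream domains are out of scope of the default call
path. Protein-mode scanning (`scan_protein_set()`) strips stop symbols
from motifs, which slightly widens terminal-spacing motifs — the same
trade-off the original reference-database screen accepted. Reported
retrieval counts on real banks depend on bank vintage and cannot be
compared across snapshots.
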