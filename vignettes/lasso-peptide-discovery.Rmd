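---
title: "Discovering and characterizing lasso peptides with lassokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and characterizing lasso peptides with lassokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lassokit)
```

## The problem

Lasso peptides are ribosomally synthesized and post-translationally modified
peptides (RiPPs) in which the side-chain carboxylate of an Asp or Glu at
position 7, 8 or 9 of the mature core is bonded to the amine of the
N-terminal residue, forming a macrolactam ring through which the C-terminal
tail is threaded. They are encoded by compact biosynthetic gene clusters
(BGCs): a short precursor gene (A) whose product is a leader peptide
followed by the retained core (typically 14–24 residues), a leader peptidase
(B), a lasso cyclase (C), a RiPP recognition element (E), and usually — but
not always — ABC transporters.

Many such clusters are silent under laboratory conditions, so their products
must be predicted and then confirmed by mass spectrometry. `lassokit`
implements the desk half of that workflow as composable, tested functions:

1. mine genomes for candidate clusters by cyclase homology and gene
   neighborhood context;
2. split precursors into leader and core using the conserved leader motif;
3. predict intact cyclized masses and charge states;
4. generate theoretical a/b/y fragment tables that respect the lasso
   topology;
5. localize the ring-closing residue from a deconvoluted MS/MS peak list;
6. group precursors into subfamilies with a sequence similarity network
   (SSN).

A seeded synthetic-data module generates genomes with planted clusters,
motif-obeying precursors, and lasso MS/MS spectra, so the whole chain is
testable end to end without any external downloads.

## Mass arithmetic and its conventions

All masses are monoisotopic. A linear peptide weighs the sum of its residue
masses plus one water; macrolactam formation expels one water, so the
cyclized mass is simply the residue-mass sum — it does not depend on which
residue closes the ring:

```{r}
linear_peptide_mass("LYGVRNDEEINWHFDYWT")
cyclized_mass("LYGVRNDEEINWHFDYWT")
mz(cyclized_mass("LYGVRNDEEINWHFDYWT"), 2)
```

Two distinct charge-carrier constants are deliberately in play, and both are
surfaced by `mass_constants()` and recorded on every ion table:

* **proton mass** (1.007276 Da) for precursor charge states
  ([M+zH]^z+^ arithmetic);
* **hydrogen atom mass** (1.007825 Da) for fragment ions, the convention of
  the classic web fragment-ion calculators against which published lasso
  fragment tables were computed. The two conventions differ by an electron;
  fragment series are internally consistent either way, but matching
  published tables to better than a millidalton requires the hydrogen
  convention, which is why it is the fragment default.

Residue masses are stored to five decimals, derived from elemental formulas
and IUPAC monoisotopic atomic masses. Output is printed to four decimals;
all comparisons in code use explicit numeric tolerances, never string
equality. Average masses, isotope envelopes and non-proton adducts are out
of scope.

## Leader/core prediction

Actinobacterial lasso leaders share a 17-position motif,
`YxxPx[LV]xxxGxxxxxT x`, with anchors Tyr1, Pro4, Gly10 and Thr16 and a
tolerated Leu/Val at position 6. Thr16 is the penultimate leader residue, so
`enumerate_core_candidates()` cleaves after motif position 17 — one residue
past the conserved Thr. That rule is the only one consistent with both
experimentally confirmed cores in the validation set, and it is ranked ahead
of the older heuristic (also enumerated) that mature cores start with Gly:

```{r}
cands <- enumerate_core_candidates("MEHDEKTPYETPAVYGLGAFAEETGLYGVRNDEEINWHFDYWT")
cands[1:4, c("rank", "core", "rule", "motif_score", "core_in_window")]
```

Design choices worth knowing:

* the motif score counts matched positions among the four anchors plus the
  tolerated position 6 (so 5 beats 4); windows missing any anchor are not
  reported at all;
* the 14–24 core-length window is a *soft* constraint — violations demote a
  candidate's rank but never delete it, because historical first-pass
  predictions on real clusters have been wrong in exactly this respect;
* Gly-start cleavage is only searched in the C-terminal half of the
  precursor, which avoids an explosion of leader-internal Gly candidates
  while covering every plausible core;
* ring candidates are the Asp/Glu residues at core positions 7–9
  (configurable).

`predict_products()` turns each candidate ring residue into a
`lasso_peptide` with its cyclized mass and m/z at z = 1, 2.

## Lasso fragmentation and ring localization

Collision-induced fragmentation of a lasso peptide cannot open the
macrolactam. Three consequences define the theoretical table built by
`lasso_ion_table()` for a core of length n with ring at r:

* a/b ions with index ≥ r contain the intact ring and are shifted down by
  one water (18.010565 Da);
* ions requiring a backbone cleavage *inside* the ring (a/b with index < r,
  y with index > n − r) cannot form and are flagged unobservable;
* a_r/b_r — the bare macrolactam with no tail residue — is also flagged
  unobservable by default, matching its consistent experimental absence
  (configurable via `bare_ring_observable`).

Unobservable ions are kept in the table with their theoretical m/z because
the localization scorer uses them as *negative* evidence.

`infer_ring()` exploits the abrupt series boundaries: for the true r, the
first observable a/b ion is index r + 1 and the largest observable y ion is
index n − r. Each candidate r is scored as
(matched observable ions) − w × (matched should-be-unobservable ions), with
w = 1 by default: published assignments treat the *absence* of ring-internal
ions as decisive, so their presence must count against a candidate. A
candidate is *consistent* when its first matched a/b index is exactly r + 1
and its largest matched y index is exactly n − r. The verdict is `called`
only when exactly one candidate is consistent and no other candidate
strictly outscores it.

The consistency checks, not the raw score, carry the discrimination. A
candidate r′ smaller than the true r matches exactly the same peaks as the
true candidate (its extra expected ions simply go unmatched), so scores tie
systematically; requiring the series boundaries to sit at r + 1 and n − r
resolves the tie on evidence rather than on a smaller-r prior. Ties and
conflicting evidence return `ambiguous`, an empty match set returns
`no-call`; the scorer never guesses.

One limitation is inherent to the evidence itself: if every diagnostic ion
(a/b at r + 1 and y at n − r) is missing while the next ions in each series
survive, the spectrum is genuinely indistinguishable from that of a peptide
cyclized at r + 1, and no peak-presence method can avoid the mis-assignment.
The package's recovery guarantee — verified over 200 seeded spectra — is
therefore conditional: with dropout confined to non-diagnostic ions, the
planted ring is recovered in every case and a wrong position is never
called.

Matching (`match_peaks()`) is greedy nearest-first within tolerance, one
peak per ion and one ion per peak, with signed deltas reported. The default
tolerance of 0.01 Da on deconvoluted singly-protonated masses is a
documented engineering choice: published predicted-vs-observed deviations
are about 1 mDa, so 0.01 Da is generous yet still discriminating between
adjacent candidates (the a/b shift between neighboring ring positions is a
full residue mass). Scores are intensity-agnostic; intensities are carried
for reporting only. Raw multiply-charged spectra are rejected with an
instruction to deconvolute first.

## Cluster mining

Mining is homology-seeded: a Smith–Waterman scan of the annotated proteome
against a bundled cyclase exemplar finds seeds; `assemble_cluster()` then
gathers genes within ±8 genes and ±10 kb (whichever is smaller), assigns
roles by alignment to peptidase/RRE/transporter exemplars, and reports
completeness (B + C + E required; transporters counted but optional —
transporterless lasso clusters are documented), the maximum intergenic gap
(flagged above 500 bp), and motif-positive short ORFs (25–70 aa, start
codons ATG/GTG/TTG on either strand, bacterial code) as precursor
candidates.

The aligner is an in-package affine-gap implementation (gap of length L
costs open + L·extend; BLOSUM62, open 10, extend 0.5, normalized-score
threshold 0.3 — all configurable). Determinism is part of its contract:
ties in the traceback resolve toward the smallest row, then column, and
aligned columns win over gaps. Its scores are verified in the test suite
against exhaustive enumeration of all local alignments on short peptides
and against an independent aligner on longer ones. Raw and normalized
scores are reported; no E-value statistics are attached.

The bundled reference FASTA contains *constructed* stand-in sequences (the
file name says `synthetic`): they have realistic lengths and composition
but are not database accessions, and the mining validation is accordingly
self-consistent — synthetic genomes plant genes derived from these same
references. Swapping in a curated FASTA of real cyclase/peptidase/RRE
sequences changes nothing else about the pipeline.

## Subfamily networks

`build_ssn()` computes all-vs-all global percent identity (end-gap-free
alignment, identical columns over aligned columns) and keeps edges at or
above the threshold; connected components are subfamilies. Defaults of 40%
for precursors (50% for cores) are engineering choices, reported in the
output. Component labels are canonical — the lexicographically smallest
member id — so results are independent of input order, and raising the
threshold can only split components, never merge them. GraphML export
(`write_ssn_graphml()`) feeds standard viewers. A true multiple alignment
and score-calibrated (bitscore/E-value) SSNs are out of scope.

## The synthetic-data module

`simulation_spec()` fixes every generator parameter; a fixed seed gives
byte-identical outputs, and every artifact ships its ground truth so
recovery tests compare against recorded truth, never re-derived values.

* **Precursors** (`gen_precursor()`): an initiator Met, a short random
  prefix, one leader-motif instance (cleavage site therefore known), and a
  random core of length 14–24 with an Asp/Glu planted at a position drawn
  from {7, 8, 9}. Template mode instead mutates a supplied precursor at a
  per-position rate (rate 0 reproduces the template exactly).
* **Genomes** (`gen_cluster_genome()`): reference proteins and the
  generated precursor are back-translated with codon choice weighted by
  gc^(GC count) per synonymous codon toward a target GC of 0.72
  (Streptomyces-like, so the ORF finder is exercised on realistic
  composition), laid out in a configurable gene order (default the
  six-gene C-E-B-A-D-F arrangement with two transporters) with 20–120 bp
  intergenic spacers; unrelated decoy genes are planted outside the
  cluster behind 1.5 kb gaps.
* **Spectra** (`gen_spectrum()`): all observable ions of the planted
  (core, r), Gaussian mass jitter (default sd 0.002 Da, consistent with
  instrument-scale deviations and a 5-sigma margin under the 0.01 Da
  tolerance), per-ion dropout, never any ring-internal ion, plus uniform
  noise peaks with log-normal intensities. Intensity distributions are
  documented placeholders — the matcher only uses presence/absence.

What the generator does *not* emulate: chromatography, isotope envelopes,
charge-state distributions, co-eluting peptides, real codon-usage tables,
pseudogenes, or homology between decoys and real enzyme families. Passing
the recovery tests therefore demonstrates correctness of the topology
model, the scoring logic and the mining plumbing — not performance on real
instrument data, where calibration error, deisotoping artifacts and chimeric
spectra add failure modes the spectra here do not contain.

## Numerical and degenerate-input choices

* Cyclized mass = linear mass − 18.010565 exactly; permutation of residues
  leaves intact masses unchanged (composition-only).
* Ring positions are restricted to 2 ≤ r ≤ n with Asp/Glu enforced at
  construction; the hypothetical r = 1 "ring" is rejected as a degenerate
  type rather than modeled.
* Dropout of 1.0 for a whole ion series is allowed in the generator and
  must yield `ambiguous`/`no-call`, never a wrong position.
* Empty peak lists are data (no matches), not errors; empty match sets give
  `no-call`.
* Coordinates are 1-based inclusive throughout (the R/Bioconductor
  convention), making GFF3 round trips lossless.
* Tightening a tolerance can only shrink a match set (verified property).

## Problem sizes

The shipped test suite runs at small, fixed sizes chosen to finish in well
under a minute per file while still exercising every code path: exhaustive
alignment oracles on peptides of length ≤ 6 (100 pairs), ring-recovery over
200 seeded spectra, SSN oracles on graphs of ≤ 20 nodes, and mined genomes
of roughly 9 kb with 6–8 genes. All sizes scale up by changing the
`simulation_spec()` arguments; nothing in the implementation depends on
them.
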