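---
title: "Designing synthetic translational coupling elements with syntce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing synthetic translational coupling elements with syntce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntce)
```

## The design problem

In bacterial polycistronic operons, translation of a downstream cistron
often depends on ribosomes finishing the upstream one: the terminating
ribosome unwinds local mRNA structure around the next ribosome binding
site (RBS) and reinitiates. A *synthetic translational coupling element*
(synTCE) engineers this behaviour as a drop-in cassette between two open
reading frames:

* a hairpin **stem** (default 6 bp, supported 0–12 bp) that occludes the
  intergenic RBS from de novo initiation while the upstream gene is off;
* a **loop** (8–20 nt) carrying a purine-rich RBS (`AGAGGAGA`);
* an **overlapping stop–start junction** `URAUG` (R = A or G): the
  upstream stop codon (`UAA`/`UGA`) shares its final nucleotide with the
  downstream `AUG`, giving an intergenic distance of −1 and placing the
  downstream ORF in frame `(f + 2) mod 3` relative to the upstream frame
  `f`.

Placed downstream of a translational riboregulator (e.g. a toehold
switch), the cassette transmits the upstream ON/OFF state to one or more
downstream outputs: ribosomes translating the upstream ORF run through
the stem, expose the loop RBS, terminate on the junction stop and
reinitiate at the overlapping start. Because reinitiation starts exactly
at the junction `AUG`, the downstream protein carries no unwanted
N-terminal extension — the property that makes signal peptides and
holin-type N-termini usable downstream.

`syntce` generates these cassettes, scores them thermodynamically,
filters them, compiles them
with opaque riboregulator parts and ORFs into annotated multi-output
operon transcripts and logic-gate layouts, and provides the quantitative
utilities (geometric-mean fold change with quadrature errors, feature
regression, CFU counts) used to analyse coupling measurements.

## Coordinates and sequence model

All sequences are RNA internally (`to_rna()` transcribes T → U at the
boundary); coordinates are 0-based, half-open, 5′→3′. Ambiguity codes
are allowed only in patterns (`match_iupac()`), never in concrete
sequences — design constraints are patterns, parts are concrete. The
stop codon set is fixed to the standard bacterial `UAA`, `UAG`, `UGA`.

## The thermodynamic layer

The energy model is a nearest-neighbour ΔG37 parameter set
(Turner-2004-style values, shipped as a versioned TSV in
`inst/extdata/nn_params.tsv`): the 36 ordered stacks over the six
admissible pairs (AU, UA, CG, GC, GU, UG), hairpin-loop initiation
penalties for loop sizes 3–30 with logarithmic extrapolation beyond, and
a +0.5 kcal/mol terminal penalty per AU/GU helix end. Temperature is
fixed at 37 °C with no salt correction, matching the conditions the
designs target. Absolute numbers from other parameter sets (e.g. the
NUPACK "rna06" ensemble) will differ slightly; the package's contract is
the *ordering* of stems, the signs, and the trends, which are what the
filters and ranking consume.

Four scores build on the table:

* `stem_dG(stem5)` — energy of the perfect duplex `stem5 :
  revcomp(stem5)`: the sum of the n−1 stacks plus terminal penalties.
* `asd_duplex_dG(mrna, window, anti_sd)` — the best hybridization energy
  of the anti-Shine-Dalgarno sequence (default `ACCUCCUUA`, the 3′ tail
  of *E. coli* 16S rRNA; the concept is standard, the string is
  configurable) over every ungapped antiparallel alignment against a
  window. Only contiguous runs of ≥ 2 WC/GU pairs are scored; a run
  whose energy is positive (possible for short wobble-rich runs) does
  not count as pairing, so the reported energy is always ≤ 0.
* `spacing_penalty(spacing)` — a piecewise quadratic that is zero at the
  optimal distance between the SD duplex and the start codon (default
  5 nt) and rises as `0.30·d²` on the compressed side and `0.15·d²` on
  the stretched side (capped at 25 kcal/mol). Compression is penalized
  more steeply than stretch, following the established behaviour of
  translation-initiation calculators; the constants are package
  defaults, documented here, and configurable via `rbs_config()`.
* `rbs_strength(mrna, start_pos)` — the two-term RBS score
  `ΔG(rRNA:mRNA) + ΔG(spacing)`, searching a 20-nt window upstream of
  the start codon. When no duplex forms at all the hybridization term is
  0 and the maximal spacing penalty is charged. Standby-site and
  long-range-fold terms of full initiation calculators are deliberately
  out of scope: only the two terms that the coupling analysis sums are
  implemented. Ties between equal-energy duplex alignments resolve
  toward the 3′-most (start-proximal) run, then the smallest start —
  a documented determinism rule, not a physical claim.

`hairpin_structure_check()` certifies a designed window: the designed
structure (full-length stem closing the loop) must be *formable*, must
be the minimum-energy hairpin among an exhaustive enumeration of every
alternative single-hairpin registration in the window (all contiguous
complementary stems of ≥ 3 bp — windows are < 60 nt, so enumeration is
exact and fast), and must reach a stability threshold (default
−6 kcal/mol). A full MFE folding engine can be substituted through the
same interface without touching callers; exhaustive single-hairpin
enumeration was chosen because it is exact at these window sizes and has
no external dependency.

## Candidate generation, filtering, ranking

```{r design, eval = FALSE}
spec <- syntce_spec(stem_len = 6, n_candidates = 50, seed = 1)
cands <- design_syntce(spec)
head(candidate_table(cands))
```

Only the stem is randomized (the loop, RBS and junction are fixed
domains). Generation is rejection sampling, uniform over stems,
deterministic given the seed, with a bounded attempt budget and an
explicit "unsatisfiable constraints" error — exact and simple at these
domain sizes. For stem lengths ≤ 8 an `enumerate = TRUE` path screens
the whole `4^n` space and serves as the brute-force reference in tests.

Three filters gate a candidate:

1. **No premature in-frame stop**: no stop codon in the upstream reading
   frame anywhere in the cassette before the junction stop (the
   terminating ribosome must reach the junction).
2. **Pattern constraints**: ten IUPAC patterns (`AAAA`, `CCCC`, `GGGG`,
   `UUUU`, and six-long runs of K/M/R/S/W/Y classes) forbid runs of
   identical or chemically similar nucleotides. A violation is a match
   lying *entirely within a randomized domain* (stem5 or stem3). Matches
   spanning into fixed domains are not counted: the fixed loop begins
   with the eight-purine RBS, so any overlap rule would forbid every
   stem ending in a purine and penalize designs for sequence the
   designer cannot change. Constraints govern designed domains; fixed
   parts are exempt by construction.
3. **Structure check** as above.

Ranking is explicit and deterministic (there is no canonical objective
for choosing among passing designs, so the key is a package decision):
passing candidates
first, by ascending designed hairpin ΔG (most stable occlusion first),
then ascending RBS-strength total (strongest predicted reinitiation
first), then lexicographic cassette as a tie-break.

Two geometric constraints are enforced with clear errors rather than
silently repaired: the spliced upstream context must be a codon multiple,
and `2·stem_len + loop length` must be a multiple of 3 — otherwise the
junction stop cannot sit in the upstream reading frame at all. This is
why the default loop is the 15-nt `AGAGGAGACAACAUC` (RBS + 7-nt tail):
at the default 6-bp stem the hairpin insert is 27 nt, a codon multiple,
and the loop's first and last residues (A, C) cannot pair, so the
designed stem registration is maximal. With these defaults roughly 9% of
random pattern-clean 6-bp stems pass all three filters; the stability
threshold dominates.

## Operon assembly and validation

`assemble_operon()` compiles an ordered part list — `switch* orf
([linker] syntce orf)* [output_tag]` — into one annotated transcript. At
each synTCE the upstream ORF's own stop codon is stripped and replaced
by the junction's overlapping stop, so the upstream protein is preserved
(extended only by the translated linker/hairpin codons); the downstream
ORF's first AUG completes both the stop codon and the URAUG motif.
Switch parts are opaque: only length (a codon multiple, for frame
continuity across concatenated modules) and ordering are enforced, since
their internal toehold structure is prior art outside this package's
scope. Every assembly is re-parsed before it is returned: each CDS must
decode stop-free to its annotated stop in its annotated frame, and each
junction URAUG must be found at its annotated position.

`validate_junction()` reports the intergenic distance (−1 for URAUG),
its class — "optimal" for −1..5 (the empirically effective band),
"degrading" for 6..14 and "poor" beyond (the two upper bands are package
conventions for graded warnings over the observed gradual decay) — the
RBS score at the coupled start, the hairpin check, and warnings when the
upstream translated run exceeds 1 kb (coupling decay) or 3 kb (ON/OFF
convergence; thresholds from the reported decay and convergence points).
`scan_internal_rbs()` flags AUG/GUG positions whose RBS score beats a
threshold — the spurious initiation sites that accumulate in long
linkers.

`gate_layout()` arranges OR/NAND gates (2–6 concatenated switch modules
in one frame; more than six is refused as unvalidated scale) and
AND/NIMPLY gates (one switch with split-trigger input metadata), chains
extra outputs through synTCEs, and attaches a qualitative truth-table
stub per input combination. No kinetics are simulated; the stub records
expected logic states only.

## Measurement analysis

Fluorescence distributions are roughly log-normal, so averages are
geometric means. `fold_change()` is the ratio of geometric means
ON/OFF; its relative error adds the two states' relative errors in
quadrature. "Relative error" is the sample standard deviation of the
replicates divided by their geometric mean — the s.d.-based convention,
with the geometric mean as the normalizer since it is the reported
average. `fit_linear()` is ordinary least squares (`stats::lm`) with
`r² = 1 − SS_res/SS_tot`, reported on the raw response by default
(log-response is the caller's transform). `cfu_per_ml()` is
`colonies × dilution / 0.005` (5 µl spots). `feature_table()` joins the
design features (stem ΔG, RBS components, intergenic distance, loop
length, internal-RBS count) for feature-vs-output regressions; its
`local_struct_dG` column is a windowed minimum-hairpin-energy score
(±20 nt around the coupled start) — a clearly-labelled stand-in for a
full local-folding metric, with no parity claim to any particular
published statistic.

## The synthetic-data generator

`fixture_spec()` / `make_fixture_orf()` / `make_fixture_linker()`
produce the synthetic parts every test and demo runs on: stop-free
random codon bodies (uniform over the 61 sense codons) with an AUG
start, a terminal stop, a GC band of 0.35–0.65 (a typical bacterial
coding range), and — by default — no window hybridizing to the anti-SD
with ≥ 4 contiguous pairs, removed by local codon resampling, so that
fixture coupling junctions are not confounded by spurious internal RBSs.
Default ORF lengths 90–300 nt and linkers 30–90 nt keep test assemblies
reporter-gene-sized while exercising every code path; the long-linker
warnings are exercised with purpose-built 1.2 kb and 3.5 kb ORFs.

What the fixtures do *not* emulate: real codon-usage bias, real 5′
structure around starts, and real switch sequences (switches are opaque
random codon runs in tests). Passing tests therefore certify the
design arithmetic, filters, scores and file formats — not that any
particular wet-lab construct will achieve a given fold change.

## Numerical choices and degenerate inputs

Empty and 1-nt stems have zero stacking energy by definition; stem
length 0 reproduces the first-generation (hairpin-free) architecture and
always fails the structure check, by design. Hairpin loops shorter than
3 nt are rejected. Loop penalties beyond size 30 use
`ΔG(30) + 1.079·ln(n/30)`. All randomness funnels through one seeded
Mersenne-Twister scope that restores the caller's RNG state; candidate
provenance records the seed and draw index. File outputs carry no
timestamps, so identical configuration and seed give byte-identical
FASTA, TSV and GenBank outputs. Test problem sizes (1000 sampled
candidates at stem 6; exhaustive enumeration at stem 4; 100 random
duplex windows ≤ 30 nt) were chosen so the whole suite re-derives every
claim by brute force in well under a minute per block.

## Known limitations

* Single-hairpin enumeration ignores multi-helix and pseudoknotted
  alternatives; for the < 60-nt cassette windows this is almost always
  the dominant competition, but an external folding engine is the right
  plug-in for longer contexts.
* The two-term RBS score omits standby sites, start-codon identity
  bonuses and long-range refolding; it is a ranking score, not an
  initiation-rate prediction.
* GenBank support covers the subset of the flat-file format the package
  writes (simple `a..b` locations, label/note qualifiers).
* All-strong stems containing four-in-a-row homopolymers (e.g.
  `GGGGGG`) can mis-register — an extended hairpin beats the designed
  one — which the structure check correctly flags; the pattern
  constraints exclude such stems from designed sets anyway.
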