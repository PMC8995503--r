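---
title: "Attenuator design and quantification: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuator design and quantification: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrdesign)
```

## The system being modeled

A knockdown-replacement (KDR) construct expresses, from one transcript, an
shRNA that silences an endogenous gene and a replacement copy of the gene.
Driven by a strong ubiquitous promoter, the replacement ORF would be
over-expressed; a stem-loop ("hairpin") inserted in the 5' UTR attenuates
its translation by sterically hindering initiation/scanning. Attenuation
strength is governed primarily by the hairpin's folding free energy, so a
library of hairpins graded in ΔG° gives graded expression, and a measured
calibration (percent of un-attenuated control) lets a user pick the member
matching a physiological target.

Every insert in this package shares a constant scaffold: a 7-nt G/C-rich
base arm taken from the NotI recognition sequence (`GCGGCCG`) forms the
outer stem, and the fixed hexamer `TATACT` forms the unpaired loop. Only
the *variable stem* between them is designed. An insert with an `L`-bp
variable stem is `2(7 + L) + 6` nt long, so stems of 5–9 bp give the
30–38 nt length classes.

## Stem enumeration and trimming

`enumerate_stems()` generates every stem of the maximum length (default
11 nt) with exactly the required number of A/T bases (default 1 —
maximising and homogenising G/C content so stability is tuned by
composition shuffling rather than large composition changes), then removes:

* stems containing a forbidden motif on either strand. The default motif
  set is the five recognition sites the cloning geometry relies on (AgeI
  `ACCGGT`, NotI `GCGGCCGC`, SbfI `CCTGCAGG`, EcoRI `GAATTC`, XhoI
  `CTCGAG`); recreating one inside a stem would break vector assembly.
  The screen applies to the stem in isolation; junction-level occurrences
  created by concatenation (e.g. a stem beginning with `C` after the
  `GCGGCCG` arm restores a full NotI site) are the province of
  `validate_cloning_sites()` on the assembled construct.
* self-complementary stems: some substring of at least `self_comp_window`
  nt (default 4) whose reverse complement occurs downstream in the same
  stem with at least 3 intervening bases — i.e. the stem could hairpin on
  itself and compete with the designed fold. The window is a parameter
  because the exact rule used by the original generator is not recoverable;
  4 nt is the shortest helix that is stable enough to matter at 37 °C.

Lower-stability variants derive from each full-length stem by deleting the
base pair *adjacent to the loop* ("innermost" — the loop is the innermost
element of a hairpin), one pair at a time, down to `trim_floor` (default
1 nt; the floor is configurable because the original pipeline's post-trim
count implies an unstated floor or extra filter). Deleting the 3'-most
base of the stored 5' arm implements this; the partner base disappears
implicitly on assembly. After pooling, exact duplicates collapse (keeping
the lexicographically first provenance, for determinism) and all-G/C stems
are dropped — with one A/T in the full stem, every trim that removed the
A/T would otherwise duplicate a shorter pure-G/C series.

The unscreened enumeration count has the closed form `L · 2 · 2^(L−1)`
(position × identity of the A/T base × G/C choices elsewhere), which the
tests use as an analytic oracle. With default screening the pipeline's
full-scale counts (reported by `library_diagnostics()`) do **not**
reproduce the 1,360 / 5,729 counts published for the original library —
those depended on generator settings that were never published — so they
are logged as a distance, never asserted. The free-energy span of the
default library does land within ~1 kcal/mol of the published −15.7 to
−48.2 kcal/mol range.

## Nearest-neighbor free energy

`hairpin_dG()` evaluates the intended stem-loop as an isolated hairpin:

* Watson–Crick stack free energies summed over consecutive stem pairs;
* a hairpin-loop initiation penalty by loop length (3–30 nt supported);
* the terminal mismatch of the loop-closing pair for loops ≥ 4 nt
  (included by default and toggleable via
  `load_energy_model(terminal_mismatch = )`, since "initial dG" conventions
  differ between folding servers; for 3-nt loops the A-U end penalty
  applies instead);
* the A-U helix-end penalty when the outermost pair is A-U.

Parameters ship as plain TSV tables with provenance headers: the Turner
2004 RNA set (default — the attenuator acts in mRNA, so T is read as U) and
the SantaLucia/Mathews 2004 DNA set (`load_energy_model("DNA")`). Versions
are pinned by the test suite. Energies are ΔG° at 37 °C in kcal/mol; no
temperature rescaling is attempted.

Deliberate exclusions: bulges, internal loops, multiloops, coaxial
stacking, dangling ends, G-U wobble pairs and sequence-specific
tetra-/hexaloop bonuses. The designed inserts are perfect contiguous
helices closed by `TATACT` (which earns no special-loop bonus), so none of
these terms arise for library members; the restriction matters only if the
evaluator is pointed at arbitrary structures. Within this domain the
evaluator agrees with ViennaRNA's fixed-structure evaluation (`RNAeval
-d0`) to numerical precision, which the tests check on 100 random designs
(tolerance 0.5 kcal/mol RMS; observed agreement is ~1e-15).

## Maximum pairing and fold verification

`max_pairing_fold()` is a Nussinov-style dynamic program returning a
maximum-cardinality non-crossing Watson–Crick pairing with a minimum loop
of 3 nt. Ties are resolved deterministically: first toward structures with
the most stacked pair adjacencies (favoring long contiguous helices over
scattered pairs), then toward the lexicographically smallest pair list via
a fixed traceback order. The suite checks pair counts against exhaustive
structure enumeration for lengths ≤ 12 and determinism by re-running.

`verify_intended_fold()` asks whether the designed stem is the dominant
fold. Raw pair-count maximality is the wrong criterion on its own: a lone
pair (no stacked neighbor) carries no stacking energy — the designed
`TATACT` loop itself admits one isolated A–T pair under a 3-nt loop
minimum — so the comparison ignores isolated pairs in the refold. With
that physically motivated correction, every accepted library member's
intended stem achieves the maximal stacked pair count. Separately, the
insert is scanned for self-complementary stretches (≥ window) whose implied
pairing is *not* the intended one; this flags planted counterexamples such
as a variable stem equal to the reverse complement of the base arm. Note
that G/C-rich designs frequently contain short off-register
self-complementarities, so this conservative flag is reported, not used as
an acceptance filter.

## Panel selection

The working range identified for practical attenuation is roughly −27 to
−40 kcal/mol (about 50% down to 10% of control). `select_panel()`
formalises the originally manual "uniform increments" selection: k ideal
grid points are placed uniformly across the range and distinct library
members are assigned to them minimising total |ΔG − grid|. Because both
sequences are sorted, an optimal assignment is order-preserving and an
O(n·k) dynamic program solves it exactly; the suite verifies equality with
exhaustive subset search on 200 random instances (n ≤ 12, k ≤ 5). Ties
resolve toward the more stable member. On a dense pool over (−27, −40)
with k = 24 the ideal mean increment is 13/23 ≈ 0.565 kcal/mol; an
achievable pool lands slightly below (the published panel averaged 0.54).

## Calibration statistics

`summarize_replicates()` uses the sample SD over √n and a z·SEM half-width
with z = 1.96 by default — the printed half-width/SEM ratios of the
reference calibration are ≈1.96, i.e. normal-theory intervals; z is a
parameter for t-based intervals. Rounding happens only at presentation.
`rank_by_performance()` orders by *measured* percent-of-control within
promoter (measured attenuation, not modeled ΔG, is the operative quantity;
ties break toward the less stable member). `choose_attenuator()` returns
the entry nearest the target percent (100% → the control by definition;
equidistant targets resolve to the less-attenuated entry, the conservative
choice when over-expression is the lesser risk is not known).
`predicted_vs_observed()` declares agreement when the integrated mean lies
within the plasmid mean ± its 95% half-width. Calibration is
promoter-specific; cross-promoter display scaling is presentation only and
is not applied by any computation here.

The packaged calibration fixtures carry the three measured SOD1
conditions (−30.1, −34.0, −38.9 kcal/mol) for plasmid and integrated
measurements; `ranked_library_synthetic.tsv` is a synthetic, plausible
nine-member table for exercising ranking logic and says so in its header.

## Pixelwise ratiometry

Images are 16-bit two-channel pairs (green = attenuated rescue reporter,
red = IRES-driven internal control), processed as floating point.
Composites are subdivided into an n×n grid (default 10, i.e. 100
sub-images; a 948-px composite gives 94-px tiles with the 8 remainder
rows/columns discarded from the bottom/right — the tiling is otherwise
lossless and exactly recomposable). A pixel enters the analysis when *both*
channels exceed their uniform background thresholds (default; a pixel with
sub-background green yields an unreliable ratio) — a red-only mode exists
because the original software's masking rule is not documented. The
primary statistic is the mean over masked pixels of the per-pixel
green/red ratio ("pixel-wise comparison"); sum(green)/sum(red) is offered
as an alternative estimator. No background subtraction or flat-field
correction is applied — thresholding only. Replicates aggregate as
pixel-weighted means within a replicate, unweighted across replicates,
then `summarize_replicates()`.

### The synthetic generator, and what passing tests do not show

`generate_synthetic_pair()` emulates the relevant gross features of the
real micrographs: sparse non-overlapping elliptical cells on a dark
background, per-cell red intensity from a truncated normal
(20,000 ± 6,000, clipped to 8,000–50,000 on the 16-bit scale), green =
true_fraction × red with independent 5% multiplicative noise per pixel on
both channels, additive Gaussian background (150 ± 40), clipped to 16 bits.
Defaults (192×192 px, 25 cells) give several thousand foreground pixels
per scene — comfortably above the ≥1,000-pixel averaging scale at which
per-pixel noise washes out. Everything is driven by an explicit seed; no
hidden global RNG state leaks (the generator saves and restores
`.Random.seed`), and identical seeds give bit-identical TIFFs.

The generator deliberately omits: cell-to-cell contact and overlap,
intensity gradients within cells, illumination-field inhomogeneity,
chromatic misregistration, saturation, and autofluorescence. Closed-loop
recovery of true fractions {0.10, 0.35, 0.58, 1.00} within ±3 percentage
points (checked over 100 seeded runs) therefore validates the *estimator
pipeline* — masking, tiling, ratio statistics, normalisation to control —
not robustness to those real-world artifacts, which the uniform-threshold
design inherits from the original protocol.

## Construct assembly

`assemble_construct()` concatenates one part per role in the plan order
(minimal: promoter–attenuator–Kozak–rescue–miRE; the inducible variant
inserts IRES and reporter before the miRE cassette), producing features in
0-based half-open top-strand coordinates (unambiguous arithmetic; the
GenBank-style writer converts to 1-based closed). The attenuator part is
the `assemble_hairpin()` insert verbatim and the junction to the Kozak part
is plain concatenation — the original scaffold's partial overlap with a
Kozak consensus is a property of the chosen sequences, and no overlap
geometry is guessed. `validate_cloning_sites()` scans both strands
(palindromic sites counted once per genomic position) and applies
per-role rules: by default the rescue gene must be internally free of
NotI/SbfI and the final miRE cassette free of EcoRI/XhoI, since those pairs
are the insertion sites. shRNA content itself is user-supplied; only site
compatibility is validated. The GenBank subset read/written here is
deliberately minimal (no installed R package writes GenBank flat files)
and is round-trip exact for this package's records.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations for exact
oracles and tight Monte-Carlo error at interactive run times: brute-force
pairing comparisons at lengths ≤ 12 (500 cases), brute-force enumeration at
stem lengths ≤ 6, panel brute force at n ≤ 12/k ≤ 5 (200 instances), 100
random designs against the reference evaluator, and 100-seed closed-loop
image runs at 192×192 px. The full default design pipeline (~22,000
full-length stems, ~40,000 scored structures) runs in seconds and is
exercised end-to-end in the diagnostics. All stochastic components take
explicit seeds.

## Known limitations

* The energy model is a hairpin evaluator, not a general folding engine:
  no bulges, internal loops, multiloops, wobble pairs, or special-loop
  bonuses; loops are capped at 30 nt.
* Enumeration cost grows as `choose(L, a)·2^L`; the default one-A/T,
  11-nt configuration is cheap, but permissive A/T counts at longer stems
  grow quickly.
* The ΔG → expression relationship is empirical, nonlinear, and
  promoter/cell-type specific; this package ranks and matches on measured
  calibration tables and never predicts expression from ΔG alone.
* The published library counts are not reproducible from the published
  constraint description; they are treated as diagnostics.
* Ratiometry assumes converted TIFFs, uniform manual thresholds, and no
  segmentation; per-cell statistics are out of scope.
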