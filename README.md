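# kdrdesign

Design and quantification toolkit for **single-transcript
knockdown-replacement (KDR)** expression systems.

In a KDR construct an shRNA (a microRNA-adapted "miRE" cassette in the
3' UTR) silences an endogenous gene while a replacement copy of that gene is
expressed from the *same* transcript. Because the ubiquitous promoters
needed for potent shRNA expression would grossly over-express the
replacement gene, a stem-loop "attenuator" placed in the 5' UTR throttles
translation of the rescue ORF. Attenuation strength tracks the hairpin's
folding free energy: the more stable the stem-loop, the less protein is
made. Choosing an attenuator of the right stability therefore titrates
replacement expression to a physiological level — the core requirement for
gene-therapy-style rescue of genes such as *SOD1*, where both over- and
under-expression are harmful.

The package is aimed at synthetic biologists and molecular neuroscientists
building such constructs. It covers the loop end to end:

* **Stem design** — exhaustive enumeration of variable stem sequences under
  composition constraints (fixed length, exactly one A/T pair, forbidden
  restriction motifs on either strand, no self-complementarity), iterative
  "trimming" of the loop-adjacent pair to create graded-stability variants,
  and assembly onto the constant scaffold
  `GCGGCCG + stem + TATACT + revcomp(stem) + revcomp(GCGGCCG)`
  (a NotI-derived G/C-rich base arm and a fixed non-complementary hexaloop).
* **Thermodynamics** — nearest-neighbor scoring of the assembled stem-loop

  ΔG°₃₇ = Σᵢ ΔG°stack(pᵢ, pᵢ₊₁) + ΔG°init(loop) + ΔG°mismatch(closing pair)
  [+ ΔG°AU-end]

  with the Turner 2004 RNA parameters (SantaLucia/Mathews DNA set
  selectable), plus a Nussinov maximum-pairing dynamic program used to
  verify that the intended stem, not an alternative fold, dominates.
* **Panel selection** — exact dynamic-programming selection of a k-member
  panel whose free energies sit on a uniform grid across a working range
  (the useful regime is roughly −27 to −40 kcal/mol, spanning ~50% down to
  ~10% of un-attenuated expression).
* **Calibration** — replicate statistics (mean, SEM, z·SEM confidence
  half-widths), performance ranking of measured attenuators, target-matching
  (`choose_attenuator`), and plasmid-predicted vs genomically-integrated
  agreement checks (`predicted_vs_observed`).
* **Ratiometry** — pixelwise GFP/RFP quantification of attenuation from
  two-channel 16-bit micrographs: tiling of composites, uniform background
  thresholds, mean-of-ratios (or ratio-of-sums) statistics, replicate
  aggregation — plus a seed-deterministic synthetic scene generator for
  closed-loop validation against known ground truth.
* **Construct assembly** — concatenation of parts in the pKDR order
  (promoter, attenuator, Kozak, rescue, [IRES, reporter,] miRE), annotated
  records with 0-based half-open coordinates, GenBank-style round-tripping,
  and validation of the AgeI/NotI, NotI/SbfI, EcoRI/XhoI cloning geometry.

## Worked example

```r
library(kdrdesign)

# score every constrained design with stems up to 8 bp
lib <- build_library(design_constraints(stem_length_max = 8))
lib
#> <kdr_library> 3586 scored hairpin inserts, dG [-39.5, -15.9] kcal/mol

# an 8-member panel uniformly spaced over a working range
pan <- select_panel(lib, k = 8, dg_range = c(-27, -38))
head(pan$members, 3)
#>       id delta_g grid_point   deviation
#> 1 HP0857   -37.9  -38.00000  0.10000000
#> 2 HP1993   -36.3  -36.42857  0.12857143
#> 3 HP2476   -34.9  -34.85714 -0.04285714

# pick the attenuator matching a 35% expression target from measured
# calibration data (percent of the un-attenuated control)
plasmid <- read_calibration(system.file("extdata",
  "calibration_sod1_plasmid.tsv", package = "kdrdesign"))
choose_attenuator(35, plasmid)$entry
#>   hairpin_id delta_g_kcal_mol promoter mean_percent sem n ci95_halfwidth
#> 3       HP13              -34      CBh        34.91 1.4 3          2.744

# does integrated-construct expression agree with the plasmid prediction?
integrated <- read_calibration(system.file("extdata",
  "calibration_sod1_integrated.tsv", package = "kdrdesign"))
predicted_vs_observed(plasmid, integrated)
#>   hairpin_id plasmid_mean ci95_halfwidth integrated_mean abs_deviation within_ci
#> 1       HP06        58.05         5.0568           54.56          3.49      TRUE
#> 2       HP13        34.91         2.7440           35.27          0.36      TRUE
#> 3       HP22         9.10         1.2544            8.14          0.96      TRUE
```

Every integrated-construct mean lies inside the 95% confidence interval of
its plasmid-based measurement — the agreement that makes plasmid
calibration predictive for stable lines.

Closing the loop on the imaging side, a synthetic scene with a known
attenuation fraction is recovered by the ratiometry pipeline:

```r
r    <- generate_synthetic_pair(synthetic_scene(true_fraction = 0.35, seed = 11))
ctrl <- generate_synthetic_pair(synthetic_scene(true_fraction = 1,    seed = 12))
thr  <- ctrl$truth$suggested_threshold
percent_of_control(
  pixelwise_ratio(r$pair,    pixel_mask(r$pair,    thr, thr)),
  pixelwise_ratio(ctrl$pair, pixel_mask(ctrl$pair, thr, thr)))
#> [1] 35.53  # truth: 35
```

A thin command-line front end over the same functions lives at
`inst/cli/kdr.R` (sub-commands `library`, `panel`, `simulate`, `quantify`,
`construct`).

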