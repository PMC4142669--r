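---
title: "Unbiased counting of myelinated nerve fibers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unbiased counting of myelinated nerve fibers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereofiber)
```

# The estimation problem

A transverse semithin section of a peripheral nerve contains on the order
of a thousand myelinated fibers. The quantities of interest in
regeneration studies are the total number of myelinated fibers and their
size spectrum (axon diameter, fiber diameter, myelin thickness, g-ratio).
Exhaustive counting is impractical, so fields are sampled under the
microscope and counts extrapolated. Two classical pitfalls make the naive
extrapolation biased:

* **the edge effect** — a profile straddling a frame border belongs to
  several fields at once; counting "whatever intersects the frame"
  overcounts large profiles, and ad hoc rules ("count left edge, not
  right") are error-prone;
* **resolution truncation** — the thinnest myelinated fibers are below
  what light optics resolve, so a light-microscopy (LM) count is a count
  of *detectable* fibers, systematically below an electron-microscopy (EM)
  count of the same section.

`stereofiber` implements the design-based (stereological) workflow that
removes the first bias by construction, models the second explicitly, and
— because real nerves come without ground truth — ships a synthetic
section generator against which every stage is validated.

# Sampling model

## Fields

Fields are placed by systematic uniform random sampling (SURS): a regular
square grid of candidate field centers covers the nerve's bounding box,
the whole grid is shifted by a single uniform random offset within one
grid cell, and candidates whose field rectangle intersects the nerve disk
are enumerated in serpentine order. Under SURS every point of the section
has the same probability of falling inside a counting frame — the
property all downstream unbiasedness rests on.

Two refinements matter in practice:

* **Exact field count.** A protocol asks for a fixed number of fields
  (`n_fields`), but the random grid may intersect the nerve in more
  candidates than that. Discarding the trailing candidates of the
  serpentine enumeration would systematically ignore one side of the
  section; combined with the random spatial fluctuation of fiber packing,
  that turns into a per-section bias of a percent or two. Instead, when
  `m > n_fields` candidates intersect, the package keeps a *systematic
  subsample* — every `m/n_fields`-th candidate in serpentine order from a
  random start (the fractionator principle) — so every candidate is
  retained with equal probability and no region is favoured.
* **Edge overhang.** Fields need only intersect the nerve, so frames near
  the boundary partly cover epineurium or background. Counting frames are
  not clipped geometrically (the top rule needs no guard zones), but the
  density denominator uses the *tissue* area of each frame, the exact
  frame ∩ nerve intersection (closed-form circle–circle lens; piecewise
  closed-form circle–rectangle integral). For interior frames this equals
  the plain frame area; for overhanging frames it is what keeps the
  density estimator unbiased. Both intersection routines are tested
  against Monte-Carlo integration.

## Frames

* **LM**: two congruent circular frames per field, centered at ±¼ of the
  field width on the field's horizontal midline — congruent, disjoint and
  wholly inside the field. Defaults: 60 × 60 µm field (a 100× oil-immersion
  camera field is some tens of µm), frame radius 10 µm, 15 fields per
  section (the top of the usual 10–15 range, for the most precise count).
  All configurable.
* **EM**: the whole live screen at 8000×, 12.2 × 16.2 µm, is a single
  rectangular frame. Default 100 fields; EM frames are tiny, and 100 of
  them give a total frame area about twice the LM design's, balancing the
  precision of the two modalities.

## The top rule (2D disector)

Each fiber profile is associated with a unique point: the topmost point of
its circular outline, `(x, y + diameter/2)`. A fiber is counted in a frame
iff its top lies inside the frame. Uniqueness of the top is what kills the
edge effect: whatever the frame layout, a fiber can be counted at most
once per tiling, and with half-open rectangular frames
`[x0, x1) × [y0, y1)` a tiling of the plane counts every fiber *exactly*
once — a property the tests assert exactly, not approximately, on 100
generated sections.

Numerical conventions: circular frames use the strict interior (a top at
exactly the frame radius is out); rectangles are half-open so tilings
partition the plane. Both boundaries have measure zero under continuous
coordinates, so the choice cannot bias counts; it only makes the tiling
test exact. Ties are impossible for disks (one maximum each).

The top can be taken on the outer fiber outline (what a toluidine-blue
profile shows at LM — the default for LM designs) or on the axon outline
(what is identified on an EM live image — the default for EM designs).
Both are unique points of concentric disks, so either convention yields
unbiased counts; the package implements both rather than presuming one.

# Estimators

For frames `f` with counts `c_f` and tissue areas `a_f`:

* density `λ̂ = Σc_f / Σa_f` (fibers/mm²; ratio of sums — for congruent
  frames identical to the mean of per-frame ratios, which the tests
  assert);
* total number `N̂ = λ̂ × A`, with `A` the whole-nerve cross-sectional
  area. The EM estimate reuses the same whole-nerve area measured at LM;
  the synthetic pipeline passes the section's true area to both.

Estimates are kept real-valued; rounding happens only in reports. The
acceptance suite verifies that over 1000 independent systematic placements
on one fixed 1200-fiber section, the mean of `N̂` is within 2% of truth
for both the LM and the EM design.

# Morphometry

For each counted fiber the axon and fiber areas give the circle-fitting
(equivalent) diameters `d = 2√(area/π)` and `D`, myelin thickness
`(D − d)/2` and g-ratio. The package computes the g-ratio as `d/D`, the
standard axon-to-fiber convention with support in (0, 1); sources
occasionally print the inverted ratio, so `g_convention = "D_over_d"` is
available, but `d/D` is the default and the one under which "thinner
myelin at equal calibre" reads as a *higher* g. In the synthetic pipeline
areas are derived exactly from the generated diameters; optional
multiplicative lognormal noise (`area_noise_sd`, default 0) emulates
manual tracing error without ever inverting the axon-inside-fiber
geometry. Summaries report means with the sample (n − 1) standard
deviation, the convention of "mean ± SD" figure captions; single-fiber
groups report SD = 0 with an explicit degeneracy flag.

# The detection (resolution) model

Modality-dependent detectability is modelled as a threshold on diameter:
`detection_model("LM")` drops fibers whose **axon** diameter is below
0.5 µm (≈ the diffraction scale of light optics); `detection_model("EM")`
drops nothing. The threshold is applied to the axon because identifying a
myelinated profile at LM requires resolving the pale axon lumen inside
the dark ring; a switch (`diameter = "fiber"`) applies it to the outer
diameter instead for sensitivity analyses. A logistic soft model
(`soft_midpoint`, `soft_slope`) replaces the hard cutoff when the
idealization is too sharp; it is stochastic and seeded. Detection is
applied *before* sampling — the observer never counts a fiber they cannot
see — and leaves the whole-nerve area untouched, since measuring the
nerve outline does not require resolving individual small fibers. The
hard model is monotone (raising the threshold never increases the count)
and nested (the EM-detected set contains the LM-detected set), both
asserted as properties.

# The synthetic section generator

Each fiber is two concentric disks (axon inside myelin) in continuous
Cartesian µm coordinates, origin at the nerve center, y upward. Axon
diameters are drawn from a two-component mixture: a main lognormal
component and a small-calibre lognormal tail (median 0.35 µm, σ_log 0.2)
representing the sub-resolution fibers only EM resolves. The g-ratio is a
truncated normal; fiber diameter follows as `D = d/g`. Defaults:

| parameter | control | regenerated (25 d post-crush) |
|---|---|---|
| axon diameter | lognormal, median 3.5 µm, σ_log 0.35 | median 2.2 µm, σ_log 0.35 |
| g-ratio | Normal(0.65, 0.05) on (0.40, 0.85) | Normal(0.75, 0.05) on (0.50, 0.90) |
| small-fiber fraction | 0.10 | 0.20 |
| fibers per section | 1200 | 1200 |

These are *simulation defaults chosen for plausibility* — a regenerated
nerve has recovered its fiber complement but with smaller axons, thinner
myelin relative to calibre (higher g), and a larger small-fiber tail — not
measured values. Draws violating the physical support (d ≤ 0, g outside
(0, 1)) are rejection-resampled.

Placement is random sequential adsorption (RSA, in C++): fibers sorted by
decreasing diameter, candidate centers uniform on the region keeping the
fiber wholly inside the nerve, overlapping candidates rejected, up to
10 000 attempts per fiber. RSA is simple and reproducible but saturates
well below biological packing: the default nerve radius of 160 µm puts the
default control population at a packing fraction of ≈ 0.40, inside the
regime where largest-first RSA reliably places every fiber. A requested
population whose disk area exceeds `packing_limit` (0.55) × nerve area
fails fast with a packing error rather than looping. Sections are
bitwise-reproducible given (parameters, seed).

The **cohort generator** emulates the paired design of a crush experiment:
each animal contributes a control and a regenerated nerve. Animals share a
lognormal size multiplier (σ = 0.05) on all calibres and the nerve radius;
each nerve's true fiber count is drawn with a between-nerve lognormal
coefficient of variation (`count_cv`, default 0.12) around the phenotype
target, reflecting the ~10–15% count variability between rodent nerves.
Without it every synthetic nerve would carry an identical complement and a
control-vs-crush count comparison would degenerate into a pure test of the
detection asymmetry, which real data do not show. Because fiber number and
nerve calibre co-vary anatomically, a nerve's radius also scales with the
square root of its count multiplier, conserving packing density.

What the generator does **not** emulate: unmyelinated fibers, blood
vessels, Schwann-cell nuclei, fascicular substructure, non-circular or
crenated profiles, staining artefacts, or spatial trends in fiber density
(fibers are exchangeable up to packing constraints). Passing tests
therefore demonstrate the correctness of the *counting and estimation
machinery* under idealized geometry; they cannot certify performance on
real micrographs with misidentified structures, which remains the
observer's responsibility.

# Statistics

All group contrasts are two-tailed paired t-tests (the experimental design
pairs the two nerves of one animal, and the two modalities on one nerve),
computed via `stats::t.test(paired = TRUE)` with explicit degenerate
handling: all differences exactly zero gives t = 0, p = 1; constant
nonzero differences (zero variance) give p = 0 with a
`degenerate_variance` flag instead of an error. Significance tiers use
inclusive cutoffs (\* p ≤ 0.05, \*\* p ≤ 0.01, \*\*\* p ≤ 0.001). No
multiple-comparison correction is applied, matching common practice in
this literature; with four size parameters and several count contrasts per
experiment this is a known limitation the user should keep in mind. The
test's empirical type-I error at n = 5 pairs is validated against the
nominal 0.05 by simulation (10 000 null replicates in the acceptance
suite).

# Seeds and determinism

Every stochastic stage takes an explicit integer seed; the pipeline
derives stage seeds deterministically from one master seed
(`seed × 1009 + stage offset`, reduced modulo 2³¹ − 1), so a replicate
re-run with the same config is identical byte for byte, and two stages
never share a stream by accident. Fiber tables are written with 17
significant digits and parsed with a correctly-rounded reader, so
write → read → write is byte-stable.

# Validation problem sizes

The acceptance suite runs: 1000 systematic placements per modality on one
fixed 1200-fiber section (estimator bias ≤ 2%); 50 random scatters × 20
random frames against a brute-force counting oracle (exact agreement);
100 sections under a tiling of half-open frames (exact one-count-per-fiber);
100 paired LM/EM placements plus 50 five-animal cohorts for the
undercount direction and its paired-t significance; 50 cohorts for the
control-vs-crush contrasts; and 10 000 null t-tests. These sizes keep the
whole suite within a few minutes on one CPU while leaving Monte-Carlo
standard errors well inside the asserted margins.

# Known limitations

* RSA packing cannot reach biological packing fractions (> 0.5); the
  default geometry compensates with a slightly larger nerve rather than
  sparser fibers.
* The hard detection threshold is an idealization of a continuous
  visibility curve; the logistic option softens but does not calibrate it
  against real optics (no PSF simulation).
* Misidentification (counting a non-fiber structure, splitting a crenated
  profile) is not modelled; the unbiasedness demonstrated here is of the
  sampling design, not of the observer.
* Profiles are perfect circles; circle-fitting diameters on real,
  irregular profiles carry shape error the synthetic validation cannot
  probe.
* No coefficient-of-error (within-section variance) machinery beyond
  retaining per-frame counts for diagnostics.
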