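# stereofiber

Design-based stereology of myelinated nerve fibers in R.

Counting every myelinated fiber in a transverse nerve section is
impractical, and naive counting in sampled microscope fields is biased:
profiles straddling a frame edge are counted more than once or not at all
(the *edge effect*), and a light microscope cannot resolve the thinnest
fibers at all. `stereofiber` implements the standard unbiased workflow used
in peripheral-nerve regeneration studies — for example, quantifying how
well a crushed mouse median nerve has regrown — together with a synthetic
ground-truth generator that lets every estimator be validated against a
known answer.

The pipeline:

1. **Systematic uniform random sampling** of microscope fields: a regular
   grid with one uniform random offset, so every location of the section has
   equal inclusion probability. Light microscopy (LM) uses camera fields
   with two circular counting frames each; electron microscopy (EM) uses
   the 12.2 × 16.2 µm live screen at 8000× as one rectangular frame.
2. **Top-rule counting (2D disector)**: a fiber is counted in a frame iff
   the unique topmost point of its profile lies inside the frame — strictly
   inside for circles, half-open `[x0, x1) × [y0, y1)` for rectangles.
   Because each fiber has exactly one top, no tiling of frames can count it
   twice: the edge effect vanishes by construction.
3. **Morphometry** of every counted fiber from its axon and fiber areas:
   circle-fitting diameters `d = 2√(area_axon/π)` and `D = 2√(area_fiber/π)`,
   myelin thickness `(D − d)/2`, and g-ratio `d/D`.
4. **Estimation**: mean fiber density = Σcounts / Σ(frame area ∩ nerve), in
   fibers/mm²; total fiber number = density × whole-nerve cross-sectional
   area.
5. **Resolution model**: fibers whose axon diameter falls below the LM
   detection limit (default 0.5 µm) are invisible to the LM observer but not
   to EM — reproducing the systematic LM undercount seen when the same
   nerves are quantified with both modalities.
6. **Paired statistics**: two-tailed paired t-tests with the conventional
   significance tiers (\*, \*\*, \*\*\* at p ≤ 0.05, 0.01, 0.001).

## Worked example

Simulate one regenerated (25-day post-crush phenotype) nerve with 1200
fibers of known position and calibre, then quantify it as an LM and an EM
observer would:

```r
library(stereofiber)

section <- simulate_section(fiber_phenotype("regenerated"), seed = 11)
section
#> <nerve_section 'regenerated_seed11'> 1200 fibers, nerve radius 160.0 um, area 80425 um^2

lm <- estimate_section(section, sampling_design("LM"), seed = 1)
em <- estimate_section(section, sampling_design("EM"), seed = 1)
glance(lm)
#>           section_id modality total_counted density_per_mm2 total_fibers true_n_fibers
#> 1 regenerated_seed11       LM            81           12144        976.7          1200
glance(em)
#>           section_id modality total_counted density_per_mm2 total_fibers true_n_fibers
#> 1 regenerated_seed11       EM           245           14180         1140          1200
```

The LM observer counted 81 fibers in its circular frames, giving a density
of 12 144 fibers/mm² and an estimated total of about 977 fibers — well
below the EM estimate of 1140, because one fifth of this regenerating
population is a sub-resolution tail the light microscope cannot see (the
EM estimate scatters around the true 1200; the LM estimate scatters around
the 966 fibers of this section whose axons are above the 0.5 µm detection
limit). Morphometry of the counted
fibers:

```r
summarize_measurements(lm$measurements[[1]])
#>   parameter  n  mean     sd
#> 1      d_um 81 2.381 0.8345
#> 2      D_um 81 3.184 1.1726
#> 3 myelin_um 81 0.401 0.1904
#> 4   g_ratio 81 0.754 0.0486
```

A full paired experiment — five animals, each contributing an uninjured
control nerve and a crushed/regenerated nerve, quantified with both
modalities — runs end to end from one config:

```r
res <- run_replicate(pipeline_config(seed = 2024))
res$comparisons[, c("comparison", "t", "df", "p_value", "tier")]
#>                           comparison       t df  p_value tier
#> 1  total_fibers_LM: control vs crush   1.825  4 1.42e-01   ns
#> 2  total_fibers_EM: control vs crush   0.564  4 6.03e-01   ns
#> 3     total_fibers_control: LM vs EM  -2.683  4 5.50e-02   ns
#> 4 total_fibers_regenerated: LM vs EM -12.569  4 2.31e-04  ***
#> 5          d_um_LM: control vs crush  14.128  4 1.46e-04  ***
#> 6          D_um_LM: control vs crush  15.991  4 8.94e-05  ***
#> 7     myelin_um_LM: control vs crush  17.695  4 5.99e-05  ***
#> 8       g_ratio_LM: control vs crush -23.929  4 1.81e-05  ***
```

This is the expected physiology of a nerve 25 days after crush: the fiber
*number* has recovered (control vs crush not significant, rows 1–2), the
fibers themselves are still smaller with thinner myelin (rows 5–7), and
light microscopy undercounts the small-fibered regenerated nerve relative
to electron microscopy (row 4).

`autoplot(section, frames = frames, counts = counts)` draws the section
with its counting frames and highlights the counted fibers;
`plot_estimates(res$estimates)` gives the usual mean ± SD bar chart;
`render_section()` rasterizes a section to a grayscale image.

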