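# poltirf

Orientation analysis of fluorescent sensors in single nuclear pore
complexes (NPCs) imaged by polarized total internal reflection fluorescence
microscopy (pol-TIRFM).

## The problem

NPCs on the basal surface of a flattened adherent nucleus all point the
same way: their eight-fold symmetry axis is perpendicular to the coverslip.
Fusing mEGFP rigidly to a nucleoporin — continuing the nucleoporin's
carboxy-terminal alpha helix into the mEGFP amino-terminal helix — locks
the mEGFP excitation dipole to the orientation of that domain. Excitation
is proportional to cos²Θ between the field and the dipole, so alternating
TIR excitation between p-polarization (along the nucleocytoplasmic axis)
and s-polarization (in the coverslip plane) and forming the per-punctum
intensity ratio

```
p:s = (ix_p ⟨sin²θ⟩ + iz_p ⟨cos²θ⟩) / (ix_s ⟨sin²θ⟩)
```

(with `ix`, `iz` the azimuth-averaged evanescent-field intensity components
and ⟨·⟩ averaging over the sensor's wobble cone) reports the mean dipole
polar angle θ_d of each individual NPC. Shifts of this ratio reveal
conformational changes of the host nucleoporin, e.g. when
nucleocytoplasmic transport is perturbed.

The package is aimed at microscopists designing or validating such
orientational sensors. It provides, end to end and fully testable on
synthetic data:

- a Fresnel-based evanescent-field model with azimuthal beam scanning and
  the closed-form p:s prediction for oriented, wobbling dipole ensembles;
- the linker-geometry model: each residue added to a rigid alpha-helical
  linker twists the fluorophore 103° about the helix axis (flexible
  linkers decouple it), so a working sensor shifts its p:s ratio upon a
  single-residue change;
- an acquisition-faithful simulator (20 alternating p/s frames, Gaussian
  PSF, shot/read noise, camera gain and offset) with ground truth;
- the automated quantification pipeline: frame summing, camera-background
  subtraction, top-hat + Laplacian-of-Gaussian detection in a nuclear ROI,
  dual-polarization Gaussian-fit quality control, and max-pixel p:s ratios;
- acceptor-photobleaching FRET quantification, E = (I_post − I_pre)/I_post;
- condition statistics: quartile summaries, Student's t-test, one-way
  ANOVA with Tukey post hoc, spatial-uniformity and intensity-unimodality
  checks, with broom-style `tidy()`/`glance()` and ggplot2 helpers.

## Worked example

Simulate a control/perturbed pair of fields of view — identical except for
a 20° shift of every NPC's dipole polar angle — quantify both with the
automated pipeline, and compare the per-punctum ratios:

```r
library(poltirf)

base <- scene_spec(seed = 11)            # 128x128 px, 50 NPCs, 20 frames
pair <- generate_condition_pair(base, delta_theta_deg = 20, seeds = c(11, 12))

cfg <- analysis_config(roi = base$nuclear_roi)
a <- quantify_stack(pair$control$stack,   cfg)
b <- quantify_stack(pair$perturbed$stack, cfg)

cmp <- compare_two(a$ps_ratio[a$accepted], b$ps_ratio[b$accepted])
glance(cmp)
#> # A tibble: 1 × 4
#>   test             statistic  p_value n_significant_pairs
#>   <chr>                <dbl>    <dbl>               <int>
#> 1 Student's t-test      35.3 1.74e-57                  NA

c(median_control   = median(a$ps_ratio, na.rm = TRUE),
  median_perturbed = median(b$ps_ratio, na.rm = TRUE))
#>   median_control median_perturbed
#>        2.1163815        0.6061742
```

The control median (~2.1) sits close to the forward prediction for the
default 45° dipole with a 15° wobble cone (`predict_ps_ratio()` gives
2.22; the max-pixel readout carries a small known downward bias), and
tilting the dipoles 20° further from the optical axis drives the ratio
down, exactly the direction the forward model predicts — a highly
significant shift at ~50 accepted puncta per condition.

`plot_condition_boxes()`, `plot_ratio_map()` and `plot_forward_curve()`
draw the standard views; `vignettes/pol-tirf-orientation.Rmd` documents
the model, the algorithm and every default in detail.

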