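# fgfield

Estimation of **figure-ground responsive fields** (RF-FGs): the spatial
map of where figure and ground regions of a visual scene drive a neuron's
spiking, in and around its classical receptive field (CRF). The intended
users are visual neurophysiologists pairing spike counts with
human-derived figure/ground segmentation labels, and anyone validating
such estimators on simulated neurons.

## The method

Each stimulus is represented by an *FG label* `L_i`: a G×G grid of +1
(figure) and −1 (ground) whose boundary passes through the patch center.
Given per-stimulus spike counts `s_i` over N stimuli, the core estimator
is the bias-compensated spike-triggered average

    K = Σ_i L_i s_i / Σ_i s_i  −  Σ_i L_i / N,

whose positive (negative) cells mark locations where a figure (ground)
increases the response. The subtraction cancels the bias from the
non-white label ensemble: a neuron responding equally to every stimulus
yields an exactly zero kernel. Around this core the package provides

* magnitude **permutation significance** (shuffled stimulus→count
  assignment) and a subset-size **convergence ratio** from a saturating
  curve fit — a kernel is *effective* when p < 0.05 and ratio ≥ 0.9;
* an **adaptive filter** (exponentially weighted recursive least squares)
  as a whiteness-free linear cross-check;
* **spike-triggered covariance** `C_spike − C_base` on STA-centered
  labels, with a randomized eigenvalue-difference rule selecting
  significant nonlinear kernels;
* rectified **STA and STA+STC response models** with jointly optimized
  weights, plus a binned-rate linearity diagnostic;
* 2D-Gaussian **CRF fitting**, responsiveness and FG-modulation screens;
* geometry metrics: **PR ratio**, **overlap ratio**, rotation/CRF-scale
  alignment, population averaging;
* a **synthetic module**: half-plane / curved / dot / translated label
  ensembles and virtual neurons (ideal FG, rectified-linear, linear,
  energy, non-FG) with known ground truth.

## Worked example

An ideal figure-preferring cell — one spike whenever the figure side
covers its CRF center — probed with 210 half-plane labels:

```r
library(fgfield)

labels <- gen_halfplane_labels(105, 25)          # 210 labels, 25 x 25
neuron <- virtual_neuron("ideal_fg", crf = crf(center = c(12, 6), 3, 3))
spikes <- simulate_responses(neuron, labels, n_trials = 10, seed = 42)

kernel <- rffg_sta(labels, spikes, n_perm = 1000, convergence = TRUE,
                   seed = 42)
kernel
#> <rffg> STA kernel, 25x25, magnitude 200.8, p_perm = 0.000999, convergence = 1.000, effective

ideal <- ideal_rffg(labels, crf(c(12, 6), 3, 3), "figure")
cosine_similarity(kernel, ideal)
#> [1] 1
pr_ratio(kernel, "figure")
#> [1] 0.5
overlap_ratio(crf(c(12, 6), 3, 3), kernel, "figure")
#> [1] 0.097
```

The estimate is the ideal kernel exactly (cosine 1): a figure-preferring
subregion around the CRF center, an antagonistic ground subregion opposite
the patch center. The PR ratio 0.5 says preferred and non-preferred
subregions occupy equal shares of the kernel's support, and the small
overlap ratio says the preferred subregion extends far beyond the 1-SD CRF
ellipse — both signatures of this stimulus geometry. `plot(kernel)` draws
the signed map; `rffg_af()`, `rffg_stc()` + `significant_stcs()`,
`fit_sta_model()` / `fit_sta_stc_model()` and `run_pipeline()` take the
same objects through the rest of the stack. The methods vignette
(`vignettes/fgfield-methods.Rmd`) documents the models, defaults and
numerical choices.

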