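# nirsax

Decoding whole-text reading-comprehension state (*understood* vs *not
understood*) from multi-channel fNIRS trials.

fNIRS records cortical hemodynamics — oxygenated and deoxygenated
hemoglobin concentration changes — while a participant reads a text; the
signal between the text-onset and text-offset markers is one *trial*.
`nirsax` implements a complete decoder for such trials:

1. **Labeling** — three strategies: by multiple-choice answer correctness,
   by 1–10 self-assessment score (three classes), or *double-validated*
   (both criteria must agree; middle scores and disagreements are
   excluded).
2. **Preprocessing** — linear interpolation of every channel to a common
   length (the set-wide maximum, 1300 samples for study-shaped data),
   then **ICEEMDAN**: improved complete ensemble empirical mode
   decomposition with adaptive noise (ε₀ = 0.2, L = 100 noise
   realizations; compiled EMD sifting core), yielding intrinsic mode
   functions IMF₁…IMF_J with exact reconstruction
   x = ΣIMF_j + residue.
3. **Feature extraction** — one selected IMF per channel is symbolized
   with **SAX** (z-normalization, piecewise aggregate approximation to
   100/650/1300 segments, Gaussian-equiprobable breakpoints for alphabets
   of 5–8 symbols, A=1, B=2, …), augmented by **triple window shifting**
   (three 80%-length windows per trial), and summarized by population
   moments (mean, variance, skewness, kurtosis, std) with sequential
   forward feature selection.
4. **Classification** — k-NN (Euclidean, k tuned in 1–25 by stratified
   trial-level cross-validation) over an exhaustive search of all channel
   combinations of size ≤ 4 (6195 combinations for 20 channels), with a
   stratified 70/30 trial split.
5. **Evaluation** — confusion-matrix metrics (CA, SE, SP, Jaccard,
   F-measure, precision), rank-based ROC AUC, and the **polygon area
   metric**: the six metrics CA, SE, SP, AUC, J, FM on the spokes of a
   regular unit hexagon,
   `PAM = (√3/4 · Σ aᵢbᵢ) / (6√3/4)` over adjacent pairs.

A synthetic hemodynamic trial generator (`synth_generate`,
`study_shaped`) emulates the recording conditions — 450 trials from 15
participants, 20 channels at 10.1725 Hz, variable lengths to 1300
samples, canonical double-gamma responses plus physiological
oscillations, drift and noise, with a controllable class effect — so the
full pipeline is testable end to end without recorded data.

## Worked example

Evaluation of a classifier's test predictions, here reconstructed from a
published confusion matrix (49/3/26/4) of the best double-validated run:

```r
library(nirsax)
cm <- confusion_from_counts(tp = 49, fn = 3, tn = 26, fp = 4)
m  <- basic_metrics(cm)
scores <- c(rep(1, 49), rep(0, 3), rep(1, 4), rep(0, 26))  # hard scores
labs   <- rep(c("understood", "not_understood"), c(52, 30))
m$auc  <- roc_auc(scores, labs, "understood")
pam(m$ca, m$se, m$sp, m$auc, m$j, m$fm)
```

This prints metrics `CA 0.9146, SE 0.9423, SP 0.8667, AUC 0.9045,
J 0.8750, FM 0.9333, precision 0.9245` and a PAM of `0.8207`: the
classifier's polygon fills 82.07% of the full hexagon. (The AUC of hard
0/1 predictions is the single-operating-point area (SE+SP)/2.)

Symbolization in miniature:

```r
symbolize(c(-2.1, -0.3, 0.4, 2.0, 0.1, -1.2), sax_config(6, 4))
#> <symbolic_series> w=6 a=4: ABCDCA       # numeric: 1 2 3 4 3 1
```

An end-to-end run on synthetic data:

```r
ts  <- study_shaped(seed = 11, effect_size = 3)   # 450 trials, 20 channels
cfg <- run_config(strategy = 3, imf_index = 3,
                  channels = c(2, 3, 7, 9, 12, 15),  # reduced search
                  n_runs = 1, select = "test_max", seed = 4)
run_pipeline(ts, cfg)
```

which labels 450 trials (keeping the ~270 double-validated ones), splits
70/30, and searches all 56 combinations of the six channels; with the
planted effect the reported test accuracy exceeds 0.85.

There is also a thin CLI over the same functions
(`inst/cli/nirsax.R generate|run|report`, YAML configs).

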