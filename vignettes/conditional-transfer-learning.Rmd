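---
title: "Conditional transfer learning for EEG emotion classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional transfer learning for EEG emotion classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctleeg)
library(dplyr)
```

## The problem

Subject-dependent EEG emotion classifiers need labeled calibration trials
from the very person they will serve, and collecting ecologically valid
emotional EEG is slow: a music-listening protocol yields perhaps 16 labeled
30-second trials per person. With so little data, per-subject two-class
accuracies (positive vs. negative valence; high vs. low arousal) scatter
widely around the 50% chance level — some subjects engage with the stimuli
and produce learnable EEG correlates, others do not.

Transfer learning offers a way out: borrow labeled trials from *source
subjects* (SSs) already in a repository to improve the model of a new
*target subject* (TS). But borrowing blindly risks **negative transfer** —
pooling data from people whose emotion-related EEG signatures differ from
the target's can make the model worse. `ctleeg` implements a **conditional
transfer learning (cTL)** pipeline that answers the three canonical transfer
questions explicitly:

* **When to transfer.** Only when the TS's *default* model — trained solely
  on the TS's own trials — performs at or below the two-class chance level
  (50%). Such a subject has little to lose and, if their poor default stems
  from noisy or scarce evidence rather than absent signal, much to gain.
  The boundary is inclusive on the poor side: exactly 50% gates as "poor".
* **How to transfer.** From the most *similar* source subjects. Similarity
  is the Pearson correlation between ReliefF feature-relevance weight
  vectors: two subjects are similar when the same hemispheric-asymmetry
  features discriminate their emotional classes.
* **What to transfer.** The selected SSs' labeled feature rows, concatenated
  with the TS's training rows; the feature subspace and classifier are then
  re-optimized on the augmented set.

Two benchmark scenarios bracket cTL: **rTL** (routine transfer: always
augment, regardless of the gate) and **oTL** (oracle transfer: keep
whichever of default/transferred is better per subject — an upper bound
that requires evaluating both, hence not prospective).

## The feature pipeline

Raw trials (trials × channels × samples, microvolts) pass through:

1. **Short-time Fourier transform.** A 1-s Hamming window with 50% overlap;
   per frame and channel, the periodogram is averaged over the bins whose
   center frequency falls inside each of five bands: delta 1–3, theta 4–7,
   alpha 8–13, beta 14–30, gamma 31–50 Hz (inclusive edges at the native
   1-Hz resolution of a 1-s window). Bins outside 1–50 Hz are discarded,
   which realizes the broadband band-pass. Band power is a *mean* over
   bins, not a sum, so bands of different widths are comparable. Frequency
   gaps between the printed band edges (e.g. 3–4 Hz) belong to no band and
   are dropped.
2. **Gain-model baseline calibration.** Each (trial, channel, band) power
   series is divided by the mean power of the frames lying fully inside the
   trial's first 5 s, yielding a dimensionless gain relative to the
   pre-stimulus interval. A zero baseline is a hard error — it can only
   arise from degenerate (identically zero) input.
3. **DLAT (differential laterality).** For each of the 12 left–right
   symmetric channel pairs of the 30-channel 10-20 montage and each band,
   the feature is left-channel minus right-channel calibrated power,
   averaged over the post-baseline frames: 12 × 5 = 60 features per trial.
   The difference direction is fixed as left − right and verified by an
   antisymmetry test (swapping all pair members negates every column).
   Baseline frames are excluded from the temporal pooling by default —
   they define the reference, not the response — but `include_baseline =
   TRUE` restores them, since published descriptions of such pipelines do
   not always pin this down.
4. **Within-subject z-transform.** Each feature column is standardized to
   zero mean, unit variance across the subject's 16 trials (population
   denominator). This is also what makes feature rows from different
   subjects commensurable when they are pooled during transfer.

Symmetric pairs are derived automatically from 10-20 nomenclature (odd
final digit = left, next even digit = its mirror; trailing `z` = midline),
with the legacy temporal labels T3/T4/T5/T6 normalized to T7/T8/P7/P8, and
can be overridden in the montage YAML for non-standard caps.

## Feature weighting, similarity, and the classifier

**ReliefF** (two-class, written from scratch) weights each feature by how
much it separates nearest neighbors of opposite classes versus same-class
neighbors, under Manhattan distance on max-min-scaled features. Defaults:
`k = 10` nearest hits/misses, clipped to the smallest class size minus one
(the literature's standard recommendation), and `m = "all"` — every
instance is visited, making the weights deterministic. Distance ties break
by ascending instance index. The per-subject weight vector over the 60 DLAT
features is both the feature ranking *and* the subject's "emotion-relevant
feature space" for similarity.

**Similarity** between a TS and each SS is the Pearson correlation of raw
ReliefF weight vectors. The published phrase "ReliefF-sorted feature
spaces" admits a rank-based reading too, so a Spearman option exists, but
raw-weight Pearson is the default: it preserves the magnitude information
that rank correlation discards. Source ranking uses signed r descending
(larger r = more similar); the dissimilarity statistic reported per TS is
the population standard deviation of the |r| of the selected sources.

**Gaussian naive Bayes** models each class-conditional feature distribution
as an independent Gaussian: empirical class priors, per-class moments with
the population denominator, variances floored at `1e-9` times the largest
overall feature variance so constant-within-class features cannot produce a
division error. Posteriors are computed in log space; hard-label ties go to
class 0. These numerical contracts are deliberately explicit rather than
delegated to a toolbox default.

## Leave-trial-out validation and the optimization loop

Every per-subject accuracy in the package is a **leave-trial-out (LTO)**
accuracy: with 16 trials, 16 folds, each trained on the other 15. The
held-out trial is disjoint from *everything* — ReliefF ranking, similarity
profiling, source selection, feature-count optimization, and the final fit
— and every fold records the identity of each training row so tests can
audit this mechanically.

Inside each training fold, the feature count `d` is chosen by
**class-balanced repeated cross-validation**: the majority class is
subsampled without replacement to the minority size (500 repetitions by
default; when classes are already balanced the subsample is the identity
and only the fold assignment varies), each repetition runs stratified
5-fold CV, and a GNB is scored on the top-`d` ReliefF features for every
`d` from 1 to 60 ("add one feature in"). Accuracies are pooled over
repetitions × folds before the argmax over `d`; ties go to the smallest
`d`. Whether the original analysis pooled before or after the argmax is
not stated anywhere we could check; pooling first is the lower-variance
choice. If the minority class has fewer members than the fold count, the
repetitions fall back to leave-one-out CV (logged). The final model is
trained on one seeded class-balanced subsample of the (possibly augmented)
training set, so its priors are 0.5/0.5.

In transfer folds the chain is: ReliefF on the TS's 15 training trials →
similarity against each SS's weight space (SS weights come from their full
16 trials) → select the `O` most similar (or dissimilar) SSs → augment
(15 + O × 16 rows, source labels unchanged) → re-rank with ReliefF on the
augmented set → optimize `d` → fit → predict the held-out trial.
Augmentation order is canonical (sorted subject ids), so only the selected
*set* — not the selection rank — can influence the model; this also makes
the similar and dissimilar modes provably identical at `O = n − 1`.

**The transferability gate** defaults to `outer_default`: good/poor is read
off the subject's own full LTO default accuracy, matching how the published
figures group subjects. This uses each trial's outcome in the gate that
also governs that trial's scenario composition, which is fine for
retrospective analysis but not strictly prospective; `gate_source =
"nested"` instead re-estimates the gate inside each fold from the 15
training trials only (an inner LTO), at roughly 15× the cost. The package
implements both because the published procedure is silent on the
distinction.

**Randomness and reproducibility.** All randomness flows from one master
seed through a documented per-(subject, fold, repetition) derivation (a
Lehmer-style fold of integer ids, always below 2^31), so identical
configurations give bit-identical results and partial re-runs reproduce.

## The synthetic cohort generator

The original 26-subject music-listening dataset is not publicly deposited,
so the package ships a generator that emulates its *shape* — 26 subjects ×
16 trials × 30 channels × 30 s at 250 Hz, balanced binary labels per task —
and turns the two scientific hypotheses into explicit knobs:

* **engagement** scales the class-signal amplitude per subject (0 = pure
  noise: no class information whatsoever);
* **signature_similarity** (ρ) mixes a cohort-common discriminative
  asymmetry pattern with a subject-specific one (1 = everyone shares the
  same signature, 0 = fully idiosyncratic).

Each channel carries a 1/f pink-noise background (exponent 1, sd 10 µV)
plus band-limited Gaussian rhythms in the five bands (sds 4/4/5/4/3 µV,
alpha slightly prominent — unremarkable resting-EEG proportions). On a
set of eight active (pair, band) slots per task — fronto-central alpha plus
frontal theta for valence, fronto-parietal beta plus temporal gamma for
arousal, echoing the classic distributed asymmetry markers — the
rhythm amplitude after the 5-s baseline is modulated oppositely on the two
channels of the pair: `1 ± engagement × effect_size × pattern`, signed by
the trial's class label (`effect_size` defaults to 0.4). The baseline is
never modulated, so gain calibration exposes the planted asymmetry.
Because the signal lives purely in band-power amplitudes — the only domain
the feature pipeline observes — this is the simplest mechanism sufficient
to exercise every stage; it deliberately does *not* model eye blinks,
ERPs, phase dynamics, nonstationarity, or the music stimuli themselves.
Consequently, passing tests demonstrate that the pipeline recovers planted
band-power asymmetry structure under realistic noise, not that it would
reach any particular accuracy on real recordings.

Eight slots per task is a deliberate dimensionality choice: subject
signatures are unit-normalized vectors over the active slots, and
inter-subject signature similarity is only a meaningful planted quantity
when idiosyncratic (random) signatures are close to orthogonal to the
cohort-common one. In very few dimensions random signatures align with the
common pattern by chance and "similar" versus "dissimilar" source selection
loses its planted contrast.

`planted_truth()` exposes what was planted — per-subject engagement, the
expected transferability label, and the true inter-subject
pattern-correlation matrix — for parameter-recovery tests.

One honest caveat: a *zero*-engagement subject's realized LTO accuracy is
close to a Binomial(16, ½) draw, so the chance-level gate labels it "poor"
only a little over half the time. Expected transferability is recoverable
for subjects who carry signal (gated "good" in ≥ 90% of runs); for
signal-free subjects the realized gate label is intrinsically a coin toss,
and the tests assert exactly that.

## Study conditions used in the shipped experiments

The hypothesis-recovery experiments (tests and the worked examples) use
8-subject cohorts: a ρ = 1 cluster of five subjects, three of them weakly
engaged (engagement 0.25) and two strongly (1.5), plus three strong
idiosyncratic subjects (ρ = 0). Weak — rather than zero — engagement for
the transfer candidates is deliberate: a signal-free subject's test trials
cannot be classified above chance by *any* model, so transfer gains on
such subjects would be a pure selection artifact; with weak signal, a
model trained on many similar-signature source trials genuinely
outperforms one trained on 15 noisy own-trials. Reduced problem sizes
(8 subjects, 50 balance repetitions, source counts 1..7, and a 128-Hz
sampling rate where the full 250 Hz adds nothing to band power at 1-Hz
resolution) keep every experiment at desk scale; they are the package's
chosen simulation conditions, stated here once so results are
interpretable.

The chance-level calibration experiment keeps the default spec (250 Hz,
30-s trials), permutes each subject's labels uniformly at random, and runs
the full default pipeline over 20 cohort seeds; its mean accuracy is the
package's primary calibration figure and is recomputed from scratch by
`scripts/acceptance.R`.

## Worked example

A compact run at the shipped study conditions (this chunk is not evaluated
during package installation; run it interactively):

```{r example, eval = FALSE}
spec <- cohort_spec(
  n_subjects = 8, fs = 128, duration = 30,
  engagement = c(0.25, 0.25, 0.25, 1.5, 1.5, 1.5, 1.5, 1.5),
  signature_similarity = c(1, 1, 1, 1, 1, 0, 0, 0),
  seed = 701
)
feats <- extract_features(generate_cohort(spec))
cfg <- pipeline_config(task = "valence", n_balance_reps = 50, seed = 801)

ctl <- run_scenario(feats, "cTL", cfg)
rtl <- run_scenario(feats, "rTL", cfg)
dft <- run_scenario(feats, "default", cfg)
glance(ctl)
tidy(compare_scenarios(list(dft, rtl, ctl)))
autoplot(ctl)

sw <- sweep_source_count(feats, cfg, O_range = 1:7)
glance(sw)
autoplot(sw)
```

## Known limitations

* The generator's band-power-domain signal cannot falsify claims about
  phase-based or nonstationary EEG features; it validates the pipeline, not
  the neuroscience.
* The `outer_default` gate is retrospective (see above); prospective use
  should prefer `nested` and accept the cost.
* ReliefF hyperparameters (`k`, `m`) are unreported for the original
  analysis; the defaults here follow the method literature and are
  documented as assumptions.
* EDF interchange quantizes to 16 bits over each channel's range; round
  trips are exact only to one quantization step (microvolt-scale signals
  lose nothing that band-power features would see).
* Four-class emotion labels, cross-dataset transfer, and
  transfer-component methods (TCA/KPCA/TPT) are out of scope.
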