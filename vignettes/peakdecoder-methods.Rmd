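---
title: "Scoring co-elution and estimating identification error rates in LC-IM-MS DIA metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring co-elution and estimating identification error rates in LC-IM-MS DIA metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakdecoder)
```

## The problem

In data-independent acquisition (DIA) every precursor in a wide m/z range is
co-fragmented in every cycle, so a fragment spectrum is never uniquely tied
to one precursor. Targeted data extraction mines such data at library
coordinates and produces, per metabolite and run, a *peak-group*: the
extracted ion chromatograms (XICs) of one precursor and its fragment
transitions. Whether that peak-group is the metabolite or an interference is
a statistical question: true peak-groups show tight co-elution (and, with
ion mobility, co-mobility) of fragments with their precursor and fragment
intensities proportional to the reference spectrum; interferences do not.

Unlike proteomics, metabolomics has no sequence database from which decoys
can be generated by reversal or shuffling, so error rates for metabolite
identification are rarely controlled. The approach implemented here builds
the decoys *from the data*: deconvoluted experimental peak-groups serve as
targets, and paired fragment-swapped versions of them serve as decoys, which
yields a null model with realistic precursor properties without requiring a
single annotated spectrum.

## The procedure

1. **Feature input.** Untargeted feature detection with spectral
   deconvolution supplies precursor features with pseudo-MS2 fragment lists
   (`read_feature_alignment()`).
2. **Target selection and decoy generation.** Features with S/N >= 15 and at
   least 3 fragments within 1-130% of the precursor height are targets; the
   top 16 fragments are kept (`select_targets()`). Targets are paired within
   one representative run — same fragment count, precursor m/z within 50 Th
   (similar molecular size), retention-time difference at least 3 min (so a
   tailing peak is never paired with itself) and otherwise maximal
   (`pair_targets()`). Each pair yields two decoys that keep every precursor
   property while the m/z values of k fragments, k drawn uniformly so that
   k/n is in [0.4, 0.6], are exchanged between the members at matching
   intensity rank (`generate_decoys()`). The paired construction makes the
   decoy marginals (precursor m/z, RT, CCS, fragment count) *exactly* equal
   to the targets' — a prerequisite for a valid target-decoy error model.
   Note that no integer k satisfies the band for n = 3, so 3-fragment pairs
   are excluded, as are targets for which no partner exists.
3. **Extraction.** The transition list (`write_transition_list()`) is handed
   to a targeted-extraction tool; its XIC report (area, height, LC FWHM,
   apex RT, ppm mass error per transition and run) is read back
   (`read_xic_report()`).
4. **Filtering and training.** Fragments with unassigned height are removed;
   each fragment is checked against five quality rules (area <= 0, height
   < 1% of the precursor, |mass error| > 15 ppm, |RT difference| > 0.1 min,
   |FWHM difference| > 2x the precursor FWHM). Targets need a precursor
   S/N >= 20, at least 2 clean fragments and at least 3 fragments in total;
   fragments ranked beyond twice the clean count (ordered by flag count,
   then height) are dropped, which deliberately *keeps* some low-quality
   fragments so the classifier sees realistic interference
   (`filter_training_set()`). Survival is paired: a decoy survives only
   with its target and with the same fragment subset, and the target
   fragment heights become the expected intensities of both. Seven
   descriptors summarize each group (`compute_descriptors()`): the cosine
   similarity between fragment areas and expected intensities, and the mean
   and sample (n-1) standard deviation of the signed precursor-fragment RT
   differences, FWHM differences, and of the fragment mass errors. A
   radial-kernel SVM with standardization, 10-fold cross-validation and
   probability calibration is fitted (`train_peakdecoder()`, via e1071);
   the calibrated target-class probability is the **PeakDecoder score**.
5. **FDR table.** Sweeping every observed score as a threshold gives
   FDR = FP/(TP+FP) per operating point; a monotone envelope (minimum FDR
   over all more lenient thresholds, the q-value transform) makes the
   FDR-to-score mapping well defined (`build_fdr_table()`,
   `fdr_score_threshold()`).
6. **Annotation.** Query metabolites extracted at the coordinates of an
   RT-CCS-MS/MS library are scored with the library fragment intensities as
   the expected vector (`score_queries()`); a metabolite is identified when
   in at least one run |mass error| < 18 ppm, |RT error| < 0.4 min,
   |CCS error| < 0.8% and score > 0.8 — or above the score threshold at the
   requested FDR (`apply_id_cutoffs()`). Groups without enough scorable
   fragments are annotated at the MS1-only RT-CCS level.
   `match_features()` quantifies, per library entry, how combining mass
   (0.01 Th), RT (0.2 min) and CCS (0.8%) tolerances narrows the candidate
   features.

The drift-time offset of fragments relative to their precursor in
drift-tube IM with alternating-energy acquisition is modelled as
`((fragment_mz - precursor_mz)/precursor_mz)*0.7 - precursor_mz*1e-4`
milliseconds (`mobility_offset()`); lighter fragments traverse the
post-drift region faster during high-energy frames, so offsets are negative
and largest for the smallest fragments. The transition-list writer carries
the offset per transition so extraction windows can be centred correctly.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `min_sn` (selection) | 15 | ratio | drop weak UFD features |
| `min_fragments` | 3 | count | minimum in-band fragments per target |
| `rel_intensity_range` | 0.01-1.30 | fraction | fragment/precursor height band |
| `top_n` | 16 | count | fragments kept per target |
| `mz_window` | 50 | Th | pairing: similar molecular size |
| `min_rt_gap` | 3 | min | pairing: avoid tailing-peak self-pairs |
| `swap_fraction_range` | 0.4-0.6 | fraction | fragments exchanged per decoy |
| `min_precursor_sn` (filter) | 20 | ratio | training-set precursor quality |
| quality thresholds | 1%, 15 ppm, 0.1 min, 2x FWHM | — | fragment flags |
| `min_good_fragments` / `min_total_fragments` | 2 / 3 | count | target survival |
| `cost`, `gamma` | 1, 1/7 | — | SVM hyperparameters (1/#descriptors) |
| id cutoffs | 18 ppm, 0.4 min, 0.8%, score 0.8 | — | identification rule |
| selectivity tolerances | 0.01 Th, 0.2 min, 0.8% | — | `match_features()` |

All tabulated values are the method's published operating points; they are
exposed as arguments so that stringency can be raised for high-complexity
samples, where a smaller, cleaner training set estimates low FDRs better
than a large noisy one.

## FDR table: in-sample vs out-of-fold scores

The original procedure scores the *full training set* with the final model
and derives the FDR table from those in-sample scores; this is the default
here (`cmd_train(fdr_scores = "training")`). In-sample decoy scores are
slightly depressed, so the table is optimistic: on synthetic data the
estimated 1% operating point corresponds to roughly 2% held-out FDR — the
same two-fold underestimation reported for the original implementation
against manually curated ground truth. `crossval_scores()` provides
out-of-fold scores (stratified 10-fold); an FDR table built from them is
well calibrated (estimated/actual ratio near 0.9 in the package's
calibration tests) and is the recommended setting whenever the FDR value
itself, not only the ranking, is consumed.

## What the synthetic data emulates

The generator (`simulate_peakgroups()`, `simulate_query()`) models the XIC
summary metrics directly — the only surface the algorithm consumes — not
raw spectra, chromatographic peak shapes or drift-tube physics. True
peak-groups have fragment RT jitter of 0.01 min, mass errors of 3 ppm (sd),
FWHM tracking the precursor and areas proportional to the expected
profile; false groups keep the paired precursor but jitter RT by 0.15 min,
draw 12 ppm mass errors, independent FWHM and a *derangement*
(fixed-point-free permutation) of the intensity profile, so their profiles
are genuinely decorrelated from the expected vector even at small fragment
counts. A 5% interference rate zeroes areas or shifts fragment RTs in true
groups to exercise the filter's interference rules. Precursor S/N is
lognormal (median 60), fragment counts uniform on 3-16, precursor m/z
uniform on 80-800 Th over a 9-minute gradient, and CCS follows a square-root
mass trend — magnitudes typical of small-molecule HILIC drift-tube data.
Absent metabolites in query simulations are modelled as interference picked
up at the library coordinates: random apex RT over the gradient, the CCS of
an unrelated molecule (3% sd), a precursor mass error spread across the
extraction window (uniform +/- 25 ppm) and deranged fragment intensities.

Because the false class is a clean two-component mixture, class separation
is higher than in real samples (cross-validation accuracies around 99.8%
versus 97-99% reported on microbial data), and a passing calibration here
shows that the estimator is consistent under the model's assumptions — not
that real-data FDRs are exact. Conversely, the generator does not model
batch effects, saturation, co-eluting isomer ladders or manual peak-boundary
corrections; parity with identification counts from real studies is out of
reach at desk scale and is not asserted anywhere in the test suite.

## Numerical and design choices

- Fragment intensity ranks break ties by ascending m/z, so ranking is
  deterministic across readers and dialects.
- Missing numeric cells ("", NA, #N/A, NaN) stay missing; no metric is ever
  coerced to 0, and an unscorable group yields a missing score, never 0.
- RT/FWHM differences are signed (the mean carries direction; the sd the
  spread); standard deviations are sample (n-1) throughout.
- The swap positions of a decoy pair are sampled once and mirrored in both
  members, preserving each member's intensity profile.
- Pairing is greedy in descending precursor height and one-to-one, keeping
  the target:decoy ratio exactly 1:1.
- A target whose paired decoy cannot mirror its filtered fragment subset is
  dropped together with the decoy, so target and decoy counts stay equal
  after filtering.
- Cosine similarity of a zero-norm vector is defined as 0 with a warning
  (degenerate group); cosine inputs must be non-negative.
- The FDR threshold for a requested level is the smallest score threshold
  whose enveloped FDR does not exceed it, restricted to operating points
  that accept at least one discovery; when unattainable, the minimum
  attainable FDR is reported with a warning.
- The library's raw fragment intensities are the default expected vector
  for query scoring; max-100 normalized intensities are retained and
  selectable (`intensity_mode = "normalized"`), since cosine similarity is
  scale-invariant the choice only matters when fragments are missing.
- Problem sizes in the test suite (1000+1000 training groups, 10-seed
  sweeps, 500-target decoy checks) were chosen so the full statistical
  behaviour — calibration, marginal preservation, negative control — is
  measurable while the suite stays comfortably re-runnable on one CPU.

## Known limitations

- FDR control bounds the expected false-discovery *fraction*; it cannot
  guarantee zero false positives in any finite query set, and 2-fragment
  query groups are the least discriminable (training groups always have
  >= 3 fragments).
- Very low-complexity samples yield too few targets for reliable FDR
  estimation (the method itself warns below 50 vectors per class).
- The classifier is a single model across fragment counts; per-count models
  and alternative spectral similarity metrics are natural extensions.
- Queries require a library acquired under compatible chromatographic and
  mobility conditions; the package does not predict RT or CCS.
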