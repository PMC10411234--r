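---
title: "Evaluating synthetic-image realism with observer studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating synthetic-image realism with observer studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(realismeval)
```

## The problem and the model

Synthetic medical images are only as useful as they are realistic: for a
simulation study or a virtual clinical trial to transfer to the clinic,
the *distribution* of synthetic images should match the distribution of
real ones, not merely individual exemplars. `realismeval` treats this as
a detection problem. An image is an $M$-pixel vector $\hat{f}$; the
synthetic class is hypothesis $H_1$ with density $q_1(\hat{f})$ and the
real class is $H_2$ with density $q_2(\hat{f})$. In a two-alternative
forced-choice (2-AFC) trial an observer sees one draw from each class and
must pick the real one; the probability of a correct pick equals that
observer's AUC.

The *ideal observer* decides by the likelihood ratio
$\Lambda(\hat{f}) = q_2(\hat{f})/q_1(\hat{f})$ and upper-bounds every
other observer's performance. Its AUC relates to the overlap of the two
distributions through the Bhattacharyya coefficient
$\mathrm{BC} = \int \sqrt{q_1 q_2}\,d^M\hat{f} \in (0, 1]$ and distance
$D_B = -\log \mathrm{BC}$:

$$\mathrm{AUC} \;\approx\; \tfrac12 + \tfrac12\,
  \mathrm{erf}\!\left(\sqrt{2\,D_B(q_1, q_2)}\right).$$

The approximation truncates a Maclaurin expansion of the
likelihood-generating function $G(\beta)$ after its value at the origin,
where $G(0) = -4 \log \langle \Lambda^{1/2} \rangle_1 = 4 D_B$. Two
consequences matter in practice:

* **The floor is meaningful.** $\mathrm{AUC} = 0.5$ exactly when
  $D_B = 0$, i.e. when the synthetic distribution matches the real one.
  An ideal observer at chance certifies distributional realism, which a
  human observer at chance cannot (a human uses some unknown statistic,
  and a matched statistic distribution does not imply matched image
  distributions).
* **The approximation is exact for Gaussian $\lambda$.** When
  $\lambda = \log \Lambda$ is Gaussian — in particular for two Gaussian
  classes with common covariance $\Sigma$ and means $\mu_1, \mu_2$ — all
  higher derivatives of $G$ vanish and
  $\mathrm{AUC} = \Phi(d_A/\sqrt2)$ with
  $d_A^2 = \Delta\mu^\top \Sigma^{-1} \Delta\mu = 8 D_B$. The test suite
  asserts this identity to $10^{-12}$ over random equal-covariance pairs.

The derivation also yields identities the package turns into runnable
checks: $\langle \Lambda^k \rangle_2 = \langle \Lambda^{k+1} \rangle_1$
(`moment_identity_check()`) and $p_2(\lambda) = e^{\lambda} p_1(\lambda)$
(`lambda_density_identity_check()`).

## Estimators and their numerical choices

**Density families.** No particular family is imposed by the theory; the
package implements the minimal set that exercises every estimator path:
multivariate Gaussian (closed form available), Gaussian mixture
(continuous, no closed form), and independent per-pixel Poisson (discrete
counts). How to attach an *empirical* image set to a density model is
deliberately left open: clinical image distributions have no known
analytical form, and fitting one is a research problem outside this
package's scope. The rank-sum estimator `auc_empirical_roc()` is the
model-free entry point when only per-image scores exist.

**Bhattacharyya.** `bhattacharyya()` offers three routes, which the tests
cross-check against each other and against independent oracles:

* `closed_form` (Gaussian/Gaussian): $D_B = \tfrac18 \Delta\mu^\top
  \bar\Sigma^{-1} \Delta\mu + \tfrac12 \log \det\bar\Sigma /
  \sqrt{\det\Sigma_1 \det\Sigma_2}$, $\bar\Sigma = (\Sigma_1 +
  \Sigma_2)/2$, via log-determinants for stability. Identical parameters
  give distance exactly 0 and coefficient exactly 1.
* `quadrature` ($M \le 2$): adaptive integration of
  $\exp\{\tfrac12(\log q_1 + \log q_2)\}$ over ±10 combined standard
  deviations per axis at absolute tolerance $10^{-10}$ (nested 1-D
  adaptive rules; no cubature dependency). For two Poisson models the
  "quadrature" route is an exact summation over all non-negligible
  support. Mixing discrete and continuous families is rejected.
* `sample_mc` (any family, any $M$): the identity
  $\mathrm{BC} = \langle e^{\lambda/2} \rangle_1$ estimated from draws
  under $H_1$, with a standard error from the sample variance,
  propagated to the distance by the delta method. An estimate exceeding
  1 by more than 3 standard errors sets a `flagged` field rather than
  failing: it indicates a mis-specified $\lambda$ or undersampling.

**Log space throughout.** Likelihood ratios are computed and stored as
$\lambda$; $\Lambda$ is materialized only inside reductions like
$e^{\lambda/2}$. Image-scale densities underflow otherwise.

**Ties.** The 2-AFC Monte-Carlo estimator scores ties as one half
($\mathrm{step}(0) := \tfrac12$). This convention is what makes the
sequential estimator coincide in expectation — and the `all_pairs` mode
coincide *bit-exactly* — with the tie-corrected Mann–Whitney AUC, the
2-AFC/AUC equivalence at the heart of the study design. The `all_pairs`
mode therefore uses integer win/tie counts so the half-integer numerator
is exact.

**Stochastic tolerances.** Every Monte-Carlo comparison in the package
and its tests uses a uniform 3-standard-error rule. For the
$\lambda$-density histogram check, per-bin standard errors are plug-in
estimates; a bin is only judged when both the $H_2$ histogram and the
$e^\lambda$-reweighted $H_1$ histogram have at least 10 raw draws in it
(the usual chi-square-test support convention). In particular, the
reweighted estimator cannot say anything about regions $H_1$ never
visits; such bins are reported as sparse or empty rather than failed.

**Reproducibility.** All randomness flows through one named generator
(Mersenne–Twister with inversion sampling), seeded explicitly per call;
global RNG state is saved and restored. Identical model, size and seed
reproduce results bit-for-bit, including byte-identical phantom PNGs.

## The 2-AFC study toolkit

`study_config()` captures what an investigator specifies: title, a
four-digit passcode, instructions, the ordered pair list, a shuffle
switch with its seed, and a contact address. `build_session()` adds one
piece of design hygiene the original web-based protocol leaves implicit:
a seeded fair coin decides per trial which side shows the real image.
Without side randomization, position bias contaminates accuracy; the
truth side is recorded per trial so scoring stays exact.

`score_responses()` reports percent accuracy (kept exact internally,
rounded to integer percent for display, matching how such tables are
conventionally printed), the median confidence with the *lower-median*
convention for even counts (deterministic and integer-valued on the 1–5
scale), a 2×5 correct/incorrect-by-confidence tally, and exact binomial
inference against chance — a two-sided test and Clopper–Pearson 95%
interval, chosen over normal approximations because per-reader trial
counts are small (typically 50). Accuracy credibly *below* chance (CI
upper bound < 0.5) sets an `untrained_flag` on the summary: it usually
means the reader misunderstood the task, and the advice is caution, not
exclusion — the flag never drops data.

`pooled_summary()` sums counts across readers and recomputes everything
on the pooled tally. It takes counts as given: if per-reader percentages
and a pooled count disagree in a source being reproduced, the package
reproduces each as stated and does not reconcile them (the bundled
worked-example fixtures keep the two summaries as separate fixture sets
for exactly this reason).

`sus_score()` implements the System Usability Scale rule: odd items map
strongly-disagree→0 … strongly-agree→4, even items the reverse, total
times 2.5. The flip symmetry (score + flipped-score = 100) and the
0–100 bounds are asserted property-style in the tests.

## What the synthetic generators emulate — and what they don't

* `two_pixel_dataset()` / `two_pixel_sweep()`: the two-pixel Gaussian
  illustration of the AUC–overlap relationship. All math is delegated to
  the distributions and ideal-observer modules; the tests assert equality
  with those modules' outputs so no formula exists twice.
* `phantom_pairs()`: elliptical warm background, random hot disk lesions
  (rejected if they straddle the body boundary; overlaps between lesions
  allowed), Gaussian PSF blur with reflective boundary handling (avoids
  dark frames on small images; recorded in the manifest), then per-pixel
  Poisson noise, written as 16-bit grayscale PNG with a ground-truth
  manifest. The `realism_gap` parameter scales the synthetic arm's
  background and lesion contrast by $1 + \text{gap}$: zero makes the two
  arms exchangeable (any image statistic scores AUC ≈ 0.5), larger values
  create a detectable difference. This is a *stand-in*: it contains no
  scanner physics, attenuation, or reconstruction, and a green test on
  phantoms establishes that the evaluation machinery works, not that any
  particular clinical synthesis method is realistic.
* `virtual_reader_log()`: stochastic readers (per-trial correctness with
  probability `accuracy`, confidence from outcome-conditional
  distributions) and exact-count readers whose tallies hit specified
  counts exactly, used to rebuild published summary tables as fixtures.
  Apportionment of confidence counts uses the largest-remainder method.
* Defaults state a realistic small-study world: 50 trials per reader,
  six readers, 64×64 phantoms at 50 counts/pixel background, lesions of
  radius 3–6 px at contrast 2–4, PSF FWHM 2 px. These were chosen once,
  up front, to mirror small oncologic PET reader studies.

## Known limitations

* The truncation error of the erf approximation beyond the Gaussian-
  $\lambda$ case is not corrected, only probed empirically: for
  unequal-covariance pairs the Monte-Carlo AUC quantifies the gap, and no
  general tolerance is claimed.
* Quadrature is limited to $M \le 2$; higher dimensions must use the
  Monte-Carlo estimator and accept its standard error.
* Density estimation from raw image sets is out of scope, as are
  channelized or anthropomorphic observer models, n-AFC designs, web
  hosting, and DICOM/NIfTI I/O.
* The 16-bit PNG writer is a minimal encoder (no interlacing, no
  scanline filtering); it exists because no installed package writes
  16-bit PNG, and every file it writes is verified against an
  independent decoder in the tests.

## A compact end-to-end run

```{r example}
q1 <- gaussian_model(c(0, 0), diag(2))
q2 <- gaussian_model(c(1, 0), diag(2))
bh <- bhattacharyya(q1, q2, "closed_form")
bh
auc_approx_from_db(bh$distance)
auc_2afc_mc(q1, q2, n_pairs = 2e4, seed = 1)

ses <- build_session(study_config(
  "demo", "1234",
  data.frame(synthetic = rep("s.png", 20), real = rep("r.png", 20)),
  shuffle = TRUE, shuffle_seed = 3, check_files = FALSE))
log <- virtual_reader_log(virtual_reader_spec(0.76), ses, "vr", seed = 2)
score_responses(ses, log, "vr")
```
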