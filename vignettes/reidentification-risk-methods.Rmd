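---
title: "Modelling speaker reidentification risk with reidrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling speaker reidentification risk with reidrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reidrisk` estimates how vulnerable a shared, de-identified speech data set
is to a marketer attack: an adversary enrolls a large set of identified
speakers, scores every shared recording against every enrollment, and
claims a reidentification whenever a score clears a calibrated acceptance
threshold. This vignette explains the statistical model, the synthetic
data generator, the calibration procedure, the numerical choices, and what
conclusions the package's simulations do and do not support.

## The verification model

All inference happens at the embedding level. A recording is a
`d`-dimensional vector assumed to follow the two-covariance PLDA model

$$x = \mu + y_s + \varepsilon, \qquad
  y_s \sim \mathcal N(0, \Phi_b), \qquad
  \varepsilon \sim \mathcal N(0, \Phi_w),$$

with a speaker identity latent $y_s$ shared by all recordings of speaker
$s$. Both covariances are full rank; no subspace truncation is applied,
which keeps scoring exact and is ample at the dimensionalities used here.
The same-speaker versus different-speaker log-likelihood ratio for an
enrolled average $\bar e$ of $n$ recordings and a probe $p$ is computed in
closed form from the joint Gaussian of $(\bar e, p)$ under the two
hypotheses, with the enrolled vector's within-covariance scaled by $1/n$.
Enrollment averaging with this variance correction is the standard
treatment for multi-recording enrollment; scoring reduces to three cached
quadratic forms per distinct $n$, so a full probe-by-enrollment score
matrix is a handful of matrix products.

Fitting is by EM on the exact marginal likelihood. The global mean is the
grand mean; $\Phi_b$ and $\Phi_w$ start from the one-way ANOVA moment
estimates (with negative between-speaker eigenvalues clipped), and the
per-iteration log-likelihood is recorded and checked to be non-decreasing.
EM needs *per-recording* inputs: a single averaged vector per speaker
carries no information about $\Phi_w$, so the pipeline always fits on the
enrollment recordings and averages only for enrollment. If $\Phi_w$
becomes ill-conditioned (condition number above $10^{10}$), a ridge
$\lambda I$ with $\lambda = 10^{-6}\,\overline{\mathrm{diag}(\Phi_w)}$ is
added and the model is flagged `regularized`.

## Threshold calibration

The acceptance threshold minimises the detection cost function
$C_{FR}\,FR(t)\,\pi + C_{FA}\,FA(t)\,(1-\pi)$, with $FR$ and $FA$ as error
*rates* by default. The cost prose can also be read over raw counts, and a
`"counts"` mode is provided, but rates are the default: they are what makes
the prior term meaningful and what standard minDCF implementations
compute. Two presets are built in: `default` $(1, 1, 0.01)$ and `strict`
$(10, 0.1, 0.001)$; the strict preset encodes an adversary for whom a
false acceptance is far costlier than a missed match.

Numerical details that matter:

* **Candidate set.** Error rates are piecewise constant between adjacent
  scores, so the search evaluates midpoints of adjacent sorted unique
  scores plus one sentinel on each side. The sentinels stand in for the
  infinite tails; they are placed half a median inter-score gap outside
  the data rather than at an arbitrary fixed offset, because calibrated
  thresholds are *averaged* across bootstrap runs and must stay finite and
  on the scale of the scores even when a run's optimum is the
  accept-nothing region.
* **Ties.** Equal-cost candidates resolve to the largest threshold — the
  conservative choice for the adversary. Score ties at the threshold are
  accepted (`>=` comparison).
* **EER.** The equal-error operating point is the candidate minimising
  $|FAR - FRR|$, reporting $(FAR + FRR)/2$ there. On small discrete trial
  sets the two rates rarely cross exactly; this is the usual discrete
  convention.

Calibration bootstraps over speakers: each run draws two independent
100-speaker subsets of the training speakers, enrolls the first, probes
one held-out recording per speaker of the second (withheld from the
enrollment average when the speaker sits in both subsets), labels pairs by
identity and feeds them to the minDCF search. Runs with disjoint subsets
have no genuine trial and are discarded; the final threshold is the mean
over retained runs. The subset-pairing geometry intentionally mirrors the
attack itself. The default of 200 runs (100 in the experiment presets,
which train on fewer speakers) sits inside the 100–500 range that makes
the mean threshold stable; an optional stopping rule halts when the
running mean moves less than $10^{-3}$ over 25 runs.

## The synthetic cohort generator

Real inputs to this kind of study — web-scraped celebrity speech and
clinical recordings passed through a pretrained neural embedder — cannot
be redistributed. The generator reproduces the *statistical structure*
that the analysis actually consumes: Gaussian speaker latents
($\Phi_b = I$), within-speaker recording noise, isotropic channel noise,
and per-task effects. Task $t$ rotates the identity latent by $\theta_t$
in a fixed 2-plane (drawn once from the seed) and adds a constant offset
$b_t$; recordings then get noise $\sigma_t^2 \Phi_w$. Rotation plus offset
— rather than loading shrinkage alone — lets a task stay highly
identifiable *within*-task while sharing little identity information
*cross*-task, which is the empirically observed signature of
non-connected tasks such as vowel prolongation.

Two presets define the study conditions:

* `voxceleb_like` — one connected-speech task, 5 recordings per speaker,
  `dim = 16`, within-speaker variance 0.35, channel noise SD 0.25. The
  implied verifier operates at roughly one percent equal error rate,
  comparable to modern embedding systems on broadcast speech. At this
  operating point the strict calibration lands just above the impostor
  maximum of each bootstrap run: most overlap speakers still clear it
  (stable true-acceptance counts) and the false-acceptance rate is pinned
  near the reciprocal of the per-run trial count, so false acceptances
  grow in proportion to the search space — the regime the attack analysis
  is about. An earlier, weaker setting (within-speaker variance 1) was
  rejected at design time because the strict calibration then degenerated
  (no genuine trial above the impostor maximum in most runs) and the
  threshold tracked training-set size instead of the score scale.
* `mayo_like` — six elicited tasks ordered by similarity to connected
  speech (reading > sentence > word > SMR > AMR > vowel), 3 recordings per
  speaker per task. Along that ordering the rotation angle (0.15, 0, 0.5,
  0.85, 1.2, 1.5 rad; sentence is the reference) and offset magnitude
  (0.3, 0, 0.8, 1.4, 2.0, 2.8) increase while the within-speaker scale
  (0.37, 0.35, 0.30, 0.25, 0.19, 0.14) decreases — stereotyped tasks have
  few dynamic speaker factors. The scales were fixed once so that the
  sentence-to-sentence baseline under the default cost preset sits in the
  reported clinical operating regime (precision around two thirds at
  500 × 55 comparisons); the vowel task's offset is large enough that
  connected-speech training transfers almost no identity information to
  it. Reading is more connected than sentence repetition yet sentence is
  the rotation reference; reading therefore carries a small nonzero angle.

The generator does **not** model: audio, neural embedding geometry
(non-Gaussian tails, length concentration), speech disorders as acoustic
phenomena, longitudinal drift, or distinct recording-condition factors
(the cassette/DVD/microphone variation collapses into the single channel
noise term — the original augmentation protocol behind embedding averaging
is not inferable from the published description). Consequently the
simulations replicate *qualitative orderings and trends* — how risk moves
with search-space size, overlap and task similarity — not the published
numeric values, which depend on real audio and a pretrained embedder.

## Attack execution and risk accounting

A split samples known speakers uniformly among those eligible for the
enrollment task, overlap speakers uniformly from the known set, and
unknown-only speakers from the remainder; each unknown speaker contributes
exactly one probe recording, withheld from that speaker's enrollment
average. If a requested known-set size exceeds the eligible pool (as
happens for task-limited designs), all eligible speakers are used and the
shortfall recorded. Acceptance variants: `all` (every pair above
threshold), `rank1` (best match per probe only), `topN` (the N best
accepted pairs overall — an adversary who knows the overlap size);
`pool_probes` replaces each probe by the speaker's mean embedding across
all recordings, modelling linkable shared data.

Risk summaries count true and false acceptances (the attack's true/false
positives). Conventions for the derived quantities:

* `FAR = FA / (comparisons − genuine pairs)`: impostor comparisons are the
  statistically correct base, and at attack scales the distinction from
  total comparisons is negligible.
* Precision is *undefined* (`NA`), not zero, when nothing is accepted;
  aggregation averages per-run precision over runs with at least one
  acceptance and reports how many contributed.
* `FA/TA` is also reported as the ratio of mean counts. The two
  conventions answer different questions and need not be consistent with
  each other, so both are computed and labelled.
* Trend tests are Pearson correlations with the exact two-tailed
  $t$-distribution p-value ($t = r\sqrt{(n-2)/(1-r^2)}$); no multiple
  testing correction is applied, matching the analysis the package
  replicates.

## Experiment presets and problem sizes

The experiment presets shrink the original set sizes about tenfold while
preserving overlap counts, split counts and cost presets: the realistic
scan uses known sets of 200, 500 and 1000 speakers against 50 unknown (5
overlap, strict preset, 20 splits per size), the full-overlap worst case
the same sizes with every unknown speaker known, and the task scenarios
500 known / 55 unknown / 5 overlap with the default preset, 20 splits.
Each split refits the PLDA on its own known set and recalibrates the
threshold, as a per-scenario-trained attacker would. These sizes keep a
complete experiment family in the low minutes on one CPU while leaving
enough events for the trend statistics; per-split false-acceptance counts
are small and bursty at this scale, so correlation estimates carry
visible sampling noise from the split lottery.

Every random stage — cohort generation, split sampling, probe choice,
bootstrap subsets — derives its stream from one master seed through a
deterministic mixer, making experiments reproducible byte for byte.

## Limitations

Synthetic Gaussians cannot certify the absolute risk of any real data
set; they quantify how risk *scales* under a correctly specified verifier.
Passing the package's checks therefore shows the pipeline's mechanics and
orderings are right, not that a particular clinical corpus is safe to
release. Multistage attacks (demographic prediction to prune the search
space), score normalisation (s-norm/z-norm), non-Gaussian embedding
geometry and cross-corpus domain shift are out of scope.
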