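---
title: "Methods: intersubject correlation, movement annotation, and the engagement model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intersubject correlation, movement annotation, and the engagement model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(iscpipe)
```

## The analysis in one paragraph

Several viewers watch the same block-structured silent video while EEG is
recorded.  Correlated component analysis (CorrCA) finds channel weightings
whose projected time courses correlate maximally across viewers; each
viewer's intersubject correlation (ISC) — the sum of their leave-one-out
correlations over the top three components — indexes how strongly the
stimulus drives their brain in common with everyone else's, and is treated
as a marker of attentional engagement.  Computing ISC in 1.5 s sliding
windows (0.3 s hop) gives an engagement time course that is then regressed,
in a linear mixed-effects model with subject random intercepts, on the
movement content of the stimulus (annotated from pose keypoints), the
viewer's age group, their interaction, and a low-level visual-dynamics
covariate (ALD).

## Model and assumptions

**Covariances.** With per-subject centered data $X_k$ over non-excised
samples, $R_{kl} = X_k X_l^\top/(n-1)$, $R_w = \tfrac1N\sum_k R_{kk}$,
$R_b = \tfrac1{N(N-1)}\sum_{k\neq l} R_{kl}$.  Both are averaged
element-wise with equal weight across stimuli (video blocks) so a single
set of projection vectors serves all stimuli.

**CorrCA.** $w$ maximizes $\rho(w) = w^\top R_b w / w^\top R_w w$; we solve
the generalized eigenproblem of $R_b$ against the shrunk
$(1-\gamma) R_w + \gamma\,(\mathrm{tr}\,R_w/D)\,I$.  Assumptions: a common
channel montage and temporal alignment across subjects (zero-phase
filtering preserves it); spatial stationarity of the shared response over
the recording (one global $W$).  The forward model
$A = R_w W (W^\top R_w W)^{-1}$ (computed from the regularized $R_w$,
which matters only when channels were zeroed) is what should be
interpreted topographically, never $W$ itself.

**ISC.** Leave-one-out: for subject $k$ and component $c$, the Pearson
correlation between $y_{kc}$ and the mean of the other subjects'
$y_{jc}$; ISC$_k = \sum_{c \le K} r_{kc}$ with $K = 3$.  Negative
component correlations are summed as-is, not clipped.  Windowed ISC
re-removes per-subject means within each window and never refits $W$.

**Engagement model.** `isc ~ group * movement + ald + (1 | subject)`,
REML, reference levels `movement = "neither"` and `group = "adults"`;
movement is an exhaustive, exclusive four-level factor (`both` is its own
level, not an `arm`+`leg` coding).  The model assumes independent
residuals — see "Known limitations" for why that assumption is the
pipeline's weakest link at this window geometry.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `hp`, `lp` | 1, 50 | Hz | analysis band of the preprocessing chain |
| filter order | 4 | — | Butterworth sections, zero-phase (forward-backward) |
| `k_sd_channels` | 4 | SD of channel power | bad-channel zeroing threshold |
| `k_sd_outliers` | 3 | SD of \|x\| | outlier threshold, rule configurable |
| `pad_ms` | 40 | ms | zeroed margin on each side of an outlier |
| `skip` | 5 | s | clip-onset excision (scene cuts inflate ISC) |
| `gamma` | 0.1 | — | covariance shrinkage; 0 breaks on zeroed channels |
| `window_len`, `hop` | 1.5, 0.3 | s | window geometry (80% overlap) |
| `k_sum` (K) | 3 | components | ISC = sum of top-3 correlations |
| `theta_low`, `theta_high` | 2, 30 | px/frame | dual displacement thresholds |
| `rule_fraction` | 0.25 | — | window positive if ≥25% transitions positive |
| `df_method` | satterthwaite | — | df for fixed-effect t-tests |

The movement thresholds have no principled defaults: in the source study
they were tuned by visual inspection, so here they are plain configuration
with a displacement histogram available from `limb_displacement()` output
for tuning.  The 25% window rule is this package's choice: at 25 fps a
1.5 s window holds ~37 transitions, so a short (~1.4 s) arm movement that
overlaps a window substantially still clears the bar, while a 1–2-frame
flicker does not.

## What the synthetic generator emulates — and what it does not

Every subject shares one latent source $s(t)$ (Gaussian noise band-limited
to 1–15 Hz so the preprocessing band passes it), multiplied by a gain
track $g(t) = \text{base\_gain} + \text{movement\_gains}[\text{category}(t)]$
and mapped to channels by a fixed smooth topography; subject noise is
independent.  Movement gates the *shared* signal only — the one mechanism
by which stimulus movement can move ISC — so downstream effect estimates
have a known monotone relationship to the generating gains.  Movement
events alternate with gaps as exponential renewal processes with the
event-duration means reported for the source stimuli (arm ≈ 1.36 s,
leg ≈ 9.2 s; gap means 4 s and 20 s are this package's choice of a
plausible event density).  Keypoint tracks add Gaussian jitter everywhere,
exact per-frame displacements during events, and large whole-skeleton
jumps at clip boundaries; frame stacks have per-clip base luminance and
per-frame global modulation with an independently recorded ALD track.

Defaults are a reduced scale of the study design: 8 subjects, 32 channels,
250 Hz, 2 blocks of 4 × 15 s clips (the study: 39 subjects, 32 common
channels, 500 Hz, 4 blocks of 4 min).  Not emulated: volume conduction
from a head model, 1/f spectra and alpha rhythms, heteroscedastic or
subject-specific topographies, realistic video content, pose-estimation
failure modes (identity switches, partial occlusion).  A green test on
synthetic data therefore establishes the *mechanics* of the pipeline
(recovery, alignment, determinism, calibration of the machinery under its
own assumptions), not performance on real EEG.

## Numerical choices

- **Filtering** is zero-phase forward–backward IIR (Butterworth, order 4
  per section) with odd-reflection padding scaled to three cutoff periods
  of the high-pass section; the mean is removed before filtering so a DC
  channel maps to exactly zero.  Tests compare measured sinusoid gains to
  the filter's analytic squared-magnitude response.
- **Outlier rule**: the wording "magnitude exceeded 3 SDs of the mean
  magnitude" admits several readings; the default flags
  $|x| > \text{mean}|x| + 3\,\text{SD}(|x|)$ and the alternatives
  ($3\,\text{SD}(|x|)$, $3\,\text{SD}(x)$) are selectable.  Thresholds are
  computed before any zeroing; flagging is single-pass, as is bad-channel
  detection, and both are per subject.
- **ICA**: symmetric fastICA (logcosh), per subject, deterministic from a
  seed.  Ocular components are selected by $|r| > 0.7$ against an EOG
  surrogate built from the frontal channels and low-passed at 8 Hz —
  without the low-pass, on independent-noise data a component aligned with
  one frontal channel reaches $|r| \approx 1/\sqrt2 > 0.7$ spuriously.
  An explicit component list overrides selection; an empty list is the
  identity.
- **Degenerate inputs**: all-zero channels are never rescaled (z-score
  leaves them; ISC counts zero-variance projections as 0 and logs it);
  windows with more than 50% excised samples are dropped and flagged, and
  the drop propagates structurally to the annotation and ALD series, which
  receive the ISC grid by reference.
- **Sign convention**: each forward-model column's largest-magnitude entry
  is made positive, making results invariant to subject order and LAPACK
  sign choices.
- **Satterthwaite df** are computed from lme4's deviance function:
  df$_j = 2 v_j^2 / (g_j^\top A\, g_j)$ with $v_j$ the coefficient
  variance, $g_j$ its finite-difference gradient in the variance
  parameters, and $A$ twice the inverse Hessian of the REML criterion.
  On singular fits the Hessian is not positive definite and the code
  falls back to residual df with a warning.  Validated against the
  classical closed form (df $= m - 2$ for a balanced two-group
  between-subject effect).
- **Wilcoxon post-hoc**: exact null for $n \le 25$ paired subjects, normal
  approximation with continuity correction above; all-zero difference
  vectors return $p = 1$ rather than erroring; the Bonferroni family is
  all pairwise movement comparisons across the four (group × ALD-level)
  panels.

## Design decisions where the design was open

- *ISC formulation*: correlation of each subject with the **mean of the
  others** (not the mean of pairwise correlations).  This is the
  formulation consistent with "a single number per participant" and is the
  one the tests pin down.
- *Pooling*: all subjects enter one pooled CorrCA; ICA and channel/outlier
  statistics are per subject.
- *ALD*: enters the mixed model unstandardized (a z-scored variant is
  available); transitions spanning a clip boundary are excluded from the
  per-window maximum since they encode cuts, not motion — mirroring the
  rationale for excising clip onsets.
- *Person matching* in multi-person frames is by detection index; the
  annotation is an "any joint of the category, any person" rule.
- *Windowed ISC* drops windows with >50% excision (configurable); partial
  windows are otherwise used as-is.

## Known limitations

**Type-I calibration of the window-level mixed model fails by
construction.**  With 1.5 s windows every 0.3 s, adjacent windowed-ISC
values share 80% of their samples, and movement regressors arrive in runs
of many consecutive windows (events last 1.4–9 s and are smeared by the
window length).  The engagement model assumes independent residuals, so
the standard errors of the window-level movement effects are understated
by roughly 2–3×: in the package's own null simulation (all movement gains
zero, 200 replicates — `tests/testthat/test-acceptance.R`, criterion 5)
the per-effect false-positive rate at $\alpha = 0.05$ is ~0.4 instead of
0.05.  No choice available within this pipeline's fixed window geometry
and model formula restores nominal calibration; the honest remedies are
per-subject aggregation before testing (exactly what the post-hoc
Wilcoxon procedure does), non-overlapping windows, or a residual
autocorrelation model.  Effect *recovery* (sign, monotonicity in the
generating gain, CI coverage of a real effect) is unaffected and green.

Beyond that: the leave-one-out ISC of filters fit and scored on the same
noise data is positively biased by component selection (the null tests
use held-out filters); the synthetic world's simplifications listed above
bound what green tests can certify; and Bonferroni across all panels is
conservative when conditions are correlated.
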