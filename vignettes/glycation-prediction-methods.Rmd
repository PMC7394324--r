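---
title: "Predicting lysine glycation from residue structural context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine glycation from residue structural context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GlycSite)
```

## The problem

Glycation is the non-enzymatic attachment of reducing sugars to lysine
(and arginine) side chains. Because no enzyme selects the site, glycated
lysines show little sequence-motif bias, which makes them hard to
predict from the primary sequence alone. GlycSite instead classifies
each lysine by the *predicted structural context* of its neighbourhood:
per-residue accessible surface area (ASA), backbone angles
$\phi, \psi, \theta, \tau$, and three-state secondary-structure
probabilities $(p_h, p_e, p_c)$, as produced by standard structure
predictors in the `.spd3` per-residue table dialect. Producing those
profiles is an external preprocessing step; this package consumes them.

## Data model and encoding

Each annotated lysine $K_i$ is cut out with a fixed window of odd
length $\delta = 2\sigma + 1$ (default $\delta = 13$, $\sigma = 6$):

$$S_{K_i} = \{A_{-\sigma}, \dots, A_{-1}, K_i, A_{1}, \dots, A_{\sigma}\}.$$

When the site lies within $\sigma$ residues of a terminus, the missing
flank is filled by **mirror reflection**: window position $q < 1$ maps
to $2 - q$ and $q > L$ to $2L - q$, applied repeatedly until the index
lands in $[1, L]$. The terminal residue itself is not duplicated — the
reflection is a true mirror about the boundary — and the rule is total
for every protein of length at least 2, which matters because curated
glycation sets contain peptides as short as 20 residues. Which slots
were mirrored is recorded per segment.

Every window slot contributes the 8-value feature block
$F = (\mathrm{ASA}, \phi, \psi, \theta, \tau, p_h, p_e, p_c)$ of the
residue it resolves to, concatenated in N→C order: $\delta \times 8$
dimensions, i.e. 104 under the defaults. Angles enter raw, in degrees —
the feature set is defined as the angles themselves, not a sin/cos
embedding.

### Scaling

Features have wildly different natural ranges (ASA in tens of
Å², angles in $[-180, 180]$, probabilities in $[0, 1]$), so vectors are
min–max scaled to $[0, 1]$ per dimension, the standard libsvm-guide
practice. The scaler is fitted on training data only — inside
cross-validation it is refitted on each training fold and applied to
the held-out fold, and test values are deliberately *not* clipped to
$[0, 1]$. A dimension that is constant in the fitting set maps to 0.

## Class balancing by kNN cleaning

Benchmarks of this kind are imbalanced at roughly 1:6
(glycated : non-glycated). Before training, the negative class is
reduced by **kNN cleaning** with $k = 16$: a negative is removed iff it
appears among the $k$ nearest negatives (Euclidean distance on scaled
vectors) of at least one positive, a single pass taking the union over
positives. Ties are broken by ascending sample index, so the filter is
deterministic and order-independent. All positives are kept. The
alternative reading — drop a negative whose *own* $k$-neighbourhood
contains a positive — is available as
`knnFilterConfig(mode = "negative-neighborhood")`.

**Filter placement.** The replicated protocol cleans once, before any
fold structure exists (`filterPlacement = "pre-cv"`). This leaks
information: the retained negatives are precisely those far from
positives in feature space, including the positives of future test
folds, so even label-permuted data scores above chance under this
placement. The package therefore also provides
`"within-fold"` placement, where each training fold is cleaned
independently and test folds are never filtered; the permuted-null MCC
is then indistinguishable from 0, and that placement is what the
bundled null checks use. Reported headline numbers use the pre-CV
placement for comparability with the conventional protocol; both modes
are one flag apart.

## Classifier

A soft-margin SVM with the polynomial kernel in the libsvm convention

$$\kappa(u, v) = (\gamma\, u^\top v + c_0)^d, \qquad
  \gamma = 0.03125,\; c_0 = 0,\; d = 3,\; C = 512,$$

the grid-searched settings for this task. The $\gamma$ multiplier is
part of the kernel definition: a tuned $\gamma$ is only meaningful
under this parameterisation. Training delegates the quadratic program
to libsvm (via e1071), but the stored model is self-contained — support
vectors, dual coefficients $\alpha_i y_i$, bias $\beta$, kernel
parameters and scaler — and the decision function

$$f(x') = \sum_i \alpha_i y_i\, \kappa(x_i, x') + \beta$$

is evaluated by the package's own kernel-sum code, which the tests
check against an explicit Gram-matrix computation. A strictly positive
$f$ predicts glycated; an exact zero maps to non-glycated, the
conservative choice given that false-positive glycation calls are the
clinically costly error. `gridSearch()` reproduces the usual
exponential $(C, \gamma)$ ladder; it optimises mean CV accuracy by
default (MCC is available via `objective = "mcc"`) and breaks ties
toward smaller $C$, then smaller $\gamma$.

## Evaluation protocol

`runKFoldCV()` draws, per repeat, a fresh stratified partition into
$k$ roughly equal folds (stratification matters: with a few hundred
samples unstratified 6-folds can go degenerate). Each fold is held out
once; scaler and SVM are refitted on the remainder; every sample is
tested exactly once per repeat. Per repeat, the held-out predictions
are pooled and Sn, Sp, Acc, MCC (zero denominators define a metric as
0) and AUC are computed, then averaged over repeats — micro-averaging
within a repeat is more stable with small folds than per-fold
macro-averaging, and matches the convention of averaging independent
re-partition runs (50 in the full protocol). AUC uses the raw decision
values — the only continuous output — in the rank/Mann–Whitney
formulation, ties counting half. The jackknife is implemented as
leave-one-out: $n$ deterministic fits, pooled predictions, no repeats.
`pairedMetricTest()` compares two methods' per-run metrics with a
paired two-sided t-test (all-zero differences give $p = 1$, constant
non-zero differences $p = 0$). `windowSizeScan()` re-runs the whole
pipeline per window length.

## The synthetic benchmark generator

Real inputs require an external structure predictor and a curated site
database, so the package ships a seeded generator that emulates the
*shape* of such a benchmark: 55 proteins of uniform length 50–400,
~7% lysine content, and a glycated fraction of $235/1753 \approx 0.134$
(optionally exact counts via `nSites`/`nPositives`). Background
features per residue: ASA $\sim \mathcal{N}(60, 25^2)$ truncated at 0;
$\phi \sim U(-180, -30)$, $\psi \sim U(-120, 180)$ (Ramachandran-like),
$\theta \sim U(70, 150)$, $\tau \sim U(-180, 180)$;
$(p_h, p_e, p_c) \sim \mathrm{Dirichlet}(2, 1, 2)$. Residues within
±2 of a glycated site receive mean shifts — ASA $+15$ Å², $p_h +0.15$
(renormalised), $\tau +10°$ (wrapped) — sizes chosen so the classes
overlap substantially but remain separable well above chance, similar
in spirit to a mid-strength biological effect. The signal lives in the
structural features, never the residue letters, matching the working
hypothesis that structural context rather than sequence motif carries
the information; confining it to ±2 residues also makes the window-scan
optimum testable (windows beyond ±2 add only noise dimensions).

What the generator does **not** emulate: spatial autocorrelation of
real secondary structure, predictor-specific error characteristics,
homology between proteins, or composition biases. Passing the bundled
checks therefore demonstrates that the pipeline is implemented
correctly and can recover a planted structural signal — not that any
particular accuracy will be achieved on real proteins.

## Numerical and design choices

- Positions are 1-based and inclusive everywhere, as in `.spd3` files
  and PTM databases.
- Non-standard residues (X/B/Z/U) are ordinary positions: features come
  from the profile, not the letter. No sequence-length limits.
- `.spd3` parsing is header-name-driven when a header exists,
  positional otherwise; the file stores probabilities coil-first
  (P(C), P(E), P(H)) while the feature block orders them
  $(p_h, p_e, p_c)$.
- $p_h + p_e + p_c$ outside $[0.9, 1.1]$ warns but does not fail;
  predicted probabilities are not guaranteed normalised.
- All randomness flows from explicit integer seeds; the same seed gives
  byte-identical synthetic bundles, CV summaries and model files. Text
  serialisations use `%.17g`, so model round-trips preserve decision
  values exactly.
- The bundled end-to-end checks run 10-fold CV with 10 repeats on the
  default 55-protein synthetic benchmark (~900 sites before cleaning),
  a size at which the repeat-mean MCC is stable to well under 0.05
  while the whole run stays in tens of seconds; the full 50-repeat
  protocol is one argument away.

## Limitations

The kNN-cleaning semantics that produced the historically reported
1518→303 negative reduction are under-determined (union semantics can
remove more or fewer depending on neighbour overlap), so that count is
not a reproduction target; both plausible semantics are implemented.
The pre-CV filter placement overstates generalisation performance for
the reasons above. Independent-test-set evaluation and probability
calibration are out of scope.
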