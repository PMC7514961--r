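---
title: "Heart-sound classification with wavelet-fractal features and a twin SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-sound classification with wavelet-fractal features and a twin SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpcg)
```

## The problem

A phonocardiogram (PCG) records the acoustic activity of the heart. Each
cardiac cycle contains two principal transients — S1 (closure of the
atrioventricular valves, energy concentrated below ~100 Hz) and S2 (closure
of the semilunar valves, somewhat higher-pitched) — and, in many
pathologies, a *murmur*: broadband noise generated by turbulent flow,
typically in the 100–400 Hz band and locked to a phase of the cycle (the
systolic interval between S1 and S2 in the cases modelled here). The task
is binary screening: label a short recording *normal* or *abnormal*.

`twinpcg` implements a complete pipeline: a fixed 5 s analysis window
(10,000 samples at 2000 Hz, zero-padded when the record is shorter — how
variable-length records are windowed is our choice, made once), an
18-dimensional feature vector, and a kernel twin support vector machine.

## The features

**Subband two-norms.** The window is decomposed to level 4 with the
orthogonal Daubechies-6 filter pair, splitting *both* the approximation and
the detail branch at every level, so all 16 terminal subbands
(4,0)…(4,15) are retained in natural (Paley) order — no best-basis
pruning, which also means the entropy criterion that usually guides
pruning has no effect on a full fixed-depth tree. Feature *k* is the
two-norm of subband *k*'s coefficients. Boundary handling is
periodization, chosen because it makes the transform exactly orthogonal:
the Parseval identity (coefficient energy = signal energy) then holds to
machine precision and is asserted in the tests. The norms are computed on
the raw decomposition coefficients rather than reconstructed node signals;
under orthogonality the energies agree, and the coefficient route avoids a
second filter pass.

**Wavelet energy entropy.** With node energies $E_k$ and fractions
$\varepsilon_k = E_k / \sum_j E_j$, the entropy is
$H = -\sum_k \varepsilon_k \ln \varepsilon_k$ with $0 \ln 0 := 0$. Two
conventions needed fixing. First, the total energy is the plain sum
$E=\sum_k E_k$ — the only normalisation under which the fractions sum to
one, which is the defining constraint of the distribution. Second, $H$ is
computed once per record over the 16 node fractions (a per-sample variant
is not well defined when the fractions are per-node constants). The
logarithm is natural; any other base rescales $H$ by a constant that the
downstream z-scoring absorbs. $H$ is invariant to recording gain and
bounded by $[0, \ln 16]$, with the maximum iff the spectrum is uniform —
both tested. A zero-energy window has no defined entropy and is rejected
with an error rather than a silent placeholder value; the pipeline applies
this rule to every feature set so that a silent record never yields a
feature row.

**Box-counting dimension.** The sampled waveform is treated as a polyline,
time mapped to $[0,1]$, amplitude affinely mapped to $[0,1]$ (a flat
signal maps to the constant 1/2), and the unit square tiled by
$\delta\times\delta$ boxes anchored at the origin. Covering the
interpolated polyline — not the isolated sample points, which undercount
at coarse scales and break refinement monotonicity — is counted column by
column: each column contributes
$\lfloor v_{\max}/\delta \rfloor - \lfloor v_{\min}/\delta \rfloor + 1$
boxes. Scales follow the dyadic rule $\delta_i = 2^{i-1}\delta_t$ with
$\delta_t$ the sample spacing; the default number of scales is
$i_{\max} = \lfloor \log_2 N \rfloor - 4$ (nine scales for $N = 10{,}000$),
keeping at least 16 samples in the coarsest column. The dimension is the
ordinary least-squares slope of $\log N_\delta$ vs $\log(1/\delta)$ over
*all* computed scales — no automatic scaling-region selection. The
estimate is invariant to positive affine amplitude maps by construction
(asserted to 1e-12) and reported with its $r^2$.

One bias is worth stating plainly: a *sampled* signal is a rectifiable
polyline below the sample scale, so at the finest dyadic scales the local
log–log slope tends towards 1 regardless of the underlying process. For
discretised Brownian paths (asymptotic dimension 1.5) at $N = 10{,}000$
the 20-seed mean estimate under the default scale rule is ≈ 1.37, with
coarse-scale local slopes near 1.45 — the estimator approaches the
asymptote from below. The unit tests freeze the simulation-verified value
rather than the asymptotic one. For classification this bias is harmless:
all records share it, and only the *ordering* of roughness matters.

## The classifier

The twin SVM fits two nonparallel hyperplanes in the kernel-expanded
space, $K(x, C^\top)u_k + b_k = 0$, where $C$ stacks all training rows, by
two quadratic programs: plane 1 minimises
$\tfrac12\lVert K(A,C^\top)u_1 + e b_1\rVert^2 + c_1 e^\top \zeta$ subject
to $-(K(B,C^\top)u_1 + e b_1) + \zeta \ge e$, $\zeta \ge 0$ (close to the
abnormal class $A$, at least unit distance from the normal class $B$, with
hinge slack), and plane 2 mirrors the roles. A test point joins the class
of the nearer plane, distances
$d_k = |K(x,C^\top)u_k + b_k| / \sqrt{u_k^\top K(C,C^\top) u_k}$ (the
absolute value is required for a distance; the printed form of the
decision rule omits it but the verbal rule — nearer plane wins — implies
it). An exact tie is assigned to the normal class, the literal "otherwise"
branch of that rule.

Numerically, each dual is a box-constrained QP
$\min_\alpha \tfrac12 \alpha^\top G (H^\top H + \epsilon I)^{-1} G^\top
\alpha - e^\top\alpha$, $0 \le \alpha \le c$, with no equality constraint —
so exact cyclic coordinate descent applies: every coordinate update is the
closed-form box-clipped minimiser, the objective never increases, and
iteration stops when the projected-gradient (KKT) residual falls below
1e-12 scaled by the curvature of $Q$. The curvature scaling matters: when
a class Gram block is nearly singular the ridge $\epsilon = 10^{-6}$ makes
$Q$ entries of order $10^6$, and an unscaled residual threshold would
never be reached. The ridge itself is required because $H^\top H$ is
singular whenever the class size plus one is below the number of training
rows — the usual case with a kernel expansion. The tests validate the
whole dual route against an exact primal brute force (exhaustive
enumeration of the hinge KKT states) on every small instance: worst
observed objective gap 2e-6.

Features are z-scored with training-set statistics inside `twsvm_fit`
(switchable off). The norms are of order 10, the entropy of order 1, the
dimension of order 1.5; an unscaled Gaussian kernel would be dominated by
the norms. The statistics are stored in the model and reapplied at
prediction, never recomputed from test data — a no-leakage property the
tests assert by recomputation. Default hyperparameters are
$c_1 = c_2 = \sigma_1 = \sigma_2 = 3.5$; the cross-validation grid is a
single point at these defaults unless the user supplies a grid, since no
search protocol beyond repeated 10-fold CV is canonical for this method.

## Evaluation

With abnormal as the positive class: accuracy, sensitivity (= recall),
specificity, precision and F1, all in percent. A measure whose denominator
is zero raises an error naming the measure — silent zeros corrupt grid
search. Cross-validation folds are stratified (class proportions
preserved; screening cohorts are imbalanced), deterministic given the
seed, and ties in mean accuracy go to the first grid row. The train/test
split is stratified and requires an explicit seed; 200 training records
are used when at least 350 are available, otherwise the same 4/7
proportion.

## The synthetic cohort

`synthesize_pcg` builds one record: Gaussian-enveloped tone bursts for S1
(default 50 Hz centre, ~90 ms envelope) and S2 (80 Hz, ~70 ms) at the
configured heart rate, plus — for the abnormal class only — band-limited
(100–400 Hz) murmur noise confined to the systolic interval by a
raised-cosine window, plus white sensor noise. Identical configurations
(including the seed) give bit-identical waveforms, and the normal/abnormal
pair for one seed differs only inside systole.

`synthesize_dataset` turns this into a cohort with per-record variation:
heart rate U(45, 120) bpm; S1 and S2 centre frequencies U(35, 65) and
U(65, 105) Hz; log-uniform recording gain on 0.3–3 (uncalibrated devices);
murmur amplitude U(0.35, 0.6) for patients (a loud murmur, grade 3+); and
two contaminants present in essentially every real auscultation:
continuous flow/respiratory noise in the murmur band (flat spectrum,
amplitude U(0.09, 0.19) for healthy subjects, U(0.03, 0.08) for patients,
whose murmur dominates the band instead) and 1/f friction/motion artifact
over 20–450 Hz, amplitude U(0.01, 0.04). White noise sd is fixed at 0.005.

The amplitude ranges were chosen once, with a specific statistical shape
in mind: the *total* murmur-band energy distributions of the two classes
overlap, so no single subband energy separates them. What does separate
them is how that energy is organised in time — murmurs are locked to
systole, flow noise is diffuse — and temporal organisation is exactly what
the time-blind subband norms (and the entropy, a function of them) cannot
see, while the box-counting dimension can: at matched band energy a
bursty signal is smooth over most columns and diffuse noise is rough
everywhere. The consequence, visible in the acceptance run, is that the
16-norm descriptor performs modestly, adding the entropy helps little,
and adding the fractal dimension lifts test accuracy above 90% — the same
qualitative ordering of the three nested feature sets that motivates
carrying all 18 features on real data, produced here by a mechanism rather
than by a lucky seed.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: real murmur spectra (shape, radiation, grading),
diastolic and continuous murmurs, split or variable S2, arrhythmia,
pediatric heart rates, sensor placement effects, clipping, and the
label noise of human annotation. Results on this cohort validate the
*pipeline's mechanics*, not clinical performance.

## Numerical choices and degenerate inputs

* Signals are zero-padded to a multiple of $2^{\text{level}}$ before
  decomposition (padding preserves energy, so Parseval still holds).
* Records shorter than $2^{\text{level}}$ samples, zero-energy windows,
  multi-channel WAVs, non-positive kernel widths, empty classes, and
  infeasible stratifications all raise immediate, specific errors.
* Integer PCM is rescaled to $[-1, 1]$ on read so that the
  scale-dependent norm features are computed on one fixed convention.
* The box-count column scan uses the exact sample-aligned fast path when
  $\delta$ is a multiple of the sample spacing (the dyadic scales always
  are) and a boundary-interpolating general path otherwise; both agree
  with a brute-force rasterizer exactly on the tested fixtures.
* Problem sizes in the test-suite and acceptance runs — a 350-record
  cohort, 10,000-sample windows, brute-force oracles on instances with at
  most 20 training points and 512-sample signals — were chosen as the
  smallest sizes at which every contract of the method is exercised at
  full fidelity.

## Known limitations

* No heart-cycle segmentation: features are window-global. Recordings
  shorter than 5 s are zero-padded, which dilutes all features.
* No resampling: records must already be at the configured rate.
* The fractal estimator's finite-sampling bias (above) makes its absolute
  value scheme-dependent; compare dimensions only within one pipeline.
* The twin SVM stores the full training matrix; prediction is
  $O(n_{\text{train}})$ per record. Fine at cohort scale, not for
  streaming use.
* Hyperparameter selection beyond the single default grid point is the
  user's responsibility; the package deliberately ships no automatic
  search heuristic.
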