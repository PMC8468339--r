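---
title: "Simulation model and evaluation statistics in mrisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation model and evaluation statistics in mrisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrisim)
```

`mrisim` is a *teaching* simulator: its goal is that a trainee who turns a
knob on an MRI console (TE, TR, flip angle, slice angulation, an artifact
toggle) sees the image change the way a real scanner would, at interactive
speed. It deliberately trades physical completeness for responsiveness and
transparency: every stage is a closed-form expression or a linear operator
that can be inspected, not a Bloch-equation integrator. The package also
ships the statistical toolkit used to evaluate whether such a simulator
actually improves learning outcomes in a randomized pre/post two-group
design.

## The simulation model

### Anatomical model

The ground truth is a set of co-registered 3-D maps: proton density (PD,
dimensionless in $[0,1]$), longitudinal relaxation time $T_1$ and
transverse relaxation time $T_2$ (both ms), an optional main-field
inhomogeneity map $\Delta B_0$ (ppm), and an integer tissue-label map.
`build_phantom()` paints geometric primitives (ellipsoids, boxes, slabs)
into these maps; later tissues overwrite earlier ones, so a pathology is
simply one more primitive painted over healthy tissue. Enforced invariants:
$PD \in [0,1]$, $T_1, T_2 > 0$ and $T_2 \le T_1$ wherever tissue is
present, and an orthonormal direction matrix.

`head_phantom()` provides nested ellipsoids with literature-typical 1.5 T
values (CSF $T_1 \approx 4000$ / $T_2 \approx 2000$ ms, grey matter
$900/100$, white matter $600/80$, fat $260/80$). These defaults are
pedagogical, not an atlas: passing tests on this phantom demonstrates the
pipeline's correctness, not anatomical realism.

$\Delta B_0$ only exists to demonstrate why shimming matters, so any
smooth reproducible field suffices: `make_b0_perturbation()` low-pass
filters white Gaussian noise with an isotropic Gaussian kernel of the
requested correlation length (mm) and rescales to the requested peak
amplitude (ppm). Volumes are exchanged as NIfTI-1 files (64-bit float, so
round trips are bit-exact) tied together by a JSON manifest.

### Geometry and reslicing

A `plan_geometry` is the full clinical prescription: an orthonormal
frequency/phase/slice axis triad, in-plane FOV and matrix, slice thickness
and centre-to-centre separation, stack centre, and a phase-oversampling
factor. Pixel $(i,j)$ of slice $s$ (1-based) sits at

$$\mathbf{x} = \mathbf{c}
  + \Big(\tfrac{i-0.5}{N_f}-\tfrac12\Big)\,\mathrm{FOV}_f\,\hat{\mathbf{f}}
  + \Big(\tfrac{j-0.5}{N_p}-\tfrac12\Big)\,\mathrm{FOV}_p\,\hat{\mathbf{p}}
  + \big(s-1-\tfrac{n_s-1}{2}\big)\,\Delta s\,\hat{\mathbf{s}},$$

with voxel-centre sampling and zero-based half-open grids throughout.

`reslice()` samples the property maps by trilinear interpolation (labels:
nearest neighbour) and realizes slice thickness by averaging `n_sub = 5`
midpoint-centred sub-planes across the slab. Averaging the *property maps*
before contrast evaluation is a partial-volume approximation — the exact
alternative would average the contrast of infinitely many sub-voxels — but
it is linear, cheap, and exact for homogeneous regions and linear ramps
(both covered by tests). Outside the model, PD and $\Delta B_0$ resolve to
0 and $T_{1,2}$ to a 1 ms sentinel, so empty space contributes exactly
zero signal and no division by zero can occur. The default
frequency-encoding direction follows the longer in-plane anatomical
extent; the user can swap the assignment, as consoles allow.

### Sequence contrast

Contrast is evaluated per voxel with the canonical steady-state textbook
expressions, all times in ms and the flip angle $\alpha$ in degrees:

* Spin echo (SE, also the in-plane expression for FSE):
  $S = PD\,(1-e^{-TR/T_1})\,e^{-TE/T_2}$
* Spoiled gradient echo:
  $S = PD\,\sin\alpha\,\dfrac{1-E_1}{1-E_1\cos\alpha}\,e^{-TE/T_2^*}$,
  $E_1 = e^{-TR/T_1}$, maximal at the Ernst angle
  $\alpha_E=\arccos E_1$
* Inversion-recovery SE (magnitude reconstruction):
  $S = PD\,\lvert 1-2e^{-TI/T_1}+e^{-TR/T_1}\rvert\,e^{-TE/T_2}$

Note that the IR magnitude is *not* monotone in TR at fixed TI: the
recovery term $e^{-TR/T_1}$ enters with positive sign, so shortening TR can
move a tissue across its null. This is a property of the closed form, not a
bug, and is asserted as such in the tests (monotonicity is checked in TE,
and in TR for SE only).

Gradient echoes see $T_2^*$ from the additive-rate model
$1/T_2^* = 1/T_2 + \gamma' B_0 \lvert\Delta B_0\rvert$ with
$\gamma' = 2\pi\cdot 42.576\times10^{-3}\ \mathrm{ms^{-1}T^{-1}ppm^{-1}}
\approx 0.2675$, the angular frequency of a 1 ppm offset — a deliberate
upper-bound coupling that makes an unshimmed magnet visibly hurt the image.
The shimming option simply evaluates contrast with $\Delta B_0 \equiv 0$.
Field strength enters *only* through this term; relaxation times are not
rescaled with $B_0$ (a documented simplification — the point is the
mechanism, not quantitative field dependence).

Saturation bands multiply PD (not the final signal) inside their slab, so
their effect propagates identically through every family. The coil model is
binary on purpose: a homogeneous (body) coil is 1 everywhere; a surface
coil decays as $e^{-d/\lambda}$ with Euclidean distance from its reference
point, making coil choice visible without a full biot-savart model.

### k-space and artifacts

`forward_kspace()`/`inverse_recon()` use the **unitary, DC-centred** 2-D
DFT. The unitary scaling is what makes two statements exact: Parseval's
identity (asserted to 1e-9 relative in every artifact-free run) and "a
noise sigma in k-space is the same sigma in image space". Artifacts are
applied in a fixed order matching a single acquisition pass:

1. **Echo-train attenuation** (FSE): phase line $j$ is scaled by
   $e^{-t_j/T_{2,\mathrm{eff}}}$, where $T_{2,\mathrm{eff}}$ is the
   PD-weighted mean $T_2$ of the slice and $t_j$ the echo time of the
   line's echo under linear ordering anchored so the centre lines are
   acquired at the echo closest to TE:
   $t_j = TE + (e_j - e^*)\,\Delta TE$ (clamped at 0), $e^* =$
   round$(TE/\Delta TE)$ clamped to $[1, ETL]$. With $ETL=1$ every line
   carries the same $e^{-TE/T_{2,\mathrm{eff}}}$ — a pure global scale —
   while longer trains blur the point-spread function along phase.
   A per-line scalar filter (rather than voxel-wise weighting) keeps the
   operation a k-space filter, which is exactly how the blurring is taught.
2. **Motion**: periodic rigid in-plane translation along the frequency
   axis during phase encoding. Line $j$ acquires
   $e^{-2\pi i k_f d_j}$ with $d_j = A\sin(2\pi j/p)$; a period of $p$
   lines produces ghosts at multiples of $N_p/p$ pixels along phase —
   the classic discrete-ghost law, verified on point phantoms for
   $p \in \{4, 8, 16\}$. Inter-line (not intra-line) motion is the
   simplest model that produces it.
3. **Spikes**: a complex amplitude added at one k-space offset from DC;
   the reconstruction gains a plane-wave stripe whose cycle counts equal
   the offset.
4. **Thermal noise**: i.i.d. circular complex Gaussian added to every
   entry; the air region of the magnitude image then follows a Rayleigh
   law with the same scale (asserted by a Kolmogorov–Smirnov test at
   level 0.01 on $10^4$ pixels).
5. **Reconstruction**: plain inverse magnitude, or partial-Fourier
   synthesis — keep the first $\lceil f N_p\rceil$ phase lines
   ($f \in (0.5, 1]$, plus optional overscan) and fill the rest by
   Hermitian conjugation. No phase-correction stage is applied: the fill
   is exact for zero-phase images and visibly fails when image phase is
   present, which is itself the teaching point.

Phase wrap-around is handled on the contrast image before the forward
transform: with the no-phase-wrap option the phase-oversampled
reconstruction is centre-cropped; without it the oversampled extent folds
by periodic summation $I(p) = \sum_m I_{\mathrm{over}}(p + mN_p)$. For
real images this placement is equivalent to folding after reconstruction
and keeps k-space at the nominal matrix for every artifact operator.

Every stochastic stage draws from `derive_seed(root_seed, stage_label)`,
so a session is bit-reproducible from `(model, protocol, seed)` and adding
one artifact never perturbs another's noise stream.

### Protocols and the CLI

`validate_protocol()` resolves a JSON document into typed objects,
returning an itemized `"json.path: message"` error list rather than
raising, so a console front end can show all problems at once. Patient
position is provenance metadata only — it does not alter physics.
`run_protocol()` executes entries in order and records provenance
sufficient to re-run bit-identically. A thin command-line front end
(`inst/cli/mrisim.R`: `phantom`, `plan`, `simulate`, `score`, `analyze`)
wraps the exported functions for shell use.

A 256×256, 10-slice artifact-free SE entry takes about 2.5 s on one CPU
core (design target: interactive, ~2 s); the batched shared-weight
trilinear gather in `reslice()` is the dominant cost.

## The evaluation statistics

The measurement instrument is a 20-item multiple-choice questionnaire
(four options plus an explicit "I do not know"), split into a theory part
(items 1–10) and a practical part (items 11–20). Two ratings are
implemented: **hits** (number of correct answers) and **null-expectation**
(+1 per hit, −1/3 per error, 0 per "I do not know", so uniform guessing
over four options scores zero in expectation — verified by Monte Carlo
within 3 standard errors at $10^5$ draws).

Reliability uses KR-20 for binary hit scores and Cronbach's alpha for the
numeric null-expectation rating. Conventions matter in the third decimal
at $n = 60$ and are fixed as: item proportions $p_i$ with divisor $n$;
all other variances unbiased ($n-1$). On a binary matrix KR-20 equals
alpha exactly when both use the same item-variance convention, a property
the tests assert.

`select_items()` reduces a part to a target size by greedy backward
elimination maximizing KR-20, with deterministic tie-breaking (lowest
corrected item-total correlation, then lowest index). Exhaustive search
over all subsets confirms the greedy choice on the test fixture. The
published reduced subsets {4,5,6,8,10} and {11,12,13,17,20} are accepted
as fixed inputs for reproduction runs, since the exact original selection
procedure is not recoverable from its description.

`compare_groups()` mirrors the reported analysis path: Shapiro–Wilk
normality per group gates a pooled-variance two-sided unpaired t-test
versus a two-sided unpaired rank-sum test. (The unpaired rank-sum test is
the only internally consistent reading of the analysis description, which
names a signed-rank test yet states that unpaired tests were run; a
signed-rank test is paired by construction.) A constant sample is treated
as failing normality. Effect sizes use Cohen's d with the pooled SD,
$d = (m_1 - m_2)\big/\sqrt{\tfrac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}}$,
which with equal $n$ reduces to $\sqrt{(s_1^2+s_2^2)/2}$ — the form that
reproduces the published post-test practical-part value 0.684 from its
printed summary statistics. No multiple-testing correction is applied, as
none is described for the original analysis. Learning gain is the matched
post-minus-pre difference per participant; unmatched records are dropped
with a logged count.

### The synthetic response generator

`generate_responses()` emulates the deposited data layout (participant,
phase, group, 20 responses) with a logistic item-response model: each
participant has a persistent latent ability $a \sim N(0,1)$; each item is
skipped with the "don't know" propensity (default 0.35) and otherwise
answered correctly with probability $\mathrm{logit}^{-1}(a - b_j)$, with
default difficulties an increasing grid on $[0.6, 1.4]$ logits. These
defaults keep pre-test scores low (about 1 of 5 reduced-part items
correct), matching what novices score on an expert-written instrument.

The effect parameter is a **target Cohen's d on the hits-score scale** of
the configured items. Because Bernoulli item noise attenuates any latent
shift (a 0.7-logit shift yields roughly d ≈ 0.5 on scores), the generator
calibrates the latent shift by computing the score mean and variance under
the response model by numerical quadrature over the ability distribution
and root-finding the shift whose standardized score difference equals the
target. Parameter-recovery simulations (200 replicates at n = 200/group)
recover a configured d = 0.7 within ±0.1, and the full
score-then-compare pipeline has a type-I error within [0.035, 0.065] at
nominal 0.05 over 2000 null replicates.

What the generator does **not** emulate: item-specific discrimination,
learning transfer between parts, response styles, or missingness beyond
the "don't know" mechanism. Passing tests on synthetic cohorts therefore
validates the statistical machinery and its calibration, not conclusions
about any particular real cohort.

## Numerical choices and degenerate inputs

* Transform convention: unitary, DC at `floor(n/2)+1`; all artifact
  operators preserve it.
* Tolerances: identity reslice 1e-12; interpolation oracles 1e-6;
  transform round trips 1e-10; Parseval 1e-9 relative; orthonormality
  1e-9.
* Degenerate inputs rejected with typed conditions: `t2 > t1`,
  non-positive spacing/FOV, `te >= tr`, `ti >= tr`, flip outside (0, 90],
  partial-Fourier fraction ≤ 0.5, spike outside the matrix, fewer than 3
  observations per group, zero total-score variance (undefined
  reliability).
* Ties in item selection and the rank test are handled deterministically
  (documented tie-breaks; normal approximation with continuity and ties
  correction).

## Known limitations

No Bloch-equation dynamics, chemical shift, flow, diffusion, EPI
distortion or parallel imaging — deliberately out of scope for an
interactive teaching tool. The phantom generator produces primitives, not
segmented anatomies. The FSE model uses a per-slice scalar
$T_{2,\mathrm{eff}}$, so tissues with very different $T_2$ within one
slice share one blur kernel. Partial-Fourier reconstruction has no
homodyne/POCS phase correction, by design.
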