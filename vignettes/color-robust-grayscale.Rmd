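---
title: "Grayscale conversion for color-robust histopathology analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grayscale conversion for color-robust histopathology analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histogray)
```

## The problem

Hematoxylin-and-eosin (H&E) slides digitized on different scanners or in
different laboratories differ systematically in color: staining protocols,
reagent batches and scanner optics all shift channel intensities and hue.
Models trained on one source often degrade sharply on another. Because H&E
carries most of its diagnostic signal in morphology — dark blue/purple
nuclei against pink stroma — collapsing the three color channels to a single
intensity channel is a candidate standardization step: it removes the
variable (color) at the cost of chromatic detail. `histogray` provides the
computational machinery to study that trade-off: the conversion operators
themselves, the tile preparation pipeline around them, and the evaluation
and paired-statistics layer used to compare models trained on different
inputs.

The deep networks whose outputs those statistics compare are deliberately
out of scope: the package ingests per-sample predictions (correct/incorrect
outcomes, scores, masks), it does not train models.

## Conversion operators

Four classical operators map a pixel $(R, G, B) \in [0,1]^3$ to a gray
value:

* **Intensity** $(R + G + B)/3$,
* **Luster** $(\max(R,G,B) + \min(R,G,B))/2$ — the HLS lightness channel,
* **Luminosity** $0.21R + 0.72G + 0.07B$,
* **Luminance** $0.3R + 0.59G + 0.11B$.

All four are convex channel combinations: they preserve $[0,1]$, fix
achromatic pixels, and are monotone in every channel. The luminosity and
luminance weights above are the package defaults; the ITU-style triple
$(0.299, 0.587, 0.114)$ can be passed through the `coefficients` argument
for cross-library comparison.

### Luminance rounding dialects

Different computer-vision libraries implement the *same* luminance formula
with different low-level arithmetic, and the resulting one-quantization-step
discrepancies are large enough to change downstream model behavior. Rather
than asserting a cause for any particular library pair, the package models
the *class* of discrepancy with two documented dialects: `"float"` evaluates
the weighted sum in double precision; `"fixed-point-8bit"` quantizes the
channels to 0–255 (round half up, matching the image-export rule), rounds
the 8-bit weighted sum half to even, and rescales. An exhaustive sweep of
all $256^3$ 8-bit triples (run in the test suite and the acceptance script)
confirms the dialects never differ by more than $1/255$ per pixel.

### ACSRM

The attention-based operator derives its channel weights from the
relationships *between* channels. With $F \in \mathbb{R}^{3 \times N}$ the
matrix of flattened channel vectors:

$$ G = FF^{\mathsf T}, \qquad
   Z_{i\cdot} = \frac{G_{i\cdot} - \mu(G_{i\cdot})}{\sigma(G_{i\cdot}) + \varepsilon}, \qquad
   S = \mathrm{softmax}_{\text{row}}(Z), \qquad
   \mathrm{gray} = \tfrac{1}{3}\, \mathbf{1}^{\mathsf T} S\, F. $$

Design choices that the printed formula leaves open, and how they were
resolved:

* **Orientation of $F$.** Channels are rows, so $G$ is $3\times 3$. This is
  the only orientation in which $\tfrac13 \mathbf 1^\top S F$ yields one
  value per pixel and the $1/3$ prefactor makes the implied channel weights
  $w = \tfrac13\mathrm{colSums}(S)$ a convex combination; the alternative
  ($N \times N$ pixel attention) is quadratic in image size and leaves the
  $1/3$ meaningless.
* **Standardization axis.** $\mu_{\text{row}}$/$\sigma_{\text{row}}$ are
  row-wise (population $\sigma$ over the 3 entries of each row), and the
  softmax is applied row-wise to match. A whole-matrix standardization
  reading is conceivable but contradicts the explicit row subscripts; it is
  noted here and not implemented.
* **Degeneracy.** On an achromatic image every Gram row is constant and
  $\sigma_{\text{row}} = 0$. The guard $\varepsilon$ (default $10^{-8}$)
  takes $Z \to 0$, the attention to uniform, and the weights to
  $(\tfrac13,\tfrac13,\tfrac13)$ — the natural limit.
* **Scale.** $G$, $\mu_{\text{row}}$ and $\sigma_{\text{row}}$ all scale by
  $a^2$ under $\mathrm{img} \mapsto a\,\mathrm{img}$, so the weights are
  scale-invariant and the operator is positively homogeneous of degree one.
  Weights computed on 0–255 inputs equal those computed on $[0,1]$ inputs.
* **Scope.** Weights are computed per image from the full frame (the
  formula is global). Per-image rather than dataset-level statistics are
  used; tiles extracted from one slide therefore each get their own
  weights.

These properties — row-stochasticity, convexity of $w$, homogeneity,
invariance under pixel permutation, equivariance under channel permutation,
and exact agreement with an explicit scalar-loop evaluation — are all
asserted in the test suite.

## Tile preparation

### Tissue localization

Tissue is located on the intensity-converted image: H&E tissue is darker
than the white slide, so foreground is the *darker* side of the Otsu
threshold. Otsu's threshold maximizes the between-class variance
$\omega_0\omega_1(\mu_0-\mu_1)^2$ over a 256-bin histogram with an exclusive
two-class split; the implementation is the package's own vectorized
cumulative form (first-argmax on plateaus), checked against a naive
per-threshold search in the tests. The binary map is cleaned by
morphological closing (disc radius 5 px), hole filling and removal of
components below 0.1% of the image area — all configurable toolkit
defaults, since localization post-processing protocols vary — and
components are labeled with 8-connectivity.

### Conditional patch extraction

Patch eligibility follows class-aware area rules evaluated on the aligned
label mask, with strict `<` and inclusive `>=` bounds exactly as printed in
the protocols they mirror. Two presets ship: the prostate-cancer preset
(background < 50%; non-cancer: cancer < 30% and benign >= 50%; cancer:
cancer >= 30%; 10 patches per class) and the metastasis preset (background
< 70%; non-cancer: cancer < 20% and normal >= 30%; 10 non-cancer and 30
cancer patches). The metastasis protocol prints only its background and
non-cancer adjustments; the cancer rule (>= 30%) is inherited from the
previous strategy it amends. Windows are 0-based and half-open,
$[r, r+S) \times [c, c+S)$.

The extractor enumerates *all* eligible top-left positions exactly (window
compositions via per-class summed-area tables) instead of rejection-sampling
candidate coordinates. Non-overlapping placement then proceeds greedily
through a seeded random permutation of the eligible positions; if the
random order falls short of the target, a deterministic row-major repacking
pass recovers a maximal disjoint set. The count so achieved *is* the
"iteratively reduced" target: a random first placement can block a packing
that a systematic pass finds (on the two-column toy geometry the unique
2-packing requires corner placements), and the repacking pass guarantees
the extractor never returns fewer patches than the achievable disjoint
packing up to the target. Only when a class yields zero non-overlapping
patches — typically because the other class's patches block every window —
is the non-overlap constraint lifted; overlap-mode patches still satisfy
eligibility and are flagged `overlap_allowed`. Cancer patches are placed
before non-cancer ones, and every returned window is re-audited against the
mask before it is returned. All randomness flows from one seed, so equal
inputs and seed give byte-identical output.

### Flip balancing

Class balancing adds horizontal, vertical and combined flips of minority
patches (at most 4x, never adding an array identical to one already
present, so symmetric patches contribute nothing); `"flips-then-duplicate"`
mode then tops up to exactly the majority count by seeded resampling. With
training class sizes 23/222/52 this yields 92/222/208 after flips and
222/222/222 after top-up.

## Metrics and conventions

* Precision, recall and F1 follow their count definitions; a zero
  denominator reports 0 with an explicit `degenerate` flag (matching
  published tables that print F1 = 0.00 for never-predicted classes).
* AUC uses the rank (Mann–Whitney) formulation; tied scores contribute 1/2
  per positive–negative pair.
* IoU and Dice are set ratios on binary masks. Per pair,
  $\mathrm{DSC} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ holds exactly — but not
  for dataset *means* of either metric, so the identity must never be
  applied to table averages. Two empty masks score 1 ("perfect agreement on
  absence") with a `degenerate` attribute; other conventions (0, NaN) exist
  and callers can branch on the flag.
* All computation is full precision; `report_round()` (round half to even,
  2 decimals) is the single reporting-layer rounding used when comparing
  against printed tables. Macro averages are unweighted means of per-class
  scores; reconstructed multi-class averages may still differ from printed
  "Avg." columns computed from unrounded per-class values.

## Paired statistics

**McNemar.** Two classifiers on one test set reduce to the 2x2 joint
outcome table; only the discordant counts $b, c$ matter. The exact variant
is the two-tailed binomial test $p = \min(1,\, 2\,P(X \le \min(b,c)))$,
$X \sim \mathrm{Bin}(b+c, \tfrac12)$; the chi-square variant uses the
continuity-corrected statistic $(|b-c|-1)^2/(b+c)$, clamped to 0 at
$b = c$. Published comparisons of this kind rarely name the variant, so
`"auto"` selects exact below 25 discordant pairs and chi-square above, and
both are exposed — every bundled reference significance call reproduces
under *both* variants, so the choice is immaterial here. $b + c = 0$
returns $p = 1$ with a `no_discordance` flag.

**Wilcoxon signed-rank.** Paired per-sample scores (e.g. per-patch IoU)
are compared through ranked absolute differences with average ranks for
ties. Zero differences are discarded by default (classic convention); the
Pratt policy (rank zeros, exclude them from the sums) is available. The
exact mode computes the null distribution of $W^+$ by dynamic-programming
convolution over doubled ranks — equivalent to enumerating all $2^m$ sign
assignments and valid under ties — and is used automatically for
$m \le 20$; beyond that a normal approximation with
$\mathrm{Var}(W^+) = \sum_i r_i^2/4$ (which embeds the tie correction) and
a 0.5 continuity correction takes over.

**Multiplicity.** Significance grids threshold at $\alpha$ with a strict
inequality and apply no correction by default, matching per-comparison
reporting at $\alpha = 0.05$; a Holm option is available.

## Synthetic data

The phantom generator provides ground-truth-aligned inputs without slide
archives. It draws an elliptical tissue region on a near-white background,
stamps circular cancer blobs, scatters randomly oriented elliptical nuclei
(denser inside cancer blobs, nuclear density factor 2 by default), and adds
Gaussian texture noise (sd 0.02). The default palette — nuclei
$(0.29, 0.20, 0.51)$, stroma $(0.91, 0.63, 0.75)$, background
$(0.97, 0.96, 0.97)$ — was chosen once to satisfy the H&E appearance
contract *nuclei darker than stroma darker than background* under every
conversion operator; default canvas 256 x 256 with 120 nuclei of 2–5 px
semi-axes gives nuclear densities that make 64-px windows inside cancer
blobs pass the cancer eligibility rule.

Cross-domain color variation is simulated as a channel-wise affine map plus
an optional hue rotation, $\mathrm{out} = \mathrm{clip}(g \odot
\mathrm{rot}_h(\mathrm{img}) + b)$, with hue rotation performed in the HSV
parameterization (hue shifted modulo one turn; saturation and value
untouched — stated explicitly because "hue" is convention-dependent). The
identity shift is a bit-exact no-op. On hue-only shifts every conversion
operator provably or empirically shrinks the mean per-pixel cross-domain
difference relative to RGB (luster is exactly invariant, since HSV value
and saturation determine the channel max and min); this restates the
qualitative claim that grayscale visually suppresses color variation as a
measurable statement *on this simulator only*.

Paired-outcome simulation solves the joint law from the requested marginals
and agreement rate: $P(\text{both correct}) = (g - 1 + p + q)/2$, the rest
by subtraction, with the feasibility window
$|1-p-q| \le g \le 1-|p-q|$ reported on violation. Paired IoU simulation
draws baselines from $U(0.35, 0.8)$ — the working range of competent
segmentation models, kept away from the clip boundaries so that null
differences stay symmetric — and adds a systematic shift plus
$N(0, \text{noise})$ pair noise.

What the phantom does **not** model: realistic tissue morphology, stain
co-localization physics, compression artifacts, or pyramidal slide formats.
Passing tests on phantom data demonstrate the *computational* correctness
of the pipeline, not clinical validity on real slides.

## Numerical and I/O conventions

* Canonical representation: floating point in $[0,1]$; source bit depth is
  carried as metadata. Export quantization rounds half up; PNG export is
  8-bit (16-bit and float use TIFF; float TIFF round-trips exactly at
  32-bit float precision). Channel-wise standardization uses the population
  standard deviation (ddof = 0), the common deep-learning preprocessing
  convention.
* Resizing is bilinear with anti-aliasing on downscale (no kernel is
  mandated by the protocols mirrored here; one is fixed for
  reproducibility). A factor of 4 maps 1536 x 1376 regions to 384 x 344.
  Because source dimensions vary, the resize operation takes explicit
  factors or target sizes rather than hard-coding any dataset's geometry.
* Problem sizes in the test suite are chosen so every oracle remains
  affordable: scalar-loop oracles run on images up to 16 x 16, the
  disjoint-packing comparison uses the two-column toy geometry scaled by 8
  (56 x 56 masks, 28-px patches — identical structure, tractable
  enumeration), Wilcoxon calibration uses 1000 simulations at n = 30, and
  the luminance dialect sweep covers all $256^3$ triples in 256 vectorized
  chunks.

## Known limitations

* The extractor's repacking pass guarantees a *maximal* disjoint set, which
  equals the true maximum on the rectangular-position geometries used in
  validation but is not a general maximum-packing solver (that problem is
  NP-hard); extraction counts are guaranteed never to exceed the exhaustive
  bound and to reach it on the validated geometries.
* Pyramidal whole-slide containers are out of scope; the toolkit operates
  on extracted regions and tiles.
* The luminance dialect mechanism reproduces the *magnitude class* of
  cross-library discrepancies (<= 1/255), not any specific library's bit
  pattern.
* Exact McNemar and Wilcoxon paths are exact; the normal Wilcoxon path is
  an approximation whose accuracy degrades below ~20 informative pairs
  (where the exact path is used instead).
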