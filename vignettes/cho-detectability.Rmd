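---
title: "Channelised Hotelling observers for low-contrast CT detectability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channelised Hotelling observers for low-contrast CT detectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chodetect)
```

## The measurement

The package measures low-contrast detectability the way reader studies do:
by forced choice. A trial presents one signal-present ROI and three
signal-absent ROIs; the observer must pick the signal-present one, and the
fraction of correct picks over many trials is the percent correct (PC).
Chance is 25% for four alternatives; a trivially easy task saturates at
100%. PC as a function of acquisition condition — dose, reconstruction
strength, target contrast and size — is the quantity of interest.

The observer is the channelised Hotelling observer (CHO), an
anthropomorphic linear model. It sees an ROI only through a small set of
radial frequency channels, mimicking the frequency-selective front end of
human vision, and applies the ideal linear (Hotelling) discriminant in that
reduced space. Its paradigm is signal-known-exactly / location-known-exactly
with stationary noise: the target profile and its position are fixed and
known, and only the noise varies between ROIs. That is the regime the
synthetic phantom module reproduces. It is simpler than anatomical
backgrounds, a deliberate simplification: it isolates the effect of dose and
reconstruction on detection from the variability of anatomy, at the price of
absolute PCs that overstate clinical performance.

## The channels

Channel `j` of the dense difference-of-Gaussian (DDoG) set has radial
frequency response

$$U_j(\rho) = \exp\!\left[-\tfrac12\left(\frac{\rho}{W\sigma_j}\right)^2\right]
            - \exp\!\left[-\tfrac12\left(\frac{\rho}{\sigma_j}\right)^2\right],
\qquad \sigma_j = \sigma_0\,\alpha^{\,j},$$

with defaults $W = 1.67$, $\sigma_0 = 0.005$, $\alpha = 1.4$ and ten
channels. Frequencies are in cycles/pixel on the DFT grid of the ROI, which
makes the observer independent of the physical pixel pitch; the pitch is
carried only as metadata. Indexing starts at $j = 1$ (so
$\sigma_1 = 0.007$); a $j = 0$ start would only shift the band edges of the
same log-spaced family, and the Hotelling template is insensitive to such
relabelling.

Each spatial template is built by sampling $U_j(\rho)$ on the
two-dimensional discrete-frequency grid, inverse-transforming (the sampled
profile is even, so the transform is real to rounding error) and circularly
recentring on the ROI's centre pixel. Because $U_j(0) = 0$, every template
has exactly zero mean, which makes the decision variable invariant to any
constant HU offset — the reason the synthetic ROIs can use a zero HU
background without loss of generality. No per-channel normalisation is
applied beyond the profile's own amplitude: the Hotelling solve is invariant
to per-channel rescaling, so the literal profile is used.

One practical constraint: on small ROIs the lowest channels can fall below
the grid's lowest nonzero frequency ($1/\text{side}$ cycles/pixel) and carry
essentially no energy, which makes the channel covariance numerically
singular. The training solve detects this and applies a minimal automatic
ridge with a warning, but the right fix is to match the channel set to the
ROI: for the default 41-pixel ROIs the default ten channels are fine; for
substantially smaller ROIs use fewer channels or a larger $\sigma_0$.

## Template, decision variable, detectability

Training projects the ROIs onto the channels and estimates class means
$\bar g_{cs}, \bar g_{cn}$ and unbiased ($n-1$) sample covariances
$K_{cs}, K_{cn}$ from the channel outputs — a 10×10 computation that is
algebraically identical to the textbook image-space route
$U^T K U$ but far cheaper; the equivalence of the two routes is asserted by
a test. The template solves

$$\left[\tfrac12(K_{cs}+K_{cn}) + \lambda_{\mathrm{ridge}} I\right] w
  = \bar g_{cs}-\bar g_{cn}$$

by a linear solve, never an explicit inverse; the default ridge is zero.
The decision variable of an ROI is $\lambda = w^T U^T g$, and the trial
winner is the alternative with the largest $\lambda$ (ties, which have
probability zero under continuous noise, resolve deterministically to the
lowest presented position after the seeded presentation shuffle).

The channel-space detectability index
$d' = \sqrt{(\bar g_{cs}-\bar g_{cn})^T\,[\tfrac12(K_{cs}+K_{cn})]^{-1}\,
(\bar g_{cs}-\bar g_{cn})}$
is reported alongside PC. For Gaussian channel outputs with equal class
covariances, the M-AFC percent correct has the closed form

$$\mathrm{PC}(d', M) = 100\int \phi(x-d')\,\Phi(x)^{M-1}\,dx,$$

evaluated by adaptive quadrature in `pc_closed_form()`. This is used purely
as a validation oracle: the empirical PC of the trial engine converges to it,
and the test suite checks the agreement at several $d'$ values.

## Training protocol and its bias

The default protocol is resubstitution: the template is trained on the full
dataset and the same dataset is scored. With 100 signal-present and 1000
signal-absent ROIs per category this single-set protocol is a recognised,
reliable choice when the data are too few to split into independent training
and testing sets. It does carry a small optimistic bias: with no signal at all (zero
contrast), a resubstitution-scored 4-AFC sits a few percentage points above
the 25% chance level, because the template partly memorises the sampling
noise of its own training means. The effect shrinks as $1/n$ and is
negligible once $d'$ is appreciable, but the test suite checks the
chance-level property on an independently generated dataset, where PC is
at 25% to binomial accuracy. A train/test split is available by training
on one dataset and scoring another; the bootstrap also exposes
`refit_per_replicate = TRUE` to retrain inside each replicate instead of
holding the template fixed (the default mirrors resampling only the trial
composition).

## Forced-choice mechanics

Each 4-AFC pass uses every signal-present ROI exactly once, in seeded
shuffled order — 100 signal ROIs, 100 trials per pass by default. The three
signal-absent alternatives are drawn without replacement within a trial and
with replacement across trials from the shared 1000-ROI noise pool. All
randomness (signal order, noise draws, presentation shuffle) derives from a
single integer seed, so a trial log is bit-reproducible. The score-level
engine `run_afc_scores()` is exported separately so the trial mechanics can
be exercised on arbitrary decision-variable samples — that is how the
closed-form comparison above is run.

## Uncertainty

The bootstrap resamples the signal-present collection with replacement to
its original size, runs a full 4-AFC pass against the fixed noise pool, and
repeats 150 times; the summary is the mean and SD of the 150 replicate PCs
with a normal-approximation 95% CI (mean ± 1.96 SD, clipped to [0, 100]).
The noise pool is held fixed across replicates. On separable data every
replicate is 100% and the interval collapses to a point. Replicate spread
tracks the binomial SD of a 100-trial pass (inflated somewhat by resampling
ties) and shrinks as the signal set grows. Human-reader PC tables are
summarised differently, as the conventional mean ± 1.96 SE over observers per
category (`summarize_human_pcs()`), because there the unit of replication is
the reader, not the trial.

## The synthetic phantom

Physical phantom acquisitions are scanner-bound, so the generator emulates
the statistical structure of such data rather than any particular scanner's
pixels:

* **Signal**: a centred anti-aliased disc — plateau at the target contrast,
  zero background, boundary pixels by 16×16 sub-pixel area sampling. A 2-D
  disc is used rather than a 3-D sphere sectioned by the slice profile,
  since the observer mathematics is two-dimensional and slice positioning
  is not modelled; the rendered disc is the exact truth profile the signal-
  present ROIs are built from.
* **Noise**: white Gaussian by default; optionally NPS-shaped noise obtained
  by filtering a white field with the square root of a radial power spectrum
  $\propto \rho^{e}\,e^{-\rho}$, normalised so the expected pixel SD matches
  the requested value. Real reconstructed CT noise is correlated, so the
  shaped option is closer in texture, but neither reproduces any specific
  reconstruction algorithm.
* **Dose**: noise SD scales as $\sigma \propto 1/\sqrt{\mathrm{CTDI_{vol}}}$
  (quantum-limited scaling), anchored at a reference point. Measured HU
  noise depends on scanner, kernel and phantom, so the anchor is a free
  configuration parameter; the default of 10 HU at 15 mGy is a typical
  chest-phantom noise level at full dose and puts the four-level dose ladder
  {1.0, 3.5, 8.0, 15.0} mGy in the regime where the hardest category is
  sub-asymptotic and the easiest saturates, the behaviour such phantom
  studies show.
* **Iterative-reconstruction strength**: represented honestly as a noise
  knob, not a reconstruction model. Strengths 1–5 map to noise-SD
  multipliers {1.00, 0.90, 0.80, 0.70, 0.60} (roughly linear towards the
  ~40–50% noise reduction vendors quote at the strongest setting); with the
  shaped-noise model the spectral exponent can be varied per strength as
  well. For user-supplied real data the strength is pass-through metadata.
* **Seeding**: one master seed per dataset, with per-ROI substreams derived
  by counter, so datasets are bit-reproducible and extending a dataset never
  changes the ROIs already generated.

What passing tests on this generator do show: the observer, trial and
bootstrap machinery are correct (oracle agreement, chance level, dose
monotonicity, saturation of the easy task). What they cannot show: fidelity
to any particular scanner or reconstruction — real noise is non-stationary
across the field of view and its texture depends on the algorithm, neither
of which the surrogate reproduces.

## Numerical and design choices

* Covariances use the unbiased $n-1$ normalisation.
* The automatic ridge on a singular solve is $10^{-8}\,\mathrm{tr}(S)/n$,
  scale-invariant and minimal; it is applied only on failure and warned
  about.
* No internal noise is added to the decision variable: the emulated model
  has none, which is also why it can slightly outperform human readers on
  hard tasks.
* ROI extraction coordinates are 0-based, `(x = column, y = row, slice)`,
  with the ROI spanning the closed square of side `roi_side` centred on the
  named pixel; DICOM-style rescale slope/intercept are applied when given.
* Category enumeration is a deterministic Cartesian product, dose outermost
  and diameter innermost; per-category seeds derive from the master seed and
  category index, so a study rerun is bit-identical and category failures
  degrade to flagged rows rather than aborting the sweep.
* Stacks serialise as raw little-endian float32 (exact to single precision)
  or multi-page TIFF with an affine rescale recorded in the JSON sidecar,
  because TIFF float storage is normalised to [0, 1].

## Problem sizes

The shipped tests run the full-size study design where it matters — 41×41
ROIs, 100 signal / 1000 noise, 150 bootstrap replicates for the saturation,
chance, and dose-monotonicity checks — and smaller 21-pixel ROIs with a
matched 8-channel bank for the many property checks where geometry is
irrelevant. Monte-Carlo oracles use $10^5$–$10^7$ draws, sized so their
standard errors sit well inside the asserted tolerances.

## Known limitations

Stationary, signal-independent noise; 2-D discs only; no internal-noise
model for calibrating absolute PC to specific human readers; no
reconstruction simulation (dose and strength act through the noise
surrogate); DICOM series are not read directly — extract ROIs from arrays
or TIFF stacks, applying the source's rescale slope/intercept.
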