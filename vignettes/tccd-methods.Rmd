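---
title: "Methods: two-color coincidence detection for single-vesicle quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-color coincidence detection for single-vesicle quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tccd)
```

## The measurement model

An extracellular vesicle (EV) carries several copies of a surface marker
(e.g. the tetraspanin CD9). Incubated with an equimolar mixture of the same
antibody labeled with two spectrally orthogonal fluorophores, an EV binds
antibodies of both colors with high probability, whereas a free antibody or
a single free protein carries exactly one color, and a marker-negative
particle (a synthetic liposome, a lipoprotein, a protein oligomer) carries
none. Driven through a confocal detection volume under fast flow, each
particle produces a sub-millisecond photon burst: dual-colored for EVs,
single-colored for free antibody, none for unlabeled particles. Two-color
coincidence detection (TCCD) therefore identifies EVs as *coincident*
bursts in the two detection channels.

The raw observable is a pair of aligned photon-count vectors, one count per
time bin per channel (`time_trace`, default bin width $10^{-4}$ s). The
analysis proceeds in three stages.

**Burst search (per channel).** The background $b$ (counts/bin) is
estimated by an iterated trimmed mean: compute the mean $m$ and standard
deviation $s$ of the kept bins, discard bins above $m + 3s$, repeat to
convergence (at most 10 passes). The detection threshold is
$\lceil b + k\sqrt{\max(b, 0.1)} \rceil$ with $k = 5$ by default — the
Poisson-scaled analogue of a $k\sigma$ rule, with the 0.1 floor guarding
the zero-background case. Maximal runs of consecutive supra-threshold bins
are merged into single events so a burst straddling a bin edge is not
counted twice; per-bin (unmerged) counting is retained as an option because
its chance null is exact. Event intensity is the background-corrected
photon sum over the event's bins, floored at zero.

**Coincidence statistics.** With $n_A$ and $n_B$ detected events and
$C_{\mathrm{obs}}$ observed coincidences (greedy one-to-one matching of
overlapping spans, or doubly supra-threshold bins in bin-level mode), the
expected chance coincidences of two independent streams are

$$E = \frac{n_A\, n_B}{n_{\mathrm{bins}}},$$

exact for bin-level statistics and a rare-short-event approximation for
merged events. The chance-corrected coincidence count is
$C = \max(C_{\mathrm{obs}} - E,\, 0)$ and the association quotient is

$$Q = \frac{C}{n_A + n_B - C},$$

the chance-corrected fraction of events that are coincident ($Q \in [0,1]$,
symmetric in the channels). Because the literature leaves open whether the
chance correction enters the denominator, the variant
$Q = C / (n_A + n_B - C_{\mathrm{obs}})$ is selectable, and every summary
records which variant produced it. The specific event rate is
$C / T$ for an acquisition of duration $T$: chance-corrected coincident
transits per second, proportional to analyte concentration at fixed flow.

**Sample-level quantification.** Q is mapped to particle concentration by
an ordinary least-squares calibration line fitted to a calibrant series;
concentrations convert between particles/mL and femtomolar via Avogadro's
number ($c_{\mathrm{fM}} = c_{\mathrm{mL^{-1}}} \times 10^{18} / N_A$).
Assay sensitivity follows the CLSI-style one-sided 95% construction:
$\mathrm{LoB} = \bar{x}_{\mathrm{blank}} + 1.645\, s_{\mathrm{blank}}$ over
blank replicates and
$\mathrm{LoD} = \mathrm{LoB} + 1.645\, s_{\mathrm{low}}$ over replicates of
a low-concentration sample (sample standard deviations; the 1.645
multiplier is a parameter). Concentration-series fits report $r^2$ and the
pointwise confidence band
$\hat{y}(x) \pm t_{0.975,\,n-2}\, s \sqrt{1/n + (x-\bar{x})^2 / S_{xx}}$.

## The generative simulator

Every stage is validated against a generative model of the acquisition
(`sim_config()` / `simulate_trace()`), which records a per-transit ground
truth log. Per species, transit counts over the trace are
Poisson(rate × duration) and each transit lands in one uniformly random
bin. An EV binds $n \sim$ zero-truncated Poisson($\lambda$) antibodies
(an EV binding none is invisible and should not enter the labeled-EV rate),
each independently carrying the channel-A fluorophore with probability
$p$; the transit deposits Poisson(brightness × copies) photons per channel
on top of per-bin Poisson background. Free antibodies carry one fluorophore;
contaminants deposit nothing (a nonspecific-binding rate, default 0, is
available for sensitivity analyses). Optional crosstalk duplicates a
binomial fraction of channel-A counts into channel B after signal
generation.

Default parameters are chosen once as plausible single-molecule fast-flow
conditions: 0.1 ms bins; 100 s acquisitions; background 0.3 counts/bin per
channel (a few-kHz count rate); 50 free-antibody transits/s per channel
(the free-antibody level in the detection mix is a free parameter of the
assay, not a measured value); $\lambda = 3$ antibodies per EV, matching
the few-copies-per-vesicle regime of tetraspanin markers; brightness 44
photons per fluorophore per transit, so a three-antibody EV totals ≈132
counts; $p = 0.5$ (equimolar color mix); crosstalk 0.

What the simulator deliberately omits: diffusion through a Gaussian
detection volume (transits deposit into a single bin, appropriate when the
transit time is below the bin width under fast flow), fluorophore
photophysics (blinking, triplets, saturation), spectral bleed-through
beyond a scalar crosstalk fraction, detector dead time (co-occurring
transits simply sum), and antibody depletion at high analyte concentration
(which in the real assay makes Q roll off and is the reason calibration is
range-guarded). Tests passing on simulated data therefore validate the
*statistics* of the pipeline — chance-null calibration, linearity,
specificity, stoichiometry recovery — not instrument-specific artifacts.

## Numerical and design choices

**Bin indexing and spans.** Bins are 0-based; event spans are inclusive on
both ends, matching the merge rule ("maximal run of consecutive
supra-threshold bins") and the on-disk CSV formats. Counts are validated as
non-negative integers and never silently repaired.

**Trimmed-background bias at low counts.** On discrete Poisson counts with
mean around 1 the iterated $m + 3s$ trim clips the distribution's own
upper tail: the fixed point keeps bins ≤ 3 whose conditional mean is
~0.94, a ~6% underestimate. This is inherent to the rule, stable under
burst contamination (which is what the estimator is for), and small on the
threshold scale; the tests pin it down rather than hide it.

**False events near threshold.** Poisson upper tails are fatter than a
Gaussian $k\sigma$ bound, so at sub-count-per-bin backgrounds the default
threshold admits a noticeable population of false single-bin events
clustered at the detection limit. These are independent between channels,
so the chance correction removes their effect on $Q$, $C$ and the event
rate. They do bias naive intensity statistics, which is why the
single-antibody brightness estimator (median of single-colored event
intensities — median, because rare aggregates would drag a mean up)
first drops events whose peak fails to clear the threshold by more than
one count. Genuine single-fluorophore bursts peak at the full fluorophore
brightness, far above threshold, so the filter costs essentially nothing
there.

**Stoichiometry and selection bias.** The mean antibodies-per-EV estimate
divides the mean total (A + B) intensity of coincident bursts by the
single-antibody brightness. Requiring a burst in *both* channels censors
vesicles whose antibodies happened to all carry one color, so the raw
ratio estimates the dual-colored subpopulation's mean, which exceeds the
population mean (for $\lambda = 3$, $p = 0.5$: 3.86 versus 3.16 truncated,
3.0 untruncated). Under the copy-number model the color counts are
independent Poissons, and the dual-color conditional mean is

$$m(\lambda) = \frac{\lambda p}{1 - e^{-\lambda p}} +
  \frac{\lambda (1-p)}{1 - e^{-\lambda(1-p)}},$$

which the default estimator inverts numerically (monotone in $\lambda$;
root-found on $[10^{-8}, 10^4]$). Ratios at or below the $\lambda \to 0$
floor of $m$ (= 2) return 0 with a warning. The uncorrected ratio remains
available as `method = "ratio"`; both are reported with the per-event
ratio list for histograms.

**Degenerate inputs.** $Q = 0$ by definition when $n_A + n_B = 0$; a
constant response fits with $r^2 = 0$ (and a calibration with non-positive
slope refuses to be inverted); an empty event set is a valid burst-search
result; all-zero blanks give LoB = 0.

**Seeds.** Simulations are bit-reproducible given their configuration;
series runs derive member seeds as base seed + run index so replicates are
independent but the whole series is reproducible.

## Validation problem sizes

The shipped validation suite exercises: the chance null on 500
antibody-only 100-s acquisitions at default rates (bin-level mode, mean
$C_{\mathrm{obs}} - E$ within three standard errors of zero and
$|\bar{Q}| < 0.01$); linearity of the event rate over a two-decade EV-rate
series (5 rates × 3 replicates × 10 s, $r^2 \ge 0.98$); specificity on a
constant-total-rate EV/contaminant mixture series (5 fractions × 3
replicates, ground-truth totals flat, chance-corrected $C$ tracking the EV
fraction with $r^2 \ge 0.95$); stoichiometry recovery at $\lambda = 3$
from >1000 coincident bursts (estimate within [2.4, 3.6]); and LoB/LoD
behavior on blank-only pipelines with controlled low-sample variance
(LoD = LoB at zero injected variance, monotone growth with it, and a
pipeline LoD bracketed by a genuinely simulated low sample). These sizes
are the package's own validation choices and run in a few minutes on a
laptop; all thresholds above restate what the tests assert, nothing more.

## Known limitations

- The chance estimator $E = n_A n_B / n_{\mathrm{bins}}$ is exact only at
  bin level; for merged events it slightly misstates the null when events
  are long or dense. Bin-level mode exists precisely for null-critical
  work.
- The stoichiometry correction assumes the zero-truncated-Poisson /
  Bernoulli color model; real labeling (epitope clustering, steric
  exclusion) may depart from it, in which case the raw ratio brackets the
  answer from above.
- Intensity-based quantities assume single-bin transits; partial transits
  split across bins would bias intensities low unless bins are widened.
- The calibration line is valid only inside its fitted range; Q saturates
  at high analyte concentration (antibody depletion), and out-of-range
  inversions are flagged, not trusted.
- Trace I/O is plain-text CSV; at $10^7$ bins files are large but
  readable — binary trace formats are out of scope here.
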