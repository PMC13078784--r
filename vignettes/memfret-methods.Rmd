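---
title: "Inferring membrane-receptor conformational states from single-molecule FRET lifetimes"
author: "memfret authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring membrane-receptor conformational states from single-molecule FRET lifetimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfret)
```

# The problem

Single-molecule FRET on immobilized membrane receptors (here: full-length
EGFR embedded in lipid nanodiscs) reports the distance between a donor dye on
the C-terminal tail and an acceptor at the membrane or at a bound ATP analog.
Each molecule yields a stream of detected photons with two clocks: the
*macrotime* (absolute arrival time, used to follow intensity and
photobleaching) and the *nanotime* (delay after the excitation pulse, which
encodes the donor fluorescence decay). Energy transfer shortens the donor
lifetime, so the distribution of donor lifetimes across many molecules and
time windows resolves the receptor's conformational equilibrium — here a
*compact* state (tail near the bilayer, short lifetime) and an *open* state
(tail away from the bilayer, long lifetime) whose relative amplitudes shift
with lipid composition and EGF.

`memfret` implements the full inference chain plus the companion
coarse-grained-trajectory metrics, and — because raw photon streams for such
experiments are rarely deposited — a seeded synthetic generator with the
statistical structure the analysis assumes, so that every stage is testable
end to end.

# The analysis chain

## Binning and change-point segmentation

Photon macrotimes are binned at 100 ms per channel (`binPhotons()`). Regions
of constant intensity are found by recursive binary segmentation on the
Poisson counts (`detectChangepoints()`): each candidate split maximizes the
generalized likelihood-ratio statistic

$$G = 2\left[\ell(x_{1:j};\hat\lambda_1) + \ell(x_{j+1:n};\hat\lambda_2)
      - \ell(x_{1:n};\hat\lambda)\right],$$

and is accepted when its Monte-Carlo p-value — simulated under the segment's
fitted constant-rate null with a fixed calibration seed, with the usual
$+1$ correction — falls below `alpha` (default 0.01). The Monte-Carlo
calibration keeps the per-segment false-positive rate at or below the
nominal level without relying on asymptotics at these short trace lengths;
ties in the split statistic break toward the earlier index, and the
procedure is deterministic given `(counts, alpha, seed)`.

Because bleach events almost never align with bin edges, the transition bin
carries an intermediate count that the segmentation often isolates as a one-
or two-bin sliver. `mergeShortSegments()` absorbs segments shorter than 3
bins into the closer-rate neighbour *without* recomputing the neighbour's
rate — the sliver is a rate mixture, and folding its counts into a
background segment would push that segment above the bleach-acceptance
tolerance (we observed exactly this failure mode on synthetic data before
adopting the rule).

## Trace selection

`selectTraces()` accepts a molecule when each channel shows exactly one
downward step terminating at the background level with no recovery
afterwards (blinking and multi-step traces are rejected with labelled
reasons), the acceptor pre-bleach rate is at least 3x background (a stand-in
for the direct-excitation acceptor check), and the acceptor bleaches no
later than the donor. A segment counts as background when its rate is within
$3\sqrt{b/\mathrm{len}}$ of the expected background $b$ counts/bin — the
Poisson standard error of the segment mean; the multiplier and the threshold
are configurable because the source workflow does not state them. The FRET
window runs from the start of the trace to acceptor photobleaching, and
donor photons inside it form the FRET-level photon set.

## Bunch-wise lifetime fitting

FRET-level donor photons are grouped into consecutive, non-overlapping
bunches of 1000 (`bunchPhotons()`; the trailing remainder is discarded).
Each bunch is fitted by maximizing the per-photon log-likelihood of

$$p(t) = (1-b)\,\frac{f_{\mathrm{IRF}\otimes\exp}(t;\tau)}{Z(\tau)}
       + \frac{b}{W},$$

where $f_{\mathrm{IRF}\otimes\exp}$ is the exponentially modified Gaussian
(a mono-exponential decay convolved analytically with a Gaussian instrument
response), truncated and renormalized on the TCSPC window $W$
(`fitDecayMLE()`). Numerical choices:

* the EMG log-density and CDF are evaluated through `pnorm(log.p = TRUE)`,
  which stays finite for the large exponents that arise at short lifetimes;
* the background fraction $b$ is *fixed* (measured separately on a blank),
  not co-estimated — at 1000 photons the $\tau$–$b$ degeneracy would
  otherwise inflate the lifetime variance;
* optimization is a deterministic golden-section search on a fixed bracket
  `[0.02, 2W]` ns; an optimum at a bracket edge is flagged unconverged and
  excluded downstream;
* nanotime discretization is ignored (photon delays treated as continuous
  at channel centres), an approximation that is negligible at the ~3 ps
  channel width of a 12.5 ns / 4096-channel window.

The window $W$ defaults to 12.5 ns (80 MHz repetition rate). The generator
redraws nanotimes falling outside the window rather than wrapping them, and
the fit likelihood uses the matching truncated form, so generator and
estimator are mutually consistent. The IRF is modelled as a Gaussian (mean
2 ns, sigma 0.15 ns by default): instrument response functions are rarely
characterized in enough detail to copy, and the Gaussian is the standard
closed-form-convolvable choice.

Per-condition lifetime histograms use equal-width bins with the bin count
set to the rounded square root of the number of bunches
(`buildLifetimeHistogram()`).

## Förster conversion

Lifetimes convert to FRET efficiencies and donor–acceptor distances by

$$E = 1 - \tau_{DA}/\tau_D, \qquad r = R_0\,\left(\frac{1-E}{E}\right)^{1/6},$$

with $R_0$ = 8.4 nm (snap surface 594 / Cy5) or 7.5 nm (snap surface 594 /
atto 647N) and $\tau_D$ the median per-bunch lifetime of a donor-only
construct (`estimateDonorReference()`). Efficiencies at or below zero
(lifetime at or above the reference) have no finite distance; the conversion
returns `Inf` and the value is flagged *beyond range*. The beyond-range
threshold defaults to $1.5 R_0$; with the 8.4 nm pair this separates starred
(>= 12.9 nm) from unstarred (<= 12.2 nm) medians, but the same rule at
$R_0$ = 7.5 nm would star an 11.6 nm median that the source tables leave
unstarred — the threshold is therefore per-dye-pair configurable, and we do
not claim to have recovered the exact original rule.

Per-condition medians carry 95% confidence intervals from a seeded
percentile bootstrap (10^4 resamples by default); the interval method is our
choice, as reported CIs rarely name one. Distances are computed per bunch
and then aggregated, matching the histogram-of-bunches workflow.

## Global mixture, BIC and Ashman's D

Lifetime sets from all conditions are fitted jointly by a Gaussian mixture
whose means and widths are shared across conditions while the amplitudes are
free per condition (`fitGlobalMixture()`): expectation–maximization
generalized to shared components, 20 seeded starts from quantile-spread
means, a 0.01 ns width floor against degenerate collapse, and a
monotonicity assertion on the joint log-likelihood at every iteration.
Components are reported sorted by mean; the *open* state is the largest-mean
component, since distance increases with donor lifetime. We fit the unbinned
per-bunch lifetime values — histograms are display only — and the Gaussians
are untruncated even though lifetimes are positive (the fitted components
place negligible mass below zero).

Model order is chosen by the Bayesian Information Criterion
$\mathrm{BIC} = -2\ln L + p\ln n$ with $p = 2k + (k-1)C$ free parameters for
$k$ components over $C$ conditions and $n$ the total bunch count across all
conditions; ties break toward fewer states (`selectK()`). Separation is
scored by Ashman's D,
$D_{ij} = |\mu_i-\mu_j| / \sqrt{(\sigma_i^2+\sigma_j^2)/2}$, with $D > 2$
read as well separated; the fitted two-state parameters (1.3/2.7 ns peaks,
0.35/0.67 ns widths) give $D = 2.62$.

Amplitude uncertainties come from the observed information of each
condition's likelihood in its own mixing weights with the shared shapes held
fixed — an approximation that ignores the (small, $O(1/C)$) covariance with
the shared means and widths. EGF-induced amplitude changes
(`egfAmplitudeChange()`) difference the open-state amplitudes of paired
conditions in percentage points. Condition pairs are compared by classical
equal-variance one-way ANOVA (`anovaPair()`, built on
`stats::oneway.test`), with significance at $p \le 0.001$.

# Trajectory metrics

For coarse-grained simulation frames the package computes the two
accessibility metrics used alongside the FRET experiments:

* `countAtpSiteContacts()` — the number of (lipid bead, ATP-site bead) pairs
  at a minimum-image distance strictly below 16 Å, the largest molecular
  radius of the fluorescent ATP analog; the ATP site is residues 694–703,
  719, 766–769, 772–773, 817, 820 and 831 (`atpSiteResidues()`). "Pairs"
  means all lipid beads against all beads of the listed residues, and the
  cutoff is a strict inequality.
* `residueDistance()` — the minimum-image distance between residues 721
  (closest to the ATP site) and 1186 (the C-terminus), in nm, using residue
  centroids by default (a backbone-bead convention would differ only when a
  residue carries several beads; the choice is configurable because the
  original is unstated).

`whamReweight()` implements the standard self-consistent WHAM iteration in
kT units over binned, harmonically biased collective-variable windows,
reporting the unbiased profile (shifted to min 0), per-window free energies
and per-sample weights for reweighting any observable. Windows must overlap:
the occupancy graph over shared histogram bins has to be connected, and
disconnected inputs fail with a diagnostic rather than silently returning a
profile stitched up to arbitrary constants. The iteration is written for one
collective variable; multi-dimensional umbrella schemes are out of scope and
would need a binned bias matrix in more dimensions. `blockStats()` supplies
the three-equal-partition error convention (value plus per-block min/max,
remainder samples to the last block).

`normalizeAtpBinding()` covers the ensemble assay: per-replicate ratios of
the ATP-analog band to the expressed-receptor band, reported as mean ±
standard error over biological replicates (SEM rather than SD is our
default, the original convention being unstated; densitometry itself is out
of scope).

# The synthetic generator

`simulateCondition()` emulates what the analysis assumes about the data:

* molecule states drawn from per-condition two-state weights; the default
  mixture (`egfrMixtureSpec()`) uses the fitted peaks 1.3 and 2.7 ns, widths
  0.35 and 0.67 ns, and open-state amplitudes of 60–96% across the eight
  POPC/POPS ± EGF conditions;
* single-step photobleaching: exponential acceptor bleach times, donor
  bleach following after an exponential gap, and a five-second
  background-only tail;
* staged Poisson arrivals (FRET stage, donor-only stage after acceptor
  bleach, background only after donor bleach); after acceptor bleach the
  donor rate rises by $1/(1-E)$, with $E$ floored at 0.05 so molecules whose
  drawn lifetime approaches or exceeds $\tau_D$ show a flat-to-upward donor
  step rather than an unphysical drop;
* nanotimes from the truncated IRF-convolved decay mixed with a uniform
  background fraction, identical to the fit model;
* within-state lifetime breathing: the FRET-stage lifetime is redrawn from
  the state's Gaussian component every 2 s (piecewise constant). A lifetime
  frozen per molecule would make per-bunch estimates clusters of repeats of
  a few hundred distinct values, and the global mixture fit then fails to
  recover the generating parameters *even when fed the exact ground-truth
  lifetimes* — the bunch-level independence that the histogram fitting
  assumes is a property real conformational dynamics provide and the
  generator must too. The 2 s interval is slow compared to a 1000-photon
  bunch (~2 s at 500 counts/s, so a bunch sees one or two draws) and fast
  compared to a trace; `redrawInterval = Inf` restores the frozen
  behaviour.

Count rates (500 s^-1 donor in the FRET stage, 300 s^-1 acceptor,
10 s^-1 background per channel) and bleach-time scales are not taken from
any instrument; they are chosen once so that a typical molecule yields a few
thousand FRET-level photons — a handful of bunches — which makes bunching,
selection and fitting operate in a realistic regime.

What the generator does *not* emulate: acceptor nanotime physics (only
presence/absence matters downstream), diffusing-molecule bursts, blinking
kinetics (blinking traces are rejected, not modelled), spectral crosstalk,
and detector afterpulsing. Passing tests therefore demonstrate correctness
of the inference chain under the stated model, not robustness to every
instrumental artifact of real data.

`simulateLangevinCV()` provides overdamped Euler–Maruyama sampling of a 1-D
collective variable under a caller-supplied potential plus harmonic window
biases (kT units), and `makeCGFrame()` builds labelled bead frames for the
contact metrics.

# Problem sizes and verification

The test suite verifies each operation against an independent oracle where
one exists: a quadrature-based numeric convolution for the decay density, a
dense-grid likelihood maximization for the MLE, explicit double loops and
27-image enumeration for contacts and periodic distances, closed-form
moments for samplers, and ground-truth tables for the end-to-end run. The
sizes used are: 10^5-draw moment and chi-square checks and a 10^6-photon
nanotime KL check (< 10^-3) for the generator; 1000 bunches per lifetime for
the <= 2% MLE bias bound; 1000 traces of 300 bins for the change-point
false-positive bound (<= 2 alpha); 3000 values per condition for mixture
recovery (means ± 0.05 ns, amplitudes ± 0.03); 500 replications of n = 300
for 93–97% bootstrap coverage; 10^4 simulations for ANOVA type-I
calibration at p <= 0.001; five umbrella windows of 6x10^4 steps for the
0.2 kT WHAM profile bound (evaluated on bins holding at least 0.5% of the
unbiased probability, with the profile's additive constant matched by mean
over those bins); and an end-to-end run of 4 conditions x 200 molecules in
which the shared means must return within ± 0.1 ns and the per-condition
open amplitudes within 5 percentage points of the realized bunch-level
ground truth. Fitted amplitudes are compared against the *realized* state
fractions rather than the nominal weights because with 200 molecules the
binomial sampling of states alone moves the truth by several points.

# Known limitations

* The change-point test is applied to 100-ms binned counts, not
  photon-by-photon arrival times; sub-bin bleach timing is unresolvable by
  construction.
* Mixture amplitude standard errors ignore shared-parameter covariance.
* WHAM is one-dimensional here.
* The Gaussian IRF and uniform background are modelling choices; a measured
  IRF would enter through a different convolution kernel.
* Distances inherit every caveat of the point-dipole Förster relation —
  no orientation-factor modelling, no correction for dye diffusion
  averaging.
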