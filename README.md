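# memfret

Conformational-state inference for membrane receptors from immobilized
single-molecule FRET photon streams, with companion accessibility metrics
for coarse-grained simulation frames.

Single-molecule FRET on a receptor such as full-length EGFR in a lipid
nanodisc reports the distance between a donor dye on the C-terminal tail and
an acceptor at the membrane (or on a bound ATP analog) through the donor
fluorescence lifetime: energy transfer shortens the lifetime as the distance
closes. Across many molecules the lifetime distribution resolves a two-state
equilibrium between a *compact* conformation (tail near the bilayer, short
lifetime) and an *open* conformation (tail away from the bilayer, long
lifetime), whose balance shifts with lipid composition and ligand.

`memfret` implements the full chain:

1. **Trace segmentation** — photon macrotimes binned at 100 ms
   (`binPhotons`), constant-intensity regions found by recursive binary
   segmentation with a Monte-Carlo-calibrated Poisson likelihood-ratio test
   (`detectChangepoints`), and molecules kept only when both channels bleach
   in a single step (`selectTraces`).
2. **Lifetime estimation** — consecutive 1000-photon donor bunches
   (`bunchPhotons`) fitted by maximum likelihood with a mono-exponential
   decay convolved analytically with a Gaussian IRF, truncated to the TCSPC
   window and mixed with a fixed uniform background (`fitDecayMLE`);
   histograms use square-root-rule binning (`buildLifetimeHistogram`).
3. **Förster conversion** — E = 1 − τ_DA/τ_D and
   r = R₀ ((1−E)/E)^(1/6), with R₀ = 8.4 nm (snap surface 594/Cy5) or
   7.5 nm (snap surface 594/atto 647N), per-condition bootstrap median
   distances and beyond-range flagging (`distanceFromLifetime`,
   `medianDistanceCI`).
4. **State modelling** — a global Gaussian mixture with means and widths
   shared across all conditions and free per-condition amplitudes
   (`fitGlobalMixture`), model order by BIC = −2 ln L + p ln n
   (`selectK`), separation by Ashman's D = |μ₁−μ₂|/√((σ₁²+σ₂²)/2)
   (`ashmanD`), EGF amplitude changes (`egfAmplitudeChange`) and one-way
   ANOVA comparisons (`anovaPair`).
5. **Trajectory metrics** — lipid contacts with the ATP-binding site at a
   strict 16 Å minimum-image cutoff (`countAtpSiteContacts`), the residue
   721 ↔ 1186 distance (`residueDistance`), WHAM reweighting of
   umbrella-biased collective-variable series (`whamReweight`) and
   three-partition block errors (`blockStats`).
6. **Synthetic data** — a seeded generator for photon streams with staged
   Poisson rates, single-step bleaching, IRF-convolved nanotimes and
   two-state lifetime mixtures (`simulateCondition`), plus Langevin sampling
   and coarse-grained frames for the trajectory metrics.

See `vignettes/memfret-methods.Rmd` for the model, its assumptions, the
tunable parameters and the design decisions.

## Worked example

A two-condition synthetic experiment (100 molecules each, open-state
amplitudes 69% without EGF and 91% with EGF), run end to end:

```r
library(memfret)
cfg <- list(
  conditions = list(
    list(label = "15% POPS -EGF", open_fraction = 0.69, n_molecules = 100),
    list(label = "15% POPS +EGF", open_fraction = 0.91, n_molecules = 100)),
  molecule = list(acceptor_bleach_time = 8, donor_bleach_time = 12),
  pairs = list(list(minus = "15% POPS -EGF", plus = "15% POPS +EGF",
                    label = "15% POPS")))
report <- runPipeline(cfg, seed = 7, verbose = TRUE)
```

```
segment[15% POPS -EGF]: 94/100 accepted
segment[15% POPS +EGF]: 93/100 accepted
fit: 414/373 bunches
model: selected k = 2

k = 2  means: 1.24 2.61  sigmas: 0.26 0.64
      condition open_pct se_pct
1 15% POPS -EGF     76.5   2.44
2 15% POPS +EGF     87.3   2.11
     label open_minus_pct open_plus_pct delta_pct se_pct
1 15% POPS           76.5          87.3      10.8   3.23
Ashman D: 2.8
```

Reading the output: ~93% of simulated molecules pass the single-bleach-step
selection; their FRET-level photons yield 414 and 373 bunch lifetimes; BIC
prefers two states over three; the shared peaks come back near the
generating 1.3 and 2.7 ns; and the open-state amplitude rises by ~11
percentage points on EGF addition (generating truth at this sample size:
the realized state draw, a few points off the nominal 69→91%). Ashman's
D = 2.8 > 2 marks the two fitted components as well separated. At 200
molecules per condition the shared means return within ±0.1 ns and
amplitudes within 5 points (this is asserted by the test suite).

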