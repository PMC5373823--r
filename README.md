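# smlmcorr

Pair correlation analysis for two-color single-molecule localization
microscopy (SMLM), and a lattice model of how membrane heterogeneity turns
receptor clustering into receptor phosphorylation.

## The problem

SMLM reconstructs membrane protein distributions as point patterns, but two
artifacts frustrate naive co-localization analysis: a single reversibly
photoswitching fluorophore is localized tens of times (overcounting, which
makes monomers look like clusters), and finite localization precision
(~30 nm) blurs structure. `smlmcorr` implements the statistics that are
robust to both:

- **Cross-correlation `C(r)`** — the density of channel-B localizations at
  distance `r` from channel-A localizations, divided by the density expected
  for a random co-distribution inside the same region of interest (ROI).
  `C = 1` means random co-distribution, `C > 1` co-clustering, `C < 1`
  exclusion. Overcounting cancels exactly in `C(r)`. Two numerically
  equivalent routes are provided: direct pair counting and FFTs on
  reconstructed 25 nm-pixel images, both normalized through the mask's
  spatial autocorrelation so that arbitrarily shaped (even hole-punched)
  ROIs give unbiased curves.
- **Surface density from the autocorrelation** — for near-random molecule
  distributions with approximately Poisson blinking, fitting
  `G(r) = 1 + A exp(-r^2 / 2 sigma^2)` to the single-channel
  autocorrelation gives the true molecule density
  `rho = 1 / (2 pi sigma^2 A)`, independent of how often each molecule
  blinked.
- **Analytic error bars** — the per-bin uncertainty of a single-cell `C(r)`
  from the angular scatter of the 2D correlation, corrected for PSF-induced
  pixel correlations (`dC1`) and for under-sampled PSFs (`dC2`).
- **Potential of mean force** — `PMF(r) = -ln C(r)` in units of kBT.
- **Live-cell analysis** — steady-state `C(r)` from frame-resolved streams
  (lag-averaged up to 50 frames, normalized by 1 um-blurred average images
  to remove long-range sampling gradients), a conservative nearest-neighbor
  tracker (500 nm gate, ambiguities terminate trajectories), step-size
  distributions, and the step sizes of probes found within 100 nm of a
  reference channel.
- **Ising signaling model** — a conserved order-parameter 2D Ising lattice
  (Kawasaki exchange dynamics, exact critical temperature
  `Tc = 2/ln(1+sqrt(2))`, run at `1.05 Tc`) carrying receptors and kinases
  as ordered components and phosphatases as disordered ones. A circular
  field clusters receptors (or stabilizes an ordered domain); accepted
  moves fire reaction rules (kinase contact phosphorylates at 0.1%,
  phosphatase contact dephosphorylates at 100%, optional receptor-bound
  kinase feedback). Snapshot cross-correlations bridge the simulation back
  to the imaging observables, including Gaussian PSF blurring.
- **Synthetic data** — ground-truth scene generators (random, clustered,
  co-clustered), a blinking/burst observation model, membrane-topology
  masks, live-cell Brownian streams; every generated table joins back to
  ground truth for testing.

## Worked example

```r
library(smlmcorr)

# a co-clustered two-color scene: 20 discs of 50 nm radius, 10 molecules
# per disc and channel, sampled with realistic blinking
sc   <- generate_scene(scene_spec("co_clustered", fov_nm = c(10000, 10000),
                                  n_discs = 20, disc_radius_nm = 50,
                                  mols_per_disc = 10), seed = 1)
locs <- sample_localizations(sc, blink_model(mean_obs = 20, n_frames = 5000,
                                             sigma_nm = 30), seed = 2)
mask <- rect_mask(10000, 10000, margin_nm = 150)
la   <- split_channel(locs, "ch1")
lb   <- split_channel(locs, "ch2")

cc <- crosscorr_fft(reconstruct_image(la, mask),
                    reconstruct_image(lb, mask), mask, r_max_nm = 600)
da <- density_from_autocorr(group_sequential(la), mask)
cc <- variance_dc2(cc, n1 = da$n_roi,
                   n2 = density_from_autocorr(group_sequential(lb),
                                              mask)$n_roi)
round(cc$C[1:6], 2)
#> [1] 237.44 206.46 146.38  90.17  48.95  20.56
da
#> <density_estimate> rho = 0.20 um^-2 (A = 240.367, sigma = 57.9 nm); ~86.1 obs/molecule
head(pmf_from_corr(cc), 3)
#>   r_nm    pmf_kt
#> 1 12.5 -5.469929
#> 2 37.5 -5.330120
#> 3 62.5 -4.986188
```

The first `C(r)` bins report a ~240-fold enrichment of channel-B
localizations within 25 nm of channel-A localizations, decaying toward 1
at the ~100 nm disc scale; the PMF restates that as an effective ~5.5 kBT
attraction. The density estimate illustrates the documented caveat for
strongly self-clustered species: 0.20 um^-2 is the density of *clusters*
(20 discs / 94 um^2 ROI = 0.21 um^-2), not of individual molecules, which
is why the apparent observations-per-molecule figure is inflated. For
near-randomly distributed probes the same estimator recovers the molecule
density itself to within ~10% (see the reproduction script below).

For the simulator:

```r
suite <- run_simulation_suite(L = 128, sweeps = 2000, equil_sweeps = 500,
                              seeds = 1:5)
suite$ordering
#> het_rbk_gt_het_norbk het_norbk_gt_uniform domain48_gt_domain24 composition_monotone
#>                 TRUE                 TRUE                 TRUE                 TRUE
```

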