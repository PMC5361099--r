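---
title: "Synergistic digital–analogue PCR: model, design rules, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synergistic digital-analogue PCR: model, design rules, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synpcr)
```

## The estimation model

A sample at unknown concentration $C$ is split into $N$ partitions, each
characterized by a modulation factor $d_i v_i$ (dilution $\times$ volume).
Molecule loading is Poisson: $m_i \sim \mathrm{Pois}(C\,d_i v_i)$. A
partition reads *positive* if it held at least $m_{tr}$ molecules
(default 1). The likelihood factors are

$$p_i(s_i{=}0 \mid C) = e^{-C d_i v_i}, \qquad
  p_i(s_i{=}1 \mid C) = P(m_i \ge m_{tr}) \;,$$

sigmoids in $C$ centred at the characteristic concentration
$C^*_i = \ln 2 / (d_i v_i)$ (for $m_{tr}=1$), where the binary signal is
worth its full 1 bit of Shannon entropy. The posterior is
$\rho(C) \propto \rho_0(C)\prod_i p_i(s_i \mid C)$ with the flat prior
$\rho_0 = 1/C_\infty$.

A real-time instrument adds the threshold cycle $ct_i$ of every positive
partition. With a constant per-cycle amplification factor $q$, the ratio
of starting counts in two positive wells is $q^{\,ct_j - ct_i}$. Taking
the positive well with the *largest* $ct$ (fewest starting molecules) as
reference $\omega$, well $i$ must have started with at least
$m_{tr}\, q^{\Delta ct_i}$ molecules, $\Delta ct_i = ct_\omega - ct_i$.
Its likelihood factor becomes the upper Poisson tail above

$$k_i = \max\!\big(m_{tr},\ \lceil m_{tr}\, q^{\Delta ct_i}\rceil\big),$$

a much steeper sigmoid shifted toward the true concentration. Counts are
integers, so we take the ceiling; this preserves the guarantee "held at
least $k_i$ molecules". When $q^{\Delta ct} < m_{tr}$ (possible only
through noise) the threshold never drops below $m_{tr}$. The raw tails
are used as likelihood factors without re-normalization, and at
$\Delta ct = 0$ the synergistic factor reduces *exactly* (same code path)
to the digital one.

### Calibration-free estimation of q

Along a known modulation ladder the expected crossing cycle falls
linearly in $\ln(d_i v_i)$ with slope $-1/\ln q$, so ordinary least
squares on the positive Ct wells gives $\hat q = e^{-1/\hat b}$ with a
delta-method standard error — no reference samples. Wells whose implied
starting count (relative to the reference) is below 5 molecules are
dominated by Poisson loading noise rather than amplification and are
dropped once before refitting. Estimates outside the physical range
$(1, 2]$ (frequent when only a few low-count wells are positive) fall
back to a user-specified fixed value, default $q = 1.9$, and the
provenance is recorded in the fit's evidence. The q uncertainty is *not*
propagated into the posterior (point plug-in), mirroring the published
procedure; `evidence$q_se` supports a manual sensitivity check.

### What "precision" means here

The assay's result *is* the posterior $\rho(C)$; its precision
$\sigma = \mathrm{sd}(\rho)/E(C)$ is the posterior relative standard
deviation. All profile and calibration code reports the mean of this
quantity over Monte-Carlo replicates as `sigma`. The sampling spread of
the posterior-mean point estimates across replicates is reported
alongside (`sigma_sampling`); for sparse ladders it is substantially
larger, because the log-wide skewed posterior makes the posterior mean a
long-tailed point estimate under the flat-in-$C$ prior. Only the
posterior-based measure reproduces the published performance figures of
the reference designs, which is why it is the primary one.

## Priors, grid, and numerics

* **Grid.** 2000 log-spaced points spanning
  $[C^*_{\min}/10^3,\ C^*_{\max}\cdot 10^3]$ of the layout; trapezoid
  quadrature for normalization, moments, and credible intervals
  (central 68% and 95% by CDF inversion).
* **Prior.** Flat in $C$ with $C_\infty = 10^3\, C^*_{\max}$ (the grid's
  upper end). A flat-in-log option exists because the flat-$C$ prior
  pulls $E(C)$ upward on log-wide posteriors and makes results weakly
  $C_\infty$-dependent near the upper boundary. Under the flat-log prior
  with concentrations drawn log-uniformly, 95% credible intervals cover
  the truth at the nominal rate (the suite checks 93–97%); under the
  default flat-$C$ prior with a fixed truth, coverage is nearer 92% —
  a known property of the published prior choice, not a defect.
* **Poisson tails.** Upper tails go through `ppois` (regularized
  incomplete gamma), never naive summation — except in the test oracle,
  which *is* naive summation. For Ct-shifted wells the tail is evaluated
  exactly only inside the transition window
  $\lambda \in (k/2,\ k + 12\sqrt{k} + 5]$; above it the log-tail is 0 to
  below $10^{-30}$, below it a four-term series with geometric remainder
  is used (max log-error $1.4\times10^{-3}$, posterior moments within
  $5\times10^{-4}$ relative of the exact path).
* **Boundary readouts.** All-negative and all-positive readouts yield
  valid but prior-bounded posteriors; they are flagged, counted in
  profiles, and a warning is raised beyond a 5% rate.
* **Censoring.** A positive whose crossing falls beyond the cycling
  program (45 cycles by default) reads negative-censored; a censored
  positive contributes digital information only. Crossings earlier than
  cycle 1 are reported at cycle 1.

## The simulator (and what a green test establishes)

Grand-canonical Monte-Carlo: counts are fresh Poisson draws per
replicate; a well with $m$ molecules crosses at
$ct = ct_{\mathrm{cal}} - \log_q m + \varepsilon$,
$\varepsilon \sim N(0, 0.25\ \text{cycles})$, with
$ct_{\mathrm{cal}} = 38$ (single-molecule crossing) and a 45-cycle
program — the only cycle count the source protocol prints. The noise sd
and $ct_{\mathrm{cal}}$ are assumptions (no noise model is published);
they are exposed in every simulating function. Per-cycle branching-process
stochasticity is absorbed into the Gaussian term. The simulator does not
model PCR inhibition, well-to-well efficiency variation, pipetting error,
or false positives/negatives — a green simulation test therefore
establishes correctness of the statistical machinery under ideal
amplification, not robustness to those effects.

One interaction worth knowing: because thresholds enter as
$\lceil q^{\Delta ct}\rceil$ and $E[q^{\varepsilon}] > 1$, Gaussian Ct
noise *tightens* the posterior slightly (e.g. the 200-well, $x=0.9$
reference design reads $\sigma \approx 13\%$ noiseless and
$\approx 11\%$ at 0.25-cycle noise). The posterior does not model Ct
noise, again following the published construction.

## Design rules and their calibration

For a geometric ladder $d_i v_i = d_0 v_0 x^i$ the attainable precision
saturates once enough margin compartments surround the active stripe.
The published closed-form constants for $x(\sigma_{\max})$ and
$\Delta N_x$ are not available (supplementary material), so
`calibrate_design()` regenerates both relations empirically: for each
$x$ on a grid, a ladder centred on a reference concentration is grown
symmetrically until $\sigma$ changes by less than 2% between margin
sizes (replicate draws shared across margin sizes, so the comparison is
paired); that point defines $\sigma_\infty(x)$ and $\Delta N_x$. Ladders
with $x \ge 0.925$ (synergistic) do not saturate by the $\Delta N = 30$
cutoff and are flagged, as specified. Self-similarity of geometric
ladders (verified exactly in the suite) lets one reference concentration
stand for all.

`design_assay()` then follows the explicit recipe: invert the monotone
envelope of $\sigma_\infty(x)$ for $x$, take
$N_{\mathrm{core}} = \lceil \log \Omega / -\log x\rceil$ compartments to
span the dynamic range, add $\Delta N_x$ margins per side, and size
$d_0 v_0$ so the largest $C^*$ sits $\Delta N$ ladder steps above $C^+$.
Precision below the single-copy limit is bought with *libraries* —
$k$ copies of every modulation, scaling $\sigma_\infty$ by
$\approx 1/\sqrt{k}$ (verified for the digital readout; the synergistic
readout gains at least as much since every copy contributes a Ct). With
`library_copies = NULL` the engine searches $(x, k)$ for the smallest
total well count meeting $\sigma_{\max}$ — this is how the 10%-over-6-logs
designs reproduce the published well counts (about 1160 end-point vs
about 320 synergistic against the published 1125 and 332). Uniform
replication is assumed; non-uniform libraries are a supplementary-only
detail and out of scope. In digital mode no single-copy ladder reaches
$\sigma_\infty$ below about 0.19 by the $\Delta N$ cutoff, so the
specified table span down to 0.05 is only reachable through libraries.

## Known limitations

* Four published figures are reproduced outside a 10% band and the
  corresponding checks are left red rather than tuned: the 32-well
  plateau (34.8% here vs 40%), the 200-well plateau (11.1% vs 10%), the
  16-well 4-log synergistic average (48.5% here vs a printed 60% that
  conflicts with the same paper's 52% for the identical geometry — our
  value tracks the 52% figure), and the matched-compartment gain
  (2.4–2.8-fold vs "2-fold"; our calibrated end-point design realizes
  part of its well count as library copies, each of which contributes an
  extra Ct to the synergistic re-analysis).
* The q-estimation procedure is an implementation choice (the published
  one is supplementary-only); it is exact on noiseless data and
  statistically calibrated under noise, but other schemes could differ.
* Concentration units are relative to the modulation unit throughout;
  user-facing I/O conventionally uses copies per mL.
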