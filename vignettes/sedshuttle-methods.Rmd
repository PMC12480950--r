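---
title: "Methods: electron-shuttle-linked denitrification analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electron-shuttle-linked denitrification analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sedshuttle implements the quantitative chain used to ask whether
humic-substance (HS) electron shuttling in lake sediments enhances
denitrification and suppresses nitrous oxide (N2O) emission: dissolved-gas
recovery, excess-gas and flux estimation, 15N isotope-pairing rate
partitioning, microbial-fuel-cell (MFC) power density, 16S-normalized qPCR
expression ratios, and a survey-scale driver-regression workflow. This
vignette documents the models, the tunable parameters, the synthetic-data
generators, and the numerical and design choices.

## Dissolved gases

**Headspace mass balance.** A water sample of volume $V_l$ is shaken to
equilibrium against a headspace $V_g$ of ambient air; the original dissolved
concentration is recovered from the measured headspace concentration $C_g$ as

$$C_w = C_g\,(K_0 R T + V_g/V_l) - C_{air}\,V_g/V_l,$$

with $R = 0.082$ L atm mol$^{-1}$ K$^{-1}$ and $K_0$ (mol L$^{-1}$
atm$^{-1}$) the solubility coefficient at the equilibration temperature $T$.
The inversion is exact: a forward partition followed by
`headspace_original_concentration()` returns the input to machine precision,
and the test suite exercises this over random admissible geometries. Negative
recoveries indicate inconsistent inputs and are flagged, never clamped, so
mass-balance problems remain auditable. The equilibration temperature is a
separate input from the in-situ temperature used for equilibrium
concentrations — the two genuinely differ in the field protocol.

**Solubility parameterizations.** The package commits to named published
fits, frozen in the tests against independently hand-evaluated oracles:

* N2O $K_0$ and the moist-air equilibrium function: Weiss & Price (1980)
  ln-polynomials;
* N2 and Ar air-saturation concentrations: Hamme & Emerson (2004) fits
  (µmol kg$^{-1}$, treated as µmol L$^{-1}$ — the <0.3% density error of
  fresh water is far below field measurement error).

Atmospheric mole fractions (N2 0.780840, Ar 0.009340, N2O 332 ppb) are
configuration values in `atm_mole_fractions`, not hard-wired constants, and
equilibrium concentrations are linear in mole fraction and pressure.
Defaults are salinity 0 (freshwater lake) and 1 atm.

**Excess gas and flux.** $\Delta$N2 and $\Delta$N2O are signed differences
from atmospheric equilibrium (undersaturation is preserved). Diffusive flux
is $F = k \Delta\mathrm{N_2O}$ with the excess converted to µmol m$^{-3}$
(×1000), so $k$ in m d$^{-1}$ yields µmol m$^{-2}$ d$^{-1}$. The piston
velocity $k$ is user data; a quadratic wind helper
($k_{600} = 0.251\,u_{10}^2$ cm h$^{-1}$, Schmidt scaling
$(Sc/600)^{-1/2}$, Wanninkhof 2014) is provided for convenience only. The
N2:Ar method multiplies the measured ratio by the Ar equilibrium
concentration, exploiting argon's biological inertness.

## Isotope pairing

With a nitrate pool at 15N atom fraction $F_N$, denitrification (rate $D$)
produces $^{30}$N2 at $D F_N^2$ and $^{29}$N2 at $2 D F_N (1-F_N)$, while
anammox (rate $A$) pairs one labeled and one ambient atom, producing
$^{29}$N2 at $A F_N$. Inverting the measured slopes $p_{29}, p_{30}$:

$$D = p_{30}/F_N^2, \qquad A = \big(p_{29} - 2\tfrac{1-F_N}{F_N} p_{30}\big)/F_N.$$

This is the revised (Thamdrup-style) variant; it is isolated in
`ipt_partition()` so an alternative can be substituted in one place. Slopes
come from OLS on the sacrificial-vial time series with replicates pooled
(not averaged first), preserving degrees of freedom. A negative anammox
estimate — a $^{29}$N2 deficit relative to the pairing prediction — is
reported raw with a flag plus a clamped copy for downstream summaries.
$F_N$ is a user input because ambient nitrate dilutes the tracer
site-specifically; `fn_from_nitrate()` computes it from added and ambient
concentrations. The generator default $F_N = 0.8$ reflects a 0.17 mM
15NO3$^-$ addition over modest porewater nitrate. Per-gram normalization
uses the vial geometry (11 mL over ~2 g dry sediment) and counts N2
molecules unless `as_n_atoms = TRUE`.

## MFC power density

Per sweep point $I = V/R_{ext}$; current density $I/A$ and power density
$VI/A$ (µW m$^{-2}$) use the projected anode area. Maximum power density
(MPD) is the empirical curve maximum — a plot-based reading with no
interpolation — with ties broken toward larger external resistance. On a
Thevenin cell $V = V_{oc} R/(R+R_{int})$ whose grid contains
$R = R_{int}$, MPD equals $V_{oc}^2/(4 R_{int} A)$ exactly; off-grid sweeps
stay below that bound. `estimate_internal_resistance()` fits the Thevenin
model (Levenberg-Marquardt) as a diagnostic.

## qPCR expression

Relative expression is $E^{\,Ct_{16S} - Ct_{target}}$ with default
efficiency $E = 2$; whether field studies use efficiency-corrected forms is
rarely stated, so per-gene efficiencies are accepted as data. Fold-ratios
(treatment/control per matched pair) are summarized by the geometric mean —
ratios are multiplicative — with the arithmetic mean behind a flag. The
paired test routes on Shapiro-Wilk normality of the differences at
$\alpha = 0.05$: paired $t$ when normal, Wilcoxon signed-rank otherwise,
and the route taken is reported. BH-FDR is applied across the 7-gene family
(nirS, nirK, nosZI, nosZII, omcB, omcS, pilA) via `stats::p.adjust`.

## Driver regression

The survey-scale chain in `stepwise_aic_mlr()` follows the sequential
workflow of field biogeochemistry: (1) Spearman screening of candidates
against the response at $\alpha = 0.05$; (2) bidirectional stepwise AIC
from an intercept-only start (`MASS::stepAIC`); (3) variance-inflation
screening (drop the worst predictor until all VIF < 5); (4) pruning of
individually non-significant predictors with refitting. Each gate is
switchable, and the whole procedure is deterministic given the table.
Standardized coefficients are $\beta_j\,sd(x_j)/sd(y)$ with identically
transformed CIs; for a single predictor this equals the Pearson $r$ to
machine precision. Cohen's $d$ uses $d = 2t/\sqrt{df}$ — the conversion
consistent with one of the two reported $(t, d)$ pairings in this
literature; published pairs are not always mutually consistent, so the
formula is documented here rather than inferred per dataset.

Two nonlinear fits support the biology: exponential association
$y = a e^{bx} + c$ (one-sided $t = \hat b/SE$ with $df = n-3$ for growth)
and one-phase decay $Y = (Y_0 - \mathrm{plateau})e^{-Kx} + \mathrm{plateau}$
with $K \ge 0$, used for the attenuation of HS-amendment benefits with
native HS. Both use Levenberg-Marquardt with endpoint-heuristic starts and
a fixed, deterministic ladder of scaled restarts (no RNG), keeping refits
bit-reproducible; plateau-only decay data are flagged unidentifiable
rather than fitted.

## Synthetic-data generators

Each generator is a pure function of config + seed, and each has an exact
noise-free inversion by its analysis stage — the central testable property
of the package. Defaults encode the study conditions:

* **Survey** (`generate_survey`): 12 sites; HS log-uniform over 9.5-230.1
  mg g$^{-1}$; HA share drawn from N(0.928, 0.094) truncated to (0, 1]
  (truncation shifts the realized mean to ≈0.89); MPD linear in HS with
  noise calibrated against the realized signal variance to an
  $R^2 \approx 0.7355$ coupling; excess N2 linear in MPD at
  $R^2 \approx 0.7926$; N2O metrics negatively coupled to MPD; DO, pH,
  temperature and inorganic nitrogen are independent noise — so "only MPD
  drives $\Delta$N2" is true by construction.
* **Incubations** (`generate_incubation`): forward isotope-pairing slopes,
  linear in time over 0/6/12/24 h, three replicate vials per time point,
  Gaussian concentration noise (default 0.02 µmol L$^{-1}$, ~2% of the
  24-h signal, a realistic MIMS precision); default rates
  $D = 0.05$, $A = 0.02$ µmol L$^{-1}$ h$^{-1}$ give a ~71% denitrification
  share; HS_C vials multiply $D$ by 2.6, optionally attenuated
  exponentially by native HS; per-pair lognormal heterogeneity (CV 0.2).
* **Headspace / polarization**: forward mass balance and Thevenin model
  with Gaussian measurement noise.
* **qPCR** (`generate_qpcr`): reference and target Ct values with shared
  pair offsets; HS_C target Ct shifted by $-\log_2(\mathrm{fold})$. Default
  folds use the reported values where available (omcB 31.5, omcS 2.0,
  pilA 3.3, nosZII 31.5, nosZI 7.7, nirS 4.6); nirK is not individually
  reported and is set to 12.0, inside the observed 4.6-396.1 range.

What the generators do **not** emulate: spatial or temporal autocorrelation
among sites, non-Gaussian measurement error, nitrate-pool drawdown during
incubation (slopes stay linear by construction), DNRA, inter-gene
correlation in expression, and instrument drift. Passing tests therefore
demonstrate correctness of the estimators under the assumed error model,
not robustness to every feature of real field data.

## Problem sizes and known limitations

The shipped tests and the acceptance script use desk-scale sizes chosen to
give stable Monte Carlo estimates: 1000 draws for exact-inversion checks,
200 synthetic surveys for selection-rate estimates, 1000 replicates for the
null false-discovery simulation, 100-300 replicates elsewhere.

One selection-rate observation is worth recording. At $n = 12$ sites with
six candidate factors and the $R^2 \approx 0.79$ coupling, the full
validated chain selects MPD alone in about 94% of synthetic surveys (and
plain stepwise AIC without the screening and pruning gates does far worse —
chance predictors enter AIC at well above the 5% intuition at this sample
size). In about 2% of surveys some noise factor exceeds MPD's standardized
coefficient in the forced full model. These are properties of small-$n$
model selection itself, not implementation defects; single-dataset
selection results at this scale should be read with that base rate in mind.

Other limitations: the solubility fits are trusted within 270-330 K and
error outside; the IPT variant assumes binomial pairing from a single
well-mixed nitrate pool; MPD depends on the sweep protocol and is treated
as data; and the driver chain assumes linear relations after optional
transformation and cannot adjudicate causality.
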