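---
title: "Growth laws and proteome allocation under ppGpp titration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth laws and proteome allocation under ppGpp titration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgppalloc)
library(dplyr)
```

## The scientific problem

The bacterial alarmone (p)ppGpp is the central regulator of ribosome
synthesis in *E. coli*. Titration experiments that push its level both up
(inducible synthetase) and down (inducible hydrolase) show a striking
symmetry: growth slows in *both* directions. `ppgppalloc` implements the
quantitative reading of such experiments: either perturbation forces the
proteome away from its optimal allocation between ribosomes and metabolic
proteins, and whichever sector shrinks becomes the flux bottleneck.

## The three-sector model and its assumptions

The proteome mass is split into a ribosome-affiliated sector $\phi_R$, a
metabolic sector $\phi_M$, and a constant housekeeping sector $\phi_Q$, with
$\phi_R + \phi_M = \phi_{\max} = 1 - \phi_Q$. During steady-state
exponential growth,

$$\lambda = \gamma\,\phi_R, \qquad \lambda = \nu\,\phi_M,$$

where $\gamma$ (translational efficiency) and $\nu$ (metabolic efficiency)
are condition-specific constants with units of 1/h per unit proteome
fraction. Balancing both fluxes under the budget constraint gives the unique
optimum $\lambda^* = \gamma\nu\phi_{\max}/(\gamma+\nu)$, computed by
`balanced_growth()`.

When ppGpp pins $\phi_R$ away from the optimum, the model assumes the slower
of the two fluxes sets the realized growth rate:

$$\lambda(\phi_R) = \min\big(\gamma\,\phi_R,\; \nu(\phi_{\max}-\phi_R)\big).$$

This is the minimal formalization of the flux-bottleneck picture: it is
continuous, reduces to the two linear growth laws on the respective
branches, and is maximised exactly at the balanced optimum (a property the
test suite checks against a grid-search oracle over random parameter sets).
Key assumptions worth keeping in mind: steady-state growth only (no
stringent-response transients), condition-independent $\gamma$ and $\nu$
over the fitted range, and a strictly constant $\phi_Q$.

The measurable proxy for $\phi_R$ is the RNA/protein mass ratio, converted
with $\phi_R = (R/P)\cdot\rho$, $\rho = 0.76$. Constitutive and metabolic
promoter activities are modelled as proportional to $\phi_M$, which is what
makes them rise when ppGpp rises and collapse when ppGpp is depleted.

```{r tent}
params <- allocation_params(gamma = 6, nu = 3, phi_max = 0.4)
balanced_growth(params)
plot_perturbed_growth(params)
```

## Parameters that matter

| parameter | meaning | unit | default | rationale |
|---|---|---|---|---|
| `gamma` | translational efficiency | 1/h per fraction | 6 | places $\lambda^* = 0.8$/h, a typical minimal-medium rate |
| `nu` | metabolic efficiency | 1/h per fraction | 3 | ditto; $\gamma > \nu$ as in carbon-limited growth |
| `phi_max` | growth-linked proteome budget | — | 0.40 | the canonical ~40% of the *E. coli* proteome |
| `rho` | $\phi_R$ per unit R/P | — | 0.76 | the standard RNA-to-ribosomal-protein conversion |
| `f_rrna` | rRNA share of total RNA | — | 0.86 | stable across growth conditions |
| `m_aa` | mean residue mass | Da | 109 | proteome-average amino acid |
| `m_rrna` | rRNA mass per ribosome | Da | 1.507e6 | 16S+23S+5S |
| `lacz_len` | LacZ monomer length | aa | 1023 | mature monomer convention |

All are constructor arguments (`allocation_params()`,
`ribosome_constants()`), never hard-coded, so every deduction is auditable
and overridable. Stored fractions keep full precision; rounding to integer
percent (`percent_label()`, half away from zero) happens only at display
time — 0.4256 is stored, "43%" is printed.

## Assay reductions and their numerical choices

**Growth rates.** `fit_growth_rate()` fits $\log \mathrm{OD}_{600}$ against
time by ordinary least squares over the OD window $[0.1, 0.5]$ (endpoints
inclusive; ties kept). Log-OLS rather than a nonlinear exponential fit: it
is the standard slope extraction, exact on noiseless data, and has no
convergence failures. There is no outlier rejection, and slightly negative
slopes are reported with a warning instead of being truncated at zero —
truncation would bias Monte-Carlo recovery studies. Curves are fitted
individually; averaging replicate rates is an explicit downstream step, and
run summaries record that convention.

**Miller units.** The classical colorimetric normalisation
$1000(\mathrm{OD}_{420} - 1.75\,\mathrm{OD}_{550})/(t\,v\,\mathrm{OD}_{600})$.
Blank-dominated readings go negative; they are reported (with a warning),
not clamped, to preserve error propagation in later averages.

**Elongation rate.** The LacZ induction curve is reduced by the classical
square-root plot: after the inducer is added, no completed LacZ exists until
the first monomer finishes at $t_{\mathrm{first}} = L/\mathrm{ER}$ (with $L$
the LacZ length), after which accumulated activity grows quadratically, so
$\sqrt{\text{activity}}$ is linear with x-intercept $t_{\mathrm{first}}$.
Numerical choices: the pre-induction baseline and its spread are estimated
from the growing initial flat segment; the post-rise region starts at the
first point above baseline + 3 spreads (configurable via `rise_sigma`); the
regression uses only points with positive net activity. The estimate is
invariant to adding a constant baseline. Degenerate curves (no rise, falling
activity, negative x-intercept) raise classed errors rather than numbers.

**Active ribosome fraction.** Flux balance requires each amino acid of
protein to be duplicated once per generation:
$f = (\lambda/3600)/(\mathrm{ER}\cdot n)$, with
$n = (R/P)\,f_{\mathrm{rRNA}}\,m_{\mathrm{aa}}/m_{\mathrm{rRNA}}$ ribosomes
per amino acid of protein. Values above $1 + 10^{-6}$ mean the inputs
contradict the balance and raise an error; values inside the tolerance band
are clamped to 1.

## Parameter recovery from a two-direction titration

`recover_parameters()` reads the two branches off a paired titration:
the ppGpp-up series must show a positive (λ, R/P) slope
(translation-limited branch, $\gamma$ = slope of λ on $\phi_R$) and the
ppGpp-down series a negative one (metabolic branch, $\nu = -1/\text{slope}$
of $\phi_R$ on λ, $\phi_{\max}$ = its zero-growth intercept). A wrong slope
sign raises a branch-assignment error; nothing is silently relabelled. The
translation branch is fitted with a free intercept by default (`offset_up`),
because measured nutrient-limitation growth laws show a small positive R/P
offset at zero growth even though the idealized law has none; the
through-origin fit is available with `offset_up = FALSE`, and the fitted
offset is always reported so the tension stays visible. Similarly, the model
treats $\gamma$ as constant although elongation rates sag slightly at slow
growth; the free intercept absorbs most of that curvature.

A related reporting choice: the zero-growth ribosomal fraction deduced from
the R/P intercept 0.56 is 0.4256 (43%), while the budget $\phi_{\max}$ is
quoted as ~40%. The package reports both numbers at full precision rather
than reconciling them; their near-equality is the substantive claim (at
extreme ppGpp shortage the R-sector fills the entire growth-linked budget,
leaving $\phi_M \to 0$).

```{r recover}
phys <- simulate_experiment(sim_config())$physiology
fit <- recover_parameters(phys)
tidy(fit)
glance(fit)
```

## What the synthetic generator emulates — and what it does not

`simulate_titration()` generates a virtual titration in the causal order the
biology dictates: inducer → ppGpp (log-linear per decade of inducer, the
simplest monotone choice since the measured dose responses constrain only
monotonicity) → $\phi_R$ (repressive Hill function per direction) → λ (the
min rule) → R/P, promoter activity, and a per-sample elongation rate tied
through a configured active fraction. Measurement noise is multiplicative
log-normal on every positive-valued readout, reflecting the
scale-proportional errors of OD and colorimetric measurements; the default
CVs are 2% (OD600), 5% (R/P, growth rate, Miller), 3% (induction
activity), consistent with reported triplicate spreads within 10% and the
larger uncertainty of ppGpp quantification. Defaults: 8 inducer levels × 3
replicates per direction (24 samples/branch), generating parameters
$\gamma = 6$, $\nu = 3$, $\phi_{\max} = 0.4$, seed 20190327. Randomness is
split into per-(direction, purpose, replicate) substreams, so adding a
replicate never perturbs existing draws and identical configurations are
bit-reproducible.

What it deliberately does not emulate: stringent-response transients,
stationary-phase phenotypes and suppressor mutations, ribosome maturation
or queuing, mechanistic ppGpp–RNA-polymerase interaction, and any
instrument-level artefacts (plate-reader drift, carryover). Passing
recovery tests on these simulations therefore demonstrates that the
*analysis chain* is correct and well-conditioned at realistic noise — not
that the three-sector model is the true generative process for any given
real dataset.

## Problem sizes and tolerances used by the test suite

The suite checks closed-form optima against a step-$10^{-5}$ grid-search
oracle over 1000 random parameter sets drawn from $\gamma,\nu \in [2,8]$,
$\phi_{\max} \in [0.3, 0.5]$ (agreement to $10^{-4}$ relative; outside this
physiological neighbourhood a fixed-step grid oracle itself becomes the
accuracy bottleneck). Estimator checks use 100 Monte-Carlo growth curves of
8 in-window points at 2% OD noise (mean recovered rate within 1% of truth;
the per-curve scatter of any unbiased estimator in this window design is
~1.4%), elongation-rate recovery within 5% at 3% noise, and parameter
recovery within 5% at the default noise with 24 samples per branch — exact
to $10^{-9}$ at zero noise. OLS paths are cross-checked against hand-coded
normal-equation oracles to 10 significant digits.

## Known limitations

- Branch assignment trusts the experimental direction labels plus a sign
  test; a titration straddling the optimum within one direction would mix
  branches and should be split by the user.
- The min-rule growth predictor is piecewise linear; if real data show
  curvature near the optimum (co-limitation), both branch fits will still be
  consistent but the recovered $\lambda^*$ will overestimate the observed
  maximum slightly.
- The elongation-rate reduction assumes a clean quadratic rise; strongly
  saturating induction curves violate the square-law window and should be
  truncated before fitting.
- ppGpp is treated in arbitrary units throughout; no absolute calibration
  of inducer → ppGpp is implied.
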