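# ppgppalloc

Quantitative analysis of *Escherichia coli* growth physiology under titrated
(p)ppGpp levels, for bacterial physiologists working with growth-law data.
The alarmone ppGpp sets how the proteome is split between ribosome-affiliated
proteins and metabolic proteins; both raising it (via an inducible ppGpp
synthetase) and lowering it (via an inducible hydrolase) slow steady-state
growth, because either the protein-synthesis flux or the metabolic flux
becomes limiting. This package implements the full analysis chain for such
experiments: assay reduction, the allocation model, growth-law fitting,
parameter recovery, and a synthetic-data generator that makes every stage
testable without raw instrument files.

## The model

The proteome is partitioned into three coarse-grained sectors: the
ribosome-affiliated fraction φ_R, the metabolic fraction φ_M, and a
growth-rate-independent housekeeping fraction φ_Q. The two growth-linked
sectors obey

- λ = γ·φ_R (translation: γ is the translational efficiency, 1/h per unit fraction),
- λ = ν·φ_M (metabolism: ν is the metabolic efficiency),
- φ_R + φ_M = φ_max = 1 − φ_Q (≈ 0.40 in *E. coli*),

and the measurable RNA/protein mass ratio converts to φ_R as
φ_R = (R/P)·ρ with ρ = 0.76. Under balanced growth both fluxes are equal and
λ\* = γνφ_max/(γ+ν). When ppGpp forces the allocation off this optimum the
realized growth rate is the limiting flux,

    λ(φ_R) = min( γ·φ_R , ν·(φ_max − φ_R) ),

so high ppGpp (small φ_R) is translation-limited and low ppGpp (small φ_M)
is metabolism-limited — both slower than λ\*. Titrating ppGpp in either
direction therefore traces out one branch of this tent-shaped curve as a
linear growth law in the (λ, R/P) plane, and fitting both branches recovers
γ, ν and φ_max.

The toolkit also reduces the underlying assays: exponential growth rates as
the log-linear OLS slope of OD600 over the 0.1–0.5 window; β-galactosidase
activity in Miller units, 1000·(OD420 − 1.75·OD550)/(t·v·OD600); the
translational elongation rate from the square-root transform of a LacZ
induction curve (ER = 1023 aa / first-completion lag); and the active
ribosome fraction from flux balance, f = (λ/3600)/(ER·n), with n the
ribosome number per amino acid of protein deduced from R/P.

## Worked example

Simulate a two-direction titration (8 inducer levels × 3 replicates per
direction, 5% measurement noise) and recover the generating parameters
γ = 6 /h, ν = 3 /h, φ_max = 0.4:

```r
library(ppgppalloc)
library(dplyr)

params <- allocation_params(gamma = 6, nu = 3, phi_max = 0.4)
balanced_growth(params)
#> # A tibble: 1 × 4
#>   lambda phi_R phi_M rp_ratio
#>    <dbl> <dbl> <dbl>    <dbl>
#> 1    0.8 0.133 0.267    0.175

phys <- simulate_experiment(sim_config())$physiology
recover_parameters(phys)
#> <allocation_fit> recovered three-sector parameters
#>   gamma = 5.908 /h, nu = 3.03 /h, phi_max = 0.3995
#>   optimum: lambda* = 0.8 /h at phi_R* = 0.1354
#>   branch fits: r^2(up) = 0.9829 (n = 24), r^2(down) = 0.9765 (n = 24)
```

The optimum at λ\* = 0.8 /h is the unperturbed growth rate; the recovered
efficiencies land within ~2% of the generating values at this noise level.
Fitting the ppGpp-depletion branch as a growth law extrapolates ribosome
content to zero growth:

```r
fit_growth_law(filter(phys, direction == "ppgpp_down"))
#> <growth_law_fit> rp_ratio = 0.52561 -0.43429 * lambda  (r^2 = 0.9765, n = 24)
#>   r_max = 0.5256; zero-growth phi_R = 0.3995 (40%)
```

`r_max` is the y-intercept of R/P versus λ; multiplied by ρ it gives the
maximal ribosomal proteome fraction, which at extreme ppGpp shortage fills
the whole growth-linked budget φ_max — the quantitative reason a ppGpp-null
strain cannot grow in minimal medium. With the measured intercept
R/P = 0.56, `phi_R_from_rp(0.56, 0.76)` gives 0.4256, displayed as 43%.

`autoplot()` methods are provided for growth-law and allocation fits, and
`plot_perturbed_growth(params)` draws the tent-shaped λ(φ_R) curve.

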