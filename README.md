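# skinmarkov

A spatial two-state Markov-chain simulator of skin-cancer progression,
with an analytic validation benchmark, Monte Carlo uncertainty
quantification, and calibration to tumour-mass growth curves.

## The problem and the model

Skin cancer spreads through tissue both by local contamination — cancerous
regions convert their neighbours via proliferation and migration — and by
initiation from lifetime UV exposure, which is strongest at the skin
surface and attenuates with depth. `skinmarkov` models a patch of
epidermis as a rectangular lattice of nodes in 1, 2 or 3 dimensions, each
node either susceptible (S = 0) or cancerous (S = 1), with irreversible
transitions. A susceptible node *i* carries an exponential hazard

    lambda_i  =  lambda * sum_{j in N_i} S_j / d(x_i, x_j)  +  alpha * R_i

where the sum runs over nearest neighbours at distances *d*, and the UV
exposure factor `R_i` is 0 (no UV), 1 on the surface layer only, or
`exp(-beta * zhat)` at depth `zhat` below the surface. The `1/d` scaling
makes the expected traversal time of a fixed physical distance independent
of grid resolution, so the three parameters `lambda` (base rate), `alpha`
(UV sensitivity) and `beta` (UV attenuation) are the entire model.

Spatially averaged, the model has an exact non-spatial benchmark,
`p(t) = 1 - exp(-integral of lambda)`, used to validate the lattice
sampler; the statistic of interest for a spatial run is `T_f`, the first
time a fraction `f` of the domain is cancerous. Uncertainty — both the
stochasticity of the process and ignorance of the inputs — is quantified
by Monte Carlo: repeated trials with `(lambda, alpha, beta)` drawn from
normal distributions yield the mean of `T_{1/2}`, its Monte Carlo Error
`s_N / sqrt(N)`, its empirical CDF, and input–output Pearson correlations.

## Worked example

Growth from the UV-exposed surface of a 32 x 32 x 32 unit cube
(`lambda = 0.01`, `alpha = 0.1` on the top layer):

```r
library(skinmarkov)
set.seed(1)
lat <- build_lattice(c(32, 32, 32))
model <- rate_model(lambda = 0.01, alpha = 0.1, uv_mode = "surface")
traj <- simulate_growth(lat, model, stop_count = 30000)
traj
#> trajectory (fixed_tau): 30020/32768 nodes cancerous at t=29.35 (30020 events)
time_to_fraction(traj, 30000 / 32768)
#> [1] 29.35
```

The run starts from an all-susceptible state; cancer initiates on the
surface (1024 exposed nodes, hazard 0.1 each) and a front descends by
nearest-neighbour contamination, occupying 30,000 of 32,768 nodes after
about 29 dimensionless time units.

Validating the sampler against the analytic chain (uniform-rate mode, run
to all-cancer) and quantifying input uncertainty on a 2-D lattice:

```r
tr_u <- simulate_growth(lat, rate_model(0.01, mode = "uniform"),
                        stop_fraction = 1, tau_control = tau_rule(tau = 1),
                        max_steps = 1e5)
rms_vs_analytic(tr_u, 0.01)
#> validation_report: n=32768, lambda=0.01, tau=1, n_t=1046, RMS=6.0280e-04

st <- run_study(build_lattice(c(100, 100)), parameter_dists(),
                N = 50, seed = 1)
st
#> mc_study: N=50 (done 50), f=0.5
#>   T_f mean=3.5018, s=0.5538, MCE=0.0783
#>   r(lambda)=-0.5763  r(alpha)=-0.4442  r(beta)=0.5212
```

The RMS of the lattice fraction against `p(t) = 1 - e^{-0.01 t}` is pure
sampling noise (it shrinks like `n^{-1/2}`). In the study, `T_{1/2}` falls
with `lambda` and `alpha` (faster contamination / initiation) and rises
with `beta` (stronger UV absorption shields deeper tissue).

A thin CLI wraps the same functions (`exec/skinmarkov`), with subcommands
`simulate`, `validate`, `mc`, `calibrate`, `synth-curve` and `fixtures`;
ready-made scenario configurations ship in `inst/extdata/` and from
`scenario_fixtures()`.

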