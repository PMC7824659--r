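# moverstayer

Mover–stayer Markov models of intra-urban residential relocation.

## The problem

Where will a city's residents live in the long run, if current moving
patterns persist? Census origin–destination tables record how many people
relocated from zone *i* to zone *j* within a one-year or five-year window.
Treating the city as a **closed system** (fixed total population, no
external migration), relocation becomes a diffusive relaxation process: the
population vector drifts towards a stationary "equilibrium city", at a rate
set by the spectrum of the relocation matrix.

The package is aimed at urban and population modellers who have
zone-to-zone flow tables and want (a) a long-run forecast of the spatial
population structure and (b) internally consistent extrapolation of
short-window flows to longer windows.

## The model

Populations are row vectors evolving as a Markov chain,

    X(t+1) = X(t) P,        P = (1 − ε) I + ε H,

the *mover–stayer* decomposition: each year a resident moves with
probability ε (the relocation frequency; τ = 1/ε is the characteristic
relocation time) and, conditional on moving, picks a destination from the
row-stochastic **spatial kernel** H, estimated from flows by
h<sub>ij</sub> = T<sub>ij</sub> / Σ<sub>k≠i</sub> T<sub>ik</sub>. The
equilibrium X<sub>eq</sub> is the left unit-eigenvector of P — identical
for every ε ∈ (0, 1], so the forecast depends on the kernel only.
Relaxation towards it follows the discrete transport law

    Q(t) = U(t) L,          L = P − I = −ε(I − H),

with driving force U(t) = X(t) − X<sub>eq</sub> and rate
Q(t) = X(t+1) − X(t); near equilibrium ‖U(t)‖ decays geometrically at the
second-largest eigenvalue modulus |λ₂(P)|.

A single frequency cannot reconcile one-year and five-year census stayer
shares (s₁ ≈ 0.9 would force s₅ ≈ 0.9⁵ ≈ 0.6, while observed five-year
shares are ≈ 0.7–0.78). The package therefore splits the population into
two components with shares α, 1−α and frequencies ε₁, ε₂ solving

    α(1−ε₁)  + (1−α)(1−ε₂)  = s₁
    α(1−ε₁)⁵ + (1−α)(1−ε₂)⁵ = s₅,

found by a dense sign scan plus bisection of the reduced quintic
(`mover_stayer_fit()`). Supporting machinery includes mixture equilibria
with shared or component-specific kernels, the aggregate-kernel
approximation Ĥ = Σ α<sub>k</sub>H<sub>k</sub>, spectral relaxation
diagnostics, a refractory ("no move for τ years after moving") rival
model, synthetic linear/block toy cities, the exact kernel split
αH₁ + (1−α)H₂ = H, CSV input/output and a command-line interface
(`inst/cli/moverstayer`).

## Worked example

Calibrate to Sydney's census stayer shares (s₁ = 0.91, s₅ = 0.73) with
α = 0.95 and predict the 30-year stayer share:

```r
library(moverstayer)
fit <- mover_stayer_fit(s1 = 0.91, s5 = 0.73, alpha = 0.95)
fit
#> Two-component mover-stayer calibration
#>   shares: s1Y = 0.91, s5Y = 0.73; alpha = 0.95
#>   epsilon1 = 0.051322 (tau = 19.5 y), epsilon2 = 0.824884 (tau = 1.2 y)
predict(fit, c(1, 5, 30))
#>         1         5        30
#> 0.9100000 0.7300000 0.1955644
```

95% of the population moves about once every 19.5 years, a fast 5% about
every 1.2 years; together they reproduce both census shares exactly and
predict that ≈ 0.2 of residents stay put over 30 years — where the
homogeneous model (`one_component_extrapolation(0.91, 30)` ≈ 0.06) is far
too pessimistic.

Equilibrium of a toy city, and how fast it is approached:

```r
lc <- linear_city_kernels(n_zones = 99, beta = 0.1, center = 50)
m  <- relocation_model(0.2, lc$H1)
eq <- stationary_distribution(m, total = 1)
which.max(as.numeric(eq$x_eq))
#> [1] 50
tr <- evolve(population_vector(rep(1, 99)), m, 60)
relaxation_diagnostics(tr, m, window = 20:60)
#> Relaxation decay estimate (l2 norm)
#>   fitted slope    : -0.2231436
#>   spectral slope  : -0.2231436  (|lambda2| = 0.8 )
#>   terminal ||Q||/||U|| : 0.2
```

The centre-seeking city equilibrates onto its central suburb, and the
empirical decay of log‖U(t)‖ matches the spectral prediction
log|λ₂(P)| = log 0.8.

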