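---
title: "Methods: mover–stayer relocation models and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mover–stayer relocation models and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moverstayer)
```

## The model and its assumptions

The package describes intra-urban residential relocation as a discrete-time
Markov chain on the city's zones. Four assumptions define the scope:

1. **Closed system.** The total population $\bar x$ is fixed; there is no
   external migration or boundary growth. Every operation conserves
   $\sum_i x_i(t)$ and the tests assert it to $10^{-6}\bar x$ over
   thousand-step trajectories.
2. **Time-homogeneity.** The relocation matrix $P$ does not change during
   relaxation. This is what makes the evolution irreversible in the
   thermodynamic sense: once $X(t) = X_{eq}$ there is no force to leave it.
3. **Discrete annual steps.** Census windows are one and five years;
   horizons are integer years throughout, with no sub-annual interpolation.
4. **Mover–stayer structure.** $P = (1-\epsilon)I + \epsilon H$ separates
   the *temporal* term $\epsilon$ (per-year probability of moving, units
   1/year; $\tau = 1/\epsilon$ the mean residence time) from the *spatial*
   term $H$, the row-stochastic destination-choice kernel.

Populations are **row vectors** and evolution is right-multiplication
$X(t+1) = X(t)P$; every stationary vector in the package is a *left*
eigenvector. Mixing the two conventions is the classic silent failure of
this model family, so the convention is fixed package-wide.

Heterogeneous mobility enters as a mixture: component $k$ holds a share
$\alpha_k$ of every zone's population and follows its own
$P_k = (1-\epsilon_k)I + \epsilon_k H_k$. Components evolve independently;
only their sum is observed. With a shared kernel, each component's
equilibrium is $\alpha_k X_{eq}$ with $X_{eq}$ the stationary vector of
$H$ — independent of all $\epsilon_k$ and $\alpha_k$, which is why the
long-run forecast needs the kernel only.

## Parameters that matter

| Parameter | Meaning | Units | Default | Why |
|---|---|---|---|---|
| $\epsilon$, $\epsilon_k$ | relocation frequency | 1/year | — (calibrated) | defines the mover–stayer split |
| $\alpha$ | share of component 1 | — | 0.9 | not identifiable from two window lengths; fixed by the analyst |
| $s_1$, $s_5$ | stayer shares at 1 and 5 years | — | — (data) | the two calibration moments |
| $\tau$ (refractory) | post-move immobility | years | — | rival model's single extra parameter |
| `n_scan` | root-scan density | points | $10^4$ | resolves both roots of the two-solution regime |
| row-sum tolerance | kernel validation | — | $10^{-9}$ | renormalisation allowed at construction only |

The default $\alpha = 0.9$ reflects the renter/owner reading of the two
components: roughly one household in ten is highly mobile. The calibrated
pair at Sydney-like shares ($s_1 = 0.91$, $s_5 = 0.73$, $\alpha = 0.95$)
is $\epsilon_1 \approx 0.051$, $\epsilon_2 \approx 0.825$ — slow majority,
fast minority.

## Calibration numerics

Substituting $a = 1-\epsilon_1$, $b(a) = (s_1 - \alpha a)/(1-\alpha)$
reduces the two-moment system to the scalar quintic
$f(a) = \alpha a^5 + (1-\alpha)b(a)^5 - s_5 = 0$ on the feasible interval
$[\max(0, (s_1-(1-\alpha))/\alpha),\ \min(1, s_1/\alpha)]$ (where both
$a, b \in [0,1]$). Roots are located by a dense $10^4$-point sign scan and
refined by bisection to $10^{-12}$ in $a$; every reported root must satisfy
both original equations to $10^{-10}$, which the tests enforce as a
contract. A derivative-free scan was chosen deliberately: in the
two-solution regime the quintic has two nearby simple roots, and
Newton-type iterations can jump basins.

Two numerical edge cases get special treatment:

* **Tangent roots.** On the boundary between the two-solution and
  no-solution regimes — including the exact degenerate case
  $s_5 = s_1^5$, whose only root is $\epsilon_1=\epsilon_2=1-s_1$ — $f$
  touches zero at an extremum without changing sign. The scan therefore
  also refines interior extrema with $|f| < 10^{-6}$ by golden-section
  search and accepts them when $|f| < 10^{-10}$. A double root is
  ill-conditioned by nature (a $10^{-16}$ perturbation of $s_5$ moves it
  by $\sim 10^{-8}$), so tests assert it only to $10^{-5}$.
* **Root bookkeeping.** Each root is an *ordered* pair: $\epsilon_1$
  belongs to the $\alpha$ share. Fits at $\alpha$ and $1-\alpha$ are
  mirror images, and the primary reported root is the one with
  $\epsilon_1 \le \epsilon_2$ (component 1 = slow, "stayer-like" group)
  when such a root exists. An empty admissible root set is returned as
  `n_solutions = 0`, not an error, so solution-count maps can be drawn.

$\alpha$ is never estimated: with only two window lengths the system is
underdetermined in three unknowns. The solution-count map
(`count_solutions()`) reports computed existence/uniqueness regions rather
than fixed printed boundaries; at Sydney-like shares the scan finds roots
in slightly wider $\alpha$ ranges than the commonly quoted symmetric
bands, and the computed map is treated as authoritative.

## Equilibrium computation

`stationary_distribution()` uses a dual route:

* **Primitive matrices** (some power strictly positive, checked on the
  boolean support pattern up to exponent $N$, entries $> 10^{-15}$ counted
  positive): LAPACK eigendecomposition of $P^\top$, eigenvalue nearest 1,
  real part taken, scaled to $\bar x$. The residual
  $\|X_{eq}P - X_{eq}\|_\infty$ must pass $10^{-8}$.
* **Non-primitive matrices** — periodic chains (a two-zone swap kernel) or
  reducible ones (block kernels with absorbing destination sets): the
  result is *flagged* (`is_unique = FALSE`) rather than rejected, and the
  vector is computed by damped power iteration on $(P+I)/2$, which has the
  same unit-eigenvalue left eigenvectors but is aperiodic. From the
  uniform start this picks a canonical member of the dominant eigenspace.

The test suite cross-checks the eigen route against an independent
long power iteration (with a Cesàro average, so it is also valid for
periodic chains) on random kernels up to $N = 50$ at $10^{-8}$.

## Relaxation diagnostics

With $U(t) = X(t) - X_{eq}$ and $Q(t) = X(t+1) - X(t)$, the transport law
$Q = UL$, $L = P - I = -\epsilon(I-H)$ implies geometric decay of the
driving force at the second-largest eigenvalue modulus.
`relaxation_diagnostics()` fits the slope of $\log\|U(t)\|$ over a tail
window (default: the last half of the trace, configurable) by ordinary
least squares and compares it with $\log|\lambda_2(P)|$.

Choices made where the theory leaves latitude:

* **Norm.** Euclidean by default, $L_1$ optionally; the asymptotic slope
  does not depend on the choice, the pre-asymptotic transient does.
  Reported norms are normalised by the component total $\alpha_k \bar x$,
  a display convention that leaves slopes unchanged.
* **Which matrix's spectrum.** For a mixture, per-component traces are
  analysed against $\lambda_2(P_k)$ — the summed trace is not Markov. The
  kernel's and the component's eigenvalues are linked by
  $\lambda(P_k) = 1 - \epsilon_k(1-\lambda(H))$; the package exposes
  $|\lambda_2(P_k)|$ and orders eigenvalues by modulus, so complex pairs
  are handled.
* **Degenerate inputs.** Traces shorter than 5 steps, non-primitive
  models, and traces already at equilibrium ($\|U\| < 10^{-12}\bar x$
  across the window) are rejected with specific errors: a slope fitted to
  noise is worse than no slope.

On the 99-zone linear city at $\epsilon = 0.2$ the fitted slope matches
the spectral one within 2% over the window $t \in [20, 60]$; for the
symmetric two-zone chain the identity $\|Q\|/\|U\| = 2\epsilon$ holds at
every step and is tested exactly.

## The refractory (immobility) rival model

A natural competing explanation for the five-year gap is that people
simply do not move again soon after moving. The package implements it as
a renewal chain over age-since-last-move states $0..\tau$: ages below
$\tau$ cannot move; at age $\ge \tau$ the annual hazard is $q$. The
stationary age distribution is $\pi_i \propto q$ for $i < \tau$ and
$\pi_\tau \propto 1$, and calibrating the stationary one-year stayer
share to $s_1$ gives $q = (1-s_1)/(1-\tau(1-s_1))$, feasible only for
$\tau \le s_1/(1-s_1)$. Window stayer probabilities come from powers of
the transition matrix restricted to no-move paths. At $\tau = 0$ the model
collapses to $s_1^t$ exactly.

The construction makes the qualitative conclusion transparent: forcing the
refractory ages to hazard zero pushes the movers' hazard *above* $1-s_1$,
so the model's five-year stayer share falls **below** $s_1^5$ for every
$\tau \ge 1$ — it widens the gap it was meant to close, which is the
argument for population heterogeneity. Because this model was rebuilt
from its verbal description, its correctness authority is an independent
agent-based Monte-Carlo simulation (stationary initialisation) kept in
the test helpers; the analytic shares must agree with it within three
Monte-Carlo standard errors ($2\times 10^5$ agents in the unit tests,
$10^6$ in the acceptance suite).

## Synthetic cities: what they emulate, and what not

The generators reproduce the standard stress tests for the
aggregate-kernel approximation:

* **Linear city** (99 zones on a line, centre at 50, decay $\beta = 0.1$
  per zone): centre-seeking kernel $h_{1;ij} \propto e^{-\beta d_j}$ and
  periphery-seeking $h_{2;ij} \propto e^{+\beta d_j}$, destination-
  normalised. In the exponential form with origin-dependent weights the
  origin factor cancels, so rows are identical and each kernel is rank
  one; we normalise over destinations explicitly, since the alternative
  origin-indexed normaliser does not produce a row-stochastic matrix. A
  consequence worth noting: for rank-one kernels the aggregate-kernel
  equilibrium is *exact*, because the stationary vector of
  $\hat H = \sum_k \alpha_k H_k$ is literally the mixture of the rows.
  The toy city is therefore the friendliest possible case for the
  approximation, and the block cities below are the harder one.
* **Block city**: $H_1$ positive exactly on a destination column set $A$
  (uniform random entries, rows normalised), $H_2$ on the complement.
  These kernels are reducible; their stationary vectors live on $A$ and
  its complement respectively, which the tests check as a support
  property. Generation is deterministic under a seed and restores the
  caller's RNG state.
* **Kernel split**: the exact decomposition $\alpha H_1 + (1-\alpha)H_2 =
  H$ routing component 1 into a destination set as far as observed flows
  allow (branching on $a_i \le \alpha$ vs $a_i > \alpha$, where $a_i$ is
  row $i$'s flow share into the set). The recombination identity, row
  sums and nonnegativity are enforced to $10^{-12}$ on random inputs.

Toy kernels keep positive diagonals (a "move" may end in the starting
zone), whereas kernels estimated from flow tables have structurally zero
diagonals; the `zero_diagonal` flag records which convention an object
follows and the two are never silently mixed.

What the synthetic cities do **not** emulate: real flow tables' sampling
noise and zero-inflation, zone-size heterogeneity, temporal drift of $P$,
and within-zone moves recorded separately from stays. Passing tests on
toy cities therefore validate the algebra and the numerics, not the
adequacy of the time-homogeneous closed-system assumptions for any
particular data set.

## Other design decisions

* **Stayer shares** over zones of unequal size are population-weighted
  when weights are supplied, plain means otherwise; both are exposed
  because "average share over suburbs" is ambiguous without a weighting
  convention.
* **Zero-outflow origins** in kernel estimation raise an error by
  default; uniform imputation over the other $N-1$ zones exists as an
  explicit opt-in policy with a warning, never silently.
* **Detailed balance** ($x_i p_{ij} = x_j p_{ji}$ at equilibrium) holds
  only for reversible chains and is *not* implied by stationarity, so the
  package tests stationarity of marginals and leaves pairwise flow
  symmetry to the `net_flow()` diagnostic.
* **Matrix powers** are computed by repeated multiplication, not
  eigendecomposition: horizons are small integers and bit-stable results
  matter more than asymptotic speed.
* **CSV numerics** are written with 17 significant digits so that
  write/read round-trips are bit-exact; zone ordering follows the input
  and is never silently sorted.

## Problem sizes

The test suite uses cities of 2–99 zones, trajectories up to $10^3$
steps, $10^4$-point calibration scans across share grids, and a single
$10^6$-agent Monte-Carlo run; the full suite completes in seconds on one
CPU. These sizes were chosen as the smallest at which every asymptotic
claim (spectral slopes, mixture convergence at $10^{-6}$, Monte-Carlo
agreement at three standard errors) is comfortably inside its tolerance.

## Known limitations

* $\alpha$ is an input; with only two window lengths the mixture is not
  identifiable, and with more than two genuine mobility classes a
  two-component fit misattributes mass.
* The equilibrium forecast inherits the constancy-of-$P$ assumption;
  structural breaks (rezoning, housing shocks) invalidate it.
* Periodic or reducible kernels yield flagged, convention-dependent
  stationary vectors (uniform-start power iteration); any other member of
  the dominant eigenspace is equally stationary.
* No continuous-time limit and no sub-annual dynamics.
* No geographic machinery: destination sets and distances are supplied
  explicitly, never derived from coordinates.
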