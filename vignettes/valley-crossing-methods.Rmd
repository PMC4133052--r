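---
title: "Methods: crossing fitness valleys and plateaus in subdivided populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossing fitness valleys and plateaus in subdivided populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valleycross)
```

## The model

An asexual population evolves on the minimal rugged landscape: three
genotypes `0 -> 1 -> 2` with fitnesses $f_0 = 1$, $f_1 = 1 - \delta$ and
$f_2 = 1 + s$, $s > 0$. The intermediate may be deleterious
($\delta > 0$, a fitness *valley*), neutral ($\delta = 0$, a *plateau*),
or weakly beneficial ($\delta < 0$). Mutations are forward-only and occur
with probability $\mu$ per division. The population is subdivided into
$D$ demes. Each individual divides at rate $f_i\,(1 - N_d/K)$ — logistic
growth with carrying capacity $K$ — and dies at rate $g$, so a deme
fluctuates around the equilibrium occupancy $N = K\,(1 - g/\bar f)$.
Migration is a random exchange of two individuals between two uniformly
chosen demes; each individual changes deme at rate $m$, so migration
events occur at total rate $M_{\mathrm{tot}} = m N D / 2$ (the factor 2
is a documented convention constant, `migration_factor`, because one
event relocates two individuals; every window bound carries it
symbolically). The quantity of interest is the mean time $\tau$ for the
*whole* metapopulation to fix genotype `2`, starting from all-`0`.

All analytic machinery assumes $m \ll g$ (a migrant's fate within a deme
is resolved before the next exchange) and $N\mu \ll 1$ (no competition
between concurrent mutant lineages; the large-mutation-supply
"semi-deterministic" regime is deliberately out of scope and flagged,
not modelled). `validate_model()` recomputes these flags from the specs
on every call.

## Single-deme theory

**Fixation.** The probability that a single mutant of fitness $f_j$
fixes among $N-1$ residents of fitness $f_i$ is the Moran result
$$\rho_{ij} = \frac{1 - f_i/f_j}{1 - (f_i/f_j)^N},$$
implemented on $x=\log(f_j/f_i)$ with `expm1` so the neutral limit
$1/N$ is approached continuously to machine precision, with a log-space
branch once $(f_i/f_j)^N$ would overflow. The detailed-balance identity
$\rho_{ij}/\rho_{ji} = (f_j/f_i)^{N-1}$ holds exactly in this
parameterisation and is enforced to $10^{-10}$ in the tests.

**Sequential fixation.** Small demes cross in two steps: mutation `1`
fixes at rate $r_1 = N \mu g\, \rho_{01}$ ($N\mu g$ is the mutation
supply per unit time, since each individual turns over at rate $g$),
then mutation `2` fixes at rate $r_2 = N \mu g\, \rho_{12}$. The
crossing time is hypoexponential with mean $1/r_1 + 1/r_2$.

**Tunneling.** Large populations cross without the intermediate ever
fixing: a `1`-lineage of transient mutants produces a `2` that
establishes. This is a single event of rate $N \mu g\, p_1$ with the
branching-process success probability
$$p_1 = \tfrac{1}{2}\left(-\delta + \sqrt{\delta^2 + 4 \mu s_{\rm est}}\right),$$
which reduces to $\sqrt{\mu s_{\rm est}}$ on a plateau and to
$\mu s_{\rm est}/\delta$ for deep valleys. The establishment probability
of genotype `2` uses $s_{\rm est} = s/(1+s)$ (continuous-time branching
result) rather than $s$; the difference is $O(s^2)$ and the choice is
user-overridable. `classify_regime()` compares the two mean times and
locates the threshold size $N^\*$ by bisection in $\log N$ — we do not
assume closed forms for the threshold, which keeps the classification
robust to regime-boundary prefactors.

**The champion deme.** With $D$ quasi-independent demes, the
metapopulation is at best driven by the *champion* — the first deme to
cross. Its mean crossing time is the mean of the minimum of $D$
i.i.d. hypoexponential variables, computed by adaptive quadrature of
$S(t)^D$ (relative tolerance $10^{-8}$; stable equal-rates branch). When
$r_2/r_1 > 50$ and $D \le r_2/r_1$ the exponential order-statistic
identity $1/(D r_1)$ is used instead — the champion crosses $D$ times
faster than an average isolated deme. For very large $D$ the second
step limits the champion and the quadrature path is always taken.

## The migration Markov chain

Between mutations, the number $k$ of demes fixed for a mutant genotype
changes only through migration. An exchange is *relevant* with
probability $q(k) = k(D-k)/\binom{D}{2}$, and a relevant exchange
increases $k$ with probability $\rho_{\rm up}(1-\rho_{\rm down})$,
decreases it with $\rho_{\rm down}(1-\rho_{\rm up})$. This yields a
tri-diagonal absorbing chain on $k \in \{0,\dots,D\}$ whose steps are
migration events. Absorption probabilities and conditional expected step
counts are computed two independent ways: closed forms built from the
cumulative ratio products $\gamma_j$ (always evaluated in log space,
because deep valleys make $\rho_{\rm down}/\rho_{\rm up}$ span hundreds
of orders of magnitude), and a tri-diagonal linear solve of the embedded
jump chain, done with a Thomas algorithm in extended precision. The two
routes must agree to $10^{-10}$ wherever the solve is well conditioned
(absorption probabilities above $\sim 10^{-4}$; rarer outcomes are
outside the reach of double-precision solves and only the log-space
closed form applies).

Two conditional expectations follow, both started from $k = 1$:

* $n_e$ — migration events until a single `1`-fixed deme is wiped out
  (chain with $\rho_{\rm up} = \rho_{01}$, $\rho_{\rm down} =
  \rho_{10}$), conditional on extinction. Simplified estimate
  $1/(q(1)\rho_{10}(1-\rho_{01}))$, valid when $\rho_{01} \ll \rho_{10}$.
* $n_f$ — migration events until a single `2`-fixed deme spreads to all
  $D$ (chain with $\rho_{02}$, $\rho_{20}$), conditional on spreading.
  Simplified estimate $\sum_k 1/(q(k)\rho_{02})$, valid for $1/N \ll s$.

The conditional (not unconditional) definition is the default; both are
exposed. The general chain values matter because subdivision is
typically most beneficial at intermediate $N\delta$, where the
simplified forms start to err.

## The optimal migration window

Subdivision is maximally effective when demes cross quasi-independently
*and* the winning mutation spreads quickly:

1. **Quasi-independence.** A `1`-fixed deme must fix mutation `2`
   (time $\tau_{\rm fix2} = 1/(N\mu g \rho_{12})$) before migration
   wipes it out (time $\tau_e = n_e/M_{\rm tot}$), giving
   $m/\mu < 2 g \rho_{12} n_e / D$.
2. **Rapid spreading.** The spreading time
   $\tau_s = n_f/M_{\rm tot}$ must beat the champion crossing time
   $\tau_f$, giving $m/\mu > 2 n_f/(N D \mu \tau_f)$.

Both bounds are assembled symbolically from these two inequalities with
the chain-based $n_e$, $n_f$ and the quadrature $\tau_f$ (the
`_approx` variants use the simplified estimates). Inside the window the
metapopulation crosses about as fast as its champion deme,
$\tau \approx \tau_{\rm deme}/D$; the width ratio
$R = (m/\mu)_{\max}/(m/\mu)_{\min}$ grows exponentially with $N$ for
deep valleys. Since demes must stay in the sequential-fixation regime
($N < N^\*$) for any of this to help, the widest achievable window is
$R$ evaluated just below $N^\*$ (`window_ratio_bound()`).

A useful rule of thumb, used to size the validation experiments: at the
geometric centre of the window the extinction and spreading overheads
are each $\sim 1/\sqrt{R}$ of the champion time, so the achieved
crossing time exceeds the ideal champion time by a factor of roughly
$1 + 2/\sqrt{R}$. Tight agreement with the best scenario therefore
requires $R \gtrsim 10^2$, and scenarios with $R \sim 30$ are expected
to land some tens of percent above $\tau_f$.

**Speedups.** When demes fix sequentially while the pooled population of
$ND$ individuals tunnels, the best-scenario ratio of metapopulation to
non-subdivided crossing time is $p_1/\rho_{01} < 1$; on a plateau this
is $N\sqrt{\mu s_{\rm est}}$, and its deep-valley analogue
$(\mu s_{\rm est}/\delta^2)e^{N\delta}$ is minimised at
$\delta^\* = 2/N$ with minimum $e^2 \mu s_{\rm est} N^2/4$
(`optimal_valley_depth()` minimises this deep-valley form numerically
and cross-checks the analytic stationary point; a correction term
$(1-e^{-N\delta})$ would move the stationary point to
$N\delta \approx 1.6$ and is deliberately not included, keeping the
reported optimum the deep-valley one). If isolated demes themselves
tunnel, subdivision cannot help: tunneling times are inversely
proportional to population size, so the champion gains exactly the
factor the non-subdivided population already has.

**Islands.** The hub-and-spoke variant couples one large population to
$C$ small islands; each migration event involves the hub and a uniformly
chosen island, at total rate $m_I$. The same two conditions give bounds
on $m_I/\mu$ with $\rho_{\rm ext}$ (a wild-type migrant fixing among
island intermediates) in the shielding condition and
$\rho_{02}^{(N_{\rm large})}$ in the spreading condition, the champion
factor now being $C$.

## The simulator

`simulate_crossing()` is an exact Gillespie algorithm: waiting times are
exponential in the total rate and events are chosen proportionally to
their rates, with per-deme aggregate division rates maintained
incrementally (periodically refreshed to cancel floating-point drift)
and compiled inner loops. Migration picks two distinct demes uniformly,
one uniform individual from each, and swaps them; an exchange involving
an empty deme, or two individuals of the same genotype, is counted as a
no-op event rather than resampled. Division rates clamp at zero when a
deme exceeds its carrying capacity. Every run starts from all demes
monomorphic `0` at equilibrium occupancy (overridable), and ends at
crossing, at `t_max` (explicit censoring), or on metapopulation
extinction (reported, never silently retried). Replicates draw child
seeds deterministically from a base seed, so results are reproducible
bit for bit; the hot loop uses a xoshiro256++ generator seeded from R's
RNG stream, so `set.seed()` governs everything.

`simulate_fixed_N()` implements the alternative fixed-size scheme used
for cross-validation: per-deme Moran replacement events at rate $N g$
(divider chosen by fitness, a uniform individual removed), identical
mutation and migration semantics. It is valid when migration is much
rarer than replacement ($m \ll g$; a warning fires otherwise).

## Study conditions for the validation experiments

The test-suite experiments run at reduced scale so that complete
crossing-time distributions are measurable in minutes on one CPU.
Scaling down means raising $\mu$ to $10^{-4}$–$10^{-3}$ and shrinking
demes to $N \sim 20$–$600$ while preserving the regime structure each
check probes (sequential margin $\rho_{01}/p_1 \gtrsim 3$, window ratio
$R > 10$, $N\mu \lesssim 0.2$, $m \ll g$). The main conditions are:

* *Regime transition*: plateau, $s = 0.1$, $\mu = 3\times10^{-4}$,
  $N = 36$–$576$ spanning $N^\* \approx 180$; 120 replicates per size.
* *Migration window*: valley $\delta = 0.2$, $s = 0.3$,
  $\mu = 3\times10^{-4}$, $N = 24$, $D = 4$, giving $R \approx 34$;
  a log grid across the window plus points a factor 3 outside.
* *Degree of subdivision*: valley $\delta = 0.08$, total capacity 640,
  $D = 4$–$64$ at fixed per-individual migration rate.
* *Islands*: valley islands $N_{\rm island} = 24$, $C = 6$, hub
  $N_{\rm large} = 100$ (hub tunnels slowly; champion island wins).

Two systematic effects at this scale are worth recording. First, the
two-rate theory ignores fixation sojourns (a successful lineage takes
$O(N/g)$ time units to sweep a deme), which add a few percent to
simulated times once crossing times drop below $\sim 10^4$ time units;
tolerances of the affected checks (factor 1.5 on regime tracking, 3–3.5
standard errors elsewhere) absorb this. Second, under the
carrying-capacity scheme the deme size fluctuates, and because
$\rho_{01} \sim \delta e^{-N\delta}$ is convex in $N$, fluctuations
*accelerate* deep-valley crossing by roughly $e^{N\delta^2/2}$ — about
1.6 at $N = 24$, $\delta = 0.2$, yet negligible at the large-$N$,
small-$\delta$ parameter sets the fixed-$N$ theory is usually applied
to. Checks that compare simulated crossing times against fixed-$N$
predictions at tight tolerance therefore use the fixed-size scheme
(legitimate here since $m \ll g$), while the carrying-capacity scheme is
validated against theory on plateaus (where $\rho_{01} = 1/N$ carries no
such convexity) and against the fixed-size scheme directly at low
migration. Passing these scaled-down checks shows the machinery is
internally consistent in every regime it models; it does not by itself
demonstrate behaviour at experimentally realistic mutation rates
($\mu \sim 10^{-10}$), where the same formulas predict far wider windows
($R$ of several orders of magnitude) but simulation is out of reach.

## Numerical choices

* Near-neutral fixation probabilities via `expm1` on log fitness
  ratios; overflow branch for $Nx < -700$.
* Chain closed forms in log space throughout; linear-solve cross-check
  via extended-precision Thomas algorithm on the embedded jump chain
  (the raw transition matrix is self-loop dominated and catastrophically
  cancels); hard `numerical_instability` error if routes disagree.
* Migrant fixation probabilities that underflow double precision are
  floored at the smallest normal double rather than zero so log-space
  products stay defined.
* Champion quadrature: `integrate` on $(0,\infty)$ after rescaling time
  by $r_1$, relative tolerance $10^{-8}$; fast-path switch at rate ratio
  50 (configurable).
* $\delta^\*$ search by Brent's method on $\log$ of the objective over
  $(10^{-8}, 1)$, cross-checked on a grid.
* Degenerate inputs: $\mu = 0$ is accepted by the simulator (runs are
  censored or, on request, stop at monomorphism for fixation
  experiments) but rejected by the crossing-time theory; $D = 1$ yields
  a "window not applicable" result rather than an error.

## Known limitations

Three genotypes and forward mutations only; no recombination, no deme
extinction/recolonisation, no fitness-dependent migration, no spatial
structure beyond the two topologies; genotype-independent death rate;
the semi-deterministic large-$N\mu$ regime is refused rather than
modelled. The default death rate $g = 0.1$ is a configuration default
(crossing times simply scale as $1/g$ at fixed fitnesses of order one)
and is overridable everywhere.
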