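---
title: "Methods: chaotic coexistence of temperate and obligate lytic phage"
author: "lysochaos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaotic coexistence of temperate and obligate lytic phage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`lysochaos` simulates communities of bacteriophage strains preying on a
single bacterial species through their lysogens. Strains are organised into
superinfection-immunity classes $c = 1, \dots, N_c$: a lysogen carrying a
prophage of class $c$ is immune to every phage of that class but can be
lysed by phage of any other class. Within a class, strains are
distinguished by their lysogeny fraction $f \in [0, 1]$, the fixed
probability that an infection lysogenizes rather than lyses the host.
Strains with $f = 0$ are obligate lytic and have no lysogens.

The state is the set of free-phage densities $P_{cf}$ and lysogen
densities $L_{cf}$ (for $f > 0$), with class totals
$L_c = \sum_f L_{cf}$. They evolve as

$$\frac{dP_{cf}}{dt} = b\gamma L_{cf}
  - \Big(\delta + k \sum_{c'} L_{c'}\Big) P_{cf}
  + k b (1-f) P_{cf} \sum_{c' \neq c} L_{c'},$$

$$\frac{dL_{cf}}{dt} = (\alpha - \gamma) L_{cf}
  - k L_{cf} \sum_{c' \neq c} \sum_{f'} (1-f') P_{c'f'}.$$

The three phage terms are induction of the strain's own lysogens
(burst size $b$, induction rate $\gamma$), death/outflow plus adsorption
to any lysogen (immune lysogens soak up phage without being lysed), and
growth through lysis of other-class lysogens. Lysogens grow at $\alpha$,
are lost to induction, and are killed by the lytic fraction of other-class
phage. Key simplifications: sensitive (non-lysogenic) bacteria are
negligible, double lysogens are disallowed, and lysis is instantaneous —
each of these is relaxed by an explicit extension (below). Bacteria are
limited by phage predation, not by resources, so a community without
cross-class predation (e.g. a single immunity class) grows without bound.

Two closed forms anchor the analysis. Setting $dP/dt = 0$ for a fully
dormant strain ($f = 1$) gives the homeostatic phage-to-lysogen ratio
$P^*/L = b\gamma/(k L + \delta)$, and its prey-free simplification
$b\gamma/\delta$: when a temperate strain's $P/L$ ratio dips below this
floor, induction restores it. Setting $dP/dt = dL/dt = 0$ in the symmetric
community ($N_c$ equivalent single-strain classes) gives the fixed point
$P^{ss} = (\alpha-\gamma) / (k (N_c - 1)(1-f))$, with the lysogen density
following from the linear phage balance ([`symmetric_fixed_point()`]).
The chaotic attractor never settles there, but time-averaged phage
densities track $P^{ss}$ closely.

## Parameters and units

Time is measured in bacterial generations: $\alpha = 1$ means lysogens
double on the unit timescale, and "2000 generations" means $t \in
[0, 2000]$. The alternative convention $\alpha = \ln 2$ would only rescale
time. Densities are per unit volume (think cells/mL with
$k$ in mL cell$^{-1}$ gen$^{-1}$). Substituting $P \to kP$, $L \to kL$
eliminates $k$ from the equations entirely, so $k$ fixes the density
scale while the dynamical regime is set by $(\alpha, \gamma, \delta, b)$
alone.

Package defaults (`default_parameters()`):

| parameter | value | meaning |
|---|---|---|
| `alpha` | 1 | lysogen growth rate (1/generation) |
| `gamma` | 1e-3 | spontaneous induction rate (1/generation) |
| `delta` | 1 | phage death/outflow rate (1/generation) |
| `k` | 1e-9 | adsorption rate (volume cell$^{-1}$ gen$^{-1}$) |
| `b` | 10 | burst size |

These were chosen once, as the package's study conditions, to sit well
inside the chaotic regime while reproducing the model's characteristic
quantitative behaviour, and are not tuned per experiment:

* a scan of $(\gamma, \delta, b)$ showed sustained chaos for the
  three-class temperate community over a broad region with
  $\gamma \lesssim 10^{-3}$; at $\gamma = 10^{-2}$ the symmetric system
  spirals into its fixed point. The chosen point gives a largest Lyapunov
  exponent of $\approx +0.05$ to $+0.08$ per generation at $N_c = 3$.
* with the defaults, the prey-free floor estimate $b\gamma/\delta$
  overestimates the trough $P/L$ ratios of temperate strains by a factor
  of about 2 (median $\approx 2.1$ over the standard twelve-strain
  scenario), while $P/L$ itself spans up to $\sim 9$ decades within a run.
* the small burst size makes boom-bust cycles violent enough that in a
  two-class community the obligate lytic strain usually — but not always —
  fluctuates below any realistic extinction threshold, and population
  minima then *rise* as more immunity classes are added.

Spontaneous induction rates of order $10^{-3}$ per generation and
effective burst sizes of order 10 are within the range reported for
temperate phage under unfavourable growth conditions; the fixed-point
densities land at $10^8$–$10^9$ per volume, a typical chemostat scale.

Scenario communities use a default temperate lysogeny fraction of
$f = 0.3$ (a moderate propensity; the twelve-strain "bunching" scenario
instead uses the declared set $\{0, 0.1, 0.5, 0.9\}$ per class). All of
these are arguments, not constants.

## Integration

The equations are integrated in log-density coordinates
($x = \ln P$, $y = \ln L$), which guarantees positivity and resolves the
nine-plus decades separating booms from troughs — the troughs being the
scientifically relevant feature. The right-hand sides are compiled C
called directly by `deSolve` (`lsoda` by default; the finite-lysis-time
variant uses fixed-order BDF (`vode`), whose error control handles the
added fast relaxation mode more robustly; runs with density bounds use
the root-finding `lsodar`, or `radau` when combined with finite lysis
time). Defaults: `rtol = 1e-8`, `atol = 1e-10` in log space, output every
0.1 generation. Exact zeros in initial conditions are padded to a floor
of $10^{-30}$ before the log transform.

Inflow-dominated compartments (double lysogens, exposed cells) have
log-slopes `inflow/density` that can overflow when a compartment sits
hundreds of decades below its inflow scale; these slopes are capped at
$10^{12}$/generation, which only bounds the (unresolvably fast) recovery
from such depths and never binds in the resolved dynamics, where rates
stay below $\sim 10^2$/generation.

Optional density bounds (`stop_below`, `stop_above`) terminate a run via
the solver's root finder once any population leaves them. They exist for
communities whose outcome is decided while some component diverges: a
single-immunity-class community has no predation on its lysogens, which
then grow without bound, and competition experiments routinely send the
loser to absurd depths.

Initial conditions are drawn log-uniformly over $10^6$–$10^9$ per volume
by default (several decades around the fixed-point scale), one seed per
run, with an option to tie within-class lysogen densities (whose ratios
are conserved by the dynamics — see below).

## Analyses

**Extinction.** The ODE never reaches zero; extinction is an
interpretation. The default threshold is $10^{-3}$ per volume — less than
one organism per litre when densities are per mL — applied to the
post-transient window (the first 20% of each run is discarded unless a
window is given). The class-number sweep additionally mirrors the
convention of excluding two-class runs whose obligate lytic strain
fluctuated to extinction, using a scale-based cut of $10^{-6} P^{ss}$ for
that purpose.

**Outcome labels.** A summarized run is `extinction(...)` if any strain's
minimum fell below threshold, `fixed-point` if the Lyapunov estimate is
non-positive and the densities stopped moving (relative drift
$< 10^{-4}$ over the last tenth of the window), else `coexistence`.

**Lyapunov exponent.** Two-trajectory Benettin estimate in log space: a
copy of the state is displaced by $10^{-8}$ (log units), both copies are
integrated together, and the separation is renormalized every generation;
the estimate is the mean per-block divergence rate, with a standard error
across blocks (correlated blocks, so a scale rather than a strict CI).
Chaotic runs use a 200-generation transient and a 500-generation horizon;
the estimate is insensitive to doubling the renormalization interval.
Prey-free control communities grow without bound and are measured over
short horizons from unit-scale densities instead.

**Troughs and bunching.** Local minima of $\log_{10}(P/L)$ with a
prominence of at least 0.5 decades count as troughs (robust to grid
wiggle). `trough_floor_gap()` reports each temperate strain's global
minimum ratio as a fold-gap below $b\gamma/\delta$, and the cross-strain
spread of $P/L$ at the common troughs of each class. At the deep troughs
the spread collapses to order one while the ratios range over
$10^6$–$10^9$ within the run.

**Averages.** Time averages use trapezoidal integration on the output
grid, so they are insensitive to the grid spacing.

## Conserved within-class structure

The lysogen equation does not involve the strain's own $f$, so all
lysogens of one class share the same per-capita growth: the ratios
$L_{cf}/L_{cf'}$ are exact invariants of the flow. The integrator
preserves them to $\sim 10^{-13}$ relative over 2000 generations (the
identical right-hand sides make the numerical error common mode). Two
consequences: (i) initialising within-class lysogens equal keeps them
equal forever; (ii) any heterogeneity in $\alpha$ or $\gamma$ *within* a
class turns this neutral direction into plain exponential competitive
exclusion among the class's lysogens — which is why the heterogeneity
robustness experiments on multi-strain classes jitter the phage traits
($\delta$, $k$, $b$) and leave growth rates shared.

## Scenarios

`scenario()` enumerates the standard experiments: the two-strain
competitions (`pairwise_same_class`, `pairwise_diff_class`), the minimal
chaotic community (`temperate_chaos_Nc3`), the invasion of an obligate
lytic strain into one class of that community (`lytic_invasion`, run
alongside its no-lytic baseline; the invader starts at $t = 0$ from the
same log-uniform draw as everyone else, since a mid-run injection
protocol would add an arbitrary choice — an injection can still be set up
manually with `simulate_community(t_start = ...)`), the twelve-strain
bunching community (`multistrain_bunching`), and a six-class community
(`temperate_Nc6`). `run_nc_sweep()` competes $N_c - 1$ single-temperate
classes against one two-strain (lytic + temperate) class across
$N_c = 2, \dots, 6$.

Two structural facts about the pairwise competitions are worth stating
plainly. In the same-class pair the lytic strain has no prey at all
(its only potential host is immune), so it washes out at rate
$\geq \delta$: the temperate strain always wins. In the different-class
pair the system reduces exactly to the classic two-species
Lotka–Volterra model ($dP_1 = k(b-1)P_1 L_2 - \delta P_1$,
$dL_2 = (\alpha-\gamma)L_2 - k L_2 P_1$, with the temperate phage slaved
to its lysogen): the orbits are neutral closed cycles with a conserved
invariant, so whether a population ever crosses an extinction threshold
is decided entirely by the initial displacement from the fixed point,
not by the dynamics. Under the default initial range the cycles stay
clear of the threshold and the pair coexists indefinitely on a neutral
orbit. We deliberately report this as `coexistence` rather than forcing
the expected extinction: it is a real — if structurally fragile —
property of the exact simplified model.

## Model extensions

All extensions share the integrator and analytics and reduce *exactly*
(to $10^{-12}$ relative, tested) to the core model when their knobs are
zeroed; since the reference equations for the fuller models are not part
of the package's sources, this reduction property is the correctness
anchor, and each mechanism below is a declared design choice.

**Sensitive bacteria** ($S$): grow exponentially at $\alpha$, adsorb
every phage (lysogenized with probability $f$ into $L_{cf}$, lysed
otherwise). Under the defaults total phage pressure exceeds $\alpha$
almost always, so $S$ collapses and the community behaves like the core
model plus a transient.

**Double lysogens** ($D_{cc'}$, unordered class pairs): a single lysogen
of class $c$ infected by phage of class $c' \neq c$ is lysogenized with
probability $f'$, forming a double lysogen immune to both classes; doubles
grow at $\alpha$, induce either prophage at the lysogen-weighted class
induction rate (bursting the corresponding class's strains in proportion
to their single-lysogen shares), and are lysed by third classes; triple
lysogens are disallowed. This mechanism has a structural consequence:
single lysogens face lytic pressure from $N_c - 1$ classes but doubles
only from $N_c - 2$, and with purely exponential growth both balances
cannot hold simultaneously, so doubles progressively displace singles
regardless of the formation rate. Temperate phage then persist through
double-lysogen induction, but obligate lytic strains lose most of their
prey base and decline. Chaos itself (a positive Lyapunov exponent)
persists.

**Finite lysis time** ($\tau$): every lysis event (induction or lytic
infection) routes through an exposed compartment that matures to a burst
at rate $1/\tau$. As $\tau \to 0$ trajectories converge to the
instantaneous model (tested at $\tau = 10^{-3}$, and linearly in $\tau$
on chaotic communities, where any model difference is also amplified at
the Lyapunov rate). At $\tau = 0.1$ generations the lag extends the
decline phases and deepens troughs by orders of magnitude, driving
populations below any fixed threshold.

**Coinfection-induced lysogeny** ($\kappa$): the effective lysogeny
fraction rises with instantaneous phage pressure,
$f_{\mathrm{eff}} = 1 - (1-f)/(1 + kP_{\mathrm{tot}}/\kappa)$ — equal to
$f$ at zero pressure, saturating at 1.

**Heterogeneity**: `jitter_parameters()` draws per-strain log-normal
multiplicative factors (median 1, spread = approximate CV), seeded.
All-parameter jitter of 20% on the single-strain-per-class chaotic
community leaves chaos and coexistence intact in most seeds; on
multi-strain classes see the conserved-structure caveat above.

## What the synthetic scenarios do and do not show

Every input is generated by the package itself: the scenarios *are* the
study conditions, with seeded log-uniform initial densities and the
default rate constants. They emulate a well-mixed, resource-unlimited
(phage-limited) chemostat with fixed strain strategies. They do not
emulate: resource limitation or bacterial carrying capacities, spatial
structure, demographic noise at low copy number (the ODE happily tracks
$10^{-40}$ of an organism — the extinction threshold is the analysis-side
correction), mutation or host-range evolution, or experimentally
calibrated rate constants for any particular phage. Passing tests
therefore demonstrate properties of the model under the declared
conditions, not predictions fitted to data.

## Problem sizes used by the tests

The automated checks run at desk scale, chosen so the full suite
completes in minutes while every ensemble remains large enough for its
statistic: trough statistics from 3 seeds × 2500 generations (the
acceptance script uses 8 seeds); the class-number sweep at 10 seeds ×
2000 generations per $N_c \in \{2,\dots,6\}$; Lyapunov estimates over
500-generation horizons after 200-generation transients; pairwise
competitions at 10 seeds; extension robustness at 3 seeds × 1500
generations. Full-scale ensembles (e.g. 50 seeds) are a single argument
change.

## Known limitations

* The different-class pairwise competition is structurally neutral (see
  above); any claim about its "winner" is threshold- and
  initial-condition-dependent.
* The extension mechanisms are package-declared; their long-run community
  composition (notably the double-lysogen takeover and the finite-lysis
  trough deepening) should be revisited against reference equations if
  those become available.
* The Lyapunov standard error underestimates uncertainty when divergence
  rates are strongly autocorrelated; treat it as a scale.
* `lsoda`'s step control occasionally needs the density bounds
  (`stop_below`/`stop_above`) in degenerate communities; these truncate
  trajectories rather than failing the run.
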