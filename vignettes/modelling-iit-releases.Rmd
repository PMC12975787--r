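---
title: "Modelling incompatible-insect-technique releases under bi-directional Wolbachia incompatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling incompatible-insect-technique releases under bi-directional Wolbachia incompatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iitsim)
```

## The problem

The incompatible insect technique (IIT) suppresses a mosquito population by
mass-releasing males whose *Wolbachia* infection is incompatible with the
resident females: incompatible matings produce no viable offspring.  For
*Aedes albopictus* the situation is unusual because the wild population
already carries its own double infection (here labelled `wAlbAB`), so a
release strain carrying a different infection (`ARwP`) is incompatible with
the wild type in *both* directions.  Bi-directional cytoplasmic
incompatibility (CI) cuts both ways: released males sterilise wild females,
but any accidentally released `ARwP` females are themselves sterilised by
wild males — unless those males are old enough that their CI has decayed.

`iitsim` implements this system as a continuous-time Markov population
process on integer compartments and uses it for two *in silico* studies:

1. **Cage trials** estimating the unstable equilibrium threshold
   $\omega^*$ — the initial `ARwP` proportion above which the released
   strain tends to establish rather than die out.
2. **Release-policy scenarios** (naive, complete stop, maintain) in an open
   patch with wild-type immigration, scored for suppression success,
   reversibility six months after releases end, and a released-insect cost
   proxy.

## State space and events

The state is a vector of non-negative integer counts:

* immature stages $I_{s,1..n}$ per strain $s$ (an Erlang chain of `immature_shape`
  stages gives a Gamma-distributed development time);
* adult males $M_{s,1..K}$ per strain and CI-age class ($K = 20$);
* unmated adult females $U_s$;
* mated females $F_{f \times m, c}$ indexed by the female's strain, her
  mate's strain, and the mate's CI-efficacy class *at mating* — the efficacy
  is frozen at that moment and CI-age classes with identical efficacy are
  collapsed into one compartment.

Events are: stage progression at rate $n/\bar\tau$ per stage; emergence from
the last stage as two competing channels (male / unmated female) at half the
stage rate each, which realises a per-individual Bernoulli(½) sex split;
male CI-class aging at rate $a$ (class $K$ absorbing); per-capita deaths
($\mu_M$ for males, $\mu_F$ for all female compartments); mating at total
rate $\eta$ per unmated female whenever any males are present, allocated
across male compartments with probability proportional to $\gamma_m M_{m,k}$
(Fried's index $\gamma$ weights a strain's mating competitiveness, so the
*allocation* tracks male abundance while the total rate does not); births
from each mated compartment at rate
$\lambda\,(1 - e)\,\max(0,\,1 - I_{\mathrm{tot}}/C)$
where $e$ is the frozen CI efficacy of the cross; and wild-type immigration
plus per-capita emigration from every adult compartment.  Offspring always
inherit the mother's strain (perfect maternal transmission); incompatibility
removes a fraction of births rather than converting them.

CI efficacy follows the age-decay profile of wild-type males: 100% through
class 14, 67% in classes 15–19, 0% at class 20.  The aging rate defaults to
$a = 1\,\mathrm{d}^{-1}$ so that class indices track days spent in a CI
state in distribution (each adult still has an exponentially distributed
lifespan; its CI state follows a death-truncated Erlang clock).  `ARwP`-male
incompatibility does not decay, same-strain crosses are fully compatible,
and *Wolbachia*-cleared males are compatible with every female.  Setting
`decay_enabled: false` makes every cross constant in class, which also
reduces the uni-directional arm to the classic IIT model in which only
cleared-female × infected-male crosses fail.

## Parameters

All rates are per day; defaults live in `inst/extdata/default.yaml`.

| parameter | default | meaning |
|---|---|---|
| `lambda_birth` | 0.24 | future adults per mated female per day, before density modification |
| `mu_M` | 0.125 | male death rate (8-day mean lifespan) |
| `mating_rate` ($\eta$) | 0.7 | per unmated female |
| `immature_mean_duration` | 17.5 d | mean egg-to-adult development time |
| `immature_shape` | 5 | Erlang stages of development |
| `ci_aging_rate` ($a$) | 1.0 | CI class progression |
| `feasibility_ratio` | 0.999 | target of the $\mu_F$ derivation (below) |
| `N0` | 420 | steady-state adults the capacity is calibrated to |
| `overflooding_ratio` | 5 | released males per current wild male |
| `contamination_rate` | 0.01 | female fraction of a release (Binomial draw) |
| `release_interval` | 7 d | release cadence |
| `omega_star` | 0.4 | unstable-equilibrium threshold used by policies |
| `suppression_fraction` | 0.10 | suppression cut (below 42 of 420 adults) |
| `migration_total` | 0 / 2 / 10 per week | study values |

The numeric fitness values are the package's own defaults for an urban-block
*Ae. albopictus* population, chosen once to satisfy the biological anchors
the model is built around: the derived female lifespan must fall in the 9–10
day range at feasibility ratio 0.999, development takes two to three weeks,
and males are shorter-lived than females.  The `low` and `high` sets bracket
them with faster/shorter and slower/longer life histories.  Strain fitness
multipliers default to 1 for every strain — the released strain's
reproductive advantage over the wild type then comes entirely from CI age
decay — and are exposed per strain for sensitivity work (e.g. an `ARwP`
Fried's index of 0.36 for a poorly competing release colony).

**Derived female death rate.**  The model admits a positive wild-type
equilibrium only when $\mu_F / (\tfrac12 \lambda\, p_{\mathrm{mated}}) < 1$,
i.e. a female must on average produce more than one daughter.  $\mu_F$ is
set to the largest feasible value, the solution of
$\mu_F = 0.999 \cdot \tfrac12 \lambda\, p_{\mathrm{mated}}$.  Because
$p_{\mathrm{mated}} = \eta / (\eta + \mu_F)$ itself depends on $\mu_F$, the
pair is resolved by fixed-point iteration from a 9.5-day-lifespan initial
guess, run to machine precision with a final synchronisation step so the
stored pair satisfies the target ratio exactly.  An 8-day point-estimate
lifespan fails the constraint under the default birth rate, which is why the
rate is derived rather than fixed.

**Calibration.**  At the wild-type steady state the density factor must
equal the feasibility ratio, so the immature-pool capacity is
$C = I_{\mathrm{tot}} / (1 - 0.999)$ with every compartment given in closed
form per unit recruitment; the scale is set so the adult total is exactly
`N0`.  The generated mean-field right-hand side (rate × stoichiometry summed
over the same event list the stochastic engine uses) vanishes at this state
to numerical precision — that consistency is a test, not an assumption.
Migration is calibrated for net-zero drift: inflow `migration_total/7` per
day is split over the wild adult compartments proportionally to their
equilibrium shares, and the per-capita emigration rate
$\varepsilon = (\mathrm{migration\_total}/7)/N_0$ applies to *all* adult
compartments of every strain (released-strain emigrants are simply lost;
immigrants are always wild type, with immigrating mated females assigned the
fully compatible wild × wild cross).  Distributing immigration over all
adult compartments — mated females included — is a modelling choice; the
share vector is exposed on the equilibrium object should a different split
be wanted.

**A deliberately near-critical equilibrium.**  Deriving $\mu_F$ at ratio
0.999 makes the equilibrium density factor 0.999, i.e. the wild population
sits just above replacement with a very weak restoring force.  Two practical
consequences are worth knowing.  First, uncontrolled adult counts diffuse
like a near-critical branching process: over 920 days the package's own
simulations show a spread of roughly ±30% (one standard deviation) around
`N0`, so "quasi-stationary" here means no systematic drift and negligible
extinction risk, not tight fluctuation bands.  Second, after suppression the
wild type rebounds mainly through immigration: each immigrant founds a
lineage whose expected size stays near one, so the expected rebound grows
roughly linearly with the cumulative number of immigrants — fast at 10
adults/week, marginal at 2/week.  Both behaviours are properties of the
chosen parameterisation, not numerical artefacts.

## Simulation engine

The exact mode is the Gillespie direct method with full propensity
recomputation per event; the exponential clock is redrawn after every
sampling or intervention boundary, which is exact by memorylessness.  The
tau-leap mode uses a fixed 0.1-day step with Poisson channel counts and a
non-negativity safeguard: a leap that would drive any count negative is
rolled back and re-simulated exactly over that sub-interval.  On the default
patch model the two modes agree on ensemble means to well within Monte-Carlo
error; exact mode is the reference and tau the batch workhorse (a 920-day
replicate costs ~0.1 s).  All randomness flows through R's RNG, so a single
seed reproduces a run bit-for-bit, and replicate batches draw
counter-based per-replicate seeds so any replicate can be reproduced in
isolation.

## Experimental protocols

**Cage trials** start from 420 adults, half male and half female, an `ARwP`
fraction `p` per sex rounded half-up (so 0.05 × 210 = 10.5 becomes 11), all
females unmated, all males freshly emerged in CI class 1 (a `stationary`
placement option exists), and an immature pool seeded at the wild
equilibrium level split by strain shares — starting with an empty pool would
produce an artificial adult crash one development time in.  Runs last up to
500 days, ending 180 days after either stopping condition first holds on the
daily grid: `ARwP` adults reach zero, or wild adults drop strictly below 42.
Establishment of a strain means strictly more than 10% of `N0` adults at the
end of the (possibly truncated) run, evaluated at the replicate's own end
time.  The threshold $\omega^*$ is reported two ways — the smallest grid
proportion with *any* establishment and the smallest with ≥50% — because
under bi-directional CI the establishment probability jumps from zero to
rare (about 1% at `p` = 0.45 under the defaults) before climbing, and a
single-number summary hides that structure.

**Release scenarios** run 920 days from the integer-rounded wild
equilibrium.  Every 7 days, starting at day 0, the policy is evaluated and
— while releasing — `round(5 × current wild males)` adults are added, with
a Binomial(total, 0.01) female contamination, males entering CI class 1 and
females entering the unmated pool.  No stopping condition is considered
before day 100; releases are forced off from day 730.  The naive policy
stops when wild adults drop below 10% of `N0`; complete-stop additionally
stops when `ARwP` adults exceed $\omega^* N_0$; maintain uses the same stop
rule but resumes when the wild type rebounds above 10% *and* `ARwP` falls
below $0.8\,\omega^* N_0$ (the 0.8 factor prevents stop/start chatter at a
single threshold).  All proportions use the initial `N0` as denominator.

Success means wild adults below 10% of `N0` (and, as a separate criterion,
`ARwP` below $\omega^* N_0$) at evaluation time.  The "within stopping
time" evaluation happens when the release *program* ends: at the permanent
stop for naive and complete-stop, and at day 730 for maintain — a paused
maintain program can always resume, so its pauses are part of the strategy
rather than an end point; anchoring the evaluation at a pause instant would
condition on the stop trigger and make the statistic vacuous.  The 6-month
evaluation is 183 days after the program end, capped at the horizon.  The
cost proxy counts released adults in 100-day bins anchored at day 0 with the
last bin ending at day 700 (half-open bins, `[600, 700)` last).

## What the synthetic experiments do and do not show

The generator reproduces the mechanism under study — bi-directional CI with
age decay, density-limited recruitment, weekly overflooding releases,
migration-driven reversibility — under constant fitness parameters in a
single well-mixed patch.  It deliberately omits seasonality and
overwintering, temperature-dependent rates, spatial structure beyond one
patch, explicit egg/larva/pupa stage mortalities, and disease transmission.
Passing tests therefore demonstrate internal consistency and
reproducibility of the model's stated dynamics at these population scales;
they say nothing about field performance where those omitted forces matter.

## Numerical choices

* Tau-leap step 0.1 day; exact fallback inside any leap that would go
  negative.  Propensity overflow or NaN aborts with a diagnostic.
* Largest-remainder rounding (ties by compartment order) for the patch
  initial state, round-half-up for cage strain splits — bit-reproducible.
* Policy decisions strictly precede the release at the same instant;
  strict inequalities throughout (42 adults is *not* suppressed; 168 is
  *not* past the 0.4 threshold).
* Stopping conditions are checked on the daily sampling grid.
* The mean-field right-hand side clamps negative intermediate solver states
  to zero before rate evaluation.
* Default master seed 20260310; every reported table prints its seed.

The test suite keeps simulation sizes modest by choice: 100–200 replicates
per scenario cell and per cage grid point (with binomial standard errors
reported alongside), a 40-adult toy configuration for
distribution-level checks against a matrix-exponential oracle, and
law-of-large-numbers checks at ten times the toy population.

## Known limitations

* The near-critical calibration makes long-horizon wild-only counts
  diffusive (above); summaries over 920 days carry wide replicate bands.
* Strain-specific fitness differences (e.g. an intrinsic cost of the
  released infection relative to a *Wolbachia*-cleared host) default to
  none; the uni-directional arm's threshold estimate is sensitive to that
  choice, and field-calibrated multipliers should be supplied through the
  per-strain config fields when available.
* Contamination is Binomial per release; a deterministic mode exists for
  variance decomposition but changes small-count tails.
* Cost is counted in released insects only — no rearing, sorting or
  delivery overheads.
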