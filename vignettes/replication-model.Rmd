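---
title: "Modelling whole-genome replication with limited firing factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-genome replication with limited firing factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliforge)
```

## The model

`repliforge` simulates one S phase of budding-yeast DNA replication as a
continuous-time Markov jump process on a 1-kb genome grid. The state is:
the replication status of every bin, the fate of every origin (pending,
fired, or passively replicated), the set of active forks, and the
partition of the firing-factor pool into free and recycling factors.
Three event families drive it:

* **Origin firing.** A pending origin $i$ fires with propensity
  $f_i \cdot F_\mathrm{free}$, where $f_i$ is its association rate with
  firing factors (per minute per free factor). Firing replicates the
  origin's bin, creates a leftward and a rightward fork there, and moves
  one factor from the free pool into a recycling state. The factor pool is
  the only coupling between origins: when many origins fire early,
  $F_\mathrm{free}$ collapses and the remaining origins' effective rates
  drop with it, even though every $f_i$ is constant in time.
* **Fork steps.** Each active fork replicates the next bin in its
  direction. In the default `stochastic_steps` mode steps are exponential
  with rate $v$ (the fork speed, kb/min), matching the jump-process
  semantics of the rest of the model; `fork_mode = "deterministic"`
  advances each fork exactly every $1/v$ minutes instead, for users who
  prefer the literal reading of a constant fork speed. On toy genomes the
  two modes agree on mean timing to well within Monte-Carlo error (the
  test suite checks this); the stochastic mode additionally contributes
  the Gamma-shaped travel-time variance that the per-bin timing SD
  reflects. A fork stepping onto an already-replicated bin, or past a
  chromosome end, terminates instantly; when a fork replicates the bin of
  a pending origin, that origin is passivated. The opposing fork of a
  converging pair terminates on its own next step attempt.
* **Recycling.** Each recycling factor independently returns to the free
  pool at rate $r$ per minute, so the aggregate recycle propensity is
  $r \cdot N_\mathrm{recycling}$. Recycling is deliberately independent of
  fork termination: the limiting pre-initiation factors are released
  before the replisome departs, rather than travelling with the fork.

All factors are available at $t = 0$ (no gradual activation at the G1/S
transition), licensing is not modelled, and each origin's $f_i$ is constant
through S phase — origin-specific chromatin or sequence effects are folded
into $f_i$, and cell-to-cell variability arises solely from the
stochasticity of the event process.

Because all waiting times are exponential, the simulator is an exact
Gillespie algorithm: no time discretisation is involved, and event ties
have probability zero. The event loop is implemented in C++ with R's RNG,
so a simulation is reproducible from a single integer seed and ensembles
are reproducible from a base seed (each replicate derives its own stream).

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_factors` (F) | 200 | count | copy number of Dpb11, the scarcest essential initiation factor |
| `recycle_rate` (r) | 0.05 | /min | expected recycling delay (20 min) ≈ one third of S phase |
| `fork_speed` (v) | 1.4 | kb/min | experimentally determined replication fork rate |
| `max_time` | 500 | min | safety cap only; incomplete runs are flagged, reported, and excluded from timing statistics |

Firing rates $f_i$ are whatever the fit produces; with $F = 200$ and yeast
timing data they land around $10^{-5}$–$10^{-3}$ per minute per factor.

## Fitting firing rates to timing data

The only per-origin unknown is $f_i$. Given an experimental timing profile
$T_i$ (minutes from S-phase onset at 1-kb resolution; gaps are linearly
interpolated and edges extended by the reader), the fit iterates:

1. **Initialisation** $f_{i,0} = \frac{1}{F}\,\frac{1}{T_i}$ — if factors
   were never limiting, an origin would fire on average at its measured
   replication time.
2. **Simulate** an ensemble (default 500 replicates; 200 are plenty for
   the shipped fixture) and take the per-bin mean replication time over
   completed replicates, $\tilde T_{i,n}$. The mean (not the median) is
   used because the objective is a mean absolute error.
3. **Update** $f_{i,n+1} = f_{i,n} (\tilde T_{i,n} / T_i)^\alpha$ with
   $\alpha = 1.2$: origins replicating too late are accelerated, too early
   decelerated. $\alpha$ trades convergence speed against oscillation;
   1.2 converges in ~10 iterations without instability on every problem we
   generate. $\alpha = 0$ freezes the rates (useful as a control).
4. **Score** each iteration by genome-wide MAE over *all* bins (not only
   origin bins), with RMSE and $R^2$ as side diagnostics, and keep the
   lowest-MAE iteration — the MAE trajectory is noisy at small ensemble
   sizes, so the final iteration is not necessarily the best one.

Numerical guards: rates are clamped to $[10^{-8}, 10^3]$ (the
multiplicative update can otherwise blow up on bins where the simulated
and experimental times differ by orders of magnitude); a zero experimental
time at an origin is an error (the initialisation would be infinite); each
iteration draws a fresh ensemble seed from the master seed so Monte-Carlo
noise does not correlate across iterations and stall the multiplicative
update; and the fit aborts if fewer than half the replicates of an
iteration complete, which only happens when rates have become pathological.
Timing profiles are assumed to be expressed in minutes from S-phase onset;
`read_timing_profile(origin_shift =)` re-zeroes datasets on other clocks.

## Population statistics

All statistics are computed from completed replicates of a
`run_ensemble()` result:

* **Timing mean/SD** per bin; the mean profile is the same code path the
  fitting loop uses, so fit errors and reported profiles cannot diverge.
* **S-phase length**: completion time of each replicate.
* **IOD**: distances between successive fired origins within a replicate
  and chromosome, pooled.
* **Efficiency**: percentage of (completed) simulations in which an origin
  fired; its complement is the passivation rate.
* **RFD** per bin: $(n_R - n_L)/(n_R + n_L)$ counting fork passages only.
  Bins replicated by origin firing in a given replicate are excluded from
  that bin's counts rather than counted as zero — including them would
  bias RFD toward 0 exactly at origins; a bin with no fork passage across
  the whole ensemble is reported `NA` rather than 0, since "no
  information" and "perfectly balanced" are different facts.
* **Replicons**: per replicate, the origin's bin plus all bins its two
  forks replicated; the partition property (replicons of fired origins
  tile the genome exactly) is asserted in the tests.
* **Time curves** (active forks, free factors, fired and available
  origins, fraction unreplicated, firing rate per minute) reconstructed
  from event logs on a uniform grid (default 1 min); the firing-rate curve
  is a centred moving count over one grid step. Curves are typically
  cropped at the ensemble-mean S-phase length for plotting.
* **Firing-factor sweeps**: re-simulate fixed fitted rates across a range
  of $F$, record MAE versus the experimental profile, and summarise with
  an unweighted least-squares fifth-degree polynomial when at least six
  $F$ values are available (fewer leaves the polynomial underdetermined
  relative to its six coefficients, so it is skipped with a warning).
  Sweep points share a base seed so only $F$ differs.

## The synthetic fixture and what it does (not) show

Everything is testable offline through a synthetic module:
`make_toy_genome()` places origins uniformly on distinct bins and draws
rates log-uniformly; `generate_reference_timing()` simulates the resulting
"experimental" profile, making parameter recovery a closed-loop test — the
generative rates are ground truth, and the reference profile is produced
by the same simulator the fit runs, which is precisely the point: it
isolates the inference machinery from model misspecification.

The shipped worked fixture is two 300-kb chromosomes with 12 origins whose
rates span a factor of ten (log-uniform on 0.01–0.1 /min/factor, fixed
seed), simulated with a firing-factor pool of **4**. The pool is scaled
down with the genome — about one factor per three origins, the same ratio
as 200 factors to 626 origins genome-wide — because factor competition is
the phenomenon the model exists to describe: with hundreds of factors and
only 12 origins, the pool never depletes, every origin fires independently
at $f_i F$, and the closed-form initialisation is already essentially the
fixed point of the fit, leaving the fitting algorithm nothing to do. In
the scaled competitive regime the initialisation misjudges the effective
factor availability and the iterative fit has to recover the timing
landscape, which it does (to ~10% of the initial MAE with $R^2 > 0.99$;
see `scripts/acceptance.R` output).

Limits of the fixture: it has no measurement noise, no diploid averaging,
no missing-data gaps, and a 600-kb genome with 50-kb origin spacing, so
fork travel contributes relatively more to its timing landscape than on a
12-Mb genome with ~19-kb spacing. One visible consequence: the shape of
the timing profile is extremely robust to the factor pool when the pool is
saturating (mean-centred per-bin correlations > 0.99 across $F$ from 25 to
400), but at fixture scale it decorrelates across a wide sweep *within*
the competitive regime ($F$ of 1–16), where factor starvation reorders
regions — whole-genome shape robustness across large factor perturbations
is a many-origins property, and a 12-origin toy shows the monotone
timing shift (completion time more than halves from $F=1$ to $F=16$) but
not the full shape invariance. Passing tests on the fixture therefore
demonstrate the correctness of the simulator and the inference loop, not
the field-accuracy of any particular biological parameter set.

Problem sizes in the tests and acceptance script (600-kb fixture, 200-500
replicates, 15 fitting iterations, $10^4$-replicate oracle checks on
single-origin toys) were chosen so the whole suite replays in well under a
minute of simulation time while keeping Monte-Carlo standard errors an
order of magnitude below every asserted tolerance.

## Degenerate inputs and edge behaviour

* $F = 0$, or any state with zero total propensity and no active forks,
  ends the run as *stalled* (`completed = FALSE`) rather than erroring.
* Chromosomes with no origin are rejected up front — they could never
  replicate.
* Two origins on one bin are rejected by the simulator; the catalog mapper
  resolves such collisions first (`keep_first`, `merge_max_rate`, or
  `error`), since 1-kb binning can merge neighbouring catalog entries.
* An origin interval maps to the bin containing its midpoint; OriDB-style
  inclusive coordinates and BED half-open coordinates are both handled.
* Incomplete replicates are excluded from timing statistics but always
  counted and reported, and efficiency denominators use completed
  replicates only.

## Known limitations

The model deliberately omits licensing dynamics, fork stalling and
position-dependent fork speeds, dNTP/checkpoint feedback, rDNA repeat
origins, cooperative or factory firing, and any time dependence of
$f_i$. It fits a single population timing profile; allele-specific or
single-cell timing data would need a different objective.
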