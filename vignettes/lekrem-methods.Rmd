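---
title: "Modelling lek behaviour as a relational event process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lek behaviour as a relational event process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`lekrem` treats the behavioural stream on a lek — a communal display ground
where males aggregate and females visit to choose mates — as a
continuous-time marked point process over a finite set of event types. At
any moment every *possible* event type `c` carries a hazard

    lambda(c | history) = exp(theta' u(c, X, A_t))   if c is supported,
                          0                          otherwise,

where `u` is a vector of predictor statistics built from the event history
`A_t` and covariates `X`, and `theta` the coefficient vector. The system is
piecewise constant: hazards change only when an event (including a
scheduled clock tick) updates the state, so waiting times between events
are conditionally exponential with rate equal to the summed hazard of the
support set, and the next event's identity is categorical with
probabilities proportional to the individual hazards. This yields both a
tractable likelihood and, read forwards, a Gillespie-style generative
simulator — the same state machine and design matrices drive
`rem_loglik()`/`fit_rem()` and `simulate_lek()`, which is what makes
self-consistency (fit-to-own-simulation) testable.

### Event taxonomy and support constraints

Events are dyadic attacks; instantaneous responses by the attacked male
(face-off, short fight, or chase) that set the fight's kind; disengagements
(the first male to successfully disengage wins; from a chase only the
attacker can disengage, winning it); solicitations (operationalised as the
male mounting) opening a copulation; copulation ends; departures; and
exogenous arrivals, female entry/exit, 15-minute clock ticks, disturbances
and day ends. For n actors the taxonomy has `n(n-1) + 8n + 5` types — 1115
for 29 named males plus the bulk actor.

Hard constraints zero the hazards of impossible events: only present males
interact or depart; solicitations require females; males inside an attack
or copulation cycle are unavailable (though a copulating male can still be
*attacked* — an interruption that supplants the copulation end); the single
bulk "X" actor aggregates transient unidentified males and may hold several
simultaneous fights. Responses are modelled as zero-duration competing
risks: they contribute a multinomial choice probability to the likelihood
but no waiting time. We picked this reading because the field protocol
records the response as instantaneous; a corollary is that the response
window cannot itself be interrupted.

### Predictor statistics

`stat_catalog()` generates statistics as pattern x scope x window x
channel combinations. Scopes are *general* (the focal male's overall
record) or *pairwise* (his record with the specific partner); windows are
cumulative, yesterday, so-far-today, or a reciprocal-square-root recency
`1/sqrt(seconds since the qualifying event)`; the channel names the event
category whose hazard the statistic modifies. The win-loss record pattern
crossed over both scopes, the three count windows and the four
fight-relevant channels yields 24 predictors. Two context rules matter:
interrupt-channel statistics apply only while the candidate's receiver is
copulating (so they estimate history-by-copulation interactions on top of
baseline attack risk), and solicitation-channel statistics count only
events that occurred with females present. Pairwise scope is accepted for
all history channels; for candidates with no defined partner (a
solicitation or departure) a pairwise statistic evaluates to its base
value of zero. Days without a true consecutive predecessor reset
yesterday-window counters to zero. Recency markers are kept within-day:
overnight gaps are hours long, where `1/sqrt(s)` is effectively zero, so
day ends clear them.

Two covariate choices are ours, since no transform is prescribed: the
pairwise centroid distance enters in metres centred and scaled by the
roster-wide mean/SD of male-male distances (so its coefficient is per SD
of spacing), and time-of-day enters as hours since session start at the
last clock tick.

### Estimation and model selection

`fit_rem()` maximises the log-likelihood plus an independent Gaussian
log-prior, mean 0 and SD 10 by default, on every coefficient — weak on the
log-hazard scale, but enough to keep channels that are structurally
possible yet never observed (e.g. a male that never departs) at a finite
mode. One replay of the history assembles stacked per-interval design
matrices with exposure weights; the penalised objective, its analytic
gradient and its Hessian are then pure linear algebra, optimised by BFGS
(gradient tolerance around 1e-6, zero-vector start, deterministic given
the data). Posterior SEs come from the inverse observed information at the
mode, with an eigenvalue pseudo-inverse fallback when near-singular.

BIC is `k log(n) - 2 logLik` with `n` the number of observed endogenous
events, responses included — n is not prescribed anywhere authoritative,
so we document this choice rather than claim it. `select_rem()` performs
greedy forward addition then backward pruning of candidate statistics by
BIC, ties broken toward the smaller model, optionally across several base
models; the canonical contrast is the single solicitation intercept
("aggression" scheme, which forces fighting statistics to carry variation
in solicitation) against per-male intercepts for ever-solicited males
("differential attractiveness").

### Simulation

`simulate_lek()` alternates exponential waiting-time draws with
categorical identity draws, pre-empted by the exogenous scaffold
(arrivals, female windows, disturbances, clock grid, observation end):
scheduled events are fixed inputs, so a sampled event later than the next
scheduled one is discarded in its favour. A departing male's potential
return is scheduled after an exponential delay with his mean absence
interval. State carries across days so that yesterday-window statistics in
day d+1 see day d's events; a day gap resets them.

## The synthetic-data generator

No field recordings ship with the package, so `synth_config()` presets
define the study conditions everything is tested under:

* **toy** — two males, no females, 2-hour sessions, three free parameters
  (attack, disengage, depart intercepts at -4.8, -3.0, -7.5, chosen to
  give a realistic fight tempo of roughly one cycle per minute and about
  200 events per day; five days gives the ~1000-event datasets used by the
  recovery study).
* **paper_scale** — 14 identified males present on any day with
  probability 0.55, 15 single-day "U" males, the bulk actor, 18 four-hour
  days, one jittered female window per day, disturbances at about 4 per 18
  days. Intercepts were calibrated once to the reported field scale
  (~84 fights and ~4 copulations per day across ~8.6 males present,
  ~22/72 interrupted copulations, ~290 events per day); the worked-example
  magnitudes used throughout the documentation (-8.54 departure, -1.37
  female presence on departure, 2.84 lost-chase recency, 3.8
  copulation-onset attack indicator) are used verbatim so the worked
  examples double as fixtures.
* **experiment** — six territory-holding males with equal per-male attack
  (-10), disengage (-3.4) and solicitation (-9) intercepts, a fixed 2-hour
  female window in a 4-hour session, no departures or disturbances, eight
  days of which the first is burn-in. Treatments add one SD (0.5 on the
  log-hazard scale, our stand-in for the spread of fitted per-male
  intercepts) to the focal male's attack and/or disengage intercept; the
  high-susceptibility scenario adds the same to his incoming-attack
  effect. Treatment effects are z-scores against control using the
  replicate-level control SD (replicate-level rather than SD-of-means,
  since the contrast is per simulated week).

What the generator emulates: realistic event densities, attendance,
female windows, cycle structure, winner/loser and recency feedbacks, and
interruption risk. What it does not: spatial movement (centroids are
static covariates), observation error, identification failure, weather,
plumage or display content. Passing recovery tests therefore show that
the estimator inverts *this* generative process at field-like scale — not
that any particular field dataset satisfies the model's assumptions.

## Numerical choices and degenerate inputs

Simultaneous timestamps are ordered attack < response < disengage <
copulation end < others, preserving cycle validity at the 1/30 s recording
resolution. Recency uses `1/sqrt(max(dt, 1))` so a refresh in the same
second caps at 1 rather than diverging. Division-guarded metrics (win rate
with no decided fights, interruption rate with no copulations) return `NA`
rather than propagating NaN. A model fit refuses design columns that never
appear (identifiability error naming the parameter) instead of silently
returning a prior-only estimate. Zero-duration response windows must be
immediate: a response at a later timestamp than its attack is a validation
error.

Sizes used by the shipped test-suite studies — 50 datasets of ~1000 events
for coverage, a 200/1000/5000 grid for error shrinkage, 20 replicates for
the scheme-recovery study, 200 replicates per condition for the treatment
experiments — were chosen as the smallest runs that make the Monte-Carlo
error small relative to the effects being checked.

## Known limitations

* The response multinomial depends only on fight-kind intercepts; the
  catalog has no response channel, so "which fight kind" cannot yet depend
  on history.
* The bulk actor's counters aggregate over all partners, which blurs
  pairwise statistics involving transient males.
* Whether a mid-session disturbance ends the day or birds return is left
  to the scaffold (the generator schedules re-arrivals a few minutes
  later); both readings are possible in the field protocol.
* Greedy BIC search is a documented stand-in for an exhaustive selection
  protocol; it can stop at local optima of the statistic set.
* Posterior uncertainty is a Laplace approximation at the mode, not an
  MCMC posterior.
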