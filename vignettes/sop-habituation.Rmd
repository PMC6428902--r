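---
title: "Simulating habituation with the SOP model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating habituation with the SOP model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sophab)
```

## The model

SOP treats the representation of every stimulus — and of the experimental
context — as a large pool of elements distributed over three activity states:
inactive (I), primary activity (A1) and secondary activity (A2). The package
simulates the *mean proportions* `(pI, pA1, pA2)` deterministically, one
abstract time step ("moment") at a time. A moment has no assigned physical
duration; it is the model's unit of processing time.

Per moment, for a node with effective rates `p1_eff`, `pd1_eff`, `pd2_eff`,
`p2`, all flows are computed from the previous moment's state and applied
simultaneously:

```
promoted_A1 = p1_eff * pI          (0 when the stimulus is off)
promoted_A2 = p2 * (pI - promoted_A1)
pA1' = pA1 - pd1_eff * pA1 + promoted_A1
pA2' = pA2 - pd2_eff * pA2 + pd1_eff * pA1 + promoted_A2
pI'  = 1 - pA1' - pA2'
```

The simultaneous update is the unique simple ordering that reproduces the
canonical single-presentation walk-through exactly — from `(1, 0, 0)`, one
stimulus-on moment with `p1 = 0.8, pd1 = 0.1, pd2 = 0.02` gives
`(0.2, 0.8, 0)` and the next (off) moment `(0.2, 0.72, 0.08)`:

```{r walkthrough}
r <- effective_rates(p1_eff = 0.8, pd1_eff = 0.1, pd2_eff = 0.02)
s1 <- step_node(activity_state(1, 0, 0), r, stimulus_on = TRUE); s1
step_node(s1, r, stimulus_on = FALSE)
```

Conservation holds exactly because `pI` is recomputed as the complement.
When both recruitment channels apply, `p1` takes precedence and `p2` acts on
the inactive fraction `p1` leaves behind, so the total outflow from I can
never exceed `pI`; this situation (stimulus on while the context primes the
same node) is not exercised by the standard protocols but must be
conservation-safe under arbitrary configs. All effective rates are clamped to
[0, 1] after the disruption increments, since e.g. `pd1 + pA1/c1` can exceed
1 under non-default constants.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `p1_s` | 0.8 (0.5 / 0.2 medium / low) | probability/moment | stimulus intensity: I→A1 recruitment while on |
| `pd1_s`, `pd2_s` | 0.1, 0.02 | probability/moment | A1→A2 and A2→I decay; their 5:1 ratio makes A2 the long-lived refractory state |
| `p1_Ctxt` | 0.05 | probability/moment | the context as a weak tonic cue, on throughout a session |
| `pd1_Ctxt`, `pd2_Ctxt` | 0.1, 0.02 | probability/moment | as for the stimulus |
| `theta` | 0.07 | proportion | explicit-cue A1 level above which context recruitment shuts off |
| `c1`, `c2` | 2, 10 | divisor | convert explicit A1 / A2 into decay increments `pA1/c1`, `pA2/c2` |
| `L_plus`, `L_minus` | 0.02, 0.0004 | 1/moment | excitatory / inhibitory learning rates (see calibration) |
| `w1`, `w2` | 1, 0 | — | response weights in `R = f(w1*pA1 + w2*pA2)` |
| session length | 300 moments | — | first onset at moment 60; ISI measured onset-to-onset |

With `w2 = 0` the response *is* `pA1`, appropriate for reflexive responses
(startle, limb flexion) where the secondary state is behaviorally silent and
acts only through priming; `w2 < 0` models opponent secondary responses and
`w2 > 0` summation, both available through `response_rule()` but not used by
the packaged protocols.

Session length 300 comfortably contains the standard 4-trial schedules at
ISI ≤ 32 (last onset at moment 156) plus post-trial decay; longer schedules
(the 10-trial below-zero condition) extend the session so that the tail after
the last onset stays at 144 moments. The transition between sessions is not
simulated as elapsed time: all activity is zeroed at the session end and only
the associative strengths V carry over, which is the model's stand-in for a
long inter-session interval.

## Within-moment ordering

One full moment of a protocol runs: (1) effective rates for every explicit
node — decay increments from the *other* explicit nodes' previous-moment
activity (the distractor rules, applied symmetrically across explicit cues)
and priming `p2 = pA1_Ctxt * sum_i g(i, node) * V_i` from the context's
previous-moment A1; (2) all explicit nodes step simultaneously; (3) the
context's rates are computed from the explicit nodes' *just-updated* activity
(threshold test and decay increments) and the context steps; (4) each
context→stimulus association updates from the just-updated activities,
`V ← clamp(V + L⁺·pA1_Ctxt·pA1_s − L⁻·pA1_Ctxt·pA2_s, 0, 1)`.

The ordering inside a moment is underdetermined by the model's description;
we fix this one and document it. Letting the context react to the
current moment's explicit activity means the context is already disrupted at
the onset moment itself; the alternative (context stepping from
previous-moment explicit states) delays disruption by one moment and changes
no qualitative outcome — we verified every characteristic check is unaffected.
Every explicit node, distractors included, learns its own association with
the context under the same rule, which is what lets a repeated distractor
lose effectiveness in principle.

The inhibitory learning term uses the product of context A1 with stimulus
**A2** (concurrent A1–A2 activity). Printed statements of the two learning
rules sometimes show the same A1×A1 product for both; that is inconsistent
with the surrounding prose and with the rules' function (an A1×A1 inhibitory
term would exactly cancel excitation), so we implement the prose version and
treat the printed inhibitory formula as a typo.

V is clamped to [0, 1]: since `pA1_Ctxt ≤ 1` and `g ≤ 1`, `p2` is then always
a valid probability. Net-inhibitory (negative) association is not
represented; if inhibition would drive V below zero it stays at 0.

## Calibrating the learning rates

The learning *rules* are fixed by the model but no rate values are published,
so `L_plus` and `L_minus` are this package's calibration, chosen once so that
the between-session phenomena emerge within 1–10 sessions under the standard
protocols, and exposed in every config. Two constraints pin them:

* **Below-zero near-asymptote.** In the 10-trial training condition the
  trials after the fourth must sit on a near-flat asymptote (the 4-trial and
  10-trial conditions' final training peaks within ~10%). Within-session
  growth of V adds retrieval priming on top of self-generated priming and
  keeps late trials declining, so this bounds `L_plus` from above: at
  `L_plus = 0.1` the trial-4 vs trial-10 gap is ~28%, at `L_plus = 0.02` it
  is ~6%. (Self-priming alone, `L_plus = 0`, gives < 0.1%.)
* **Visible long-term effects.** Partial spontaneous recovery, potentiation
  over ten sessions and the below-zero test difference need V to grow
  appreciably per session, bounding `L_plus` from below and `L_minus` from
  above. The post-training tail of a session (the stimulus's A2 trace
  persists for ~200 moments while the context's A1 recovers) accumulates pure
  inhibition; with `L_minus` at a fifth of `L_plus` this tail drives V to the
  0 clamp at every session end and *no* long-term effect survives.

`L_plus = 0.02, L_minus = 0.0004` satisfies both. The 50:1 ratio is larger
than in typical conditioning applications of these rules; it is a consequence
of the long refractory tail relative to the brief A1 spike in the standard
habituation schedules.

## What the packaged protocols emulate

The protocol builders (`build_figure_protocol()`) reproduce a standardized
experimental design — 1-moment stimulus, onset at moment 60, ISI 2–32
moments, 1–10 sessions — not any specific organism or published dataset. The
trial-level dependent variable is the peak `pA1` in the window from each
onset to the next onset of the same node (or the session end), matching how
response amplitude is plotted in habituation experiments. Passing checks
therefore show that the *model mechanisms* produce the qualitative
regularities; they say nothing about quantitative fit to any empirical
preparation, about real-time units, or about stochastic trial-to-trial
variability (the simulator is deterministic by design; an element-level
Monte-Carlo simulation is used in the test suite as an oracle, not as the
engine).

Generalization between stimuli is a static retrieval-time multiplier: a test
node receives `g` times the association trained to the source node
(`p2 = pA1_Ctxt * g * V_trained`), not a transfer of V between nodes. The
never-trained control is therefore exactly the `g = 0` condition. The
intensity manipulation overrides `p1` per event on the same node, matching a
design where the same stimulus is presented at different intensities and
tested at a common one.

## Degenerate inputs and numerical conventions

Activity states are validated to sum to 1 within 1e−9 and stored clamped to
[0, 1]; conservation after every step is exact by construction (complement).
Probabilities outside [0, 1] anywhere in a config are rejected at
construction, not silently clamped; only the *derived* effective rates are
clamped. Peak windows must be non-empty (an event at the last moment of a
session is its own window). Ties in a peak window resolve to the earliest
moment (`which.max`). Runs are bit-reproducible: identical protocols produce
byte-identical CSV exports.

## Known limitations

* **Habituation of dishabituation does not emerge.** The distractor raises
  the trial-2 peak robustly (dishabituation), but the distractor-minus-control
  difference *grows* over sessions rather than shrinking, under every
  configuration we examined (learning rates over two orders of magnitude,
  distractor placement anywhere between the trials, disruption keyed to all
  explicit cues or to the habituating stimulus only). The control's trial-2
  peak keeps declining as the context-stimulus association grows, while the
  distractor condition is insulated from that decline: the distractor's A2
  tail flushes both the self-generated and the retrieval-primed refractory
  trace, and while the distractor's A1 exceeds the disruption threshold the
  context cannot replenish the priming. The proposed counter-mechanism — the
  distractor acquiring its own context association and losing effectiveness —
  is too weak at one 1-moment presentation per session: context A1 is
  suppressed around the distractor, so its V grows by well under 0.05 per
  session even at high learning rates, and the flush scales with the
  distractor's A2, which a small V barely changes. The characteristic-#9
  check is implemented as specified and reported as failing.
* **The uniform-context comparison.** The motivating argument for context
  disruption is that a uniformly active context would acquire no net
  association. In this instantiation the comparison comes out the other way:
  disabling disruption *increases* terminal V at the package defaults,
  because the threshold rule collapses context A1 exactly during the
  stimulus's brief A1 spike (the excitatory window) while the suppression has
  already lapsed during most of the long A2 tail (the inhibitory window).
  Disruption buys roughly 5.6·L⁻ of avoided inhibition per standard session
  at a cost of roughly 3.5·L⁺ of foregone excitation, so it only pays when
  L⁻ is comparable to L⁺ — a regime in which the post-training tail drives V
  to the 0 clamp anyway. Long-term habituation itself does not depend on
  this comparison; V grows fine with disruption enabled.
* **Intensity effects are level effects.** The weaker training stimulus
  (p1 = 0.2) responds less *in absolute level* throughout training, and the
  intensity effect on learning shows up at a common-intensity test; the
  *proportional* within-session decrement is larger for the stronger
  stimulus, because refractory A2 accumulation scales with p1. Claims about
  "more pronounced decrement for weaker stimuli" hold here only in the
  response-level reading.
* Emotive sensitization, multiple response systems (beyond the `w1`/`w2`
  weights), stimulus–stimulus associations among explicit cues, and any
  neural interpretation are out of scope.
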