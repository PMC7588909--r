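---
title: "A precision-lesion model of alternate antagonism and paradoxical translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A precision-lesion model of alternate antagonism and paradoxical translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphasim)
```

## The phenomenon and the modelling question

Some bilingual patients recover from aphasia in a strikingly itinerant way.
On one day the patient can name pictures in her first language (L1) but not
in L2; the next day the pattern reverses (*alternate antagonism*). At the
same time she cannot translate words *into* the language she is currently
using for naming, yet translates fluently into the language she cannot name
in (*paradoxical translation*) — while word repetition stays intact in both
languages throughout. A pattern like this cannot be explained by destruction
of either language network; it looks like a failure of *control* over intact
networks.

`aphasim` implements a computational account of this pattern: a synthetic
subject performs picture naming, word repetition and word translation by
Bayesian (active) inference under a discrete generative model, and the
lesion is a loss of *precision* — confidence in the mapping from hidden
causes to sensory consequences — rather than removal of any representation.
A matched-seed control subject runs the identical paradigm so that every
behavioural difference is attributable to the precision loss alone.

## The generative model

The agent's world model is a two-epoch categorical POMDP with five
hidden-state factors and five outcome modalities.

| factor  | levels | role |
|---------|--------|------|
| context | 3 | which task: naming, repetition, translation |
| heard   | 2 | stimulus language (L1/L2) |
| target  | 2 | language of the reply (L1/L2) — the controllable factor |
| concept | 12 | the concept in play (man, girl, ..., newspaper) |
| epoch   | 2 | trial phase: stimulus (1), response + feedback (2) |

| modality | levels | role |
|----------|--------|------|
| task     | 3  | announces the task (identity in context) |
| language | 2  | stimulus language at epoch 1; spoken language at epoch 2 |
| audition | 25 | 12 concepts x 2 languages of words, plus N/A |
| visual   | 13 | 12 pictures plus N/A |
| feedback | 3  | neutral, positive, negative |

Likelihoods follow the task structure: during naming the agent sees the
picture and hears nothing; during repetition and translation it hears the
word of the heard language and concept; at epoch 2 it hears itself speak
the word of the target language and concept. Feedback is neutral at epoch 1
and, at epoch 2, positive when the reply language matches the heard language
for naming and repetition, positive when it *differs* for translation, and
negative otherwise. Transitions are identities for context, heard language
and concept; the epoch factor moves 1 to 2 with 2 absorbing; and the target
factor is moved by one of two one-step policies, *speak L1* or *speak L2*,
each mapping every previous state to the chosen language.

Three likelihood-noise parameters make the sensory channels realistically
soft rather than delta functions. They are free parameters of the model (no
empirical values exist for them); the committed defaults were fixed by a
closed-form calibration of the two-policy decision margins (below) and are
not tuned per run:

* `cue_noise = 0.3` — the epoch-1 language cue reports the correct stimulus
  language with probability 0.7. The cue is the only language evidence in
  naming trials (nothing is heard), so this parameter sets how much residual
  uncertainty a naming trial carries.
* `word_confusability = 0.25` — a heard word's likelihood leaks a quarter of
  its mass onto the translation-equivalent word, the confusable neighbour in
  a bilingual lexicon. Hearing a word therefore identifies its language
  strongly but not absolutely.
* `feedback_noise = 0.25` — evaluative feedback is delivered with
  reliability 0.75, mass split over the other two levels.

Preferences live only on the feedback modality, `(0, +3, -6)` nats over
(neutral, positive, negative): the agent wants praise and strongly dislikes
correction. Initial priors are uniform except for the epoch factor (the
agent knows a trial starts at epoch 1); the environment, not the prior,
fixes the true trial states. All stored distributions are floored at
`1e-8` and renormalised, which keeps logarithms finite and makes the
precision-1 lesion an exact identity.

## Inference and action

Belief updating is variational. The posterior is factorised across the five
hidden factors, but within each factor the two epochs are kept as a joint
(chain) belief, so evidence at either epoch is smoothed exactly through that
factor's transition. Each sweep re-estimates one factor's chain given the
expected log-likelihood of the observed outcomes under the other factors'
marginals — an exact coordinate minimisation, so the recorded free energy is
non-increasing by construction. A fully naive per-factor-per-epoch
mean field was rejected during development: with near-deterministic
(floored-identity) transitions, the backward message behaves like ±18-nat
pseudo-evidence and any weak percept is amplified into false certainty,
which both breaks agreement with the exact enumeration oracle and destroys
the graded beliefs the precision account relies on. Sweeps stop when no
marginal moves by more than `1e-4` (at most 16 sweeps; non-convergence is
flagged, never fatal).

Policies are scored one epoch ahead by expected free energy
`G = risk + ambiguity`: ambiguity is the expected conditional entropy of
outcomes given predicted states, and risk is the divergence of predicted
outcomes from the preference distribution, summed over modalities. Because
preferences are defined over outcomes (feedback) and never over states, the
outcome form of the risk term is the default; a literal state-risk variant
(divergence of predicted states from the prior-predictive states) is
available via `risk_over = "states"` for comparison. The policy posterior is
a softmax of `-(F + G)` at precision `gamma = 16`, and the reply is the
maximum-probability policy (ties to the lower index; a sampling mode exists
for stochastic experiments but reproducibility under matched seeds argues
for the deterministic default).

## The lesion

`apply_precision()` implements precision loss as a temperature operator on
likelihood columns: a targeted column `c` becomes
`normalise(exp(omega * log c))`. At `omega = 1` nothing changes; as
`omega -> 0` the column flattens to uniform, so observations generated
through that mapping no longer discriminate among their causes. The operator
is monotone (within-column ordering is preserved) and only ever applied to
the *agent's* model — the environment keeps emitting veridical outcomes, so
lesioned and control subjects receive identical stimuli under matched seeds.

Which columns to target is the one genuinely open design choice, because
the clinical pattern constrains it sharply. A lesion of the auditory
evidence channels themselves (the `"audition-language"` preset) cannot
reproduce the pattern, for a reason one can see without simulation:
repetition and translation trials present *the same stimulus*, so any
lesion of stimulus evidence degrades both tasks together, and a
policy-side ambiguity penalty pushes both tasks in the same direction —
yet the clinical pattern demands repetition intact while translation fails
*toward* the affected language. Flattening can also never reverse evidence
(a flattened column still favours the true cause), so confidently wrong
percepts are unavailable as a mechanism.

What does work is lesioning the *evaluative* mapping: the committed default
(`"feedback-control"` preset) flattens the feedback-likelihood columns
keyed to the affected heard language at epoch 2, in the two tasks that
require language *selection* — naming and translation — while sparing
repetition, whose reply simply echoes the stimulus language. This is the
model analogue of the hierarchical-control account the simulation speaks
to: naming and translating demand suppression of the non-target language
network (external and internal suppression respectively), repetition
demands none, and the depleted resource is the precision of the mapping
that links task, language and outcome value. With that target:

* On an affected-L1 day, a naming-in-L1 trial retains only the soft cue as
  language evidence (`P(heard = L1) = 0.7`), and the flattened feedback
  columns make "speak L1" an uninformative gamble while the intact
  heard-L2 columns still promise reward for "speak L2" weighted by the
  residual 0.3 belief — so the agent systematically names in L2.
* A translation-from-L1 trial knows the heard language almost surely
  (the word itself), but its feedback prediction is flattened for both
  replies; the decision is then carried by the small intact-column
  "lottery" weighted by the `word_confusability` residual, which favours
  replying in L1 — translation fails *into the accessible language*,
  the paradox.
* Repetition's feedback columns are untouched, and its strong word evidence
  makes the correct reply dominate by over 4 nats — repetition stays at
  ceiling every day.

All three margins were first derived in closed form from the two-policy
risk comparison and then confirmed by simulation; the smallest (the
translation lottery) is about 0.2 nats, an order of magnitude above the
engine's convergence tolerance.

## The paradigm and schedule

Each simulated day runs six blocks in fixed order — naming in L1,
repetition in L1, translation from L1, naming in L2, repetition in L2,
translation from L2 — with 5 items per block drawn uniformly without
replacement from the 12 concepts (30 trials per day). The committed
schedule runs 9 days with precision staircase
`0.1, 0.1, 0.1, 0.1, 0.25, 0.25, 0.5, 0.5, 1` and the affected language
alternating daily (odd days L1). At `omega = 0.1` naming and translation
fail on the affected side; at `0.25` the translation lottery is overcome
and only naming still alternates; at `0.5` the full repertoire recovers;
day 9 is an exact identity with the control subject. A `"slow"` schedule
preset stretches the same staircase over weeks, the timescale on which a
second reported patient showed the same pattern.

Seeding is hierarchical: a base seed spawns per-day streams, which spawn
per-block item draws and per-trial streams, identically for both subjects.
With the deterministic action default, randomness only enters through item
sampling, so the counterfactual comparison is exact.

## What the synthetic data do and do not show

The generator emulates the *structure* of a clinical testing session —
blocked tasks, small item sets, daily retesting — under an exactly known
generative process, which is what makes the in-silico lesion interpretable:
every deficit is attributable to the precision manipulation by
construction. It does not emulate real psycholinguistic data: there is no
phonology or acoustics (words are atomic symbols), no latencies, no
within-task learning or fatigue (the model has no capacity to learn between
trials), concept-level errors are not scored (correctness is language match
only), and the precision trajectory is imposed rather than emerging from a
higher hierarchical level. Passing tests therefore demonstrate internal
consistency of the account — that a single precision parameter moving
through a staircase reproduces the qualitative recovery pattern — not a fit
to any patient's trial-level data, whose per-day counts exist only as
published bar charts.

## Numerical choices

* Probability floor `1e-8` on every stored distribution; logs are finite
  and `omega = 1` is bitwise identity.
* KL divergences use the `0 log 0 = 0` convention and floor only the
  reference inside the logarithm, keeping the evidence bound tight to
  `1e-7` on the 288-state model.
* Convergence: max-abs marginal change `< 1e-4`, at most 16 sweeps; the
  task model converges in 3-5 sweeps on every trial type.
* Ties in action selection break to the lower policy index; with the
  committed parameters no decision in the study is closer than 0.04 nats,
  so tie-breaking never decides a trial.
* Exhaustive enumeration (the test oracle) is exact on the 288-joint-state
  task model and refuses spaces above `1e4` states.

## Problem sizes used in the tests

The full study (two subjects, 9 days, 30 trials each) runs in under a
minute on one core; the test suite exercises the exhaustive 72-case
control ceiling, oracle comparisons on the full 288-state model, and
smaller 2-day studies for serialization and counterfactual checks. These
sizes were chosen to keep the complete check suite comfortably
interactive.

## Known limitations

* The lesion target is a design commitment, not a derivation: other
  mechanisms (for example transition-prior manipulations) might reproduce
  the same phenomenology and are deliberately out of scope.
* The structured variational family is exact within factors but mean-field
  across them; posterior correlations between factors (for example heard
  language and concept under a corrupted word) are represented only through
  their marginals.
* Two languages, twelve concepts and a two-epoch horizon are hard-wired to
  the task; the engine itself is generic over discrete models but the
  builders are not.
* The able/unable thresholds of the pattern classifier (4/5 and 1/5) are
  conventions that make the qualitative clinical vocabulary operational;
  they are configurable and all committed results are far from the
  boundaries.
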