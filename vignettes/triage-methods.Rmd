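---
title: "Rule-based cardiac symptom triage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based cardiac symptom triage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearttriage)
```

## The problem and the model

Women with coronary artery disease frequently experience recurrent cardiac
pain whose character differs from the classic presentation, and decide —
often alone — whether a new episode warrants emergency care, a clinic visit,
or self-management. `hearttriage` encodes the deterministic decision rules of
a chatbot-guided self-management tool for exactly this population, plus the
statistics used to evaluate such tools, so that the rules can be audited,
property-tested and simulated end to end.

The central object is the **Event Profile**: a once-captured description of
the user's index cardiac event as four code sets — pain *qualities*
(`dull`, `heavy`, `tight`, `pressure`, `sharp`, `burning`), body-map
*locations*, *radiation* sites, and *associated symptoms* (shortness of
breath, palpitations, racing heart, lightheadedness, faintness, dizziness).
Every recurring **Heart Check** compares current symptom episodes to this
stored baseline:

* **Similarity.** A dimension matches iff the episode's and the profile's
  code sets intersect; an episode is similar iff at least
  `similarity_min_dimensions` (default 2) of the 4 dimensions match.
* **High risk.** An episode carries high-risk symptoms iff it has ≥ 3 *new*
  typical features (dull/heavy/tight chest pain absent from the profile) or
  *any* new associated symptom.
* **Level of care.** With the onset age $t$ of each qualifying (similar or
  high-risk) episode measured against the evaluation clock: red iff some
  qualifying $t \le 24$ h; else yellow iff some qualifying
  $24 < t \le 168$ h; else green. Red maps to "notify a family member and
  call 911", yellow to "see your primary care provider within 48 hours",
  green to continued app access.

The **Wellness Check** scores seven life domains (general activities, paid
and unpaid work, walking, mood, relations with others, sleep, enjoyment of
life) on an integer 0–10 wellness scale; domains scoring **≤ 4** (boundary
included) are flagged and matching library items are recommended.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `similarity_min_dimensions` | 2 | dimensions | The source rule names the four comparison dimensions but no cut-off. ≥2-of-4 is stricter than any-single-match (which would fire on a lone coincidental location) yet still sensitive; it is exposed in `triage_config()` precisely because it is a design choice, not a published constant. |
| `high_risk_typical` | dull, heavy, tight | codes | The published definition of typical features. |
| `red_window_hours` | 24 | h | "Within 24 hours", read inclusively: $t \le 24$. |
| `yellow_window_hours` | 168 | h | "Beyond 24 hours but within 7 days": $24 < t \le 168$. |
| wellness threshold | 4 | score | The implemented fix after usability testing: content is selected for scores ≤ 4, and *not* shown for excellent scores. |
| `heart_check_interval_hours` | 72 | h | 3-day cadence; on-demand requests override at any time. |
| `wellness_interval_hours` | 168 | h | 7-day minimum cadence. |
| pacing `base_delay_ms`, `per_char_delay_ms` | 600, 35 | ms | Chat speed was a mobile usability finding; delays scale with message length, are pure transcript metadata and are never slept. |

Numerical/tie-break choices: timestamps are ISO-8601 UTC and all window
arithmetic is done in seconds (no DST ambiguity); window boundaries are
closed at the top (an episode aged exactly 24.0 h is red, exactly 168.0 h is
yellow); multiple episodes reduce by maximum severity; "new" is always
relative to the Event Profile, never to earlier Heart Checks; episode age is
measured from onset to the evaluation clock, not to the time the check was
administered, because the category definitions speak of when symptoms
*occurred*. A qualifying episode older than 7 days falls outside both the
red and yellow category definitions and therefore classifies green; it is
retained in the rationale with window `"expired"` so the decision is
auditable rather than silently dropped.

The 0–10 wellness bounds mirror the Brief Pain Inventory interference
response range, reversed to a wellness orientation (10 = best); whether the
production instrument stores interference internally and inverts for display
is unpublished, so this package standardizes on the wellness orientation
end to end.

## Vocabularies and the body map

Vocabularies are **closed sets** loaded from configuration
(`inst/extdata/vocab.json`); an unrecognized symptom token is a validation
error, never a warning, because a triage rule that silently ignores a
symptom it cannot parse is unsafe. The body map is a flat list of coded
regions (front/back side + label) covering chest, jaw, neck, shoulders,
arms, axillae and back. The published map is an image; the bundled region
taxonomy is an informed reconstruction, labelled as such, and any region
set containing the required anatomy validates.

## The dialogue engine

The chatbot is a declarative finite-state machine (JSON), not hard-coded
prompts. `load_script()` rejects dangling transitions, unreachable states
and any state from which no terminal is reachable (liveness via reverse
graph search), so a defective script fails at load time, not mid-
conversation. Input schemas (`yes_no`, `choice`, `integer` with bounds,
`free_text`) re-prompt on violation without changing state. The bundled
script reconstructs the five usability-testing scenarios (sign-in/Event
Profile, Heart Check, Wellness Check, library, library retrieval and notes)
behind a menu state, and its greeting explicitly discloses that the bot is
not a real person — a high-priority finding from the first usability cycle.
A simulated clock is injected everywhere; nothing reads the system clock,
which is what makes transcript replays byte-identical.

## Usability statistics

SUS responses are scored $2.5[\sum_{odd}(x_i - 1) + \sum_{even}(5 - x_i)]$,
assuming the standard alternating item polarity (the instrument's item count
and 0–100 range are published, the formula is the cited standard). Group
summaries pool by the exact sum-of-squares decomposition
$SS = \sum_i (n_i-1)s_i^2 + \sum_i n_i(m_i-\bar m)^2$,
$s = \sqrt{SS/(\sum n_i - 1)}$, with sample (n−1) SDs at both levels —
the convention validated by reproducing the published pooled SUS summary
81.75 (SD 10.41) exactly. The two-group interval is the pooled-variance
Student $t$ (not Welch), validated by the published $df = 8 = n_1+n_2-2$ and
CI endpoints (−16.6, 15.6).

Two caveats the tests make explicit rather than hide:

* Pooling two *identical* groups $(m, s, n)$ yields
  $s\sqrt{(2n-2)/(2n-1)}$, not $s$: concatenation changes the degrees of
  freedom. At $n = 5$ that is a 5.7% shrinkage. Exact pooling is the correct
  operation; the "identical groups are unchanged" intuition only holds
  asymptotically.
* The published between-cycle $t_8 = -0.72$ is internally inconsistent with
  the published group summaries and CI, which imply $t \approx -0.07$; the
  $t$ statistic is treated as a typographical artifact and only the CI
  endpoints and df are reproduced.
* Recomputing the pooled **age** summary from the printed per-cycle values
  58.4 (4.827) and 52.8 (8.872) gives mean 55.6 exactly but SD 7.3519,
  which displays as 7.4 against the published 7.3. The published figure was
  computed from the ten raw ages; rounding of the printed group means alone
  (±0.05) moves the between-group term across the 7.35 display boundary.
  The corresponding assertion is deliberately left failing at printed
  precision instead of widening the tolerance.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` stands in for real participants (default `n_users = 10`,
the usability sample size). Per user it draws an Event Profile, a
homogeneous Poisson stream of symptom episodes (`episode_rate_per_week = 1`
over `horizon_weeks = 4` — a plausible recurrent-pain burden, chosen once),
weekly wellness checks following a bounded integer random walk (per-week
drift mean 0, SD 1, clipped to 0–10), and a SUS response; cohort SUS targets
default to the published 81.75 (SD 10.41).

Two design choices are load-bearing for testing:

* **Labels by construction.** Similarity (probability `p_similar = 0.25`)
  is injected by *copying* ≥ 2 profile dimensions into the episode;
  high-risk (probability `p_high_risk = 0.1`) by *adding* one associated
  symptom absent from the profile. Non-injected episodes draw qualities from
  the atypical set and locations disjoint from the profile, so they can
  never qualify by accident. Ground-truth labels therefore exist for every
  episode, `p_similar = p_high_risk = 0` cohorts are provably all-green, and
  saturated configurations are provably all-red.
* **Per-user substreams.** Each user's stream is seeded by a congruential
  mix of (master seed, user index), so adding or removing users never
  perturbs the others' clinical data. SUS vectors are the one exception:
  they are a cohort-level joint construction (they target *sample* mean and
  SD, which depend on n by definition) and are documented as such.

`generate_sus_responses()` snaps normal draws to the 2.5-point SUS lattice,
then deterministically repairs the sample mean (single-element lattice
nudges) and SD (mean-preserving spread/shrink of the extreme pair), and
expands each score into an item vector that rescores exactly; for n ≥ 10 the
realized mean and SD land within 2.5 of target.

What the generator does **not** emulate: real epidemiology of symptom
recurrence, demographic covariates, missing or malformed entries, free-text
answers, or correlated wellness/symptom dynamics. A green end-to-end test
therefore establishes that the *rules* are implemented correctly and
deterministically — not that the rules are clinically valid, which is
explicitly out of scope.

## Known limitations

* The similarity cut-off (≥ 2 of 4) is a documented assumption, not a
  published constant; sensitivity to it can be explored via
  `triage_config()`.
* A high-risk episode older than 7 days classifies green under the literal
  category definitions; whether it should still raise concern is an open
  clinical question flagged in the rationale output.
* The bundled dialogue scripts are reconstructions of the published
  five-scenario workflow, not the production scripts, whose wording is
  unpublished.
* Config and script files are JSON only; YAML would be a trivial extension
  but is not required by any contract here.
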