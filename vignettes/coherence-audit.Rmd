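---
title: "Auditing probabilistic coherence with synthetic judges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing probabilistic coherence with synthetic judges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(probcoherence)
library(dplyr)
```

## The problem

Classical probability theory imposes hard constraints on any set of
probability judgments. For events A and B:

* the **conjunction rule**: P(A and B) can exceed neither P(A) nor P(B);
* the **disjunction rule**: P(A or B) can fall below neither constituent;
* **binary complementarity**: P(A) + P(not-A) = 1, and jointly
  P(A and B) + P(A and not-B) + P(not-A and B) + P(not-A and not-B) = 1.

Decades of judgment-and-decision-making research show that people violate
all of these. The elicitation protocol implemented here probes them with
election judgments: a respondent judges, on a 0-100 scale, the likelihood
that each of two candidates wins each of three U.S. states, plus every
two-state conjunction, disjunction and conditional, with composites also
shown in reversed order — 78 items in all. Because each atomic event has
exactly two outcomes ("Biden wins Ohio" is the negation of "Trump wins
Ohio"), negations are probed without ever phrasing an explicit "not".

This package makes the whole audit reproducible without any human or
live-model data: it builds the battery, elicits answers from *synthetic
responders* with known generative structure, runs the persona-plus-bounded-
memory chat protocol used for LLM participants, scores the violations, and
compares cohorts. Pluggable responders mean the same pipeline that
validates the scoring on models with known ground truth can drive a real
chat backend through the adapter contract.

## The battery

`build_battery()` enumerates the items for one state triplet (T1:
Ohio-Missouri-Michigan; T2: Georgia-Montana-Nevada):

```{r}
b <- build_battery("T1", seed = 1)
count(b, kind, reversed)
b$prompt_text[1]
```

Six marginals always precede every composite, so composite judgments
cannot anchor the marginals. Composites are grouped into blocks, one per
state pair and composite kind (the low-complexity block structure); block
order and within-block order are seeded permutations. The exact wording of
the original items is not public, so prompts are rendered from a fixed
template and stored verbatim in every transcript — scoring never re-parses
text. Conditionals are elicited to preserve the 78-item protocol but carry
no scoring rules, since no coherence metric is defined for them here.

Candidate labels are configurable (e.g. "Democratic candidate" /
"Republican candidate") to support hypothetical-future-election framings;
nothing downstream depends on the labels because items carry abstract
candidate codes.

## Responder models

### Coherent classical baseline

A `latent_world()` is a full joint distribution over the 8 ways the two
candidates can split the three states. `coherent_respond()` answers every
item with the exact classical probability of its event (conditionals via
Bayes' rule). Every metric below is zero on this output, which makes it
the executable oracle for the scoring module.

A numerical note: `random_world()` snaps its Dirichlet draws to a dyadic
grid (multiples of 2^-20). All classical event probabilities are then
exact in double precision, so "zero" in the oracle tests means bitwise
zero, not zero up to tolerance.

### Finite-sample Bayesian sampler

The sampler answers an item of true probability p with (S + b) / (N + 2b),
S ~ Binomial(N, p), under a symmetric beta prior b. Composite items get
fewer samples than marginals (`n_compound < n_marginal` is enforced), so
their estimates are pulled harder toward 1/2 — which is exactly what
produces conjunction fallacies (conjunctions with small true p are pulled
up past a marginal) and disjunction fallacies (large-p disjunctions pulled
down), including *double* fallacies, and non-zero complementarity
deviations. The defaults (`n_marginal = 18`, `n_compound = 5`, `beta = 1`)
are the small-sample regime in which these human-like violations are
clearly expressed; each item gets one independent binomial draw, since
within-participant sample reuse is not specified by the model as used
here.

### Sequential quantum projections

The quantum responder realizes the two-dimensional projection model: the
cognitive state is a ray at angle psi, each atom "candidate A wins s" a
ray at angle theta_s, and the negated atom the orthogonal ray at
theta_s + 90. Marginals are squared projections, cos^2(psi - theta);
composites are evaluated *sequentially*: first project on X, then on Y,

P(X then Y) = cos^2(psi - theta_X) * cos^2(theta_X - theta_Y),

with disjunctions evaluated through the complement conjunction
(De Morgan) and conditionals as pure transition probabilities. This is the
smallest structure exhibiting incompatibility, order effects and the
single/double fallacy asymmetry: a sequential product can never exceed its
first factor, so the conjunction can never exceed *both* constituents —
double fallacies are impossible under any evaluation order — while single
fallacies against the second-evaluated event arise freely. Orthogonality
of each atom pair enforces binary complementarity exactly.

The open design question is what "evaluate the more likely event first"
means at the level of a battery with four sign combinations per state
pair. Two readings are implemented:

* `ordering = "more_likely_first"` (default) fixes the order per state
  pair: the state whose marginal is more extreme — the one the judge is
  more decided about — is evaluated first in all four sign combinations
  (ties broken by the candidate-A marginal, then triplet order). Under
  this pair-consistent order the four conjunction responses of a pair sum
  exactly to 1, so *joint* complementarity is preserved along with the
  marginal kind — the full signature of a noise-free sequential judge:
  only single fallacies, exact complementarity, and (by the De Morgan
  duality, which makes each participant's mean conjunction and disjunction
  fallacy scores equal) a perfect coupling between conjunction and
  disjunction fallacy rates.
* `ordering = "more_likely_first_item"` applies the rule literally per
  item: whichever of the two atoms has the larger marginal goes first.
  Double fallacies remain impossible and marginal complementarity exact,
  but the four-term conjunction sums are no longer 1 (the evaluation order
  flips between sign combinations), so joint complementarity breaks — a
  property worth studying, and tested, but not the coherent-signature
  default.
* `ordering = "as_presented"` uses presentation order, the natural control
  for order-effect studies.

```{r}
cfg <- quantum_config(psi = 0, theta = c(Ohio = 30, Missouri = 60, Michigan = 100))
rs <- quantum_respond(b, cfg)
score_participant(rs) |> select(marginal_comp:df_prevalence)
```

## The elicitation harness

`run_session()` reproduces the LLM-participant protocol: a
persona-initialization message built from a fixed demographic template
("You are a 54-year-old female with a bachelor's degree living in Ohio."),
followed by task instructions; the instruction text bundled as
`default_instructions()` is a reconstruction around the three directives
known to have been given (intuitive first impressions, a single integer
0-100, answer as if the outcome were unknown). The initialization exchange
(prompt plus a fixed acknowledgment) stays in context for the whole
session, and before every query all but the `window_pairs = 7` most recent
question-answer pairs are removed — a bounded working memory in between
full recall and none. Every transcript row records
`context_size_at_query`, so the memory bound is auditable after the fact.

Replies are parsed strictly (`parse_reply()`): one integer token 0-100,
optional percent sign; anything else triggers a retry with the same
prompt (3 attempts by default, a policy this package fixes since none is
specified by the protocol description) and is then recorded missing.
Sessions with more than 10% missing items are flagged. Rounding to
integers happens only at this reply boundary, so the analytic invariants
of the responders hold exactly in direct response sets, and a replayed
transcript scores identically to the responder's (rounded) direct output.

`run_cohort()` runs one independent session per persona with item order
re-randomized per persona. `simulate_personas()` generates cohorts with
the demographic fields the protocol uses (age, gender, four-level
education, state of residence); its default size and triplet split
(553 = 284 + 269) mirror the study cohort this battery was built for.
The demographic values themselves are sampled uniformly-ish — they
condition nothing in the synthetic responders, whose behaviour is driven
by worlds and configs, so only their shape matters for testing the
plumbing.

## Scoring

For each ordered conjunction item with judged value c and constituent
marginals a, b:

* CF = max(c - a, 0) + max(c - b, 0)  (single-or-double magnitude, 0 to 2)
* DCF = max(c - max(a, b), 0)         (double magnitude, 0 to 1)

and mirror-image DF/DDF scores for disjunctions. Violations are strict:
ties score zero, which with integer raw responses is exact. Each of the
24 ordered conjunction and 24 ordered disjunction items is scored
independently against the participant's own marginals (reversed and
unreversed presentations both count). Complementarity deviations are
|P(A) + P(not-A) - 1| averaged over the three states, and |four-term
conjunction sum - 1| averaged over the six pair-by-presentation-order
configurations — the only decomposition of this battery yielding six
complete four-term sums. All metrics are computed on the normalized [0, 1]
scale; `unit = 100` scores raw slider values instead, and the two differ
exactly by the factor 100 (the metrics are linear in that sense).
Prevalence is reported both as participant-level rates (then averaged)
and pooled over items (`prevalence_summary()`), since the two conventions
differ and both appear in practice; items missing a value are excluded
from averages, and coverage below 90% of composites is an error rather
than a silent imputation.

```{r}
w <- random_world("T1", seed = 8)
score_participant(coherent_respond(b, w)) |> select(marginal_comp:ddf_mean)
```

## Group comparisons

`compare_cohorts()` runs the six core contrasts (marginal and joint
complementarity, mean CF, DCF, DF, DDF) between two scored cohorts —
paired on persona when the cohorts are persona-matched, Welch otherwise —
and attaches each cohort's prevalence summaries and the CF-DF coupling
correlation (`fallacy_coupling()`). A strong positive CF-DF coupling is
the diagnostic of a single sequential mechanism behind both fallacy
types; under the pair-consistent quantum order it is exactly 1, while
independent noise sources predict r near 0. p values are two-sided
throughout and uncorrected, matching the reporting conventions of the
contrasts this layer mirrors; degenerate contrasts (e.g. a cohort against
itself) are reported as rows with NA statistics and a note rather than
errors. `political_sensitivity()` complements the coherence metrics with
per-state paired contrasts of the two candidates' raw marginals, the
check that judgments are actually content-sensitive rather than uniformly
non-committal.

```{r, fig.width = 6, fig.height = 3.5}
personas <- simulate_personas(40, seed = 3)
worlds <- make_persona_worlds(personas, random_world("T1", seed = 3),
                              heterogeneity = 0.5, seed = 3)
arch <- purrr::imap(worlds, function(w, id) {
  bayesian_sampler_respond(b, w, sampler_config(seed = match(id, names(worlds))),
                           persona_id = id)
}) |> bind_rows()
sampler_scores <- score_cohort(arch)
coherent_scores <- purrr::imap(worlds, function(w, id) {
  score_participant(coherent_respond(b, w, persona_id = id))
}) |> bind_rows()
cmp <- compare_cohorts(sampler_scores, coherent_scores,
                       names = c("sampler", "coherent"))
tidy(cmp)
plot_fallacies(bind_rows(mutate(sampler_scores, group = "sampler"),
                         mutate(coherent_scores, group = "coherent")))
```

## What the synthetic data does and does not show

The generators emulate the *structure* of the study conditions: the exact
item algebra and counterbalancing, the persona and memory protocol, the
553-persona cohort shape, and the three generative regimes whose
signatures the scoring must separate — all-zero scores (coherent), only
single and tightly coupled fallacies with intact complementarity
(sequential quantum, pair-consistent order), and positive single *and*
double fallacy rates with broken complementarity (small-sample Bayesian
sampler). Passing tests therefore show that the pipeline measures what it
claims to measure on known mechanisms.

They do not emulate real judges: no content knowledge, no
persona-demographic effects on answers, no response-time or anchoring
dynamics, no drift across a session, and integer rounding is the only
response noise in harness runs. Empirical prevalence levels from human or
LLM cohorts are properties of those cohorts, not of this package; to
reproduce them one plugs the corresponding data (or a live backend
implementing the responder contract) into exactly this scoring and
comparison path.

Problem sizes used in the shipped checks — a 1,000-configuration quantum
grid, 100 coherent worlds, a 500-participant sampler cohort, one
553-persona mock cohort, 1,000 oracle response sets — are the package's
chosen balance of statistical resolution against a test suite that runs
in a couple of minutes.

## Known limitations

* The conditional items' direction conventions in the original protocol
  are unrecoverable; all four per pair are enumerated, and conditionals
  are never scored.
* The quantum realization is the minimal 2-D projective one; richer noisy
  variants (POVM-based samplers) that can produce double fallacies and
  complementarity failures are intentionally out of scope.
* The sampler uses independent draws per item; correlated sampling within
  a participant would change variance, not the direction of the
  signatures.
* `welch_t()` and `paired_t()` are thin, validated wrappers over
  `stats::t.test()`; the package adds the domain-specific degeneracy
  handling, not new inference.
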