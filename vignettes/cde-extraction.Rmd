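---
title: "Constrained-label extraction of common data elements from clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained-label extraction of common data elements from clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdextract)
```

## The extraction model

A *value-list common data element* (CDE) is a precisely defined question
about a clinical document paired with a fixed set of mutually exclusive
answer categories, e.g. "Lesion present?" with categories *yes*, *no*.
Filling every applicable CDE of a form turns a free-text report into a
synoptic, structured record.

`cdextract` treats each CDE as a constrained classification problem for an
autoregressive language model. A prompt is rendered from a template that
embeds the report text, the question and the allowed categories, and ends
with an answer cue. For each category $c_i$ the backend returns the log of
the model's probability of emitting $c_i$ as the continuation of the
prompt, $\log p_i$. The *relative probability* of category $i$ is

$$ r_i = \frac{p_i}{\sum_j p_j} = \frac{e^{\log p_i}}{\sum_j e^{\log p_j}}, $$

computed in log space after shifting by the maximum for numerical
stability. The category with the highest relative probability is selected;
$r_{\hat\imath}$ is reported as the *certainty* of the classification and
later drives selective prediction. An exact tie is resolved in favour of
the earliest tied category in the form's declared order, which makes the
selection a deterministic function of the backend scores.

Two properties follow directly and are asserted as invariants in the test
suite: the relative probabilities of a CDE sum to one, and the certainty of
a $k$-way classification is at least $1/k$.

### Multi-token categories

A backend scores the full category string as a token sequence; its
log-probability is the sum of per-token conditional log-probabilities
(the joint sequence probability). This is the literal reading of
"probability of the next tokens", but it penalises longer category
strings. A length-normalised mode
(`score_categories(..., length_normalize = TRUE)`) divides each
log-probability by the token count a backend reports, for backends that
supply one; it is off by default because it changes the selection rule
rather than merely rescaling it. Scoring only the first token of each
category was considered and rejected: categories frequently share a first
word ("no lesion" / "no prior imaging" style lists), where first-token
scoring cannot separate them.

### The answer cue and the leading space

Every rendered prompt terminates immediately after the answer cue
(`"A:"`, `"ANSWER:"`, or the template's equivalent). The scored
continuation is `" "` + category — one leading space — because most
subword tokenizers fold leading whitespace into the first token; fixing
the convention package-wide means every backend scores the same string.

## The CDE form and parent gating

Forms are hierarchical: CDEs live in named groups and sub-groups (two
levels reproduce the shape of a typical breast-imaging reporting form:
an anamnesis part and a findings/assessment part), and a CDE may be
*gated* on a parent: it is applicable only when the parent holds one of a
set of activating values. Lesion-description items gated on "lesion
present = yes" are the canonical example. Gates name a single parent; the
activating set may contain several values. Multi-parent gates are rejected
at validation — nothing in the intended use requires conjunctive gating,
and single-parent gates keep applicability a simple reachability question.

Validation additionally requires a gate's parent to precede the child in
form order. Classification traverses the form once, in order, and decides
each gate from the value *selected* for the parent on the same report;
generation of synthetic truth does the same with sampled values. With
parents always upstream, both are single-pass and the gating graph is
acyclic by construction.

The JSON dialect is deliberately small: `form_id`, `groups` (object of
main group → array of sub-groups), and `cdes`, each with `id`, `question`,
`categories`, `group_path`, optional `gate {parent, values}` and optional
per-CDE `prompts` overrides. Category and CDE order in the document is
semantic (tie-breaking, traversal) and is preserved exactly on round-trip.

## Prompt variants

Four variants are built in, selected per run:

* **default** — a packaged general instruction to classify the text into
  the named topic given the possible categories (the constant
  is overridable per CDE through the form's `prompts` entry);
* **adapted** — a question–answer dialog with four labelled sections in
  fixed order, `INSTRUCTION`, `QUESTION`, `TEXT`, `ANSWER`, the answer cue
  ending the prompt so it directly contextualises the scored category;
* **fewshot** — worked (report, answer) examples rendered before the query
  in the same layout. Shots are stored in the form JSON, not sampled at
  run time, so a run is a pure function of its inputs;
* **cot** — the adapted template augmented with an explicit step-by-step
  reasoning directive placed before the answer cue.

Placeholders `[TEXT]` (required exactly once), `[TOPIC]` and
`[CATEGORIES]` (joined by `", "` in declared order) are substituted at
render time; no rendered prompt may retain a placeholder.

One design point deserves emphasis: with probability-based selection the
categories are scored *immediately* after the answer cue, so a
chain-of-thought directive changes the conditioning context but no
generated reasoning text is inserted between cue and answer. A
generate-then-score mode would require a generating backend and a policy
for bounding the generation; it is intentionally not implemented, and the
`cot` variant should be read as "reasoning-primed scoring".

## Scoring backends

The backend contract is a single generic:
`backend_score(backend, prompt, continuations, context)` returning one
finite log-probability ≤ 0 per continuation, deterministically. The
package does not bundle a model runtime; any scorer — in particular a
locally hosted causal language model computing continuation
log-probabilities by teacher forcing (greedy generation is never involved
in selection, and sampling temperature is irrelevant) — attaches through
`function_backend()` in a few lines. Two backends ship with the package:

* `mock_backend()` — a deterministic keyword scorer used by the test
  suite and simulation studies. A category scores $-1$ when one of its
  trigger phrases occurs in the prompt and
  $-1 - m - s\,( \mathrm{rank} - 1)$ otherwise, with the fallback ranking
  by decreasing prevalence (default miss penalty $m = 8$, step
  $s = 0.1$). The design makes phrase-backed decisions nearly certain
  (relative probability above 0.999 for binary CDEs) and fallback guesses
  barely better than chance with certainty near $1/k$ — a crude, fully
  analysable emulation of a *calibrated* classifier, which is exactly
  what the selective-prediction machinery needs to be testable.
* `replay_backend()` — replays the recorded per-category scores of a
  previous run (the sidecar JSON written by `classify_corpus()`);
  swapping the original backend for the replay must reproduce the
  prediction grid byte for byte. This is the package's audit mechanism
  for backend exchangeability.

The `context` argument (report and CDE identifiers) extends the minimal
prompt/continuations contract; replay keys on it and the mock uses it to
find the CDE's vocabulary. Model-style backends are free to ignore it.

## Evaluation methodology

All metrics operate cell by cell on the aligned report × CDE grid,
excluding cells whose ground truth is missing (`NA`). Cells whose truth is
the not-applicable marker (parent gate closed in truth) are **included**
by default and graded as exact matches against a predicted not-applicable:
a wrongly predicted parent therefore propagates its penalty to every
descendant cell, which grades the whole form rather than only the open
branches. `na_mode = "exclude"` restricts grading to applicable cells; the
two modes answer different questions and both are exposed.

* **Overall accuracy** is the exact-match proportion over evaluated
  cells, reported in percent with a percentile bootstrap confidence
  interval.
* **Micro/macro precision, recall and F1** use one-vs-rest counts per
  class over one global class universe (every value observed in truth or
  prediction, across all CDEs pooled). Since every cell carries exactly
  one true and one predicted label, micro precision, recall and F1 all
  equal overall accuracy — asserted to `1e-12` in the tests as an
  implementation check. Macro averages the per-class metrics unweighted.
  A per-CDE macro variant was considered; the global class universe is
  the plainer reading of "metrics for each class independently" and is
  what is implemented.
* **Cohen's kappa** measures chance-corrected agreement between two
  categorical raters, $\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from
  the pooled marginal value distributions; it is reported overall and per
  group/sub-group when a form is supplied. The degenerate case
  $p_e = 1$ with perfect agreement is defined as $\kappa = 1$.
* **Certainty sweep** — for thresholds $t$ (defaults 0.9, 0.99, 0.999)
  the covered set is the evaluated cells with certainty strictly greater
  than $t$; accuracy on the covered set and the coverage rate are
  reported. Coverage is non-increasing in $t$ by construction; accuracy
  at a positive threshold is undefined (not zero) when nothing is
  covered. Not-applicable predictions inherit the certainty of the gating
  parent's selection — the confidence that a child does not apply *is*
  the confidence in the parent value that closed its gate — so every cell
  carries a certainty and the sweep at $t = 0$ reproduces overall
  accuracy exactly.

### Paired bootstrap comparison

Two systems evaluated on the same grid are compared by resampling the
evaluated cells with replacement — the same resample applied to both, 2000
iterations by default — and recomputing the metric difference each time.
The two-sided p-value is $2\min(\hat P(d \le 0), \hat P(d \ge 0))$ clipped
to $[0,1]$. Cells are the resampling unit because the metrics themselves
are defined cell by cell; a per-report mode (`resample = "report"`) is
available for sensitivity analysis when within-report cells are not
believed exchangeable. `compare_models()` runs every unordered pair of
systems per metric and applies a Bonferroni correction across pairs
within each metric: with five systems at $\alpha = 0.05$ that is
$\binom{5}{2} = 10$ pairs and a corrected threshold of $0.005$. Each
(pair, metric) test draws its own seed-derived resampling stream, so the
whole comparison is reproducible from one seed. Confidence intervals
throughout are percentile intervals from the same machinery.

## The synthetic corpus generator

Real report corpora with expert-assigned CDE values are rarely shareable,
so the generator produces corpora whose ground truth is known by
construction. Per report it samples truth values per CDE from configured
prevalences (children only under activating parents), emits one signal
sentence per applicable value drawn from that value's trigger phrases,
drops each sentence with probability `noise_rate`, interleaves
Poisson-many distractor sentences, and places anamnesis-section sentences
(CDEs under the form's first main group) before report-section sentences.
The corpus is fully determined by the seed.

What this emulates: the *statistical* structure of semi-structured
clinical reporting — sectioning, gated sub-findings, sparse signal
phrases amid irrelevant text, signal dropout. What it does not: real
clinical language (negation scope, hedging, anaphora, synonymy,
terminology drift). Passing tests on this generator therefore validate
the pipeline's selection, gating, evaluation and calibration mechanics;
they say nothing about any particular language model's clinical accuracy.
`noise_rate` is implemented as omission of the signal sentence (not
corruption): omission is the failure mode the analytic accuracy below
models, and a replacement model would need its own corruption
distribution.

Pairing the generator with the keyword mock gives a closed-form test
oracle. With signal present (probability $1 - \nu$) the mock is correct;
with the signal dropped it falls back to the most prevalent category,
correct with probability equal to that category's prevalence. For an
ungated CDE the expected cell accuracy is
$(1-\nu) + \nu \max_c \pi_c$ — with $\nu = 0.2$ and uniform binary
prevalence, $0.8 + 0.2 \cdot 0.5 = 0.9$. For gated CDEs
`expected_mock_accuracy()` propagates the joint distribution of (truth
value, predicted value), including the not-applicable state, down the
gating hierarchy, so gate mismatches between truth and prediction are
accounted for exactly; the tests confirm the measured accuracy on
generated corpora lies within three binomial standard errors of the
analytic value.

Two fixture bundles (`cde_fixture()`) cover testing needs: `mini` (three
CDEs, one gate) and `mammo_like` (twenty CDEs, two main groups, five
sub-groups, a three-level gate chain) whose invented content mirrors only
the *shape* of a breast-imaging form.

## Problem sizes and numerical choices

The shipped tests run the pipeline at 500-cell (25 × 20) and 1000-cell
(100 × 10) grids for the selective-prediction and parameter-recovery
studies, 2000 bootstrap iterations where the comparison machinery is the
subject and 50–500 where it is incidental; the acceptance script uses a
61-report × 20-CDE corpus (1220 cells). These sizes give binomial
standard errors around one percentage point, small enough for the
three-sigma recovery checks to be meaningful. Other numerical choices:
softmax shift-by-max; relative-probability sum asserted to $10^{-9}$;
micro-identity asserted to $10^{-12}$; strict `>` at certainty
thresholds; ties in fallback prevalence ranking broken by declared
category order.

## Limitations

Only categorical (value-list) CDEs are handled; numeric or free-text
values are out of scope by design. Gates are single-parent. The bundled
backends do not generate text, so the chain-of-thought variant primes but
never emits reasoning. Evaluation assumes a single label per cell;
multi-label CDEs would need a different grid semantics. The generator's
corpora are vocabulary-matched to the mock backend — results obtained
with that pairing characterise the pipeline, not any language model.
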