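# cdextract

Structured data extraction from free-text clinical reports, for people who
need a synoptic record — a value for every applicable question of a
standardized reporting form — out of narrative text, without training a
task-specific model. The intended users are clinical-NLP researchers and
data managers who maintain *common data element* (CDE) forms and want a
reproducible, auditable pipeline from report corpus to evaluated value
grid.

## The method

Each value-list CDE is a question with mutually exclusive categories
`c_1 … c_k`. A prompt is rendered from a template (the report text, the
question, the category list, an answer cue at the very end), and a scoring
backend — typically an autoregressive language model — returns the log
joint probability `log p_i` of each category as the continuation of that
prompt. The category is selected by the highest **relative probability**

```
r_i = exp(log p_i) / Σ_j exp(log p_j),
```

and `r` of the winner is kept as the classification's **certainty**,
usable for selective prediction (only accept classifications with
`r > 0.9 / 0.99 / 0.999`, trading coverage for accuracy). Forms are
hierarchical: a CDE can be gated on a parent value ("lesion description"
items only apply when a lesion is reported), and gating during extraction
follows the values the classifier itself selected.

Around the classifier, the package implements the matching evaluation
methodology: cell-by-cell exact-match accuracy with bootstrap confidence
intervals, micro/macro precision–recall–F1 over a pooled class universe,
Cohen's kappa (overall and per form group) for inter-rater agreement,
certainty-threshold accuracy/coverage sweeps, and paired bootstrap
comparison of systems with Bonferroni correction across model pairs.
A synthetic corpus generator with known ground truth, plus a deterministic
keyword-scoring mock backend with a closed-form expected accuracy, makes
the whole pipeline testable fully offline; a real language model attaches
through `function_backend()` without touching anything else.

## Worked example

```r
library(cdextract)

fx   <- cde_fixture("mammo_like")   # 20 CDEs, 2 groups, 5 sub-groups, gated findings
cfg  <- generator_config(fx, n_reports = 30, noise_rate = 0.2, seed = 7)
corp <- generate_corpus(cfg)        # synthetic reports + ground truth
bk   <- mock_backend(fx$form, fx$keyword_map, prevalence = cfg$prevalence)
pred <- classify_corpus(bk, fx$form, corp$reports, quiet = TRUE)

metrics_report(pred, corp$truth, form = fx$form, seed = 1)
#> Overall accuracy: 86.7% [95% CI 83.8-89.5] on 600 cells
#> Micro  P/R/F1: 86.7 / 86.7 / 86.7 %
#> Macro  P/R/F1: 90.8 / 73.4 / 78.2 %
#> Accuracy by group:
#>      group accuracy
#>  Anamnesis 90.66667
#>     Report 85.33333

certainty_sweep(pred, corp$truth)
#> Certainty sweep over 600 evaluated cells
#>  threshold n_covered coverage accuracy
#>      0.900       447    74.5%   100.0%
#>      0.990       447    74.5%   100.0%
#>      0.999       447    74.5%   100.0%
```

Reading the output: with a 20% chance that a report simply omits the
sentence carrying a CDE's value, the mock classifier answers 86.7% of the
600 graded cells exactly right (micro metrics coincide with accuracy
because every cell has exactly one true and one predicted label; the
macro figures weight rare categories equally). The sweep shows selective
prediction at work: the 74.5% of cells the classifier is nearly certain
about are all correct, so flagging the rest for human review would catch
every error — the mock is calibrated by construction, which is precisely
what makes it a useful test harness.

To attach a real scorer instead of the mock:

```r
llm <- function_backend(function(prompt, continuations) {
  # return one log-probability per continuation, e.g. from a locally
  # served causal LM scoring each continuation after the prompt
  my_model_logprobs(prompt, continuations)
}, name = "local-llm")
pred <- classify_corpus(llm, form, "reports.csv", variant = "adapted")
```

A command-line wrapper with `extract`, `evaluate`, `compare` and
`simulate` subcommands is installed at
`system.file("cli", "cdextract", package = "cdextract")`.

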