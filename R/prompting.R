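# Prompt templates and placeholder substitution.
#
# A template is a string carrying the placeholders [TEXT] (the report,
# required exactly once), [TOPIC] (the CDE question) and [CATEGORIES] (the
# allowed answers joined by ", " in declared order). The rendered prompt
# always ends with the answer cue so that the very next tokens a backend
# scores are the candidate category itself.

PROMPT_VARIANTS <- c("default", "adapted", "fewshot", "cot")

# Packaged default instruction: a general instruction to classify the text
# into the named topic given the possible categories. Overridable per CDE
# through the form JSON `prompts` entry.
DEFAULT_TEMPLATE_TEXT <- paste0(
  "Classify the following text with respect to the topic \"[TOPIC]\".\n",
  "Possible categories: [CATEGORIES]\n\n",
  "Text: [TEXT]\n\n",
  "The correct category is:")

COT_DIRECTIVE <- paste0(
  "Think step by step: consider each possible category in turn and what in ",
  "the text speaks for or against it before giving the answer.")

#' Create a prompt template
#'
#' @param template_text Template string; must contain `[TEXT]` exactly once.
#'   `[TOPIC]` and `[CATEGORIES]` are substituted wherever present.
#' @param variant One of `"default"`, `"adapted"`, `"fewshot"`, `"cot"`.
#' @param shots For `variant = "fewshot"` only: list of
#'   `list(text =, answer =)` worked examples, each a full report paired
#'   with its correct category. Shots travel with the template (typically
#'   from the form JSON), not sampled at run time, so rendering stays
#'   reproducible.
#' @return An object of class `"prompt_template"`.
#' @export
#' @examples
#' tpl <- prompt_template("Q: [TOPIC] ([CATEGORIES])\n[TEXT]\nA:")
#' cde <- value_list_cde("x", "Lesion mentioned?", c("yes", "no"))
#' cat(render_prompt(tpl, "No focal finding.", cde))
prompt_template <- function(template_text, variant = "default", shots = NULL) {
  variant <- match.arg(variant, PROMPT_VARIANTS)
  stopifnot(is.character(template_text), length(template_text) == 1L)
  n_text <- lengths(regmatches(template_text,
                               gregexpr("[TEXT]", template_text, fixed = TRUE)))
  if (n_text != 1L)
    stop("template must contain the placeholder [TEXT] exactly once (found ",
         n_text, ")", call. = FALSE)
  if (identical(variant, "fewshot")) {
    if (is.null(shots) || length(shots) == 0L)
      stop("fewshot template needs at least one shot", call. = FALSE)
    ok <- vapply(shots, function(s)
      is.list(s) && !is.null(s$text) && !is.null(s$answer), logical(1))
    if (!all(ok))
      stop("each shot must be list(text =, answer =)", call. = FALSE)
  } else if (!is.null(shots) && length(shots) > 0L) {
    stop("shots are only allowed for the fewshot variant", call. = FALSE)
  }
  structure(list(variant = variant, template_text = template_text,
                 shots = shots),
            class = "prompt_template")
}

#' @export
print.prompt_template <- function(x, ...) {
  cat("<prompt_template: ", x$variant,
      if (length(x$shots)) paste0(", ", length(x$shots), " shot(s)"),
      ">\n", sep = "")
  cat(x$template_text, "\n")
  invisible(x)
}

#' The built-in default classification template
#'
#' A general instruction to classify the report into the named topic given
#' the possible categories, ending with an answer cue.
#' @return A `"prompt_template"` of variant `"default"`.
#' @export
default_template <- function() prompt_template(DEFAULT_TEMPLATE_TEXT, "default")

#' Build an adapted question-answer template
#'
#' Mimics a question-answer dialog with four labelled sections in fixed
#' order -- INSTRUCTION, QUESTION, TEXT (the `[TEXT]` placeholder), ANSWER --
#' where the ANSWER cue terminates the prompt and provides the direct
#' context in which the candidate categories are scored.
#'
#' @param question The classification question for this CDE.
#' @param instruction Task instruction, e.g. that the question is to be
#'   answered from the report text alone.
#' @return A `"prompt_template"` of variant `"adapted"`.
#' @export
#' @examples
#' adapted_template("Lesion mentioned?")
adapted_template <- function(question,
                             instruction = paste(
                               "Answer the question based only on the",
                               "information in the following report.")) {
  stopifnot(is.character(question), length(question) == 1L, nzchar(question))
  prompt_template(
    paste0("INSTRUCTION: ", instruction, "\n",
           "QUESTION: ", question, "\n",
           "TEXT: [TEXT]\n",
           "ANSWER:"),
    variant = "adapted")
}

#' Derive a chain-of-thought template from a base template
#'
#' Augments the base template's instruction with an explicit step-by-step
#' reasoning directive placed before the answer cue. Candidate categories
#' are still scored directly after the cue; the directive changes the
#' context in which they are scored, not the selection mechanism.
#'
#' @param base A `"prompt_template"` that is not already chain-of-thought.
#' @return A `"prompt_template"` of variant `"cot"`.
#' @export
cot_template <- function(base) {
  stopifnot(inherits(base, "prompt_template"))
  if (identical(base$variant, "cot"))
    stop("template is already a chain-of-thought template", call. = FALSE)
  txt <- base$template_text
  # insert the directive on its own line immediately before the final
  # answer-cue line
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  cue <- length(lines)
  txt <- paste(c(lines[seq_len(cue - 1L)], COT_DIRECTIVE, lines[cue]),
               collapse = "\n")
  prompt_template(txt, variant = "cot")
}

#' Render the classification prompt for one (report, CDE) pair
#'
#' Substitutes `[TEXT]` with the report, `[TOPIC]` with the CDE question and
#' `[CATEGORIES]` with the categories joined by `", "` in declared order.
#' For a few-shot template every shot is rendered first using the same
#' layout, each followed by its answer, then the query report. Rendering is
#' pure: identical inputs give byte-identical output, and no placeholder
#' survives in the result.
#'
#' @param template A `"prompt_template"`.
#' @param report_text Non-empty report text.
#' @param cde The [value_list_cde()] being classified.
#' @return The prompt string, ending with the answer cue.
#' @export
render_prompt <- function(template, report_text, cde) {
  stopifnot(inherits(template, "prompt_template"),
            inherits(cde, "value_list_cde"))
  if (!is.character(report_text) || length(report_text) != 1L ||
      !nzchar(report_text))
    stop("report_text must be a non-empty string", call. = FALSE)
  fill <- function(txt, body) {
    txt <- sub("[TEXT]", body, txt, fixed = TRUE)
    txt <- gsub("[TOPIC]", cde$question, txt, fixed = TRUE)
    gsub("[CATEGORIES]", paste(cde$categories, collapse = ", "), txt,
         fixed = TRUE)
  }
  parts <- character()
  for (s in template$shots)
    parts <- c(parts, paste0(fill(template$template_text, s$text), " ",
                             s$answer))
  paste(c(parts, fill(template$template_text, report_text)),
        collapse = "\n\n")
}

# Resolve the template used for a CDE under a named variant: a per-CDE
# override from the form JSON wins; otherwise the built-in construction for
# that variant. fewshot has no built-in fallback (shots must be supplied).
resolve_template <- function(cde, variant) {
  variant <- match.arg(variant, PROMPT_VARIANTS)
  ov <- cde$prompts[[variant]]
  if (!is.null(ov)) {
    if (is.character(ov)) return(prompt_template(ov, variant))
    return(prompt_template(ov$template, variant,
                           shots = lapply(ov$shots, function(s)
                             list(text = s$text, answer = s$answer))))
  }
  switch(variant,
    default = default_template(),
    adapted = adapted_template(cde$question),
    cot     = cot_template(adapted_template(cde$question)),
    fewshot = stop("CDE '", cde$id,
                   "': fewshot variant requires shots in the form's ",
                   "'prompts' entry", call. = FALSE))
}
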