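# Scoring backends.
#
# A backend scores candidate continuations of a prompt: it returns one
# finite log-probability (<= 0) per continuation, the log of the joint
# probability of that continuation's token sequence following the prompt.
# Backends must be deterministic for a fixed state -- identical arguments
# give identical values -- which is what makes every downstream artifact
# reproducible. The generic carries an optional `context` (report_id,
# cde_id) that backends may use as a stable key; language-model style
# backends ignore it.

#' Score continuations of a prompt under a backend
#'
#' @param backend A scoring backend (see [mock_backend()],
#'   [replay_backend()], [function_backend()]).
#' @param prompt The rendered prompt string.
#' @param continuations Character vector of candidate continuations (the
#'   category strings, each scored with a single leading space appended to
#'   the prompt's answer cue).
#' @param context Optional list with elements such as `report_id`, `cde_id`
#'   identifying the classification instance.
#' @return Numeric vector of log-probabilities, same length as
#'   `continuations`, all finite and `<= 0`. May carry an attribute
#'   `n_tokens` (integer vector) giving each continuation's token count,
#'   enabling length-normalised scoring.
#' @export
backend_score <- function(backend, prompt, continuations, context = NULL) {
  UseMethod("backend_score")
}

#' @export
backend_score.default <- function(backend, prompt, continuations,
                                  context = NULL) {
  stop("not a scoring backend: ", paste(class(backend), collapse = "/"),
       call. = FALSE)
}

backend_name <- function(backend) backend$name %||% class(backend)[[1L]]

new_backend <- function(x, class) {
  structure(x, class = c(class, "cde_backend"))
}

#' @export
print.cde_backend <- function(x, ...) {
  cat("<scoring backend: ", backend_name(x), ">\n", sep = "")
  invisible(x)
}

#' Deterministic keyword-matching mock backend
#'
#' A fully offline stand-in for a language model, built for testing and
#' simulation studies: the log-probability of a category is `-1 - penalty`,
#' where the penalty is 0 when one of the category's trigger phrases (from
#' the synthetic corpus vocabulary) occurs in the prompt, and
#' `miss_penalty + rank_step * (rank - 1)` otherwise, with categories ranked
#' by decreasing prevalence (ties by declared order). A report that carries
#' the signal phrase is therefore classified correctly with near-1
#' certainty, while a report without any signal falls back, with low
#' certainty, to the most prevalent category -- a crude but analytically
#' tractable emulation of a calibrated classifier.
#'
#' @param form The [cde_form()] the backend will be asked about.
#' @param keyword_map Named list: `keyword_map[[cde_id]][[category]]` is a
#'   character vector of trigger phrases.
#' @param prevalence Optional named list: `prevalence[[cde_id]]` is a named
#'   probability vector over that CDE's categories; uniform when omitted.
#'   Only the induced ranking is used.
#' @param miss_penalty Penalty added when no trigger phrase matches;
#'   controls how certain phrase-backed decisions are relative to fallback
#'   guesses.
#' @param rank_step Penalty increment between successive fallback ranks.
#' @return A scoring backend.
#' @export
mock_backend <- function(form, keyword_map, prevalence = NULL,
                         miss_penalty = 8, rank_step = 0.1) {
  stopifnot(inherits(form, "cde_form"))
  check_keyword_map(form, keyword_map)
  new_backend(list(name = "mock", form = form, keyword_map = keyword_map,
                   prevalence = prevalence, miss_penalty = miss_penalty,
                   rank_step = rank_step),
              "mock_backend")
}

check_keyword_map <- function(form, keyword_map) {
  for (cde in form$cdes) {
    km <- keyword_map[[cde$id]]
    if (is.null(km))
      stop("keyword_map has no entry for cde '", cde$id, "'", call. = FALSE)
    for (cat in cde$categories)
      if (length(km[[cat]]) < 1L)
        stop("keyword_map[['", cde$id, "']] has no trigger phrase for ",
             "category '", cat, "'", call. = FALSE)
  }
  all_phrases <- unlist(keyword_map, use.names = FALSE)
  if (anyDuplicated(all_phrases))
    warning("trigger phrases are shared between categories; ",
            "mock scoring may be ambiguous", call. = FALSE)
  invisible(TRUE)
}

# ranking of a CDE's categories by decreasing prevalence, ties by declared
# order; returns integer ranks aligned with cde$categories
fallback_ranks <- function(cde, prevalence) {
  pv <- prevalence[[cde$id]]
  p <- rep(1 / length(cde$categories), length(cde$categories))
  names(p) <- cde$categories
  if (!is.null(pv)) p[names(pv)] <- pv
  ord <- order(-p, seq_along(p))
  ranks <- integer(length(p))
  ranks[ord] <- seq_along(p)
  ranks
}

#' @export
backend_score.mock_backend <- function(backend, prompt, continuations,
                                       context = NULL) {
  cde_id <- context$cde_id
  if (is.null(cde_id)) {
    # fall back to locating the CDE by its question text in the prompt
    qs <- vapply(backend$form$cdes, `[[`, character(1), "question")
    hit <- which(vapply(qs, function(q) grepl(q, prompt, fixed = TRUE),
                        logical(1)))
    if (length(hit) != 1L)
      stop("mock backend cannot identify the CDE from the prompt; ",
           "pass context$cde_id", call. = FALSE)
    cde_id <- cde_ids(backend$form)[hit]
  }
  cde <- get_cde(backend$form, cde_id)
  km <- backend$keyword_map[[cde_id]]
  ranks <- fallback_ranks(cde, backend$prevalence)
  vapply(seq_along(continuations), function(i) {
    cat_i <- sub("^ ", "", continuations[[i]])  # leading-space convention
    phrases <- km[[cat_i]]
    hit <- any(vapply(phrases, function(ph) grepl(ph, prompt, fixed = TRUE),
                      logical(1)))
    if (hit) -1
    else {
      r <- ranks[match(cat_i, cde$categories)]
      if (is.na(r)) r <- length(cde$categories) + 1L
      -1 - backend$miss_penalty - backend$rank_step * (r - 1L)
    }
  }, numeric(1))
}

#' Replay backend over recorded scores
#'
#' Reproduces a previous run exactly from its recorded per-category
#' log-probabilities (the sidecar scores written by [classify_corpus()]).
#' Swapping the original backend for a replay of its own scores yields a
#' byte-identical prediction table, which is the package's backend-exchange
#' audit check.
#'
#' @param scores A data frame with columns `report_id`, `cde_id`,
#'   `category`, `log_prob` (as returned by [read_scores()]).
#' @return A scoring backend.
#' @export
replay_backend <- function(scores) {
  need <- c("report_id", "cde_id", "category", "log_prob")
  if (!is.data.frame(scores) || !all(need %in% names(scores)))
    stop("scores must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  new_backend(list(name = "replay", scores = scores), "replay_backend")
}

#' @export
backend_score.replay_backend <- function(backend, prompt, continuations,
                                         context = NULL) {
  if (is.null(context$report_id) || is.null(context$cde_id))
    stop("replay backend requires context$report_id and context$cde_id",
         call. = FALSE)
  s <- backend$scores
  rows <- s$report_id == context$report_id & s$cde_id == context$cde_id
  lp <- s$log_prob[rows][match(sub("^ ", "", continuations),
                               s$category[rows])]
  if (anyNA(lp))
    stop("replay backend has no recorded score for (",
         context$report_id, ", ", context$cde_id, ")", call. = FALSE)
  lp
}

#' Wrap an arbitrary scoring function as a backend
#'
#' The adapter through which any external scorer -- including a locally
#' served causal language model computing continuation log-probabilities by
#' teacher forcing -- plugs into the classifier. The function must be
#' deterministic and return one finite log-probability `<= 0` per
#' continuation.
#'
#' @param fn `function(prompt, continuations)` (a `context` argument is
#'   passed on if `fn` accepts one) returning a numeric vector of
#'   log-probabilities.
#' @param name Identifier used in error messages and run manifests.
#' @return A scoring backend.
#' @export
#' @examples
#' # a toy backend preferring shorter categories
#' b <- function_backend(function(prompt, continuations)
#'   -nchar(continuations), name = "short-wins")
#' backend_score(b, "Q: size?\nA:", c("big", "smaller"))
function_backend <- function(fn, name = "function") {
  stopifnot(is.function(fn))
  new_backend(list(name = name, fn = fn), "function_backend")
}

#' @export
backend_score.function_backend <- function(backend, prompt, continuations,
                                           context = NULL) {
  if ("context" %in% names(formals(backend$fn)))
    backend$fn(prompt, continuations, context = context)
  else backend$fn(prompt, continuations)
}
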