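# Probability-based category selection and corpus traversal.

#' Score a CDE's categories as continuations of a prompt
#'
#' Obtains one log-probability per category from the backend (each category
#' scored as `" <category>"`, with the single leading space that most
#' tokenizers fold into the first token) and converts them to relative
#' probabilities with a numerically stable softmax (shift by the maximum in
#' log space). The relative probability of the selected category is the
#' model's *certainty* for the classification.
#'
#' @inheritParams backend_score
#' @param categories Ordered character vector of candidate categories.
#' @param length_normalize If `TRUE` and the backend reports per-
#'   continuation token counts (attribute `n_tokens`), each log-probability
#'   is divided by its token count before normalisation, removing the
#'   penalty that joint sequence probability puts on longer category
#'   strings.
#' @return A data frame with columns `category`, `log_prob`, `rel_prob`
#'   (rows in input order; `rel_prob` sums to 1).
#' @export
#' @examples
#' b <- function_backend(function(p, k) log(c(0.02, 0.01, 0.01)))
#' score_categories(b, "T: x\nA:", c("a", "b", "c"))
score_categories <- function(backend, prompt, categories, context = NULL,
                             length_normalize = FALSE) {
  if (length(categories) < 1L)
    stop("need at least one category", call. = FALSE)
  if (!is.character(prompt) || length(prompt) != 1L || !nzchar(prompt))
    stop("prompt must be a non-empty string", call. = FALSE)
  lp <- tryCatch(
    backend_score(backend, prompt, paste0(" ", categories), context = context),
    error = function(e)
      stop("backend '", backend_name(backend), "' failed: ",
           conditionMessage(e), call. = FALSE))
  if (length(lp) != length(categories))
    stop("backend '", backend_name(backend), "' returned ", length(lp),
         " scores for ", length(categories), " categories", call. = FALSE)
  if (any(!is.finite(lp)))
    stop("backend '", backend_name(backend),
         "' returned non-finite log-probabilities", call. = FALSE)
  if (length_normalize) {
    nt <- attr(lp, "n_tokens")
    if (is.null(nt))
      stop("backend '", backend_name(backend),
           "' reports no token counts; cannot length-normalize",
           call. = FALSE)
    lp <- lp / pmax(nt, 1L)
  }
  lp <- as.numeric(lp)
  rel <- exp(lp - max(lp))
  rel <- rel / sum(rel)
  data.frame(category = as.character(categories), log_prob = lp,
             rel_prob = rel, stringsAsFactors = FALSE)
}

#' Classify one report against one CDE
#'
#' Renders the prompt for the (report, CDE) pair, scores every allowed
#' category, and selects the one with the highest relative probability; an
#' exact tie is broken in favour of the earliest tied category in the CDE's
#' declared order. Wall-clock time for the call is recorded.
#'
#' @inheritParams score_categories
#' @param report_text The report's free text.
#' @param cde A [value_list_cde()].
#' @param template A `"prompt_template"`; defaults to the CDE's resolved
#'   default-variant template.
#' @param report_id Identifier carried into the result.
#' @return A list of class `"cde_classification"` with elements `report_id`,
#'   `cde_id`, `applicable`, `selected`, `certainty`, `scores` (the
#'   [score_categories()] frame) and `elapsed_seconds`.
#' @export
classify_cde <- function(backend, report_text, cde,
                         template = resolve_template(cde, "default"),
                         report_id = NA_character_,
                         length_normalize = FALSE) {
  stopifnot(inherits(cde, "value_list_cde"))
  t0 <- proc.time()[["elapsed"]]
  prompt <- render_prompt(template, report_text, cde)
  scores <- withCallingHandlers(
    score_categories(backend, prompt, cde$categories,
                     context = list(report_id = report_id, cde_id = cde$id),
                     length_normalize = length_normalize),
    error = function(e) {
      stop("classification failed for (report '", report_id, "', cde '",
           cde$id, "'): ", conditionMessage(e), call. = FALSE)
    })
  win <- which.max(scores$rel_prob)  # first maximum = declared-order tie-break
  structure(
    list(report_id = report_id, cde_id = cde$id, applicable = TRUE,
         selected = scores$category[[win]],
         certainty = scores$rel_prob[[win]], scores = scores,
         elapsed_seconds = proc.time()[["elapsed"]] - t0),
    class = "cde_classification")
}

#' @export
print.cde_classification <- function(x, ...) {
  if (x$applicable)
    cat(sprintf("[%s | %s] -> %s (certainty %.4f, %.3fs)\n",
                x$report_id, x$cde_id, x$selected, x$certainty,
                x$elapsed_seconds))
  else
    cat(sprintf("[%s | %s] -> %s (gate closed)\n",
                x$report_id, x$cde_id, cde_na_marker()))
  invisible(x)
}

#' Classify one report against every CDE of a form
#'
#' Traverses the form in declared order. A gated CDE is scored only if the
#' value *selected* for its parent activates the gate; otherwise it is
#' emitted as not applicable, with the not-applicable marker as its value
#' and no category scores. A not-applicable result inherits the certainty
#' of the gating parent's selection, so that selective-prediction sweeps
#' have a certainty for every cell: the confidence that a child does not
#' apply is exactly the confidence in the parent value that closed its
#' gate.
#'
#' @inheritParams classify_cde
#' @param form A [cde_form()].
#' @param variant Prompt variant: `"default"`, `"adapted"`, `"fewshot"` or
#'   `"cot"`.
#' @return List of `"cde_classification"` objects, one per CDE in form
#'   order.
#' @export
classify_report <- function(backend, form, report_text,
                            report_id = NA_character_, variant = "default",
                            length_normalize = FALSE) {
  stopifnot(inherits(form, "cde_form"))
  selected <- character(0)
  certainty <- numeric(0)
  out <- vector("list", length(form$cdes))
  for (i in seq_along(form$cdes)) {
    cde <- form$cdes[[i]]
    open <- is.null(cde$gate) ||
      (cde$gate$parent %in% names(selected) &&
         selected[[cde$gate$parent]] %in% cde$gate$values)
    if (open) {
      res <- classify_cde(backend, report_text, cde,
                          template = resolve_template(cde, variant),
                          report_id = report_id,
                          length_normalize = length_normalize)
    } else {
      res <- structure(
        list(report_id = report_id, cde_id = cde$id, applicable = FALSE,
             selected = cde_na_marker(),
             certainty = certainty[[cde$gate$parent]],
             scores = data.frame(category = character(), log_prob = numeric(),
                                 rel_prob = numeric()),
             elapsed_seconds = 0),
        class = "cde_classification")
    }
    selected[[cde$id]] <- res$selected
    certainty[[cde$id]] <- res$certainty
    out[[i]] <- res
  }
  out
}

#' Classify a whole corpus of reports
#'
#' Runs [classify_report()] over every row of a report table and assembles
#' the full report-by-CDE prediction grid. Per-report and total elapsed
#' times are reported through `message()`, mirroring a per-document
#' extraction log.
#'
#' @inheritParams classify_report
#' @param reports Either a data frame with columns `report_id`, `text`, or
#'   a path to a CSV file with those columns (see [read_reports()]).
#' @param output_path Optional path; when given, the prediction grid is
#'   written there as CSV.
#' @param scores_path Optional path; when given, the full per-category
#'   scores are recorded there as JSON, from which [replay_backend()] can
#'   reproduce the run.
#' @param quiet Suppress the timing log.
#' @return A `"cde_predictions"` data frame with columns `report_id`,
#'   `cde_id`, `applicable`, `selected`, `certainty`, carrying the per-
#'   report timings in attribute `"timing"`.
#' @export
classify_corpus <- function(backend, form, reports, variant = "default",
                            output_path = NULL, scores_path = NULL,
                            length_normalize = FALSE, quiet = FALSE) {
  if (is.character(reports)) reports <- read_reports(reports)
  check_reports(reports)
  if (nrow(reports) == 0L)
    warning("report table is empty; emitting an empty grid", call. = FALSE)
  rows <- vector("list", nrow(reports))
  score_rec <- vector("list", nrow(reports))
  total0 <- proc.time()[["elapsed"]]
  for (r in seq_len(nrow(reports))) {
    rid <- reports$report_id[[r]]
    res <- classify_report(backend, form, reports$text[[r]], report_id = rid,
                           variant = variant,
                           length_normalize = length_normalize)
    secs <- sum(vapply(res, `[[`, numeric(1), "elapsed_seconds"))
    if (!quiet)
      message(sprintf("report %s: %d CDEs in %.3fs", rid, length(res), secs))
    rows[[r]] <- data.frame(
      report_id = rid,
      cde_id = vapply(res, `[[`, character(1), "cde_id"),
      applicable = vapply(res, `[[`, logical(1), "applicable"),
      selected = vapply(res, `[[`, character(1), "selected"),
      certainty = vapply(res, `[[`, numeric(1), "certainty"),
      stringsAsFactors = FALSE)
    score_rec[[r]] <- lapply(res[vapply(res, `[[`, logical(1), "applicable")],
      function(x) list(report_id = x$report_id, cde_id = x$cde_id,
                       category = x$scores$category,
                       log_prob = x$scores$log_prob))
    rows[[r]]$seconds <- secs / length(res)
  }
  grid <- if (length(rows)) do.call(rbind, rows) else
    data.frame(report_id = character(), cde_id = character(),
               applicable = logical(), selected = character(),
               certainty = numeric(), seconds = numeric())
  timing <- data.frame(
    report_id = reports$report_id,
    seconds = if (length(rows))
      vapply(rows, function(d) sum(d$seconds), numeric(1)) else numeric())
  grid$seconds <- NULL
  if (!quiet)
    message(sprintf("corpus: %d reports x %d CDEs in %.3fs",
                    nrow(reports), length(form$cdes),
                    proc.time()[["elapsed"]] - total0))
  grid <- structure(grid, class = c("cde_predictions", "data.frame"),
                    timing = timing, form_id = form$form_id,
                    variant = variant)
  if (!is.null(scores_path))
    write_scores(do.call(c, score_rec), scores_path)
  if (!is.null(output_path)) write_predictions(grid, output_path)
  grid
}

#' @export
print.cde_predictions <- function(x, ...) {
  cat("CDE predictions: ", length(unique(x$report_id)), " report(s) x ",
      length(unique(x$cde_id)), " CDE(s), form '",
      attr(x, "form_id") %||% "?", "', variant '",
      attr(x, "variant") %||% "?", "'\n", sep = "")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

# ---- table I/O -------------------------------------------------------------

check_reports <- function(reports) {
  if (!is.data.frame(reports) ||
      !all(c("report_id", "text") %in% names(reports)))
    stop("reports need columns 'report_id' and 'text'", call. = FALSE)
  if (anyDuplicated(reports$report_id))
    stop("duplicate report_id values", call. = FALSE)
  invisible(reports)
}

#' Read a report corpus from CSV
#'
#' @param path CSV file with columns `report_id`, `text` (UTF-8).
#' @return Data frame with those columns; ids are checked for uniqueness.
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) stop("reports file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  check_reports(df)
}

#' Write / read a prediction grid as CSV
#'
#' The grid format is `report_id,cde_id,applicable,selected,certainty`, one
#' row per (report, CDE) cell.
#' @param pred A `"cde_predictions"` data frame.
#' @param path Output (input) CSV path.
#' @return `path` invisibly; for the reader, the grid.
#' @export
write_predictions <- function(pred, path) {
  utils::write.csv(as.data.frame(pred)[, c("report_id", "cde_id",
                                           "applicable", "selected",
                                           "certainty")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = c(report_id = "character",
                                       cde_id = "character",
                                       applicable = "logical",
                                       selected = "character",
                                       certainty = "numeric"))
  structure(df, class = c("cde_predictions", "data.frame"))
}

#' Read a ground-truth value grid from CSV
#'
#' @param path CSV with columns `report_id`, `cde_id`, `value`; empty value
#'   cells are read as `NA` (missing ground truth, excluded from metrics).
#' @return Data frame with those columns.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  if (!all(c("report_id", "cde_id", "value") %in% names(df)))
    stop("truth needs columns report_id, cde_id, value", call. = FALSE)
  df$value[!nzchar(df$value)] <- NA_character_
  df
}

#' @rdname read_truth
#' @param truth Truth data frame to write.
#' @export
write_truth <- function(truth, path) {
  out <- truth[, c("report_id", "cde_id", "value")]
  out$value[is.na(out$value)] <- ""
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Record / load per-category scores
#'
#' The sidecar JSON written by [classify_corpus()]: one record per scored
#' (report, CDE) with the categories and their raw log-probabilities.
#' @param records List of score records (internal form).
#' @param path JSON path.
#' @return For the reader, a data frame with columns `report_id`, `cde_id`,
#'   `category`, `log_prob` suitable for [replay_backend()].
#' @export
write_scores <- function(records, path) {
  jsonlite::write_json(unname(records %||% list()), path,
                       auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  do.call(rbind, lapply(recs, function(r)
    data.frame(report_id = r$report_id, cde_id = r$cde_id,
               category = unlist(r$category, use.names = FALSE),
               log_prob = as.numeric(unlist(r$log_prob, use.names = FALSE)),
               stringsAsFactors = FALSE)))
}
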