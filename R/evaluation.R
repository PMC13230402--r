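# Evaluation of prediction grids against ground truth: exact-match
# accuracy, micro/macro precision-recall-F1, Cohen's kappa,
# certainty-threshold sweeps.
#
# All metrics are computed cell by cell over the aligned (report, CDE)
# grid, excluding cells where the ground truth is missing (NA). Cells whose
# truth is the not-applicable marker are, by default, included and graded
# as exact matches against a predicted not-applicable -- so a wrong parent
# prediction propagates its penalty to every descendant cell; set
# na_mode = "exclude" to grade applicable cells only.

# Align a prediction grid to a truth grid on (report_id, cde_id), keeping
# the truth's row order (so that resampling depends only on row positions,
# never on identifier labels). Returns parallel vectors.
align_cells <- function(pred, truth, require_certainty = FALSE) {
  for (nm in c("report_id", "cde_id"))
    if (!nm %in% names(pred) || !nm %in% names(truth))
      stop("grids need report_id and cde_id columns", call. = FALSE)
  pv <- if ("selected" %in% names(pred)) pred$selected else pred$value
  if (is.null(pv)) stop("prediction grid needs 'selected' or 'value'",
                        call. = FALSE)
  tk <- paste(truth$report_id, truth$cde_id, sep = "\r")
  pk <- paste(pred$report_id, pred$cde_id, sep = "\r")
  if (anyDuplicated(tk)) stop("duplicate cells in truth grid", call. = FALSE)
  if (anyDuplicated(pk)) stop("duplicate cells in prediction grid",
                              call. = FALSE)
  if (length(tk) != length(pk) || !all(tk %in% pk))
    stop("prediction and truth grids do not share the same ",
         "(report, CDE) index set", call. = FALSE)
  m <- match(tk, pk)
  cert <- if ("certainty" %in% names(pred)) pred$certainty[m] else NULL
  if (require_certainty && (is.null(cert) || anyNA(cert)))
    stop("every predicted cell needs a certainty for this analysis",
         call. = FALSE)
  list(report_id = truth$report_id, cde_id = truth$cde_id,
       pred = as.character(pv[m]), truth = as.character(truth$value),
       certainty = cert)
}

included_mask <- function(cells, na_mode = c("include", "exclude")) {
  na_mode <- match.arg(na_mode)
  inc <- !is.na(cells$truth)
  if (na_mode == "exclude")
    inc <- inc & cells$truth != cde_na_marker()
  inc
}

#' Exact-match overall accuracy
#'
#' The proportion of evaluable (report, CDE) cells whose predicted value
#' equals the ground-truth value exactly. Cells without ground truth are
#' excluded; a closed gate predicted as closed (both not-applicable) counts
#' as correct under the default `na_mode = "include"`.
#'
#' @param pred Prediction grid ([classify_corpus()] output or any data
#'   frame with `report_id`, `cde_id` and `selected`/`value`).
#' @param truth Truth grid with columns `report_id`, `cde_id`, `value`
#'   (`NA` = missing ground truth).
#' @param na_mode `"include"` grades truth-not-applicable cells;
#'   `"exclude"` drops them.
#' @return List with `accuracy` (percent), `n_evaluated`, `n_correct`.
#' @export
overall_accuracy <- function(pred, truth, na_mode = "include") {
  cells <- align_cells(pred, truth)
  inc <- included_mask(cells, na_mode)
  if (!any(inc))
    stop("no cells with ground truth: overall accuracy is undefined",
         call. = FALSE)
  correct <- cells$pred[inc] == cells$truth[inc]
  list(accuracy = 100 * mean(correct), n_evaluated = sum(inc),
       n_correct = sum(correct))
}

# one-vs-rest confusion counts per class over parallel label vectors
class_counts <- function(pred, truth) {
  classes <- sort(unique(c(pred, truth)))
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (k in classes) {
    tp[[k]] <- sum(pred == k & truth == k)
    fp[[k]] <- sum(pred == k & truth != k)
    fn[[k]] <- sum(pred != k & truth == k)
  }
  list(classes = classes, tp = tp, fp = fp, fn = fn)
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Micro- and macro-averaged precision, recall and F1
#'
#' One-vs-rest true/false positives and false negatives are counted per
#' class over all evaluable cells of all CDEs combined (the class universe
#' is every value observed in truth or prediction). Micro-averaging pools
#' the counts globally before computing the metrics, weighting frequent
#' classes more; macro-averaging computes the metrics per class and
#' averages them unweighted, treating rare and frequent classes equally.
#' Because every cell carries exactly one predicted and one true label, the
#' micro-averaged precision, recall and F1 all coincide with overall
#' accuracy.
#'
#' @inheritParams overall_accuracy
#' @return List with elements `micro` and `macro` (each a named vector
#'   `precision`, `recall`, `f1`, in percent), `n_evaluated` and `classes`.
#' @export
micro_macro_metrics <- function(pred, truth, na_mode = "include") {
  cells <- align_cells(pred, truth)
  inc <- included_mask(cells, na_mode)
  if (!any(inc))
    stop("no cells with ground truth: metrics are undefined", call. = FALSE)
  cc <- class_counts(cells$pred[inc], cells$truth[inc])
  micro <- prf(sum(cc$tp), sum(cc$fp), sum(cc$fn))
  per_class <- vapply(cc$classes, function(k)
    prf(cc$tp[[k]], cc$fp[[k]], cc$fn[[k]]), numeric(3))
  macro <- rowMeans(per_class)
  list(micro = 100 * micro, macro = 100 * macro,
       n_evaluated = sum(inc), classes = cc$classes)
}

#' Cohen's kappa between two categorical raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, where
#' `p_o` is the observed proportion of agreeing cells and `p_e` the
#' agreement expected by chance from the two raters' marginal value
#' distributions, pooled over all cells rated by both. When a form is
#' supplied, kappa is additionally reported per main group and sub-group.
#'
#' @param rater_a,rater_b Value grids (columns `report_id`, `cde_id`,
#'   `value` or `selected`); cells missing (`NA`) in either rater are
#'   excluded.
#' @param form Optional [cde_form()] for the per-group breakdown.
#' @param na_mode As in [overall_accuracy()].
#' @return List with `kappa`, `p_o`, `p_e`, `n`, and (with a form)
#'   `by_group`: a data frame of per-(sub-)group kappas.
#' @export
#' @examples
#' a <- data.frame(report_id = 1:4, cde_id = "x", value = c("a","a","b","b"))
#' b <- data.frame(report_id = 1:4, cde_id = "x", value = c("a","b","a","b"))
#' cohens_kappa(a, b)$kappa   # 0: agreement equals chance
cohens_kappa <- function(rater_a, rater_b, form = NULL,
                         na_mode = "include") {
  bt <- rater_b
  if (!"value" %in% names(bt)) bt$value <- bt$selected
  cells <- align_cells(rater_a, bt)
  inc <- included_mask(cells, na_mode) & !is.na(cells$pred)
  kappa_of <- function(a, b) {
    n <- length(a)
    if (n == 0L) return(list(kappa = NA_real_, p_o = NA_real_,
                             p_e = NA_real_, n = 0L))
    p_o <- mean(a == b)
    vals <- union(a, b)
    p_e <- sum(vapply(vals, function(v) mean(a == v) * mean(b == v),
                      numeric(1)))
    if (1 - p_e < .Machine$double.eps) {
      if (p_o == 1) return(list(kappa = 1, p_o = p_o, p_e = p_e, n = n))
      stop("kappa undefined: chance agreement is 1 but observed is not",
           call. = FALSE)
    }
    list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e, n = n)
  }
  out <- kappa_of(cells$pred[inc], cells$truth[inc])
  if (!is.null(form)) {
    gp <- lapply(form$cdes, `[[`, "group_path")
    names(gp) <- cde_ids(form)
    rows <- list()
    groups <- c(lapply(names(form$groups), function(g) list(level = "group",
                                                            path = g)),
                unlist(lapply(names(form$groups), function(g)
                  lapply(form$groups[[g]], function(s)
                    list(level = "subgroup", path = c(g, s)))),
                  recursive = FALSE))
    for (grp in groups) {
      ids <- names(gp)[vapply(gp, function(p)
        length(p) >= length(grp$path) &&
          identical(p[seq_along(grp$path)], grp$path), logical(1))]
      sel <- inc & cells$cde_id %in% ids
      if (!any(sel)) next
      k <- tryCatch(kappa_of(cells$pred[sel], cells$truth[sel]),
                    error = function(e) list(kappa = NA_real_, n = sum(sel)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = paste(grp$path, collapse = "/"), level = grp$level,
        kappa = k$kappa, n = k$n, stringsAsFactors = FALSE)
    }
    out$by_group <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  out
}

#' Accuracy/coverage sweep over certainty thresholds
#'
#' Selective prediction: for each threshold `t`, only cells whose certainty
#' (the selected category's relative probability) strictly exceeds `t` are
#' retained ("covered"), and exact-match accuracy is computed on those.
#' The coverage rate is the fraction of evaluable cells retained; it is
#' non-increasing in the threshold, while accuracy typically rises --
#' trading completeness of the extraction for reliability.
#'
#' @inheritParams overall_accuracy
#' @param thresholds Certainty thresholds as fractions.
#' @return A `"cde_sweep"` data frame with columns `threshold`,
#'   `n_covered`, `coverage` (percent), `accuracy` (percent on covered
#'   cells; `NA` when coverage is zero).
#' @export
certainty_sweep <- function(pred, truth, thresholds = c(0.9, 0.99, 0.999),
                            na_mode = "include") {
  cells <- align_cells(pred, truth, require_certainty = TRUE)
  inc <- included_mask(cells, na_mode)
  if (!any(inc))
    stop("no cells with ground truth", call. = FALSE)
  n_inc <- sum(inc)
  rows <- lapply(thresholds, function(t) {
    cov <- inc & cells$certainty > t
    data.frame(
      threshold = t, n_covered = sum(cov),
      coverage = 100 * sum(cov) / n_inc,
      accuracy = if (any(cov))
        100 * mean(cells$pred[cov] == cells$truth[cov]) else NA_real_)
  })
  structure(do.call(rbind, rows), class = c("cde_sweep", "data.frame"),
            n_evaluated = n_inc)
}

#' @export
print.cde_sweep <- function(x, ...) {
  cat("Certainty sweep over", attr(x, "n_evaluated"), "evaluated cells\n")
  df <- as.data.frame(x)
  df$coverage <- sprintf("%.1f%%", df$coverage)
  df$accuracy <- ifelse(is.na(df$accuracy), "undefined",
                        sprintf("%.1f%%", df$accuracy))
  print(df, row.names = FALSE)
  invisible(x)
}

# ---- metric registry (shared with the bootstrap machinery) ----------------

# each metric maps parallel included pred/truth label vectors to a scalar %
metric_fun <- function(metric) {
  switch(metric,
    overall_accuracy = function(p, t) 100 * mean(p == t),
    micro_precision = ,
    micro_recall = ,
    micro_f1 = function(p, t) {
      cc <- class_counts(p, t)
      100 * prf(sum(cc$tp), sum(cc$fp),
                sum(cc$fn))[[sub("micro_", "", metric)]]
    },
    macro_precision = ,
    macro_recall = ,
    macro_f1 = function(p, t) {
      cc <- class_counts(p, t)
      per <- vapply(cc$classes, function(k)
        prf(cc$tp[[k]], cc$fp[[k]], cc$fn[[k]]), numeric(3))
      100 * rowMeans(per)[[sub("macro_", "", metric)]]
    },
    stop("unknown metric: ", metric, call. = FALSE))
}

EVAL_METRICS <- c("overall_accuracy", "micro_precision", "micro_recall",
                  "micro_f1", "macro_precision", "macro_recall", "macro_f1")

#' Full metrics report for one prediction grid
#'
#' Computes overall accuracy (with a percentile bootstrap confidence
#' interval), micro/macro precision, recall and F1, and per-group and
#' per-CDE accuracies when a form is supplied.
#'
#' @inheritParams overall_accuracy
#' @param form Optional [cde_form()] for group breakdowns.
#' @param iterations Bootstrap iterations for the confidence interval.
#' @param conf_level Confidence level for the percentile interval.
#' @param seed Integer seed for the bootstrap resamples.
#' @return An object of class `"cde_metrics"`.
#' @export
metrics_report <- function(pred, truth, form = NULL, na_mode = "include",
                           iterations = 2000, conf_level = 0.95, seed = 1) {
  cells <- align_cells(pred, truth)
  inc <- included_mask(cells, na_mode)
  if (!any(inc)) stop("no cells with ground truth", call. = FALSE)
  p <- cells$pred[inc]; t <- cells$truth[inc]
  acc <- 100 * mean(p == t)
  mm <- micro_macro_metrics(pred, truth, na_mode = na_mode)
  boot <- local({
    n <- length(p)
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    vapply(seq_len(iterations), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      100 * mean(p[idx] == t[idx])
    }, numeric(1))
  })
  ci <- unname(stats::quantile(boot, c((1 - conf_level) / 2,
                                       1 - (1 - conf_level) / 2)))
  by_cde <- stats::aggregate(correct ~ cde_id,
    data = data.frame(cde_id = cells$cde_id[inc], correct = p == t),
    FUN = function(z) 100 * mean(z))
  names(by_cde)[2] <- "accuracy"
  by_group <- NULL
  if (!is.null(form)) {
    gp <- vapply(form$cdes, function(c)
      if (length(c$group_path)) c$group_path[[1L]] else "(ungrouped)",
      character(1))
    names(gp) <- cde_ids(form)
    g <- gp[cells$cde_id[inc]]
    by_group <- stats::aggregate(correct ~ group,
      data = data.frame(group = unname(g), correct = p == t),
      FUN = function(z) 100 * mean(z))
    names(by_group)[2] <- "accuracy"
  }
  structure(
    list(overall_accuracy = acc, ci = ci, conf_level = conf_level,
         micro = mm$micro, macro = mm$macro, n_evaluated = sum(inc),
         by_cde = by_cde, by_group = by_group, na_mode = na_mode,
         iterations = iterations, seed = seed),
    class = "cde_metrics")
}

#' @export
print.cde_metrics <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.1f%% [%.0f%% CI %.1f-%.1f] on %d cells\n",
              x$overall_accuracy, 100 * x$conf_level, x$ci[1], x$ci[2],
              x$n_evaluated))
  cat(sprintf("Micro  P/R/F1: %.1f / %.1f / %.1f %%\n",
              x$micro[["precision"]], x$micro[["recall"]], x$micro[["f1"]]))
  cat(sprintf("Macro  P/R/F1: %.1f / %.1f / %.1f %%\n",
              x$macro[["precision"]], x$macro[["recall"]], x$macro[["f1"]]))
  if (!is.null(x$by_group)) {
    cat("Accuracy by group:\n")
    print(x$by_group, row.names = FALSE)
  }
  invisible(x)
}

# save/restore the global RNG so seeded internals do not disturb the
# caller's random stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
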