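# Hierarchical value-list CDE forms: construction, validation, JSON I/O,
# and parent-gated applicability.

#' Marker for cells whose parent gate is closed
#'
#' Categorical grids use this string to record that a CDE did not apply to a
#' report because its parent CDE held a non-activating value. It is a legal
#' cell value in prediction and truth tables and is compared like any other
#' value (a closed gate predicted as closed is an exact match). Missing
#' ground truth, by contrast, is encoded as `NA` and excluded from metrics.
#' @return A length-one character string.
#' @export
#' @examples
#' cde_na_marker()
cde_na_marker <- function() "NOT_APPLICABLE"

#' Define a single value-list CDE
#'
#' A value-list common data element (CDE) is one classification topic: a
#' question about the report together with an ordered set of mutually
#' exclusive answer categories. A CDE may be *gated* on a parent CDE, in
#' which case it is only applicable to a report when the parent holds one of
#' the listed activating values (e.g. lesion-description items only apply
#' when a lesion is reported at all).
#'
#' @param id Unique string key within the form.
#' @param question Human-readable classification topic text.
#' @param categories Ordered character vector of at least two distinct,
#'   non-empty answer strings. Order is significant: it is the declared
#'   order used for tie-breaking during classification.
#' @param group_path Character vector naming the group (and optionally
#'   sub-group) this CDE belongs to, e.g. `c("Report", "Findings")`.
#' @param gate `NULL` for an ungated CDE, else `list(parent =, values =)`
#'   naming the parent CDE id and the set of parent values that activate
#'   this CDE.
#' @param prompts Optional named list of per-CDE prompt template overrides,
#'   keyed by variant name (see [prompt_template()]). Each entry is either a
#'   template string or a list with elements `template` and (for few-shot)
#'   `shots`.
#' @return An object of class `"value_list_cde"`.
#' @seealso [cde_form()], [applicable_cdes()]
#' @export
#' @examples
#' value_list_cde("lesion", "Is a lesion mentioned?", c("yes", "no"))
value_list_cde <- function(id, question, categories, group_path = character(),
                           gate = NULL, prompts = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(question), length(question) == 1L, nzchar(question))
  categories <- as.character(categories)
  norm <- trimws(gsub("[[:space:]]+", " ", categories))
  if (length(categories) < 2L || any(!nzchar(norm)))
    stop("CDE '", id, "': needs >= 2 non-empty categories", call. = FALSE)
  if (anyDuplicated(norm))
    stop("CDE '", id, "': categories must be pairwise distinct ",
         "(after whitespace normalization)", call. = FALSE)
  if (!is.null(gate)) {
    if (!is.list(gate) || is.null(gate$parent) || is.null(gate$values))
      stop("CDE '", id, "': gate must be list(parent=, values=)", call. = FALSE)
    if (length(gate$parent) != 1L)
      stop("CDE '", id, "': a CDE gates on a single parent", call. = FALSE)
    gate <- list(parent = as.character(gate$parent),
                 values = as.character(gate$values))
    if (length(gate$values) < 1L)
      stop("CDE '", id, "': gate needs >= 1 activating value", call. = FALSE)
  }
  structure(
    list(id = id, question = question, categories = categories,
         group_path = as.character(group_path), gate = gate,
         prompts = prompts),
    class = "value_list_cde"
  )
}

#' Assemble a CDE form
#'
#' A form is the ordered collection of value-list CDEs, organised in a
#' (two-level) hierarchy of named groups and sub-groups, that drives both
#' classification and evaluation. Construction validates the structural
#' invariants: unique ids, gates referencing an *earlier* CDE of the form
#' with activating values drawn from the parent's category list, and group
#' paths that exist in the declared hierarchy. Requiring parents to precede
#' their children in form order makes the gating graph acyclic by
#' construction and lets classification and simulation traverse the form in
#' a single pass.
#'
#' @param form_id String identifier for the form.
#' @param cdes List of [value_list_cde()] objects, in classification order.
#' @param groups Named list mapping each main-group name to a character
#'   vector of its sub-group names (possibly empty). `NULL` derives the
#'   hierarchy from the CDEs' `group_path`s.
#' @return An object of class `"cde_form"`.
#' @export
#' @examples
#' form <- cde_form("demo", list(
#'   value_list_cde("lesion", "Lesion mentioned?", c("yes", "no"),
#'                  group_path = "Report"),
#'   value_list_cde("side", "Which side?", c("left", "right", "both"),
#'                  group_path = "Report",
#'                  gate = list(parent = "lesion", values = "yes"))
#' ))
#' form
cde_form <- function(form_id, cdes, groups = NULL) {
  stopifnot(is.character(form_id), length(form_id) == 1L, nzchar(form_id))
  if (!is.list(cdes) || length(cdes) == 0L)
    stop("a form must contain at least one CDE", call. = FALSE)
  if (!all(vapply(cdes, inherits, logical(1), "value_list_cde")))
    stop("'cdes' must be a list of value_list_cde objects", call. = FALSE)
  ids <- vapply(cdes, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate cde ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (is.null(groups)) {
    groups <- list()
    for (cde in cdes) {
      gp <- cde$group_path
      if (length(gp) == 0L) next
      main <- gp[[1L]]
      if (is.null(groups[[main]])) groups[[main]] <- character()
      if (length(gp) > 1L)
        groups[[main]] <- union(groups[[main]], gp[[2L]])
    }
  }
  form <- structure(list(form_id = form_id, cdes = cdes, groups = groups),
                    class = "cde_form")
  validate_cde_form(form)
  form
}

validate_cde_form <- function(form) {
  ids <- cde_ids(form)
  for (i in seq_along(form$cdes)) {
    cde <- form$cdes[[i]]
    if (!is.null(cde$gate)) {
      j <- match(cde$gate$parent, ids)
      if (is.na(j))
        stop("CDE '", cde$id, "': gate references unknown parent '",
             cde$gate$parent, "'", call. = FALSE)
      if (j >= i)
        stop("CDE '", cde$id, "': gate parent '", cde$gate$parent,
             "' must precede it in form order", call. = FALSE)
      bad <- setdiff(cde$gate$values, form$cdes[[j]]$categories)
      if (length(bad))
        stop("CDE '", cde$id, "': activating value(s) ",
             paste(sQuote(bad), collapse = ", "),
             " not among parent '", cde$gate$parent, "' categories",
             call. = FALSE)
    }
    gp <- cde$group_path
    if (length(gp) >= 1L) {
      if (!gp[[1L]] %in% names(form$groups))
        stop("CDE '", cde$id, "': group '", gp[[1L]],
             "' not in form group hierarchy", call. = FALSE)
      if (length(gp) >= 2L && !gp[[2L]] %in% form$groups[[gp[[1L]]]])
        stop("CDE '", cde$id, "': sub-group '", gp[[2L]],
             "' not under group '", gp[[1L]], "'", call. = FALSE)
    }
  }
  invisible(form)
}

cde_ids <- function(form) vapply(form$cdes, `[[`, character(1), "id")

get_cde <- function(form, id) {
  i <- match(id, cde_ids(form))
  if (is.na(i)) stop("unknown cde id: ", id, call. = FALSE)
  form$cdes[[i]]
}

#' @export
print.cde_form <- function(x, ...) {
  n_gated <- sum(vapply(x$cdes, function(c) !is.null(c$gate), logical(1)))
  cat("CDE form '", x$form_id, "': ", length(x$cdes), " value-list CDEs (",
      n_gated, " gated), ", length(x$groups), " main group(s)\n", sep = "")
  for (g in names(x$groups)) {
    sub <- x$groups[[g]]
    cat("  ", g,
        if (length(sub)) paste0(" [", paste(sub, collapse = ", "), "]"),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cde_form <- function(object, ...) {
  df <- data.frame(
    id = cde_ids(object),
    question = vapply(object$cdes, `[[`, character(1), "question"),
    n_categories = vapply(object$cdes, function(c) length(c$categories),
                          integer(1)),
    group = vapply(object$cdes, function(c)
      paste(c$group_path, collapse = "/"), character(1)),
    gate = vapply(object$cdes, function(c)
      if (is.null(c$gate)) "" else
        paste0(c$gate$parent, "=",
               paste(c$gate$values, collapse = "|")), character(1)),
    stringsAsFactors = FALSE
  )
  df
}

#' Read a CDE form from its JSON document
#'
#' The on-disk task definition is a UTF-8 JSON document with keys
#' `form_id`, `groups` (object mapping main-group name to an array of
#' sub-group names) and `cdes`, an array of objects
#' `{id, question, categories, group_path, gate: {parent, values}, prompts}`.
#' Ordering of CDEs and of each category list is preserved exactly; all form
#' invariants are checked on load.
#'
#' @param path Path to the JSON document.
#' @return A validated [cde_form()].
#' @seealso [write_cde_form()]
#' @export
read_cde_form <- function(path) {
  if (!file.exists(path)) stop("form file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$form_id) || is.null(doc$cdes))
    stop("form document must have 'form_id' and 'cdes'", call. = FALSE)
  cdes <- lapply(doc$cdes, function(d) {
    value_list_cde(
      id = d$id, question = d$question,
      categories = unlist(d$categories, use.names = FALSE),
      group_path = unlist(d$group_path %||% list(), use.names = FALSE),
      gate = if (!is.null(d$gate))
        list(parent = d$gate$parent,
             values = unlist(d$gate$values, use.names = FALSE)),
      prompts = d$prompts
    )
  })
  groups <- lapply(doc$groups %||% list(), function(g)
    unlist(g, use.names = FALSE) %||% character())
  cde_form(doc$form_id, cdes, groups = groups)
}

#' Write a CDE form to a JSON document
#'
#' Inverse of [read_cde_form()]: the written document reconstructs the form
#' identically, field by field, including unicode question text.
#'
#' @param form A [cde_form()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cde_form <- function(form, path) {
  validate_cde_form(form)
  doc <- list(
    form_id = form$form_id,
    groups = lapply(form$groups, as.list),
    cdes = lapply(form$cdes, function(cde) {
      d <- list(id = cde$id, question = cde$question,
                categories = as.list(cde$categories),
                group_path = as.list(cde$group_path))
      if (!is.null(cde$gate))
        d$gate <- list(parent = cde$gate$parent,
                       values = as.list(cde$gate$values))
      if (!is.null(cde$prompts)) d$prompts <- cde$prompts
      d
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Which CDEs of a form are applicable under a partial assignment?
#'
#' Ungated CDEs are always applicable. A gated CDE is applicable exactly
#' when its parent appears in `assigned` with one of the gate's activating
#' values; a gated CDE whose parent is unassigned is not applicable. Output
#' order follows form order.
#'
#' @param form A [cde_form()].
#' @param assigned Named character vector (or named list) mapping cde ids to
#'   assigned values; may be empty.
#' @return Character vector of applicable cde ids, in form order.
#' @export
#' @examples
#' form <- cde_fixture("mini")$form
#' applicable_cdes(form)                       # ungated only
#' applicable_cdes(form, c(lesion = "yes"))    # child gate opens
applicable_cdes <- function(form, assigned = character()) {
  assigned <- unlist(assigned)
  if (length(assigned)) {
    bad <- setdiff(names(assigned), cde_ids(form))
    if (length(bad))
      stop("assigned values for unknown cde id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- vapply(form$cdes, function(cde) {
    if (is.null(cde$gate)) return(TRUE)
    pv <- assigned[cde$gate$parent]
    !is.na(pv) && pv %in% cde$gate$values
  }, logical(1))
  cde_ids(form)[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
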