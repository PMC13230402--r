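# Synthetic report corpora with known ground truth.
#
# The generator emulates the statistical structure of semi-structured
# clinical reports -- an anamnesis pre-text followed by the main report
# text, with one signal sentence per applicable CDE value, parent-gated
# sub-findings, irrelevant distractor sentences, and a noise process that
# drops signal sentences -- not realistic radiology prose. Every corpus is
# fully determined by its seed.

#' Configuration for the synthetic corpus generator
#'
#' @param form A [cde_form()] (or a [cde_fixture()] bundle, whose form,
#'   keyword map and prevalences are then used as defaults).
#' @param keyword_map Named list: `keyword_map[[cde_id]][[category]]` is a
#'   character vector of trigger phrases; every category needs at least one.
#' @param n_reports Number of reports to generate.
#' @param prevalence Named list of per-CDE categorical distributions over
#'   values (named probability vectors summing to 1); uniform when omitted
#'   for a CDE. Children are only sampled under activating parents, so the
#'   gate structure is respected by construction.
#' @param distractor_rate Expected number of irrelevant sentences per
#'   report (Poisson).
#' @param noise_rate Probability in `[0, 1)` that a truth-bearing signal
#'   sentence is omitted from the report.
#' @param distractors Character vector of irrelevant sentences to draw
#'   from; a built-in pool is used when omitted.
#' @param seed Integer seed determining the corpus completely.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(form, keyword_map = NULL, n_reports = 50,
                             prevalence = NULL, distractor_rate = 1,
                             noise_rate = 0, distractors = NULL, seed = 1) {
  if (inherits(form, "cde_fixture")) {
    if (is.null(keyword_map)) keyword_map <- form$keyword_map
    if (is.null(prevalence)) prevalence <- form$prevalence
    form <- form$form
  }
  stopifnot(inherits(form, "cde_form"))
  if (is.null(keyword_map))
    stop("keyword_map is required", call. = FALSE)
  check_keyword_map(form, keyword_map)
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate >= 1)
    stop("noise_rate must be in [0, 1)", call. = FALSE)
  if (!is.numeric(distractor_rate) || distractor_rate < 0)
    stop("distractor_rate must be >= 0", call. = FALSE)
  stopifnot(n_reports >= 0)
  prevalence <- lapply(stats::setNames(nm = cde_ids(form)), function(id) {
    cde <- get_cde(form, id)
    pv <- prevalence[[id]]
    if (is.null(pv)) {
      pv <- rep(1 / length(cde$categories), length(cde$categories))
      names(pv) <- cde$categories
    } else {
      if (is.null(names(pv)) ||
          !setequal(names(pv), cde$categories))
        stop("prevalence for '", id, "' must be named over its categories",
             call. = FALSE)
      pv <- pv[cde$categories]
      if (any(pv < 0) || abs(sum(pv) - 1) > 1e-8)
        stop("prevalence for '", id, "' must be a probability distribution",
             call. = FALSE)
    }
    pv
  })
  structure(
    list(form = form, keyword_map = keyword_map, n_reports = n_reports,
         prevalence = prevalence, distractor_rate = distractor_rate,
         noise_rate = noise_rate,
         distractors = distractors %||% default_distractors(),
         seed = as.integer(seed)),
    class = "generator_config")
}

default_distractors <- function() c(
  "The examination was performed without complications.",
  "The patient tolerated the procedure well.",
  "Images were archived in the local picture archive.",
  "Written informed consent was obtained beforehand.",
  "Technical image quality was adequate for interpretation.",
  "The referring physician was notified of the appointment.",
  "Standard positioning was used for all acquisitions.",
  "The examination protocol followed departmental routine.")

#' Generate a synthetic report corpus with ground truth
#'
#' For each report, truth values are sampled per CDE from the configured
#' prevalences, respecting parent gates (a gated CDE whose parent's truth
#' is non-activating gets the not-applicable marker). Each applicable truth
#' value contributes one sentence drawn from its trigger phrases -- omitted
#' with probability `noise_rate` -- and Poisson-many distractor sentences
#' are interleaved; anamnesis-section sentences (CDEs under the form's
#' first main group) precede report-section sentences.
#'
#' @param config A [generator_config()].
#' @param reports_path,truth_path Optional CSV output paths.
#' @return List with `reports` (data frame `report_id`, `text`) and `truth`
#'   (data frame `report_id`, `cde_id`, `value`).
#' @export
generate_corpus <- function(config, reports_path = NULL, truth_path = NULL) {
  stopifnot(inherits(config, "generator_config"))
  form <- config$form
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  anam_group <- if (length(form$groups)) names(form$groups)[[1L]] else NULL
  ids <- cde_ids(form)
  report_rows <- vector("list", config$n_reports)
  truth_rows <- vector("list", config$n_reports)
  for (r in seq_len(config$n_reports)) {
    rid <- sprintf("R%04d", r)
    truth <- character(0)
    anam <- character()
    main <- character()
    for (cde in form$cdes) {
      open <- is.null(cde$gate) || truth[[cde$gate$parent]] %in% cde$gate$values
      if (!open) {
        truth[[cde$id]] <- cde_na_marker()
        next
      }
      pv <- config$prevalence[[cde$id]]
      val <- sample(names(pv), 1L, prob = pv)
      truth[[cde$id]] <- val
      if (stats::runif(1) >= config$noise_rate) {
        phrases <- config$keyword_map[[cde$id]][[val]]
        s <- phrases[[sample.int(length(phrases), 1L)]]
        in_anam <- !is.null(anam_group) && length(cde$group_path) &&
          cde$group_path[[1L]] == anam_group
        if (in_anam) anam <- c(anam, s) else main <- c(main, s)
      }
    }
    n_d <- stats::rpois(1L, config$distractor_rate)
    if (n_d > 0L) {
      d <- sample(config$distractors, n_d, replace = TRUE)
      to_anam <- stats::runif(n_d) < 0.5
      anam <- c(anam, d[to_anam])
      main <- c(main, d[!to_anam])
    }
    if (length(anam) > 1L) anam <- sample(anam)
    if (length(main) > 1L) main <- sample(main)
    text <- paste(c(if (length(anam)) c("Anamnesis:", anam),
                    "Report:", main), collapse = " ")
    report_rows[[r]] <- data.frame(report_id = rid, text = text,
                                   stringsAsFactors = FALSE)
    truth_rows[[r]] <- data.frame(report_id = rid, cde_id = ids,
                                  value = unname(truth[ids]),
                                  stringsAsFactors = FALSE)
  }
  reports <- if (config$n_reports)
    do.call(rbind, report_rows) else
    data.frame(report_id = character(), text = character())
  truth <- if (config$n_reports)
    do.call(rbind, truth_rows) else
    data.frame(report_id = character(), cde_id = character(),
               value = character())
  if (!is.null(reports_path))
    utils::write.csv(reports, reports_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(truth_path)) write_truth(truth, truth_path)
  list(reports = reports, truth = truth)
}

#' Analytic expected accuracy of the keyword mock on a generator config
#'
#' Computes, exactly, the cell accuracy the keyword [mock_backend()] (with
#' the same keyword map and prevalences) attains in expectation on corpora
#' from this configuration. For each CDE the joint distribution of (truth
#' value, predicted value) -- over the categories plus the not-applicable
#' state -- is propagated down the gating hierarchy: a present signal
#' phrase yields the correct category, an omitted one (probability
#' `noise_rate`) makes the mock fall back to the most prevalent category,
#' and gate mismatches between truth and prediction propagate to
#' descendants. The overall value is the unweighted mean of the per-CDE
#' diagonal masses, matching an accuracy computed over the full grid.
#'
#' @param config A [generator_config()].
#' @return Expected cell accuracy as a fraction in `[0, 1]`.
#' @export
#' @examples
#' fx <- cde_fixture("mini")
#' cfg <- generator_config(fx, n_reports = 10, noise_rate = 0.2)
#' expected_mock_accuracy(cfg)
expected_mock_accuracy <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  form <- config$form
  noise <- config$noise_rate
  joints <- list()
  acc <- numeric(length(form$cdes))
  for (i in seq_along(form$cdes)) {
    cde <- form$cdes[[i]]
    states <- c(cde$categories, ".NA")
    J <- matrix(0, length(states), length(states),
                dimnames = list(truth = states, pred = states))
    pv <- config$prevalence[[cde$id]]
    ranks <- fallback_ranks(cde, config$prevalence)
    mode_cat <- cde$categories[[which(ranks == 1L)]]
    if (is.null(cde$gate)) {
      p_both <- 1; p_t_only <- 0; p_p_only <- 0; p_neither <- 0
    } else {
      Jp <- joints[[cde$gate$parent]]
      pstates <- rownames(Jp)
      act <- pstates %in% cde$gate$values
      p_both <- sum(Jp[act, act])
      p_t_only <- sum(Jp[act, !act])
      p_p_only <- sum(Jp[!act, act])
      p_neither <- sum(Jp[!act, !act])
    }
    for (v in cde$categories) {
      J[v, v] <- J[v, v] + p_both * pv[[v]] * (1 - noise)
      J[v, mode_cat] <- J[v, mode_cat] + p_both * pv[[v]] * noise
      J[v, ".NA"] <- J[v, ".NA"] + p_t_only * pv[[v]]
    }
    J[".NA", mode_cat] <- J[".NA", mode_cat] + p_p_only
    J[".NA", ".NA"] <- J[".NA", ".NA"] + p_neither
    joints[[cde$id]] <- J
    acc[[i]] <- sum(diag(J))
  }
  mean(acc)
}

#' Packaged fixture forms with generator vocabulary
#'
#' Two illustrative, deliberately non-clinical fixtures: `"mini"` -- three
#' CDEs with one gate, for unit tests -- and `"mammo_like"` -- twenty CDEs
#' in two main groups and five sub-groups (including a three-level gate
#' chain), mirroring the *shape* of a breast-imaging reporting form with
#' invented content, for integration tests.
#'
#' @param name `"mini"` or `"mammo_like"`.
#' @return An object of class `"cde_fixture"`: list with `form`
#'   ([cde_form()]), `keyword_map`, and `prevalence` defaults.
#' @export
cde_fixture <- function(name = c("mini", "mammo_like")) {
  name <- match.arg(name)
  fx <- if (name == "mini") fixture_mini() else fixture_mammo_like()
  structure(fx, class = "cde_fixture")
}

#' @export
print.cde_fixture <- function(x, ...) {
  cat("CDE fixture bundle (form + generator vocabulary)\n")
  print(x$form)
  invisible(x)
}

fixture_mini <- function() {
  form <- cde_form("mini", list(
    value_list_cde("prior_mammo", "Prior mammogram mentioned?",
                   c("yes", "no"), group_path = "Anamnesis"),
    value_list_cde("lesion", "Lesion mentioned?", c("yes", "no"),
                   group_path = "Report"),
    value_list_cde("side", "Which side is the lesion on?",
                   c("left", "right", "both"), group_path = "Report",
                   gate = list(parent = "lesion", values = "yes"))
  ), groups = list(Anamnesis = character(), Report = character()))
  keyword_map <- list(
    prior_mammo = list(
      yes = c("A prior mammogram from an outside clinic is on file.",
              "Previous mammographic images are available for comparison."),
      no = c("No prior mammographic examination is documented.")),
    lesion = list(
      yes = c("A focal mass is described in the breast tissue.",
              "There is a newly demarcated nodular opacity."),
      no = c("No focal suspicious finding is delineated.")),
    side = list(
      left = c("The finding projects onto the left breast."),
      right = c("The finding projects onto the right breast."),
      both = c("Corresponding findings are seen in both breasts.")))
  list(form = form, keyword_map = keyword_map, prevalence = NULL)
}

fixture_mammo_like <- function() {
  yn <- c("yes", "no")
  spec <- list(
    # id, question, categories, group, subgroup, gate_parent, gate_values
    list("fam_history", "Family history of breast cancer?", yn,
         "Anamnesis", "History", NULL, NULL),
    list("fam_degree", "Degree of affected relative?",
         c("first", "second"), "Anamnesis", "History", "fam_history", "yes"),
    list("symptoms", "Reported symptoms?", c("none", "pain", "lump"),
         "Anamnesis", "History", NULL, NULL),
    list("prior_mammo", "Prior mammogram mentioned?", yn,
         "Anamnesis", "Prior imaging", NULL, NULL),
    list("prior_interval", "Interval since prior mammogram?",
         c("recent", "old"), "Anamnesis", "Prior imaging",
         "prior_mammo", "yes"),
    list("density_left", "Tissue density left?", c("low", "medium", "high"),
         "Report", "Composition", NULL, NULL),
    list("density_right", "Tissue density right?", c("low", "medium", "high"),
         "Report", "Composition", NULL, NULL),
    list("lesion_present", "Lesion present?", yn,
         "Report", "Findings", NULL, NULL),
    list("lesion_count", "Number of lesions?", c("one", "multiple"),
         "Report", "Findings", "lesion_present", "yes"),
    list("lesion_side", "Side of the lesion?", c("left", "right", "both"),
         "Report", "Findings", "lesion_present", "yes"),
    list("lesion_shape", "Shape of the lesion?",
         c("round", "oval", "irregular"), "Report", "Findings",
         "lesion_present", "yes"),
    list("lesion_margin", "Margin of the lesion?",
         c("smooth", "spiculated"), "Report", "Findings",
         "lesion_present", "yes"),
    list("calcifications", "Calcifications associated?", yn,
         "Report", "Findings", "lesion_present", "yes"),
    list("calc_pattern", "Pattern of the calcifications?",
         c("clustered", "diffuse"), "Report", "Findings",
         "calcifications", "yes"),
    list("suspicion_left", "Level of suspicion left?",
         c("low", "intermediate", "high"), "Report", "Assessment",
         NULL, NULL),
    list("suspicion_right", "Level of suspicion right?",
         c("low", "intermediate", "high"), "Report", "Assessment",
         NULL, NULL),
    list("followup", "Recommended follow-up?",
         c("routine", "short interval", "biopsy"), "Report", "Assessment",
         NULL, NULL),
    list("comparison_done", "Comparison with prior images performed?", yn,
         "Report", "Assessment", NULL, NULL),
    list("report_complete", "Report formally complete?", yn,
         "Report", "Assessment", NULL, NULL),
    list("results_communicated", "Results communicated to referrer?", yn,
         "Report", "Assessment", NULL, NULL))
  cdes <- lapply(spec, function(s)
    value_list_cde(s[[1]], s[[2]], s[[3]], group_path = c(s[[4]], s[[5]]),
                   gate = if (!is.null(s[[6]]))
                     list(parent = s[[6]], values = s[[7]])))
  form <- cde_form("mammo_like", cdes,
                   groups = list(Anamnesis = c("History", "Prior imaging"),
                                 Report = c("Composition", "Findings",
                                            "Assessment")))
  stems <- c(
    fam_history = "A family history of breast cancer is recorded as",
    fam_degree = "The affected relative is of degree",
    symptoms = "The presenting symptom category is",
    prior_mammo = "A prior mammogram being mentioned is recorded as",
    prior_interval = "The interval since the prior mammogram is classed",
    density_left = "The left-sided tissue density is graded",
    density_right = "The right-sided tissue density is graded",
    lesion_present = "A lesion being present is recorded as",
    lesion_count = "The number of lesions is classed",
    lesion_side = "The side of the lesion is noted as",
    lesion_shape = "The shape of the lesion is described as",
    lesion_margin = "The margin of the lesion is described as",
    calcifications = "Associated calcifications are recorded as",
    calc_pattern = "The calcification pattern is described as",
    suspicion_left = "The left-sided level of suspicion is rated",
    suspicion_right = "The right-sided level of suspicion is rated",
    followup = "The recommended follow-up is",
    comparison_done = "Comparison with prior images is recorded as",
    report_complete = "Formal completeness of the report is recorded as",
    results_communicated = "Communication of results to the referrer is")
  keyword_map <- lapply(stats::setNames(nm = cde_ids(form)), function(id) {
    cde <- get_cde(form, id)
    lapply(stats::setNames(nm = cde$categories), function(cat)
      c(sprintf("%s %s in this document.", stems[[id]], cat),
        sprintf("%s %s on review.", stems[[id]], cat)))
  })
  # mild non-uniform prevalences for the gating parents so that gated
  # sub-findings occur in a realistic minority of reports
  prevalence <- list(
    fam_history = c(yes = 0.3, no = 0.7),
    prior_mammo = c(yes = 0.6, no = 0.4),
    lesion_present = c(yes = 0.4, no = 0.6),
    calcifications = c(yes = 0.35, no = 0.65))
  list(form = form, keyword_map = keyword_map, prevalence = prevalence)
}
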