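test_that("relative probabilities follow the normalization formula", {
  b <- const_backend(log(c(0.02, 0.01, 0.01)))
  s <- score_categories(b, "T: x\nA:", c("a", "b", "c"))
  expect_equal(s$rel_prob, c(0.5, 0.25, 0.25))
  expect_equal(sum(s$rel_prob), 1, tolerance = 1e-12)
  expect_equal(s$category, c("a", "b", "c"))

  one <- score_categories(const_backend(-3), "p", "only")
  expect_equal(one$rel_prob, 1)

  four <- score_categories(const_backend(rep(-2.5, 4)), "p",
                           c("a", "b", "c", "d"))
  expect_equal(four$rel_prob, rep(0.25, 4))
})

test_that("normalization is stable for extreme log-probabilities", {
  s <- score_categories(const_backend(c(-1000, -1001)), "p", c("a", "b"))
  expect_true(all(is.finite(s$rel_prob)))
  expect_equal(sum(s$rel_prob), 1, tolerance = 1e-12)
  expect_gt(s$rel_prob[1], s$rel_prob[2])
})

test_that("backend failures surface with backend name and context", {
  bad <- function_backend(function(p, k) stop("boom"), name = "grumpy")
  expect_error(score_categories(bad, "p", c("a", "b")), "grumpy")
  nonfinite <- function_backend(function(p, k) c(-1, -Inf), name = "inf")
  expect_error(score_categories(nonfinite, "p", c("a", "b")), "non-finite")
  short <- function_backend(function(p, k) -1, name = "short")
  expect_error(score_categories(short, "p", c("a", "b")), "2 categories")
  cde <- value_list_cde("x", "Q?", c("a", "b"))
  expect_error(classify_cde(bad, "text", cde, report_id = "r1"),
               "report 'r1', cde 'x'")
})

test_that("classify_cde selects the softmax argmax with hand-checked certainty", {
  cde <- value_list_cde("x", "Which?", c("first", "second", "third"))
  res <- classify_cde(const_backend(c(-1, -2, -3)), "some report", cde)
  expect_identical(res$selected, "first")
  # independent hand evaluation of the softmax on (-1, -2, -3)
  naive <- exp(-1) / (exp(-1) + exp(-2) + exp(-3))
  expect_equal(res$certainty, naive, tolerance = 1e-12)
  expect_equal(res$certainty, 0.66524096, tolerance = 1e-7)
  expect_gte(res$elapsed_seconds, 0)
})

test_that("exact ties break to the earliest declared category", {
  cde <- value_list_cde("x", "Which?", c("yes", "no"))
  res <- classify_cde(const_backend(c(-2, -2)), "some report", cde)
  expect_identical(res$selected, "yes")
  expect_equal(res$certainty, 0.5)
})

test_that("two-way classifications always have certainty >= 1/2", {
  set.seed(7)
  cde <- value_list_cde("x", "Which?", c("yes", "no"))
  for (i in 1:50) {
    res <- classify_cde(const_backend(-stats::rexp(2)), "r", cde)
    expect_gte(res$certainty, 0.5)
  }
})

test_that("selection agrees with brute-force argmax on random instances", {
  set.seed(123)
  for (i in 1:120) {
    k <- sample(2:6, 1)
    lp <- -stats::rexp(k, rate = 0.5)
    cde <- value_list_cde("x", "Which?", paste0("cat", seq_len(k)))
    res <- classify_cde(const_backend(lp), "rep text", cde)
    expect_identical(res$selected, cde$categories[which.max(exp(lp))])
    expect_equal(sum(res$scores$rel_prob), 1, tolerance = 1e-9)
  }
})

test_that("report traversal honours gates from *predicted* parent values", {
  form <- chain_form()
  # parent predicted "on", child predicted "cold" -> grandchild gate closed
  script <- list("r1|parent" = c(-1, -5), "r1|child" = c(-4, -1),
                 "r1|grandchild" = c(-1, -2))
  res <- classify_report(scripted_backend(script), form, "text",
                         report_id = "r1")
  expect_length(res, 3L)
  expect_true(res[[1]]$applicable)
  expect_true(res[[2]]$applicable)
  expect_false(res[[3]]$applicable)
  expect_identical(res[[3]]$selected, NAV)
  expect_equal(nrow(res[[3]]$scores), 0L)
  # the not-applicable cell inherits the gating parent's certainty
  expect_equal(res[[3]]$certainty, res[[2]]$certainty)

  # parent predicted "off": every descendant closed
  script2 <- list("r1|parent" = c(-5, -1))
  res2 <- classify_report(scripted_backend(script2), form, "text",
                          report_id = "r1")
  expect_false(res2[[2]]$applicable)
  expect_false(res2[[3]]$applicable)
})

test_that("gating decisions match applicable_cdes recomputed post hoc", {
  fx <- cde_fixture("mammo_like")
  cfg <- generator_config(fx, n_reports = 8, noise_rate = 0.3, seed = 21)
  corp <- generate_corpus(cfg)
  bk <- mock_backend(fx$form, fx$keyword_map, prevalence = cfg$prevalence)
  for (r in seq_len(nrow(corp$reports))) {
    res <- classify_report(bk, fx$form, corp$reports$text[[r]],
                           report_id = corp$reports$report_id[[r]])
    sel <- vapply(res, `[[`, character(1), "selected")
    names(sel) <- vapply(res, `[[`, character(1), "cde_id")
    open <- applicable_cdes(fx$form, sel[sel != NAV])
    expect_identical(names(sel)[vapply(res, `[[`, logical(1), "applicable")],
                     open)
  }
})

test_that("corpus classification emits a complete deterministic grid", {
  fx <- cde_fixture("mini")
  cfg <- generator_config(fx, n_reports = 5, seed = 4)
  corp <- generate_corpus(cfg)
  bk <- mock_backend(fx$form, fx$keyword_map)
  p1 <- classify_corpus(bk, fx$form, corp$reports, quiet = TRUE)
  expect_equal(nrow(p1), 15L)
  expect_setequal(unique(p1$cde_id), c("prior_mammo", "lesion", "side"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_predictions(p1, f1)
  p2 <- classify_corpus(bk, fx$form, corp$reports, quiet = TRUE,
                        output_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_s3_class(attr(p1, "timing"), "data.frame")
  expect_equal(nrow(attr(p1, "timing")), 5L)
})

test_that("empty and malformed report tables are handled before scoring", {
  fx <- cde_fixture("mini")
  bk <- mock_backend(fx$form, fx$keyword_map)
  empty <- data.frame(report_id = character(), text = character())
  expect_warning(grid <- classify_corpus(bk, fx$form, empty, quiet = TRUE),
                 "empty")
  expect_equal(nrow(grid), 0L)
  dup <- data.frame(report_id = c("a", "a"), text = c("x", "y"))
  expect_error(classify_corpus(bk, fx$form, dup, quiet = TRUE), "duplicate")
  bad <- data.frame(id = "a", body = "x")
  expect_error(classify_corpus(bk, fx$form, bad, quiet = TRUE), "columns")
})

test_that("a replay of recorded scores reproduces the grid byte for byte", {
  fx <- cde_fixture("mini")
  cfg <- generator_config(fx, n_reports = 6, noise_rate = 0.2, seed = 9)
  corp <- generate_corpus(cfg)
  bk <- mock_backend(fx$form, fx$keyword_map)
  scores_path <- withr::local_tempfile(fileext = ".json")
  g1 <- withr::local_tempfile(fileext = ".csv")
  g2 <- withr::local_tempfile(fileext = ".csv")
  classify_corpus(bk, fx$form, corp$reports, quiet = TRUE,
                  output_path = g1, scores_path = scores_path)
  rb <- replay_backend(read_scores(scores_path))
  classify_corpus(rb, fx$form, corp$reports, quiet = TRUE, output_path = g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("length-normalized scoring divides by reported token counts", {
  b <- function_backend(function(p, k) {
    lp <- c(-2, -4)
    attr(lp, "n_tokens") <- c(1L, 4L)
    lp
  })
  plain <- score_categories(b, "p", c("a", "b"))
  norm <- score_categories(b, "p", c("a", "b"), length_normalize = TRUE)
  expect_identical(plain$category[which.max(plain$rel_prob)], "a")
  expect_identical(norm$category[which.max(norm$rel_prob)], "b")
  no_counts <- const_backend(c(-1, -2))
  expect_error(score_categories(no_counts, "p", c("a", "b"),
                                length_normalize = TRUE), "token counts")
})
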