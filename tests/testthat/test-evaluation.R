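test_that("overall accuracy excludes missing truth and counts by hand", {
  truth <- grid_of(c("a", "a", "b", NA, "b", "a", "b", "a", NA, "b"))
  pred <- pred_of(c("a", "a", "b", "a", "b", "b", "a", "a", "b", "b"))
  # 2 truth-missing cells excluded; of the remaining 8, rows 6 and 7 wrong
  res <- overall_accuracy(pred, truth)
  expect_equal(res$accuracy, 75)
  expect_equal(res$n_evaluated, 8L)
  expect_equal(res$n_correct, 6L)

  expect_equal(overall_accuracy(truth, truth)$accuracy, 100)
  allwrong <- pred_of(rep("z", 10))
  expect_equal(overall_accuracy(allwrong, truth)$accuracy, 0)
  allna <- grid_of(rep(NA_character_, 10))
  expect_error(overall_accuracy(pred, allna), "undefined")
})

test_that("changing a prediction on a truth-missing cell changes nothing", {
  set.seed(5)
  truth <- grid_of(sample(c("a", "b", NA), 30, replace = TRUE))
  pred <- pred_of(sample(c("a", "b"), 30, replace = TRUE),
                  certainty = stats::runif(30, 0.5, 1))
  pred2 <- pred
  pred2$selected[is.na(truth$value)] <- "zzz"
  expect_equal(overall_accuracy(pred, truth), overall_accuracy(pred2, truth))
  expect_equal(micro_macro_metrics(pred, truth),
               micro_macro_metrics(pred2, truth))
  expect_equal(as.data.frame(certainty_sweep(pred, truth)),
               as.data.frame(certainty_sweep(pred2, truth)))
})

test_that("not-applicable grading modes differ as documented", {
  truth <- grid_of(c("a", NAV, NAV, "b"))
  pred <- pred_of(c("a", NAV, "b", "b"))
  inc <- overall_accuracy(pred, truth, na_mode = "include")
  exc <- overall_accuracy(pred, truth, na_mode = "exclude")
  expect_equal(inc$n_evaluated, 4L)
  expect_equal(inc$accuracy, 75)   # matched NA marker counts as correct
  expect_equal(exc$n_evaluated, 2L)
  expect_equal(exc$accuracy, 100)
})

test_that("misaligned grids are rejected", {
  truth <- grid_of(c("a", "b"))
  pred <- pred_of(c("a", "b", "a"))
  expect_error(overall_accuracy(pred, truth), "index set")
  expect_error(overall_accuracy(pred_of(c("a", "b")),
                                rbind(truth, truth)), "duplicate")
})

test_that("micro metrics equal overall accuracy on single-label grids", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    classes <- paste0("c", seq_len(sample(2:5, 1)))
    truth <- grid_of(sample(classes, n, replace = TRUE))
    pred <- pred_of(sample(classes, n, replace = TRUE))
    mm <- micro_macro_metrics(pred, truth)
    acc <- overall_accuracy(pred, truth)$accuracy
    expect_equal(unname(mm$micro[["precision"]]), acc, tolerance = 1e-12)
    expect_equal(unname(mm$micro[["recall"]]), acc, tolerance = 1e-12)
    expect_equal(unname(mm$micro[["f1"]]), acc, tolerance = 1e-12)
    expect_true(all(mm$macro >= 0 & mm$macro <= 100))
  }
})

test_that("macro metrics match a hand-built confusion matrix", {
  # 3-class grid with confusion counts written out:
  #            pred a  pred b  pred c
  #  truth a       3       1       0     (4 a's)
  #  truth b       1       2       1     (4 b's)
  #  truth c       0       0       2     (2 c's)
  truth <- grid_of(c(rep("a", 4), rep("b", 4), rep("c", 2)))
  pred <- pred_of(c("a", "a", "a", "b",
                    "a", "b", "b", "c",
                    "c", "c"))
  mm <- micro_macro_metrics(pred, truth)
  p_a <- 3 / 4; r_a <- 3 / 4
  p_b <- 2 / 3; r_b <- 2 / 4
  p_c <- 2 / 3; r_c <- 2 / 2
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(unname(mm$macro[["precision"]]),
               100 * mean(c(p_a, p_b, p_c)), tolerance = 1e-12)
  expect_equal(unname(mm$macro[["recall"]]),
               100 * mean(c(r_a, r_b, r_c)), tolerance = 1e-12)
  expect_equal(unname(mm$macro[["f1"]]),
               100 * mean(c(f1(p_a, r_a), f1(p_b, r_b), f1(p_c, r_c))),
               tolerance = 1e-12)
  expect_equal(unname(mm$micro[["f1"]]), 100 * 7 / 10, tolerance = 1e-12)
  expect_equal(micro_macro_metrics(truth, truth)$macro,
               c(precision = 100, recall = 100, f1 = 100))
})

test_that("Cohen's kappa matches hand-evaluated agreement tables", {
  # alternating agreement: p_o = 0.5, p_e = 0.5, kappa = 0
  a <- grid_of(c("a", "a", "b", "b"))
  b <- grid_of(c("a", "b", "a", "b"))
  k <- cohens_kappa(a, b)
  expect_equal(k$p_o, 0.5)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0)

  # 2x2 agreement table [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5, kappa = 0.4
  ra <- grid_of(c(rep("x", 25), rep("y", 25)))
  rb <- grid_of(c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15)))
  k2 <- cohens_kappa(ra, rb)
  expect_equal(k2$p_o, 0.7)
  expect_equal(k2$p_e, 0.5)
  expect_equal(k2$kappa, 0.4, tolerance = 1e-12)
  expect_equal(k2$n, 50L)

  # self-agreement on any non-constant rating is exactly 1
  expect_equal(cohens_kappa(ra, ra)$kappa, 1)
  # both raters constant and equal: p_e = 1, agreement perfect
  cc <- grid_of(rep("x", 8))
  expect_equal(cohens_kappa(cc, cc)$kappa, 1)
})

test_that("kappa stays within [-1, 1] and matches an independent oracle", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    a <- sample(c("u", "v", "w"), n, replace = TRUE)
    b <- sample(c("u", "v", "w"), n, replace = TRUE)
    k <- cohens_kappa(grid_of(a), grid_of(b))$kappa
    expect_gte(k, -1); expect_lte(k, 1)
    oracle <- e1071::classAgreement(table(factor(a, c("u", "v", "w")),
                                          factor(b, c("u", "v", "w"))))$kappa
    expect_equal(k, oracle, tolerance = 1e-12)
  }
})

test_that("kappa is reported per group and sub-group of a form", {
  fx <- cde_fixture("mammo_like")
  cfg <- generator_config(fx, n_reports = 15, seed = 2)
  corp <- generate_corpus(cfg)
  # a second rater disagreeing on some assessment cells
  other <- corp$truth
  set.seed(8)
  flip <- other$cde_id == "followup" & stats::runif(nrow(other)) < 0.5
  other$value[flip] <- "biopsy"
  k <- cohens_kappa(corp$truth, other, form = fx$form)
  expect_s3_class(k$by_group, "data.frame")
  expect_setequal(
    k$by_group$group[k$by_group$level == "group"],
    c("Anamnesis", "Report"))
  expect_true(all(c("Report/Findings", "Report/Assessment") %in%
                    k$by_group$group))
  anam <- k$by_group[k$by_group$group == "Anamnesis", ]
  expect_equal(anam$kappa, 1)
})

test_that("certainty sweep trades coverage for accuracy monotonically", {
  truth <- grid_of(c("a", "a", "b", "b", "a", NA))
  pred <- pred_of(c("a", "b", "b", "b", "a", "a"),
                  certainty = c(0.95, 0.6, 0.999, 0.8, 0.97, 0.5))
  sw <- certainty_sweep(pred, truth, thresholds = c(0, 0.9, 0.99))
  expect_equal(sw$n_covered, c(5L, 3L, 1L))
  expect_true(all(diff(sw$coverage) <= 0))
  expect_equal(sw$accuracy[1], 80)        # overall accuracy at t = 0
  expect_equal(sw$accuracy[2], 100)       # the wrong low-certainty cell drops
  # strict ">" at the threshold: a cell at exactly 0.999 is not covered
  sw999 <- certainty_sweep(pred, truth, thresholds = 0.999)
  expect_equal(sw999$n_covered, 0L)
  expect_true(is.na(sw999$accuracy))
  # certainty required
  expect_error(certainty_sweep(pred_of(c("a", "b")), grid_of(c("a", "b"))),
               "certainty")
})

test_that("metrics report aggregates accuracies with a bootstrap CI", {
  fx <- cde_fixture("mini")
  cfg <- generator_config(fx, n_reports = 20, noise_rate = 0.3, seed = 13)
  corp <- generate_corpus(cfg)
  bk <- mock_backend(fx$form, fx$keyword_map)
  pred <- classify_corpus(bk, fx$form, corp$reports, quiet = TRUE)
  rep1 <- metrics_report(pred, corp$truth, form = fx$form,
                         iterations = 200, seed = 42)
  expect_true(rep1$ci[1] <= rep1$overall_accuracy &&
                rep1$overall_accuracy <= rep1$ci[2])
  expect_setequal(rep1$by_group$group, c("Anamnesis", "Report"))
  expect_equal(nrow(rep1$by_cde), 3L)
  rep2 <- metrics_report(pred, corp$truth, form = fx$form,
                         iterations = 200, seed = 42)
  expect_identical(rep1$ci, rep2$ci)
  expect_output(print(rep1), "Overall accuracy")
})
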