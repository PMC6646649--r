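test_that("aggregate score is the per-case sum of recalls, bounded by R", {
  pre <- matrix(c(1, 1, 0, 1, 0, 0, 1), 7, 1, dimnames = list(paste0("R", 1:7), "c1"))
  x <- make_test_study(pre, pre, truth = "cancer")
  expect_identical(aggregate_scores(x, "pre")[["c1"]], 4L)

  none <- matrix(0, 7, 1, dimnames = list(paste0("R", 1:7), "c1"))
  y <- make_test_study(none, none, truth = "cancer")
  expect_identical(aggregate_scores(y, "post")[["c1"]], 0L)

  z <- simulate_study(sim_config(n_cancer = 10, n_normal = 5), seed = 4)
  agg <- aggregate_scores(z, "post")
  expect_true(all(agg >= 0 & agg <= 7))
  brute <- sapply(z$cases$case_id, function(cid) {
    sum(z$decisions$recall[z$decisions$case_id == cid & z$decisions$phase == "post"])
  })
  expect_identical(unname(agg[names(brute)]), unname(as.integer(brute)))
})

test_that("ROC endpoints, monotonicity, and degenerate-tie behaviour", {
  sep <- roc_from_scores(c(2, 3, 0, 1), c("cancer", "cancer", "normal", "normal"))
  expect_identical(sep$auc, 1)
  expect_identical(unlist(sep$points[1, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
  expect_identical(unlist(sep$points[nrow(sep$points), c("fpr", "tpr")],
                          use.names = FALSE), c(1, 1))
  expect_true(all(diff(sep$points$fpr) >= 0) && all(diff(sep$points$tpr) >= 0))

  tied <- roc_from_scores(rep(3, 6), rep(c("cancer", "normal"), 3))
  expect_identical(tied$auc, 0.5)
  expect_identical(nrow(tied$points), 2L)

  expect_error(roc_from_scores(1:4, rep("cancer", 4)), class = "cadreader_undefined")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair-enumeration oracle", {
  withr::with_seed(202, {
    for (i in 1:60) {
      n <- sample(6:40, 1)
      truth <- sample(c("cancer", "normal"), n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      scores <- sample(0:7, n, replace = TRUE)
      r <- roc_from_scores(scores, truth)
      expect_equal(r$auc, auc_pair_oracle(scores, truth), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with pROC on a shared instance", {
  withr::with_seed(77, {
    truth <- sample(c("cancer", "normal"), 60, replace = TRUE, prob = c(0.6, 0.4))
    scores <- sample(0:7, 60, replace = TRUE) + ifelse(truth == "cancer", 2, 0)
  })
  ours <- roc_from_scores(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("normal", "cancer"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC is invariant under strictly increasing score transforms", {
  withr::with_seed(303, {
    truth <- sample(c("cancer", "normal"), 40, replace = TRUE)
    truth[1:2] <- c("cancer", "normal")
    scores <- sample(0:7, 40, replace = TRUE)
  })
  a <- roc_from_scores(scores, truth)
  b <- roc_from_scores(exp(scores / 3) + 5, truth)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$points$fpr, b$points$fpr)
  expect_equal(a$points$tpr, b$points$tpr)
})

test_that("stand-alone CAD score is the max mark score, zero when unmarked", {
  pre <- matrix(0, 1, 3, dimnames = list("R1", c("c1", "c2", "n1")))
  x <- make_test_study(pre, pre, truth = c("cancer", "cancer", "normal"),
                       hit_cases = c("c1", "c2"), false_mark_cases = "c1")
  x$marks$neuscore <- c(75, 40, 62)   # c1 truth-hit 75, c1 false 40, c2 hit 62
  s <- standalone_case_scores(x)
  expect_identical(s[["c1"]], 75)
  expect_identical(s[["c2"]], 62)
  expect_identical(s[["n1"]], 0)
})

test_that("reader operating points span (0,1) for perfect and (1,1) for recall-all", {
  perfect_pre <- matrix(c(1, 1, 0), 1, 3,
                        dimnames = list("R1", c("c1", "c2", "n1")))
  x <- make_test_study(perfect_pre, perfect_pre,
                       truth = c("cancer", "cancer", "normal"))
  op <- reader_operating_point(x, "R1", "pre")
  expect_identical(c(op$fpr, op$tpr), c(0, 1))

  all_in <- matrix(1, 1, 3, dimnames = list("R1", c("c1", "c2", "n1")))
  y <- make_test_study(all_in, all_in, truth = c("cancer", "cancer", "normal"))
  op2 <- reader_operating_point(y, "R1", "post")
  expect_identical(c(op2$fpr, op2$tpr), c(1, 1))

  z <- simulate_study(sim_config(n_cancer = 20, n_normal = 10), seed = 9)
  op3 <- reader_operating_point(z, "R3", "post")
  expect_identical(op3$tpr, reader_cdr(z, "R3", "post"))
  expect_identical(op3$fpr, fp_recall_metrics(z, "R3")$fp_post / 10)
})

test_that("theoretical transform recalls every flagged case and never drops one", {
  pre <- matrix(c(0, 1, 0, 0), 1, 4,
                dimnames = list("R1", c("c1", "c2", "n1", "n2")))
  post <- matrix(0, 1, 4, dimnames = list("R1", c("c1", "c2", "n1", "n2")))
  x <- make_test_study(pre, post, truth = c("cancer", "cancer", "normal", "normal"),
                       hit_cases = "c1", false_mark_cases = "n1")
  th <- theoretical_transform(x)
  rec <- th$decisions[th$decisions$phase == "post", ]
  rec <- setNames(rec$recall, rec$case_id)
  expect_identical(rec[["c1"]], 1L)   # missed but flagged -> recalled
  expect_identical(rec[["c2"]], 1L)   # unflagged recall survives
  expect_identical(rec[["n1"]], 1L)   # false flag converts the normal
  expect_identical(rec[["n2"]], 0L)
  # converted cancer recall points at the truth (counts as TP)
  expect_identical(reader_cdr(th, "R1", "post"), 1)
})

test_that("theoretical tpr and fpr never fall below the unaided ones", {
  for (s in c(6, 15)) {
    x <- simulate_study(sim_config(n_cancer = 30, n_normal = 15), seed = s)
    th <- theoretical_transform(x)
    for (r in x$readers) {
      pre_op <- reader_operating_point(x, r, "pre")
      th_op <- reader_operating_point(th, r, "post")
      expect_gte(th_op$tpr, pre_op$tpr)
      expect_gte(th_op$fpr, pre_op$fpr)
      pre_raw <- reader_cdr(x, r, "pre", localization = FALSE)
      th_raw <- reader_cdr(th, r, "post", localization = FALSE)
      expect_gte(th_raw, pre_raw)
    }
  }
})

test_that("adding a truth-hitting mark to an unflagged missed cancer raises theoretical tpr", {
  pre <- matrix(c(0, 1), 1, 2, dimnames = list("R1", c("c1", "c2")))
  x <- make_test_study(pre, pre, truth = c("cancer", "cancer"))
  base_tpr <- reader_cdr(theoretical_transform(x), "R1", "post")
  tb <- truth_box_for("R")
  x$marks <- tibble::tibble(case_id = "c1", view = tb$view, x = tb$x, y = tb$y,
                            w = tb$w, h = tb$h, neuscore = 90)
  flagged_tpr <- reader_cdr(theoretical_transform(x), "R1", "post")
  expect_gt(flagged_tpr, base_tpr)
})

test_that("percentage change in AUC matches the published pooled figures", {
  expect_equal(pct_change_auc(0.7599, 0.8148), 7.2246, tolerance = 1e-4)
  expect_identical(round_half_away(pct_change_auc(0.7599, 0.8148), 1), 7.2)
  expect_identical(pct_change_auc(0.42, 0.42), 0)
  expect_equal(pct_change_auc(0.5, 0.55), 10)
  expect_error(pct_change_auc(0, 0.5), class = "cadreader_undefined")
})
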