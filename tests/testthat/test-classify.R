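test_that("metric formulas match hand computation", {
  m <- compute_metrics(tp = 9, fp = 1, tn = 8, fn = 2)
  pos <- m$per_class[m$per_class$class == "positive", ]
  expect_equal(pos$precision, 0.9)
  expect_equal(pos$recall, 9 / 11)
  expect_equal(pos$f1, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))
  expect_equal(m$accuracy, 17 / 20)

  perfect <- compute_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$precision == 1))
  expect_true(all(perfect$per_class$f1 == 1))

  expect_warning(z <- compute_metrics(tp = 0, fp = 0, tn = 8, fn = 2),
                 "precision")
  expect_equal(z$per_class$precision[z$per_class$class == "positive"], 0)
})

test_that("multi-class metrics agree with a brute-force recount", {
  withr::with_seed(1, {
    truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
    pred <- ifelse(stats::runif(60) < 0.7, truth,
                   sample(c("A", "B", "C"), 60, replace = TRUE))
  })
  m <- compute_metrics(confusion_counts(truth, pred))
  expect_equal(m$accuracy, mean(truth == pred))
  for (cl in c("A", "B", "C")) {
    tp <- sum(truth == cl & pred == cl)
    p_hand <- if (sum(pred == cl) == 0) 0 else tp / sum(pred == cl)
    r_hand <- if (sum(truth == cl) == 0) 0 else tp / sum(truth == cl)
    row <- m$per_class[m$per_class$class == cl, ]
    expect_equal(row$precision, p_hand)
    expect_equal(row$recall, r_hand)
  }
})

test_that("grid search returns singleton grids, is deterministic, and validates family", {
  tb <- make_separable_table()
  gs <- grid_search_fit(tb, "DT", grid = list(maxdepth = 4, minsplit = 5),
                        seed = 1)
  expect_equal(gs$best_params$maxdepth, 4)
  expect_equal(gs$best_params$minsplit, 5)

  g2 <- list(maxdepth = c(3, 6), minsplit = c(2, 10))
  a <- grid_search_fit(tb, "DT", g2, seed = 9)
  b <- grid_search_fit(tb, "DT", g2, seed = 9)
  expect_identical(a$best_params, b$best_params)

  expect_error(grid_search_fit(tb, "SVM"),
               class = "cardiowave_invalid_family")
})

test_that("boosting separates a strongly planted two-class table", {
  tb <- make_separable_table(n = 80, d = 3)
  gs <- grid_search_fit(tb, "XGB",
                        grid = list(nrounds = 50, max_depth = 3, eta = 0.3),
                        seed = 2)
  pred <- predict(gs, tb)
  expect_gte(mean(pred == tb$class_label), 0.99)
})

test_that("all four model families fit and predict through the same surface", {
  tb <- make_separable_table(n = 60, d = 3)
  for (fam in c("DT", "RF", "MLP", "XGB")) {
    grid <- lapply(default_grid(fam), function(v) v[1])
    gs <- grid_search_fit(tb, fam, grid, seed = 3)
    pred <- predict(gs, tb)
    expect_gte(mean(pred == tb$class_label), 0.8)
  }
})

test_that("LOSO covers every subject exactly once and blocks label leaks", {
  tb <- make_separable_table(n = 60, d = 3)
  rep <- evaluate_loso(tb, "DT", grid = list(maxdepth = 3, minsplit = 2),
                       seed = 1)
  expect_identical(rep$scheme, "LOSO")
  expect_equal(nrow(rep$predictions), nrow(tb))
  per_subject <- table(rep$predictions$subject_id)
  expect_equal(as.integer(per_subject),
               as.integer(table(tb$subject_id)[names(per_subject)]))
  # metrics recomputable from stored prediction pairs
  recount <- compute_metrics(
    confusion_counts(rep$predictions$truth, rep$predictions$pred))
  expect_equal(rep$accuracy, recount$accuracy)

  bad <- tb
  bad$class_label[bad$subject_id == "S01"] <-
    rep(c("AS", "NON_AS"), length.out = sum(bad$subject_id == "S01"))
  expect_error(evaluate_loso(bad, "DT"), class = "cardiowave_data_leak")
})

test_that("LOSO with three single-segment subjects yields three predictions", {
  tb <- make_separable_table(n = 24, d = 3)
  tb3 <- tb[match(unique(tb$subject_id)[1:3], tb$subject_id), ]
  tb3$class_label <- c("AS", "NON_AS", "AS")
  rep <- suppressWarnings(  # degenerate folds can yield 0/0 metrics
    evaluate_loso(tb3, "XGB",
                  grid = list(nrounds = 5, max_depth = 2, eta = 0.3),
                  seed = 1))
  expect_equal(nrow(rep$predictions), 3)
})

test_that("leave-data-out splits are stratified partitions of the data", {
  tb <- make_planted_table(n = 100, p = 20, k = 5, d = 3, seed = 11)
  rep <- evaluate_leave_data_out(tb, "XGB",
                                 grid = list(nrounds = 30, max_depth = 3,
                                             eta = 0.3),
                                 ratio = 0.2, seed = 5)
  expect_equal(nrow(rep$predictions), 20)
  expect_equal(length(rep$test_index), 20)
  expect_equal(length(intersect(rep$test_index,
                                setdiff(seq_len(100), rep$test_index))), 0)
  # stratification: both classes near 20% held out
  held <- tb$class_label[rep$test_index]
  expect_equal(sum(held == "AS"), 10)
  expect_equal(sum(held == "NON_AS"), 10)

  big <- evaluate_leave_data_out(tb, "XGB",
                                 grid = list(nrounds = 30, max_depth = 3,
                                             eta = 0.3),
                                 ratio = 0.8, seed = 5)
  expect_equal(nrow(big$predictions), 80)
})

test_that("a class fully swallowed by the test split raises a degenerate-split error", {
  tb <- make_planted_table(n = 40, p = 10, k = 2, d = 2, seed = 2)
  tb$class_label[1:2] <- "AS_TR"
  tb$class_label[3:40] <- rep(c("AS", "NON_AS"), 19)
  expect_error(
    evaluate_leave_data_out(tb, "DT", grid = list(maxdepth = 3),
                            ratio = 0.9, seed = 1),
    class = "cardiowave_degenerate_split")
})

test_that("channel filtering keeps only the requested sources", {
  tb <- make_planted_table(n = 30, p = 60, seed = 4)
  sub <- filter_channels(tb, c("SCG_Z"))
  feats <- setdiff(names(sub), c("subject_id", "class_label"))
  expect_true(all(grepl("^SCG_Z_", feats)))
  expect_gt(length(feats), 0)
})
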