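test_that("planted discriminative features are recovered", {
  tb <- make_planted_table(n = 200, p = 250, k = 10, d = 2, seed = 42)
  sel <- elastic_net_select(tb, seed = 1)
  planted <- attr(tb, "planted")
  expect_gte(sum(planted %in% sel$selected_names), 8)
  expect_identical(sel$task, "BINARY")
  # bookkeeping invariants
  expect_equal(sel$n_selected, length(sel$selected_names))
  expect_equal(sel$reduction_pct,
               100 * (1 - sel$n_selected / sel$n_original))
  expect_true(all(sel$coefficients != 0))
})

test_that("selection is stable under feature column order", {
  tb <- make_planted_table(n = 120, p = 60, k = 5, d = 2.5, seed = 8)
  sel1 <- elastic_net_select(tb, seed = 3)
  feats <- setdiff(names(tb), c("subject_id", "class_label"))
  shuffled <- tb[c("subject_id", "class_label",
                   withr::with_seed(1, sample(feats)))]
  attr(shuffled, "planted") <- attr(tb, "planted")
  sel2 <- elastic_net_select(shuffled, seed = 3)
  expect_setequal(sel1$selected_names, sel2$selected_names)
})

test_that("label permutation selects almost nothing under the 1-SE rule", {
  tb <- make_planted_table(n = 150, p = 200, k = 10, d = 2, seed = 5)
  n_sel <- vapply(1:20, function(i) {
    perm <- tb
    perm$class_label <- withr::with_seed(100 + i,
                                         sample(perm$class_label))
    elastic_net_select(perm, seed = i)$n_selected
  }, numeric(1))
  expect_true(all(n_sel <= 0.05 * 200))
})

test_that("sparsity decreases monotonically with the penalty on the path", {
  tb <- make_planted_table(n = 150, p = 100, k = 8, d = 2, seed = 21)
  sel <- elastic_net_select(tb, seed = 2)
  # path_df: lambda descending -> nonzero count must never shrink
  expect_true(all(diff(sel$path_df$lambda) <= 0))
  expect_true(all(diff(sel$path_df$df) >= 0))
})

test_that("multi-class selection unions one-vs-rest supports", {
  tb <- make_planted_table(n = 160, p = 80, k = 6, d = 2.5, seed = 13)
  labs <- rep(c("AS", "AS_MI", "AS_MS", "AS_TR"), length.out = nrow(tb))
  tb$class_label <- labs
  # plant one extra feature separating AS_TR
  tb[[attr(tb, "planted")[1]]] <-
    rnorm(nrow(tb)) + 3 * (labs == "AS_TR")
  sel <- elastic_net_select(tb, seed = 4)
  expect_identical(sel$task, "MULTICLASS")
  expect_true(attr(tb, "planted")[1] %in% sel$selected_names)
})

test_that("degenerate label and constant-column inputs are handled", {
  tb <- make_planted_table(n = 60, p = 30, seed = 3)
  tb$class_label <- "AS"
  expect_error(elastic_net_select(tb),
               class = "cardiowave_degenerate_labels")

  tb2 <- make_planted_table(n = 60, p = 30, seed = 3)
  tb2[[attr(tb2, "planted")[1]]] <- 1  # constant
  expect_warning(sel <- elastic_net_select(tb2, seed = 1), "constant")
  expect_false(attr(tb2, "planted")[1] %in% sel$selected_names)
})

test_that("distribution summaries match hand counts and Pareto laws", {
  s <- summarize_selection(c("SCG_Z_MAX_5.00", "GCG_Y_MAX_12.00",
                             "GCG_Y_MED_21.00"))
  expect_equal(s$n_selected, 3)
  bands <- stats::setNames(s$bands$count, s$bands$category)
  expect_equal(bands[["<10 Hz"]], 1)
  expect_equal(bands[["10-20 Hz"]], 1)
  expect_equal(bands[[">20 Hz"]], 1)
  stat <- stats::setNames(s$statistics$count, s$statistics$category)
  expect_equal(stat[["MAX"]], 2)
  expect_equal(stat[["MED"]], 1)
  src <- stats::setNames(s$sources$count, s$sources$category)
  expect_equal(src[["GCG_Y"]], 2)
  expect_equal(src[["SCG_Z"]], 1)

  for (fam in list(s$bands, s$statistics, s$sources)) {
    expect_equal(sum(fam$count), 3)
    expect_true(all(diff(fam$pareto_pct) >= 0))
    expect_equal(fam$pareto_pct[nrow(fam)], 100)
  }

  one <- summarize_selection("SCG_X_IQR_3.00")
  expect_equal(one$statistics$pareto_pct[1], 100)

  expect_error(summarize_selection("bogus_name"),
               class = "cardiowave_malformed_feature_name")
})

test_that("tidiers expose coefficients and reduction summaries", {
  tb <- make_planted_table(n = 120, p = 50, k = 5, d = 2.5, seed = 6)
  sel <- elastic_net_select(tb, seed = 1)
  td <- tidy(sel)
  expect_true(all(c("feature", "coefficient", "freq_hz") %in% names(td)))
  expect_equal(nrow(td), sel$n_selected)
  gl <- glance(sel)
  expect_equal(gl$n_selected, sel$n_selected)
})
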