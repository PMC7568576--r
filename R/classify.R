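#' Confusion matrix and classification metrics
#'
#' `confusion_counts()` cross-tabulates truth against prediction over a
#' shared level set. `compute_metrics()` computes, for each class taken
#' one-vs-rest, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R), and overall accuracy = trace/total. A zero
#' denominator yields 0 with a warning.
#'
#' @param truth,pred factors or character vectors of equal length.
#' @return `confusion_counts()`: a K x K integer matrix (rows = truth,
#'   columns = prediction).
#' @export
confusion_counts <- function(truth, pred) {
  levels <- sort(unique(c(as.character(truth), as.character(pred))))
  table(
    truth = factor(truth, levels = levels),
    pred = factor(pred, levels = levels)
  )
}

#' @rdname confusion_counts
#' @param confusion K x K confusion matrix (rows = truth); alternatively
#'   give binary counts via `tp`, `fp`, `tn`, `fn`.
#' @param tp,fp,tn,fn binary-task counts (used when `confusion` is
#'   missing); the positive class is labeled `"positive"`.
#' @return `compute_metrics()`: object of class `evaluation_metrics` -
#'   list with `per_class` (tibble `class`, `precision`, `recall`, `f1`),
#'   `accuracy`, and `confusion`.
#' @examples
#' m <- compute_metrics(tp = 9, fp = 1, tn = 8, fn = 2)
#' m$accuracy  # 17/20
#' @export
compute_metrics <- function(confusion = NULL, tp = NULL, fp = NULL,
                            tn = NULL, fn = NULL) {
  if (is.null(confusion)) {
    stopifnot(!is.null(tp), !is.null(fp), !is.null(tn), !is.null(fn))
    confusion <- matrix(c(tp, fn, fp, tn), nrow = 2, byrow = TRUE,
                        dimnames = list(truth = c("positive", "negative"),
                                        pred = c("positive", "negative")))
  }
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  stopifnot(total > 0)
  k <- nrow(confusion)
  classes <- rownames(confusion) %||% as.character(seq_len(k))
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warn(sprintf("%s undefined for class %s (0/0); reporting 0", what, cl))
      0
    } else num / den
  }
  per <- lapply(seq_len(k), function(i) {
    tp_i <- confusion[i, i]
    fp_i <- sum(confusion[-i, i])
    fn_i <- sum(confusion[i, -i])
    p <- safe_div(tp_i, tp_i + fp_i, "precision", classes[i])
    r <- safe_div(tp_i, tp_i + fn_i, "recall", classes[i])
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    tibble(class = classes[i], precision = p, recall = r, f1 = f1)
  })
  structure(list(
    per_class = bind_rows(per),
    accuracy = sum(diag(confusion)) / total,
    confusion = confusion
  ), class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf("<evaluation_metrics> accuracy %.3f\n", x$accuracy))
  print(x$per_class)
  invisible(x)
}

default_grids <- function() {
  list(
    DT = list(maxdepth = c(3, 5, 10, 30), minsplit = c(2, 5, 10)),
    RF = list(num.trees = c(100, 300, 500), max.depth = c(5, 10, 0)),
    MLP = list(size = c(16, 64), decay = c(1e-3, 1e-4)),
    XGB = list(nrounds = c(100, 300), max_depth = c(3, 6),
               eta = c(0.05, 0.1))
  )
}

#' Default hyper-parameter grid for a model family
#'
#' @param family `"DT"`, `"RF"`, `"MLP"` or `"XGB"`.
#' @return named list of parameter vectors (the grid axes).
#' @export
default_grid <- function(family) {
  g <- default_grids()
  if (!family %in% names(g)) {
    abort(paste0("unknown model family: ", family),
          class = "cardiowave_invalid_family")
  }
  g[[family]]
}

fit_family <- function(family, x, y, params, seed) {
  y <- factor(y)
  if (nlevels(y) < 2) {
    # degenerate training fold: constant classifier
    return(structure(list(level = levels(y)), class = "cw_constant"))
  }
  switch(family,
    DT = {
      d <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth %||% 30,
                     minsplit = params$minsplit %||% 2,
                     cp = params$cp %||% 0.0, xval = 0))
    },
    RF = {
      d <- data.frame(.y = y, x, check.names = FALSE)
      ranger::ranger(.y ~ ., data = d,
                     num.trees = params$num.trees %||% 300,
                     max.depth = params$max.depth %||% 0,
                     seed = seed, num.threads = 1)
    },
    MLP = {
      with_seed(seed,
        nnet::nnet(x, nnet::class.ind(y),
                   size = params$size %||% 16,
                   decay = params$decay %||% 1e-3,
                   maxit = params$maxit %||% 200,
                   MaxNWts = 1e6, softmax = TRUE, trace = FALSE))
    },
    XGB = {
      nc <- nlevels(y)
      obj <- if (nc == 2) "binary:logistic" else "multi:softmax"
      pars <- list(max_depth = params$max_depth %||% 6,
                   eta = params$eta %||% 0.1,
                   objective = obj, nthread = 1,
                   seed = seed)
      if (nc > 2) pars$num_class <- nc
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(params = pars, data = dtrain,
                         nrounds = params$nrounds %||% 100,
                         verbose = 0)
    },
    abort(paste0("unknown model family: ", family),
          class = "cardiowave_invalid_family")
  )
}

predict_family <- function(family, fit, x, levels) {
  if (inherits(fit, "cw_constant")) {
    return(rep(fit$level, nrow(x)))
  }
  switch(family,
    DT = {
      p <- predict(fit, newdata = as.data.frame(x, check.names = FALSE),
                   type = "class")
      as.character(p)
    },
    RF = as.character(predict(fit, data = as.data.frame(x, check.names = FALSE),
                              num.threads = 1)$predictions),
    MLP = {
      p <- predict(fit, x)
      levels[max.col(p)]
    },
    XGB = {
      p <- predict(fit, x)
      if (length(levels) == 2) levels[(p > 0.5) + 1L] else levels[p + 1L]
    }
  )
}

split_folds <- function(y, k, seed) {
  # stratified fold assignment, deterministic in seed
  idx <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      rows <- which(y == cl)
      idx[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  idx
}

#' Exhaustive grid search with inner cross-validation
#'
#' Sweeps every combination of the grid axes, scores each by stratified
#' `inner_cv`-fold accuracy, breaks ties by first-in-grid order, and
#' refits the winner on the full table.
#'
#' @param table feature table (tibble with `class_label` and feature
#'   columns; `subject_id`/`start_s` are ignored for fitting).
#' @param family `"DT"`, `"RF"`, `"MLP"` or `"XGB"`.
#' @param grid named list of parameter value vectors; default
#'   [default_grid()].
#' @param inner_cv inner folds (default 3).
#' @param seed integer seed controlling folds and stochastic fits.
#' @return object of class `grid_search_fit`: list with `fit`,
#'   `best_params`, `cv_accuracy`, `results` (one row per grid point),
#'   `family`, `levels`.
#' @export
grid_search_fit <- function(table, family, grid = default_grid(family),
                            inner_cv = 3, seed = 1) {
  if (!family %in% names(default_grids())) {
    abort(paste0("unknown model family: ", family),
          class = "cardiowave_invalid_family")
  }
  stopifnot(length(grid) > 0)
  y <- as.character(table$class_label)
  x <- as.matrix(table[feature_columns(table)])
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  levels <- sort(unique(y))
  acc <- numeric(nrow(pts))
  if (nrow(pts) == 1) {
    acc[1] <- NA_real_  # nothing to compare
  } else {
    foldid <- split_folds(y, inner_cv, seed)
    for (j in seq_len(nrow(pts))) {
      params <- as.list(pts[j, , drop = FALSE])
      correct <- 0
      for (f in seq_len(inner_cv)) {
        tr <- foldid != f
        fit <- fit_family(family, x[tr, , drop = FALSE], y[tr], params,
                          seed + f)
        pred <- predict_family(family, fit, x[!tr, , drop = FALSE], levels)
        correct <- correct + sum(pred == y[!tr])
      }
      acc[j] <- correct / length(y)
    }
  }
  best <- if (all(is.na(acc))) 1L else which.max(acc)  # ties: first in grid
  best_params <- as.list(pts[best, , drop = FALSE])
  fit <- fit_family(family, x, y, best_params, seed)
  structure(list(
    fit = fit, best_params = best_params,
    cv_accuracy = acc[best],
    results = bind_cols(as_tibble(pts), tibble(cv_accuracy = acc)),
    family = family, levels = levels,
    feature_names = colnames(x)
  ), class = "grid_search_fit")
}

#' @export
predict.grid_search_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$feature_names])
  predict_family(object$family, object$fit, x, object$levels)
}

new_evaluation_report <- function(scheme, predictions, family, best_params,
                                  seed, extra = list()) {
  metrics <- compute_metrics(
    confusion_counts(predictions$truth, predictions$pred))
  structure(c(list(
    scheme = scheme,
    per_class = metrics$per_class,
    accuracy = metrics$accuracy,
    confusion = metrics$confusion,
    predictions = predictions,
    model_family = family,
    best_params = best_params,
    seed = seed
  ), extra), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s: accuracy %.3f (%d predictions)\n",
              x$scheme, x$model_family, x$accuracy, nrow(x$predictions)))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) x$per_class

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(scheme = x$scheme, model_family = x$model_family,
         accuracy = x$accuracy, n_predictions = nrow(x$predictions))
}

#' Leave-one-subject-out evaluation
#'
#' For each subject, optionally runs elastic-net feature selection and
#' then grid search on all remaining subjects' segments, predicts the
#' held-out subject's segments, and pools all held-out predictions into
#' one confusion matrix. No segment of the held-out subject ever enters
#' model fitting or feature selection, so subject identity cannot leak.
#'
#' @param table feature table with `subject_id`, `class_label` and
#'   feature columns.
#' @param family,grid,inner_cv,seed as in [grid_search_fit()].
#' @param select run [elastic_net_select()] inside each training fold and
#'   restrict to the selected features (default FALSE).
#' @param cv_folds folds for the embedded selection.
#' @return an `evaluation_report` with scheme `"LOSO"`; `predictions`
#'   has one row per segment (`subject_id`, `truth`, `pred`).
#' @export
evaluate_loso <- function(table, family, grid = default_grid(family),
                          inner_cv = 3, seed = 1, select = FALSE,
                          cv_folds = 5) {
  subjects <- unique(table$subject_id)
  stopifnot(length(subjects) >= 3)
  lab_per_subj <- dplyr::distinct(table, .data$subject_id, .data$class_label)
  if (anyDuplicated(lab_per_subj$subject_id)) {
    abort("a subject id carries more than one class label",
          class = "cardiowave_data_leak")
  }
  preds <- list()
  fold_params <- list()
  for (s in subjects) {
    train <- filter(table, .data$subject_id != s)
    test <- filter(table, .data$subject_id == s)
    if (select) {
      sel <- elastic_net_select(train, cv_folds = cv_folds, seed = seed)
      keep <- sel$selected_names
      if (length(keep) == 0) keep <- feature_columns(train)
      train <- select(train, all_of(c(meta_columns(train), keep)))
      test <- select(test, all_of(c(meta_columns(test), keep)))
    }
    gs <- grid_search_fit(train, family, grid, inner_cv, seed)
    fold_params[[s]] <- gs$best_params
    preds[[s]] <- tibble(
      subject_id = test$subject_id,
      truth = as.character(test$class_label),
      pred = predict(gs, test)
    )
  }
  new_evaluation_report("LOSO", bind_rows(preds), family,
                        fold_params, seed)
}

#' Leave-data-out (segment-level hold-out) evaluation
#'
#' Stratified random split at the segment level: subjects may appear in
#' both halves, which is exactly the subject bias that makes this scheme
#' optimistic relative to [evaluate_loso()].
#'
#' @inheritParams evaluate_loso
#' @param ratio fraction of segments held out for testing (default 0.2).
#' @param stratified stratify the split by class (default TRUE).
#' @return an `evaluation_report` with scheme `"LEAVE_DATA_OUT"`.
#' @export
evaluate_leave_data_out <- function(table, family,
                                    grid = default_grid(family),
                                    ratio = 0.2, stratified = TRUE,
                                    inner_cv = 3, seed = 1,
                                    select = FALSE, cv_folds = 5) {
  stopifnot(ratio > 0, ratio < 1)
  y <- as.character(table$class_label)
  n <- nrow(table)
  test_idx <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(unique(y), function(cl) {
        rows <- which(y == cl)
        sample(rows, round(length(rows) * ratio))
      }))
    } else {
      sample.int(n, round(n * ratio))
    }
  })
  test_idx <- sort(test_idx)
  train <- table[-test_idx, , drop = FALSE]
  test <- table[test_idx, , drop = FALSE]
  if (!all(unique(y) %in% train$class_label)) {
    abort("a class is absent from the training split",
          class = "cardiowave_degenerate_split")
  }
  if (select) {
    sel <- elastic_net_select(train, cv_folds = cv_folds, seed = seed)
    keep <- sel$selected_names
    if (length(keep) == 0) keep <- feature_columns(train)
    train <- select(train, all_of(c(meta_columns(train), keep)))
    test <- select(test, all_of(c(meta_columns(test), keep)))
  }
  gs <- grid_search_fit(train, family, grid, inner_cv, seed)
  preds <- tibble(
    subject_id = if ("subject_id" %in% names(test)) test$subject_id else
      NA_character_,
    truth = as.character(test$class_label),
    pred = predict(gs, test)
  )
  new_evaluation_report("LEAVE_DATA_OUT", preds, family, gs$best_params,
                        seed, extra = list(ratio = ratio,
                                           test_index = test_idx))
}
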