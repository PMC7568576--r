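#' Elastic-net feature selection
#'
#' Fits a penalized logistic regression (binomial for two classes; a
#' union of one-vs-rest binomial fits when more classes are present)
#' along a penalty path on z-scored features, chooses the penalty by
#' k-fold cross-validated deviance (the 1-SE rule by default, which
#' yields stable sparse sets), and returns the features with nonzero
#' coefficients at the chosen penalty. The elastic-net mixing parameter
#' `l1_ratio` (glmnet's alpha) defaults to 0.5.
#'
#' @param table feature table: tibble with `subject_id`, `class_label`,
#'   optionally `start_s`, and numeric feature columns (see
#'   [build_feature_table()]).
#' @param l1_ratio elastic-net mixing in `[0, 1]` (1 = lasso).
#' @param cv_folds folds for the cross-validated penalty choice.
#' @param seed integer; fold assignment (and hence the whole selection)
#'   is deterministic in it.
#' @param rule `"1se"` (default) or `"min"` penalty rule.
#' @return object of class `selection_result`: list with
#'   `selected_names`, `coefficients` (named vector over selected
#'   features; for multi-class, the largest-magnitude one-vs-rest
#'   coefficient), `n_original`, `n_selected`, `reduction_pct`
#'   (= 100 * (1 - n_selected / n_original)), `task` (`"BINARY"` or
#'   `"MULTICLASS"`), `path_df` (nonzero counts along the penalty path).
#' @examples
#' # see vignette("cardiowave-methods") for a planted-feature example
#' @export
elastic_net_select <- function(table, l1_ratio = 0.5, cv_folds = 5,
                               seed = 1, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  y <- as.character(table$class_label)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    abort("need at least 2 classes", class = "cardiowave_degenerate_labels")
  }
  feats <- feature_columns(table)
  x <- as.matrix(table[feats])
  if (nrow(x) < 2 * cv_folds) {
    abort("too few rows for the requested folds",
          class = "cardiowave_invalid_argument")
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant feature column(s)", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  xz <- scale(x)
  task <- if (length(classes) == 2) "BINARY" else "MULTICLASS"
  targets <- if (task == "BINARY") classes[2] else classes

  coefs <- numeric(ncol(xz))
  names(coefs) <- colnames(xz)
  path_df <- NULL
  for (cl in targets) {
    yy <- as.integer(y == cl)
    foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(xz))))
    cvfit <- glmnet::cv.glmnet(xz, yy, family = "binomial",
                               alpha = l1_ratio, foldid = foldid,
                               standardize = FALSE)
    s <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
    b <- as.numeric(coef(cvfit, s = s))[-1]
    keep <- abs(b) > abs(coefs)
    coefs[keep] <- b[keep]
    if (is.null(path_df)) {
      path_df <- tibble(lambda = cvfit$glmnet.fit$lambda,
                        df = cvfit$glmnet.fit$df)
    }
  }
  selected <- names(coefs)[coefs != 0]
  n_orig <- length(feats)
  structure(list(
    selected_names = selected,
    coefficients = coefs[selected],
    n_original = n_orig,
    n_selected = length(selected),
    reduction_pct = 100 * (1 - length(selected) / n_orig),
    task = task,
    l1_ratio = l1_ratio,
    rule = rule,
    path_df = path_df
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %s: %d / %d features selected (%.2f%% reduction, %s rule)\n",
    x$task, x$n_selected, x$n_original, x$reduction_pct, x$rule))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) {
  if (!length(x$selected_names)) {
    return(tibble(feature = character(0), coefficient = numeric(0),
                  channel = character(0), statistic = character(0),
                  freq_hz = numeric(0)))
  }
  parsed <- tryCatch(parse_feature_names(x$selected_names),
                     error = function(e) tibble(feature = x$selected_names))
  parsed$coefficient <- unname(x$coefficients[parsed$feature])
  parsed
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble(task = x$task, n_original = x$n_original,
         n_selected = x$n_selected, reduction_pct = x$reduction_pct)
}

#' Distribution summary of a selected feature set
#'
#' Counts selected features by frequency band (below 10 Hz, 10-20 Hz,
#' above 20 Hz - the acoustic-band view under which AS energy
#' concentrates below 10 Hz), by statistic (MEAN/MED/MAX/STD/IQR) and by
#' signal source (the six SCG/GCG axes), each with a Pareto sequence:
#' cumulative percentage after sorting categories by descending count.
#'
#' @param result a `selection_result`, or a character vector of selected
#'   feature names.
#' @return object of class `selection_summary`: list of three tibbles
#'   (`bands`, `statistics`, `sources`), each with `category`, `count`
#'   and, in descending-count order, `pareto_pct`; plus `n_selected`.
#' @export
summarize_selection <- function(result) {
  names <- if (inherits(result, "selection_result")) {
    result$selected_names
  } else {
    as.character(result)
  }
  parsed <- parse_feature_names(names)
  n <- nrow(parsed)

  band <- cut(parsed$freq_hz, breaks = c(-Inf, 10, 20, Inf),
              labels = c("<10 Hz", "10-20 Hz", ">20 Hz"), right = FALSE)
  # boundary convention: [0,10) / [10,20] / (20, inf): move exactly-20 down
  band[parsed$freq_hz == 20] <- "10-20 Hz"

  count_table <- function(values, levels) {
    counts <- table(factor(values, levels = levels))
    tb <- tibble(category = names(counts), count = as.integer(counts))
    tb <- arrange(tb, desc(.data$count))
    tb$pareto_pct <- if (n > 0) 100 * cumsum(tb$count) / n else numeric(nrow(tb))
    tb
  }

  structure(list(
    bands = count_table(band, c("<10 Hz", "10-20 Hz", ">20 Hz")),
    statistics = count_table(parsed$statistic, STATS),
    sources = count_table(parsed$channel, CHANNELS),
    n_selected = n
  ), class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("<selection_summary> %d selected features\n", x$n_selected))
  cat("frequency bands:\n"); print(x$bands)
  cat("statistics:\n"); print(x$statistics)
  cat("sources:\n"); print(x$sources)
  invisible(x)
}

#' @export
tidy.selection_summary <- function(x, ...) {
  bind_rows(
    mutate(x$bands, family = "band"),
    mutate(x$statistics, family = "statistic"),
    mutate(x$sources, family = "source")
  )
}
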