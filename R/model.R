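# Classifier layer. Synergistic pairs are coded as the positive class (1),
# antagonistic as negative (0). Gradient-boosted trees come from xgboost
# (missing feature values handled natively by its sparsity-aware splits);
# this module owns everything around them: stratified repeated CV, the
# metric panel, the exhaustive feature-subset search, baseline classifiers
# and the Y-scrambling permutation test.

.label_levels <- c("antagonistic", "synergistic")

.label_to_binary <- function(label) {
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(label))
  }
  if (!all(label %in% .label_levels)) {
    abort("labels must be 'synergistic' or 'antagonistic'")
  }
  as.integer(label == "synergistic")
}

.feature_matrix <- function(data, features) {
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("feature column(s) absent from data: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(data[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Default boosted-tree hyperparameters
#'
#' Library defaults for binary classification (logistic objective,
#' learning rate 0.3, depth 6, single thread for reproducibility);
#' override any of them via `...`. All values end up in the run manifest.
#'
#' @param ... Named overrides merged over the defaults.
#' @return Named list of xgboost parameters.
#' @export
syn_params <- function(...) {
  modifyList(list(objective = "binary:logistic", eta = 0.3, max_depth = 6,
                  nthread = 1), list(...))
}

#' Train a boosted-tree synergy classifier
#'
#' @param data Feature table with a `label` column
#'   (`synergistic`/`antagonistic`) and the feature columns; missing
#'   feature values (NA) are allowed.
#' @param features Feature subset to train on (canonical order is kept).
#' @param params Hyperparameters from [syn_params()].
#' @param nrounds Number of boosting rounds.
#' @param seed Integer seed; fitting is deterministic given it.
#' @return A `syn_fit`: list with the fitted booster, `features`,
#'   `params`, `nrounds`, `seed` and an `importance` tibble (`feature`,
#'   `gain`, `fscore`; unused features carry 0).
#' @export
syn_train <- function(data, features = feature_names(), params = syn_params(),
                      nrounds = 100, seed = 1) {
  features <- intersect(feature_names(), features) |>
    (\(x) if (length(x) == 0) features else x)()
  y <- .label_to_binary(data$label)
  if (length(unique(y)) < 2) abort("training data must contain both classes")
  m <- .feature_matrix(data, features)
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(m, label = y, missing = NA, nthread = 1),
    nrounds = nrounds, verbose = 0)
  raw <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  imp <- tibble::tibble(feature = features, gain = 0, fscore = 0)
  if (!is.null(raw) && nrow(raw) > 0) {
    idx <- match(raw$Feature, imp$feature)
    imp$gain[idx] <- raw$Gain
    imp$fscore[idx] <- raw$Frequency
  }
  structure(list(booster = booster, features = features, params = params,
                 nrounds = nrounds, seed = seed, importance = imp),
            class = "syn_fit")
}

#' @export
print.syn_fit <- function(x, ...) {
  cat(sprintf("<syn_fit> %d boosting rounds on %s\n", x$nrounds,
              paste(x$features, collapse = " + ")))
  invisible(x)
}

#' @export
tidy.syn_fit <- function(x, ...) {
  dplyr::arrange(x$importance, dplyr::desc(.data$gain))
}

#' Predict synergy probability for new drug pairs
#'
#' @param fit A `syn_fit`.
#' @param newdata Feature table containing the fit's feature columns.
#' @return Numeric vector of probabilities in \[0, 1\]; values above 0.5
#'   lean synergistic, below antagonistic.
#' @export
predict_probability <- function(fit, newdata) {
  if (!inherits(fit, "syn_fit")) abort("expected a syn_fit")
  m <- .feature_matrix(newdata, fit$features)
  as.numeric(predict(fit$booster,
                     xgboost::xgb.DMatrix(m, missing = NA, nthread = 1)))
}

#' Interpret a synergy probability
#'
#' Probabilities above 0.5 indicate a synergistic-leaning combination and
#' below 0.5 an antagonistic-leaning one; values within `epsilon` of 0.5
#' are flagged as additive-leaning.
#'
#' @param prob Numeric vector of probabilities.
#' @param epsilon Half-width of the additive band around 0.5.
#' @return Character vector in `{"synergistic", "antagonistic",
#'   "additive-leaning"}`.
#' @export
interpret_probability <- function(prob, epsilon = 0.05) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) abort("probabilities must lie in [0, 1]")
  dplyr::case_when(
    abs(prob - 0.5) <= epsilon ~ "additive-leaning",
    prob > 0.5 ~ "synergistic",
    TRUE ~ "antagonistic"
  )
}

.auc_midrank <- function(y, prob) {
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(prob)  # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric panel
#'
#' AUC (rank statistic with midranks for ties) plus confusion-matrix
#' metrics at a fixed threshold: sensitivity, specificity, PPV, NPV,
#' accuracy and F1. Synergistic is the positive class.
#'
#' @param labels Labels (`synergistic`/`antagonistic` or 0/1).
#' @param probabilities Predicted synergy probabilities.
#' @param threshold Decision threshold (default 0.5, not tuned).
#' @return One-row tibble with the seven metrics (undefined ratios are
#'   `NA`).
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  y <- .label_to_binary(labels)
  if (length(y) != length(probabilities)) abort("labels/probabilities length mismatch")
  pred <- as.integer(probabilities > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  tibble::tibble(
    auc = .auc_midrank(y, probabilities),
    sensitivity = rec,
    specificity = safe(tn, tn + fp),
    ppv = prec,
    npv = safe(tn, tn + fn),
    accuracy = (tp + tn) / length(y),
    f1 = if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
      2 * prec * rec / (prec + rec)
  )
}

#' Cross-validation configuration
#'
#' @param n_folds Folds per run (default 5).
#' @param n_repeats CV repetitions (default 50).
#' @param seed Base seed; repeat r uses `seed + r`.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 5, n_repeats = 50, seed = 1) {
  structure(list(n_folds = n_folds, n_repeats = n_repeats, seed = seed,
                 stratified = TRUE), class = "cv_config")
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin (with a shuffled fold order), so per-fold class counts
# differ from perfect proportionality by less than one member.
.stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(sample(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of the boosted-tree classifier
#'
#' Each repetition draws a fresh stratified fold assignment (class
#' prevalence preserved up to integer rounding), trains on the in-folds
#' and scores the held-out fold, then computes the metric panel on the
#' pooled out-of-fold predictions of that repetition. Metrics are
#' summarized as mean and SD across repetitions. The per-pair, per-repeat
#' out-of-fold record feeds the applicability-domain analysis.
#'
#' @param data Labeled feature table (needs `drug_a`/`drug_b` columns for
#'   the CV record; synthesized row ids are used when absent).
#' @param features Feature subset.
#' @param config A [cv_config()].
#' @param params,nrounds Passed to [syn_train()].
#' @return A `syn_cv`: list with `metrics` (one row per repeat),
#'   `summary` (mean/sd per metric), `cv_record` (tibble `pair_id`,
#'   `repeat`, `prob`, `correct`), `features`, `config`.
#' @export
repeated_cv <- function(data, features = feature_names(),
                        config = cv_config(), params = syn_params(),
                        nrounds = 100) {
  y <- .label_to_binary(data$label)
  if (min(table(y)) < config$n_folds) {
    abort("each class must have at least n_folds members")
  }
  ids <- if (all(c("drug_a", "drug_b") %in% names(data))) {
    pair_id(data$drug_a, data$drug_b)
  } else {
    sprintf("pair_%04d", seq_len(nrow(data)))
  }
  metrics <- vector("list", config$n_repeats)
  records <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    set.seed(config$seed + r)
    fold <- .stratified_folds(y, config$n_folds)
    prob <- rep(NA_real_, nrow(data))
    for (k in seq_len(config$n_folds)) {
      hold <- fold == k
      fit <- syn_train(data[!hold, , drop = FALSE], features, params,
                       nrounds, seed = config$seed + r)
      prob[hold] <- predict_probability(fit, data[hold, , drop = FALSE])
    }
    metrics[[r]] <- dplyr::bind_cols(tibble::tibble(run = r),
                                     compute_metrics(y, prob))
    records[[r]] <- tibble::tibble(pair_id = ids, run = r, prob = prob,
                                   correct = as.integer(prob > 0.5) == y)
  }
  metrics <- dplyr::bind_rows(metrics)
  summary <- metrics |>
    tidyr::pivot_longer(-"run", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(metrics = metrics, summary = summary,
                 cv_record = dplyr::bind_rows(records),
                 features = features, config = config),
            class = "syn_cv")
}

#' @export
print.syn_cv <- function(x, ...) {
  cat(sprintf("<syn_cv> %d x %d-fold CV on %s\n", x$config$n_repeats,
              x$config$n_folds, paste(x$features, collapse = " + ")))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.syn_cv <- function(x, ...) x$summary

#' @export
glance.syn_cv <- function(x, ...) {
  wide <- setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(tibble::as_tibble(wide),
                   tibble::tibble(n_repeats = x$config$n_repeats,
                                  n_folds = x$config$n_folds))
}

#' Exhaustive feature-subset model search
#'
#' Evaluates every non-empty subset of the seven features (127 models) by
#' mean repeated-CV accuracy under a shared fold scheme. The best subset
#' is the accuracy argmax; ties prefer the smaller subset, then
#' lexicographic order.
#'
#' @param data Labeled feature table.
#' @param config A [cv_config()]; the default search uses the same
#'   repeated-CV machinery as [repeated_cv()].
#' @param params,nrounds Passed to [syn_train()].
#' @param features Candidate feature pool (default all seven).
#' @return A `syn_search`: list with `results` (tibble `subset`, `size`,
#'   `accuracy`), `best_subset` (character vector), `n_models`.
#' @export
subset_search <- function(data, config = cv_config(), params = syn_params(),
                          nrounds = 100, features = feature_names()) {
  subsets <- unlist(lapply(seq_along(features), function(k) {
    combn(features, k, simplify = FALSE)
  }), recursive = FALSE)
  acc <- vapply(subsets, function(sub) {
    cv <- repeated_cv(data, sub, config, params, nrounds)
    mean(cv$metrics$accuracy)
  }, 0)
  results <- tibble::tibble(
    subset = vapply(subsets, paste, "", collapse = "+"),
    size = lengths(subsets),
    accuracy = acc
  )
  ord <- order(-results$accuracy, results$size, results$subset)
  structure(list(results = results, best_subset = subsets[[ord[1]]],
                 n_models = length(subsets), config = config),
            class = "syn_search")
}

#' @export
print.syn_search <- function(x, ...) {
  cat(sprintf("<syn_search> %d models; best: %s (accuracy %.3f)\n",
              x$n_models, paste(x$best_subset, collapse = " + "),
              max(x$results$accuracy)))
  invisible(x)
}

#' @export
tidy.syn_search <- function(x, ...) {
  dplyr::arrange(x$results, dplyr::desc(.data$accuracy))
}

# ---- baseline classifiers --------------------------------------------------

.fit_baseline <- function(kind, data, features, seed) {
  y <- factor(.label_to_binary(data$label), levels = c(0, 1))
  df <- as.data.frame(.feature_matrix(data, features))
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2) abort("baseline training data must contain both classes")
  set.seed(seed)
  switch(kind,
    lr = {
      fit <- suppressWarnings(glm(y ~ ., data = cbind(df, y = y),
                                  family = binomial()))
      list(predict = function(nd) {
        as.numeric(predict(fit, newdata = nd, type = "response"))
      })
    },
    nb = {
      fit <- e1071::naiveBayes(x = df, y = y)
      list(predict = function(nd) {
        predict(fit, newdata = nd, type = "raw")[, "1"]
      })
    },
    rf = {
      fit <- randomForest::randomForest(x = df, y = y)
      list(predict = function(nd) {
        predict(fit, newdata = nd, type = "prob")[, "1"]
      })
    },
    abort(sprintf("unknown baseline '%s'", kind))
  )
}

.classifier_cv <- function(kind, data, features, config, params, nrounds) {
  if (kind == "xgb") {
    return(repeated_cv(data, features, config, params, nrounds))
  }
  data <- complete_cases(data, features)
  y <- .label_to_binary(data$label)
  if (min(table(y)) < config$n_folds) {
    abort("each class must have at least n_folds complete-case members")
  }
  metrics <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    set.seed(config$seed + r)
    fold <- .stratified_folds(y, config$n_folds)
    prob <- rep(NA_real_, nrow(data))
    for (k in seq_len(config$n_folds)) {
      hold <- fold == k
      mdl <- .fit_baseline(kind, data[!hold, , drop = FALSE], features,
                           seed = config$seed + r)
      nd <- as.data.frame(.feature_matrix(data[hold, , drop = FALSE], features))
      prob[hold] <- mdl$predict(nd)
    }
    metrics[[r]] <- dplyr::bind_cols(tibble::tibble(run = r),
                                     compute_metrics(y, prob))
  }
  list(metrics = dplyr::bind_rows(metrics))
}

#' Compare the boosted-tree model with baseline classifiers
#'
#' Trains XGBoost, logistic regression (LR), naive Bayes (NB) and random
#' forest (RF) on the training table and reports, per classifier and
#' metric, the repeated-CV mean and SD, the independent-validation (IV)
#' value, and |CV - IV| as an overfitting gauge. Baselines see
#' complete-case rows only (they cannot consume missing features); the
#' boosted-tree model uses all rows.
#'
#' @param train,valid Disjoint labeled feature tables.
#' @param features Feature subset.
#' @param config A [cv_config()].
#' @param params,nrounds Boosted-tree settings.
#' @return A tibble: `classifier`, `metric`, `cv_mean`, `cv_sd`, `iv`,
#'   `abs_diff`.
#' @export
compare_classifiers <- function(train, valid, features = feature_names(),
                                config = cv_config(), params = syn_params(),
                                nrounds = 100) {
  kinds <- c("xgb", "lr", "nb", "rf")
  purrr::map_dfr(kinds, function(kind) {
    cv <- .classifier_cv(kind, train, features, config, params, nrounds)
    cv_long <- cv$metrics |>
      tidyr::pivot_longer(-"run", names_to = "metric", values_to = "value") |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(cv_mean = mean(.data$value, na.rm = TRUE),
                       cv_sd = sd(.data$value, na.rm = TRUE),
                       .groups = "drop")
    if (kind == "xgb") {
      fit <- syn_train(train, features, params, nrounds, seed = config$seed)
      v <- valid
      prob <- predict_probability(fit, v)
    } else {
      tr <- complete_cases(train, features)
      v <- complete_cases(valid, features)
      mdl <- .fit_baseline(kind, tr, features, seed = config$seed)
      prob <- mdl$predict(as.data.frame(.feature_matrix(v, features)))
    }
    iv <- compute_metrics(v$label, prob) |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                          values_to = "iv")
    dplyr::left_join(cv_long, iv, by = "metric") |>
      dplyr::mutate(classifier = kind,
                    abs_diff = abs(.data$cv_mean - .data$iv),
                    .before = 1)
  })
}

#' Y-scrambling permutation test of validation accuracy
#'
#' Refits the classifier on label-shuffled copies of the training table
#' and records validation accuracy under each null model. The p-value is
#' (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param train,valid Labeled feature tables.
#' @param features Feature subset.
#' @param n_perm Number of permutations (2000 in the full design).
#' @param seed Integer seed.
#' @param params,nrounds Boosted-tree settings.
#' @return A `syn_permtest`: list with `observed`, `null` (numeric
#'   vector), `p_value`, `n_perm`.
#' @export
permutation_test <- function(train, valid, features = feature_names(),
                             n_perm = 2000, seed = 1, params = syn_params(),
                             nrounds = 100) {
  y_valid <- .label_to_binary(valid$label)
  fit <- syn_train(train, features, params, nrounds, seed = seed)
  observed <- mean(as.integer(
    predict_probability(fit, valid) > 0.5) == y_valid)
  null <- vapply(seq_len(n_perm), function(i) {
    set.seed(seed + i)
    shuffled <- train
    shuffled$label <- sample(shuffled$label)
    f <- tryCatch(
      syn_train(shuffled, features, params, nrounds, seed = seed + i),
      error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    mean(as.integer(predict_probability(f, valid) > 0.5) == y_valid)
  }, 0)
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= observed)) / (length(null) + 1)
  structure(list(observed = observed, null = null, p_value = p,
                 n_perm = n_perm),
            class = "syn_permtest")
}

#' @export
print.syn_permtest <- function(x, ...) {
  cat(sprintf("<syn_permtest> observed accuracy %.3f vs %d null models; p = %.4g\n",
              x$observed, length(x$null), x$p_value))
  invisible(x)
}

#' @export
glance.syn_permtest <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = mean(x$null),
                 null_sd = sd(x$null), p_value = x$p_value,
                 n_perm = length(x$null))
}
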