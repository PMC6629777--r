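# Classifier layer: training, metrics, CV, subset search, baselines,
# permutation test.

test_that("training is deterministic, handles missing values and degenerate subsets", {
  d <- planted_dataset(n = 150, seed = 1)
  d$bps[1:20] <- NA  # boosted trees must cope with missing entries
  f1 <- syn_train(d, seed = 7)
  f2 <- syn_train(d, seed = 7)
  expect_identical(predict_probability(f1, d), predict_probability(f2, d))
  p <- predict_probability(f1, d)
  expect_true(all(p >= 0 & p <= 1))
  # single-feature subset still trains and predicts
  f3 <- syn_train(d, features = "adrid")
  expect_true(all(predict_probability(f3, d) >= 0))
  # single-class input errors
  d1 <- d; d1$label <- "synergistic"
  expect_error(syn_train(d1), "both classes")
})

test_that("planted-signal features dominate the importance ranking", {
  d <- planted_dataset(n = 300, beta = c(adrid = 3, bps = -3), sigma = 0.3,
                       seed = 3)
  fit <- syn_train(d, seed = 3)
  ranking <- tidy(fit)$feature
  expect_setequal(ranking[1:2], c("adrid", "bps"))
})

test_that("probability interpretation uses the 0.5 scale with an additive band", {
  expect_equal(interpret_probability(c(0.9, 0.1, 0.51, 0.46)),
               c("synergistic", "antagonistic", "additive-leaning",
                 "additive-leaning"))
  expect_equal(interpret_probability(0.51, epsilon = 0), "synergistic")
  expect_error(interpret_probability(1.2), "0, 1")
})

test_that("metric panel matches a brute-force tallier on random inputs", {
  set.seed(55)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    prob <- round(runif(n), 2)  # rounding forces ties for the AUC
    m <- compute_metrics(y, prob)
    o <- oracle_metrics(y, prob)
    expect_equal(m$accuracy, (o$tp + o$tn) / n)
    if (!is.na(m$sensitivity)) expect_equal(m$sensitivity, o$tp / (o$tp + o$fn))
    if (!is.na(m$specificity)) expect_equal(m$specificity, o$tn / (o$tn + o$fp))
    if (!is.na(m$ppv)) expect_equal(m$ppv * (o$tp + o$fp), o$tp)
    if (!is.na(m$npv)) expect_equal(m$npv * (o$tn + o$fn), o$tn)
    if (!is.na(m$f1)) {
      prec <- o$tp / (o$tp + o$fp); rec <- o$tp / (o$tp + o$fn)
      expect_equal(m$f1, 2 * prec * rec / (prec + rec))
    }
    expect_equal(m$auc, oracle_auc(y, prob))
  }
})

test_that("metric panel handles hand-computed confusion cases", {
  # all predicted positive on a 42:16 split
  y <- c(rep(1, 42), rep(0, 16))
  m <- compute_metrics(y, rep(0.9, 58))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_equal(m$accuracy, 42 / 58)
  # perfect separation
  m2 <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(all(m2[c("auc", "sensitivity", "specificity", "ppv", "npv",
                       "accuracy", "f1")] == 1))
  # one-class labels: AUC undefined with a warning
  expect_warning(m3 <- compute_metrics(c(1, 1), c(0.6, 0.7)), "one class")
  expect_true(is.na(m3$auc))
  # random scores give AUC near one half
  set.seed(8)
  m4 <- compute_metrics(rbinom(4000, 1, 0.5), runif(4000))
  se <- sqrt(1 / 12) / sqrt(1000)  # loose large-n bound
  expect_lt(abs(m4$auc - 0.5), 3 * se)
})

test_that("midrank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rbinom(80, 1, 0.6)
  prob <- round(runif(80), 1)
  m <- compute_metrics(y, prob)
  ref <- as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$auc, ref)
})

test_that("stratified folds preserve prevalence within one member", {
  set.seed(10)
  d <- planted_dataset(n = 115, seed = 10)
  d$label <- c(rep("synergistic", 85), rep("antagonistic", 30))
  cv <- repeated_cv(d, "adrid", cv_config(5, 3, seed = 2), nrounds = 10)
  # reconstruct the folds the same way to check the stratification rule
  y <- as.integer(d$label == "synergistic")
  for (r in 1:3) {
    set.seed(2 + r)
    fold <- drugsyn:::.stratified_folds(y, 5)
    for (k in 1:5) {
      expect_lt(abs(sum(y[fold == k]) - 85 / 5), 1)
      expect_lt(abs(sum(1 - y[fold == k]) - 30 / 5), 1)
    }
  }
  # record bookkeeping: each pair held out exactly once per repeat
  expect_equal(nrow(cv$cv_record), 115 * 3)
  per_pair <- table(cv$cv_record$pair_id)
  expect_true(all(per_pair == 3))
  expect_error(repeated_cv(d[c(1:4, 90:93), ], "adrid", cv_config(5, 2, 1)),
               "n_folds")
})

test_that("repeated CV recovers a strong planted signal and is seed-stable", {
  d <- planted_dataset(n = 200, beta = c(adrid = 3, bps = -3), sigma = 0.3,
                       seed = 4)
  cv <- repeated_cv(d, feature_names(), cv_config(5, 5, seed = 9),
                    nrounds = 40)
  expect_gt(mean(cv$metrics$accuracy), 0.8)
  cv2 <- repeated_cv(d, feature_names(), cv_config(5, 5, seed = 9),
                     nrounds = 40)
  expect_identical(glance(cv), glance(cv2))
  expect_equal(nrow(cv$metrics), 5)
  expect_true(all(cv$summary$mean >= 0 & cv$summary$mean <= 1))
})

test_that("subset search enumerates 127 models and finds planted features", {
  d <- planted_dataset(n = 120, beta = c(adrid = 4, bps = -4), sigma = 0.2,
                       seed = 6)
  res <- subset_search(d, cv_config(3, 1, seed = 5), nrounds = 8)
  expect_equal(res$n_models, 127)
  expect_equal(nrow(res$results), 127)
  expect_equal(sum(choose(7, 1:7)), 127)
  expect_true(all(c("adrid", "bps") %in% res$best_subset))
  # argmax property: best subset beats every single feature alone
  singles <- res$results$accuracy[res$results$size == 1]
  expect_gte(max(res$results$accuracy), max(singles))
  # every subset evaluated exactly once
  expect_equal(anyDuplicated(res$results$subset), 0)
})

test_that("classifier comparison reports CV, IV and their gap for all four models", {
  d <- planted_dataset(n = 160, seed = 12)
  train <- d[1:110, ]; valid <- d[111:160, ]
  tab <- compare_classifiers(train, valid, feature_names(),
                             cv_config(5, 2, seed = 3), nrounds = 20)
  expect_setequal(unique(tab$classifier), c("xgb", "lr", "nb", "rf"))
  expect_setequal(unique(tab$metric),
                  c("auc", "sensitivity", "specificity", "ppv", "npv",
                    "accuracy", "f1"))
  expect_equal(nrow(tab), 4 * 7)
  ok <- !is.na(tab$abs_diff)
  expect_true(all(tab$abs_diff[ok] >= 0))
  expect_equal(tab$abs_diff[ok], abs(tab$cv_mean - tab$iv)[ok])
  acc <- tab[tab$metric == "accuracy", ]
  expect_true(all(acc$cv_mean > 0.5))
})

test_that("permutation test separates signal from noise", {
  d <- planted_dataset(n = 150, beta = c(adrid = 4, bps = -4), sigma = 0.2,
                       seed = 14)
  train <- d[1:100, ]; valid <- d[101:150, ]
  pt <- permutation_test(train, valid, n_perm = 60, seed = 2, nrounds = 15)
  expect_lte(pt$p_value, 0.05)
  expect_gt(pt$p_value, 0)
  # pure-noise labels: p should be unremarkable
  set.seed(99)
  d0 <- planted_dataset(n = 120, beta = c(adrid = 0), sigma = 1, seed = 15)
  pt0 <- permutation_test(d0[1:80, ], d0[81:120, ], n_perm = 60, seed = 3,
                          nrounds = 15)
  expect_gt(pt0$p_value, 0.05)
  expect_lte(pt0$p_value, 1)
})
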