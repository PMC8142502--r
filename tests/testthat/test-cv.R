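test_that("holdout split is stratified, sized by rounding, deterministic", {
  d <- generate_synthetic(synth_config(n_per_class = 60, seed = 1))
  d <- d[c(1:60, 61:100), ]  # 60 MP / 40 NONMP
  sp <- make_split(d, 0.2, seed = 5)
  expect_length(sp$test_ids, 20L)
  lab <- d$label[match(sp$test_ids, d$id)]
  expect_equal(sum(lab == "MP"), 12L)
  expect_equal(sum(lab == "NONMP"), 8L)
  expect_setequal(c(sp$test_ids, sp$train_ids), d$id)
  expect_identical(make_split(d, 0.2, seed = 5)$test_ids, sp$test_ids)

  # round-half-away-from-zero at the study size: 0.2 * 351 = 70.2 -> 70
  d351 <- generate_synthetic(synth_config(n_per_class = 200, seed = 2))
  d351 <- d351[c(1:215, 225:360), ]
  d351$id <- sprintf("q%03d", seq_len(351))
  expect_length(make_split(d351, 0.2, seed = 1)$test_ids, 70L)
  expect_error(make_split(d, 1.2), "fraction")
})

test_that("fold plans partition ids evenly, once per repeat, reproducibly", {
  ids <- sprintf("p%02d", 1:20)
  labs <- rep(c("MP", "NONMP"), 10)
  plan <- make_fold_plan(ids, labs, repeats = 8, K = 10, seed = 9)
  for (r in unique(plan$rep)) {
    pr <- plan[plan$rep == r, ]
    expect_setequal(pr$id, ids)                       # validation exactly once
    expect_true(all(table(pr$fold) == 2))             # 20 ids over 10 folds
  }
  sizes <- table(plan$fold[plan$rep == 1])
  expect_lte(max(sizes) - min(sizes), 1)
  plan2 <- make_fold_plan(ids, labs, repeats = 8, K = 10, seed = 9)
  expect_identical(fold_plan_checksum(plan), fold_plan_checksum(plan2))
  plan3 <- make_fold_plan(ids, labs, repeats = 8, K = 10, seed = 10)
  expect_false(identical(fold_plan_checksum(plan), fold_plan_checksum(plan3)))
  expect_error(make_fold_plan(ids[1:5], labs[1:5], K = 10), "at least")
})

test_that("a perfectly separating feature yields perfect CV metrics", {
  d <- tiny_dataset(n_per_class = 15)
  feats <- tibble::tibble(id = d$id, ind = as.numeric(d$label == "MP"))
  plan <- make_fold_plan(d$id, d$label, repeats = 3, K = 10, seed = 1)
  for (fam in c("NB", "DT", "KNN")) {
    cv <- run_cv(feats, d[, c("id", "label")], classifier_config(fam),
                 plan, seed = 1)
    expect_equal(cv$metrics$acc, 1, info = fam)
    expect_equal(cv$metrics$mcc, 1, info = fam)
  }
})

test_that("prediction log has one row per protein per repeat", {
  d <- tiny_dataset(n_per_class = 10)
  feats <- extract_features(d, "SGAAC")
  plan <- make_fold_plan(d$id, d$label, repeats = 4, K = 5, seed = 2)
  cv <- run_cv(feats, d[, c("id", "label")], classifier_config("NB"),
               plan, seed = 2)
  expect_equal(nrow(cv$log), 20L * 4L)
  expect_equal(nrow(dplyr::distinct(cv$log, id, rep)), 20L * 4L)
  expect_identical(cv$log$correct, cv$log$truth == cv$log$predicted)
  expect_equal(nrow(cv$per_repeat), 4L)
})

test_that("shuffled labels give chance-level accuracy", {
  withr::with_seed(31, {
    d <- tiny_dataset(n_per_class = 20, seed = 77)
    d$label <- sample(d$label)   # destroy the signal
    feats <- extract_features(d, "SGAAC")
    plan <- make_fold_plan(d$id, d$label, repeats = 10, K = 10, seed = 3)
    cv <- run_cv(feats, d[, c("id", "label")], classifier_config("NB"),
                 plan, seed = 3)
    # majority-class fraction is 0.5 on balanced data; 3 binomial SEs
    expect_lt(abs(cv$metrics$acc - 0.5), 3 * sqrt(0.25 / 40))
  })
})

test_that("CV accuracy recovers a known Bayes rate on synthetic data", {
  # one Gaussian feature, unit separation: Bayes accuracy pnorm(0.5)
  withr::with_seed(32, {
    n <- 60
    d <- tibble::tibble(id = sprintf("s%03d", 1:(2 * n)),
                        sequence = strrep("A", 31),
                        label = rep(c("MP", "NONMP"), each = n))
    feats <- tibble::tibble(id = d$id,
                            x = rnorm(2 * n, ifelse(d$label == "MP", 0.5, -0.5)))
    plan <- make_fold_plan(d$id, d$label, repeats = 20, K = 10, seed = 4)
    cv <- run_cv(feats, d[, c("id", "label")], classifier_config("NB"),
                 plan, seed = 4)
    bayes <- pnorm(0.5)
    se <- sqrt(bayes * (1 - bayes) / (2 * n))
    expect_lt(abs(cv$metrics$acc - bayes), 3 * se)
  })
})

test_that("every classifier family fits, predicts and scores in [0, 1]", {
  d <- tiny_dataset(n_per_class = 12, seed = 13)
  feats <- extract_features(d, "SGAAC")
  plan <- make_fold_plan(d$id, d$label, repeats = 1, K = 4, seed = 5)
  for (fam in c("SVM", "KNN", "NB", "DT", "RF", "MLP", "ADA", "LR")) {
    cfg <- classifier_config(fam)
    if (fam == "ADA") cfg <- classifier_config("ADA", nlearners = 25)
    cv <- run_cv(feats, d[, c("id", "label")], cfg, plan, seed = 5)
    expect_true(all(cv$log$score >= 0 & cv$log$score <= 1), info = fam)
    expect_gte(cv$metrics$acc, 0.8)  # classes are fully separable
  }
})

test_that("benchmark cells share one fold plan and deterministic reruns agree", {
  d <- tiny_dataset(n_per_class = 15, seed = 14)
  b1 <- benchmark_grid(d, c("SGAAC", "CTDC"), c("NB", "KNN"),
                       repeats = 2, K = 5, seed = 6)
  expect_equal(nrow(b1$report), 4L)
  expect_length(unique(b1$report$fold_checksum), 1L)
  b2 <- benchmark_grid(d, c("SGAAC", "CTDC"), c("NB", "KNN"),
                       repeats = 2, K = 5, seed = 6)
  expect_equal(b1$report, b2$report)
  expect_true(all(b1$report$acc >= 0.8))  # separable sanity ordering

  td <- tidy(b1)
  expect_true(all(c("descriptor", "family", "metric", "value") %in% names(td)))
  g <- glance(b1)
  expect_equal(g$n_cells, 4L)
  expect_s3_class(autoplot(b1), "ggplot")
})

test_that("holdout evaluation trains only on the training side", {
  d <- tiny_dataset(n_per_class = 15, seed = 15)
  feats <- extract_features(d, "SGAAC")
  sp <- make_split(d, 0.2, seed = 7)
  m <- evaluate_holdout(feats, d[, c("id", "label")],
                        classifier_config("NB"), sp, seed = 7)
  expect_gte(m$acc, 0.8)
  expect_true("auc" %in% names(m))
})

test_that("in-package Gaussian NB agrees with an independent implementation", {
  withr::with_seed(33, {
    X <- matrix(rnorm(80 * 6, rep(c(0, 1), each = 40)), 80, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rep(c("MP", "NONMP"), each = 40)
    Xnew <- matrix(rnorm(30 * 6), 30, 6,
                   dimnames = list(NULL, paste0("f", 1:6)))
  })
  fit <- mooncop:::fit_classifier(classifier_config("NB"), X, y)
  ours <- mooncop:::predict_classifier(fit, Xnew)$score
  ref <- e1071::naiveBayes(as.data.frame(X), factor(y))
  theirs <- predict(ref, as.data.frame(Xnew), type = "raw")[, "MP"]
  expect_equal(ours, unname(theirs), tolerance = 1e-6)
})
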