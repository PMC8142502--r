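# Evaluation protocol: stratified 80/20 holdout, repeated stratified
# K-fold cross-validation with a fold plan that is built once and shared
# across every descriptor x model combination being compared, and
# per-repeat pooled metrics averaged over repeats.

# documented counter scheme: every stochastic component draws its seed
# from the master seed plus a stage offset, keeping seeds under 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647)
}

# stratified assignment of ids to K folds (fold sizes differ by <= 1
# overall, classes spread as evenly as possible)
stratified_folds <- function(ids, labels, K) {
  fold <- integer(length(ids))
  offset <- 0L
  for (lab in unique(labels)) {
    i <- which(labels == lab)
    # rotate the fold sequence between strata so small strata do not all
    # land in fold 1, then deal shuffled ids round-robin
    fold[sample(i)] <- ((seq_along(i) - 1L + offset) %% K) + 1L
    offset <- offset + length(i)
  }
  fold
}

#' Stratified train/test split
#'
#' Reserves a random, class-stratified fraction of the proteins as a
#' holdout test set. The test size is `round(fraction * n)` (half away
#' from zero), apportioned between classes proportionally.
#'
#' @param data Protein dataset tibble with MP/NONMP labels.
#' @param test_fraction Fraction reserved for testing, in (0, 1).
#' @param seed Integer seed; the same seed always gives the same split.
#' @return A list of class `"split_plan"` with character vectors
#'   `test_ids`, `train_ids` and the `seed`.
#' @export
make_split <- function(data, test_fraction = 0.2, seed = 1L) {
  data <- check_trainable(as_protein_dataset(data, sanitize = NULL))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  n_test <- round_half_up(test_fraction * nrow(data))
  labs <- unique(data$label)
  # proportional allocation, remainders to the largest fractional parts
  sizes <- vapply(labs, function(l) sum(data$label == l), numeric(1))
  raw <- n_test * sizes / sum(sizes)
  take <- floor(raw)
  rem <- n_test - sum(take)
  if (rem > 0) {
    extra <- order(raw - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1
  }
  withr::with_seed(derive_seed(seed, 1L), {
    test_ids <- unlist(lapply(seq_along(labs), function(i) {
      pool <- data$id[data$label == labs[i]]
      sample(pool, take[i])
    }))
  })
  test_ids <- as.character(test_ids)
  train_ids <- setdiff(data$id, test_ids)
  if (length(unique(data$label[data$id %in% train_ids])) < 2L ||
      length(unique(data$label[data$id %in% test_ids])) < 2L) {
    stop("split leaves a side without both classes; adjust fraction",
         call. = FALSE)
  }
  structure(list(test_ids = test_ids, train_ids = train_ids, seed = seed),
            class = "split_plan")
}

#' Shared repeated K-fold plan
#'
#' Builds `repeats` independent stratified K-fold partitions of the given
#' proteins. Within each repeat every protein appears in the validation
#' fold exactly once and fold sizes differ by at most one. The returned
#' plan is a plain tibble `(repeat, id, fold)` intended to be built once
#' and consumed by *every* descriptor x model run being compared, so that
#' performance differences cannot come from fold assignment;
#' `fold_plan_checksum()` fingerprints it for provenance.
#'
#' @param ids Character vector of protein ids.
#' @param labels Class labels parallel to `ids` (used for stratification).
#' @param repeats Number of repeats (default 100).
#' @param K Folds per repeat (default 10).
#' @param seed Integer seed.
#' @return Tibble with columns `rep`, `id`, `fold` and attributes
#'   `repeats`, `K`, `seed`.
#' @export
make_fold_plan <- function(ids, labels, repeats = 100L, K = 10L, seed = 1L) {
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  if (length(ids) < K) {
    stop("need at least K = ", K, " proteins, got ", length(ids),
         call. = FALSE)
  }
  plan <- withr::with_seed(derive_seed(seed, 2L), {
    purrr::map_dfr(seq_len(repeats), function(r) {
      tibble(rep = r, id = as.character(ids),
             fold = stratified_folds(ids, labels, K))
    })
  })
  attr(plan, "repeats") <- as.integer(repeats)
  attr(plan, "K") <- as.integer(K)
  attr(plan, "seed") <- as.integer(seed)
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' @rdname make_fold_plan
#' @param plan A fold plan.
#' @export
fold_plan_checksum <- function(plan) {
  rlang::hash(list(plan$rep, plan$id, plan$fold))
}

#' Run repeated K-fold cross-validation
#'
#' For every repeat and fold of the shared plan, fits the classifier on
#' the other K-1 folds and predicts the validation fold. Feature
#' standardization (when the config enables it) is fitted on the training
#' folds only. Metrics are pooled over the folds of each repeat, then
#' averaged over repeats; the full per-protein prediction log (one row per
#' protein per repeat) is retained for outlier analysis.
#'
#' @param features Feature tibble (`id` first column) covering all plan ids.
#' @param labels Tibble with columns `id`, `label` (or a protein dataset).
#' @param config A [classifier_config()].
#' @param plan A fold plan from [make_fold_plan()].
#' @param seed Integer seed for the stochastic model families.
#' @return Object of class `"cv_result"`: list with `metrics` (mean over
#'   repeats), `per_repeat` metrics tibble, `log` (the prediction log
#'   tibble: `id`, `rep`, `fold`, `truth`, `predicted`, `score`,
#'   `correct`), `config`, and the plan's checksum.
#' @export
run_cv <- function(features, labels, config, plan, seed = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  labels <- normalize_labels(labels)
  ids <- unique(plan$id)
  X <- feature_matrix(features, ids)
  y <- setNames(labels$label[match(ids, labels$id)], ids)
  if (anyNA(y)) stop("labels missing for plan id(s): ",
                     paste(head(ids[is.na(y)]), collapse = ", "),
                     call. = FALSE)
  repeats <- attr(plan, "repeats") %||% max(plan$rep)
  K <- attr(plan, "K") %||% max(plan$fold)
  logs <- vector("list", repeats * K)
  li <- 1L
  for (r in seq_len(repeats)) {
    pr <- plan[plan$rep == r, ]
    fold_of <- setNames(pr$fold, pr$id)[ids]
    for (k in seq_len(K)) {
      val <- ids[fold_of == k]
      trn <- ids[fold_of != k]
      set.seed(derive_seed(seed, 1000L + r * K + k))
      fit <- tryCatch(
        fit_classifier(config, X[trn, , drop = FALSE], y[trn]),
        error = function(e) {
          stop("classifier ", config$family, " failed at repeat ", r,
               ", fold ", k, ": ", conditionMessage(e), call. = FALSE)
        })
      pred <- predict_classifier(fit, X[val, , drop = FALSE])
      logs[[li]] <- tibble(id = val, rep = r, fold = k,
                           truth = as.character(y[val]),
                           predicted = pred$class, score = pred$score)
      li <- li + 1L
    }
  }
  log <- bind_rows(logs)
  log$correct <- log$truth == log$predicted
  per_repeat <- log |>
    group_by(.data$rep) |>
    summarise(metrics_from_predictions(.data$truth, .data$predicted,
                                       .data$score),
              .groups = "drop")
  metrics <- as_tibble(as.list(colMeans(per_repeat[, -1])))
  structure(list(metrics = metrics, per_repeat = per_repeat, log = log,
                 config = config, repeats = repeats, K = K,
                 fold_checksum = fold_plan_checksum(plan)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$config$family, ", ", x$repeats, " x ", x$K,
      "-fold CV (fold plan ", substr(x$fold_checksum, 1, 8), ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}

# labels argument: protein dataset or (id, label) tibble
normalize_labels <- function(labels) {
  stopifnot(is.data.frame(labels), all(c("id", "label") %in% names(labels)))
  tibble(id = as.character(labels$id), label = as.character(labels$label))
}

# feature tibble -> numeric matrix indexed by the requested ids
feature_matrix <- function(features, ids) {
  stopifnot(is.data.frame(features), names(features)[1] == "id")
  miss <- setdiff(ids, features$id)
  if (length(miss) > 0L) {
    stop("features missing for id(s): ", paste(head(miss), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(features[match(ids, features$id), -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Fit on the training split and evaluate on the holdout
#'
#' Complements [run_cv()]: one fit on all training proteins, one
#' evaluation on the reserved test proteins.
#'
#' @inheritParams run_cv
#' @param split A [make_split()] plan.
#' @return One-row metrics tibble (with AUC).
#' @export
evaluate_holdout <- function(features, labels, config, split, seed = 1L) {
  labels <- normalize_labels(labels)
  X <- feature_matrix(features, c(split$train_ids, split$test_ids))
  y <- setNames(labels$label[match(rownames(X), labels$id)], rownames(X))
  set.seed(derive_seed(seed, 99L))
  fit <- fit_classifier(config, X[split$train_ids, , drop = FALSE],
                        y[split$train_ids])
  pred <- predict_classifier(fit, X[split$test_ids, , drop = FALSE])
  metrics_from_predictions(y[split$test_ids], pred$class, pred$score)
}
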