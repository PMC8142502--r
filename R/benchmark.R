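#' Benchmark descriptor x classifier combinations under shared folds
#'
#' Runs the full evaluation protocol for every combination of the given
#' descriptors and classifier families: repeated K-fold cross-validation
#' on the training proteins using one shared fold plan (so every cell sees
#' identical folds), plus a single holdout evaluation on the reserved test
#' proteins. The result is the tabular equivalent of the study's
#' performance heat maps.
#'
#' @param data Protein dataset tibble with MP/NONMP labels.
#' @param descriptors Character vector of descriptor names, or a named
#'   list of [descriptor_spec()] objects.
#' @param families Character vector of classifier families, or a named
#'   list of [classifier_config()] objects.
#' @param test_fraction Holdout fraction (default 0.2).
#' @param repeats,K Cross-validation repeats and folds.
#' @param seed Master seed; split, folds and stochastic models all derive
#'   from it.
#' @param keep_logs Keep each cell's full prediction log (needed for
#'   outlier analysis on benchmark output).
#' @return Object of class `"benchmark_result"`: list with `report` (one
#'   row per cell: descriptor, family, CV metrics, holdout metrics
#'   prefixed `test_`, and the shared `fold_checksum`), `split`, `plan`,
#'   and optionally `logs` (named list of prediction logs).
#' @export
benchmark_grid <- function(data, descriptors, families,
                           test_fraction = 0.2, repeats = 100L, K = 10L,
                           seed = 1L, keep_logs = FALSE) {
  data <- check_trainable(as_protein_dataset(data, sanitize = NULL))
  specs <- resolve_specs(descriptors)
  configs <- resolve_configs(families)
  split <- make_split(data, test_fraction, seed = seed)
  train <- data[data$id %in% split$train_ids, ]
  plan <- make_fold_plan(train$id, train$label, repeats = repeats, K = K,
                         seed = seed)
  labels <- data[, c("id", "label")]
  logs <- list()
  report <- purrr::map_dfr(names(specs), function(dn) {
    feats <- extract_features(data, specs[[dn]])
    purrr::map_dfr(names(configs), function(fn) {
      cv <- run_cv(feats, labels, configs[[fn]], plan, seed = seed)
      ho <- evaluate_holdout(feats, labels, configs[[fn]], split,
                             seed = seed)
      if (keep_logs) logs[[paste(dn, fn, sep = ".")]] <<- cv$log
      dplyr::bind_cols(tibble(descriptor = dn, family = fn),
                       cv$metrics,
                       dplyr::rename_with(ho, ~ paste0("test_", .x)),
                       tibble(fold_checksum = cv$fold_checksum))
    })
  })
  structure(list(report = report, split = split, plan = plan,
                 logs = if (keep_logs) logs else NULL, seed = seed),
            class = "benchmark_result")
}

resolve_specs <- function(descriptors) {
  if (is.character(descriptors)) {
    specs <- lapply(descriptors, descriptor_spec)
    names(specs) <- descriptors
  } else {
    specs <- descriptors
    if (is.null(names(specs))) {
      names(specs) <- vapply(specs, `[[`, character(1), "name")
    }
  }
  specs
}

resolve_configs <- function(families) {
  if (is.character(families)) {
    configs <- lapply(families, classifier_config)
    names(configs) <- families
  } else {
    configs <- families
    if (is.null(names(configs))) {
      names(configs) <- vapply(configs, `[[`, character(1), "family")
    }
  }
  configs
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", nrow(x$report), " descriptor x classifier ",
      "cells, shared fold plan ",
      substr(x$report$fold_checksum[1], 1, 8), "\n", sep = "")
  print(x$report[, c("descriptor", "family", "acc", "f_measure", "mcc",
                     "test_acc")])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a benchmark result
#'
#' `tidy()` returns the long cell-by-metric table; `glance()` returns a
#' one-row summary with the best cell by CV accuracy.
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy benchmark_result
#' @export
tidy.benchmark_result <- function(x, ...) {
  x$report |>
    tidyr::pivot_longer(cols = -c("descriptor", "family", "fold_checksum"),
                        names_to = "metric", values_to = "value")
}

#' @rdname tidy.benchmark_result
#' @method glance benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) {
  best <- x$report[which.max(x$report$acc), ]
  tibble(n_cells = nrow(x$report),
         best_descriptor = best$descriptor,
         best_family = best$family,
         best_acc = best$acc,
         best_test_acc = best$test_acc)
}

#' Plot a benchmark result as a metric grid
#'
#' Descriptor x classifier tiles filled by the chosen cross-validation
#' metric.
#'
#' @param object A `benchmark_result`.
#' @param metric Metric column to display (default `"acc"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, metric = "acc", ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$family, y = .data$descriptor,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data[[metric]])), size = 3) +
    ggplot2::scale_fill_gradient(low = "#d73027", high = "#1a9850") +
    ggplot2::labs(x = "classifier", y = "descriptor", fill = metric) +
    ggplot2::theme_minimal()
}

#' Tidy / summarise a cross-validation result
#'
#' `tidy()` returns per-repeat pooled metrics; `glance()` the repeat
#' means with their standard errors.
#'
#' @param x A `cv_result` from [run_cv()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$per_repeat

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  m <- x$per_repeat[, -1]
  dplyr::bind_cols(
    as_tibble(as.list(colMeans(m))),
    as_tibble(as.list(setNames(vapply(m, sd, numeric(1)) / sqrt(nrow(m)),
                               paste0("se_", names(m))))),
    tibble(repeats = x$repeats, K = x$K)
  )
}

#' Distribution of per-protein misclassification counts
#'
#' Histogram of miss counts across repeats, with the COP threshold drawn.
#'
#' @param object A tally tibble from [tally_misclassifications()].
#' @param threshold Threshold line to draw (default 90).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mooncop_tally
#' @export
autoplot.mooncop_tally <- function(object, threshold = 90, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$misses)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold - 0.5, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "misclassifications across repeats",
                  y = "proteins") +
    ggplot2::theme_minimal()
}
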