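# Candidate-outlier-protein (COP) machinery: proteins that a classifier
# gets wrong in (almost) every one of the repeated cross-validation rounds
# are candidate label errors / natural outliers. Misclassification tallies
# are derived from the per-protein prediction log of run_cv(), thresholded
# (default: wrong in >= 90 of 100 repeats), summarised, combined across
# descriptor x model runs, and finally removed to quantify their drag on
# accuracy.

#' Tally misclassifications per protein
#'
#' Counts, for every protein, the number of cross-validation repeats in
#' which its validation-fold prediction was wrong. The log must be
#' complete: every protein appears exactly once per repeat.
#'
#' @param log Prediction log tibble from [run_cv()] (columns `id`, `rep`,
#'   `correct`), or a `cv_result`.
#' @return Tibble of class `"mooncop_tally"` with columns `id`, `misses`
#'   and attribute `repeats`.
#' @export
tally_misclassifications <- function(log) {
  if (inherits(log, "cv_result")) log <- log$log
  stopifnot(all(c("id", "rep", "correct") %in% names(log)))
  R <- length(unique(log$rep))
  per <- count(log, .data$id, name = "rows")
  bad <- per$id[per$rows != R]
  if (length(bad) > 0L) {
    stop("incomplete prediction log for protein(s): ",
         paste(head(bad), collapse = ", "), " (expected ", R,
         " rows each)", call. = FALSE)
  }
  out <- log |>
    group_by(.data$id) |>
    summarise(misses = sum(!.data$correct), .groups = "drop")
  attr(out, "repeats") <- R
  class(out) <- c("mooncop_tally", class(out))
  out
}

#' Detect candidate outlier proteins (COPs)
#'
#' Thresholds a misclassification tally: a protein misclassified in at
#' least `threshold` of the repeats (inclusive rule, the default) is a
#' COP. The strict rule (`mode = "strict"`, miss count strictly greater
#' than the threshold) is also available, since both readings appear in
#' the outlier-detection literature.
#'
#' @param tally A tally from [tally_misclassifications()].
#' @param threshold Miss-count threshold in `1..repeats` (default 90).
#' @param mode `"inclusive"` (`misses >= threshold`) or `"strict"`
#'   (`misses > threshold`).
#' @return Character vector of COP ids.
#' @export
detect_cops <- function(tally, threshold = 90L, mode = c("inclusive", "strict")) {
  mode <- match.arg(mode)
  R <- attr(tally, "repeats") %||% max(tally$misses)
  if (threshold < 1L || threshold > R) {
    stop("threshold must be in 1..", R, call. = FALSE)
  }
  keep <- if (mode == "inclusive") tally$misses >= threshold
          else tally$misses > threshold
  tally$id[keep]
}

#' Summarise a COP set
#'
#' Class composition and always-misclassified fraction of a COP set:
#' `frequency` is the number of COPs, `fraction_mp` / `fraction_nonmp`
#' their class composition, and `fm` the fraction of COPs misclassified
#' in *every* repeat (the study's F.M. statistic). An empty COP set yields
#' frequency 0 with `NA` fractions.
#'
#' @param cops Character vector of COP ids.
#' @param labels Tibble with `id`, `label` covering the COPs.
#' @param tally The tally the COPs were detected from.
#' @param descriptor,family Optional provenance strings for the report.
#' @return One-row tibble: `descriptor`, `family`, `frequency`,
#'   `fraction_mp`, `fraction_nonmp`, `fm`.
#' @export
cop_stats <- function(cops, labels, tally, descriptor = NA_character_,
                      family = NA_character_) {
  labels <- normalize_labels(labels)
  R <- attr(tally, "repeats")
  if (length(cops) == 0L) {
    return(tibble(descriptor = descriptor, family = family, frequency = 0L,
                  fraction_mp = NA_real_, fraction_nonmp = NA_real_,
                  fm = NA_real_))
  }
  if (!all(cops %in% tally$id)) {
    stop("COP id(s) absent from tally: ",
         paste(head(setdiff(cops, tally$id)), collapse = ", "),
         call. = FALSE)
  }
  lab <- labels$label[match(cops, labels$id)]
  if (anyNA(lab)) stop("labels missing for some COPs", call. = FALSE)
  misses <- tally$misses[match(cops, tally$id)]
  tibble(descriptor = descriptor, family = family,
         frequency = length(cops),
         fraction_mp = mean(lab == "MP"),
         fraction_nonmp = mean(lab == "NONMP"),
         fm = mean(misses == R))
}

#' Combine COP sets across runs
#'
#' Intersection (the conservative reading: a protein must be flagged by
#' every run) or union of COP sets from several descriptor x model runs.
#'
#' @param sets Non-empty list of character vectors of COP ids.
#' @param mode `"intersection"` or `"union"`.
#' @return Character vector (sorted, unique).
#' @export
combine_cops <- function(sets, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (!is.list(sets) || length(sets) == 0L) {
    stop("sets must be a non-empty list", call. = FALSE)
  }
  out <- Reduce(if (mode == "intersection") intersect else union, sets)
  sort(unique(as.character(out)))
}

#' Remove COPs and re-evaluate
#'
#' Quantifies the drag of a COP set on classifier performance: runs the
#' full repeated-CV protocol on the original dataset and again on the
#' dataset with the COPs removed (fresh fold plans of the same repeats, K
#' and seed scheme), returning both metric sets.
#'
#' @param data Protein dataset tibble.
#' @param cops Character vector of protein ids to remove (must be a
#'   proper subset of the dataset).
#' @param descriptor Descriptor name or [descriptor_spec()].
#' @param config A [classifier_config()].
#' @param repeats,K,seed CV protocol parameters.
#' @return List with `before` and `after` (mean metric tibbles), the two
#'   `cv_result` objects (`cv_before`, `cv_after`), and `removed`.
#' @export
remove_and_reevaluate <- function(data, cops, descriptor, config,
                                  repeats = 100L, K = 10L, seed = 1L) {
  data <- check_trainable(as_protein_dataset(data, sanitize = NULL))
  if (!all(cops %in% data$id)) {
    stop("COP id(s) not in dataset: ",
         paste(head(setdiff(cops, data$id)), collapse = ", "),
         call. = FALSE)
  }
  reduced <- data[!data$id %in% cops, ]
  cc <- class_counts(reduced)
  if (nrow(cc) < 2L || any(cc$n < K)) {
    stop("removal leaves a class with fewer than K = ", K,
         " proteins", call. = FALSE)
  }
  run_one <- function(d) {
    feats <- extract_features(d, descriptor)
    plan <- make_fold_plan(d$id, d$label, repeats = repeats, K = K,
                           seed = seed)
    run_cv(feats, d[, c("id", "label")], config, plan, seed = seed)
  }
  before <- run_one(data)
  after <- run_one(reduced)
  list(before = before$metrics, after = after$metrics,
       cv_before = before, cv_after = after, removed = sort(cops))
}

#' Score candidate proteins by repeated refits
#'
#' Estimates the moonlighting probability of unlabeled candidate proteins
#' by refitting the classifier `repeats` times on bootstrap resamples of
#' the labeled training set (class-stratified, so both classes survive
#' every resample) and averaging the predicted MP probability. The
#' bootstrap supplies the repeat-to-repeat variability that makes the
#' average informative even for deterministic model families; set
#' `bootstrap = FALSE` to refit on the identical data each time (all
#' repeats then agree for deterministic families).
#'
#' @param train Labeled protein dataset (MP/NONMP).
#' @param candidates Protein dataset tibble of candidates (labels
#'   ignored).
#' @param descriptor Descriptor name or spec (default `"QSOrder"`).
#' @param config Classifier config (default Gaussian NB).
#' @param repeats Number of refits (default 100).
#' @param bootstrap Resample the training set each repeat.
#' @param seed Integer seed.
#' @return Tibble: `id`, `mean_probability`, `sd_probability`, `repeats`.
#' @export
score_candidates <- function(train, candidates, descriptor = "QSOrder",
                             config = classifier_config("NB"),
                             repeats = 100L, bootstrap = TRUE, seed = 1L) {
  train <- check_trainable(as_protein_dataset(train, sanitize = NULL))
  candidates <- as_protein_dataset(candidates, sanitize = NULL)
  if (any(candidates$id %in% train$id)) {
    stop("candidate id(s) collide with training ids", call. = FALSE)
  }
  spec <- if (inherits(descriptor, "descriptor_spec")) descriptor
          else descriptor_spec(descriptor)
  all_feats <- extract_features(bind_rows(train, candidates), spec)
  Xtr <- feature_matrix(all_feats, train$id)
  Xca <- feature_matrix(all_feats, candidates$id)
  y <- setNames(train$label, train$id)
  by_class <- split(train$id, train$label)
  probs <- matrix(NA_real_, nrow = repeats, ncol = nrow(candidates))
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 5000L + r))
    ids <- if (bootstrap) {
      unlist(lapply(by_class, function(p) sample(p, length(p), replace = TRUE)))
    } else train$id
    fit <- fit_classifier(config, Xtr[ids, , drop = FALSE], y[ids])
    probs[r, ] <- predict_classifier(fit, Xca)$score
  }
  tibble(id = candidates$id,
         mean_probability = colMeans(probs),
         sd_probability = apply(probs, 2, sd),
         repeats = repeats)
}
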