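# random prediction log with a known number of repeats
random_log <- function(n_prot = 12, R = 10, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("p%02d", seq_len(n_prot))
    tidyr::expand_grid(id = ids, rep = seq_len(R)) |>
      dplyr::mutate(fold = sample(1:5, dplyr::n(), replace = TRUE),
                    truth = rep(sample(c("MP", "NONMP"), n_prot,
                                       replace = TRUE), each = R),
                    predicted = sample(c("MP", "NONMP"), dplyr::n(),
                                       replace = TRUE),
                    score = runif(dplyr::n()),
                    correct = truth == predicted)
  })
}

test_that("tallies equal brute-force recounts and reject incomplete logs", {
  for (seed in 1:5) {
    log <- random_log(seed = seed)
    t <- tally_misclassifications(log)
    o <- o_tally(log)
    expect_equal(stats::setNames(t$misses, t$id), o[t$id])
    expect_equal(attr(t, "repeats"), 10L)
  }
  log <- random_log()
  expect_error(tally_misclassifications(log[-1, ]), "p01")

  perfect <- random_log()
  perfect$correct <- TRUE
  expect_true(all(tally_misclassifications(perfect)$misses == 0))
})

test_that("COP thresholding honors inclusive and strict rules at the boundary", {
  t <- tibble::tibble(id = c("p1", "p2", "p3"), misses = c(95L, 89L, 90L))
  attr(t, "repeats") <- 100L
  class(t) <- c("mooncop_tally", class(t))
  expect_setequal(detect_cops(t, 90), c("p1", "p3"))
  expect_setequal(detect_cops(t, 90, mode = "strict"), "p1")
  expect_error(detect_cops(t, 0), "1\\.\\.100")
  expect_error(detect_cops(t, 101), "1\\.\\.100")

  # monotone: raising the threshold never adds a COP; brute-force filter
  withr::with_seed(41, {
    for (i in 1:25) {
      tt <- tibble::tibble(id = sprintf("q%02d", 1:40),
                           misses = sample(0:100, 40, replace = TRUE))
      attr(tt, "repeats") <- 100L
      prev <- tt$id
      for (thr in c(50, 75, 90, 100)) {
        got <- detect_cops(tt, thr)
        expect_setequal(got, tt$id[tt$misses >= thr])
        expect_true(all(got %in% prev))
        prev <- got
        strict <- detect_cops(tt, thr, mode = "strict")
        expect_setequal(strict, tt$id[tt$misses > thr])
      }
    }
  })
})

test_that("COP statistics report class fractions and the F.M. share", {
  t <- tibble::tibble(id = c("a", "b", "c", "d"),
                      misses = c(100L, 100L, 92L, 10L))
  attr(t, "repeats") <- 100L
  labels <- tibble::tibble(id = c("a", "b", "c", "d"),
                           label = c("MP", "NONMP", "NONMP", "MP"))
  st <- cop_stats(c("a", "b", "c"), labels, t, "SAAC", "SVM")
  expect_equal(st$frequency, 3L)
  expect_equal(st$fraction_mp, 1 / 3)
  expect_equal(st$fraction_nonmp, 2 / 3)
  expect_equal(st$fm, 2 / 3)
  expect_equal(st$fraction_mp + st$fraction_nonmp, 1)

  empty <- cop_stats(character(0), labels, t)
  expect_equal(empty$frequency, 0L)
  expect_true(is.na(empty$fm))
  expect_error(cop_stats("zz", labels, t), "zz")
})

test_that("COP sets combine by exact intersection or union", {
  sets <- list(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(combine_cops(sets), c("b", "c"))
  expect_equal(combine_cops(sets, "union"), c("a", "b", "c", "d"))
  expect_equal(combine_cops(list(c("x", "y"), c("y", "x"))), c("x", "y"))
  expect_error(combine_cops(list()), "non-empty")
})

test_that("removing an empty COP set reproduces the original run exactly", {
  d <- generate_synthetic(synth_config(n_per_class = 20, delta = 0.4,
                                       seed = 19))
  rr <- remove_and_reevaluate(d, character(0), "SGAAC",
                              classifier_config("NB"), repeats = 3, K = 5,
                              seed = 8)
  expect_equal(rr$before, rr$after)
  expect_error(
    remove_and_reevaluate(d, d$id[d$label == "MP"][1:16], "SGAAC",
                          classifier_config("NB"), repeats = 2, K = 5,
                          seed = 8),
    "fewer than")
})

test_that("flipped-label proteins are recovered and their removal helps", {
  d <- generate_synthetic(synth_config(n_per_class = 50, delta = 0.3,
                                       outlier_fraction = 0.1, seed = 23))
  truth <- attr(d, "outlier_ids")
  feats <- extract_features(d, "SAAC")
  plan <- make_fold_plan(d$id, d$label, repeats = 25, K = 10, seed = 23)
  cv <- run_cv(feats, d[, c("id", "label")], classifier_config("NB"),
               plan, seed = 23)
  t <- tally_misclassifications(cv)
  cops <- detect_cops(t, threshold = 23)  # 90% of 25 repeats, rounded up
  expect_gte(length(intersect(cops, truth)) / length(truth), 0.8)
  expect_lte(length(setdiff(cops, truth)) / (nrow(d) - length(truth)), 0.05)

  # ground-truth outliers sit above non-outliers in the tally ranking
  w <- stats::wilcox.test(t$misses[t$id %in% truth],
                          t$misses[!t$id %in% truth],
                          alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 1e-4)

  rr <- remove_and_reevaluate(d, cops, "SAAC", classifier_config("NB"),
                              repeats = 10, K = 10, seed = 23)
  expect_gt(rr$after$acc, rr$before$acc)
})

test_that("candidate scoring averages repeated refits into [0, 1]", {
  d <- tiny_dataset(n_per_class = 12, seed = 55)
  cand <- tibble::tibble(id = c("candMP", "candNON"),
                         sequence = c(rand_seq(40, AA[1:10]),
                                      rand_seq(40, AA[11:20])))
  sc <- score_candidates(d, cand, descriptor = "SGAAC",
                         repeats = 20, seed = 5)
  expect_equal(sc$id, cand$id)
  expect_true(all(sc$mean_probability >= 0 & sc$mean_probability <= 1))
  # candidate drawn from the MP-typed distribution scores as MP
  expect_gt(sc$mean_probability[1], 0.9)
  expect_lt(sc$mean_probability[2], 0.1)

  # without bootstrap all repeats are identical for a deterministic model
  sc2 <- score_candidates(d, cand, descriptor = "SGAAC",
                          repeats = 5, bootstrap = FALSE, seed = 5)
  expect_equal(sc2$sd_probability, c(0, 0))
  one <- score_candidates(d, cand, descriptor = "SGAAC",
                          repeats = 1, bootstrap = FALSE, seed = 5)
  expect_equal(sc2$mean_probability, one$mean_probability)

  single <- d[d$label == "MP", ]
  expect_error(score_candidates(single, cand, descriptor = "SGAAC"),
               "NONMP")
})
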