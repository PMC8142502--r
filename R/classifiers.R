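# Classifier family wrappers. Every family is driven through the same
# fit/predict pair so the CV engine, the benchmark grid and the candidate
# scorer never branch on the family. The moonlighting class "MP" is the
# positive class; factors are always leveled c("NONMP", "MP") so that every
# engine's "probability of the second level" is the MP probability.

CLASSIFIER_FAMILIES <- c("SVM", "KNN", "NB", "DT", "RF", "MLP", "ADA", "LR")

label_factor <- function(y) factor(as.character(y), levels = c("NONMP", "MP"))

#' Configure a classifier family
#'
#' Returns a config object for one of the eight supported families with
#' the hyperparameters used throughout the benchmark: KNN with k = 5 and
#' Euclidean distance; SVM with RBF kernel and cost C = 1; decision tree
#' with Gini impurity, maximum depth 3 and minimum split size 5; AdaBoost
#' with 200 stumps; random forest with 50 trees; a single-hidden-layer
#' perceptron with 20 units trained for at most 150 iterations; Gaussian
#' naive Bayes; and ridge-regularized logistic regression. Any
#' hyperparameter can be overridden through `...`.
#'
#' Feature standardization (z-score, fitted on the training folds only) is
#' on by default for the scale-sensitive families (SVM, KNN, MLP, LR) and
#' off for the tree/ensemble/NB families; override with `scale`.
#'
#' @param family One of `"SVM"`, `"KNN"`, `"NB"`, `"DT"`, `"RF"`,
#'   `"MLP"`, `"ADA"`, `"LR"`.
#' @param ... Hyperparameter overrides (see Details).
#' @param scale Logical; standardize features (default depends on family).
#' @return An object of class `"classifier_config"`.
#' @examples
#' classifier_config("KNN")
#' classifier_config("DT", maxdepth = 2)
#' @export
classifier_config <- function(family, ..., scale = NULL) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  defaults <- switch(family,
    SVM = list(cost = 1, gamma = NULL),   # NULL gamma = 1/ncol heuristic
    KNN = list(k = 5L),
    NB  = list(var_eps = 1e-9),           # variance floor, Gaussian NB
    DT  = list(maxdepth = 3L, minsplit = 5L),
    RF  = list(ntree = 50L),
    MLP = list(size = 20L, maxit = 150L, decay = 0),
    ADA = list(nlearners = 200L),
    LR  = list(lambda = NULL))            # NULL = 1/n_train (ridge)
  params <- modifyList(defaults, list(...))
  extra <- setdiff(names(params), names(defaults))
  if (length(extra) > 0L) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(scale)) scale <- family %in% c("SVM", "KNN", "MLP", "LR")
  structure(list(family = family, params = params, scale = scale),
            class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  shown <- x$params[!vapply(x$params, is.null, logical(1))]
  cat("<classifier_config> ", x$family,
      if (x$scale) " (standardized features)" else "", "\n", sep = "")
  if (length(shown)) {
    cat("  ", paste(names(shown), unlist(shown), sep = " = ",
                    collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

# z-score parameters from training data; zero-variance features are kept
# but left uncentered-scaled by sd 1 so they contribute nothing
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

fit_classifier <- function(config, X, y) {
  y <- label_factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  sc <- if (config$scale) fit_scaler(X) else NULL
  if (!is.null(sc)) X <- apply_scaler(X, sc)
  p <- config$params
  model <- switch(config$family,
    SVM = e1071::svm(X, y, kernel = "radial", cost = p$cost,
                     gamma = p$gamma %||% (1 / ncol(X)),
                     scale = FALSE, probability = TRUE),
    KNN = list(X = X, y = y, k = p$k),   # lazy learner
    NB  = fit_gaussian_nb(X, y, p$var_eps),
    DT  = fit_rpart(X, y, p$maxdepth, p$minsplit),
    RF  = randomForest::randomForest(X, y, ntree = p$ntree),
    MLP = nnet::nnet(X, stats::model.matrix(~ y - 1)[, 2, drop = FALSE],
                     size = p$size, maxit = p$maxit, decay = p$decay,
                     entropy = TRUE, trace = FALSE,
                     MaxNWts = (ncol(X) + 2L) * p$size + p$size + 1L + 10L),
    ADA = fit_adaboost(X, y, p$nlearners),
    LR  = fit_ridge_lr(X, y, p$lambda))
  structure(list(family = config$family, model = model, scaler = sc,
                 config = config),
            class = "mooncop_fit")
}

# MP probability for new data
predict_classifier <- function(fit, X) {
  if (!is.null(fit$scaler)) X <- apply_scaler(X, fit$scaler)
  m <- fit$model
  score <- switch(fit$family,
    SVM = {
      pr <- attr(predict(m, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "MP"])
    },
    KNN = {
      pred <- class::knn(m$X, X, m$y, k = m$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "MP", win, 1 - win)
    },
    NB  = predict_gaussian_nb(m, X),
    DT  = predict(m, as.data.frame(X), type = "prob")[, "MP"],
    RF  = predict(m, X, type = "prob")[, "MP"],
    MLP = as.numeric(predict(m, X)),
    ADA = predict_adaboost(m, X),
    LR  = {
      Xp <- if (ncol(X) < 2L) cbind(X, .pad = 0) else X
      as.numeric(predict(m, Xp, type = "response"))
    })
  score <- pmin(pmax(as.numeric(score), 0), 1)
  list(class = ifelse(score >= 0.5, "MP", "NONMP"), score = score)
}

fit_rpart <- function(X, y, maxdepth, minsplit) {
  df <- as.data.frame(X)
  df$.y <- y
  rpart::rpart(.y ~ ., data = df, method = "class",
               parms = list(split = "gini"),
               control = rpart::rpart.control(maxdepth = maxdepth,
                                              minsplit = minsplit,
                                              cp = 0, xval = 0))
}

# Gaussian naive Bayes with a variance floor (var_eps * largest feature
# variance), so constant-within-class features cannot produce degenerate
# densities on small folds
fit_gaussian_nb <- function(X, y, var_eps = 1e-9) {
  lev <- levels(y)
  stats <- lapply(lev, function(l) {
    Xi <- X[y == l, , drop = FALSE]
    list(mu = colMeans(Xi), var = apply(Xi, 2, stats::var))
  })
  names(stats) <- lev
  allvar <- do.call(rbind, lapply(stats, `[[`, "var"))
  allvar[is.na(allvar)] <- 0
  floorv <- var_eps * max(allvar, 1e-12)
  for (l in lev) {
    v <- stats[[l]]$var
    v[is.na(v) | v < floorv] <- floorv
    stats[[l]]$var <- v
  }
  list(levels = lev, prior = table(y) / length(y), stats = stats)
}

predict_gaussian_nb <- function(m, X) {
  loglik <- sapply(m$levels, function(l) {
    s <- m$stats[[l]]
    rowSums(dnorm(X, rep(s$mu, each = nrow(X)),
                  rep(sqrt(s$var), each = nrow(X)), log = TRUE)) +
      log(as.numeric(m$prior[l]))
  })
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1)
  d <- loglik[, "MP"] - loglik[, "NONMP"]
  1 / (1 + exp(-d))
}

# AdaBoost.M1 over depth-1 rpart stumps; probability via the logistic
# calibration of the additive margin
fit_adaboost <- function(X, y, nlearners) {
  ynum <- ifelse(y == "MP", 1, -1)
  n <- length(ynum)
  w <- rep(1 / n, n)
  df <- as.data.frame(X)
  df$.y <- y
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(nlearners)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2,
                                                       cp = -1, xval = 0))
    h <- ifelse(predict(fit, df, type = "class") == "MP", 1, -1)
    err <- sum(w[h != ynum])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ynum * h)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (length(stumps) == 0L) {  # no stump beats chance: fall back to prior
    return(list(stumps = list(), alphas = numeric(0),
                prior_mp = mean(y == "MP")))
  }
  list(stumps = stumps, alphas = alphas, prior_mp = mean(y == "MP"))
}

predict_adaboost <- function(m, X) {
  if (length(m$stumps) == 0L) return(rep(m$prior_mp, nrow(X)))
  df <- as.data.frame(X)
  F <- rep(0, nrow(X))
  for (t in seq_along(m$stumps)) {
    h <- ifelse(predict(m$stumps[[t]], df, type = "class") == "MP", 1, -1)
    F <- F + m$alphas[t] * h
  }
  1 / (1 + exp(-2 * F))
}

fit_ridge_lr <- function(X, y, lambda = NULL) {
  if (is.null(lambda)) lambda <- 1 / nrow(X)
  Xp <- if (ncol(X) < 2L) cbind(X, .pad = 0) else X
  glmnet::glmnet(Xp, y, family = "binomial", alpha = 0, lambda = lambda,
                 standardize = FALSE)
}
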