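#' The classification-algorithm roster
#'
#' Thirteen algorithm names accepted by [classifier_spec()]. Backends marked
#' approximate are surrogates: no native implementation of the original
#' algorithm is bundled, so a closely related learner stands in and reports
#' flag it.
#'
#' @return `classifier_roster()`: a tibble with columns `name`, `backend`,
#'   `approximate`.
#' @export
classifier_roster <- function() {
  tibble(
    name = c("random_forest", "svm_poly", "svm_rbf", "adaboost_m1", "bagging",
             "bayes_net", "naive_bayes", "knn", "decision_tree", "part",
             "logistic", "mlp", "ripper"),
    backend = c("randomForest", "e1071::svm", "e1071::svm",
                "in-package AdaBoost.M1 (rpart stumps)",
                "in-package bagging (rpart trees)", "e1071::naiveBayes",
                "e1071::naiveBayes", "class::knn", "rpart", "rpart",
                "stats::glm", "nnet::nnet", "rpart"),
    approximate = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                    TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  )
}

#' Specify a classification algorithm
#'
#' Picks one of the thirteen roster algorithms with its hyperparameters. Only
#' the random-forest tree count is pinned by the method (100 trees); all other
#' hyperparameters are backend defaults, recorded on the spec so every run is
#' auditable.
#'
#' @param name Algorithm name; see [classifier_roster()].
#' @param seed Integer seed used for every stochastic step of fitting and
#'   scoring.
#' @param ... Hyperparameter overrides (e.g. `ntree`, `k`, `size`, `nrounds`).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(name, seed = 1L, ...) {
  roster <- classifier_roster()
  if (!name %in% roster$name) {
    abort(paste0("unknown classifier '", name, "'; see classifier_roster()"))
  }
  defaults <- switch(name,
    random_forest = list(ntree = 100L),
    svm_poly = list(kernel = "polynomial", degree = 3),
    svm_rbf = list(kernel = "radial"),
    adaboost_m1 = list(nrounds = 50L, maxdepth = 1L),
    bagging = list(nbags = 25L),
    knn = list(k = 5L),
    mlp = list(size = 5L, decay = 0.01, maxit = 200L),
    part = list(cp = 0.005),
    ripper = list(maxdepth = 3L, minsplit = 10L),
    list()
  )
  params <- utils::modifyList(defaults, list(...))
  if (name == "random_forest" && params$ntree <= 0) {
    abort("random forest tree count must be positive")
  }
  structure(
    list(name = name, seed = as.integer(seed), params = params,
         approximate = roster$approximate[roster$name == name]),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  p <- if (length(x$params) == 0) "backend defaults" else
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<classifier_spec> %s (%s%s), seed %d\n", x$name, p,
              if (x$approximate) "; approximate surrogate" else "", x$seed))
  invisible(x)
}

# split a feature tibble into the numeric design matrix and the label factor
design_matrix <- function(data) {
  meta <- intersect(c("drug", "side_effect", "dataset", "fold"), names(data))
  x <- as.matrix(data[, setdiff(names(data), c(meta, "label")), drop = FALSE])
  storage.mode(x) <- "double"
  y <- if ("label" %in% names(data)) {
    factor(as.character(data$label), levels = PAIR_LEVELS)
  } else NULL
  list(x = x, y = y)
}

#' Fit a classifier on a feature table
#'
#' @param data Feature tibble from [build_features()]: a `label` column plus
#'   numeric feature columns (`drug`/`side_effect` columns are ignored).
#' @param spec A [classifier_spec()].
#' @return A `sidefx_model` that can score feature tables of the same width.
#' @export
fit_classifier <- function(data, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  d <- design_matrix(data)
  if (is.null(d$y)) abort("`data` must contain a `label` column")
  if (ncol(d$x) == 0) abort("feature matrix has width 0")
  if (nrow(d$x) < 2) abort("need at least two training samples")
  if (dplyr::n_distinct(d$y) < 2) {
    abort("training labels contain a single class; both classes are required")
  }
  # degenerate design: every feature constant carries no information, and
  # some backends cannot even split on it — score with the class prior
  if (all(apply(d$x, 2, function(col) diff(range(col)) == 0))) {
    return(structure(
      list(spec = spec, fit = list(prior = mean(d$y == "positive")),
           feature_names = colnames(d$x), constant = TRUE),
      class = "sidefx_model"
    ))
  }
  df <- as.data.frame(d$x)
  df$label <- d$y
  p <- spec$params
  fit <- withr::with_seed(spec$seed, switch(spec$name,
    random_forest = randomForest::randomForest(
      x = d$x, y = d$y, ntree = p$ntree
    ),
    svm_poly = ,
    svm_rbf = do.call(e1071::svm, c(
      list(x = d$x, y = d$y, probability = TRUE, scale = FALSE), p
    )),
    adaboost_m1 = fit_adaboost(df, p$nrounds, p$maxdepth),
    bagging = fit_bagging(df, p$nbags),
    bayes_net = ,
    naive_bayes = e1071::naiveBayes(x = as.data.frame(d$x), y = d$y),
    knn = list(x = d$x, y = d$y, k = p$k),
    decision_tree = rpart::rpart(label ~ ., df, method = "class"),
    part = rpart::rpart(label ~ ., df, method = "class",
                        control = rpart::rpart.control(cp = p$cp)),
    ripper = rpart::rpart(
      label ~ ., df, method = "class",
      control = rpart::rpart.control(maxdepth = p$maxdepth,
                                     minsplit = p$minsplit)
    ),
    logistic = suppressWarnings(glm(label ~ ., df, family = binomial())),
    mlp = nnet::nnet(label ~ ., df, size = p$size, decay = p$decay,
                     maxit = p$maxit, trace = FALSE)
  ))
  structure(
    list(spec = spec, fit = fit, feature_names = colnames(d$x)),
    class = "sidefx_model"
  )
}

# AdaBoost.M1 with shallow rpart trees as the weak learner
fit_adaboost <- function(df, nrounds, maxdepth) {
  n <- nrow(df)
  w <- rep(1 / n, n)
  y <- df$label
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(nrounds)) {
    stump <- rpart::rpart(
      label ~ ., df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = maxdepth, cp = 0,
                                     minsplit = 2, xval = 0)
    )
    pred <- predict(stump, df, type = "class")
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (length(stumps) == 0) {
    # no stump beat chance: fall back to the class prior as a constant score
    return(list(stumps = list(), alphas = numeric(0),
                prior = mean(y == "positive")))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y == "positive"))
}

predict_adaboost <- function(fit, df) {
  if (length(fit$stumps) == 0) return(rep(fit$prior, nrow(df)))
  votes <- vapply(fit$stumps, function(s) {
    as.numeric(predict(s, df, type = "class") == "positive")
  }, numeric(nrow(df)))
  votes <- matrix(votes, nrow = nrow(df))
  as.vector(votes %*% fit$alphas) / sum(fit$alphas)
}

# bootstrap-aggregated rpart trees; score = mean tree probability
fit_bagging <- function(df, nbags) {
  trees <- lapply(seq_len(nbags), function(b) {
    idx <- sample(nrow(df), nrow(df), replace = TRUE)
    # resample until both classes are present in the bag
    while (dplyr::n_distinct(df$label[idx]) < 2) {
      idx <- sample(nrow(df), nrow(df), replace = TRUE)
    }
    rpart::rpart(label ~ ., df[idx, , drop = FALSE], method = "class")
  })
  list(trees = trees)
}

predict_bagging <- function(fit, df) {
  probs <- vapply(fit$trees, function(tr) {
    predict(tr, df, type = "prob")[, "positive"]
  }, numeric(nrow(df)))
  rowMeans(matrix(probs, nrow = nrow(df)))
}

#' Save and load fitted classifiers
#'
#' The archive is self-describing: it stores the [classifier_spec()] (name,
#' seed, hyperparameters), the feature layout, and the backend payload, so a
#' reloaded model refuses feature tables of the wrong width just like a fresh
#' one.
#'
#' @param model A `sidefx_model` from [fit_classifier()].
#' @param path File path for the archive.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sidefx_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sidefx_model")) {
    abort("file does not contain a sidefx model archive")
  }
  model
}

#' Score pairs with a fitted classifier
#'
#' `predict_scores()` returns a score in `[0, 1]` per row (the classifier's
#' confidence that the pair is a true drug/side-effect association);
#' `predict_labels()` thresholds the scores, with the boundary score counting
#' as positive.
#'
#' @param model A `sidefx_model` from [fit_classifier()].
#' @param data Feature tibble with the same feature columns (width) the model
#'   was trained on.
#' @param threshold Decision threshold for `predict_labels()` (default 0.5,
#'   inclusive: `score >= threshold` is positive).
#' @return `predict_scores()`: numeric vector in `[0, 1]`;
#'   `predict_labels()`: factor with levels `negative`, `positive`.
#' @export
predict_scores <- function(model, data) {
  stopifnot(inherits(model, "sidefx_model"))
  d <- design_matrix(data)
  if (!identical(colnames(d$x), model$feature_names)) {
    abort(sprintf(
      "feature width/layout mismatch: model trained on %d features, given %d",
      length(model$feature_names), ncol(d$x)
    ))
  }
  if (isTRUE(model$constant)) {
    return(rep(model$fit$prior, nrow(d$x)))
  }
  df <- as.data.frame(d$x)
  spec <- model$spec
  scores <- withr::with_seed(spec$seed + 1L, switch(spec$name,
    random_forest = predict(model$fit, d$x, type = "prob")[, "positive"],
    svm_poly = ,
    svm_rbf = attr(
      predict(model$fit, d$x, probability = TRUE), "probabilities"
    )[, "positive"],
    adaboost_m1 = predict_adaboost(model$fit, df),
    bagging = predict_bagging(model$fit, df),
    bayes_net = ,
    naive_bayes = predict(model$fit, df, type = "raw",
                          threshold = 0.001, eps = 1e-9)[, "positive"],
    knn = {
      pred <- class::knn(model$fit$x, d$x, model$fit$y, k = model$fit$k,
                         prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "positive", pwin, 1 - pwin)
    },
    decision_tree = ,
    part = ,
    ripper = predict(model$fit, df, type = "prob")[, "positive"],
    logistic = unname(predict(model$fit, df, type = "response")),
    mlp = as.vector(predict(model$fit, df))
  ))
  pmin(1, pmax(0, unname(scores)))
}

#' @rdname predict_scores
#' @export
predict_labels <- function(model, data, threshold = 0.5) {
  scores <- predict_scores(model, data)
  factor(ifelse(scores >= threshold, "positive", "negative"),
         levels = PAIR_LEVELS)
}
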