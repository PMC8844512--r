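# Uniform training / prediction interface over six classifier families.
# The contribution of this package is the descriptor + selection pipeline;
# the model fits themselves are delegated to established backends
# (randomForest, e1071, xgboost, stats::glm, rpart).

MODEL_FORMAT_VERSION <- 1L

CLASSIFIER_FAMILIES <- c("random_forest", "naive_bayes", "svm",
                         "gradient_boosting", "logistic_regression",
                         "decision_tree")

#' Specify a classifier
#'
#' @param family One of `"random_forest"` (default backend, 500 trees),
#'   `"naive_bayes"`, `"svm"` (RBF kernel with probability scores),
#'   `"gradient_boosting"` (xgboost backend), `"logistic_regression"`,
#'   `"decision_tree"`.
#' @param hyperparameters Named list of backend overrides (e.g.
#'   `list(ntree = 1000)` for random forest, `list(nrounds = 200)` for
#'   gradient boosting, `list(cost = 10, gamma = 0.01)` for the SVM).
#' @param seed Seed applied before fitting, so training is deterministic.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = "random_forest",
                            hyperparameters = list(), seed = 42L) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  stopifnot(is.list(hyperparameters))
  structure(list(family = family, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

hp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

#' Train a classifier on a labelled feature matrix
#'
#' Fits the backend named by `spec$family` after setting `spec$seed`, and
#' records the feature-name contract: prediction later refuses any matrix
#' whose columns differ in name or order from fit time.
#'
#' @param fm A labelled `feature_matrix` with both classes present.
#' @param spec A [classifier_spec()].
#' @return Object of class `aqp_model`.
#' @export
train <- function(fm, spec = classifier_spec("random_forest")) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "classifier_spec"))
  y <- fm$y
  if (is.null(y) || anyNA(y)) stop("training needs fully labelled data")
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  x <- fm$x
  set.seed(spec$seed)
  fit <- switch(spec$family,
    random_forest = randomForest::randomForest(
      x, factor(y, levels = 0:1), ntree = hp(spec, "ntree", 500L),
      mtry = hp(spec, "mtry", max(1L, floor(sqrt(ncol(x)))))),
    naive_bayes = e1071::naiveBayes(x, factor(y, levels = 0:1)),
    svm = e1071::svm(
      x, factor(y, levels = 0:1), kernel = hp(spec, "kernel", "radial"),
      cost = hp(spec, "cost", 1), gamma = hp(spec, "gamma", 1 / ncol(x)),
      probability = TRUE),
    gradient_boosting = {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp(spec, "max_depth", 6L),
                      eta = hp(spec, "eta", 0.3),
                      nthread = 1L, seed = spec$seed),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
        nrounds = hp(spec, "nrounds", 100L), verbose = 0)
    },
    logistic_regression = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      withCallingHandlers(
        stats::glm(.y ~ ., data = df, family = stats::binomial()),
        warning = function(w) {
          # perfectly separated training data is expected on easy problems
          if (grepl("fitted probabilities|did not converge",
                    conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    },
    decision_tree = {
      df <- data.frame(.y = factor(y, levels = 0:1), x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   cp = hp(spec, "cp", 0.01))
    })
  structure(list(spec = spec, feature_names = colnames(x), fit = fit,
                 n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                 trained_at = format(Sys.time(), tz = "UTC"),
                 format_version = MODEL_FORMAT_VERSION),
            class = "aqp_model")
}

#' @export
print.aqp_model <- function(x, ...) {
  cat(sprintf("<aqp_model> %s on %d features (%d pos / %d neg), seed %d\n",
              x$spec$family, length(x$feature_names), x$n_pos, x$n_neg,
              x$spec$seed))
  invisible(x)
}

check_feature_contract <- function(model, x) {
  have <- colnames(x)
  want <- model$feature_names
  if (length(have) != length(want) || any(have != want)) {
    bad <- which(have[seq_len(min(length(have), length(want)))] !=
                   want[seq_len(min(length(have), length(want)))])[1]
    detail <- if (length(have) != length(want))
      sprintf("model expects %d features, got %d", length(want), length(have))
    else
      sprintf("first mismatch at column %d: expected '%s', got '%s'",
              bad, want[bad], have[bad])
    stop("feature contract violation: ", detail)
  }
}

#' Predict class labels and scores
#'
#' Scores are positive-class probabilities in [0, 1]; the predicted label
#' is 1 iff score >= 0.5. Input columns must match the model's
#' feature-name contract exactly (name and order).
#'
#' @param object An `aqp_model`.
#' @param fm A `feature_matrix` (labels ignored).
#' @param ... Unused.
#' @return Data frame with columns `id`, `score`, `label`.
#' @export
predict.aqp_model <- function(object, fm, ...) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x
  check_feature_contract(object, x)
  set.seed(object$spec$seed)
  score <- switch(object$spec$family,
    random_forest = predict(object$fit, x, type = "prob")[, "1"],
    naive_bayes = predict(object$fit, x, type = "raw")[, "1"],
    svm = {
      pr <- predict(object$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    gradient_boosting = predict(object$fit,
                                xgboost::xgb.DMatrix(x, nthread = 1L)),
    logistic_regression = {
      df <- data.frame(x, check.names = FALSE)
      unname(predict(object$fit, newdata = df, type = "response"))
    },
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      predict(object$fit, newdata = df, type = "prob")[, "1"]
    })
  score <- as.numeric(score)
  data.frame(id = if (is.null(rownames(x))) seq_len(nrow(x)) else rownames(x),
             score = score, label = as.integer(score >= 0.5),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Save / load a trained model
#'
#' The model file embeds a format version, the classifier spec and the
#' feature-name contract; loading verifies the version and refuses
#' unreadable or foreign files. A save/load round trip preserves
#' predictions exactly.
#'
#' @param model An `aqp_model`.
#' @param path File path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aqp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("cannot read model file ", path,
                                             ": ", conditionMessage(e)))
  if (!inherits(model, "aqp_model"))
    stop("not an aquapred model file: ", path)
  if (!identical(model$format_version, MODEL_FORMAT_VERSION))
    stop("model format version ", model$format_version,
         " not supported (expected ", MODEL_FORMAT_VERSION, ")")
  model
}
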