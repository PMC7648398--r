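# Class-weighted binary classifiers (logistic regression, RBF support-vector
# machine, random forest) over the concatenated expression-code + k-mer
# feature table.

#' Class weights from the label imbalance
#'
#' The negative class gets weight 1 and the positive class the
#' negative:positive count ratio, so a 1:2.6391 positive:negative training
#' set weights positives 2.6391. Full precision is used internally;
#' `w_pos_reported` is rounded to 4 decimals for reporting.
#'
#' @param labels Label set with non-empty `positives` and `negatives`.
#' @return List with `w_neg` (1), `w_pos` (full precision) and
#'   `w_pos_reported` (4 dp).
#' @export
make_class_weights <- function(labels) {
  assert_label_set(labels)
  ratio <- length(labels$negatives) / length(labels$positives)
  list(w_neg = 1, w_pos = ratio, w_pos_reported = round(ratio, 4L))
}

#' Configure a binary classifier
#'
#' @param algorithm One of `"LR"` (L2-free logistic regression via `glm`),
#'   `"SVM"` (RBF kernel, Platt-calibrated probabilities) or `"RF"`
#'   (probability forest, 500 trees).
#' @param hyperparameters Named list overriding algorithm defaults
#'   (`cost`/`gamma` for SVM, `num.trees`/`mtry` for RF).
#' @param class_weights Optional list as from [make_class_weights()]; when
#'   `NULL` the weights are derived from the training labels at fit time.
#' @param probability_calibration For SVM: fit Platt-style probability
#'   estimates (default TRUE).
#' @param seed Integer seed controlling any fit-time randomness.
#' @return A list of class `model_config`.
#' @export
model_config <- function(algorithm = c("LR", "SVM", "RF"),
                         hyperparameters = list(), class_weights = NULL,
                         probability_calibration = TRUE, seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
                     LR = list(),
                     SVM = list(cost = 1, gamma = NULL),
                     RF = list(num.trees = 500L, mtry = NULL))
  hp <- utils::modifyList(defaults, hyperparameters)
  if (!is.null(class_weights) &&
      (class_weights$w_neg <= 0 || class_weights$w_pos <= 0))
    stop("class weights must be positive")
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 class_weights = class_weights,
                 probability_calibration = isTRUE(probability_calibration),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Train a class-weighted binary classifier
#'
#' Min-max statistics are computed on the supplied (training) rows, stored
#' in the model, and reapplied to held-out rows at prediction time, so
#' cross-validation folds never leak scaling information. Class weights
#' enter the loss (LR prior weights, SVM class.weights, RF case weights).
#' Deterministic given `config$seed`.
#'
#' @param features Gene x feature numeric matrix covering all labeled genes.
#' @param labels Label set.
#' @param config A [model_config()].
#' @param scale_features Fit/store min-max scaling (default TRUE). Set FALSE
#'   when the caller has already scaled globally.
#' @return A `trained_model` object.
#' @export
train_model <- function(features, labels, config, scale_features = TRUE) {
  stopifnot(inherits(config, "model_config"), is.matrix(features))
  assert_label_set(labels)
  labeled <- c(labels$positives, labels$negatives)
  missing <- setdiff(labeled, rownames(features))
  if (length(missing) > 0L)
    stop("labeled gene(s) missing from the feature table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (anyNA(features)) stop("feature table contains missing values")
  X <- features[labeled, , drop = FALSE]
  if (scale_features) {
    sc <- minmax_normalize(X)
    X <- sc$values
    scaling_stats <- sc$stats
  } else {
    scaling_stats <- NULL
  }
  y <- factor(ifelse(labeled %in% labels$positives, "pos", "neg"),
              levels = c("neg", "pos"))
  cw <- if (is.null(config$class_weights)) make_class_weights(labels)
        else config$class_weights
  case_w <- ifelse(y == "pos", cw$w_pos, cw$w_neg)
  hp <- config$hyperparameters
  set.seed(config$seed)
  fit <- switch(
    config$algorithm,
    LR = {
      df <- data.frame(X, check.names = FALSE)
      df$.class <- y
      # weighted binomial likelihood; glm's non-integer-successes warning and
      # separation warnings are expected here
      suppressWarnings(
        stats::glm(.class ~ ., data = df, family = stats::binomial(),
                   weights = case_w))
    },
    SVM = {
      args <- list(x = X, y = y, kernel = "radial", cost = hp$cost,
                   class.weights = c(neg = cw$w_neg, pos = cw$w_pos),
                   probability = config$probability_calibration,
                   scale = FALSE)
      if (!is.null(hp$gamma)) args$gamma <- hp$gamma
      do.call(e1071::svm, args)
    },
    RF = {
      dat <- data.frame(X, check.names = FALSE)
      dat$.class <- y
      args <- list(dependent.variable.name = ".class", data = dat,
                   num.trees = hp$num.trees, probability = TRUE,
                   case.weights = case_w, seed = config$seed,
                   num.threads = 1L)
      if (!is.null(hp$mtry)) args$mtry <- hp$mtry
      do.call(ranger::ranger, args)
    })
  structure(list(config = config, fit = fit,
                 feature_names = colnames(features),
                 scaling_stats = scaling_stats,
                 class_weights = cw),
            class = "trained_model")
}

#' Positive-class probability per gene
#'
#' Held-out rows are scaled with the stored training-fold min-max statistics
#' before scoring. Rows must carry exactly the model's feature set.
#'
#' @param model A [train_model()] result.
#' @param features Gene x feature matrix (same feature names as at fit time,
#'   any order).
#' @return Named numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "trained_model"), is.matrix(features))
  unknown <- setdiff(colnames(features), model$feature_names)
  absent <- setdiff(model$feature_names, colnames(features))
  if (length(unknown) > 0L || length(absent) > 0L)
    stop("feature mismatch; unknown: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         "; absent: ", paste(utils::head(absent, 5), collapse = ", "))
  X <- features[, model$feature_names, drop = FALSE]
  if (!is.null(model$scaling_stats))
    X <- minmax_normalize(X, model$scaling_stats)$values
  p <- switch(
    model$config$algorithm,
    LR = {
      df <- data.frame(X, check.names = FALSE)
      # rank-deficient fits are routine when features outnumber training
      # rows; the fitted-score ordering is still well defined
      as.numeric(suppressWarnings(
        stats::predict(model$fit, newdata = df, type = "response")))
    },
    SVM = {
      pr <- stats::predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "pos"]
    },
    RF = {
      stats::predict(model$fit, data = data.frame(X, check.names = FALSE),
                     num.threads = 1L)$predictions[, "pos"]
    })
  p <- pmin(pmax(as.numeric(p), 0), 1)
  names(p) <- rownames(features)
  p
}
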