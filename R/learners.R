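# Model specifications and the common fit/predict surface for the four
# from-scratch supervised learners. Hyperparameters are fixed by design
# ("further hyperparameter tuning was not deemed to be appropriate") and
# overridable only explicitly here.

#' Specify one of the four classifiers
#'
#' Fixed default hyperparameters: KNN k = 3 with exhaustive Euclidean search;
#' decision tree with confidence factor 0.25, minimum 2 objects per node,
#' top-rank Shannon information gain; SVM with polynomial kernel, C = 3.5 and
#' simple-logistic score calibration; MLP with one hidden layer of 150
#' logistic units, learning rate 0.001, momentum 0.9, random initial weights.
#' Feature values are consumed as-is (raw intensities); no hidden scaling.
#'
#' @param model One of `"knn"`, `"tree"`, `"svm"`, `"mlp"`, or `"custom"`.
#' @param ... Overrides of the model's defaults (see Details); for
#'   `"custom"`, supply `fit = function(x, y) predictor` where `predictor`
#'   is `function(newx) labels` (used for baselines and test oracles).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = c("knn", "tree", "svm", "mlp", "custom"),
                       ...) {
  kind <- match.arg(model)
  defaults <- switch(kind,
    knn = list(k = 3L),
    tree = list(confidence_factor = 0.25, min_objects = 2L),
    svm = list(c = 3.5, degree = 1L, coef0 = 1, gamma = 1,
               max_passes = 20L, tol = 1e-3, calibrate = TRUE),
    mlp = list(learning_rate = 0.001, momentum = 0.9, hidden_units = 150L,
               epochs = 500L, init_range = 0.05, loss_tol = 1e-6,
               normalize = TRUE),
    custom = list(fit = NULL)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) {
    stop("unknown ", kind, " parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(override)] <- override
  structure(c(list(kind = kind), defaults), class = "model_spec")
}

#' Train a classifier
#'
#' Dispatches to the from-scratch implementation named by the spec. Training
#' is deterministic given (spec, data, seed).
#'
#' @param spec A [model_spec()].
#' @param x Numeric feature matrix (samples x features).
#' @param y Class labels (factor or character).
#' @param seed Integer seed for any stochastic training (MLP weight
#'   initialisation and sample shuffling).
#' @return An object of class `trained_model` with a `predict` method.
#' @export
fit_model <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  fit <- switch(spec$kind,
    knn = fit_knn(x, y, spec),
    tree = fit_tree(x, y, spec),
    svm = fit_svm(x, y, spec),
    mlp = fit_mlp(x, y, spec, seed = seed),
    custom = {
      if (!is.function(spec$fit)) {
        stop("custom spec needs a fit function", call. = FALSE)
      }
      list(predictor = spec$fit(x, y), levels = levels(y))
    }
  )
  structure(list(spec = spec, fit = fit, levels = levels(y)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained %s model (%d classes: %s)\n", x$spec$kind,
              length(x$levels), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict class labels
#'
#' @param object A `trained_model`.
#' @param newdata Numeric feature matrix of query rows.
#' @param ... Unused.
#' @return Factor of predicted labels with the training class levels.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  lab <- switch(object$spec$kind,
    knn = predict_knn(object$fit, newdata),
    tree = predict_tree(object$fit, newdata),
    svm = predict_svm(object$fit, newdata),
    mlp = predict_mlp(object$fit, newdata),
    custom = as.character(object$fit$predictor(newdata))
  )
  factor(lab, levels = object$levels)
}

# ---- KNN ------------------------------------------------------------------

fit_knn <- function(x, y, spec) {
  k <- as.integer(spec$k)
  if (k > nrow(x)) {
    stop(sprintf("k = %d exceeds %d training rows", k, nrow(x)),
         call. = FALSE)
  }
  list(x = x, y = y, k = k)
}

predict_knn <- function(fit, newdata) {
  knn_predict(fit$x, fit$y, newdata, k = fit$k)
}

#' K-nearest-neighbour prediction
#'
#' Majority vote among the `k` nearest training rows by Euclidean distance,
#' found by exhaustive (linear) search. Vote ties are broken by the class of
#' the nearest neighbour belonging to a tied class; distance ties are broken
#' by training-row order, so prediction is deterministic.
#'
#' @param train_x Training feature matrix.
#' @param train_y Training labels (factor or character).
#' @param query_x Query feature matrix.
#' @param k Number of neighbours (default 3); must not exceed `nrow(train_x)`.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, query_x, k = 3L) {
  train_x <- as.matrix(train_x)
  query_x <- as.matrix(query_x)
  if (!is.factor(train_y)) train_y <- factor(train_y)
  k <- as.integer(k)
  if (k > nrow(train_x)) {
    stop(sprintf("k = %d exceeds %d training rows", k, nrow(train_x)),
         call. = FALSE)
  }
  # squared Euclidean distances, all queries at once
  tn <- rowSums(train_x^2)
  qn <- rowSums(query_x^2)
  cross <- query_x %*% t(train_x)
  d2 <- outer(qn, tn, `+`) - 2 * cross
  y_chr <- as.character(train_y)
  vapply(seq_len(nrow(query_x)), function(i) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    votes <- table(y_chr[ord])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    # tie: the nearest neighbour whose class is among the tied classes wins
    y_chr[ord[which(y_chr[ord] %in% top)[1L]]]
  }, character(1))
}
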