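# Donor-grouped stratified tenfold cross-validation with pooled out-of-sample
# confusion matrices, feature scaling, and 2-D PCA.

#' Plan donor-grouped stratified folds
#'
#' Assigns whole donors to folds: within each class, donors are shuffled
#' (seeded) and dealt round-robin across folds with a pointer carried across
#' classes, so classes spread as evenly as possible (per class, fold donor
#' counts differ by at most 1) and every sample of a donor shares that
#' donor's fold. With 15 donors and 10 folds, 5 folds hold 2 donors and 5
#' hold 1.
#'
#' @param metadata Data.frame with `sample_id`, `donor_id`, `class`.
#' @param n_folds Number of folds (default 10); must not exceed the donor
#'   count. `n_folds` equal to the donor count gives leave-one-donor-out.
#' @param seed Integer seed for the within-class donor shuffle.
#' @return An object of class `fold_plan`: `donor_fold` (data.frame
#'   `donor_id`, `fold`), `sample_fold` (named integer vector by sample id),
#'   `n_folds`, `seed`.
#' @export
plan_folds <- function(metadata, n_folds = 10L, seed = 1L) {
  stopifnot(all(c("sample_id", "donor_id", "class") %in% names(metadata)))
  dc <- unique(metadata[, c("donor_id", "class")])
  if (anyDuplicated(dc$donor_id)) {
    stop("a donor maps to more than one class", call. = FALSE)
  }
  n_folds <- as.integer(n_folds)
  if (n_folds > nrow(dc)) {
    stop(sprintf("n_folds = %d exceeds %d donors", n_folds, nrow(dc)),
         call. = FALSE)
  }
  cls <- if (is.factor(metadata$class)) levels(metadata$class) else
    unique(as.character(dc$class))
  assign_fold <- integer(0)
  ptr <- 0L
  for (cl in cls) {
    donors <- dc$donor_id[as.character(dc$class) == cl]
    if (!length(donors)) next
    donors <- with_seed(seed + match(cl, cls),
                        donors[sample.int(length(donors))])
    folds <- ((ptr + seq_along(donors) - 1L) %% n_folds) + 1L
    ptr <- ptr + length(donors)
    names(folds) <- donors
    assign_fold <- c(assign_fold, folds)
  }
  donor_fold <- data.frame(donor_id = names(assign_fold),
                           fold = unname(assign_fold),
                           stringsAsFactors = FALSE)
  sample_fold <- assign_fold[metadata$donor_id]
  names(sample_fold) <- metadata$sample_id
  structure(list(donor_fold = donor_fold, sample_fold = sample_fold,
                 n_folds = n_folds, seed = seed),
            class = "fold_plan")
}

#' Run donor-grouped cross-validation and pool the results
#'
#' For each fold, trains on all other folds' samples and predicts the
#' held-out fold; all held-out predictions are pooled into a single
#' out-of-sample confusion matrix (each sample counted exactly once) and a
#' categorical accuracy (trace / total). Donor leakage is asserted on every
#' fold: the intersection of train and test donors must be empty.
#'
#' @param fm A `feature_matrix` from [assemble_matrix()].
#' @param spec A [model_spec()].
#' @param plan A `fold_plan` from [plan_folds()] covering all samples.
#' @param seed Integer seed; a per-fold training seed is derived from it.
#' @return An object of class `pooled_result`: `confusion` (true x
#'   predicted), `accuracy`, `predictions` (per-sample log), `spec`, `plan`.
#' @export
run_grouped_cv <- function(fm, spec, plan, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(plan, "fold_plan"))
  fold <- plan$sample_fold[fm$sample_id]
  if (anyNA(fold)) stop("fold plan does not cover all samples", call. = FALSE)
  pred <- factor(rep(NA_character_, length(fold)), levels = levels(fm$class))
  for (f in sort(unique(fold))) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    leak <- intersect(fm$donor_id[train_idx], fm$donor_id[test_idx])
    if (length(leak)) {
      stop("donor leakage across train/test: ", paste(leak, collapse = ", "),
           call. = FALSE)
    }
    y_train <- fm$class[train_idx]
    if (nlevels(droplevels(y_train)) < nlevels(fm$class)) {
      warning(sprintf("fold %d: training data lacks %d class(es)", f,
                      nlevels(fm$class) - nlevels(droplevels(y_train))))
    }
    model <- fit_model(spec, fm$x[train_idx, , drop = FALSE], y_train,
                       seed = seed + 1000L * f)
    pred[test_idx] <- predict(model, fm$x[test_idx, , drop = FALSE])
  }
  confusion <- table(true = fm$class, predicted = pred)
  structure(list(
    confusion = confusion,
    accuracy = sum(diag(confusion)) / sum(confusion),
    predictions = data.frame(sample_id = fm$sample_id,
                             donor_id = fm$donor_id, fold = unname(fold),
                             true = fm$class, predicted = pred,
                             stringsAsFactors = FALSE),
    spec = spec, plan = plan
  ), class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("pooled out-of-sample confusion matrix (%s, %d folds):\n",
              x$spec$kind, x$plan$n_folds))
  print(x$confusion)
  cat(sprintf("categorical accuracy: %.1f%% (%d / %d)\n",
              100 * x$accuracy, sum(diag(x$confusion)), sum(x$confusion)))
  invisible(x)
}

#' Plan record-wise (non-grouped) stratified folds
#'
#' Assigns individual samples to folds stratified by class, ignoring donor
#' identity. This deliberately leaks donors across train/test and exists to
#' quantify the optimism of record-wise evaluation against the grouped plan;
#' it is not a valid evaluation protocol for this study design.
#'
#' @inheritParams plan_folds
#' @return A `fold_plan` whose `donor_fold` is empty.
#' @export
plan_record_folds <- function(metadata, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  cls <- if (is.factor(metadata$class)) levels(metadata$class) else
    unique(as.character(metadata$class))
  sample_fold <- integer(nrow(metadata))
  ptr <- 0L
  for (cl in cls) {
    idx <- which(as.character(metadata$class) == cl)
    if (!length(idx)) next
    idx <- with_seed(seed + match(cl, cls), idx[sample.int(length(idx))])
    sample_fold[idx] <- ((ptr + seq_along(idx) - 1L) %% n_folds) + 1L
    ptr <- ptr + length(idx)
  }
  names(sample_fold) <- metadata$sample_id
  structure(list(donor_fold = data.frame(donor_id = character(0),
                                         fold = integer(0)),
                 sample_fold = sample_fold, n_folds = n_folds, seed = seed),
            class = "fold_plan")
}

#' Record-wise cross-validation (leaky baseline)
#'
#' Identical pooling to [run_grouped_cv()] but without the donor-leakage
#' assertion, for use with [plan_record_folds()] when quantifying the
#' grouped-vs-ungrouped accuracy gap.
#'
#' @inheritParams run_grouped_cv
#' @return A `pooled_result`.
#' @export
run_record_cv <- function(fm, spec, plan, seed = 1L) {
  fold <- plan$sample_fold[fm$sample_id]
  if (anyNA(fold)) stop("fold plan does not cover all samples", call. = FALSE)
  pred <- factor(rep(NA_character_, length(fold)), levels = levels(fm$class))
  for (f in sort(unique(fold))) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    model <- fit_model(spec, fm$x[train_idx, , drop = FALSE],
                       fm$class[train_idx], seed = seed + 1000L * f)
    pred[test_idx] <- predict(model, fm$x[test_idx, , drop = FALSE])
  }
  confusion <- table(true = fm$class, predicted = pred)
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 predictions = data.frame(sample_id = fm$sample_id,
                                          fold = unname(fold),
                                          true = fm$class, predicted = pred,
                                          stringsAsFactors = FALSE),
                 spec = spec, plan = plan),
            class = "pooled_result")
}

#' Scale feature columns
#'
#' `none` returns the input unchanged; `standardise` maps each m/z column to
#' mean 0, sd 1; `minmax` maps each column onto [0, 1]. Constant columns map
#' to all zeros under both scalings. Applied prior to dimensionality
#' reduction only; the learners consume raw intensities.
#'
#' @param fm A `feature_matrix`.
#' @param mode One of `"none"`, `"standardise"`, `"minmax"`.
#' @return The scaled `feature_matrix`.
#' @export
scale_features <- function(fm, mode = c("none", "standardise", "minmax")) {
  mode <- match.arg(mode)
  if (mode == "none") return(fm)
  x <- fm$x
  if (mode == "standardise") {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    x <- sweep(x, 2, mu)
    nz <- sdv > 0
    x[, nz] <- sweep(x[, nz, drop = FALSE], 2, sdv[nz], "/")
    x[, !nz] <- 0
  } else {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    rng <- hi - lo
    x <- sweep(x, 2, lo)
    nz <- rng > 0
    x[, nz] <- sweep(x[, nz, drop = FALSE], 2, rng[nz], "/")
    x[, !nz] <- 0
  }
  fm$x <- x
  fm
}

#' 2-D principal component scores
#'
#' Scores on the first two principal components of the column-centred matrix,
#' computed by singular value decomposition. Component signs are fixed so
#' that each component's largest-magnitude loading is positive. If the data
#' have fewer than two non-degenerate directions, the second coordinate is
#' all zeros and the result is flagged (`attr(., "degenerate")`).
#'
#' @param fm A `feature_matrix` (or a plain numeric matrix).
#' @return A data.frame `sample_id`, `dim1`, `dim2` of class `embedding_2d`.
#' @export
pca2d <- function(fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  ids <- if (inherits(fm, "feature_matrix")) fm$sample_id else
    if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(x)))
  if (nrow(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = 2, nv = 2)
  degenerate <- length(sv$d) < 2L || sv$d[2] <= sv$d[1] * 1e-10
  scores <- sv$u %*% diag(sv$d[1:2], nrow = 2)
  for (j in 1:2) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  if (degenerate) scores[, 2] <- 0
  out <- data.frame(sample_id = ids, dim1 = scores[, 1], dim2 = scores[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("embedding_2d", "data.frame")
  out
}
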