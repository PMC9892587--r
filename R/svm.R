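# Soft-margin SVM trained by sequential minimal optimisation (SMO) with a
# polynomial kernel, C = 3.5; multiclass by one-vs-one majority vote;
# "simple logistic" post-hoc calibration of decision values for scores only.

poly_kernel <- function(a, b, spec) {
  (spec$gamma * (a %*% t(b)) + spec$coef0)^spec$degree
}

# Platt-style SMO on a precomputed kernel; deterministic second-choice
# heuristic (maximal |E_i - E_j|, ties by index).
smo_train <- function(K, y, C, tol, max_passes) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  iter <- 0L
  max_iter <- 500L * n
  fcache <- function() as.vector(K %*% (alpha * y)) + b
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1L
    changed <- 0L
    E <- fcache() - y
    for (i in seq_len(n)) {
      Ei <- sum(K[, i] * alpha * y) + b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        E <- as.vector(K %*% (alpha * y)) + b - y
        j <- setdiff(order(-abs(Ei - E)), i)[1L]
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-12) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        alpha[i] <- ai; alpha[j] <- aj
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else
          (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

fit_svm <- function(x, y, spec) {
  if (nlevels(droplevels(y)) < 2L) {
    stop("SVM training needs at least two classes", call. = FALSE)
  }
  lv <- levels(y)
  present <- lv[lv %in% unique(as.character(y))]
  pairs <- utils::combn(present, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    idx <- which(as.character(y) %in% pr)
    xs <- x[idx, , drop = FALSE]
    ys <- ifelse(as.character(y)[idx] == pr[1L], 1, -1)
    K <- poly_kernel(xs, xs, spec)
    sm <- smo_train(K, ys, spec$c, spec$tol, spec$max_passes)
    m <- list(pair = pr, sv_x = xs, sv_ay = sm$alpha * ys, b = sm$b)
    if (isTRUE(spec$calibrate)) {
      d <- as.vector(K %*% m$sv_ay) + m$b
      cal <- tryCatch(
        suppressWarnings(stats::glm.fit(cbind(1, d), (ys + 1) / 2,
                                        family = stats::binomial())$coefficients),
        error = function(e) c(0, 1))
      m$calibration <- cal
    }
    m
  })
  list(models = models, levels = lv, spec = spec)
}

svm_pair_decision <- function(model, newdata, spec) {
  as.vector(poly_kernel(newdata, model$sv_x, spec) %*% model$sv_ay) + model$b
}

predict_svm <- function(fit, newdata) {
  lv <- fit$levels
  votes <- matrix(0, nrow = nrow(newdata), ncol = length(lv),
                  dimnames = list(NULL, lv))
  margin <- matrix(0, nrow = nrow(newdata), ncol = length(lv),
                   dimnames = list(NULL, lv))
  for (m in fit$models) {
    d <- svm_pair_decision(m, newdata, fit$spec)
    win <- ifelse(d >= 0, m$pair[1L], m$pair[2L])
    for (i in seq_along(win)) {
      votes[i, win[i]] <- votes[i, win[i]] + 1
      margin[i, m$pair[1L]] <- margin[i, m$pair[1L]] + d[i]
      margin[i, m$pair[2L]] <- margin[i, m$pair[2L]] - d[i]
    }
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) {
      # vote tie: largest aggregate decision margin, then class order
      top <- top[which.max(margin[i, top])]
    }
    lv[top[1L]]
  }, character(1))
}

# calibrated pairwise probabilities (scores only; argmax predictions use
# uncalibrated one-vs-one votes)
svm_pair_scores <- function(fit, newdata) {
  out <- lapply(fit$models, function(m) {
    d <- svm_pair_decision(m, newdata, fit$spec)
    cal <- if (!is.null(m$calibration)) m$calibration else c(0, 1)
    stats::plogis(cal[1L] + cal[2L] * d)
  })
  names(out) <- vapply(fit$models, function(m) {
    paste(m$pair, collapse = "_vs_")
  }, character(1))
  out
}
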