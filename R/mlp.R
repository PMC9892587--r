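# Single-hidden-layer multilayer perceptron: 150 logistic-sigmoid hidden
# units, softmax output, cross-entropy loss, per-sample stochastic gradient
# descent with momentum; weights initialised uniformly in [-init, +init].
#
# The learner min-max normalises its inputs to [0, 1] as part of training
# (ranges learnt on the training fold, reapplied at prediction): the fixed
# learning rate 0.001 and init range 0.05 are only meaningful on unit-scale
# inputs -- on raw a.u.-scale intensities every logistic hidden unit
# saturates at initialisation and its gradient is numerically zero, so the
# network provably cannot train. The normalisation is part of the model, is
# exposed as `normalize` in the spec, and can be switched off.

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# forward pass + analytic gradients of the cross-entropy loss for one sample;
# params: list(W1 h x d, b1 h, W2 c x h, b2 c); y is the true class index.
mlp_gradients <- function(params, x, y) {
  z1 <- as.vector(params$W1 %*% x) + params$b1
  a1 <- sigmoid(z1)
  z2 <- as.vector(params$W2 %*% a1) + params$b2
  p <- softmax(z2)
  loss <- -log(max(p[y], .Machine$double.xmin))
  d2 <- p
  d2[y] <- d2[y] - 1
  d1 <- as.vector(crossprod(params$W2, d2)) * a1 * (1 - a1)
  list(loss = loss, p = p,
       gW2 = tcrossprod(d2, a1), gb2 = d2,
       gW1 = tcrossprod(d1, x), gb1 = d1)
}

mlp_normalize <- function(x, lo, rng) {
  x <- sweep(x, 2, lo)
  nz <- rng > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, rng[nz], "/")
  x[, !nz] <- 0
  x
}

fit_mlp <- function(x, y, spec, seed = 1L) {
  norm <- NULL
  if (isTRUE(spec$normalize)) {
    lo <- apply(x, 2, min)
    rng <- apply(x, 2, max) - lo
    norm <- list(lo = lo, rng = rng)
    x <- mlp_normalize(x, lo, rng)
  }
  n <- nrow(x); d <- ncol(x)
  h <- as.integer(spec$hidden_units)
  nc <- nlevels(y)
  y_int <- as.integer(y)
  lr <- spec$learning_rate
  mom <- spec$momentum
  params <- with_seed(seed, list(
    W1 = matrix(stats::runif(h * d, -spec$init_range, spec$init_range), h, d),
    b1 = stats::runif(h, -spec$init_range, spec$init_range),
    W2 = matrix(stats::runif(nc * h, -spec$init_range, spec$init_range),
                nc, h),
    b2 = stats::runif(nc, -spec$init_range, spec$init_range)
  ))
  vel <- lapply(params, function(p) p * 0)
  epochs <- as.integer(spec$epochs)
  prev_loss <- Inf
  if (epochs >= 1L && n >= 1L) {
    orders <- with_seed(seed + 1L, lapply(seq_len(epochs), function(e) {
      sample.int(n)
    }))
    for (e in seq_len(epochs)) {
      total_loss <- 0
      for (i in orders[[e]]) {
        g <- mlp_gradients(params, x[i, ], y_int[i])
        if (!is.finite(g$loss)) {
          stop("MLP training diverged: non-finite loss at epoch ", e,
               call. = FALSE)
        }
        total_loss <- total_loss + g$loss
        for (nm in c("W1", "b1", "W2", "b2")) {
          vel[[nm]] <- mom * vel[[nm]] - lr * g[[paste0("g", nm)]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
      }
      mean_loss <- total_loss / n
      if (abs(prev_loss - mean_loss) < spec$loss_tol) break
      prev_loss <- mean_loss
    }
  }
  list(params = params, levels = levels(y), norm = norm)
}

predict_mlp <- function(fit, newdata) {
  p <- mlp_scores(fit, newdata)
  fit$levels[max.col(p, ties.method = "first")]
}

mlp_scores <- function(fit, newdata) {
  if (!is.null(fit$norm)) {
    newdata <- mlp_normalize(newdata, fit$norm$lo, fit$norm$rng)
  }
  a1 <- sigmoid(tcrossprod(newdata, fit$params$W1) +
                  matrix(fit$params$b1, nrow(newdata),
                         length(fit$params$b1), byrow = TRUE))
  z2 <- tcrossprod(a1, fit$params$W2) +
    matrix(fit$params$b2, nrow(newdata), length(fit$params$b2), byrow = TRUE)
  t(apply(z2, 1, softmax))
}

# evaluate expr with a temporary RNG state seeded by `seed`, restoring any
# pre-existing state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
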