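# The four from-scratch classifiers.

test_that("KNN votes by Euclidean neighbourhood with deterministic ties", {
  x <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  y <- c("A", "A", "B")
  expect_equal(knn_predict(x, y, x[2L, , drop = FALSE], k = 1), "A")
  expect_equal(knn_predict(x, y, matrix(c(0.4, 0.4), 1), k = 3), "A")
  # 1-1-1 vote across three classes: nearest neighbour's class wins
  x3 <- matrix(c(0, 1, 2), ncol = 1)
  y3 <- c("A", "B", "C")
  expect_equal(knn_predict(x3, y3, matrix(0.9), k = 3), "B")
  expect_error(knn_predict(x3, y3, matrix(1), k = 5), "exceeds")
})

test_that("KNN equals the brute-force neighbour oracle on random rows", {
  set.seed(2024)
  train <- matrix(rnorm(120 * 5), ncol = 5)
  train[, 5] <- train[, 5] * 1e4      # wide feature scales consumed as-is
  y <- sample(c("benign", "early", "metastatic"), 120, replace = TRUE)
  query <- matrix(rnorm(200 * 5), ncol = 5)
  query[, 5] <- query[, 5] * 1e4
  expect_equal(knn_predict(train, y, query, k = 3),
               unname(brute_knn(train, y, query, k = 3)))
})

test_that("decision tree splits by information gain and prunes to leaves", {
  expect_equal(shannon_entropy(c(1, 1)), 1)
  expect_equal(shannon_entropy(c(2, 0)), 0)
  expect_equal(shannon_entropy(c(3, 3, 3)), log2(3))

  # pure training set: a single leaf
  xp <- matrix(rnorm(20), ncol = 2)
  fit_pure <- fit_model(model_spec("tree"), xp, rep("A", 10))
  expect_equal(fit_pure$fit$root$type, "leaf")
  expect_equal(as.character(predict(fit_pure, xp)), rep("A", 10))

  # 1-D separable data: one split with threshold between the classes
  x1 <- matrix(c(-3, -2, -1.5, -1, 1, 1.5, 2, 3), ncol = 1)
  y1 <- rep(c("A", "B"), each = 4)
  fit1 <- fit_model(model_spec("tree"), x1, y1)
  expect_equal(fit1$fit$root$type, "split")
  expect_gt(fit1$fit$root$threshold, -1)
  expect_lt(fit1$fit$root$threshold, 1)
  expect_equal(as.character(predict(fit1, x1)), y1)
})

test_that("SVM separates soft margins and agrees in sign with a QP oracle", {
  set.seed(5)
  a <- cbind(rnorm(10, -3), rnorm(10, -3))
  b <- cbind(rnorm(10, 3), rnorm(10, 3))
  x <- rbind(a, b)
  y <- rep(c("neg", "pos"), each = 10)
  fit <- fit_model(model_spec("svm"), x, y)
  expect_equal(as.character(predict(fit, x)), y)

  # duplicated conflicting-label point still trains (margin violation <= C)
  xc <- rbind(x, x[1L, ])
  yc <- c(y, "pos")
  fitc <- fit_model(model_spec("svm"), xc, yc)
  expect_s3_class(fitc, "trained_model")
  alpha_bound <- max(abs(fitc$fit$models[[1L]]$sv_ay))
  expect_lte(alpha_bound, 3.5 + 1e-6)

  expect_error(fit_model(model_spec("svm"), x, rep("one", 20)),
               "two classes")

  # decision values agree in sign with an independent SVM on <= 20 points
  skip_if_not_installed("e1071")
  ours <- svm_pair_decision(fit$fit$models[[1L]], x, fit$fit$spec)
  ref <- e1071::svm(x, factor(y), kernel = "polynomial", degree = 1,
                    gamma = 1, coef0 = 1, cost = 3.5, scale = FALSE)
  dref <- attr(predict(ref, x, decision.values = TRUE), "decision.values")
  # e1071 orients its decision by its own level order; align once by sign
  orient <- sign(sum(sign(ours) * sign(dref)))
  expect_true(all(sign(ours) == orient * sign(dref)))
})

test_that("MLP gradients match central finite differences", {
  set.seed(8)
  d <- 3L; h <- 4L; nc <- 3L
  params <- list(W1 = matrix(runif(h * d, -0.5, 0.5), h, d),
                 b1 = runif(h, -0.5, 0.5),
                 W2 = matrix(runif(nc * h, -0.5, 0.5), nc, h),
                 b2 = runif(nc, -0.5, 0.5))
  xs <- matrix(rnorm(4 * d), ncol = d)
  ys <- c(1L, 2L, 3L, 2L)
  eps <- 1e-6
  for (s in 1:4) {
    g <- maldiscreen:::mlp_gradients(params, xs[s, ], ys[s])
    for (nm in c("W1", "b1", "W2", "b2")) {
      target <- params[[nm]]
      num <- array(0, dim = dim(as.matrix(target)))
      for (i in seq_along(target)) {
        up <- params; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
        lu <- maldiscreen:::mlp_gradients(up, xs[s, ], ys[s])$loss
        ld <- maldiscreen:::mlp_gradients(dn, xs[s, ], ys[s])$loss
        num[i] <- (lu - ld) / (2 * eps)
      }
      ana <- as.numeric(g[[paste0("g", nm)]])
      rel <- abs(ana - as.numeric(num)) /
        pmax(abs(as.numeric(num)), abs(ana), 1e-8)
      rel[abs(ana) < 1e-10 & abs(as.numeric(num)) < 1e-6] <- 0
      expect_lt(max(rel), 1e-4)
    }
  }
})

test_that("MLP learns XOR and untrained predictions are seed-determined", {
  x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  x <- x[rep(1:4, 8), ]
  y <- factor(rep(c("A", "B", "B", "A"), 8))
  spec <- model_spec("mlp", hidden_units = 8L, learning_rate = 0.3,
                     momentum = 0.9, epochs = 2000L, loss_tol = 0)
  fit <- fit_model(spec, x, y, seed = 5)
  expect_equal(mean(predict(fit, x) == y), 1)

  zero <- model_spec("mlp", epochs = 0L)
  f1 <- fit_model(zero, x, y, seed = 5)
  f2 <- fit_model(zero, x, y, seed = 5)
  expect_identical(predict(f1, x), predict(f2, x))
})

test_that("training is deterministic and label renaming permutes predictions", {
  co <- simulate_cohort(cohort_design(donors_per_class = 2L), seed = 31)
  fm <- cohort_features(co)
  q <- fm$x[seq(1, nrow(fm$x), by = 5), , drop = FALSE]
  for (kind in c("knn", "tree", "svm", "mlp")) {
    spec <- if (kind == "mlp") model_spec("mlp", epochs = 20L) else
      model_spec(kind)
    m1 <- fit_model(spec, fm$x, fm$class, seed = 17)
    m2 <- fit_model(spec, fm$x, fm$class, seed = 17)
    expect_identical(predict(m1, q), predict(m2, q))

    # bijective label renaming: predictions map through the same renaming
    y2 <- factor(paste0("grp_", as.character(fm$class)),
                 levels = paste0("grp_", levels(fm$class)))
    m3 <- fit_model(spec, fm$x, y2, seed = 17)
    expect_identical(as.character(predict(m3, q)),
                     paste0("grp_", as.character(predict(m1, q))))
  }
})

test_that("switching off the MLP's input normalisation is explicit", {
  co <- simulate_cohort(cohort_design(donors_per_class = 2L), seed = 13)
  fm <- cohort_features(co)
  raw <- fit_model(model_spec("mlp", epochs = 30L, normalize = FALSE),
                   fm$x, fm$class, seed = 2)
  expect_null(raw$fit$norm)
  norm <- fit_model(model_spec("mlp", epochs = 30L), fm$x, fm$class,
                    seed = 2)
  expect_false(is.null(norm$fit$norm))
})
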