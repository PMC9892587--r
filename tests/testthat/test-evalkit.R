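# Donor-grouped stratified CV, pooled confusion matrices, scaling, PCA.

test_that("fold plans keep donors whole and classes balanced", {
  co <- simulate_cohort(seed = 1)
  plan <- plan_folds(co$metadata, n_folds = 10, seed = 3)
  # 15 donors into 10 folds: 5 folds hold 2 donors, 5 hold 1
  counts <- table(plan$donor_fold$fold)
  expect_equal(sort(as.integer(counts)), c(rep(1L, 5), rep(2L, 5)))
  # every donor's 9 samples share one fold
  per_donor <- tapply(plan$sample_fold, co$metadata$donor_id,
                      function(f) length(unique(f)))
  expect_true(all(per_donor == 1L))
  # per class, fold donor counts differ by at most 1
  donor_class <- unique(co$metadata[, c("donor_id", "class")])
  for (cl in levels(co$metadata$class)) {
    donors <- donor_class$donor_id[donor_class$class == cl]
    f <- plan$donor_fold$fold[match(donors, plan$donor_fold$donor_id)]
    tab <- tabulate(f, 10)
    expect_lte(max(tab) - min(tab), 1L)
  }

  # leave-one-donor-out limit
  lodo <- plan_folds(co$metadata, n_folds = 15, seed = 3)
  expect_equal(sort(as.integer(table(lodo$donor_fold$fold))), rep(1L, 15))

  # seeds change the assignment, not the invariants
  plan2 <- plan_folds(co$metadata, n_folds = 10, seed = 4)
  expect_false(identical(plan$donor_fold, plan2$donor_fold))
  expect_equal(sort(as.integer(table(plan2$donor_fold$fold))),
               c(rep(1L, 5), rep(2L, 5)))

  expect_error(plan_folds(co$metadata, n_folds = 16), "exceeds")
})

test_that("pooled CV counts every sample once and rejects donor leakage", {
  fm <- perfect_fixture()
  plan <- plan_folds(data.frame(sample_id = fm$sample_id,
                                donor_id = fm$donor_id,
                                class = fm$class), n_folds = 3, seed = 1)
  res <- run_grouped_cv(fm, model_spec("knn", k = 1), plan)
  expect_equal(sum(res$confusion), length(fm$sample_id))
  expect_equal(res$accuracy, 1)
  expect_equal(sum(diag(res$confusion)), sum(res$confusion))
  # every sample appears exactly once in the prediction log
  expect_equal(sort(res$predictions$sample_id), sort(fm$sample_id))

  # fixed-class dummy baseline on the balanced design: accuracy 1/3
  dummy <- model_spec("custom", fit = function(x, y) {
    lev <- levels(y)
    function(newx) rep(lev[1L], nrow(newx))
  })
  res_dummy <- run_grouped_cv(fm, dummy, plan)
  expect_equal(res_dummy$accuracy, 1 / 3)

  # tampered plan with a donor on both sides must be refused
  bad <- plan
  donor <- fm$donor_id[1L]
  idx <- which(fm$donor_id == donor)
  bad$sample_fold[fm$sample_id[idx[1L]]] <-
    bad$sample_fold[fm$sample_id[idx[1L]]] %% 3 + 1
  expect_error(run_grouped_cv(fm, model_spec("knn", k = 1), bad),
               "leakage")
})

test_that("grouped CV is harder than record-wise CV under donor effects", {
  # zero class effects: any skill in record-wise CV is donor leakage
  panel <- scale_panel_effects(default_panel(), 0)
  gap <- vapply(1:20, function(s) {
    co <- simulate_cohort(cohort_design(donors_per_class = 3L), panel,
                          seed = 100 + s)
    fm <- cohort_features(co)
    meta <- co$metadata
    grouped <- run_grouped_cv(fm, model_spec("knn"),
                              plan_folds(meta, 9, seed = s))
    record <- run_record_cv(fm, model_spec("knn"),
                            plan_record_folds(meta, 9, seed = s))
    record$accuracy - grouped$accuracy
  }, numeric(1))
  expect_gt(mean(gap), 0)
})

test_that("feature scaling modes match their definitions", {
  fm <- perfect_fixture()
  expect_identical(scale_features(fm, "none"), fm)

  std <- scale_features(fm, "standardise")
  nonconst <- apply(fm$x, 2, sd) > 0
  expect_true(all(abs(colMeans(std$x[, nonconst, drop = FALSE])) < 1e-12))
  expect_true(all(abs(apply(std$x[, nonconst, drop = FALSE], 2, sd) - 1) <
                    1e-12))

  mm <- scale_features(fm, "minmax")
  expect_true(all(mm$x >= 0 & mm$x <= 1))
  toy <- fm
  toy$x <- matrix(c(2, 4, 6), ncol = 1)[rep(1:3, length.out = nrow(fm$x)), ,
                                        drop = FALSE]
  expect_equal(sort(unique(as.numeric(scale_features(toy, "minmax")$x))),
               c(0, 0.5, 1))

  const <- fm
  const$x <- cbind(fm$x, 7)
  expect_true(all(scale_features(const, "standardise")$x[, ncol(const$x)] ==
                    0))
  expect_true(all(scale_features(const, "minmax")$x[, ncol(const$x)] == 0))
})

test_that("2-D PCA matches an eigendecomposition oracle", {
  set.seed(99)
  x <- matrix(rnorm(60), nrow = 10, ncol = 6)
  sc <- pca2d(x)
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(cov(xc), symmetric = TRUE)
  oracle <- xc %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    got <- sc[[paste0("dim", j)]]
    dev <- min(max(abs(got - oracle[, j])), max(abs(got + oracle[, j])))
    expect_lt(dev, 1e-8)
  }
  # score covariance is diagonal with non-increasing variance
  cv <- cov(cbind(sc$dim1, sc$dim2))
  expect_lt(abs(cv[1, 2]), 1e-8)
  expect_gte(cv[1, 1], cv[2, 2])

  # collinear data: second coordinate flagged degenerate and zeroed
  line <- outer(seq_len(12), c(1, 2, 3))
  sc2 <- pca2d(line)
  expect_true(attr(sc2, "degenerate"))
  expect_true(all(sc2$dim2 == 0))

  expect_error(pca2d(x[1:2, ]), "3 samples")
})
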