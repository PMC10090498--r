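test_that("PCA keeps the smallest component count reaching the threshold", {
  # two uncorrelated features with exact sample variances 9.5 and 0.5:
  # explained ratios 0.95 / 0.05
  set.seed(17)
  z1 <- scale(rnorm(40))[, 1] * sqrt(9.5)
  z2 <- scale(residuals(lm(rnorm(40) ~ z1)))[, 1] * sqrt(0.5)
  x <- cbind(z1, z2)
  model <- pca_fit(x, 0.9)
  expect_equal(model$explained_ratio, c(0.95, 0.05), tolerance = 1e-10)
  expect_equal(model$k, 1)
  expect_equal(pca_fit(x, 0.96)$k, 2)
})

test_that("PCA invariants hold on random data", {
  set.seed(31)
  x <- matrix(rnorm(25 * 8), 25, 8) %*% matrix(rnorm(64, sd = 0.6), 8, 8)
  model <- pca_fit(x, 0.9)
  expect_equal(sum(model$explained_ratio), 1, tolerance = 1e-10)
  expect_false(is.unsorted(rev(model$explained_ratio)))
  # loadings orthonormal
  expect_equal(crossprod(model$rotation), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  # training scores are centred per component
  scores <- pca_transform(model, x)
  expect_equal(colMeans(scores), rep(0, model$k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # score variance accounts for the kept eigenvalues
  ev <- sort(eigen(stats::cov(x), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(apply(scores, 2, stats::var), ev[seq_len(model$k)],
               tolerance = 1e-8, ignore_attr = TRUE)

  # full basis reconstructs the data
  full <- pca_fit(x, 1.0)
  s_full <- pca_transform(full, x, k = 8)
  recon <- s_full %*% t(full$rotation) +
    matrix(full$mean, nrow(x), 8, byrow = TRUE)
  expect_equal(recon, x, tolerance = 1e-8, ignore_attr = TRUE)

  # transforming the training mean gives the zero vector
  expect_equal(drop(pca_transform(model, full$mean)), rep(0, model$k),
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(pca_transform(model, x[, 1:5]), "feature count")
  expect_error(pca_fit(matrix(3, 10, 4)), "constant")
})

test_that("linear SVM solves the textbook 1-D separable case", {
  x <- matrix(c(-1, 1), ncol = 1)
  y <- c(-1, 1)
  fit <- svm_train(x, y, kernel = "linear", C = 1e6)
  expect_equal(predict(fit, x), y)
  expect_equal(nrow(fit$support_vectors), 2)
  expect_equal(unname(fit$w), 1, tolerance = 1e-4)
  expect_equal(fit$margin, 2, tolerance = 1e-3)  # rho = 2 / ||w||
  # decision value on a margin support vector is +-1
  expect_equal(abs(decision_values(fit, x)), c(1, 1), tolerance = 1e-4)
})

test_that("RBF kernel separates XOR where the linear kernel cannot", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1, 1, -1, -1)
  rbf <- svm_train(x, y, kernel = "rbf", C = 1e6, gamma = 1)
  expect_equal(predict(rbf, x), y)  # 4/4
  lin <- svm_train(x, y, kernel = "linear", C = 1e6)
  expect_lte(mean(predict(lin, x) == y), 3 / 4)
})

test_that("duplicating every training point leaves decisions unchanged", {
  pool <- small_pool()
  fit1 <- svm_train(pool$x, pool$y, C = 2, gamma = 0.5)
  fit2 <- svm_train(rbind(pool$x, pool$x), c(pool$y, pool$y),
                    C = 2, gamma = 0.5)
  grid <- matrix(rnorm(40), ncol = 4)
  expect_equal(predict(fit1, grid), predict(fit2, grid))
})

test_that("SVM input validation", {
  pool <- small_pool()
  expect_error(svm_train(pool$x, rep(1, nrow(pool$x))), "both classes")
  expect_error(svm_train(pool$x, rep(c(0, 1), 12)), "labels")
})

test_that("grid search covers the powers-of-two grid and is deterministic", {
  pool <- small_pool()
  cfg <- fast_cfg()
  cv1 <- grid_search_cv(pool$x, pool$y, cfg)
  cv2 <- grid_search_cv(pool$x, pool$y, cfg)
  expect_equal(nrow(cv1$grid), 5 * 5)  # (2*m1+1) x (2*m2+1)
  expect_setequal(unique(cv1$grid$C), 2^(-2:2))
  expect_identical(cv1$grid, cv2$grid)
  expect_equal(cv1$best_C, cv2$best_C)
  expect_length(cv1$fold_accuracies, cfg$cv_splits * cfg$cv_repeats)
  expect_true(all(cv1$grid$mean_accuracy >= 0 & cv1$grid$mean_accuracy <= 1))
})

test_that("grid-point accuracy matches a hand-rolled fold loop", {
  pool <- small_pool(n_per_class = 12)  # 24-sample pool
  cfg <- fast_cfg()
  cv <- grid_search_cv(pool$x, pool$y, cfg)

  # independent oracle: explicit loop over the same fold assignments
  fold_sets <- withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$cv_repeats),
           function(i) fibrodep:::stratified_folds(pool$y, cfg$cv_splits))
  })
  for (row in c(1, 7, 13, 25)) {
    C <- cv$grid$C[row]
    gamma <- cv$grid$gamma[row]
    accs <- c()
    for (folds in fold_sets) {
      for (f in seq_len(cfg$cv_splits)) {
        test <- folds == f
        fit <- e1071::svm(pool$x[!test, , drop = FALSE],
                          factor(pool$y[!test], levels = c(1, -1)),
                          type = "C-classification", kernel = "radial",
                          cost = C, gamma = gamma, scale = FALSE)
        pred <- as.numeric(as.character(
          predict(fit, pool$x[test, , drop = FALSE])
        ))
        accs <- c(accs, mean(pred == pool$y[test]))
      }
    }
    expect_equal(cv$grid$mean_accuracy[row], mean(accs), tolerance = 1e-12)
  }
})

test_that("a saturated grid resolves ties to the smallest C then gamma", {
  # classes far apart and tight: every grid point classifies perfectly
  pool <- small_pool(sep = 3, sd = 0.1)
  cv <- grid_search_cv(pool$x, pool$y, fast_cfg())
  expect_true(all(cv$grid$mean_accuracy == 1))
  expect_equal(cv$best_C, 2^-2)
  expect_equal(cv$best_gamma, 2^-2)
})

test_that("decisions are invariant to a consistent feature permutation", {
  pool <- small_pool()
  perm <- c(3, 1, 4, 2)
  fit <- svm_train(pool$x, pool$y, C = 4, gamma = 0.3)
  fitp <- svm_train(pool$x[, perm], pool$y, C = 4, gamma = 0.3)
  newx <- matrix(rnorm(20), ncol = 4)
  expect_equal(predict(fit, newx), predict(fitp, newx[, perm]))
})

test_that("scheme 2 trains on replicates only and tests on originals", {
  ds <- classification_samples(
    simulate_dataset(sim_config(effect_size = 2), seed = 1)
  )
  aug <- augment_dataset(ds, snr_db = 32, replicates = 3, seed = 2)
  rep2 <- evaluate_scheme(aug, scheme = 2, cfg = fast_cfg(), n_eval = 2)
  expect_equal(unique(rep2$runs$n_test), 61)        # the originals
  expect_equal(unique(rep2$runs$n_train), 61 * 3)   # the replicates
  expect_gte(rep2$mean_accuracy, 0.95)
  # repeated evaluation under the same config is deterministic
  rep2b <- evaluate_scheme(aug, scheme = 2, cfg = fast_cfg(), n_eval = 2)
  expect_equal(rep2$runs, rep2b$runs)
  expect_error(
    evaluate_scheme(augment_dataset(ds, replicates = 0), 2, fast_cfg()),
    "replicates"
  )
})

test_that("scheme 1 splits the combined pool; group split is supported", {
  ds <- classification_samples(
    simulate_dataset(sim_config(effect_size = 2), seed = 1)
  )
  aug <- augment_dataset(ds, snr_db = 32, replicates = 2, seed = 2)
  # the gamma grid must reach well below 1/n_features for 20-gene profiles
  cfg <- svm_config(m1 = 2, m2 = 4, cv_splits = 3, cv_repeats = 2, seed = 11)
  rep1 <- evaluate_scheme(aug, scheme = 1, cfg = cfg, n_eval = 2,
                          test_fraction = 0.3)
  expect_equal(unique(rep1$runs$n_train + rep1$runs$n_test), 61 * 3)
  expect_true(all(rep1$runs$n_test > 40 & rep1$runs$n_test < 70))
  expect_gte(rep1$mean_accuracy, 0.9)

  grp <- evaluate_scheme(aug, scheme = 1, cfg = cfg, n_eval = 2,
                         group_by_source = TRUE)
  expect_gte(grp$mean_accuracy, 0.9)
  # patient-level split keeps test sizes a multiple of the replicate factor
  expect_true(all(grp$runs$n_test %% 3 == 0))
})

test_that("accuracy rises with the planted effect size", {
  mean_acc <- vapply(c(0, 1, 2), function(es) {
    accs <- vapply(1:10, function(s) {
      ds <- classification_samples(simulate_dataset(
        sim_config(n_genes = 8, blocks = list(), effect_genes = 1:4,
                   effect_size = es),
        seed = 100 + s
      ))
      aug <- augment_dataset(ds, snr_db = 32, replicates = 2,
                             seed = 200 + s)
      cfg <- svm_config(m1 = 1, m2 = 4, cv_splits = 3, cv_repeats = 1,
                        seed = s)
      evaluate_scheme(aug, scheme = 1, cfg = cfg, n_eval = 1,
                      group_by_source = TRUE)$mean_accuracy
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(mean_acc) > 0))
  expect_lt(mean_acc[1], 0.8)   # null stays near chance
  expect_gt(mean_acc[3], 0.9)   # strong signal nearly separable
})

test_that("parameter landscape reports SV counts that grow as gamma shrinks", {
  # compact features put the whole gamma grid at or below the well-fit
  # kernel width, the regime where smoothing recruits support vectors
  pool <- small_pool(n_per_class = 15, sep = 2)
  pool$x <- pool$x * 0.15
  cfg <- svm_config(m1 = 1, m2 = 4, cv_splits = 3, cv_repeats = 1, seed = 3)
  land <- parameter_landscape(pool$x, pool$y, cfg)
  expect_equal(nrow(land), 3 * 9)
  expect_true(all(c("cv_accuracy", "n_support_vectors") %in% names(land)))
  # smoother kernels (small gamma) recruit at least as many SVs:
  # negative rank correlation between gamma and SV count
  rho <- stats::cor(log(land$gamma), land$n_support_vectors,
                    method = "spearman")
  expect_lte(rho, 0)
})

test_that("large C fits training data at least as well as tiny C", {
  pool <- small_pool(n_per_class = 15, sep = 1.2, seed = 9)
  acc <- function(C) {
    fit <- svm_train(pool$x, pool$y, C = C, gamma = 0.5)
    mean(predict(fit, pool$x) == pool$y)
  }
  expect_gte(acc(2^8), acc(2^-8))
})
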