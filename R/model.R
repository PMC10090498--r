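#' Fit a PCA dimension-reduction model
#'
#' Mean-centres the training matrix (training mean only; no scaling —
#' features are already on a common log scale), eigendecomposes the
#' covariance, and keeps the smallest number of leading components whose
#' cumulative explained-variance ratio reaches `variance_threshold`.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param variance_threshold Fraction of total variance to retain, in
#'   (0, 1]; default 0.90.
#' @return An object of class `pca_model`: `mean` (length-p centre),
#'   `rotation` (p x p orthonormal loadings), `explained_ratio`
#'   (non-increasing, sums to 1 over positive-variance components), `k`
#'   (retained component count) and `threshold`.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' pca_fit(x, 0.9)$k
pca_fit <- function(x, variance_threshold = 0.9) {
  stopifnot(is.matrix(x), nrow(x) >= 2,
            variance_threshold > 0, variance_threshold <= 1)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total == 0) stop("feature matrix is constant (zero variance)", call. = FALSE)
  ratio <- pc$sdev^2 / total
  k <- which(cumsum(ratio) >= variance_threshold - 1e-12)[1]
  if (variance_threshold == 1) k <- sum(pc$sdev^2 > 1e-12 * total)
  structure(
    list(mean = pc$center, rotation = pc$rotation,
         explained_ratio = ratio, k = k,
         threshold = variance_threshold),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", length(x$mean), " features -> ", x$k,
      " components (", round(100 * sum(x$explained_ratio[seq_len(x$k)]), 1),
      "% variance, threshold ", 100 * x$threshold, "%)\n", sep = "")
  invisible(x)
}

#' Project data onto a fitted PCA basis
#'
#' Applies the training centring and the retained loadings unchanged to
#' new data — no refit, so test samples never influence the basis.
#'
#' @param model A [pca_fit()] result.
#' @param x Numeric matrix, samples in rows; feature count must match the
#'   model.
#' @param k Number of components to use (default: the model's retained
#'   count).
#' @return Score matrix, `nrow(x)` x `k`.
#' @export
pca_transform <- function(model, x, k = model$k) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$mean)) {
    stop("feature count (", ncol(x), ") does not match PCA model (",
         length(model$mean), ")", call. = FALSE)
  }
  sweep(x, 2, model$mean) %*% model$rotation[, seq_len(k), drop = FALSE]
}

#' SVM / cross-validation configuration
#'
#' Bundles the classifier settings: kernel, the powers-of-two grid bounds
#' for the penalty `C` (`2^-m1 .. 2^m1`) and RBF width `gamma`
#' (`2^-m2 .. 2^m2`), the repeated stratified K-fold layout (default 6
#' splits, 6 repeats) and the PCA variance threshold.
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param m1,m2 Grid half-widths (exponents) for C and gamma.
#' @param cv_splits,cv_repeats K-fold splits and repeats.
#' @param variance_threshold PCA variance threshold, see [pca_fit()].
#' @param seed Integer seed governing fold assignment.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = c("rbf", "linear"), m1 = 8, m2 = 8,
                       cv_splits = 6, cv_repeats = 6,
                       variance_threshold = 0.9, seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot(m1 >= 0, m2 >= 0, cv_splits >= 2, cv_repeats >= 1)
  structure(
    list(kernel = kernel, m1 = m1, m2 = m2,
         cv_splits = cv_splits, cv_repeats = cv_repeats,
         variance_threshold = variance_threshold, seed = seed),
    class = "svm_config"
  )
}

grid_values <- function(m) 2^seq(-m, m)

#' Train a soft-margin SVM
#'
#' Solves the soft-margin dual (via libsvm) for the given kernel, penalty
#' and RBF width; prediction is the sign of the kernel sum over support
#' vectors. Labels are +1 (depressed) / -1 (not depressed). Features are
#' used as given (no internal rescaling).
#'
#' @param x Numeric matrix, samples in rows (e.g. PCA scores).
#' @param y Labels in `{+1, -1}` (numeric) or a 2-level factor.
#' @param kernel `"rbf"` or `"linear"`.
#' @param C Penalty parameter (> 0).
#' @param gamma RBF width (> 0; ignored for linear kernel).
#' @return An object of class `svm_fit`: the libsvm fit plus `kernel`,
#'   `C`, `gamma`, `support_vectors`, `dual_coefs` (alpha_j * y_j), `bias`
#'   and, for the linear kernel, the explicit weight vector `w` and
#'   margin `2 / ||w||`.
#' @export
svm_train <- function(x, y, kernel = c("rbf", "linear"), C = 1,
                      gamma = 1 / ncol(x)) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, gamma > 0)
  y <- as.numeric(as.character(y))
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  fit <- e1071::svm(x, factor(y, levels = c(1, -1)),
                    type = "C-classification",
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    cost = C, gamma = gamma, scale = FALSE)
  # libsvm orients the decision function toward whichever class it met
  # first; canonicalise so positive decision values mean the +1 class
  flip <- if (fit$levels[fit$labels[1]] == "1") 1 else -1
  w <- NULL
  if (kernel == "linear") w <- flip * drop(t(fit$coefs) %*% fit$SV)
  structure(
    list(fit = fit, kernel = kernel, C = C, gamma = gamma,
         support_vectors = fit$SV, dual_coefs = flip * drop(fit$coefs),
         bias = flip * -fit$rho, w = w, flip = flip,
         margin = if (!is.null(w)) 2 / sqrt(sum(w^2)) else NA_real_),
    class = "svm_fit"
  )
}

#' @export
predict.svm_fit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  as.numeric(as.character(predict(object$fit, newdata)))
}

#' Decision values of an SVM fit
#' @param object An [svm_train()] result.
#' @param newdata Score matrix.
#' @return Numeric decision-function values (prediction is their sign).
#' @export
decision_values <- function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  pred <- predict(object$fit, newdata, decision.values = TRUE)
  unname(object$flip * drop(attr(pred, "decision.values")))
}

# Stratified fold assignment; relies on the caller's RNG state
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(split(y, folds), function(v) length(unique(v)), 1L) < 2)) {
    stop("degenerate fold with a single class; reduce cv_splits", call. = FALSE)
  }
  folds
}

#' Repeated K-fold grid search over (C, gamma)
#'
#' For every pair on the powers-of-two grid, estimates accuracy by
#' stratified `cv_splits`-fold cross-validation repeated `cv_repeats`
#' times (identical folds across the grid, so pairs compete on the same
#' splits) and selects the pair with the highest mean accuracy; ties go
#' to the smallest C, then the smallest gamma.
#'
#' @param x Numeric matrix of features (samples in rows), typically PCA
#'   scores.
#' @param y Labels in `{+1, -1}`.
#' @param cfg An [svm_config].
#' @return A list of class `cv_report`: `grid` (tibble `C`, `gamma`,
#'   `mean_accuracy`), `best_C`, `best_gamma`, `cv_accuracy`,
#'   `fold_accuracies` (per fold x repeat for the best pair) and the
#'   config used.
#' @export
grid_search_cv <- function(x, y, cfg = svm_config()) {
  y <- as.numeric(as.character(y))
  stopifnot(all(y %in% c(-1, 1)), nrow(x) == length(y))

  fold_sets <- withr::with_seed(cfg$seed, {
    purrr::map(seq_len(cfg$cv_repeats),
               ~ stratified_folds(y, cfg$cv_splits))
  })

  Cs <- grid_values(cfg$m1)
  gammas <- if (cfg$kernel == "rbf") grid_values(cfg$m2) else 1
  grid <- tidyr::expand_grid(C = Cs, gamma = gammas)

  acc_matrix <- matrix(NA_real_, nrow = nrow(grid),
                       ncol = cfg$cv_repeats * cfg$cv_splits)
  col <- 0
  for (rep_i in seq_len(cfg$cv_repeats)) {
    folds <- fold_sets[[rep_i]]
    for (f in seq_len(cfg$cv_splits)) {
      col <- col + 1
      test <- folds == f
      for (g in seq_len(nrow(grid))) {
        fit <- svm_train(x[!test, , drop = FALSE], y[!test],
                         kernel = cfg$kernel,
                         C = grid$C[g], gamma = grid$gamma[g])
        pred <- predict(fit, x[test, , drop = FALSE])
        acc_matrix[g, col] <- mean(pred == y[test])
      }
    }
  }
  grid$mean_accuracy <- rowMeans(acc_matrix)

  best <- order(-grid$mean_accuracy, grid$C, grid$gamma)[1]
  out <- list(
    grid = grid,
    best_C = grid$C[best], best_gamma = grid$gamma[best],
    cv_accuracy = grid$mean_accuracy[best],
    fold_accuracies = acc_matrix[best, ],
    scheme = NULL, test_accuracy = NULL, config = cfg
  )
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", nrow(x$grid), " grid points\n", sep = "")
  cat(sprintf("  best C = %g, gamma = %g, CV accuracy = %.4f\n",
              x$best_C, x$best_gamma, x$cv_accuracy))
  if (!is.null(x$test_accuracy)) {
    cat(sprintf("  scheme %s test accuracy = %.4f\n",
                as.character(x$scheme %||% "-"), x$test_accuracy))
  }
  invisible(x)
}

#' Train the full PCA + SVM classifier
#'
#' Fits the PCA reduction on the training matrix, projects it, and trains
#' the SVM at the given (C, gamma) on the scores. Use after
#' [grid_search_cv()] has picked the parameters.
#'
#' @param x Training feature matrix (samples x hub genes).
#' @param y Labels in `{+1, -1}`.
#' @param cfg An [svm_config].
#' @param C,gamma SVM parameters (e.g. the grid-search winners).
#' @return An object of class `trained_classifier`: `pca` ([pca_fit()]
#'   model), `svm` ([svm_train()] fit), `C`, `gamma`.
#' @export
train_classifier <- function(x, y, cfg = svm_config(), C = 1,
                             gamma = 1 / ncol(x)) {
  pca <- pca_fit(x, cfg$variance_threshold)
  scores <- pca_transform(pca, x)
  svm <- svm_train(scores, y, kernel = cfg$kernel, C = C, gamma = gamma)
  structure(list(pca = pca, svm = svm, C = C, gamma = gamma),
            class = "trained_classifier")
}

#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  predict(object$svm, pca_transform(object$pca, newdata))
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("<trained_classifier> ", length(x$pca$mean), " features -> ",
      x$pca$k, " PCs; ", x$svm$kernel, " SVM (C = ", x$C,
      ", gamma = ", signif(x$gamma, 4), "), ",
      nrow(x$svm$support_vectors), " support vectors\n", sep = "")
  invisible(x)
}

feature_matrix <- function(ds) t(ds$values)

#' Evaluate the classifier under one of two cross-validation schemes
#'
#' Scheme 1 splits the combined pool (originals + replicates) randomly
#' (stratified by class) into training and testing portions. Scheme 2
#' trains on the synthetic replicates only and tests on the original
#' patients. In both schemes the PCA basis and the grid search use the
#' training portion only, then the winning (C, gamma) is refit on the
#' whole training portion and scored on the held-out test portion. The
#' evaluation repeats `n_eval` times under derived seeds and reports the
#' mean test accuracy.
#'
#' Note that the scheme-1 split is at sample level, so replicates of a
#' test patient can appear in training; `group_by_source = TRUE` gives
#' the stricter variant that keeps each patient's replicates on one side
#' of the split.
#'
#' @param aug An [augment_dataset()] result restricted to hub genes and
#'   classification samples (every sample labelled DEPRESSED or
#'   NOT_DEPRESSED).
#' @param scheme 1 or 2.
#' @param cfg An [svm_config].
#' @param test_fraction Scheme-1 test proportion.
#' @param n_eval Number of evaluation repetitions.
#' @param group_by_source Scheme-1 only: split by source patient instead
#'   of by sample.
#' @return A list of class `scheme_report`: `scheme`, `runs` (tibble with
#'   per-run `best_C`, `best_gamma`, `cv_accuracy`, `test_accuracy`,
#'   `pca_k`, `n_train`, `n_test`), `mean_accuracy`, `config`.
#' @export
evaluate_scheme <- function(aug, scheme, cfg = svm_config(),
                            test_fraction = 0.3, n_eval = 5,
                            group_by_source = FALSE) {
  stopifnot(scheme %in% c(1, 2))
  x <- feature_matrix(aug)
  y <- class_labels(aug)
  is_orig <- aug$samples$replicate == 0
  if (scheme == 2 && !any(!is_orig)) {
    stop("scheme 2 needs synthetic replicates for training", call. = FALSE)
  }

  runs <- purrr::map(seq_len(n_eval), function(run) {
    run_seed <- (cfg$seed * 1000L + run) %% .Machine$integer.max
    if (scheme == 1) {
      test <- withr::with_seed(run_seed, {
        if (group_by_source) {
          src <- unique(aug$samples$source_id)
          src_y <- y[match(src, aug$samples$sample_id)]
          test_src <- unlist(lapply(split(src, src_y), function(s) {
            sample(s, max(1, round(test_fraction * length(s))))
          }))
          aug$samples$source_id %in% test_src
        } else {
          idx <- unlist(lapply(split(seq_along(y), y), function(i) {
            sample(i, max(1, round(test_fraction * length(i))))
          }))
          seq_along(y) %in% idx
        }
      })
    } else {
      test <- is_orig
    }
    train <- !test

    run_cfg <- cfg
    run_cfg$seed <- run_seed
    pca <- pca_fit(x[train, , drop = FALSE], cfg$variance_threshold)
    train_scores <- pca_transform(pca, x[train, , drop = FALSE])
    cv <- grid_search_cv(train_scores, y[train], run_cfg)
    svm <- svm_train(train_scores, y[train], kernel = cfg$kernel,
                     C = cv$best_C, gamma = cv$best_gamma)
    pred <- predict(svm, pca_transform(pca, x[test, , drop = FALSE]))
    tibble::tibble(
      run = run, seed = run_seed,
      best_C = cv$best_C, best_gamma = cv$best_gamma,
      cv_accuracy = cv$cv_accuracy,
      test_accuracy = mean(pred == y[test]),
      pca_k = pca$k, n_train = sum(train), n_test = sum(test)
    )
  }) |>
    dplyr::bind_rows()

  structure(
    list(scheme = scheme, runs = runs,
         mean_accuracy = mean(runs$test_accuracy), config = cfg),
    class = "scheme_report"
  )
}

#' @export
print.scheme_report <- function(x, ...) {
  cat("<scheme_report> scheme ", x$scheme, ", ", nrow(x$runs),
      " runs\n", sep = "")
  cat(sprintf("  mean test accuracy = %.4f (per-run %s)\n",
              x$mean_accuracy,
              paste(sprintf("%.3f", x$runs$test_accuracy), collapse = ", ")))
  invisible(x)
}

#' Full (C, gamma) landscape: accuracy and support-vector counts
#'
#' Emits, for every grid point, the repeated-CV mean accuracy and the
#' number of support vectors of a fit on the full pool — the table behind
#' accuracy/SV-count surface plots and the check that smaller gamma
#' (smoother kernels) recruits more support vectors.
#'
#' @param x Feature matrix (samples in rows).
#' @param y Labels in `{+1, -1}`.
#' @param cfg An [svm_config].
#' @return Tibble with columns `C`, `gamma`, `cv_accuracy`,
#'   `n_support_vectors`.
#' @export
parameter_landscape <- function(x, y, cfg = svm_config()) {
  cv <- grid_search_cv(x, y, cfg)
  grid <- cv$grid
  grid$n_support_vectors <- purrr::map2_int(grid$C, grid$gamma, function(C, g) {
    nrow(svm_train(x, y, kernel = cfg$kernel, C = C, gamma = g)$support_vectors)
  })
  dplyr::rename(grid, cv_accuracy = "mean_accuracy")
}
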