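#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a KS cutoff result
#' @param x A [ks_cutoff()] object.
#' @param ... Unused.
#' @return One-row tibble with `D`, `cutoff`, `p_value`, `D_critical`,
#'   `alpha`.
#' @export
tidy.ks_cutoff <- function(x, ...) {
  tibble::tibble(D = x$D, cutoff = x$cutoff, p_value = x$p_value,
                 D_critical = x$D_critical, alpha = x$alpha)
}

#' @rdname tidy.ks_cutoff
#' @export
glance.ks_cutoff <- function(x, ...) {
  dplyr::mutate(tidy(x), n_healthy = x$n_healthy, n_disease = x$n_disease,
                significant = x$D > x$D_critical)
}

#' Tidy a link classification
#' @param x A [classify_links()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-pair tibble. `glance()`: one row of region
#'   counts plus the cutoff.
#' @export
tidy.link_classification <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @rdname tidy.link_classification
#' @export
glance.link_classification <- function(x, ...) {
  counts <- link_counts(x)
  tibble::tibble(
    cutoff = attr(x, "cutoff"),
    n_disrupted = counts[["DISRUPTED"]],
    n_invoked = counts[["INVOKED"]],
    n_common_strong = counts[["COMMON_STRONG"]],
    n_common_weak = counts[["COMMON_WEAK"]],
    n_pairs = nrow(x)
  )
}

#' Tidy a PCA model
#' @param x A [pca_fit()] result.
#' @param ... Unused.
#' @return `tidy()`: per-component tibble (`component`,
#'   `explained_ratio`, `cumulative`, `retained`). `glance()`: one row
#'   with `k`, `threshold`, `cumulative_at_k`.
#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_ratio),
    explained_ratio = x$explained_ratio,
    cumulative = cumsum(x$explained_ratio),
    retained = seq_along(x$explained_ratio) <= x$k
  )
}

#' @rdname tidy.pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(k = x$k, threshold = x$threshold,
                 cumulative_at_k = sum(x$explained_ratio[seq_len(x$k)]),
                 n_features = length(x$mean))
}

#' Tidy a cross-validation report
#' @param x A [grid_search_cv()] result.
#' @param ... Unused.
#' @return `tidy()`: the (C, gamma, mean_accuracy) grid. `glance()`: one
#'   row with the winning pair and its accuracy.
#' @export
tidy.cv_report <- function(x, ...) x$grid

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(best_C = x$best_C, best_gamma = x$best_gamma,
                 cv_accuracy = x$cv_accuracy,
                 n_grid = nrow(x$grid),
                 test_accuracy = x$test_accuracy %||% NA_real_)
}

#' Tidy a scheme evaluation report
#' @param x An [evaluate_scheme()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-run tibble. `glance()`: one row with the
#'   scheme and mean accuracy.
#' @export
tidy.scheme_report <- function(x, ...) x$runs

#' @rdname tidy.scheme_report
#' @export
glance.scheme_report <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n_runs = nrow(x$runs),
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = stats::sd(x$runs$test_accuracy),
                 mean_pca_k = mean(x$runs$pca_k))
}

#' Tidy a trained classifier
#' @param x A [train_classifier()] result.
#' @param ... Unused.
#' @return One row: kernel, C, gamma, support-vector count, PCA k.
#' @export
glance.trained_classifier <- function(x, ...) {
  tibble::tibble(kernel = x$svm$kernel, C = x$C, gamma = x$gamma,
                 n_support_vectors = nrow(x$svm$support_vectors),
                 pca_k = x$pca$k)
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attr(x, "cutoff") <- NULL
  attr(x, "counts") <- NULL
  x
}
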