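#' Expression dataset with group and depression labels
#'
#' The central container of the pipeline: a genes-by-samples matrix of
#' log-scale expression values (already normalized, e.g. by RMA) together
#' with a per-sample annotation table. Each sample belongs to one of two
#' groups, `"HEALTHY"` or `"FMS"` (fibromyalgia syndrome), and FMS samples
#' may additionally carry a binary major-depression label; healthy samples
#' are always `"UNKNOWN"` for depression.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as gene and sample identifiers; if absent they
#'   are generated.
#' @param group Character vector of per-sample groups, values in
#'   `c("HEALTHY", "FMS")`, recycled names not allowed; length must equal
#'   `ncol(values)`.
#' @param depression Optional character vector of per-sample depression
#'   labels in `c("DEPRESSED", "NOT_DEPRESSED", "UNKNOWN")`. Defaults to
#'   `"UNKNOWN"` for every sample. Healthy samples must be `"UNKNOWN"`.
#'
#' @return An object of class `expr_dataset`: a list with elements
#'   `values` (the matrix) and `samples` (a tibble with columns
#'   `sample_id`, `group`, `depression`).
#' @export
#' @examples
#' m <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' ds <- expr_dataset(m, group = c("HEALTHY", "HEALTHY", "FMS", "FMS"),
#'                    depression = c("UNKNOWN", "UNKNOWN",
#'                                   "DEPRESSED", "NOT_DEPRESSED"))
#' ds
expr_dataset <- function(values, group, depression = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("gene_%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("sample_%03d", seq_len(ncol(values)))
  }
  if (is.null(depression)) depression <- rep("UNKNOWN", ncol(values))
  samples <- tibble::tibble(
    sample_id  = colnames(values),
    group      = as.character(group),
    depression = as.character(depression)
  )
  validate_expr_dataset(new_expr_dataset(values, samples))
}

new_expr_dataset <- function(values, samples, ..., class = character()) {
  structure(
    list(values = values, samples = samples, ...),
    class = c(class, "expr_dataset")
  )
}

validate_expr_dataset <- function(ds) {
  values <- ds$values
  samples <- ds$samples
  if (anyNA(values)) stop("expression matrix contains missing values", call. = FALSE)
  if (anyDuplicated(rownames(values))) {
    stop("duplicated gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample identifiers", call. = FALSE)
  }
  if (nrow(samples) != ncol(values)) {
    stop("sample annotation rows (", nrow(samples),
         ") do not match expression columns (", ncol(values), ")", call. = FALSE)
  }
  bad_group <- setdiff(unique(samples$group), c("HEALTHY", "FMS"))
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "), call. = FALSE)
  }
  bad_dep <- setdiff(unique(samples$depression),
                     c("DEPRESSED", "NOT_DEPRESSED", "UNKNOWN"))
  if (length(bad_dep)) {
    stop("unknown depression label(s): ", paste(bad_dep, collapse = ", "), call. = FALSE)
  }
  if (any(samples$group == "HEALTHY" & samples$depression != "UNKNOWN")) {
    stop("healthy samples must have depression = \"UNKNOWN\"", call. = FALSE)
  }
  ds
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  tab <- table(x$samples$group)
  cat("  groups:     ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  dep <- table(x$samples$depression[x$samples$group == "FMS"])
  if (length(dep)) {
    cat("  FMS depression labels:",
        paste(names(dep), dep, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Gene identifiers of a dataset
#' @param ds An [expr_dataset].
#' @return Character vector of gene identifiers (row order).
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' Sample identifiers of a dataset
#' @param ds An [expr_dataset].
#' @return Character vector of sample identifiers (column order).
#' @export
sample_ids <- function(ds) ds$samples$sample_id

#' Subset a dataset by genes and/or samples
#'
#' @param ds An [expr_dataset].
#' @param genes Character vector of gene ids to keep (in the given order),
#'   or `NULL` to keep all.
#' @param samples Character vector of sample ids to keep, or `NULL`.
#' @return An [expr_dataset] restricted to the requested rows/columns.
#' @export
subset_dataset <- function(ds, genes = NULL, samples = NULL) {
  values <- ds$values
  ann <- ds$samples
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(values))
    if (length(missing)) {
      stop("genes not present in dataset: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    values <- values[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, ann$sample_id)
    if (length(missing)) {
      stop("samples not present in dataset: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    values <- values[, samples, drop = FALSE]
    ann <- ann[match(samples, ann$sample_id), , drop = FALSE]
  }
  out <- ds
  out$values <- values
  out$samples <- ann
  validate_expr_dataset(out)
}

#' Samples usable for depression classification
#'
#' FMS samples with a known depression label; the classification stages of
#' the pipeline operate on these only (FMS samples lacking an annotation
#' are excluded).
#'
#' @param ds An [expr_dataset].
#' @return An [expr_dataset] containing only FMS samples labelled
#'   `DEPRESSED` or `NOT_DEPRESSED`.
#' @export
classification_samples <- function(ds) {
  keep <- ds$samples$group == "FMS" &
    ds$samples$depression %in% c("DEPRESSED", "NOT_DEPRESSED")
  if (!any(keep)) stop("no FMS samples with a depression label", call. = FALSE)
  subset_dataset(ds, samples = ds$samples$sample_id[keep])
}

#' Numeric class labels for the classifier
#'
#' Maps depression annotations to the +1/-1 coding used by the SVM:
#' `DEPRESSED` is +1, `NOT_DEPRESSED` is -1.
#'
#' @param ds An [expr_dataset] of classification samples.
#' @return Named numeric vector of +1/-1 labels, one per sample.
#' @export
class_labels <- function(ds) {
  dep <- ds$samples$depression
  if (any(!dep %in% c("DEPRESSED", "NOT_DEPRESSED"))) {
    stop("all samples must carry a DEPRESSED/NOT_DEPRESSED label; ",
         "see classification_samples()", call. = FALSE)
  }
  stats::setNames(ifelse(dep == "DEPRESSED", 1, -1), ds$samples$sample_id)
}
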