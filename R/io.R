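#' Read a GEO series-matrix file (or equivalent TSV) into a dataset
#'
#' Parses the series-matrix text format: metadata lines begin with `!`,
#' the numeric block sits between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`, and the first line of the block is a header
#' of sample identifiers. A plain tab-delimited table (genes in rows,
#' header of sample ids, no `!` lines) is accepted too.
#'
#' Group and depression labels are recovered from
#' `!Sample_characteristics_ch1` lines of the form `key: value`. The cell
#' whose key matches `group_key` assigns the group: a value containing
#' "fibromyalgia" (or "fms") maps to `FMS`, one containing "healthy" or
#' "control" maps to `HEALTHY`. The cell whose key matches
#' `depression_key` assigns the depression label: yes/true/1 maps to
#' `DEPRESSED`, no/false/0 to `NOT_DEPRESSED`. Samples whose phenotype
#' cannot be parsed are labelled `UNKNOWN` with a warning; which FMS
#' samples carry a usable depression annotation is therefore decided by
#' the file, not guessed.
#'
#' @param path Path to the series-matrix or TSV file.
#' @param labels Optional path to a label sidecar TSV with columns
#'   `sample_id`, `group` and (optionally) `depression`; overrides any
#'   labels parsed from the file. Required for plain TSV input unless all
#'   samples should default to `HEALTHY`/`UNKNOWN`.
#' @param group_key,depression_key Case-insensitive regular expressions
#'   matched against the characteristic keys (defaults `"diagnosis"` and
#'   `"major depression"`).
#' @return An [expr_dataset].
#' @export
read_series_matrix <- function(path, labels = NULL,
                               group_key = "diagnosis",
                               depression_key = "major depression") {
  lines <- readLines(path, warn = FALSE)
  meta <- grepl("^!", lines)
  begin <- which(lines == "!series_matrix_table_begin")
  end <- which(lines == "!series_matrix_table_end")

  if (length(begin) == 1 && length(end) == 1) {
    data_lines <- lines[(begin + 1):(end - 1)]
    data_offset <- begin  # line number of the header inside the file
    char_lines <- lines[meta][grepl("^!Sample_characteristics",
                                    lines[meta])]
    acc_line <- grep("^!Sample_geo_accession", lines, value = TRUE)
  } else if (length(begin) + length(end) > 0) {
    stop("malformed series matrix: unmatched table begin/end markers",
         call. = FALSE)
  } else {
    data_lines <- lines[!meta & nzchar(lines)]
    data_offset <- 0L
    char_lines <- character()
    acc_line <- character()
  }

  if (length(data_lines) < 2) {
    stop("no data rows found in ", path, call. = FALSE)
  }
  header <- strip_quotes(strsplit(data_lines[1], "\t", fixed = TRUE)[[1]])
  if (length(header) < 2) {
    stop("malformed header at line ", data_offset + 1,
         ": fewer than two columns", call. = FALSE)
  }
  sample_names <- header[-1]
  if (anyDuplicated(sample_names)) {
    stop("duplicated sample IDs in header at line ", data_offset + 1, ": ",
         paste(unique(sample_names[duplicated(sample_names)]), collapse = ", "),
         call. = FALSE)
  }

  body <- strsplit(data_lines[-1], "\t", fixed = TRUE)
  n_col <- length(header)
  values <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1)
  row_ids <- character(length(body))
  for (i in seq_along(body)) {
    cells <- strip_quotes(body[[i]])
    line_no <- data_offset + 1 + i
    if (length(cells) != n_col) {
      stop("line ", line_no, ": expected ", n_col, " columns, found ",
           length(cells), call. = FALSE)
    }
    row_ids[i] <- cells[1]
    num <- suppressWarnings(as.numeric(cells[-1]))
    if (anyNA(num)) {
      stop("line ", line_no, ": non-numeric expression value", call. = FALSE)
    }
    values[i, ] <- num
  }
  rownames(values) <- row_ids
  colnames(values) <- sample_names

  group <- rep("HEALTHY", length(sample_names))
  depression <- rep("UNKNOWN", length(sample_names))

  if (length(char_lines)) {
    parsed <- parse_characteristics(char_lines, length(sample_names),
                                    group_key, depression_key)
    group <- parsed$group
    depression <- parsed$depression
    if (any(parsed$unparsed)) {
      warning(sum(parsed$unparsed),
              " sample(s) had no parsable group phenotype; labelled UNKNOWN/HEALTHY",
              call. = FALSE)
    }
  }

  if (!is.null(labels)) {
    side <- utils::read.delim(labels, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% names(side))) {
      stop("label sidecar must have columns sample_id and group", call. = FALSE)
    }
    idx <- match(sample_names, side$sample_id)
    if (anyNA(idx)) {
      stop("label sidecar is missing samples: ",
           paste(sample_names[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    group <- side$group[idx]
    depression <- if ("depression" %in% names(side)) {
      side$depression[idx]
    } else rep("UNKNOWN", length(sample_names))
  }
  depression[group == "HEALTHY"] <- "UNKNOWN"
  expr_dataset(values, group = group, depression = depression)
}

strip_quotes <- function(x) gsub('^"|"$', "", x)

parse_characteristics <- function(char_lines, n_samples,
                                  group_key, depression_key) {
  group <- rep(NA_character_, n_samples)
  depression <- rep("UNKNOWN", n_samples)
  for (line in char_lines) {
    cells <- strip_quotes(strsplit(line, "\t", fixed = TRUE)[[1]])[-1]
    if (length(cells) != n_samples) next
    key <- trimws(sub(":.*$", "", cells))
    val <- trimws(sub("^[^:]*:", "", cells))
    is_group <- grepl(group_key, key, ignore.case = TRUE)
    group[is_group & grepl("fibromyalgia|fms", val, ignore.case = TRUE)] <- "FMS"
    group[is_group & grepl("healthy|control", val, ignore.case = TRUE)] <- "HEALTHY"
    is_dep <- grepl(depression_key, key, ignore.case = TRUE)
    depression[is_dep & grepl("^(yes|true|1)$", val, ignore.case = TRUE)] <- "DEPRESSED"
    depression[is_dep & grepl("^(no|false|0)$", val, ignore.case = TRUE)] <- "NOT_DEPRESSED"
  }
  unparsed <- is.na(group)
  group[unparsed] <- "HEALTHY"
  depression[group == "HEALTHY"] <- "UNKNOWN"
  list(group = group, depression = depression, unparsed = unparsed)
}

#' Read a gene panel file
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#' Symbols are uppercased (matching is symbol-identical, no alias
#' resolution).
#'
#' @param path Path to the panel file.
#' @return Character vector of unique, uppercased gene symbols.
#' @export
read_gene_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  panel <- toupper(lines[nzchar(lines)])
  if (!length(panel)) stop("panel file contains no gene symbols", call. = FALSE)
  unique(panel)
}

#' Collapse probe-level rows to a gene panel
#'
#' Restricts a dataset to the genes of a panel, collapsing multiple probes
#' per gene. The default rule keeps, for each gene, the probe with the
#' largest mean expression across samples; `method = "mean"` averages the
#' probes instead. Row order follows the panel order. Panel genes missing
#' from the data are recorded in the `missing_genes` attribute of the
#' result (and messaged), never silently dropped.
#'
#' @param ds An [expr_dataset] whose rows are probes (or genes).
#' @param panel Character vector of gene symbols (see [read_gene_panel()]).
#' @param mapping Optional data frame with columns `probe` and `gene`
#'   mapping row ids of `ds` to symbols. If `NULL`, row ids are taken to be
#'   gene symbols already.
#' @param method Collapse rule, `"max_mean"` (default) or `"mean"`.
#' @return An [expr_dataset] with one row per panel gene present, attribute
#'   `missing_genes` listing absent panel genes.
#' @export
collapse_to_panel <- function(ds, panel, mapping = NULL,
                              method = c("max_mean", "mean")) {
  method <- match.arg(method)
  panel <- toupper(panel)
  if (is.null(mapping)) {
    mapping <- data.frame(probe = rownames(ds$values),
                          gene = toupper(rownames(ds$values)))
  }
  mapping$gene <- toupper(mapping$gene)
  mapping <- mapping[mapping$gene %in% panel &
                       mapping$probe %in% rownames(ds$values), , drop = FALSE]
  if (!nrow(mapping)) {
    stop("no overlap between panel, mapping and dataset rows", call. = FALSE)
  }

  collapsed <- mapping |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_map(function(rows, key) {
      block <- ds$values[rows$probe, , drop = FALSE]
      row <- switch(method,
        max_mean = block[which.max(rowMeans(block)), ],
        mean = colMeans(block)
      )
      tibble::tibble(gene = key$gene, profile = list(row))
    }) |>
    dplyr::bind_rows()

  present <- panel[panel %in% collapsed$gene]
  missing <- setdiff(panel, present)
  values <- do.call(rbind, collapsed$profile[match(present, collapsed$gene)])
  rownames(values) <- present
  colnames(values) <- colnames(ds$values)

  if (length(missing)) {
    message(length(missing), " panel gene(s) absent from data: ",
            paste(missing, collapse = ", "))
  }
  out <- ds
  out$values <- values
  out <- validate_expr_dataset(out)
  attr(out, "missing_genes") <- missing
  out
}

#' Write / read an expression dataset as plain TSV
#'
#' The expression matrix is written genes-in-rows with a `gene_id` first
#' column, and the sample annotations to a `<path>.labels.tsv` sidecar.
#' Values survive the round trip exactly (15 significant digits).
#'
#' @param ds An [expr_dataset].
#' @param path Output TSV path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns an [expr_dataset].
#' @export
write_expression_tsv <- function(ds, path) {
  df <- data.frame(gene_id = rownames(ds$values), ds$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(ds$samples), paste0(path, ".labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  side <- utils::read.delim(paste0(path, ".labels.tsv"),
                            stringsAsFactors = FALSE)
  idx <- match(colnames(values), side$sample_id)
  if (anyNA(idx)) stop("label sidecar does not cover all samples", call. = FALSE)
  expr_dataset(values, group = side$group[idx],
               depression = side$depression[idx])
}

#' Write / read a link classification as an edge-list TSV
#'
#' Columns: `gene_a`, `gene_b`, `abs_r_healthy`, `abs_r_disease`, `region`,
#' `cutoff`. One header line plus one row per gene pair.
#'
#' @param links A [classify_links()] result.
#' @param path Output TSV path.
#' @return `write_links()` returns `path` invisibly; `read_links()` the
#'   restored link table.
#' @export
write_links <- function(links, path) {
  df <- as.data.frame(links)
  df$cutoff <- attr(links, "cutoff")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_links
#' @export
read_links <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cutoff <- df$cutoff[1]
  df$cutoff <- NULL
  out <- tibble::as_tibble(df)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("link_classification", class(out))
  out
}

#' Write / read a hub ranking TSV
#'
#' Columns: `gene`, `rsum_disrupted`, `rsum_invoked`, `selected`,
#' `hub_class`.
#'
#' @param ranking A [rsum_scores()] / [select_hubs()] result.
#' @param path Output TSV path.
#' @return `write_hub_ranking()` returns `path` invisibly;
#'   `read_hub_ranking()` the restored ranking.
#' @export
write_hub_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hub_ranking
#' @export
read_hub_ranking <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("hub_class" %in% names(df)) df$hub_class[is.na(df$hub_class)] <- ""
  out <- tibble::as_tibble(df)
  class(out) <- c("hub_ranking", class(out))
  out
}

#' Write / read a cross-validation report as structured text
#'
#' Key/value lines (`scheme`, `best_C`, `best_gamma`, `test_accuracy`,
#' `fold_accuracies`) followed by a `[grid]` section with the full
#' C-by-gamma mean-accuracy table.
#'
#' @param report A [grid_search_cv()] or [evaluate_scheme()] result.
#' @param path Output path.
#' @return `write_cv_report()` returns `path` invisibly;
#'   `read_cv_report()` the restored report.
#' @export
write_cv_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  kv <- function(key, value) {
    writeLines(paste(key, paste(format(value, digits = 15), collapse = ","),
                     sep = "\t"), con)
  }
  kv("scheme", report$scheme %||% NA)
  kv("best_C", report$best_C)
  kv("best_gamma", report$best_gamma)
  kv("cv_accuracy", report$cv_accuracy)
  if (!is.null(report$test_accuracy)) kv("test_accuracy", report$test_accuracy)
  kv("fold_accuracies", report$fold_accuracies)
  writeLines("[grid]", con)
  utils::write.table(as.data.frame(report$grid), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cv_report
#' @export
read_cv_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grid_at <- match("[grid]", lines)
  head_lines <- strsplit(lines[seq_len(grid_at - 1)], "\t", fixed = TRUE)
  kv <- stats::setNames(
    lapply(head_lines, function(x) {
      vals <- strsplit(x[2], ",")[[1]]
      vals[vals == "NA"] <- NA
      as.numeric(vals)
    }),
    vapply(head_lines, `[`, "", 1)
  )
  grid <- utils::read.delim(text = lines[(grid_at + 1):length(lines)],
                            stringsAsFactors = FALSE)
  out <- list(
    scheme = if (!is.na(kv$scheme[1])) kv$scheme[1] else NULL,
    best_C = kv$best_C[1], best_gamma = kv$best_gamma[1],
    cv_accuracy = kv$cv_accuracy[1],
    test_accuracy = if (!is.null(kv$test_accuracy)) kv$test_accuracy[1] else NULL,
    fold_accuracies = kv$fold_accuracies,
    grid = tibble::as_tibble(grid)
  )
  class(out) <- "cv_report"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
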