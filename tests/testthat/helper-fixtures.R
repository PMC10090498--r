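# Shared fixtures, all generated in code.

# Tiny deterministic dataset: 4 genes, 8 samples, both groups labelled.
tiny_dataset <- function() {
  set.seed(42)
  m <- matrix(rnorm(4 * 8, mean = 8), nrow = 4,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:8)))
  expr_dataset(
    m,
    group = rep(c("HEALTHY", "FMS"), each = 4),
    depression = c(rep("UNKNOWN", 4),
                   "DEPRESSED", "DEPRESSED", "NOT_DEPRESSED", "NOT_DEPRESSED")
  )
}

# Hand-built correlation table for the 3-gene toy used in the region tests.
toy_correlation_table <- function() {
  out <- tibble::tibble(
    gene_a = c("GA", "GA", "GB"),
    gene_b = c("GB", "GC", "GC"),
    r_healthy = c(0.9, 0.1, 0.5),
    r_disease = c(0.2, 0.8, 0.6)
  )
  class(out) <- c("correlation_table", class(out))
  out
}

# A synthetic GEO-style series-matrix file (written fresh each call).
# Clearly synthetic: small made-up expression block with the phenotype
# line layout of the real format.
write_synthetic_series_matrix <- function(path, n_fms_dep = 2,
                                          n_fms_nodep = 2, n_fms_na = 1,
                                          n_healthy = 3) {
  n <- n_fms_dep + n_fms_nodep + n_fms_na + n_healthy
  ids <- sprintf("GSM%03d", seq_len(n))
  diagnosis <- c(rep("fibromyalgia", n_fms_dep + n_fms_nodep + n_fms_na),
                 rep("healthy control", n_healthy))
  dep <- c(rep("Yes", n_fms_dep), rep("No", n_fms_nodep),
           rep("-", n_fms_na), rep("-", n_healthy))
  set.seed(7)
  expr <- matrix(round(rnorm(5 * n, mean = 8, sd = 1), 4), nrow = 5)
  q <- function(x) paste0('"', x, '"')
  lines <- c(
    '!Series_title\t"synthetic fixture"',
    paste(c('!Sample_geo_accession', q(ids)), collapse = "\t"),
    paste(c('!Sample_characteristics_ch1',
            q(paste0("diagnosis: ", diagnosis))), collapse = "\t"),
    paste(c('!Sample_characteristics_ch1',
            q(paste0("major depression: ", dep))), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c('"ID_REF"', q(ids)), collapse = "\t"),
    vapply(1:5, function(i) {
      paste(c(q(paste0("probe_", i)), format(expr[i, ])), collapse = "\t")
    }, ""),
    "!series_matrix_table_end"
  )
  writeLines(lines, path)
  invisible(path)
}

# Independent KS oracle: brute-force double loop over all observed values.
brute_force_ks <- function(x, y) {
  candidates <- sort(unique(c(x, y)))
  best_D <- -1
  best_at <- NA_real_
  for (v in candidates) {
    d <- abs(mean(x <= v) - mean(y <= v))
    if (d > best_D + 1e-12) {
      best_D <- d
      best_at <- v
    }
  }
  list(D = best_D, cutoff = best_at)
}

# Small augmented classification pool for the SVM/CV tests.
small_pool <- function(n_per_class = 12, d = 4, sep = 3, seed = 5, sd = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per_class * d, sd = sd), ncol = d),
    matrix(rnorm(n_per_class * d, mean = sep / sqrt(d), sd = sd), ncol = d)
  )
  y <- rep(c(-1, 1), each = n_per_class)
  list(x = x, y = y)
}

fast_cfg <- function(...) {
  svm_config(m1 = 2, m2 = 2, cv_splits = 3, cv_repeats = 2, seed = 11, ...)
}
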