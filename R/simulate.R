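#' Simulation configuration for two-group expression data
#'
#' Describes a synthetic expression study with planted co-expression
#' structure: samples are drawn from a multivariate normal whose
#' correlation matrix is the identity except inside compound-symmetry
#' blocks. A block active only in one group creates, downstream, the
#' group-specific strong links the co-expression analysis is designed to
#' detect (healthy-only blocks yield disrupted links, FMS-only blocks
#' yield invoked links). A mean shift on `effect_genes` gives depressed
#' FMS samples a class signal of tunable strength.
#'
#' Defaults mirror the study conditions of the motivating cohort: 70
#' healthy controls, 61 FMS patients of whom 25/61 are depressed, and a
#' 20-gene panel (the hub-feature dimension).
#'
#' @param n_genes Number of genes in the panel.
#' @param n_healthy,n_fms Samples per group.
#' @param blocks List of blocks, each `list(genes =, rho =, group =)`:
#'   `genes` an integer index set, `rho` the within-block correlation in
#'   (0, 1), `group` one of `"HEALTHY_ONLY"`, `"FMS_ONLY"`, `"BOTH"`.
#'   Blocks must be pairwise disjoint; compound symmetry with rho in
#'   (0, 1) keeps every generated matrix positive semidefinite.
#' @param baseline_sd Marginal standard deviation of every gene.
#' @param baseline_mean Marginal mean (log-scale expression level).
#' @param depression_fraction Fraction of FMS samples labelled DEPRESSED.
#' @param effect_genes Integer indices of genes receiving the depression
#'   mean shift; defaults to genes 6-15 (the invoked block and its
#'   neighbours), clipped to the panel.
#' @param effect_size Mean shift for depressed samples, in units of
#'   `baseline_sd` (0 = no class signal).
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(effect_size = 2)
#' ds <- simulate_dataset(cfg, seed = 1)
#' ds
sim_config <- function(n_genes = 20,
                       n_healthy = 70,
                       n_fms = 61,
                       blocks = list(
                         list(genes = 1:5, rho = 0.8, group = "HEALTHY_ONLY"),
                         list(genes = 6:10, rho = 0.8, group = "FMS_ONLY")
                       ),
                       baseline_sd = 1,
                       baseline_mean = 8,
                       depression_fraction = 25 / 61,
                       effect_genes = NULL,
                       effect_size = 0) {
  stopifnot(n_genes >= 1, n_healthy >= 1, n_fms >= 1,
            baseline_sd > 0, is.numeric(effect_size))
  if (depression_fraction <= 0 || depression_fraction >= 1) {
    stop("`depression_fraction` must lie in (0, 1)", call. = FALSE)
  }
  seen <- integer()
  for (b in blocks) {
    if (!all(c("genes", "rho", "group") %in% names(b))) {
      stop("each block needs fields genes, rho, group", call. = FALSE)
    }
    if (b$rho <= 0 || b$rho >= 1) {
      stop("block rho must lie in (0, 1)", call. = FALSE)
    }
    if (!b$group %in% c("HEALTHY_ONLY", "FMS_ONLY", "BOTH")) {
      stop("block group must be HEALTHY_ONLY, FMS_ONLY or BOTH", call. = FALSE)
    }
    if (any(b$genes < 1 | b$genes > n_genes)) {
      stop("block gene indices outside 1..n_genes", call. = FALSE)
    }
    if (length(intersect(seen, b$genes))) {
      stop("blocks must be pairwise disjoint", call. = FALSE)
    }
    seen <- c(seen, b$genes)
  }
  if (is.null(effect_genes)) {
    effect_genes <- intersect(6:15, seq_len(n_genes))
  }
  if (length(effect_genes) &&
      any(effect_genes < 1 | effect_genes > n_genes)) {
    stop("effect_genes outside 1..n_genes", call. = FALSE)
  }
  structure(
    list(n_genes = n_genes, n_healthy = n_healthy, n_fms = n_fms,
         blocks = blocks, baseline_sd = baseline_sd,
         baseline_mean = baseline_mean,
         depression_fraction = depression_fraction,
         effect_genes = effect_genes, effect_size = effect_size),
    class = "sim_config"
  )
}

#' Group-specific correlation matrix of a simulation config
#'
#' Identity everywhere except inside blocks active in the requested group,
#' where off-diagonal entries equal the block's target correlation.
#' Compound-symmetry blocks with rho in (0, 1) are positive semidefinite
#' by construction.
#'
#' @param cfg A [sim_config].
#' @param group `"HEALTHY"` or `"FMS"`.
#' @return An `n_genes` x `n_genes` correlation matrix.
#' @export
build_group_correlation <- function(cfg, group = c("HEALTHY", "FMS")) {
  group <- match.arg(group)
  R <- diag(cfg$n_genes)
  active <- switch(group,
    HEALTHY = c("HEALTHY_ONLY", "BOTH"),
    FMS = c("FMS_ONLY", "BOTH")
  )
  for (b in cfg$blocks) {
    if (b$group %in% active) {
      R[b$genes, b$genes] <- b$rho
      diag(R)[b$genes] <- 1
    }
  }
  R
}

#' Simulate a two-group expression dataset
#'
#' Draws each group from a multivariate normal with the group's planted
#' correlation matrix scaled by `baseline_sd^2`. Within the FMS group,
#' `round(depression_fraction * n_fms)` samples are labelled DEPRESSED and
#' receive a `+effect_size * baseline_sd` mean shift on `effect_genes`;
#' the rest are NOT_DEPRESSED. Healthy samples are UNKNOWN. Fully
#' reproducible from `seed`.
#'
#' @param cfg A [sim_config].
#' @param seed Integer seed.
#' @return An [expr_dataset].
#' @export
simulate_dataset <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(seed, {
    Sigma_h <- cfg$baseline_sd^2 * build_group_correlation(cfg, "HEALTHY")
    Sigma_f <- cfg$baseline_sd^2 * build_group_correlation(cfg, "FMS")
    mu <- rep(cfg$baseline_mean, cfg$n_genes)
    healthy <- MASS::mvrnorm(cfg$n_healthy, mu = mu, Sigma = Sigma_h)
    fms <- MASS::mvrnorm(cfg$n_fms, mu = mu, Sigma = Sigma_f)
    if (cfg$n_healthy == 1) healthy <- matrix(healthy, nrow = 1)
    if (cfg$n_fms == 1) fms <- matrix(fms, nrow = 1)

    n_dep <- round(cfg$depression_fraction * cfg$n_fms)
    depressed <- seq_len(cfg$n_fms) <= n_dep
    fms[depressed, cfg$effect_genes] <-
      fms[depressed, cfg$effect_genes] + cfg$effect_size * cfg$baseline_sd

    values <- t(rbind(healthy, fms))
    rownames(values) <- sprintf("GENE%02d", seq_len(cfg$n_genes))
    colnames(values) <- c(sprintf("H%03d", seq_len(cfg$n_healthy)),
                          sprintf("F%03d", seq_len(cfg$n_fms)))
    expr_dataset(
      values,
      group = c(rep("HEALTHY", cfg$n_healthy), rep("FMS", cfg$n_fms)),
      depression = c(rep("UNKNOWN", cfg$n_healthy),
                     ifelse(depressed, "DEPRESSED", "NOT_DEPRESSED"))
    )
  })
}

#' Ground-truth link set of a simulation config
#'
#' The gene pairs whose planted correlation structure makes them disrupted
#' (inside a HEALTHY_ONLY block) or invoked (inside an FMS_ONLY block).
#'
#' @param cfg A [sim_config].
#' @return Tibble with columns `gene_a`, `gene_b`, `truth`
#'   (`DISRUPTED`/`INVOKED`).
#' @export
true_links <- function(cfg) {
  ids <- sprintf("GENE%02d", seq_len(cfg$n_genes))
  rows <- purrr::map(cfg$blocks, function(b) {
    if (b$group == "BOTH" || length(b$genes) < 2) return(NULL)
    pairs <- t(utils::combn(sort(b$genes), 2))
    tibble::tibble(
      gene_a = ids[pairs[, 1]], gene_b = ids[pairs[, 2]],
      truth = if (b$group == "HEALTHY_ONLY") "DISRUPTED" else "INVOKED"
    )
  })
  dplyr::bind_rows(rows)
}

#' Standard fixture configurations
#'
#' Four named configurations exercised throughout the test-suite and the
#' acceptance checks: `null` (no blocks, no class signal),
#' `disrupted_only`, `invoked_only`, and `mixed` (both block types plus a
#' 2-SD depression shift).
#'
#' @param n_healthy,n_fms Samples per group (defaults mirror the cohort).
#' @return Named list of [sim_config] objects.
#' @export
fixture_configs <- function(n_healthy = 70, n_fms = 61) {
  list(
    null = sim_config(n_healthy = n_healthy, n_fms = n_fms,
                      blocks = list(), effect_size = 0),
    disrupted_only = sim_config(
      n_healthy = n_healthy, n_fms = n_fms,
      blocks = list(list(genes = 1:5, rho = 0.8, group = "HEALTHY_ONLY")),
      effect_size = 0
    ),
    invoked_only = sim_config(
      n_healthy = n_healthy, n_fms = n_fms,
      blocks = list(list(genes = 6:10, rho = 0.8, group = "FMS_ONLY")),
      effect_size = 0
    ),
    mixed = sim_config(n_healthy = n_healthy, n_fms = n_fms,
                       effect_size = 2)
  )
}

#' Write a deterministic fixture family to disk
#'
#' Generates the four [fixture_configs()] datasets under one seed and
#' writes each as a TSV (with label sidecar) plus a `manifest.tsv` listing
#' the ground-truth disrupted/invoked pairs and per-fixture label counts.
#' Two runs with the same seed produce byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named list of the written dataset paths.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfgs <- fixture_configs()
  paths <- list()
  manifest <- list()
  for (name in names(cfgs)) {
    ds <- simulate_dataset(cfgs[[name]], seed = seed)
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_expression_tsv(ds, path)
    paths[[name]] <- path
    truth <- true_links(cfgs[[name]])
    n_dep <- sum(ds$samples$depression == "DEPRESSED")
    n_not <- sum(ds$samples$depression == "NOT_DEPRESSED")
    manifest[[name]] <- dplyr::bind_rows(
      if (nrow(truth)) dplyr::mutate(truth, fixture = name,
                                     .before = 1) else NULL,
      tibble::tibble(fixture = name, gene_a = "", gene_b = "",
                     truth = sprintf("LABELS:%d_DEPRESSED/%d_NOT", n_dep, n_not))
    )
  }
  utils::write.table(as.data.frame(dplyr::bind_rows(manifest)),
                     file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
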