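#' Per-group pairwise Pearson correlations
#'
#' Computes, for every unordered gene pair of the panel, the Pearson
#' correlation within the healthy samples and (independently) within the
#' FMS samples. These two |r| populations are the raw material of the
#' differential co-expression analysis: their cumulative distributions are
#' compared to locate the disease-specific cutoff.
#'
#' @param ds An [expr_dataset] with both groups present.
#' @param genes Optional character vector restricting/ordering the panel;
#'   defaults to all genes of `ds`.
#' @param fms_samples Which FMS samples define the disease correlations:
#'   `"all"` (default; co-expression contrasts disease vs health and uses
#'   every FMS sample) or `"labelled"` (only FMS samples with a known
#'   depression label).
#' @return A tibble of class `correlation_table` with columns `gene_a`,
#'   `gene_b`, `r_healthy`, `r_disease`; one row per pair, `gene_a`
#'   preceding `gene_b` in panel order, `g*(g-1)/2` rows for `g` genes.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(), seed = 1)
#' ct <- pairwise_correlations(ds)
#' ct
pairwise_correlations <- function(ds, genes = NULL,
                                  fms_samples = c("all", "labelled")) {
  fms_samples <- match.arg(fms_samples)
  if (is.null(genes)) genes <- gene_ids(ds)
  ds <- subset_dataset(ds, genes = genes)
  if (length(genes) < 2) stop("need at least two genes", call. = FALSE)

  healthy_ids <- ds$samples$sample_id[ds$samples$group == "HEALTHY"]
  fms_keep <- ds$samples$group == "FMS"
  if (fms_samples == "labelled") {
    fms_keep <- fms_keep &
      ds$samples$depression %in% c("DEPRESSED", "NOT_DEPRESSED")
  }
  fms_ids <- ds$samples$sample_id[fms_keep]
  if (length(healthy_ids) < 3 || length(fms_ids) < 3) {
    stop("need at least 3 samples per group for correlations", call. = FALSE)
  }

  group_cor <- function(ids, label) {
    x <- t(ds$values[, ids, drop = FALSE])
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance gene(s) in ", label, " group: ",
           paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    }
    stats::cor(x)
  }
  R_h <- group_cor(healthy_ids, "healthy")
  R_d <- group_cor(fms_ids, "FMS")

  pairs <- t(utils::combn(length(genes), 2))
  out <- tibble::tibble(
    gene_a = genes[pairs[, 1]],
    gene_b = genes[pairs[, 2]],
    r_healthy = R_h[pairs],
    r_disease = R_d[pairs]
  )
  attr(out, "n_healthy") <- length(healthy_ids)
  attr(out, "n_disease") <- length(fms_ids)
  class(out) <- c("correlation_table", class(out))
  out
}

#' Disease-specific cutoff from a two-sample KS comparison of |r| CDFs
#'
#' Compares the empirical cumulative distributions of absolute Pearson
#' correlations in the healthy and disease groups. The maximum deviation
#' `D = max_x |F_healthy(x) - F_disease(x)|`, evaluated at every observed
#' |r| value, both measures how far the disease rewires co-expression and
#' locates the cutoff: the strong/weak threshold is the smallest |r| at
#' which the deviation attains D. The asymptotic two-sample KS p-value and
#' the critical deviation `D_crit = c(alpha) * sqrt((n1+n2)/(n1*n2))`
#' (with `c(0.05) = 1.36`) are reported alongside.
#'
#' @param ct A [pairwise_correlations()] table (or any object with
#'   `r_healthy`/`r_disease` columns).
#' @param alpha Significance level for the critical deviation.
#' @return An object of class `ks_cutoff`: list with elements `D`,
#'   `cutoff`, `p_value`, `D_critical`, `alpha`, `n_healthy`, `n_disease`
#'   and an `ecdf` tibble (evaluation grid) for plotting.
#' @export
ks_cutoff <- function(ct, alpha = 0.05) {
  x <- abs(ct$r_healthy)
  y <- abs(ct$r_disease)
  if (!length(x) || !length(y)) stop("empty correlation table", call. = FALSE)

  grid <- sort(unique(c(x, y)))
  F_h <- stats::ecdf(x)(grid)
  F_d <- stats::ecdf(y)(grid)
  dev <- abs(F_h - F_d)
  D <- max(dev)
  cutoff <- grid[which(dev >= D - 1e-12)[1]]  # smallest |r| attaining D

  n1 <- length(x)
  n2 <- length(y)
  n_eff <- n1 * n2 / (n1 + n2)
  p <- ks_asymptotic_p(sqrt(n_eff) * D)
  c_alpha <- sqrt(-log(alpha / 2) / 2)
  structure(
    list(D = D, cutoff = cutoff, p_value = p,
         D_critical = c_alpha * sqrt((n1 + n2) / (n1 * n2)),
         alpha = alpha, n_healthy = n1, n_disease = n2,
         ecdf = tibble::tibble(abs_r = grid, cdf_healthy = F_h,
                               cdf_disease = F_d)),
    class = "ks_cutoff"
  )
}

# Kolmogorov tail: P(sup |B(t)| > t_stat), two-sided series
ks_asymptotic_p <- function(t_stat) {
  if (t_stat <= 0) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t_stat^2))
  min(1, max(0, p))
}

#' @export
print.ks_cutoff <- function(x, ...) {
  cat("<ks_cutoff>\n")
  cat(sprintf("  D = %.4f (critical %.4f at alpha %.3g), p = %.3g\n",
              x$D, x$D_critical, x$alpha, x$p_value))
  cat(sprintf("  cutoff |r| = %.4f  (n = %d vs %d pairs)\n",
              x$cutoff, x$n_healthy, x$n_disease))
  invisible(x)
}

#' Classify gene pairs into the four co-expression regions
#'
#' A pair is *strongly* co-expressed in a group when its |r| is at least
#' the cutoff. The four regions of the (|r|_healthy, |r|_disease) plane:
#' `DISRUPTED` (strong in health only: co-expression lost in disease),
#' `INVOKED` (strong in disease only: co-expression gained),
#' `COMMON_STRONG` and `COMMON_WEAK`.
#'
#' @param ct A [pairwise_correlations()] table.
#' @param cutoff Strong/weak threshold in `[0, 1]`, typically
#'   `ks_cutoff(ct)$cutoff`.
#' @return A tibble of class `link_classification` with columns `gene_a`,
#'   `gene_b`, `abs_r_healthy`, `abs_r_disease`, `region`; attributes
#'   `cutoff` and `counts` (named region tally).
#' @export
classify_links <- function(ct, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0, cutoff <= 1)
  out <- tibble::tibble(
    gene_a = ct$gene_a,
    gene_b = ct$gene_b,
    abs_r_healthy = abs(ct$r_healthy),
    abs_r_disease = abs(ct$r_disease)
  )
  strong_h <- out$abs_r_healthy >= cutoff
  strong_d <- out$abs_r_disease >= cutoff
  out$region <- dplyr::case_when(
    strong_h & !strong_d ~ "DISRUPTED",
    !strong_h & strong_d ~ "INVOKED",
    strong_h & strong_d ~ "COMMON_STRONG",
    .default = "COMMON_WEAK"
  )
  counts <- vapply(c("DISRUPTED", "INVOKED", "COMMON_STRONG", "COMMON_WEAK"),
                   function(r) sum(out$region == r), integer(1))
  attr(out, "cutoff") <- cutoff
  attr(out, "counts") <- counts
  class(out) <- c("link_classification", class(out))
  out
}

#' Region tally of a link classification
#' @param links A [classify_links()] result.
#' @return Named integer vector over the four regions.
#' @export
link_counts <- function(links) {
  counts <- attr(links, "counts")
  if (is.null(counts)) {
    counts <- vapply(c("DISRUPTED", "INVOKED", "COMMON_STRONG", "COMMON_WEAK"),
                     function(r) sum(links$region == r), integer(1))
  }
  counts
}

#' Are links more often invoked than disrupted?
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the
#' (disrupted, invoked) counts against equal expected counts: under the
#' null, a rewired pair is as likely to lose as to gain strong
#' co-expression in disease.
#'
#' @param links A [classify_links()] result.
#' @return An `htest` (from [stats::chisq.test()]) with the statistic and
#'   p-value.
#' @export
link_imbalance_test <- function(links) {
  counts <- link_counts(links)
  n <- counts[c("DISRUPTED", "INVOKED")]
  if (sum(n) < 1) stop("no disrupted or invoked links to test", call. = FALSE)
  stats::chisq.test(n, p = c(0.5, 0.5))
}

#' Rsum connectivity scores per gene
#'
#' For each gene, sums the absolute Pearson correlations of its incident
#' links within each differential class: `rsum_disrupted` sums
#' |r|_healthy over the gene's disrupted links (connectivity it loses in
#' disease), `rsum_invoked` sums |r|_disease over its invoked links
#' (connectivity it gains). Genes with no incident class links score 0.
#' Genes with the largest Rsum are the hub candidates.
#'
#' @param links A [classify_links()] result.
#' @return A tibble of class `hub_ranking`: columns `gene`,
#'   `rsum_disrupted`, `rsum_invoked`, one row per panel gene in name
#'   order.
#' @export
rsum_scores <- function(links) {
  genes <- sort(unique(c(links$gene_a, links$gene_b)))
  long <- dplyr::bind_rows(
    dplyr::select(links, gene = "gene_a", "abs_r_healthy", "abs_r_disease",
                  "region"),
    dplyr::select(links, gene = "gene_b", "abs_r_healthy", "abs_r_disease",
                  "region")
  )
  scores <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      rsum_disrupted = sum(.data$abs_r_healthy[.data$region == "DISRUPTED"]),
      rsum_invoked = sum(.data$abs_r_disease[.data$region == "INVOKED"]),
      .groups = "drop"
    )
  out <- tibble::tibble(gene = genes) |>
    dplyr::left_join(scores, by = "gene") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("rsum"),
                                ~ tidyr::replace_na(.x, 0)))
  class(out) <- c("hub_ranking", class(out))
  out
}

#' Select top hub genes per differential class
#'
#' Picks the `k_disrupted` genes with the largest `rsum_disrupted` and the
#' `k_invoked` genes with the largest `rsum_invoked` as classifier
#' features. Ties are broken by gene-name order. A gene topping both
#' lists is kept in the class where its Rsum is larger (disrupted on an
#' exact tie) and the other class takes its next candidate, so the
#' selection always contains `k_disrupted + k_invoked` distinct genes.
#'
#' @param ranking A [rsum_scores()] tibble.
#' @param k_disrupted,k_invoked Hubs per class (defaults 10 + 10 = 20
#'   features).
#' @return The ranking tibble with added columns `selected` (logical) and
#'   `hub_class` (`"DISRUPTED"`, `"INVOKED"` or `NA`), class
#'   `hub_ranking`.
#' @export
select_hubs <- function(ranking, k_disrupted = 10, k_invoked = 10) {
  stopifnot(k_disrupted >= 0, k_invoked >= 0)
  rd <- stats::setNames(ranking$rsum_disrupted, ranking$gene)
  ri <- stats::setNames(ranking$rsum_invoked, ranking$gene)

  order_candidates <- function(score) {
    pos <- score[score > 0]
    names(pos)[order(-pos, names(pos))]
  }
  cand_d <- order_candidates(rd)
  cand_i <- order_candidates(ri)

  excl_d <- excl_i <- character()
  repeat {
    top_d <- utils::head(setdiff(cand_d, excl_d), k_disrupted)
    top_i <- utils::head(setdiff(cand_i, excl_i), k_invoked)
    if (length(top_d) < k_disrupted || length(top_i) < k_invoked) {
      stop("not enough positive-score genes: achievable k = (",
           length(setdiff(cand_d, excl_d)), " disrupted, ",
           length(setdiff(cand_i, excl_i)), " invoked)", call. = FALSE)
    }
    overlap <- intersect(top_d, top_i)
    if (!length(overlap)) break
    for (g in overlap) {
      if (rd[g] >= ri[g]) excl_i <- c(excl_i, g) else excl_d <- c(excl_d, g)
    }
  }

  out <- ranking |>
    dplyr::mutate(
      hub_class = dplyr::case_when(
        .data$gene %in% top_d ~ "DISRUPTED",
        .data$gene %in% top_i ~ "INVOKED",
        .default = NA_character_
      ),
      selected = !is.na(.data$hub_class)
    )
  class(out) <- c("hub_ranking", class(out))
  out
}

#' Gene symbols of the selected hub features
#' @param ranking A [select_hubs()] result.
#' @return Character vector: disrupted hubs (by decreasing Rsum) then
#'   invoked hubs.
#' @export
hub_genes <- function(ranking) {
  if (!"selected" %in% names(ranking)) {
    stop("run select_hubs() first", call. = FALSE)
  }
  sel <- ranking[ranking$selected, ]
  d <- sel[sel$hub_class == "DISRUPTED", ]
  i <- sel[sel$hub_class == "INVOKED", ]
  c(d$gene[order(-d$rsum_disrupted, d$gene)],
    i$gene[order(-i$rsum_invoked, i$gene)])
}

#' Compare Rsum magnitude between invoked and disrupted hubs
#'
#' Independent two-sample t-test (pooled variance by default) of the
#' selected invoked hubs' `rsum_invoked` values against the selected
#' disrupted hubs' `rsum_disrupted` values; a positive statistic means
#' invoked hubs carry more differential connectivity.
#'
#' @param ranking A [select_hubs()] result.
#' @param var.equal Passed to [stats::t.test()].
#' @return An `htest`.
#' @export
rsum_group_test <- function(ranking, var.equal = TRUE) {
  if (!"selected" %in% names(ranking)) {
    stop("run select_hubs() first", call. = FALSE)
  }
  inv <- ranking$rsum_invoked[ranking$selected &
                                ranking$hub_class == "INVOKED"]
  dis <- ranking$rsum_disrupted[ranking$selected &
                                  ranking$hub_class == "DISRUPTED"]
  if (length(inv) < 2 || length(dis) < 2) {
    stop("each hub class needs at least 2 members", call. = FALSE)
  }
  two_sample_t(inv, dis, var.equal = var.equal)
}

# t.test() refuses all-constant input; a zero-spread, equal-mean comparison
# is a well-defined null result (t = 0, p = 1) here
two_sample_t <- function(x, y, var.equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    out <- list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
                p.value = 1, estimate = c(mean(x), mean(y)),
                method = "Two Sample t-test (degenerate: constant data)",
                alternative = "two.sided")
    class(out) <- "htest"
    return(out)
  }
  stats::t.test(x, y, var.equal = var.equal)
}
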