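test_that("pairwise correlations match the covariance formula", {
  # frozen oracle: x = (1,2,3), y = (1,2,4) gives r = 3 / sqrt(2 * 14/3)
  m <- rbind(GX = c(1, 2, 3, 0, 0, 1),
             GY = c(1, 2, 4, 0, 1, 0),
             GZ = c(-1, -2, -3, 1, 0, 0))
  colnames(m) <- paste0("S", 1:6)
  ds <- expr_dataset(m, group = rep(c("HEALTHY", "FMS"), each = 3))
  ct <- pairwise_correlations(ds)
  expect_equal(nrow(ct), 3)
  r_xy <- ct$r_healthy[ct$gene_a == "GX" & ct$gene_b == "GY"]
  expect_equal(r_xy, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(r_xy, 0.9819805061, tolerance = 1e-9)
  r_xz <- ct$r_healthy[ct$gene_a == "GX" & ct$gene_b == "GZ"]
  expect_equal(r_xz, -1)              # perfect anticorrelation
})

test_that("a g-gene panel yields g(g-1)/2 pairs and flags zero variance", {
  ds <- simulate_dataset(sim_config(n_genes = 15, n_healthy = 10, n_fms = 10),
                         seed = 1)
  ct <- pairwise_correlations(ds)
  expect_equal(nrow(ct), 15 * 14 / 2)
  expect_equal(attr(ct, "n_healthy"), 10)

  flat <- ds
  flat$values["GENE03", flat$samples$group == "FMS"] <- 5
  expect_error(pairwise_correlations(flat), "zero-variance.*GENE03")
})

test_that("fms_samples = 'labelled' restricts the disease group", {
  ds <- simulate_dataset(sim_config(), seed = 2)
  ds$samples$depression[ds$samples$group == "FMS"][1:9] <- "UNKNOWN"
  ct_all <- pairwise_correlations(ds)
  ct_lab <- pairwise_correlations(ds, fms_samples = "labelled")
  expect_equal(attr(ct_all, "n_disease"), 61)
  expect_equal(attr(ct_lab, "n_disease"), 52)
  expect_false(identical(ct_all$r_disease, ct_lab$r_disease))
  expect_identical(ct_all$r_healthy, ct_lab$r_healthy)
})

test_that("ks_cutoff matches brute-force enumeration on the 4-point toy", {
  ct <- tibble::tibble(r_healthy = c(0.1, 0.2, 0.3, 0.4),
                       r_disease = c(0.3, 0.4, 0.5, 0.6))
  ks <- ks_cutoff(ct)
  expect_equal(ks$D, 0.5)
  expect_equal(ks$cutoff, 0.2)  # smallest |r| attaining the max deviation
})

test_that("ks_cutoff equals the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    ct <- tibble::tibble(
      r_healthy = round(runif(n, -1, 1), sample(c(1, 2, 8), 1)),
      r_disease = round(runif(n, -1, 1), sample(c(1, 2, 8), 1))
    )
    ks <- ks_cutoff(ct)
    oracle <- brute_force_ks(abs(ct$r_healthy), abs(ct$r_disease))
    expect_equal(ks$D, oracle$D, tolerance = 1e-12)
    expect_equal(ks$cutoff, oracle$cutoff, tolerance = 1e-12)
  }
})

test_that("identical |r| samples give D = 0, p = 1, smallest-|r| cutoff", {
  ct <- tibble::tibble(r_healthy = c(0.5, -0.2, 0.7),
                       r_disease = c(-0.5, 0.2, 0.7))
  ks <- ks_cutoff(ct)
  expect_equal(ks$D, 0)
  expect_equal(ks$p_value, 1)
  expect_equal(ks$cutoff, 0.2)
  # c(0.05) * sqrt((n1 + n2) / (n1 * n2)) with c(0.05) = 1.36
  expect_equal(ks$D_critical, 1.3581015 * sqrt(6 / 9), tolerance = 1e-6)
})

test_that("asymptotic KS p-value agrees with stats::ks.test on clean data", {
  set.seed(4)
  x <- runif(300)
  y <- runif(300)^1.3
  ct <- tibble::tibble(r_healthy = x, r_disease = y)
  ks <- ks_cutoff(ct)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(ks$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ks$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("link classification applies the four-region rule", {
  links <- classify_links(toy_correlation_table(), 0.5)
  expect_equal(links$region, c("DISRUPTED", "INVOKED", "COMMON_STRONG"))
  expect_equal(unname(link_counts(links)), c(1L, 1L, 1L, 0L))

  all_strong <- classify_links(toy_correlation_table(), 0)
  expect_true(all(all_strong$region == "COMMON_STRONG"))  # cutoff 0 boundary
})

test_that("region counts partition all pairs and respect monotonicity", {
  ds <- simulate_dataset(sim_config(), seed = 6)
  ct <- pairwise_correlations(ds)
  for (cutoff in c(0.1, 0.3, 0.6, 0.9)) {
    links <- classify_links(ct, cutoff)
    expect_equal(sum(link_counts(links)), nrow(ct))
  }
  lo <- classify_links(ct, 0.2)
  hi <- classify_links(ct, 0.5)
  weak_lo <- lo$region == "COMMON_WEAK"
  expect_true(all(hi$region[weak_lo] == "COMMON_WEAK"))
})

test_that("chi-square imbalance test matches the closed form", {
  mk <- function(nd, ni) {
    region <- c(rep("DISRUPTED", nd), rep("INVOKED", ni))
    out <- tibble::tibble(gene_a = "a", gene_b = "b",
                          abs_r_healthy = 0.5, abs_r_disease = 0.5,
                          region = region)
    class(out) <- c("link_classification", class(out))
    out
  }
  big <- link_imbalance_test(mk(328, 1054))
  expect_equal(unname(big$statistic), 2 * 363^2 / 691, tolerance = 1e-10)
  expect_equal(unname(big$statistic), 381.4, tolerance = 0.02)
  expect_lt(big$p.value, 0.001)

  null <- link_imbalance_test(mk(50, 50))
  expect_equal(unname(null$statistic), 0)
  expect_equal(null$p.value, 1)

  lop <- link_imbalance_test(mk(0, 10))
  expect_equal(unname(lop$statistic), 10)
  expect_equal(lop$p.value, stats::pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(lop$p.value, 0.0016, tolerance = 0.01)
})

test_that("Rsum scores sum class-defining |r| over incident class links", {
  links <- classify_links(toy_correlation_table(), 0.5)
  hr <- rsum_scores(links)
  score <- function(g, col) hr[[col]][hr$gene == g]
  # GA-GB disrupted with |r_healthy| = 0.9 -> both endpoints score 0.9
  expect_equal(score("GA", "rsum_disrupted"), 0.9)
  expect_equal(score("GB", "rsum_disrupted"), 0.9)
  expect_equal(score("GC", "rsum_disrupted"), 0)
  # GA-GC invoked with |r_disease| = 0.8
  expect_equal(score("GA", "rsum_invoked"), 0.8)
  expect_equal(score("GC", "rsum_invoked"), 0.8)
  expect_equal(score("GB", "rsum_invoked"), 0)
})

test_that("Rsum totals double-count each link at both endpoints", {
  ds <- simulate_dataset(sim_config(), seed = 8)
  links <- classify_links(pairwise_correlations(ds), 0.3)
  hr <- rsum_scores(links)
  expect_equal(sum(hr$rsum_disrupted),
               2 * sum(links$abs_r_healthy[links$region == "DISRUPTED"]),
               tolerance = 1e-10)
  expect_equal(sum(hr$rsum_invoked),
               2 * sum(links$abs_r_disease[links$region == "INVOKED"]),
               tolerance = 1e-10)
})

test_that("hub selection takes per-class maxima with name-order ties", {
  links <- classify_links(toy_correlation_table(), 0.5)
  hr <- select_hubs(rsum_scores(links), 1, 1)
  expect_equal(sum(hr$selected), 2)
  # GA ties GB on disrupted (0.9 each) -> GA by name; GA also tops invoked,
  # but its disrupted score is larger, so invoked falls to GC
  expect_equal(hr$hub_class[hr$gene == "GA"], "DISRUPTED")
  expect_equal(hr$hub_class[hr$gene == "GC"], "INVOKED")
  expect_equal(hub_genes(hr), c("GA", "GC"))
})

test_that("equal scores select the first k genes in name order", {
  hr <- tibble::tibble(gene = c("GD", "GB", "GA", "GC"),
                       rsum_disrupted = 1, rsum_invoked = 1)
  class(hr) <- c("hub_ranking", class(hr))
  sel <- select_hubs(hr, 2, 2)
  expect_setequal(sel$gene[sel$selected & sel$hub_class == "DISRUPTED"],
                  c("GA", "GB"))
  expect_setequal(sel$gene[sel$selected & sel$hub_class == "INVOKED"],
                  c("GC", "GD"))
})

test_that("hub selection yields distinct genes and errors when infeasible", {
  ds <- simulate_dataset(sim_config(effect_size = 2), seed = 1)
  links <- classify_links(pairwise_correlations(ds),
                          ks_cutoff(pairwise_correlations(ds))$cutoff)
  hr <- select_hubs(rsum_scores(links), 10, 10)
  hubs <- hub_genes(hr)
  expect_length(hubs, 20)
  expect_false(anyDuplicated(hubs) > 0)

  expect_error(select_hubs(rsum_scores(classify_links(
    toy_correlation_table(), 0.5
  )), 5, 5), "achievable k")
})

test_that("planted hubs dominate their class rankings", {
  cfg <- sim_config(
    n_healthy = 200, n_fms = 200,
    blocks = list(list(genes = 1:5, rho = 0.8, group = "HEALTHY_ONLY"),
                  list(genes = 6:10, rho = 0.8, group = "FMS_ONLY")),
    effect_size = 0
  )
  ds <- simulate_dataset(cfg, seed = 21)
  ct <- pairwise_correlations(ds)
  # the planted design is symmetric (both groups hold 10 strong pairs), so
  # the two |r| distributions coincide and the KS deviation is pure noise;
  # classify at a cutoff separating the noise bulk from the planted 0.8
  links <- classify_links(ct, 0.4)
  hr <- select_hubs(rsum_scores(links), 5, 5)
  expect_setequal(hr$gene[hr$selected & hr$hub_class == "DISRUPTED"],
                  sprintf("GENE%02d", 1:5))
  expect_setequal(hr$gene[hr$selected & hr$hub_class == "INVOKED"],
                  sprintf("GENE%02d", 6:10))
})

test_that("Rsum group comparison matches the pooled-variance formula", {
  mk_ranking <- function(inv, dis) {
    hr <- tibble::tibble(
      gene = paste0("G", seq_len(length(inv) + length(dis))),
      rsum_disrupted = c(rep(0, length(inv)), dis),
      rsum_invoked = c(inv, rep(0, length(dis))),
      hub_class = c(rep("INVOKED", length(inv)),
                    rep("DISRUPTED", length(dis))),
      selected = TRUE
    )
    class(hr) <- c("hub_ranking", class(hr))
    hr
  }
  tt <- rsum_group_test(mk_ranking(c(5, 6, 7), c(1, 2, 3)))
  expect_equal(unname(tt$statistic), 4.898979, tolerance = 1e-6)
  expect_equal(tt$p.value, 0.0081, tolerance = 0.02)
  expect_gt(unname(tt$statistic), 0)  # invoked larger -> positive t

  same <- rsum_group_test(mk_ranking(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
})
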