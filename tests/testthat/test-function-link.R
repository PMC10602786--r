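sim_with_keystone <- function(beta = 0.4, noise = 0.05, seed = 1,
                              n_taxa = 12) {
  ke <- data.frame(taxon = "taxon_04", fraction = "TPH", beta = beta)
  simulate_consortium(synthetic_spec(n_taxa = n_taxa,
                                     keystone_effects = ke,
                                     noise_sd = noise, seed = seed))
}

test_that("perfect dependence gives an all-positive combined coefficient", {
  sim <- sim_with_keystone(beta = 0, noise = 0.05, seed = 61)
  tab <- sim$relative
  # response equal to a taxon's (standardized) abundance
  x <- tab$values[, "taxon_02"]
  eff <- as.numeric(scale(x)) * 0.05 + 0.5
  rec <- degradation_record(rownames(tab$values), tab$generation,
                            tab$replicate, "TPH", 1, 1 - eff)
  fa <- taxon_function_scores(tab, rec, "TPH", P = 200, seed = 2)
  row <- fa[fa$taxon == "taxon_02", ]
  expect_true(all(c(row$z_pearson, row$z_spearman, row$z_mi,
                    row$z_bray_curtis) > 0))
  expect_gt(row$combined, 0)
  expect_equal(row$direction, "+")
  expect_equal(fa$taxon[which.max(fa$combined)], "taxon_02")
})

test_that("combined coefficient is exactly antisymmetric under response negation", {
  sim <- sim_with_keystone(beta = 0.3, seed = 62)
  tab <- sim$relative
  rec <- sim$responses[sim$responses$fraction == "TPH", ]
  flipped <- rec
  eff <- flipped$efficiency
  flipped$residual_treatment <- flipped$residual_control * (1 + eff)
  flipped$efficiency <- -eff
  fa1 <- taxon_function_scores(tab, rec, "TPH", P = 150, seed = 5)
  fa2 <- taxon_function_scores(tab, flipped, "TPH", P = 150, seed = 5)
  expect_equal(fa2$combined, -fa1$combined, tolerance = 1e-9)
  expect_equal(fa2$z_pearson, -fa1$z_pearson, tolerance = 1e-9)
  expect_equal(fa2$z_spearman, -fa1$z_spearman, tolerance = 1e-9)
  expect_equal(fa2$z_mi, -fa1$z_mi, tolerance = 1e-9)
  expect_equal(fa2$z_gblm, -fa1$z_gblm, tolerance = 1e-9)
  expect_equal(fa2$z_bray_curtis, -fa1$z_bray_curtis, tolerance = 1e-9)
})

test_that("top tables order by combined coefficient with q stars", {
  fa <- data.frame(taxon = c("a", "b", "c", "d"),
                   fraction = "TPH",
                   combined = c(5, -3, 8, -7),
                   p = c(0.01, 0.2, 0.001, 0.004),
                   q = c(0.02, 0.26, 0.004, 0.016))
  tt <- top_tables(fa, k = 2)
  expect_equal(tt$positive$taxon, c("c", "a"))
  expect_equal(tt$negative$taxon, c("d", "b"))
  expect_equal(tt$positive$star, c("*", "*"))
  expect_equal(tt$negative$star, c("*", ""))
  # k beyond the taxon count truncates; empty input stays empty
  expect_equal(nrow(top_tables(fa, k = 10)$positive), 4L)
  expect_equal(nrow(top_tables(fa[0, ], k = 3)$positive), 0L)
})

test_that("exact Wilcoxon enumeration matches the closed case and wilcox.test", {
  g <- group_compare(list(c(1, 2, 3), c(4, 5, 6)), "wilcoxon")
  expect_true(g$exact)
  expect_equal(g$p_value, 0.1)  # 2/20 assignments are as extreme
  # tie-free comparison against R's exact implementation
  set.seed(71)
  for (i in 1:15) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    ours <- group_compare(list(a, b), "wilcoxon")
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # identical groups sit at the null center
  gid <- group_compare(list(c(2, 4, 6), c(2, 4, 6)), "wilcoxon")
  expect_gt(gid$p_value, 0.9)
})

test_that("kruskal-wallis H is label-symmetric and matches kruskal.test", {
  set.seed(72)
  vals <- list(rnorm(9), rnorm(9) + 1, rnorm(9))
  ours <- group_compare(vals, "kruskal")
  ref <- kruskal.test(vals)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # permuting group order leaves H unchanged
  perm <- group_compare(vals[c(3, 1, 2)], "kruskal")
  expect_equal(perm$statistic, ours$statistic)
  # small-sample exact path agrees with the chi-square one in direction
  ex <- group_compare(list(c(1, 2), c(3, 4), c(9, 10)), "kruskal")
  expect_true(ex$exact)
  expect_lte(ex$p_value, 1)
})

test_that("diversity metrics match closed forms", {
  v <- rbind(u = rep(0.25, 4), s = c(1, 0, 0, 0), m = c(0.5, 0.3, 0.2, 0))
  colnames(v) <- paste0("t", 1:4)
  tab <- abundance_table(v, rep("G1", 3), mode = "relative")
  cm <- community_metrics(tab)
  expect_equal(cm$alpha$shannon[1], log(4))
  expect_equal(cm$alpha$evenness[1], 1)
  expect_equal(cm$alpha$shannon[2], 0)
  expect_equal(cm$alpha$evenness[2], 0)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(cm$alpha$shannon[3], -sum(p * log(p)))
  expect_true(isSymmetric(cm$beta))
  expect_true(all(diag(cm$beta) == 0))
  # direct-sum oracle on a random sample
  set.seed(73)
  x <- runif(5); x <- x / sum(x)
  v2 <- rbind(a = x, b = rev(x))
  colnames(v2) <- paste0("t", 1:5)
  cm2 <- community_metrics(abundance_table(v2, rep("G1", 2),
                                           mode = "relative"))
  expect_equal(cm2$alpha$shannon[1], -sum(x * log(x)), tolerance = 1e-12)
})

test_that("core/shared/unique taxa match brute-force set logic", {
  # 2 generations x 2 replicates, 4 taxa with known membership
  v <- rbind(
    G1_r1 = c(a = 0.40, b = 0.30, c = 0.30, d = 0),
    G1_r2 = c(a = 0.50, b = 0.20, c = 0.30, d = 0),
    G2_r1 = c(a = 0.998, b = 0.001, c = 0, d = 0.001),
    G2_r2 = c(a = 0.999, b = 0.0005, c = 0, d = 0.0005))
  tab <- abundance_table(v, rep(c("G1", "G2"), each = 2), mode = "relative")
  cu <- core_and_unique(tab)
  # a: prevalence 1, mean ab >> 0.2% -> core; b: prevalence 1 but mean
  # (0.3+0.2+0.001+0.0005)/4 = 12.5% -> core; c: prevalence 0.5 -> not core
  expect_setequal(cu$core, c("a", "b"))
  expect_setequal(cu$shared, c("a", "b"))
  expect_equal(cu$unique$G1, "c")
  expect_equal(cu$unique$G2, "d")
  expect_equal(unname(cu$counts$shared), 2L)
  # a taxon everywhere at 0.05% fails the abundance leg
  v2 <- cbind(v * 0.9995, e = 0.0005)
  v2 <- v2 / rowSums(v2)
  cu2 <- core_and_unique(abundance_table(v2, rep(c("G1", "G2"), each = 2),
                                         mode = "relative"))
  expect_false("e" %in% cu2$core)
  # raising thresholds only shrinks the core
  loose <- core_and_unique(tab, prevalence_min = 0.4,
                           abundance_min = 0.0001)
  expect_true(all(cu$core %in% loose$core))
})
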