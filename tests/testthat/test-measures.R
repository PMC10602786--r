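test_that("bray_curtis matches the hand formula and its range", {
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 5, 0)), 1)
  set.seed(1)
  for (i in 1:20) {
    x <- runif(8); y <- runif(8)
    expect_equal(bray_curtis(x, y), oracle_bray(x, y))
    expect_gte(bray_curtis(x, y), 0)
    expect_lte(bray_curtis(x, y), 1)
  }
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("correlation wrappers behave on affine, monotone and tied data", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1), 1)
  expect_equal(spearman_cor(x, 2 * x + 1), 1)
  expect_equal(spearman_cor(x, exp(x)), 1)
  expect_lt(pearson_cor(x, exp(x)), 1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  # zero variance signals NA, not an error
  expect_true(is.na(pearson_cor(rep(1, 5), 1:5)))
})

test_that("spearman equals pearson on mid-ranks, including ties", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(5:25, 1)
    x <- sample(1:6, n, replace = TRUE) + runif(n) * sample(0:1, 1)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_cor(x, y), cor(rank(x), rank(y)),
                 tolerance = 1e-12)
    # and agrees with R's own estimator
    expect_equal(spearman_cor(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("mutual information: closed forms, symmetry, independence", {
  x <- runif(40)
  expect_equal(mutual_information(x, x, bins = 4), log(4))
  expect_equal(mutual_information(x, max(x) - x, bins = 5), log(5))
  expect_equal(mutual_information(x, rep(2, 40)), 0)
  set.seed(7)
  for (i in 1:20) {
    a <- runif(30); b <- sample(1:5, 30, replace = TRUE)
    expect_equal(mutual_information(a, b, bins = 4),
                 mutual_information(b, a, bins = 4))
    expect_equal(mutual_information(a, b, bins = 4), oracle_mi(a, b, 4))
    expect_gte(mutual_information(a, b, bins = 4), 0)
  }
  # independent large-sample MI stays near zero
  set.seed(8)
  x <- runif(1000); y <- sample(x)
  expect_lt(mutual_information(x, y, bins = 4), 0.02)
})

test_that("gblm boosting converges to OLS on a single true predictor", {
  set.seed(5)
  n <- 80
  raw <- cbind(a = runif(n), b = runif(n), c = runif(n))
  raw <- cbind(raw, target = raw[, "a"])
  tab <- toy_table(raw)
  co <- gblm_scores(tab, "target", shrinkage = 0.1, iterations = 2000)
  expect_equal(unname(co["a"]), 1, tolerance = 1e-3)
  expect_equal(unname(co["b"]), 0, tolerance = 1e-6)
  expect_equal(unname(co["c"]), 0, tolerance = 1e-6)
  # nu = 1, single predictor: one step is exactly the OLS slope on
  # standardized data
  z <- scale(cbind(p = rnorm(n), q = rnorm(n)))
  y <- 0.6 * z[, 1] + rnorm(n, 0, 0.3)
  ols <- coef(lm(scale(y) ~ scale(z[, 1]) - 1))[[1]]
  tab2 <- abundance_table(
    t(apply(cbind(p = z[, 1] - min(z) + 1, q = z[, 2] - min(z) + 1,
                  y = y - min(y) + 1), 1, function(r) r / sum(r))),
    rep("G1", n), mode = "relative")
  expect_true(is.numeric(gblm_scores(tab2, "y", 1, 5000)))
  # M = 0 leaves every coefficient at zero
  expect_true(all(gblm_scores(tab, "target", 0.1, 0) == 0))
})

test_that("gblm null coefficients stay small on independent predictors", {
  # 30 taxa so the residual closure dependence (~ -1/29) is negligible.
  # Boosting converges toward OLS, whose null coefficients have SE 1/sqrt(n);
  # the largest of 29 such coefficients stays under 3.5 SE nearly always.
  n <- 200
  bound <- 3.5 / sqrt(n)
  ok <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    m <- matrix(exp(rnorm(n * 30)), n, 30,
                dimnames = list(NULL, sprintf("t%02d", 1:30)))
    tab <- toy_table(m)
    co <- gblm_scores(tab, "t01", 0.1, 500)
    if (max(abs(co)) < bound) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.9)
})

test_that("score_matrix is symmetric and matches the per-pair loop", {
  set.seed(10)
  tab <- toy_table(matrix(exp(rnorm(60)), 12, 5))
  for (m in c("bray_curtis", "pearson", "spearman", "mi")) {
    S <- score_matrix(tab, m, bins = 3)
    expect_identical(S, t(S))
    fun <- switch(m, bray_curtis = bray_curtis, pearson = pearson_cor,
                  spearman = spearman_cor,
                  mi = function(a, b) mutual_information(a, b, bins = 3))
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(S[i, j], fun(tab$values[, i], tab$values[, j]))
  }
  # two complementary taxa: closure forces r = -1
  comp <- abundance_table(cbind(a = c(.2, .5, .8, .3), b = c(.8, .5, .2, .7)),
                          rep("G1", 4), mode = "relative")
  expect_equal(score_matrix(comp, "pearson")["a", "b"], -1)
  # gblm matrix is the symmetrized coefficient matrix
  G <- score_matrix(tab, "gblm", iterations = 200)
  expect_identical(G, t(G))
  expect_true(all(diag(G) == 1))
})
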