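# construct a vector with exactly the requested sample mean and SD
with_moments <- function(n, m, s, seed) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  m + s * x
}

test_that("pooled two-sample t from summaries matches t.test on raw data", {
  expect_equal(two_sample_t(1, 0.5, 10, 1, 0.8, 12)[["t"]], 0)

  x1 <- with_moments(126, 0.27, 0.11, 1)
  x2 <- with_moments(121, 0.31, 0.12, 2)
  got <- two_sample_t(0.27, 0.11, 126, 0.31, 0.12, 121)
  ref <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(got[["t"]], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got[["df"]], 245)
  expect_equal(got[["p"]], ref$p.value, tolerance = 1e-10)
  # frozen value from the direct pooled formula (the published table prints
  # -2.45 from unrounded raw data; rounded summaries give -2.73)
  expect_equal(got[["t"]], -2.7328, tolerance = 1e-4)

  # |t| grows with n at fixed summaries
  expect_gt(abs(two_sample_t(0.27, 0.11, 252, 0.31, 0.12, 242)[["t"]]),
            abs(got[["t"]]))
  expect_error(two_sample_t(0, 0, 1, 1, 1, 5), "n >= 2")
})

test_that("group_summary tabulates per-feature group stats with df = n1+n2-2", {
  set.seed(3)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(1, 0), 15)
  gs <- group_summary(X, y)
  expect_equal(gs$feature, c("a", "b"))
  expect_equal(gs$df, c(28, 28))
  ref <- t.test(X[y == 1, 1], X[y == 0, 1], var.equal = TRUE)
  expect_equal(gs$t[1], unname(ref$statistic))
})

test_that("PCA retains the minimal components reaching the variance threshold", {
  set.seed(4)
  # two perfectly correlated features -> one component explains everything
  x <- rnorm(50)
  p1 <- pca_reduce(cbind(a = x, b = 2 * x))
  expect_equal(p1$n_retained, 1L)
  expect_equal(p1$explained_variance_ratio[1], 1, tolerance = 1e-12)

  # identity covariance: threshold requires nearly all components,
  # minimality holds, and ratios match an eigendecomposition oracle
  X <- matrix(rnorm(2000 * 10), 2000, 10)
  p2 <- pca_reduce(X)
  cum <- cumsum(p2$explained_variance_ratio)
  expect_gte(cum[p2$n_retained], 0.95)
  expect_lt(cum[p2$n_retained - 1], 0.95)
  expect_gte(p2$n_retained, 8L)
  ev <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(p2$explained_variance_ratio, ev / sum(ev), tolerance = 1e-10)

  # completeness: all components reproduce the standardized data
  Z <- scale(X)
  expect_equal(p2$scores %*% t(p2$loadings), Z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # orthonormal loadings
  expect_equal(crossprod(p2$loadings), diag(10), tolerance = 1e-10,
               ignore_attr = TRUE)
  # deterministic sign: largest-magnitude loading positive
  for (j in 1:10) {
    v <- p2$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_warning(pca_reduce(cbind(X, const = rep(1, 2000))), "zero-variance")
})

test_that("the logistic IRLS agrees with stats::glm", {
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(100, 1, plogis(X[, 1] - 0.5 * X[, 3]))
  fit <- stepwise_logistic(X, y, alpha = 1)  # admit everything
  g <- glm(y ~ X[, fit$selected, drop = FALSE], family = binomial)
  expect_equal(fit$terms$beta, unname(coef(g))[-1], tolerance = 1e-6)
  expect_equal(fit$terms$se,
               unname(summary(g)$coefficients[-1, 2]), tolerance = 1e-3)
  expect_equal(fit$loglik_model, as.numeric(logLik(g)), tolerance = 1e-8)
  expect_equal(fit$loglik_null,
               as.numeric(logLik(glm(y ~ 1, family = binomial))),
               tolerance = 1e-8)
})

test_that("stepwise forward selection is deterministic and respects alpha", {
  set.seed(11)
  X <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- rbinom(200, 1, plogis(1.5 * X[, 2]))
  f1 <- stepwise_logistic(X, y)
  f2 <- stepwise_logistic(X, y)
  expect_identical(f1$selected, f2$selected)
  expect_true("x2" %in% f1$selected)
  # Wald-entry variant also selects the informative term
  fw <- stepwise_logistic(X, y, criterion = "wald")
  expect_true("x2" %in% fw$selected)
  # odds ratios are exp(beta); Wald is (beta/se)^2; Holm >= raw p
  expect_equal(f1$terms$odds_ratio, exp(f1$terms$beta))
  expect_equal(f1$terms$wald, (f1$terms$beta / f1$terms$se)^2)
  expect_true(all(f1$terms$p_corrected >= f1$terms$p_raw - 1e-12))
})

test_that("perfect separation is flagged and reported via the penalized fallback", {
  X <- matrix(c(seq(-3, -1, length.out = 15), seq(1, 3, length.out = 15)),
              ncol = 1, dimnames = list(NULL, "gap"))
  y <- rep(c(0, 1), each = 15)
  expect_warning(fit <- stepwise_logistic(X, y), "separation")
  expect_true(fit$separation)
  expect_true(is.finite(fit$terms$beta))
})

test_that("Nagelkerke R2 matches a brute-force likelihood computation", {
  # worked 4-row dataset; model likelihood maximized independently by optim
  x <- c(1, 2, 3, 4)
  y <- c(0, 0, 1, 1)
  nll <- function(b) {
    p <- plogis(b[1] + b[2] * x)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS")
  ll1 <- -opt$value
  ll0 <- sum(dbinom(y, 1, mean(y), log = TRUE))
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / 4)
  expect_equal(nagelkerke_r2(ll0, ll1, 4),
               r2_cs / (1 - exp(2 * ll0 / 4)), tolerance = 1e-6)

  expect_equal(nagelkerke_r2(-60, -60, 100), 0)
  # monotone in the model log-likelihood
  vals <- sapply(c(-55, -45, -30, -10), function(l) nagelkerke_r2(-60, l, 100))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(nagelkerke_r2(0, 0, 10), "degenerate")
})

test_that("PC-feature correlations equal direct Pearson computation", {
  set.seed(13)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  p <- pca_reduce(X, cum_var_threshold = 0.5)
  cm <- pc_feature_correlations(p, X)
  expect_equal(dim(cm), c(p$n_retained, 6L))
  # oracle: the covariance-formula Pearson r
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (j in 1:6) {
    expect_equal(cm[1, j], pearson(p$scores[, 1], X[, j]), tolerance = 1e-12)
  }
  # a PC correlates perfectly with itself presented as a feature
  X2 <- cbind(X, pc1 = p$scores[, 1])
  expect_equal(pc_feature_correlations(p, X2)[1, "pc1"], 1)
  # zero-variance feature -> NA
  X3 <- cbind(X, const = 1)
  expect_true(is.na(pc_feature_correlations(p, X3)[1, "const"]))
})
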