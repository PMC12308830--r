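# Spearman correlation, BH-FDR, OLS regression, size correlations.

test_that("spearman handles perfect monotone relations", {
  expect_equal(spearman_test(1:4, 4:1)$rho, -1)
  expect_equal(spearman_test(1:3, 1:3)$rho, 1)
  expect_error(spearman_test(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_test(1:3, 1:4), "equal length")
})

test_that("tied data match a hand mid-rank Pearson oracle", {
  x <- c(1, 2, 2, 3)
  y <- c(1, 3, 2, 4)
  rx <- c(1, 2.5, 2.5, 4)
  ry <- c(1, 3, 2, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_test(x, y)$rho, oracle)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(20)
  y <- rnorm(20)
  base <- spearman_test(x, y)
  expect_equal(spearman_test(exp(x), y)$rho, base$rho)
  expect_equal(spearman_test(x, y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearman_test(exp(x), y)$p_value, base$p_value)
})

test_that("small samples use the exact permutation distribution", {
  set.seed(8)
  x <- rnorm(7)
  y <- rnorm(7)
  st <- spearman_test(x, y)
  expect_equal(st$method, "exact permutation")
  expect_equal(st$p_value,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  st2 <- spearman_test(rnorm(25), rnorm(25))
  expect_equal(st2$method, "t approximation")
})

test_that("the exact null distribution matches full enumeration", {
  # brute force: every permutation of 1..n
  for (n in 4:6) {
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                   drop = FALSE]
    s_all <- apply(perms, 1, function(p) sum((seq_len(n) - p)^2))
    counts <- chromTE:::spearman_exact_counts(n)
    expect_equal(sum(counts), factorial(n))
    for (s in unique(s_all)) {
      expect_equal(counts[s + 1], sum(s_all == s))
    }
    expect_equal(sum(counts[setdiff(seq_along(counts) - 1,
                                    unique(s_all)) + 1]), 0)
  }
})

test_that("perfect monotone pairs keep a nonzero exact p at n = 10", {
  st <- spearman_test(1:10, -(1:10))
  expect_equal(st$rho, -1)
  expect_equal(st$p_value, 2 / factorial(10))
})

test_that("large-sample p matches the t approximation formula", {
  set.seed(13)
  x <- rnorm(30)
  y <- x + rnorm(30, sd = 2)
  st <- spearman_test(x, y)
  tval <- st$rho * sqrt((30 - 2) / (1 - st$rho^2))
  expect_equal(st$p_value, 2 * pt(-abs(tval), 28))
})

test_that("BH adjustment reproduces hand-applied step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 4 * 0.02 / 3, 0.04))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches the step-up oracle on random vectors", {
  set.seed(21)
  for (rep in 1:10) {
    p <- runif(sample(2:30, 1))
    got <- bh_fdr(p)
    expect_equal(got, bh_oracle(p))
    expect_true(all(got >= p))
  }
})

test_that("OLS recovers exact and noisy linear structure", {
  set.seed(2)
  x1 <- rnorm(50)
  x2 <- rnorm(50)
  fit0 <- suppressWarnings(
    ols_regression(2 * x1 - 3 * x2 + 1, data.frame(x1, x2)))
  expect_equal(fit0$r_squared, 1)
  expect_lt(max(abs(fit0$residuals)), 1e-10)
  y <- 2 * x1 - 3 * x2 + rnorm(50, sd = 0.01)
  set.seed(31)
  x1 <- rnorm(200); x2 <- rnorm(200)
  y <- 2 * x1 - 3 * x2 + rnorm(200, sd = 0.01)
  fit <- ols_regression(y, data.frame(x1, x2))
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "x1"] - 2),
            3 * co$std_error[co$term == "x1"])
  expect_lt(abs(co$estimate[co$term == "x2"] + 3),
            3 * co$std_error[co$term == "x2"])
})

test_that("rank-deficient designs name the offending predictor", {
  x1 <- rnorm(20)
  expect_error(ols_regression(rnorm(20), data.frame(x1, dup = 2 * x1)),
               "dup")
  expect_error(ols_regression(rnorm(3), data.frame(a = rnorm(3),
                                                   b = rnorm(3))),
               "predictors")
})

test_that("t-values agree with a normal-equations oracle", {
  set.seed(41)
  X <- cbind(1, matrix(rnorm(60), ncol = 3))
  y <- X %*% c(1, 0.5, -0.2, 0) + rnorm(20, sd = 0.3)
  fit <- ols_regression(as.numeric(y),
                        data.frame(a = X[, 2], b = X[, 3], d = X[, 4]))
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  s2 <- sum(res^2) / (20 - 4)
  se <- sqrt(diag(XtX_inv) * s2)
  expect_equal(fit$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$t_value, as.numeric(beta / se),
               tolerance = 1e-8)
})

test_that("t statistics are null-distributed under permutation", {
  set.seed(51)
  x1 <- rnorm(40)
  x2 <- rnorm(40)
  y <- rnorm(40)
  pvals <- vapply(1:400, function(i) {
    f <- ols_regression(sample(y), data.frame(x1, x2))
    f$coefficients$p_value[f$coefficients$term == "x1"]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("size correlations find built-in inverse scaling", {
  set.seed(61)
  sizes <- data.frame(chrom = paste0("c", 1:20),
                      length = seq(5e6, 3e7, length.out = 20))
  d <- data.frame(chrom = sizes$chrom,
                  dens = 1 / sizes$length * (1 + rnorm(20, sd = 0.05)))
  out <- correlate_across_chromosomes(d, "dens", sizes)
  expect_lt(out$rho, 0)
  expect_lt(out$p_adjusted, 0.05)
  d$flat <- 1
  expect_error(correlate_across_chromosomes(d, "flat", sizes), "constant")
  # exclusion removes the named chromosome
  d$dens[1] <- NA
  out2 <- correlate_across_chromosomes(d, "dens", sizes,
                                       exclude_chroms = "c2")
  expect_equal(out2$n, 18)
})
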