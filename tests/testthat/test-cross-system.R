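make_xy <- function(n = 19, p = 4, q = 3, seed = 1, noise = 0) {
  with_seed_local(seed, {
    X <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("x", 1:q)))
    B <- matrix(rnorm(q * p), q, p)
    Y <- X %*% B + noise * matrix(rnorm(n * p), n, p)
    colnames(Y) <- paste0("y", 1:p)
    list(X = scale(X), Y = Y)
  })
}

test_that("noiseless linear responses give explained variance 1 and minimal p", {
  d <- make_xy(noise = 0)
  r <- rda_analysis(d$Y, d$X, n_perm = 199, seed = 1)
  expect_equal(r$explained_variance, 1.0, tolerance = 1e-9)
  expect_equal(r$permutation_p, 1 / 200, tolerance = 1e-12)
})

test_that("univariate RDA equals OLS R-squared", {
  d <- make_xy(p = 1, noise = 0.8, seed = 2)
  r <- rda_analysis(d$Y, d$X)
  ols <- summary(lm(d$Y ~ d$X))$r.squared
  expect_equal(r$explained_variance, ols, tolerance = 1e-9)
})

test_that("RDA agrees with the vegan implementation on explained variance", {
  skip_if_not_installed("vegan")
  d <- make_xy(noise = 0.5, seed = 3)
  ours <- rda_analysis(d$Y, d$X)
  vg <- vegan::rda(d$Y ~ d$X)
  expect_equal(ours$explained_variance,
               vg$CCA$tot.chi / vg$tot.chi, tolerance = 1e-9)
})

test_that("independent responses yield baseline variance and null p-values", {
  ps <- vapply(1:20, function(s) {
    with_seed_local(s + 900, {
      X <- scale(matrix(rnorm(40 * 3), 40, 3))
      Y <- matrix(rnorm(40 * 4), 40, 4)
    })
    r <- rda_analysis(Y, X, n_perm = 199, seed = s)
    r$permutation_p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("collinear predictors are dropped with a warning", {
  d <- make_xy(noise = 0.5, seed = 4)
  X2 <- cbind(d$X, dup = d$X[, 1])
  expect_warning(r <- rda_analysis(d$Y, X2), "collinear")
  expect_equal(r$explained_variance, rda_analysis(d$Y, d$X)$explained_variance,
               tolerance = 1e-9)
})

test_that("paired permutation test matches exact enumeration", {
  with_seed_local(7, {
    a <- runif(10); b <- a + rnorm(10, 0.1, 0.2)
  })
  # independent brute-force oracle over all sign patterns
  d <- a - b
  obs <- abs(mean(d))
  n <- length(d)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0, -1, 1)
    if (abs(mean(signs * d)) >= obs - 1e-12) count <- count + 1L
  }
  p_oracle <- count / 2^n
  expect_equal(paired_permutation_test(a, b, exact = TRUE)$p_value, p_oracle,
               tolerance = 1e-12)
  # Monte-Carlo agrees within sampling error
  p_mc <- paired_permutation_test(a, b, n_perm = 4000, seed = 1)$p_value
  expect_lt(abs(p_mc - p_oracle), 3 * sqrt(p_oracle * (1 - p_oracle) / 4000) +
              1e-3)
})

test_that("paired permutation test is symmetric and saturates for equal inputs", {
  x <- c(0.2, 0.4, 0.9, 0.1, 0.5)
  expect_equal(paired_permutation_test(x, x, seed = 1)$p_value, 1)
  with_seed_local(8, {
    a <- runif(12); b <- runif(12)
  })
  p1 <- paired_permutation_test(a, b, seed = 5)$p_value
  p2 <- paired_permutation_test(b, a, seed = 5)$p_value
  expect_equal(p1, p2)
  expect_error(paired_permutation_test(1:3, 1:4), "equal length")
})

test_that("19 identical positive differences are overwhelmingly significant", {
  a <- rep(1, 19); b <- rep(0.5, 19)
  p <- paired_permutation_test(a, b, exact = TRUE)$p_value
  expect_equal(p, 2 / 2^19, tolerance = 1e-15)
  p_mc <- paired_permutation_test(a, b, n_perm = 10000, seed = 2)$p_value
  expect_lt(p_mc, 0.001)
})

test_that("stepwise regression recovers a strong single predictor", {
  with_seed_local(11, {
    x1 <- rnorm(40); x2 <- rnorm(40)
    y <- 2 * x1 + rnorm(40, 0, 0.01)
  })
  fit <- stepwise_regression(y, data.frame(x1 = x1, x2 = x2),
                             standardize = FALSE)
  expect_identical(fit$selected, "x1")
  expect_equal(unname(fit$coefficients["x1"]), 2, tolerance = 0.01)
  expect_lt(fit$p_value, 1e-6)
})

test_that("stepwise F degrees of freedom follow the selected model size", {
  with_seed_local(12, {
    X <- as.data.frame(matrix(rnorm(19 * 6), 19, 6))
    y <- 1.5 * X[[1]] - 1.2 * X[[2]] + 0.9 * X[[3]] + rnorm(19, 0, 0.05)
  })
  fit <- stepwise_regression(y, X)
  if (length(fit$selected) == 3L) {
    expect_equal(fit$df1, 3)
    expect_equal(fit$df2, 15)
  }
  expect_equal(fit$df2, 19 - length(fit$selected) - 1)
})

test_that("stepwise on pure noise usually selects nothing", {
  empty <- vapply(1:20, function(s) {
    with_seed_local(s + 700, {
      y <- rnorm(19)
      X <- as.data.frame(matrix(rnorm(19 * 3), 19, 3))
    })
    length(stepwise_regression(y, X)$selected) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.5)
})

test_that("rank group comparison reproduces the hand-ranked H statistic", {
  res <- rank_group_compare(list(a = c(1, 2, 3), b = c(10, 11, 12)))
  # brute-force oracle: H from explicit ranks
  ranks <- rank(c(1, 2, 3, 10, 11, 12))
  n <- 6
  H <- 12 / (n * (n + 1)) *
    (3 * (mean(ranks[1:3]) - (n + 1) / 2)^2 +
     3 * (mean(ranks[4:6]) - (n + 1) / 2)^2)
  expect_equal(res$H, H, tolerance = 1e-9)
  expect_equal(res$H, 3.857, tolerance = 1e-3)
  # identical groups: H ~ 0, p ~ 1
  res0 <- rank_group_compare(list(c(1, 2, 3), c(1, 2, 3)))
  expect_lt(res0$H, 1e-9)
  expect_gt(res0$p_value, 0.99)
  # label permutation within groups changes nothing
  res2 <- rank_group_compare(list(a = c(3, 1, 2), b = c(12, 10, 11)))
  expect_equal(res2$H, res$H)
  expect_error(rank_group_compare(list(1:3)), "groups")
  expect_error(rank_group_compare(list(1:3, 5)), "values")
})

test_that("environmental correlation handles identity, nulls and affine maps", {
  x <- seq(0.1, 1, length.out = 19)
  r <- correlate_with_environment(x, x, n_perm = 999, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p_value, 1 / 1000, tolerance = 1e-12)
  r2 <- correlate_with_environment(x, 3 * x + 2, n_perm = 99, seed = 1)
  expect_equal(r2$r, 1)
  # null type-I rate in a sane band
  rej <- vapply(1:20, function(s) {
    with_seed_local(s + 800, {
      a <- rnorm(19); b <- rnorm(19)
    })
    correlate_with_environment(a, b, n_perm = 399, seed = s)$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.15)
  expect_error(correlate_with_environment(rep(1, 6), rnorm(6)), "variance")
})

test_that("cross-system table blocks have the documented shape", {
  # synthetic standardized networks via the manual constructor in the
  # network tests would couple files; build tiny real ones instead
  st <- simulate_study(n_sites = 4, seed = 21)
  cfg <- test_config(n_subsamples = 20, n_L = 8, E_range = 2:6)
  nets <- lapply(st$sites, function(s) {
    proc <- lapply(as.data.frame(s$series), function(v) {
      preprocess(monthly_series(v, start = s$start))
    })
    standardize_network(build_site_network(proc, config = cfg, seed = 1,
                                           exogenous = "temperature",
                                           site = s$site))
  })
  tab <- assemble_cross_system_table(nets, st$metadata)
  expect_equal(dim(tab$response$links_ef), c(4L, 4L))
  expect_equal(dim(tab$response$links_bd), c(4L, 4L))
  expect_equal(dim(tab$response$pairwise), c(4L, 6L))
  expect_equal(dim(tab$response$triangular), c(4L, 4L))
  expect_true(all(colnames(tab$response$triangular) ==
                  c("I-N", "I-P", "II-N", "II-P")))
  # predictors standardized
  expect_lt(max(abs(colMeans(tab$predictors))), 1e-9)
  expect_equal(unname(apply(tab$predictors, 2, sd)), rep(1, ncol(tab$predictors)),
               tolerance = 1e-9)
  # incomplete metadata drops the site with a warning
  md <- st$metadata
  md$depth[2] <- NA
  expect_warning(tab2 <- assemble_cross_system_table(nets, md), "incomplete")
  expect_length(tab2$sites, 3L)
  md$area[c(1, 3)] <- NA
  expect_error(suppressWarnings(assemble_cross_system_table(nets, md)),
               "complete")
})
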