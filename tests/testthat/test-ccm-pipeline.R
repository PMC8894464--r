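test_that("embedding dimension selection is total and range-respecting", {
  b <- benchmark_pair(5)
  E <- select_embedding_dimension(b$y, b$x)
  expect_true(E >= 2 && E <= 20)
  # white noise still returns some E without error
  with_seed_local(99, {
    wn1 <- rnorm(60); wn2 <- rnorm(60)
  })
  E2 <- select_embedding_dimension(wn1, wn2)
  expect_true(E2 >= 2 && E2 <= 20)
  # short series truncates the search instead of failing
  E3 <- select_embedding_dimension(wn1[1:25], wn2[1:25])
  expect_true(E3 >= 2 && E3 <= 20)
})

test_that("deterministic benchmark selects a low embedding dimension", {
  Es <- vapply(1:10, function(s) {
    b <- benchmark_pair(s)
    as.integer(select_embedding_dimension(b$y, b$x))
  }, integer(1))
  expect_true(all(Es >= 2 & Es <= 6))
})

test_that("lag scan evaluates the fixed grid and breaks ties to smaller k", {
  b <- benchmark_pair(6)
  lag <- select_lag(b$y, b$x, E = 2)
  expect_length(lag$rho_by_lag, 4L)
  expect_true(lag$k_lag %in% 0:3)
  # constructed tie: cause identical at all lags (constant-plus-tiny series
  # would degenerate, so use an exact tie by duplicating the rho landscape)
  x <- rep(c(0.2, 0.8), 50)
  y <- rep(c(0.3, 0.7), 50)
  lag2 <- select_lag(x, y, E = 2)
  # period-2 series: lags 0 and 2 give identical mappings -> smallest wins
  expect_equal(lag2$rho_by_lag[["k0"]], lag2$rho_by_lag[["k2"]],
               tolerance = 1e-12)
  expect_true(lag2$k_lag %in% c(0L, 1L))
})

test_that("lagged forcing concentrates the selected lag at small k", {
  ks <- vapply(1:10, function(s) {
    b <- benchmark_pair(s + 40)
    quantify_link(b$x, b$y, test_config(E_range = 2:10), seed = s)$k_lag
  }, integer(1))
  mode_k <- as.integer(names(which.max(table(ks))))
  expect_true(mode_k %in% c(0L, 1L))
})

test_that("convergence test matches hand calculations on constructed curves", {
  up <- fake_skill_curve(seq(0.10, 0.80, length.out = 20), n_pred = 400)
  ct <- test_convergence(up)
  expect_equal(ct$kendall_tau, 1)
  expect_lt(ct$kendall_p, 0.05)
  expect_true(ct$converged)
  # hand Fisher Z: atanh(0.8) - atanh(0.1) over sqrt(2/397)
  z_hand <- (atanh(0.8) - atanh(0.1)) / sqrt(2 / 397)
  expect_equal(ct$fisher_z, z_hand, tolerance = 1e-12)
  expect_equal(ct$fisher_p, pnorm(z_hand, lower.tail = FALSE),
               tolerance = 1e-12)

  flat <- fake_skill_curve(rep(0.5, 20), n_pred = 400)
  ctf <- test_convergence(flat)
  expect_equal(ctf$delta_rho, 0)
  expect_false(ctf$converged)

  down <- fake_skill_curve(seq(0.8, 0.1, length.out = 20), n_pred = 400)
  ctd <- test_convergence(down)
  expect_lt(ctd$kendall_tau, 0)
  expect_false(ctd$converged)

  expect_error(test_convergence(fake_skill_curve(c(0.1, 0.2, 0.3))), ">= 4")
  expect_warning(test_convergence(fake_skill_curve(c(0.1, 0.2, 0.3, 1.0))),
                 "clipped")
})

test_that("significance implies convergence implies positive trend and gain", {
  for (s in 1:5) {
    b <- benchmark_pair(s + 10)
    r <- quantify_link(b$x, b$y, test_config(), seed = s)
    if (r$significant) expect_true(r$convergence$converged)
    if (r$convergence$converged) {
      expect_gt(r$convergence$delta_rho, 0)
      expect_gt(r$convergence$kendall_tau, 0)
    }
    expect_true(r$LS >= 0 && r$LS <= 1)
    expect_true(abs(r$rho_Lmax) <= 1)
  }
})

test_that("quantify_link detects the forced direction more strongly", {
  b <- benchmark_pair(20)
  fwd <- quantify_link(b$x, b$y, test_config(), seed = 1)
  rev <- quantify_link(b$y, b$x, test_config(), seed = 1)
  expect_true(fwd$significant)
  expect_gt(fwd$LS, rev$LS)
})

test_that("a self-link is recognized and never significant", {
  b <- benchmark_pair(21)
  r <- quantify_link(b$x, b$x, test_config(), seed = 1)
  expect_true(r$self_link)
  expect_false(r$significant)
  expect_gt(r$LS, 0.95)
})

test_that("insufficient overlap is a validation error", {
  x <- c(rnorm(40), rep(NA, 60))
  y <- c(rep(NA, 60), rnorm(40))
  expect_error(quantify_link(x, y, test_config()), "non-missing")
})

test_that("bootstrap standard errors are seeded and small on a strong link", {
  b <- benchmark_pair(22)
  se1 <- bootstrap_se(b$x, b$y, E = 2, k_lag = 1, n_boot = 200, seed = 3)
  se2 <- bootstrap_se(b$x, b$y, E = 2, k_lag = 1, n_boot = 200, seed = 3)
  expect_identical(se1, se2)
  expect_lt(se1, 0.1)
  se3 <- bootstrap_se(b$x, b$y, E = 2, k_lag = 1, n_boot = 200, seed = 4)
  expect_lt(abs(se3 - se1) / se1, 1)   # different seeds agree to MC error
  expect_error(bootstrap_se(b$x, b$y, E = 2, k_lag = 1, n_boot = 1), "n_boot")
})

test_that("linkage strength grows with coupling strength", {
  betas <- c(0.02, 0.05, 0.1, 0.2)
  med_ls <- vapply(betas, function(beta) {
    median(vapply(1:8, function(s) {
      b <- benchmark_pair(s + 60, beta = beta)
      quantify_link(b$x, b$y, test_config(E_range = 2:10), seed = s)$LS
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(betas, med_ls, method = "spearman"), 0.9)
})
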