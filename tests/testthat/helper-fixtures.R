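# Shared fixtures, all generated in code.

# two-species logistic benchmark: X forces Y with strength beta
benchmark_pair <- function(seed, beta = 0.1, n = 400) {
  spec <- coupling_spec(c("X", "Y"), c(3.8, 3.5),
                        matrix(c(0, 0, beta, 0), 2, 2, byrow = TRUE))
  sim <- simulate_coupled_logistic(spec, n, seed = seed)
  list(x = rescale(sim$series[, "X"]), y = rescale(sim$series[, "Y"]),
       truth = sim$truth)
}

# independent AR(1) pair
ar1_pair <- function(seed, n = 400, phi = 0.5) {
  with_seed_local(seed, {
    list(x = rescale(as.numeric(stats::arima.sim(list(ar = phi), n))),
         y = rescale(as.numeric(stats::arima.sim(list(ar = phi), n))))
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# quick ccm config for tests (no bootstrap unless asked)
test_config <- function(...) ccm_config(n_boot = 0L, ...)

# monthly series with a known seasonal + trend + anomaly decomposition
seasonal_series <- function(n = 480, slope = 0.01, amp = 2, seed = 42) {
  with_seed_local(seed, {
    t_idx <- 0:(n - 1)
    month <- (t_idx %% 12) + 1
    anomaly <- as.numeric(stats::arima.sim(list(ar = 0.3), n))
    anomaly <- (anomaly - mean(anomaly)) / sd(anomaly)
    values <- 10 + slope * t_idx + amp * sin(2 * pi * month / 12) + anomaly
    list(series = monthly_series(values, start = c(2000, 1)),
         anomaly = anomaly)
  })
}

# hand-built skill_curve object for convergence-test units
fake_skill_curve <- function(rho_mean, L = seq(10, by = 20,
                                               length.out = length(rho_mean)),
                             n_pred = 400) {
  curve <- data.frame(L = L, rep = 1L, rho = rho_mean)
  structure(list(curve = curve,
                 summary = data.frame(L = L, rho_mean = rho_mean),
                 L0 = L[1], Lmax = L[length(L)],
                 rho_Lmax = rho_mean[length(rho_mean)],
                 n_pred = n_pred, n_pred0 = n_pred,
                 E = 3L, tau = 1L, k_lag = 0L, n_subsamples = 1L),
            class = "skill_curve")
}
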