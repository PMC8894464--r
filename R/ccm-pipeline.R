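# The full per-link CCM protocol: embedding-dimension selection by hindcast
# cross-mapping, lag scan over k = 0..3 months, library-size convergence
# testing (Kendall trend + Fisher delta-rho Z), the significance call, the
# linkage strength rho(Lmax), and bootstrap standard errors.

#' CCM pipeline configuration
#'
#' Bundles the tunable settings of the per-link protocol. Defaults follow the
#' standard protocol where one is stated (E searched over 2..20, cross-map
#' lags 0..3 months, monthly tau = 1, 500 bootstrap resamples, alpha = 0.05)
#' and documented package choices otherwise (library-size grid of 20 sizes,
#' 100 random subsets per size).
#'
#' @param E_range candidate embedding dimensions.
#' @param lags candidate cross-map lags (months).
#' @param tau coordinate lag of the embedding (months).
#' @param n_L number of library sizes on the convergence grid.
#' @param n_subsamples library subsets per size.
#' @param alpha significance level for both convergence criteria.
#' @param n_boot bootstrap replicates for the standard error (0 = skip).
#' @param min_overlap minimum common non-missing months for a link.
#' @param exclusion_radius temporal Theiler window in months: library points
#'   within this distance of a prediction point are never its neighbours.
#'   Guards against false positives driven by serial autocorrelation rather
#'   than shared dynamics.
#' @param seasonal_exclusion never use neighbours an exact multiple of 12
#'   months away (default `TRUE`); see [cross_map()].
#' @param se_mult parsimony margin for embedding-dimension and lag selection:
#'   the smallest candidate within `se_mult` standard errors (Fisher-z scale,
#'   autocorrelation-corrected) of the best skill is chosen. 0 reproduces a
#'   plain argmax.
#' @return list of class `ccm_config`.
#' @export
ccm_config <- function(E_range = 2:20, lags = 0:3, tau = 1L, n_L = 20L,
                       n_subsamples = 100L, alpha = 0.05, n_boot = 500L,
                       min_overlap = 30L, exclusion_radius = 3L,
                       seasonal_exclusion = TRUE, se_mult = 2) {
  structure(list(E_range = as.integer(E_range), lags = as.integer(lags),
                 tau = as.integer(tau), n_L = as.integer(n_L),
                 n_subsamples = as.integer(n_subsamples), alpha = alpha,
                 n_boot = as.integer(n_boot), min_overlap = as.integer(min_overlap),
                 exclusion_radius = as.integer(exclusion_radius),
                 seasonal_exclusion = isTRUE(seasonal_exclusion),
                 se_mult = se_mult),
            class = "ccm_config")
}

#' Effective sample size for correlated monthly series
#'
#' Serial autocorrelation reduces the information content of a correlation
#' between two time series. Following the standard cross-correlation
#' adjustment, the effective sample size is
#' `n_eff = n / (1 + 2 * sum_k r_x(k) r_y(k))`, truncated at lag
#' `min(n/4, 50)` and never larger than `n`. Used to scale the Fisher
#' delta-rho test and the parsimony margin of model selection.
#'
#' @param x,y the two series (numeric or [monthly_series()]).
#' @return list with `n` (complete pairs), `factor` (>= 1) and `n_eff`.
#' @export
effective_sample_size <- function(x, y) {
  xv <- as_values(x); yv <- as_values(y)
  ok <- !is.na(xv) & !is.na(yv)
  n <- sum(ok)
  if (n < 10L) return(list(n = n, factor = 1, n_eff = n))
  K <- min(floor(n / 4), 50L)
  ax <- stats::acf(xv[ok], lag.max = K, plot = FALSE)$acf[-1]
  ay <- stats::acf(yv[ok], lag.max = K, plot = FALSE)$acf[-1]
  fac <- max(1, 1 + 2 * sum(ax * ay))
  list(n = n, factor = fac, n_eff = n / fac)
}

#' Select the embedding dimension by hindcast cross-mapping
#'
#' Scores each candidate `E` by the full-library skill of the hindcast in
#' which the effect's embedding `X(t)` projects one step backward to the
#' candidate cause `Y(t - 1)`; this guards against overfitting `E` when the
#' two series are unrelated. Because an exact argmax over many candidates
#' still overfits the selection statistic's sampling noise, the smallest `E`
#' whose skill lies within `se_mult` standard errors (Fisher-z scale, with
#' the autocorrelation-corrected effective sample size) of the maximum is
#' returned: when nothing distinguishes the candidates beyond noise the most
#' parsimonious reconstruction wins. The search range is truncated when the
#' series is too short for large `E`. `E` is selected per ordered pair.
#'
#' @param effect effect series `X`.
#' @param cause candidate cause `Y`.
#' @param E_range candidate dimensions (default 2..20).
#' @param tau coordinate lag.
#' @param exclusion_radius temporal Theiler window, as in [cross_map()].
#' @param seasonal_exclusion exclude same-calendar-month neighbours, as in
#'   [cross_map()].
#' @param se_mult parsimony margin in standard errors (0 = plain argmax).
#' @return the selected `E` (integer), with the per-E skills in
#'   `attr(, "rho")`.
#' @export
select_embedding_dimension <- function(effect, cause, E_range = 2:20, tau = 1L,
                                       exclusion_radius = 0L,
                                       seasonal_exclusion = FALSE,
                                       se_mult = 1) {
  rhos <- rep(NA_real_, length(E_range))
  for (i in seq_along(E_range)) {
    E <- E_range[i]
    ctx <- tryCatch(ccm_context(effect, cause, E, tau, k_lag = 1L),
                    error = function(e) NULL)
    if (is.null(ctx) || ctx$n < E + 2) next
    rhos[i] <- context_rho(ctx, seq_len(ctx$n),
                           exclusion_radius = exclusion_radius,
                           seasonal_exclusion = seasonal_exclusion)
  }
  if (all(is.na(rhos))) {
    stop_invalid("no embedding dimension admits enough embedded vectors")
  }
  margin <- se_mult * selection_se(effect, cause)
  best <- pick_parsimonious(rhos, margin)
  structure(as.integer(E_range[best]), rho = rhos)
}

# standard error of atanh(rho) under the autocorrelation-corrected
# effective sample size
selection_se <- function(effect, cause) {
  ess <- effective_sample_size(effect, cause)
  if (ess$n_eff <= 4) return(Inf)
  sqrt(1 / (ess$n_eff - 3))
}

# index of the first (most parsimonious) candidate within `margin` of the
# best skill on the atanh scale
pick_parsimonious <- function(rhos, margin) {
  z <- atanh(pmin(pmax(rhos, -1 + 1e-12), 1 - 1e-12))
  zmax <- max(z, na.rm = TRUE)
  if (!is.finite(margin)) margin <- Inf
  which(!is.na(z) & z >= zmax - margin - 1e-12)[1]
}

#' Select the cross-map lag
#'
#' Evaluates full-library cross-map skill for each candidate lag `k`
#' (mapping `X(t + k)` to `Y(t)`) at the chosen `E` and returns the smallest
#' lag within `se_mult` standard errors of the best skill (exact ties always
#' break to the smallest `k`; `se_mult = 0` gives a plain argmax).
#'
#' @param effect,cause series as in [select_embedding_dimension()].
#' @param E embedding dimension.
#' @param lags candidate lags, default `0:3` months.
#' @param tau coordinate lag.
#' @param exclusion_radius temporal Theiler window, as in [cross_map()].
#' @param seasonal_exclusion exclude same-calendar-month neighbours, as in
#'   [cross_map()].
#' @param se_mult parsimony margin in standard errors.
#' @return list with `k_lag`, `rho`, and the per-lag skills `rho_by_lag`.
#' @export
select_lag <- function(effect, cause, E, lags = 0:3, tau = 1L,
                       exclusion_radius = 0L, seasonal_exclusion = FALSE,
                       se_mult = 1) {
  rhos <- vapply(lags, function(k) {
    ctx <- ccm_context(effect, cause, E, tau, k_lag = k)
    if (ctx$n < E + 2) return(NA_real_)
    context_rho(ctx, seq_len(ctx$n), exclusion_radius = exclusion_radius,
                seasonal_exclusion = seasonal_exclusion)
  }, numeric(1))
  if (all(is.na(rhos))) stop_invalid("no lag admits enough embedded vectors")
  best <- pick_parsimonious(rhos, se_mult * selection_se(effect, cause))
  list(k_lag = as.integer(lags[best]), rho = rhos[best],
       rho_by_lag = stats::setNames(rhos, paste0("k", lags)))
}

#' Test convergence of a cross-map skill curve
#'
#' Applies the two convergence criteria to `rho(L)`: (1) a one-sided Kendall
#' rank-correlation test for a monotonically increasing trend of the mean
#' skill in `L`; (2) Fisher's delta-rho Z test comparing the skill at the
#' maximal library size against the minimal one,
#' `Z = (atanh(rho_Lmax) - atanh(rho_L0)) / sqrt(1/(n1-3) + 1/(n0-3))` with
#' `n1`, `n0` the numbers of prediction points at the maximal and minimal
#' library sizes, each divided by the serial-correlation factor of
#' [effective_sample_size()] when `ess_factor > 1` is supplied. Convergence requires both: an increasing
#' trend (`tau > 0`, `p < alpha`) and a significant improvement
#' (`delta_rho > 0`, `p < alpha`).
#'
#' @param curve a [skill_curve()].
#' @param alpha significance level (default 0.05).
#' @param ess_factor serial-correlation correction factor (>= 1) applied to
#'   the Fisher test's sample sizes; see [effective_sample_size()].
#' @return An object of class `convergence_test`.
#' @export
test_convergence <- function(curve, alpha = 0.05, ess_factor = 1) {
  stopifnot(inherits(curve, "skill_curve"))
  smry <- curve$summary[is.finite(curve$summary$rho_mean), ]
  if (nrow(smry) < 4L) stop_invalid("need >= 4 distinct library sizes")
  kt <- suppressWarnings(
    cor.test(smry$L, smry$rho_mean, method = "kendall",
             alternative = "greater"))
  rho0 <- smry$rho_mean[1]
  rho1 <- smry$rho_mean[nrow(smry)]
  n1 <- curve$n_pred / max(1, ess_factor)
  n0 <- (curve$n_pred0 %||% curve$n_pred) / max(1, ess_factor)
  if (min(n0, n1) <= 3L) stop_invalid("too few prediction points for Fisher test")
  clipz <- function(r) {
    if (abs(r) >= 1) {
      warning("|rho| >= 1 clipped before atanh", call. = FALSE)
      r <- sign(r) * (1 - 1e-12)
    }
    atanh(r)
  }
  z <- (clipz(rho1) - clipz(rho0)) / sqrt(1 / (n1 - 3) + 1 / (n0 - 3))
  fisher_p <- pnorm(z, lower.tail = FALSE)
  delta <- rho1 - rho0
  tau_hat <- unname(kt$estimate)
  converged <- is.finite(tau_hat) && tau_hat > 0 && kt$p.value < alpha &&
    delta > 0 && fisher_p < alpha
  structure(list(kendall_tau = tau_hat, kendall_p = kt$p.value,
                 delta_rho = delta, fisher_z = z, fisher_p = fisher_p,
                 alpha = alpha, converged = converged),
            class = "convergence_test")
}

#' @export
print.convergence_test <- function(x, ...) {
  cat(sprintf(
    "<convergence_test> tau=%.3f (p=%.3g), delta_rho=%.3f, Z=%.2f (p=%.3g) -> %s\n",
    x$kendall_tau, x$kendall_p, x$delta_rho, x$fisher_z, x$fisher_p,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Quantify one directed causal link by CCM
#'
#' Runs the full per-link protocol for `cause -> effect`: the effect series
#' is embedded, the embedding dimension is selected by hindcast, the
#' cross-map lag is scanned over the candidate set, the library-size skill
#' curve is computed and tested for convergence, and the linkage strength is
#' taken as `LS = max(rho(Lmax), 0)` (negative skill carries no causal
#' information; the raw value is retained). The link is significant iff the
#' convergence test passes.
#'
#' @param cause putative causal series.
#' @param effect effect series (embedded side).
#' @param config a [ccm_config()].
#' @param seed integer seed (subsampling and bootstrap).
#' @param cause_name,effect_name identifiers for reporting.
#' @return An object of class `ccm_result`.
#' @export
quantify_link <- function(cause, effect, config = ccm_config(), seed = 1L,
                          cause_name = "cause", effect_name = "effect") {
  xv <- as_values(effect); yv <- as_values(cause)
  if (length(xv) != length(yv)) {
    stop_invalid("cause and effect must share one time index")
  }
  overlap <- sum(!is.na(xv) & !is.na(yv))
  if (overlap < config$min_overlap) {
    stop_invalid("only ", overlap, " common non-missing months (< ",
                 config$min_overlap, ")")
  }
  self_link <- isTRUE(all.equal(xv, yv))
  excl <- config$exclusion_radius
  seas <- isTRUE(config$seasonal_exclusion)
  ess <- effective_sample_size(effect, cause)
  E <- select_embedding_dimension(effect, cause, config$E_range, config$tau,
                                  exclusion_radius = excl,
                                  seasonal_exclusion = seas,
                                  se_mult = config$se_mult)
  lag <- select_lag(effect, cause, E, config$lags, config$tau,
                    exclusion_radius = excl, seasonal_exclusion = seas,
                    se_mult = config$se_mult)
  curve <- skill_curve(effect, cause, E, config$tau, lag$k_lag,
                       n_L = config$n_L, n_subsamples = config$n_subsamples,
                       seed = seed, exclusion_radius = excl,
                       seasonal_exclusion = seas)
  conv <- test_convergence(curve, config$alpha, ess_factor = ess$factor)
  rho_Lmax <- curve$rho_Lmax
  se <- if (config$n_boot > 0) {
    bootstrap_se(cause, effect, E, lag$k_lag, n_boot = config$n_boot,
                 seed = seed + 1L, tau = config$tau, exclusion_radius = excl,
                 seasonal_exclusion = seas)
  } else NA_real_
  structure(list(cause = cause_name, effect = effect_name,
                 E = as.integer(E), k_lag = lag$k_lag,
                 rho_Lmax = rho_Lmax, LS = max(rho_Lmax, 0),
                 curve = curve, convergence = conv,
                 significant = conv$converged && !self_link,
                 self_link = self_link, se = se, ess = ess,
                 E_search = attr(E, "rho"), lag_search = lag$rho_by_lag),
            class = "ccm_result")
}

#' @export
print.ccm_result <- function(x, ...) {
  cat(sprintf(
    "<ccm_result> %s -> %s: E=%d k=%d rho(Lmax)=%.3f LS=%.3f se=%.3f %s%s\n",
    x$cause, x$effect, x$E, x$k_lag, x$rho_Lmax, x$LS, x$se,
    if (x$significant) "significant" else "n.s.",
    if (x$self_link) " [self-link]" else ""))
  invisible(x)
}

#' Bootstrap standard error of the linkage strength
#'
#' Resamples the library of embedded data points with replacement (library
#' size preserved, prediction set fixed), recomputes `rho(Lmax)` for each
#' replicate, and returns the sample standard deviation over replicates.
#'
#' @param cause,effect series as in [quantify_link()].
#' @param E,k_lag embedding settings of the quantified link.
#' @param n_boot number of replicates (default 500).
#' @param seed integer seed.
#' @param tau coordinate lag.
#' @param exclusion_radius temporal Theiler window, as in [cross_map()].
#' @param seasonal_exclusion exclude same-calendar-month neighbours, as in
#'   [cross_map()].
#' @return the bootstrap standard error (numeric scalar).
#' @export
bootstrap_se <- function(cause, effect, E, k_lag, n_boot = 500L, seed = 1L,
                         tau = 1L, exclusion_radius = 0L,
                         seasonal_exclusion = FALSE) {
  if (n_boot < 2) stop_invalid("n_boot must be >= 2")
  ctx <- ccm_context(effect, cause, E, tau, k_lag)
  if (ctx$n < E + 2) stop_invalid("too few valid embedded vectors")
  libs <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      sample.int(ctx$n, ctx$n, replace = TRUE)
    })
  })
  rhos <- ccm_rho_batch(ctx$dist, libs, ctx$target, as.integer(ctx$time),
                        as.integer(exclusion_radius),
                        as.integer(seasonal_exclusion), as.integer(E + 1L),
                        FALSE)
  sd(rhos, na.rm = TRUE)
}
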