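# State-space reconstruction primitives: time-delay embedding, simplex
# (nearest-neighbour) cross-map estimation, and library-size skill curves.
# The neighbour search runs in compiled code; all randomness (library
# subsampling) is drawn from R's RNG so a seed fixes the whole computation.

#' Time-delay embedding
#'
#' Builds the lagged-coordinate reconstruction
#' `(x(t), x(t - tau), ..., x(t - (E - 1) tau))`. Any vector touching a
#' missing value is dropped; the time index of each retained vector is kept.
#'
#' @param x numeric vector or [monthly_series()].
#' @param E embedding dimension (>= 2).
#' @param tau lag between coordinates, in months (default 1).
#' @return An object of class `delay_embedding`: list with `vectors`
#'   (rows = embedded points), `time` (1-based time of each row), `E`, `tau`.
#' @export
embed_series <- function(x, E, tau = 1L) {
  v <- as_values(x)
  n <- length(v)
  check_scalar_number(E, "E"); check_scalar_number(tau, "tau")
  if (E < 2) stop_invalid("E must be >= 2")
  if (tau < 1) stop_invalid("tau must be >= 1")
  if (n < (E - 1) * tau + 2) {
    stop_invalid("series too short for E = ", E, ", tau = ", tau)
  }
  t0 <- (E - 1) * tau + 1
  times <- t0:n
  mat <- sapply(0:(E - 1), function(l) v[times - l * tau])
  mat <- matrix(mat, ncol = E)
  valid <- !apply(mat, 1, anyNA)
  structure(list(vectors = mat[valid, , drop = FALSE], time = times[valid],
                 E = as.integer(E), tau = as.integer(tau), n_input = n),
            class = "delay_embedding")
}

# Internal cross-map context: embed the effect series, align the target
# (putative cause) at lag k, precompute the distance matrix. Rows are the
# embedded vectors of the effect whose target value exists; `time` maps rows
# back to the original index. Cross-mapping X(t + k) vs Y(t) is realised as
# row at time t predicting target[t - k].
ccm_context <- function(effect, cause, E, tau = 1L, k_lag = 0L) {
  emb <- embed_series(effect, E, tau)
  y <- as_values(cause)
  tt <- emb$time - k_lag
  ok <- tt >= 1 & tt <= length(y)
  target <- rep(NA_real_, length(emb$time))
  target[ok] <- y[tt[ok]]
  keep <- !is.na(target)
  vec <- emb$vectors[keep, , drop = FALSE]
  list(vectors = vec, time = emb$time[keep], target = target[keep],
       E = emb$E, tau = emb$tau, k_lag = as.integer(k_lag),
       dist = ccm_dist_matrix(vec), n = nrow(vec))
}

context_rho <- function(ctx, lib, pred = seq_len(ctx$n), nn = ctx$E + 1L,
                        exclusion_radius = 0L, seasonal_exclusion = FALSE) {
  pred_hat <- ccm_predict(ctx$dist, as.integer(lib - 1L),
                          as.integer(pred - 1L), ctx$target,
                          as.integer(ctx$time), as.integer(exclusion_radius),
                          as.integer(seasonal_exclusion), as.integer(nn))
  safe_cor(pred_hat, ctx$target[pred])
}

#' Simplex cross-map estimation
#'
#' Uses the delay embedding of the effect series `X` to estimate states of
#' the putative cause `Y`: for each prediction point the `E + 1` nearest
#' library neighbours (Euclidean distance, leave-one-out, ties broken by
#' earliest time) receive exponential weights `w_i = exp(-d_i / d_min)` and
#' the estimate is their weighted mean of the cause's values. The cross-map
#' skill `rho` is the Pearson correlation between estimates and observations.
#'
#' @param effect effect series `X` (its embedding is the reference set).
#' @param cause putative causal series `Y` (the mapping target).
#' @param E embedding dimension.
#' @param tau coordinate lag.
#' @param k_lag cross-map lag `k`: maps `X(t + k)` to `Y(t)`.
#' @param lib integer indices (into the valid embedded vectors) forming the
#'   library; default = full library.
#' @param exclusion_radius temporal Theiler window: library points within
#'   this many months of the prediction point are excluded as neighbours
#'   (0 = exclude only the identical point).
#' @param seasonal_exclusion also exclude library points an exact multiple of
#'   12 months away: month-wise standardization leaves each series a small
#'   fixed per-calendar-month offset (the climatology estimation error), and
#'   same-month neighbours would share it, letting pure seasonality mimic
#'   skill.
#' @param warn warn when fewer than `E + 1` neighbours are available.
#' @return list with `rho`, `predicted`, `observed`, `time`, `n_pred`.
#' @export
cross_map <- function(effect, cause, E, tau = 1L, k_lag = 0L, lib = NULL,
                      exclusion_radius = 0L, seasonal_exclusion = FALSE,
                      warn = TRUE) {
  ctx <- ccm_context(effect, cause, E, tau, k_lag)
  if (ctx$n < E + 2) stop_invalid("too few valid embedded vectors")
  if (is.null(lib)) lib <- seq_len(ctx$n)
  if (length(lib) == 0L) stop_invalid("library must be non-empty")
  if (warn && length(unique(lib)) - 1L < E + 1L) {
    warning("library smaller than E + 2: using all available neighbours",
            call. = FALSE)
  }
  pred_hat <- ccm_predict(ctx$dist, as.integer(lib - 1L),
                          as.integer(seq_len(ctx$n) - 1L), ctx$target,
                          as.integer(ctx$time), as.integer(exclusion_radius),
                          as.integer(seasonal_exclusion), as.integer(E + 1L))
  list(rho = safe_cor(pred_hat, ctx$target),
       predicted = pred_hat, observed = ctx$target, time = ctx$time,
       n_pred = sum(is.finite(pred_hat) & is.finite(ctx$target)))
}

#' Cross-map skill as a function of library size
#'
#' Computes the convergence curve `rho(L)` on a grid of `n_L` library sizes
#' from `L0 = E` to `Lmax` (the number of valid embedded vectors). For each
#' `L < Lmax`, `n_subsamples` random library subsets of size `L` are drawn
#' without replacement and the skill is cross-validated: predictions are made
#' at the points outside the library, so the estimate is free of the
#' leave-one-out anti-correlation that otherwise biases small-library skill
#' downward. At `Lmax` the full library is used once with leave-one-out
#' prediction over all points.
#'
#' @param effect,cause series as in [cross_map()].
#' @param E,tau,k_lag embedding settings.
#' @param n_L number of library sizes on the grid (>= 2).
#' @param n_subsamples random subsets per library size.
#' @param seed integer seed for the subsampling.
#' @param exclusion_radius temporal Theiler window, as in [cross_map()].
#' @param seasonal_exclusion exclude same-calendar-month neighbours, as in
#'   [cross_map()].
#' @return An object of class `skill_curve`: list with `curve` (data frame
#'   `L`, `rep`, `rho`), `summary` (`L`, `rho_mean`), `L0`, `Lmax`,
#'   `rho_Lmax`, `n_pred`, and the settings.
#' @export
skill_curve <- function(effect, cause, E, tau = 1L, k_lag = 0L, n_L = 20L,
                        n_subsamples = 100L, seed = 1L,
                        exclusion_radius = 0L, seasonal_exclusion = FALSE) {
  if (n_L < 2) stop_invalid("n_L must be >= 2")
  ctx <- ccm_context(effect, cause, E, tau, k_lag)
  L0 <- as.integer(E)
  Lmax <- ctx$n
  if (Lmax < L0 + 2) stop_invalid("library too small: Lmax < L0 + 2")
  grid <- unique(as.integer(round(seq(L0, Lmax, length.out = n_L))))
  libs <- list()
  Lcol <- integer(0)
  repcol <- integer(0)
  with_seed(seed, {
    for (L in grid) {
      if (L >= Lmax) {
        libs[[length(libs) + 1L]] <- seq_len(Lmax)
        Lcol <- c(Lcol, L); repcol <- c(repcol, 1L)
      } else {
        for (b in seq_len(n_subsamples)) {
          libs[[length(libs) + 1L]] <- sample.int(Lmax, L)
        }
        Lcol <- c(Lcol, rep(L, n_subsamples))
        repcol <- c(repcol, seq_len(n_subsamples))
      }
    }
  })
  rho <- ccm_rho_batch(ctx$dist, libs, ctx$target, as.integer(ctx$time),
                       as.integer(exclusion_radius),
                       as.integer(seasonal_exclusion), as.integer(E + 1L),
                       TRUE)
  curve <- data.frame(L = Lcol, rep = repcol, rho = rho)
  mu <- tapply(curve$rho, curve$L, mean, na.rm = TRUE)
  smry <- data.frame(L = as.integer(names(mu)), rho_mean = as.numeric(mu))
  structure(list(curve = curve, summary = smry[order(smry$L), ],
                 L0 = L0, Lmax = Lmax,
                 rho_Lmax = curve$rho[curve$L == Lmax][1],
                 n_pred = ctx$n, n_pred0 = ctx$n - L0,
                 E = as.integer(E), tau = as.integer(tau),
                 k_lag = as.integer(k_lag), n_subsamples = as.integer(n_subsamples)),
            class = "skill_curve")
}

#' @export
print.skill_curve <- function(x, ...) {
  cat(sprintf("<skill_curve> E=%d k=%d: rho(L0=%d)=%.3f -> rho(Lmax=%d)=%.3f\n",
              x$E, x$k_lag, x$L0, x$summary$rho_mean[1], x$Lmax, x$rho_Lmax))
  invisible(x)
}

#' Export a skill curve as a plain data frame
#' @param curve a [skill_curve()].
#' @return data frame with columns `L`, `rep`, `rho`.
#' @export
skill_curve_table <- function(curve) {
  stopifnot(inherits(curve, "skill_curve"))
  curve$curve
}
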