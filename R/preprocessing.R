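# Stationarity preprocessing for monthly monitoring series: linear
# detrending, month-wise deseasonalization against the monthly climatology,
# and z-scoring to zero mean / unit variance. Missing months are carried
# through every step untouched — never interpolated, since fabricated values
# would be treated as dynamics by the state-space analysis downstream.

#' Monthly time series container
#'
#' One variable's regular monthly series at one site. The index is contiguous
#' calendar months starting at `start`; missing months are `NA` values, so
#' `values[t]` always refers to month `start + (t - 1)`.
#'
#' @param values numeric vector, `NA` = missing month.
#' @param start length-2 integer `c(year, month)` of the first value.
#' @param site,variable identifiers.
#' @return An object of class `monthly_series`.
#' @export
monthly_series <- function(values, start = c(2000L, 1L), site = "site",
                           variable = "variable") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_invalid("values must be non-empty")
  if (length(start) != 2L || start[2] < 1 || start[2] > 12) {
    stop_invalid("start must be c(year, month) with month in 1..12")
  }
  structure(values,
            start = as.integer(start), site = site, variable = variable,
            steps = character(), class = "monthly_series")
}

as_values <- function(x) {
  if (inherits(x, "monthly_series")) as.numeric(unclass(x)) else as.numeric(x)
}

# calendar month (1..12) of each index position
series_months <- function(x) {
  start <- attr(x, "start") %||% c(2000L, 1L)
  ((start[2] - 1L + seq_along(x) - 1L) %% 12L) + 1L
}

rebuild_series <- function(template, values, step) {
  structure(as.numeric(values),
            start = attr(template, "start"), site = attr(template, "site"),
            variable = attr(template, "variable"),
            steps = c(attr(template, "steps") %||% character(), step),
            class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<monthly_series> %s / %s: %d months from %d-%02d, %d missing\n",
              attr(x, "site"), attr(x, "variable"), n,
              attr(x, "start")[1], attr(x, "start")[2], sum(is.na(x))))
  if (length(attr(x, "steps"))) {
    cat("  steps:", paste(attr(x, "steps"), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Aggregate dated samples to a monthly series
#'
#' Averages all samples falling in the same calendar month; the resulting
#' index is contiguous from the first to the last sampled month, with
#' unsampled months marked missing.
#'
#' @param raw data frame with columns `year`, `month`, `value` (or a `date`
#'   column of class Date).
#' @param site,variable identifiers attached to the result.
#' @return A [monthly_series()].
#' @export
aggregate_monthly <- function(raw, site = "site", variable = "variable") {
  if (!is.data.frame(raw) || nrow(raw) == 0L) {
    stop_invalid("raw must be a non-empty data frame")
  }
  if ("date" %in% names(raw) && !all(c("year", "month") %in% names(raw))) {
    d <- as.POSIXlt(raw$date)
    raw$year <- d$year + 1900L
    raw$month <- d$mon + 1L
  }
  stopifnot(all(c("year", "month", "value") %in% names(raw)))
  if (any(raw$month < 1 | raw$month > 12)) stop_invalid("month must be in 1..12")
  key <- raw$year * 12L + (raw$month - 1L)      # months since year 0
  means <- tapply(raw$value, key, mean, na.rm = TRUE)
  kmin <- min(key); kmax <- max(key)
  full <- kmin:kmax
  values <- rep(NA_real_, length(full))
  values[match(as.integer(names(means)), full)] <- as.numeric(means)
  values[is.nan(values)] <- NA_real_
  monthly_series(values, start = c(kmin %/% 12L, kmin %% 12L + 1L),
                 site = site, variable = variable)
}

#' Remove the long-term linear trend
#'
#' Returns the residuals of an ordinary least-squares regression of value on
#' the time index `t = 0, 1, 2, ...` over the contiguous monthly index;
#' missing months are excluded from the fit and stay missing in the output.
#'
#' With `seasonal_intercepts = TRUE` the trend is estimated jointly with
#' calendar-month intercepts, so the slope measures the long-term drift of
#' the monthly anomalies rather than being contaminated by the (generally
#' non-orthogonal) seasonal cycle; [preprocess()] uses this form so that the
#' full pipeline is exactly invariant to adding any linear trend plus any
#' fixed 12-periodic signal.
#'
#' @param series a [monthly_series()] (or plain numeric vector).
#' @param seasonal_intercepts estimate the trend with per-calendar-month
#'   intercepts (default `FALSE`: plain value-on-time regression).
#' @return detrended [monthly_series()].
#' @export
detrend_linear <- function(series, seasonal_intercepts = FALSE) {
  v <- as_values(series)
  ok <- !is.na(v)
  if (sum(ok) < 3L) stop_invalid("detrending needs >= 3 non-missing values")
  t_idx <- seq_along(v) - 1
  out <- rep(NA_real_, length(v))
  if (seasonal_intercepts) {
    m_ok <- factor(series_months(series)[ok])
    X <- stats::model.matrix(~ 0 + m_ok)
    fit <- lm.fit(cbind(X, t = t_idx[ok]), v[ok])
    # keep the (centered) seasonal offsets: only the trend is removed here
    seas <- drop(X %*% fit$coefficients[seq_len(ncol(X))])
    out[ok] <- fit$residuals + seas - mean(seas)
  } else {
    fit <- lm.fit(cbind(1, t_idx[ok]), v[ok])
    out[ok] <- fit$residuals
  }
  rebuild_series(series, out, "detrend")
}

#' Deseasonalize against the monthly climatology
#'
#' Standardizes each value by the mean and (sample) standard deviation of all
#' values observed in the same calendar month:
#' \eqn{D(t_i) = (O(t_i) - \mu_{month}) / \sigma_{month}}. Months whose
#' climatological sd is zero get anomaly 0 (the vanishing-variance limit),
#' with a warning.
#'
#' @param series a [monthly_series()].
#' @return deseasonalized [monthly_series()] with the climatology (data frame
#'   `month`, `mean`, `sd`, `n`) attached as attribute `"climatology"`
#'   (accessor [climatology()]).
#' @export
deseasonalize <- function(series) {
  v <- as_values(series)
  m <- series_months(series)
  ok <- !is.na(v)
  present <- sort(unique(m[ok]))
  clim <- data.frame(month = 1:12, mean = NA_real_, sd = NA_real_, n = 0L)
  for (mo in present) {
    x <- v[ok & m == mo]
    if (length(x) < 2L) {
      stop_invalid("calendar month ", mo,
                   " has fewer than 2 observations; cannot deseasonalize")
    }
    clim$mean[mo] <- mean(x)
    clim$sd[mo] <- sd(x)
    clim$n[mo] <- length(x)
  }
  if (any(clim$sd[present] == 0)) {
    warning("zero climatological sd in month(s) ",
            paste(present[clim$sd[present] == 0], collapse = ", "),
            "; anomalies set to 0", call. = FALSE)
  }
  out <- rep(NA_real_, length(v))
  for (mo in present) {
    idx <- ok & m == mo
    if (clim$sd[mo] == 0) {
      out[idx] <- 0
    } else {
      out[idx] <- (v[idx] - clim$mean[mo]) / clim$sd[mo]
    }
  }
  res <- rebuild_series(series, out, "deseasonalize")
  attr(res, "climatology") <- clim
  res
}

#' Monthly climatology of a deseasonalized series
#' @param x a series returned by [deseasonalize()] or [preprocess()].
#' @return data frame `month`, `mean`, `sd`, `n`.
#' @export
climatology <- function(x) attr(x, "climatology")

#' Rescale to zero mean and unit variance
#'
#' z-scores the non-missing values using the sample (n - 1) standard
#' deviation.
#'
#' @param series a [monthly_series()] or numeric vector.
#' @return rescaled [monthly_series()].
#' @export
rescale <- function(series) {
  v <- as_values(series)
  ok <- !is.na(v)
  if (length(unique(v[ok])) < 2L) {
    stop_invalid("rescaling needs >= 2 distinct non-missing values")
  }
  s <- sd(v[ok])
  if (s == 0) stop_invalid("zero variance: cannot rescale")
  out <- (v - mean(v[ok])) / s
  if (!inherits(series, "monthly_series")) series <- monthly_series(v)
  rebuild_series(series, out, "rescale")
}

#' Full stationarity preprocessing
#'
#' Composition, in order, of [detrend_linear()], [deseasonalize()] and
#' [rescale()]. The output has long-term mean 0 and unit sample variance over
#' non-missing values, per-calendar-month mean ~0, and is invariant to adding
#' any affine-in-time trend plus any fixed 12-periodic signal to the input.
#'
#' @param series a [monthly_series()].
#' @return processed [monthly_series()] with provenance in `attr(, "steps")`
#'   and the deseasonalization climatology attached.
#' @export
preprocess <- function(series) {
  d <- detrend_linear(series, seasonal_intercepts = TRUE)
  s <- deseasonalize(d)
  clim <- climatology(s)
  out <- rescale(s)
  attr(out, "climatology") <- clim
  out
}
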