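# Seeded synthetic generators with known causal structure: coupled logistic
# maps (the canonical CCM benchmark) and a five-variable mock lake ecosystem,
# plus an observation layer adding the artefacts (trend, seasonality, noise,
# gaps) that the preprocessing module is designed to remove.

#' Specify a coupled nonlinear system
#'
#' Defines a discrete-time coupled logistic system. Variable `i` is updated as
#' \deqn{x_i(t+1) = x_i(t) (r_i - r_i x_i(t) - \sum_{j \ne i} \beta_{ij} x_j(t)) + \epsilon_i(t)}
#' so a non-zero off-diagonal coupling `coupling_matrix[i, j]` means variable
#' `j` forces variable `i`, i.e. a ground-truth causal edge `j -> i`.
#' Diagonal entries describe self-regulation and are never reported as causal
#' edges. Exogenous variables (e.g. temperature) must have an all-zero
#' off-diagonal row: nothing in the system feeds back on them.
#'
#' @param variable_names character vector of variable identifiers.
#' @param growth_rates numeric, map growth parameter r per variable.
#' @param coupling_matrix numeric matrix; `[i, j]` is the strength with which
#'   variable `j` forces variable `i`. Off-diagonal non-zeros define the
#'   ground-truth causal network.
#' @param exogenous_flags logical per variable; `TRUE` marks variables with no
#'   incoming edges from the system.
#' @param initial_state numeric in (0, 1) per variable.
#' @param process_noise_sd scalar or per-variable non-negative noise sd.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(variable_names, growth_rates, coupling_matrix,
                          exogenous_flags = rep(FALSE, length(variable_names)),
                          initial_state = rep(0.5, length(variable_names)),
                          process_noise_sd = 0) {
  p <- length(variable_names)
  if (p < 1L || anyDuplicated(variable_names)) {
    stop_invalid("variable_names must be non-empty and unique")
  }
  if (length(growth_rates) != p || any(!is.finite(growth_rates))) {
    stop_invalid("growth_rates must be finite, one per variable")
  }
  coupling_matrix <- as.matrix(coupling_matrix)
  if (!all(dim(coupling_matrix) == c(p, p)) || any(!is.finite(coupling_matrix))) {
    stop_invalid("coupling_matrix must be a finite ", p, "x", p, " matrix")
  }
  if (length(exogenous_flags) != p || !is.logical(exogenous_flags)) {
    stop_invalid("exogenous_flags must be logical, one per variable")
  }
  for (i in which(exogenous_flags)) {
    if (any(coupling_matrix[i, -i] != 0)) {
      stop_invalid("exogenous variable '", variable_names[i],
                   "' has non-zero incoming couplings")
    }
  }
  if (length(initial_state) != p || any(!is.finite(initial_state)) ||
      any(initial_state <= 0 | initial_state >= 1)) {
    stop_invalid("initial_state values must lie in (0, 1)")
  }
  if (length(process_noise_sd) == 1L) {
    process_noise_sd <- rep(process_noise_sd, p)
  }
  if (any(!is.finite(process_noise_sd)) || any(process_noise_sd < 0)) {
    stop_invalid("process_noise_sd must be non-negative")
  }
  dimnames(coupling_matrix) <- list(variable_names, variable_names)
  structure(
    list(variable_names = variable_names, growth_rates = growth_rates,
         coupling_matrix = coupling_matrix, exogenous_flags = exogenous_flags,
         initial_state = initial_state, process_noise_sd = process_noise_sd),
    class = "coupling_spec")
}

#' Ground-truth causal network implied by a coupling specification
#'
#' Edge `j -> i` exists iff `coupling_matrix[i, j] != 0` for `i != j`.
#' Exogenous variables receive no incoming edges by construction.
#'
#' @param spec a [coupling_spec()].
#' @return An object of class `ground_truth_network` wrapping an edge-list
#'   data frame (`cause`, `effect`, `coefficient`).
#' @export
ground_truth_network <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  b <- spec$coupling_matrix
  idx <- which(b != 0 & row(b) != col(b), arr.ind = TRUE)
  edges <- data.frame(
    cause = spec$variable_names[idx[, "col"]],
    effect = spec$variable_names[idx[, "row"]],
    coefficient = b[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$cause, edges$effect), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("Ground-truth causal network:", nrow(x$edges), "edge(s)\n")
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

clip_unit <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

#' Simulate coupled logistic maps
#'
#' The standard nonlinear benchmark for convergent cross-mapping: chaotic
#' logistic maps coupled through the off-diagonal entries of the coupling
#' matrix. States are clipped to `(1e-6, 1 - 1e-6)` so process noise cannot
#' push the map out of its domain; in noise-free mode leaving (0, 1) is
#' treated as a divergent-parameters error instead.
#'
#' @param spec a [coupling_spec()].
#' @param n_steps number of retained steps (>= 50).
#' @param burn_in discarded initial steps.
#' @param seed integer seed for process noise (ignored when noise sd is 0).
#' @return list with `series` (n_steps x p matrix, named columns) and
#'   `truth` (the [ground_truth_network()]).
#' @export
simulate_coupled_logistic <- function(spec, n_steps, burn_in = 100L, seed = 1L) {
  stopifnot(inherits(spec, "coupling_spec"))
  check_scalar_number(n_steps, "n_steps")
  if (n_steps < 50) stop_invalid("n_steps must be >= 50")
  if (burn_in < 0) stop_invalid("burn_in must be >= 0")
  p <- length(spec$variable_names)
  total <- n_steps + burn_in
  noisy <- any(spec$process_noise_sd > 0)
  out <- matrix(NA_real_, total, p, dimnames = list(NULL, spec$variable_names))
  with_seed(if (noisy) seed else NULL, {
    x <- spec$initial_state
    r <- spec$growth_rates
    b <- spec$coupling_matrix
    for (t in seq_len(total)) {
      forcing <- as.vector(b %*% x) - diag(b) * x
      xn <- x * (r - r * x - forcing)
      if (!noisy && any(xn <= 0 | xn >= 1)) {
        stop_invalid("trajectory left (0, 1) at step ", t,
                     ": invalid parameters for a bounded logistic system")
      }
      if (noisy) xn <- xn + rnorm(p, 0, spec$process_noise_sd)
      x <- clip_unit(xn)
      out[t, ] <- x
    }
  })
  list(series = out[(burn_in + 1):total, , drop = FALSE],
       truth = ground_truth_network(spec))
}

#' Default coupling specification for the mock lake ecosystem
#'
#' Five variables: phytoplankton species `richness`, phytoplankton `biomass`
#' (chlorophyll-a proxy), the nutrients `no3` and `po4`, and exogenous water
#' `temperature`. The default network embeds the diversity-biomass-nutrient
#' feedbacks of interest: richness -> biomass -> no3 -> richness (a Type I
#' triangular feedback by construction), a biomass <-> po4 pairwise feedback,
#' and temperature forcing on biomass (diversity responds to temperature
#' only indirectly, through the food web). Nutrients are replenished
#' logistically toward capacity (constant loading) and depleted by biomass
#' through the biomass -> nutrient couplings. Couplings sit in the
#' weak-to-moderate regime where cross-mapping is informative: much stronger
#' coupling synchronizes the system and direction becomes undecidable.
#'
#' @param beta_scale multiplier applied to all off-diagonal couplings (site
#'   heterogeneity hook).
#' @param process_noise_sd process noise sd on the map scale.
#' @return A [coupling_spec()].
#' @export
mock_ecosystem_spec <- function(beta_scale = 1, process_noise_sd = 0.04) {
  vars <- c("richness", "biomass", "no3", "po4", "temperature")
  b <- matrix(0, 5, 5, dimnames = list(vars, vars))
  # row = effect, column = cause
  b["richness", "no3"] <- 0.27          # nutrient limitation of diversity
  b["biomass", "richness"] <- 0.29      # diversity begets function
  b["biomass", "po4"] <- 0.25           # P limitation of biomass
  b["biomass", "temperature"] <- 0.50   # thermal growth forcing
  b["no3", "biomass"] <- 0.29           # uptake depletes N
  b["po4", "biomass"] <- 0.29           # uptake depletes P
  b <- b * beta_scale
  coupling_spec(
    variable_names = vars,
    growth_rates = c(3.7, 3.8, 3.6, 3.72, 0),
    coupling_matrix = b,
    exogenous_flags = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    initial_state = c(0.4, 0.4, 0.4, 0.4, 0.5),
    process_noise_sd = c(rep(process_noise_sd, 4), 0))
}

#' Simulate the five-variable mock lake ecosystem
#'
#' Monthly-step nonlinear skeleton for one monitoring site. Temperature is an
#' exogenous seasonal sinusoid plus an AR(1) anomaly; its standardized anomaly
#' forces the endogenous variables through the coupling matrix, so the causal
#' signal survives deseasonalization exactly as in field data. Richness,
#' biomass and the two nutrients follow coupled logistic dynamics per the
#' coupling matrix. States are mapped to natural units (species counts, ug/L
#' chlorophyll-a, umol/L nutrients, degrees C); the mapping is affine per
#' variable and therefore invisible to the (z-scored) analysis.
#'
#' @param n_years integer in `[16, 41]`, matching the span of long-term
#'   monitoring series.
#' @param seed integer seed.
#' @param spec a [coupling_spec()] over
#'   `richness, biomass, no3, po4, temperature` with temperature exogenous.
#' @param temp_ar numeric, AR(1) coefficient of the temperature anomaly.
#' @param temp_anom_sd innovation sd of the temperature anomaly (degrees C).
#' @param substeps growth iterations per month (default 2). Plankton
#'   generation times are much shorter than a month, so a monthly transition
#'   is the composition of several growth steps; this also prevents the
#'   artificial month-to-month alternation a single logistic step imprints
#'   on monthly anomalies.
#' @return list with `series` (n_years*12 x 5 matrix in natural units),
#'   `states` (raw map states), `start` = c(year, month), and `truth`.
#' @export
simulate_mock_ecosystem <- function(n_years, seed = 1L,
                                    spec = mock_ecosystem_spec(),
                                    temp_ar = 0.6, temp_anom_sd = 0.8,
                                    substeps = 2L) {
  check_scalar_number(n_years, "n_years")
  if (n_years < 16 || n_years > 41) stop_invalid("n_years must be in [16, 41]")
  stopifnot(inherits(spec, "coupling_spec"))
  vars <- c("richness", "biomass", "no3", "po4", "temperature")
  if (!identical(sort(spec$variable_names), sort(vars))) {
    stop_invalid("spec must cover exactly: ", paste(vars, collapse = ", "))
  }
  if (!spec$exogenous_flags[match("temperature", spec$variable_names)]) {
    stop_invalid("temperature must be flagged exogenous")
  }
  n <- n_years * 12L
  burn <- 120L
  total <- n + burn
  month <- ((seq_len(total) - 1L) %% 12L) + 1L
  noisy <- any(spec$process_noise_sd > 0)
  with_seed(seed, {
    # exogenous temperature: stationary AR(1) anomaly
    innov <- rnorm(total, 0, temp_anom_sd)
    anom <- numeric(total)
    anom[1] <- innov[1] / sqrt(1 - temp_ar^2)
    for (t in 2:total) anom[t] <- temp_ar * anom[t - 1] + innov[t]
    anom_sd_stat <- temp_anom_sd / sqrt(1 - temp_ar^2)
    u_temp <- if (anom_sd_stat > 0) {
      clip_unit(0.5 + 0.2 * tanh(anom / (1.5 * anom_sd_stat)))
    } else rep(0.5, total)

    b <- spec$coupling_matrix[vars, vars]
    r <- spec$growth_rates[match(vars, spec$variable_names)]
    nsd <- spec$process_noise_sd[match(vars, spec$variable_names)]
    endo <- vars[vars != "temperature"]
    states <- matrix(NA_real_, total, 5, dimnames = list(NULL, vars))
    x <- spec$initial_state[match(vars, spec$variable_names)]
    names(x) <- vars
    for (t in seq_len(total)) {
      x["temperature"] <- u_temp[t]
      for (ss in seq_len(substeps)) {
        xn <- x
        for (v in endo) {
          forcing <- sum(b[v, ] * x) - b[v, v] * x[v]
          val <- x[v] * (r[match(v, vars)] - r[match(v, vars)] * x[v] - forcing)
          if (nsd[match(v, vars)] > 0) {
            val <- val + rnorm(1, 0, nsd[match(v, vars)] / sqrt(substeps))
          }
          xn[v] <- clip_unit(val)
        }
        x <- xn
      }
      states[t, ] <- x
    }
    states <- states[(burn + 1):total, , drop = FALSE]
    anom <- anom[(burn + 1):total]
    month <- month[(burn + 1):total]
    # natural units; temperature carries its own seasonality
    series <- cbind(
      richness = 10 + 40 * states[, "richness"],
      biomass = 2 + 35 * states[, "biomass"],
      no3 = 5 + 45 * states[, "no3"],
      po4 = 0.2 + 2.8 * states[, "po4"],
      temperature = 14 + 8 * sin(2 * pi * month / 12 - pi / 2) + anom)
  })
  list(series = series, states = states, start = c(year = 2000L, month = 1L),
       truth = ground_truth_network(spec))
}

#' Specify an observation layer
#'
#' Describes the artefacts of real monitoring data that sit on top of the
#' dynamical signal: a long-term linear trend, a fixed seasonal cycle,
#' i.i.d. Gaussian observation noise, and missing months. These are exactly
#' the features the preprocessing pipeline removes.
#'
#' @param trend_slope slope per month, scalar or per variable.
#' @param seasonal_amplitude amplitude of the 12-month sinusoid.
#' @param seasonal_phase phase in radians.
#' @param obs_noise_sd observation noise sd.
#' @param missing_fraction fraction in `[0, 1)` of months masked at random.
#' @param seed integer seed.
#' @return An object of class `observation_spec`.
#' @export
observation_spec <- function(trend_slope = 0, seasonal_amplitude = 0,
                             seasonal_phase = 0, obs_noise_sd = 0,
                             missing_fraction = 0, seed = 1L) {
  check_scalar_number(missing_fraction, "missing_fraction")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop_invalid("missing_fraction must be in [0, 1)")
  }
  if (any(obs_noise_sd < 0)) stop_invalid("obs_noise_sd must be >= 0")
  structure(
    list(trend_slope = trend_slope, seasonal_amplitude = seasonal_amplitude,
         seasonal_phase = seasonal_phase, obs_noise_sd = obs_noise_sd,
         missing_fraction = missing_fraction, seed = seed),
    class = "observation_spec")
}

#' Add observation artefacts to a simulated series
#'
#' Adds `slope * t`, `amplitude * sin(2 pi month / 12 + phase)` and Gaussian
#' noise to each column, then masks a deterministic count
#' `round(missing_fraction * n)` of points per variable, uniformly at random
#' under the seed. Scalar spec fields are recycled across variables.
#'
#' @param series numeric matrix (rows = consecutive months, named columns).
#' @param obs an [observation_spec()].
#' @param start_month calendar month (1-12) of the first row.
#' @return matrix of the same shape with `NA` for masked points.
#' @export
add_observation_layer <- function(series, obs, start_month = 1L) {
  stopifnot(inherits(obs, "observation_spec"))
  series <- as.matrix(series)
  n <- nrow(series)
  p <- ncol(series)
  rec <- function(x) if (length(x) == 1L) rep(x, p) else x
  slope <- rec(obs$trend_slope); amp <- rec(obs$seasonal_amplitude)
  phase <- rec(obs$seasonal_phase); nsd <- rec(obs$obs_noise_sd)
  stopifnot(length(slope) == p, length(amp) == p,
            length(phase) == p, length(nsd) == p)
  t_idx <- seq_len(n) - 1L
  month <- ((start_month - 1L + t_idx) %% 12L) + 1L
  out <- series
  n_miss <- round(obs$missing_fraction * n)
  with_seed(obs$seed, {
    for (j in seq_len(p)) {
      out[, j] <- series[, j] + slope[j] * t_idx +
        amp[j] * sin(2 * pi * month / 12 + phase[j])
      if (nsd[j] > 0) out[, j] <- out[, j] + rnorm(n, 0, nsd[j])
      if (n_miss > 0) out[sample.int(n, n_miss), j] <- NA_real_
    }
  })
  out
}

#' Simulate a multi-site monitoring study
#'
#' Generates `n_sites` mock lake ecosystems with heterogeneous series lengths
#' (16-41 years), site-specific coupling strengths arranged along a latent
#' environmental gradient, an observation layer, and a site-metadata table
#' (depth, area, long-term means) for the cross-system analyses.
#'
#' @param n_sites number of sites (study default 19).
#' @param seed integer seed.
#' @param missing_fraction fraction of months masked per series.
#' @param obs_noise_frac observation noise sd as a fraction of each
#'   variable's skeleton sd.
#' @return list with `sites` (per site: `site`, `start`, `series`, `truth`),
#'   and `metadata` (one row per site).
#' @export
simulate_study <- function(n_sites = 19L, seed = 1L, missing_fraction = 0.02,
                           obs_noise_frac = 0.1) {
  check_scalar_number(n_sites, "n_sites")
  out <- vector("list", n_sites)
  meta <- vector("list", n_sites)
  with_seed(seed, {
    site_seeds <- sample.int(2^31 - 2, n_sites * 2)
    years <- sample(16:41, n_sites, replace = TRUE)
    gradient <- runif(n_sites)            # latent productivity gradient
    depth <- exp(rnorm(n_sites, 2.5, 0.8))       # m
    area <- exp(rnorm(n_sites, 3.0, 1.5))        # km^2
  })
  for (s in seq_len(n_sites)) {
    g <- gradient[s]
    # diversity-biomass coupling strengthens along the gradient; nutrient
    # couplings weaken, mimicking oligotrophic vs eutrophic contrasts
    spec <- mock_ecosystem_spec()
    b <- spec$coupling_matrix
    b["biomass", "richness"] <- b["biomass", "richness"] * (0.7 + 0.6 * g)
    b["biomass", "po4"] <- b["biomass", "po4"] * (1.2 - 0.5 * g)
    b["richness", "no3"] <- b["richness", "no3"] * (1.2 - 0.4 * g)
    spec$coupling_matrix <- b
    sim <- simulate_mock_ecosystem(years[s], seed = site_seeds[s], spec = spec)
    skeleton_sd <- apply(sim$series, 2, sd)
    obs <- observation_spec(
      trend_slope = c(0.002, 0.004, 0.004, 0.0002, 0.001),
      seasonal_amplitude = c(4, 6, 8, 0.5, 0),  # temperature already seasonal
      seasonal_phase = c(0, pi / 3, pi, pi, 0),
      obs_noise_sd = obs_noise_frac * skeleton_sd,
      missing_fraction = missing_fraction,
      seed = site_seeds[n_sites + s])
    series <- add_observation_layer(sim$series, obs, start_month = sim$start["month"])
    out[[s]] <- list(site = sprintf("site%02d", s), start = sim$start,
                     series = series, truth = sim$truth)
    meta[[s]] <- data.frame(
      site = sprintf("site%02d", s), depth = depth[s], area = area[s],
      richness_mean = mean(series[, "richness"], na.rm = TRUE),
      temperature_mean = mean(series[, "temperature"], na.rm = TRUE),
      po4_mean = mean(series[, "po4"], na.rm = TRUE),
      no3_mean = mean(series[, "no3"], na.rm = TRUE),
      biomass_mean = mean(series[, "biomass"], na.rm = TRUE),
      n_years = years[s], stringsAsFactors = FALSE)
  }
  list(sites = out, metadata = do.call(rbind, meta))
}
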