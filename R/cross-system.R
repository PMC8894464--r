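# Cross-site comparison layer: module-strength tables, redundancy analysis
# (RDA) with seeded permutation tests, paired permutation comparisons of
# link strengths, AIC stepwise regression, Kruskal-Wallis group comparison,
# and correlation with permutation significance.

#' Assemble the cross-system table
#'
#' One row per site; four standard response blocks (standardized linkage
#' strengths of links into biomass, links into richness, pairwise feedback
#' loop weights among the endogenous variables, and the four triangular
#' loop weights) and a predictor block of site characteristics (depth, area,
#' long-term mean richness, temperature, PO4, NO3, biomass). Predictors with
#' a log10 flag are transformed, then all predictors are standardized to
#' zero mean / unit variance. Sites with incomplete metadata are dropped
#' with a warning.
#'
#' @param networks list of standardized [site_network] objects.
#' @param metadata data frame with a `site` column and the predictor columns.
#' @param predictors predictor column names to use.
#' @param log10_vars predictors to log10-transform (default: depth, area,
#'   biomass and nutrient means).
#' @param biomass,richness,no3,po4,temperature variable names in the networks.
#' @return An object of class `cross_system_table`: list with `sites`,
#'   `response` (named list of numeric matrices) and `predictors`
#'   (standardized matrix).
#' @export
assemble_cross_system_table <- function(
    networks, metadata,
    predictors = c("depth", "area", "richness_mean", "temperature_mean",
                   "po4_mean", "no3_mean", "biomass_mean"),
    log10_vars = c("depth", "area", "po4_mean", "no3_mean", "biomass_mean"),
    biomass = "biomass", richness = "richness", no3 = "no3", po4 = "po4",
    temperature = "temperature") {
  if (length(networks) < 3L) stop_invalid("need >= 3 sites")
  stopifnot(is.data.frame(metadata), "site" %in% names(metadata))
  for (net in networks) require_standardized(net)
  sites <- vapply(networks, function(n) n$site, character(1))
  endo <- c(richness, biomass, no3, po4)
  others_ef <- c(richness, no3, po4, temperature)
  others_bd <- c(biomass, no3, po4, temperature)
  sls_of <- function(net, cause, effect) get_link(net, cause, effect)$SLS
  links_ef <- t(vapply(networks, function(net) {
    vapply(others_ef, sls_of, numeric(1), net = net, effect = biomass)
  }, numeric(length(others_ef))))
  links_bd <- t(vapply(networks, function(net) {
    vapply(others_bd, sls_of, numeric(1), net = net, effect = richness)
  }, numeric(length(others_bd))))
  colnames(links_ef) <- paste0(others_ef, "->", biomass)
  colnames(links_bd) <- paste0(others_bd, "->", richness)
  pw_pairs <- t(combn(endo, 2))
  pairwise <- t(vapply(networks, function(net) {
    apply(pw_pairs, 1, function(p) pairwise_loop(net, p[1], p[2])$loop_weight)
  }, numeric(nrow(pw_pairs))))
  colnames(pairwise) <- apply(pw_pairs, 1, paste, collapse = "<->")
  triangular <- t(vapply(networks, function(net) {
    vapply(triangular_loops(net, richness, biomass, no3, po4),
           function(l) l$loop_weight, numeric(1))
  }, numeric(4)))
  rownames(links_ef) <- rownames(links_bd) <- rownames(pairwise) <-
    rownames(triangular) <- sites

  meta <- metadata[match(sites, metadata$site), , drop = FALSE]
  missing_pred <- setdiff(predictors, names(meta))
  if (length(missing_pred)) {
    stop_invalid("metadata lacks predictors: ", paste(missing_pred, collapse = ", "))
  }
  X <- as.matrix(meta[, predictors, drop = FALSE])
  for (v in intersect(log10_vars, predictors)) X[, v] <- log10(X[, v])
  complete <- complete.cases(X)
  if (sum(complete) < 3L) stop_invalid("fewer than 3 complete site rows")
  if (any(!complete)) {
    warning("dropping sites with incomplete metadata: ",
            paste(sites[!complete], collapse = ", "), call. = FALSE)
  }
  X <- X[complete, , drop = FALSE]
  X <- scale(X)
  keep_sd <- attr(X, "scaled:scale") > 0
  X <- X[, keep_sd, drop = FALSE]
  structure(list(
    sites = sites[complete],
    response = list(links_ef = links_ef[complete, , drop = FALSE],
                    links_bd = links_bd[complete, , drop = FALSE],
                    pairwise = pairwise[complete, , drop = FALSE],
                    triangular = triangular[complete, , drop = FALSE]),
    predictors = X), class = "cross_system_table")
}

drop_collinear <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping collinear predictor(s): ",
            paste(colnames(X)[-keep], collapse = ", "), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination of a response block on site characteristics:
#' responses are centered, regressed on the predictors by least squares, and
#' the fitted values are eigen-decomposed (via SVD). The explained-variance
#' fraction is the constrained share of total response variance,
#' `trace(cov(fitted)) / trace(cov(response))`. Site and response scores on
#' the first two constrained axes are returned for the biplot, together with
#' predictor scores (correlations of predictors with the site scores).
#'
#' @param Y numeric response matrix (rows = sites) or a
#'   [assemble_cross_system_table()] with `response_block` naming the block.
#' @param X predictor matrix (standardized); defaults to the table's
#'   predictor block when `Y` is a `cross_system_table`.
#' @param response_block block name when `Y` is a table.
#' @param n_perm permutations for the significance test (0 = skip).
#' @param seed integer seed for the permutation test.
#' @return An object of class `rda_result`: `explained_variance`,
#'   `site_scores`, `response_scores`, `predictor_scores`, `eig`,
#'   `permutation_p`.
#' @export
rda_analysis <- function(Y, X = NULL, response_block = "links_ef",
                         n_perm = 0L, seed = 1L) {
  if (inherits(Y, "cross_system_table")) {
    if (is.null(X)) X <- Y$predictors
    Y <- Y$response[[response_block]]
  }
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop_invalid("Y and X must have matching rows")
  X <- drop_collinear(X)
  if (nrow(Y) < ncol(X) + 2L) stop_invalid("need rows >= predictors + 2")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  fit <- lm.fit(cbind(1, X), Yc)
  Yhat <- Yc - fit$residuals
  tot <- sum(Yc^2)
  if (tot == 0) stop_invalid("response block has zero variance")
  expl <- sum(Yhat^2) / tot
  sv <- svd(Yhat)
  naxes <- min(2L, sum(sv$d > 1e-10))
  site_scores <- sv$u[, seq_len(naxes), drop = FALSE] %*%
    diag(sv$d[seq_len(naxes)], naxes)
  response_scores <- sv$v[, seq_len(naxes), drop = FALSE]
  dimnames(site_scores) <- list(rownames(Y), paste0("RDA", seq_len(naxes)))
  dimnames(response_scores) <- list(colnames(Y), paste0("RDA", seq_len(naxes)))
  predictor_scores <- suppressWarnings(cor(X, site_scores))
  p <- if (n_perm > 0) {
    rda_permutation_test(Y, X, n_perm = n_perm, seed = seed)
  } else NA_real_
  structure(list(explained_variance = expl,
                 eig = sv$d^2 / (nrow(Y) - 1),
                 site_scores = site_scores,
                 response_scores = response_scores,
                 predictor_scores = predictor_scores,
                 permutation_p = p, n = nrow(Y)),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("<rda_result> n=%d, explained variance = %.3f, permutation p = %s\n",
              x$n, x$explained_variance,
              if (is.na(x$permutation_p)) "not tested" else
                format(x$permutation_p, digits = 3)))
  invisible(x)
}

rda_explained <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  fit <- lm.fit(cbind(1, X), Yc)
  sum((Yc - fit$residuals)^2) / sum(Yc^2)
}

#' Permutation test for RDA significance
#'
#' Permutes the rows of the predictor block and recomputes the
#' explained-variance statistic; `p = (1 + #\{perm >= observed\}) /
#' (1 + n_perm)`.
#'
#' @param Y,X response and predictor matrices as in [rda_analysis()].
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return permutation p-value.
#' @export
rda_permutation_test <- function(Y, X, n_perm = 10000L, seed = 1L) {
  if (n_perm < 99) stop_invalid("n_perm must be >= 99")
  Y <- as.matrix(Y); X <- drop_collinear(as.matrix(X))
  obs <- rda_explained(Y, X)
  n <- nrow(Y)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      rda_explained(Y, X[sample.int(n), , drop = FALSE])
    }, numeric(1)) >= obs - 1e-12)
  })
  (1 + hits) / (1 + n_perm)
}

#' Paired permutation test for site-matched strengths
#'
#' Tests whether two module strengths differ across sites, pairing by site.
#' The statistic is the mean difference; the null flips the sign of each
#' site's difference independently. Two-sided p with the +1 Monte-Carlo
#' correction, or exact enumeration of all `2^n` sign patterns when
#' `exact = TRUE`.
#'
#' @param a,b numeric vectors of per-site strengths, paired by position.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed integer seed.
#' @param exact enumerate all sign patterns (n <= 20).
#' @return list with `statistic` (mean difference), `p_value`, `n`.
#' @export
paired_permutation_test <- function(a, b, n_perm = 10000L, seed = 1L,
                                    exact = FALSE) {
  if (length(a) != length(b)) stop_invalid("a and b must have equal length")
  d <- a - b
  if (anyNA(d)) {
    d <- d[!is.na(d)]
  }
  n <- length(d)
  if (n < 2L) stop_invalid("need >= 2 complete pairs")
  obs <- abs(mean(d))
  if (exact) {
    if (n > 20L) stop_invalid("exact enumeration limited to n <= 20")
    hits <- 0L
    for (mask in 0:(2^n - 1)) {
      signs <- ifelse(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0, -1, 1)
      if (abs(mean(signs * d)) >= obs - 1e-12) hits <- hits + 1L
    }
    p <- hits / 2^n
  } else {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(b2) {
        abs(mean(d * sample(c(-1, 1), n, replace = TRUE)))
      }, numeric(1)) >= obs - 1e-12)
    })
    p <- (1 + hits) / (1 + n_perm)
  }
  list(statistic = mean(d), p_value = p, n = n)
}

#' Stepwise regression of a module strength on site characteristics
#'
#' Bidirectional stepwise model selection by AIC, starting from the
#' intercept-only model, on standardized predictors. Returns the selected
#' OLS model with its coefficients and overall F test on
#' `(k, n - k - 1)` degrees of freedom.
#'
#' @param y per-site module strength.
#' @param predictors data frame or matrix of site characteristics.
#' @param standardize z-score the predictors first (default `TRUE`).
#' @return list with `model` (the `lm`), `coefficients`, `selected`,
#'   `F`, `df1`, `df2`, `p_value`.
#' @export
stepwise_regression <- function(y, predictors, standardize = TRUE) {
  X <- as.data.frame(predictors)
  if (nrow(X) != length(y)) stop_invalid("y and predictors must match")
  if (length(y) <= ncol(X) + 1L) stop_invalid("need n > predictors + 1")
  if (standardize) X[] <- lapply(X, function(col) as.numeric(scale(col)))
  dat <- cbind(data.frame(.y = y), X)
  null_model <- lm(.y ~ 1, data = dat)
  upper <- as.formula(paste(".y ~", paste(names(X), collapse = " + ")))
  fit <- step(null_model, scope = list(lower = ~1, upper = upper),
              direction = "both", trace = 0)
  selected <- setdiff(names(coef(fit)), "(Intercept)")
  if (length(selected) == 0L) {
    return(list(model = fit, coefficients = coef(fit),
                selected = character(), F = NA_real_,
                df1 = 0L, df2 = length(y) - 1L, p_value = NA_real_))
  }
  fs <- summary(fit)$fstatistic
  list(model = fit, coefficients = coef(fit), selected = selected,
       F = unname(fs["value"]), df1 = unname(fs["numdf"]),
       df2 = unname(fs["dendf"]),
       p_value = unname(pf(fs["value"], fs["numdf"], fs["dendf"],
                           lower.tail = FALSE)))
}

#' Rank-based comparison of strengths across categories
#'
#' Kruskal-Wallis rank-sum test (tie-corrected H statistic, chi-square
#' p-value) across groups of module strengths, e.g. the four triangular
#' feedback types.
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2 values).
#' @return list with `H`, `df`, `p_value`.
#' @export
rank_group_compare <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop_invalid("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop_invalid("every group needs >= 2 values")
  }
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Correlation between module strength and an environmental gradient
#'
#' Pearson (or Spearman) correlation with a permutation p-value obtained by
#' permuting the environmental values; two-sided, +1 corrected.
#'
#' @param module_strengths per-site strengths.
#' @param env_values per-site environmental characteristic.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_with_environment <- function(module_strengths, env_values,
                                       n_perm = 10000L, seed = 1L,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(module_strengths) & !is.na(env_values)
  x <- module_strengths[ok]; e <- env_values[ok]
  n <- length(x)
  if (n < 5L) stop_invalid("need >= 5 complete pairs")
  if (sd(x) == 0 || sd(e) == 0) stop_invalid("zero variance input")
  r_obs <- cor(x, e, method = method)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      abs(cor(x, e[sample.int(n)], method = method))
    }, numeric(1)) >= abs(r_obs) - 1e-12)
  })
  list(r = r_obs, p_value = (1 + hits) / (1 + n_perm), n = n)
}
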