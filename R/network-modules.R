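# Per-site causal networks: quantify every ordered pair, standardize linkage
# strengths within the site (SLS = LS / max LS), and quantify pairwise and
# triangular feedback loops by Neutel's loop weight (geometric mean of the
# member SLS). Networks are standardized separately per site: no cross-site
# pooling of skills.

#' Build a site's causal network
#'
#' Runs [quantify_link()] for every ordered pair of variables. Links into
#' exogenous variables (e.g. temperature) are still quantified — they serve
#' as false-positive diagnostics — but are flagged and excluded from
#' feedback loops.
#'
#' @param series named list of preprocessed series (one per variable, common
#'   time index).
#' @param variables variables to include (default: all of `series`).
#' @param config a [ccm_config()].
#' @param seed integer seed; per-link seeds are derived deterministically.
#' @param exogenous character vector of exogenous variable names.
#' @param site site identifier.
#' @param keep_results keep the full `ccm_result` objects (memory-heavy).
#' @return An object of class `site_network`: list with `site`, `variables`,
#'   `exogenous`, `links` (data frame), `standardized`, and optionally
#'   `results`.
#' @export
build_site_network <- function(series, variables = names(series),
                               config = ccm_config(), seed = 1L,
                               exogenous = character(), site = "site",
                               keep_results = FALSE) {
  if (length(variables) < 2L) stop_invalid("need >= 2 variables")
  if (!all(variables %in% names(series))) {
    stop_invalid("series missing for: ",
                 paste(setdiff(variables, names(series)), collapse = ", "))
  }
  pairs <- expand.grid(cause = variables, effect = variables,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$cause != pairs$effect, , drop = FALSE]
  pairs <- pairs[order(pairs$effect, pairs$cause), , drop = FALSE]
  rows <- vector("list", nrow(pairs))
  results <- if (keep_results) vector("list", nrow(pairs)) else NULL
  for (i in seq_len(nrow(pairs))) {
    ca <- pairs$cause[i]; ef <- pairs$effect[i]
    res <- quantify_link(series[[ca]], series[[ef]], config = config,
                         seed = seed + i, cause_name = ca, effect_name = ef)
    rows[[i]] <- data.frame(
      site = site, cause = ca, effect = ef, E = res$E, k_lag = res$k_lag,
      rho_Lmax = res$rho_Lmax, LS = res$LS, SLS = NA_real_,
      significant = res$significant, se = res$se,
      into_exogenous = ef %in% exogenous, stringsAsFactors = FALSE)
    if (keep_results) results[[i]] <- res
  }
  links <- do.call(rbind, rows)
  rownames(links) <- NULL
  structure(list(site = site, variables = variables, exogenous = exogenous,
                 links = links, standardized = FALSE, results = results),
            class = "site_network")
}

#' @export
print.site_network <- function(x, ...) {
  cat(sprintf("<site_network> %s: %d variables, %d links (%d significant)%s\n",
              x$site, length(x$variables), nrow(x$links),
              sum(x$links$significant),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Standardize linkage strengths within a site
#'
#' Sets `SLS = LS / max(LS)` over all the site's directed links, so the
#' strongest link in the system has SLS 1 and all links are comparable on a
#' relative scale regardless of site-level differences in noise or series
#' length. Idempotent.
#'
#' @param net a [build_site_network()] result.
#' @param significant_only use only significant links in the maximum
#'   (default `FALSE`: all quantified links enter the denominator).
#' @return the network with `SLS` filled and `standardized = TRUE`.
#' @export
standardize_network <- function(net, significant_only = FALSE) {
  stopifnot(inherits(net, "site_network"))
  ls_pool <- if (significant_only) {
    net$links$LS[net$links$significant]
  } else net$links$LS
  mx <- if (length(ls_pool)) max(ls_pool) else 0
  if (!is.finite(mx) || mx <= 0) {
    stop_invalid("all linkage strengths are zero; cannot standardize")
  }
  net$links$SLS <- net$links$LS / mx
  net$standardized <- TRUE
  net
}

get_link <- function(net, cause, effect) {
  i <- which(net$links$cause == cause & net$links$effect == effect)
  if (length(i) != 1L) {
    stop_invalid("no link record for ", cause, " -> ", effect)
  }
  net$links[i, , drop = FALSE]
}

require_standardized <- function(net) {
  stopifnot(inherits(net, "site_network"))
  if (!isTRUE(net$standardized)) {
    stop_invalid("network must be standardized first (standardize_network)")
  }
  invisible(net)
}

new_loop <- function(loop_type, links, weight) {
  structure(list(loop_type = loop_type, links = links,
                 loop_weight = weight,
                 significant = all(links$significant)),
            class = "feedback_loop")
}

#' @export
print.feedback_loop <- function(x, ...) {
  cat(sprintf("<feedback_loop> %s: %s; weight=%.3f %s\n", x$loop_type,
              paste(paste0(x$links$cause, "->", x$links$effect), collapse = ", "),
              x$loop_weight, if (x$significant) "significant" else "n.s."))
  invisible(x)
}

#' Pairwise feedback loop weight
#'
#' Weight of the two-link cycle `A -> B -> A`: the geometric mean
#' `sqrt(SLS(A -> B) * SLS(B -> A))`. The loop is significant iff both
#' member links are individually significant.
#'
#' @param net a standardized [site_network].
#' @param var_a,var_b the two variables.
#' @return An object of class `feedback_loop`.
#' @export
pairwise_loop <- function(net, var_a, var_b) {
  require_standardized(net)
  ab <- get_link(net, var_a, var_b)
  ba <- get_link(net, var_b, var_a)
  links <- rbind(ab, ba)
  new_loop("pairwise", links, sqrt(ab$SLS * ba$SLS))
}

#' Triangular feedback loop weights
#'
#' The four triangular diversity-biomass-nutrient feedbacks, each weighted by
#' the cube root of the product of its member SLS:
#' Type I (contains the diversity-to-biomass link):
#' `I-N = richness -> biomass -> no3 -> richness` and `I-P` with `po4`;
#' Type II (contains the biomass-to-diversity link):
#' `II-N = biomass -> richness -> no3 -> biomass` and `II-P` with `po4`.
#' Exogenous variables never appear in any loop.
#'
#' @param net a standardized [site_network] containing `richness`,
#'   `biomass`, `no3`, `po4`.
#' @param richness,biomass,no3,po4 variable names (override for datasets
#'   using different identifiers).
#' @return named list of four `feedback_loop` objects
#'   (`I-N`, `I-P`, `II-N`, `II-P`).
#' @export
triangular_loops <- function(net, richness = "richness", biomass = "biomass",
                             no3 = "no3", po4 = "po4") {
  require_standardized(net)
  need <- c(richness, biomass, no3, po4)
  if (!all(need %in% net$variables)) {
    stop_invalid("network lacks variables: ",
                 paste(setdiff(need, net$variables), collapse = ", "))
  }
  tri <- function(type, v1, v2, v3) {
    l <- rbind(get_link(net, v1, v2), get_link(net, v2, v3),
               get_link(net, v3, v1))
    new_loop(type, l, prod(l$SLS)^(1 / 3))
  }
  list(
    "I-N" = tri("I-N", richness, biomass, no3),
    "I-P" = tri("I-P", richness, biomass, po4),
    "II-N" = tri("II-N", biomass, richness, no3),
    "II-P" = tri("II-P", biomass, richness, po4))
}

#' Directional bias of a pairwise feedback
#'
#' `SLS(A -> B) - SLS(B -> A)`: positive when the forward direction
#' dominates. Antisymmetric in its arguments.
#'
#' @param net a standardized [site_network].
#' @param var_a,var_b the two variables.
#' @return signed numeric scalar.
#' @export
directional_bias <- function(net, var_a, var_b) {
  require_standardized(net)
  get_link(net, var_a, var_b)$SLS - get_link(net, var_b, var_a)$SLS
}

#' Edge recovery metrics against a ground-truth network
#'
#' Compares the significant links of an inferred network with the known
#' edges of a synthetic generator. Self-links and links into exogenous
#' variables are excluded from both sets. With no predicted links, precision
#' is 1 by the empty-set convention (no false positives were asserted); with
#' an empty truth, recall is 1.
#'
#' @param net a [site_network] built on synthetic data.
#' @param truth a [ground_truth_network()].
#' @return named numeric `c(precision, recall)` with counts in attributes.
#' @export
recovery_metrics <- function(net, truth) {
  stopifnot(inherits(net, "site_network"), inherits(truth, "ground_truth_network"))
  pred <- net$links[net$links$significant & !net$links$into_exogenous, ,
                    drop = FALSE]
  pred_keys <- paste(pred$cause, pred$effect, sep = "->")
  te <- truth$edges[!(truth$edges$effect %in% net$exogenous), , drop = FALSE]
  true_keys <- paste(te$cause, te$effect, sep = "->")
  tp <- sum(pred_keys %in% true_keys)
  precision <- if (length(pred_keys) == 0L) 1 else tp / length(pred_keys)
  recall <- if (length(true_keys) == 0L) 1 else tp / length(true_keys)
  structure(c(precision = precision, recall = recall),
            tp = tp, n_pred = length(pred_keys), n_true = length(true_keys))
}
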