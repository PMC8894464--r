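# build a small site_network by hand so the algebraic operations can be
# tested exactly, without running CCM
manual_network <- function(ls_values, significant = NULL,
                           variables = c("richness", "biomass", "no3", "po4",
                                         "temperature"),
                           exogenous = "temperature") {
  pairs <- expand.grid(cause = variables, effect = variables,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$cause != pairs$effect, ]
  pairs <- pairs[order(pairs$effect, pairs$cause), ]
  n <- nrow(pairs)
  ls <- rep_len(ls_values, n)
  if (is.null(significant)) significant <- rep(TRUE, n)
  links <- data.frame(site = "m", cause = pairs$cause, effect = pairs$effect,
                      E = 3L, k_lag = 0L, rho_Lmax = ls, LS = ls,
                      SLS = NA_real_, significant = rep_len(significant, n),
                      se = 0.01, into_exogenous = pairs$effect %in% exogenous,
                      stringsAsFactors = FALSE)
  rownames(links) <- NULL
  structure(list(site = "m", variables = variables, exogenous = exogenous,
                 links = links, standardized = FALSE, results = NULL),
            class = "site_network")
}

set_sls <- function(net, cause, effect, value) {
  i <- which(net$links$cause == cause & net$links$effect == effect)
  net$links$SLS[i] <- value
  net
}

test_that("standardization divides by the in-site maximum and is idempotent", {
  net <- manual_network(c(0.8, 0.4, 0.2))
  net$links$LS <- rep(c(0.8, 0.4, 0.2), length.out = nrow(net$links))
  st <- standardize_network(net)
  expect_equal(sort(unique(st$links$SLS)), c(0.25, 0.5, 1))
  expect_equal(max(st$links$SLS), 1)
  st2 <- standardize_network(st)
  expect_identical(st$links$SLS, st2$links$SLS)
  # all-zero network cannot be standardized
  z <- manual_network(0)
  expect_error(standardize_network(z), "zero")
})

test_that("single-link dominance gives SLS 1 to that link", {
  net <- manual_network(0)
  net$links$LS[1] <- 0.6
  st <- standardize_network(net)
  expect_equal(st$links$SLS[1], 1)
  expect_true(all(st$links$SLS[-1] == 0))
})

test_that("pairwise loop weight is the geometric mean of both directions", {
  net <- standardize_network(manual_network(0.5))
  net <- set_sls(net, "richness", "biomass", 0.9)
  net <- set_sls(net, "biomass", "richness", 0.4)
  lp <- pairwise_loop(net, "richness", "biomass")
  expect_equal(lp$loop_weight, 0.6, tolerance = 1e-12)
  # annihilation and identity
  net0 <- set_sls(net, "biomass", "richness", 0)
  expect_equal(pairwise_loop(net0, "richness", "biomass")$loop_weight, 0)
  nets <- set_sls(set_sls(net, "richness", "biomass", 0.7),
                  "biomass", "richness", 0.7)
  expect_equal(pairwise_loop(nets, "richness", "biomass")$loop_weight, 0.7)
})

test_that("triangular loops follow the Type I/II directions and cube-root identity", {
  net <- standardize_network(manual_network(0.5))
  net$links$SLS <- rep(0.8, nrow(net$links))
  tl <- triangular_loops(net)
  expect_named(tl, c("I-N", "I-P", "II-N", "II-P"))
  expect_equal(tl[["I-N"]]$loop_weight, 0.8, tolerance = 1e-12)
  expect_equal(paste(tl[["I-N"]]$links$cause, tl[["I-N"]]$links$effect,
                     sep = "->"),
               c("richness->biomass", "biomass->no3", "no3->richness"))
  expect_equal(paste(tl[["II-P"]]$links$cause, tl[["II-P"]]$links$effect,
                     sep = "->"),
               c("biomass->richness", "richness->po4", "po4->biomass"))
  # (1, 1, 0.125) -> cube root of 1/8
  net2 <- set_sls(set_sls(set_sls(net, "richness", "biomass", 1),
                          "biomass", "no3", 1), "no3", "richness", 0.125)
  expect_equal(triangular_loops(net2)[["I-N"]]$loop_weight, 0.5,
               tolerance = 1e-12)
  # temperature can never sit inside a loop
  members <- unlist(lapply(tl, function(l) c(l$links$cause, l$links$effect)))
  expect_false("temperature" %in% members)
})

test_that("loop weights sit between the min and max member SLS", {
  set.seed(3)
  net <- standardize_network(manual_network(runif(20, 0.05, 0.9)))
  for (pair in list(c("richness", "biomass"), c("no3", "po4"))) {
    lp <- pairwise_loop(net, pair[1], pair[2])
    expect_gte(lp$loop_weight, min(lp$links$SLS))
    expect_lte(lp$loop_weight, max(lp$links$SLS))
  }
  for (l in triangular_loops(net)) {
    expect_gte(l$loop_weight, min(l$links$SLS))
    expect_lte(l$loop_weight, max(l$links$SLS))
  }
})

test_that("loop weights are invariant to rescaling all LS by a constant", {
  set.seed(4)
  base <- manual_network(runif(20, 0.1, 0.8))
  scaled <- base
  scaled$links$LS <- scaled$links$LS * 0.37
  w1 <- vapply(triangular_loops(standardize_network(base)),
               function(l) l$loop_weight, numeric(1))
  w2 <- vapply(triangular_loops(standardize_network(scaled)),
               function(l) l$loop_weight, numeric(1))
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("directional bias is the SLS difference and antisymmetric", {
  net <- standardize_network(manual_network(0.5))
  net <- set_sls(net, "richness", "biomass", 1.0)
  net <- set_sls(net, "biomass", "richness", 0.4)
  expect_equal(directional_bias(net, "richness", "biomass"), 0.6,
               tolerance = 1e-12)
  expect_equal(directional_bias(net, "biomass", "richness"), -0.6,
               tolerance = 1e-12)
  nets <- set_sls(net, "biomass", "richness", 1.0)
  expect_equal(directional_bias(nets, "richness", "biomass"), 0)
})

test_that("loop significance requires every member link significant", {
  net <- manual_network(0.5)
  net$links$significant <- TRUE
  i <- which(net$links$cause == "biomass" & net$links$effect == "no3")
  net$links$significant[i] <- FALSE
  st <- standardize_network(net)
  tl <- triangular_loops(st)
  expect_false(tl[["I-N"]]$significant)   # contains biomass->no3
  expect_true(tl[["II-P"]]$significant)
})

test_that("recovery metrics implement the empty-set conventions", {
  spec <- mock_ecosystem_spec()
  truth <- ground_truth_network(spec)
  # perfect detection
  net <- manual_network(0.5, significant = FALSE)
  keys <- paste(net$links$cause, net$links$effect, sep = "->")
  tkeys <- paste(truth$edges$cause, truth$edges$effect, sep = "->")
  net$links$significant <- keys %in% tkeys
  pr <- recovery_metrics(net, truth)
  expect_equal(as.numeric(pr), c(1, 1))
  # nothing significant: recall 0, precision 1 by convention
  net0 <- manual_network(0.5, significant = FALSE)
  pr0 <- recovery_metrics(net0, truth)
  expect_equal(as.numeric(pr0), c(1, 0))
  # empty truth with one false positive: precision 0
  empty_spec <- coupling_spec(c("richness", "biomass", "no3", "po4",
                                "temperature"),
                              rep(3.6, 5), diag(0.5, 5),
                              exogenous_flags = c(rep(FALSE, 4), TRUE))
  etruth <- ground_truth_network(empty_spec)
  net1 <- manual_network(0.5, significant = FALSE)
  net1$links$significant[1] <- TRUE
  pr1 <- recovery_metrics(net1, etruth)
  expect_equal(as.numeric(pr1), c(0, 1))
})

test_that("variable relabeling permutes the network consistently", {
  b <- benchmark_pair(30, n = 200)
  series <- list(A = b$x, B = b$y)
  cfg <- test_config(n_subsamples = 30, n_L = 10)
  net1 <- build_site_network(series, config = cfg, seed = 5)
  net2 <- build_site_network(list(B = b$y, A = b$x), config = cfg, seed = 5)
  l1 <- net1$links[order(net1$links$cause), ]
  l2 <- net2$links[order(l2_order <- net2$links$cause), ]
  expect_equal(l1$LS, l2$LS, tolerance = 1e-12)
  expect_error(build_site_network(series, variables = "A", config = cfg),
               ">= 2")
})
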