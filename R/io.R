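# Readers and writers for the long-format monitoring CSV (site, year, month,
# variable, value; empty cell = missing), edge lists, loops, and run
# configuration in YAML.

#' Write site datasets as long-format CSV
#'
#' Columns `site, year, month, variable, value`; missing values are written
#' as empty cells. Values are formatted with 17 significant digits so a
#' write/read round trip is bit-identical.
#'
#' @param sites list of site datasets (each with `site`, `start`, `series`),
#'   as produced by [simulate_study()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(sites, path) {
  rows <- lapply(sites, function(s) {
    n <- nrow(s$series)
    key <- (s$start[1] * 12L + s$start[2] - 1L) + seq_len(n) - 1L
    do.call(rbind, lapply(colnames(s$series), function(v) {
      data.frame(site = s$site, year = key %/% 12L, month = key %% 12L + 1L,
                 variable = v,
                 value = ifelse(is.na(s$series[, v]), "",
                                sprintf("%.17g", s$series[, v])),
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format monitoring CSV
#'
#' Parses the long format written by [write_long_csv()] into one
#' [monthly_series()] per (site, variable), each on a contiguous monthly
#' index with missing months as `NA`. Duplicate (site, year, month,
#' variable) rows and unparseable values are errors that name the
#' offending lines.
#'
#' @param path CSV path with header `site, year, month, variable, value`.
#' @return named list of sites; each site is a named list of
#'   [monthly_series()].
#' @export
read_long_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(value = "character"))
  need <- c("site", "year", "month", "variable", "value")
  if (!all(need %in% names(df))) {
    stop_invalid("CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$month < 1 | df$month > 12)) {
    stop_invalid("month out of 1..12 on line(s) ",
                 paste(head(which(df$month < 1 | df$month > 12) + 1L, 5),
                       collapse = ", "))
  }
  key <- paste(df$site, df$year, df$month, df$variable)
  if (anyDuplicated(key)) {
    stop_invalid("duplicate (site, year, month, variable) rows: lines ",
                 paste(head(which(duplicated(key)) + 1L, 5), collapse = ", "))
  }
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.na(df$value) & df$value != "" & is.na(val))
  if (length(bad)) {
    stop_invalid("unparseable value on line(s) ",
                 paste(head(bad + 1L, 5), collapse = ", "))
  }
  df$value_num <- val
  out <- list()
  for (s in unique(df$site)) {
    ds <- df[df$site == s, , drop = FALSE]
    out[[s]] <- list()
    for (v in unique(ds$variable)) {
      dv <- ds[ds$variable == v, , drop = FALSE]
      k <- dv$year * 12L + (dv$month - 1L)
      kmin <- min(k); kmax <- max(k)
      values <- rep(NA_real_, kmax - kmin + 1L)
      values[k - kmin + 1L] <- dv$value_num
      out[[s]][[v]] <- monthly_series(
        values, start = c(kmin %/% 12L, kmin %% 12L + 1L),
        site = s, variable = v)
    }
  }
  out
}

#' Write a ground-truth edge list as CSV
#' @param truth a [ground_truth_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth_network"))
  write.csv(truth$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a site network's links as CSV
#' @param net a [site_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  stopifnot(inherits(net, "site_network"))
  write.csv(net$links, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize per-link CCM evidence as JSON
#' @param result a [quantify_link()] result.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
link_record_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "ccm_result"))
  rec <- list(cause = result$cause, effect = result$effect, E = result$E,
              k_lag = result$k_lag, rho_Lmax = result$rho_Lmax,
              LS = result$LS, kendall_tau = result$convergence$kendall_tau,
              kendall_p = result$convergence$kendall_p,
              delta_rho = result$convergence$delta_rho,
              fisher_p = result$convergence$fisher_p,
              significant = result$significant, se = result$se)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Run configuration
#'
#' Assembles and validates every setting of an end-to-end run, with defaults
#' matching the standard protocol (`E` in 2..20, lags 0..3 months, monthly
#' `tau` 1, 500 bootstrap resamples, 10,000 permutations).
#'
#' @param seed master seed of the run.
#' @param n_sites number of simulated sites (when simulating).
#' @param input_csv optional path to a long-format CSV to analyse instead of
#'   simulating.
#' @param exogenous exogenous variable names.
#' @param n_perm cross-system permutation count.
#' @param ... overrides passed to [ccm_config()].
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_sites = 19L, input_csv = NULL,
                       exogenous = "temperature", n_perm = 10000L, ...) {
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 input_csv = input_csv, exogenous = exogenous,
                 n_perm = as.integer(n_perm), ccm = ccm_config(...)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys mirror the arguments of [run_config()] with
#'   CCM settings under a `ccm:` block.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ccm_args <- y$ccm %||% list()
  do.call(run_config, c(list(seed = y$seed %||% 1L,
                             n_sites = y$n_sites %||% 19L,
                             input_csv = y$input_csv,
                             exogenous = y$exogenous %||% "temperature",
                             n_perm = y$n_perm %||% 10000L),
                        ccm_args))
}

#' Run the end-to-end pipeline
#'
#' Simulates (or reads) the multi-site dataset, preprocesses every series,
#' builds and standardizes the per-site causal networks, quantifies
#' pairwise and triangular feedback loops, assembles the cross-system table,
#' and runs the redundancy analysis on the links-into-biomass block. All
#' randomness derives from `config$seed`; rerunning with the same
#' configuration reproduces every output exactly. Sites whose series fail a
#' stage (e.g. a missing variable) are skipped with a warning and the run
#' continues.
#'
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, edge lists, loops, the
#'   cross-system table and a JSON manifest are written there.
#' @return list with `networks`, `loops`, `table`, `rda`, `metadata`,
#'   `manifest` (and `truths` when simulating).
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character()
  note <- function(...) {
    warnings_log <<- c(warnings_log, paste0(...))
    warning(..., call. = FALSE)
  }
  if (is.null(config$input_csv)) {
    study <- simulate_study(config$n_sites, seed = config$seed)
    sites <- study$sites
    metadata <- study$metadata
    truths <- lapply(sites, function(s) s$truth)
    names(truths) <- vapply(sites, function(s) s$site, character(1))
    site_series <- lapply(sites, function(s) {
      lapply(as.data.frame(s$series), monthly_series,
             start = s$start, site = s$site)
    })
    names(site_series) <- names(truths)
  } else {
    site_series <- read_long_csv(config$input_csv)
    metadata <- NULL
    truths <- NULL
  }
  networks <- list()
  loops <- list()
  vars <- c("richness", "biomass", "no3", "po4", "temperature")
  for (i in seq_along(site_series)) {
    sname <- names(site_series)[i]
    sl <- site_series[[i]]
    if (!all(vars %in% names(sl))) {
      note("site ", sname, " lacks variables: ",
           paste(setdiff(vars, names(sl)), collapse = ", "), "; skipped")
      next
    }
    net <- tryCatch({
      proc <- lapply(sl[vars], preprocess)
      n <- build_site_network(proc, vars, config = config$ccm,
                              seed = config$seed + i * 1000L,
                              exogenous = config$exogenous, site = sname)
      standardize_network(n)
    }, error = function(e) {
      note("site ", sname, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(net)) next
    networks[[sname]] <- net
    endo <- setdiff(vars, config$exogenous)
    pw <- apply(t(combn(endo, 2)), 1, function(p) {
      pairwise_loop(net, p[1], p[2])
    })
    names(pw) <- apply(t(combn(endo, 2)), 1, paste, collapse = "<->")
    loops[[sname]] <- list(pairwise = pw, triangular = triangular_loops(net))
  }
  if (length(networks) == 0L) stop_invalid("no site could be analysed")
  table <- NULL; rda_res <- NULL
  if (!is.null(metadata) && length(networks) >= 3L) {
    table <- assemble_cross_system_table(networks, metadata)
    rda_res <- tryCatch(
      rda_analysis(table, response_block = "links_ef",
                   n_perm = config$n_perm, seed = config$seed),
      error = function(e) {
        note("cross-system RDA skipped: ", conditionMessage(e))
        NULL
      })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ccmnet")),
    seed = config$seed, n_sites = config$n_sites,
    exogenous = config$exogenous, n_perm = config$n_perm,
    ccm = unclass(config$ccm), warnings = warnings_log)
  bundle <- list(networks = networks, loops = loops, table = table,
                 rda = rda_res, metadata = metadata, truths = truths,
                 manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (sname in names(networks)) {
      write_network_csv(networks[[sname]],
                        file.path(output_dir, paste0("links_", sname, ".csv")))
    }
    loop_rows <- do.call(rbind, lapply(names(loops), function(sname) {
      ll <- c(loops[[sname]]$pairwise, loops[[sname]]$triangular)
      do.call(rbind, lapply(names(ll), function(nm) {
        l <- ll[[nm]]
        data.frame(site = sname, loop = nm, loop_type = l$loop_type,
                   members = paste(paste0(l$links$cause, "->", l$links$effect),
                                   collapse = ";"),
                   loop_weight = l$loop_weight, significant = l$significant,
                   stringsAsFactors = FALSE)
      }))
    }))
    write.csv(loop_rows, file.path(output_dir, "loops.csv"),
              row.names = FALSE, quote = FALSE)
    if (!is.null(table)) {
      cst <- do.call(cbind, table$response)
      write.csv(data.frame(site = table$sites, cst, check.names = FALSE),
                file.path(output_dir, "cross_system.csv"), row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
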