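# Reproducible experiment driver: plain-text key = value configs in, a
# deterministic directory of JSON/CSV results out.  Every numeric report
# embeds its provenance: preset parameters, seeds, Monte Carlo sizes,
# tolerances and the package version.  Reports contain no timestamps, so a
# rerun with the same config is byte-identical.

parse_config_value <- function(v) {
  v <- trimws(v)
  if (grepl(",", v)) return(unlist(lapply(strsplit(v, ",")[[1]],
                                          parse_config_value)))
  if (v %in% c("true", "TRUE", "True")) return(TRUE)
  if (v %in% c("false", "FALSE", "False")) return(FALSE)
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  gsub('^"|"$', "", v)
}

#' Read a key = value experiment config
#'
#' Plain-text format: one `key = value` per line, `#` comments, commas for
#' vectors.  Returns a named list with line-precise errors on malformed
#' input.
#'
#' @param path config file path.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    if (!grepl("=", ln))
      stop("config line ", i, " is not 'key = value': ", trimws(lines[i]))
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    if (!nzchar(key)) stop("config line ", i, " has an empty key")
    out[[key]] <- parse_config_value(paste(kv[-1], collapse = "="))
  }
  out
}

config_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

est_report <- function(est) {
  list(bits = nats_to_bits(est$point),
       lower_bits = nats_to_bits(est$lower),
       upper_bits = nats_to_bits(est$upper),
       stderr_bits = nats_to_bits(est$stderr),
       n_x = est$n_x, n_theta = est$n_theta)
}

resolve_config_prior <- function(cfg, spec, seed, log) {
  prior_kind <- config_get(cfg, "prior", "jeffreys")
  n_prior <- config_get(cfg, "n_prior", 2e4)
  if (prior_kind == "jeffreys") {
    log("sampling Jeffreys prior: n =", n_prior)
    sample_jeffreys(spec, n = n_prior, seed = child_seed(seed, 1L))
  } else if (prior_kind == "lognormal") {
    sample_lognormal(spec, n = n_prior, seed = child_seed(seed, 1L))
  } else if (prior_kind == "optimize") {
    log("solving for the optimal prior")
    optimize_prior(spec, seed = child_seed(seed, 1L),
                   tol_bits = config_get(cfg, "tol_bits", 0.1),
                   K_init = config_get(cfg, "K_init", 20L),
                   max_iter = config_get(cfg, "max_iter", 40L),
                   n_x = config_get(cfg, "n_x_solver", 600L))
  } else {
    # a path to an atomic prior file
    read_prior(prior_kind)
  }
}

#' Run a configured experiment
#'
#' Tasks: `score` (mutual information and worst-case bias of a prior on a
#' preset), `optimize` (solve for the optimal atomic prior and score it),
#' `posterior-sweep` (posterior deviation over synthetic observations), and
#' `deff-curve` (effective dimensionality across noise levels).  Writes
#' `result.json`, `config.txt` (echo), `log.txt` and, where a prior is
#' produced, `prior.csv` into `out_dir`.  Reruns with identical config and
#' seed are byte-identical.
#'
#' @param config path to a key = value config file, or an equivalent named
#'   list.
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `out_dir` entry.
#' @return the result list, invisibly.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- out_dir %||% config_get(cfg, "out_dir")
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logf <- function(...) {
    msg <- paste(...)
    log_lines <<- c(log_lines, msg)
    invisible(NULL)
  }
  flush_log <- function() writeLines(log_lines, file.path(out_dir, "log.txt"))
  on.exit(flush_log(), add = TRUE)

  task <- config_get(cfg, "task", "score")
  seed <- as.integer(config_get(cfg, "seed", 1))
  preset <- config_get(cfg, "preset")
  if (is.null(preset)) stop("config must name a preset")
  spec <- build_preset(preset, sigma = config_get(cfg, "sigma"))
  n_x <- as.integer(config_get(cfg, "n_x", 2000L))
  logf("task:", task, "preset:", preset, "seed:", seed)

  # echo config for provenance
  writeLines(vapply(names(cfg), function(k)
    paste(k, "=", paste(cfg[[k]], collapse = ",")), ""),
    file.path(out_dir, "config.txt"))

  provenance <- list(preset = preset_provenance(spec), seed = seed,
                     n_x = n_x, task = task,
                     package_version = as.character(
                       utils::packageVersion("infoprior")))
  result <- list(provenance = provenance)

  if (task == "score") {
    prior <- resolve_config_prior(cfg, spec, seed, logf)
    if (inherits(prior, "weighted_sample") &&
        !is.null(prior$diagnostics$rhat))
      logf("prior MCMC: acceptance", signif(prior$diagnostics$acceptance, 3),
           "rhat", signif(prior$diagnostics$rhat, 4))
    mi <- mutual_information(prior, spec, n_x = min(n_x, 1000L),
                             seed = child_seed(seed, 2L),
                             n_outer = as.integer(config_get(cfg, "n_outer",
                                                             500L)),
                             n_theta = as.integer(config_get(cfg, "n_theta",
                                                             10000L)))
    B <- worst_case_bias(prior, spec, n_x = n_x,
                         seed = child_seed(seed, 3L), mi = mi)
    result$I <- est_report(mi)
    result$B <- c(est_report(B), list(theta_star = B$theta_star))
    if (inherits(prior, "atomic_prior"))
      write_prior(prior, file.path(out_dir, "prior.csv"))
  } else if (task == "optimize") {
    prior <- optimize_prior(spec, seed = child_seed(seed, 1L),
                            tol_bits = config_get(cfg, "tol_bits", 0.1),
                            K_init = as.integer(config_get(cfg, "K_init",
                                                           20L)),
                            max_iter = as.integer(config_get(cfg, "max_iter",
                                                             40L)),
                            n_x = as.integer(config_get(cfg, "n_x_solver",
                                                        600L)))
    sol <- attr(prior, "solver")
    write_prior(prior, file.path(out_dir, "prior.csv"))
    result$K <- nrow(prior$locations)
    result$I_trace_bits <- nats_to_bits(sol$I_history)
    result$iterations <- sol$iterations
    result$converged <- sol$converged
    result$B <- est_report(sol$B)
    logf("solver:", sol$iterations, "iterations, converged:", sol$converged)
  } else if (task == "posterior-sweep") {
    n_obs <- as.integer(config_get(cfg, "n_obs", 30L))
    opt <- optimize_prior(spec, seed = child_seed(seed, 1L),
                          max_iter = as.integer(config_get(cfg, "max_iter",
                                                           25L)))
    prior <- resolve_config_prior(cfg, spec, child_seed(seed, 2L), logf)
    records <- list()
    mi <- NULL
    for (i in seq_len(n_obs)) {
      a <- with_seed_or_not(child_seed(seed, 100L + i),
                            sample.int(nrow(opt$locations), 1L,
                                       prob = opt$weights))
      x <- simulate_observation(spec, opt$locations[a, ],
                                seed = child_seed(seed, 200L + i))
      rep_i <- posterior_deviation(spec, prior, x,
                                   seed = child_seed(seed, 300L + i))
      b <- bias_pressure(rep_i$theta_hat, prior, spec, n_x = n_x,
                         seed = child_seed(seed, 400L + i), mi = mi,
                         method = "plugin")
      mi <- b$I
      records[[i]] <- list(delta = rep_i$delta,
                           b_bits = nats_to_bits(b$point),
                           theta_hat = rep_i$theta_hat)
      logf(sprintf("obs %d: Delta = %.2f, b = %.2f bits", i, rep_i$delta,
                   nats_to_bits(b$point)))
    }
    result$observations <- records
    result$median_delta <- stats::median(vapply(records, `[[`, 0, "delta"))
  } else if (task == "deff-curve") {
    sigmas <- config_get(cfg, "sigmas", c(1, 0.5, 0.25, 0.125))
    curve <- effective_dimension(spec, sigmas, seed = child_seed(seed, 1L),
                                 max_iter = as.integer(config_get(
                                   cfg, "max_iter", 25L)))
    result$sigmas <- curve$sigmas
    result$I_bits <- curve$I_bits
    result$d_eff <- curve$d_eff
    result$slope_stderr <- curve$slope_stderr
    result$converged <- curve$converged
  } else stop("unknown task '", task, "'")

  write_json_report(result, file.path(out_dir, "result.json"))
  invisible(result)
}
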