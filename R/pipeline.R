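# Pipeline driver: simulate and/or read inputs, fit kinetics, run the
# categorical tests, assemble a reproducible JSON report.

REPORT_SCHEMA_VERSION <- 1L

#' Lightweight leveled logging
#'
#' Writes `[level] stage: message` lines to standard error.  The threshold is
#' controlled by `options(uvkin.log_level = "debug"|"info"|"warn"|"quiet")`
#' (default `"info"`).
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`.
#' @param stage Pipeline stage label.
#' @param ... Message parts, pasted together.
#' @return Invisibly, whether the line was emitted.
#' @export
uvkin_log <- function(level = "info", stage = "uvkin", ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  threshold <- levels[[getOption("uvkin.log_level", "info")]]
  emit <- levels[[level]] >= threshold
  if (emit)
    message(sprintf("[%s] %s: %s", level, stage, paste0(..., collapse = "")))
  invisible(emit)
}

# 32-bit FNV-1a over the serialized config: a stable fingerprint for
# reproducibility audits, not a cryptographic hash.
config_hash <- function(cfg) {
  bytes <- serialize(cfg, connection = NULL, version = 3L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

fit_to_record <- function(fit, label = NULL) {
  rec <- unclass(fit)
  rec$label <- label
  rec[!vapply(rec, is.null, logical(1))]
}

test_to_record <- function(res) {
  rec <- unclass(res)
  rec[!vapply(rec, is.null, logical(1))]
}

#' Run the simulate -> fit -> stats -> report pipeline
#'
#' Executes, in order and as requested by the configuration: synthetic
#' survival-series generation ([simulate_survival_series()]), survival-series
#' reading and kinetic fitting ([fit_survival()]), contingency-table tests
#' ([chisq_test()], [fisher_exact()]) and the two-way ANOVA
#' ([two_way_anova()]); the results are assembled into a versioned report
#' with a provenance block (config echo, config hash, seed, timestamp,
#' package version).
#'
#' Recognised configuration keys: lamp/culture keys (see [read_config()]),
#' `fit_mode` (`"time"`/`"fluence"`), `n0`, `seed`, `series` (character
#' vector of survival CSV paths), `simulate` (list of [sim_spec()]
#' arguments), `contingency` (path; tested with chi-square, and Fisher when
#' 2 x 2), `treatment` (path; two-way ANOVA).
#'
#' @param config A named list or the path of a YAML config file.
#' @param out Optional path; when given the report is written there as JSON.
#' @param seed Optional seed overriding the config's `seed` key.
#' @return The report, an object of class `"uvkin_report"` (a nested list).
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  if (!is.list(config))
    validation_error("'config' must be a list or a config file path")
  seed <- seed %||% config$seed %||% 1L
  check_scalar_number(seed, "seed")
  has_input <- !is.null(config$series) || !is.null(config$simulate) ||
    !is.null(config$contingency) || !is.null(config$treatment)
  if (!has_input)
    validation_error("config names no input: give 'series', 'simulate', 'contingency' or 'treatment'")

  hash <- config_hash(config)
  uvkin_log("info", "config", "hash=", hash, " seed=", seed)
  irr <- config_from_keys(config)
  mode <- config$fit_mode %||% "time"
  check_mode(mode)

  fits <- list()
  series_list <- list()

  if (!is.null(config$simulate)) {
    spec <- do.call(sim_spec, modifyList(config$simulate, list(seed = seed)))
    uvkin_log("info", "simulate", spec$replicates, " replicate(s), k_true=",
              spec$k_true, ", seed=", seed)
    sims <- simulate_survival_series(spec)
    names(sims) <- sprintf("sim%03d", seq_along(sims))
    series_list <- c(series_list, sims)
  }
  if (!is.null(config$series)) {
    for (p in config$series) {
      uvkin_log("info", "read", p)
      series_list[[basename(p)]] <- read_survival_csv(p, n0 = config$n0)
    }
  }
  for (nm in names(series_list)) {
    uvkin_log("info", "fit", nm, " (", mode, " mode)")
    fits[[nm]] <- fit_to_record(
      fit_survival(series_list[[nm]], config = irr, mode = mode), nm)
  }

  stats_out <- list()
  if (!is.null(config$contingency)) {
    tab <- read_contingency_csv(config$contingency)
    uvkin_log("info", "stats", "chi-square on ", config$contingency)
    stats_out$chisq <- test_to_record(chisq_test(tab))
    if (all(dim(tab) == c(2L, 2L)))
      stats_out$fisher <- test_to_record(fisher_exact(tab))
  }
  if (!is.null(config$treatment)) {
    grid <- read_treatment_csv(config$treatment)
    uvkin_log("info", "stats", "two-way ANOVA on ", config$treatment)
    aovr <- two_way_anova(grid)
    stats_out$anova <- lapply(aovr, test_to_record)
  }

  report <- structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    provenance = list(
      package = "uvkin",
      version = as.character(packageVersion("uvkin")),
      seed = as.integer(seed),
      config_hash = hash,
      config = config,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    fits = fits,
    stats = stats_out), class = "uvkin_report")

  if (!is.null(out)) write_run_report(report, out)
  report
}

#' Write a pipeline report as JSON
#'
#' @param report A `"uvkin_report"` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  if (!inherits(report, "uvkin_report"))
    validation_error("'report' must be a uvkin_report")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a pipeline report back from JSON
#'
#' @param path Path of a JSON report written by [write_run_report()].
#' @return A `"uvkin_report"`.
#' @export
read_run_report <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  structure(rep, class = "uvkin_report")
}

#' @export
print.uvkin_report <- function(x, ...) {
  cat(sprintf("uvkin pipeline report (schema %s)\n", x$schema_version))
  cat(sprintf("  seed %s, config %s, %s\n", x$provenance$seed,
              x$provenance$config_hash, x$provenance$timestamp))
  cat(sprintf("  %d kinetic fit(s), %d statistics block(s)\n",
              length(x$fits), length(x$stats)))
  invisible(x)
}
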