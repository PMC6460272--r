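# CSV dialects and key-value configuration files.
#
# Survival series:    time_min,cfu            (one series per file)
# Contingency table:  header = column labels; first column = row labels
# Treatment grid:     treatment,time_min,replicate,cfu

#' Read a survival series from CSV
#'
#' Expects columns `time_min` (numeric, strictly increasing) and `cfu`
#' (non-negative integers).  When `n0` is not supplied the file must contain
#' a `t = 0` row, whose count is used as the control population.
#'
#' @param path Path to the CSV file.
#' @param n0 Optional control population (CFU); overrides the t = 0 row.
#' @param max_count Plate-countability ceiling passed to [survival_series()].
#' @return A [survival_series()].
#' @export
read_survival_csv <- function(path, n0 = NULL, max_count = 1e9) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) parse_error(sprintf(
                   "cannot parse %s: %s", path, conditionMessage(e))))
  need <- c("time_min", "cfu")
  miss <- setdiff(need, names(df))
  if (length(miss))
    parse_error(sprintf("%s: missing column(s): %s", path,
                        paste(miss, collapse = ", ")))
  if (!is.numeric(df$time_min))
    parse_error(sprintf("%s: 'time_min' must be numeric", path))
  if (!is.numeric(df$cfu))
    parse_error(sprintf("%s: 'cfu' must be numeric", path))
  bad <- which(!is.finite(df$cfu) | df$cfu < 0 | df$cfu != round(df$cfu))
  if (length(bad))
    parse_error(sprintf("%s: non-integer or negative 'cfu' at row(s): %s",
                        path, paste(bad + 1L, collapse = ", ")))  # +1: header
  if (any(diff(df$time_min) <= 0)) {
    at <- which(diff(df$time_min) <= 0)[1]
    parse_error(sprintf("%s: 'time_min' not strictly increasing at row %d",
                        path, at + 2L))
  }
  survival_series(df$time_min, df$cfu, n0 = n0, max_count = max_count)
}

#' Write a survival series to CSV
#'
#' @param series A [survival_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(series, path) {
  if (!inherits(series, "survival_series"))
    validation_error("'series' must be a survival_series")
  write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a contingency table from CSV
#'
#' The header row carries the column labels and the first column the row
#' labels; remaining cells are non-negative integer counts.
#'
#' @param path Path to the CSV file.
#' @return A [contingency_table()].
#' @export
read_contingency_csv <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) parse_error(sprintf(
                   "cannot parse %s: %s", path, conditionMessage(e))))
  if (ncol(df) < 3L)
    parse_error(sprintf("%s: need a label column plus >= 2 count columns", path))
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    parse_error(sprintf("%s: count cells must be numeric", path))
  tryCatch(contingency_table(m, row_labels = labels,
                             col_labels = colnames(df)[-1]),
           uvkin_validation_error = function(e) parse_error(sprintf(
             "%s: %s", path, conditionMessage(e))))
}

#' Write a contingency table to CSV
#'
#' @param table A [contingency_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contingency_csv <- function(table, path) {
  if (!inherits(table, "contingency_table"))
    validation_error("'table' must be a contingency_table")
  df <- data.frame(label = rownames(table), unclass(table),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a treatment grid from CSV
#'
#' Expects the long-format columns `treatment`, `time_min`, `replicate`,
#' `cfu`; the design must be balanced.
#'
#' @param path Path to the CSV file.
#' @return A [treatment_grid()].
#' @export
read_treatment_csv <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) parse_error(sprintf(
                   "cannot parse %s: %s", path, conditionMessage(e))))
  treatment_grid(df)
}

#' Write a treatment grid to CSV
#'
#' @param grid A [treatment_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_treatment_csv <- function(grid, path) {
  if (!inherits(grid, "treatment_grid"))
    validation_error("'grid' must be a treatment_grid")
  df <- as.data.frame(grid)
  df$treatment <- as.character(df$treatment)
  df$time_min <- as.character(df$time_min)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a key-value configuration file
#'
#' Configuration files are YAML key-value documents.  Recognised keys
#' include the lamp parameters (`wavelength_nm`, `intensity_wm2`,
#' `bandwidth_nm`, `od600`, `transmittance`), `fit_mode`, `n0`, `seed`, a
#' `simulate` block mirroring [sim_spec()] arguments, and input paths
#' (`series`, `contingency`, `treatment`).
#'
#' @param path Path to the YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) parse_error(sprintf(
                    "cannot parse config %s: %s", path, conditionMessage(e))))
  if (!is.list(cfg))
    parse_error(sprintf("%s: config must be a key-value mapping", path))
  cfg
}

# Build an irradiance_config from config-file keys (falling back to package
# defaults); inconsistent od600/transmittance pairs surface as validation
# errors here.  When only a transmittance is given the OD600 default is
# dropped rather than cross-checked.
config_from_keys <- function(cfg) {
  args <- list()
  for (key in c("wavelength_nm", "intensity_wm2", "bandwidth_nm"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  if (!is.null(cfg$transmittance)) {
    args$transmittance <- cfg$transmittance
    args["od600"] <- list(cfg$od600)  # keeps an explicit NULL in place
  } else if (!is.null(cfg$od600)) {
    args$od600 <- cfg$od600
  }
  do.call(irradiance_config, args)
}
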