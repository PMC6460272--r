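# Seeded generators emulating plate-count irradiance experiments: first-order
# kill with Poisson counting noise, phenotype contingency tables, and
# balanced treatment grids.
#
# Seeding contract: one root seed; each replicate (or draw) uses a child
# stream derived deterministically from the root, so adding replicates never
# changes earlier ones.

child_seed <- function(root, index) {
  # deterministic 32-bit-safe child stream; distinct across (root, index)
  as.integer((as.numeric(root) %% 65536) * 32749 + 7919 * index) %% 2147483647L
}

#' Specification of a synthetic survival experiment
#'
#' Describes the generating conditions of a plate-count irradiance
#' experiment: true survival constant, range of the unirradiated control
#' population, exposure-time grid, plated fraction after serial dilution, and
#' replicate count.  Defaults emulate a stationary-phase culture with
#' controls between 1.5e7 and 2.5e7 CFU exposed for 0/15/30/45/60 min, with a
#' 1e-5 plated fraction so that control plates carry on the order of 200
#' countable colonies.
#'
#' @param k_true True survival constant per minute (>= 0; 0 disables kill).
#' @param n0_range Length-2 interval of control populations (CFU).
#' @param times Exposure times in minutes, strictly increasing from 0.
#' @param dilution Plated fraction in (0, 1].
#' @param replicates Number of independent series (>= 1).
#' @param seed Integer root seed.
#' @param poisson_ceiling Expected counts above this are returned as rounded
#'   expectations instead of Poisson draws (guards lambda overflow when
#'   `dilution = 1` meets a huge population).
#' @return An object of class `"sim_spec"`.
#' @examples
#' sim_spec(k_true = 0.035, replicates = 3, seed = 1)
#' @export
sim_spec <- function(k_true = 0.035, n0_range = c(1.5e7, 2.5e7),
                     times = c(0, 15, 30, 45, 60), dilution = 1e-5,
                     replicates = 1L, seed = 1L, poisson_ceiling = 1e9) {
  check_scalar_number(k_true, "k_true", 0)
  if (!is.numeric(n0_range) || length(n0_range) != 2L ||
      any(n0_range <= 0) || n0_range[1] > n0_range[2])
    validation_error("'n0_range' must be a positive interval c(lo, hi)")
  if (!is.numeric(times) || length(times) < 2L || any(times < 0) ||
      any(diff(times) <= 0))
    validation_error("'times' must be >= 2 strictly increasing non-negative values")
  check_scalar_number(dilution, "dilution", 0, 1, strict_lower = TRUE)
  check_scalar_number(replicates, "replicates", 1)
  check_scalar_number(seed, "seed")
  check_scalar_number(poisson_ceiling, "poisson_ceiling", 0,
                      strict_lower = TRUE)
  structure(list(k_true = k_true, n0_range = as.numeric(n0_range),
                 times = as.numeric(times), dilution = dilution,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), poisson_ceiling = poisson_ceiling),
            class = "sim_spec")
}

#' Simulate survival series with Poisson plate-count noise
#'
#' For each replicate the control population N0 is drawn uniformly from
#' `n0_range`; at each exposure time the expected plated count is
#' `N0 * exp(-k_true * t) * dilution` and the observed count is a Poisson
#' draw around it.  The series records `N0 * dilution` — the expected control
#' count on the plate — as its `n0`.  Output is deterministic for a fixed
#' spec and seed, replicate by replicate.
#'
#' @param spec A [sim_spec()].
#' @return A list of [survival_series()] objects, length `spec$replicates`.
#' @examples
#' sims <- simulate_survival_series(sim_spec(replicates = 2, seed = 42))
#' fit_survival(sims[[1]])
#' @export
simulate_survival_series <- function(spec) {
  if (!inherits(spec, "sim_spec"))
    validation_error("'spec' must be a sim_spec")
  lapply(seq_len(spec$replicates), function(i) {
    set.seed(child_seed(spec$seed, i))
    n0_pop <- runif(1, spec$n0_range[1], spec$n0_range[2])
    mu <- n0_pop * exp(-spec$k_true * spec$times) * spec$dilution
    counts <- ifelse(mu > spec$poisson_ceiling, round(mu),
                     rpois(length(mu), mu))
    survival_series(spec$times, counts, n0 = n0_pop * spec$dilution,
                    max_count = Inf)
  })
}

#' Simulate an isolate phenotype contingency table
#'
#' Multinomial draw of `n` isolates over an r x c cell-probability table
#' built from the outer product of the row and column marginals, tilted by an
#' association parameter: cell (i, j) has probability proportional to
#' `row_probs[i] * col_probs[j] * exp(association * u_i * v_j)` with centred
#' integer scores u and v.  `association = 0` gives exact independence, so
#' draws are a null model for tests of association.
#'
#' @param row_probs,col_probs Marginal probability weights (each sums to 1).
#' @param association Log-linear association strength (0 = independence).
#' @param n Number of isolates to distribute (>= 1).
#' @param seed Integer seed.
#' @return A [contingency_table()] whose grand total is `n`.
#' @examples
#' simulate_isolate_table(rep(1/4, 4), rep(1/7, 7), 0, n = 88, seed = 3)
#' @export
simulate_isolate_table <- function(row_probs, col_probs, association = 0,
                                   n, seed) {
  for (p in list(row_probs, col_probs)) {
    if (!is.numeric(p) || length(p) < 2L || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9)
      validation_error("probability weights must be >= 0 and sum to 1 (within 1e-9)")
  }
  check_scalar_number(association, "association")
  check_scalar_number(n, "n", 1)
  check_scalar_number(seed, "seed")
  u <- seq_along(row_probs) - (length(row_probs) + 1) / 2
  v <- seq_along(col_probs) - (length(col_probs) + 1) / 2
  cellp <- outer(row_probs, col_probs) * exp(association * outer(u, v))
  cellp <- cellp / sum(cellp)
  set.seed(child_seed(seed, 1L))
  draw <- rmultinom(1, size = n, prob = as.vector(cellp))
  contingency_table(matrix(draw, nrow = length(row_probs)))
}

#' Simulate a balanced treatment grid of Poisson counts
#'
#' Draws `replicates` Poisson counts around each cell mean of a treatment x
#' exposure-time design, producing the balanced long-format grid that
#' [two_way_anova()] expects.  Row names of `cell_means` label the treatment
#' levels, column names the exposure times in minutes.
#'
#' @param cell_means Matrix of non-negative expected counts, treatments in
#'   rows, times in columns.
#' @param replicates Replicates per cell (>= 2 for interaction testing).
#' @param seed Integer seed.
#' @return A [treatment_grid()].
#' @examples
#' mu <- matrix(20, 3, 4, dimnames = list(paste0("T", 1:3), c(15, 30, 45, 60)))
#' simulate_ae_grid(mu, replicates = 3, seed = 7)
#' @export
simulate_ae_grid <- function(cell_means, replicates = 3L, seed = 1L) {
  cell_means <- as.matrix(cell_means)
  if (!is.numeric(cell_means) || any(!is.finite(cell_means)) ||
      any(cell_means < 0))
    validation_error("'cell_means' must be finite non-negative")
  if (nrow(cell_means) < 2L || ncol(cell_means) < 2L)
    validation_error("'cell_means' needs >= 2 treatments and >= 2 times")
  check_scalar_number(replicates, "replicates", 2)
  check_scalar_number(seed, "seed")
  treatments <- rownames(cell_means) %||% paste0("T", seq_len(nrow(cell_means)))
  times <- colnames(cell_means) %||% seq_len(ncol(cell_means))
  rows <- expand.grid(treatment = treatments, time_min = times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    set.seed(child_seed(seed, r))
    data.frame(treatment = rows$treatment, time_min = rows$time_min,
               replicate = r,
               cfu = rpois(nrow(rows), as.vector(cell_means)))
  }))
  treatment_grid(out)
}
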