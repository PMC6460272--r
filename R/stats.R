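# Categorical statistics battery for isolate phenotype and treatment data.
# The tests themselves are delegated to the reference implementations in base
# R's stats package; this module supplies the typed containers, validation
# and degenerate-case contracts around them.

#' Construct a contingency table of isolate counts
#'
#' An r x c matrix of non-negative integer counts with row and column labels,
#' e.g. sampling site x colony morphology, or pigmentation x UV resistance.
#'
#' @param counts Matrix (or coercible) of non-negative integers, at least
#'   2 x 2, grand total > 0.
#' @param row_labels,col_labels Optional character labels; default to
#'   existing dimnames or generated names.
#' @return An object of class `"contingency_table"` (an integer matrix with
#'   dimnames).
#' @examples
#' contingency_table(rbind(c(12, 9), c(5, 19)),
#'                   row_labels = c("pigmented", "nonpigmented"),
#'                   col_labels = c("resistant", "sensitive"))
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(!is.finite(counts)))
    validation_error("'counts' must be a finite numeric matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    validation_error("'counts' must be non-negative integers")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    validation_error("a contingency table needs at least 2 rows and 2 columns")
  if (sum(counts) <= 0)
    validation_error("the grand total must be positive")
  if (is.null(row_labels))
    row_labels <- rownames(counts) %||% paste0("row", seq_len(nrow(counts)))
  if (is.null(col_labels))
    col_labels <- colnames(counts) %||% paste0("col", seq_len(ncol(counts)))
  if (length(row_labels) != nrow(counts) || length(col_labels) != ncol(counts))
    validation_error("label lengths must match the table dimensions")
  dimnames(counts) <- list(row_labels, col_labels)
  structure(counts, class = c("contingency_table", class(counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_test_result <- function(statistic, df, p_value, method, note = NULL) {
  structure(list(statistic = unname(statistic),
                 df = if (is.null(df)) NULL else unname(df),
                 p_value = unname(p_value), method = method, note = note),
            class = "uv_test_result")
}

#' @export
print.uv_test_result <- function(x, digits = 4, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic))
    cat(sprintf("  statistic = %s%s, p = %s\n",
                format(x$statistic, digits = digits),
                if (!is.null(x$df)) sprintf(", df = %g", x$df) else "",
                format.pval(x$p_value, digits = digits)))
  else
    cat(sprintf("  p = %s\n", format.pval(x$p_value, digits = digits)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Pearson's chi-square test for a contingency table
#'
#' Chi-square test of independence with expected counts from the margins and
#' p-value from the chi-square upper tail, df = (r-1)(c-1).  With
#' `continuity_correction = TRUE` the Yates correction (subtracting 0.5 from
#' each |O - E|) is applied, and only to 2 x 2 tables — its standard scope —
#' even when the flag is set on a larger table.
#'
#' @param table A [contingency_table()] or matrix coercible to one.
#' @param continuity_correction Apply the Yates correction (2 x 2 only).
#' @return A `"uv_test_result"` with `statistic`, `df`, `p_value`.
#' @examples
#' chisq_test(rbind(c(10, 20), c(20, 10)))                 # Yates: 5.4
#' chisq_test(rbind(c(10, 20), c(20, 10)), FALSE)          # Pearson: 6.667
#' @export
chisq_test <- function(table, continuity_correction = TRUE) {
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    numeric_error("degenerate table: a row or column margin is zero")
  m <- unclass(table)
  corrected <- continuity_correction && all(dim(m) == c(2L, 2L))
  res <- suppressWarnings(chisq.test(m, correct = corrected))
  as_test_result(res$statistic, res$parameter, res$p.value,
                 if (corrected)
                   "Pearson's chi-square test with Yates continuity correction"
                 else "Pearson's chi-square test")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact test: the p-value sums, over all tables sharing the
#' observed margins, the hypergeometric probabilities of tables no more
#' likely than the observed one (the probability-mass ordering used by R's
#' reference implementation).
#'
#' @param table A 2 x 2 [contingency_table()] or matrix coercible to one.
#' @return A `"uv_test_result"`; `df` is absent for exact tests.
#' @examples
#' fisher_exact(rbind(c(2, 0), c(0, 2)))  # p = 1/3
#' @export
fisher_exact <- function(table) {
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  if (!all(dim(table) == c(2L, 2L)))
    validation_error("fisher_exact is restricted to 2 x 2 tables")
  res <- fisher.test(unclass(table))
  as_test_result(NULL, NULL, min(res$p.value, 1),
                 "Fisher's exact test (two-sided)")
}

#' Kruskal-Wallis rank-sum test
#'
#' Mid-rank k-sample test with the standard tie correction
#' \eqn{H' = H / (1 - \sum(t^3 - t)/(N^3 - N))}, df = groups - 1, p-value
#' from the chi-square approximation.  All observations identical is reported
#' as statistic 0, p = 1 (no rank separation), not an error.
#'
#' @param groups A list of numeric vectors, one per group (>= 2 nonempty
#'   groups, total N >= 3).
#' @return A `"uv_test_result"`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))  # H = 2.4, df = 1
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    validation_error("'groups' must be a list of >= 2 numeric vectors")
  sizes <- lengths(groups)
  if (any(sizes == 0L))
    validation_error("every group must be nonempty")
  if (sum(sizes) < 3L)
    validation_error("need a total of >= 3 observations")
  pooled <- unlist(groups, use.names = FALSE)
  if (!is.numeric(pooled) || any(!is.finite(pooled)))
    validation_error("group values must be finite numeric")
  if (all(pooled == pooled[1]))
    return(as_test_result(0, length(groups) - 1L, 1,
                          "Kruskal-Wallis rank sum test",
                          note = "all observations identical"))
  g <- factor(rep(seq_along(groups), sizes))
  res <- kruskal.test(pooled, g)
  as_test_result(res$statistic, res$parameter, res$p.value,
                 "Kruskal-Wallis rank sum test")
}

#' Construct a balanced treatment grid of replicate CFU counts
#'
#' Long-format replicate counts indexed by treatment level (e.g. aqueous
#' extract concentration in mg/ml, or a control label) and UV exposure time
#' in minutes.  The design must be balanced: the same number of replicates in
#' every treatment x time cell, as in a triplicated plate experiment.
#'
#' @param data A data frame with columns `treatment`, `time_min`,
#'   `replicate`, `cfu` (non-negative integer counts).
#' @return An object of class `"treatment_grid"` (the validated data frame).
#' @export
treatment_grid <- function(data) {
  need <- c("treatment", "time_min", "replicate", "cfu")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    parse_error(sprintf("treatment grid needs columns: %s",
                        paste(need, collapse = ", ")))
  if (any(!is.finite(data$cfu)) || any(data$cfu < 0) ||
      any(data$cfu != round(data$cfu)))
    validation_error("'cfu' must be non-negative integers")
  data$treatment <- factor(data$treatment)
  data$time_min <- factor(data$time_min)
  if (nlevels(data$treatment) < 2L || nlevels(data$time_min) < 2L)
    validation_error("each factor needs >= 2 levels")
  tab <- table(data$treatment, data$time_min)
  if (length(unique(as.vector(tab))) != 1L || any(tab == 0))
    validation_error(
      "unbalanced design: every treatment x time cell must hold the same number of replicates; balance or subsample before testing")
  structure(data, class = c("treatment_grid", "data.frame"),
            replicates = unique(as.vector(tab)))
}

#' Two-way analysis of variance with interaction
#'
#' Balanced two-factor ANOVA of CFU counts on treatment, exposure time and
#' their interaction, using the standard decomposition
#' SS_total = SS_treatment + SS_time + SS_interaction + SS_error and F ratios
#' against the error mean square.  For balanced data the Type I/II/III
#' distinction is moot.
#'
#' Degenerate variance cases follow a documented contract: with zero error
#' mean square, a factor with nonzero sum of squares is reported with
#' `statistic = Inf` and a `zero-variance` note; an all-constant grid reports
#' every F as 0 with p = 1.
#'
#' @param grid A [treatment_grid()] with >= 2 replicates per cell.
#' @return A list of three `"uv_test_result"` objects named `treatment`,
#'   `time` and `interaction`, with attribute `"ss"` holding the full
#'   sums-of-squares table.
#' @export
two_way_anova <- function(grid) {
  if (!inherits(grid, "treatment_grid")) grid <- treatment_grid(grid)
  if (attr(grid, "replicates") < 2L)
    validation_error(">= 2 replicates per cell are required for the interaction term")

  if (all(grid$cfu == grid$cfu[1])) {
    zero <- function(df1) as_test_result(0, df1, 1, "Two-way ANOVA",
                                         note = "zero variance: all counts equal")
    dfA <- nlevels(grid$treatment) - 1L
    dfB <- nlevels(grid$time_min) - 1L
    out <- list(treatment = zero(dfA), time = zero(dfB),
                interaction = zero(dfA * dfB))
    attr(out, "ss") <- data.frame(
      term = c("treatment", "time", "interaction", "error"),
      df = c(dfA, dfB, dfA * dfB,
             nrow(grid) - (dfA + 1L) * (dfB + 1L)),
      ss = c(0, 0, 0, 0))
    return(out)
  }

  fit <- aov(cfu ~ treatment * time_min, data = grid)
  tab <- suppressWarnings(anova(fit))
  ss <- data.frame(term = c("treatment", "time", "interaction", "error"),
                   df = tab$Df, ss = tab$`Sum Sq`)
  # treat a residual sum of squares that is zero to rounding as exactly zero
  eps <- 1e-10 * sum(tab$`Sum Sq`)
  zero_mse <- tab$`Sum Sq`[4] <= eps
  one <- function(i, label) {
    if (zero_mse) {
      f <- if (tab$`Sum Sq`[i] > eps) Inf else 0
      as_test_result(f, tab$Df[i], if (f > 0) 0 else 1,
                     sprintf("Two-way ANOVA: %s", label),
                     note = "zero error variance")
    } else {
      as_test_result(tab$`F value`[i], tab$Df[i], tab$`Pr(>F)`[i],
                     sprintf("Two-way ANOVA: %s", label))
    }
  }
  out <- list(treatment = one(1, "treatment effect"),
              time = one(2, "exposure-time effect"),
              interaction = one(3, "treatment x time interaction"))
  attr(out, "ss") <- ss
  out
}
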