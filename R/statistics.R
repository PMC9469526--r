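# Group-level statistics: qPCR fold changes, growth metrics, two-sample
# tests and the condition-level regression layer linking rim localization
# to lamin expression and nuclear morphology.

#' Relative expression fold changes by the 2^-ddCq method
#'
#' Per replicate, dCq = Cq_target - Cq_reference; per condition,
#' ddCq = mean dCq(condition) - mean dCq(control); fold = 2^-ddCq.
#'
#' @param records Tibble with columns `condition`, `gene`, `replicate`,
#'   `cq_target`, `cq_reference`.
#' @param control Name of the control condition.
#' @return Tibble per (gene, condition): `n`, `delta_cq`, `ddcq`,
#'   `fold_change`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   condition = rep(c("ctr", "mut"), each = 3), gene = "geneX",
#'   replicate = rep(1:3, 2),
#'   cq_target = c(20, 20.1, 19.9, 19, 19.1, 18.9), cq_reference = 15
#' )
#' ddcq_fold_change(rec, control = "ctr")
ddcq_fold_change <- function(records, control) {
  needed <- c("condition", "gene", "cq_target", "cq_reference")
  if (!all(needed %in% names(records))) {
    abort(paste("records must have columns:", paste(needed, collapse = ", ")))
  }
  if (!control %in% records$condition) {
    abort(sprintf("control condition '%s' not present.", control))
  }
  if (any(!is.finite(records$cq_target)) || any(!is.finite(records$cq_reference)) ||
      any(records$cq_target <= 0) || any(records$cq_reference <= 0)) {
    abort("Cq values must be positive and finite (missing reference gene rows?).")
  }
  dcq <- dplyr::summarise(
    dplyr::group_by(records, .data$gene, .data$condition),
    n = dplyr::n(),
    delta_cq = mean(.data$cq_target - .data$cq_reference),
    .groups = "drop"
  )
  ctrl <- dplyr::select(
    dplyr::filter(dcq, .data$condition == control),
    "gene", control_delta_cq = "delta_cq"
  )
  out <- dplyr::left_join(dcq, ctrl, by = "gene")
  out <- dplyr::mutate(out,
                       ddcq = .data$delta_cq - .data$control_delta_cq,
                       fold_change = 2^(-.data$ddcq))
  dplyr::select(out, -"control_delta_cq")
}

#' Population doublings between two cell counts
#'
#' PD = log10(nt / n0) x 3.33 (3.33 ~ 1/log10(2), so PD counts doublings).
#'
#' @param n0 Cells plated.
#' @param nt Cells counted after the growth interval.
#' @return Numeric population doublings (vectorized).
#' @export
#' @examples
#' population_doubling(1e5, 2e5)  # ~1 doubling
population_doubling <- function(n0, nt) {
  if (any(n0 <= 0) || any(nt <= 0)) abort("cell counts must be positive.")
  log10(nt / n0) * 3.33
}

#' Significance stars for a p-value
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Unpaired two-tailed Student's t-test
#'
#' Classical equal-variance two-sample t-test (Welch available behind
#' `var_equal = FALSE`), with the conventional star annotation. Two
#' identical degenerate samples (zero pooled variance, equal means) return
#' p = 1 by convention; zero pooled variance with unequal means is an
#' error.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param var_equal Use the pooled-variance Student statistic (default).
#' @return One-row tibble: `t`, `df`, `p_value`, `stars`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
ttest_unpaired <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) abort("each sample needs n >= 2.")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                    stars = "ns", mean_a = mean(a), mean_b = mean(b),
                    n_a = length(a), n_b = length(b)))
    }
    abort("degenerate variance: both samples constant with unequal means.")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, stars = significance_stars(ht$p.value),
         mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b))
}

#' Ordinary least-squares regression on condition-level means
#'
#' Simple OLS linking two condition-level quantities (e.g. percent positive
#' rim vs lamin expression), reporting the slope, r-squared and the
#' two-tailed slope p-value (identical to the correlation test p-value for
#' simple OLS).
#'
#' @param data Data frame with the predictor and response columns.
#' @param x,y Column names (strings) of predictor and response.
#' @return An object of class `rim_regression` with [tidy()], [glance()]
#'   and [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:5, y = 2 * (1:5) + 1)
#' glance(group_linear_regression(d, "x", "y"))
group_linear_regression <- function(data, x, y) {
  if (!all(c(x, y) %in% names(data))) abort("x and y must name columns of data.")
  d <- tibble(x = data[[x]], y = data[[y]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3L) abort("need at least 3 paired points for a regression p-value.")
  if (sd(d$x) == 0) abort("no variance in predictor.")
  fit <- lm(y ~ x, data = d)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  degenerate_y <- sd(d$y) == 0
  p <- if (degenerate_y) 1 else sm$coefficients["x", "Pr(>|t|)"]
  r2 <- if (degenerate_y) 0 else sm$r.squared
  structure(
    list(fit = fit, data = d, x_name = x, y_name = y,
         slope = unname(coef(fit)["x"]), intercept = unname(coef(fit)[1]),
         r_squared = r2, p_value = p, n = nrow(d)),
    class = "rim_regression"
  )
}

#' @export
print.rim_regression <- function(x, ...) {
  cat(sprintf("OLS %s ~ %s (n = %d)\n", x$y_name, x$x_name, x$n))
  cat(sprintf("  slope = %.4g, intercept = %.4g, r^2 = %.3f, p = %.4g %s\n",
              x$slope, x$intercept, x$r_squared, x$p_value,
              significance_stars(x$p_value)))
  invisible(x)
}

#' @export
tidy.rim_regression <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @export
glance.rim_regression <- function(x, ...) {
  xn <- x$x_name
  yn <- x$y_name
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         p_value = x$p_value, stars = significance_stars(x$p_value),
         n = x$n, x = xn, y = yn)
}

#' Condition-level correlation table and pairwise regressions
#'
#' Joins rim metrics, morphometry summaries and expression levels into one
#' row per condition, then fits every configured (x, y) regression pair.
#' Default pairs regress percent positive rim on each expression level, on
#' the aberration index, and on the merged predictor
#' z(lamin A / lamin C) + z(aberration index) (both standardized across
#' conditions). No multiple-testing correction is applied.
#'
#' @param rim_metrics Tibble: `condition`, `pct_positive_rim` (one row per
#'   condition).
#' @param morpho_summary Tibble: `condition`, `aberration_index_mean` (from
#'   [summarize_morphometry()]).
#' @param expression Tibble: `condition`, `protein`, `level` (pre-quantified
#'   densitometry or expression levels); spread to one column per protein.
#' @param pairs Optional list of `c(x, y)` character pairs; defaults cover
#'   every expression column, the aberration index and the merged predictor
#'   against `pct_positive_rim`.
#' @return List of class `rim_correlation`: `table` (the joined tibble) and
#'   `regressions` (one [glance()] row per pair).
#' @export
build_correlation_table <- function(rim_metrics, morpho_summary, expression,
                                    pairs = NULL) {
  check_cond <- function(df, nm) {
    if (!"condition" %in% names(df)) abort(sprintf("%s needs a condition column.", nm))
    unique(df$condition)
  }
  c1 <- check_cond(rim_metrics, "rim_metrics")
  c2 <- check_cond(morpho_summary, "morpho_summary")
  c3 <- check_cond(expression, "expression")
  mismatch <- c(setdiff(c1, c2), setdiff(c2, c1), setdiff(c1, c3), setdiff(c3, c1))
  if (length(mismatch) > 0L) {
    abort(paste("conditions do not align across inputs; unmatched:",
                paste(sort(unique(mismatch)), collapse = ", ")))
  }
  expr_wide <- tidyr::pivot_wider(expression, id_cols = "condition",
                                  names_from = "protein", values_from = "level")
  tab <- dplyr::left_join(rim_metrics, morpho_summary, by = "condition")
  tab <- dplyr::left_join(tab, expr_wide, by = "condition")
  tab <- dplyr::arrange(tab, .data$condition)

  zscore <- function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) return(v * 0)
    (v - mean(v)) / s
  }
  if (all(c("lamin_a", "lamin_c") %in% names(tab))) {
    tab$merged_lamin_morpho <- zscore(tab$lamin_a / tab$lamin_c) +
      zscore(tab$aberration_index_mean)
  }
  if (is.null(pairs)) {
    xs <- c(setdiff(names(expr_wide), "condition"), "aberration_index_mean",
            intersect("merged_lamin_morpho", names(tab)))
    pairs <- lapply(xs, function(x) c(x, "pct_positive_rim"))
  }
  regressions <- purrr::map_dfr(pairs, function(p) {
    fit <- tryCatch(group_linear_regression(tab, p[1], p[2]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(slope = NA_real_, intercept = NA_real_,
                    r_squared = NA_real_, p_value = NA_real_,
                    stars = NA_character_, n = sum(stats::complete.cases(
                      tab[, p, drop = FALSE])), x = p[1], y = p[2]))
    }
    glance(fit)
  })
  structure(list(table = tab, regressions = regressions),
            class = "rim_correlation")
}

#' @export
print.rim_correlation <- function(x, ...) {
  cat(sprintf("Correlation layer over %d conditions\n", nrow(x$table)))
  print(x$regressions)
  invisible(x)
}
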