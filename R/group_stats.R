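#' Validate an outcome table
#'
#' Tidy per-specimen outcomes: one row per (specimen, outcome) with a group
#' label, an optional second factor, and a numeric value.
#'
#' @param df Data frame with at least columns `group` and `value`;
#'   optionally `sample_id`, `factor2`, `outcome`.
#' @return The validated data frame (factors coerced).
#' @export
outcome_table <- function(df) {
  for (col in c("group", "value"))
    if (!col %in% names(df))
      stop_cartindent(sprintf("outcome table is missing column '%s'", col),
                      "cartindent_format_error")
  if (!is.numeric(df$value) || any(!is.finite(df$value)))
    stop_cartindent("outcome values must be finite numerics", "cartindent_validation_error")
  df$group <- factor(df$group)
  if (nlevels(df$group) < 2L)
    stop_cartindent("need at least 2 groups", "cartindent_validation_error")
  cnt <- table(df$group)
  if (any(cnt < 2L))
    stop_cartindent(sprintf("group(s) with fewer than 2 observations: %s",
                            paste(names(cnt)[cnt < 2], collapse = ", ")),
                    "cartindent_validation_error")
  if ("factor2" %in% names(df)) df$factor2 <- factor(df$factor2)
  df
}

#' Fixed-effects ANOVA on an outcome table
#'
#' One-way, or two-way with interaction for balanced designs. An unbalanced
#' two-factor table falls back to separate one-way decompositions per factor
#' with a warning, refusing the silent ambiguity of unbalanced two-way sums
#' of squares.
#'
#' @param table Outcome table (see [outcome_table()]).
#' @param factors Factor columns to use: `"group"` or
#'   `c("group", "factor2")`.
#' @return A data frame with columns `term`, `df`, `sum_sq`, `mean_sq`,
#'   `F`, `p` (residual row included). For the unbalanced fallback, a named
#'   list of such tables, one per factor.
#' @export
anova_table <- function(table, factors = "group") {
  table <- outcome_table(table)
  stopifnot(all(factors %in% names(table)), length(factors) %in% 1:2)
  if (stats::var(table$value) == 0)
    stop_cartindent("zero total variance: all observations identical",
                    "cartindent_validation_error")
  tidy_aov <- function(form) {
    fit <- stats::aov(form, data = table)
    s <- summary(fit)[[1]]
    data.frame(term = trimws(rownames(s)), df = s$Df, sum_sq = s$`Sum Sq`,
               mean_sq = s$`Mean Sq`, F = s$`F value`, p = s$`Pr(>F)`,
               row.names = NULL)
  }
  if (length(factors) == 1L)
    return(tidy_aov(stats::reformulate(factors, "value")))
  cells <- table(table[[factors[1]]], table[[factors[2]]])
  if (any(cells == 0L))
    stop_cartindent("two-way ANOVA needs every factor cell non-empty",
                    "cartindent_validation_error")
  if (length(unique(as.vector(cells))) == 1L) {
    tidy_aov(stats::as.formula(paste("value ~", factors[1], "*", factors[2])))
  } else {
    warning("unbalanced two-factor design: falling back to one-way ANOVA per factor")
    stats::setNames(lapply(factors, function(f) tidy_aov(stats::reformulate(f, "value"))),
                    factors)
  }
}

#' Tukey HSD all-pairs comparisons
#'
#' Studentized-range adjusted p-values for all group pairs of a one-way
#' layout, using the pooled within-group mean square. The significance flag
#' uses strict `p < alpha`. For unequal group sizes the Tukey-Kramer
#' standard error is used.
#'
#' @param table Outcome table (see [outcome_table()]).
#' @param alpha Family-wise significance level, default 0.05.
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean of `group2` minus mean of `group1`), `se`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(table, alpha = 0.05) {
  table <- outcome_table(table)
  g <- table$group
  k <- nlevels(g)
  n_i <- tapply(table$value, g, length)
  m_i <- tapply(table$value, g, mean)
  df_err <- length(table$value) - k
  mse <- sum(tapply(table$value, g, function(v) sum((v - mean(v))^2))) / df_err
  if (mse <= 0)
    stop_cartindent("zero within-group variance: studentized range undefined",
                    "cartindent_validation_error")
  pairs <- utils::combn(levels(g), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  out$diff <- as.numeric(m_i[out$group2] - m_i[out$group1])
  out$se <- as.numeric(sqrt(mse / 2 * (1 / n_i[out$group1] + 1 / n_i[out$group2])))
  q_obs <- abs(out$diff) / out$se
  out$p_adj <- stats::ptukey(q_obs, nmeans = k, df = df_err, lower.tail = FALSE)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Per-group mean and standard deviation summary
#'
#' Sample standard deviation (n - 1 denominator), the form in which group
#' outcomes are conventionally reported (mean +/- SD).
#'
#' @param table Outcome table (see [outcome_table()]).
#' @return Data frame with `group`, `n`, `mean`, `sd` and a formatted
#'   `label` column.
#' @export
summarize_groups <- function(table) {
  table <- outcome_table(table)
  g <- table$group
  out <- data.frame(group = levels(g),
                    n = as.integer(table(g)),
                    mean = as.numeric(tapply(table$value, g, mean)),
                    sd = as.numeric(tapply(table$value, g, stats::sd)))
  out$label <- sprintf("%.2f ± %.2f", out$mean, out$sd)
  out
}
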