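#' Paired infarct-size table
#'
#' Long-format table of infarct sizes (% of endocardial perimeter) per subject
#' and measurement method, the input to all agreement statistics.
#'
#' @param subject Subject identifiers.
#' @param method Method labels (e.g. `"t1rho"`, `"reference"`,
#'   `"planimetry"`).
#' @param size_percent Sizes in `[0, 100]`.
#' @return A `data.frame` of class `paired_size_table`.
#' @export
paired_size_table <- function(subject, method, size_percent) {
  stopifnot(length(subject) == length(method),
            length(subject) == length(size_percent))
  if (any(size_percent < 0 | size_percent > 100, na.rm = TRUE)) {
    stop("size_percent must lie in [0, 100]")
  }
  structure(data.frame(subject = subject, method = method,
                       size_percent = size_percent),
            class = c("paired_size_table", "data.frame"))
}

# extract matched columns for two methods
paired_columns <- function(table, method_a, method_b) {
  a <- table[table$method == method_a, c("subject", "size_percent")]
  b <- table[table$method == method_b, c("subject", "size_percent")]
  m <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no paired observations for methods '", method_a,
                     "' and '", method_b, "'")
  m
}

#' Bland-Altman limits of agreement
#'
#' Differences `a - b` per subject; bias is their mean and the limits of
#' agreement are `bias +/- 1.96 * SD` (sample SD).
#'
#' @param table A [paired_size_table()].
#' @param method_a,method_b Method labels to compare.
#' @return Object of class `agreement_result` with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`, and the mean-vs-difference `pairs` for
#'   plotting.
#' @export
bland_altman <- function(table, method_a, method_b) {
  m <- paired_columns(table, method_a, method_b)
  if (nrow(m) < 2L) stop("Bland-Altman requires at least 2 paired observations")
  d <- m$size_percent_a - m$size_percent_b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    method_a = method_a, method_b = method_b,
    bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    n = nrow(m),
    pairs = data.frame(subject = m$subject,
                       mean = (m$size_percent_a + m$size_percent_b) / 2,
                       difference = d)
  ), class = "agreement_result")
}

#' Correlation and least-squares fit between two methods
#'
#' Ordinary least squares of `method_a` sizes on `method_b` sizes;
#' `r_squared` is the squared Pearson correlation.
#'
#' @param table A [paired_size_table()].
#' @param method_a,method_b Method labels (response and regressor).
#' @return List with `r_squared`, `slope`, `intercept`, `n`.
#' @export
correlation_r2 <- function(table, method_a, method_b) {
  m <- paired_columns(table, method_a, method_b)
  if (nrow(m) < 3L) stop("correlation requires at least 3 paired observations")
  if (stats::var(m$size_percent_a) == 0 || stats::var(m$size_percent_b) == 0) {
    stop("zero variance in one of the methods")
  }
  fit <- stats::lm(size_percent_a ~ size_percent_b, data = m)
  r <- stats::cor(m$size_percent_a, m$size_percent_b)
  list(r_squared = r^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = nrow(m))
}

#' Two-way fixed-effects ANOVA
#'
#' Balanced complete two-factor layout; the interaction term is included when
#' cells are replicated. Unbalanced designs are rejected rather than silently
#' reweighted.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factor levels, same length as `values`.
#' @return Object of class `anova_result`: data frame `terms` (term, df, ss,
#'   ms, statistic, p_value) and `ss_total`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  stopifnot(length(values) == length(fa), length(values) == length(fb))
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    stop("both factors need at least 2 levels")
  }
  cell_n <- table(fa, fb)
  if (length(unique(as.vector(cell_n))) != 1L || any(cell_n == 0)) {
    stop("unbalanced design: all cells must have the same number of replicates")
  }
  replicated <- cell_n[1] > 1L
  d <- data.frame(y = values, A = fa, B = fb)
  form <- if (replicated) y ~ A * B else y ~ A + B
  fit <- stats::aov(form, data = d)
  s <- summary(fit)[[1]]
  terms <- data.frame(
    term = trimws(rownames(s)),
    df = s[["Df"]],
    ss = s[["Sum Sq"]],
    ms = s[["Mean Sq"]],
    statistic = s[["F value"]],
    p_value = s[["Pr(>F)"]]
  )
  # a constant response explains nothing: force F = 0 rather than 0/0 fuzz
  if (sum(terms$ss) <= 1e-12 * max(1, sum(values^2))) {
    fac <- terms$term != "Residuals"
    terms$statistic[fac] <- 0
    terms$p_value[fac] <- 1
  }
  zero <- is.nan(terms$statistic) & terms$ss == 0
  terms$statistic[zero] <- 0
  terms$p_value[zero] <- 1
  structure(list(terms = terms, ss_total = sum(terms$ss)),
            class = "anova_result")
}
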