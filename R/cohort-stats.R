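# Cohort statistics: normality-gated two-group comparisons,
# categorical tests, correlations, median split, and the
# univariate-screen -> fully-adjusted regression strategy.
#
# Conventions (documented once):
#  * normality gate: Shapiro-Wilk p >= 0.05 AND |sample skewness| < 1;
#  * two-group branch: Welch t when both groups pass the gate,
#    Wilcoxon rank-sum otherwise;
#  * chi-squared without continuity correction;
#  * ties at the median go to the low group;
#  * no multiple-testing adjustment; alpha = 0.05 throughout.

#' Normality gate
#'
#' A sample passes the gate when the Shapiro-Wilk p-value is >= 0.05
#' and the absolute sample skewness is below 1. Degenerate (constant)
#' samples fail the gate and are flagged.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha Shapiro-Wilk significance level of the gate.
#' @return list: is_normal, shapiro_p, skewness, degenerate.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stopf("normality gate needs at least 3 values (got %d)", n)
  if (stats::sd(values) == 0)
    return(list(is_normal = FALSE, shapiro_p = NA_real_,
                skewness = NA_real_, degenerate = TRUE))
  if (n > 5000L) values <- values[round(seq(1, n, length.out = 5000L))]
  sw <- stats::shapiro.test(values)
  sk <- sample_skewness(values)
  list(is_normal = sw$p.value >= alpha && abs(sk) < 1,
       shapiro_p = sw$p.value, skewness = sk, degenerate = FALSE)
}

#' Normality-gated two-group comparison
#'
#' Welch's t-test when both groups pass \code{\link{normality_gate}},
#' Wilcoxon rank-sum otherwise. The branch is a pure function of the
#' two samples.
#'
#' @param x,y numeric vectors (each n >= 3).
#' @param labels length-2 character vector of group names.
#' @param variable name of the compared quantity (for reporting).
#' @return an object of class \code{comparison_result}: group
#'   summaries (mean, sd, median, IQR), test_used ("t" or
#'   "wilcoxon"), statistic, p_value, and the per-group gate
#'   diagnostics.
#' @export
compare_groups <- function(x, y, labels = c("group1", "group2"),
                           variable = NA_character_) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stopf("both groups need at least 3 finite values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && x[1] == y[1])
    stopf("degenerate comparison: both groups constant and equal")
  gx <- normality_gate(x); gy <- normality_gate(y)
  use_t <- gx$is_normal && gy$is_normal
  if (use_t) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  }
  structure(list(
    variable = variable, labels = labels,
    n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
    median = c(stats::median(x), stats::median(y)),
    iqr = c(stats::IQR(x), stats::IQR(y)),
    test_used = if (use_t) "t" else "wilcoxon",
    statistic = unname(ht$statistic), p_value = ht$p.value,
    gate = list(gx, gy)
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: %s %.3g +/- %.3g vs %s %.3g +/- %.3g; %s test, p = %.4g\n",
              x$variable, x$labels[1], x$mean[1], x$sd[1],
              x$labels[2], x$mean[2], x$sd[2], x$test_used, x$p_value))
  invisible(x)
}

#' Pearson chi-squared test without continuity correction
#'
#' @param table matrix of nonnegative integer counts (e.g. 2 x 2
#'   sex-by-status).
#' @return list: statistic, df, p_value, expected, observed.
#' @export
chi_squared_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stopf("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("zero marginal: test undefined")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected, observed = table)
}

#' Correlation with two-sided test
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @param method "pearson" or "spearman".
#' @return list: r, p_value, n, method.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stopf("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance: correlation undefined")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x),
       method = method)
}

#' Median split with per-variable comparisons
#'
#' Splits records at the median of \code{key}: values <= median form
#' the low group, values > median the high group (ties go low). Each
#' variable in \code{compare} is then tested between the groups with
#' \code{\link{compare_groups}}.
#'
#' @param records data.frame.
#' @param key column to split on (default \code{"mean_gd"}).
#' @param compare character vector of columns to compare (default: all
#'   numeric columns except the key).
#' @return list: median, low, high (data.frames), comparison
#'   (data.frame with group means/SDs, test used and p per variable).
#' @export
median_split <- function(records, key = "mean_gd", compare = NULL) {
  if (!key %in% names(records)) stopf("key column '%s' not found", key)
  v <- records[[key]]
  if (length(v) < 2L) stopf("median split needs at least 2 records")
  med <- stats::median(v)
  low <- records[v <= med, , drop = FALSE]
  high <- records[v > med, , drop = FALSE]
  if (is.null(compare)) {
    num <- vapply(records, is.numeric, logical(1))
    compare <- setdiff(names(records)[num], key)
  }
  comparison <- NULL
  for (var in compare) {
    xv <- low[[var]]; yv <- high[[var]]
    if (sum(is.finite(xv)) < 3 || sum(is.finite(yv)) < 3) next
    cr <- tryCatch(compare_groups(xv, yv, labels = c("low", "high"),
                                  variable = var),
                   error = function(e) NULL)
    if (is.null(cr)) next
    comparison <- rbind(comparison, data.frame(
      variable = var, mean_low = cr$mean[1], sd_low = cr$sd[1],
      mean_high = cr$mean[2], sd_high = cr$sd[2],
      test_used = cr$test_used, p_value = cr$p_value))
  }
  list(median = med, low = low, high = high, comparison = comparison)
}

#' Univariate screen followed by a fully adjusted model
#'
#' Each candidate covariate is first regressed on its own against the
#' outcome (ordinary least squares). Covariates with univariate
#' p < \code{alpha} enter one multivariable model. If the residuals of
#' the full model fail a Shapiro-Wilk check (p < 0.05) and the outcome
#' is strictly positive, the outcome is log-transformed and the full
#' model refit.
#'
#' @param data data.frame of complete cases (rows with NA in the
#'   outcome or a candidate are dropped).
#' @param outcome name of the outcome column.
#' @param covariates character vector of candidate covariate columns.
#' @param alpha univariate selection level (default 0.05).
#' @return an object of class \code{regression_result}: a coefficient
#'   table (unadjusted and, for selected covariates, adjusted
#'   estimates with 95% CIs and p-values), \code{selected},
#'   \code{log_transformed} and the fitted full model.
#' @export
regression_strategy <- function(data, outcome, covariates, alpha = 0.05) {
  cols <- c(outcome, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) stopf("missing columns: %s", paste(missing_cols, collapse = ", "))
  df <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  # coerce logicals/factors to numeric dummies for the condition check
  for (cv in covariates) if (is.logical(df[[cv]])) df[[cv]] <- as.numeric(df[[cv]])
  if (nrow(df) < 10L)
    stopf("need at least 10 complete cases (got %d)", nrow(df))
  # collinearity among candidates: flag the offending pair
  num <- df[, covariates, drop = FALSE]
  if (length(covariates) > 1L) {
    cm <- suppressWarnings(stats::cor(num))
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (max(abs(cm)) > 0.999 ||
        kappa(scale(as.matrix(num)), exact = TRUE) > 1e8)
      stopf("collinear covariates: %s and %s", covariates[worst[1]],
            covariates[worst[2]])
  }

  uni <- lapply(covariates, function(cv) {
    fit <- stats::lm(stats::reformulate(cv, outcome), data = df)
    ci <- stats::confint(fit)[2, ]
    sm <- summary(fit)$coefficients
    data.frame(covariate = cv, estimate = sm[2, 1], ci_lower = ci[1],
               ci_upper = ci[2], p_value = sm[2, 4])
  })
  uni <- do.call(rbind, uni)
  selected <- uni$covariate[uni$p_value < alpha]

  tab <- uni
  tab$adjusted_estimate <- tab$adjusted_ci_lower <- tab$adjusted_ci_upper <-
    tab$adjusted_p <- NA_real_
  log_transformed <- FALSE
  full <- NULL
  if (length(selected)) {
    full <- stats::lm(stats::reformulate(selected, outcome), data = df)
    res_p <- tryCatch(stats::shapiro.test(stats::residuals(full))$p.value,
                      error = function(e) NA_real_)
    if (is.finite(res_p) && res_p < 0.05 && all(df[[outcome]] > 0)) {
      log_transformed <- TRUE
      df$.log_outcome <- log(df[[outcome]])
      full <- stats::lm(stats::reformulate(selected, ".log_outcome"), data = df)
    }
    smf <- summary(full)$coefficients
    cif <- stats::confint(full)
    for (cv in selected) {
      i <- which(tab$covariate == cv)
      tab$adjusted_estimate[i] <- smf[cv, 1]
      tab$adjusted_ci_lower[i] <- cif[cv, 1]
      tab$adjusted_ci_upper[i] <- cif[cv, 2]
      tab$adjusted_p[i] <- smf[cv, 4]
    }
  }
  structure(list(outcome = outcome, table = tab, selected = selected,
                 log_transformed = log_transformed, n = nrow(df),
                 full_model = full),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> outcome %s (n = %d)%s\n", x$outcome, x$n,
              if (x$log_transformed) ", log-transformed outcome" else ""))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
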