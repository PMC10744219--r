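# Agreement statistics (Pearson regression, Bland-Altman), adjusted linear
# regression, and cohort normative tables.

#' Pearson correlation with two-sided significance test
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return list with `r`, `p_value`, `n`.
#' @examples
#' pearson_regression(c(1, 2, 3, 4), c(2, 1, 4, 3))$r  # 0.6
#' @export
pearson_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant series")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = y - x`; bias is `mean(d)` and the 95% limits of
#' agreement are `bias +/- 1.96 * sd(d)` (sample SD, n - 1 denominator).
#'
#' @param x,y paired measurements of equal length, n >= 2.
#' @return object of class `"bland_altman"`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the per-pair `mean`/`diff` vectors for
#'   plotting.
#' @examples
#' bland_altman(c(0, 0, 0), c(2, -2, 3))  # bias 1, LoA (-4.19, 6.19)
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- y - x
  s <- stats::sd(d)
  structure(list(bias = mean(d), sd_diff = s,
                 loa_low = mean(d) - 1.96 * s, loa_high = mean(d) + 1.96 * s,
                 n = length(d), mean = (x + y) / 2, diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f, 95%% LoA [%.2f, %.2f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Interobserver agreement summary
#'
#' Combines Pearson regression and Bland-Altman analysis of two observers'
#' paired measurements.
#'
#' @param x,y paired measurements (e.g. segmental InD from two observers).
#' @return object of class `"ind_agreement"`: `pearson_r`, `p_value`, `bias`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
interobserver_agreement <- function(x, y) {
  pr <- pearson_regression(x, y)
  ba <- bland_altman(x, y)
  structure(list(pearson_r = pr$r, p_value = pr$p_value, bias = ba$bias,
                 loa_low = ba$loa_low, loa_high = ba$loa_high, n = pr$n),
            class = "ind_agreement")
}

#' @export
print.ind_agreement <- function(x, ...) {
  cat(sprintf("Agreement (n = %d): R = %.2f (p = %.2g), bias %.2f, LoA [%.2f, %.2f]\n",
              x$n, x$pearson_r, x$p_value, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Covariate-adjusted linear regression
#'
#' Ordinary least squares of `outcome` on `predictor`, optionally adjusted
#' for covariate columns, with t-based 95% confidence intervals (degrees of
#' freedom n - p).
#'
#' @param outcome,predictor numeric vectors.
#' @param covariates optional data.frame of covariate columns (e.g. age, sex).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `"adjusted_fit"`: a coefficient table
#'   (`term`, `estimate`, `ci_low`, `ci_high`, `p_value`), `n`, the covariate
#'   names and the underlying `lm` fit.
#' @export
adjusted_ols <- function(outcome, predictor, covariates = NULL,
                         conf_level = 0.95) {
  df <- data.frame(.outcome = outcome, predictor = predictor)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    df <- cbind(df, covariates)
  }
  if (nrow(df) <= ncol(df) + 1L)
    stop("too few observations for the number of parameters")
  mm <- stats::model.matrix(~ ., data = df[, -1L, drop = FALSE])
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(.outcome ~ ., data = df)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  dfres <- fit$df.residual
  tq <- stats::qt(1 - (1 - conf_level) / 2, dfres)
  tval <- ifelse(se > 0, est / se, sign(est) * Inf)
  tab <- data.frame(term = names(est), estimate = unname(est),
                    ci_low = unname(est - tq * se),
                    ci_high = unname(est + tq * se),
                    p_value = unname(2 * stats::pt(-abs(tval), dfres)),
                    row.names = NULL)
  structure(list(coefficients = tab, n = nrow(df), covariates = cov_names,
                 fit = fit), class = "adjusted_fit")
}

#' @export
print.adjusted_fit <- function(x, ...) {
  cat(sprintf("Adjusted OLS (n = %d%s)\n", x$n,
              if (length(x$covariates))
                paste0(", adjusted for ", paste(x$covariates, collapse = ", "))
              else ""))
  tab <- x$coefficients
  tab[-1L] <- lapply(tab[-1L], signif, digits = 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.adjusted_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Cohort normative table of segmental InD
#'
#' Stratified summary of a cohort of bullseyes: per stratum (by default age
#' decade) and per segment, the number of subjects, mean, SD, the 95%
#' confidence interval of the mean (`mean +/- 1.96 sd/sqrt(n)`) and the 95%
#' reference interval (`mean +/- 1.96 sd`); both interval types are reported
#' because normative tables use either.
#'
#' @param data long-format data.frame with columns `subject_id`, `segment`,
#'   `ind_pct` and any stratification columns.
#' @param strata character vector of stratification column names; the special
#'   name `"age_group"` is derived from a numeric `age` column in decades.
#' @param digits rounding of the reported statistics (default 1 decimal).
#' @return data.frame with one row per stratum x segment cell; cells with
#'   fewer than 2 subjects are omitted with a warning.
#' @export
cohort_table <- function(data, strata = "age_group", digits = 1) {
  need <- c("subject_id", "segment", "ind_pct")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  if ("age_group" %in% strata && !"age_group" %in% names(data)) {
    if (!"age" %in% names(data))
      stop("strata 'age_group' needs an 'age' column")
    data$age_group <- cut(data$age, breaks = seq(20, 80, by = 10),
                          include.lowest = TRUE, right = TRUE)
  }
  keys <- c(strata, "segment")
  split_key <- interaction(data[keys], drop = TRUE)
  rows <- lapply(split(data, split_key), function(cell) {
    n <- length(unique(cell$subject_id))
    if (n < 2L) return(NULL)
    m <- mean(cell$ind_pct); s <- stats::sd(cell$ind_pct)
    out <- cell[1L, keys, drop = FALSE]
    out$n <- n
    out$mean_pct <- round(m, digits)
    out$sd_pct <- round(s, digits)
    out$ci_low <- round(m - 1.96 * s / sqrt(n), digits)
    out$ci_high <- round(m + 1.96 * s / sqrt(n), digits)
    out$ref_low <- round(m - 1.96 * s, digits)
    out$ref_high <- round(m + 1.96 * s, digits)
    out
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    warning(dropped, " cell(s) with fewer than 2 subjects omitted")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no reportable cells (all strata empty)")
  out <- out[order(out[[strata[1L]]], out$segment), ]
  rownames(out) <- NULL
  out
}
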