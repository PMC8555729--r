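## Prior-influence regressions, mean splits, 3-sigma comparison, Fisher-z
## correlation intervals.

#' Per-participant mean interpretation for one direction of evidence
#'
#' Interpretation ratings are averaged per participant, separately per
#' direction of evidence; the regressions of interpretation on prior belief
#' run on these means, not on trial rows.
#'
#' @param trials data frame with `participant_id`, `true_direction`,
#'   `rating`.
#' @param direction +1 (endorsing texts) or -1 (rejecting texts).
#' @return data frame with `participant_id` and `mean_rating`; participants
#'   with no trial in that direction are absent.
#' @export
average_interpretation <- function(trials, direction) {
  stopifnot(direction %in% c(-1, 1))
  sub <- trials[trials$true_direction == direction, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(participant_id = character(0), mean_rating = numeric(0),
                      stringsAsFactors = FALSE))
  }
  agg <- tapply(sub$rating, sub$participant_id, mean)
  data.frame(participant_id = names(agg), mean_rating = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ordinary least squares fit of interpretation on prior belief
#'
#' Fits `y = alpha + gamma * x + e` by OLS (via [stats::lm()]); `alpha` is
#' the average interpretation of the evidence and `gamma` the direction and
#' strength of the influence of the prior belief on that interpretation.
#'
#' @param x prior beliefs.
#' @param y mean interpretation ratings (same length).
#' @return object of class `"regression_fit"`: `alpha`, `gamma`,
#'   `se_alpha`, `se_gamma`, `rse` (residual standard error,
#'   `sqrt(RSS/(n-2))`), `n`.
#' @export
ols_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("OLS fit needs at least 3 observations", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("degenerate design: predictor is constant", call. = FALSE)
  fit <- lm(y ~ x)
  # a noise-free line is a legitimate input (rse = 0); silence summary.lm's
  # perfect-fit warning
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(list(
    alpha = unname(cf[1, 1]), gamma = unname(cf[2, 1]),
    se_alpha = unname(cf[1, 2]), se_gamma = unname(cf[2, 2]),
    rse = sqrt(sum(residuals(fit)^2) / (n - 2)), n = n
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("alpha = %.3f +/- %.3f, gamma = %.3f +/- %.3f, RSE = %.3f (n = %d)\n",
              x$alpha, x$se_alpha, x$gamma, x$se_gamma, x$rse, x$n))
  invisible(x)
}

#' Split participants at the mean of a variable
#'
#' Values strictly above the arithmetic mean are `"high"`, strictly below
#' `"low"`. The conventional definition uses strict inequalities only, so a
#' value exactly at the mean needs a tie rule; the default sends it to
#' `"high"` (toggleable).
#'
#' @param values numeric vector (>= 2 distinct values).
#' @param ties `"high"` or `"low"`: side for values exactly at the mean.
#' @return object of class `"split_result"`: `threshold` (the mean),
#'   `assignment` (character vector `"high"`/`"low"`), `n_high`, `n_low`.
#' @export
mean_split <- function(values, ties = c("high", "low")) {
  ties <- match.arg(ties)
  vals <- values[is.finite(values)]
  if (length(unique(vals)) < 2)
    stop("degenerate split: fewer than 2 distinct values", call. = FALSE)
  m <- mean(vals)
  assignment <- ifelse(values > m, "high",
                       ifelse(values < m, "low", ties))
  assignment[!is.finite(values)] <- NA_character_
  structure(list(threshold = m, assignment = assignment,
                 n_high = sum(assignment == "high", na.rm = TRUE),
                 n_low = sum(assignment == "low", na.rm = TRUE)),
            class = "split_result")
}

#' Compare a parameter across two fits by 3-sigma regions
#'
#' Two parameters are declared significantly different when their
#' `estimate +/- 3 * SE` intervals are disjoint.
#'
#' @param fit_a,fit_b `"regression_fit"` objects.
#' @param parameter `"gamma"` or `"alpha"`.
#' @return `"significant"` or `"not_significant"`.
#' @export
three_sigma_compare <- function(fit_a, fit_b, parameter = c("gamma", "alpha")) {
  parameter <- match.arg(parameter)
  se_name <- paste0("se_", parameter)
  a <- c(fit_a[[parameter]] - 3 * fit_a[[se_name]],
         fit_a[[parameter]] + 3 * fit_a[[se_name]])
  b <- c(fit_b[[parameter]] - 3 * fit_b[[se_name]],
         fit_b[[parameter]] + 3 * fit_b[[se_name]])
  if (a[2] < b[1] || b[2] < a[1]) "significant" else "not_significant"
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y numeric vectors (n >= 4).
#' @param level confidence level (default 0.95).
#' @return list: `r`, `ci_low`, `ci_high`, `df` (= n - 2), `n`.
#' @export
corr_fisher_ci <- function(x, y, level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("correlation CI needs n >= 4", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  list(r = r, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se),
       df = n - 2L, n = n)
}
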