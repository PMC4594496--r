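#' Normative sample summary
#'
#' Summary statistics of a small healthy control sample on two tasks, the
#' anchor of every single-case test: per-task mean and SD, the inter-task
#' correlation, and the sample size.
#'
#' @param mean_x,sd_x Control mean and SD on task x (e.g. LL); `sd_x > 0`.
#' @param mean_y,sd_y Control mean and SD on task y (e.g. CL); `sd_y > 0`.
#' @param r Inter-task correlation, |r| < 1.
#' @param n Control sample size (>= 2).
#' @param task_x,task_y Task labels.
#' @return An object of class `normative_summary`.
#' @examples
#' normative_summary(5.5, 1.5, 13.4, 8.4, r = 0.8, n = 12)
#' @export
normative_summary <- function(mean_x, sd_x, mean_y, sd_y, r, n,
                              task_x = "LL", task_y = "CL") {
  vals <- c(mean_x, sd_x, mean_y, sd_y, r, n)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop_invalid_parameter("all summary statistics must be finite numbers")
  if (sd_x <= 0 || sd_y <= 0)
    stop_invalid_parameter("control SDs must be positive")
  if (abs(r) >= 1)
    stop_invalid_parameter("inter-task correlation must satisfy |r| < 1")
  if (n < 2)
    stop_invalid_parameter("control sample size must be >= 2")
  structure(list(mean_x = mean_x, sd_x = sd_x, mean_y = mean_y, sd_y = sd_y,
                 r = r, n = as.integer(n),
                 task_x = task_x, task_y = task_y),
            class = "normative_summary")
}

#' @export
print.normative_summary <- function(x, ...) {
  cat(sprintf(
    "Normative sample (n = %d): %s = %.3g ± %.3g; %s = %.3g ± %.3g; r = %.3g\n",
    x$n, x$task_x, x$mean_x, x$sd_x, x$task_y, x$mean_y, x$sd_y, x$r))
  invisible(x)
}

#' Two-tailed p from a Student's t statistic
#'
#' @param statistic Test statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Two-tailed tail probability, symmetric in the sign of `statistic`.
#' @examples
#' p_from_t(2.42, 11)  # ~0.034
#' @export
p_from_t <- function(statistic, df) {
  if (!is.numeric(df) || any(df < 1))
    stop_invalid_parameter("`df` must be >= 1")
  2 * stats::pt(abs(statistic), df, lower.tail = FALSE)
}

case_htest <- function(statistic, df, method, data.name, estimate = NULL) {
  res <- list(statistic = c(t = statistic), parameter = c(df = df),
              p.value = p_from_t(statistic, df), method = method,
              data.name = data.name, alternative = "two.sided")
  if (!is.null(estimate)) res$estimate <- estimate
  structure(res, class = "htest")
}

#' Revised Standardized Difference Test (RSDT)
#'
#' Tests whether a single case's discrepancy between two tasks, each
#' standardized against the control sample, is abnormal relative to the
#' discrepancies seen in the controls. The statistic is the positive root of
#' the method's small-sample-corrected quadratic in the squared standardized
#' discrepancy, signed by \eqn{z_x - z_y} and referred to Student's t with
#' \eqn{n - 1} degrees of freedom, two-tailed (Crawford & Garthwaite, 2005).
#'
#' @param x,y The case's scores on task x and task y.
#' @param norm A [normative_summary()].
#' @return An object of class `htest` with the statistic, `df = n - 1` and
#'   the two-tailed p-value.
#' @examples
#' nrm <- normative_summary(5.5, 1.5, 13.4, 8.4, r = 0.8, n = 12)
#' rsdt(10.4, 11.5, nrm)
#' @export
rsdt <- function(x, y, norm) {
  check_case_scores(x, y, norm)
  zx <- (x - norm$mean_x) / norm$sd_x
  zy <- (y - norm$mean_y) / norm$sd_y
  n <- norm$n; r <- norm$r
  a <- (1 + r) * (1 - r^2)
  b <- (1 - r) * (4 * (n - 1)^2 + 4 * (1 + r) * (n - 1) + (1 + r) * (5 + r))
  cc <- -2 * (zx - zy)^2 * (n * (n - 1)^2 / (n + 1))
  stat <- sign0(zx - zy) * sqrt((-b + sqrt(b^2 - 4 * a * cc)) / (2 * a))
  case_htest(stat, n - 1L, "Revised standardized difference test (RSDT)",
             sprintf("case (%g, %g) vs %s/%s controls (n = %d)",
                     x, y, norm$task_x, norm$task_y, n),
             estimate = c(z_x = zx, z_y = zy))
}

sign0 <- function(v) if (v == 0) 1 else sign(v)

#' Unstandardized Difference Test (UDT)
#'
#' Companion to [rsdt()] for raw (unstandardized) task scores: the case's
#' discrepancy is compared to the controls' mean discrepancy and scaled by
#' the control discrepancy SD inflated for a sample of one,
#' \deqn{t = \frac{(x - y) - (\bar X - \bar Y)}
#'              {s_{x-y}\sqrt{1 + 1/n}}, \quad
#'       s_{x-y} = \sqrt{s_x^2 + s_y^2 - 2 r s_x s_y},}
#' with \eqn{df = n - 1}, two-tailed. Appropriate when the two tasks share a
#' scale; used here as a closed-form cross-check on the RSDT machinery.
#'
#' @inheritParams rsdt
#' @return An `htest`.
#' @export
udt <- function(x, y, norm) {
  check_case_scores(x, y, norm)
  s_d <- sqrt(norm$sd_x^2 + norm$sd_y^2 - 2 * norm$r * norm$sd_x * norm$sd_y)
  if (s_d <= 0)
    stop(errorCondition(
      "degenerate control discrepancy variance (r = 1 with equal SDs)",
      class = c("cl_degenerate_variance", "error")))
  stat <- ((x - y) - (norm$mean_x - norm$mean_y)) /
    (s_d * sqrt(1 + 1 / norm$n))
  case_htest(stat, norm$n - 1L, "Unstandardized difference test (UDT)",
             sprintf("case (%g, %g) vs %s/%s controls (n = %d)",
                     x, y, norm$task_x, norm$task_y, norm$n))
}

#' Two-case comparison referred to a control sample
#'
#' Tests whether two single cases differ on a score, scaling their
#' difference by the control sample's SD of that score:
#' \eqn{z = (d_1 - d_2) / (s \sqrt 2)}, referred to Student's t with
#' \eqn{n - 1} degrees of freedom, two-tailed. The statistic is signed as
#' case 1 minus case 2.
#'
#' @param d1,d2 The two cases' scores (e.g. each case's CL − LL difference).
#' @param sd_controls SD of that score in the control sample (> 0).
#' @param n Control sample size (>= 2).
#' @return An `htest`.
#' @examples
#' case_comparison(1.1, 24.4, sd_controls = 6.8, n = 12)  # t ~ -2.42
#' @export
case_comparison <- function(d1, d2, sd_controls, n) {
  if (!is.numeric(sd_controls) || sd_controls <= 0)
    stop_invalid_parameter("`sd_controls` must be positive")
  if (!is.numeric(n) || n < 2)
    stop_invalid_parameter("`n` must be >= 2")
  stopifnot(is.finite(d1), is.finite(d2))
  stat <- (d1 - d2) / (sd_controls * sqrt(2))
  case_htest(stat, as.integer(n) - 1L,
             "Two-case comparison vs control sample SD",
             sprintf("case1 = %g, case2 = %g, control SD = %g (n = %d)",
                     d1, d2, sd_controls, as.integer(n)))
}

#' Single-score deficit test
#'
#' Case-versus-controls test on one score: the case's deviation from the
#' control mean scaled by the control SD inflated for a sample of one,
#' \eqn{t = (x - \bar X) / (s \sqrt{1 + 1/n})}, \eqn{df = n - 1}, two-tailed.
#'
#' @param x Case score.
#' @param mean,sd Control mean and SD (`sd > 0`).
#' @param n Control sample size (>= 2).
#' @return An `htest`.
#' @examples
#' deficit_test(10.4, mean = 5.5, sd = 1.5, n = 12)  # t ~ 3.14
#' @export
deficit_test <- function(x, mean, sd, n) {
  if (!is.numeric(sd) || sd <= 0)
    stop_invalid_parameter("`sd` must be positive")
  if (!is.numeric(n) || n < 2)
    stop_invalid_parameter("`n` must be >= 2")
  stopifnot(is.finite(x), is.finite(mean))
  stat <- (x - mean) / (sd * sqrt(1 + 1 / n))
  case_htest(stat, as.integer(n) - 1L, "Single-score deficit test",
             sprintf("case %g vs controls %g ± %g (n = %d)",
                     x, mean, sd, as.integer(n)))
}

check_case_scores <- function(x, y, norm) {
  if (!inherits(norm, "normative_summary"))
    stop_invalid_parameter("`norm` must be a normative_summary")
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L)
  if (!is.finite(x) || !is.finite(y))
    stop_invalid_parameter("case scores must be finite")
  invisible(TRUE)
}
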