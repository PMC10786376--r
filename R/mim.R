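#' Per-group summary statistics
#'
#' The minimal sufficient scale statistics for one normal group: the sample
#' size and the sample variance with divisor \eqn{n - 1}.  Group means carry
#' no information about the variances and are not required.
#'
#' @param label group label (single string).
#' @param n sample size, an integer >= 2.
#' @param s2 sample variance (divisor n - 1); must be strictly positive,
#'   since a degenerate group breaks the normal scale model.
#' @return an object of class `"group_summary"`.
#' @examples
#' group_summary("control", n = 10, s2 = 0.052)
#' @export
group_summary <- function(label, n, s2) {
  if (length(label) != 1L || !nzchar(as.character(label)))
    stop("`label` must be a non-empty string")
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("group '", label, "': sample size must be an integer >= 2")
  if (length(s2) != 1L || is.na(s2) || s2 <= 0)
    stop("group '", label, "': sample variance must be > 0 ",
         "(a group of identical observations carries no scale information)")
  structure(list(label = as.character(label), n = n, s2 = as.numeric(s2)),
            class = "group_summary")
}

#' Study summary: one control group plus k treatment groups
#'
#' The unit of inference for the variance-comparison tests: a control
#' [group_summary()] and an ordered list of \eqn{k \ge 1} treatment
#' summaries with unique labels.
#'
#' @param control a [group_summary()] for the control group.
#' @param treatments a list of [group_summary()] objects, one per treatment.
#' @return an object of class `"study_summary"`.
#' @examples
#' smokers <- study_summary(
#'   control = group_summary("non-smokers", 10, 0.0520),
#'   treatments = list(group_summary("former", 10, 0.0389),
#'                     group_summary("light",  10, 0.0250),
#'                     group_summary("heavy",  10, 0.0075)))
#' observed_statistic(smokers)
#' @export
study_summary <- function(control, treatments) {
  if (!inherits(control, "group_summary"))
    stop("`control` must be a group_summary")
  if (inherits(treatments, "group_summary")) treatments <- list(treatments)
  if (!is.list(treatments) || length(treatments) < 1L ||
      !all(vapply(treatments, inherits, logical(1), "group_summary")))
    stop("`treatments` must be a list of k >= 1 group_summary objects")
  labels <- c(control$label, vapply(treatments, `[[`, character(1), "label"))
  if (anyDuplicated(labels))
    stop("group labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  structure(list(control = control, treatments = treatments,
                 k = length(treatments)),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Variance-comparison study: control '", x$control$label, "' vs ",
      x$k, " treatment group(s)\n", sep = "")
  df <- data.frame(
    group = c(x$control$label,
              vapply(x$treatments, `[[`, character(1), "label")),
    role = c("control", rep("treatment", x$k)),
    n = c(x$control$n, vapply(x$treatments, `[[`, integer(1), "n")),
    variance = c(x$control$s2, vapply(x$treatments, `[[`, numeric(1), "s2")))
  print(df, row.names = FALSE)
  invisible(x)
}

.study_df <- function(study) {
  ratio_dist(study$control$n - 1L,
             vapply(study$treatments, `[[`, integer(1), "n") - 1L)
}

.treatment_s2 <- function(study)
  vapply(study$treatments, `[[`, numeric(1), "s2")

#' Observed control-to-minimum variance ratio
#'
#' The test statistic \eqn{T = S_0^2 / \min_i S_i^2}: the control sample
#' variance divided by the smallest treatment sample variance.  Large values
#' of \eqn{T} are evidence that some treatment is less variable than the
#' control.
#'
#' @param study a [study_summary()].
#' @return positive scalar \eqn{T}.
#' @export
observed_statistic <- function(study) {
  stopifnot(inherits(study, "study_summary"))
  study$control$s2 / min(.treatment_s2(study))
}

#' MIM plausibility of a variance-ratio value
#'
#' Plausibility of the assertion \eqn{\{\theta\}} about
#' \eqn{\theta = \min_i \sigma_i^2/\sigma_0^2}, computed as
#' \deqn{pl(\theta) = 1 - F(T\,\theta),}
#' where \eqn{T} is the observed statistic and \eqn{F} is the data-free null
#' CDF of the control-to-minimum chi-square ratio ([ratio_cdf()]).  At
#' \eqn{\theta = 1} this is the evidence measure of the MIM test of
#' \eqn{H_0: \theta = 1} against \eqn{H_1: \theta < 1}, and plays the role
#' of a p-value: under the null it is exactly Unif(0, 1) distributed.
#'
#' @param study a [study_summary()].
#' @param theta positive value (or vector) of the variance ratio to assess.
#' @return plausibility value(s) in \[0, 1\].
#' @examples
#' smokers <- study_summary(
#'   group_summary("non-smokers", 10, 0.0520),
#'   list(group_summary("former", 10, 0.0389),
#'        group_summary("light",  10, 0.0250),
#'        group_summary("heavy",  10, 0.0075)))
#' mim_plausibility(smokers, 1)
#' @export
mim_plausibility <- function(study, theta = 1) {
  stopifnot(inherits(study, "study_summary"))
  if (anyNA(theta) || any(theta <= 0)) stop("`theta` must be positive")
  T <- observed_statistic(study)
  1 - ratio_cdf(.study_df(study), T * theta)
}

#' The MIM test for variances against a control
#'
#' Tests \eqn{H_0: \sigma_i^2 = \sigma_0^2} for all treatments against the
#' tree-ordered alternative that at least one treatment variance is smaller,
#' rejecting when the plausibility of \eqn{\theta = 1} is at most `alpha`.
#' Valid for arbitrary (unequal) sample sizes.
#'
#' @param study a [study_summary()].
#' @param alpha significance level in (0, 1).
#' @return a `"test_result"` with fields `method`, `statistic`,
#'   `plausibility`, `alpha`, `reject`.
#' @examples
#' smokers <- study_summary(
#'   group_summary("non-smokers", 10, 0.0520),
#'   list(group_summary("former", 10, 0.0389),
#'        group_summary("light",  10, 0.0250),
#'        group_summary("heavy",  10, 0.0075)))
#' mim_test(smokers, alpha = 0.05)
#' @export
mim_test <- function(study, alpha = 0.05) {
  .check_alpha(alpha)
  pl <- mim_plausibility(study, 1)
  new_test_result("MIM", observed_statistic(study), pl, alpha)
}

new_test_result <- function(method, statistic, plausibility, alpha) {
  structure(list(method = method, statistic = statistic,
                 plausibility = plausibility, alpha = alpha,
                 reject = plausibility <= alpha),
            class = "test_result")
}

.check_alpha <- function(alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single number strictly inside (0, 1)")
}

#' @export
print.test_result <- function(x, ...) {
  lbl <- if (x$method == "MIM") "plausibility / p-value (MIM)" else "p-value"
  cat(x$method, " test of H0: all treatment variances equal the control\n",
      "  statistic T = S0^2 / min Si^2 = ", format(x$statistic), "\n",
      "  ", lbl, " = ", sprintf("%.4f", x$plausibility), "\n",
      "  decision at alpha = ", format(x$alpha), ": ",
      if (x$reject) "reject H0 (some treatment variance is smaller)"
      else "fail to reject H0", "\n", sep = "")
  invisible(x)
}

#' Plausibility curve over a grid of variance ratios
#'
#' Evaluates [mim_plausibility()] on a grid of \eqn{\theta} values.  The
#' default grid has 400 log-spaced points covering plausibilities from
#' 0.999 down to 0.001, so the whole informative range of the curve is
#' visible.  Cutting the curve at height \eqn{\alpha} gives the
#' \eqn{100(1-\alpha)\%} upper confidence bound for \eqn{\theta}.
#'
#' @param study a [study_summary()].
#' @param theta_grid strictly increasing positive grid; `NULL` for the
#'   default.
#' @param n_points number of points in the default grid.
#' @return a `"plausibility_curve"`: list with `thetas` and `pl_values`
#'   (nonincreasing in `thetas`).
#' @export
plausibility_curve <- function(study, theta_grid = NULL, n_points = 400L) {
  stopifnot(inherits(study, "study_summary"))
  T <- observed_statistic(study)
  if (is.null(theta_grid)) {
    dist <- .study_df(study)
    lim <- ratio_quantile(dist, c(0.001, 0.999)) / T
    theta_grid <- exp(seq(log(lim[1L]), log(lim[2L]), length.out = n_points))
  } else {
    if (length(theta_grid) < 1L || anyNA(theta_grid) ||
        any(theta_grid <= 0) || is.unsorted(theta_grid, strictly = TRUE))
      stop("`theta_grid` must be a strictly increasing positive grid")
  }
  structure(list(thetas = theta_grid,
                 pl_values = mim_plausibility(study, theta_grid)),
            class = "plausibility_curve")
}

#' @export
print.plausibility_curve <- function(x, ...) {
  cat("Plausibility curve on", length(x$thetas), "theta values in [",
      format(min(x$thetas)), ",", format(max(x$thetas)), "]\n")
  invisible(x)
}

#' @rdname plausibility_curve
#' @param x a `"plausibility_curve"`.
#' @param alpha if non-`NULL`, draw a horizontal reference at this level.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.plausibility_curve <- function(x, alpha = 0.05, ...) {
  plot.default(x$thetas, x$pl_values, type = "l", log = "x",
               xlab = expression(theta), ylab = "plausibility", ...)
  if (!is.null(alpha)) abline(h = alpha, lty = 3)
  invisible(x)
}

#' Upper confidence bound for the minimum variance ratio
#'
#' The \eqn{100(1-\alpha)\%} one-sided upper bound for
#' \eqn{\theta = \min_i \sigma_i^2/\sigma_0^2}, obtained by inverting the
#' plausibility function: \eqn{\theta_U = F^{-1}(1-\alpha) / T}, the
#' supremum of \eqn{\{\theta : pl(\theta) > \alpha\}}.  The test-interval
#' duality holds: the level-\eqn{\alpha} MIM test rejects exactly when
#' \eqn{\theta_U < 1}.
#'
#' @param study a [study_summary()].
#' @param alpha one minus the confidence level.
#' @return positive scalar \eqn{\theta_U}.
#' @export
mim_upper_bound <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "study_summary"))
  .check_alpha(alpha)
  ratio_quantile(.study_df(study), 1 - alpha) / observed_statistic(study)
}
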