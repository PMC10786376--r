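#' Spurrier's exact test for variances against a control
#'
#' The optimal lower one-sided test for the equal-treatment-sample-size
#' design.  With \eqn{F_i = (S_i^2/\sigma_i^2)/(S_0^2/\sigma_0^2)} a
#' multivariate-F vector and \eqn{F_{(1)} = \min_i F_i}, the p-value is
#' \deqn{p = P(F_{(1)} \le c)
#'   = 1 - \int_0^\infty \left[1 - H\!\left(\frac{x c (m-1)}{n-1}\right)
#'   \right]^k g(x)\, dx,}
#' where \eqn{c = \min_i s_i^2/s_0^2} is the observed minimum variance
#' ratio, \eqn{H} is the \eqn{\chi^2(m-1)} CDF and \eqn{g} the
#' \eqn{\chi^2(n-1)} density.  The integral is evaluated by the same
#' chi-square-probability-substitution quadrature used for [ratio_cdf()]
#' (absolute error at most 1e-8), with an independent Gauss-Laguerre path
#' retained internally as a cross-check.
#'
#' @param n control sample size (>= 2).
#' @param m common treatment sample size (>= 2).
#' @param k number of treatment groups (>= 1).
#' @param c observed statistic \eqn{\min_i s_i^2/s_0^2 > 0}.
#' @return the p-value, a single number in \[0, 1\].
#' @examples
#' # four groups of 10: control variance 0.0520, smallest treatment 0.0075
#' spurrier_pvalue(n = 10, m = 10, k = 3, c = 0.0075 / 0.0520)
#' @seealso [spurrier_from_study()], [mim_test()]
#' @export
spurrier_pvalue <- function(n, m, k, c) {
  n <- as.integer(n); m <- as.integer(m); k <- as.integer(k)
  if (anyNA(c(n, m, k)) || n < 2L || m < 2L || k < 1L)
    stop("require n >= 2, m >= 2, k >= 1")
  if (length(c) != 1L || is.na(c) || c <= 0)
    stop("`c` (the minimum treatment-to-control variance ratio) must be > 0")
  if (is.infinite(c)) return(1)
  scale <- c * (m - 1) / (n - 1)
  f <- function(u)
    exp(k * pchisq(qchisq(u, n - 1) * scale, m - 1,
                   lower.tail = FALSE, log.p = TRUE))
  fv <- function(x)
    exp(dchisq(x, n - 1, log = TRUE) +
          k * pchisq(x * scale, m - 1, lower.tail = FALSE, log.p = TRUE))
  # integrand transitions around x ~ (m - 1)/scale; same split policy as
  # ratio_cdf: lower probability half on the u scale, upper half on the raw
  # x scale out to infinity
  xc <- (m - 1) / scale * c(0.01, 0.03, 0.1, 0.2, 0.35, 0.5, 0.7, 1, 1.5, 2.5, 5, 10, 30, 100)
  int <- .integrate_split(f, pchisq(xc, n - 1), upper.limit = 0.5,
                          abs.tol = 1e-10) +
    .integrate_tail(fv, from = qchisq(0.5, n - 1),
                    cuts = c(xc, qchisq(c(1e-1, 1e-2, 1e-4, 1e-6, 1e-8,
                                          1e-10, 1e-12),
                                        n - 1, lower.tail = FALSE)),
                    abs.tol = 1e-10)
  min(max(1 - int, 0), 1)
}

# Gauss-Laguerre evaluation of the same integral (cross-check path).
.spurrier_pvalue_laguerre <- function(n, m, k, c, n_nodes = 128L) {
  gl <- .gauss_laguerre(n_nodes)
  t <- gl$nodes  # x = 2t, x ~ chi^2(n-1) density
  lw <- log(gl$weights) + ((n - 1) / 2 - 1) * log(t) - lgamma((n - 1) / 2)
  ls <- k * pchisq(2 * t * c * (m - 1) / (n - 1), m - 1,
                   lower.tail = FALSE, log.p = TRUE)
  1 - sum(exp(lw + ls))
}

#' Spurrier's test from a study summary
#'
#' Adapter from the shared [study_summary()] container.  Refuses studies
#' whose treatment sample sizes are unequal, since Spurrier's test is only
#' defined for a common treatment size; use [mim_test()] in that case.
#'
#' @param study a [study_summary()] whose treatments share one sample size.
#' @param alpha significance level in (0, 1).
#' @return a `"test_result"` with method `"Spurrier"`; the reported
#'   `statistic` is \eqn{T = S_0^2/\min_i S_i^2 = 1/c} so that MIM and
#'   Spurrier results print on the same scale.
#' @export
spurrier_from_study <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "study_summary"))
  .check_alpha(alpha)
  sizes <- vapply(study$treatments, `[[`, integer(1), "n")
  if (length(unique(sizes)) != 1L)
    stop("Spurrier's test requires equal sample sizes among the treatment ",
         "groups (observed sizes: ", paste(sizes, collapse = ", "),
         "); use the MIM test for unequal designs")
  T <- observed_statistic(study)
  p <- spurrier_pvalue(n = study$control$n, m = sizes[1L],
                       k = study$k, c = 1 / T)
  new_test_result("Spurrier", T, p, alpha)
}
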