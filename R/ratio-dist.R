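#' Null distribution of the control-to-minimum variance ratio
#'
#' Constructs the distribution of the auxiliary variable
#' \deqn{R = \frac{V_0^2/d_0}{\min_i V_i^2/d_i},}
#' where \eqn{V_0^2 \sim \chi^2(d_0)} and \eqn{V_i^2 \sim \chi^2(d_i)} are
#' independent, \eqn{d_0} is the control degrees of freedom (\eqn{n_0 - 1})
#' and \eqn{d_i} the treatment degrees of freedom (\eqn{n_i - 1}).  Under the
#' null hypothesis of equal variances the observed statistic
#' \eqn{T = S_0^2/\min_i S_i^2} is distributed as \eqn{R}, so this
#' distribution is the reference distribution of the MIM test.  For a single
#' treatment group (\eqn{k = 1}) \eqn{R} is an ordinary
#' \eqn{F(d_0, d_1)} variate.
#'
#' @param df0 positive integer, control degrees of freedom (\eqn{n_0 - 1}).
#' @param dfs vector of positive integers, treatment degrees of freedom
#'   (\eqn{n_i - 1}), one per treatment group.
#' @param abs.tol absolute error tolerance requested of the quadrature.
#'
#' @return an object of class `"ratio_dist"` with elements `df0`, `dfs`,
#'   `k` and `abs.tol`, accepted by [ratio_cdf()] and [ratio_quantile()].
#'
#' @examples
#' rd <- ratio_dist(9, c(9, 9, 9))
#' ratio_cdf(rd, 1)
#' ratio_quantile(rd, 0.95)
#' @seealso [ratio_cdf()], [ratio_quantile()], [ratio_cdf_mc()]
#' @export
ratio_dist <- function(df0, dfs, abs.tol = 1e-10) {
  df0 <- as.integer(df0)
  dfs <- as.integer(dfs)
  if (length(df0) != 1L || is.na(df0) || df0 < 1L)
    stop("`df0` must be a single integer >= 1 (control group needs >= 2 observations)")
  if (length(dfs) < 1L || anyNA(dfs) || any(dfs < 1L))
    stop("`dfs` must contain k >= 1 integers, each >= 1 (every group needs >= 2 observations)")
  structure(
    list(df0 = df0, dfs = dfs, k = length(dfs), abs.tol = abs.tol),
    class = "ratio_dist"
  )
}

#' @export
print.ratio_dist <- function(x, ...) {
  cat("Control-to-minimum variance-ratio distribution\n")
  cat("  control df:  ", x$df0, "\n", sep = "")
  cat("  treatment df:", paste(x$dfs, collapse = ", "), "\n")
  cat("  quadrature abs.tol: ", format(x$abs.tol), "\n", sep = "")
  invisible(x)
}

# Integrand after the probability substitution u = P(chi^2_{d0} <= v):
#   F(x) = int_0^1 prod_i P(chi^2_{d_i} > d_i q(u) / (d0 x)) du,
# with q = qchisq(., d0).  The substitution absorbs the chi-square weight
# (and the d0 = 1 endpoint singularity) so the integrand is bounded on (0,1).
# Survival probabilities come from the upper-tail branch of pchisq, never
# from 1 - pchisq, to avoid cancellation in the far tail.  `upper = TRUE`
# evaluates at u = 1 - w through the upper-tail quantile so that the region
# near u = 1 keeps full floating-point resolution.
.ratio_integrand <- function(u, df0, dfs, x, upper = FALSE) {
  v <- qchisq(u, df0, lower.tail = !upper)
  out <- rep(1, length(u))
  for (d in dfs)
    out <- out * pchisq(d * v / (df0 * x), d, lower.tail = FALSE)
  out
}

#' CDF of the control-to-minimum variance ratio
#'
#' Evaluates \eqn{F(x) = P(R \le x)} for the ratio variable described in
#' [ratio_dist()], as the one-dimensional integral
#' \deqn{F(x) = \int_0^\infty \prod_{i=1}^{k}
#'   \left[1 - H_{d_i}\!\left(\frac{d_i v}{d_0 x}\right)\right]
#'   g_{d_0}(v)\, dv,}
#' with \eqn{H_d} the \eqn{\chi^2(d)} CDF and \eqn{g_d} its density.  The
#' integral is computed by adaptive quadrature after substituting
#' \eqn{u = H_{d_0}(v)}, which removes the chi-square weight and any endpoint
#' singularity (degrees of freedom of 1 are supported).
#'
#' @param dist a [ratio_dist()] object.
#' @param x positive numeric vector of evaluation points.
#'
#' @return numeric vector of probabilities \eqn{F(x)}, with absolute
#'   quadrature error at most `dist$abs.tol` (an error is raised if the
#'   quadrature cannot certify 1e-8).
#'
#' @examples
#' # with one treatment group the ratio is a standard F variate
#' ratio_cdf(ratio_dist(9, 9), 1.7)
#' pf(1.7, 9, 9)
#' @export
ratio_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "ratio_dist"))
  if (length(x) == 0L) return(numeric(0))
  if (anyNA(x) || any(x <= 0))
    stop("`x` must be positive")
  vapply(x, function(xi) {
    if (is.infinite(xi)) return(1)
    # The integrand drops from 1 to 0 around v ~ df0 * x; seed the adaptive
    # rule with cuts there so narrow boundary layers are not missed.  The
    # lower half of probability space is integrated on the u scale, the
    # upper half on the survival scale w = 1 - u, which keeps resolution
    # near u = 1 where qchisq(u, .) degrades.
    vc <- dist$df0 * xi * c(0.01, 0.03, 0.1, 0.2, 0.35, 0.5, 0.7, 1, 1.5, 2.5, 5, 10, 30, 100)
    lo <- .integrate_split(
      .ratio_integrand, pchisq(vc, dist$df0), upper.limit = 0.5,
      abs.tol = dist$abs.tol, df0 = dist$df0, dfs = dist$dfs, x = xi)
    hi <- .integrate_tail(
      function(v) .ratio_vspace(v, dist$df0, dist$dfs, xi),
      from = qchisq(0.5, dist$df0),
      cuts = c(vc, qchisq(c(1e-1, 1e-2, 1e-4, 1e-6, 1e-8, 1e-10, 1e-12),
                          dist$df0, lower.tail = FALSE)),
      abs.tol = dist$abs.tol)
    min(max(lo + hi, 0), 1)
  }, numeric(1))
}

# Sum of adaptive integrals of f over the panels of (0, upper.limit) defined
# by the interior cut points; certifies a total absolute error below 1e-8.
.integrate_split <- function(f, cuts, abs.tol, upper.limit = 1, ...) {
  edges <- sort(unique(c(0, pmin(pmax(cuts, 0), upper.limit), upper.limit)))
  edges <- edges[c(TRUE, diff(edges) > 1e-15)]
  total <- 0; err <- 0
  for (j in seq_len(length(edges) - 1L)) {
    q <- integrate(f, edges[j], edges[j + 1L], ...,
                   rel.tol = 1e-8, abs.tol = min(abs.tol, 1e-12),
                   subdivisions = 500L, stop.on.error = FALSE)
    if (!(q$message %in% "OK"))
      stop("quadrature did not converge on (", format(edges[j]), ", ",
           format(edges[j + 1L]), "): ", q$message)
    total <- total + q$value; err <- err + q$abs.error
  }
  if (err > 1e-8)
    stop("quadrature error estimate ", format(err), " exceeds 1e-8")
  total
}

# Chi-square-weighted integrand on the raw v scale, in log form so the
# density and far-tail survival factors cannot underflow prematurely.
.ratio_vspace <- function(v, df0, dfs, x) {
  ls <- dchisq(v, df0, log = TRUE)
  for (d in dfs)
    ls <- ls + pchisq(d * v / (df0 * x), d, lower.tail = FALSE, log.p = TRUE)
  exp(ls)
}

# Adaptive integral of f over (from, Inf), split at the cut points; the
# final unbounded piece uses QUADPACK's infinite-range transformation,
# which is well suited to the exponential chi-square tail.
.integrate_tail <- function(f, from, cuts, abs.tol) {
  edges <- sort(unique(c(from, cuts[cuts > from])))
  total <- 0; err <- 0
  for (j in seq_along(edges)) {
    upper <- if (j < length(edges)) edges[j + 1L] else Inf
    q <- integrate(f, edges[j], upper,
                   rel.tol = 1e-8, abs.tol = min(abs.tol, 1e-12),
                   subdivisions = 500L, stop.on.error = FALSE)
    if (!(q$message %in% "OK"))
      stop("quadrature did not converge on (", format(edges[j]), ", ",
           format(upper), "): ", q$message)
    total <- total + q$value; err <- err + q$abs.error
  }
  if (err > 1e-8)
    stop("quadrature error estimate ", format(err), " exceeds 1e-8")
  total
}

#' Monte-Carlo oracle for the variance-ratio CDF
#'
#' Brute-force estimate of \eqn{P(R \le x)} by simulating the defining
#' chi-square variables directly; used to validate the quadrature in
#' [ratio_cdf()].  The Monte-Carlo standard error of the estimate is
#' \eqn{\sqrt{p(1-p)/n}}.
#'
#' @param df0,dfs degrees of freedom as in [ratio_dist()].
#' @param x positive scalar evaluation point.
#' @param n_draws number of independent draws.
#' @param seed integer seed; the draw is reproducible given the seed.
#'
#' @return estimated probability (a single number in \[0, 1\]).
#' @examples
#' ratio_cdf_mc(4, c(4, 4, 4), x = 1.7, n_draws = 1e5, seed = 1)
#' @export
ratio_cdf_mc <- function(df0, dfs, x, n_draws, seed) {
  dist <- ratio_dist(df0, dfs)  # reuse validation
  if (length(x) != 1L || is.na(x) || x <= 0)
    stop("`x` must be a single positive number")
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) stop("`n_draws` must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  num <- rchisq(n_draws, dist$df0) / dist$df0
  den <- rchisq(n_draws, dist$dfs[1L]) / dist$dfs[1L]
  for (d in dist$dfs[-1L])
    den <- pmin(den, rchisq(n_draws, d) / d)
  mean(num / den <= x)
}

#' Quantile function of the control-to-minimum variance ratio
#'
#' Inverts [ratio_cdf()] by bracketed root search.  The initial bracket is
#' built from ordinary F quantiles (which bound the ratio distribution for a
#' single treatment) and expanded geometrically until it straddles `p`;
#' bisection then refines to 1e-10 in \eqn{x} or 1e-8 in probability.
#'
#' @param dist a [ratio_dist()] object.
#' @param p probability (or vector of probabilities) strictly inside (0, 1).
#'
#' @return numeric vector `x` with `ratio_cdf(dist, x)` equal to `p` within
#'   1e-8.
#' @examples
#' ratio_quantile(ratio_dist(9, 9), 0.5)  # F(9, 9) median = 1
#' @export
ratio_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "ratio_dist"))
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly inside (0, 1)")
  vapply(p, function(pi) {
    lo <- qf(pi, dist$df0, max(dist$dfs)) / (dist$k + 1)
    hi <- qf(pi, dist$df0, min(dist$dfs)) * (dist$k + 1)
    while (ratio_cdf(dist, lo) > pi && lo > 1e-300) lo <- lo / 8
    while (ratio_cdf(dist, hi) < pi && hi < 1e300) hi <- hi * 8
    uniroot(function(x) ratio_cdf(dist, x) - pi,
            lower = lo, upper = hi, tol = 1e-10)$root
  }, numeric(1))
}

# Gauss-Laguerre cross-check path for the same integral, kept independent of
# the adaptive route.  Nodes/weights by Golub-Welsch on the Laguerre Jacobi
# matrix; the chi-square weight exp(-v/2) v^{d0/2-1} is folded in via the
# substitution v = 2t.
.gauss_laguerre <- function(n) {
  i <- seq_len(n)
  a <- 2 * i - 1            # diagonal
  b <- i[-n]                # off-diagonal
  J <- diag(a)
  J[cbind(i[-n], i[-n] + 1L)] <- b
  J[cbind(i[-n] + 1L, i[-n])] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1L, ]^2)
}

.ratio_cdf_laguerre <- function(dist, x, n_nodes = 128L) {
  gl <- .gauss_laguerre(n_nodes)
  t <- gl$nodes                      # v = 2t, v ~ chi^2(d0) density
  lw <- log(gl$weights) + (dist$df0 / 2 - 1) * log(2 * t) -
    lgamma(dist$df0 / 2) - (dist$df0 / 2) * log(2) + log(2)
  vapply(x, function(xi) {
    ls <- 0
    for (d in dist$dfs)
      ls <- ls + pchisq(d * 2 * t / (dist$df0 * xi), d,
                        lower.tail = FALSE, log.p = TRUE)
    sum(exp(lw + ls))
  }, numeric(1))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
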