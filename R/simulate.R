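#' Simulation scenario for the variance-comparison tests
#'
#' Describes one Monte-Carlo scenario: group sizes and variances (control
#' first), optional group means (irrelevant to the scale tests, default 0,
#' configurable to verify location invariance), the number of replicate
#' studies, the significance level, the master seed, and which tests to run.
#'
#' @param sizes integer vector of k+1 group sizes, control first; each >= 2.
#' @param variances positive vector of k+1 population variances, control
#'   first.
#' @param means group means, recycled to length k+1 (default all 0).
#' @param reps number of replicate studies (default 10000).
#' @param alpha significance level.
#' @param seed master integer seed; per-rep child seeds are derived from it
#'   (see [generate_study()]) so results are bit-reproducible.
#' @param methods subset of `c("MIM", "Spurrier")`; Spurrier may only be
#'   requested when all treatment sizes are equal.
#' @return an object of class `"simulation_spec"`.
#' @examples
#' simulation_spec(sizes = c(5, 5, 5, 5), variances = c(2, 2, 2, 2),
#'                 reps = 100, seed = 1)
#' @export
simulation_spec <- function(sizes, variances, means = 0, reps = 10000L,
                            alpha = 0.05, seed = 1L,
                            methods = c("MIM", "Spurrier")) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 2L || anyNA(sizes) || any(sizes < 2L))
    stop("`sizes` must give k + 1 integers >= 2, control first")
  if (length(variances) != length(sizes) || anyNA(variances) ||
      any(variances <= 0))
    stop("`variances` must be ", length(sizes), " positive values")
  means <- rep_len(as.numeric(means), length(sizes))
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("`reps` must be >= 1")
  .check_alpha(alpha)
  methods_given <- !missing(methods)
  methods <- match.arg(methods, c("MIM", "Spurrier"), several.ok = TRUE)
  trt_sizes <- sizes[-1L]
  if ("Spurrier" %in% methods && length(unique(trt_sizes)) != 1L) {
    if (methods_given)
      stop("Spurrier's test requires equal treatment sample sizes; ",
           "drop it from `methods` or equalize `sizes`")
    methods <- "MIM"  # default silently narrows to the applicable test
  }
  structure(list(sizes = sizes, variances = as.numeric(variances),
                 means = means, reps = reps, alpha = alpha,
                 seed = as.integer(seed), methods = methods,
                 k = length(sizes) - 1L),
            class = "simulation_spec")
}

# One child seed per replicate, drawn in a single batch under the master
# seed, so rep i gets the same seed regardless of evaluation order.
.child_seeds <- function(seed, reps) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, reps)
}

#' Generate one replicate study
#'
#' Draws independent normal samples per group with the scenario's means,
#' variances and sizes, and summarizes them.  Replicate `rep_index` is
#' seeded with the `rep_index`-th child seed derived from the master seed,
#' so the same `(seed, rep_index)` pair always yields the same samples.
#'
#' @param spec a [simulation_spec()].
#' @param rep_index replicate number in `1:spec$reps`.
#' @return a [study_summary()]; the raw samples are attached as attribute
#'   `"samples"` (a list of numeric vectors, control first).
#' @export
generate_study <- function(spec, rep_index = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  rep_index <- as.integer(rep_index)
  if (is.na(rep_index) || rep_index < 1L || rep_index > spec$reps)
    stop("`rep_index` must lie in 1..reps")
  child <- .child_seeds(spec$seed, spec$reps)[rep_index]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(child)
  samples <- lapply(seq_along(spec$sizes), function(i)
    rnorm(spec$sizes[i], spec$means[i], sqrt(spec$variances[i])))
  labels <- c("control", paste0("treatment", seq_len(spec$k)))
  gs <- lapply(seq_along(samples), function(i)
    group_summary(labels[i], spec$sizes[i], var(samples[[i]])))
  out <- study_summary(gs[[1L]], gs[-1L])
  attr(out, "samples") <- setNames(samples, labels)
  out
}

# Vectorized engine shared by run_study() and pl_null_distribution():
# simulates the per-rep statistic T = S0^2 / min Si^2 for all reps.
.simulate_statistics <- function(spec) {
  seeds <- .child_seeds(spec$seed, spec$reps)
  old <- .save_rng(); on.exit(.restore_rng(old))
  vapply(seq_len(spec$reps), function(r) {
    set.seed(seeds[r])
    s2 <- vapply(seq_along(spec$sizes), function(i)
      var(rnorm(spec$sizes[i], spec$means[i], sqrt(spec$variances[i]))),
      numeric(1))
    s2[1L] / min(s2[-1L])
  }, numeric(1))
}

#' Run a Monte-Carlo type-I-error / power study
#'
#' For each replicate, generates a study under the scenario and applies each
#' requested test at level `alpha`; returns the rejection rate per method
#' with its binomial Monte-Carlo standard error
#' \eqn{\sqrt{r(1-r)/\mathrm{reps}}}.  When the scenario's variances are all
#' equal the rate estimates the type I error; otherwise it estimates power.
#'
#' Because the null reference distribution is fixed within a scenario, each
#' test reduces to comparing the replicate statistic
#' \eqn{T = S_0^2/\min_i S_i^2} with a critical value computed once:
#' \eqn{F^{-1}(1-\alpha)} for the MIM test, and the inverted Spurrier
#' p-value for Spurrier's test.  The two critical values are computed by
#' their own routes, so rep-by-rep agreement of the two tests remains a
#' meaningful check.
#'
#' @param spec a [simulation_spec()].
#' @return a `"simulation_result"`: list with `rejection_rate` and
#'   `mc_stderr` (named per method), `reps_used`, and the `spec`.
#' @examples
#' run_study(simulation_spec(c(5, 5, 5, 5), c(2, 2, 2, 2),
#'                           reps = 200, seed = 42))
#' @export
run_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  stat <- .simulate_statistics(spec)
  dist <- ratio_dist(spec$sizes[1L] - 1L, spec$sizes[-1L] - 1L)
  rate <- numeric(0)
  if ("MIM" %in% spec$methods) {
    crit <- ratio_quantile(dist, 1 - spec$alpha)
    rate["MIM"] <- mean(stat >= crit)
  }
  if ("Spurrier" %in% spec$methods) {
    n <- spec$sizes[1L]; m <- spec$sizes[2L]; k <- spec$k
    # Spurrier rejects when p(c) <= alpha with c = 1/T; invert p in c.
    c_crit <- uniroot(function(c) spurrier_pvalue(n, m, k, c) - spec$alpha,
                      lower = 1e-8, upper = 1e8, tol = 1e-12)$root
    rate["Spurrier"] <- mean(1 / stat <= c_crit)
  }
  structure(list(rejection_rate = rate,
                 mc_stderr = sqrt(rate * (1 - rate) / spec$reps),
                 reps_used = spec$reps, spec = spec),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  null_case <- length(unique(x$spec$variances)) == 1L
  cat("Monte-Carlo ", if (null_case) "type-I-error" else "power",
      " study: ", x$reps_used, " reps, alpha = ", format(x$spec$alpha),
      "\n  sizes     (control first): ",
      paste(x$spec$sizes, collapse = ", "),
      "\n  variances (control first): ",
      paste(format(x$spec$variances), collapse = ", "), "\n", sep = "")
  for (m in names(x$rejection_rate))
    cat(sprintf("  %-9s rejection rate %.4f (MC s.e. %.4f)\n",
                m, x$rejection_rate[m], x$mc_stderr[m]))
  invisible(x)
}

#' Null distribution of the plausibility: the validity diagnostic
#'
#' Under the null configuration (all variances equal) the MIM plausibility
#' at \eqn{\theta = 1} is exactly Unif(0, 1).  This diagnostic simulates the
#' plausibility over `reps` replicate studies and compares its empirical CDF
#' with the uniform via a one-sample Kolmogorov-Smirnov test.  An empirical
#' curve hugging the diagonal is what exact type-I-error control looks like.
#'
#' @param spec a [simulation_spec()] whose variances are all equal.
#' @return a `"pl_null"`: list with `pl` (the replicate plausibilities),
#'   `ks` (the [stats::ks.test()] result, `NULL` when `reps == 1`), and the
#'   `spec`.  Has a `plot()` method drawing the ECDF against the diagonal.
#' @examples
#' d <- pl_null_distribution(
#'   simulation_spec(c(5, 5, 5, 5), c(1, 1, 1, 1), reps = 200, seed = 7))
#' d$ks$p.value
#' @export
pl_null_distribution <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (length(unique(spec$variances)) != 1L)
    stop("the uniformity diagnostic requires a null configuration ",
         "(all variances equal)")
  stat <- .simulate_statistics(spec)
  dist <- ratio_dist(spec$sizes[1L] - 1L, spec$sizes[-1L] - 1L)
  pl <- 1 - .ratio_cdf_many(dist, stat)
  ks <- if (spec$reps > 1L) ks.test(pl, punif) else NULL
  structure(list(pl = pl, ks = ks, spec = spec), class = "pl_null")
}

# Batch CDF evaluation for many x at one df vector: fixed graded-panel
# Gauss-Legendre rule on the u = pchisq(v, df0) scale, vectorized across x,
# with panels graded toward both endpoints.  The fixed rule is accurate in
# the body of the distribution but cannot chase the boundary layer of
# extreme-tail x values, so those (batch estimate outside [1e-3, 1 - 1e-3])
# are recomputed through the adaptive ratio_cdf() route.  Agreement with
# ratio_cdf() is asserted in the tests.
.ratio_cdf_many <- function(dist, x, nodes_per_panel = 48L) {
  stopifnot(all(x > 0))
  breaks <- c(0, 1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.5,
              0.9, 0.99, 0.999, 0.9999, 0.99999, 1)
  gl <- .gauss_legendre(nodes_per_panel)
  u <- w <- numeric(0)
  for (j in seq_len(length(breaks) - 1L)) {
    a <- breaks[j]; b <- breaks[j + 1L]
    u <- c(u, (a + b) / 2 + (b - a) / 2 * gl$nodes)
    w <- c(w, (b - a) / 2 * gl$weights)
  }
  v <- qchisq(u, dist$df0)
  ls <- matrix(0, length(u), length(x))
  for (d in dist$dfs)
    ls <- ls + pchisq(outer(d * v / dist$df0, x, "/"), d,
                      lower.tail = FALSE, log.p = TRUE)
  out <- pmin(pmax(as.numeric(w %*% exp(ls)), 0), 1)
  tail_x <- out < 1e-3 | out > 1 - 1e-3
  if (any(tail_x)) out[tail_x] <- ratio_cdf(dist, x[tail_x])
  out
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
}

#' @rdname pl_null_distribution
#' @param x a `"pl_null"` object.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.pl_null <- function(x, ...) {
  plot(ecdf(x$pl), verticals = TRUE, do.points = FALSE,
               xlab = "plausibility", ylab = "empirical CDF",
               main = "pl(B) under H0 vs Unif(0,1)", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}
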