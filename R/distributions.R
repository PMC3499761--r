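# The four parameter distributions the growth algorithm accepts (gamma,
# normal, uniform, constant), with optional truncation, plus fitting,
# seeded sampling and the two-sample KS comparison used for validation.

#' Create a distribution specification
#'
#' @param kind One of `"gamma"`, `"normal"`, `"uniform"`, `"constant"`.
#' @param shape,scale Gamma parameters (`shape`, `scale` > 0).
#' @param mean,sd Normal parameters (`sd` > 0).
#' @param low,high Uniform bounds (`low < high`).
#' @param value Constant value.
#' @param truncation Optional length-2 numeric `c(low, high)`; samples are
#'   restricted to this interval by rejection. Use `-Inf`/`Inf` for one-sided
#'   truncation.
#' @return A `dist_spec` object.
#' @examples
#' dist_spec("gamma", shape = 25, scale = 0.1)
#' dist_spec("normal", mean = 40, sd = 8, truncation = c(0, 180))
#' @export
dist_spec <- function(kind = c("gamma", "normal", "uniform", "constant"),
                      shape = NULL, scale = NULL, mean = NULL, sd = NULL,
                      low = NULL, high = NULL, value = NULL,
                      truncation = NULL) {
  kind <- match.arg(kind)
  params <- switch(kind,
    gamma = {
      stopifnot(is.numeric(shape), shape > 0, is.numeric(scale), scale > 0)
      list(shape = shape, scale = scale)
    },
    normal = {
      stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
      list(mean = mean, sd = sd)
    },
    uniform = {
      stopifnot(is.numeric(low), is.numeric(high), low < high)
      list(low = low, high = high)
    },
    constant = {
      stopifnot(is.numeric(value))
      list(value = value)
    }
  )
  if (!is.null(truncation)) {
    stopifnot(length(truncation) == 2L, truncation[1L] < truncation[2L])
  }
  structure(
    list(kind = kind, params = params, truncation = truncation),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(names(x$params), signif(unlist(x$params), 5), sep = " = ", collapse = ", ")
  tr <- if (is.null(x$truncation)) {
    ""
  } else {
    sprintf(" truncated to [%s, %s]", x$truncation[1L], x$truncation[2L])
  }
  cat(sprintf("<dist_spec %s(%s)%s>\n", x$kind, p, tr))
  invisible(x)
}

#' Fit a distribution of a given kind to a sample
#'
#' Normal by sample moments; gamma by the method of moments
#' (shape = mean^2/var, scale = var/mean); uniform by the sample range;
#' constant by the mean. At least two values are required for the
#' non-constant kinds.
#'
#' @param x Numeric sample (`NA`s dropped).
#' @param kind Distribution kind, as in [dist_spec()].
#' @param truncation Optional truncation bounds stored on the result.
#' @return A [dist_spec()].
#' @examples
#' fit_dist(c(8, 10, 12, 10), "gamma")
#' @export
fit_dist <- function(x, kind = c("gamma", "normal", "uniform", "constant"),
                     truncation = NULL) {
  kind <- match.arg(kind)
  x <- x[!is.na(x)]
  if (kind == "constant") {
    if (!length(x)) abort("empty sample")
    return(dist_spec("constant", value = mean(x), truncation = truncation))
  }
  if (length(x) < 2L) abort("need at least 2 values to fit a non-constant kind")
  m <- mean(x)
  v <- var(x)
  if (kind %in% c("gamma", "normal") && v == 0) {
    abort(sprintf(
      "sample has zero variance; use kind = \"constant\" instead of \"%s\"", kind
    ))
  }
  switch(kind,
    gamma = {
      if (m <= 0) abort("gamma requires a positive sample mean")
      dist_spec("gamma", shape = m^2 / v, scale = v / m, truncation = truncation)
    },
    normal = dist_spec("normal", mean = m, sd = sqrt(v), truncation = truncation),
    uniform = dist_spec("uniform", low = min(x), high = max(x), truncation = truncation)
  )
}

# analytic probability mass inside the truncation interval
truncation_mass <- function(spec) {
  if (is.null(spec$truncation)) {
    return(1)
  }
  lo <- spec$truncation[1L]
  hi <- spec$truncation[2L]
  p <- spec$params
  switch(spec$kind,
    gamma = pgamma(hi, p$shape, scale = p$scale) - pgamma(lo, p$shape, scale = p$scale),
    normal = pnorm(hi, p$mean, p$sd) - pnorm(lo, p$mean, p$sd),
    uniform = punif(hi, p$low, p$high) - punif(lo, p$low, p$high),
    constant = as.numeric(p$value >= lo & p$value <= hi)
  )
}

draw_raw <- function(spec, n) {
  p <- spec$params
  switch(spec$kind,
    gamma = rgamma(n, p$shape, scale = p$scale),
    normal = rnorm(n, p$mean, p$sd),
    uniform = runif(n, p$low, p$high),
    constant = rep(p$value, n)
  )
}

#' Sample from a distribution specification
#'
#' Truncation is honoured by rejection sampling. Identical
#' `(spec, n, seed)` always return the identical sample; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [dist_spec()].
#' @param n Number of values.
#' @param seed Integer seed; when `NULL` the current RNG stream is used
#'   (for callers that manage their own seeded stream).
#' @return A numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  if (truncation_mass(spec) < 1e-6) {
    abort("truncation interval has negligible probability mass (< 1e-6)")
  }
  draw <- function() {
    if (is.null(spec$truncation)) {
      return(draw_raw(spec, n))
    }
    out <- double(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- draw_raw(spec, max(n, 100L))
      out <- c(out, cand[cand >= spec$truncation[1L] & cand <= spec$truncation[2L]])
      tries <- tries + 1L
      if (tries > 10000L) abort("rejection sampling failed to converge")
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Density (or probability mass) of a distribution specification
#'
#' Truncated specifications are renormalised to the truncation interval.
#'
#' @param spec A [dist_spec()] or a `pois_spec` (see
#'   [target_distributions()]).
#' @param x Points at which to evaluate.
#' @return Numeric vector of densities.
#' @export
ddist <- function(spec, x) {
  UseMethod("ddist")
}

#' @export
ddist.dist_spec <- function(spec, x) {
  p <- spec$params
  d <- switch(spec$kind,
    gamma = dgamma(x, p$shape, scale = p$scale),
    normal = dnorm(x, p$mean, p$sd),
    uniform = dunif(x, p$low, p$high),
    constant = as.numeric(x == p$value)
  )
  if (!is.null(spec$truncation)) {
    inside <- x >= spec$truncation[1L] & x <= spec$truncation[2L]
    d <- ifelse(inside, d / truncation_mass(spec), 0)
  }
  d
}

#' Two-sample Kolmogorov–Smirnov comparison
#'
#' D is the supremum gap between the two empirical CDFs; the p-value comes
#' from the asymptotic two-sample KS distribution with effective sample size
#' n_a n_b / (n_a + n_b), the regime relevant for comparing a small
#' reconstruction sample against thousands of generated cells.
#'
#' @param a,b Non-empty numeric samples.
#' @return A one-row tibble with `statistic` (D) and `p_value`.
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50))
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = unname(res$p.value)
  )
}

#' Tidy and summarise distribution specifications
#'
#' `tidy()` returns one row per parameter; `glance()` returns a one-row
#' summary with the analytic mean and SD of the (untruncated) distribution.
#'
#' @param x A `dist_spec`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dist_spec
#' @export
tidy.dist_spec <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    term = names(x$params),
    estimate = unlist(x$params, use.names = FALSE)
  )
}

#' @rdname tidy.dist_spec
#' @method glance dist_spec
#' @export
glance.dist_spec <- function(x, ...) {
  p <- x$params
  mo <- switch(x$kind,
    gamma = c(p$shape * p$scale, sqrt(p$shape) * p$scale),
    normal = c(p$mean, p$sd),
    uniform = c((p$low + p$high) / 2, (p$high - p$low) / sqrt(12)),
    constant = c(p$value, 0)
  )
  tibble::tibble(kind = x$kind, mean = mo[1L], sd = mo[2L])
}
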