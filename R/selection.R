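# Population selection: filter generated cells by emergent-parameter
# windows around the reference statistics, then resample the survivors so
# the key marginals match target distributions.

EMERGENT_PARAMETERS <- c(
  "total_dendritic_length", "n_bifurcations", "surface_area",
  "avg_path_to_tips", "avg_euclidean_to_tips", "max_euclidean_to_tips",
  "max_branch_order", "partition_asymmetry", "transverse_spread",
  "longitudinal_spread"
)

#' Build filter criteria from a reference emergent table
#'
#' Each emergent parameter gets an acceptance window
#' `mean +/- width * sd`, with mean and SD computed from the reference
#' reconstruction set (not from the generated pool). The default width is 2
#' standard deviations for every parameter except `surface_area`, which uses
#' 1.65 — the 2 SD surface-area window would admit areas inconsistent with
#' the allowed total length. Under normality the 2 SD window retains over
#' 95% of the biological population and the 1.65 SD window over 90%.
#'
#' @param reference_emergent Emergent table of the reference set, from
#'   [extract_emergent()].
#' @param widths Named numeric vector of SD multipliers overriding the
#'   defaults.
#' @return A `filter_criteria` tibble: `parameter`, `reference_mean`,
#'   `reference_sd`, `width`.
#' @export
filter_criteria <- function(reference_emergent, widths = NULL) {
  missing <- setdiff(EMERGENT_PARAMETERS, names(reference_emergent))
  if (length(missing)) {
    abort(paste0(
      "reference emergent table lacks: ", paste(missing, collapse = ", ")
    ))
  }
  w <- setNames(rep(2.0, length(EMERGENT_PARAMETERS)), EMERGENT_PARAMETERS)
  w["surface_area"] <- 1.65
  if (!is.null(widths)) {
    stopifnot(all(names(widths) %in% EMERGENT_PARAMETERS), all(widths > 0))
    w[names(widths)] <- widths
  }
  out <- tibble::tibble(
    parameter = EMERGENT_PARAMETERS,
    reference_mean = vapply(
      EMERGENT_PARAMETERS,
      function(p) mean(reference_emergent[[p]], na.rm = TRUE), double(1)
    ),
    reference_sd = vapply(
      EMERGENT_PARAMETERS,
      function(p) sd(reference_emergent[[p]], na.rm = TRUE), double(1)
    ),
    width = unname(w)
  )
  if (any(!is.finite(out$reference_sd) | out$reference_sd <= 0)) {
    abort("reference SD must be positive for every emergent parameter")
  }
  class(out) <- c("filter_criteria", class(out))
  out
}

#' Filter a population by emergent-parameter windows
#'
#' A cell is accepted iff `|value - reference_mean| <= width * reference_sd`
#' for every parameter covered by the criteria, with the boundary inclusive
#' (a cell sitting exactly at the window edge is kept). The decision is
#' per-cell and order-independent.
#'
#' @param emergent Emergent table ([extract_emergent()]), one row per cell.
#' @param criteria A [filter_criteria()] table; it may cover a subset of
#'   parameters only if built with `widths` explicitly, but must cover every
#'   parameter it names with a positive SD.
#' @return `emergent` with two extra columns: `accepted` (logical) and
#'   `failed_parameters` (character, comma-separated rejection reasons,
#'   `""` for accepted cells).
#' @export
filter_emergent <- function(emergent, criteria) {
  missing <- setdiff(criteria$parameter, names(emergent))
  if (length(missing)) {
    abort(paste0("emergent table lacks: ", paste(missing, collapse = ", ")))
  }
  fails <- vector("list", nrow(criteria))
  ok <- rep(TRUE, nrow(emergent))
  for (i in seq_len(nrow(criteria))) {
    p <- criteria$parameter[i]
    dev <- abs(emergent[[p]] - criteria$reference_mean[i])
    pass <- dev <= criteria$width[i] * criteria$reference_sd[i]
    pass[is.na(pass)] <- FALSE
    ok <- ok & pass
    fails[[i]] <- !pass
  }
  fail_mat <- do.call(cbind, fails)
  reasons <- unname(apply(fail_mat, 1L, function(row) {
    paste(criteria$parameter[row], collapse = ",")
  }))
  out <- emergent
  out$accepted <- ok
  out$failed_parameters <- reasons
  out
}

#' Target distributions for population matching
#'
#' The selected population is matched, marginally, to a truncated Gaussian
#' for `total_dendritic_length` and `surface_area` and a Poisson for
#' `n_bifurcations` — the canonical shapes for those three parameters. By
#' default the means/SDs come from the reference emergent statistics and the
#' Gaussian truncation bounds coincide with the filter windows.
#'
#' @param criteria A [filter_criteria()] table (source of means, SDs and
#'   truncation windows).
#' @param total_dendritic_length,surface_area Optional [dist_spec()]
#'   overrides (truncated normals).
#' @param n_bifurcations Optional Poisson rate override.
#' @return A `target_distributions` list with elements
#'   `total_dendritic_length`, `surface_area` (both `dist_spec`) and
#'   `n_bifurcations` (a `pois_spec` with a rate and truncation bounds).
#' @export
target_distributions <- function(criteria, total_dendritic_length = NULL,
                                 surface_area = NULL, n_bifurcations = NULL) {
  row <- function(p) criteria[criteria$parameter == p, ]
  trunc_normal <- function(p) {
    r <- row(p)
    dist_spec("normal",
      mean = r$reference_mean, sd = r$reference_sd,
      truncation = r$reference_mean + c(-1, 1) * r$width * r$reference_sd
    )
  }
  nb <- row("n_bifurcations")
  pois <- structure(
    list(
      rate = nb$reference_mean,
      truncation = nb$reference_mean + c(-1, 1) * nb$width * nb$reference_sd
    ),
    class = "pois_spec"
  )
  if (!is.null(n_bifurcations)) pois$rate <- n_bifurcations
  structure(
    list(
      total_dendritic_length = total_dendritic_length %||%
        trunc_normal("total_dendritic_length"),
      surface_area = surface_area %||% trunc_normal("surface_area"),
      n_bifurcations = pois
    ),
    class = "target_distributions"
  )
}

#' @export
ddist.pois_spec <- function(spec, x) {
  d <- dpois(round(x), spec$rate)
  if (!is.null(spec$truncation)) {
    lo <- ceiling(spec$truncation[1L])
    hi <- floor(spec$truncation[2L])
    mass <- ppois(hi, spec$rate) - ppois(lo - 1, spec$rate)
    inside <- x >= spec$truncation[1L] & x <= spec$truncation[2L]
    d <- ifelse(inside, d / mass, 0)
  }
  d
}

#' Sample from a target distribution
#'
#' Draws from a matching target — a (possibly truncated) [dist_spec()] or
#' the truncated-Poisson `pois_spec` of [target_distributions()] — e.g. to
#' build the comparison sample for a KS check of a matched population.
#'
#' @param spec A `dist_spec` or `pois_spec`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_target <- function(spec, n, seed = NULL) {
  if (inherits(spec, "pois_spec")) {
    draw <- function() {
      out <- double(0)
      while (length(out) < n) {
        cand <- rpois(max(n, 100L), spec$rate)
        if (!is.null(spec$truncation)) {
          cand <- cand[cand >= spec$truncation[1L] & cand <= spec$truncation[2L]]
        }
        out <- c(out, cand)
      }
      out[seq_len(n)]
    }
    if (is.null(seed)) draw() else with_seed(seed, draw())
  } else {
    sample_dist(spec, n, seed)
  }
}

# Freedman-Diaconis histogram density estimate evaluated at the sample's own
# points (pool marginal density for importance weights)
fd_density <- function(x) {
  iqr <- stats::IQR(x)
  bw <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else diff(range(x)) / 30
  if (bw <= 0) bw <- 1
  breaks <- seq(min(x) - bw / 2, max(x) + bw, by = bw)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
    nbins = length(breaks) - 1L
  )
  dens <- counts / (length(x) * bw)
  dens[findInterval(x, breaks, rightmost.closed = TRUE)]
}

# empirical pmf at the sample's own points (discrete pool marginal)
emp_pmf <- function(x) {
  tab <- table(x)
  as.vector(tab[as.character(x)]) / length(x)
}

#' Select a sub-population matching target distributions
#'
#' Weighted resampling without replacement: each pool cell gets weight
#' `prod_k target_k(value_k) / pool_k(value_k)` over the three matched
#' parameters (independence assumed — parameter covariance is not
#' modelled), where the pool marginal is a Freedman–Diaconis histogram
#' estimate for the continuous parameters and the empirical pmf for
#' `n_bifurcations`. With a sufficiently large, well-supported pool the
#' selected marginals are KS-indistinguishable from their targets.
#'
#' @param pool Emergent table of the accepted cells (rows are candidate
#'   cells; must contain the three matched parameters).
#' @param targets A [target_distributions()] object.
#' @param n_out Number of cells to select (`<=` pool size).
#' @param seed Integer seed; identical inputs give the identical selection.
#' @return The selected rows of `pool` (a tibble, `n_out` rows).
#' @export
match_target_distributions <- function(pool, targets, n_out, seed) {
  stopifnot(inherits(targets, "target_distributions"))
  if (n_out > nrow(pool)) {
    abort(sprintf(
      "n_out (%d) exceeds pool size (%d)", as.integer(n_out), nrow(pool)
    ))
  }
  pars <- names(targets)
  missing <- setdiff(pars, names(pool))
  if (length(missing)) {
    abort(paste0("pool lacks: ", paste(missing, collapse = ", ")))
  }

  w <- rep(1, nrow(pool))
  for (p in pars) {
    x <- pool[[p]]
    target_d <- ddist(targets[[p]], x)
    pool_d <- if (inherits(targets[[p]], "pois_spec")) emp_pmf(x) else fd_density(x)
    pool_d[pool_d <= 0] <- min(pool_d[pool_d > 0])
    w <- w * target_d / pool_d
  }

  # the pool must support every decile band of each target
  for (p in pars) {
    spec <- targets[[p]]
    qs <- target_quantiles(spec, seq(0.05, 0.95, by = 0.1))
    bands <- cbind(head(qs, -1L), tail(qs, -1L))
    for (b in seq_len(nrow(bands))) {
      if (!any(pool[[p]] >= bands[b, 1L] & pool[[p]] <= bands[b, 2L])) {
        abort(sprintf(
          "pool has no support for %s in target band [%.4g, %.4g]",
          p, bands[b, 1L], bands[b, 2L]
        ))
      }
    }
  }

  if (all(w <= 0)) abort("all selection weights are zero")
  pi <- n_out * w / sum(w)
  if (n_out < nrow(pool) && sum(pmax(pi - 1, 0)) > 0.01 * n_out) {
    warn(paste0(
      "pool cannot fully supply the target marginals at this n_out ",
      sprintf(
        "(%.1f%% of the requested mass needs inclusion probabilities > 1); ",
        100 * sum(pmax(pi - 1, 0)) / n_out
      ),
      "the selection will be flatter than the targets near their modes - ",
      "use a larger pool or a smaller n_out"
    ))
  }
  idx <- with_seed(seed, systematic_sample(w, n_out))
  pool[idx, , drop = FALSE]
}

# Fixed-size weighted sampling without replacement by systematic (Madow)
# sampling: cell i is included with probability pi_i = n * w_i / sum(w)
# (capped at 1 with iterative redistribution), so the expected number of
# selected cells in any value band is exactly target-proportional — the
# property the marginal-matching contract needs. Successive sampling
# (sample(..., prob = w, replace = FALSE)) does not have it at non-trivial
# sampling fractions.
systematic_sample <- function(w, n_out) {
  n <- length(w)
  stopifnot(n_out <= n)
  pi <- n_out * w / sum(w)
  for (it in 1:100) {
    over <- pi >= 1
    if (!any(pi > 1)) break
    room <- n_out - sum(over)
    pi[!over] <- pi[!over] * room / sum(pi[!over])
    pi[over] <- 1
  }
  pi <- pmin(pi, 1)
  cum <- cumsum(pi)
  u <- runif(1L)
  idx <- findInterval(u + seq_len(n_out) - 1L, c(0, cum), rightmost.closed = TRUE)
  unique(idx[idx >= 1L & idx <= n])
}

# quantiles of a target spec (truncation-aware)
target_quantiles <- function(spec, probs) {
  if (inherits(spec, "pois_spec")) {
    lo <- if (is.null(spec$truncation)) 0 else ceiling(spec$truncation[1L])
    hi <- if (is.null(spec$truncation)) Inf else floor(spec$truncation[2L])
    plo <- ppois(lo - 1, spec$rate)
    phi <- ppois(hi, spec$rate)
    stats::qpois(plo + probs * (phi - plo), spec$rate)
  } else {
    p <- spec$params
    tr <- spec$truncation %||% c(-Inf, Inf)
    plo <- pnorm(tr[1L], p$mean, p$sd)
    phi <- pnorm(tr[2L], p$mean, p$sd)
    qnorm(plo + probs * (phi - plo), p$mean, p$sd)
  }
}
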