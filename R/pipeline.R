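# End-to-end pipeline helpers: refit growth inputs from an extracted basic
# parameter table, and the generate-vs-reference KS self-consistency check
# used to validate the whole morphology pipeline.

#' Basic parameters whose drawn values are directly measurable
#'
#' The growth algorithm realises these parameters exactly as drawn, so their
#' extracted distributions over a large generated population should match
#' the generator input up to sampling noise. `n_stems` (integer-valued, so a
#' KS comparison is dominated by ties) and `terminal_diameter` (emergent:
#' tip diameter is the threshold-censored product of taper and length) are
#' deliberately not on this list.
#'
#' @return Character vector of parameter names.
#' @export
directly_drawn_parameters <- function() {
  c(
    "soma_diameter", "stem_initial_diameter", "taper_rate",
    "internal_path_length", "terminal_path_length", "rall_power",
    "daughter_diameter_ratio", "bifurcation_amplitude"
  )
}

#' Fit growth parameters from an extracted basic-parameter table
#'
#' For each basic parameter, pools the per-entity values across cells and
#' fits the requested distribution kind with [fit_dist()]. The
#' `terminal_initial_diameter` sample (initial diameter of terminal
#' branches) seeds the `terminal_diameter_threshold` spec: the threshold
#' itself is not observable, but a branch is terminal exactly when its
#' initial diameter fell at or below the cell's threshold draw, so the
#' terminal initial diameters are the measurable face of the termination
#' rule. (Tip diameters would be doubly biased — threshold-censored and
#' then tapered.)
#'
#' @param basic A tidy table from [extract_basic()].
#' @param kinds Named character vector mapping each basic parameter to a
#'   distribution kind (default: the granule archetype's pairing).
#' @param stem_elevation_cone,segment_step,max_branch_order Scalar controls
#'   passed through to [growth_params()].
#' @return A [growth_params()] object.
#' @export
fit_growth_params <- function(basic, kinds = granule_archetype()$kinds,
                              stem_elevation_cone = 35, segment_step = 5,
                              max_branch_order = 12L) {
  need <- setNames(GROWTH_DIST_FIELDS, GROWTH_DIST_FIELDS)
  need[["terminal_diameter_threshold"]] <- "terminal_initial_diameter"
  specs <- lapply(seq_along(need), function(i) {
    field <- names(need)[i]
    par <- unname(need[i])
    vals <- basic$value[basic$parameter == par]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      abort(sprintf("basic parameter table has no values for '%s'", par))
    }
    if (is.na(kinds[par])) {
      abort(sprintf("no distribution kind given for '%s'", par))
    }
    if (field == "terminal_diameter_threshold") {
      internal_d <- basic$value[basic$parameter == "internal_initial_diameter"]
      return(fit_termination_threshold(vals, internal_d[!is.na(internal_d)]))
    }
    fit_dist(vals, kinds[[par]])
  })
  names(specs) <- names(need)
  do.call(growth_params, c(specs, list(
    stem_elevation_cone = stem_elevation_cone,
    segment_step = segment_step,
    max_branch_order = max_branch_order
  )))
}

#' Fit the termination-threshold distribution from branch outcomes
#'
#' A branch is terminal exactly when its initial diameter d0 fell at or
#' below the cell's threshold draw, so terminal/internal status given d0 is
#' a Bernoulli outcome with success probability 1 - G(d0), where G is the
#' threshold CDF. The gamma threshold distribution is therefore fitted by
#' maximum likelihood on the observed branch outcomes — an unbiased
#' estimator, unlike a direct fit to terminal initial diameters, which are
#' censored from above and would bias the threshold low (and generated
#' trees correspondingly too deep). Falls back to a moment fit of the
#' terminal initial diameters if the likelihood optimisation fails.
#'
#' @param terminal_d0 Initial diameters of terminal branches.
#' @param internal_d0 Initial diameters of internal branches.
#' @return A gamma [dist_spec()].
#' @export
fit_termination_threshold <- function(terminal_d0, internal_d0) {
  start <- fit_dist(terminal_d0, "gamma")
  if (!length(internal_d0)) {
    return(start)
  }
  nll <- function(par) {
    shape <- exp(par[1L])
    scale <- exp(par[2L])
    p_term <- 1 - pgamma(terminal_d0, shape, scale = scale)
    p_int <- pgamma(internal_d0, shape, scale = scale)
    -(sum(log(pmax(p_term, 1e-12))) + sum(log(pmax(p_int, 1e-12))))
  }
  fit <- tryCatch(
    stats::optim(log(c(start$params$shape, start$params$scale)), nll,
      control = list(maxit = 1000)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$convergence != 0) {
    return(start)
  }
  dist_spec("gamma", shape = exp(fit$par[1L]), scale = exp(fit$par[2L]))
}

#' KS self-consistency of the generate-measure loop
#'
#' The full morphology pipeline run as a closed loop: grow a synthetic
#' reference set, extract its basic parameters, refit the generator input
#' distributions, generate a large virtual population, re-extract, and
#' compare generated against reference samples with the two-sample KS test,
#' per directly drawn parameter. Repeated over independent seeds; the median
#' p-value per parameter is the summary of interest (the real-vs-virtual
#' comparison reports p > 0.05 per parameter).
#'
#' @param archetype Reference archetype (default [granule_archetype()]).
#' @param n_ref Reference set size (default 19).
#' @param n_gen Generated population size per run (default 10000).
#' @param n_seeds Number of independent runs (default 20).
#' @param base_seed Root seed.
#' @param parameters Parameters to compare (default
#'   [directly_drawn_parameters()]).
#' @return A tibble with columns `run`, `parameter`, `statistic`, `p_value`.
#' @seealso [ks_self_consistency_summary()]
#' @export
ks_self_consistency <- function(archetype = granule_archetype(), n_ref = 19,
                                n_gen = 10000, n_seeds = 20, base_seed = 1,
                                parameters = directly_drawn_parameters()) {
  runs <- lapply(seq_len(n_seeds), function(r) {
    run_seed <- derive_seed(base_seed, paste0("run", r))
    refs <- make_reference_set(archetype, n = n_ref, seed = derive_seed(run_seed, "reference"))
    ref_basic <- extract_basic(refs)
    fitted <- fit_growth_params(ref_basic, archetype$kinds)
    pop <- generate_population(fitted, n_gen, derive_seed(run_seed, "population"))
    gen_basic <- extract_basic(pop)
    per_par <- lapply(parameters, function(par) {
      ks <- ks_two_sample(
        gen_basic$value[gen_basic$parameter == par],
        ref_basic$value[ref_basic$parameter == par]
      )
      quick_tibble(
        run = r, parameter = par,
        statistic = ks$statistic, p_value = ks$p_value
      )
    })
    dplyr::bind_rows(per_par)
  })
  dplyr::bind_rows(runs)
}

#' Summarise a KS self-consistency experiment
#'
#' @param runs Output of [ks_self_consistency()].
#' @return One row per parameter with the median and minimum p-value across
#'   runs and the fraction of runs with p > 0.05.
#' @export
ks_self_consistency_summary <- function(runs) {
  dplyr::summarise(runs,
    median_p = stats::median(.data$p_value),
    min_p = min(.data$p_value),
    frac_p_over_0.05 = mean(.data$p_value > 0.05),
    .by = "parameter"
  )
}
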