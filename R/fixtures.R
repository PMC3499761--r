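# Synthetic reference reconstructions: a granule-cell-like archetype with
# known ground-truth parameter distributions, standing in for an in-vivo
# reconstruction set so every pipeline stage can be exercised and checked
# for parameter recovery without external data.

#' Granule-cell-like reference archetype
#'
#' A named growth-parameter preset emulating in-vivo labelled dentate granule
#' cells: unipolar trees with 1-4 stems confined to a cone toward the
#' molecular layer, stem diameters around 2.6 um, tapering branches, total
#' dendritic lengths in the low thousands of micrometres. The ground-truth
#' distribution of every basic parameter is recorded alongside the
#' [growth_params()] so downstream recovery checks can compare fitted
#' against true parameters.
#'
#' @return A `reference_archetype`: a list with elements `name`, `params`
#'   (a [growth_params()]) and `kinds` (named character vector giving the
#'   distribution kind of each basic parameter, used when refitting).
#' @examples
#' arch <- granule_archetype()
#' arch$params
#' @export
granule_archetype <- function() {
  params <- growth_params(
    soma_diameter = dist_spec("normal", mean = 10.5, sd = 1.2),
    n_stems = dist_spec("uniform", low = 1, high = 4),
    stem_initial_diameter = dist_spec("gamma", shape = 27.04, scale = 0.09615),
    taper_rate = dist_spec("gamma", shape = 9, scale = 1.333e-4),
    internal_path_length = dist_spec(
      "gamma",
      shape = 4.592, scale = 16.33, truncation = c(5, Inf)
    ),
    terminal_path_length = dist_spec(
      "gamma",
      shape = 6.25, scale = 24, truncation = c(5, Inf)
    ),
    rall_power = dist_spec("normal", mean = 1.5, sd = 0.12),
    daughter_diameter_ratio = dist_spec("uniform", low = 1, high = 1.6),
    bifurcation_amplitude = dist_spec("normal", mean = 40, sd = 10),
    terminal_diameter_threshold = dist_spec("gamma", shape = 32.1, scale = 0.0265),
    stem_elevation_cone = 35,
    segment_step = 5,
    max_branch_order = 12L
  )
  structure(
    list(
      name = "granule-like",
      params = params,
      kinds = c(
        soma_diameter = "normal",
        n_stems = "uniform",
        stem_initial_diameter = "gamma",
        taper_rate = "gamma",
        internal_path_length = "gamma",
        terminal_path_length = "gamma",
        terminal_initial_diameter = "gamma",
        internal_initial_diameter = "gamma",
        rall_power = "normal",
        daughter_diameter_ratio = "uniform",
        bifurcation_amplitude = "normal",
        terminal_diameter = "gamma"
      )
    ),
    class = "reference_archetype"
  )
}

#' Generate a synthetic reference reconstruction set
#'
#' Grows `n` cells from the archetype, each from a seed derived from
#' `(seed, "ref<i>")`, so the set is reproducible. When `dir` is given, one
#' canonical SWC file per cell (`ref_001.swc`, ...) plus a
#' `ground_truth.yaml` with the archetype's true distribution parameters are
#' written there; these files are synthetic stand-ins, not real
#' reconstructions.
#'
#' @param archetype A [granule_archetype()]-style archetype.
#' @param n Number of reference cells (default 19; at least 2).
#' @param seed Integer seed.
#' @param dir Optional output directory for SWC files.
#' @return A population tibble (`cell`, `seed`, `morphology`) with the
#'   archetype attached as attribute `"archetype"`.
#' @export
make_reference_set <- function(archetype = granule_archetype(), n = 19,
                               seed = 1, dir = NULL) {
  stopifnot(inherits(archetype, "reference_archetype"), n >= 2)
  pop <- generate_population(archetype$params, n, derive_seed(seed, archetype$name))
  for (m in pop$morphology) validate_morphology(m)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      write_swc(pop$morphology[[i]], file.path(dir, sprintf("ref_%03d.swc", i)))
    }
    if (requireNamespace("yaml", quietly = TRUE)) {
      gt <- lapply(archetype$params[GROWTH_DIST_FIELDS], function(s) {
        c(list(kind = s$kind), s$params)
      })
      yaml::write_yaml(
        list(archetype = archetype$name, synthetic = TRUE, ground_truth = gt),
        file.path(dir, "ground_truth.yaml")
      )
    }
  }
  attr(pop, "archetype") <- archetype
  pop
}
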