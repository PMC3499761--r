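# Structural scaffold of the dentate gyrus network model: cell counts,
# deterministic septotemporal placement, hilar injury, lamellar stimulation
# sets, and the scale-dependent synaptic parameter rules. Membrane dynamics
# and connectivity instantiation are out of scope; connectivity tables are
# user-supplied.

FULL_SCALE_COUNTS <- c(
  granule = 1000000L, mossy = 30000L, basket = 10000L, hipp = 12000L
)

#' Configure a dentate scaffold
#'
#' Full-scale counts are 1,000,000 granule, 30,000 mossy, 10,000 basket and
#' 12,000 HIPP cells, evenly distributed along the septotemporal axis; the
#' reduced models divide these by the scale divisor (1:20 and 1:2000 are the
#' published reductions). The axis length is configurable (default 6 mm, the
#' approximate septotemporal extent of the rat dentate gyrus) and affects
#' only positions, not counts.
#'
#' @param scale `"full"`, `"1:20"`, `"1:2000"`, or a numeric divisor.
#' @param counts Named integer vector of full-scale counts (override for
#'   custom models).
#' @param axis_length_mm Septotemporal axis length in millimetres.
#' @param lamella_fraction Fraction of the axis forming one lamella
#'   (default 0.10; the middle lamella is the central slab of this width).
#' @param injury_severity Default injury severity, fraction of maximal hilar
#'   cell loss / sprouting (default 0.80).
#' @return A `scaffold_config` list.
#' @export
scaffold_config <- function(scale = "full", counts = FULL_SCALE_COUNTS,
                            axis_length_mm = 6, lamella_fraction = 0.10,
                            injury_severity = 0.80) {
  divisor <- scale_divisor(scale)
  stopifnot(
    all(counts >= 0), !is.null(names(counts)),
    axis_length_mm > 0,
    lamella_fraction > 0, lamella_fraction <= 1,
    injury_severity >= 0, injury_severity <= 1
  )
  structure(
    list(
      scale = scale, divisor = divisor, counts = counts,
      axis_length_mm = axis_length_mm, lamella_fraction = lamella_fraction,
      injury_severity = injury_severity
    ),
    class = "scaffold_config"
  )
}

scale_divisor <- function(scale) {
  if (is.numeric(scale)) {
    stopifnot(scale >= 1)
    return(scale)
  }
  switch(as.character(scale),
    "full" = 1,
    "1:20" = 20,
    "1:2000" = 2000,
    abort(sprintf("unknown scale '%s' (use \"full\", \"1:20\", \"1:2000\" or a number)", scale))
  )
}

#' Build the structural scaffold
#'
#' Places `round(full_count / divisor)` cells of each type at the bin
#' midpoints of the septotemporal axis, `x_i = (i + 0.5) / N * L` — a
#' deterministic, seed-free layout under which lamellar selections come out
#' as exact integer counts for the published configurations. Global
#' identifiers are unique across types.
#'
#' @param config A [scaffold_config()].
#' @return A `network_scaffold` tibble: `gid` (global identifier),
#'   `cell_type`, `type_index`, `position_mm`, `alive`, with the config and
#'   a `sprouting` flag stored as attributes.
#' @examples
#' sc <- build_scaffold(scaffold_config("1:20"))
#' dplyr::count(sc, cell_type)
#' @export
build_scaffold <- function(config) {
  stopifnot(inherits(config, "scaffold_config"))
  n_by_type <- as.integer(round(config$counts / config$divisor))
  if (any(n_by_type == 0L)) {
    warn(paste0(
      "zero cells at this scale for type(s): ",
      paste(names(config$counts)[n_by_type == 0L], collapse = ", ")
    ))
  }
  types <- names(config$counts)
  L <- config$axis_length_mm
  parts <- lapply(seq_along(types), function(t) {
    n <- n_by_type[t]
    quick_tibble(
      cell_type = rep(types[t], n),
      type_index = seq_len(n),
      position_mm = (seq_len(n) - 0.5) / n * L
    )
  })
  out <- dplyr::bind_rows(parts)
  out <- tibble::add_column(out, gid = seq_len(nrow(out)), .before = 1L)
  out$alive <- TRUE
  attr(out, "config") <- config
  attr(out, "sprouting") <- 0
  class(out) <- c("network_scaffold", class(tibble::tibble()))
  out
}

#' @export
print.network_scaffold <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "# A network scaffold: %d cells (scale %s), %d alive, sprouting %.0f%%\n",
    nrow(x), as.character(cfg$scale), sum(x$alive), 100 * attr(x, "sprouting")
  ))
  NextMethod()
}

#' Apply hilar injury to a scaffold
#'
#' The injured dentate loses hilar cells (mossy and HIPP) and gains
#' recurrent granule-cell collaterals (mossy fiber sprouting); both are
#' modelled at a common severity, 80% of maximum by default — the level
#' that maximises epileptiform activity and matches mossy cell survival in
#' human temporal lobe epilepsy. A seeded uniform choice of
#' `round(severity * N)` mossy and HIPP cells is marked dead; granule and
#' basket cells are untouched. The severity is recorded as the scaffold's
#' `sprouting` attribute, which drives the sprouted-conductance rule in
#' [scale_rules()].
#'
#' @param scaffold A [build_scaffold()] result.
#' @param severity Fraction of maximal injury in `[0, 1]` (default from the
#'   scaffold's config).
#' @param seed Integer seed for the cell-loss draw.
#' @return The scaffold with updated `alive` flags and `sprouting`
#'   attribute.
#' @export
apply_injury <- function(scaffold, severity = NULL, seed = 1) {
  cfg <- attr(scaffold, "config")
  severity <- severity %||% cfg$injury_severity
  stopifnot(severity >= 0, severity <= 1)
  if (severity > 0) {
    for (type in c("mossy", "hipp")) {
      rows <- which(scaffold$cell_type == type & scaffold$alive)
      n_dead <- round(severity * length(rows))
      if (n_dead > 0) {
        dead <- with_seed(
          derive_seed(seed, paste0("injury_", type)),
          sample(rows, n_dead)
        )
        scaffold$alive[dead] <- FALSE
      }
    }
  }
  attr(scaffold, "sprouting") <- severity
  scaffold
}

#' Lamellar perforant-path stimulation set
#'
#' Selects the cells receiving simultaneous perforant-path input: all alive
#' granule and basket cells whose septotemporal position falls in the
#' stimulated sub-interval of the middle lamella. The middle lamella is the
#' central `lamella_fraction` of the axis; the stimulated sub-interval is
#' its leading `sublamella_fraction` (half-open, so counts are exact for
#' the published configurations: the whole middle lamella at 1:20 scale
#' stimulates 5,000 granule and 50 basket cells, and 1/10th of it at full
#' scale stimulates 10,000 granule and 100 basket cells). Mossy cells are
#' not selected geometrically — the published mossy percentages are not
#' derivable from the counts — so `mossy_count` alive mossy cells nearest
#' the axis midpoint are taken explicitly (defaults: 20 at full scale, 10
#' at 1:20).
#'
#' @param scaffold A [build_scaffold()] (optionally injured) scaffold.
#' @param sublamella_fraction Leading fraction of the middle lamella to
#'   stimulate (1 = whole middle lamella).
#' @param mossy_count Explicit number of mossy cells to stimulate.
#' @param onset_ms Stimulation onset (default 5 ms).
#' @return A `stimulation_set` tibble: `gid`, `cell_type`, `position_mm`,
#'   with the onset and the stimulated interval as attributes.
#' @export
stimulation_set <- function(scaffold, sublamella_fraction = 1,
                            mossy_count = NULL, onset_ms = 5) {
  cfg <- attr(scaffold, "config")
  stopifnot(sublamella_fraction > 0, sublamella_fraction <= 1)
  L <- cfg$axis_length_mm
  lam <- cfg$lamella_fraction
  lo <- (0.5 - lam / 2) * L
  hi <- lo + sublamella_fraction * lam * L
  in_band <- scaffold$position_mm >= lo & scaffold$position_mm < hi

  sel <- scaffold$alive & in_band & scaffold$cell_type %in% c("granule", "basket")

  if (is.null(mossy_count)) {
    mossy_count <- if (cfg$divisor <= 1) 20L else 10L
  }
  mossy_rows <- which(scaffold$cell_type == "mossy" & scaffold$alive)
  if (length(mossy_rows)) {
    near <- mossy_rows[order(abs(scaffold$position_mm[mossy_rows] - L / 2))]
    sel[head(near, mossy_count)] <- TRUE
  }

  out <- scaffold[sel, c("gid", "cell_type", "position_mm")]
  if (!nrow(out)) warn("stimulation set is empty")
  attr(out, "onset_ms") <- onset_ms
  attr(out, "interval_mm") <- c(lo, hi)
  class(out) <- c("stimulation_set", class(tibble::tibble()))
  out
}

#' Scale-dependent synaptic parameter rules
#'
#' Returns the effective parameters that compensate for network scale and
#' injury: reduced models multiply every pairwise connection probability
#' (x5 at 1:20 scale, x1 at full scale, divisor-proportional otherwise);
#' sprouted granule-to-granule synapses peak at 0.5 nS (reduced from the
#' 1.0 nS first estimate); granule-to-interneuron (basket and HIPP)
#' conductances are divided by 2 to avoid depolarisation block.
#'
#' @param config A [scaffold_config()].
#' @return A one-row tibble: `scale`, `connection_probability_multiplier`,
#'   `sprouted_gc_gc_conductance_nS`, `gc_to_inhibitory_divisor`.
#' @examples
#' scale_rules(scaffold_config("1:20"))
#' @export
scale_rules <- function(config) {
  stopifnot(inherits(config, "scaffold_config"))
  mult <- if (config$divisor == 1) {
    1
  } else if (config$divisor == 20) {
    5
  } else {
    abort(sprintf(
      "no published connection-probability multiplier for scale '%s'",
      as.character(config$scale)
    ))
  }
  tibble::tibble(
    scale = as.character(config$scale),
    connection_probability_multiplier = mult,
    sprouted_gc_gc_conductance_nS = 0.5,
    gc_to_inhibitory_divisor = 2
  )
}
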