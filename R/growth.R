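# Stochastic dendritic growth: a Hillman-style recursive algorithm that
# turns per-parameter distributions into virtual dendritic trees.
#
# The generator is built so that the measured value of every directly drawn
# basic parameter equals the drawn value: the first node of a branch carries
# the drawn initial diameter, branches are straight with exactly the drawn
# path length, the drawn bifurcation amplitude separates the daughter
# initial directions, and daughter diameters satisfy the drawn Rall power
# and diameter ratio at the measured parent end diameter. Extracting basic
# parameters from a generated population therefore recovers the input
# distributions up to sampling noise, which is the property the validation
# pipeline tests.

GROWTH_DIST_FIELDS <- c(
  "soma_diameter", "n_stems", "stem_initial_diameter", "taper_rate",
  "internal_path_length", "terminal_path_length", "rall_power",
  "daughter_diameter_ratio", "bifurcation_amplitude",
  "terminal_diameter_threshold"
)

#' Assemble growth parameters for the dendritic growth algorithm
#'
#' One [dist_spec()] per basic parameter, plus three scalar controls. Length
#' and diameter parameters are in micrometres, angles in degrees, taper in
#' micrometres of diameter lost per micrometre of path.
#'
#' @param soma_diameter,n_stems,stem_initial_diameter,taper_rate
#'   [dist_spec()] objects. `n_stems` draws are rounded and clamped to at
#'   least 1.
#' @param internal_path_length,terminal_path_length [dist_spec()] objects for
#'   branch path lengths; terminal branches draw their total path length
#'   directly, so measured terminal branch length matches the input.
#' @param rall_power,daughter_diameter_ratio,bifurcation_amplitude
#'   [dist_spec()] objects governing each bifurcation. Ratio draws below 1
#'   are inverted (the ratio is defined as larger/smaller); amplitude draws
#'   are redrawn until inside (0, 180).
#' @param terminal_diameter_threshold [dist_spec()]; a branch whose initial
#'   diameter is at or below a fresh draw from this spec becomes terminal.
#' @param stem_elevation_cone Half-angle (degrees) of the cone about +y in
#'   which stem directions are drawn uniformly (granule cells are unipolar
#'   toward the molecular layer).
#' @param segment_step Spatial discretisation of branches (micrometres,
#'   default 5).
#' @param max_branch_order Hard recursion guard: branches at this order are
#'   forced terminal.
#' @return A `growth_params` object.
#' @seealso [grow_neuron()], [generate_population()], [granule_archetype()]
#' @export
growth_params <- function(soma_diameter, n_stems, stem_initial_diameter,
                          taper_rate, internal_path_length,
                          terminal_path_length, rall_power,
                          daughter_diameter_ratio, bifurcation_amplitude,
                          terminal_diameter_threshold,
                          stem_elevation_cone = 35,
                          segment_step = 5,
                          max_branch_order = 12L) {
  specs <- list(
    soma_diameter = soma_diameter, n_stems = n_stems,
    stem_initial_diameter = stem_initial_diameter, taper_rate = taper_rate,
    internal_path_length = internal_path_length,
    terminal_path_length = terminal_path_length, rall_power = rall_power,
    daughter_diameter_ratio = daughter_diameter_ratio,
    bifurcation_amplitude = bifurcation_amplitude,
    terminal_diameter_threshold = terminal_diameter_threshold
  )
  bad <- names(specs)[!vapply(specs, inherits, logical(1), "dist_spec")]
  if (length(bad)) {
    abort(paste0("not dist_spec objects: ", paste(bad, collapse = ", ")))
  }
  stopifnot(
    is.numeric(stem_elevation_cone), stem_elevation_cone > 0,
    stem_elevation_cone <= 90,
    is.numeric(segment_step), segment_step > 0,
    is.numeric(max_branch_order), max_branch_order >= 1
  )
  structure(
    c(specs, list(
      stem_elevation_cone = stem_elevation_cone,
      segment_step = segment_step,
      max_branch_order = as.integer(max_branch_order)
    )),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  for (f in GROWTH_DIST_FIELDS) {
    cat(sprintf("  %-28s", f))
    print(x[[f]])
  }
  cat(sprintf(
    "  stem cone %g deg | step %g um | max order %d\n",
    x$stem_elevation_cone, x$segment_step, x$max_branch_order
  ))
  invisible(x)
}

# one truncated draw from a spec using the *current* RNG stream
draw1 <- function(spec) {
  tr <- spec$truncation
  p <- spec$params
  for (i in 1:10000) {
    v <- switch(spec$kind,
      gamma = rgamma(1L, p$shape, scale = p$scale),
      normal = rnorm(1L, p$mean, p$sd),
      uniform = runif(1L, p$low, p$high),
      constant = p$value
    )
    if (is.null(tr) || (v >= tr[1L] && v <= tr[2L])) {
      return(v)
    }
    if (spec$kind == "constant") {
      abort("constant value outside its truncation interval")
    }
  }
  abort("rejection sampling failed to converge (10000 draws)")
}

# Buffered draw stream: draws from the current RNG stream in vectorised
# chunks and hands values out one at a time. Sampling-equivalent to draw1
# (truncation by rejection) but ~5x cheaper per draw; determinism is per
# (spec, seed, consumption order).
make_stream <- function(spec, chunk = 64L) {
  if (spec$kind == "constant") {
    v <- spec$params$value
    tr <- spec$truncation
    if (!is.null(tr) && (v < tr[1L] || v > tr[2L])) {
      abort("constant value outside its truncation interval")
    }
    return(function() v)
  }
  p <- spec$params
  tr <- spec$truncation
  raw <- switch(spec$kind,
    gamma = function(n) rgamma(n, p$shape, scale = p$scale),
    normal = function(n) rnorm(n, p$mean, p$sd),
    uniform = function(n) runif(n, p$low, p$high)
  )
  buf <- double(0)
  pos <- 0L
  function() {
    if (pos >= length(buf)) {
      tries <- 0L
      repeat {
        cand <- raw(chunk)
        if (!is.null(tr)) cand <- cand[cand >= tr[1L] & cand <= tr[2L]]
        if (length(cand)) break
        tries <- tries + 1L
        if (tries > 1000L) abort("rejection sampling failed to converge")
      }
      buf <<- cand
      pos <<- 0L
    }
    pos <<- pos + 1L
    buf[pos]
  }
}

#' Grow one virtual neuron
#'
#' Runs the stochastic growth algorithm: a soma of drawn diameter at the
#' origin; drawn number of stems with directions uniform in azimuth inside
#' the elevation cone about +y; each branch grown straight in
#' `segment_step` increments with linear taper to the drawn total path
#' length. At a branch start the cell draws a terminal-diameter threshold:
#' if the branch's initial diameter is at or below it (or the branch order
#' hits `max_branch_order`) the branch is terminal, otherwise it ends in a
#' bifurcation whose daughter diameters satisfy
#' d_parent^n = d1^n + d2^n at the drawn Rall power n and drawn ratio
#' d1/d2, with the daughters separated by the drawn amplitude in a
#' uniformly oriented bifurcation plane (the thicker daughter deviating
#' less, in proportion to diameter share). Non-physical taper draws (which
#' would shrink a branch below 0.05 um) are redrawn; redraw and
#' order-guard events are available via `attr(, "log")`.
#'
#' @param params A [growth_params()].
#' @param seed Integer seed; the same `(params, seed)` reproduce the same
#'   morphology exactly.
#' @return A [morphology][as_morphology] with a `log` attribute (counts of
#'   taper redraws and order-guard terminations).
#' @export
grow_neuron <- function(params, seed) {
  stopifnot(inherits(params, "growth_params"))
  with_seed(seed, grow_impl(params))
}

grow_impl <- function(params, d_min = 0.01) {
  step <- params$segment_step
  max_order <- params$max_branch_order
  cone_rad <- params$stem_elevation_cone * pi / 180
  deg <- pi / 180

  r_stem_d <- make_stream(params$stem_initial_diameter)
  r_taper <- make_stream(params$taper_rate)
  r_int_len <- make_stream(params$internal_path_length)
  r_term_len <- make_stream(params$terminal_path_length)
  r_rall <- make_stream(params$rall_power)
  r_ratio <- make_stream(params$daughter_diameter_ratio)
  r_amp <- make_stream(params$bifurcation_amplitude)
  r_thr <- make_stream(params$terminal_diameter_threshold)
  r_unif <- local({
    buf <- double(0)
    pos <- 0L
    function() {
      if (pos >= length(buf)) {
        buf <<- runif(64L)
        pos <<- 0L
      }
      pos <<- pos + 1L
      buf[pos]
    }
  })

  d_soma <- draw1(params$soma_diameter)
  n_stems <- max(1L, as.integer(round(draw1(params$n_stems))))

  xs <- list(0)
  ys <- list(0)
  zs <- list(0)
  rs <- list(d_soma / 2)
  ps <- list(-1L)
  n_nodes <- 1L
  n_chunks <- 1L
  taper_redraws <- 0L
  taper_clamps <- 0L
  order_guard_hits <- 0L

  # branch stack as parallel scalar vectors (LIFO): start, direction,
  # initial diameter, order, parent node
  cap <- 64L
  s_x <- s_y <- s_z <- s_dx <- s_dy <- s_dz <- s_d0 <- double(cap)
  s_ord <- s_par <- integer(cap)
  top <- 0L

  for (i in seq_len(n_stems)) {
    d0 <- r_stem_d()
    az <- 2 * pi * r_unif()
    cth <- cos(cone_rad) + (1 - cos(cone_rad)) * r_unif()
    sth <- sqrt(1 - cth^2)
    top <- top + 1L
    s_x[top] <- 0
    s_y[top] <- 0
    s_z[top] <- 0
    s_dx[top] <- sth * cos(az)
    s_dy[top] <- cth
    s_dz[top] <- sth * sin(az)
    s_d0[top] <- d0
    s_ord[top] <- 0L
    s_par[top] <- 1L
  }

  while (top > 0L) {
    px <- s_x[top]
    py <- s_y[top]
    pz <- s_z[top]
    ux <- s_dx[top]
    uy <- s_dy[top]
    uz <- s_dz[top]
    d0 <- s_d0[top]
    order <- s_ord[top]
    parent <- s_par[top]
    top <- top - 1L

    thr <- r_thr()
    guard <- order >= max_order
    terminal <- d0 <= thr || guard
    if (guard && d0 > thr) order_guard_hits <- order_guard_hits + 1L

    L <- if (terminal) r_term_len() else r_int_len()
    if (L <= 0) abort("drew a non-positive branch length; check the length specs")

    taper <- r_taper()
    tries <- 0L
    while (d0 - taper * L <= d_min) {
      taper <- r_taper()
      tries <- tries + 1L
      taper_redraws <- taper_redraws + 1L
      if (tries > 100L) {
        # a branch this thin admits almost no drawn taper: clamp to the
        # largest physical value instead of stalling (logged)
        taper <- max(0, (d0 - d_min) / L) * 0.99
        taper_clamps <- taper_clamps + 1L
        break
      }
    }
    d_end <- d0 - taper * L

    if (L <= step * (1 + 1e-9)) {
      s <- L
      m <- 1L
      diam <- d0
    } else {
      s <- step * seq_len(floor(L / step))
      m <- length(s)
      if (L - s[m] > 1e-9) {
        s <- c(s, L)
        m <- m + 1L
      }
      diam <- d0 + (d_end - d0) * (s - s[1L]) / (L - s[1L])
    }

    n_chunks <- n_chunks + 1L
    xs[[n_chunks]] <- px + ux * s
    ys[[n_chunks]] <- py + uy * s
    zs[[n_chunks]] <- pz + uz * s
    rs[[n_chunks]] <- diam / 2
    ps[[n_chunks]] <- c(parent, n_nodes + seq_len(m - 1L))
    end_node <- n_nodes + m
    n_nodes <- end_node
    if (n_nodes > 2e5L) abort("runaway growth: > 200,000 nodes in one cell")

    if (!terminal) {
      n_r <- min(5, max(0.5, r_rall()))
      R <- r_ratio()
      if (R < 1) R <- 1 / R
      A <- r_amp()
      tries <- 0L
      while (A <= 0 || A >= 180) {
        A <- r_amp()
        tries <- tries + 1L
        if (tries > 100L) abort("bifurcation_amplitude spec keeps drawing outside (0, 180)")
      }
      d2 <- d_end / (1 + R^n_r)^(1 / n_r)
      d1 <- R * d2

      # orthonormal frame about the parent direction
      if (abs(ux) < 0.9) {
        e1x <- 1 - ux * ux
        e1y <- -ux * uy
        e1z <- -ux * uz
      } else {
        e1x <- -uz * ux
        e1y <- -uz * uy
        e1z <- 1 - uz * uz
      }
      inv <- 1 / sqrt(e1x^2 + e1y^2 + e1z^2)
      e1x <- e1x * inv
      e1y <- e1y * inv
      e1z <- e1z * inv
      e2x <- uy * e1z - uz * e1y
      e2y <- uz * e1x - ux * e1z
      e2z <- ux * e1y - uy * e1x
      phi <- 2 * pi * r_unif()
      wx <- cos(phi) * e1x + sin(phi) * e2x
      wy <- cos(phi) * e1y + sin(phi) * e2y
      wz <- cos(phi) * e1z + sin(phi) * e2z
      dev1 <- (A * deg) * d2 / (d1 + d2) # thicker daughter deviates less
      dev2 <- (A * deg) - dev1
      ex <- px + ux * L
      ey <- py + uy * L
      ez <- pz + uz * L
      c1 <- cos(dev1)
      s1 <- sin(dev1)
      c2 <- cos(dev2)
      s2 <- sin(dev2)

      if (top + 2L > cap) {
        cap <- cap * 2L
        length(s_x) <- cap
        length(s_y) <- cap
        length(s_z) <- cap
        length(s_dx) <- cap
        length(s_dy) <- cap
        length(s_dz) <- cap
        length(s_d0) <- cap
        length(s_ord) <- cap
        length(s_par) <- cap
      }
      # push thinner daughter first so the thicker one is grown first
      top <- top + 1L
      s_x[top] <- ex
      s_y[top] <- ey
      s_z[top] <- ez
      s_dx[top] <- c2 * ux - s2 * wx
      s_dy[top] <- c2 * uy - s2 * wy
      s_dz[top] <- c2 * uz - s2 * wz
      s_d0[top] <- d2
      s_ord[top] <- order + 1L
      s_par[top] <- end_node
      top <- top + 1L
      s_x[top] <- ex
      s_y[top] <- ey
      s_z[top] <- ez
      s_dx[top] <- c1 * ux + s1 * wx
      s_dy[top] <- c1 * uy + s1 * wy
      s_dz[top] <- c1 * uz + s1 * wz
      s_d0[top] <- d1
      s_ord[top] <- order + 1L
      s_par[top] <- end_node
    }
  }

  m <- quick_tibble(
    node_id = seq_len(n_nodes),
    structure = c(1L, rep(3L, n_nodes - 1L)),
    x = unlist(xs, use.names = FALSE),
    y = unlist(ys, use.names = FALSE),
    z = unlist(zs, use.names = FALSE),
    radius = unlist(rs, use.names = FALSE),
    parent_id = as.integer(unlist(ps, use.names = FALSE))
  )
  class(m) <- c("morphology", class(tibble::tibble()))
  attr(m, "log") <- list(
    taper_redraws = taper_redraws,
    taper_clamps = taper_clamps,
    order_guard_hits = order_guard_hits
  )
  m
}

#' Generate a population of virtual neurons
#'
#' Cell `i` is grown from its own seed `derive_seed(base_seed, "cell<i>")`,
#' mirroring per-cell random streams keyed on a global identifier, so the
#' population is identical however the work is chunked. A cell whose growth
#' fails (pathological parameter draws) is redrawn from a retry stream, up
#' to 5 times, with a warning.
#'
#' @param params A [growth_params()].
#' @param n Number of cells.
#' @param base_seed Integer root seed.
#' @return A tibble with columns `cell`, `seed` and a `morphology`
#'   list-column.
#' @examples
#' pop <- generate_population(granule_archetype()$params, n = 3, base_seed = 1)
#' extract_emergent(pop)
#' @export
generate_population <- function(params, n, base_seed) {
  stopifnot(n >= 1)
  cells <- seq_len(n)
  seeds <- integer(n)
  morphs <- vector("list", n)
  for (i in cells) {
    seed_i <- derive_seed(base_seed, paste0("cell", i))
    m <- NULL
    for (k in 0:5) {
      m <- tryCatch(grow_neuron(params, seed_i), error = function(e) e)
      if (!inherits(m, "error")) break
      warn(sprintf("cell %d failed to grow (retry %d): %s", i, k + 1L, conditionMessage(m)))
      seed_i <- derive_seed(base_seed, paste0("cell", i, "retry", k + 1L))
    }
    if (inherits(m, "error")) {
      abort(sprintf("cell %d failed to grow after 5 retries", i))
    }
    seeds[i] <- seed_i
    morphs[[i]] <- m
  }
  tibble::tibble(cell = cells, seed = seeds, morphology = morphs)
}
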