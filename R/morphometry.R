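# Morphometry: branch decomposition and extraction of the basic (growth
# algorithm input) and emergent (whole cell summary) parameters.
#
# All heavy lifting happens on a single node table covering a whole
# population (column `cell` + the seven SWC columns), with ancestor chains
# resolved by pointer doubling so extraction over 10^4 cells stays vectorised.

# ---- population plumbing ----------------------------------------------------

# Normalise any accepted input (one morphology, a list of morphologies, or a
# population tibble with a `morphology` list-column) to one big node table.
pop_nodes <- function(x) {
  if (inherits(x, "morphology")) {
    morphs <- list(x)
    cells <- 1L
  } else if (is.data.frame(x) && "morphology" %in% names(x)) {
    morphs <- x$morphology
    cells <- if ("cell" %in% names(x)) x$cell else seq_along(morphs)
  } else if (is.list(x)) {
    morphs <- x
    cells <- if (!is.null(names(x))) names(x) else seq_along(x)
  } else {
    abort("expected a morphology, a list of morphologies, or a population tibble")
  }
  nn <- vapply(morphs, nrow, integer(1))
  col <- function(v) unlist(lapply(morphs, function(m) m[[v]]), use.names = FALSE)
  quick_tibble(
    cell = rep(cells, nn),
    node_id = col("node_id"), structure = col("structure"),
    x = col("x"), y = col("y"), z = col("z"), radius = col("radius"),
    parent_id = col("parent_id")
  )
}

# Per-node annotations shared by every extractor. Assumes each cell's rows
# are contiguous and topologically ordered (guaranteed by as_morphology).
annotate_nodes <- function(df) {
  n <- nrow(df)
  cellf <- match(df$cell, unique(df$cell))
  local_idx <- seq_len(n) - match(cellf, cellf) + 1L
  if (all(df$node_id == local_idx)) {
    # node ids are the within-cell row positions (true for every generated
    # morphology): parent rows resolve by offset arithmetic
    offset <- seq_len(n) - local_idx
    pr <- df$parent_id + offset
    pr[df$parent_id == -1L] <- NA_integer_
  } else {
    key_mod <- max(df$node_id) + 2
    pr <- match(cellf * key_mod + df$parent_id, cellf * key_mod + df$node_id)
    pr[df$parent_id == -1L] <- NA_integer_
  }

  dend <- is_dendrite(df$structure)
  has_p <- !is.na(pr)
  nch <- tabulate(pr[dend & has_p], nbins = n)
  dx <- df$x - df$x[pr]
  dy <- df$y - df$y[pr]
  dz <- df$z - df$z[pr]
  seglen <- sqrt(dx * dx + dy * dy + dz * dz)
  seglen[!has_p] <- 0

  is_soma <- df$structure == 1L
  pr1 <- pr
  pr1[!has_p] <- 1L
  is_head <- dend & has_p & (is_soma[pr1] | nch[pr1] >= 2L)
  is_head[dend & !has_p] <- TRUE # dendrite root (degenerate, soma-less input)

  # pointer doubling: head[i] = nearest branch head at or above i
  h <- seq_len(n)
  follow <- dend & !is_head & has_p
  h[follow] <- pr[follow]
  repeat {
    h2 <- h[h]
    if (identical(h2, h)) break
    h <- h2
  }
  pos <- cbind(df$x, df$y, df$z)
  list(
    df = df, n = n, cellf = cellf, pr = pr, dend = dend, nch = nch,
    pos = pos, seglen = seglen, is_soma = is_soma, is_head = is_head,
    head = h,
    is_tip = dend & nch == 0L,
    is_bif = dend & nch >= 2L
  )
}

# Cumulative path length from the root, by pointer doubling with carried sums.
cum_path_length <- function(ann) {
  acc <- ann$seglen
  ptr <- ifelse(is.na(ann$pr), 0L, ann$pr)
  while (any(ptr > 0L)) {
    acc <- acc + c(0, acc)[ptr + 1L]
    ptr <- c(0L, ptr)[ptr + 1L]
  }
  acc
}

# Branch table: one row per branch head. Branches merge degree-2
# (continuation) nodes; each runs from its anchor (soma or a bifurcation
# node) to the next bifurcation node or tip.
branch_table <- function(ann) {
  heads <- which(ann$is_head)
  bid <- match(ann$head, heads) # branch id per node (NA for soma)
  len <- as.vector(rowsum(ann$seglen[ann$dend], bid[ann$dend]))
  ends <- which(ann$dend & ann$nch != 1L)
  end_of <- integer(length(heads))
  end_of[bid[ends]] <- ends
  anchor <- ann$pr[heads]

  ord <- integer(length(heads))
  for (k in seq_along(heads)) {
    a <- anchor[k]
    ord[k] <- if (is.na(a) || ann$is_soma[a]) 0L else ord[bid[a]] + 1L
  }
  quick_tibble(
    cell = ann$df$cell[heads],
    head = heads,
    anchor = anchor,
    end = end_of,
    kind = ifelse(ann$nch[end_of] == 0L, "terminal", "internal"),
    branch_order = ord,
    path_length = len,
    initial_diameter = 2 * ann$df$radius[heads],
    final_diameter = 2 * ann$df$radius[end_of]
  )
}

# Per-bifurcation geometry: parent end diameter, daughter initial diameters,
# amplitude between daughter initial directions. Only binary bifurcations
# produce rows; higher-order multifurcations are counted elsewhere and
# reported via the `n_multifurcations` attribute.
bifurcation_table <- function(ann) {
  heads <- which(ann$is_head)
  danchor <- ann$pr[heads]
  at_bif <- !is.na(danchor) & ann$is_bif[pmax(danchor, 1L)]
  hb <- heads[at_bif]
  ab <- danchor[at_bif]
  o <- order(ab, hb)
  hb <- hb[o]
  ab <- ab[o]
  counts <- table(ab)
  binary <- as.integer(names(counts)[counts == 2L])
  keep <- ab %in% binary
  hb <- hb[keep]
  ab <- ab[keep]
  first <- seq_along(ab) %% 2L == 1L
  b <- ab[first]
  c1 <- hb[first]
  c2 <- hb[!first]
  u1 <- ann$pos[c1, , drop = FALSE] - ann$pos[b, , drop = FALSE]
  u2 <- ann$pos[c2, , drop = FALSE] - ann$pos[b, , drop = FALSE]
  cosang <- rowSums(u1 * u2) / (row_norm(u1) * row_norm(u2))
  out <- quick_tibble(
    cell = ann$df$cell[b],
    node = b,
    parent_diameter = 2 * ann$df$radius[b],
    d1 = 2 * ann$df$radius[c1],
    d2 = 2 * ann$df$radius[c2],
    child1 = c1,
    child2 = c2,
    amplitude_deg = acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  )
  attr(out, "n_multifurcations") <- sum(counts > 2L)
  out
}

# Solve d0^n = d1^n + d2^n for n in [0.5, 5] by vectorised bisection;
# NA where no solution exists in the bracket.
solve_rall <- function(d0, d1, d2, lower = 0.5, upper = 5, iters = 60L) {
  a <- d1 / d0
  b <- d2 / d0
  g <- function(n) a^n + b^n - 1
  lo <- rep(lower, length(d0))
  hi <- rep(upper, length(d0))
  solvable <- a < 1 & b < 1 & g(lo) >= 0 & g(hi) <= 0
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    up <- g(mid) > 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  out <- (lo + hi) / 2
  out[!solvable] <- NA_real_
  out
}

# ---- user-facing extractors -------------------------------------------------

#' Decompose a morphology into branches
#'
#' A branch runs from the soma or a bifurcation node to the next bifurcation
#' node or dendritic tip, merging any in-line continuation nodes, so a
#' many-segment path counts as one branch. The segment from the anchor to the
#' branch's first own node is part of the branch, and the branch's initial
#' diameter is taken at that first own node.
#'
#' @param m A [morphology][as_morphology].
#' @return A tibble with one row per branch: `branch_id`, `kind`
#'   (`"internal"` ends at a bifurcation, `"terminal"` at a tip),
#'   `branch_order` (bifurcations between soma and branch start),
#'   `path_length`, `initial_diameter`, `final_diameter` (micrometres) and a
#'   `nodes` list-column of member node ids. A soma-only morphology yields
#'   zero rows.
#' @examples
#' m <- read_swc(c("1 1 0 0 0 5 -1", "2 3 0 10 0 1 1", "3 3 0 20 0 1 2"))
#' decompose_branches(m)
#' @export
decompose_branches <- function(m) {
  validate_morphology(m)
  ann <- annotate_nodes(pop_nodes(m))
  if (!any(ann$is_head)) {
    return(tibble::tibble(
      branch_id = integer(), kind = character(), branch_order = integer(),
      path_length = double(), initial_diameter = double(),
      final_diameter = double(), nodes = list()
    ))
  }
  br <- branch_table(ann)
  heads <- which(ann$is_head)
  bid <- match(ann$head, heads)
  nodes <- split(ann$df$node_id[ann$dend], bid[ann$dend])
  tibble::tibble(
    branch_id = seq_len(nrow(br)),
    kind = br$kind,
    branch_order = br$branch_order,
    path_length = br$path_length,
    initial_diameter = br$initial_diameter,
    final_diameter = br$final_diameter,
    nodes = unname(nodes)
  )
}

#' Extract basic morphometric parameters
#'
#' The basic parameters are the raw per-entity measurements consumed by the
#' dendritic growth algorithm: `soma_diameter` and `n_stems` (per cell),
#' `stem_initial_diameter` (per stem), `taper_rate` (per branch; diameter
#' decrease per micrometre of path, so a constant-diameter branch scores 0),
#' `internal_path_length` and `terminal_path_length` (per branch of each
#' kind), `terminal_initial_diameter` and `internal_initial_diameter`
#' (initial diameter of each branch, split by kind — together the
#' observables of the growth algorithm's termination rule),
#' `rall_power`, `daughter_diameter_ratio` (larger/smaller) and
#' `bifurcation_amplitude` (degrees, per bifurcation), and
#' `terminal_diameter` (per tip). The Rall power at a bifurcation is the
#' exponent n solving d_parent^n = d_1^n + d_2^n, found by bisection on
#' \[0.5, 5\]; bifurcations with no solution in that bracket (for example a
#' daughter at least as thick as its parent) are recorded as `NA` with a
#' warning.
#'
#' @param x A [morphology][as_morphology], a list of morphologies, or a
#'   population tibble as returned by [generate_population()].
#' @return A tidy tibble with columns `cell`, `parameter`, `entity_id`
#'   (within-cell index of the measured entity) and `value`.
#' @export
extract_basic <- function(x) {
  ann <- annotate_nodes(pop_nodes(x))
  df <- ann$df
  roots <- which(is.na(ann$pr))
  soma_rows <- roots[ann$is_soma[roots]]

  out <- list(
    quick_tibble(
      cell = df$cell[soma_rows], parameter = rep("soma_diameter", length(soma_rows)),
      value = 2 * df$radius[soma_rows]
    ),
    quick_tibble(
      cell = df$cell[soma_rows], parameter = rep("n_stems", length(soma_rows)),
      value = as.double(ann$nch[soma_rows])
    )
  )
  if (any(ann$is_head)) {
    br <- branch_table(ann)
    stems <- br$branch_order == 0L
    internal <- br$kind == "internal"
    out <- c(out, list(
      quick_tibble(
        cell = br$cell[stems],
        parameter = rep("stem_initial_diameter", sum(stems)),
        value = br$initial_diameter[stems]
      ),
      quick_tibble(
        cell = br$cell, parameter = rep("taper_rate", nrow(br)),
        value = (br$initial_diameter - br$final_diameter) / br$path_length
      ),
      quick_tibble(
        cell = br$cell[internal],
        parameter = rep("internal_path_length", sum(internal)),
        value = br$path_length[internal]
      ),
      quick_tibble(
        cell = br$cell[!internal],
        parameter = rep("terminal_path_length", sum(!internal)),
        value = br$path_length[!internal]
      ),
      quick_tibble(
        cell = br$cell[!internal],
        parameter = rep("terminal_initial_diameter", sum(!internal)),
        value = br$initial_diameter[!internal]
      ),
      quick_tibble(
        cell = br$cell[internal],
        parameter = rep("internal_initial_diameter", sum(internal)),
        value = br$initial_diameter[internal]
      )
    ))
    bif <- bifurcation_table(ann)
    if (nrow(bif)) {
      rall <- solve_rall(bif$parent_diameter, bif$d1, bif$d2)
      if (anyNA(rall)) {
        warn(sprintf(
          "%d bifurcation(s) had no Rall power in [0.5, 5]; recorded as NA",
          sum(is.na(rall))
        ))
      }
      out <- c(out, list(
        quick_tibble(
          cell = bif$cell, parameter = rep("rall_power", nrow(bif)),
          value = rall
        ),
        quick_tibble(
          cell = bif$cell,
          parameter = rep("daughter_diameter_ratio", nrow(bif)),
          value = pmax(bif$d1, bif$d2) / pmin(bif$d1, bif$d2)
        ),
        quick_tibble(
          cell = bif$cell, parameter = rep("bifurcation_amplitude", nrow(bif)),
          value = bif$amplitude_deg
        )
      ))
    }
    tips <- which(ann$is_tip)
    out <- c(out, list(quick_tibble(
      cell = df$cell[tips], parameter = rep("terminal_diameter", length(tips)),
      value = 2 * df$radius[tips]
    )))
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, match(.data$cell, unique(df$cell)), .data$parameter)
  res <- dplyr::mutate(res,
    entity_id = dplyr::row_number(),
    .by = c("cell", "parameter")
  )
  tibble::as_tibble(res[c("cell", "parameter", "entity_id", "value")])
}

#' Extract emergent morphometric parameters
#'
#' Emergent parameters are whole-cell summaries not used by the growth
#' algorithm; they validate and filter generated populations. Per cell:
#' `total_dendritic_length` (sum of branch path lengths, micrometres),
#' `n_bifurcations`, `surface_area` (sum over inter-node frusta of
#' pi (r1 + r2) * slant with slant = sqrt(h^2 + (r1 - r2)^2); soma excluded),
#' `avg_path_to_tips` and `avg_euclidean_to_tips`, `max_euclidean_to_tips`
#' (from the soma centre), `max_branch_order`, `partition_asymmetry` (mean
#' over bifurcations of |l - r| / (l + r - 2) on daughter-subtree tip counts,
#' taken as 0 when l = r = 1), `transverse_spread` (max pairwise tip distance
#' in the xy plane) and `longitudinal_spread` (max tip distance along z).
#'
#' @inheritParams extract_basic
#' @return A tibble with one row per cell: `cell` plus the ten emergent
#'   parameters. An error if a cell has no dendritic tips.
#' @export
extract_emergent <- function(x) {
  ann <- annotate_nodes(pop_nodes(x))
  df <- ann$df
  cells <- unique(df$cell)
  cellf <- ann$cellf
  ncell <- length(cells)
  if (!any(ann$is_tip)) abort("morphology has no dendritic tips")

  by_cell <- function(v, rows, fun = sum) {
    out <- rep(if (identical(fun, max)) -Inf else 0, ncell)
    if (length(rows)) {
      agg <- tapply(v, cellf[rows], fun)
      out[as.integer(names(agg))] <- agg
    }
    out
  }

  tips_per_cell <- tabulate(cellf[ann$is_tip], nbins = ncell)
  if (any(tips_per_cell == 0L)) {
    abort(sprintf(
      "cell %s has no dendritic tips", as.character(cells[which(tips_per_cell == 0L)[1L]])
    ))
  }

  total_len <- by_cell(ann$seglen[ann$dend], which(ann$dend))
  n_bif <- by_cell(pmax(ann$nch - 1L, 0L)[ann$is_bif], which(ann$is_bif))

  # frusta: one per dendritic node with a parent; at the soma attachment the
  # soma radius is replaced by the stem node's own radius (soma excluded)
  seg <- which(ann$dend & !is.na(ann$pr))
  r2 <- df$radius[seg]
  r1 <- ifelse(ann$is_soma[ann$pr[seg]], r2, df$radius[ann$pr[seg]])
  slant <- sqrt(ann$seglen[seg]^2 + (r1 - r2)^2)
  area <- by_cell(pi * (r1 + r2) * slant, seg)

  cp <- cum_path_length(ann)
  tiprows <- which(ann$is_tip)
  avg_path <- by_cell(cp[tiprows], tiprows) / tips_per_cell

  roots <- which(is.na(ann$pr))
  root_of_cell <- integer(ncell)
  root_of_cell[cellf[roots]] <- roots
  euclid <- row_norm(ann$pos[tiprows, , drop = FALSE] -
    ann$pos[root_of_cell[cellf[tiprows]], , drop = FALSE])
  avg_euc <- by_cell(euclid, tiprows) / tips_per_cell
  max_euc <- by_cell(euclid, tiprows, max)

  br <- branch_table(ann)
  max_order <- by_cell(br$branch_order, which(ann$is_head), max)

  # partition asymmetry via branch-level tip counts
  heads <- which(ann$is_head)
  bid <- match(ann$head, heads)
  tb <- as.integer(br$kind == "terminal")
  parent_bid <- ifelse(is.na(br$anchor) | ann$is_soma[pmax(br$anchor, 1L)],
    NA_integer_, bid[pmax(br$anchor, 1L)]
  )
  for (k in rev(seq_along(heads))) {
    p <- parent_bid[k]
    if (!is.na(p)) tb[p] <- tb[p] + tb[k]
  }
  bif <- bifurcation_table(ann)
  pa <- rep(0, ncell) # unbranched cells are trivially balanced
  if (nrow(bif)) {
    l <- tb[bid[bif$child1]]
    r <- tb[bid[bif$child2]]
    pa_term <- ifelse(l + r == 2L, 0, abs(l - r) / (l + r - 2))
    bc <- match(bif$cell, cells)
    pa_sum <- as.vector(rowsum(pa_term, bc))
    pa_n <- as.vector(rowsum(rep(1L, length(bc)), bc))
    pa[sort(unique(bc))] <- pa_sum / pa_n
  }

  # spreads over tips, per cell
  tx <- split(ann$pos[tiprows, 1L], cellf[tiprows])
  ty <- split(ann$pos[tiprows, 2L], cellf[tiprows])
  tz <- split(ann$pos[tiprows, 3L], cellf[tiprows])
  spread_xy <- function(xs, ys) {
    if (length(xs) < 2L) {
      return(0)
    }
    max(stats::dist(cbind(xs, ys)))
  }
  transverse <- mapply(spread_xy, tx, ty)
  longitudinal <- vapply(tz, function(z) diff(range(z)), double(1))
  idx <- as.integer(names(tx))
  tr <- lo <- rep(0, ncell)
  tr[idx] <- transverse
  lo[idx] <- longitudinal

  tibble::tibble(
    cell = cells,
    total_dendritic_length = total_len,
    n_bifurcations = n_bif,
    surface_area = area,
    avg_path_to_tips = avg_path,
    avg_euclidean_to_tips = avg_euc,
    max_euclidean_to_tips = max_euc,
    max_branch_order = as.integer(max_order),
    partition_asymmetry = pa,
    transverse_spread = tr,
    longitudinal_spread = lo
  )
}
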