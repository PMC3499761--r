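#' Read a morphology from SWC text
#'
#' Parses the 7-column Southampton Archive format (id, structure code, x, y,
#' z, radius, parent id; `#` lines are comments). Coordinates and radii are in
#' micrometres. Multi-point soma contours are collapsed to their centroid
#' (single-point soma) with a warning; axon nodes (code 2) and any other
#' non-somatic, non-dendritic structures are dropped with their subtrees,
#' with a warning. Parents must be declared before the children that
#' reference them.
#'
#' @param source Path to an `.swc` file, or a character vector of SWC text
#'   (a single string with newlines, or one element per line).
#' @return A validated [morphology][as_morphology].
#' @seealso [write_swc()], [apply_shrinkage_correction()]
#' @examples
#' txt <- c(
#'   "# toy cell",
#'   "1 1 0 0 0 5 -1",
#'   "2 3 0 10 0 1 1",
#'   "3 3 0 20 0 1 2"
#' )
#' read_swc(txt)
#' @export
read_swc <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- trimws(lines[keep])
  lineno <- lineno[keep]
  if (!length(lines)) abort("no data lines in SWC input")

  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    i <- which(nf != 7L)[1L]
    abort(sprintf("line %d: expected 7 columns, found %d", lineno[i], nf[i]))
  }
  v <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7L, byrow = TRUE)
  if (anyNA(v)) {
    i <- which(rowSums(is.na(v)) > 0)[1L]
    abort(sprintf("line %d: non-numeric field", lineno[i]))
  }
  m <- quick_tibble(
    node_id = as.integer(v[, 1L]), structure = as.integer(v[, 2L]),
    x = v[, 3L], y = v[, 4L], z = v[, 5L], radius = v[, 6L],
    parent_id = as.integer(v[, 7L])
  )

  n_roots <- sum(m$parent_id == -1L)
  if (n_roots != 1L) {
    abort(sprintf("SWC input must have exactly one root, found %d", n_roots))
  }

  # parents must already be declared
  seen <- match(m$parent_id, m$node_id)
  bad <- which(m$parent_id != -1L &
    (is.na(seen) | seen >= seq_len(nrow(m))))
  if (length(bad)) {
    abort(sprintf(
      "line %d: parent id %d not declared before node %d",
      lineno[bad[1L]], m$parent_id[bad[1L]], m$node_id[bad[1L]]
    ))
  }
  if (any(m$radius <= 0)) {
    i <- which(m$radius <= 0)[1L]
    abort(sprintf("line %d: non-positive radius", lineno[i]))
  }

  m <- collapse_soma(m)
  m <- drop_foreign_structures(m)
  as_morphology(m)
}

# Collapse a multi-point soma contour to its centroid; reparent soma children.
collapse_soma <- function(m) {
  soma <- which(m$structure == 1L)
  if (length(soma) <= 1L) {
    return(m)
  }
  warn(sprintf(
    "collapsing %d-point soma contour to a single centroid node", length(soma)
  ))
  centroid <- c(mean(m$x[soma]), mean(m$y[soma]), mean(m$z[soma]))
  rad <- mean(m$radius[soma])
  soma_ids <- m$node_id[soma]
  keep <- m[-soma, , drop = FALSE]
  keep$parent_id[keep$parent_id %in% soma_ids] <- m$node_id[soma[1L]]
  root <- quick_tibble(
    node_id = m$node_id[soma[1L]], structure = 1L,
    x = centroid[1L], y = centroid[2L], z = centroid[3L],
    radius = rad, parent_id = -1L
  )
  dplyr::bind_rows(root, keep)
}

# Drop axon (code 2) and other non-soma/non-dendrite nodes, with subtrees.
drop_foreign_structures <- function(m) {
  foreign <- !(m$structure %in% c(1L, 3L, 4L))
  if (!any(foreign)) {
    return(m)
  }
  # propagate: a node is dropped if it or any ancestor is foreign
  pr <- match(m$parent_id, m$node_id)
  drop <- foreign
  for (i in seq_len(nrow(m))) {
    if (!drop[i] && !is.na(pr[i]) && drop[pr[i]]) drop[i] <- TRUE
  }
  warn(sprintf(
    "dropping %d non-somatic, non-dendritic node(s) (e.g. axon, code 2)",
    sum(drop)
  ))
  m[!drop, , drop = FALSE]
}

#' Write a morphology as canonical SWC text
#'
#' Emits the canonical 7-column form: node ids renumbered 1..N in pre-order
#' (every parent before its children, siblings in their stored order), one
#' data line per node. `read_swc(write_swc(m))` is structurally the identity,
#' and `write_swc(read_swc(t)) == t` for text already in canonical form.
#'
#' @param m A [morphology][as_morphology].
#' @param file Optional path; when given the text is written there.
#' @return The SWC text as a character vector of lines (invisibly when `file`
#'   is given).
#' @export
write_swc <- function(m, file = NULL) {
  validate_morphology(m)
  n <- nrow(m)
  pr <- parent_row(m)
  kids <- split(seq_len(n), factor(pr, levels = seq_len(n)))
  order <- integer(n)
  stack <- which(is.na(pr))
  k <- 0L
  while (length(stack)) {
    i <- stack[1L]
    stack <- stack[-1L]
    k <- k + 1L
    order[k] <- i
    stack <- c(kids[[i]], stack)
  }
  new_id <- integer(n)
  new_id[order] <- seq_len(n)
  parent_new <- ifelse(is.na(pr), -1L, new_id[pr])
  num <- function(v) as.character(v) # round-trip exact in R >= 4.0
  lines <- paste(
    new_id[order], m$structure[order],
    num(m$x[order]), num(m$y[order]), num(m$z[order]),
    num(m$radius[order]), parent_new[order]
  )
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Correct a reconstruction for tissue shrinkage
#'
#' Histological processing shrinks tissue anisotropically; reconstructions are
#' rescaled by a transverse (xy-plane) and a depth (z-axis) factor. The
#' defaults are the published estimates for in-vivo labelled granule cells:
#' 1.06x transverse and 1.96x depth. Radii and topology are left untouched.
#'
#' @param m A [morphology][as_morphology].
#' @param transverse_factor Multiplier applied to `x` and `y` (default 1.06).
#' @param depth_factor Multiplier applied to `z` (default 1.96).
#' @return The corrected morphology.
#' @examples
#' m <- as_morphology(data.frame(
#'   node_id = 1:2, structure = c(1, 3), x = c(0, 1), y = c(0, 1),
#'   z = c(0, 1), radius = 1, parent_id = c(-1, 1)
#' ))
#' apply_shrinkage_correction(m)
#' @export
apply_shrinkage_correction <- function(m, transverse_factor = 1.06,
                                       depth_factor = 1.96) {
  if (!is.numeric(transverse_factor) || transverse_factor <= 0 ||
    !is.numeric(depth_factor) || depth_factor <= 0) {
    abort("shrinkage factors must be positive numbers")
  }
  validate_morphology(m)
  m$x <- m$x * transverse_factor
  m$y <- m$y * transverse_factor
  m$z <- m$z * depth_factor
  m
}
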