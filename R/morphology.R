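#' Morphology objects
#'
#' A morphology is a rooted tree of 3-D points with radii — one neuron. It is
#' stored as a tibble with one row per SWC node and columns `node_id`,
#' `structure` (1 soma, 3/4 dendrite), `x`, `y`, `z` (micrometres), `radius`
#' (micrometres) and `parent_id` (`-1` for the root). Rows are kept in
#' topological order (every parent precedes its children), which the rest of
#' the package relies on.
#'
#' @param x A data frame with the seven SWC columns above.
#' @return A validated `morphology` tibble.
#' @examples
#' m <- as_morphology(data.frame(
#'   node_id = 1:3, structure = c(1, 3, 3),
#'   x = c(0, 0, 0), y = c(0, 10, 20), z = 0,
#'   radius = c(5, 1, 1), parent_id = c(-1, 1, 2)
#' ))
#' m
#' @export
as_morphology <- function(x) {
  cols <- c("node_id", "structure", "x", "y", "z", "radius", "parent_id")
  if (!all(cols %in% names(x))) {
    abort(paste0(
      "a morphology needs columns ",
      paste(setdiff(cols, names(x)), collapse = ", "), " (missing)"
    ))
  }
  m <- tibble::as_tibble(x)[cols]
  m$node_id <- as.integer(m$node_id)
  m$structure <- as.integer(m$structure)
  m$parent_id <- as.integer(m$parent_id)
  for (v in c("x", "y", "z", "radius")) m[[v]] <- as.double(m[[v]])
  class(m) <- c("morphology", class(tibble::tibble()))
  validate_morphology(m)
}

#' Validate a morphology
#'
#' Checks the structural invariants: positive radii, unique node ids, exactly
#' one root (`parent_id == -1`), every parent declared before its child, and
#' hence a single connected tree.
#'
#' @param m A `morphology` (or coercible data frame).
#' @return `m`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_morphology <- function(m) {
  if (nrow(m) == 0L) abort("morphology has no nodes")
  if (anyDuplicated(m$node_id)) abort("duplicate node_id in morphology")
  if (any(!is.finite(m$radius)) || any(m$radius <= 0)) {
    abort("all radii must be positive and finite")
  }
  if (any(!is.finite(m$x) | !is.finite(m$y) | !is.finite(m$z))) {
    abort("non-finite coordinates in morphology")
  }
  roots <- which(m$parent_id == -1L)
  if (length(roots) != 1L) {
    abort(sprintf("morphology must have exactly one root, found %d", length(roots)))
  }
  if (roots != 1L) abort("root node must come first")
  pr <- match(m$parent_id, m$node_id)
  bad <- which(is.na(pr) & m$parent_id != -1L)
  if (length(bad)) {
    abort(sprintf(
      "node %d references unknown parent id %d",
      m$node_id[bad[1L]], m$parent_id[bad[1L]]
    ))
  }
  if (any(pr[-roots] >= seq_len(nrow(m))[-roots])) {
    abort("parents must be declared before their children (topological order)")
  }
  invisible(m)
}

#' @export
print.morphology <- function(x, ...) {
  pr <- match(x$parent_id, x$node_id)
  dend <- x$structure %in% c(3L, 4L)
  nch <- tabulate(pr[dend], nbins = nrow(x))
  tips <- sum(dend & nch == 0)
  cat(sprintf(
    "# A morphology: %d nodes, %d dendritic tips\n", nrow(x), tips
  ))
  NextMethod()
}

# parent row index (NA for root); assumes validated morphology
parent_row <- function(m) {
  pr <- match(m$parent_id, m$node_id)
  pr[m$parent_id == -1L] <- NA_integer_
  pr
}

is_dendrite <- function(structure) structure %in% c(3L, 4L)
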