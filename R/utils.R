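#' Derive a child random seed from a root seed and a label
#'
#' Every stochastic routine in dendropop draws from its own seeded stream so
#' that populations are reproducible and independent of generation order: cell
#' `i` of a population is always grown from `derive_seed(base_seed, "cell<i>")`
#' no matter how the population is chunked. The derivation is a stable
#' polynomial byte hash, so it does not depend on R's RNG state.
#'
#' @param seed Integer root seed.
#' @param label Character label naming the purpose of the child stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "cell1")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483629 # largest prime below 2^31
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Euclidean norm of rows of a 3-column matrix
row_norm <- function(m) sqrt(rowSums(m^2))

# fast tibble constructor for internally validated columns
quick_tibble <- function(...) {
  cols <- list(...)
  tibble::new_tibble(cols, nrow = length(cols[[1L]]))
}
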