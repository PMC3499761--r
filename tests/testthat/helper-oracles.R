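# Independent brute-force oracles for morphometry and the KS statistic.
# Deliberately naive: explicit recursion and O(n^2) enumeration on small
# trees, sharing no code with the package's vectorised extractors.

oracle_children <- function(df) {
  lapply(df$node_id, function(id) df$node_id[df$parent_id == id])
}

oracle_emergent <- function(df) {
  # df: plain data frame with the seven SWC columns; assumes single soma root
  id2row <- function(id) which(df$node_id == id)
  dend <- df$structure %in% c(3, 4)
  kids <- lapply(df$node_id, function(id) {
    ch <- df$node_id[df$parent_id == id]
    ch[dend[vapply(ch, id2row, integer(1))]]
  })
  nkid <- lengths(kids)
  root_id <- df$node_id[df$parent_id == -1]
  pos <- function(id) unlist(df[id2row(id), c("x", "y", "z")])
  seg <- function(id) {
    p <- df$parent_id[id2row(id)]
    sqrt(sum((pos(id) - pos(p))^2))
  }
  tips <- df$node_id[dend & nkid[match(df$node_id, df$node_id)] == 0]
  bifs <- df$node_id[dend & nkid >= 2]

  total <- sum(vapply(df$node_id[dend], seg, double(1)))

  # surface: frusta; soma-anchored segments use the child's radius both ends
  area <- 0
  for (id in df$node_id[dend]) {
    i <- id2row(id)
    p <- id2row(df$parent_id[i])
    r2 <- df$radius[i]
    r1 <- if (df$structure[p] == 1) r2 else df$radius[p]
    h <- seg(id)
    area <- area + pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2)
  }

  # root-to-node path as list of ids
  path_to <- function(id) {
    out <- id
    while (df$parent_id[id2row(id)] != -1) {
      id <- df$parent_id[id2row(id)]
      out <- c(id, out)
    }
    out
  }
  path_len <- function(id) {
    p <- path_to(id)
    sum(vapply(p[-1], seg, double(1)))
  }
  tip_paths <- vapply(tips, path_len, double(1))
  tip_euc <- vapply(tips, function(t) sqrt(sum((pos(t) - pos(root_id))^2)), double(1))

  # branch order of the branch containing a tip = number of bifurcation
  # nodes strictly on the root->tip path (excluding the tip itself)
  tip_order <- vapply(tips, function(t) {
    p <- path_to(t)
    sum(p[-length(p)] %in% bifs)
  }, double(1))

  # partition asymmetry over binary bifurcations
  count_tips_below <- function(id) {
    ch <- kids[[id2row(id)]]
    if (!length(ch)) {
      return(1L)
    }
    sum(vapply(ch, count_tips_below, integer(1)))
  }
  pa_terms <- c()
  for (b in bifs) {
    ch <- kids[[id2row(b)]]
    if (length(ch) == 2) {
      l <- count_tips_below(ch[1])
      r <- count_tips_below(ch[2])
      pa_terms <- c(pa_terms, if (l + r == 2) 0 else abs(l - r) / (l + r - 2))
    }
  }

  txy <- 0
  tz <- 0
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      a <- pos(tips[i])
      b <- pos(tips[j])
      txy <- max(txy, sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2))
      tz <- max(tz, abs(a[3] - b[3]))
    }
  }

  list(
    total_dendritic_length = total,
    n_bifurcations = sum(pmax(nkid[dend & nkid >= 2] - 1, 0)),
    surface_area = area,
    avg_path_to_tips = mean(tip_paths),
    avg_euclidean_to_tips = mean(tip_euc),
    max_euclidean_to_tips = max(tip_euc),
    max_branch_order = max(tip_order),
    partition_asymmetry = if (length(pa_terms)) mean(pa_terms) else 0,
    transverse_spread = txy,
    longitudinal_spread = tz
  )
}

# random binary tree with soma root, <= max_nodes nodes, random geometry
random_tree <- function(max_nodes = 30, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(
      node_id = 1L, structure = 1L, x = 0, y = 0, z = 0,
      radius = 4, parent_id = -1L
    )
    n_stems <- sample(1:2, 1)
    grow_tips <- c()
    for (s in seq_len(n_stems)) {
      df <- rbind(df, data.frame(
        node_id = nrow(df) + 1L, structure = 3L,
        x = rnorm(1, 0, 5), y = runif(1, 5, 15), z = rnorm(1, 0, 5),
        radius = runif(1, 1, 2), parent_id = 1L
      ))
      grow_tips <- c(grow_tips, nrow(df))
    }
    while (nrow(df) < max_nodes - 1 && length(grow_tips)) {
      t_id <- sample(grow_tips, 1)
      grow_tips <- setdiff(grow_tips, t_id)
      n_child <- sample(c(1, 1, 2), 1) # bias toward continuation nodes
      if (nrow(df) + n_child > max_nodes) break
      for (k in seq_len(n_child)) {
        df <- rbind(df, data.frame(
          node_id = nrow(df) + 1L, structure = 3L,
          x = df$x[t_id] + rnorm(1, 0, 4),
          y = df$y[t_id] + runif(1, 2, 10),
          z = df$z[t_id] + rnorm(1, 0, 4),
          radius = max(0.2, df$radius[t_id] * runif(1, 0.6, 1)),
          parent_id = df$node_id[t_id]
        ))
        grow_tips <- c(grow_tips, nrow(df))
      }
    }
    df
  })
}

# brute-force two-sample KS statistic: max ECDF gap over all sample points
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), double(1))))
}

# brute-force Rall power by fine grid + refinement
oracle_rall <- function(d0, d1, d2) {
  f <- function(n) d1^n + d2^n - d0^n
  grid <- seq(0.5, 5, by = 1e-4)
  vals <- f(grid)
  i <- which(diff(sign(vals)) != 0)
  if (!length(i)) {
    return(NA_real_)
  }
  uniroot(f, c(grid[i[1]], grid[i[1] + 1]), tol = 1e-10)$root
}

# a hand-built Y-tree: soma, stem with an inline node, bifurcation, two tips
y_tree <- function() {
  as_morphology(data.frame(
    node_id = 1:6,
    structure = c(1, 3, 3, 3, 3, 3),
    x = c(0, 0, 0, 0, -30, 40),
    y = c(0, 20, 40, 60, 100, 90),
    z = 0,
    radius = c(5, 1.5, 1.4, 1.3, 0.8, 0.7),
    parent_id = c(-1, 1, 2, 3, 4, 4)
  ))
}
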