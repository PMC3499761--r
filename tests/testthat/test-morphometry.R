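test_that("branch decomposition merges continuation nodes and orders branches", {
  # unbranched 3-node stem: one terminal branch of order 0
  stem <- read_swc(c("1 1 0 0 0 5 -1", "2 3 0 10 0 1 1", "3 3 0 20 0 1 2"))
  br <- decompose_branches(stem)
  expect_equal(nrow(br), 1L)
  expect_equal(br$branch_order, 0L)

  # stem with an in-line degree-2 node before one bifurcation: 3 branches
  br <- decompose_branches(y_tree())
  expect_equal(nrow(br), 3L)
  expect_equal(sort(br$kind), c("internal", "terminal", "terminal"))
  expect_equal(sort(br$branch_order), c(0L, 1L, 1L))
  internal <- br[br$kind == "internal", ]
  expect_equal(internal$path_length, 60) # 20 + 20 + 20, inline node merged
  expect_equal(lengths(internal$nodes), 3L)

  # every dendritic node belongs to exactly one branch
  expect_setequal(unlist(br$nodes), 2:6)

  # soma-only morphology: zero branches, not an error
  soma <- as_morphology(data.frame(
    node_id = 1, structure = 1, x = 0, y = 0, z = 0, radius = 5, parent_id = -1
  ))
  expect_equal(nrow(decompose_branches(soma)), 0L)
})

test_that("basic parameters come out as the defining raw measurements", {
  b <- extract_basic(y_tree())
  val <- function(p) b$value[b$parameter == p]
  expect_equal(val("n_stems"), 1)
  expect_equal(val("soma_diameter"), 10)
  expect_equal(val("stem_initial_diameter"), 3) # 2 * 1.5
  expect_equal(val("internal_path_length"), 60)
  expect_equal(sort(val("terminal_diameter")), c(1.4, 1.6))
  expect_equal(val("daughter_diameter_ratio"), 1.6 / 1.4)
  # constant-diameter tree: zero taper everywhere
  stem <- read_swc(c("1 1 0 0 0 5 -1", "2 3 0 10 0 1 1", "3 3 0 20 0 1 2"))
  expect_equal(extract_basic(stem)$value[
    extract_basic(stem)$parameter == "taper_rate"
  ], 0)
  # two stems
  two <- as_morphology(data.frame(
    node_id = 1:3, structure = c(1, 3, 3), x = c(0, 10, -10), y = c(0, 10, 10),
    z = 0, radius = c(5, 1, 1), parent_id = c(-1, 1, 1)
  ))
  bb <- extract_basic(two)
  expect_equal(bb$value[bb$parameter == "n_stems"], 2)
})

test_that("the Rall power solver matches an independent root finder", {
  # equal daughters d = d0 * 2^(-1/n): 1.5874 = 2 * 2^(-1/3) gives n = 3,
  # and 1.2599 = 2 * 2^(-2/3) gives n = 1.5
  n_hat <- dendropop:::solve_rall(2, 1.5874, 1.5874)
  expect_equal(n_hat, oracle_rall(2, 1.5874, 1.5874), tolerance = 1e-6)
  expect_equal(n_hat, 3.0, tolerance = 1e-3)
  expect_equal(dendropop:::solve_rall(2, 1.2599, 1.2599), 1.5, tolerance = 1e-3)
  # randomised agreement with the oracle
  for (s in 1:20) {
    withr::with_seed(s, {
      d0 <- runif(1, 1, 3)
      n_true <- runif(1, 0.8, 3)
      r <- runif(1, 1, 1.8)
      d2 <- d0 / (1 + r^n_true)^(1 / n_true)
      d1 <- r * d2
      expect_equal(dendropop:::solve_rall(d0, d1, d2), n_true, tolerance = 1e-6)
    })
  }
  # daughter thicker than parent: no solution, recorded NA with a warning
  expect_true(is.na(dendropop:::solve_rall(1, 1.2, 0.8)))
  fat <- as_morphology(data.frame(
    node_id = 1:5, structure = c(1, 3, 3, 3, 3),
    x = c(0, 0, 0, -10, 10), y = c(0, 10, 20, 30, 30), z = 0,
    radius = c(5, 1, 1, 1.2, 0.4), parent_id = c(-1, 1, 2, 3, 3)
  ))
  expect_warning(b <- extract_basic(fat), "Rall")
  expect_true(is.na(b$value[b$parameter == "rall_power"]))
})

test_that("emergent parameters reproduce hand-computable cases", {
  # two straight 100 um stems: additivity of total length
  two <- as_morphology(data.frame(
    node_id = 1:3, structure = c(1, 3, 3), x = 0, y = c(0, 100, -100),
    z = 0, radius = c(5, 1, 1), parent_id = c(-1, 1, 1)
  ))
  expect_equal(extract_emergent(two)$total_dendritic_length, 200)

  # single cylinder d = 2, L = 10: area 2 pi r L = 20 pi
  cyl <- as_morphology(data.frame(
    node_id = 1:2, structure = c(1, 3), x = 0, y = c(0, 10), z = 0,
    radius = c(5, 1), parent_id = c(-1, 1)
  ))
  expect_equal(extract_emergent(cyl)$surface_area, 20 * pi)

  # perfectly symmetric 4-tip tree: partition asymmetry 0
  sym4 <- as_morphology(data.frame(
    node_id = 1:8, structure = c(1, rep(3, 7)),
    x = c(0, 0, -20, 20, -30, -10, 10, 30),
    y = c(0, 20, 40, 40, 60, 60, 60, 60),
    z = 0, radius = c(5, 2, 1.5, 1.5, 1, 1, 1, 1),
    parent_id = c(-1, 1, 2, 2, 3, 3, 4, 4)
  ))
  expect_equal(extract_emergent(sym4)$partition_asymmetry, 0)

  # 5-tip caterpillar: bifurcations split (1,4), (1,3), (1,2), (1,1); the
  # first three score 1 and the deepest (two sibling tips) scores 0 by the
  # degenerate-case convention, so the mean is 3/4
  cat5 <- as_morphology(data.frame(
    node_id = 1:10, structure = c(1, rep(3, 9)),
    x = c(0, 0, -10, 5, -10, 10, -10, 15, 5, 25),
    y = c(0, 10, 20, 20, 30, 30, 40, 40, 50, 50),
    z = 0, radius = c(5, 2, 1, 1.8, 1, 1.6, 1, 1.4, 1, 1),
    parent_id = c(-1, 1, 2, 2, 4, 4, 6, 6, 8, 8)
  ))
  expect_equal(extract_emergent(cat5)$partition_asymmetry, 0.75)
  expect_equal(extract_emergent(cat5)$n_bifurcations, 4)

  # spreads from tips at (0,0,0), (3,4,0), (0,0,7)
  spread <- as_morphology(data.frame(
    node_id = 1:5, structure = c(1, 3, 3, 3, 3),
    x = c(0, 1, 0, 3, 0), y = c(0, 1, 0, 4, 0), z = c(0, 1, 0, 0, 7),
    radius = c(5, 1, 0.9, 0.8, 0.8), parent_id = c(-1, 1, 2, 2, 2)
  ))
  em <- extract_emergent(spread)
  expect_equal(em$transverse_spread, 5)
  expect_equal(em$longitudinal_spread, 7)

  # no dendritic tips: an error
  soma <- as_morphology(data.frame(
    node_id = 1, structure = 1, x = 0, y = 0, z = 0, radius = 5, parent_id = -1
  ))
  expect_error(extract_emergent(soma), "tips")
})

test_that("all ten emergent parameters match a brute-force oracle on random trees", {
  for (s in 1:12) {
    df <- random_tree(max_nodes = 30, seed = s)
    em <- extract_emergent(as_morphology(df))
    oracle <- oracle_emergent(df)
    for (p in names(oracle)) {
      expect_equal(em[[p]], oracle[[p]], tolerance = 1e-9,
        info = sprintf("parameter %s, tree seed %d", p, s)
      )
    }
  }
})

test_that("structural invariants hold on generated morphologies", {
  pop <- generate_population(granule_archetype()$params, 20, base_seed = 99)
  em <- extract_emergent(pop)
  # triangle inequality between path and Euclidean tip distances
  expect_true(all(em$avg_euclidean_to_tips <= em$avg_path_to_tips + 1e-9))
  expect_true(all(em$partition_asymmetry >= 0 & em$partition_asymmetry <= 1))
  for (i in seq_len(nrow(pop))) {
    m <- pop$morphology[[i]]
    br <- decompose_branches(m)
    # partition conservation: branch lengths sum to segment lengths
    pr <- match(m$parent_id, m$node_id)
    seg <- sqrt((m$x - m$x[pr])^2 + (m$y - m$y[pr])^2 + (m$z - m$z[pr])^2)
    expect_equal(sum(br$path_length), sum(seg[m$structure == 3L]), tolerance = 1e-9)
    # Euler relation per stem for binary trees
    n_tips <- sum(br$kind == "terminal")
    n_stems <- sum(br$branch_order == 0L)
    expect_equal(em$n_bifurcations[i], n_tips - n_stems)
  }
})
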