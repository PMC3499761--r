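# all-constant parameter set used by the degenerate-contract tests
constant_params <- function(threshold = 5, n_stems = 2, term_len = 100) {
  growth_params(
    soma_diameter = dist_spec("constant", value = 10),
    n_stems = dist_spec("constant", value = n_stems),
    stem_initial_diameter = dist_spec("constant", value = 2.5),
    taper_rate = dist_spec("constant", value = 0.001),
    internal_path_length = dist_spec("constant", value = 50),
    terminal_path_length = dist_spec("constant", value = term_len),
    rall_power = dist_spec("constant", value = 1.5),
    daughter_diameter_ratio = dist_spec("constant", value = 1.3),
    bifurcation_amplitude = dist_spec("constant", value = 40),
    terminal_diameter_threshold = dist_spec("constant", value = threshold)
  )
}

test_that("a threshold above the stem diameter forces single terminal branches", {
  m <- grow_neuron(constant_params(threshold = 5, n_stems = 3, term_len = 100), seed = 1)
  br <- decompose_branches(m)
  expect_equal(nrow(br), 3L)
  expect_true(all(br$kind == "terminal"))
  expect_equal(extract_emergent(m)$total_dendritic_length, 3 * 100)
})

test_that("growth is byte-for-byte deterministic in (params, seed)", {
  p <- granule_archetype()$params
  expect_identical(write_swc(grow_neuron(p, 123)), write_swc(grow_neuron(p, 123)))
  expect_false(identical(write_swc(grow_neuron(p, 123)), write_swc(grow_neuron(p, 124))))
})

test_that("generated bifurcations satisfy the Rall relation at the drawn power", {
  # constant Rall power and ratio: every measured bifurcation must solve to
  # exactly those values, and the relation must hold to 1e-6 relative error
  p <- constant_params(threshold = 0.8)
  m <- grow_neuron(p, seed = 5)
  b <- extract_basic(m)
  rall <- b$value[b$parameter == "rall_power"]
  ratio <- b$value[b$parameter == "daughter_diameter_ratio"]
  expect_gt(length(rall), 3)
  expect_equal(rall, rep(1.5, length(rall)), tolerance = 1e-6)
  expect_equal(ratio, rep(1.3, length(ratio)), tolerance = 1e-9)

  # explicit residual check on measured diameters, stochastic parameters
  m2 <- grow_neuron(granule_archetype()$params, seed = 6)
  ann <- dendropop:::annotate_nodes(dendropop:::pop_nodes(m2))
  bif <- dendropop:::bifurcation_table(ann)
  n_hat <- dendropop:::solve_rall(bif$parent_diameter, bif$d1, bif$d2)
  resid <- abs(bif$d1^n_hat + bif$d2^n_hat - bif$parent_diameter^n_hat) /
    bif$parent_diameter^n_hat
  expect_true(all(resid < 1e-6))
})

test_that("measured directly-drawn values equal the drawn constants", {
  p <- constant_params(threshold = 0.8)
  b <- extract_basic(grow_neuron(p, seed = 11))
  val <- function(par) b$value[b$parameter == par]
  expect_equal(unique(val("soma_diameter")), 10)
  expect_equal(unique(val("stem_initial_diameter")), 2.5)
  expect_equal(val("internal_path_length"), rep(50, length(val("internal_path_length"))))
  expect_equal(val("terminal_path_length"), rep(100, length(val("terminal_path_length"))))
  expect_equal(val("taper_rate"), rep(0.001, length(val("taper_rate"))), tolerance = 1e-12)
  expect_equal(val("bifurcation_amplitude"),
    rep(40, length(val("bifurcation_amplitude"))),
    tolerance = 1e-9
  )
})

test_that("population generation is chunk-independent and validates throughout", {
  p <- granule_archetype()$params
  all10 <- generate_population(p, 10, base_seed = 77)
  first5 <- generate_population(p, 5, base_seed = 77)
  expect_identical(
    lapply(all10$morphology[1:5], as.data.frame),
    lapply(first5$morphology, as.data.frame)
  )
  for (m in all10$morphology) {
    expect_silent(validate_morphology(m))
    expect_silent(extract_emergent(m))
  }
  # orders never exceed the guard
  em <- extract_emergent(all10)
  expect_true(all(em$max_branch_order <= p$max_branch_order))
})

test_that("stems start inside the elevation cone about +y", {
  p <- granule_archetype()$params
  pop <- generate_population(p, 25, base_seed = 13)
  for (m in pop$morphology) {
    stems <- m[m$parent_id == 1L & m$structure == 3L, ]
    dirs <- cbind(stems$x, stems$y, stems$z)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    angles <- acos(pmin(1, dirs[, 2])) * 180 / pi
    expect_true(all(angles <= p$stem_elevation_cone + 1e-9))
  }
})

test_that("a hard order guard stops runaway recursion", {
  p <- constant_params(threshold = 0) # never terminal by diameter
  p$max_branch_order <- 4L
  m <- grow_neuron(p, seed = 2)
  br <- decompose_branches(m)
  expect_equal(max(br$branch_order), 4L)
  expect_gt(attr(m, "log")$order_guard_hits, 0)
})

test_that("measured internal path lengths track the input distribution", {
  # KS between measured internal lengths and fresh draws from the input
  # spec, over 20 seeded population runs: expect at least 18/20 with p > 0.05
  p <- granule_archetype()$params
  spec <- p$internal_path_length
  pvals <- vapply(1:20, function(s) {
    pop <- generate_population(p, 30, base_seed = 1000 + s)
    b <- extract_basic(pop)
    x <- b$value[b$parameter == "internal_path_length"]
    ks_two_sample(x, sample_dist(spec, length(x), seed = 5000 + s))$p_value
  }, double(1))
  expect_gte(sum(pvals > 0.05), 18)
})
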