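# build a synthetic emergent table (rows = cells) around given means/sds
synthetic_emergent <- function(n, means, sds, seed = 1) {
  withr::with_seed(seed, {
    out <- tibble::tibble(cell = seq_len(n))
    for (p in names(means)) {
      out[[p]] <- rnorm(n, means[p], sds[p])
    }
    out
  })
}

emergent_names <- c(
  "total_dendritic_length", "n_bifurcations", "surface_area",
  "avg_path_to_tips", "avg_euclidean_to_tips", "max_euclidean_to_tips",
  "max_branch_order", "partition_asymmetry", "transverse_spread",
  "longitudinal_spread"
)

reference_criteria <- function(seed = 3) {
  means <- setNames(c(3500, 15, 9000, 350, 330, 500, 4, 0.3, 450, 400), emergent_names)
  sds <- setNames(c(700, 4, 1800, 60, 60, 80, 1, 0.08, 90, 80), emergent_names)
  filter_criteria(synthetic_emergent(40, means, sds, seed = seed))
}

test_that("filter criteria default to 2 SD with 1.65 SD for surface area", {
  crit <- reference_criteria()
  expect_equal(crit$width[crit$parameter == "surface_area"], 1.65)
  expect_equal(unique(crit$width[crit$parameter != "surface_area"]), 2.0)
  expect_true(all(crit$reference_sd > 0))
})

test_that("the acceptance window is inclusive at exactly width * sd", {
  crit <- reference_criteria()
  mid <- setNames(crit$reference_mean, crit$parameter)
  at_mean <- tibble::as_tibble(c(list(cell = 1L), as.list(mid)))
  expect_true(filter_emergent(at_mean, crit)$accepted)

  i <- which(crit$parameter == "total_dendritic_length")
  edge <- at_mean
  edge$total_dendritic_length <- crit$reference_mean[i] + 2.0 * crit$reference_sd[i]
  expect_true(filter_emergent(edge, crit)$accepted)
  over <- at_mean
  over$total_dendritic_length <- crit$reference_mean[i] + 2.001 * crit$reference_sd[i]
  res <- filter_emergent(over, crit)
  expect_false(res$accepted)
  expect_equal(res$failed_parameters, "total_dendritic_length")
})

test_that("filtering is idempotent and order-independent", {
  crit <- reference_criteria()
  pool <- synthetic_emergent(500,
    setNames(crit$reference_mean, crit$parameter),
    setNames(crit$reference_sd, crit$parameter),
    seed = 8
  )
  once <- filter_emergent(pool, crit)
  again <- filter_emergent(once[names(pool)], crit)
  expect_equal(once$accepted, again$accepted)
  shuffled <- filter_emergent(pool[rev(seq_len(nrow(pool))), ], crit)
  expect_equal(rev(shuffled$accepted), once$accepted)
})

test_that("single-parameter windows retain the theoretical normal coverage", {
  n <- 100000
  x <- withr::with_seed(21, rnorm(n))
  em <- tibble::tibble(cell = seq_len(n), total_dendritic_length = x)
  crit2 <- tibble::tibble(
    parameter = "total_dendritic_length",
    reference_mean = 0, reference_sd = 1, width = 2.0
  )
  frac2 <- mean(filter_emergent(em, crit2)$accepted)
  expect_gt(frac2, 0.95)
  expect_equal(frac2, 2 * pnorm(2) - 1, tolerance = 0.005)
  crit165 <- crit2
  crit165$width <- 1.65
  frac165 <- mean(filter_emergent(em, crit165)$accepted)
  expect_gt(frac165, 0.90)
  expect_equal(frac165, 2 * pnorm(1.65) - 1, tolerance = 0.005)
})

test_that("matching returns the whole pool when n_out equals the pool size", {
  crit <- reference_criteria()
  targets <- target_distributions(crit)
  pool <- tibble::tibble(
    cell = 1:400,
    total_dendritic_length = sample_target(targets$total_dendritic_length, 400, seed = 1),
    surface_area = sample_target(targets$surface_area, 400, seed = 2),
    n_bifurcations = sample_target(targets$n_bifurcations, 400, seed = 3)
  )
  sel <- match_target_distributions(pool, targets, n_out = 400, seed = 9)
  expect_equal(sel$cell, pool$cell)
})

test_that("matching is deterministic, bounded by the pool, and error-checked", {
  crit <- reference_criteria()
  targets <- target_distributions(crit)
  pool <- tibble::tibble(
    cell = 1:2000,
    total_dendritic_length = withr::with_seed(1, rnorm(2000, 3500, 1100)),
    surface_area = withr::with_seed(2, rnorm(2000, 9000, 2600)),
    n_bifurcations = withr::with_seed(3, rpois(2000, 15))
  )
  s1 <- match_target_distributions(pool, targets, 300, seed = 4)
  s2 <- match_target_distributions(pool, targets, 300, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1$cell %in% pool$cell))
  expect_error(match_target_distributions(pool, targets, 3000, seed = 1), "exceeds")

  off <- dplyr::mutate(pool, total_dendritic_length = total_dendritic_length + 50000)
  expect_error(match_target_distributions(off, targets, 100, seed = 1), "no support")
})

test_that("matched marginals are KS-indistinguishable from their targets", {
  # wide generator pool, targets well inside its support
  crit <- reference_criteria()
  targets <- target_distributions(crit)
  pool <- tibble::tibble(
    cell = seq_len(50000),
    total_dendritic_length = withr::with_seed(11, rnorm(50000, 3500, 950)),
    surface_area = withr::with_seed(12, rnorm(50000, 9000, 2400)),
    n_bifurcations = withr::with_seed(13, rpois(50000, 15))
  )
  sel <- match_target_distributions(pool, targets, 10000, seed = 5)
  for (p in c("total_dendritic_length", "surface_area")) {
    ref <- sample_target(targets[[p]], 10000, seed = 100 + nchar(p))
    expect_gt(ks_two_sample(sel[[p]], ref)$p_value, 0.05)
  }
  # discrete parameter: compare the truncated-Poisson pmf by chi-square-free
  # total variation distance rather than KS (ties)
  tv <- {
    obs <- table(factor(sel$n_bifurcations, levels = 0:60)) / nrow(sel)
    expc <- ddist(targets$n_bifurcations, 0:60)
    sum(abs(obs - expc / sum(expc))) / 2
  }
  expect_lt(tv, 0.05)
})

test_that("the matched population's marginals recover reference-derived targets over seeds", {
  # reference-recovery at reduced size: pools of 8000, selections of 1500,
  # repeated over 20 seeds; expect >= 18/20 runs with all marginal p > 0.05
  crit <- reference_criteria()
  targets <- target_distributions(crit)
  ok <- vapply(1:20, function(s) {
    pool <- tibble::tibble(
      cell = seq_len(8000),
      total_dendritic_length = withr::with_seed(200 + s, rnorm(8000, 3500, 950)),
      surface_area = withr::with_seed(400 + s, rnorm(8000, 9000, 2400)),
      n_bifurcations = withr::with_seed(600 + s, rpois(8000, 15))
    )
    sel <- match_target_distributions(pool, targets, 1500, seed = 800 + s)
    p1 <- ks_two_sample(
      sel$total_dendritic_length,
      sample_target(targets$total_dendritic_length, 1500, seed = 900 + s)
    )$p_value
    p2 <- ks_two_sample(
      sel$surface_area,
      sample_target(targets$surface_area, 1500, seed = 950 + s)
    )$p_value
    p1 > 0.05 && p2 > 0.05
  }, logical(1))
  expect_gte(sum(ok), 18)
})
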