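# Minimum-variance path solver: movement rules, metrics, solvers, oracle.

test_that("neighbors implement the bounded separation change with clipping", {
  rule <- move_rule()
  n1 <- neighbors(c(1L, 1L), rule, c(30L, 17L))
  expect_equal(unname(n1),
               cbind(rep(2L, 4), 1:4))  # -2..0 clipped at column 1
  n2 <- neighbors(c(5L, 17L), rule, c(30L, 17L))
  expect_equal(unname(n2), cbind(rep(6L, 3), 15:17))
  expect_equal(nrow(neighbors(c(30L, 9L), rule, c(30L, 17L))), 0L)
  expect_error(neighbors(c(0L, 1L), rule, c(30L, 17L)), "outside")
})

test_that("mean step energy telescopes from the endpoints", {
  expect_equal(mean_step_energy(0, 29, 29), 1)
  expect_equal(mean_step_energy(5, 5, 29), 0)
  expect_equal(mean_step_energy(5, -24, 29), -1)
  expect_error(mean_step_energy(0, 1, 0), "n_steps")
})

test_that("edge weight is the squared deviation from the mean step", {
  expect_equal(edge_weight(0, 1, 1), 0)
  expect_equal(edge_weight(0, 3, 1), 4)
  set.seed(3)
  for (i in 1:20) {
    e <- rnorm(2); m <- rnorm(1)
    expect_gte(edge_weight(e[1], e[2], m), 0)
  }
  expect_equal(edge_weight(0, Inf, 1), Inf)
})

test_that("path variance and total climb match hand calculations", {
  expect_equal(path_variance(c(0, 1, 2, 3)), 0)
  expect_equal(path_variance(c(0, 1, 3)), 0.5)
  expect_equal(path_variance(c(5, 5, 5, 5)), 0)
  expect_error(path_variance(3), "at least 2")
  expect_equal(total_climb(c(5, 4, 3)), 0)
  expect_equal(total_climb(c(0, 2, 1, 3)), 4)
  expect_equal(total_climb(c(1, 1, 1)), 0)
})

test_that("flat and ramp matrices give zero-variance fixed-column paths", {
  flat <- energy_matrix(matrix(2, 30, 17))
  p <- smoothest_path(flat)
  expect_equal(p$metrics$variance, 0)
  expect_equal(nrow(p$steps), 30L)

  ramp <- energy_matrix(matrix(rep(seq(0, -29), 17), 30, 17))
  pr <- smoothest_path(ramp)
  expect_equal(pr$steps$sep_index, rep(1L, 30))
  expect_equal(pr$metrics$variance, 0)
  expect_equal(pr$weight, 0)
})

test_that("the returned path is feasible and its metrics are consistent", {
  for (seed in 1:10) {
    m <- rand_matrix(30, 17, seed = seed)
    p <- smoothest_path(m)
    expect_equal(p$steps$rot_index, 1:30)
    expect_true(all(diff(p$steps$sep_index) %in% (-2:3)))
    expect_equal(p$steps$sep_index[c(1, 30)], c(1L, 1L))
    # telescoping: steps sum exactly to the endpoint difference
    expect_equal(sum(diff(p$energies)), p$energies[30] - p$energies[1])
    # reported variance is the sample variance of the step changes
    expect_equal(p$metrics$variance, stats::var(diff(p$energies)))
    # weight = (n - 1) * variance for the variance objective (n = 29 steps)
    expect_equal(p$weight, 28 * p$metrics$variance, tolerance = 1e-9)
    # never worse than the fixed-column path
    fixed_sigma2 <- stats::var(diff(unclass(m)[, 1]))
    expect_lte(p$metrics$variance, fixed_sigma2 + 1e-12)
    # max_barrier / total_climb invariants
    expect_gte(p$metrics$total_climb,
               max(0, p$energies[30] - p$energies[1]))
    expect_gte(p$metrics$max_barrier, 0)
  }
})

test_that("adding a constant to the matrix changes nothing returned", {
  m <- rand_matrix(12, 8, seed = 42)
  m2 <- energy_matrix(unclass(m) + 1000,
                      rot_axis = attr(m, "rot_axis"),
                      sep_axis = attr(m, "sep_axis"))
  p1 <- smoothest_path(m)
  p2 <- smoothest_path(m2)
  expect_equal(p1$steps$sep_index, p2$steps$sep_index)
  expect_equal(p1$weight, p2$weight, tolerance = 1e-7)
  expect_equal(p1$metrics$variance, p2$metrics$variance, tolerance = 1e-9)
})

test_that("label-setting and layered DP agree node for node", {
  for (seed in 1:25) {
    m <- rand_matrix(sample(5:30, 1), sample(3:17, 1), seed = 1000 + seed)
    a <- smoothest_path(m, method = "dijkstra")
    b <- smoothest_path(m, method = "dp")
    expect_identical(a$steps$sep_index, b$steps$sep_index)
    expect_identical(a$weight, b$weight)
  }
})

test_that("the exhaustive oracle counts feasible paths correctly", {
  # 2 rows: only the direct start->goal step exists
  m2 <- rand_matrix(2, 3, seed = 1)
  bf <- brute_force_smoothest(m2, move_rule())
  expect_equal(bf$feasible_path_count, 1L)
  # goal out of reach of the step rule -> infeasible
  expect_error(brute_force_smoothest(m2, move_rule(sep_deltas = 0L,
                                                   goal_sep = 3L)),
               "no feasible path")
  # 3 rows x 2 columns: routes via (2,1) and (2,2)
  m3 <- rand_matrix(3, 2, seed = 2)
  bf3 <- brute_force_smoothest(m3, move_rule())
  expect_equal(bf3$feasible_path_count, 2L)
  # size guard
  expect_error(brute_force_smoothest(rand_matrix(11, 3, seed = 3)),
               "too large")
})

test_that("solver matches the exhaustive oracle on random small grids", {
  for (seed in 1:60) {
    rows <- sample(3:6, 1)
    cols <- sample(2:5, 1)
    m <- rand_matrix(rows, cols, seed = 2000 + seed)
    goal <- sample(seq_len(cols), 1)
    rule <- move_rule(goal_sep = goal)
    bf <- brute_force_smoothest(m, rule)
    dj <- smoothest_path(m, rule)
    expect_identical(dj$weight, bf$weight)
    expect_identical(dj$steps$sep_index, bf$path$steps$sep_index)
  }
})

test_that("variance and squared-step objectives pick the same paths", {
  # the two edge definitions differ by a path-independent constant
  for (seed in 1:30) {
    m <- rand_matrix(sample(4:8, 1), sample(3:6, 1), seed = 3000 + seed)
    a <- smoothest_path(m, objective = "variance")
    b <- smoothest_path(m, objective = "squared")
    expect_identical(a$steps$sep_index, b$steps$sep_index)
    n <- nrow(m) - 1L
    mbar <- (a$energies[nrow(m)] - a$energies[1]) / n
    expect_equal(b$weight - a$weight, n * mbar^2, tolerance = 1e-8)
  }
})

test_that("masked nodes are infeasible and can block all routes", {
  v <- matrix(0, 4, 3)
  v[2, ] <- NA  # an impassable rotation row
  m <- energy_matrix(v)
  expect_error(smoothest_path(m), "no feasible path")
  # masking only part of a row forces a detour
  v2 <- matrix(0, 4, 3)
  v2[2, 1] <- Inf
  v2[3, 1] <- 5
  p <- smoothest_path(energy_matrix(v2))
  expect_false(p$steps$sep_index[2] == 1)
  # masked start is an error
  v3 <- matrix(0, 3, 2); v3[1, 1] <- NA
  expect_error(smoothest_path(energy_matrix(v3)), "masked")
})

test_that("tie-breaking is deterministic and prefers small column moves", {
  flat <- energy_matrix(matrix(0, 6, 5))
  p1 <- smoothest_path(flat)
  p2 <- smoothest_path(flat, method = "dp")
  expect_equal(p1$steps$sep_index, rep(1L, 6))
  expect_equal(p2$steps$sep_index, rep(1L, 6))
})

test_that("path report validates, serializes and round-trips", {
  m <- rand_matrix(30, 17, seed = 7)
  p <- smoothest_path(m)
  rep <- path_report(p, m)
  expect_equal(nrow(rep$steps), 30L)
  expect_equal(sum(!is.na(rep$steps$dE)), 29L)
  stem <- withr::local_tempfile()
  files <- write_path_report(rep, stem)
  expect_true(all(file.exists(files)))
  back <- jsonlite::read_json(files[["json"]], simplifyVector = TRUE)
  expect_equal(back$steps$sep_index, rep$steps$sep_index)
  expect_equal(back$metrics$variance, rep$metrics$variance,
               tolerance = 1e-12)
  tsv <- utils::read.delim(files[["tsv"]])
  expect_equal(nrow(tsv), 30L)
  # a report on a mismatched matrix is rejected
  expect_error(path_report(p, rand_matrix(30, 17, seed = 8)),
               "do not match")
  expect_error(path_report(p, rand_matrix(12, 17, seed = 7)), "shape")
})
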