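make_traj <- function(x, y, id = "c1", area = NA_real_, flags = character()) {
  trajectory(id, time = seq(0, by = 30, length.out = length(x)), x = x,
             y = y, area = area, flags = flags)
}

test_that("distance metrics match hand values and brute-force summation", {
  tr <- make_traj(c(0, 3, 3), c(0, 0, 4))
  expect_equal(accumulated_distance(tr), 7)
  expect_equal(euclidean_distance(tr), 5)
  expect_equal(directness(tr), 5 / 7)

  still <- make_traj(rep(2, 6), rep(-1, 6))
  expect_equal(accumulated_distance(still), 0)
  expect_equal(euclidean_distance(still), 0)
  expect_true(is.na(directness(still)))  # 0/0 reported missing, not 0 or 1

  loop <- make_traj(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(euclidean_distance(loop), 0)
  expect_equal(directness(loop), 0)

  set.seed(101)
  rnd <- random_trajectory("r", n = 201)
  expect_equal(accumulated_distance(rnd), oracle_path_length(rnd$x, rnd$y),
               tolerance = 1e-9)

  expect_error(accumulated_distance(make_traj(0, 0)), "insufficient")
  expect_error(euclidean_distance(make_traj(0, 0)), "insufficient")
})

test_that("euclidean <= accumulated on every 3-step unit lattice path, equal iff straight", {
  steps <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    xy <- rbind(c(0, 0), steps[[i]], steps[[j]], steps[[k]])
    xy <- apply(xy, 2, cumsum)
    tr <- make_traj(xy[, 1], xy[, 2])
    acc <- accumulated_distance(tr)
    euc <- euclidean_distance(tr)
    expect_lte(euc, acc + 1e-12)
    straight <- (i == j && j == k)
    expect_equal(isTRUE(all.equal(euc, acc)), straight)
  }
})

test_that("metrics are invariant under translation and rotation and match their definition", {
  set.seed(7)
  for (rep in 1:20) {
    tr <- random_trajectory(paste0("r", rep))
    acc <- accumulated_distance(tr)
    euc <- euclidean_distance(tr)
    expect_equal(directness(tr), euc / acc, tolerance = 1e-12)
    th <- runif(1, 0, 2 * pi)
    rot <- make_traj(cos(th) * tr$x - sin(th) * tr$y + 13,
                     sin(th) * tr$x + cos(th) * tr$y - 5)
    expect_equal(accumulated_distance(rot), acc, tolerance = 1e-9)
    expect_equal(euclidean_distance(rot), euc, tolerance = 1e-9)
  }
})

test_that("translate_to_origin zeroes starts and leaves displacements intact", {
  tr <- make_traj(c(5, 8, 8), c(5, 5, 9))
  set <- trajectory_set(list(tr))
  out <- translate_to_origin(set)
  t1 <- out$trajectories[[1]]
  expect_equal(c(t1$x[1], t1$y[1]), c(0, 0))
  expect_equal(diff(t1$x), diff(tr$x))
  expect_equal(accumulated_distance(t1), accumulated_distance(tr))
  expect_equal(euclidean_distance(t1), euclidean_distance(tr))
  # identity on an already-origin trajectory; empty sets pass through
  at0 <- trajectory_set(list(make_traj(c(0, 1), c(0, 1))))
  expect_identical(translate_to_origin(at0), at0)
  empty <- trajectory_set(list())
  expect_equal(length(translate_to_origin(empty)), 0)
})

test_that("exclusion filtering removes flagged cells, warns when empty, and is idempotent", {
  trs <- c(lapply(1:7, function(i) make_traj(c(0, i), c(0, 0),
                                             id = paste0("ok", i))),
           lapply(1:3, function(i) make_traj(c(0, i), c(0, 0),
                                             id = paste0("bad", i),
                                             flags = "divided")))
  set <- trajectory_set(trs)
  kept <- suppressMessages(apply_exclusions(set))
  expect_equal(length(kept), 7)
  expect_equal(attr(kept, "n_excluded"), 3)
  again <- apply_exclusions(kept)
  expect_equal(attr(again, "n_excluded"), 0)
  expect_identical(again$trajectories, kept$trajectories)
  allbad <- trajectory_set(list(make_traj(c(0, 1), c(0, 0),
                                          flags = "apoptosed")))
  expect_warning(suppressMessages(apply_exclusions(allbad)), "empty")
})

test_that("metric-vs-area regression matches the closed-form OLS oracle", {
  set.seed(33)
  areas <- c(120, 340, 560, 800, 1500)
  trs <- lapply(seq_along(areas), function(i) {
    tr <- random_trajectory(paste0("c", i))
    tr$area <- areas[i]
    tr
  })
  set <- trajectory_set(trs)
  fit <- regress_metric_vs_area(set, "euclidean")
  eu <- vapply(trs, euclidean_distance, numeric(1))
  ora <- oracle_ols(areas, eu)
  expect_equal(fit$slope, ora$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, ora$intercept, tolerance = 1e-9)
  expect_equal(fit$r_squared, ora$r_squared, tolerance = 1e-9)

  # metric exactly linear in area -> R^2 = 1
  lin <- lapply(seq_along(areas), function(i) {
    make_traj(c(0, 2 + 0.01 * areas[i]), c(0, 0), id = paste0("l", i),
              area = areas[i])
  })
  expect_equal(regress_metric_vs_area(trajectory_set(lin),
                                      "euclidean")$r_squared, 1,
               tolerance = 1e-9)

  same <- lapply(1:4, function(i) {
    tr <- random_trajectory(paste0("s", i)); tr$area <- 100; tr
  })
  expect_error(regress_metric_vs_area(trajectory_set(same), "euclidean"),
               "degenerate")
  expect_error(regress_metric_vs_area(trajectory_set(trs[1:2]), "euclidean"),
               "insufficient")
})

test_that("trajectory containers validate their invariants", {
  expect_error(trajectory("a", c(0, 0), c(1, 2), c(1, 2)), "increasing")
  expect_error(trajectory("a", c(0, 30), c(1, 2), c(1, 2), area = -5),
               "area")
  expect_error(trajectory("a", c(0, 30), c(1, 2), c(1, 2), flags = "weird"),
               "flag")
  dup <- list(make_traj(c(0, 1), c(0, 1), id = "x"),
              make_traj(c(0, 2), c(0, 2), id = "x"))
  expect_error(trajectory_set(dup), "unique")
})
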