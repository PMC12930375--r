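test_that("identical series align along the diagonal at zero cost", {
  set.seed(2)
  a <- matrix(rnorm(30), 10, 3)
  r <- dtw(a, a)
  expect_equal(r$cost, 0)
  expect_equal(r$normalized_cost, 0)
  expect_equal(r$path, cbind(1:10, 1:10))
})

test_that("the classic stretch example and its path are recovered", {
  r <- dtw(c(0, 0, 1), c(0, 1))
  expect_equal(r$cost, 0)
  expect_equal(r$path, rbind(c(1, 1), c(2, 1), c(3, 2)))
})

test_that("dtw cost equals exhaustive path enumeration on random short pairs", {
  set.seed(11)
  for (case in 1:220) {
    d <- sample(1:2, 1)
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    a <- matrix(rnorm(n * d), n, d)
    b <- matrix(rnorm(m * d), m, d)
    r <- dtw(a, b)
    expect_equal(r$cost, oracle_dtw_cost(a, b), tolerance = 1e-12)
    # path validity: endpoints and admissible monotone steps
    expect_equal(r$path[1, ], c(1, 1), ignore_attr = TRUE)
    expect_equal(r$path[nrow(r$path), ], c(n, m), ignore_attr = TRUE)
    steps <- diff(r$path)
    expect_true(all(steps >= 0 & steps <= 1 & rowSums(steps) >= 1))
    # symmetry in cost
    expect_equal(dtw(b, a)$cost, r$cost, tolerance = 1e-12)
    expect_lte(r$normalized_cost, r$cost + 1e-12)
  }
})

test_that("dtw_from_cost matches dtw on its induced local-cost matrix", {
  set.seed(5)
  a <- matrix(rnorm(12), 6, 2); b <- matrix(rnorm(10), 5, 2)
  M <- as.matrix(dist(rbind(a, b)))[1:6, 7:11]
  expect_equal(dtw_from_cost(M)$cost, dtw(a, b)$cost, tolerance = 1e-12)
  expect_equal(dtw_from_cost(matrix(0, 4, 7))$cost, 0)
  # 2x2 with cheap diagonal: enumerate the three admissible paths by hand
  expect_equal(dtw_from_cost(rbind(c(0, 5), c(5, 0)))$cost, 0)
  expect_error(dtw_from_cost(rbind(c(0, -1), c(1, 0))), "non-negative")
})

test_that("aligning against a time-dilated copy stretches the shorter series at zero cost", {
  set.seed(6)
  a <- matrix(rnorm(16), 8, 2)
  dilated <- a[rep(1:8, each = 2), ]        # every frame duplicated
  r <- dtw(a, dilated)
  expect_equal(r$cost, 0)
  expect_equal(nrow(r$path), 16)            # short series visits each row twice
  expect_true(all(table(r$path[, 1]) == 2))
})

test_that("normalization divisors follow the configured convention", {
  a <- matrix(c(0, 0, 3), 3, 1); b <- matrix(c(0, 1), 2, 1)
  r_path <- dtw(a, b, normalization = "path")
  r_max <- dtw(a, b, normalization = "max")
  r_sum <- dtw(a, b, normalization = "sum")
  expect_equal(r_path$normalized_cost, r_path$cost / nrow(r_path$path))
  expect_equal(r_max$normalized_cost, r_max$cost / 3)
  expect_equal(r_sum$normalized_cost, r_sum$cost / 5)
  expect_error(dtw(matrix(1, 2, 2), matrix(1, 2, 3)), "dimension mismatch")
})

test_that("DBA fixed points: single series and identical replicas", {
  set.seed(14)
  a <- matrix(rnorm(24), 12, 2)
  one <- dba_barycenter(list(a))
  expect_equal(one$barycenter, a)
  expect_equal(tail(one$objective_trace, 1), 0)
  same <- dba_barycenter(list(a, a, a))
  expect_equal(same$barycenter, a)
  expect_equal(tail(same$objective_trace, 1), 0)
  expect_equal(unname(same$normalized_costs), c(0, 0, 0))
})

test_that("two constant series average to the constant midpoint", {
  x <- matrix(0, 10, 1); y <- matrix(2, 10, 1)
  b <- dba_barycenter(list(x, y))
  expect_equal(b$barycenter, matrix(1, 10, 1))
})

test_that("DBA objective trace is non-increasing on random inputs", {
  set.seed(19)
  for (case in 1:8) {
    k <- sample(2:4, 1)
    series <- lapply(seq_len(k), function(i)
      matrix(rnorm(sample(8:15, 1) * 2), ncol = 2))
    b <- dba_barycenter(series)
    expect_true(all(diff(b$objective_trace) <= 1e-9))
    # every barycenter index has at least one associated frame per replica
    for (as in b$association)
      expect_true(all(lengths(as) >= 1L))
  }
})

test_that("nothing is pruned when replicas are identical", {
  a <- matrix(rnorm(20), 10, 2)
  pr <- prune_outliers(list(r1 = a, r2 = a, r3 = a, r4 = a))
  expect_equal(nrow(pr$report$removed), 0L)
  expect_setequal(pr$report$kept, c("r1", "r2", "r3", "r4"))
})

test_that("fixed-count pruning removes exactly the worst replica", {
  set.seed(23)
  base <- matrix(rnorm(30), 15, 2)
  wiggle <- function() base + matrix(rnorm(30, sd = 0.05), 15, 2)
  series <- list(r1 = wiggle(), r2 = wiggle(), r3 = wiggle(),
                 out = base + 3)
  pr <- prune_outliers(series, rule = "count", count = 1)
  expect_equal(pr$report$removed$replica_id, "out")
  expect_setequal(pr$report$kept, c("r1", "r2", "r3"))
})

test_that("the gap rule prunes a planted outlier replica first", {
  spec <- generator_spec(n_systems = 1, replicas_per_system = 5,
                         n_frames = 150, n_residues = 40,
                         states = matrix(runif(160, 0.2, 0.8), 80, 2),
                         boundaries = 75L,
                         outlier = list(system = 1, replica = 3,
                                        effect_size = 0.4),
                         flip_noise = 0.02, warp_roughness = 0.3, seed = 41)
  ens <- generate_ensemble(spec)
  v <- build_vocabulary(ens$tables)
  occ <- lapply(ens$tables, function(t) to_occupancy(t, v))
  f <- filter_edges(occ, lower_cutoff = 0.1)
  emb <- embed_ensembles(f$series, embedding_config(seed = 4))
  names(emb) <- names(ens$tables)
  pr <- prune_outliers(emb)
  expect_gte(nrow(pr$report$removed), 1L)
  expect_equal(pr$report$removed$replica_id[1], ens$truth$outlier)
})
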