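test_that("pairwise matrix is symmetric, zero-diagonal, and matches dtw()", {
  set.seed(3)
  series <- lapply(1:4, function(i) matrix(rnorm(20), 10, 2))
  series[[4]] <- series[[1]]                 # duplicated series
  dm <- pairwise_dtw_matrix(series)
  M <- dm$matrix
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 4), ignore_attr = TRUE)
  expect_equal(M[1, 4], 0)                   # duplicates at distance zero
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(M[i, j], dtw(series[[i]], series[[j]])$normalized_cost)
})

test_that("Ward linkage matches the Lance-Williams textbook recurrence", {
  set.seed(17)
  for (case in 1:20) {
    n <- 8
    pts <- matrix(rnorm(n * 3), n)
    M <- as.matrix(dist(pts))
    tree <- ward_linkage(M)
    ref <- oracle_ward(M)
    expect_equal(tree$height, ref$height, tolerance = 1e-9)
    expect_equal(tree$merge, ref$merge)
  }
  expect_error(ward_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("a two-point matrix merges at its distance-derived height", {
  tree <- ward_linkage(rbind(c(0, 3), c(3, 0)))
  expect_length(tree$height, 1L)
  expect_equal(tree$height, 3)
})

test_that("two tight triplets far apart split at the top of the tree", {
  pts <- rbind(matrix(rnorm(9, sd = 0.05), 3),
               matrix(rnorm(9, sd = 0.05) + 10, 3))
  M <- as.matrix(dist(pts))
  rownames(M) <- colnames(M) <- paste0("p", 1:6)
  tree <- ward_linkage(M)
  sol <- select_k(tree, "largest-gap")
  expect_equal(sol$k, 2L)
  expect_equal(length(unique(sol$assignment[1:3])), 1L)
  expect_equal(length(unique(sol$assignment[4:6])), 1L)
  expect_false(sol$assignment[1] == sol$assignment[4])
})

test_that("largest-gap reads the height profile as specified", {
  tree <- structure(list(
    merge = rbind(c(-1L, -2L), c(-3L, 1L), c(-4L, -5L), c(2L, 3L)),
    height = c(0.1, 0.12, 0.11, 3.0),
    order = 1:5, labels = paste0("r", 1:5), method = "ward.D2"),
    class = "hclust")
  expect_equal(select_k(tree, "largest-gap")$k, 2L)
})

test_that("equal merge heights fall back to k = 1 with a warning", {
  tree <- structure(list(
    merge = rbind(c(-1L, -2L), c(-3L, 1L), c(-4L, 2L)),
    height = c(1, 1, 1), order = 1:4, labels = paste0("r", 1:4),
    method = "ward.D2"), class = "hclust")
  expect_warning(sol <- select_k(tree, "largest-gap"), "k = 1")
  expect_equal(sol$k, 1L)
})

test_that("elbow criterion picks maximum curvature of the height profile", {
  # heights rise gently then jump: curvature peaks at the jump
  tree <- structure(list(
    merge = rbind(c(-1L, -2L), c(-3L, 1L), c(-4L, 2L), c(-5L, 3L),
                  c(-6L, 4L)),
    height = c(0.1, 0.2, 0.3, 2.0, 2.1), order = 1:6,
    labels = paste0("r", 1:6), method = "ward.D2"), class = "hclust")
  # curvature h[i+1] - 2 h[i] + h[i-1] peaks at merge 3 (before the jump),
  # so the cut falls between merges 3 and 4: R - 3 = 3 clusters
  expect_equal(select_k(tree, "elbow")$k, 3L)
})

test_that("clustering is invariant to replica input order up to relabeling", {
  set.seed(29)
  mk <- function(center) mdsync:::new_embedding_series(
    matrix(rnorm(30, mean = center, sd = 0.1), 15, 2),
    paste0("r", center, sample.int(1000, 1)))
  series <- c(lapply(c(0, 0, 0), mk), lapply(c(5, 5, 5), mk))
  dm1 <- pairwise_dtw_matrix(series)
  sol1 <- select_k(ward_linkage(dm1), "largest-gap")
  perm <- c(4, 1, 5, 2, 6, 3)
  dm2 <- pairwise_dtw_matrix(series[perm])
  sol2 <- select_k(ward_linkage(dm2), "largest-gap")
  expect_equal(sol1$k, sol2$k)
  a1 <- sol1$assignment[names(sol2$assignment)]
  expect_equal(oracle_ari(a1, sol2$assignment), 1.0)
})

test_that("RMSD cost matrix vanishes for self and rigid-motion copies", {
  set.seed(31)
  frame <- matrix(rnorm(15), 5, 3)
  expect_equal(rmsd_cost_matrix(list(frame), list(frame))[1, 1], 0,
               tolerance = 1e-8)
  theta <- 0.7
  Rz <- rbind(c(cos(theta), -sin(theta), 0),
              c(sin(theta), cos(theta), 0),
              c(0, 0, 1))
  moved <- frame %*% t(Rz) + matrix(c(3, -2, 7), 5, 3, byrow = TRUE)
  expect_equal(rmsd_cost_matrix(list(frame), list(moved))[1, 1], 0,
               tolerance = 1e-8)
  expect_error(rmsd_cost_matrix(list(frame), list(frame[1:4, ])),
               "atom-count")
})

test_that("RMSD matches an independent quaternion superposition oracle", {
  set.seed(37)
  for (case in 1:10) {
    A <- matrix(rnorm(12), 4, 3)
    B <- A
    B[1, ] <- B[1, ] + runif(3, -2, 2)     # displace one atom
    expect_equal(rmsd_cost_matrix(list(A), list(B))[1, 1],
                 oracle_rmsd(A, B), tolerance = 1e-6)
  }
  # full matrix over toy trajectories
  trajA <- lapply(1:3, function(i) matrix(rnorm(12), 4, 3))
  trajB <- lapply(1:4, function(i) matrix(rnorm(12), 4, 3))
  M <- rmsd_cost_matrix(trajA, trajB)
  expect_equal(dim(M), c(3L, 4L))
  expect_equal(M[2, 3], oracle_rmsd(trajA[[2]], trajB[[3]]), tolerance = 1e-6)
})

test_that("k-medoids with silhouette recovers a clean two-group split", {
  set.seed(41)
  pts <- rbind(matrix(rnorm(10, sd = 0.01), 5, 2),
               matrix(rnorm(10, sd = 0.01) + 8, 5, 2))
  M <- as.matrix(dist(pts))
  rownames(M) <- colnames(M) <- paste0("r", 1:10)
  sol <- kmedoids_with_silhouette(M, k_range = 2:5)
  expect_equal(sol$k, 2L)
  expect_equal(length(unique(sol$assignment[1:5])), 1L)
  expect_false(sol$assignment[1] == sol$assignment[6])
})

test_that("silhouette-based k choice matches exhaustive evaluation", {
  set.seed(43)
  pts <- rbind(matrix(rnorm(8, sd = 0.3), 4, 2),
               matrix(rnorm(8, sd = 0.3) + 4, 4, 2),
               matrix(rnorm(8, sd = 0.3) + c(8, 0), 4, 2))
  M <- as.matrix(dist(pts))
  sol <- kmedoids_with_silhouette(M, k_range = 2:6)
  widths <- vapply(2:6, function(k) {
    asg <- cluster::pam(as.dist(M), k = k, diss = TRUE)$clustering
    oracle_mean_silhouette(M, asg)
  }, numeric(1))
  expect_equal(sol$k, (2:6)[which.max(widths)])
  expect_equal(unname(attr(sol, "silhouette")), widths, tolerance = 1e-12)
})

test_that("distance matrix and dendrogram exports are readable", {
  set.seed(47)
  series <- lapply(1:4, function(i)
    mdsync:::new_embedding_series(matrix(rnorm(20, mean = i), 10, 2),
                                  paste0("r", i)))
  dm <- pairwise_dtw_matrix(series)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".nwk")
  write_dist_matrix(dm, p1)
  back <- read.table(p1, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), dm$matrix, ignore_attr = TRUE,
               tolerance = 1e-15)
  write_newick(ward_linkage(dm), p2)
  tree <- ape::read.tree(p2)
  expect_setequal(tree$tip.label, paste0("r", 1:4))
})
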