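test_that("edgeless graphs yield documents determined by node labels alone", {
  g <- list(nodes = c("a", "b", "c"), labels = c("A:ALA:1", "A:GLY:2", "A:ALA:1"),
            edges = matrix(integer(0), ncol = 2))
  doc <- wl_relabel(g, k = 2)
  expect_length(doc$tokens, 9L)             # (k+1) * n tokens
  expect_equal(doc$tokens[1:3], g$labels)   # iteration 0 = initial labels
  # empty neighborhoods: each iteration digests the node's own label only,
  # so equal labels give equal tokens at every iteration and distinct
  # labels stay distinct
  for (it in 1:2) {
    tok <- doc$tokens[it * 3 + 1:3]
    expect_identical(tok[1], tok[3])
    expect_false(tok[1] == tok[2])
  }
})

test_that("WL documents are invariant under isomorphic relabeling of node ids", {
  set.seed(7)
  for (rep in 1:50) {
    g <- random_graph(sample(4:9, 1), runif(1, 0.2, 0.7))
    n <- length(g$nodes)
    perm <- sample.int(n)
    g2 <- list(nodes = g$nodes,
               labels = g$labels[order(perm)],
               edges = matrix(perm[g$edges], ncol = 2))
    d1 <- sort(wl_relabel(g, 3)$tokens)
    d2 <- sort(wl_relabel(g2, 3)$tokens)
    expect_identical(d1, d2)
  }
})

test_that("WL documents are invariant to edge-list permutation and orientation", {
  set.seed(13)
  g <- random_graph(8, 0.4)
  g2 <- g
  g2$edges <- g$edges[sample.int(nrow(g$edges)), 2:1, drop = FALSE]
  expect_identical(sort(wl_relabel(g, 3)$tokens), sort(wl_relabel(g2, 3)$tokens))
})

test_that("WL separates a path from a triangle at iteration 1", {
  path <- list(labels = c("X", "X", "X"),
               edges = rbind(c(1L, 2L), c(2L, 3L)))
  tri <- list(labels = c("X", "X", "X"),
              edges = rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)))
  dp <- wl_relabel(path, 1)$tokens
  dt <- wl_relabel(tri, 1)$tokens
  expect_identical(dp[1:3], dt[1:3])            # iteration 0 identical
  expect_false(identical(sort(dp[4:6]), sort(dt[4:6])))
  # hand-run: triangle nodes all digest "X|X,X"; path ends digest "X|X"
  expect_equal(length(unique(dt[4:6])), 1L)
  expect_equal(length(unique(dp[4:6])), 2L)
})

test_that("corpus extraction and per-graph documents agree", {
  lines <- c("0\thb\tA:ALA:1:CB\tA:GLY:5:CA",
             "1\thb\tA:GLY:5:CA\tA:VAL:9:CB",
             "1\tvdw\tA:ALA:1:CB\tA:VAL:9:CB")
  occ <- to_occupancy(tab <- parse_contact_table(lines, "r"),
                      build_vocabulary(tab))
  nodes <- mdsync:::vocab_nodes(occ$vocab)
  ends <- mdsync:::vocab_edge_ends(occ$vocab, nodes)
  corpus <- mdsync:::cpp_wl_corpus(nodes, ends, occ$matrix, 3L)
  gs <- to_frame_graphs(occ)
  for (f in seq_along(gs)) {
    ids <- corpus$tokens[(corpus$offsets[f] + 1):corpus$offsets[f + 1]]
    expect_identical(corpus$vocab[ids + 1L], wl_relabel(gs[[f]], 3)$tokens)
  }
})

test_that("training is deterministic and respects the configured dimensions", {
  set.seed(21)
  docs <- lapply(1:12, function(i) wl_relabel(random_graph(6, 0.5), 2))
  cfg <- embedding_config(dimensions = 16, epochs = 10, min_token_count = 1,
                          seed = 5)
  m1 <- train_embeddings(docs, cfg)
  m2 <- train_embeddings(docs, cfg)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(12L, 16L))
  m3 <- train_embeddings(docs, embedding_config(dimensions = 8, epochs = 10,
                                                min_token_count = 1, seed = 5))
  expect_equal(ncol(m3), 8L)
})

test_that("duplicated documents embed closer than random document pairs", {
  set.seed(31)
  base <- lapply(1:25, function(i) wl_relabel(random_graph(10, 0.4), 2))
  docs <- c(base, base)                      # 25 duplicated pairs
  m <- train_embeddings(docs, embedding_config(epochs = 60,
                                               min_token_count = 1, seed = 2))
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  dup_sim <- vapply(1:25, function(i) cosine(m[i, ], m[i + 25, ]), numeric(1))
  rnd_sim <- vapply(1:200, function(i) {
    ij <- sample.int(25, 2)
    cosine(m[ij[1], ], m[ij[2] + 25, ])
  }, numeric(1))
  expect_gt(mean(dup_sim), mean(rnd_sim))
})

test_that("embedding clouds separate two contact regimes", {
  # two regimes differing in >= 20 edges; between-centroid distance must
  # exceed the mean within-regime spread
  set.seed(77)
  n_edges <- 40
  pA <- runif(n_edges, 0.1, 0.9)
  pB <- pA
  pB[1:20] <- 1 - pB[1:20]
  mk <- function(p, n) vapply(p, function(q) rbinom(n, 1, q), integer(n))
  keys <- paste0("A:R:1--A:R:", 2:(n_edges + 1))
  vocab <- structure(data.frame(res_a = "A:R:1",
                                res_b = paste0("A:R:", 2:(n_edges + 1)),
                                key = keys, stringsAsFactors = FALSE),
                     class = c("edge_vocab", "data.frame"))
  sA <- mdsync:::new_occupancy_series(mk(pA, 60), vocab, "A")
  sB <- mdsync:::new_occupancy_series(mk(pB, 60), vocab, "B")
  emb <- embed_ensembles(list(sA, sB),
                         embedding_config(epochs = 40, min_token_count = 2,
                                          seed = 9))
  cA <- colMeans(emb[[1]]$matrix); cB <- colMeans(emb[[2]]$matrix)
  between <- sqrt(sum((cA - cB)^2))
  spread <- mean(c(sqrt(rowSums(sweep(emb[[1]]$matrix, 2, cA)^2)),
                   sqrt(rowSums(sweep(emb[[2]]$matrix, 2, cB)^2))))
  expect_gt(between, spread)
})

test_that("PCA reduction honors subspace structure and variance targets", {
  set.seed(3)
  # points exactly in a 2-d affine subspace of 16-d
  basis <- qr.Q(qr(matrix(rnorm(32), 16, 2)))
  X <- matrix(rnorm(200), 100, 2) %*% t(basis) +
    matrix(5, 100, 16)
  s <- mdsync:::new_embedding_series(X, "r1")
  red <- reduce_pca(list(s), 0.90)
  expect_lte(ncol(red[[1]]$matrix), 2L)

  Y <- matrix(rnorm(100 * 16), 100, 16)
  s2 <- mdsync:::new_embedding_series(Y, "r2")
  full <- reduce_pca(list(s2), 1.0)
  expect_equal(ncol(full[[1]]$matrix), 16L)
  expect_error(reduce_pca(list(s2), 0), "\\(0, 1\\]")

  # reconstruction error equals the sum of discarded eigenvalues
  red2 <- reduce_pca(list(s2), 0.6)
  d <- ncol(red2[[1]]$matrix)
  ev <- eigen(cov(Y), symmetric = TRUE, only.values = TRUE)$values
  centered <- sweep(Y, 2, colMeans(Y))
  resid <- sum(centered^2) - sum(red2[[1]]$matrix^2)
  expect_equal(resid / (nrow(Y) - 1), sum(ev[-seq_len(d)]), tolerance = 1e-8)
})

test_that("embeddings round-trip exactly through the TSV table", {
  set.seed(8)
  s1 <- mdsync:::new_embedding_series(matrix(rnorm(48), 3), "r1", "sysA")
  s2 <- mdsync:::new_embedding_series(matrix(rnorm(64), 4), "r2", "sysA")
  path <- tempfile(fileext = ".tsv")
  write_embeddings(list(s1, s2), path)
  back <- read_embeddings(path)
  expect_equal(back[[1]]$matrix, s1$matrix, ignore_attr = TRUE)
  expect_equal(back[[2]]$matrix, s2$matrix, ignore_attr = TRUE)
  expect_equal(back[[2]]$replica_id, "r2")
})
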