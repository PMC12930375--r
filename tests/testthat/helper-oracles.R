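# Independent oracles used across the suite. Each reimplements the quantity
# under test from first principles (enumeration, textbook recurrences, or a
# different algebraic route) and never calls the package's production path.

# --- exhaustive DTW: minimum summed local cost over all admissible warp
# paths, by recursion over the path lattice (feasible for n, m <= ~7) -------
oracle_dtw_cost <- function(a, b) {
  a <- if (is.null(dim(a))) matrix(a, ncol = 1) else a
  b <- if (is.null(dim(b))) matrix(b, ncol = 1) else b
  n <- nrow(a); m <- nrow(b)
  lc <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  memo <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 1 && j == 1) lc(1, 1) else {
      best <- Inf
      if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
      if (i > 1) best <- min(best, rec(i - 1, j))
      if (j > 1) best <- min(best, rec(i, j - 1))
      best + lc(i, j)
    }
    memo[[key]] <- val
    val
  }
  rec(n, m)
}

# enumerate every admissible warp path for tiny lattices (start (1,1), end
# (n,m), unit steps); returns list of 2-col matrices
oracle_enumerate_paths <- function(n, m) {
  out <- list()
  grow <- function(path) {
    tip <- path[nrow(path), ]
    if (tip[1] == n && tip[2] == m) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (step in list(c(1, 1), c(1, 0), c(0, 1))) {
      nxt <- tip + step
      if (nxt[1] <= n && nxt[2] <= m) grow(rbind(path, nxt))
    }
  }
  grow(matrix(c(1, 1), 1))
  out
}

# --- exact optimal partitioning (unpruned O(n^2) dynamic program) for the
# penalized mean-shift segmentation -----------------------------------------
oracle_segment <- function(x, beta) {
  n <- length(x)
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  segcost <- function(a, b) s2[b + 1] - s2[a + 1] - (s1[b + 1] - s1[a + 1])^2 / (b - a)
  F <- c(-beta, rep(Inf, n))
  prev <- integer(n + 1)
  for (t in 1:n) {
    cand <- 0:(t - 1)
    costs <- F[cand + 1] + vapply(cand, segcost, numeric(1), b = t) + beta
    best <- which.min(costs)
    F[t + 1] <- costs[best]
    prev[t + 1] <- cand[best]
  }
  cps <- integer(0); t <- n
  while (t > 0) { tau <- prev[t + 1]; if (tau > 0) cps <- c(tau, cps); t <- tau }
  list(changepoints = cps, objective = F[n + 1])
}

# --- textbook Lance-Williams agglomeration for Ward's criterion on squared
# dissimilarities (heights reported on the original scale) -------------------
oracle_ward <- function(M) {
  n <- nrow(M)
  D <- M^2
  sizes <- rep(1, n)
  active <- 1:n
  id <- -(1:n)                       # hclust convention: negatives = leaves
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (s in 1:(n - 1)) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) for (jj in seq_along(active)) if (ii < jj) {
      i <- active[ii]; j <- active[jj]
      if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights[s] <- sqrt(best[1])
    pair <- c(id[i], id[j])
    # hclust merge convention: singletons by observation index, before
    # composite clusters; composites by formation order
    merges[s, ] <- if (all(pair < 0)) -sort(-pair) else sort(pair)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) if (k != i && k != j) {
      nk <- sizes[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    id[i] <- s
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}

# --- quaternion-based least-RMSD superposition (Horn's method), an
# independent route to the Kabsch result -------------------------------------
oracle_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- t(B) %*% A
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[1, 3] + M[3, 1]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# --- mean silhouette width computed directly from its definition ------------
oracle_mean_silhouette <- function(M, assignment) {
  n <- nrow(M)
  s <- numeric(n)
  for (i in 1:n) {
    own <- assignment == assignment[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(M[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(assignment), assignment[i]),
                    function(cl) mean(M[i, assignment == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# --- adjusted Rand index between two labelings ------------------------------
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sij <- choose2(as.vector(tab))
  si <- choose2(rowSums(tab)); sj <- choose2(colSums(tab))
  n2 <- choose2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# small random labelled graph as a frame_graph-style list
random_graph <- function(n_nodes, p_edge, labels = NULL) {
  pairs <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  sel <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  list(nodes = as.character(seq_len(n_nodes)),
       labels = labels %||% sprintf("L%d", sample.int(3, n_nodes, replace = TRUE)),
       edges = matrix(as.integer(sel), ncol = 2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
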