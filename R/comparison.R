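#' Pairwise normalized DTW distance matrix
#'
#' Computes the normalized dependent-DTW cost for every unordered pair of
#' series; the result is symmetric with a zero diagonal.
#'
#' @param series_list list (length `>= 2`) of matrices / `embedding_series`
#'   with a common dimension count.
#' @param normalization as in [dtw()].
#' @return a `dist_matrix`: list with `labels` (replica ids), `systems`
#'   (system ids or `NA`), and the symmetric numeric `matrix`.
#' @export
pairwise_dtw_matrix <- function(series_list, normalization = "path") {
  if (length(series_list) < 2L) stop("need at least two series")
  ids <- series_ids(series_list)
  systems <- vapply(series_list, function(s)
    if (inherits(s, "embedding_series")) s$system_id else NA_character_,
    character(1))
  mats <- lapply(series_list, as_series_matrix)
  R <- length(mats)
  M <- matrix(0, R, R, dimnames = list(ids, ids))
  for (i in seq_len(R - 1L)) for (j in seq.int(i + 1L, R)) {
    r <- cpp_dtw(mats[[i]], mats[[j]], FALSE)
    M[i, j] <- M[j, i] <- r$cost /
      norm_divisor(r$path, nrow(mats[[i]]), nrow(mats[[j]]), normalization)
  }
  structure(list(labels = ids, systems = unname(systems), matrix = M),
            class = "dist_matrix")
}

as_plain_matrix <- function(dm) {
  if (inherits(dm, "dist_matrix")) dm$matrix else as.matrix(dm)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix: %d series\n", length(x$labels)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion applied
#' to the (formally non-Euclidean) DTW distances, using the Lance-Williams
#' update on squared dissimilarities (the `ward.D2` convention).
#'
#' @param dist_matrix a `dist_matrix` or a symmetric numeric matrix.
#' @return an `hclust` tree with replica labels.
#' @export
ward_linkage <- function(dist_matrix) {
  M <- as_plain_matrix(dist_matrix)
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(M < 0)) stop("distance matrix must be non-negative")
  hclust(as.dist(M), method = "ward.D2")
}

new_cluster_solution <- function(k, assignment, criterion) {
  structure(list(k = as.integer(k), assignment = assignment,
                 criterion = criterion),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d (%s)\n", x$k, x$criterion))
  print(x$assignment)
  invisible(x)
}

#' Select the number of clusters from a linkage tree
#'
#' `"largest-gap"` places the cut where the difference between consecutive
#' merge heights is largest, giving the number of clusters present just
#' below that gap. `"elbow"` picks the cluster count at maximum curvature
#' (discrete second difference) of the merge-height profile; ties resolve
#' toward smaller `k`. If all merge heights are equal the tree carries no
#' cut information and `k = 1` is returned with a warning.
#'
#' @param tree an `hclust` object (see [ward_linkage()]).
#' @param method `"largest-gap"` or `"elbow"`.
#' @return a `cluster_solution` with `k`, the per-label `assignment`, and
#'   the criterion used.
#' @export
select_k <- function(tree, method = c("largest-gap", "elbow")) {
  method <- match.arg(method)
  h <- tree$height
  n_merge <- length(h)
  R <- n_merge + 1L
  if (n_merge < 2L) stop("need at least 2 merges to select k")
  if (diff(range(h)) <= max(abs(h), 1) * 1e-12) {
    warning("all merge heights equal; falling back to k = 1")
    return(new_cluster_solution(1L, structure(rep(1L, R), names = tree$labels),
                                method))
  }
  if (method == "largest-gap") {
    gaps <- diff(h)                       # gap after merge i, i = 1..n-1
    i_star <- which.max(gaps)             # cut between merge i* and i*+1
    k <- R - i_star
  } else {
    if (n_merge < 3L) stop("elbow criterion needs at least 3 merges")
    curv <- h[3:n_merge] - 2 * h[2:(n_merge - 1L)] + h[1:(n_merge - 2L)]
    # curvature at merge i (i = 2..n-1); ties toward smaller k = later merge
    i_star <- (2:(n_merge - 1L))[max(which(curv == max(curv)))]
    k <- R - i_star
  }
  k <- max(1L, min(k, R))
  assignment <- cutree(tree, k = k)
  new_cluster_solution(k, assignment, method)
}

#' Cut a linkage tree at a fixed cluster count
#' @param tree an `hclust` object.
#' @param k number of clusters.
#' @return a `cluster_solution` with criterion `"fixed"`.
#' @export
cut_k <- function(tree, k) {
  new_cluster_solution(k, cutree(tree, k = k), "fixed")
}

#' Pairwise frame Calpha-RMSD cost matrix
#'
#' For the geometric-descriptor baseline: entry `(i, j)` is the least RMSD
#' after optimal rigid-body superposition (Kabsch) of frame `i` of the first
#' trajectory onto frame `j` of the second. Feed the result to
#' [dtw_from_cost()] to obtain one inter-trajectory distance.
#'
#' @param coords_a,coords_b 3-D arrays `frames x atoms x 3` (or lists of
#'   `atoms x 3` matrices) with equal atom counts, `>= 3` atoms.
#' @return numeric `n x m` matrix of RMSD values in the input length unit.
#' @export
rmsd_cost_matrix <- function(coords_a, coords_b) {
  to_list <- function(x) {
    if (is.list(x)) lapply(x, as.matrix)
    else lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
  }
  A <- to_list(coords_a); B <- to_list(coords_b)
  if (nrow(A[[1]]) != nrow(B[[1]])) stop("atom-count mismatch")
  n_atoms <- nrow(A[[1]])
  if (n_atoms < 3L) stop("need at least 3 atoms per frame")
  xyz <- function(m) as.numeric(t(m))    # bio3d xyz vector layout
  inds <- seq_len(3L * n_atoms)
  M <- matrix(0, length(A), length(B))
  for (i in seq_along(A)) {
    ai <- xyz(A[[i]])
    for (j in seq_along(B)) {
      # superpose with bio3d, report the RMSD at full precision
      fitted <- bio3d::fit.xyz(ai, xyz(B[[j]]),
                               fixed.inds = inds, mobile.inds = inds)
      M[i, j] <- sqrt(sum((ai - fitted)^2) / n_atoms)
    }
  }
  M
}

#' K-medoids clustering with silhouette-based model selection
#'
#' Runs PAM k-medoids on the precomputed distance matrix for every `k` in
#' `k_range` and returns the solution maximizing the mean silhouette width
#' (ties toward smaller `k`). PAM's build/swap phases are deterministic, so
#' repeated runs agree.
#'
#' @param dist_matrix a `dist_matrix` or symmetric numeric matrix.
#' @param k_range integer candidate cluster counts, within
#'   `[2, n_series - 1]`.
#' @return a `cluster_solution` with criterion `"silhouette"`; attribute
#'   `silhouette` holds the mean silhouette width per candidate `k`.
#' @export
kmedoids_with_silhouette <- function(dist_matrix, k_range = NULL) {
  M <- as_plain_matrix(dist_matrix)
  R <- nrow(M)
  k_range <- k_range %||% seq.int(2L, R - 1L)
  if (any(k_range < 2L | k_range > R - 1L))
    stop("k_range must lie within [2, n_series - 1]")
  d <- as.dist(M)
  widths <- vapply(k_range, function(k)
    cluster::pam(d, k = k, diss = TRUE)$silinfo$avg.width, numeric(1))
  best <- k_range[which.max(widths)]
  fit <- cluster::pam(d, k = best, diss = TRUE)
  assignment <- fit$clustering
  names(assignment) <- rownames(M) %||% seq_len(R)
  out <- new_cluster_solution(best, assignment, "silhouette")
  attr(out, "silhouette") <- structure(widths, names = k_range)
  out
}

#' Write a distance matrix as TSV with header labels
#' @param dist_matrix a `dist_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(dist_matrix, path) {
  M <- as_plain_matrix(dist_matrix)
  df <- data.frame(id = rownames(M) %||% seq_len(nrow(M)),
                   apply(M, 2L, fmt_num), check.names = FALSE)
  names(df) <- c("id", colnames(M) %||% seq_len(ncol(M)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram in Newick text
#' @param tree an `hclust` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
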