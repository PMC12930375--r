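norm_divisor <- function(path, n, m, normalization) {
  switch(normalization,
         path = nrow(path),
         max = max(n, m),
         sum = n + m,
         stop("unknown normalization: ", normalization))
}

new_dtw_result <- function(cost, path, n, m, normalization) {
  structure(list(cost = cost,
                 normalized_cost = cost / norm_divisor(path, n, m, normalization),
                 path = path, normalization = normalization),
            class = "dtw_result")
}

#' Dependent multivariate dynamic time warping
#'
#' Classic DTW with the standard cumulative recurrence. The local cost
#' between two frames is the Euclidean distance over all dimensions jointly
#' (dependent DTW). The optimal warp path starts at `(1, 1)`, ends at
#' `(n, m)`, moves by diagonal/vertical/horizontal unit steps, and backtrace
#' ties are broken deterministically (diagonal, then vertical, then
#' horizontal).
#'
#' @param a,b numeric matrices (frames x dimensions, equal dimension count)
#'   or numeric vectors (treated as 1-dimensional series), or
#'   `embedding_series`.
#' @param normalization divisor for the normalized score: `"path"` (warp
#'   path length, the default; equals the series length for an equal-length
#'   diagonal path), `"max"` (`max(n, m)`), or `"sum"` (`n + m`).
#' @return a `dtw_result`: `cost` (sum of local distances along the optimal
#'   path), `normalized_cost`, `path` (2-column matrix of 1-based index
#'   pairs), `normalization`.
#' @export
dtw <- function(a, b, normalization = c("path", "max", "sum")) {
  normalization <- match.arg(normalization)
  a <- as_series_matrix(a); b <- as_series_matrix(b)
  if (ncol(a) != ncol(b)) stop("series dimension mismatch")
  if (nrow(a) < 1 || nrow(b) < 1) stop("series must have at least one frame")
  r <- cpp_dtw(a, b, FALSE)
  new_dtw_result(r$cost, r$path, nrow(a), nrow(b), normalization)
}

#' DTW over a precomputed local-cost matrix
#'
#' Applies the same cumulative recurrence and backtrace to an arbitrary
#' non-negative local-cost matrix, e.g. a pairwise frame RMSD matrix from
#' [rmsd_cost_matrix()] for the geometric-descriptor baseline.
#'
#' @param cost_matrix numeric `n x m` matrix of non-negative local costs.
#' @param normalization as in [dtw()].
#' @return a `dtw_result`.
#' @export
dtw_from_cost <- function(cost_matrix, normalization = c("path", "max", "sum")) {
  normalization <- match.arg(normalization)
  cost_matrix <- as.matrix(cost_matrix)
  if (any(cost_matrix < 0)) stop("local costs must be non-negative")
  r <- cpp_dtw_from_cost(cost_matrix)
  new_dtw_result(r$cost, r$path, nrow(cost_matrix), ncol(cost_matrix),
                 normalization)
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("DTW: cost %.6g, normalized %.6g (by %s), path length %d\n",
              x$cost, x$normalized_cost, x$normalization, nrow(x$path)))
  invisible(x)
}

# linear resampling of a series to L rows (per-dimension interpolation over
# the normalized index axis)
resample_series <- function(m, L) {
  n <- nrow(m)
  if (n == L) return(m)
  xout <- if (L == 1L) 0.5 else seq(0, 1, length.out = L)
  xin <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
  if (n == 1L) return(matrix(rep(m[1, ], each = L), nrow = L))
  apply(m, 2L, function(col) approx(xin, col, xout = xout, rule = 2)$y)
}

# association: for each barycenter index, the series rows matched by the path
path_association <- function(path, L) {
  assoc <- split(path[, 2L], factor(path[, 1L], levels = seq_len(L)))
  lapply(assoc, as.integer)
}

#' DTW barycenter averaging (DBA)
#'
#' Computes a consensus (barycenter) trajectory minimizing the average DTW
#' cost to all replicas while accommodating variable lengths. Each iteration
#' aligns every series to the current barycenter and replaces each barycenter
#' point by the mean of all frames associated to it. Alignment and the
#' monitored objective use squared-Euclidean local costs, for which the mean
#' update provably never increases the objective; the reported per-replica
#' scores are standard Euclidean-cost DTW results.
#'
#' @param series_list list of numeric matrices / `embedding_series` with a
#'   common dimension count.
#' @param init `"medoid"` (series with minimal summed DTW cost to the others,
#'   linearly resampled to the barycenter length) or `"first"`.
#' @param max_iter maximum refinement iterations.
#' @param tol stop when the relative objective decrease falls below `tol`.
#' @param normalization normalization mode for the reported replica scores.
#' @return a `dba_result`: `barycenter` (`L x D`, `L` = median series
#'   length), `results` (per-replica Euclidean `dtw_result` vs the
#'   barycenter), `normalized_costs` (named), `association` (per replica: a
#'   list mapping each barycenter index to contributing frame indices),
#'   `iterations_run`, `objective_trace` (non-increasing mean of per-series
#'   squared-cost DTW).
#' @export
dba_barycenter <- function(series_list, init = c("medoid", "first"),
                           max_iter = 30L, tol = 1e-6,
                           normalization = "path") {
  init <- match.arg(init)
  if (inherits(series_list, "embedding_series")) series_list <- list(series_list)
  if (length(series_list) == 0L) stop("need at least one series")
  ids <- series_ids(series_list)
  mats <- lapply(series_list, as_series_matrix)
  D <- unique(vapply(mats, ncol, integer(1)))
  if (length(D) != 1L) stop("series dimension mismatch")
  lens <- vapply(mats, nrow, integer(1))
  L <- as.integer(round(stats::median(lens)))

  bary <- if (init == "first" || length(mats) == 1L) {
    resample_series(mats[[1]], L)
  } else {
    costs <- matrix(0, length(mats), length(mats))
    for (i in seq_along(mats)) for (j in seq_along(mats)) if (i < j) {
      cc <- cpp_dtw(mats[[i]], mats[[j]], TRUE)$cost
      costs[i, j] <- costs[j, i] <- cc
    }
    resample_series(mats[[which.min(rowSums(costs))]], L)
  }

  trace <- numeric(0)
  assoc <- NULL
  for (iter in seq_len(max_iter)) {
    aligns <- lapply(mats, function(m) cpp_dtw(bary, m, TRUE))
    obj <- mean(vapply(aligns, `[[`, numeric(1), "cost"))
    trace <- c(trace, obj)
    assoc <- lapply(seq_along(mats), function(r)
      path_association(aligns[[r]]$path, L))
    sums <- matrix(0, L, D)
    counts <- numeric(L)
    for (r in seq_along(mats)) {
      p <- aligns[[r]]$path
      rs <- rowsum(mats[[r]][p[, 2L], , drop = FALSE], group = p[, 1L])
      sums[as.integer(rownames(rs)), ] <-
        sums[as.integer(rownames(rs)), , drop = FALSE] + rs
      counts <- counts + tabulate(p[, 1L], nbins = L)
    }
    new_bary <- sums / counts
    converged <- iter > 1L &&
      (trace[iter - 1L] - obj) <= tol * max(trace[iter - 1L], .Machine$double.eps)
    bary <- new_bary
    if (converged || obj == 0) break
  }
  # final alignment of the reported barycenter, Euclidean cost
  results <- lapply(seq_along(mats), function(r) {
    rr <- cpp_dtw(bary, mats[[r]], FALSE)
    new_dtw_result(rr$cost, rr$path, L, lens[r], normalization)
  })
  assoc <- lapply(results, function(rr) path_association(rr$path, L))
  names(results) <- names(assoc) <- ids
  ncosts <- vapply(results, `[[`, numeric(1), "normalized_cost")
  structure(list(barycenter = bary, results = results,
                 normalized_costs = ncosts, association = assoc,
                 ids = ids, iterations_run = length(trace),
                 objective_trace = trace),
            class = "dba_result")
}

#' @export
print.dba_result <- function(x, ...) {
  cat(sprintf("DBA consensus: length %d, %d replicas, %d iterations\n",
              nrow(x$barycenter), length(x$results), x$iterations_run))
  cat("normalized DTW costs to barycenter:\n")
  print(round(x$normalized_costs, 4))
  invisible(x)
}

#' Iteratively prune outlier replicas against the consensus
#'
#' Repeats: compute the barycenter of the surviving replicas, score each by
#' normalized DTW cost to it, and remove the worst replica while the stop
#' rule fires, recomputing after each removal. Stops when no removal fires
#' or only two replicas remain.
#'
#' Stop rules: `"gap"` (default, data-driven) removes the worst replica while
#' its cost exceeds the second worst by more than the mean adjacent gap of
#' the sorted costs; `"threshold"` removes while the worst normalized cost
#' exceeds `threshold`; `"count"` removes exactly `count` replicas.
#'
#' @param series_list list (length `>= 2`) of matrices / `embedding_series`.
#' @param rule `"gap"`, `"threshold"`, or `"count"`.
#' @param threshold normalized-cost threshold for `rule = "threshold"`.
#' @param count removals for `rule = "count"`.
#' @param normalization score normalization mode.
#' @param ... passed to [dba_barycenter()].
#' @return list with `report` (a `pruning_report`: `kept` ids, `removed`
#'   data.frame in removal order with the normalized cost at removal time)
#'   and `barycenter` (final `dba_result` over the kept replicas).
#' @export
prune_outliers <- function(series_list, rule = c("gap", "threshold", "count"),
                           threshold = NULL, count = NULL,
                           normalization = "path", ...) {
  rule <- match.arg(rule)
  if (length(series_list) < 2L) stop("need at least two replicas")
  if (rule == "threshold" && is.null(threshold))
    stop("rule = 'threshold' requires a threshold")
  if (rule == "count" && is.null(count))
    stop("rule = 'count' requires a count")
  ids <- series_ids(series_list)
  names(series_list) <- ids
  removed <- data.frame(replica_id = character(0), normalized_cost = numeric(0),
                        round = integer(0), stringsAsFactors = FALSE)
  max_removals <- length(series_list) - 2L
  if (rule == "count") max_removals <- min(max_removals, count)
  round_i <- 0L
  repeat {
    bary <- dba_barycenter(series_list, normalization = normalization, ...)
    costs <- sort(bary$normalized_costs, decreasing = TRUE)
    if (nrow(removed) >= max_removals || length(series_list) <= 2L) break
    worst <- names(costs)[1]
    fire <- switch(rule,
      gap = {
        gaps <- -diff(costs)
        length(gaps) >= 1L && gaps[1] > mean(gaps) && gaps[1] > 0
      },
      threshold = costs[1] > threshold,
      count = TRUE)
    if (!fire) break
    round_i <- round_i + 1L
    removed <- rbind(removed, data.frame(replica_id = worst,
                                         normalized_cost = unname(costs[1]),
                                         round = round_i,
                                         stringsAsFactors = FALSE))
    series_list <- series_list[names(series_list) != worst]
  }
  report <- structure(list(kept = names(series_list), removed = removed),
                      class = "pruning_report")
  list(report = report, barycenter = bary)
}

#' @export
print.pruning_report <- function(x, ...) {
  cat(sprintf("Pruning: kept %d replica(s), removed %d\n",
              length(x$kept), nrow(x$removed)))
  if (nrow(x$removed) > 0) print(x$removed)
  invisible(x)
}

#' Write per-replica alignment scores as TSV
#' @param bary a `dba_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_scores <- function(bary, path) {
  df <- data.frame(replica_id = bary$ids,
                   dtw_cost = fmt_num(vapply(bary$results, `[[`, numeric(1), "cost")),
                   normalized_cost = fmt_num(bary$normalized_costs))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
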