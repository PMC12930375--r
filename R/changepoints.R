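new_deviation_profile <- function(values, source, window = 1L,
                                  noise_var = NULL) {
  values <- as.numeric(values)
  # first-difference noise estimate of the unsmoothed profile; smoothing
  # carries it along so the segmentation penalty reflects the raw noise
  if (is.null(noise_var))
    noise_var <- if (length(values) >= 3L) mean(diff(values)^2) / 2 else 0
  structure(list(values = values, source = source,
                 window = as.integer(window), noise_var = noise_var),
            class = "deviation_profile")
}

#' @export
print.deviation_profile <- function(x, ...) {
  cat(sprintf("Deviation profile (%s): length %d, mean %.4g, window %d\n",
              x$source, length(x$values), mean(x$values), x$window))
  invisible(x)
}

#' Frame-wise deviation of a replica from the consensus
#'
#' For every barycenter index `t`, the value is the Euclidean distance
#' between the barycenter point and the mean of the replica frames that the
#' warp path associates to `t`. For a replica that took part in the
#' consensus the stored association is used; any other alignable series is
#' DTW-aligned to the barycenter first.
#'
#' @param replica an `embedding_series` or numeric matrix.
#' @param consensus a `dba_result` from [dba_barycenter()].
#' @return a `deviation_profile` whose length equals the barycenter length.
#' @export
deviation_profile <- function(replica, consensus) {
  stopifnot(inherits(consensus, "dba_result"))
  m <- as_series_matrix(replica)
  id <- if (inherits(replica, "embedding_series")) replica$replica_id else NULL
  L <- nrow(consensus$barycenter)
  assoc <- if (!is.null(id) && id %in% names(consensus$association)) {
    consensus$association[[id]]
  } else {
    path_association(cpp_dtw(consensus$barycenter, m, FALSE)$path, L)
  }
  if (any(lengths(assoc) == 0L))
    stop("empty association at a barycenter index; alignment is inconsistent")
  vals <- vapply(seq_len(L), function(t) {
    mu <- colMeans(m[assoc[[t]], , drop = FALSE])
    sqrt(sum((consensus$barycenter[t, ] - mu)^2))
  }, numeric(1))
  new_deviation_profile(vals, paste(id %||% "replica", "vs consensus"))
}

#' Divergence profile between two aligned replicas
#'
#' Cross-system mode: aligns the pair with dependent DTW and reports, along
#' the first series' frame axis, the mean local Euclidean distance over the
#' warp-path steps visiting each frame. Used on the best replica of each
#' system to localize when two conditions diverge.
#'
#' @param a,b `embedding_series` or numeric matrices with equal dimensions.
#' @return a `deviation_profile` of length `nrow(a)`; attribute `path`
#'   carries the warp path for pulling windows back to `b`'s frames.
#' @export
divergence_pair <- function(a, b) {
  ma <- as_series_matrix(a); mb <- as_series_matrix(b)
  r <- cpp_dtw(ma, mb, FALSE)
  local <- sqrt(rowSums((ma[r$path[, 1L], , drop = FALSE] -
                           mb[r$path[, 2L], , drop = FALSE])^2))
  vals <- vapply(split(local, factor(r$path[, 1L], levels = seq_len(nrow(ma)))),
                 mean, numeric(1))
  ida <- if (inherits(a, "embedding_series")) a$replica_id else "a"
  idb <- if (inherits(b, "embedding_series")) b$replica_id else "b"
  out <- new_deviation_profile(unname(vals), paste(ida, "vs", idb))
  attr(out, "path") <- r$path
  out
}

#' Moving-average smoothing of a deviation profile
#'
#' Centered moving average with edge truncation (the window shrinks near the
#' boundaries), suppressing thermal noise while preserving profile length.
#'
#' @param profile a `deviation_profile` or numeric vector.
#' @param window odd window width in frames (`window = 1` is the identity).
#' @return same type as the input, smoothed.
#' @export
smooth_profile <- function(profile, window = 25L) {
  if (window < 1L || window %% 2L == 0L)
    stop("smoothing window must be odd and >= 1")
  x <- if (inherits(profile, "deviation_profile")) profile$values else profile
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (inherits(profile, "deviation_profile"))
    new_deviation_profile(sm, profile$source, window,
                          noise_var = profile$noise_var)
  else sm
}

# Exact penalized segmentation via PELT. Segment cost is the within-segment
# sum of squared deviations from the segment mean, computed from cumulative
# sums; the pruning bound uses K = 0, which preserves exactness for this
# cost. F[t] = min over admissible tau of F[tau] + C(tau+1..t) + beta.
pelt_core <- function(x, beta) {
  n <- length(x)
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  segcost <- function(a, b) {  # cost of x[(a+1)..b], vectorized over a
    len <- b - a
    s2[b + 1L] - s2[a + 1L] - (s1[b + 1L] - s1[a + 1L])^2 / len
  }
  F <- c(-beta, rep(Inf, n))
  prev <- integer(n + 1L)
  cand <- 0L
  for (t in seq_len(n)) {
    costs <- F[cand + 1L] + segcost(cand, t) + beta
    best <- which.min(costs)
    F[t + 1L] <- costs[best]
    prev[t + 1L] <- cand[best]
    cand <- c(cand[costs - beta <= F[t + 1L]], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    tau <- prev[t + 1L]
    if (tau > 0L) cps <- c(tau, cps)
    t <- tau
  }
  list(changepoints = cps, objective = F[n + 1L])
}

#' PELT change-point segmentation
#'
#' Minimizes the total within-segment sum of squared deviations from the
#' segment mean plus a penalty linear in the number of change points, using
#' the Pruned Exact Linear Time algorithm (pruning preserves the exact
#' optimum for this cost). The default penalty is `2 * sigma^2 * log(n)`,
#' a BIC-like choice for a mean-shift model, with the noise variance
#' estimated from first differences. For a `deviation_profile` smoothed by
#' [smooth_profile()] the estimate recorded before smoothing is used:
#' moving-average smoothing suppresses the apparent first-difference
#' variance by roughly `window^2`, so an estimate taken after smoothing
#' would drastically over-segment.
#'
#' @param x numeric series (e.g. a smoothed deviation profile) or a
#'   `deviation_profile`.
#' @param penalty positive penalty per change point; `NULL` for the default.
#' @return a `changepoint_set`: `indices` (strictly increasing segment end
#'   positions in `(0, n)`, so `k` marks a boundary between positions `k`
#'   and `k + 1`), `penalty`, `segment_means`, `objective`.
#' @export
pelt_segment <- function(x, penalty = NULL) {
  noise_var <- NULL
  if (inherits(x, "deviation_profile")) {
    noise_var <- x$noise_var
    x <- x$values
  }
  n <- length(x)
  if (n < 2L) stop("need a series of length >= 2")
  if (is.null(penalty)) {
    sigma2 <- noise_var %||%
      (if (n >= 3L) mean(diff(x)^2) / 2 else var(x))
    penalty <- max(2 * sigma2 * log(n), .Machine$double.eps)
  }
  if (penalty <= 0) stop("penalty must be positive")
  fit <- pelt_core(x, penalty)
  bounds <- c(0L, fit$changepoints, n)
  means <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  structure(list(indices = fit$changepoints, penalty = penalty,
                 segment_means = means, objective = fit$objective,
                 n = n),
            class = "changepoint_set")
}

#' @export
print.changepoint_set <- function(x, ...) {
  cat(sprintf("Change points (penalty %.4g): %s\n", x$penalty,
              if (length(x$indices)) paste(x$indices, collapse = ", ")
              else "none"))
  cat("segment means:", paste(signif(x$segment_means, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-window contact-frequency differences between two groups
#'
#' Pulls an aligned-axis window back to raw frames of every replica through
#' the supplied warp maps, then reports each contact's mean occupancy in
#' group A and group B over those frames, the difference `A - B`, and which
#' group favors the contact, ranked by absolute difference.
#'
#' @param group_a,group_b lists of `occupancy_series` sharing one vocabulary.
#' @param window integer `c(start, end)` (1-based, inclusive) on the aligned
#'   axis.
#' @param maps_a,maps_b per-replica associations from aligned index to raw
#'   frame indices (e.g. `dba_result$association` entries, or the identity
#'   for the reference series of [divergence_pair()]). `NULL` means the
#'   aligned axis already is that replica's frame axis.
#' @param residue optional residue id; restricts the table to contacts
#'   touching it.
#' @return a `contact_shift_table` data.frame: `res_a`, `res_b`,
#'   `occupancy_a`, `occupancy_b`, `difference`, `favors`; attribute
#'   `window`.
#' @export
contact_shift_table <- function(group_a, group_b, window,
                                maps_a = NULL, maps_b = NULL,
                                residue = NULL) {
  if (inherits(group_a, "occupancy_series")) group_a <- list(group_a)
  if (inherits(group_b, "occupancy_series")) group_b <- list(group_b)
  vocab <- group_a[[1]]$vocab
  for (s in c(group_a, group_b))
    if (!identical(s$vocab$key, vocab$key))
      stop("groups do not share one edge vocabulary")
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[2] < window[1])
    stop("window must be c(start, end) with 1 <= start <= end")

  pool <- function(group, maps) {
    rows <- 0
    acc <- numeric(nrow(vocab))
    for (i in seq_along(group)) {
      s <- group[[i]]
      frames <- if (is.null(maps)) {
        if (window[2] > s$n_frames) stop("window outside the aligned axis")
        seq.int(window[1], window[2])
      } else {
        map <- maps[[i]]
        if (window[2] > length(map)) stop("window outside the aligned axis")
        unique(unlist(map[window[1]:window[2]], use.names = FALSE))
      }
      acc <- acc + colSums(s$matrix[frames, , drop = FALSE])
      rows <- rows + length(frames)
    }
    acc / rows
  }
  occ_a <- pool(group_a, maps_a)
  occ_b <- pool(group_b, maps_b)
  df <- data.frame(res_a = vocab$res_a, res_b = vocab$res_b,
                   occupancy_a = occ_a, occupancy_b = occ_b,
                   difference = occ_a - occ_b,
                   stringsAsFactors = FALSE)
  df$favors <- ifelse(df$difference > 0, "A",
                      ifelse(df$difference < 0, "B", "tie"))
  if (!is.null(residue))
    df <- df[df$res_a == residue | df$res_b == residue, , drop = FALSE]
  df <- df[order(-abs(df$difference), df$res_a, df$res_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("contact_shift_table", "data.frame"),
            window = window)
}

#' Write change points as TSV
#' @param cps a `changepoint_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_changepoints <- function(cps, path) {
  bounds <- c(0L, cps$indices, cps$n)
  df <- data.frame(segment = seq_len(length(bounds) - 1L),
                   start = bounds[-length(bounds)] + 1L,
                   end = bounds[-1],
                   mean = fmt_num(cps$segment_means))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# penalty\t%s", fmt_num(cps$penalty)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
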