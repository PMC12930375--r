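#' Binary Shannon entropy
#'
#' `H(p) = -p log2 p - (1-p) log2 (1-p)` in bits, with `0 log 0 := 0`. For a
#' presence/absence contact this is 0 when the contact is invariant and 1
#' when it is present in exactly half the frames.
#'
#' @param p occupancy fraction(s) in `[0, 1]`.
#' @return entropy in bits, same length as `p`.
#' @export
binary_entropy <- function(p) {
  if (any(p < 0 | p > 1)) stop("occupancy must lie in [0, 1]")
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  q <- p[ok]
  h[ok] <- -q * log2(q) - (1 - q) * log2(1 - q)
  h
}

#' Occupancy interval retained at a given entropy cutoff
#'
#' Solves `H(p*) = cutoff` for the lower root by bisection; contacts are
#' retained exactly when their occupancy lies in `[p*, 1 - p*]`.
#'
#' @param cutoff entropy cutoff in bits, in `(0, 1)`.
#' @param tol root-finding tolerance.
#' @return numeric of length 2: the retained occupancy interval endpoints.
#' @export
entropy_cutoff_occupancy <- function(cutoff, tol = 1e-12) {
  stopifnot(cutoff > 0, cutoff < 1)
  p_star <- uniroot(function(p) binary_entropy(p) - cutoff,
                    lower = .Machine$double.eps, upper = 0.5,
                    tol = tol)$root
  c(p_star, 1 - p_star)
}

#' Per-edge occupancy and Shannon entropy across an ensemble
#'
#' Pools active-frame counts across every series in the list (all frames of
#' all replicas), yielding per-edge occupancy `p` and binary entropy `H(p)`.
#'
#' @param series_list list of `occupancy_series` sharing one vocabulary (or a
#'   single series).
#' @return an `edge_entropy` data.frame with columns `res_a`, `res_b`, `key`,
#'   `n_active`, `occupancy`, `entropy`, and attribute `n_frames_total`.
#' @export
edge_entropy <- function(series_list) {
  if (inherits(series_list, "occupancy_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1)
  vocab <- series_list[[1]]$vocab
  for (s in series_list) {
    if (!inherits(s, "occupancy_series")) stop("expected occupancy_series")
    if (!identical(s$vocab$key, vocab$key))
      stop("occupancy series do not share one edge vocabulary")
  }
  n_active <- Reduce(`+`, lapply(series_list, function(s) colSums(s$matrix)))
  n_total <- sum(vapply(series_list, function(s) s$n_frames, numeric(1)))
  p <- n_active / n_total
  structure(data.frame(res_a = vocab$res_a, res_b = vocab$res_b,
                       key = vocab$key, n_active = as.integer(n_active),
                       occupancy = p, entropy = binary_entropy(p),
                       stringsAsFactors = FALSE),
            class = c("edge_entropy", "data.frame"),
            n_frames_total = n_total)
}

#' Entropy-filter contact edges
#'
#' Retains edges whose entropy satisfies `H >= lower_cutoff` and, if an
#' upper cutoff is set, `H <= upper_cutoff`; every series is column-subset to
#' the retained vocabulary in original order. With the default cutoffs only
#' effectively invariant contacts (occupancy near 0 or 1) are removed.
#'
#' @param series_list list of `occupancy_series` sharing one vocabulary.
#' @param table optional precomputed [edge_entropy()] table for these series;
#'   computed if missing.
#' @param lower_cutoff lower entropy cutoff in bits (default 0.1).
#' @param upper_cutoff optional upper entropy cutoff in bits (default none).
#' @return list with `series` (filtered list), `vocab` (retained
#'   `edge_vocab`), and `table` (the entropy table with a `retained` flag).
#' @export
filter_edges <- function(series_list, table = NULL, lower_cutoff = 0.1,
                         upper_cutoff = NULL) {
  if (inherits(series_list, "occupancy_series")) series_list <- list(series_list)
  stopifnot(lower_cutoff >= 0, lower_cutoff <= 1)
  if (!is.null(upper_cutoff))
    stopifnot(upper_cutoff >= lower_cutoff, upper_cutoff <= 1)
  if (is.null(table)) table <- edge_entropy(series_list)
  vocab <- series_list[[1]]$vocab
  if (!identical(table$key, vocab$key))
    stop("entropy table was not computed over these series")
  keep <- table$entropy >= lower_cutoff
  if (!is.null(upper_cutoff)) keep <- keep & table$entropy <= upper_cutoff
  if (!any(keep))
    stop("no edges retained at lower_cutoff = ", lower_cutoff,
         "; try a lower cutoff")
  table$retained <- keep
  new_vocab <- structure(vocab[keep, , drop = FALSE],
                         class = c("edge_vocab", "data.frame"))
  rownames(new_vocab) <- NULL
  filtered <- lapply(series_list, function(s) {
    new_occupancy_series(s$matrix[, keep, drop = FALSE], new_vocab,
                         s$replica_id, s$system_id)
  })
  list(series = filtered, vocab = new_vocab, table = table)
}

#' Write an entropy report as TSV
#'
#' @param table an `edge_entropy` table (optionally with a `retained` flag).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_entropy_report <- function(table, path) {
  out <- data.frame(res_a = table$res_a, res_b = table$res_b,
                    occupancy = fmt_num(table$occupancy),
                    entropy_bits = fmt_num(table$entropy),
                    retained = if (!is.null(table$retained))
                      as.integer(table$retained) else NA_integer_)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.edge_entropy <- function(x, ...) {
  cat(sprintf("Edge entropy over %d frames: %d edges, median H = %.3f bits\n",
              attr(x, "n_frames_total"), nrow(x), stats::median(x$entropy)))
  invisible(x)
}
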