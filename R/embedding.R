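#' Embedding configuration
#'
#' Collects the tunables of the frame-embedding stage. The structural
#' defaults (3 WL iterations, 16 dimensions) capture local-to-intermediate
#' connectivity in a compact latent space; the training hyperparameters
#' follow common document-embedding practice and are all overridable.
#'
#' @param wl_iterations number of WL refinement iterations (`>= 1`).
#' @param dimensions embedding dimensionality (`>= 2`).
#' @param epochs training epochs over the document corpus.
#' @param learning_rate initial SGD learning rate (decays linearly).
#' @param negative negative samples per positive token.
#' @param min_token_count tokens seen fewer times across the whole corpus are
#'   dropped before training (default 5, the customary document-embedding
#'   choice; WL tokens seen once carry no shared structure and dominate the
#'   vocabulary otherwise).
#' @param seed integer seed; fixed seed implies bitwise-identical embeddings.
#' @return an `embedding_config` list.
#' @export
embedding_config <- function(wl_iterations = 3L, dimensions = 16L,
                             epochs = 100L, learning_rate = 0.025,
                             negative = 5L, min_token_count = 5L,
                             seed = 42L) {
  stopifnot(wl_iterations >= 1, dimensions >= 2, epochs >= 1,
            learning_rate > 0, negative >= 1, min_token_count >= 1)
  structure(list(wl_iterations = as.integer(wl_iterations),
                 dimensions = as.integer(dimensions),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 negative = as.integer(negative),
                 min_token_count = as.integer(min_token_count),
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Weisfeiler-Lehman relabeling of a frame graph
#'
#' Iteration 0 emits each node's initial label; iteration `i` emits, per
#' node, a stable 16-hex-character digest of its iteration-`(i-1)` label
#' concatenated with the sorted multiset of its neighbours' labels. The
#' document is the token multiset accumulated over iterations `0..k`, so
#' coarse and fine neighbourhood scales coexist.
#'
#' @param graph a `frame_graph` (see [to_frame_graphs()]), or any list with
#'   `labels` and a 2-column integer `edges` matrix.
#' @param k number of WL iterations (`>= 1`).
#' @return a `wl_document`: list with `tokens` (character, length
#'   `(k+1) * n_nodes`), `n_nodes`, and `k`.
#' @export
wl_relabel <- function(graph, k = 3L) {
  stopifnot(k >= 1)
  labels <- graph$labels %||% graph$nodes
  edges <- graph$edges
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- matrix(integer(0), ncol = 2L)
  tokens <- cpp_wl_document(as.character(labels),
                            matrix(as.integer(edges), ncol = 2L),
                            as.integer(k))
  structure(list(tokens = tokens, n_nodes = length(labels), k = as.integer(k)),
            class = "wl_document")
}

#' @export
print.wl_document <- function(x, ...) {
  cat(sprintf("WL document: %d tokens (%d nodes x %d iterations incl. 0)\n",
              length(x$tokens), x$n_nodes, x$k + 1L))
  invisible(x)
}

new_embedding_series <- function(matrix, replica_id, system_id = NA_character_) {
  if (any(!is.finite(matrix))) stop("non-finite embedding values")
  structure(list(replica_id = replica_id, system_id = system_id,
                 matrix = matrix),
            class = "embedding_series")
}

#' @export
print.embedding_series <- function(x, ...) {
  cat(sprintf("Embedding series '%s': %d frames x %d dims\n",
              x$replica_id, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# shared trainer: tokens as integer ids (0-based), doc offsets (0-based,
# length n_docs + 1), counts per id; applies min_token_count then trains.
train_core <- function(tokens, offsets, counts, config) {
  if (length(counts) == 0L) stop("empty document corpus: no tokens")
  if (config$min_token_count > 1L) {
    keep <- counts >= config$min_token_count
    if (!any(keep)) stop("min_token_count removed every token")
    remap <- cumsum(keep) - 1L
    kept_tok <- keep[tokens + 1L]
    new_tokens <- remap[tokens + 1L][kept_tok]
    # recompute offsets over surviving tokens
    doc_of <- findInterval(seq_along(tokens) - 1L, offsets,
                           rightmost.closed = FALSE) # 1-based doc index
    n_docs <- length(offsets) - 1L
    kept_per_doc <- tabulate(doc_of[kept_tok], nbins = n_docs)
    offsets <- c(0L, cumsum(kept_per_doc))
    tokens <- new_tokens
    counts <- counts[keep]
  }
  cpp_pvdbow_train(as.integer(tokens), as.integer(offsets),
                   as.integer(counts), config$dimensions, config$epochs,
                   config$learning_rate, config$negative, config$seed)
}

#' Train document embeddings for a list of WL documents
#'
#' All documents are embedded jointly in one model so their coordinates are
#' commensurable across replicas and systems. Training is a distributed
#' bag-of-tokens objective with negative sampling, run single-threaded so a
#' fixed seed gives bitwise-identical output.
#'
#' @param documents list of `wl_document` objects (one per frame, in order).
#' @param config an [embedding_config()].
#' @return numeric matrix, one row per document, `config$dimensions` columns.
#' @export
train_embeddings <- function(documents, config = embedding_config()) {
  stopifnot(length(documents) >= 1)
  toks <- lapply(documents, function(d)
    if (inherits(d, "wl_document")) d$tokens else as.character(d))
  if (all(lengths(toks) == 0L))
    stop("all documents are empty: graphs have no nodes or labels")
  flat <- unlist(toks, use.names = FALSE)
  vocab <- unique(flat)                  # first-appearance order
  ids <- match(flat, vocab) - 1L
  counts <- tabulate(ids + 1L, nbins = length(vocab))
  offsets <- c(0L, cumsum(lengths(toks)))
  m <- train_core(ids, offsets, counts, config)
  if (any(!is.finite(m))) stop("non-finite embedding values")
  m
}

#' Embed occupancy series jointly into a latent space
#'
#' Extracts WL documents for every frame of every series (all sharing the
#' vocabulary node set) and trains one joint embedding model, so wild-type
#' and variant trajectories live in one coordinate system. This is the
#' high-throughput path: WL extraction and token interning run in compiled
#' code.
#'
#' @param series_list list of `occupancy_series` sharing one vocabulary.
#' @param config an [embedding_config()].
#' @return list of `embedding_series`, one per input series, same order.
#' @export
embed_ensembles <- function(series_list, config = embedding_config()) {
  if (inherits(series_list, "occupancy_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1)
  vocab <- series_list[[1]]$vocab
  for (s in series_list)
    if (!identical(s$vocab$key, vocab$key))
      stop("occupancy series do not share one edge vocabulary")
  nodes <- vocab_nodes(vocab)
  ends <- vocab_edge_ends(vocab, nodes)
  big <- do.call(rbind, lapply(series_list, `[[`, "matrix"))
  corpus <- cpp_wl_corpus(nodes, ends, big, config$wl_iterations)
  m <- train_core(corpus$tokens, corpus$offsets, corpus$counts, config)
  if (any(!is.finite(m))) stop("non-finite embedding values")
  n_per <- vapply(series_list, function(s) s$n_frames, integer(1))
  stop_at <- cumsum(n_per)
  start_at <- stop_at - n_per + 1L
  lapply(seq_along(series_list), function(i)
    new_embedding_series(m[start_at[i]:stop_at[i], , drop = FALSE],
                         series_list[[i]]$replica_id,
                         series_list[[i]]$system_id))
}

#' Reduce embedding series by PCA
#'
#' Projects all series (stacked) onto the smallest number of principal
#' components whose cumulative explained variance reaches `variance_kept`.
#' Intended for visualization and clustering diagnostics only: trajectory
#' alignment always consumes the raw embedding space.
#'
#' @param series_list list of `embedding_series`.
#' @param variance_kept fraction of variance to retain, in `(0, 1]`.
#' @return list of reduced `embedding_series`; attribute `explained` carries
#'   the per-component explained-variance fractions retained.
#' @export
reduce_pca <- function(series_list, variance_kept = 0.90) {
  if (inherits(series_list, "embedding_series")) series_list <- list(series_list)
  if (variance_kept <= 0 || variance_kept > 1)
    stop("variance_kept must lie in (0, 1]")
  X <- do.call(rbind, lapply(series_list, `[[`, "matrix"))
  if (nrow(X) < 2L) stop("need at least two total frames for PCA")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  nonzero <- ev > max(ev) * 1e-12
  d <- which(cumsum(frac) >= variance_kept - 1e-12)[1]
  d <- min(d, sum(nonzero))
  d <- max(d, 1L)
  scores <- pc$x[, seq_len(d), drop = FALSE]
  n_per <- vapply(series_list, function(s) nrow(s$matrix), integer(1))
  stop_at <- cumsum(n_per)
  start_at <- stop_at - n_per + 1L
  out <- lapply(seq_along(series_list), function(i)
    new_embedding_series(scores[start_at[i]:stop_at[i], , drop = FALSE],
                         series_list[[i]]$replica_id,
                         series_list[[i]]$system_id))
  attr(out, "explained") <- frac[seq_len(d)]
  out
}

#' Write embedding series to a TSV table
#'
#' Full-precision text serialization (`system_id`, `replica_id`, `frame`,
#' one column per dimension); [read_embeddings()] round-trips exactly.
#'
#' @param series_list list of `embedding_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(series_list, path) {
  if (inherits(series_list, "embedding_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    d <- as.data.frame(s$matrix)
    names(d) <- paste0("d", seq_len(ncol(d)))
    cbind(data.frame(system_id = s$system_id, replica_id = s$replica_id,
                     frame = seq_len(nrow(d)) - 1L), d)
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read embedding series written by [write_embeddings()]
#'
#' @param path TSV path.
#' @return list of `embedding_series`.
#' @export
read_embeddings <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  dims <- grep("^d[0-9]+$", names(df), value = TRUE)
  key <- paste(df$system_id, df$replica_id, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    new_embedding_series(as.matrix(sub[, dims, drop = FALSE]),
                         sub$replica_id[1], sub$system_id[1])
  })
  out
}
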