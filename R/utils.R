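`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library internals never perturb the
#' caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable content hash of an R object (FNV-1a over its serialization), used to
# key cached pipeline intermediates.
object_hash <- function(x) {
  cpp_fnv_raw(serialize(x, NULL, version = 2))
}

# full-precision numeric formatting for text artifacts
fmt_num <- function(x) formatC(x, format = "g", digits = 17)

as_series_matrix <- function(x) {
  if (inherits(x, "embedding_series")) return(x$matrix)
  if (is.numeric(x) && is.null(dim(x))) return(matrix(x, ncol = 1L))
  if (is.matrix(x)) return(x)
  stop("expected a numeric matrix, numeric vector, or embedding_series")
}

series_ids <- function(series_list) {
  ids <- vapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    if (inherits(s, "embedding_series") && !is.null(s$replica_id)) s$replica_id
    else names(series_list)[i] %||% paste0("series", i)
  }, character(1))
  if (any(ids == "" | is.na(ids)))
    ids[ids == "" | is.na(ids)] <- paste0("series", which(ids == "" | is.na(ids)))
  ids
}
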