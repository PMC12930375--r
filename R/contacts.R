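# Residue identifiers are "chain:resname:resid" strings. A residue is
# identified by chain + residue number; the 3-letter residue name travels
# along as annotation. Ordering is total: lexicographic on chain, then
# numeric residue number (resname as a final tiebreak), so contact endpoints
# can always be canonically sorted.

res_fields <- function(res) {
  parts <- strsplit(res, ":", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("malformed residue id (expected chain:resname:resid): ",
         res[bad][1])
  chain <- vapply(parts, `[[`, character(1), 1L)
  resname <- vapply(parts, `[[`, character(1), 2L)
  resid <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(resid))
    stop("non-integer residue number in residue id: ", res[is.na(resid)][1])
  data.frame(chain = chain, resname = resname, resid = resid,
             stringsAsFactors = FALSE)
}

res_order <- function(res) {
  f <- res_fields(res)
  order(f$chain, f$resid, f$resname)
}

# TRUE where a must come after b in canonical order
res_after <- function(a, b) {
  fa <- res_fields(a)
  fb <- res_fields(b)
  (fa$chain > fb$chain) |
    (fa$chain == fb$chain & fa$resid > fb$resid) |
    (fa$chain == fb$chain & fa$resid == fb$resid & fa$resname > fb$resname)
}

atom_to_res <- function(atom) {
  parts <- strsplit(atom, ":", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) return(rep(NA_character_, length(atom)))
  vapply(parts, function(p) paste(p[1:3], collapse = ":"), character(1))
}

pair_key <- function(res_a, res_b) paste(res_a, res_b, sep = "--")

new_contact_table <- function(df, replica_id, n_frames) {
  structure(df, class = c("contact_table", "data.frame"),
            replica_id = replica_id, n_frames = as.integer(n_frames))
}

#' Parse a residue-contact table
#'
#' Reads tab-separated per-frame contact records in the GetContacts-style
#' dialect: comment lines start with `#`; data lines are
#' `frame<TAB>interaction_type<TAB>atom_1<TAB>atom_2` where an atom is
#' `chain:resname:resid[:atomname]`. Extra trailing columns are ignored.
#' Atom-level records are collapsed to residue level; duplicate residue
#' pairs within a frame (e.g. several atoms or interaction types) are merged
#' into one contact whose `type` field joins the distinct interaction types;
#' intra-residue contacts are dropped; endpoints are canonically ordered.
#'
#' @param x path to a contact file, or a character vector of lines.
#' @param replica_id label attached to the resulting table.
#' @param n_frames total frame count; defaults to `max(frame) + 1` so that
#'   trailing frames with zero contacts can be declared explicitly.
#' @return a `contact_table`: data.frame with columns `frame` (0-based
#'   integer), `type`, `res_a`, `res_b`, carrying `replica_id` and `n_frames`
#'   attributes. Frames form the contiguous range `0..n_frames-1`; frames
#'   without contacts simply have no rows.
#' @export
parse_contact_table <- function(x, replica_id = "replica1", n_frames = NULL) {
  lines <- if (length(x) == 1L && !grepl("[\t\n]", x) && file.exists(x))
    readLines(x, warn = FALSE) else x
  # the writer records the declared frame count in a comment; honor it so
  # write -> parse round-trips preserve trailing contact-free frames
  tf <- regmatches(lines, regexec("^#\\s*total_frames:(\\d+)\\s*$", lines))
  tf <- unlist(lapply(tf, `[`, 2L))
  if (is.null(n_frames) && any(!is.na(tf)))
    n_frames <- as.integer(tf[!is.na(tf)][1])
  is_data <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(is_data)
  lines <- lines[is_data]
  if (length(lines) == 0L) stop("empty contact input: no data lines")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 4L))
    stop("malformed contact line ", lineno[which(nfield < 4L)[1]],
         ": expected >= 4 tab-separated fields")
  frame <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 1L)))
  if (anyNA(frame))
    stop("malformed contact line ", lineno[which(is.na(frame))[1]],
         ": non-integer frame index")
  if (any(frame < 0L))
    stop("malformed contact line ", lineno[which(frame < 0L)[1]],
         ": negative frame index")
  type <- vapply(parts, `[[`, character(1), 2L)
  res_a <- atom_to_res(vapply(parts, `[[`, character(1), 3L))
  res_b <- atom_to_res(vapply(parts, `[[`, character(1), 4L))
  if (anyNA(res_a) || anyNA(res_b))
    stop("malformed contact line ",
         lineno[which(is.na(res_a) | is.na(res_b))[1]],
         ": atom id must be chain:resname:resid[:atomname]")
  # drop intra-residue atom pairs, canonicalize endpoint order
  keep <- res_a != res_b
  frame <- frame[keep]; type <- type[keep]
  res_a <- res_a[keep]; res_b <- res_b[keep]
  if (length(frame) == 0L) stop("empty contact input: no inter-residue contacts")
  swap <- res_after(res_a, res_b)
  tmp <- res_a[swap]; res_a[swap] <- res_b[swap]; res_b[swap] <- tmp
  # dedup within frame, merging interaction types as metadata
  key <- paste(frame, pair_key(res_a, res_b), sep = "@")
  type <- vapply(split(type, key)[unique(key)],
                 function(tt) paste(sort(unique(tt)), collapse = ","),
                 character(1))
  first <- !duplicated(key)
  df <- data.frame(frame = frame[first], type = unname(type),
                   res_a = res_a[first], res_b = res_b[first],
                   stringsAsFactors = FALSE)
  df <- df[order(df$frame, df$res_a, df$res_b), , drop = FALSE]
  rownames(df) <- NULL
  nf <- max(df$frame) + 1L
  if (!is.null(n_frames)) {
    if (n_frames < nf) stop("n_frames smaller than largest frame index + 1")
    nf <- as.integer(n_frames)
  }
  new_contact_table(df, replica_id, nf)
}

#' Write a contact table in the tab-separated contact dialect
#'
#' Emits the same dialect [parse_contact_table()] reads (residue-level ids,
#' one row per contact), so write/parse round-trips are exact.
#'
#' @param table a `contact_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(table, path) {
  stopifnot(inherits(table, "contact_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# frame\tinteraction_type\tatom_1\tatom_2",
               sprintf("# total_frames:%d", attr(table, "n_frames"))), con)
  if (nrow(table) > 0)
    writeLines(paste(table$frame, table$type, table$res_a, table$res_b,
                     sep = "\t"), con)
  invisible(path)
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("Contact table '%s': %d contacts over %d frames, %d distinct pairs\n",
              attr(x, "replica_id"), nrow(x), attr(x, "n_frames"),
              length(unique(pair_key(x$res_a, x$res_b)))))
  invisible(x)
}

#' Build a shared edge vocabulary
#'
#' The vocabulary is the canonically sorted union of all residue pairs seen
#' in any input table. It fixes a deterministic column order so occupancy
#' matrices of different replicas and systems are directly comparable.
#'
#' @param tables list of `contact_table` objects (or a single one).
#' @return an `edge_vocab`: data.frame with columns `res_a`, `res_b`, `key`.
#' @export
build_vocabulary <- function(tables) {
  if (inherits(tables, "contact_table")) tables <- list(tables)
  if (length(tables) == 0L) stop("need at least one contact table")
  res_a <- unlist(lapply(tables, `[[`, "res_a"), use.names = FALSE)
  res_b <- unlist(lapply(tables, `[[`, "res_b"), use.names = FALSE)
  key <- pair_key(res_a, res_b)
  first <- !duplicated(key)
  res_a <- res_a[first]; res_b <- res_b[first]
  fa <- res_fields(res_a); fb <- res_fields(res_b)
  o <- order(fa$chain, fa$resid, fa$resname, fb$chain, fb$resid, fb$resname)
  structure(data.frame(res_a = res_a[o], res_b = res_b[o],
                       key = key[first][o], stringsAsFactors = FALSE),
            class = c("edge_vocab", "data.frame"))
}

#' @export
print.edge_vocab <- function(x, ...) {
  cat(sprintf("Edge vocabulary: %d residue pairs over %d residues\n",
              nrow(x), length(unique(c(x$res_a, x$res_b)))))
  invisible(x)
}

vocab_nodes <- function(vocab) {
  nodes <- unique(c(vocab$res_a, vocab$res_b))
  nodes[res_order(nodes)]
}

vocab_edge_ends <- function(vocab, nodes = vocab_nodes(vocab)) {
  cbind(match(vocab$res_a, nodes), match(vocab$res_b, nodes))
}

new_occupancy_series <- function(matrix, vocab, replica_id, system_id = NA_character_) {
  structure(list(replica_id = replica_id, system_id = system_id,
                 n_frames = nrow(matrix), vocab = vocab, matrix = matrix),
            class = "occupancy_series")
}

#' Convert a contact table to a binary occupancy series
#'
#' @param table a `contact_table`.
#' @param vocab an `edge_vocab` covering every pair in `table` (build it over
#'   all tables under comparison first).
#' @param n_frames number of frames; defaults to the table's `n_frames`.
#' @param system_id optional system/condition label.
#' @return an `occupancy_series` with an integer 0/1 `n_frames x |vocab|`
#'   matrix; entry `(f, e)` is 1 iff pair `e` was observed at frame `f - 1`.
#' @export
to_occupancy <- function(table, vocab, n_frames = NULL, system_id = NA_character_) {
  stopifnot(inherits(table, "contact_table"), inherits(vocab, "edge_vocab"))
  nf <- as.integer(n_frames %||% attr(table, "n_frames"))
  if (nrow(table) > 0 && max(table$frame) >= nf)
    stop("table contains frames beyond n_frames")
  m <- matrix(0L, nrow = nf, ncol = nrow(vocab),
              dimnames = list(NULL, vocab$key))
  if (nrow(table) > 0) {
    col <- match(pair_key(table$res_a, table$res_b), vocab$key)
    if (anyNA(col))
      stop("contact pair not in vocabulary: ",
           pair_key(table$res_a, table$res_b)[which(is.na(col))[1]],
           " (build the vocabulary over all input tables first)")
    m[cbind(table$frame + 1L, col)] <- 1L
  }
  new_occupancy_series(m, vocab, attr(table, "replica_id"), system_id)
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("Occupancy series '%s': %d frames x %d edges (density %.3f)\n",
              x$replica_id, x$n_frames, ncol(x$matrix), mean(x$matrix)))
  invisible(x)
}

#' Coarse-grained contact construction from bead coordinates
#'
#' For coarse-grained systems with one bead per residue, the node set is the
#' residues whose bead lies within `node_radius` of any mutation-site bead
#' (inclusive, measured in the reference frame), and a contact is emitted per
#' frame for every node pair strictly closer than `edge_cutoff`.
#'
#' @param coords data.frame with columns `frame` (0-based), `chain`,
#'   `resname`, `resid`, `x`, `y`, `z` (angstrom); one row per bead per frame.
#' @param mutation_sites character vector of `chain:resname:resid` ids.
#' @param node_radius node-selection radius in angstrom (default 15,
#'   inclusive).
#' @param edge_cutoff contact distance in angstrom (default 6, strict `<`).
#' @param reference `"first"` selects nodes from the first frame;
#'   `"any"` keeps residues within the radius in at least one frame.
#' @param replica_id label for the resulting table.
#' @return a `contact_table` with interaction type `"cg"`.
#' @export
build_cg_contacts <- function(coords, mutation_sites, node_radius = 15,
                              edge_cutoff = 6, reference = c("first", "any"),
                              replica_id = "replica1") {
  reference <- match.arg(reference)
  need <- c("frame", "chain", "resname", "resid", "x", "y", "z")
  if (!all(need %in% names(coords)))
    stop("coords must have columns: ", paste(need, collapse = ", "))
  res <- paste(coords$chain, coords$resname, coords$resid, sep = ":")
  frames <- sort(unique(coords$frame))
  if (length(frames) == 0L) stop("no frames in coordinates")
  if (!all(mutation_sites %in% res))
    stop("unknown mutation site(s): ",
         paste(setdiff(mutation_sites, res), collapse = ", "))

  node_set_for <- function(f) {
    sel <- coords$frame == f
    xyz <- as.matrix(coords[sel, c("x", "y", "z")])
    rr <- res[sel]
    mut <- xyz[rr %in% mutation_sites, , drop = FALSE]
    d2min <- apply(xyz, 1L, function(p)
      min(colSums((t(mut) - p)^2)))
    rr[d2min <= node_radius^2]
  }
  nodes <- if (reference == "first") node_set_for(frames[1]) else
    unique(unlist(lapply(frames, node_set_for)))

  rows <- lapply(frames, function(f) {
    sel <- coords$frame == f & res %in% nodes
    xyz <- as.matrix(coords[sel, c("x", "y", "z")])
    rr <- res[sel]
    if (length(rr) < 2L) return(NULL)
    d <- as.matrix(dist(xyz))
    hit <- which(upper.tri(d) & d < edge_cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    data.frame(frame = f, type = "cg",
               res_a = rr[hit[, 1]], res_b = rr[hit[, 2]],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L)
    stop("no contacts found below the edge cutoff")
  swap <- res_after(df$res_a, df$res_b)
  tmp <- df$res_a[swap]; df$res_a[swap] <- df$res_b[swap]; df$res_b[swap] <- tmp
  df <- df[order(df$frame, df$res_a, df$res_b), , drop = FALSE]
  rownames(df) <- NULL
  new_contact_table(df, replica_id, max(frames) + 1L)
}

#' Materialize per-frame residue-contact graphs
#'
#' The node set is the union of all vocabulary endpoints and is constant
#' across frames (isolated nodes are kept) so graphs of different frames and
#' replicas share one node universe; each node's initial label is its residue
#' identity.
#'
#' @param series an `occupancy_series`.
#' @return list of `frame_graph` objects: `nodes` (residue ids), `labels`,
#'   `edges` (2-column integer matrix of node indices).
#' @export
to_frame_graphs <- function(series) {
  stopifnot(inherits(series, "occupancy_series"))
  nodes <- vocab_nodes(series$vocab)
  ends <- vocab_edge_ends(series$vocab, nodes)
  lapply(seq_len(series$n_frames), function(f) {
    active <- series$matrix[f, ] != 0L
    structure(list(nodes = nodes, labels = nodes,
                   edges = ends[active, , drop = FALSE]),
              class = "frame_graph")
  })
}

#' @export
print.frame_graph <- function(x, ...) {
  cat(sprintf("Frame graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
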