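#' Assemble a pipeline configuration
#'
#' Collects every stage option with its default. The configuration
#' round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param inputs named list: one entry per system, each a character vector
#'   of contact-table paths (one per replica). Alternatively `NULL` when
#'   `simulate` is given.
#' @param simulate optional [generator_spec()]; when set, inputs are
#'   generated in memory instead of read from disk.
#' @param entropy list: `lower_cutoff` (bits), `upper_cutoff` (bits or
#'   `NULL`).
#' @param embedding an [embedding_config()].
#' @param alignment list: `normalization` (`"path"`, `"max"`, `"sum"`),
#'   `max_iter`, `tol`, `prune_rule` (`"gap"`, `"threshold"`, `"count"`,
#'   or `"none"`), `threshold`, `count`.
#' @param clustering list: `method` (`"largest-gap"`, `"elbow"`, or
#'   `"fixed"`), `k` (for `"fixed"`).
#' @param changepoint list: `window` (odd moving-average width), `penalty`
#'   (`NULL` for the BIC-like default), `mode` (`"pair"` aligns the best
#'   replica of the two most distant systems; `"consensus"` profiles each
#'   system's best replica against its own barycenter).
#' @param seed integer master seed (embedding seed derives from it).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            entropy = list(), embedding = list(),
                            alignment = list(), clustering = list(),
                            changepoint = list(), seed = 1L) {
  defaults <- list(
    entropy = list(lower_cutoff = 0.1, upper_cutoff = NULL),
    alignment = list(normalization = "path", max_iter = 30L, tol = 1e-6,
                     prune_rule = "gap", threshold = NULL, count = NULL),
    clustering = list(method = "largest-gap", k = NULL),
    changepoint = list(window = 25L, penalty = NULL, mode = "pair"))
  merge <- function(d, u) { d[names(u)] <- u; d }
  if (is.null(inputs) && is.null(simulate))
    stop("either inputs or simulate must be given")
  emb <- if (inherits(embedding, "embedding_config")) embedding
  else do.call(embedding_config, embedding)
  structure(list(inputs = inputs, simulate = simulate,
                 entropy = merge(defaults$entropy, entropy),
                 embedding = emb,
                 alignment = merge(defaults$alignment, alignment),
                 clustering = merge(defaults$clustering, clustering),
                 changepoint = merge(defaults$changepoint, changepoint),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$embedding <- unclass(x$embedding)
  if (!is.null(x$simulate)) {
    x$simulate <- unclass(x$simulate)
    x$simulate$states <- as.numeric(x$simulate$states)
    x$simulate$states_dim <- dim(config$simulate$states)
  }
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' Read a pipeline configuration written by [write_pipeline_config()]
#' @param path YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$simulate)) {
    dims <- unlist(x$simulate$states_dim)
    x$simulate$states <- matrix(unlist(x$simulate$states), dims[1], dims[2])
    x$simulate$states_dim <- NULL
    x$simulate <- do.call(generator_spec, x$simulate)
  }
  pipeline_config(inputs = x$inputs, simulate = x$simulate,
                  entropy = x$entropy, embedding = x$embedding,
                  alignment = x$alignment, clustering = x$clustering,
                  changepoint = x$changepoint, seed = x$seed)
}

pipeline_stages <- c("ingest", "vocabulary", "entropy_filter", "embed",
                     "align", "compare", "changepoints", "contact_shifts")

stage_error <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

# cached stage evaluation: key = hash of config-relevant inputs
stage_cached <- function(cache_dir, key_obj, stage, expr) {
  key <- object_hash(key_obj)
  f <- file.path(cache_dir, sprintf("%s_%s.rds", stage, key))
  if (file.exists(f)) return(readRDS(f))
  val <- tryCatch(force(expr), error = function(e) stage_error(stage, e))
  saveRDS(val, f)
  val
}

#' Run the full synchronization pipeline
#'
#' Executes parse, vocabulary, entropy filter (per system, retained edges
#' pooled), joint embedding, per-system barycenter + outlier pruning,
#' pairwise distance matrix, Ward clustering with data-driven `k`, change
#' points, and contact-shift tables, writing every artifact plus a manifest
#' into `out_dir`. Stage intermediates are cached under `out_dir/cache`
#' keyed by a hash of the stage-relevant configuration, so reruns resume.
#'
#' @param config a `pipeline_config` or a YAML path.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the main results: `entropy` (per-system
#'   tables), `embeddings`, `consensus` (per-system pruning + barycenter),
#'   `dist`, `tree`, `clusters`, `profile`, `changepoints`, `shifts`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache <- file.path(out_dir, "cache")
  dir.create(cache, showWarnings = FALSE)
  files <- character(0)
  emit <- function(path) { files[length(files) + 1L] <<- basename(path); path }

  ## ingest ----------------------------------------------------------------
  tables <- stage_cached(cache, list(config$inputs, config$simulate), "ingest", {
    if (!is.null(config$simulate)) {
      generate_ensemble(config$simulate)$tables
    } else {
      tabs <- list()
      for (sys in names(config$inputs)) {
        paths <- config$inputs[[sys]]
        if (!all(file.exists(paths)))
          stop("missing input file(s) for system ", sys, ": ",
               paste(paths[!file.exists(paths)], collapse = ", "))
        for (i in seq_along(paths)) {
          id <- sprintf("%s_rep%d", sys, i)
          tab <- parse_contact_table(paths[i], replica_id = id)
          attr(tab, "system_id") <- sys
          tabs[[id]] <- tab
        }
      }
      tabs
    }
  })
  if (length(tables) < 2L)
    stage_error("ingest", simpleError("need at least two replicas in total"))
  systems <- vapply(tables, function(t) attr(t, "system_id"), character(1))

  ## vocabulary + occupancy ------------------------------------------------
  occ <- stage_cached(cache, list(tables), "vocabulary", {
    vocab <- build_vocabulary(tables)
    lapply(tables, function(t)
      to_occupancy(t, vocab, system_id = attr(t, "system_id")))
  })

  ## entropy filter (per system; retained edges pooled across systems) ------
  filt <- stage_cached(cache, list(occ, config$entropy), "entropy_filter", {
    per_sys <- split(seq_along(occ), systems)
    ent_tabs <- lapply(per_sys, function(idx) edge_entropy(occ[idx]))
    keep <- Reduce(`|`, lapply(ent_tabs, function(tab) {
      k <- tab$entropy >= config$entropy$lower_cutoff
      if (!is.null(config$entropy$upper_cutoff))
        k <- k & tab$entropy <= config$entropy$upper_cutoff
      k
    }))
    if (!any(keep))
      stop("no edges retained at lower_cutoff = ",
           config$entropy$lower_cutoff, "; try a lower cutoff")
    vocab <- occ[[1]]$vocab
    new_vocab <- structure(vocab[keep, , drop = FALSE],
                           class = c("edge_vocab", "data.frame"))
    rownames(new_vocab) <- NULL
    series <- lapply(occ, function(s)
      new_occupancy_series(s$matrix[, keep, drop = FALSE], new_vocab,
                           s$replica_id, s$system_id))
    list(series = series, vocab = new_vocab, tables = ent_tabs,
         retained = keep)
  })
  for (sys in names(filt$tables)) {
    tab <- filt$tables[[sys]]
    tab$retained <- filt$retained
    write_entropy_report(tab, emit(file.path(out_dir,
                                             sprintf("entropy_%s.tsv", sys))))
  }

  ## embed (jointly) --------------------------------------------------------
  emb_cfg <- config$embedding
  emb_cfg$seed <- as.integer((config$seed * 1000003L) %% .Machine$integer.max)
  embeddings <- stage_cached(cache, list(filt$series, emb_cfg), "embed",
                             embed_ensembles(filt$series, emb_cfg))
  write_embeddings(embeddings, emit(file.path(out_dir, "embeddings.tsv")))

  ## align: per-system DBA + pruning ----------------------------------------
  consensus <- stage_cached(cache, list(embeddings, config$alignment), "align", {
    per_sys <- split(seq_along(embeddings), systems)
    lapply(per_sys, function(idx) {
      ser <- embeddings[idx]
      al <- config$alignment
      if (al$prune_rule == "none" || length(ser) < 2L) {
        bary <- dba_barycenter(ser, max_iter = al$max_iter, tol = al$tol,
                               normalization = al$normalization)
        list(report = structure(list(kept = series_ids(ser),
                                     removed = data.frame()),
                                class = "pruning_report"),
             barycenter = bary)
      } else {
        prune_outliers(ser, rule = al$prune_rule, threshold = al$threshold,
                       count = al$count, normalization = al$normalization,
                       max_iter = al$max_iter, tol = al$tol)
      }
    })
  })
  for (sys in names(consensus)) {
    co <- consensus[[sys]]
    write_alignment_scores(co$barycenter,
                           emit(file.path(out_dir,
                                          sprintf("scores_%s.tsv", sys))))
    bc <- as.data.frame(co$barycenter$barycenter)
    names(bc) <- paste0("d", seq_len(ncol(bc)))
    bc[] <- lapply(bc, function(x) sprintf("%.17g", x))
    write.table(bc, emit(file.path(out_dir,
                                   sprintf("barycenter_%s.tsv", sys))),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rem <- co$report$removed
    write.table(if (nrow(rem)) rem else
                  data.frame(replica_id = character(0),
                             normalized_cost = numeric(0),
                             round = integer(0)),
                emit(file.path(out_dir, sprintf("pruning_%s.tsv", sys))),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## compare: pairwise matrix + Ward + k ------------------------------------
  cmp <- stage_cached(cache, list(embeddings, config$alignment$normalization,
                                  config$clustering), "compare", {
    dm <- pairwise_dtw_matrix(embeddings,
                              normalization = config$alignment$normalization)
    tree <- ward_linkage(dm)
    sol <- if (config$clustering$method == "fixed")
      cut_k(tree, config$clustering$k)
    else select_k(tree, config$clustering$method)
    list(dist = dm, tree = tree, clusters = sol)
  })
  write_dist_matrix(cmp$dist, emit(file.path(out_dir, "distance_matrix.tsv")))
  write_newick(cmp$tree, emit(file.path(out_dir, "dendrogram.nwk")))
  write.table(data.frame(replica_id = names(cmp$clusters$assignment),
                         system_id = systems[names(cmp$clusters$assignment)],
                         cluster = unname(cmp$clusters$assignment)),
              emit(file.path(out_dir, "clusters.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## change points ----------------------------------------------------------
  cp <- stage_cached(cache, list(embeddings, consensus, config$changepoint,
                                 cmp$dist), "changepoints", {
    mode <- config$changepoint$mode
    best_of <- vapply(names(consensus), function(sys) {
      nc <- consensus[[sys]]$barycenter$normalized_costs
      names(nc)[which.min(nc)]
    }, character(1))
    ids <- vapply(embeddings, `[[`, character(1), "replica_id")
    if (mode == "pair" && length(consensus) >= 2L) {
      # the two systems whose best replicas are most distant
      sys_names <- names(consensus)
      M <- cmp$dist$matrix[best_of, best_of, drop = FALSE]
      w <- which(M == max(M), arr.ind = TRUE)[1, ]
      pa <- best_of[w[1]]; pb <- best_of[w[2]]
      prof <- divergence_pair(embeddings[[match(pa, ids)]],
                              embeddings[[match(pb, ids)]])
      ref <- c(pa, pb)
    } else {
      sys1 <- names(consensus)[1]
      pa <- best_of[sys1]
      prof <- deviation_profile(embeddings[[match(pa, ids)]],
                                consensus[[sys1]]$barycenter)
      ref <- pa
    }
    sm <- smooth_profile(prof, config$changepoint$window)
    cps <- pelt_segment(sm, config$changepoint$penalty)
    list(profile = prof, smoothed = sm, changepoints = cps, reference = ref)
  })
  write_changepoints(cp$changepoints,
                     emit(file.path(out_dir, "changepoints.tsv")))
  write.table(data.frame(index = seq_along(cp$profile$values),
                         deviation = fmt_num(cp$profile$values),
                         smoothed = fmt_num(cp$smoothed$values)),
              emit(file.path(out_dir, "deviation_profile.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## contact shifts over the most divergent segment -------------------------
  shifts <- stage_cached(cache, list(filt$series, cp, systems), "contact_shifts", {
    cps <- cp$changepoints
    bounds <- c(0L, cps$indices, cps$n)
    seg <- which.max(cps$segment_means)
    window <- c(bounds[seg] + 1L, bounds[seg + 1L])
    if (length(cp$reference) == 2L) {
      ids <- vapply(filt$series, `[[`, character(1), "replica_id")
      a <- match(cp$reference[1], ids); b <- match(cp$reference[2], ids)
      path <- attr(cp$profile, "path")
      maps_b <- list(path_association(path, cps$n))
      tab <- contact_shift_table(filt$series[a], filt$series[b], window,
                                 maps_a = NULL, maps_b = maps_b)
    } else {
      sys1 <- names(consensus)[1]
      co <- consensus[[sys1]]
      kept <- co$report$kept
      ids <- vapply(filt$series, `[[`, character(1), "replica_id")
      grp <- filt$series[match(kept, ids)]
      tab <- contact_shift_table(grp, grp, window,
                                 maps_a = co$barycenter$association[kept],
                                 maps_b = co$barycenter$association[kept])
    }
    list(table = tab, window = window)
  })
  st <- shifts$table
  st$occupancy_a <- fmt_num(st$occupancy_a)
  st$occupancy_b <- fmt_num(st$occupancy_b)
  st$difference <- fmt_num(st$difference)
  write.table(st, emit(file.path(out_dir, "contact_shifts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## manifest ----------------------------------------------------------------
  manifest <- list(
    package = "mdsync",
    version = as.character(packageVersion("mdsync")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = pipeline_stages,
    outputs = sort(unique(files)),
    config_hash = object_hash(unclass(config)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(entropy = filt$tables, embeddings = embeddings,
                 consensus = consensus, dist = cmp$dist, tree = cmp$tree,
                 clusters = cmp$clusters, profile = cp$profile,
                 changepoints = cp$changepoints, shifts = shifts$table,
                 manifest = manifest))
}
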