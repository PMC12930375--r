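# Synthetic contact-ensemble generator. Every replica reads a shared latent
# state sequence through its own random monotone time warp, emits each
# contact as a Bernoulli draw from the active state's occupancy profile, and
# flips bits i.i.d. at a small rate. Condition-specific edges carry
# system-dependent profiles; one replica may draw from a perturbed profile
# (the planted outlier). All ground truth (warps, boundaries, condition
# edges, outlier, canonical change points) is returned alongside the data.

#' Specification for a synthetic contact ensemble
#'
#' @param n_systems number of systems/conditions.
#' @param replicas_per_system replicas simulated per system.
#' @param n_frames canonical trajectory length in frames.
#' @param length_jitter replicas end up to this many frames early (uniform).
#' @param n_residues residues in the synthetic protein.
#' @param states numeric matrix `n_edges x n_states` of per-edge Bernoulli
#'   occupancies (the shared baseline profiles); edge pairs are laid out over
#'   the residues deterministically from the seed.
#' @param boundaries strictly increasing canonical frame indices where the
#'   latent state switches (length `n_states - 1`).
#' @param condition_effects list with one integer vector of edge indices per
#'   system (pairwise disjoint); in the owning system those edges use
#'   `condition_high` in the divergent state, in every other system
#'   `condition_low`.
#' @param condition_state which latent state carries the condition effect.
#' @param condition_high,condition_low occupancies of a condition edge in
#'   the divergent state for the owning / non-owning systems.
#' @param outlier `NULL` or `list(system =, replica =, effect_size =)`; the
#'   planted outlier draws from a profile in which `effect_size` of the
#'   variable edges have occupancy `1 - p` in every state.
#' @param warp_knots knots of the piecewise-linear per-replica time warps.
#' @param warp_roughness scales the random knot displacement (0 = identity
#'   warp up to length rescaling).
#' @param flip_noise i.i.d. bit-flip probability applied after sampling.
#' @param seed integer seed; fixed seed gives byte-identical ensembles.
#' @return a validated `generator_spec` list.
#' @export
generator_spec <- function(n_systems = 2L, replicas_per_system = 4L,
                           n_frames = 200L, length_jitter = 0L,
                           n_residues = 60L, states, boundaries,
                           condition_effects = NULL, condition_state = NULL,
                           condition_high = 0.9, condition_low = 0.1,
                           outlier = NULL, warp_knots = 8L,
                           warp_roughness = 0.4, flip_noise = 0.02,
                           seed = 1L) {
  spec <- structure(list(n_systems = as.integer(n_systems),
                         replicas_per_system = as.integer(replicas_per_system),
                         n_frames = as.integer(n_frames),
                         length_jitter = as.integer(length_jitter),
                         n_residues = as.integer(n_residues),
                         states = as.matrix(states),
                         boundaries = as.integer(boundaries),
                         condition_effects = condition_effects,
                         condition_state = condition_state,
                         condition_high = condition_high,
                         condition_low = condition_low,
                         outlier = outlier,
                         warp_knots = as.integer(warp_knots),
                         warp_roughness = warp_roughness,
                         flip_noise = flip_noise,
                         seed = as.integer(seed)),
                    class = "generator_spec")
  validate_generator_spec(spec)
  spec
}

validate_generator_spec <- function(spec) {
  with(spec, {
    stopifnot(n_systems >= 1, replicas_per_system >= 1, n_frames >= 2,
              length_jitter >= 0, length_jitter < n_frames,
              n_residues >= 4, warp_knots >= 2, warp_roughness >= 0,
              flip_noise >= 0, flip_noise <= 1)
    if (any(states < 0 | states > 1)) stop("state occupancies must lie in [0, 1]")
    n_states <- ncol(states)
    if (length(boundaries) != n_states - 1L)
      stop("need n_states - 1 boundaries")
    if (n_states > 1L &&
        (any(diff(c(0L, boundaries, n_frames)) <= 0L)))
      stop("boundaries must be strictly increasing within (0, n_frames)")
    if (!is.null(condition_effects)) {
      if (length(condition_effects) != n_systems)
        stop("one condition edge set per system required")
      all_idx <- unlist(condition_effects)
      if (anyDuplicated(all_idx))
        stop("condition edge sets must be pairwise disjoint")
      if (length(all_idx) > nrow(states))
        stop("vocabulary smaller than the combined condition effect")
      if (any(all_idx < 1L | all_idx > nrow(states)))
        stop("condition edge index outside the vocabulary")
      if (is.null(condition_state) || condition_state < 1L ||
          condition_state > n_states)
        stop("condition_state must name a latent state")
    }
    if (!is.null(outlier)) {
      stopifnot(outlier$system >= 1, outlier$system <= n_systems,
                outlier$replica >= 1, outlier$replica <= replicas_per_system,
                outlier$effect_size > 0, outlier$effect_size <= 1)
    }
  })
  invisible(spec)
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf(paste0("Generator spec: %d systems x %d replicas x %d frames, ",
                     "%d edges, %d states, seed %d\n"),
              x$n_systems, x$replicas_per_system, x$n_frames,
              nrow(x$states), ncol(x$states), x$seed))
  invisible(x)
}

# deterministic edge layout: n_edges distinct residue pairs over n_residues,
# sampled from the seeded stream already active in generate_ensemble
sample_edge_pairs <- function(n_edges, n_residues) {
  all_pairs <- which(upper.tri(diag(n_residues)), arr.ind = TRUE)
  if (n_edges > nrow(all_pairs))
    stop("more edges requested than residue pairs")
  sel <- all_pairs[sample.int(nrow(all_pairs), n_edges), , drop = FALSE]
  i <- pmin(sel[, 1L], sel[, 2L])
  j <- pmax(sel[, 1L], sel[, 2L])
  res_names <- sprintf("A:RES:%d", seq_len(n_residues))
  data.frame(a = i, b = j, res_a = res_names[i], res_b = res_names[j],
             stringsAsFactors = FALSE)
}

# random monotone piecewise-linear warp: knot fractions u (canonical) and v
# (replica); replica fraction -> canonical fraction is interp(v, u)
sample_warp_knots <- function(K, roughness) {
  u <- seq(0, 1, length.out = K)
  w <- 1 + roughness * runif(K - 1L, -0.9, 0.9)
  v <- c(0, cumsum(w) / sum(w))
  list(u = u, v = v)
}

warp_replica_to_canonical <- function(knots, frame, n_rep, n_canon) {
  fr <- if (n_rep == 1L) 0.5 else frame / (n_rep - 1L)
  cf <- approx(knots$v, knots$u, xout = fr, rule = 2)$y
  as.integer(round(cf * (n_canon - 1L)))
}

warp_canonical_to_replica <- function(knots, t, n_rep, n_canon) {
  cf <- if (n_canon == 1L) 0.5 else t / (n_canon - 1L)
  fr <- approx(knots$u, knots$v, xout = cf, rule = 2)$y
  as.integer(round(fr * (n_rep - 1L)))
}

#' Generate a synthetic contact ensemble with known ground truth
#'
#' @param spec a [generator_spec()].
#' @return list with `tables` (list of `contact_table`, one per replica,
#'   named `sys<k>_rep<r>`, each carrying a `system_id` attribute) and
#'   `truth` (a `ground_truth` list: per-replica warp knots and lengths,
#'   per-replica state boundaries, condition edge keys per system, the
#'   outlier replica id, canonical change points, and the edge layout).
#' @export
generate_ensemble <- function(spec) {
  validate_generator_spec(spec)
  with_seed(spec$seed, {
    n_edges <- nrow(spec$states)
    n_states <- ncol(spec$states)
    pairs <- sample_edge_pairs(n_edges, spec$n_residues)

    # per-system occupancy profiles
    profiles <- lapply(seq_len(spec$n_systems), function(s) {
      P <- spec$states
      if (!is.null(spec$condition_effects)) {
        for (u in seq_len(spec$n_systems)) {
          idx <- spec$condition_effects[[u]]
          P[idx, spec$condition_state] <-
            if (u == s) spec$condition_high else spec$condition_low
        }
      }
      P
    })

    state_of <- findInterval(seq_len(spec$n_frames) - 1L,
                             c(0L, spec$boundaries))

    tables <- list()
    warps <- list()
    rep_boundaries <- list()
    outlier_id <- NULL
    outlier_edges <- integer(0)
    # edges whose profile varies: bit-flip noise and the outlier perturbation
    # apply only to these, so the structurally invariant class stays exactly
    # invariant (occupancy 0 or 1 across the ensemble)
    variable <- which(apply(spec$states, 1L, function(p)
      any(p > 0 & p < 1) || length(unique(p)) > 1L))
    if (!is.null(spec$outlier)) {
      n_pert <- max(1L, round(spec$outlier$effect_size * length(variable)))
      outlier_edges <- sort(sample(variable, n_pert))
    }

    for (s in seq_len(spec$n_systems)) {
      for (r in seq_len(spec$replicas_per_system)) {
        id <- sprintf("sys%d_rep%d", s, r)
        n_rep <- spec$n_frames -
          if (spec$length_jitter > 0L)
            sample.int(spec$length_jitter + 1L, 1L) - 1L else 0L
        knots <- sample_warp_knots(spec$warp_knots, spec$warp_roughness)
        P <- profiles[[s]]
        is_outlier <- !is.null(spec$outlier) &&
          spec$outlier$system == s && spec$outlier$replica == r
        if (is_outlier) {
          P[outlier_edges, ] <- 1 - P[outlier_edges, ]
          outlier_id <- id
        }
        t_canon <- warp_replica_to_canonical(knots, seq_len(n_rep) - 1L,
                                             n_rep, spec$n_frames)
        st <- state_of[t_canon + 1L]
        prob <- t(P[, st, drop = FALSE])          # n_rep x n_edges
        occ <- matrix(runif(n_rep * n_edges), n_rep, n_edges) < prob
        if (spec$flip_noise > 0 && length(variable) > 0L) {
          flips <- matrix(FALSE, n_rep, n_edges)
          flips[, variable] <-
            matrix(runif(n_rep * length(variable)), n_rep) < spec$flip_noise
          occ <- xor(occ, flips)
        }
        hit <- which(occ, arr.ind = TRUE)
        df <- data.frame(frame = hit[, 1L] - 1L, type = "syn",
                         res_a = pairs$res_a[hit[, 2L]],
                         res_b = pairs$res_b[hit[, 2L]],
                         stringsAsFactors = FALSE)
        df <- df[order(df$frame, df$res_a, df$res_b), , drop = FALSE]
        rownames(df) <- NULL
        tab <- new_contact_table(df, id, n_rep)
        attr(tab, "system_id") <- sprintf("sys%d", s)
        tables[[id]] <- tab
        warps[[id]] <- list(knots = knots, n_rep = n_rep,
                            n_canon = spec$n_frames)
        rep_boundaries[[id]] <- vapply(spec$boundaries, function(b)
          warp_canonical_to_replica(knots, b, n_rep, spec$n_frames),
          integer(1))
      }
    }
    condition_keys <- if (!is.null(spec$condition_effects))
      lapply(spec$condition_effects, function(idx)
        pair_key(pairs$res_a[idx], pairs$res_b[idx])) else NULL
    truth <- structure(list(warps = warps, rep_boundaries = rep_boundaries,
                            condition_edges = condition_keys,
                            outlier = outlier_id,
                            outlier_edges = if (length(outlier_edges))
                              pair_key(pairs$res_a[outlier_edges],
                                       pairs$res_b[outlier_edges]) else NULL,
                            canonical_changepoints = spec$boundaries,
                            pairs = pairs),
                       class = "ground_truth")
    list(tables = tables, truth = truth)
  })
}

#' Default benchmark ensemble specification
#'
#' A documented three-condition benchmark sized after a targeted-MD-scale
#' study: 3 systems x 5 replicas x 500 canonical frames (replicas up to 20
#' frames shorter), 450 contacts over 120 residues, three latent states with
#' canonical boundaries at frames 150 and 300. A third of the contacts are
#' invariant (always present, removed by the entropy filter); the rest carry
#' state-dependent occupancies. Each system owns 25 condition-specific
#' contacts that switch on only in the middle state of that system, so
#' conditions share the flanking states and diverge transiently. One replica
#' of system 1 is a planted outlier with 30% of the variable contacts
#' profile-flipped.
#'
#' @param seed integer seed.
#' @return a `generator_spec`.
#' @export
default_benchmark_spec <- function(seed = 1L) {
  n_edges <- 450L
  n_states <- 3L
  n_invariant <- 150L
  n_condition <- 25L
  with_seed(seed + 7919L, {
    states <- matrix(runif(n_edges * n_states, 0.15, 0.85), n_edges, n_states)
    states[seq_len(n_invariant), ] <- 1          # invariant, entropy-pruned
    condition_effects <- split(
      n_invariant + seq_len(3L * n_condition),
      rep(1:3, each = n_condition))
  })
  generator_spec(n_systems = 3L, replicas_per_system = 5L, n_frames = 500L,
                 length_jitter = 20L, n_residues = 120L, states = states,
                 boundaries = c(150L, 300L),
                 condition_effects = unname(condition_effects),
                 condition_state = 2L, condition_high = 0.9,
                 condition_low = 0.1,
                 outlier = list(system = 1L, replica = 5L, effect_size = 0.3),
                 warp_knots = 8L, warp_roughness = 0.4, flip_noise = 0.02,
                 seed = seed)
}

#' Toy bead coordinates for exercising the coarse-grained builder
#'
#' A small synthetic bead layout (one bead per residue on a noisy line, with
#' a mild per-frame drift), sufficient to exercise [build_cg_contacts()] and
#' [rmsd_cost_matrix()]; it carries no physical realism.
#'
#' @param n_frames,n_beads layout size.
#' @param spacing mean bead spacing in angstrom.
#' @param drift per-frame random displacement scale in angstrom.
#' @param seed integer seed.
#' @return data.frame with columns `frame`, `chain`, `resname`, `resid`,
#'   `x`, `y`, `z`.
#' @export
make_toy_beads <- function(n_frames = 5L, n_beads = 12L, spacing = 4,
                           drift = 0.5, seed = 1L) {
  with_seed(seed, {
    base <- cbind(x = spacing * seq_len(n_beads),
                  y = runif(n_beads, -1, 1),
                  z = runif(n_beads, -1, 1))
    do.call(rbind, lapply(seq_len(n_frames) - 1L, function(f) {
      xyz <- base + matrix(rnorm(n_beads * 3, sd = drift), n_beads, 3)
      data.frame(frame = f, chain = "A", resname = "BEA",
                 resid = seq_len(n_beads),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 stringsAsFactors = FALSE)
    }))
  })
}
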