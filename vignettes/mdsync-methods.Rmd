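---
title: "Synchronizing MD trajectory ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronizing MD trajectory ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Independent molecular-dynamics (MD) replicas of the same system rarely pass
through comparable states at the same time: thermal noise desynchronizes
them, so frame-by-frame comparison across replicas (or across wild-type and
variant conditions) conflates timing differences with genuine mechanistic
differences. `mdsync` addresses this by describing each frame as a
residue-contact graph, embedding frames as fixed-length vectors, and
aligning replicas on the time axis before any comparison. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic benchmark does and does not
demonstrate.

## From frames to contact graphs

The unit of input is a per-frame, per-replica table of residue–residue
contacts (the tab-separated dialect produced by common contact-enumeration
tools: `frame, interaction_type, atom_1, atom_2`). Atom-level records are
collapsed to residue pairs; several interaction types between the same
residue pair in a frame count as one edge, because nothing downstream
distinguishes edge types — the type string is kept as metadata only. For
coarse-grained systems without contact tables, `build_cg_contacts()`
constructs contacts from bead coordinates: the node set is every residue
within 15 Å (inclusive) of a mutation site, and an edge is drawn between
nodes strictly closer than 6 Å in a frame. Node selection uses the first
frame as reference by default (`reference = "any"` keeps residues that ever
enter the radius); the first frame is the natural reference because all
replicas of a system start from a common equilibrated structure.

All replicas and systems under comparison share one *edge vocabulary* (the
sorted union of observed pairs) and hence one node set, held constant
across frames with isolated nodes kept. This is a requirement of the
embedding stage: token documents are only comparable when graphs live on a
common node universe.

## Entropy filtering

Each contact's occupancy $p$ (fraction of frames in which it is present,
pooled over all frames and replicas of an ensemble) is scored by the binary
Shannon entropy $H(p) = -p\log_2 p - (1-p)\log_2(1-p)$, in bits. Contacts
with $H$ below a cutoff (default 0.1 bits) are discarded: these are the
effectively invariant contacts, present in essentially all frames or
almost none ($p$ outside $[0.013, 0.987]$ at the default cutoff), which
carry no information about conformational transitions. An upper cutoff for
pruning extremely noisy contacts exists in `EntropyFilterSpec`-style usage
(`filter_edges(upper_cutoff = )`) but is off by default: at the default
setting only invariant contacts are removed.

Filtering is *ensemble-specific*: each system (condition) gets its own
entropy table, and the pipeline retains the union of the per-system
retained sets, so a contact that is informative in any condition stays in
the shared column space for all of them. Dense systems may warrant a higher
cutoff (e.g. 0.3 bits) to strip ubiquitous contacts more aggressively;
raising the cutoff can only shrink the retained set.

## Graph embedding

Each frame graph becomes a document of Weisfeiler–Lehman (WL) subtree
tokens: iteration 0 emits every node's residue identity; iteration $i$
emits per node a digest of its previous label and the sorted multiset of
its neighbours' previous labels. Three iterations are used by default,
capturing connectivity up to three contacts away; tokens from *all*
iterations are emitted, so coarse and fine neighbourhood scales coexist.
The digest is a 64-bit FNV-1a hash printed as 16 hex characters — stable
across runs and platforms, which makes documents reproducible without a
shared dictionary.

Documents from every replica and every system under comparison are
embedded *jointly* in one model, so all coordinates are commensurable;
per-system training is deliberately not offered. The model is a
distributed bag-of-tokens (PV-DBOW) objective with negative sampling: a
16-dimensional vector per frame is trained to predict the frame's tokens.
Training is single-threaded with an internal deterministic generator, so a
fixed seed gives bitwise-identical embeddings. Defaults: 16 dimensions,
100 epochs, initial learning rate 0.025 with linear decay, 5 negative
samples, and a minimum token count of 5. The minimum count matters more
than usual here: with 3 WL iterations over noisy contact graphs, roughly
half of all token occurrences are tokens seen exactly once in the whole
corpus; they carry no shared structure and would otherwise dominate the
vocabulary and the training cost. Dropping them follows standard
document-embedding practice.

PCA (`reduce_pca()`, retaining 90% variance by default) is provided for
visualization and clustering diagnostics only; alignment always operates
in the original embedding space.

## Alignment and consensus

Replicas are aligned with *dependent* dynamic time warping: one local cost
— the Euclidean distance over all 16 dimensions jointly — drives a single
warp path per pair. Backtrace ties are broken deterministically (diagonal,
then vertical, then horizontal). Normalized DTW scores divide the path
cost by the warp-path length by default; for equal-length series aligned
along the diagonal this reduces to the series length. `max(n, m)` and
`n + m` divisors are available (`normalization =`), since conventions
differ across the literature.

The consensus trajectory is a DTW barycenter (DBA): initialize with the
medoid replica (minimum summed DTW cost to the others) resampled to the
median replica length, then iterate "align every replica to the barycenter;
replace each barycenter point by the mean of all frames associated to it".
Internally the alignment and the monitored objective use squared-Euclidean
local costs: for that cost the mean update provably never increases the
objective, so the objective trace is guaranteed non-increasing and
convergence is monitored by relative decrease (tolerance $10^{-6}$, at most
30 iterations). The per-replica scores reported to the user are standard
Euclidean-cost DTW results against the final barycenter.

Outlier replicas are pruned iteratively: compute the barycenter, score
replicas by normalized DTW cost, and remove the worst replica while the
stop rule fires, recomputing after each removal (never below two
replicas). The default stop rule is a data-driven largest-gap criterion —
remove the worst replica while its cost exceeds the second worst by more
than the mean adjacent gap of the sorted costs — chosen because published
ensembles show pruning decisions driven by a conspicuous gap between the
worst and second-worst scores rather than by a fixed threshold. Fixed
threshold and fixed count rules are also exposed.

## Ensemble comparison

All replicas of all systems enter a pairwise normalized-DTW distance
matrix (outliers included by default, so their separation remains visible
in the dendrogram). Ward's hierarchical clustering is applied via the
Lance–Williams update on squared dissimilarities (the `ward.D2`
convention); DTW distances are not Euclidean, so Ward here is a standard
heuristic rather than a variance decomposition, and we document it as
such. The number of clusters is chosen by the largest gap between
consecutive merge heights (default) or by the elbow criterion (maximum
discrete curvature of the height profile, ties toward smaller $k$); if all
merge heights are equal the tree carries no cut information and $k = 1$ is
returned with a warning.

A descriptor-based baseline is included for benchmarking: a pairwise
frame-to-frame Cα-RMSD matrix (least RMSD after optimal rigid
superposition) fed to the same DTW recurrence via `dtw_from_cost()`,
followed by PAM k-medoids with silhouette-based selection of $k$. This
mirrors the common geometry-driven alignment protocol and reuses
everything downstream of the cost matrix.

## Divergence detection

Two deviation-profile modes are exposed, because the divergence of
interest can be replica-vs-consensus or condition-vs-condition:

* `deviation_profile()`: for each barycenter index, the Euclidean distance
  between the barycenter point and the mean of the replica frames
  associated to it by the warp path.
* `divergence_pair()`: align the best replica of each of two systems
  (lowest normalized cost to its own barycenter) and report the mean local
  distance along the warp path per frame of the first series. Static
  differences between systems appear as a roughly constant offset in this
  profile; transient, state-specific differences appear as windows of
  elevated distance.

Profiles are smoothed by a centered moving average (default window 25
frames, roughly 5% of a 500-frame trajectory; the window shrinks at the
boundaries so length is preserved) and segmented by PELT under a penalty
linear in the number of change points, with the within-segment sum of
squared deviations from the segment mean as cost. PELT's pruning is exact
for this cost, and the implementation is tested to coincide with the
unpruned $O(n^2)$ optimal-partitioning program.

One numerical choice deserves emphasis: the default penalty is the
BIC-like $2\hat\sigma^2\log L$, and $\hat\sigma^2$ is estimated from first
differences of the *unsmoothed* profile. A deviation profile records this
estimate at construction and smoothing carries it along. Estimating noise
after a width-$w$ moving average divides the apparent first-difference
variance by roughly $w^2$ while segment-level fluctuations shrink far
less, which makes the penalty negligible and shatters the profile into
dozens of spurious segments. For segmented windows, `contact_shift_table()`
pulls aligned indices back to raw frames through the warp maps and ranks
contacts by the difference in mean occupancy between the two groups,
optionally restricted to contacts touching a residue of interest (e.g. a
mutation site).

## The synthetic benchmark

`default_benchmark_spec()` defines the conditions used throughout the test
suite: 3 systems × 5 replicas × 500 canonical frames (each replica up to
20 frames shorter, mimicking runs that terminate early), 450 contacts over
120 residues, and three latent states with canonical boundaries at frames
150 and 300 — a three-phase structure at the scale of a targeted-MD
transport cycle. One third of the contacts are invariant (always present;
the entropy filter removes them), the rest carry state-dependent
occupancies drawn once from $U(0.15, 0.85)$. Each system owns 25
condition-specific contacts that switch on (occupancy 0.9 vs 0.1
elsewhere) only in the middle state of that system, so conditions share
the flanking states and diverge transiently — the situation the
change-point stage is meant to localize. Each replica reads the latent
states through its own random monotone piecewise-linear time warp (8
knots), emulating asynchronous sampling; presence bits are flipped i.i.d.
with probability 0.02 on the variable contacts. One replica of system 1
draws 30% of the variable contacts from a profile-flipped distribution —
the planted outlier. All ground truth (warps, per-replica state
boundaries, condition edges, outlier identity) is returned with the data.

What passing these tests shows: the pipeline recovers known cluster
structure, planted outliers, and planted divergence windows from data with
realistic occupancy noise, asynchronous timing, and variable lengths. What
it does not show: robustness to temporally correlated noise (the generator
flips bits independently), to force-field-level artifacts, or to contact
definitions other than the binary presence/absence used here; and the
generator plants discrete latent states, whereas real transitions can be
gradual. Conclusions about real MD data rest on the method, not on these
synthetic checks alone.

## Problem sizes and determinism

The test suite and the acceptance script run the full default benchmark
(15 replicas × ~500 frames; WL corpus ≈ 3.5M tokens, ≈ 1.8M after the
minimum-count filter), which completes in a few minutes on one core —
embedding dominates, DTW/DBA and PELT are seconds. Every stochastic stage
(generator, embedding trainer) consumes an explicit seed, training is
single-threaded by design, and the pipeline writes all numeric artifacts
in full precision, so identical configurations and seeds reproduce
byte-identical run directories.

## Known limitations

* Ward linkage on DTW distances is a pragmatic convention, not a model.
* The largest-gap pruning rule is a design choice; the field has no
  canonical stop criterion for consensus pruning.
* Graphs are unlabeled on edges; interaction types are not used.
* No Sakoe–Chiba band is applied by default; alignment is $O(nm)$ per
  pair.
* The change-point cost model is mean-shift only; variance-shift
  alternatives are out of scope.
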