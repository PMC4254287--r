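#' Estimate the geometric cluster-size parameter
#'
#' Cluster sizes (numbers of distinct species per cluster) are modelled as
#' geometric, `P(n) = (1 - p)^(n-1) * p` for `n >= 1`; the parameter is
#' estimated as the inverse of the sample mean cluster size.
#'
#' @param cluster_sizes Integer vector of observed cluster sizes (>= 1).
#' @return The estimate `p = 1 / mean(cluster_sizes)`.
#' @export
estimate_geometric_p <- function(cluster_sizes) {
  if (length(cluster_sizes) == 0) {
    stop("cannot estimate p from an empty size list", call. = FALSE)
  }
  stopifnot(all(cluster_sizes >= 1))
  1 / mean(cluster_sizes)
}

#' Geometric cluster-size model
#'
#' @param p Success parameter in (0, 1]; the mean cluster size is `1/p`
#'   before truncation.
#' @param max_size Largest permitted cluster size (a cluster cannot contain
#'   more distinct species than exist); sampling resamples until the draw is
#'   feasible, preserving the pmf shape below the cut.
#' @return A list of class `geometric_size_model`.
#' @export
geometric_size_model <- function(p, max_size) {
  stopifnot(is.numeric(p), length(p) == 1, p > 0, p <= 1)
  stopifnot(max_size >= 1)
  structure(list(p = p, max_size = as.integer(max_size)),
            class = "geometric_size_model")
}

#' Sample cluster sizes from a (truncated) geometric model
#'
#' @param n Number of draws.
#' @param model A `geometric_size_model`.
#' @return Integer vector of sizes in `1:model$max_size`.
#' @export
sample_cluster_sizes <- function(n, model) {
  stopifnot(inherits(model, "geometric_size_model"))
  if (model$p == 1) return(rep(1L, n))
  sizes <- 1L + stats::rgeom(n, model$p)
  bad <- which(sizes > model$max_size)
  while (length(bad) > 0) {
    sizes[bad] <- 1L + stats::rgeom(length(bad), model$p)
    bad <- bad[sizes[bad] > model$max_size]
  }
  sizes
}

#' Simulation configuration
#'
#' Bundles the three ingredients of the cluster simulator: relative sighting
#' frequencies of the species, the cluster-size distribution, and (for the
#' preference mode) the observed co-occurrence counts the swap step matches.
#'
#' @param frequencies Named non-negative vector of relative sighting
#'   frequencies (normalized internally).
#' @param n_occurrences Total number N of species occurrences to generate;
#'   set to the observed total to reproduce observed sighting frequencies
#'   and cluster numbers on average.
#' @param size_model A `geometric_size_model`; defaults to the geometric
#'   model with parameter `p` truncated at the number of species.
#' @param p Convenience alternative to `size_model`.
#' @param k Number of preference swaps (step 3); the study value is 10000.
#' @param target_counts Observed `co_occurrence_counts` over the same
#'   species, required when `include_preferences = TRUE`.
#' @param include_preferences Run swap step 3 after cluster formation.
#' @param n_reps Replicates for [simulate_betweenness_ranks()].
#' @param seed Optional integer seed governing the whole simulation.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(frequencies, n_occurrences, size_model = NULL,
                              p = NULL, k = 10000, target_counts = NULL,
                              include_preferences = FALSE, n_reps = 1000,
                              seed = NULL) {
  stopifnot(is.numeric(frequencies), length(frequencies) >= 1,
            all(frequencies >= 0), sum(frequencies) > 0)
  if (is.null(names(frequencies))) {
    stop("frequencies must be named by species id", call. = FALSE)
  }
  frequencies <- frequencies / sum(frequencies)
  if (is.null(size_model)) {
    if (is.null(p)) stop("supply either size_model or p", call. = FALSE)
    size_model <- geometric_size_model(p, max_size = length(frequencies))
  }
  stopifnot(inherits(size_model, "geometric_size_model"))
  stopifnot(n_occurrences >= 1, k >= 0, n_reps >= 1)
  if (include_preferences) {
    if (is.null(target_counts)) {
      stop("include_preferences = TRUE requires target_counts", call. = FALSE)
    }
    if (!setequal(rownames(target_counts), names(frequencies))) {
      stop("target_counts species do not match frequencies", call. = FALSE)
    }
  }
  structure(list(frequencies = frequencies,
                 n_occurrences = as.integer(n_occurrences),
                 size_model = size_model, k = as.integer(k),
                 target_counts = target_counts,
                 include_preferences = include_preferences,
                 n_reps = as.integer(n_reps), seed = seed),
            class = "simulation_config")
}

#' Generate abundance-only (preference-free) clusters
#'
#' Steps 1 and 2 of the cluster simulator. Step 1 draws N species
#' occurrences i.i.d. from the relative frequencies. Step 2 forms clusters:
#' repeatedly draw a target size from the size model and fill the cluster
#' with occurrences drawn without replacement from the remaining pool,
#' never placing a species twice in one cluster, until all N occurrences
#' are assigned. When the remaining pool cannot supply the drawn size
#' without duplication the cluster closes at the largest feasible size.
#' On average the output reproduces the input frequencies and the target
#' cluster-size distribution.
#'
#' @param config A `simulation_config`.
#' @return A list of character vectors, each the species set of one cluster;
#'   of class `simulated_clusters` with a `species` attribute.
#' @export
generate_null_clusters <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  .generate_clusters_impl(config)
}

# Core of steps 1-2, without touching the seed (so replicate loops can run
# on one RNG stream).
.generate_clusters_impl <- function(config, phi = NULL) {
  freqs <- config$frequencies
  species <- names(freqs)
  S <- length(freqs)
  n <- config$n_occurrences

  # step 1: i.i.d. occurrence draws, kept as per-species remaining counts
  draws <- sample.int(S, n, replace = TRUE, prob = freqs)
  remaining <- tabulate(draws, nbins = S)

  clusters <- vector("list", n)  # at most n clusters
  n_clusters <- 0L
  total_left <- n
  while (total_left > 0L) {
    target <- sample_cluster_sizes(1L, config$size_model)
    members <- integer(0)
    while (length(members) < target) {
      weights <- remaining
      if (length(members) > 0) weights[members] <- 0
      if (!is.null(phi) && length(members) > 0) {
        # preference reweighting: odds multiplied by planted pairwise factors
        mult <- apply(phi[, members, drop = FALSE], 1, prod)
        weights <- weights * mult
      }
      if (all(weights == 0)) break  # no eligible species: close the cluster
      pick <- sample.int(S, 1L, prob = weights)
      members <- c(members, pick)
      remaining[pick] <- remaining[pick] - 1L
      total_left <- total_left - 1L
    }
    n_clusters <- n_clusters + 1L
    clusters[[n_clusters]] <- members
  }
  clusters <- clusters[seq_len(n_clusters)]
  out <- lapply(clusters, function(ix) species[ix])
  structure(out, species = species, class = "simulated_clusters")
}

# Sizes-first variant used when the caller fixes the number of clusters:
# draw the n_clusters target sizes up front, build the occurrence pool with
# exactly matching total size, then fill with the same weighted-without-
# replacement rule (optionally phi-reweighted). A cluster that cannot reach
# its target size without duplicating a species closes early; its unused
# tokens stay in the pool for later clusters.
.generate_clusters_sized <- function(freqs, size_model, n_clusters,
                                     phi = NULL) {
  species <- names(freqs)
  S <- length(freqs)
  sizes <- sample_cluster_sizes(n_clusters, size_model)
  n <- sum(sizes)
  draws <- sample.int(S, n, replace = TRUE, prob = freqs)
  remaining <- tabulate(draws, nbins = S)
  clusters <- vector("list", n_clusters)
  for (ci in seq_len(n_clusters)) {
    target <- sizes[ci]
    members <- integer(0)
    while (length(members) < target) {
      weights <- remaining
      if (length(members) > 0) weights[members] <- 0
      if (!is.null(phi) && length(members) > 0) {
        mult <- apply(phi[, members, drop = FALSE], 1, prod)
        weights <- weights * mult
      }
      if (all(weights == 0)) break
      pick <- sample.int(S, 1L, prob = weights)
      members <- c(members, pick)
      remaining[pick] <- remaining[pick] - 1L
    }
    clusters[[ci]] <- members
  }
  out <- lapply(clusters, function(ix) species[ix])
  structure(out, species = species, class = "simulated_clusters")
}

# clusters (list of species-id vectors) -> binary occurrence matrix
clusters_to_matrix <- function(clusters, species) {
  n <- length(clusters)
  mat <- matrix(0L, nrow = n, ncol = length(species),
                dimnames = list(NULL, species))
  lens <- lengths(clusters)
  rows <- rep.int(seq_len(n), lens)
  cols <- match(unlist(clusters, use.names = FALSE), species)
  mat[cbind(rows, cols)] <- 1L
  mat
}

#' Co-occurrence counts of simulated clusters
#'
#' @param clusters A `simulated_clusters` list (or any list of species-id
#'   vectors).
#' @param species Species universe for the count matrix; defaults to the
#'   generator's species set.
#' @return A `co_occurrence_counts` matrix.
#' @export
cluster_counts <- function(clusters, species = attr(clusters, "species")) {
  if (is.null(species)) {
    stop("supply the species universe for the counts", call. = FALSE)
  }
  mat <- clusters_to_matrix(clusters, species)
  w <- crossprod(mat)
  diag(w) <- 0L
  storage.mode(w) <- "integer"
  class(w) <- c("co_occurrence_counts", class(w))
  w
}

#' Association-difference score between two cluster sets
#'
#' Each co-occurrence matrix is first normalized by its own total number of
#' co-occurrences over all pairs (an all-singleton set normalizes to all
#' zero), giving relative association strengths; the score is the sum over
#' unordered pairs of squared differences between the two relative matrices.
#' Scaling either matrix by a constant leaves the score unchanged.
#'
#' @param sim_counts,obs_counts `co_occurrence_counts` over the same species
#'   set.
#' @return A non-negative number; 0 iff the relative strengths coincide.
#' @export
association_difference <- function(sim_counts, obs_counts) {
  ws <- unclass(sim_counts); wo <- unclass(obs_counts)
  if (!identical(dim(ws), dim(wo)) ||
      !setequal(rownames(ws), rownames(wo))) {
    stop("species sets of the two count matrices do not match", call. = FALSE)
  }
  wo <- wo[rownames(ws), rownames(ws)]
  rel <- function(w) {
    tot <- sum(w[upper.tri(w)])
    if (tot > 0) w / tot else w * 0
  }
  ds <- rel(ws) - rel(wo)
  sum(ds[upper.tri(ds)]^2)
}

#' Preference swaps (simulator step 3)
#'
#' Performs `k` proposals, each picking two distinct clusters and one species
#' occurrence in each and swapping them. A proposal is rejected (immediately
#' reversed) if it would place a species twice in one cluster or strictly
#' increase the association-difference score against the observed counts;
#' ties are accepted. Cluster sizes and per-species occurrence totals are
#' conserved, and the difference score never increases, pulling the
#' simulated co-occurrence structure toward the observed one.
#'
#' @param clusters A `simulated_clusters` list with at least two clusters.
#' @param target_counts Observed `co_occurrence_counts` over the generator's
#'   species set.
#' @param k Number of proposals (`k = 0` returns the input unchanged).
#' @return The updated `simulated_clusters` (same number and sizes of
#'   clusters, same per-species totals) with attributes `d_trace` (the
#'   difference score after each proposal) and `accepted`.
#' @export
apply_preference_swaps <- function(clusters, target_counts, k) {
  stopifnot(k >= 0)
  species <- attr(clusters, "species")
  if (is.null(species)) species <- rownames(target_counts)
  if (!setequal(rownames(target_counts), species)) {
    stop("target_counts species do not match the clusters", call. = FALSE)
  }
  if (k == 0) return(clusters)
  if (length(clusters) < 2) {
    stop("need at least two clusters to swap", call. = FALSE)
  }
  mat <- clusters_to_matrix(clusters, species)
  wt <- unclass(target_counts)[species, species]
  tot <- sum(wt[upper.tri(wt)])
  rel <- if (tot > 0) wt / tot else wt * 0
  res <- .preference_swaps(mat, rel, as.integer(k))
  m <- res$matrix
  out <- lapply(seq_len(nrow(m)), function(i) species[which(m[i, ] == 1L)])
  structure(out, species = species, d_trace = res$d_trace,
            accepted = res$accepted, class = "simulated_clusters")
}

#' Replicate betweenness-rank percentiles
#'
#' Runs the simulator `n_reps` times; for each replicate builds the weighted
#' co-occurrence network and computes betweenness ranks. In abundance-only
#' mode (`include_preferences = FALSE`) the replicates show what network
#' positions relative abundance alone produces; in preference mode step 3
#' additionally matches the observed relative association strengths. The
#' spread of ranks over replicates measures the robustness of observed
#' network positions.
#'
#' @param config A `simulation_config`; its `seed` (if any) is set once at
#'   the start, so the whole replicate set is reproducible.
#' @return A `data.frame` of class `rank_percentiles` with columns
#'   `species`, `mean_rank`, `p5`, `p95` (5% and 95% percentiles of the
#'   replicate ranks, inverse-ECDF convention so that two replicates give
#'   min and max) and a `mode` attribute.
#' @export
simulate_betweenness_ranks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_reps < 2) {
    stop("need at least two replicates for percentiles", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  species <- names(config$frequencies)
  ranks <- matrix(NA_real_, nrow = config$n_reps, ncol = length(species),
                  dimnames = list(NULL, species))
  for (r in seq_len(config$n_reps)) {
    clusters <- .generate_clusters_impl(config)
    if (config$include_preferences) {
      clusters <- apply_preference_swaps(clusters, config$target_counts,
                                         config$k)
    }
    counts <- cluster_counts(clusters, species)
    net <- network_from_counts(counts, min_weight = 1)
    ranks[r, ] <- betweenness_ranks(betweenness_scores(net))[species]
  }
  out <- data.frame(species = species,
                    mean_rank = colMeans(ranks),
                    p5 = apply(ranks, 2, quantile, probs = 0.05, type = 1),
                    p95 = apply(ranks, 2, quantile, probs = 0.95, type = 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mode") <- if (config$include_preferences) "preference"
                       else "abundance_only"
  attr(out, "n_reps") <- config$n_reps
  class(out) <- c("rank_percentiles", "data.frame")
  out
}
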