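# Shared permutation engine for the two group-size tests. The statistic is
# the difference of context medians; the permutation scheme shuffles the
# species' own group-size list over the fixed context labels, conserving the
# pooled multiset of sizes and hence the species' total count of individuals.
perm_median_engine <- function(sizes, in_context, n_perm, seed,
                               exhaustive_limit = 20000) {
  stopifnot(length(sizes) == length(in_context))
  k <- length(sizes)
  n1 <- sum(in_context)
  n0 <- k - n1
  if (n1 == 0 || n0 == 0) {
    return(list(testable = FALSE, p = NA_real_, observed_stat = NA_real_,
                median_context = if (n1 > 0) median(sizes[in_context]) else NA_real_,
                median_other = if (n0 > 0) median(sizes[!in_context]) else NA_real_,
                n_context = n1, n_other = n0, n_perm = 0L, exhaustive = FALSE))
  }
  obs <- median(sizes[in_context]) - median(sizes[!in_context])
  tol <- 1e-9
  n_comb <- choose(k, n1)
  if (n_comb <= exhaustive_limit) {
    idx <- combn(k, n1)
    stats <- apply(idx, 2, function(ii) {
      median(sizes[ii]) - median(sizes[-ii])
    })
    p <- mean(abs(stats) >= abs(obs) - tol)
    n_used <- ncol(idx)
    exhaustive <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      ii <- sample.int(k, n1)
      stat <- median(sizes[ii]) - median(sizes[-ii])
      if (abs(stat) >= abs(obs) - tol) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    n_used <- n_perm
    exhaustive <- FALSE
  }
  list(testable = TRUE, p = p, observed_stat = obs,
       median_context = median(sizes[in_context]),
       median_other = median(sizes[!in_context]),
       n_context = n1, n_other = n0, n_perm = n_used,
       exhaustive = exhaustive)
}

groupsize_result <- function(species, context, engine, seed) {
  structure(c(list(species = species, context = context, seed = seed), engine),
            class = "group_size_test_result")
}

#' @export
print.group_size_test_result <- function(x, ...) {
  if (!x$testable) {
    cat(sprintf("Group-size test for %s (%s): untestable (context sizes %d/%d)\n",
                x$species, x$context, x$n_context, x$n_other))
  } else {
    cat(sprintf(
      "Group-size test for %s (%s): medians %.1f vs %.1f, two-sided p = %.4g (%s, n = %d)\n",
      x$species, x$context, x$median_context, x$median_other, x$p,
      if (x$exhaustive) "exhaustive" else "Monte Carlo", x$n_perm))
  }
  invisible(x)
}

#' Do conspecific group sizes differ between single- and mixed-species
#' clusters?
#'
#' Permutation test on one species' sighting series. The test statistic is
#' `median(group sizes in mixed clusters) - median(group sizes in
#' single-species clusters)`; the null distribution is obtained by permuting
#' the species' observed group sizes over the fixed context labels, which
#' keeps the species' total number of observed individuals constant. The
#' two-sided p-value uses the absolute statistic. When the number of label
#' assignments is small the test enumerates all of them exactly; otherwise it
#' uses add-one-corrected Monte Carlo.
#'
#' @param series A `sighting_series` (see [sighting_series()]).
#' @param n_perm Monte Carlo permutations (ignored in exhaustive mode).
#' @param seed Optional integer seed for Monte Carlo mode.
#' @return A `group_size_test_result`; if either context has no occurrences
#'   the result is explicitly marked untestable (`testable = FALSE`, `p = NA`)
#'   rather than returning a p-value.
#' @export
test_group_size_context <- function(series, n_perm = 1e5, seed = NULL) {
  stopifnot(inherits(series, "sighting_series"))
  engine <- perm_median_engine(series$occurrences$group_size,
                               series$occurrences$is_mixed, n_perm, seed)
  groupsize_result(series$species_id, "single_vs_mixed", engine, seed)
}

#' Do conspecific group sizes depend on the presence of a specific partner?
#'
#' Same permutation machinery as [test_group_size_context()], with contexts
#' defined by whether the named partner species was present in the cluster.
#' Note the design is asymmetric: testing species A against partner B uses
#' A's group sizes and is not required to agree with testing B against A.
#'
#' @param series A `sighting_series`.
#' @param partner A partner species id.
#' @param n_perm,seed As in [test_group_size_context()].
#' @return A `group_size_test_result`; untestable when the partner is present
#'   in all, or none, of the species' occurrences.
#' @export
test_group_size_dyad <- function(series, partner, n_perm = 1e5, seed = NULL) {
  stopifnot(inherits(series, "sighting_series"))
  stopifnot(is.character(partner), length(partner) == 1)
  present <- vapply(series$partners, function(p) partner %in% p, logical(1))
  engine <- perm_median_engine(series$occurrences$group_size, present,
                               n_perm, seed)
  groupsize_result(series$species_id, paste0("partner:", partner),
                   engine, seed)
}
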