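#' Margin-preserving chain state
#'
#' Wraps an occurrence matrix as the state of a Markov chain on the set of
#' binary matrices sharing its row and column sums. The chain moves by
#' checkerboard flips: a uniformly proposed (row pair, column pair) whose 2x2
#' submatrix alternates 0/1 is flipped to the opposite alternation; any other
#' proposal leaves the state unchanged. Row sums (cluster sizes) and column
#' sums (per-species sighting counts) are conserved exactly at every step.
#' With `stratify_by_habitat = TRUE` only row pairs from the same habitat may
#' be flipped, conditioning the null on the per-habitat cluster composition.
#'
#' @param matrix An `occurrence_matrix` (or any binary integer matrix).
#' @param stratify_by_habitat Restrict flips to same-habitat row pairs
#'   (requires the matrix to carry a `habitat` attribute).
#' @return A list of class `margin_chain_state` with elements `matrix`,
#'   `step_count` and `strata` (integer vector, or `NULL`).
#' @export
margin_chain_state <- function(matrix, stratify_by_habitat = FALSE) {
  mat <- as_binary_matrix(matrix)
  strata <- NULL
  if (stratify_by_habitat) {
    habitat <- attr(matrix, "habitat")
    if (is.null(habitat)) {
      stop("matrix carries no habitat attribute; cannot stratify", call. = FALSE)
    }
    strata <- as.integer(factor(habitat))
  }
  structure(list(matrix = mat, step_count = 0L, strata = strata),
            class = "margin_chain_state")
}

as_binary_matrix <- function(matrix) {
  mat <- unclass(matrix)
  attr(mat, "habitat") <- NULL
  if (!is.matrix(mat) || !all(mat %in% c(0L, 1L))) {
    stop("expected a binary matrix", call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  mat
}

#' One checkerboard proposal
#'
#' Reference single-step implementation of the chain move (the bulk runs use
#' a compiled kernel; see [randomize_occurrences()]). Proposes a uniformly
#' random row pair and column pair; flips the 2x2 submatrix if it is a
#' checkerboard and, under stratification, both rows share a stratum.
#'
#' @param state A `margin_chain_state`.
#' @return The updated `margin_chain_state` (step count incremented whether
#'   or not the proposal was accepted).
#' @export
checkerboard_step <- function(state) {
  stopifnot(inherits(state, "margin_chain_state"))
  m <- state$matrix
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("chain requires at least 2 rows and 2 columns", call. = FALSE)
  }
  rows <- sample.int(nrow(m), 2)
  cols <- sample.int(ncol(m), 2)
  ok_stratum <- is.null(state$strata) ||
    state$strata[rows[1]] == state$strata[rows[2]]
  sub <- m[rows, cols]
  if (ok_stratum &&
      ((sub[1, 1] == 1 && sub[2, 2] == 1 && sub[1, 2] == 0 && sub[2, 1] == 0) ||
       (sub[1, 1] == 0 && sub[2, 2] == 0 && sub[1, 2] == 1 && sub[2, 1] == 1))) {
    m[rows, cols] <- 1L - sub
    state$matrix <- m
  }
  state$step_count <- state$step_count + 1L
  state
}

#' Randomize an occurrence matrix by checkerboard flips
#'
#' Runs the margin-preserving chain for a fixed number of proposals and
#' returns the resulting matrix. Used directly for conservation checks and
#' as the engine behind [bc_pvalue()].
#'
#' @param matrix Binary matrix (an `occurrence_matrix` works as-is).
#' @param nsteps Number of proposals.
#' @param stratify_by_habitat Restrict flips to same-habitat row pairs.
#' @param seed Optional integer seed (set locally before the run).
#' @return The randomized matrix; same dimensions, dimnames, row and column
#'   sums as the input.
#' @export
randomize_occurrences <- function(matrix, nsteps, stratify_by_habitat = FALSE,
                                  seed = NULL) {
  state <- margin_chain_state(matrix, stratify_by_habitat)
  if (!is.null(seed)) set.seed(seed)
  strata <- if (is.null(state$strata)) integer(0) else state$strata
  out <- .chain_run(state$matrix, as.integer(nsteps), strata)
  dimnames(out) <- dimnames(state$matrix)
  out
}

#' Besag-Clifford sequential Monte Carlo p-value
#'
#' Computes a valid Monte Carlo p-value for an arbitrary test statistic of a
#' binary occurrence matrix under the fixed-margin null (all matrices with
#' the observed row and column sums equally likely), without requiring chain
#' convergence. The serial scheme is used: the observed matrix is placed at
#' a uniformly random position U of a stationary path of m + 1 states, by
#' running the chain twice from the observed matrix - once for `U * thin`
#' proposals (the backward half of the path, realized as a forward run
#' because the proposal kernel is symmetric and the chain reversible) and
#' once for `(m - U) * thin` proposals - recording the statistic every
#' `thin` proposals. The upper-tail p-value is
#' `(1 + #{T_i >= T_obs}) / (m + 1)`; the lower tail mirrors it. Ties count
#' as exceedances in both tails (conservative), and the add-one correction
#' means a p-value is never 0.
#'
#' @param matrix An `occurrence_matrix` (or binary integer matrix).
#' @param statistic Function taking the matrix and returning a numeric scalar
#'   or a named numeric vector. A vector-valued statistic yields one test per
#'   component, all evaluated on the same sampled chain states.
#' @param m Number of sampled states (p-value resolution is `1/(m+1)`).
#' @param thin Proposals between recorded states; defaults to the number of
#'   matrix cells (one expected sweep).
#' @param seed Optional integer seed.
#' @param stratify_by_habitat Restrict flips to same-habitat row pairs,
#'   conditioning the null on per-habitat cluster composition.
#' @return For a scalar statistic, a `bc_test_result` list with elements
#'   `observed_stat`, `p_upper`, `p_lower`, `m`, `thin`, `n_steps`,
#'   `n_exceed_upper`, `n_exceed_lower`, `seed`. For a vector statistic, a
#'   named list of `bc_test_result`s.
#' @references Besag, J. and Clifford, P. (1989) Generalized Monte Carlo
#'   significance tests. Biometrika 76, 633-642.
#' @export
bc_pvalue <- function(matrix, statistic, m = 1000, thin = NULL, seed = NULL,
                      stratify_by_habitat = FALSE) {
  stopifnot(is.function(statistic), m >= 1)
  state <- margin_chain_state(matrix, stratify_by_habitat)
  if (nrow(state$matrix) < 2 || ncol(state$matrix) < 2) {
    stop("chain requires at least 2 rows and 2 columns", call. = FALSE)
  }
  if (is.null(thin)) thin <- length(state$matrix)
  stopifnot(thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  strata <- if (is.null(state$strata)) integer(0) else state$strata
  dn <- dimnames(state$matrix)

  eval_stat <- function(mat, where) {
    dimnames(mat) <- dn
    out <- tryCatch(statistic(mat), error = function(e) {
      stop("statistic failed on ", where, " state: ", conditionMessage(e),
           call. = FALSE)
    })
    if (!is.numeric(out) || length(out) < 1 || any(!is.finite(out))) {
      stop("statistic must return finite numeric value(s)", call. = FALSE)
    }
    out
  }

  t_obs <- eval_stat(state$matrix, "observed")
  n_stat <- length(t_obs)

  u <- sample.int(m + 1L, 1L) - 1L  # position of the data: uniform {0..m}
  samples <- matrix(NA_real_, nrow = n_stat, ncol = m)
  col <- 0L
  for (half_len in c(u, m - u)) {
    cur <- state$matrix
    for (i in seq_len(half_len)) {
      cur <- .chain_run(cur, as.integer(thin), strata)
      col <- col + 1L
      samples[, col] <- eval_stat(cur, "sampled")
    }
  }

  results <- lapply(seq_len(n_stat), function(j) {
    n_up <- sum(samples[j, ] >= t_obs[j])
    n_lo <- sum(samples[j, ] <= t_obs[j])
    structure(list(observed_stat = unname(t_obs[j]),
                   p_upper = (1 + n_up) / (m + 1),
                   p_lower = (1 + n_lo) / (m + 1),
                   m = m, thin = thin,
                   n_steps = as.integer(m * thin),
                   n_exceed_upper = n_up, n_exceed_lower = n_lo,
                   seed = seed),
              class = "bc_test_result")
  })
  if (n_stat == 1) {
    results[[1]]
  } else {
    names(results) <- names(t_obs)
    results
  }
}

#' @export
print.bc_test_result <- function(x, ...) {
  cat("Besag-Clifford randomization test\n")
  cat("  observed statistic:", x$observed_stat, "\n")
  cat(sprintf("  p_upper = %.4g, p_lower = %.4g  (m = %d, thin = %d)\n",
              x$p_upper, x$p_lower, x$m, x$thin))
  invisible(x)
}
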