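# Seed priors, the random walk with restart, and ranked-pair selection.

#' Does an evidence vector qualify as a reliable seed?
#'
#' A fingerprint seeds the walk when its vector shows membership in at
#' least `min_db` curated interaction databases (nonzero indicator
#' components) and strictly more than half of all components are nonzero.
#'
#' @param v Named numeric evidence vector (`PAIR_VECTOR_COMPONENTS` order).
#' @param indicators Component names counting as database-membership
#'   indicators.
#' @param min_db Minimum number of nonzero indicators.
#' @return `TRUE` or `FALSE`.
#' @export
is_reliable_seed <- function(v, indicators = c("EPPI1", "EPPI2", "TAP1", "TAP5"),
                             min_db = 2L) {
  if (is.null(names(v))) names(v) <- PAIR_VECTOR_COMPONENTS
  stopifnot(all(indicators %in% names(v)))
  sum(v[indicators] != 0) >= min_db && sum(v != 0) > length(v) / 2
}

#' Seed prior probabilities over fingerprints
#'
#' Fingerprints passing the reliability rule share equal prior mass
#' 1/|seeds|; all others start at 0. The walk is linear in the prior, so
#' rankings are identical to any other uniform seed mass.
#'
#' @param table A `fingerprint_table`.
#' @param indicators,min_db Passed to [is_reliable_seed()].
#' @return Numeric prior vector over fingerprints (sums to 1), with the
#'   seed IDs in attribute `"seeds"`.
#' @export
seed_priors <- function(table, indicators = c("EPPI1", "EPPI2", "TAP1", "TAP5"),
                        min_db = 2L) {
  stopifnot(inherits(table, "fingerprint_table"))
  V <- table$vectors
  ind <- match(indicators, colnames(V))
  if (anyNA(ind)) stop("unknown indicator component(s)")
  half <- ncol(V) / 2
  is_seed <- rowSums(V[, ind, drop = FALSE] != 0) >= min_db &
    rowSums(V != 0) > half
  if (!any(is_seed)) {
    stop("no fingerprint satisfies the seed rule; relax `indicators`/`min_db`")
  }
  f0 <- as.numeric(is_seed) / sum(is_seed)
  attr(f0, "seeds") <- which(is_seed) - 1L
  f0
}

#' Random walk with restart to the steady state
#'
#' Iterates F_r = (1 - alpha) M F_{r-1} + alpha F_0 from F_1 = F_0 until
#' the L1 difference between successive iterates falls below `tol`. `M` is
#' the row-normalized adjacency of the similarity graph and is applied on
#' the left exactly as written, without renormalizing between iterations.
#'
#' @param M Row-stochastic (sparse or dense) transition matrix.
#' @param f0 Prior probability vector.
#' @param alpha Restart probability in (0, 1\].
#' @param tol L1 convergence threshold.
#' @param max_iter Iteration cap; reaching it raises an error that reports
#'   the last residual.
#' @return List with `posterior`, `iterations` (number of update steps),
#'   `l1_diff` (final step difference), and `diffs` (the full step-
#'   difference trace).
#' @export
random_walk_with_restart <- function(M, f0, alpha = 0.8, tol = 1e-6,
                                     max_iter = 10000L) {
  stopifnot(alpha > 0, alpha <= 1, tol > 0, length(f0) == nrow(M))
  f_prev <- as.numeric(f0)
  diffs <- numeric(0)
  for (r in seq_len(max_iter)) {
    f <- (1 - alpha) * as.numeric(M %*% f_prev) + alpha * as.numeric(f0)
    dif <- sum(abs(f - f_prev))
    diffs <- c(diffs, dif)
    f_prev <- f
    if (dif < tol) {
      return(list(posterior = f, iterations = r, l1_diff = dif, diffs = diffs))
    }
  }
  stop(sprintf(
    "random walk did not converge in %d iterations (last L1 residual %.3g)",
    max_iter, diffs[length(diffs)]
  ))
}

#' Score every pair with its fingerprint's posterior and rank
#'
#' Each pair inherits the steady-state probability of its fingerprint;
#' pairs are sorted by descending score with ties broken by canonical pair
#' ID. Seed fingerprints' pairs take part in the ranking like any other.
#'
#' @param posterior Steady-state probability vector over fingerprints.
#' @param table The `fingerprint_table` the walk was run on.
#' @return `data.frame` with `protein_a`, `protein_b`, `score`,
#'   `fingerprint` (0-based ID), in rank order.
#' @export
score_and_rank_pairs <- function(posterior, table) {
  stopifnot(inherits(table, "fingerprint_table"),
            length(posterior) == length(table$id))
  fid <- table$pair_fingerprint
  score <- as.numeric(posterior)[fid + 1L]
  out <- data.frame(
    protein_a = table$pairs$protein_a,
    protein_b = table$pairs$protein_b,
    score = score,
    fingerprint = fid,
    stringsAsFactors = FALSE
  )
  o <- radix_order(-out$score, out$protein_a, out$protein_b)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the top-ranked pairs as the reconstructed network
#'
#' @param ranked Ranked pair table from [score_and_rank_pairs()].
#' @param top_n Number of edges to keep (more than available keeps all).
#' @return `data.frame` with `protein_a`, `protein_b`, `weight` — the
#'   reconstructed weighted network.
#' @export
select_top <- function(ranked, top_n) {
  stopifnot(top_n >= 0)
  out <- head(ranked, top_n)
  data.frame(
    protein_a = out$protein_a, protein_b = out$protein_b,
    weight = out$score, stringsAsFactors = FALSE
  )
}
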