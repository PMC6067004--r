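# Evaluation: neighborhood-affinity matching of predicted against benchmark
# complexes, hypergeometric functional homogeneity, and the GO
# edge-relevance proportion of a reconstructed network.

#' Neighborhood affinity between two protein sets
#'
#' NA(p, b) = |p intersect b|^2 / (|p| * |b|): 1 for identical sets, 0 for
#' disjoint ones, symmetric in its arguments.
#'
#' @param p,b Non-empty character vectors of protein IDs.
#' @return Value in \[0, 1\].
#' @export
na_score <- function(p, b) {
  p <- unique(p)
  b <- unique(b)
  if (!length(p) || !length(b)) stop("neighborhood affinity of an empty set")
  length(intersect(p, b))^2 / (length(p) * length(b))
}

#' Count matched predicted and benchmark complexes
#'
#' A predicted complex counts as matched when some benchmark complex
#' reaches affinity >= `omega` with it, and vice versa.
#'
#' @param P List of predicted complexes (character vectors).
#' @param B List of benchmark complexes.
#' @param omega Match threshold in (0, 1\].
#' @return Integer vector `c(Ncp, Ncb)`.
#' @export
match_counts <- function(P, B, omega = 0.25) {
  stopifnot(omega > 0, omega <= 1)
  if (!length(P) || !length(B)) return(c(Ncp = 0L, Ncb = 0L))
  M <- matrix(0, length(P), length(B))
  for (i in seq_along(P)) {
    for (j in seq_along(B)) M[i, j] <- na_score(P[[i]], B[[j]])
  }
  hit <- M >= omega
  c(Ncp = sum(rowSums(hit) > 0), Ncb = sum(colSums(hit) > 0))
}

#' Precision, recall and F-value of a complex prediction
#'
#' Precision = Ncp/|P|, Recall = Ncb/|B|,
#' F = 2 * Precision * Recall / (Precision + Recall) with the 0/0 case
#' defined as 0. An empty prediction set yields all-zero scores (so
#' parameter sweeps never crash); an empty benchmark is an error.
#'
#' @inheritParams match_counts
#' @return An `eval_summary` list: `n_predicted`, `n_benchmark`, `ncp`,
#'   `ncb`, `precision`, `recall`, `f_value`, `omega`.
#' @export
precision_recall_f <- function(P, B, omega = 0.25) {
  if (!length(B)) stop("a non-empty benchmark complex set is required")
  counts <- match_counts(P, B, omega)
  precision <- if (length(P)) counts[["Ncp"]] / length(P) else 0
  recall <- counts[["Ncb"]] / length(B)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(n_predicted = length(P), n_benchmark = length(B),
         ncp = counts[["Ncp"]], ncb = counts[["Ncb"]],
         precision = precision, recall = recall, f_value = f, omega = omega),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "<eval_summary> %d predicted vs %d benchmark (omega = %g)\n  matched: %d / %d  precision %.4f  recall %.4f  F %.4f\n",
    x$n_predicted, x$n_benchmark, x$omega, x$ncp, x$ncb,
    x$precision, x$recall, x$f_value
  ))
  invisible(x)
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability that a cluster of size `C_size`, drawn from a network of
#' `V_size` proteins of which `F_size` belong to a functional group,
#' contains at least `k` group members:
#' 1 - sum_(i=0)^(k-1) choose(F, i) choose(V-F, C-i) / choose(V, C).
#' Evaluated through the log-space hypergeometric CDF for stability;
#' vectorized over `k`.
#'
#' @param k Observed overlap count(s), 0 <= k <= min(F_size, C_size).
#' @param F_size Functional group size.
#' @param C_size Cluster size.
#' @param V_size Network size.
#' @return P-value(s) in \[0, 1\]; `k = 0` gives exactly 1.
#' @export
hypergeom_pvalue <- function(k, F_size, C_size, V_size) {
  if (F_size > V_size || C_size > V_size || F_size < 0 || C_size < 0) {
    stop("impossible hypergeometric parameters")
  }
  if (any(k < 0 | k > pmin(F_size, C_size))) {
    stop("k must lie in [0, min(F_size, C_size)]")
  }
  phyper(k - 1, F_size, V_size - F_size, C_size, lower.tail = FALSE)
}

#' Functional homogeneity of a predicted complex
#'
#' The smallest hypergeometric enrichment p-value of the cluster over all
#' functional groups; small values mark functionally coherent clusters.
#'
#' @param cluster Character vector of member proteins.
#' @param groups List of functional groups (character vectors).
#' @param V_size Total number of proteins in the network.
#' @param bonferroni Multiply by the number of groups (capped at 1)?
#'   Off by default.
#' @return The minimum p-value.
#' @export
functional_homogeneity <- function(cluster, groups, V_size,
                                   bonferroni = FALSE) {
  stopifnot(length(groups) >= 1L)
  cluster <- unique(cluster)
  pvals <- vapply(groups, function(g) {
    g <- unique(g)
    hypergeom_pvalue(length(intersect(cluster, g)),
                     F_size = length(g), C_size = length(cluster),
                     V_size = V_size)
  }, numeric(1))
  p <- min(pvals)
  if (bonferroni) p <- min(1, p * length(groups))
  p
}

#' Proportion of network edges with functionally relevant endpoints
#'
#' Fraction of edges whose endpoint similarity exceeds the threshold
#' (strictly). Edges with no available similarity are counted as below
#' threshold, with a warning.
#'
#' @param edges Edge `data.frame` (`protein_a`, `protein_b`).
#' @param similarity Named numeric vector keyed by the canonical pair key
#'   (`paste(a, b, sep = "\t")`), or a numeric vector aligned with the
#'   edge rows.
#' @param threshold Relevance cutoff (default 0.5).
#' @return Proportion in \[0, 1\]; `NA` for an empty edge set.
#' @export
edge_relevance_proportion <- function(edges, similarity, threshold = 0.5) {
  if (!nrow(edges)) {
    warning("empty edge set")
    return(NA_real_)
  }
  if (!is.null(names(similarity))) {
    s <- similarity[match(pair_key(edges$protein_a, edges$protein_b),
                          names(similarity))]
  } else {
    stopifnot(length(similarity) == nrow(edges))
    s <- similarity
  }
  if (anyNA(s)) {
    warning(sprintf("%d edge(s) without similarity counted as below threshold",
                    sum(is.na(s))))
    s[is.na(s)] <- -Inf
  }
  mean(s > threshold)
}

#' GO relevance of a reconstructed network's edges
#'
#' Convenience wrapper computing, per aspect, the proportion of edges whose
#' endpoint GO semantic similarity exceeds the threshold.
#'
#' @param network Edge `data.frame`.
#' @param bundle An `evidence_bundle` with GO annotations.
#' @param aspects Aspects to report.
#' @param threshold Relevance cutoff.
#' @return Named numeric vector of proportions.
#' @export
edge_go_relevance <- function(network, bundle,
                              aspects = intersect(c("CC", "BP", "MF"),
                                                  names(bundle$go_annotations)),
                              threshold = 0.5) {
  vapply(aspects, function(a) {
    s <- go_sim_component(network$protein_a, network$protein_b, a, bundle)
    edge_relevance_proportion(network, s, threshold)
  }, numeric(1))
}
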