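# Fingerprints: equivalence classes of pairs sharing an identical quantized
# evidence vector, and the top-T fingerprint similarity graph the random
# walk operates on.

quantize_matrix <- function(V, precision) {
  if (!all(is.finite(V))) stop("non-finite component in pair vector(s)")
  Q <- round(V, precision) # round-half-even
  Q[Q == 0] <- 0 # normalize -0
  Q
}

quantize_keys <- function(Q, precision) {
  cols <- lapply(seq_len(ncol(Q)), function(j) {
    formatC(Q[, j], format = "f", digits = precision)
  })
  do.call(paste, c(cols, sep = "|"))
}

#' Quantize an evidence vector into a hashable fingerprint key
#'
#' Rounds each component half-to-even to `precision` decimals and
#' serializes the result in the fixed component order, making "same vector"
#' well-defined for real-valued features.
#'
#' @param v Numeric vector (finite components).
#' @param precision Number of decimals (>= 0).
#' @return A single character key.
#' @export
quantize_vector <- function(v, precision = 4L) {
  stopifnot(precision >= 0L)
  Q <- quantize_matrix(matrix(v, nrow = 1L), precision)
  quantize_keys(Q, precision)
}

#' Collapse pairs with identical quantized vectors into fingerprints
#'
#' Pairs whose quantized evidence vectors coincide are mapped to the same
#' fingerprint ID. IDs run 0..F-1 in lexicographic order of the quantized
#' vectors; member lists partition the input pairs.
#'
#' @param pairs `data.frame` with `protein_a`, `protein_b`; pairs must be
#'   unique.
#' @param vectors Numeric matrix of evidence vectors, one row per pair.
#' @param precision Quantization precision in decimals.
#' @return An object of class `fingerprint_table`: list with `id` (0-based
#'   IDs), `vectors` (F x 17 representative matrix in ID order), `members`
#'   (list of row indices into `pairs`), `counts`, `pair_fingerprint`
#'   (per-pair ID), and the `pairs` table itself.
#' @export
assign_fingerprints <- function(pairs, vectors, precision = 4L) {
  stopifnot(nrow(pairs) == nrow(vectors), precision >= 0L)
  key <- pair_key(pairs$protein_a, pairs$protein_b)
  if (anyDuplicated(key)) {
    stop("duplicate pair: ", key[duplicated(key)][1L])
  }
  n <- nrow(vectors)
  if (!n) {
    return(structure(
      list(id = integer(0),
           vectors = matrix(numeric(0), 0, ncol(vectors),
                            dimnames = list(NULL, colnames(vectors))),
           members = list(), counts = integer(0),
           pair_fingerprint = integer(0), pairs = pairs),
      class = "fingerprint_table"
    ))
  }
  Q <- quantize_matrix(as.matrix(vectors), precision)
  qkey <- quantize_keys(Q, precision)
  first <- !duplicated(qkey)
  reps <- Q[first, , drop = FALSE]
  repkey <- qkey[first]
  # IDs in lexicographic (component-wise) order of the quantized vectors
  o <- do.call(order, as.data.frame(reps))
  reps <- reps[o, , drop = FALSE]
  repkey <- repkey[o]
  fid <- match(qkey, repkey) - 1L
  members <- split(seq_len(n), fid)
  names(members) <- NULL
  structure(
    list(id = seq_len(nrow(reps)) - 1L, vectors = reps, members = members,
         counts = lengths(members), pair_fingerprint = fid, pairs = pairs),
    class = "fingerprint_table"
  )
}

#' @export
print.fingerprint_table <- function(x, ...) {
  cat(sprintf("<fingerprint_table> %d fingerprints over %d pairs\n",
              length(x$id), nrow(x$pairs)))
  invisible(x)
}

#' Min-max similarity from a Euclidean distance
#'
#' Rescales a distance into a similarity: 1 - (dist - dmin)/(dmax - dmin),
#' so the globally closest realized fingerprint pair scores 1 and the
#' farthest scores 0. When `dmax == dmin` (degenerate network) every pair
#' scores 1.
#'
#' @param dist Distance(s) to convert, each within \[dmin, dmax\].
#' @param dmin,dmax Global minimum and maximum realized distances.
#' @return Similarity value(s) in \[0, 1\].
#' @export
eq1_similarity <- function(dist, dmin, dmax) {
  stopifnot(dmin <= dmax)
  eps <- 1e-12 * max(1, abs(dmax))
  if (any(dist < dmin - eps | dist > dmax + eps)) {
    stop("distance outside [dmin, dmax]")
  }
  if (dmax == dmin) return(rep(1, length(dist)))
  pmin(1, pmax(0, 1 - (dist - dmin) / (dmax - dmin)))
}

#' Build the top-T fingerprint similarity graph
#'
#' Links every fingerprint to its `T` nearest fingerprints by Euclidean
#' distance on the representative vectors (ties broken toward the smaller
#' fingerprint ID), symmetrizes the directed relation by union, weights
#' edges with [eq1_similarity()] using the global min/max over all realized
#' distances, and row-normalizes the weighted adjacency into the walk's
#' transition matrix.
#'
#' @param table A `fingerprint_table` with at least 2 fingerprints.
#' @param T Number of nearest neighbors per fingerprint.
#' @return An object of class `similarity_graph`: list with `edges`
#'   (`from`, `to`, `dist`, `weight`; 1-based fingerprint indices),
#'   sparse `adjacency` and row-stochastic `transition` matrices, `dmin`,
#'   `dmax`, and `n_nodes`.
#' @export
build_knn_graph <- function(table, T = 10L) {
  stopifnot(inherits(table, "fingerprint_table"))
  F_ <- nrow(table$vectors)
  if (F_ < 2L) stop("need at least 2 fingerprints to build a similarity graph")
  T_ <- as.integer(min(T, F_ - 1L))
  if (T_ < 1L) stop("T must be >= 1")
  res <- knn_brute_cpp(table$vectors, T_)
  from <- rep(seq_len(F_), times = T_)
  to <- as.vector(res$idx)
  dist <- as.vector(res$dist)
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  keep <- !duplicated(lo * (F_ + 1) + hi)
  lo <- lo[keep]
  hi <- hi[keep]
  dist <- dist[keep]
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]; dist <- dist[o]
  weight <- eq1_similarity(dist, res$dmin, res$dmax)
  adj <- sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(weight, weight),
                      dims = c(F_, F_))
  rs <- rowSums(adj)
  inv <- ifelse(rs > 0, 1 / rs, 0) # an all-zero row stays zero
  trans <- Diagonal(x = inv) %*% adj
  structure(
    list(edges = data.frame(from = lo, to = hi, dist = dist, weight = weight),
         adjacency = adj, transition = trans,
         dmin = res$dmin, dmax = res$dmax, n_nodes = F_, T = T_),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d fingerprints, %d undirected edges (T = %d)\n",
              x$n_nodes, nrow(x$edges), x$T))
  invisible(x)
}
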