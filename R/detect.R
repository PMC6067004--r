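# Protein complex detection on the reconstructed weighted network:
# a weight-ordered seed queue and threshold-gated cluster expansion under a
# diameter bound.

# Internal indexed view of a weighted edge list.
index_network <- function(network) {
  stopifnot(all(c("protein_a", "protein_b", "weight") %in% names(network)))
  if (nrow(network) && any(!is.finite(network$weight) | network$weight < 0)) {
    stop("edge weights must be finite and non-negative")
  }
  verts <- radix_sort(unique(c(network$protein_a, network$protein_b)))
  ia <- match(network$protein_a, verts)
  ib <- match(network$protein_b, verts)
  nv <- length(verts)
  nbr <- rep(list(integer(0)), nv)
  wts <- rep(list(numeric(0)), nv)
  ends <- c(ia, ib)
  other <- c(ib, ia)
  w2 <- c(network$weight, network$weight)
  o <- order(ends)
  ends <- ends[o]; other <- other[o]; w2 <- w2[o]
  grp <- split(seq_along(ends), ends)
  for (nm in names(grp)) {
    i <- as.integer(nm)
    nbr[[i]] <- other[grp[[nm]]]
    wts[[i]] <- w2[grp[[nm]]]
  }
  list(verts = verts, nbr = nbr, wts = wts,
       weight = vapply(wts, sum, numeric(1)),
       degree = lengths(nbr))
}

#' Vertex weights of a weighted network
#'
#' The weight of a vertex is the sum of the weights of its incident edges;
#' vertices named in `vertices` but absent from the edge list get 0.
#'
#' @param network Weighted edge `data.frame` (`protein_a`, `protein_b`,
#'   `weight`).
#' @param vertices Optional vertex universe to report on.
#' @return Named numeric vector.
#' @export
vertex_weights <- function(network, vertices = NULL) {
  net <- index_network(network)
  w <- setNames(net$weight, net$verts)
  if (!is.null(vertices)) {
    w <- setNames(ifelse(vertices %in% names(w), w[vertices], 0), vertices)
  }
  w
}

#' Order vertices into the seed queue
#'
#' Non-increasing by weight; equal weights are ordered by non-increasing
#' degree, and full ties lexicographically by ID.
#'
#' @param weights Named numeric vertex weights.
#' @param degrees Named integer vertex degrees (same names).
#' @return Character vector of vertex IDs in queue order.
#' @export
build_seed_queue <- function(weights, degrees) {
  stopifnot(identical(sort(names(weights)), sort(names(degrees))))
  ids <- names(weights)
  o <- radix_order(-weights, -as.numeric(degrees[ids]), ids)
  ids[o]
}

#' Interaction probability of a vertex with respect to a subgraph
#'
#' E_vk = e_vk / w_k, where e_vk sums the weights of edges between `v` and
#' the cluster `K` and w_k sums the weights of edges inside `K`. A vertex
#' with no edge into `K` scores 0; when `K` carries no internal edge weight
#' (a singleton seed) a connected vertex scores `Inf`, so the seed's
#' best-connected neighbor is always admissible first.
#'
#' @param v Vertex ID, not in `K`.
#' @param K Character vector of cluster members.
#' @param network Weighted edge `data.frame`.
#' @return Non-negative value (possibly `Inf`).
#' @export
interaction_probability <- function(v, K, network) {
  stopifnot(!(v %in% K))
  in_k <- network$protein_a %in% K & network$protein_b %in% K
  touch_v <- (network$protein_a == v & network$protein_b %in% K) |
    (network$protein_b == v & network$protein_a %in% K)
  e_vk <- sum(network$weight[touch_v])
  w_k <- sum(network$weight[in_k])
  if (e_vk == 0) return(0)
  if (w_k == 0) return(Inf)
  e_vk / w_k
}

# Diameter (longest shortest path, unweighted hops) of the subgraph induced
# by the vertex index set `members`; Inf if disconnected.
induced_diameter <- function(net, members) {
  k <- length(members)
  if (k <= 1L) return(0L)
  pos <- integer(length(net$verts))
  pos[members] <- seq_len(k)
  local <- lapply(members, function(v) {
    nb <- net$nbr[[v]]
    pos[nb[pos[nb] > 0L]]
  })
  ecc_max <- 0L
  for (s in seq_len(k)) {
    dist <- rep(-1L, k)
    dist[s] <- 0L
    q <- s
    while (length(q)) {
      nxt <- integer(0)
      for (u in q) {
        for (w in local[[u]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[u] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      q <- nxt
    }
    if (any(dist < 0L)) return(Inf)
    ecc_max <- max(ecc_max, max(dist))
  }
  ecc_max
}

# Core expansion loop on an indexed network. Returns integer member indices.
expand_core <- function(net, seed_idx, T_in, d, allowed = NULL) {
  nv <- length(net$verts)
  in_k <- logical(nv)
  in_k[seed_idx] <- TRUE
  members <- seed_idx
  w_k <- 0
  e <- numeric(nv) # e_vk for the frontier
  nb <- net$nbr[[seed_idx]]
  for (t in seq_along(nb)) e[nb[t]] <- e[nb[t]] + net$wts[[seed_idx]][t]
  repeat {
    cand <- which(e > 0 & !in_k)
    if (!is.null(allowed)) cand <- cand[allowed[cand]]
    if (!length(cand)) break
    E <- if (w_k > 0) e[cand] / w_k else rep(Inf, length(cand))
    ok <- E >= T_in
    if (!any(ok)) break
    cand <- cand[ok]
    E <- E[ok]
    o <- radix_order(-E, -net$weight[cand], net$verts[cand])
    admitted <- 0L
    for (v in cand[o]) {
      if (induced_diameter(net, c(members, v)) <= d) {
        admitted <- v
        break
      }
    }
    if (!admitted) break
    in_k[admitted] <- TRUE
    members <- c(members, admitted)
    w_k <- w_k + e[admitted]
    e[admitted] <- 0
    nb <- net$nbr[[admitted]]
    ws <- net$wts[[admitted]]
    outside <- !in_k[nb]
    for (t in which(outside)) e[nb[t]] <- e[nb[t]] + ws[t]
  }
  attr(members, "w_k") <- w_k
  members
}

#' Grow one cluster from a seed vertex
#'
#' Starting from the seed, repeatedly admits the neighboring vertex with
#' the highest interaction probability (ties: higher vertex weight, then
#' lexicographic ID) among those with E_vk >= `T_in` whose admission keeps
#' the cluster's unweighted diameter within `d`; E_vk is recomputed after
#' every addition and expansion stops when no neighbor qualifies.
#'
#' @param seed Seed protein ID (must appear in the network).
#' @param network Weighted edge `data.frame`.
#' @param T_in Admission threshold on E_vk.
#' @param d Diameter bound in unweighted hops.
#' @return Character vector of member IDs (sorted), with the summed
#'   internal edge weight in attribute `"w_k"` and the seed in `"seed"`.
#' @export
expand_cluster <- function(seed, network, T_in = 0.6, d = 2L) {
  net <- index_network(network)
  s <- match(seed, net$verts)
  if (is.na(s)) stop("seed '", seed, "' is not in the network")
  members <- expand_core(net, s, T_in, d)
  out <- radix_sort(net$verts[members])
  attr(out, "w_k") <- attr(members, "w_k")
  attr(out, "seed") <- seed
  out
}

#' Detect protein complexes on a weighted network
#'
#' Seeds are taken in order from the weight-sorted queue; each seed grows a
#' cluster by [expand_cluster()]'s rule, all cluster members are removed
#' from the queue (blocking re-seeding only — proteins may still join later
#' clusters unless `allow_overlap` is off), and clusters smaller than
#' `min_complex_size` are discarded. Output order follows seed rank.
#'
#' @param network Weighted edge `data.frame`.
#' @param config An [mlpr_config()]; `T_in`, `d`, `min_complex_size` and
#'   `allow_overlap` are used.
#' @return List of complexes (sorted member vectors), with per-complex
#'   seeds in attribute `"seeds"` and internal edge weights in `"w_k"`.
#' @export
detect_complexes <- function(network, config = mlpr_config()) {
  if (!nrow(network)) return(structure(list(), seeds = character(0), w_k = numeric(0)))
  net <- index_network(network)
  queue_ids <- build_seed_queue(setNames(net$weight, net$verts),
                                setNames(net$degree, net$verts))
  queue <- match(queue_ids, net$verts)
  in_queue <- rep(TRUE, length(net$verts))
  unclustered <- rep(TRUE, length(net$verts))
  res <- list()
  seeds <- character(0)
  wks <- numeric(0)
  for (s in queue) {
    if (!in_queue[s]) next
    members <- expand_core(net, s, config$T_in, config$d,
                           allowed = if (config$allow_overlap) NULL else unclustered)
    in_queue[members] <- FALSE
    if (length(members) >= config$min_complex_size) {
      unclustered[members] <- FALSE
      res[[length(res) + 1L]] <- radix_sort(net$verts[members])
      seeds <- c(seeds, net$verts[s])
      wks <- c(wks, attr(members, "w_k"))
    }
  }
  structure(res, seeds = seeds, w_k = wks)
}
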