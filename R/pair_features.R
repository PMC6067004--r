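# The 17-component evidence vector describing one unordered protein pair.
#
# Component order is fixed; every downstream structure (fingerprints, seed
# rule, quantization keys) relies on it.

#' Fixed component order of the pair evidence vector
#'
#' Domain score, GO semantic similarity and GO-slim sharing per aspect,
#' coexpression, STRING-like score, five AP-MS reliability scores, two
#' database memberships, and the shared-neighborhood feature.
#'
#' @format Character vector of the 17 component names.
#' @export
PAIR_VECTOR_COMPONENTS <- c(
  "D", "MF", "mf", "BP", "bp", "CC", "cc", "CE", "S",
  "TAP1", "TAP2", "TAP3", "TAP4", "TAP5", "EPPI1", "EPPI2", "CD"
)

#' Enumerate all unordered protein pairs
#'
#' Produces the n(n-1)/2 canonical pairs of a protein list in lexicographic
#' order, with no self-pairs.
#'
#' @param ids Character vector of unique protein IDs.
#' @return `data.frame` with columns `protein_a`, `protein_b`.
#' @examples
#' enumerate_pairs(c("B", "A", "C")) # (A,B), (A,C), (B,C)
#' @export
enumerate_pairs <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate protein ID: ", ids[duplicated(ids)][1L])
  }
  ids <- radix_sort(ids)
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  }
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  data.frame(protein_a = ids[i], protein_b = ids[j], stringsAsFactors = FALSE)
}

#' GO semantic similarity of two proteins in one aspect
#'
#' Information-content similarity in the style of Lord: the average, over
#' all cross pairs of the proteins' directly annotated terms, of
#' 2 IC(MICA) / (IC(t_a) + IC(t_b)), where MICA is the most informative
#' common ancestor and 0/0 is defined as 0. Returns 0 when either protein
#' has no annotation in the aspect.
#'
#' @param a,b Protein IDs.
#' @param aspect One of `"MF"`, `"BP"`, `"CC"`.
#' @param bundle An `evidence_bundle` carrying annotations and ontology.
#' @return Similarity in \[0, 1\].
#' @export
go_semantic_similarity <- function(a, b, aspect, bundle) {
  ann <- bundle$go_annotations[[aspect]]
  if (is.null(ann)) return(0)
  ta <- ann[[a]] %||% character(0)
  tb <- ann[[b]] %||% character(0)
  if (!length(ta) || !length(tb)) return(0)
  ic <- bundle$ic[[aspect]]
  vals <- outer(ta, tb, Vectorize(function(x, y) {
    term_pair_similarity(bundle$ontology, ic, x, y)
  }))
  mean(vals)
}

#' GO-slim sharing indicator
#'
#' 1 if the two proteins share at least one slim term after removing the
#' trivial aspect-root terms, else 0.
#'
#' @inheritParams go_semantic_similarity
#' @return 0 or 1.
#' @export
go_slim_similarity <- function(a, b, aspect, bundle) {
  sl <- bundle$go_slims[[aspect]]
  if (is.null(sl)) return(0)
  sa <- setdiff(sl[[a]] %||% character(0), bundle$slim_roots)
  sb <- setdiff(sl[[b]] %||% character(0), bundle$slim_roots)
  as.numeric(length(intersect(sa, sb)) > 0L)
}

#' Coexpression of two proteins
#'
#' Pearson correlation of the two (optionally log-transformed) expression
#' profiles. Pairs with a missing or zero-variance profile return 0 with a
#' warning.
#'
#' @inheritParams go_semantic_similarity
#' @return Correlation in \[-1, 1\].
#' @export
coexpression <- function(a, b, bundle) {
  e <- bundle$expression
  if (is.null(e)) return(0)
  if (!(a %in% rownames(e)) || !(b %in% rownames(e))) {
    warning("missing expression profile; coexpression set to 0")
    return(0)
  }
  x <- e[a, ]
  y <- e[b, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance expression profile; coexpression set to 0")
    return(0)
  }
  as.numeric(cor(x, y))
}

#' Domain-domain interaction score of a protein pair
#'
#' Sum of the interaction confidences over all cross pairs of the two
#' proteins' domains; unknown domain pairs contribute 0 and the lookup is
#' unordered.
#'
#' @inheritParams go_semantic_similarity
#' @return Non-negative score.
#' @export
ddi_score <- function(a, b, bundle) {
  da <- bundle$domains[[a]] %||% character(0)
  db <- bundle$domains[[b]] %||% character(0)
  if (!length(da) || !length(db)) return(0)
  g <- expand.grid(da = da, db = db, stringsAsFactors = FALSE)
  canon <- canonicalize_pairs(g$da, g$db)
  v <- bundle$ddi_map[pair_key(canon$protein_a, canon$protein_b)]
  sum(v, na.rm = TRUE)
}

#' Czekanowski-Dice distance between interaction neighborhoods
#'
#' With N(x) the neighbors of x in the network plus x itself, the distance
#' is |N(a) symmetric-difference N(b)| / (|N(a) union N(b)| +
#' |N(a) intersect N(b)|): 0 for identical neighborhoods, 1 for disjoint
#' ones. Isolated proteins use N(x) = \{x\}.
#'
#' @param a,b Protein IDs.
#' @param topology Edge `data.frame` of the observed network.
#' @return Distance in \[0, 1\]. The pair-vector feature stores
#'   1 - distance by default so that larger means stronger evidence.
#' @export
cd_distance <- function(a, b, topology) {
  nb <- function(p) {
    if (is.null(topology) || !nrow(topology)) return(p)
    unique(c(p,
             topology$protein_b[topology$protein_a == p],
             topology$protein_a[topology$protein_b == p]))
  }
  na_ <- nb(a)
  nb_ <- nb(b)
  inter <- length(intersect(na_, nb_))
  tot <- length(na_) + length(nb_)
  (tot - 2 * inter) / tot
}

#' Build the 17-component evidence vector of one pair
#'
#' @param a,b Protein IDs (order irrelevant; features are symmetric).
#' @param bundle An `evidence_bundle`; missing sources contribute 0.
#' @param cd_as_similarity Store 1 - CD distance (default) or the raw
#'   distance.
#' @return Named numeric vector in the fixed component order
#'   `PAIR_VECTOR_COMPONENTS`.
#' @export
build_pair_vector <- function(a, b, bundle, cd_as_similarity = TRUE) {
  pairs <- data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
  drop(build_pair_vectors(pairs, bundle, cd_as_similarity = cd_as_similarity))
}

#' Build evidence vectors for many pairs at once
#'
#' Vectorized workhorse behind [build_pair_vector()]: computes all 17
#' components for a whole pair table, sharing per-source precomputation
#' (term similarity matrices, standardized expression, neighborhood lists).
#'
#' @param pairs `data.frame` with `protein_a`, `protein_b` (canonical
#'   unordered pairs, e.g. from [enumerate_pairs()]).
#' @param bundle An `evidence_bundle`.
#' @param cd_as_similarity Store 1 - CD distance (default) or the raw
#'   distance.
#' @return Numeric matrix, one row per pair, columns
#'   `PAIR_VECTOR_COMPONENTS`.
#' @export
build_pair_vectors <- function(pairs, bundle, cd_as_similarity = TRUE) {
  stopifnot(inherits(bundle, "evidence_bundle"),
            all(c("protein_a", "protein_b") %in% names(pairs)))
  pa <- pairs$protein_a
  pb <- pairs$protein_b
  n <- length(pa)
  V <- matrix(0, nrow = n, ncol = length(PAIR_VECTOR_COMPONENTS),
              dimnames = list(NULL, PAIR_VECTOR_COMPONENTS))
  if (!n) return(V)
  cp <- canonicalize_pairs(pa, pb) # score-map keys are canonical
  key <- pair_key(cp$protein_a, cp$protein_b)

  for (aspect in names(bundle$go_annotations)) {
    col <- aspect # MF / BP / CC
    V[, col] <- go_sim_component(pa, pb, aspect, bundle)
  }
  for (aspect in names(bundle$go_slims)) {
    col <- tolower(aspect) # mf / bp / cc
    V[, col] <- slim_component(pa, pb, aspect, bundle)
  }
  V[, "CE"] <- ce_component(pa, pb, bundle)
  V[, "D"] <- ddi_component(pa, pb, bundle)
  if (length(bundle$string_map)) {
    v <- bundle$string_map[match(key, names(bundle$string_map))]
    V[, "S"] <- ifelse(is.na(v), 0, v)
  }
  for (nm in names(bundle$tap_maps)) {
    v <- bundle$tap_maps[[nm]][match(key, names(bundle$tap_maps[[nm]]))]
    V[, nm] <- ifelse(is.na(v), 0, v)
  }
  for (nm in names(bundle$eppi_keys)) {
    V[, nm] <- as.numeric(key %in% bundle$eppi_keys[[nm]])
  }
  cd <- cd_component(pa, pb, bundle$topology)
  V[, "CD"] <- if (cd_as_similarity) 1 - cd else cd
  V
}

# --- vectorized component kernels -----------------------------------------

go_sim_component <- function(pa, pb, aspect, bundle) {
  ann <- bundle$go_annotations[[aspect]]
  out <- numeric(length(pa))
  if (is.null(ann) || !length(ann)) return(out)
  ic <- bundle$ic[[aspect]]
  terms <- radix_sort(unique(unlist(ann, use.names = FALSE)))
  nt <- length(terms)
  S <- matrix(0, nt, nt)
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      s <- term_pair_similarity(bundle$ontology, ic, terms[i], terms[j])
      S[i, j] <- s
      S[j, i] <- s
    }
  }
  tidx <- lapply(ann, function(ts) match(ts, terms))
  ia <- match(pa, names(ann))
  ib <- match(pb, names(ann))
  both <- which(!is.na(ia) & !is.na(ib))
  for (k in both) {
    out[k] <- mean(S[tidx[[ia[k]]], tidx[[ib[k]]], drop = FALSE])
  }
  out
}

slim_component <- function(pa, pb, aspect, bundle) {
  sl <- bundle$go_slims[[aspect]]
  out <- numeric(length(pa))
  if (is.null(sl) || !length(sl)) return(out)
  clean <- lapply(sl, function(x) setdiff(x, bundle$slim_roots))
  ia <- match(pa, names(clean))
  ib <- match(pb, names(clean))
  both <- which(!is.na(ia) & !is.na(ib))
  for (k in both) {
    if (any(clean[[ia[k]]] %in% clean[[ib[k]]])) out[k] <- 1
  }
  out
}

ce_component <- function(pa, pb, bundle) {
  zs <- bundle$zscores
  out <- numeric(length(pa))
  if (is.null(zs)) return(out)
  ia <- match(pa, rownames(zs))
  ib <- match(pb, rownames(zs))
  both <- which(!is.na(ia) & !is.na(ib))
  if (length(both)) {
    m <- ncol(zs)
    out[both] <- rowSums(zs[ia[both], , drop = FALSE] *
                           zs[ib[both], , drop = FALSE]) / (m - 1L)
    # guard tiny numeric overshoot of |r| = 1
    out <- pmin(1, pmax(-1, out))
  }
  out
}

ddi_component <- function(pa, pb, bundle) {
  out <- numeric(length(pa))
  dom <- bundle$domains
  if (is.null(dom) || !length(dom) || !length(bundle$ddi_map)) return(out)
  # integer-rank canonical keys over the domain vocabulary
  vocab <- radix_sort(unique(c(
    unlist(dom, use.names = FALSE),
    unlist(strsplit(names(bundle$ddi_map), "\t", fixed = TRUE), use.names = FALSE)
  )))
  dmap <- setNames(
    as.numeric(bundle$ddi_map),
    vapply(strsplit(names(bundle$ddi_map), "\t", fixed = TRUE), function(p) {
      r <- sort(match(p, vocab))
      paste(r, collapse = "_")
    }, character(1))
  )
  dranks <- lapply(dom, function(d) match(d, vocab))
  ia <- match(pa, names(dom))
  ib <- match(pb, names(dom))
  both <- which(!is.na(ia) & !is.na(ib))
  for (k in both) {
    ra <- dranks[[ia[k]]]
    rb <- dranks[[ib[k]]]
    g1 <- rep(ra, times = length(rb))
    g2 <- rep(rb, each = length(ra))
    kk <- paste(pmin(g1, g2), pmax(g1, g2), sep = "_")
    out[k] <- sum(dmap[kk], na.rm = TRUE)
  }
  out
}

cd_component <- function(pa, pb, topology) {
  n <- length(pa)
  if (is.null(topology) || !nrow(topology)) return(rep(1, n)) # disjoint {a},{b}
  verts <- radix_sort(unique(c(pa, pb, topology$protein_a, topology$protein_b)))
  ea <- match(topology$protein_a, verts)
  eb <- match(topology$protein_b, verts)
  nbr <- vector("list", length(verts))
  for (i in seq_along(verts)) nbr[[i]] <- i # self-inclusive neighborhoods
  adj <- split(c(eb, ea), c(ea, eb))
  for (nm in names(adj)) {
    i <- as.integer(nm)
    nbr[[i]] <- c(i, unique(adj[[nm]]))
  }
  sizes <- lengths(nbr)
  ia <- match(pa, verts)
  ib <- match(pb, verts)
  out <- numeric(n)
  for (k in seq_len(n)) {
    li <- nbr[[ia[k]]]
    lj <- nbr[[ib[k]]]
    inter <- sum(match(li, lj, nomatch = 0L) > 0L)
    tot <- sizes[ia[k]] + sizes[ib[k]]
    out[k] <- (tot - 2 * inter) / tot
  }
  out
}
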