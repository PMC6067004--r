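# Internal helpers shared across modules.
#
# All string comparison that affects results (pair canonicalization,
# tie-breaking, output ordering) goes through radix order, i.e. C-locale
# byte order, so that results never depend on the session locale.

`%||%` <- function(a, b) if (is.null(a)) b else a

radix_sort <- function(x) sort(x, method = "radix")

radix_order <- function(...) order(..., method = "radix")

# Element-wise "a comes after b" in byte order, via ranks in the pooled
# sorted vocabulary (base `>` on character would use the locale collation).
str_gt <- function(a, b) {
  u <- sort(unique(c(a, b)), method = "radix")
  match(a, u) > match(b, u)
}

# Canonical unordered pair: lexicographically smaller ID first.
canonicalize_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  swap <- str_gt(a, b)
  pa <- a
  pb <- b
  pa[swap] <- b[swap]
  pb[swap] <- a[swap]
  list(protein_a = pa, protein_b = pb, swapped = swap)
}

pair_key <- function(a, b) paste(a, b, sep = "\t")

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

empty_edge_df <- function(weighted = TRUE) {
  data.frame(
    protein_a = character(0), protein_b = character(0),
    weight = numeric(0), stringsAsFactors = FALSE
  )
}
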