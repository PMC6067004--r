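# Shared miniature fixtures, built in code.

# DAG: root -> {midA, midB}; midA -> {t1, t2}; midB -> {t3}.
tiny_ontology <- function() {
  ontology(list(
    midA = "root", midB = "root",
    t1 = "midA", t2 = "midA", t3 = "midB"
  ))
}

# Corpus of four proteins with hand-computable information content:
# t1 covers {a, b}, t2 {b, c}, t3 {d}; midA {a, b, c}, midB {d}; root all.
tiny_annotations <- function() {
  list(a = "t1", b = c("t1", "t2"), c = "t2", d = "t3")
}

edge_df <- function(a, b, w = NULL) {
  canon <- mlpr:::canonicalize_pairs(a, b)
  data.frame(
    protein_a = canon$protein_a, protein_b = canon$protein_b,
    weight = if (is.null(w)) NA_real_ else w,
    stringsAsFactors = FALSE
  )
}

# Unit-weight clique on the given vertex IDs.
clique_edges <- function(ids, w = 1) {
  p <- enumerate_pairs(ids)
  p$weight <- w
  p
}

# A small complete synthetic fixture for property tests (fast to build).
small_fixture <- function(seed = 11L) {
  generate_fixture(truth_spec(
    n_proteins = 40L, n_complexes = 4L, size_range = c(3L, 5L),
    n_samples = 12L, seed = seed
  ))
}

pk <- function(a, b) paste(a, b, sep = "\t")

# Independent upper-tail hypergeometric oracle by direct summation of
# binomial-coefficient mass terms.
hyper_upper_oracle <- function(k, F_size, C_size, V_size) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
  1 - sum(choose(F_size, i) * choose(V_size - F_size, C_size - i) /
            choose(V_size, C_size))
}
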