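test_that("pair enumeration is complete, canonical and duplicate-safe", {
  p <- enumerate_pairs(c("B", "A", "C"))
  expect_equal(p$protein_a, c("A", "A", "B"))
  expect_equal(p$protein_b, c("B", "C", "C"))
  expect_equal(nrow(enumerate_pairs("X")), 0L)
  expect_equal(nrow(enumerate_pairs(character(0))), 0L)
  expect_error(enumerate_pairs(c("A", "A")), "duplicate")

  # count oracle: direct double loop
  for (n in c(2L, 7L, 23L, 60L)) {
    ids <- sprintf("Q%03d", seq_len(n))
    cnt <- 0L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) cnt <- cnt + 1L
    expect_equal(nrow(enumerate_pairs(ids)), cnt)
  }
})

test_that("GO semantic similarity follows the MICA definition", {
  ont <- tiny_ontology()
  bundle <- evidence_bundle(
    go_annotations = list(MF = tiny_annotations()),
    ontology = ont
  )
  # identical single informative term
  expect_equal(go_semantic_similarity("a", "a", "MF", bundle), 1)
  # only common ancestor is the root with IC 0
  expect_equal(go_semantic_similarity("a", "d", "MF", bundle), 0)
  # unannotated protein
  expect_equal(go_semantic_similarity("a", "zz", "MF", bundle), 0)
  # b = {t1, t2} vs c = {t2}: mean of sim(t1,t2) and sim(t2,t2) = 1
  s12 <- 2 * -log(3 / 4) / (2 * -log(2 / 4))
  expect_equal(go_semantic_similarity("b", "c", "MF", bundle),
               mean(c(s12, 1)))
})

test_that("GO-slim sharing ignores trivial root terms", {
  ont <- tiny_ontology()
  bundle <- evidence_bundle(
    go_slims = list(BP = list(p = c("midA", "root"), q = c("midA"),
                              r = c("midB", "root"), s = c("root"))),
    ontology = ont
  )
  expect_equal(go_slim_similarity("p", "q", "BP", bundle), 1)
  expect_equal(go_slim_similarity("q", "r", "BP", bundle), 0)
  # only shared term is the root
  expect_equal(go_slim_similarity("p", "s", "BP", bundle), 0)
})

test_that("coexpression is Pearson correlation with guarded degenerate cases", {
  e <- rbind(
    p1 = c(1, 2, 3), p2 = c(2, 4, 6), p3 = c(3, 2, 1), p4 = c(5, 5, 5)
  )
  colnames(e) <- paste0("s", 1:3)
  bundle <- evidence_bundle(expression = e)
  expect_equal(coexpression("p1", "p1", bundle), 1)
  expect_equal(coexpression("p1", "p3", bundle), -1)
  expect_equal(coexpression("p1", "p2", bundle), 1)
  expect_warning(z <- coexpression("p1", "p4", bundle), "zero-variance")
  expect_equal(z, 0)
  expect_warning(z <- coexpression("p1", "p9", bundle), "missing")
  expect_equal(z, 0)
})

test_that("domain interaction score sums confidences over unordered cross pairs", {
  bundle <- evidence_bundle(
    domains = list(a = c("d1", "d2"), b = "d3", c = character(0)),
    ddi = data.frame(domain_a = c("d1", "d3"), domain_b = c("d3", "d2"),
                     weight = c(0.4, 0.6))
  )
  expect_equal(ddi_score("a", "b", bundle), 1.0) # 0.4 + 0.6, both directions
  expect_equal(ddi_score("b", "a", bundle), 1.0)
  expect_equal(ddi_score("a", "c", bundle), 0)
  expect_equal(ddi_score("a", "zz", bundle), 0)
})

test_that("Czekanowski-Dice distance matches hand-set arithmetic", {
  topo <- edge_df(c("a", "a", "b"), c("b", "c", "c"))
  # N(a) = N(b) = N(c) = {a,b,c}: identical neighborhoods
  expect_equal(cd_distance("a", "b", topo), 0)
  # disjoint: isolated proteins
  expect_equal(cd_distance("x", "y", topo), 1)
  # N(a) = {a,b,c}, N(b) = {a,b}: |sym diff| / (|union| + |inter|) = 1/5
  topo2 <- edge_df(c("a", "a"), c("b", "c"))
  expect_equal(cd_distance("b", "a", topo2), 0.2)
})

test_that("the assembled pair vector matches a hand-built one componentwise", {
  ont <- tiny_ontology()
  expr <- rbind(a = c(1, 2, 4), b = c(2, 3, 8), d = c(9, 1, 3))
  colnames(expr) <- paste0("s", 1:3)
  bundle <- evidence_bundle(
    go_annotations = list(MF = tiny_annotations()),
    go_slims = list(CC = list(a = "midA", b = "midA")),
    ontology = ont,
    expression = expr,
    domains = list(a = c("d1", "d2"), b = "d3"),
    ddi = data.frame(domain_a = c("d1", "d2"), domain_b = c("d3", "d3"),
                     weight = c(0.4, 0.6)),
    string_scores = edge_df("a", "b", 0.9),
    tap_scores = list(edge_df("a", "b", 0.5), edge_df("x", "y", 0.4)),
    eppi_sets = list(edge_df("x", "y"), edge_df("a", "b")),
    topology = edge_df(c("a", "a", "b"), c("b", "c", "c"))
  )
  v <- build_pair_vector("a", "b", bundle)
  expect_equal(names(v), PAIR_VECTOR_COMPONENTS)
  expect_equal(unname(v["D"]), 1.0)
  expect_equal(unname(v["MF"]), go_semantic_similarity("a", "b", "MF", bundle))
  expect_equal(unname(v["mf"]), 0)
  expect_equal(unname(v["cc"]), 1)
  expect_equal(unname(v["CE"]), cor(expr["a", ], expr["b", ]))
  expect_equal(unname(v["S"]), 0.9)
  expect_equal(unname(v["TAP1"]), 0.5)
  expect_equal(unname(v["TAP2"]), 0)
  expect_equal(unname(v["EPPI1"]), 0)
  expect_equal(unname(v["EPPI2"]), 1)
  expect_equal(unname(v["CD"]), 1) # identical neighborhoods
  # raw-distance polarity flag
  v2 <- build_pair_vector("a", "b", bundle, cd_as_similarity = FALSE)
  expect_equal(unname(v2["CD"]), 0)

  # a pair absent from every source is all-zero
  v0 <- build_pair_vector("y", "z", evidence_bundle(
    eppi_sets = list(edge_df("a", "b"))
  ))
  expect_equal(unname(v0), rep(0, 17))
  # membership in the second database only
  v1 <- build_pair_vector("a", "b", evidence_bundle(
    eppi_sets = list(edge_df("x", "y"), edge_df("a", "b"))
  ))
  expect_equal(unname(v1), c(rep(0, 15), 1, 0))
})

test_that("feature values are symmetric and respect their ranges", {
  fx <- small_fixture()
  bundle <- fx$bundle
  set.seed(5)
  prot <- sample(fx$proteins, 12)
  pairs <- enumerate_pairs(prot)
  V <- build_pair_vectors(pairs, bundle)
  Vswap <- build_pair_vectors(
    data.frame(protein_a = pairs$protein_b, protein_b = pairs$protein_a,
               stringsAsFactors = FALSE), bundle
  )
  expect_equal(V, Vswap)
  expect_true(all(V[, c("mf", "bp", "cc", "EPPI1", "EPPI2")] %in% c(0, 1)))
  rng01 <- V[, c("MF", "BP", "CC", "CD")]
  expect_true(all(rng01 >= 0 & rng01 <= 1))
  expect_true(all(V[, "CE"] >= -1 & V[, "CE"] <= 1))
  expect_true(all(V[, c("D", "S", "TAP1", "TAP2", "TAP3", "TAP4", "TAP5")] >= 0))
  # the vectorized builder agrees with the scalar one
  for (k in sample(nrow(pairs), 5)) {
    expect_equal(
      unname(build_pair_vector(pairs$protein_a[k], pairs$protein_b[k], bundle)),
      unname(V[k, ])
    )
  }
})
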