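test_that("neighborhood affinity matches its set formula", {
  expect_equal(na_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(na_score(c("a", "b"), c("x", "y")), 0)
  expect_equal(na_score(c("a", "b", "c"), c("a", "b", "d", "e")), 4 / 12)
  expect_error(na_score(character(0), "a"), "empty")
  # symmetry and range on random set pairs
  set.seed(2)
  pool <- sprintf("g%02d", 1:30)
  for (i in 1:25) {
    p <- sample(pool, sample(2:8, 1))
    b <- sample(pool, sample(2:8, 1))
    expect_equal(na_score(p, b), na_score(b, p))
    expect_gte(na_score(p, b), 0)
    expect_lte(na_score(p, b), 1)
  }
})

test_that("match counts and precision/recall/F reproduce hand values", {
  P <- list(c("a", "b", "c"))
  B <- list(c("a", "b", "d"), c("x", "y", "z"))
  expect_equal(unname(match_counts(P, B, 0.25)), c(1L, 1L)) # NA = 4/9

  idP <- list(c("a", "b", "c"), c("d", "e", "f"))
  s <- precision_recall_f(idP, idP, 0.25)
  expect_equal(c(s$precision, s$recall, s$f_value), c(1, 1, 1))

  # Ncp=1, |P|=2, Ncb=1, |B|=4 -> precision .5, recall .25, F = 1/3
  P2 <- list(c("a", "b", "c"), c("q", "r", "s"))
  B2 <- list(c("a", "b", "d"), c("k1", "k2", "k3"),
             c("m1", "m2", "m3"), c("n1", "n2", "n3"))
  s2 <- precision_recall_f(P2, B2, 0.25)
  expect_equal(s2$ncp, 1L)
  expect_equal(s2$ncb, 1L)
  expect_equal(s2$precision, 0.5)
  expect_equal(s2$recall, 0.25)
  expect_equal(s2$f_value, 1 / 3)

  # no pair reaches omega
  s3 <- precision_recall_f(list(c("a", "b", "c")), B2, omega = 1)
  expect_equal(s3$f_value, 0)
  # empty prediction set: defined zero, not an error
  s4 <- precision_recall_f(list(), B2, 0.25)
  expect_equal(c(s4$precision, s4$recall, s4$f_value), c(0, 0, 0))
  expect_error(precision_recall_f(P2, list(), 0.25), "benchmark")
})

test_that("precision and recall are monotone as omega decreases", {
  set.seed(12)
  pool <- sprintf("p%02d", 1:40)
  P <- replicate(8, sample(pool, sample(3:6, 1)), simplify = FALSE)
  B <- replicate(6, sample(pool, sample(3:6, 1)), simplify = FALSE)
  omegas <- c(0.9, 0.5, 0.25, 0.1)
  res <- lapply(omegas, function(w) precision_recall_f(P, B, w))
  prec <- vapply(res, `[[`, numeric(1), "precision")
  rec <- vapply(res, `[[`, numeric(1), "recall")
  expect_true(all(diff(prec) >= 0))
  expect_true(all(diff(rec) >= 0))
  # F is bounded by twice the smaller of precision and recall
  for (r in res) expect_lte(r$f_value, 2 * min(r$precision, r$recall) + 1e-12)
})

test_that("the hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeom_pvalue(0, 5, 3, 10), 1)
  expect_equal(hypergeom_pvalue(3, 5, 3, 10), 10 / 120)
  # boundary: k = C = F = V reduces to the single term P(X = k)
  expect_equal(hypergeom_pvalue(4, 4, 4, 4), 1)
  expect_error(hypergeom_pvalue(5, 3, 4, 10), "k must")
  expect_error(hypergeom_pvalue(1, 11, 4, 10), "impossible")

  for (V in c(2:12, 20L, 33L, 47L, 60L)) {
    for (F_ in 0:V) {
      for (C_ in seq(0L, V, by = max(1L, V %/% 7L))) {
        ks <- 0:min(F_, C_)
        got <- hypergeom_pvalue(ks, F_, C_, V)
        want <- vapply(ks, hyper_upper_oracle, numeric(1), F_, C_, V)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("functional homogeneity is the minimum enrichment p-value", {
  groups <- list(g1 = c("a", "b", "c"), g2 = c("x", "y"))
  # cluster equal to a group in a large network: strongly enriched
  p <- functional_homogeneity(c("a", "b", "c"), groups, V_size = 100)
  expect_lt(p, 1e-4)
  expect_equal(p, hyper_upper_oracle(3, 3, 3, 100))
  # disjoint from all groups
  expect_equal(functional_homogeneity(c("q", "r"), groups, V_size = 100), 1)
  # min over two hand-enumerated tails
  cl <- c("a", "x", "q")
  p2 <- functional_homogeneity(cl, groups, V_size = 10)
  expect_equal(p2, min(hyper_upper_oracle(1, 3, 3, 10),
                       hyper_upper_oracle(1, 2, 3, 10)))
  # Bonferroni flag caps at 1
  expect_lte(functional_homogeneity(cl, groups, V_size = 10,
                                    bonferroni = TRUE), 1)
})

test_that("edge relevance counts strict exceedances and flags missing pairs", {
  edges <- edge_df(c("a", "a", "b", "c"), c("b", "c", "c", "d"))
  sim <- setNames(c(0.9, 0.6, 0.51, 0.2), pk(edges$protein_a, edges$protein_b))
  expect_equal(edge_relevance_proportion(edges, sim, 0.5), 0.75)
  expect_equal(edge_relevance_proportion(edges, rep(1, 4), 0.5), 1)
  expect_equal(edge_relevance_proportion(edges, rep(0, 4), 0.5), 0)
  # strictly above: a value equal to the threshold does not count
  expect_equal(edge_relevance_proportion(edges, rep(0.5, 4), 0.5), 0)
  sim_missing <- sim[1:2]
  expect_warning(r <- edge_relevance_proportion(edges, sim_missing, 0.5),
                 "without similarity")
  expect_equal(r, 0.5)
})
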