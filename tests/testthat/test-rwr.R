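test_that("the seed rule requires database support and broad evidence", {
  v <- setNames(rep(0, 17), PAIR_VECTOR_COMPONENTS)
  expect_false(is_reliable_seed(v))
  # two database indicators and 9 of 17 components nonzero
  v1 <- v
  v1[c("EPPI1", "EPPI2", "MF", "BP", "CC", "CE", "S", "D", "CD")] <- 1
  expect_equal(sum(v1 != 0), 9)
  expect_true(is_reliable_seed(v1))
  # broad evidence but only one database indicator
  v2 <- v
  v2[c("D", "MF", "mf", "BP", "bp", "CC", "cc", "CE", "S",
       "TAP2", "TAP3", "TAP4", "EPPI1", "CD")] <- 1
  expect_false(is_reliable_seed(v2))
  # exactly half nonzero is not "above half"
  v3 <- v1
  v3["CD"] <- 0 # 8 of 17
  expect_false(is_reliable_seed(v3))
  # the indicator set is configurable
  expect_true(is_reliable_seed(v2, indicators = c("EPPI1", "TAP2"), min_db = 2))
})

test_that("seed priors spread equal mass over qualifying fingerprints", {
  pairs <- enumerate_pairs(sprintf("x%d", 1:5))
  V <- matrix(0, nrow(pairs), 17, dimnames = list(NULL, PAIR_VECTOR_COMPONENTS))
  V[1, ] <- 1 # qualifies
  V[2, c(PAIR_VECTOR_COMPONENTS[1:8], "EPPI1", "EPPI2")] <- seq(0.1, 1, length.out = 10)
  V[3, "CE"] <- 0.5 # does not qualify
  fpt <- assign_fingerprints(pairs, V, 4L)
  f0 <- seed_priors(fpt)
  expect_equal(sum(f0), 1)
  expect_setequal(unique(f0), c(0, 0.5))
  expect_length(attr(f0, "seeds"), 2L)

  Vn <- matrix(0, 3, 17, dimnames = list(NULL, PAIR_VECTOR_COMPONENTS))
  fptn <- assign_fingerprints(pairs[1:3, ], Vn, 4L)
  expect_error(seed_priors(fptn), "seed rule")
})

test_that("the walk reproduces the closed-form steady state", {
  # 2-node swap graph: F = 0.8 (I - 0.2 M)^{-1} (1,0) = (25/30, 5/30)
  M <- matrix(c(0, 1, 1, 0), 2)
  r <- random_walk_with_restart(M, c(1, 0), alpha = 0.8, tol = 1e-10)
  expect_equal(r$posterior, c(25 / 30, 5 / 30), tolerance = 1e-8)

  # restart-only limit
  r1 <- random_walk_with_restart(M, c(0.3, 0.7), alpha = 1, tol = 1e-10)
  expect_equal(r1$posterior, c(0.3, 0.7))
  expect_equal(r1$iterations, 1L)

  # symmetric complete graph with uniform prior stays uniform
  Mc <- matrix(1 / 3, 4, 4) - diag(1 / 3, 4) + diag(0, 4)
  Mc <- Mc / rowSums(Mc)
  ru <- random_walk_with_restart(Mc, rep(0.25, 4), 0.8, 1e-10)
  expect_equal(ru$posterior, rep(0.25, 4), tolerance = 1e-9)

  # random graphs up to 50 fingerprints vs direct linear solve
  set.seed(17)
  for (rep in 1:6) {
    n_prot <- sample(8:10, 1) # at most 45 pairs, so F <= 45
    pairs <- enumerate_pairs(sprintf("p%02d", seq_len(n_prot)))
    V <- matrix(sample(0:2, nrow(pairs) * 5, replace = TRUE) / 2, nrow(pairs))
    fpt <- assign_fingerprints(pairs, V, 4L)
    F_ <- length(fpt$id)
    g <- build_knn_graph(fpt, 3L)
    f0 <- runif(F_)
    f0 <- f0 / sum(f0)
    alpha <- 0.8
    r <- random_walk_with_restart(g$transition, f0, alpha, 1e-12)
    direct <- solve(diag(F_) - (1 - alpha) * as.matrix(g$transition),
                    alpha * f0)
    expect_lt(max(abs(r$posterior - direct)), 1e-8)
    # fixed-point residual bound
    resid <- sum(abs(r$posterior -
                       (1 - alpha) * as.numeric(g$transition %*% r$posterior) -
                       alpha * f0))
    expect_lt(resid, 10 * 1e-12)
  }
})

test_that("iteration differences contract at least geometrically", {
  set.seed(23)
  for (rep in 1:5) {
    pairs <- enumerate_pairs(sprintf("p%02d", 1:9))
    V <- matrix(runif(nrow(pairs) * 4), nrow(pairs))
    fpt <- assign_fingerprints(pairs, V, 4L)
    g <- build_knn_graph(fpt, 4L)
    F_ <- g$n_nodes
    f0 <- as.numeric(seq_len(F_) == 1L)
    alpha <- 0.8
    tol <- 1e-6
    r <- random_walk_with_restart(g$transition, f0, alpha, tol)
    d <- r$diffs
    if (length(d) > 1) {
      expect_true(all(d[-1] / d[-length(d)] <= (1 - alpha) + 1e-9))
    }
    expect_lte(r$iterations, ceiling(log(tol) / log(1 - alpha)) + 1)
  }
  # reaching the cap is an error carrying the last residual
  M <- matrix(c(0, 1, 1, 0), 2)
  expect_error(random_walk_with_restart(M, c(1, 0), 0.2, 1e-12, max_iter = 3L),
               "did not converge")
})

test_that("the walk is linear in the prior and confined to seeded components", {
  # two disconnected 2-cliques, row-normalized
  M <- Matrix::sparseMatrix(i = c(1, 2, 3, 4), j = c(2, 1, 4, 3), x = 1)
  f0 <- c(0.5, 0.5, 0, 0)
  r <- random_walk_with_restart(M, f0, 0.8, 1e-10)
  expect_equal(r$posterior[3:4], c(0, 0)) # exactly zero off the seeded part
  r2 <- random_walk_with_restart(M, 3 * f0, 0.8, 1e-10)
  expect_equal(r2$posterior, 3 * r$posterior, tolerance = 1e-9)
})

test_that("pairs inherit fingerprint scores with deterministic tie order", {
  pairs <- enumerate_pairs(c("a", "b", "c")) # (a,b), (a,c), (b,c)
  V <- rbind(c(1, 0), c(0, 1), c(1, 0)) # (a,b) and (b,c) share a fingerprint
  fpt <- assign_fingerprints(pairs, V, 4L)
  post <- c(0.1, 0.3) # id0 = (0,1) -> (a,c); id1 = (1,0)
  ranked <- score_and_rank_pairs(post, fpt)
  expect_equal(ranked$score, c(0.3, 0.3, 0.1))
  # fingerprint tie resolved lexicographically by pair
  expect_equal(ranked$protein_a, c("a", "b", "a"))
  expect_equal(ranked$protein_b, c("b", "c", "c"))

  expect_equal(nrow(select_top(ranked, 0L)), 0L)
  expect_equal(nrow(select_top(ranked, 99L)), 3L)
  top2 <- select_top(ranked, 2L)
  expect_equal(top2$weight, c(0.3, 0.3))
  expect_equal(top2$protein_a, c("a", "b"))
})
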