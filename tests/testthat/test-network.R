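test_that("shrinkage intensity matches its defining formula", {
  X <- random_data_matrix(10, 6, seed = 101)
  X[, 2] <- X[, 1] # perfect duplicate pair
  sc <- shrink_correlation(X)
  # duplicated genes: r = 1 with zero variance contribution; shrunk entry
  # is exactly 1 - lambda
  expect_equal(sc$R[1, 2], 1 - sc$lambda)
  expect_lte(sc$R[1, 2], 1)

  # analytic lambda equals a brute-force double-loop evaluation
  Y <- random_data_matrix(15, 8, seed = 202)
  expect_equal(shrink_correlation(Y)$lambda, oracle_lambda(Y),
               tolerance = 1e-12)

  # forced lambda = 1 gives the identity target
  expect_identical(unname(shrink_correlation(Y, lambda = 1)$R), diag(8))

  # shrinkage never increases off-diagonal magnitude
  sc2 <- shrink_correlation(Y)
  R0 <- stats::cor(Y)
  off <- upper.tri(R0)
  expect_true(all(abs(sc2$R[off]) <= abs(R0[off]) + 1e-14))

  expect_error(shrink_correlation(Y[1:2, ]), "n >= 3")
  Z <- Y; Z[, 1] <- 5
  expect_warning(shrink_correlation(Z), "zero-variance")
})

test_that("partial correlation matches closed forms and the classic estimator", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  dimnames(R) <- list(letters[1:3], letters[1:3])
  P <- partial_correlation(R)
  # equicorrelated closed form (r - r^2) / (1 - r^2) = 1/3
  expect_equal(unname(P[upper.tri(P)]), rep(1 / 3, 3))

  expect_identical(partial_correlation(diag(4)), diag(4))

  X <- random_data_matrix(30, 5, seed = 7)
  P2 <- partial_correlation(shrink_correlation(X, lambda = 0))
  expect_true(isSymmetric(P2))
  expect_equal(unname(diag(P2)), rep(1, 5))
  expect_true(all(abs(P2) <= 1 + 1e-12))
})

test_that("the mixture null model recovers kappa and eta0", {
  v <- with_seed(303, rnull_pcor(10000, kappa = 20))
  m <- fit_edge_null(v)
  expect_gt(m$kappa, 20 * 0.8)
  expect_lt(m$kappa, 20 * 1.2)
  expect_gte(m$eta0, 0.9)

  # fitted null density integrates to 1 (quadrature)
  gr <- seq(-1, 1, length.out = 20001)
  dens <- browningnet:::dnull_pcor(gr, m$kappa)
  expect_equal(sum(dens) * (gr[2] - gr[1]), 1, tolerance = 1e-3)

  # 20% alternative mass near |p| = 0.8 -> eta0 in the calibrated band
  v2 <- with_seed(304, c(rnull_pcor(8000, 20),
                         sample(c(-1, 1), 2000, TRUE) * rnorm(2000, 0.8, 0.03)))
  m2 <- fit_edge_null(v2)
  expect_gte(m2$eta0, 0.7)
  expect_lte(m2$eta0, 0.95)

  expect_error(fit_edge_null(rep(0.1, 200)), "identical")
  expect_error(fit_edge_null(rnull_pcor(50, 10)), "100")
})

test_that("edge FDR is 1 at zero, monotone, and strict at the threshold", {
  v <- with_seed(305, c(rnull_pcor(5000, 50),
                        sample(c(-1, 1), 60, TRUE) * runif(60, 0.5, 0.9)))
  m <- fit_edge_null(v)
  f0 <- edge_fdr(0, m, reference = v)
  expect_identical(f0, 1)
  grid <- seq(0, 0.95, by = 0.05)
  fg <- edge_fdr(grid, m, reference = v)
  expect_true(all(diff(fg) <= 1e-12)) # non-increasing in |pcor|

  P <- matrix(0, 3, 3); diag(P) <- 1
  dimnames(P) <- list(letters[1:3], letters[1:3])
  P[1, 2] <- P[2, 1] <- 0.9
  ed <- select_edges(P, m, fdr_threshold = 0.05)
  expect_identical(nrow(ed), 1L)
  # ties at the threshold are excluded: strict <
  thr <- ed$fdr[1]
  expect_identical(nrow(select_edges(P, m, fdr_threshold = thr)), 0L)
})

test_that("fast-greedy communities reproduce hand-computed modularity", {
  tri2 <- data.frame(
    gene_a = c("a1", "a2", "a1", "b1", "b2", "b1"),
    gene_b = c("a2", "a3", "a3", "b2", "b3", "b3"),
    weight = 1, stringsAsFactors = FALSE)
  part <- detect_communities(tri2)
  expect_equal(part$Q, 0.5) # two triangles: Q = 2 (1/2 - 1/4) = 0.5
  expect_identical(length(unique(part$membership)), 2L)
  expect_identical(length(unique(part$membership[c("a1", "a2", "a3")])), 1L)

  # one community for everything has Q = 0 by definition
  memb1 <- stats::setNames(rep(1, 6), c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(modularity_q(tri2, memb1), 0)

  # deterministic given the edge list
  expect_identical(detect_communities(tri2), detect_communities(tri2))

  # empty edge set: all singletons, Q = 0
  empty <- detect_communities(tri2[0, ], nodes = c("x", "y"))
  expect_identical(unname(empty$membership), c(1L, 2L))
  expect_identical(empty$Q, 0)

  # isolated nodes stay singletons
  part2 <- detect_communities(tri2, nodes = c("a1", "a2", "a3", "b1", "b2",
                                              "b3", "iso"))
  expect_identical(sum(part2$membership == part2$membership[["iso"]]), 1L)
})

test_that("CNM is near-optimal on small graphs (exhaustive oracle)", {
  graphs <- list(
    path5 = data.frame(gene_a = paste0("n", 1:4), gene_b = paste0("n", 2:5),
                       weight = 1),
    wtri = data.frame(gene_a = c("a", "b", "c", "c", "d", "e"),
                      gene_b = c("b", "c", "a", "d", "e", "f"),
                      weight = c(3, 3, 3, 1, 2, 2)),
    star = data.frame(gene_a = rep("h", 5), gene_b = paste0("s", 1:5),
                      weight = 1),
    ring6 = data.frame(gene_a = paste0("r", 1:6),
                       gene_b = paste0("r", c(2:6, 1)), weight = 1))
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    nodes <- sort(unique(c(g$gene_a, g$gene_b)))
    got <- detect_communities(g, nodes = nodes)$Q
    best <- oracle_best_modularity(g, nodes)
    expect_gte(got, 0.95 * best)
  }
})

test_that("lncrna_neighborhood filters by biotype", {
  nodes <- data.frame(gene_id = c("m1", "m2", "lnc1", "lnc2", "m3"),
                      biotype = c("mRNA", "mRNA", "lncRNA", "lncRNA", "mRNA"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(gene_a = c("lnc1", "lnc1", "lnc1"),
                      gene_b = c("m1", "m2", "lnc2"),
                      pcor = 0.5, fdr = 0.01, stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges), class = "PcorNetwork")
  expect_identical(lncrna_neighborhood(net, "lnc1"), c("m1", "m2"))
  expect_identical(lncrna_neighborhood(net, "lnc2"), character(0))
  expect_error(lncrna_neighborhood(net, "m1"), "not a lncRNA")
  expect_error(lncrna_neighborhood(net, "nope"), "absent")
})
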