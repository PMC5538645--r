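test_that("hypergeometric overlap matches exhaustive enumeration", {
  expect_identical(hypergeom_overlap(0, 3, 4, 10), 1)
  expect_equal(hypergeom_overlap(2, 3, 3, 6), 0.5)
  expect_equal(oracle_hyper(2, 3, 3, 6), 0.5)
  # n = N forces the full universe into the draw: k = K with certainty
  expect_equal(hypergeom_overlap(3, 3, 6, 6), 1)
  expect_error(hypergeom_overlap(4, 3, 3, 6), "exceeds")
  expect_error(hypergeom_overlap(1, 7, 3, 6), "exceed N")
})

test_that("binomial overrepresentation matches exact summation", {
  expect_identical(binomial_overrep(0, 10, 0.3), 1)
  expect_equal(binomial_overrep(5, 10, 0.5), 0.623046875)
  expect_equal(oracle_binom(5, 10, 0.5), 0.623046875)
  expect_equal(binomial_overrep(4, 4, 0.01), 0.01^4)
  expect_error(binomial_overrep(2, 4, 0), "p0")
  expect_error(binomial_overrep(5, 4, 0.5), "k <= n")
})

test_that("BH adjustment is exact, order-preserving, and idempotent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.04, 0.001, 0.9, 0.02, NA)
  q <- bh_adjust(p)
  expect_identical(which(is.na(q)), 5L)
  expect_equal(q[!is.na(q)], stats::p.adjust(p[!is.na(p)], "BH"))
  expect_equal(bh_adjust(bh_adjust(p)), bh_adjust(q)) # idempotent
  # monotone along sorted p
  with_seed(41, {
    pv <- runif(50)
    qv <- bh_adjust(pv)
    expect_true(all(diff(qv[order(pv)]) >= -1e-14))
  })
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
})

test_that("preranked GSEA matches the independent running sum", {
  scores <- stats::setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5),
                            paste0("g", 1:10))
  # set = top-ranked gene only: ES = 1 at position 1
  r <- preranked_gsea(scores, "g1", n_perm = 50, seed = 11)
  expect_equal(r$ES, 1)
  # dual-implementation equality on assorted toy sets
  for (gs in list(c("g2", "g5"), c("g9", "g10"), c("g1", "g6", "g7"))) {
    got <- preranked_gsea(scores, gs, n_perm = 10, seed = 1)$ES
    expect_equal(got, oracle_gsea_es(scores, gs), info = paste(gs, collapse = ","))
  }
  # reversing all score signs negates the ES for the same set
  es_fwd <- preranked_gsea(scores, c("g1", "g2"), n_perm = 10, seed = 2)$ES
  es_rev <- preranked_gsea(-scores, c("g1", "g2"), n_perm = 10, seed = 2)$ES
  expect_equal(es_rev, -es_fwd)
  # bit-exact reproducibility under a fixed seed; invariance to relabeling
  a <- preranked_gsea(scores, c("g2", "g3"), n_perm = 200, seed = 99)
  b <- preranked_gsea(scores, c("g2", "g3"), n_perm = 200, seed = 99)
  expect_identical(a$p_perm, b$p_perm)
  relabeled <- scores
  names(relabeled) <- sub("^g", "x", names(relabeled))
  cc <- preranked_gsea(relabeled, c("x2", "x3"), n_perm = 200, seed = 99)
  expect_identical(a$p_perm, cc$p_perm)
  expect_gte(a$p_perm, 1 / 201)

  expect_error(preranked_gsea(scores, character(0), seed = 1), "empty")
  expect_error(preranked_gsea(scores, names(scores), seed = 1), "universe")
  expect_error(preranked_gsea(scores, "g1", n_perm = 10), "seed")
  expect_message(preranked_gsea(scores, c("g1", "zz"), n_perm = 10, seed = 1),
                 "dropped")
  expect_error(suppressMessages(preranked_gsea(scores, "zz", n_perm = 10, seed = 1)),
               "unknown")
})

toy_network <- function() {
  nodes <- data.frame(
    gene_id = c(paste0("m", 1:20), "lncA", "lncB"),
    biotype = c(rep("mRNA", 20), "lncRNA", "lncRNA"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    gene_a = c("lncA", "lncA", "lncA", "m1"),
    gene_b = c("m1", "m2", "m3", "m4"),
    pcor = 0.4, fdr = 0.01, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "PcorNetwork")
}

test_that("per-lncRNA annotation flags planted sets and skips isolates", {
  net <- toy_network()
  sets <- list(planted = c("m1", "m2", "m3", "m5"),
               decoy = c("m10", "m11", "m12", "m13"))
  class(sets) <- "GeneSetCollection"
  res <- suppressMessages(annotate_lncrnas(net, sets))
  expect_false("lncB" %in% res$lncrna) # empty neighborhood skipped
  top <- res[res$lncrna == "lncA", ]
  expect_identical(top$set[which.min(top$p)], "planted")
  expect_true(top$hit[top$set == "planted"])
  expect_lt(top$p[top$set == "planted"], 0.01)
  empty <- structure(list(), class = "GeneSetCollection")
  expect_identical(nrow(suppressMessages(annotate_lncrnas(net, empty))), 0L)
})

test_that("random neighborhoods hit sets at about the nominal rate", {
  # null simulation: p < 0.01 hits over random draws stay near 1%
  with_seed(53, {
    universe <- sprintf("u%03d", 1:200)
    sets <- lapply(1:40, function(i) sample(universe, 20))
    names(sets) <- paste0("S", 1:40)
    hits <- 0; total <- 0
    for (rep in 1:50) {
      nb <- sample(universe, 8)
      tb <- browningnet:::enrich_table(nb, sets, universe)
      hits <- hits + sum(tb$p < 0.01)
      total <- total + nrow(tb)
    }
    expect_lt(hits / total, 0.03)
  })
})

test_that("cluster overrepresentation uses lncRNA-connected mRNAs", {
  net <- toy_network()
  memb <- stats::setNames(c(rep(1L, 10), rep(2L, 10), 1L, 2L),
                          net$nodes$gene_id)
  part <- structure(list(membership = memb, Q = 0.3),
                    class = "CommunityPartition")
  sets <- list(planted = c("m1", "m2", "m3"),
               broad = paste0("m", 1:10))
  class(sets) <- "GeneSetCollection"
  res <- suppressMessages(cluster_overrep(net, part, sets))
  # cluster 2 has no lncRNA-connected mRNAs -> only cluster 1 reported
  expect_setequal(unique(res$cluster), 1L)
  expect_identical(res$set[which.min(res$p)], "planted")
  # singleton tested list, gene in a set with p0 = 0.5 -> p = 0.5
  p0half <- list(half = paste0("m", 1:10))
  class(p0half) <- "GeneSetCollection"
  net2 <- net
  net2$edges <- net$edges[1, ] # lncA - m1 only
  res2 <- suppressMessages(cluster_overrep(net2, part, p0half))
  expect_equal(res2$p, 0.5)
  missing <- list(gone = c("zz1", "zz2"))
  class(missing) <- "GeneSetCollection"
  expect_error(suppressMessages(cluster_overrep(net, part, missing)), "gone")
})
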