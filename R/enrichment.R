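# Set-level statistics: hypergeometric overlap, binomial overrepresentation,
# Benjamini-Hochberg adjustment, preranked GSEA, and the guilt-by-association
# drivers (per-lncRNA neighborhood enrichment, per-cluster overrepresentation).

#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance that a uniform
#' draw of `n` items from a universe of `N`, of which `K` are marked, contains
#' `k` or more marked items. Computed via [stats::phyper()] (log-space safe
#' down to ~1e-300).
#'
#' @param k observed overlap; @param K set size in the universe;
#' @param n query size; @param N universe size. All scalars, vectorized over
#'   `k`, `K`, `n`.
#' @return p-value(s) in `(0, 1]`.
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  assert_that(all(N >= 1) && all(K >= 0) && all(n >= 0) && all(k >= 0),
              "negative or empty hypergeometric parameters")
  assert_that(all(K <= N) && all(n <= N), "K and n must not exceed N")
  assert_that(all(k <= pmin(K, n)), "k exceeds min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Upper-tail binomial overrepresentation probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, with `p0` the category's background
#' fraction in the reference universe.
#'
#' @param k observed count; @param n trials; @param p0 background probability
#'   in `(0, 1)`.
#' @return p-value(s) in `(0, 1]`.
#' @export
binomial_overrep <- function(k, n, p0) {
  assert_that(all(p0 > 0) && all(p0 < 1), "p0 must lie strictly in (0, 1)")
  assert_that(all(k >= 0) && all(k <= n), "need 0 <= k <= n")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in the input order, with enforced monotonicity along the
#' sorted p-values; ties are handled stably and the procedure is idempotent.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  assert_that(all(p >= 0 & p <= 1), "p-value outside [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    out[ok] <- q
  }
  out
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted running-sum statistic on a ranked gene list: walking the
#' list from the top, hits increment the sum by `|score|^weight` (normalized
#' over the set's hits), misses decrement by `1/(N - K)`; the enrichment score
#' ES is the signed extremum. The null is by gene-label permutation under a
#' fixed seed; NES divides ES by the mean `|null ES|` of the same sign, and
#' `p_perm = (1 + #{same-sign null |ES| >= |ES|}) / (n_perm + 1)`.
#'
#' @param scores named numeric vector of ranking scores (e.g. log2 fold
#'   changes); sorted internally, ties broken by name for determinism.
#' @param gene_set character vector; members absent from `names(scores)` are
#'   dropped with a note (error if all are).
#' @param weight exponent on `|score|` for hit increments (default 1).
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @return a one-row data.frame (class `GseaResult`): `set`, `ES`, `NES`,
#'   `p_perm`, `n_perm`, `size`, `seed`.
#' @export
preranked_gsea <- function(scores, gene_set, weight = 1, n_perm = 1000, seed) {
  assert_that(!missing(seed), "preranked_gsea requires an explicit seed")
  assert_that(!is.null(names(scores)) && !anyDuplicated(names(scores)),
              "scores must be uniquely named by gene")
  assert_that(all(is.finite(scores)), "scores must be finite")
  nm <- deparse(substitute(gene_set))
  unknown <- setdiff(gene_set, names(scores))
  if (length(unknown) > 0) {
    gene_set <- intersect(gene_set, names(scores))
    if (length(gene_set) == 0) stop_bn("all gene-set members unknown")
    message(sprintf("preranked_gsea: dropped %d unknown gene(s)", length(unknown)))
  }
  assert_that(length(gene_set) >= 1, "empty gene set")
  N <- length(scores); K <- length(gene_set)
  assert_that(K < N, "gene set equals the whole universe")
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  es_stat <- function(hit, s) {
    w <- abs(s)^weight
    inc <- numeric(N)
    denom <- sum(w[hit])
    inc[hit] <- if (denom > 0) w[hit] / denom else 1 / sum(hit)
    inc[!hit] <- -1 / (N - K)
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
  }
  es <- es_stat(hit, s)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ph <- logical(N)
    ph[sample.int(N, K)] <- TRUE
    es_stat(ph, s)
  }, numeric(1)))
  same <- null_es * sign(es) >= 0
  nes <- if (any(same)) es / mean(abs(null_es[same])) else NA_real_
  p <- (1 + sum(same & abs(null_es) >= abs(es))) / (n_perm + 1)
  structure(data.frame(set = NA_character_, ES = es, NES = nes, p_perm = p,
                       n_perm = n_perm, size = K, seed = seed,
                       stringsAsFactors = FALSE),
            class = c("GseaResult", "data.frame"))
}

#' Run preranked GSEA over a gene-set collection
#' @param scores named scores as in [preranked_gsea()].
#' @param collection `GeneSetCollection` (named list of gene id vectors).
#' @param ... passed to [preranked_gsea()].
#' @param seed master seed; each set gets a derived sub-seed.
#' @return data.frame with one row per testable set plus a BH `q` column.
#' @export
gsea_collection <- function(scores, collection, seed, ...) {
  rows <- lapply(names(collection), function(nm) {
    gs <- intersect(collection[[nm]], names(scores))
    if (length(gs) == 0 || length(gs) >= length(scores)) return(NULL)
    r <- preranked_gsea(scores, gs, seed = sub_seed(seed, paste0("gsea:", nm)), ...)
    r$set <- nm
    r
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- bh_adjust(out$p_perm)
  out
}

enrich_table <- function(query, sets, universe) {
  query <- unique(query)
  if (length(sets) == 0) {
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  assert_that(all(query %in% universe), "query contains genes outside the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p = if (K == 0) 1 else hypergeom_overlap(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Per-lncRNA guilt-by-association annotation
#'
#' For each lncRNA node of the network, tests its direct-mRNA neighborhood
#' (see [lncrna_neighborhood()]) for overlap with each gene set by the
#' hypergeometric test; sets with `p < alpha` are flagged as hits. This
#' reproduces the role of per-lncRNA functional annotation at the
#' conventional `P < 0.01` reporting level. lncRNAs with empty neighborhoods
#' are skipped with a note.
#'
#' @param network `PcorNetwork`.
#' @param collection `GeneSetCollection`.
#' @param alpha reporting threshold on the raw p (default 0.01).
#' @param universe gene universe; defaults to the network's mRNA nodes.
#' @return data.frame: `lncrna`, `set`, `k`, `K`, `n`, `N`, `p`, `q`, `hit`.
#' @export
annotate_lncrnas <- function(network, collection, alpha = 0.01,
                             universe = NULL) {
  nodes <- network$nodes
  lncs <- nodes$gene_id[nodes$biotype == "lncRNA"]
  if (is.null(universe)) universe <- nodes$gene_id[nodes$biotype == "mRNA"]
  rows <- lapply(lncs, function(ln) {
    nb <- lncrna_neighborhood(network, ln)
    if (length(nb) == 0) {
      message(sprintf("annotate_lncrnas: '%s' has no mRNA neighbors, skipped", ln))
      return(NULL)
    }
    tb <- enrich_table(nb, collection, universe)
    if (nrow(tb) == 0) return(NULL)
    tb$lncrna <- ln
    tb
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(lncrna = character(), set = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p = numeric(), q = numeric(), hit = logical(),
                      stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p) # BH across the whole family of (lncRNA, set) tests
  out$hit <- out$p < alpha
  out[, c("lncrna", "set", "k", "K", "n", "N", "p", "q", "hit")]
}

#' Per-cluster overrepresentation by the binomial test
#'
#' For each community, the tested gene list is the cluster's mRNAs that are
#' directly connected to at least one lncRNA; each set's significance is
#' `P(X >= k)` under `Binomial(n_cluster, p0)` with `p0` the set's fraction of
#' the reference universe. A `tier` column labels highly significant results
#' (`p < tier_p`, default 1e-9) without filtering anything out.
#'
#' @param network `PcorNetwork`; @param partition `CommunityPartition`.
#' @param collection `GeneSetCollection`.
#' @param universe reference universe (default: network mRNA nodes).
#' @param tier_p labeling threshold for the "highly significant" tier.
#' @return data.frame: `cluster`, `set`, `k`, `n`, `p0`, `p`, `q`, `tier`.
#' @export
cluster_overrep <- function(network, partition, collection, universe = NULL,
                            tier_p = 1e-9) {
  nodes <- network$nodes
  if (is.null(universe)) universe <- nodes$gene_id[nodes$biotype == "mRNA"]
  absent <- names(collection)[vapply(collection, function(s)
    length(intersect(s, universe)) == 0, logical(1))]
  if (length(absent) > 0) {
    stop_bn("gene set(s) absent from universe: %s", paste(absent, collapse = ", "))
  }
  lncs <- nodes$gene_id[nodes$biotype == "lncRNA"]
  linked <- unique(unlist(lapply(lncs, function(ln)
    lncrna_neighborhood(network, ln)), use.names = FALSE))
  memb <- partition$membership
  rows <- list()
  for (cl in sort(unique(memb))) {
    cl_genes <- names(memb)[memb == cl]
    test_genes <- intersect(cl_genes, linked)
    if (length(test_genes) == 0) {
      message(sprintf("cluster_overrep: cluster %s has no lncRNA-connected mRNAs, skipped", cl))
      next
    }
    for (nm in names(collection)) {
      members <- intersect(collection[[nm]], universe)
      p0 <- length(members) / length(universe)
      if (p0 <= 0 || p0 >= 1) next
      k <- length(intersect(test_genes, members))
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, set = nm, k = k, n = length(test_genes), p0 = p0,
        p = binomial_overrep(k, length(test_genes), p0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(cluster = integer(), set = character(), k = integer(),
                      n = integer(), p0 = numeric(), p = numeric(),
                      q = numeric(), tier = character(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$p, out$cluster, out$set), , drop = FALSE]
  out$q <- bh_adjust(out$p)
  out$tier <- ifelse(out$p < tier_p, "highly_significant", "")
  rownames(out) <- NULL
  out
}
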