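# Coexpression-network core: shrinkage correlation (Schaefer-Strimmer
# analytic intensity), partial correlation by precision-matrix scaling,
# mixture-null edge FDR, fast-greedy (CNM) modularity communities, and
# lncRNA neighborhood extraction for guilt-by-association.

#' Shrinkage correlation matrix with analytic intensity
#'
#' Computes the sample correlation matrix `R` and shrinks it toward the
#' identity: `R* = (1 - lambda) R + lambda I`, with
#' `lambda* = sum_{i<j} Var_hat(r_ij) / sum_{i<j} r_ij^2` truncated to
#' `[0, 1]` (`Var_hat` is the standard unbiased estimate of the empirical
#' correlation coefficient's variance). This makes the estimate positive
#' definite and invertible in the small-n / large-p regime the method is
#' built for. If every off-diagonal `r` is exactly zero, `lambda = 1` by
#' convention (logged).
#'
#' @param X samples x genes numeric matrix (log2 expression), n >= 3.
#' @param lambda optional fixed intensity overriding the analytic estimate.
#' @return list of class `ShrinkageCorrelation`: `R` (shrunk matrix),
#'   `lambda`, `n`, `dropped` (zero-variance genes removed, with warning).
#' @export
shrink_correlation <- function(X, lambda = NULL) {
  assert_that(is.matrix(X) && nrow(X) >= 3, "need a matrix with n >= 3 samples")
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0) {
    warn_bn("dropping %d zero-variance gene(s): %s", length(dropped),
            paste(utils::head(dropped, 5), collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  p <- ncol(X)
  assert_that(p >= 2, "need at least 2 genes with nonzero variance")
  Xs <- scale(X) # unit sd with n-1 denominator
  R <- crossprod(Xs) / (n - 1)
  if (is.null(lambda)) {
    # Var_hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2,
    # w_kij = xs_ki * xs_kj, wbar_ij = (n-1)/n * r_ij
    S2 <- crossprod(Xs^2)       # sum_k w_kij^2
    wbar <- (n - 1) / n * R
    varhat <- n / (n - 1)^3 * (S2 - n * wbar^2)
    off <- upper.tri(R)
    denom <- sum(R[off]^2)
    if (denom == 0) {
      message("shrink_correlation: all off-diagonal correlations are zero; lambda set to 1")
      lambda <- 1
    } else {
      lambda <- max(0, min(1, sum(varhat[off]) / denom))
    }
  } else {
    assert_that(lambda >= 0 && lambda <= 1, "lambda must lie in [0, 1]")
  }
  Rstar <- (1 - lambda) * R
  diag(Rstar) <- 1
  Rstar <- (Rstar + t(Rstar)) / 2
  structure(list(R = Rstar, lambda = lambda, n = n, dropped = dropped),
            class = "ShrinkageCorrelation")
}

#' Partial correlations from a (shrunk) correlation matrix
#'
#' Inverts the correlation matrix and rescales the precision:
#' `p_ij = -omega_ij / sqrt(omega_ii * omega_jj)`, diagonal set to 1.
#'
#' @param R correlation matrix or `ShrinkageCorrelation`.
#' @return symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_correlation <- function(R) {
  if (inherits(R, "ShrinkageCorrelation")) R <- R$R
  assert_that(is.matrix(R) && nrow(R) == ncol(R), "R must be square")
  Om <- tryCatch(solve(R), error = function(e) {
    stop_bn("correlation matrix is singular; re-run shrink_correlation with a lambda floor > 0")
  })
  d <- 1 / sqrt(diag(Om))
  P <- -Om * tcrossprod(d)
  diag(P) <- 1
  P <- (P + t(P)) / 2
  dimnames(P) <- dimnames(R)
  P
}

# Null density of a partial correlation with kappa degrees of freedom:
#   f0(r; kappa) = (1 - r^2)^((kappa - 3) / 2) / Beta(1/2, (kappa - 1) / 2)
# equivalently r^2 ~ Beta(1/2, (kappa - 1)/2); E[r^2] = 1/kappa.
dnull_pcor <- function(r, kappa, log = FALSE) {
  ld <- (kappa - 3) / 2 * log1p(-r^2) - lbeta(0.5, (kappa - 1) / 2)
  if (log) ld else exp(ld)
}

pnull_abs_pcor <- function(t, kappa) stats::pbeta(t^2, 0.5, (kappa - 1) / 2)

rnull_pcor <- function(m, kappa) {
  sqrt(stats::rbeta(m, 0.5, (kappa - 1) / 2)) * sample(c(-1, 1), m, replace = TRUE)
}

#' Fit the mixture null model for edge significance
#'
#' Models the observed off-diagonal partial correlations as
#' `f(p) = eta0 * f0(p; kappa) + (1 - eta0) * fA(p)` with
#' `f0(p; kappa) proportional to (1 - p^2)^((kappa - 3)/2)`. `kappa` is fitted
#' by maximum likelihood on the assumed-null-dominated central region
#' (`|p|` below the `central_quantile` empirical quantile, default 0.8, of the
#' truncated null); `eta0` is a conservative ratio of the empirical central
#' mass to the fitted null's central mass, truncated to `[0, 1]`.
#'
#' @param pcor_values numeric vector of off-diagonal partial correlations
#'   (>= 100 values).
#' @param central_quantile quantile of `|p|` bounding the ML fitting region.
#' @return list of class `EdgeFdrModel`: `eta0`, `kappa`, `m` (value count).
#' @export
fit_edge_null <- function(pcor_values, central_quantile = 0.8) {
  v <- pcor_values[is.finite(pcor_values)]
  assert_that(length(v) >= 100, "need at least 100 partial correlation values")
  assert_that(all(abs(v) <= 1 + 1e-12), "partial correlations must lie in [-1, 1]")
  v <- pmin(1, pmax(-1, v))
  if (stats::sd(v) == 0) stop_bn("degenerate input: all values identical")
  a <- abs(v)
  cc <- stats::quantile(a, central_quantile, names = FALSE)
  if (cc <= 0 || cc >= 1) cc <- min(0.999, max(a[a < 1]))
  central <- v[a <= cc]
  # ML for kappa on the doubly truncated null over [-c, c]
  negll <- function(log_km3) {
    kappa <- exp(log_km3) + 3
    -(sum(dnull_pcor(central, kappa, log = TRUE)) -
        length(central) * log(pnull_abs_pcor(cc, kappa)))
  }
  init <- log(max(1e-3, 1 / max(stats::var(central), 1e-12) - 3 + 1e-3))
  opt <- stats::optim(init, negll, method = "Brent",
                      lower = log(1e-3), upper = log(1e8))
  kappa <- exp(opt$par) + 3
  # conservative density-ratio eta0 at the center: empirical central mass
  # over fitted-null central mass, at the empirical median of |p|
  delta <- stats::median(a)
  if (delta <= 0) delta <- cc / 2
  eta0 <- min(1, mean(a <= delta) / pnull_abs_pcor(delta, kappa))
  structure(list(eta0 = eta0, kappa = kappa, m = length(v)),
            class = "EdgeFdrModel")
}

#' Tail-area FDR for partial-correlation magnitudes
#'
#' Two-sided tail-area false discovery rate under the fitted mixture:
#' `Fdr(t) = min(1, eta0 * P0(|P| >= t) / Phat(|P| >= t))`, with the
#' empirical tail taken over `reference` (by default the values themselves).
#' `Fdr(0)` is 1 by convention (a vanishing partial correlation carries no
#' evidence), and monotone non-increase in `|t|` is enforced.
#'
#' @param values partial correlations to score.
#' @param model `EdgeFdrModel` from [fit_edge_null()].
#' @param reference values defining the empirical tail (defaults to `values`).
#' @return numeric vector of FDR values in `[0, 1]`.
#' @export
edge_fdr <- function(values, model, reference = values) {
  t <- abs(values)
  ref <- abs(reference[is.finite(reference)])
  m <- length(ref)
  # empirical survival including the point itself
  surv <- (m - findInterval(t - 1e-15, sort(ref))) / m
  surv <- pmax(surv, 1 / m)
  raw <- pmin(1, model$eta0 * (1 - pnull_abs_pcor(t, model$kappa)) / surv)
  raw[t == 0] <- 1
  # enforce Fdr non-increasing in |t|
  ord <- order(t, decreasing = TRUE)
  mono <- raw
  mono[ord] <- cummax(raw[ord])
  mono
}

# local fdr under the same mixture (reported, never used for selection):
# fdr(t) = min(1, eta0 * f0(t) / fhat(t)) with fhat a kernel estimate of the
# |pcor| density reflected at 0.
local_fdr <- function(values, model, reference = values) {
  a <- abs(reference[is.finite(reference)])
  dens <- stats::density(c(a, -a), from = 0, to = 1, n = 512)
  # density of the symmetrized sample at t is f_|p|(t) / 2 for t in (0, 1]
  fhat_abs <- pmax(2 * stats::approx(dens$x, dens$y, xout = pmin(abs(values), 1),
                                     rule = 2)$y, 1e-12)
  f0_abs <- 2 * dnull_pcor(abs(values), model$kappa)
  pmin(1, model$eta0 * f0_abs / fhat_abs)
}

#' Select significant edges from a partial-correlation matrix
#'
#' Pairs whose tail-area FDR is strictly below `fdr_threshold`
#' (the "FDR < 5%" rule; ties at the threshold are excluded) become edges,
#' weighted by `|pcor|`.
#'
#' @param P symmetric partial-correlation matrix with gene dimnames.
#' @param model `EdgeFdrModel`.
#' @param fdr_threshold strict upper bound on edge FDR (default 0.05).
#' @return data.frame: `gene_a`, `gene_b`, `pcor`, `fdr`, `lfdr` (local fdr,
#'   reported only), sorted by (gene_a, gene_b) with `gene_a < gene_b`.
#' @export
select_edges <- function(P, model, fdr_threshold = 0.05) {
  assert_that(!is.null(rownames(P)), "P needs gene dimnames")
  idx <- which(upper.tri(P), arr.ind = TRUE)
  vals <- P[idx]
  fdr <- edge_fdr(vals, model)
  lfdr <- local_fdr(vals, model)
  keep <- fdr < fdr_threshold
  ed <- data.frame(gene_a = rownames(P)[idx[keep, 1]],
                   gene_b = colnames(P)[idx[keep, 2]],
                   pcor = vals[keep], fdr = fdr[keep], lfdr = lfdr[keep],
                   stringsAsFactors = FALSE)
  swap <- ed$gene_a > ed$gene_b
  tmp <- ed$gene_a[swap]; ed$gene_a[swap] <- ed$gene_b[swap]; ed$gene_b[swap] <- tmp
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL
  ed
}

#' Build a partial-correlation network from log2 expression
#'
#' Convenience wrapper: [shrink_correlation()] then [partial_correlation()],
#' [fit_edge_null()] and [select_edges()], returning nodes tagged with
#' biotype.
#'
#' @param X samples x genes log2-expression matrix.
#' @param biotypes named character vector (`"mRNA"`/`"lncRNA"`) covering the
#'   genes of `X`.
#' @param fdr_threshold strict edge FDR cutoff (default 0.05).
#' @param lambda optional fixed shrinkage intensity.
#' @return list of class `PcorNetwork`: `nodes` (gene_id, biotype), `edges`,
#'   `model`, `lambda`, `pcor` (full matrix).
#' @export
build_pcor_network <- function(X, biotypes, fdr_threshold = 0.05,
                               lambda = NULL) {
  assert_that(all(colnames(X) %in% names(biotypes)),
              "biotypes must cover every gene in X")
  sc <- shrink_correlation(X, lambda = lambda)
  P <- partial_correlation(sc)
  model <- fit_edge_null(P[upper.tri(P)])
  edges <- select_edges(P, model, fdr_threshold)
  nodes <- data.frame(gene_id = colnames(P),
                      biotype = unname(biotypes[colnames(P)]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, model = model,
                 lambda = sc$lambda, pcor = P),
            class = "PcorNetwork")
}

#' @export
print.PcorNetwork <- function(x, ...) {
  cat(sprintf("PcorNetwork: %d nodes (%d lncRNA), %d edges; lambda = %.3f, eta0 = %.3f, kappa = %.1f\n",
              nrow(x$nodes), sum(x$nodes$biotype == "lncRNA"),
              nrow(x$edges), x$lambda, x$model$eta0, x$model$kappa))
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c [ w_in(c) / m - (d_c / 2m)^2 ]` with `m` the total edge weight,
#' `w_in(c)` the weight inside community `c` and `d_c` its weighted degree
#' sum.
#'
#' @param edges data.frame with `gene_a`, `gene_b` and a `weight` column (or
#'   `pcor`, in which case `|pcor|` is used).
#' @param membership named vector mapping node to cluster.
#' @return numeric scalar.
#' @export
modularity_q <- function(edges, membership) {
  if (nrow(edges) == 0) return(0)
  w <- if ("weight" %in% colnames(edges)) edges$weight else abs(edges$pcor)
  m <- sum(w)
  ca <- membership[edges$gene_a]; cb <- membership[edges$gene_b]
  win <- tapply(w[ca == cb], ca[ca == cb], sum)
  deg <- tapply(c(w, w), c(edges$gene_a, edges$gene_b), sum)
  dc <- tapply(deg, membership[names(deg)], sum)
  q <- sum(win) / m - sum((dc / (2 * m))^2)
  unname(q)
}

#' Fast-greedy (Clauset-Newman-Moore) community detection
#'
#' Agglomerative modularity optimization on the `|pcor|`-weighted graph:
#' every node starts as its own community; at each step the connected pair of
#' communities with the largest modularity gain is merged (ties broken by the
#' lexicographically smallest pair of cluster ids, cluster id = smallest node
#' index it contains); the partition with the maximal modularity encountered
#' is returned. Isolated nodes stay singleton clusters. Deterministic given
#' the edge list.
#'
#' @param network `PcorNetwork`, or a data.frame of edges with
#'   `gene_a`/`gene_b` and `weight` or `pcor`.
#' @param nodes optional character vector of node ids (defaults to the
#'   network's nodes; isolated nodes must be listed here to appear).
#' @return list of class `CommunityPartition`: `membership` (named integer
#'   vector with consecutive cluster ids) and `Q`.
#' @export
detect_communities <- function(network, nodes = NULL) {
  if (inherits(network, "PcorNetwork")) {
    edges <- network$edges
    if (is.null(nodes)) nodes <- network$nodes$gene_id
  } else {
    edges <- network
    if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  }
  w <- if (nrow(edges) == 0) numeric(0)
  else if ("weight" %in% colnames(edges)) edges$weight else abs(edges$pcor)
  n <- length(nodes)
  if (nrow(edges) == 0) {
    memb <- stats::setNames(seq_len(n), nodes)
    return(structure(list(membership = memb, Q = 0),
                     class = "CommunityPartition"))
  }
  ia <- match(edges$gene_a, nodes); ib <- match(edges$gene_b, nodes)
  assert_that(!anyNA(ia) && !anyNA(ib), "edge endpoint missing from node list")
  assert_that(all(ia != ib), "self-loops are not allowed")
  m <- sum(w)
  # community-level weight matrix (dense; graphs here are modest)
  E <- matrix(0, n, n)
  for (k in seq_along(w)) {
    E[ia[k], ib[k]] <- E[ia[k], ib[k]] + w[k]
    E[ib[k], ia[k]] <- E[ib[k], ia[k]] + w[k]
  }
  deg <- rowSums(E)
  comm <- seq_len(n)        # community of each node (id = smallest node index)
  active <- rep(TRUE, n)
  win <- rep(0, n)          # internal weight per community
  dc <- deg                 # weighted degree per community
  q_now <- sum(win) / m - sum((dc[active] / (2 * m))^2)
  best_q <- q_now
  best_comm <- comm
  repeat {
    act <- which(active)
    if (length(act) < 2) break
    # candidate merges: connected community pairs
    sub <- E[act, act, drop = FALSE]
    cand <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    ci <- act[cand[, 1]]; cj <- act[cand[, 2]]
    dq <- sub[cand] / m - dc[ci] * dc[cj] / (2 * m^2)
    lo <- pmin(ci, cj); hi <- pmax(ci, cj)
    pick <- order(-dq, lo, hi)[1]
    a <- lo[pick]; b <- hi[pick]
    # merge b into a
    win[a] <- win[a] + win[b] + E[a, b]
    dc[a] <- dc[a] + dc[b]
    E[a, ] <- E[a, ] + E[b, ]
    E[, a] <- E[, a] + E[, b]
    E[a, a] <- 0
    E[b, ] <- 0; E[, b] <- 0
    active[b] <- FALSE
    comm[comm == b] <- a
    q_now <- sum(win[active]) / m - sum((dc[active] / (2 * m))^2)
    if (q_now > best_q + 1e-12) {
      best_q <- q_now
      best_comm <- comm
    }
  }
  # deterministic local-move refinement: sweep nodes in order, adopting the
  # single best positive-gain relocation, until no move improves Q
  A <- matrix(0, n, n)
  for (k in seq_along(w)) {
    A[ia[k], ib[k]] <- A[ia[k], ib[k]] + w[k]
    A[ib[k], ia[k]] <- A[ib[k], ia[k]] + w[k]
  }
  kdeg <- rowSums(A)
  comm <- best_comm
  dcom <- tapply(kdeg, comm, sum)
  dc2 <- stats::setNames(rep(0, n), seq_len(n))
  dc2[names(dcom)] <- dcom
  for (sweep in seq_len(50)) {
    moved <- FALSE
    for (v in seq_len(n)) {
      nb <- which(A[v, ] > 0)
      if (length(nb) == 0) next
      cands <- sort(unique(comm[nb]))
      cands <- setdiff(cands, comm[v])
      if (length(cands) == 0) next
      cur <- comm[v]
      w_to <- vapply(cands, function(d) sum(A[v, comm == d]), numeric(1))
      w_cur <- sum(A[v, comm == cur]) # v has no self-loop
      gain <- (w_to - w_cur) / m -
        kdeg[v] * (dc2[as.character(cands)] - (dc2[as.character(cur)] - kdeg[v])) /
          (2 * m^2)
      bi <- which.max(gain)
      if (gain[bi] > 1e-12) {
        d <- cands[bi]
        dc2[as.character(cur)] <- dc2[as.character(cur)] - kdeg[v]
        dc2[as.character(d)] <- dc2[as.character(d)] + kdeg[v]
        comm[v] <- d
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb_ref <- stats::setNames(comm, nodes)
  q_ref <- modularity_q(
    data.frame(gene_a = nodes[ia], gene_b = nodes[ib], weight = w,
               stringsAsFactors = FALSE), memb_ref)
  if (q_ref > best_q + 1e-12) {
    best_q <- q_ref
    best_comm <- comm
  }
  memb <- stats::setNames(match(best_comm, sort(unique(best_comm))), nodes)
  structure(list(membership = memb, Q = best_q),
            class = "CommunityPartition")
}

#' @export
print.CommunityPartition <- function(x, ...) {
  cat(sprintf("CommunityPartition: %d nodes in %d clusters, Q = %.4f\n",
              length(x$membership), length(unique(x$membership)), x$Q))
  invisible(x)
}

#' Direct mRNA neighborhood of a lncRNA
#'
#' The set of mRNA nodes sharing an edge with the given lncRNA (direct edges
#' only) — the gene list that guilt-by-association annotation is run on.
#'
#' @param network `PcorNetwork`.
#' @param lnc_id lncRNA node id.
#' @return character vector of mRNA ids (possibly empty).
#' @export
lncrna_neighborhood <- function(network, lnc_id) {
  nodes <- network$nodes
  assert_that(lnc_id %in% nodes$gene_id, "id '%s' absent from network", lnc_id)
  assert_that(nodes$biotype[nodes$gene_id == lnc_id] == "lncRNA",
              "id '%s' is not a lncRNA", lnc_id)
  ed <- network$edges
  nb <- c(ed$gene_b[ed$gene_a == lnc_id], ed$gene_a[ed$gene_b == lnc_id])
  sort(intersect(nb, nodes$gene_id[nodes$biotype == "mRNA"]))
}
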