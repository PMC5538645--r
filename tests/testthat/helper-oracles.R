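# Independent oracles: brute-force / enumeration implementations that the
# package's analytic paths are checked against. These deliberately share no
# code with the implementation.

# exhaustive hypergeometric upper tail: enumerate all C(N, n) draws
oracle_hyper <- function(k, K, n, N) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# exact binomial upper tail by term-wise summation
oracle_binom <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# regex-free triple-nucleotide sweep for UGU counts in one window
oracle_ugu_window <- function(seq, start, end) {
  # start/end are 0-based half-open
  chars <- strsplit(seq, "")[[1]]
  count <- 0L
  if (end - start >= 3) {
    for (i in (start + 1):(end - 2)) { # 1-based positions of window triples
      if (chars[i] == "U" && chars[i + 1] == "G" && chars[i + 2] == "U") {
        count <- count + 1L
      }
    }
  }
  count
}

# independent GSEA running-sum enrichment score
oracle_gsea_es <- function(scores, gene_set, weight = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  N <- length(s); K <- sum(hit)
  running <- 0
  best <- 0
  denom <- sum(abs(s[hit])^weight)
  for (i in seq_len(N)) {
    running <- running +
      if (hit[i]) abs(s[i])^weight / denom else -1 / (N - K)
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}

# enumerate all set partitions of nodes, return the best weighted modularity
oracle_best_modularity <- function(edges, nodes) {
  n <- length(nodes)
  parts <- list(integer(0))
  # generate restricted growth strings
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    mx <- if (length(prefix) == 0) 0 else max(prefix)
    out <- list()
    for (v in seq_len(mx + 1)) out <- c(out, grow(c(prefix, v)))
    out
  }
  best <- -Inf
  for (p in grow(integer(0))) {
    memb <- stats::setNames(p, nodes)
    q <- modularity_q(edges, memb)
    if (q > best) best <- q
  }
  best
}

# random full-rank data matrix with named genes
random_data_matrix <- function(n, p, seed) {
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- sprintf("g%02d", seq_len(p))
    X
  })
}

# brute-force Schaefer-Strimmer lambda by explicit double loop
oracle_lambda <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xs <- scale(X)
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- Xs[, i] * Xs[, j]
      r <- sum(w) / (n - 1)
      wbar <- mean(w)
      varr <- n / (n - 1)^3 * sum((w - wbar)^2)
      num <- num + varr
      den <- den + r^2
    }
  }
  max(0, min(1, num / den))
}

# tiny synthetic config for fast structural tests
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_mrna = 120, n_lnc = 10,
             modules = rep(list(list(size = 10, lnc_frac = 0.1,
                                     topology = "random", strength = 0.4,
                                     degree = 2.6, hub_chords = 3,
                                     hub_strength = 0.5)), 2),
             n_up = 20, n_down = 20, ...)
}

# random RNA sequence
random_rna <- function(len, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                        collapse = ""))
}
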