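# Per-contrast differential-regulation calling on FPKM replicates and the
# cross-condition consensus filters. The test is Welch's t on log2(FPKM + c)
# with BH adjustment per contrast; isoform-level machinery is out of scope,
# and externally produced contrast tables with the same columns are accepted
# by every downstream stage.

#' Differential expression for one treatment-vs-control contrast
#'
#' log2 fold change is the difference of arm means of `log2(FPKM + pseudocount)`;
#' p-values come from Welch's two-sample t-test on the same transformed values
#' and are BH-adjusted across all genes of the contrast. With a single
#' replicate per arm only the fold change is computed (`p`/`q` are `NA`).
#' Genes with zero variance in both arms but unequal means get `p = 0` with a
#' warning and a `zero_variance` flag (the effect is infinitely certain under
#' the model); equal-mean constant genes get `p = 1`.
#'
#' @param expr an `ExpressionMatrix`.
#' @param treatment,control condition labels looked up in `expr$meta$condition`.
#' @param depot optional depot restriction (both arms must share it).
#' @param contrast label stored in the result (default
#'   `"<treatment>_vs_<control>"`).
#' @param pseudocount added to FPKM before log2 (default 1).
#' @param alpha,min_abs_log2fc thresholds used for the `direction` call
#'   (defaults 0.05 and 1; boundaries inclusive).
#' @return data.frame (class `ContrastResult`): `gene_id`, `contrast`,
#'   `log2fc`, `p`, `q`, `direction`, `zero_variance`.
#' @export
compute_contrast <- function(expr, treatment, control, depot = NULL,
                             contrast = paste0(treatment, "_vs_", control),
                             pseudocount = 1, alpha = 0.05,
                             min_abs_log2fc = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  meta <- expr$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(depot)) keep <- meta$depot == depot
  ti <- which(keep & meta$condition == treatment)
  ci <- which(keep & meta$condition == control)
  assert_that(length(ti) >= 1, "treatment condition '%s' absent from meta", treatment)
  assert_that(length(ci) >= 1, "control condition '%s' absent from meta", control)
  assert_that(nrow(expr$values) >= 1, "zero genes in expression matrix")
  lx <- log2(expr$values + pseudocount)
  xt <- lx[, ti, drop = FALSE]
  xc <- lx[, ci, drop = FALSE]
  mt <- rowMeans(xt); mc <- rowMeans(xc)
  lfc <- mt - mc
  nt <- length(ti); nc <- length(ci)
  if (nt < 2 || nc < 2) {
    p <- rep(NA_real_, length(lfc)); q <- p
    zv <- rep(FALSE, length(lfc))
  } else {
    vt <- apply(xt, 1, stats::var)
    vc <- apply(xc, 1, stats::var)
    se2 <- vt / nt + vc / nc
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((vt / nt)^2 / (nt - 1) + (vc / nc)^2 / (nc - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    zv <- se2 == 0
    if (any(zv)) {
      p[zv & lfc != 0] <- 0
      p[zv & lfc == 0] <- 1
      if (any(zv & lfc != 0)) {
        warn_bn("%d gene(s) with zero variance in both arms but unequal means; p set to 0",
                sum(zv & lfc != 0))
      }
    }
    q <- bh_adjust(p)
  }
  direction <- rep("ns", length(lfc))
  if (nt >= 2 && nc >= 2) {
    direction[q <= alpha & lfc >= min_abs_log2fc] <- "up"
    direction[q <= alpha & lfc <= -min_abs_log2fc] <- "down"
  }
  structure(data.frame(gene_id = rownames(expr$values), contrast = contrast,
                       log2fc = as.numeric(lfc), p = p, q = q,
                       direction = direction, zero_variance = zv,
                       stringsAsFactors = FALSE),
            class = c("ContrastResult", "data.frame"))
}

#' Split a contrast result into up- and down-regulated gene sets
#'
#' Thresholds are inclusive: a gene qualifies as up when `q <= alpha` and
#' `log2fc >= min_abs_log2fc`, as down when `q <= alpha` and
#' `log2fc <= -min_abs_log2fc` (the conventional "FDR <= 0.05, absolute
#' fold-change >= 2-fold" rule at the defaults).
#'
#' @param results `ContrastResult` data.frame.
#' @param alpha FDR threshold (default 0.05).
#' @param min_abs_log2fc log2 fold-change threshold (default 1).
#' @param fold_change_only allow q-less results (single-replicate designs);
#'   qualification then uses the fold change alone. Must be set explicitly.
#' @return list with character vectors `up` and `down`.
#' @export
apply_de_filter <- function(results, alpha = 0.05, min_abs_log2fc = 1,
                            fold_change_only = FALSE) {
  if (all(is.na(results$q)) && !fold_change_only) {
    stop_bn("results carry no q-values; set fold_change_only = TRUE to filter on log2fc alone")
  }
  if (fold_change_only) {
    up <- results$gene_id[results$log2fc >= min_abs_log2fc]
    down <- results$gene_id[results$log2fc <= -min_abs_log2fc]
  } else {
    ok <- !is.na(results$q) & results$q <= alpha
    up <- results$gene_id[ok & results$log2fc >= min_abs_log2fc]
    down <- results$gene_id[ok & results$log2fc <= -min_abs_log2fc]
  }
  list(up = up, down = down)
}

#' Cross-condition consensus filter
#'
#' Counts, per gene, in how many of the five contrasts it qualifies as
#' differentially regulated (`q <= alpha`, `|log2fc| >= min_abs_log2fc`).
#' `mode = "any"` counts qualification regardless of sign (the network-input
#' rule at `k_min = 3`); `mode = "concordant"` counts only sign-consistent
#' qualifications under the browning sign convention: induction during
#' browning/BAT activation agrees with repression during whitening. Each
#' contrast must declare its `browning_sign` (+1 for browning/activation
#' contrasts, -1 for whitening) via the `signs` argument.
#'
#' @param contrasts list of `ContrastResult` data.frames (one per contrast).
#' @param signs named numeric vector (+1/-1), names matching the contrast
#'   labels; required for `mode = "concordant"`.
#' @param k_min minimum number of qualifying contrasts (3 for the network
#'   input, 4 for the stringent consensus list).
#' @param mode `"any"` or `"concordant"`.
#' @param direction for concordant mode, the consensus direction sought:
#'   `"up"` (browning-induced, default) or `"down"`.
#' @param alpha,min_abs_log2fc qualification thresholds (inclusive).
#' @return data.frame (class `ConsensusTable`): `gene_id`,
#'   `qualifying_contrasts` (comma-joined), `n_qualifying`, `retained`.
#' @export
consensus_filter <- function(contrasts, k_min = 3,
                             mode = c("any", "concordant"), signs = NULL,
                             direction = c("up", "down"),
                             alpha = 0.05, min_abs_log2fc = 1) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  assert_that(length(contrasts) == 5, "exactly 5 contrasts are required")
  labels <- vapply(contrasts, function(x) x$contrast[1], character(1))
  assert_that(!anyDuplicated(labels), "duplicate contrast labels")
  assert_that(k_min >= 1 && k_min <= 5, "k_min must be in 1..5")
  if (mode == "concordant") {
    assert_that(!is.null(signs) && all(labels %in% names(signs)),
                "concordant mode: every contrast needs a browning_sign declaration")
    assert_that(all(signs %in% c(-1, 1)), "signs must be +1 or -1")
  }
  genes <- sort(unique(unlist(lapply(contrasts, `[[`, "gene_id"))))
  qual <- matrix(FALSE, length(genes), 5, dimnames = list(genes, labels))
  for (i in seq_along(contrasts)) {
    cr <- contrasts[[i]]
    ok <- !is.na(cr$q) & cr$q <= alpha & abs(cr$log2fc) >= min_abs_log2fc
    if (mode == "concordant") {
      want <- if (direction == "up") 1 else -1
      ok <- ok & sign(cr$log2fc) * signs[[labels[i]]] == want
    }
    qual[cr$gene_id[ok], i] <- TRUE
  }
  n_qual <- rowSums(qual)
  structure(data.frame(
    gene_id = genes,
    qualifying_contrasts = apply(qual, 1, function(r)
      paste(labels[r], collapse = ",")),
    n_qualifying = as.integer(n_qual),
    retained = n_qual >= k_min,
    stringsAsFactors = FALSE, row.names = NULL),
    class = c("ConsensusTable", "data.frame"),
    mode = mode, k_min = k_min)
}

#' Venn-region tabulation and pairwise overlap significance
#'
#' Counts every region of the k-set Venn diagram (k <= 5) and computes the
#' upper-tail hypergeometric p for each pairwise overlap. The universe must be
#' declared explicitly; there is no default.
#'
#' @param sets named list of character vectors (2 to 5 sets).
#' @param universe character vector of all eligible identifiers.
#' @return list with `regions` (data.frame: membership pattern, count) and
#'   `pairwise` (data.frame: set_a, set_b, k, K, n, N, p).
#' @export
overlap_tabulate <- function(sets, universe) {
  assert_that(length(sets) >= 2 && length(sets) <= 5,
              "between 2 and 5 sets are supported")
  assert_that(!is.null(names(sets)) && !anyDuplicated(names(sets)),
              "sets must be uniquely named")
  outside <- setdiff(unique(unlist(sets)), universe)
  assert_that(length(outside) == 0, "element(s) outside declared universe: %s",
              paste(utils::head(outside, 5), collapse = ", "))
  k <- length(sets)
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  all_patterns <- apply(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE], 1,
                        paste, collapse = "")
  counts <- table(factor(pattern, levels = sort(all_patterns)))
  regions <- data.frame(pattern = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  N <- length(universe)
  pairs <- utils::combn(names(sets), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- sets[[pairs[1, j]]]; b <- sets[[pairs[2, j]]]
    kk <- length(intersect(a, b))
    data.frame(set_a = pairs[1, j], set_b = pairs[2, j],
               k = kk, K = length(unique(a)), n = length(unique(b)), N = N,
               p = hypergeom_overlap(kk, length(unique(a)), length(unique(b)), N),
               stringsAsFactors = FALSE)
  }))
  list(regions = regions, pairwise = pairwise)
}
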