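# Tissue-specificity calling over a multi-tissue FPKM panel, BAT-selective
# gene listing, strand-aware 50-kb promoter windows, and ChIP-peak /
# promoter overlap enrichment.

#' Tissue-specific gene sets from a multi-tissue panel
#'
#' A gene is called specific to tissue `t` when `FPKM_t >= min_fpkm` and
#' `FPKM_t >= ratio * median(FPKM over all other tissues)`. A gene may be
#' assigned to at most `max_tissues` tissues (the top ones by FPKM). The rule
#' itself is a declared, replaceable construction; what downstream analyses
#' consume is only the resulting sets.
#'
#' @param panel genes x tissues numeric matrix (FPKM >= 0) with dimnames.
#' @param ratio fold-over-median threshold (default 5).
#' @param min_fpkm absolute expression floor (default 1).
#' @param max_tissues maximum assignments per gene (default 2).
#' @return named list of character vectors, one per tissue.
#' @export
tissue_specific_sets <- function(panel, ratio = 5, min_fpkm = 1,
                                 max_tissues = 2) {
  assert_that(is.matrix(panel) && ncol(panel) >= 2,
              "panel needs at least 2 tissues")
  assert_that(!anyDuplicated(colnames(panel)), "tissue labels must be unique")
  assert_that(all(panel >= 0), "panel values must be non-negative")
  nt <- ncol(panel)
  qualifies <- matrix(FALSE, nrow(panel), nt, dimnames = dimnames(panel))
  for (t in seq_len(nt)) {
    others <- panel[, -t, drop = FALSE]
    med <- apply(others, 1, stats::median)
    qualifies[, t] <- panel[, t] >= min_fpkm & panel[, t] >= ratio * med
  }
  over <- rowSums(qualifies) > max_tissues
  if (any(over)) {
    for (g in which(over)) {
      keep <- order(-panel[g, ], colnames(panel))[seq_len(max_tissues)]
      qualifies[g, -keep] <- FALSE
    }
  }
  sets <- lapply(seq_len(nt), function(t) rownames(panel)[qualifies[, t]])
  names(sets) <- colnames(panel)
  sets
}

#' Overlap of a DE gene set with tissue-specific sets
#'
#' Hypergeometric upper-tail overlap of the query against each tissue's
#' specific set, BH-adjusted across tissues.
#'
#' @param de_set character vector of query genes (must lie in `universe`).
#' @param tissue_sets named list from [tissue_specific_sets()].
#' @param universe declared gene universe (the catalog).
#' @return data.frame: `set` (tissue), `k`, `K`, `n`, `N`, `p`, `q`.
#' @export
specificity_overlap <- function(de_set, tissue_sets, universe) {
  enrich_table(de_set, tissue_sets, universe)
}

#' BAT-selective gene list
#'
#' Genes enriched in BAT relative to both white depots:
#' `FPKM_BAT >= min_fpkm` and `FPKM_BAT >= fold * max(FPKM_iWAT, FPKM_eWAT)`.
#'
#' @param expr_bat,expr_iwat,expr_ewat named FPKM vectors over one shared
#'   gene catalog.
#' @param fold enrichment factor (default 3).
#' @param min_fpkm absolute floor in BAT (default 1).
#' @return character vector of gene ids.
#' @export
bat_selective_genes <- function(expr_bat, expr_iwat, expr_ewat, fold = 3,
                                min_fpkm = 1) {
  g <- names(expr_bat)
  assert_that(!is.null(g) && identical(g, names(expr_iwat)) &&
                identical(g, names(expr_ewat)),
              "the three depot vectors must share one gene catalog")
  keep <- expr_bat >= min_fpkm & expr_bat >= fold * pmax(expr_iwat, expr_ewat)
  g[keep]
}

#' Strand-aware promoter windows upstream of the TSS
#'
#' For a `+` strand gene the window is `[max(0, tss - width), tss)`; for a
#' `-` strand gene, `[tss, tss + width)`. Windows are clipped at the contig
#' start, never merged across genes.
#'
#' @param annotation validated annotation data.frame.
#' @param width window width in bp (default 50000).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
promoter_windows <- function(annotation, width = 50000) {
  ann <- validate_annotation(annotation)
  plus <- ann$strand == "+"
  start <- ifelse(plus, pmax(0, ann$tss - width), ann$tss)
  end <- ifelse(plus, ann$tss, ann$tss + width)
  data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# which windows are overlapped by >= 1 peak (any-bp overlap of half-open
# intervals); O((n + m) log) per chromosome via sorted peaks + cummax ends
windows_bound <- function(windows, peaks) {
  bound <- rep(FALSE, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0) next
    ord <- order(pk$start)
    ps <- pk$start[ord]
    ce <- cummax(pk$end[ord])
    # peaks with start <= win_end - 1; bound iff max end among them > win_start
    j <- findInterval(windows$end[wi] - 1, ps)
    hit <- j >= 1 & ifelse(j >= 1, ce[pmax(j, 1)], 0) > windows$start[wi]
    bound[wi] <- hit
  }
  bound
}

#' Peak-promoter overlap enrichment
#'
#' A gene is "bound" by a peak source when at least one peak overlaps its
#' promoter window by >= 1 bp. Reports, per source: the bound fraction of the
#' query genes (the "percent of promoters targeted" statistic) and the
#' hypergeometric overlap `(k = bound & query, K = bound in universe,
#' n = |query|, N = |universe|)`, BH-adjusted across sources. Peaks on
#' chromosomes absent from the annotation are ignored with a warning.
#'
#' @param peaks peak data.frame (one or several sources in the `source`
#'   column).
#' @param windows promoter windows from [promoter_windows()].
#' @param query_genes genes of interest (e.g. browning-induced).
#' @param universe declared gene universe (must contain `query_genes`).
#' @return list with `per_source` (data.frame: source, bound_fraction, k, K,
#'   n, N, p, q) and `bound` (logical matrix gene x source).
#' @export
peak_promoter_enrichment <- function(peaks, windows, query_genes, universe) {
  assert_that(all(query_genes %in% universe),
              "query genes outside the declared universe")
  windows <- windows[windows$gene_id %in% universe, , drop = FALSE]
  stray <- setdiff(unique(peaks$chrom), unique(windows$chrom))
  if (length(stray) > 0) {
    warn_bn("ignoring peaks on chromosome(s) absent from annotation: %s",
            paste(stray, collapse = ", "))
    peaks <- peaks[!peaks$chrom %in% stray, , drop = FALSE]
  }
  sources <- unique(peaks$source)
  if (length(sources) == 0) sources <- character(0)
  bound <- matrix(FALSE, nrow(windows), length(sources),
                  dimnames = list(windows$gene_id, sources))
  for (s in sources) {
    bound[, s] <- windows_bound(windows, peaks[peaks$source == s, , drop = FALSE])
  }
  rows <- lapply(sources, function(s) {
    bound_genes <- rownames(bound)[bound[, s]]
    k <- length(intersect(bound_genes, query_genes))
    K <- length(bound_genes)
    n <- length(query_genes)
    N <- length(universe)
    data.frame(source = s,
               bound_fraction = if (n > 0) k / n else NA_real_,
               k = k, K = K, n = n, N = N,
               p = hypergeom_overlap(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  per_source <- do.call(rbind, rows)
  if (is.null(per_source)) {
    per_source <- data.frame(source = character(), bound_fraction = numeric(),
                             k = integer(), K = integer(), n = integer(),
                             N = integer(), p = numeric(), q = numeric(),
                             stringsAsFactors = FALSE)
  } else {
    per_source$q <- bh_adjust(per_source$p)
  }
  list(per_source = per_source, bound = bound)
}
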