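# End-to-end driver: simulate -> differential -> consensus -> network ->
# communities -> guilt-by-association annotation -> regulatory -> UTR scan ->
# ordination, under one master seed, with a JSON run manifest carrying the
# config echo, every threshold actually applied, per-stage sub-seeds and
# output-file digests. Re-running with an identical config is byte-identical.

#' Run the full synthetic-study analysis pipeline
#'
#' Stages (each writes TSV/JSON under `outdir`):
#' \enumerate{
#'   \item generate the synthetic study ([simulate_study()]) under `data/`;
#'   \item per-contrast differential expression ([compute_contrast()]);
#'   \item consensus filters: any-direction at `k_min_network` (network
#'     input) and concordant browning-induced at `k_min_consensus`;
#'   \item five-way Venn tabulation of the up-programs;
#'   \item shrinkage partial-correlation network on the consensus genes with
#'     edge FDR < `edge_fdr` and fast-greedy communities;
#'   \item per-lncRNA neighborhood enrichment and per-cluster binomial
#'     overrepresentation against the emitted gene sets; preranked GSEA on
#'     the first contrast's log2 fold changes;
#'   \item tissue-specific sets, specificity overlap, BAT-selective genes,
#'     promoter windows and peak-promoter enrichment;
#'   \item UGU window scan of the BAT-selective genes' 3'UTRs;
#'   \item FPKM > 5 filter, PCA and Ward/Spearman clustering of samples.
#' }
#' A stage failure aborts with the stage named and quarantines partial
#' outputs under `failed/`.
#'
#' @param config a `SimConfig` (synthetic mode).
#' @param outdir output directory.
#' @param k_min_network,k_min_consensus consensus thresholds (3 and 4).
#' @param edge_fdr strict edge FDR bound (default 0.05).
#' @param alpha,min_abs_log2fc DE thresholds (0.05, 1).
#' @param min_fpkm_pca strict FPKM floor for ordination (5).
#' @param gsea_n_perm permutations for the GSEA stage (default 200; scaled
#'   for runtime, the statistic itself is exact).
#' @return invisibly, a list with the in-memory stage results and `manifest`.
#' @export
run_all <- function(config, outdir, k_min_network = 3, k_min_consensus = 4,
                    edge_fdr = 0.05, alpha = 0.05, min_abs_log2fc = 1,
                    min_fpkm_pca = 5, gsea_n_perm = 200) {
  stopifnot(inherits(config, "SimConfig"))
  assert_that(k_min_network <= nrow(config$contrasts) &&
                k_min_consensus <= nrow(config$contrasts),
              "k_min exceeds the number of contrasts (%d)",
              nrow(config$contrasts))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  res <- new.env(parent = emptyenv())
  on_fail <- function(e) {
    failed <- file.path(outdir, "failed")
    dir.create(failed, showWarnings = FALSE)
    for (f in setdiff(list.files(outdir), "failed")) {
      file.rename(file.path(outdir, f), file.path(failed, f))
    }
    stop_bn("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  tryCatch({
    stage <- "simulate"
    sim <- simulate_study(config, file.path(outdir, "data"))
    truth <- sim$truth
    expr <- read_expression(sim$paths$expression, sim$paths$meta)
    ann <- read_annotation(sim$paths$annotation)
    sets <- read_gmt(sim$paths$gene_sets)
    utrs <- read_fasta(sim$paths$utrs)
    peaks <- do.call(rbind, lapply(config$peak_sources, function(s)
      read_bed(sim$paths[[paste0("peaks_", s)]], source = s)))

    stage <- "differential"
    contrasts <- lapply(seq_len(nrow(config$contrasts)), function(i) {
      cc <- config$contrasts[i, ]
      compute_contrast(expr, cc$treatment, cc$control, depot = cc$depot,
                       contrast = cc$name, alpha = alpha,
                       min_abs_log2fc = min_abs_log2fc)
    })
    names(contrasts) <- config$contrasts$name
    for (nm in names(contrasts)) {
      write_tsv_strict(contrasts[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")))
    }

    stage <- "consensus"
    signs <- stats::setNames(config$contrasts$browning_sign,
                             config$contrasts$name)
    cons_any <- consensus_filter(contrasts, k_min = k_min_network,
                                 mode = "any", alpha = alpha,
                                 min_abs_log2fc = min_abs_log2fc)
    cons_up <- consensus_filter(contrasts, k_min = k_min_consensus,
                                mode = "concordant", signs = signs,
                                direction = "up", alpha = alpha,
                                min_abs_log2fc = min_abs_log2fc)
    write_tsv_strict(cons_any, file.path(outdir, "consensus_any_k3.tsv"))
    write_tsv_strict(cons_up, file.path(outdir, "consensus_concordant_k4.tsv"))

    stage <- "venn"
    up_sets <- lapply(contrasts, function(cr)
      apply_de_filter(cr, alpha, min_abs_log2fc)$up)
    venn <- overlap_tabulate(up_sets, universe = rownames(expr$values))
    write_tsv_strict(venn$regions, file.path(outdir, "venn_up_regions.tsv"))
    write_tsv_strict(venn$pairwise, file.path(outdir, "venn_up_pairwise.tsv"))

    stage <- "network"
    net_genes <- cons_any$gene_id[cons_any$retained]
    assert_that(length(net_genes) >= 20,
                "only %d consensus genes; too few for network inference",
                length(net_genes))
    X <- t(log2(expr$values[net_genes, , drop = FALSE] + 1))
    network <- build_pcor_network(X, truth$biotype, fdr_threshold = edge_fdr)
    partition <- detect_communities(network)
    write_network(network, file.path(outdir, "network_edges.tsv"),
                  file.path(outdir, "network_nodes.tsv"),
                  partition = partition,
                  path_graphml = file.path(outdir, "network.graphml"))
    jsonlite::write_json(
      list(eta0 = network$model$eta0, kappa = network$model$kappa,
           lambda = network$lambda, edge_fdr_threshold = edge_fdr,
           modularity_Q = partition$Q,
           n_clusters = length(unique(partition$membership))),
      file.path(outdir, "network_null_model.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "enrichment"
    lnc_annot <- annotate_lncrnas(network, sets)
    write_tsv_strict(lnc_annot, file.path(outdir, "lncrna_annotation.tsv"))
    cl_over <- cluster_overrep(network, partition, sets)
    write_tsv_strict(cl_over, file.path(outdir, "cluster_overrep.tsv"))
    scores <- stats::setNames(contrasts[[1]]$log2fc, contrasts[[1]]$gene_id)
    gsea <- gsea_collection(scores, sets,
                            seed = sub_seed(config$seed, "gsea"),
                            n_perm = gsea_n_perm)
    write_tsv_strict(gsea, file.path(outdir, "gsea_contrast1.tsv"))

    stage <- "regulatory"
    panel_df <- read_tsv_strict(file.path(outdir, "data", "tissue_panel.tsv"))
    panel <- as.matrix(panel_df[, -1])
    rownames(panel) <- panel_df$gene_id
    tsets <- tissue_specific_sets(panel)
    spec <- specificity_overlap(cons_up$gene_id[cons_up$retained], tsets,
                                universe = rownames(panel))
    write_tsv_strict(spec, file.path(outdir, "tissue_specificity_overlap.tsv"))
    bat_sel <- bat_selective_genes(panel[, "BAT"], panel[, "iWAT"],
                                   panel[, "eWAT"])
    writeLines(sort(bat_sel), file.path(outdir, "bat_selective_genes.txt"))
    windows <- promoter_windows(ann, width = config$promoter_width)
    ppe <- peak_promoter_enrichment(peaks, windows,
                                    query_genes = cons_up$gene_id[cons_up$retained],
                                    universe = ann$gene_id)
    write_tsv_strict(ppe$per_source, file.path(outdir, "peak_promoter_enrichment.tsv"))

    stage <- "motif_scan"
    scan_genes <- intersect(names(utrs), bat_sel)
    if (length(scan_genes) == 0) scan_genes <- names(utrs)
    cbs_rank <- rank_cbs_candidates(scan_utrs(utrs[scan_genes]),
                                    tier_threshold = config$cbs_tier)
    write_tsv_strict(cbs_rank, file.path(outdir, "cbs_ranking.tsv"))

    stage <- "ordination"
    expr_f <- filter_expressed(expr, min_fpkm = min_fpkm_pca)
    mrna_f <- expression_matrix(
      expr_f$values[truth$biotype[rownames(expr_f$values)] == "mRNA", ,
                    drop = FALSE], expr_f$meta)
    pca <- pca_samples(mrna_f)
    pca_df <- data.frame(sample_id = rownames(pca$scores),
                         pca$scores[, 1:min(4, ncol(pca$scores)), drop = FALSE],
                         stringsAsFactors = FALSE, check.names = FALSE)
    write_tsv_strict(pca_df, file.path(outdir, "pca_scores.tsv"))
    write_tsv_strict(
      data.frame(component = paste0("PC", seq_along(pca$var_explained)),
                 var_explained = pca$var_explained),
      file.path(outdir, "pca_variance.tsv"))
    hc <- hcluster_samples(expr_f)
    write_tsv_strict(
      data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                 height = hc$height),
      file.path(outdir, "hclust_merges.tsv"))

    stage <- "manifest"
    thresholds <- list(alpha = alpha, min_abs_log2fc = min_abs_log2fc,
                       k_min_network = k_min_network,
                       k_min_consensus = k_min_consensus,
                       edge_fdr = edge_fdr, min_fpkm_pca = min_fpkm_pca,
                       gsea_n_perm = gsea_n_perm,
                       promoter_width = config$promoter_width,
                       cbs_tier = config$cbs_tier,
                       pca_transform = "log2(FPKM+1)",
                       hclust = "ward.D2 on 1 - spearman rho")
    files <- sort(setdiff(
      list.files(outdir, recursive = TRUE),
      c("run_manifest.json", file.path("failed", list.files(file.path(outdir, "failed"))))))
    digests <- as.list(tools::md5sum(file.path(outdir, files)))
    names(digests) <- files
    manifest <- list(
      seed = config$seed,
      sub_seeds = list(expression = sub_seed(config$seed, sprintf(
        "expression_n%d", ncol(expr$values))),
        gsea = sub_seed(config$seed, "gsea")),
      thresholds = thresholds,
      config = config[setdiff(names(config), c("modules", "contrasts"))],
      n_consensus_network = sum(cons_any$retained),
      n_consensus_up = sum(cons_up$retained),
      n_edges = nrow(network$edges),
      modularity_Q = partition$Q,
      file_digests = digests)
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(truth = truth, expr = expr, contrasts = contrasts,
                   consensus_any = cons_any, consensus_up = cons_up,
                   network = network, partition = partition,
                   lnc_annotation = lnc_annot, cluster_overrep = cl_over,
                   gsea = gsea, tissue_sets = tsets, specificity = spec,
                   bat_selective = bat_sel, peak_enrichment = ppe,
                   cbs_ranking = cbs_rank, pca = pca, hclust = hc,
                   manifest = manifest))
  }, error = on_fail)
}
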