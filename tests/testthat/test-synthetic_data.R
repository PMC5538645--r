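test_that("sharing fraction controls cross-condition program identity", {
  # no modules so programs are pure pool draws; flip off so "up" sets compare
  cfg1 <- sim_config(seed = 5, n_mrna = 400, n_lnc = 20, modules = list(),
                     n_up = 30, n_down = 30, sharing = 1,
                     whitening_flip = FALSE)
  t1 <- build_truth(cfg1)
  ups <- lapply(t1$de, `[[`, "up")
  for (u in ups[-1]) expect_setequal(u, ups[[1]])

  cfg0 <- sim_config(seed = 5, n_mrna = 400, n_lnc = 20, modules = list(),
                     n_up = 30, n_down = 30, sharing = 0,
                     whitening_flip = FALSE)
  t0 <- build_truth(cfg0)
  ups0 <- lapply(t0$de, `[[`, "up")
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(ups0[[i]], ups0[[j]]), 0)
  }
})

test_that("truth manifests are deterministic and stream-isolated", {
  cfg <- small_config(seed = 9)
  t1 <- suppressMessages(build_truth(cfg))
  t2 <- suppressMessages(build_truth(cfg))
  expect_identical(t1, t2)
  # same seed, different component labels give different draws
  expect_false(sub_seed(9, "expression_n12") == sub_seed(9, "peaks"))
})

test_that("module covariances are positive definite and edges consistent", {
  cfg <- small_config(seed = 2)
  truth <- suppressMessages(build_truth(cfg))
  for (Om in truth$precisions) {
    ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    S <- solve(Om)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  # every planted edge connects genes of one module, present in the catalog
  te <- truth$true_edges
  expect_true(all(te$gene_a %in% truth$genes))
  expect_true(all(truth$membership[te$gene_a] == truth$membership[te$gene_b]))
  # an impossible band structure fails loudly
  bad <- sim_config(seed = 1, n_mrna = 50, n_lnc = 5,
                    modules = list(list(size = 10, lnc_frac = 0,
                                        topology = "band", strength = 0.6,
                                        degree = 2)),
                    n_up = 5, n_down = 5)
  expect_error(build_truth(bad), "positive definite")
})

test_that("zero-noise limit makes replicates of a condition identical", {
  cfg <- sim_config(seed = 4, n_mrna = 50, n_lnc = 5, modules = list(),
                    n_up = 0, n_down = 0, noise_sd = 0)
  truth <- build_truth(cfg)
  expr <- simulate_expression(truth)
  grp <- paste(expr$meta$depot, expr$meta$condition)
  for (g in unique(grp)) {
    cols <- expr$values[, grp == g, drop = FALSE]
    expect_lt(max(abs(cols - cols[, 1])), 1e-12)
  }
})

test_that("planted effects and edge signs are recovered at large n", {
  cfg <- sim_config(seed = 6, n_mrna = 150, n_lnc = 10,
                    modules = list(list(size = 10, lnc_frac = 0,
                                        topology = "band", strength = 0.4,
                                        degree = 2)),
                    n_up = 20, n_down = 20, effect = 2, replicates = 60,
                    noise_sd = 0.3)
  truth <- build_truth(cfg)
  expr <- simulate_expression(truth)
  # empirical mean log2FC of a planted non-module up gene ~ 2 (MC error)
  free_up <- setdiff(truth$de$cold_iWAT$up,
                     names(truth$membership)[truth$membership > 0])
  lx <- log2(expr$values)
  m <- expr$meta
  lfc <- rowMeans(lx[free_up, m$depot == "iWAT" & m$condition == "cold"]) -
    rowMeans(lx[free_up, m$depot == "iWAT" & m$condition == "control"])
  expect_lt(max(abs(lfc - 2)), 0.5)
  expect_lt(abs(mean(lfc) - 2), 0.1)

  # empirical partial correlation of planted band edges has the planted sign
  meta <- data.frame(sample_id = sprintf("s%d", 1:500), depot = "iWAT",
                     condition = "control", replicate = 1:500,
                     stringsAsFactors = FALSE)
  big <- simulate_expression(truth, cfg, meta = meta)
  ids <- rownames(truth$precisions[[1]])
  P <- partial_correlation(stats::cor(t(log2(big$values[ids, ]))))
  te <- truth$true_edges
  est <- P[cbind(te$gene_a, te$gene_b)]
  expect_true(all(sign(est) == sign(te$pcor)))
})

test_that("peaks land in strand-aware upstream windows", {
  cfg <- small_config(seed = 8, peak_target_rate = 1,
                      peak_background_per_gene = 0)
  truth <- suppressMessages(build_truth(cfg))
  peaks <- simulate_peaks(truth)
  win <- promoter_windows(truth$annotation)
  rownames(win) <- win$gene_id
  tw <- win[truth$peak_targets, ]
  # every emitted peak lies inside some target window (background rate 0)
  for (r in seq_len(nrow(peaks))) {
    inside <- any(tw$chrom == peaks$chrom[r] &
                    tw$start <= peaks$start[r] & tw$end >= peaks$end[r])
    expect_true(inside)
  }
  empty <- small_config(seed = 8, peak_target_rate = 0,
                        peak_background_per_gene = 0)
  t2 <- suppressMessages(build_truth(empty))
  t2$peak_targets <- character(0)
  expect_identical(nrow(simulate_peaks(t2, empty)), 0L)
})

test_that("planted UGU windows are exact and infeasible plans rejected", {
  cfg <- small_config(seed = 12)
  truth <- suppressMessages(build_truth(cfg))
  utr <- simulate_utrs(truth)
  for (r in seq_len(nrow(utr$truth$cbs))) {
    g <- utr$truth$cbs$gene_id[r]
    planned <- utr$truth$cbs$planned[r]
    ws <- count_ugu_windows(utr$seqs[[g]])
    expect_identical(max(ws$ugu_count), planned)
    expect_identical(utr$truth$cbs$achieved[r], planned)
  }
  # unplanted genes never reach the planted tier
  other <- setdiff(names(utr$seqs), utr$truth$cbs$gene_id)
  maxes <- vapply(utr$seqs[other], function(s) max(count_ugu_windows(s)$ugu_count),
                  integer(1))
  expect_lt(max(maxes), min(truth$config$cbs_counts))
  expect_error(small_config(seed = 1, cbs_counts = 50), "infeasible")
})

test_that("simulate_study emits byte-identical files for identical configs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_config(seed = 77)
  suppressMessages(simulate_study(cfg, d1))
  suppressMessages(simulate_study(cfg, d2))
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
})
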