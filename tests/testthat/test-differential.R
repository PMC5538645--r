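make_expr <- function(values, conditions, depot = "iWAT") {
  n <- ncol(values)
  meta <- data.frame(sample_id = paste0("s", seq_len(n)), depot = depot,
                     condition = conditions,
                     replicate = stats::ave(seq_len(n), conditions,
                                            FUN = seq_along),
                     stringsAsFactors = FALSE)
  colnames(values) <- meta$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  expression_matrix(values, meta)
}

# fabricate a ContrastResult row set
fake_contrast <- function(genes, lfc, q, contrast) {
  structure(data.frame(gene_id = genes, contrast = contrast, log2fc = lfc,
                       p = q, q = q, direction = "ns", zero_variance = FALSE,
                       stringsAsFactors = FALSE),
            class = c("ContrastResult", "data.frame"))
}

test_that("compute_contrast gets the closed-form cases right", {
  vals <- rbind(const = c(5, 5, 5, 5),
                fc = c(7, 7, 1, 1))
  ex <- make_expr(vals, c("trt", "trt", "ctl", "ctl"))
  expect_warning(cr <- compute_contrast(ex, "trt", "ctl"), "zero variance")
  expect_identical(cr$log2fc[cr$gene_id == "const"], 0)
  expect_identical(cr$direction[cr$gene_id == "const"], "ns")
  # log2((7+1)/(1+1)) = 2 exactly
  expect_equal(cr$log2fc[cr$gene_id == "fc"], 2)

  # single replicate per arm: log2fc only
  ex1 <- make_expr(rbind(g = c(7, 1)), c("trt", "ctl"))
  cr1 <- compute_contrast(ex1, "trt", "ctl")
  expect_equal(cr1$log2fc, 2)
  expect_true(is.na(cr1$p) && is.na(cr1$q))
  expect_error(apply_de_filter(cr1), "fold_change_only")
  expect_identical(apply_de_filter(cr1, fold_change_only = TRUE)$up, "g")

  expect_error(compute_contrast(ex, "missing", "ctl"), "absent")
})

test_that("zero variance with unequal means flags and sets p to 0", {
  vals <- rbind(zv = c(4, 4, 1, 1), ok = c(5, 6, 4, 5))
  ex <- make_expr(vals, c("trt", "trt", "ctl", "ctl"))
  expect_warning(cr <- compute_contrast(ex, "trt", "ctl"), "zero variance")
  expect_identical(cr$p[cr$gene_id == "zv"], 0)
  expect_true(cr$zero_variance[cr$gene_id == "zv"])
})

test_that("DE filter thresholds are inclusive and sets are disjoint", {
  cr <- fake_contrast(c("a", "b", "c", "d"),
                      lfc = c(1.2, 1.0, 0.9, -1.0),
                      q = c(0.01, 0.05, 0.01, 0.05), "x")
  f <- apply_de_filter(cr)
  expect_setequal(f$up, c("a", "b")) # q = 0.05 and lfc = 1.0 inclusive
  expect_setequal(f$down, "d")
  expect_length(intersect(f$up, f$down), 0)
  # property: up/down disjoint on computed contrasts
  cfg <- small_config(seed = 21)
  truth <- suppressMessages(build_truth(cfg))
  expr <- simulate_expression(truth)
  cc <- compute_contrast(expr, "cold", "control", depot = "iWAT")
  ff <- apply_de_filter(cc)
  expect_length(intersect(ff$up, ff$down), 0)
})

test_that("consensus filter counts contrasts under both modes", {
  labs <- c("c1", "c2", "c3", "c4", "c5")
  signs <- stats::setNames(c(1, 1, 1, 1, -1), labs)
  genes <- c("gA", "gB", "gC")
  # gA qualifies (up) in contrasts 1, 2, 5; gB up in 1-4 and also up in 5;
  # gC in 2 contrasts only
  qual <- list(c1 = c(gA = 1, gB = 1, gC = 1), c2 = c(gA = 1, gB = 1, gC = 1),
               c3 = c(gB = 1), c4 = c(gB = 1), c5 = c(gA = 1, gB = 1))
  contrasts <- lapply(labs, function(l) {
    lfc <- ifelse(genes %in% names(qual[[l]]), 2, 0)
    fake_contrast(genes, lfc, q = ifelse(lfc != 0, 0.01, 0.9), l)
  })
  any3 <- consensus_filter(contrasts, k_min = 3, mode = "any")
  expect_true(any3$retained[any3$gene_id == "gA"])
  expect_false(any3$retained[any3$gene_id == "gC"])
  # concordant: gB's whitening (c5) up-qualification must not count
  conc <- consensus_filter(contrasts, k_min = 4, mode = "concordant",
                           signs = signs)
  expect_identical(conc$n_qualifying[conc$gene_id == "gB"], 4L)
  expect_true(conc$retained[conc$gene_id == "gB"])
  expect_false(conc$retained[conc$gene_id == "gA"]) # 2 concordant only
  expect_error(consensus_filter(contrasts, mode = "concordant"),
               "sign")
  expect_error(consensus_filter(contrasts[1:4]), "5 contrasts")
})

test_that("consensus is monotone in k_min", {
  with_seed(31, {
    labs <- paste0("c", 1:5)
    genes <- sprintf("g%02d", 1:40)
    contrasts <- lapply(labs, function(l) {
      fake_contrast(genes, lfc = sample(c(-2, 0, 2), 40, replace = TRUE),
                    q = sample(c(0.01, 0.5), 40, replace = TRUE), l)
    })
    k3 <- consensus_filter(contrasts, k_min = 3, mode = "any")
    k4 <- consensus_filter(contrasts, k_min = 4, mode = "any")
    expect_true(all(k4$gene_id[k4$retained] %in% k3$gene_id[k3$retained]))
  })
})

test_that("overlap_tabulate enumerates Venn regions and pairwise p", {
  res <- overlap_tabulate(list(A = c("a", "b"), B = c("b", "c")),
                          universe = c("a", "b", "c", "d"))
  counts <- stats::setNames(res$regions$count, res$regions$pattern)
  expect_identical(counts[["11"]], 1L) # b
  expect_identical(counts[["10"]], 1L)
  expect_identical(counts[["01"]], 1L)
  expect_identical(counts[["00"]], 1L)

  # exhaustive-enumeration oracle: K=3, n=3, k=2, N=6 -> 0.5
  res2 <- overlap_tabulate(list(A = c("a", "b", "c"), B = c("b", "c", "d")),
                           universe = letters[1:6])
  expect_equal(res2$pairwise$p, 0.5)
  expect_equal(oracle_hyper(2, 3, 3, 6), 0.5)

  same <- replicate(5, c("a", "b"), simplify = FALSE)
  names(same) <- paste0("S", 1:5)
  res3 <- overlap_tabulate(same, universe = c("a", "b", "c"))
  nonzero <- res3$regions[res3$regions$count > 0, ]
  expect_identical(sort(nonzero$pattern), c("00000", "11111"))

  expect_error(overlap_tabulate(list(A = "z", B = "a"), universe = c("a", "b")),
               "outside")
})
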