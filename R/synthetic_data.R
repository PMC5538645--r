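# Seeded generator of a complete synthetic browning/whitening study:
# expression with a planted Gaussian-graphical coexpression structure and
# planted differential-expression programs, gene annotation on synthetic
# contigs, a multi-tissue panel with BAT-enriched genes, ChIP-like peaks
# preferentially placed in 50-kb upstream windows of induced genes, and
# 3'UTR sequences with planted UGU-rich windows — all documented in a
# ground-truth manifest against which recovery is tested.
#
# The generative model is multivariate normal on the log2 scale (FPKM =
# 2^log2-expression): the downstream network method assumes (partial)
# correlation structure on expression, and lognormal FPKM is the minimal
# model with controllable GGM structure. One master seed feeds a labelled
# stream per component (sub_seed), so adding a component does not perturb
# the draws of the others.

#' Configuration for the synthetic study generator
#'
#' Defaults state the emulated design: 5 treatment contrasts (iWAT cold /
#' CL316243 / exercise vs iWAT control; BAT acute cold / thermoneutral vs
#' BAT control), 3 replicates per condition, ~2,000 mRNAs + 150 lncRNAs, two dozen
#' 10-gene coexpression modules with one designated "thermogenic" module
#' containing lncRNAs, planted 64-fold (6 log2 units) DE programs partially
#' shared across conditions (whitening reverses the sign), a 29-tissue
#' panel, peaks placed in 50-kb upstream windows of induced genes, and
#' 3'UTRs with planted >= 20-UGU 100-nt windows.
#'
#' @param seed mandatory integer master seed.
#' @param n_mrna,n_lnc catalog sizes.
#' @param replicates replicates per (depot, condition).
#' @param modules list of module descriptors `list(size, lnc_frac, topology
#'   ("band"|"random"), strength, degree)`; module 1 is the thermogenic one.
#' @param n_up,n_down planted program sizes per contrast.
#' @param effect planted effect in log2 units.
#' @param sharing fraction of each program drawn from the cross-condition
#'   shared pool, in `[0, 1]`.
#' @param whitening_flip reverse planted direction in whitening contrasts?
#' @param noise_sd independent residual sd on the log2 scale.
#' @param module_sd marginal sd of the module latent component.
#' @param baseline_range range of baseline log2 FPKM means.
#' @param n_tissues tissue panel size; @param n_bat_enriched,n_iwat_enriched
#'   planted tissue-enriched set sizes; @param tissue_fold planted
#'   fold-enrichment; @param tissue_sd log2 between-tissue noise sd.
#' @param peak_sources labels of emitted peak sets; @param
#'   peak_target_rate probability a target gene receives a planted peak per
#'   source; @param peak_background_per_gene expected background peaks per
#'   gene; @param promoter_width upstream window width (bp).
#' @param utr_length emitted 3'UTR length (nt); @param cbs_counts planned
#'   UGU counts of the planted windows (one gene each); @param cbs_tier the
#'   top-tier threshold the plan must reach.
#' @param gene_spacing,contigs genomic layout of the synthetic contigs.
#' @return validated list of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       n_mrna = 2000, n_lnc = 150,
                       replicates = 3,
                       modules = default_modules(),
                       n_up = 200, n_down = 200,
                       effect = 6, sharing = 0.6,
                       whitening_flip = TRUE,
                       noise_sd = 0.1, module_sd = 0.5,
                       baseline_range = c(1, 9),
                       n_tissues = 29,
                       n_bat_enriched = 60, n_iwat_enriched = 40,
                       tissue_fold = 30, tissue_sd = 1,
                       peak_sources = c("PPARg", "PRDM16"),
                       peak_target_rate = 0.9,
                       peak_background_per_gene = 0.3,
                       promoter_width = 50000,
                       utr_length = 300,
                       cbs_counts = c(20, 21, 22, 23, 24, 25, 26),
                       cbs_tier = 20,
                       gene_spacing = 100000,
                       contigs = c("chrA", "chrB")) {
  assert_that(!missing(seed) && is.numeric(seed) && length(seed) == 1,
              "a scalar seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_mrna = n_mrna, n_lnc = n_lnc,
              replicates = replicates, modules = modules,
              contrasts = default_contrasts(),
              n_up = n_up, n_down = n_down, effect = effect,
              sharing = sharing, whitening_flip = whitening_flip,
              noise_sd = noise_sd, module_sd = module_sd,
              baseline_range = baseline_range,
              n_tissues = n_tissues, n_bat_enriched = n_bat_enriched,
              n_iwat_enriched = n_iwat_enriched,
              tissue_fold = tissue_fold, tissue_sd = tissue_sd,
              peak_sources = peak_sources,
              peak_target_rate = peak_target_rate,
              peak_background_per_gene = peak_background_per_gene,
              promoter_width = promoter_width,
              utr_length = utr_length, cbs_counts = cbs_counts,
              cbs_tier = cbs_tier, gene_spacing = gene_spacing,
              contigs = contigs)
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

#' Default coexpression-module plan (six 40-gene modules)
#' @return list of module descriptors; module 1 is the thermogenic module.
#' @export
default_modules <- function() {
  rep(list(list(size = 10, lnc_frac = 0.1, topology = "random",
                strength = 0.4, degree = 2.6, hub_chords = 3,
                hub_strength = 0.5)), 24)
}

#' The five emulated treatment contrasts with their sign conventions
#'
#' `browning_sign` is +1 for browning / BAT-activation contrasts (induction
#' is the browning-consistent direction) and -1 for whitening
#' (thermoneutrality), where repression is browning-consistent.
#'
#' @return data.frame: `name`, `depot`, `treatment`, `control`,
#'   `browning_sign`.
#' @export
default_contrasts <- function() {
  data.frame(
    name = c("cold_iWAT", "cl316243_iWAT", "exercise_iWAT",
             "acute_cold_BAT", "thermoneutral_BAT"),
    depot = c("iWAT", "iWAT", "iWAT", "BAT", "BAT"),
    treatment = c("cold", "cl316243", "exercise", "acute_cold",
                  "thermoneutral"),
    control = c("control", "control", "control", "control", "control"),
    browning_sign = c(1, 1, 1, 1, -1),
    stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  n_genes <- cfg$n_mrna + cfg$n_lnc
  msize <- sum(vapply(cfg$modules, `[[`, numeric(1), "size"))
  assert_that(msize <= n_genes, "module sizes (%d) exceed gene universe (%d)",
              msize, n_genes)
  assert_that(cfg$sharing >= 0 && cfg$sharing <= 1, "sharing must lie in [0, 1]")
  assert_that(cfg$peak_target_rate >= 0 && cfg$peak_target_rate <= 1,
              "peak_target_rate must lie in [0, 1]")
  assert_that(cfg$replicates >= 1, "replicates must be >= 1")
  max_pack <- floor((100 - 1) / 2) # overlapping UGUGU... packing in 100 nt
  bad <- cfg$cbs_counts[cfg$cbs_counts > max_pack]
  assert_that(length(bad) == 0,
              "planned UGU count %d infeasible in a 100-nt window (max %d)",
              if (length(bad)) bad[1] else 0, max_pack)
  assert_that(all(cfg$cbs_counts >= 0), "cbs counts must be >= 0")
  spec_size <- cfg$n_up - round(cfg$sharing * cfg$n_up) +
    cfg$n_down - round(cfg$sharing * cfg$n_down)
  need <- round(cfg$sharing * cfg$n_up) + round(cfg$sharing * cfg$n_down) +
    5 * spec_size
  assert_that(need <= n_genes,
              "DE plan needs %d genes but the universe has %d", need, n_genes)
  invisible(cfg)
}

# precision matrix of one module; unit diagonal, entries chosen so the
# planted partial correlation of an edge (i, j) equals -omega_ij.
# "band": chain with -strength on the first off-diagonal (PD for
# strength < 1/(2 cos(pi/(m+1)))). "random": ring plus random chords up to
# the target mean degree — connected and community-cohesive. If the
# requested strength violates positive definiteness the off-diagonals are
# rescaled so the smallest eigenvalue is 0.1 (message); a structure that
# cannot be repaired this way is an error.
module_precision <- function(mod, seed) {
  m <- mod$size
  Om <- diag(m)
  if (mod$topology == "band") {
    for (i in seq_len(m - 1)) {
      Om[i, i + 1] <- Om[i + 1, i] <- -mod$strength
    }
  } else if (mod$topology == "random") {
    # hub positions (the lncRNAs) sit off the ring, attached by a few
    # strong spokes: sparse star edges admit high partial correlations
    # under positive definiteness, so the lncRNA's edges are the module's
    # most detectable ones
    hub_pos <- mod$hub_pos %||% integer(0)
    ring <- setdiff(seq_len(m), hub_pos)
    with_seed(seed, {
      for (a in seq_along(ring)) { # ring backbone over non-hub members
        b <- if (a == length(ring)) 1 else a + 1
        Om[ring[a], ring[b]] <- Om[ring[b], ring[a]] <- -mod$strength
      }
      hub_chords <- mod$hub_chords %||% 2
      hub_strength <- mod$hub_strength %||% mod$strength
      for (h in hub_pos) {
        partners <- sample(ring, min(hub_chords, length(ring)))
        for (p in partners) Om[h, p] <- Om[p, h] <- -hub_strength
      }
      n_chords <- max(0, round((mod$degree - 2) * m / 2))
      if (n_chords > 0) {
        free <- which(upper.tri(Om) & Om == 0, arr.ind = TRUE)
        free <- free[!(free[, 1] %in% hub_pos) & !(free[, 2] %in% hub_pos), ,
                     drop = FALSE]
        pick <- free[sample.int(nrow(free), min(n_chords, nrow(free))), ,
                     drop = FALSE]
        for (r in seq_len(nrow(pick))) {
          Om[pick[r, 1], pick[r, 2]] <- Om[pick[r, 2], pick[r, 1]] <- -mod$strength
        }
      }
    })
  } else {
    stop_bn("unknown module topology '%s'", mod$topology)
  }
  ev <- min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    if (mod$topology != "random") {
      stop_bn("requested module structure is not positive definite (min eigenvalue %.3g)", ev)
    }
    off <- Om; diag(off) <- 0
    fac <- (1 - 0.1) / (1 - ev)
    Om <- diag(m) + off * fac
    message(sprintf("module_precision: strength rescaled by %.3f to keep positive definiteness", fac))
    ev2 <- min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values)
    if (ev2 <= 0) stop_bn("requested module structure is not positive definite")
  }
  Om
}

#' Build the ground-truth manifest of a synthetic study
#'
#' Deterministic given the config seed. Lays out the gene catalog and
#' annotation, draws module memberships and symmetric-positive-definite
#' module precision matrices, plants per-condition DE programs with the
#' configured cross-condition sharing (whitening contrasts get the reversed
#' direction when `whitening_flip` is on), designates the thermogenic module
#' (module 1: contains lncRNAs; its mRNAs form the planted "thermogenesis"
#' gene set), and fixes peak-target genes, tissue-enriched sets and the
#' planted UGU-window plan.
#'
#' @param config a `SimConfig`.
#' @return list of class `SyntheticTruth`.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  genes <- c(sprintf("mRNA_%04d", seq_len(cfg$n_mrna)),
             sprintf("lnc_%03d", seq_len(cfg$n_lnc)))
  biotype <- stats::setNames(rep(c("mRNA", "lncRNA"), c(cfg$n_mrna, cfg$n_lnc)),
                             genes)
  n_genes <- length(genes)

  # --- module membership: interleave lncRNAs into each module -------------
  mrna_pool <- genes[biotype == "mRNA"]
  lnc_pool <- genes[biotype == "lncRNA"]
  membership <- stats::setNames(rep(0L, n_genes), genes)
  precisions <- list()
  edges <- list()
  mi <- 1L; li <- 1L
  for (k in seq_along(cfg$modules)) {
    mod <- cfg$modules[[k]]
    n_l <- round(mod$size * mod$lnc_frac)
    n_m <- mod$size - n_l
    ids_m <- mrna_pool[mi:(mi + n_m - 1)]; mi <- mi + n_m
    ids_l <- lnc_pool[li:(li + n_l - 1)]; li <- li + n_l
    # alternate so band modules link lncRNAs to mRNA neighbors
    ids <- character(mod$size)
    lpos <- if (n_l > 0) round(seq(2, mod$size - 1, length.out = n_l)) else integer(0)
    ids[lpos] <- ids_l
    ids[setdiff(seq_len(mod$size), lpos)] <- ids_m
    membership[ids] <- k
    mod$hub_pos <- lpos # lncRNAs get chords: guilt-by-association needs neighbors
    Om <- module_precision(mod, sub_seed(cfg$seed, paste0("module", k)))
    dimnames(Om) <- list(ids, ids)
    precisions[[k]] <- Om
    sup <- which(upper.tri(Om) & Om != 0, arr.ind = TRUE)
    edges[[k]] <- data.frame(gene_a = ids[sup[, 1]], gene_b = ids[sup[, 2]],
                             pcor = -Om[sup], module = k,
                             stringsAsFactors = FALSE)
  }
  true_edges <- do.call(rbind, edges)
  module_genes <- names(membership)[membership > 0]

  # --- planted DE programs -------------------------------------------------
  n_shared_up <- round(cfg$sharing * cfg$n_up)
  n_shared_down <- round(cfg$sharing * cfg$n_down)
  n_spec_up <- cfg$n_up - n_shared_up
  n_spec_down <- cfg$n_down - n_shared_down
  n_mod <- length(cfg$modules)
  half <- ceiling(n_mod / 2)
  up_mods <- names(membership)[membership %in% seq_len(half)]
  down_mods <- names(membership)[membership > half & membership <= n_mod]
  free <- setdiff(genes, module_genes)
  de <- with_seed(sub_seed(cfg$seed, "de_programs"), {
    shared_up <- utils::head(c(up_mods, sample(free)), n_shared_up)
    free2 <- setdiff(free, shared_up)
    shared_down <- utils::head(c(setdiff(down_mods, shared_up), sample(free2)),
                               n_shared_down)
    avail <- setdiff(genes, c(module_genes, shared_up, shared_down))
    avail <- sample(avail)
    take <- function(n) {
      out <- utils::head(avail, n)
      avail <<- utils::tail(avail, max(0, length(avail) - n))
      out
    }
    # Each module sits out one designated contrast (rotating), so module
    # mates share a distinctive multi-condition response profile — the
    # correlation signal that guilt-by-association rests on. Free (single)
    # shared genes respond in every contrast.
    n_contr <- nrow(cfg$contrasts)
    drop_contrast <- stats::setNames(((seq_len(n_mod) - 1) %% n_contr) + 1,
                                     seq_len(n_mod))
    drop_contrast[1] <- 0 # the thermogenic program responds in all 5
    de <- list()
    for (i in seq_len(nrow(cfg$contrasts))) {
      nm <- cfg$contrasts$name[i]
      in_module <- membership > 0
      sitting_out <- names(membership)[in_module][
        drop_contrast[membership[in_module]] == i]
      up <- c(setdiff(shared_up, sitting_out), take(n_spec_up))
      down <- c(setdiff(shared_down, sitting_out), take(n_spec_down))
      if (cfg$whitening_flip && cfg$contrasts$browning_sign[i] < 0) {
        tmp <- up; up <- down; down <- tmp
      }
      de[[nm]] <- list(up = up, down = down)
    }
    # per-module response multipliers differentiate modules that share a
    # sitting-out contrast: every module gets its own graded profile
    attr(de, "profile_mult") <- matrix(
      stats::runif(n_mod * n_contr, 0.75, 1.25), n_mod, n_contr,
      dimnames = list(NULL, cfg$contrasts$name))
    attr(de, "shared_up") <- shared_up
    attr(de, "shared_down") <- shared_down
    de
  })
  profile_mult <- attr(de, "profile_mult")

  # --- annotation on synthetic contigs ------------------------------------
  ann <- with_seed(sub_seed(cfg$seed, "annotation"), {
    contig <- cfg$contigs[1 + (seq_len(n_genes) - 1) %% length(cfg$contigs)]
    idx <- stats::ave(seq_len(n_genes), contig, FUN = seq_along)
    tss <- as.integer(30000 + (idx - 1) * cfg$gene_spacing +
                        sample(0:20000, n_genes, replace = TRUE))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    utr_start <- as.integer(tss + 5000)
    data.frame(gene_id = genes, biotype = unname(biotype), chrom = contig,
               strand = strand, tss = tss,
               utr3_start = utr_start,
               utr3_end = as.integer(utr_start + cfg$utr_length),
               stringsAsFactors = FALSE)
  })

  # --- baseline abundances -------------------------------------------------
  baseline <- with_seed(sub_seed(cfg$seed, "baseline"), {
    stats::setNames(stats::runif(n_genes, cfg$baseline_range[1],
                                 cfg$baseline_range[2]), genes)
  })

  # --- tissue-enriched sets ------------------------------------------------
  shared_up <- attr(de, "shared_up")
  shared_down <- attr(de, "shared_down")
  thermo_mrnas <- names(membership)[membership == 1 & biotype[names(membership)] == "mRNA"]
  thermo_lncs <- names(membership)[membership == 1 & biotype[names(membership)] == "lncRNA"]
  # the thermogenic lncRNAs are BAT-enriched, like the thermogenic mRNAs
  bat_enriched <- utils::head(unique(c(
    thermo_mrnas, thermo_lncs, shared_up[biotype[shared_up] == "mRNA"])),
    cfg$n_bat_enriched)
  iwat_enriched <- utils::head(shared_down[biotype[shared_down] == "mRNA"],
                               cfg$n_iwat_enriched)

  # --- planted gene sets (guilt-by-association targets) --------------------
  set_names <- c("thermogenesis", "fatty_acid_oxidation",
                 "oxidative_phosphorylation", "cellular_respiration",
                 "lipid_biosynthesis", "cAMP_signaling",
                 "immune_response", "inflammatory_response",
                 "translation", "rna_processing",
                 "cell_cycle", "extracellular_matrix")
  set_names <- make.unique(rep_len(set_names, length(cfg$modules)))
  gene_sets <- lapply(seq_along(cfg$modules), function(k) {
    ids <- names(membership)[membership == k]
    ids[biotype[ids] == "mRNA"]
  })
  names(gene_sets) <- set_names[seq_along(gene_sets)]
  gene_sets$BAT_enriched <- bat_enriched
  gene_sets$WAT_enriched <- iwat_enriched

  # --- CBS plan ------------------------------------------------------------
  # BAT-enriched genes carry the plan; pad from the rest of the catalog when
  # the enriched set is smaller than the plan (degenerate configs)
  cbs_pool <- unique(c(bat_enriched, genes[biotype == "mRNA"]))
  cbs_genes <- utils::head(cbs_pool, length(cfg$cbs_counts))
  assert_that(length(cbs_genes) == length(cfg$cbs_counts),
              "not enough BAT-enriched genes to carry the CBS plan")
  cbs <- data.frame(gene_id = cbs_genes, planned = as.integer(cfg$cbs_counts),
                    window_start = NA_integer_, achieved = NA_integer_,
                    stringsAsFactors = FALSE)

  thermo_lnc <- names(membership)[membership == 1 & biotype[names(membership)] == "lncRNA"][1]

  structure(list(
    config = cfg, genes = genes, biotype = biotype,
    membership = membership, precisions = precisions,
    true_edges = true_edges,
    de = de, shared_up = shared_up, shared_down = shared_down,
    profile_mult = profile_mult,
    annotation = ann, baseline = baseline,
    tissue_enriched = list(BAT = bat_enriched, iWAT = iwat_enriched),
    gene_sets = gene_sets,
    peak_targets = shared_up,
    cbs = cbs,
    thermogenic_module = 1L, thermogenic_lnc = thermo_lnc),
    class = "SyntheticTruth")
}

#' Sample metadata implied by a config
#' @param config a `SimConfig`.
#' @param replicates optional override of the per-condition replicate count.
#' @return data.frame: `sample_id`, `depot`, `condition`, `replicate`.
#' @export
design_meta <- function(config, replicates = NULL) {
  reps <- replicates %||% config$replicates
  cond <- unique(rbind(
    data.frame(depot = config$contrasts$depot,
               condition = config$contrasts$treatment,
               stringsAsFactors = FALSE),
    data.frame(depot = config$contrasts$depot,
               condition = config$contrasts$control,
               stringsAsFactors = FALSE)))
  cond <- cond[order(cond$depot, cond$condition), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
    data.frame(sample_id = sprintf("%s_%s_r%d", cond$depot[i],
                                   cond$condition[i], seq_len(reps)),
               depot = cond$depot[i], condition = cond$condition[i],
               replicate = seq_len(reps), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# signed planted effect of every gene in a given (depot, condition) arm.
# Includes the constant depot signature (tissue-enriched genes high in their
# own depot) so depots are separable; being constant within depot it cancels
# out of every within-depot contrast.
planted_shift <- function(truth, depot, condition) {
  cfg <- truth$config
  shift <- stats::setNames(numeric(length(truth$genes)), truth$genes)
  if (depot %in% names(truth$tissue_enriched)) {
    shift[truth$tissue_enriched[[depot]]] <- log2(cfg$tissue_fold)
  }
  hit <- cfg$contrasts$depot == depot & cfg$contrasts$treatment == condition
  if (!any(hit)) return(shift) # control arm: planted depot signature only
  nm <- cfg$contrasts$name[hit][1]
  eff <- function(g) {
    k <- truth$membership[g]
    cfg$effect * ifelse(k > 0, truth$profile_mult[pmax(k, 1), nm], 1)
  }
  up <- truth$de[[nm]]$up; down <- truth$de[[nm]]$down
  shift[up] <- shift[up] + eff(up)
  shift[down] <- shift[down] - eff(down)
  shift
}

#' Simulate the FPKM expression matrix
#'
#' Per sample, log2 expression = gene baseline + planted condition effect +
#' module latent (multivariate normal with covariance the inverse planted
#' precision, rescaled to marginal sd `module_sd`) + independent
#' `N(0, noise_sd^2)` noise; FPKM is `2^log2expression`.
#'
#' @param truth from [build_truth()].
#' @param config the same `SimConfig` (kept explicit so test-only overrides
#'   of, e.g., sample count leave the truth untouched).
#' @param meta optional sample sheet (default [design_meta()]).
#' @return an `ExpressionMatrix`.
#' @export
simulate_expression <- function(truth, config = truth$config, meta = NULL) {
  cfg <- config
  if (is.null(meta)) meta <- design_meta(cfg)
  genes <- truth$genes
  n_s <- nrow(meta)
  chols <- lapply(truth$precisions, function(Om) {
    S <- solve(Om)
    d <- cfg$module_sd / sqrt(diag(S))
    S <- S * tcrossprod(d)
    chol(S)
  })
  vals <- with_seed(sub_seed(cfg$seed, paste0("expression_n", n_s)), {
    M <- matrix(0, length(genes), n_s, dimnames = list(genes, meta$sample_id))
    for (j in seq_len(n_s)) {
      x <- truth$baseline +
        planted_shift(truth, meta$depot[j], meta$condition[j])
      if (cfg$noise_sd > 0) x <- x + stats::rnorm(length(genes), 0, cfg$noise_sd)
      for (k in seq_along(chols)) {
        ids <- rownames(truth$precisions[[k]])
        x[ids] <- x[ids] + drop(crossprod(chols[[k]],
                                          stats::rnorm(length(ids))))
      }
      M[, j] <- x
    }
    2^M
  })
  expression_matrix(vals, meta)
}

#' Simulate the multi-tissue FPKM panel
#'
#' Each gene's log2 expression per tissue is its baseline plus
#' `N(0, tissue_sd^2)`; planted tissue-enriched genes additionally get
#' `log2(tissue_fold)` in their tissue.
#'
#' @param truth from [build_truth()].
#' @param config the `SimConfig`.
#' @return genes x tissues FPKM matrix (first tissues: BAT, iWAT, eWAT).
#' @export
simulate_tissue_panel <- function(truth, config = truth$config) {
  cfg <- config
  tissues <- c("BAT", "iWAT", "eWAT",
               paste0("tissue_", sprintf("%02d", seq_len(max(0, cfg$n_tissues - 3)))))
  tissues <- tissues[seq_len(cfg$n_tissues)]
  with_seed(sub_seed(cfg$seed, "tissue_panel"), {
    M <- matrix(stats::rnorm(length(truth$genes) * length(tissues), 0,
                             cfg$tissue_sd),
                length(truth$genes), length(tissues),
                dimnames = list(truth$genes, tissues))
    M <- M + truth$baseline
    M[truth$tissue_enriched$BAT, "BAT"] <-
      M[truth$tissue_enriched$BAT, "BAT"] + log2(cfg$tissue_fold)
    M[truth$tissue_enriched$iWAT, "iWAT"] <-
      M[truth$tissue_enriched$iWAT, "iWAT"] + log2(cfg$tissue_fold)
    2^M
  })
}

#' Simulate ChIP-like peaks
#'
#' For every planted target gene (the shared browning-induced program), each
#' source places one peak uniformly inside the strand-aware 50-kb upstream
#' window with probability `peak_target_rate`; background peaks are placed
#' uniformly along the contigs at `peak_background_per_gene` per gene.
#' Windows running past the contig start are clipped at 0 (message).
#'
#' @param truth from [build_truth()]; @param config the `SimConfig`.
#' @return peak data.frame (`chrom`, `start`, `end`, `score`, `source`),
#'   sorted.
#' @export
simulate_peaks <- function(truth, config = truth$config) {
  cfg <- config
  ann <- truth$annotation
  win <- promoter_windows(ann, width = cfg$promoter_width)
  rownames(win) <- win$gene_id
  clipped <- win$end - win$start < cfg$promoter_width
  if (any(clipped[win$gene_id %in% truth$peak_targets])) {
    message(sprintf("simulate_peaks: %d target window(s) clipped at contig start",
                    sum(clipped[win$gene_id %in% truth$peak_targets])))
  }
  contig_len <- tapply(ann$tss + cfg$gene_spacing, ann$chrom, max)
  with_seed(sub_seed(cfg$seed, "peaks"), {
    out <- list()
    for (s in cfg$peak_sources) {
      hit <- truth$peak_targets[stats::runif(length(truth$peak_targets)) <
                                  cfg$peak_target_rate]
      if (length(hit) > 0) {
        w <- win[hit, , drop = FALSE]
        width <- sample(200:500, length(hit), replace = TRUE)
        start <- floor(w$start + stats::runif(length(hit)) *
                         pmax(1, w$end - w$start - width))
        out[[length(out) + 1]] <- data.frame(
          chrom = w$chrom, start = as.integer(start),
          end = as.integer(pmin(start + width, w$end)),
          score = round(stats::runif(length(hit), 5, 100), 2),
          source = s, stringsAsFactors = FALSE)
      }
      n_bg <- round(cfg$peak_background_per_gene * length(truth$genes))
      if (n_bg > 0) {
        ch <- sample(names(contig_len), n_bg, replace = TRUE)
        width <- sample(200:500, n_bg, replace = TRUE)
        start <- floor(stats::runif(n_bg) * (contig_len[ch] - width))
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = as.integer(start),
          end = as.integer(start + width),
          score = round(stats::runif(n_bg, 5, 100), 2),
          source = s, stringsAsFactors = FALSE)
      }
    }
    pk <- do.call(rbind, out)
    if (is.null(pk)) {
      pk <- data.frame(chrom = character(), start = integer(),
                       end = integer(), score = numeric(),
                       source = character(), stringsAsFactors = FALSE)
    }
    pk <- pk[order(pk$source, pk$chrom, pk$start, pk$end), , drop = FALSE]
    rownames(pk) <- NULL
    pk
  })
}

# a 100-nt block holding exactly `count` overlapping UGU occurrences:
# "UGUGU...U" (length 2*count + 1) padded with a UGU-free AC filler
cbs_block <- function(count, width = 100) {
  assert_that(count <= floor((width - 1) / 2),
              "planned UGU count %d infeasible in a %d-nt window", count, width)
  run <- if (count > 0) {
    paste(rep(c("U", "G"), length.out = 2 * count + 1), collapse = "")
  } else ""
  pad <- paste(rep(c("A", "C"), length.out = width - nchar(run)), collapse = "")
  paste0(run, pad)
}

#' Simulate 3'UTR sequences with planted UGU-rich windows
#'
#' Every annotated gene gets a background RNA sequence of its 3'UTR length
#' (base composition keeping expected UGU density around 1 per 100-nt
#' window, far below the planted tier); each CBS-plan gene additionally
#' carries one 100-nt block with exactly its planned number of overlapping
#' UGU occurrences, flanked by C's so no extra occurrence is created at the
#' boundary. Achieved counts are recounted from the emitted sequence and
#' recorded in the returned truth.
#'
#' @param truth from [build_truth()]; @param config the `SimConfig`.
#' @return list: `seqs` (named RNA strings) and `truth` (updated `cbs`
#'   table).
#' @export
simulate_utrs <- function(truth, config = truth$config) {
  cfg <- config
  ann <- truth$annotation
  lens <- ann$utr3_end - ann$utr3_start
  seqs <- with_seed(sub_seed(cfg$seed, "utrs"), {
    s <- vapply(seq_len(nrow(ann)), function(i) {
      paste(sample(c("A", "C", "G", "U"), lens[i], replace = TRUE,
                   prob = c(0.3, 0.25, 0.25, 0.2)), collapse = "")
    }, character(1))
    names(s) <- ann$gene_id
    for (r in seq_len(nrow(truth$cbs))) {
      g <- truth$cbs$gene_id[r]
      L <- nchar(s[[g]])
      assert_that(L >= 104, "UTR of '%s' too short for a planted window", g)
      pos <- 1 + sample.int(L - 104, 1) # 1-based insert position, 2-nt flanks
      block <- paste0("CC", cbs_block(truth$cbs$planned[r]), "CC")
      substr(s[[g]], pos, pos + 103) <- block
      win_lo <- pos + 2L; win_hi <- pos + 101L # 1-based planted window
      # scrub background UGU occurrences outside the planted window so the
      # planned count is the exact per-gene maximum (G -> C cannot create a
      # new UGU)
      occ <- ugu_positions(s[[g]]) + 1L
      stray <- occ[occ < win_lo | occ + 2L > win_hi]
      for (q in stray) substr(s[[g]], q + 1L, q + 1L) <- "C"
      truth$cbs$window_start[r] <- pos + 1L # 0-based start of the 100-nt block
    }
    s
  })
  for (r in seq_len(nrow(truth$cbs))) {
    ws <- count_ugu_windows(seqs[[truth$cbs$gene_id[r]]])
    truth$cbs$achieved[r] <- max(ws$ugu_count)
  }
  list(seqs = seqs, truth = truth)
}

#' Generate and write a complete synthetic study
#'
#' Emits `expression.tsv`, `meta.tsv`, `annotation.tsv`,
#' `peaks_<source>.bed`, `utrs.fasta`, `tissue_panel.tsv`,
#' `gene_sets.gmt` and `truth.json` under `outdir`. Byte-identical across
#' runs with an identical config.
#'
#' @param config a `SimConfig`; @param outdir output directory (created).
#' @return invisibly, a list with `truth`, `expr`, `panel`, `peaks`, `utrs`
#'   and the file paths.
#' @export
simulate_study <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- build_truth(config)
  expr <- simulate_expression(truth, config)
  panel <- simulate_tissue_panel(truth, config)
  peaks <- simulate_peaks(truth, config)
  utr <- simulate_utrs(truth, config)
  truth <- utr$truth
  paths <- list(
    expression = file.path(outdir, "expression.tsv"),
    meta = file.path(outdir, "meta.tsv"),
    annotation = file.path(outdir, "annotation.tsv"),
    tissue_panel = file.path(outdir, "tissue_panel.tsv"),
    utrs = file.path(outdir, "utrs.fasta"),
    gene_sets = file.path(outdir, "gene_sets.gmt"),
    truth = file.path(outdir, "truth.json"))
  write_expression(expr, paths$expression, paths$meta)
  write_annotation(truth$annotation, paths$annotation)
  write_tsv_strict(data.frame(gene_id = rownames(panel), panel,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   paths$tissue_panel)
  write_fasta(utr$seqs, paths$utrs)
  write_gmt(truth$gene_sets, paths$gene_sets)
  for (s in unique(peaks$source)) {
    paths[[paste0("peaks_", s)]] <- file.path(outdir, paste0("peaks_", s, ".bed"))
    write_bed(peaks[peaks$source == s, , drop = FALSE],
              paths[[paste0("peaks_", s)]])
  }
  manifest <- list(
    seed = config$seed,
    membership = as.list(truth$membership[truth$membership > 0]),
    true_edges = truth$true_edges,
    de = lapply(truth$de, function(x) x[c("up", "down")]),
    peak_targets = truth$peak_targets,
    cbs = truth$cbs,
    tissue_enriched = truth$tissue_enriched,
    thermogenic_lnc = truth$thermogenic_lnc)
  jsonlite::write_json(manifest, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(truth = truth, expr = expr, panel = panel, peaks = peaks,
                 utrs = utr$seqs, paths = paths))
}
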