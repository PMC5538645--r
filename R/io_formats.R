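# Readers/writers for every on-disk artifact the pipeline touches.
# Conventions enforced at this boundary:
#   * all genomic intervals are 0-based half-open (BED convention);
#   * the TSS is a single 0-based coordinate;
#   * FASTA sequences are uppercased and DNA 'T' is normalized to RNA 'U'
#     so downstream scans match the literal "UGU";
#   * readers reject invalid values instead of coercing, naming the record.

#' Construct and validate an expression matrix with sample metadata
#'
#' @param values numeric gene x sample matrix of FPKM (finite, >= 0), with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param meta data.frame with columns `sample_id`, `depot`, `condition`,
#'   `replicate`; one row per sample, same order as `colnames(values)`.
#' @return an object of class `ExpressionMatrix` (list with `values`, `meta`).
#' @export
expression_matrix <- function(values, meta) {
  assert_that(is.matrix(values) && is.numeric(values),
              "expression values must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  assert_that(!is.null(gid) && !anyDuplicated(gid),
              "gene ids missing or duplicated")
  assert_that(!is.null(sid) && !anyDuplicated(sid),
              "sample ids missing or duplicated")
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_bn("invalid expression cell at gene '%s', sample '%s' (value %s)",
            gid[bad[1, 1]], sid[bad[1, 2]], format(values[bad[1, , drop = FALSE]]))
  }
  need <- c("sample_id", "depot", "condition", "replicate")
  assert_that(is.data.frame(meta) && all(need %in% colnames(meta)),
              "meta must have columns: %s", paste(need, collapse = ", "))
  if (!identical(as.character(meta$sample_id), sid)) {
    offenders <- union(setdiff(sid, meta$sample_id), setdiff(meta$sample_id, sid))
    if (length(offenders) == 0) offenders <- "(ordering differs)"
    stop_bn("meta/sample mismatch: %s", paste(offenders, collapse = ", "))
  }
  assert_that(all(meta$replicate == as.integer(meta$replicate)) &&
                all(meta$replicate >= 1),
              "replicate must be a positive integer")
  structure(list(values = values, meta = meta), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d conditions)\n",
              nrow(x$values), ncol(x$values),
              length(unique(paste(x$meta$depot, x$meta$condition)))))
  invisible(x)
}

#' Read an FPKM expression matrix and its sample metadata
#'
#' @param matrix_path TSV with a `gene_id` column then one numeric column per
#'   sample (header row holds sample ids).
#' @param meta_path TSV with columns `sample_id`, `depot`, `condition`,
#'   `replicate`.
#' @return validated [expression_matrix()].
#' @export
read_expression <- function(matrix_path, meta_path) {
  df <- read_tsv_strict(matrix_path, colClasses = NA)
  assert_that(colnames(df)[1] == "gene_id",
              "first column of %s must be 'gene_id'", matrix_path)
  gid <- as.character(df$gene_id)
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_bn("non-numeric expression cell at gene '%s', sample '%s'",
              gid[bad %||% 1], colnames(vals)[j])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gid
  meta <- read_tsv_strict(meta_path)
  meta$sample_id <- as.character(meta$sample_id)
  meta$replicate <- as.integer(meta$replicate)
  expression_matrix(m, meta)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' Inverse of [read_expression()]; writing then reading then writing again is
#' byte-identical.
#'
#' @param expr an `ExpressionMatrix`.
#' @param matrix_path output TSV path.
#' @param meta_path optional output path for the sample metadata TSV.
#' @export
write_expression <- function(expr, matrix_path, meta_path = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(expr$values),
                   expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_strict(df, matrix_path)
  if (!is.null(meta_path)) write_tsv_strict(expr$meta, meta_path)
  invisible(matrix_path)
}

validate_annotation <- function(ann) {
  need <- c("gene_id", "biotype", "chrom", "strand", "tss")
  assert_that(all(need %in% colnames(ann)),
              "annotation must have columns: %s", paste(need, collapse = ", "))
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  assert_that(length(dup) == 0, "duplicate gene_id in annotation: %s",
              paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(ann$biotype), c("mRNA", "lncRNA"))
  assert_that(length(bad) == 0, "unknown biotype token: %s",
              paste(bad, collapse = ", "))
  bad <- setdiff(unique(ann$strand), c("+", "-"))
  assert_that(length(bad) == 0, "unknown strand token: %s",
              paste(bad, collapse = ", "))
  assert_that(all(ann$tss >= 0), "negative tss coordinate")
  if (!"utr3_start" %in% colnames(ann)) ann$utr3_start <- NA_integer_
  if (!"utr3_end" %in% colnames(ann)) ann$utr3_end <- NA_integer_
  has <- !is.na(ann$utr3_start) & !is.na(ann$utr3_end)
  off <- has & ann$utr3_end <= ann$utr3_start
  if (any(off)) stop_bn("utr3 end <= start for gene '%s'", ann$gene_id[which(off)[1]])
  ann[, c(need, "utr3_start", "utr3_end")]
}

#' Read a gene annotation (TSV or GTF-lite)
#'
#' TSV columns: `gene_id`, `biotype` (mRNA/lncRNA), `chrom`, `strand` (+/-),
#' `tss` (0-based), optional `utr3_start`/`utr3_end` (0-based half-open).
#' GTF-lite: 9-column GTF whose attribute field carries `gene_id` and
#' `biotype`; `gene` features give the TSS (strand-aware 5' end, converted to
#' 0-based), `three_prime_utr` features the 3'UTR interval.
#'
#' @param path input path.
#' @param format `"tsv"` (default), `"gtf"`, or `"auto"` (by extension).
#' @return data.frame, one row per gene, validated.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "tsv") {
    ann <- read_tsv_strict(path)
    ann$gene_id <- as.character(ann$gene_id)
    ann$tss <- as.integer(ann$tss)
    if ("utr3_start" %in% colnames(ann)) ann$utr3_start <- as.integer(ann$utr3_start)
    if ("utr3_end" %in% colnames(ann)) ann$utr3_end <- as.integer(ann$utr3_end)
    return(validate_annotation(ann))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(fields) == 9), "malformed GTF line (need 9 fields)")
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  feat <- vapply(fields, `[[`, character(1), 3)
  chrom <- vapply(fields, `[[`, character(1), 1)
  start1 <- as.integer(vapply(fields, `[[`, character(1), 4)) # 1-based GTF
  end1 <- as.integer(vapply(fields, `[[`, character(1), 5))
  strand <- vapply(fields, `[[`, character(1), 7)
  attrs <- vapply(fields, `[[`, character(1), 9)
  gid <- attr_get(attrs, "gene_id")
  bty <- attr_get(attrs, "biotype")
  gi <- feat == "gene"
  assert_that(any(gi), "GTF-lite has no 'gene' features")
  ann <- data.frame(
    gene_id = gid[gi], biotype = bty[gi], chrom = chrom[gi],
    strand = strand[gi],
    tss = ifelse(strand[gi] == "+", start1[gi] - 1L, end1[gi] - 1L),
    utr3_start = NA_integer_, utr3_end = NA_integer_,
    stringsAsFactors = FALSE)
  ui <- feat == "three_prime_utr"
  if (any(ui)) {
    idx <- match(gid[ui], ann$gene_id)
    ann$utr3_start[idx] <- start1[ui] - 1L
    ann$utr3_end[idx] <- end1[ui]
  }
  validate_annotation(ann)
}

#' Write a gene annotation as TSV
#' @param ann validated annotation data.frame.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  write_tsv_strict(validate_annotation(ann), path)
}

#' Read a BED3+ peak file
#'
#' Intervals are kept 0-based half-open and sorted by (chrom, start, end).
#'
#' @param path BED path (3 or more columns; column 5 used as score if present).
#' @param source label attached to the peak set (e.g. `"PPARg_BAT"`).
#' @return data.frame with columns `chrom`, `start`, `end`, `score`, `source`.
#' @export
read_bed <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      score = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  assert_that(all(lengths(fields) >= 3), "BED line with fewer than 3 fields")
  pk <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = as.integer(vapply(fields, `[[`, character(1), 2)),
    end = as.integer(vapply(fields, `[[`, character(1), 3)),
    score = vapply(fields, function(f)
      if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_,
      numeric(1)),
    source = source, stringsAsFactors = FALSE)
  bad <- which(pk$start >= pk$end)
  if (length(bad) > 0) {
    stop_bn("BED interval with start >= end: %s:%d-%d",
            pk$chrom[bad[1]], pk$start[bad[1]], pk$end[bad[1]])
  }
  pk[order(pk$chrom, pk$start, pk$end), , drop = FALSE]
}

#' Write peaks as BED3+score
#' @param peaks peak data.frame from [read_bed()] or [simulate_peaks()].
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(peaks) > 0) {
    ord <- order(peaks$chrom, peaks$start, peaks$end)
    peaks <- peaks[ord, , drop = FALSE]
    score <- if ("score" %in% colnames(peaks)) peaks$score else NA
    lines <- sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom, peaks$start, peaks$end,
                     paste0("peak", seq_len(nrow(peaks))),
                     ifelse(is.na(score), "0", format(score, trim = TRUE)))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT path: per line, set name, description, then member ids.
#' @return object of class `GeneSetCollection`: named list of character
#'   vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) stop_bn("empty GMT set on line %d", short[1])
  nm <- vapply(fields, `[[`, character(1), 1)
  assert_that(!anyDuplicated(nm), "duplicate GMT set name: %s",
              paste(nm[duplicated(nm)], collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), nm)
  class(sets) <- "GeneSetCollection"
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors (descriptions attribute used
#'   when present).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read FASTA sequences
#'
#' Sequences are uppercased; with `rna = TRUE` (the default, for 3'UTR
#' scanning) `T` is normalized to `U`.
#'
#' @param path FASTA path.
#' @param rna normalize to the RNA alphabet?
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, rna = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  assert_that(length(lines) > 0 && hdr[1], "not a FASTA file: %s", path)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  assert_that(!anyDuplicated(ids), "duplicate FASTA id: %s",
              paste(ids[duplicated(ids)], collapse = ", "))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # ids with no sequence lines yield empty strings
  out <- stats::setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  out <- toupper(out)
  if (rna) out <- chartr("T", "U", out)
  out
}

#' Write FASTA sequences (60-column wrap)
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con, sep = "\n")
    s <- seqs[[nm]]
    if (nchar(s) > 0) {
      starts <- seq(1, nchar(s), by = 60)
      writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con, sep = "\n")
    }
  }
  invisible(path)
}

#' Write a partial-correlation network (and optional partition) to TSV
#'
#' Edge rows are canonicalized (`gene_a < gene_b` lexicographically) and
#' sorted so output is byte-stable; node rows carry biotype and cluster.
#'
#' @param network a `PcorNetwork` (see [build_pcor_network()]).
#' @param path_edges,path_nodes output TSV paths.
#' @param partition optional `CommunityPartition`; adds a `cluster` column.
#' @param path_graphml optional GraphML mirror of the edge list.
#' @export
write_network <- function(network, path_edges, path_nodes,
                          partition = NULL, path_graphml = NULL) {
  ed <- network$edges
  if (any(ed$gene_a == ed$gene_b)) {
    stop_bn("internal error: self-loop in network at '%s'",
            ed$gene_a[ed$gene_a == ed$gene_b][1])
  }
  swap <- ed$gene_a > ed$gene_b
  tmp <- ed$gene_a[swap]; ed$gene_a[swap] <- ed$gene_b[swap]; ed$gene_b[swap] <- tmp
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  write_tsv_strict(ed[, c("gene_a", "gene_b", "pcor", "fdr")], path_edges)
  nodes <- network$nodes
  nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  nodes$cluster <- if (is.null(partition)) NA_integer_ else
    partition$membership[nodes$gene_id]
  write_tsv_strict(nodes[, c("gene_id", "biotype", "cluster")], path_nodes)
  if (!is.null(path_graphml)) {
    con <- file(path_graphml, open = "wb")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
      '  <key id="b" for="node" attr.name="biotype" attr.type="string"/>',
      '  <graph edgedefault="undirected">'), con, sep = "\n")
    writeLines(sprintf('    <node id="%s"><data key="b">%s</data></node>',
                       nodes$gene_id, nodes$biotype), con, sep = "\n")
    if (nrow(ed) > 0) {
      writeLines(sprintf(
        '    <edge source="%s" target="%s"><data key="w">%s</data></edge>',
        ed$gene_a, ed$gene_b,
        format(abs(ed$pcor), digits = 15, scientific = FALSE, trim = TRUE)),
        con, sep = "\n")
    }
    writeLines(c("  </graph>", "</graphml>"), con, sep = "\n")
  }
  invisible(path_edges)
}

#' Read a network edge TSV written by [write_network()]
#' @param path edge TSV path.
#' @return data.frame with columns `gene_a`, `gene_b`, `pcor`, `fdr`.
#' @export
read_network_edges <- function(path) {
  ed <- read_tsv_strict(path)
  assert_that(all(c("gene_a", "gene_b", "pcor", "fdr") %in% colnames(ed)),
              "edge file missing required columns")
  ed
}
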