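# UGU-density screen of 3'UTRs for Celf1-binding-site candidates: sliding
# 100-nt windows, overlapping trimer occurrences, genome-wide ranking with a
# ">= 20 UGU" top tier.

ugu_positions <- function(seq) {
  # 0-based start positions of (possibly overlapping) "UGU" occurrences
  m <- gregexpr("(?=UGU)", seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Count UGU occurrences in sliding windows over an RNA sequence
#'
#' Scans with a window of `window` nt advanced by `step`; a final shorter
#' window is included when the sequence is not covered (and a sequence
#' shorter than `window` is one partial window), provided it has >= 3 nt.
#' Occurrences of the literal `"UGU"` lying fully inside a window are
#' counted, overlapping matches included. `N` never matches.
#'
#' @param seq RNA-alphabet string (`ACGUN`; the io layer normalizes T to U).
#' @param window window width in nt (default 100).
#' @param step window stride in nt (default 1).
#' @return data.frame: `start`, `end` (0-based half-open, in UTR
#'   coordinates), `ugu_count`.
#' @export
count_ugu_windows <- function(seq, window = 100, step = 1) {
  assert_that(is.character(seq) && length(seq) == 1, "seq must be one string")
  L <- nchar(seq)
  assert_that(L >= 3, "sequence shorter than 3 nt")
  bad <- regmatches(seq, regexpr("[^ACGUN]", seq))
  assert_that(length(bad) == 0, "non-ACGUN character in sequence: '%s'",
              if (length(bad)) bad else "")
  occ <- ugu_positions(seq)
  starts <- seq.int(0L, max(0L, L - window), by = step)
  last_end <- starts[length(starts)] + window
  if (last_end < L) {
    tail_start <- max(0L, L - window)
    if (!(tail_start %in% starts)) starts <- c(starts, tail_start)
  }
  ends <- as.integer(pmin(starts + window, L))
  starts <- as.integer(starts)
  keep <- ends - starts >= 3
  starts <- starts[keep]; ends <- ends[keep]
  occ_sorted <- sort(occ)
  counts <- vapply(seq_along(starts), function(i) {
    # occurrence at position q lies inside [start, end) iff
    # q >= start and q + 3 <= end
    sum(occ_sorted >= starts[i] & occ_sorted <= ends[i] - 3L)
  }, integer(1))
  data.frame(start = starts, end = ends, ugu_count = counts)
}

#' Scan a set of 3'UTR sequences for their best UGU window
#'
#' @param seqs named character vector of RNA sequences (see [read_fasta()]).
#' @param window,step as in [count_ugu_windows()].
#' @return data.frame, one row per gene: `gene_id`, `start`, `end`,
#'   `ugu_count` of the maximal-count window (ties broken by smallest start).
#'   Sequences shorter than 3 nt are skipped with a note.
#' @export
scan_utrs <- function(seqs, window = 100, step = 1) {
  rows <- lapply(names(seqs), function(g) {
    if (nchar(seqs[[g]]) < 3) {
      message(sprintf("scan_utrs: sequence '%s' shorter than 3 nt, skipped", g))
      return(NULL)
    }
    ws <- count_ugu_windows(seqs[[g]], window = window, step = step)
    best <- ws[order(-ws$ugu_count, ws$start)[1], , drop = FALSE]
    data.frame(gene_id = g, best, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop_bn("no scannable sequences")
  rownames(out) <- NULL
  out
}

#' Rank genes by their best UGU window and label the top tier
#'
#' Genes are ranked by descending maximal window count, ties by gene id;
#' `tier` is `"top"` for counts at or above `tier_threshold` (the ">= 20 UGU
#' per 100-bp window" group), empty otherwise.
#'
#' @param scores per-gene best windows from [scan_utrs()] (columns `gene_id`,
#'   `start`, `end`, `ugu_count`).
#' @param tier_threshold inclusive count bound for the top tier (default 20).
#' @return the input ordered by rank, with `rank` and `tier` columns added.
#' @export
rank_cbs_candidates <- function(scores, tier_threshold = 20) {
  assert_that(is.data.frame(scores) && nrow(scores) > 0, "empty input")
  assert_that(all(c("gene_id", "ugu_count") %in% colnames(scores)),
              "scores need gene_id and ugu_count columns")
  out <- scores[order(-scores$ugu_count, scores$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tier <- ifelse(out$ugu_count >= tier_threshold, "top", "")
  rownames(out) <- NULL
  out
}
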