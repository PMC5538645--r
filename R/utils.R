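#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bn <- function(...) stop(sprintf(...), call. = FALSE)

warn_bn <- function(...) warning(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_bn(...)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed for a named component
#'
#' One run seed feeds every stochastic stage; each stage draws from its own
#' stream keyed by a component label, so adding a component does not perturb
#' the draws of the others. The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param component character label of the consuming component.
#' @return a single integer usable with [set.seed()].
#' @export
sub_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(component))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 1) + 1)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two labelings of the same items, corrected for chance;
#' 1 means identical partitions, 0 is the expectation under random labeling.
#'
#' @param a,b vectors of cluster labels, same length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Rand index between two partitions
#' @param a,b vectors of cluster labels, same length.
#' @return numeric scalar in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}

# Deterministic TSV writer: no quoting surprises, "." decimal, LF endings,
# fixed 'NA' for missing. Byte-reproducibility of pipeline outputs rests on
# every writer funneling through here.
write_tsv_strict <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt_col <- function(x) {
    if (is.numeric(x) && !is.integer(x)) {
      out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE, nsmall = 0)
      }, character(1))
      out
    } else {
      ifelse(is.na(x), "NA", as.character(x))
    }
  }
  header <- paste(colnames(df), collapse = "\t")
  if (nrow(df) == 0) {
    writeLines(header, con, sep = "\n")
    return(invisible(path))
  }
  cols <- lapply(df, fmt_col)
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

read_tsv_strict <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
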