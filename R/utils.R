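# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Complement bases
#'
#' Vectorized complement of A/C/G/T characters (single bases or strings).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length, complemented base-by-base.
#' @keywords internal
dna_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# Reverse-complement of plain character strings. Probe sequences are
# short (25-35 bases) and this is called in tight design loops, so a
# chartr + reverse implementation beats constructing sequence objects.
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), ""),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All seeded operations in the package go
# through this so that library calls never perturb user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Longest homopolymer run in each sequence.
max_homopolymer <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    if (length(ch) == 0L) return(0L)
    max(rle(ch)$lengths)
  }, integer(1))
}

# Longest substring shared between a sequence and its own reverse
# complement -- a cheap proxy for hairpin/self-dimer potential.
max_selfcomp <- function(x) {
  vapply(x, function(s) {
    a <- strsplit(s, "")[[1]]
    b <- strsplit(dna_revcomp(s), "")[[1]]
    n <- length(a)
    best <- 0L
    prev <- integer(n)
    for (i in seq_len(n)) {
      cur <- integer(n)
      hit <- a[i] == b
      cur[hit] <- 1L
      if (i > 1L) {
        idx <- which(hit & seq_len(n) > 1L)
        cur[idx] <- prev[idx - 1L] + 1L
      }
      best <- max(best, max(cur, 0L))
      prev <- cur
    }
    best
  }, integer(1), USE.NAMES = FALSE)
}

# GC count of each 25-mer (or any DNA string); errors on non-ACGT.
gc_count <- function(x) {
  bad <- grepl("[^ACGTacgt]", x)
  if (any(bad)) {
    stop("non-ACGT character in probe sequence(s): ",
         paste(head(x[bad], 3), collapse = ", "))
  }
  nchar(gsub("[ATat]", "", x))
}

stop_if_not_df_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " must contain column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(x, path, row.names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE)
  invisible(path)
}
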