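# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# Normalize a nucleotide string to the internal DNA alphabet (uppercase, U->T).
# Errors on characters outside {A,C,G,T,U,N}.
normalize_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,U,N}: '%s'",
                 what, x[which(bad)[1L]]), call. = FALSE)
  }
  x
}

# DNA -> RNA for folding backends.
to_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
    paste(COMPLEMENT[ch], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n > 0L, gc / n, NA_real_)
}

# Non-negative scalar integer check.
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
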