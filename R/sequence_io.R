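# Readers/writers for the on-disk formats the pipeline touches.
#
# Conventions used throughout the package:
#  * internal alphabet is DNA (T); U is accepted on input and converted,
#    folding converts back to RNA;
#  * all coordinates are 0-based, half-open;
#  * tabular artifacts are plain TSV without quoting.

#' Read a FASTA file
#'
#' Parses a (optionally gzipped) FASTA file into a data frame of sequence
#' records. Sequences are uppercased and normalized to the DNA alphabet
#' (U becomes T); multi-line sequences are concatenated and record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (first word of the header),
#'   `desc` (remainder of the header, possibly empty) and `seq`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "ACGU", "GGC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(), desc = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop(sprintf("malformed FASTA: line %d precedes the first '>' header",
                 nonblank[1L]), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(sprintf("malformed FASTA: record '%s' has an empty sequence",
                 id[which(empty)[1L]]), call. = FALSE)
  }
  if (any(!nzchar(id))) stop("malformed FASTA: empty record id", call. = FALSE)
  data.frame(id = id, desc = desc, seq = normalize_seq(unname(seqs)),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line-wrapping width for sequences.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("desc" %in% names(records) && nzchar(records$desc[i]))
      paste0(" ", records$desc[i]) else ""
    writeLines(paste0(">", records$id[i], desc), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records (Sanger quality encoding). Each record is
#' validated: sequence and quality strings must have equal length and the
#' separator line must start with `+`.
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A data frame with columns `id`, `seq` (normalized to DNA) and
#'   `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (record %d incomplete)",
                 length(lines), length(lines) %/% 4L + 1L), call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seq <- lines[idx + 1L]
  sep <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  if (any(!startsWith(hdr, "@"))) {
    stop(sprintf("malformed FASTQ: record %d does not start with '@'",
                 which(!startsWith(hdr, "@"))[1L]), call. = FALSE)
  }
  if (any(!startsWith(sep, "+"))) {
    stop(sprintf("malformed FASTQ: record %d separator line does not start with '+'",
                 which(!startsWith(sep, "+"))[1L]), call. = FALSE)
  }
  mism <- nchar(seq) != nchar(qual)
  if (any(mism)) {
    stop(sprintf("malformed FASTQ: record %d sequence and quality lengths differ",
                 which(mism)[1L]), call. = FALSE)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             seq = normalize_seq(seq), qual = qual, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence and quality lengths differ", call. = FALSE)
  out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Construct a tag table
#'
#' A tag table is the package's collapsed-sRNA container: one row per unique
#' tag sequence, one integer count column per library.
#'
#' @param tags Character vector of unique tag sequences (or identifiers;
#'   alphabet validation happens in the readers and in sequence-consuming
#'   operations, not here, so derived tables may carry miRNA ids).
#' @param counts Matrix or data frame of non-negative integer counts,
#'   one column per library, rows parallel to `tags`.
#' @param libraries Library names (defaults to the column names of `counts`).
#' @return A data frame of class `tag_table` with a `tag` column followed by
#'   one count column per library.
#' @export
tag_table <- function(tags, counts, libraries = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(libraries)) stop("library names are required", call. = FALSE)
  stopifnot(length(tags) == nrow(counts), length(libraries) == ncol(counts))
  if (anyDuplicated(tags)) stop("tag sequences must be unique", call. = FALSE)
  if (length(tags) && any(!nzchar(tags)))
    stop("tags must be non-empty", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  tab <- data.frame(tag = as.character(tags), stringsAsFactors = FALSE)
  for (j in seq_along(libraries)) tab[[libraries[j]]] <- as.integer(counts[, j])
  class(tab) <- c("tag_table", "data.frame")
  tab
}

#' @rdname tag_table
#' @param table A `tag_table`.
#' @export
tag_libraries <- function(table) setdiff(names(table), "tag")

#' Write / read a tag table as TSV
#'
#' The on-disk format is a tab-separated file with a header row
#' (`tag` followed by library names); `read_tag_table(write_tag_table(t))`
#' is the identity.
#'
#' @param table A `tag_table`.
#' @param path Output / input path.
#' @return `write_tag_table` returns `path` invisibly; `read_tag_table`
#'   returns a `tag_table`.
#' @export
write_tag_table <- function(table, path) {
  stopifnot(inherits(table, "tag_table") || is.data.frame(table))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_table
#' @export
read_tag_table <- function(path) {
  if (!file.exists(path)) stop("tag table not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!"tag" %in% names(df)) stop("tag table lacks a 'tag' column", call. = FALSE)
  libs <- setdiff(names(df), "tag")
  cnt <- as.matrix(df[libs])
  if (nrow(df) > 0 && (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))))
    stop("tag table counts must be non-negative integers", call. = FALSE)
  if (nrow(df) == 0L) cnt <- matrix(integer(), 0L, length(libs),
                                    dimnames = list(NULL, libs))
  tag_table(df$tag, cnt, libs)
}

#' Read a flat YAML configuration file of pipeline parameters
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
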