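# Raw reads -> annotated unique tags: adapter trimming, quality/length
# filtering, collapsing, ncRNA class annotation and conserved miRNA
# matching, plus library-annotation summary tables.

#' Clean raw sRNA reads
#'
#' Removal reasons are assessed in a fixed order (first match wins):
#' low mean quality, missing/untrimmable 3' adapter, poly-A composition
#' (at least 80% A after trimming), then length outside
#' `[min_len, max_len]`. The 3' adapter is located as the longest read
#' suffix matching a prefix of the adapter, allowing one mismatch per 10
#' adapter bases compared.
#'
#' @param reads Data frame with columns `seq` and optionally `qual`
#'   (Sanger-encoded); a character vector of sequences is also accepted.
#' @param adapter3 3' adapter sequence; `NULL` or `""` skips adapter
#'   trimming (pre-trimmed input).
#' @param min_len,max_len Retained insert length range in nt (default
#'   18-30).
#' @param min_q Minimum mean Phred quality (default 20); only applied when
#'   qualities are present.
#' @param polyA_frac Poly-A removal threshold on the A fraction after
#'   trimming (default 0.8).
#' @return A list with `reads` (character vector of clean inserts) and
#'   `stats`, a `clean_stats` list with `raw`, `clean`, `unique` and the
#'   per-reason removal counts (`low_quality`, `no_adapter`, `poly_a`,
#'   `too_short`, `too_long`).
#' @export
clean_reads <- function(reads, adapter3 = NULL, min_len = 18L, max_len = 30L,
                        min_q = 20, polyA_frac = 0.8) {
  if (is.character(reads)) reads <- data.frame(seq = reads,
                                               stringsAsFactors = FALSE)
  seqs <- normalize_seq(reads$seq %||% character(0))
  quals <- reads$qual
  n <- length(seqs)
  removed <- c(low_quality = 0L, no_adapter = 0L, poly_a = 0L,
               too_short = 0L, too_long = 0L)
  keep <- character(0)
  use_adapter <- !is.null(adapter3) && nzchar(adapter3)
  if (use_adapter) adapter3 <- normalize_seq(adapter3, "adapter")
  for (i in seq_len(n)) {
    s <- seqs[i]
    if (!is.null(quals) && nzchar(quals[i])) {
      q <- utf8ToInt(quals[i]) - 33L
      if (mean(q) < min_q) {
        removed["low_quality"] <- removed["low_quality"] + 1L
        next
      }
    }
    if (use_adapter) {
      cut <- locate_adapter(s, adapter3)
      if (is.na(cut)) {
        removed["no_adapter"] <- removed["no_adapter"] + 1L
        next
      }
      s <- substr(s, 1L, cut)
    }
    len <- nchar(s)
    if (len > 0L &&
        nchar(gsub("[^A]", "", s)) / len >= polyA_frac) {
      removed["poly_a"] <- removed["poly_a"] + 1L
      next
    }
    if (len < min_len) {
      removed["too_short"] <- removed["too_short"] + 1L
      next
    }
    if (len > max_len) {
      removed["too_long"] <- removed["too_long"] + 1L
      next
    }
    keep <- c(keep, s)
  }
  stats <- list(raw = n, clean = length(keep),
                unique = length(unique(keep)), removed = as.list(removed))
  class(stats) <- "clean_stats"
  list(reads = keep, stats = stats)
}

# 0-based insert length before the adapter, or NA when no acceptable
# adapter match is found. The match must extend to the read's 3' end
# (suffix of read vs prefix of adapter), allowing floor(matched/10)
# mismatches.
locate_adapter <- function(read, adapter) {
  n <- nchar(read)
  la <- nchar(adapter)
  rc <- strsplit(read, "", fixed = TRUE)[[1L]]
  ac <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  for (p in seq_len(n)) {          # adapter starting at read position p
    span <- min(n - p + 1L, la)
    mism <- sum(rc[p:(p + span - 1L)] != ac[seq_len(span)])
    if (mism <= span %/% 10L) return(p - 1L)
  }
  NA_integer_
}

#' Collapse cleaned reads into a tag table
#'
#' @param reads_per_library Named list of character vectors of clean reads,
#'   one element per library.
#' @return A `tag_table` with one row per distinct sequence; per-library
#'   counts sum to the per-library clean read totals.
#' @export
collapse_reads <- function(reads_per_library) {
  stopifnot(is.list(reads_per_library), !is.null(names(reads_per_library)))
  libs <- names(reads_per_library)
  tabs <- lapply(reads_per_library, function(r) table(normalize_seq(r)))
  tags <- sort(unique(unlist(lapply(tabs, names))))
  counts <- vapply(tabs, function(tb) {
    v <- as.integer(tb[tags])
    v[is.na(v)] <- 0L
    v
  }, integer(length(tags)))
  if (length(tags) == 1L) counts <- matrix(counts, nrow = 1L,
                                           dimnames = list(NULL, libs))
  if (length(tags) == 0L) counts <- matrix(integer(), 0L, length(libs),
                                           dimnames = list(NULL, libs))
  tag_table(tags, counts, libs)
}

#' Length distribution of a tag table
#'
#' @param table A `tag_table`.
#' @param weighted If `TRUE`, count total reads per length; otherwise count
#'   unique tags.
#' @param range Length range to tabulate (default 18:30).
#' @return Integer matrix, rows = lengths, columns = libraries.
#' @export
length_distribution <- function(table, weighted = TRUE, range = 18:30) {
  libs <- tag_libraries(table)
  out <- matrix(0L, length(range), length(libs),
                dimnames = list(as.character(range), libs))
  if (nrow(table) == 0L) return(out)
  len <- nchar(table$tag)
  for (j in seq_along(libs)) {
    w <- if (weighted) table[[libs[j]]] else as.integer(table[[libs[j]]] > 0L)
    s <- tapply(w, factor(len, levels = range), sum)
    s[is.na(s)] <- 0L
    out[, j] <- as.integer(s)
  }
  out
}

#' Match a tag against a catalog of known miRNAs
#'
#' Ungapped comparison with a +/-2 nt end-shift scan: the tag is slid along
#' each catalog entry whose length differs by at most 2 nt, mismatches are
#' counted over the overlap, and the minimum-mismatch hit with at most
#' `max_mm` mismatches wins; ties keep the first catalog entry.
#'
#' @param tag Tag sequence.
#' @param catalog Data frame with columns `id` and `seq`.
#' @param max_mm Maximum mismatches (default 2).
#' @return A list with `id` and `mismatches`, or `NULL` when nothing is
#'   within `max_mm`.
#' @export
match_conserved <- function(tag, catalog, max_mm = 2L) {
  tag <- normalize_seq(tag, "tag")
  tc <- strsplit(tag, "", fixed = TRUE)[[1L]]
  lt <- length(tc)
  best <- NULL
  for (k in seq_len(nrow(catalog))) {
    cs <- catalog$seq[k]
    lc <- nchar(cs)
    if (abs(lc - lt) > 2L) next
    cc <- strsplit(cs, "", fixed = TRUE)[[1L]]
    for (off in -2L:2L) {   # tag position 1 aligns catalog position 1 + off
      i1 <- max(1L, 1L - off)            # tag indices in overlap
      i2 <- min(lt, lc - off)
      if (i2 - i1 + 1L < lt - 2L) next   # require near-full tag coverage
      mism <- sum(tc[i1:i2] != cc[(i1 + off):(i2 + off)])
      if (mism <= max_mm && (is.null(best) || mism < best$mismatches)) {
        best <- list(id = catalog$id[k], mismatches = as.integer(mism))
      }
    }
    if (!is.null(best) && best$mismatches == 0L) break
  }
  best
}

CLASS_PRIORITY <- c("rRNA", "tRNA", "snRNA", "snoRNA")

#' Annotate unique tags by ncRNA class and conserved miRNA identity
#'
#' Each tag receives exactly one class, assessed in priority order
#' rRNA > tRNA > snRNA > snoRNA (exact substring containment in the class
#' reference sequences) > miRNA (catalog match within `max_mm` mismatches,
#' see [match_conserved()]) > unann.
#'
#' @param table A `tag_table`.
#' @param class_map Named list of character vectors: class reference
#'   sequences for (a subset of) rRNA, tRNA, snRNA, snoRNA.
#' @param catalog Known-miRNA catalog (data frame `id`, `seq`) or `NULL`.
#' @param max_mm Maximum catalog mismatches.
#' @return The input table with added columns `class`, `catalog_id`,
#'   `catalog_mm`.
#' @export
annotate_tags <- function(table, class_map = list(), catalog = NULL,
                          max_mm = 2L) {
  tags <- normalize_seq(table$tag)
  class <- rep("unann", length(tags))
  catalog_id <- rep(NA_character_, length(tags))
  catalog_mm <- rep(NA_integer_, length(tags))
  haystacks <- lapply(class_map, function(seqs)
    paste(normalize_seq(seqs), collapse = "#"))
  for (i in seq_along(tags)) {
    assigned <- FALSE
    for (cl in intersect(CLASS_PRIORITY, names(haystacks))) {
      if (grepl(tags[i], haystacks[[cl]], fixed = TRUE)) {
        class[i] <- cl
        assigned <- TRUE
        break
      }
    }
    if (!assigned && !is.null(catalog) && nrow(catalog) > 0L) {
      hit <- match_conserved(tags[i], catalog, max_mm)
      if (!is.null(hit)) {
        class[i] <- "miRNA"
        catalog_id[i] <- hit$id
        catalog_mm[i] <- hit$mismatches
      }
    }
  }
  out <- table
  out$class <- class
  out$catalog_id <- catalog_id
  out$catalog_mm <- catalog_mm
  out
}

ANNOTATION_CLASSES <- c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "unann")

#' Annotation summary from an annotated tag table
#'
#' @param annotated Output of [annotate_tags()].
#' @return See [summarize_class_counts()].
#' @export
annotation_summary <- function(annotated) {
  libs <- setdiff(names(annotated),
                  c("tag", "class", "catalog_id", "catalog_mm"))
  uq <- matrix(0L, length(ANNOTATION_CLASSES), length(libs),
               dimnames = list(ANNOTATION_CLASSES, libs))
  tot <- uq
  for (j in seq_along(libs)) {
    cnt <- annotated[[libs[j]]]
    for (cl in ANNOTATION_CLASSES) {
      sel <- annotated$class == cl & cnt > 0L
      uq[cl, j] <- sum(sel)
      tot[cl, j] <- sum(cnt[annotated$class == cl])
    }
  }
  summarize_class_counts(uq, tot)
}

#' Class-count summary with percentages
#'
#' Formats class-by-library unique and total read counts into the
#' conventional annotation summary: for every library, unique and total
#' counts per class with percentages of the library totals, rounded to two
#' decimals.
#'
#' @param unique_counts,total_counts Integer matrices, rows = classes,
#'   columns = libraries. A `Total` row is computed as the column sums
#'   unless a row named `Total` is already present (so externally tabulated totals can
#'   be passed through verbatim).
#' @return A data frame with columns `category`, then per library
#'   `<lib>_unique`, `<lib>_unique_pct`, `<lib>_total`, `<lib>_total_pct`.
#' @export
summarize_class_counts <- function(unique_counts, total_counts) {
  stopifnot(identical(dim(unique_counts), dim(total_counts)))
  libs <- colnames(unique_counts)
  if (!"Total" %in% rownames(unique_counts)) {
    unique_counts <- rbind(Total = colSums(unique_counts), unique_counts)
    total_counts <- rbind(Total = colSums(total_counts), total_counts)
  }
  u_tot <- unique_counts["Total", ]
  t_tot <- total_counts["Total", ]
  out <- data.frame(category = rownames(unique_counts),
                    stringsAsFactors = FALSE)
  for (j in seq_along(libs)) {
    out[[paste0(libs[j], "_unique")]] <- unique_counts[, j]
    out[[paste0(libs[j], "_unique_pct")]] <-
      round(100 * unique_counts[, j] / u_tot[j], 2)
    out[[paste0(libs[j], "_total")]] <- total_counts[, j]
    out[[paste0(libs[j], "_total_pct")]] <-
      round(100 * total_counts[, j] / t_tot[j], 2)
  }
  rownames(out) <- NULL
  out
}
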