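# Novel miRNA discovery: candidate precursor windows around tag clusters,
# secondary-structure folding, the four hairpin screening criteria,
# MFE/AMFE/MFEI metrics and the processing-precision filter.

#' Fold an RNA sequence into its minimum-free-energy secondary structure
#'
#' Two backends are available. `"bundled"` is the package's own exact
#' dynamic-programming model over pseudoknot-free structures (stacking bonus
#' of -2 kcal/mol for a stacked GC pair, -1 for stacked AU/GU, +3 per hairpin
#' loop, minimum loop size 3). `"vienna"` shells out to the `RNAfold`
#' executable if present on the PATH. The backend used is recorded in the
#' return value so downstream thresholds can be interpreted.
#'
#' Sequences with more than 10% `N` are not folded; they are reported as
#' rejected rather than raising an error.
#'
#' @param seq A nucleotide string (DNA or RNA alphabet).
#' @param backend `"bundled"` (default) or `"vienna"`.
#' @return A list with elements `structure` (dot-bracket), `mfe` (kcal/mol,
#'   <= 0), `backend`, and `ok` (`FALSE` with a `reason` when the sequence
#'   was rejected).
#' @examples
#' fold("GGGGGAAAACCCCC")
#' @export
fold <- function(seq, backend = c("bundled", "vienna")) {
  backend <- match.arg(backend)
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n > 0 && nchar(gsub("[^N]", "", seq)) / n > 0.1) {
    return(list(structure = NA_character_, mfe = NA_real_,
                backend = backend, ok = FALSE, reason = "N fraction > 10%"))
  }
  rna <- to_rna(seq)
  if (backend == "bundled") {
    res <- .fold_bundled_cpp(rna)
    return(list(structure = res$structure, mfe = res$mfe,
                backend = "bundled", ok = TRUE))
  }
  out <- tryCatch(
    system2("RNAfold", args = c("--noPS"), input = rna,
            stdout = TRUE, stderr = FALSE),
    error = function(e) NULL)
  if (is.null(out) || length(out) < 2L)
    stop("RNAfold backend unavailable or failed", call. = FALSE)
  line <- out[2L]
  m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1L]]
  if (length(m) != 3L) stop("could not parse RNAfold output: ", line, call. = FALSE)
  list(structure = m[2L], mfe = as.numeric(m[3L]), backend = "vienna", ok = TRUE)
}

#' Base-pair partner table of a dot-bracket string
#'
#' @param structure Dot-bracket string.
#' @return Integer vector, `p[i]` is the 1-based partner of position `i`
#'   (`NA` if unpaired).
#' @export
pairing_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1L]]
  p <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid character in dot-bracket string: ", ch[i], call. = FALSE)
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  p
}

# Terminal (hairpin) loops: pairs with no pair strictly inside.
# Returns a list of integer vectors of 1-based loop positions.
terminal_loops <- function(structure) {
  p <- pairing_table(structure)
  loops <- list()
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (!is.na(p[i]) && p[i] > i) {
      inner <- if (p[i] - i > 1L) (i + 1L):(p[i] - 1L) else integer(0)
      if (all(is.na(p[inner]))) loops[[length(loops) + 1L]] <- inner
    }
    i <- i + 1L
  }
  loops
}

#' Count terminal loops of a structure
#'
#' A candidate precursor passes the "single hairpin" criterion when its
#' structure has exactly one terminal loop.
#'
#' @param structure Dot-bracket string.
#' @return Integer count of hairpin loops.
#' @export
n_hairpin_loops <- function(structure) length(terminal_loops(structure))

#' Hairpin energy metrics
#'
#' AMFE is the MFE scaled to 100 nt; MFEI divides AMFE by the GC percentage.
#' High-confidence plant pre-miRNAs typically show MFEI below about -0.85,
#' separating them from other structured RNAs.
#'
#' @param seq Precursor sequence.
#' @param mfe Minimum free energy in kcal/mol (<= 0).
#' @return A list with `amfe` (kcal/mol per 100 nt), `mfei` (dimensionless;
#'   `NA` when GC is zero) and `gc` (fraction).
#' @examples
#' hairpin_metrics(strrep("GC", 50), -50)
#' @export
hairpin_metrics <- function(seq, mfe) {
  stopifnot(nchar(seq) > 0, mfe <= 0)
  len <- nchar(seq)
  gc <- gc_fraction(normalize_seq(seq))
  amfe <- mfe / len * 100
  mfei <- if (gc > 0) amfe / (gc * 100) else NA_real_
  list(amfe = amfe, mfei = mfei, gc = gc)
}

# Infer the star span implied by the structure and the mature span, applying
# the canonical 2-nt 3' overhang geometry: the strand opposite the paired
# part of the mature (excluding the mature's own 2-nt 3' overhang), extended
# by 2 nt at its 3' end. Spans are 0-based half-open relative to the
# precursor. Returns NULL when the mature is too poorly paired to anchor.
infer_star_span <- function(structure, mature_span) {
  p <- pairing_table(structure)
  m1 <- mature_span[1L] + 1L  # 1-based inclusive
  m2 <- mature_span[2L]       # 1-based inclusive end
  if (m1 < 1L || m2 > length(p)) return(NULL)
  five_arm <- {
    partners <- p[m1:m2]
    ok <- which(!is.na(partners))
    if (length(ok) == 0L) return(NULL)
    median(partners[ok]) > m2  # star downstream => mature on 5' arm
  }
  # anchor positions: mature 5' end and the base 2 nt in from the 3' end
  anchor_of <- function(pos_range) {
    for (q in pos_range) if (!is.na(p[q])) return(p[q])
    NA_integer_
  }
  if (five_arm) {
    a_start <- anchor_of(seq(m2 - 2L, m1))        # partner of (m2-2) ~ star 5' end
    a_end <- anchor_of(seq(m1, m2 - 2L))          # partner of m1 ~ star 3' side
    if (is.na(a_start) || is.na(a_end)) return(NULL)
    c(a_start - 1L, a_end + 2L)                   # +2-nt 3' overhang, half-open
  } else {
    a_end <- anchor_of(seq(m2 - 2L, m1))          # partner of (m2-2)
    a_start <- anchor_of(seq(m1, m2 - 2L))        # partner of m1
    if (is.na(a_start) || is.na(a_end)) return(NULL)
    c(a_start - 1L - 2L, a_end)                   # star 3' end is upstream side
  }
}

#' Check miRNA/miRNA* duplex geometry on a folded precursor
#'
#' Implements the duplex criterion: the mature must pair into a single
#' opposing stem arm (it may not cross the terminal loop or pair with
#' itself), at least `min_paired_frac` of its bases must be paired, the
#' pairing must be antiparallel-monotone (a helix, not scattered partners),
#' the implied star strand (partners of the mature shifted for 2-nt
#' 3' overhangs on both strands) must fit inside the precursor on the
#' opposite arm, and the duplex may not be grossly asymmetric (star length
#' within `max_asymmetry` nt of the mature length). When an observed
#' `star_span` is supplied it must match the implied star exactly, so a
#' blunt-ended duplex (no 3' overhang) fails.
#'
#' @param structure Dot-bracket string of the precursor.
#' @param mature_span 0-based half-open span of the mature within the
#'   precursor.
#' @param star_span Optional observed star span; when `NULL` the star is
#'   inferred from the pairing with the 2-nt overhang rule and only the
#'   geometric checks apply.
#' @param min_paired_frac Minimum fraction of paired mature bases.
#' @param max_asymmetry Maximum absolute difference between star and mature
#'   lengths (bulge allowance, default 6 nt).
#' @return `TRUE` or `FALSE`.
#' @export
duplex_check <- function(structure, mature_span, star_span = NULL,
                         min_paired_frac = 0.6, max_asymmetry = 6L) {
  p <- pairing_table(structure)
  n <- length(p)
  m1 <- mature_span[1L] + 1L
  m2 <- mature_span[2L]
  if (m1 < 1L || m2 > n || m2 <= m1) return(FALSE)
  mature_pos <- m1:m2
  partners <- p[mature_pos]
  paired <- !is.na(partners)
  # (c) >= 60% of mature bases paired
  if (mean(paired) < min_paired_frac) return(FALSE)
  # (a) the mature may not pair with itself (spanning the terminal loop)
  # and its partners must all fall on one opposing arm
  q <- partners[paired]
  if (any(q %in% mature_pos)) return(FALSE)
  if (!(all(q < m1) || all(q > m2))) return(FALSE)
  # pairing must be antiparallel-monotone (a clean helix, not scattered)
  if (is.unsorted(rev(q), strictly = TRUE)) return(FALSE)
  # (b) implied star strand with 2-nt 3' overhangs on both strands
  star <- infer_star_span(structure, mature_span)
  if (is.null(star)) return(FALSE)
  if (star[1L] < 0L || star[2L] > n) return(FALSE)
  star_pos <- (star[1L] + 1L):star[2L]
  if (any(star_pos %in% mature_pos)) return(FALSE)
  if (abs(length(star_pos) - length(mature_pos)) > max_asymmetry)
    return(FALSE)
  if (!is.null(star_span)) {
    if (!identical(as.integer(star_span), as.integer(star))) return(FALSE)
  }
  TRUE
}

#' Processing precision of a candidate precursor
#'
#' The fraction of reads mapping within the precursor whose 5' ends fall
#' within `tol` nucleotides of the mature or star 5' end, computed on read
#' counts (not unique tags). Imprecisely processed loci (degradation
#' fragments, siRNA-like clusters) score low.
#'
#' @param starts Integer vector of 0-based 5'-end positions (precursor
#'   coordinates) of the reads mapping within the precursor.
#' @param counts Read counts parallel to `starts`.
#' @param mature_span,star_span 0-based half-open spans within the precursor
#'   (`star_span` may be `NULL` if no star is known).
#' @param tol Tolerance in nt around the mature/star 5' ends (default 2).
#' @return Precision in `[0, 1]`, or `NA` when no reads map.
#' @export
processing_precision <- function(starts, counts, mature_span,
                                 star_span = NULL, tol = 2L) {
  stopifnot(length(starts) == length(counts))
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  ends5 <- mature_span[1L]
  if (!is.null(star_span)) ends5 <- c(ends5, star_span[1L])
  hit <- vapply(starts, function(s) any(abs(s - ends5) <= tol), logical(1L))
  sum(counts[hit]) / total
}

#' Align tags exactly to reference transcripts
#'
#' Finds all exact, full-length, ungapped occurrences of each tag on the
#' forward strand of the reference transcripts using a k-mer index (one
#' index per tag length).
#'
#' @param table A `tag_table` (or data frame with a `tag` column).
#' @param reference Data frame of sequence records (`id`, `seq`).
#' @return A data frame with columns `tag`, `transcript`, `start`, `end`
#'   (0-based half-open) and `count` (reads summed over libraries).
#' @export
align_tags <- function(table, reference) {
  libs <- setdiff(names(table), "tag")
  total <- if (length(libs)) rowSums(as.matrix(table[libs])) else
    rep(1, nrow(table))
  tags <- table$tag
  out <- vector("list", 0L)
  for (len in sort(unique(nchar(tags)))) {
    sel <- which(nchar(tags) == len)
    kmers <- data.table::rbindlist(lapply(seq_len(nrow(reference)), function(r) {
      s <- reference$seq[r]
      n <- nchar(s)
      if (n < len) return(NULL)
      st <- seq_len(n - len + 1L)
      data.table::data.table(tag = substring(s, st, st + len - 1L),
                             transcript = reference$id[r], start = st - 1L)
    }))
    if (nrow(kmers) == 0L) next
    q <- data.table::data.table(tag = tags[sel], count = total[sel])
    hit <- merge(kmers, q, by = "tag", allow.cartesian = TRUE)
    if (nrow(hit)) out[[length(out) + 1L]] <- hit
  }
  if (length(out) == 0L) {
    return(data.frame(tag = character(), transcript = character(),
                      start = integer(), end = integer(), count = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- as.data.frame(data.table::rbindlist(out))
  res$end <- res$start + nchar(res$tag)
  res <- res[, c("tag", "transcript", "start", "end", "count")]
  res[order(res$transcript, res$start, res$tag), , drop = FALSE]
}

#' Extract candidate precursor windows around tag clusters
#'
#' Tags whose alignment spans overlap or abut within 3 nt are merged into
#' clusters; each cluster emits two windows, one with the long flank
#' downstream and one with it upstream, clipped to the transcript.
#'
#' @param alignments Output of [align_tags()].
#' @param reference Data frame of sequence records.
#' @param flank_up,flank_down Short and long flank lengths in nt.
#' @return Data frame with columns `transcript`, `win_start`, `win_end`,
#'   `cluster_start`, `cluster_end` (all 0-based half-open).
#' @export
extract_candidates <- function(alignments, reference,
                               flank_up = 20L, flank_down = 200L) {
  if (nrow(alignments) == 0L) {
    return(data.frame(transcript = character(), win_start = integer(),
                      win_end = integer(), cluster_start = integer(),
                      cluster_end = integer(), stringsAsFactors = FALSE))
  }
  tx_len <- setNames(nchar(reference$seq), reference$id)
  res <- list()
  for (tx in unique(alignments$transcript)) {
    a <- alignments[alignments$transcript == tx, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    cl_start <- a$start[1L]
    cl_end <- a$end[1L]
    flush <- function(s, e) {
      L <- tx_len[[tx]]
      w1 <- c(max(0L, s - flank_up), min(L, e + flank_down))
      w2 <- c(max(0L, s - flank_down), min(L, e + flank_up))
      data.frame(transcript = tx,
                 win_start = c(w1[1L], w2[1L]), win_end = c(w1[2L], w2[2L]),
                 cluster_start = s, cluster_end = e, stringsAsFactors = FALSE)
    }
    if (nrow(a) > 1L) {
      for (i in 2:nrow(a)) {
        if (a$start[i] <= cl_end + 3L) {
          cl_end <- max(cl_end, a$end[i])
        } else {
          res[[length(res) + 1L]] <- flush(cl_start, cl_end)
          cl_start <- a$start[i]
          cl_end <- a$end[i]
        }
      }
    }
    res[[length(res) + 1L]] <- flush(cl_start, cl_end)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  unique(out)
}

# Trim a folded window to the stem region anchored on the mature span: the
# minimal span covering the mature and the partners of its longest
# contiguous antiparallel pairing run (small bulges allowed), plus a small
# margin. Using the longest run rather than all partners keeps a stray
# mature edge base that got recruited into a distant flank helix from
# dragging the precursor span across unrelated structure.
# Coordinates are 0-based half-open within the window.
trim_to_stem <- function(structure, mature_rel, margin = 4L, max_bulge = 6L) {
  p <- pairing_table(structure)
  m_pos <- (mature_rel[1L] + 1L):mature_rel[2L]
  m_pos <- m_pos[m_pos >= 1L & m_pos <= length(p)]
  paired <- m_pos[!is.na(p[m_pos])]
  if (length(paired) == 0L) return(NULL)
  q <- p[paired]
  runs <- list()
  run <- 1L
  for (k in seq_along(paired)[-1L]) {
    contiguous <- q[k] < q[k - 1L] &&
      (q[k - 1L] - q[k]) <= max_bulge &&
      (paired[k] - paired[k - 1L]) <= max_bulge
    if (contiguous) run <- c(run, k) else {
      runs[[length(runs) + 1L]] <- run
      run <- k
    }
  }
  runs[[length(runs) + 1L]] <- run
  best <- runs[[which.max(lengths(runs))]]
  span <- c(m_pos, q[best])
  lo <- min(span) - 1L - margin
  hi <- max(span) + margin
  c(max(0L, lo), min(length(p), hi))
}

#' Screen candidate windows for novel miRNAs
#'
#' Applies the hairpin screening criteria to each candidate window:
#' the trimmed precursor must fold into a single hairpin, the mature/star
#' duplex must show 2-nt 3' overhang geometry on opposite arms, the MFE must
#' be at or below `mfe_max`, the mature read count must reach `min_reads`,
#' and the processing precision must pass `precision_min` (candidates at
#' exactly the threshold are retained). Overlapping accepted candidates are
#' deduplicated keeping the lowest-MFE one. The rejection reason recorded is
#' the first failing criterion in the order fold, hairpin, duplex, mfe,
#' count, precision.
#'
#' @param windows Output of [extract_candidates()].
#' @param alignments Output of [align_tags()] (all tags, used for the mature
#'   call and the precision denominator).
#' @param reference Data frame of sequence records.
#' @param min_reads Minimum mature read count (default 5).
#' @param mfe_max MFE acceptance threshold in kcal/mol (default -18).
#' @param precision_min Processing-precision threshold (default 0.1,
#'   inclusive).
#' @param backend Folding backend, see [fold()].
#' @return Data frame of candidates with spans, structure, energies
#'   (`mfe`, `amfe`, `mfei`, `gc`), `mature_count`, `precision`, `verdict`
#'   and `reason`; accepted rows carry `accepted = TRUE`.
#' @export
screen_novel <- function(windows, alignments, reference, min_reads = 5,
                         mfe_max = -18, precision_min = 0.1,
                         backend = "bundled") {
  rows <- list()
  tx_seq <- setNames(reference$seq, reference$id)
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    a <- alignments[alignments$transcript == w$transcript &
                      alignments$start >= w$win_start &
                      alignments$end <= w$win_end, , drop = FALSE]
    if (nrow(a) == 0L) next
    # clip very long windows around the cluster so folding stays tractable
    ws <- w$win_start
    we <- w$win_end
    if (we - ws > 400L) {
      mid <- (w$cluster_start + w$cluster_end) %/% 2L
      ws <- max(0L, mid - 200L)
      we <- min(nchar(tx_seq[[w$transcript]]), ws + 400L)
      a <- a[a$start >= ws & a$end <= we, , drop = FALSE]
      if (nrow(a) == 0L) next
    }
    # the mature call comes from the anchoring cluster, not the whole window
    in_cluster <- a$start < w$cluster_end & a$end > w$cluster_start
    if (!any(in_cluster)) next
    mature_row <- a[in_cluster, ][which.max(a$count[in_cluster]), ]
    window_seq <- substring(tx_seq[[w$transcript]], ws + 1L, we)
    f0 <- fold(window_seq, backend = backend)
    rec <- list(transcript = w$transcript, mature_tag = mature_row$tag,
                mature_count = mature_row$count)
    fail <- function(reason, extra = list()) {
      c(rec, extra,
        list(verdict = "rejected", reason = reason, accepted = FALSE))
    }
    if (!isTRUE(f0$ok)) {
      rows[[length(rows) + 1L]] <- fail("fold", list(
        pre_start = ws, pre_end = we, mfe = NA_real_))
      next
    }
    mature_rel <- c(mature_row$start - ws, mature_row$end - ws)
    stem <- trim_to_stem(f0$structure, mature_rel)
    if (is.null(stem)) {
      rows[[length(rows) + 1L]] <- fail("duplex", list(
        pre_start = ws, pre_end = we, mfe = f0$mfe))
      next
    }
    ps <- ws + stem[1L]
    pe <- ws + stem[2L]
    pre_seq <- substring(tx_seq[[w$transcript]], ps + 1L, pe)
    f <- fold(pre_seq, backend = backend)
    met <- hairpin_metrics(pre_seq, min(f$mfe, 0))
    m_rel <- c(mature_row$start - ps, mature_row$end - ps)
    star_rel <- if (isTRUE(f$ok)) infer_star_span(f$structure, m_rel) else NULL
    pre_tags <- alignments[alignments$transcript == w$transcript &
                             alignments$start >= ps &
                             alignments$end <= pe, , drop = FALSE]
    precision <- processing_precision(pre_tags$start - ps, pre_tags$count,
                                      m_rel, star_rel)
    extra <- list(pre_start = ps, pre_end = pe, structure = f$structure,
                  mfe = f$mfe, amfe = met$amfe, mfei = met$mfei, gc = met$gc,
                  mature_start = ps + m_rel[1L], mature_end = ps + m_rel[2L],
                  star_start = if (is.null(star_rel)) NA_integer_ else ps + star_rel[1L],
                  star_end = if (is.null(star_rel)) NA_integer_ else ps + star_rel[2L],
                  precision = precision, backend = f$backend)
    reason <- NULL
    if (!isTRUE(f$ok)) reason <- "fold"
    else if (n_hairpin_loops(f$structure) != 1L) reason <- "hairpin"
    else if (!duplex_check(f$structure, m_rel)) reason <- "duplex"
    else if (!(f$mfe <= mfe_max)) reason <- "mfe"
    else if (mature_row$count < min_reads) reason <- "count<5"
    else if (is.na(precision) || precision < precision_min) reason <- "precision"
    rows[[length(rows) + 1L]] <- c(rec, extra, list(
      verdict = if (is.null(reason)) "accepted" else "rejected",
      reason = reason %||% "", accepted = is.null(reason)))
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript = character(), mature_tag = character(),
                      accepted = logical(), stringsAsFactors = FALSE))
  }
  all_names <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  # deduplicate overlapping accepted candidates, keeping the lowest MFE
  acc <- which(df$accepted)
  if (length(acc) > 1L) {
    keep <- rep(TRUE, length(acc))
    ord <- acc[order(df$mfe[acc])]
    chosen <- list()
    for (j in ord) {
      overlaps <- any(vapply(chosen, function(c0) {
        df$transcript[j] == df$transcript[c0] &&
          df$pre_start[j] < df$pre_end[c0] && df$pre_end[j] > df$pre_start[c0]
      }, logical(1L)))
      if (overlaps) {
        df$accepted[j] <- FALSE
        df$verdict[j] <- "rejected"
        df$reason[j] <- "duplicate"
      } else {
        chosen[[length(chosen) + 1L]] <- j
      }
    }
  }
  rownames(df) <- NULL
  df
}
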