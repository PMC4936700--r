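# Degradome-guided target calling: miRNA-transcript duplex scoring with
# G:U wobbles, transcript 5'-end profiles, cleavage-site calls opposite
# miRNA positions 10-11, and three-category classification.

# Per-position duplex states between a miRNA base and the transcript base it
# faces. Both sequences are in the internal DNA alphabet; the target site is
# the transcript window read 5'->3', so miRNA position i (1-based from its
# 5' end) faces the site base at (site length - i + 1).
duplex_state <- function(m, t) {
  if (t == COMPLEMENT[[m]]) return("match")
  if ((m == "G" && t == "T") || (m == "T" && t == "G")) return("wobble")
  "mismatch"
}

STATE_SYMBOL <- c(match = "|", wobble = "o", mismatch = "x", gap = "-")

#' Score a miRNA/target-site duplex
#'
#' Ungapped antiparallel pairing of the miRNA (5'->3') against a candidate
#' target site (transcript window, 5'->3'). Penalties follow the standard
#' plant-target scoring convention: mismatch 1, G:U wobble 0.5, gap 2, all
#' doubled within miRNA positions 2-13. Any non-match opposite miRNA
#' positions 10 or 11 (the cleavage site) invalidates the alignment. Site
#' lengths differing from the miRNA by up to 2 nt are handled by treating
#' the unfaced miRNA 3'-end positions as gaps; larger differences return
#' `NULL`.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site Target-site sequence on the transcript, 5'->3'.
#' @param penalties Named list overriding `mismatch`, `wobble`, `gap`,
#'   the `core` positions, and the `core_multiplier`.
#' @return A list with `score`, `states` (per miRNA position), `symbol`
#'   (compact string, miRNA 5'->3') and `valid` (no non-match at positions
#'   10-11), or `NULL` when the lengths are incompatible.
#' @examples
#' score_duplex("ACGTACGTACGTACGTACGTA", revcomp("ACGTACGTACGTACGTACGTA"))
#' @export
score_duplex <- function(mirna, site, penalties = list()) {
  pen <- modifyList(list(mismatch = 1, wobble = 0.5, gap = 2,
                         core = 2:13, core_multiplier = 2), penalties)
  mirna <- normalize_seq(mirna, "miRNA")
  site <- normalize_seq(site, "site")
  L <- nchar(mirna)
  Ls <- nchar(site)
  if (abs(L - Ls) > 2L) return(NULL)
  mc <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  sc <- strsplit(site, "", fixed = TRUE)[[1L]]
  states <- character(L)
  score <- 0
  for (i in seq_len(L)) {
    j <- Ls - i + 1L  # site base faced by miRNA position i
    st <- if (j >= 1L) duplex_state(mc[i], sc[j]) else "gap"
    states[i] <- st
    p <- switch(st, match = 0, wobble = pen$wobble,
                mismatch = pen$mismatch, gap = pen$gap)
    if (i %in% pen$core) p <- p * pen$core_multiplier
    score <- score + p
  }
  valid <- all(states[c(10L, 11L)] == "match")
  list(score = score, states = states,
       symbol = paste(STATE_SYMBOL[states], collapse = ""), valid = valid)
}

#' Find candidate target sites of a miRNA on a transcript
#'
#' Scans every window of miRNA length over the transcript, keeps windows
#' with duplex score at most `max_score` and perfect pairing opposite miRNA
#' positions 10-11, and deduplicates overlapping hits keeping the
#' minimum-score (then leftmost) one.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param transcript Transcript sequence (or a single-row record data
#'   frame).
#' @param max_score Maximum duplex score (default 4).
#' @param penalties See [score_duplex()].
#' @return Data frame with columns `start`, `end` (0-based half-open site
#'   span), `score` and `symbol`; zero rows when nothing passes.
#' @export
find_target_sites <- function(mirna, transcript, max_score = 4,
                              penalties = list()) {
  if (is.data.frame(transcript)) transcript <- transcript$seq[1L]
  mirna <- normalize_seq(mirna, "miRNA")
  tx <- normalize_seq(transcript, "transcript")
  L <- nchar(mirna)
  n <- nchar(tx)
  empty <- data.frame(start = integer(), end = integer(), score = numeric(),
                      symbol = character(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  pen <- modifyList(list(mismatch = 1, wobble = 0.5, gap = 2,
                         core = 2:13, core_multiplier = 2), penalties)
  mc <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  txc <- strsplit(tx, "", fixed = TRUE)[[1L]]
  starts <- 0:(n - L)  # 0-based window starts
  score <- numeric(length(starts))
  invalid <- logical(length(starts))
  for (i in seq_len(L)) {
    tb <- txc[starts + L - i + 1L]  # base faced by miRNA position i
    st <- ifelse(tb == COMPLEMENT[[mc[i]]], "match",
                 ifelse((mc[i] == "G" & tb == "T") | (mc[i] == "T" & tb == "G"),
                        "wobble", "mismatch"))
    p <- ifelse(st == "match", 0, ifelse(st == "wobble", pen$wobble,
                                         pen$mismatch))
    if (i %in% pen$core) p <- p * pen$core_multiplier
    score <- score + p
    if (i %in% c(10L, 11L)) invalid <- invalid | st != "match"
  }
  keep <- which(!invalid & score <= max_score)
  if (length(keep) == 0L) return(empty)
  hits <- data.frame(start = starts[keep], end = starts[keep] + L,
                     score = score[keep], stringsAsFactors = FALSE)
  hits <- hits[order(hits$score, hits$start), , drop = FALSE]
  chosen <- integer(0)
  for (r in seq_len(nrow(hits))) {
    if (!any(hits$start[r] < hits$end[chosen] &
               hits$end[r] > hits$start[chosen])) {
      chosen <- c(chosen, r)
    }
  }
  hits <- hits[chosen, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$symbol <- vapply(seq_len(nrow(hits)), function(r) {
    score_duplex(mirna, substring(tx, hits$start[r] + 1L, hits$end[r]),
                 penalties)$symbol
  }, character(1L))
  rownames(hits) <- NULL
  hits
}

#' Per-transcript degradome 5'-end profile
#'
#' Aligns fixed-length degradome tags exactly (full-length, ungapped,
#' forward strand) to one transcript and counts tag 5' ends per position.
#'
#' @param tags Character vector of degradome tag sequences.
#' @param counts Read counts parallel to `tags`.
#' @param transcript Transcript sequence (or single-row record data frame
#'   with `id`/`seq`).
#' @return A list with `counts` (integer vector over 0-based positions,
#'   length = transcript length), `total` (aligned tag reads), `max` and
#'   `median` (median over positions with at least one count; `NA` if
#'   none).
#' @export
build_profile <- function(tags, counts, transcript) {
  id <- NULL
  if (is.data.frame(transcript)) {
    id <- transcript$id[1L]
    transcript <- transcript$seq[1L]
  }
  stopifnot(length(tags) == length(counts))
  tx <- normalize_seq(transcript, "transcript")
  n <- nchar(tx)
  prof <- integer(n)
  total <- 0
  for (k in seq_along(tags)) {
    m <- gregexpr(tags[k], tx, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (pos in m) {  # 1-based match start
      prof[pos] <- prof[pos] + counts[k]
      total <- total + counts[k]
    }
  }
  nz <- prof[prof > 0]
  list(transcript = id, counts = prof, total = total,
       max = if (n) max(prof) else 0L,
       median = if (length(nz)) median(nz) else NA_real_)
}

#' Degradome profiles for all transcripts at once
#'
#' Equivalent to calling [build_profile()] per transcript, but aligns the
#' fixed-length tags through one k-mer index join, which scales to
#' library-sized tag tables.
#'
#' @param table A `tag_table` of degradome tags (all the same length).
#' @param reference Data frame of sequence records (`id`, `seq`).
#' @param libraries Library columns to sum (default: all).
#' @return Named list of profiles (see [build_profile()]), one per
#'   transcript.
#' @export
build_profiles <- function(table, reference, libraries = tag_libraries(table)) {
  tlen <- unique(nchar(table$tag))
  if (length(tlen) > 1L)
    stop("degradome tags must have a single fixed length", call. = FALSE)
  total <- if (nrow(table)) rowSums(as.matrix(table[libraries])) else numeric(0)
  profs <- lapply(seq_len(nrow(reference)), function(r) {
    n <- nchar(reference$seq[r])
    list(transcript = reference$id[r], counts = integer(n), total = 0,
         max = 0L, median = NA_real_)
  })
  names(profs) <- reference$id
  if (nrow(table) == 0L || length(tlen) == 0L) return(profs)
  kmers <- data.table::rbindlist(lapply(seq_len(nrow(reference)), function(r) {
    s <- reference$seq[r]
    n <- nchar(s)
    if (n < tlen) return(NULL)
    st <- seq_len(n - tlen + 1L)
    data.table::data.table(tag = substring(s, st, st + tlen - 1L),
                           transcript = reference$id[r], start = st - 1L)
  }))
  hits <- merge(kmers, data.table::data.table(tag = table$tag, count = total),
                by = "tag", allow.cartesian = TRUE)
  if (nrow(hits)) {
    hdf <- as.data.frame(hits)
    for (txid in unique(hdf$transcript)) {
      h <- hdf[hdf$transcript == txid, ]
      prof <- profs[[txid]]
      agg <- rowsum(h$count, group = h$start)
      idx <- as.integer(rownames(agg)) + 1L
      prof$counts[idx] <- prof$counts[idx] + as.integer(agg[, 1L])
      prof$total <- sum(prof$counts)
      nz <- prof$counts[prof$counts > 0]
      prof$max <- max(prof$counts)
      prof$median <- if (length(nz)) median(nz) else NA_real_
      profs[[txid]] <- prof
    }
  }
  profs
}

#' Call a cleavage site from a degradome profile and a duplex alignment
#'
#' The cleavage coordinate is the transcript base paired to miRNA position
#' 10 (slicing occurs between the bases opposite positions 10 and 11). Site
#' abundance is the maximum profile count within +/-1 nt of that
#' coordinate. Categories: I when the abundance equals the transcript-wide
#' maximum, II when it lies strictly between the maximum and the median of
#' positions with at least one count, III when it is at or below that
#' median (but at least 1). No call is made at zero abundance.
#'
#' @param profile Output of [build_profile()].
#' @param site_start,site_end 0-based half-open target-site span (from
#'   [find_target_sites()]).
#' @param peak_window Half-width of the abundance window (default 1 nt).
#' @return A list with `position` (0-based cleavage coordinate),
#'   `abundance` and `category` (`"I"`, `"II"`, `"III"`), or `NULL`.
#' @export
call_cleavage <- function(profile, site_start, site_end, peak_window = 1L) {
  L <- site_end - site_start
  pos <- site_start + L - 10L  # 0-based base paired to miRNA position 10
  n <- length(profile$counts)
  if (pos < 0L || pos >= n) return(NULL)
  win <- max(0L, pos - peak_window):min(n - 1L, pos + peak_window)
  abundance <- max(profile$counts[win + 1L])
  if (abundance == 0L) return(NULL)
  med <- profile$median
  category <- if (abundance == profile$max) "I"
  else if (abundance > med) "II"
  else "III"
  list(position = pos, abundance = abundance, category = category)
}

#' Pool target calls across libraries and tally categories
#'
#' Each (miRNA, transcript, position) site keeps its best category across
#' libraries (I < II < III); each (miRNA, transcript) target is counted once
#' at the best category among its sites.
#'
#' @param calls Data frame with columns `library`, `mirna`, `transcript`,
#'   `position`, `abundance`, `category` (one row per call per library).
#' @return A list with `targets` (per-target best categories and site
#'   lists), `sites` (per-site best categories) and `tally` (targets and
#'   sites per category).
#' @export
summarize_targets <- function(calls) {
  lev <- c("I", "II", "III")
  tally0 <- data.frame(category = lev, targets = 0L, sites = 0L,
                       stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0L) {
    return(list(targets = data.frame(), sites = data.frame(), tally = tally0))
  }
  calls$category <- factor(calls$category, levels = lev)
  key <- paste(calls$mirna, calls$transcript, calls$position, sep = "\r")
  best <- tapply(as.integer(calls$category), key, min)
  sites <- data.frame(do.call(rbind, strsplit(names(best), "\r", fixed = TRUE)),
                      stringsAsFactors = FALSE)
  names(sites) <- c("mirna", "transcript", "position")
  sites$position <- as.integer(sites$position)
  sites$category <- lev[best]
  tkey <- paste(sites$mirna, sites$transcript, sep = "\r")
  tbest <- tapply(match(sites$category, lev), tkey, min)
  targets <- data.frame(do.call(rbind, strsplit(names(tbest), "\r", fixed = TRUE)),
                        stringsAsFactors = FALSE)
  names(targets) <- c("mirna", "transcript")
  targets$category <- lev[tbest]
  targets$n_sites <- as.integer(table(tkey)[names(tbest)])
  tally <- data.frame(
    category = lev,
    targets = vapply(lev, function(l) sum(targets$category == l), integer(1L)),
    sites = vapply(lev, function(l) sum(sites$category == l), integer(1L)),
    stringsAsFactors = FALSE)
  rownames(sites) <- rownames(targets) <- rownames(tally) <- NULL
  list(targets = targets, sites = sites, tally = tally)
}
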