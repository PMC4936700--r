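# Normalization, fold change, the Audic-Claverie exact test and
# significance calls for library contrasts, plus summary arithmetic for
# annotation tables.

#' Reads-per-million normalization
#'
#' @param count Raw read count (non-negative).
#' @param total Library total of clean reads (positive).
#' @return `count / total * 1e6`.
#' @examples
#' normalize_rpm(2821727, 14733335)
#' @export
normalize_rpm <- function(count, total) {
  if (any(total <= 0)) stop("library total must be positive", call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count / total * 1e6
}

#' Log2 fold change between normalized abundances
#'
#' A small pseudo-abundance guards zeros; the function is antisymmetric in
#' its first two arguments.
#'
#' @param rpm_a,rpm_b Normalized abundances (RPM) in the two libraries.
#' @param pseudo Pseudo-RPM added to both (default 0.01).
#' @return `log2((rpm_a + pseudo) / (rpm_b + pseudo))`.
#' @export
log2_fold_change <- function(rpm_a, rpm_b, pseudo = 0.01) {
  stopifnot(all(rpm_a >= 0), all(rpm_b >= 0), pseudo > 0)
  log2((rpm_a + pseudo) / (rpm_b + pseudo))
}

#' Audic-Claverie exact test for two digital counts
#'
#' Given a count `x` in a library of total `N1` and a count `y` in a library
#' of total `N2`, the conditional distribution of `y` given `x` is
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!} (1+N2/N1)^{-(x+y+1)}.}
#' The lower tail `C` sums `p(y'|x)` for `y' <= y`, the upper tail `D` for
#' `y' >= y` (both including the observed point), and the two-sided p-value
#' doubles the smaller tail, capped at 1. Evaluation is in log-space via
#' `lgamma`, so large counts do not overflow.
#'
#' @param x,y Observed counts (non-negative integers).
#' @param N1,N2 Library totals (positive).
#' @return A list with `C`, `D` and `p`.
#' @examples
#' audic_claverie(0, 0, 1e6, 1e6)  # C = 0.5, D = 1, p = 1
#' @export
audic_claverie <- function(x, y, N1, N2) {
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive", call. = FALSE)
  if (x < 0 || y < 0 || x != floor(x) || y != floor(y))
    stop("counts must be non-negative integers", call. = FALSE)
  r <- N2 / N1
  logr <- log(N2) - log(N1)
  log1pr <- log1p(r)
  logp_given <- function(yy) {
    yy * logr + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
      (x + yy + 1) * log1pr
  }
  yy <- 0:y
  lp <- logp_given(yy)
  mx <- max(lp)
  C <- min(1, exp(mx) * sum(exp(lp - mx)))
  # upper tail summed directly (never via 1 - C, which cancels when C ~ 1).
  # The terms are log-concave with mode near mu = r (x + 1); summing to
  # 60 standard deviations past max(y, mu) leaves a relative truncation
  # error far below double precision.
  mu <- r * (x + 1)
  spread <- sqrt(max(y, mu) + 25)
  y_hi <- ceiling(max(y, mu) + 60 * spread + 100)
  yy2 <- y:y_hi
  lp2 <- logp_given(yy2)
  mx2 <- max(lp2)
  D <- min(1, exp(mx2) * sum(exp(lp2 - mx2)))
  p <- min(1, 2 * min(C, D))
  list(C = C, D = D, p = p)
}

#' Differential expression calls over library contrasts
#'
#' Runs the Audic-Claverie test and the fold-change rule over every miRNA
#' row of a tag table for each requested contrast. A miRNA is called `up`
#' when log2 fold change (A over B) exceeds 1 and the two-sided p-value is
#' at most 0.05, `down` when the fold change is below -1 at the same
#' p-value, `ns` otherwise; fold-change inequalities are strict, the p
#' threshold is inclusive. A Benjamini-Hochberg adjusted p-value column is
#' emitted for reference but not used for the calls.
#'
#' @param table A `tag_table` restricted to miRNA rows (the `tag` column may
#'   hold ids rather than sequences).
#' @param contrasts List of two-element character vectors `c(libA, libB)`;
#'   the fold change is A over B.
#' @param totals Named vector of per-library totals used as the
#'   normalization denominator (defaults to the table's column sums;
#'   the study convention is total clean reads per library).
#' @param alpha P-value threshold (inclusive, default 0.05).
#' @param lfc Log2 fold-change threshold (strict, default 1).
#' @param pseudo Pseudo-RPM for the fold change.
#' @return Data frame with one row per miRNA per contrast: `mirna`,
#'   `contrast`, `x`, `y`, `N1`, `N2`, `rpm_a`, `rpm_b`, `log2fc`, `C`, `D`,
#'   `p`, `padj`, `call`.
#' @export
call_differential <- function(table, contrasts, totals = NULL, alpha = 0.05,
                              lfc = 1, pseudo = 0.01) {
  libs <- setdiff(names(table), "tag")
  if (is.null(totals)) totals <- colSums(as.matrix(table[libs]))
  res <- list()
  for (ct in contrasts) {
    a <- ct[1L]; b <- ct[2L]
    if (!a %in% libs || !b %in% libs || !a %in% names(totals) ||
        !b %in% names(totals))
      stop("unknown library in contrast: ", a, " vs ", b, call. = FALSE)
    N1 <- totals[[b]]; N2 <- totals[[a]]  # x from B (baseline), y from A
    for (i in seq_len(nrow(table))) {
      x <- table[[b]][i]; y <- table[[a]][i]
      rpm_a <- normalize_rpm(y, totals[[a]])
      rpm_b <- normalize_rpm(x, totals[[b]])
      l2 <- log2_fold_change(rpm_a, rpm_b, pseudo)
      ac <- audic_claverie(x, y, N1, N2)
      res[[length(res) + 1L]] <- data.frame(
        mirna = table$tag[i], contrast = paste0(a, " vs ", b),
        x = x, y = y, N1 = N1, N2 = N2, rpm_a = rpm_a, rpm_b = rpm_b,
        log2fc = l2, C = ac$C, D = ac$D, p = ac$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$padj <- NA_real_
  for (ct in unique(out$contrast)) {
    sel <- out$contrast == ct
    out$padj[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  out$call <- "ns"
  out$call[out$log2fc > lfc & out$p <= alpha] <- "up"
  out$call[out$log2fc < -lfc & out$p <= alpha] <- "down"
  rownames(out) <- NULL
  out
}

#' miRNAs differentially expressed in every listed contrast
#'
#' @param de Output of [call_differential()].
#' @param contrasts Character vector of contrast names (default: all).
#' @return Character vector of miRNA ids called up or down in each contrast.
#' @export
shared_differential <- function(de, contrasts = unique(de$contrast)) {
  sets <- lapply(contrasts, function(ct) {
    de$mirna[de$contrast == ct & de$call != "ns"]
  })
  Reduce(intersect, sets)
}

#' Percentage of unique tags shared between two libraries
#'
#' The fraction of the union: `100 * common / (unique_a + unique_b -
#' common)`.
#'
#' @param unique_a,unique_b Unique-tag counts of the two libraries.
#' @param common Number of tags present in both.
#' @return Percentage of the union of the two tag sets.
#' @examples
#' common_unique_fraction(4270792, 3930801, 1117707)  # 15.78
#' @export
common_unique_fraction <- function(unique_a, unique_b, common) {
  if (common > min(unique_a, unique_b))
    stop("common exceeds one of the set sizes", call. = FALSE)
  100 * common / (unique_a + unique_b - common)
}
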