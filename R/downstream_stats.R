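# Post-target statistics: hypergeometric GO enrichment and Livak 2^-ddCt
# relative expression, plus miRNA-target anticorrelation summaries.

#' Hypergeometric GO-term enrichment of a target gene set
#'
#' For each term, computes the upper-tail hypergeometric probability of
#' observing at least `k` annotated genes among the `n` targets, given `K`
#' annotated genes in the background of size `N`. Terms at `p <= alpha` are
#' flagged enriched; a Benjamini-Hochberg column is added for reference but
#' the raw threshold makes the call.
#'
#' @param target_ids Character vector of target gene ids (must be a subset
#'   of the background).
#' @param background_ids Character vector of background gene ids.
#' @param term_map Named list mapping gene id -> character vector of term
#'   ids, or a data frame with columns `gene` and `term`.
#' @param alpha Enrichment threshold on the raw p-value (default 0.05).
#' @return Data frame with columns `term`, `k`, `n`, `K`, `N`, `p`, `padj`,
#'   `enriched`, sorted by `p`.
#' @export
hypergeom_enrichment <- function(target_ids, background_ids, term_map,
                                 alpha = 0.05) {
  target_ids <- unique(target_ids)
  background_ids <- unique(background_ids)
  missing <- setdiff(target_ids, background_ids)
  if (length(missing))
    stop("target gene not in background: ", missing[1L], call. = FALSE)
  if (is.data.frame(term_map)) {
    term_map <- split(term_map$term, term_map$gene)
  }
  term_map <- term_map[intersect(names(term_map), background_ids)]
  gene_of_term <- split(rep(names(term_map), lengths(term_map)),
                        unlist(term_map, use.names = FALSE))
  N <- length(background_ids)
  n <- length(target_ids)
  res <- lapply(names(gene_of_term), function(term) {
    genes <- unique(gene_of_term[[term]])
    K <- length(genes)
    k <- length(intersect(genes, target_ids))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      padj = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  out$padj <- p.adjust(out$p, method = "BH")
  out$enriched <- out$p <= alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Livak 2^-ddCt relative expression
#'
#' Replicate Ct values are averaged per sample, then
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt_sample - dCt_calibrator`
#' and relative expression `2^-ddCt`; the calibrator sample is 1 by
#' construction.
#'
#' @param records Data frame with columns `sample`, `ct_target`, `ct_ref`
#'   (one row per replicate measurement).
#' @param calibrator Name of the calibrator sample.
#' @return Data frame with columns `sample`, `dct`, `ddct`, `rel_expr`.
#' @examples
#' livak_relative_expression(
#'   data.frame(sample = c("PA2", "PA2H"), ct_target = c(24, 22),
#'              ct_ref = c(18, 18)), calibrator = "PA2")
#' @export
livak_relative_expression <- function(records, calibrator) {
  stopifnot(all(c("sample", "ct_target", "ct_ref") %in% names(records)))
  samples <- unique(records$sample)
  if (!calibrator %in% samples)
    stop("calibrator sample not found: ", calibrator, call. = FALSE)
  dct <- vapply(samples, function(s) {
    r <- records[records$sample == s, ]
    mean(r$ct_target) - mean(r$ct_ref)
  }, numeric(1L))
  ddct <- dct - dct[[calibrator]]
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct),
             rel_expr = unname(2^(-ddct)), stringsAsFactors = FALSE)
}

#' miRNA-target expression trend concordance
#'
#' For each miRNA-target pair, the sign of the Spearman rank correlation
#' between matched relative-expression vectors over the same samples;
#' `|rho| < 0.3` (or a constant vector) is reported as `flat`.
#'
#' @param pairs Data frame with columns `mirna` and `target`.
#' @param mirna_expr,target_expr Named lists (by miRNA / target id) of
#'   numeric expression vectors over identical sample orderings.
#' @return Data frame with columns `mirna`, `target`, `rho`, `trend`
#'   (`negative`, `positive` or `flat`).
#' @export
anticorrelation_summary <- function(pairs, mirna_expr, target_expr) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    m <- mirna_expr[[pairs$mirna[i]]]
    t <- target_expr[[pairs$target[i]]]
    stopifnot(length(m) == length(t))
    rho <- suppressWarnings(cor(m, t, method = "spearman"))
    trend <- if (is.na(rho) || abs(rho) < 0.3) "flat"
    else if (rho < 0) "negative" else "positive"
    data.frame(mirna = pairs$mirna[i], target = pairs$target[i],
               rho = ifelse(is.na(rho), 0, rho), trend = trend,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
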