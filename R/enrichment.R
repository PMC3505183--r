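# Term enrichment of a DE gene set against an expressed-gene background:
# chi-square on the 2x2 table, Fisher exact fallback when expected counts are
# small, Benjamini step-up correction across terms.

#' Expected counts of a 2x2 contingency table
#'
#' `E[i, j] = row_i * col_j / total`, the independence expectation used to
#' decide between the chi-square approximation and the Fisher exact test.
#'
#' @param table 2x2 matrix of non-negative counts with positive total.
#' @return 2x2 matrix of expected values; `sum(expected) == sum(observed)`.
#' @export
expected_counts <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  n <- sum(table)
  if (n <= 0) stop("table total must be positive")
  outer(rowSums(table), colSums(table)) / n
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Point-probability method: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table (with the usual `1 + 1e-7` relative slack on the
#' comparison).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  m <- sum(table[1L, ])        # size of group 1 (e.g. DE genes)
  n <- sum(table[2L, ])        # size of group 2
  k <- sum(table[, 1L])        # column-1 margin (e.g. genes in the term)
  if (m + n == 0) stop("table total must be positive")
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- seq.int(max(0L, k - n), min(m, k))
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(table[1L, 1L], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Term enrichment by chi-square with Fisher fallback
#'
#' For every term with at least one background gene, forms the 2x2 table
#' `a` = DE genes in the term, `b` = DE genes outside it, `c` = non-DE
#' background genes in the term, `d` = the rest. The p-value is a 1-df
#' chi-square without continuity correction unless any expected cell count is
#' below 5, in which case the two-sided Fisher exact test is used. Benjamini
#' step-up q-values are computed across all tested terms.
#'
#' @param de_genes character vector of differentially expressed genes; must be
#'   a subset of `background`.
#' @param background character vector of background genes (all genes detected
#'   in the relevant libraries, not the full reference set).
#' @param annotation an `AnnotationMap` (data.frame `gene_id`, `term`);
#'   annotations outside the background are ignored.
#' @return data.frame of class `EnrichmentResult` with columns `term`, `a`,
#'   `b`, `c`, `d`, `method` (`chi_square` or `fisher_exact`), `p_value`,
#'   `benjamini_q`, sorted by `benjamini_q` then `p_value`.
#' @export
enrich_terms <- function(de_genes, background, annotation) {
  background <- unique(background)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% background))
    stop("de_genes must be a subset of background")
  if (length(background) < 2L) stop("background must contain >= 2 genes")
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  terms <- split(ann$gene_id, ann$term)
  n_de <- length(de_genes)
  n_bg <- length(background)
  rows <- lapply(names(terms), function(tm) {
    g <- unique(terms[[tm]])
    a <- sum(g %in% de_genes)
    b <- n_de - a
    c_ <- length(g) - a
    d <- n_bg - n_de - c_
    tab <- matrix(c(a, c_, b, d), nrow = 2L)
    ex <- expected_counts(tab)
    if (any(ex < 5)) {
      method <- "fisher_exact"
      p <- fisher_exact_2x2(tab)
    } else {
      method <- "chi_square"
      p <- if (all(tab[1L, ] / sum(tab[1L, ]) == tab[2L, ] / sum(tab[2L, ]))) 1
        else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    data.frame(term = tm, a = a, b = b, c = c_, d = d, method = method,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(term = character(0), a = integer(0), b = integer(0),
                    c = integer(0), d = integer(0), method = character(0),
                    p_value = numeric(0), stringsAsFactors = FALSE)
  out$benjamini_q <- benjamini_hochberg(out$p_value)
  out <- out[order(out$benjamini_q, out$p_value, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
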