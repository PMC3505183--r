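# TPM quantification, detection calls, correlation and saturation QC.

#' Normalize counts to transcripts per million clean tags
#'
#' TPM = count x 1e6 / total clean tags of the library. The denominator is
#' the library's total clean tags (not only mapped tags). Genes with count 0
#' are floored at TPM = 0.01 so ratios against undetected genes are defined.
#'
#' @param counts named numeric vector of unambiguous tag counts per gene.
#' @param total_clean total clean tags of the library (> 0).
#' @return Named numeric vector of TPM values.
#' @examples
#' tpm_normalize(c(g1 = 1, g2 = 0), total_clean = 3759150)
#' @export
tpm_normalize <- function(counts, total_clean) {
  stopifnot(is.numeric(counts), length(total_clean) == 1L)
  if (!is.finite(total_clean) || total_clean <= 0)
    stop("total_clean must be positive")
  tpm <- counts * 1e6 / total_clean
  tpm[counts == 0] <- 0.01
  tpm
}

#' Format a TPM value the way expression tables print it
#'
#' Two decimal places.
#'
#' @param tpm numeric vector.
#' @return Character vector, e.g. `"0.27"`.
#' @export
format_tpm <- function(tpm) sprintf("%.2f", tpm)

#' Assemble a gene x library expression matrix
#'
#' @param gene_counts named list (library_id -> named vector of unambiguous
#'   tag counts per gene), e.g. the `gene_counts` elements returned by
#'   [classify_library()].
#' @param library_totals named numeric vector (library_id -> total clean
#'   tags).
#' @param genes gene universe for the rows; defaults to the union of genes
#'   observed across libraries. Genes absent from a library get count 0 and
#'   TPM 0.01.
#' @param stages optional named character vector (library_id -> stage label).
#' @return An `ExpressionMatrix`: list with `counts` and `tpm` (gene x
#'   library matrices), `library_totals` and `stages`.
#' @export
build_expression_matrix <- function(gene_counts, library_totals,
                                    genes = NULL, stages = NULL) {
  stopifnot(is.list(gene_counts), length(gene_counts) >= 1L,
            !is.null(names(gene_counts)),
            all(names(gene_counts) %in% names(library_totals)))
  libs <- names(gene_counts)
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(gene_counts, names))))
  counts <- matrix(0L, nrow = length(genes), ncol = length(libs),
                   dimnames = list(genes, libs))
  for (l in libs) {
    x <- gene_counts[[l]]
    x <- x[names(x) %in% genes]
    counts[names(x), l] <- as.integer(x)
  }
  tpm <- counts
  storage.mode(tpm) <- "double"
  for (l in libs) tpm[, l] <- tpm_normalize(counts[, l], library_totals[[l]])
  structure(list(counts = counts, tpm = tpm,
                 library_totals = library_totals[libs],
                 stages = stages),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "libraries\n")
  invisible(x)
}

#' Genes detected in exactly one library
#'
#' A gene is detected in a library when it has at least one unambiguous tag
#' (count > 0). Genes detected in zero or in two or more of the subset
#' libraries are excluded.
#'
#' @param em an `ExpressionMatrix`.
#' @param libraries libraries to compare (>= 2); default all.
#' @return Named character vector: gene_id -> the single library in which it
#'   was detected.
#' @export
detect_stage_specific <- function(em, libraries = colnames(em$counts)) {
  stopifnot(inherits(em, "ExpressionMatrix"), length(libraries) >= 2L,
            all(libraries %in% colnames(em$counts)))
  m <- em$counts[, libraries, drop = FALSE] > 0L
  one <- rowSums(m) == 1L
  hits <- m[one, , drop = FALSE]
  setNames(libraries[max.col(hits, ties.method = "first")], rownames(hits))
}

#' Pearson correlation of two libraries on log10 TPM
#'
#' Computed over genes detected (count > 0) in at least one of the two
#' libraries; the floored TPM (0.01) enters for a gene undetected in the
#' other library.
#'
#' @param em an `ExpressionMatrix`.
#' @param lib_a,lib_b library ids.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_correlation <- function(em, lib_a, lib_b) {
  stopifnot(inherits(em, "ExpressionMatrix"),
            all(c(lib_a, lib_b) %in% colnames(em$counts)))
  use <- em$counts[, lib_a] > 0L | em$counts[, lib_b] > 0L
  if (sum(use) < 3L) stop("fewer than 3 genes detected in the pair")
  cor(log10(em$tpm[use, lib_a]), log10(em$tpm[use, lib_b]),
      method = "pearson")
}

#' Sequencing saturation curve
#'
#' Subsamples the clean tag pool without replacement at each grid size (one
#' shared random permutation, so subsamples are nested and the curve is
#' non-decreasing) and counts genes detected by at least one unambiguous tag.
#'
#' @param lib a cleaned `TagLibrary`.
#' @param index a `TagIndex`.
#' @param grid subsample sizes (each <= total clean tags); default 10 equal
#'   steps up to the full library.
#' @param seed integer seed for the permutation.
#' @return data.frame with columns `size` and `genes_detected`.
#' @export
saturation_curve <- function(lib, index, grid = NULL, seed = 1L) {
  stopifnot(inherits(lib, "TagLibrary"), !is.null(lib$clean))
  total <- lib$totals$total_clean
  if (is.null(grid)) grid <- unique(ceiling(seq_len(10L) / 10 * total))
  grid <- sort(as.numeric(grid))
  if (any(grid < 1) || any(grid > total))
    stop("grid sizes must lie in [1, total_clean]")
  tags <- names(lib$clean)
  cl <- .classify_tags(tags, index)
  unamb <- cl$category == "UNAMBIGUOUS_GENE"
  gene_id <- rep.int(NA_character_, length(tags))
  gene_id[unamb] <- vapply(cl$gene_hits[unamb], `[`, character(1L), 1L)
  gene_f <- factor(gene_id)
  # Expand to one entry per tag copy (gene index or NA), permute once, then
  # read detection off the first occurrence position of each gene.
  pool <- rep.int(as.integer(gene_f), times = as.integer(lib$clean))
  pool <- with_seed(seed, sample(pool))
  first <- rep.int(NA_integer_, nlevels(gene_f))
  seen <- !duplicated(pool) & !is.na(pool)
  first[pool[seen]] <- which(seen)
  first <- first[!is.na(first)]
  detected <- vapply(grid, function(s) sum(first <= s), numeric(1L))
  data.frame(size = grid, genes_detected = as.integer(detected))
}
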