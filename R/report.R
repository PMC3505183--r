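# Report-surface helpers: library statistics text block, gene-family
# summaries, cross-species expansion percentages, simple QC plots.

#' Render library mapping statistics as a fixed-width text block
#'
#' One row per statistic (the standard DGE sequencing-statistics labels), one
#' `N` / `%` column pair per library.
#'
#' @param stats_list named list (library_id -> data.frame from
#'   [library_stats_table()] or [classify_library()]`$stats`).
#' @return Character vector of report lines.
#' @export
format_library_stats <- function(stats_list) {
  stopifnot(is.list(stats_list), length(stats_list) >= 1L)
  labels <- stats_list[[1L]]$statistic
  lines <- sprintf("%-42s", "Statistic")
  for (lib in names(stats_list))
    lines <- paste0(lines, sprintf("%12s %6s", lib, "%"))
  for (i in seq_along(labels)) {
    row <- sprintf("%-42s", labels[i])
    for (lib in names(stats_list)) {
      s <- stats_list[[lib]]
      pct <- if (is.na(s$pct[i])) "" else sprintf("%.1f", s$pct[i])
      row <- paste0(row, sprintf("%12d %6s", as.integer(s$n[i]), pct))
    }
    lines <- c(lines, row)
  }
  lines
}

#' Percent expansion of one gene-family count over another
#'
#' `100 * (a - b) / b`, rounded to the nearest integer with halves away from
#' zero — the convention used when comparing family sizes across species
#' (e.g. 71 CCEs vs 51 is a 39% expansion).
#'
#' @param a,b family counts (`b` is the comparison species).
#' @return Integer percentage.
#' @export
percent_expansion <- function(a, b) {
  stopifnot(all(b > 0))
  round_half_up(100 * (a - b) / b)
}

#' Tally genes per family or class
#'
#' Counts labels from a declared vocabulary (unknown labels are an error) and
#' optionally derives percent expansion against comparison totals from
#' another species.
#'
#' @param gene_families character vector of family/class labels, one per gene
#'   (names optional).
#' @param vocabulary allowed labels.
#' @param comparison_totals optional named numeric vector (family ->
#'   comparison count) for percent-expansion columns.
#' @return data.frame with columns `family`, `n` and, when comparison totals
#'   are given, `comparison_n` and `expansion_pct`; the attribute `total`
#'   holds `sum(n)`.
#' @export
summarize_family_counts <- function(gene_families,
                                    vocabulary = c("CCE", "P450", "GST"),
                                    comparison_totals = NULL) {
  bad <- setdiff(unique(gene_families), vocabulary)
  if (length(bad))
    stop("unknown family label(s): ", paste(bad, collapse = ", "))
  n <- vapply(vocabulary, function(v) sum(gene_families == v), numeric(1L))
  out <- data.frame(family = vocabulary, n = as.integer(n),
                    stringsAsFactors = FALSE)
  if (!is.null(comparison_totals)) {
    stopifnot(all(vocabulary %in% names(comparison_totals)))
    out$comparison_n <- as.integer(comparison_totals[vocabulary])
    out$expansion_pct <- percent_expansion(out$n, out$comparison_n)
  }
  attr(out, "total") <- sum(out$n)
  out
}

#' Cross-species detoxification family totals
#'
#' Reference totals of the three insect detoxification gene families
#' (carboxyl/cholinesterases, cytochrome P450 monooxygenases, cytosolic
#' glutathione S-transferases) in four dipteran genomes, with the number of
#' Culex quinquefasciatus members detected in DGE libraries. Used as worked
#' input for [summarize_family_counts()] and [percent_expansion()].
#'
#' @return data.frame with columns `family`, `d_melanogaster`, `a_gambiae`,
#'   `a_aegypti`, `c_quinquefasciatus`, `cqf_detected`.
#' @export
detox_family_counts <- function() {
  data.frame(
    family = c("CCE", "P450", "GST"),
    d_melanogaster = c(35L, 85L, 37L),
    a_gambiae = c(51L, 106L, 28L),
    a_aegypti = c(55L, 164L, 26L),
    c_quinquefasciatus = c(71L, 196L, 35L),
    cqf_detected = c(46L, 150L, 29L),
    stringsAsFactors = FALSE
  )
}

#' Quick QC plots
#'
#' Base-graphics views of the abundance distribution and saturation curve.
#'
#' @param ab data.frame from [abundance_distribution()].
#' @param ... passed to [graphics::barplot()] / [graphics::plot()].
#' @return Invisibly, the input.
#' @export
plot_abundance_distribution <- function(ab, ...) {
  m <- rbind(total = ab$total_tags / sum(ab$total_tags),
             distinct = ab$distinct_tags / sum(ab$distinct_tags))
  graphics::barplot(m, beside = TRUE, names.arg = ab$bin,
                    legend.text = c("total clean tags", "distinct clean tags"),
                    ylab = "fraction of library", xlab = "tag copy number",
                    ...)
  invisible(ab)
}

#' @rdname plot_abundance_distribution
#' @param sat data.frame from [saturation_curve()].
#' @export
plot_saturation <- function(sat, ...) {
  graphics::plot(sat$size, sat$genes_detected, type = "b",
                 xlab = "clean tags sampled", ylab = "genes detected", ...)
  invisible(sat)
}
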