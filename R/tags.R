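# Tag library container and raw-to-clean processing.

#' Construct a tag library
#'
#' A `TagLibrary` holds the raw tag -> count map of one sequencing library,
#' its metadata, and (after [extract_clean_tags()]) the clean tag -> count map
#' and summary totals.
#'
#' @param raw named numeric vector of non-negative integer counts; names are
#'   tag sequences.
#' @param library_id,stage,strain library metadata; `stage` is free text
#'   (conventionally one of egg/larva/pupa/adult/other).
#' @return An object of class `TagLibrary` with elements `library_id`,
#'   `stage`, `strain`, `raw`, `clean` (NULL until cleaned) and `totals`.
#' @export
tag_library <- function(raw, library_id = "lib1", stage = "other",
                        strain = "synthetic") {
  stopifnot(is.numeric(raw), !is.null(names(raw)), all(raw >= 0),
            all(raw == round(raw)), !anyDuplicated(names(raw)))
  raw <- setNames(as.integer(raw), names(raw))
  raw <- raw[order(names(raw))]
  structure(list(library_id = library_id, stage = stage, strain = strain,
                 raw = raw, clean = NULL,
                 totals = list(total_raw = sum(raw), total_clean = NA_integer_,
                               distinct_clean = NA_integer_)),
            class = "TagLibrary")
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary '%s' (stage %s, strain %s)\n", x$library_id,
              x$stage, x$strain))
  cat(sprintf("  Total raw tag      %d\n", x$totals$total_raw))
  if (!is.null(x$clean)) {
    cat(sprintf("  Total clean tag    %d\n", x$totals$total_clean))
    cat(sprintf("  Distinct clean tag %d\n", x$totals$distinct_clean))
  }
  invisible(x)
}

#' Filter a raw tag library to clean tags
#'
#' Applies the standard DGE cleaning rules, in order: (a) drop tags equal to
#' or prefixed by the adaptor sequence; (b) drop empty or whitespace tags;
#' (c) drop tags flagged low-quality; (d) drop malformed tags (length != 21,
#' not starting with CATG, or containing non-ACGT symbols); (e) finally drop
#' tags with a total copy number of 1. Totals are updated on the result.
#'
#' @param lib a `TagLibrary` with raw counts.
#' @param adaptor adaptor sequence; defaults to [dge_adaptor()].
#' @param quality_flags optional named logical vector (tag -> TRUE when the
#'   tag is low quality); tags absent from the vector are kept.
#' @return The `TagLibrary` with `clean` and `totals` filled. If nothing
#'   survives, the clean map is empty and a warning condition is signalled.
#' @export
extract_clean_tags <- function(lib, adaptor = dge_adaptor(),
                               quality_flags = NULL) {
  stopifnot(inherits(lib, "TagLibrary"))
  if (length(lib$raw) == 0L) stop("raw tag map is empty")
  tags <- names(lib$raw)
  keep <- !(startsWith(tags, adaptor) | tags == adaptor)
  keep <- keep & nzchar(trimws(tags))
  if (!is.null(quality_flags)) {
    low <- names(quality_flags)[as.logical(quality_flags)]
    keep <- keep & !(tags %in% low)
  }
  keep <- keep & is_valid_tag(tags)
  clean <- lib$raw[keep]
  clean <- clean[clean >= 2L]
  if (length(clean) == 0L)
    warning("no tags survived cleaning; clean library is empty")
  lib$clean <- clean
  lib$totals$total_clean <- sum(clean)
  lib$totals$distinct_clean <- length(clean)
  lib
}

#' Default tag-abundance bins
#'
#' Copy-number bins partitioning `[2, Inf)`, used to summarize how total and
#' distinct clean tags distribute over expression levels.
#'
#' @return A list of `c(lo, hi)` pairs (`hi` may be `Inf`).
#' @export
default_abundance_bins <- function() {
  list(c(2, 5), c(6, 10), c(11, 20), c(21, 50), c(51, 100), c(101, Inf))
}

#' Distribution of clean tags over abundance bins
#'
#' Assigns every distinct clean tag to exactly one copy-number bin and totals
#' tag copies and distinct tags per bin.
#'
#' @param lib a cleaned `TagLibrary`.
#' @param bins list of `c(lo, hi)` copy-number ranges; must partition
#'   `[2, Inf)` (sorted, contiguous, non-overlapping).
#' @return data.frame with columns `bin`, `lo`, `hi`, `total_tags`,
#'   `distinct_tags`; column sums reproduce the library totals.
#' @export
abundance_distribution <- function(lib, bins = default_abundance_bins()) {
  stopifnot(inherits(lib, "TagLibrary"), !is.null(lib$clean))
  lo <- vapply(bins, `[`, numeric(1L), 1L)
  hi <- vapply(bins, `[`, numeric(1L), 2L)
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  if (any(hi < lo) || lo[1L] != 2 || !is.infinite(hi[length(hi)]) ||
      (length(lo) > 1L && any(lo[-1L] != hi[-length(hi)] + 1)))
    stop("bins must partition [2, Inf) without overlap")
  counts <- lib$clean
  idx <- findInterval(counts, lo)
  total <- vapply(seq_along(lo), function(i) sum(counts[idx == i]), numeric(1L))
  distinct <- tabulate(idx, nbins = length(lo))
  lab <- ifelse(is.infinite(hi), paste0(">", lo - 1),
                paste0("[", lo, ",", hi, "]"))
  data.frame(bin = lab, lo = lo, hi = hi, total_tags = as.integer(total),
             distinct_tags = distinct, stringsAsFactors = FALSE)
}

#' Summary totals of a cleaned library
#'
#' @param lib a cleaned `TagLibrary`.
#' @return A list with `library_id`, `total_raw`, `total_clean`,
#'   `distinct_clean`.
#' @export
library_summary <- function(lib) {
  stopifnot(inherits(lib, "TagLibrary"), !is.null(lib$clean))
  list(library_id = lib$library_id,
       total_raw = lib$totals$total_raw,
       total_clean = lib$totals$total_clean,
       distinct_clean = lib$totals$distinct_clean)
}

#' Read / write tag count tables
#'
#' Tag libraries are serialized as 2-column tab-separated files
#' (tag sequence, count) with a header line.
#'
#' @param lib a `TagLibrary`; raw counts are written unless `what = "clean"`.
#' @param path file path.
#' @param what which map to write: `"raw"` or `"clean"`.
#' @return `write_tag_library()` returns `path` invisibly;
#'   `read_tag_library()` returns a `TagLibrary` with raw counts.
#' @export
write_tag_library <- function(lib, path, what = c("raw", "clean")) {
  what <- match.arg(what)
  x <- if (what == "raw") lib$raw else lib$clean
  stopifnot(!is.null(x))
  df <- data.frame(tag = names(x), count = as.integer(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_library
#' @param library_id,stage,strain metadata for the library read from `path`.
#' @export
read_tag_library <- function(path, library_id = basename(path),
                             stage = "other", strain = "synthetic") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2L)
  tag_library(setNames(as.integer(df[[2L]]), as.character(df[[1L]])),
              library_id = library_id, stage = stage, strain = strain)
}
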