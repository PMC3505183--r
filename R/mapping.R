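# CATG-anchored tag index and tag classification with at most one mismatch.

#' Build a tag index from a reference
#'
#' Indexes every complete CATG-anchored 21-mer window of every transcript
#' (sense strand) and of the genome (both strands; minus-strand windows are
#' stored as their tag-space sequence, which also starts with CATG).
#'
#' @param ref a `SyntheticReference`, or a list with elements `transcripts`
#'   (named character vector of gene sequences), `genome` (character scalar,
#'   may be `NULL`) and optionally `n_reference_genes`.
#' @return An object of class `TagIndex`: `gene_keys` / `gene_hits` (window
#'   sequences and, per window, the sorted set of gene ids), `genome_keys` /
#'   `genome_hits` (windows and `strand:position` labels), and
#'   `n_reference_genes` (denominator for the "tag-mapped genes" percentage).
#' @export
build_tag_index <- function(ref) {
  if (inherits(ref, "SyntheticReference")) {
    transcripts <- setNames(ref$genes$transcript, ref$genes$gene_id)
    genome <- ref$genome
    n_ref <- nrow(ref$genes)
  } else {
    stopifnot(is.list(ref), !is.null(ref$transcripts))
    transcripts <- ref$transcripts
    genome <- ref$genome
    n_ref <- if (!is.null(ref$n_reference_genes)) ref$n_reference_genes
      else length(transcripts)
  }
  if (length(transcripts) == 0L) stop("no transcripts to index")
  short <- nchar(transcripts) < .TAG_LEN
  if (any(short)) {
    warning(sum(short), " transcript(s) shorter than ", .TAG_LEN,
            " bases skipped")
    transcripts <- transcripts[!short]
  }
  win <- lapply(transcripts, tag_windows)
  gene_of <- rep(names(win), lengths(win))
  wseq <- unlist(win, use.names = FALSE)
  pairs <- unique(data.frame(w = wseq, g = gene_of, stringsAsFactors = FALSE))
  gene_hits <- lapply(split(pairs$g, pairs$w), function(g) sort(unique(g)))
  genome_keys <- character(0); genome_hits <- list()
  if (!is.null(genome) && nzchar(genome)) {
    gl <- nchar(genome)
    win_at <- function(s, p) {
      if (length(p) == 0L) character(0)
      else substring(s, p, p + .TAG_LEN - 1L)
    }
    pos_plus <- tag_window_starts(genome)
    rc <- revcomp(genome)
    pos_minus <- tag_window_starts(rc)
    gw <- c(win_at(genome, pos_plus), win_at(rc, pos_minus))
    glab <- c(sprintf("+:%d", pos_plus),
              sprintf("-:%d", gl - (pos_minus + .TAG_LEN - 1L) + 1L))
    genome_hits <- lapply(split(glab, gw), sort)
    genome_keys <- names(genome_hits)
  }
  structure(list(gene_keys = names(gene_hits), gene_hits = unname(gene_hits),
                 genome_keys = genome_keys, genome_hits = unname(genome_hits),
                 n_reference_genes = n_ref),
            class = "TagIndex")
}

#' @export
print.TagIndex <- function(x, ...) {
  cat("TagIndex:", length(x$gene_keys), "gene windows,",
      length(x$genome_keys), "genome windows,", x$n_reference_genes,
      "reference genes\n")
  invisible(x)
}

# All single-mismatch variants of each tag as an m x 51 character matrix.
# Positions 1-4 are skipped: both tags and index keys start with CATG, so a
# single mismatch between them can only sit at positions 5..21.
.tag_variants <- function(tags) {
  m <- length(tags)
  out <- matrix(character(0), nrow = m, ncol = 3L * (.TAG_LEN - 4L))
  col <- 0L
  for (pos in 5L:.TAG_LEN) {
    cur <- match(substr(tags, pos, pos), .BASES)
    pre <- substr(tags, 1L, pos - 1L)
    post <- substr(tags, pos + 1L, .TAG_LEN)
    for (k in 1L:3L) {
      col <- col + 1L
      out[, col] <- paste0(pre, .BASES[((cur - 1L + k) %% 4L) + 1L], post)
    }
  }
  out
}

# Match tags (and optionally their 1-mismatch variants) against keys, and
# return per-tag hit sets.  Returns list(exact = list or NULL per tag,
# mm = list or NULL per tag).
.match_tier <- function(tags, keys, hits, variants = NULL) {
  ex <- match(tags, keys)
  exact <- vector("list", length(tags))
  ok <- !is.na(ex)
  exact[ok] <- hits[ex[ok]]
  mm <- NULL
  if (!is.null(variants)) {
    m <- nrow(variants)
    vi <- match(variants, keys)          # column-major over m x 51
    hit <- !is.na(vi)
    mm <- vector("list", m)
    if (any(hit)) {
      tag_of <- rep.int(seq_len(m), ncol(variants))[hit]
      sets <- hits[vi[hit]]
      flat <- unlist(sets, use.names = FALSE)
      owner <- rep.int(tag_of, lengths(sets))
      grouped <- split(flat, owner)
      mm[as.integer(names(grouped))] <- lapply(grouped,
                                               function(g) sort(unique(g)))
    }
  }
  list(exact = exact, mm = mm)
}

# Vectorized classification of distinct tags. Returns a data.frame-like list:
# category, best_mismatch, gene_hits (list).
.classify_tags <- function(tags, index, max_mismatch = 1L) {
  m <- length(tags)
  category <- rep.int(NA_character_, m)
  best_mm <- rep.int(NA_integer_, m)
  gene_hits <- vector("list", m)

  g0 <- .match_tier(tags, index$gene_keys, index$gene_hits)$exact
  has_g0 <- !vapply(g0, is.null, logical(1L))
  gene_hits[has_g0] <- g0[has_g0]
  best_mm[has_g0] <- 0L

  need <- which(!has_g0)
  variants <- NULL
  if (max_mismatch >= 1L && length(need)) {
    variants <- .tag_variants(tags[need])
    g1 <- .match_tier(tags[need], index$gene_keys, index$gene_hits,
                      variants)$mm
    has_g1 <- !vapply(g1, is.null, logical(1L))
    gene_hits[need[has_g1]] <- g1[has_g1]
    best_mm[need[has_g1]] <- 1L
    need <- need[!has_g1]
    variants <- variants[!has_g1, , drop = FALSE]
  }

  has_gene <- !vapply(gene_hits, is.null, logical(1L))
  ng <- lengths(gene_hits)
  category[has_gene & ng == 1L] <- "UNAMBIGUOUS_GENE"
  category[has_gene & ng >= 2L] <- "AMBIGUOUS_GENE"

  if (length(need) && length(index$genome_keys)) {
    e <- .match_tier(tags[need], index$genome_keys, index$genome_hits)$exact
    has_e <- !vapply(e, is.null, logical(1L))
    category[need[has_e]] <- "GENOME_ONLY"
    best_mm[need[has_e]] <- 0L
    rest <- need[!has_e]
    if (max_mismatch >= 1L && length(rest)) {
      v <- variants[!has_e, , drop = FALSE]
      g1 <- .match_tier(tags[rest], index$genome_keys, index$genome_hits,
                        v)$mm
      has_1 <- !vapply(g1, is.null, logical(1L))
      category[rest[has_1]] <- "GENOME_ONLY"
      best_mm[rest[has_1]] <- 1L
    }
  }
  category[is.na(category)] <- "UNKNOWN"
  list(category = category, best_mismatch = best_mm, gene_hits = gene_hits)
}

#' Classify a single tag against the index
#'
#' Gene hits take precedence over genome-only hits, and within each target an
#' exact hit takes precedence over a 1-mismatch hit (`best_mismatch` records
#' the tier used; the mismatch tier is an error model, not an arbitrator, so
#' an ambiguous exact gene hit beats a unique 1-mismatch hit).
#'
#' @param tag a 21-base CATG-anchored tag sequence.
#' @param index a `TagIndex`.
#' @param max_mismatch 0 or 1.
#' @return A `TagAnnotation` list: `tag`, `category` (one of
#'   `UNAMBIGUOUS_GENE`, `AMBIGUOUS_GENE`, `GENOME_ONLY`, `UNKNOWN`),
#'   `gene_hits` (character vector) and `best_mismatch` (0, 1, or NA for
#'   unknown tags).
#' @export
map_tag <- function(tag, index, max_mismatch = 1L) {
  stopifnot(inherits(index, "TagIndex"), length(tag) == 1L,
            max_mismatch %in% c(0L, 1L))
  if (!is_valid_tag(tag)) stop("malformed tag: ", tag)
  r <- .classify_tags(tag, index, max_mismatch)
  structure(list(tag = tag, category = r$category[1L],
                 gene_hits = if (is.null(r$gene_hits[[1L]])) character(0)
                             else r$gene_hits[[1L]],
                 best_mismatch = r$best_mismatch[1L]),
            class = "TagAnnotation")
}

#' Table-2-style library mapping statistics
#'
#' Assembles the standard DGE mapping report from raw counts. Percentages use
#' the conventional denominators: distinct clean tags for the distinct-tag
#' rows, total clean tags for the total-unknown row, and the number of
#' reference genes for the tag-mapped-genes row; all are printed with one
#' decimal, halves rounded away from zero.
#'
#' @param total_raw,total_clean,distinct_clean library totals.
#' @param distinct_gene distinct tags mapping to >= 1 gene (ambiguous or not).
#' @param distinct_unambiguous distinct tags mapping to exactly one gene.
#' @param genes_mapped number of genes hit by unambiguous tags.
#' @param n_reference_genes size of the reference gene set.
#' @param distinct_genome_only distinct tags mapping only to the genome.
#' @param total_unknown,distinct_unknown unmapped tag copies / distinct tags.
#' @return data.frame with columns `statistic`, `n`, `pct` (NA where the
#'   report prints no percentage).
#' @export
library_stats_table <- function(total_raw, total_clean, distinct_clean,
                                distinct_gene, distinct_unambiguous,
                                genes_mapped, n_reference_genes,
                                distinct_genome_only, total_unknown,
                                distinct_unknown) {
  data.frame(
    statistic = c("Total raw tag", "Total clean tag", "Distinct clean tag",
                  "Distinct tag mapping to gene",
                  "Distinct unambiguous tag mapping to gene",
                  "Unambiguous tag-mapped genes",
                  "Distinct tag mapping to genome",
                  "Total unknown tag", "Distinct unknown tag"),
    n = c(total_raw, total_clean, distinct_clean, distinct_gene,
          distinct_unambiguous, genes_mapped, distinct_genome_only,
          total_unknown, distinct_unknown),
    pct = c(NA, NA, NA,
            pct1(distinct_gene, distinct_clean),
            pct1(distinct_unambiguous, distinct_clean),
            pct1(genes_mapped, n_reference_genes),
            pct1(distinct_genome_only, distinct_clean),
            pct1(total_unknown, total_clean),
            pct1(distinct_unknown, distinct_clean)),
    stringsAsFactors = FALSE
  )
}

#' Classify every distinct clean tag of a library
#'
#' Maps all distinct clean tags with [map_tag()] semantics (vectorized),
#' tallies the Table-2-style mapping statistics, and sums the counts of
#' unambiguous tags per gene.
#'
#' @param lib a cleaned `TagLibrary`.
#' @param index a `TagIndex`.
#' @param max_mismatch 0 or 1.
#' @return A list with `stats` (see [library_stats_table()]), `gene_counts`
#'   (named integer vector of unambiguous tag counts per gene) and
#'   `annotations` (data.frame: tag, count, category, best_mismatch, gene).
#' @export
classify_library <- function(lib, index, max_mismatch = 1L) {
  stopifnot(inherits(lib, "TagLibrary"), !is.null(lib$clean),
            inherits(index, "TagIndex"))
  tags <- names(lib$clean)
  counts <- as.integer(lib$clean)
  cl <- .classify_tags(tags, index, max_mismatch)
  unamb <- cl$category == "UNAMBIGUOUS_GENE"
  gene <- rep.int(NA_character_, length(tags))
  gene[unamb] <- vapply(cl$gene_hits[unamb], `[`, character(1L), 1L)
  gene_counts <- integer(0)
  if (any(unamb)) {
    s <- rowsum(as.numeric(counts[unamb]), group = gene[unamb], reorder = TRUE)
    gene_counts <- setNames(as.integer(s[, 1L]), rownames(s))
  }
  is_unknown <- cl$category == "UNKNOWN"
  stats <- library_stats_table(
    total_raw = lib$totals$total_raw,
    total_clean = lib$totals$total_clean,
    distinct_clean = lib$totals$distinct_clean,
    distinct_gene = sum(cl$category %in% c("UNAMBIGUOUS_GENE",
                                           "AMBIGUOUS_GENE")),
    distinct_unambiguous = sum(unamb),
    genes_mapped = length(gene_counts),
    n_reference_genes = index$n_reference_genes,
    distinct_genome_only = sum(cl$category == "GENOME_ONLY"),
    total_unknown = sum(counts[is_unknown]),
    distinct_unknown = sum(is_unknown)
  )
  list(stats = stats,
       gene_counts = gene_counts,
       annotations = data.frame(tag = tags, count = counts,
                                category = cl$category,
                                best_mismatch = cl$best_mismatch,
                                gene = gene, stringsAsFactors = FALSE))
}
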