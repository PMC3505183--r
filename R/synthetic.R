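# Synthetic data generation: toy references, expression profiles, tag
# libraries, annotations and protein alignments with known ground truth.

#' Generate a synthetic transcript + genome reference
#'
#' Creates `n_genes` random transcripts, each guaranteed to carry at least one
#' complete CATG-anchored 21-mer tag window (the generator overwrites four
#' bases near the 3' end with `CATG` when no window arises by chance), and a
#' toy genome built as `spacer | gene 1 | spacer | ... | gene n | spacer`.
#' Spacers are random sequence and may themselves contain CATG windows, so
#' genome-only tag classifications are exercised downstream.
#'
#' The canonical tag of a gene is the 21-mer starting at the 3'-most CATG that
#' has at least 17 bases after the anchor; all upstream windows remain valid
#' gene tags for the index built by [build_tag_index()].
#'
#' @param n_genes number of genes (>= 1).
#' @param length_range integer vector `c(min, max)` of transcript lengths in
#'   bases; `min` must be >= 25 so a CATG + 17 window always fits.
#' @param spacer length in bases of the random spacer placed before, between
#'   and after genes on the genome.
#' @param seed integer seed; output is bit-reproducible for a fixed seed.
#' @return An object of class `SyntheticReference`: a list with `genes`
#'   (data.frame: `gene_id`, `transcript`, `canonical_tag`, `tagless`),
#'   `genome` (character scalar) and `coordinates` (data.frame: `gene_id`,
#'   `start`, `end`, 0-based half-open on the genome).
#' @examples
#' ref <- generate_reference(5, c(100, 150), spacer = 30, seed = 1)
#' ref$genes$canonical_tag
#' @export
generate_reference <- function(n_genes, length_range = c(200L, 400L),
                               spacer = 50L, seed = 1L) {
  stopifnot(n_genes >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L], spacer >= 0L)
  if (length_range[1L] < 25L)
    stop("length_range too small to host a CATG + 17 base tag window")
  with_seed(seed, {
    lens <- if (length_range[1L] == length_range[2L]) {
      rep.int(as.integer(length_range[1L]), n_genes)
    } else {
      sample(seq.int(length_range[1L], length_range[2L]), n_genes,
             replace = TRUE)
    }
    tx <- random_dna(n_genes, max(lens))
    tx <- substring(tx, 1L, lens)
    # Guarantee a tag window: overwrite so CATG + 17 ends flush at the 3' end.
    fix <- vapply(tx, function(s) length(tag_window_starts(s)) == 0L,
                  logical(1L), USE.NAMES = FALSE)
    if (any(fix)) {
      p <- lens[fix] - .TAG_LEN + 1L
      tx[fix] <- mapply(function(s, pos) {
        substr(s, pos, pos + 3L) <- .TAG_ANCHOR
        s
      }, tx[fix], p, USE.NAMES = FALSE)
    }
    canonical <- vapply(tx, function(s) {
      p <- max(tag_window_starts(s))
      substr(s, p, p + .TAG_LEN - 1L)
    }, character(1L), USE.NAMES = FALSE)
    gene_id <- sprintf("G%04d", seq_len(n_genes))
    spacers <- random_dna(n_genes + 1L, max(spacer, 1L))
    if (spacer == 0L) spacers <- rep.int("", n_genes + 1L)
    pieces <- character(2L * n_genes + 1L)
    pieces[seq(1L, by = 2L, length.out = n_genes + 1L)] <- spacers
    pieces[seq(2L, by = 2L, length.out = n_genes)] <- tx
    genome <- paste0(pieces, collapse = "")
    start <- spacer + c(0L, cumsum(lens + spacer))[seq_len(n_genes)]
    ref <- list(
      genes = data.frame(gene_id = gene_id, transcript = tx,
                         canonical_tag = canonical, tagless = FALSE,
                         stringsAsFactors = FALSE),
      genome = genome,
      coordinates = data.frame(gene_id = gene_id, start = start,
                               end = start + lens, stringsAsFactors = FALSE)
    )
    class(ref) <- "SyntheticReference"
    ref
  })
}

#' @export
print.SyntheticReference <- function(x, ...) {
  cat("SyntheticReference:", nrow(x$genes), "genes; genome of",
      nchar(x$genome), "bases\n")
  invisible(x)
}

#' Construct an expression profile
#'
#' @param abundance named non-negative numeric vector of relative abundances
#'   (gene_id -> weight); normalized to sum to 1.
#' @param de_truth optional named vector of true fold changes between two
#'   conditions (1 = null); defaults to 1 for every gene.
#' @return An object of class `ExpressionProfile` with elements `abundance`
#'   and `de_truth`.
#' @export
make_profile <- function(abundance, de_truth = NULL) {
  stopifnot(is.numeric(abundance), !is.null(names(abundance)),
            all(nzchar(names(abundance))), !anyDuplicated(names(abundance)),
            all(abundance >= 0), sum(abundance) > 0)
  abundance <- abundance / sum(abundance)
  if (is.null(de_truth)) {
    de_truth <- setNames(rep.int(1, length(abundance)), names(abundance))
  } else {
    stopifnot(identical(sort(names(de_truth)), sort(names(abundance))),
              all(de_truth > 0))
    de_truth <- de_truth[names(abundance)]
  }
  structure(list(abundance = abundance, de_truth = de_truth),
            class = "ExpressionProfile")
}

#' Uniform expression profile over the genes of a reference
#'
#' @param ref a `SyntheticReference` (or character vector of gene ids).
#' @return An `ExpressionProfile` with equal abundance on every gene.
#' @export
uniform_profile <- function(ref) {
  ids <- if (inherits(ref, "SyntheticReference")) ref$genes$gene_id else ref
  make_profile(setNames(rep.int(1, length(ids)), ids))
}

#' Log-normal expression profile
#'
#' Draws per-gene abundances from a log-normal distribution, the usual
#' heavy-tailed shape of transcript abundance in bulk libraries (a few very
#' highly expressed genes, many rare ones).
#'
#' @inheritParams uniform_profile
#' @param sdlog log-scale standard deviation of the abundance distribution.
#' @param seed integer seed.
#' @return An `ExpressionProfile`.
#' @export
lognormal_profile <- function(ref, sdlog = 1.5, seed = 1L) {
  ids <- if (inherits(ref, "SyntheticReference")) ref$genes$gene_id else ref
  with_seed(seed, make_profile(setNames(rlnorm(length(ids), 0, sdlog), ids)))
}

#' Spike true fold changes into a profile
#'
#' Produces a pair of condition profiles (A, B) in which exactly `n_de` genes
#' differ by a fold change drawn uniformly from `fold_range`, with the
#' direction (up or down in B) randomized per gene; all other genes are null.
#' Both profiles are renormalized to sum to 1, so realized expression ratios
#' of null genes absorb a small common composition factor.
#'
#' @param profile an `ExpressionProfile` (condition A).
#' @param n_de number of genes to perturb (<= number of genes).
#' @param fold_range numeric `c(lo, hi)` with `lo > 1`.
#' @param seed integer seed.
#' @return A list with elements `a` and `b`, both `ExpressionProfile`s whose
#'   `de_truth` records the true B/A fold change per gene.
#' @export
spike_differential <- function(profile, n_de, fold_range = c(2, 10),
                               seed = 1L) {
  stopifnot(inherits(profile, "ExpressionProfile"),
            n_de >= 0L, n_de <= length(profile$abundance),
            length(fold_range) == 2L, fold_range[1L] > 1,
            fold_range[1L] <= fold_range[2L])
  with_seed(seed, {
    ids <- names(profile$abundance)
    truth <- setNames(rep.int(1, length(ids)), ids)
    if (n_de > 0L) {
      pick <- sample(ids, n_de)
      fold <- runif(n_de, fold_range[1L], fold_range[2L])
      dir <- sample(c(1, -1), n_de, replace = TRUE)
      truth[pick] <- fold^dir
    }
    a <- make_profile(profile$abundance, de_truth = truth)
    b <- make_profile(profile$abundance * truth, de_truth = truth)
    list(a = a, b = b)
  })
}

# Flip `k[i]` random positions of tags[i] to a different base. Positions 1..21
# are all eligible (errors may destroy the CATG anchor, as on a sequencer).
mutate_tags <- function(tags, k) {
  n <- length(tags)
  if (n == 0L) return(character(0))
  mat <- vapply(seq_len(.TAG_LEN), function(j) substr(tags, j, j),
                character(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1L)
  rows <- integer(0); cols <- integer(0)
  one <- which(k == 1L)
  if (length(one)) {
    rows <- one
    cols <- sample.int(.TAG_LEN, length(one), replace = TRUE)
  }
  multi <- which(k >= 2L)
  for (i in multi) {
    pos <- sample.int(.TAG_LEN, k[i])
    rows <- c(rows, rep.int(i, k[i]))
    cols <- c(cols, pos)
  }
  li <- (cols - 1L) * n + rows
  cur <- match(mat[li], .BASES)
  mat[li] <- .BASES[((cur - 1L + sample.int(3L, length(li), replace = TRUE)) %% 4L) + 1L]
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Simulate a raw DGE tag library
#'
#' Draws `depth` raw tags. Each tag is, mutually exclusively, (i) a copy of a
#' gene's canonical tag drawn multinomially with the profile's abundances,
#' with every base independently flipped with probability `error_rate`;
#' (ii) the fixed adaptor sequence ([dge_adaptor()]), with probability
#' `adaptor_rate`; or (iii) a unique random CATG-anchored 21-mer (singleton
#' noise), with probability `singleton_rate`. The sum of raw counts equals
#' `depth` exactly.
#'
#' @param ref a `SyntheticReference`.
#' @param profile an `ExpressionProfile` over (a subset of) the reference
#'   genes; unknown gene ids are an error.
#' @param depth total number of raw tags (default emulates a 3.5-million-tag
#'   library).
#' @param error_rate per-base sequencing error probability.
#' @param adaptor_rate fraction of tags replaced by the adaptor sequence.
#' @param singleton_rate fraction of tags replaced by unique random 21-mers.
#' @param seed integer seed.
#' @param library_id,stage,strain library metadata carried on the result.
#' @return A `TagLibrary` (see [tag_library()]) with `raw` counts filled and
#'   `clean` unset.
#' @export
simulate_library <- function(ref, profile, depth = 3.5e6,
                             error_rate = 0.005, adaptor_rate = 0.005,
                             singleton_rate = 0.02, seed = 1L,
                             library_id = "lib1", stage = "other",
                             strain = "synthetic") {
  stopifnot(inherits(ref, "SyntheticReference"),
            inherits(profile, "ExpressionProfile"), depth >= 1)
  rates <- c(error_rate, adaptor_rate, singleton_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  unknown <- setdiff(names(profile$abundance), ref$genes$gene_id)
  if (length(unknown))
    stop("profile references unknown gene_id(s): ",
         paste(head(unknown, 3L), collapse = ", "))
  gidx <- match(names(profile$abundance), ref$genes$gene_id)
  w <- profile$abundance
  tagless <- ref$genes$tagless[gidx]
  w[tagless] <- 0
  if (sum(w) == 0) stop("no tagged gene has positive abundance")
  with_seed(seed, {
    p_cat <- c(max(0, 1 - adaptor_rate - singleton_rate),
               adaptor_rate, singleton_rate)
    n_cat <- drop(rmultinom(1L, size = depth, prob = p_cat))
    parts <- list()
    if (n_cat[1L] > 0L) {
      gene_counts <- drop(rmultinom(1L, size = n_cat[1L], prob = w))
      canonical <- ref$genes$canonical_tag[gidx]
      copy_gene <- rep.int(seq_along(gene_counts), gene_counts)
      flips <- rbinom(length(copy_gene), .TAG_LEN, error_rate)
      intact <- tabulate(copy_gene[flips == 0L], nbins = length(gene_counts))
      parts$intact <- setNames(intact, canonical)
      err <- which(flips > 0L)
      if (length(err)) {
        mut <- mutate_tags(canonical[copy_gene[err]], flips[err])
        tb <- table(mut)
        parts$errors <- setNames(as.integer(tb), names(tb))
      }
    }
    if (n_cat[2L] > 0L)
      parts$adaptor <- setNames(n_cat[2L], .DGE_ADAPTOR)
    if (n_cat[3L] > 0L) {
      s <- paste0(.TAG_ANCHOR, random_dna(n_cat[3L], .TAG_LEN - 4L))
      while (anyDuplicated(s)) {
        d <- which(duplicated(s))
        s[d] <- paste0(.TAG_ANCHOR, random_dna(length(d), .TAG_LEN - 4L))
      }
      parts$singletons <- setNames(rep.int(1L, n_cat[3L]), s)
    }
    raw <- sum_by_name(unlist(unname(parts)))
    raw <- raw[raw > 0L]
    tag_library(raw, library_id = library_id, stage = stage, strain = strain)
  })
}

#' Generate a gene-to-term annotation table
#'
#' Assigns random gene sets of sizes drawn from `term_size_range` to
#' `n_terms` flat terms. If `enriched_term` is supplied, that term annotates
#' exactly the listed genes (useful as enrichment ground truth).
#'
#' @param ref a `SyntheticReference` or character vector of gene ids.
#' @param n_terms number of random terms.
#' @param term_size_range integer `c(min, max)` genes per term; `max` must not
#'   exceed the number of genes.
#' @param enriched_term optional `list(term = <id>, genes = <character>)`.
#' @param seed integer seed.
#' @return An `AnnotationMap`: a data.frame with columns `gene_id` and `term`.
#' @export
generate_annotation <- function(ref, n_terms, term_size_range = c(5L, 20L),
                                enriched_term = NULL, seed = 1L) {
  ids <- if (inherits(ref, "SyntheticReference")) ref$genes$gene_id else ref
  stopifnot(n_terms >= 0L, term_size_range[1L] >= 1L,
            term_size_range[2L] <= length(ids))
  with_seed(seed, {
    out <- list()
    if (n_terms > 0L) {
      sizes <- sample(seq.int(term_size_range[1L], term_size_range[2L]),
                      n_terms, replace = TRUE)
      out <- lapply(seq_len(n_terms), function(i) {
        data.frame(gene_id = sample(ids, sizes[i]),
                   term = sprintf("T%03d", i), stringsAsFactors = FALSE)
      })
    }
    if (!is.null(enriched_term)) {
      stopifnot(is.list(enriched_term), all(enriched_term$genes %in% ids))
      out <- c(out, list(data.frame(gene_id = enriched_term$genes,
                                    term = enriched_term$term,
                                    stringsAsFactors = FALSE)))
    }
    ann <- if (length(out)) do.call(rbind, out)
      else data.frame(gene_id = character(0), term = character(0),
                      stringsAsFactors = FALSE)
    annotation_map(ann)
  })
}

#' Construct an annotation map from a gene/term table
#'
#' @param x data.frame with columns `gene_id` and `term`.
#' @return The table, deduplicated, with class `AnnotationMap`.
#' @export
annotation_map <- function(x) {
  stopifnot(is.data.frame(x), all(c("gene_id", "term") %in% names(x)))
  x <- unique(x[, c("gene_id", "term")])
  rownames(x) <- NULL
  class(x) <- c("AnnotationMap", "data.frame")
  x
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# Substitute each residue with probability p to a different amino acid.
.mutate_aa <- function(seq, p) {
  hit <- runif(length(seq)) < p
  n <- sum(hit)
  if (n) {
    cur <- match(seq[hit], .AA)
    seq[hit] <- .AA[((cur - 1L + sample.int(19L, n, replace = TRUE)) %% 20L) + 1L]
  }
  seq
}

#' Generate a synthetic protein alignment
#'
#' Simulates equal-length amino-acid rows. Without a guide tree, every taxon
#' derives independently from one random ancestral sequence with per-site
#' substitution probability `mutation_rate`. With a guide tree (an `ape`
#' `phylo` with branch lengths), substitutions accumulate along branches with
#' per-site probability `min(1, mutation_rate * branch_length)`. Gaps are then
#' laid down independently per cell with probability `gap_rate`.
#'
#' @param n_taxa number of taxa (>= 3); must equal the number of tips when a
#'   guide tree is supplied.
#' @param length alignment columns.
#' @param mutation_rate per-site substitution probability (per branch-length
#'   unit when a guide tree is used).
#' @param gap_rate per-cell gap probability.
#' @param guide_tree optional `phylo` object.
#' @param seed integer seed.
#' @return A `ProteinAlignment` (character matrix, taxa in rows).
#' @export
generate_alignment <- function(n_taxa, length = 200L, mutation_rate = 0.05,
                               gap_rate = 0.02, guide_tree = NULL, seed = 1L) {
  stopifnot(n_taxa >= 3L, length >= 1L,
            mutation_rate >= 0, gap_rate >= 0, gap_rate <= 1)
  with_seed(seed, {
    root <- sample(.AA, length, replace = TRUE)
    if (is.null(guide_tree)) {
      rows <- lapply(seq_len(n_taxa), function(i) .mutate_aa(root, mutation_rate))
      labels <- sprintf("t%d", seq_len(n_taxa))
    } else {
      stopifnot(inherits(guide_tree, "phylo"),
                ape::Ntip(guide_tree) == n_taxa,
                !is.null(guide_tree$edge.length))
      tr <- ape::reorder.phylo(guide_tree, "cladewise")
      nnode <- ape::Ntip(tr) + tr$Nnode
      seqs <- vector("list", nnode)
      seqs[[ape::Ntip(tr) + 1L]] <- root
      for (e in seq_len(nrow(tr$edge))) {
        par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
        p <- min(1, mutation_rate * tr$edge.length[e])
        seqs[[child]] <- .mutate_aa(seqs[[par]], p)
      }
      rows <- seqs[seq_len(n_taxa)]
      labels <- tr$tip.label
    }
    m <- do.call(rbind, rows)
    gaps <- matrix(runif(length(m)) < gap_rate, nrow = nrow(m))
    m[gaps] <- "-"
    rownames(m) <- labels
    protein_alignment(m)
  })
}
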