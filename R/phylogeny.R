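# MEGA-style distance phylogenetics: p-distance with pairwise deletion,
# neighbor-joining with a documented tie-break, bootstrap bipartition
# supports, and clade assignment of query taxa.

#' Construct a protein alignment
#'
#' @param x either a character matrix (taxa in rows, one residue per cell) or
#'   a named character vector of equal-length aligned sequences. Gaps are
#'   `-`. Amino-acid ambiguity codes (B, Z, X) are kept verbatim and compare
#'   equal only to themselves.
#' @return A `ProteinAlignment`: character matrix with unique row names.
#' @export
protein_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    stopifnot(!is.null(names(x)), length(unique(nchar(x))) == 1L)
    labs <- names(x)
    x <- do.call(rbind, strsplit(unname(x), ""))
    rownames(x) <- labs
  }
  stopifnot(is.matrix(x), is.character(x), !is.null(rownames(x)),
            !anyDuplicated(rownames(x)), nrow(x) >= 2L, ncol(x) >= 1L)
  class(x) <- c("ProteinAlignment", "matrix", "array")
  x
}

#' Read / write aligned FASTA
#'
#' @param path file path to an aligned protein FASTA.
#' @return `read_alignment()` returns a `ProteinAlignment`;
#'   `write_alignment()` returns `path` invisibly.
#' @export
read_alignment <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  m <- do.call(rbind, strsplit(as.character(s), ""))
  rownames(m) <- names(s)
  protein_alignment(m)
}

#' @rdname read_alignment
#' @param aln a `ProteinAlignment`.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste0, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

# Core p-distance under pairwise deletion. Returns list(d, comp) or, when a
# pair shares no gap-free column, list(fail = c(i, j)).
.p_distance_core <- function(m) {
  n <- nrow(m)
  ng <- m != "-"
  d <- matrix(0, n, n)
  comp <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      use <- ng[i, ] & ng[j, ]
      cs <- sum(use)
      if (cs == 0L) return(list(fail = c(i, j)))
      mm <- sum(m[i, use] != m[j, use])
      d[i, j] <- d[j, i] <- mm / cs
      comp[i, j] <- comp[j, i] <- cs
    }
  }
  list(d = d, comp = comp)
}

#' p-distance matrix with pairwise deletion
#'
#' `d[i, j]` is the proportion of mismatching residues among the columns where
#' neither sequence has a gap (pairwise deletion). Ambiguity codes mismatch
#' everything except themselves.
#'
#' @param aln a `ProteinAlignment`.
#' @return A `DistanceMatrix`: list with `taxa`, `d` (symmetric matrix in
#'   `[0, 1]`, zero diagonal) and `comparable_sites` (per-pair gap-free column
#'   counts).
#' @export
p_distance <- function(aln) {
  stopifnot(inherits(aln, "ProteinAlignment"))
  res <- .p_distance_core(unclass(aln))
  if (!is.null(res$fail))
    stop(sprintf("no comparable (gap-free) sites between '%s' and '%s'",
                 rownames(aln)[res$fail[1L]], rownames(aln)[res$fail[2L]]))
  taxa <- rownames(aln)
  dimnames(res$d) <- dimnames(res$comp) <- list(taxa, taxa)
  structure(list(taxa = taxa, d = res$d, comparable_sites = res$comp),
            class = "DistanceMatrix")
}

#' Write a distance matrix as a square PHYLIP file
#'
#' @param dm a `DistanceMatrix` (or square numeric matrix with dimnames).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(dm, path) {
  d <- if (inherits(dm, "DistanceMatrix")) dm$d else dm
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste0(formatC(rownames(d)[i], width = -12L),
                      paste(sprintf("%.8f", d[i, ]), collapse = " ")), con)
  invisible(path)
}

# ---- neighbor joining ------------------------------------------------------

#' Neighbor-joining tree
#'
#' Classic agglomerative neighbor joining (Saitou-Nei Q criterion, standard
#' branch-length formulas). Ties in the Q matrix are broken by the lowest
#' `(row, column)` index pair so trees are reproducible. Additive input
#' distances are recovered exactly. Negative branch lengths are kept in the
#' returned object; they are clamped to zero only on serialization
#' ([write_newick()]).
#'
#' @param dm a `DistanceMatrix` from [p_distance()] or a symmetric numeric
#'   matrix with dimnames and zero diagonal; >= 3 taxa.
#' @return An unrooted `phylo` tree (ape) with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "DistanceMatrix")) dm$d else dm
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12, check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(nrow(d)))
  n <- nrow(d)
  node <- seq_len(n)            # tips positive, internal nodes negative
  next_int <- 0L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  D <- unname(d)
  while (length(node) > 3L) {
    r <- length(node)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    next_int <- next_int - 1L
    parent <- c(parent, next_int, next_int)
    child <- c(child, node[i], node[j])
    elen <- c(elen, li, lj)
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    node <- c(node[keep], next_int)
  }
  a <- D[1L, 2L]; b <- D[1L, 3L]; cc <- D[2L, 3L]
  next_int <- next_int - 1L
  parent <- c(parent, rep.int(next_int, 3L))
  child <- c(child, node)
  elen <- c(elen, (a + b - cc) / 2, (a + cc - b) / 2, (b + cc - a) / 2)
  root <- next_int
  # renumber: tips keep 1..n, internal nodes get n+1, n+2, ... in preorder
  # from the root (ape convention: root = n + 1)
  kids <- split(seq_along(parent), parent)
  new_id <- integer(-next_int)  # indexed by -internal_id
  cnt_int <- 0L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    cnt_int <- cnt_int + 1L
    new_id[-v] <- n + cnt_int
    ch <- child[kids[[as.character(v)]]]
    stack <- c(stack, ch[ch < 0L])
  }
  edge <- cbind(new_id[-parent],
                ifelse(child > 0L, child, new_id[pmax(-child, 1L)]))
  storage.mode(edge) <- "integer"
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = labels, Nnode = cnt_int),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

# Non-trivial bipartitions of an unrooted tree, as canonical keys: the sorted
# tip labels of the side not containing the alphabetically first taxon.
tree_bipartitions <- function(tree) {
  n <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  anchor <- min(tree$tip.label)
  keys <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(post$edge))) {
    ch <- post$edge[e, 2L]
    if (ch <= n) next                      # trivial split
    clade <- sets[[ch]]
    if (length(clade) >= n - 1L) next      # trivial complement
    side <- if (anchor %in% clade) setdiff(tree$tip.label, clade) else clade
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, ch)
  }
  setNames(keys, nodes)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' p-distance neighbor-joining tree per replicate, and scores each internal
#' edge of the full-data tree by the percentage of replicates whose tree
#' contains the same bipartition (matched by bipartition identity, so the
#' scores are invariant to rerooting). Replicates in which some pair of taxa
#' has no comparable site are dropped; if 10% or more are dropped the run is
#' an error.
#'
#' @param aln a `ProteinAlignment` with >= 4 taxa.
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed integer seed; supports are bit-reproducible for a fixed seed.
#' @return The full-data `phylo` tree whose `node.label` holds the support
#'   percentage of the edge above each internal node (empty for the root).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L) {
  stopifnot(inherits(aln, "ProteinAlignment"), nrow(aln) >= 4L, n_reps >= 1L)
  m <- unclass(aln)
  full <- neighbor_joining(p_distance(aln))
  keys <- tree_bipartitions(full)
  hits <- setNames(numeric(length(keys)), names(keys))
  dropped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      core <- .p_distance_core(m[, cols, drop = FALSE])
      if (!is.null(core$fail)) {
        dropped <- dropped + 1L
        next
      }
      dimnames(core$d) <- list(rownames(m), rownames(m))
      rep_keys <- tree_bipartitions(neighbor_joining(core$d))
      hits <- hits + (keys %in% rep_keys)
    }
  })
  if (dropped >= 0.1 * n_reps)
    stop(dropped, " of ", n_reps, " replicates had incomparable pairs")
  used <- n_reps - dropped
  support <- 100 * hits / used
  lab <- rep.int("", full$Nnode)
  node <- as.integer(names(keys)) - ape::Ntip(full)
  lab[node] <- format(support, trim = TRUE)
  full$node.label <- lab
  attr(full, "support") <- setNames(support, names(keys))
  attr(full, "replicates_used") <- used
  full
}

#' Serialize a tree to newick
#'
#' Negative branch lengths (a known artifact of neighbor joining) are clamped
#' to zero here, and only here. Bootstrap supports, when present, are printed
#' as integers (halves away from zero); supports below `support_min` can be
#' blanked, following the figure convention of showing only values above a
#' display threshold.
#'
#' @param tree a `phylo` object.
#' @param path optional output file; when `NULL` the newick string is
#'   returned.
#' @param support_min optional display threshold in percent (e.g. 70).
#' @return The newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL, support_min = NULL) {
  tree$edge.length <- pmax(tree$edge.length, 0)
  sup <- attr(tree, "support")
  if (!is.null(sup)) {
    lab <- rep.int("", tree$Nnode)
    keep <- if (is.null(support_min)) rep.int(TRUE, length(sup))
      else sup >= support_min
    node <- as.integer(names(sup)) - ape::Ntip(tree)
    lab[node[keep]] <- as.character(round_half_up(sup[keep]))
    tree$node.label <- lab
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Assign query taxa to reference clades
#'
#' Each query leaf receives the clade label of its nearest labeled reference
#' leaf by patristic (path-length) distance; an exact tie between references
#' of different clades leaves the query unassigned (`NA`).
#'
#' @param query_taxa character vector of query leaf labels (must be in the
#'   tree).
#' @param tree a `phylo` object with branch lengths.
#' @param reference_clades named character vector: reference leaf label ->
#'   clade.
#' @return Named character vector: query -> clade (or `NA` when tied).
#' @export
assign_clade <- function(query_taxa, tree, reference_clades) {
  stopifnot(inherits(tree, "phylo"), length(reference_clades) >= 1L,
            all(names(reference_clades) %in% tree$tip.label))
  missing <- setdiff(query_taxa, tree$tip.label)
  if (length(missing))
    stop("query taxa not in tree: ", paste(missing, collapse = ", "))
  pd <- ape::cophenetic.phylo(tree)
  refs <- names(reference_clades)
  out <- setNames(rep.int(NA_character_, length(query_taxa)), query_taxa)
  for (q in query_taxa) {
    dq <- pd[q, refs]
    dmin <- min(dq)
    tol <- 1e-12 * max(1, abs(dmin))
    best <- unique(reference_clades[refs[dq <= dmin + tol]])
    if (length(best) == 1L) out[q] <- best
  }
  out
}
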