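# Shared fixtures and independent oracles, built in code at test time.

# A tag that is CATG + the given 17-mer (pads/truncates as needed).
mk_tag <- function(suffix17) {
  s <- paste0(suffix17, paste(rep("A", 17), collapse = ""))
  paste0("CATG", substr(s, 1, 17))
}

# Small reproducible reference shared by several tests.
test_ref <- function(n = 20, seed = 101) {
  generate_reference(n, length_range = c(120L, 220L), spacer = 40L,
                     seed = seed)
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Brute-force tag classification oracle: scan every index key at Hamming
# distance 0 then 1, gene keys before genome keys (mirrors the documented
# precedence, computed by exhaustive scan rather than hashing).
oracle_map <- function(tag, index, max_mismatch = 1) {
  gd <- vapply(index$gene_keys, hamming, numeric(1), a = tag)
  md <- if (length(index$genome_keys))
    vapply(index$genome_keys, hamming, numeric(1), a = tag) else numeric(0)
  for (tier in 0:max_mismatch) {
    hit <- which(gd == tier)
    if (length(hit)) {
      genes <- sort(unique(unlist(index$gene_hits[hit])))
      cat_ <- if (length(genes) == 1) "UNAMBIGUOUS_GENE" else "AMBIGUOUS_GENE"
      return(list(category = cat_, gene_hits = genes, best_mismatch = tier))
    }
  }
  for (tier in 0:max_mismatch) {
    if (any(md == tier))
      return(list(category = "GENOME_ONLY", gene_hits = character(0),
                  best_mismatch = tier))
  }
  list(category = "UNKNOWN", gene_hits = character(0),
       best_mismatch = NA_integer_)
}

# Exhaustive two-sided Fisher oracle: enumerate all tables with the observed
# margins and sum the probabilities (computed from factorials directly) of
# those no more probable than the observed table.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d; n <- r1 + r2
  if (n == 0) stop("empty table")
  logp <- function(a2) {
    b2 <- r1 - a2; c2_ <- c1 - a2; d2 <- r2 - c2_
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(a2) - lfactorial(b2) - lfactorial(c2_) -
      lfactorial(d2)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(support, logp, numeric(1))
  p_obs <- exp(logp(a))
  min(1, sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)]))
}

# Random unrooted tree with positive branch lengths (for additive-matrix
# oracles).
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 1.5)
  tr
}

# Sorted canonical bipartition keys of a tree (independent of the package's
# internal representation, via ape::prop.part).
oracle_bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  anchor <- min(labs)
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side && length(side) < n) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  sort(unique(keys[vapply(pp, function(i) length(i) > 1 && length(i) < n - 1,
                          logical(1))]))
}

pkg_bipartitions <- function(tree) {
  keys <- dgetag:::tree_bipartitions(tree)
  sort(unique(gsub("\r", "|", unname(keys))))
}
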