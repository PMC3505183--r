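# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Decimal rounding where exact halves move away from zero (so 74.5 prints as
#' 75), matching the report conventions used throughout the package; base R's
#' `round()` rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return Numeric vector of rounded values.
#' @export
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage n/d printed Table-2 style: one decimal, half away from zero.
pct1 <- function(n, d) round_half_up(100 * n / d, 1L)

# Random DNA strings, vectorized over n.
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Positions p (1-based) of CATG occurrences in `seq` with >= 17 bases after
# the anchor, i.e. start positions of complete 21-mer tag windows.
tag_window_starts <- function(seq) {
  hits <- gregexpr(.TAG_ANCHOR, seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  hits <- as.integer(hits)
  hits[hits <= nchar(seq) - .TAG_LEN + 1L]
}

# All complete CATG-anchored 21-mer windows of `seq`.
tag_windows <- function(seq) {
  p <- tag_window_starts(seq)
  if (length(p) == 0L) return(character(0))
  substring(seq, p, p + .TAG_LEN - 1L)
}


is_valid_tag <- function(tags) {
  nchar(tags) == .TAG_LEN &
    startsWith(tags, .TAG_ANCHOR) &
    !grepl("[^ACGT]", tags)
}

# Sum a named count vector by name, returning a named integer vector sorted
# by name (deterministic ordering for serialization).
sum_by_name <- function(counts) {
  if (length(counts) == 0L) return(setNames(integer(0), character(0)))
  s <- rowsum(as.numeric(counts), group = names(counts), reorder = TRUE)
  setNames(as.integer(round(s[, 1L])), rownames(s))
}
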