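test_that("p-distance implements pairwise deletion and stays in bounds", {
  aln <- protein_alignment(c(a = "ACG-TT", b = "ACGAAT"))
  dm <- p_distance(aln)
  expect_equal(dm$comparable_sites["a", "b"], 5)
  expect_equal(dm$d["a", "b"], 0.2)

  same <- protein_alignment(c(x = "MKLV", y = "MKLV"))
  expect_equal(max(p_distance(same)$d), 0)

  # permutation equivariance
  aln3 <- generate_alignment(6, 80, mutation_rate = 0.3, seed = 4)
  d1 <- p_distance(aln3)$d
  perm <- c(4, 1, 6, 2, 5, 3)
  d2 <- p_distance(protein_alignment(unclass(aln3)[perm, ]))$d
  expect_equal(d2, d1[perm, perm])

  # shared gap columns do not change distances
  padded <- protein_alignment(cbind(unclass(aln3),
                                    matrix("-", 6, 10)))
  expect_equal(p_distance(padded)$d, d1)

  bad <- protein_alignment(c(a = "AA--", b = "--AA", c = "AAAA"))
  expect_error(p_distance(bad), "comparable")
})

test_that("neighbor joining recovers the worked 4-taxon tree exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  expect_equal(pkg_bipartitions(tr), "C|D")  # AB|CD split
  # branch lengths (A, B, internal, C, D) = (1, 2, 1, 3, 4)
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
  pl <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pl, d, tolerance = 1e-12)
  asym <- matrix(c(0, 1, 2,
                   1.5, 0, 1,
                   2, 1, 0), 3, 3, byrow = TRUE)
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("three taxa solve the three-point closed form", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(d)
  expect_equal(nrow(tr$edge), 3)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(len["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(len["c"]), (0.5 + 0.6 - 0.3) / 2)
})

test_that("additive matrices are reconstructed exactly (oracle: path lengths and ape)", {
  for (s in 1:15) {
    n <- 5 + (s %% 8)
    gt <- random_additive_tree(n, seed = 1000 + s)
    D <- ape::cophenetic.phylo(gt)
    tr <- neighbor_joining(D)
    expect_equal(pkg_bipartitions(tr), oracle_bipartitions(gt))
    pl <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(pl - D)), 1e-9)
    # independent implementation agrees on topology
    expect_equal(phangorn::RF.dist(tr, ape::nj(D)), 0)
  }
})

test_that("bootstrap supports behave at the boundaries and are reproducible", {
  # homoplasy-free alignment: every column supports AB|CD
  block <- function(ch, n) strrep(ch, n)
  aln <- protein_alignment(c(A = paste0(block("A", 30), block("G", 20)),
                             B = paste0(block("A", 30), block("G", 20)),
                             C = paste0(block("C", 30), block("T", 20)),
                             D = paste0(block("C", 30), block("T", 20))))
  tr <- bootstrap_support(aln, n_reps = 200, seed = 9)
  expect_equal(unname(attr(tr, "support")), 100)

  one <- bootstrap_support(aln, n_reps = 1, seed = 2)
  expect_true(all(attr(one, "support") %in% c(0, 100)))

  aln2 <- generate_alignment(6, 120, mutation_rate = 0.3, gap_rate = 0.05,
                             seed = 12)
  b1 <- bootstrap_support(aln2, n_reps = 100, seed = 5)
  b2 <- bootstrap_support(aln2, n_reps = 100, seed = 5)
  expect_identical(attr(b1, "support"), attr(b2, "support"))

  # newick serialization clamps negatives and prints integer supports
  txt <- write_newick(b1, support_min = 0)
  expect_false(grepl("-0\\.|:-", txt))
})

test_that("clade assignment follows nearest patristic reference with tie -> NA", {
  tr <- ape::read.tree(text = "((q1:0.1,r1:0.1):0.5,(r2:0.1,(q2:0.3,r3:0.3):0.1):0.5);")
  refs <- c(r1 = "B", r2 = "F", r3 = "G")
  out <- assign_clade(c("q1", "q2"), tr, refs)
  expect_equal(unname(out["q1"]), "B")   # sister to r1 (distance 0.2)
  expect_equal(unname(out["q2"]), "F")   # r2 at 0.5 beats sister r3 at 0.6
  # exact tie between clades F and G
  tied <- ape::read.tree(text = "((q:1.0,x:1.0):1.0,(rF:2.0,rG:2.0):1.0);")
  out2 <- assign_clade("q", tied, c(rF = "F", rG = "G"))
  expect_true(is.na(out2[["q"]]))
  expect_error(assign_clade("nope", tr, refs), "not in tree")
})

test_that("clade-structured alignments are classified correctly at low mutation rates", {
  # two tight clades joined by one long internal branch
  nwk <- "(((a1:0.1,a2:0.1):0.1,(a3:0.1,a4:0.1):0.1):1.0,(b1:0.2,(b2:0.1,b3:0.1):0.1):1.0);"
  gt <- ape::read.tree(text = nwk)
  aln <- generate_alignment(7, 300, mutation_rate = 0.3, gap_rate = 0,
                            guide_tree = gt, seed = 21)
  tr <- neighbor_joining(p_distance(aln))
  refs <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  out <- assign_clade(c("a3", "a4", "b3"), tr, refs)
  expect_equal(unname(out), c("A", "A", "B"))
})

test_that("alignment FASTA and distance PHYLIP round trips preserve content", {
  aln <- generate_alignment(5, 60, mutation_rate = 0.2, gap_rate = 0.05,
                            seed = 31)
  f <- withr::local_tempfile(fileext = ".fa")
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_equal(unclass(back), unclass(aln))
  dm <- p_distance(aln)
  p <- withr::local_tempfile(fileext = ".phy")
  write_distance_phylip(dm, p)
  lines <- readLines(p)
  expect_equal(as.integer(trimws(lines[1])), 5)
  expect_length(lines, 6)
})
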