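test_that("index windows match an independent pattern-scan oracle", {
  ref <- test_ref(12, seed = 55)
  idx <- build_tag_index(ref)
  # oracle: Biostrings pattern matching on each transcript
  oracle_windows <- unlist(lapply(seq_len(nrow(ref$genes)), function(i) {
    tx <- ref$genes$transcript[i]
    hits <- Biostrings::start(Biostrings::matchPattern(
      "CATG", Biostrings::DNAString(tx)))
    hits <- hits[hits <= nchar(tx) - 20]
    substring(tx, hits, hits + 20)
  }))
  expect_setequal(idx$gene_keys, unique(oracle_windows))

  # single-window transcript
  one <- list(transcripts = c(g1 = paste0(strrep("T", 30),
                                          mk_tag("ACACACACACACACACA"))),
              genome = NULL)
  idx1 <- build_tag_index(one)
  expect_length(idx1$gene_keys, 1)

  # shared window maps to a two-gene set
  w <- mk_tag("GTGTGTGTGTGTGTGTG")
  two <- build_tag_index(list(
    transcripts = c(gA = paste0(strrep("A", 10), w),
                    gB = paste0(strrep("C", 25), w)),
    genome = NULL))
  expect_identical(two$gene_hits[[match(w, two$gene_keys)]], c("gA", "gB"))

  expect_warning(build_tag_index(list(transcripts = c(s = "CATGAA",
                                                      g = one$transcripts),
                                      genome = NULL)),
                 "skipped")
})

test_that("map_tag applies tier and gene/genome precedence", {
  w1 <- mk_tag("AAAAAAAAAAAAAAAAA")
  w2 <- mk_tag("AAAAAAAACAAAAAAAA")  # Hamming 1 from w1
  w3 <- mk_tag("TTTTTTTTGTTTTTTTT")  # Hamming 1 from query q3
  q3 <- mk_tag("TTTTTTTTCTTTTTTTT")
  idx <- build_tag_index(list(
    transcripts = c(g1 = paste0(strrep("G", 5), w1),
                    g2 = paste0(strrep("G", 5), w2),
                    g3 = paste0(strrep("G", 5), w3)),
    genome = paste0(strrep("A", 5), q3, strrep("A", 5))))

  # exact unique hit
  hit <- map_tag(w3, idx)
  expect_equal(hit$category, "UNAMBIGUOUS_GENE")
  expect_equal(hit$gene_hits, "g3")
  expect_equal(hit$best_mismatch, 0)

  # w1 is exact on g1 and 1-mismatch on g2: the exact tier wins
  expect_equal(map_tag(w1, idx)$gene_hits, "g1")

  # one mismatch away from two different genes, no exact hit
  mid <- mk_tag("AAAAAAAAGAAAAAAAA")
  amb <- map_tag(mid, idx)
  expect_equal(amb$category, "AMBIGUOUS_GENE")
  expect_setequal(amb$gene_hits, c("g1", "g2"))
  expect_equal(amb$best_mismatch, 1)

  # q3 hits the genome exactly but g3 at one mismatch: gene precedence
  expect_equal(map_tag(q3, idx)$category, "UNAMBIGUOUS_GENE")

  # genome-only and unknown
  spacer_tag <- mk_tag("CCGGCCGGCCGGCCGGC")
  idx2 <- build_tag_index(list(
    transcripts = c(g1 = paste0(strrep("G", 5), w1)),
    genome = paste0(strrep("T", 3), spacer_tag, strrep("T", 3))))
  expect_equal(map_tag(spacer_tag, idx2)$category, "GENOME_ONLY")
  far <- mk_tag("GGGGGGGGGGGGGGGGG")
  expect_equal(map_tag(far, idx2)$category, "UNKNOWN")
  expect_true(is.na(map_tag(far, idx2)$best_mismatch))

  expect_error(map_tag("CATGNN", idx), "malformed")
})

test_that("map_tag agrees with the brute-force Hamming oracle", {
  ref <- test_ref(10, seed = 66)
  idx <- build_tag_index(ref)
  set.seed(13)
  # mix of exact windows, mutated windows, and random tags
  queries <- c(
    sample(idx$gene_keys, 5),
    vapply(sample(idx$gene_keys, 10, replace = TRUE), function(w) {
      p <- sample(5:21, 1)
      substr(w, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(w, p, p)), 1)
      w
    }, ""),
    paste0("CATG", replicate(10, paste(sample(c("A", "C", "G", "T"), 17,
                                              replace = TRUE), collapse = "")))
  )
  for (q in queries) {
    got <- map_tag(q, idx)
    want <- oracle_map(q, idx)
    expect_equal(got$category, want$category, info = q)
    expect_equal(got$gene_hits, want$gene_hits, info = q)
    expect_equal(got$best_mismatch, want$best_mismatch, info = q)
  }
})

test_that("classification partitions distinct tags and counts only unambiguous tags", {
  ref <- test_ref(25, seed = 91)
  lib <- extract_clean_tags(simulate_library(ref, lognormal_profile(ref),
                                             depth = 2e5, seed = 92))
  cl <- classify_library(lib, build_tag_index(ref))
  s <- cl$stats
  n <- function(lab) s$n[s$statistic == lab]
  expect_equal(n("Distinct tag mapping to gene") +
                 n("Distinct tag mapping to genome") +
                 n("Distinct unknown tag"),
               n("Distinct clean tag"))
  expect_true(all(cl$gene_counts >= 0))
  expect_lte(sum(cl$gene_counts), lib$totals$total_clean)
  # unambiguous categories are disjoint parts of gene-mapped
  expect_lte(n("Distinct unambiguous tag mapping to gene"),
             n("Distinct tag mapping to gene"))
  # per-gene counts equal an independent tally from the annotations table
  ann <- cl$annotations
  byg <- tapply(ann$count[ann$category == "UNAMBIGUOUS_GENE"],
                ann$gene[ann$category == "UNAMBIGUOUS_GENE"], sum)
  expect_equal(cl$gene_counts[names(byg)], setNames(as.integer(byg),
                                                    names(byg)))
})

test_that("a noise-free library has no unknown distinct tags", {
  ref <- test_ref(15, seed = 71)
  lib <- extract_clean_tags(simulate_library(ref, uniform_profile(ref),
                                             depth = 50000, error_rate = 0,
                                             adaptor_rate = 0,
                                             singleton_rate = 0, seed = 72))
  s <- classify_library(lib, build_tag_index(ref))$stats
  expect_equal(s$n[s$statistic == "Distinct unknown tag"], 0)
  expect_equal(s$n[s$statistic == "Total unknown tag"], 0)
})
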