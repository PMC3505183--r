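test_that("TPM follows the clean-tag denominator with a 0.01 floor", {
  expect_equal(unname(tpm_normalize(c(g = 1), 3759150)), 0.2660175,
               tolerance = 1e-6)
  expect_equal(format_tpm(tpm_normalize(c(g = 1), 3759150)), "0.27")
  expect_equal(unname(tpm_normalize(c(g = 0), 3759150)), 0.01)
  expect_equal(unname(tpm_normalize(c(g = 100), 1e6)), 100)
  # scale consistency: doubling counts and totals leaves TPM unchanged
  x <- c(a = 3, b = 0, c = 17)
  expect_equal(tpm_normalize(x, 1234), tpm_normalize(2 * x, 2468))
  # mapped fraction identity
  expect_equal(sum(x * 1e6 / 1234), 1e6 * sum(x) / 1234)
  expect_error(tpm_normalize(x, 0), "positive")
})

test_that("stage-specific detection returns genes seen in exactly one library", {
  counts <- list(egg = c(g1 = 3, g2 = 2, g4 = 1),
                 larva = c(g2 = 2, g3 = 9),
                 pupa = c(g3 = 1),
                 adult = setNames(integer(0), character(0)))
  em <- build_expression_matrix(counts, c(egg = 100, larva = 100, pupa = 100,
                                          adult = 100),
                                genes = c("g1", "g2", "g3", "g4", "g5"))
  sp <- detect_stage_specific(em)
  expect_equal(sp[["g1"]], "egg")
  expect_equal(sp[["g4"]], "egg")
  expect_false("g2" %in% names(sp))  # two libraries
  expect_false("g3" %in% names(sp))
  expect_false("g5" %in% names(sp))  # never detected
})

test_that("stage-restricted simulations recover specificity truth without noise", {
  ref <- test_ref(30, seed = 61)
  ids <- ref$genes$gene_id
  stage_sets <- split(ids, rep(c("egg", "larva", "pupa"), each = 10))
  libs <- lapply(names(stage_sets), function(st) {
    prof <- uniform_profile(stage_sets[[st]])
    extract_clean_tags(simulate_library(ref, prof, depth = 30000,
                                        error_rate = 0, adaptor_rate = 0,
                                        singleton_rate = 0,
                                        seed = match(st, names(stage_sets)),
                                        library_id = st, stage = st))
  })
  names(libs) <- names(stage_sets)
  idx <- build_tag_index(ref)
  gc <- lapply(libs, function(l) classify_library(l, idx)$gene_counts)
  em <- build_expression_matrix(gc, vapply(libs, function(l)
    l$totals$total_clean, numeric(1)), genes = ids)
  sp <- detect_stage_specific(em)
  for (st in names(stage_sets)) {
    detected <- names(sp)[sp == st]
    expect_setequal(detected, intersect(stage_sets[[st]], names(sp)))
    # every gene expressed in exactly that stage and detected at all
    expect_true(all(detected %in% stage_sets[[st]]))
  }
})

test_that("library correlation is 1 for identical or rescaled libraries", {
  counts <- list(a = c(g1 = 10, g2 = 100, g3 = 1000),
                 b = c(g1 = 20, g2 = 200, g3 = 2000))
  em <- build_expression_matrix(counts, c(a = 5000, b = 5000))
  expect_equal(pearson_correlation(em, "a", "a"), 1)
  expect_equal(pearson_correlation(em, "a", "b"), 1)  # pure log shift
  em2 <- build_expression_matrix(list(a = c(g1 = 1), b = c(g2 = 1)),
                                 c(a = 10, b = 10), genes = c("g1", "g2"))
  expect_error(pearson_correlation(em2, "a", "b"), "fewer than 3")
})

test_that("technical replicates of one profile correlate highly at depth", {
  ref <- generate_reference(2000, c(200, 400), seed = 81)
  prof <- lognormal_profile(ref, sdlog = 1.5, seed = 82)
  idx <- build_tag_index(ref)
  libs <- lapply(1:2, function(k)
    extract_clean_tags(simulate_library(ref, prof, depth = 3e6, seed = 82 + k,
                                        library_id = paste0("rep", k))))
  gc <- lapply(libs, function(l) classify_library(l, idx)$gene_counts)
  names(gc) <- c("rep1", "rep2")
  em <- build_expression_matrix(gc, c(rep1 = libs[[1]]$totals$total_clean,
                                      rep2 = libs[[2]]$totals$total_clean),
                                genes = ref$genes$gene_id)
  expect_gte(pearson_correlation(em, "rep1", "rep2"), 0.95)
})

test_that("saturation curves are nested, monotone, and plateau at depth", {
  ref <- test_ref(20, seed = 51)
  lib <- extract_clean_tags(simulate_library(ref, uniform_profile(ref),
                                             depth = 40000, seed = 52))
  idx <- build_tag_index(ref)
  sat <- saturation_curve(lib, idx, seed = 1)
  expect_true(all(diff(sat$genes_detected) >= 0))
  # full-size point equals full-library detection
  cl <- classify_library(lib, idx)
  expect_equal(sat$genes_detected[nrow(sat)],
               sum(cl$gene_counts > 0))
  expect_identical(saturation_curve(lib, idx, seed = 1), sat)
})

test_that("gene discovery nearly stops by 3 million tags in a deep library", {
  ref <- generate_reference(12000, c(200, 400), seed = 71)
  prof <- lognormal_profile(ref, sdlog = 1.5, seed = 72)
  lib <- extract_clean_tags(simulate_library(ref, prof, depth = 3.5e6,
                                             seed = 73))
  idx <- build_tag_index(ref)
  sat <- saturation_curve(lib, idx,
                          grid = c(0.5e6, 1e6, 2e6, 3e6,
                                   lib$totals$total_clean),
                          seed = 2)
  g3 <- sat$genes_detected[sat$size == 3e6]
  gf <- sat$genes_detected[nrow(sat)]
  expect_gte(g3, 0.98 * gf)
})
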