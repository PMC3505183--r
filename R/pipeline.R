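# End-to-end orchestration from a declarative config, plus reference I/O.

#' Write / read a synthetic reference
#'
#' Serialized as transcript FASTA, genome FASTA and a 3-column coordinates
#' TSV (`gene_id`, `start`, `end`; 0-based half-open).
#'
#' @param ref a `SyntheticReference`.
#' @param dir output directory (created if needed).
#' @return `write_reference()` returns `dir` invisibly; `read_reference()`
#'   returns a `SyntheticReference`.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- Biostrings::DNAStringSet(setNames(ref$genes$transcript,
                                          ref$genes$gene_id))
  Biostrings::writeXStringSet(tx, file.path(dir, "transcripts.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(genome = ref$genome)),
    file.path(dir, "genome.fa"))
  write.table(ref$coordinates, file.path(dir, "coordinates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  tx <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
  genome <- as.character(Biostrings::readDNAStringSet(
    file.path(dir, "genome.fa"))[[1L]])
  coords <- read.delim(file.path(dir, "coordinates.tsv"),
                       stringsAsFactors = FALSE)
  seqs <- as.character(tx)
  canonical <- vapply(seqs, function(s) {
    p <- tag_window_starts(s)
    if (length(p) == 0L) return(NA_character_)
    substr(s, max(p), max(p) + .TAG_LEN - 1L)
  }, character(1L), USE.NAMES = FALSE)
  ref <- list(genes = data.frame(gene_id = names(tx), transcript = seqs,
                                 canonical_tag = canonical,
                                 tagless = is.na(canonical),
                                 stringsAsFactors = FALSE),
              genome = genome, coordinates = coords)
  class(ref) <- "SyntheticReference"
  ref
}

#' Pipeline configuration
#'
#' Declarative description of one pipeline run. The bundled demo
#' ([demo_config()]) simulates everything; real tag tables can be supplied
#' through the `libraries` field instead.
#'
#' @param seed integer master seed, recorded in the run log; every stochastic
#'   stage derives its own seed from it.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param simulate list of generator settings: `n_genes`, `length_range`,
#'   `spacer`, `depth`, `error_rate`, `adaptor_rate`, `singleton_rate`,
#'   `n_de`, `fold_range`, `sdlog`, `n_terms`, `n_taxa`, `aln_length`,
#'   `mutation_rate`, `gap_rate`.
#' @param libraries optional named list (library_id -> list(path, stage,
#'   strain)) of 2-column tag TSVs; used instead of simulation, together with
#'   `reference_dir`.
#' @param reference_dir directory from [write_reference()] (only with
#'   `libraries`).
#' @param de_pair character pair: the libraries compared for differential
#'   expression, reference/susceptible condition first.
#' @param fdr_max,min_abs_log2,max_mismatch,bootstrap_reps,support_display_min
#'   analysis thresholds.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(seed = 42L, out_dir = NULL, simulate = NULL,
                            libraries = NULL, reference_dir = NULL,
                            de_pair = c("slab_larva", "sg_larva"),
                            fdr_max = 0.001, min_abs_log2 = 1.0,
                            max_mismatch = 1L, bootstrap_reps = 1000L,
                            support_display_min = 70) {
  stopifnot(fdr_max > 0, min_abs_log2 >= 0, bootstrap_reps >= 1L,
            max_mismatch %in% c(0L, 1L))
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              simulate = simulate, libraries = libraries,
              reference_dir = reference_dir, de_pair = de_pair,
              fdr_max = fdr_max, min_abs_log2 = min_abs_log2,
              max_mismatch = as.integer(max_mismatch),
              bootstrap_reps = as.integer(bootstrap_reps),
              support_display_min = support_display_min)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Bundled demo configuration
#'
#' A fully synthetic end-to-end run: 400 genes, three libraries of 5e5 tags
#' (susceptible larva, a technical replicate, and a resistant larva with 20
#' genes spiked 4- to 8-fold), realistic noise rates, 25 annotation terms and
#' a 12-taxon alignment for the phylogeny stage.
#'
#' @param out_dir optional output directory.
#' @param seed master seed (default 42).
#' @return A `PipelineConfig`.
#' @export
demo_config <- function(out_dir = NULL, seed = 42L) {
  pipeline_config(
    seed = seed, out_dir = out_dir,
    simulate = list(n_genes = 400L, length_range = c(200L, 400L),
                    spacer = 50L, depth = 5e5, error_rate = 0.005,
                    adaptor_rate = 0.005, singleton_rate = 0.02,
                    n_de = 20L, fold_range = c(4, 8), sdlog = 1.2,
                    n_terms = 25L, n_taxa = 12L, aln_length = 250L,
                    mutation_rate = 0.4, gap_rate = 0.02),
    de_pair = c("slab_larva", "sg_larva"),
    bootstrap_reps = 1000L
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes simulation (or library loading), tag cleaning, index building and
#' classification, expression quantification, correlation and saturation QC,
#' differential expression, term enrichment and tree building, and writes the
#' report bundle (TSV sheets, text statistics block, newick tree, run log) to
#' `config$out_dir` when set. Every output is a deterministic function of the
#' config: re-running with the same config is byte-identical.
#'
#' @param config a `PipelineConfig`.
#' @return Invisibly, a list with `reference`, `libraries`, `stats`,
#'   `expression`, `stage_specific`, `correlation`, `saturation`, `de`,
#'   `enrichment`, `tree`, `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  seed <- config$seed
  truth <- NULL
  annotation <- NULL
  aln <- NULL
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    ref <- generate_reference(sm$n_genes, sm$length_range, sm$spacer,
                              seed = seed)
    base_profile <- lognormal_profile(ref, sdlog = sm$sdlog, seed = seed + 1L)
    sp <- spike_differential(base_profile, n_de = sm$n_de,
                             fold_range = sm$fold_range, seed = seed + 2L)
    truth <- sp$b$de_truth
    sim <- function(profile, id, stage, strain, k)
      simulate_library(ref, profile, depth = sm$depth,
                       error_rate = sm$error_rate,
                       adaptor_rate = sm$adaptor_rate,
                       singleton_rate = sm$singleton_rate,
                       seed = seed + k, library_id = id, stage = stage,
                       strain = strain)
    libs <- list(
      slab_larva = sim(sp$a, "slab_larva", "larva", "S-lab", 3L),
      slab_larva_rep = sim(sp$a, "slab_larva_rep", "larva", "S-lab", 4L),
      sg_larva = sim(sp$b, "sg_larva", "larva", "SG", 5L)
    )
    annotation <- generate_annotation(
      ref, n_terms = sm$n_terms,
      enriched_term = list(term = "T_SPIKED",
                           genes = names(truth)[truth != 1]),
      seed = seed + 6L)
    aln <- generate_alignment(sm$n_taxa, length = sm$aln_length,
                              mutation_rate = sm$mutation_rate,
                              gap_rate = sm$gap_rate,
                              guide_tree = with_seed(seed + 7L,
                                ape::rtree(sm$n_taxa)),
                              seed = seed + 8L)
  } else {
    stopifnot(!is.null(config$libraries), !is.null(config$reference_dir))
    ref <- read_reference(config$reference_dir)
    libs <- lapply(names(config$libraries), function(id) {
      l <- config$libraries[[id]]
      read_tag_library(l$path, library_id = id,
                       stage = if (is.null(l$stage)) "other" else l$stage,
                       strain = if (is.null(l$strain)) "NA" else l$strain)
    })
    names(libs) <- names(config$libraries)
  }

  libs <- lapply(libs, extract_clean_tags)
  index <- build_tag_index(ref)
  classified <- lapply(libs, classify_library, index = index,
                       max_mismatch = config$max_mismatch)
  stats <- lapply(classified, `[[`, "stats")
  totals <- vapply(libs, function(l) l$totals$total_clean, numeric(1L))
  em <- build_expression_matrix(lapply(classified, `[[`, "gene_counts"),
                                totals, genes = ref$genes$gene_id,
                                stages = vapply(libs, `[[`, "", "stage"))
  specific <- detect_stage_specific(em)
  pairs <- utils::combn(names(libs), 2L)
  correlation <- data.frame(
    lib_a = pairs[1L, ], lib_b = pairs[2L, ],
    pearson_r = vapply(seq_len(ncol(pairs)), function(k)
      pearson_correlation(em, pairs[1L, k], pairs[2L, k]), numeric(1L)),
    stringsAsFactors = FALSE)
  sat <- saturation_curve(libs[[1L]], index, seed = seed + 9L)
  de <- call_de_genes(em, config$de_pair[1L], config$de_pair[2L],
                      fdr_max = config$fdr_max,
                      min_abs_log2 = config$min_abs_log2)
  enr <- NULL
  if (!is.null(annotation)) {
    background <- rownames(em$counts)[
      rowSums(em$counts[, config$de_pair, drop = FALSE] > 0L) > 0L]
    enr <- enrich_terms(intersect(de$gene_id[de$significant], background),
                        background, annotation)
  }
  tree <- NULL
  if (!is.null(aln))
    tree <- bootstrap_support(aln, n_reps = config$bootstrap_reps,
                              seed = seed + 10L)

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    writeLines(format_library_stats(stats), file.path(out, "table_stats.txt"))
    all_stats <- do.call(rbind, lapply(names(stats), function(l)
      cbind(library_id = l, stats[[l]])))
    .write_tsv(all_stats, file.path(out, "library_stats.tsv"))
    for (l in names(libs))
      .write_tsv(abundance_distribution(libs[[l]]),
                 file.path(out, paste0("abundance_", l, ".tsv")))
    .write_tsv(data.frame(gene_id = rownames(em$counts), em$counts),
               file.path(out, "counts.tsv"))
    .write_tsv(data.frame(gene_id = rownames(em$tpm), em$tpm),
               file.path(out, "tpm.tsv"))
    .write_tsv(data.frame(gene_id = names(specific), library = specific),
               file.path(out, "stage_specific.tsv"))
    .write_tsv(correlation, file.path(out, "correlation.tsv"))
    .write_tsv(sat, file.path(out, "saturation.tsv"))
    .write_tsv(de, file.path(out, "de_results.tsv"))
    if (!is.null(enr)) .write_tsv(enr, file.path(out, "enrichment.tsv"))
    if (!is.null(tree))
      write_newick(tree, file.path(out, "tree.nwk"),
                   support_min = config$support_display_min)
    cfg_path <- file.path(out, "config.yaml")
    yaml::write_yaml(config[setdiff(names(config), "out_dir")], cfg_path)
    writeLines(c(
      sprintf("dgetag version: %s",
              as.character(utils::packageVersion("dgetag"))),
      sprintf("seed: %d", seed),
      sprintf("config md5: %s", unname(tools::md5sum(cfg_path)))
    ), file.path(out, "run_log.txt"))
  }

  invisible(list(reference = ref, libraries = libs, stats = stats,
                 expression = em, stage_specific = specific,
                 correlation = correlation, saturation = sat, de = de,
                 enrichment = enr, tree = tree, truth = truth))
}
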