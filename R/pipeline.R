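#' Quantify an in-memory synthetic experiment
#'
#' Runs the full read-processing and counting pipeline (adapter trim,
#' length filter, collapse, one-mismatch mapping, priority counting,
#' nested subtraction, CPM normalization) on an
#' [generate_fcg_experiment()] result without touching disk. Used by the
#' analysis scripts and tests; [run_pipeline()] is the file-based
#' equivalent.
#'
#' @param experiment An `fcg_experiment` (or any list with `sim` and
#'   `libraries` of [generate_library()] results).
#' @param adapter,min_len,max_len As in [pipeline_config()].
#' @return list with `reference`, `count_table`, `abundance`,
#'   `assignments` (per-library [nested_subtraction()] results),
#'   `per_library` (read-accounting data.frame).
#' @export
quantify_experiment <- function(experiment,
                                adapter = experiment$sim$config$adapter,
                                min_len = 18L, max_len = 30L) {
  sim <- experiment$sim
  ref <- build_reference(matures = sim$mature, precursors = sim$hairpin)
  index <- build_alignment_index(ref)
  assignments <- list()
  acc <- list()
  for (label in names(experiment$libraries)) {
    reads <- experiment$libraries[[label]]$reads
    kept <- length_filter(trim_adapter(reads$sequence, adapter),
                          min_len, max_len)
    ur <- collapse_reads(kept)
    hits <- align_reads(ur, index)
    a <- nested_subtraction(assign_counts(ur, hits, ref))
    assignments[[label]] <- a
    acc[[label]] <- data.frame(
      library = label, raw_reads = nrow(reads),
      filtered_reads = length(kept), unique_reads = nrow(ur),
      mapped = a$mapped_total, assigned = sum(a$counts$total),
      ambiguous = a$ambiguous, unmapped = a$unmapped,
      mapping_rate = a$mapped_total / length(kept),
      stringsAsFactors = FALSE)
  }
  ct <- build_count_table(assignments, ref)
  list(reference = ref, count_table = ct, abundance = cpm_normalize(ct),
       assignments = assignments, per_library = do.call(rbind, acc))
}

#' Pipeline configuration
#'
#' Collects file paths and the analysis parameters with the study's
#' defaults (18-30 nt length window, at most 1 mismatch, 100 CPM
#' highly-expressed threshold). Every parameter is echoed into the run
#' manifest for provenance.
#'
#' @param mature_fasta,hairpin_fasta Reference FASTA paths.
#' @param reads Named character vector: library label -> read file
#'   (FASTQ or qseq, by extension).
#' @param design Design sheet path (TSV) or data.frame.
#' @param out_dir Output directory.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len Read length window after trimming.
#' @param max_mismatches Mapping mismatch allowance (0 or 1).
#' @param cpm_threshold,min_libraries Highly-expressed filter.
#' @param pseudocount CPM pseudocount for zero group means.
#' @param pca_transform Feature transform for [pca_libraries()].
#' @param child_map Optional mature-to-hairpin TSV path.
#' @param seed Seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mature_fasta, hairpin_fasta, reads, design,
                            out_dir,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_len = 18L, max_len = 30L,
                            max_mismatches = 1L,
                            cpm_threshold = 100, min_libraries = 1L,
                            pseudocount = 0.5,
                            pca_transform = "log2cpm",
                            child_map = NULL, seed = 1L) {
  stopifnot(max_mismatches %in% c(0L, 1L), length(reads) >= 1L,
            !is.null(names(reads)))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; `reads` is a mapping of library label to file.
#' @param ... Overrides applied after reading.
#' @return list of class `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$reads)) y$reads <- unlist(y$reads)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

read_any <- function(path) {
  if (grepl("\\.qseq(\\.gz)?$", path)) read_qseq(path) else read_fastq(path)
}

#' Run the full quantification and sex-difference pipeline
#'
#' Builds the reference, processes each library (adapter trim, length
#' filter, collapse, one-mismatch mapping), applies the priority counting
#' rules and nested-pair subtraction, normalizes to CPM, filters the
#' highly expressed set, computes the sex-difference statistics, and
#' writes all tables plus a run manifest (parameters, input checksums,
#' per-library read-conservation summary) under `out_dir`.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a result bundle: `reference`, `count_table`,
#'   `abundance`, `stats`, `per_library` (read accounting), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ref <- stage("build-ref",
               build_reference(mature_fasta = config$mature_fasta,
                               hairpin_fasta = config$hairpin_fasta,
                               child_map = config$child_map))
  index <- build_alignment_index(ref)

  design <- config$design
  if (is.character(design)) design <- utils::read.delim(design,
                                                        stringsAsFactors = FALSE)
  design <- validate_design(design)

  assignments <- list()
  per_library <- list()
  for (lib in names(config$reads)) {
    raw <- stage(paste0("read[", lib, "]"), read_any(config$reads[[lib]]))
    trimmed <- trim_adapter(raw$sequence, config$adapter)
    kept <- length_filter(trimmed, config$min_len, config$max_len)
    ur <- collapse_reads(kept)
    hits <- stage(paste0("map[", lib, "]"), align_reads(ur, index))
    if (config$max_mismatches == 0L)
      hits <- hits[hits$mismatches == 0L, , drop = FALSE]
    a <- stage(paste0("count[", lib, "]"), assign_counts(ur, hits, ref))
    a <- nested_subtraction(a)
    assignments[[lib]] <- a
    per_library[[lib]] <- data.frame(
      library = lib, raw_reads = nrow(raw), filtered_reads = length(kept),
      unique_reads = nrow(ur), mapped = a$mapped_total,
      assigned = sum(a$counts$total), ambiguous = a$ambiguous,
      unmapped = a$unmapped,
      mapping_rate = if (length(kept)) a$mapped_total / length(kept) else NA,
      stringsAsFactors = FALSE)
  }
  ct <- build_count_table(assignments, ref)
  ab <- cpm_normalize(ct)
  stats <- stage("stats",
                 sex_difference_stats(ab, design,
                                      cpm_threshold = config$cpm_threshold,
                                      min_libraries = config$min_libraries,
                                      pseudocount = config$pseudocount))

  out <- config$out_dir
  write_reference(ref, file.path(out, "reference.fa"),
                  file.path(out, "reference_metadata.tsv"))
  write_count_table(ct, file.path(out, "count_table.tsv"))
  utils::write.table(
    data.frame(target = rownames(ab$cpm), ab$cpm, check.names = FALSE),
    file.path(out, "cpm.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(do.call(rbind, per_library),
                     file.path(out, "read_accounting.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stats_json <- list(
    highly_expressed_n = length(stats$highly_expressed),
    medians = as.list(stats$medians),
    sign_tests = stats$sign_tests,
    condition_tests = stats$condition_tests,
    pca_variance_fraction = stats$pca$variance_fraction)
  jsonlite::write_json(stats_json, file.path(out, "stats_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  inputs <- c(config$mature_fasta, config$hairpin_fasta,
              unname(config$reads))
  manifest <- list(
    package = "mirsexdiff",
    version = as.character(packageVersion("mirsexdiff")),
    parameters = config[c("adapter", "min_len", "max_len",
                          "max_mismatches", "cpm_threshold",
                          "min_libraries", "pseudocount", "pca_transform",
                          "seed")],
    inputs = as.list(setNames(unname(tools::md5sum(inputs)), inputs)),
    libraries = names(config$reads))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(reference = ref, count_table = ct, abundance = ab,
                 stats = stats, per_library = do.call(rbind, per_library),
                 manifest = manifest))
}
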