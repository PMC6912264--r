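# End-to-end orchestration: ingest -> filter -> log2 -> QC -> (confirmed
# exclusions) -> dataset collection -> per-dataset ANOVA -> consensus ->
# clustering / volcano / enrichment, with provenance (config hash, seeds,
# package version) written next to every run.

#' Pipeline run configuration
#'
#' All randomness flows from `seed` through a fixed derivation scheme: the
#' imputation base seed is `seed + 100` (dataset i then uses
#' `seed + 100 + i`), so partial reruns reproduce exactly.
#'
#' @param intensity_path,sample_sheet_path,gmt_path Input file paths
#'   (`gmt_path` may be `NULL` to disable enrichment).
#' @param out_dir Output directory (created if needed).
#' @param organism Organism analyzed (default `"human"`).
#' @param min_unique_peptides Protein-inclusion threshold (default 1).
#' @param imputation [imputation_params()]; its `base_seed` is overridden by
#'   the derivation scheme.
#' @param thresholds [de_thresholds()].
#' @param qc_k Principal components for QC (default 2).
#' @param k_mad Outlier-flag MAD multiplier (default 5; see
#'   [flag_outlier_samples()]).
#' @param exclude_samples Character vector of confirmed exclusions.
#' @param auto_exclude If TRUE, flagged samples are excluded without
#'   confirmation (for unattended runs); default FALSE, mirroring
#'   analyst-in-the-loop QC.
#' @param enrichment_q_max,enrichment_min_de Reporting filter for enrichment.
#' @param seed Global integer seed.
#' @return A `run_config` object.
#' @export
run_config <- function(intensity_path, sample_sheet_path, gmt_path = NULL,
                       out_dir, organism = "human", min_unique_peptides = 1L,
                       imputation = imputation_params(),
                       thresholds = de_thresholds(),
                       qc_k = 2L, k_mad = 5,
                       exclude_samples = character(),
                       auto_exclude = FALSE,
                       enrichment_q_max = 0.05, enrichment_min_de = 4L,
                       seed = 1L) {
  cfg <- list(intensity_path = intensity_path,
              sample_sheet_path = sample_sheet_path,
              gmt_path = gmt_path, out_dir = out_dir, organism = organism,
              min_unique_peptides = check_count(min_unique_peptides,
                                                "min_unique_peptides", min = 0L),
              imputation = imputation, thresholds = thresholds,
              qc_k = check_count(qc_k, "qc_k"),
              k_mad = check_number(k_mad, "k_mad", min = 0, allow_inf = TRUE),
              exclude_samples = exclude_samples,
              auto_exclude = check_flag(auto_exclude, "auto_exclude"),
              enrichment_q_max = check_number(enrichment_q_max,
                                              "enrichment_q_max", min = 0, max = 1),
              enrichment_min_de = check_count(enrichment_min_de,
                                              "enrichment_min_de", min = 0L),
              seed = check_count(seed, "seed", min = 0L))
  stopifnot(inherits(cfg$imputation, "imputation_params"),
            inherits(cfg$thresholds, "de_thresholds"))
  structure(cfg, class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Fail-fast validation of all input paths, then the complete analysis chain.
#' Every table is written as TSV under `out_dir` together with a
#' `provenance.json` sidecar carrying the configuration, its hash, all
#' derived seeds and the package version; identical config and seed give
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with all in-memory results and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$intensity_path, config$sample_sheet_path, config$gmt_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("fail-fast: input path does not exist: ", p, call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_it <- function(...) {
    line <- sprintf("[%s] %s", "proteoconsensus", sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  ingest <- read_intensity_table(config$intensity_path)
  sheet <- read_sample_sheet(config$sample_sheet_path)
  log_it("ingest: %d proteins x %d samples", nrow(ingest$intensity),
         ncol(ingest$intensity))

  filt <- filter_proteins(ingest$intensity, ingest$annotations,
                          organism = config$organism,
                          min_unique_peptides = config$min_unique_peptides)
  log_it("filter: %d %s proteins with >= %d unique peptide(s)",
         nrow(filt$intensity), config$organism, config$min_unique_peptides)

  logm <- log2_transform(filt$intensity)
  qc <- qc_summaries(logm, sheet, k = config$qc_k)
  flagged <- flag_outlier_samples(qc, sheet, k_mad = config$k_mad)
  log_it("qc: flagged %d sample(s)%s", length(flagged),
         if (length(flagged)) paste0(": ", paste(flagged, collapse = ", ")) else "")

  exclude <- config$exclude_samples
  if (config$auto_exclude) exclude <- union(exclude, as.character(flagged))
  not_flagged <- setdiff(exclude, as.character(flagged))
  if (length(not_flagged)) {
    log_it("excluding unflagged sample(s) on explicit instruction: %s",
           paste(not_flagged, collapse = ", "))
  }
  excl <- apply_exclusions(logm, sheet, exclude)
  logm <- excl$logm
  sheet <- excl$sheet
  log_it("exclusions: %d sample(s) removed, %d remain", length(exclude), ncol(logm))

  imp <- config$imputation
  imp$base_seed <- config$seed + 100L
  collection <- build_dataset_collection(logm, imp)
  results <- analyze_collection(collection, sheet)
  calls <- call_de(results, config$thresholds)
  summary <- summarize_calls(calls)
  log_it("consensus: %s",
         paste(sprintf("%s: %d DE", summary$per_contrast$contrast,
                       summary$per_contrast$n_de), collapse = "; "))

  volcano <- do.call(rbind, lapply(names(contrast_specs()), function(ct) {
    v <- volcano_table(results, ct, dataset = 1L, thresholds = config$thresholds)
    v$contrast <- ct
    v
  }))

  clustering <- NULL
  if (length(summary$union) >= 2L) {
    de_mat <- collection$datasets[[2]]$matrix[summary$union, , drop = FALSE]
    clustering <- tryCatch(cluster_proteins(standardize(de_mat)),
                           error = function(e) {
                             log_it("clustering skipped: %s", conditionMessage(e))
                             NULL
                           })
  }

  enrichment <- NULL
  if (!is.null(config$gmt_path)) {
    db <- read_gene_sets(config$gmt_path)
    gene_of <- stats::setNames(filt$annotations$gene, filt$annotations$accession)
    background <- unique(gene_of[rownames(logm)])
    de_genes <- unique(gene_of[summary$union])
    enrichment <- fisher_enrichment(de_genes, background, db)
    enrichment_sig <- filter_terms(enrichment, config$enrichment_q_max,
                                   config$enrichment_min_de)
    log_it("enrichment: %d/%d terms pass the reporting filter",
           nrow(enrichment_sig), nrow(enrichment))
  }

  paths <- list(
    results = write_tsv(results, file.path(config$out_dir, "contrast_results.tsv")),
    calls = write_tsv(calls, file.path(config$out_dir, "consensus_calls.tsv")),
    summary = file.path(config$out_dir, "summary.json"),
    volcano = write_tsv(volcano, file.path(config$out_dir, "volcano.tsv")),
    qc_scores = write_tsv(
      data.frame(sample_id = rownames(qc$scores), qc$scores,
                 stringsAsFactors = FALSE),
      file.path(config$out_dir, "qc_scores.tsv")),
    log = file.path(config$out_dir, "run.log"),
    provenance = file.path(config$out_dir, "provenance.json")
  )
  jsonlite::write_json(summary$per_contrast, paths$summary, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(enrichment)) {
    paths$enrichment <- write_tsv(enrichment,
                                  file.path(config$out_dir, "enrichment.tsv"))
  }
  if (!is.null(clustering)) {
    paths$leaf_order <- file.path(config$out_dir, "clustering_leaf_order.txt")
    writeLines(clustering$leaf_order, paths$leaf_order)
  }

  provenance <- list(
    package = "proteoconsensus",
    version = as.character(utils::packageVersion("proteoconsensus")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    imputation_seeds = imp$base_seed + seq_len(imp$n_imputations),
    thresholds = unclass(config$thresholds),
    imputation = unclass(imp),
    excluded_samples = exclude,
    flagged_samples = as.character(flagged)
  )
  jsonlite::write_json(provenance, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, paths$log)

  invisible(list(qc = qc, flagged = flagged, collection = collection,
                 results = results, calls = calls, summary = summary,
                 volcano = volcano, clustering = clustering,
                 enrichment = enrichment, sheet = sheet, paths = paths,
                 provenance = provenance))
}
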