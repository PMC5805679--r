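#' Build and validate a pipeline configuration
#'
#' Collects every input path, contrast and threshold the five analysis
#' stages need, with the study conventions as defaults (FDR 0.05, ANOVA
#' S0 0.4, t-test S0 0.5, imputation width 0.3 / downshift 1.8, histogram
#' bin width 0.1). Validation runs before any stage.
#'
#' @param counts Path to the gene x sample counts TSV.
#' @param samples Path to the sample table TSV (columns `sample_id`, `group`,
#'   `assay`; assays `rna` and `protein`).
#' @param contrast `c(groupA, groupB)` for the enrichment Wald test.
#' @param fasta,regions Transcript FASTA and region-table paths for motif
#'   scanning.
#' @param intensities Path to the protein intensities TSV.
#' @param gmt Path to a GMT category file for over-representation analysis.
#' @param out_dir Output directory (created if absent).
#' @param fdr_threshold,s0_anova,s0_ttest,impute_width,impute_downshift,bin_width
#'   Analysis thresholds; defaults are the study conventions.
#' @param background_n Background cohort size for motif comparison.
#' @param seed Integer seed covering every stochastic step.
#' @return Validated config list of class `PipelineConfig`.
#' @export
pipeline_config <- function(counts, samples, contrast, fasta, regions,
                            intensities, gmt, out_dir,
                            fdr_threshold = 0.05, s0_anova = 0.4,
                            s0_ttest = 0.5, impute_width = 0.3,
                            impute_downshift = 1.8, bin_width = 0.1,
                            background_n = NULL, seed = 1) {
  cfg <- list(counts = counts, samples = samples, contrast = contrast,
              fasta = fasta, regions = regions, intensities = intensities,
              gmt = gmt, out_dir = out_dir, fdr_threshold = fdr_threshold,
              s0_anova = s0_anova, s0_ttest = s0_ttest,
              impute_width = impute_width, impute_downshift = impute_downshift,
              bin_width = bin_width, background_n = background_n, seed = seed)
  validate_pipeline_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()]; relative input paths are resolved against the YAML
#'   file's directory.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("counts", "samples", "fasta", "regions", "intensities", "gmt"))
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  if (!is.null(y$out_dir) && !grepl("^/", y$out_dir))
    y$out_dir <- file.path(base, y$out_dir)
  do.call(pipeline_config, y)
}

validate_pipeline_config <- function(cfg) {
  for (f in c("counts", "samples", "fasta", "regions", "intensities", "gmt")) {
    if (is.null(cfg[[f]])) stop_ripcor("config is missing '%s'", f)
    if (!file.exists(cfg[[f]])) stop_ripcor("config %s: file not found: %s", f, cfg[[f]])
  }
  if (length(cfg$contrast) != 2) stop_ripcor("contrast must have two group labels")
  num <- c("fdr_threshold", "s0_anova", "s0_ttest", "impute_width",
           "impute_downshift", "bin_width")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop_ripcor("config %s must be a non-negative number", f)
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the five stages in order — enrichment, motif scan, proteomics,
#' RNA-protein integration, over-representation analysis — writing each
#' stage's outputs as TSV under `out_dir` and recording inputs, outputs
#' (with MD5 checksums), parameters, seed and package version in a JSON run
#' manifest. Rerunning with an identical config and inputs reproduces
#' identical outputs; with `cache = TRUE`, stages whose input/parameter hash
#' matches the previous manifest are skipped. A stage failure aborts the run
#' with the stage name; the partial manifest is preserved.
#'
#' @param cfg A [pipeline_config()].
#' @param cache Reuse outputs of unchanged stages (default `FALSE`).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg, cache = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  prev <- if (cache && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL
  manifest <- list(package = "ripcor",
                   version = as.character(utils::packageVersion("ripcor")),
                   seed = cfg$seed, stages = list())
  state <- new.env()

  stages <- list(
    enrich = stage_enrich, scan = stage_scan, proteomics = stage_proteomics,
    integrate = stage_integrate, ora = stage_ora)

  for (nm in names(stages)) {
    key <- stage_key(cfg, nm)
    entry <- NULL
    if (!is.null(prev)) {
      pe <- Filter(function(s) identical(s$stage, nm), prev$stages)
      if (length(pe) == 1 && identical(pe[[1]]$key, key) &&
          all(file.exists(unlist(lapply(pe[[1]]$outputs, `[[`, "path"))))) {
        entry <- pe[[1]]
        entry$cached <- TRUE
      }
    }
    if (is.null(entry)) {
      message(sprintf("[%s] running", nm))
      outputs <- tryCatch(stages[[nm]](cfg, state), error = function(e) {
        manifest$stages[[length(manifest$stages) + 1]] <<-
          list(stage = nm, key = key, error = conditionMessage(e))
        write_manifest(manifest, manifest_path)
        stop_ripcor("pipeline aborted at stage '%s': %s", nm,
                    conditionMessage(e))
      })
      entry <- list(stage = nm, key = key, seed = cfg$seed,
                    params = stage_params(cfg, nm),
                    outputs = lapply(outputs, function(p)
                      list(path = p, md5 = unname(tools::md5sum(p)))))
    } else {
      message(sprintf("[%s] cached", nm))
      stage_reload(nm, cfg, state)
    }
    manifest$stages[[length(manifest$stages) + 1]] <- entry
  }
  write_manifest(manifest, manifest_path)
  invisible(manifest)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

stage_params <- function(cfg, nm) {
  switch(nm,
    enrich = cfg[c("contrast", "fdr_threshold")],
    scan = cfg[c("background_n", "seed")],
    proteomics = cfg[c("s0_anova", "impute_width", "impute_downshift", "seed")],
    integrate = cfg[c("bin_width", "fdr_threshold")],
    ora = cfg[c("fdr_threshold")])
}

stage_key <- function(cfg, nm) {
  inputs <- switch(nm,
    enrich = c(cfg$counts, cfg$samples),
    scan = c(cfg$fasta, cfg$regions),
    proteomics = c(cfg$intensities, cfg$samples),
    integrate = c(cfg$counts, cfg$intensities, cfg$samples),
    ora = c(cfg$gmt, cfg$counts, cfg$samples))
  paste(c(unname(tools::md5sum(inputs)),
          unlist(lapply(stage_params(cfg, nm), as.character))), collapse = ":")
}

read_sample_table <- function(path, assay_wanted) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  s <- s[s$assay == assay_wanted, , drop = FALSE]
  stats::setNames(s$group, s$sample_id)
}

stage_enrich <- function(cfg, state) {
  groups <- read_sample_table(cfg$samples, "rna")
  cm <- read_matrix(cfg$counts, "counts", groups = groups)
  res <- nb_wald_test(cm, contrast = cfg$contrast)
  state$cm <- cm
  state$enrichment <- res
  state$enriched <- res$gene_id[!is.na(res$fdr) & res$fdr < cfg$fdr_threshold &
                                  res$log2fc > 0]
  out <- file.path(cfg$out_dir, "enrichment.tsv")
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  list(out)
}

stage_scan <- function(cfg, state) {
  transcripts <- read_fasta_regions(cfg$fasta, cfg$regions)
  hits <- scan_cohort(transcripts)
  symbols <- vapply(transcripts, `[[`, "", "gene_symbol")
  state$tx_lengths <- stats::setNames(
    vapply(transcripts, function(t) nchar(t$sequence), 0L), symbols)
  bound_ids <- vapply(transcripts, `[[`, "", "transcript_id")[
    symbols %in% state$enriched]
  target <- transcripts[vapply(transcripts, `[[`, "", "transcript_id") %in% bound_ids]
  n_bg <- if (is.null(cfg$background_n))
    min(length(transcripts) - length(target), max(length(target), 1))
  else cfg$background_n
  summary_rows <- NULL
  if (length(target) >= 1 && n_bg >= 1) {
    bg <- sample_background(transcripts, n_bg, seed = cfg$seed,
                            exclude = bound_ids)
    ts <- summarize_cohort(hits[hits$transcript_id %in% bound_ids, ], target)
    bs <- summarize_cohort(
      hits[hits$transcript_id %in% vapply(bg, `[[`, "", "transcript_id"), ], bg)
    summary_rows <- compare_cohorts(ts, bs)
  }
  hits_out <- file.path(cfg$out_dir, "motif_hits.tsv")
  utils::write.table(hits, hits_out, sep = "\t", quote = FALSE, row.names = FALSE)
  outs <- list(hits_out)
  if (!is.null(summary_rows)) {
    sum_out <- file.path(cfg$out_dir, "motif_summary.tsv")
    utils::write.table(summary_rows, sum_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <- c(outs, list(sum_out))
  }
  outs
}

stage_proteomics <- function(cfg, state) {
  groups <- read_sample_table(cfg$samples, "protein")
  im <- read_matrix(cfg$intensities, "intensities", groups = groups)
  im <- filter_detection(im)
  im <- normalize_reference_scaling(im, colnames(im$intensities)[1])
  iml <- log2_transform(im)
  imp <- impute_downshifted(iml, width = cfg$impute_width,
                            downshift = cfg$impute_downshift, seed = cfg$seed)
  res <- moderated_test(imp$imputed, s0 = cfg$s0_anova, design = "anova",
                        fdr_threshold = cfg$fdr_threshold)
  state$prot_norm <- im             # raw scale, normalized, pre-imputation
  state$prot_deimputed <- de_impute(imp$imputed, imp$record)
  state$prot_results <- res
  out <- file.path(cfg$out_dir, "proteomics.tsv")
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  list(out)
}

stage_integrate <- function(cfg, state) {
  cm <- state$cm
  if (is.null(cm$lengths)) {
    # transcript models supply the lengths; genes without one drop out of RPKM
    lens <- state$tx_lengths[rownames(cm$counts)]
    keep <- !is.na(lens)
    if (!any(keep))
      stop_ripcor("no gene in the count matrix has a transcript model")
    cm <- count_matrix(cm$counts[keep, , drop = FALSE], cm$groups,
                       lengths = stats::setNames(lens[keep],
                                                 rownames(cm$counts)[keep]))
  }
  rp <- rpkm(cm)
  shared_samples <- intersect(colnames(rp),
                              colnames(state$prot_norm$intensities))
  if (length(shared_samples) < 3)
    stop_ripcor("RNA and protein layers share %d samples; need >= 3",
                length(shared_samples))
  prot_log2 <- state$prot_deimputed$intensities[, shared_samples, drop = FALSE]
  per_gene <- per_gene_correlation(rp[, shared_samples, drop = FALSE], prot_log2)
  per_sample <- per_sample_correlation(
    rp[, shared_samples, drop = FALSE],
    state$prot_norm$intensities[, shared_samples, drop = FALSE])
  split <- per_gene$gene_id %in% state$enriched
  dist <- if (sum(split) >= 2 && sum(!split) >= 2)
    correlation_distribution(per_gene$r, split) else
    correlation_distribution(per_gene$r)
  state$per_gene <- per_gene
  g_out <- file.path(cfg$out_dir, "per_gene_correlation.tsv")
  s_out <- file.path(cfg$out_dir, "per_sample_correlation.tsv")
  d_out <- file.path(cfg$out_dir, "correlation_distribution.tsv")
  utils::write.table(per_gene, g_out, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(per_sample, s_out, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(bin_lo = dist$breaks[-length(dist$breaks)],
               bin_hi = dist$breaks[-1], count = dist$counts),
    d_out, sep = "\t", quote = FALSE, row.names = FALSE)
  list(g_out, s_out, d_out)
}

stage_ora <- function(cfg, state) {
  categories <- read_gmt(cfg$gmt)
  universe <- state$enrichment$gene_id
  query <- intersect(state$enriched, universe)
  res <- hypergeometric_ora(query, categories, universe)
  out <- file.path(cfg$out_dir, "ora.tsv")
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  list(out)
}

# rebuild the in-memory state a cached stage would have produced
stage_reload <- function(nm, cfg, state) {
  if (nm == "enrich") {
    groups <- read_sample_table(cfg$samples, "rna")
    state$cm <- read_matrix(cfg$counts, "counts", groups = groups)
    res <- utils::read.delim(file.path(cfg$out_dir, "enrichment.tsv"))
    state$enrichment <- res
    state$enriched <- res$gene_id[!is.na(res$fdr) & res$fdr < cfg$fdr_threshold &
                                    res$log2fc > 0]
  } else if (nm == "scan") {
    transcripts <- read_fasta_regions(cfg$fasta, cfg$regions)
    state$tx_lengths <- stats::setNames(
      vapply(transcripts, function(t) nchar(t$sequence), 0L),
      vapply(transcripts, `[[`, "", "gene_symbol"))
  } else if (nm == "proteomics") {
    groups <- read_sample_table(cfg$samples, "protein")
    im <- read_matrix(cfg$intensities, "intensities", groups = groups)
    im <- filter_detection(im)
    im <- normalize_reference_scaling(im, colnames(im$intensities)[1])
    state$prot_norm <- im
    iml <- log2_transform(im)
    imp <- impute_downshifted(iml, width = cfg$impute_width,
                              downshift = cfg$impute_downshift, seed = cfg$seed)
    state$prot_deimputed <- de_impute(imp$imputed, imp$record)
    state$prot_results <- utils::read.delim(file.path(cfg$out_dir, "proteomics.tsv"))
  }
  invisible(NULL)
}
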