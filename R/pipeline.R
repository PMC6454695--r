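#' Run a pipeline stage from a configuration
#'
#' One entry point behind the command-line script: dispatches on
#' `config$mode` (`simulate`, `blood`, `lung`, `targeted`, `roh`), reads
#' the referenced inputs, runs the corresponding caller with any threshold
#' overrides, and writes a BED6 of called regions, a region summary TSV, a
#' filter attrition TSV and a JSON run manifest echoing the parameters
#' used. Every threshold appears exactly once in the config, with the
#' caller defaults applying when absent.
#'
#' @param config Named list, or path to a YAML file with the same keys.
#'   Common keys: `mode`, `out_dir`; mode-specific keys are the arguments
#'   of the corresponding caller plus input paths (`sample_sheet`,
#'   `deletions`, `snv_vcf`, `target_interval`, `vcf`, `sim`).
#' @return Invisibly, a list with the result object and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% stop("config$mode is required", call. = FALSE)
  if (!mode %in% c("simulate", "blood", "lung", "targeted", "roh")) {
    stop("unknown mode: ", mode, call. = FALSE)
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(mode,
         simulate = pipeline_simulate(config, out_dir),
         blood = pipeline_blood(config, out_dir),
         lung = pipeline_lung(config, out_dir),
         targeted = pipeline_targeted(config, out_dir),
         roh = pipeline_roh(config, out_dir))
}

pipeline_simulate <- function(config, out_dir) {
  sim <- do.call(sim_config, config$sim %||% list(seed = config$seed))
  deletion <- if (!is.null(config$deletions)) {
    read_deletions_bed(config$deletions)
  }
  study <- simulate_study(sim, deletion = deletion)
  paths <- write_simulated_study(study, out_dir,
                                 format = config$format %||% "cpg_report",
                                 deletion = deletion)
  write_manifest(out_dir, "simulate", unclass(sim), paths)
  invisible(list(result = study, paths = paths))
}

load_sheet_counts <- function(config) {
  samples <- read_sample_sheet(config$sample_sheet)
  if (is.null(samples$path)) {
    stop("sample sheet needs a 'path' column for pipeline runs",
         call. = FALSE)
  }
  # paths resolve relative to the sheet first, then as given
  base <- dirname(config$sample_sheet)
  rel <- file.path(base, samples$path)
  paths <- ifelse(file.exists(rel), rel, samples$path)
  counts <- lapply(seq_len(nrow(samples)), function(i) {
    read_counts_file(paths[i], samples$sample_id[i])
  })
  names(counts) <- samples$sample_id
  list(samples = samples, counts = counts)
}

pipeline_blood <- function(config, out_dir) {
  inp <- load_sheet_counts(config)
  args <- config[intersect(names(config),
                           names(formals(call_blood_dmrs)))]
  res <- do.call(call_blood_dmrs,
                 c(list(counts = inp$counts, samples = inp$samples), args))
  paths <- write_region_outputs(res, out_dir, "blood")
  invisible(list(result = res, paths = paths))
}

pipeline_lung <- function(config, out_dir) {
  inp <- load_sheet_counts(config)
  deletions <- read_deletions_bed(config$deletions)
  hemi <- config$hemi_sample %||%
    inp$samples$sample_id[inp$samples$category == "hemizygous_paternal"][1L]
  if (is.na(hemi)) stop("no hemizygous sample identified", call. = FALSE)
  del <- if (!is.null(config$deletion_index)) {
    deletions[config$deletion_index, , drop = FALSE]
  } else deletions[1L, , drop = FALSE]
  args <- config[intersect(names(config),
                           setdiff(names(formals(call_lung_dmrs)),
                                   c("counts", "hemi_sample", "deletion")))]
  res <- do.call(call_lung_dmrs,
                 c(list(counts = inp$counts, hemi_sample = hemi,
                        deletion = del), args))
  paths <- write_region_outputs(res, out_dir, "lung")
  invisible(list(result = res, paths = paths))
}

pipeline_targeted <- function(config, out_dir) {
  inp <- load_sheet_counts(config)
  blood_samples <- inp$samples[inp$samples$category %in%
                                 c("upd16mat", "upd16pat", "biparental"), ]
  pool <- intersect_loci(pool_by_category(inp$counts, blood_samples))
  calls <- classify_sites(pool, config$delta_threshold %||% 40)
  deletions <- read_deletions_bed(config$deletions)
  ti <- read_target_interval(config$target_interval)
  snvs <- if (!is.null(config$snv_vcf)) read_snv_vcf(config$snv_vcf)
  lung_calls <- NULL
  if (!is.null(config$lung)) {
    lung_res <- pipeline_lung(c(config$lung,
                                list(out_dir = file.path(out_dir, "lung"))),
                              file.path(out_dir, "lung"))
    lung_calls <- lung_res$result$calls
  }
  cand <- call_targeted_candidates(
    calls, pool, ti, snvs = snvs, lung_calls = lung_calls,
    deletions = deletions,
    min_concordant_sites = config$min_concordant_sites %||% 1)
  tsv <- file.path(out_dir, "targeted_candidates.tsv")
  write.table(cand, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- write_manifest(out_dir, "targeted",
                             list(delta_threshold =
                                    config$delta_threshold %||% 40),
                             tsv)
  invisible(list(result = cand, paths = c(tsv, manifest)))
}

pipeline_roh <- function(config, out_dir) {
  snvs <- read_snv_vcf(config$vcf)
  min_mb <- config$min_mb %||% 10
  rows <- list()
  for (s in unique(snvs$sample_id)) {
    runs <- detect_roh(snvs[snvs$sample_id == s, , drop = FALSE],
                       max_het_interrupts =
                         config$max_het_interrupts %||% 0,
                       min_snvs = config$min_snvs %||% 25)
    flag <- flag_isodisomy(runs, threshold_bp = min_mb * 1e6)
    rows[[s]] <- cbind(sample_id = s,
                       isodisomy = flag$isodisomy,
                       if (nrow(runs)) runs else
                         data.frame(chrom = NA, start = NA, end = NA,
                                    n_snvs = 0L, length_bp = 0L))
  }
  res <- do.call(rbind, rows)
  tsv <- file.path(out_dir, "roh.tsv")
  write.table(res, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- write_manifest(out_dir, "roh", list(min_mb = min_mb), tsv)
  invisible(list(result = res, paths = c(tsv, manifest)))
}

read_target_interval <- function(path) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(x[[1L]]),
             start = as.integer(x[[2L]]) + 1L,
             end = as.integer(x[[3L]]), stringsAsFactors = FALSE)[1L, ]
}

write_region_outputs <- function(res, out_dir, prefix) {
  bed <- file.path(out_dir, paste0(prefix, "_regions.bed"))
  write_regions_bed(res$regions, bed)
  tsv <- file.path(out_dir, paste0(prefix, "_regions.tsv"))
  write.table(res$regions, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  att <- file.path(out_dir, paste0(prefix, "_attrition.tsv"))
  write.table(attrition_report(res$attrition), att, sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- write_manifest(out_dir, prefix, res$params,
                             c(bed, tsv, att))
  c(bed, tsv, att, manifest)
}

#' Tabulate the filter attrition funnel
#'
#' Turns the named attrition counts a caller records into a two-column
#' stage/count table; counts are non-increasing along the region funnel.
#'
#' @param attrition Named numeric vector (component `attrition` of a
#'   `pod_dmr`).
#' @return data.frame with columns `stage` and `count`.
#' @export
attrition_report <- function(attrition) {
  data.frame(stage = names(attrition),
             count = as.integer(unname(attrition)),
             stringsAsFactors = FALSE)
}

write_manifest <- function(out_dir, mode, params, paths) {
  manifest <- file.path(out_dir, paste0(mode, "_manifest.json"))
  params <- params[!vapply(params, is.null, logical(1L))]
  jsonlite::write_json(list(mode = mode, parameters = params,
                            outputs = basename(paths)),
                       manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest
}
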