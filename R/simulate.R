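#' Configuration for the allele-specific methylation simulator
#'
#' Defines a synthetic chromosome segment of strand-resolved CpG cytosines
#' with maternal and paternal allele methylation probabilities, planted
#' parent-of-origin DMRs, and a read-sampling model (negative-binomial
#' coverage, binomial methylated counts, optional per-sample logit
#' jitter). Background sites have identical allele probabilities drawn
#' from a low/intermediate/high beta mixture, mimicking the bimodal
#' methylome; planted regions overwrite one parental probability to the
#' configured effect.
#'
#' @param n_sites Number of strand-resolved cytosine loci (even when
#'   `strand_pairs`).
#' @param chrom Chromosome label.
#' @param origin First dinucleotide position.
#' @param spacing_mean Mean gap (bp) between neighbouring dinucleotides.
#' @param prop_low,prop_high,prop_mid Background mixture proportions
#'   (must sum to 1).
#' @param shape_low,shape_high,shape_mid Two-element beta shape vectors of
#'   the mixture components.
#' @param n_regions Planted DMRs.
#' @param region_width Width of each planted region, in sites.
#' @param effect_high,effect_low Allele methylation probabilities of the
#'   methylated and unmethylated parental allele inside planted regions.
#' @param mean_coverage,dispersion Negative-binomial coverage model
#'   (`mu`, `size`); dispersion emulates uneven capture.
#' @param samples_per_category Named integer vector of sample counts per
#'   category.
#' @param jitter_sd Per-sample, per-site SD of gaussian noise on the logit
#'   of the expected methylation (technical/biological variability).
#' @param strand_pairs Emit both strand cytosines per dinucleotide, with
#'   independent read draws from a shared probability.
#' @param seed Mandatory RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 5000, chrom = "chr16", origin = 1000000,
                       spacing_mean = 100,
                       prop_low = 0.45, prop_high = 0.45, prop_mid = 0.10,
                       shape_low = c(2, 18), shape_high = c(18, 2),
                       shape_mid = c(5, 5),
                       n_regions = 10, region_width = 8,
                       effect_high = 0.95, effect_low = 0.05,
                       mean_coverage = 30, dispersion = 8,
                       samples_per_category = c(upd16mat = 2,
                                                upd16pat = 2,
                                                biparental = 2),
                       jitter_sd = 0.25, strand_pairs = TRUE,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config: seed is mandatory", call. = FALSE)
  props <- c(prop_low, prop_high, prop_mid)
  if (abs(sum(props) - 1) > 1e-8) {
    stop("mixture proportions must sum to 1", call. = FALSE)
  }
  if (n_sites < 1 || mean_coverage <= 0 || dispersion <= 0 ||
      spacing_mean < 2 || region_width < 1) {
    stop("sim_config: counts and rates must be positive", call. = FALSE)
  }
  if (strand_pairs && n_sites %% 2 != 0) {
    stop("n_sites must be even with strand_pairs", call. = FALSE)
  }
  if (n_regions > 0 && n_regions * (region_width + 2) > n_sites) {
    stop("planted regions do not fit without overlapping", call. = FALSE)
  }
  bad <- setdiff(names(samples_per_category), POD_CATEGORIES)
  if (length(bad)) stop("unknown category: ", bad[1L], call. = FALSE)
  structure(list(
    n_sites = as.integer(n_sites), chrom = chrom,
    origin = as.integer(origin), spacing_mean = spacing_mean,
    prop_low = prop_low, prop_high = prop_high, prop_mid = prop_mid,
    shape_low = shape_low, shape_high = shape_high, shape_mid = shape_mid,
    n_regions = as.integer(n_regions),
    region_width = as.integer(region_width),
    effect_high = effect_high, effect_low = effect_low,
    mean_coverage = mean_coverage, dispersion = dispersion,
    samples_per_category = samples_per_category,
    jitter_sd = jitter_sd, strand_pairs = strand_pairs,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate per-site allele methylation ground truth
#'
#' Lays out the site grid, draws background methylation from the
#' configured beta mixture with identical maternal and paternal
#' probabilities, and plants non-overlapping DMRs by overwriting one
#' parental probability. Planted regions are spread over equal blocks of
#' the grid with at least one background site between them; directions
#' alternate maternal/paternal. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `pod_truth`: list with `sites` (`chrom`,
#'   `pos`, `strand`, `p_m`, `p_p`, `region_id`), `regions` (planted
#'   intervals with direction and site span) and `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sites
  if (config$strand_pairs) {
    ndi <- n %/% 2L
    gaps <- 2L + stats::rgeom(ndi, 1 / (config$spacing_mean - 1))
    starts <- config$origin + cumsum(c(0L, gaps[-ndi]))
    pos <- as.integer(rbind(starts, starts + 1L))
    strand <- rep(c("+", "-"), ndi)
  } else {
    gaps <- 2L + stats::rgeom(n, 1 / (config$spacing_mean - 1))
    pos <- as.integer(config$origin + cumsum(c(0L, gaps[-n])))
    strand <- rep("+", n)
  }

  comp <- sample.int(3L, if (config$strand_pairs) n %/% 2L else n,
                     replace = TRUE,
                     prob = c(config$prop_low, config$prop_high,
                              config$prop_mid))
  shapes <- list(config$shape_low, config$shape_high, config$shape_mid)
  p_bg <- vapply(comp, function(k) {
    stats::rbeta(1L, shapes[[k]][1L], shapes[[k]][2L])
  }, numeric(1L))
  if (config$strand_pairs) p_bg <- rep(p_bg, each = 2L)

  p_m <- p_bg
  p_p <- p_bg
  region_id <- integer(length(pos))
  regions <- NULL
  k <- config$n_regions
  if (k > 0) {
    w <- config$region_width
    block <- n %/% k
    starts_idx <- integer(k)
    for (r in seq_len(k)) {
      lo <- (r - 1L) * block + 2L         # one-site margin at block edges
      hi <- r * block - w
      s <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
      if (config$strand_pairs && s %% 2 == 0L) s <- s - 1L
      starts_idx[r] <- s
    }
    if (any(diff(starts_idx) < w + 1L)) {
      stop("planted regions overlap; reduce n_regions or region_width",
           call. = FALSE)
    }
    direction <- rep(c("maternal_methylated", "paternal_methylated"),
                     length.out = k)
    for (r in seq_len(k)) {
      idx <- starts_idx[r]:(starts_idx[r] + w - 1L)
      region_id[idx] <- r
      if (direction[r] == "maternal_methylated") {
        p_m[idx] <- config$effect_high
        p_p[idx] <- config$effect_low
      } else {
        p_m[idx] <- config$effect_low
        p_p[idx] <- config$effect_high
      }
    }
    regions <- data.frame(
      region_id = seq_len(k), chrom = config$chrom,
      start = pos[starts_idx], end = pos[starts_idx + w - 1L],
      direction = direction, first_site = starts_idx,
      last_site = starts_idx + w - 1L, width_sites = w,
      stringsAsFactors = FALSE)
  } else {
    regions <- data.frame(region_id = integer(), chrom = character(),
                          start = integer(), end = integer(),
                          direction = character(), first_site = integer(),
                          last_site = integer(), width_sites = integer(),
                          stringsAsFactors = FALSE)
  }
  sites <- data.frame(chrom = config$chrom, pos = pos, strand = strand,
                      p_m = p_m, p_p = p_p, region_id = region_id,
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, regions = regions, config = config),
            class = "pod_truth")
}

#' Flip the direction of planted regions
#'
#' Produces a second tissue's truth sharing positions and background with
#' the input but with the selected planted regions' parental probabilities
#' swapped — emulating tissue-specific inversion of a parent-of-origin
#' methylation bias.
#'
#' @param truth A `pod_truth`.
#' @param region_ids Planted regions to invert (default: all).
#' @return A `pod_truth` with flipped regions.
#' @export
invert_truth <- function(truth, region_ids = truth$regions$region_id) {
  flip_sites <- truth$sites$region_id %in% region_ids
  tmp <- truth$sites$p_m[flip_sites]
  truth$sites$p_m[flip_sites] <- truth$sites$p_p[flip_sites]
  truth$sites$p_p[flip_sites] <- tmp
  flip <- truth$regions$region_id %in% region_ids
  truth$regions$direction[flip] <- ifelse(
    truth$regions$direction[flip] == "maternal_methylated",
    "paternal_methylated", "maternal_methylated")
  truth
}

#' Draw per-sample CpG counts from a simulated truth
#'
#' Expected methylation per site is `p_m` for `upd16mat`, `p_p` for
#' `upd16pat`, their mean for `biparental`, and, for
#' `hemizygous_paternal`, `p_p` inside the (maternal) deletion interval
#' with thinned (halved) coverage and the biparental mean outside.
#' Coverage is negative-binomial; methylated counts are binomial at the
#' (optionally logit-jittered) expected methylation.
#'
#' @param truth A `pod_truth`.
#' @param category Sample category.
#' @param config The [sim_config()] (defaults to the truth's).
#' @param deletion One-row deletion data.frame (`chrom`, `start`, `end`),
#'   required for `hemizygous_paternal`.
#' @param seed Optional seed; by default draws continue from the current
#'   RNG state so that a study is reproducible from one seed.
#' @return A count table (`chrom`, `pos`, `strand`, `meth`, `unmeth`).
#' @export
sample_counts <- function(truth, category, config = truth$config,
                          deletion = NULL, seed = NULL) {
  category <- match.arg(category, POD_CATEGORIES)
  if (!is.null(seed)) set.seed(seed)
  s <- truth$sites
  n <- nrow(s)
  pi <- switch(category,
    upd16mat = s$p_m,
    upd16pat = s$p_p,
    biparental = (s$p_m + s$p_p) / 2,
    hemizygous_paternal = {
      if (is.null(deletion)) {
        stop("hemizygous_paternal sampling needs a deletion interval",
             call. = FALSE)
      }
      inside <- s$chrom == deletion$chrom[1L] &
        s$pos >= deletion$start[1L] & s$pos <= deletion$end[1L]
      ifelse(inside, s$p_p, (s$p_m + s$p_p) / 2)
    })
  coverage <- stats::rnbinom(n, size = config$dispersion,
                             mu = config$mean_coverage)
  if (category == "hemizygous_paternal") {
    inside <- s$chrom == deletion$chrom[1L] &
      s$pos >= deletion$start[1L] & s$pos <= deletion$end[1L]
    coverage[inside] <- stats::rbinom(sum(inside), coverage[inside], 0.5)
  }
  if (config$jitter_sd > 0) {
    eps <- 1e-9
    pi <- stats::plogis(stats::qlogis(pmin(pmax(pi, eps), 1 - eps)) +
                          stats::rnorm(n, 0, config$jitter_sd))
  }
  meth <- stats::rbinom(n, coverage, pi)
  data.frame(chrom = s$chrom, pos = s$pos, strand = s$strand,
             meth = as.integer(meth),
             unmeth = as.integer(coverage - meth),
             stringsAsFactors = FALSE)
}

#' Simulate a complete study
#'
#' Draws the truth and one count table per sample, in a fixed category and
#' sample order, so the whole study is reproducible from the config seed.
#' Sample ids are `<category>_<i>`; tissue is `lung` when a hemizygous
#' carrier is simulated, `blood` otherwise.
#'
#' @param config A [sim_config()].
#' @param deletion Deletion interval, required when `samples_per_category`
#'   includes `hemizygous_paternal`.
#' @param truth Optional pre-built `pod_truth` (e.g. an inverted-tissue
#'   variant); the RNG is still seeded from the config.
#' @return List with `truth`, `samples` (sample sheet) and `counts`
#'   (named list of count tables).
#' @export
simulate_study <- function(config, deletion = NULL, truth = NULL) {
  if (is.null(truth)) {
    truth <- simulate_truth(config)   # seeds the RNG
  } else {
    set.seed(config$seed)
  }
  spc <- config$samples_per_category
  tissue <- if ("hemizygous_paternal" %in% names(spc)) "lung" else "blood"
  samples <- do.call(rbind, lapply(names(spc), function(cat) {
    data.frame(sample_id = paste0(cat, "_", seq_len(spc[[cat]])),
               category = cat, tissue = tissue, stringsAsFactors = FALSE)
  }))
  counts <- lapply(seq_len(nrow(samples)), function(i) {
    sample_counts(truth, samples$category[i], config, deletion)
  })
  names(counts) <- samples$sample_id
  list(truth = truth, samples = samples, counts = counts)
}

#' Inject heterozygous SNVs for masking tests
#'
#' Builds synthetic het SNV calls at the requested positions for the
#' designated samples (a stand-in for variant calls from bisulfite reads).
#'
#' @param truth A `pod_truth` (supplies the chromosome).
#' @param positions Integer positions of the variants.
#' @param sample_ids Samples carrying the variants.
#' @return SNV data.frame in the [read_snv_vcf()] layout.
#' @export
inject_snvs <- function(truth, positions, sample_ids) {
  if (!length(positions)) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), genotype = character(),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(pos = as.integer(positions), sample_id = sample_ids,
                      stringsAsFactors = FALSE)
  data.frame(chrom = truth$config$chrom, pos = grid$pos, ref = "C",
             alt = "T", sample_id = grid$sample_id, genotype = "het",
             stringsAsFactors = FALSE)
}

#' Write a simulated study to disk
#'
#' Serializes per-sample count files (CpG-report format by default, which
#' preserves strand; Bismark coverage optional), a sample sheet with a
#' `path` column, the ground-truth site and region tables, and, when
#' given, a deletions BED.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param format `"cpg_report"` or `"coverage"`.
#' @param deletion Optional deletion data.frame with `deleted_parent` (and
#'   optionally `sample_id`).
#' @return Invisibly, the paths written.
#' @export
write_simulated_study <- function(study, dir,
                                  format = c("cpg_report", "coverage"),
                                  deletion = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "cpg_report") ".CpG_report.txt" else ".cov"
  paths <- character(0)
  samples <- study$samples
  # paths in the sheet are relative to the sheet itself
  samples$path <- paste0(samples$sample_id, ext)
  for (i in seq_len(nrow(samples))) {
    target <- file.path(dir, samples$path[i])
    if (format == "cpg_report") {
      write_cpg_report(study$counts[[samples$sample_id[i]]], target)
    } else {
      write_coverage_file(study$counts[[samples$sample_id[i]]], target)
    }
    paths <- c(paths, target)
  }
  sheet <- file.path(dir, "samples.tsv")
  write.table(samples, sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_sites <- file.path(dir, "truth_sites.tsv")
  write.table(study$truth$sites, truth_sites, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_regions <- file.path(dir, "truth_regions.tsv")
  write.table(study$truth$regions, truth_regions, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths <- c(paths, sheet, truth_sites, truth_regions)
  if (!is.null(deletion)) {
    dbed <- file.path(dir, "deletions.bed")
    out <- data.frame(deletion$chrom, deletion$start - 1L, deletion$end,
                      deletion$deleted_parent,
                      deletion$sample_id %||% ".")
    write.table(out, dbed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths <- c(paths, dbed)
  }
  invisible(paths)
}

#' Score called regions against planted truth
#'
#' A planted region counts as recovered when a called region of the same
#' direction overlaps it; sensitivity is the recovered fraction. Called
#' regions overlapping no planted region are false regions (reported
#' overall and at the >= `false_min_sites` size).
#'
#' @param regions Called region table (`chrom`, `start`, `end`,
#'   `direction`, `n_sites`).
#' @param truth A `pod_truth`.
#' @param false_min_sites Site count from which a false region is counted
#'   in `n_false_large` (default 5).
#' @param max_boundary_offset_sites When finite, a planted region only
#'   counts as recovered if the called boundaries land within this many
#'   grid sites of the planted ones.
#' @return List: `sensitivity`, `n_recovered`, `n_planted`, `n_false`,
#'   `n_false_large`.
#' @export
evaluate_recovery <- function(regions, truth, false_min_sites = 5,
                              max_boundary_offset_sites = Inf) {
  planted <- truth$regions
  if (nrow(planted) == 0) {
    return(list(sensitivity = NA_real_, n_recovered = 0L, n_planted = 0L,
                n_false = nrow(regions),
                n_false_large = sum(regions$n_sites >= false_min_sites)))
  }
  pos_index <- function(p) {
    findInterval(p, truth$sites$pos)
  }
  recovered <- logical(nrow(planted))
  false_hit <- rep(TRUE, nrow(regions))
  for (i in seq_len(nrow(planted))) {
    for (j in seq_len(nrow(regions))) {
      overlap <- regions$chrom[j] == planted$chrom[i] &&
        regions$start[j] <= planted$end[i] &&
        regions$end[j] >= planted$start[i]
      if (!overlap) next
      false_hit[j] <- FALSE
      if (regions$direction[j] != planted$direction[i]) next
      if (is.finite(max_boundary_offset_sites)) {
        off_s <- abs(pos_index(regions$start[j]) - planted$first_site[i])
        off_e <- abs(pos_index(regions$end[j]) - planted$last_site[i])
        if (off_s > max_boundary_offset_sites ||
            off_e > max_boundary_offset_sites) next
      }
      recovered[i] <- TRUE
    }
  }
  list(sensitivity = mean(recovered),
       n_recovered = sum(recovered),
       n_planted = nrow(planted),
       n_false = sum(false_hit),
       n_false_large = sum(false_hit &
                             regions$n_sites >= false_min_sites))
}
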