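#' Restrict counts to a deletion interval
#'
#' Keeps the loci with `start <= pos <= end` (1-based inclusive on both
#' sides) on the interval's chromosome.
#'
#' @param counts Per-sample count table.
#' @param interval One-row data.frame (or list) with `chrom`, `start`,
#'   `end` in 1-based inclusive coordinates.
#' @return The restricted count table.
#' @export
restrict_to_interval <- function(counts, interval) {
  validate_counts(counts)
  keep <- counts$chrom == interval$chrom[1L] &
    counts$pos >= interval$start[1L] & counts$pos <= interval$end[1L]
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("no loci inside interval ", interval$chrom[1L], ":",
            interval$start[1L], "-", interval$end[1L], call. = FALSE)
  }
  attr(out, "sample_id") <- attr(counts, "sample_id")
  out
}

#' Keep loci captured at least once in every sample
#'
#' The lenient hemizygous-mode prefilter: a locus survives when every
#' listed sample has coverage of at least one read there.
#'
#' @param counts Named list of per-sample count tables.
#' @param sample_ids Samples that must all cover a locus (default: all).
#' @return data.frame `chrom`, `pos`, `strand` of surviving loci,
#'   position-sorted.
#' @export
prefilter_covered_everywhere <- function(counts,
                                         sample_ids = names(counts)) {
  if (length(sample_ids) < 2) {
    stop("need at least two samples", call. = FALSE)
  }
  counts <- counts[sample_ids]
  covered <- lapply(counts, function(x) {
    locus_key(x)[x$meth + x$unmeth >= 1L]
  })
  keys <- Reduce(intersect, covered)
  ref <- counts[[1L]]
  out <- ref[match(keys, locus_key(ref)), c("chrom", "pos", "strand")]
  out <- out[locus_order(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify loci from a hemizygous-deletion contrast
#'
#' At each locus the hemizygous carrier's percent methylation is compared
#' with each dizygous control. A locus qualifies when every
#' `|hemi - control|` difference is at least `delta_threshold` and all
#' differences share one sign. When the hemizygous sample is *more*
#' methylated than every control, the exposed (non-deleted) parental
#' allele is called methylated; when *less* methylated, the deleted
#' parent's allele is: the dizygous controls average both alleles, so the
#' missing methylation must have sat on the allele the carrier lost.
#'
#' @param hemi_pct Numeric vector of hemizygous-sample percents.
#' @param ctrl_pct Matrix (loci x controls) of control percents.
#' @param deleted_parent `"maternal"` or `"paternal"`: origin of the
#'   deleted allele in the carrier.
#' @param delta_threshold Minimum absolute percent difference versus each
#'   control (default 20).
#' @param loci Optional data.frame `chrom`, `pos`, `strand` carried
#'   through to the result.
#' @return data.frame of hemizygous site calls with `qualifies`,
#'   `direction` (`maternal_methylated` / `paternal_methylated` / `none`)
#'   and the per-control deltas.
#' @export
classify_hemi_sites <- function(hemi_pct, ctrl_pct, deleted_parent,
                                delta_threshold = 20, loci = NULL) {
  deleted_parent <- match.arg(deleted_parent, c("maternal", "paternal"))
  ctrl_pct <- as.matrix(ctrl_pct)
  stopifnot(length(hemi_pct) == nrow(ctrl_pct))
  deltas <- hemi_pct - ctrl_pct
  ok <- !is.na(hemi_pct) & !apply(is.na(ctrl_pct), 1L, any)
  big <- apply(abs(deltas) >= delta_threshold, 1L, all)
  above <- apply(deltas > 0, 1L, all)
  below <- apply(deltas < 0, 1L, all)
  qualifies <- ok & big & (above | below)
  exposed <- if (deleted_parent == "maternal") "paternal" else "maternal"
  meth_parent <- ifelse(qualifies, ifelse(above, exposed, deleted_parent),
                        "none")
  direction <- ifelse(meth_parent == "none", "none",
                      paste0(meth_parent, "_methylated"))
  out <- data.frame(
    pct_hemi = hemi_pct,
    delta_min = apply(abs(deltas), 1L, min),
    qualifies = qualifies,
    direction = direction,
    stringsAsFactors = FALSE
  )
  if (!is.null(loci)) out <- cbind(loci[, c("chrom", "pos", "strand")], out)
  rownames(out) <- NULL
  out
}

#' Collapse and filter hemizygous-mode regions
#'
#' Adjacent qualifying same-direction calls are collapsed (the
#' single-discordant merge is off by default in this mode); regions are
#' kept when they contain at least `min_dmc` differentially methylated
#' cytosines and every sample's median per-site coverage over the member
#' sites is at least `min_median_cov`.
#'
#' @param calls Position-sorted hemizygous site calls
#'   ([classify_hemi_sites()] with `loci` supplied).
#' @param coverage Matrix (loci x samples) of per-sample coverage aligned
#'   with `calls`.
#' @param min_dmc Minimum qualifying cytosines per region (default 5).
#' @param min_median_cov Minimum per-sample median coverage (default 7).
#' @param merge_single_discordant Default `FALSE` in this mode.
#' @return A `pod_regions` with per-sample median coverage columns;
#'   attribute `attrition` as in [filter_blood_regions()].
#' @export
call_lung_regions <- function(calls, coverage, min_dmc = 5,
                              min_median_cov = 7,
                              merge_single_discordant = FALSE) {
  x <- collapse_regions(calls, merge_single_discordant)
  reg <- x$regions
  nr <- nrow(reg)
  coverage <- as.matrix(coverage)
  if (is.null(colnames(coverage))) {
    colnames(coverage) <- paste0("sample", seq_len(ncol(coverage)))
  }
  med <- matrix(NA_real_, nr, ncol(coverage),
                dimnames = list(NULL, colnames(coverage)))
  for (r in seq_len(nr)) {
    idx <- x$members[[r]]
    med[r, ] <- apply(coverage[idx, , drop = FALSE], 2L, stats::median)
  }
  pass_sites <- reg$n_sites >= min_dmc
  pass_cov <- apply(med >= min_median_cov, 1L, all)
  if (nr == 0) pass_cov <- logical(0)
  keep <- pass_sites & pass_cov
  colnames(med) <- paste0("median_cov_", colnames(coverage))
  x$regions <- cbind(reg, as.data.frame(med))[keep, , drop = FALSE]
  rownames(x$regions) <- NULL
  x$members <- x$members[keep]
  attr(x, "attrition") <- c(
    regions_in = nr,
    removed_site_count = sum(!pass_sites),
    removed_median_coverage = sum(pass_sites & !pass_cov),
    regions_out = sum(keep)
  )
  x
}

#' Call parent-of-origin DMRs from a hemizygous deletion carrier
#'
#' End-to-end hemizygous mode: restrict all samples to the deleted
#' interval, keep loci captured at least once in every sample, compare the
#' carrier's percent methylation against each dizygous control
#' ([classify_hemi_sites()]), collapse qualifying same-direction sites and
#' apply the site-count and per-sample median-coverage filters.
#'
#' @param counts Named list of per-sample count tables (carrier and
#'   controls).
#' @param hemi_sample Sample id of the deletion carrier.
#' @param deletion One-row data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive) and `deleted_parent`.
#' @param control_samples Sample ids of the dizygous controls (default:
#'   all other samples in `counts`).
#' @inheritParams classify_hemi_sites
#' @inheritParams call_lung_regions
#' @return A `pod_dmr` (mode `"lung"`).
#' @export
call_lung_dmrs <- function(counts, hemi_sample, deletion,
                           control_samples = setdiff(names(counts),
                                                     hemi_sample),
                           delta_threshold = 20, min_dmc = 5,
                           min_median_cov = 7,
                           merge_single_discordant = FALSE) {
  stopifnot(hemi_sample %in% names(counts),
            all(control_samples %in% names(counts)))
  use <- c(hemi_sample, control_samples)
  restricted <- lapply(counts[use], restrict_to_interval, deletion)
  n_in <- length(unique(unlist(lapply(restricted, locus_key))))
  loci <- suppressWarnings(prefilter_covered_everywhere(restricted, use))
  keys <- locus_key(loci)
  pct <- sapply(use, function(s) {
    x <- restricted[[s]]
    i <- match(keys, locus_key(x))
    percent_methylation(x$meth[i], x$unmeth[i])
  })
  pct <- matrix(pct, nrow = length(keys), dimnames = list(NULL, use))
  coverage <- sapply(use, function(s) {
    x <- restricted[[s]]
    i <- match(keys, locus_key(x))
    x$meth[i] + x$unmeth[i]
  })
  coverage <- matrix(coverage, nrow = length(keys),
                     dimnames = list(NULL, use))
  calls <- classify_hemi_sites(
    hemi_pct = pct[, hemi_sample],
    ctrl_pct = pct[, control_samples, drop = FALSE],
    deleted_parent = deletion$deleted_parent[1L],
    delta_threshold = delta_threshold, loci = loci
  )
  filtered <- call_lung_regions(calls, coverage, min_dmc, min_median_cov,
                                merge_single_discordant)
  attrition <- c(
    loci_in_interval = n_in,
    loci_covered_everywhere = nrow(loci),
    sites_qualifying = sum(calls$qualifies),
    attr(filtered, "attrition")
  )
  structure(list(
    regions = filtered$regions,
    members = filtered$members,
    calls = calls,
    coverage = coverage,
    deletion = deletion,
    mode = "lung",
    params = list(delta_threshold = delta_threshold, min_dmc = min_dmc,
                  min_median_cov = min_median_cov,
                  merge_single_discordant = merge_single_discordant,
                  hemi_sample = hemi_sample,
                  control_samples = control_samples),
    attrition = attrition
  ), class = "pod_dmr")
}
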