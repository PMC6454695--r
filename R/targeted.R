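#' Scan a target interval for small (2-4 site) candidate regions
#'
#' Re-runs the trio-mode collapse on blood site calls and keeps regions
#' with two to four qualifying sites lying entirely within the target
#' interval — regions that the main trio mode discards for falling short
#' of its five-site rule. The trio coverage and intra-category
#' concordance filters still apply.
#'
#' @param calls Blood site calls ([classify_sites()]).
#' @param pool The `pod_pool` the calls were classified from.
#' @param target_interval One-row data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. a chromosome band.
#' @param min_sites,max_sites Site-count window (defaults 2 and 4).
#' @inheritParams filter_blood_regions
#' @param merge_single_discordant see [collapse_regions()].
#' @return A data.frame of candidates: the region columns plus logical
#'   flags `snv_masked`, `overlaps_hemizygous_interval`, `lung_concordant`,
#'   `multi_cpg`, `promoted` (all initialized to `NA`/`FALSE` until
#'   [mask_snv_regions()] and [cross_tissue_concordance()] fill them), with
#'   member-site tables in attribute `members`.
#' @export
scan_small_regions <- function(calls, pool, target_interval, min_sites = 2,
                               max_sites = 4, min_median_cov = 10,
                               intra_discord = 50, intra_cov = 3,
                               merge_single_discordant = TRUE) {
  collapsed <- collapse_regions(calls, merge_single_discordant)
  filtered <- blood_region_filter(collapsed, pool, min_sites = min_sites,
                                  max_sites = max_sites,
                                  min_median_cov = min_median_cov,
                                  intra_discord = intra_discord,
                                  intra_cov = intra_cov)
  reg <- filtered$regions
  inside <- reg$chrom == target_interval$chrom[1L] &
    reg$start >= target_interval$start[1L] &
    reg$end <= target_interval$end[1L]
  reg <- reg[inside, , drop = FALSE]
  members <- filtered$members[inside]
  rownames(reg) <- NULL
  if (nrow(reg)) {
    reg$snv_masked <- NA
    reg$overlaps_hemizygous_interval <- NA
    reg$lung_concordant <- NA
    reg$multi_cpg <- NA
    reg$promoted <- FALSE
  } else {
    reg[c("snv_masked", "overlaps_hemizygous_interval", "lung_concordant",
          "multi_cpg")] <- logical(0)
    reg$promoted <- logical(0)
  }
  member_sites <- lapply(members, function(i) {
    filtered$calls[i, c("chrom", "pos", "strand"), drop = FALSE]
  })
  attr(reg, "members") <- member_sites
  reg
}

# Genomic footprint of the CpG dinucleotide each member cytosine belongs
# to: a forward-strand C at pos covers pos and pos+1; a reverse-strand C
# at pos covers pos-1 and pos.
cpg_footprint <- function(sites) {
  start <- ifelse(sites$strand == "-", sites$pos - 1L, sites$pos)
  data.frame(chrom = sites$chrom, start = start, end = start + 1L,
             stringsAsFactors = FALSE)
}

#' Flag candidates whose CpGs carry SNVs
#'
#' A candidate is masked when any supplied SNV (union over all samples)
#' overlaps either base of a member CpG dinucleotide: a variant at the C or
#' the G can destroy the CpG and mimic a methylation difference. Masking
#' drops the whole candidate from promotion.
#'
#' @param candidates Candidates from [scan_small_regions()].
#' @param snvs SNV calls ([read_snv_vcf()]); `NULL` or empty leaves all
#'   candidates unmasked.
#' @return `candidates` with the `snv_masked` flag filled in.
#' @export
mask_snv_regions <- function(candidates, snvs) {
  members <- attr(candidates, "members")
  if (nrow(candidates) == 0) return(candidates)
  if (is.null(snvs) || nrow(snvs) == 0) {
    candidates$snv_masked <- FALSE
    return(candidates)
  }
  snv_gr <- GenomicRanges::GRanges(snvs$chrom,
                                   IRanges::IRanges(snvs$pos, snvs$pos))
  candidates$snv_masked <- vapply(members, function(sites) {
    fp <- cpg_footprint(sites)
    fp_gr <- GenomicRanges::GRanges(fp$chrom,
                                    IRanges::IRanges(fp$start, fp$end))
    length(GenomicRanges::findOverlaps(fp_gr, snv_gr)) > 0
  }, logical(1L))
  candidates
}

#' Promote candidates concordant with the hemizygous lung contrast
#'
#' Applies the three cross-tissue criteria: a candidate is promoted when it
#' (1) lies within a maternal-deletion interval (so the paternal allele is
#' exposed in lung), (2) shows the same inferred methylated parent in the
#' hemizygous lung contrast at `min_concordant_sites` or more member sites
#' at the lung delta threshold, and (3) spans more than one CpG
#' dinucleotide (a forward/reverse pair at one dinucleotide counts once) —
#' and is not SNV-masked.
#'
#' @param candidates Candidates after [mask_snv_regions()].
#' @param lung_calls Hemizygous site calls ([classify_hemi_sites()] with
#'   loci), or `NULL` when no lung data are available (candidates then stay
#'   unpromoted).
#' @param deletions Deletion intervals ([read_deletions_bed()]).
#' @param min_concordant_sites Member sites that must agree with the lung
#'   direction (default 1).
#' @return `candidates` with all flags and `promoted` filled in.
#' @export
cross_tissue_concordance <- function(candidates, lung_calls, deletions,
                                     min_concordant_sites = 1) {
  if (nrow(candidates) == 0) return(candidates)
  members <- attr(candidates, "members")

  mat_del <- deletions[deletions$deleted_parent == "maternal", , drop = FALSE]
  if (nrow(mat_del)) {
    cand_gr <- GenomicRanges::GRanges(
      candidates$chrom,
      IRanges::IRanges(candidates$start, candidates$end))
    del_gr <- GenomicRanges::GRanges(
      mat_del$chrom, IRanges::IRanges(mat_del$start, mat_del$end))
    hits <- GenomicRanges::findOverlaps(cand_gr, del_gr, type = "within")
    candidates$overlaps_hemizygous_interval <-
      seq_len(nrow(candidates)) %in% S4Vectors::queryHits(hits)
  } else {
    candidates$overlaps_hemizygous_interval <- FALSE
  }

  if (is.null(lung_calls) || nrow(lung_calls) == 0) {
    message("no lung calls supplied; candidates remain unpromoted")
    candidates$lung_concordant <- FALSE
  } else {
    lung_keys <- locus_key(lung_calls)
    candidates$lung_concordant <- vapply(seq_len(nrow(candidates)),
                                         function(r) {
      sites <- members[[r]]
      i <- match(locus_key(sites), lung_keys)
      i <- i[!is.na(i)]
      if (!length(i)) return(FALSE)
      hit <- lung_calls$qualifies[i] &
        lung_calls$direction[i] == candidates$direction[r]
      sum(hit) >= min_concordant_sites
    }, logical(1L))
  }

  candidates$multi_cpg <- vapply(members, function(sites) {
    length(unique(dinucleotide_id(sites$chrom, sites$pos, sites$strand))) >= 2
  }, logical(1L))

  masked <- candidates$snv_masked
  masked[is.na(masked)] <- FALSE
  candidates$promoted <- !masked &
    candidates$overlaps_hemizygous_interval &
    candidates$lung_concordant & candidates$multi_cpg
  candidates
}

#' Targeted small-region re-scan with SNV masking and lung concordance
#'
#' Convenience wrapper chaining [scan_small_regions()],
#' [mask_snv_regions()] and [cross_tissue_concordance()].
#'
#' @inheritParams scan_small_regions
#' @inheritParams mask_snv_regions
#' @inheritParams cross_tissue_concordance
#' @return The candidate table with all flags filled in.
#' @export
call_targeted_candidates <- function(calls, pool, target_interval,
                                     snvs = NULL, lung_calls = NULL,
                                     deletions, min_sites = 2,
                                     max_sites = 4, min_median_cov = 10,
                                     intra_discord = 50, intra_cov = 3,
                                     min_concordant_sites = 1) {
  cand <- scan_small_regions(calls, pool, target_interval, min_sites,
                             max_sites, min_median_cov, intra_discord,
                             intra_cov)
  cand <- mask_snv_regions(cand, snvs)
  cross_tissue_concordance(cand, lung_calls, deletions,
                           min_concordant_sites)
}
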