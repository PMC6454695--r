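#' Classify pooled loci for parent-of-origin methylation bias
#'
#' A locus qualifies when the absolute difference in percent methylation
#' between the pooled maternal-UPD and paternal-UPD categories is at least
#' `delta_threshold` *and* the biparental control lies strictly between the
#' two (ties fail). Direction is `maternal_methylated` when the maternal
#' percent exceeds the paternal percent. Loci with undefined percent in any
#' of the three categories are not classifiable and are dropped (their
#' count is recorded in attribute `n_unclassifiable`).
#'
#' @param pool A `pod_pool` carrying categories `upd16mat`, `upd16pat`,
#'   `biparental` (usually after [intersect_loci()]).
#' @param delta_threshold Minimum absolute percent difference between
#'   maternal and paternal categories (default 40).
#' @return A data.frame of site calls (`chrom`, `pos`, `strand`,
#'   `pct_mat`, `pct_bip`, `pct_pat`, `delta`, `direction`, `qualifies`),
#'   position-sorted, one row per classifiable locus.
#' @export
classify_sites <- function(pool, delta_threshold = 40) {
  stopifnot(inherits(pool, "pod_pool"))
  need <- c("upd16mat", "upd16pat", "biparental")
  if (!all(need %in% pool$categories)) {
    stop("pool must carry categories upd16mat, upd16pat, biparental",
         call. = FALSE)
  }
  l <- pool$loci
  pm <- l$pct_upd16mat
  pp <- l$pct_upd16pat
  pb <- l$pct_biparental
  ok <- !is.na(pm) & !is.na(pp) & !is.na(pb)
  delta <- abs(pm - pp)
  intermediate <- (pm > pb & pb > pp) | (pm < pb & pb < pp)
  qualifies <- ok & delta >= delta_threshold & intermediate
  direction <- ifelse(qualifies,
                      ifelse(pm > pp, "maternal_methylated",
                             "paternal_methylated"),
                      "none")
  calls <- data.frame(
    chrom = l$chrom[ok], pos = l$pos[ok], strand = l$strand[ok],
    pct_mat = pm[ok], pct_bip = pb[ok], pct_pat = pp[ok],
    delta = delta[ok], direction = direction[ok],
    qualifies = qualifies[ok], stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL
  attr(calls, "n_unclassifiable") <- sum(!ok)
  attr(calls, "delta_threshold") <- delta_threshold
  calls
}

#' Collapse site calls into candidate regions
#'
#' Maximal runs of adjacent qualifying sites with the same direction become
#' regions; adjacency is over the ordered set of classifiable loci, not
#' genomic base pairs. With `merge_single_discordant = TRUE` (the trio-mode
#' rule), two same-direction regions separated by exactly one discordant
#' site — a classifiable site that does not qualify in the regions'
#' direction, including a lone opposite-direction qualifying site — are
#' combined, iteratively left to right until no merge applies. The
#' intervening discordant site never counts toward `n_sites`.
#'
#' @param calls Site-call data.frame from [classify_sites()] or
#'   [classify_hemi_sites()] (needs `chrom`, `pos`, `strand`, `direction`,
#'   `qualifies`).
#' @param merge_single_discordant Apply the single-discordant-site merge
#'   rule (default `TRUE`; the hemizygous lung mode runs with `FALSE`).
#' @return An object of class `pod_regions`: list with `regions`
#'   (data.frame `chrom`, `start`, `end`, `direction`, `n_sites`),
#'   `members` (per region, integer indices of member sites into `calls`)
#'   and `calls`.
#' @export
collapse_regions <- function(calls, merge_single_discordant = TRUE) {
  ord <- locus_order(calls)
  if (!identical(ord, seq_len(nrow(calls)))) {
    warning("site calls not position-sorted; sorting internally",
            call. = FALSE)
    calls <- calls[ord, , drop = FALSE]
    rownames(calls) <- NULL
  }
  dirs <- match(calls$direction, c("maternal_methylated",
                                   "paternal_methylated"), nomatch = 0L)
  dirs[!calls$qualifies] <- 0L

  regions <- list()
  members <- list()
  for (chr in unique(calls$chrom)) {
    rows <- which(calls$chrom == chr)
    res <- collapse_runs_cpp(dirs[rows], merge_single_discordant)
    nr <- length(res$first)
    if (nr == 0) next
    reg <- data.frame(
      chrom = chr,
      start = calls$pos[rows[res$first]],
      end = calls$pos[rows[res$last]],
      direction = c("maternal_methylated",
                    "paternal_methylated")[res$dir],
      n_sites = res$n_sites,
      stringsAsFactors = FALSE
    )
    regions[[length(regions) + 1L]] <- reg
    mem <- split(rows[res$region > 0L], res$region[res$region > 0L])
    members <- c(members, unname(mem[order(as.integer(names(mem)))]))
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               direction = character(), n_sites = integer(),
               stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  structure(list(regions = regions, members = members, calls = calls,
                 merge_single_discordant = merge_single_discordant),
            class = "pod_regions")
}

#' Apply the trio-mode region-level filters
#'
#' Keeps a region when (a) it contains at least `min_sites` qualifying
#' sites; (b) in every category the median pooled coverage over the member
#' sites is at least `min_median_cov`; and (c) no category contains two
#' samples whose region-level percent methylation (per-sample counts summed
#' over member sites) differs by more than `intra_discord` while both
#' samples have a median per-site coverage above `intra_cov` within the
#' region. With a single sample per category the concordance check passes
#' vacuously.
#'
#' @param x A `pod_regions` from [collapse_regions()].
#' @param pool The `pod_pool` the calls were classified from.
#' @param min_sites Minimum qualifying sites per region (default 5).
#' @param min_median_cov Minimum per-category median pooled coverage
#'   (default 10).
#' @param intra_discord Maximum tolerated intra-category per-sample percent
#'   difference (default 50) ...
#' @param intra_cov ... enforced only when both samples exceed this median
#'   per-site coverage (default 3).
#' @return A `pod_regions` with the surviving regions, annotated with
#'   per-category median coverage columns; attribute `attrition` records
#'   counts removed by each filter.
#' @export
filter_blood_regions <- function(x, pool, min_sites = 5,
                                 min_median_cov = 10, intra_discord = 50,
                                 intra_cov = 3) {
  blood_region_filter(x, pool, min_sites = min_sites, max_sites = Inf,
                      min_median_cov = min_median_cov,
                      intra_discord = intra_discord, intra_cov = intra_cov)
}

blood_region_filter <- function(x, pool, min_sites, max_sites,
                                min_median_cov, intra_discord, intra_cov) {
  stopifnot(inherits(x, "pod_regions"), inherits(pool, "pod_pool"))
  reg <- x$regions
  nr <- nrow(reg)
  pool_keys <- locus_key(pool$loci)
  call_rows <- match(locus_key(x$calls), pool_keys)

  cats <- pool$categories
  med_cov <- matrix(NA_real_, nr, length(cats),
                    dimnames = list(NULL, cats))
  pass_sites <- reg$n_sites >= min_sites & reg$n_sites <= max_sites
  pass_cov <- rep(TRUE, nr)
  pass_concord <- rep(TRUE, nr)

  for (r in seq_len(nr)) {
    idx <- call_rows[x$members[[r]]]
    for (ci in seq_along(cats)) {
      cov <- pool$loci[[paste0("meth_", cats[ci])]][idx] +
        pool$loci[[paste0("unmeth_", cats[ci])]][idx]
      med_cov[r, ci] <- stats::median(cov)
    }
    if (any(med_cov[r, ] < min_median_cov)) pass_cov[r] <- FALSE

    for (cat in cats) {
      ids <- pool$samples$sample_id[pool$samples$category == cat]
      if (length(ids) < 2) next
      m <- colSums(pool$sample_meth[idx, ids, drop = FALSE])
      u <- colSums(pool$sample_unmeth[idx, ids, drop = FALSE])
      pct <- percent_methylation(m, u)
      medc <- apply(pool$sample_meth[idx, ids, drop = FALSE] +
                      pool$sample_unmeth[idx, ids, drop = FALSE],
                    2L, stats::median)
      for (i in seq_along(ids)[-1L]) for (j in seq_len(i - 1L)) {
        if (!is.na(pct[i]) && !is.na(pct[j]) &&
            abs(pct[i] - pct[j]) > intra_discord &&
            medc[i] > intra_cov && medc[j] > intra_cov) {
          pass_concord[r] <- FALSE
        }
      }
    }
  }

  keep <- pass_sites & pass_cov & pass_concord
  colnames(med_cov) <- paste0("median_cov_", cats)
  reg <- cbind(reg, as.data.frame(med_cov))
  x$regions <- reg[keep, , drop = FALSE]
  rownames(x$regions) <- NULL
  x$members <- x$members[keep]
  attr(x, "attrition") <- c(
    regions_in = nr,
    removed_site_count = sum(!pass_sites),
    removed_median_coverage = sum(pass_sites & !pass_cov),
    removed_intra_category_discordance =
      sum(pass_sites & pass_cov & !pass_concord),
    regions_out = sum(keep)
  )
  x
}

#' Call parent-of-origin DMRs from a UPD trio design
#'
#' End-to-end trio mode: pool counts within the `upd16mat`, `upd16pat` and
#' `biparental` categories, restrict to loci represented in all three,
#' classify each locus (absolute maternal-vs-paternal percent difference of
#' at least `delta_threshold` with strictly intermediate control), collapse
#' qualifying sites into regions with the single-discordant-site merge, and
#' apply the region-level site-count, coverage and intra-category
#' concordance filters.
#'
#' @inheritParams pool_by_category
#' @inheritParams classify_sites
#' @inheritParams filter_blood_regions
#' @param merge_single_discordant see [collapse_regions()].
#' @return An object of class `pod_dmr` with components `regions` (the
#'   final region table), `prefilter` (the `pod_regions` before the
#'   region-level filters), `calls`, `pool`, `params` and `attrition`.
#' @seealso [call_lung_dmrs()], [call_targeted_candidates()]
#' @export
call_blood_dmrs <- function(counts, samples, delta_threshold = 40,
                            min_sites = 5, min_median_cov = 10,
                            intra_discord = 50, intra_cov = 3,
                            merge_single_discordant = TRUE) {
  pool <- pool_by_category(counts, samples)
  n_all <- nrow(pool$loci)
  pool <- intersect_loci(pool)
  n_common <- nrow(pool$loci)
  calls <- classify_sites(pool, delta_threshold)
  collapsed <- collapse_regions(calls, merge_single_discordant)
  filtered <- filter_blood_regions(collapsed, pool, min_sites,
                                   min_median_cov, intra_discord, intra_cov)
  attrition <- c(
    loci_total = n_all,
    loci_all_categories = n_common,
    sites_classifiable = nrow(calls),
    sites_qualifying = sum(calls$qualifies),
    regions_collapsed = nrow(collapsed$regions),
    attr(filtered, "attrition")[c("removed_site_count",
                                  "removed_median_coverage",
                                  "removed_intra_category_discordance")],
    regions_final = nrow(filtered$regions)
  )
  structure(list(
    regions = filtered$regions,
    members = filtered$members,
    prefilter = collapsed,
    calls = calls,
    pool = pool,
    mode = "blood",
    params = list(delta_threshold = delta_threshold, min_sites = min_sites,
                  min_median_cov = min_median_cov,
                  intra_discord = intra_discord, intra_cov = intra_cov,
                  merge_single_discordant = merge_single_discordant),
    attrition = attrition
  ), class = "pod_dmr")
}
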