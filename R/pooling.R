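#' Percent methylation from counts
#'
#' `100 * meth / (meth + unmeth)`; `NA` (undefined) when both counts are
#' zero. Vectorised.
#'
#' @param meth,unmeth Non-negative counts.
#' @return Numeric vector in `[0, 100]`, `NA` at zero coverage.
#' @export
percent_methylation <- function(meth, unmeth) {
  if (any(meth < 0, unmeth < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  cov <- meth + unmeth
  ifelse(cov > 0, 100 * meth / cov, NA_real_)
}

#' Pool CpG counts within sample categories
#'
#' Sums methylated/unmethylated counts at each locus over all samples of
#' each category; coverage increases, while the per-sample counts are
#' retained for the region-level concordance filters. A locus absent from a
#' sample contributes zero counts; representation is judged per category,
#' not per sample. All samples are expected to come from one tissue.
#'
#' @param counts Named list of per-sample count tables (names are sample
#'   ids; see [read_cpg_report()]).
#' @param samples Sample sheet (`sample_id`, `category`, `tissue`).
#' @param categories Categories to pool; each must have at least one sample.
#' @return An object of class `pod_pool`: a list with
#'   \describe{
#'     \item{loci}{data.frame `chrom`, `pos`, `strand` plus, per category,
#'       `meth_<cat>`, `unmeth_<cat>`, `pct_<cat>` (NA at zero pooled
#'       coverage).}
#'     \item{sample_meth, sample_unmeth}{locus x sample count matrices.}
#'     \item{samples}{the sample sheet rows used.}
#'   }
#' @export
pool_by_category <- function(counts, samples,
                             categories = c("upd16mat", "upd16pat",
                                            "biparental")) {
  validate_samples(samples)
  samples <- samples[samples$category %in% categories, , drop = FALSE]
  missing_cat <- setdiff(categories, samples$category)
  if (length(missing_cat)) {
    stop("no samples in category: ", paste(missing_cat, collapse = ", "),
         call. = FALSE)
  }
  if (!all(samples$sample_id %in% names(counts))) {
    stop("counts missing for sample(s): ",
         paste(setdiff(samples$sample_id, names(counts)), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(samples$tissue)) > 1) {
    warning("pooling samples from more than one tissue", call. = FALSE)
  }
  counts <- counts[samples$sample_id]
  for (i in seq_along(counts)) validate_counts(counts[[i]], names(counts)[i])

  all_loci <- unique(do.call(rbind, lapply(counts, function(x) {
    x[, c("chrom", "pos", "strand")]
  })))
  all_loci <- all_loci[locus_order(all_loci), , drop = FALSE]
  rownames(all_loci) <- NULL
  keys <- locus_key(all_loci)

  nloc <- nrow(all_loci)
  nsam <- nrow(samples)
  sm <- matrix(0L, nloc, nsam, dimnames = list(NULL, samples$sample_id))
  su <- sm
  for (s in samples$sample_id) {
    x <- counts[[s]]
    i <- match(locus_key(x), keys)
    sm[i, s] <- x$meth
    su[i, s] <- x$unmeth
  }

  loci <- all_loci
  for (cat in categories) {
    cols <- samples$sample_id[samples$category == cat]
    m <- rowSums(sm[, cols, drop = FALSE])
    u <- rowSums(su[, cols, drop = FALSE])
    loci[[paste0("meth_", cat)]] <- as.integer(m)
    loci[[paste0("unmeth_", cat)]] <- as.integer(u)
    loci[[paste0("pct_", cat)]] <- percent_methylation(m, u)
  }
  structure(list(loci = loci, sample_meth = sm, sample_unmeth = su,
                 samples = samples, categories = categories),
            class = "pod_pool")
}

#' Restrict pooled loci to those represented in all categories
#'
#' Keeps exactly the loci with pooled coverage of at least one read in
#' every category. Idempotent; the output is a subset of the input.
#'
#' @param pool A `pod_pool` from [pool_by_category()].
#' @return A `pod_pool` restricted to the common loci.
#' @export
intersect_loci <- function(pool) {
  stopifnot(inherits(pool, "pod_pool"))
  keep <- rep(TRUE, nrow(pool$loci))
  for (cat in pool$categories) {
    cov <- pool$loci[[paste0("meth_", cat)]] +
      pool$loci[[paste0("unmeth_", cat)]]
    keep <- keep & cov >= 1L
  }
  subset_pool(pool, keep)
}

subset_pool <- function(pool, keep) {
  pool$loci <- pool$loci[keep, , drop = FALSE]
  rownames(pool$loci) <- NULL
  pool$sample_meth <- pool$sample_meth[keep, , drop = FALSE]
  pool$sample_unmeth <- pool$sample_unmeth[keep, , drop = FALSE]
  pool
}

#' @export
print.pod_pool <- function(x, ...) {
  cat("Pooled CpG counts: ", nrow(x$loci), " loci, ",
      nrow(x$samples), " samples in ", length(x$categories),
      " categories (", paste(x$categories, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
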