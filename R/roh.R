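#' Detect runs of homozygosity from SNV genotypes
#'
#' A transparent run-length detector: maximal runs of homozygous calls
#' (`hom_ref` or `hom_alt`), scanned left to right per chromosome,
#' tolerating up to `max_het_interrupts` embedded heterozygous calls and
#' requiring at least `min_snvs` supporting homozygous sites. After a run
#' is broken, scanning resumes past the breaking heterozygous call, so the
#' reported runs are disjoint.
#'
#' @param snvs SNV calls for one sample (`chrom`, `pos`, `genotype`),
#'   position-sorted (sorted internally otherwise).
#' @param max_het_interrupts Heterozygous calls tolerated inside a run
#'   (default 0).
#' @param min_snvs Minimum homozygous SNVs supporting a run (default 25).
#' @return data.frame with columns `chrom`, `start`, `end` (positions of
#'   the first/last homozygous SNV), `n_snvs`, `length_bp`.
#' @export
detect_roh <- function(snvs, max_het_interrupts = 0, min_snvs = 25) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snvs = integer(),
                      length_bp = integer(), stringsAsFactors = FALSE)
  if (is.null(snvs) || nrow(snvs) == 0) return(empty)
  snvs <- snvs[order(snvs$chrom, snvs$pos), , drop = FALSE]
  out <- list()
  for (chr in unique(snvs$chrom)) {
    x <- snvs[snvs$chrom == chr, , drop = FALSE]
    hom <- x$genotype %in% c("hom_ref", "hom_alt")
    n <- nrow(x)
    i <- 1L
    while (i <= n) {
      if (!hom[i]) { i <- i + 1L; next }
      j <- i
      hets <- 0L
      last_hom <- i
      while (j < n) {
        nxt <- j + 1L
        if (hom[nxt]) {
          last_hom <- nxt
          j <- nxt
        } else if (hets < max_het_interrupts) {
          hets <- hets + 1L
          j <- nxt
        } else break
      }
      support <- sum(hom[i:last_hom])
      if (support >= min_snvs) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = x$pos[i], end = x$pos[last_hom],
          n_snvs = support,
          length_bp = x$pos[last_hom] - x$pos[i] + 1L,
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag a sample as isodisomic from its homozygosity runs
#'
#' `TRUE` when any run is longer than `threshold_bp` (default 10 Mb), the
#' conventional length above which a run of homozygosity indicates
#' isodisomy rather than ordinary autozygosity.
#'
#' @param runs Output of [detect_roh()].
#' @param threshold_bp Length threshold in base pairs (default 1e7).
#' @return A list: `isodisomy` (logical) and `supporting_runs` (the runs
#'   exceeding the threshold).
#' @export
flag_isodisomy <- function(runs, threshold_bp = 1e7) {
  hit <- runs$length_bp > threshold_bp
  list(isodisomy = any(hit),
       supporting_runs = runs[hit, , drop = FALSE])
}
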