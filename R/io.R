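#' Read a Bismark cytosine (CpG) report
#'
#' Parses the seven-column Bismark cytosine report
#' (`chrom`, `pos`, `strand`, `count_methylated`, `count_unmethylated`,
#' `context`, `trinucleotide`). Only rows in CpG context are retained;
#' zero-coverage sites are kept (downstream filters own inclusion policy).
#' Positions are 1-based as in the file.
#'
#' @param path Path to the tab-separated report.
#' @param sample_id Sample identifier attached to the result.
#' @return A data.frame with columns `chrom`, `pos`, `strand`, `meth`,
#'   `unmeth`, one row per strand-resolved CpG cytosine, sorted by
#'   chromosome, position and strand, with attribute `sample_id`.
#' @export
read_cpg_report <- function(path, sample_id) {
  raw <- read_tsv_lines(path, 7L, "CpG report")
  if (nrow(raw) == 0) {
    warning("empty CpG report: ", path, call. = FALSE)
    out <- empty_counts()
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  names(raw) <- c("chrom", "pos", "strand", "meth", "unmeth", "context", "tri")
  keep <- raw$context == "CpG"
  out <- data.frame(
    chrom = as.character(raw$chrom[keep]),
    pos = parse_int_col(raw$pos[keep], path, "pos"),
    strand = as.character(raw$strand[keep]),
    meth = parse_int_col(raw$meth[keep], path, "count_methylated"),
    unmeth = parse_int_col(raw$unmeth[keep], path, "count_unmethylated"),
    stringsAsFactors = FALSE
  )
  validate_counts(out, path)
  out <- out[locus_order(out), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  out
}

#' Write counts in Bismark cytosine-report format
#'
#' Inverse of [read_cpg_report()]: emits the seven-column CpG-report dialect
#' (context fixed to `CpG`, trinucleotide reported as `CGN`). Round-trips
#' `chrom`, `pos`, `strand`, `meth` and `unmeth` exactly.
#'
#' @param counts Count table as returned by [read_cpg_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_report <- function(counts, path) {
  validate_counts(counts)
  out <- data.frame(counts$chrom, counts$pos, counts$strand, counts$meth,
                    counts$unmeth, "CpG", "CGN")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Bismark coverage file
#'
#' Parses the six-column Bismark `.cov` dialect (`chrom`, `start`, `end`,
#' `percent`, `meth`, `unmeth`; 1-based, start = end). The dialect does not
#' record strand: strand is set to `"+"` for locus keying. The percent
#' column is ignored and recomputed from the counts; a discrepancy larger
#' than 0.5 percentage points triggers a warning, and the counts win.
#'
#' @inheritParams read_cpg_report
#' @return As [read_cpg_report()].
#' @export
read_coverage_file <- function(path, sample_id) {
  raw <- read_tsv_lines(path, 6L, "coverage file")
  if (nrow(raw) == 0) {
    warning("empty coverage file: ", path, call. = FALSE)
    out <- empty_counts()
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  names(raw) <- c("chrom", "start", "end", "percent", "meth", "unmeth")
  out <- data.frame(
    chrom = as.character(raw$chrom),
    pos = parse_int_col(raw$start, path, "start"),
    strand = "+",
    meth = parse_int_col(raw$meth, path, "meth"),
    unmeth = parse_int_col(raw$unmeth, path, "unmeth"),
    stringsAsFactors = FALSE
  )
  stated <- suppressWarnings(as.numeric(raw$percent))
  cov <- out$meth + out$unmeth
  recomputed <- ifelse(cov > 0, 100 * out$meth / cov, NA_real_)
  off <- !is.na(stated) & !is.na(recomputed) & abs(stated - recomputed) > 0.5
  if (any(off)) {
    warning(sprintf(
      "%s: percent column inconsistent with counts at %d row(s); counts win",
      path, sum(off)), call. = FALSE)
  }
  validate_counts(out, path)
  out <- out[locus_order(out), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  out
}

#' Write counts in Bismark coverage format
#'
#' Emits the six-column `.cov` dialect. Strand is not representable in this
#' dialect and is dropped; zero-coverage sites are written with an empty
#' percent of 0.
#'
#' @inheritParams write_cpg_report
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(counts, path) {
  validate_counts(counts)
  cov <- counts$meth + counts$unmeth
  pct <- ifelse(cov > 0, round(100 * counts$meth / cov, 6), 0)
  out <- data.frame(counts$chrom, counts$pos, counts$pos, pct,
                    counts$meth, counts$unmeth)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a count file, auto-detecting the Bismark dialect
#'
#' Seven tab-separated columns are read as a cytosine report
#' ([read_cpg_report()]), six as a coverage file ([read_coverage_file()]).
#'
#' @inheritParams read_cpg_report
#' @export
read_counts_file <- function(path, sample_id) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    warning("empty count file: ", path, call. = FALSE)
    out <- empty_counts()
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  nf <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  if (nf == 7L) read_cpg_report(path, sample_id)
  else if (nf == 6L) read_coverage_file(path, sample_id)
  else stop(path, ": cannot identify count dialect (", nf,
            " columns; expected 6 or 7)", call. = FALSE)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `category`, `tissue` and
#' optionally `path` (per-sample count file). Categories and tissues come
#' from closed vocabularies (`upd16mat`, `upd16pat`, `biparental`,
#' `hemizygous_paternal`; `blood`, `fibroblast`, `lung`).
#'
#' @param path Path to the sheet.
#' @return A data.frame, validated.
#' @export
read_sample_sheet <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_samples(x)
  x
}

#' Read deletion intervals with parental origin
#'
#' BED-like tab-separated file: `chrom`, `start` (0-based, BED convention),
#' `end`, `deleted_parent` (`maternal`/`paternal`) and optionally a fifth
#' column with the carrier `sample_id`. Returned intervals are 1-based
#' inclusive.
#'
#' @param path Path to the file.
#' @return data.frame with columns `chrom`, `start`, `end`,
#'   `deleted_parent`, `sample_id`.
#' @export
read_deletions_bed <- function(path) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(x) < 4) stop(path, ": deletions BED needs >= 4 columns", call. = FALSE)
  out <- data.frame(
    chrom = as.character(x[[1L]]),
    start = as.integer(x[[2L]]) + 1L,
    end = as.integer(x[[3L]]),
    deleted_parent = as.character(x[[4L]]),
    sample_id = if (ncol(x) >= 5) as.character(x[[5L]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  bad <- setdiff(out$deleted_parent, c("maternal", "paternal"))
  if (length(bad)) {
    stop(path, ": deleted_parent must be maternal or paternal, got ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(out$start > out$end)) stop(path, ": interval start > end", call. = FALSE)
  out
}

#' Read SNV calls from a VCF
#'
#' Reads a VCF 4.x with a GT FORMAT field. Only single-nucleotide records
#' (one-base REF and ALT) that are unfiltered (`PASS` or `.`) are kept;
#' records with no GT call for a sample are skipped with a warning.
#'
#' @param path Path to the (uncompressed or bgzipped) VCF.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `genotype` (`hom_ref`, `het`, `hom_alt`).
#' @export
read_snv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), sample_id = character(),
                      genotype = character(), stringsAsFactors = FALSE)
  if (nrow(v@fix) == 0) return(empty)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & !is.na(fix$ALT) & nchar(fix$ALT) == 1L &
    (is.na(fix$FILTER) | fix$FILTER %in% c("PASS", "."))
  if (!any(keep)) return(empty)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) {
    warning(path, ": no GT field; all records skipped", call. = FALSE)
    return(empty)
  }
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  res <- lapply(colnames(gt), function(s) {
    g <- parse_genotypes(gt[, s])
    ok <- !is.na(g)
    if (any(!ok)) {
      warning(sprintf("%s: %d record(s) with missing GT skipped for sample %s",
                      path, sum(!ok), s), call. = FALSE)
    }
    data.frame(chrom = fix$CHROM[ok], pos = as.integer(fix$POS[ok]),
               ref = fix$REF[ok], alt = fix$ALT[ok], sample_id = s,
               genotype = g[ok], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

parse_genotypes <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2L || anyNA(suppressWarnings(as.integer(a)))) {
      return(NA_character_)
    }
    a <- as.integer(a)
    if (all(a == 0L)) "hom_ref"
    else if (a[1L] == a[2L]) "hom_alt"
    else "het"
  }, character(1L))
}

#' Write a minimal single-sample VCF of SNV calls
#'
#' Companion writer for [read_snv_vcf()], used to serialize simulated SNVs.
#' One file per set of samples; genotypes are written unphased.
#'
#' @param snvs data.frame as returned by [read_snv_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path) {
  samples <- sort(unique(snvs$sample_id))
  key <- paste(snvs$chrom, snvs$pos, snvs$ref, snvs$alt, sep = "\r")
  sites <- !duplicated(key)
  site_df <- snvs[sites, c("chrom", "pos", "ref", "alt")]
  ord <- order(site_df$chrom, site_df$pos)
  site_df <- site_df[ord, , drop = FALSE]
  site_key <- paste(site_df$chrom, site_df$pos, site_df$ref, site_df$alt,
                    sep = "\r")
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  gt <- matrix("./.", nrow = nrow(site_df), ncol = length(samples),
               dimnames = list(NULL, samples))
  idx <- cbind(match(key, site_key), match(snvs$sample_id, samples))
  gt[idx] <- gt_code[snvs$genotype]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (nrow(site_df)) {
    body <- cbind(site_df$chrom, site_df$pos, ".", site_df$ref, site_df$alt,
                  ".", "PASS", ".", "GT", gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write called regions as BED6
#'
#' Serializes regions to BED6 with 0-based half-open coordinates
#' (`start - 1`, `end`), the direction label as the name, the number of
#' member sites as the score, and strand `"."`. Unsorted input is sorted
#' internally with a note.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `direction`, `n_sites`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (any(regions$end < regions$start)) {
    stop("region with end < start", call. = FALSE)
  }
  ord <- order(regions$chrom, regions$start)
  if (!identical(ord, seq_len(nrow(regions)))) {
    message("write_regions_bed: input not sorted; sorting by chrom,start")
    regions <- regions[ord, , drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end),
    strand = "*",
    name = regions$direction,
    score = regions$n_sites
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# -- low-level parsing helpers -----------------------------------------------

read_tsv_lines <- function(path, ncol_expected, what) {
  if (!file.exists(path)) stop(what, " not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(as.data.frame(matrix(character(), ncol = ncol_expected),
                         stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != ncol_expected)) {
    bad <- which(nf != ncol_expected)[1L]
    stop(sprintf("%s %s: malformed row at line %d (%d fields, expected %d)",
                 what, path, bad, nf[bad], ncol_expected), call. = FALSE)
  }
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  out
}

parse_int_col <- function(x, path, col) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("%s: non-integer value '%s' in column %s (data row %d)",
                 path, x[bad], col, bad), call. = FALSE)
  }
  v
}
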