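# Internal helpers shared across modules.

# Canonical per-sample CpG count table: chrom, pos, strand, meth, unmeth.
# Positions are 1-based; forward and reverse cytosines of one dinucleotide
# are distinct loci, never destranded.
validate_counts <- function(x, what = "counts") {
  need <- c("chrom", "pos", "strand", "meth", "unmeth")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop(sprintf("%s must be a data.frame with columns %s",
                 what, paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$meth < 0) || any(x$unmeth < 0)) {
    stop(sprintf("%s: negative methylated/unmethylated counts", what),
         call. = FALSE)
  }
  if (any(x$pos < 1)) stop(sprintf("%s: positions must be >= 1", what), call. = FALSE)
  if (!all(x$strand %in% c("+", "-"))) {
    stop(sprintf("%s: strand must be '+' or '-'", what), call. = FALSE)
  }
  key <- locus_key(x)
  if (anyDuplicated(key)) {
    stop(sprintf("%s: duplicate locus (chrom,pos,strand): %s",
                 what, key[duplicated(key)][1L]), call. = FALSE)
  }
  invisible(x)
}

locus_key <- function(x) paste(x$chrom, x$pos, x$strand, sep = "\r")

# Sort order used everywhere: chromosome, then position, then strand (+ first),
# so that forward/reverse cytosines of a dinucleotide stay adjacent.
locus_order <- function(x) order(x$chrom, x$pos, match(x$strand, c("+", "-")))

validate_samples <- function(samples) {
  need <- c("sample_id", "category", "tissue")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop("sample sheet must have columns sample_id, category, tissue",
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  bad <- setdiff(samples$category, POD_CATEGORIES)
  if (length(bad)) {
    stop("unknown sample category: ", paste(bad, collapse = ", "),
         "; expected one of ", paste(POD_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(samples$tissue, POD_TISSUES)
  if (length(bad)) {
    stop("unknown tissue: ", paste(bad, collapse = ", "),
         "; expected one of ", paste(POD_TISSUES, collapse = ", "),
         call. = FALSE)
  }
  invisible(samples)
}

empty_counts <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             meth = integer(), unmeth = integer(), stringsAsFactors = FALSE)
}

# Identifier of the CpG dinucleotide a strand-resolved cytosine belongs to:
# the position of the C on the forward strand (reverse-strand C sits at pos,
# its dinucleotide starts at pos - 1).
dinucleotide_id <- function(chrom, pos, strand) {
  start <- ifelse(strand == "-", pos - 1L, pos)
  paste(chrom, start, sep = "\r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
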