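# Independent oracles and fixture builders used across the suite.

# ---- region-collapse oracle -------------------------------------------------
# Site-neighbour fixpoint merger, deliberately structured differently from
# the package's run-list algorithm. Input: character vector over
# c("M", "P", "x") (maternal-qualifying, paternal-qualifying, discordant).
# Returns a data.frame first/last/dir/n_sites (site indices), or 0 rows.
oracle_collapse_core <- function(dirs, merge = TRUE) {
  # dirs: integer vector, 0 = discordant, 1 = M, 2 = P
  n <- length(dirs)
  assign <- integer(n)           # region id per member site, 0 = none
  dir_of <- integer(0)           # direction per region id
  rid <- 0L
  i <- 1L
  while (i <= n) {
    if (dirs[i] > 0L) {
      rid <- rid + 1L
      dir_of[rid] <- dirs[i]
      while (i <= n && dirs[i] == dir_of[rid]) {
        assign[i] <- rid
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }

  if (merge && rid > 1L && n >= 3L) {
    repeat {
      merged <- FALSE
      for (s in 2L:(n - 1L)) {
        a <- assign[s - 1L]
        b <- assign[s + 1L]
        if (a == 0L || b == 0L || a == b) next
        if (dir_of[a] != dir_of[b]) next
        c_ok <- assign[s] == 0L ||
          (sum(assign == assign[s]) == 1L &&
             dir_of[assign[s]] != dir_of[a])
        if (!c_ok) next
        if (assign[s] != 0L) assign[s] <- 0L   # dissolve the lone opposite
        assign[assign == b] <- a
        merged <- TRUE
        break
      }
      if (!merged) break
    }
  }

  ids <- unique(assign[assign > 0L])
  if (!length(ids)) {
    return(list(first = integer(), last = integer(), dir = integer(),
                n_sites = integer()))
  }
  first <- vapply(ids, function(r) min(which(assign == r)), 1L)
  ord <- order(first)
  ids <- ids[ord]
  list(
    first = first[ord],
    last = vapply(ids, function(r) max(which(assign == r)), 1L),
    dir = dir_of[ids],
    n_sites = vapply(ids, function(r) sum(assign == r), 1L)
  )
}

oracle_collapse <- function(pattern, merge = TRUE) {
  core <- oracle_collapse_core(match(pattern, c("M", "P"), nomatch = 0L),
                               merge)
  data.frame(first = core$first, last = core$last,
             dir = c("M", "P")[core$dir],
             n_sites = core$n_sites, stringsAsFactors = FALSE)
}

# Run the package's collapse on a pattern string and return the same layout
# as oracle_collapse (site indices, since fixtures use pos = 1..n).
collapse_pattern <- function(pattern, merge = TRUE) {
  calls <- calls_from_pattern(pattern)
  res <- collapse_regions(calls, merge_single_discordant = merge)
  reg <- res$regions
  data.frame(first = reg$start, last = reg$end,
             dir = unname(c(maternal_methylated = "M",
                            paternal_methylated = "P")[reg$direction]),
             n_sites = reg$n_sites, stringsAsFactors = FALSE)
}

calls_from_pattern <- function(pattern) {
  n <- length(pattern)
  data.frame(
    chrom = "chr16", pos = seq_len(n), strand = "+",
    direction = c(M = "maternal_methylated", P = "paternal_methylated",
                  x = "none")[pattern],
    qualifies = pattern %in% c("M", "P"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# ---- pooling oracle ---------------------------------------------------------
# Nested-loop pooling: for every locus key and category, sum counts over the
# member samples that carry the locus.
oracle_pool <- function(counts, samples, categories) {
  keys <- sort(unique(unlist(lapply(counts, function(x) {
    paste(x$chrom, x$pos, x$strand, sep = "\r")
  }))))
  out <- list()
  for (cat in categories) {
    ids <- samples$sample_id[samples$category == cat]
    m <- u <- setNames(numeric(length(keys)), keys)
    for (s in ids) {
      x <- counts[[s]]
      for (r in seq_len(nrow(x))) {
        k <- paste(x$chrom[r], x$pos[r], x$strand[r], sep = "\r")
        m[k] <- m[k] + x$meth[r]
        u[k] <- u[k] + x$unmeth[r]
      }
    }
    out[[cat]] <- list(meth = m, unmeth = u)
  }
  out
}

# ---- fixture builders -------------------------------------------------------
make_counts <- function(pos, meth, unmeth, chrom = "chr16", strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             strand = rep(strand, length.out = length(pos)),
             meth = as.integer(meth), unmeth = as.integer(unmeth),
             stringsAsFactors = FALSE)
}

trio_sheet <- function(n_mat = 1, n_pat = 1, n_bip = 1) {
  data.frame(
    sample_id = c(paste0("mat", seq_len(n_mat)),
                  paste0("pat", seq_len(n_pat)),
                  paste0("bip", seq_len(n_bip))),
    category = c(rep("upd16mat", n_mat), rep("upd16pat", n_pat),
                 rep("biparental", n_bip)),
    tissue = "blood", stringsAsFactors = FALSE
  )
}

# One sample per category with exact percents at a fixed coverage: a percent
# p at coverage c needs integer p*c/100.
trio_counts_from_pcts <- function(pos, pct_mat, pct_bip, pct_pat,
                                  coverage = 20, strand = "+",
                                  chrom = "chr16") {
  mk <- function(p) {
    m <- as.integer(round(p * coverage / 100))
    make_counts(pos, m, coverage - m, chrom = chrom, strand = strand)
  }
  list(mat1 = mk(pct_mat), pat1 = mk(pct_pat), bip1 = mk(pct_bip))
}

random_counts <- function(n, chrom = "chr16") {
  pos <- sort(sample.int(10 * n, n))
  make_counts(pos, meth = rbinom(n, 30, runif(n)),
              unmeth = rbinom(n, 30, runif(n)),
              strand = sample(c("+", "-"), n, replace = TRUE), chrom = chrom)
}
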