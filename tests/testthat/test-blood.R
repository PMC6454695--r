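make_trio_pool <- function(pcts, coverage = 20) {
  # pcts: matrix/data.frame with columns mat, bip, pat, one row per site
  pos <- seq(100, by = 10, length.out = nrow(pcts))
  counts <- trio_counts_from_pcts(pos, pcts[, 1], pcts[, 2], pcts[, 3],
                                  coverage = coverage)
  intersect_loci(pool_by_category(counts, trio_sheet()))
}

test_that("site classification needs a large delta and intermediate control", {
  pool <- make_trio_pool(rbind(
    c(90, 50, 10),   # textbook maternal imprint
    c(90, 95, 10),   # control not intermediate
    c(60, 50, 25),   # delta 35 below threshold
    c(10, 50, 90)    # mirrored, paternal
  ))
  calls <- classify_sites(pool)
  expect_equal(calls$qualifies, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(calls$direction[1], "maternal_methylated")
  expect_equal(calls$delta[1], 80)
  expect_equal(calls$direction[4], "paternal_methylated")
})

test_that("classification boundaries are exact and ties fail", {
  pool <- make_trio_pool(rbind(
    c(75, 50, 35),        # delta exactly 40 -> qualifies
    c(75, 75, 35),        # control ties maternal -> fails
    c(75, 35, 35)         # control ties paternal -> fails
  ), coverage = 20)
  calls <- classify_sites(pool)
  expect_equal(calls$qualifies, c(TRUE, FALSE, FALSE))

  # delta of 39.99 fails: percents 75 and 35.01 at coverage 10000
  pool2 <- make_trio_pool(rbind(c(75, 50, 35.01)), coverage = 10000)
  expect_false(classify_sites(pool2)$qualifies)

  # raising the threshold never increases qualifying sites
  set.seed(31)
  pcts <- cbind(runif(200, 0, 100), runif(200, 0, 100),
                runif(200, 0, 100))
  pool3 <- make_trio_pool(round(pcts * 20) / 20, coverage = 2000)
  n_q <- vapply(c(20, 40, 60, 80), function(d) {
    sum(classify_sites(pool3, delta_threshold = d)$qualifies)
  }, numeric(1))
  expect_true(all(diff(n_q) <= 0))
})

test_that("region collapse applies the single-discordant merge rule", {
  r <- collapse_pattern(c("M", "M", "M", "x", "M", "M"))
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_sites, 5L)
  expect_equal(c(r$first, r$last), c(1L, 6L))

  r <- collapse_pattern(c("M", "M", "x", "x", "M", "M"))
  expect_equal(r$n_sites, c(2L, 2L))

  r <- collapse_pattern(c("M", "M", "P", "P"))
  expect_equal(r$dir, c("M", "P"))
  expect_equal(r$n_sites, c(2L, 2L))

  # iterative merging: alternating discordant singletons fuse to one region
  r <- collapse_pattern(c("M", "x", "M", "x", "M"))
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_sites, 3L)

  # a lone opposite-direction site acts as the discordant separator
  r <- collapse_pattern(c("M", "M", "P", "M", "M"))
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_sites, 4L)

  # merge is off on request
  r <- collapse_pattern(c("M", "M", "M", "x", "M", "M"), merge = FALSE)
  expect_equal(r$n_sites, c(3L, 2L))
})

test_that("collapse matches the fixpoint oracle on random patterns", {
  set.seed(41)
  for (rep in 1:20) {
    pattern <- sample(c("M", "P", "x"), 200, replace = TRUE,
                      prob = c(0.3, 0.3, 0.4))
    expect_identical(collapse_pattern(pattern), oracle_collapse(pattern))
    expect_identical(collapse_pattern(pattern, merge = FALSE),
                     oracle_collapse(pattern, merge = FALSE))
  }
})

test_that("collapse matches exhaustive enumeration on short patterns", {
  for (len in 1:7) {
    grid <- do.call(expand.grid,
                    c(rep(list(c("M", "P", "x")), len),
                      stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      pattern <- unlist(grid[i, ], use.names = FALSE)
      expect_identical(collapse_pattern(pattern),
                       oracle_collapse(pattern))
    }
  }
})

test_that("collapse sorts unsorted input with a warning and splits chroms", {
  calls <- calls_from_pattern(c("M", "M", "M"))
  shuffled <- calls[c(2, 1, 3), ]
  expect_warning(res <- collapse_regions(shuffled), "sort")
  expect_equal(res$regions$n_sites, 3L)

  two <- rbind(calls, transform(calls, chrom = "chr2"))
  res2 <- collapse_regions(two)
  expect_equal(nrow(res2$regions), 2L)
  expect_equal(sort(unique(res2$regions$chrom)), c("chr16", "chr2"))
})

# Fixture for the region-level filters: two samples per category, explicit
# per-sample percents for a 6-site qualifying run.
filter_fixture <- function(cov_mat = 12, cov_pat = 12, cov_bip = 12,
                           mat2_pct = 90, cov_mat2 = NULL) {
  pos <- seq(100, 150, by = 10)
  n <- length(pos)
  mk <- function(p, cov) {
    make_counts(pos, as.integer(round(p * cov / 100)),
                cov - as.integer(round(p * cov / 100)))
  }
  cov_mat2 <- cov_mat2 %||% cov_mat
  counts <- list(mat1 = mk(90, cov_mat), mat2 = mk(mat2_pct, cov_mat2),
                 pat1 = mk(10, cov_pat), pat2 = mk(10, cov_pat),
                 bip1 = mk(50, cov_bip), bip2 = mk(50, cov_bip))
  sheet <- trio_sheet(n_mat = 2, n_pat = 2, n_bip = 2)
  pool <- intersect_loci(pool_by_category(counts, sheet))
  calls <- classify_sites(pool)
  list(regions = collapse_regions(calls), pool = pool)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("region filters enforce site count, coverage and concordance", {
  # all filters pass: 6 sites, pooled median coverage 24 per category
  fx <- filter_fixture()
  kept <- filter_blood_regions(fx$regions, fx$pool)
  expect_equal(nrow(kept$regions), 1L)
  expect_equal(kept$regions$n_sites, 6L)

  # paternal category pooled median coverage below 10 -> removed
  fx <- filter_fixture(cov_pat = 4)   # pooled 8 < 10
  kept <- filter_blood_regions(fx$regions, fx$pool)
  expect_equal(nrow(kept$regions), 0L)
  expect_equal(unname(attr(kept, "attrition")["removed_median_coverage"]),
               1)

  # two maternal samples at 90% vs 30% with coverage above 3 -> removed
  fx <- filter_fixture(mat2_pct = 30, cov_mat = 10, cov_mat2 = 10,
                       cov_pat = 20, cov_bip = 20)
  kept <- filter_blood_regions(fx$regions, fx$pool)
  expect_equal(nrow(kept$regions), 0L)

  # same discordance but the second sample at median coverage 3 (not > 3):
  # the concordance rule does not apply
  fx <- filter_fixture(mat2_pct = 0, cov_mat = 30, cov_mat2 = 3,
                       cov_pat = 30, cov_bip = 30)
  kept <- filter_blood_regions(fx$regions, fx$pool)
  expect_equal(nrow(kept$regions), 1L)
})

test_that("regions below the site minimum are removed", {
  pcts <- rbind(matrix(rep(c(90, 50, 10), 4), ncol = 3, byrow = TRUE),
                c(50, 50, 50))
  pool <- make_trio_pool(pcts, coverage = 20)
  calls <- classify_sites(pool)
  regions <- collapse_regions(calls)
  expect_equal(regions$regions$n_sites, 4L)
  kept <- filter_blood_regions(regions, pool)
  expect_equal(nrow(kept$regions), 0L)
  kept4 <- filter_blood_regions(regions, pool, min_sites = 4)
  expect_equal(nrow(kept4$regions), 1L)
})

test_that("raising the coverage threshold never adds surviving regions", {
  set.seed(51)
  cfg <- sim_config(n_sites = 1000, n_regions = 3, seed = 77,
                    mean_coverage = 12)
  st <- simulate_study(cfg)
  pool <- intersect_loci(pool_by_category(st$counts, st$samples))
  calls <- classify_sites(pool)
  regions <- collapse_regions(calls)
  n_regions <- vapply(c(2, 6, 10, 20, 40), function(cov) {
    nrow(filter_blood_regions(regions, pool,
                              min_median_cov = cov)$regions)
  }, numeric(1))
  expect_true(all(diff(n_regions) <= 0))
})
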