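test_that("interval restriction is 1-based inclusive on both ends", {
  counts <- make_counts(c(83673382, 86298284, 86505460), c(1, 1, 1),
                        c(1, 1, 1))
  del <- data.frame(chrom = "chr16", start = 83673382, end = 86298284)
  got <- restrict_to_interval(counts, del)
  expect_equal(got$pos, c(83673382L, 86298284L))   # boundaries in, rest out

  one <- data.frame(chrom = "chr16", start = 86505460, end = 86505460)
  expect_equal(restrict_to_interval(counts, one)$pos, 86505460L)

  off <- data.frame(chrom = "chr16", start = 1, end = 10)
  expect_warning(empty <- restrict_to_interval(counts, off), "no loci")
  expect_equal(nrow(empty), 0L)
})

test_that("coverage prefilter keeps loci captured once per sample", {
  counts <- list(
    a = make_counts(c(10, 20, 30), c(1, 5, 0), c(0, 0, 0)),
    b = make_counts(c(10, 20, 30), c(1, 0, 0), c(0, 0, 0)),
    c = make_counts(c(10, 20, 30), c(1, 9, 0), c(0, 0, 0)))
  loci <- prefilter_covered_everywhere(counts)
  expect_equal(loci$pos, 10L)           # (1,1,1) kept; (5,0,9), (0,0,0) out
  expect_error(prefilter_covered_everywhere(counts["a"]), "two samples")
})

test_that("restriction and coverage prefilter commute", {
  set.seed(61)
  counts <- list(a = random_counts(100), b = random_counts(100))
  counts <- lapply(counts, function(x) { x$strand <- "+"; x })
  del <- data.frame(chrom = "chr16", start = 200, end = 600)
  a <- prefilter_covered_everywhere(lapply(counts, restrict_to_interval,
                                           del)) |> suppressWarnings()
  pre <- prefilter_covered_everywhere(counts)
  b <- pre[pre$pos >= del$start & pre$pos <= del$end, ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("hemizygous classification requires consistent signed deltas", {
  loci <- data.frame(chrom = "chr16", pos = c(1, 2, 3, 4), strand = "+")
  calls <- classify_hemi_sites(
    hemi_pct = c(85, 50, 30, 70),
    ctrl_pct = rbind(c(55, 60), c(40, 75), c(55, 52), c(50, 50)),
    deleted_parent = "maternal", loci = loci)
  # hemi above both controls: the exposed paternal allele is methylated
  expect_equal(calls$qualifies[1], TRUE)
  expect_equal(calls$direction[1], "paternal_methylated")
  # controls straddle the carrier: mixed signs, not qualifying
  expect_false(calls$qualifies[2])
  # hemi below both controls: the deleted maternal allele was methylated
  expect_true(calls$qualifies[3])
  expect_equal(calls$direction[3], "maternal_methylated")
  # delta exactly 20 against both controls qualifies
  expect_true(calls$qualifies[4])

  # mirrored inference with a paternal deletion
  flip <- classify_hemi_sites(85, cbind(55, 60), "paternal")
  expect_equal(flip$direction, "maternal_methylated")
})

test_that("lowering the hemizygous delta never removes a qualifying site", {
  set.seed(62)
  hemi <- runif(300, 0, 100)
  ctrl <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  q30 <- classify_hemi_sites(hemi, ctrl, "maternal",
                             delta_threshold = 30)$qualifies
  q20 <- classify_hemi_sites(hemi, ctrl, "maternal",
                             delta_threshold = 20)$qualifies
  expect_true(all(q20[q30]))
})

test_that("lung regions need five cytosines and 7x in every sample", {
  loci <- data.frame(chrom = "chr16", pos = 1:5, strand = "+")
  calls <- data.frame(loci, qualifies = TRUE,
                      direction = "paternal_methylated")
  cov_ok <- matrix(7, 5, 3, dimnames = list(NULL, c("h", "c1", "c2")))
  got <- call_lung_regions(calls, cov_ok)
  expect_equal(nrow(got$regions), 1L)
  expect_equal(got$regions$n_sites, 5L)

  cov_low <- cov_ok
  cov_low[, "c2"] <- 6
  expect_equal(nrow(call_lung_regions(calls, cov_low)$regions), 0L)

  calls4 <- calls[1:4, ]
  expect_equal(nrow(call_lung_regions(calls4, cov_ok[1:4, ])$regions), 0L)
})

test_that("hemizygous caller recovers planted regions inside the deletion", {
  cfg <- sim_config(n_sites = 1500, n_regions = 0, seed = 63,
                    samples_per_category = c(hemizygous_paternal = 1,
                                             biparental = 2))
  truth <- simulate_truth(cfg)
  del <- data.frame(chrom = "chr16", start = truth$sites$pos[400],
                    end = truth$sites$pos[1400],
                    deleted_parent = "maternal", stringsAsFactors = FALSE)
  # plant two 6-site paternal-methylated regions inside the deletion
  planted <- list(600:605, 800:805)
  for (idx in planted) {
    truth$sites$p_m[idx] <- 0.05
    truth$sites$p_p[idx] <- 0.95
  }
  truth$regions <- data.frame(
    region_id = 1:2, chrom = "chr16",
    start = sapply(planted, function(i) truth$sites$pos[min(i)]),
    end = sapply(planted, function(i) truth$sites$pos[max(i)]),
    direction = "paternal_methylated",
    first_site = sapply(planted, min), last_site = sapply(planted, max),
    width_sites = 6L, stringsAsFactors = FALSE)
  stopifnot(truth$regions$start > del$start, truth$regions$end < del$end)
  st <- simulate_study(cfg, deletion = del, truth = truth)
  res <- call_lung_dmrs(st$counts, "hemizygous_paternal_1", del)
  ev <- evaluate_recovery(res$regions, truth)
  expect_equal(ev$n_recovered, 2L)
  expect_equal(ev$n_false_large, 0L)
  expect_true(all(res$regions$direction == "paternal_methylated"))
})

test_that("a synthetic null yields few qualifying sites and no regions", {
  # identical methylation in carrier and controls: three samples drawn from
  # the same biparental distribution, one arbitrarily labelled the carrier
  del <- data.frame(chrom = "chr16", start = 1, end = 10^9,
                    deleted_parent = "maternal", stringsAsFactors = FALSE)
  rates <- numeric(100)
  for (i in seq_along(rates)) {
    cfg <- sim_config(n_sites = 1000, n_regions = 0, seed = 700 + i,
                      jitter_sd = 0,
                      samples_per_category = c(biparental = 3))
    st <- simulate_study(cfg)
    res <- call_lung_dmrs(st$counts, "biparental_1", del)
    rates[i] <- res$attrition[["sites_qualifying"]] /
      res$attrition[["loci_covered_everywhere"]]
    expect_equal(nrow(res$regions), 0L)
  }
  expect_lt(mean(rates), 0.01)
})
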