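test_that("config validation rejects impossible settings", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(prop_low = 0.8, prop_high = 0.8, prop_mid = 0,
                          seed = 1), "sum to 1")
  expect_error(sim_config(n_sites = 100, n_regions = 20, region_width = 8,
                          seed = 1), "overlapping")
  expect_error(sim_config(n_sites = 11, seed = 1), "even")
})

test_that("truth generation is deterministic and marks planted regions", {
  cfg <- sim_config(n_sites = 1000, n_regions = 3, seed = 9)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)

  # null genome: identical allele probabilities everywhere
  null <- simulate_truth(sim_config(n_sites = 500, n_regions = 0,
                                    seed = 9))
  expect_identical(null$sites$p_m, null$sites$p_p)
  expect_equal(nrow(null$regions), 0L)

  # planted regions carry the configured effect in the right direction
  for (r in seq_len(nrow(t1$regions))) {
    idx <- t1$regions$first_site[r]:t1$regions$last_site[r]
    if (t1$regions$direction[r] == "maternal_methylated") {
      expect_true(all(t1$sites$p_m[idx] - t1$sites$p_p[idx] >= 0.89))
    } else {
      expect_true(all(t1$sites$p_p[idx] - t1$sites$p_m[idx] >= 0.89))
    }
    expect_true(all(t1$sites$region_id[idx] == r))
  }
  # background sites have no allelic difference
  bg <- t1$sites$region_id == 0
  expect_identical(t1$sites$p_m[bg], t1$sites$p_p[bg])
  # planted regions do not overlap and are position-sorted
  expect_true(all(diff(t1$regions$first_site) >
                    t1$regions$width_sites[-nrow(t1$regions)]))
})

test_that("strand pairs share a dinucleotide with adjacent positions", {
  cfg <- sim_config(n_sites = 200, n_regions = 0, seed = 10)
  tr <- simulate_truth(cfg)
  odd <- seq(1, 199, by = 2)
  expect_equal(tr$sites$strand[odd], rep("+", 100))
  expect_equal(tr$sites$strand[odd + 1], rep("-", 100))
  expect_equal(tr$sites$pos[odd + 1], tr$sites$pos[odd] + 1L)
  expect_equal(tr$sites$p_m[odd], tr$sites$p_m[odd + 1])
})

test_that("count sampling follows the disomy-state mixture", {
  cfg <- sim_config(n_sites = 10, n_regions = 0, jitter_sd = 0,
                    mean_coverage = 20, seed = 12)
  tr <- simulate_truth(cfg)
  tr$sites$p_m <- 1
  tr$sites$p_p <- 0
  # deterministic limit: fully methylated maternal allele in upd(16)mat
  mat <- sample_counts(tr, "upd16mat", cfg, seed = 1)
  expect_true(all(mat$unmeth == 0L))      # meth equals coverage
  pat <- sample_counts(tr, "upd16pat", cfg, seed = 1)
  expect_true(all(pat$meth == 0L))

  # biparental mixes the alleles: percent converges to 50 at deep coverage
  cfg2 <- sim_config(n_sites = 2000, n_regions = 0, jitter_sd = 0,
                     mean_coverage = 10000, dispersion = 1e6, seed = 12)
  tr2 <- simulate_truth(cfg2)
  bip <- sample_counts(tr2, "biparental", cfg2, seed = 2)
  pct <- 100 * bip$meth / (bip$meth + bip$unmeth)
  pi <- 100 * (tr2$sites$p_m + tr2$sites$p_p) / 2
  expect_lt(mean(abs(pct - pi)), 1)
  expect_gt(stats::cor(pct, pi), 0.999)
})

test_that("hemizygous sampling exposes one allele at halved coverage", {
  cfg <- sim_config(n_sites = 2000, n_regions = 0, jitter_sd = 0,
                    mean_coverage = 40, seed = 13)
  tr <- simulate_truth(cfg)
  tr$sites$p_m <- 0.9
  tr$sites$p_p <- 0.1
  mid <- tr$sites$pos[1000]
  del <- data.frame(chrom = "chr16", start = tr$sites$pos[1], end = mid)
  x <- sample_counts(tr, "hemizygous_paternal", cfg, deletion = del,
                     seed = 3)
  inside <- x$pos <= mid
  cov <- x$meth + x$unmeth
  # paternal allele exposed inside the deletion, mixture outside
  expect_lt(mean(x$meth[inside]) / mean(cov[inside]), 0.2)
  pct_out <- sum(x$meth[!inside]) / sum(cov[!inside])
  expect_gt(pct_out, 0.4)
  expect_lt(pct_out, 0.6)
  expect_lt(mean(cov[inside]), 0.6 * mean(cov[!inside]))
  expect_error(sample_counts(tr, "hemizygous_paternal", cfg),
               "deletion")
})

test_that("a full study is reproducible from its seed", {
  cfg <- sim_config(n_sites = 400, n_regions = 2, seed = 14)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  expect_equal(names(s1$counts), s1$samples$sample_id)
})

test_that("trio recovery finds planted regions at the site level", {
  cfg <- sim_config(n_sites = 2000, n_regions = 4, seed = 15)
  st <- simulate_study(cfg)
  res <- call_blood_dmrs(st$counts, st$samples)
  ev <- evaluate_recovery(res$regions, st$truth,
                          max_boundary_offset_sites = 1)
  expect_equal(ev$n_recovered, 4L)
  expect_equal(ev$n_false, 0L)
})

test_that("inverting a truth flips planted directions only", {
  cfg <- sim_config(n_sites = 400, n_regions = 2, seed = 16)
  tr <- simulate_truth(cfg)
  inv <- invert_truth(tr)
  expect_identical(inv$sites$p_m[tr$sites$region_id == 0],
                   tr$sites$p_m[tr$sites$region_id == 0])
  planted <- tr$sites$region_id > 0
  expect_identical(inv$sites$p_m[planted], tr$sites$p_p[planted])
  expect_true(all(inv$regions$direction != tr$regions$direction))
})

test_that("detection power is monotone in effect size and coverage", {
  effects <- list(c(0.65, 0.35), c(0.80, 0.20), c(0.95, 0.05))
  coverages <- c(8, 30, 90)
  sens <- matrix(NA_real_, 3, 3)
  for (i in seq_along(effects)) {
    for (j in seq_along(coverages)) {
      hits <- 0L
      for (rep in 1:2) {
        cfg <- sim_config(n_sites = 1200, n_regions = 3,
                          effect_high = effects[[i]][1],
                          effect_low = effects[[i]][2],
                          mean_coverage = coverages[j],
                          seed = 8000 + 100 * i + 10 * j + rep)
        st <- simulate_study(cfg)
        res <- call_blood_dmrs(st$counts, st$samples)
        hits <- hits + evaluate_recovery(res$regions,
                                         st$truth)$n_recovered
      }
      sens[i, j] <- hits / 6
    }
  }
  tol <- 1 / 6 + 1e-9   # one planted region of slack between cells
  expect_true(all(apply(sens, 1, diff) >= -tol))
  expect_true(all(apply(sens, 2, diff) >= -tol))
})

test_that("injected SNVs are het calls at the requested footprints", {
  cfg <- sim_config(n_sites = 100, n_regions = 0, seed = 17)
  tr <- simulate_truth(cfg)
  snv <- inject_snvs(tr, c(500L, 501L), c("a", "b"))
  expect_equal(nrow(snv), 4L)
  expect_true(all(snv$genotype == "het"))
  expect_true(all(snv$chrom == "chr16"))
  expect_equal(nrow(inject_snvs(tr, integer(0), "a")), 0L)
})
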