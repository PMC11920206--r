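test_that("site classification partitions frequencies with tolerance eps", {
  prof <- data.frame(chrom = "chr20", pos = 1:6, region = "DUP1",
                     fixed_diff = NA,
                     freq = c(1.0, 0.5, 0.30, 0.02, 0.96, 0.47),
                     n_called = c(100, 100, 100, 100, 100, 10),
                     missing_frac = 0)
  cls <- classify_sites(prof, eps = 0.05, min_called = 20)
  expect_equal(as.character(cls$class),
               c("FIXED_REF", "FIXED_HET", "POLYMORPHIC", "FIXED_ALT",
                 "FIXED_REF", "UNDEFINED"))
  # idempotent and partition-complete
  expect_identical(classify_sites(cls)$class, cls$class)
  expect_false(anyNA(cls$class))
  expect_error(classify_sites(prof, eps = 0.25), "eps")
})

test_that("bubble detection flags fixed-dominated regions only", {
  n <- 40
  prof <- data.frame(chrom = "chr20", pos = c(1:n, 101:(100 + n)),
                     region = rep(c("DUP1", "INT"), each = n),
                     fixed_diff = NA,
                     freq = c(rep(c(1, 0, 0.5), length.out = n) ,
                              runif(n, 0.25, 0.42)),
                     n_called = 100, missing_frac = 0)
  cls <- classify_sites(prof)
  regions <- list(DUP1 = fm_interval("chr20", 1, n, "DUP1"),
                  INT = fm_interval("chr20", 101, 100 + n, "INT"),
                  DUP2 = fm_interval("chr20", 300, 400, "DUP2"))
  rep_ <- detect_bubble(cls, regions, tau = 0.5)
  expect_true(rep_$bubble[rep_$region == "DUP1"])
  expect_false(rep_$bubble[rep_$region == "INT"])
  expect_equal(rep_$status[rep_$region == "DUP2"], "insufficient")
  expect_true(is.na(rep_$bubble[rep_$region == "DUP2"]))
  expect_equal(rep_$fixed_fraction[rep_$region == "DUP1"], 1)
  expect_equal(rep_$fixed_het_fraction[rep_$region == "DUP1"],
               mean(rep(c(1, 0, 0.5), length.out = n) == 0.5))
})

test_that("the change-point scan finds clean and noisy breaks", {
  cls <- fake_classes(rep(c(1, 0), each = 10))
  bp <- detect_breakpoint(cls, min_sites = 20)
  expect_equal(bp$index, 10)
  expect_equal(bp$position, 10)
  expect_equal(bp$left_rate, 1)
  expect_equal(bp$right_rate, 0)

  const <- detect_breakpoint(fake_classes(rep(1, 30)), min_sites = 20)
  expect_true(is.na(const$position))
  expect_equal(const$lrt, 0)

  # Bernoulli(0.9) -> Bernoulli(0.1), truth at 300 of 1000: recovery
  # within +/- 20 sites in >= 95% of replicates
  set.seed(19)
  hits <- vapply(1:100, function(i) {
    x <- c(rbinom(300, 1, 0.9), rbinom(700, 1, 0.1))
    bp <- detect_breakpoint(fake_classes(x))
    !is.na(bp$index) && abs(bp$index - 300) <= 20
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("reference-consistent segments are maximal qualifying runs", {
  region <- fm_interval("chr20", 1, 40, "DUP2")
  prof <- data.frame(chrom = "chr20", pos = 1:40, region = "DUP2",
                     fixed_diff = NA,
                     freq = c(rep(0.9, 10), rep(0.1, 5), rep(0.55, 8),
                              rep(0.3, 17)),
                     n_called = 100, missing_frac = 0)
  cls <- classify_sites(prof)
  seg <- reference_consistent_segments(cls, region, min_sites = 5)
  expect_equal(seg$start, c(1, 16))
  expect_equal(seg$end, c(10, 23))
  # all sites qualifying -> single segment spanning the region
  prof$freq <- 0.6
  seg1 <- reference_consistent_segments(classify_sites(prof), region)
  expect_equal(nrow(seg1), 1)
  expect_equal(c(seg1$start, seg1$end), c(1, 40))
  # alternating high/low never reaches min_sites
  prof$freq <- rep(c(0.9, 0.1), 20)
  expect_equal(nrow(reference_consistent_segments(classify_sites(prof),
                                                  region)), 0)
})

test_that("dosage r-squared matches hand computation and its invariances", {
  gt <- rbind(c(0, 0, 1, 1, 2, 2),
              c(2, 2, 1, 1, 0, 0),
              c(0, 1, 2, 0, 1, 2))
  obs <- toy_obs(gt)
  r2 <- pairwise_r2(obs)
  expect_equal(r2[1, 1], 1)
  expect_equal(r2[1, 2], 1)        # perfect negative correlation squares to 1
  expect_equal(r2[1, 3], cor(gt[1, ], gt[3, ])^2, tolerance = 1e-12)
  expect_true(isSymmetric(unname(r2)))
  # sample permutation invariance
  perm <- sample(ncol(gt))
  r2p <- pairwise_r2(toy_obs(gt[, perm]))
  expect_equal(unname(r2p), unname(r2))
  # allele relabeling (ref <-> alt flips dosage) leaves r^2 unchanged
  r2f <- pairwise_r2(toy_obs(2 - gt))
  expect_equal(unname(r2f), unname(r2))
  # too few shared calls -> undefined entry
  gt_na <- rbind(c(0, 1, 2, NA, NA, NA), c(NA, NA, NA, 0, 1, 2))
  expect_true(is.na(pairwise_r2(toy_obs(gt_na))[1, 2]))
  expect_error(pairwise_r2(toy_obs(gt[1, , drop = FALSE])), "2 usable")
})

test_that("LD boundary splits perfect blocks and ignores uniform LD", {
  # two perfect internal blocks, zero cross correlation
  set.seed(23)
  f1 <- rbinom(60, 1, 0.5); f2 <- rbinom(60, 1, 0.5)
  gt <- rbind(matrix(rep(2 * f1, 6), 6, byrow = TRUE),
              matrix(rep(2 * f2, 6), 6, byrow = TRUE))
  colnames(gt) <- sprintf("S%03d", 1:60)
  obs <- toy_obs(gt, pos = 101:112, region = "DUP1")
  bg <- toy_obs(matrix(rbinom(6 * 60, 2, 0.4), 6, 60,
                       dimnames = list(NULL, sprintf("S%03d", 1:60))),
                pos = 901:906, region = "BG1")
  comb <- obs
  comb$sites <- rbind(obs$sites, bg$sites)
  comb$gt <- rbind(obs$gt, bg$gt)
  comb$ad_ref <- rbind(obs$ad_ref, bg$ad_ref)
  comb$ad_alt <- rbind(obs$ad_alt, bg$ad_alt)
  w <- data.frame(chrom = "chr20", start = c(101, 901, 904),
                  end = c(112, 903, 906),
                  region = c("SCAN", "BG1", "BG1"), partial = FALSE)
  res <- ld_retention_and_boundary(comb, w,
                                   fm_interval("chr20", 101, 112, "DUP1"))
  expect_equal(res$boundary$index, 6)
  expect_equal(res$boundary$position, 106)
  expect_gt(res$boundary$contrast, 0.9)
  # uniform LD: no boundary reported
  gtu <- matrix(rep(2 * f1, 12), 12, byrow = TRUE,
                dimnames = list(NULL, sprintf("S%03d", 1:60)))
  combu <- comb
  combu$gt <- rbind(gtu, bg$gt)
  resu <- ld_retention_and_boundary(combu, w,
                                    fm_interval("chr20", 101, 112, "DUP1"))
  expect_true(is.na(resu$boundary$position))
  expect_error(ld_retention_and_boundary(comb, w[w$region == "SCAN", ],
                                         NULL), "background")
})
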