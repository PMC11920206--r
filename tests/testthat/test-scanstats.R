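test_that("site filtering applies MAF and call-rate thresholds", {
  # 10 samples; craft sites with known pooled MAF / call rate
  gt <- rbind(
    c(2, 2, 2, 2, 2, 2, 2, 2, 2, 1),   # maf 0.05  -> kept
    c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2),   # maf 0     -> dropped
    c(2, 2, 2, 2, 2, 2, 2, 2, 2, 0),   # maf 0.10  -> kept
    c(1, 1, 2, 0, 2, 1, 0, 2, 1, 2),   # common    -> kept
    c(1, 1, 2, 0, 2, 1, 0, 2, NA, NA), # call rate 0.8 -> dropped
    c(1, 1, 2, 0, 2, 1, 0, 2, 1, NA))  # call rate 0.9 -> kept
  obs <- toy_obs(gt)
  filt <- filter_variants(obs, maf = 0.05, max_missing = 0.9)
  expect_equal(filt$sites$pos, c(1, 3, 4, 6))
  # site with maf 0.04 (1/24 = 0.042) removed
  gt2 <- matrix(2, 1, 12); gt2[1, 1] <- 1
  expect_equal(nrow(filter_variants(toy_obs(gt2))$gt), 0)
})

test_that("group allele frequencies match brute-force recomputation", {
  expect_equal(ref_allele_frequency(toy_obs(matrix(2, 3, 4)),
                                    sprintf("S%03d", 1:4))$freq, rep(1, 3))
  expect_equal(ref_allele_frequency(toy_obs(matrix(1, 3, 4)),
                                    sprintf("S%03d", 1:4))$freq, rep(0.5, 3))
  expect_equal(ref_allele_frequency(toy_obs(matrix(c(2, 1, 0), 1, 3)),
                                    sprintf("S%03d", 1:3))$freq, 0.5)
  set.seed(7)
  for (rep in 1:5) {
    gt <- matrix(sample(c(0:2, NA), 5 * 8, replace = TRUE), 5, 8,
                 dimnames = list(NULL, sprintf("S%03d", 1:8)))
    obs <- toy_obs(gt)
    grp <- sample(colnames(gt), 4)
    expect_equal(ref_allele_frequency(obs, grp)$freq, freq_oracle(gt, grp))
  }
  expect_error(ref_allele_frequency(toy_obs(matrix(1, 2, 2)), "ghost"),
               "unknown")
})

test_that("windowed pi matches the hand formula", {
  # one site, 4 called alleles split 2/2, window of 1000 bp
  gt <- matrix(c(2, 0, NA, NA), 1, 4)
  obs <- toy_obs(gt, pos = 500)
  w <- data.frame(chrom = "chr20", start = 1, end = 1000, region = "SCAN",
                  partial = FALSE)
  pi <- windowed_pi(obs, sprintf("S%03d", 1:4), w)
  expect_equal(pi$value, (2 * 2 / choose(4, 2)) / 1000)
  expect_equal(pi$n_sites, 1)
  # monomorphic window is zero
  expect_equal(windowed_pi(toy_obs(matrix(2, 4, 4)), sprintf("S%03d", 1:4),
                           w)$value, 0)
  # random toys against the site-loop oracle
  set.seed(11)
  for (rep in 1:5) {
    gt <- matrix(sample(c(0:2, NA), 6 * 10, replace = TRUE), 6, 10,
                 dimnames = list(NULL, sprintf("S%03d", 1:10)))
    obs <- toy_obs(gt)
    grp <- sprintf("S%03d", 1:10)
    w6 <- data.frame(chrom = "chr20", start = 1, end = 6, region = "SCAN",
                     partial = FALSE)
    expect_equal(windowed_pi(obs, grp, w6)$value, pi_oracle(gt, grp, 6))
  }
})

test_that("Weir-Cockerham FST agrees with the formula-literal oracle", {
  set.seed(13)
  grp_a <- sprintf("S%03d", 1:10); grp_b <- sprintf("S%03d", 11:20)
  w <- data.frame(chrom = "chr20", start = 1, end = 50, region = "SCAN",
                  partial = FALSE)
  for (rep in 1:30) {
    p1 <- runif(1); p2 <- runif(1)
    gt <- cbind(matrix(rbinom(8 * 10, 2, p1), 8, 10),
                matrix(rbinom(8 * 10, 2, p2), 8, 10))
    gt[sample(length(gt), 5)] <- NA
    colnames(gt) <- sprintf("S%03d", 1:20)
    obs <- toy_obs(gt)
    got <- windowed_fst(obs, grp_a, grp_b, w)$value
    want <- wc_fst_oracle(gt, grp_a, grp_b)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # identical frequencies: near zero; opposite fixation: exactly one
  gt_same <- matrix(rbinom(20 * 100, 2, 0.4), 20, 100)
  colnames(gt_same) <- sprintf("S%03d", 1:100)
  v <- windowed_fst(toy_obs(gt_same), sprintf("S%03d", 1:50),
                    sprintf("S%03d", 51:100), w)$value
  expect_lt(abs(v), 0.05)
  gt_opp <- cbind(matrix(2, 5, 10), matrix(0, 5, 10))
  colnames(gt_opp) <- sprintf("S%03d", 1:20)
  expect_equal(windowed_fst(toy_obs(gt_opp), grp_a, grp_b, w)$value, 1)
  expect_error(windowed_fst(toy_obs(gt_opp), grp_a, c(grp_a[1], grp_b)),
               "overlap")
})

test_that("Z-scores, one-sided p-values and BH q-values are correct", {
  bg <- data.frame(value = c(0, 2))          # mean 1, sd sqrt(2)
  mk <- function(values) {
    structure(data.frame(chrom = "chr20", start = seq_along(values),
                         end = seq_along(values), region = "SCAN",
                         partial = FALSE, n_sites = 1, value = values),
              class = c("fm_window_stats", "data.frame"))
  }
  z0 <- zscore_fdr(mk(1), background = bg)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 0.5)
  z165 <- zscore_fdr(mk(1 + sqrt(2) * 1.645), background = bg)
  expect_equal(z165$p, 0.05, tolerance = 1e-3)
  # BH step-up by hand: p = (.01,.02,.03,.04), m = 4 -> q all 0.04
  vals <- 1 + sqrt(2) * qnorm(c(0.01, 0.02, 0.03, 0.04), lower.tail = FALSE)
  q <- zscore_fdr(mk(vals), background = bg)$q
  expect_equal(q, rep(0.04, 4), tolerance = 1e-12)
  # q monotone in p-rank; 5% flags are a superset of 1% flags
  set.seed(17)
  vals <- rnorm(40, 1, 2)
  ann <- zscore_fdr(mk(vals), background = bg)
  ord <- order(ann$p)
  expect_true(all(diff(ann$q[ord]) >= -1e-12))
  expect_true(all(which(ann$q < 0.01) %in% which(ann$q < 0.05)))
  expect_error(zscore_fdr(mk(1), background = data.frame(value = c(1, 1))),
               "SD")
})

test_that("the sliding-window grid keeps flagged partial windows", {
  map <- build_region_map(100)
  w <- make_windows(map)
  scan <- w[w$region == "SCAN", ]
  expect_equal(scan$start[1], map$scan_region$start)
  expect_equal(diff(scan$start)[1], round(10000 / 100))
  expect_true(all(scan$end <= map$scan_region$end))
  expect_true(all(scan$partial == (scan$end - scan$start + 1 < 200)))
  expect_true(any(startsWith(w$region, "BG")))
})
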