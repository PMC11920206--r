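test_that("copy number and reference dosage follow the FM genotype", {
  s <- sim_small(config = "FM-2", seed = 41, n_wt = 3, n_fm_het = 3,
                 n_fm_hom = 3)
  pop <- s$pop
  ind <- pop$individuals
  wt <- which(ind$truth == "N/N")[1]
  het <- which(ind$truth == "FM/N")[1]
  hom <- which(ind$truth == "FM/FM")[1]
  cs_wt <- site_copy_state(pop, wt)
  expect_true(all(cs_wt$c == 2))
  expect_true(all(cs_wt$d >= 0 & cs_wt$d <= cs_wt$c))
  cs_het <- site_copy_state(pop, het)
  cs_hom <- site_copy_state(pop, hom)
  dup <- cs_het$region %in% c("DUP1", "DUP2")
  expect_true(all(cs_het$c[dup] == 3))
  expect_true(all(cs_hom$c[dup] == 4))
  expect_true(all(cs_het$c[!dup] == 2))
  expect_true(all(cs_hom$d <= cs_hom$c))
  expect_error(site_copy_state(pop, "nope"), "unknown")
})

test_that("deterministic observation is an exact function of (d, c) and the band", {
  s <- sim_small(config = "FM-2", seed = 43, n_wt = 2, n_fm_hom = 2,
                 donor_divergence = 1)
  obs <- observe(s$pop, depth = 30, error_rate = 0, deterministic = TRUE)
  for (j in seq_len(nrow(s$pop$individuals))) {
    cs <- site_copy_state(s$pop, j)
    frac <- cs$d / cs$c
    expected <- ifelse(frac > 0.8, 2L, ifelse(frac < 0.2, 0L, 1L))
    expect_identical(unname(obs$gt[, j]), expected)
  }
  # FM/FM at a donor fixed difference has ref fraction exactly 1/2 -> het
  hom <- which(s$pop$individuals$truth == "FM/FM")
  fd <- which(s$pop$registry$region == "DUP1")   # all fixed diffs here
  expect_true(all(obs$gt[fd, hom] == 1L))
})

test_that("read sampling yields near-certain het calls at fixed differences", {
  s <- sim_small(config = "FM-2", seed = 45, donor_divergence = 1)
  obs <- s$obs
  hom <- obs$samples$sample[obs$samples$truth == "FM/FM"]
  fd <- obs$sites$region == "DUP1" & obs$sites$fixed_diff
  called_het <- mean(obs$gt[fd, hom] == 1L, na.rm = TRUE)
  expect_gt(called_het, 0.95)
})

test_that("relative depth conserves the copy-number signal", {
  s <- sim_small(config = "FM-2", seed = 47)
  obs <- s$obs
  map <- s$map
  truth <- obs$samples$truth
  rd1 <- relative_depth(obs, map$dup1)
  rdi <- relative_depth(obs, map$int_region)
  # WT samples: ratio 1 in all regions (4 SE Poisson tolerance)
  n_dup1 <- sum(obs$sites$region == "DUP1")
  se <- sqrt(1 / (30 * n_dup1)) * 2    # rough SE of the ratio at depth 30
  expect_true(all(abs(rd1[truth == "N/N"] - 1) < 4 * se + 0.05))
  expect_true(all(abs(rd1[truth == "FM/FM"] - 2) < 4 * se + 0.1))
  expect_true(all(abs(rdi[truth == "FM/FM"] - 1) < 4 * se + 0.05))
})

test_that("VCF output round-trips and encodes missing calls correctly", {
  s <- sim_small(config = "FM-2", seed = 49, n_wt = 3, n_fm_hom = 3)
  obs <- s$obs
  obs$gt[5, 2] <- NA; obs$ad_ref[5, 2] <- 0; obs$ad_alt[5, 2] <- 0
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(obs, path)
  back <- read_vcf(path, map = s$map)
  expect_identical(unname(back$gt), unname(obs$gt))
  expect_equal(unname(back$ad_ref), unname(round(obs$ad_ref)))
  expect_equal(back$sites$pos, obs$sites$pos)
  expect_identical(colnames(back$gt), colnames(obs$gt))
  # missing call written as ./. with AD 0,0
  lines <- readLines(path)
  row5 <- strsplit(lines[grepl("^chr", lines)][5], "\t")[[1]]
  expect_identical(row5[11], "./.:0,0")
})

test_that("header-only VCFs and multiallelic records are handled", {
  s <- sim_small(seed = 51, n_wt = 2, n_fm_hom = 2)
  empty <- s$obs
  keep <- rep(FALSE, nrow(empty$gt))
  empty$sites <- empty$sites[keep, ]; empty$gt <- empty$gt[keep, , drop = FALSE]
  empty$ad_ref <- empty$ad_ref[keep, , drop = FALSE]
  empty$ad_alt <- empty$ad_alt[keep, , drop = FALSE]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(empty, path)
  expect_true(any(grepl("^#CHROM", readLines(path))))

  multi <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr20,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr20\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr20\t20\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t1/2",
    "chr20\t30\t.\tA\tG\t.\tPASS\t.\tGT\t1|1\t./.")
  mpath <- withr::local_tempfile(fileext = ".vcf")
  writeLines(multi, mpath)
  suppressMessages(v <- read_vcf(mpath))
  expect_equal(attr(v, "n_multiallelic_skipped"), 1)
  expect_equal(nrow(v$gt), 2)
  expect_identical(unname(v$gt[2, ]), c(0L, NA_integer_))  # phased accepted
})
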