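test_that("site placement is Poisson at the requested density", {
  map <- build_region_map(1)
  params <- fm_sim_params(n_wt = 3, n_fm_hom = 3, site_density = 1 / 200,
                          seed = 1)
  f <- simulate_founders(map, params, seed = 42)
  n_dup1 <- sum(f$registry$region == "DUP1")
  lambda <- interval_length_bp(map$dup1) * (1 / 200)   # ~637
  expect_lt(abs(n_dup1 - lambda), 4 * sqrt(lambda))
  expect_true(all(diff(f$registry$pos) > 0))
  expect_true(all(f$registry$region %in%
                    c("FLANK1", "DUP1", "INT", "DUP2", "FLANK2", "BG1", "BG2")))
  # scaled maps keep expected per-region counts
  f100 <- simulate_founders(build_region_map(100), params, seed = 42)
  n100 <- sum(f100$registry$region == "DUP1")
  expect_lt(abs(n100 - lambda), 4 * sqrt(lambda))
})

test_that("the symmetric-SFS limit pins founder frequencies at one half", {
  map <- build_region_map(100)
  f <- simulate_founders(map, fm_sim_params(sfs_alpha = Inf, seed = 2),
                         seed = 2)
  expect_true(all(f$registry$p_founder == 0.5))
})

test_that("simulation is fully deterministic under a fixed seed", {
  map <- build_region_map(100)
  p <- fm_sim_params(n_wt = 10, n_fm_het = 5, n_fm_hom = 10, seed = 99)
  a <- simulate_population(map, p)
  b <- simulate_population(map, p)
  expect_identical(a$registry, b$registry)
  expect_identical(a$pool, b$pool)
  expect_identical(a$fm_haps, b$fm_haps)
  expect_identical(a$individuals, b$individuals)
})

test_that("the FM allele carries donor copies with forced fixed differences", {
  map <- build_region_map(100)
  params <- fm_sim_params(donor_divergence = 1, seed = 5)
  f <- simulate_founders(map, params, seed = 5)
  hap <- construct_fm_allele(f, params = params, seed = 6)
  dup1 <- which(f$registry$region == "DUP1")
  int <- which(f$registry$region == "INT")
  expect_true(all(hap$main[dup1] != hap$dup1_copy2))
  expect_true(all(hap$fixed_diff[dup1]))
  expect_false(any(hap$fixed_diff[int]))
  # single-copy regions take donor A's alleles
  expect_identical(hap$main[int], f$pool[int, hap$donors[1]])
  # zero divergence: copies equal wherever donors happened to agree
  p0 <- fm_sim_params(donor_divergence = 0, seed = 5)
  h0 <- construct_fm_allele(f, params = p0, donor_idx = c(1, 2))
  agree <- f$pool[dup1, 1] == f$pool[dup1, 2]
  expect_true(all(h0$main[dup1][agree] == h0$dup1_copy2[agree]))
  expect_false(any(h0$fixed_diff[dup1][agree]))
  # FM-2 copy counts: two DUP1 copies, one INT, two DUP2
  expect_false(is.null(hap$dup1_copy2))
  expect_false(is.null(hap$dup2_copy2))
  tiny <- f; tiny$pool <- f$pool[, 1, drop = FALSE]
  expect_error(construct_fm_allele(tiny, params = params), "donors")
})

test_that("erosion replaces free segments at the specified rate", {
  map <- build_region_map(100)
  params <- fm_sim_params(config = "FM-2", donor_divergence = 1, seed = 11)
  f <- simulate_founders(map, params, seed = 11)
  founder <- construct_fm_allele(f, params = params, seed = 12)
  int <- which(f$registry$region == "INT")
  dup1 <- which(f$registry$region == "DUP1")

  p0 <- params; p0$erosion_p <- 0
  none <- erode_population(founder, f, p0, 5, seed = 13)
  for (h in none) expect_identical(h$main, founder$main)

  p1 <- params; p1$erosion_p <- 1
  all_er <- erode_population(founder, f, p1, 5, seed = 14)
  for (h in all_er) {
    # frozen DUP1 copies and the frozen (inverted) DUP2 copy are untouched
    expect_identical(h$main[dup1], founder$main[dup1])
    expect_identical(h$dup1_copy2, founder$dup1_copy2)
    # INT and the free DUP2 copy now match some wild-type haplotype
    expect_true(any(apply(f$pool[int, ], 2, identical, h$main[int])))
  }
  ev <- attr(all_er, "erosion_events")
  expect_true(all(ev$eroded))

  ph <- params; ph$erosion_p <- 0.5
  many <- erode_population(founder, f, ph, 200, seed = 15)
  ev <- attr(many, "erosion_events")
  frac <- mean(ev$eroded[ev$segment == "INT"])
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 200))
})

test_that("under FM-2 the frozen DUP1 span is identical across FM chromosomes", {
  s <- sim_small(config = "FM-2", seed = 21, donor_divergence = 1)
  dup1 <- which(s$pop$registry$region == "DUP1")
  ref_main <- s$pop$fm_haps[[1]]$main[dup1]
  ref_c2 <- s$pop$fm_haps[[1]]$dup1_copy2
  for (h in s$pop$fm_haps) {
    expect_identical(h$main[dup1], ref_main)
    expect_identical(h$dup1_copy2, ref_c2)
    expect_true(all(h$fixed_diff[dup1]))
  }
})

test_that("individual assembly honours requested class counts", {
  map <- build_region_map(100)
  p <- fm_sim_params(n_wt = 10, n_fm_het = 5, n_fm_hom = 5, seed = 31)
  pop <- simulate_population(map, p)
  expect_equal(nrow(pop$individuals), 20)
  expect_equal(as.integer(table(pop$individuals$truth)[c("N/N", "FM/N",
                                                         "FM/FM")]),
               c(10L, 5L, 5L))
  hets <- pop$individuals[pop$individuals$truth == "FM/N", ]
  expect_true(all((hets$hap1_type == "fm") != (hets$hap2_type == "fm")))
  p0 <- fm_sim_params(n_wt = 4, n_fm_hom = 0, n_fm_het = 2, seed = 31)
  pop0 <- simulate_population(map, p0)
  expect_false(any(pop0$individuals$truth == "FM/FM"))
  # requesting more individuals than the pool can serve fails loudly
  f <- simulate_founders(map, p, n_pool = 3, seed = 1)
  expect_error(assemble_individuals(f, list(), p), "insufficient")
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(fm_sim_params(erosion_p = 1.2), "probability")
  expect_error(fm_sim_params(n_wt = -1), "integer")
  expect_error(fm_sim_params(site_density = 0), "site_density")
  expect_error(fm_sim_params(config = "XX"))
})
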