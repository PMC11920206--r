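# Shared fixtures and independent oracles used across the suite.

# Build a minimal observed dataset straight from a genotype-dosage matrix
# (sites x samples; entries 0/1/2 reference dosage, NA missing).
toy_obs <- function(gt, pos = NULL, region = "INT", chrom = "chr20",
                    fixed_diff = FALSE, map = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(colnames(gt))) colnames(gt) <- sprintf("S%03d", seq_len(ncol(gt)))
  if (is.null(pos)) pos <- seq_len(n)
  sites <- data.frame(chrom = chrom, pos = pos,
                      region = rep_len(region, n),
                      p_founder = NA_real_,
                      fixed_diff = rep_len(fixed_diff, n),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  ad_ref <- ifelse(is.na(gt), 0, gt * 10)
  ad_alt <- ifelse(is.na(gt), 0, (2 - gt) * 10)
  structure(list(sites = sites, gt = gt, ad_ref = ad_ref, ad_alt = ad_alt,
                 depth = NULL,
                 samples = data.frame(sample = colnames(gt),
                                      truth = NA_character_,
                                      stringsAsFactors = FALSE),
                 map = map, het_band = c(0.2, 0.8), depth_mean = 30,
                 error_rate = 0),
            class = "fm_observed")
}

# Formula-literal Weir & Cockerham (1984) two-population FST oracle: loops
# over sites, computes the variance components step by step from raw
# genotype tables, and returns the ratio-of-sums estimate over all sites.
wc_fst_oracle <- function(gt, group_a, group_b) {
  num <- 0; den <- 0
  r <- 2
  for (s in seq_len(nrow(gt))) {
    ga <- gt[s, group_a]; gb <- gt[s, group_b]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    n1 <- length(ga); n2 <- length(gb)
    if (n1 < 1 || n2 < 1) next
    p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
    h1 <- sum(ga == 1) / n1;  h2 <- sum(gb == 1) / n2
    nbar <- (n1 + n2) / r
    if (nbar <= 1) next
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) NA_real_ else num / den
}

# Brute-force per-group reference-allele frequency from a genotype table.
freq_oracle <- function(gt, group) {
  apply(gt[, group, drop = FALSE], 1, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) NA_real_ else sum(g) / (2 * length(g))
  })
}

# Brute-force windowed pi for one window over all rows of a genotype table.
pi_oracle <- function(gt, group, L) {
  tot <- 0
  for (s in seq_len(nrow(gt))) {
    g <- gt[s, group]; g <- g[!is.na(g)]
    n <- 2 * length(g)
    if (n < 2) next
    nr <- sum(g); na_ <- n - nr
    tot <- tot + nr * na_ / choose(n, 2)
  }
  tot / L
}

# Fake classified profile for breakpoint tests: binary fixed-het series.
fake_classes <- function(x, pos = seq_along(x)) {
  data.frame(chrom = "chr20", pos = pos, region = "DUP1", fixed_diff = NA,
             freq = ifelse(x == 1, 0.5, 0.9), n_called = 100,
             missing_frac = 0,
             class = factor(ifelse(x == 1, "FIXED_HET", "POLYMORPHIC"),
                            levels = c("FIXED_REF", "FIXED_ALT", "FIXED_HET",
                                       "POLYMORPHIC", "UNDEFINED")),
             stringsAsFactors = FALSE)
}

# Small default simulation shared by end-to-end tests.
sim_small <- function(config = "FM-2", seed = 1, ...) {
  map <- build_region_map(100)
  pop <- simulate_population(map, fm_sim_params(config = config, seed = seed,
                                                ...))
  list(map = map, pop = pop,
       obs = observe(pop, depth = 30, seed = seed + 7919))
}
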