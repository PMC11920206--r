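# Observation model: what short-read mapping against the single-copy
# reference would produce from a simulated population. Reads from every
# chromosomal copy of a duplicated locus pile onto the one reference copy, so
# read depth sums over copies and the allele fraction averages over paralogs;
# a diploid caller then sees depth-inflated sites whose allele fractions sit
# at multiples of 1/c.

# Per-haplotype copy count and reference-allele sum at every registry site.
.hap_copy_ref <- function(hap, registry, geometry = NULL) {
  if (is.matrix(hap) || is.numeric(hap)) {        # wild-type pool haplotype
    return(list(copies = rep(1L, length(hap)), ref = hap))
  }
  stopifnot(inherits(hap, "fm_haplotype"))
  copies <- rep(1L, nrow(registry)); ref <- hap$main
  if (!is.null(hap$dup1_copy2)) {
    idx <- which(registry$region == "DUP1")
    copies[idx] <- 2L; ref[idx] <- ref[idx] + hap$dup1_copy2
  }
  if (!is.null(hap$dup2_copy2)) {
    idx <- which(registry$region == "DUP2")
    copies[idx] <- 2L; ref[idx] <- ref[idx] + hap$dup2_copy2
  }
  list(copies = copies, ref = ref)
}

#' Copy number and reference dosage of one individual at every site
#'
#' For an individual's pair of haplotypes, returns the total chromosomal copy
#' number `c` of each site's locus (2 outside duplications; 3 for FM/N and 4
#' for FM/FM inside a duplicated region) and the number `d` of those copies
#' carrying the reference allele.
#'
#' @param pop an `fm_population`.
#' @param individual sample name or row index.
#' @return data.frame with columns `pos`, `region`, `c`, `d`.
#' @export
site_copy_state <- function(pop, individual) {
  ind <- pop$individuals
  j <- if (is.character(individual)) match(individual, ind$sample)
       else as.integer(individual)
  if (is.na(j) || j < 1 || j > nrow(ind)) stop("unknown individual")
  get_hap <- function(type, idx)
    if (type == "wt") pop$pool[, idx] else pop$fm_haps[[idx]]
  h1 <- .hap_copy_ref(get_hap(ind$hap1_type[j], ind$hap1_idx[j]), pop$registry)
  h2 <- .hap_copy_ref(get_hap(ind$hap2_type[j], ind$hap2_idx[j]), pop$registry)
  data.frame(pos = pop$registry$pos, region = pop$registry$region,
             c = h1$copies + h2$copies, d = h1$ref + h2$ref)
}

# sites x individuals matrices of c and d for the whole population.
.population_copy_state <- function(pop) {
  ind <- pop$individuals
  ns <- nrow(pop$registry); ni <- nrow(ind)
  cm <- matrix(0L, ns, ni); dm <- matrix(0L, ns, ni)
  hap_cache <- new.env(parent = emptyenv())
  get_cr <- function(type, idx) {
    key <- paste0(type, idx)
    if (!is.null(hap_cache[[key]])) return(hap_cache[[key]])
    h <- if (type == "wt") pop$pool[, idx] else pop$fm_haps[[idx]]
    cr <- .hap_copy_ref(h, pop$registry)
    hap_cache[[key]] <- cr
    cr
  }
  for (j in seq_len(ni)) {
    a <- get_cr(ind$hap1_type[j], ind$hap1_idx[j])
    b <- get_cr(ind$hap2_type[j], ind$hap2_idx[j])
    cm[, j] <- a$copies + b$copies
    dm[, j] <- a$ref + b$ref
  }
  list(c = cm, d = dm)
}

.depth_windows <- function(map) {
  w_len <- max(1, round(20000 / map$scale))
  grid <- function(r) {
    starts <- seq(r$start, r$end, by = w_len)
    data.frame(chrom = r$chrom, start = starts,
               end = pmin(starts + w_len - 1, r$end),
               region = r$label, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c(list(map$scan_region), map$background_regions), grid))
}

#' Observe a simulated population through collapsed-reference sequencing
#'
#' Per site and sample, the read count is Poisson with mean
#' `depth * c / 2` (c = chromosomal copy number), reference reads are
#' Binomial with success probability `(d/c)(1-e) + (1-d/c)e`, and the diploid
#' genotype is called from the reference-read fraction: missing if no reads,
#' hom-alt below `het_band[1]`, hom-ref above `het_band[2]`, het otherwise
#' (band edges call het). Window depths average site read counts within
#' non-overlapping 20 kb/scale windows; the genome background is the mean
#' over background-region sites.
#'
#' @param pop an `fm_population`.
#' @param depth mean haploid-pair coverage (reads per site for c = 2).
#' @param error_rate per-read allele error rate, in `[0, 0.5)`.
#' @param het_band reference-fraction band `(lo, hi)` called heterozygous.
#' @param seed optional seed.
#' @param deterministic if `TRUE`, replaces sampling with expectations
#'   (`n = depth*c/2`, ref fraction exact) so calls are a pure function of
#'   `(d, c)` and the band.
#' @return object of class `fm_observed`: `sites` (registry + truth flags),
#'   `gt` (sites x samples reference-allele dosage 0/1/2, `NA` missing),
#'   `ad_ref`/`ad_alt` read-count matrices, `depth` (list: `windows`
#'   data.frame, `matrix` windows x samples, `background` per-sample mean),
#'   `samples` data.frame with truth labels.
#' @export
observe <- function(pop, depth = 30, error_rate = 0.001,
                    het_band = c(0.2, 0.8), seed = NULL,
                    deterministic = FALSE) {
  stopifnot(inherits(pop, "fm_population"))
  if (nrow(pop$individuals) == 0) stop("empty population")
  if (depth <= 0) stop_invalid("depth must be > 0")
  if (error_rate < 0 || error_rate >= 0.5)
    stop_invalid("error_rate must be in [0, 0.5)")
  lo <- het_band[1]; hi <- het_band[2]
  if (!(0 < lo && lo < hi && hi < 1))
    stop_invalid("het_band must satisfy 0 < lo < hi < 1")
  if (!is.null(seed)) set.seed(seed)
  cs <- .population_copy_state(pop)
  frac <- cs$d / cs$c
  pref <- frac * (1 - error_rate) + (1 - frac) * error_rate
  mu <- depth * cs$c / 2
  if (deterministic) {
    n <- mu
    ref <- n * pref
  } else {
    n <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    ref <- matrix(stats::rbinom(length(n), n, pref), nrow(n), ncol(n))
  }
  alt <- n - ref
  ratio <- ifelse(n > 0, ref / n, NA_real_)
  gt <- matrix(NA_integer_, nrow(n), ncol(n))
  gt[!is.na(ratio) & ratio > hi] <- 2L
  gt[!is.na(ratio) & ratio < lo] <- 0L
  gt[!is.na(ratio) & ratio >= lo & ratio <= hi] <- 1L
  samples <- pop$individuals$sample
  colnames(gt) <- colnames(ref) <- colnames(alt) <- samples

  dw <- .depth_windows(pop$map)
  pos <- pop$registry$pos
  widx <- lapply(seq_len(nrow(dw)),
                 function(i) which(pos >= dw$start[i] & pos <= dw$end[i]))
  dmat <- t(vapply(widx, function(ix) {
    if (length(ix) == 0) rep(NA_real_, length(samples))
    else colMeans(n[ix, , drop = FALSE])
  }, numeric(length(samples))))
  colnames(dmat) <- samples
  keep <- !is.na(dmat[, 1])
  bg_rows <- which(startsWith(pop$registry$region, "BG"))
  background <- colMeans(n[bg_rows, , drop = FALSE])

  sites <- pop$registry
  sites$fixed_diff <- pop$founder$fixed_diff
  sites$ref <- "A"; sites$alt <- "G"
  structure(list(
    sites = sites, gt = gt, ad_ref = ref, ad_alt = alt,
    depth = list(windows = dw[keep, , drop = FALSE],
                 matrix = dmat[keep, , drop = FALSE],
                 background = background),
    samples = data.frame(sample = samples, truth = pop$individuals$truth,
                         stringsAsFactors = FALSE),
    map = pop$map,
    het_band = het_band, depth_mean = depth, error_rate = error_rate
  ), class = "fm_observed")
}

#' @export
print.fm_observed <- function(x, ...) {
  cat("Collapsed-reference observation:", nrow(x$gt), "sites x",
      ncol(x$gt), "samples\n")
  cat("  mean depth:", x$depth_mean, " het band: (",
      x$het_band[1], ",", x$het_band[2], ")\n")
  invisible(x)
}
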