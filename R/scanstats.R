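# Windowed population-genetic scan statistics on the collapsed genotype
# matrix: site filtering (MAF / missingness), per-group reference-allele
# frequency profiles, windowed nucleotide diversity, the Weir & Cockerham
# (1984) FST estimator (ratio-of-sums over windows), and Z-score + BH-FDR
# annotation against the genome-background window distribution.

.subset_sites <- function(obs, keep) {
  obs$sites <- obs$sites[keep, , drop = FALSE]
  rownames(obs$sites) <- NULL
  obs$gt <- obs$gt[keep, , drop = FALSE]
  obs$ad_ref <- obs$ad_ref[keep, , drop = FALSE]
  obs$ad_alt <- obs$ad_alt[keep, , drop = FALSE]
  obs
}

.group_cols <- function(obs, group) {
  j <- match(group, colnames(obs$gt))
  if (anyNA(j))
    stop("unknown sample(s) in group: ",
         paste(group[is.na(j)], collapse = ", "))
  j
}

#' Filter variant sites on MAF and missingness
#'
#' Keeps biallelic sites with minor-allele frequency at least `maf` (computed
#' from all called alleles across all samples) and per-site call rate at
#' least `max_missing` (the VCFtools `--max-missing` convention: 0.9 keeps
#' sites with at most 10% missing genotypes). Site order is preserved.
#'
#' @param obs an `fm_observed`.
#' @param maf minimum minor-allele frequency.
#' @param max_missing minimum call rate.
#' @return the filtered `fm_observed`.
#' @export
filter_variants <- function(obs, maf = 0.05, max_missing = 0.9) {
  stopifnot(inherits(obs, "fm_observed"))
  called <- !is.na(obs$gt)
  n_called <- 2 * rowSums(called)
  n_ref <- rowSums(obs$gt, na.rm = TRUE)
  p <- ifelse(n_called > 0, n_ref / n_called, NA_real_)
  m <- pmin(p, 1 - p)
  call_rate <- rowMeans(called)
  keep <- !is.na(m) & m >= maf & call_rate >= max_missing
  .subset_sites(obs, keep)
}

#' Reference-allele frequency profile for a sample group
#'
#' Per site, the reference-allele frequency computed from called genotypes in
#' the group: `(2 hom-ref + het) / (2 called)`.
#'
#' @param obs an `fm_observed`.
#' @param group character vector of sample names.
#' @return data.frame of class `fm_freq_profile`: chrom, pos, region,
#'   `fixed_diff` truth flag, `freq` (NA when nothing called), `n_called`
#'   (called alleles), `missing_frac`.
#' @export
ref_allele_frequency <- function(obs, group) {
  j <- .group_cols(obs, group)
  g <- obs$gt[, j, drop = FALSE]
  called <- !is.na(g)
  n_called <- 2 * rowSums(called)
  freq <- ifelse(n_called > 0, rowSums(g, na.rm = TRUE) / n_called, NA_real_)
  out <- data.frame(chrom = obs$sites$chrom, pos = obs$sites$pos,
                    region = obs$sites$region,
                    fixed_diff = obs$sites$fixed_diff,
                    freq = freq, n_called = n_called,
                    missing_frac = 1 - rowMeans(called),
                    stringsAsFactors = FALSE)
  class(out) <- c("fm_freq_profile", "data.frame")
  out
}

#' Sliding-window grid over the scan and background regions
#'
#' Windows are 1-based inclusive `[start, start + window - 1]`, advancing by
#' `step` from each region's start; the final partial window is kept and
#' flagged. Defaults are the 20 kb / 10 kb grid divided by the map scale.
#'
#' @param map an `fm_region_map`.
#' @param window,step window length and step in bp (already at map scale).
#' @return data.frame: chrom, start, end, region, partial.
#' @export
make_windows <- function(map, window = max(1, round(20000 / map$scale)),
                         step = max(1, round(10000 / map$scale))) {
  if (window < 1 || step < 1) stop_invalid("window and step must be >= 1")
  grid <- function(r) {
    starts <- seq(r$start, r$end, by = step)
    ends <- pmin(starts + window - 1, r$end)
    data.frame(chrom = r$chrom, start = starts, end = ends,
               region = r$label, partial = ends - starts + 1 < window,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c(list(map$scan_region),
                                 map$background_regions), grid))
  rownames(out) <- NULL
  out
}

.window_site_index <- function(windows, pos) {
  lapply(seq_len(nrow(windows)),
         function(i) which(pos >= windows$start[i] & pos <= windows$end[i]))
}

#' Windowed nucleotide diversity
#'
#' Per window, `pi = sum_sites[n_ref * n_alt / C(n, 2)] / L` where `n` is the
#' number of called alleles at the site within the group and `L` the window
#' length in bp — the standard VCF-based windowed-pi definition (monomorphic
#' and uncalled sites contribute zero).
#'
#' @param obs an `fm_observed`.
#' @param group character vector of sample names.
#' @param windows window grid from [make_windows()].
#' @return data.frame of class `fm_window_stats`: window columns plus
#'   `n_sites` and `value`; attribute `stat = "pi"`.
#' @export
windowed_pi <- function(obs, group, windows) {
  if (any(windows$end < windows$start)) stop_invalid("zero-length window")
  j <- .group_cols(obs, group)
  g <- obs$gt[, j, drop = FALSE]
  n <- 2 * rowSums(!is.na(g))
  n_ref <- rowSums(g, na.rm = TRUE)
  n_alt <- n - n_ref
  contrib <- ifelse(n >= 2, n_ref * n_alt / choose(n, 2), 0)
  idx <- .window_site_index(windows, obs$sites$pos)
  out <- windows
  out$n_sites <- lengths(idx)
  out$value <- vapply(seq_along(idx), function(i) {
    L <- windows$end[i] - windows$start[i] + 1
    sum(contrib[idx[[i]]]) / L
  }, numeric(1))
  structure(out, class = c("fm_window_stats", "data.frame"), stat = "pi")
}

# Per-site Weir & Cockerham (1984) variance components for two populations.
# Inputs are per-site vectors; returns a, b, c components (zero where the
# site is unusable). Sites monomorphic across both groups yield a=b=c=0 and
# are excluded from ratio-of-sums by contributing nothing.
.wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  usable <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 2
  nbar <- (n1 + n2) / r
  ok <- usable & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  # sites monomorphic across both samples carry no information
  mono <- pbar <= 0 | pbar >= 1
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  list(a = a, b = b, c = cc)
}

.group_site_stats <- function(obs, group) {
  j <- .group_cols(obs, group)
  g <- obs$gt[, j, drop = FALSE]
  n <- rowSums(!is.na(g))                  # called diploid individuals
  p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, rowSums(g == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Windowed Weir--Cockerham FST
#'
#' Per-site variance components a, b, c of the Weir & Cockerham (1984)
#' two-population estimator, aggregated per window as the weighted
#' (ratio-of-sums) estimator `sum(a) / sum(a + b + c)`. Windows whose
#' denominator is zero are reported with `n_sites` and `NA` value.
#'
#' @param obs an `fm_observed`.
#' @param group_a,group_b disjoint sample-name vectors, each of size >= 2.
#' @param windows window grid from [make_windows()].
#' @return data.frame of class `fm_window_stats`; attribute `stat = "fst"`.
#' @export
windowed_fst <- function(obs, group_a, group_b, windows) {
  if (length(intersect(group_a, group_b)) > 0)
    stop_invalid("groups overlap: ",
                 paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_invalid("each group needs >= 2 samples")
  sa <- .group_site_stats(obs, group_a)
  sb <- .group_site_stats(obs, group_b)
  p1 <- ifelse(is.na(sa$p), 0, sa$p); p2 <- ifelse(is.na(sb$p), 0, sb$p)
  h1 <- ifelse(is.na(sa$h), 0, sa$h); h2 <- ifelse(is.na(sb$h), 0, sb$h)
  comp <- .wc_components(sa$n, sb$n, p1, p2, h1, h2)
  idx <- .window_site_index(windows, obs$sites$pos)
  out <- windows
  out$n_sites <- lengths(idx)
  out$value <- vapply(seq_along(idx), function(i) {
    ix <- idx[[i]]
    den <- sum(comp$a[ix] + comp$b[ix] + comp$c[ix])
    if (length(ix) == 0 || den == 0) return(NA_real_)
    sum(comp$a[ix]) / den
  }, numeric(1))
  structure(out, class = c("fm_window_stats", "data.frame"), stat = "fst")
}

#' Z-score and BH-FDR annotation against the genome background
#'
#' Standardizes window values against the mean and SD of the background
#' windows (`z = (value - mean_bg) / sd_bg`), converts to one-sided
#' upper-tail normal p-values (the scan asks whether the FM locus is
#' *higher* than background; `side = "two"` is available), and applies
#' Benjamini--Hochberg FDR across the whole tested window set.
#'
#' @param stats an `fm_window_stats` data.frame covering the tested set
#'   (scan plus background windows).
#' @param background either `NULL` (rows of `stats` whose `region` starts
#'   with `"BG"`), a logical/integer index into `stats`, or a separate
#'   data.frame with a `value` column used only for the background moments.
#' @param side `"upper"` (default) or `"two"`.
#' @param fdr significance threshold on q.
#' @return `stats` with columns `z`, `p`, `q`, `significant` added.
#' @export
zscore_fdr <- function(stats, background = NULL, side = c("upper", "two"),
                       fdr = 0.05) {
  side <- match.arg(side)
  if (is.null(background)) background <- startsWith(stats$region, "BG")
  bg_values <- if (is.data.frame(background)) background$value
               else stats$value[background]
  bg_values <- bg_values[!is.na(bg_values)]
  if (length(bg_values) < 2) stop("background needs >= 2 defined windows")
  mu <- mean(bg_values); sdev <- stats::sd(bg_values)
  if (sdev == 0) stop("background SD is zero; Z-scores undefined")
  stats$z <- (stats$value - mu) / sdev
  stats$p <- if (side == "upper") stats::pnorm(stats$z, lower.tail = FALSE)
             else 2 * stats::pnorm(-abs(stats$z))
  stats$q <- NA_real_
  def <- !is.na(stats$p)
  stats$q[def] <- stats::p.adjust(stats$p[def], method = "BH")
  stats$significant <- !is.na(stats$q) & stats$q < fdr
  stats
}

#' Mean window Z over a region
#'
#' The per-region "average Z" summary: mean of window z-scores for windows
#' whose midpoint falls inside the region.
#'
#' @param stats annotated `fm_window_stats` (after [zscore_fdr()]).
#' @param region an `fm_interval`.
#' @return mean z (NA if no windows).
#' @export
region_mean_z <- function(stats, region) {
  mid <- (stats$start + stats$end) / 2
  inr <- stats$chrom == region$chrom & mid >= region$start & mid <= region$end
  if (!any(inr)) return(NA_real_)
  mean(stats$z[inr], na.rm = TRUE)
}
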