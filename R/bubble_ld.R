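# Allele-frequency site-class analysis and linkage disequilibrium. In FM
# homozygotes, recombination-suppressed duplicated spans show only three site
# classes when mapped to the collapsed reference — fixed reference, fixed
# alternate, or fixed heterozygosity (frequency pinned at 0.5 where the two
# frozen copies differ). The "bubble" is a region dominated by these fixed
# classes; its boundaries, internal breakpoints and LD block structure trace
# where recombination was and was not suppressed.

.SITE_CLASSES <- c("FIXED_REF", "FIXED_ALT", "FIXED_HET", "POLYMORPHIC",
                   "UNDEFINED")

#' Classify sites from a group frequency profile
#'
#' `UNDEFINED` below `min_called` called alleles; otherwise `FIXED_REF`
#' (`f >= 1 - eps`), `FIXED_ALT` (`f <= eps`), `FIXED_HET`
#' (`|f - 0.5| <= eps`) or `POLYMORPHIC`. `eps` must stay below 0.25 or the
#' classes would overlap.
#'
#' @param profile an `fm_freq_profile` from [ref_allele_frequency()].
#' @param eps frequency tolerance around 0, 0.5 and 1.
#' @param min_called minimum called alleles for classification.
#' @return `profile` with a `class` factor column added.
#' @export
classify_sites <- function(profile, eps = 0.05, min_called = 20) {
  if (!is.numeric(eps) || eps < 0 || eps >= 0.25)
    stop_invalid("eps must be in [0, 0.25)")
  f <- profile$freq
  cls <- rep("POLYMORPHIC", nrow(profile))
  cls[f >= 1 - eps] <- "FIXED_REF"
  cls[f <= eps] <- "FIXED_ALT"
  cls[abs(f - 0.5) <= eps] <- "FIXED_HET"
  cls[is.na(f) | profile$n_called < min_called] <- "UNDEFINED"
  profile$class <- factor(cls, levels = .SITE_CLASSES)
  profile
}

.region_rows <- function(profile, region) {
  which(profile$pos >= region$start & profile$pos <= region$end)
}

#' Detect allele-frequency bubbles per region
#'
#' A region is flagged as a bubble when the fraction of its classified
#' (non-UNDEFINED) sites in the fixed classes (FIXED_REF, FIXED_ALT,
#' FIXED_HET) exceeds `tau`. Regions with fewer than `min_sites` classified
#' sites are reported `insufficient`, never silently flagged.
#'
#' @param classes classified profile from [classify_sites()].
#' @param regions named list of `fm_interval`s (e.g. [signature_regions()]).
#' @param tau fixed-fraction threshold for the bubble flag.
#' @param min_sites minimum classified sites per region.
#' @return data.frame of class `fm_bubble_report`: region, n_classified,
#'   fixed_fraction, fixed_het_fraction, bubble, status.
#' @export
detect_bubble <- function(classes, regions, tau = 0.5, min_sites = 10) {
  rows <- lapply(regions, function(r) {
    ix <- .region_rows(classes, r)
    cl <- classes$class[ix]
    cl <- cl[cl != "UNDEFINED"]
    n <- length(cl)
    if (n < min_sites)
      return(data.frame(n_classified = n, fixed_fraction = NA_real_,
                        fixed_het_fraction = NA_real_, bubble = NA,
                        status = "insufficient"))
    fixed <- mean(cl %in% c("FIXED_REF", "FIXED_ALT", "FIXED_HET"))
    data.frame(n_classified = n, fixed_fraction = fixed,
               fixed_het_fraction = mean(cl == "FIXED_HET"),
               bubble = fixed > tau, status = "ok")
  })
  out <- cbind(data.frame(region = names(regions), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("fm_bubble_report", "data.frame")
  out
}

# Maximum two-segment Bernoulli log-likelihood scan over a binary series.
# Returns the best change point (last index of the left segment) and the
# log-likelihood ratio statistic against the one-segment model.
.bernoulli_scan <- function(x) {
  n <- length(x)
  ll <- function(k, m) {     # k successes of m
    if (m == 0) return(0)
    p <- k / m
    out <- 0
    if (k > 0) out <- out + k * log(p)
    if (m - k > 0) out <- out + (m - k) * log(1 - p)
    out
  }
  cs <- cumsum(x)
  tot <- cs[n]
  ll1 <- ll(tot, n)
  best_k <- NA_integer_; best_ll <- -Inf
  for (k in seq_len(n - 1)) {
    l <- ll(cs[k], k) + ll(tot - cs[k], n - k)
    if (l > best_ll + 1e-12) { best_ll <- l; best_k <- k }
  }
  list(changepoint = best_k, lrt = 2 * (best_ll - ll1),
       left_rate = cs[best_k] / best_k,
       right_rate = (tot - cs[best_k]) / (n - best_k))
}

#' Detect a change point in a site-class series
#'
#' Binary series `x_i = 1` if site i belongs to `target_classes` (default
#' `FIXED_HET`: the fixed-heterozygosity signal whose sharp disruption within
#' DUP1 marks the breakpoint). The single change point maximizing the
#' two-segment Bernoulli log-likelihood is found by exhaustive scan and
#' reported only when the likelihood-ratio statistic against the one-segment
#' model exceeds `lrt_threshold`.
#'
#' @param classes classified profile from [classify_sites()].
#' @param region optional `fm_interval` restricting the scan.
#' @param target_classes classes counted as 1 in the series.
#' @param lrt_threshold minimum LRT statistic (2 log LR) to report.
#' @param min_sites minimum classified sites.
#' @return list of class `fm_breakpoint`: `position` (genomic position of the
#'   last left-segment site; `NA` if none), `index`, `left_rate`,
#'   `right_rate`, `lrt`, `n_sites`.
#' @export
detect_breakpoint <- function(classes, region = NULL,
                              target_classes = "FIXED_HET",
                              lrt_threshold = 10, min_sites = 20) {
  ix <- if (is.null(region)) seq_len(nrow(classes))
        else .region_rows(classes, region)
  sub <- classes[ix, , drop = FALSE]
  sub <- sub[sub$class != "UNDEFINED", , drop = FALSE]
  if (nrow(sub) < min_sites)
    stop("need >= ", min_sites, " classified sites, got ", nrow(sub))
  x <- as.integer(sub$class %in% target_classes)
  sc <- .bernoulli_scan(x)
  found <- is.finite(sc$lrt) && sc$lrt > lrt_threshold
  structure(list(
    position = if (found) sub$pos[sc$changepoint] else NA_real_,
    index = if (found) sc$changepoint else NA_integer_,
    left_rate = sc$left_rate, right_rate = sc$right_rate,
    lrt = sc$lrt, n_sites = nrow(sub)
  ), class = "fm_breakpoint")
}

#' Reference-consistent segments within a region
#'
#' Maximal runs of consecutive classified sites whose group frequency is at
#' least `0.5 - eps` — the signature of a frozen duplicate copy matching the
#' reference (pooled paralog frequency always >= 0.5 there).
#'
#' @param classes classified profile from [classify_sites()].
#' @param region an `fm_interval`.
#' @param eps tolerance below 0.5.
#' @param min_sites minimum run length to report.
#' @return data.frame: start, end (genomic positions), n_sites.
#' @export
reference_consistent_segments <- function(classes, region, eps = 0.05,
                                          min_sites = 5) {
  ix <- .region_rows(classes, region)
  sub <- classes[ix, , drop = FALSE]
  sub <- sub[sub$class != "UNDEFINED", , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(start = numeric(), end = numeric(),
                      n_sites = integer()))
  hit <- sub$freq >= 0.5 - eps
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_sites
  data.frame(start = sub$pos[starts[keep]], end = sub$pos[ends[keep]],
             n_sites = r$lengths[keep])
}

#' Pairwise genotype-dosage r-squared
#'
#' Composite LD: squared Pearson correlation of unphased genotype dosage
#' vectors (0/1/2) over samples called at both sites. Entries with fewer than
#' `min_shared` co-called samples, or where either site is monomorphic among
#' the shared samples, are `NA`.
#'
#' @param obs an `fm_observed` (typically after [filter_variants()]).
#' @param interval optional `fm_interval` restricting sites.
#' @param samples optional sample subset.
#' @param min_shared minimum co-called samples per pair.
#' @return symmetric r-squared matrix with unit diagonal; attribute
#'   `"pos"` gives site positions.
#' @export
pairwise_r2 <- function(obs, interval = NULL, samples = NULL, min_shared = 4) {
  keep <- if (is.null(interval)) seq_len(nrow(obs$gt))
          else which(obs$sites$pos >= interval$start &
                     obs$sites$pos <= interval$end)
  if (length(keep) < 2) stop("need >= 2 usable sites")
  g <- obs$gt[keep, , drop = FALSE]
  if (!is.null(samples)) g <- g[, .group_cols(obs, samples), drop = FALSE]
  gv <- t(g)                                     # samples x sites
  suppressWarnings(r <- stats::cor(gv, use = "pairwise.complete.obs"))
  r2 <- r^2
  shared <- crossprod(!is.na(gv))
  r2[shared < min_shared] <- NA_real_
  diag(r2) <- ifelse(diag(shared) >= min_shared, 1, NA_real_)
  attr(r2, "pos") <- obs$sites$pos[keep]
  r2
}

# Rectangle-mean machinery over an r2 matrix with NAs, via 2-D cumulative
# sums of values and defined-mask counts.
.cum2 <- function(m) {
  m <- apply(m, 2, cumsum)
  t(apply(m, 1, cumsum))
}

#' LD retention per window and block-boundary detection
#'
#' LD retention is the mean defined pairwise r-squared among sites within
#' each window (pair distance bounded by the window length), annotated with
#' Z/p/q against the background windows via [zscore_fdr()]. Within
#' `target_interval`, the block boundary is the inter-site split maximizing
#' the contrast between mean within-block r-squared and mean cross-block
#' r-squared; it is reported only when that contrast exceeds
#' `contrast_threshold`.
#'
#' @param obs an `fm_observed` (after filtering).
#' @param windows window grid from [make_windows()] (scan + background).
#' @param target_interval `fm_interval` searched for a block boundary
#'   (e.g. DUP1), or `NULL` to skip.
#' @param samples optional sample subset for the dosage correlations.
#' @param contrast_threshold minimum (within - cross) contrast to report.
#' @param min_shared minimum co-called samples per site pair.
#' @return list of class `fm_ld_result`: `windows` (annotated window stats,
#'   `stat = "ld"`), `boundary` (list: position, index, contrast, within,
#'   cross — positions `NA` when no boundary), `target_r2` (matrix or NULL).
#' @export
ld_retention_and_boundary <- function(obs, windows, target_interval = NULL,
                                      samples = NULL,
                                      contrast_threshold = 0.2,
                                      min_shared = 4) {
  if (!any(startsWith(windows$region, "BG")))
    stop("no background windows available")
  g <- obs$gt
  if (!is.null(samples)) g <- g[, .group_cols(obs, samples), drop = FALSE]
  gv <- t(g)
  pos <- obs$sites$pos
  idx <- .window_site_index(windows, pos)
  retention <- vapply(seq_along(idx), function(i) {
    ix <- idx[[i]]
    if (length(ix) < 2) return(NA_real_)
    suppressWarnings(r <- stats::cor(gv[, ix, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    r2 <- r^2
    shared <- crossprod(!is.na(gv[, ix, drop = FALSE]))
    r2[shared < min_shared] <- NA_real_
    vals <- r2[upper.tri(r2)]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  wstats <- windows
  wstats$n_sites <- lengths(idx)
  wstats$value <- retention
  wstats <- structure(wstats, class = c("fm_window_stats", "data.frame"),
                      stat = "ld")
  wstats <- zscore_fdr(wstats)

  boundary <- list(position = NA_real_, index = NA_integer_,
                   contrast = NA_real_, within = NA_real_, cross = NA_real_)
  target_r2 <- NULL
  if (!is.null(target_interval)) {
    tix <- which(pos >= target_interval$start & pos <= target_interval$end)
    if (length(tix) >= 4) {
      suppressWarnings(r <- stats::cor(gv[, tix, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      r2 <- r^2
      shared <- crossprod(!is.na(gv[, tix, drop = FALSE]))
      r2[shared < min_shared] <- NA_real_
      target_r2 <- r2
      attr(target_r2, "pos") <- pos[tix]
      m <- length(tix)
      vals <- ifelse(is.na(r2), 0, r2); diag(vals) <- 0
      mask <- ifelse(is.na(r2), 0, 1); diag(mask) <- 0
      cv <- .cum2(vals); cm <- .cum2(mask)
      rect <- function(cum, i2, j2) cum[i2, j2]
      best <- NULL
      for (k in seq_len(m - 1)) {
        # cross block: rows 1..k, cols k+1..m
        cr_v <- cv[k, m] - cv[k, k]
        cr_n <- cm[k, m] - cm[k, k]
        # within: all pairs minus cross (matrices symmetric; halves cancel)
        wi_v <- (cv[m, m] - 2 * cr_v) / 2
        wi_n <- (cm[m, m] - 2 * cr_n) / 2
        if (cr_n == 0 || wi_n == 0) next
        contrast <- wi_v / wi_n - cr_v / cr_n
        if (is.null(best) || contrast > best$contrast + 1e-12)
          best <- list(index = k, contrast = contrast,
                       within = wi_v / wi_n, cross = cr_v / cr_n)
      }
      if (!is.null(best) && best$contrast > contrast_threshold)
        boundary <- list(position = pos[tix][best$index], index = best$index,
                        contrast = best$contrast, within = best$within,
                        cross = best$cross)
      else if (!is.null(best))
        boundary[c("contrast", "within", "cross")] <-
          best[c("contrast", "within", "cross")]
    }
  }
  structure(list(windows = wstats, boundary = boundary,
                 target_r2 = target_r2),
            class = "fm_ld_result")
}
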