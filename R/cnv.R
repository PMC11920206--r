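# Copy-number genotyping from relative sequencing depth: the ratio of a
# region's mean depth to the genome background is ~1.0 for N/N, ~1.5 for FM/N
# (one extra copy on one haplotype) and ~2.0 for FM/FM in the duplicated
# regions; samples are classified per region and the two duplications must
# agree for a call.

#' Relative depth of a region, per sample
#'
#' Mean depth over the windows overlapping `region`, divided by the per-sample
#' genome-background mean depth.
#'
#' @param obs an `fm_observed` (its `depth` element is the depth profile), or
#'   the profile list itself.
#' @param region an `fm_interval`.
#' @return named numeric vector of per-sample ratios.
#' @export
relative_depth <- function(obs, region) {
  profile <- if (inherits(obs, "fm_observed")) obs$depth else obs
  stopifnot(inherits(region, "fm_interval"))
  w <- profile$windows
  mid <- (w$start + w$end) / 2
  inr <- w$chrom == region$chrom & mid >= region$start & mid <= region$end
  if (!any(inr)) stop("region ", region$label, " overlaps no depth windows")
  bg <- profile$background
  if (any(bg <= 0))
    stop("zero background depth for sample(s): ",
         paste(names(bg)[bg <= 0], collapse = ", "))
  colMeans(profile$matrix[inr, , drop = FALSE]) / bg
}

.depth_class <- function(ratio, t1, t2) {
  ifelse(ratio < t1, "N/N", ifelse(ratio < t2, "FM/N", "FM/FM"))
}

#' Call FM genotypes from relative depth
#'
#' Per duplicated region, a sample is classed `N/N` below `t1`, `FM/N` in
#' `[t1, t2)` and `FM/FM` at or above `t2`; the overall call is the shared
#' class when DUP1 and DUP2 agree, else `ambiguous`. Thresholds default to
#' the midpoints between the expected ratios 1.0/1.5/2.0.
#'
#' @param obs an `fm_observed`, or a data.frame with columns `sample`,
#'   `ratio_dup1`, `ratio_dup2` (and optionally `ratio_int`).
#' @param map region map (required when `obs` is an `fm_observed`; defaults
#'   to the map stored in it).
#' @param t1,t2 depth-ratio thresholds.
#' @return data.frame of class `fm_cnv_calls`: sample, ratio_dup1,
#'   ratio_dup2, ratio_int, call.
#' @export
call_fm_genotype <- function(obs, map = NULL, t1 = 1.25, t2 = 1.75) {
  if (!(is.numeric(t1) && is.numeric(t2) && t1 < t2))
    stop_invalid("thresholds must satisfy t1 < t2")
  if (inherits(obs, "fm_observed")) {
    map <- map %||% obs$map
    ratios <- data.frame(
      sample = colnames(obs$gt),
      ratio_dup1 = relative_depth(obs, map$dup1),
      ratio_dup2 = relative_depth(obs, map$dup2),
      ratio_int = relative_depth(obs, map$int_region),
      stringsAsFactors = FALSE)
  } else {
    ratios <- obs
    if (!all(c("sample", "ratio_dup1", "ratio_dup2") %in% names(ratios)))
      stop_invalid("need columns sample, ratio_dup1, ratio_dup2")
    if (is.null(ratios$ratio_int)) ratios$ratio_int <- NA_real_
  }
  if (any(ratios$ratio_dup1 < 0 | ratios$ratio_dup2 < 0, na.rm = TRUE))
    stop_invalid("negative depth ratio")
  c1 <- .depth_class(ratios$ratio_dup1, t1, t2)
  c2 <- .depth_class(ratios$ratio_dup2, t1, t2)
  ratios$call <- ifelse(c1 == c2, c1, "ambiguous")
  rownames(ratios) <- NULL
  class(ratios) <- c("fm_cnv_calls", "data.frame")
  ratios
}

#' Sample groups from CNV calls
#'
#' @param calls an `fm_cnv_calls` data.frame.
#' @return named list of sample-name vectors, one per call class present.
#' @export
cnv_groups <- function(calls) {
  split(calls$sample, calls$call)
}
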