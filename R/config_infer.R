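# The headline computation: summarize the observed per-region evidence into a
# signature vector (bubble flags plus continuous support) and match it
# against the predicted signatures of the four candidate architectures. The
# boolean bubble triple over (DUP1, INT, DUP2) is the discriminating
# statistic — exactly the verbal logic by which the configurations predict
# where suppressed recombination, hence the allele-frequency bubble, must
# appear; the continuous evidence is reported but not scored.

#' Observed per-region signature
#'
#' Combines the bubble report (fixed-class fractions and flags), the windowed
#' nucleotide-diversity ratio between cohorts, and optionally the mean
#' LD-retention Z per region into one signature vector.
#'
#' @param bubble an `fm_bubble_report` over (DUP1, INT, DUP2).
#' @param pi_fm,pi_wt `fm_window_stats` from [windowed_pi()] for the FM/FM
#'   and N/N cohorts (may be `NULL`, leaving `pi_ratio` `NA`).
#' @param ld an `fm_ld_result` (may be `NULL`, leaving `ld_z` `NA`).
#' @param regions named list of the three `fm_interval`s.
#' @return data.frame of class `fm_signature`: region, fixed_fraction,
#'   fixed_het_fraction, pi_ratio, ld_z, bubble.
#' @export
observed_signature <- function(bubble, pi_fm = NULL, pi_wt = NULL, ld = NULL,
                               regions) {
  need <- c("DUP1", "INT", "DUP2")
  if (!all(need %in% bubble$region) || !all(need %in% names(regions)))
    stop("signature needs regions DUP1, INT and DUP2")
  region_mean <- function(stats, region) {
    if (is.null(stats)) return(NA_real_)
    mid <- (stats$start + stats$end) / 2
    inr <- mid >= region$start & mid <= region$end &
      stats$chrom == region$chrom
    if (!any(inr)) return(NA_real_)
    mean(stats$value[inr], na.rm = TRUE)
  }
  rows <- lapply(need, function(nm) {
    b <- bubble[bubble$region == nm, ]
    pf <- region_mean(pi_fm, regions[[nm]])
    pw <- region_mean(pi_wt, regions[[nm]])
    data.frame(
      region = nm,
      fixed_fraction = b$fixed_fraction,
      fixed_het_fraction = b$fixed_het_fraction,
      pi_ratio = if (!is.na(pw) && pw > 0) pf / pw else NA_real_,
      ld_z = if (is.null(ld)) NA_real_
             else region_mean_z(ld$windows, regions[[nm]]),
      bubble = isTRUE(b$bubble),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fm_signature", "data.frame")
  out
}

#' Call the FM-locus configuration from an observed signature
#'
#' Computes the Hamming distance between the observed bubble-flag triple and
#' each configuration's predicted triple (WT (0,0,0), FM-1 (1,1,1),
#' FM-2 (1,0,0), FM-3 (0,0,1)). An exact match gives a `confident` call;
#' otherwise the nearest model(s) are reported as `ambiguous-nearest` with a
#' tie flag.
#'
#' @param signature an `fm_signature` (or logical triple over
#'   DUP1/INT/DUP2).
#' @return object of class `fm_config_call`: `best`, `status`
#'   (`"confident"` or `"ambiguous-nearest"`), `tie`, `distances`,
#'   `observed_flags`, `signature`.
#' @export
call_configuration <- function(signature) {
  flags <- if (inherits(signature, "fm_signature")) {
    stats::setNames(signature$bubble, signature$region)[c("DUP1", "INT", "DUP2")]
  } else {
    if (length(signature) != 3) stop("need a triple of bubble flags")
    stats::setNames(as.logical(signature), c("DUP1", "INT", "DUP2"))
  }
  if (anyNA(flags)) stop("bubble flags must be defined for all three regions")
  dist <- vapply(fm_configurations(), function(cf)
    sum(flags != predicted_signature(cf)), numeric(1))
  dmin <- min(dist)
  nearest <- names(dist)[dist == dmin]
  structure(list(
    best = nearest[1],
    status = if (dmin == 0) "confident" else "ambiguous-nearest",
    tie = length(nearest) > 1,
    nearest = nearest,
    distances = dist,
    observed_flags = flags,
    signature = if (inherits(signature, "fm_signature")) signature else NULL
  ), class = "fm_config_call")
}

#' @export
print.fm_config_call <- function(x, ...) {
  cat("FM-locus configuration call:", x$best,
      paste0("(", x$status, if (x$tie) ", tie" else "", ")\n"))
  cat("  observed bubble flags (DUP1, INT, DUP2):",
      paste(as.integer(x$observed_flags), collapse = ", "), "\n")
  cat("  Hamming distances:",
      paste(sprintf("%s=%d", names(x$distances), x$distances),
            collapse = "  "), "\n")
  invisible(x)
}

#' Infer the FM-locus configuration from collapsed observations
#'
#' The top-level fit: CNV-genotypes the samples from relative depth, defines
#' the FM/FM and N/N cohorts (an explicit `groups` list overrides), filters
#' sites, computes the FM-cohort allele-frequency profile and site classes,
#' detects per-region bubbles, computes windowed diversity for both cohorts
#' (and FST and LD retention when requested), assembles the observed
#' signature and matches it against the four candidate architectures.
#'
#' If CNV genotyping finds no FM/FM cohort (the wild-type situation), no
#' bubble can exist anywhere and the call is WT with all flags clear.
#'
#' @param obs an `fm_observed`.
#' @param map the `fm_region_map` (defaults to the one stored in `obs`).
#' @param groups optional list with elements `fm` and `wt`: explicit sample
#'   groups overriding the CNV-derived cohorts.
#' @param maf,max_missing site filters (see [filter_variants()]).
#' @param eps,min_called site-classification parameters.
#' @param tau bubble fixed-fraction threshold.
#' @param include_ld compute LD retention and its per-region Z (slower).
#' @param include_fst compute windowed FST between the cohorts.
#' @param min_group minimum cohort size to attempt frequency analysis.
#' @return object of class `fm_config_fit`: the configuration call plus all
#'   intermediate evidence (`cnv`, `signature`, `bubble`, `classes`,
#'   `pi_fm`, `pi_wt`, `fst`, `ld`, `groups`, `windows`).
#' @examples
#' \donttest{
#' pop <- simulate_population(build_region_map(100), fm_sim_params(seed = 7))
#' fit <- infer_fm_configuration(observe(pop, seed = 7), include_ld = FALSE)
#' fit
#' }
#' @export
infer_fm_configuration <- function(obs, map = NULL, groups = NULL,
                                   maf = 0.05, max_missing = 0.9,
                                   eps = 0.05, min_called = 20, tau = 0.5,
                                   include_ld = TRUE, include_fst = TRUE,
                                   min_group = 2) {
  stopifnot(inherits(obs, "fm_observed"))
  map <- map %||% obs$map
  cnv <- call_fm_genotype(obs, map)
  if (is.null(groups)) {
    gg <- cnv_groups(cnv)
    groups <- list(fm = gg[["FM/FM"]] %||% character(),
                   wt = gg[["N/N"]] %||% character())
  }
  regions <- signature_regions(map)
  filtered <- filter_variants(obs, maf = maf, max_missing = max_missing)
  windows <- make_windows(map)
  have_fm <- length(groups$fm) >= min_group
  have_wt <- length(groups$wt) >= min_group

  classes <- NULL; bubble <- NULL
  pi_fm <- NULL; pi_wt <- NULL; fst <- NULL; ld <- NULL
  if (have_fm) {
    prof <- ref_allele_frequency(filtered, groups$fm)
    classes <- classify_sites(prof, eps = eps, min_called = min_called)
    bubble <- detect_bubble(classes, regions, tau = tau)
    pi_fm <- windowed_pi(filtered, groups$fm, windows)
  }
  if (have_wt) pi_wt <- windowed_pi(filtered, groups$wt, windows)
  if (include_fst && have_fm && have_wt)
    fst <- zscore_fdr(windowed_fst(filtered, groups$fm, groups$wt, windows))
  if (include_ld)
    ld <- ld_retention_and_boundary(filtered, windows,
                                    target_interval = map$dup1)
  if (have_fm) {
    sig <- observed_signature(bubble, pi_fm, pi_wt, ld, regions)
    # a region with too few classified sites cannot support a bubble claim
    sig$bubble[is.na(sig$bubble)] <- FALSE
  } else {
    # no FM/FM cohort: nothing is duplicated-and-frozen, flags all clear
    sig <- data.frame(region = c("DUP1", "INT", "DUP2"),
                      fixed_fraction = NA_real_,
                      fixed_het_fraction = NA_real_,
                      pi_ratio = NA_real_, ld_z = NA_real_, bubble = FALSE,
                      stringsAsFactors = FALSE)
    class(sig) <- c("fm_signature", "data.frame")
  }
  call <- call_configuration(sig)
  structure(list(call = call, signature = sig, cnv = cnv, groups = groups,
                 classes = classes, bubble = bubble, pi_fm = pi_fm,
                 pi_wt = pi_wt, fst = fst, ld = ld, windows = windows,
                 map = map, n_sites_filtered = nrow(filtered$gt)),
            class = "fm_config_fit")
}

#' @export
print.fm_config_fit <- function(x, ...) {
  print(x$call)
  cat("  cohorts: FM/FM n =", length(x$groups$fm),
      "; N/N n =", length(x$groups$wt),
      "; filtered sites:", x$n_sites_filtered, "\n")
  invisible(x)
}

#' @export
summary.fm_config_fit <- function(object, ...) {
  print(object$call)
  cat("\nPer-region evidence:\n")
  print(object$signature, row.names = FALSE)
  cat("\nCNV call table:\n")
  print(table(object$cnv$call))
  if (!is.null(object$fst)) {
    cat("\nMean FST window Z: DUP1 =",
        round(region_mean_z(object$fst, object$map$dup1), 2),
        " INT =", round(region_mean_z(object$fst, object$map$int_region), 2),
        " DUP2 =", round(region_mean_z(object$fst, object$map$dup2), 2), "\n")
  }
  if (!is.null(object$ld) && !is.na(object$ld$boundary$position))
    cat("\nLD block boundary in DUP1 at position",
        object$ld$boundary$position,
        sprintf("(contrast %.2f)\n", object$ld$boundary$contrast))
  invisible(object)
}

#' Plot the FM-cohort allele-frequency profile of a fit
#'
#' Reference-allele frequency of the FM/FM cohort along the scan region with
#' the duplicated intervals shaded — the collapsed-reference "bubble" view.
#'
#' @param x an `fm_config_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fm_config_fit <- function(x, ...) {
  if (is.null(x$classes)) {
    warning("no FM/FM cohort; nothing to plot")
    return(invisible(x))
  }
  cl <- x$classes
  scan <- x$map$scan_region
  inscan <- cl$pos >= scan$start & cl$pos <= scan$end
  graphics::plot(cl$pos[inscan], cl$freq[inscan], pch = 16, cex = 0.4,
                 xlab = paste0("position on ", scan$chrom),
                 ylab = "reference allele frequency (FM/FM)",
                 ylim = c(0, 1), ...)
  for (r in list(x$map$dup1, x$map$dup2))
    graphics::rect(r$start, -0.04, r$end, 1.04, border = NA,
                   col = grDevices::adjustcolor("steelblue", 0.15))
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
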