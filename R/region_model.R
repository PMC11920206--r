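# Geometry of the FM locus: the two duplicated intervals on chicken
# chromosome 20, the single-copy intervening region, the scan region and the
# genome-background regions, plus the per-configuration copy/suppression
# geometry and the per-region "bubble" signature each configuration predicts.

# Scale-1 coordinates (GRCg6a chromosome 20, 1-based inclusive).
.FM_COORDS <- list(
  chrom      = "chr20",
  chrom_len  = 13897287,
  scan       = c(10600000L, 11700000L),
  dup1       = c(10766772L, 10894151L),
  dup2       = c(11306686L, 11477501L),
  background = list(c(3000000L, 3250000L), c(5000000L, 5250000L))
)

# Region sizes as published in the original reports (kb, one decimal).  The
# DUP2 value 170.5 differs from the coordinate arithmetic (170.8 kb); it is
# retained verbatim because the ancestral-unit sum (710.4 kb) is quoted with
# it.  See `ancestral_unit_length_kb()`.
.FM_PUBLISHED_KB <- c(dup1 = 127.4, int = 412.5, dup2 = 170.5)

#' Create a genomic interval
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param label region name.
#' @return an object of class `fm_interval`.
#' @export
fm_interval <- function(chrom, start, end, label = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end || start < 1)
    stop_invalid("invalid interval [", start, ", ", end, "]")
  structure(list(chrom = chrom, start = start, end = end, label = label),
            class = "fm_interval")
}

#' Interval length in bp
#'
#' Uses the end-minus-start convention under which the printed 127.4 kb for
#' DUP1 is recovered from its coordinates (10,894,151 - 10,766,772 = 127,379).
#'
#' @param x an `fm_interval`.
#' @return length in bp.
#' @export
interval_length_bp <- function(x) {
  stopifnot(inherits(x, "fm_interval"))
  x$end - x$start
}

#' @export
print.fm_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s, %.1f kb)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$label, interval_length_bp(x) / 1000))
  invisible(x)
}

.scale_pos <- function(pos, scale) pmax(1, round(pos / scale))

#' Build the FM-locus region map
#'
#' Returns the coordinates of DUP1, the intervening single-copy region (INT),
#' DUP2, the two flanks, the ~1.1 Mb scan region and two genome-background
#' regions on chromosome 20. At `scale = 1` these are the published
#' coordinates; at `scale = s` every coordinate is divided by `s` (rounded),
#' shrinking all interval lengths by `s` while preserving order and relative
#' gaps — the desk-scale geometry used for simulation.
#'
#' @param scale positive divisor applied to all coordinates (`>= 1`).
#' @return an object of class `fm_region_map` with elements `dup1`,
#'   `int_region`, `dup2`, `flank1`, `flank2`, `scan_region`,
#'   `background_regions` (list), `chrom_len` and `scale`.
#' @examples
#' m <- build_region_map()
#' interval_length_bp(m$dup1) / 1000  # 127.379 -> printed 127.4 kb
#' @export
build_region_map <- function(scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale < 1)
    stop_invalid("scale must be a single number >= 1")
  cc <- .FM_COORDS
  s <- function(p) .scale_pos(p, scale)
  dup1 <- fm_interval(cc$chrom, s(cc$dup1[1]), s(cc$dup1[2]), "DUP1")
  dup2 <- fm_interval(cc$chrom, s(cc$dup2[1]), s(cc$dup2[2]), "DUP2")
  int  <- fm_interval(cc$chrom, dup1$end + 1, dup2$start - 1, "INT")
  scan <- fm_interval(cc$chrom, s(cc$scan[1]), s(cc$scan[2]), "SCAN")
  bg <- lapply(seq_along(cc$background), function(i) {
    b <- cc$background[[i]]
    fm_interval(cc$chrom, s(b[1]), s(b[2]), paste0("BG", i))
  })
  structure(list(
    dup1 = dup1, int_region = int, dup2 = dup2,
    flank1 = fm_interval(cc$chrom, scan$start, dup1$start - 1, "FLANK1"),
    flank2 = fm_interval(cc$chrom, dup2$end + 1, scan$end, "FLANK2"),
    scan_region = scan, background_regions = bg,
    chrom = cc$chrom, chrom_len = ceiling(cc$chrom_len / scale),
    scale = scale
  ), class = "fm_region_map")
}

#' @export
print.fm_region_map <- function(x, ...) {
  cat("FM locus region map (scale ", x$scale, ")\n", sep = "")
  for (r in list(x$scan_region, x$dup1, x$int_region, x$dup2)) print(r)
  for (b in x$background_regions) print(b)
  invisible(x)
}

#' Named analysis regions of a map
#'
#' @param map an `fm_region_map`.
#' @return named list of the three signature regions (DUP1, INT, DUP2).
#' @export
signature_regions <- function(map) {
  list(DUP1 = map$dup1, INT = map$int_region, DUP2 = map$dup2)
}

#' Span between the duplications in kb
#'
#' The length of the non-duplicated region between DUP1 and DUP2 measured
#' boundary-to-boundary (`dup2$start - dup1$end`), the convention under which
#' the published 412.54 kb is recovered (412,535 bp).
#'
#' @param map an `fm_region_map` (scale 1 for the published value).
#' @param digits decimals for the printed kb value.
#' @return length in kb, rounded half-up to `digits`.
#' @export
intervening_span_kb <- function(map, digits = 2) {
  stopifnot(inherits(map, "fm_region_map"))
  round_half_up((map$dup2$start - map$dup1$end) / 1000, digits)
}

#' Region sizes as published
#'
#' The kb sizes of DUP1, INT and DUP2 as printed in the original reports
#' (127.4, 412.5 and 170.5). Note the published DUP2 size (170.5) predates and
#' differs slightly from its coordinate arithmetic (170.8 kb); both are kept,
#' and the published value is used only where the published arithmetic uses it
#' (the ancestral tandem-unit sum).
#'
#' @return named numeric vector (kb).
#' @export
published_region_kb <- function() .FM_PUBLISHED_KB

#' Length of the hypothesized ancestral tandem-duplication unit
#'
#' Under the birth model of the FM allele — a single tandem duplication of the
#' whole DUP1..DUP2 span by unequal crossing over, followed by an inversion
#' that deleted one copy of the intervening region — the ancestral duplicated
#' unit spans DUP1 + INT + DUP2. Summing the published one-decimal sizes
#' reproduces the published 710.4 kb.
#'
#' @param printed_lengths named numeric vector with elements `dup1`, `int`,
#'   `dup2`: per-region sizes in kb at one-decimal precision.
#' @return total span in kb.
#' @examples
#' ancestral_unit_length_kb(published_region_kb())  # 710.4
#' @export
ancestral_unit_length_kb <- function(printed_lengths = published_region_kb()) {
  need <- c("dup1", "int", "dup2")
  if (!all(need %in% names(printed_lengths)) ||
      any(is.na(printed_lengths[need])))
    stop_invalid("printed_lengths must name dup1, int and dup2")
  round_half_up(sum(printed_lengths[need]), 1)
}

.FM_CONFIGS <- c("WT", "FM-1", "FM-2", "FM-3")

#' Copy/suppression geometry of a candidate configuration
#'
#' Encodes, for each of the three signature regions, how many copies the FM
#' haplotype carries and which copies are recombination-suppressed ("frozen").
#' WT carries one free copy of everything. FM-1 (inversion of the whole
#' DUP1-INT-DUP2 block) freezes everything; FM-2 (inverted DUP2 copy inserted
#' between tandem DUP1 copies) freezes both DUP1 copies and one DUP2 copy;
#' FM-3 is the mirror image (both DUP2 copies frozen, one DUP1 copy frozen).
#'
#' @param config one of `"WT"`, `"FM-1"`, `"FM-2"`, `"FM-3"`.
#' @return object of class `fm_geometry`: list with `label`, `copies` (ordered
#'   physical copy list: source region, orientation, suppressed flag) and
#'   `regions` (per-region copy count and per-copy frozen flags).
#' @export
configuration_geometry <- function(config) {
  config <- match.arg(config, .FM_CONFIGS)
  cp <- function(region, orientation, suppressed)
    list(region = region, orientation = orientation, suppressed = suppressed)
  reg <- function(n_copies, frozen) list(n_copies = n_copies, frozen = frozen)
  g <- switch(config,
    "WT" = list(
      copies = list(cp("DUP1", "forward", FALSE), cp("INT", "forward", FALSE),
                    cp("DUP2", "forward", FALSE)),
      regions = list(DUP1 = reg(1L, FALSE), INT = reg(1L, FALSE),
                     DUP2 = reg(1L, FALSE))),
    "FM-1" = list(
      copies = list(cp("DUP1", "forward", TRUE), cp("DUP2", "inverted", TRUE),
                    cp("INT", "inverted", TRUE), cp("DUP1", "inverted", TRUE),
                    cp("DUP2", "forward", TRUE)),
      regions = list(DUP1 = reg(2L, c(TRUE, TRUE)), INT = reg(1L, TRUE),
                     DUP2 = reg(2L, c(TRUE, TRUE)))),
    "FM-2" = list(
      copies = list(cp("DUP1", "forward", TRUE), cp("DUP2", "inverted", TRUE),
                    cp("DUP1", "forward", TRUE), cp("INT", "forward", FALSE),
                    cp("DUP2", "forward", FALSE)),
      regions = list(DUP1 = reg(2L, c(TRUE, TRUE)), INT = reg(1L, FALSE),
                     DUP2 = reg(2L, c(TRUE, FALSE)))),
    "FM-3" = list(
      copies = list(cp("DUP1", "forward", TRUE), cp("DUP2", "forward", TRUE),
                    cp("DUP1", "inverted", FALSE), cp("INT", "forward", FALSE),
                    cp("DUP2", "forward", TRUE)),
      regions = list(DUP1 = reg(2L, c(TRUE, FALSE)), INT = reg(1L, FALSE),
                     DUP2 = reg(2L, c(TRUE, TRUE))))
  )
  structure(c(list(label = config), g), class = "fm_geometry")
}

#' Predicted per-region bubble signature of a configuration
#'
#' A region shows an allele-frequency "bubble" (site frequencies pinned at 0,
#' 0.5 and 1 in FM homozygotes) precisely when all of its copies on the FM
#' haplotype are recombination-suppressed: WT (0,0,0); FM-1 (1,1,1);
#' FM-2 (1,0,0); FM-3 (0,0,1).
#'
#' @param config configuration label.
#' @return named logical triple over (DUP1, INT, DUP2).
#' @export
predicted_signature <- function(config) {
  g <- configuration_geometry(config)
  vapply(g$regions, function(r) all(r$frozen), logical(1))
}

#' All candidate configuration labels
#' @return character vector `c("WT", "FM-1", "FM-2", "FM-3")`.
#' @export
fm_configurations <- function() .FM_CONFIGS
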