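# Readers and writers for the standard formats the pipeline exchanges:
# VCF v4.2 (GT:AD), per-window depth TSV, BED (0-based half-open at the file
# boundary only), newick trees and JSON truth/report sidecars. Every format
# written by the package round-trips losslessly through its reader.

.gt_string <- c("1/1", "0/1", "0/0")  # dosage 0, 1, 2

#' Write a genotype matrix as VCF v4.2
#'
#' Biallelic records with GT and AD fields and a contig header. Missing calls
#' are written `./.` with AD `0,0`.
#'
#' @param obs an `fm_observed`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(obs, path) {
  stopifnot(inherits(obs, "fm_observed"))
  s <- obs$sites
  n <- nrow(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=fmscan",
    sprintf("##contig=<ID=%s,length=%d>",
            obs$map$chrom %||% s$chrom[1],
            as.integer(obs$map$chrom_len %||% max(s$pos))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,',
           'Description="Allelic depths for the ref and alt alleles">'),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(obs$gt)), collapse = "\t")), con)
  if (n > 0) {
    gtc <- matrix(.gt_string[obs$gt + 1L], n, ncol(obs$gt))
    gtc[is.na(obs$gt)] <- "./."
    ad <- matrix(paste0(round(obs$ad_ref), ",", round(obs$ad_alt)),
                 n, ncol(obs$gt))
    cells <- matrix(paste0(gtc, ":", ad), n, ncol(obs$gt))
    body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".",
                  "GT:AD", apply(cells, 1, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses GT (phased or unphased; phasing is ignored) and AD from a VCF.
#' Multiallelic records are skipped with a logged count (biallelic loci
#' only); records missing GT in FORMAT raise an error.
#'
#' @param path VCF file (plain or bgzipped).
#' @param map optional `fm_region_map` used to annotate sites with region
#'   labels.
#' @return an `fm_observed`-compatible object (no depth profile); attribute
#'   `"n_multiallelic_skipped"` counts dropped records.
#' @export
read_vcf <- function(path, map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) > 0 && !all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop("GT missing from FORMAT")
  multi <- grepl(",", fix[, "ALT"])
  n_skip <- sum(multi)
  if (n_skip > 0) {
    message("skipped ", n_skip, " multiallelic record(s)")
    v <- v[!multi, ]
    fix <- vcfR::getFIX(v)
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                     error = function(e) NULL)
  count_ref <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 2L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 0L
    out
  }
  gt <- matrix(count_ref(gt_raw), nrow(gt_raw), ncol(gt_raw),
               dimnames = dimnames(gt_raw))
  split_ad <- function(k) {
    out <- matrix(0, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    if (!is.null(ad_raw)) {
      parts <- strsplit(ifelse(is.na(ad_raw), "0,0", ad_raw), ",",
                        fixed = TRUE)
      out[] <- as.numeric(vapply(parts, function(p)
        if (length(p) >= k) p[k] else "0", ""))
    }
    out
  }
  pos <- as.numeric(fix[, "POS"])
  region <- rep(NA_character_, length(pos))
  if (!is.null(map)) {
    for (r in .named_regions(map)) {
      inr <- fix[, "CHROM"] == r$chrom & pos >= r$start & pos <= r$end
      region[inr] <- r$label
    }
  }
  sites <- data.frame(chrom = fix[, "CHROM"], pos = pos, region = region,
                      fixed_diff = NA, ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  out <- structure(list(sites = sites, gt = gt,
                        ad_ref = split_ad(1), ad_alt = split_ad(2),
                        depth = NULL,
                        samples = data.frame(sample = colnames(gt),
                                             truth = NA_character_,
                                             stringsAsFactors = FALSE),
                        map = map),
                   class = "fm_observed")
  attr(out, "n_multiallelic_skipped") <- n_skip
  out
}

#' Write / read the per-window depth profile TSV
#'
#' Long-format TSV with columns sample, chrom, start, end, region,
#' mean_depth; the per-sample genome-background mean is stored in rows with
#' region `BACKGROUND_MEAN` (start and end 0), so the profile round-trips
#' losslessly.
#'
#' @param obs an `fm_observed` (or its `depth` profile list).
#' @param path file path.
#' @return `path` invisibly (writer); depth profile list (reader).
#' @export
write_depth_tsv <- function(obs, path) {
  profile <- if (inherits(obs, "fm_observed")) obs$depth else obs
  w <- profile$windows
  samples <- colnames(profile$matrix)
  long <- data.frame(
    sample = rep(samples, each = nrow(w)),
    chrom = rep(w$chrom, length(samples)),
    start = rep(w$start, length(samples)),
    end = rep(w$end, length(samples)),
    region = rep(w$region, length(samples)),
    mean_depth = as.vector(profile$matrix),
    stringsAsFactors = FALSE)
  bg <- data.frame(sample = samples, chrom = w$chrom[1], start = 0, end = 0,
                   region = "BACKGROUND_MEAN",
                   mean_depth = as.numeric(profile$background),
                   stringsAsFactors = FALSE)
  utils::write.table(rbind(long, bg), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "mean_depth")
  if (!all(need %in% names(d)))
    stop("malformed depth TSV: need columns ", paste(need, collapse = ", "))
  isbg <- d$region == "BACKGROUND_MEAN"
  bg <- d[isbg, ]
  d <- d[!isbg, ]
  samples <- unique(d$sample)
  w <- unique(d[, c("chrom", "start", "end", "region")])
  rownames(w) <- NULL
  key <- paste(d$chrom, d$start, d$end)
  wkey <- paste(w$chrom, w$start, w$end)
  mat <- matrix(NA_real_, nrow(w), length(samples),
                dimnames = list(NULL, samples))
  mat[cbind(match(key, wkey), match(d$sample, samples))] <- d$mean_depth
  background <- stats::setNames(bg$mean_depth[match(samples, bg$sample)],
                                samples)
  list(windows = w, matrix = mat, background = background)
}

#' Write / read region maps as BED
#'
#' Internal coordinates are 1-based inclusive; the BED file is 0-based
#' half-open with a `name` column, converted only at this boundary.
#'
#' @param map an `fm_region_map` (or a data.frame with chrom/start/end/name).
#' @param path file path.
#' @return `path` invisibly (writer); data.frame with 1-based inclusive
#'   `start`/`end` and `name` (reader).
#' @export
write_bed <- function(map, path) {
  df <- if (inherits(map, "fm_region_map")) {
    ivs <- c(list(map$dup1, map$int_region, map$dup2, map$scan_region),
             map$background_regions)
    data.frame(chrom = vapply(ivs, `[[`, "", "chrom"),
               start = vapply(ivs, `[[`, 0, "start"),
               end = vapply(ivs, `[[`, 0, "end"),
               name = vapply(ivs, `[[`, "", "label"),
               stringsAsFactors = FALSE)
  } else map
  bed <- data.frame(df$chrom, format(df$start - 1, scientific = FALSE,
                                     trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE), df$name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("malformed BED: fewer than 3 columns")
  out <- data.frame(chrom = d[[1]], start = as.numeric(d[[2]]) + 1,
                    end = as.numeric(d[[3]]),
                    name = if (ncol(d) >= 4) d[[4]] else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed BED: start > end")
  out
}

#' Write / read newick trees
#'
#' @param tree a `phylo` object (writer).
#' @param path file path.
#' @return `path` invisibly (writer); a `phylo` object (reader).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write the simulation truth sidecar
#'
#' JSON with the generating configuration, per-individual genotype truth,
#' per-site donor fixed-difference flags and per-segment erosion events.
#'
#' @param pop an `fm_population`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(pop, path) {
  jsonlite::write_json(list(
    config = pop$params$config,
    seed = pop$params$seed,
    individuals = pop$individuals[, c("sample", "truth")],
    sites = data.frame(pos = pop$registry$pos, region = pop$registry$region,
                       fixed_diff = pop$founder$fixed_diff),
    erosion_events = pop$erosion_events
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
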