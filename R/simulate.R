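# Synthetic-data generator. Builds a neutral wild-type haplotype pool over a
# Poisson site registry, constructs the FM allele for a chosen configuration
# via an inter-chromosomal birth event between two donor haplotypes (creating
# fixed differences between the duplicated copies), erodes the FM-linked
# haplotype outside the recombination-suppressed span, and assembles diploid
# individuals with known truth labels.
#
# Haplotype encoding: allele 1 = reference, 0 = alternate. An FM haplotype is
# a list with `main` (one allele per registry site; for duplicated regions
# this slot holds copy 1) plus `dup1_copy2`/`dup2_copy2` vectors over the
# region's sites when the configuration carries two copies.

#' Simulation parameters
#'
#' @param n_wt,n_fm_het,n_fm_hom individual counts per true FM genotype class
#'   (N/N, FM/N, FM/FM).
#' @param site_density expected segregating sites per bp of unscaled (scale-1)
#'   sequence; on a map at scale `s` the per-bp intensity is multiplied by `s`
#'   so expected per-region site counts are scale-invariant.
#' @param sfs_alpha shape of the symmetric Beta(alpha, alpha) distribution of
#'   founder reference-allele frequencies (`Inf` = all frequencies 0.5).
#' @param config configuration label generating the FM allele.
#' @param erosion_p per-segment probability that a non-suppressed segment of
#'   an FM chromosome has been replaced by wild-type content through
#'   recombination over the allele's history (collapses `1 - exp(-r g)`).
#' @param donor_divergence probability that a duplicated-region site is
#'   promoted to a guaranteed fixed difference between the two donor
#'   haplotypes.
#' @param identical_interval optional `fm_interval`: donor haplotypes are
#'   forced identical (no fixed differences) at sites inside it — injects a
#'   fixed-heterozygosity breakpoint while keeping the span suppressed.
#' @param free_interval optional `fm_interval`: recombination suppression is
#'   lifted for otherwise-frozen duplicate copies at sites inside it (both
#'   copies erode there) — injects a breakpoint at which both fixed
#'   heterozygosity and LD structure end, the recombination reading of a
#'   sharp fixed-het disruption.
#' @param ref_match_interval optional `fm_interval`: the frozen first copy of
#'   each duplicated region is set to the reference allele at sites inside
#'   it, creating a reference-consistent segment (pooled frequency >= 0.5).
#' @param n_pool_extra extra wild-type pool haplotypes beyond those needed for
#'   individuals and donors (erosion source diversity).
#' @param seed root RNG seed.
#' @return object of class `fm_sim_params`.
#' @export
fm_sim_params <- function(n_wt = 50, n_fm_het = 0, n_fm_hom = 50,
                          site_density = 1 / 200, sfs_alpha = 0.3,
                          config = "FM-2", erosion_p = 0.9,
                          donor_divergence = 0.1, identical_interval = NULL,
                          free_interval = NULL, ref_match_interval = NULL,
                          n_pool_extra = 20, seed = 1) {
  assert_count(n_wt, "n_wt"); assert_count(n_fm_het, "n_fm_het")
  assert_count(n_fm_hom, "n_fm_hom")
  if (!is.numeric(site_density) || site_density <= 0)
    stop_invalid("site_density must be > 0")
  if (!(is.numeric(sfs_alpha) && (sfs_alpha > 0)))
    stop_invalid("sfs_alpha must be > 0 (Inf allowed)")
  assert_prob(erosion_p, "erosion_p")
  assert_prob(donor_divergence, "donor_divergence")
  config <- match.arg(config, fm_configurations())
  for (nm in c("identical_interval", "free_interval", "ref_match_interval")) {
    v <- get(nm)
    if (!is.null(v) && !inherits(v, "fm_interval"))
      stop_invalid(nm, " must be an fm_interval or NULL")
  }
  structure(list(n_wt = n_wt, n_fm_het = n_fm_het, n_fm_hom = n_fm_hom,
                 site_density = site_density, sfs_alpha = sfs_alpha,
                 config = config, erosion_p = erosion_p,
                 donor_divergence = donor_divergence,
                 identical_interval = identical_interval,
                 free_interval = free_interval,
                 ref_match_interval = ref_match_interval,
                 n_pool_extra = n_pool_extra, seed = seed),
            class = "fm_sim_params")
}

.named_regions <- function(map) {
  c(list(FLANK1 = map$flank1, DUP1 = map$dup1, INT = map$int_region,
         DUP2 = map$dup2, FLANK2 = map$flank2),
    stats::setNames(map$background_regions,
                    vapply(map$background_regions, `[[`, "", "label")))
}

#' Place sites and draw the wild-type founder pool
#'
#' Sites are placed by a Poisson process with intensity
#' `site_density * scale` per bp within each named region of the map
#' (duplications, INT, flanks, background). Each site receives a founder
#' reference-allele frequency drawn Beta(`sfs_alpha`, `sfs_alpha`); pool
#' haplotypes sample alleles per site independently at those frequencies.
#'
#' @param map an `fm_region_map`.
#' @param params an `fm_sim_params`.
#' @param n_pool number of pool haplotypes (default sized for the requested
#'   individuals plus donors and `n_pool_extra`).
#' @param seed optional seed set before drawing.
#' @return list with `registry` (data.frame: chrom, pos, region, p_founder)
#'   and `pool` (sites x haplotypes 0/1 matrix, 1 = reference allele).
#' @export
simulate_founders <- function(map, params, n_pool = NULL, seed = NULL) {
  stopifnot(inherits(map, "fm_region_map"), inherits(params, "fm_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_pool))
    n_pool <- 2L * params$n_wt + params$n_fm_het + 2L + params$n_pool_extra
  regions <- .named_regions(map)
  dens <- params$site_density * map$scale
  pos <- list()
  for (nm in names(regions)) {
    r <- regions[[nm]]
    lambda <- (r$end - r$start + 1) * dens
    n <- stats::rpois(1, lambda)
    n <- min(n, r$end - r$start + 1)
    if (n == 0)
      stop("degenerate region: no sites placed in ", nm,
           "; increase site_density or reduce scale")
    pos[[nm]] <- sort(sample.int(r$end - r$start + 1, n) + r$start - 1)
  }
  registry <- data.frame(
    chrom = map$chrom,
    pos = unlist(pos, use.names = FALSE),
    region = rep(names(regions), lengths(pos)),
    stringsAsFactors = FALSE)
  registry <- registry[order(registry$pos), , drop = FALSE]
  rownames(registry) <- NULL
  ns <- nrow(registry)
  registry$p_founder <- if (is.infinite(params$sfs_alpha)) rep(0.5, ns)
                        else stats::rbeta(ns, params$sfs_alpha, params$sfs_alpha)
  pool <- matrix(stats::rbinom(ns * n_pool, 1L,
                               rep(registry$p_founder, n_pool)),
                 nrow = ns, ncol = n_pool)
  list(registry = registry, pool = pool)
}

#' Construct the founding FM haplotype
#'
#' Two distinct donor haplotypes A and B are drawn from the pool. Single-copy
#' regions take A's alleles. For each region that the configuration carries in
#' two copies, copy 1 takes A's alleles and copy 2 takes B's; each such site
#' is additionally promoted to a guaranteed A != B fixed difference with
#' probability `donor_divergence` (suppressed inside
#' `params$identical_interval`, where the donors are instead forced equal).
#'
#' @param founders output of [simulate_founders()].
#' @param geometry an `fm_geometry` (defaults to `params$config`).
#' @param params an `fm_sim_params`.
#' @param donor_idx optional length-2 pool column indices for donors A and B.
#' @param seed optional seed.
#' @return list of class `fm_haplotype`: `main`, `dup1_copy2`, `dup2_copy2`,
#'   `fixed_diff` (logical per registry site: copies differ), `donors`.
#' @export
construct_fm_allele <- function(founders, geometry = NULL, params,
                                donor_idx = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(geometry)) geometry <- configuration_geometry(params$config)
  stopifnot(inherits(geometry, "fm_geometry"))
  pool <- founders$pool; registry <- founders$registry
  if (ncol(pool) < 2) stop("insufficient donors: pool must hold >= 2 haplotypes")
  if (is.null(donor_idx)) donor_idx <- sample.int(ncol(pool), 2)
  a <- pool[, donor_idx[1]]; b <- pool[, donor_idx[2]]
  force_equal <- rep(FALSE, nrow(registry))
  ii <- params$identical_interval
  if (!is.null(ii))
    force_equal <- registry$pos >= ii$start & registry$pos <= ii$end
  hap <- list(main = a, dup1_copy2 = NULL, dup2_copy2 = NULL,
              fixed_diff = rep(FALSE, nrow(registry)), donors = donor_idx)
  rmi <- params$ref_match_interval
  for (rg in c("DUP1", "DUP2")) {
    if (geometry$regions[[rg]]$n_copies < 2) next
    idx <- which(registry$region == rg)
    c1 <- a[idx]; c2 <- b[idx]
    promote <- stats::runif(length(idx)) < params$donor_divergence
    c2[promote] <- 1L - c1[promote]
    c2[force_equal[idx]] <- c1[force_equal[idx]]
    if (!is.null(rmi)) {
      match_ref <- registry$pos[idx] >= rmi$start & registry$pos[idx] <= rmi$end
      c1[match_ref] <- 1L
    }
    slot <- if (rg == "DUP1") "dup1_copy2" else "dup2_copy2"
    hap$main[idx] <- c1
    hap[[slot]] <- c2
    hap$fixed_diff[idx] <- c1 != c2
  }
  class(hap) <- "fm_haplotype"
  hap
}

# Free (erodable) segments of an FM haplotype under a geometry. Each segment
# carries its registry rows, the haplotype slot it lives in, and the indices
# into that slot's vector (`rel`; equal to `rows` for the main slot). An
# optional `free_interval` lifts suppression for otherwise-frozen duplicate
# copies at the sites inside it, adding sub-interval segments.
.free_segments <- function(registry, geometry, free_interval = NULL) {
  segs <- list()
  add <- function(name, rows, slot, rel) {
    if (length(rows))
      segs[[length(segs) + 1]] <<- list(name = name, rows = rows, slot = slot,
                                        rel = rel)
  }
  in_free <- if (is.null(free_interval)) rep(FALSE, nrow(registry))
             else registry$pos >= free_interval$start &
                  registry$pos <= free_interval$end
  for (nm in setdiff(unique(registry$region), c("DUP1", "INT", "DUP2")))
    add(nm, which(registry$region == nm), "main",
        which(registry$region == nm))
  int_rows <- which(registry$region == "INT")
  if (!all(geometry$regions$INT$frozen))
    add("INT", int_rows, "main", int_rows)
  for (rg in c("DUP1", "DUP2")) {
    g <- geometry$regions[[rg]]
    rows <- which(registry$region == rg)
    slot2 <- if (rg == "DUP1") "dup1_copy2" else "dup2_copy2"
    free1 <- if (g$frozen[1]) rows[in_free[rows]] else rows
    if (length(free1))
      add(paste0(rg, ".copy1", if (g$frozen[1]) ".freed" else ""),
          free1, "main", free1)
    if (g$n_copies >= 2) {
      free2 <- if (g$frozen[2]) rows[in_free[rows]] else rows
      if (length(free2))
        add(paste0(rg, ".copy2", if (g$frozen[2]) ".freed" else ""),
            free2, slot2, match(free2, rows))
    }
  }
  segs
}

#' Erode FM chromosomes outside the suppressed span
#'
#' Each FM chromosome starts as a copy of the founder haplotype. Every
#' segment whose suppression status is free (flanks, background, INT unless
#' frozen, non-suppressed duplicate copies) is independently replaced, with
#' probability `erosion_p`, by the corresponding segment of a random
#' wild-type pool haplotype. Frozen segments are never touched.
#'
#' @param founder the founding `fm_haplotype`.
#' @param founders output of [simulate_founders()] (erosion source pool).
#' @param params an `fm_sim_params`.
#' @param n_fm_chromosomes number of FM chromosome instances to produce.
#' @param geometry geometry the founder was built under.
#' @param seed optional seed.
#' @return list of `fm_haplotype` instances; attribute `"erosion_events"` is a
#'   data.frame (chromosome, segment, eroded, source).
#' @export
erode_population <- function(founder, founders, params, n_fm_chromosomes,
                             geometry = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(geometry)) geometry <- configuration_geometry(params$config)
  segs <- .free_segments(founders$registry, geometry, params$free_interval)
  pool <- founders$pool
  out <- vector("list", n_fm_chromosomes)
  ev <- list()
  for (k in seq_len(n_fm_chromosomes)) {
    h <- founder
    touched_dup <- character()
    for (s in segs) {
      eroded <- stats::runif(1) < params$erosion_p
      src <- NA_integer_
      if (eroded) {
        src <- sample.int(ncol(pool), 1)
        if (s$slot == "main") h$main[s$rows] <- pool[s$rows, src]
        else h[[s$slot]][s$rel] <- pool[s$rows, src]
        if (startsWith(s$name, "DUP"))
          touched_dup <- union(touched_dup, substr(s$name, 1, 4))
      }
      ev[[length(ev) + 1]] <- data.frame(chromosome = k, segment = s$name,
                                         eroded = eroded, source = src)
    }
    for (rg in touched_dup) {          # refresh copy-difference bookkeeping
      idx <- which(founders$registry$region == rg)
      slot2 <- if (rg == "DUP1") "dup1_copy2" else "dup2_copy2"
      if (!is.null(h[[slot2]]))
        h$fixed_diff[idx] <- h$main[idx] != h[[slot2]]
    }
    out[[k]] <- h
  }
  attr(out, "erosion_events") <- do.call(rbind, ev) %||%
    data.frame(chromosome = integer(), segment = character(),
               eroded = logical(), source = integer())
  out
}

#' Assemble diploid individuals
#'
#' Wild-type individuals receive two distinct pool haplotypes, heterozygotes
#' one pool haplotype and one FM chromosome, homozygotes two FM chromosomes.
#' True FM genotype labels are recorded.
#'
#' @param founders output of [simulate_founders()].
#' @param fm_haps list of eroded FM chromosomes.
#' @param params an `fm_sim_params`.
#' @return data.frame: sample, hap1_type, hap1_idx, hap2_type, hap2_idx,
#'   truth (`N/N`, `FM/N`, `FM/FM`).
#' @export
assemble_individuals <- function(founders, fm_haps, params) {
  n_ind <- params$n_wt + params$n_fm_het + params$n_fm_hom
  need_wt <- 2L * params$n_wt + params$n_fm_het
  need_fm <- params$n_fm_het + 2L * params$n_fm_hom
  if (ncol(founders$pool) < need_wt)
    stop("insufficient haplotypes: pool has ", ncol(founders$pool),
         ", need ", need_wt)
  if (length(fm_haps) < need_fm)
    stop("insufficient haplotypes: ", length(fm_haps), " FM chromosomes, need ",
         need_fm)
  wt_i <- seq_len(need_wt); fm_i <- seq_len(need_fm)
  truth <- rep(c("N/N", "FM/N", "FM/FM"),
               c(params$n_wt, params$n_fm_het, params$n_fm_hom))
  h1t <- character(n_ind); h2t <- character(n_ind)
  h1i <- integer(n_ind); h2i <- integer(n_ind)
  wi <- 0L; fi <- 0L
  for (j in seq_len(n_ind)) {
    if (truth[j] == "N/N") {
      h1t[j] <- "wt"; h2t[j] <- "wt"
      h1i[j] <- wt_i[wi + 1L]; h2i[j] <- wt_i[wi + 2L]; wi <- wi + 2L
    } else if (truth[j] == "FM/N") {
      h1t[j] <- "fm"; h2t[j] <- "wt"
      h1i[j] <- fm_i[fi + 1L]; fi <- fi + 1L
      h2i[j] <- wt_i[wi + 1L]; wi <- wi + 1L
    } else {
      h1t[j] <- "fm"; h2t[j] <- "fm"
      h1i[j] <- fm_i[fi + 1L]; h2i[j] <- fm_i[fi + 2L]; fi <- fi + 2L
    }
  }
  data.frame(sample = sprintf("S%03d", seq_len(n_ind)),
             hap1_type = h1t, hap1_idx = h1i,
             hap2_type = h2t, hap2_idx = h2i,
             truth = truth, stringsAsFactors = FALSE)
}

#' Simulate a population segregating for the FM allele
#'
#' Runs the full generator: founder pool, FM allele construction, erosion and
#' individual assembly. A single root seed drives four stage streams (founders,
#' allele construction, erosion, assembly — derived in that order), so the
#' whole population is reproducible.
#'
#' @param map an `fm_region_map`.
#' @param params an `fm_sim_params`.
#' @return object of class `fm_population`: `registry`, `pool`, `fm_haps`,
#'   `individuals`, `geometry`, `params`, `map`, `erosion_events`.
#' @examples
#' pop <- simulate_population(build_region_map(100),
#'                            fm_sim_params(n_wt = 5, n_fm_hom = 5, seed = 1))
#' table(pop$individuals$truth)
#' @export
simulate_population <- function(map, params = fm_sim_params()) {
  set.seed(params$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)
  founders <- simulate_founders(map, params, seed = stage_seeds[1])
  geometry <- configuration_geometry(params$config)
  founder <- construct_fm_allele(founders, geometry, params,
                                 seed = stage_seeds[2])
  need_fm <- params$n_fm_het + 2L * params$n_fm_hom
  fm_haps <- erode_population(founder, founders, params, need_fm, geometry,
                              seed = stage_seeds[3])
  set.seed(stage_seeds[4])
  individuals <- assemble_individuals(founders, fm_haps, params)
  structure(list(registry = founders$registry, pool = founders$pool,
                 fm_haps = fm_haps, individuals = individuals,
                 geometry = geometry, params = params, map = map,
                 founder = founder,
                 erosion_events = attr(fm_haps, "erosion_events")),
            class = "fm_population")
}

#' @export
print.fm_population <- function(x, ...) {
  cat("Simulated FM-locus population (", x$params$config, ")\n", sep = "")
  cat("  sites:", nrow(x$registry), " individuals:", nrow(x$individuals), "\n")
  print(table(truth = x$individuals$truth))
  invisible(x)
}
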