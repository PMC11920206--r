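# End-to-end runner: simulate (or load files) -> observe -> CNV genotype ->
# scan -> bubble -> LD -> configuration call -> trees, with every stage's
# output written to disk in its documented format and a single JSON summary.

#' Run the whole FM-locus pipeline
#'
#' Chains the simulator, observation model, CNV genotyping, windowed scans,
#' bubble/LD analysis, configuration inference and per-duplication NJ trees,
#' writing each product into `dir` (VCF, depth TSV, truth JSON, CNV TSV,
#' window TSVs, bubble/LD/config JSON, newick trees, run summary JSON).
#' Fully deterministic given `params$seed`.
#'
#' @param dir output directory (created if needed).
#' @param map an `fm_region_map`.
#' @param params an `fm_sim_params`.
#' @param depth,error_rate observation-model settings (see [observe()]).
#' @param include_trees build the DUP1/DUP2 neighbor-joining trees.
#' @param include_ld compute LD retention.
#' @return the run summary list, invisibly; `summary.json` in `dir` holds
#'   the same content.
#' @export
run_fm_pipeline <- function(dir, map = build_region_map(100),
                            params = fm_sim_params(), depth = 30,
                            error_rate = 0.001, include_trees = TRUE,
                            include_ld = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  pop <- simulate_population(map, params)
  obs <- observe(pop, depth = depth, error_rate = error_rate,
                 seed = params$seed + 1L)
  write_vcf(obs, p("variants.vcf"))
  write_depth_tsv(obs, p("depth.tsv"))
  write_truth_json(pop, p("truth.json"))
  write_bed(map, p("regions.bed"))

  fit <- infer_fm_configuration(obs, map, include_ld = include_ld)
  utils::write.table(fit$cnv, p("cnv_calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in c("pi_fm", "pi_wt", "fst")) {
    if (!is.null(fit[[nm]]))
      utils::write.table(fit[[nm]], p(paste0(nm, "_windows.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$bubble))
    jsonlite::write_json(fit$bubble, p("bubble.json"), auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(fit$ld)) {
    utils::write.table(fit$ld$windows, p("ld_windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(fit$ld$boundary, p("ld_boundary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  trees <- NULL
  if (include_trees && length(fit$groups$fm) >= 1 &&
      ncol(obs$gt) >= 3) {
    filtered <- filter_variants(obs)
    t1 <- neighbor_joining(distance_matrix(filtered, map$dup1))
    t2 <- neighbor_joining(distance_matrix(filtered, map$dup2))
    write_newick(t1, p("tree_dup1.nwk"))
    write_newick(t2, p("tree_dup2.nwk"))
    trees <- branch_length_contrast(t1, t2, fit$groups$fm)
  }

  cnv_acc <- mean(fit$cnv$call == pop$individuals$truth)
  summary <- list(
    config_truth = params$config,
    config_call = fit$call$best,
    call_status = fit$call$status,
    bubble_flags = as.list(stats::setNames(fit$signature$bubble,
                                           fit$signature$region)),
    cnv_accuracy = cnv_acc,
    n_sites_filtered = fit$n_sites_filtered,
    branch_contrast = trees,
    seed = params$seed)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(summary)
}
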