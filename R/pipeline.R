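#' Pipeline configuration
#'
#' All tunables default to the published analysis values: library QC at two
#' million mapped reads, inactivity filter at CPM <= 1 in more than 77 % of
#' samples in both supertypes, candidate thresholds FDR < 0.01, fold change
#' > 4, mean CPM > 4, and 95 % confidence intervals. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the default keys (see Details).
#' @details Keys: `min_mapped` (2e6), `cpm_threshold` (1), `frac` (0.77),
#'   `max_fdr` (0.01), `min_fold` (4), `min_cpm` (4), `conf` (0.95),
#'   `top_n` (500), `group1` ("non_lepidic_AD"), `group2` ("PDSCC"),
#'   `n_regions`, `n_de`, `de_log2fc`, `n_separators`, `seed`.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(min_mapped = 2e6, cpm_threshold = 1, frac = 0.77,
                   max_fdr = 0.01, min_fold = 4, min_cpm = 4, conf = 0.95,
                   top_n = 500, group1 = "non_lepidic_AD", group2 = "PDSCC",
                   n_regions = 2000, n_de = 30, de_log2fc = 3,
                   n_separators = 7, seed = 1L)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read a flat YAML pipeline configuration
#' @param path YAML file of scalar key: value pairs.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates simulate -> qc -> cpm -> filter -> mds -> de ->
#' evaluate -> panel -> cluster, writing every stage output as TSV (plus
#' Newick trees) into `out_dir` together with a machine-readable
#' `manifest.json` recording the package version, seed, thresholds, stage
#' outputs and their checksums. Deterministic given the configuration.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  outputs <- character()
  emit <- function(name, writer) { writer(file.path(out_dir, name))
    outputs <<- c(outputs, name) }

  log_stage("simulate", "cohort with %d regions, seed %d",
            config$n_regions, config$seed)
  cohort <- simulate_cohort(cohort_config(
    n_regions = config$n_regions, n_de = config$n_de,
    de_log2fc = config$de_log2fc, n_separators = config$n_separators,
    seed = config$seed))
  ihc <- simulate_ihc(default_marker_panel(), cohort$samples,
                      seed = config$seed + 1L)
  emit("counts.tsv", function(p) write_tsv_matrix(cohort$counts, p))
  emit("regions.bed", function(p) write_bed_regions(cohort$counts$regions, p))
  emit("samples.tsv", function(p) write_sample_table(cohort$samples, p))
  emit("ground_truth.tsv", function(p)
    utils::write.table(cohort$truth, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  write_ihc_table(ihc, out_dir)
  outputs <- c(outputs, "ihc_scores.tsv", "ihc_markers.tsv")

  log_stage("qc", "libraries > %g mapped reads", config$min_mapped)
  qcd <- qc_libraries(cohort$counts, config$min_mapped)

  log_stage("cpm", "normalising %d samples", ncol(qcd$counts))
  cpm_mat <- cpm(qcd)
  emit("cpm.tsv", function(p) write_tsv_matrix(cpm_mat, p))

  log_stage("filter", "CPM <= %g in more than %g%% of both supertypes",
            config$cpm_threshold, 100 * config$frac)
  keep <- filter_inactive(cpm_mat, cohort$samples, config$cpm_threshold,
                          config$frac)
  cpm_f <- cpm_mat[keep, , drop = FALSE]
  qcd_f <- cage_counts(qcd$counts[keep, , drop = FALSE],
                       qcd$regions[qcd$regions$region_id %in% keep, ],
                       qcd$lib_sizes)
  log_stage("filter", "%d of %d regions retained", length(keep),
            nrow(cpm_mat))

  log_stage("mds", "top %d leading fold changes", config$top_n)
  mds <- mds_cage(cpm_f, top_n = config$top_n)
  emit("mds.tsv", function(p)
    utils::write.table(data.frame(sample_id = rownames(mds$coords),
                                  mds$coords),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))

  log_stage("de", "%s vs %s", config$group1, config$group2)
  de <- de_screen(qcd_f, cohort$samples, config$group1, config$group2,
                  screen_thresholds(config$max_fdr, config$min_fold,
                                    config$min_cpm))
  emit("de_results.tsv", function(p)
    utils::write.table(de, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("ma_plot.tsv", function(p)
    utils::write.table(data.frame(region_id = de$region_id,
                                  mean_cpm = de$mean_cpm,
                                  log2fc = de$log2fc,
                                  candidate = de$candidate),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))

  log_stage("evaluate", "per-marker diagnostic performance")
  marker_eval <- evaluate_markers(ihc, conf = config$conf)
  emit("marker_performance.tsv", function(p)
    utils::write.table(marker_eval, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  log_stage("panel", "exhaustive two-marker search")
  calls <- binarize(ihc)
  search <- exhaustive_search(ihc$markers, calls, ihc$samples)
  emit("panel_search.tsv", function(p)
    utils::write.table(search, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  seq_out <- sequential_panel(
    panel_rule(search$ad_marker[1], search$scc_marker[1]),
    panel_rule(search$ad_marker[min(2, nrow(search))],
               search$scc_marker[min(2, nrow(search))]),
    calls, ihc$samples)

  log_stage("cluster", "binary-profile UPGMA on samples and markers")
  cl <- cluster_ihc(ihc)
  emit("sample_tree.nwk", function(p) tree_newick(cl$sample_tree, p))
  emit("marker_tree.nwk", function(p) tree_newick(cl$marker_tree, p))
  emit("heatmap_matrix.tsv", function(p)
    write_tsv_matrix(heatmap_order(ihc, cl$sample_tree, cl$marker_tree), p))

  stages <- list(simulate = c("counts.tsv", "regions.bed", "samples.tsv",
                              "ground_truth.tsv", "ihc_scores.tsv",
                              "ihc_markers.tsv"),
                 qc = character(), cpm = "cpm.tsv", filter = character(),
                 mds = "mds.tsv", de = c("de_results.tsv", "ma_plot.tsv"),
                 evaluate = "marker_performance.tsv",
                 panel = "panel_search.tsv",
                 cluster = c("sample_tree.nwk", "marker_tree.nwk",
                             "heatmap_matrix.tsv"))
  manifest <- list(
    package = "promopanel",
    version = as.character(utils::packageVersion("promopanel")),
    seed = config$seed,
    thresholds = unclass(config),
    stages = stages,
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, ihc = ihc, qc = qcd, cpm = cpm_mat,
                 retained = keep, mds = mds, de = de,
                 marker_eval = marker_eval, search = search,
                 sequential = seq_out, cluster = cl, manifest = manifest))
}
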