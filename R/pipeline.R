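#' Pipeline configuration
#'
#' Bundles the per-stage configurations under a single seed so the whole
#' simulate -> call -> filter -> compare workflow is reproducible:
#' identical config and seed give byte-identical outputs.
#'
#' @param sim a [sim_config()].
#' @param varscan a [varscan_config()].
#' @param priors a [prior_config()].
#' @param model a [genotype_likelihood_model()].
#' @param filter a [filter_config()].
#' @param thresholds caller inclusion thresholds (see
#'   [run_all_callers()]).
#' @param jsm_mode `"jsm2"` or `"jsm1"`.
#' @param grid_step grid for the marginalized-frequency caller.
#' @param train_fraction EM training subsample fraction.
#' @param sweep_thresholds score grid for [threshold_sweep()].
#' @param seed master seed; overrides `sim$seed`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), varscan = varscan_config(),
                            priors = prior_config(),
                            model = genotype_likelihood_model(),
                            filter = filter_config(),
                            thresholds = list(varscan_p = 0.05,
                                              somaticsniper_S = 15,
                                              jointsnvmix_score = 0.001,
                                              strelka_phred = 1),
                            jsm_mode = "jsm2", grid_step = 0.01,
                            train_fraction = 1,
                            sweep_thresholds = seq(0, 1, length.out = 101),
                            seed = sim$seed) {
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, varscan = varscan, priors = priors,
                 model = model, filter = filter, thresholds = thresholds,
                 jsm_mode = jsm_mode, grid_step = grid_step,
                 train_fraction = train_fraction,
                 sweep_thresholds = sweep_thresholds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' 20,000 sites at modest depth with a handful of planted somatic
#' events; runs the full pipeline in a couple of minutes.
#'
#' @param seed master seed.
#' @export
demo_pipeline_config <- function(seed = 1L) {
  pipeline_config(sim = sim_config(n_sites = 20000L, seed = seed,
                                   mean_depth_normal = 40,
                                   mean_depth_tumour = 40,
                                   n_clonal_somatic = 20L,
                                   n_subclonal_somatic = 20L,
                                   tumour_purity = 0.8),
                  seed = seed)
}

.tsv <- function(df, path, digits = NULL) {
  out <- df
  for (cl in names(out))
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
      out[[cl]] <- ifelse(is.na(out[[cl]]), "NA",
                          sprintf("%.6f", out[[cl]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full comparison pipeline
#'
#' Stages: (1) simulate the matched pair and write the pileup and truth;
#' (2) run all four callers and write the raw candidates; (3) apply the
#' filter suite, writing the per-rule report and the filtered
#' candidates; (4) write the comparison tables (overlaps, pairwise score
#' correlations, threshold sweep, unique-call VAF profiles, filter pass
#' rates, truth evaluation); (5) run the normal-normal split null and
#' write its calls. A manifest of every output with its MD5 content hash
#' is written last; identical config and seed reproduce identical
#' hashes. Every intermediate is a plain file re-loadable by the module
#' that consumes it.
#'
#' @param config a [pipeline_config()].
#' @param out_dir writable output directory (created if needed).
#' @param verbose print per-stage progress.
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  p <- function(f) file.path(out_dir, f)

  say("stage 1: simulate (%d sites)", config$sim$n_sites)
  sim <- simulate_pair(config$sim)
  write_paired_pileup(sim$pileup, p("pileup.tsv"))
  write_truth(sim$truth, p("truth.tsv"))

  say("stage 2: call")
  calls <- run_all_callers(sim$pileup, varscan = config$varscan,
                           priors = config$priors, model = config$model,
                           jsm_mode = config$jsm_mode,
                           grid_step = config$grid_step,
                           thresholds = config$thresholds,
                           train_fraction = config$train_fraction,
                           train_seed = config$seed)
  write_candidates(calls, p("raw_candidates.tsv"), "tsv")
  write_candidates(calls, p("raw_candidates.vcf"), "vcf")

  say("stage 3: filter (%d calls)", nrow(calls))
  verdicts <- apply_filters_all(calls, sim$pileup, config$filter)
  .tsv(verdicts, p("filter_report.tsv"))
  filtered <- calls[verdicts$overall_pass, , drop = FALSE]
  filtered <- .as_candidate_calls(filtered)
  write_candidates(filtered, p("filtered_candidates.tsv"), "tsv")

  say("stage 4: compare (%d filtered calls)", nrow(filtered))
  mat <- comparison_matrix(filtered)
  ov <- overlap_counts(mat, "somatic")
  .tsv(data.frame(subset = names(ov), n = as.integer(ov)),
       p("overlaps.tsv"))
  .tsv(pairwise_score_correlation(mat), p("correlations.tsv"))
  known <- sim$truth[sim$truth$truth_class %in%
                     c("germline_het", "germline_hom"), c("chrom", "pos")]
  .tsv(threshold_sweep(mat, known, config$sweep_thresholds),
       p("sweep.tsv"))
  .tsv(vaf_profile(mat), p("vaf_profiles.tsv"))
  pr <- pass_rate_table(verdicts)
  .tsv(pr$table, p("pass_rates.tsv"))
  .tsv(pr$tests, p("pass_rate_tests.tsv"))
  ev <- evaluate_against_truth(mat, sim$truth)
  .tsv(ev$sensitivity, p("truth_eval.tsv"))
  .tsv(ev$calls, p("truth_eval_calls.tsv"))

  say("stage 5: split null")
  sn <- split_null(config$sim)
  sn_calls <- run_all_callers(sn$pair$pileup, varscan = config$varscan,
                              priors = config$priors, model = config$model,
                              jsm_mode = config$jsm_mode,
                              grid_step = config$grid_step,
                              thresholds = config$thresholds,
                              train_fraction = config$train_fraction,
                              train_seed = config$seed)
  write_candidates(sn_calls, p("split_null_candidates.tsv"), "tsv")

  files <- c("pileup.tsv", "truth.tsv", "raw_candidates.tsv",
             "raw_candidates.vcf", "filter_report.tsv",
             "filtered_candidates.tsv", "overlaps.tsv", "correlations.tsv",
             "sweep.tsv", "vaf_profiles.tsv", "pass_rates.tsv",
             "pass_rate_tests.tsv", "truth_eval.tsv",
             "truth_eval_calls.tsv", "split_null_candidates.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
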