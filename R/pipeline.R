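# End-to-end demo pipeline: simulate -> call ploidy -> cohort statistics.

REPORT_SCHEMA_VERSION <- "1.0"

#' Build a run configuration
#'
#' A fully serializable description of one pipeline run. A persisted config
#' re-runs to identical outputs for the same package version: one top-level
#' seed fans out into named sub-streams (layout / fates / per-embryo depth),
#' so no stage's consumption of random numbers can shift another's.
#'
#' @param seed Master integer seed.
#' @param n_embryos_per_cross Embryos per cross in the simulated cohort.
#' @param n_sequenced Number of CI blastoderm embryos put through the
#'   depth-based ploidy caller.
#' @param n_depth_files How many of the sequenced embryos get their depth
#'   profile written to disk as bedGraph (0 = none).
#' @param out_dir Output directory (created if missing).
#' @param arm_length_bp,gene_length_bp Layout parameters.
#' @param coverage,noise Depth-simulation parameters.
#' @param fate Named list of `FateParams` (default [default_fate_params()]).
#' @param percent_threshold,evenness_threshold Transgene-caller thresholds.
#' @param paternal_markers Paternal-only markers for [call_ploidy()].
#' @return A `RunConfig`.
#' @export
run_config <- function(seed = 1, n_embryos_per_cross = 250, n_sequenced = 24,
                       n_depth_files = 2, out_dir = tempfile("embryoploidy_"),
                       arm_length_bp = 100000, gene_length_bp = 1000,
                       coverage = 50, noise = "poisson",
                       fate = default_fate_params(),
                       percent_threshold = 25, evenness_threshold = 0.9,
                       paternal_markers = c("egfp", "Y")) {
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(list(seed = as.integer(seed),
                 n_embryos_per_cross = n_embryos_per_cross,
                 n_sequenced = n_sequenced, n_depth_files = n_depth_files,
                 out_dir = out_dir, arm_length_bp = arm_length_bp,
                 gene_length_bp = gene_length_bp, coverage = coverage,
                 noise = noise, fate = fate,
                 percent_threshold = percent_threshold,
                 evenness_threshold = evenness_threshold,
                 paternal_markers = paternal_markers),
            class = "RunConfig")
}

demo_log <- function(...) message("[embryoploidy] ", ...)

validate_report <- function(report) {
  req <- c("schema_version", "seed", "thresholds", "cohort", "lethal_phase",
           "egg_to_adult", "sequenced")
  miss <- setdiff(req, names(report))
  if (length(miss)) stop_bad("report schema violation, missing: ",
                             paste(miss, collapse = ", "))
  invisible(report)
}

#' Run the demonstration pipeline
#'
#' Simulates a four-cross embryo cohort under the fate model, selects CI
#' embryos that reached the blastoderm stage, simulates their sequencing
#' depth profiles according to their true ploidy (diploid XY/XX or
#' maternal-only haploid), calls ploidy on each from depth alone, tabulates
#' haploid/diploid fractions among blastoderms, runs the lethal-phase and
#' egg-to-adult analyses, and writes one JSON report (plus optional
#' per-embryo bedGraph files). Deterministic per seed.
#'
#' @param config A `RunConfig` from [run_config()].
#' @return Invisibly, list(report, report_path, layout).
#' @export
run_demo <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (!is.numeric(config$n_embryos_per_cross) ||
      config$n_embryos_per_cross < 1) {
    stop_bad("config validation: n_embryos_per_cross must be >= 1")
  }
  if (config$n_sequenced < 0 || config$n_depth_files < 0) {
    stop_bad("config validation: sequenced/depth-file counts must be >= 0")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  demo_log("stage layout: building miniature genome")
  layout <- tryCatch(
    build_layout(config$arm_length_bp, config$gene_length_bp,
                 seed = substream_seed(seed, "layout")),
    error = function(e) stop_bad("stage 'layout' failed: ", conditionMessage(e)))

  demo_log("stage cohort: simulating ", config$n_embryos_per_cross,
           " embryos x ", length(config$fate), " crosses")
  cohort <- tryCatch(
    simulate_cohort(config$fate, config$n_embryos_per_cross,
                    seed = substream_seed(seed, "fates")),
    error = function(e) stop_bad("stage 'cohort' failed: ", conditionMessage(e)))
  write_cohort_tsv(cohort, file.path(config$out_dir, "cohort.tsv"))

  ci_blast <- cohort[cohort$cross == "ci" & cohort$reached_blastula, ]
  n_seq <- min(config$n_sequenced, nrow(ci_blast))
  demo_log("stage sequencing: calling ploidy on ", n_seq, " CI blastoderms")
  calls <- vector("list", n_seq)
  for (i in seq_len(n_seq)) {
    id <- ci_blast$embryo_id[i]
    kt <- if (ci_blast$ploidy[i] == "haploid") {
      karyotype_preset("haploid_maternal")
    } else {
      sex_male <- with_substream(substream_seed(seed, "sex", id),
                                 stats::runif(1) < 0.5)
      karyotype_preset(if (sex_male) "diploid_xy" else "diploid_xx")
    }
    prof <- tryCatch(
      simulate_depth(layout, kt, target_coverage = config$coverage,
                     noise = config$noise,
                     seed = substream_seed(seed, "depth", id),
                     embryo_id = id),
      error = function(e) stop_bad("stage 'depth' failed for embryo ", id,
                                   ": ", conditionMessage(e)))
    if (i <= config$n_depth_files) {
      write_bedgraph(prof, file.path(config$out_dir,
                                     paste0(id, ".bedgraph")))
    }
    calls[[i]] <- tryCatch(
      call_embryo(prof, layout, paternal_markers = config$paternal_markers,
                  percent_threshold = config$percent_threshold,
                  evenness_threshold = config$evenness_threshold),
      error = function(e) stop_bad("stage 'call-ploidy' failed for embryo ",
                                   id, ": ", conditionMessage(e)))
  }
  called <- vapply(calls, function(cl) cl$ploidy, character(1))
  truth <- ci_blast$ploidy[seq_len(n_seq)]

  demo_log("stage stats: lethal phase and attrition")
  lethal <- lethal_phase_analysis(cohort)
  adults <- egg_to_adult_counts(cohort)
  adults <- adults[adults$total > 0, , drop = FALSE]
  attrition <- defect_rate_report(
    adults,
    comparisons = if (all(c("ci", "wild_type") %in% adults$group)) {
      list(list(a = "ci", b = "wild_type", method = "fisher"))
    } else list())

  if (n_seq > 0) {
    pdm <- percent_depth_matrix(calls)
    utils::write.table(
      data.frame(gene = rownames(pdm), pdm, check.names = FALSE),
      file.path(config$out_dir, "percent_depth_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    seed = seed,
    thresholds = list(percent_threshold = config$percent_threshold,
                      evenness_threshold = config$evenness_threshold,
                      dosage_band_edges = c(25, 75, 125),
                      arm_majority = "3 of 5"),
    cohort = list(
      n_per_cross = config$n_embryos_per_cross,
      blastula_fraction_ci = mean(cohort$reached_blastula[cohort$cross == "ci"]),
      diploid_fraction_among_ci_blastoderms =
        if (nrow(ci_blast)) mean(ci_blast$ploidy == "diploid") else NA
    ),
    sequenced = list(
      n = n_seq,
      called_diploid = sum(called == "diploid"),
      called_haploid = sum(called == "haploid"),
      called_other = sum(!called %in% c("diploid", "haploid")),
      concordance_with_truth = if (n_seq) mean(called == truth) else NA
    ),
    lethal_phase = lethal,
    egg_to_adult = attrition$proportions,
    attrition_tests = attrition$tests
  )
  validate_report(report)
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  demo_log("report written to ", report_path)
  invisible(list(report = report, report_path = report_path, layout = layout))
}
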