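# End-to-end orchestration.
#
# Stage order follows the analysis: (optional) simulate -> sex-confound
# filter -> outcome labeling (threshold derived from labs when present,
# otherwise supplied) -> baseline scan -> dyad/triad screening -> networks
# and metrics -> BEST comparison. Every stage writes its tabular output
# under the output directory and the run closes with a JSON manifest
# (package version, seed, configuration, per-stage record counts, file
# checksums, warnings). The manifest contains nothing volatile, so two runs
# with the same seed produce byte-identical manifests; wall-clock timings
# go to a separate, unhashed file.

PIPELINE_STAGES <- c("sex_filter", "label", "baseline", "dyads", "triads",
                     "network", "best")

#' Assemble a pipeline configuration
#'
#' @param scenario a `simulation_scenario` to simulate a cohort, or `NULL`
#'   when reading files.
#' @param cohort_path,catalog_path input files (ignored when `scenario`
#'   is given).
#' @param out_dir output directory, created if missing.
#' @param threshold fixed delta-z threshold; `NULL` derives it from labs.
#' @param ranges healthy-range configuration for the lab partition.
#' @param sex_alpha significance level of the sex-confound filter.
#' @param prior Beta prior shared by baseline and interaction scans.
#' @param min_prob probability threshold (seeds, flags, Stay/Swap).
#' @param min_occurrences rarity cutoff for interaction tuples.
#' @param best a [best_config()] for the metric comparison.
#' @param stages subset of `sex_filter`, `label`, `baseline`, `dyads`,
#'   `triads`, `network`, `best` to run; stages whose inputs were skipped
#'   are skipped too.
#' @param rng_seed master seed for simulation and MCMC.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, cohort_path = NULL,
                            catalog_path = NULL, out_dir = tempfile("pcrun"),
                            threshold = NULL,
                            ranges = default_healthy_ranges(),
                            sex_alpha = 0.05, prior = c(1, 1),
                            min_prob = 0.9, min_occurrences = 6L,
                            best = best_config(), stages = PIPELINE_STAGES,
                            rng_seed = 42L) {
  if (is.null(scenario) && is.null(cohort_path)) {
    stop("either a simulation scenario or a cohort path is required")
  }
  stopifnot(min_prob > 0, min_prob < 1, sex_alpha > 0, sex_alpha < 1)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(scenario = scenario, cohort_path = cohort_path,
                 catalog_path = catalog_path, out_dir = out_dir,
                 threshold = threshold, ranges = ranges,
                 sex_alpha = sex_alpha, prior = prior, min_prob = min_prob,
                 min_occurrences = as.integer(min_occurrences), best = best,
                 stages = stages, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  keep <- config[c("threshold", "sex_alpha", "prior", "min_prob",
                   "min_occurrences", "stages", "rng_seed")]
  keep$best <- unclass(config$best)
  keep$ranges <- config$ranges
  keep$simulated <- !is.null(config$scenario)
  keep
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result` with the in-memory stage outputs
#'   (`cohort`, `threshold`, `baseline`, `seeds`, `dyads`, `triads`,
#'   `networks`, `metrics`, `best`), plus `manifest_path` and
#'   `manifest_md5`. On a stage failure a `FAILED` marker naming the stage
#'   is left in the output directory and the error is re-signalled.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outf <- function(name) file.path(config$out_dir, name)
  manifest <- list(package = "psychcooccur",
                   version = as.character(utils::packageVersion("psychcooccur")),
                   seed = config$rng_seed,
                   config = config_fingerprint(config),
                   stages = list(), warnings = character())
  res <- list()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  warn <- function(...) {
    manifest$warnings <<- c(manifest$warnings, sprintf(...))
  }
  current_stage <- "init"
  run_stage <- function(stage, enabled, fn) {
    current_stage <<- stage
    if (!enabled) {
      note(stage, status = "skipped")
      return(invisible(NULL))
    }
    fn()
  }
  on_failure <- function(e) {
    writeLines(sprintf("stage '%s' failed: %s", current_stage,
                       conditionMessage(e)), outf("FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  }
  timings <- list()
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  want <- function(stage) stage %in% config$stages

  withCallingHandlers(tryCatch({
    # --- acquire cohort -----------------------------------------------
    current_stage <- "input"
    if (!is.null(config$scenario)) {
      gen <- generate_cohort(config$scenario, seed = config$rng_seed)
      coh <- gen$cohort
      coh$outcome <- NULL  # labels re-derived by the labeling stage
      write_ground_truth(gen$ground_truth, outf("ground_truth.json"))
      res$ground_truth <- gen$ground_truth
      note("input", status = "simulated", n = n_records(coh))
    } else {
      coh <- read_cohort(config$cohort_path, config$catalog_path)
      note("input", status = "read", n = n_records(coh),
           path = config$cohort_path)
    }

    # --- sex-confound filter ------------------------------------------
    timed("sex_filter", run_stage("sex_filter", want("sex_filter"), function() {
      filt <- sex_association_filter(coh, config$sex_alpha)
      coh <<- restrict_catalog(coh, filt$retained)
      for (w in filt$warnings) warn("%s", w)
      utils::write.csv(filt$removed, outf("sex_removed.csv"),
                       row.names = FALSE)
      note("sex_filter", status = "done", removed = nrow(filt$removed),
           retained = nrow(filt$retained))
      res$sex_filter <<- filt
    }))

    # --- outcome labeling ---------------------------------------------
    timed("label", run_stage("label", want("label"), function() {
      if (is.null(config$threshold) && !any(has_labs(coh))) {
        pc_error("pc_no_labs_error",
                 "outcome stage: no lab data and no fixed threshold supplied")
      }
      lab <- label_cohort(coh, config$threshold, config$ranges)
      coh <<- lab$cohort
      thr <- lab$threshold
      if (inherits(thr, "threshold_result")) {
        jsonlite::write_json(unclass(thr), outf("threshold.json"),
                             auto_unbox = TRUE, digits = NA)
      } else {
        jsonlite::write_json(list(threshold = thr, fixed = TRUE),
                             outf("threshold.json"), auto_unbox = TRUE,
                             digits = NA)
      }
      note("label", status = "done",
           threshold = if (inherits(thr, "threshold_result"))
             thr$threshold else thr,
           n_impv = sum(coh$outcome == "IMPV"),
           n_mc = sum(coh$outcome == "MC"))
      res$threshold <<- thr
    }))
    write_cohort(coh, outf("cohort.csv"))
    write_catalog(coh$catalog, outf("catalog.csv"))
    res$cohort <- coh

    needs_labels <- function(stage) {
      if (is.null(coh$outcome)) {
        pc_error("pc_unlabeled_error",
                 "%s stage requires outcome labels (enable 'label')", stage)
      }
    }

    # --- baseline scan ------------------------------------------------
    baseline <- NULL
    timed("baseline", run_stage("baseline", want("baseline"), function() {
      needs_labels("baseline")
      baseline <<- baseline_scan(coh, config$prior, config$min_prob)
      if (any(baseline$correction_applied)) {
        warn("zero-cell correction applied to %d baseline table(s)",
             sum(baseline$correction_applied))
      }
      write_result_table(baseline, outf("baseline.csv"))
      note("baseline", status = "done", n = nrow(baseline),
           flagged = sum(baseline$flag != ""))
      res$baseline <<- baseline
      res$seeds <<- select_seeds(baseline, config$min_prob)
    }))

    # --- interaction scans --------------------------------------------
    scan_stage <- function(stage, fn) {
      timed(stage, run_stage(stage, want(stage) && !is.null(baseline),
                             function() {
        sc <- fn(coh, baseline, config$prior, config$min_prob,
                 config$min_occurrences)
        write_result_table(sc, outf(paste0(stage, ".csv")))
        if (stage == "dyads") {
          export_interaction_edges(sc, tsv_path = outf("dyad_edges.tsv"),
                                   graphml_path = outf("dyad_edges.graphml"))
        }
        note(stage, status = "done", n = nrow(sc),
             stay = sum(sc$designation == "Stay"),
             swap = sum(sc$designation == "Swap"))
        res[[stage]] <<- sc
      }))
    }
    scan_stage("dyads", dyad_scan)
    scan_stage("triads", triad_scan)

    # --- networks and metrics -----------------------------------------
    metrics <- NULL
    timed("network", run_stage("network", want("network"), function() {
      needs_labels("network")
      shared <- shared_characteristics(coh)
      nets <- lapply(c(IMPV = "IMPV", MC = "MC"), function(g) {
        net <- build_network(coh, g, shared)
        export_network(net,
                       graphml_path = outf(sprintf("network_%s.graphml", g)),
                       tsv_path = outf(sprintf("network_%s.tsv", g)))
        net
      })
      metrics <<- lapply(nets, compute_all_metrics)
      write_metric_distributions(metrics, outf("metrics.csv"))
      note("network", status = "done", shared = length(shared),
           edges_impv = nrow(nets$IMPV$edges),
           edges_mc = nrow(nets$MC$edges))
      res$networks <<- nets
      res$metrics <<- metrics
    }))

    # --- BEST comparison ----------------------------------------------
    timed("best", run_stage("best", want("best") && !is.null(metrics),
                            function() {
      cfg <- config$best
      cfg$rng_seed <- config$rng_seed
      cmp <- compare_all_metrics(metrics$IMPV, metrics$MC, cfg)
      write_result_table(cmp, outf("best.csv"))
      note("best", status = "done", n = nrow(cmp),
           differentiating = sum(cmp$differentiating))
      res$best <<- cmp
    }))
  }, error = on_failure))

  # --- manifest --------------------------------------------------------
  files <- sort(setdiff(list.files(config$out_dir),
                        c("manifest.json", "timings.json", "FAILED")))
  sums <- tools::md5sum(file.path(config$out_dir, files))
  manifest$files <- stats::setNames(as.list(unname(sums)), files)
  jsonlite::write_json(manifest, outf("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(timings, outf("timings.json"), auto_unbox = TRUE)
  res$manifest_path <- outf("manifest.json")
  res$manifest_md5 <- unname(tools::md5sum(outf("manifest.json")))
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run:", x$manifest_path, "\n")
  if (!is.null(x$threshold) && inherits(x$threshold, "threshold_result")) {
    cat(sprintf("  derived threshold %.3f\n", x$threshold$threshold))
  }
  if (!is.null(x$baseline)) {
    cat(sprintf("  baseline: %d characteristics, %d flagged\n",
                nrow(x$baseline), sum(x$baseline$flag != "")))
  }
  if (!is.null(x$dyads)) {
    cat(sprintf("  dyads: %d stay, %d swap\n",
                sum(x$dyads$designation == "Stay"),
                sum(x$dyads$designation == "Swap")))
  }
  if (!is.null(x$best)) {
    cat(sprintf("  BEST: %d/%d metrics differentiating\n",
                sum(x$best$differentiating), nrow(x$best)))
  }
  invisible(x)
}
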