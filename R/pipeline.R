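# End-to-end orchestration: simulate -> features -> screen -> densities ->
# atlas -> z-scores -> reliability -> classification -> differential pairs,
# with a reproducible run manifest.

#' Pipeline run configuration
#'
#' Bundles every stage's parameters. `stages` toggles stages off: a stage
#' that is absent is skipped, and downstream stages consume the best
#' available upstream artifact (e.g. with `"screen"` off, densities are
#' computed from unfiltered events and the reliability report is marked
#' uncorrected).
#'
#' @param cohort a [cohort_config()].
#' @param brain named list of [build_toy_brain()] arguments.
#' @param screen a [training_spec()].
#' @param stages character vector of stage names, a subset of
#'   `c("simulate", "features", "screen", "density", "atlas", "zscore",
#'   "reliability", "classify", "diffpairs")`.
#' @param jackknife jackknife protocol, `"refit"` or `"fixed"`.
#' @param p_enter,p_remove stepwise selection thresholds.
#' @param sig_threshold differential-activity significance threshold.
#' @param seed master seed (overrides `cohort$seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            brain = list(n_pairs = 8, n_subcortical = 3,
                                         subdivisions = 3),
                            screen = training_spec(),
                            stages = c("simulate", "features", "screen",
                                       "density", "atlas", "zscore",
                                       "reliability", "classify",
                                       "diffpairs"),
                            jackknife = "refit", p_enter = 0.05,
                            p_remove = 0.10, sig_threshold = 1e-8,
                            seed = NULL) {
  known <- c("simulate", "features", "screen", "density", "atlas", "zscore",
             "reliability", "classify", "diffpairs")
  if (!all(stages %in% known))
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  if (!is.null(seed)) cohort$seed <- seed
  structure(list(cohort = cohort, brain = brain, screen = screen,
                 stages = stages, jackknife = jackknife, p_enter = p_enter,
                 p_remove = p_remove, sig_threshold = sig_threshold),
            class = "pipeline_config")
}

pipeline_stage <- function(name, outdir, fn) {
  res <- tryCatch(fn(), error = function(e) {
    err <- list(failed_stage = name, message = conditionMessage(e))
    jsonlite::write_json(err, file.path(outdir, "error.json"),
                         auto_unbox = TRUE)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message("stage ", name, ": done")
  res
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages and writes every artifact as TSV/JSON
#' under `outdir`. Outputs are pure functions of the configuration and
#' seed: rerunning with an identical configuration reproduces byte-identical
#' tables. A `manifest.json` records the configuration (with its md5 hash),
#' the stages run, and the files written; a stage failure writes
#' `error.json` naming the stage and halts.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  on <- function(s) s %in% config$stages
  res <- list()

  model <- do.call(build_toy_brain, config$brain)
  write_parcellation(model$regions, file.path(outdir, "parcellation.tsv"))

  events <- NULL
  if (on("simulate")) {
    sim <- pipeline_stage("simulate", outdir,
                          function() simulate_cohort(config$cohort, model))
    events <- sim$events
    write_events(events, file.path(outdir, "events.tsv"))
    write_tsv_table(sim$subjects, file.path(outdir, "subjects.tsv"))
    res$subjects <- sim$subjects
  } else if (file.exists(file.path(outdir, "events.tsv"))) {
    events <- read_events(file.path(outdir, "events.tsv"))
    res$subjects <- read_tsv_table(file.path(outdir, "subjects.tsv"))
  } else stop("no events: enable the simulate stage or provide events.tsv")

  feats <- NULL
  if (on("features")) {
    feats <- pipeline_stage("features", outdir,
                            function() compute_features(events, model))
    write_tsv_table(cbind(events[, c("subject_id", "session", "condition",
                                     "region_id")], feats),
                    file.path(outdir, "features.tsv"))
  }

  analysis_events <- events
  screened <- NULL
  if (on("screen")) {
    screened <- pipeline_stage("screen", outdir, function()
      screen_cohort(events, model, "rest_vs_empty", config$screen,
                    seed = config$cohort$seed, features = feats))
    write_tsv_table(screened$report, file.path(outdir, "screen_report.tsv"))
    write_events(screened$filtered_events,
                 file.path(outdir, "events_screened.tsv"))
    task_screen <- pipeline_stage("screen", outdir, function()
      screen_cohort(events, model, "rest_vs_task", config$screen,
                    seed = config$cohort$seed, features = feats))
    write_tsv_table(task_screen$report,
                    file.path(outdir, "screen_report_task.tsv"))
    analysis_events <- screened$filtered_events
    res$screen <- screened$report
    res$screen_task <- task_screen$report
  }

  density <- density_raw <- NULL
  if (on("density")) {
    density <- pipeline_stage("density", outdir, function()
      compute_density(count_events(analysis_events, model$regions)))
    density_raw <- compute_density(count_events(events, model$regions))
    write_tsv_table(density, file.path(outdir, "density.tsv"))
    res$density <- density
  }

  atlas <- NULL
  if (on("atlas") && !is.null(density)) {
    atlas <- pipeline_stage("atlas", outdir,
                            function() build_atlas(density))
    write_atlas(atlas, file.path(outdir, "atlas.tsv"), model$regions)
    res$atlas <- atlas
  }

  zscores <- NULL
  if (on("zscore") && !is.null(atlas)) {
    zscores <- pipeline_stage("zscore", outdir,
                              function() to_zscores(density, atlas))
    write_tsv_table(zscores, file.path(outdir, "zscores.tsv"))
    res$zscores <- zscores
  }

  if (on("reliability") && !is.null(zscores)) {
    rel <- pipeline_stage("reliability", outdir, function() {
      sel <- function(z, ses, cond)
        z[z$session == ses & z$condition == cond, ]
      short <- test_retest(sel(zscores, "baseline", "rest"),
                           sel(zscores, "baseline", "task"))
      long <- if ("followup" %in% unique(zscores$session))
        test_retest(sel(zscores, "baseline", "rest"),
                    sel(zscores, "followup", "rest")) else NULL
      out <- merge(stats::setNames(short, c("region_id", "n",
                                            "pearson_r_short",
                                            "mean_diff_short")),
                   if (!is.null(long))
                     stats::setNames(long, c("region_id", "n_long",
                                             "pearson_r_long", "mean_diff"))
                   else data.frame(region_id = short$region_id,
                                   n_long = NA, pearson_r_long = NA,
                                   mean_diff = NA),
                   by = "region_id", all = TRUE)
      out$correction <- if (on("screen")) "random_forest" else "uncorrected"
      out
    })
    write_tsv_table(rel, file.path(outdir, "reliability.tsv"))
    res$reliability <- rel

    if (on("screen") && !is.null(density_raw)) {
      cmp <- pipeline_stage("reliability", outdir, function() {
        atlas_raw <- build_atlas(density_raw)
        z_raw <- to_zscores(density_raw, atlas_raw)
        sel <- function(z, ses) z[z$session == ses & z$condition == "rest", ]
        long_scr <- test_retest(sel(zscores, "baseline"),
                                sel(zscores, "followup"))
        long_raw <- test_retest(sel(z_raw, "baseline"),
                                sel(z_raw, "followup"))
        compare_methods(long_scr$pearson_r, long_raw$pearson_r)
      })
      jsonlite::write_json(cmp, file.path(outdir, "method_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      res$method_comparison <- cmp
    }
  }

  if (on("classify") && !is.null(zscores) &&
      length(config$cohort$symptom_specs)) {
    cls <- pipeline_stage("classify", outdir, function() {
      zr <- zscores[zscores$condition == "rest", ]
      keep_regions <- model$regions$region_id[
        model$regions$tissue %in% c("cortex", "white_rim")]
      zr <- zr[zr$region_id %in% keep_regions, ]
      zm <- zscore_matrix(zr)
      subj_of_row <- sub("/.*", "", rownames(zm))
      out <- list()
      for (spec in config$cohort$symptom_specs) {
        lab <- res$subjects[[paste0("label_", spec$name)]][
          match(subj_of_row, res$subjects$subject_id)]
        rep_ <- jackknife_evaluate(zm, lab, protocol = config$jackknife,
                                   p_enter = config$p_enter,
                                   p_remove = config$p_remove)
        model_full <- stepwise_train(zm, lab, config$p_enter,
                                     config$p_remove)
        out[[spec$name]] <- list(report = rep_, model = model_full)
        jsonlite::write_json(
          list(symptom = spec$name, selected = model_full$selected,
               weights = as.list(model_full$weights),
               signs = as.list(model_full$signs)),
          file.path(outdir, paste0("classifier_", spec$name, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
      tab <- do.call(rbind, lapply(names(out), function(nm) {
        r <- out[[nm]]$report
        data.frame(symptom = nm,
                   neg_neg = r$counts[["neg_neg"]],
                   neg_pos = r$counts[["neg_pos"]],
                   pos_neg = r$counts[["pos_neg"]],
                   pos_pos = r$counts[["pos_pos"]],
                   pct_neg = r$pct_neg, pct_pos = r$pct_pos,
                   p_neg = r$p_neg_chisq, p_pos = r$p_pos_chisq,
                   right = r$right, wrong = r$wrong,
                   p_combined = r$p_combined_chisq)
      }))
      write_tsv_table(tab, file.path(outdir, "classification.tsv"))
      out
    })
    res$classification <- cls
  }

  if (on("diffpairs") && !is.null(density)) {
    dp <- pipeline_stage("diffpairs", outdir, function() {
      cnt <- count_events(
        analysis_events[analysis_events$session == "baseline" &
                          analysis_events$condition == "rest", ],
        model$regions)
      differential_pairs(cnt, model$regions,
                         screen_report = if (on("screen")) screened$report,
                         threshold = config$sig_threshold)
    })
    write_tsv_table(dp, file.path(outdir, "diffpairs.tsv"))
    tl <- tally_pairs(dp)
    jsonlite::write_json(tl, file.path(outdir, "diffpairs_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    res$diffpairs <- dp
    res$diffpairs_tally <- tl
  }

  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass_deep(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$cohort$seed, stages = config$stages,
                   files = sort(list.files(outdir)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
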