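#' Build a pipeline run configuration
#'
#' Nested key-value configuration for the end-to-end run
#' (simulate, preprocess, measure, decode, clusterstat, quality). Defaults
#' give a small demonstration cohort (12 participants, 20 decoding
#' iterations, 200 permutations, 500 bootstrap replicates) that completes
#' in minutes; scale the fields up for full-size runs. Unknown keys are
#' rejected before any stage runs, and a configuration round-trips through
#' YAML unchanged.
#'
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @param ... Named overrides of nested sections, e.g.
#'   `cohort = list(n_participants = 20)`.
#' @return A `run_config` (nested named list).
#' @examples
#' cfg <- run_config(seed = 7, decoding = list(n_iterations = 10))
#' @export
run_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = as.integer(seed),
    cohort = list(n_participants = 12L, n_trials = 50L, p3b_effect_uV = -0.7,
                  noise_sd_uV = list(standing = 6, sitting = 6),
                  artifact_rate = list(standing = 919 / 6300, sitting = 215 / 6300),
                  p3_gain_sd = 0.35, lapse_rate = 0.1),
    preprocessing = list(low_hz = 0.1, high_hz = 30, threshold_uV = 100,
                         window_ms = c(-200, 800), baseline_ms = c(-200, 0)),
    measures = list(window_ms = c(250, 550), fraction = 0.5),
    decoding = list(mode = "frequent_only", n_folds = 3L, n_iterations = 20L,
                    cost = 1),
    cluster = list(n_permutations = 200L, alpha = 0.05, span = 5L),
    quality = list(n_bootstrap = 500L)
  )
  overrides <- list(...)
  cfg <- .merge_config(defaults, overrides, path = "")
  structure(cfg, class = "run_config")
}

.merge_config <- function(base, over, path) {
  bad <- setdiff(names(over), names(base))
  if (length(bad)) {
    stop("unknown configuration key", if (length(bad) > 1) "s", ": ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  }
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]], paste0(path, ".", nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); validated `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = raw$seed), raw[setdiff(names(raw), "seed")]))
}

# table writer that stamps the producing config's checksum into a header line
.write_stage_table <- function(df, path, config_md5) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_md5=%s", config_md5), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  )
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> measure -> decode -> clusterstat ->
#' quality under one configuration, writing every stage artifact beneath
#' `output_dir` and returning a manifest with a content checksum per
#' artifact. Rerunning with the same configuration reproduces identical
#' checksums for all deterministic stages. Any stage failure aborts with
#' the stage name.
#'
#' @param config A [run_config()].
#' @param output_dir Output root (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return A `run_manifest` data frame: stage, artifact, path, md5.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg_path <- file.path(output_dir, "config.yaml")
  write_run_config(config, cfg_path)
  cfg_md5 <- unname(tools::md5sum(cfg_path))
  artifacts <- list()
  add <- function(stage_name, label, path) {
    artifacts[[length(artifacts) + 1]] <<- data.frame(
      stage = stage_name, artifact = label, path = path,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  add("config", "config", cfg_path)

  # -- simulate ---------------------------------------------------------
  spec <- stage("simulate", {
    co <- config$cohort
    cohort_spec(n_participants = co$n_participants, seed = config$seed,
                noise_sd_uV = unlist(co$noise_sd_uV),
                artifact_rate = unlist(co$artifact_rate),
                p3b_effect_uV = co$p3b_effect_uV, p3_gain_sd = co$p3_gain_sd,
                lapse_rate = co$lapse_rate, n_trials = co$n_trials)
  })
  raw_dir <- file.path(output_dir, "raw")
  manifest <- stage("simulate", generate_cohort(spec, raw_dir))
  add("simulate", "cohort_manifest", file.path(raw_dir, "manifest.tsv"))
  log("simulate: %d participants x 2 conditions, %d trials each",
      spec$n_participants, spec$n_trials)

  # -- preprocess -------------------------------------------------------
  pp <- config$preprocessing
  epoch_sets <- stage("preprocess", {
    out <- list()
    for (i in seq_len(nrow(manifest))) {
      rec <- read_recording(file.path(raw_dir, manifest$edf[i]))
      res <- preprocess_recording(rec, pp$low_hz, pp$high_hz, pp$window_ms,
                                  pp$baseline_ms, pp$threshold_uV,
                                  participant = manifest$participant[i])
      out[[paste(manifest$participant[i], manifest$condition[i], sep = "_")]] <-
        res$epochs
    }
    out
  })
  all_cond <- unlist(lapply(epoch_sets, function(e) e$labels$condition))
  all_rej <- unlist(lapply(epoch_sets, function(e) e$rejected))
  report <- rejection_summary(all_cond, all_rej)
  rep_path <- file.path(output_dir, "rejection_report.tsv")
  .write_stage_table(report, rep_path, cfg_md5)
  add("preprocess", "rejection_report", rep_path)
  epochs_path <- file.path(output_dir, "epochs.rds")
  saveRDS(epoch_sets, epochs_path)
  add("preprocess", "epochs", epochs_path)
  log("preprocess: %d epochs, %d rejected (%s)",
      sum(report$n_total), sum(report$n_rejected),
      paste(sprintf("%s %.2f%%", report$condition, report$pct_rejected),
            collapse = ", "))

  # -- measure ----------------------------------------------------------
  meas <- stage("measure", {
    win <- config$measures$window_ms
    fr <- config$measures$fraction
    rows <- list()
    for (p in unique(manifest$participant)) {
      for (cond in POSTURE_CONDITIONS) {
        ep <- epoch_sets[[paste(p, cond, sep = "_")]]
        freq <- average_erp(ep, "frequent", cond)
        rare <- average_erp(ep, "rare", cond)
        nov <- average_erp(ep, "novelty", cond)
        if (!is.null(freq)) rows[[length(rows) + 1]] <- measure_erp(freq, "Pz", win, fr)
        if (!is.null(rare)) rows[[length(rows) + 1]] <- measure_erp(rare, "Pz", win, fr)
        if (!is.null(rare) && !is.null(freq)) {
          rows[[length(rows) + 1]] <- measure_erp(difference_wave(rare, freq),
                                                  "Pz", win, fr)
        }
        if (!is.null(nov)) rows[[length(rows) + 1]] <- measure_erp(nov, "Fz", win, fr)
      }
    }
    do.call(rbind, rows)
  })
  meas_path <- file.path(output_dir, "measures.tsv")
  .write_stage_table(meas, meas_path, cfg_md5)
  add("measure", "measures", meas_path)
  log("measure: %d cells", nrow(meas))

  # -- decode -----------------------------------------------------------
  dec <- config$decoding
  dspec <- decoding_spec(dec$mode, dec$n_folds, dec$n_iterations,
                         seed = config$seed, cost = dec$cost)
  results <- stage("decode", {
    counts <- do.call(rbind, lapply(unique(manifest$participant), function(p) {
      data.frame(participant = p, condition = POSTURE_CONDITIONS,
                 n_clean = c(
                   count_clean_epochs(epoch_sets[[paste(p, "standing", sep = "_")]], dspec$mode),
                   count_clean_epochs(epoch_sets[[paste(p, "sitting", sep = "_")]], dspec$mode)),
                 stringsAsFactors = FALSE)
    }))
    selection <- select_datasets(counts, dspec)
    log("decode: %d of %d participants included (%.2f%%)",
        selection$summary$n_included, selection$summary$n_total,
        selection$summary$pct_included)
    lapply(selection$included, function(p) {
      run_decoding(epoch_sets[[paste(p, "standing", sep = "_")]],
                   epoch_sets[[paste(p, "sitting", sep = "_")]],
                   dspec, participant = p)
    })
  })
  if (length(results) == 0) stop("pipeline stage 'decode' failed: no participant passed selection")
  acc_tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(participant = r$participant, time_ms = r$times_ms,
               accuracy = r$accuracy, stringsAsFactors = FALSE)
  }))
  acc_path <- file.path(output_dir, "decoding_accuracy.tsv")
  .write_stage_table(acc_tab, acc_path, cfg_md5)
  add("decode", "accuracy", acc_path)
  pred_path <- file.path(output_dir, "predictions.rds")
  saveRDS(results, pred_path)
  add("decode", "predictions", pred_path)

  # -- clusterstat ------------------------------------------------------
  cl <- config$cluster
  ct <- stage("clusterstat",
              cluster_test(results, cl$n_permutations, cl$alpha,
                           seed = derive_seed(config$seed, "perm"),
                           span = cl$span))
  cl_path <- file.path(output_dir, "clusters.tsv")
  .write_stage_table(ct$clusters, cl_path, cfg_md5)
  add("clusterstat", "clusters", cl_path)
  null_path <- file.path(output_dir, "null_distribution.txt")
  writeLines(format(ct$null, digits = 10), null_path)
  add("clusterstat", "null_distribution", null_path)
  log("clusterstat: %d clusters, %d significant",
      nrow(ct$clusters), sum(ct$clusters$significant))

  # -- quality ----------------------------------------------------------
  qual <- stage("quality", {
    win <- config$measures$window_ms
    rows <- list()
    for (p in unique(manifest$participant)) {
      for (cond in POSTURE_CONDITIONS) {
        ep <- epoch_sets[[paste(p, cond, sep = "_")]]
        for (cell in list(c("frequent", "Pz"), c("rare", "Pz"), c("novelty", "Fz"))) {
          amps <- single_trial_amplitudes(ep, cell[2], win, class = cell[1])
          rows[[length(rows) + 1]] <- data.frame(
            participant = p, condition = cond, class = cell[1],
            channel = cell[2], metric = "asme_uV", value = asme(amps),
            n_trials = length(amps), n_bootstrap = NA_integer_,
            n_dropped_replicates = NA_integer_, stringsAsFactors = FALSE)
        }
        b <- bsme(ep, "Pz", win, config$measures$fraction,
                  n_bootstrap = config$quality$n_bootstrap,
                  seed = derive_seed(config$seed, p, cond, "bsme"))
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, condition = cond, class = "merged",
          channel = "Pz", metric = "bsme_ms", value = b$value,
          n_trials = b$n_trials, n_bootstrap = b$n_bootstrap,
          n_dropped_replicates = b$n_dropped, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  qual_path <- file.path(output_dir, "quality.tsv")
  .write_stage_table(qual, qual_path, cfg_md5)
  add("quality", "quality", qual_path)
  log("quality: %d rows", nrow(qual))

  out <- do.call(rbind, artifacts)
  class(out) <- c("run_manifest", class(out))
  out
}
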