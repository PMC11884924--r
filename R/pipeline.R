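#' Default run configuration
#'
#' @param n_subjects,n_improved cohort size and responder count.
#' @param frequencies session-day stimulation frequencies, Hz.
#' @param n_blocks blocks per day.
#' @param seed master seed; every random operation derives from it.
#' @param contrast feature contrast for the prognosis stage.
#' @param window_duration phase-window length, seconds.
#' @param top_k features kept in the reduced classifier.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(n_subjects = 8, n_improved = 3,
                       frequencies = c(25, 50, 100), n_blocks = 4,
                       seed = 1, contrast = "post_minus_pre",
                       window_duration = 180, top_k = 3) {
  cfg <- list(n_subjects = n_subjects, n_improved = n_improved,
              frequencies = frequencies, n_blocks = n_blocks,
              seed = seed, contrast = contrast,
              window_duration = window_duration, top_k = top_k)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  required <- c("n_subjects", "n_improved", "frequencies", "n_blocks",
                "seed", "contrast", "window_duration", "top_k")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config validation: missing fields ", paste(missing, collapse = ", "))
  if (cfg$n_subjects < 1) stop("config validation: n_subjects must be >= 1")
  if (cfg$n_improved > cfg$n_subjects)
    stop("config validation: n_improved exceeds n_subjects")
  if (!cfg$contrast %in% c("post_minus_pre", "on_minus_pre"))
    stop("config validation: unknown contrast ", cfg$contrast)
  if (cfg$window_duration < 60)
    stop("config validation: window_duration below 60 s")
  invisible(cfg)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path path to a `.json` (or `.yaml`/`.yml`, when the yaml package
#'   is available) config file; fields as in [run_config()], missing fields
#'   take the defaults.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package unavailable; use a JSON config")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_table_prov <- function(d, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hrvdbs %s config=%s",
                     as.character(utils::packageVersion("hrvdbs")),
                     config_hash(cfg)), con)
  utils::write.table(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full synthetic experiment
#'
#' One-command reproduction: simulates the cohort, writes per-subject RR
#' files, computes the tidy HRV index table, the phase and frequency
#' statistics, the per-subject feature matrix and the prognosis report. All
#' outputs are deterministic given the config seed, and every table carries
#' a provenance header (package version + config hash).
#'
#' @param config a `run_config` (or path readable by [read_config()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`cohort`, `indices`,
#'   `phase_stats`, `freq_stats`, `features`, `prognosis`, `out_dir`).
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("hrvdbs_run_")) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  logf("run_all: seed %d, %d subjects, config %s",
       config$seed, config$n_subjects, config_hash(config))

  spec <- cohort_spec(n_subjects = config$n_subjects,
                      n_improved = config$n_improved,
                      frequencies = config$frequencies,
                      n_blocks = config$n_blocks,
                      seed = config$seed)
  cohort <- simulate_cohort(spec)
  rr_dir <- file.path(out_dir, "rr")
  dir.create(rr_dir, showWarnings = FALSE)
  for (subj in cohort$subjects)
    for (d in seq_along(subj$days))
      write_rr(subj$days[[d]]$rr,
               file.path(rr_dir, sprintf("%s_day%d.csv", subj$id, d)),
               header = sprintf("subject=%s day=%d frequency=%g",
                                subj$id, d, subj$days[[d]]$frequency))
  logf("cohort simulated: %d subjects x %d days",
       length(cohort$subjects), length(config$frequencies))

  indices <- phase_indices(cohort, duration = config$window_duration)
  write_table_prov(indices, file.path(out_dir, "hrv_indices.csv"), config)
  logf("index table: %d rows", nrow(indices))

  phase_stats <- tryCatch(phase_contrasts(indices), error = function(e) {
    logf("phase contrasts failed: %s", conditionMessage(e)); NULL
  })
  if (!is.null(phase_stats))
    write_table_prov(phase_stats, file.path(out_dir, "phase_stats.csv"), config)
  freq_stats <- tryCatch(frequency_contrasts(indices, config$contrast),
                         error = function(e) {
    logf("frequency contrasts failed: %s", conditionMessage(e)); NULL
  })
  if (!is.null(freq_stats))
    write_table_prov(freq_stats, file.path(out_dir, "freq_stats.csv"), config)

  features <- delta_features(indices, contrast = config$contrast)
  write_table_prov(features, file.path(out_dir, "features.csv"), config)
  labels <- label_outcomes(cohort$labels)
  write_table_prov(labels, file.path(out_dir, "labels.csv"), config)

  prog <- NULL
  keep <- match(features$subject, labels$subject)
  X <- as.matrix(features[hrv_index_names()])
  y <- labels$improved[keep]
  prog <- tryCatch(
    compare_feature_sets(X, y, top_k = config$top_k, seed = config$seed),
    error = function(e) {
      logf("prognosis stage failed: %s", conditionMessage(e)); NULL
    })
  if (!is.null(prog)) {
    jsonlite::write_json(
      list(ranking = prog$ranking, selected = prog$selected,
           auc_all = list(mean = prog$all$mean_auc, sd = prog$all$sd_auc,
                          per_fold = prog$all$fold_auc),
           auc_top = list(mean = prog$top$mean_auc, sd = prog$top$sd_auc,
                          per_fold = prog$top$fold_auc),
           seed = config$seed),
      file.path(out_dir, "prognosis.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    logf("prognosis: top-%d = %s; AUC all %.3f, top %.3f", config$top_k,
         paste(prog$selected, collapse = ","),
         prog$all$mean_auc, prog$top$mean_auc)
  }
  logf("run_all: done -> %s", out_dir)
  invisible(list(cohort = cohort, indices = indices,
                 phase_stats = phase_stats, freq_stats = freq_stats,
                 features = features, prognosis = prog, out_dir = out_dir))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `ecg2rr`, `hrv`, `epoch`, `analyze`, `prognose`,
#' `all`. Invoked by the `inst/cli/hrvdbs` script; callable directly with a
#' character vector of arguments. Exit status: 0 on success, 2 on validation
#' errors, 3 on partial failure inside `run_all`.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
hrvdbs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: hrvdbs <simulate|ecg2rr|hrv|epoch|analyze|prognose|all> [--config FILE] [--out DIR] [--seed N] [--in FILE]"
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opt <- list(config = NULL, out = "hrvdbs_out", seed = NULL, input = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- args[i]
    if (!key %in% c("--config", "--out", "--seed", "--in")) {
      message("unknown option: ", key); return(invisible(2L))
    }
    val <- args[i + 1L]
    opt[[c("--config" = "config", "--out" = "out", "--seed" = "seed",
           "--in" = "input")[key]]] <- val
    i <- i + 2L
  }
  cfg <- tryCatch({
    base <- if (is.null(opt$config)) run_config() else read_config(opt$config)
    if (!is.null(opt$seed)) base$seed <- as.integer(opt$seed)
    validate_config(base)
    base
  }, error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(cfg)) return(invisible(2L))

  status <- tryCatch({
    switch(cmd,
      simulate = {
        spec <- cohort_spec(n_subjects = cfg$n_subjects,
                            n_improved = cfg$n_improved,
                            frequencies = cfg$frequencies,
                            n_blocks = cfg$n_blocks, seed = cfg$seed)
        cohort <- simulate_cohort(spec)
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        for (subj in cohort$subjects)
          for (d in seq_along(subj$days))
            write_rr(subj$days[[d]]$rr,
                     file.path(opt$out, sprintf("%s_day%d.csv", subj$id, d)))
        utils::write.csv(label_outcomes(cohort$labels),
                         file.path(opt$out, "labels.csv"), row.names = FALSE)
        0L
      },
      ecg2rr = {
        if (is.null(opt$input)) stop("ecg2rr needs --in <ecg file>")
        ecg <- read_ecg(opt$input)
        rr <- clean_rr(peaks_to_rr(detect_r_peaks(powerline_notch(ecg))))
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        write_rr(rr, file.path(opt$out, paste0(basename(opt$input), ".rr.csv")))
        0L
      },
      hrv = {
        if (is.null(opt$input)) stop("hrv needs --in <rr file>")
        rr <- read_rr(opt$input)
        idx <- hrv_indices(rr)
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(idx, file.path(opt$out, "hrv_indices.csv"),
                         row.names = FALSE)
        0L
      },
      epoch = , analyze = , prognose = , all = {
        res <- run_all(cfg, out_dir = opt$out)
        if (is.null(res$prognosis) || is.null(res$phase_stats)) 3L else 0L
      },
      { message("unknown subcommand: ", cmd); message(usage); 2L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 2L })
  invisible(status)
}
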