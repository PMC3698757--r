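# Pipeline orchestration and the file-based command entry points
# (simulate / analyze / stats) used by the command-line wrapper.

#' Run configuration
#'
#' One configuration object holding every tunable of the pipeline, grouped
#' per stage; round-trips losslessly through YAML. All outputs written by the
#' command entry points embed the configuration hash, package version and
#' seed for provenance.
#'
#' @param preset Strain preset name (for simulation).
#' @param n_animals,duration_hours,sample_rate,seed Simulation settings.
#' @param dark_onset,dark_hours,start_clock Light schedule.
#' @param min_hr,max_hr Beat-detector heart-rate limits, beats/min.
#' @param resample_rate,segment_s,overlap,window_min Spectral settings.
#' @param min_len,min_dsbp,min_dpi,delay,min_r Sequence-method criteria.
#' @param alpha Statistical significance level.
#' @param treatment `TRUE` to apply the default [drug_schedule()].
#' @return A `run_config` list.
#' @export
run_config <- function(preset = "WKY", n_animals = 5, duration_hours = 24,
                       sample_rate = 250, seed = 42,
                       dark_onset = 20, dark_hours = 12,
                       start_clock = dark_onset,
                       min_hr = 200, max_hr = 500,
                       resample_rate = 10, segment_s = 60, overlap = 0.5,
                       window_min = 5,
                       min_len = 3, min_dsbp = 0.5, min_dpi = 1, delay = 0,
                       min_r = 0.8, alpha = 0.05, treatment = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[intersect(names(raw),
                                           names(formals(run_config)))])
  cfg
}

# FNV-style rolling hash of the YAML rendering of a config, for provenance
# stamping; reduced modulo a 26-bit prime so every step stays exact in
# R's integer/double arithmetic
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(cfg)))
  h <- 2166136261 %% 67108859
  for (b in bytes)
    h <- (bitwXor(as.integer(h), as.integer(b)) * 16777619) %% 67108859
  sprintf("%08x", as.integer(h))
}

provenance <- function(cfg) {
  list(config_hash = config_hash(cfg),
       package = as.character(utils::packageVersion("telemetrybp")),
       seed = cfg$seed)
}

cfg_schedule <- function(cfg) light_schedule(cfg$dark_onset, cfg$dark_hours)
cfg_simconfig <- function(cfg) {
  sim_config(sample_rate = cfg$sample_rate,
             duration_hours = cfg$duration_hours,
             schedule = cfg_schedule(cfg), start_clock = cfg$start_clock,
             seed = cfg$seed, n_animals = cfg$n_animals)
}
cfg_criteria <- function(cfg) {
  sequence_criteria(cfg$min_len, cfg$min_dsbp, cfg$min_dpi, cfg$delay,
                    cfg$min_r)
}

#' Analyze one recording end-to-end
#'
#' beats -> telemetry bins -> hourly LF / sBRG -> period summaries.
#'
#' @param waveform A [bp_waveform()], or a [beat_series()] to skip detection.
#' @param cfg A [run_config()].
#' @param animal Animal id attached to summaries.
#' @return List: `beats`, `bins`, `lf` (hourly band powers), `sbrg` (hourly
#'   gains), `summaries` ([period_summary()] rows), `counts` (per-stage
#'   bookkeeping).
#' @export
analyze_waveform <- function(waveform, cfg = run_config(), animal = 1L) {
  beats <- if (inherits(waveform, "beat_series")) waveform
           else detect_beats(waveform, cfg$min_hr, cfg$max_hr)
  bins <- bin_telemetry(beats)
  lf <- try(lf_sbp_series(beats, window_min = cfg$window_min,
                          rate = cfg$resample_rate,
                          segment_s = cfg$segment_s, overlap = cfg$overlap),
            silent = TRUE)
  sb <- try(sbrg_series(beats, window_min = cfg$window_min,
                        criteria = cfg_criteria(cfg)), silent = TRUE)
  if (inherits(lf, "try-error")) lf <- NULL
  if (inherits(sb, "try-error")) sb <- NULL
  summ <- period_summary(bins, animal = animal)
  list(beats = beats, bins = bins, lf = lf, sbrg = sb, summaries = summ,
       counts = list(beats = nrow(beats),
                     artifacts = attr(beats, "n_artifacts"),
                     invalid_bins = sum(!bins$valid),
                     invalid_lf = if (is.null(lf)) NA else sum(!lf$valid),
                     invalid_sbrg = if (is.null(sb)) NA else sum(!sb$valid)))
}

#' Analyze a simulated cohort in memory
#'
#' Runs [analyze_waveform()] per animal (on the rendered waveform when
#' present, else on the beat series) and pools the period summaries.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param cfg A [run_config()].
#' @return List: `per_animal` (analysis lists), `summaries` (pooled),
#'   `dipper` (cohort-level [classify_dipper()] call).
#' @export
analyze_cohort <- function(cohort, cfg = run_config()) {
  per <- lapply(cohort$animals, function(a) {
    src <- if (!is.null(a$waveform)) a$waveform else a$beats
    analyze_waveform(src, cfg, animal = a$animal)
  })
  summ <- do.call(rbind, lapply(per, `[[`, "summaries"))
  dip <- try(classify_dipper(summ, alpha = cfg$alpha), silent = TRUE)
  if (inherits(dip, "try-error")) dip <- NULL
  list(per_animal = per, summaries = summ, dipper = dip)
}

#' Simulate a cohort to files
#'
#' Writes one waveform CSV (+ YAML sidecar) per animal and a cohort
#' ground-truth YAML. Deterministic under the config seed.
#'
#' @param cfg A [run_config()] (or path to its YAML).
#' @param out_dir Output directory (created).
#' @return Invisibly, the vector of waveform CSV paths.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (cfg$n_animals < 1) stop("config error: need at least one animal")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("unwritable output path: ", out_dir)
  schedule <- if (isTRUE(cfg$treatment)) drug_schedule() else NULL
  cohort <- simulate_cohort(make_strain_preset(cfg$preset), cfg_simconfig(cfg),
                            schedule = schedule)
  prov <- provenance(cfg)
  paths <- vapply(cohort$animals, function(a) {
    p <- file.path(out_dir, sprintf("animal_%02d.csv", a$animal))
    write_waveform(a$waveform, p, meta = c(prov, list(animal = a$animal)))
    p
  }, character(1))
  yaml::write_yaml(c(prov, list(truth = lapply(cohort$truth, unclass))),
                   file.path(out_dir, "ground_truth.yaml"))
  invisible(paths)
}

#' Analyze waveform files to summary tables
#'
#' Stage order per animal: beat detection, telemetry bins, hourly LF and
#' sBRG, period summaries; a failure in one animal is isolated (logged,
#' other animals still analyzed). Writes `bins_*.csv`, `lf_*.csv`,
#' `sbrg_*.csv`, pooled `period_summaries.csv`, `dipper.csv` and a
#' `run_info.yaml` with provenance and per-stage counts.
#'
#' @param cfg A [run_config()] or YAML path.
#' @param in_dir Directory of waveform CSVs written by [cmd_simulate()].
#' @param out_dir Output directory.
#' @return Invisibly, the pooled period-summary data frame.
#' @export
cmd_analyze <- function(cfg, in_dir, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  files <- sort(list.files(in_dir, pattern = "^animal_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("data error: no waveform CSVs in ", in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list(); summaries <- list()
  for (i in seq_along(files)) {
    res <- try({
      wf <- read_waveform(files[i])
      analyze_waveform(wf, cfg, animal = i)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("animal ", i, " failed: ", attr(res, "condition")$message)
      counts[[i]] <- list(error = attr(res, "condition")$message)
      next
    }
    stem <- sprintf("%02d", i)
    data.table::fwrite(res$bins, file.path(out_dir, paste0("bins_", stem, ".csv")))
    if (!is.null(res$lf))
      data.table::fwrite(res$lf, file.path(out_dir, paste0("lf_", stem, ".csv")))
    if (!is.null(res$sbrg))
      data.table::fwrite(res$sbrg, file.path(out_dir, paste0("sbrg_", stem, ".csv")))
    summaries[[i]] <- res$summaries
    counts[[i]] <- res$counts
  }
  summ <- do.call(rbind, summaries)
  if (is.null(summ)) stop("data error: no animal could be analyzed")
  data.table::fwrite(summ, file.path(out_dir, "period_summaries.csv"))
  dip <- try(classify_dipper(summ, alpha = cfg$alpha), silent = TRUE)
  if (!inherits(dip, "try-error"))
    data.table::fwrite(data.frame(classification = dip$classification,
                                  dark_mean = dip$dark_mean,
                                  light_mean = dip$light_mean,
                                  dip_percent = dip$dip_percent,
                                  p_value = dip$p_value, test = dip$test),
                       file.path(out_dir, "dipper.csv"))
  yaml::write_yaml(c(provenance(cfg), list(per_animal_counts = counts)),
                   file.path(out_dir, "run_info.yaml"))
  invisible(summ)
}

#' Run the statistical decision tree on a long-format CSV
#'
#' @param cfg A [run_config()] or YAML path.
#' @param table_csv Long-format CSV with a `value` column and factor columns.
#' @param out_dir Output directory; writes `test_results.csv` (F / H table),
#'   `pairwise.csv` and a human-readable `decision_trace.txt`.
#' @param factors Factor columns; default: all non-`value`, non-`animal`
#'   columns.
#' @return Invisibly, the [decision_tree()] result.
#' @export
cmd_stats <- function(cfg, table_csv, out_dir, factors = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  df <- data.table::fread(table_csv, data.table = FALSE)
  if (!"value" %in% names(df))
    stop("schema error: table needs a 'value' column")
  if (is.null(factors))
    factors <- setdiff(names(df), c("value", "animal"))
  if (!length(factors) || !all(factors %in% names(df)))
    stop("schema error: missing factor columns")
  res <- decision_tree(df, "value", factors, alpha = cfg$alpha)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  main <- data.frame(term = names(res$test$statistic),
                     statistic = unname(res$test$statistic),
                     p_value = res$test$p_value)
  data.table::fwrite(main, file.path(out_dir, "test_results.csv"))
  pw <- if (!is.null(res$posthoc)) res$posthoc$pairwise else res$test$pairwise
  if (!is.null(pw))
    data.table::fwrite(pw, file.path(out_dir, "pairwise.csv"))
  con <- file(file.path(out_dir, "decision_trace.txt"), "w")
  on.exit(close(con))
  writeLines(c(sprintf("route: %s", res$trace$route),
               sprintf("reason: %s", res$trace$reason),
               sprintf("shapiro_p: %s",
                       paste(sprintf("%s=%.4g", names(res$trace$shapiro_p),
                                     res$trace$shapiro_p), collapse = ", ")),
               sprintf("bartlett_p: %.4g", res$trace$bartlett_p),
               sprintf("test: %s", res$test$method),
               sprintf("config_hash: %s", config_hash(cfg))), con)
  invisible(res)
}
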