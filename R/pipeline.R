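## End-to-end orchestration: synthesize (or read) recordings, preprocess,
## compute spectral frames, score sleep, stage, summarize, and build tables.

#' Pipeline run configuration
#'
#' Every analysis constant appears once here with its default: the 0.5 g
#' body-movement threshold, the 0.05/0.15/0.40 Hz band edges, 60 s windows
#' and epochs, 4 Hz tachogram grid, 125 Hz accelerometry, and alpha = 0.05
#' with k = 3 day contrasts in the Bonferroni recheck.
#'
#' @param mode `"synthetic"` (generate a cohort from `design`) or `"csv"`
#'   (read per-night `*_rri.csv` / `*_accel.csv` pairs from `input_dir`).
#' @param design a [cohort_design()] (synthetic mode).
#' @param input_dir directory of recordings (csv mode).
#' @param out_dir output directory (created if needed); NULL writes nothing.
#' @param bands a [band_definition()].
#' @param grid_rate tachogram grid rate, Hz.
#' @param window_s spectral window / epoch length, s.
#' @param movement_threshold_g movement artifact threshold, g.
#' @param ectopic_min_ms,ectopic_max_ms,ectopic_max_rel_jump ectopic rules.
#' @param theta_s_scale,theta_d staging thresholds (see [classify_stages()]).
#' @param run_len onset persistence rule, epochs.
#' @param t_variant,bonferroni_cap statistics options (see [build_tables()]).
#' @param seed master seed for synthetic mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"), design = NULL,
                       input_dir = NULL, out_dir = NULL,
                       bands = band_definition(), grid_rate = 4,
                       window_s = 60, movement_threshold_g = 0.5,
                       ectopic_min_ms = 300, ectopic_max_ms = 2000,
                       ectopic_max_rel_jump = 0.2, theta_s_scale = 4,
                       theta_d = 0.60, run_len = 10,
                       t_variant = "welch", bonferroni_cap = FALSE,
                       seed = 20220501) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(design))
    design <- cohort_design(master_seed = seed)
  if (mode == "csv" && (is.null(input_dir) || !dir.exists(input_dir)))
    stop("csv mode requires an existing input_dir", call. = FALSE)
  structure(list(mode = mode, design = design, input_dir = input_dir,
                 out_dir = out_dir, bands = bands, grid_rate = grid_rate,
                 window_s = window_s,
                 movement_threshold_g = movement_threshold_g,
                 ectopic_min_ms = ectopic_min_ms,
                 ectopic_max_ms = ectopic_max_ms,
                 ectopic_max_rel_jump = ectopic_max_rel_jump,
                 theta_s_scale = theta_s_scale, theta_d = theta_d,
                 run_len = run_len, t_variant = t_variant,
                 bonferroni_cap = bonferroni_cap, seed = as.integer(seed)),
            class = "run_config")
}

#' Process one night (recording pair) through the analysis chain
#'
#' Movement gating, ectopic filtering, tachogram resampling, per-minute
#' spectral frames, actigraphic sleep scoring, autonomic staging, and the
#' night summary.
#'
#' @param rri an [rri_series()].
#' @param accel an [accel_series()].
#' @param config a [run_config()].
#' @return A list: `rri` (flagged), `tach`, `frames`, `sw`, `hypnogram`,
#'   `durations`, `summary`, `quality` (fractions of flagged intervals and
#'   invalid frames).
#' @export
process_night <- function(rri, accel, config = run_config()) {
  rri <- flag_movement_artifacts(rri, accel, config$movement_threshold_g)
  rri <- filter_ectopic(rri, config$ectopic_min_ms, config$ectopic_max_ms,
                        config$ectopic_max_rel_jump)
  tach <- resample_evenly(rri, grid_rate = config$grid_rate)
  frames <- frame_series(tach, bands = config$bands, window_s = config$window_s)
  sw <- score_sleep(accel, epoch_s = config$window_s, run_len = config$run_len)
  h <- classify_stages(frames, sw, theta_s_scale = config$theta_s_scale,
                       theta_d = config$theta_d)
  list(rri = rri, tach = tach, frames = frames, sw = sw, hypnogram = h,
       durations = stage_durations(h),
       summary = night_summary(frames, h),
       quality = c(frac_movement = mean(rri$movement_flag),
                   frac_ectopic = mean(rri$ectopic_flag),
                   frac_invalid_frames = mean(!frames$valid)))
}

night_summary_row <- function(group, subject, day, durations, summary) {
  data.frame(subject = subject, group = group, day = day,
             total_min = unname(durations["total"]),
             s_min = unname(durations["S"]),
             ps_shallow_min = unname(durations["PS_SHALLOW"]),
             ps_deep_min = unname(durations["PS_DEEP"]),
             lf = unname(summary$overall["lf_amp"]),
             hf = unname(summary$overall["hf_amp"]),
             lf_hf = unname(summary$overall["lf_hf"]))
}

read_csv_nights <- function(input_dir) {
  rri_files <- list.files(input_dir, "_rri\\.csv$", full.names = TRUE)
  if (!length(rri_files)) stop("no *_rri.csv files in input_dir", call. = FALSE)
  stems <- sub("_rri\\.csv$", "", rri_files)
  acc_files <- paste0(stems, "_accel.csv")
  missing <- !file.exists(acc_files)
  if (any(missing))
    stop("missing acceleration file(s) for night(s): ",
         paste(basename(stems[missing]), collapse = ", "), call. = FALSE)
  lapply(seq_along(stems), function(i) {
    nm <- basename(stems[i])
    parts <- strsplit(nm, "_")[[1]]   # expected <group>_s<subject>_d<day>
    list(group = parts[1],
         subject = as.integer(sub("^s", "", parts[2])),
         day = as.integer(sub("^d", "", parts[3])),
         rri = read_rri_csv(rri_files[i]),
         accel = read_accel_csv(acc_files[i]),
         stages = NULL)
  })
}

#' Run the full pipeline
#'
#' Synthesizes or reads a cohort of overnight recordings, processes every
#' night, and builds the group/day trial tables. With `out_dir` set, writes
#' per-night CSVs (cleaned RRI, frames, sleep/wake, hypnogram), the summary
#' and table CSVs, and a JSON run manifest (config, seed, package version).
#' Identical config + seed give identical outputs. A failing night aborts
#' with a message naming the stage and night; outputs written so far are
#' retained.
#'
#' @param config a [run_config()].
#' @return A list of class `run_report`: `summaries` (per-night data.frame),
#'   `tables` ([build_tables()] output), `nights` (per-night results),
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  nights_in <- if (config$mode == "synthetic") generate_cohort(config$design)$nights
               else read_csv_nights(config$input_dir)
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  rows <- list(); nights <- list()
  for (i in seq_along(nights_in)) {
    nt <- nights_in[[i]]
    id <- sprintf("%s_s%02d_d%d", nt$group, nt$subject, nt$day)
    res <- tryCatch(process_night(nt$rri, nt$accel, config),
                    error = function(e)
                      stop(sprintf("night %s failed in processing: %s",
                                   id, conditionMessage(e)), call. = FALSE))
    rows[[i]] <- night_summary_row(nt$group, nt$subject, nt$day,
                                   res$durations, res$summary)
    nights[[i]] <- c(list(id = id), res["quality"],
                     list(durations = res$durations, summary = res$summary))
    if (!is.null(out)) {
      write_rri_csv(res$rri, file.path(out, paste0(id, "_rri_clean.csv")))
      write_frames_csv(res$frames, file.path(out, paste0(id, "_frames.csv")))
      write_sleep_csv(res$sw, file.path(out, paste0(id, "_sleep.csv")))
      write_hypnogram_csv(res$hypnogram, file.path(out, paste0(id, "_hypnogram.csv")))
    }
  }
  summaries <- do.call(rbind, rows)
  tables <- build_tables(summaries, t_variant = config$t_variant,
                         bonferroni_cap = config$bonferroni_cap)
  manifest <- list(
    package = "somnohrv",
    version = as.character(packageVersion("somnohrv")),
    seed = config$seed,
    mode = config$mode,
    n_nights = length(nights),
    config = config_fingerprint(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(out)) {
    write.csv(summaries, file.path(out, "summaries.csv"), row.names = FALSE)
    write.csv(tables$group_table, file.path(out, "table1_groups.csv"),
              row.names = FALSE)
    write.csv(tables$between_table, file.path(out, "table1_tests.csv"),
              row.names = FALSE)
    write.csv(tables$stage_table, file.path(out, "table2_stages.csv"),
              row.names = FALSE)
    write.csv(tables$day_table, file.path(out, "table3_days.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(summaries = summaries, tables = tables, nights = nights,
                 manifest = manifest),
            class = "run_report")
}

## Deterministic fingerprint of the numeric/char config content (so manifests
## of identical runs compare equal without serializing closures).
config_fingerprint <- function(config) {
  flat <- unlist(config[c("mode", "grid_rate", "window_s",
                          "movement_threshold_g", "ectopic_min_ms",
                          "ectopic_max_ms", "ectopic_max_rel_jump",
                          "theta_s_scale", "theta_d", "run_len", "t_variant",
                          "bonferroni_cap", "seed")])
  bands <- unlist(config$bands)
  paste0("somnohrv:", paste(names(flat), flat, sep = "=", collapse = ";"),
         ";bands=", paste(bands, collapse = ","))
}
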