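# CSV schemas and the end-to-end pipeline driver.
#
# All files are plain CSV with a header row; writers optionally prepend
# `#`-prefixed metadata lines which every reader skips.

read_checked <- function(path, required, col_types) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  # restrict the column spec to columns present so optional ones don't warn
  hdr <- readr::read_lines(path, n_max = 50)
  hdr <- hdr[!startsWith(hdr, "#")][1]
  present <- strsplit(hdr, ",")[[1]]
  col_types$cols <- col_types$cols[intersect(names(col_types$cols), present)]
  df <- readr::read_csv(path, col_types = col_types, comment = "#",
                        progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing mandatory column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

write_with_meta <- function(df, path, meta = NULL) {
  if (!is.null(meta)) {
    con <- file(path, open = "w")
    writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
    close(con)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  tibble::tibble(file = path, rows = nrow(df))
}

#' Read and write raw-trace CSVs
#'
#' Schema: `time_s, x_g, y_g, z_g` (header required), accelerations in g.
#'
#' @param path CSV path.
#' @param patient_id,sampling_rate Attributes attached on read; the rate
#'   defaults to the inverse median sampling interval.
#' @return `read_trace_csv()`: a [raw_trace()]; `write_trace_csv()`: a
#'   one-row manifest tibble.
#' @export
read_trace_csv <- function(path, patient_id = NULL, sampling_rate = NULL) {
  df <- read_checked(path, c("time_s", "x_g", "y_g", "z_g"),
                     readr::cols(.default = readr::col_double()))
  if (is.null(sampling_rate)) {
    sampling_rate <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s))
                     else NA_real_
  }
  raw_trace(df$time_s, df$x_g, df$y_g, df$z_g,
            patient_id = patient_id %||%
              sub("\\.csv$", "", basename(path)),
            sampling_rate = sampling_rate)
}

#' @rdname read_trace_csv
#' @param trace Trace tibble.
#' @param meta Optional named list written as `# key: value` header lines.
#' @export
write_trace_csv <- function(trace, path, meta = NULL) {
  write_with_meta(trace[c("time_s", "x_g", "y_g", "z_g")], path, meta)
}

EVENT_COLUMNS <- c("patient_id", "event_id", "category", "start_s", "end_s",
                   "real_steps")

#' Read and write the event-protocol CSV
#'
#' Schema: `patient_id, event_id, category, start_s, end_s, real_steps`
#' plus one `steps_<code>` column per device-by-location (any set of codes;
#' unknown codes are preserved). Rows with a category outside 1--4 are
#' rejected with their line number.
#'
#' @param path CSV path.
#' @return `read_events_csv()`: flat event tibble (no epochs; see
#'   [attach_epochs()]); `write_events_csv()`: a one-row manifest tibble.
#' @export
read_events_csv <- function(path) {
  df <- read_checked(path, EVENT_COLUMNS, readr::cols(
    patient_id = readr::col_character(),
    event_id = readr::col_character(),
    category = readr::col_integer(),
    .default = readr::col_double()))
  bad <- which(!df$category %in% 1:4 | df$end_s <= df$start_s)
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s: invalid event row(s) at data line(s) %s (category outside 1-4 or end <= start)",
      basename(path), paste(bad, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname read_events_csv
#' @param events Flat event tibble.
#' @param meta Optional metadata header (named list).
#' @export
write_events_csv <- function(events, path, meta = NULL) {
  write_with_meta(dplyr::select(events, -dplyr::any_of("epochs")), path, meta)
}

#' Read and write the epoch CSV
#'
#' Schema: `patient_id, event_id, epoch_start_s, svm, wear` (plus any extra
#' columns); `event_id` may be empty for continuous monitoring data.
#'
#' @param path CSV path.
#' @return `read_epochs_csv()`: epoch tibble; `write_epochs_csv()`: one-row
#'   manifest tibble.
#' @export
read_epochs_csv <- function(path) {
  read_checked(path, c("epoch_start_s", "svm", "wear"), readr::cols(
    patient_id = readr::col_character(),
    event_id = readr::col_character(),
    wear = readr::col_logical(),
    partial = readr::col_logical(),
    n_samples = readr::col_integer(),
    .default = readr::col_double()))
}

#' @rdname read_epochs_csv
#' @param epochs Epoch tibble.
#' @param meta Optional metadata header (named list).
#' @export
write_epochs_csv <- function(epochs, path, meta = NULL) {
  write_with_meta(epochs, path, meta)
}

#' Nest an epoch table into an event table
#'
#' Joins per-event epoch rows (e.g. from [read_epochs_csv()]) onto the flat
#' event table as the `epochs` list-column expected by
#' [calibrate_threshold()] and [event_features()].
#'
#' @param events Flat event tibble.
#' @param epochs Epoch tibble with `event_id`.
#' @return The event tibble with an `epochs` list-column.
#' @export
attach_epochs <- function(events, epochs) {
  nested <- epochs |>
    dplyr::select(-dplyr::any_of("patient_id")) |>
    tidyr::nest(.by = "event_id", .key = "epochs")
  out <- dplyr::left_join(events, nested, by = "event_id")
  empty <- purrr::map_lgl(out$epochs, is.null)
  if (any(empty)) {
    stop(sprintf("no epochs for event(s): %s",
                 paste(out$event_id[empty], collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Read and write the per-patient timepoint CSV
#'
#' Schema: `patient_id, timepoint_label, day_index, barthel20, eq5d_index`
#' plus the activity summary columns where present. Barthel values outside
#' 0--20 or EQ-5D indices above 1 are rejected with their line numbers.
#'
#' @param path CSV path.
#' @return `read_timepoints_csv()`: timepoint tibble;
#'   `write_timepoints_csv()`: one-row manifest tibble.
#' @export
read_timepoints_csv <- function(path) {
  df <- read_checked(path, c("patient_id", "timepoint_label", "day_index",
                             "barthel20", "eq5d_index"), readr::cols(
    patient_id = readr::col_character(),
    timepoint_label = readr::col_character(),
    day_index = readr::col_integer(),
    barthel20 = readr::col_integer(),
    .default = readr::col_double()))
  bad <- which(df$barthel20 < 0 | df$barthel20 > 20 | df$eq5d_index > 1)
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid score(s) at data line(s) %s", basename(path),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname read_timepoints_csv
#' @param timepoints Timepoint tibble.
#' @param meta Optional metadata header (named list).
#' @export
write_timepoints_csv <- function(timepoints, path, meta = NULL) {
  write_with_meta(timepoints, path, meta)
}

#' Run configuration for the end-to-end pipeline
#'
#' Collects every constant the pipeline applies; defaults are the published
#' study values (band 0.5--20 Hz, 60-s epochs, 90th percentile, percent
#' boundaries 10/25/60, SVM boundaries 0.0047/0.0072/0.01, threshold 0.005 g
#' when not recalibrated).
#'
#' @param filter_low,filter_high Band edges in Hz.
#' @param epoch_length Epoch length in seconds.
#' @param svm_variant `"literal"` or `"euclidean"`.
#' @param percentile Calibration percentile.
#' @param threshold Fallback activity threshold (g) used when no category-1
#'   events are available to recalibrate.
#' @param pct_boundaries,svm_boundaries Category boundary triples.
#' @param window Period length in minutes for daily summaries.
#' @param wear_window,svm_floor Non-wear rule (see [detect_wear()]).
#' @param seed Seed for any stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(filter_low = 0.5, filter_high = 20, epoch_length = 60,
                       svm_variant = "literal", percentile = 90,
                       threshold = 0.005,
                       pct_boundaries = PCT_ACTIVE_BOUNDARIES,
                       svm_boundaries = MEAN_SVM_BOUNDARIES,
                       window = 15, wear_window = 60, svm_floor = 0.001,
                       seed = 1L) {
  svm_variant <- match.arg(svm_variant, c("literal", "euclidean"))
  stopifnot(percentile >= 0, percentile <= 100, threshold > 0, window >= 1)
  structure(list(filter_low = filter_low, filter_high = filter_high,
                 epoch_length = epoch_length, svm_variant = svm_variant,
                 percentile = percentile, threshold = threshold,
                 pct_boundaries = pct_boundaries,
                 svm_boundaries = svm_boundaries, window = window,
                 wear_window = wear_window, svm_floor = svm_floor,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_meta <- function(config, extra = NULL) {
  c(list(
    svm_variant = config$svm_variant,
    filter_band_hz = sprintf("%g-%g", config$filter_low,
                             config$filter_high),
    epoch_length_s = config$epoch_length,
    percentile = config$percentile,
    wear_rule = sprintf("run of >=%d epochs below %g g",
                        config$wear_window, config$svm_floor),
    window_min = config$window, seed = config$seed), extra)
}

#' Run a pipeline stage on a fixture directory
#'
#' Drives the whole analysis from the CSV fixtures, one named stage at a
#' time. `"simulate"` writes a synthetic cohort; `"epochs"` converts raw
#' traces to epoch CSVs; `"calibrate"` derives the activity threshold;
#' `"classify"` computes event features and the agreement reports on both
#' feature scales; `"validate-steps"` writes the device validation table;
#' `"longitudinal"` the recovery comparisons; `"report"` runs calibrate
#' through longitudinal. Every output carries a metadata header recording
#' the constants used. Deterministic given the config seed.
#'
#' @param command One of `"simulate"`, `"epochs"`, `"calibrate"`,
#'   `"classify"`, `"validate-steps"`, `"longitudinal"`, `"report"`.
#' @param input_dir Directory holding the input CSVs (fixture layout of
#'   [write_fixtures()]).
#' @param output_dir Directory for outputs (created if needed).
#' @param config A [run_config()].
#' @param gen_config A [generator_config()] (used by `"simulate"`).
#' @return Invisibly, a manifest tibble of files written.
#' @export
run_pipeline <- function(command, input_dir = NULL, output_dir,
                         config = run_config(),
                         gen_config = generator_config(seed = config$seed)) {
  command <- match.arg(command, c("simulate", "epochs", "calibrate",
                                  "classify", "validate-steps",
                                  "longitudinal", "report"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- config_meta(config)
  manifest <- list()
  emit <- function(df, name, extra = NULL) {
    m <- write_with_meta(df, file.path(output_dir, name),
                         config_meta(config, extra))
    manifest[[length(manifest) + 1L]] <<- m
  }

  if (command == "simulate") {
    cohort <- simulate_cohort(gen_config)
    man <- write_fixtures(cohort, output_dir)
    return(invisible(man))
  }
  if (command == "epochs") {
    files <- list.files(file.path(input_dir, "traces"), pattern = "\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no trace CSVs under traces/",
                                  call. = FALSE)
    ep <- purrr::map(files, function(f) {
      tr <- read_trace_csv(f)
      process_trace(tr, low = config$filter_low, high = config$filter_high,
                    variant = config$svm_variant,
                    epoch_length = config$epoch_length,
                    wear_window = config$wear_window,
                    svm_floor = config$svm_floor) |>
        dplyr::mutate(patient_id = attr(tr, "patient_id"),
                      .before = 1)
    }) |> purrr::list_rbind()
    emit(ep, "epochs.csv")
    return(invisible(purrr::list_rbind(manifest)))
  }

  events <- attach_epochs(
    read_events_csv(file.path(input_dir, "events.csv")),
    read_epochs_csv(file.path(input_dir, "epochs.csv")))

  if (command %in% c("calibrate", "classify", "report")) {
    thr <- tryCatch(calibrate_threshold(events, config$percentile),
                    error = function(e) config$threshold)
    if (command %in% c("calibrate", "report")) {
      emit(tibble::tibble(threshold_g = as.numeric(thr),
                          threshold_rounded = round(as.numeric(thr), 3),
                          n_epochs = attr(thr, "n_epochs") %||% NA_integer_),
           "threshold.csv")
    }
    if (command %in% c("classify", "report")) {
      feats <- event_features(events, as.numeric(thr))
      emit(feats, "features.csv")
      for (sc in c("pct_active", "mean_svm")) {
        model <- category_model(sc,
          boundaries = if (sc == "pct_active") config$pct_boundaries
                       else config$svm_boundaries)
        pred <- classify_category(feats[[sc]], model)
        acc <- classification_accuracy(pred, feats$category)
        agree <- withr::with_seed(config$seed,
          cluster_agreement(feats[[sc]], feats$category))
        emit(dplyr::mutate(glance(acc),
                           cluster_agreement = as.numeric(agree),
                           scale = sc),
             paste0("agreement_", sc, ".csv"))
        an <- anova_discrimination(feats, sc, "category")
        emit(tidy(an), paste0("anova_", sc, ".csv"))
      }
    }
  }
  if (command %in% c("validate-steps", "report")) {
    emit(device_validation_report(dplyr::select(events, -"epochs")),
         "device_validation.csv")
  }
  if (command %in% c("longitudinal", "report")) {
    tp <- read_timepoints_csv(file.path(input_dir, "timepoints.csv"))
    rep <- recovery_report(tp)
    emit(rep$comparisons, "recovery_comparisons.csv")
    emit(rep$correlations, "recovery_correlations.csv")
  }
  invisible(purrr::list_rbind(manifest))
}
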