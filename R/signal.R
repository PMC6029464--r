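# Raw tri-axial accelerometry -> filtered per-sample SVM -> 60-s epochs.

#' Build a raw accelerometer trace
#'
#' Assembles per-sample tri-axial accelerations (units: g) into the trace
#' tibble used throughout the package. Time must be strictly increasing and
#' all three axes complete.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param x_g,y_g,z_g Numeric vectors of axis accelerations in g.
#' @param patient_id Identifier attached to the trace.
#' @param sampling_rate Sampling rate in Hz.
#' @return A tibble with columns `time_s`, `x_g`, `y_g`, `z_g` and attributes
#'   `patient_id` and `sampling_rate`.
#' @export
raw_trace <- function(time_s, x_g, y_g, z_g, patient_id = "P1",
                      sampling_rate = 100) {
  n <- length(time_s)
  if (n == 0L) stop("trace must contain at least one sample", call. = FALSE)
  if (length(x_g) != n || length(y_g) != n || length(z_g) != n) {
    stop("axis vectors must have the same length as `time_s`", call. = FALSE)
  }
  if (anyNA(time_s) || anyNA(x_g) || anyNA(y_g) || anyNA(z_g)) {
    stop("trace contains missing samples", call. = FALSE)
  }
  if (n > 1L && any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), x_g = as.numeric(x_g),
                        y_g = as.numeric(y_g), z_g = as.numeric(z_g))
  attr(out, "patient_id") <- patient_id
  attr(out, "sampling_rate") <- sampling_rate
  out
}

trace_rate <- function(trace) {
  sr <- attr(trace, "sampling_rate")
  if (!is.null(sr)) return(sr)
  # fall back to the median sampling interval
  if (nrow(trace) < 2L) stop("cannot infer sampling rate from one sample",
                             call. = FALSE)
  1 / stats::median(diff(trace$time_s))
}

#' Zero-phase band-pass filter of a tri-axial trace
#'
#' Applies a 4th-order Butterworth band-pass (default 0.5--20 Hz) to each
#' axis, forward--backward so the result is zero-phase. Output length equals
#' input length and all three axes are filtered identically.
#'
#' @param trace Trace tibble from [raw_trace()] (columns `time_s`, `x_g`,
#'   `y_g`, `z_g`).
#' @param low,high Band edges in Hz; must satisfy `0 < low < high <
#'   sampling_rate / 2`.
#' @param order Butterworth order (applied once per direction).
#' @return The trace with filtered axes; attributes are preserved.
#' @export
bandpass_filter <- function(trace, low = 0.5, high = 20, order = 4) {
  sr <- trace_rate(trace)
  if (!(low > 0 && low < high && high < sr / 2)) {
    stop(sprintf(
      "band [%g, %g] Hz invalid: need 0 < low < high < sampling_rate/2 = %g",
      low, high, sr / 2), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (sr / 2), type = "pass")
  out <- trace
  for (ax in c("x_g", "y_g", "z_g")) {
    out[[ax]] <- as.numeric(signal::filtfilt(bf, trace[[ax]]))
  }
  out
}

#' Per-sample signal vector magnitude
#'
#' Computes the scalar activity signal from the three axes. The default
#' `"literal"` variant is `|x^2 + y^2 + z^2 - 1|`; the `"euclidean"` variant
#' is `|sqrt(x^2 + y^2 + z^2) - 1|` (the conventional ENMO-style magnitude).
#' Both are zero for a stationary device reporting unit gravity.
#'
#' @param trace Trace tibble (filtered or raw).
#' @param variant `"literal"` (default) or `"euclidean"`.
#' @return A tibble with columns `time_s` and `svm`, one row per sample;
#'   trace attributes are carried over.
#' @export
compute_svm <- function(trace, variant = c("literal", "euclidean")) {
  variant <- match.arg(variant)
  ss <- trace$x_g^2 + trace$y_g^2 + trace$z_g^2
  svm <- if (variant == "literal") abs(ss - 1) else abs(sqrt(ss) - 1)
  out <- tibble::tibble(time_s = trace$time_s, svm = svm)
  attr(out, "patient_id") <- attr(trace, "patient_id")
  attr(out, "sampling_rate") <- attr(trace, "sampling_rate")
  out
}

#' Aggregate per-sample SVM into fixed epochs
#'
#' Averages the per-sample SVM over consecutive epochs (default 60 s) aligned
#' to the trace start. A trailing partial epoch is kept (and flagged
#' `partial`) when it covers at least half the epoch length, otherwise
#' dropped.
#'
#' @param svm_df Tibble with columns `time_s` and `svm` from [compute_svm()].
#' @param epoch_length Epoch length in seconds.
#' @return An epoch tibble: `epoch_start_s`, `svm` (epoch mean), `n_samples`,
#'   `partial`, and a `wear` column initialised to `TRUE` (see
#'   [detect_wear()]).
#' @export
epoch_aggregate <- function(svm_df, epoch_length = 60) {
  if (nrow(svm_df) == 0L) stop("empty SVM series", call. = FALSE)
  t0 <- svm_df$time_s[1]
  rel <- svm_df$time_s - t0
  # each sample covers one sampling interval, so the covered span extends
  # one dt past the last sample time
  dt <- if (nrow(svm_df) > 1L) stats::median(diff(svm_df$time_s)) else 0
  span <- rel[length(rel)] + dt
  if (span + 1e-9 < epoch_length / 2) {
    stop("series shorter than half an epoch; nothing to aggregate",
         call. = FALSE)
  }
  idx <- floor(rel / epoch_length)
  out <- svm_df |>
    dplyr::mutate(.epoch = idx) |>
    dplyr::group_by(.epoch) |>
    dplyr::summarise(svm = mean(.data$svm), n_samples = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(epoch_start_s = t0 + .data$.epoch * epoch_length)
  last <- which.max(out$.epoch)
  # trailing partial epoch: span within epoch < epoch_length; keep if >= half
  covered <- span - out$.epoch[last] * epoch_length
  partial <- rep(FALSE, nrow(out))
  if (covered + 1e-9 < epoch_length) {
    if (covered + 1e-9 < epoch_length / 2) {
      out <- out[-last, , drop = FALSE]
      partial <- partial[-last]
    } else {
      partial[last] <- TRUE
    }
  }
  if (nrow(out) == 0L) stop("no epoch covers at least half its length",
                            call. = FALSE)
  out <- tibble::tibble(epoch_start_s = out$epoch_start_s, svm = out$svm,
                        n_samples = out$n_samples, partial = partial,
                        wear = TRUE)
  attr(out, "epoch_length") <- epoch_length
  attr(out, "patient_id") <- attr(svm_df, "patient_id")
  out
}

#' Flag non-wear epochs
#'
#' Marks as non-wear any run of at least `window` consecutive epochs whose
#' SVM all lie below `svm_floor`; every other epoch is wear. A taped-on
#' device at true rest still shows noise above the floor, so long dead-flat
#' stretches indicate the device was off the body.
#'
#' @param epochs Epoch tibble from [epoch_aggregate()].
#' @param window Minimum run length, in epochs (minutes for 60-s epochs).
#' @param svm_floor SVM level in g below which an epoch counts as candidate
#'   non-wear.
#' @return The epoch tibble with its `wear` column updated.
#' @export
detect_wear <- function(epochs, window = 60, svm_floor = 0.001) {
  below <- epochs$svm < svm_floor
  wear <- rep(TRUE, length(below))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths >= window)
  for (i in long) wear[starts[i]:ends[i]] <- FALSE
  epochs$wear <- wear
  epochs
}

#' Full raw-trace to epoch pipeline
#'
#' Convenience chain: band-pass filter the axes, compute the per-sample SVM,
#' aggregate into epochs and flag non-wear time.
#'
#' @inheritParams bandpass_filter
#' @inheritParams compute_svm
#' @inheritParams epoch_aggregate
#' @inheritParams detect_wear
#' @param filter If `FALSE`, skip the band-pass stage.
#' @return Epoch tibble (see [epoch_aggregate()]).
#' @export
process_trace <- function(trace, low = 0.5, high = 20,
                          variant = c("literal", "euclidean"),
                          epoch_length = 60, wear_window = 60,
                          svm_floor = 0.001, filter = TRUE) {
  variant <- match.arg(variant)
  if (filter) trace <- bandpass_filter(trace, low = low, high = high)
  trace |>
    compute_svm(variant = variant) |>
    epoch_aggregate(epoch_length = epoch_length) |>
    detect_wear(window = wear_window, svm_floor = svm_floor)
}
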