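# Step-counter validation: event-level detection, steps/min discrimination,
# and regression against counted ("real") steps.

DEVICE_CODES <- c("MFA", "FBA", "MFW", "FBW")

device_column <- function(events, device_location) {
  col <- paste0("steps_", device_location)
  if (!col %in% names(events)) {
    stop(sprintf("no measured-steps column `%s` for device %s",
                 col, device_location), call. = FALSE)
  }
  col
}

#' Did a step counter register an event as active?
#'
#' An event counts as detected-active for a device when the device
#' registered at least one step during the event.
#'
#' @param events Event tibble with a `steps_<device>` column.
#' @param device_location Device-by-location code (`"MFA"`, `"FBA"`,
#'   `"MFW"`, `"FBW"` or any custom code with a matching column).
#' @return Logical vector, one entry per event; `NA` where the device has no
#'   reading for the event.
#' @export
detect_active_event <- function(events, device_location) {
  col <- device_column(events, device_location)
  ms <- events[[col]]
  if (all(is.na(ms))) {
    stop(sprintf("device %s has no measured-steps entries", device_location),
         call. = FALSE)
  }
  ms >= 1
}

#' Detection confusion table for one device
#'
#' Tallies true/false positives and negatives of event-level activity
#' detection. Truth defaults to the protocol rule: an event is truly active
#' when at least one real step was counted (categories 1--2 carry zero real
#' steps by protocol). Events without a reading for the device are skipped.
#'
#' @param events Event tibble with `real_steps` and a `steps_<device>`
#'   column.
#' @param device_location Device code (see [detect_active_event()]).
#' @param truth Optional logical vector overriding the real-steps truth rule.
#' @return One-row tibble: `device_location`, `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
detection_confusion <- function(events, device_location, truth = NULL) {
  col <- device_column(events, device_location)
  if (is.null(truth)) {
    if (!"real_steps" %in% names(events)) {
      stop("no `real_steps` column: truth unassignable", call. = FALSE)
    }
    truth <- events$real_steps >= 1
  }
  if (anyNA(truth)) stop("truth unassignable for some events", call. = FALSE)
  pred <- events[[col]] >= 1
  keep <- !is.na(pred)
  truth <- truth[keep]; pred <- pred[keep]
  tibble::tibble(device_location = device_location,
                 tp = sum(pred & truth), fp = sum(pred & !truth),
                 tn = sum(!pred & !truth), fn = sum(!pred & truth),
                 n = length(pred))
}

#' Sensitivity and specificity from a confusion table
#'
#' Sensitivity is the true-positive rate `100 * tp / (tp + fn)`; specificity
#' the true-negative rate `100 * tn / (tn + fp)`, both in percent.
#'
#' @param confusion Tibble with columns `tp`, `fp`, `tn`, `fn` (one or more
#'   rows, e.g. from [detection_confusion()]).
#' @return The input with `sensitivity` and `specificity` columns appended
#'   (percent).
#' @export
sensitivity_specificity <- function(confusion) {
  if (any(confusion$tp + confusion$fn == 0)) {
    stop("sensitivity undefined: no truly active events", call. = FALSE)
  }
  if (any(confusion$tn + confusion$fp == 0)) {
    stop("specificity undefined: no truly inactive events", call. = FALSE)
  }
  dplyr::mutate(confusion,
                sensitivity = 100 * .data$tp / (.data$tp + .data$fn),
                specificity = 100 * .data$tn / (.data$tn + .data$fp))
}

#' Steps per minute by clinical category
#'
#' Computes each event's device-registered steps per protocol minute and
#' tests whether the rates discriminate the clinical categories (one-way
#' ANOVA with pairwise post-hoc, see [anova_discrimination()]).
#'
#' @param events Event tibble with `category`, `start_s`, `end_s` and a
#'   `steps_<device>` column.
#' @param device_location Device code.
#' @param alpha Significance level for the post-hoc comparisons.
#' @return List with `rates` (tibble: `patient_id`, `category`,
#'   `steps_per_min`) and `anova` (an `anova_discrimination`).
#' @export
steps_per_minute_by_category <- function(events, device_location,
                                         alpha = 0.05) {
  col <- device_column(events, device_location)
  dur_min <- (events$end_s - events$start_s) / 60
  if (any(dur_min <= 0)) stop("zero-duration event", call. = FALSE)
  rates <- tibble::tibble(
    patient_id = events$patient_id, category = events$category,
    steps_per_min = events[[col]] / dur_min) |>
    dplyr::filter(!is.na(.data$steps_per_min))
  if (dplyr::n_distinct(rates$category) < 2L) {
    stop("need events in at least 2 categories", call. = FALSE)
  }
  list(rates = rates,
       anova = anova_discrimination(rates, "steps_per_min", "category",
                                    alpha = alpha))
}

#' Regress real step rate on a device or SVM predictor
#'
#' Ordinary least squares of the counted (real) steps-per-minute on either a
#' device's measured steps-per-minute or the event mean SVM. An optional
#' inclusion threshold drops events whose real rate falls below it before
#' fitting (used to restrict to genuinely walked events).
#'
#' @param pairs Tibble with columns `real` (real steps/min) and `predictor`.
#' @param inclusion_threshold Minimum real steps/min for inclusion, or
#'   `NULL` for none.
#' @param intercept Fit an intercept (default) or force the line through the
#'   origin.
#' @return A `step_regression` object wrapping the `lm` fit with fields
#'   `slope`, `intercept`, `r_squared`, `n`, `inclusion_threshold`;
#'   `tidy()`/`glance()` methods apply.
#' @export
regress_steps <- function(pairs, inclusion_threshold = NULL,
                          intercept = TRUE) {
  stopifnot(all(c("real", "predictor") %in% names(pairs)))
  df <- dplyr::filter(pairs, !is.na(.data$real), !is.na(.data$predictor))
  if (!is.null(inclusion_threshold)) {
    df <- dplyr::filter(df, .data$real >= inclusion_threshold)
  }
  if (nrow(df) < 3L) {
    stop(sprintf("need at least 3 pairs after filtering, have %d", nrow(df)),
         call. = FALSE)
  }
  fml <- if (intercept) real ~ predictor else real ~ predictor - 1
  fit <- stats::lm(fml, data = df)
  # noiseless validation data fit perfectly; that is expected, not suspect
  r2 <- withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  structure(list(slope = unname(co[["predictor"]]),
                 intercept = if (intercept) unname(co[["(Intercept)"]]) else 0,
                 r_squared = r2, n = nrow(df),
                 inclusion_threshold = inclusion_threshold, fit = fit),
            class = "step_regression")
}

#' @export
print.step_regression <- function(x, ...) {
  thr <- if (is.null(x$inclusion_threshold)) "none"
         else sprintf("%g real steps/min", x$inclusion_threshold)
  cat(sprintf(
    "Step regression: slope %.3f, intercept %.3f, R^2 = %.3f, n = %d (inclusion threshold: %s)\n",
    x$slope, x$intercept, x$r_squared, x$n, thr))
  invisible(x)
}

#' @exportS3Method
tidy.step_regression <- function(x, ...) {
  tibble::tibble(term = c(if (x$intercept != 0 ||
                              "(Intercept)" %in% names(stats::coef(x$fit)))
                            "(Intercept)", "predictor"),
                 estimate = c(if ("(Intercept)" %in% names(stats::coef(x$fit)))
                                x$intercept, x$slope))
}

#' @exportS3Method
glance.step_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n,
                 inclusion_threshold = x$inclusion_threshold %||% NA_real_)
}

#' Device validation report across devices
#'
#' Replicates the device-comparison summary: for each device with readings,
#' the number of evaluated events, event-detection sensitivity and
#' specificity, and the regression R-squared of measured against real steps
#' per minute.
#'
#' @param events Event tibble.
#' @param devices Device codes to evaluate (defaults to all `steps_*`
#'   columns present).
#' @return Tibble: `device_location`, `n`, `sensitivity`, `specificity`,
#'   `r_squared`.
#' @export
device_validation_report <- function(events, devices = NULL) {
  if (is.null(devices)) {
    devices <- sub("^steps_", "", grep("^steps_", names(events), value = TRUE))
  }
  purrr::map(devices, function(dv) {
    conf <- sensitivity_specificity(detection_confusion(events, dv))
    col <- device_column(events, dv)
    dur_min <- (events$end_s - events$start_s) / 60
    pr <- tibble::tibble(real = events$real_steps / dur_min,
                         predictor = events[[col]] / dur_min)
    r2 <- tryCatch(regress_steps(pr)$r_squared, error = function(e) NA_real_)
    dplyr::mutate(conf, r_squared = r2)
  }) |> purrr::list_rbind()
}
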