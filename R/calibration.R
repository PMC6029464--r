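# Population-specific activity threshold and per-event activity features.

#' Calibrate the activity threshold from inactive-period epochs
#'
#' Pools the epoch SVM values of all category-1 (bedrest asleep) events and
#' returns their 90th percentile (linear interpolation between order
#' statistics). Epochs recorded while the patient is clinically inactive
#' define, by their upper tail, the boundary between "active" and "not
#' active" minutes for this slow-moving population; the published value for
#' the study cohort is 0.005 g.
#'
#' @param events Nested event tibble (see [simulate_cohort()] or
#'   [read_events_csv()] + [attach_epochs()]): one row per event with a
#'   list-column `epochs` of epoch tibbles.
#' @param percentile Percentile to use, in \[0, 100\].
#' @param category Category whose events define inactivity (default 1).
#' @return The threshold in g (scalar). Attribute `n_epochs` records how
#'   many pooled epochs contributed.
#' @export
calibrate_threshold <- function(events, percentile = 90, category = 1) {
  stopifnot(percentile >= 0, percentile <= 100)
  ev <- dplyr::filter(events, .data$category == !!category)
  if (nrow(ev) == 0L) {
    stop(sprintf("threshold calibration needs at least one category-%d event",
                 category), call. = FALSE)
  }
  pooled <- unlist(purrr::map(ev$epochs, function(e) e$svm[e$wear]))
  if (length(pooled) == 0L) {
    stop("category-1 events contain no wear epochs to pool", call. = FALSE)
  }
  thr <- unname(stats::quantile(pooled, probs = percentile / 100, type = 7))
  attr(thr, "n_epochs") <- length(pooled)
  thr
}

#' Classify epochs as active or not active minutes
#'
#' An epoch is an active minute when its SVM strictly exceeds the threshold;
#' an epoch exactly at the threshold is not active (the threshold is defined
#' from inactive periods). Non-wear epochs are marked `NA`.
#'
#' @param epochs Epoch tibble (`svm`, `wear`).
#' @param threshold Activity threshold in g, > 0.
#' @return The epoch tibble with a logical `active` column (`NA` for
#'   non-wear epochs).
#' @export
classify_active_minutes <- function(epochs, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  epochs$active <- ifelse(epochs$wear, epochs$svm > threshold, NA)
  epochs
}

#' Per-event activity features
#'
#' Reduces each event's wear epochs to the two scalar features the category
#' models operate on: the percent of active minutes and the mean epoch SVM.
#'
#' @param events Nested event tibble with an `epochs` list-column.
#' @param threshold Activity threshold in g.
#' @return A tibble with one row per event: identifying columns carried over
#'   (`patient_id`, `event_id`, `category` where present), plus `n_epochs`
#'   (wear epochs), `pct_active` in \[0, 100\] and `mean_svm` in g.
#' @export
event_features <- function(events, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  feats <- purrr::map(events$epochs, function(e) {
    w <- e[e$wear, , drop = FALSE]
    if (nrow(w) == 0L) return(NULL)
    tibble::tibble(n_epochs = nrow(w),
                   pct_active = 100 * mean(w$svm > threshold),
                   mean_svm = mean(w$svm))
  })
  bad <- which(purrr::map_lgl(feats, is.null))
  if (length(bad) > 0L) {
    id <- if ("event_id" %in% names(events)) events$event_id[bad[1]] else bad[1]
    stop(sprintf("event %s has no wear epochs; features undefined", id),
         call. = FALSE)
  }
  keep <- intersect(c("patient_id", "event_id", "category", "start_s",
                      "end_s"), names(events))
  dplyr::bind_cols(events[keep], purrr::list_rbind(feats))
}
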