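# Daily activity summaries over continuous monitoring and the recovery
# comparisons against the clinical scores.

#' Daily activity summary from continuous epoch data
#'
#' Summarises each monitored day into the three recovery metrics: total
#' active minutes, the fraction of highly active (category-4) periods, and
#' the active minutes spent inside those periods. A "period" is a fixed
#' window of `window` consecutive wear minutes; each complete window is
#' classified through the percent-active-minutes category model, and a
#' trailing partial window is kept when it covers at least half the window
#' length.
#'
#' @param epochs Epoch tibble (`epoch_start_s`, `svm`, `wear`); may span
#'   several days, split at multiples of 86400 s.
#' @param threshold Activity threshold in g.
#' @param model A [category_model()] on the `pct_active` scale.
#' @param window Period length in wear minutes.
#' @return Tibble with one row per day: `day`, `wear_minutes`,
#'   `active_minutes`, `cat4_period_fraction` (percent of windows classified
#'   category 4), `cat4_active_minutes`, `n_windows`.
#' @export
daily_summary <- function(epochs, threshold, model = category_model("pct_active"),
                          window = 15) {
  stopifnot(inherits(model, "category_model"),
            model$scale == "pct_active", window >= 1)
  if (!any(epochs$wear)) stop("no wear epochs in the supplied day",
                              call. = FALSE)
  epochs |>
    dplyr::mutate(day = floor(.data$epoch_start_s / 86400)) |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(~ one_day_summary(.x, threshold, model, window)) |>
    dplyr::ungroup()
}

one_day_summary <- function(epochs, threshold, model, window) {
  w <- epochs[epochs$wear, , drop = FALSE]
  if (nrow(w) == 0L) stop("no wear epochs in the supplied day", call. = FALSE)
  active <- w$svm > threshold
  # consecutive windows of `window` wear minutes, in time order
  win_id <- (seq_len(nrow(w)) - 1L) %/% window
  sizes <- tabulate(win_id + 1L)
  keep <- sizes >= window / 2            # drop a too-short trailing window
  pct <- 100 * tapply(active, win_id, mean)[keep]
  act_in_win <- tapply(active, win_id, sum)[keep]
  cats <- classify_category(as.numeric(pct), model)
  n_win <- sum(keep)
  tibble::tibble(
    wear_minutes = nrow(w),
    active_minutes = sum(active),
    cat4_period_fraction = if (n_win > 0) 100 * mean(cats == 4L) else NA_real_,
    cat4_active_minutes = sum(act_in_win[cats == 4L]),
    n_windows = n_win)
}

#' Average daily summaries into one timepoint record
#'
#' Multi-day monitoring around a nominal timepoint is reduced to the mean of
#' its per-day summaries.
#'
#' @param days Tibble from [daily_summary()].
#' @return One-row tibble with the averaged metrics and `n_days`.
#' @export
summarise_timepoint <- function(days) {
  dplyr::summarise(days,
                   active_minutes = mean(.data$active_minutes),
                   cat4_period_fraction = mean(.data$cat4_period_fraction,
                                               na.rm = TRUE),
                   cat4_active_minutes = mean(.data$cat4_active_minutes),
                   n_days = dplyr::n())
}

#' Paired comparison of a metric between two timepoints
#'
#' Compares per-patient values shortly after the operation against values
#' shortly before discharge. `"paired_t"` runs the paired Student t-test;
#' `"mann_whitney"` the Mann--Whitney U test (unpaired two-sample Wilcoxon,
#' the test the clinical analysis plan names for non-normal data). The
#' default `"auto"` picks the t-test when the paired differences pass a
#' Shapiro--Wilk normality check at the 0.05 level and Mann--Whitney
#' otherwise.
#'
#' Degenerate inputs are reported rather than erroring: identical vectors
#' give `p_value = 1`, and a constant non-zero shift gives `p_value = 0`,
#' both with `degenerate = TRUE`.
#'
#' @param t1,t2 Numeric vectors, one entry per patient, aligned.
#' @param test `"auto"`, `"paired_t"` or `"mann_whitney"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `mean_t1`,
#'   `sd_t1`, `mean_t2`, `sd_t2`, `n`, `degenerate`.
#' @export
paired_compare <- function(t1, t2, test = c("auto", "paired_t",
                                            "mann_whitney")) {
  test <- match.arg(test)
  keep <- !is.na(t1) & !is.na(t2)
  t1 <- t1[keep]; t2 <- t2[keep]
  n <- length(t1)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  d <- t2 - t1
  summ <- tibble::tibble(mean_t1 = mean(t1), sd_t1 = stats::sd(t1),
                         mean_t2 = mean(t2), sd_t2 = stats::sd(t2), n = n)
  if (stats::sd(d) == 0) {
    # zero variance of differences: no test statistic exists
    p <- if (all(d == 0)) 1 else 0
    return(dplyr::bind_cols(
      tibble::tibble(test = "degenerate", statistic = NA_real_, p_value = p),
      summ, tibble::tibble(degenerate = TRUE)))
  }
  if (test == "auto") {
    test <- if (stats::shapiro.test(d)$p.value >= 0.05) "paired_t"
            else "mann_whitney"
  }
  ht <- if (test == "paired_t") {
    stats::t.test(t2, t1, paired = TRUE)
  } else {
    stats::wilcox.test(t2, t1, paired = FALSE, exact = FALSE)
  }
  dplyr::bind_cols(
    tibble::tibble(test = test, statistic = unname(ht$statistic),
                   p_value = ht$p.value),
    summ, tibble::tibble(degenerate = FALSE))
}

#' Correlation between an activity metric and a clinical score
#'
#' Pearson's R or Spearman's rho with its two-sided p-value; the squared
#' coefficient is reported alongside because associations between measured
#' activity and the functional scores are usually quoted as R-squared.
#'
#' @param activity,score Numeric vectors, aligned per patient.
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `method`, `coefficient`, `r_squared`, `p_value`,
#'   `n`.
#' @export
correlate_scores <- function(activity, score,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(activity) & !is.na(score)
  activity <- activity[keep]; score <- score[keep]
  if (length(activity) < 3L) stop("need at least 3 complete pairs",
                                  call. = FALSE)
  if (stats::sd(activity) == 0 || stats::sd(score) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ht <- stats::cor.test(activity, score, method = method, exact = FALSE)
  tibble::tibble(method = method, coefficient = unname(ht$estimate),
                 r_squared = unname(ht$estimate)^2, p_value = ht$p.value,
                 n = length(activity))
}

#' Recovery comparison across all timepoint metrics
#'
#' Runs [paired_compare()] for every activity and clinical metric between
#' the two timepoints of a per-patient timepoint table, and
#' [correlate_scores()] of each activity metric with each clinical score at
#' each timepoint.
#'
#' @param timepoints Tibble with `patient_id`, `timepoint_label` (two
#'   levels), the activity metrics (`active_minutes`,
#'   `cat4_period_fraction`, `cat4_active_minutes`) and scores (`barthel20`,
#'   `eq5d_index`).
#' @param test Passed to [paired_compare()].
#' @return List of tibbles `comparisons` (one row per metric) and
#'   `correlations` (one row per metric x score x timepoint).
#' @export
recovery_report <- function(timepoints, test = "auto") {
  labs <- unique(timepoints$timepoint_label)
  if (length(labs) != 2L) {
    stop("timepoint table must contain exactly 2 timepoint labels",
         call. = FALSE)
  }
  metrics <- intersect(c("active_minutes", "cat4_period_fraction",
                         "cat4_active_minutes", "barthel20", "eq5d_index"),
                       names(timepoints))
  wide <- timepoints |>
    dplyr::select(dplyr::all_of(c("patient_id", "timepoint_label", metrics))) |>
    tidyr::pivot_wider(names_from = "timepoint_label",
                       values_from = dplyr::all_of(metrics))
  comparisons <- purrr::map(metrics, function(m) {
    dplyr::bind_cols(tibble::tibble(metric = m),
                     paired_compare(wide[[paste0(m, "_", labs[1])]],
                                    wide[[paste0(m, "_", labs[2])]],
                                    test = test))
  }) |> purrr::list_rbind()
  act <- intersect(c("active_minutes", "cat4_period_fraction",
                     "cat4_active_minutes"), metrics)
  sco <- intersect(c("barthel20", "eq5d_index"), metrics)
  correlations <- purrr::map(act, function(a) {
    purrr::map(sco, function(s) {
      purrr::map(labs, function(lb) {
        dplyr::bind_cols(
          tibble::tibble(metric = a, score = s, timepoint = lb),
          correlate_scores(wide[[paste0(a, "_", lb)]],
                           wide[[paste0(s, "_", lb)]]))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  list(comparisons = comparisons, correlations = correlations)
}
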