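# Shared fixture builders: everything is generated in code at test time.

# epoch tibble from a bare SVM vector (all wear unless stated)
make_epochs <- function(svm, wear = TRUE, start = 0, epoch_length = 60) {
  tibble::tibble(
    epoch_start_s = start + (seq_along(svm) - 1) * epoch_length,
    svm = svm,
    n_samples = 6000L,
    partial = FALSE,
    wear = rep_len(wear, length(svm)))
}

# nested one-row-per-event tibble from a list of SVM vectors
make_events <- function(svm_list, category = seq_along(svm_list),
                        patient_id = "P1") {
  ev <- tibble::tibble(
    patient_id = patient_id,
    event_id = sprintf("E%02d", seq_along(svm_list)),
    category = as.integer(category),
    start_s = (seq_along(svm_list) - 1) * 36000,
    end_s = (seq_along(svm_list) - 1) * 36000 +
      60 * lengths(svm_list))
  ev$real_steps <- ifelse(ev$category >= 3, 50L, 0L)
  ev$epochs <- lapply(seq_along(svm_list), function(i) {
    make_epochs(svm_list[[i]], start = ev$start_s[i])
  })
  ev
}

# sine-wave trace on one axis, zeros elsewhere
sine_trace <- function(freq, rate = 100, dur = 10, axis = "x_g",
                       amplitude = 1) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  ax <- list(x_g = numeric(length(t)), y_g = numeric(length(t)),
             z_g = numeric(length(t)))
  ax[[axis]] <- amplitude * sin(2 * pi * freq * t)
  raw_trace(t, ax$x_g, ax$y_g, ax$z_g, sampling_rate = rate)
}

# a noise-free generator: fixed SVM level per category, faithful devices
noise_free_config <- function(seed = 1, n_patients = 2, ...) {
  generator_config(
    seed = seed, n_patients = n_patients,
    svm_sdlog = c(0, 0, 0, 0),
    devices = tibble::tibble(code = "MFA", miss_prob = 0,
                             capture_rate = 1, spurious_per_min = 0),
    ...)
}
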