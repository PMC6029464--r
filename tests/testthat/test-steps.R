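# Step-counter validation: detection rules, confusion tallies, rates,
# regression.

toy_events <- function(real, measured, category = NULL) {
  n <- length(real)
  if (is.null(category)) category <- rep(1:4, length.out = n)
  tibble::tibble(
    patient_id = "P1", event_id = sprintf("E%02d", seq_len(n)),
    category = category,
    start_s = (seq_len(n) - 1) * 3600, end_s = (seq_len(n) - 1) * 3600 + 600,
    real_steps = real, steps_MFA = measured)
}

test_that("an event is detected active iff at least one step registered", {
  ev <- toy_events(real = c(0, 5, 80), measured = c(0, 1, 57))
  expect_identical(detect_active_event(ev, "MFA"), c(FALSE, TRUE, TRUE))
  expect_error(detect_active_event(ev, "XXX"), "steps_XXX")
})

test_that("confusion tallies match a hand count and a brute-force oracle", {
  # perfect device: no false entries
  ev <- toy_events(real = c(0, 0, 10, 20), measured = c(0, 0, 10, 20))
  cf <- detection_confusion(ev, "MFA")
  expect_identical(cf$fp + cf$fn, 0L)

  # dead device: sensitivity 0, specificity 1
  dead <- toy_events(real = c(0, 0, 10, 20), measured = rep(0, 4))
  sdead <- sensitivity_specificity(detection_confusion(dead, "MFA"))
  expect_equal(sdead$sensitivity, 0)
  expect_equal(sdead$specificity, 100)

  # randomized 20-event toys vs an exhaustive loop tally
  withr::with_seed(13, {
    for (rep in 1:5) {
      real <- rbinom(20, 1, 0.5) * rpois(20, 30)
      meas <- ifelse(runif(20) < 0.3, 0, real + rpois(20, 2))
      ev <- toy_events(real, meas)
      got <- detection_confusion(ev, "MFA")
      tp <- fp <- tn <- fn <- 0
      for (i in 1:20) {
        truly <- real[i] >= 1; det <- meas[i] >= 1
        if (truly && det) tp <- tp + 1
        if (!truly && det) fp <- fp + 1
        if (!truly && !det) tn <- tn + 1
        if (truly && !det) fn <- fn + 1
      }
      expect_equal(unlist(got[c("tp", "fp", "tn", "fn")]),
                   c(tp = tp, fp = fp, tn = tn, fn = fn),
                   ignore_attr = FALSE)
    }
  })
})

test_that("sensitivity and specificity are the true positive/negative rates", {
  tab <- tibble::tibble(device_location = "MFA", tp = 9, fn = 1, tn = 9,
                        fp = 1, n = 20)
  got <- sensitivity_specificity(tab)
  expect_equal(got$sensitivity, 90)
  expect_equal(got$specificity, 90)
  expect_error(sensitivity_specificity(
    tibble::tibble(tp = 0, fn = 0, tn = 5, fp = 1)), "sensitivity undefined")
  # invariance to event order
  withr::with_seed(3, {
    real <- c(rep(0, 10), rpois(10, 20) + 1)
    meas <- ifelse(runif(20) < 0.2, 0, real)
    ev <- toy_events(real, meas)
    a <- sensitivity_specificity(detection_confusion(ev, "MFA"))
    b <- sensitivity_specificity(detection_confusion(ev[sample(20), ], "MFA"))
    expect_equal(a$sensitivity, b$sensitivity)
    expect_equal(a$specificity, b$specificity)
  })
})

test_that("a noise-free ankle device yields 100 % sensitivity and specificity", {
  co <- simulate_cohort(noise_free_config(seed = 6, n_patients = 6))
  res <- sensitivity_specificity(detection_confusion(co$events, "MFA"))
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100)
})

test_that("event-miss probability propagates to sensitivity", {
  cfg <- generator_config(
    seed = 10, n_patients = 63, events_per_category = 8,
    devices = tibble::tibble(code = "MFA", miss_prob = 0.05,
                             capture_rate = 1, spurious_per_min = 0))
  co <- simulate_cohort(cfg)
  cf <- detection_confusion(co$events, "MFA")
  n_active <- cf$tp + cf$fn
  sens <- sensitivity_specificity(cf)$sensitivity
  # detected count is Binomial(n_active, 0.95); 3-SE band for a single
  # pre-seeded draw of a proportion
  se <- 100 * sqrt(0.95 * 0.05 / n_active)
  expect_lt(abs(sens - 95), 3 * se)
})

test_that("steps per minute discriminate a constructed high-activity class", {
  # category 4 at ~10 steps/min vs near-zero noise elsewhere
  ev4 <- toy_events(real = rep(c(0, 0, 0, 100), 5),
                    measured = rep(c(0, 0, 0, 100), 5) +
                      rep(c(0, 1, 0, 2), 5))
  r <- steps_per_minute_by_category(ev4, "MFA")
  p34 <- r$anova$pairs
  expect_true(all(p34$significant[p34$group2 == "4"]))
  expect_lt(r$anova$anova$p_value, 0.001)
  expect_error(steps_per_minute_by_category(
    dplyr::mutate(ev4, end_s = start_s), "MFA"), "zero-duration")
})

test_that("anova p-value agrees with a permutation oracle", {
  withr::with_seed(33, {
    df <- tibble::tibble(category = rep(1:4, each = 8),
                         steps_per_min = c(rnorm(8, 0, 1), rnorm(8, 0.3, 1),
                                           rnorm(8, 0.6, 1), rnorm(8, 2, 1)))
    r <- anova_discrimination(df, "steps_per_min", "category")
    f_obs <- r$anova$f_statistic
    f_perm <- replicate(2000, {
      perm <- sample(df$steps_per_min)
      summary(stats::aov(perm ~ factor(df$category)))[[1]][1, "F value"]
    })
    p_perm <- mean(f_perm >= f_obs)
    mc_se <- sqrt(p_perm * (1 - p_perm) / 2000) + 1e-4
    expect_lt(abs(r$anova$p_value - p_perm), 4 * mc_se + 0.01)
  })
})

test_that("regression identities hold", {
  # exact line
  pr <- tibble::tibble(predictor = 1:10, real = 2 * (1:10))
  r <- regress_steps(pr)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)

  # constant predictor: no variance explained
  withr::with_seed(8, prc <- tibble::tibble(predictor = rep(3, 10),
                                            real = rnorm(10)))
  expect_equal(regress_steps(prc)$r_squared, 0, tolerance = 1e-12)

  # R^2 equals the squared Pearson correlation in simple OLS
  withr::with_seed(9, {
    pr2 <- tibble::tibble(predictor = rnorm(50), real = rnorm(50))
    pr2$real <- pr2$real + 0.8 * pr2$predictor
  })
  r2 <- regress_steps(pr2)
  expect_equal(r2$r_squared, cor(pr2$predictor, pr2$real)^2,
               tolerance = 1e-12)

  # inclusion threshold drops sub-threshold pairs before fitting
  pr3 <- tibble::tibble(predictor = c(0, 0, 1:8), real = c(0, 0.5, 1:8))
  rt <- regress_steps(pr3, inclusion_threshold = 1)
  expect_identical(rt$n, 8L)
  expect_error(regress_steps(pr3[1:2, ]), "at least 3")
})

test_that("noiseless measured-vs-real steps regress with R^2 > 0.99", {
  co <- simulate_cohort(noise_free_config(seed = 44, n_patients = 6))
  ev <- co$events[co$events$real_steps > 0, ]
  dur <- (ev$end_s - ev$start_s) / 60
  pr <- tibble::tibble(real = ev$real_steps / dur,
                       predictor = ev$steps_MFA / dur)
  expect_gt(regress_steps(pr)$r_squared, 0.99)
})

test_that("the device validation report covers every device column", {
  co <- simulate_cohort(generator_config(seed = 21, n_patients = 10))
  rep <- device_validation_report(dplyr::select(co$events, -"epochs"))
  expect_setequal(rep$device_location, c("MFA", "FBA", "MFW", "FBW"))
  expect_true(all(rep$sensitivity >= 0 & rep$sensitivity <= 100))
  # the ankle-worn Misfit outperforms the wrist devices by construction
  expect_gt(rep$sensitivity[rep$device_location == "MFA"],
            rep$sensitivity[rep$device_location == "FBW"])
})
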