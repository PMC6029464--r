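# Category models: interval classification, discriminant boundary fitting,
# agreement and ANOVA discrimination.

test_that("published interval classification matches the > notation", {
  m <- category_model("pct_active")
  expect_identical(classify_category(c(5, 10, 10.01, 25, 25.01, 60, 70), m),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L))
  ms <- category_model("mean_svm")
  expect_identical(classify_category(c(0.0034, 0.0155), ms), c(1L, 4L))
  expect_identical(classify_category(0.01, ms), 3L)   # exactly b3
  expect_error(classify_category(-1, m), "non-negative")
  expect_error(classify_category(101, m), "exceed 100")
})

test_that("published category means fall into their own intervals", {
  # Table means: percent-active 5.63/27.76/43.68/77.94, SVM 0.0034/0.0047/
  # 0.0080/0.0155. The category-2 means are known edge cases: 27.76 lies
  # above the published 25 boundary and 0.0047 sits exactly on the category
  # 1/2 boundary, so self-consistency holds for categories 1, 3 and 4.
  mp <- category_model("pct_active")
  expect_identical(classify_category(c(5.63, 43.68, 77.94), mp),
                   c(1L, 3L, 4L))
  ms <- category_model("mean_svm")
  expect_identical(classify_category(c(0.0034, 0.0080, 0.0155), ms),
                   c(1L, 3L, 4L))
})

test_that("classification is monotone in the feature value", {
  m <- category_model("pct_active")
  v <- sort(runif(200, 0, 100))
  expect_true(all(diff(classify_category(v, m)) >= 0))
})

test_that("model construction validates its boundaries", {
  expect_error(category_model("pct_active", c(25, 10, 60)), "increasing")
  expect_error(category_model("pct_active", c(-1, 10, 60)), "non-negative")
  expect_silent(category_model("mean_svm"))
})

test_that("pooled-variance discriminant boundaries are adjacent midpoints", {
  set.seed(101)
  feats <- tibble::tibble(
    category = rep(1:4, each = 20),
    pct_active = rep(c(0, 20, 40, 80), each = 20) + rnorm(80, sd = 1e-6))
  fit <- fit_boundaries_lda(feats)
  expect_equal(fit$boundaries, c(10, 30, 60), tolerance = 1e-5)
  expect_identical(fit$provenance, "lda-fitted")
})

test_that("two-class equal-variance boundary is the midpoint of the means", {
  b <- actiward:::qda_boundary(3, 2, 9, 2)
  expect_equal(b, 6)
  # unequal variances: boundary where the two class densities cross
  b2 <- actiward:::qda_boundary(0, 1, 10, 3)
  expect_equal(dnorm(b2, 0, 1), dnorm(b2, 10, 3), tolerance = 1e-9)
  expect_true(b2 > 0 && b2 < 10)
})

test_that("discriminant fit recovers boundaries from its own model", {
  means <- c(5, 28, 44, 78); sd0 <- 4
  n <- 1000
  withr::with_seed(61, {
    feats <- tibble::tibble(
      category = rep(1:4, each = n),
      pct_active = rnorm(4 * n, mean = rep(means, each = n), sd = sd0))
  })
  fit <- fit_boundaries_lda(feats)
  true_b <- (means[-4] + means[-1]) / 2
  se_b <- sqrt(2 * sd0^2 / n) / 2       # SE of a midpoint of two means
  expect_true(all(abs(fit$boundaries - true_b) < 2 * se_b + 1e-9))

  # grid-search oracle: the midpoint boundaries should classify the
  # training data at least as well as any nearby boundary shift
  acc_of <- function(b) {
    pred <- classify_category(pmax(feats$pct_active, 0),
                              category_model("pct_active", b))
    mean(pred == feats$category)
  }
  base <- acc_of(fit$boundaries)
  for (shift in c(-2, 2)) {
    expect_gte(base + 0.005, acc_of(fit$boundaries + shift))
  }
})

test_that("pooled-variance boundaries agree with an external LDA", {
  skip_if_not_installed("MASS")
  withr::with_seed(67, {
    feats <- tibble::tibble(
      category = rep(1:4, each = 200),
      pct_active = rnorm(800, rep(c(6, 28, 44, 78), each = 200), 6))
  })
  fit <- fit_boundaries_lda(feats)
  ld <- MASS::lda(category ~ pct_active, data = feats,
                  prior = rep(0.25, 4))
  grid <- seq(0, 100, by = 0.001)
  pred <- as.integer(as.character(
    stats::predict(ld, tibble::tibble(pct_active = grid))$class))
  # external decision points: where the predicted class steps up
  ext <- grid[which(diff(pred) > 0)]
  expect_equal(fit$boundaries, ext, tolerance = 0.01)
})

test_that("discriminant fit rejects degenerate classes", {
  feats <- tibble::tibble(category = c(1, 1, 2, 2, 3, 3, 4),
                          pct_active = c(1, 2, 11, 12, 30, 31, 70))
  expect_error(fit_boundaries_lda(feats), "category 4")
})

test_that("accuracy and confusion follow the gold-standard convention", {
  r <- classification_accuracy(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$accuracy, 1)
  r2 <- classification_accuracy(c(1, 2), c(1, 3))
  expect_equal(r2$accuracy, 0.5)
  expect_identical(unname(r2$confusion[3, 2]), 1L)  # clinical 3 predicted 2
  expect_equal(sum(r2$confusion), 2L, ignore_attr = TRUE)
  expect_error(classification_accuracy(1:3, 1:4), "same length")
  # tidy/glance surfaces
  expect_identical(nrow(tidy(r2)), 16L)
  expect_equal(glance(r2)$accuracy, 0.5)
})

test_that("cluster agreement is perfect for separated point masses", {
  v <- rep(c(0, 10, 20, 30), each = 5)
  lab <- rep(1:4, each = 5)
  expect_equal(as.numeric(cluster_agreement(v, lab)), 1)
  # label permutation of the clusters cannot hurt the optimal matching
  expect_equal(as.numeric(cluster_agreement(v, rep(c(2, 1, 4, 3), each = 5))),
               1)
})

test_that("degenerate identical values fall back to forced assignment", {
  v <- rep(1, 6)
  lab <- c(1, 1, 2, 3, 4, 4)
  got <- as.numeric(cluster_agreement(v, lab))
  # independent enumeration: a single occupied cluster mapped to any one
  # category captures at most that category's frequency
  oracle <- max(table(lab)) / length(lab)
  expect_equal(got, oracle)
})

test_that("cluster agreement equals a brute-force assignment oracle", {
  withr::with_seed(77, {
    v <- c(rnorm(10, 0, 1), rnorm(10, 4, 1), rnorm(10, 8, 1),
           rnorm(10, 12, 1))
    lab <- rep(1:4, each = 10)
    got <- cluster_agreement(v, lab)
    cl <- attr(got, "clusters")
    # enumerate all 24 injective cluster -> category maps
    perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
    best <- max(apply(perms, 1, function(r) sum(r[cl] == lab)))
    expect_equal(as.numeric(got), best / length(v))
  })
})

test_that("anova discrimination flags separated groups and not identical ones", {
  same <- tibble::tibble(g = rep(c("a", "b"), each = 5),
                         v = rep(c(1, 2, 3, 4, 5), 2))
  r <- anova_discrimination(same, "v", "g")
  expect_false(any(r$pairs$significant))

  apart <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                          v = c(0, 0.001, -0.001, 10, 10.001, 9.999))
  r2 <- anova_discrimination(apart, "v", "g")
  expect_true(all(r2$pairs$significant))
  expect_lt(r2$anova$p_value, 1e-6)

  expect_error(anova_discrimination(
    tibble::tibble(g = c("a", "a", "b"), v = 1:3), "v", "g"),
    "fewer than 2")
})

test_that("Fisher LSD matches a pooled two-group t-test on two groups", {
  withr::with_seed(91, {
    df <- tibble::tibble(g = rep(c("a", "b"), each = 8),
                         v = c(rnorm(8, 0), rnorm(8, 1)))
  })
  r <- anova_discrimination(df, "v", "g")
  tt <- t.test(v ~ g, data = df, var.equal = TRUE)
  expect_equal(r$pairs$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("category separations mirror the published difficulty ordering", {
  # under the default generator the category 1 vs 2 SVM contrast is the
  # smallest of all pairs, as in the published mean-SVM table
  cfg <- generator_config(seed = 1)
  withr::with_seed(41, {
    feats <- tibble::tibble(
      category = rep(1:4, each = 18),
      mean_svm = rlnorm(72, rep(cfg$svm_meanlog, each = 18),
                        rep(cfg$svm_sdlog, each = 18)))
  })
  r <- anova_discrimination(feats, "mean_svm", "category")
  d12 <- r$pairs$difference[r$pairs$group1 == "1" & r$pairs$group2 == "2"]
  expect_equal(min(r$pairs$difference), d12)
})
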