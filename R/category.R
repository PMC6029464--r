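# Four-level activity categorisation on a scalar feature, plus agreement
# statistics against the clinical labels.

#' Published category boundaries
#'
#' Fixed cut-offs for the four clinical activity levels in the post-fracture
#' ward population, on the two feature scales:
#' percent active minutes (category 1: 0--10, 2: >10--25, 3: >25--60,
#' 4: >60 %) and plain mean SVM per event (category 1: 0--0.0047,
#' 2: >0.0047--0.0072, 3: >0.0072--0.01, 4: >0.01 g).
#'
#' @name boundaries
#' @keywords internal
NULL

#' @rdname boundaries
#' @export
PCT_ACTIVE_BOUNDARIES <- c(10, 25, 60)

#' @rdname boundaries
#' @export
MEAN_SVM_BOUNDARIES <- c(0.0047, 0.0072, 0.01)

#' Construct a four-level category model
#'
#' A category model is a strictly increasing triple of boundaries `(b1, b2,
#' b3)` on one of the two feature scales, with intervals left-open and
#' right-closed: category 1 is `[0, b1]`, category 2 `(b1, b2]`, category 3
#' `(b2, b3]`, category 4 `(b3, Inf)`.
#'
#' @param scale `"pct_active"` or `"mean_svm"`.
#' @param boundaries Increasing numeric triple; `NULL` selects the published
#'   boundaries for the scale ([PCT_ACTIVE_BOUNDARIES] /
#'   [MEAN_SVM_BOUNDARIES]).
#' @param provenance Free-text origin tag (`"published"` for the defaults,
#'   `"lda-fitted"` for fitted models).
#' @return An object of class `category_model`.
#' @export
category_model <- function(scale = c("pct_active", "mean_svm"),
                           boundaries = NULL, provenance = NULL) {
  scale <- match.arg(scale)
  if (is.null(boundaries)) {
    boundaries <- if (scale == "pct_active") PCT_ACTIVE_BOUNDARIES
                  else MEAN_SVM_BOUNDARIES
    provenance <- provenance %||% "published"
  }
  provenance <- provenance %||% "custom"
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 3L || anyNA(boundaries) ||
      any(!is.finite(boundaries))) {
    stop("`boundaries` must be three finite numbers", call. = FALSE)
  }
  if (any(diff(boundaries) <= 0) || any(boundaries < 0)) {
    stop("`boundaries` must be non-negative and strictly increasing",
         call. = FALSE)
  }
  structure(list(scale = scale, boundaries = boundaries,
                 provenance = provenance),
            class = "category_model")
}

#' @export
print.category_model <- function(x, ...) {
  cat(sprintf("<category_model: %s scale, %s>\n", x$scale, x$provenance))
  b <- signif(x$boundaries, 6)
  cat(sprintf("  1: [0, %g]  2: (%g, %g]  3: (%g, %g]  4: (%g, Inf)\n",
              b[1], b[1], b[2], b[2], b[3], b[3]))
  invisible(x)
}

#' @exportS3Method
tidy.category_model <- function(x, ...) {
  b <- x$boundaries
  tibble::tibble(category = 1:4,
                 lower = c(0, b), upper = c(b, Inf),
                 scale = x$scale, provenance = x$provenance)
}

#' Classify feature values into activity categories
#'
#' Maps each non-negative feature value to a category 1--4 through the
#' model's left-open, right-closed intervals; a value exactly on a boundary
#' belongs to the lower category.
#'
#' @param values Numeric vector of feature values (>= 0; <= 100 on the
#'   percent scale).
#' @param model A [category_model()].
#' @return Integer vector of categories in `{1, 2, 3, 4}`.
#' @export
classify_category <- function(values, model) {
  stopifnot(inherits(model, "category_model"))
  if (any(values < 0, na.rm = TRUE)) {
    stop("feature values must be non-negative", call. = FALSE)
  }
  if (model$scale == "pct_active" && any(values > 100, na.rm = TRUE)) {
    stop("percent-active values cannot exceed 100", call. = FALSE)
  }
  b <- model$boundaries
  as.integer(1L + (values > b[1]) + (values > b[2]) + (values > b[3]))
}

#' Fit category boundaries by one-dimensional discriminant analysis
#'
#' Fits a Gaussian discriminant with equal priors to the labelled scalar
#' feature and returns the decision points between adjacent categories.
#' With a pooled (shared) variance the boundaries are the midpoints of
#' adjacent class means (linear discriminant). With per-class variances the
#' boundary between adjacent classes is the root of the quadratic
#' discriminant equation lying between the two class means.
#'
#' @param features Tibble with the feature and the clinical label.
#' @param value Column holding the feature (default `pct_active`).
#' @param class Column holding the clinical category (default `category`).
#' @param variance `"pooled"` (linear) or `"per_class"` (quadratic).
#' @param scale Feature scale recorded on the returned model.
#' @return A [category_model()] with provenance `"lda-fitted"` (or
#'   `"qda-fitted"`); attribute `class_stats` holds the per-class means, SDs
#'   and counts.
#' @export
fit_boundaries_lda <- function(features, value = "pct_active",
                               class = "category",
                               variance = c("pooled", "per_class"),
                               scale = c("pct_active", "mean_svm")) {
  variance <- match.arg(variance)
  scale <- match.arg(scale)
  v <- features[[value]]
  g <- as.integer(features[[class]])
  if (is.null(v)) stop(sprintf("no column `%s` in `features`", value),
                       call. = FALSE)
  for (k in 1:4) {
    if (sum(g == k, na.rm = TRUE) < 2L) {
      stop(sprintf("category %d has fewer than 2 events; cannot fit", k),
           call. = FALSE)
    }
  }
  st <- tibble::tibble(category = 1:4,
                       n = purrr::map_int(1:4, ~ sum(g == .x)),
                       mean = purrr::map_dbl(1:4, ~ mean(v[g == .x])),
                       sd = purrr::map_dbl(1:4, ~ stats::sd(v[g == .x])))
  if (any(diff(st$mean) <= 0)) {
    stop("class means are not increasing in category; boundaries undefined",
         call. = FALSE)
  }
  if (variance == "pooled") {
    bounds <- (st$mean[-4] + st$mean[-1]) / 2
    prov <- "lda-fitted"
  } else {
    bounds <- purrr::map_dbl(1:3, function(k) {
      qda_boundary(st$mean[k], st$sd[k], st$mean[k + 1], st$sd[k + 1])
    })
    prov <- "qda-fitted"
  }
  out <- category_model(scale = scale, boundaries = bounds, provenance = prov)
  attr(out, "class_stats") <- st
  out
}

# Root of the equal-prior quadratic discriminant between two Gaussians,
# constrained to (m1, m2); falls back to the midpoint when the variances
# coincide (the quadratic degenerates to the linear case).
qda_boundary <- function(m1, s1, m2, s2) {
  if (isTRUE(all.equal(s1, s2))) return((m1 + m2) / 2)
  a <- 1 / s1^2 - 1 / s2^2
  b <- -2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m1^2 / s1^2 - m2^2 / s2^2 + 2 * log(s1 / s2)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real discriminant boundary between classes",
                     call. = FALSE)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) == 0L) {
    stop("no discriminant root between the class means", call. = FALSE)
  }
  inside[1]
}

#' Classification accuracy against the clinical gold standard
#'
#' @param predicted,clinical Equal-length vectors of categories 1--4;
#'   `clinical` is the gold standard.
#' @return An `agreement_report` with elements `accuracy` (fraction correct)
#'   and `confusion` (4x4 count matrix, rows = clinical, columns =
#'   predicted); [generics::tidy()] and [generics::glance()] methods apply.
#' @export
classification_accuracy <- function(predicted, clinical) {
  if (length(predicted) != length(clinical)) {
    stop("`predicted` and `clinical` must have the same length",
         call. = FALSE)
  }
  if (length(predicted) == 0L) stop("no events to score", call. = FALSE)
  p <- factor(as.integer(predicted), levels = 1:4)
  c_ <- factor(as.integer(clinical), levels = 1:4)
  confusion <- table(clinical = c_, predicted = p)
  structure(list(accuracy = mean(p == c_), confusion = unclass(confusion),
                 n = length(p)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement with clinical categories: %.1f%% of %d events\n",
              100 * x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method
tidy.agreement_report <- function(x, ...) {
  as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::rename(count = "Freq")
}

#' @exportS3Method
glance.agreement_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n)
}

#' Agreement between unsupervised clusters and clinical categories
#'
#' Partitions the scalar feature into `k` clusters (1-D k-means, 50
#' restarts), maps cluster labels to clinical categories by the one-to-one
#' assignment that maximises matches (exhaustive over the k! permutations),
#' and returns the matched fraction. When the data contain fewer distinct
#' values than `k`, each distinct value forms its own cluster and the
#' remaining clusters stay empty (forced assignment).
#'
#' @param values Numeric feature vector.
#' @param clinical Clinical categories 1--4, same length.
#' @param k Number of clusters.
#' @param nstart Random restarts for k-means.
#' @return Fraction of events whose optimally mapped cluster equals the
#'   clinical category; attributes `assignment` (cluster -> category map)
#'   and `clusters` (cluster index per event).
#' @export
cluster_agreement <- function(values, clinical, k = 4, nstart = 50) {
  n <- length(values)
  if (n < k) stop(sprintf("need at least k = %d values, got %d", k, n),
                  call. = FALSE)
  if (length(clinical) != n) {
    stop("`values` and `clinical` must have the same length", call. = FALSE)
  }
  uniq <- sort(unique(values))
  if (length(uniq) < k) {
    cl <- match(values, uniq)
  } else {
    km <- stats::kmeans(values, centers = k, nstart = nstart)
    # relabel clusters in increasing-centre order so the map is reproducible
    ord <- order(km$centers[, 1])
    cl <- match(km$cluster, ord)
  }
  perms <- permutations_4(k)
  best <- -1L
  best_map <- NULL
  for (i in seq_len(nrow(perms))) {
    mapped <- perms[i, cl]
    hits <- sum(mapped == clinical)
    if (hits > best) {
      best <- hits
      best_map <- perms[i, ]
    }
  }
  out <- best / n
  attr(out, "assignment") <- best_map
  attr(out, "clusters") <- cl
  out
}

# All permutations of 1..k (k <= 4 here, so at most 24 rows).
permutations_4 <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_4(k - 1L)
  out <- NULL
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  colnames(out) <- NULL
  out
}

#' One-way ANOVA with pairwise post-hoc discrimination
#'
#' Tests whether the feature discriminates the clinical categories: a
#' one-way ANOVA across groups followed by pairwise post-hoc comparisons.
#' The default post-hoc is Fisher's LSD, reporting for each pair the
#' critical average difference at `alpha` (the smallest mean difference that
#' would be declared significant) and whether the observed difference
#' exceeds it; Tukey's HSD is available instead.
#'
#' @param features Tibble with the feature and group columns.
#' @param value,group Column names (strings) of the feature and the
#'   category.
#' @param alpha Significance level.
#' @param posthoc `"lsd"` (Fisher) or `"tukey"`.
#' @return An `anova_discrimination` object: `anova` (the `aov` summary
#'   row), `pairs` (tibble: group pair, means, observed difference, critical
#'   difference, p-value, significant), `alpha`, `posthoc`. `tidy()` returns
#'   the pairs table; `glance()` the ANOVA row; `print()` mirrors the
#'   triangular critical-difference / yes-no layout.
#' @export
anova_discrimination <- function(features, value, group, alpha = 0.05,
                                 posthoc = c("lsd", "tukey")) {
  posthoc <- match.arg(posthoc)
  v <- features[[value]]
  g <- factor(features[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  lev <- levels(g)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- table(g)
  if (any(ns < 2L)) {
    stop(sprintf("group %s has fewer than 2 values",
                 lev[which(ns < 2L)[1]]), call. = FALSE)
  }
  fit <- stats::aov(v ~ g)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  means <- tapply(v, g, mean)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  ptab <- purrr::map(pairs, function(pr) {
    ni <- ns[[pr[1]]]; nj <- ns[[pr[2]]]
    se <- sqrt(mse * (1 / ni + 1 / nj))
    diff <- abs(means[[pr[2]]] - means[[pr[1]]])
    if (posthoc == "lsd") {
      crit <- stats::qt(1 - alpha / 2, dfe) * se
      p <- 2 * stats::pt(-diff / se, dfe)
    } else {
      crit <- stats::qtukey(1 - alpha, length(lev), dfe) * se / sqrt(2)
      p <- stats::ptukey(diff / se * sqrt(2), length(lev), dfe,
                         lower.tail = FALSE)
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   mean1 = means[[pr[1]]], mean2 = means[[pr[2]]],
                   difference = diff, critical_difference = crit,
                   p_value = p, significant = diff > crit)
  }) |> purrr::list_rbind()
  structure(list(anova = tibble::tibble(
                   df_between = an[1, "Df"], df_within = dfe,
                   f_statistic = an[1, "F value"],
                   p_value = an[1, "Pr(>F)"], mse = mse),
                 pairs = ptab, means = means, alpha = alpha,
                 posthoc = posthoc),
            class = "anova_discrimination")
}

#' @exportS3Method
tidy.anova_discrimination <- function(x, ...) x$pairs

#' @exportS3Method
glance.anova_discrimination <- function(x, ...) x$anova

#' @export
print.anova_discrimination <- function(x, ...) {
  lev <- names(x$means)
  k <- length(lev)
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g (%s post-hoc, alpha = %g)\n",
              x$anova$f_statistic, x$anova$p_value, x$posthoc, x$alpha))
  # triangular layout: critical differences above the diagonal,
  # yes/no significance below
  m <- matrix("-", k, k, dimnames = list(lev, lev))
  for (i in seq_len(nrow(x$pairs))) {
    r <- x$pairs[i, ]
    m[r$group1, r$group2] <- formatC(r$critical_difference, digits = 4,
                                     format = "g")
    m[r$group2, r$group1] <- ifelse(r$significant, "yes", "no")
  }
  tab <- cbind(mean = formatC(unname(x$means), digits = 4, format = "g"), m)
  print(tab, quote = FALSE)
  invisible(x)
}
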