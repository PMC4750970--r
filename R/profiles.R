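# Pass 2, mixture-ratio reconstruction: vertical pixel-line "profiles" are
# extracted from spotted pollen regions, filtered by information content,
# and classified by an equal-weight ensemble of near/far Manhattan-distance
# rules; the fraction of profiles voted to the first class is the slide's
# predicted mixture ratio.

#' Information content of a profile
#'
#' Mean absolute difference of adjacent pixel intensities,
#' `IC = (1/n) * sum_i |x_i - x_{i+1}|` with `n = length - 1`, in intensity
#' units per pixel.  High values indicate in-focus, high-contrast lines;
#' profiles with `IC < 5.0` are conventionally discarded as out of focus.
#'
#' @param p numeric vector of pixel intensities (length >= 2).
#' @export
info_content <- function(p) {
  if (length(p) < 2L) stopf("a profile needs at least 2 pixels")
  mean(abs(diff(p)))
}

#' Extract qualifying vertical profiles from a plane
#'
#' A profile is a vertical line of `L` contiguous pixels that (1) lies
#' entirely inside the pollen mask and (2) has information content at least
#' `ic_min`.  The scan is deterministic and column-major: columns left to
#' right, start rows top to bottom.
#'
#' @param plane numeric matrix (single channel).
#' @param mask binary matrix matching `plane` (1 = pollen).
#' @param L profile length in pixels.
#' @param ic_min information-content threshold (intensity units per pixel;
#'   default 5.0).
#' @param row_stride,col_stride scan strides (1 = every start considered).
#' @return list with `profiles` (n x L matrix) and `origins`
#'   (data.frame of 0-based `row`, `col`).
#' @export
extract_profiles <- function(plane, mask, L, ic_min = 5.0,
                             row_stride = 1L, col_stride = 1L) {
  plane <- as.matrix(plane)
  mask <- as.matrix(mask)
  if (!identical(dim(plane), dim(mask)))
    stopf("plane and mask dimensions differ")
  if (!is_count(L, min = 2L) || L > nrow(plane))
    stopf("profile length %s invalid for plane height %d", format(L),
          nrow(plane))
  storage.mode(mask) <- "integer"
  res <- cpp_extract_profiles(plane, mask, as.integer(L), ic_min,
                              as.integer(row_stride), as.integer(col_stride))
  list(profiles = res$profiles,
       origins = data.frame(row = res$row, col = res$col))
}

#' Manhattan distance between two profiles
#' @param p,r numeric vectors of equal length.
#' @export
manhattan_dist <- function(p, r) {
  if (length(p) != length(r))
    stopf("profile lengths differ: %d vs %d", length(p), length(r))
  sum(abs(p - r))
}

# Canonical two-class bookkeeping: classes in first-seen-sorted order; the
# first class ("class A", black spruce in the motivating problem) wins
# documented tie-breaks when priors are equal.
profile_classes <- function(labels) {
  cl <- sort(unique(as.character(labels)))
  if (length(cl) > 2L) stopf("profile classification is two-class")
  cl
}

# Core rule construction from a precomputed candidate-to-training distance
# vector; threshold search is exhaustive over the distinct distances.
rule_from_distances <- function(d, labels, reference, classes, priors) {
  is_a <- as.character(labels) == classes[1]
  nA <- sum(is_a); nB <- length(labels) - nA
  if (nA == 0L || nB == 0L) {
    warning("single-class training set: degenerate rule (error 0 by convention)")
    only <- if (nA > 0L) classes[1] else classes[2]
    return(new_profile_rule(reference, max(d), c(nA, nB), c(0L, 0L),
                            only, only, 0, classes, priors))
  }
  ord <- order(d)
  du <- d[ord]
  cumA <- cumsum(is_a[ord])
  cumB <- seq_along(du) - cumA
  last <- !duplicated(du, fromLast = TRUE)  # last occurrence of each distinct d
  tA <- cumA[last]; tB <- cumB[last]; tu <- du[last]
  # bin predictions: majority joint count, tie -> larger prior, then class A
  tie_class <- if (priors[2] > priors[1]) classes[2] else classes[1]
  near_pred <- ifelse(tA > tB, classes[1], ifelse(tB > tA, classes[2], tie_class))
  farA <- nA - tA; farB <- nB - tB
  far_pred <- ifelse(farA > farB, classes[1],
                     ifelse(farB > farA, classes[2], tie_class))
  err <- ifelse(near_pred == classes[1], tB, tA) +
         ifelse(far_pred == classes[1], farB, farA)
  best <- which.min(err)  # ties -> smallest threshold (first index)
  new_profile_rule(reference, tu[best],
                   c(tA[best], tB[best]), c(farA[best], farB[best]),
                   near_pred[best], far_pred[best],
                   err[best] / length(labels), classes, priors)
}

new_profile_rule <- function(reference, threshold, near_counts, far_counts,
                             near_class, far_class, error_rate, classes,
                             priors) {
  structure(list(reference = as.numeric(reference), threshold = threshold,
                 near_counts = stats::setNames(as.numeric(near_counts), classes),
                 far_counts = stats::setNames(as.numeric(far_counts), classes),
                 near_class = near_class, far_class = far_class,
                 error_rate = error_rate, classes = classes,
                 priors = stats::setNames(as.numeric(priors), classes)),
            class = "profile_rule")
}

#' Evaluate a candidate rule profile against a labeled training set
#'
#' Computes Manhattan distances from the candidate to every training
#' profile, searches the near/far threshold exhaustively over the distinct
#' observed distances, and keeps the threshold minimizing training error.
#' Each bin (near: distance <= threshold; far: beyond) predicts the class
#' with the larger joint count in that bin (ties fall to the larger-prior
#' class, then to the first class).
#'
#' @param candidate numeric profile (the rule's reference line).
#' @param train n x L matrix of training profiles.
#' @param labels length-n class labels (two classes).
#' @return a `profile_rule` with the chosen threshold, per-bin class
#'   counts, bin predictions and training `error_rate`.
#' @export
evaluate_rule <- function(candidate, train, labels) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stopf("training set is empty")
  if (length(candidate) != ncol(train))
    stopf("candidate length %d does not match training profiles (%d)",
          length(candidate), ncol(train))
  classes <- profile_classes(labels)
  if (length(classes) == 1L) classes <- c(classes, paste0(classes, "_other"))
  priors <- c(sum(labels == classes[1]), sum(labels == classes[2]))
  d <- cpp_manhattan_matrix(matrix(as.numeric(candidate), nrow = 1), train)[1, ]
  rule_from_distances(d, labels, candidate, classes, priors)
}

#' Learn a pool of rules and keep the best as an equal-weight ensemble
#'
#' Candidate rule profiles are drawn at random from the training set
#' (seeded), each optimized and scored by [evaluate_rule()], then
#' rank-ordered by training error; the top `k` form the ensemble.
#'
#' @param train n x L matrix of labeled training profiles.
#' @param labels length-n class labels.
#' @param n_rules number of candidate rules to sample and evaluate
#'   (default 1024; capped at n when sampling without replacement).
#' @param k ensemble size (top-k by error rate).
#' @param seed integer seed for candidate sampling.
#' @return a `rule_ensemble`.
#' @export
learn_rule_ensemble <- function(train, labels, n_rules = 1024L, k = 128L,
                                seed = 1L) {
  train <- as.matrix(train)
  n <- nrow(train)
  if (n < 2L) stopf("need at least 2 training profiles")
  classes <- profile_classes(labels)
  priors <- c(sum(labels == classes[1]), sum(labels == classes[2]))
  idx <- with_seed(seed, {
    if (n_rules <= n) sample.int(n, n_rules)
    else sample.int(n, n_rules, replace = TRUE)
  })
  D <- cpp_manhattan_matrix(train[idx, , drop = FALSE], train)
  rules <- lapply(seq_along(idx), function(i)
    rule_from_distances(D[i, ], labels, train[idx[i], ], classes, priors))
  build_ensemble(rules, min(k, length(rules)))
}

#' Combine the top-k rules into an equal-weight ensemble
#'
#' Rules are sorted by ascending training error rate (stable for ties:
#' first-evaluated first) and the best `k` kept with equal voting weight.
#'
#' @param rules list of `profile_rule` objects.
#' @param k number of rules to keep (`1 <= k <= length(rules)`).
#' @export
build_ensemble <- function(rules, k) {
  if (!is_count(k)) stopf("`k` must be a positive integer")
  if (k > length(rules)) stopf("k = %d exceeds the %d available rules",
                               k, length(rules))
  ord <- order(vapply(rules, `[[`, numeric(1), "error_rate"))
  top <- rules[ord][seq_len(k)]
  structure(list(rules = top, k = as.integer(k),
                 classes = top[[1]]$classes, priors = top[[1]]$priors),
            class = "rule_ensemble")
}

#' Classify profiles by equal-weight majority vote of the ensemble's rules
#'
#' Each rule votes its near-bin class when the profile lies within the
#' rule's threshold of its reference line, its far-bin class otherwise.
#' Vote ties go to the larger-prior class (then to the first class).
#'
#' @param ensemble a `rule_ensemble`.
#' @param profiles n x L matrix (or a single profile vector).
#' @return character vector of predicted classes.
#' @export
classify_profiles <- function(ensemble, profiles) {
  stopifnot(inherits(ensemble, "rule_ensemble"))
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  profiles <- as.matrix(profiles)
  refs <- do.call(rbind, lapply(ensemble$rules, `[[`, "reference"))
  D <- cpp_manhattan_matrix(refs, profiles)  # k x n
  classes <- ensemble$classes
  k <- length(ensemble$rules)
  votes_a <- numeric(ncol(D))
  for (j in seq_len(k)) {
    r <- ensemble$rules[[j]]
    pred <- ifelse(D[j, ] <= r$threshold, r$near_class, r$far_class)
    votes_a <- votes_a + (pred == classes[1])
  }
  tie_class <- if (ensemble$priors[2] > ensemble$priors[1]) classes[2] else classes[1]
  ifelse(votes_a * 2 > k, classes[1],
         ifelse(votes_a * 2 < k, classes[2], tie_class))
}

#' Predicted mixture ratio of a slide
#'
#' The fraction of the slide's profiles voted to the first class by the
#' ensemble — the raw voted fraction, deliberately uncalibrated.
#'
#' @param ensemble a `rule_ensemble`.
#' @param profiles n x L matrix of the slide's profiles.
#' @return the fraction in `[0, 1]`, or `NA` with attribute
#'   `abstained = TRUE` (and a warning) when no profiles are available.
#' @export
predict_slide_ratio <- function(ensemble, profiles) {
  if (is.null(profiles) || NROW(profiles) == 0L) {
    warning("no profiles extracted from slide: abstaining")
    return(structure(NA_real_, abstained = TRUE))
  }
  pred <- classify_profiles(ensemble, profiles)
  mean(pred == ensemble$classes[1])
}

#' Coefficient of determination between predicted and actual ratios
#'
#' r-squared of the ordinary least-squares regression of `predicted` on
#' `actual` — the accuracy measure for slide-ratio reconstruction.
#'
#' @param predicted,actual numeric vectors of equal length (>= 3);
#'   `actual` must not be constant.
#' @export
r_squared <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) < 3L)
    stopf("need equal-length vectors of at least 3 ratios")
  if (stats::sd(actual) == 0) stopf("`actual` is constant: r^2 undefined")
  if (stats::sd(predicted) == 0) return(0)  # no variance explained
  fit <- stats::lm(predicted ~ actual)
  1 - sum(stats::residuals(fit)^2) / sum((predicted - mean(predicted))^2)
}
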