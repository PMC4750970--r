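# End-to-end wiring of the two-pass pipeline: profile collection across a
# slide's z-planes, and the mixture-ratio experiment (train rules on pure
# reference slides, predict the ratio series, score r^2).

#' Collect qualifying profiles from a slide
#'
#' Selects every `z_step`-th z-plane, takes the configured channel, obtains
#' the pollen mask for each plane (from a trained spotting model when one
#' is supplied, else from the provided ground-truth mask), extracts
#' vertical profiles passing the information-content filter, pools them
#' across planes, and optionally subsamples to at most `max_profiles`
#' (seeded).
#'
#' @param stack an [image_stack()].
#' @param mask binary ground-truth pollen mask (used when `spotter` is
#'   `NULL`).
#' @param L profile length in pixels.
#' @param ic_min information-content threshold (default 5.0).
#' @param z_step keep every `z_step`-th plane (default 1).
#' @param channel 0-based channel (default 0, the red band of RGB data).
#' @param row_stride,col_stride profile scan strides.
#' @param max_profiles cap on returned profiles (default unlimited).
#' @param seed seed for the subsample.
#' @param spotter optional trained spotting `hash_model`.
#' @return n x L profile matrix (possibly 0-row).
#' @export
collect_slide_profiles <- function(stack, mask = NULL, L, ic_min = 5.0,
                                   z_step = 1L, channel = 0L,
                                   row_stride = 1L, col_stride = 1L,
                                   max_profiles = Inf, seed = 1L,
                                   spotter = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  sel <- select_planes(stack, z_step)
  pooled <- list()
  for (z in seq_along(sel$planes)) {
    plane <- sel$planes[[z]][, , channel + 1L]
    m <- if (!is.null(spotter)) {
      w <- gh_window(sel$planes[[z]])
      predict_window_mask(spotter, w)
    } else {
      if (is.null(mask)) stopf("either a mask or a spotting model is required")
      as.matrix(mask)
    }
    pr <- extract_profiles(plane, m, L, ic_min, row_stride, col_stride)
    if (nrow(pr$profiles) > 0L) pooled[[length(pooled) + 1L]] <- pr$profiles
  }
  if (length(pooled) == 0L) return(matrix(numeric(0), ncol = L))
  all_pr <- do.call(rbind, pooled)
  if (is.finite(max_profiles) && nrow(all_pr) > max_profiles) {
    keep <- with_seed(seed, sample.int(nrow(all_pr), max_profiles))
    all_pr <- all_pr[keep, , drop = FALSE]
  }
  all_pr
}

#' Reconstruct mixture ratios for a slide series from pure reference slides
#'
#' Trains a near/far rule ensemble on profiles pooled from pure reference
#' slides (class A = ratio-1 slides), predicts the class-A profile fraction
#' of every test slide, and scores the coefficient of determination
#' against the true ratios.
#'
#' @param reference list of `synthetic_slide` records (or equivalent lists
#'   with `stack`, `mask`, `label` in `{"A","B"}` or `{1, 0}`).
#' @param test list of slide records with numeric true-ratio `label`.
#' @param L profile length (default 40; must fit inside grain interiors).
#' @param ic_min information-content threshold (default 5.0).
#' @param z_step plane step (default 1).
#' @param channel 0-based channel (default 0).
#' @param row_stride,col_stride profile scan strides (default 2 for speed).
#' @param max_profiles_per_slide profile cap per slide.
#' @param n_rules candidate rules to evaluate.
#' @param k ensemble size.
#' @param seed integer seed.
#' @param spotter optional spotting model used to produce pollen masks
#'   (ground-truth masks are used when `NULL`).
#' @return list with `ensemble`, `predicted`, `actual`, `r_squared`, `fit`
#'   (slope/intercept of predicted on actual).
#' @export
run_ratio_experiment <- function(reference, test, L = 40L, ic_min = 5.0,
                                 z_step = 1L, channel = 0L,
                                 row_stride = 2L, col_stride = 2L,
                                 max_profiles_per_slide = 400L,
                                 n_rules = 512L, k = 64L, seed = 1L,
                                 spotter = NULL) {
  train_profiles <- list(); train_labels <- character(0)
  for (i in seq_along(reference)) {
    sl <- reference[[i]]
    lab <- sl$label
    cls <- if (identical(lab, "A") || identical(lab, 1) || identical(lab, 1L))
      "A" else "B"
    pr <- collect_slide_profiles(sl$stack, sl$mask, L, ic_min, z_step,
                                 channel, row_stride, col_stride,
                                 max_profiles_per_slide,
                                 seed = derive_seed(seed, i),
                                 spotter = spotter)
    if (nrow(pr) > 0L) {
      train_profiles[[length(train_profiles) + 1L]] <- pr
      train_labels <- c(train_labels, rep(cls, nrow(pr)))
    }
  }
  train <- do.call(rbind, train_profiles)
  ensemble <- learn_rule_ensemble(train, train_labels, n_rules = n_rules,
                                  k = k, seed = derive_seed(seed, 0L))
  predicted <- numeric(length(test)); actual <- numeric(length(test))
  for (i in seq_along(test)) {
    sl <- test[[i]]
    pr <- collect_slide_profiles(sl$stack, sl$mask, L, ic_min, z_step,
                                 channel, row_stride, col_stride,
                                 max_profiles_per_slide,
                                 seed = derive_seed(seed, 1000L + i),
                                 spotter = spotter)
    predicted[i] <- predict_slide_ratio(ensemble, pr)
    actual[i] <- as.numeric(sl$label)
  }
  fit <- stats::lm(predicted ~ actual)
  list(ensemble = ensemble, predicted = predicted, actual = actual,
       r_squared = r_squared(predicted, actual),
       fit = c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2])))
}
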