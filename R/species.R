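# Pass 2, grain-level species classification: sample square windows from
# slides, keep those with enough spotted pollen, classify each pollen pixel
# with a species hash model (positive = first class), gate window calls by
# pixel-vote confidence, and aggregate classified windows to a slide call.

#' Configuration for the window species classifier
#'
#' @param window_size window side length in pixels (default 256).
#' @param windows_per_slide windows sampled per slide for training.
#' @param test_windows_per_slide windows sampled per held-out slide during
#'   cross-validation (default 100).
#' @param min_pollen_fraction minimum spotted-pollen fraction for a window
#'   to qualify (default 0.5: "greater than 50% pollen content").
#' @param confidence_min minimum pixel-vote confidence, in percent, below
#'   which a window is abstained (default 43.61, the optimum found by
#'   seeded random search for the spruce discrimination problem).
#' @param min_classifications_per_slide minimum number of windows that must
#'   be classified per slide; abstained windows are force-classified in
#'   descending confidence order until it is met (default 1).
#' @param spec [grid_spec()] of the species pixel model (default grid 3x3,
#'   spacing 10, quantization 14.24 — the random-search optimum for the
#'   spruce discrimination problem).
#' @param max_attempts_factor sampling tries per requested window before
#'   giving up (default 50).
#' @export
window_classifier_config <- function(window_size = 256L,
                                     windows_per_slide = 1232L,
                                     test_windows_per_slide = 100L,
                                     min_pollen_fraction = 0.5,
                                     confidence_min = 43.61,
                                     min_classifications_per_slide = 1L,
                                     spec = grid_spec(grid_size = 3L,
                                                      grid_spacing = 10L,
                                                      quantization = 14.24),
                                     max_attempts_factor = 50L) {
  stopifnot(is_count(window_size), is_count(windows_per_slide),
            is_count(min_classifications_per_slide),
            inherits(spec, "grid_spec"))
  if (min_pollen_fraction < 0 || min_pollen_fraction > 1)
    stopf("`min_pollen_fraction` must lie in [0, 1]")
  if (confidence_min < 0 || confidence_min > 100)
    stopf("`confidence_min` must lie in [0, 100]")
  structure(list(window_size = as.integer(window_size),
                 windows_per_slide = as.integer(windows_per_slide),
                 test_windows_per_slide = as.integer(test_windows_per_slide),
                 min_pollen_fraction = min_pollen_fraction,
                 confidence_min = confidence_min,
                 min_classifications_per_slide =
                   as.integer(min_classifications_per_slide),
                 spec = spec,
                 max_attempts_factor = as.integer(max_attempts_factor)),
            class = "window_classifier_config")
}

#' Sample pollen-rich windows from a slide
#'
#' Draws seeded uniform window origins (over all z-planes) and keeps only
#' windows whose spotted-pollen fraction exceeds
#' `cfg$min_pollen_fraction`, until `cfg$windows_per_slide` qualify or the
#' attempt budget is exhausted.
#'
#' @param stack an [image_stack()].
#' @param mask binary pollen mask (matrix shared by all z-planes, or list
#'   of per-plane matrices).
#' @param cfg a [window_classifier_config()].
#' @param seed integer sampling seed.
#' @param n_windows optional override of `cfg$windows_per_slide`.
#' @return list of `gh_window` objects with masks attached (possibly empty,
#'   with a warning, when no window qualifies).
#' @export
sample_windows <- function(stack, mask, cfg, seed,
                           n_windows = cfg$windows_per_slide) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(cfg, "window_classifier_config"))
  d <- dim(stack$planes[[1]])
  ws <- cfg$window_size
  if (ws > d[1] || ws > d[2])
    stopf("window size %d exceeds plane dimensions %d x %d", ws, d[1], d[2])
  nz <- length(stack$planes)
  masks <- if (is.list(mask)) mask else rep(list(as.matrix(mask)), nz)
  out <- list()
  max_attempts <- cfg$max_attempts_factor * n_windows
  with_seed(seed, {
    attempts <- 0L
    while (length(out) < n_windows && attempts < max_attempts) {
      attempts <- attempts + 1L
      z <- sample.int(nz, 1L) - 1L
      r0 <- sample.int(d[1] - ws + 1L, 1L) - 1L
      c0 <- sample.int(d[2] - ws + 1L, 1L) - 1L
      m <- masks[[z + 1L]][r0 + seq_len(ws), c0 + seq_len(ws)]
      if (mean(m) > cfg$min_pollen_fraction) {
        w <- extract_window(stack, z, r0, c0, ws, ws)
        out[[length(out) + 1L]] <- set_window_mask(w, m)
      }
    }
  })
  if (length(out) == 0L)
    warning("no window reached the minimum pollen fraction; returning none")
  out
}

#' Pixel-vote confidence of a window call
#'
#' The absolute difference between the two class fractions of the window's
#' classified pollen pixels, in percent: a 100%/0% split gives confidence
#' 100, a 50%/50% split gives 0.
#'
#' @param frac_a,frac_b class fractions over classified pollen pixels
#'   (must sum to 1).
#' @export
window_confidence <- function(frac_a, frac_b) {
  if (is.na(frac_a) || is.na(frac_b))
    stopf("confidence is undefined without classified pollen pixels")
  if (abs(frac_a + frac_b - 1) > 1e-8)
    stopf("class fractions must sum to 1 (got %g + %g)", frac_a, frac_b)
  abs(frac_a - frac_b) * 100
}

#' Classify one window, with confidence gating
#'
#' Every mask-positive pixel is classified by the species model (positive
#' count > negative count calls the first class); the window's call is the
#' pixel majority, abstained when the confidence falls below
#' `confidence_min` or when the window holds no pollen pixels.
#'
#' @param model species `hash_model` (positive label = class A).
#' @param window a `gh_window`.
#' @param mask binary pollen mask for the window (defaults to the window's
#'   own mask).
#' @param confidence_min abstention threshold in percent.
#' @param classes length-2 class names (`c("A", "B")` by default).
#' @return list with `class` (`NA` when abstained), `confidence`,
#'   `abstained`, `frac_a`, `n_pixels`.
#' @export
classify_window <- function(model, window, mask = window$mask,
                            confidence_min = 0,
                            classes = c("A", "B")) {
  stopifnot(inherits(model, "hash_model"), inherits(window, "gh_window"))
  if (is.null(mask)) stopf("window has no pollen mask")
  mask <- as.matrix(mask)
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(list(class = NA_character_, confidence = NA_real_,
                abstained = TRUE, frac_a = NA_real_, n_pixels = 0L))
  bins <- pixel_bins(window$pixels, idx[, 1] - 1L, idx[, 2] - 1L,
                     model$spec, model$seed)
  pred <- predict_bins(model, bins)
  frac_a <- mean(pred$label == 1L)
  conf <- window_confidence(frac_a, 1 - frac_a)
  cls <- if (frac_a > 0.5) classes[1] else classes[2]
  list(class = if (conf < confidence_min) NA_character_ else cls,
       confidence = conf, abstained = conf < confidence_min,
       frac_a = frac_a, n_pixels = nrow(idx), voted_class = cls)
}

#' Aggregate window calls to a slide-level species call
#'
#' Windows passing the confidence gate vote with equal weight; if fewer
#' than `cfg$min_classifications_per_slide` pass, abstained windows are
#' force-classified in descending confidence order until the minimum is
#' met.  The slide call is the majority class (ties broken by the larger
#' summed confidence).
#'
#' @param model species `hash_model`.
#' @param windows list of `gh_window` objects with pollen masks.
#' @param cfg a [window_classifier_config()].
#' @param classes length-2 class names.
#' @return list with `class`, `n_classified`, `n_forced`, and a
#'   per-window data.frame `detail`.
#' @export
classify_slide <- function(model, windows, cfg, classes = c("A", "B")) {
  stopifnot(inherits(cfg, "window_classifier_config"))
  if (length(windows) < 1L) stopf("at least one window is required")
  res <- lapply(windows, classify_window, model = model,
                confidence_min = cfg$confidence_min, classes = classes)
  detail <- data.frame(
    voted_class = vapply(res, function(r) r$voted_class %||% NA_character_,
                         character(1)),
    confidence = vapply(res, `[[`, numeric(1), "confidence"),
    abstained = vapply(res, `[[`, logical(1), "abstained"),
    n_pixels = vapply(res, `[[`, integer(1), "n_pixels"))
  usable <- !is.na(detail$voted_class)
  classified <- usable & !detail$abstained
  n_forced <- 0L
  need <- cfg$min_classifications_per_slide - sum(classified)
  if (need > 0L) {
    pool <- which(usable & detail$abstained)
    pool <- pool[order(detail$confidence[pool], decreasing = TRUE)]
    force_idx <- head(pool, need)
    classified[force_idx] <- TRUE
    n_forced <- length(force_idx)
  }
  detail$classified <- classified
  if (!any(classified))
    return(list(class = NA_character_, n_classified = 0L, n_forced = n_forced,
                detail = detail))
  votes <- table(factor(detail$voted_class[classified], levels = classes))
  cls <- if (votes[1] > votes[2]) classes[1]
         else if (votes[2] > votes[1]) classes[2]
         else {  # tie: larger summed confidence wins; equal -> class A
    conf_a <- sum(detail$confidence[classified &
                                    detail$voted_class == classes[1]])
    conf_b <- sum(detail$confidence[classified &
                                    detail$voted_class == classes[2]])
    if (conf_b > conf_a) classes[2] else classes[1]
  }
  list(class = cls, n_classified = sum(classified), n_forced = n_forced,
       detail = detail)
}

#' Train a species pixel model from pure-slide windows
#'
#' Grid examples are built only for mask-positive (pollen) pixels; windows
#' come from pure reference slides so the class label is certain.  The
#' first class is the model's positive label.
#'
#' @param windows list of `gh_window` objects with pollen masks.
#' @param labels per-window class labels (two classes).
#' @param spec a [grid_spec()].
#' @param seed integer random-table seed.
#' @param classes length-2 class names (defaults to sorted unique labels).
#' @export
train_species_model <- function(windows, labels, spec, seed,
                                classes = sort(unique(as.character(labels)))) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(windows) != length(labels)) stopf("one label per window required")
  B <- as.integer(spec$bins)
  pos <- numeric(B); neg <- numeric(B)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (is.null(w$mask)) stopf("window %d has no pollen mask", i)
    idx <- which(w$mask == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    bins <- pixel_bins(w$pixels, idx[, 1] - 1L, idx[, 2] - 1L, spec, seed)
    tab <- tabulate(bins + 1L, nbins = B)
    if (as.character(labels[i]) == classes[1]) pos <- pos + tab
    else neg <- neg + tab
  }
  new_hash_model(spec, seed, pos, neg)
}

#' Leave-two-slides-out cross-validation of slide classification
#'
#' Each repeat holds out 2 slides, trains the species model on windows
#' sampled from the remainder (resampling the split when a class is absent
#' from the training side), and scores the fraction of held-out slides
#' called correctly.
#'
#' @param slides list of slide records: each a list with `stack`
#'   ([image_stack()]), `mask` (binary pollen mask) and `label` (class).
#' @param cfg a [window_classifier_config()].
#' @param n_repeats number of seeded random splits (default 10).
#' @param seed integer seed.
#' @param n_holdout number of held-out slides per repeat (default 2).
#' @param permute_labels permutation-null mode: redraw a random permutation
#'   of the slide labels in every repeat before splitting, destroying the
#'   label-texture association.  A fresh permutation per repeat gives the
#'   proper permutation distribution; a fixed permutation at this slide
#'   count suffers the well-known below-chance "anti-learning" artifact of
#'   cross-validation under permuted labels.
#' @return list with `accuracy` (mean over held-out slide calls),
#'   `per_repeat` accuracies, `sd`, and a data.frame `calls`.
#' @export
cross_validate_slides <- function(slides, cfg, n_repeats = 10L, seed = 1L,
                                  n_holdout = 2L, permute_labels = FALSE) {
  stopifnot(inherits(cfg, "window_classifier_config"))
  n <- length(slides)
  if (n < 4L) stopf("need at least 4 slides for leave-%d-out", n_holdout)
  labels <- vapply(slides, `[[`, character(1), "label")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stopf("slide labels must form two classes")
  calls <- list()
  per_repeat <- numeric(n_repeats)
  true_labels <- labels
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, rep_i)
    if (permute_labels)
      labels <- with_seed(derive_seed(rep_seed, 999L), sample(true_labels))
    test_idx <- with_seed(rep_seed, {
      repeat {
        ti <- sample.int(n, n_holdout)
        if (length(unique(labels[-ti])) == 2L) break
      }
      ti
    })
    train_windows <- list(); train_labels <- character(0)
    for (i in setdiff(seq_len(n), test_idx)) {
      sw <- sample_windows(slides[[i]]$stack, slides[[i]]$mask, cfg,
                           seed = derive_seed(rep_seed, i))
      train_windows <- c(train_windows, sw)
      train_labels <- c(train_labels, rep(labels[i], length(sw)))
    }
    model <- train_species_model(train_windows, train_labels, cfg$spec,
                                 seed = derive_seed(rep_seed, 0L),
                                 classes = classes)
    ok <- logical(length(test_idx))
    for (j in seq_along(test_idx)) {
      i <- test_idx[j]
      tw <- sample_windows(slides[[i]]$stack, slides[[i]]$mask, cfg,
                           seed = derive_seed(rep_seed, 1000L + i),
                           n_windows = cfg$test_windows_per_slide)
      call <- if (length(tw) == 0L) NA_character_
              else classify_slide(model, tw, cfg, classes = classes)$class
      ok[j] <- identical(call, labels[i])
      calls[[length(calls) + 1L]] <- data.frame(
        repeat_id = rep_i, slide = i, truth = labels[i],
        call = call %||% NA_character_, correct = ok[j])
    }
    per_repeat[rep_i] <- mean(ok)
  }
  calls <- do.call(rbind, calls)
  list(accuracy = mean(calls$correct), per_repeat = per_repeat,
       sd = stats::sd(per_repeat), calls = calls)
}
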