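# Grain-level species classification: window sampling, confidence gating,
# slide aggregation, leave-2-slides-out cross-validation.

# A two-level species model: dark pixels (level 0) vote class A, bright
# pixels (level 1) vote class B.  grid_size 1 with q = 128 makes every
# pixel its own example, so window class fractions are exact by design.
two_level_model <- function() {
  spec <- grid_spec(grid_size = 1, grid_spacing = 1, quantization = 128,
                    bins = 64)
  dark <- gh_window(matrix(10L, 4, 4), mask = matrix(1L, 4, 4))
  bright <- gh_window(matrix(200L, 4, 4), mask = matrix(1L, 4, 4))
  train_species_model(list(dark, bright), c("A", "B"), spec, seed = 1)
}

# Window with an exact fraction of dark (class-A) pixels.
frac_window <- function(frac_a, n = 10) {
  px <- matrix(200L, n, n)
  px[seq_len(round(frac_a * n * n))] <- 10L
  gh_window(px, mask = matrix(1L, n, n))
}

test_that("confidence is the absolute class-fraction difference in percent", {
  expect_identical(window_confidence(1, 0), 100)
  expect_identical(window_confidence(0.5, 0.5), 0)
  expect_identical(window_confidence(0.75, 0.25), 50)
  expect_identical(window_confidence(0.25, 0.75), 50)  # symmetric
  with_seed2(2, {
    f <- runif(25)
    for (x in f) {
      expect_gte(window_confidence(x, 1 - x), 0)
      expect_lte(window_confidence(x, 1 - x), 100)
    }
  })
  expect_error(window_confidence(0.6, 0.6), "sum to 1")
  expect_error(window_confidence(NA, 1), "undefined")
})

test_that("window classification gates on pixel-vote confidence", {
  m <- two_level_model()
  unanimous <- classify_window(m, frac_window(1), confidence_min = 43.61)
  expect_identical(unanimous$class, "A")
  expect_identical(unanimous$confidence, 100)

  split6040 <- classify_window(m, frac_window(0.6), confidence_min = 43.61)
  expect_true(split6040$abstained)           # confidence 20 < 43.61
  expect_equal(split6040$confidence, 20)
  expect_identical(split6040$class, NA_character_)

  split8020 <- classify_window(m, frac_window(0.8), confidence_min = 43.61)
  expect_false(split8020$abstained)          # confidence 60 >= 43.61
  expect_equal(split8020$confidence, 60)
  expect_identical(split8020$class, "A")

  empty <- classify_window(m, gh_window(matrix(10L, 4, 4),
                                        mask = matrix(0L, 4, 4)))
  expect_true(empty$abstained)
  expect_identical(empty$n_pixels, 0L)
})

test_that("raising the confidence floor never classifies more windows", {
  m <- two_level_model()
  wins <- lapply(c(1, 0.9, 0.75, 0.6, 0.55), frac_window)
  counts <- vapply(c(0, 20, 45, 80, 101), function(cm) {
    sum(!vapply(wins, function(w)
      classify_window(m, w, confidence_min = cm)$abstained, logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("slide calls aggregate window votes with forced minimums", {
  m <- two_level_model()
  cfg <- window_classifier_config(window_size = 10L, windows_per_slide = 5L,
                                  confidence_min = 43.61,
                                  spec = m$spec)
  una <- classify_slide(m, lapply(c(1, 1, 1), frac_window), cfg)
  expect_identical(una$class, "A")

  maj <- classify_slide(m, lapply(c(0.9, 0.8, 0.2), frac_window), cfg)
  expect_identical(maj$class, "A")           # A, A, B -> A

  # all below the gate: the single highest-confidence window decides
  forced <- classify_slide(m, lapply(c(0.55, 0.4), frac_window), cfg)
  expect_identical(forced$n_forced, 1L)
  expect_identical(forced$class, "B")        # 0.4 -> conf 20 beats 0.55 -> 10
  expect_identical(forced$n_classified, 1L)

  # gate-free limit: minimum = all windows reduces to plain majority
  cfg_all <- window_classifier_config(window_size = 10L,
                                      windows_per_slide = 5L,
                                      confidence_min = 100,
                                      min_classifications_per_slide = 3L,
                                      spec = m$spec)
  plain <- classify_slide(m, lapply(c(0.9, 0.6, 0.3), frac_window), cfg_all)
  expect_identical(plain$n_classified, 3L)
  expect_identical(plain$class, "A")         # votes A, A, B
})

test_that("sampled windows honor the pollen-content filter", {
  s <- small_slide()
  cfg <- window_classifier_config(window_size = 24L, windows_per_slide = 15L,
                                  spec = grid_spec(3, 2, 64, bins = 65536))
  wins <- sample_windows(s$stack, s$mask, cfg, seed = 3)
  expect_gt(length(wins), 0)
  # re-filter oracle: every returned window really exceeds 50% pollen
  for (w in wins) {
    o <- w$origin
    frac <- mean(s$mask[o[2] + 1:24, o[3] + 1:24])
    expect_gt(frac, 0.5)
    expect_identical(w$mask, s$mask[o[2] + 1:24, o[3] + 1:24])
  }
  # determinism
  wins2 <- sample_windows(s$stack, s$mask, cfg, seed = 3)
  expect_identical(lapply(wins, `[[`, "origin"), lapply(wins2, `[[`, "origin"))

  bg_stack <- image_stack(list(matrix(200L, 64, 64)))
  cfgs <- window_classifier_config(window_size = 16L, windows_per_slide = 3L,
                                   spec = cfg$spec)
  expect_warning(none <- sample_windows(bg_stack, matrix(0L, 64, 64), cfgs, 1),
                 "no window")
  expect_length(none, 0L)
})

test_that("separable slides cross-validate perfectly with exact bookkeeping", {
  # trivially separable classes: far-apart mean intensities, low contrast,
  # so even heavily imbalanced training splits classify perfectly
  spec <- small_slide_spec()
  spec$texture_a <- list(sigma = 1, anisotropy = 1, contrast = 10, base = 60)
  spec$texture_b <- list(sigma = 2, anisotropy = 1, contrast = 10, base = 160)
  slides <- list()
  for (i in 1:6) {
    s <- spec
    s$ratio_a <- if (i <= 3) 1 else 0
    sl <- generate_slide(s, seed = 100 + i)
    sl$label <- if (i <= 3) "A" else "B"
    slides[[i]] <- sl
  }
  cfg <- window_classifier_config(window_size = 24L, windows_per_slide = 10L,
                                  test_windows_per_slide = 10L,
                                  spec = grid_spec(3, 2, 64, bins = 262144))
  cv <- cross_validate_slides(slides, cfg, n_repeats = 3, seed = 2)
  expect_identical(cv$accuracy, 1)
  expect_identical(nrow(cv$calls), 6L)       # 3 repeats x 2 held-out slides
  expect_length(cv$per_repeat, 3L)
})
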