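# Hash pixel classifier: quantization, grid sampling, randomized hashing,
# count-array training and prediction, serialization.

test_that("quantize is floor division, fractional factors included", {
  expect_identical(quantize(0:255, 1), 0:255)           # 1x = original image
  expect_identical(quantize(255, 128), 1L)              # only levels {0,1}
  expect_identical(quantize(127, 128), 0L)
  expect_identical(quantize(127, 64), 1L)
  expect_identical(quantize(200, 14.24), as.integer(floor(200 / 14.24)))
  expect_error(quantize(10, 0.5), ">= 1")
  expect_error(quantize(300, 2), "intensities")
})

test_that("grid coordinates form a clamped row-major lattice", {
  spec1 <- grid_spec(grid_size = 1, grid_spacing = 7)
  expect_identical(grid_coordinates(c(5, 6), spec1, c(20, 20)),
                   cbind(row = 5, col = 6))

  spec8 <- grid_spec(grid_size = 8, grid_spacing = 2)
  cc <- grid_coordinates(c(50, 50), spec8, c(200, 200))
  expect_identical(nrow(cc), 64L)                       # every other pixel
  expect_identical(sort(unique(diff(sort(unique(cc[, "row"]))))), 2)
  # footprint spans (g-1)*s + 1 pixels per side before clamping
  expect_identical(diff(range(cc[, "row"])) + 1, (8 - 1) * 2 + 1)

  corner <- grid_coordinates(c(0, 0), grid_spec(grid_size = 4, grid_spacing = 1),
                             c(32, 32))
  expect_true(all(corner >= 0))
  expect_identical(range(corner[, "row"]), c(0, 2))     # offsets -1..2 clamped
})

test_that("hashing is deterministic, bounded, and matches the R reference path", {
  spec <- grid_spec(grid_size = 3, grid_spacing = 2, quantization = 32,
                    bins = 4096)
  lv <- matrix(sample(0:7, 45, replace = TRUE), nrow = 5)
  expect_identical(hash_examples(lv, spec, 11), hash_examples(lv, spec, 11))
  expect_false(identical(hash_examples(lv, spec, 11),
                         hash_examples(lv, spec, 12)))
  expect_true(all(hash_examples(lv, spec, 11) >= 0 &
                  hash_examples(lv, spec, 11) < 4096))
  spec_b1 <- grid_spec(grid_size = 3, grid_spacing = 2, quantization = 32,
                       bins = 1)
  expect_identical(unique(hash_examples(lv, spec_b1, 11)), 0L)

  # the compiled per-pixel path equals hashing the transparent grid levels
  s <- tiny_stack(h = 40, w = 40)
  plane <- s$planes[[1]]
  centers <- cbind(row = c(0L, 5L, 39L, 17L), col = c(0L, 33L, 39L, 2L))
  levels <- grid_example_levels(plane, centers, spec)
  expect_identical(grainhash:::pixel_bins(plane, centers[, 1], centers[, 2],
                                          spec, 11),
                   hash_examples(levels, spec, 11))
})

test_that("bin occupancy over random examples is approximately uniform", {
  spec <- grid_spec(grid_size = 4, grid_spacing = 1, quantization = 16,
                    bins = 1024)
  lv <- with_seed2(99, matrix(sample(0:15, 1e5 * 16, replace = TRUE),
                              nrow = 1e5))
  bins <- hash_examples(lv, spec, 7)
  obs <- tabulate(bins + 1L, nbins = 1024)
  expected <- 1e5 / 1024
  chisq <- sum((obs - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.999, 1023))
})

test_that("training conserves counts, is linear and order-independent", {
  spec <- grid_spec(grid_size = 2, grid_spacing = 1, quantization = 64,
                    bins = 256)
  bins <- with_seed2(3, sample(0:255, 500, replace = TRUE))
  labels <- with_seed2(4, rbinom(500, 1, 0.3))
  m <- train_hash_model(bins, labels, spec, 1)
  expect_equal(sum(m$pos_counts), sum(labels == 1))
  expect_equal(sum(m$neg_counts), sum(labels == 0))

  m1 <- train_hash_model(c(17), c(1), spec, 1)
  expect_identical(sum(m1$pos_counts > 0), 1L)
  expect_identical(m1$pos_counts[18], 1)
  expect_identical(sum(m1$neg_counts), 0)

  m2 <- train_hash_model(c(bins, bins), c(labels, labels), spec, 1)
  expect_identical(m2$pos_counts, 2 * m$pos_counts)

  perm <- with_seed2(5, sample(500))
  mp <- train_hash_model(bins[perm], labels[perm], spec, 1)
  expect_identical(mp$pos_counts, m$pos_counts)
  expect_identical(mp$neg_counts, m$neg_counts)

  expect_error(train_hash_model(integer(0), integer(0), spec, 1), "empty")
})

test_that("train/predict agrees exactly with an explicit-table classifier", {
  spec <- grid_spec(grid_size = 3, grid_spacing = 1, quantization = 32,
                    bins = 512)
  n <- 5000
  bins <- with_seed2(21, sample(0:511, n, replace = TRUE))
  labels <- with_seed2(22, rbinom(n, 1, 0.4))
  model <- train_hash_model(bins, labels, spec, 9)
  tab <- oracle_table_train(bins, labels)
  test_bins <- with_seed2(23, sample(0:511, 1000, replace = TRUE))
  expect_identical(predict_bins(model, test_bins)$label,
                   oracle_table_predict(tab, test_bins))
})

test_that("prediction follows the pos > neg rule with negative tie-break", {
  spec <- grid_spec(grid_size = 1, grid_spacing = 1, quantization = 1,
                    bins = 16)
  m <- train_hash_model(c(3, 3, 3, 3, 5, 5, 7, 7), c(1, 1, 1, 0, 1, 0, 0, 0),
                        spec, 1)
  r <- predict_bins(m, c(3, 5, 7, 9))
  expect_identical(r$label, c(1L, 0L, 0L, 0L))  # 3:1 pos; 1:1 tie; 0:2; 0:0
  expect_identical(r$pos_count[1], 3)
  expect_identical(r$neg_count[1], 1)
})

test_that("with vast bins and distinct examples the model memorizes", {
  spec <- grid_spec(grid_size = 4, grid_spacing = 1, quantization = 8,
                    bins = 2048000)
  lv <- with_seed2(31, matrix(sample(0:31, 200 * 16, replace = TRUE),
                              nrow = 200))
  lv <- unique(lv)
  labels <- with_seed2(32, rbinom(nrow(lv), 1, 0.5))
  bins <- hash_examples(lv, spec, 5)
  m <- train_hash_model(bins, labels, spec, 5)
  expect_identical(predict_bins(m, bins)$label, as.integer(labels))
})

test_that("models round-trip through the versioned container", {
  dir <- withr::local_tempdir()
  s <- small_slide()
  spec <- grid_spec(grid_size = 3, grid_spacing = 1, quantization = 64,
                    bins = 65536)
  w <- gh_window(s$stack$planes[[2]], mask = s$mask)
  m <- train_spotter(list(w), spec, 17)
  path <- file.path(dir, "model.bin")
  save_hash_model(m, path)
  m2 <- load_hash_model(path)
  centers <- with_seed2(41, cbind(sample(0:255, 100, TRUE),
                                  sample(0:255, 100, TRUE)))
  for (i in c(1, 50, 100)) {
    expect_identical(predict_pixel(m2, s$stack$planes[[2]], centers[i, ]),
                     predict_pixel(m, s$stack$planes[[2]], centers[i, ]))
  }

  writeBin(readBin(path, "raw", 100), trunc <- file.path(dir, "trunc.bin"))
  expect_error(load_hash_model(trunc), "model")

  # serialized size is linear in the bin count
  sizes <- vapply(c(1e3, 1e4, 1e5), function(B) {
    sp <- grid_spec(grid_size = 1, grid_spacing = 1, quantization = 64,
                    bins = B)
    mm <- train_hash_model(0, 1, sp, 1)
    f <- file.path(dir, sprintf("m%d.bin", B))
    save_hash_model(mm, f)
    file.size(f)
  }, numeric(1))
  expect_gt(sizes[2] / sizes[1], 5)
  expect_lt(abs(sizes[3] / sizes[2] - 10), 1)
})

test_that("the configuration count matches the quantized color combinatorics", {
  spec <- grid_spec(grid_size = 8, grid_spacing = 1, quantization = 64,
                    channels = 0:2)
  expect_identical(n_quant_levels(spec), 4L)
  expect_equal(grid_config_log10(spec), 64 * log10(4^3))
  expect_gt(grid_config_log10(spec), 115)  # > 10^115 configurations
})
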