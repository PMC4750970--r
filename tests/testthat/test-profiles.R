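# Profile extraction, information content, Manhattan-distance rules,
# ensembles and ratio prediction.

test_that("information content is the mean absolute adjacent difference", {
  expect_identical(info_content(rep(42, 10)), 0)
  expect_identical(info_content(c(0, 255)), 255)
  expect_equal(info_content(c(0, 10, 0, 10)), 10)
  expect_error(info_content(5), "at least 2")

  # invariances: reversal, constant shift; linear in intensity scaling
  p <- with_seed2(1, runif(64, 0, 255))
  expect_equal(info_content(rev(p)), info_content(p))
  expect_equal(info_content(p + 10), info_content(p))
  expect_equal(info_content(2 * p), 2 * info_content(p))
})

test_that("the IC filter passes exactly the profiles at or above threshold", {
  plane <- cbind(c(0, 5, 0, 5, 0), c(10, 10, 10, 10, 10))
  mask <- matrix(1L, 5, 2)
  res <- extract_profiles(plane, mask, L = 5, ic_min = 5)
  expect_identical(res$origins$col, 0L)  # constant column filtered out
  expect_equal(info_content(res$profiles[1, ]), 5)
})

test_that("profile extraction matches a brute-force scan", {
  with_seed2(7, {
    plane <- matrix(runif(40 * 30, 0, 255), 40, 30)
    mask <- matrix(rbinom(40 * 30, 1, 0.8), 40, 30)
  })
  L <- 8
  res <- extract_profiles(plane, mask, L, ic_min = 5)
  # independent oracle: enumerate all column-major candidate lines
  exp_rows <- integer(0); exp_cols <- integer(0)
  for (c in 1:30) for (r in 1:(40 - L + 1)) {
    seg <- plane[r:(r + L - 1), c]
    if (all(mask[r:(r + L - 1), c] == 1) && mean(abs(diff(seg))) >= 5) {
      exp_rows <- c(exp_rows, r - 1L); exp_cols <- c(exp_cols, c - 1L)
    }
  }
  expect_identical(res$origins$row, exp_rows)
  expect_identical(res$origins$col, exp_cols)

  expect_identical(nrow(extract_profiles(plane, mask * 0L, L)$profiles), 0L)
  flat <- matrix(100, 40, 30)
  expect_identical(nrow(extract_profiles(flat, mask^0, L)$profiles), 0L)
  expect_error(extract_profiles(plane, mask, L = 41), "profile length")
})

test_that("Manhattan distance attains the documented extremes", {
  expect_identical(manhattan_dist(c(3, 4), c(3, 4)), 0)
  expect_identical(manhattan_dist(c(0, 0), c(255, 255)), 510)
  expect_identical(manhattan_dist(rep(0, 128), rep(255, 128)), 32640)
  expect_error(manhattan_dist(1:3, 1:4), "lengths differ")

  # symmetry and triangle inequality on random profiles
  with_seed2(11, {
    for (i in 1:20) {
      a <- runif(16, 0, 255); b <- runif(16, 0, 255); c <- runif(16, 0, 255)
      expect_identical(manhattan_dist(a, b), manhattan_dist(b, a))
      expect_lte(manhattan_dist(a, c),
                 manhattan_dist(a, b) + manhattan_dist(b, c))
    }
  })
})

test_that("rule evaluation separates clusters and honors symmetry", {
  # class A tight around the candidate, class B far away: error 0
  with_seed2(13, {
    candidate <- rep(100, 8)
    trainA <- matrix(rep(candidate, 20), 20, byrow = TRUE) +
      matrix(runif(160, -2, 2), 20)
    trainB <- matrix(rep(200, 160), 20, 8) + matrix(runif(160, -2, 2), 20)
  })
  train <- rbind(trainA, trainB)
  labels <- rep(c("A", "B"), each = 20)
  rule <- evaluate_rule(candidate, train, labels)
  expect_identical(rule$error_rate, 0)
  expect_identical(rule$near_class, "A")
  expect_identical(rule$far_class, "B")

  # equidistant identical distributions: no rule beats the 0.5 baseline
  sym <- rbind(matrix(90, 10, 4), matrix(110, 10, 4))
  rule_sym <- evaluate_rule(rep(100, 4), sym, rep(c("A", "B"), each = 10))
  expect_identical(rule_sym$error_rate, 0.5)

  expect_warning(evaluate_rule(candidate, trainA, rep("A", 20)),
                 "single-class")
})

test_that("threshold choice and error rate match the brute-force oracle", {
  with_seed2(17, {
    for (case in 1:15) {
      n <- sample(10:40, 1)
      train <- matrix(sample(0:255, n * 6, TRUE), n, 6)
      labels <- sample(c("A", "B"), n, TRUE, prob = c(0.6, 0.4))
      if (length(unique(labels)) < 2) next
      cand <- train[sample(n, 1), ]
      rule <- evaluate_rule(cand, train, labels)
      oracle <- brute_force_rule(cand, train, labels)
      expect_equal(rule$error_rate, oracle$err)
      expect_equal(rule$threshold, oracle$t)
    }
  })
})

test_that("ensembles rank stably, vote by majority, and break ties by prior", {
  mk_rule <- function(err, near = "A", ref = rep(0, 4), thr = 10,
                      priors = c(A = 10, B = 10)) {
    grainhash:::new_profile_rule(ref, thr, c(5, 5), c(5, 5), near,
                                 if (near == "A") "B" else "A", err,
                                 c("A", "B"), priors)
  }
  rules <- list(mk_rule(0.3), mk_rule(0.1), mk_rule(0.2), mk_rule(0.1))
  ens <- build_ensemble(rules, 2)
  expect_identical(vapply(ens$rules, `[[`, numeric(1), "error_rate"),
                   c(0.1, 0.1))
  expect_identical(ens$rules[[1]], rules[[2]])  # stable tie order
  expect_error(build_ensemble(rules, 0), "positive")
  expect_error(build_ensemble(rules, 9), "exceeds")

  # k = 1: ensemble equals the best rule; profile at distance 0 is "near"
  e1 <- build_ensemble(rules, 1)
  expect_identical(classify_profiles(e1, rep(0, 4)), "A")
  expect_identical(classify_profiles(e1, rep(100, 4)), "B")

  # 2-vs-1 majority: two rules near->A, one rule near->B
  maj <- build_ensemble(list(mk_rule(0.1, "A"), mk_rule(0.2, "A"),
                             mk_rule(0.3, "B")), 3)
  expect_identical(classify_profiles(maj, rep(0, 4)), "A")

  # even-k tie falls to the larger training prior
  tie <- build_ensemble(list(mk_rule(0.1, "A", priors = c(A = 5, B = 15)),
                             mk_rule(0.1, "B", priors = c(A = 5, B = 15))), 2)
  expect_identical(classify_profiles(tie, rep(0, 4)), "B")
})

test_that("slide ratios are voted fractions with abstention on empty input", {
  with_seed2(19, {
    trainA <- matrix(runif(80, 0, 40), 10, 8)
    trainB <- matrix(runif(80, 200, 255), 10, 8)
  })
  train <- rbind(trainA, trainB)
  labels <- rep(c("A", "B"), each = 10)
  ens <- learn_rule_ensemble(train, labels, n_rules = 10, k = 3, seed = 1)
  expect_identical(predict_slide_ratio(ens, trainA), 1)
  expect_identical(predict_slide_ratio(ens, train), 0.5)
  expect_warning(r <- predict_slide_ratio(ens, NULL), "abstaining")
  expect_true(is.na(r) && isTRUE(attr(r, "abstained")))
})

test_that("r-squared matches the closed-form least-squares value", {
  expect_equal(r_squared(c(0, 0.5, 1), c(0, 0.5, 1)), 1)
  expect_equal(r_squared(rep(0.5, 4), c(0, 0.3, 0.6, 1)), 0)
  # frozen from the closed form Sxy^2 / (Sxx * Syy)
  expect_equal(r_squared(c(0.1, 0.4, 0.95), c(0, 0.5, 1)), 0.9719730942,
               tolerance = 1e-9)
  expect_error(r_squared(c(1, 2), c(1, 2)), "at least 3")
  expect_error(r_squared(c(1, 2, 3), c(2, 2, 2)), "constant")
})

test_that("profiles pool across selected z-planes with a seeded cap", {
  s <- small_slide()
  pr_all <- collect_slide_profiles(s$stack, s$mask, L = 16, ic_min = 0,
                                   row_stride = 4, col_stride = 4)
  pr_one <- collect_slide_profiles(s$stack, s$mask, L = 16, ic_min = 0,
                                   z_step = 3, row_stride = 4, col_stride = 4)
  expect_gt(nrow(pr_all), nrow(pr_one))
  capped <- collect_slide_profiles(s$stack, s$mask, L = 16, ic_min = 0,
                                   row_stride = 4, col_stride = 4,
                                   max_profiles = 50, seed = 2)
  expect_identical(nrow(capped), 50L)
  capped2 <- collect_slide_profiles(s$stack, s$mask, L = 16, ic_min = 0,
                                    row_stride = 4, col_stride = 4,
                                    max_profiles = 50, seed = 2)
  expect_identical(capped, capped2)
})
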