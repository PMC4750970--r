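# Shared fixtures and independent oracles. Expensive objects are memoised
# so several test files can reuse one instance.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Deterministic small multi-plane stack with a gradient pattern.
tiny_stack <- function(h = 12, w = 10, nz = 3, nch = 1) {
  planes <- lapply(seq_len(nz), function(z) {
    vals <- (outer(seq_len(h), seq_len(w), function(r, c) (r * 7 + c * 3 + z * 11)) %% 256L)
    array(rep(as.integer(vals), nch), dim = c(h, w, nch))
  })
  image_stack(planes, slide_id = "tiny")
}

# Two-texture labeled window: mask-1 region dark (0..60), background bright
# (180..255); trivially separable by intensity.
separable_window <- function(h = 48, w = 48, seed = 1) {
  with_seed2(seed, {
    mask <- matrix(0L, h, w)
    mask[seq_len(h / 2), ] <- 1L
    px <- matrix(0L, h, w)
    px[mask == 1L] <- sample(0:60, sum(mask), replace = TRUE)
    px[mask == 0L] <- sample(180:255, sum(mask == 0L), replace = TRUE)
    gh_window(px, mask = mask)
  })
}

# Seed helper mirroring the package-internal RNG scoping.
with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Small synthetic slide spec for unit tests (distinct from the study-scale
# defaults used in the acceptance suite).
small_slide_spec <- function(seed = 5, ratio = 0.5, n_grains = 12L,
                             image_size = 256L) {
  synthetic_slide_spec(image_size = image_size, n_grains = n_grains,
                       ratio_a = ratio, radius_range = c(16, 20),
                       n_z_planes = 3L, focus_plane = 1L, seed = seed)
}

small_slide <- function() memo("small_slide", generate_slide(small_slide_spec()))

# Transparent reference classifier: explicit (bin -> label counts) table.
oracle_table_train <- function(bins, labels) {
  tab <- new.env(parent = emptyenv())
  for (i in seq_along(bins)) {
    key <- as.character(bins[i])
    cur <- tab[[key]] %||% c(pos = 0, neg = 0)
    if (labels[i] == 1) cur["pos"] <- cur["pos"] + 1 else cur["neg"] <- cur["neg"] + 1
    tab[[key]] <- cur
  }
  tab
}

oracle_table_predict <- function(tab, bins) {
  vapply(bins, function(b) {
    cur <- tab[[as.character(b)]] %||% c(pos = 0, neg = 0)
    as.integer(cur["pos"] > cur["neg"])
  }, integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force near/far rule oracle: scans every distinct candidate-to-train
# distance as threshold, recounting misclassifications directly.
brute_force_rule <- function(candidate, train, labels) {
  classes <- sort(unique(labels))
  priors <- c(sum(labels == classes[1]), sum(labels == classes[2]))
  tie_class <- if (priors[2] > priors[1]) classes[2] else classes[1]
  d <- apply(train, 1, function(r) sum(abs(r - candidate)))
  thresholds <- sort(unique(d))
  best <- NULL
  for (t in thresholds) {
    near <- d <= t
    bin_pred <- function(sel) {
      nA <- sum(labels[sel] == classes[1]); nB <- sum(sel) - nA
      if (nA > nB) classes[1] else if (nB > nA) classes[2] else tie_class
    }
    np <- bin_pred(near); fp <- bin_pred(!near)
    pred <- ifelse(near, np, fp)
    err <- mean(pred != labels)
    if (is.null(best) || err < best$err) best <- list(t = t, err = err)
  }
  best
}

# Independent seed derivation for fixtures (keep distinct from internals).
derive_seed <- grainhash:::derive_seed

# Study-scale fixtures (memoised): the 12-slide pure reference set and the
# 22-slide constructed-ratio series at the simulator's default conditions.
study_spec <- function() synthetic_slide_spec(seed = 11)

study_reference_set <- function()
  memo("study_refs", generate_reference_set(study_spec()))

study_ratio_series <- function()
  memo("study_series", generate_ratio_series(study_spec()))

# Window classifier configuration for the synthetic suite (grain radius
# ~20-26 px, so 24-px windows play the role of the grain-sized windows).
study_species_cfg <- function()
  window_classifier_config(window_size = 24L, windows_per_slide = 30L,
                           test_windows_per_slide = 30L,
                           spec = grid_spec(3, 2, 64))
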