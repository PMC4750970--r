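# Synthetic-slide simulator: textured circular grains of two classes on a
# noisy bright background, imaged as a z-stack with defocus blur away from
# the focal plane, with known per-grain labels and ground-truth masks.
# Stands in for slide-scanner imagery so every stage of the two-pass
# pipeline can be validated against known truth.

#' Specification of a synthetic slide
#'
#' The two grain classes share geometry and differ only in texture: each
#' grain's interior is low-pass filtered Gaussian speckle with a
#' class-specific spatial scale (`sigma`, px), orientation anisotropy,
#' contrast (intensity s.d.) and mean interior intensity (`base`),
#' approximating differences in exine ornamentation.  The background is
#' bright Gaussian noise; z-planes other than the focal plane are blurred
#' in proportion to their focal offset.
#'
#' @param image_size side length in pixels (default 1024).
#' @param n_grains grains per slide (default 100, the constructed-slide
#'   design).
#' @param ratio_a fraction of grains from class A in `[0, 1]`.
#' @param radius_range grain radius range in pixels.
#' @param texture_a,texture_b per-class texture parameters: lists with
#'   `sigma`, `anisotropy`, `contrast`, `base`.
#' @param background list with `mean`, `sd` (slide background) and
#'   `plane_noise_sd` (per-plane sensor noise).
#' @param n_z_planes z-planes per stack (default 5).
#' @param focus_plane 0-based index of the sharp plane (default middle).
#' @param defocus_sigma blur sigma in pixels per plane of focal offset.
#' @param min_gap minimum gap between grain rims in pixels (no overlap).
#' @param max_place_attempts placement retries before failing.
#' @param seed integer seed; the spec plus seed fully determine the slide.
#' @export
synthetic_slide_spec <- function(image_size = 1024L, n_grains = 100L,
                                 ratio_a = 0.5, radius_range = c(20, 26),
                                 texture_a = list(sigma = 1.0, anisotropy = 1,
                                                  contrast = 45, base = 115),
                                 texture_b = list(sigma = 2.0, anisotropy = 1,
                                                  contrast = 35, base = 150),
                                 background = list(mean = 200, sd = 6,
                                                   plane_noise_sd = 2),
                                 n_z_planes = 5L, focus_plane = 2L,
                                 defocus_sigma = 1.5, min_gap = 2,
                                 max_place_attempts = 20000L, seed = 1L) {
  if (ratio_a < 0 || ratio_a > 1) stopf("`ratio_a` must lie in [0, 1]")
  if (any(radius_range <= 0) || radius_range[1] > radius_range[2])
    stopf("`radius_range` must be positive and ordered")
  if (!is_count(n_z_planes) || focus_plane < 0 || focus_plane >= n_z_planes)
    stopf("`focus_plane` must be a valid 0-based plane index")
  structure(list(image_size = as.integer(image_size),
                 n_grains = as.integer(n_grains), ratio_a = ratio_a,
                 radius_range = radius_range, texture_a = texture_a,
                 texture_b = texture_b, background = background,
                 n_z_planes = as.integer(n_z_planes),
                 focus_plane = as.integer(focus_plane),
                 defocus_sigma = defocus_sigma, min_gap = min_gap,
                 max_place_attempts = as.integer(max_place_attempts),
                 seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

# Non-overlapping grain placement by rejection sampling.
place_grains <- function(spec) {
  n <- spec$n_grains
  size <- spec$image_size
  radii <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
  rows <- numeric(n); cols <- numeric(n)
  attempts <- 0L
  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > spec$max_place_attempts)
        stopf("could not place %d non-overlapping grains in %d attempts",
              n, spec$max_place_attempts)
      r <- radii[i]
      cand_row <- stats::runif(1, r + 1, size - r - 1)
      cand_col <- stats::runif(1, r + 1, size - r - 1)
      if (i == 1L) break
      j <- seq_len(i - 1L)
      d2 <- (rows[j] - cand_row)^2 + (cols[j] - cand_col)^2
      if (all(d2 > (radii[j] + r + spec$min_gap)^2)) break
    }
    rows[i] <- cand_row; cols[i] <- cand_col
  }
  data.frame(row = rows, col = cols, radius = radii)
}

render_grain <- function(img, mask, row, col, radius, tex) {
  size <- nrow(img)
  r0 <- max(1L, floor(row - radius)); r1 <- min(size, ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(size, ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col)
  disk <- dr * dr + dc * dc <= radius * radius
  noise <- matrix(stats::rnorm(length(rr) * length(cc)),
                  nrow = length(rr))
  sm <- cpp_gblur(noise, tex$sigma * tex$anisotropy,
                  tex$sigma / tex$anisotropy)
  sm <- sm / stats::sd(sm)
  tile <- tex$base + tex$contrast * sm
  img[rr, cc][disk] <- tile[disk]
  mask[rr, cc][disk] <- 1L
  list(img = img, mask = mask)
}

#' Generate one synthetic slide
#'
#' Places exactly `n_grains` non-overlapping grains (class A count =
#' `round(ratio_a * n_grains)`), renders the sharp focal plane, derives
#' the other z-planes by defocus blur plus per-plane sensor noise, and
#' returns the stack together with the ground-truth mask (shared by all
#' z-planes: geometry is fixed, only focus varies) and per-grain labels.
#' Fully reproducible from the spec and seed.
#'
#' @param spec a [synthetic_slide_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @param slide_id slide identifier.
#' @return list of class `synthetic_slide` with `stack` ([image_stack()]),
#'   `mask` (binary matrix), `grains` (data.frame: 0-based `row`, `col`,
#'   `radius`, `class`) and `label` (the true class-A ratio).
#' @export
generate_slide <- function(spec, seed = spec$seed, slide_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  with_seed(seed, {
    n <- spec$n_grains
    n_a <- round(spec$ratio_a * n)
    classes <- sample(c(rep("A", n_a), rep("B", n - n_a)))
    geom <- place_grains(spec)
    size <- spec$image_size
    bg <- spec$background
    sharp <- matrix(stats::rnorm(size * size, bg$mean, bg$sd), nrow = size)
    mask <- matrix(0L, size, size)
    for (i in seq_len(n)) {
      tex <- if (classes[i] == "A") spec$texture_a else spec$texture_b
      res <- render_grain(sharp, mask, geom$row[i], geom$col[i],
                          geom$radius[i], tex)
      sharp <- res$img; mask <- res$mask
    }
    planes <- vector("list", spec$n_z_planes)
    for (z in seq_len(spec$n_z_planes) - 1L) {
      off <- abs(z - spec$focus_plane)
      pl <- if (off == 0L) sharp
            else cpp_gblur(sharp, spec$defocus_sigma * off,
                           spec$defocus_sigma * off)
      pl <- pl + matrix(stats::rnorm(size * size, 0, bg$plane_noise_sd),
                        nrow = size)
      planes[[z + 1L]] <- matrix(pmin.int(pmax.int(as.integer(round(pl)), 0L),
                                          255L), nrow = size)
    }
    grains <- data.frame(row = geom$row - 1, col = geom$col - 1,
                         radius = geom$radius, class = classes)
    structure(list(stack = image_stack(planes, slide_id = slide_id,
                                       slide_label = spec$ratio_a),
                   mask = mask, grains = grains, label = spec$ratio_a),
              class = "synthetic_slide")
  })
}

#' Generate a mixture-ratio slide series
#'
#' The constructed-slide design: every ratio in `ratios`, duplicated
#' `duplicates` times with distinct seeds — defaults give 22 slides at
#' 0–100% class A in 10% steps.
#'
#' @param spec base [synthetic_slide_spec()].
#' @param ratios class-A fractions (default `seq(0, 1, by = 0.1)`).
#' @param duplicates slides per ratio (default 2).
#' @return list of `synthetic_slide` objects.
#' @export
generate_ratio_series <- function(spec, ratios = seq(0, 1, by = 0.1),
                                  duplicates = 2L) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  if (any(ratios < 0 | ratios > 1)) stopf("ratios must lie in [0, 1]")
  out <- list()
  k <- 0L
  for (r in ratios) {
    for (dup in seq_len(duplicates)) {
      k <- k + 1L
      s <- spec
      s$ratio_a <- r
      out[[k]] <- generate_slide(s, seed = derive_seed(spec$seed, k),
                                 slide_id = sprintf("ratio_%03d_rep%d",
                                                    round(100 * r), dup))
    }
  }
  out
}

#' Generate a pure reference-slide set with individual-level variation
#'
#' Pure slides (ratio 0 or 1) for species training.  Each simulated
#' "individual" receives a jittered copy of its class's texture parameters,
#' shared across that individual's replicate slides, so held-out
#' individuals differ systematically from training individuals — the
#' unseen-individual challenge.  Defaults give 12 slides: 2 individuals
#' per class x 3 replicates.
#'
#' @param spec base [synthetic_slide_spec()].
#' @param individuals_per_class simulated individuals per class (default 2).
#' @param replicates replicate slides per individual (default 3).
#' @param jitter_sd log-normal jitter s.d. applied to `sigma` and
#'   `contrast`, and (x4, additively) to `base`, per individual.
#' @return list of `synthetic_slide` objects, each with added fields
#'   `class_label` ("A"/"B"), `individual`, and `texture` (the
#'   individual's parameters).
#' @export
generate_reference_set <- function(spec, individuals_per_class = 2L,
                                   replicates = 3L, jitter_sd = 0.06) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  if (!is_count(individuals_per_class)) stopf("individuals_per_class >= 1")
  out <- list()
  k <- 0L
  for (cl in c("A", "B")) {
    base_tex <- if (cl == "A") spec$texture_a else spec$texture_b
    for (ind in seq_len(individuals_per_class)) {
      tex <- with_seed(derive_seed(spec$seed, 500L + 10L * ind +
                                     (cl == "B")), {
        list(sigma = base_tex$sigma * exp(stats::rnorm(1, 0, jitter_sd)),
             anisotropy = base_tex$anisotropy,
             contrast = base_tex$contrast * exp(stats::rnorm(1, 0, jitter_sd)),
             base = base_tex$base + stats::rnorm(1, 0, 4 * jitter_sd * 10))
      })
      for (rep_i in seq_len(replicates)) {
        k <- k + 1L
        s <- spec
        s$ratio_a <- if (cl == "A") 1 else 0
        if (cl == "A") s$texture_a <- tex else s$texture_b <- tex
        sl <- generate_slide(s, seed = derive_seed(spec$seed, k),
                             slide_id = sprintf("ref_%s_ind%d_rep%d",
                                                cl, ind, rep_i))
        sl$class_label <- cl
        sl$label <- cl  # species CV consumes the class, not the ratio
        sl$individual <- sprintf("%s%d", cl, ind)
        sl$texture <- tex
        out[[k]] <- sl
      }
    }
  }
  out
}
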