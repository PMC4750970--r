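# Locality-sensitive-hashing histogram classifier over quantized pixel-grid
# features: the learning core shared by pollen spotting (pass 1) and
# grain-level species classification (pass 2).
#
# Each pixel of interest yields a "grid example": a square lattice of
# neighboring intensities (side `grid_size`, pitch `grid_spacing`, clamped at
# plane borders), quantized by integer division with factor `q`.  A fixed
# random table of 64-bit values — one entry per (grid slot, channel, level) —
# is summed over the example's slots (wrapping modulo 2^64) and reduced
# modulo `bins` to a bin index; per-bin positive/negative label counts form
# the trained model.  Prediction looks up the bin and calls the pixel
# positive iff the positive count strictly exceeds the negative count
# (ties, including never-seen bins, fall to the negative/background class).

#' Feature-representation parameters for the hash pixel classifier
#'
#' @param grid_size pixels per grid side (1 disables neighborhood context).
#' @param grid_spacing lattice pitch in pixels between sampled neighbors.
#' @param quantization quantization factor `q >= 1` (fractional allowed);
#'   intensities map to levels `floor(value / q)`, giving
#'   `Q = floor(max_intensity / q) + 1` levels.
#' @param bins number of counting bins `B` for bin statistics
#'   (default 2,048,000).
#' @param channels ordered 0-based channel subset used to build examples
#'   (default channel 0).
#' @param max_intensity maximum intensity value (default 255).
#' @export
grid_spec <- function(grid_size = 8L, grid_spacing = 8L, quantization = 10,
                      bins = 2048000, channels = 0L, max_intensity = 255L) {
  if (!is_count(grid_size)) stopf("`grid_size` must be a positive integer")
  if (!is_count(grid_spacing)) stopf("`grid_spacing` must be a positive integer")
  if (!is_scalar_num(quantization) || quantization < 1)
    stopf("`quantization` must be a real >= 1")
  if (!is_count(bins)) stopf("`bins` must be a positive integer")
  if (length(channels) < 1L || any(channels < 0) || any(channels != floor(channels)))
    stopf("`channels` must be non-negative 0-based indices")
  structure(list(grid_size = as.integer(grid_size),
                 grid_spacing = as.integer(grid_spacing),
                 quantization = as.numeric(quantization),
                 bins = as.numeric(bins),
                 channels = as.integer(channels),
                 max_intensity = as.integer(max_intensity)),
            class = "grid_spec")
}

#' Quantize intensities by (possibly fractional) integer division
#'
#' `level = floor(value / q)`.  With `q = 128` on 8-bit data only levels
#' 0 and 1 survive; `q = 1` is the identity.
#'
#' @param value numeric vector of intensities in `[0, max_intensity]`.
#' @param q quantization factor `>= 1`.
#' @param max_intensity intensity ceiling (default 255).
#' @export
quantize <- function(value, q, max_intensity = 255L) {
  if (!is_scalar_num(q) || q < 1) stopf("quantization factor must be >= 1")
  if (any(value < 0 | value > max_intensity))
    stopf("intensities must lie in [0, %d]", max_intensity)
  as.integer(floor(value / q))
}

#' Number of quantized levels for a spec
#' @param spec a [grid_spec()].
#' @export
n_quant_levels <- function(spec) {
  as.integer(floor(spec$max_intensity / spec$quantization) + 1)
}

#' Grid-example sampling coordinates around a center pixel
#'
#' Returns the `grid_size^2` lattice coordinates (0-based, row-major order)
#' sampled for a pixel of interest, clamped to the plane bounds so border
#' pixels remain classifiable (edge replication).  For even grid sizes the
#' center is top-left biased: offsets run from `-floor((g-1)/2) * s` to
#' `ceil((g-1)/2) * s`.
#'
#' @param center 0-based `c(row, col)` of the pixel of interest.
#' @param spec a [grid_spec()].
#' @param dims plane dimensions `c(height, width)`.
#' @return integer matrix with columns `row`, `col`.
#' @export
grid_coordinates <- function(center, spec, dims) {
  stopifnot(inherits(spec, "grid_spec"), length(center) == 2L)
  if (center[1] < 0 || center[1] >= dims[1] ||
      center[2] < 0 || center[2] >= dims[2])
    stopf("center (%d, %d) outside plane of %d x %d",
          center[1], center[2], dims[1], dims[2])
  g <- spec$grid_size
  s <- spec$grid_spacing
  offs <- (seq_len(g) - 1L - (g - 1L) %/% 2L) * s
  rows <- pmin(pmax(center[1] + offs, 0L), dims[1] - 1L)
  cols <- pmin(pmax(center[2] + offs, 0L), dims[2] - 1L)
  cbind(row = rep(rows, each = g), col = rep(cols, times = g))
}

#' Quantized grid-example levels for given centers (reference path)
#'
#' Transparent R construction of grid examples — one row per center, one
#' column per (grid cell, channel) slot, values being quantized levels.
#' Used for introspection and as an independent check of the compiled path.
#'
#' @param plane `h x w x ch` integer array (or matrix).
#' @param centers integer matrix of 0-based `row`, `col` centers.
#' @param spec a [grid_spec()].
#' @export
grid_example_levels <- function(plane, centers, spec) {
  plane <- as_plane(plane)
  d <- dim(plane)
  nch <- length(spec$channels)
  if (any(spec$channels >= d[3]))
    stopf("spec channels exceed plane channel count %d", d[3])
  out <- matrix(0L, nrow = nrow(centers), ncol = spec$grid_size^2 * nch)
  for (i in seq_len(nrow(centers))) {
    cc <- grid_coordinates(centers[i, ], spec, d[1:2])
    vals <- vapply(seq_len(nrow(cc)), function(j)
      plane[cc[j, 1] + 1L, cc[j, 2] + 1L, spec$channels + 1L],
      integer(nch))
    # vapply returns nch x ncells; slots are cell-major, channel-minor
    out[i, ] <- quantize(as.integer(vals), spec$quantization,
                         spec$max_intensity)
  }
  out
}

#' Hash grid examples into bin indices
#'
#' Sums the seeded random-table entries of every (slot, level) pair modulo
#' 2^64, then reduces modulo `spec$bins`.  Deterministic across runs and
#' platforms given (spec, seed).
#'
#' @param levels integer matrix of quantized levels, one example per row.
#' @param spec a [grid_spec()].
#' @param seed integer seed of the random table.
#' @return 0-based integer bin indices.
#' @export
hash_examples <- function(levels, spec, seed) {
  stopifnot(inherits(spec, "grid_spec"))
  cpp_hash_levels(as.matrix(levels), as.numeric(seed), n_quant_levels(spec),
                  spec$bins)
}

# Bin index of every pixel in a plane restricted to the spec's channels;
# returns an h x w integer matrix of 0-based bins.
plane_bins <- function(plane, spec, seed) {
  plane <- as_plane(plane)
  d <- dim(plane)
  if (any(spec$channels >= d[3]))
    stopf("spec channels exceed plane channel count %d", d[3])
  sub <- plane[, , spec$channels + 1L, drop = FALSE]
  bins <- cpp_plane_bins(as.integer(sub), d[1], d[2], length(spec$channels),
                         spec$grid_size, spec$grid_spacing, spec$quantization,
                         spec$max_intensity, spec$bins, as.numeric(seed))
  matrix(bins, nrow = d[1], ncol = d[2])
}

# Bin indices for selected 0-based centers of a plane.
pixel_bins <- function(plane, centers_row, centers_col, spec, seed) {
  plane <- as_plane(plane)
  d <- dim(plane)
  sub <- plane[, , spec$channels + 1L, drop = FALSE]
  cpp_pixel_bins(as.integer(sub), d[1], d[2], length(spec$channels),
                 as.integer(centers_row), as.integer(centers_col),
                 spec$grid_size, spec$grid_spacing, spec$quantization,
                 spec$max_intensity, spec$bins, as.numeric(seed))
}

#' Train a hash histogram model from binned labeled examples
#'
#' Accumulates per-bin positive and negative counts in a single pass.
#' Training is order-independent: the model depends only on the multiset of
#' (bin, label) pairs.
#'
#' @param bins 0-based integer bin indices, one per example.
#' @param labels binary labels (1/TRUE = positive class).
#' @param spec the [grid_spec()] the bins were computed with.
#' @param seed the random-table seed the bins were computed with.
#' @return an object of class `hash_model`.
#' @export
train_hash_model <- function(bins, labels, spec, seed) {
  stopifnot(inherits(spec, "grid_spec"))
  labels <- as.integer(as.logical(labels))
  bins <- as.integer(bins)
  if (length(bins) == 0L) stopf("cannot train on an empty example stream")
  if (length(bins) != length(labels)) stopf("bins and labels differ in length")
  if (any(bins < 0 | bins >= spec$bins)) stopf("bin index outside [0, B)")
  B <- as.integer(spec$bins)
  pos <- tabulate(bins[labels == 1L] + 1L, nbins = B)
  neg <- tabulate(bins[labels == 0L] + 1L, nbins = B)
  new_hash_model(spec, seed, as.numeric(pos), as.numeric(neg))
}

new_hash_model <- function(spec, seed, pos, neg) {
  structure(list(spec = spec, seed = as.integer(seed),
                 pos_counts = pos, neg_counts = neg,
                 n_pos = sum(pos), n_neg = sum(neg),
                 format_version = 1L),
            class = "hash_model")
}

#' @export
print.hash_model <- function(x, ...) {
  cat(sprintf(paste0("<hash_model: grid %dx%d, spacing %d, q=%g, B=%s; ",
                     "%s positive / %s negative examples>\n"),
              x$spec$grid_size, x$spec$grid_size, x$spec$grid_spacing,
              x$spec$quantization, format(x$spec$bins, big.mark = ","),
              format(x$n_pos, big.mark = ","),
              format(x$n_neg, big.mark = ",")))
  invisible(x)
}

#' Predict labels for binned examples
#'
#' @param model a trained `hash_model`.
#' @param bins 0-based bin indices.
#' @return list with `label` (integer 0/1), `pos_count`, `neg_count`.
#' @export
predict_bins <- function(model, bins) {
  stopifnot(inherits(model, "hash_model"))
  if (model$n_pos + model$n_neg == 0) stopf("model has not been trained")
  p <- model$pos_counts[bins + 1L]
  n <- model$neg_counts[bins + 1L]
  list(label = as.integer(p > n), pos_count = p, neg_count = n)
}

#' Classify one pixel of a plane
#'
#' @param model a trained `hash_model`.
#' @param plane matrix or `h x w x ch` array.
#' @param center 0-based `c(row, col)`.
#' @return list with `label` (1 = positive), `pos_count`, `neg_count`.
#' @export
predict_pixel <- function(model, plane, center) {
  b <- pixel_bins(plane, center[1], center[2], model$spec, model$seed)
  r <- predict_bins(model, b)
  list(label = r$label[1], pos_count = r$pos_count[1],
       neg_count = r$neg_count[1])
}

#' log10 of the number of distinct grid-example configurations
#'
#' A grid of `N = grid_size^2` sampled pixels quantized to
#' `K = Q^n_channels` colors can take `K^N` configurations; this returns
#' `log10(K^N) = N * n_channels * log10(Q)`, which overflows no finite
#' double for the sizes of interest.
#'
#' @param spec a [grid_spec()].
#' @export
grid_config_log10 <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  spec$grid_size^2 * length(spec$channels) * log10(n_quant_levels(spec))
}

#' Save / load a hash model (versioned container)
#'
#' The container stores the spec, seed and the two count arrays; the random
#' table is regenerated from the seed on load, so a round trip restores
#' predictions bit-exactly.
#'
#' @param model a `hash_model`.
#' @param path file path.
#' @export
save_hash_model <- function(model, path) {
  stopifnot(inherits(model, "hash_model"))
  payload <- list(format = "grainhash-hash-model",
                  version = model$format_version,
                  spec = unclass(model$spec), seed = model$seed,
                  pos_counts = model$pos_counts, neg_counts = model$neg_counts)
  saveRDS(payload, path, compress = FALSE)  # size stays linear in B (~32 MB at the default B)
  invisible(path)
}

#' @rdname save_hash_model
#' @export
load_hash_model <- function(path) {
  payload <- tryCatch(readRDS(path),
                      error = function(e) stopf("not a readable model file: %s",
                                                conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "grainhash-hash-model"))
    stopf("file is not a grainhash hash-model container")
  if (!identical(payload$version, 1L))
    stopf("unsupported model format version: %s", format(payload$version))
  spec <- do.call(grid_spec, payload$spec[c("grid_size", "grid_spacing",
                                            "quantization", "bins", "channels",
                                            "max_intensity")])
  new_hash_model(spec, payload$seed, payload$pos_counts, payload$neg_counts)
}
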