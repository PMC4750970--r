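# Pass 1 — pollen spotting: train the hash pixel classifier on
# expert-style labeled windows, emit per-pixel pollen masks, and evaluate
# pixel-level agreement with leave-one-window-out cross-validation.

#' Train a pollen-spotting model from labeled windows
#'
#' Every pixel of every labeled window becomes one training example (its
#' mask value supplies the binary label).  Windows labeled by multiple
#' annotators are passed as separate windows — replicates are deliberately
#' not merged by vote, so annotator disagreement acts as label smoothing
#' and the example count is `sum over windows of height x width`.
#'
#' @param windows list of `gh_window` objects, each carrying a binary mask.
#' @param spec a [grid_spec()].
#' @param seed integer random-table seed.
#' @return a trained `hash_model` whose `n_pos + n_neg` equals the total
#'   pixel count across windows.
#' @export
train_spotter <- function(windows, spec, seed) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.list(windows) || length(windows) < 1L)
    stopf("at least one labeled window is required")
  B <- as.integer(spec$bins)
  pos <- numeric(B)
  neg <- numeric(B)
  for (w in windows) {
    if (!inherits(w, "gh_window") || is.null(w$mask))
      stopf("every training window must be a gh_window with a binary mask")
    bins <- plane_bins(w$pixels, spec, seed)
    pos <- pos + tabulate(bins[w$mask == 1L] + 1L, nbins = B)
    neg <- neg + tabulate(bins[w$mask == 0L] + 1L, nbins = B)
  }
  new_hash_model(spec, seed, pos, neg)
}

#' Predict a binary pollen mask for a window
#'
#' Classifies every pixel independently with the trained model; the
#' returned mask has the window's dimensions with 1 = pollen.
#'
#' @param model a trained `hash_model`.
#' @param window a `gh_window` (mask, if any, is ignored).
#' @export
predict_window_mask <- function(model, window) {
  stopifnot(inherits(model, "hash_model"), inherits(window, "gh_window"))
  if (model$n_pos + model$n_neg == 0) stopf("model has not been trained")
  bins <- plane_bins(window$pixels, model$spec, model$seed)
  mask <- matrix(as.integer(model$pos_counts[bins + 1L] >
                            model$neg_counts[bins + 1L]),
                 nrow = nrow(bins), ncol = ncol(bins))
  mask
}

#' Fraction of pixels on which two masks agree
#'
#' Plain pixel agreement over all pixels (background included) —
#' `1 - normalized Hamming distance`, symmetric in its arguments.
#'
#' @param a,b binary matrices of equal dimensions.
#' @export
pixel_agreement <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stopf("mask dimensions differ: %d x %d vs %d x %d",
          nrow(a), ncol(a), nrow(b), ncol(b))
  mean(a == b)
}

#' Dice overlap coefficient between two binary masks
#' @param a,b binary matrices of equal dimensions.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stopf("mask dimensions differ")
  2 * sum(a == 1 & b == 1) / (sum(a == 1) + sum(b == 1))
}

#' Leave-one-window-out cross-validation of the spotter
#'
#' With `n` labeled windows runs an `n`-fold cross-validation: each fold
#' trains on `n - 1` windows and scores pixel agreement on the held-out
#' window's mask.  Count arrays are additive, so each fold's model is the
#' full model minus the held-out window's contribution; this makes the
#' procedure a single pass over the data.
#'
#' @param windows list of labeled `gh_window` objects (>= 2).
#' @param spec a [grid_spec()].
#' @param seed integer random-table seed.
#' @return list with `mean_accuracy`, `fold_accuracy` (one per window) and
#'   `pooled_accuracy` (all held-out pixels pooled).
#' @export
loo_cross_validate <- function(windows, spec, seed) {
  stopifnot(inherits(spec, "grid_spec"))
  n <- length(windows)
  if (n < 2L) stopf("leave-one-out needs at least 2 windows")
  B <- as.integer(spec$bins)
  wpos <- vector("list", n)
  wneg <- vector("list", n)
  wbins <- vector("list", n)
  pos <- numeric(B); neg <- numeric(B)
  for (i in seq_len(n)) {
    w <- windows[[i]]
    if (is.null(w$mask)) stopf("window %d has no mask", i)
    bins <- plane_bins(w$pixels, spec, seed)
    wbins[[i]] <- bins
    wpos[[i]] <- tabulate(bins[w$mask == 1L] + 1L, nbins = B)
    wneg[[i]] <- tabulate(bins[w$mask == 0L] + 1L, nbins = B)
    pos <- pos + wpos[[i]]
    neg <- neg + wneg[[i]]
  }
  acc <- numeric(n)
  agree_px <- 0; total_px <- 0
  for (i in seq_len(n)) {
    p <- pos - wpos[[i]]
    q <- neg - wneg[[i]]
    pred <- as.integer(p[wbins[[i]] + 1L] > q[wbins[[i]] + 1L])
    eq <- pred == as.vector(windows[[i]]$mask)
    acc[i] <- mean(eq)
    agree_px <- agree_px + sum(eq)
    total_px <- total_px + length(eq)
  }
  list(mean_accuracy = mean(acc), fold_accuracy = acc,
       pooled_accuracy = agree_px / total_px)
}

#' Bookkeeping: number of labeled training examples (pixels)
#'
#' Every pixel of every window, replicated once per annotator, is one
#' training example; 637 windows of 1000 x 1000 pixels labeled by 11
#' annotators give 7.007e9 examples.
#'
#' @param n_windows number of labeled windows.
#' @param window_height,window_width window dimensions in pixels.
#' @param n_annotators independent annotators per window.
#' @export
spotting_example_count <- function(n_windows, window_height, window_width,
                                   n_annotators = 1) {
  as.numeric(n_windows) * as.numeric(window_height) *
    as.numeric(window_width) * as.numeric(n_annotators)
}
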