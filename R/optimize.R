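# Hyperparameter search with cross-validated objectives: one-dimension-
# at-a-time coordinate descent (the pass-1 strategy) and seeded uniform
# random search (the pass-2 strategy), plus learning-curve generation.
# Objectives are maximized and cached per parameter point.

#' Define a parameter search space
#'
#' Each named dimension is either a finite ordered value vector (discrete —
#' e.g. powers of two for grid size and spacing) or a continuous interval
#' given as `list(min =, max =)` (sampled uniformly by random search).
#'
#' @param ... named dimensions.
#' @export
param_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0L || is.null(names(dims)) || any(names(dims) == ""))
    stopf("every dimension must be named")
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (is.list(d)) {
      if (!all(c("min", "max") %in% names(d)) || d$min >= d$max)
        stopf("continuous dimension '%s' needs min < max", nm)
    } else if (length(d) < 1L) {
      stopf("dimension '%s' is empty", nm)
    }
  }
  structure(dims, class = "param_space")
}

is_continuous_dim <- function(d) is.list(d)

new_search_trace <- function(points, objectives) {
  df <- do.call(rbind, lapply(points, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  df$objective <- objectives
  best <- which.max(objectives)
  structure(list(trace = df, best_point = points[[best]],
                 best_objective = objectives[best]),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("<search_trace: %d evaluated points; best objective %.4f at %s>\n",
              nrow(x$trace), x$best_objective,
              paste(names(x$best_point), unlist(x$best_point),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

make_cached_objective <- function(objective, cache = TRUE) {
  env <- new.env(parent = emptyenv())
  function(point) {
    key <- paste(names(point), vapply(point, format, character(1)),
                 sep = "=", collapse = ";")
    if (cache && !is.null(env[[key]])) return(env[[key]])
    val <- tryCatch(objective(point), error = function(e) {
      warning(sprintf("objective failed at %s: %s", key,
                      conditionMessage(e)))
      NA_real_
    })
    if (cache) env[[key]] <- val
    val
  }
}

#' One-dimension-at-a-time coordinate descent
#'
#' Sweeps each dimension in declared order with the others held at the
#' current best value, advancing along the dimension's ordering from the
#' start value and stopping at the first non-improvement (greedy).  By
#' default one full cycle over the dimensions is performed, mirroring the
#' single-pass optimization of the spotting parameters; additional cycles
#' repeat the sweep from the incumbent.
#'
#' @param space a [param_space()] (discrete dimensions only).
#' @param objective function of a named parameter list returning a scalar
#'   score to maximize; failures at a point are skipped with a warning.
#' @param start named list of start values (default: first value of each
#'   dimension).
#' @param cycles number of sweeps over all dimensions (default 1).
#' @param cache cache objective evaluations per point (default TRUE).
#' @return a `search_trace` (never worse than the start point).
#' @export
coordinate_descent <- function(space, objective, start = NULL, cycles = 1L,
                               cache = TRUE) {
  stopifnot(inherits(space, "param_space"))
  if (any(vapply(space, is_continuous_dim, logical(1))))
    stopf("coordinate descent requires discrete ordered dimensions")
  if (is.null(start)) start <- lapply(space, `[[`, 1L)
  if (!setequal(names(start), names(space)))
    stopf("`start` must name every dimension")
  for (nm in names(space)) {
    if (!start[[nm]] %in% space[[nm]])
      stopf("start value of '%s' is not in the space", nm)
  }
  obj <- make_cached_objective(objective, cache)
  points <- list(); objectives <- numeric(0)
  eval_point <- function(p) {
    v <- obj(p)
    points[[length(points) + 1L]] <<- p
    objectives[length(objectives) + 1L] <<- v
    v
  }
  current <- start[names(space)]
  best_val <- eval_point(current)
  for (cycle in seq_len(cycles)) {
    for (nm in names(space)) {
      vals <- space[[nm]]
      i <- match(current[[nm]], vals)
      while (i < length(vals)) {
        cand <- current
        cand[[nm]] <- vals[i + 1L]
        v <- eval_point(cand)
        if (is.na(v) || v <= best_val) break
        best_val <- v
        current <- cand
        i <- i + 1L
      }
    }
  }
  new_search_trace(points, objectives)
}

#' Seeded uniform random search
#'
#' Draws `n_points` parameter points (discrete dimensions uniform over
#' their values, continuous uniform over their interval), evaluates each,
#' and reports the best.  The point sequence is fully reproducible from
#' the seed.
#'
#' @param space a [param_space()].
#' @param objective function of a named parameter list (maximized).
#' @param n_points number of random points to evaluate (default 397).
#' @param seed integer seed.
#' @param cache cache objective evaluations (default TRUE).
#' @export
random_search <- function(space, objective, n_points = 397L, seed = 1L,
                          cache = TRUE) {
  stopifnot(inherits(space, "param_space"))
  if (!is_count(n_points)) stopf("`n_points` must be a positive integer")
  obj <- make_cached_objective(objective, cache)
  points <- with_seed(seed, {
    lapply(seq_len(n_points), function(i) {
      p <- lapply(space, function(d) {
        if (is_continuous_dim(d)) stats::runif(1, d$min, d$max)
        else d[[sample.int(length(d), 1L)]]
      })
      names(p) <- names(space)
      p
    })
  })
  objectives <- vapply(points, obj, numeric(1))
  new_search_trace(points, objectives)
}

#' Learning curves over training-pool size
#'
#' For each size, draws `reps` seeded subsamples of the pool and applies
#' `evaluator` to the subset, recording one accuracy per repetition.
#'
#' @param pool_size number of available training units (e.g. slides).
#' @param sizes vector of subset sizes to evaluate (each `<= pool_size`).
#' @param reps repetitions per size.
#' @param evaluator `function(indices, rep_seed)` returning an accuracy.
#' @param seed integer seed.
#' @return data.frame with columns `size`, `rep`, `accuracy`
#'   (`length(sizes) * reps` rows).
#' @export
learning_curve <- function(pool_size, sizes, reps, evaluator, seed = 1L) {
  if (any(sizes > pool_size)) stopf("a size exceeds the pool (%d)", pool_size)
  if (any(sizes < 1L)) stopf("sizes must be positive")
  rows <- list()
  for (s in sizes) {
    for (r in seq_len(reps)) {
      rep_seed <- derive_seed(seed, s * 1000L + r)
      idx <- with_seed(rep_seed, sample.int(pool_size, s))
      acc <- evaluator(idx, rep_seed)
      rows[[length(rows) + 1L]] <- data.frame(size = s, rep = r,
                                              accuracy = acc)
    }
  }
  do.call(rbind, rows)
}
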