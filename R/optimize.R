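# Real-coded genetic algorithm over a surrogate predictor, with an
# exhaustive lattice search as a verification oracle.

#' Genetic-algorithm configuration
#'
#' @param pop Population size (>= 4).
#' @param generations Number of generations.
#' @param crossover Probability that an offspring is produced by blend
#'   (BLX-0.5) crossover rather than copied from a parent.
#' @param mutation Per-gene probability of Gaussian mutation (sd = 10% of
#'   the gene's range).
#' @param elitism Number of best individuals copied unchanged into the
#'   next generation.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param bounds Numeric matrix with rows `lo`, `hi` and one column per
#'   factor (coded scale). Defaults to the coded box `[-1, 1]^k` when the
#'   dimension is known from context.
#' @param weights Non-negative scalarization weights, one per response,
#'   not all zero.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop = 50, generations = 100, crossover = 0.8,
                      mutation = 0.1, elitism = 2, seed = 1L,
                      bounds = NULL, weights = rep(1, 4)) {
  if (pop < 4) stop("'pop' must be >= 4")
  if (elitism < 0 || elitism >= pop) stop("'elitism' must be in [0, pop)")
  weights <- as.numeric(weights)
  if (any(weights < 0) || all(weights == 0))
    stop("'weights' must be non-negative and not all zero")
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (nrow(bounds) != 2 || any(bounds[1, ] >= bounds[2, ]))
      stop("'bounds' must be a 2-row matrix with lo < hi")
  }
  structure(list(pop = as.integer(pop),
                 generations = as.integer(generations),
                 crossover = crossover, mutation = mutation,
                 elitism = as.integer(elitism), seed = as.integer(seed),
                 bounds = bounds, weights = weights),
            class = "ga_config")
}

#' Observed response ranges for fitness normalization
#'
#' @param responses Matrix or data frame of observed responses.
#' @return 2-row matrix (`min`, `max`) with one column per response.
#' @export
response_ranges <- function(responses) {
  Y <- as.matrix(responses)
  rbind(min = apply(Y, 2, min), max = apply(Y, 2, max))
}

#' Scalarize multi-response predictions into a single fitness value
#'
#' Each predicted response is min-max normalized against its observed
#' range and the normalized values are combined as a weighted mean:
#' `sum(w_i * (yhat_i - min_i) / (max_i - min_i)) / sum(w_i)`. The result
#' lies in `[0, 1]` whenever predictions stay within the observed ranges.
#'
#' @param predicted Numeric vector (one point) or matrix (points x
#'   responses) of predictions.
#' @param weights Non-negative weights, one per response, not all zero.
#' @param ranges 2-row `min`/`max` matrix, as from [response_ranges()].
#' @return Numeric fitness vector, one value per point.
#' @export
scalarize <- function(predicted, weights, ranges) {
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  weights <- as.numeric(weights)
  if (any(weights < 0) || all(weights == 0))
    stop("'weights' must be non-negative and not all zero")
  ranges <- as.matrix(ranges)
  span <- ranges[2, ] - ranges[1, ]
  if (any(span <= 0)) stop("degenerate normalization range")
  norm <- sweep(sweep(predicted, 2, ranges[1, ]), 2, span, `/`)
  as.numeric(norm %*% weights) / sum(weights)
}

ga_decode <- function(x, factors, scheme, snap) {
  nm <- vapply(factors, `[[`, "", "name")
  out <- numeric(length(nm))
  for (i in seq_along(factors)) {
    out[i] <- if (nm[i] %in% snap)
      decode_value(factors[[i]], x[i], "ordinal")
    else decode_value(factors[[i]], x[i], scheme)
  }
  names(out) <- nm
  out
}

#' Optimize extraction conditions with a real-coded genetic algorithm
#'
#' Maximizes the scalarized surrogate prediction over the (coded) factor
#' box using tournament selection (size 2), blend crossover, Gaussian
#' mutation and elitism. The best-ever individual is returned; with
#' elitism it can never regress across generations. Runs are
#' deterministic given the config seed.
#'
#' @param predict_fn Function mapping a numeric matrix of coded points
#'   (points x factors) to a matrix of predicted responses.
#' @param config A [ga_config()]; `config$bounds` defaults to
#'   `[-1, 1]^k`.
#' @param ranges Normalization ranges for [scalarize()].
#' @param factors Optional list of [factor_spec()]; when given, the best
#'   settings are also reported in actual units.
#' @param scheme Coding scheme used for decoding (default `"affine"`).
#' @param init_points Optional matrix of coded points (e.g. the design
#'   runs) seeded into the initial population, so every design point is a
#'   candidate from generation one.
#' @param snap Character vector of factor names whose reported setting is
#'   snapped to the nearest design level (useful when only discrete
#'   settings, such as the three ultrasonic frequencies, are physically
#'   available). Snapping affects reporting only, not the search.
#' @return An object of class `ga_result`: `best` (coded), `best_actual`
#'   (when `factors` given), `predicted`, `fitness`, per-generation
#'   best-ever `trace`, and the config.
#' @export
ga_optimize <- function(predict_fn, config, ranges, factors = NULL,
                        scheme = "affine", init_points = NULL,
                        snap = character()) {
  stopifnot(inherits(config, "ga_config"))
  bounds <- config$bounds
  if (is.null(bounds)) {
    k <- if (!is.null(factors)) length(factors)
         else if (!is.null(init_points)) ncol(init_points)
         else stop("supply config$bounds, factors or init_points to fix the dimension")
    bounds <- matrix(rep(c(-1, 1), k), nrow = 2,
                     dimnames = list(c("lo", "hi"), NULL))
  }
  k <- ncol(bounds)
  lo <- bounds[1, ]; hi <- bounds[2, ]
  evaluate <- function(P) {
    f <- scalarize(predict_fn(P), config$weights, ranges)
    bad <- !is.finite(f)
    if (any(bad)) {
      warning(sum(bad), " individual(s) with non-finite fitness discarded")
      f[bad] <- -Inf
    }
    f
  }

  withr::with_seed(config$seed, {
    P <- matrix(stats::runif(config$pop * k), config$pop, k)
    P <- sweep(sweep(P, 2, hi - lo, `*`), 2, lo, `+`)
    if (!is.null(init_points)) {
      init_points <- as.matrix(init_points)
      take <- seq_len(min(nrow(init_points), config$pop))
      P[take, ] <- pmin(pmax(init_points[take, , drop = FALSE],
                             rep(lo, each = length(take))),
                        rep(hi, each = length(take)))
    }
    fit <- evaluate(P)
    best_x <- P[which.max(fit), ]
    best_f <- max(fit)
    trace <- numeric(config$generations)
    mut_sd <- 0.1 * (hi - lo)

    for (gen in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      newP <- matrix(NA_real_, config$pop, k)
      n_elite <- config$elitism
      if (n_elite > 0) newP[seq_len(n_elite), ] <- P[ord[seq_len(n_elite)], ]
      for (j in seq.int(n_elite + 1L, config$pop)) {
        pick <- function() {
          c2 <- sample.int(config$pop, 2)
          c2[which.max(fit[c2])]
        }
        p1 <- P[pick(), ]
        if (stats::runif(1) < config$crossover) {
          p2 <- P[pick(), ]
          mn <- pmin(p1, p2); mx <- pmax(p1, p2)
          d <- mx - mn
          child <- stats::runif(k, mn - 0.5 * d, mx + 0.5 * d)
        } else child <- p1
        mut <- stats::runif(k) < config$mutation
        if (any(mut))
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mut_sd[mut])
        newP[j, ] <- pmin(pmax(child, lo), hi)
      }
      P <- newP
      fit <- evaluate(P)
      if (max(fit) > best_f) {
        best_f <- max(fit)
        best_x <- P[which.max(fit), ]
      }
      trace[gen] <- best_f
    }
  })

  pred <- predict_fn(matrix(best_x, nrow = 1))
  structure(list(
    best = best_x,
    best_actual = if (!is.null(factors))
      ga_decode(best_x, factors, scheme, snap) else NULL,
    predicted = drop(pred),
    fitness = best_f,
    trace = trace,
    config = config), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA optimum (seed %d): fitness %.4f\n",
              x$config$seed, x$fitness))
  if (!is.null(x$best_actual)) {
    cat("  settings: ",
        paste(sprintf("%s = %.3g", names(x$best_actual), x$best_actual),
              collapse = ", "), "\n")
  } else {
    cat("  coded settings: ", paste(signif(x$best, 4), collapse = ", "), "\n")
  }
  cat("  predicted responses: ",
      paste(signif(x$predicted, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive lattice search over the factor box
#'
#' Brute-force evaluation of the scalarized surrogate on a regular
#' lattice; the exact arg-max over the lattice. Used as an independent
#' oracle for the genetic algorithm.
#'
#' @inheritParams ga_optimize
#' @param resolution Lattice points per factor (scalar or per-factor
#'   vector, each >= 3).
#' @param bounds 2-row `lo`/`hi` matrix (coded scale); defaults to
#'   `[-1, 1]^k` with `k` taken from `resolution`'s length or `weights`.
#' @param weights Scalarization weights.
#' @param cap Maximum lattice size.
#' @return List with `best` (coded point), `fitness` and `resolution`.
#' @export
grid_search_oracle <- function(predict_fn, resolution, bounds = NULL,
                               weights, ranges, cap = 5e6) {
  if (is.null(bounds)) {
    k <- length(resolution)
    if (k == 1) stop("supply per-factor 'resolution' or 'bounds' to fix the dimension")
    bounds <- matrix(rep(c(-1, 1), k), nrow = 2)
  }
  k <- ncol(bounds)
  resolution <- rep_len(as.integer(resolution), k)
  if (any(resolution < 3)) stop("'resolution' must be >= 3 per factor")
  if (prod(resolution) > cap)
    stop("lattice of ", prod(resolution), " points exceeds cap ", cap)
  axes <- lapply(seq_len(k), function(i)
    seq(bounds[1, i], bounds[2, i], length.out = resolution[i]))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- colnames(bounds)
  f <- scalarize(predict_fn(grid), weights, ranges)
  i <- which.max(f)
  list(best = grid[i, ], fitness = f[i], resolution = resolution)
}
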