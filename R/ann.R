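# Feed-forward neural surrogate (k inputs -> H tanh units -> m linear
# outputs) trained by damped Gauss-Newton (Levenberg-Marquardt) on the
# network Jacobian, or by BFGS on the same objective.

#' Partition runs into training / testing / validation sets
#'
#' Set sizes follow largest-remainder apportionment of
#' `n_runs * fractions` (so 27 runs at 65/20/15 percent give 18/5/4);
#' membership is a seeded random permutation and is fully reproducible.
#'
#' @param n_runs Number of runs to partition (>= 5).
#' @param fractions Numeric triple (train, test, validation) summing to 1.
#' @param seed Integer seed controlling membership.
#' @return An object of class `split_plan` with integer index vectors
#'   `train`, `test`, `val`.
#' @examples
#' split_data(27, c(0.65, 0.20, 0.15), seed = 1)
#' @export
split_data <- function(n_runs, fractions = c(0.65, 0.20, 0.15), seed = 1L) {
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 5) stop("'n_runs' must be >= 5")
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions <= 0))
    stop("'fractions' must be 3 positive values")
  if (abs(sum(fractions) - 1) > 1e-8) stop("'fractions' must sum to 1")

  quota <- n_runs * fractions
  sizes <- floor(quota)
  short <- n_runs - sum(sizes)
  if (short > 0) {
    give <- order(quota - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[give] <- sizes[give] + 1
  }
  perm <- withr::with_seed(seed, sample.int(n_runs))
  structure(list(
    train = sort(perm[seq_len(sizes[1])]),
    test = sort(perm[sizes[1] + seq_len(sizes[2])]),
    val = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]),
    fractions = fractions, sizes = sizes, seed = seed),
    class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan (seed %d): train %d / test %d / val %d\n",
              x$seed, length(x$train), length(x$test), length(x$val)))
  invisible(x)
}

ann_npar <- function(k, H, m, cascade) {
  H * k + H + m * H + m + if (cascade) m * k else 0L
}

ann_unpack <- function(par, k, H, m, cascade) {
  i <- H * k
  W1 <- matrix(par[seq_len(i)], H, k)
  b1 <- par[i + seq_len(H)]; i <- i + H
  W2 <- matrix(par[i + seq_len(m * H)], m, H); i <- i + m * H
  b2 <- par[i + seq_len(m)]; i <- i + m
  W3 <- if (cascade) matrix(par[i + seq_len(m * k)], m, k) else NULL
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3)
}

ann_forward <- function(par, X, k, H, m, cascade) {
  w <- ann_unpack(par, k, H, m, cascade)
  n <- nrow(X)
  Z <- tanh(X %*% t(w$W1) + matrix(w$b1, n, H, byrow = TRUE))
  Y <- Z %*% t(w$W2) + matrix(w$b2, n, m, byrow = TRUE)
  if (cascade) Y <- Y + X %*% t(w$W3)
  list(Z = Z, Y = Y)
}

# Jacobian of the stacked residual vector (column-major over outputs)
# with respect to the packed parameter vector.
ann_jacobian <- function(par, X, k, H, m, cascade) {
  w <- ann_unpack(par, k, H, m, cascade)
  n <- nrow(X)
  fw <- ann_forward(par, X, k, H, m, cascade)
  Z <- fw$Z
  dZ <- 1 - Z^2
  J <- matrix(0, n * m, length(par))
  off_b1 <- H * k
  off_W2 <- off_b1 + H
  off_b2 <- off_W2 + m * H
  off_W3 <- off_b2 + m
  for (o in seq_len(m)) {
    rows <- (o - 1L) * n + seq_len(n)
    for (h in seq_len(H)) {
      s <- w$W2[o, h] * dZ[, h]
      for (i in seq_len(k))
        J[rows, (i - 1L) * H + h] <- s * X[, i]          # W1[h, i]
      J[rows, off_b1 + h] <- s                            # b1[h]
      J[rows, off_W2 + (h - 1L) * m + o] <- Z[, h]        # W2[o, h]
    }
    J[rows, off_b2 + o] <- 1                              # b2[o]
    if (cascade)
      for (i in seq_len(k))
        J[rows, off_W3 + (i - 1L) * m + o] <- X[, i]      # W3[o, i]
  }
  J
}

scale_minmax <- function(Y) {
  lo <- apply(Y, 2, min)
  hi <- apply(Y, 2, max)
  if (any(hi - lo <= 0)) stop("constant response column cannot be scaled")
  list(scaled = sweep(sweep(Y, 2, lo), 2, (hi - lo) / 2, `/`) - 1,
       lo = lo, hi = hi)
}

unscale_minmax <- function(Ys, lo, hi) {
  sweep(sweep((Ys + 1) / 2, 2, hi - lo, `*`), 2, lo, `+`)
}

train_lm_core <- function(par, Xtr, Ytr, Xval, Yval, k, H, m, cascade,
                          max_iter, tol) {
  resid_fn <- function(p) as.vector(
    ann_forward(p, Xtr, k, H, m, cascade)$Y - Ytr)
  val_mse <- function(p) {
    if (is.null(Xval) || nrow(Xval) == 0) return(NA_real_)
    mean((ann_forward(p, Xval, k, H, m, cascade)$Y - Yval)^2)
  }
  nr <- length(Ytr)
  r <- resid_fn(par)
  sse <- sum(r^2)
  lambda <- 1e-3
  hist <- data.frame(iter = 0L, train_mse = sse / nr, val_mse = val_mse(par))
  for (it in seq_len(max_iter)) {
    J <- ann_jacobian(par, Xtr, k, H, m, cascade)
    g <- crossprod(J, r)
    A <- crossprod(J)
    D <- diag(pmax(diag(A), 1e-8), nrow(A))
    accepted <- FALSE
    old <- sse
    for (try in 1:25) {
      delta <- tryCatch(solve(A + lambda * D, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- par - as.vector(delta)
        rc <- resid_fn(cand)
        sc <- sum(rc^2)
        if (is.finite(sc) && sc < sse) {
          par <- cand; r <- rc; sse <- sc
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) break
    hist <- rbind(hist, data.frame(iter = it, train_mse = sse / nr,
                                   val_mse = val_mse(par)))
    if ((old - sse) / nr < tol) break
  }
  list(par = par, history = hist, train_mse = sse / nr,
       val_mse = val_mse(par))
}

train_bfgs_core <- function(par, Xtr, Ytr, Xval, Yval, k, H, m, cascade,
                            max_iter, tol) {
  nr <- length(Ytr)
  env <- new.env()
  env$hist <- list()
  fn <- function(p) {
    v <- sum((ann_forward(p, Xtr, k, H, m, cascade)$Y - Ytr)^2)
    env$hist[[length(env$hist) + 1L]] <- v / nr
    v
  }
  gr <- function(p) {
    r <- as.vector(ann_forward(p, Xtr, k, H, m, cascade)$Y - Ytr)
    2 * as.vector(crossprod(ann_jacobian(p, Xtr, k, H, m, cascade), r))
  }
  opt <- stats::optim(par, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  val_mse <- if (is.null(Xval) || nrow(Xval) == 0) NA_real_ else
    mean((ann_forward(opt$par, Xval, k, H, m, cascade)$Y - Yval)^2)
  tr <- unlist(env$hist)
  tr <- cummin(tr)  # best-so-far objective over evaluations
  list(par = opt$par,
       history = data.frame(iter = seq_along(tr) - 1L, train_mse = tr,
                            val_mse = NA_real_),
       train_mse = opt$value / nr, val_mse = val_mse)
}

ann_inputs <- function(design) {
  if (inherits(design, "bbd_design"))
    list(X = coded_matrix(design), factors = design_factors(design),
         scheme = attr(design, "scheme") %||% "affine")
  else
    list(X = as.matrix(design), factors = NULL, scheme = NULL)
}

#' Train a feed-forward neural surrogate
#'
#' Fits a `k`-input, `n_hidden` tanh-unit, `m`-output network to the
#' (min-max scaled) responses by minimizing training-set mean squared
#' error, either with a damped Gauss-Newton (Levenberg-Marquardt) loop on
#' the analytic network Jacobian (`algorithm = "lm"`) or with BFGS on the
#' same objective. Inputs are the coded factors; outputs are scaled to
#' `[-1, 1]` per response over all runs and inverse-scaled at prediction
#' time. Training is deterministic given `(data, seed, options)`.
#'
#' @param design A `bbd_design` or a numeric matrix of coded inputs.
#' @param responses Matrix or data frame of responses (runs x outputs).
#' @param n_hidden Number of hidden units (1 to 20).
#' @param algorithm `"lm"` (default) or `"bfgs"`.
#' @param split A [split_data()] plan; by default computed from `seed`
#'   with the 65/20/15 fractions.
#' @param seed Integer seed for weight initialization (uniform in
#'   `[-0.5, 0.5]`) and the default split.
#' @param max_iter,tol Iteration cap and minimum per-iteration decrease
#'   of training MSE (scaled units).
#' @param n_restarts Independent restarts (seeds `seed`, `seed + 1`, ...);
#'   the restart with the lowest validation MSE is kept.
#' @param cascade If `TRUE`, adds direct input-to-output (skip)
#'   connections (a cascade-forward network).
#' @return An object of class `ann_surrogate`.
#' @export
train_ann <- function(design, responses, n_hidden = 10,
                      algorithm = c("lm", "bfgs"), split = NULL,
                      seed = 1L, max_iter = 500L, tol = 1e-8,
                      n_restarts = 1L, cascade = FALSE) {
  algorithm <- match.arg(algorithm)
  inp <- ann_inputs(design)
  X <- inp$X
  Y <- as.matrix(responses)
  if (!is.numeric(X) || !is.numeric(Y) || anyNA(X) || anyNA(Y) ||
      any(!is.finite(X)) || any(!is.finite(Y)))
    stop("inputs and responses must be finite and numeric")
  if (nrow(X) != nrow(Y)) stop("design and responses have different run counts")
  n_hidden <- as.integer(n_hidden)
  if (is.na(n_hidden) || n_hidden < 1 || n_hidden > 20)
    stop("'n_hidden' must be between 1 and 20")
  k <- ncol(X); m <- ncol(Y); n <- nrow(X)
  if (is.null(split)) split <- split_data(n, seed = seed)

  sc <- scale_minmax(Y)
  Ys <- sc$scaled
  tr <- split$train; va <- split$val; te <- split$test
  core <- if (algorithm == "lm") train_lm_core else train_bfgs_core

  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    par0 <- withr::with_seed(seed + r - 1L,
                             stats::runif(ann_npar(k, n_hidden, m, cascade),
                                          -0.5, 0.5))
    res <- core(par0, X[tr, , drop = FALSE], Ys[tr, , drop = FALSE],
                X[va, , drop = FALSE], Ys[va, , drop = FALSE],
                k, n_hidden, m, cascade, max_iter, tol)
    score <- if (is.na(res$val_mse)) res$train_mse else res$val_mse
    if (is.null(best) || score < best$score) {
      best <- res
      best$score <- score
      best$restart_seed <- seed + r - 1L
    }
  }

  test_mse <- if (length(te))
    mean((ann_forward(best$par, X[te, , drop = FALSE], k, n_hidden, m,
                      cascade)$Y - Ys[te, , drop = FALSE])^2) else NA_real_

  structure(list(
    n_hidden = n_hidden, k = k, m = m, cascade = cascade,
    par = best$par,
    weights = ann_unpack(best$par, k, n_hidden, m, cascade),
    y_lo = sc$lo, y_hi = sc$hi,
    input_names = colnames(X),
    response_names = colnames(Y) %||% paste0("y", seq_len(m)),
    factors = inp$factors, scheme = inp$scheme,
    algorithm = algorithm, split = split, seed = seed,
    restart_seed = best$restart_seed,
    mse_history = best$history,
    train_mse = best$train_mse, val_mse = best$val_mse,
    test_mse = test_mse
  ), class = "ann_surrogate")
}

#' @export
print.ann_surrogate <- function(x, ...) {
  cat(sprintf("ANN surrogate %d-%d-%d (%s%s), %d parameters, seed %d\n",
              x$k, x$n_hidden, x$m, x$algorithm,
              if (x$cascade) ", cascade" else "",
              length(x$par), x$seed))
  cat(sprintf("  scaled MSE: train %.3g / val %.3g / test %.3g (%d iterations)\n",
              x$train_mse, x$val_mse, x$test_mse, max(x$mse_history$iter)))
  invisible(x)
}

#' Predict from a neural surrogate
#'
#' @param model An `ann_surrogate`.
#' @param points A `bbd_design`, a data frame of factor settings in
#'   actual units (when the surrogate was trained on a design), or a
#'   numeric matrix of coded inputs.
#' @return Matrix of predicted responses (points x outputs), on the
#'   original response scales.
#' @export
predict_ann <- function(model, points) {
  stopifnot(inherits(model, "ann_surrogate"))
  if (is.numeric(points) && is.null(dim(points)))
    points <- matrix(points, nrow = 1)
  if (is.matrix(points) && is.numeric(points)) {
    X <- points
  } else {
    if (is.null(model$factors))
      stop("surrogate was trained on a raw matrix; supply coded inputs")
    nm <- vapply(model$factors, `[[`, "", "name")
    pts <- as.data.frame(points)
    missing <- setdiff(nm, names(pts))
    if (length(missing)) stop("points lack factor column(s): ",
                              paste(missing, collapse = ", "))
    X <- vapply(model$factors,
                function(f) code_value(f, pts[[f$name]], model$scheme),
                numeric(nrow(pts)))
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  }
  if (ncol(X) != model$k) stop("expected ", model$k, " inputs")
  if (any(abs(X) > 1 + 1e-8))
    warning("some points lie outside the coded box [-1, 1]; extrapolating")
  Ys <- ann_forward(model$par, X, model$k, model$n_hidden, model$m,
                    model$cascade)$Y
  out <- unscale_minmax(Ys, model$y_lo, model$y_hi)
  colnames(out) <- model$response_names
  out
}

#' Select the hidden-layer size by validation error
#'
#' Trains one surrogate per candidate hidden-layer size under a common
#' split and seed and selects the size with the lowest
#' validation-partition MSE (ties broken toward the smaller network).
#'
#' @inheritParams train_ann
#' @param h_range Integer vector of candidate hidden-layer sizes.
#' @param ... Further arguments passed to [train_ann()].
#' @return An object of class `ann_sweep`: `selected` (the chosen size),
#'   `table` (per-size train/val/test MSE, with a `note` column holding
#'   any training failure message) and `model` (the selected surrogate).
#' @export
sweep_hidden_neurons <- function(design, responses, h_range = 1:20,
                                 algorithm = c("lm", "bfgs"),
                                 split = NULL, seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  h_range <- sort(unique(as.integer(h_range)))
  if (!length(h_range)) stop("'h_range' is empty")
  n <- nrow(as.matrix(responses))
  if (is.null(split)) split <- split_data(n, seed = seed)

  tab <- data.frame(n_hidden = h_range, train_mse = NA_real_,
                    val_mse = NA_real_, test_mse = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  models <- vector("list", length(h_range))
  for (i in seq_along(h_range)) {
    fit <- tryCatch(
      train_ann(design, responses, n_hidden = h_range[i],
                algorithm = algorithm, split = split, seed = seed, ...),
      error = function(e) e)
    if (inherits(fit, "error")) {
      tab$note[i] <- conditionMessage(fit)
    } else {
      models[[i]] <- fit
      tab$train_mse[i] <- fit$train_mse
      tab$val_mse[i] <- fit$val_mse
      tab$test_mse[i] <- fit$test_mse
    }
  }
  score <- ifelse(is.na(tab$val_mse), tab$train_mse, tab$val_mse)
  if (all(is.na(score))) stop("training failed for every hidden-layer size")
  sel <- which.min(score)  # ties resolve to the smaller size (sorted range)
  structure(list(selected = h_range[sel], table = tab,
                 model = models[[sel]], split = split, seed = seed),
            class = "ann_sweep")
}

#' @export
print.ann_sweep <- function(x, ...) {
  cat(sprintf("Hidden-neuron sweep: selected H = %d (seed %d)\n",
              x$selected, x$seed))
  print(transform(x$table, train_mse = signif(train_mse, 4),
                  val_mse = signif(val_mse, 4),
                  test_mse = signif(test_mse, 4)), row.names = FALSE)
  invisible(x)
}

#' Save / load a neural surrogate as portable JSON
#'
#' Weights are written with 17 significant digits, enough to round-trip
#' IEEE doubles exactly.
#'
#' @param model An `ann_surrogate`.
#' @param path File path.
#' @return `ann_load()` returns the restored `ann_surrogate`.
#' @export
ann_save <- function(model, path) {
  stopifnot(inherits(model, "ann_surrogate"))
  out <- model
  out$weights <- NULL
  out$factors <- if (!is.null(model$factors))
    lapply(model$factors, unclass) else NULL
  out$split <- unclass(model$split)
  jsonlite::write_json(unclass(out), path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname ann_save
#' @export
ann_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$par <- as.numeric(x$par)
  x$y_lo <- stats::setNames(as.numeric(x$y_lo), x$response_names)
  x$y_hi <- stats::setNames(as.numeric(x$y_hi), x$response_names)
  x$weights <- ann_unpack(x$par, x$k, x$n_hidden, x$m, isTRUE(x$cascade))
  if (!is.null(x$factors))
    x$factors <- lapply(seq_len(nrow(x$factors)), function(i)
      factor_spec(x$factors$name[i], x$factors$unit[i],
                  unlist(x$factors$levels[i])))
  x$split <- structure(x$split, class = "split_plan")
  x$mse_history <- as.data.frame(x$mse_history)
  structure(x, class = "ann_surrogate")
}
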