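# Full second-order (quadratic) response-surface models on the coded scale.

quad_formula <- function(nm) {
  lin <- paste(nm, collapse = " + ")
  sq <- paste(sprintf("I(%s^2)", nm), collapse = " + ")
  ia <- utils::combn(nm, 2, FUN = paste, collapse = ":")
  stats::as.formula(paste(".response ~", lin, "+", sq, "+",
                          paste(ia, collapse = " + ")))
}

#' Names of the full second-order model terms
#'
#' @param factors List of [factor_spec()] objects.
#' @return Character vector: intercept, linear, pure quadratic and
#'   two-way interaction term labels, in model order.
#' @export
quad_term_names <- function(factors) {
  nm <- vapply(factors, `[[`, "", "name")
  c("(Intercept)", nm, sprintf("I(%s^2)", nm),
    utils::combn(nm, 2, FUN = paste, collapse = ":"))
}

#' Fit a full second-order response-surface model
#'
#' Ordinary least squares fit of the complete quadratic polynomial
#' (intercept, linear, pure quadratic and two-way interaction terms) in
#' the coded factors. For `k` factors the model has
#' `1 + 2k + choose(k, 2)` coefficients (15 for `k = 4`).
#'
#' @param design A `bbd_design` (or any design with factor attributes).
#' @param response Numeric response vector aligned with the design rows.
#' @param scheme Coding scheme; defaults to the design's scheme.
#' @param response_name Label used in reports.
#' @return An object of class `quad_rsm`: coefficients on the coded
#'   scale, residual df and mean square, and the underlying `lm` fit.
#' @examples
#' study <- sh_study()
#' m <- fit_quadratic(study$design, study$responses$tpc, response_name = "tpc")
#' predict(m, data.frame(ethanol_pct = 50, time_min = 35, temp_C = 40,
#'                       freq_kHz = 35))
#' @export
fit_quadratic <- function(design, response, scheme = NULL,
                          response_name = deparse(substitute(response))) {
  factors <- design_factors(design)
  if (is.null(scheme)) scheme <- attr(design, "scheme") %||% "affine"
  response <- as.numeric(response)
  if (length(response) != nrow(design))
    stop("length(response) (", length(response),
         ") does not match the number of design runs (", nrow(design), ")")
  if (anyNA(response) || any(!is.finite(response)))
    stop("response contains missing or non-finite values")
  k <- length(factors)
  p <- 1 + 2 * k + choose(k, 2)
  if (nrow(design) < p + 1)
    stop("need at least ", p + 1, " runs to fit the ", p, "-term model")

  coded <- as.data.frame(coded_matrix(design, scheme))
  dat <- cbind(coded, .response = response)
  fit <- stats::lm(quad_formula(names(coded)), data = dat)
  if (fit$rank < p)
    stop("design is rank-deficient for the full quadratic model")

  structure(list(
    fit = fit,
    factors = factors,
    scheme = scheme,
    response_name = response_name,
    coefficients = stats::coef(fit),
    n = nrow(design),
    n_terms = p,
    residual_df = fit$df.residual,
    residual_mse = sum(stats::resid(fit)^2) / fit$df.residual,
    design = design,
    response = response
  ), class = "quad_rsm")
}

#' @export
print.quad_rsm <- function(x, ...) {
  cat(sprintf("Second-order response surface for '%s' (%s coding)\n",
              x$response_name, x$scheme))
  cat(sprintf("  %d runs, %d terms, residual df %d, residual MSE %.4g\n",
              x$n, x$n_terms, x$residual_df, x$residual_mse))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.quad_rsm <- function(object, ...) object$coefficients

new_points <- function(model, newdata) {
  nm <- vapply(model$factors, `[[`, "", "name")
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
    if (!all(nm %in% names(newdata))) names(newdata) <- nm
  }
  newdata <- as.data.frame(newdata)
  missing <- setdiff(nm, names(newdata))
  if (length(missing))
    stop("prediction points lack factor column(s): ",
         paste(missing, collapse = ", "))
  coded <- matrix(NA_real_, nrow(newdata), length(nm),
                  dimnames = list(NULL, nm))
  for (i in seq_along(model$factors))
    coded[, i] <- code_value(model$factors[[i]], newdata[[nm[i]]],
                             model$scheme)
  if (model$scheme == "affine" && any(abs(coded) > 1 + 1e-8))
    warning("some points lie outside the factor box; extrapolating")
  as.data.frame(coded)
}

#' Predict from a fitted response surface
#'
#' @param object A `quad_rsm` model.
#' @param newdata Data frame of factor settings in actual units (or a
#'   named numeric vector for a single point). If omitted, the design
#'   points used in fitting.
#' @param ... Unused.
#' @return Numeric vector of predicted response values.
#' @export
predict.quad_rsm <- function(object, newdata, ...) {
  if (missing(newdata) || is.null(newdata))
    return(as.numeric(stats::fitted(object$fit)))
  as.numeric(stats::predict(object$fit, newdata = new_points(object, newdata)))
}

pure_error <- function(model) {
  pattern <- apply(coded_matrix(model$design, model$scheme), 1,
                   paste, collapse = "/")
  y <- model$response
  ss <- 0; df <- 0L
  for (g in split(seq_along(y), pattern)) {
    if (length(g) > 1) {
      ss <- ss + sum((y[g] - mean(y[g]))^2)
      df <- df + length(g) - 1L
    }
  }
  list(ss = ss, df = df)
}

#' ANOVA for a fitted response surface
#'
#' Partial (type-III) sums of squares per model term -- for this
#' single-df-per-term model each partial SS equals `t^2 * MSE` of the
#' coefficient -- together with the model, residual, lack-of-fit,
#' pure-error and total rows. Pure error comes from replicated design
#' points (the center replicates in a standard Box-Behnken design); when
#' no replicates exist the lack-of-fit partition is omitted with a
#' warning.
#'
#' @param object A `quad_rsm` model.
#' @param alpha Significance level used for the `signif` flag.
#' @param ... Unused.
#' @return An object of class `rsm_anova`: a data frame of ANOVA rows
#'   (`source`, `ss`, `df`, `ms`, `f`, `p`, `signif`) with the adequacy
#'   summary ([adequacy()]) attached as attribute `"adequacy"` and
#'   `alpha` as attribute `"alpha"`.
#' @export
anova.quad_rsm <- function(object, alpha = 0.05, ...) {
  fit <- object$fit
  y <- object$response
  mse <- object$residual_mse
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1]

  ss_term <- sm[-1, "t value"]^2 * mse
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- object$n_terms - 1L
  df_res <- object$residual_df

  f_mod <- (ss_mod / df_mod) / mse
  rows <- data.frame(
    source = c("Model", terms, "Residual"),
    ss = c(ss_mod, ss_term, ss_res),
    df = c(df_mod, rep(1L, length(terms)), df_res),
    stringsAsFactors = FALSE)
  rows$ms <- rows$ss / rows$df
  rows$f <- c(f_mod, ss_term / mse, NA)
  rows$p <- c(stats::pf(f_mod, df_mod, df_res, lower.tail = FALSE),
              stats::pf(ss_term / mse, 1, df_res, lower.tail = FALSE), NA)

  pe <- pure_error(object)
  if (pe$df >= 1) {
    ss_lof <- ss_res - pe$ss
    df_lof <- df_res - pe$df
    f_lof <- (ss_lof / df_lof) / (pe$ss / pe$df)
    p_lof <- stats::pf(f_lof, df_lof, pe$df, lower.tail = FALSE)
    rows <- rbind(rows,
      data.frame(source = c("Lack of fit", "Pure error"),
                 ss = c(ss_lof, pe$ss), df = c(df_lof, pe$df),
                 ms = c(ss_lof / df_lof, pe$ss / pe$df),
                 f = c(f_lof, NA), p = c(p_lof, NA)))
  } else {
    warning("no replicated design points; lack-of-fit partition omitted")
  }
  rows <- rbind(rows, data.frame(source = "Total", ss = ss_tot,
                                 df = object$n - 1L, ms = NA,
                                 f = NA, p = NA))
  rows$signif <- !is.na(rows$p) & rows$p < alpha
  rownames(rows) <- NULL
  structure(rows, class = c("rsm_anova", "data.frame"),
            adequacy = adequacy(object), alpha = alpha,
            response_name = object$response_name)
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("ANOVA for response '%s' (alpha = %g)\n",
              attr(x, "response_name"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 5); df$ms <- signif(df$ms, 5)
  df$f <- signif(df$f, 4); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  ad <- attr(x, "adequacy")
  cat(sprintf("R2 %.4f | adj R2 %.4f | CV %.2f%% | adequate precision %.2f\n",
              ad$r2, ad$adj_r2, ad$cv_percent, ad$adequate_precision))
  invisible(x)
}

#' Adequacy diagnostics of a fitted response surface
#'
#' Plain and adjusted R2, the coefficient of variation
#' (`100 * sqrt(MSE) / mean(y)`, in percent) and adequate precision, the
#' signal-to-noise ratio `(max(yhat) - min(yhat)) / sqrt(p * MSE / n)`
#' over the design points, where `p` is the number of model terms.
#' Ratios above 4 indicate a surface with enough signal to navigate the
#' design space.
#'
#' @param model A `quad_rsm` model.
#' @return A list with elements `r2`, `adj_r2`, `cv_percent` and
#'   `adequate_precision` (`Inf` for a perfect fit).
#' @export
adequacy <- function(model) {
  stopifnot(inherits(model, "quad_rsm"))
  if (model$residual_df < 1) stop("no residual degrees of freedom")
  y <- model$response
  yhat <- stats::fitted(model$fit)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (model$n - 1) / model$residual_df
  mse <- model$residual_mse
  # an exact interpolation leaves only rounding error in the residuals
  perfect <- mse <= 1e-20 * max(1, mean(y^2))
  ap <- if (perfect) Inf else
    (max(yhat) - min(yhat)) / sqrt(model$n_terms * mse / model$n)
  list(r2 = r2, adj_r2 = adj,
       cv_percent = 100 * sqrt(mse) / mean(y),
       adequate_precision = ap)
}

#' Evaluate a response surface on a two-factor grid
#'
#' Predictions over the coded square `[-1, 1]^2` for two chosen factors,
#' holding the remaining factors at given actual values (default: their
#' center levels). This is the numerical backbone of the usual RSM
#' interaction contour plots.
#'
#' @param model A `quad_rsm` model.
#' @param vary Character vector of two distinct factor names.
#' @param fixed Named list or vector of actual values for the remaining
#'   factors; defaults to their center levels.
#' @param resolution Grid points per axis.
#' @return An object of class `rsm_grid`: a list with the two axes in
#'   actual units (`axis1`, `axis2`), their coded counterparts, the
#'   prediction matrix `pred` (`axis1` on rows) and the fixed settings.
#' @export
surface_grid <- function(model, vary, fixed = NULL, resolution = 50) {
  nm <- vapply(model$factors, `[[`, "", "name")
  vary <- as.character(vary)
  if (length(vary) != 2 || vary[1] == vary[2])
    stop("'vary' must name two distinct factors")
  if (!all(vary %in% nm)) stop("unknown factor in 'vary'")
  if (any(vary %in% names(fixed)))
    stop("factor(s) ", paste(intersect(vary, names(fixed)), collapse = ", "),
         " cannot be both varied and fixed")
  others <- setdiff(nm, vary)
  fix <- vapply(model$factors[match(others, nm)],
                function(f) f$levels[2], 0)
  names(fix) <- others
  if (length(fixed)) {
    unknown <- setdiff(names(fixed), others)
    if (length(unknown)) stop("unknown fixed factor(s): ",
                              paste(unknown, collapse = ", "))
    fix[names(fixed)] <- unlist(fixed)
  }
  coded_seq <- seq(-1, 1, length.out = resolution)
  fs <- model$factors[match(vary, nm)]
  ax1 <- decode_value(fs[[1]], coded_seq, model$scheme)
  ax2 <- decode_value(fs[[2]], coded_seq, model$scheme)
  pts <- expand.grid(a = ax1, b = ax2)
  newdata <- data.frame(pts$a, pts$b)
  names(newdata) <- vary
  for (o in others) newdata[[o]] <- fix[[o]]
  z <- matrix(predict(model, newdata), resolution, resolution)
  structure(list(vary = vary, axis1 = ax1, axis2 = ax2,
                 coded1 = coded_seq, coded2 = coded_seq,
                 pred = z, fixed = as.list(fix),
                 response_name = model$response_name),
            class = "rsm_grid")
}
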