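#' Define an experimental factor with three levels
#'
#' A factor in a Box-Behnken design takes exactly three levels: low,
#' center and high, given in the factor's physical units.
#'
#' @param name Short label used as a column name (e.g. `"ethanol_pct"`).
#' @param unit Unit of measurement (e.g. `"%"`, `"min"`, `"degC"`, `"kHz"`).
#' @param levels Numeric vector of three strictly increasing actual values.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("freq_kHz", "kHz", c(26, 35, 40))
#' @export
factor_spec <- function(name, unit, levels) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit))
    stop("'unit' must be a non-empty string")
  levels <- as.numeric(levels)
  if (length(levels) != 3L || anyNA(levels) || any(diff(levels) <= 0))
    stop("'levels' must be 3 distinct, strictly increasing values for factor '",
         name, "'")
  structure(list(name = name, unit = unit, levels = levels),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: low %g / center %g / high %g\n",
              x$name, x$unit, x$levels[1], x$levels[2], x$levels[3]))
  invisible(x)
}

#' Factors of the packaged seaweed extraction study
#'
#' The four process factors of the bundled multifrequency
#' ultrasonic-assisted extraction study: ethanol concentration (30/50/70
#' %), sonication time (20/35/50 min), temperature (20/40/60 degC) and
#' ultrasonic frequency (26/35/40 kHz). Note that the frequency levels
#' are unequally spaced, so its affine coding of the center level is not
#' exactly zero.
#'
#' @return A list of four [factor_spec()] objects.
#' @export
sh_factors <- function() {
  list(factor_spec("ethanol_pct", "%",    c(30, 50, 70)),
       factor_spec("time_min",    "min",  c(20, 35, 50)),
       factor_spec("temp_C",      "degC", c(20, 40, 60)),
       factor_spec("freq_kHz",    "kHz",  c(26, 35, 40)))
}

check_factors <- function(factors) {
  if (!is.list(factors) || !all(vapply(factors, inherits, TRUE, "factor_spec")))
    stop("'factors' must be a list of factor_spec objects")
  nm <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("factor names must be unique")
  nm
}

#' Convert between actual factor values and coded levels
#'
#' Two coding schemes are supported. `"affine"` maps an actual value v to
#' `(v - (low + high)/2) / ((high - low)/2)`, so low/high map to -1/+1 and
#' the center level maps to 0 only when the levels are equally spaced.
#' `"ordinal"` maps the three levels to -1/0/+1 by rank and accepts only
#' on-level values. The package default is `"affine"`, which is the
#' scheme that reproduces the predicted values printed alongside the
#' bundled study (see the methods vignette).
#'
#' @param factor A [factor_spec()].
#' @param actual Numeric vector of values in the factor's units.
#' @param coded Numeric vector of coded values.
#' @param scheme `"affine"` or `"ordinal"`.
#' @return `code_value()` returns coded values; `decode_value()` returns
#'   actual values (for `"ordinal"`, the nearest of the three levels).
#' @examples
#' f <- factor_spec("freq_kHz", "kHz", c(26, 35, 40))
#' code_value(f, 35, "ordinal")  # 0
#' code_value(f, 35, "affine")   # 2/7
#' @export
code_value <- function(factor, actual, scheme = c("affine", "ordinal")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(factor, "factor_spec"))
  lv <- factor$levels
  if (scheme == "ordinal") {
    idx <- match(actual, lv)
    if (anyNA(idx))
      stop("ordinal coding of factor '", factor$name,
           "' requires on-level values; got ",
           paste(actual[is.na(idx)], collapse = ", "))
    idx - 2
  } else {
    half <- (lv[3] - lv[1]) / 2
    if (half == 0) stop("degenerate levels for factor '", factor$name, "'")
    (actual - (lv[1] + lv[3]) / 2) / half
  }
}

#' @rdname code_value
#' @export
decode_value <- function(factor, coded, scheme = c("affine", "ordinal")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(factor, "factor_spec"))
  lv <- factor$levels
  if (scheme == "ordinal") {
    idx <- pmin(pmax(round(coded), -1), 1) + 2
    lv[idx]
  } else {
    (lv[1] + lv[3]) / 2 + coded * (lv[3] - lv[1]) / 2
  }
}

#' Build a Box-Behnken design
#'
#' Constructs the standard Box-Behnken design for `k` factors: for each
#' of the `choose(k, 2)` factor pairs, the four combinations of the two
#' factors at their extreme levels with all other factors at their
#' center, followed by `n_center` all-center replicate runs. Run order is
#' canonical (pair-major), not randomized.
#'
#' @param factors List of 3 to 5 [factor_spec()] objects.
#' @param n_center Number of center-point replicates (>= 1; >= 3 if a
#'   lack-of-fit test is intended downstream).
#' @param scheme Default coding scheme attached to the design.
#' @return A data frame of class `bbd_design` with columns `run_id`, one
#'   column per factor (actual units) and `is_center`, plus attributes
#'   `factors` and `scheme`.
#' @examples
#' d <- build_bbd(sh_factors(), n_center = 3)
#' nrow(d)  # 27
#' @export
build_bbd <- function(factors, n_center = 3, scheme = c("affine", "ordinal")) {
  scheme <- match.arg(scheme)
  nm <- check_factors(factors)
  k <- length(factors)
  if (k < 3 || k > 5)
    stop("Box-Behnken designs are supported for 3 to 5 factors, got ", k)
  n_center <- as.integer(n_center)
  if (is.na(n_center) || n_center < 1) stop("'n_center' must be >= 1")

  pairs <- utils::combn(k, 2)
  corners <- cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  coded <- matrix(0, nrow = 4 * ncol(pairs) + n_center, ncol = k,
                  dimnames = list(NULL, nm))
  row <- 1L
  for (j in seq_len(ncol(pairs))) {
    coded[row:(row + 3L), pairs[, j]] <- corners
    row <- row + 4L
  }
  actual <- coded
  for (i in seq_len(k))
    actual[, i] <- factors[[i]]$levels[coded[, i] + 2]

  out <- data.frame(run_id = seq_len(nrow(coded)), actual,
                    is_center = rowSums(coded != 0) == 0,
                    check.names = FALSE)
  attr(out, "factors") <- factors
  attr(out, "scheme") <- scheme
  class(out) <- c("bbd_design", "data.frame")
  out
}

#' Interpret a data frame of actual factor settings as a design
#'
#' Attaches factor specifications and a coding scheme to a run table read
#' from file, computing the `is_center` flag from the factor levels.
#'
#' @param df Data frame with a `run_id` column (added if absent) and one
#'   column per factor, in actual units.
#' @inheritParams build_bbd
#' @return A `bbd_design` object.
#' @export
as_bbd_design <- function(df, factors, scheme = c("affine", "ordinal")) {
  scheme <- match.arg(scheme)
  nm <- check_factors(factors)
  missing <- setdiff(nm, names(df))
  if (length(missing))
    stop("design table lacks factor columns: ", paste(missing, collapse = ", "))
  out <- data.frame(
    run_id = if ("run_id" %in% names(df)) df$run_id else seq_len(nrow(df)),
    df[nm], check.names = FALSE)
  centers <- vapply(factors, function(f) f$levels[2], 0)
  out$is_center <- rowSums(sweep(as.matrix(out[nm]), 2, centers, `!=`)) == 0
  attr(out, "factors") <- factors
  attr(out, "scheme") <- scheme
  class(out) <- c("bbd_design", "data.frame")
  out
}

design_factors <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) stop("design carries no factor specifications; ",
                       "use build_bbd() or as_bbd_design()")
  f
}

#' Coded design matrix
#'
#' @param design A `bbd_design`.
#' @param scheme Coding scheme; defaults to the scheme stored on the design.
#' @return Numeric matrix (runs x factors) of coded levels.
#' @export
coded_matrix <- function(design, scheme = NULL) {
  factors <- design_factors(design)
  if (is.null(scheme)) scheme <- attr(design, "scheme") %||% "affine"
  out <- vapply(factors,
                function(f) code_value(f, design[[f$name]], scheme),
                numeric(nrow(design)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- vapply(factors, `[[`, "", "name")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate the structure of a Box-Behnken design
#'
#' Checks every run against the Box-Behnken invariants: each actual value
#' is one of its factor's three levels; non-center runs have exactly two
#' factors at an extreme level and the rest at center; center runs are
#' all-center and flagged. Violations are reported, never raised.
#'
#' @param design A `bbd_design`.
#' @param lack_of_fit If `TRUE`, additionally warn (as a violation entry)
#'   when fewer than 3 center replicates are present, since the pure-error
#'   partition of a lack-of-fit test then rests on fewer than 2 df.
#' @return Character vector of violation messages; empty when the design
#'   is structurally valid.
#' @export
validate_design <- function(design, lack_of_fit = FALSE) {
  factors <- design_factors(design)
  nm <- vapply(factors, `[[`, "", "name")
  out <- character()
  codes <- matrix(NA_real_, nrow(design), length(factors))
  for (i in seq_along(factors)) {
    v <- design[[nm[i]]]
    idx <- match(v, factors[[i]]$levels)
    bad <- which(is.na(idx))
    for (b in bad)
      out <- c(out, sprintf("run %s: %s = %g is not a design level of %s",
                            design$run_id[b], nm[i], v[b], nm[i]))
    codes[, i] <- idx - 2
  }
  ok_rows <- !apply(is.na(codes), 1, any)
  n_extreme <- rowSums(abs(codes) == 1)
  for (r in which(ok_rows)) {
    if (isTRUE(design$is_center[r])) {
      if (n_extreme[r] != 0)
        out <- c(out, sprintf("run %s: flagged center but has %d factor(s) at an extreme level",
                              design$run_id[r], n_extreme[r]))
    } else if (n_extreme[r] != 2) {
      out <- c(out, sprintf("run %s: non-center run has %d factor(s) at an extreme level (expected 2)",
                            design$run_id[r], n_extreme[r]))
    }
  }
  if (lack_of_fit) {
    n_center <- sum(design$is_center, na.rm = TRUE)
    if (n_center < 3)
      out <- c(out, sprintf(
        "design: only %d center replicate(s); lack-of-fit pure error needs >= 3",
        n_center))
  }
  out
}
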