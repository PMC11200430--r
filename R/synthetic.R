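# Synthetic studies with known ground truth, and the packaged 27-run
# extraction study.

#' Define a ground-truth response surface for simulation
#'
#' @param beta Named numeric vector (one response) or matrix (terms x
#'   responses) of true coefficients on the coded scale, with row names
#'   matching [quad_term_names()].
#' @param noise_sd Gaussian noise standard deviation per response, in
#'   response units (recycled).
#' @param seed Integer seed used by [generate_study()].
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(beta, noise_sd, seed = 1L) {
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1,
                                         dimnames = list(names(beta), "y1"))
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    stop("'beta' must carry term names (see quad_term_names())")
  noise_sd <- rep_len(as.numeric(noise_sd), ncol(beta))
  if (anyNA(noise_sd) || any(noise_sd < 0)) stop("'noise_sd' must be >= 0")
  names(noise_sd) <- colnames(beta)
  structure(list(beta = beta, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate a Box-Behnken study from a known surface
#'
#' Builds the canonical Box-Behnken design for the given factors and
#' draws responses from the true quadratic surface (evaluated at the
#' coded design points) plus i.i.d. Gaussian noise. Reproducible from
#' `truth$seed`.
#'
#' @param factors List of [factor_spec()] objects.
#' @param truth A [ground_truth()] whose coefficient rows match the full
#'   quadratic model for these factors.
#' @param n_center Number of center replicates.
#' @param scheme Coding scheme of the generated design.
#' @return List with elements `design` (a `bbd_design`) and `responses`
#'   (data frame, one column per response).
#' @examples
#' f <- sh_factors()
#' beta <- stats::setNames(rep(0, 15), quad_term_names(f))
#' beta["(Intercept)"] <- 60; beta["ethanol_pct"] <- 5
#' sim <- generate_study(f, ground_truth(beta, noise_sd = 1, seed = 7))
#' @export
generate_study <- function(factors, truth, n_center = 3,
                           scheme = c("affine", "ordinal")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(truth, "ground_truth"))
  expected <- quad_term_names(factors)
  if (!identical(sort(rownames(truth$beta)), sort(expected)))
    stop("ground-truth terms do not match the full quadratic model ",
         "for these factors")
  beta <- truth$beta[expected, , drop = FALSE]

  design <- build_bbd(factors, n_center = n_center, scheme = scheme)
  coded <- as.data.frame(coded_matrix(design))
  X <- stats::model.matrix(quad_formula(names(coded))[-2], data = coded)
  stopifnot(identical(colnames(X), expected))
  mu <- X %*% beta
  noise <- withr::with_seed(truth$seed, {
    e <- matrix(stats::rnorm(nrow(mu) * ncol(mu)), nrow(mu))
    sweep(e, 2, truth$noise_sd, `*`)
  })
  responses <- as.data.frame(mu + noise)
  names(responses) <- colnames(beta)
  list(design = design, responses = responses)
}

#' The packaged 27-run ultrasonic extraction study
#'
#' Loads the bundled four-factor Box-Behnken study of multifrequency
#' ultrasonic-assisted extraction of the brown seaweed *Sargassum
#' horneri*: 27 runs (24 edge runs + 3 center replicates) over ethanol
#' concentration, sonication time, temperature and ultrasonic frequency,
#' with four measured responses (total phenolic content, mg GAE/g; total
#' flavonoid content, mg CAE/g; DPPH and ABTS radical scavenging, %
#' inhibition), their replicate standard deviations, and the
#' response-surface and neural-network predicted values published
#' alongside the measurements.
#'
#' @return A list:
#' \describe{
#'   \item{design}{`bbd_design` with the study's (printed) run order.}
#'   \item{responses}{Data frame `tpc`, `tfc`, `dpph`, `abts`.}
#'   \item{sd}{Replicate standard deviations, same columns.}
#'   \item{rsm_pred}{Published response-surface predictions.}
#'   \item{ann_pred}{Published neural-network predictions.}
#' }
#' @export
sh_study <- function() {
  path <- system.file("extdata", "sh_bbd_study.csv", package = "uaeopt",
                      mustWork = TRUE)
  raw <- utils::read.csv(path)
  resp <- c("tpc", "tfc", "dpph", "abts")
  need <- c("run", "ethanol_pct", "time_min", "temp_C", "freq_kHz",
            as.vector(t(outer(resp, c("", "_sd", "_rsm", "_ann"),
                              paste0))))
  if (nrow(raw) != 27 || !identical(names(raw), need) ||
      anyNA(raw) || !all(vapply(raw, is.numeric, TRUE)))
    stop("packaged study fixture is corrupted")
  design <- as_bbd_design(
    data.frame(run_id = raw$run, raw[2:5], check.names = FALSE),
    sh_factors(), scheme = "affine")
  viol <- validate_design(design, lack_of_fit = TRUE)
  if (length(viol)) stop("packaged study fixture is corrupted: ", viol[1])
  pick <- function(suffix) stats::setNames(raw[paste0(resp, suffix)], resp)
  list(design = design,
       responses = pick(""),
       sd = pick("_sd"),
       rsm_pred = pick("_rsm"),
       ann_pred = pick("_ann"))
}

#' Ground truth mimicking the packaged study
#'
#' A simulation preset in a realistic regime: the true coefficients are
#' the full quadratic fits of the packaged study's four responses, and
#' the default noise levels are those fits' residual standard deviations.
#'
#' @param noise_sd Optional override of the per-response noise SD.
#' @param seed Seed stored in the returned truth.
#' @return A [ground_truth()] with a 15 x 4 coefficient matrix.
#' @export
sh_truth <- function(noise_sd = NULL, seed = 1L) {
  study <- sh_study()
  fits <- lapply(stats::setNames(nm = names(study$responses)), function(r)
    fit_quadratic(study$design, study$responses[[r]], response_name = r))
  beta <- vapply(fits, stats::coef, numeric(15))
  if (is.null(noise_sd))
    noise_sd <- vapply(fits, function(f) sqrt(f$residual_mse), 0)
  ground_truth(beta, noise_sd, seed = seed)
}
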