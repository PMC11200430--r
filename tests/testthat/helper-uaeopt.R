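# Shared fixtures: load the packaged study once per test run.
study <- sh_study()

study_fits <- lapply(names(study$responses), function(r)
  fit_quadratic(study$design, study$responses[[r]], response_name = r))
names(study_fits) <- names(study$responses)

# Predictor over coded points backed by the four response-surface fits.
rsm_predict_fn <- function(fits = study_fits, factors = sh_factors()) {
  nm <- vapply(factors, `[[`, "", "name")
  function(P) {
    A <- P
    for (i in seq_along(factors))
      A[, i] <- decode_value(factors[[i]], P[, i], "affine")
    A <- as.data.frame(A)
    names(A) <- nm
    vapply(fits, function(m) as.numeric(predict(m, A)), numeric(nrow(P)))
  }
}

# A full-quadratic coefficient vector with the given non-zero entries.
quad_beta <- function(factors, ...) {
  beta <- stats::setNames(rep(0, length(quad_term_names(factors))),
                          quad_term_names(factors))
  set <- list(...)
  beta[names(set)] <- unlist(set)
  beta
}
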