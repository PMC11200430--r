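# End-to-end orchestration: fit all responses, select a neural
# surrogate, optimize, compare, and write a report bundle.

#' Configure an end-to-end optimization run
#'
#' @param data List with elements `design` (a `bbd_design`) and
#'   `responses` (data frame); defaults to the packaged study
#'   ([sh_study()]).
#' @param scheme Coding scheme for the response-surface fits.
#' @param alpha ANOVA significance level.
#' @param ann List of neural-surrogate options: `h_range` (candidate
#'   hidden sizes), `algorithm`, `n_restarts`.
#' @param ga List overriding [ga_config()] arguments (e.g. `pop`,
#'   `generations`, `weights`).
#' @param surrogate Which surrogate the optimizer should use: `"ann"`
#'   (default) or `"rsm"`.
#' @param snap Factor names reported at the nearest design level after
#'   optimization; defaults to the frequency factor when present, since
#'   only its three discrete settings are physically available.
#' @param out_dir Output directory for the report bundle; `NULL` to skip
#'   writing files.
#' @param seed Master seed; the split, training and GA seeds derive
#'   from it.
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(data = NULL, scheme = "affine", alpha = 0.05,
                            ann = list(), ga = list(),
                            surrogate = c("ann", "rsm"),
                            snap = NULL, out_dir = NULL, seed = 1L) {
  surrogate <- match.arg(surrogate)
  if (!scheme %in% c("affine", "ordinal"))
    stop("unknown coding scheme '", scheme, "'")
  ann_opts <- utils::modifyList(
    list(h_range = 1:20, algorithm = "lm", n_restarts = 1L), ann)
  structure(list(data = data, scheme = scheme, alpha = alpha,
                 ann = ann_opts, ga = ga, surrogate = surrogate,
                 snap = snap, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full optimization workflow
#'
#' Fits the full quadratic response surface to every response (with
#' ANOVA and adequacy diagnostics), sweeps the hidden-layer size of the
#' neural surrogate, optimizes the scalarized responses with the genetic
#' algorithm over the chosen surrogate, and compares the two surrogates'
#' prediction ability. When `config$out_dir` is set, writes a report
#' bundle (coefficients, ANOVA tables, adequacy summary, sweep table,
#' serialized surrogate, optimization result, comparison grid and a text
#' summary); every file records the package version and master seed.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with `fits`, `anova`, `adequacy`, `sweep`,
#'   `ann`, `ga`, `comparison` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  data <- stage("data", {
    d <- config$data %||% sh_study()
    if (is.null(d$design) || is.null(d$responses))
      stop("'data' must have elements 'design' and 'responses'")
    d
  })
  design <- data$design
  responses <- as.data.frame(data$responses)
  factors <- design_factors(design)

  fits <- stage("rsm", lapply(stats::setNames(nm = names(responses)),
    function(r) fit_quadratic(design, responses[[r]],
                              scheme = config$scheme, response_name = r)))
  reports <- stage("anova", lapply(fits, stats::anova,
                                   alpha = config$alpha))
  adeq <- stage("adequacy", do.call(rbind, lapply(names(fits), function(r) {
    a <- adequacy(fits[[r]])
    data.frame(response = r, r2 = a$r2, adj_r2 = a$adj_r2,
               cv_percent = a$cv_percent,
               adequate_precision = a$adequate_precision)
  })))

  sweep_res <- stage("ann", do.call(sweep_hidden_neurons, c(
    list(design = design, responses = responses, seed = config$seed),
    config$ann[intersect(names(config$ann),
                         c("h_range", "algorithm", "n_restarts"))])))
  ann_model <- sweep_res$model

  ga_res <- stage("optimize", {
    cfg <- do.call(ga_config, utils::modifyList(
      list(seed = config$seed, weights = rep(1, ncol(responses))),
      config$ga))
    predict_fn <- if (config$surrogate == "ann")
      function(P) predict_ann(ann_model, P)
    else
      function(P) {
        colnames(P) <- vapply(factors, `[[`, "", "name")
        vapply(fits, function(f)
          as.numeric(stats::predict(f$fit, as.data.frame(P))),
          numeric(nrow(P)))
      }
    snap <- config$snap %||%
      intersect("freq_kHz", vapply(factors, `[[`, "", "name"))
    ga_optimize(predict_fn, cfg, ranges = response_ranges(responses),
                factors = factors, scheme = config$scheme,
                init_points = coded_matrix(design, config$scheme),
                snap = snap)
  })

  comparison <- stage("compare", compare_models(
    responses,
    as.data.frame(lapply(fits, function(f) predict(f))),
    as.data.frame(predict_ann(ann_model, design))))

  out <- list(fits = fits, anova = reports, adequacy = adeq,
              sweep = sweep_res, ann = ann_model, ga = ga_res,
              comparison = comparison, config = config)
  if (!is.null(config$out_dir))
    stage("report", write_bundle(out, config$out_dir))
  invisible(out)
}

config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config),
                                      c("data", "out_dir"))]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

write_bundle <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- out$config
  provenance <- sprintf(
    "# uaeopt %s | seed %d | config %s",
    as.character(utils::packageVersion("uaeopt")),
    config$seed, config_hash(config))
  put <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(provenance, path)
    suppressWarnings(utils::write.table(
      df, path, append = TRUE, sep = ",", row.names = FALSE,
      qmethod = "double"))
    path
  }
  coefs <- do.call(rbind, lapply(names(out$fits), function(r)
    data.frame(response = r, term = names(stats::coef(out$fits[[r]])),
               estimate = unname(stats::coef(out$fits[[r]])))))
  put(coefs, "coefficients.csv")
  for (r in names(out$anova))
    put(as.data.frame(out$anova[[r]]), sprintf("anova_%s.csv", r))
  put(out$adequacy, "adequacy.csv")
  put(out$sweep$table, "ann_sweep.csv")
  ann_save(out$ann, file.path(dir, "ann_model.json"))
  put(data.frame(metric = c(names(out$ga$best_actual), "fitness"),
                 value = c(unname(out$ga$best_actual), out$ga$fitness)),
      "ga_optimum.csv")
  put(out$comparison$metrics, "comparison.csv")

  s <- c(provenance, "",
         "Response-surface adequacy:",
         sprintf("  %-6s R2 %.4f (adj %.4f), CV %.2f%%, adequate precision %.2f",
                 out$adequacy$response, out$adequacy$r2, out$adequacy$adj_r2,
                 out$adequacy$cv_percent, out$adequacy$adequate_precision),
         "",
         sprintf("Neural surrogate: %d-%d-%d selected from sweep (val MSE %.4g)",
                 out$ann$k, out$ann$n_hidden, out$ann$m, out$ann$val_mse),
         "",
         sprintf("GA optimum (surrogate: %s): fitness %.4f",
                 config$surrogate, out$ga$fitness),
         sprintf("  %s = %.4g", names(out$ga$best_actual),
                 out$ga$best_actual),
         sprintf("  predicted: %s",
                 paste(sprintf("%s %.2f", names(out$fits),
                               out$ga$predicted), collapse = ", ")),
         "",
         "Better surrogate by R2:",
         sprintf("  %-6s %s", out$comparison$verdicts$response,
                 out$comparison$verdicts$r2))
  writeLines(s, file.path(dir, "summary.txt"))
  invisible(dir)
}
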