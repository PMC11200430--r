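# Spectrophotometric assay calibrations for the packaged study.

#' Calibration lines of the antioxidant assays
#'
#' The linear calibration curves (absorbance = slope x concentration +
#' intercept) used to quantify the four responses of the packaged
#' extraction study: total phenolic content against gallic acid, total
#' flavonoid content against catechin, and the DPPH and ABTS
#' radical-scavenging assays against ascorbic acid.
#'
#' @return Data frame with columns `assay`, `slope`, `intercept`,
#'   `r2` (reported calibration fit) and `unit`.
#' @export
calibration_lines <- function() {
  data.frame(
    assay = c("tpc", "tfc", "dpph", "abts"),
    slope = c(0.0526, 0.0336, 0.0555, 0.0369),
    intercept = c(0.0020, 0.0021, 0.0123, 0.0133),
    r2 = c(0.9856, 0.9894, 0.9879, 0.9823),
    unit = c("mg GAE/g", "mg CAE/g", "% inhibition", "% inhibition"),
    stringsAsFactors = FALSE)
}

resolve_line <- function(line) {
  if (is.character(line)) {
    tab <- calibration_lines()
    i <- match(line, tab$assay)
    if (is.na(i)) stop("unknown assay '", line, "'; available: ",
                       paste(tab$assay, collapse = ", "))
    line <- tab[i, ]
  }
  if (is.null(line$slope) || is.null(line$intercept))
    stop("calibration line needs 'slope' and 'intercept'")
  if (line$slope == 0) stop("calibration slope must be non-zero")
  line
}

#' Convert absorbance readings to concentrations
#'
#' Inverts a calibration line: `x = (absorbance - intercept) / slope`.
#' Negative concentrations (readings below the blank) are returned as-is
#' but flagged with a warning.
#'
#' @param line An assay name (`"tpc"`, `"tfc"`, `"dpph"`, `"abts"`), a
#'   row of [calibration_lines()], or any list with `slope` and
#'   `intercept`.
#' @param absorbance Numeric vector of absorbance readings.
#' @return Numeric vector of concentrations in the line's output unit.
#' @examples
#' concentration_from_absorbance("tpc", 0.5280)  # 10 mg GAE/g equivalent
#' @export
concentration_from_absorbance <- function(line, absorbance) {
  line <- resolve_line(line)
  x <- (as.numeric(absorbance) - line$intercept) / line$slope
  if (any(x < 0))
    warning(sum(x < 0), " reading(s) below the calibration intercept ",
            "give negative concentrations")
  x
}

#' Percent inhibition of a radical-scavenging assay
#'
#' `100 * (control - sample) / control`. Values outside `[0, 100]`
#' (sample absorbance above the control, or negative readings) are
#' clipped to the reporting range with a warning.
#'
#' @param control_absorbance Absorbance of the radical-only control
#'   (must be positive).
#' @param sample_absorbance Absorbance in the presence of the sample.
#' @return Percent inhibition in `[0, 100]`.
#' @export
percent_inhibition <- function(control_absorbance, sample_absorbance) {
  if (any(control_absorbance <= 0))
    stop("'control_absorbance' must be positive")
  p <- 100 * (control_absorbance - sample_absorbance) / control_absorbance
  out_of_range <- p < 0 | p > 100
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " value(s) outside [0, 100] clipped to the reporting range")
    p <- pmin(pmax(p, 0), 100)
  }
  p
}
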