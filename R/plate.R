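#' Percent reduction of PrestoBlue viability reagent
#'
#' Two modes are provided. `as_printed` is the published two-wavelength
#' equation using only the test-well absorbances:
#' `100 * (117216*A1 - 80586*A2) / (155677*A1 - 14652*A2)`,
#' where A1 is the 570 nm and A2 the 600 nm absorbance of the test well and
#' the constants are the vendor's molar extinction coefficients of the
#' oxidized/reduced reagent. `vendor_control` places the media-only blank
#' absorbances N1/N2 in the denominator instead (the vendor's full
#' formulation; replicate media-only wells should be averaged first, see
#' [presto_blue_plate()]).
#'
#' @param A1,A2 test-well absorbance at 570 / 600 nm (vectorized).
#' @param N1,N2 media-only absorbances at 570 / 600 nm (required in
#'   `vendor_control` mode).
#' @param mode `"as_printed"` (default) or `"vendor_control"`.
#' @return percent reduction per well.
#' @export
presto_blue_reduction <- function(A1, A2, N1 = NULL, N2 = NULL,
                                  mode = c("as_printed", "vendor_control")) {
  mode <- match.arg(mode)
  if (any(!is.finite(A1)) || any(!is.finite(A2)) || any(A1 <= 0) || any(A2 <= 0)) {
    stop_param("absorbances must be positive and finite")
  }
  num <- 117216 * A1 - 80586 * A2
  den <- if (mode == "as_printed") {
    155677 * A1 - 14652 * A2
  } else {
    if (is.null(N1) || is.null(N2)) {
      stop_param("vendor_control mode requires media-only absorbances N1 and N2")
    }
    155677 * mean(N1) - 14652 * mean(N2)
  }
  if (any(den == 0)) stop_param("zero denominator in mode '", mode, "'")
  100 * num / den
}

#' Apply the PrestoBlue reduction formula to a plate table
#'
#' Media-only replicate wells are averaged before use in `vendor_control`
#' mode.
#'
#' @param plate a `plate_table` from [read_plate()] (columns `well`, `role`,
#'   `A570`, `A600`).
#' @param mode see [presto_blue_reduction()].
#' @return data.frame with `well` and `percent_reduction` for test wells;
#'   attribute `mode`.
#' @export
presto_blue_plate <- function(plate, mode = c("as_printed", "vendor_control")) {
  mode <- match.arg(mode)
  test <- plate[plate$role == "test", , drop = FALSE]
  media <- plate[plate$role == "media_only", , drop = FALSE]
  if (mode == "vendor_control" && nrow(media) == 0) {
    stop_param("vendor_control mode requires at least one media_only well")
  }
  pr <- presto_blue_reduction(test$A570, test$A600,
                              N1 = media$A570, N2 = media$A600, mode = mode)
  out <- data.frame(well = test$well, percent_reduction = pr)
  attr(out, "mode") <- mode
  out
}

#' Clonogenic plating efficiency
#'
#' `PE = colonies / seeded * 100` (percent).
#'
#' @param colonies colonies formed in the untreated condition.
#' @param seeded cells seeded (> 0).
#' @return plating efficiency, percent.
#' @export
plating_efficiency <- function(colonies, seeded) {
  if (any(seeded <= 0)) stop_param("'seeded' must be positive")
  if (any(colonies < 0)) stop_param("colony counts must be non-negative")
  100 * colonies / seeded
}

#' Clonogenic survival fraction
#'
#' `SF = colonies_treated / (seeded * PE/100) * 100` (percent): colony count
#' after treatment normalized by the number of clonogenic cells plated. PE
#' enters as a fraction; with the untreated colony count this identity gives
#' SF = 100% by construction.
#'
#' @param colonies_treated colonies formed after treatment.
#' @param seeded cells seeded (> 0).
#' @param PE plating efficiency in percent (> 0), from
#'   [plating_efficiency()].
#' @return survival fraction, percent.
#' @export
survival_fraction <- function(colonies_treated, seeded, PE) {
  if (any(seeded <= 0)) stop_param("'seeded' must be positive")
  if (any(PE <= 0)) stop_param("plating efficiency must be positive")
  if (any(colonies_treated < 0)) stop_param("colony counts must be non-negative")
  100 * colonies_treated / (seeded * PE / 100)
}

#' Express measurements relative to a control group
#'
#' `100 * mean(values) / mean(control_values)`, e.g. LDH release as a
#' percentage of control cells.
#'
#' @param values measurements of the condition of interest.
#' @param control_values measurements of the control condition (positive
#'   mean).
#' @return percent of control.
#' @export
relative_percent <- function(values, control_values) {
  if (length(values) == 0 || length(control_values) == 0) {
    stop_param("empty input")
  }
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop_param("control mean must be positive")
  100 * mean(values) / m
}

#' Percent of positive cells
#'
#' @param positive number of positive cells (0 <= positive <= total).
#' @param total total cells (> 0).
#' @return percent positive, in [0, 100].
#' @export
percent_positive <- function(positive, total) {
  if (any(total <= 0)) stop_param("'total' must be positive")
  if (any(positive < 0) || any(positive > total)) {
    stop_param("'positive' must be between 0 and 'total'")
  }
  100 * positive / total
}
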