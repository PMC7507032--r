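# Exactly specified bench-assay quantification formulas, as pure functions.

#' Immunohistochemistry final score
#'
#' Product of the positive-cell percentage score and the average staining
#' intensity class (0 absent, 1 weak, 2 moderate, 3 strong).
#'
#' @param percentage_score Non-negative integer percentage score.
#' @param intensity Staining intensity class in `{0, 1, 2, 3}`.
#' @return `percentage_score * intensity`.
#' @examples
#' ihc_final_score(4, 3) # 12
#' @export
ihc_final_score <- function(percentage_score, intensity) {
  if (!all(intensity %in% c(0, 1, 2, 3)))
    fail("`intensity` must be 0, 1, 2 or 3")
  if (any(percentage_score < 0) || any(percentage_score != round(percentage_score)))
    fail("`percentage_score` must be a non-negative integer")
  percentage_score * intensity
}

#' Xenograft tumour volume (ellipsoid approximation)
#'
#' `0.52 * width^2 * length` in cubic millimetres; the squared term is the
#' short-axis (width) measurement of the standard ellipsoid approximation.
#'
#' @param width_mm,length_mm Calliper measurements in millimetres, >= 0.
#' @return Volume in cubic millimetres.
#' @examples
#' tumor_volume(10, 20) # 1040
#' @export
tumor_volume <- function(width_mm, length_mm) {
  if (any(width_mm < 0) || any(length_mm < 0))
    fail("measurements must be non-negative")
  0.52 * width_mm^2 * length_mm
}

#' qPCR relative expression by the ddCt method
#'
#' `2^-ddCt` with `ddCt = (ct_target_case - ct_ref_case) -
#' (ct_target_ctrl - ct_ref_ctrl)`, normalising the target gene to a
#' reference gene (e.g. GAPDH/ACTB) and to the control condition.
#'
#' @param ct_target_case,ct_ref_case Ct values in the case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control sample.
#' @return Fold change of the case relative to the control.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (anyNA(cts) || any(!is.finite(cts))) fail("all Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' ChIP-qPCR percent of input
#'
#' Expresses immunoprecipitated DNA relative to the whole pre-IP chromatin.
#' When the input Ct was measured on a fraction `input_fraction` of the
#' chromatin (the usual case), it is first adjusted to the whole-sample
#' equivalent (`ct_input + log2(input_fraction)`, i.e. fewer cycles); then
#' `percent = 100 * 2^(ct_input_adjusted - ct_ip)`. Each additional IP cycle
#' halves the result.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the input sample.
#' @param input_fraction Fraction of chromatin used as input, in `(0, 1]`.
#' @param input_adjusted Set `TRUE` if `ct_input` is already expressed on
#'   the whole-sample scale.
#' @return Percent of input.
#' @export
chip_percent_input <- function(ct_ip, ct_input, input_fraction = 0.01,
                               input_adjusted = FALSE) {
  if (anyNA(c(ct_ip, ct_input)) || any(!is.finite(c(ct_ip, ct_input))))
    fail("Ct values must be finite")
  assert_scalar_number(input_fraction, "input_fraction", min = 0, max = 1,
                       strict_min = TRUE)
  adj <- if (input_adjusted) ct_input else ct_input + log2(input_fraction)
  100 * 2^(adj - ct_ip)
}

#' Dual-luciferase normalised fold activity
#'
#' Firefly activity normalised to the Renilla internal control, relative to
#' the same ratio in the control condition:
#' `(firefly / renilla) / (firefly_ctrl / renilla_ctrl)`.
#'
#' @param firefly,renilla Readings in the test condition.
#' @param firefly_ctrl,renilla_ctrl Readings in the control condition.
#' @return Normalised fold activity.
#' @export
dual_luciferase_ratio <- function(firefly, renilla, firefly_ctrl,
                                  renilla_ctrl) {
  if (any(c(renilla, renilla_ctrl) <= 0))
    fail("Renilla readings must be positive")
  (firefly / renilla) / (firefly_ctrl / renilla_ctrl)
}
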