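#' Unit conversions for glucose and HbA1c
#'
#' Plasma glucose converts between mg/dl and mmol/l with the molar-mass
#' factor 18.016 g/mol; HbA1c converts between the DCCT percentage scale
#' and the IFCC mmol/mol scale via the master equation
#' \code{mmol/mol = 10.929 * (pct - 2.15)}.
#'
#' @param v Numeric vector of non-negative values on the source scale.
#' @return Numeric vector on the target scale.
#' @examples
#' glucose_mgdl_to_mmoll(200) # 11.1 mmol/l at 1 d.p.
#' hba1c_pct_to_mmolmol(6.5)  # 47.5, reported clinically as 48 mmol/mol
#' @name unit_conversions
NULL

.GLUCOSE_MGDL_PER_MMOLL <- 18.016
.HBA1C_IFCC_SLOPE <- 10.929
.HBA1C_IFCC_INTERCEPT <- 2.15

.check_nonneg <- function(v, what) {
  if (any(!is.na(v) & v < 0)) {
    stop(sprintf("negative %s value not allowed", what), call. = FALSE)
  }
  invisible(v)
}

#' @rdname unit_conversions
#' @export
glucose_mgdl_to_mmoll <- function(v) {
  .check_nonneg(v, "glucose")
  v / .GLUCOSE_MGDL_PER_MMOLL
}

#' @rdname unit_conversions
#' @export
glucose_mmoll_to_mgdl <- function(v) {
  .check_nonneg(v, "glucose")
  v * .GLUCOSE_MGDL_PER_MMOLL
}

#' @rdname unit_conversions
#' @export
hba1c_pct_to_mmolmol <- function(v) {
  .check_nonneg(v, "HbA1c")
  .HBA1C_IFCC_SLOPE * (v - .HBA1C_IFCC_INTERCEPT)
}

#' @rdname unit_conversions
#' @export
hba1c_mmolmol_to_pct <- function(v) {
  v / .HBA1C_IFCC_SLOPE + .HBA1C_IFCC_INTERCEPT
}
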