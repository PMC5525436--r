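# Lipid phenotype preparation: unit conversion, Friedewald LDL
# derivation with the triglyceride validity cutoff, and the
# log-triglyceride transform.

# Standard clinical conversion divisors (mg/dL -> mmol/L).
.CHOL_DIVISOR <- 38.67
.TG_DIVISOR <- 88.57

# Friedewald TG validity cutoff: derived LDL is unreliable above this.
.TG_CUTOFF_MMOL <- 4.51
.TG_CUTOFF_MGDL <- 400

#' Convert a lipid concentration to mmol/L
#'
#' Cholesterol-type analytes (TC, HDL, LDL) divide by 38.67; triglycerides
#' divide by 88.57. Values already in mmol/L pass through unchanged.
#'
#' @param value nonnegative concentration(s); `NA` propagates.
#' @param analyte `"cholesterol"` or `"triglyceride"`.
#' @param from_unit `"mg/dL"` or `"mmol/L"`.
#' @return value(s) in mmol/L.
#' @export
#' @examples
#' convert_units(400, "triglyceride", "mg/dL")  # 4.516..., above cutoff
convert_units <- function(value, analyte = c("cholesterol", "triglyceride"),
                          from_unit = c("mg/dL", "mmol/L")) {
  analyte <- match.arg(analyte)
  from_unit <- match.arg(from_unit)
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be nonnegative")
  }
  if (from_unit == "mmol/L") return(value)
  divisor <- if (analyte == "cholesterol") .CHOL_DIVISOR else .TG_DIVISOR
  value / divisor
}

#' Friedewald LDL derivation
#'
#' `LDL = TC - HDL - k * TG` with `k = 0.45` in mmol/L or `k = 0.20` in
#' mg/dL. The formula is invalid at high triglycerides: whenever TG
#' exceeds 4.51 mmol/L (400 mg/dL), or any input is missing, the derived
#' LDL is returned as `NA`. Vectorized.
#'
#' @param tc,hdl,tg total cholesterol, HDL and triglycerides, all in
#'   `unit`.
#' @param unit `"mmol/L"` (default) or `"mg/dL"`.
#' @return derived LDL values with `NA` where the formula does not apply.
#' @export
#' @examples
#' friedewald_ldl(5.0, 1.3, 2.0)            # 2.80
#' friedewald_ldl(5.0, 1.3, 4.6)            # NA: TG above cutoff
#' friedewald_ldl(200, 50, 100, "mg/dL")    # 130
friedewald_ldl <- function(tc, hdl, tg, unit = c("mmol/L", "mg/dL")) {
  unit <- match.arg(unit)
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE)) {
    stop("lipid concentrations must be nonnegative")
  }
  k <- if (unit == "mmol/L") 0.45 else 0.20
  cutoff <- if (unit == "mmol/L") .TG_CUTOFF_MMOL else .TG_CUTOFF_MGDL
  ldl <- tc - hdl - k * tg
  ldl[is.na(tc) | is.na(hdl) | is.na(tg) | tg > cutoff] <- NA_real_
  ldl
}

#' Natural-log transform of triglycerides
#'
#' Returns `log(tg)`; missing propagates. Nonpositive values are
#' unusable measurements and come back as `NA` with a warning.
#'
#' @param tg triglyceride values (mmol/L).
#' @return log-TG values.
#' @export
log_transform_tg <- function(tg) {
  bad <- !is.na(tg) & tg <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive TG value(s) set to NA before log")
    tg[bad] <- NA_real_
  }
  log(tg)
}

#' Prepare a lipid panel for analysis
#'
#' Applies the full phenotype preparation to a raw lipid table: converts
#' to mmol/L if needed, derives LDL by Friedewald's formula when no
#' measured LDL column is supplied (the TG cutoff rule applies only to
#' derived LDL), and adds `log_tg`.
#'
#' @param panel data.frame with `sample_id`, `tc`, `hdl`, `tg` and
#'   optionally `ldl`.
#' @param unit unit of the input columns.
#' @param derive_ldl force Friedewald derivation even when an `ldl`
#'   column is present.
#' @return the panel in mmol/L with `ldl` and `log_tg` columns and an
#'   `ldl_derived` attribute.
#' @export
prep_lipid_panel <- function(panel, unit = c("mmol/L", "mg/dL"),
                             derive_ldl = !("ldl" %in% names(panel))) {
  unit <- match.arg(unit)
  stopifnot(all(c("sample_id", "tc", "hdl", "tg") %in% names(panel)))
  out <- panel
  if (unit == "mg/dL") {
    out$tc <- convert_units(out$tc, "cholesterol", "mg/dL")
    out$hdl <- convert_units(out$hdl, "cholesterol", "mg/dL")
    if ("ldl" %in% names(out)) {
      out$ldl <- convert_units(out$ldl, "cholesterol", "mg/dL")
    }
    out$tg <- convert_units(out$tg, "triglyceride", "mg/dL")
  }
  if (derive_ldl) {
    out$ldl <- friedewald_ldl(out$tc, out$hdl, out$tg, "mmol/L")
  }
  out$log_tg <- log_transform_tg(out$tg)
  attr(out, "ldl_derived") <- derive_ldl
  out
}
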