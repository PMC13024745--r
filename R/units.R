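#' Convert between assay and model concentration/mass units
#'
#' Supported pairs: `"ug/mL"` <-> `"mM"` (requires `molar_mass` in g/mol;
#' ug/mL equals mg/L, so mM = (ug/mL) / M) and `"mg"` <-> `"ug"`. Round-trip
#' conversion is an identity to machine precision.
#'
#' @param value Non-negative numeric vector.
#' @param from,to Unit strings.
#' @param molar_mass Molar mass (g/mol), required for ug/mL <-> mM.
#' @return Converted values.
#' @examples
#' convert_units(11.77, "ug/mL", "mM", molar_mass = 356.41)
#' @export
convert_units <- function(value, from, to, molar_mass = NULL) {
  if (!is.numeric(value) || anyNA(value)) gs_stop("`value` must be numeric")
  if (any(value < 0)) gs_stop("`value` must be non-negative")
  key <- paste(from, to, sep = "->")
  needs_mw <- key %in% c("ug/mL->mM", "mM->ug/mL")
  if (needs_mw) {
    if (is.null(molar_mass)) gs_stop("molar_mass is required for %s", key)
    gs_check_scalar(molar_mass, "molar_mass", min = 0, strict = TRUE)
  }
  switch(key,
    "ug/mL->mM" = value / molar_mass,
    "mM->ug/mL" = value * molar_mass,
    "mg->ug"    = value * 1000,
    "ug->mg"    = value / 1000,
    gs_stop("unsupported unit conversion: %s", key)
  )
}

#' Molar-mass registry for the fixture compounds
#'
#' Configuration constants (g/mol) used to bridge ug/mL assay readouts and the
#' mM model scale; standard reference values, never inferred from data.
#'
#' @return Named numeric vector of molar masses.
#' @examples
#' molar_masses()["sulindac"]
#' @export
molar_masses <- function() {
  c(sulindac = 356.41, meglumine = 195.21)
}
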