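#' Describe a dissolution protocol
#'
#' @param vessel_volume Medium volume V (mL).
#' @param aliquot_volume Volume v withdrawn (and replaced with fresh medium)
#'   at each sampling time (mL); must be < `vessel_volume`.
#' @param dose Drug dose in the vessel (mg).
#' @param temperature,stir_rpm,medium Annotations.
#' @return An object of class `dissolution_protocol`.
#' @examples
#' paddle_sink_protocol()
#' @export
dissolution_protocol <- function(vessel_volume, aliquot_volume, dose,
                                 temperature = 37, stir_rpm = 100,
                                 medium = "deionized water") {
  gs_check_scalar(vessel_volume, "vessel_volume", min = 0, strict = TRUE)
  gs_check_scalar(aliquot_volume, "aliquot_volume", min = 0)
  gs_check_scalar(dose, "dose", min = 0, strict = TRUE)
  if (aliquot_volume >= vessel_volume) {
    gs_stop("aliquot_volume (%g mL) must be smaller than vessel_volume (%g mL)",
            aliquot_volume, vessel_volume)
  }
  structure(list(vessel_volume = vessel_volume, aliquot_volume = aliquot_volume,
                 dose = dose, temperature = temperature, stir_rpm = stir_rpm,
                 medium = medium),
            class = "dissolution_protocol")
}

#' @rdname dissolution_protocol
#' @details `paddle_sink_protocol()` is the sink-condition paddle setup
#'   (900 mL medium, 2 mL aliquots, 2.1 mg dose, 100 rpm, 37 C);
#'   `nonsink_protocol()` is the supersaturation setup (200 mL, 2 mL aliquots,
#'   80 mg dose).
#' @export
paddle_sink_protocol <- function() {
  dissolution_protocol(vessel_volume = 900, aliquot_volume = 2, dose = 2.1)
}

#' @rdname dissolution_protocol
#' @export
nonsink_protocol <- function() {
  dissolution_protocol(vessel_volume = 200, aliquot_volume = 2, dose = 80)
}

#' Read a dissolution protocol from a JSON descriptor
#'
#' Expects keys `vessel_ml`, `aliquot_ml`, `dose_mg` and optionally `temp_c`,
#' `rpm`, `medium`.
#'
#' @param file JSON path.
#' @return A [dissolution_protocol()].
#' @export
read_protocol <- function(file) {
  if (!file.exists(file)) gs_stop("protocol file not found: %s", file)
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (k in c("vessel_ml", "aliquot_ml", "dose_mg")) {
    if (is.null(cfg[[k]])) gs_stop("protocol JSON missing key `%s`", k,
                                   class = "gelsolv_schema_error")
  }
  dissolution_protocol(cfg$vessel_ml, cfg$aliquot_ml, cfg$dose_mg,
                       temperature = cfg$temp_c %||% 37,
                       stir_rpm = cfg$rpm %||% 100,
                       medium = cfg$medium %||% "deionized water")
}

#' Construct a sampled concentration time-series
#'
#' @param times Sampling times (min), strictly increasing, first >= 0.
#' @param concentrations Measured concentrations (ug/mL), >= 0.
#' @param label Series label.
#' @return A data frame of class `concentration_series` with columns
#'   `time` and `conc`.
#' @export
concentration_series <- function(times, concentrations, label = "series") {
  if (length(times) != length(concentrations)) {
    gs_stop("times and concentrations must have equal length")
  }
  if (length(times) < 2L) gs_stop("at least 2 timepoints are required")
  if (anyNA(times) || anyNA(concentrations)) gs_stop("series must not contain NA")
  if (times[1] < 0 || any(diff(times) <= 0)) {
    gs_stop("times must be strictly increasing and start at >= 0")
  }
  if (any(concentrations < 0)) gs_stop("concentrations must be non-negative")
  structure(data.frame(time = as.numeric(times), conc = as.numeric(concentrations)),
            class = c("concentration_series", "data.frame"), label = label)
}

#' Read concentration time-series from a long-format CSV
#'
#' Expects columns `time_min,conc_ug_per_ml,label`; returns one
#' [concentration_series()] per label.
#'
#' @param file CSV path.
#' @return Named list of `concentration_series`.
#' @export
read_concentration_series <- function(file) {
  if (!file.exists(file)) gs_stop("series file not found: %s", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("time_min", "conc_ug_per_ml", "label")
  if (!all(need %in% names(df))) {
    gs_stop("series CSV must have columns `%s`", paste(need, collapse = ","),
            class = "gelsolv_schema_error")
  }
  out <- lapply(split(df, df$label), function(d) {
    d <- d[order(d$time_min), ]
    concentration_series(d$time_min, d$conc_ug_per_ml, label = d$label[1])
  })
  out
}

#' Sampling-corrected cumulative release profile
#'
#' Converts sampled medium concentrations into cumulative released drug under
#' a withdraw-and-replace protocol. Each withdrawn aliquot removes drug from
#' the vessel, so the cumulative amount at sample n accounts for all prior
#' withdrawals:
#' \deqn{A_n = C_n V + v \sum_{i<n} C_i}
#' with C in ug/mL, volumes in mL and A in mg. This is the unique
#' mass-consistent accounting for sample-and-replace sampling: at every index,
#' `A_n` equals mass currently in the vessel plus total mass removed in prior
#' aliquots.
#'
#' @param protocol A [dissolution_protocol()].
#' @param series A [concentration_series()] of sampled concentrations
#'   (values as measured in the vessel immediately before each withdrawal).
#' @return A data frame of class `release_profile` with columns `time`,
#'   `cumulative_amount` (mg) and `cumulative_percent` (% of dose). Percentages
#'   above 100 (possible only through measurement noise) raise a warning and
#'   are flagged in the attribute `exceeds_dose`.
#' @examples
#' pr <- cumulative_release(paddle_sink_protocol(),
#'                          concentration_series(c(20, 120), c(1, 2)))
#' @export
cumulative_release <- function(protocol, series) {
  if (!inherits(protocol, "dissolution_protocol")) gs_stop("`protocol` must be a dissolution_protocol")
  if (!inherits(series, "concentration_series")) {
    series <- concentration_series(series$time, series$conc)
  }
  V <- protocol$vessel_volume
  v <- protocol$aliquot_volume
  C <- series$conc
  prior <- c(0, cumsum(C)[-length(C)])
  amount_mg <- (C * V + v * prior) / 1000
  percent <- 100 * amount_mg / protocol$dose
  exceeds <- percent > 100
  if (any(exceeds)) {
    warning("cumulative release exceeds 100% of dose at ",
            sum(exceeds), " timepoint(s); attributable to measurement noise",
            call. = FALSE)
  }
  structure(data.frame(time = series$time, cumulative_amount = amount_mg,
                       cumulative_percent = percent),
            class = c("release_profile", "data.frame"),
            label = attr(series, "label"), exceeds_dose = exceeds)
}

# Internal: exact-match lookup of requested times in a time vector
gs_match_times <- function(at_times, times, what) {
  idx <- vapply(at_times, function(t) {
    j <- which(abs(times - t) <= 1e-9 * max(1, abs(t)))
    if (length(j) == 0L) NA_integer_ else j[1]
  }, integer(1))
  if (anyNA(idx)) {
    gs_stop("timepoint(s) not sampled in %s: %s (no interpolation is performed)",
            what, paste(at_times[is.na(idx)], collapse = ", "),
            class = "gelsolv_missing_timepoint")
  }
  idx
}

#' Apparent-solubility / concentration enhancement ratio
#'
#' Fold enhancement of a sample concentration over a reference, rounded
#' half-up to `decimals` places (the presentation convention for printed
#' fold values).
#'
#' @param value_sample,value_reference Concentrations in the same units;
#'   `value_reference` must be positive.
#' @param decimals Decimal places for half-up rounding (default 2).
#' @return The rounded fold enhancement.
#' @examples
#' enhancement_ratio(3640.24, 11.77)  # 309.28
#' @export
enhancement_ratio <- function(value_sample, value_reference, decimals = 2L) {
  gs_check_scalar(value_sample, "value_sample", min = 0)
  gs_check_scalar(value_reference, "value_reference", min = 0, strict = TRUE)
  gs_check_scalar(decimals, "decimals", min = 0)
  round_half_up(value_sample / value_reference, decimals)
}

# Half-up decimal rounding (base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Supersaturation metrics of a release concentration series
#'
#' For each requested time (exact-match policy, no interpolation), reports the
#' sample concentration and its fold enhancement over the reference series,
#' plus the sample series' maximum concentration C_max, its time, and the
#' trapezoidal area under the concentration-time curve.
#'
#' @param series,reference_series [concentration_series()] objects; the
#'   requested times must be sampled in both.
#' @param at_times Times (min) at which folds are reported.
#' @param decimals Rounding for the fold values (see [enhancement_ratio()]).
#' @return A list with `at` (data frame: `time`, `conc`, `conc_reference`,
#'   `fold`), `c_max` (ug/mL), `t_max` (min) and `auc` (ug min/mL).
#' @export
supersaturation_metrics <- function(series, reference_series, at_times,
                                    decimals = 2L) {
  if (!inherits(series, "concentration_series") ||
      !inherits(reference_series, "concentration_series")) {
    gs_stop("both series must be concentration_series objects")
  }
  i <- gs_match_times(at_times, series$time, "the sample series")
  j <- gs_match_times(at_times, reference_series$time, "the reference series")
  folds <- mapply(function(a, b) enhancement_ratio(a, b, decimals),
                  series$conc[i], reference_series$conc[j])
  imax <- which.max(series$conc)
  list(
    at = data.frame(time = as.numeric(at_times), conc = series$conc[i],
                    conc_reference = reference_series$conc[j], fold = folds),
    c_max = series$conc[imax],
    t_max = series$time[imax],
    auc = trapz_auc(series$time, series$conc)
  )
}

# Trapezoidal area under the curve
trapz_auc <- function(t, y) {
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Percent released at requested times
#'
#' Exact-match lookup of cumulative release percentages in a
#' [cumulative_release()] profile.
#'
#' @param profile A `release_profile`.
#' @param at_times Times (min); must be sampled.
#' @return Named numeric vector of cumulative percents.
#' @export
profile_summary <- function(profile, at_times) {
  if (!inherits(profile, "release_profile")) gs_stop("`profile` must be a release_profile")
  idx <- gs_match_times(at_times, profile$time, "the release profile")
  stats::setNames(profile$cumulative_percent[idx], paste0("t", at_times))
}
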