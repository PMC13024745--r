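#' Construct a phase-solubility dataset
#'
#' Holds measured equilibrium drug solubility as a function of total ligand
#' concentration, together with the drug's intrinsic solubility S0 (its
#' equilibrium solubility in ligand-free medium). All concentrations in mM;
#' use [convert_units()] to bridge ug/mL assay readouts.
#'
#' @param ligand_total Total ligand concentrations (mM), strictly increasing.
#' @param drug_total Measured total drug solubility at each ligand level (mM).
#' @param intrinsic_solubility S0, the ligand-free drug solubility (mM).
#' @param temperature Optional annotation, degrees C.
#' @return An object of class `phase_solubility_dataset`.
#' @export
phase_solubility_dataset <- function(ligand_total, drug_total,
                                     intrinsic_solubility,
                                     temperature = NA_real_) {
  if (length(ligand_total) != length(drug_total)) {
    gs_stop("ligand_total and drug_total must have equal length")
  }
  if (length(ligand_total) < 3L) gs_stop("at least 3 data points are required")
  if (anyNA(ligand_total) || anyNA(drug_total)) gs_stop("concentrations must not be NA")
  if (any(ligand_total < 0) || any(drug_total < 0)) {
    gs_stop("concentrations must be non-negative")
  }
  if (any(diff(ligand_total) <= 0)) gs_stop("ligand_total must be strictly increasing")
  gs_check_scalar(intrinsic_solubility, "intrinsic_solubility", min = 0, strict = TRUE)
  structure(
    list(ligand_total = as.numeric(ligand_total),
         drug_total = as.numeric(drug_total),
         intrinsic_solubility = intrinsic_solubility,
         temperature = temperature),
    class = "phase_solubility_dataset"
  )
}

#' @export
print.phase_solubility_dataset <- function(x, ...) {
  cat(sprintf("Phase-solubility dataset: %d points, ligand %.4g-%.4g mM, S0 = %.4g mM\n",
              length(x$ligand_total), min(x$ligand_total), max(x$ligand_total),
              x$intrinsic_solubility))
  invisible(x)
}

#' Read a phase-solubility dataset from CSV
#'
#' Expects columns `ligand_mM` and `drug_solubility`. Drug solubilities in
#' ug/mL are converted to mM via `molar_mass`.
#'
#' @param file CSV path.
#' @param intrinsic_solubility S0 in the same units as `drug_solubility`.
#' @param units Units of `drug_solubility` and `intrinsic_solubility`:
#'   `"mM"` or `"ug/mL"`.
#' @param molar_mass Drug molar mass (g/mol), required for ug/mL input.
#' @inheritParams phase_solubility_dataset
#' @return A `phase_solubility_dataset`.
#' @export
read_phase_solubility <- function(file, intrinsic_solubility, units = c("mM", "ug/mL"),
                                  molar_mass = NULL, temperature = NA_real_) {
  units <- match.arg(units)
  if (!file.exists(file)) gs_stop("file not found: %s", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("ligand_mM", "drug_solubility") %in% names(df))) {
    gs_stop("phase-solubility CSV must have columns `ligand_mM,drug_solubility`",
            class = "gelsolv_schema_error")
  }
  drug <- df$drug_solubility
  s0 <- intrinsic_solubility
  if (units == "ug/mL") {
    if (is.null(molar_mass)) gs_stop("molar_mass is required for ug/mL input")
    drug <- convert_units(drug, "ug/mL", "mM", molar_mass)
    s0 <- convert_units(s0, "ug/mL", "mM", molar_mass)
  }
  phase_solubility_dataset(df$ligand_mM, drug, s0, temperature)
}

#' Predicted total drug solubility under the 1:1 complexation model
#'
#' For a 1:1 drug-ligand complex with stability constant K (mM^-1) and
#' intrinsic drug solubility S0 (mM), solving the equilibrium and mass
#' balances with the solid drug phase present gives the linear
#' Higuchi-Connors relation
#' \deqn{S_T = S_0 + \frac{K S_0}{1 + K S_0} L_T}
#' whose intercept is S0 and whose slope lies strictly in (0, 1) for
#' K, S0 > 0.
#'
#' @param K11 Stability constant of the 1:1 complex (mM^-1).
#' @param S0 Intrinsic drug solubility (mM).
#' @param ligand_total Total ligand concentration(s), mM.
#' @return Total drug solubility (mM), vectorized over `ligand_total`.
#' @examples
#' predict_total_solubility(2, 0.05, 1)  # 0.1409091
#' @export
predict_total_solubility <- function(K11, S0, ligand_total) {
  gs_check_scalar(K11, "K11", min = 0)
  gs_check_scalar(S0, "S0", min = 0, strict = TRUE)
  if (!is.numeric(ligand_total) || anyNA(ligand_total) || any(ligand_total < 0)) {
    gs_stop("ligand_total must be non-negative")
  }
  S0 + (K11 * S0 / (1 + K11 * S0)) * ligand_total
}

#' Equilibrium speciation of a 1:1 drug-ligand system
#'
#' Solves the mass-action equilibrium `K11 * [D][L] = [DL]` subject to the
#' mass balances `D_T = [D] + [DL]` and `L_T = [L] + [DL]`. The complex
#' concentration is the physically admissible root (in
#' `[0, min(D_T, L_T)]`) of the quadratic
#' `K11 (D_T - C)(L_T - C) = C`, computed in a numerically stable form.
#'
#' @param K11 Stability constant (mM^-1).
#' @param drug_total,ligand_total Total concentrations (mM); vectors are
#'   recycled to common length.
#' @return A data frame of class `speciation` with columns `free_drug`,
#'   `free_ligand`, `complex_conc` (mM).
#' @examples
#' solve_speciation(1, 1, 1)  # complex (3 - sqrt(5))/2
#' @export
solve_speciation <- function(K11, drug_total, ligand_total) {
  gs_check_scalar(K11, "K11", min = 0)
  if (!is.numeric(drug_total) || !is.numeric(ligand_total) ||
      anyNA(drug_total) || anyNA(ligand_total) ||
      any(drug_total < 0) || any(ligand_total < 0)) {
    gs_stop("drug_total and ligand_total must be non-negative")
  }
  n <- max(length(drug_total), length(ligand_total))
  d <- rep_len(as.numeric(drug_total), n)
  l <- rep_len(as.numeric(ligand_total), n)
  if (K11 == 0) {
    C <- rep(0, n)
  } else {
    # K C^2 - (K (D+L) + 1) C + K D L = 0; b < 0, take the smaller root via
    # the stable c/q form to avoid cancellation at large K.
    b <- -(K11 * (d + l) + 1)
    cc <- K11 * d * l
    disc <- pmax(b^2 - 4 * K11 * cc, 0)
    q <- -(b - sqrt(disc)) / 2
    C <- ifelse(q > 0, cc / q, 0)
    C <- pmin(C, pmin(d, l))
  }
  out <- data.frame(free_drug = d - C, free_ligand = l - C, complex_conc = C)
  class(out) <- c("speciation", "data.frame")
  out
}

#' Estimate the 1:1 stability constant from a phase-solubility diagram
#'
#' Ordinary least squares of total drug solubility on total ligand
#' concentration within the linear diagram region, inverted through the
#' Higuchi-Connors slope relation:
#' \deqn{K_{1:1} = \frac{slope}{S_0 (1 - slope)}}
#' By default S0 is the measured intrinsic solubility stored in the dataset
#' (the model fixes the intercept there); set `s0_from_intercept = TRUE` to
#' use the regression intercept instead.
#'
#' @param data A [phase_solubility_dataset()].
#' @param linear_range Optional `c(low, high)` in mM of `ligand_total`
#'   delimiting the linear region. Default: from [detect_breakpoint()] when
#'   the dataset has >= 5 points, otherwise the full range.
#' @param s0_from_intercept Use the fitted intercept as S0 (default FALSE).
#' @return An object of class `complexation_fit`: list with `K11` (mM^-1),
#'   `slope`, `intercept` (mM), `linear_range`, `r_squared`, `diagram_class`,
#'   `n_points`.
#' @examples
#' sim <- simulate_phase_solubility(K11 = 1.5, S0 = 0.04, noise_cv = 0)
#' fit_K11(sim$data)
#' @export
fit_K11 <- function(data, linear_range = NULL, s0_from_intercept = FALSE) {
  if (!inherits(data, "phase_solubility_dataset")) {
    gs_stop("`data` must be a phase_solubility_dataset")
  }
  diagram_class <- NA_character_
  if (is.null(linear_range)) {
    if (length(data$ligand_total) >= 5L) {
      bp <- detect_breakpoint(data)
      linear_range <- c(min(data$ligand_total), bp$breakpoint)
      diagram_class <- bp$diagram_class
    } else {
      linear_range <- range(data$ligand_total)
    }
  }
  if (length(linear_range) != 2L || linear_range[1] > linear_range[2]) {
    gs_stop("linear_range must be c(low, high)")
  }
  keep <- data$ligand_total >= linear_range[1] & data$ligand_total <= linear_range[2]
  if (sum(keep) < 3L) gs_stop("fewer than 3 points inside the linear range")
  x <- data$ligand_total[keep]
  y <- data$drug_total[keep]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 1e-12 * max(abs(y)) / max(abs(x))) {
    gs_stop("no solubilization trend (slope <= 0)")
  }
  if (slope >= 1) gs_stop("slope inconsistent with 1:1 model (slope >= 1)")
  S0 <- if (s0_from_intercept) intercept else data$intrinsic_solubility
  if (S0 <= 0) gs_stop("S0 must be positive to invert the slope relation")
  out <- list(
    K11 = slope / (S0 * (1 - slope)),
    slope = slope,
    intercept = intercept,
    S0 = S0,
    linear_range = as.numeric(linear_range),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    diagram_class = diagram_class,
    n_points = sum(keep)
  )
  class(out) <- "complexation_fit"
  out
}

#' @export
print.complexation_fit <- function(x, ...) {
  cat(sprintf("1:1 complexation fit (%d points, ligand %.4g-%.4g mM)\n",
              x$n_points, x$linear_range[1], x$linear_range[2]))
  cat(sprintf("  slope = %.4f, intercept = %.4g mM, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  K1:1 = %.4g mM^-1 (S0 = %.4g mM)", x$K11, x$S0))
  if (!is.na(x$diagram_class)) cat(sprintf("  [%s diagram]", x$diagram_class))
  cat("\n")
  invisible(x)
}

#' Detect the onset of negative (A_N) deviation in a phase-solubility diagram
#'
#' Grid search over the observed ligand concentrations: for each candidate
#' breakpoint, a straight line is fitted to the points at or below the
#' candidate and extrapolated upward, and the diagram is classified A_N at the
#' smallest candidate for which every point above it falls below the
#' extrapolated line significantly (a one-sided criterion on the residuals).
#'
#' Because concentration assays have multiplicative (constant-CV) error, the
#' below-fit is weighted least squares with weights proportional to
#' 1/fitted^2, and the residual scale is the relative (CV-like) residual SD.
#' Each above-point's standardized residual is compared to the one-sided
#' t-quantile `-qt(1 - alpha, df)` at the below-fit's residual degrees of
#' freedom; the standardization uses the full out-of-sample prediction SE
#' (new-observation variance plus extrapolation variance of the fitted line),
#' so short below-fits with unreliable scale estimates and large leverage do
#' not trigger spurious detections. If no candidate qualifies the diagram is
#' linear (A_L) and the breakpoint is the largest observed ligand
#' concentration.
#'
#' A decreasing concentration tail above the detected breakpoint (B-type-like
#' behaviour, out of scope) is still classified A_N but raises a warning.
#'
#' @param data A [phase_solubility_dataset()] with >= 5 points.
#' @param alpha One-sided per-point significance level of the deviation test
#'   (default 0.01).
#' @return A list with `breakpoint` (mM, always one of the observed ligand
#'   values) and `diagram_class` (`"A_L"` or `"A_N"`).
#' @export
detect_breakpoint <- function(data, alpha = 0.01) {
  if (!inherits(data, "phase_solubility_dataset")) {
    gs_stop("`data` must be a phase_solubility_dataset")
  }
  L <- data$ligand_total
  S <- data$drug_total
  n <- length(L)
  if (n < 5L) gs_stop("breakpoint detection requires at least 5 points",
                      class = "gelsolv_insufficient_data")
  for (i in 3:(n - 1)) {
    below <- seq_len(i)
    above <- (i + 1):n
    # OLS pilot for the weights, then WLS under the constant-CV error model
    pilot <- stats::lm(S[below] ~ L[below])
    f <- pmax(stats::fitted(pilot), 1e-12 * max(S))
    w <- 1 / f^2
    sw <- sum(w); swx <- sum(w * L[below]); swxx <- sum(w * L[below]^2)
    swy <- sum(w * S[below]); swxy <- sum(w * L[below] * S[below])
    dd <- sw * swxx - swx^2
    slope <- (sw * swxy - swx * swy) / dd
    inter <- (swy - slope * swx) / sw
    resid <- S[below] - (inter + slope * L[below])
    sigma_rel <- max(sqrt(sum(w * resid^2) / (i - 2)), 1e-10)
    pred <- inter + slope * L[above]
    lever <- (swxx - 2 * L[above] * swx + L[above]^2 * sw) / dd
    se_pred <- sigma_rel * sqrt(pmax(pred, 0)^2 + lever)
    r <- (S[above] - pred) / se_pred
    if (all(r < -stats::qt(1 - alpha, df = i - 2))) {
      if (length(above) >= 2L) {
        tail_slope <- stats::coef(stats::lm(S[above] ~ L[above]))[2]
        if (is.finite(tail_slope) && tail_slope < 0) {
          warning("decreasing solubility tail above the breakpoint: ",
                  "B-type behaviour is out of scope; classified A_N",
                  call. = FALSE)
        }
      }
      return(list(breakpoint = L[i], diagram_class = "A_N"))
    }
  }
  list(breakpoint = max(L), diagram_class = "A_L")
}

#' Total solubility with free-ligand aggregation (A_N deviation model)
#'
#' Models the negative deviation of A_N-type diagrams as self-aggregation of
#' the free ligand at high concentration, which lowers the ligand
#' concentration effectively available for complexation. The effective ligand
#' saturates as
#' \deqn{L_{eff} = L_0 + \frac{L_T - L_0}{1 + \beta (L_T - L_0)}, \quad L_T > L_0}
#' (and \eqn{L_{eff} = L_T} below the onset \eqn{L_0}), and is substituted
#' into the linear Higuchi-Connors relation. With `onset = 0` this is the
#' saturation form `L_T / (1 + beta L_T)`; with `beta = 0` it reduces exactly
#' to [predict_total_solubility()].
#'
#' @inheritParams predict_total_solubility
#' @param beta Aggregation parameter (mM^-1), >= 0.
#' @param onset Ligand concentration (mM) above which aggregation sets in
#'   (default 0: aggregation acts at all concentrations).
#' @return Total drug solubility (mM).
#' @export
predict_with_aggregation <- function(K11, S0, beta, ligand_total, onset = 0) {
  gs_check_scalar(beta, "beta", min = 0)
  gs_check_scalar(onset, "onset", min = 0)
  if (!is.numeric(ligand_total) || anyNA(ligand_total) || any(ligand_total < 0)) {
    gs_stop("ligand_total must be non-negative")
  }
  excess <- pmax(ligand_total - onset, 0)
  l_eff <- pmin(ligand_total, onset) + excess / (1 + beta * excess)
  predict_total_solubility(K11, S0, l_eff)
}
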