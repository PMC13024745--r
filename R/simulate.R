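#' Simulate a phase-solubility dataset with known ground truth
#'
#' Generates a diagram on a ligand grid from the 1:1 Higuchi-Connors model,
#' optionally with negative (A_N) deviation from free-ligand aggregation above
#' an onset concentration, plus multiplicative Gaussian measurement noise
#' (relative errors truncated at -0.99 so concentrations stay positive).
#'
#' The default grid is ten geometric doublings 25/2^9 ... 25 mM
#' (0.0488-25 mM), whose lower eight points (up to 6.25 mM) form the linear
#' region and whose upper points carry the deviation when `beta > 0`.
#'
#' @param K11 True stability constant (mM^-1).
#' @param S0 True intrinsic solubility (mM).
#' @param ligand_grid Strictly increasing ligand concentrations (mM).
#' @param noise_cv Multiplicative noise coefficient of variation (0 = exact).
#' @param beta Aggregation parameter (mM^-1); 0 gives a pure A_L diagram.
#' @param onset Aggregation onset (mM), used when `beta > 0`.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A list with `data` (a [phase_solubility_dataset()]) and `truth`
#'   (list: `K11`, `S0`, `beta`, `onset`, `noiseless` mean values).
#' @examples
#' sim <- simulate_phase_solubility(seed = 1)
#' fit_K11(sim$data)$K11
#' @export
simulate_phase_solubility <- function(K11 = 1.5, S0 = 0.04,
                                      ligand_grid = 25 / 2^(9:0),
                                      noise_cv = 0.05, beta = 0, onset = 6.25,
                                      seed = NULL) {
  gs_check_scalar(noise_cv, "noise_cv", min = 0)
  if (any(diff(ligand_grid) <= 0)) gs_stop("ligand_grid must be strictly increasing")
  mean_s <- predict_with_aggregation(K11, S0, beta, ligand_grid, onset = onset)
  obs <- mean_s
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    eps <- pmax(stats::rnorm(length(mean_s), 0, noise_cv), -0.99)
    obs <- mean_s * (1 + eps)
  }
  list(
    data = phase_solubility_dataset(ligand_grid, obs, intrinsic_solubility = S0),
    truth = list(K11 = K11, S0 = S0, beta = beta, onset = onset,
                 noiseless = mean_s)
  )
}

#' Simulate a sample-and-replace dissolution run with known ground truth
#'
#' Between samples the vessel concentration follows a first-order approach to
#' a plateau, `C(t) = C_prev + (C_inf - C_prev) (1 - exp(-k dt))` (a kinetic
#' stand-in that exercises the accounting, not a mechanistic release model).
#' At each sampling time the pre-withdrawal concentration is recorded (with
#' multiplicative noise if `noise_cv > 0`) and the withdrawal of an aliquot
#' with fresh-medium replacement dilutes the vessel by `(V - v)/V`. Newly
#' dissolved mass is tracked so the true cumulative released amount and
#' percent are emitted alongside; noise affects recorded values only.
#'
#' @param protocol A [dissolution_protocol()].
#' @param C_inf Plateau concentration the vessel relaxes toward (ug/mL);
#'   default 90% of dose dissolved (`0.9 * dose / V * 1000`).
#' @param k First-order rate constant (min^-1).
#' @param sample_times Sampling times (min), strictly increasing.
#' @param noise_cv Multiplicative noise CV on recorded concentrations.
#' @param C0 Initial concentration (ug/mL).
#' @param seed Integer seed.
#' @return A list with `series` (the noisy recorded [concentration_series()])
#'   and `truth` (list: `series` noiseless, `cumulative_amount` mg,
#'   `cumulative_percent`).
#' @examples
#' sim <- simulate_dissolution(noise_cv = 0)
#' cumulative_release(paddle_sink_protocol(), sim$series)
#' @export
simulate_dissolution <- function(protocol = paddle_sink_protocol(),
                                 C_inf = NULL, k = 0.02,
                                 sample_times = c(5, 10, 20, 30, 45, 60, 90, 120),
                                 noise_cv = 0.05, C0 = 0, seed = NULL) {
  if (!inherits(protocol, "dissolution_protocol")) gs_stop("`protocol` must be a dissolution_protocol")
  gs_check_scalar(k, "k", min = 0)
  gs_check_scalar(noise_cv, "noise_cv", min = 0)
  gs_check_scalar(C0, "C0", min = 0)
  if (length(sample_times) < 2L || any(diff(sample_times) <= 0) || sample_times[1] <= 0) {
    gs_stop("sample_times must be strictly increasing and positive")
  }
  V <- protocol$vessel_volume
  v <- protocol$aliquot_volume
  if (is.null(C_inf)) C_inf <- 0.9 * protocol$dose / V * 1000
  gs_check_scalar(C_inf, "C_inf", min = 0)

  if (noise_cv > 0 && !is.null(seed)) set.seed(seed)
  n <- length(sample_times)
  recorded <- dissolved_ug <- numeric(n)
  C <- C0
  t_prev <- 0
  total_dissolved <- C0 * V
  for (i in seq_len(n)) {
    dt <- sample_times[i] - t_prev
    C_new <- C + (C_inf - C) * (1 - exp(-k * dt))
    total_dissolved <- total_dissolved + (C_new - C) * V
    recorded[i] <- C_new
    dissolved_ug[i] <- total_dissolved
    C <- C_new * (V - v) / V  # withdraw aliquot, replace with fresh medium
    t_prev <- sample_times[i]
  }
  obs <- recorded
  if (noise_cv > 0) {
    eps <- pmax(stats::rnorm(n, 0, noise_cv), -0.99)
    obs <- recorded * (1 + eps)
  }
  list(
    series = concentration_series(sample_times, obs, label = "simulated"),
    truth = list(
      series = concentration_series(sample_times, recorded, label = "noiseless"),
      cumulative_amount = dissolved_ug / 1000,
      cumulative_percent = 100 * dissolved_ug / 1000 / protocol$dose
    )
  )
}
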