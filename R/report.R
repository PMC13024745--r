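#' Published reference values for the sulindac-meglumine worked example
#'
#' Reported study quantities used as inputs and cross-check expectations by
#' [reproduce_report()]: total Hansen parameters of the two components, the
#' apparent solubilities (ug/mL) of crystalline drug, physical mixture and
#' hydrogel, and the non-sink release concentrations (ug/mL) at 720 min.
#'
#' @return Named list of reference constants.
#' @export
published_values <- function() {
  list(
    delta_sul = 23.74, delta_meg = 25.89, delta_diff = 2.15,
    solubility_crystalline = 11.77, solubility_pm = 3640.24,
    solubility_hydrogel = 6432.13,
    fold_pm = 309.28, fold_hydrogel = 546.48,
    conc720_hydrogel = 276.17, conc720_crystalline = 18.28,
    conc720_pm = 255.57,
    fold720_vs_crystalline = 15.11, fold720_vs_pm = 1.08
  )
}

#' One-command reproduction report
#'
#' Recomputes the package's worked-example quantities from the shipped
#' fixtures and reference inputs, compares each to its published expectation,
#' and reports pass/fail per check. Stochastic validation (stability-constant
#' recovery, breakpoint recovery, release round-trip) is run from `seed`.
#'
#' @param seed Integer seed for the stochastic checks.
#' @param n_rep Number of replicate simulations for the stochastic checks.
#' @return A data frame of class `gelsolv_report` with one row per check
#'   (`id`, `description`, `computed`, `expected`, `tolerance`, `pass`), plus
#'   attributes `seed` and `overall_pass`.
#' @export
reproduce_report <- function(seed = 1L, n_rep = 200L) {
  pv <- published_values()
  tab <- load_group_table()
  sul <- compute_hansen(read_composition(
    system.file("extdata", "sulindac_groups.csv", package = "gelsolv")), tab)
  meg <- compute_hansen(read_composition(
    system.file("extdata", "meglumine_groups.csv", package = "gelsolv")), tab)
  scr <- miscibility_screen(pv$delta_sul, pv$delta_meg)

  fold_pm <- enhancement_ratio(pv$solubility_pm, pv$solubility_crystalline)
  fold_gel <- enhancement_ratio(pv$solubility_hydrogel, pv$solubility_crystalline)
  fold720_cr <- enhancement_ratio(pv$conc720_hydrogel, pv$conc720_crystalline)
  fold720_pm <- enhancement_ratio(pv$conc720_hydrogel, pv$conc720_pm)

  rec <- k11_recovery_study(seed = seed, n_rep = n_rep)
  bp <- breakpoint_recovery_study(seed = seed + 1L, n_rep = n_rep)

  sim <- simulate_dissolution(noise_cv = 0)
  prof <- cumulative_release(paddle_sink_protocol(), sim$truth$series)
  rt_err <- max(abs(prof$cumulative_percent - sim$truth$cumulative_percent) /
                  pmax(sim$truth$cumulative_percent, .Machine$double.eps))

  rows <- list(
    list("miscibility_delta_diff", "|delta_SUL - delta_MEG| from published totals",
         scr$delta_diff, pv$delta_diff, 0.005),
    list("hansen_delta_sulindac", "group-contribution delta total, sulindac fixture",
         sul$delta_total, pv$delta_sul, 0.05 * pv$delta_sul),
    list("hansen_delta_meglumine", "group-contribution delta total, meglumine fixture",
         meg$delta_total, pv$delta_meg, 0.05 * pv$delta_meg),
    list("enhancement_fold_pm", "apparent-solubility fold, physical mixture",
         fold_pm, pv$fold_pm, 0.005),
    list("enhancement_fold_hydrogel", "apparent-solubility fold, hydrogel",
         fold_gel, pv$fold_hydrogel, 0.005),
    list("supersaturation_fold_vs_crystalline", "720-min fold vs crystalline drug",
         fold720_cr, pv$fold720_vs_crystalline, 0.005),
    list("supersaturation_fold_vs_pm", "720-min fold vs physical mixture",
         fold720_pm, pv$fold720_vs_pm, 0.005),
    list("k11_recovery_median_relerr", "median |rel. error| of K1:1, 5% noise",
         rec$median_rel_err, 0, 0.10),
    list("an_breakpoint_hit_rate", "A_N breakpoint within one grid step, fraction",
         bp$hit_rate, 1, 0.05),
    list("release_roundtrip_max_relerr", "noiseless release accounting round-trip",
         rt_err, 0, 1e-9)
  )
  rep <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], description = r[[2]], computed = r[[3]],
               expected = r[[4]], tolerance = r[[5]],
               pass = abs(r[[3]] - r[[4]]) <= r[[5]])
  }))
  class(rep) <- c("gelsolv_report", "data.frame")
  attr(rep, "seed") <- seed
  attr(rep, "overall_pass") <- all(rep$pass)
  rep
}

#' @export
print.gelsolv_report <- function(x, ...) {
  cat(sprintf("gelsolv reproduction report (seed %d)\n", attr(x, "seed")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-38s computed %10.4f  expected %10.4f (tol %.3g)\n",
                if (x$pass[i]) "PASS" else "FAIL",
                x$id[i], x$computed[i], x$expected[i], x$tolerance[i]))
  }
  cat("overall:", if (attr(x, "overall_pass")) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Stability-constant recovery study on synthetic diagrams
#'
#' Repeatedly simulates 8-point linear diagrams (the 0.0488-6.25 mM doubling
#' grid) with multiplicative noise, refits K1:1 and summarizes the relative
#' estimation error.
#'
#' @param K11,S0 Generating parameters.
#' @param noise_cv Noise level (default 5%).
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @return List with `median_rel_err`, `rel_err` vector and `n_rep`.
#' @export
k11_recovery_study <- function(K11 = 1.5, S0 = 0.04, noise_cv = 0.05,
                               n_rep = 200L, seed = 1L) {
  grid <- 25 / 2^(9:2)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_rep)
  rel_err <- vapply(seeds, function(s) {
    sim <- simulate_phase_solubility(K11 = K11, S0 = S0, ligand_grid = grid,
                                     noise_cv = noise_cv, beta = 0, seed = s)
    fit <- fit_K11(sim$data, linear_range = range(grid))
    abs(fit$K11 - K11) / K11
  }, numeric(1))
  list(median_rel_err = stats::median(rel_err), rel_err = rel_err, n_rep = n_rep)
}

#' A_N breakpoint recovery study on synthetic diagrams
#'
#' Repeatedly simulates A_N diagrams on the full 0.0488-25 mM doubling grid
#' with aggregation beyond `onset`, runs [detect_breakpoint()] and scores a
#' hit when the diagram is classified A_N with the detected breakpoint within
#' one grid step of the true onset.
#'
#' @param beta Aggregation parameter (mM^-1).
#' @param onset True deviation onset (mM); must be a grid point.
#' @inheritParams k11_recovery_study
#' @return List with `hit_rate`, logical `hits` and `n_rep`.
#' @export
breakpoint_recovery_study <- function(beta = 0.2, onset = 6.25, K11 = 1.5,
                                      S0 = 0.04, noise_cv = 0.05,
                                      n_rep = 200L, seed = 1L) {
  grid <- 25 / 2^(9:0)
  k <- which(abs(grid - onset) < 1e-9)
  if (length(k) != 1L) gs_stop("onset must be one of the grid points")
  ok <- grid[max(k - 1, 1):min(k + 1, length(grid))]
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_rep)
  hits <- vapply(seeds, function(s) {
    sim <- simulate_phase_solubility(K11 = K11, S0 = S0, ligand_grid = grid,
                                     noise_cv = noise_cv, beta = beta,
                                     onset = onset, seed = s)
    bp <- suppressWarnings(detect_breakpoint(sim$data))
    bp$diagram_class == "A_N" && any(abs(bp$breakpoint - ok) < 1e-9)
  }, logical(1))
  list(hit_rate = mean(hits), hits = hits, n_rep = n_rep)
}
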