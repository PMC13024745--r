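test_that("predict_total_solubility matches the closed form", {
  # no complexation: intrinsic solubility at any ligand level
  expect_equal(predict_total_solubility(0, 0.033, 10), 0.033)
  # hand evaluation: S0 + (K S0 / (1 + K S0)) L
  expect_equal(predict_total_solubility(2, 0.05, 1), 0.05 + (0.1 / 1.1) * 1.0)
  # intercept is S0 exactly; linear and strictly increasing in L
  expect_equal(predict_total_solubility(1.7, 0.2, 0), 0.2)
  L <- seq(0, 10, by = 0.5)
  S <- predict_total_solubility(1.7, 0.2, L)
  expect_true(all(diff(S) > 0))
  expect_equal(max(abs(diff(S, differences = 2))), 0, tolerance = 1e-12)
})

test_that("Higuchi-Connors slope stays in (0,1) and solubility is monotone in K, S0, L", {
  set.seed(11)
  for (rep in 1:30) {
    K <- stats::runif(1, 0.01, 50)
    S0 <- stats::runif(1, 1e-4, 2)
    slope <- K * S0 / (1 + K * S0)
    expect_gt(slope, 0); expect_lt(slope, 1)
    L <- stats::runif(1, 0, 30)
    base <- predict_total_solubility(K, S0, L)
    expect_gte(predict_total_solubility(K * 1.3, S0, L), base)
    expect_gte(predict_total_solubility(K, S0 * 1.3, L), base)
    expect_gte(predict_total_solubility(K, S0, L * 1.3), base)
  }
})

test_that("solve_speciation solves the quadratic with exact mass balances", {
  # hand-solved case: K=1, D=L=1 gives C = (3 - sqrt(5))/2
  sp <- solve_speciation(1, 1, 1)
  expect_equal(sp$complex_conc, (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_lt(abs(1 * sp$free_drug * sp$free_ligand - sp$complex_conc), 1e-12)

  # no binding
  sp0 <- solve_speciation(0, 2, 3)
  expect_equal(sp0$complex_conc, 0)
  expect_equal(sp0$free_drug, 2)
  expect_equal(sp0$free_ligand, 3)

  # stoichiometric limit at very large K
  spL <- solve_speciation(1e9, 1, 2)
  expect_equal(spL$complex_conc, 1, tolerance = 1e-6)
  expect_equal(spL$free_drug, 0, tolerance = 1e-6)
})

test_that("speciation invariants hold across random instances", {
  set.seed(12)
  for (rep in 1:50) {
    K <- stats::runif(1, 0, 100)
    D <- stats::runif(1, 0, 10)
    L <- stats::runif(1, 0, 10)
    sp <- solve_speciation(K, D, L)
    expect_true(all(unlist(sp) >= 0))
    scale <- max(D, L, .Machine$double.eps)
    expect_lt(abs(sp$free_drug + sp$complex_conc - D) / scale, 1e-9)
    expect_lt(abs(sp$free_ligand + sp$complex_conc - L) / scale, 1e-9)
    expect_lt(abs(K * sp$free_drug * sp$free_ligand - sp$complex_conc) /
                max(sp$complex_conc, 1), 1e-9)
  }
})

test_that("fit_K11 inverts the slope relation exactly on clean data", {
  # slope 0.5 with S0 = 1 gives K = 1 by hand
  fit <- fit_K11(linear_dataset(slope = 0.5, S0 = 1.0))
  expect_equal(fit$K11, 1.0, tolerance = 1e-9)
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-9)

  # noiseless generator output returns the generating K
  sim <- simulate_phase_solubility(K11 = 1.5, S0 = 0.04, noise_cv = 0)
  fit <- fit_K11(sim$data)
  expect_equal(fit$K11, 1.5, tolerance = 1e-6)
})

test_that("fit_K11 restricted below the deviation onset is linear", {
  sim <- simulate_phase_solubility(K11 = 1.5, S0 = 0.04, noise_cv = 0,
                                   beta = 0.2, onset = 6.25)
  fit <- fit_K11(sim$data, linear_range = c(0, 6.25))
  expect_gt(fit$r_squared, 0.99)
  expect_equal(fit$K11, 1.5, tolerance = 1e-6)
})

test_that("fit_K11 rejects slopes incompatible with the 1:1 model", {
  flat <- phase_solubility_dataset(1:5, rep(0.5, 5), 0.5)
  expect_error(fit_K11(flat, linear_range = c(1, 5)), "no solubilization trend")
  steep <- phase_solubility_dataset(1:5, 0.1 + 1.2 * (1:5), 0.1)
  expect_error(fit_K11(steep, linear_range = c(1, 5)), "inconsistent with 1:1")
  expect_error(fit_K11(linear_dataset(grid = 1:6), linear_range = c(1, 2)),
               "fewer than 3")
})

test_that("fit_K11 can take S0 from the intercept on request", {
  d <- linear_dataset(slope = 0.4, S0 = 0.25, grid = 1:8)
  fit <- fit_K11(d, linear_range = c(1, 8), s0_from_intercept = TRUE)
  expect_equal(fit$S0, 0.25, tolerance = 1e-9)
  expect_equal(fit$K11, 0.4 / (0.25 * 0.6), tolerance = 1e-9)
})

test_that("detect_breakpoint classifies clean diagrams", {
  # perfectly linear: A_L with breakpoint at the data maximum
  sim <- simulate_phase_solubility(noise_cv = 0, beta = 0)
  bp <- detect_breakpoint(sim$data)
  expect_identical(bp$diagram_class, "A_L")
  expect_equal(bp$breakpoint, max(sim$data$ligand_total))

  # aggregation beyond 6.25 mM: A_N at the onset grid point
  siman <- simulate_phase_solubility(noise_cv = 0, beta = 0.2, onset = 6.25)
  bpan <- detect_breakpoint(siman$data)
  expect_identical(bpan$diagram_class, "A_N")
  expect_equal(bpan$breakpoint, 6.25)

  expect_error(detect_breakpoint(phase_solubility_dataset(1:4, 1 + 0.1 * (1:4), 1)),
               "at least 5", class = "gelsolv_insufficient_data")
})

test_that("detect_breakpoint stays on the observed grid under noise", {
  set.seed(21)
  seeds <- sample.int(1e6, 30)
  for (s in seeds) {
    sim <- simulate_phase_solubility(noise_cv = 0.05,
                                     beta = sample(c(0, 0.2), 1), seed = s)
    bp <- suppressWarnings(detect_breakpoint(sim$data))
    expect_true(bp$breakpoint %in% sim$data$ligand_total)
  }
})

test_that("a decreasing tail is classified A_N with a warning", {
  d <- phase_solubility_dataset(c(1, 2, 3, 4, 5, 6, 7),
                                c(0.1, 0.2, 0.3, 0.4, 0.5, 0.30, 0.15),
                                intrinsic_solubility = 0.01)
  expect_warning(bp <- detect_breakpoint(d), "B-type")
  expect_identical(bp$diagram_class, "A_N")
})

test_that("aggregation model reduces to the linear model and bends downward", {
  L <- seq(0, 25, length.out = 50)
  expect_equal(predict_with_aggregation(1.5, 0.04, 0, L),
               predict_total_solubility(1.5, 0.04, L))
  # beta > 0: strictly below the linear prediction for L > 0
  ag <- predict_with_aggregation(1.5, 0.04, 0.2, L)
  lin <- predict_total_solubility(1.5, 0.04, L)
  expect_true(all(ag[L > 0] < lin[L > 0]))
  expect_equal(ag[1], lin[1])
  # concavity: non-positive second differences on an equispaced grid
  expect_true(all(diff(ag, differences = 2) <= 1e-12))
})

test_that("aggregation with an onset leaves the diagram linear below it", {
  L <- 25 / 2^(9:0)
  ag <- predict_with_aggregation(1.5, 0.04, 0.2, L, onset = 6.25)
  lin <- predict_total_solubility(1.5, 0.04, L)
  expect_equal(ag[L <= 6.25], lin[L <= 6.25])
  expect_true(all(ag[L > 6.25] < lin[L > 6.25]))
})

test_that("dataset constructor and CSV reader enforce the contract", {
  expect_error(phase_solubility_dataset(c(1, 2), c(1, 2), 0.5), "at least 3")
  expect_error(phase_solubility_dataset(c(1, 2, 2), c(1, 2, 3), 0.5),
               "strictly increasing")
  expect_error(phase_solubility_dataset(c(1, 2, 3), c(1, -2, 3), 0.5),
               "non-negative")

  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(ligand_mM = c(1, 2, 4),
                              drug_solubility = c(35.6, 71.3, 142.6)),
                   f, row.names = FALSE)
  ds <- read_phase_solubility(f, intrinsic_solubility = 11.77, units = "ug/mL",
                              molar_mass = 356.41)
  expect_equal(ds$drug_total, c(35.6, 71.3, 142.6) / 356.41)
  expect_equal(ds$intrinsic_solubility, 11.77 / 356.41)
  expect_error(read_phase_solubility(f, 11.77, units = "ug/mL"), "molar_mass")
})
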