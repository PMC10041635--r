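test_that("anchor pH follows the mechanistic maxima", {
  expect_equal(anchor_pH("k1", pKa = 9, pKaH = 4), 0)
  expect_equal(anchor_pH("k2", pKa = 9), 14)
  expect_equal(anchor_pH("k2Ar", pKa = 9), 14)
  expect_equal(anchor_pH("k3"), 14)
  expect_equal(anchor_pH("k4", pKa = 9, pKaH = 4), 4)
  expect_equal(anchor_pH("k2cat", pKa = 6.5), 6.5)
  expect_equal(anchor_pH("k5"), 0)
  expect_error(anchor_pH("k4", pKa = 9), "pKaH")
})

test_that("two-point and noiseless regressions recover exact lines", {
  two <- fit_mechanism_regression(data.frame(
    molecule_id = c("a", "b"), mechanism = "k2",
    deltaE = c(0, 1), log_kmax = c(1, 3)))
  expect_equal(two$slope, 2)
  expect_equal(two$intercept, 1)
  expect_equal(two$r_squared, 1)
  expect_identical(two$n_points, 2L)

  dE <- seq(-0.01, 0.02, length.out = 10)
  ten <- fit_mechanism_regression(data.frame(
    molecule_id = letters[1:10], mechanism = "k4",
    deltaE = dE, log_kmax = -300 * dE - 5))
  expect_equal(ten$slope, -300, tolerance = 1e-9)
  expect_equal(ten$intercept, -5, tolerance = 1e-9)
  expect_equal(ten$deltaE_range, c(-0.01, 0.02))

  expect_error(fit_mechanism_regression(data.frame(
    molecule_id = "a", mechanism = "k3", deltaE = 0.1, log_kmax = -2)),
    "k3.*at least 2")
  expect_error(fit_mechanism_regression(data.frame(
    molecule_id = c("a", "b"), mechanism = "k3",
    deltaE = c(0.1, 0.1), log_kmax = c(-2, -3))),
    "identical")
})

test_that("regression equals the closed-form least-squares oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    x <- stats::rnorm(n, sd = 0.01)
    if (length(unique(x)) < 2) next
    y <- stats::rnorm(n, mean = -200 * x - 4, sd = 0.5)
    fit <- fit_mechanism_regression(data.frame(
      molecule_id = as.character(seq_len(n)), mechanism = "k2",
      deltaE = x, log_kmax = y))
    # normal-equations oracle
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    ss_res <- sum((y - slope * x - intercept)^2)
    ss_tot <- sum((y - mean(y))^2)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, intercept, tolerance = 1e-10)
    if (ss_tot > 0) {
      expect_equal(fit$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-10)
    }
  }
})

test_that("r_squared is invariant under affine rescaling of deltaE units", {
  set.seed(4)
  x <- stats::rnorm(12, sd = 0.01)
  y <- -250 * x - 3 + stats::rnorm(12, sd = 0.3)
  base <- fit_mechanism_regression(data.frame(
    molecule_id = as.character(1:12), mechanism = "k1",
    deltaE = x, log_kmax = y))
  scaled <- fit_mechanism_regression(data.frame(
    molecule_id = as.character(1:12), mechanism = "k1",
    deltaE = 627.5 * x + 0.42, log_kmax = y))  # e.g. hartree -> kcal/mol
  expect_equal(scaled$r_squared, base$r_squared, tolerance = 1e-12)
})

test_that("plateau prediction flags extrapolation outside the training range", {
  cal <- fit_mechanism_regression(data.frame(
    molecule_id = c("a", "b"), mechanism = "k2cat",
    deltaE = c(-0.0137, 0.0065), log_kmax = c(2 * -0.0137 + 1, 2 * 0.0065 + 1)))
  mid <- predict_log_kmax(cal, 0.005)
  expect_equal(mid$log_kmax, 2 * 0.005 + 1)
  expect_false(mid$extrapolated)
  expect_false(predict_log_kmax(cal, -0.0137)$extrapolated)  # closed boundary
  out <- predict_log_kmax(cal, -0.0658)
  expect_true(out$extrapolated)
  expect_equal(out$log_kmax, 2 * -0.0658 + 1)  # value still returned
})

test_that("calibration points read exact anchors and interpolate between brackets", {
  # single-pathway molecule measured exactly at its anchor
  aryl <- mol_row("a1", category = "aryl", pKa = 8, dE = c(k2Ar = 0.005))
  meas <- meas_rows("a1", pH = c(6, 10, 14), log_kobs = c(-4.5, -3, -3))
  pts <- extract_calibration_points(pdb_dataset(aryl, meas))
  expect_identical(nrow(pts), 1L)
  expect_equal(pts$log_kmax, -3)
  expect_identical(pts$method, "anchor")
  expect_equal(pts$anchor_pH, 14)

  # anchor between two measurements: linear midpoint interpolation
  rules_k4 <- default_mechanism_rules()
  rules_k4$categories$zwitterion_only <- "k4"
  zmol <- mol_row("z1", category = "zwitterion_only", pKa = 9, pKaH = 4,
                  dE = c(k4 = -0.002))
  zmeas <- meas_rows("z1", pH = c(3.6, 4.4), log_kobs = c(-3.2, -3.0))
  zpts <- extract_calibration_points(pdb_dataset(zmol, zmeas),
                                     rules = rules_k4)
  expect_equal(zpts$log_kmax, -3.1)
  expect_equal(zpts$anchor_pH, 4)

  # unbracketed anchor is skipped with a warning
  lowonly <- meas_rows("a1", pH = c(2, 6, 9.5), log_kobs = c(-7.5, -4.5, -2))
  expect_warning(
    none <- extract_calibration_points(pdb_dataset(aryl, lowonly)),
    "unbracketed.*k2Ar")
  expect_identical(nrow(none), 0L)
})

test_that("plateau decomposition recovers known levels from noiseless curves", {
  cfg <- default_algo_config()
  pH <- seq(0, 14, length.out = 12)

  k2curve <- mechanism_curve("k2", L = -3, pKa = 8, config = cfg)
  m1 <- meas_rows("x", pH, cap_rates(predict(k2curve, pH), cfg))
  L1 <- fit_plateaus(m1, "k2", pKa = 8, config = cfg)
  expect_equal(unname(L1[["k2"]]), -3, tolerance = 1e-6)

  curves <- list(mechanism_curve("k2", -2.2, pKa = 8, config = cfg),
                 mechanism_curve("k4", -3.7, pKa = 8, pKaH = 3, config = cfg))
  comb <- combine_curves(curves, pH, cfg)
  m2 <- meas_rows("x", pH, comb$combined)
  L2 <- fit_plateaus(m2, c("k2", "k4"), pKa = 8, pKaH = 3, config = cfg)
  expect_equal(unname(L2[["k2"]]), -2.2, tolerance = 1e-4)
  expect_equal(unname(L2[["k4"]]), -3.7, tolerance = 1e-4)

  expect_error(fit_plateaus(m2[0, ], "k2", pKa = 8), "no measurements")
  expect_error(fit_plateaus(m2[1, , drop = FALSE], c("k2", "k4"),
                            pKa = 8, pKaH = 3),
               "more free plateau levels")
  expect_error(fit_plateaus(m2, character(0), pKa = 8), "empty active")
})

test_that("extract-fit-predict round-trip is exact on noiseless single-pathway data", {
  synth <- generate_synthetic(synthetic_spec(
    n_molecules = 12, category_mix = c(aryl = 1), noise_sd = 0, seed = 5))
  pts <- extract_calibration_points(synth$dataset)
  truth <- merge(pts, synth$truth$plateaus,
                 by = c("molecule_id", "mechanism"))
  expect_identical(nrow(truth), 12L)
  expect_lt(max(abs(truth$log_kmax - truth$L)), 1e-9)

  cal <- fit_calibrations(pts)$k2Ar
  for (i in seq_len(nrow(truth))) {
    pred <- predict_log_kmax(cal, truth$deltaE.x[i])
    expect_equal(pred$log_kmax, truth$L[i], tolerance = 1e-9)
  }
})
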