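cfg <- default_algo_config()

test_that("curve shapes follow plateau, slopes and breakpoints", {
  k4 <- mechanism_curve("k4", L = -3, pKa = 9, pKaH = 4, config = cfg)
  expect_equal(predict(k4, 6), -3)           # zwitterion plateau
  expect_equal(predict(k4, 2), -4.5)         # 0.75 x 2 pH units below pKaH
  expect_equal(predict(k4, 11), -4.5)        # falls above pKa too

  k2 <- mechanism_curve("k2", L = -2, pKa = 9, config = cfg)
  expect_equal(predict(k2, 12), -2)
  expect_equal(predict(k2, 7), -3.5)

  expect_equal(predict(mechanism_curve("k1", -1, config = cfg), c(0, 3)),
               c(-1, -4))
  expect_equal(predict(mechanism_curve("k3", -2, config = cfg), c(14, 10)),
               c(-2, -10))
  expect_equal(predict(mechanism_curve("k5", -1, config = cfg), 4), -4)
  k2cat <- mechanism_curve("k2cat", 0, pKa = 6, config = cfg)
  expect_equal(predict(k2cat, c(5, 6, 8)), c(-2, 0, -4))

  expect_error(mechanism_curve("k4", -3, pKa = 9), "pKaH")
  expect_error(mechanism_curve("k4", -3, pKa = 4, pKaH = 9), "pKaH < pKa")
  expect_error(mechanism_curve("k2", -3), "pKa")
})

test_that("curves are continuous at breakpoints for random parameters", {
  set.seed(21)
  eps <- 1e-7
  for (rep in 1:25) {
    L <- stats::runif(1, -8, 1)
    pKa <- stats::runif(1, 5, 10)
    pKaH <- stats::runif(1, 1, 4)
    for (mech in MECHANISMS) {
      crv <- mechanism_curve(mech, L, pKa = pKa, pKaH = pKaH, config = cfg)
      for (b in crv$breakpoints) {
        expect_lt(abs(predict(crv, b - eps) - predict(crv, b + eps)), 1e-5)
      }
      # the plateau level is the curve's maximum everywhere
      grid <- seq(0, 14, by = 0.25)
      expect_true(all(predict(crv, grid) <= L + 1e-12))
    }
  }
})

test_that("finite-difference slopes reproduce the configured slopes on segment interiors", {
  pKa <- 8.3
  pKaH <- 3.1
  segments <- list(
    k1    = list(list(c(0, 14), -1)),
    k2    = list(list(c(0, pKa), 0.75), list(c(pKa, 14), 0)),
    k2Ar  = list(list(c(0, pKa), 0.75), list(c(pKa, 14), 0)),
    k2cat = list(list(c(0, pKa), 2), list(c(pKa, 14), -2)),
    k3    = list(list(c(0, 14), 2)),
    k4    = list(list(c(0, pKaH), 0.75), list(c(pKaH, pKa), 0),
                 list(c(pKa, 14), -0.75)),
    k5    = list(list(c(0, 14), -0.75))
  )
  h <- 1e-4
  for (mech in names(segments)) {
    crv <- mechanism_curve(mech, -3, pKa = pKa, pKaH = pKaH, config = cfg)
    for (seg in segments[[mech]]) {
      xs <- seq(seg[[1]][1] + 0.05, seg[[1]][2] - 0.05, length.out = 5)
      fd <- (predict(crv, xs + h) - predict(crv, xs - h)) / (2 * h)
      expect_equal(fd, rep(seg[[2]], length(xs)), tolerance = 1e-8)
    }
  }
})

test_that("combining curves sums rates in linear space and caps the result", {
  grid <- seq(0, 14, by = 0.5)
  one <- combine_curves(list(mechanism_curve("k2", -2, pKa = 0.5,
                                             config = cfg)), grid, cfg)
  expect_equal(one$combined[grid >= 0.5], rep(-2, sum(grid >= 0.5)))

  # two equal contributions add log10(2)
  two <- combine_curves(list(mechanism_curve("k2", -5, pKa = 1, config = cfg),
                             mechanism_curve("k3", -5, pKa = 1, config = cfg)),
                        14, cfg)
  expect_equal(two$combined, -5 + log10(2), tolerance = 1e-12)

  # values beyond the cap are clipped on the combined curve only
  hot <- combine_curves(list(mechanism_curve("k2", 3.5, pKa = 2,
                                             config = cfg)), 14, cfg)
  expect_equal(hot$combined, 2)
  expect_equal(unname(hot$per_mechanism[1, "k2"]), 3.5)
  expect_equal(hot$combined_uncapped, 3.5)

  expect_error(combine_curves(list(), grid, cfg), "no curves")
})

test_that("combined log-rate obeys the log-sum-exp sandwich and capping is idempotent", {
  set.seed(33)
  grid <- seq(0, 14, by = 0.2)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    mechs <- sample(MECHANISMS, n)
    curves <- lapply(mechs, function(m) {
      mechanism_curve(m, stats::runif(1, -8, 1), pKa = stats::runif(1, 5, 10),
                      pKaH = stats::runif(1, 1, 4), config = cfg)
    })
    prof <- combine_curves(curves, grid, cfg)
    mx <- apply(prof$per_mechanism, 1, max)
    expect_true(all(prof$combined_uncapped >= mx - 1e-12))
    expect_true(all(prof$combined_uncapped <= mx + log10(n) + 1e-12))
  }
  x <- stats::runif(50, -20, 10)
  expect_identical(cap_rates(cap_rates(x, cfg), cfg), cap_rates(x, cfg))
  xs <- sort(x)
  expect_true(all(diff(cap_rates(xs, cfg)) >= 0))  # order-preserving
})

test_that("half-life converts log-rates to first-order lifetimes", {
  expect_equal(half_life(0), log(2))
  expect_equal(half_life(2), 6.93e-3, tolerance = 1e-3)
  expect_equal(half_life(-9), 6.93e8, tolerance = 1e-3)
  lk <- seq(-9, 2, by = 0.5)
  expect_true(all(diff(half_life(lk)) < 0))  # strictly decreasing
})

test_that("profile prediction composes the pipeline and reports dropped mechanisms", {
  cals <- list(k1 = cal_from_line("k1", -250, -4.5),
               k2 = cal_from_line("k2", -300, -4),
               k3 = cal_from_line("k3", -280, -4),
               k4 = cal_from_line("k4", -260, -3.5))
  dE <- c(k1 = 0.004, k2 = -0.003, k3 = 0.001, k4 = -0.002)
  mol <- mol_row("obh1", category = "other_basic_heterocycle",
                 pKa = 8.2, pKaH = 2.5, dE = dE)
  prof <- predict_profile(mol, cals)
  expect_setequal(colnames(prof$per_mechanism), c("k1", "k2", "k3", "k4"))

  # the combined profile equals an explicit combination of the same curves
  expected <- combine_curves(lapply(names(dE), function(m) {
    mechanism_curve(m, cals[[m]]$slope * dE[[m]] + cals[[m]]$intercept,
                    pKa = 8.2, pKaH = 2.5, config = default_algo_config())
  }), prof$pH_grid)
  expect_equal(prof$combined, expected$combined, tolerance = 1e-12)

  # a missing energy difference drops that pathway with a warning
  mol3 <- mol_row("obh2", category = "other_basic_heterocycle",
                  pKa = 8.2, pKaH = 2.5, dE = dE[c("k1", "k2", "k4")])
  expect_warning(prof3 <- predict_profile(mol3, cals), "k3")
  expect_setequal(colnames(prof3$per_mechanism), c("k1", "k2", "k4"))
  expect_identical(prof3$dropped, "k3")

  bare <- mol_row("obh3", category = "other_basic_heterocycle",
                  pKa = 8.2, pKaH = 2.5)
  expect_warning(expect_error(predict_profile(bare, cals), "no active"))

  # absent pKaH is imputed from a training table before curve building
  noH <- mol_row("obh4", category = "other_basic_heterocycle",
                 pKa = 8.2, dE = dE)
  training <- rbind(mol_row("t1", pKa = 8, pKaH = 2),
                    mol_row("t2", pKa = 9, pKaH = 4))
  profH <- predict_profile(noH, cals, training = training)
  ref <- predict_profile(mol_row("obh4", category = "other_basic_heterocycle",
                                 pKa = 8.2, pKaH = 3, dE = dE), cals)
  expect_equal(profH$combined, ref$combined)
})
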