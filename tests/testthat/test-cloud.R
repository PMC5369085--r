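test_that("the quadratic pseudo-bound matches the published regressions", {
  expect_equal(pseudo_bound(c(40, 80, 180, 280, 565)), 849, tolerance = 1e-9)
  expect_equal(pseudo_bound(c(35, 75, 115, 150, 250)), 333.99,
               tolerance = 0.1)
  expect_equal(pseudo_bound(c(2, 4, 14, 24, 36)), 52.42, tolerance = 0.05)
  # exactly linear inputs: zero curvature, linear extrapolation
  expect_equal(pseudo_bound(c(10, 20, 30, 40, 50)), 60, tolerance = 1e-9)
  expect_error(pseudo_bound(c(1, 2)), "3 bounds")
})

test_that("cloud parameters regenerate the published table to +-0.01", {
  got <- cloud_params(load_fixture("criteria_bounds"), k = 0.1)
  ref <- load_fixture("cloud_params")
  merged <- dplyr::inner_join(got, ref, by = c("criterion", "level"))
  expect_identical(nrow(merged), 36L)
  closed <- merged$level != "VI"
  expect_lt(max(abs(merged$ex.x - merged$ex.y)[closed]), 0.01 + 1e-9)
  expect_lt(max(abs(merged$en.x - merged$en.y)[closed]), 0.01 + 1e-9)
  expect_lt(max(abs(merged$he.x - merged$he.y)[closed]), 0.01 + 1e-9)
  # level VI derives from the pseudo-bound; the published table evaluated
  # rounded regression coefficients, so exact OLS differs by up to ~0.2
  expect_lt(max(abs(merged$ex.x - merged$ex.y)[!closed]), 0.25)
  expect_lt(max(abs(merged$en.x - merged$en.y)[!closed]), 0.15)
  expect_lt(max(abs(merged$he.x - merged$he.y)[!closed]), 0.02)

  # spot values: PM2.5 level II and CO level I
  pm2 <- got[got$criterion == "PM2.5" & got$level == "II", ]
  expect_equal(pm2$ex, 55)
  expect_equal(pm2$en, 40 / 3)
  expect_equal(pm2$he, 4 / 3)
  co1 <- got[got$criterion == "CO" & got$level == "I", ]
  expect_equal(co1$ex, 1)
  expect_equal(round(co1$en, 2), 0.67)

  # degenerate atomisation: k = 0 gives a deterministic cloud
  expect_true(all(cloud_params(load_fixture("criteria_bounds"), k = 0)$he == 0))
})

test_that("half sides mark only the extreme levels", {
  got <- cloud_params()
  expect_true(all(got$half_side[got$level == "I"] == "lower"))
  expect_true(all(got$half_side[got$level == "VI"] == "upper"))
  expect_true(all(got$half_side[!got$level %in% c("I", "VI")] == "none"))
})

test_that("certainty follows the X-condition cloud generator", {
  expect_equal(certainty(55, ex = 55, en = 13.33, he = 1.33, reps = 5),
               rep(1, 5))
  # deterministic cloud: mu at one entropy from the centre is exp(-1/2)
  expect_equal(certainty(55 + 13.33, ex = 55, en = 13.33, he = 0),
               exp(-0.5))
  # half-cloud saturation below the centre (SO2 level I)
  expect_equal(certainty(10.7273, ex = 25, en = 16.67, he = 1.67,
                         half_side = "lower", reps = 3), rep(1, 3))
  # bounded and reproducible
  mu <- certainty(70, ex = 55, en = 13.33, he = 1.33, reps = 2000, seed = 4)
  expect_true(all(mu >= 0 & mu <= 1))
  expect_identical(mu, certainty(70, ex = 55, en = 13.33, he = 1.33,
                                 reps = 2000, seed = 4))
  # vanishing hyper-entropy: Monte-Carlo mean converges to the closed form
  mu_small <- certainty(70, ex = 55, en = 13.33, he = 1e-8, reps = 2000,
                        seed = 5)
  expect_equal(mean(mu_small), exp(-(70 - 55)^2 / (2 * 13.33^2)),
               tolerance = 1e-3)
})

test_that("half-cloud membership is monotone on the open side", {
  xs <- seq(25, 120, by = 5)
  mus <- vapply(xs, function(x) {
    certainty(x, ex = 25, en = 16.67, he = 0, half_side = "lower")
  }, numeric(1))
  expect_true(all(diff(mus) <= 0))
  expect_equal(certainty(10, ex = 25, en = 16.67, he = 0,
                         half_side = "lower"), 1)
})

test_that("entropy weights match an independent histogram computation", {
  set.seed(41)
  data <- purrr::map_dfr(seq_along(aerowarn:::aq_criteria), function(i) {
    tibble::tibble(
      criterion = aerowarn:::aq_criteria[i],
      value = rgamma(400, shape = i, scale = 10)
    )
  })
  got <- entropy_weights(data, bins = 10)
  expect_equal(sum(got$omega), 1, tolerance = 1e-12)
  for (cr in aerowarn:::aq_criteria) {
    e_oracle <- oracle_bin_entropy(data$value[data$criterion == cr], 10)
    expect_equal(got$entropy[got$criterion == cr], e_oracle,
                 tolerance = 1e-8)
  }
})

test_that("entropy weight edge cases resolve as prescribed", {
  # one uniform criterion (E = 1), one fully concentrated (E = 0)
  u <- rep(seq(0.5, 9.5, by = 1) / 10, each = 10)  # exactly uniform over bins
  conc <- rep(c(0, 1e-9), 50)                      # all mass in one bin
  data <- tibble::tibble(
    criterion = rep(c("A", "B"), each = 100),
    value = c(u, conc)
  )
  got <- entropy_weights(data, bins = 10)
  expect_equal(got$omega[got$criterion == "A"], 0, tolerance = 1e-9)
  expect_equal(got$omega[got$criterion == "B"], 1, tolerance = 1e-9)

  # all criteria uniform: degenerate 0/0 resolved to equal weights
  data_u <- tibble::tibble(
    criterion = rep(c("A", "B", "C"), each = 100),
    value = rep(u, 3)
  )
  expect_equal(entropy_weights(data_u, bins = 10)$omega, rep(1 / 3, 3))
})

test_that("combined weights reproduce the published entropy-AHP column", {
  w <- combine_weights(load_fixture("weights"))
  expect_lt(abs(w$w[w$criterion == "PM2.5"] - 0.4292), 1e-4)
  expect_lt(abs(w$w[w$criterion == "PM10"] - 0.3505), 1e-4)
  expect_equal(sum(w$w), 1, tolerance = 1e-12)

  # uniform expert weights collapse to the entropy weights
  omega <- c(0.2, 0.3, 0.5)
  expect_equal(combine_weights(rep(1 / 3, 3), omega)$w, omega)
  expect_error(combine_weights(c(0, 0), c(0, 0)), "zero")
})

test_that("evaluation reproduces the published certainty degrees", {
  ev <- evaluate_air_quality(load_fixture("eval_samples"), reps = 2000,
                             seed = 42)
  expect_equal(ev$I[ev$case == "A_3"], 0.9119, tolerance = 0.01)
  expect_equal(ev$II[ev$case == "A_4"], 0.6136, tolerance = 0.02)
  expect_equal(ev$II[ev$case == "A_2"], 0.5421, tolerance = 0.02)
  expect_equal(ev$I[ev$case == "A_9"], 0.1284, tolerance = 0.02)

  # final levels for the eight internally consistent published rows
  consistent <- c(A_1 = "I", A_2 = "II", A_3 = "I", A_4 = "II", A_5 = "IV",
                  A_7 = "I", A_8 = "I", A_9 = "II")
  expect_equal(setNames(ev$final_level[match(names(consistent), ev$case)],
                        names(consistent)), consistent)

  # the published A_6 row lists the same three values with the III/IV/V
  # columns cyclically shifted; the computed certainties match them as a set
  a6 <- unlist(ev[ev$case == "A_6", c("III", "IV", "V")])
  expect_equal(sort(as.numeric(a6)), sort(c(0.1554, 0.1877, 0.3408)),
               tolerance = 0.02)
})

test_that("evaluation honours exact centres and determinism", {
  clouds <- cloud_params()
  lvl3 <- clouds[clouds$level == "III", ]
  sample3 <- setNames(as.list(lvl3$ex), as.character(lvl3$criterion))
  ev <- evaluate_air_quality(tibble::as_tibble(sample3), reps = 50, seed = 1)
  expect_equal(ev$III, 1, tolerance = 1e-9)
  expect_identical(ev$final_level, "III")

  a <- evaluate_air_quality(load_fixture("eval_samples")[1, ], reps = 100,
                            seed = 9)
  b <- evaluate_air_quality(load_fixture("eval_samples")[1, ], reps = 100,
                            seed = 9)
  expect_identical(a, b)

  expect_error(
    evaluate_air_quality(tibble::tibble(`PM2.5` = 10), reps = 10),
    "Missing criterion"
  )
})
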