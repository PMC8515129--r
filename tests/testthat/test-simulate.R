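test_that("simulation is deterministic given the seed", {
  cfg <- default_calibration()
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(a, b)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(a$v2, c2$v2))
})

test_that("the default calibration is a pure function", {
  expect_identical(default_calibration(), default_calibration())
})

test_that("phantom digitization is deterministic", {
  s <- phantom_spec("snowman", voxel = 1)
  expect_identical(make_phantom(s)$mask$labels, make_phantom(s)$mask$labels)
})

test_that("default cohorts carry the expected marginal structure", {
  cfg <- default_calibration()
  cfg$n <- 5000
  co <- simulate_cohort(cfg, seed = 77)
  # pooled medians near the reference values (43/55-weighted group medians)
  expect_lt(abs(median(co$v2) - 3395) / 3395, 0.30)
  expect_lt(abs(median(co$d1) - 27.05) / 27.05, 0.30)
  expect_lt(abs(median(co$d2) - 25.98) / 25.98, 0.30)
  expect_gt(median(co$d2), 20)
  expect_lt(median(co$d2), 32)
  # zero-inflated suprasellar volume: purely intrasellar tumors dominate
  # the non-recurrent stratum
  expect_equal(median(co$v1[co$recurrent == 0]), 0)
  expect_gt(median(co$v1[co$recurrent == 1]), 0)
})

test_that("the recurrent fraction tracks the calibration target", {
  fracs <- vapply(1:20, function(s)
    mean(simulate_cohort(default_calibration(), seed = 200 + s)$recurrent),
    numeric(1))
  expect_lt(abs(mean(fracs) - 55 / 98), 0.05)
  expect_true(all(abs(fracs - 55 / 98) < 0.15))
})

test_that("binned recurrence probabilities track the logistic mechanism", {
  cfg <- default_calibration()
  cfg$n <- 20000
  co <- simulate_cohort(cfg, seed = 88)
  bins <- cut(co$vd_true, quantile(co$vd_true, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  emp <- tapply(co$recurrent, bins, mean)
  mod <- tapply(plogis(cfg$beta0 + cfg$beta1 * co$vd_true), bins, mean)
  expect_true(all(abs(emp - mod) < 0.05))
})

test_that("a null mechanism yields an uninformative score", {
  cfg <- cohort_sim_config(n = 2000, beta1 = 0, beta0 = 0)
  co <- simulate_cohort(cfg, seed = 55)
  r <- roc_analysis(co$vd_true, co$recurrent)
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_sim_config(n = 5), "n >= 10")
  expect_error(cohort_sim_config(v2_sdlog = -1))
  expect_error(simulate_cohort(default_calibration()), "seed")
})
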