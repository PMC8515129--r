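test_that("the V-D value is the sum of the two ratios", {
  expect_equal(vd_value(0, 1000, 20, 20), 1.0)
  expect_equal(vd_value(2000, 4000, 20, 26), 0.5 + 20 / 26)
  expect_error(vd_value(1, 0, 1, 1), "V-D undefined")
  expect_error(vd_value(1, 10, 1, 0), "V-D undefined")
  expect_error(vd_value(-1, 10, 1, 1), "non-negative")
})

test_that("published worked cases are internally consistent", {
  cases <- read.csv(system.file("extdata", "worked_cases.csv",
                                package = "vdscore"))
  # volume additivity: V1 + V2 reproduces the printed total exactly
  expect_equal(round(cases$v1 + cases$v2, 2), cases$tv_printed)
  # the back-computed diameter ratio VD - V1/V2 must be a plausible
  # D1/D2 value (positive, below 2); case 5 prints its volume labels
  # transposed relative to its own score and is excluded
  d_ratio <- cases$vd_printed[1:4] - cases$v1[1:4] / cases$v2[1:4]
  expect_true(all(d_ratio > 0 & d_ratio < 2))
})

test_that("V-D is monotone in each argument", {
  base <- vd_value(1000, 2000, 20, 25)
  expect_gt(vd_value(1100, 2000, 20, 25), base)
  expect_gt(vd_value(1000, 1900, 20, 25), base)
  expect_gt(vd_value(1000, 2000, 21, 25), base)
  expect_gt(vd_value(1000, 2000, 20, 24), base)
  for (d1 in c(5, 17, 33))
    expect_equal(vd_value(0, 1234, d1, 26), d1 / 26)
})

test_that("size classes partition (0, Inf) with closed upper boundaries", {
  expect_equal(as.character(classify_size(14.99)), "small")
  expect_equal(as.character(classify_size(15)), "large")
  expect_equal(as.character(classify_size(22.90)), "large")
  expect_equal(as.character(classify_size(29.999)), "large")
  expect_equal(as.character(classify_size(30)), "giant")
  expect_error(classify_size(0), "positive")
  d1 <- exp(runif(200, log(1), log(80)))
  expect_false(anyNA(classify_size(d1)))          # exhaustive coverage
})

test_that("recurrence rules use strict thresholds", {
  expect_equal(classify_recurrence("total", followup_volume = 150),
               "recurrent")
  expect_equal(classify_recurrence("total", followup_volume = 100),
               "non_recurrent")                    # exactly 0.1 cm^3
  expect_equal(classify_recurrence("subtotal", 1200, residual_volume = 1000),
               "non_recurrent")                    # 20% growth
  expect_equal(classify_recurrence("subtotal", 1250, residual_volume = 1000),
               "non_recurrent")                    # exactly 25%
  expect_equal(classify_recurrence("subtotal", 1300, residual_volume = 1000),
               "recurrent")                        # 30% growth
  expect_equal(classify_recurrence("subtotal", 1000, residual_volume = 1000),
               "non_recurrent")                    # unchanged residual
  expect_error(classify_recurrence("subtotal", 500, residual_volume = 0),
               "positive residual_volume")
})

test_that("rater discordance flags >20% relative to the mean", {
  expect_false(flag_rater_discordance(1000, 1100))  # 9.5%
  expect_true(flag_rater_discordance(1000, 1500))   # 40%
  expect_false(flag_rater_discordance(1000, 1000))
  expect_true(flag_rater_discordance(1500, 1000))   # symmetric in raters
  expect_error(flag_rater_discordance(0, 1000), "positive")
})
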