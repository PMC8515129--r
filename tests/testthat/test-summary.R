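test_that("a constructed V-D effect is flagged while sex is not", {
  set.seed(14)
  n <- 120
  d <- data.frame(
    group = rep(c("a", "b"), each = n / 2),
    sex = sample(c("M", "F"), n, TRUE),
    vd = c(rlnorm(n / 2, log(1.0), 0.4), rlnorm(n / 2, log(2.0), 0.4)))
  tab <- summarize_cohort(d, "group", c("vd", "sex"))
  expect_lt(tab$p[tab$variable == "vd"], 0.001)
  expect_gt(tab$p[tab$variable == "sex" & !is.na(tab$p)], 0.05)
})

test_that("identical groups produce a null comparison", {
  d <- data.frame(g = rep(c("x", "y"), each = 3), v = rep(c(1, 2, 3), 2))
  tab <- suppressWarnings(summarize_cohort(d, "g", "v"))
  expect_gt(tab$p, 0.9)
  expect_equal(tab$x, tab$y)              # identical summaries
})

test_that("group tests hold their nominal type-I error", {
  set.seed(15)
  n <- 200
  reps <- 500
  p <- vapply(seq_len(reps), function(i) {
    d <- data.frame(g = rep(c("a", "b"), each = n / 2), v = rnorm(n))
    summarize_cohort(d, "g", "v")$p
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
})

test_that("categorical rows report counts, percentages and chi-square", {
  set.seed(16)
  d <- data.frame(g = rep(c("a", "b"), each = 30),
                  k = factor(sample(0:2, 60, TRUE)))
  tab <- summarize_cohort(d, "g", "k")
  head_row <- tab[tab$variable == "k" & is.na(tab$level), ]
  expect_equal(head_row$test, "chi-square")
  lev <- tab[!is.na(tab$level), ]
  pct <- as.numeric(sub(".*\\((.*)%\\)", "\\1", lev$a))
  expect_equal(sum(pct), 100, tolerance = 0.2)
})

test_that("constant variables are skipped with a note", {
  d <- data.frame(g = rep(c("a", "b"), each = 5), v = rep(1, 10))
  tab <- summarize_cohort(d, "g", "v")
  expect_match(tab$note, "constant")
  expect_true(is.na(tab$p))
})

test_that("Spearman matrix is symmetric with unit diagonal", {
  set.seed(17)
  d <- data.frame(x = rnorm(50))
  d$y <- d$x^3                             # strictly monotone
  d$z <- rnorm(50)
  d$const <- 1
  m <- spearman_matrix(d, c("x", "y", "z", "const"))
  expect_equal(m["x", "y"], 1)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_true(is.na(m["x", "const"]))      # all-tied -> undefined
})

test_that("Spearman is invariant under monotone transforms and small under independence", {
  set.seed(18)
  d <- data.frame(x = rexp(1000), y = rnorm(1000))
  m1 <- spearman_matrix(d, c("x", "y"))
  d2 <- data.frame(x = log(d$x), y = d$y^3 + 5)  # monotone maps
  m2 <- spearman_matrix(d2, c("x", "y"))
  expect_equal(m1["x", "y"], m2["x", "y"], tolerance = 1e-12)
  expect_lt(abs(m1["x", "y"]), 0.1)
})
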