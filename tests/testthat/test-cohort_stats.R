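test_that("chi-square matches the brute-force Pearson oracle to 1e-12", {
  set.seed(13)
  for (i in 1:20) {
    r <- sample(2:3, 1); cc <- sample(2:4, 1)
    m <- matrix(rpois(r * cc, 12) + 1, r, cc)
    got <- chi_square_test(m)
    want <- oracle_chisq(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("published contingency tables give the recomputed Pearson results", {
  tp53 <- chi_square_test(matrix(c(24, 8, 59, 5), 2, byrow = TRUE))
  expect_equal(tp53$statistic, 5.383, tolerance = 1e-3)
  expect_equal(tp53$p_value, 0.0203, tolerance = 1e-2)
  pten <- chi_square_test(matrix(c(53, 0, 30, 13), 2, byrow = TRUE))
  expect_lt(pten$p_value, 0.001)
  prop <- chi_square_test(matrix(c(10, 20, 5, 10), 2, byrow = TRUE))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "Row")
  # Yates correction shrinks the statistic
  yates <- chi_square_test(matrix(c(24, 8, 59, 5), 2, byrow = TRUE), "yates")
  expect_lt(yates$statistic, tp53$statistic)
})

test_that("rank tests agree with exact enumeration and handle identical groups", {
  d <- tibble::tibble(load = c(1, 2, 3, 4, 5, 6),
                      group = rep(c("a", "b"), each = 3))
  got <- rank_test(d)
  expect_equal(got$p_value, oracle_ranksum_enum(1:3, 4:6), tolerance = 1e-12)
  same <- rank_test(tibble::tibble(load = rep(1:3, 2),
                                   group = rep(c("a", "b"), each = 3)))
  expect_gt(same$p_value, 0.9)
  kw <- rank_test(tibble::tibble(load = rep(1:3, 3),
                                 group = rep(c("a", "b", "c"), each = 3)))
  expect_equal(kw$method, "kruskal_wallis")
  expect_equal(kw$p_value, 1)
  expect_error(rank_test(tibble::tibble(load = 1, group = "a")), "two")
})

test_that("rank separation of an ultramutated group is detected at cohort scale", {
  set.seed(5)
  loads <- tibble::tibble(
    load = c(rpois(16, 94), rpois(80, 36)),
    group = rep(c("POLE", "rest"), c(16, 80)))
  expect_lt(rank_test(loads)$p_value, 0.001)
})

test_that("Kaplan-Meier matches hand-computed product-limit values", {
  two <- km_estimate(tibble::tibble(time = c(1, 5), event = c(1, 0)))
  expect_equal(two$surv[two$time == 1], 0.5)

  none <- km_estimate(tibble::tibble(time = 1:4, event = 0))
  expect_true(all(none$surv == 1))
  expect_true(is.na(km_median(none)$median))

  three <- km_estimate(tibble::tibble(time = 1:3, event = 1))
  expect_equal(three$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km_median(three)$median, 2)

  # curve properties: starts at 1, non-increasing
  set.seed(8)
  km <- km_estimate(tibble::tibble(time = rexp(40, 0.05) + 0.1,
                                   event = rbinom(40, 1, 0.8)))
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_lte(km$surv[1], 1)
})

test_that("log-rank matches the direct O-E oracle and its invariances", {
  d <- tibble::tibble(time = c(1, 2, 3, 10, 20, 30), event = 1,
                      group = rep(c("a", "b"), each = 3))
  got <- logrank_test(d)
  want <- oracle_logrank2(d$time, d$event, d$group)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$p_value, want$p, tolerance = 1e-9)

  relabeled <- dplyr::mutate(d, group = ifelse(group == "a", "z", "y"))
  rescaled <- dplyr::mutate(d, time = time * 12)
  expect_equal(logrank_test(relabeled)$statistic, got$statistic)
  expect_equal(logrank_test(rescaled)$statistic, got$statistic)

  same <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = 1,
                         group = rep(c("a", "b"), each = 3))
  expect_equal(logrank_test(same)$statistic, 0, tolerance = 1e-12)

  cens <- tibble::tibble(time = 1:6, event = 0,
                         group = rep(c("a", "b"), each = 3))
  expect_warning(res <- logrank_test(cens), "censored")
  expect_equal(res$p_value, 1)
})
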