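test_that("measurable-lesion rule: enhancing, >= 2 slices, both diameters > 10 mm", {
  expect_true(is_measurable(12, 15, 3, TRUE))
  expect_false(is_measurable(12, 10, 3, TRUE))   # strict > 10 mm
  expect_false(is_measurable(10.0, 12, 2, TRUE))
  expect_true(is_measurable(10.1, 10.1, 2, TRUE))
  expect_false(is_measurable(12, 15, 1, TRUE))   # single axial slice
  expect_false(is_measurable(12, 15, 3, FALSE))  # non-enhancing
})

test_that("sum of perpendicular products counts only measurable lesions", {
  one <- make_lesion_records(data.frame(lesion_id = 1, timepoint = "t0",
                                        d1_mm = 20, d2_mm = 20,
                                        axial_slices = 3))
  expect_equal(sum_perpendicular_products(one), 400)
  two <- make_lesion_records(data.frame(lesion_id = 1:2, timepoint = "t0",
                                        d1_mm = c(20, 11), d2_mm = c(20, 11),
                                        axial_slices = c(3, 2)))
  expect_equal(sum_perpendicular_products(two), 521)
  mixed <- make_lesion_records(data.frame(lesion_id = 1:3, timepoint = "t0",
                                          d1_mm = c(20, 9, 30),
                                          d2_mm = c(20, 9, 30),
                                          axial_slices = c(3, 3, 1)))
  expect_equal(sum_perpendicular_products(mixed), 400)
  expect_equal(sum_perpendicular_products(two[0, ]), 0)
})

test_that("progression threshold sits exactly at a 25% increase", {
  base <- make_lesion_records(data.frame(lesion_id = 1, timepoint = "t0",
                                         d1_mm = 20, d2_mm = 20,
                                         axial_slices = 3))
  fup <- function(d) make_lesion_records(data.frame(
    lesion_id = 1, timepoint = "t1", d1_mm = d, d2_mm = 20, axial_slices = 3))
  expect_true(classify_progression(base, fup(25)))     # 500 = +25% exactly
  expect_false(classify_progression(base, fup(24.8)))  # 496 = +24%
  expect_true(classify_progression(base, fup(20), flair_increase = TRUE))
  expect_error(classify_progression(base[0, ], fup(20)), "indeterminate")
  expect_true(classify_progression(base[0, ], fup(20), flair_increase = TRUE))
  # monotone: increasing follow-up burden never revokes progression
  sums <- seq(15, 35, by = 0.5)
  calls <- vapply(sums, function(d) classify_progression(base, fup(d)),
                  logical(1))
  expect_false(is.unsorted(calls))
})

test_that("PFS uses 30.44-day months and rejects non-positive intervals", {
  expect_error(compute_pfs("2020-01-01", "2020-01-01"), "non-positive")
  expect_equal(compute_pfs("2020-01-01", as.Date("2020-01-01") + 213),
               7.0, tolerance = 0.01)
  expect_equal(compute_pfs("2020-01-01", "2021-01-01"), 12.0, tolerance = 0.05)
})

test_that("Kaplan-Meier curve matches a hand-computed product-limit table", {
  # no events: flat at 1
  km0 <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  km2 <- km_curve(c(1, 2), c(1, 1))
  expect_equal(km2$survival, c(0.5, 0))

  # 6 subjects, censoring at t=2: hand-computed PI(1 - d_i/n_i)
  tm <- c(1, 2, 3, 4, 5, 6)
  ev <- c(1, 0, 1, 1, 0, 1)
  km <- km_curve(tm, ev)
  s <- km$survival[km$n_event > 0]
  expect_equal(s, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0))
  # non-increasing, starts at/below 1
  expect_true(all(diff(km$survival) <= 0))
  expect_lte(max(km$survival), 1)
})

test_that("log-rank test separates separated groups and is label-symmetric", {
  t1 <- c(1, 2, 3, 2, 4); e1 <- rep(1, 5)
  same <- logrank_test(c(t1, t1), c(e1, e1), rep(c("a", "b"), each = 5))
  expect_lt(same$statistic, 1e-10)
  expect_gt(same$p_value, 0.99)

  ta <- seq(1, 5, length.out = 20); tb <- seq(10, 20, length.out = 20)
  lr <- logrank_test(c(ta, tb), rep(1, 40), rep(c("a", "b"), each = 20))
  expect_lt(lr$p_value, 0.01)
  lr_sw <- logrank_test(c(ta, tb), rep(1, 40), rep(c("b", "a"), each = 20))
  expect_equal(lr$statistic, lr_sw$statistic)
  expect_gte(lr$statistic, 0)
})

test_that("Cox fit recovers a simulated hazard ratio and flags empty-event groups", {
  grp <- rep(c("ref", "risk"), each = 100)
  with_seed(101, {
    tm <- c(rexp(100, rate = 0.1), rexp(100, rate = 0.3))  # true HR 3
  })
  fit <- cox_hr(tm, rep(1, 200), grp)
  expect_gt(fit$hr, 2.2); expect_lt(fit$hr, 4.0)
  expect_lt(fit$p_value, 0.001)

  ident <- cox_hr(c(tm[1:100], tm[1:100]), rep(1, 200), grp)
  expect_equal(ident$hr, 1, tolerance = 1e-6)

  expect_error(cox_hr(tm, c(rep(1, 100), rep(0, 100)), grp), "no events")

  # consistency: log-HR bias shrinks with n on the exponential simulation
  bias_at <- function(n, seed) {
    with_seed(seed, {
      tt <- c(rexp(n / 2, 0.1), rexp(n / 2, 0.3))
    })
    abs(cox_hr(tt, rep(1, n), rep(c("a", "b"), each = n / 2))$log_hr - log(3))
  }
  biases <- vapply(c(50, 200, 800), function(n) {
    mean(vapply(1:8, function(s) bias_at(n, 1000 * n + s), numeric(1)))
  }, numeric(1))
  expect_true(biases[3] < biases[1])
})

test_that("median stratification assigns ties at the median to the low group", {
  st <- stratify_by_median(1:45)
  expect_length(st$low, 23L)
  expect_length(st$high, 22L)
  expect_equal(st$cutoff, 23)
  expect_true(all(1:23 %in% st$low))

  st2 <- stratify_by_median(c(4, 8, 1, 9, 3, 7))
  expect_length(st2$low, 3L)
  expect_length(st2$high, 3L)

  expect_error(stratify_by_median(rep(2, 10)), "degenerate")
})
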