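test_that("difference sign convention: d = full - subsample", {
  mk <- function(v) data.frame(plot_id = "P1", event_id = c("E1", "E2"),
                               indicator = "AH_TotalFoliarCover", value = v)
  d <- compute_differences(mk(c(50, 60)), mk(c(45, 62)))
  expect_equal(d$d, c(5, -2))
  # undefined cells excluded pairwise
  d2 <- compute_differences(mk(c(50, NA)), mk(c(45, 62)))
  expect_equal(nrow(d2), 1)
  expect_error(
    compute_differences(mk(c(1, 2)),
                        data.frame(plot_id = "P9", event_id = "E1",
                                   indicator = "AH_TotalFoliarCover", value = 1)),
    class = "transectopt_empty_input")
})

test_that("nested LoA matches the hand one-way ANOVA example", {
  d <- data.frame(plot_id = rep(c("A", "B", "C"), each = 2),
                  d = c(1, 3, -1, 1, 0, 2))
  f <- fit_nested_loa(d, level = 0.95)
  expect_equal(f$bias, 1.0, tolerance = 1e-12)
  expect_equal(f$sigma_e2, 2.0, tolerance = 1e-12)
  expect_equal(f$sigma_b2, 0.0, tolerance = 1e-12)
  expect_equal(f$agree_halfwidth, qnorm(0.975) * sqrt(2), tolerance = 1e-9)
  expect_equal(f$limit_hi, 1 + qnorm(0.975) * sqrt(2), tolerance = 1e-9)
  # invariant ordering
  expect_true(f$mover_lo <= f$limit_lo)
  expect_true(f$limit_lo <= f$bias)
  expect_true(f$bias <= f$limit_hi)
  expect_true(f$limit_hi <= f$mover_hi)
})

test_that("degenerate and error cases of the nested LoA", {
  d0 <- data.frame(plot_id = c("A", "A", "B"), d = rep(0, 3))
  f0 <- fit_nested_loa(d0, 0.95)
  expect_equal(f0$bias, 0)
  expect_equal(f0$agree_halfwidth, 0)
  expect_equal(c(f0$mover_lo, f0$mover_hi), c(0, 0))
  dc <- data.frame(plot_id = c("A", "A", "B"), d = rep(3.5, 3))
  fc <- fit_nested_loa(dc, 0.95)
  expect_equal(c(fc$mover_lo, fc$mover_hi), c(3.5, 3.5))
  expect_error(fit_nested_loa(data.frame(plot_id = "A", d = c(1, 2)), 0.95),
               class = "transectopt_insufficient_subjects")
})

test_that("LoA is shift- and scale-equivariant", {
  d <- simulate_differences(0.5, 1, 0.7, 8, 4:11, seed = 33)
  f <- fit_nested_loa(d, 0.95)
  dc <- d; dc$d <- d$d + 3
  fc <- fit_nested_loa(dc, 0.95)
  expect_equal(fc$bias, f$bias + 3)
  expect_equal(fc$limit_lo, f$limit_lo + 3)
  expect_equal(fc$limit_hi, f$limit_hi + 3)
  expect_equal(fc$mover_lo, f$mover_lo + 3)
  expect_equal(fc$mover_hi, f$mover_hi + 3)
  expect_equal(fc$agree_halfwidth, f$agree_halfwidth)
  ds <- d; ds$d <- d$d * 2.5
  fs <- fit_nested_loa(ds, 0.95)
  expect_equal(fs$bias, f$bias * 2.5)
  expect_equal(fs$agree_halfwidth, f$agree_halfwidth * 2.5)
  expect_equal(fs$mover_hi - fs$bias, (f$mover_hi - f$bias) * 2.5)
  expect_equal(fs$sigma_b2, f$sigma_b2 * 2.5^2)
  expect_equal(fs$sigma_e2, f$sigma_e2 * 2.5^2)
})

test_that("with one event per plot the fit reduces to classical Bland-Altman", {
  set.seed(5)
  d <- data.frame(plot_id = sprintf("P%02d", 1:20), d = rnorm(20, 1, 2))
  f <- fit_nested_loa(d, 0.95)
  expect_equal(f$bias, mean(d$d))
  expect_equal(f$sigma_e2, 0)
  expect_equal(f$sigma_b2, var(d$d))
  expect_equal(f$agree_halfwidth, qnorm(0.975) * sd(d$d))
  expect_equal(f$bias_hi, mean(d$d) + qt(0.975, 19) * sd(d$d) / sqrt(20))
})

test_that("nested bias CI stays near nominal where a pooled CI collapses", {
  k <- 13; nrep <- 500
  hit_nested <- hit_pooled <- logical(nrep)
  for (r in seq_len(nrep)) {
    d <- simulate_differences(0, sigma_b = 2, sigma_e = 0.5, k = k, n_i = 10,
                              seed = 40000 + r)
    f <- fit_nested_loa(d, 0.95)
    hit_nested[r] <- f$bias_lo <= 0 && f$bias_hi >= 0
    # deliberately wrong pooled analysis ignoring the plot nesting
    N <- nrow(d)
    se <- sd(d$d) / sqrt(N)
    ci <- mean(d$d) + c(-1, 1) * qt(0.975, N - 1) * se
    hit_pooled[r] <- ci[1] <= 0 && ci[2] >= 0
  }
  expect_gte(mean(hit_nested), 0.92)
  expect_lte(mean(hit_nested), 0.98)
  expect_lt(mean(hit_pooled), 0.75)   # anti-conservative under nesting
})

test_that("acceptable-difference criteria flag bias and interval width", {
  crit <- acceptance_criteria()
  mk <- function(bias, bias_lo, bias_hi, mover_lo, mover_hi) {
    structure(list(bias = bias, bias_lo = bias_lo, bias_hi = bias_hi,
                   mover_lo = mover_lo, mover_hi = mover_hi),
              class = "nested_loa")
  }
  f1 <- evaluate_criteria(mk(0.1, -0.5, 0.7, -2.9, 3.0), "AH_TotalFoliarCover", crit)
  expect_true(f1$unbiased); expect_true(f1$interval); expect_true(f1$pass)
  f2 <- evaluate_criteria(mk(0.8, 0.2, 1.4, -2, 2), "AH_TotalFoliarCover", crit)
  expect_false(f2$unbiased); expect_false(f2$pass)
  f3 <- evaluate_criteria(mk(0, -0.1, 0.1, -2.5, 2.5), "NumSpecies", crit)
  expect_false(f3$interval)          # 2.5 species bound vs 2-species criterion
  f4 <- evaluate_criteria(mk(0, -0.1, 0.1, -4.9, 4.9), "Hgt_Mean_cm", crit)
  expect_true(f4$pass)
  expect_error(evaluate_criteria(f1, "NotAnIndicator", crit),
               class = "transectopt_config_error")
})

test_that("normality diagnostics report, and never gate, the analysis", {
  # well-behaved normal differences rarely flagged
  p_ok <- vapply(1:500, function(s) {
    set.seed(s)
    d <- data.frame(indicator = "x", d = rnorm(100))
    check_difference_normality(d)$p_value
  }, numeric(1))
  expect_gte(mean(p_ok > 0.01), 0.98)
  # heavy tails strongly rejected
  p_t1 <- vapply(1:100, function(s) {
    set.seed(s)
    d <- data.frame(indicator = "x", d = rt(200, df = 1))
    check_difference_normality(d)$p_value
  }, numeric(1))
  expect_gte(mean(p_t1 < 0.05), 0.5)
  # constant differences are reported as undefined, not an error
  rep_const <- check_difference_normality(
    data.frame(indicator = "x", d = rep(1, 10)))
  expect_true(is.na(rep_const$p_value))
  expect_match(rep_const$note, "constant")
})
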