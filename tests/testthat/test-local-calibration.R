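test_that("pure-class windows give posterior 1 or 0", {
  d <- labeled_scores(c(1:10 / 100, 10 + 1:10 / 100), rep(c(0, 1), each = 10))
  cv <- local_posterior(d, grid = c(0.05, 10.05),
                        config = analysis_config(window_max_count = 5,
                                                 window_min_fraction = 0.1))
  expect_equal(cv$posterior_test, c(0, 1))
  expect_equal(cv$lr_plus[1], 0)
  expect_equal(cv$lr_plus[2], Inf)
})

test_that("no-signal scores give a flat posterior at the test prior", {
  set.seed(43)
  n <- 5000
  y <- rbinom(n, 1, 0.3)
  s <- rnorm(n) # independent of y
  cv <- local_posterior(labeled_scores(s, y), grid = "uniform",
                        grid_length = 50)
  # tail windows hold as few as 50 items (binomial SE ~ 0.065), so the
  # pointwise bound is loose over the full range and tight in the center
  expect_true(all(abs(cv$posterior_test - mean(y)) < 0.22))
  central <- cv$score >= quantile(s, 0.1) & cv$score <= quantile(s, 0.9)
  expect_lt(mean(abs(cv$posterior_test[central] - mean(y))), 0.03)
})

test_that("vectorized window estimator equals the literal one-point-at-a-time rule", {
  set.seed(47)
  for (i in 1:25) {
    n <- sample(12:300, 1)
    s <- round(rnorm(n), sample(1:3, 1)) # induce ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1L
    if (sum(y) == n) y[1] <- 0L
    d <- labeled_scores(s, y)
    grid <- sort(unique(s))
    cv <- local_posterior(d, grid = grid)
    expect_equal(cv$posterior_test,
                 oracle_local_posterior(s, y, grid),
                 tolerance = 1e-12)
  }
})

test_that("window count rule is enforced and windows adapt outward", {
  d <- generate_binary(binormal_spec(n = 200, seed = 51))
  cv <- local_posterior(d)
  k <- min(ceiling(0.10 * 200), 50)
  expect_true(all(cv$window_count >= k))
  expect_true(all(cv$window_halfwidth >= attr(cv, "epsilon")))
  tiny <- labeled_scores(1:8, rep(c(0, 1), 4))
  expect_error(local_posterior(tiny), "at least 10")
})

test_that("posterior-odds to lr+ conversion follows the prior-odds identity", {
  expect_equal(local_lr_plus(0.2, test_prior = 0.2), 1)
  expect_equal(local_lr_plus(0, test_prior = 0.3), 0)
  expect_equal(local_lr_plus(0.5, test_prior = 0.2), 4)
  v <- local_lr_plus(c(0.5, 1), test_prior = 0.5)
  expect_equal(v[2], Inf)
  expect_equal(attr(v, "infinite"), 2L)
  expect_error(local_lr_plus(0.5, test_prior = 1), "test_prior")
})

test_that("mean windowed posterior over items recovers the test prior", {
  d <- generate_binary(binormal_spec(n = 10000, seed = 53))
  cv <- local_posterior(d)
  post_at_items <- cv$posterior_test[match(d$score, cv$score)]
  expect_lt(abs(mean(post_at_items) - mean(d$label)), 0.02)
})

test_that("lr+ estimates are class-prior independent under negative subsampling", {
  d <- generate_binary(binormal_spec(n = 40000, seed = 59))
  grid <- seq(-0.5, 1.5, length.out = 9)
  cv_full <- local_posterior(d, grid = grid)
  set.seed(60)
  neg <- which(d$label == 0)
  keep <- setdiff(seq_len(nrow(d)), sample(neg, length(neg) %/% 2))
  sub <- labeled_scores(d$score[keep], d$label[keep])
  cv_sub <- local_posterior(sub, grid = grid)
  # posteriors shift with the prior, lr+ does not (up to MC error)
  expect_gt(mean(cv_sub$posterior_test), mean(cv_full$posterior_test) + 0.05)
  expect_equal(log(cv_sub$lr_plus), log(cv_full$lr_plus), tolerance = 0.15)
})

test_that("log lr+ is linear in score for equal-sigma binormal data", {
  d <- generate_binary(binormal_spec(mu1 = 1.5, n = 50000, seed = 61))
  qs <- quantile(d$score, c(0.05, 0.95))
  grid <- seq(qs[1], qs[2], length.out = 40)
  cv <- local_posterior(d, grid = grid)
  slope <- coef(lm(log(cv$lr_plus) ~ cv$score))[2]
  expect_equal(unname(slope), 1.5, tolerance = 0.15) # truth dmu/sigma^2
})

test_that("smoothing: none is identity, isotonic fixes order and helps accuracy", {
  d <- generate_binary(binormal_spec(n = 3000, seed = 67))
  cv <- local_posterior(d, grid = "uniform", grid_length = 80)
  expect_identical(smooth_curve(cv, "none"), cv)

  iso <- smooth_curve(cv, "isotonic")
  expect_true(all(diff(iso$posterior_test) >= -1e-12))
  expect_s3_class(attr(iso, "raw"), "local_calibration_curve")
  # an already-monotone curve is unchanged
  iso2 <- smooth_curve(iso, "isotonic")
  expect_equal(iso2$posterior_test, iso$posterior_test, tolerance = 1e-12)
  # projection onto the monotone cone cannot move away from the (monotone)
  # analytic posterior in L2
  truth <- attr(d, "truth")$posterior_fun(cv$score, mean(d$label))
  expect_lte(mean((iso$posterior_test - truth)^2),
             mean((cv$posterior_test - truth)^2) + 1e-12)

  ma <- smooth_curve(cv, "moving_average", window = 5)
  expect_equal(length(ma$posterior_test), nrow(cv))
  expect_equal(ma$posterior_test[3], mean(cv$posterior_test[1:5]))
})

test_that("bootstrap lower-bound curve is conservative and tightens thresholds", {
  d <- generate_binary(binormal_spec(mu1 = 2, n = 1500, seed = 97))
  cfg <- analysis_config()
  grid <- seq(quantile(d$score, 0.05), quantile(d$score, 0.95),
              length.out = 40)
  point <- local_posterior(d, grid = grid, config = cfg)
  low <- curve_lower_bound(d, grid = grid, config = cfg,
                           iterations = 60, seed = 7)
  expect_true(all(low$posterior_test <= point$posterior_test + 1e-12))
  model <- evidence_model(c = 351, prior = 0.1)
  thr_point <- evidence_thresholds(point, model)
  thr_low <- evidence_thresholds(low, model)
  for (lev in names(thr_point)) {
    if (!is.na(thr_point[[lev]]) && !is.na(thr_low[[lev]])) {
      expect_gte(thr_low[[lev]], thr_point[[lev]])
    } else if (!is.na(thr_low[[lev]])) {
      fail("lower-bound curve reached a level the point curve did not")
    }
  }
  low2 <- curve_lower_bound(d, grid = grid, config = cfg,
                            iterations = 60, seed = 7)
  expect_identical(low2$lr_plus, low$lr_plus)
})
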