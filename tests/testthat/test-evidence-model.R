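test_that("level requirements are the 1/8, 1/4, 1/2, 1 powers of c", {
  req <- level_requirements(350)
  expect_equal(unname(req),
               c(350^(1 / 8), 350^(1 / 4), 350^(1 / 2), 350))
  expect_equal(round(req[["supporting"]], 2), 2.08)
  expect_equal(round(req[["strong"]], 1), 18.7)
  expect_true(all(diff(req) > 0))
  # independent exp/log evaluation
  expect_equal(level_requirements(8511)[["supporting"]],
               exp(log(8511) / 8), tolerance = 1e-12)
  expect_equal(round(level_requirements(8511)[["supporting"]], 2), 3.1)
  expect_error(level_requirements(1), "greater than 1")
  expect_error(level_requirements(0.5), "greater than 1")
})

test_that("evidence combination is exponent-additive", {
  expect_equal(combine_evidence(evidence_counts(n_su = 8), 350), 350)
  expect_equal(combine_evidence(evidence_counts(n_st = 1, n_vs = 1), 350),
               350^1.5)
  expect_equal(combine_evidence(evidence_counts(n_su = 2, n_st = 1), 350),
               350^(3 / 4), tolerance = 1e-12)
  expect_equal(round(combine_evidence(evidence_counts(n_su = 2, n_st = 1), 350)),
               81)
  set.seed(71)
  for (i in 1:20) {
    a <- sample(0:3, 4, replace = TRUE)
    b <- sample(0:3, 4, replace = TRUE)
    ca <- do.call(evidence_counts, as.list(setNames(a, c("n_su", "n_mo", "n_st", "n_vs"))))
    cb <- do.call(evidence_counts, as.list(setNames(b, c("n_su", "n_mo", "n_st", "n_vs"))))
    cab <- do.call(evidence_counts, as.list(setNames(a + b, c("n_su", "n_mo", "n_st", "n_vs"))))
    expect_equal(combine_evidence(ca, 123) * combine_evidence(cb, 123),
                 combine_evidence(cab, 123), tolerance = 1e-9)
  }
  expect_error(evidence_counts(n_su = -1), "non-negative")
})

test_that("odds-form posterior behaves and inverts exactly", {
  expect_equal(posterior_from_lr(1, 0.37), 0.37)
  expect_equal(round(posterior_from_lr(6, 0.21), 1), 0.6)
  expect_equal(round(posterior_from_lr(15, 0.25), 1), 0.8)
  expect_equal(posterior_from_lr(Inf, 0.1), 1)
  expect_equal(posterior_from_lr(0, 0.9), 0)
  lr_grid <- 10^seq(-3, 6, length.out = 40)
  for (a in c(0.01, 0.1, 0.5)) {
    p <- posterior_from_lr(lr_grid, a)
    expect_true(all(diff(p) > 0)) # strictly increasing in lr
    expect_equal(lr_from_posterior(p, a), lr_grid, tolerance = 1e-10)
  }
})

test_that("evidence thresholds honor the for-all quantifier over the upper tail", {
  model <- evidence_model(c = 350, prior = 0.1)
  req <- model$requirements
  make_curve <- function(score, lr) {
    structure(
      data.frame(score = score, posterior_test = posterior_from_lr(lr, 0.5),
                 lr_plus = lr, window_halfwidth = 0.1,
                 window_count = 50),
      class = c("local_calibration_curve", "data.frame"),
      alpha_test = 0.5, epsilon = 0.1, flipped = FALSE)
  }
  # constant curve just above the Strong requirement
  flat <- make_curve(1:5, rep(req[["strong"]] + 0.1, 5))
  thr <- evidence_thresholds(flat, model)
  expect_equal(unname(thr[c("supporting", "moderate", "strong")]),
               c(1, 1, 1))
  expect_true(is.na(thr[["very_strong"]]))

  # never reaches Supporting
  low <- make_curve(1:5, rep(req[["supporting"]] - 0.5, 5))
  expect_true(all(is.na(evidence_thresholds(low, model))))

  # sawtooth with an interior dip below the Supporting requirement
  score <- seq(0, 1, length.out = 20)
  lr <- rep(req[["supporting"]] + 1, 20)
  lr[12] <- req[["supporting"]] - 0.5
  saw <- make_curve(score, lr)
  thr_saw <- evidence_thresholds(saw, model)
  # exhaustive scan oracle: smallest tau with all suffix values >= requirement
  ok <- vapply(seq_along(score), function(i) all(lr[i:20] >= req[["supporting"]]), TRUE)
  expect_equal(thr_saw[["supporting"]], score[which(ok)[1]])
  expect_gt(thr_saw[["supporting"]], score[12]) # strictly above the dip
})

test_that("thresholds are monotone across levels for random curves", {
  model <- evidence_model(c = 350, prior = 0.1)
  set.seed(73)
  for (i in 1:50) {
    m <- sample(5:40, 1)
    lr <- exp(rnorm(m, mean = rnorm(1, 1, 2), sd = 2))
    curve <- structure(
      data.frame(score = sort(runif(m)), posterior_test = posterior_from_lr(lr, 0.5),
                 lr_plus = lr, window_halfwidth = 0.1, window_count = 50),
      class = c("local_calibration_curve", "data.frame"),
      alpha_test = 0.5, epsilon = 0.1, flipped = FALSE)
    thr <- evidence_thresholds(curve, model)
    present <- !is.na(thr)
    expect_true(all(diff(thr[present]) >= 0))
    # a reached higher level implies all lower levels reached at or below
    if (present[["very_strong"]]) expect_true(all(present))
  }
})

test_that("fraction reaching each level applies the prior-corrected PPP", {
  d <- labeled_scores(c(0.9, 0.8, 0.4, 0.3, 0.2, 0.1),
                      c(1, 1, 1, 0, 0, 0))
  thr <- c(supporting = 0.05, moderate = NA, strong = NA, very_strong = NA)
  ppp <- fraction_reaching(d, thr, 0.3)
  expect_equal(unname(ppp[["supporting"]]), 1) # tau below all scores
  expect_equal(unname(ppp[["moderate"]]), 0)   # absent level

  # TPR = FPR collapses PPP to that common rate for every alpha
  balanced <- labeled_scores(c(3, 1, 3, 1), c(1, 1, 0, 0))
  for (a in c(0.1, 0.5, 0.9)) {
    expect_equal(unname(fraction_reaching(balanced, c(x = 2), a)[["x"]]), 0.5)
  }

  # direct substitution: alpha*TPR + (1-alpha)*FPR
  m <- threshold_metrics(d, 0.35)
  expect_equal(unname(fraction_reaching(d, c(x = 0.35), 0.1)[["x"]]),
               0.1 * m$tpr + 0.9 * m$fpr, tolerance = 1e-12)
  expect_equal(0.1 * 0.6 + 0.9 * 0.1, 0.15) # the worked example
})

test_that("solve_c matches the closed-form inversion and is monotone in the prior", {
  rule8su <- list(list(counts = evidence_counts(n_su = 8), class = "pathogenic"))
  got <- solve_c(0.5, rule8su)
  expect_equal(got$c, 99)
  expect_equal(got$c_exact, 99, tolerance = 1e-4)

  # degenerate targets: any evidence suffices, c collapses to just above 1
  expect_lt(solve_c(0.3, rule8su,
                    targets = c(pathogenic = 0.3, likely_pathogenic = 0.3))$c_exact,
            1.001)

  # closed form: c = max over rules of L^(1/exponent), L = target/prior odds ratio
  set.seed(79)
  for (i in 1:10) {
    prior <- runif(1, 0.05, 0.5)
    rules <- lapply(1:3, function(j) {
      list(counts = evidence_counts(n_su = sample(0:4, 1), n_mo = sample(0:2, 1),
                                    n_st = sample(0:2, 1), n_vs = sample(0:1, 1)),
           class = sample(c("pathogenic", "likely_pathogenic"), 1))
    })
    rules <- Filter(function(r) combine_evidence(r$counts, 2) > 1, rules)
    if (!length(rules)) next
    targets <- c(pathogenic = 0.99, likely_pathogenic = 0.90)
    cf <- max(vapply(rules, function(r) {
      ex <- r$counts$n_su / 8 + r$counts$n_mo / 4 + r$counts$n_st / 2 + r$counts$n_vs
      L <- (targets[[r$class]] / (1 - targets[[r$class]])) * ((1 - prior) / prior)
      max(L, 1)^(1 / ex)
    }, 0))
    got <- solve_c(prior, rules)
    expect_equal(got$c_exact, max(cf, 1 + 1e-9), tolerance = 1e-4)
  }

  # smaller prior requires larger c
  cs <- vapply(c(0.01, 0.05, 0.1, 0.25), function(a) solve_c(a, rule8su)$c_exact, 0)
  expect_true(all(diff(cs) < 0))
  expect_error(solve_c(0.5, list()), "non-empty")
})

test_that("benign-direction thresholds mirror the pathogenic construction", {
  model <- evidence_model(c = 350, prior = 0.1)
  lr <- c(0.001, 0.01, 0.05, 0.3, 1, 5, 40, 400) # increasing in score
  score <- 1:8
  curve <- structure(
    data.frame(score = score, posterior_test = posterior_from_lr(lr, 0.5),
               lr_plus = lr, window_halfwidth = 0.5, window_count = 50),
    class = c("local_calibration_curve", "data.frame"),
    alpha_test = 0.5, epsilon = 0.5, flipped = FALSE)
  thr_b <- evidence_thresholds(curve, model, direction = "benign")
  req <- 1 / model$requirements
  # exhaustive scan: largest tau with all prefix values <= 1/requirement
  for (lev in names(req)) {
    ok <- vapply(seq_along(score), function(i) all(lr[1:i] <= req[[lev]]), TRUE)
    expected <- if (any(ok)) score[max(which(ok))] else NA_real_
    expect_equal(unname(thr_b[[lev]]), expected)
  }
  # benign thresholds decrease with level strength
  present <- !is.na(thr_b)
  expect_true(all(diff(thr_b[present]) <= 0))
})
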