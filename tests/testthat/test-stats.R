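test_that("the linear fit is exact on noiseless lines and validates input", {
  p <- c(77.2, 103.9, 130.7, 157.4)
  fit <- fit_linear(p, 0.05 * p + 8)
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, 8, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)
  expect_identical(fit$df, 2L)
  expect_error(fit_linear(p[1:2], c(1, 2)), "at least 3")
  expect_error(fit_linear(rep(100, 5), rnorm(5)), "rank-deficient")
})

test_that("the linear fit matches the normal-equations oracle", {
  # independent closed forms: slope = Sxy/Sxx etc.
  set.seed(77)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    x <- runif(n, 0, 100)
    y <- runif(1, -5, 5) + runif(1, -0.1, 0.1) * x + rnorm(n)
    fit <- fit_linear(x, y)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    rss <- sum((y - intercept - slope * x)^2)
    s2 <- rss / (n - 2)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, intercept, tolerance = 1e-10)
    expect_equal(fit$rss, rss, tolerance = 1e-10)
    expect_equal(fit$slope_se, sqrt(s2 / sxx), tolerance = 1e-10)
    expect_equal(fit$intercept_se,
                 sqrt(s2 * (1 / n + mean(x)^2 / sxx)), tolerance = 1e-10)
  }
})

test_that("the exponential fit recovers exact and degenerate curves", {
  p <- seq(70, 160, length.out = 12)
  fit <- fit_exponential(p, 0.1 * exp(0.012 * p))
  expect_true(fit$converged)
  expect_equal(fit$a, 0.1, tolerance = 1e-6)
  expect_equal(fit$b, 0.012, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # flat data degenerates to a = mean, b ~ 0
  flat <- fit_exponential(p, rep(2.5, 12))
  expect_equal(flat$a, 2.5, tolerance = 1e-6)
  expect_equal(flat$b, 0, tolerance = 1e-8)
  expect_error(fit_exponential(p, c(-1, rep(1, 11))), "positive")
  expect_error(fit_exponential(p[1:2], c(1, 2)), "at least 3")
})

test_that("identical inputs compare as identical", {
  p <- rep(c(77.2, 103.9, 130.7, 157.4), each = 4)
  set.seed(5)
  y <- 8 + 0.05 * p + rnorm(16, sd = 0.2)
  res <- compare_lines(fit_linear(p, y), fit_linear(p, y))
  expect_identical(res$test, c("slopes", "elevations"))
  expect_true(all(res$F < 1e-10))
  expect_true(all(res$p_value > 0.999))
  E <- 0.117 * exp(0.0122 * p) * exp(rnorm(16, sd = 0.05))
  fe <- fit_exponential(p, E)
  resc <- compare_curves(fe, fe)
  expect_lt(resc$F, 1e-6)
  expect_gt(resc$p_value, 0.999)
})

test_that("the curve comparison respects nested-model structure", {
  set.seed(31)
  p <- rep(c(77.2, 103.9, 130.7, 157.4), each = 4)
  for (i in 1:20) {
    a <- runif(1, 0.05, 0.3); b <- runif(1, 0.005, 0.02)
    EA <- a * exp(b * p) * exp(rnorm(16, sd = 0.1))
    EB <- a * exp(b * p) * exp(rnorm(16, sd = 0.1))
    fa <- fit_exponential(p, EA); fb <- fit_exponential(p, EB)
    dat <- c(EA, EB)
    shared <- fit_exponential(c(p, p), dat)
    expect_gte(shared$rss + 1e-12, fa$rss + fb$rss)
    expect_gte(compare_curves(fa, fb)$F, 0)
  }
})

test_that("strong differences are detected, near-null data are not flagged", {
  p <- rep(c(77.2, 103.9, 130.7, 157.4), each = 4)
  set.seed(12)
  yA <- 8 + 0.05 * p + rnorm(16, sd = 0.1)
  yB <- 9.5 + 0.05 * p + rnorm(16, sd = 0.1) # large elevation shift
  res <- compare_lines(fit_linear(p, yA), fit_linear(p, yB))
  expect_false(res$significant[res$test == "slopes"])
  expect_true(res$significant[res$test == "elevations"])
  yC <- 4 + 0.10 * p + rnorm(16, sd = 0.1)   # slope difference
  res2 <- compare_lines(fit_linear(p, yA), fit_linear(p, yC))
  expect_true(res2$significant[res2$test == "slopes"])
  expect_false("elevations" %in% res2$test)
  EA <- 0.117 * exp(0.0122 * p) * exp(rnorm(16, sd = 0.05))
  EB <- 0.117 * exp(0.0366 * p) * exp(rnorm(16, sd = 0.05)) # 3x rate
  resc <- compare_curves(fit_exponential(p, EA), fit_exponential(p, EB))
  expect_true(resc$significant)
})

test_that("the slope test holds its size in a quick null simulation", {
  p <- rep(c(77.2, 103.9, 130.7, 157.4), each = 4)
  set.seed(2718)
  rej <- replicate(300, {
    yA <- 8 + 0.05 * p + rnorm(16, sd = 0.2)
    yB <- 8 + 0.05 * p + rnorm(16, sd = 0.2)
    r <- compare_lines(fit_linear(p, yA), fit_linear(p, yB))
    r$significant[r$test == "slopes"]
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("run_comparisons maps the study design onto the planned contrasts", {
  cfg <- study_config(n_sham = 2, n_pin = 2,
                      stages = c("control", "Fe-9", "Fe-8"), seed = 14)
  pts <- generate_study(cfg)$points
  rep <- run_comparisons(pts)
  # 3 between-group + 2 x 2 within-group contrasts, each tested for f0 and E'
  expect_identical(length(unique(rep$results$contrast)), 7L)
  expect_setequal(unique(rep$results$response), c("f0", "Eprime"))
  expect_identical(nrow(rep$skipped), 0L)
  expect_true(all(rep$results$p_value >= 0 & rep$results$p_value <= 1))
  # elevation rows only appear when the slope test is not significant
  for (ct in unique(rep$results$contrast)) {
    rows <- rep$results[rep$results$contrast == ct &
                          rep$results$response == "f0", ]
    if ("elevations" %in% rows$test)
      expect_false(rows$significant[rows$test == "slopes"])
  }
})

test_that("run_comparisons skips honestly and supports Holm adjustment", {
  cfg <- study_config(n_sham = 2, n_pin = 2, stages = c("control", "Fe-9"),
                      seed = 9)
  pts <- generate_study(cfg)$points
  # starve one cell below the minimum size
  pts2 <- pts[!(pts$group == "pin" & pts$stage == "Fe-9" &
                  pts$mass_index > 1), ]
  rep2 <- run_comparisons(pts2)
  expect_gt(nrow(rep2$skipped), 0)
  expect_match(rep2$skipped$reason[1], "usable points")
  # Holm can only reduce the number of significant results
  rep_raw <- run_comparisons(pts)
  rep_holm <- run_comparisons(pts, adjust = "holm")
  expect_lte(sum(rep_holm$results$significant),
             sum(rep_raw$results$significant))
})
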