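test_that("the univariate fit recovers exact lines and OLS identities", {
  x <- c(1, 2, 3, 4, 5)
  f <- suppressWarnings(fit_linear(x, 2 * x + 1))  # lm flags the perfect fit
  expect_equal(f$c0, 1)
  expect_equal(f$c1, 2)

  # mean-centred antisymmetric data: intercept is the activity mean
  y <- c(-2, -1, 0, 1, 2) + 5
  f2 <- suppressWarnings(fit_linear(c(-1, -0.5, 0, 0.5, 1), y))
  expect_equal(f2$c0, mean(y))

  expect_error(fit_linear(rep(1, 5), x), "zero descriptor variance")

  set.seed(31)
  x <- stats::rnorm(40); y <- 0.5 * x + stats::rnorm(40)
  f3 <- fit_linear(x, y)
  pred <- predict_activity(f3, x)
  # training determination equals squared Pearson correlation for OLS
  r2_det <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(r2_det, stats::cor(x, y)^2)
  # residuals orthogonal to the descriptor
  expect_equal(sum((y - pred) * x), 0, tolerance = 1e-9)
})

test_that("published model coefficients reproduce the printed predictions", {
  # split-model coefficient pairs and the descriptor of compound 1
  expect_equal(predict_activity(list(c0 = -3.1689, c1 = 0.0272), 246.56),
               3.53, tolerance = 0.005)
  expect_equal(predict_activity(list(c0 = -9.6171, c1 = 0.0758), 179.87),
               4.02, tolerance = 0.005)
  expect_equal(predict_activity(list(c0 = -7.0645, c1 = 0.0482), 222.70),
               3.67, tolerance = 0.005)
  # compound 60, split 3
  expect_equal(predict_activity(list(c0 = -7.0645, c1 = 0.0482), 271.04),
               6.00, tolerance = 0.005)
  # degenerate slope gives the constant model
  expect_equal(predict_activity(list(c0 = 4.2, c1 = 0), c(1, 100)), c(4.2, 4.2))
})

test_that("perfect predictions score perfectly across the battery", {
  y <- c(3.5, 4.1, 4.8, 5.2, 5.9)
  m <- set_metrics(y, y, train_mean = mean(y))
  expect_equal(m$r2, 1)
  expect_equal(m$r2_det, 1)
  expect_equal(m$ccc, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$s, 0)
  expect_equal(loo_q2(y * 2 + 1, y), 1)
  rm2 <- rm2_metrics(y, y)
  expect_equal(rm2$mean, 1)
  expect_equal(rm2$delta, 0)
})

test_that("concordance penalizes scale and location shifts", {
  set.seed(41)
  x <- stats::rnorm(30)
  expect_lt(ccc(x, x + 1), 1)
  expect_lt(ccc(x, 2 * x), 1)
  for (i in 1:20) {
    y <- stats::rnorm(30)
    expect_lte(ccc(x, y), abs(stats::cor(x, y)) + 1e-12)
  }
})

test_that("metrics are equivariant under joint permutation of the pairs", {
  set.seed(43)
  obs <- stats::rnorm(15, 5); prd <- obs + stats::rnorm(15, 0, 0.3)
  m1 <- set_metrics(obs, prd, train_mean = 5)
  p <- sample(15)
  m2 <- set_metrics(obs[p], prd[p], train_mean = 5)
  expect_equal(m1, m2)
})

test_that("fischer ratio follows from the training determination", {
  # n = 30, R^2 = 0.782 corresponds to F of about 100
  expect_equal(0.782 * 28 / (1 - 0.782), 100.4, tolerance = 0.05)
  set.seed(47)
  x <- stats::rnorm(30); y <- x + stats::rnorm(30)
  f <- fit_linear(x, y)
  r2 <- stats::cor(x, y)^2
  expect_equal(r2 * 28 / (1 - r2),
               unname(summary(f$lm)$fstatistic["value"]))
})

test_that("leave-one-out Q2 matches explicit refitting", {
  set.seed(53)
  x <- stats::rnorm(20); y <- 0.8 * x + stats::rnorm(20, 0, 0.4)
  press <- sum(vapply(seq_along(y), function(i) {
    f <- stats::lm(y[-i] ~ x[-i])
    (y[i] - (coef(f)[1] + coef(f)[2] * x[i]))^2
  }, numeric(1)))
  expect_equal(loo_q2(x, y), 1 - press / sum((y - mean(y))^2))
})

test_that("rm2 equals one for exactly proportional predictions", {
  obs <- c(1, 2, 3, 4, 5)
  rm2 <- rm2_metrics(obs, 1.7 * obs)
  expect_equal(rm2$rm2, 1)
  expect_equal(rm2$rm2_prime, 1)
  set.seed(59)
  for (i in 1:20) {
    o <- stats::rnorm(12, 5); p <- o + stats::rnorm(12, 0, 0.5)
    r <- rm2_metrics(o, p)
    expect_gte(r$delta, 0)
    expect_lte(r$rm2, 1)
    expect_lte(r$rm2_prime, 1)
  }
})

test_that("transcribed split-3 validation predictions match printed statistics", {
  ds <- flavonol_pic50()
  ref <- attr(ds, "reference")
  val <- ds$compounds$split3 == "VAL"
  obs <- ds$compounds$pic50[val]
  prd <- ref$pred3[match(ds$compounds$id[val], ref$id)]
  m <- set_metrics(obs, prd)
  expect_equal(m$n, 20)
  expect_equal(m$mae, 0.209, tolerance = 0.005 / 0.209)
  expect_equal(m$r2, 0.727, tolerance = 0.01 / 0.727)
  expect_equal(m$ccc, 0.847, tolerance = 0.01)
  rm2 <- rm2_metrics(obs, prd)
  # printed mean rm2 0.615; convention-sensitive, soft agreement
  expect_equal(rm2$mean, 0.615, tolerance = 0.1)
})

test_that("y-scrambling separates real signal from permutation noise", {
  ds <- generate_library(n = 40, seed = 14, noise_sigma = 0.1)
  fit <- mc_optimize(ds, ds$splits[1], epochs = 8, seed = 3)
  ys <- y_scramble(fit, ds, n_iter = 10, seed = 1)
  expect_lt(ys$mean_rr2, ys$r2)
  expect_gt(ys$crp2, 0.5)
  # forced identity permutation: scrambled R2 equals the reference, cRp2 = 0
  n_trn <- length(fit$state$y_trn)
  ys_id <- y_scramble(fit, ds, permutations = list(seq_len(n_trn)))
  expect_equal(ys_id$mean_rr2, ys_id$r2)
  expect_equal(ys_id$crp2, 0)
})

test_that("model selection maximizes validation mean rm2 with R2 tie-break", {
  mk <- function(rm2, r2) {
    data.frame(set = c("TRN", "VAL"), r2 = c(0.9, r2),
               rm2_mean = c(NA, rm2))
  }
  reports <- list(mk(0.555, 0.679), mk(0.613, 0.775), mk(0.615, 0.727))
  expect_equal(select_best_model(reports), 3)
  expect_equal(select_best_model(reports[2]), 1)
  tied <- list(mk(0.6, 0.70), mk(0.6, 0.75))
  expect_equal(select_best_model(tied), 2)
})
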