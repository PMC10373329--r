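# a tiny library whose activity is exactly proportional to one attribute
# count; the optimum TF1 = 2 (perfect correlations) is reachable
single_signal_dataset <- function(n = 28, seed = 4) {
  generate_library(n = n, seed = seed, noise_sigma = 0,
                   planted_weights = c("SK:N" = 0.5), intercept = 4)
}

test_that("IIC scales the calibration correlation by the MAE ratio", {
  expect_equal(iic(c(0.1, 0.1, -0.2), 0.9), 0.45)
  expect_equal(iic(c(-0.3, 0.3), 0.8), 0.8)            # symmetric sides
  expect_equal(iic(c(0.1, 0.2, 0.3), 0.9), 0)           # no negative side
  expect_equal(iic(c(-0.1, -0.2), 0.9), 0)              # no positive side
  expect_equal(iic(c(0, 0, 0), 1), 0)                   # zero residuals: all "positive"
})

test_that("IIC magnitude is bounded by the correlation, equality iff symmetric", {
  set.seed(21)
  for (i in 1:200) {
    res <- stats::rnorm(sample(4:12, 1))
    r <- stats::runif(1, -1, 1)
    v <- iic(res, r)
    expect_lte(abs(v), abs(r) + 1e-12)
    neg <- res[res < 0]; pos <- res[res >= 0]
    if (length(neg) && length(pos) &&
        abs(mean(abs(neg)) - mean(pos)) < 1e-12) {
      expect_equal(abs(v), abs(r))
    }
  }
})

test_that("target function implements the balance of correlation", {
  expect_equal(tf_value(0.9, 0.7, const = 0.1), 1.58)
  expect_equal(tf_value(0.8, 0.8, const = 0.7), 1.6)    # equal correlations: 2r
  expect_equal(tf_value(0.9, 0.7, iic_cal = 0.5, const = 0.1, w_iic = 0),
               tf_value(0.9, 0.7, const = 0.1))         # w_iic = 0 disables IIC
  expect_equal(tf_value(0.9, 0.7, iic_cal = 0.5, const = 0.1, w_iic = 0.2),
               1.58 + 0.1)
})

test_that("an epoch with zero perturbation leaves the state unchanged", {
  ds <- single_signal_dataset()
  st <- mc_state_init(ds, ds$splits[1], seed = 1, perturb = 0)
  st2 <- run_epoch(st)
  expect_identical(st2$cw$weights, st$cw$weights)
  expect_equal(st2$eval$tf, st$eval$tf)
})

test_that("trajectories are deterministic given the seed", {
  ds <- single_signal_dataset()
  X <- profile_matrix(ds)
  f1 <- mc_optimize(ds, ds$splits[1], epochs = 3, seed = 7, X = X)
  f2 <- mc_optimize(ds, ds$splits[1], epochs = 3, seed = 7, X = X)
  expect_identical(f1$cw$weights, f2$cw$weights)
  expect_identical(f1$journal, f2$journal)
  f3 <- mc_optimize(ds, ds$splits[1], epochs = 3, seed = 8, X = X)
  expect_false(identical(f1$cw$weights, f3$cw$weights))
})

test_that("the target function never decreases across accepted steps", {
  ds <- generate_library(n = 30, seed = 6, noise_sigma = 0.2)
  fit <- mc_optimize(ds, ds$splits[1], epochs = 6, seed = 2)
  expect_true(all(diff(fit$journal$tf) >= 0))
})

test_that("a pure single-attribute signal is fit to perfect correlation", {
  ds <- single_signal_dataset(n = 32)
  fit <- mc_optimize(ds, ds$splits[1], epochs = 12, tf = "tf1", seed = 3)
  expect_gt(fit$journal$tf[nrow(fit$journal)], 1.95)  # optimum is 2.0
  expect_gt(fit$metrics[fit$metrics$set == "TRN", "r2"], 0.95)
})

test_that("TF2 with zero IIC weight reproduces the TF1 trajectory exactly", {
  ds <- generate_library(n = 24, seed = 9, noise_sigma = 0.1)
  X <- profile_matrix(ds)
  f_tf1 <- mc_optimize(ds, ds$splits[1], epochs = 3, tf = "tf1", seed = 5, X = X)
  f_tf2 <- mc_optimize(ds, ds$splits[1], epochs = 3, tf = "tf2", w_iic = 0,
                       seed = 5, X = X)
  expect_identical(f_tf1$cw$weights, f_tf2$cw$weights)
  expect_equal(f_tf1$journal$tf, f_tf2$journal$tf)
})

test_that("grid search trains every cell and returns the argmax", {
  ds <- generate_library(n = 24, seed = 10, noise_sigma = 0.1)
  X <- profile_matrix(ds)
  gs <- grid_search(ds, ds$splits[1], T_grid = 1:2, N_grid = 1:2,
                    tf = "tf2", seed = 4, X = X)
  expect_equal(dim(gs$scores), c(2, 2))
  expect_false(anyNA(gs$scores))
  best <- which(gs$scores == max(gs$scores), arr.ind = TRUE)
  expect_true(any(best[, 1] == match(gs$threshold, 1:2) &
                  best[, 2] == match(gs$epochs, 1:2)))
  # winning fit is reproducible from its (T, N, seed)
  refit <- mc_optimize(ds, ds$splits[1], threshold = gs$threshold,
                       epochs = gs$epochs, tf = "tf2", seed = 4, X = X)
  expect_identical(refit$cw$weights, gs$fit$cw$weights)

  single <- grid_search(ds, ds$splits[1], T_grid = 2, N_grid = 3, seed = 4, X = X)
  expect_equal(single$threshold, 2)
  expect_equal(single$epochs, 3)
})

test_that("replicate runs use distinct seeds and persist their tables", {
  ds <- single_signal_dataset()
  fits <- mc_replicates(ds, ds$splits[1], seeds = c(11, 12, 13), epochs = 2)
  expect_length(fits, 3)
  expect_equal(vapply(fits, function(f) f$cw$seed, integer(1)), c(11L, 12L, 13L))
  expect_false(identical(fits[[1]]$cw$weights, fits[[2]]$cw$weights))
})

test_that("degenerate descriptor variance on the training set is an error", {
  df <- data.frame(id = c("a", "b", "c", "d", "e", "f"),
                   smiles = rep("CCO", 6), pic50 = c(4, 5, 4, 5, 4, 5),
                   split1 = c("TRN", "TRN", "iTRN", "iTRN", "CAL", "VAL"),
                   stringsAsFactors = FALSE)
  ds <- mcqsar:::new_qsar_dataset(df, "split1")
  expect_error(mc_optimize(ds, "split1", epochs = 1, seed = 1), "degenerate")
})
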