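# Monte Carlo hill climbing of correlation weights.
#
# Target functions (R = Pearson correlation of observed vs predicted):
#   TF1 = R_TRN + R_iTRN - |R_TRN - R_iTRN| * Const
#   TF2 = TF1 + w_IIC * IIC_CAL
# One epoch visits every unblocked key once in seeded-shuffled order,
# perturbs its weight by a uniform draw in +/- `perturb`, refits the
# univariate regression on the training set, and keeps the perturbation iff
# the target function strictly increases.

#' Index of ideality of correlation
#'
#' Calibration-set correlation scaled by the ratio of the two signed mean
#' absolute errors: residuals are split by sign, each side's MAE is the mean
#' |residual| over that side (a nonnegative magnitude), and
#' `IIC = r_cal * min(maeNeg, maePos) / max(maeNeg, maePos)`. If either side
#' is empty the IIC is 0 by convention.
#'
#' @param residuals Observed minus calculated activities.
#' @param r_cal Pearson correlation of observed vs calculated on the same set.
#' @return The IIC value.
#' @export
iic <- function(residuals, r_cal) {
  stopifnot(length(residuals) > 0)
  neg <- residuals[residuals < 0]
  pos <- residuals[residuals >= 0]
  if (!length(neg) || !length(pos)) return(0)
  mae_neg <- mean(abs(neg))
  mae_pos <- mean(pos)
  if (max(mae_neg, mae_pos) == 0) return(r_cal)  # perfect fit: ratio -> 1
  r_cal * min(mae_neg, mae_pos) / max(mae_neg, mae_pos)
}

#' Balance-of-correlation target function
#'
#' @param r_trn,r_itrn Correlations on the training and invisible training sets.
#' @param iic_cal IIC on the calibration set (ignored when `w_iic = 0`).
#' @param const Empirical constant of the balance term.
#' @param w_iic Weight of the IIC term; 0 gives TF1, a positive value TF2.
#' @return The target-function value.
#' @export
tf_value <- function(r_trn, r_itrn, iic_cal = 0, const = 0.1, w_iic = 0) {
  r_trn + r_itrn - abs(r_trn - r_itrn) * const + w_iic * iic_cal
}

# closed-form univariate OLS; returns c0, c1
ols_fit <- function(x, y) {
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= 0) return(NULL)
  c1 <- stats::cov(x, y) / vx
  list(c0 = mean(y) - c1 * mean(x), c1 = c1)
}

# Evaluate the optimizer state for a given DCW vector.
# Predictions on every set use the training-set regression.
mc_evaluate <- function(dcw, st) {
  fit <- ols_fit(dcw[st$idx_trn], st$y_trn)
  if (is.null(fit)) return(NULL)
  pred <- fit$c0 + fit$c1 * dcw
  r_trn <- suppressWarnings(stats::cor(st$y_trn, pred[st$idx_trn]))
  r_itrn <- suppressWarnings(stats::cor(st$y_itrn, pred[st$idx_itrn]))
  r_cal <- suppressWarnings(stats::cor(st$y_cal, pred[st$idx_cal]))
  if (!is.finite(r_trn) || !is.finite(r_itrn) || !is.finite(r_cal)) return(NULL)
  iic_cal <- iic(st$y_cal - pred[st$idx_cal], r_cal)
  tf <- tf_value(r_trn, r_itrn, iic_cal, st$const, st$w_iic)
  list(fit = fit, r_trn = r_trn, r_itrn = r_itrn, r_cal = r_cal,
       iic_cal = iic_cal, tf = tf)
}

#' Initialize a Monte Carlo optimizer state
#'
#' Computes attribute prevalence on the training set, blocks keys below the
#' threshold, draws initial weights and evaluates the target function.
#'
#' @param dataset A `qsar_dataset`.
#' @param split Split column name.
#' @param threshold Prevalence threshold `T`.
#' @param tf `"tf1"` or `"tf2"`.
#' @param const Balance constant of the target function.
#' @param w_iic IIC weight used when `tf = "tf2"`.
#' @param seed Integer seed; governs initialization and the whole trajectory.
#' @param init_range Uniform initialization range for the weights.
#' @param perturb Half-width of the uniform perturbation applied to a weight.
#' @param X Optional precomputed [profile_matrix()] (computed if `NULL`).
#' @return An opaque state list consumed by [run_epoch()].
#' @export
mc_state_init <- function(dataset, split, threshold = 1L, tf = c("tf2", "tf1"),
                          const = 0.1, w_iic = 0.2, seed = 1L,
                          init_range = c(0.1, 1.1), perturb = 0.5, X = NULL) {
  tf <- match.arg(tf)
  if (is.null(X)) X <- profile_matrix(dataset)
  ids <- list(trn = role_ids(dataset, split, "TRN"),
              itrn = role_ids(dataset, split, "iTRN"),
              cal = role_ids(dataset, split, "CAL"),
              val = role_ids(dataset, split, "VAL"))
  if (any(!vapply(ids[c("trn", "itrn", "cal")], length, 1L))) {
    stop("split '", split, "' must populate TRN, iTRN and CAL", call. = FALSE)
  }
  y <- stats::setNames(dataset$compounds$pic50, dataset$compounds$id)
  prev_trn <- prevalence(X, ids$trn)
  blocked <- apply_threshold(prev_trn, threshold)
  cw <- init_cw(colnames(X), blocked, seed = seed, range = init_range,
                threshold = threshold)
  free <- setdiff(colnames(X), blocked)
  if (!length(free)) stop("all attributes blocked at threshold ", threshold, call. = FALSE)
  # per-key nonzero rows for incremental DCW updates
  cols <- lapply(free, function(k) {
    nz <- which(X[, k] != 0)
    list(rows = nz, counts = as.numeric(X[nz, k]))
  })
  names(cols) <- free
  st <- list(
    X = X, cw = cw, free = free, cols = cols,
    idx_trn = match(ids$trn, rownames(X)),
    idx_itrn = match(ids$itrn, rownames(X)),
    idx_cal = match(ids$cal, rownames(X)),
    idx_val = match(ids$val, rownames(X)),
    y_trn = unname(y[ids$trn]), y_itrn = unname(y[ids$itrn]),
    y_cal = unname(y[ids$cal]), y_val = unname(y[ids$val]),
    ids = ids, const = const,
    w_iic = if (tf == "tf1") 0 else w_iic,
    tf_kind = tf, perturb = perturb, split = split,
    epoch = 0L, evaluations = 0L
  )
  st$dcw <- dcw_values(X, cw)
  ev <- mc_evaluate(st$dcw, st)
  if (is.null(ev)) stop("degenerate descriptor variance on the training set", call. = FALSE)
  st$eval <- ev
  st
}

#' Run one Monte Carlo epoch
#'
#' One pass over all unblocked keys in shuffled order; each perturbation is
#' kept iff the target function strictly increases, so the TF value is
#' non-decreasing across the epoch.
#'
#' @param st State from [mc_state_init()] (or a previous epoch).
#' @return The updated state.
#' @export
run_epoch <- function(st) {
  order_keys <- sample(st$free)
  w <- st$cw$weights
  dcw <- st$dcw
  cur <- st$eval
  for (k in order_keys) {
    delta <- stats::runif(1, -st$perturb, st$perturb)
    if (delta == 0) next
    col <- st$cols[[k]]
    dcw_new <- dcw
    dcw_new[col$rows] <- dcw_new[col$rows] + delta * col$counts
    cand <- mc_evaluate(dcw_new, st)
    st$evaluations <- st$evaluations + 1L
    if (!is.null(cand) && cand$tf > cur$tf) {
      w[k] <- w[k] + delta
      dcw <- dcw_new
      cur <- cand
    }
  }
  st$cw$weights <- w
  st$dcw <- dcw
  st$eval <- cur
  st$epoch <- st$epoch + 1L
  st
}

#' Train a correlation-weight model by Monte Carlo optimization
#'
#' Initializes the weight table from the training-set attribute universe and
#' runs `epochs` hill-climbing epochs under the chosen target function. The
#' validation set is never touched during optimization.
#'
#' @inheritParams mc_state_init
#' @param epochs Number of epochs `N`.
#' @param journal Keep the per-epoch trace (TF and set correlations).
#' @return An `mcqsar_fit`: list with `cw` (trained `cw_table`), `model`
#'   (`c0`, `c1`), `tf`, `split`, `dcw` (per-compound descriptor values),
#'   `metrics` (per-set battery, see [metrics_report()]) and `journal`.
#' @export
mc_optimize <- function(dataset, split, threshold = 1L, epochs = 10L,
                        tf = c("tf2", "tf1"), const = 0.1, w_iic = 0.2,
                        seed = 1L, init_range = c(0.1, 1.1), perturb = 0.5,
                        X = NULL, journal = TRUE) {
  tf <- match.arg(tf)
  st <- mc_state_init(dataset, split, threshold = threshold, tf = tf,
                      const = const, w_iic = w_iic, seed = seed,
                      init_range = init_range, perturb = perturb, X = X)
  trace <- vector("list", epochs)
  tf_prev <- st$eval$tf
  for (e in seq_len(epochs)) {
    st <- run_epoch(st)
    if (st$eval$tf < tf_prev) stop("target function decreased; optimizer invariant violated")
    tf_prev <- st$eval$tf
    trace[[e]] <- data.frame(epoch = e, evaluations = st$evaluations,
                             tf = st$eval$tf, r_trn = st$eval$r_trn,
                             r_itrn = st$eval$r_itrn, r_cal = st$eval$r_cal,
                             iic_cal = st$eval$iic_cal)
  }
  st$cw$epochs <- as.integer(epochs)
  fit <- structure(list(
    cw = st$cw, model = st$eval$fit, tf = tf, split = split,
    dcw = st$dcw, state = st,
    journal = if (journal) do.call(rbind, trace) else NULL
  ), class = "mcqsar_fit")
  fit$metrics <- metrics_report(fit, dataset)
  fit
}

#' @export
print.mcqsar_fit <- function(x, ...) {
  cat(sprintf("Monte Carlo QSAR fit (%s, split %s, T = %d, N = %d, seed = %d)\n",
              toupper(x$tf), x$split, x$cw$threshold, x$cw$epochs, x$cw$seed))
  cat(sprintf("pIC50 = %.4f + %.4f x DCW(%d, %d)\n",
              x$model$c0, x$model$c1, x$cw$threshold, x$cw$epochs))
  if (!is.null(x$metrics)) print(x$metrics, digits = 3)
  invisible(x)
}

#' Grid search over threshold and epoch counts
#'
#' Trains one model per (T, N) cell and selects the cell with the best
#' calibration-set score: R^2 under TF1 (overtraining control) or the IIC
#' under TF2. Ties are broken by smaller N, then smaller T.
#'
#' @inheritParams mc_optimize
#' @param T_grid,N_grid Integer vectors of candidate thresholds and epochs.
#' @return List with `threshold`, `epochs`, `scores` (matrix T x N) and
#'   `fit` (the winning `mcqsar_fit`).
#' @export
grid_search <- function(dataset, split, T_grid = 1:10, N_grid = 1:50,
                        tf = c("tf2", "tf1"), const = 0.1, w_iic = 0.2,
                        seed = 1L, X = NULL, ...) {
  tf <- match.arg(tf)
  stopifnot(length(T_grid) > 0, length(N_grid) > 0)
  if (is.null(X)) X <- profile_matrix(dataset)
  scores <- matrix(NA_real_, length(T_grid), length(N_grid),
                   dimnames = list(T = T_grid, N = N_grid))
  best <- NULL
  for (ti in seq_along(T_grid)) {
    # epochs nest: run the largest N once per T and score the prefix states
    st <- mc_state_init(dataset, split, threshold = T_grid[ti], tf = tf,
                        const = const, w_iic = w_iic, seed = seed, X = X, ...)
    snapshots <- vector("list", length(N_grid))
    target_N <- max(N_grid)
    for (e in seq_len(target_N)) {
      st <- run_epoch(st)
      hit <- which(N_grid == e)
      if (length(hit)) snapshots[[hit]] <- list(eval = st$eval, cw = st$cw, dcw = st$dcw)
    }
    for (ni in seq_along(N_grid)) {
      snap <- snapshots[[ni]]
      scores[ti, ni] <- if (tf == "tf1") snap$eval$r_cal^2 else snap$eval$iic_cal
      better <- is.null(best) || scores[ti, ni] > best$score ||
        (scores[ti, ni] == best$score &&
           (N_grid[ni] < best$epochs ||
              (N_grid[ni] == best$epochs && T_grid[ti] < best$threshold)))
      if (better) {
        best <- list(score = scores[ti, ni], threshold = T_grid[ti],
                     epochs = N_grid[ni])
      }
    }
  }
  fit <- mc_optimize(dataset, split, threshold = best$threshold,
                     epochs = best$epochs, tf = tf, const = const,
                     w_iic = w_iic, seed = seed, X = X, ...)
  list(threshold = best$threshold, epochs = best$epochs, scores = scores, fit = fit)
}

#' Replicate training runs with distinct seeds
#'
#' @inheritParams mc_optimize
#' @param seeds Integer vector of seeds, one run each (default 3 runs).
#' @return List of `mcqsar_fit` objects.
#' @export
mc_replicates <- function(dataset, split, seeds = 1:3, X = NULL, ...) {
  if (is.null(X)) X <- profile_matrix(dataset)
  lapply(seeds, function(s) mc_optimize(dataset, split, seed = s, X = X, ...))
}
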