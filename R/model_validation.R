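# The one-descriptor linear model and its validation battery.
#
# pIC50 = C0 + C1 x DCW(T*, N*), fitted by ordinary least squares on the
# training set. Reported per set: n, R^2, CCC, IIC, s, MAE; Q^2 (leave-one-
# out) and the Fischer ratio F on the training set; Roy's rm^2 metrics on
# the validation set; cRp^2 from Y-scrambling at model level.

#' Fit the univariate activity regression
#'
#' @param dcw Descriptor values.
#' @param activity Observed activities.
#' @return List with `c0`, `c1`, their standard errors `se0`, `se1`, and
#'   the underlying `lm` fit.
#' @export
fit_linear <- function(dcw, activity) {
  stopifnot(length(dcw) == length(activity), length(dcw) >= 3)
  if (stats::var(dcw) <= 0) stop("zero descriptor variance; cannot fit", call. = FALSE)
  fit <- stats::lm(activity ~ dcw)
  cf <- summary(fit)$coefficients
  list(c0 = unname(cf[1, 1]), c1 = unname(cf[2, 1]),
       se0 = unname(cf[1, 2]), se1 = unname(cf[2, 2]), lm = fit)
}

#' Predict activity from descriptor values
#'
#' @param model A list with `c0` and `c1` (e.g. from [fit_linear()] or the
#'   `model` element of an `mcqsar_fit`).
#' @param dcw Descriptor values.
#' @return Predicted activities `c0 + c1 * dcw`.
#' @export
predict_activity <- function(model, dcw) {
  model$c0 + model$c1 * dcw
}

#' Lin's concordance correlation coefficient
#'
#' @param x,y Paired observations (e.g. observed and predicted activity).
#' @return CCC value in `[-1, 1]`.
#' @export
ccc <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  # population (1/n) moments, the convention under which CCC = 1 iff x == y
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

#' Leave-one-out cross-validated Q2 of the univariate regression
#'
#' Uses the closed-form hat-value identity for OLS: the leave-one-out
#' residual is `e_i / (1 - h_i)`.
#'
#' @param x Descriptor values (training set).
#' @param y Observed activities (training set).
#' @return Q2 value.
#' @export
loo_q2 <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  fit <- ols_fit(x, y)
  e <- y - (fit$c0 + fit$c1 * x)
  h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
  press <- sum((e / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Per-set validation metrics
#'
#' @param observed,predicted Paired activity vectors.
#' @param train_mean Mean observed activity of the training set; when given,
#'   the determination coefficient computed against it (the training-
#'   reference formula) is reported as `r2_det`.
#' @param s_denominator `"n"` (default) or `"n-2"` for the standard error of
#'   estimation.
#' @return List with `n`, `r2` (squared Pearson correlation), `r2_det`,
#'   `ccc`, `iic`, `s`, `mae`.
#' @export
set_metrics <- function(observed, predicted, train_mean = NULL,
                        s_denominator = c("n", "n-2")) {
  n <- length(observed)
  stopifnot(n == length(predicted), n >= 2)
  s_denominator <- match.arg(s_denominator)
  r <- stats::cor(observed, predicted)
  ss_res <- sum((observed - predicted)^2)
  denom <- if (s_denominator == "n") n else n - 2
  r2_det <- if (is.null(train_mean)) NA_real_ else
    1 - ss_res / sum((observed - train_mean)^2)
  list(
    n = n,
    r2 = r^2,
    r2_det = r2_det,
    ccc = ccc(observed, predicted),
    iic = iic(observed - predicted, r),
    s = sqrt(ss_res / denom),
    mae = mean(abs(observed - predicted))
  )
}

#' Roy's rm2 metrics for external validation
#'
#' `r0^2` is the through-origin determination coefficient of predicted on
#' observed; the primed variant interchanges the axes. Each rm2 penalizes
#' r^2 by the deviation of the through-origin fit:
#' `rm2 = r^2 (1 - sqrt(r^2 - r0^2))`.
#'
#' @param observed,predicted Paired activity vectors (n >= 3).
#' @return List with `rm2`, `rm2_prime`, `mean` and `delta`.
#' @export
rm2_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  r2 <- stats::cor(observed, predicted)^2
  r02 <- function(x, y) {        # y regressed on x through the origin
    k <- sum(x * y) / sum(x^2)
    1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
  }
  rm2 <- r2 * (1 - sqrt(pmax(0, r2 - r02(observed, predicted))))
  rm2p <- r2 * (1 - sqrt(pmax(0, r2 - r02(predicted, observed))))
  list(rm2 = rm2, rm2_prime = rm2p,
       mean = (rm2 + rm2p) / 2, delta = abs(rm2 - rm2p))
}

#' Full per-set metrics report for a trained model
#'
#' One row per set with the validation battery; the validation set
#' additionally carries the rm2 metrics, the training set Q2 and F.
#'
#' @param fit An `mcqsar_fit`.
#' @param dataset The `qsar_dataset` the fit was trained on.
#' @return A data frame of class `mcqsar_metrics` with one row per set.
#' @export
metrics_report <- function(fit, dataset) {
  st <- fit$state
  y <- stats::setNames(dataset$compounds$pic50, dataset$compounds$id)
  pred_all <- predict_activity(fit$model, fit$dcw)
  train_mean <- mean(y[st$ids$trn])
  rows <- lapply(c(TRN = "trn", iTRN = "itrn", CAL = "cal", VAL = "val"), function(set) {
    ids <- st$ids[[set]]
    if (!length(ids)) return(NULL)
    obs <- unname(y[ids]); prd <- unname(pred_all[ids])
    m <- set_metrics(obs, prd, train_mean = train_mean)
    row <- data.frame(n = m$n, r2 = m$r2, r2_det = m$r2_det, ccc = m$ccc,
                      iic = m$iic, q2 = NA_real_, s = m$s, mae = m$mae,
                      f = NA_real_, rm2_mean = NA_real_, rm2_delta = NA_real_)
    if (set == "trn") {
      x <- unname(fit$dcw[ids])
      row$q2 <- loo_q2(x, obs)
      row$f <- m$r2 * (m$n - 2) / (1 - m$r2)
    }
    if (set == "val" && m$n >= 3) {
      rm2 <- rm2_metrics(obs, prd)
      row$rm2_mean <- rm2$mean
      row$rm2_delta <- rm2$delta
    }
    row
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out <- cbind(set = rownames(out), out)
  rownames(out) <- NULL
  class(out) <- c("mcqsar_metrics", class(out))
  out
}

#' @export
print.mcqsar_metrics <- function(x, digits = 3, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Y-scrambling robustness check
#'
#' Refits the model after random permutation of the activities and reports
#' Todeschini's `cRp^2 = R * sqrt(R^2 - Rr^2)` where `Rr^2` is the mean
#' scrambled determination. `"refit"` mode permutes the activities and
#' refits the univariate regression on the fixed descriptor values (the
#' standard check for a fixed-descriptor model); `"retrain"` mode re-runs
#' the full Monte Carlo optimization on the permuted activities.
#'
#' @param fit An `mcqsar_fit`.
#' @param dataset The training `qsar_dataset`.
#' @param n_iter Number of scrambling iterations.
#' @param seed Seed for the permutations.
#' @param mode `"refit"` (default) or `"retrain"`.
#' @param retrain_epochs Epochs per retrain when `mode = "retrain"`.
#' @param permutations Optional list of explicit permutations of the
#'   training indices (overrides `n_iter`/`seed`); mainly for testing the
#'   scrambling contract.
#' @return List with `r2` (reference training R^2), `mean_rr2` and `crp2`.
#' @export
y_scramble <- function(fit, dataset, n_iter = 10L, seed = 1L,
                       mode = c("refit", "retrain"), retrain_epochs = NULL,
                       permutations = NULL) {
  mode <- match.arg(mode)
  st <- fit$state
  y_trn <- st$y_trn
  r2_ref <- stats::cor(y_trn, fit$dcw[st$ids$trn])^2
  set.seed(seed)
  perms <- permutations %||%
    replicate(n_iter, sample(length(y_trn)), simplify = FALSE)
  rr2 <- vapply(perms, function(p) {
    y_perm <- y_trn[p]
    if (mode == "refit") {
      stats::cor(y_perm, fit$dcw[st$ids$trn])^2
    } else {
      ds <- dataset
      idx <- match(st$ids$trn, ds$compounds$id)
      ds$compounds$pic50[idx] <- y_perm
      refit <- mc_optimize(ds, fit$split, threshold = fit$cw$threshold,
                           epochs = retrain_epochs %||% fit$cw$epochs,
                           tf = fit$tf, seed = fit$cw$seed, X = st$X)
      stats::cor(y_perm, refit$dcw[st$ids$trn])^2
    }
  }, numeric(1))
  mean_rr2 <- mean(rr2)
  crp2 <- sqrt(r2_ref) * sqrt(max(0, r2_ref - mean_rr2))
  list(r2 = r2_ref, mean_rr2 = mean_rr2, crp2 = crp2, rr2 = rr2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the best model by validation-set mean rm2
#'
#' @param reports List of `mcqsar_metrics` data frames (one per candidate
#'   model).
#' @return Index of the selected report; ties are broken by the higher
#'   validation R^2.
#' @export
select_best_model <- function(reports) {
  stopifnot(length(reports) >= 1)
  score <- vapply(reports, function(r) {
    v <- r[r$set == "VAL", ]
    if (!nrow(v) || is.na(v$rm2_mean)) stop("report lacks validation rm2", call. = FALSE)
    v$rm2_mean
  }, numeric(1))
  r2 <- vapply(reports, function(r) r[r$set == "VAL", "r2"], numeric(1))
  best <- which(score == max(score))
  if (length(best) > 1) best <- best[which.max(r2[best])]
  best
}
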