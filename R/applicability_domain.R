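# Applicability domain by attribute statistical defect.
#
# defect(A) = |P_TRN(A) - P_CAL(A)| / (N_TRN(A) + N_CAL(A)), where P is the
# fraction of a set's molecules containing the attribute and N the count of
# such molecules; an attribute absent from the training set has defect 1.
# A molecule's defect is the sum over its distinct active attributes, and a
# molecule is an AD outlier when its defect exceeds twice the training-set
# mean defect.

#' Statistical defect of an attribute
#'
#' @param n_trn,n_cal Number of training / calibration molecules containing
#'   the attribute (presence, not multiplicity).
#' @param size_trn,size_cal Set sizes. All arguments recycle.
#' @return Defect value(s); exactly 1 where `n_trn = 0`.
#' @export
attribute_defect <- function(n_trn, size_trn, n_cal, size_cal) {
  stopifnot(all(size_trn > 0), all(size_cal > 0))
  p_trn <- n_trn / size_trn
  p_cal <- n_cal / size_cal
  defect <- abs(p_trn - p_cal) / (n_trn + n_cal)
  defect[n_trn == 0] <- 1
  defect
}

#' Defect table over a dataset's attribute universe
#'
#' @param X Attribute count matrix from [profile_matrix()].
#' @param dataset A `qsar_dataset`.
#' @param split Split column name.
#' @return Data frame with one row per attribute key: presence counts and
#'   proportions in the training and calibration sets, and the defect.
#' @export
defect_table <- function(X, dataset, split) {
  trn <- role_ids(dataset, split, "TRN")
  cal <- role_ids(dataset, split, "CAL")
  n_trn <- prevalence(X, trn)
  n_cal <- prevalence(X, cal)
  data.frame(
    key = colnames(X),
    n_trn = unname(n_trn), n_cal = unname(n_cal),
    p_trn = unname(n_trn) / length(trn), p_cal = unname(n_cal) / length(cal),
    defect = unname(attribute_defect(n_trn, length(trn), n_cal, length(cal))),
    row.names = NULL
  )
}

#' Per-molecule statistical defects and AD outlier flags
#'
#' Sums each molecule's attribute defects over its distinct active keys
#' (presence, not multiplicity). Keys blocked by the model's prevalence
#' threshold are not part of the model and are skipped, except that keys
#' absent from the training set always contribute their defect of 1.
#'
#' @param X Attribute count matrix.
#' @param dataset A `qsar_dataset`.
#' @param split Split column name.
#' @param blocked Optionally, the model's blocked key set (e.g.
#'   `fit$cw$blocked`); see Details.
#' @return Data frame with `id`, `defect`, `outlier` (strict inequality
#'   against twice the mean training defect) and `n_unseen` (active keys
#'   absent from the training set).
#' @export
molecule_defects <- function(X, dataset, split, blocked = NULL) {
  dt <- defect_table(X, dataset, split)
  d <- stats::setNames(dt$defect, dt$key)
  unseen <- dt$key[dt$n_trn == 0]
  keep <- if (is.null(blocked)) dt$key else union(setdiff(dt$key, blocked), unseen)
  present <- X[, keep, drop = FALSE] > 0
  total <- as.numeric(present %*% d[keep])
  n_unseen <- as.integer(rowSums(present[, intersect(keep, unseen), drop = FALSE]))
  trn <- role_ids(dataset, split, "TRN")
  if (!length(trn)) stop("empty training set", call. = FALSE)
  mean_trn <- mean(total[match(trn, rownames(X))])
  data.frame(
    id = rownames(X),
    defect = total,
    outlier = total > 2 * mean_trn,
    n_unseen = n_unseen,
    row.names = NULL
  )
}

#' Residual outliers of a fitted model
#'
#' Flags compounds whose absolute prediction error exceeds `k` times the
#' standard error of estimation of the training set.
#'
#' @param observed,predicted Named activity vectors (names = compound ids).
#' @param trn_ids Training-set ids used to compute `s` (unless supplied).
#' @param k Error multiplier (3 for the conventional preliminary-model
#'   screen).
#' @param s Optionally, a precomputed standard error of estimation.
#' @return Character vector of outlier ids.
#' @export
residual_outliers <- function(observed, predicted, trn_ids = names(observed),
                              k = 3, s = NULL) {
  stopifnot(length(observed) == length(predicted))
  err <- observed - predicted
  if (is.null(s)) {
    e_trn <- err[trn_ids]
    s <- sqrt(mean(e_trn^2))
  }
  names(observed)[abs(err) > k * s]
}
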