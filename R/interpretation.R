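# Mechanistic interpretation: promoters of activity increase / decrease.
#
# The correlation weight of an attribute is re-estimated in three or more
# independent optimization runs. Attributes whose weight is positive in
# every run are promoters of activity increase; negative in every run,
# promoters of decrease; anything else (sign changes, or an exact zero) is
# undefined because the evidence is unstable.

#' Classify an attribute from its replicate correlation weights
#'
#' @param weights Numeric vector of correlation weights, one per run.
#' @return `"increase"`, `"decrease"` or `"undefined"`.
#' @export
classify_promoter <- function(weights) {
  stopifnot(length(weights) >= 1)
  if (all(weights > 0)) "increase"
  else if (all(weights < 0)) "decrease"
  else "undefined"
}

# human-readable gloss for frequent attribute keys
PROMOTER_GLOSS <- c(
  "SSK:=~C" = "aliphatic carbon at a double bond",
  "SSK:C~O" = "aliphatic oxygen bound to aliphatic carbon",
  "SSK:(~c" = "branching on aromatic ring",
  "SK:N" = "aliphatic nitrogen",
  "SK:O" = "aliphatic oxygen",
  "SK:C" = "aliphatic carbon",
  "SK:c" = "aromatic carbon",
  "SK:n" = "aromatic nitrogen",
  "SK:o" = "aromatic oxygen"
)

#' Promoter table across replicate optimization runs
#'
#' Collects the correlation weight of every unblocked attribute from each
#' run, classifies it by the sign-unanimity rule, and attaches set
#' prevalence counts and the applicability-domain defect.
#'
#' Weights are reported in the orientation of each run's regression: when a
#' run converges to a negative slope, its weights are sign-flipped so that a
#' positive reported weight always means "raises the predicted activity".
#' Published models carry positive slopes, for which this is a no-op.
#'
#' @param fits List of `mcqsar_fit` objects trained on the same split with
#'   identical (T, N) and distinct seeds; three or more runs are expected
#'   (fewer triggers a warning, classification is still computed).
#' @param dataset The `qsar_dataset` used for training.
#' @param X Attribute count matrix (recomputed if `NULL`).
#' @return Data frame sorted by decreasing |mean weight|: key, one `cw_run*`
#'   column per run, prevalence counts `n_trn`, `n_itrn`, `n_cal`, `defect`,
#'   `class`, and a human-readable `gloss` where known.
#' @export
extract_promoters <- function(fits, dataset, X = NULL) {
  stopifnot(length(fits) >= 1)
  split <- fits[[1]]$split
  tn <- vapply(fits, function(f) c(f$cw$threshold, f$cw$epochs), numeric(2))
  if (length(fits) > 1 && (any(tn[1, ] != tn[1, 1]) || any(tn[2, ] != tn[2, 1]))) {
    stop("all runs must share the same (T, N)", call. = FALSE)
  }
  if (length(fits) < 3) {
    warning("fewer than 3 runs; promoter classification is unstable")
  }
  if (is.null(X)) X <- profile_matrix(dataset)
  free <- setdiff(names(fits[[1]]$cw$weights), fits[[1]]$cw$blocked)
  W <- vapply(fits, function(f) sign(f$model$c1) * f$cw$weights[free],
              numeric(length(free)))
  W <- matrix(W, nrow = length(free),
              dimnames = list(free, paste0("cw_run", seq_along(fits))))
  n_trn <- prevalence(X, role_ids(dataset, split, "TRN"))[free]
  n_itrn <- prevalence(X, role_ids(dataset, split, "iTRN"))[free]
  n_cal <- prevalence(X, role_ids(dataset, split, "CAL"))[free]
  defect <- attribute_defect(n_trn, length(role_ids(dataset, split, "TRN")),
                             n_cal, length(role_ids(dataset, split, "CAL")))
  out <- data.frame(key = free, W,
                    n_trn = unname(n_trn), n_itrn = unname(n_itrn),
                    n_cal = unname(n_cal), defect = unname(defect),
                    class = apply(W, 1, classify_promoter),
                    gloss = unname(PROMOTER_GLOSS[free]),
                    row.names = NULL)
  out[order(-abs(rowMeans(W))), ]
}
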