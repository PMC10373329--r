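# Correlation-weight table and the descriptor of correlation weights (DCW).
#
# DCW(T*, N*) of a molecule is the sum over its attribute keys of
# multiplicity x correlation weight. Keys rarer than the threshold T in the
# training set are blocked: their weight is frozen at exactly 0 and never
# updated. The weights of the remaining keys are what the Monte Carlo
# optimizer trains.

#' Attribute count matrix of a dataset
#'
#' Computes the hybrid attribute profile of every compound and assembles the
#' molecule-by-attribute count matrix used by all downstream steps.
#'
#' @param dataset A `qsar_dataset`.
#' @param halo_key Passed to [attribute_profile()].
#' @return Integer matrix, one row per compound (rownames = ids), one column
#'   per attribute key seen anywhere in the dataset (colnames = serialized
#'   keys, lexicographic order).
#' @export
profile_matrix <- function(dataset, halo_key = TRUE) {
  profiles <- lapply(dataset$compounds$smiles, attribute_profile, halo_key = halo_key)
  keys <- sort(unique(unlist(lapply(profiles, names))), method = "radix")
  X <- matrix(0L, nrow = length(profiles), ncol = length(keys),
              dimnames = list(dataset$compounds$id, keys))
  for (i in seq_along(profiles)) {
    X[i, names(profiles[[i]])] <- profiles[[i]]
  }
  X
}

#' Attribute prevalence (molecule presence counts) in one set
#'
#' @param X Attribute count matrix from [profile_matrix()].
#' @param ids Compound ids of the set (rows of `X`).
#' @return Named integer vector: for every column of `X`, the number of the
#'   set's molecules containing the attribute at least once.
#' @export
prevalence <- function(X, ids) {
  ids <- as.character(ids)
  if (!length(ids)) stop("empty set", call. = FALSE)
  missing <- setdiff(ids, rownames(X))
  if (length(missing)) stop("ids not in matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  counts <- colSums(X[ids, , drop = FALSE] > 0)
  stats::setNames(as.integer(counts), colnames(X))
}

#' Block attribute keys below a prevalence threshold
#'
#' @param counts Named prevalence vector over the training set.
#' @param threshold Minimum training-set presence `T`; keys with presence
#'   `< T` are blocked (weight frozen at 0).
#' @return Character vector of blocked keys.
#' @export
apply_threshold <- function(counts, threshold) {
  stopifnot(threshold >= 1)
  names(counts)[counts < threshold]
}

#' Initialize a correlation-weight table
#'
#' Unblocked keys receive independent uniform draws; blocked keys are fixed
#' at exactly 0.
#'
#' @param keys All attribute keys of the model universe.
#' @param blocked Keys frozen at weight 0.
#' @param seed Integer seed (reproducibility contract).
#' @param range Numeric `c(lo, hi)` of the uniform initialization.
#' @param threshold,epochs Provenance recorded in the table.
#' @return A `cw_table`: list with `weights` (named numeric), `blocked`,
#'   `threshold`, `epochs`, `seed`.
#' @export
init_cw <- function(keys, blocked = character(0), seed = 1L,
                    range = c(0.1, 1.1), threshold = 1L, epochs = NA_integer_) {
  stopifnot(range[1] <= range[2], all(blocked %in% keys))
  set.seed(seed)
  w <- stats::setNames(stats::runif(length(keys), range[1], range[2]), keys)
  w[blocked] <- 0
  structure(list(weights = w, blocked = blocked, threshold = as.integer(threshold),
                 epochs = epochs, seed = as.integer(seed)),
            class = "cw_table")
}

#' @export
print.cw_table <- function(x, ...) {
  cat("Correlation-weight table:", length(x$weights), "keys (",
      length(x$blocked), "blocked ), T =", x$threshold,
      ", N =", x$epochs, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Descriptor of correlation weights for one profile
#'
#' @param profile Named integer count vector (an attribute profile).
#' @param cw A `cw_table`.
#' @return List with `value` (sum of multiplicity x weight), `active` (keys
#'   present in the table) and `unseen` (keys absent from the table; they
#'   contribute 0 and feed the applicability-domain defect).
#' @export
compute_dcw <- function(profile, cw) {
  hit <- names(profile) %in% names(cw$weights)
  value <- sum(profile[hit] * cw$weights[names(profile)[hit]])
  list(value = as.numeric(value), active = sum(hit), unseen = sum(!hit))
}

#' Descriptor values for every row of a count matrix
#'
#' Vectorized [compute_dcw()]: columns of `X` missing from the table
#' contribute 0.
#'
#' @param X Attribute count matrix.
#' @param cw A `cw_table` (or a named weight vector).
#' @return Named numeric vector of DCW values, one per row of `X`.
#' @export
dcw_values <- function(X, cw) {
  w <- if (inherits(cw, "cw_table")) cw$weights else cw
  common <- intersect(colnames(X), names(w))
  v <- as.numeric(X[, common, drop = FALSE] %*% w[common])
  stats::setNames(v, rownames(X))
}

#' Write a trained model to a text file
#'
#' Stable, diffable serialization: header fields, then one `key TAB weight`
#' line per attribute in lexicographic key order.
#'
#' @param fit An `mcqsar_fit` from [mc_optimize()].
#' @param path Output path.
#' @export
write_cw_model <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cw <- fit$cw
  writeLines(c(
    sprintf("threshold\t%d", cw$threshold),
    sprintf("epochs\t%d", cw$epochs),
    sprintf("seed\t%d", cw$seed),
    sprintf("tf\t%s", fit$tf),
    sprintf("c0\t%.10g", fit$model$c0),
    sprintf("c1\t%.10g", fit$model$c1),
    "[weights]"
  ), con)
  w <- cw$weights[order(names(cw$weights), method = "radix")]
  writeLines(sprintf("%s\t%.10g", names(w), w), con)
  invisible(path)
}

#' Read a model written by [write_cw_model()]
#'
#' @param path Model file path.
#' @return List with `cw` (a `cw_table`), `model` (`c0`, `c1`) and `tf`.
#' @export
read_cw_model <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "[weights]")
  header <- strsplit(lines[seq_len(sep - 1)], "\t", fixed = TRUE)
  h <- stats::setNames(vapply(header, `[`, "", 2), vapply(header, `[`, "", 1))
  wl <- strsplit(lines[-seq_len(sep)], "\t", fixed = TRUE)
  w <- stats::setNames(as.numeric(vapply(wl, `[`, "", 2)), vapply(wl, `[`, "", 1))
  cw <- structure(list(weights = w, blocked = names(w)[w == 0],
                       threshold = as.integer(h[["threshold"]]),
                       epochs = as.integer(h[["epochs"]]),
                       seed = as.integer(h[["seed"]])),
                  class = "cw_table")
  list(cw = cw, model = list(c0 = as.numeric(h[["c0"]]), c1 = as.numeric(h[["c1"]])),
       tf = h[["tf"]])
}
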