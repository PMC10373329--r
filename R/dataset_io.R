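ROLE_LEVELS <- c("TRN", "iTRN", "CAL", "VAL")

# Table-caption symbol convention: + training, - invisible training,
# # calibration, * validation.
ROLE_SYMBOLS <- c("+" = "TRN", "-" = "iTRN", "#" = "CAL", "*" = "VAL")

decode_role <- function(x, row = NA_integer_) {
  x <- trimws(x)
  # tolerate the unicode minus that PDF extraction produces
  x[x == "−"] <- "-"
  out <- rep(NA_character_, length(x))
  sym <- x %in% names(ROLE_SYMBOLS)
  out[sym] <- ROLE_SYMBOLS[x[sym]]
  word <- !sym & toupper(x) %in% toupper(ROLE_LEVELS)
  out[word] <- ROLE_LEVELS[match(toupper(x[word]), toupper(ROLE_LEVELS))]
  bad <- !sym & !word & !is.na(x) & nzchar(x)
  if (any(bad)) {
    stop("unknown role symbol '", x[which(bad)[1]], "' in row ",
         if (length(row) == length(x)) row[which(bad)[1]] else which(bad)[1],
         call. = FALSE)
  }
  out
}

encode_role <- function(x) {
  names(ROLE_SYMBOLS)[match(x, ROLE_SYMBOLS)]
}

new_qsar_dataset <- function(compounds, splits) {
  stopifnot(is.data.frame(compounds), all(c("id", "smiles", "pic50") %in% names(compounds)))
  structure(list(compounds = compounds, splits = splits), class = "qsar_dataset")
}

#' Read a compound table with split assignments
#'
#' Parses a delimited table with columns `id`, `smiles`, `pic50` and one
#' column per data split. Role cells may hold either the symbols `+`
#' (training), `-` (invisible training), `#` (calibration), `*` (validation)
#' or the words `TRN`, `iTRN`, `CAL`, `VAL`. Rows with an empty activity are
#' kept as prediction-only compounds.
#'
#' @param path Path to a delimited text file with a header row.
#' @param split_columns Character vector of split column names. Default: all
#'   columns starting with `"split"`.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A `qsar_dataset`: a list with `compounds` (data frame holding id,
#'   smiles, pic50 and one canonical-role column per split) and `splits`.
#'   Any additional columns of the input are carried through unchanged.
#' @export
parse_dataset <- function(path, split_columns = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, comment.char = "")
  if (nrow(df) == 0) stop("empty dataset: ", path, call. = FALSE)
  for (col in c("id", "smiles", "pic50")) {
    if (!col %in% names(df)) stop("missing required column '", col, "'", call. = FALSE)
  }
  if (is.null(split_columns)) {
    split_columns <- grep("^split", names(df), value = TRUE)
  }
  missing <- setdiff(split_columns, names(df))
  if (length(missing)) stop("missing split column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate compound id: ", df$id[duplicated(df$id)][1], call. = FALSE)
  }
  if (any(!nzchar(trimws(df$smiles)))) stop("empty SMILES string", call. = FALSE)
  df$smiles <- gsub("[[:space:]]+", "", df$smiles)  # printed tables embed stray spaces
  df$pic50 <- suppressWarnings(as.numeric(df$pic50))
  for (s in split_columns) df[[s]] <- decode_role(as.character(df[[s]]), seq_len(nrow(df)))
  new_qsar_dataset(df, split_columns)
}

#' Write a compound table
#'
#' Inverse of [parse_dataset()]; roles are written either as canonical words
#' or as the `+ - # *` symbol convention.
#'
#' @param dataset A `qsar_dataset`.
#' @param path Output file path.
#' @param symbols Write roles as symbols instead of words.
#' @param sep Field separator.
#' @export
write_dataset <- function(dataset, path, symbols = FALSE, sep = ",") {
  df <- dataset$compounds
  if (symbols) for (s in dataset$splits) df[[s]] <- encode_role(df[[s]])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat("QSAR dataset:", nrow(x$compounds), "compounds,",
      length(x$splits), "split(s)\n")
  for (s in x$splits) {
    tab <- table(factor(x$compounds[[s]], levels = ROLE_LEVELS))
    cat(" ", s, ": ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Summarize a QSAR dataset
#'
#' Per-split set sizes plus the range and mean of the observed activity.
#'
#' @param object A `qsar_dataset`.
#' @param ... Unused.
#' @return A list with `n`, `activity` (min/max/mean over observed pIC50)
#'   and `sets` (per-split role counts).
#' @export
summary.qsar_dataset <- function(object, ...) {
  act <- object$compounds$pic50
  act <- act[is.finite(act)]
  if (!length(act)) stop("no compound has an observed activity", call. = FALSE)
  sets <- lapply(object$splits, function(s) {
    tab <- table(factor(object$compounds[[s]], levels = ROLE_LEVELS))
    stats::setNames(as.integer(tab), names(tab))
  })
  names(sets) <- object$splits
  structure(list(
    n = nrow(object$compounds),
    activity = c(min = min(act), max = max(act), mean = mean(act)),
    sets = sets
  ), class = "qsar_dataset_summary")
}

#' @export
print.qsar_dataset_summary <- function(x, ...) {
  cat("Compounds:", x$n, "\n")
  cat(sprintf("pIC50: min %.2f  max %.2f  mean %.2f\n",
              x$activity["min"], x$activity["max"], x$activity["mean"]))
  for (s in names(x$sets)) {
    cat(" ", s, ": ", paste(sprintf("%s=%d", names(x$sets[[s]]), x$sets[[s]]),
                            collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract the compound ids holding a given role
#'
#' @param dataset A `qsar_dataset`.
#' @param split Split column name.
#' @param role One of `"TRN"`, `"iTRN"`, `"CAL"`, `"VAL"`.
#' @return Character vector of compound ids.
#' @export
role_ids <- function(dataset, split, role) {
  stopifnot(split %in% dataset$splits, role %in% ROLE_LEVELS)
  df <- dataset$compounds
  df$id[!is.na(df[[split]]) & df[[split]] == role]
}

#' The packaged flavonol anti-prostate-cancer dataset
#'
#' Eighty flavonol derivatives with PC-3 pIC50 activities (-log10 molar IC50),
#' three random splits into training / invisible training / calibration /
#' validation sets, and -- as reference data for tests -- the descriptor
#' values and predictions printed for the published models of each split.
#' Compound ids follow the source numbering; six outlier compounds (31, 32,
#' 36, 37, 67, 80) were removed there before modelling and are absent here.
#'
#' @param reference Attach the printed per-split descriptor (`dcw1..3`) and
#'   prediction (`pred1..3`) columns as the `"reference"` attribute.
#' @return A `qsar_dataset` with splits `split1`, `split2`, `split3`.
#' @export
flavonol_pic50 <- function(reference = TRUE) {
  path <- system.file("extdata", "flavonol_pic50.csv", package = "mcqsar", mustWork = TRUE)
  ds <- parse_dataset(path)
  ref_cols <- c("dcw1", "dcw2", "dcw3", "pred1", "pred2", "pred3")
  ref <- ds$compounds[, c("id", ref_cols)]
  ds$compounds <- ds$compounds[, setdiff(names(ds$compounds), ref_cols)]
  if (reference) attr(ds, "reference") <- ref
  ds
}
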