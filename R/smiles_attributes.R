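# SMILES-side structural attributes.
#
# Attribute keys serialize as "NAMESPACE:payload" strings. The SMILES side
# contributes:
#   SK:<token>            one key per SMILES symbol (atom, bond, branch, digit)
#   SSK:<a>~<b>           one key per adjacent token pair, pair sorted
#   BOND:=x#x@x           presence flags of double/triple/stereo bond symbols
#   NOSP:NxOxSxPx         presence flags of N, O, S, P atoms (case-insensitive)
#   HALO:FxClxBrxIx       presence flags of the four halogens
#   PAIR:<a>|<b>          the three pairwise combinations of BOND/NOSP/HALO
#   HARD:<bond>|<nosp>|<halo>
#   CMAX:<n>              number of ring-closure digit pairings
#   NMAX:<n> / OMAX:<n>   total nitrogen / oxygen atom counts

TWO_CHAR_TOKENS <- c("Cl", "Br", "Si")
ORGANIC_ATOMS <- c("B", "C", "N", "O", "P", "S", "F", "I",
                   "b", "c", "n", "o", "p", "s")
NON_ATOM_TOKENS <- c("(", ")", "=", "#", "@", "-", as.character(1:9))

#' Tokenize a SMILES string
#'
#' Splits a SMILES string of the supported dialect (organic-subset atoms,
#' aromatic lowercase, ring-closure digits 1-9, branches, `=`/`#`/`@`/`-`
#' bond symbols, two-character `Cl`/`Br`/`Si`) into its symbol units.
#' Whitespace is stripped first. Concatenating the returned tokens
#' reproduces the input.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens, with a `positions` attribute giving
#'   the 1-based character offset of each token.
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  s <- gsub("[[:space:]]+", "", smiles)
  if (!nzchar(s)) stop("empty SMILES string", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  tokens <- character(0)
  pos <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    two <- if (i < n) paste0(chars[i], chars[i + 1L]) else ""
    if (two %in% TWO_CHAR_TOKENS) {
      tokens <- c(tokens, two); pos <- c(pos, i); i <- i + 2L
    } else if (chars[i] %in% ORGANIC_ATOMS || chars[i] %in% NON_ATOM_TOKENS) {
      tokens <- c(tokens, chars[i]); pos <- c(pos, i); i <- i + 1L
    } else {
      stop("unsupported SMILES character '", chars[i], "' at position ", i,
           call. = FALSE)
    }
  }
  attr(tokens, "positions") <- pos
  tokens
}

is_atom_token <- function(tokens) {
  tokens %in% c(TWO_CHAR_TOKENS, ORGANIC_ATOMS)
}

#' Local SMILES attributes (single symbols and adjacent pairs)
#'
#' One `SK` key per token and one `SSK` key per adjacent token pair; the
#' pair is canonicalized by sorting its two texts so the multiset is
#' invariant under string reversal.
#'
#' @param tokens Output of [tokenize_smiles()].
#' @return Named integer vector of attribute counts.
#' @export
local_attributes <- function(tokens) {
  keys <- paste0("SK:", tokens)
  if (length(tokens) > 1) {
    a <- tokens[-length(tokens)]
    b <- tokens[-1]
    # byte-order comparison keeps pair canonicalization locale-independent
    swap <- mapply(function(x, y) identical(sort(c(x, y), method = "radix")[1], y), a, b)
    lo <- ifelse(swap, b, a)
    hi <- ifelse(swap, a, b)
    keys <- c(keys, paste0("SSK:", lo, "~", hi))
  }
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

ring_closure_count <- function(tokens) {
  digits <- tokens[tokens %in% as.character(1:9)]
  open <- character(0)
  pairs <- 0L
  for (d in digits) {
    if (d %in% open) {
      open <- open[open != d]
      pairs <- pairs + 1L
    } else {
      open <- c(open, d)
    }
  }
  if (length(open)) {
    stop("unmatched ring-closure digit(s): ", paste(open, collapse = ", "),
         call. = FALSE)
  }
  pairs
}

#' Global SMILES attributes (whole-molecule codes)
#'
#' Order-1 attributes describing the molecule as a whole: bond-type and
#' element presence flags, their pairwise and full combinations, the number
#' of ring-closure pairings and the nitrogen/oxygen atom counts.
#'
#' @param tokens Output of [tokenize_smiles()].
#' @param halo_key Also emit the standalone `HALO` presence key (it always
#'   participates in `PAIR`/`HARD`).
#' @return Named integer vector of attribute counts (all equal to 1).
#' @export
global_attributes <- function(tokens, halo_key = TRUE) {
  atoms <- tokens[is_atom_token(tokens)]
  flag <- function(x) as.integer(x)
  bond <- sprintf("=%d#%d@%d",
                  flag("=" %in% tokens), flag("#" %in% tokens), flag("@" %in% tokens))
  up <- toupper(atoms)
  # "Si" uppercases to "SI", so it never trips the sulfur flag
  nosp <- sprintf("N%dO%dS%dP%d",
                  flag("N" %in% up), flag("O" %in% up),
                  flag("S" %in% up), flag("P" %in% up))
  halo <- sprintf("F%dCl%dBr%dI%d",
                  flag("F" %in% atoms), flag("Cl" %in% atoms),
                  flag("Br" %in% atoms), flag("I" %in% atoms))
  keys <- c(
    paste0("BOND:", bond),
    paste0("NOSP:", nosp),
    if (halo_key) paste0("HALO:", halo),
    paste0("PAIR:", bond, "|", nosp),
    paste0("PAIR:", bond, "|", halo),
    paste0("PAIR:", nosp, "|", halo),
    paste0("HARD:", bond, "|", nosp, "|", halo),
    paste0("CMAX:", ring_closure_count(tokens)),
    paste0("NMAX:", sum(up == "N")),
    paste0("OMAX:", sum(up == "O"))
  )
  stats::setNames(rep(1L, length(keys)), keys)
}

#' Full SMILES-side attribute profile of a molecule
#'
#' @param smiles A single SMILES string.
#' @param halo_key Passed to [global_attributes()].
#' @return Named integer vector of attribute counts.
#' @export
smiles_attribute_profile <- function(smiles, halo_key = TRUE) {
  tokens <- tokenize_smiles(smiles)
  c(local_attributes(tokens), global_attributes(tokens, halo_key = halo_key))
}
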