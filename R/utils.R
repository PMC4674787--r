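# Shared sequence helpers. All sequences are held internally as uppercase DNA
# (U -> T); the original alphabet is tracked by callers where it matters.

#' Normalise a nucleotide string to uppercase DNA letters
#'
#' RNA input (containing U/u) is converted to the DNA alphabet; an attribute is
#' not attached here -- callers that need the original alphabet record it.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over A, C, G, T, N.
#' @export
norm_dna <- function(x) {
  chartr("u", "t", chartr("U", "T", toupper(x)))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# complement without reversal
complement_dna <- function(x) chartr("ACGTN", "TGCAN", x)

# TRUE where miRNA base a can pair target base b (Watson-Crick or G:U wobble,
# in DNA letters so U == T)
pair_type <- function(a, b) {
  key <- paste0(a, b)
  ifelse(key %in% c("AT", "TA", "CG", "GC"), "wc",
         ifelse(key %in% c("GT", "TG"), "wobble", "none"))
}

# Hamming distance between equal-length strings (vectorised over pairs)
str_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b) || length(a) == 1L || length(b) == 1L)
  mapply(function(x, y) {
    rx <- charToRaw(x); ry <- charToRaw(y)
    if (length(rx) != length(ry)) stop("str_mismatches: unequal lengths")
    sum(rx != ry)
  }, a, b, USE.NAMES = FALSE)
}

# positions (1-based) where equal-length strings differ
mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# a base that neither Watson-Crick pairs nor wobbles with miRNA base `a`
nonpairing_base <- function(a) {
  vapply(a, function(b) {
    bad <- switch(b, A = c("T"), C = c("G"), G = c("C", "T"), T = c("A", "G"),
                  c("A", "C", "G", "T"))
    sample(setdiff(c("A", "C", "G", "T"), bad), 1L)
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
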