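# Shared low-level helpers: codon translation, reverse complement, rounding.

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reverse complement of a DNA string
#'
#' @param x character scalar over {A,C,G,T,N}.
#' @return reverse-complemented character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a CDS with the standard genetic code
#'
#' Translation uses codon table 1, stops at the first stop codon and never
#' includes the stop in the returned protein.  A trailing incomplete codon is
#' ignored.
#'
#' @param cds character scalar, in-frame coding sequence (already
#'   strand-corrected).
#' @return character scalar protein; attribute `premature_stop` is `TRUE` when
#'   a stop codon occurred before the final complete codon.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) {
    return(structure("", premature_stop = FALSE))
  }
  trimmed <- substr(cds, 1L, 3L * n_codon)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(trimmed),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    protein <- substr(aa, 1L, stop_at - 1L)
    premature <- stop_at < n_codon
  } else {
    protein <- aa
    premature <- FALSE
  }
  structure(protein, premature_stop = premature)
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# deterministic child seed derivation, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample integers uniformly from [lo, hi]; safe against R's scalar-x
# sample() surprise when lo == hi
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}
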