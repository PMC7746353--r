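#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Internal sequence helpers. All sequences are normalised to uppercase DNA
# alphabet (U -> T) on entry so that RNA and DNA inputs are interchangeable;
# writers that promise RNA output convert back with `to_rna()`.

norm_seq <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf(
      "sequence contains characters outside the ACGTUN alphabet (first offender: %s)",
      x[which(bad)[1]]
    ))
  }
  x
}

to_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Watson-Crick complementarity of two aligned bases (no G:T/G:U wobble).
is_wc <- function(a, b) comp_base[a] == b & a != "N"

# Wobble pair (G:U, i.e. G:T in the DNA alphabet), either orientation.
is_gu <- function(a, b) (a == "G" & b == "T") | (a == "T" & b == "G")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%&&%` <- function(x, y) if (isTRUE(x)) y else x
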