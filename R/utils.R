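# Small sequence helpers shared across modules. Sequences are plain upper-case
# character strings; Biostrings does the heavy lifting underneath.

AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

assert_dna <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single DNA string.", arg))
  }
  x <- toupper(x)
  if (nchar(x) > 0 && grepl("[^ACGT]", x)) {
    abort(sprintf("`%s` contains characters other than A/C/G/T.", arg))
  }
  x
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate DNA to protein
#'
#' Thin vectorised wrapper around [Biostrings::translate()] using the standard
#' genetic code. Stops translate to `*` and are kept, so callers can inspect
#' frame integrity themselves.
#'
#' @param x Character vector of in-frame DNA strings (lengths divisible by 3).
#' @return Character vector of amino-acid strings.
#' @export
translate_dna <- function(x) {
  if (length(x) == 0) return(character())
  bad <- nchar(x) %% 3 != 0
  if (any(bad)) {
    abort(sprintf("sequence length not divisible by 3 (first offender: %d nt)",
                  nchar(x[bad][1])))
  }
  as.character(Biostrings::translate(Biostrings::DNAStringSet(toupper(x)),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "error"))
}

split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3 != 0) abort("sequence length not divisible by 3")
  if (n == 0) return(character())
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# 0-based half-open interval helpers used for locus/cassette annotations
interval_width <- function(start, end) end - start

check_interval <- function(start, end, max, what) {
  if (start < 0 || end > max || start >= end) {
    abort(sprintf("%s interval [%d, %d) out of bounds for sequence of %d nt",
                  what, start, end, max))
  }
  invisible(TRUE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stop-free random coding sequence of n_codons codons
random_orf <- function(n_codons, start_atg = FALSE) {
  sense <- setdiff(names(GENETIC_CODE_TABLE), c("TAA", "TAG", "TGA"))
  codons <- sample(sense, n_codons, replace = TRUE)
  if (start_atg && n_codons > 0) codons[1] <- "ATG"
  paste(codons, collapse = "")
}
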