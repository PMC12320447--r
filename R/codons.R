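# Genetic code and codon usage. The code table comes from Biostrings; the
# human usage frequencies (per thousand codons, GenBank CDS-derived) are the
# standard reference table and only their within-amino-acid ranking matters
# for codon assignment.

GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

HUMAN_CODON_USAGE <- c(
  TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9,
  CTT = 13.2, CTC = 19.6, CTA = 7.2, CTG = 39.6,
  ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
  GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1,
  TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
  CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
  ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
  GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
  TAT = 12.2, TAC = 15.3, TAA = 1.0, TAG = 0.8,
  CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
  AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
  GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
  TGT = 10.6, TGC = 12.6, TGA = 1.6, TGG = 13.2,
  CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4,
  AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
  GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5
)

#' Codon usage table
#'
#' Returns the bundled human codon usage table as a tibble. Frequencies are
#' per thousand codons; ranking within each amino acid decides which codons
#' [assign_codons()] picks.
#'
#' @return A tibble with columns `codon`, `amino_acid`, `per_thousand`.
#' @export
codon_usage_human <- function() {
  tibble(
    codon = names(HUMAN_CODON_USAGE),
    amino_acid = unname(GENETIC_CODE_TABLE[names(HUMAN_CODON_USAGE)]),
    per_thousand = unname(HUMAN_CODON_USAGE)
  )
}

codons_for <- function(aa) {
  names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == aa]
}

#' Pick codons for an amino acid by usage
#'
#' Ranks the codons of `aa` by usage frequency (ties broken alphabetically)
#' and returns the top `k`, after dropping any codons in `exclude`. Requesting
#' more codons than exist returns all available ones, so single-codon amino
#' acids (Met, Trp) yield a length-1 result. A synonymous control codon is
#' obtained by excluding the reference codon and taking `k = 1`.
#'
#' @param aa Single amino-acid letter (or `"*"` for a stop codon).
#' @param k Number of codons wanted.
#' @param usage Codon usage tibble as from [codon_usage_human()].
#' @param exclude Codons to ignore (e.g. the reference codon).
#' @return Character vector of between 0 and `k` codons, highest usage first.
#' @export
#' @examples
#' assign_codons("L", 2)
#' assign_codons("M", 2) # only ATG exists
assign_codons <- function(aa, k = 2L, usage = codon_usage_human(),
                          exclude = character()) {
  if (!is.character(aa) || length(aa) != 1L ||
      !(aa %in% c(AA_STANDARD, "*"))) {
    abort("`aa` must be a single standard amino-acid letter or '*'.")
  }
  cand <- setdiff(codons_for(aa), toupper(exclude))
  if (length(cand) == 0) return(character())
  freq <- usage$per_thousand[match(cand, usage$codon)]
  cand <- cand[order(-freq, cand)]
  head(cand, k)
}

IUPAC_DNA <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Expand a degenerate codon scheme
#'
#' Enumerates every concrete codon matched by a 3-letter IUPAC degenerate
#' codon (e.g. `NNN` gives all 64, `NNK` gives 32).
#'
#' @param scheme 3-letter IUPAC string.
#' @return Character vector of codons in alphabetical order.
#' @export
expand_degenerate <- function(scheme) {
  scheme <- toupper(scheme)
  if (!is.character(scheme) || length(scheme) != 1L || nchar(scheme) != 3L ||
      grepl(sprintf("[^%s]", paste(names(IUPAC_DNA), collapse = "")), scheme)) {
    abort("`scheme` must be a 3-letter IUPAC degenerate codon such as 'NNN' or 'NNK'.")
  }
  parts <- strsplit(scheme, "")[[1]]
  grid <- expand.grid(
    b3 = strsplit(IUPAC_DNA[[parts[3]]], "")[[1]],
    b2 = strsplit(IUPAC_DNA[[parts[2]]], "")[[1]],
    b1 = strsplit(IUPAC_DNA[[parts[1]]], "")[[1]],
    stringsAsFactors = FALSE
  )
  sort(paste0(grid$b1, grid$b2, grid$b3))
}
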