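# Deterministic toy fixtures built in code.

# stop-free CDS assembled codon-wise; none of these codons can create an
# in-frame stop by concatenation
TOY_CODONS <- c("GCT", "GAC", "GAA", "GGT", "CAC", "ATT", "AAG", "CTG", "CCA")

toy_cds <- function(n_nt) {
  codons <- rep(TOY_CODONS, length.out = ceiling(n_nt / 3))
  substr(paste(codons, collapse = ""), 1, n_nt)
}

# two-exon locus with a controllable first-exon width (hence a controllable
# upstream leftover = width %% 3) and a 30-nt donor-like intron
toy_locus <- function(first_exon_width = 12L, second_exon_width = NULL,
                      intron_length = 30L) {
  w1 <- as.integer(first_exon_width)
  # total exon content is the CDS, so it must be a codon multiple
  w2 <- if (is.null(second_exon_width)) {
    30L + (3L - w1 %% 3L) %% 3L
  } else {
    as.integer(second_exon_width)
  }
  cds <- toy_cds(w1 + w2)
  intron <- paste0("GTAAGT", strrep("C", intron_length - 8L), "AG")
  sequence <- paste0(substr(cds, 1, w1), intron,
                     substr(cds, w1 + 1, w1 + w2))
  target_locus(
    locus_id = sprintf("toy_w%d", w1),
    sequence = sequence,
    exons = data.frame(start = c(0L, w1 + intron_length),
                       end = c(w1, w1 + intron_length + w2)),
    cut_site = w1 + intron_length %/% 2L,
    signal_peptide = c(0L, min(6L, w1 - 1L)),
    transmembrane = c(w1 + intron_length + 5L, w1 + intron_length + 20L)
  )
}

TOY_PAYLOAD <- "ATGGACGAAGGTCACATTAAG" # 7 codons, stop-free

# small member table plus an abundance table from named raw counts
toy_members <- function() {
  design_scanning_library(
    paste(c("GAC", "GAA", "AAG"), collapse = ""),
    config = scan_config(window = c(1L, 3L), stop_positions = 2L)
  )
}

abundance_from_counts <- function(members, counts, sample_id = "s") {
  tab <- tibble::tibble(member_id = members$member_id,
                        raw_count = as.integer(counts[members$member_id]))
  tab$raw_count[is.na(tab$raw_count)] <- 0L
  compute_abundance(tab, members, sample_id = sample_id)
}

# uniform abundance table over the non-control members
uniform_abundance <- function(members, depth = 1000L, sample_id = "s") {
  counts <- setNames(rep(depth, nrow(members)), members$member_id)
  abundance_from_counts(members, counts, sample_id)
}
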