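# Target locus model. A locus is stored strand-normalized: the stored string
# is the coding strand, exons are 0-based half-open intervals on it and exon
# content is treated as pure CDS (UTRs are outside the model). Phase of an
# exon is the cumulative CDS length of the preceding exons mod 3.

#' Construct a target locus
#'
#' Builds the locus description used by cassette assembly: the
#' strand-normalized genomic string, its exon intervals (0-based, half-open),
#' the intronic Cas9 cut/integration site, and optional signal-peptide and
#' transmembrane-domain intervals used by [validate_integration_site()].
#' Exon phases are derived from cumulative exon lengths; if `cds_phase` is
#' supplied it is checked against them.
#'
#' @param locus_id Locus name.
#' @param sequence Coding-strand DNA string.
#' @param exons Data frame with 0-based half-open `start`, `end` columns,
#'   sorted and non-overlapping.
#' @param cut_site 0-based offset of the integration site; must fall strictly
#'   inside an intron.
#' @param signal_peptide,transmembrane Optional length-2 numeric vectors,
#'   0-based half-open nucleotide intervals.
#' @param strand `"+"` or `"-"`; records the original orientation only, the
#'   stored sequence is always coding-forward.
#' @param cds_phase Optional integer vector of per-exon phases (0-2) to
#'   cross-check.
#' @return An object of class `target_locus`.
#' @export
target_locus <- function(locus_id, sequence, exons, cut_site,
                         signal_peptide = NULL, transmembrane = NULL,
                         strand = "+", cds_phase = NULL) {
  sequence <- assert_dna(sequence)
  exons <- as_tibble(exons)[, c("start", "end")]
  n <- nchar(sequence)
  if (nrow(exons) < 1) abort("a locus needs at least one exon")
  for (i in seq_len(nrow(exons))) {
    check_interval(exons$start[i], exons$end[i], n, sprintf("exon %d", i))
  }
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    abort("exons must be sorted and non-overlapping")
  }
  widths <- exons$end - exons$start
  phase <- c(0L, cumsum(widths)[-length(widths)] %% 3L)
  if (!is.null(cds_phase) && !identical(as.integer(cds_phase), as.integer(phase))) {
    abort("supplied `cds_phase` is inconsistent with cumulative exon lengths")
  }
  if (is.null(cut_site) || is.na(cut_site)) abort("`cut_site` is required")
  intron_idx <- which_intron(exons, cut_site)
  if (is.na(intron_idx)) {
    abort("`cut_site` must lie strictly inside an intron")
  }
  for (iv in list(signal_peptide = signal_peptide, transmembrane = transmembrane)) {
    if (!is.null(iv) && (length(iv) != 2 || iv[1] >= iv[2])) {
      abort("signal_peptide/transmembrane must be length-2 (start < end) or NULL")
    }
  }
  structure(
    list(
      locus_id = locus_id, sequence = sequence, exons = exons,
      cds_phase = as.integer(phase), cut_site = as.integer(cut_site),
      signal_peptide = signal_peptide, transmembrane = transmembrane,
      strand = match.arg(strand, c("+", "-"))
    ),
    class = "target_locus"
  )
}

# index of the intron (following exon i) strictly containing `pos`, else NA
which_intron <- function(exons, pos) {
  if (nrow(exons) < 2) return(NA_integer_)
  for (i in seq_len(nrow(exons) - 1)) {
    if (pos > exons$end[i] && pos < exons$start[i + 1]) return(i)
  }
  NA_integer_
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("<target_locus> %s: %d nt, %d exons, cut site %d (intron %d)\n",
              x$locus_id, nchar(x$sequence), nrow(x$exons), x$cut_site,
              which_intron(x$exons, x$cut_site)))
  invisible(x)
}

#' Read a target locus from GFF3 + FASTA
#'
#' Imports exon features for one gene/transcript from a GFF3 file and the
#' matching sequence from a FASTA file, strand-normalizing on ingest: for
#' minus-strand genes the sequence is reverse-complemented and all intervals
#' flipped, so downstream logic is strand-agnostic. `cut_site` and the
#' optional domain intervals are given in strand-normalized coordinates.
#'
#' @param gff,fasta File paths.
#' @param cut_site Integration site, 0-based, strand-normalized.
#' @param locus_id Sequence name to use; defaults to the FASTA record name.
#' @inheritParams target_locus
#' @return A `target_locus`.
#' @export
read_target_locus <- function(gff, fasta, cut_site, locus_id = NULL,
                              signal_peptide = NULL, transmembrane = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) < 1) abort("FASTA file contains no sequence")
  seq_name <- sub("\\s.*", "", names(seqs)[1])
  sequence <- as.character(seqs[[1]])
  gr <- as.data.frame(rtracklayer::import(gff))
  gr <- gr[tolower(as.character(gr$type)) == "exon", , drop = FALSE]
  if (nrow(gr) == 0) abort("GFF3 file contains no exon features")
  strand <- as.character(gr$strand[1])
  if (strand == "*") strand <- "+"
  starts <- gr$start - 1L # GFF is 1-based closed
  ends <- gr$end
  n <- nchar(sequence)
  if (strand == "-") {
    sequence <- revcomp(sequence)
    tmp <- n - ends
    ends <- n - starts
    starts <- tmp
  }
  ord <- order(starts)
  target_locus(
    locus_id = locus_id %||% seq_name,
    sequence = sequence,
    exons = tibble(start = starts[ord], end = ends[ord]),
    cut_site = cut_site,
    signal_peptide = signal_peptide,
    transmembrane = transmembrane,
    strand = strand
  )
}

#' Check a candidate integration site
#'
#' A SEED integration site must be intronic (so that non-integrated alleles
#' splice normally) and, when the target's signal-peptide and transmembrane
#' intervals are known, must lie strictly between them so that truncation at
#' the insert removes surface expression of the target.
#'
#' @param locus A `target_locus`.
#' @return A tibble with columns `pass` (logical) and `reason`.
#' @export
#' @examples
#' toy <- target_locus("toy", strrep("ACGT", 60),
#'   exons = data.frame(start = c(0, 140), end = c(60, 200)),
#'   cut_site = 100
#' )
#' validate_integration_site(toy)
validate_integration_site <- function(locus) {
  stopifnot(inherits(locus, "target_locus"))
  cut <- locus$cut_site
  if (is.null(cut) || is.na(cut)) abort("locus has no cut site")
  intronic <- !is.na(which_intron(locus$exons, cut))
  if (!intronic) {
    return(tibble(pass = FALSE, reason = "not intronic"))
  }
  sp <- locus$signal_peptide
  tm <- locus$transmembrane
  if (!is.null(sp) && cut <= sp[2]) {
    return(tibble(pass = FALSE,
                  reason = "cut site not downstream of the signal peptide"))
  }
  if (!is.null(tm) && cut >= tm[1]) {
    return(tibble(pass = FALSE,
                  reason = "disruption would not remove surface expression (cut site not upstream of the transmembrane domain)"))
  }
  tibble(pass = TRUE, reason = "intronic cut site between signal peptide and transmembrane domain")
}
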