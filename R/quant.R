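# Amplicon quantification: anchor-scan and trim reads to the library region,
# count exact matches against member oligos, and report control-excluded
# abundances. No mismatches are permitted at any step, by design: the anchors
# and the members are exact sequences, and any read with an error anywhere in
# them is dropped or left unmapped.

#' Anchor specification
#'
#' The fixed sequences immediately flanking the variable library region in
#' the amplicon. Reads lacking either anchor (exact match) are discarded.
#'
#' @param upstream,downstream Anchor DNA strings.
#' @param min_length Minimum anchor length accepted (10 nt is a sensible
#'   floor for specificity; shorter anchors raise spurious matches).
#' @return A list of class `anchor_spec`.
#' @export
anchor_spec <- function(upstream, downstream, min_length = 10L) {
  upstream <- assert_dna(upstream)
  downstream <- assert_dna(downstream)
  if (nchar(upstream) < min_length || nchar(downstream) < min_length) {
    abort(sprintf("anchors must be at least %d nt", min_length))
  }
  structure(list(upstream = upstream, downstream = downstream),
            class = "anchor_spec")
}

#' Extract the library region from reads
#'
#' Scans each read for the upstream anchor and, downstream of it, the
#' downstream anchor (both exact); returns the substring strictly between
#' them. Reads missing either anchor, or whose anchors are out of order, get
#' `NA` with status `"no_anchor"`. First occurrences are used; additional
#' occurrences are counted in the `multi_anchor` attribute.
#'
#' @param reads Character vector of read sequences.
#' @param anchors An [anchor_spec()].
#' @return A tibble with columns `region` (chr, `NA` when discarded) and
#'   `status` (`"ok"`/`"no_anchor"`).
#' @export
extract_library_region <- function(reads, anchors) {
  stopifnot(inherits(anchors, "anchor_spec"))
  reads <- toupper(reads)
  up <- anchors$upstream
  down <- anchors$downstream
  up_pos <- regexpr(up, reads, fixed = TRUE)
  start <- ifelse(up_pos > 0, up_pos + nchar(up), NA_integer_)
  rest <- ifelse(is.na(start), "", substring(reads, start))
  down_pos <- regexpr(down, rest, fixed = TRUE)
  ok <- !is.na(start) & down_pos > 0
  region <- rep(NA_character_, length(reads))
  region[ok] <- substr(rest[ok], 1, down_pos[ok] - 1)
  multi <- sum(gregexpr_count(rest[ok], down) > 1L)
  out <- tibble(region = region,
                status = ifelse(ok, "ok", "no_anchor"))
  attr(out, "multi_anchor") <- multi
  out
}

gregexpr_count <- function(x, pattern) {
  if (length(x) == 0) return(integer())
  vapply(gregexpr(pattern, x, fixed = TRUE),
         function(h) if (h[1] < 0) 0L else length(h), integer(1))
}

#' Count regions against library members
#'
#' Exact matching only: each trimmed region increments the one member whose
#' oligo sequence it equals; everything else is unmapped. Errors if the
#' member table contains duplicate oligo sequences, which exact matching
#' cannot distinguish.
#'
#' @param regions Character vector of library-region sequences (NAs allowed,
#'   counted as unmapped input upstream).
#' @param members Member tibble with `member_id` and `oligo_sequence`.
#' @return A tibble `member_id`, `raw_count`, with attribute `unmapped`.
#' @export
count_members <- function(regions, members) {
  if (anyDuplicated(members$oligo_sequence)) {
    abort("member table contains duplicate oligo sequences; exact matching cannot distinguish them")
  }
  regions <- regions[!is.na(regions)]
  idx <- match(regions, members$oligo_sequence)
  counts <- tabulate(idx, nbins = nrow(members))
  out <- tibble(member_id = members$member_id, raw_count = counts)
  attr(out, "unmapped") <- sum(is.na(idx))
  out
}

#' Control-excluded member abundances
#'
#' Abundance of a non-control member is its read count divided by the total
#' reads mapped to non-control members. Stop-codon and deletion controls are
#' excluded from the denominator and get `NA` abundance (their raw counts are
#' kept); synonymous members count as ordinary members.
#'
#' @param counts Count tibble from [count_members()].
#' @param members Member tibble (for `control_class`).
#' @param sample_id Label recorded in the output.
#' @return An abundance tibble: `sample_id`, `member_id`, `position`,
#'   `variant_aa`, `codon`, `control_class`, `raw_count`, `abundance`; totals
#'   are attached as attribute `totals`.
#' @export
compute_abundance <- function(counts, members, sample_id = "sample") {
  if (any(counts$raw_count < 0)) abort("negative counts")
  out <- members |>
    select(any_of(c("member_id", "position", "native_aa", "variant_aa",
                    "codon", "control_class"))) |>
    left_join(counts, by = "member_id") |>
    mutate(sample_id = sample_id, .before = 1)
  if (any(is.na(out$raw_count))) {
    abort("count table does not cover the member table")
  }
  is_ctrl <- out$control_class %in% c("stop", "deletion")
  denom <- sum(out$raw_count[!is_ctrl])
  if (denom == 0) abort("no usable reads: all mapped reads are on controls")
  out$abundance <- ifelse(is_ctrl, NA_real_, out$raw_count / denom)
  attr(out, "totals") <- list(
    reads_mapped = sum(out$raw_count),
    reads_control = sum(out$raw_count[is_ctrl]),
    reads_noncontrol = denom
  )
  out
}

#' @importFrom dplyr any_of
NULL

#' Quantify an amplicon FASTQ against a member library
#'
#' Full read-processing workflow: read FASTQ (optionally gzipped; base
#' qualities are ignored), extract the library region between the anchors
#' (trying each read as given, then reverse-complemented), count exact
#' matches and compute control-excluded abundances. In paired-end mode the
#' mate is consulted only for fragments whose first read yielded no anchors,
#' so each fragment is counted at most once.
#'
#' @param fastq Path to the FASTQ file (read 1).
#' @param members Member tibble.
#' @param anchors An [anchor_spec()].
#' @param fastq2 Optional path to the mate FASTQ (read 2).
#' @param sample_id Label for the output table.
#' @return Abundance tibble (see [compute_abundance()]) with attribute
#'   `stats`: `reads_in`, `reads_anchored`, `reads_mapped`, `reads_control`,
#'   `reads_unmapped`, `reads_no_anchor`.
#' @export
quantify_amplicons <- function(fastq, members, anchors, fastq2 = NULL,
                               sample_id = basename(fastq)) {
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  n_in <- length(reads)
  reg <- extract_oriented(reads, anchors)
  if (!is.null(fastq2)) {
    mates <- as.character(Biostrings::readDNAStringSet(fastq2, format = "fastq"))
    if (length(mates) != n_in) abort("paired FASTQ files differ in read count")
    miss <- is.na(reg)
    if (any(miss)) reg[miss] <- extract_oriented(revcomp(mates[miss]), anchors)
  }
  counts <- count_members(reg, members)
  ab <- compute_abundance(counts, members, sample_id = sample_id)
  totals <- attr(ab, "totals")
  attr(ab, "stats") <- list(
    reads_in = n_in,
    reads_anchored = sum(!is.na(reg)),
    reads_no_anchor = sum(is.na(reg)),
    reads_mapped = totals$reads_mapped,
    reads_unmapped = attr(counts, "unmapped"),
    reads_control = totals$reads_control
  )
  ab
}

# anchor extraction on the read as given, falling back to its reverse
# complement; returns NA where neither orientation contains both anchors
extract_oriented <- function(reads, anchors) {
  fwd <- extract_library_region(reads, anchors)
  reg <- fwd$region
  miss <- is.na(reg)
  if (any(miss)) {
    rev <- extract_library_region(revcomp(reads[miss]), anchors)
    reg[miss] <- rev$region
  }
  reg
}
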