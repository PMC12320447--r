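# Minimal GenBank flat-file emission for annotated cassettes, plus a parser
# for the subset this package writes (sequence + misc_feature/label pairs).
# Written in-package because no installed dependency emits GenBank.

#' Write a cassette as an annotated GenBank record
#'
#' Emits a flat-file GenBank record whose `misc_feature` entries mirror the
#' cassette's annotation table (converted to GenBank's 1-based closed
#' intervals). [read_genbank()] parses the same subset back, and the
#' round trip preserves sequence and annotation intervals exactly.
#'
#' @param cassette A `seed_cassette`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(cassette, path) {
  stopifnot(inherits(cassette, "seed_cassette"))
  seqn <- tolower(cassette$sequence)
  n <- nchar(seqn)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN %s",
            substr(gsub("\\s", "_", cassette$locus_id), 1, 16), n,
            format(Sys.Date(), "%d-%b-%Y")),
    sprintf("DEFINITION  SEED cassette (%s) for locus %s.",
            cassette$variant, cassette$locus_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n)
  )
  for (i in seq_len(nrow(cassette$annotations))) {
    a <- cassette$annotations[i, ]
    lines <- c(lines,
               sprintf("     misc_feature    %d..%d", a$start + 1L, a$end),
               sprintf("                     /label=\"%s\"", a$label))
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1, n, 60)
  for (s in starts) {
    chunk <- substr(seqn, s, min(s + 59, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank record written by [write_genbank()]
#'
#' @param path Path to a GenBank flat file.
#' @return A list with `sequence` (upper-case DNA) and `annotations`
#'   (tibble of `label`, `start`, `end`, 0-based half-open).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  feat <- grep("^     misc_feature", lines)
  labels <- character()
  starts <- integer()
  ends <- integer()
  for (i in feat) {
    loc <- regmatches(lines[i], regexec("(\\d+)\\.\\.(\\d+)", lines[i]))[[1]]
    lab <- sub('.*?/label="([^"]*)".*', "\\1", lines[i + 1])
    labels <- c(labels, lab)
    starts <- c(starts, as.integer(loc[2]) - 1L)
    ends <- c(ends, as.integer(loc[3]))
  }
  ori <- which(lines == "ORIGIN")
  if (length(ori) != 1) abort("not a GenBank record: no ORIGIN section")
  seq_lines <- lines[(ori + 1):(which(lines == "//") - 1)]
  seqn <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  list(sequence = seqn,
       annotations = tibble(label = labels, start = starts, end = ends))
}

#' Write a cassette as FASTA
#'
#' @param cassette A `seed_cassette`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cassette_fasta <- function(cassette, path) {
  stopifnot(inherits(cassette, "seed_cassette"))
  x <- Biostrings::DNAStringSet(cassette$sequence)
  names(x) <- sprintf("%s_%s", cassette$locus_id, cassette$variant)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
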