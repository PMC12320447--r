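# Substitution matrices in NCBI text format (as distributed with BLAST):
# '#' comment lines, a header row of residue letters, then one row per
# residue with integer scores.

#' Read a substitution matrix in NCBI text format
#'
#' Parses matrices as distributed with BLAST (e.g. BLOSUM80): comment lines
#' start with `#`, the first non-comment line names the columns and each
#' following line starts with the row residue.
#'
#' @param path Path to the matrix file.
#' @return A symmetric integer matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort("not a substitution matrix: no data rows")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(lengths(rows) != length(header) + 1L)) {
    abort("malformed substitution matrix: row length does not match header")
  }
  rn <- vapply(rows, `[[`, character(1), 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  dimnames(m) <- list(rn, header)
  if (!identical(rownames(m), colnames(m))) {
    abort("malformed substitution matrix: row and column names differ")
  }
  std <- intersect(rownames(m), AA_STANDARD)
  if (!isTRUE(all.equal(m[std, std], t(m[std, std])))) {
    abort("substitution matrix is not symmetric over the standard residues")
  }
  m
}

#' Bundled BLOSUM80 matrix
#'
#' The published BLOSUM80 substitution matrix, shipped as an NCBI-format text
#' fixture and parsed with [read_substitution_matrix()].
#'
#' @return A symmetric integer matrix.
#' @export
blosum80 <- function() {
  read_substitution_matrix(
    system.file("extdata", "BLOSUM80.txt", package = "seedscreen",
                mustWork = TRUE)
  )
}
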