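# Mutagenesis library design: BLOSUM-guided scanning libraries with homolog
# augmentation and built-in controls, and single-position saturation
# libraries from degenerate codons. A library is a tibble of members; the
# oligo of a member is the reference window with exactly one codon edited
# (or removed, for deletions).

#' Scanning-library design configuration
#'
#' Defaults mirror a residue-scanning knock-in library: at every non-alanine
#' residue, alanine plus the four least-disruptive substitutions by BLOSUM
#' score; five BLOSUM picks at alanine residues; two codons per substitution
#' where the genetic code allows; one synonymous control per position; a
#' deletion control at every position; stop controls at five positions
#' (evenly spaced across the window unless given).
#'
#' @param window Length-2 inclusive residue interval in protein numbering
#'   (default 101-150).
#' @param n_blosum_nonala,n_blosum_ala Number of BLOSUM picks beyond/for
#'   alanine.
#' @param codons_per_sub Codons synthesised per substitution.
#' @param synonymous_per_position Synonymous controls per position (0 or 1).
#' @param deletion_at_every_position Include single-residue deletions.
#' @param stop_positions Residue numbers that get a stop-codon control;
#'   `NULL` picks 5 evenly spaced positions.
#' @param usage Codon usage table (see [codon_usage_human()]).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window = c(101L, 150L), n_blosum_nonala = 4L,
                        n_blosum_ala = 5L, codons_per_sub = 2L,
                        synonymous_per_position = 1L,
                        deletion_at_every_position = TRUE,
                        stop_positions = NULL,
                        usage = codon_usage_human()) {
  window <- as.integer(window)
  if (length(window) != 2 || window[1] > window[2]) {
    abort("`window` must be an inclusive residue interval c(first, last)")
  }
  if (is.null(stop_positions)) {
    stop_positions <- unique(round(seq(window[1], window[2], length.out = 5)))
  }
  stop_positions <- as.integer(stop_positions)
  if (any(stop_positions < window[1] | stop_positions > window[2])) {
    abort("`stop_positions` must lie inside the window")
  }
  counts <- c(n_blosum_nonala, n_blosum_ala, codons_per_sub,
              synonymous_per_position)
  if (any(counts < 0)) abort("counts must be non-negative")
  structure(
    list(window = window, n_blosum_nonala = as.integer(n_blosum_nonala),
         n_blosum_ala = as.integer(n_blosum_ala),
         codons_per_sub = as.integer(codons_per_sub),
         synonymous_per_position = as.integer(synonymous_per_position),
         deletion_at_every_position = isTRUE(deletion_at_every_position),
         stop_positions = sort(stop_positions), usage = usage),
    class = "scan_config"
  )
}

#' BLOSUM-guided substitution picks for one residue
#'
#' For a non-alanine residue, returns alanine plus the `n` other residues
#' with the highest substitution score against the native (the least
#' disruptive changes); for alanine itself, the top `n_ala` non-alanine
#' residues. Ties in score are broken alphabetically by one-letter code, so
#' the pick is deterministic.
#'
#' @param native_aa Native residue (one letter, standard alphabet).
#' @param matrix Substitution matrix, e.g. [blosum80()].
#' @param n Picks in addition to alanine at non-alanine residues.
#' @param n_ala Picks at alanine residues.
#' @return Character vector of substitution residues (alanine first for
#'   non-alanine natives, then by descending score).
#' @export
#' @examples
#' pick_blosum_substitutions("D", blosum80())
pick_blosum_substitutions <- function(native_aa, matrix = blosum80(),
                                      n = 4L, n_ala = 5L) {
  if (!is.character(native_aa) || length(native_aa) != 1L ||
      !(native_aa %in% AA_STANDARD)) {
    abort("`native_aa` must be a single standard amino-acid letter")
  }
  if (!native_aa %in% rownames(matrix)) {
    abort("`native_aa` is not covered by the substitution matrix")
  }
  cand <- setdiff(intersect(AA_STANDARD, colnames(matrix)), native_aa)
  if (native_aa != "A") cand <- setdiff(cand, "A")
  scores <- matrix[native_aa, cand]
  picked <- cand[order(-scores, cand)]
  if (native_aa == "A") {
    head(picked, n_ala)
  } else {
    c("A", head(picked, n))
  }
}

#' Substitutions observed in a homolog alignment column
#'
#' Returns residues seen at this alignment column in homologous sequences
#' that are not the native residue, not gaps and not already chosen, sorted
#' alphabetically. These augment the BLOSUM picks with evolutionarily
#' tolerated substitutions.
#'
#' @param column Character vector of alignment-column residues (may contain
#'   `-` or `.` gap characters).
#' @param native_aa Native residue at this position.
#' @param already_chosen Residues already in the library at this position.
#' @return Character vector (possibly empty) of additional residues.
#' @export
augment_from_homologs <- function(column, native_aa,
                                  already_chosen = character()) {
  if (length(column) == 0) abort("empty homolog alignment column")
  col <- toupper(unlist(strsplit(column, "")))
  col <- col[col %in% AA_STANDARD]
  sort(setdiff(unique(col), c(native_aa, already_chosen)))
}

#' Design a scanning mutagenesis library
#'
#' Designs one oligo library over the residue window encoded by
#' `reference_dna`: per position, the BLOSUM picks (see
#' [pick_blosum_substitutions()]) plus any homolog-observed substitutions not
#' already chosen, with up to `codons_per_sub` codons per substitution ranked
#' by usage; plus synonymous, deletion and stop controls per the
#' configuration. Every oligo is the reference with exactly the designed
#' codon edited, and is verified by re-translation before the table is
#' returned.
#'
#' @param reference_dna In-frame DNA encoding exactly the window residues.
#' @param homologs Optional character vector of aligned homolog protein
#'   sequences, each the same length as the window.
#' @param matrix Substitution matrix (default [blosum80()]).
#' @param config A [scan_config()].
#' @return A tibble with columns `member_id`, `position`, `native_aa`,
#'   `variant_aa`, `codon`, `control_class`, `oligo_sequence`. The reference
#'   and configuration are attached as attributes `reference` and `config`.
#' @export
design_scanning_library <- function(reference_dna, homologs = NULL,
                                    matrix = blosum80(),
                                    config = scan_config()) {
  reference_dna <- assert_dna(reference_dna)
  win <- config$window
  n_res <- win[2] - win[1] + 1L
  if (nchar(reference_dna) != 3L * n_res) {
    abort(sprintf("reference encodes %d residues but the window spans %d",
                  nchar(reference_dna) %/% 3L, n_res))
  }
  ref_aa <- translate_dna(reference_dna)
  if (grepl("\\*", ref_aa)) abort("reference contains an in-frame stop codon")
  ref_codons <- split_codons(reference_dna)
  if (!is.null(homologs)) {
    homologs <- toupper(homologs)
    if (any(nchar(homologs) != n_res)) {
      abort("homolog alignment length does not match the window")
    }
  }

  rows <- list()
  for (i in seq_len(n_res)) {
    pos <- win[1] + i - 1L
    native <- substr(ref_aa, i, i)
    subs <- pick_blosum_substitutions(native, matrix,
                                      n = config$n_blosum_nonala,
                                      n_ala = config$n_blosum_ala)
    if (!is.null(homologs)) {
      column <- substr(homologs, i, i)
      subs <- c(subs, augment_from_homologs(column, native, subs))
    }
    for (aa in subs) {
      for (codon in assign_codons(aa, config$codons_per_sub, config$usage)) {
        rows[[length(rows) + 1L]] <- list(
          member_id = sprintf("%s%d%s_%s", native, pos, aa, codon),
          position = pos, native_aa = native, variant_aa = aa,
          codon = codon, control_class = "substitution",
          oligo_sequence = swap_codon(ref_codons, i, codon)
        )
      }
    }
    if (config$synonymous_per_position > 0L) {
      syn <- assign_codons(native, config$synonymous_per_position,
                           config$usage, exclude = ref_codons[i])
      for (codon in syn) {
        rows[[length(rows) + 1L]] <- list(
          member_id = sprintf("%s%dsyn_%s", native, pos, codon),
          position = pos, native_aa = native, variant_aa = native,
          codon = codon, control_class = "synonymous",
          oligo_sequence = swap_codon(ref_codons, i, codon)
        )
      }
    }
    if (config$deletion_at_every_position) {
      rows[[length(rows) + 1L]] <- list(
        member_id = sprintf("%s%ddel", native, pos),
        position = pos, native_aa = native, variant_aa = "",
        codon = "", control_class = "deletion",
        oligo_sequence = paste(ref_codons[-i], collapse = "")
      )
    }
    if (pos %in% config$stop_positions) {
      codon <- assign_codons("*", 1L, config$usage)
      rows[[length(rows) + 1L]] <- list(
        member_id = sprintf("%s%dstop_%s", native, pos, codon),
        position = pos, native_aa = native, variant_aa = "*",
        codon = codon, control_class = "stop",
        oligo_sequence = swap_codon(ref_codons, i, codon)
      )
    }
  }
  members <- bind_rows(lapply(rows, as_tibble))
  check_library(members, reference_dna, win)
  attr(members, "reference") <- reference_dna
  attr(members, "config") <- config
  members
}

swap_codon <- function(ref_codons, i, codon) {
  out <- ref_codons
  out[i] <- codon
  paste(out, collapse = "")
}

#' Design a single-position saturation library
#'
#' Expands a degenerate codon scheme (default `NNN`) at one residue of the
#' reference window: one member per concrete codon, annotated with its
#' translation. Codons reproducing the native residue are classed
#' `synonymous`, stop codons `stop`, all others `substitution`.
#'
#' @inheritParams design_scanning_library
#' @param position Residue number (in the window's own numbering).
#' @param scheme 3-letter IUPAC degenerate codon.
#' @param window Inclusive residue interval the reference encodes.
#' @return A member tibble as in [design_scanning_library()].
#' @export
#' @examples
#' ref <- strrep("GAC", 3)
#' nrow(design_saturation_library(ref, 2, "NNN", window = c(1, 3))) # 64
design_saturation_library <- function(reference_dna, position, scheme = "NNN",
                                      window = c(101L, 150L)) {
  reference_dna <- assert_dna(reference_dna)
  window <- as.integer(window)
  i <- as.integer(position) - window[1] + 1L
  n_res <- window[2] - window[1] + 1L
  if (nchar(reference_dna) != 3L * n_res) {
    abort("reference length does not match the window")
  }
  if (i < 1L || i > n_res) abort("`position` is outside the window")
  ref_codons <- split_codons(reference_dna)
  native <- GENETIC_CODE_TABLE[[ref_codons[i]]]
  codons <- expand_degenerate(scheme)
  members <- tibble(
    codon = codons,
    variant_aa = unname(GENETIC_CODE_TABLE[codons]),
    position = as.integer(position),
    native_aa = native
  ) |>
    mutate(
      control_class = dplyr::case_when(
        .data$variant_aa == "*" ~ "stop",
        .data$variant_aa == native ~ "synonymous",
        TRUE ~ "substitution"
      ),
      member_id = sprintf("%s%d%s_%s", native, position,
                          ifelse(.data$variant_aa == "*", "stop", .data$variant_aa),
                          .data$codon),
      oligo_sequence = vapply(.data$codon, function(cd) swap_codon(ref_codons, i, cd),
                              character(1))
    ) |>
    select("member_id", "position", "native_aa", "variant_aa", "codon",
           "control_class", "oligo_sequence")
  check_library(members, reference_dna, window)
  attr(members, "reference") <- reference_dna
  members
}

# design-time sanity check: ids unique, each oligo realizes its declared edit
check_library <- function(members, reference_dna, window) {
  if (anyDuplicated(members$member_id)) {
    abort("internal design error: duplicated member ids")
  }
  v <- validate_library(members, reference_dna, window)
  if (!all(v$ok)) {
    abort(sprintf("internal design error: %d oligos fail validation (first: %s)",
                  sum(!v$ok), v$member_id[!v$ok][1]))
  }
  dup <- duplicated(members$oligo_sequence)
  if (any(dup)) {
    warning(sprintf("%d members share an oligo sequence with another member (e.g. %s); exact-match counting cannot distinguish them",
                    sum(dup), members$member_id[dup][1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a library member table against its reference
#'
#' Re-derives what each oligo encodes and checks it against the declared
#' member annotation: substitutions must translate to `variant_aa` at
#' `position` (and nowhere else differ), synonymous members must translate
#' identically to the reference, deletions must remove exactly the native
#' codon, stop members must place a stop at the position. Useful both as an
#' internal design check and to audit externally supplied member tables.
#'
#' @param members Member tibble (as designed, or read from TSV).
#' @param reference_dna Reference window DNA.
#' @param window Inclusive residue interval of the reference.
#' @return The member table with logical `ok` and `reason` columns.
#' @export
validate_library <- function(members, reference_dna, window) {
  reference_dna <- assert_dna(reference_dna)
  window <- as.integer(window)
  ref_aa <- translate_dna(reference_dna)
  n_res <- nchar(ref_aa)
  one <- function(position, variant_aa, control_class, oligo_sequence, ...) {
    i <- position - window[1] + 1L
    if (i < 1L || i > n_res) return("position outside window")
    if (control_class == "deletion") {
      if (nchar(oligo_sequence) != 3L * (n_res - 1L)) {
        return("deletion oligo has wrong length")
      }
      expect <- paste0(substr(ref_aa, 1, i - 1), substr(ref_aa, i + 1, n_res))
      if (translate_dna(oligo_sequence) != expect) {
        return("deletion oligo does not remove exactly one residue")
      }
      return("")
    }
    if (nchar(oligo_sequence) != 3L * n_res) return("oligo has wrong length")
    aa <- translate_dna(oligo_sequence)
    want <- paste0(substr(ref_aa, 1, i - 1), variant_aa,
                   substr(ref_aa, i + 1, n_res))
    if (aa != want) return("oligo translation does not match declared variant")
    same <- split_codons(oligo_sequence) == split_codons(reference_dna)
    if (any(!same[-i])) return("oligo differs from reference outside the designed codon")
    ""
  }
  reasons <- purrr::pmap_chr(members, one)
  members |>
    mutate(ok = reasons == "", reason = reasons)
}

#' Read / write library member tables
#'
#' Plain TSV with the member columns used throughout the package.
#'
#' @param members Member tibble.
#' @param path File path.
#' @return `read_library_tsv()` returns the member tibble;
#'   `write_library_tsv()` returns `path` invisibly.
#' @export
write_library_tsv <- function(members, path) {
  utils::write.table(members, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = "character")) |>
    mutate(position = as.integer(.data$position))
}
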