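# SEED cassette assembly. A cassette inserts at an intronic cut site:
# LHA + [SA block | filler | P2A | payload | 3'-variant elements] + RHA.
# The synthetic exon (everything between the SA's terminal AG and the splice
# donor, or the poly(A) signal) joins the endogenous reading frame, so filler
# nucleotides keep the spliced transcript in frame on both sides.

P2A_DNA <- paste0(
  "GGAAGCGGAGCTACTAACTTCAGCCTGCTGAAGCAGGCTGGA",
  "GACGTGGAGGAGAACCCTGGACCT"
)
P2A_AA <- "GSGATNFSLLKQAGDVEENPGP"

# synthetic defaults for elements whose published sources are vectors, not
# printed sequences: branchpoint + polypyrimidine tract + acceptor AG ...
DEFAULT_SA_BLOCK <- "CTGACCTCTTCTCTTCCTCCCACAG"
# ... bovine-growth-hormone-style poly(A) signal block ...
DEFAULT_POLYA <- "AATAAAATGAGGAAATTGCATCGCATTGTCTGAGTAGGTGTCATTCT"
# ... and a minimal TATA promoter for the promoter-driven payload variant.
DEFAULT_PROMOTER <- "GGGCGGAGTTAGGGCGGAGCCAATCTATATAAGCAGAGCTCGTTTAGTGAACCGTCAGATC"

KOZAK_ATG <- "GCCACCATG"

THREE_PRIME_VARIANTS <- c("P2A_SD", "OPEN_READTHROUGH", "POLYA",
                          "EXOGENOUS_PROMOTER_STOP")

#' Splice-element configuration for cassette assembly
#'
#' Collects the synthetic sequence elements used by [assemble_seed()]. All
#' have documented defaults; in `strict` mode the splice-acceptor block must
#' be supplied explicitly (its default is a synthetic stand-in, and real
#' designs should provide the acceptor block of their chosen vector).
#'
#' @param sa_block Splice-acceptor block: branchpoint + polypyrimidine tract,
#'   ending in the acceptor `AG`.
#' @param p2a P2A coding sequence (GSG-linker form by default); must be an
#'   in-frame, stop-free ORF.
#' @param polya Poly(A) signal block (must contain `AATAAA`).
#' @param promoter Promoter for the `EXOGENOUS_PROMOTER_STOP` variant.
#' @param sd_length Number of intron nucleotides copied from the target
#'   intron's donor end to form the synthetic splice donor.
#' @param strict Require `sa_block` to be given explicitly.
#' @return A list of class `seed_elements`.
#' @export
seed_elements <- function(sa_block = NULL, p2a = P2A_DNA, polya = DEFAULT_POLYA,
                          promoter = DEFAULT_PROMOTER, sd_length = 9L,
                          strict = FALSE) {
  if (strict && is.null(sa_block)) {
    abort("strict mode: `sa_block` must be supplied explicitly")
  }
  sa_block <- assert_dna(sa_block %||% DEFAULT_SA_BLOCK, "sa_block")
  if (!grepl("AG$", sa_block)) abort("`sa_block` must end in the acceptor AG")
  p2a <- assert_dna(p2a, "p2a")
  if (nchar(p2a) %% 3 != 0 || grepl("\\*", translate_dna(p2a))) {
    abort("`p2a` must be an in-frame, stop-free coding sequence")
  }
  polya <- assert_dna(polya, "polya")
  if (!grepl("AATAAA", polya)) abort("`polya` must contain an AATAAA signal")
  structure(
    list(sa_block = sa_block, p2a = p2a, polya = polya,
         promoter = assert_dna(promoter, "promoter"),
         sd_length = as.integer(sd_length)),
    class = "seed_elements"
  )
}

#' Filler lengths that close the reading frame
#'
#' The synthetic exon interrupts the target CDS mid-codon. Given the number
#' of leftover nucleotides carried into the junction by the upstream exons
#' and the phase in which the first resumed downstream exon must land, this
#' returns the 5' filler (downstream of the splice acceptor) and 3' filler
#' (upstream of the splice donor) lengths, each 0-2 nt.
#'
#' @param upstream_leftover_nt Cumulative upstream CDS length mod 3 (0-2).
#' @param downstream_required_phase Phase of the first downstream exon (0-2).
#' @return A tibble with columns `five_prime` and `three_prime`.
#' @export
#' @examples
#' frame_fill(1, 0) # 2 nt after the acceptor, none before the donor
frame_fill <- function(upstream_leftover_nt, downstream_required_phase) {
  lo <- as.integer(upstream_leftover_nt)
  ph <- as.integer(downstream_required_phase)
  if (any(is.na(lo)) || any(lo < 0L | lo > 2L) ||
      any(is.na(ph)) || any(ph < 0L | ph > 2L)) {
    abort("inputs must be integers in 0-2")
  }
  tibble(five_prime = (3L - lo) %% 3L, three_prime = ph)
}

# deterministic filler sequence: enumerate candidates in A<C<G<T order and
# take the first whose junction codon(s) contain no stop
choose_filler <- function(len, prev_tail = "", next_head = "") {
  if (len == 0) return("")
  bases <- c("A", "C", "G", "T")
  cands <- bases
  if (len == 2) cands <- as.vector(outer(bases, bases, paste0))
  for (f in sort(cands)) {
    junction <- paste0(prev_tail, f, next_head)
    keep <- nchar(junction) - nchar(junction) %% 3
    codons <- if (keep > 0) split_codons(substr(junction, 1, keep)) else character()
    if (!any(is_stop_codon(codons))) return(f)
  }
  abort("no stop-free filler exists for this junction") # unreachable for len<3
}

#' Assemble a SEED cassette
#'
#' Builds the full homology-directed repair template for `locus`: left
#' homology arm, splice-acceptor block, frame filler, P2A, payload ORF, the
#' chosen 3' variant and the right homology arm, with an annotation table
#' covering the whole cassette.
#'
#' The four 3' variants are: `P2A_SD` (second P2A then a splice donor, so the
#' payload is released and the target's own downstream exons and poly(A) are
#' reused), `OPEN_READTHROUGH` (no 3' P2A; the payload reading frame runs on
#' into the downstream endogenous exons, e.g. to complete a receptor constant
#' domain), `POLYA` (stop codon plus poly(A) signal, no donor) and
#' `EXOGENOUS_PROMOTER_STOP` (the spliced target transcript stops right after
#' the acceptor; the payload gets its own promoter).
#'
#' @param locus A `target_locus`.
#' @param payload In-frame, stop-free payload ORF (DNA).
#' @param variant One of `"P2A_SD"`, `"OPEN_READTHROUGH"`, `"POLYA"`,
#'   `"EXOGENOUS_PROMOTER_STOP"`.
#' @param arm_length Homology arm length in nt (default 500, typical AAV
#'   repair-template practice).
#' @param elements A [seed_elements()] configuration.
#' @return An object of class `seed_cassette`.
#' @export
assemble_seed <- function(locus, payload, variant = "P2A_SD",
                          arm_length = 500L, elements = seed_elements()) {
  stopifnot(inherits(locus, "target_locus"))
  variant <- match.arg(variant, THREE_PRIME_VARIANTS)
  payload <- assert_dna(payload)
  if (nchar(payload) %% 3 != 0) {
    abort(sprintf("payload length %d is not divisible by 3", nchar(payload)))
  }
  if (grepl("\\*", translate_dna(payload))) {
    abort("payload contains an in-frame stop codon")
  }
  arm_length <- as.integer(arm_length)
  if (arm_length <= 0) abort("`arm_length` must be positive")
  cut <- locus$cut_site
  n <- nchar(locus$sequence)
  if (cut - arm_length < 0 || cut + arm_length > n) {
    abort("homology arms extend past the locus sequence")
  }
  lha <- substr(locus$sequence, cut - arm_length + 1, cut)
  rha <- substr(locus$sequence, cut + 1, cut + arm_length)

  up <- locus$exons[locus$exons$end <= cut, , drop = FALSE]
  down <- locus$exons[locus$exons$start >= cut, , drop = FALSE]
  up_cds <- paste(substring(locus$sequence, up$start + 1, up$end), collapse = "")
  leftover <- nchar(up_cds) %% 3L
  fill <- frame_fill(leftover, leftover) # next exon's phase == leftover
  f5 <- choose_filler(fill$five_prime,
                      prev_tail = substr(up_cds, nchar(up_cds) - leftover + 1,
                                         nchar(up_cds)))
  intron_start <- locus$exons$end[which_intron(locus$exons, cut)]
  sd_seq <- substr(locus$sequence, intron_start + 1,
                   intron_start + elements$sd_length)
  down_head <- substr(locus$sequence, down$start[1] + 1, down$start[1] + 3)

  parts <- c(left_homology_arm = lha, sa_block = elements$sa_block)
  if (variant %in% c("P2A_SD", "OPEN_READTHROUGH", "POLYA")) {
    parts <- c(parts, five_prime_filler = f5, p2a_5 = elements$p2a,
               payload_orf = payload)
  }
  if (variant == "P2A_SD") {
    f3 <- choose_filler(fill$three_prime, next_head = down_head)
    parts <- c(parts, p2a_3 = elements$p2a, three_prime_filler = f3,
               splice_donor = sd_seq)
  } else if (variant == "OPEN_READTHROUGH") {
    f3 <- choose_filler(fill$three_prime, next_head = down_head)
    parts <- c(parts, three_prime_filler = f3, splice_donor = sd_seq)
  } else if (variant == "POLYA") {
    f3 <- ""
    parts <- c(parts, stop_codon = "TAA", polya_signal = elements$polya)
  } else { # EXOGENOUS_PROMOTER_STOP
    f3 <- ""
    kozak <- if (startsWith(payload, "ATG")) "" else KOZAK_ATG
    parts <- c(parts, five_prime_filler = f5, stop_codon = "TAA",
               promoter = elements$promoter)
    if (nzchar(kozak)) parts <- c(parts, kozak = kozak)
    parts <- c(parts, payload_orf = payload, payload_stop = "TAA",
               polya_signal = elements$polya)
  }
  parts <- c(parts, right_homology_arm = rha)
  parts <- parts[nzchar(parts)]

  widths <- nchar(parts)
  ends <- unname(cumsum(widths))
  ann <- tibble(label = names(parts), start = ends - unname(widths),
                end = ends)
  insert <- paste(parts[!names(parts) %in%
                          c("left_homology_arm", "right_homology_arm")],
                  collapse = "")

  structure(
    list(
      locus_id = locus$locus_id, variant = variant,
      sequence = paste(parts, collapse = ""), insert = insert,
      left_homology_arm = lha, right_homology_arm = rha,
      sa_block = elements$sa_block, p2a = elements$p2a,
      polya = elements$polya, promoter = elements$promoter,
      sd_seq = sd_seq, five_prime_filler = f5, three_prime_filler = f3,
      payload = payload, arm_length = arm_length, annotations = ann
    ),
    class = "seed_cassette"
  )
}

#' @export
print.seed_cassette <- function(x, ...) {
  cat(sprintf("<seed_cassette> %s [%s]: %d nt (%d nt insert, %d nt arms)\n",
              x$locus_id, x$variant, nchar(x$sequence), nchar(x$insert),
              x$arm_length))
  print(x$annotations)
  invisible(x)
}

#' Simulate splicing of an integrated cassette
#'
#' Reconstructs the edited locus, honours exactly one synthetic splice
#' acceptor/donor pair (the acceptor block is located by sequence, the donor
#' is the last donor-motif occurrence inside the insert) and rebuilds the
#' mature transcript: upstream exons, the synthetic exon, and - for donor
#' variants - the endogenous downstream exons. The simulated CDS must be a
#' multiple of 3 and must still encode the payload verbatim; violations are
#' errors, which is the point of this function: it is the frame validator for
#' assembled cassettes.
#'
#' @param locus The `target_locus` the cassette was assembled for.
#' @param cassette A `seed_cassette` (possibly manipulated, e.g. to test
#'   corruption detection).
#' @return An object of class `spliced_transcript` with fields `mature_mrna`,
#'   `cds`, `protein`, `p2a_cleavage_offsets` and, for the promoter-driven
#'   variant, `target_protein` (the truncated target translation).
#' @export
simulate_splice <- function(locus, cassette) {
  stopifnot(inherits(locus, "target_locus"), inherits(cassette, "seed_cassette"))
  cut <- locus$cut_site
  seqn <- locus$sequence
  edited <- paste0(substr(seqn, 1, cut), cassette$insert,
                   substr(seqn, cut + 1, nchar(seqn)))
  ins_start <- cut + 1L
  ins_end <- cut + nchar(cassette$insert)

  sa_hits <- find_all(edited, cassette$sa_block)
  sa_hits <- sa_hits[sa_hits >= ins_start & sa_hits <= ins_end]
  if (length(sa_hits) == 0) abort("splice acceptor block not found in cassette")
  exon_start <- sa_hits[1] + nchar(cassette$sa_block)

  up <- locus$exons[locus$exons$end <= cut, , drop = FALSE]
  down <- locus$exons[locus$exons$start >= cut, , drop = FALSE]
  up_cds <- paste(substring(seqn, up$start + 1, up$end), collapse = "")
  down_cds <- paste(substring(seqn, down$start + 1, down$end), collapse = "")
  payload_aa <- translate_dna(cassette$payload)

  variant <- cassette$variant
  if (variant %in% c("P2A_SD", "OPEN_READTHROUGH")) {
    sd_hits <- find_all(edited, cassette$sd_seq)
    sd_hits <- sd_hits[sd_hits >= exon_start & sd_hits <= ins_end]
    if (length(sd_hits) == 0) abort("splice donor not found in cassette")
    syn_exon <- substr(edited, exon_start, max(sd_hits) - 1)
    mature <- paste0(up_cds, syn_exon, down_cds)
    cds <- mature
    if (nchar(cds) %% 3 != 0) {
      abort(sprintf("frame violation: spliced CDS length %d is not a multiple of 3",
                    nchar(cds)))
    }
    protein <- translate_dna(cds)
    protein <- sub("\\*.*$", "", protein)
    target_protein <- NULL
  } else {
    pa_hits <- find_all(edited, cassette$polya)
    pa_hits <- pa_hits[pa_hits >= exon_start & pa_hits <= ins_end]
    if (length(pa_hits) == 0) abort("poly(A) signal not found in cassette")
    syn_exon <- substr(edited, exon_start, pa_hits[1] - 1)
    mature <- paste0(up_cds, syn_exon)
    if (variant == "POLYA") {
      res <- cds_to_first_stop(mature)
      cds <- res$cds
      protein <- res$protein
      target_protein <- NULL
    } else { # EXOGENOUS_PROMOTER_STOP: two transcripts
      res_t <- cds_to_first_stop(mature)
      target_protein <- res_t$protein
      pr_hits <- find_all(edited, cassette$promoter)
      pr_hits <- pr_hits[pr_hits >= exon_start & pr_hits <= ins_end]
      if (length(pr_hits) == 0) abort("promoter not found in cassette")
      payload_mrna <- substr(edited, pr_hits[1] + nchar(cassette$promoter),
                             pa_hits[1] - 1)
      atg <- regexpr("ATG", payload_mrna, fixed = TRUE)
      if (atg < 0) abort("no start codon in promoter-driven payload transcript")
      res <- cds_to_first_stop(substring(payload_mrna, atg))
      cds <- res$cds
      protein <- res$protein
    }
  }

  if (!grepl(payload_aa, protein, fixed = TRUE)) {
    abort("frame violation: payload translation is not intact in the spliced protein")
  }
  if (variant == "OPEN_READTHROUGH" && nchar(down_cds) >= 3) {
    skip <- (3L - nchar(up_cds) %% 3L) %% 3L # complete the carried-over codon
    keep <- (nchar(down_cds) - skip) %/% 3L * 3L
    down_tail <- translate_dna(substr(down_cds, skip + 1, skip + keep))
    down_tail <- sub("\\*.*$", "", down_tail)
    if (nzchar(down_tail) && !endsWith(protein, down_tail)) {
      abort("frame violation: read-through payload is not completed by the downstream exons")
    }
  }
  p2a_off <- find_all(protein, P2A_AA)
  structure(
    list(mature_mrna = mature, cds = cds, protein = protein,
         p2a_cleavage_offsets = if (length(p2a_off)) p2a_off + nchar(P2A_AA) - 1L
                                else integer(),
         target_protein = target_protein, variant = variant),
    class = "spliced_transcript"
  )
}

#' @export
print.spliced_transcript <- function(x, ...) {
  cat(sprintf("<spliced_transcript> [%s] mRNA %d nt, CDS %d nt, protein %d aa, %d P2A site(s)\n",
              x$variant, nchar(x$mature_mrna), nchar(x$cds), nchar(x$protein),
              length(x$p2a_cleavage_offsets)))
  invisible(x)
}

find_all <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (hits[1] < 0) integer() else as.integer(hits)
}

# CDS from position 1 through the first in-frame stop codon (inclusive);
# errors if no in-frame stop exists
cds_to_first_stop <- function(x) {
  keep <- nchar(x) - nchar(x) %% 3
  codons <- split_codons(substr(x, 1, keep))
  stop_at <- which(is_stop_codon(codons))
  if (length(stop_at) == 0) {
    abort("frame violation: no in-frame stop codon before the poly(A) signal")
  }
  cds <- substr(x, 1, stop_at[1] * 3)
  list(cds = cds, protein = sub("\\*$", "", translate_dna(cds)))
}
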