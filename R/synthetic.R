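# Synthetic screen generator. Emulates, at desk scale, a pooled knock-in
# epitope-mapping screen: a toy intron-bearing surface-gene locus, a homolog
# set, a scanning library sized like the real one (649 members over residues
# 101-150), antibody-escape effects planted at three positions, a two-bin
# sort with multinomial cell and read sampling, amplicon reads flanked by
# fixed anchors, and optional per-base substitution error. All ground truth
# is recorded so recovery can be checked end to end.

DEFAULT_ANCHOR_UP <- "ACGGTCTAGCACGTCAAGGC"
DEFAULT_ANCHOR_DOWN <- "GCTTGACCAGTCGATACGTC"

#' Default amplicon anchors used by the simulator
#' @return An [anchor_spec()].
#' @export
default_anchors <- function() {
  anchor_spec(DEFAULT_ANCHOR_UP, DEFAULT_ANCHOR_DOWN)
}

#' Generate a toy target locus and payload
#'
#' Builds a valid strand-normalized locus: a stop-free CDS split across
#' `n_exons` exons with donor-like (`GTAAGT...`) introns, a signal-peptide
#' interval in the first exon, a transmembrane interval in the last exon and
#' a cut site in the middle of the first intron (hence between the two
#' domains), plus a stop-free payload ORF. Reproducible per seed.
#'
#' @param seed Integer seed.
#' @param n_exons Number of exons (>= 2).
#' @param payload_length Payload ORF length in nt (multiple of 3).
#' @return A list with elements `locus` (a [target_locus()]) and `payload`.
#' @export
make_synthetic_locus <- function(seed = 42L, n_exons = 3L,
                                 payload_length = 120L) {
  if (n_exons < 2) abort("need at least 2 exons to have an intron")
  if (payload_length %% 3 != 0 || payload_length <= 0) {
    abort("`payload_length` must be a positive multiple of 3")
  }
  withr::with_seed(seed, {
    widths <- sample(80:160, n_exons, replace = TRUE)
    # exon content is the complete CDS, so the total must be a codon multiple
    widths[n_exons] <- widths[n_exons] + (3L - sum(widths) %% 3L) %% 3L
    total <- sum(widths)
    cds <- random_orf(ceiling(total / 3))
    cds <- substr(cds, 1, total) # exon boundaries need not respect codons
    intron_lens <- sample(200:400, n_exons - 1, replace = TRUE)
    introns <- vapply(intron_lens, function(n) {
      paste0("GTAAGT", random_dna(n - 8), "AG")
    }, character(1))
    parts <- character(0)
    starts <- integer(n_exons)
    pos <- 0L
    off <- cumsum(c(0L, widths))
    for (i in seq_len(n_exons)) {
      starts[i] <- pos
      parts <- c(parts, substr(cds, off[i] + 1, off[i + 1]))
      pos <- pos + widths[i]
      if (i < n_exons) {
        parts <- c(parts, introns[i])
        pos <- pos + intron_lens[i]
      }
    }
    sequence <- paste(parts, collapse = "")
    exons <- tibble(start = starts, end = starts + widths)
    cut <- exons$end[1] + intron_lens[1] %/% 2L
    sp_end <- min(45L, widths[1] - 10L)
    locus <- target_locus(
      locus_id = sprintf("synthetic_locus_seed%d", seed),
      sequence = sequence, exons = exons, cut_site = cut,
      signal_peptide = c(3L, sp_end),
      transmembrane = c(exons$start[n_exons] + 10L,
                        exons$start[n_exons] + 70L)
    )
    list(locus = locus, payload = random_orf(payload_length / 3,
                                             start_atg = TRUE))
  })
}

#' Generate aligned synthetic homolog sequences
#'
#' Each homolog is the segment with independent per-site substitutions at
#' rate `divergence` (to a uniformly random different residue), so the
#' alignment has the same length as the segment and an expected per-site
#' divergence equal to `divergence`.
#'
#' @param segment_aa Native protein segment.
#' @param n Number of homologs.
#' @param divergence Expected per-site substitution rate in [0, 1].
#' @param seed Integer seed.
#' @return Named character vector of aligned homolog sequences.
#' @export
make_synthetic_homologs <- function(segment_aa, n = 38L, divergence = 0.1,
                                    seed = 42L) {
  if (divergence < 0 || divergence > 1) abort("`divergence` must be in [0, 1]")
  chars <- strsplit(toupper(segment_aa), "")[[1]]
  withr::with_seed(seed, {
    out <- vapply(seq_len(n), function(i) {
      hit <- runif(length(chars)) < divergence
      res <- chars
      if (any(hit)) {
        res[hit] <- vapply(chars[hit], function(a) {
          sample(setdiff(AA_STANDARD, a), 1)
        }, character(1))
      }
      paste(res, collapse = "")
    }, character(1))
  })
  setNames(out, sprintf("homolog_%02d", seq_len(n)))
}

#' Reference segment, homologs and scanning library at study scale
#'
#' Generates a 50-residue reference segment (numbered 101-150) and a
#' 38-homolog alignment constructed so that the scanning design - BLOSUM
#' picks, homolog augmentation, two codons per substitution, one synonymous
#' and one deletion control per position and five stop controls - yields
#' exactly 649 members, the scale of the screen this simulator emulates.
#' Homologs carry a controlled number of planted novel substitutions on top
#' of the native segment; the reference avoids adjacent identical codons so
#' deletion oligos stay unique.
#'
#' @param seed Integer seed.
#' @param matrix Substitution matrix for the design.
#' @param target_size Library size to hit (default 649).
#' @return A list: `reference_dna`, `segment_aa`, `homologs`, `members`
#'   (the designed library), `config`.
#' @export
synthetic_scan_inputs <- function(seed = 42L, matrix = blosum80(),
                                  target_size = 649L) {
  cfg <- scan_config()
  n_res <- cfg$window[2] - cfg$window[1] + 1L
  withr::with_seed(seed, {
    # stop-free reference without M/W natives (so every position has a
    # synonymous control) and without adjacent identical codons
    sense <- setdiff(names(GENETIC_CODE_TABLE), c("TAA", "TAG", "TGA"))
    sense <- sense[!GENETIC_CODE_TABLE[sense] %in% c("M", "W")]
    codons <- character(n_res)
    for (i in seq_len(n_res)) {
      repeat {
        cd <- sample(sense, 1)
        if (i == 1 || cd != codons[i - 1]) break
      }
      codons[i] <- cd
    }
    reference_dna <- paste(codons, collapse = "")
    segment_aa <- translate_dna(reference_dna)

    base <- design_scanning_library(reference_dna, homologs = NULL,
                                    matrix = matrix, config = cfg)
    extra <- target_size - nrow(base)
    if (extra < 0) abort("base design already exceeds the target size")

    # plan planted homolog substitutions: novel residues with 2 codons each
    # (plus one single-codon Met/Trp pick if the remainder is odd)
    plan <- list()
    order_pos <- rep(sample(seq_len(n_res)), length.out = 10L * n_res)
    pi <- 1L
    remaining <- extra
    while (remaining > 0L) {
      i <- order_pos[pi]
      pi <- pi + 1L
      pos <- cfg$window[1] + i - 1L
      native <- substr(segment_aa, i, i)
      chosen <- base$variant_aa[base$position == pos &
                                  base$control_class == "substitution"]
      planted <- vapply(plan, function(p) if (p$i == i) p$aa else "",
                        character(1))
      avail <- setdiff(AA_STANDARD, c(native, chosen, planted))
      if (remaining %% 2L == 1L && any(avail %in% c("M", "W"))) {
        aa <- intersect(avail, c("M", "W"))[1]
        cost <- 1L
      } else {
        avail <- setdiff(avail, c("M", "W"))
        if (length(avail) == 0) next
        aa <- sample(avail, 1)
        cost <- 2L
      }
      if (cost > remaining) next
      plan[[length(plan) + 1L]] <- list(i = i, aa = aa)
      remaining <- remaining - cost
    }

    # homologs: native segment plus the planted substitutions spread over rows
    homologs <- rep(segment_aa, 38L)
    for (k in seq_along(plan)) {
      row <- ((k - 1L) %% 38L) + 1L
      substr(homologs[row], plan[[k]]$i, plan[[k]]$i) <- plan[[k]]$aa
    }
    names(homologs) <- sprintf("homolog_%02d", seq_len(38L))
  })
  members <- design_scanning_library(reference_dna, homologs = homologs,
                                     matrix = matrix, config = cfg)
  if (nrow(members) != target_size) {
    abort(sprintf("synthetic design yielded %d members, expected %d",
                  nrow(members), target_size))
  }
  list(reference_dna = reference_dna, segment_aa = segment_aa,
       homologs = homologs, members = members, config = cfg)
}

#' Ground truth for a simulated sort screen
#'
#' Assigns a binding-loss probability (the chance that a cell expressing the
#' variant escapes antibody binding) to every member. Effects live at the
#' amino-acid level and are shared by codons of the same substitution.
#' Substitutions at the planted escape positions draw from `Beta(6, 2)`
#' (strong escape); substitutions elsewhere draw from `0.4 * Beta(2, 8)`
#' (small but non-zero, continuous, so recovery can be scored by rank);
#' native-residue (synonymous) members have binding loss exactly 0; deletion
#' and stop controls lose surface expression and get 1.
#'
#' @param members Member tibble.
#' @param escape_positions Residue numbers carrying planted escape effects.
#' @param seed Integer seed.
#' @param escape_shape,background_shape Beta parameters `c(alpha, beta)`.
#' @param background_scale Multiplier on the background Beta draw.
#' @return A `screen_truth` tibble: member columns plus `binding_loss`;
#'   parameters attached as attributes.
#' @export
make_screen_truth <- function(members, escape_positions = c(102L, 112L, 116L),
                              seed = 42L, escape_shape = c(6, 2),
                              background_shape = c(2, 8),
                              background_scale = 0.4) {
  key <- paste(members$position, members$variant_aa)
  sub_keys <- unique(key[members$control_class == "substitution"])
  withr::with_seed(seed, {
    eff <- vapply(sub_keys, function(k) {
      pos <- as.integer(sub("\\s.*", "", k))
      if (pos %in% escape_positions) {
        rbeta(1, escape_shape[1], escape_shape[2])
      } else {
        background_scale * rbeta(1, background_shape[1], background_shape[2])
      }
    }, numeric(1))
  })
  loss <- numeric(nrow(members))
  is_sub <- members$control_class == "substitution"
  loss[is_sub] <- eff[key[is_sub]]
  loss[members$control_class %in% c("deletion", "stop")] <- 1
  out <- members |>
    mutate(binding_loss = loss)
  class(out) <- c("screen_truth", class(out))
  attr(out, "escape_positions") <- sort(as.integer(escape_positions))
  attr(out, "seed") <- seed
  attr(out, "params") <- list(escape_shape = escape_shape,
                              background_shape = background_shape,
                              background_scale = background_scale)
  out
}

#' Simulate a two-bin sort screen to FASTQ
#'
#' Models the screen readout: cells are allocated to members multinomially
#' from a mildly skewed library composition, each cell routes to the
#' antibody-negative bin with probability equal to its variant's binding
#' loss, and each bin (input library, negative, positive) is sequenced to
#' `reads_per_bin` reads. A read is the member's oligo flanked by the fixed
#' anchors and shared backbone context, written at `read_length` nt with
#' optional per-base substitution error; files are plain FASTQ, one per bin.
#' Byte-identical output per seed.
#'
#' @param members Member tibble.
#' @param truth Optional `screen_truth`; generated from `seed` if missing.
#' @param anchors An [anchor_spec()].
#' @param n_cells Cells in the sorted pool.
#' @param reads_per_bin Reads sequenced per bin.
#' @param error_rate Per-base substitution error rate.
#' @param read_length Read length in nt.
#' @param paired Also emit reverse-complement R2 files.
#' @param composition_sd Log-normal sd of library composition skew.
#' @param seed Integer seed.
#' @param dir Output directory for FASTQ and truth JSON.
#' @return A list: `files` (named fastq paths), `truth_file`, `truth`,
#'   `counts` (per-member cells and reads per bin), `anchors`.
#' @export
simulate_sort_screen <- function(members, truth = NULL,
                                 anchors = default_anchors(),
                                 n_cells = 50000L, reads_per_bin = 100000L,
                                 error_rate = 0.001, read_length = 250L,
                                 paired = FALSE, composition_sd = 0.3,
                                 seed = 42L, dir = tempfile("screen")) {
  if (n_cells <= 0 || reads_per_bin <= 0) abort("depths must be positive")
  if (is.null(truth)) truth <- make_screen_truth(members, seed = seed)
  if (!identical(truth$member_id, members$member_id)) {
    abort("truth and member tables do not match")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(members)
  withr::with_seed(seed, {
    w <- rlnorm(n, 0, composition_sd)
    cells <- rmultinom(1, n_cells, w)[, 1]
    neg_cells <- rbinom(n, cells, truth$binding_loss)
    pos_cells <- cells - neg_cells
    reads <- list(
      input = rmultinom(1, reads_per_bin, pmax(cells, 1e-9))[, 1],
      bin_neg = rmultinom(1, reads_per_bin, pmax(neg_cells, 1e-9))[, 1],
      bin_pos = rmultinom(1, reads_per_bin, pmax(pos_cells, 1e-9))[, 1]
    )
    # shared backbone context so every fragment fills the read length
    frag <- paste0(random_dna(30L), anchors$upstream, members$oligo_sequence,
                   anchors$downstream, random_dna(read_length))
    files <- list()
    for (bin in names(reads)) {
      seqs <- substr(rep(frag, reads[[bin]]), 1L, read_length)
      seqs <- inject_errors(seqs, error_rate)
      path <- file.path(dir, paste0(bin, "_R1.fastq"))
      write_fastq(seqs, path, prefix = bin)
      files[[bin]] <- path
      if (paired) {
        path2 <- file.path(dir, paste0(bin, "_R2.fastq"))
        write_fastq(revcomp(seqs), path2, prefix = paste0(bin, "_R2"))
        files[[paste0(bin, "_R2")]] <- path2
      }
    }
  })
  counts <- tibble(
    member_id = members$member_id, cells = cells,
    cells_bin_neg = neg_cells, cells_bin_pos = pos_cells,
    reads_input = reads$input, reads_bin_neg = reads$bin_neg,
    reads_bin_pos = reads$bin_pos
  )
  truth_file <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed, n_cells = n_cells, reads_per_bin = reads_per_bin,
         error_rate = error_rate,
         escape_positions = attr(truth, "escape_positions"),
         params = attr(truth, "params"),
         members = as.data.frame(truth[, c("member_id", "position",
                                           "variant_aa", "control_class",
                                           "binding_loss")])),
    truth_file, auto_unbox = TRUE, digits = NA
  )
  list(files = files, truth_file = truth_file, truth = truth,
       counts = counts, anchors = anchors)
}

inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  width <- nchar(seqs)
  n_err <- rbinom(length(seqs), width, error_rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    at <- sample.int(width[i], n_err[i])
    s <- strsplit(seqs[i], "")[[1]]
    s[at] <- vapply(s[at], function(b) sample(setdiff(bases, b), 1),
                    character(1))
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

write_fastq <- function(seqs, path, prefix = "read") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s_%07d", prefix, seq_along(seqs))
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
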