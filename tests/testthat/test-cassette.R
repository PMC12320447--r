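# Cassette assembly and the splice simulator as frame validator.

VARIANTS <- c("P2A_SD", "OPEN_READTHROUGH", "POLYA", "EXOGENOUS_PROMOTER_STOP")

test_that("assembly and splicing keep the frame for every leftover class and variant", {
  for (w1 in c(12L, 13L, 14L)) { # upstream leftover 0, 1, 2
    locus <- toy_locus(first_exon_width = w1)
    for (v in VARIANTS) {
      cassette <- assemble_seed(locus, TOY_PAYLOAD, v, arm_length = 20L)
      tx <- simulate_splice(locus, cassette)
      expect_identical(nchar(tx$cds) %% 3L, 0L,
                       info = sprintf("w1=%d %s", w1, v))
      expect_true(grepl(translate_dna(TOY_PAYLOAD), tx$protein, fixed = TRUE),
                  info = sprintf("payload lost: w1=%d %s", w1, v))
    }
  }
})

test_that("round trip on random synthetic loci never errors (all variants)", {
  for (seed in 1:6) {
    syn <- make_synthetic_locus(seed = seed, n_exons = 2L + seed %% 3L,
                                payload_length = 90L)
    for (v in VARIANTS) {
      cassette <- assemble_seed(syn$locus, syn$payload, v, arm_length = 100L)
      tx <- simulate_splice(syn$locus, cassette)
      expect_identical(nchar(tx$cds) %% 3L, 0L)
      # payload translation is recoverable verbatim
      expect_true(grepl(translate_dna(syn$payload), tx$protein, fixed = TRUE))
    }
  }
})

test_that("the P2A_SD variant carries two P2A cleavage sites and reuses downstream exons", {
  locus <- toy_locus(first_exon_width = 13L)
  cassette <- assemble_seed(locus, TOY_PAYLOAD, "P2A_SD", arm_length = 20L)
  expect_true(all(c("p2a_5", "p2a_3", "splice_donor") %in%
                    cassette$annotations$label))
  tx <- simulate_splice(locus, cassette)
  expect_length(tx$p2a_cleavage_offsets, 2L)
  # mature transcript ends with the downstream exon (endogenous poly(A) reused)
  down <- substr(locus$sequence, locus$exons$start[2] + 1, locus$exons$end[2])
  expect_true(endsWith(tx$mature_mrna, down))
})

test_that("the open-readthrough variant is completed by the endogenous downstream exons", {
  locus <- toy_locus(first_exon_width = 14L)
  cassette <- assemble_seed(locus, TOY_PAYLOAD, "OPEN_READTHROUGH",
                            arm_length = 20L)
  expect_false("p2a_3" %in% cassette$annotations$label)
  tx <- simulate_splice(locus, cassette)
  # C-terminus equals the in-frame translation of the downstream exon
  down <- substr(locus$sequence, locus$exons$start[2] + 1, locus$exons$end[2])
  skip <- (3L - (locus$exons$end[1] %% 3L)) %% 3L
  keep <- (nchar(down) - skip) %/% 3L * 3L
  tail_aa <- translate_dna(substr(down, skip + 1, skip + keep))
  expect_true(endsWith(tx$protein, tail_aa))
})

test_that("the poly(A) variant ends with stop + poly(A) signal and no donor", {
  locus <- toy_locus()
  cassette <- assemble_seed(locus, TOY_PAYLOAD, "POLYA", arm_length = 20L)
  labels <- cassette$annotations$label
  expect_true(all(c("stop_codon", "polya_signal") %in% labels))
  expect_false("splice_donor" %in% labels)
  tx <- simulate_splice(locus, cassette)
  expect_true(endsWith(tx$cds, "TAA"))
})

test_that("the promoter-driven variant truncates the target and expresses the payload separately", {
  locus <- toy_locus(first_exon_width = 13L)
  cassette <- assemble_seed(locus, TOY_PAYLOAD, "EXOGENOUS_PROMOTER_STOP",
                            arm_length = 20L)
  expect_true(all(c("stop_codon", "promoter") %in% cassette$annotations$label))
  tx <- simulate_splice(locus, cassette)
  expect_true(grepl(translate_dna(TOY_PAYLOAD), tx$protein, fixed = TRUE))
  # target protein truncated right after the filler
  expect_lt(nchar(tx$target_protein), nchar(locus$sequence) / 3)
})

test_that("invalid payloads and arms are rejected", {
  locus <- toy_locus()
  expect_error(assemble_seed(locus, substr(TOY_PAYLOAD, 1, 10)),
               "not divisible by 3")
  expect_error(assemble_seed(locus, "ATGTAAGGT"), "stop codon")
  expect_error(assemble_seed(locus, TOY_PAYLOAD, arm_length = 10000L),
               "past the locus")
})

test_that("a 1-nt deletion in the filler is caught as a frame violation", {
  locus <- toy_locus(first_exon_width = 13L) # leftover 1 -> 2-nt 5' filler
  cassette <- assemble_seed(locus, TOY_PAYLOAD, "P2A_SD", arm_length = 20L)
  n_sa <- nchar(cassette$sa_block)
  expect_identical(nchar(cassette$five_prime_filler), 2L)
  corrupt <- cassette
  corrupt$insert <- paste0(substr(cassette$insert, 1, n_sa),
                           substr(cassette$insert, n_sa + 2,
                                  nchar(cassette$insert)))
  expect_error(simulate_splice(locus, corrupt), "frame violation")
})

test_that("GenBank emission round-trips sequence and annotation intervals", {
  locus <- toy_locus()
  cassette <- assemble_seed(locus, TOY_PAYLOAD, "P2A_SD", arm_length = 20L)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(cassette, path)
  back <- read_genbank(path)
  expect_identical(back$sequence, cassette$sequence)
  expect_identical(back$annotations,
                   cassette$annotations[, c("label", "start", "end")])
  # annotations are contiguous and cover the whole cassette
  ann <- back$annotations
  expect_identical(ann$start[-1], ann$end[-nrow(ann)])
  expect_identical(ann$end[nrow(ann)], nchar(cassette$sequence))
})

test_that("strict element mode requires an explicit splice acceptor block", {
  expect_error(seed_elements(strict = TRUE), "explicitly")
  expect_silent(seed_elements(sa_block = "TTTCTCTCCACAG", strict = TRUE))
})
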