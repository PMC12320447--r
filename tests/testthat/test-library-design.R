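# Scanning and saturation library design.

test_that("a toy 3-residue scan yields the closed-form member count", {
  members <- toy_members() # natives D, E, K; 5 subs x 2 codons each
  expect_identical(nrow(members), 3L * 5L * 2L + 3L + 3L + 1L) # 37
  comp <- table(members$control_class)
  expect_identical(as.integer(comp[c("substitution", "synonymous",
                                     "deletion", "stop")]),
                   c(30L, 3L, 3L, 1L))
  expect_false(anyDuplicated(members$member_id) > 0)
})

test_that("member count equals brute-force enumeration on random toy designs", {
  usage <- codon_usage_human()
  m <- blosum80()
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n_res <- sample(3:6, 1)
      sense <- setdiff(names(seedscreen:::GENETIC_CODE_TABLE),
                       c("TAA", "TAG", "TGA"))
      codons <- sample(sense, n_res, replace = TRUE)
      while (any(codons[-1] == codons[-n_res])) {
        codons <- sample(sense, n_res, replace = TRUE)
      }
      ref <- paste(codons, collapse = "")
      segment <- translate_dna(ref)
      homologs <- make_synthetic_homologs(segment, n = 5, divergence = 0.3,
                                          seed = seed)
      stop_pos <- sample(seq_len(n_res), 1)
    })
    cfg <- scan_config(window = c(1L, n_res), stop_positions = stop_pos)
    members <- design_scanning_library(ref, homologs, m, cfg)
    # independent count: per position, union of picks and homolog residues,
    # summing available codons per substitution
    expected <- 0L
    for (i in seq_len(n_res)) {
      native <- substr(segment, i, i)
      subs <- pick_blosum_substitutions(native, m)
      subs <- union(subs, augment_from_homologs(substr(homologs, i, i),
                                                native, subs))
      expected <- expected +
        sum(vapply(subs, function(a) length(assign_codons(a, 2, usage)),
                   integer(1)))
      expected <- expected +
        length(assign_codons(native, 1, usage, exclude = codons[i])) + # syn
        1L # deletion
    }
    expected <- expected + 1L # one stop position
    expect_identical(nrow(members), expected, info = sprintf("seed %d", seed))
    v <- validate_library(members, ref, cfg$window)
    expect_true(all(v$ok), info = sprintf("seed %d", seed))
  }
})

test_that("every oligo realizes exactly its designed change", {
  members <- toy_members()
  ref <- attr(members, "reference")
  v <- validate_library(members, ref, c(1L, 3L))
  expect_true(all(v$ok))
  # and the validator flags a corrupted oligo
  bad <- members
  bad$oligo_sequence[1] <- paste0("A", substr(bad$oligo_sequence[1], 2, 9))
  vb <- validate_library(bad, ref, c(1L, 3L))
  expect_false(vb$ok[1])
  expect_true(all(vb$ok[-1]))
})

test_that("the design is reproducible bit for bit", {
  expect_identical(toy_members(), toy_members())
  a <- synthetic_scan_inputs(seed = 3)
  b <- synthetic_scan_inputs(seed = 3)
  expect_identical(a$members, b$members)
})

test_that("homolog augmentation returns only novel non-gap residues", {
  expect_identical(augment_from_homologs(c("D", "D", "E", "A"), "D", "A"), "E")
  expect_identical(augment_from_homologs(c("D", "D", "D"), "D"), character())
  expect_identical(augment_from_homologs(c("-", ".", "-"), "D"), character())
  expect_error(augment_from_homologs(character(), "D"), "empty")
})

test_that("saturation libraries enumerate the degenerate scheme", {
  ref <- attr(toy_members(), "reference")
  sat <- design_saturation_library(ref, 2, "NNN", window = c(1L, 3L))
  expect_identical(nrow(sat), 64L)
  expect_identical(sum(sat$control_class == "stop"), 3L)
  expect_identical(sum(sat$control_class != "stop"), 61L)
  # 19 distinct non-native amino-acid substitutions
  subs <- unique(sat$variant_aa[sat$control_class == "substitution"])
  expect_length(subs, 19L)
  expect_identical(nrow(design_saturation_library(ref, 2, "NNK",
                                                  window = c(1L, 3L))), 32L)
  expect_error(design_saturation_library(ref, 9, window = c(1L, 3L)),
               "outside the window")
  expect_error(design_saturation_library(ref, 2, "NZN", window = c(1L, 3L)),
               "3-letter")
})

test_that("member tables survive a TSV round trip and re-validate", {
  members <- toy_members()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library_tsv(members, path)
  back <- read_library_tsv(path)
  expect_identical(back$member_id, members$member_id)
  expect_identical(back$oligo_sequence, members$oligo_sequence)
  v <- validate_library(back, attr(members, "reference"), c(1L, 3L))
  expect_true(all(v$ok))
})

test_that("design rejects inconsistent inputs", {
  expect_error(
    design_scanning_library("GACGAA", config = scan_config(window = c(1, 3),
                                                           stop_positions = 1)),
    "window spans"
  )
  expect_error(
    design_scanning_library(paste(c("GAC", "GAA", "AAG"), collapse = ""),
                            homologs = c(h1 = "DE"),
                            config = scan_config(window = c(1, 3),
                                                 stop_positions = 1)),
    "alignment length"
  )
  expect_error(scan_config(window = c(5, 2)), "inclusive")
  expect_error(scan_config(stop_positions = 200), "inside the window")
})
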