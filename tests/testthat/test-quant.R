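# Amplicon quantification: anchor scan, exact-match counting, abundances.

ANCH <- anchor_spec("ACGGTCTAGCACGTCAAGGC", "GCTTGACCAGTCGATACGTC")

test_that("regions are extracted strictly between exact anchors", {
  region <- "TTTTGACGAAAAGCCC"
  read <- paste0("GGAA", ANCH$upstream, region, ANCH$downstream, "TTGC")
  out <- extract_library_region(read, ANCH)
  expect_identical(out$region, region)
  expect_identical(out$status, "ok")
})

test_that("a single mismatch in an anchor discards the read", {
  region <- "TTTTGACGAAAAGCCC"
  up_mut <- ANCH$upstream
  substr(up_mut, 5, 5) <- if (substr(up_mut, 5, 5) == "A") "C" else "A"
  read <- paste0("GG", up_mut, region, ANCH$downstream, "TT")
  expect_identical(extract_library_region(read, ANCH)$status, "no_anchor")
})

test_that("reads lacking or misordering anchors are discarded, not errors", {
  up_only <- paste0("GG", ANCH$upstream, "TTTT")
  out_of_order <- paste0(ANCH$downstream, "TTTT", ANCH$upstream)
  out <- extract_library_region(c(up_only, out_of_order), ANCH)
  expect_identical(out$status, c("no_anchor", "no_anchor"))
})

test_that("counting is exact-match only and equals a naive all-pairs oracle", {
  members <- toy_members()
  withr::with_seed(11, {
    pool <- sample(members$oligo_sequence, 300, replace = TRUE)
    # corrupt a third of the regions by one substitution
    hit <- seq(1, 300, by = 3)
    for (i in hit) {
      at <- sample(nchar(pool[i]), 1)
      old <- substr(pool[i], at, at)
      substr(pool[i], at, at) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
  })
  counts <- count_members(pool, members)
  naive <- vapply(members$oligo_sequence,
                  function(o) sum(pool == o), integer(1))
  expect_identical(counts$raw_count, unname(naive))
  expect_identical(attr(counts, "unmapped"),
                   as.integer(300 - sum(naive)))
})

test_that("duplicate member oligo sequences are an error at load", {
  members <- toy_members()[1:3, ]
  members$oligo_sequence[2] <- members$oligo_sequence[1]
  expect_error(count_members("ACGT", members), "duplicate oligo")
})

test_that("abundances exclude stop and deletion controls from the denominator", {
  members <- toy_members()
  ids <- members$member_id
  stop_id <- ids[members$control_class == "stop"][1]
  a <- ids[members$control_class == "substitution"][1]
  b <- ids[members$control_class == "substitution"][2]
  ab <- abundance_from_counts(members,
                              setNames(c(30L, 70L, 100L), c(a, b, stop_id)))
  expect_equal(ab$abundance[ab$member_id == a], 0.30)
  expect_equal(ab$abundance[ab$member_id == b], 0.70)
  expect_true(is.na(ab$abundance[ab$member_id == stop_id]))
  expect_identical(attr(ab, "totals")$reads_control, 100L)
  # non-control abundances sum to one
  expect_equal(sum(ab$abundance, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("a single member with all reads has abundance one; controls-only errors", {
  members <- toy_members()
  one <- members$member_id[members$control_class == "substitution"][1]
  ab <- abundance_from_counts(members, setNames(500L, one))
  expect_equal(ab$abundance[ab$member_id == one], 1)
  del <- members$member_id[members$control_class == "deletion"][1]
  expect_error(abundance_from_counts(members, setNames(500L, del)),
               "no usable reads")
})

test_that("counts are order-free and orientation-aware", {
  members <- toy_members()
  frag <- paste0("AA", ANCH$upstream, members$oligo_sequence[1:20],
                 ANCH$downstream, "CC")
  flipped <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(frag[1:10]))
  )
  reads <- c(frag[11:20], flipped)
  path <- withr::local_tempfile(fileext = ".fastq")
  seedscreen:::write_fastq(reads, path)
  ab1 <- quantify_amplicons(path, members, ANCH)
  seedscreen:::write_fastq(rev(reads), path)
  ab2 <- quantify_amplicons(path, members, ANCH)
  expect_identical(ab1$raw_count, ab2$raw_count)
  expect_identical(sum(ab1$raw_count), 20L)
})

test_that("paired-end mode rescues fragments whose first read lacks anchors", {
  members <- toy_members()
  frag <- paste0("AA", ANCH$upstream, members$oligo_sequence[1],
                 ANCH$downstream, "CC")
  r1 <- c(frag, strrep("T", nchar(frag)))       # second fragment garbled in R1
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(c(strrep("G", nchar(frag)), frag))
  ))
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  seedscreen:::write_fastq(r1, p1)
  seedscreen:::write_fastq(r2, p2)
  ab <- quantify_amplicons(p1, members, ANCH, fastq2 = p2)
  expect_identical(ab$raw_count[ab$member_id == members$member_id[1]], 2L)
  expect_identical(attr(ab, "stats")$reads_in, 2L)
})

test_that("read accounting conserves: in = no-anchor + unmapped + mapped", {
  inp <- synthetic_scan_inputs(seed = 5)
  sim <- simulate_sort_screen(inp$members, n_cells = 5000L,
                              reads_per_bin = 5000L, error_rate = 0.002,
                              seed = 5)
  for (bin in c("input", "bin_neg", "bin_pos")) {
    ab <- quantify_amplicons(sim$files[[bin]], inp$members, sim$anchors,
                             sample_id = bin)
    st <- attr(ab, "stats")
    expect_identical(st$reads_in,
                     st$reads_no_anchor + st$reads_unmapped + st$reads_mapped)
    expect_identical(st$reads_mapped, sum(ab$raw_count))
    expect_identical(st$reads_anchored, st$reads_in - st$reads_no_anchor)
  }
})
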