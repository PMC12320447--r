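# Fold enrichment, conservation ratio, aggregation and epitope calls.

members_small <- function() toy_members()

test_that("identical selected and input abundances give unit enrichment", {
  m <- members_small()
  ab <- uniform_abundance(m)
  fe <- fold_enrichment(ab, ab, pseudocount = 0)
  expect_true(all(fe$fold_enrichment == 1))
  expect_true(all(fe$log2_fe == 0))
})

test_that("enrichment is the direct abundance ratio without pseudocount", {
  inp <- tibble::tibble(member_id = c("m1", "m2"),
                        control_class = "substitution",
                        raw_count = c(100L, 900L),
                        abundance = c(0.1, 0.9))
  sel <- dplyr::mutate(inp, raw_count = c(200L, 800L),
                       abundance = c(0.2, 0.8))
  fe <- fold_enrichment(sel, inp, pseudocount = 0)
  expect_equal(fe$fold_enrichment[fe$member_id == "m1"], 2.0)
  expect_equal(fe$log2_fe[fe$member_id == "m1"], 1.0)
})

test_that("a pseudocount keeps zero-input members finite", {
  m <- members_small()
  subs <- m$member_id[m$control_class == "substitution"]
  inp <- abundance_from_counts(m, setNames(1000L, subs[1]))
  sel <- abundance_from_counts(m, setNames(c(500L, 500L), subs[1:2]))
  expect_error(fold_enrichment(sel, inp, pseudocount = 0), "non-finite")
  fe <- fold_enrichment(sel, inp) # auto pseudocount
  expect_true(all(is.finite(fe$fold_enrichment)))
  expect_equal(attr(fe, "pseudocount"), 1 / 1000)
})

test_that("mismatched member universes are an error", {
  m <- members_small()
  ab <- uniform_abundance(m)
  expect_error(fold_enrichment(ab[-5, ], ab, pseudocount = 0),
               "different member sets")
})

test_that("the conservation ratio is the ratio of bin enrichments", {
  m <- members_small()
  id1 <- m$member_id[m$control_class == "substitution"][1]
  base <- uniform_abundance(m)
  # bin_pos doubles id1, bin_neg halves it
  n_nc <- sum(!m$control_class %in% c("stop", "deletion"))
  pos_counts <- setNames(rep(1000L, nrow(m)), m$member_id)
  neg_counts <- pos_counts
  pos_counts[id1] <- 2000L
  neg_counts[id1] <- 500L
  scores <- score_screen(base,
                         abundance_from_counts(m, neg_counts),
                         abundance_from_counts(m, pos_counts),
                         pseudocount = 0)
  r <- tidy(scores)
  got <- r$bin_ratio[r$member_id == id1]
  fe_pos <- (2000 / (1000 * (n_nc - 1) + 2000)) / (1 / n_nc)
  fe_neg <- (500 / (1000 * (n_nc - 1) + 500)) / (1 / n_nc)
  expect_equal(got, fe_pos / fe_neg)
  # everyone else is mildly shifted the other way but near 1
  expect_true(all(abs(r$log2_bin_ratio[r$member_id != id1]) < 0.2))
  # ordering is least -> most conservative
  expect_identical(r$member_id[nrow(r)], id1)
  expect_false(is.unsorted(r$bin_ratio))
})

test_that("scaling all counts leaves abundances and ratios unchanged", {
  m <- members_small()
  withr::with_seed(2, {
    counts <- setNames(sample(50:500, nrow(m), replace = TRUE), m$member_id)
  })
  ab1 <- abundance_from_counts(m, counts)
  ab3 <- abundance_from_counts(m, counts * 3L)
  expect_equal(ab1$abundance, ab3$abundance)
  fe <- fold_enrichment(ab3, ab1, pseudocount = 0)
  expect_true(all(abs(fe$log2_fe) < 1e-12))
})

test_that("raising a member's selected count never lowers its enrichment", {
  m <- members_small()
  inp <- uniform_abundance(m)
  id <- m$member_id[m$control_class == "substitution"][3]
  prev <- -Inf
  for (k in c(0L, 10L, 100L, 1000L)) {
    counts <- setNames(rep(100L, nrow(m)), m$member_id)
    counts[id] <- k
    fe <- fold_enrichment(abundance_from_counts(m, counts), inp)
    now <- fe$fold_enrichment[fe$member_id == id]
    expect_gte(now, prev)
    prev <- now
  }
})

test_that("amino-acid aggregation is the unweighted codon mean", {
  recs <- tibble::tibble(
    member_id = c("a", "b", "c"), position = c(5L, 5L, 5L),
    native_aa = "D", variant_aa = c("L", "L", "E"),
    control_class = "substitution",
    bin_ratio = c(1, 3, 2), log2_bin_ratio = log2(c(1, 3, 2))
  )
  prof <- aggregate_by_amino_acid(recs)
  expect_equal(prof$bin_ratio[prof$variant_aa == "L"], 2)
  expect_identical(prof$n_codons[prof$variant_aa == "L"], 2L)
  expect_equal(prof$bin_ratio[prof$variant_aa == "E"], 2)
  # permutation invariance
  prof2 <- aggregate_by_amino_acid(recs[c(3, 1, 2), ])
  expect_equal(dplyr::arrange(prof2, variant_aa),
               dplyr::arrange(prof, variant_aa))
})

test_that("epitope calls return planted positions and respect thresholds", {
  prof <- tidyr::expand_grid(position = 1:6, variant_aa = c("L", "E", "K")) |>
    dplyr::mutate(native_aa = "D",
                  bin_ratio = ifelse(position %in% c(2L, 4L), 0.2, 1.5),
                  n_codons = 2L)
  expect_identical(as.integer(call_epitope_positions(prof)), c(2L, 4L))
  # null profile: nothing called
  prof_null <- dplyr::mutate(prof, bin_ratio = 1.2)
  expect_length(call_epitope_positions(prof_null), 0L)
  # everything escaping: whole window called
  prof_all <- dplyr::mutate(prof, bin_ratio = 0.1)
  expect_identical(as.integer(call_epitope_positions(prof_all)), 1:6)
  expect_error(call_epitope_positions(prof, effect_threshold = -1), "positive")
  expect_error(call_epitope_positions(prof, min_fraction_escaping = 0), "in \\(0, 1\\]")
})

test_that("native residues rank most conservative when they carry no penalty", {
  # strong escape at every substitution, zero at synonymous members
  inp <- synthetic_scan_inputs(seed = 9)
  members <- inp$members
  truth <- make_screen_truth(members, seed = 9)
  truth$binding_loss[truth$control_class == "substitution"] <-
    pmax(truth$binding_loss[truth$control_class == "substitution"], 0.5)
  sim <- simulate_sort_screen(members, truth = truth, n_cells = 30000L,
                              reads_per_bin = 30000L, error_rate = 0,
                              seed = 9)
  ab <- lapply(setNames(nm = c("input", "bin_neg", "bin_pos")), function(b) {
    quantify_amplicons(sim$files[[b]], members, sim$anchors, sample_id = b)
  })
  scores <- tidy(score_screen(ab$input, ab$bin_neg, ab$bin_pos))
  top <- scores |>
    dplyr::filter(!control_class %in% c("stop", "deletion")) |>
    dplyr::group_by(position) |>
    dplyr::slice_max(bin_ratio, n = 1, with_ties = FALSE)
  # the synonymous (native) member wins at virtually every position
  expect_gte(mean(top$control_class == "synonymous"), 0.95)
})

test_that("glance summarises a score table in one row", {
  m <- members_small()
  ab <- uniform_abundance(m)
  scores <- score_screen(ab, ab, ab)
  g <- glance(scores)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_members, sum(!m$control_class %in% c("stop", "deletion")))
})
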