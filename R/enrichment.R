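# Enrichment scoring for sort-seq screens: fold enrichment of each member
# versus the input library, the two-bin conservation ratio (enrichment in
# the antibody-bound bin over the unbound bin), amino-acid aggregation over
# codons, and position-level epitope calls.

#' Per-member fold enrichment versus the input library
#'
#' `score = (abundance_selected + eps) / (abundance_input + eps)` over the
#' shared non-control member universe. The default pseudocount is one read
#' on the abundance scale of the shallower sample
#' (`1 / min(non-control mapped reads)`), which keeps zero-count members
#' finite without dominating well-covered ones; `pseudocount = 0` gives the
#' raw ratio.
#'
#' @param selected,input Abundance tibbles from [compute_abundance()] (same
#'   member universe).
#' @param pseudocount `"auto"` or a non-negative number on the abundance
#'   scale.
#' @return A tibble with per-member `fold_enrichment` and `log2_fe`
#'   (non-control members only); the pseudocount used is attached as
#'   attribute `pseudocount`.
#' @export
fold_enrichment <- function(selected, input, pseudocount = "auto") {
  sel <- filter(selected, !.data$control_class %in% c("stop", "deletion"))
  inp <- filter(input, !.data$control_class %in% c("stop", "deletion"))
  if (!setequal(sel$member_id, inp$member_id)) {
    abort("selected and input tables cover different member sets")
  }
  eps <- resolve_pseudocount(pseudocount, list(selected, input))
  out <- sel |>
    select(any_of(c("member_id", "position", "native_aa", "variant_aa",
                    "codon", "control_class")), abund_sel = "abundance") |>
    left_join(select(inp, "member_id", abund_in = "abundance"),
              by = "member_id") |>
    mutate(
      fold_enrichment = (.data$abund_sel + eps) / (.data$abund_in + eps),
      log2_fe = log2(.data$fold_enrichment)
    )
  if (any(!is.finite(out$fold_enrichment))) {
    abort("non-finite enrichment: zero input abundance with pseudocount 0")
  }
  attr(out, "pseudocount") <- eps
  out
}

resolve_pseudocount <- function(pseudocount, tables) {
  if (identical(pseudocount, "auto")) {
    totals <- vapply(tables, function(t) {
      tot <- attr(t, "totals")
      if (!is.null(tot)) tot$reads_noncontrol
      else sum(t$raw_count[!t$control_class %in% c("stop", "deletion")])
    }, numeric(1))
    1 / min(totals)
  } else {
    if (!is.numeric(pseudocount) || pseudocount < 0) {
      abort("`pseudocount` must be \"auto\" or a non-negative number")
    }
    pseudocount
  }
}

#' Two-bin conservation ratio
#'
#' For each member, the ratio of its enrichment (versus the common input
#' library) in the antibody-bound bin to that in the unbound bin. Values
#' above 1 mark conservative variants (preferentially retained by the
#' antibody), values below 1 mark epitope escape. Members are ordered least
#' to most conservative; ties are broken by bound-bin fold enrichment, then
#' member id. `rank_within_position` ranks the same way inside each residue
#' position.
#'
#' @param bin_pos,bin_neg Fold-enrichment tibbles from [fold_enrichment()]
#'   for the antibody-positive and antibody-negative bins, both computed
#'   against the same input.
#' @return A tibble of class `seed_screen_scores`, ordered least to most
#'   conservative, with `bin_ratio`, `log2_bin_ratio` and
#'   `rank_within_position`.
#' @export
conservation_ratio <- function(bin_pos, bin_neg) {
  if (!setequal(bin_pos$member_id, bin_neg$member_id)) {
    abort("bins cover different member sets")
  }
  out <- bin_pos |>
    dplyr::rename(fe_pos = "fold_enrichment", log2_fe_pos = "log2_fe",
                  abund_pos = "abund_sel") |>
    left_join(select(bin_neg, "member_id", fe_neg = "fold_enrichment",
                     abund_neg = "abund_sel"),
              by = "member_id")
  if (any(out$fe_neg == 0)) {
    abort("zero denominator enrichment: use a positive pseudocount")
  }
  out <- out |>
    mutate(bin_ratio = .data$fe_pos / .data$fe_neg,
           log2_bin_ratio = log2(.data$bin_ratio)) |>
    arrange(.data$bin_ratio, .data$fe_pos, .data$member_id) |>
    group_by(.data$position) |>
    mutate(rank_within_position = row_number()) |>
    ungroup()
  class(out) <- c("seed_screen_scores", class(out))
  attr(out, "pseudocount") <- attr(bin_pos, "pseudocount")
  out
}

#' Score a two-bin sort screen
#'
#' Convenience wrapper: fold enrichment of each bin against the input
#' library, then the conservation ratio ([conservation_ratio()]).
#'
#' @param input,bin_neg,bin_pos Abundance tibbles from
#'   [compute_abundance()].
#' @inheritParams fold_enrichment
#' @return A `seed_screen_scores` tibble.
#' @export
score_screen <- function(input, bin_neg, bin_pos, pseudocount = "auto") {
  eps <- resolve_pseudocount(pseudocount, list(input, bin_neg, bin_pos))
  conservation_ratio(
    bin_pos = fold_enrichment(bin_pos, input, eps),
    bin_neg = fold_enrichment(bin_neg, input, eps)
  )
}

#' Average member scores over codons per amino acid
#'
#' Screens test most substitutions with more than one codon; the biological
#' unit is the amino-acid change, so scores are averaged (unweighted
#' arithmetic mean) over the codons of each (position, amino acid) pair.
#'
#' @param records A `seed_screen_scores` (or any member-level) tibble.
#' @param score_cols Columns to average.
#' @return A tibble with one row per (position, variant amino acid):
#'   means of `score_cols` plus `n_codons`.
#' @export
aggregate_by_amino_acid <- function(records,
                                    score_cols = c("bin_ratio",
                                                   "log2_bin_ratio")) {
  score_cols <- intersect(score_cols, names(records))
  if (length(score_cols) == 0) abort("no score columns to aggregate")
  records |>
    filter(!.data$control_class %in% c("stop", "deletion")) |>
    group_by(.data$position, .data$native_aa, .data$variant_aa) |>
    summarise(across(all_of(score_cols), mean), n_codons = n(),
              .groups = "drop")
}

#' Call epitope positions from amino-acid profiles
#'
#' A substitution escapes the antibody when its mean bin ratio falls at or
#' below `effect_threshold` (default 0.5, i.e. two-fold preferential
#' enrichment in the antibody-negative bin). A position is called part of
#' the epitope when at least `min_fraction_escaping` of its non-native
#' substitutions escape while the position still supports surface
#' expression. Thresholds are configurable; the defaults are the package's
#' own operating point.
#'
#' @param aa_profiles Output of [aggregate_by_amino_acid()] (must contain
#'   `bin_ratio` means).
#' @param effect_threshold Escape threshold on the bin-ratio scale (> 0).
#' @param min_fraction_escaping Fraction of substitutions that must escape
#'   (in (0, 1]).
#' @return Sorted integer vector of called positions, with the per-position
#'   detail tibble attached as attribute `detail`.
#' @export
call_epitope_positions <- function(aa_profiles, effect_threshold = 0.5,
                                   min_fraction_escaping = 0.5) {
  if (!is.numeric(effect_threshold) || effect_threshold <= 0) {
    abort("`effect_threshold` must be a positive bin ratio")
  }
  if (!is.numeric(min_fraction_escaping) || min_fraction_escaping <= 0 ||
      min_fraction_escaping > 1) {
    abort("`min_fraction_escaping` must be in (0, 1]")
  }
  detail <- aa_profiles |>
    filter(.data$variant_aa != .data$native_aa, .data$variant_aa != "*") |>
    group_by(.data$position) |>
    summarise(
      n_substitutions = n(),
      n_escaping = sum(.data$bin_ratio <= effect_threshold),
      fraction_escaping = .data$n_escaping / .data$n_substitutions,
      .groups = "drop"
    ) |>
    mutate(called = .data$fraction_escaping >= min_fraction_escaping)
  positions <- sort(detail$position[detail$called])
  attr(positions, "detail") <- detail
  positions
}

#' @exportS3Method generics::tidy
tidy.seed_screen_scores <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "seed_screen_scores")
  out
}

#' @exportS3Method generics::glance
glance.seed_screen_scores <- function(x, ...) {
  tibble(
    n_members = nrow(x),
    n_positions = dplyr::n_distinct(x$position),
    pseudocount = attr(x, "pseudocount") %||% NA_real_,
    median_bin_ratio = stats::median(x$bin_ratio),
    frac_escape = mean(x$bin_ratio < 1)
  )
}
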