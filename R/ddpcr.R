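# Droplet digital PCR translocation frequency. One well carries a FAM
# translocation assay and a HEX reference assay (single-copy gene); the
# balanced-translocation frequency is the FAM-positive droplet count
# normalized to the HEX-positive count.

#' Translocation frequency from droplet counts
#'
#' `naive` mode (the default) reports `100 * fam_positive / hex_positive`,
#' the direct positive-droplet normalization. `poisson` mode converts each
#' channel's positive fraction to a per-droplet concentration
#' `lambda = -ln(1 - k / total)` before taking the ratio, as ddPCR readers
#' conventionally do; the two agree as occupancy tends to zero, and the
#' naive value never exceeds the Poisson value.
#'
#' @param wells Tibble with columns `fam_positive`, `hex_positive` and (for
#'   `poisson` mode) `total_droplets`.
#' @param mode `"naive"` or `"poisson"`.
#' @return `wells` with a `transloc_pct` column appended (percent).
#' @export
#' @examples
#' translocation_frequency(
#'   tibble::tibble(fam_positive = 10, hex_positive = 1000,
#'                  total_droplets = 20000)
#' )
translocation_frequency <- function(wells, mode = c("naive", "poisson")) {
  mode <- match.arg(mode)
  wells <- as_tibble(wells)
  need <- c("fam_positive", "hex_positive",
            if (mode == "poisson") "total_droplets")
  missing_cols <- setdiff(need, names(wells))
  if (length(missing_cols)) {
    abort(sprintf("wells table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(wells$fam_positive < 0 | wells$hex_positive < 0)) {
    abort("droplet counts must be non-negative")
  }
  if ("total_droplets" %in% names(wells) &&
      any(wells$fam_positive > wells$total_droplets |
          wells$hex_positive > wells$total_droplets)) {
    abort("positive droplet counts exceed total droplets")
  }
  if (any(wells$hex_positive == 0)) {
    abort("hex_positive is zero: reference assay failed, frequency undefined")
  }
  if (mode == "naive") {
    wells$transloc_pct <- 100 * wells$fam_positive / wells$hex_positive
  } else {
    if (any(wells$fam_positive >= wells$total_droplets |
            wells$hex_positive >= wells$total_droplets)) {
      abort("saturated channel: every droplet positive, Poisson rate undefined")
    }
    lam_f <- -log(1 - wells$fam_positive / wells$total_droplets)
    lam_h <- -log(1 - wells$hex_positive / wells$total_droplets)
    wells$transloc_pct <- 100 * lam_f / lam_h
  }
  wells
}

#' Simulate a ddPCR well
#'
#' Draws binomial positive-droplet counts for a reference channel at
#' `ref_occupancy` and a translocation channel at
#' `ref_occupancy * true_fraction`, so the naive estimator is consistent for
#' `100 * true_fraction` at low occupancy.
#'
#' @param true_fraction True translocation fraction (0-1).
#' @param n_droplets Droplets per well.
#' @param ref_occupancy Fraction of droplets positive for the reference.
#' @param seed Integer seed.
#' @return A one-row wells tibble (`fam_positive`, `hex_positive`,
#'   `total_droplets`, `true_fraction`).
#' @export
simulate_ddpcr <- function(true_fraction, n_droplets = 20000L,
                           ref_occupancy = 0.15, seed = 42L) {
  if (true_fraction < 0 || true_fraction > 1) {
    abort("`true_fraction` must be in [0, 1]")
  }
  withr::with_seed(seed, {
    hex <- rbinom(1, n_droplets, ref_occupancy)
    fam <- rbinom(1, n_droplets, ref_occupancy * true_fraction)
  })
  tibble(fam_positive = fam, hex_positive = hex,
         total_droplets = as.integer(n_droplets),
         true_fraction = true_fraction)
}
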