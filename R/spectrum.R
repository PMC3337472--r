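# Allele spectra and screen tallies: the observed data of a saturation screen.

#' Construct an allele spectrum
#'
#' An allele spectrum records, for each locus recovered in a screen, how many
#' independently isolated mutations (alleles) hit it. It is the sufficient
#' statistic for all saturation inference in this package: loci with zero
#' alleles are unobservable by construction, so every count is >= 1.
#'
#' @param alleles_per_locus Integer vector of allele counts, one per locus,
#'   all >= 1. May be empty (a screen that retained nothing).
#' @param locus_ids Optional character labels, one per locus; defaults to
#'   `locus_01`, `locus_02`, ...
#' @return An object of class `allele_spectrum` with fields `locus_id`,
#'   `n_alleles`, `n_loci`, `n_mutations` and `histogram` (number of loci with
#'   exactly k alleles, named by k).
#' @examples
#' # the published screen: 45 mutations over 24 loci
#' sp <- read_spectrum(mosaicsat_example("table1_spectrum.tsv"))
#' mean_alleles_per_locus(sp)
#' @export
allele_spectrum <- function(alleles_per_locus, locus_ids = NULL) {
  if (length(alleles_per_locus) &&
      (!is.numeric(alleles_per_locus) || anyNA(alleles_per_locus))) {
    abort_validation("`alleles_per_locus` must be numeric with no missing values")
  }
  alleles_per_locus <- as.numeric(alleles_per_locus)
  if (any(abs(alleles_per_locus - round(alleles_per_locus)) > 1e-8)) {
    abort_validation("allele counts must be whole numbers")
  }
  alleles_per_locus <- as.integer(round(alleles_per_locus))
  if (any(alleles_per_locus < 1L)) {
    abort_validation("every locus in an allele spectrum must have >= 1 allele (the zero class is unobservable)")
  }
  n <- length(alleles_per_locus)
  if (is.null(locus_ids)) {
    locus_ids <- sprintf("locus_%02d", seq_len(n))
  }
  locus_ids <- as.character(locus_ids)
  if (length(locus_ids) != n) {
    abort_validation("`locus_ids` must match `alleles_per_locus` in length")
  }
  if (anyDuplicated(locus_ids)) {
    abort_validation(sprintf("duplicated locus_id: %s",
                             locus_ids[duplicated(locus_ids)][1L]))
  }
  hist <- table(alleles_per_locus)
  structure(
    list(
      locus_id = locus_ids,
      n_alleles = alleles_per_locus,
      n_loci = n,
      n_mutations = sum(alleles_per_locus),
      histogram = stats::setNames(as.integer(hist), names(hist))
    ),
    class = "allele_spectrum"
  )
}

#' @export
print.allele_spectrum <- function(x, ...) {
  cat(sprintf("Allele spectrum: %d mutations over %d loci\n",
              x$n_mutations, x$n_loci))
  if (x$n_loci > 0) {
    cat("  alleles-per-locus histogram (k: loci):\n")
    for (k in names(x$histogram)) {
      cat(sprintf("    %s: %d\n", k, x$histogram[[k]]))
    }
  }
  invisible(x)
}

#' Mean number of alleles per locus
#'
#' @param spectrum An [allele_spectrum()] with at least one locus.
#' @return A list with `value` (`n_mutations / n_loci`) and `report` (rounded
#'   half away from zero to one decimal, the form usually quoted).
#' @export
mean_alleles_per_locus <- function(spectrum) {
  stopifnot(inherits(spectrum, "allele_spectrum"))
  if (spectrum$n_loci < 1) {
    abort_validation("cannot compute mean alleles per locus of an empty spectrum")
  }
  m <- spectrum$n_mutations / spectrum$n_loci
  list(value = m, report = round_half_up(m, 1))
}

#' Tally of screen attrition counts
#'
#' Records the attrition of candidates through an F1 mosaic screen: F1
#' candidates scored, mutants recovered as balanced stocks, and mutations
#' retained after the penetrance/expressivity filter.
#'
#' @param n_f1_candidates,n_recovered,n_retained Non-negative integers with
#'   `n_retained <= n_recovered <= n_f1_candidates`.
#' @return An object of class `screen_tally`.
#' @examples
#' screen_tally(950, 73, 45)
#' @export
screen_tally <- function(n_f1_candidates, n_recovered, n_retained) {
  check_scalar_number(n_f1_candidates, "n_f1_candidates", min = 0, integerish = TRUE)
  check_scalar_number(n_recovered, "n_recovered", min = 0, integerish = TRUE)
  check_scalar_number(n_retained, "n_retained", min = 0, integerish = TRUE)
  if (n_recovered > n_f1_candidates) {
    abort_validation("n_recovered cannot exceed n_f1_candidates")
  }
  if (n_retained > n_recovered) {
    abort_validation("n_retained cannot exceed n_recovered")
  }
  structure(
    list(n_f1_candidates = n_f1_candidates,
         n_recovered = n_recovered,
         n_retained = n_retained),
    class = "screen_tally"
  )
}

#' @export
print.screen_tally <- function(x, ...) {
  cat(sprintf("Screen tally: %g F1 candidates -> %g recovered -> %g retained\n",
              x$n_f1_candidates, x$n_recovered, x$n_retained))
  invisible(x)
}

#' F1-to-stock recovery rate
#'
#' Fraction of F1 candidate mutants that were recovered as balanced stocks.
#'
#' @param tally A [screen_tally()] with `n_f1_candidates >= 1`.
#' @return A list with `value` (the proportion) and `report_percent` (the
#'   nearest-integer percentage usually quoted).
#' @examples
#' f1_recovery_rate(screen_tally(950, 73, 45))  # 0.0768..., reported as 8%
#' @export
f1_recovery_rate <- function(tally) {
  stopifnot(inherits(tally, "screen_tally"))
  if (tally$n_f1_candidates < 1) {
    abort_validation("n_f1_candidates must be >= 1 to compute a recovery rate")
  }
  p <- tally$n_recovered / tally$n_f1_candidates
  list(value = p, report_percent = round_half_up(100 * p))
}

#' Observed-to-expected allele recovery ratio
#'
#' Ratio of the observed mean alleles per locus to the mean expected from the
#' mutagenesis arithmetic. This is the effective per-mutation survival
#' fraction through the whole screen (detection, recovery, penetrance
#' filtering combined), and is usefully compared with the independently
#' measured F1 recovery rate for order-of-magnitude agreement.
#'
#' @param observed_mean Observed mean alleles per locus (>= 0).
#' @param expected_mean Expected mean hits per gene from the design (> 0).
#' @return The ratio, a single number.
#' @export
allele_recovery_ratio <- function(observed_mean, expected_mean) {
  check_scalar_number(observed_mean, "observed_mean", min = 0)
  check_scalar_number(expected_mean, "expected_mean")
  if (expected_mean <= 0) {
    abort_validation("expected_mean must be > 0")
  }
  observed_mean / expected_mean
}
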