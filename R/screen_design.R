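# Poisson screen-design arithmetic for saturation mutagenesis screens.

#' Describe the design of a saturation mutagenesis screen
#'
#' A `screen_design` collects the mutagenesis arithmetic inputs of an F1
#' mosaic saturation screen: how many chromosome arms were mutagenized, the
#' expected number of lethal mutations induced per arm, and how many essential
#' genes lie in the screened fraction of the genome.
#'
#' The published Drosophila miRNA-pathway screen that motivates the defaults
#' elsewhere in this package screened 56,000 EMS-mutagenized arms at an
#' induction rate of 0.65 lethal mutations per arm, covering roughly 40% of
#' the ~3600 essential genes (~1440 genes on chromosome arms 2R and 3R).
#' That report also states a total of 29,900 lethal mutations screened, which
#' is not equal to 56,000 x 0.65 = 36,400; the optional
#' `lethal_mutations_screened` override exists to reproduce such printed
#' totals exactly while flagging the inconsistency (see
#' [expected_lethal_mutations()]).
#'
#' @param arms_screened Number of mutagenized chromosome arms scored.
#' @param lethal_rate_per_arm Expected lethal mutations induced per arm
#'   (dimensionless rate, >= 0).
#' @param essential_genes_total Number of essential genes genome-wide.
#' @param fraction_screened Proportion of the genome covered by the screen,
#'   in `[0, 1]`.
#' @param essential_genes_in_screen Number of essential genes in the screened
#'   fraction. Defaults to `round(essential_genes_total * fraction_screened)`
#'   (half away from zero), overridable because published counts are often
#'   themselves rounded.
#' @param lethal_mutations_screened Optional authoritative override for the
#'   total number of lethal mutations screened. When present it takes
#'   precedence over `arms_screened * lethal_rate_per_arm`.
#'
#' @return An object of class `screen_design`.
#' @seealso [expected_lethal_mutations()], [expected_hits_per_gene()],
#'   [coverage_probability()], [arms_needed()]
#' @examples
#' d <- screen_design(arms_screened = 56000, lethal_rate_per_arm = 0.65,
#'                    essential_genes_total = 3600, fraction_screened = 0.4,
#'                    essential_genes_in_screen = 1440,
#'                    lethal_mutations_screened = 29900)
#' expected_hits_per_gene(d)$report
#' @export
screen_design <- function(arms_screened,
                          lethal_rate_per_arm,
                          essential_genes_total,
                          fraction_screened = 1,
                          essential_genes_in_screen = NULL,
                          lethal_mutations_screened = NULL) {
  check_scalar_number(arms_screened, "arms_screened", min = 0, integerish = TRUE)
  check_scalar_number(lethal_rate_per_arm, "lethal_rate_per_arm", min = 0)
  check_scalar_number(essential_genes_total, "essential_genes_total",
                      min = 0, integerish = TRUE)
  check_probability(fraction_screened, "fraction_screened")
  check_scalar_number(essential_genes_in_screen, "essential_genes_in_screen",
                      min = 0, integerish = TRUE, allow_null = TRUE)
  check_scalar_number(lethal_mutations_screened, "lethal_mutations_screened",
                      min = 0, allow_null = TRUE)

  if (is.null(essential_genes_in_screen)) {
    essential_genes_in_screen <-
      round_half_up(essential_genes_total * fraction_screened)
  }
  if (essential_genes_in_screen > essential_genes_total) {
    abort_validation(sprintf(
      "essential_genes_in_screen (%s) exceeds essential_genes_total (%s)",
      essential_genes_in_screen, essential_genes_total))
  }

  structure(
    list(
      arms_screened = as.numeric(arms_screened),
      lethal_rate_per_arm = as.numeric(lethal_rate_per_arm),
      essential_genes_total = as.numeric(essential_genes_total),
      fraction_screened = as.numeric(fraction_screened),
      essential_genes_in_screen = as.numeric(essential_genes_in_screen),
      lethal_mutations_screened =
        if (is.null(lethal_mutations_screened)) NULL
        else as.numeric(lethal_mutations_screened)
    ),
    class = "screen_design"
  )
}

#' @export
print.screen_design <- function(x, ...) {
  cat("Saturation screen design\n")
  cat(sprintf("  arms screened:          %g\n", x$arms_screened))
  cat(sprintf("  lethal rate per arm:    %g\n", x$lethal_rate_per_arm))
  cat(sprintf("  essential genes total:  %g (fraction screened %g -> %g in screen)\n",
              x$essential_genes_total, x$fraction_screened,
              x$essential_genes_in_screen))
  if (!is.null(x$lethal_mutations_screened)) {
    cat(sprintf("  lethal mutations screened (override): %g\n",
                x$lethal_mutations_screened))
  }
  invisible(x)
}

#' Expected number of lethal mutations screened
#'
#' Returns `arms_screened * lethal_rate_per_arm`, unless the design carries an
#' explicit `lethal_mutations_screened` override, in which case the override
#' is returned and a consistency warning (class
#' `mosaicsat_inconsistency_warning`) is raised whenever the two disagree.
#' The override path exists because published totals do not always equal the
#' product of their printed factors, yet downstream headline numbers are
#' computed from the printed total.
#'
#' @param design A [screen_design()].
#' @return Expected (or overridden) count of lethal mutations, a single number.
#' @export
expected_lethal_mutations <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  product <- design$arms_screened * design$lethal_rate_per_arm
  if (!is.null(design$lethal_mutations_screened)) {
    override <- design$lethal_mutations_screened
    if (abs(product - override) > 1e-8) {
      warn_mosaicsat(sprintf(
        paste0("lethal_mutations_screened override (%g) differs from ",
               "arms_screened x lethal_rate_per_arm = %g; using the override"),
        override, product),
        class = "mosaicsat_inconsistency_warning")
    }
    return(override)
  }
  product
}

#' Expected mutational hits per essential gene
#'
#' The Poisson mean number of lethal hits per essential gene in the screened
#' fraction: total lethal mutations screened divided by the number of
#' essential genes in the screen.
#'
#' @param design A [screen_design()] with `essential_genes_in_screen >= 1`.
#' @return A list with `value` (the real mean) and `report` (the value rounded
#'   half away from zero to the nearest integer, the form usually quoted).
#' @examples
#' d <- screen_design(56000, 0.65, 3600, 0.4, 1440, 29900)
#' suppressWarnings(expected_hits_per_gene(d))  # 20.76..., reported as 21
#' @export
expected_hits_per_gene <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  if (design$essential_genes_in_screen < 1) {
    abort_validation("essential_genes_in_screen must be >= 1 to compute hits per gene")
  }
  lam <- expected_lethal_mutations(design) / design$essential_genes_in_screen
  list(value = lam, report = round_half_up(lam))
}

#' Probability that a gene is hit at least once
#'
#' Under a Poisson model with mean `mean_hits` mutations per gene, the
#' probability that a given gene receives at least one hit is
#' `1 - exp(-mean_hits)`.
#'
#' @param mean_hits Poisson mean hits per gene (lambda >= 0); vectorized.
#' @return Probability in `[0, 1)`, same length as `mean_hits`.
#' @export
coverage_probability <- function(mean_hits) {
  if (!is.numeric(mean_hits) || length(mean_hits) < 1L || anyNA(mean_hits)) {
    abort_validation("`mean_hits` must be numeric and non-missing")
  }
  if (any(mean_hits < 0)) abort_validation("`mean_hits` must be >= 0")
  -expm1(-mean_hits)
}

#' Minimal number of arms to reach a target coverage
#'
#' Inverts [coverage_probability()] for planning: the smallest integer number
#' of mutagenized arms `A` such that a gene in the screened fraction is hit at
#' least once with probability at least `target_coverage`, i.e.
#' `1 - exp(-A * rate / genes) >= target_coverage`.
#'
#' @param target_coverage Desired per-gene coverage probability in `[0, 1)`.
#' @param design A [screen_design()] with positive `lethal_rate_per_arm` and
#'   at least one essential gene in the screen.
#' @return Minimal arm count (non-negative integer).
#' @export
arms_needed <- function(target_coverage, design) {
  stopifnot(inherits(design, "screen_design"))
  check_scalar_number(target_coverage, "target_coverage", min = 0)
  if (target_coverage >= 1) {
    abort_validation("target_coverage must be < 1: full coverage is unattainable")
  }
  if (design$lethal_rate_per_arm <= 0) {
    abort_validation("lethal_rate_per_arm must be > 0 to plan arm numbers")
  }
  if (design$essential_genes_in_screen < 1) {
    abort_validation("essential_genes_in_screen must be >= 1")
  }
  per_arm <- design$lethal_rate_per_arm / design$essential_genes_in_screen
  a <- ceiling(-log1p(-target_coverage) / per_arm)
  # guard the closed form against floating-point boundary error
  while (a > 0 && coverage_probability((a - 1) * per_arm) >= target_coverage) a <- a - 1
  while (coverage_probability(a * per_arm) < target_coverage) a <- a + 1
  as.integer(a)
}
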