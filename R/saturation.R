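# Saturation and total-locus estimation from an observed allele spectrum.
#
# Model: hits per detectable locus ~ Poisson(lambda); a locus is observed iff
# hit >= 1 time, so observed counts are zero-truncated Poisson. Saturation is
# the fraction of detectable loci observed, P(hit >= 1) = 1 - exp(-lambda).

# Mean of a zero-truncated Poisson with rate lambda: lambda / (1 - e^-lambda).
# Strictly increasing on (0, Inf), -> 1 as lambda -> 0+.
ztp_mean_map <- function(lambda) lambda / (-expm1(-lambda))

new_saturation_estimate <- function(method, lambda_hat, spectrum,
                                    interval = NULL, n_bootstrap = NULL,
                                    seed = NULL) {
  saturation <- -expm1(-lambda_hat)
  total <- spectrum$n_loci / saturation
  structure(
    list(
      method = method,
      lambda_hat = lambda_hat,
      saturation = saturation,
      total_loci = total,
      n_loci = spectrum$n_loci,
      n_mutations = spectrum$n_mutations,
      report = list(
        saturation_percent = round_half_up(100 * saturation),
        total_loci = round_half_up(total)
      ),
      # every mutation a distinct gene: the trivial ceiling on total loci
      total_loci_upper_trivial = spectrum$n_mutations,
      interval = interval,
      n_bootstrap = n_bootstrap,
      seed = seed
    ),
    class = "saturation_estimate"
  )
}

#' @export
print.saturation_estimate <- function(x, ...) {
  cat(sprintf("Saturation estimate (%s)\n", x$method))
  cat(sprintf("  lambda_hat:  %.4f alleles per detectable locus\n", x$lambda_hat))
  cat(sprintf("  saturation:  %.4f  (report: %g%%)\n",
              x$saturation, x$report$saturation_percent))
  cat(sprintf("  total loci:  %.2f  (report: %g; observed %d; trivial upper bound %d)\n",
              x$total_loci, x$report$total_loci, x$n_loci,
              x$total_loci_upper_trivial))
  if (!is.null(x$interval)) {
    cat(sprintf("  %g%% bootstrap interval for total loci: [%.2f, %.2f] (n_boot = %d, seed = %d)\n",
                100 * x$interval$level, x$interval$total_loci[1],
                x$interval$total_loci[2], x$n_bootstrap, x$seed))
  }
  invisible(x)
}

#' Plug-in Poisson saturation estimate
#'
#' The classical back-of-the-envelope rule for saturation screens: take the
#' observed mean alleles per locus as the Poisson mean, so the estimated
#' fraction of detectable loci observed is `1 - exp(-mean)` and the estimated
#' total number of detectable loci is `n_loci / saturation`. This treats the
#' observed mean as if it were the untruncated Poisson mean; because unhit
#' loci are invisible, the observed mean overstates lambda and the plug-in
#' rule therefore overstates saturation (see [ztp_mle()] for the corrected
#' estimator).
#'
#' @param spectrum An [allele_spectrum()] with at least one locus.
#' @param use_rounded_mean If `TRUE`, use the one-decimal rounded mean (the
#'   form quoted in reports) instead of the exact mean; the two usually agree
#'   after presentation rounding.
#' @return A `saturation_estimate` (method `"plug_in"`) with `lambda_hat`,
#'   `saturation`, `total_loci` and nearest-percent / nearest-integer reports.
#' @examples
#' sp <- read_spectrum(mosaicsat_example("table1_spectrum.tsv"))
#' plug_in_saturation(sp)  # saturation ~0.847 (85%), total ~28.4 (28)
#' @export
plug_in_saturation <- function(spectrum, use_rounded_mean = FALSE) {
  stopifnot(inherits(spectrum, "allele_spectrum"))
  m <- mean_alleles_per_locus(spectrum)
  lambda <- if (use_rounded_mean) m$report else m$value
  new_saturation_estimate("plug_in", lambda, spectrum)
}

# Solve lambda / (1 - e^-lambda) = target_mean by bisection on the strictly
# increasing mean map, bracketed on (1e-9, target_mean]; unconditional
# convergence, unlike Newton.
solve_ztp_lambda <- function(target_mean, tol = 1e-10) {
  lo <- 1e-9
  hi <- target_mean  # ztp_mean_map(m) > m for all m > 0, so the root is below m
  mid <- (lo + hi) / 2
  for (i in seq_len(1000L)) {
    mid <- (lo + hi) / 2
    g <- ztp_mean_map(mid)
    if (abs(g - target_mean) <= tol || (hi - lo) < .Machine$double.eps * hi) {
      return(mid)
    }
    if (g < target_mean) lo <- mid else hi <- mid
  }
  mid
}

#' Zero-truncated Poisson maximum-likelihood saturation estimate
#'
#' The observed allele spectrum is zero-truncated: loci with no alleles are
#' unobservable. Under the Poisson model the maximum-likelihood estimate of
#' the per-locus rate therefore solves the zero-truncated mean equation
#' `lambda / (1 - exp(-lambda)) = observed mean` (the stationarity condition
#' of the zero-truncated Poisson log-likelihood). The solution always lies
#' below the observed mean, so the ZTP estimate of saturation is smaller, and
#' the total-locus estimate larger, than the plug-in values.
#'
#' @param spectrum An [allele_spectrum()] whose mean alleles per locus
#'   exceeds 1. An all-singleton spectrum (mean exactly 1) is the degenerate
#'   boundary where `lambda -> 0` and saturation is unidentifiable; it raises
#'   an error of class `mosaicsat_degenerate_error`.
#' @param tol Absolute tolerance on the mean equation residual
#'   `|lambda/(1 - exp(-lambda)) - mean|`.
#' @return A `saturation_estimate` (method `"ztp_mle"`).
#' @examples
#' sp <- read_spectrum(mosaicsat_example("table1_spectrum.tsv"))
#' ztp_mle(sp)  # lambda_hat ~1.423, saturation ~0.759, total ~31.6
#' @export
ztp_mle <- function(spectrum, tol = 1e-10) {
  stopifnot(inherits(spectrum, "allele_spectrum"))
  check_scalar_number(tol, "tol")
  if (tol <= 0) abort_validation("`tol` must be > 0")
  m <- mean_alleles_per_locus(spectrum)$value
  if (m <= 1) {
    abort_degenerate(paste0(
      "observed mean alleles per locus is ", format(m), " <= 1 ",
      "(all loci are singletons): the zero-truncated Poisson rate tends to 0 ",
      "and saturation is unidentifiable. More multi-allele loci are needed ",
      "before saturation can be estimated."))
  }
  lambda <- solve_ztp_lambda(m, tol = tol)
  new_saturation_estimate("ztp_mle", lambda, spectrum)
}

#' Bootstrap percentile interval for a saturation estimate
#'
#' Resamples loci (the exchangeable units of an allele spectrum) with
#' replacement, re-estimates saturation and total loci on each resample, and
#' returns percentile intervals. Mutations are deliberately not the resampling
#' unit: resampling mutations would break the zero-truncation structure of
#' the spectrum.
#'
#' Under `method = "ztp_mle"`, resamples whose mean drops to 1 or below are
#' degenerate and are redrawn (up to 100 attempts per resample, with a
#' warning reporting how many redraws occurred).
#'
#' @param spectrum An [allele_spectrum()] with at least two loci.
#' @param method `"plug_in"` or `"ztp_mle"`.
#' @param level Confidence level in `(0, 1)`.
#' @param n_boot Number of bootstrap resamples, >= 100.
#' @param seed Integer seed; required, so intervals are reproducible.
#' @return A list of class `bootstrap_interval` with elements `total_loci`,
#'   `saturation` and `lambda_hat` (each `c(lower, upper)`), the point
#'   `estimate`, `level`, `n_boot`, `seed` and `n_redrawn`.
#' @export
bootstrap_interval <- function(spectrum, method = c("plug_in", "ztp_mle"),
                               level = 0.95, n_boot = 1000L, seed) {
  stopifnot(inherits(spectrum, "allele_spectrum"))
  method <- match.arg(method)
  check_scalar_number(level, "level")
  if (level <= 0 || level >= 1) abort_validation("`level` must be in (0, 1)")
  check_scalar_number(n_boot, "n_boot", min = 100, integerish = TRUE)
  if (missing(seed)) abort_validation("`seed` must be supplied for bootstrap_interval")
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (spectrum$n_loci < 2) {
    abort_degenerate("cannot bootstrap a spectrum with fewer than 2 loci")
  }

  point <- switch(method,
    plug_in = plug_in_saturation(spectrum),
    ztp_mle = ztp_mle(spectrum)
  )

  counts <- spectrum$n_alleles
  n <- spectrum$n_loci
  lambda_b <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(100L)) {
        res <- counts[sample.int(n, n, replace = TRUE)]
        m <- mean(res)
        if (method == "plug_in" || m > 1) break
        n_redrawn <- n_redrawn + 1L
        if (attempt == 100L) {
          abort_degenerate(paste0(
            "bootstrap resamples are persistently degenerate (mean <= 1); ",
            "the spectrum is too close to all-singleton for a ztp_mle interval"))
        }
      }
      lambda_b[b] <- if (method == "plug_in") m else solve_ztp_lambda(m)
    }
  })
  if (n_redrawn > 0L) {
    warn_mosaicsat(sprintf(
      "%d degenerate bootstrap resamples (mean <= 1) were redrawn", n_redrawn))
  }

  sat_b <- -expm1(-lambda_b)
  total_b <- n / sat_b
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  structure(
    list(
      method = method,
      estimate = point,
      lambda_hat = stats::quantile(lambda_b, probs, names = FALSE),
      saturation = stats::quantile(sat_b, probs, names = FALSE),
      total_loci = stats::quantile(total_b, probs, names = FALSE),
      level = level,
      n_boot = as.integer(n_boot),
      seed = as.integer(seed),
      n_redrawn = n_redrawn
    ),
    class = "bootstrap_interval"
  )
}

#' @export
print.bootstrap_interval <- function(x, ...) {
  cat(sprintf("Bootstrap percentile intervals (%s, %g%%, n_boot = %d, seed = %d)\n",
              x$method, 100 * x$level, x$n_boot, x$seed))
  cat(sprintf("  total loci:  point %.2f, interval [%.2f, %.2f]\n",
              x$estimate$total_loci, x$total_loci[1], x$total_loci[2]))
  cat(sprintf("  saturation:  point %.4f, interval [%.4f, %.4f]\n",
              x$estimate$saturation, x$saturation[1], x$saturation[2]))
  if (x$n_redrawn > 0) {
    cat(sprintf("  (%d degenerate resamples redrawn)\n", x$n_redrawn))
  }
  invisible(x)
}
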