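# Stochastic simulator of an F1 mosaic saturation screen, with ground truth.
#
# Generative model (single RNG stream, seeded once; draw order is fixed and
# documented in simulate_screen so runs are reproducible):
#   1. total lethal mutations ~ Poisson(arms x rate)
#   2. each mutation lands on an essential gene (multinomial by gene_weights;
#      equivalently independent per-gene Poissons)
#   3. mutations in pathway genes give a scorable F1 phenotype w.p. p_f1_detect
#   4. detected candidates survive to balanced stocks w.p. p_recover
#   5. recovered mutations pass the penetrance/expressivity filter w.p. p_penetrant
#   6. each mutation is an isoform-restricted hypomorph w.p. p_hypomorph
#   7. pairwise complementation tests among retained mutations: same-gene
#      pairs fail unless a hypomorph is involved; each test is mis-scored
#      (result flipped) w.p. p_test_error

#' Parameters of a simulated F1 mosaic screen
#'
#' Defaults are the conditions of the published Drosophila miRNA-pathway
#' screen this package accompanies: 56,000 EMS-mutagenized arms at 0.65
#' lethal mutations per arm, ~1440 essential genes in the screened 40% of the
#' genome, and the screen's own attrition — recovery probability 73/950 and
#' penetrance-filter pass probability 45/73. The detectable pathway subset
#' defaults to 30 genes, a round value inside the 28–45 range that saturation
#' analysis of the published spectrum supports.
#'
#' @param arms_screened Mutagenized arms scored.
#' @param lethal_rate_per_arm Expected lethal mutations per arm.
#' @param n_essential_genes Essential genes in the screened fraction.
#' @param n_pathway_genes Size of the detectable (pathway) gene subset;
#'   mutations outside it never give a scorable phenotype.
#' @param gene_weights Optional relative mutational target sizes, length
#'   `n_essential_genes` (default uniform).
#' @param p_f1_detect Probability a pathway-gene mutation yields a scorable
#'   F1 phenotype.
#' @param p_recover Probability a scored F1 candidate is recovered as a
#'   balanced stock.
#' @param p_penetrant Probability a recovered mutation passes the
#'   penetrance/expressivity filter.
#' @param p_hypomorph Probability a mutation is an isoform-restricted
#'   hypomorph (complements other alleles of its own gene).
#' @param p_test_error Probability a pairwise complementation test is
#'   mis-scored (result flipped).
#' @param seed Integer seed; required.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(arms_screened = 56000,
                              lethal_rate_per_arm = 0.65,
                              n_essential_genes = 1440,
                              n_pathway_genes = 30,
                              gene_weights = NULL,
                              p_f1_detect = 1,
                              p_recover = 73 / 950,
                              p_penetrant = 45 / 73,
                              p_hypomorph = 0,
                              p_test_error = 0,
                              seed) {
  check_scalar_number(arms_screened, "arms_screened", min = 0, integerish = TRUE)
  check_scalar_number(lethal_rate_per_arm, "lethal_rate_per_arm", min = 0)
  check_scalar_number(n_essential_genes, "n_essential_genes", min = 1,
                      integerish = TRUE)
  check_scalar_number(n_pathway_genes, "n_pathway_genes", min = 0,
                      integerish = TRUE)
  if (n_pathway_genes > n_essential_genes) {
    abort_validation("n_pathway_genes cannot exceed n_essential_genes")
  }
  for (p in c("p_f1_detect", "p_recover", "p_penetrant", "p_hypomorph",
              "p_test_error")) {
    check_probability(get(p), p)
  }
  if (missing(seed)) abort_validation("`seed` must be supplied for simulation_params")
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (!is.null(gene_weights)) {
    if (!is.numeric(gene_weights) || length(gene_weights) != n_essential_genes ||
        anyNA(gene_weights) || any(gene_weights < 0) || sum(gene_weights) <= 0) {
      abort_validation("`gene_weights` must be non-negative, length n_essential_genes, with positive sum")
    }
  }
  structure(
    list(arms_screened = arms_screened,
         lethal_rate_per_arm = lethal_rate_per_arm,
         n_essential_genes = as.integer(n_essential_genes),
         n_pathway_genes = as.integer(n_pathway_genes),
         gene_weights = gene_weights,
         p_f1_detect = p_f1_detect,
         p_recover = p_recover,
         p_penetrant = p_penetrant,
         p_hypomorph = p_hypomorph,
         p_test_error = p_test_error,
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

#' Simulate one F1 mosaic saturation screen
#'
#' Draws a whole screen from the generative model described above: lethal
#' mutations over genes, F1 detection of pathway-gene mutations, Bernoulli
#' recovery and penetrance attrition, and the complementation matrix that the
#' retained mutations would produce (same-gene pairs fail to complement,
#' hypomorphs excepted, with optional mis-scoring noise). Fully reproducible
#' from `params$seed`.
#'
#' @param params A [simulation_params()].
#' @return An object of class `simulated_screen` with:
#'   \item{mutations}{data frame `mutation_id`, `true_gene`,
#'     `is_pathway_gene`, `is_hypomorph`, `fate` (one of `not_detected`,
#'     `lost_f1`, `recovered_weak`, `retained`).}
#'   \item{spectrum}{[allele_spectrum()] over the retained mutations, locus
#'     ids being the true genes.}
#'   \item{matrix}{[complementation_matrix()] over the retained mutations.}
#'   \item{truth}{ground truth: `n_pathway_genes`, per-pathway-gene hit
#'     counts (pre-attrition), and the parameter echo.}
#' @examples
#' sim <- simulate_screen(simulation_params(arms_screened = 4600,
#'   n_essential_genes = 144, seed = 1))
#' sim$spectrum
#' @export
simulate_screen <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    n_total <- stats::rpois(1L, params$arms_screened * params$lethal_rate_per_arm)
    gene <- if (n_total > 0) {
      sample.int(params$n_essential_genes, n_total, replace = TRUE,
                 prob = params$gene_weights)
    } else integer()
    is_pathway <- gene <= params$n_pathway_genes
    detected <- is_pathway & stats::runif(n_total) < params$p_f1_detect
    recovered <- detected & stats::runif(n_total) < params$p_recover
    retained <- recovered & stats::runif(n_total) < params$p_penetrant
    hypomorph <- stats::runif(n_total) < params$p_hypomorph

    fate <- rep("not_detected", n_total)
    fate[detected & !recovered] <- "lost_f1"
    fate[recovered & !retained] <- "recovered_weak"
    fate[retained] <- "retained"

    mutations <- data.frame(
      mutation_id = sprintf("M%05d", seq_len(n_total)),
      true_gene = sprintf("gene_%04d", gene),
      is_pathway_gene = is_pathway,
      is_hypomorph = hypomorph,
      fate = fate,
      stringsAsFactors = FALSE
    )

    ret <- mutations[mutations$fate == "retained", , drop = FALSE]
    counts <- table(ret$true_gene)
    spectrum <- allele_spectrum(as.integer(counts), names(counts))

    # pairwise complementation among retained mutations, deterministic pair
    # order (i < j over the sorted retained ids)
    ids <- sort(ret$mutation_id)
    gene_of <- stats::setNames(ret$true_gene, ret$mutation_id)
    hypo_of <- stats::setNames(ret$is_hypomorph, ret$mutation_id)
    if (length(ids) >= 2L) {
      cmb <- utils::combn(ids, 2L)
      a <- cmb[1L, ]; b <- cmb[2L, ]
      true_fail <- gene_of[a] == gene_of[b] & !hypo_of[a] & !hypo_of[b]
      result <- ifelse(true_fail, "fails", "complements")
      flip <- stats::runif(length(a)) < params$p_test_error
      result[flip] <- ifelse(result[flip] == "fails", "complements", "fails")
      pairs <- data.frame(mutation_a = a, mutation_b = b, result = result,
                          channel = "lethality", stringsAsFactors = FALSE)
    } else {
      pairs <- data.frame(mutation_a = character(), mutation_b = character(),
                          result = character(), channel = character(),
                          stringsAsFactors = FALSE)
    }
    cmatrix <- complementation_matrix(pairs, mutation_ids = ids)

    pathway_hits <- table(factor(
      mutations$true_gene[mutations$is_pathway_gene],
      levels = sprintf("gene_%04d", seq_len(params$n_pathway_genes))))

    structure(
      list(
        mutations = mutations,
        spectrum = spectrum,
        matrix = cmatrix,
        truth = list(
          n_pathway_genes = params$n_pathway_genes,
          pathway_gene_hits = stats::setNames(as.integer(pathway_hits),
                                              names(pathway_hits)),
          true_partition = split(ret$mutation_id, ret$true_gene),
          params = params
        )
      ),
      class = "simulated_screen"
    )
  })
}

#' @export
print.simulated_screen <- function(x, ...) {
  f <- table(factor(x$mutations$fate,
                    levels = c("not_detected", "lost_f1", "recovered_weak",
                               "retained")))
  cat(sprintf("Simulated screen (seed %d): %d lethal mutations\n",
              x$truth$params$seed, nrow(x$mutations)))
  cat(sprintf("  fates: %s\n",
              paste(sprintf("%s %d", names(f), f), collapse = ", ")))
  cat(sprintf("  retained spectrum: %d mutations over %d loci (of %d pathway genes)\n",
              x$spectrum$n_mutations, x$spectrum$n_loci,
              x$truth$n_pathway_genes))
  invisible(x)
}

#' Validate the saturation estimators by parameter recovery
#'
#' Runs `n_reps` independent simulated screens, applies both the plug-in and
#' the zero-truncated-Poisson estimators to each retained spectrum, and
#' summarizes how well the true number of pathway genes is recovered.
#' Replicates whose spectrum is degenerate for the ZTP estimator (observed
#' mean <= 1, or no retained loci) are counted and excluded from the ZTP
#' summaries, with a warning.
#'
#' @param params A [simulation_params()]; its `seed` is ignored here.
#' @param n_reps Number of replicate screens, >= 50.
#' @param seed Integer seed for the whole harness; replicate r uses
#'   `seed + r`.
#' @param n_boot Bootstrap resamples per replicate used to measure
#'   interval coverage of the true gene count (0 disables the coverage
#'   computation, which dominates the run time).
#' @param level Confidence level for the coverage intervals.
#' @return An object of class `estimator_validation`: per-replicate results
#'   (`replicates` data frame) and a `summary` list with mean/SD/bias of the
#'   total-locus estimates per method, degenerate counts, and (when measured)
#'   bootstrap-interval coverage.
#' @export
validate_estimators <- function(params, n_reps = 200L, seed,
                                n_boot = 0L, level = 0.95) {
  stopifnot(inherits(params, "simulation_params"))
  check_scalar_number(n_reps, "n_reps", min = 50, integerish = TRUE)
  if (missing(seed)) abort_validation("`seed` must be supplied for validate_estimators")
  check_scalar_number(seed, "seed", integerish = TRUE)
  check_scalar_number(n_boot, "n_boot", min = 0, integerish = TRUE)
  if (seed + n_reps + 1e6 >= 2^31) abort_validation("`seed` too large")

  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    p <- params
    p$seed <- as.integer(seed + r)
    sim <- simulate_screen(p)
    sp <- sim$spectrum
    m <- if (sp$n_loci > 0) sp$n_mutations / sp$n_loci else NA_real_
    plug_total <- if (sp$n_loci > 0) plug_in_saturation(sp)$total_loci else NA_real_
    degenerate <- is.na(m) || m <= 1
    ztp_total <- if (!degenerate) ztp_mle(sp)$total_loci else NA_real_
    covered <- NA
    if (n_boot > 0 && !degenerate && sp$n_loci >= 2) {
      ci <- suppressWarnings(
        tryCatch(bootstrap_interval(sp, "ztp_mle", level = level,
                                    n_boot = n_boot,
                                    seed = as.integer(seed + 500000 + r)),
                 mosaicsat_degenerate_error = function(e) NULL))
      if (!is.null(ci)) {
        covered <- ci$total_loci[1] <= params$n_pathway_genes &&
          params$n_pathway_genes <= ci$total_loci[2]
      }
    }
    rows[[r]] <- data.frame(
      rep = r, n_retained = sp$n_mutations, n_loci = sp$n_loci,
      mean_alleles = m, plug_in_total = plug_total, ztp_total = ztp_total,
      degenerate = degenerate, ztp_ci_covers_truth = covered
    )
  }
  reps <- do.call(rbind, rows)

  n_degenerate <- sum(reps$degenerate)
  if (n_degenerate > 0) {
    warn_mosaicsat(sprintf(
      "%d of %d replicates had degenerate spectra (mean <= 1); excluded from ztp summaries",
      n_degenerate, n_reps))
  }
  summarize <- function(x) {
    x <- x[!is.na(x)]
    list(mean = mean(x), sd = stats::sd(x),
         bias = mean(x) - params$n_pathway_genes,
         relative_bias = mean(x) / params$n_pathway_genes - 1,
         n = length(x))
  }
  cov <- reps$ztp_ci_covers_truth
  structure(
    list(
      replicates = reps,
      summary = list(
        true_loci = params$n_pathway_genes,
        plug_in = summarize(reps$plug_in_total),
        ztp_mle = summarize(reps$ztp_total),
        n_degenerate = n_degenerate,
        coverage = if (n_boot > 0) mean(cov, na.rm = TRUE) else NULL,
        n_boot = as.integer(n_boot),
        level = level,
        seed = as.integer(seed),
        n_reps = as.integer(n_reps)
      )
    ),
    class = "estimator_validation"
  )
}

#' @export
print.estimator_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Estimator validation: %d replicates, true detectable loci = %d\n",
              s$n_reps, s$true_loci))
  cat(sprintf("  plug_in total loci: mean %.2f (sd %.2f), relative bias %+.1f%%\n",
              s$plug_in$mean, s$plug_in$sd, 100 * s$plug_in$relative_bias))
  cat(sprintf("  ztp_mle total loci: mean %.2f (sd %.2f), relative bias %+.1f%% (n = %d)\n",
              s$ztp_mle$mean, s$ztp_mle$sd, 100 * s$ztp_mle$relative_bias,
              s$ztp_mle$n))
  if (s$n_degenerate > 0) {
    cat(sprintf("  degenerate replicates excluded from ztp: %d\n", s$n_degenerate))
  }
  if (!is.null(s$coverage)) {
    cat(sprintf("  ztp bootstrap %g%% interval coverage of truth: %.2f (n_boot = %d)\n",
                100 * s$level, s$coverage, s$n_boot))
  }
  invisible(x)
}
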