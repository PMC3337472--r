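# Shared generators and independent oracles for the test suite.

# Draw a random allele spectrum whose counts are zero-truncated Poisson(lambda),
# by rejection from the untruncated distribution.
random_spectrum <- function(n_loci, lambda) {
  counts <- integer()
  while (length(counts) < n_loci) {
    x <- rpois(2L * n_loci + 10L, lambda)
    counts <- c(counts, x[x >= 1L])
  }
  allele_spectrum(counts[seq_len(n_loci)])
}

# Random complete pairwise complementation matrix over n mutations.
random_comp_matrix <- function(n, p_fail = 0.3, p_partial = 0,
                               ids = sprintf("m%02d", seq_len(n))) {
  cmb <- combn(ids, 2L)
  r <- runif(ncol(cmb))
  result <- ifelse(r < p_fail, "fails",
                   ifelse(r < p_fail + p_partial, "partial", "complements"))
  complementation_matrix(
    data.frame(mutation_a = cmb[1L, ], mutation_b = cmb[2L, ],
               result = result, stringsAsFactors = FALSE),
    mutation_ids = ids)
}

# Brute-force partition oracle: repeated pairwise merging over fails edges,
# independent of the graph library used by build_groups.
brute_partition <- function(ids, fail_a, fail_b) {
  group <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(fail_a)) {
      ga <- group[fail_a[i]]; gb <- group[fail_b[i]]
      if (ga != gb) {
        group[group == gb] <- ga
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  canonical_groups(split(ids, group[ids]))
}

# Canonical form of a partition: sorted members, groups ordered by first member.
canonical_groups <- function(groups) {
  g <- lapply(groups, sort)
  g <- unname(g[order(vapply(g, `[`, character(1), 1L))])
  g
}

# Independent ZTP maximum-likelihood oracle: dense two-stage grid maximizer of
# the zero-truncated Poisson log-likelihood
#   sum_i [ k_i log(lambda) ] - n lambda - n log(1 - exp(-lambda))
# (the log k_i! terms do not involve lambda).
grid_ztp_mle <- function(spectrum) {
  k <- spectrum$n_alleles
  n <- length(k)
  loglik <- function(l) sum(k) * log(l) - n * l - n * log(-expm1(-l))
  m <- mean(k)
  coarse <- seq(1e-3, 3 * m, length.out = 4000L)
  l0 <- coarse[which.max(vapply(coarse, loglik, numeric(1)))]
  step <- coarse[2L] - coarse[1L]
  fine <- seq(max(1e-6, l0 - 2 * step), l0 + 2 * step, length.out = 4001L)
  fine[which.max(vapply(fine, loglik, numeric(1)))]
}

# Pairwise co-membership agreement between two partitions of the same ids
# (1 = identical grouping).
partition_agreement <- function(p1, p2) {
  ids <- sort(unique(unlist(p1)))
  stopifnot(identical(ids, sort(unique(unlist(p2)))))
  memb <- function(p) {
    m <- character()
    for (i in seq_along(p)) m[p[[i]]] <- as.character(i)
    m[ids]
  }
  m1 <- memb(p1); m2 <- memb(p2)
  if (length(ids) < 2L) return(1)
  cmb <- combn(seq_along(ids), 2L)
  same1 <- m1[cmb[1L, ]] == m1[cmb[2L, ]]
  same2 <- m2[cmb[1L, ]] == m2[cmb[2L, ]]
  mean(same1 == same2)
}
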