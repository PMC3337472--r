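pairs_df <- function(a, b, result, channel = NULL) {
  d <- data.frame(mutation_a = a, mutation_b = b, result = result,
                  stringsAsFactors = FALSE)
  if (!is.null(channel)) d$channel <- channel
  d
}

test_that("matrix construction validates results, symmetry and the diagonal", {
  expect_error(complementation_matrix(pairs_df("A", "B", "maybe")),
               class = "mosaicsat_validation_error")
  expect_error(complementation_matrix(pairs_df("A", "A", "fails")),
               class = "mosaicsat_validation_error")
  # contradictory orientations name the offending pair
  expect_error(
    complementation_matrix(pairs_df(c("A", "B"), c("B", "A"),
                                    c("fails", "complements"))),
    "A--B")
  # consistent duplicate orientations collapse to one entry
  m <- complementation_matrix(pairs_df(c("A", "B"), c("B", "A"),
                                       c("fails", "fails")))
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(comp_result(m, "B", "A"), "fails")
  expect_equal(comp_result(m, "A", "A"), "fails")
  expect_equal(comp_result(m, "A", "Z"), "untested")
})

test_that("testing completeness reports the tested fraction of pairs", {
  m <- complementation_matrix(pairs_df("A", "B", "fails"),
                              mutation_ids = c("A", "B", "C", "D"))
  expect_equal(testing_completeness(m), 1 / 6)
  full <- random_comp_matrix(5)
  expect_equal(testing_completeness(full), 1)
})

test_that("groups are connected components of the failure graph", {
  ids <- c("A", "B", "C", "D", "E")
  m <- complementation_matrix(pairs_df(c("A", "B", "D"), c("B", "C", "E"),
                                       rep("fails", 3)), mutation_ids = ids)
  p <- build_groups(m)
  expect_equal(canonical_groups(p$groups),
               list(c("A", "B", "C"), c("D", "E")))
  expect_equal(unname(p$membership[c("A", "C", "E")]), c("A", "A", "D"))

  # all complements: every mutation its own group
  all_comp <- random_comp_matrix(6, p_fail = 0)
  expect_equal(length(build_groups(all_comp)$groups), 6L)
})

test_that("build_groups matches a brute-force merging oracle on random matrices", {
  set.seed(31)
  for (i in 1:10) {
    m <- random_comp_matrix(8, p_fail = runif(1, 0.1, 0.5))
    fails <- m$pairs[m$pairs$result == "fails", ]
    expect_equal(canonical_groups(build_groups(m)$groups),
                 brute_partition(m$mutation_ids,
                                 fails$mutation_a, fails$mutation_b))
  }
})

test_that("build_groups is idempotent and invariant under input ordering", {
  set.seed(57)
  m <- random_comp_matrix(9, p_fail = 0.3)
  p1 <- build_groups(m)
  # shuffle rows and swap orientations
  sh <- m$pairs[sample(nrow(m$pairs)), ]
  swap <- seq_len(nrow(sh)) %% 2 == 0
  tmp <- sh$mutation_a[swap]
  sh$mutation_a[swap] <- sh$mutation_b[swap]
  sh$mutation_b[swap] <- tmp
  m2 <- complementation_matrix(sh, mutation_ids = sample(m$mutation_ids))
  p2 <- build_groups(m2)
  expect_identical(p1$groups, p2$groups)
  expect_identical(p1$membership[sort(names(p1$membership))],
                   p2$membership[sort(names(p2$membership))])
})

test_that("partial policies: as_fail coarsens, as_complement never merges partial pairs", {
  set.seed(91)
  for (i in 1:8) {
    m <- random_comp_matrix(8, p_fail = 0.2, p_partial = 0.15)
    pc <- build_groups(m, "as_complement")
    pf <- build_groups(m, "as_fail")
    # refinement: ids grouped together under as_complement stay together under as_fail
    for (g in pc$groups) {
      expect_equal(length(unique(pf$membership[g])), 1L)
    }
    # flag_only groups like as_complement but raises flags on partial pairs
    po <- build_groups(m, "flag_only")
    expect_identical(po$groups, pc$groups)
    n_partial <- sum(m$pairs$result == "partial")
    expect_equal(nrow(po$flags), 2L * n_partial)
    if (n_partial > 0) {
      expect_true(all(po$flags$flag_type == "hypomorph_candidate"))
    }
  }
})

test_that("intransitive triangles match exhaustive enumeration", {
  # minimal triangle
  m <- complementation_matrix(pairs_df(c("A", "B", "A"), c("B", "C", "C"),
                                       c("fails", "fails", "complements")))
  tri <- find_intransitive_triangles(m)
  expect_equal(nrow(tri), 1L)
  expect_equal(unlist(tri[1, ], use.names = FALSE), c("A", "B", "C"))

  # transitive matrix: none
  m2 <- complementation_matrix(pairs_df(c("A", "B", "A"), c("B", "C", "C"),
                                        rep("fails", 3)))
  expect_equal(nrow(find_intransitive_triangles(m2)), 0L)

  # random matrices vs brute force over all C(8,3) triples
  set.seed(12)
  for (i in 1:6) {
    m3 <- random_comp_matrix(8, p_fail = 0.4)
    found <- find_intransitive_triangles(m3)
    expected <- 0L
    ids <- m3$mutation_ids
    for (trio in utils::combn(ids, 3L, simplify = FALSE)) {
      for (b in trio) {
        ac <- setdiff(trio, b)
        if (comp_result(m3, ac[1], b) == "fails" &&
            comp_result(m3, ac[2], b) == "fails" &&
            comp_result(m3, ac[1], ac[2]) == "complements") {
          expected <- expected + 1L
        }
      }
    }
    expect_equal(nrow(found), expected)
  }
})

test_that("the isoform-hypomorph pattern is flagged from the packaged fixture", {
  m <- read_matrix(mosaicsat_example("ago1_synthetic_complementation.tsv"),
                   mosaicsat_example("ago1_synthetic_deficiencies.tsv"))
  p <- build_groups(m)
  expect_equal(length(p$groups), 2L)  # eight point alleles + the P insertion
  expect_true("l(2)k08121" %in% names(p$membership))
  p <- flag_hypomorph_candidates(m, p)
  hypo <- p$flags[p$flags$flag_type == "hypomorph_candidate", ]
  expect_true("l(2)k08121" %in% hypo$mutation)
  # the point alleles themselves are not flagged
  expect_false(any(grepl("^Ago1-", hypo$mutation)))
  expect_equal(nrow(p$flags[p$flags$flag_type == "conflict_with_deficiency", ]), 0L)
})

test_that("clean matrices raise no hypomorph flags", {
  # transitive single-gene matrix
  ids <- c("a1", "a2", "a3", "a4")
  cmb <- utils::combn(ids, 2)
  m <- complementation_matrix(pairs_df(cmb[1, ], cmb[2, ], "fails"))
  p <- flag_hypomorph_candidates(m, build_groups(m))
  expect_equal(nrow(p$flags), 0L)

  # two independent genes, no cross-failures
  ids2 <- c("a1", "a2", "b1", "b2")
  cmb2 <- utils::combn(ids2, 2)
  same <- substr(cmb2[1, ], 1, 1) == substr(cmb2[2, ], 1, 1)
  m2 <- complementation_matrix(pairs_df(cmb2[1, ], cmb2[2, ],
                                        ifelse(same, "fails", "complements")))
  p2 <- flag_hypomorph_candidates(m2, build_groups(m2))
  expect_equal(nrow(p2$flags), 0L)
})

test_that("intra-group intransitive triangles flag the complementing endpoints", {
  # one locus a1-a2-a3 where a1/a3 unexpectedly complement
  m <- complementation_matrix(pairs_df(c("a1", "a2", "a1"),
                                       c("a2", "a3", "a3"),
                                       c("fails", "fails", "complements")))
  p <- flag_hypomorph_candidates(m, build_groups(m))
  flagged <- sort(unique(p$flags$mutation[p$flags$flag_type == "hypomorph_candidate"]))
  expect_true(all(c("a1", "a3") %in% flagged))
})
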