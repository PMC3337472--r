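# Complementation-group inference from pairwise test matrices.
#
# A complementation "matrix" is stored sparsely as canonicalized unordered
# pairs; pairs never listed are `untested`. Locus groups are the connected
# components of the failure graph.

COMP_RESULTS <- c("complements", "fails", "partial", "untested")

canonical_pairs <- function(a, b) {
  data.frame(mutation_a = pmin(a, b), mutation_b = pmax(a, b),
             stringsAsFactors = FALSE)
}

#' Construct a pairwise complementation-test matrix
#'
#' Holds the outcomes of pairwise complementation crosses between mutant
#' lines. Each unordered pair carries one of four results: `complements`,
#' `fails` (noncomplementation: the trans-heterozygote shows the mutant
#' phenotype), `partial`, or `untested`. Noncomplementation may be scored on
#' any phenotype channel (e.g. lethality or reporter derepression); the
#' channel is retained per pair but results are already the OR over channels.
#' The diagonal (a mutation against itself) is `fails` by definition.
#'
#' @param pairs Data frame with columns `mutation_a`, `mutation_b`, `result`
#'   and optionally `channel`. Pairs listed in both orientations must agree;
#'   a contradiction is a validation error naming the pair. Unlisted pairs
#'   are `untested`.
#' @param mutation_ids Optional character vector of all mutation labels
#'   (to include mutations with no tested pair); the union with labels seen
#'   in `pairs` is used.
#' @param deficiency_tests Optional data frame of per-mutation tests against
#'   chromosomal deficiencies: columns `mutation`, `deficiency_id`, `result`.
#' @return An object of class `complementation_matrix`.
#' @seealso [build_groups()], [find_intransitive_triangles()],
#'   [flag_hypomorph_candidates()]
#' @export
complementation_matrix <- function(pairs, mutation_ids = NULL,
                                   deficiency_tests = NULL) {
  if (!is.data.frame(pairs)) abort_validation("`pairs` must be a data frame")
  needed <- c("mutation_a", "mutation_b", "result")
  missing_cols <- setdiff(needed, names(pairs))
  if (length(missing_cols)) {
    abort_validation(sprintf("`pairs` is missing column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  pairs$mutation_a <- as.character(pairs$mutation_a)
  pairs$mutation_b <- as.character(pairs$mutation_b)
  pairs$result <- as.character(pairs$result)
  bad <- !(pairs$result %in% COMP_RESULTS)
  if (any(bad)) {
    abort_validation(sprintf(
      "invalid result '%s' for pair %s--%s (allowed: %s)",
      pairs$result[bad][1L], pairs$mutation_a[bad][1L],
      pairs$mutation_b[bad][1L], paste(COMP_RESULTS, collapse = ", ")))
  }
  self <- pairs$mutation_a == pairs$mutation_b
  if (any(self)) {
    abort_validation(sprintf(
      "self-pair %s--%s listed: the diagonal is `fails` by definition and must not be supplied",
      pairs$mutation_a[self][1L], pairs$mutation_b[self][1L]))
  }
  canon <- canonical_pairs(pairs$mutation_a, pairs$mutation_b)
  key <- paste(canon$mutation_a, canon$mutation_b, sep = "\r")
  # symmetry: duplicated unordered pairs must carry one result
  for (k in unique(key[duplicated(key)])) {
    res <- unique(pairs$result[key == k])
    if (length(res) > 1L) {
      ab <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      abort_validation(sprintf(
        "asymmetric results for pair %s--%s: %s",
        ab[1L], ab[2L], paste(res, collapse = " vs ")))
    }
  }
  keep <- !duplicated(key)
  tab <- data.frame(
    mutation_a = canon$mutation_a[keep],
    mutation_b = canon$mutation_b[keep],
    result = pairs$result[keep],
    channel = if ("channel" %in% names(pairs)) as.character(pairs$channel)[keep]
              else NA_character_,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$mutation_a, tab$mutation_b), , drop = FALSE]
  rownames(tab) <- NULL

  ids <- sort(unique(c(mutation_ids, tab$mutation_a, tab$mutation_b)))

  if (!is.null(deficiency_tests)) {
    if (!is.data.frame(deficiency_tests) ||
        !all(c("mutation", "deficiency_id", "result") %in% names(deficiency_tests))) {
      abort_validation("`deficiency_tests` needs columns mutation, deficiency_id, result")
    }
    deficiency_tests <- data.frame(
      mutation = as.character(deficiency_tests$mutation),
      deficiency_id = as.character(deficiency_tests$deficiency_id),
      result = as.character(deficiency_tests$result),
      stringsAsFactors = FALSE
    )
    badd <- !(deficiency_tests$result %in% COMP_RESULTS)
    if (any(badd)) {
      abort_validation(sprintf("invalid deficiency-test result '%s' for %s",
                               deficiency_tests$result[badd][1L],
                               deficiency_tests$mutation[badd][1L]))
    }
    ids <- sort(unique(c(ids, deficiency_tests$mutation)))
  }

  structure(
    list(mutation_ids = ids, pairs = tab, deficiency_tests = deficiency_tests),
    class = "complementation_matrix"
  )
}

#' @export
print.complementation_matrix <- function(x, ...) {
  n <- length(x$mutation_ids)
  cat(sprintf("Complementation matrix: %d mutations, %d recorded pairs (completeness %.1f%%)\n",
              n, nrow(x$pairs), 100 * testing_completeness(x)))
  if (!is.null(x$deficiency_tests)) {
    cat(sprintf("  deficiency tests: %d against %d deficiencies\n",
                nrow(x$deficiency_tests),
                length(unique(x$deficiency_tests$deficiency_id))))
  }
  invisible(x)
}

# Fast lookup table of pair results, keyed "a\rb" with a < b.
pair_lookup <- function(matrix) {
  stats::setNames(matrix$pairs$result,
                  paste(matrix$pairs$mutation_a, matrix$pairs$mutation_b, sep = "\r"))
}

#' Look up the result of a pairwise complementation test
#'
#' @param matrix A [complementation_matrix()].
#' @param a,b Mutation labels. Order does not matter; `a == b` returns
#'   `"fails"` (a mutation trivially fails to complement itself).
#' @return One of `"complements"`, `"fails"`, `"partial"`, `"untested"`.
#' @export
comp_result <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "complementation_matrix"))
  if (a == b) return("fails")
  lut <- pair_lookup(matrix)
  r <- lut[paste(min(a, b), max(a, b), sep = "\r")]
  if (is.na(r)) "untested" else unname(r)
}

#' Fraction of mutation pairs actually tested
#'
#' With n mutations there are choose(n, 2) possible pairwise crosses; sparse
#' matrices split groups that fuller testing might merge, so completeness is
#' reported rather than assumed.
#'
#' @param matrix A [complementation_matrix()].
#' @return Proportion of unordered pairs with a non-`untested` result.
#' @export
testing_completeness <- function(matrix) {
  stopifnot(inherits(matrix, "complementation_matrix"))
  n <- length(matrix$mutation_ids)
  if (n < 2) return(1)
  sum(matrix$pairs$result != "untested") / choose(n, 2)
}

new_locus_partition <- function(groups, membership, flags, completeness,
                                partial_policy) {
  structure(
    list(groups = groups, membership = membership, flags = flags,
         testing_completeness = completeness, partial_policy = partial_policy),
    class = "locus_partition"
  )
}

empty_flags <- function() {
  data.frame(mutation = character(), group = character(),
             flag_type = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

#' Partition mutations into complementation groups (loci)
#'
#' Groups are the connected components of the graph whose vertices are the
#' mutations and whose edges are the noncomplementing (`fails`) pairs.
#' Mutations in the same component are classified as alleles of one locus.
#' The output is deterministic and invariant under input ordering: members
#' are sorted within each group, each group is labelled by its smallest
#' member, and groups are listed by label.
#'
#' How `partial` results are treated is governed by `partial_policy`:
#' \describe{
#'   \item{`flag_only` (default)}{the pair does not merge groups, but both
#'     members are flagged as hypomorph candidates. Partial complementation
#'     between alleles of one gene is the signature of an isoform-restricted
#'     hypomorph, and silently merging (or ignoring) it would hide exactly
#'     that signal.}
#'   \item{`as_complement`}{treated as `complements` (no edge, no flag).}
#'   \item{`as_fail`}{treated as `fails` (edge; merges groups).}
#' }
#'
#' @param matrix A [complementation_matrix()].
#' @param partial_policy One of `"flag_only"`, `"as_complement"`, `"as_fail"`.
#' @return A `locus_partition`: `groups` (named list of sorted member
#'   vectors), `membership` (named vector mapping mutation to group label),
#'   `flags` (data frame `mutation`, `group`, `flag_type`, `evidence`), and
#'   `testing_completeness`.
#' @examples
#' m <- complementation_matrix(data.frame(
#'   mutation_a = c("A", "B", "D"), mutation_b = c("B", "C", "E"),
#'   result = "fails"), mutation_ids = c("A", "B", "C", "D", "E"))
#' build_groups(m)$groups  # {A,B,C} and {D,E}
#' @export
build_groups <- function(matrix,
                         partial_policy = c("flag_only", "as_complement", "as_fail")) {
  stopifnot(inherits(matrix, "complementation_matrix"))
  partial_policy <- match.arg(partial_policy)
  ids <- matrix$mutation_ids
  edge_results <- "fails"
  if (partial_policy == "as_fail") edge_results <- c("fails", "partial")
  edges <- matrix$pairs[matrix$pairs$result %in% edge_results,
                        c("mutation_a", "mutation_b"), drop = FALSE]

  if (length(ids) == 0L) {
    return(new_locus_partition(list(), stats::setNames(character(), character()),
                               empty_flags(), 1, partial_policy))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  member_of <- comp$membership[ids]
  groups <- split(ids, member_of)
  groups <- lapply(groups, function(v) sort(unname(v)))
  labels <- vapply(groups, `[`, character(1), 1L)
  ord <- order(labels)
  groups <- stats::setNames(groups[ord], labels[ord])
  membership <- stats::setNames(rep(names(groups), lengths(groups)),
                                unlist(groups, use.names = FALSE))
  membership <- membership[ids]

  flags <- empty_flags()
  if (partial_policy == "flag_only") {
    part <- matrix$pairs[matrix$pairs$result == "partial", , drop = FALSE]
    if (nrow(part)) {
      flags <- data.frame(
        mutation = c(part$mutation_a, part$mutation_b),
        group = unname(membership[c(part$mutation_a, part$mutation_b)]),
        flag_type = "hypomorph_candidate",
        evidence = rep(sprintf("partial complementation in pair %s--%s",
                               part$mutation_a, part$mutation_b), 2L),
        stringsAsFactors = FALSE
      )
      flags <- flags[order(flags$mutation, flags$group), , drop = FALSE]
      rownames(flags) <- NULL
    }
  }

  new_locus_partition(groups, membership, flags,
                      testing_completeness(matrix), partial_policy)
}

#' @export
print.locus_partition <- function(x, ...) {
  cat(sprintf("Locus partition: %d mutations in %d groups (testing completeness %.1f%%, partial policy '%s')\n",
              length(x$membership), length(x$groups),
              100 * x$testing_completeness, x$partial_policy))
  for (lab in names(x$groups)) {
    cat(sprintf("  %s: %s\n", lab, paste(x$groups[[lab]], collapse = ", ")))
  }
  if (nrow(x$flags)) {
    cat(sprintf("  %d flag(s):\n", nrow(x$flags)))
    for (i in seq_len(nrow(x$flags))) {
      cat(sprintf("    %s [%s, group %s]: %s\n", x$flags$mutation[i],
                  x$flags$flag_type[i], x$flags$group[i], x$flags$evidence[i]))
    }
  }
  invisible(x)
}

#' Find intransitive ("complex") complementation triangles
#'
#' Noncomplementation between alleles of one gene should be transitive. A
#' triple where a--b and b--c fail but a and c complement is the classic
#' signature of complex complementation, typically caused by an
#' isoform-restricted hypomorph among the alleles.
#'
#' @param matrix A [complementation_matrix()].
#' @return A data frame with columns `a`, `b`, `c`: `b` fails both `a` and
#'   `c`, while `a` and `c` complement. Each triangle appears once with
#'   `a < c`; rows are sorted. Zero rows when the matrix is transitive.
#' @export
find_intransitive_triangles <- function(matrix) {
  stopifnot(inherits(matrix, "complementation_matrix"))
  lut <- pair_lookup(matrix)
  res <- function(a, b) {
    r <- lut[paste(pmin(a, b), pmax(a, b), sep = "\r")]
    ifelse(is.na(r), "untested", r)
  }
  out <- list()
  fails <- matrix$pairs[matrix$pairs$result == "fails", , drop = FALSE]
  for (b in matrix$mutation_ids) {
    nb <- sort(unique(c(fails$mutation_b[fails$mutation_a == b],
                        fails$mutation_a[fails$mutation_b == b])))
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2L)
    ok <- res(cmb[1L, ], cmb[2L, ]) == "complements"
    if (any(ok)) {
      out[[b]] <- data.frame(a = cmb[1L, ok], b = b, c = cmb[2L, ok],
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(), b = character(), c = character(),
                      stringsAsFactors = FALSE))
  }
  tri <- do.call(rbind, out)
  tri <- tri[order(tri$a, tri$b, tri$c), , drop = FALSE]
  rownames(tri) <- NULL
  tri
}

#' Flag hypomorph-candidate alleles in a locus partition
#'
#' Marks mutations whose complementation behaviour matches an
#' isoform-restricted (hypomorphic) allele of a locus:
#' \itemize{
#'   \item it fails (or partially fails) a deficiency anchored to a group, or
#'     fails/partially fails some member of that group, while complementing at
#'     least one other member of the group — the pattern of a P-element
#'     insertion disrupting only a subset of a gene's transcript isoforms; or
#'   \item it is one of the complementing endpoints of an intransitive
#'     triangle lying wholly inside one putative locus.
#' }
#' A deficiency is anchored to a group when at least one group member fails
#' it outright. Group members that outright complement such a deficiency are
#' additionally flagged `conflict_with_deficiency`.
#'
#' @param matrix A [complementation_matrix()] (with `deficiency_tests` if
#'   deficiency evidence is to be used).
#' @param partition The [build_groups()] partition of the same matrix.
#' @return The partition with its `flags` data frame extended; existing flags
#'   are kept and duplicates removed.
#' @export
flag_hypomorph_candidates <- function(matrix, partition) {
  stopifnot(inherits(matrix, "complementation_matrix"),
            inherits(partition, "locus_partition"))
  lut <- pair_lookup(matrix)
  res1 <- function(a, b) {
    if (a == b) return("fails")
    r <- lut[paste(min(a, b), max(a, b), sep = "\r")]
    if (is.na(r)) "untested" else unname(r)
  }
  def <- matrix$deficiency_tests
  flags <- partition$flags

  add_flag <- function(mutation, group, type, evidence) {
    flags <<- rbind(flags, data.frame(
      mutation = mutation, group = group, flag_type = type,
      evidence = evidence, stringsAsFactors = FALSE))
  }

  for (lab in names(partition$groups)) {
    members <- partition$groups[[lab]]
    defs_g <- character()
    if (!is.null(def)) {
      anchored <- def$deficiency_id[def$mutation %in% members &
                                    def$result == "fails"]
      defs_g <- sort(unique(anchored))
      # members that outright complement an anchored deficiency
      conf <- def[def$mutation %in% members &
                  def$deficiency_id %in% defs_g &
                  def$result == "complements", , drop = FALSE]
      for (i in seq_len(nrow(conf))) {
        add_flag(conf$mutation[i], lab, "conflict_with_deficiency",
                 sprintf("complements deficiency %s that other members of %s fail",
                         conf$deficiency_id[i], lab))
      }
    }
    for (m in matrix$mutation_ids) {
      others <- setdiff(members, m)
      if (!length(others)) next
      comp_with <- others[vapply(others, function(o) res1(m, o), "") == "complements"]
      if (!length(comp_with)) next
      fail_members <- others[vapply(others, function(o) res1(m, o), "") %in%
                               c("fails", "partial")]
      fail_defs <- character()
      if (!is.null(def) && length(defs_g)) {
        fail_defs <- def$deficiency_id[def$mutation == m &
                                       def$deficiency_id %in% defs_g &
                                       def$result %in% c("fails", "partial")]
      }
      if (length(fail_members) || length(fail_defs)) {
        ev <- c(
          if (length(fail_defs))
            sprintf("fails/partially fails deficiency %s of group %s",
                    paste(fail_defs, collapse = ","), lab),
          if (length(fail_members))
            sprintf("fails/partially fails member(s) %s",
                    paste(fail_members, collapse = ",")),
          sprintf("yet complements member(s) %s",
                  paste(comp_with, collapse = ","))
        )
        add_flag(m, lab, "hypomorph_candidate", paste(ev, collapse = "; "))
      }
    }
  }

  tri <- find_intransitive_triangles(matrix)
  if (nrow(tri)) {
    memb <- partition$membership
    for (i in seq_len(nrow(tri))) {
      ga <- memb[tri$a[i]]; gb <- memb[tri$b[i]]; gc <- memb[tri$c[i]]
      if (!is.na(ga) && ga == gb && gb == gc) {
        ev <- sprintf("intransitive triangle %s--%s--%s within group %s",
                      tri$a[i], tri$b[i], tri$c[i], ga)
        # the complementing endpoints carry the anomaly, not the shared failer
        add_flag(tri$a[i], unname(ga), "hypomorph_candidate", ev)
        add_flag(tri$c[i], unname(ga), "hypomorph_candidate", ev)
      }
    }
  }

  flags <- flags[!duplicated(flags[c("mutation", "group", "flag_type", "evidence")]), ,
                 drop = FALSE]
  flags <- flags[order(flags$mutation, flags$group, flags$flag_type), , drop = FALSE]
  rownames(flags) <- NULL
  partition$flags <- flags
  partition
}
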