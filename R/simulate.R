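# Clonal-evolution simulator: planted clone trees and the binary matrices
# they imply, with optional bit-flip noise and two-subclone sample mixing.

#' Sample a uniform random rooted binary tree topology
#'
#' Leaves are labeled `s1..sn`. The tree is grown by sequential insertion:
#' each new leaf is attached to an edge chosen uniformly at random (including
#' the root edge), which yields the uniform distribution over the
#' (2n-3)!! labeled rooted binary topologies.
#'
#' @param n Number of leaves (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @return A `pti_tree` with empty branches (no mutations, length NA).
#' @export
sample_topology <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L) stop("need n >= 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  blank <- function(label = NULL, children = list())
    new_node(label = label, children = children, length = NA_real_)
  tree <- blank(label = "s1")
  count_nodes <- function(node)
    1L + sum(vapply(node$children, count_nodes, integer(1)))
  insert_at <- function(node, k, leaf) {
    # replace the k-th node in preorder with a new parent of (node, leaf)
    if (k == 1L) return(list(node = blank(children = list(node, leaf)), used = NA))
    k <- k - 1L
    for (i in seq_along(node$children)) {
      sz <- count_nodes(node$children[[i]])
      if (k <= sz) {
        node$children[[i]] <- insert_at(node$children[[i]], k, leaf)$node
        return(list(node = node, used = NA))
      }
      k <- k - sz
    }
    stop("internal error: preorder index out of range")
  }
  for (i in seq_len(n)[-1L]) {
    k <- sample.int(count_nodes(tree), 1L)
    tree <- insert_at(tree, k, blank(label = paste0("s", i)))$node
  }
  class(tree) <- c("pti_tree", "pti_node")
  tree
}

#' Define a simulation scenario
#'
#' Bundles a planted clone tree with the generation parameters for the
#' binary matrix it implies. Every branch of the planted tree (including the
#' root trunk and the leaf branches) receives `1 + Poisson(branch_rate - 1)`
#' mutations, so no branch is ever empty and noise-free scenarios are exact
#' perfect phylogenies. Optional bit-flip noise models missed calls
#' (`fn_rate`, 1 -> 0) and spurious calls (`fp_rate`, 0 -> 1). An optional
#' mixed sample emulates a biopsy containing two subclones: the designated
#' sample gains each mutation founding a second clade with probability
#' `fraction` and retains each mutation specific to its own lineage with
#' probability `1 - fraction`.
#'
#' @param n_samples Number of biopsies (>= 2).
#' @param branch_rate Mean mutations per branch (>= 1).
#' @param fn_rate,fp_rate Bit-flip probabilities in \[0, 1).
#' @param mixed_sample Optional list `(sample, clade, fraction)`: the sample
#'   id to mix, the sample ids of the second clade (disjoint from `sample`),
#'   and the mixing fraction in \[0, 1\].
#' @param seed Integer seed governing all draws.
#' @param tree Optional planted `pti_tree`; by default a uniform random
#'   topology drawn with `seed`.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(n_samples, branch_rate = 10, fn_rate = 0, fp_rate = 0,
                         mixed_sample = NULL, seed = 1L, tree = NULL) {
  stopifnot(n_samples >= 2L, branch_rate >= 1,
            fn_rate >= 0, fn_rate < 1, fp_rate >= 0, fp_rate < 1)
  seed <- as.integer(seed)
  if (is.null(tree)) tree <- sample_topology(n_samples, seed = seed)
  leaves <- tree_leaves(tree)
  if (length(leaves) != n_samples) stop("tree has wrong number of leaves")
  if (!is.null(mixed_sample)) {
    stopifnot(is.list(mixed_sample),
              all(c("sample", "clade", "fraction") %in% names(mixed_sample)))
    stopifnot(mixed_sample$sample %in% leaves,
              all(mixed_sample$clade %in% leaves),
              !(mixed_sample$sample %in% mixed_sample$clade),
              mixed_sample$fraction >= 0, mixed_sample$fraction <= 1)
  }
  structure(list(n_samples = as.integer(n_samples), planted_tree = tree,
                 branch_rate = branch_rate, fn_rate = fn_rate,
                 fp_rate = fp_rate, mixed_sample = mixed_sample, seed = seed),
            class = "sim_scenario")
}

#' Realize the binary mutation matrix of a scenario
#'
#' Draws per-branch mutation counts, places each mutation in exactly the
#' leaves below its branch, applies subclone mixing and bit-flip noise, and
#' returns the resulting matrix. With `fn_rate = fp_rate = 0` and no mixing
#' the matrix is a perfect phylogeny of the planted tree.
#'
#' @param scenario A [sim_scenario()].
#' @return A [mutation_matrix()] with attributes `planted_tree`,
#'   `branch_counts` (named by clade), `total_rows` (before all-zero drops),
#'   and `scenario`.
#' @export
realize_matrix <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed((scenario$seed %% 2000000000L) + 1L)
  tree <- scenario$planted_tree
  leaves <- tree_leaves(tree)
  clades <- list()
  walk <- function(node) {
    clades[[length(clades) + 1L]] <<- tree_leaves(node)
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  counts <- 1L + stats::rpois(length(clades), scenario$branch_rate - 1)
  total <- sum(counts)
  M <- matrix(0L, total, length(leaves), dimnames = list(
    sprintf("M%04d", seq_len(total)), leaves))
  row0 <- 0L
  for (i in seq_along(clades)) {
    if (counts[i] > 0L)
      M[row0 + seq_len(counts[i]), clades[[i]]] <- 1L
    row0 <- row0 + counts[i]
  }
  names(counts) <- vapply(clades, function(cl) paste(sort(cl), collapse = ","),
                          character(1))

  mx <- scenario$mixed_sample
  if (!is.null(mx)) {
    s <- mx$sample; cl <- mx$clade; f <- mx$fraction
    in_clade <- rowSums(M[, cl, drop = FALSE]) == length(cl)
    foreign <- in_clade & M[, s] == 0L                     # clade-founding rows
    own <- M[, s] == 1L & rowSums(M[, cl, drop = FALSE]) == 0L  # own lineage
    M[foreign, s] <- stats::rbinom(sum(foreign), 1L, f)
    M[own, s] <- stats::rbinom(sum(own), 1L, 1 - f)
  }
  if (scenario$fn_rate > 0) {
    ones <- which(M == 1L)
    M[ones[stats::runif(length(ones)) < scenario$fn_rate]] <- 0L
  }
  if (scenario$fp_rate > 0) {
    zeros <- which(M == 0L)
    M[zeros[stats::runif(length(zeros)) < scenario$fp_rate]] <- 1L
  }
  out <- mutation_matrix(M)
  attr(out, "planted_tree") <- tree
  attr(out, "branch_counts") <- counts
  attr(out, "total_rows") <- total
  attr(out, "scenario") <- scenario
  out
}
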