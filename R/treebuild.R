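# Core top-down split search: shared-mutation counts theta, the split ratio,
# recursion to leaves, multifurcation collapse, and tree-weight tie-breaking.

#' Number of mutations shared by every sample in a group
#'
#' Plain intersection count: a mutation contributes when its entry is 1 in
#' every member of `group`, with no requirement of absence outside the group
#' (fully shared rows are removed beforehand as the root trunk).
#'
#' @param M A [mutation_matrix()] or coercible 0/1 matrix.
#' @param group Non-empty character vector of sample ids.
#' @return Integer count.
#' @export
shared_count <- function(M, group) {
  if (!is.matrix(M)) M <- mutation_matrix(M)
  if (length(group) == 0L) stop("group must be non-empty")
  unknown <- setdiff(group, colnames(M))
  if (length(unknown)) stop("unknown sample: ", paste(unknown, collapse = ", "))
  if (nrow(M) == 0L) return(0L)
  sum(rowSums(M[, group, drop = FALSE]) == length(group))
}

#' Candidate split sizes for n samples
#'
#' All two-way splits of n samples have shape (t, n - t); enumerating
#' t = 1..floor(n/2) covers each shape once.
#'
#' @param n Number of samples (>= 2).
#' @return Integer vector `1:floor(n/2)`.
#' @export
enumerate_split_sizes <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L) stop("need at least 2 samples")
  seq_len(n %/% 2L)
}

#' Split ratio from a vector of shared-mutation counts
#'
#' The ratio of the largest to the second-largest theta within one split
#' size. A split size whose best bipartition dominates all others
#' (second-best 0, best positive) gets ratio `Inf`; a split size with no
#' signal at all (best 0) gets ratio 0. A vector of length one is treated as
#' having second-best 0.
#'
#' @param theta Non-negative numeric vector of shared-mutation counts.
#' @return List with `theta_max`, `theta_sec_max`, `ratio`.
#' @export
split_ratio <- function(theta) {
  stopifnot(length(theta) >= 1L, all(theta >= 0))
  s <- sort(theta, decreasing = TRUE)
  tmax <- s[1L]
  tsec <- if (length(s) >= 2L) s[2L] else 0
  ratio <- if (tmax == 0) 0 else if (tsec == 0) Inf else tmax / tsec
  list(theta_max = tmax, theta_sec_max = tsec, ratio = ratio)
}

# Shared-mutation counts for many sample groups at once.
# groups: n x K 0/1 indicator matrix (columns = groups); returns K counts.
theta_groups <- function(M, groups) {
  if (nrow(M) == 0L) return(rep(0L, ncol(groups)))
  hits <- M %*% groups                      # m x K: per-row count inside group
  sizes <- colSums(groups)
  colSums(hits == rep(sizes, each = nrow(M)))
}

#' Evaluate all bipartitions of one split size
#'
#' For split size t < n/2, every size-t complement is enumerated and theta is
#' the shared-mutation count of the larger group (size n - t). For the
#' balanced case t = n/2 (n even) there is no larger group: unordered
#' bipartitions are enumerated once each and theta is the smaller of the two
#' halves' shared counts. The split ratio compares the best bipartition with
#' the second best; a large ratio marks the split size containing the true
#' branching.
#'
#' @param M A [mutation_matrix()] with >= 2 samples (trunk already removed).
#' @param t Split size, `1 <= t <= floor(n/2)`.
#' @return List of class `split_evaluation`: `t`, `candidates` (list of
#'   `group`/`complement`/`theta`), `theta`, `theta_max`, `theta_sec_max`,
#'   `ratio`.
#' @export
evaluate_split_size <- function(M, t) {
  M <- mutation_matrix_like(M)
  n <- ncol(M)
  if (n < 2L) stop("at least two samples are required")
  if (!is.numeric(t) || length(t) != 1L || t < 1L || t > n %/% 2L)
    stop("split size t must lie in 1..floor(n/2)")
  samples <- colnames(M)
  balanced <- (2L * t == n)
  if (!balanced) {
    comp <- utils::combn(n, t)
    K <- ncol(comp)
    ind <- matrix(1L, n, K)                # indicator of the larger group
    for (k in seq_len(K)) ind[comp[, k], k] <- 0L
    theta <- theta_groups(M, ind)
    candidates <- lapply(seq_len(K), function(k) {
      cmpl <- samples[comp[, k]]
      list(group = setdiff(samples, cmpl), complement = cmpl,
           theta = theta[k])
    })
  } else {
    # fix sample 1 in the first half so each unordered bipartition appears once
    rest <- utils::combn(n - 1L, t - 1L)
    K <- ncol(rest)
    indA <- matrix(0L, n, K); indB <- matrix(0L, n, K)
    for (k in seq_len(K)) {
      a <- c(1L, rest[, k] + 1L)
      indA[a, k] <- 1L; indB[-a, k] <- 1L
    }
    theta <- pmin(theta_groups(M, indA), theta_groups(M, indB))
    candidates <- lapply(seq_len(K), function(k) {
      a <- samples[indA[, k] == 1L]
      list(group = a, complement = setdiff(samples, a), theta = theta[k])
    })
  }
  r <- split_ratio(theta)
  structure(list(t = t, candidates = candidates, theta = theta,
                 theta_max = r$theta_max, theta_sec_max = r$theta_sec_max,
                 ratio = r$ratio),
            class = "split_evaluation")
}

# accept an already-validated plain matrix without re-running row drops
mutation_matrix_like <- function(M) {
  if (is.matrix(M)) M else mutation_matrix(M)
}

#' Find the optimal two-way split(s) of the sample set
#'
#' Evaluates every split size, keeps the size(s) attaining the maximal split
#' ratio, and within those returns every bipartition attaining the maximal
#' theta. More than one split is returned exactly when distinct bipartitions
#' tie on (ratio, theta); each spawns its own candidate tree downstream,
#' arbitrated later by [tree_weight()]. With two samples the unique
#' bipartition is returned without evaluation. If no bipartition at all
#' shares a mutation the split carries no signal: an empty list with
#' attribute `star = TRUE` is returned and the caller places all samples as
#' a multifurcation.
#'
#' @param M A [mutation_matrix()] or plain 0/1 matrix over the current node's
#'   samples, trunk/ancestor rows already removed. May have zero rows.
#' @return List of splits (`group`, `complement`, `theta`), with attributes
#'   `star` (logical) and `evaluations` (per split size).
#' @export
find_optimal_splits <- function(M) {
  M <- mutation_matrix_like(M)
  n <- ncol(M)
  samples <- colnames(M)
  if (n < 2L) stop("at least two samples are required")
  if (n > 25L)
    stop("node with ", n, " samples: bipartition enumeration is infeasible; ",
         "group related samples before inference")
  if (n == 2L) {
    out <- list(list(group = samples[1L], complement = samples[2L],
                     theta = if (nrow(M)) shared_count(M, samples[1L]) else 0L))
    attr(out, "star") <- FALSE
    return(out)
  }
  evals <- lapply(enumerate_split_sizes(n), function(t) evaluate_split_size(M, t))
  ratios <- vapply(evals, `[[`, numeric(1), "ratio")
  if (all(vapply(evals, `[[`, numeric(1), "theta_max") == 0)) {
    out <- list()
    attr(out, "star") <- TRUE
    attr(out, "evaluations") <- evals
    return(out)
  }
  best <- max(ratios)
  out <- list()
  for (ev in evals[ratios == best]) {
    for (cand in ev$candidates[ev$theta == ev$theta_max])
      out[[length(out) + 1L]] <- cand
  }
  attr(out, "star") <- FALSE
  attr(out, "evaluations") <- evals
  out
}

# ---- full inference ---------------------------------------------------------

#' Infer candidate phylogenetic trees from a binary mutation matrix
#'
#' Implements the iterative top-down reconstruction: the root trunk
#' (mutations shared by all samples) is removed first; at every internal
#' node the optimal two-way split of the remaining samples is found via the
#' split ratio and the recursion continues until all samples are leaves.
#' Tied optima spawn alternative candidate trees. After the topology search,
#' every mutation is assigned to the highest branch whose subtended samples
#' all carry it (mutations whose carrier pattern matches no single branch are
#' reported as unassigned), zero-length internal branches are collapsed into
#' multifurcations, and candidates are ranked by decreasing [tree_weight()].
#'
#' @param M A [mutation_matrix()] (or coercible 0/1 matrix) with >= 2 samples.
#' @param max_trees Cap on the number of candidate trees enumerated from
#'   cascading ties (default 100); exceeding it raises a warning.
#' @return A list of class `pti_fit` (also returned by [pti()]); see
#'   [pti()] for the fields.
#' @export
infer_trees <- function(M, max_trees = 100L) {
  M <- mutation_matrix(M)
  n <- ncol(M)
  if (n < 2L) stop("at least two samples are required")
  samples <- colnames(M)
  Mp <- unclass(M)  # plain integer matrix for fast indexing
  truncated <- FALSE

  recurse <- function(samps, avail) {
    if (length(avail)) {
      sub <- Mp[avail, samps, drop = FALSE]
      avail <- avail[rowSums(sub) > 0L]
    }
    shared <- if (length(avail))
      avail[rowSums(Mp[avail, samps, drop = FALSE]) == length(samps)]
    else character(0)
    if (length(samps) == 1L)
      return(list(new_node(label = samps, mutations = shared)))
    rest <- setdiff(avail, shared)
    splits <- find_optimal_splits(Mp[rest, samps, drop = FALSE])
    if (isTRUE(attr(splits, "star"))) {
      kids <- lapply(samps, function(s) recurse(s, rest)[[1L]])
      return(list(new_node(children = kids, mutations = shared)))
    }
    out <- list()
    for (sp in splits) {
      for (a in recurse(sp$group, rest)) {
        for (b in recurse(sp$complement, rest)) {
          if (length(out) >= max_trees) { truncated <<- TRUE; break }
          out[[length(out) + 1L]] <- new_node(children = list(a, b),
                                              mutations = shared)
        }
      }
    }
    out
  }

  candidates <- recurse(samples, rownames(M))
  if (truncated)
    warning("more than ", max_trees,
            " tied candidate trees; enumeration truncated")

  finished <- lapply(candidates, function(tr) {
    tr <- assign_mutations(tr, Mp)
    un <- attr(tr, "unassigned")
    tr <- collapse_zero_branches(tr)
    attr(tr, "unassigned") <- un
    class(tr) <- c("pti_tree", "pti_node")
    tr
  })
  canon <- vapply(finished, canonical_form, character(1))
  finished <- finished[!duplicated(canon)]
  canon <- canon[!duplicated(canon)]
  weights <- vapply(finished, tree_weight, numeric(1))
  ord <- order(-weights, canon)
  finished <- finished[ord]; weights <- weights[ord]

  trunk <- rownames(M)[rowSums(Mp) == n]
  structure(list(
    trees = finished,
    weights = weights,
    optimal = finished[[1L]],
    multiple_solutions = length(finished) > 1L && weights[1L] == weights[2L],
    trunk_mutations = trunk,
    trunk_length = length(trunk),
    unassigned = attr(finished[[1L]], "unassigned"),
    dropped_rows = attr(M, "dropped"),
    n_samples = n,
    n_mutations = nrow(M)
  ), class = "pti_fit")
}

# Assign every mutation row to the highest node whose leaf set is contained
# in the row's carrier set; rows with several incomparable highest nodes
# (possible only for patterns inconsistent with the topology) stay
# unassigned. Rewrites node$mutations and node$length throughout the tree.
assign_mutations <- function(tree, Mp) {
  nodes <- list(); parents <- integer(0)
  walk <- function(node, parent_idx) {
    idx <- length(nodes) + 1L
    nodes[[idx]] <<- tree_leaves(node)
    parents[idx] <<- parent_idx
    for (ch in node$children) walk(ch, idx)
  }
  walk(tree, NA_integer_)
  nnod <- length(nodes)
  samples <- colnames(Mp)
  L <- matrix(0L, nnod, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(nnod)) L[i, nodes[[i]]] <- 1L

  # inside[i, r] = TRUE iff leaves(node i) subset of carriers of row r
  inside <- (L %*% t(1L - Mp)) == 0L
  cand <- inside
  has_par <- !is.na(parents)
  cand[has_par, ] <- inside[has_par, , drop = FALSE] &
    !inside[parents[has_par], , drop = FALSE]
  n_cand <- colSums(cand)
  target <- ifelse(n_cand == 1L,
                   max.col(t(cand * 1L), ties.method = "first"), NA_integer_)
  unassigned <- rownames(Mp)[is.na(target)]

  idx_counter <- 0L
  rewrite <- function(node) {
    idx_counter <<- idx_counter + 1L
    mine <- rownames(Mp)[!is.na(target) & target == idx_counter]
    node$mutations <- mine
    node$length <- length(mine)
    node$children <- lapply(node$children, rewrite)
    node
  }
  tree <- rewrite(tree)
  attr(tree, "unassigned") <- unassigned
  tree
}

#' Pick the optimal tree from an inference result
#'
#' Candidates are already ordered by decreasing tree weight with ties broken
#' by canonical form, so the optimum is the first tree; when several trees
#' share the top weight `multiple_solutions` is set on the fit.
#'
#' @param result A `pti_fit` from [infer_trees()] or [pti()].
#' @return The optimal `pti_tree`.
#' @export
select_optimal_tree <- function(result) {
  stopifnot(inherits(result, "pti_fit"))
  result$trees[[1L]]
}
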