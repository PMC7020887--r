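# Tree-structure similarity: proportion of leaves whose root-to-leaf
# clade path is identical between two trees.

#' Similarity between two tree topologies
#'
#' For each leaf the root-to-leaf path is encoded as the ordered sequence of
#' clades (descendant-leaf sets) of the nodes traversed; a leaf matches when
#' its sequences in the two trees are identical. The score is the proportion
#' of matching leaves and ranges from 0 (no leaf on an identical path) to 1
#' (identical topologies). Zero-length internal branches are collapsed in
#' both trees first, so binary and multifurcating encodings of the same
#' history score 1. Branch lengths are otherwise ignored.
#'
#' @param t1,t2 Trees with identical leaf-label sets: `pti_tree`,
#'   [ape::phylo], or Newick string/file.
#' @return List of class `pti_similarity` with `score`, `matched_paths`,
#'   `total_paths`, and `per_leaf_match` (named logical).
#' @examples
#' similarity_score("((a,b),(c,d));", "((a,c),(b,d));")$score  # 0
#' similarity_score("((a,b),c);", "(a,b,c);")$score            # 1/3
#' @export
similarity_score <- function(t1, t2) {
  t1 <- collapse_zero_branches(as_pti_tree(t1))
  t2 <- collapse_zero_branches(as_pti_tree(t2))
  l1 <- sort(tree_leaves(t1)); l2 <- sort(tree_leaves(t2))
  if (!identical(l1, l2)) {
    diff <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("trees have different leaf sets; differing labels: ",
         paste(diff, collapse = ", "))
  }
  paths <- function(node, prefix) {
    clade <- paste(sort(tree_leaves(node)), collapse = ",")
    acc <- c(prefix, clade)
    if (is_leaf(node)) {
      out <- list(paste(acc, collapse = "|"))
      names(out) <- node$label
      return(out)
    }
    do.call(c, lapply(node$children, paths, prefix = acc))
  }
  p1 <- paths(t1, character(0)); p2 <- paths(t2, character(0))
  leaves <- l1
  match <- vapply(leaves, function(l) identical(p1[[l]], p2[[l]]), logical(1))
  structure(list(score = mean(match), matched_paths = sum(match),
                 total_paths = length(leaves), per_leaf_match = match),
            class = "pti_similarity")
}

#' @export
print.pti_similarity <- function(x, ...) {
  cat(sprintf("Tree similarity: %.4g (%d of %d leaf paths identical)\n",
              x$score, x$matched_paths, x$total_paths))
  invisible(x)
}
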