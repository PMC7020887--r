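# Recursive list representation of a rooted mutation tree.
#
# Every node is a list with fields:
#   label     - sample id for leaves, NULL for internal nodes
#   children  - list of child nodes (empty for leaves, >= 2 otherwise)
#   mutations - character vector of mutation ids assigned to the branch
#               entering this node (the root's branch is the trunk)
#   length    - numeric branch length; equals length(mutations) for inferred
#               trees, or the edge length read from Newick (NA if absent)
# The root carries class "pti_tree" and, for inferred trees, an
# "unassigned" attribute with the mutations placed on no branch.

new_node <- function(label = NULL, children = list(), mutations = character(),
                     length = NULL) {
  if (is.null(length)) length <- base::length(mutations)
  structure(list(label = label, children = children,
                 mutations = mutations, length = as.numeric(length)),
            class = "pti_node")
}

is_leaf <- function(node) length(node$children) == 0L

#' Leaf labels of a tree or subtree
#'
#' @param tree A `pti_tree` (or internal node).
#' @return Character vector of leaf labels in tree order.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Canonical string form of a tree topology
#'
#' Serializes the topology (branch lengths and mutations ignored) with the
#' children of every node sorted by their lexicographically smallest
#' descendant leaf, so that isomorphic trees map to identical strings.
#' Used for deterministic tie-breaking among equally weighted candidate
#' trees and for equality assertions in tests.
#'
#' @param tree A `pti_tree`, an [ape::phylo] object, or a Newick string.
#' @return A single character string.
#' @examples
#' canonical_form("((b,a),c);") == canonical_form("((a,b),c);")
#' @export
canonical_form <- function(tree) {
  tree <- as_pti_tree(tree)
  canon <- function(node) {
    if (is_leaf(node)) return(node$label)
    parts <- vapply(node$children, canon, character(1))
    # smallest descendant leaf of a canonical subtree string is its first label
    keys <- vapply(node$children, function(ch) min(tree_leaves(ch)), character(1))
    paste0("(", paste(parts[order(keys)], collapse = ","), ")")
  }
  canon(tree)
}

#' Tree weight for tie-breaking among candidate trees
#'
#' Computes the aggregated mutation count
#' \deqn{W_T = \sum_{i=1}^{k}\sum_{j=1}^{N_i} \omega_{ij}\,\chi_{ij}}
#' over all internal non-root branches, where \eqn{\omega_{ij}} is the branch
#' length (number of mutations on the branch) and \eqn{\chi_{ij}} the number
#' of leaves the branch subtends. The root trunk is excluded because all
#' candidate trees for one patient share it; leaf branches subtend a single
#' leaf and are excluded as well. Larger weights indicate that more of the
#' mutation signal is concentrated on deep shared branches.
#'
#' @param tree A `pti_tree`, an [ape::phylo] object, or a Newick string with
#'   branch lengths.
#' @return A single numeric weight.
#' @examples
#' tree_weight("((a:1,b:1):2,(c:2,d:1):1):3;")  # 2*2 + 1*2 = 6
#' @export
tree_weight <- function(tree) {
  tree <- as_pti_tree(tree)
  w <- function(node, is_root) {
    if (is_leaf(node)) return(0)
    own <- 0
    if (!is_root) {
      len <- node$length
      if (is.na(len)) stop("internal branch without a length; cannot compute tree weight")
      own <- len * length(tree_leaves(node))
    }
    own + sum(vapply(node$children, w, numeric(1), is_root = FALSE))
  }
  w(tree, is_root = TRUE)
}

# Collapse internal non-root branches of zero length into their parent,
# yielding multifurcations. Leaves and the root are never collapsed.
collapse_zero_branches <- function(tree) {
  splice <- function(node) {
    if (is_leaf(node)) return(node)
    node$children <- lapply(node$children, splice)
    kept <- list()
    for (ch in node$children) {
      zero <- !is_leaf(ch) && !is.na(ch$length) && ch$length == 0
      if (zero) kept <- c(kept, ch$children) else kept <- c(kept, list(ch))
    }
    node$children <- kept
    node
  }
  splice(tree)
}

#' Coerce to the package's internal tree representation
#'
#' @param x A `pti_tree`, an [ape::phylo] object, or a character scalar
#'   holding a Newick string (or a path to a Newick file).
#' @param ... Unused.
#' @return A `pti_tree`.
#' @export
as_pti_tree <- function(x, ...) UseMethod("as_pti_tree")

#' @export
as_pti_tree.pti_tree <- function(x, ...) x

#' @export
as_pti_tree.pti_node <- function(x, ...) {
  class(x) <- c("pti_tree", "pti_node")
  x
}

#' @export
as_pti_tree.phylo <- function(x, ...) {
  n_tip <- length(x$tip.label)
  root <- n_tip + 1L
  kids <- split(x$edge[, 2L], x$edge[, 1L])
  elen <- x$edge.length
  build <- function(id, len) {
    if (id <= n_tip) return(new_node(label = x$tip.label[id], length = len))
    ch_ids <- kids[[as.character(id)]]
    children <- lapply(ch_ids, function(cid) {
      e <- which(x$edge[, 2L] == cid)
      build(cid, if (is.null(elen)) NA_real_ else elen[e])
    })
    new_node(children = children, length = len)
  }
  root_len <- if (is.null(x$root.edge)) NA_real_ else x$root.edge
  tr <- build(root, root_len)
  class(tr) <- c("pti_tree", "pti_node")
  tr
}

#' @export
as_pti_tree.character <- function(x, ...) {
  stopifnot(length(x) == 1L)
  ph <- if (grepl(";", x, fixed = TRUE)) ape::read.tree(text = x) else ape::read.tree(x)
  if (is.null(ph)) stop("could not parse Newick input")
  as_pti_tree(ph)
}

#' Convert an inferred tree to an ape "phylo" object
#'
#' Branch lengths are mutation counts; the root trunk length is stored in
#' the `root.edge` component.
#'
#' @param x A `pti_tree`.
#' @param ... Unused.
#' @return An object of class [ape::phylo].
#' @importFrom ape as.phylo
#' @export
as.phylo.pti_tree <- function(x, ...) {
  leaves <- tree_leaves(x)
  n_tip <- length(leaves)
  if (n_tip == 1L) stop("cannot convert a single-leaf tree to phylo")
  edges <- list(); elens <- numeric(0)
  next_internal <- n_tip + 1L
  walk <- function(node, parent_id) {
    if (is_leaf(node)) {
      id <- match(node$label, leaves)
    } else {
      id <- next_internal; next_internal <<- next_internal + 1L
    }
    if (!is.na(parent_id)) {
      edges[[length(edges) + 1L]] <<- c(parent_id, id)
      elens[length(elens) + 1L] <<- node$length
    }
    if (!is_leaf(node)) for (ch in node$children) walk(ch, id)
    id
  }
  walk(x, NA_integer_)
  edge <- do.call(rbind, edges)
  ph <- list(edge = edge, tip.label = leaves,
             Nnode = next_internal - n_tip - 1L)
  if (!all(is.na(elens))) ph$edge.length <- ifelse(is.na(elens), 0, elens)
  if (!is.na(x$length)) ph$root.edge <- x$length
  class(ph) <- "phylo"
  ape::reorder.phylo(ph, "cladewise")
}

#' Tabulate the branches of a tree
#'
#' @param tree A `pti_tree`.
#' @return A data frame with one row per node (branch entering the node):
#'   `node_id`, `parent_id` (NA for the root), `leaf_set` (comma-joined),
#'   `branch_length`, and `mutation_ids` (comma-joined, possibly empty).
#' @export
branch_table <- function(tree) {
  tree <- as_pti_tree(tree)
  rows <- list()
  walk <- function(node, parent) {
    id <- if (is_leaf(node)) node$label else
      paste0("n_", paste(sort(tree_leaves(node)), collapse = "."))
    rows[[length(rows) + 1L]] <<- data.frame(
      node_id = id, parent_id = if (is.null(parent)) NA_character_ else parent,
      leaf_set = paste(sort(tree_leaves(node)), collapse = ","),
      branch_length = node$length,
      mutation_ids = paste(node$mutations, collapse = ","),
      stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, id)
  }
  walk(tree, NULL)
  do.call(rbind, rows)
}

#' @export
print.pti_tree <- function(x, ...) {
  cat("Rooted mutation tree with", length(tree_leaves(x)), "leaves\n")
  draw <- function(node, prefix, head) {
    len <- if (is.na(node$length)) "" else paste0(" [", node$length, "]")
    lab <- if (is_leaf(node)) node$label else "+"
    cat(prefix, head, lab, len, "\n", sep = "")
    nch <- length(node$children)
    for (i in seq_len(nch)) {
      last <- i == nch
      draw(node$children[[i]],
           paste0(prefix, if (nzchar(head)) (if (grepl("`", head)) "    " else "|   ") else ""),
           if (last) "`-- " else "|-- ")
    }
  }
  draw(x, "", "")
  un <- attr(x, "unassigned")
  if (!is.null(un) && length(un))
    cat("unassigned mutations:", length(un), "\n")
  invisible(x)
}
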