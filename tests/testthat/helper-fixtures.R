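# Fixture builders and independent oracles used across the suite.

# binary matrix from a list of carrier sets, e.g. list(ab = c("a","b"), ...)
# names give one row per entry; a count suffix "xN" repeats the pattern.
make_matrix <- function(patterns, samples) {
  m <- length(patterns)
  M <- matrix(0L, m, length(samples),
              dimnames = list(sprintf("r%02d", seq_len(m)), samples))
  for (i in seq_len(m)) M[i, patterns[[i]]] <- 1L
  M
}

random_binary_matrix <- function(m, n, p = 0.4, drop_empty = TRUE) {
  M <- matrix(rbinom(m * n, 1L, p), m, n,
              dimnames = list(sprintf("r%03d", seq_len(m)), paste0("s", seq_len(n))))
  if (drop_empty) M <- M[rowSums(M) > 0L, , drop = FALSE]
  M
}

# Oracle 1: shared-mutation count by explicit per-sample set intersection.
oracle_shared_count <- function(M, group) {
  sets <- lapply(group, function(s) rownames(M)[M[, s] == 1L])
  length(Reduce(intersect, sets))
}

# Oracle 2: root trunk by an explicit per-row all() scan.
oracle_trunk <- function(M) {
  rownames(M)[apply(M == 1L, 1L, all)]
}

# Randomly permute the child order of every node of a tree.
shuffle_children <- function(tree) {
  sh <- function(node) {
    if (length(node$children)) {
      node$children <- node$children[sample(length(node$children))]
      node$children <- lapply(node$children, sh)
    }
    node
  }
  sh(tree)
}

# Asymmetric split-ratio tie fixture (verified by hand): rows abc, ad,
# ab, ab, b over samples a..d. Split sizes t = 1 ({a,b,c}|{d}, theta 1)
# and t = 2 ({a,d}|{b,c}, theta 1) both attain ratio Inf, spawning two
# candidate trees: (((a,b),c),d) with W = 1*3 + 2*2 = 7 and, after the
# unsupported {b,c} branch collapses, ((a,d),b,c) with W = 1*2 = 2.
tie_fixture <- function() {
  make_matrix(list(c("a", "b", "c"), c("a", "d"), c("a", "b"),
                   c("a", "b"), "b"),
              letters[1:4])
}

# Mirror-image tie fixture: three mutations shared by {a,b,c} and three by
# {a,b,d}; splitting off d or c is equally supported (theta 3 each), and the
# two resulting trees have equal weight 9.
mirror_fixture <- function() {
  make_matrix(rep(list(c("a", "b", "c"), c("a", "b", "d")), each = 3L),
              letters[1:4])
}

sum_branch_lengths <- function(tree) {
  s <- function(node) node$length + sum(vapply(node$children, s, numeric(1)))
  s(tree)
}
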