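# Split statistics, optimal split selection, full inference, tree weight.

test_that("shared_count is an intersection count with no exclusivity", {
  M <- make_matrix(list(c("a","b"), c("a","c"), c("a","b","c")), c("a","b","c"))
  expect_equal(shared_count(M, c("a", "b")), 2L)
  expect_equal(shared_count(M, "a"), 3L)          # singleton group
  expect_error(shared_count(M, c("a", "zz")), "zz")
})

test_that("shared_count matches the set-intersection oracle on all 2-subsets", {
  set.seed(21)
  M <- random_binary_matrix(50, 5)
  pairs <- combn(colnames(M), 2L)
  for (k in seq_len(ncol(pairs)))
    expect_equal(shared_count(M, pairs[, k]), oracle_shared_count(M, pairs[, k]))
})

test_that("split sizes enumerate 1..floor(n/2)", {
  expect_equal(enumerate_split_sizes(6), 1:3)
  expect_equal(enumerate_split_sizes(7), 1:3)
  expect_equal(enumerate_split_sizes(2), 1L)
  expect_error(enumerate_split_sizes(1), "at least 2")
})

test_that("split ratio follows the zero-denominator rules", {
  expect_equal(split_ratio(c(10, 2, 1))$ratio, 5)
  expect_equal(split_ratio(c(10, 2, 1))$theta_sec_max, 2)
  expect_equal(split_ratio(c(4, 0, 0))$ratio, Inf)
  expect_equal(split_ratio(c(0, 0))$ratio, 0)
  expect_equal(split_ratio(7)$ratio, Inf)   # single candidate, positive
})

test_that("split-size evaluation matches hand enumeration on the planted 4-sample case", {
  # mutations: ab x2, cd x1, a x1, b x1, c x1
  M <- make_matrix(list(c("a","b"), c("a","b"), c("c","d"), "a", "b", "c"),
                   letters[1:4])
  ev2 <- evaluate_split_size(mutation_matrix(M), 2)
  expect_equal(sort(ev2$theta, decreasing = TRUE), c(1, 0, 0))
  expect_equal(ev2$ratio, Inf)     # ab|cd: min(2, 1) = 1; others 0
  ev1 <- evaluate_split_size(mutation_matrix(M), 1)
  expect_equal(ev1$theta, rep(0, 4))
  expect_equal(ev1$ratio, 0)
  sp <- find_optimal_splits(mutation_matrix(M))
  expect_length(sp, 1L)
  expect_setequal(sp[[1]]$group, c("a", "b"))
  expect_setequal(sp[[1]]$complement, c("c", "d"))
})

test_that("balanced bipartitions are enumerated once and scored by the min rule", {
  M <- make_matrix(list(c("a","b"), c("c","d"), c("c","d")), letters[1:4])
  ev <- evaluate_split_size(mutation_matrix(M), 2)
  expect_length(ev$candidates, 3L)   # C(4,2)/2 unordered bipartitions
  th <- vapply(ev$candidates, `[[`, numeric(1), "theta")
  expect_equal(sort(th, decreasing = TRUE), c(1, 0, 0))  # min(1, 2) = 1
})

test_that("two samples split without evaluation", {
  M <- make_matrix(list("x", "y", c("x","y")), c("x", "y"))
  sp <- find_optimal_splits(mutation_matrix(M))
  expect_length(sp, 1L)
  fit <- infer_trees(M)
  expect_equal(canonical_form(fit$optimal), "(x,y)")
  expect_equal(fit$trunk_length, 1L)
})

test_that("tree weight reproduces the hand-derived worked examples", {
  expect_equal(tree_weight("((a:1,b:1):2,(c:2,d:1):1):3;"), 6)
  expect_equal(tree_weight("(((a:1,b:1):1,c:1):2,d:1):3;"), 8)
  # star tree: no internal non-root branch
  M <- make_matrix(list("a", "b", "c"), c("a", "b", "c"))
  expect_equal(tree_weight(infer_trees(M)$optimal), 0)
})

test_that("noise-free perfect phylogenies are recovered exactly", {
  # explicit construction: ((a,b),(c,d)) with every branch occupied
  pats <- c(rep(list(c("a","b","c","d")), 3), rep(list(c("a","b")), 2),
            list(c("c","d")), list("a"), list("b"),
            rep(list("c"), 2), list("d"))
  M <- make_matrix(pats, letters[1:4])
  fit <- infer_trees(M)
  expect_length(fit$trees, 1L)
  expect_equal(canonical_form(fit$optimal), "((a,b),(c,d))")
  expect_equal(fit$trunk_length, 3L)
  expect_length(fit$unassigned, 0L)
  tb <- branch_table(fit$optimal)
  lens <- setNames(tb$branch_length, tb$leaf_set)
  expect_equal(lens[["a,b"]], 2)
  expect_equal(lens[["c,d"]], 1)
  expect_equal(lens[["c"]], 2)
})

test_that("all-private input collapses to a star multifurcation", {
  M <- make_matrix(list("a", "b", "c"), c("a", "b", "c"))
  fit <- infer_trees(M)
  expect_length(fit$trees, 1L)
  expect_equal(canonical_form(fit$optimal), "(a,b,c)")
  expect_length(fit$optimal$children, 3L)
})

test_that("tied optima spawn candidate trees arbitrated by tree weight", {
  fit <- infer_trees(tie_fixture())
  expect_gte(length(fit$trees), 2L)
  expect_equal(fit$weights[1:2], c(7, 2))
  expect_equal(canonical_form(fit$optimal), "(((a,b),c),d)")
  expect_equal(canonical_form(fit$trees[[2]]), "((a,d),b,c)")
  expect_false(fit$multiple_solutions)
})

test_that("mirror-image ties give equally weighted multiple solutions", {
  fit <- infer_trees(mirror_fixture())
  expect_gte(length(fit$trees), 2L)
  expect_equal(fit$weights[1:2], c(9, 9))
  expect_true(fit$multiple_solutions)
  canon <- vapply(fit$trees, canonical_form, character(1))
  expect_true(all(c("((a,b,c),d)", "((a,b,d),c)") %in% canon))
  expect_equal(canon[1], "((a,b,c),d)")  # deterministic canonical ordering
})

test_that("mutation accounting is exact on noisy random inputs", {
  set.seed(31)
  for (i in 1:20) {
    sc <- sim_scenario(sample(3:7, 1), branch_rate = 6,
                       fn_rate = 0.1, fp_rate = 0.02, seed = i)
    M <- realize_matrix(sc)
    fit <- infer_trees(M)
    for (tr in fit$trees)
      expect_equal(sum_branch_lengths(tr) + length(attr(tr, "unassigned")) +
                     fit$dropped_rows, attr(M, "total_rows"))
  }
})

test_that("inference is deterministic and invariant to column permutation", {
  set.seed(41)
  sc <- sim_scenario(6, branch_rate = 8, fn_rate = 0.05, seed = 99)
  M <- realize_matrix(sc)
  f1 <- infer_trees(M)
  f2 <- infer_trees(M)
  expect_identical(canonical_form(f1$optimal), canonical_form(f2$optimal))
  Mp <- unclass(M)[, sample(ncol(M))]
  f3 <- infer_trees(Mp)
  expect_identical(canonical_form(f1$optimal), canonical_form(f3$optimal))
  expect_identical(f1$weights, f3$weights)
})

test_that("the true first split attains the strictly largest ratio on perfect input", {
  set.seed(51)
  for (i in 1:25) {
    sc <- sim_scenario(sample(4:8, 1), branch_rate = 6, seed = i)
    M <- realize_matrix(sc)
    tr <- extract_root_trunk(M)
    planted <- attr(M, "planted_tree")
    first <- sort(vapply(planted$children, function(ch)
      length(tree_leaves(ch)), integer(1)))[1]
    n <- ncol(M)
    ratios <- vapply(enumerate_split_sizes(n), function(t)
      evaluate_split_size(tr$filtered, t)$ratio, numeric(1))
    t_true <- min(first, n - first)
    expect_equal(which(ratios == max(ratios)), t_true)
  }
})

test_that("oversized nodes hit the combinatorial guard", {
  M <- matrix(1L, 2, 26,
              dimnames = list(c("r1", "r2"), paste0("s", 1:26)))
  M[2, 1] <- 0L
  expect_error(find_optimal_splits(M), "26 samples")
})
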