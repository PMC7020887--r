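# Planted-tree generator: topology sampling, matrix realization, noise.

test_that("topology sampling is deterministic per seed and forced at n = 2", {
  expect_equal(canonical_form(sample_topology(2, seed = 5)), "(s1,s2)")
  t1 <- sample_topology(6, seed = 7)
  t2 <- sample_topology(6, seed = 7)
  expect_identical(canonical_form(t1), canonical_form(t2))
  expect_setequal(tree_leaves(t1), paste0("s", 1:6))
})

test_that("topology sampling is uniform over labeled rooted binary shapes", {
  # n = 4 has (2*4-3)!! = 15 topologies; frequencies should be uniform
  set.seed(71)
  canon <- vapply(1:3000, function(i) canonical_form(sample_topology(4)),
                  character(1))
  tab <- table(canon)
  expect_equal(length(tab), 15L)
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})

test_that("noise-free realization is a perfect phylogeny with exact bookkeeping", {
  for (seed in c(3, 17, 40)) {
    sc <- sim_scenario(5, branch_rate = 7, seed = seed)
    M <- realize_matrix(sc)
    counts <- attr(M, "branch_counts")
    expect_equal(attr(M, "total_rows"), sum(counts))
    expect_equal(nrow(M) + attr(M, "dropped"), sum(counts))
    expect_equal(attr(M, "dropped"), 0L)       # no all-zero rows without noise
    expect_true(all(counts >= 1L))             # +1 floor on every branch
    # root-branch rows are exactly the trunk
    trunk <- extract_root_trunk(M)
    key <- paste(sort(colnames(M)), collapse = ",")
    expect_equal(trunk$trunk_length, unname(counts[key]))
    # round trip
    fit <- infer_trees(M)
    expect_length(fit$trees, 1L)
    expect_equal(similarity_score(fit$optimal, attr(M, "planted_tree"))$score, 1)
    tb <- branch_table(fit$optimal)
    expect_equal(sort(tb$branch_length), sort(unname(counts)))
  }
})

test_that("false-negative noise degrades recovery monotonically on average", {
  rate_at <- function(fn) {
    hits <- 0L
    for (seed in 1:40) {
      sc <- sim_scenario(5, branch_rate = 8, fn_rate = fn, seed = seed)
      M <- realize_matrix(sc)
      s <- similarity_score(infer_trees(M)$optimal, attr(M, "planted_tree"))$score
      hits <- hits + (s == 1)
    }
    hits / 40
  }
  r <- vapply(c(0, 0.05, 0.25), rate_at, numeric(1))
  expect_equal(r[1], 1)
  expect_true(r[1] >= r[2] && r[2] >= r[3])
})

test_that("a two-subclone sample is placed with the clade contributing more mutations", {
  planted <- as_pti_tree("((x,a),(b,c));")
  groups_with <- function(f, seed) {
    sc <- sim_scenario(4, branch_rate = 20, seed = seed, tree = planted,
                       mixed_sample = list(sample = "x", clade = c("b", "c"),
                                           fraction = f))
    M <- realize_matrix(sc)
    sets <- strsplit(branch_table(infer_trees(M)$optimal)$leaf_set, ",")
    has <- function(want, avoid) any(vapply(sets, function(s)
      all(want %in% s) && !any(avoid %in% s) && length(s) < 4, logical(1)))
    c(own = has(c("x", "a"), c("b", "c")), second = has("x", "a"))
  }
  own <- mean(vapply(1:25, function(s) groups_with(0.15, s)["own"], logical(1)))
  second <- mean(vapply(1:25, function(s) groups_with(0.85, s)["second"], logical(1)))
  expect_gte(own, 0.9)     # below the balance point: stays with its own clade
  expect_gte(second, 0.9)  # above it: placement flips to the second clade
})

test_that("scenario validation rejects inconsistent mixing specs", {
  expect_error(sim_scenario(4, mixed_sample = list(sample = "s1",
                                                   clade = c("s1", "s2"),
                                                   fraction = 0.5), seed = 1))
  expect_error(sim_scenario(1), "n_samples")
})
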